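---
title: "Methods: directional PageRank of signal-flow protein networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: directional PageRank of signal-flow protein networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pprank)
```

## The model and its assumptions

A signal-directional interactome is a directed graph: an edge A → B
asserts that information flows from protein A to protein B, here taken
from an edge table where a protein interaction directional score (PIDS)
strictly greater than 2.0 asserts the direction. The package treats the
assertion *qualitatively*: every retained interaction enters the adjacency
matrix `A` with weight 1, duplicate (source, target) rows collapse to one
edge, and PIDS magnitudes are discarded after filtering. The filter is
strict (`pids > 2.0`); a row at exactly 2.0 is excluded.

Three row-stochastic walk matrices are derived from `A`:

* **forward** — `N[i, j] = 1/outdeg(i)` for each edge i → j: the walker
  follows signal flow, so stationary mass accumulates on proteins that
  *receive* information from many (and from important) sources;
* **reverse** — the same construction on the transposed adjacency: mass
  accumulates on proteins whose influence *reaches* many others, the
  emitters/regulators;
* **undirected** — `A` is symmetrised (distinct neighbour sets; a
  reciprocal A→B/B→A pair becomes a single undirected edge) and rows are
  normalised by degree.

The ranking is the stationary distribution of the damped chain
`M = α·N + (1 − α)/n·J` — the principal left eigenvector of `M` for
eigenvalue 1 — with the conventional damping `α = 0.85`. The walk
interpretation: with probability α the explorer follows a uniformly
random outgoing link; with probability 1 − α it jumps to a uniformly
random protein. By Kac's identity the stationary probability of a node is
the reciprocal of the expected number of steps between visits, which is
the package's independent simulation check (`random_surfer()`,
`mean_return_time()`).

One wording ambiguity deserves a note: "non-directional" ranking is
sometimes loosely described as an *average* ranking, but it is not the
mean of forward and reverse scores. It is PageRank on the symmetrised
network, and at α = 1 it has the closed form `degree/2m` — it tracks the
number of interactions. The package implements the symmetric-adjacency
definition; the degree closed form is asserted in the acceptance suite.

## Dangling nodes: two defensible policies

Proteins with no outgoing links in the chosen direction leave the walk
matrix with a zero row. Two resolutions are in circulation and they give
different stationary vectors, so the package implements both and records
the choice in every output:

* `stay` (default): the explorer "stays where it is" — a self-loop. This
  follows the walk description the method is usually motivated by. A
  dangling node then keeps the mass that reaches it, except for teleport
  leakage: on the single edge A → B the stationary pair is
  (0.075, 0.925) at α = 0.85.
* `teleport`: the zero row is replaced by the uniform row 1/n, the
  convention of most web-scale implementations. The same single edge
  gives (0.351, 0.649).

Which policy a given historical implementation used is generally not
recoverable from published text (the "extra scaling factor for the
degenerate cases" covers either reading), hence the dual exposure rather
than a single hard-coded rule. Isolated nodes in undirected mode are
dangling rows and follow the same policy.

## Numerical choices

* Power iteration starts from the uniform vector and stops when the L1
  change between iterates falls below `tol = 1e-12` (`max_iter = 1000`).
  Each sweep is a sparse matrix–vector product plus the rank-one uniform
  correction; the dense matrix `J` is never formed. The result is
  verified against a dense eigen-decomposition oracle at 1e-10 in the
  acceptance suite.
* At α = 1 on a periodic chain the iteration may legitimately oscillate;
  the result is then returned with `converged = FALSE` plus a warning
  rather than an error, and the command-line `rank` maps it to exit
  status 3.
* Rank positions sort by descending score with ties broken
  lexicographically by protein identifier (C collation), so listings are
  reproducible across platforms and runs.
* Scores are written to TSV with 17 significant digits; a write/read
  round trip reproduces the ranking to machine precision.

## Comparison statistics

`correlate_rankings()` computes Pearson or Spearman correlation either on
raw stationary scores or on rank positions; both conventions appear in
the literature and published r values rarely state which was used, so the
basis is an explicit argument and is recorded in output. The Pearson
p-value uses the t transform with n − 2 degrees of freedom. For small
panels a *seeded Monte-Carlo permutation* p-value is available
(`p_method = "permutation"`): full enumeration of n! permutations is
infeasible already at n ≈ 15, so the package draws `n_perm` random
permutations and applies the add-one estimator — a deliberate design
choice over an "exact" test that could not be computed.

The middle group of `extract_groups()` is the symmetric window of k
proteins starting at position `floor((n − k)/2) + 1`; published
top/mid/bottom panels never state which k were "middle", so the centred
window is fixed here and documented. `fold_ratio()` divides the mean
score of the top k by the mean of the bottom k; it is invariant under
uniform rescaling and ≥ 1 by construction.

## ANOVA, Duncan letters, and the ratio chi-square

Group summaries (mean BLAST bit score, mean protein length per
top/mid/bottom panel) are compared with a classical one-way fixed-effects
ANOVA and Duncan's multiple-range test. Duncan's critical range for a
stretch of p consecutive ordered means is
`R_p = q*(α_p, p, df) · sqrt(MSE/n_h)` with protection level
`α_p = 1 − (1 − α)^(p−1)`; the studentized-range quantile `q*` comes from
R's `qtukey`, so no table interpolation or custom CDF inversion is
needed. Sub-stretches of an accepted (homogeneous) stretch are not
re-tested, and the compact letter display assigns one letter per maximal
homogeneous stretch. For two groups the procedure reduces to an LSD-style
t test at level α, which is what the null-calibration test asserts
(~95% same-letter rate). Unequal group sizes use the harmonic mean `n_h`
— relevant because proteins without a BLAST hit are *excluded* from their
group (dropping n from 50 to 49, say) rather than zero-filled; the
exclusion count is reported per group.

Category fractions are emitted under both denominators in circulation —
percent of group members with any known pathway, and percent of all group
members — because published category tables mix the two conventions
across columns.

The location cross-tab counts nucleus, cytoplasm, membrane and
"in both nucleus and another" flags (a protein may carry several). The
accompanying test is the spreadsheet-style 1-df goodness-of-fit
chi-square of one ranking's top/bottom counts against a reference
ranking's top/bottom ratio, without continuity correction
(`ratio_chisq()`); it is exactly zero whenever the observed counts are
proportional to the reference.

## What the synthetic generator emulates — and what it does not

`generate_network()` builds the world the directional analyses assume:
**few key emitters, relatively even receivers**. Each of `n_emitters`
emitters (default 5 of 500) opens `emitter_fanout = 3` relay chains of
length `relay_depth = 3`; each chain tail fans into `emitter_fanout`
receivers; receivers additionally get `Poisson(receiver_in_mean = 2)`
in-edges from random non-emitter sources; iid background edges
(`background_edge_prob = 0.002`) are drawn among receiver pairs; and
`n_feedback_motifs = 5` node-disjoint directed cycles of length 3–5 are
injected among receivers. Everything derives from one integer seed.

Two structural choices matter and were made deliberately:

* *Background and Poisson edges never originate at emitters*, so a
  planted emitter's direct out-degree is exactly `emitter_fanout` — the
  point being emulated is that key regulators need not talk to many
  proteins directly.
* *Background edges are confined to the receiver pool.* Early drafts
  allowed background edges into relay chains; the extra reversed-graph
  out-edges on relays then split the cascade flow and emitters stopped
  dominating the reverse ranking — the generator no longer produced the
  structure it claims to plant. Similarly, letting chain tails own large
  receiver partitions made tails themselves hubs (out-degree ≈ 30) and
  inverted the intended correlation asymmetry; the modest tail fan fixes
  both. These are generator design decisions, not tuned thresholds: the
  recovery and evenness properties are asserted afterwards at the
  spec-level sizes (emitter recall ≥ 0.9 in the reverse top 10 over 20
  seeds; Spearman between forward score and in-degree > 0.7, with the
  reverse-vs-out-degree correlation materially lower).

`generate_annotations()` plants a conservation gradient:
`bits = bits_base + bits_slope · importance + N(0, bits_sd)` truncated at
0, with importance 2/1/0 for emitter/relay/receiver (defaults 180 + 70 ·
importance ± 40, which puts group means in the realistic few-hundred-bits
range and separates a 50-member top panel from the bottom panel
decisively but not degenerately). Protein lengths are log-normal (median
500 aa, sdlog 0.45). Location flags are Bernoulli with role-dependent
defaults that make receivers more nuclear and emitters more
membrane/cytoplasmic; pathway labels (`signalling`, `MAPK`,
`known_pathway`) are enriched among emitters and relays. E-values are
derived from bit scores (`1e9 · 2^-bits`, capped at 10) rather than drawn
independently.

What the generator does **not** emulate: the degree distribution of any
real interactome (no scale-free tail), literature ascertainment bias,
pathway co-membership structure, or correlated multi-location patterns.
A green pipeline test therefore establishes that the machinery recovers
planted structure of the stated shape — not that any biological claim
about a real interactome is reproduced. In particular, published
dataset-specific values (correlations between ranking methods, fold
ratios, overlap counts, table cell values) depend on an external
interactome supplement and are deliberately *not* targets anywhere in the
package.

## Known limitations

* PIDS magnitudes are unused beyond the 2.0 filter; a weighted ranking
  that exploits them quantitatively is out of scope.
* No personalised/topic-sensitive variants.
* The Monte-Carlo surfer is plain R and sequential by nature; it is an
  oracle for small graphs (10^6 steps in seconds), not a production
  ranking path.
* `duncan_mrt()` requires every group to have at least two observations;
  singleton groups have no within-group variance to contribute.
* The permutation p-value is Monte-Carlo, not exact; its resolution is
  1/(n_perm + 1).
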