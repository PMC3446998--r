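# pprank — directional PageRank analysis of protein interaction networks

`pprank` ranks proteins in a *signal-directional* protein–protein
interaction network. Most interactome rankings ignore which way
information flows along an interaction; when a direction is available —
asserted by a protein interaction directional score (PIDS), where
PIDS > 2.0 for the ordered pair (A, B) means signal flows A → B — three
distinct stationary-distribution rankings become possible, and they answer
different biological questions:

| Ranking | Walk direction | High scores mark |
|---|---|---|
| **forward** | along signal flow | broad information **receivers** ("authorities") |
| **reverse** | against signal flow | broad information **emitters**/regulators ("hubs") |
| **undirected** | symmetrised network | proteins with many interactions |

## The model

Let `A` be the 0/1 adjacency matrix of the directed network (interactions
are unweighted; duplicate pairs collapse, self-interactions are dropped).
Let `N` be `A` with each row divided by its out-degree, rows with zero
out-degree resolved by a *dangling policy* — `stay` (the random walker
stays put, the default) or `teleport` (uniform 1/n row). The scaled chain
is

```
M = α · N + (1 − α)/n · J ,   α = 0.85 by default
```

and a protein's score is its entry in the stationary vector of `M` (the
principal left eigenvector, eigenvalue 1), computed by power iteration
from the uniform start to an L1 tolerance of 1e-12. The reverse ranking
applies the same construction to the transposed adjacency matrix; the
undirected ranking symmetrises `A` and normalises by degree (at α = 1 it
reduces exactly to `degree/2m`). By Kac's identity the score is the
reciprocal of the walker's expected return time, which the package can
verify by direct simulation (`random_surfer()`, `mean_return_time()`).

Downstream, the package provides the standard comparison battery for such
rankings: Pearson/Spearman correlations between methods (on scores or
positions), top-k overlaps and three-way common sets, top-vs-bottom fold
ratios, conservation summaries (mean BLASTp bit score and protein length
per top/mid/bottom group, with one-way ANOVA and Duncan's multiple-range
test letters), pathway-category fractions, and subcellular-location
cross-tabs with a 1-df ratio chi-square test.

Because real signal-directional interactomes live in third-party
supplements, the package ships a seeded synthetic generator
(`synthetic_spec()`, `generate_network()`, `generate_annotations()`) that
plants the structure these analyses assume: a handful of key emitters
driving relay cascades into a large, evenly wired receiver pool, plus
feedback cycles, a conservation gradient that rises with planted
importance, and role-correlated subcellular locations.

## Worked example

```r
library(pprank)

g   <- generate_network(synthetic_spec(seed = 1))   # 500 proteins, 5 emitters
net <- g$network
#> interaction_network: 499 proteins, 1401 directed edges

rev <- pagerank(build_transition(net, "reverse"))
rev
#> ranking_result (reverse): 499 proteins, alpha=0.85, converged in 85 iterations
#> top: P0471, P0129, P0167, P0418, P0324

g$roles$protein_id[g$roles$role == "emitter"]
#> [1] "P0129" "P0167" "P0324" "P0418" "P0471"
```

The five planted emitters occupy reverse ranks 1–5: regulators with only
three direct out-links each dominate the emitter ranking through their
cascades. Comparing methods and summarising conservation:

```r
fwd <- pagerank(build_transition(net, "forward"))
und <- pagerank(build_transition(net, "undirected"))

correlate_rankings(fwd, und, "spearman", "position")
#> comparison_stats: spearman on position, n=499, r=0.3401, p=5.657e-15
fold_ratio(rev, 50)   # top-50 mean score / bottom-50 mean score
#> [1] 31.16

ann <- generate_annotations(g$roles, seed = 1)
group_conservation_summary(extract_groups(rev, 50), ann)
#> group_summary (reverse ranking):
#>   group  n n_excluded mean_bits letter_bits mean_length letter_length
#>     top 50          0  218.2438           A      544.96             A
#>     mid 50          0  195.1680           B      498.60             A
#>  bottom 50          0  176.8729           B      561.92             A
#> ANOVA bits:   F=9.966 p=8.731e-05
#> ANOVA length: F=0.7274 p=0.4849
```

Top-ranked emitters carry significantly higher BLAST bit scores (letter A
vs B) — the planted conservation gradient is recovered — while protein
length shows no signal, as designed.

## Command line

```sh
PPRANK=$(Rscript -e 'cat(system.file("exec/pprank", package = "pprank"))')
Rscript $PPRANK simulate  --out-dir fixtures --seed 1
Rscript $PPRANK rank      --input fixtures/edges.tsv --out-dir rankings
Rscript $PPRANK compare   --inputs rankings/ranking_forward.tsv,rankings/ranking_reverse.tsv,rankings/ranking_undirected.tsv --out compare.tsv
Rscript $PPRANK summarize --ranking rankings/ranking_reverse.tsv \
    --reference rankings/ranking_forward.tsv \
    --annotations fixtures/annotations.tsv --out-dir summaries
```

Exit codes: 0 ok, 2 input error, 3 convergence failure. All outputs are
TSV with `# key=value` provenance headers.

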