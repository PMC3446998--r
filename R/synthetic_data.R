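# Seeded synthetic interactomes with planted structure: a handful of
# high-influence emitters feeding relay chains that fan out into a large,
# evenly-wired receiver pool, plus feedback cycles and background noise.
# Annotations plant a conservation gradient (bit score rising with
# importance) and role-correlated subcellular locations, so every
# downstream summary has a known ground truth.

#' Specification of a synthetic directed interactome
#'
#' @param n_nodes Total number of proteins.
#' @param n_emitters Number of planted emitters (key regulators).
#' @param emitter_fanout Direct out-edges per emitter; each starts a relay
#'   chain, so an emitter's out-degree is exactly this value.
#' @param relay_depth Length of each relay chain (regulator cascade).
#' @param receiver_in_mean Mean of the Poisson number of extra in-edges a
#'   background receiver gets from random non-emitter sources. Default 2,
#'   a sparse, signalling-like wiring density.
#' @param background_edge_prob Probability of each background directed
#'   edge among non-emitter ordered pairs (emitters are excluded as
#'   background sources so their out-degree stays at `emitter_fanout`).
#' @param n_feedback_motifs Number of node-disjoint directed cycles
#'   (length 3-5) injected among receivers.
#' @param seed Integer seed driving the whole construction.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_nodes = 500L, n_emitters = 5L,
                           emitter_fanout = 3L, relay_depth = 3L,
                           receiver_in_mean = 2, background_edge_prob = 0.002,
                           n_feedback_motifs = 5L, seed = 1L) {
  spec <- list(n_nodes = as.integer(n_nodes),
               n_emitters = as.integer(n_emitters),
               emitter_fanout = as.integer(emitter_fanout),
               relay_depth = as.integer(relay_depth),
               receiver_in_mean = receiver_in_mean,
               background_edge_prob = background_edge_prob,
               n_feedback_motifs = as.integer(n_feedback_motifs),
               seed = as.integer(seed))
  if (spec$n_nodes < 2L) stop("n_nodes must be >= 2")
  if (spec$n_emitters >= spec$n_nodes) stop("n_emitters must be < n_nodes")
  if (spec$receiver_in_mean < 0) stop("receiver_in_mean must be >= 0")
  if (spec$background_edge_prob < 0 || spec$background_edge_prob > 1) {
    stop("background_edge_prob must be in [0, 1]")
  }
  if (spec$n_emitters > 0L && (spec$emitter_fanout < 1L || spec$relay_depth < 1L)) {
    stop("emitter_fanout and relay_depth must be >= 1 when emitters are planted")
  }
  class(spec) <- "synthetic_spec"
  spec
}

#' Generate a synthetic directed network with planted roles
#'
#' Construction, all from one seeded stream: each emitter opens
#' `emitter_fanout` relay chains of length `relay_depth`; chain tails
#' partition the receiver pool among themselves (so every receiver hangs
#' off exactly one regulator cascade); receivers then get
#' `Poisson(receiver_in_mean)` extra in-edges from random non-emitter
#' sources; background directed edges are added iid among non-emitter
#' ordered pairs; finally `n_feedback_motifs` node-disjoint directed
#' cycles of length 3-5 are injected among receivers. Emitters therefore
#' keep a *small* direct out-degree while dominating reverse (emitter)
#' PageRank through their cascades — few key emitters, relatively even
#' receivers.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `network` ([interaction_network()]), `roles` (data
#'   frame `protein_id`, `role` in emitter/relay/receiver, `importance`
#'   2/1/0) and `pids` (simulated directional scores aligned with
#'   `network$edges`, all > 2).
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_nodes
  ids <- sprintf("P%0*d", max(4L, nchar(n)), seq_len(n))
  n_relay <- spec$n_emitters * spec$emitter_fanout * spec$relay_depth
  if (spec$n_emitters + n_relay + 1L > n && spec$n_emitters > 0L) {
    stop("capacity error: emitters and relay chains leave no receiver pool")
  }
  with_seed(spec$seed, {
    perm <- sample(ids)
    emitters <- if (spec$n_emitters > 0L) perm[seq_len(spec$n_emitters)] else character(0)
    relays <- if (n_relay > 0L) perm[spec$n_emitters + seq_len(n_relay)] else character(0)
    receivers <- perm[-seq_len(spec$n_emitters + n_relay)]
    src <- character(0); tgt <- character(0)
    add_edges <- function(s, t) {
      src <<- c(src, s); tgt <<- c(tgt, t)
    }
    tails <- character(0)
    if (spec$n_emitters > 0L) {
      ri <- 0L
      for (e in emitters) {
        for (f in seq_len(spec$emitter_fanout)) {
          chain <- relays[ri + seq_len(spec$relay_depth)]
          ri <- ri + spec$relay_depth
          add_edges(c(e, chain[-length(chain)]), chain)
          tails <- c(tails, chain[length(chain)])
        }
      }
      # each cascade terminates in a modest fan into the receiver pool, so
      # emitters aggregate influence without their relays becoming hubs
      if (length(receivers) > 0L) {
        for (tl in tails) {
          fan <- sample(receivers, min(spec$emitter_fanout, length(receivers)))
          add_edges(rep(tl, length(fan)), fan)
        }
      }
    }
    non_emitters <- setdiff(ids, emitters)
    # Poisson extra in-edges for receivers from random non-emitter sources
    if (length(receivers) > 0L && spec$receiver_in_mean > 0) {
      extra <- rpois(length(receivers), spec$receiver_in_mean)
      for (i in which(extra > 0L)) {
        pool <- setdiff(non_emitters, receivers[i])
        srcs <- sample(pool, min(extra[i], length(pool)))
        add_edges(srcs, rep(receivers[i], length(srcs)))
      }
    }
    # iid background edges among ordered receiver pairs: unstructured bulk
    # wiring that leaves the planted emitter cascades intact
    if (spec$background_edge_prob > 0 && length(receivers) > 1L) {
      nr <- length(receivers)
      n_pairs <- nr * (nr - 1L)
      m <- rbinom(1L, n_pairs, spec$background_edge_prob)
      if (m > 0L) {
        pick <- sample.int(n_pairs, m)
        si <- 1L + (pick - 1L) %/% (nr - 1L)
        ti_off <- 1L + (pick - 1L) %% (nr - 1L)
        # target index skips the source itself
        ti <- ifelse(ti_off >= si, ti_off + 1L, ti_off)
        add_edges(receivers[si], receivers[ti])
      }
    }
    # node-disjoint feedback cycles among receivers
    if (spec$n_feedback_motifs > 0L) {
      lens <- sample(3:5, spec$n_feedback_motifs, replace = TRUE)
      if (sum(lens) > length(receivers)) {
        stop("capacity error: not enough receivers for the requested feedback motifs")
      }
      pool <- sample(receivers, sum(lens))
      off <- 0L
      for (L in lens) {
        cyc <- pool[off + seq_len(L)]
        off <- off + L
        add_edges(cyc, c(cyc[-1L], cyc[1L]))
      }
    }
    if (length(src) == 0L) {
      stop("empty network: the specification generates no edges")
    }
    net <- interaction_network(src, tgt)
    roles <- data.frame(
      protein_id = ids,
      role = ifelse(ids %in% emitters, "emitter",
                    ifelse(ids %in% relays, "relay", "receiver")),
      stringsAsFactors = FALSE
    )
    roles$importance <- c(emitter = 2, relay = 1, receiver = 0)[roles$role]
    pids <- round(runif(net$n_edges, 2.05, 9.95), 3)
    list(network = net, roles = roles, pids = pids)
  })
}

#' Generate per-protein annotations with a planted conservation gradient
#'
#' BLAST bit scores follow
#' `bits_base + bits_slope * importance(role) + Normal(0, bits_sd)`,
#' truncated at 0, so conservation rises from receivers (importance 0)
#' through relays (1) to emitters (2). E-values are derived from the bit
#' scores (`1e9 * 2^-bits`, capped at 10). Protein lengths are log-normal
#' (median 500 aa, sdlog 0.45 — a realistic proteome-like spread).
#' Location flags are Bernoulli with role-dependent probabilities whose
#' defaults make receivers more nuclear and emitters more
#' membrane/cytoplasmic; pathway labels (`signalling`, `MAPK`,
#' `known_pathway`) are likewise enriched among emitters and relays.
#'
#' @param roles Roles data frame from [generate_network()].
#' @param bits_base Baseline bit score (default 180).
#' @param bits_slope Bit-score increase per unit importance (default 70;
#'   with the default sd this separates top and bottom groups decisively).
#' @param bits_sd Normal noise sd on bit scores (default 40; must be >= 0).
#' @param seed Integer seed.
#' @param location_probs Optional 3x3 numeric matrix of Bernoulli
#'   probabilities, rows `emitter`/`relay`/`receiver`, columns
#'   `nucleus`/`cytoplasm`/`membrane`.
#' @return An annotation table (see [read_annotations()]).
#' @export
generate_annotations <- function(roles, bits_base = 180, bits_slope = 70,
                                 bits_sd = 40, seed = 1L,
                                 location_probs = NULL) {
  if (bits_sd < 0) stop("bits_sd must be >= 0")
  if (is.null(location_probs)) {
    location_probs <- matrix(
      c(0.15, 0.65, 0.70,   # emitter
        0.35, 0.55, 0.45,   # relay
        0.70, 0.45, 0.20),  # receiver
      nrow = 3, byrow = TRUE,
      dimnames = list(c("emitter", "relay", "receiver"),
                      c("nucleus", "cytoplasm", "membrane")))
  }
  n <- nrow(roles)
  imp <- roles$importance
  with_seed(seed, {
    bits <- pmax(0, bits_base + bits_slope * imp + rnorm(n, 0, bits_sd))
    evalue <- pmin(10, 1e9 * 2^(-bits))
    len <- pmax(50L, as.integer(round(rlnorm(n, meanlog = log(500),
                                             sdlog = 0.45))))
    lp <- location_probs[roles$role, , drop = FALSE]
    nuc <- runif(n) < lp[, "nucleus"]
    cyt <- runif(n) < lp[, "cytoplasm"]
    mem <- runif(n) < lp[, "membrane"]
    p_sig <- c(emitter = 0.85, relay = 0.60, receiver = 0.25)[roles$role]
    p_known <- c(emitter = 0.90, relay = 0.80, receiver = 0.50)[roles$role]
    sig <- runif(n) < p_sig
    mapk <- sig & (runif(n) < 0.35)
    known <- sig | (runif(n) < p_known)
    labels <- vapply(seq_len(n), function(i) {
      paste(c(if (known[i]) "known_pathway", if (sig[i]) "signalling",
              if (mapk[i]) "MAPK"), collapse = ";")
    }, "")
    validate_annotations(data.frame(
      protein_id = roles$protein_id,
      blast_bits = bits, evalue = evalue, length_aa = len,
      pathway_labels = labels,
      nucleus = nuc, cytoplasm = cyt, membrane = mem,
      stringsAsFactors = FALSE))
  })
}

#' Write a synthetic network as a PIDS edge table
#'
#' Emits the same `source/target/pids` TSV dialect that
#' [read_edge_table()] consumes; optional `# key=value` provenance header.
#'
#' @param gen A [generate_network()] result (or an `interaction_network`,
#'   in which case all PIDS are written as 3.0).
#' @param path Output path.
#' @param header Optional named vector of provenance pairs.
#' @return `path`, invisibly.
#' @export
write_edge_table <- function(gen, path, header = NULL) {
  if (inherits(gen, "interaction_network")) {
    net <- gen
    pids <- rep(3.0, net$n_edges)
  } else {
    net <- gen$network
    pids <- gen$pids
  }
  lines <- c(
    if (!is.null(header)) sprintf("# %s=%s", names(header), as.character(header)),
    "source\ttarget\tpids",
    sprintf("%s\t%s\t%.3f", net$edges[, 1L], net$edges[, 2L], pids)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write the planted-roles sidecar TSV
#'
#' @param roles Roles data frame from [generate_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roles <- function(roles, path) {
  write.table(roles, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
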