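# Comparison machinery between ranking results: top/mid/bottom group
# extraction, correlations, top-k overlaps and top-vs-bottom fold ratios.

ranked_ids <- function(result) {
  names(result$positions)[order(result$positions)]
}

check_same_nodes <- function(r1, r2) {
  if (!setequal(names(r1$scores), names(r2$scores))) {
    stop("ranking results cover different protein sets and cannot be aligned")
  }
}

#' Extract top, middle and bottom rank groups
#'
#' The middle group is a window of `k` proteins centred on the median rank:
#' positions `floor((n - k)/2) + 1` through `floor((n - k)/2) + k`.
#'
#' @param result A `ranking_result`.
#' @param k Group size (default 50, the conventional panel size for
#'   top/mid/bottom comparisons).
#' @return Object of class `rank_groups`: list with ordered identifier
#'   vectors `top`, `mid`, `bottom` and the `k` used. Groups are pairwise
#'   disjoint whenever `3k <= n`.
#' @export
extract_groups <- function(result, k = 50L) {
  stopifnot(inherits(result, "ranking_result"), k >= 1)
  k <- as.integer(k)
  n <- result$n
  if (n < k) stop(sprintf("cannot extract groups of size %d from %d proteins", k, n))
  ids <- ranked_ids(result)
  mid_start <- (n - k) %/% 2L + 1L
  structure(
    list(top = ids[seq_len(k)],
         mid = ids[mid_start:(mid_start + k - 1L)],
         bottom = ids[(n - k + 1L):n],
         k = k, n = n, method = result$method),
    class = "rank_groups"
  )
}

#' @export
print.rank_groups <- function(x, ...) {
  cat(sprintf("rank_groups (%s): k=%d of n=%d\n", x$method, x$k, x$n))
  invisible(x)
}

#' Correlate two ranking results
#'
#' Pearson (product-moment) or Spearman (rank) correlation across the
#' shared protein set, computed either on raw stationary scores or on rank
#' positions. The Pearson p-value uses the t transform with n - 2 degrees
#' of freedom; a seeded Monte-Carlo permutation p-value is available for
#' small panels where the t approximation is doubtful.
#'
#' @param r1,r2 `ranking_result` objects over the same protein set.
#' @param method `"pearson"` or `"spearman"`.
#' @param basis Correlate `"score"`s or rank `"position"`s.
#' @param p_method `"asymptotic"` (default) or `"permutation"`.
#' @param n_perm Number of Monte-Carlo permutations when
#'   `p_method = "permutation"`.
#' @param seed Seed for the permutation draw.
#' @return Object of class `comparison_stats`: list with `r`, `p`,
#'   `method`, `basis`, `n`.
#' @export
correlate_rankings <- function(r1, r2,
                               method = c("pearson", "spearman"),
                               basis = c("score", "position"),
                               p_method = c("asymptotic", "permutation"),
                               n_perm = 9999L, seed = 1L) {
  method <- match.arg(method)
  basis <- match.arg(basis)
  p_method <- match.arg(p_method)
  check_same_nodes(r1, r2)
  ids <- names(r1$scores)
  v1 <- if (basis == "score") r1$scores[ids] else as.numeric(r1$positions[ids])
  v2 <- if (basis == "score") r2$scores[ids] else as.numeric(r2$positions[ids])
  if (sd(v1) == 0 || sd(v2) == 0) {
    stop("correlation undefined: zero variance in one of the rankings")
  }
  ct <- suppressWarnings(cor.test(v1, v2, method = method, exact = FALSE))
  p <- ct$p.value
  if (p_method == "permutation") {
    obs <- unname(ct$estimate)
    perm <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        suppressWarnings(stats::cor(v1, sample(v2), method = method))
      }, numeric(1))
    })
    p <- (1 + sum(abs(perm) >= abs(obs) - 1e-15)) / (n_perm + 1)
  }
  structure(
    list(r = unname(ct$estimate), p = p, method = method, basis = basis,
         n = length(ids)),
    class = "comparison_stats"
  )
}

#' @export
print.comparison_stats <- function(x, ...) {
  cat(sprintf("comparison_stats: %s on %s, n=%d, r=%.4f, p=%.4g\n",
              x$method, x$basis, x$n, x$r, x$p))
  invisible(x)
}

#' Overlap between two top-k protein sets
#'
#' @param r1,r2 `ranking_result` objects over the same protein set.
#' @param k Panel size (<= n).
#' @return List with `count` (integer) and `shared` (sorted identifiers).
#' @export
top_k_overlap <- function(r1, r2, k) {
  check_same_nodes(r1, r2)
  stopifnot(k >= 1, k <= r1$n)
  t1 <- ranked_ids(r1)[seq_len(k)]
  t2 <- ranked_ids(r2)[seq_len(k)]
  shared <- lex_sort(intersect(t1, t2))
  list(count = length(shared), shared = shared)
}

#' Proteins common to the top k of several rankings
#'
#' @param results List of at least two `ranking_result` objects over the
#'   same protein set.
#' @param k Panel size.
#' @return Sorted character vector: the intersection of all top-k sets.
#' @export
common_top_k <- function(results, k) {
  stopifnot(is.list(results), length(results) >= 2L)
  for (r in results[-1L]) check_same_nodes(results[[1L]], r)
  stopifnot(k >= 1, k <= results[[1L]]$n)
  tops <- lapply(results, function(r) ranked_ids(r)[seq_len(k)])
  lex_sort(Reduce(intersect, tops))
}

#' Top-vs-bottom fold ratio of average ranking value
#'
#' Mean stationary score of the k best-ranked proteins divided by the mean
#' score of the k worst-ranked — the "how much bigger are the big nodes"
#' summary. Always >= 1 by construction; invariant under uniform rescaling
#' of the scores.
#'
#' @param result A `ranking_result` with `n >= 2k`.
#' @param k Panel size.
#' @return Scalar fold ratio.
#' @export
fold_ratio <- function(result, k) {
  stopifnot(inherits(result, "ranking_result"), k >= 1)
  n <- result$n
  if (n < 2L * k) stop("fold_ratio needs n >= 2k (disjoint top and bottom panels)")
  ids <- ranked_ids(result)
  top_mean <- mean(result$scores[ids[seq_len(k)]])
  bot_mean <- mean(result$scores[ids[(n - k + 1L):n]])
  if (bot_mean == 0) stop("bottom-group mean score is zero")
  top_mean / bot_mean
}

#' Pairwise comparison summary for a set of rankings
#'
#' Convenience wrapper producing one data frame with all pairwise
#' correlations and top-k overlaps plus per-ranking fold ratios and the
#' common top-k set; the machinery behind the `compare` command.
#'
#' @param results Named list of `ranking_result` objects (same node set).
#' @param k Panel size for overlaps and fold ratios.
#' @inheritParams correlate_rankings
#' @return Data frame with columns `kind`, `a`, `b`, `stat`, `value`.
#' @export
compare_rankings <- function(results, k = 50L,
                             method = c("pearson", "spearman"),
                             basis = c("score", "position")) {
  method <- match.arg(method)
  basis <- match.arg(basis)
  stopifnot(is.list(results), length(results) >= 2L)
  nm <- names(results)
  if (is.null(nm) || any(!nzchar(nm))) {
    nm <- vapply(results, function(r) r$method, "")
    names(results) <- nm
  }
  rows <- list()
  add <- function(kind, a, b, stat, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      kind = kind, a = a, b = b, stat = stat, value = value,
      stringsAsFactors = FALSE)
  }
  pairs <- utils::combn(nm, 2L, simplify = FALSE)
  for (p in pairs) {
    cs <- correlate_rankings(results[[p[1L]]], results[[p[2L]]],
                             method = method, basis = basis)
    ov <- top_k_overlap(results[[p[1L]]], results[[p[2L]]], k)
    add("correlation", p[1L], p[2L], "r", format(cs$r, digits = 17))
    add("correlation", p[1L], p[2L], "p", format(cs$p, digits = 17))
    add("overlap", p[1L], p[2L], sprintf("count@%d", k), ov$count)
    add("overlap", p[1L], p[2L], "shared", paste(ov$shared, collapse = ";"))
  }
  common <- common_top_k(results, k)
  add("common", "all", "", sprintf("count@%d", k), length(common))
  add("common", "all", "", "shared", paste(common, collapse = ";"))
  for (a in nm) {
    if (results[[a]]$n >= 2L * k) {
      add("fold", a, "", sprintf("ratio@%d", k),
          format(fold_ratio(results[[a]], k), digits = 17))
    }
  }
  do.call(rbind, rows)
}
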