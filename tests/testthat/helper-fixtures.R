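# Shared fixtures and independent oracles for the test suite.

# Random directed network (no self-loops), built straight from Bernoulli
# draws — independent of the package's generator.
random_network <- function(n, p, seed) {
  withr_seed <- function(code) code # placeholder to keep base-only
  set.seed(seed)
  ids <- sprintf("N%02d", seq_len(n))
  pairs <- expand.grid(s = ids, t = ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$s != pairs$t, ]
  keep <- runif(nrow(pairs)) < p
  if (!any(keep)) keep[sample.int(length(keep), 2L)] <- TRUE
  interaction_network(pairs$s[keep], pairs$t[keep])
}

# Edge-reversed copy of a network.
reverse_network <- function(net) {
  interaction_network(net$edges[, 2L], net$edges[, 1L])
}

# Dense oracle: stationary vector of M = alpha*P + (1-alpha)/n J via a full
# eigen-decomposition of t(M), normalised to sum 1.
eigen_pagerank <- function(tm, alpha = 0.85) {
  P <- as.matrix(tm$walk_matrix)
  n <- tm$n
  M <- alpha * P + (1 - alpha) / n
  ev <- eigen(t(M))
  i <- which.min(abs(ev$values - 1))
  v <- Re(ev$vectors[, i])
  v <- v / sum(v)
  setNames(v, tm$nodes)
}

# Dense oracle: stationary vector by solving the linear system
# x = alpha * t(P) x + (1-alpha)/n * 1  (uses sum(x) = 1).
solve_pagerank <- function(tm, alpha = 0.85) {
  P <- as.matrix(tm$walk_matrix)
  n <- tm$n
  x <- solve(diag(n) - alpha * t(P), rep((1 - alpha) / n, n))
  setNames(x / sum(x), tm$nodes)
}

# Random undirected connected non-bipartite graph, returned as a directed
# network carrying one arbitrary orientation per undirected edge (the
# package symmetrises in undirected mode). Adds a triangle to break
# bipartiteness and a spanning path for connectivity.
random_undirected_network <- function(n, p, seed) {
  set.seed(seed)
  ids <- sprintf("U%02d", seq_len(n))
  s <- character(0); t <- character(0)
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    if (runif(1) < p) {
      s <- c(s, ids[i]); t <- c(t, ids[j])
    }
  }
  s <- c(s, ids[seq_len(n - 1L)], ids[1L], ids[2L], ids[1L])
  t <- c(t, ids[seq(2L, n)], ids[2L], ids[3L], ids[3L])
  interaction_network(s, t)
}

# Undirected degree of every node (distinct neighbours).
undirected_degrees <- function(net) {
  n <- net$n_nodes
  i <- match(net$edges[, 1L], net$nodes)
  j <- match(net$edges[, 2L], net$nodes)
  key <- paste(pmin(i, j), pmax(i, j))
  keep <- !duplicated(key)
  tabulate(c(i[keep], j[keep]), nbins = n)
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
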