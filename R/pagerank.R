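# Direction-specific transition matrices and scaled PageRank.
#
# The walk matrix N is row-stochastic: N[i, j] = 1/outdeg(i) for each edge
# i -> j in the chosen direction, with dangling rows (outdeg 0) resolved by
# policy. The scaled chain is M = alpha * N + (1 - alpha)/n * J; its
# stationary vector (the principal left eigenvector, eigenvalue 1) is the
# PageRank. Power iteration never materialises J: the uniform teleport term
# is applied as a rank-one correction.

direction_levels <- c("forward", "reverse", "undirected")
dangling_levels <- c("stay", "teleport")

# Integer edge list (i -> j over node indices) for one direction mode.
edge_indices <- function(network, direction) {
  nodes <- network$nodes
  ei <- match(network$edges[, 1L], nodes)
  ej <- match(network$edges[, 2L], nodes)
  if (direction == "reverse") {
    tmp <- ei; ei <- ej; ej <- tmp
  } else if (direction == "undirected") {
    i2 <- c(ei, ej); j2 <- c(ej, ei)
    keep <- !duplicated(i2 * (network$n_nodes + 1) + j2)
    ei <- i2[keep]; ej <- j2[keep]
  }
  list(i = ei, j = ej)
}

#' Build a row-stochastic transition matrix for one ranking direction
#'
#' @param network An [interaction_network()].
#' @param direction One of `"forward"` (walk along signal flow; stationary
#'   mass accumulates on information receivers), `"reverse"` (walk against
#'   signal flow, i.e. forward on the edge-reversed network; mass
#'   accumulates on emitters/regulators) or `"undirected"` (symmetrised
#'   adjacency normalised by degree).
#' @param dangling_policy How rows with no outgoing links are resolved:
#'   `"stay"` (the walker stays put — probability 1 on the node itself) or
#'   `"teleport"` (uniform 1/n row). `"stay"` is the default.
#' @return An object of class `transition_matrix`: list with `n`, `nodes`,
#'   `walk_matrix` (sparse `dgCMatrix`, rows sum to 1), `direction`,
#'   `dangling_policy`, and `dangling` (logical vector marking resolved
#'   rows).
#' @examples
#' net <- interaction_network(c("A", "A"), c("B", "C"))
#' tm <- build_transition(net, "forward")
#' Matrix::rowSums(tm$walk_matrix)
#' @export
build_transition <- function(network,
                             direction = c("forward", "reverse", "undirected"),
                             dangling_policy = c("stay", "teleport")) {
  stopifnot(inherits(network, "interaction_network"))
  direction <- match.arg(direction)
  dangling_policy <- match.arg(dangling_policy)
  n <- network$n_nodes
  if (n < 1L) stop("network is empty")
  e <- edge_indices(network, direction)
  outdeg <- tabulate(e$i, nbins = n)
  dangling <- outdeg == 0L
  ii <- e$i; jj <- e$j; xx <- 1 / outdeg[e$i]
  if (any(dangling)) {
    d <- which(dangling)
    if (dangling_policy == "stay") {
      ii <- c(ii, d); jj <- c(jj, d); xx <- c(xx, rep(1, length(d)))
    } else {
      ii <- c(ii, rep(d, each = n))
      jj <- c(jj, rep(seq_len(n), times = length(d)))
      xx <- c(xx, rep(1 / n, length(d) * n))
    }
  }
  P <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                            dimnames = list(network$nodes, network$nodes))
  structure(
    list(n = n, nodes = network$nodes, walk_matrix = P,
         direction = direction, dangling_policy = dangling_policy,
         dangling = dangling),
    class = "transition_matrix"
  )
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf(
    "transition_matrix: %d nodes, direction=%s, dangling=%s (%d dangling row%s)\n",
    x$n, x$direction, x$dangling_policy, sum(x$dangling),
    if (sum(x$dangling) == 1L) "" else "s"))
  invisible(x)
}

# Ranking container shared by pagerank() and read_ranking().
new_ranking_result <- function(scores, method, iterations_used, converged,
                               alpha, dangling_policy) {
  n <- length(scores)
  ord <- order(-scores, names(scores), method = "radix")
  positions <- integer(n)
  positions[ord] <- seq_len(n)
  names(positions) <- names(scores)
  structure(
    list(method = method, scores = scores, positions = positions,
         percent = 100 * scores, iterations_used = iterations_used,
         converged = converged, alpha = alpha,
         dangling_policy = dangling_policy, n = n),
    class = "ranking_result"
  )
}

#' @export
print.ranking_result <- function(x, ...) {
  cat(sprintf("ranking_result (%s): %d proteins, alpha=%s, %s\n",
              x$method, x$n, format(x$alpha),
              if (isTRUE(x$converged)) {
                sprintf("converged in %d iterations", x$iterations_used)
              } else "NOT converged"))
  top <- names(sort(x$positions))[seq_len(min(5L, x$n))]
  cat("top:", paste(top, collapse = ", "), "\n")
  invisible(x)
}

#' Scaled PageRank by power iteration
#'
#' Computes the stationary probability vector of the damped chain
#' `M = alpha * N + (1 - alpha)/n * J`, where `N` is the row-stochastic
#' walk matrix of `transition` — i.e. the principal left eigenvector of
#' `M` (eigenvalue 1), normalised to sum 1. Iteration starts from the
#' uniform vector and stops when the L1 change between successive iterates
#' falls below `tol`.
#'
#' Rank positions break score ties lexicographically by protein identifier,
#' so listings are reproducible.
#'
#' @param transition A [build_transition()] result.
#' @param alpha Damping factor in (0, 1]: probability of following a link
#'   rather than teleporting uniformly. Default 0.85, the conventional
#'   PageRank setting. At `alpha = 1` (no teleport) periodic chains may
#'   legitimately fail to converge; the result is then flagged.
#' @param tol L1 convergence tolerance (default 1e-12).
#' @param max_iter Maximum number of power-iteration sweeps.
#' @return A `ranking_result`: `scores` (named, sums to 1), `positions`
#'   (1-based ranks, permutation of 1..n), `percent`, `iterations_used`,
#'   `converged`, plus the `alpha` and `dangling_policy` used.
#' @examples
#' net <- interaction_network(c("A", "B", "C"), c("B", "C", "A"))
#' pr <- pagerank(build_transition(net, "forward"))
#' pr$scores # 3-cycle: uniform 1/3
#' @export
pagerank <- function(transition, alpha = 0.85, tol = 1e-12, max_iter = 1000L) {
  stopifnot(inherits(transition, "transition_matrix"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1) {
    stop("alpha must be in (0, 1]")
  }
  n <- transition$n
  P <- transition$walk_matrix
  x <- rep(1 / n, n)
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    xn <- alpha * as.numeric(Matrix::crossprod(P, x)) + (1 - alpha) / n
    xn <- xn / sum(xn)
    delta <- sum(abs(xn - x))
    x <- xn
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf("pagerank did not converge within %d iterations (alpha=%g)",
                    max_iter, alpha))
  }
  names(x) <- transition$nodes
  new_ranking_result(x, method = transition$direction,
                     iterations_used = iters, converged = converged,
                     alpha = alpha,
                     dangling_policy = transition$dangling_policy)
}

# Out-neighbour lists for the simulator (direction already applied).
adjacency_list <- function(network, direction) {
  n <- network$n_nodes
  e <- edge_indices(network, direction)
  unname(split(e$j, factor(e$i, levels = seq_len(n))))
}

# One seeded trajectory of the scaled chain. RNG state must already be set.
# Returns integer path of length `steps`, starting after `start`.
simulate_steps <- function(adj, n, alpha, stay, steps, start) {
  lens <- lengths(adj)
  tele <- runif(steps) >= alpha
  jump <- sample.int(n, steps, replace = TRUE)
  u <- runif(steps)
  path <- integer(steps)
  cur <- start
  for (i in seq_len(steps)) {
    if (tele[i]) {
      cur <- jump[i]
    } else {
      L <- lens[cur]
      if (L > 0L) {
        cur <- adj[[cur]][1L + trunc(u[i] * L)]
      } else if (!stay) {
        cur <- 1L + trunc(u[i] * n)
      } # stay: cur unchanged
    }
    path[i] <- cur
  }
  path
}

#' Monte-Carlo random surfer
#'
#' Simulates the explorer the ranking models: at each step, with
#' probability `alpha` follow a uniformly random outgoing link of the
#' current protein (dangling nodes resolved per policy), otherwise jump to
#' a uniformly random protein. Long-run visit frequencies converge to the
#' [pagerank()] scores; this is the independent simulation oracle for the
#' algebraic computation.
#'
#' @inheritParams build_transition
#' @param alpha Damping factor in (0, 1].
#' @param steps Number of simulated steps (>= 1).
#' @param seed Integer seed; the trajectory is fully reproducible.
#' @return Named numeric vector of visit frequencies (sums to 1).
#' @export
random_surfer <- function(network,
                          direction = c("forward", "reverse", "undirected"),
                          alpha = 0.85, steps, seed,
                          dangling_policy = c("stay", "teleport")) {
  direction <- match.arg(direction)
  dangling_policy <- match.arg(dangling_policy)
  stopifnot(steps >= 1, is.numeric(seed))
  n <- network$n_nodes
  adj <- adjacency_list(network, direction)
  path <- with_seed(seed, {
    simulate_steps(adj, n, alpha, dangling_policy == "stay", as.integer(steps),
                   start = sample.int(n, 1L))
  })
  freq <- tabulate(path, nbins = n) / length(path)
  names(freq) <- network$nodes
  freq
}

#' Mean return time of the random surfer to one protein
#'
#' Simulates the scaled chain and measures the average number of steps
#' between successive visits to `node`. By Kac's identity the stationary
#' probability of a node equals the reciprocal of its expected return
#' time, so `mean_return_time(...) * pagerank(...)$scores[node]` should be
#' close to 1.
#'
#' @inheritParams random_surfer
#' @param node Protein identifier to track.
#' @param n_returns Number of return intervals to average (>= 100).
#' @return Mean return time in steps (a scalar).
#' @export
mean_return_time <- function(network,
                             direction = c("forward", "reverse", "undirected"),
                             alpha = 0.85, node, n_returns, seed,
                             dangling_policy = c("stay", "teleport")) {
  direction <- match.arg(direction)
  dangling_policy <- match.arg(dangling_policy)
  stopifnot(n_returns >= 100)
  idx <- match(node, network$nodes)
  if (is.na(idx)) stop(sprintf("node '%s' is not in the network", node))
  n <- network$n_nodes
  adj <- adjacency_list(network, direction)
  stay <- dangling_policy == "stay"
  chunk <- 200000L
  max_total <- 2e8
  with_seed(seed, {
    cur <- sample.int(n, 1L)
    visit_times <- integer(0)
    offset <- 0
    while (length(visit_times) < n_returns + 1L) {
      if (offset >= max_total) {
        stop("mean_return_time: simulation budget exhausted before enough returns")
      }
      path <- simulate_steps(adj, n, alpha, stay, chunk, start = cur)
      cur <- path[chunk]
      visit_times <- c(visit_times, offset + which(path == idx))
      offset <- offset + chunk
    }
    visit_times <- visit_times[seq_len(n_returns + 1L)]
    mean(diff(visit_times))
  })
}
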