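# One-way ANOVA and Duncan's multiple-range test with compact letter
# display, as used for top/mid/bottom conservation comparisons.

#' One-way fixed-effects ANOVA
#'
#' Classical decomposition: F = MSB / MSW with k - 1 and N - k degrees of
#' freedom, upper-tail p from the F distribution. If the within-group
#' variance is exactly zero while group means differ, F is reported as
#' `Inf` with p = 0; if all observations are identical, F = 0 and p = 1.
#'
#' @param groups List (length >= 2) of numeric vectors, each of length >= 2.
#' @return List with `F`, `p`, `df_between`, `df_within`, `mse`,
#'   `group_means`, `group_n`.
#' @examples
#' anova_oneway(list(a = c(1, 2, 3), b = c(4, 5, 6)))$F # 13.5
#' @export
anova_oneway <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  groups <- lapply(groups, function(g) as.numeric(g[!is.na(g)]))
  ni <- lengths(groups)
  if (any(ni < 2L)) stop("each group needs at least 2 observations")
  k <- length(groups)
  N <- sum(ni)
  mi <- vapply(groups, mean, numeric(1))
  grand <- sum(ni * mi) / N
  ssb <- sum(ni * (mi - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  dfb <- k - 1L
  dfw <- N - k
  msb <- ssb / dfb
  msw <- ssw / dfw
  if (msw == 0) {
    if (msb == 0) {
      F <- 0; p <- 1
    } else {
      F <- Inf; p <- 0
    }
  } else {
    F <- msb / msw
    p <- pf(F, dfb, dfw, lower.tail = FALSE)
  }
  list(F = F, p = p, df_between = dfb, df_within = dfw, mse = msw,
       group_means = mi, group_n = ni)
}

#' Duncan's multiple-range test with compact letter display
#'
#' Post-ANOVA stepwise range procedure. Group means are ordered
#' descending; a stretch of `p` consecutive ordered means is declared
#' homogeneous when its range does not exceed the critical range
#' `R_p = q*(alpha_p, p, df) * sqrt(MSE / n_h)`, where `q*` is the
#' studentized-range quantile, `alpha_p = 1 - (1 - alpha)^(p - 1)` is
#' Duncan's protection level, `df` the ANOVA error degrees of freedom and
#' `n_h` the harmonic mean of the group sizes. Sub-stretches of an
#' accepted stretch are not re-tested (the usual protection rule). Groups
#' whose means fall in a common homogeneous stretch share a letter; means
#' carrying no common letter differ at the stated level.
#'
#' For two groups the procedure reduces to an LSD-style t test at level
#' `alpha`.
#'
#' @param groups Named list (length >= 2) of numeric vectors, each of
#'   length >= 2 (singleton groups contribute no error variance and are
#'   rejected).
#' @param alpha Nominal per-comparison significance level (default 0.05).
#' @return Data frame in descending-mean order with columns `group`,
#'   `mean`, `n`, `letters`; attributes `mse`, `df`, `critical_ranges`.
#' @examples
#' set.seed(1)
#' g <- list(low = rnorm(10), high = rnorm(10, 100))
#' duncan_mrt(g)
#' @export
duncan_mrt <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2L,
            alpha > 0, alpha < 1)
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  groups <- lapply(groups, function(g) as.numeric(g[!is.na(g)]))
  ni <- lengths(groups)
  if (any(ni < 2L)) {
    stop("duncan_mrt: groups of size < 2 contribute no error variance")
  }
  av <- anova_oneway(groups)
  k <- length(groups)
  df <- av$df_within
  mse <- av$mse
  n_h <- k / sum(1 / ni)
  means <- av$group_means
  ord <- order(-means, names(groups), method = "radix")
  m <- means[ord]
  # critical range for a stretch spanning p ordered means (p = 2..k)
  crit <- vapply(2:k, function(p) {
    if (mse == 0) return(0)
    a_p <- 1 - (1 - alpha)^(p - 1)
    qtukey(1 - a_p, nmeans = p, df = df) * sqrt(mse / n_h)
  }, numeric(1))
  eps <- 1e-10 * max(1, abs(m[1L]))
  covered <- matrix(FALSE, k, k)
  accepted <- list()
  if (k >= 2L) {
    for (span in seq(k, 2L)) {
      R <- crit[span - 1L]
      for (i in seq_len(k - span + 1L)) {
        j <- i + span - 1L
        if (covered[i, j]) next
        if (m[i] - m[j] <= R + eps) {
          accepted[[length(accepted) + 1L]] <- c(i, j)
          covered[i:j, i:j] <- TRUE
        }
      }
    }
  }
  # singletons not inside any homogeneous stretch still need a letter
  for (i in seq_len(k)) {
    if (!covered[i, i]) accepted[[length(accepted) + 1L]] <- c(i, i)
  }
  starts <- vapply(accepted, `[[`, integer(1), 1L)
  ends <- vapply(accepted, `[[`, integer(1), 2L)
  o <- order(starts, -ends)
  starts <- starts[o]; ends <- ends[o]
  letter_pool <- c(LETTERS, as.vector(outer(LETTERS, LETTERS, paste0)))
  lab <- character(k)
  for (s in seq_along(starts)) {
    rng <- starts[s]:ends[s]
    lab[rng] <- paste0(lab[rng], letter_pool[s])
  }
  out <- data.frame(group = names(groups)[ord], mean = unname(m),
                    n = unname(ni[ord]), letters = lab,
                    stringsAsFactors = FALSE)
  attr(out, "mse") <- mse
  attr(out, "df") <- df
  attr(out, "critical_ranges") <- crit
  attr(out, "alpha") <- alpha
  out
}

#' Goodness-of-fit chi-square of a top/bottom count pair against a
#' reference ratio
#'
#' One-degree-of-freedom chi-square (no continuity correction) of observed
#' counts `(observed_top, observed_bottom)` against expected proportions
#' `reference_top : reference_bottom` — the spreadsheet-style test used to
#' ask whether one ranking's top/bottom split of a location category
#' departs from another ranking's split.
#'
#' @param observed_top,observed_bottom Non-negative observed counts.
#' @param reference_top,reference_bottom Non-negative reference counts
#'   (not both zero) defining the expected ratio.
#' @return List with `chi2`, `p`, `df = 1`, `expected`.
#' @examples
#' ratio_chisq(40, 10, 1, 1)$chi2 # 18
#' @export
ratio_chisq <- function(observed_top, observed_bottom,
                        reference_top, reference_bottom) {
  obs <- c(observed_top, observed_bottom)
  ref <- c(reference_top, reference_bottom)
  if (any(!is.finite(c(obs, ref))) || any(c(obs, ref) < 0)) {
    stop("counts must be finite and non-negative")
  }
  if (sum(ref) == 0) stop("reference counts must not both be zero")
  expected <- sum(obs) * ref / sum(ref)
  if (any(expected == 0)) {
    stop("expected cell count is zero; reference ratio degenerate for these data")
  }
  chi2 <- sum((obs - expected)^2 / expected)
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE),
       df = 1L, expected = expected)
}
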