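# BLAST parsing, ANOVA, Duncan letters, category/location summaries.

blast_row <- function(q, s, ev, bits) {
  sprintf("%s\t%s\t35.0\t100\t60\t3\t1\t100\t1\t100\t%g\t%g", q, s, ev, bits)
}

test_that("read_blast_tabular keeps the best hit per query", {
  lines <- c(blast_row("P1", "ce1", 1e-10, 100),
             blast_row("P1", "ce2", 1e-50, 250),
             blast_row("P2", "ce3", 0.001, 40))
  hits <- read_blast_tabular(lines)
  expect_identical(hits$blast_bits[hits$protein_id == "P1"], 250)
  expect_identical(nrow(hits), 2L)
  expect_identical(nrow(read_blast_tabular(character(0))), 0L)
  expect_error(read_blast_tabular("P1\tce1\tonly-three"), "line 1")
})

test_that("best-hit selection matches a brute-force scan on random rows", {
  set.seed(8)
  q <- sprintf("P%d", sample.int(10, 50, replace = TRUE))
  bits <- round(runif(50, 30, 400), 1)
  ev <- 10^-runif(50, 0, 50)
  lines <- mapply(blast_row, q, sprintf("s%d", 1:50), ev, bits)
  hits <- read_blast_tabular(unname(lines))
  for (qq in unique(q)) {
    expect_equal(hits$blast_bits[hits$protein_id == qq],
                 max(bits[q == qq]))
  }
})

test_that("one-way ANOVA: hand-computed F, degenerate cases", {
  av <- anova_oneway(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(av$F, 13.5)
  expect_equal(av$p, pf(13.5, 1, 4, lower.tail = FALSE))
  expect_equal(anova_oneway(list(c(1, 2, 3), c(1, 2, 3)))$F, 0)
  # zero within-variance, unequal means
  degen <- anova_oneway(list(c(2, 2), c(5, 5)))
  expect_identical(degen$F, Inf)
  expect_identical(degen$p, 0)
  expect_error(anova_oneway(list(1, c(2, 3))), "at least 2")
})

test_that("ANOVA type-I error is calibrated under the null", {
  set.seed(123)
  reps <- 1000L
  rej <- mean(replicate(reps, {
    anova_oneway(list(rnorm(10), rnorm(10), rnorm(10)))$p < 0.05
  }))
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.07)
})

test_that("duncan letters: degenerate and forced layouts", {
  same <- duncan_mrt(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_identical(same$letters, c("A", "A"))
  set.seed(5)
  far <- duncan_mrt(list(lo = rnorm(10, 0, 0.1), mid = rnorm(10, 100, 0.1),
                         hi = rnorm(10, 200, 0.1)))
  expect_identical(far$group, c("hi", "mid", "lo")) # descending means
  expect_identical(far$letters, c("A", "B", "C"))
  expect_error(duncan_mrt(list(a = 1, b = c(2, 3))), "size < 2")
})

# Independent oracle: direct implementation of the critical-range
# recursion, structured differently from the package (pairwise matrix +
# explicit interval scan) — frozen logic, shared only via qtukey.
duncan_oracle_letters <- function(groups, alpha = 0.05) {
  k <- length(groups)
  ni <- lengths(groups)
  m <- vapply(groups, mean, numeric(1))
  N <- sum(ni)
  mse <- sum(unlist(lapply(groups, function(g) (g - mean(g))^2))) / (N - k)
  nh <- k / sum(1 / ni)
  ord <- order(m, decreasing = TRUE)
  ms <- m[ord]
  sig <- matrix(FALSE, k, k) # TRUE = stretch i..j declared non-homogeneous
  done <- matrix(FALSE, k, k)
  for (span in k:2) {
    ap <- 1 - (1 - alpha)^(span - 1)
    Rp <- qtukey(1 - ap, span, N - k) * sqrt(mse / nh)
    for (i in seq_len(k - span + 1)) {
      j <- i + span - 1
      if (done[i, j]) next
      if (ms[i] - ms[j] <= Rp + 1e-10) {
        for (a in i:j) for (b in i:j) done[a, b] <- TRUE
      } else {
        sig[i, j] <- TRUE
      }
    }
  }
  # letters: maximal homogeneous stretches (homog = never marked
  # significant; singletons always homogeneous); an interval is maximal
  # when extending it on either side hits a significant stretch or an end
  homog <- function(i, j) i == j || !sig[i, j]
  intervals <- list()
  for (i in 1:k) for (j in i:k) {
    if (homog(i, j) &&
        (i == 1 || !homog(i - 1, j)) &&
        (j == k || !homog(i, j + 1))) {
      intervals[[length(intervals) + 1]] <- c(i, j)
    }
  }
  lab <- character(k)
  for (s in seq_along(intervals)) {
    rng <- intervals[[s]][1]:intervals[[s]][2]
    lab[rng] <- paste0(lab[rng], LETTERS[s])
  }
  setNames(lab, names(groups)[ord])
}

test_that("five-group layout matches the independent range-recursion oracle", {
  set.seed(77)
  g <- list(a = rnorm(8, 10, 1), b = rnorm(8, 10.4, 1), c = rnorm(8, 15, 1),
            d = rnorm(8, 15.3, 1), e = rnorm(8, 30, 1))
  got <- duncan_mrt(g)
  oracle <- duncan_oracle_letters(g)
  expect_identical(setNames(got$letters, got$group), oracle)
  # also on a tighter layout where stretches overlap
  set.seed(78)
  g2 <- list(a = rnorm(6, 0, 2), b = rnorm(6, 1, 2), c = rnorm(6, 2, 2),
             d = rnorm(6, 4, 2), e = rnorm(6, 8, 2))
  got2 <- duncan_mrt(g2)
  expect_identical(setNames(got2$letters, got2$group),
                   duncan_oracle_letters(g2))
})

test_that("duncan letters are shift invariant and calibrated for 2 groups", {
  set.seed(31)
  g <- list(a = rnorm(12, 5), b = rnorm(12, 6), c = rnorm(12, 7))
  d1 <- duncan_mrt(g)
  d2 <- duncan_mrt(lapply(g, `+`, 1000))
  expect_identical(d1$letters, d2$letters)
  # for 2 groups Duncan reduces to an LSD-style test: same letter ~95%
  set.seed(99)
  same <- mean(replicate(1000, {
    d <- duncan_mrt(list(a = rnorm(8), b = rnorm(8)))
    length(unique(d$letters)) == 1L
  }))
  expect_gt(same, 0.93)
  expect_lt(same, 0.97)
})

test_that("group_conservation_summary recovers a planted gradient", {
  gg <- generate_network(synthetic_spec(seed = 6))
  ann <- generate_annotations(gg$roles, seed = 6)
  rp <- pagerank(build_transition(gg$network, "reverse"))
  groups <- extract_groups(rp, 50)
  gs <- group_conservation_summary(groups, ann)
  tab <- gs$table
  top_letter <- tab$letter_bits[tab$group == "top"]
  bottom_letter <- tab$letter_bits[tab$group == "bottom"]
  expect_false(any(strsplit(top_letter, "")[[1]] %in%
                     strsplit(bottom_letter, "")[[1]]))
  expect_gt(tab$mean_bits[tab$group == "top"],
            tab$mean_bits[tab$group == "bottom"])
  expect_lt(gs$anova_bits$p, 0.001)
})

test_that("conservation summary bookkeeping: flat values and exclusions", {
  ids <- sprintf("P%03d", 1:150)
  ann <- data.frame(protein_id = ids, blast_bits = 100, evalue = 1e-30,
                    length_aa = 500L, pathway_labels = "",
                    nucleus = FALSE, cytoplasm = TRUE, membrane = FALSE)
  scores <- setNames(seq(150, 1) / sum(1:150), ids)
  r <- pprank:::new_ranking_result(scores, "forward", 1L, TRUE, 0.85, "stay")
  g <- extract_groups(r, 50)
  gs <- group_conservation_summary(g, ann)
  expect_equal(gs$anova_bits$F, 0)
  expect_identical(unique(gs$table$letter_bits), "A")
  # one missing BLAST hit in the top group drops n from 50 to 49
  ann$blast_bits[ann$protein_id == g$top[1]] <- NA
  gs2 <- suppressMessages(group_conservation_summary(g, ann))
  expect_identical(gs2$table$n[gs2$table$group == "top"], 49L)
  expect_identical(gs2$table$n_excluded[gs2$table$group == "top"], 1L)
  # missing annotations beyond 20% abort
  expect_error(group_conservation_summary(g, ann[1:30, ]),
               "annotations available")
})

test_that("category fractions use both denominators", {
  ids <- sprintf("P%02d", 1:50)
  labs <- rep("", 50)
  labs[1:43] <- "known_pathway"
  labs[1:37] <- "known_pathway;signalling"
  ann <- data.frame(protein_id = ids, blast_bits = 1, evalue = 1,
                    length_aa = 100L, pathway_labels = labs,
                    nucleus = FALSE, cytoplasm = FALSE, membrane = FALSE)
  cf <- category_fraction(ids, ann, "signalling")
  expect_identical(cf$count, 37L)
  expect_equal(cf$percent_of_annotated, 100 * 37 / 43, tolerance = 1e-12)
  expect_equal(round(cf$percent_of_annotated, 1), 86.0)
  expect_equal(cf$percent_of_all, 74)
  expect_identical(category_fraction(ids, ann, "absent-label")$count, 0L)
  all_lab <- category_fraction(ids[1:37], ann, "signalling")
  expect_equal(all_lab$percent_of_all, 100)
  expect_lte(cf$count, cf$n)
})

test_that("location cross-tab counts flags including multi-location", {
  ann <- data.frame(protein_id = c("A", "B", "C"),
                    blast_bits = 1, evalue = 1, length_aa = 100L,
                    pathway_labels = "",
                    nucleus = c(TRUE, FALSE, TRUE),
                    cytoplasm = c(FALSE, TRUE, FALSE),
                    membrane = c(TRUE, FALSE, FALSE))
  ct <- location_crosstab(list(g1 = "A", g2 = character(0),
                               g3 = c("A", "B", "C")), ann)
  expect_equal(unlist(ct[1, c("nucleus", "cytoplasm", "membrane",
                              "nucleus_plus")], use.names = FALSE),
               c(1, 0, 1, 1))
  expect_equal(sum(unlist(ct[2, 3:6])), 0)
  # brute-force tally on random flags
  set.seed(44)
  ids <- sprintf("R%02d", 1:40)
  ann2 <- data.frame(protein_id = ids, blast_bits = 1, evalue = 1,
                     length_aa = 100L, pathway_labels = "",
                     nucleus = runif(40) < 0.5, cytoplasm = runif(40) < 0.5,
                     membrane = runif(40) < 0.5)
  grp <- sample(ids, 25)
  ct2 <- location_crosstab(list(g = grp), ann2)
  rows <- ann2[match(grp, ann2$protein_id), ]
  expect_identical(ct2$nucleus, sum(rows$nucleus))
  expect_identical(ct2$nucleus_plus,
                   sum(rows$nucleus & (rows$cytoplasm | rows$membrane)))
})

test_that("ratio chi-square: hand value, proportionality, errors", {
  cs <- ratio_chisq(40, 10, 1, 1)
  expect_equal(cs$chi2, 18)
  expect_equal(cs$p, pchisq(18, 1, lower.tail = FALSE))
  expect_equal(ratio_chisq(25, 25, 1, 1)$chi2, 0)
  expect_equal(ratio_chisq(25, 25, 1, 1)$p, 1)
  for (k in c(2L, 5L, 9L)) {
    expect_equal(ratio_chisq(k * 3, k * 7, 3, 7)$chi2, 0, tolerance = 1e-12)
  }
  expect_error(ratio_chisq(5, 5, 0, 0), "not both be zero")
  expect_error(ratio_chisq(5, 5, 1, 0), "expected cell")
})

test_that("annotation tables round-trip through TSV", {
  gg <- generate_network(synthetic_spec(n_nodes = 60, n_emitters = 2,
                                        emitter_fanout = 2, relay_depth = 2,
                                        seed = 12))
  ann <- generate_annotations(gg$roles, seed = 12)
  f <- tempfile(fileext = ".tsv")
  write_annotations(ann, f)
  back <- read_annotations(f)
  expect_identical(back$protein_id, ann$protein_id)
  expect_equal(back$blast_bits, ann$blast_bits, tolerance = 1e-6)
  expect_identical(back$nucleus, ann$nucleus)
  expect_identical(back$pathway_labels, ann$pathway_labels)
  unlink(f)
})
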