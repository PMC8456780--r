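test_that("exact Wilcoxon agrees with exhaustive enumeration at small n", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6)), 0.1)
  set.seed(31)
  for (rep in 1:20) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    v <- sample(100, n1 + n2)                  # distinct values, no ties
    a <- v[seq_len(n1)]; b <- v[-seq_len(n1)]
    expect_equal(wilcoxon_rank_sum(a, b), oracle_wilcoxon_exact(a, b),
                 tolerance = 1e-12)
  }
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("identical groups give p near 1 under the rank-sum test", {
  a <- c(1, 2, 2, 3, 5, 8)
  expect_gte(wilcoxon_rank_sum(a, a), 0.95)
})

test_that("the vectorised rank-sum path matches wilcox.test with ties", {
  set.seed(32)
  n_in <- 17; n_out <- 23
  m <- matrix(rnbinom(40 * 50, mu = 2, size = 1), 40, 50)
  fct <- factor(rep(c("in", "out"), c(n_in, n_out)))
  for (g in seq_len(50)) {
    xg <- m[, g]
    r <- rank(xg)
    p_vec <- scellintegrate:::.wilcox_vec(sum(r[fct == "in"]), n_in, n_out,
                                          scellintegrate:::.tie_term(xg))
    p_ref <- suppressWarnings(
      wilcox.test(xg[fct == "in"], xg[fct == "out"], exact = FALSE,
                  correct = TRUE)$p.value)
    expect_equal(p_vec, p_ref, tolerance = 1e-12)
  }
})

test_that("Fisher's exact frequency test matches enumeration and fisher.test", {
  expect_equal(fisher_exact_frequency(3, 3, 0, 3), 0.1)
  expect_equal(fisher_exact_frequency(2, 4, 2, 4), 1)
  expect_equal(fisher_exact_frequency(0, 5, 0, 7), 1)    # degenerate
  expect_error(fisher_exact_frequency(5, 3, 0, 3), "inconsistent")
  for (n_in in 1:8) for (n_out in 1:8) {
    for (x_in in 0:n_in) for (x_out in 0:n_out) {
      p <- fisher_exact_frequency(x_in, n_in, x_out, n_out)
      expect_equal(p, oracle_fisher_exact(x_in, n_in, x_out, n_out),
                   tolerance = 1e-10)
    }
  }
  set.seed(33)
  for (rep in 1:25) {                    # independent reference: fisher.test
    n_in <- sample(3:40, 1); n_out <- sample(3:40, 1)
    x_in <- sample(0:n_in, 1); x_out <- sample(0:n_out, 1)
    tab <- matrix(c(x_in, n_in - x_in, x_out, n_out - x_out), 2)
    expect_equal(fisher_exact_frequency(x_in, n_in, x_out, n_out),
                 fisher.test(tab)$p.value, tolerance = 1e-7)
  }
})

test_that("Fisher's method combination follows the 4-df closed form", {
  expect_equal(combine_fisher(1, 1), 1)
  x <- -2 * (log(0.05) + log(0.05))
  expect_equal(combine_fisher(0.05, 0.05), exp(-x / 2) * (1 + x / 2),
               tolerance = 1e-12)
  expect_equal(combine_fisher(0.05, 0.05), 0.01747866137, tolerance = 1e-9)
  expect_equal(combine_fisher(0.3, 0.007), combine_fisher(0.007, 0.3))
  expect_gt(combine_fisher(0, 1), 0)     # zero floored, not -Inf
})

test_that("BH adjustment reproduces the hand-computed step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  p <- sort(runif(50))
  expect_true(all(diff(bh_adjust(p)) >= 0))
  expect_true(all(bh_adjust(p) <= 1))
})

test_that("find_markers columns agree with the scalar statistics", {
  set.seed(34)
  x <- random_counts(60, 25, mu = 3, size = 2, seed = 34)
  lab <- rep(c(1, 2), each = 30)
  mk <- find_markers(normalize_counts(x), lab)
  sub <- mk[mk$cluster == "1", ]
  norm <- normalize_counts(x)
  for (g in sample(gene_ids(x), 6)) {
    row <- sub[sub$gene == g, ]
    vals <- as.numeric(norm$values[, g])
    expect_equal(row$p_wilcoxon,
                 suppressWarnings(wilcox.test(vals[lab == 1], vals[lab == 2],
                                              exact = FALSE)$p.value),
                 tolerance = 1e-10)
    n_e_in <- sum(x$counts[lab == 1, g] > 0)
    n_e_out <- sum(x$counts[lab == 2, g] > 0)
    expect_equal(row$p_fisher, fisher_exact_frequency(n_e_in, 30, n_e_out, 30))
    expect_equal(row$p_combined, combine_fisher(row$p_wilcoxon, row$p_fisher))
    expect_equal(row$freq_in, n_e_in / 30)
  }
  expect_equal(sub$p_adj, bh_adjust(sub$p_combined), tolerance = 1e-12)
  expect_equal(sub$rank_score, sub$log2fc * (-log10(pmax(sub$p_adj, 1e-300))))
})

test_that("marker thresholds are enforced with the stated senses", {
  # gene A: strong 8-fold shift, expressed widely -> marker
  # gene B: ~2-fold shift (log2fc ~= 1) -> excluded on fold change
  # gene C: expressed in exactly 30% of the cluster -> excluded (strict >)
  set.seed(35)
  n <- 200
  m <- matrix(rnbinom(2 * n * 40, mu = 2, size = 5), 2 * n, 40)
  m[1:n, 1] <- rnbinom(n, mu = 30, size = 5)         # A in cluster 1
  m[(n + 1):(2 * n), 1] <- rnbinom(n, mu = 1, size = 5)
  m[1:n, 2] <- rnbinom(n, mu = 7, size = 5)          # B: mild shift
  m[(n + 1):(2 * n), 2] <- rnbinom(n, mu = 3, size = 5)
  m[, 3] <- 0L
  m[1:(0.3 * n), 3] <- 100L                          # C: freq_in exactly 0.3
  x <- cm_from_dense(m)
  lab <- rep(c(1, 2), each = n)
  mk <- find_markers(normalize_counts(x), lab)
  g1 <- mk[mk$cluster == "1", ]
  a <- g1[g1$gene == gene_ids(x)[1], ]
  expect_true(a$is_marker)
  expect_gte(abs(a$log2fc), 1.5)
  expect_lt(a$p_adj, 0.05)
  expect_gt(a$freq_in, 0.3)
  b <- g1[g1$gene == gene_ids(x)[2], ]
  expect_false(b$is_marker)
  expect_lt(abs(b$log2fc), 1.5)
  expect_lt(b$p_adj, 0.05)                           # significant but weak
  cc <- g1[g1$gene == gene_ids(x)[3], ]
  expect_equal(cc$freq_in, 0.3)
  expect_false(cc$is_marker)                         # strict > 0.3
})

test_that("tiny clusters are skipped with a warning", {
  x <- random_counts(43, 15, seed = 36)
  lab <- c(rep(1, 20), rep(2, 21), rep(3, 2))
  expect_warning(mk <- find_markers(normalize_counts(x), lab), "fewer than 3")
  expect_setequal(unique(mk$cluster), c("1", "2"))
})

test_that("preranked scores follow the sign and tie conventions", {
  mk <- data.frame(cluster = "1",
                   gene = c("B", "A", "C", "D"),
                   log2fc = c(2, 2, -3, 0),
                   p_adj = c(0.01, 0.01, 1e-4, 1),
                   rank_score = c(2 * 2, 2 * 2, -3 * 4, 0))
  class(mk) <- c("MarkerTable", "data.frame")
  r <- preranked_scores(mk, "1")
  expect_equal(r$score[1:2], c(4, 4))
  expect_equal(r$gene[1:2], c("A", "B"))             # lexicographic tie-break
  expect_equal(r$gene[4], "C")                       # negative sorts last
  expect_equal(r$score[3], 0)                        # p_adj = 1 -> score 0
  expect_error(preranked_scores(mk, "9"), "not present")
})
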