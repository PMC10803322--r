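test_that("normality screen accepts gaussians and rejects skewed data", {
  withr::local_seed(1)
  ok <- vapply(1:20, function(r)
    normality_screen(rnorm(1000))$p_value > 0.05, logical(1))
  expect_gte(mean(ok), 0.9)
  expect_lt(normality_screen(rlnorm(1000, sdlog = 1))$p_value, 0.05)
  res <- normality_screen(rep(3, 10))
  expect_equal(res$p_value, 0)
  expect_match(res$note, "constant")
  expect_error(normality_screen(1:4), "at least 5")
})

test_that("signed-rank exact branch matches hand enumeration", {
  # differences {+1,+2,+3}: W- = 0, exact two-sided p = 2/8
  r <- suppressWarnings(wilcoxon_paired(c(2, 4, 6), c(1, 2, 3)))
  expect_equal(r$W_minus, 0)
  expect_equal(r$W_plus, 6)
  expect_equal(r$p_value, 0.25)
  expect_identical(r$method, "exact")
  # perfectly antisymmetric differences -> p = 1
  r2 <- suppressWarnings(wilcoxon_paired(c(1, -1, 2, -2) + 5, rep(5, 4)))
  expect_equal(r2$p_value, 1, tolerance = 1e-9)
  # zero differences are dropped
  r3 <- suppressWarnings(wilcoxon_paired(c(3, 3, 5, 7, 9, 11, 13),
                                         c(3, 3, 1, 2, 3, 4, 5)))
  expect_equal(r3$n_pairs, 5L)
  # all-zero differences: undefined, p = 1 with warning
  expect_warning(r4 <- wilcoxon_paired(1:6, 1:6), "zero")
  expect_equal(r4$p_value, 1)
})

test_that("exact branch agrees with full 2^n enumeration on random cases", {
  withr::local_seed(2)
  for (r in 1:50) {
    n <- sample(5:10, 1)
    d <- round(rnorm(n), 6)
    d <- d[d != 0]
    while (anyDuplicated(abs(d)) || length(d) < 5) {
      d <- round(rnorm(n), 6); d <- d[d != 0]
    }
    mine <- suppressWarnings(wilcoxon_paired(d + 10, rep(10, length(d))))
    expect_identical(mine$method, "exact")
    expect_equal(mine$p_value, oracle_wilcox_exact(d), tolerance = 1e-12)
  }
})

test_that("ties and large n fall back to the corrected normal approximation", {
  withr::local_seed(3)
  d <- c(1, 1, 2, 3, 4, 5, 6)  # tied |differences|
  r <- suppressWarnings(wilcoxon_paired(d + 1, rep(1, 7)))
  expect_identical(r$method, "normal approximation")
  d2 <- rnorm(30)
  r2 <- wilcoxon_paired(d2, rep(0, 30))
  expect_identical(r2$method, "normal approximation")
  expect_true(r2$p_value >= 0 && r2$p_value <= 1)
})

test_that("signed-rank test detects a consistent paired shift", {
  withr::local_seed(4)
  hits <- vapply(1:50, function(r) {
    on <- rnorm(23, 10, 2)
    off <- on + rnorm(23, 0.5, 0.5)
    wilcoxon_paired(off, on)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("BH adjustment matches hand-worked examples and the step-up oracle", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  expect_equal(fdr_adjust(0.037), 0.037)
  expect_equal(fdr_adjust(c(0.001, 0.9)), c(0.002, 0.9))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  withr::local_seed(5)
  for (r in 1:100) {
    p <- runif(sample(1:50, 1))
    expect_lt(max(abs(fdr_adjust(p) - oracle_bh(p))), 1e-12)
  }
})

test_that("BH adjustment is monotone in the raw p-values", {
  withr::local_seed(6)
  for (r in 1:20) {
    p <- runif(30)
    adj <- fdr_adjust(p)
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-15))
  }
})

test_that("compare_conditions flags a planted shift with correct direction", {
  withr::local_seed(7)
  nodes <- paste0("N", 1:21)
  base <- matrix(rnorm(23 * 21, 10), 23, 21)
  off <- base
  off[, 3] <- off[, 3] + 1.5  # planted off > on on node N3
  res <- compare_conditions(toy_strengths(off, base, nodes))
  expect_equal(nrow(res), 21)
  r3 <- res[res$node == "N3", ]
  expect_true(r3$significant)
  expect_identical(r3$direction, "off>on")
  expect_true(all(res$p_fdr >= res$p_raw - 1e-15))
  # identical profiles -> no significances
  res0 <- compare_conditions(toy_strengths(base, base, nodes))
  expect_false(any(res0$significant))
})

test_that("comparison output is invariant to subject ordering", {
  withr::local_seed(8)
  nodes <- paste0("N", 1:6)
  off <- matrix(rnorm(12 * 6, 10), 12, 6)
  on <- off + matrix(rnorm(12 * 6, 0, 0.5), 12, 6)
  tab <- toy_strengths(off, on, nodes)
  shuffled <- tab[sample(nrow(tab)), ]
  a <- compare_conditions(tab)
  b <- compare_conditions(shuffled)
  b <- b[match(paste(a$axis, a$node), paste(b$axis, b$node)), ]
  expect_equal(a$p_raw, b$p_raw, tolerance = 1e-12)
  expect_equal(a$W_statistic, b$W_statistic)
})

test_that("subjects missing a condition are excluded; small axes are skipped", {
  withr::local_seed(9)
  nodes <- paste0("N", 1:3)
  tab <- toy_strengths(matrix(rnorm(8 * 3, 10), 8, 3),
                       matrix(rnorm(8 * 3, 10), 8, 3), nodes)
  tab <- tab[!(tab$subject == "S01" & tab$condition == "on"), ]
  expect_message(res <- compare_conditions(tab), "excluded")
  expect_equal(unique(res$n_pairs), 7L)
  tiny <- toy_strengths(matrix(rnorm(3 * 2, 10), 3, 2),
                        matrix(rnorm(3 * 2, 10), 3, 2), c("A", "B"))
  expect_warning(expect_warning(res_tiny <- compare_conditions(tiny),
                                "fewer than 5"), "empty result")
  expect_equal(nrow(res_tiny), 0)
})

test_that("pooled FDR family adjusts across axes jointly", {
  withr::local_seed(10)
  nodes <- c("A", "B")
  t1 <- toy_strengths(matrix(rnorm(10 * 2, 10), 10, 2),
                      matrix(rnorm(10 * 2, 10), 10, 2), nodes, axis = "ML")
  t2 <- toy_strengths(matrix(rnorm(10 * 2, 10), 10, 2),
                      matrix(rnorm(10 * 2, 10), 10, 2), nodes, axis = "AP")
  tab <- rbind(t1, t2)
  per_axis <- compare_conditions(tab, fdr_family = "axis")
  pooled <- compare_conditions(tab, fdr_family = "pooled")
  expect_equal(pooled$p_fdr, fdr_adjust(per_axis$p_raw), tolerance = 1e-12)
})
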