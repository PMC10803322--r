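toy_clinical <- function(n) {
  data.frame(subject_id = sprintf("S%02d", seq_len(n)),
             age = 60 + seq_len(n), gender = rep(c(0, 1), length.out = n),
             education_years = 10, disease_duration_months = 80,
             updrs_off = 29 - seq_len(n) %% 5, updrs_on = 17,
             stringsAsFactors = FALSE)
}

test_that("assemble_deltas applies the off-minus-on convention", {
  tab <- rbind(
    data.frame(subject = "S01", condition = "off", axis = "AP",
               node = "T10", strength = 12.0, n_trials = 4),
    data.frame(subject = "S01", condition = "on", axis = "AP",
               node = "T10", strength = 9.5, n_trials = 4))
  cl <- toy_clinical(1)
  cl$updrs_off <- 29; cl$updrs_on <- 17
  d <- assemble_deltas(tab, cl, "T10", "AP")
  expect_equal(d$delta_T10, 2.5)
  expect_equal(d$delta_updrs, 12)
  expect_named(d, c("subject_id", "delta_updrs", "delta_T10", "age",
                    "gender", "education_years", "disease_duration_months"))
  # empty node selection gives a covariates-only table
  d0 <- assemble_deltas(tab, cl, character(0), "AP")
  expect_false(any(grepl("^delta_T10", names(d0))))
  # subject missing a condition's profile is dropped with a message
  cl2 <- toy_clinical(2)
  expect_message(d2 <- assemble_deltas(tab, cl2, "T10", "AP"), "S02 dropped")
  expect_equal(nrow(d2), 1)
})

test_that("VIF matches the closed form and the brute-force oracle", {
  withr::local_seed(1)
  # orthogonal standardized predictors -> VIF 1
  x1 <- rep(c(-1, 1), 50); x2 <- rep(c(-1, 1), each = 50)
  v <- vif_screen(data.frame(x1 = x1, x2 = x2))
  expect_equal(v$vif, c(1, 1), tolerance = 1e-9)
  expect_false(any(v$flagged))
  # duplicated column -> unbounded, flagged, no crash
  v2 <- vif_screen(data.frame(a = x1, b = x1))
  expect_true(all(is.infinite(v2$vif)))
  expect_true(all(v2$flagged))
  # correlation 0.8 -> VIF ~ 1/(1-0.64)
  z <- rnorm(500)
  a <- 0.8 * z + sqrt(1 - 0.64) * rnorm(500)
  v3 <- vif_screen(data.frame(z = z, a = a))
  expect_equal(v3$vif, rep(1 / (1 - 0.64), 2), tolerance = 0.1 * 2.78)
  # random designs against the normal-equations oracle
  for (r in 1:20) {
    X <- matrix(rnorm(40 * 4), 40, 4,
                dimnames = list(NULL, paste0("p", 1:4)))
    expect_lt(max(abs(vif_screen(X)$vif - oracle_vif(X))), 1e-9)
  }
})

test_that("VIF agrees with the car package on a random design", {
  withr::local_seed(2)
  X <- as.data.frame(matrix(rnorm(60 * 3), 60, 3))
  names(X) <- c("a", "b", "c")
  X$y <- rnorm(60)
  ours <- vif_screen(X[, c("a", "b", "c")])$vif
  theirs <- car::vif(stats::lm(y ~ a + b + c, data = X))
  expect_equal(ours, unname(theirs), tolerance = 1e-9)
})

test_that("noise-free linear truth is recovered exactly", {
  withr::local_seed(3)
  n <- 40
  x1 <- rnorm(n); x2 <- rnorm(n)
  deltas <- data.frame(subject_id = sprintf("S%02d", 1:n),
                       delta_updrs = 2 * x1 - x2,
                       delta_A = x1, delta_B = x2)
  fit <- suppressWarnings(fit_multilinear(deltas))  # lm warns on perfect fit
  co <- fit$coefficients
  expect_equal(co$beta[co$predictor == "delta_A"], 2, tolerance = 1e-9)
  expect_equal(co$beta[co$predictor == "delta_B"], -1, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(length(fit$residuals_std), n)
  # rank-deficient design errors, citing the collinear predictor
  deltas$delta_C <- deltas$delta_A
  expect_error(fit_multilinear(deltas), "delta_")
})

test_that("type-I error of predictor p-values is near nominal under the null", {
  withr::local_seed(4)
  hits <- vapply(1:200, function(r) {
    n <- 50
    deltas <- data.frame(subject_id = as.character(1:n),
                         delta_updrs = rnorm(n),
                         delta_A = rnorm(n), delta_B = rnorm(n))
    fit <- fit_multilinear(deltas)
    fit$coefficients$p_value[fit$coefficients$predictor == "delta_A"] < 0.05
  }, logical(1))
  # binomial(200, 0.05): mean within ~3 SD of nominal
  expect_lt(abs(mean(hits) - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("R^2 and standardized betas are invariant to predictor rescaling", {
  withr::local_seed(5)
  n <- 30
  deltas <- data.frame(subject_id = as.character(1:n),
                       delta_updrs = rnorm(n, 10),
                       delta_A = rnorm(n), delta_B = rnorm(n))
  f1 <- fit_multilinear(deltas)
  deltas2 <- deltas
  deltas2$delta_A <- deltas2$delta_A * 250 + 3
  f2 <- fit_multilinear(deltas2)
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-12)
  expect_equal(f1$coefficients$beta_std, f2$coefficients$beta_std,
               tolerance = 1e-9)
})

test_that("cross-validation partitions correctly and is seed-reproducible", {
  withr::local_seed(6)
  n <- 23
  deltas <- data.frame(subject_id = as.character(1:n),
                       delta_updrs = rnorm(n, 10),
                       delta_A = rnorm(n), delta_B = rnorm(n))
  cv <- crossvalidate(deltas, k = 5, repetitions = 10, seed = 77)
  expect_equal(cv$fold_sizes, c(5, 5, 5, 4, 4))
  expect_equal(nrow(cv$per_repetition), 10)
  cv2 <- crossvalidate(deltas, k = 5, repetitions = 10, seed = 77)
  expect_identical(cv$per_repetition, cv2$per_repetition)
  cv3 <- crossvalidate(deltas, k = 5, repetitions = 10, seed = 78)
  expect_false(identical(cv$per_repetition, cv3$per_repetition))
  expect_error(crossvalidate(deltas, k = 24), "exceeds")
  # each subject held out exactly once per repetition: pooled predictions
  # exist for all subjects, so RMSE is finite
  expect_true(all(is.finite(cv$per_repetition$rmse)))
})

test_that("noise-free linear truth cross-validates perfectly", {
  withr::local_seed(7)
  n <- 23
  x <- rnorm(n)
  deltas <- data.frame(subject_id = as.character(1:n),
                       delta_updrs = 3 * x + 1, delta_A = x)
  cv <- crossvalidate(deltas, k = 5, repetitions = 5, seed = 1)
  expect_true(all(abs(cv$per_repetition$cor - 1) < 1e-9))
  expect_true(all(cv$per_repetition$rmse < 1e-9))
})

test_that("out-of-sample performance shows optimism relative to training", {
  withr::local_seed(8)
  n <- 30
  x1 <- rnorm(n); x2 <- rnorm(n)
  deltas <- data.frame(subject_id = as.character(1:n),
                       delta_updrs = x1 - 0.5 * x2 + rnorm(n, 0, 1.5),
                       delta_A = x1, delta_B = x2)
  fit <- fit_multilinear(deltas)
  train_cor <- sqrt(fit$r_squared)
  cv <- crossvalidate(deltas, k = 5, repetitions = 50, seed = 9)
  expect_lte(cv$mean_cor, train_cor + 0.02)
})
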