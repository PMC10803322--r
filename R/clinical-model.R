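#' Assemble per-subject clinical and topological deltas
#'
#' Builds the regression table for predicting clinical motor-score change
#' from nodal-strength change. All deltas follow the off-minus-on
#' convention: `delta_updrs = UPDRS-III(off) - UPDRS-III(on)` and, for
#' each selected node, `delta_<node> = S(off) - S(on)` on the named axis.
#' Nuisance covariates (age in years, gender as a binary code, education
#' in years, disease duration in months) are carried along. Subjects
#' lacking either condition's averaged profile or a clinical score are
#' dropped with a message.
#'
#' @param strengths Long-format table from [strength_table()] of
#'   trial-averaged profiles.
#' @param clinical Data frame with columns `subject_id`, `age`, `gender`,
#'   `education_years`, `disease_duration_months`, `updrs_off`,
#'   `updrs_on`.
#' @param nodes Character vector of node labels whose strength deltas
#'   enter as predictors (may be empty for a covariates-only table).
#' @param axis Axis of the selected nodes (default `"AP"`).
#' @return A data frame with one row per retained subject: `subject_id`,
#'   `delta_updrs`, one `delta_<node>` column per node, and the
#'   covariates.
#' @export
assemble_deltas <- function(strengths, clinical, nodes, axis = "AP") {
  need <- c("subject_id", "age", "gender", "education_years",
            "disease_duration_months", "updrs_off", "updrs_on")
  if (!all(need %in% names(clinical)))
    stop("clinical table must have columns ", paste(need, collapse = ", "))
  sub <- strengths[strengths$axis == axis & strengths$node %in% nodes, ]
  rows <- list()
  for (sid in clinical$subject_id) {
    cl <- clinical[clinical$subject_id == sid, ][1, ]
    if (!is.finite(cl$updrs_off) || !is.finite(cl$updrs_on)) {
      message("subject ", sid, " dropped: missing clinical score")
      next
    }
    row <- data.frame(subject_id = sid,
                      delta_updrs = cl$updrs_off - cl$updrs_on,
                      stringsAsFactors = FALSE)
    ok <- TRUE
    for (nd in nodes) {
      s_off <- sub$strength[sub$subject == sid & sub$node == nd &
                              sub$condition == "off"]
      s_on <- sub$strength[sub$subject == sid & sub$node == nd &
                             sub$condition == "on"]
      if (length(s_off) != 1 || length(s_on) != 1) {
        message("subject ", sid, " dropped: missing ", axis, " profile for ", nd)
        ok <- FALSE
        break
      }
      row[[paste0("delta_", nd)]] <- s_off - s_on
    }
    if (!ok) next
    row$age <- cl$age
    row$gender <- cl$gender
    row$education_years <- cl$education_years
    row$disease_duration_months <- cl$disease_duration_months
    rows[[length(rows) + 1L]] <- row
  }
  if (!length(rows)) stop("no subject had complete data")
  do.call(rbind, rows)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` is the coefficient of
#' determination from regressing predictor j on all other predictors
#' (with intercept). A perfectly collinear predictor is reported as
#' `Inf` and flagged rather than raising an error.
#'
#' @param predictors Data frame or matrix of numeric predictors (at
#'   least two columns, more rows than columns).
#' @param threshold Flagging threshold (default 5).
#' @return A data frame with columns `predictor`, `vif`, `flagged`.
#' @export
vif_screen <- function(predictors, threshold = 5) {
  x <- as.matrix(predictors)
  if (ncol(x) < 2) stop("need at least 2 predictors")
  if (nrow(x) <= ncol(x)) stop("need more rows than predictors")
  vifs <- vapply(seq_len(ncol(x)), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    tss <- sum((x[, j] - mean(x[, j]))^2)
    rss <- sum(fit$residuals^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  data.frame(predictor = colnames(x), vif = vifs,
             flagged = !is.finite(vifs) | vifs > threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Multilinear regression of clinical change on topological change
#'
#' Ordinary least squares of `delta_updrs` on every other (non-id)
#' column of the delta table. Reports raw and standardized coefficients,
#' t-based p-values, the training R^2, standardized residuals, and the
#' VIF screen of the design.
#'
#' @param deltas Table from [assemble_deltas()].
#' @param vif_threshold Passed to [vif_screen()].
#' @return An object of class `clinical_model` with elements
#'   `coefficients` (data frame: predictor, beta, beta_std, p_value),
#'   `r_squared`, `vif`, `residuals_std`, `fit` (the underlying `lm`),
#'   and `n`.
#' @export
fit_multilinear <- function(deltas, vif_threshold = 5) {
  pred_cols <- setdiff(names(deltas), c("subject_id", "delta_updrs"))
  if (!length(pred_cols)) stop("no predictors in delta table")
  if (nrow(deltas) <= length(pred_cols) + 1)
    stop("need more subjects than predictors + 1")
  vif <- if (length(pred_cols) >= 2)
    vif_screen(deltas[, pred_cols, drop = FALSE], vif_threshold) else NULL
  form <- stats::as.formula(paste("delta_updrs ~",
                                  paste(pred_cols, collapse = " + ")))
  fit <- stats::lm(form, data = deltas)
  if (any(is.na(stats::coef(fit)))) {
    flagged <- if (!is.null(vif)) vif$predictor[vif$flagged] else character(0)
    stop("rank-deficient design; collinear predictors flagged by VIF: ",
         paste(flagged, collapse = ", "))
  }
  sm <- summary(fit)
  co <- sm$coefficients
  sd_y <- stats::sd(deltas$delta_updrs)
  beta_std <- vapply(rownames(co), function(p) {
    if (p == "(Intercept)") return(NA_real_)
    co[p, 1] * stats::sd(deltas[[p]]) / sd_y
  }, numeric(1))
  res <- fit$residuals
  structure(list(
    coefficients = data.frame(predictor = rownames(co),
                              beta = co[, 1], beta_std = beta_std,
                              p_value = co[, 4],
                              stringsAsFactors = FALSE, row.names = NULL),
    r_squared = sm$r.squared,
    vif = vif,
    residuals_std = as.numeric(scale(res)),
    fit = fit,
    n = nrow(deltas)), class = "clinical_model")
}

#' @export
print.clinical_model <- function(x, ...) {
  cat(sprintf("<clinical_model> n = %d, R^2 = %.3f\n", x$n, x$r_squared))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Repeated k-fold cross-validation of the clinical model
#'
#' For each repetition, subjects are randomly partitioned into `k` folds
#' whose sizes differ by at most one; each fold is held out once while
#' the model is refit on the remainder, and the pooled out-of-sample
#' predictions are compared with the actual values. The summary is the
#' distribution, over repetitions, of the pooled predicted-vs-actual
#' Pearson correlation and root-mean-squared error. A predictor that is
#' aliased within a training fold (e.g. a binary covariate constant in
#' that fold) contributes nothing to the fold's held-out predictions.
#'
#' @param deltas Table from [assemble_deltas()].
#' @param k Number of folds (default 5).
#' @param repetitions Number of random re-partitions (default 100).
#' @param seed Integer seed governing all partitions.
#' @return An object of class `cv_summary`: data frame `per_repetition`
#'   (`repetition`, `cor`, `rmse`), `mean_cor`, `sd_cor`, `mean_rmse`,
#'   `sd_rmse`, and the `seed`, `k`, `repetitions` used.
#' @export
crossvalidate <- function(deltas, k = 5, repetitions = 100, seed = 1) {
  n <- nrow(deltas)
  if (k > n) stop("k (", k, ") exceeds the number of subjects (", n, ")")
  pred_cols <- setdiff(names(deltas), c("subject_id", "delta_updrs"))
  form <- stats::as.formula(paste("delta_updrs ~",
                                  paste(pred_cols, collapse = " + ")))
  set.seed(seed)
  reps <- lapply(seq_len(repetitions), function(r) {
    fold <- sample(rep(seq_len(k), length.out = n))
    pred <- numeric(n)
    for (f in seq_len(k)) {
      test <- fold == f
      fit <- stats::lm(form, data = deltas[!test, , drop = FALSE])
      # a predictor can be aliased within a training fold (e.g. a binary
      # covariate constant in the fold); it then contributes nothing to
      # the held-out prediction
      beta <- stats::coef(fit)
      beta[is.na(beta)] <- 0
      X <- stats::model.matrix(stats::delete.response(stats::terms(fit)),
                               data = deltas[test, , drop = FALSE])
      pred[test] <- drop(X %*% beta)
    }
    actual <- deltas$delta_updrs
    data.frame(repetition = r,
               cor = if (stats::sd(pred) > 0) stats::cor(pred, actual)
                     else NA_real_,
               rmse = sqrt(mean((pred - actual)^2)))
  })
  per <- do.call(rbind, reps)
  structure(list(per_repetition = per,
                 mean_cor = mean(per$cor), sd_cor = stats::sd(per$cor),
                 mean_rmse = mean(per$rmse), sd_rmse = stats::sd(per$rmse),
                 seed = seed, k = k, repetitions = repetitions,
                 fold_sizes = sort(tabulate(rep(seq_len(k), length.out = n),
                                            k), decreasing = TRUE)),
            class = "cv_summary")
}

#' @export
print.cv_summary <- function(x, ...) {
  cat(sprintf(
    "<cv_summary> %d-fold CV x %d repetitions (seed %d): cor %.3f +/- %.3f, RMSE %.3f +/- %.3f\n",
    x$k, x$repetitions, x$seed, x$mean_cor, x$sd_cor, x$mean_rmse, x$sd_rmse))
  invisible(x)
}
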