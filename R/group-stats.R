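#' Normality screen
#'
#' One-sample Kolmogorov-Smirnov test of the standardized values against
#' the standard normal. Advisory only: the comparison pipeline proceeds
#' nonparametrically regardless of the outcome. Standardizing with the
#' sample mean and SD makes the test conservative (Lilliefors effect),
#' which is acceptable for a screen. A constant sample is degenerate and
#' reported as non-normal with a note.
#'
#' @param values Numeric vector of at least 5 observations.
#' @return A list with `statistic`, `p_value`, `n` and `note`.
#' @export
normality_screen <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 5) stop("need at least 5 observations")
  s <- stats::sd(values)
  if (s == 0)
    return(list(statistic = NA_real_, p_value = 0, n = length(values),
                note = "constant sample; degenerate, treated as non-normal"))
  z <- (values - mean(values)) / s
  kt <- suppressWarnings(stats::ks.test(z, "pnorm"))
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       n = length(values), note = NA_character_)
}

#' Paired two-sided Wilcoxon signed-rank test
#'
#' Compares paired per-subject measurements between the off and on
#' conditions. Zero differences are dropped (Wilcoxon's original
#' treatment). The exact null distribution is used when the number of
#' non-zero differences is at most 25 and their absolute values are
#' untied; otherwise the normal approximation with continuity and tie
#' correction is used. If every difference is zero the test is undefined
#' and `p = 1` is returned with a warning.
#'
#' @param off_values,on_values Equal-length numeric vectors paired by
#'   subject.
#' @param exact_max Largest n for which the exact distribution is used
#'   (default 25).
#' @return A list with `W_plus` (sum of positive ranks, the reported
#'   `W_statistic`), `W_minus`, `n_pairs` (after zero removal), `p_value`
#'   and `method`.
#' @export
wilcoxon_paired <- function(off_values, on_values, exact_max = 25) {
  if (length(off_values) != length(on_values))
    stop("off and on vectors must have equal length (paired by subject)")
  d <- off_values - on_values
  d <- d[is.finite(d)]
  d_nz <- d[d != 0]
  n <- length(d_nz)
  if (n == 0) {
    warning("all paired differences are zero; test undefined, reporting p = 1")
    return(list(W_plus = 0, W_minus = 0, n_pairs = 0L, p_value = 1,
                method = "degenerate"))
  }
  if (n < 5)
    warning("fewer than 5 non-zero pairs; signed-rank test has little power")
  r <- rank(abs(d_nz))
  w_plus <- sum(r[d_nz > 0])
  w_minus <- sum(r[d_nz < 0])
  ties <- anyDuplicated(abs(d_nz)) > 0
  use_exact <- (n <= exact_max) && !ties
  wt <- suppressWarnings(stats::wilcox.test(d_nz, exact = use_exact,
                                            correct = TRUE))
  list(W_plus = w_plus, W_minus = w_minus, n_pairs = as.integer(n),
       p_value = wt$p.value,
       method = if (use_exact) "exact" else "normal approximation")
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values `p~_(i) = min_{k >= i} (m p_(k) / k)`,
#' clipped at 1 and mapped back to input order. Monotone in the raw
#' p-values. `method = "BY"` gives the Benjamini-Yekutieli variant valid
#' under arbitrary dependence.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param method `"BH"` (default) or `"BY"`.
#' @return Adjusted p-values in input order.
#' @export
fdr_adjust <- function(p_values, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must be finite and in [0, 1]")
  stats::p.adjust(p_values, method = method)
}

#' Paired comparison of nodal strength between conditions
#'
#' For each axis, runs the paired two-sided Wilcoxon signed-rank test on
#' every node's trial-averaged nodal strength (off vs on across
#' subjects), adjusts the 21 per-node p-values within the axis by the
#' false discovery rate, and declares the direction of significant nodes
#' by the median paired difference. Subjects missing a condition are
#' excluded; an axis with fewer than 5 complete pairs is skipped with a
#' warning. With `fdr_family = "pooled"` the adjustment is instead
#' applied across all axes jointly.
#'
#' @param strengths Long-format data frame from [strength_table()] of
#'   trial-averaged profiles (columns `subject`, `condition`, `axis`,
#'   `node`, `strength`).
#' @param alpha Significance level on the adjusted p-value (default
#'   0.05).
#' @param fdr_family `"axis"` (default) or `"pooled"`.
#' @param fdr_method `"BH"` (default) or `"BY"`.
#' @return A data frame with one row per (axis, node): `n_pairs`,
#'   `W_statistic` (sum of positive ranks), `p_raw`, `p_fdr`,
#'   `median_off`, `median_on`, `significant`, `direction`
#'   (`off>on`, `on>off` or `none`).
#' @export
compare_conditions <- function(strengths, alpha = 0.05,
                               fdr_family = c("axis", "pooled"),
                               fdr_method = c("BH", "BY")) {
  fdr_family <- match.arg(fdr_family)
  fdr_method <- match.arg(fdr_method)
  need <- c("subject", "condition", "axis", "node", "strength")
  if (!all(need %in% names(strengths)))
    stop("strength table must have columns ", paste(need, collapse = ", "))
  rows <- list()
  for (ax in unique(strengths$axis)) {
    sub <- strengths[strengths$axis == ax, ]
    wide_off <- sub[sub$condition == "off", ]
    wide_on <- sub[sub$condition == "on", ]
    common <- intersect(unique(wide_off$subject), unique(wide_on$subject))
    dropped <- setdiff(unique(sub$subject), common)
    if (length(dropped))
      message(length(dropped), " subject(s) missing a condition on axis ",
              ax, "; excluded: ", paste(dropped, collapse = ", "))
    if (length(common) < 5) {
      warning("fewer than 5 complete pairs on axis ", ax, "; axis skipped")
      next
    }
    for (nd in unique(sub$node)) {
      off_v <- wide_off$strength[wide_off$node == nd][
                 match(common, wide_off$subject[wide_off$node == nd])]
      on_v <- wide_on$strength[wide_on$node == nd][
                match(common, wide_on$subject[wide_on$node == nd])]
      wt <- suppressWarnings(wilcoxon_paired(off_v, on_v))
      rows[[length(rows) + 1L]] <- data.frame(
        axis = ax, node = nd, n_pairs = length(common),
        W_statistic = wt$W_plus, p_raw = wt$p_value,
        median_off = stats::median(off_v), median_on = stats::median(on_v),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    warning("no axis had enough complete pairs to compare; empty result")
    return(data.frame(axis = character(0), node = character(0),
                      n_pairs = integer(0), W_statistic = numeric(0),
                      p_raw = numeric(0), median_off = numeric(0),
                      median_on = numeric(0), p_fdr = numeric(0),
                      significant = logical(0), direction = character(0)))
  }
  res <- do.call(rbind, rows)
  if (fdr_family == "axis") {
    res$p_fdr <- stats::ave(res$p_raw, res$axis,
                            FUN = function(p) fdr_adjust(p, fdr_method))
  } else {
    res$p_fdr <- fdr_adjust(res$p_raw, fdr_method)
  }
  res$significant <- res$p_fdr < alpha
  md <- res$median_off - res$median_on
  res$direction <- ifelse(!res$significant, "none",
                          ifelse(md > 0, "off>on", "on>off"))
  res
}
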