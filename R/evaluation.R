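# Figures of merit for calibration models: RMSE family, recovery
# statistics, predicted-vs-actual regression, and the method-comparison t/F
# tests used to benchmark against a reference method.

#' Root-mean-square error
#'
#' `sqrt(sum((pred - actual)^2) / n)`. The same formula yields RMSEC over
#' the calibration fit, RMSECV over leave-one-out hold-outs, and RMSEP over
#' an independent validation set -- only the sample set differs.
#'
#' @param predicted,actual Aligned numeric vectors (or matrices, pooled).
#' @return Non-negative scalar (ug/mL for concentration errors).
#' @examples
#' rmse(c(0.1, -0.1, 0.2, -0.2), rep(0, 4)) # 0.158114
#' @export
rmse <- function(predicted, actual) {
  if (length(predicted) != length(actual)) stop("length mismatch")
  if (length(predicted) == 0) stop("empty input")
  sqrt(sum((predicted - actual)^2) / length(predicted))
}

#' Recovery and regression statistics
#'
#' Per-sample recoveries `R_i = 100 yhat_i / y_i`, their mean, standard
#' deviation (n-1) and relative standard deviation `100 sd / mean_R`; mean
#' relative error `re_pct = 100 mean(|yhat - y| / y)`; Pearson correlation
#' of predicted vs actual; and the ordinary least-squares slope/intercept of
#' predicted on actual.
#'
#' @param predicted,actual Aligned numeric vectors; `actual` strictly
#'   positive, `n >= 2`.
#' @return One-row tibble: `mean_r_pct`, `sd`, `rsd_pct`, `re_pct`, `r`,
#'   `slope`, `intercept`, `n`. With constant inputs `r` is reported as `NA`
#'   (undefined), never 0.
#' @export
recovery_stats <- function(predicted, actual) {
  if (length(predicted) != length(actual)) stop("length mismatch")
  n <- length(actual)
  if (n < 2) stop("need at least 2 samples")
  if (any(actual <= 0)) stop("actual concentrations must be > 0")
  rec <- 100 * predicted / actual
  mean_r <- mean(rec)
  s <- stats::sd(rec)
  r <- if (stats::sd(predicted) == 0 || stats::sd(actual) == 0) NA_real_ else
    stats::cor(predicted, actual)
  line <- if (stats::sd(actual) == 0) c(NA_real_, NA_real_) else
    stats::lm.fit(cbind(1, actual), predicted)$coefficients
  tibble::tibble(
    mean_r_pct = mean_r,
    sd = s,
    rsd_pct = 100 * s / mean_r,
    re_pct = 100 * mean(abs(predicted - actual) / actual),
    r = r,
    slope = unname(line[2]),
    intercept = unname(line[1]),
    n = n
  )
}

#' Per-component evaluation report
#'
#' Combines [rmse()] and [recovery_stats()] component by component for a
#' predicted/actual pair of concentration tables.
#'
#' @param predicted,actual Concentration tibbles with identical components
#'   and aligned samples.
#' @param kind Label for the RMSE column (`"rmsec"`, `"rmsecv"` or
#'   `"rmsep"`), reflecting which sample set the errors come from.
#' @return A tibble of class `evaluation_report`, one row per component:
#'   the RMSE (named by `kind`) plus all [recovery_stats()] columns.
#' @export
evaluation_report <- function(predicted, actual, kind = c("rmsep", "rmsec", "rmsecv")) {
  kind <- match.arg(kind)
  predicted <- conc_table(predicted)
  actual <- conc_table(actual)
  comp <- components(actual)
  if (!setequal(comp, components(predicted))) stop("component mismatch")
  out <- purrr::map_dfr(comp, function(cn) {
    stats <- recovery_stats(predicted[[cn]], actual[[cn]])
    dplyr::bind_cols(tibble::tibble(component = cn,
                                    "{kind}" := rmse(predicted[[cn]], actual[[cn]])),
                     stats)
  })
  structure(out, class = c("evaluation_report", class(out)))
}

#' Two-sample method comparison (t and F tests)
#'
#' Pooled-variance two-sample Student t test on the group means and an F
#' test on the variances (larger variance in the numerator, so `F >= 1`),
#' with critical values computed from the t and F quantiles at `alpha`
#' (two-tailed t; upper-tail F). For two groups of five recoveries the
#' critical values are 2.306 and 6.39. A paired t test is available for
#' within-sample designs.
#'
#' @param recoveries_a,recoveries_b Numeric vectors (e.g. percent
#'   recoveries from two methods), each `n >= 2`.
#' @param alpha Significance level. Default 0.05.
#' @param paired Use a paired t test (groups must be equal length).
#' @return A one-row tibble of class `method_comparison`: `t_stat`, `df_t`,
#'   `t_crit`, `f_stat`, `df_f_num`, `df_f_den`, `f_crit`, `alpha`. A zero
#'   pooled variance with unequal means yields an infinite `t_stat`.
#' @examples
#' compare_methods(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6)) # t = -1, F = 1
#' @export
compare_methods <- function(recoveries_a, recoveries_b, alpha = 0.05, paired = FALSE) {
  a <- recoveries_a; b <- recoveries_b
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  if (paired) {
    if (length(a) != length(b)) stop("paired comparison needs equal group sizes")
    d <- a - b
    df_t <- length(d) - 1
    sd_d <- stats::sd(d)
    t_stat <- if (sd_d == 0) {
      if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    } else mean(d) / (sd_d / sqrt(length(d)))
  } else {
    df_t <- length(a) + length(b) - 2
    sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) / df_t
    se <- sqrt(sp2 * (1 / length(a) + 1 / length(b)))
    t_stat <- if (se == 0) {
      if (mean(a) == mean(b)) 0 else sign(mean(a) - mean(b)) * Inf
    } else (mean(a) - mean(b)) / se
  }
  va <- stats::var(a); vb <- stats::var(b)
  if (va >= vb) {
    f_stat <- if (vb == 0) { if (va == 0) 1 else Inf } else va / vb
    df_f <- c(length(a) - 1, length(b) - 1)
  } else {
    f_stat <- vb / va
    df_f <- c(length(b) - 1, length(a) - 1)
  }
  structure(
    tibble::tibble(
      t_stat = t_stat, df_t = df_t,
      t_crit = stats::qt(1 - alpha / 2, df_t),
      f_stat = f_stat, df_f_num = df_f[1], df_f_den = df_f[2],
      f_crit = stats::qf(1 - alpha, df_f[1], df_f[2]),
      alpha = alpha
    ),
    class = c("method_comparison", "tbl_df", "tbl", "data.frame")
  )
}

#' Relative RMSEP reduction
#'
#' `100 (baseline - model) / baseline`: the percent improvement of a model's
#' prediction error over a baseline model's.
#'
#' @param rmsep_model,rmsep_baseline RMSEP values; baseline must be > 0.
#' @return Percent reduction (100 for a perfect predictor, 0 for parity,
#'   negative when the model is worse).
#' @export
rmsep_reduction <- function(rmsep_model, rmsep_baseline) {
  if (rmsep_baseline <= 0) stop("baseline RMSEP must be > 0")
  100 * (rmsep_baseline - rmsep_model) / rmsep_baseline
}
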