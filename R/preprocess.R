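#' Savitzky-Golay smoothing and derivatives
#'
#' Local least-squares polynomial filtering of each spectrum, optionally
#' returning the analytic derivative of the fitted polynomial. The default
#' 11-point cubic window is the classical choice for bench UV data. Output
#' keeps the full grid length: edge points take the value of the polynomial
#' fitted to the nearest full window, so the wavelength grid never shrinks.
#' Derivatives are scaled by `step_nm^-deriv`, giving grid-independent units
#' of AU/nm^d.
#'
#' @param spectra A [spectral_matrix()] on a uniform grid.
#' @param window Odd window length in points (> `poly`), default 11.
#' @param poly Polynomial order, default 3.
#' @param deriv Derivative order, 0, 1 or 2 (<= `poly`).
#' @return A [spectral_matrix()] with stage `"smoothed"`, `"derivative1"` or
#'   `"derivative2"`.
#' @examples
#' g <- wavelength_grid(200, 220, 0.5)
#' x <- spectral_matrix(matrix(exp(-(g$labels - 210)^2 / 20), 1), g)
#' d1 <- savgol(x, deriv = 1)
#' @export
savgol <- function(spectra, window = 11, poly = 3, deriv = 0) {
  stopifnot(inherits(spectra, "spectral_matrix"))
  if (window %% 2 == 0) stop("`window` must be odd")
  if (window > grid_points(spectra$grid)) {
    stop("`window` (", window, ") exceeds the spectrum length (",
         grid_points(spectra$grid), ")")
  }
  if (poly >= window) stop("`poly` must be < `window`")
  if (!deriv %in% 0:2) stop("`deriv` must be 0, 1 or 2")
  if (deriv > poly) stop("`deriv` must be <= `poly`")
  out <- t(apply(spectra$absorbance, 1, function(row) {
    signal::sgolayfilt(row, p = poly, n = window, m = deriv,
                       ts = spectra$grid$step_nm)
  }))
  if (nrow(spectra$absorbance) == 1) out <- matrix(out, nrow = 1)
  stage <- switch(as.character(deriv), "0" = "smoothed",
                  "1" = "derivative1", "2" = "derivative2")
  replace_absorbance(spectra, out, stage = stage)
}

#' Standard normal variate transform
#'
#' Centers and scales each spectrum to mean 0 and unit standard deviation
#' (n-1 denominator), removing multiplicative scatter and path-length
#' effects. Invariant to per-spectrum positive affine transforms.
#'
#' @param spectra A [spectral_matrix()].
#' @return A [spectral_matrix()] with stage `"snv"`.
#' @export
snv <- function(spectra) {
  stopifnot(inherits(spectra, "spectral_matrix"))
  sds <- apply(spectra$absorbance, 1, stats::sd)
  if (any(sds == 0)) {
    stop("constant spectrum (zero variance): sample '",
         spectra$sample_ids[which(sds == 0)[1]], "'")
  }
  out <- (spectra$absorbance - rowMeans(spectra$absorbance)) / sds
  replace_absorbance(spectra, out, stage = "snv")
}

#' Sequential preprocessing pipeline
#'
#' Applies an ordered sequence of preprocessing steps. Steps are drawn from
#' `"savgol"` (smoothing), `"derivative"` (Savitzky-Golay derivative of order
#' `deriv`), `"snv"` and `"mean_center"`. The empty pipeline is the identity.
#' The package default is smoothing + first derivative: it suppresses
#' high-frequency noise and removes baseline offsets while keeping the
#' concentration scale of the signal. SNV is available as an explicit step
#' for scatter-dominated data, but it standardizes each spectrum to unit
#' variance and therefore discards the overall intensity: in a strictly
#' bilinear two-analyte system that collapses the two concentration degrees
#' of freedom to their ratio, so it is not part of the default chain.
#' Mean-centering, when requested, is applied after SNV.
#'
#' @param spectra A [spectral_matrix()].
#' @param steps Character vector of step names, applied left to right.
#' @param window,poly Savitzky-Golay window and polynomial order.
#' @param deriv Derivative order used by the `"derivative"` step (1 or 2).
#' @return A [spectral_matrix()]; if `"mean_center"` is among the steps the
#'   column means are attached as attribute `"column_means"`.
#' @export
preprocess_pipeline <- function(spectra,
                                steps = c("savgol", "derivative"),
                                window = 11, poly = 3, deriv = 1) {
  stopifnot(inherits(spectra, "spectral_matrix"))
  known <- c("savgol", "derivative", "snv", "mean_center")
  if (!all(steps %in% known)) {
    stop("unknown step(s): ", paste(setdiff(steps, known), collapse = ", "))
  }
  out <- spectra
  for (s in steps) {
    out <- switch(s,
      savgol = savgol(out, window = window, poly = poly, deriv = 0),
      derivative = savgol(out, window = window, poly = poly, deriv = deriv),
      snv = snv(out),
      mean_center = {
        cc <- mean_center(out)
        attr(cc$centered, "column_means") <- cc$means
        cc$centered
      })
  }
  out
}

#' PCA diagnostics of a spectral data set
#'
#' Singular-value decomposition of the mean-centered absorbance block,
#' reporting scores and per-component percentages of total variance; used to
#' check calibration/validation homogeneity before modeling.
#'
#' @param spectra A [spectral_matrix()] with >= 2 samples.
#' @param set_labels Optional per-sample labels (e.g. `"calibration"` /
#'   `"validation"`).
#' @param n_pcs Number of score columns to keep (default all).
#' @return An object of class `pca_summary`: list with `scores` (tibble:
#'   `sample_id`, `set`, `PC1`, ...), `variance_pct` (all components, in
#'   decreasing order) and `total_variance`.
#' @export
pca_summary <- function(spectra, set_labels = NULL, n_pcs = NULL) {
  stopifnot(inherits(spectra, "spectral_matrix"))
  n <- nrow(spectra$absorbance)
  if (n < 2) stop("PCA needs at least 2 samples")
  if (is.null(set_labels)) set_labels <- rep("all", n)
  if (length(set_labels) != n) stop("need one set label per sample")
  xc <- mean_center(spectra$absorbance)$centered
  sv <- svd(xc)
  ev <- sv$d^2
  keep <- if (is.null(n_pcs)) sum(ev > 0) else min(n_pcs, length(ev))
  keep <- max(keep, 1L)
  scores <- sv$u[, seq_len(keep), drop = FALSE] %*% diag(sv$d[seq_len(keep)], keep)
  colnames(scores) <- paste0("PC", seq_len(keep))
  structure(
    list(
      scores = dplyr::bind_cols(
        tibble::tibble(sample_id = spectra$sample_ids, set = set_labels),
        tibble::as_tibble(as.data.frame(scores))
      ),
      variance_pct = 100 * ev / sum(ev),
      total_variance = sum(ev)
    ),
    class = "pca_summary"
  )
}

#' @export
print.pca_summary <- function(x, ...) {
  cat("<pca_summary>\n")
  v <- x$variance_pct[seq_len(min(3, length(x$variance_pct)))]
  cat("  variance:", paste0(sprintf("PC%d %.2f%%", seq_along(v), v), collapse = ", "), "\n")
  invisible(x)
}

#' Plot a PCA score plot
#' @param object A [pca_summary()].
#' @param ... Unused.
#' @return A ggplot object (PC1 vs PC2 score plot, colored by set).
#' @export
autoplot.pca_summary <- function(object, ...) {
  df <- object$scores
  if (!"PC2" %in% names(df)) df$PC2 <- 0
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2, colour = .data$set)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.2f%%)", object$variance_pct[1]),
      y = sprintf("PC2 (%.2f%%)", ifelse(length(object$variance_pct) > 1,
                                         object$variance_pct[2], 0)),
      title = "PCA score plot"
    )
}
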