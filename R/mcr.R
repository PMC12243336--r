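# Multivariate curve resolution by alternating least squares: D ~ C S' with
# non-negativity on both profiles. Each conditional update solves true
# non-negative least squares per column (Lawson-Hanson active set via
# pracma::lsqnonneg), never zero-clipping, so the lack of fit is monotone
# non-increasing over iterations.

#' Maximum-dissimilarity initial spectral profiles
#'
#' Picks `k` rows of the data matrix as starting spectral estimates: the
#' first is the row of largest Euclidean norm; each subsequent pick
#' maximizes the residual norm after projection onto the span of the rows
#' already chosen. Deterministic.
#'
#' @param d A [spectral_matrix()] or numeric matrix (samples x wavelengths).
#' @param k Number of components, `1 <= k <= min(n, p)`.
#' @return A `p x k` matrix of initial spectral profiles (columns).
#' @export
init_profiles <- function(d, k) {
  D <- x_matrix(d)
  if (k < 1 || k > min(dim(D))) stop("`k` must be between 1 and min(n, p)")
  chosen <- integer(0)
  # orthonormal basis of the span of chosen rows
  basis <- matrix(0, ncol(D), 0)
  for (j in seq_len(k)) {
    resid <- D - D %*% basis %*% t(basis)
    norms <- sqrt(rowSums(resid^2))
    norms[chosen] <- -Inf
    pick <- which.max(norms)
    chosen <- c(chosen, pick)
    v <- D[pick, ] - basis %*% crossprod(basis, D[pick, ])
    nv <- sqrt(sum(v^2))
    if (nv > 1e-12) basis <- cbind(basis, v / nv)
  }
  t(D[chosen, , drop = FALSE])
}

# internal: NNLS solve of A x = b for each column b of B; returns coefficient
# matrix with one column per column of B
nnls_columns <- function(A, B) {
  apply(B, 2, function(b) pracma::lsqnonneg(A, b)$x)
}

#' Multivariate curve resolution by alternating least squares
#'
#' Factorizes the absorbance block as `D ~ C S'` with `C >= 0` (sample-wise
#' contribution profiles) and `S >= 0` (spectral profiles), alternating
#' exact non-negative least-squares updates of C given S and S given C.
#' Iteration stops when the relative change in the percent lack of fit
#' between sweeps drops below `tol` (default 1% -- the conventional
#' residual-change criterion) or at `max_iter`.
#'
#' Reported diagnostics: `lof_pct = 100 sqrt(sum(e^2) / sum(d^2))`,
#' `r2_pct = 100 (1 - (lof_pct/100)^2)` (variance explained), and
#' `residual_sd = sqrt(sum(e^2) / (n p))`.
#'
#' @param d A [spectral_matrix()] (stage raw) or non-negative numeric matrix.
#' @param k Number of components (default 2).
#' @param tol Relative lack-of-fit change threshold. Default 0.01 (1%).
#' @param max_iter Maximum ALS sweeps. Default 500.
#' @param s_init Optional initial `p x k` spectral profiles; defaults to
#'   [init_profiles()].
#' @return An object of class `mcr_result`: `C` (n x k), `S` (p x k),
#'   `lof_pct`, `r2_pct`, `residual_sd`, `lof_trace` (per-iteration lack of
#'   fit), `n_iter`, `converged`, plus the grid and sample ids when `d` is a
#'   [spectral_matrix()].
#' @examples
#' C <- cbind(runif(8, 5, 25), runif(8, 5, 25))
#' S <- cbind(exp(-(1:20 - 8)^2 / 10), exp(-(1:20 - 12)^2 / 10))
#' fit <- mcr_als(C %*% t(S), k = 2, tol = 1e-6)
#' @export
mcr_als <- function(d, k = 2, tol = 0.01, max_iter = 500, s_init = NULL) {
  D <- x_matrix(d)
  if (k < 1) stop("`k` must be >= 1")
  if (tol <= 0) stop("`tol` must be > 0")
  if (!all(is.finite(D))) stop("data matrix contains non-finite entries")
  ss_tot <- sum(D^2)
  if (ss_tot == 0) stop("all-zero data matrix")
  S <- if (is.null(s_init)) init_profiles(D, k) else as.matrix(s_init)
  if (!all(dim(S) == c(ncol(D), k))) stop("`s_init` must be p x k")
  lof <- function(C, S) 100 * sqrt(sum((D - tcrossprod(C, S))^2) / ss_tot)
  lof_trace <- numeric(0)
  prev <- Inf
  converged <- FALSE
  C <- NULL
  for (it in seq_len(max_iter)) {
    C <- t(nnls_columns(S, t(D)))   # rows of D on the spectral profiles
    if (k == 1) C <- matrix(C, ncol = 1)
    S <- t(nnls_columns(C, D))      # columns of D on the contributions
    if (k == 1) S <- matrix(S, ncol = 1)
    cur <- lof(C, S)
    lof_trace <- c(lof_trace, cur)
    if (is.finite(prev) && prev > 0 && abs(prev - cur) / prev < tol) {
      converged <- TRUE
      break
    }
    if (cur == 0) { converged <- TRUE; break }
    prev <- cur
  }
  e2 <- sum((D - tcrossprod(C, S))^2)
  lof_pct <- 100 * sqrt(e2 / ss_tot)
  structure(
    list(C = C, S = S,
         lof_pct = lof_pct,
         r2_pct = lof_to_r2(lof_pct),
         residual_sd = sqrt(e2 / length(D)),
         lof_trace = lof_trace,
         n_iter = length(lof_trace),
         converged = converged,
         grid = if (inherits(d, "spectral_matrix")) d$grid else NULL,
         sample_ids = if (inherits(d, "spectral_matrix")) d$sample_ids else
           paste0("s", seq_len(nrow(D)))),
    class = "mcr_result"
  )
}

#' Variance explained implied by a lack of fit
#'
#' The identity `r2_pct = 100 (1 - (lof_pct / 100)^2)` linking percent lack
#' of fit to percent variance explained; e.g. a 5.91% fitting error explains
#' 99.65% of the variance.
#'
#' @param lof_pct Percent lack of fit.
#' @return Percent variance explained.
#' @export
lof_to_r2 <- function(lof_pct) 100 * (1 - (lof_pct / 100)^2)

#' @export
print.mcr_result <- function(x, ...) {
  cat(sprintf("<mcr_result> k = %d, lof %.4g%%, r2 %.4f%%, residual SD %.4g, %d iterations%s\n",
              ncol(x$S), x$lof_pct, x$r2_pct, x$residual_sd, x$n_iter,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Quantify analytes from resolved MCR profiles
#'
#' Resolves the rotation/scale ambiguity of [mcr_als()] at quantification
#' time: each resolved component is assigned to an analyte by best spectral
#' correlation against pure-component spectral estimates regressed from the
#' calibration rows (reported in the `assignment` attribute), and each
#' analyte is calibrated by ordinary least squares of its known calibration
#' concentrations on the resolved contribution columns, applied to every
#' sample. Because bilinear factorizations of strictly positive mixtures
#' are only defined up to an invertible linear transform, the calibration
#' regression uses all resolved columns jointly: any residual rotation of
#' the profiles is then absorbed exactly, not only their scale.
#'
#' @param result An [mcr_als()] result fitted on calibration + unknown rows.
#' @param calibration Concentration tibble for the calibration rows (one
#'   column per analyte).
#' @param cal_idx Row indices of `result` (and of the fitted data block)
#'   corresponding to `calibration`, in the same order.
#' @return A concentration tibble with predictions for every sample in the
#'   fitted block.
#' @export
quantify_from_mcr <- function(result, calibration, cal_idx) {
  stopifnot(inherits(result, "mcr_result"))
  calibration <- conc_table(calibration)
  Ycal <- conc_matrix(calibration)
  if (length(cal_idx) != nrow(Ycal)) stop("`cal_idx` must index one row per calibration sample")
  k <- ncol(result$S)
  if (ncol(Ycal) != k) stop("number of analytes must equal the number of resolved components")
  # pure-component spectral estimates from the calibration block:
  # D_cal ~ Ycal %*% t(S_pure)  =>  S_pure' = lstsq(Ycal, D_cal)
  D_cal_hat <- tcrossprod(result$C[cal_idx, , drop = FALSE], result$S)
  S_pure <- t(qr.solve(Ycal, D_cal_hat))
  cors <- stats::cor(result$S, S_pure) # resolved x analyte
  assign <- apply(cors, 2, which.max)
  if (anyDuplicated(assign)) {
    stop("ambiguous component assignment; spectral correlations:\n",
         paste(utils::capture.output(print(round(cors, 4))), collapse = "\n"))
  }
  X_cal <- cbind(1, result$C[cal_idx, , drop = FALSE])
  preds <- matrix(0, nrow(result$C), k)
  for (j in seq_len(k)) {
    beta <- stats::lm.fit(X_cal, Ycal[, j])$coefficients
    beta[is.na(beta)] <- 0
    preds[, j] <- drop(cbind(1, result$C) %*% beta)
  }
  out <- conc_from_matrix(preds, result$sample_ids, colnames(Ycal))
  attr(out, "assignment") <- stats::setNames(assign, colnames(Ycal))
  attr(out, "assignment_cor") <- cors
  out
}

#' Plot resolved spectral profiles
#' @param object An [mcr_als()] result.
#' @param ... Unused.
#' @return A ggplot object (one trace per resolved component).
#' @export
autoplot.mcr_result <- function(object, ...) {
  wl <- if (!is.null(object$grid)) object$grid$labels else seq_len(nrow(object$S))
  df <- tibble::tibble(
    wavelength_nm = rep(wl, times = ncol(object$S)),
    component = rep(paste0("component ", seq_len(ncol(object$S))), each = nrow(object$S)),
    profile = as.vector(object$S)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$wavelength_nm, y = .data$profile,
                                   colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = "resolved profile (arbitrary scale)")
}

#' @rdname tidy.mcr_result
#' @export
glance.mcr_result <- function(x, ...) {
  tibble::tibble(k = ncol(x$S), lof_pct = x$lof_pct, r2_pct = x$r2_pct,
                 residual_sd = x$residual_sd, n_iter = x$n_iter,
                 converged = x$converged)
}

#' Tidy resolved MCR profiles
#' @param x An [mcr_als()] result.
#' @param ... Unused.
#' @return `tidy()`: long tibble of resolved spectral profiles; `glance()`:
#'   one-row fit summary.
#' @export
tidy.mcr_result <- function(x, ...) {
  wl <- if (!is.null(x$grid)) x$grid$labels else seq_len(nrow(x$S))
  tibble::tibble(
    wavelength_nm = rep(wl, times = ncol(x$S)),
    component = rep(seq_len(ncol(x$S)), each = nrow(x$S)),
    profile = as.vector(x$S)
  )
}
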