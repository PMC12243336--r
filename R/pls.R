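# NIPALS two-block PLS (PLS2). Written against the classical chemometrics
# formulation: successive weight/score/loading extraction with deflation of
# both blocks; regression coefficients B_k = W_k (P_k' W_k)^-1 Q_k'.

# internal: absorbance block from a spectral_matrix or plain matrix
x_matrix <- function(x) {
  if (inherits(x, "spectral_matrix")) x$absorbance else as.matrix(x)
}

# internal: Y block from a concentration table or matrix
y_matrix <- function(y) {
  if (is.data.frame(y)) conc_matrix(conc_table(y)) else as.matrix(y)
}

# internal: NIPALS on centered blocks; returns weights/scores/loadings and
# cumulative coefficient matrices for every LV count 1..n_lv. With
# strict = FALSE, extraction stops early once X is deflated to numerical
# zero and the remaining coefficient matrices repeat the last valid one
# (extra LVs carry no information); with strict = TRUE that is an error.
nipals_core <- function(Xc, Yc, n_lv, tol = 1e-12, max_iter = 500, strict = TRUE) {
  n <- nrow(Xc); p <- ncol(Xc); q <- ncol(Yc)
  W <- matrix(0, p, n_lv); P <- matrix(0, p, n_lv)
  Q <- matrix(0, q, n_lv); Tm <- matrix(0, n, n_lv)
  Xd <- Xc; Yd <- Yc
  x_ss0 <- sum(Xc^2)
  a_reached <- 0
  for (a in seq_len(n_lv)) {
    u <- Yd[, which.max(colSums(Yd^2))]
    iter <- 0
    deficient <- FALSE
    repeat {
      iter <- iter + 1
      w <- crossprod(Xd, u)[, 1]
      nw <- sqrt(sum(w^2))
      if (nw < 1e-14 * max(1, sqrt(x_ss0))) {
        if (strict) stop("rank deficiency: X carries no variance for latent variable ", a)
        deficient <- TRUE
        break
      }
      w <- w / nw
      tt <- (Xd %*% w)[, 1]
      tt2 <- sum(tt^2)
      if (tt2 < 1e-24 * max(1, x_ss0)) {
        if (strict) stop("rank deficiency: fewer than ", n_lv,
                         " latent variables supported by X")
        deficient <- TRUE
        break
      }
      qv <- crossprod(Yd, tt)[, 1] / tt2
      if (q == 1 || iter >= max_iter) break
      u_new <- (Yd %*% qv)[, 1] / sum(qv^2)
      if (sqrt(sum((u_new - u)^2)) < tol * max(sqrt(sum(u_new^2)), 1e-300)) {
        u <- u_new
        break
      }
      u <- u_new
    }
    if (deficient) break
    p_a <- crossprod(Xd, tt)[, 1] / tt2
    Xd <- Xd - tcrossprod(tt, p_a)
    Yd <- Yd - tcrossprod(tt, qv)
    W[, a] <- w; P[, a] <- p_a; Q[, a] <- qv; Tm[, a] <- tt
    a_reached <- a
  }
  # cumulative regression coefficients per LV count (constant past a_reached)
  coefs <- vector("list", n_lv)
  for (k in seq_len(n_lv)) {
    kk <- min(k, a_reached)
    Wk <- W[, seq_len(kk), drop = FALSE]
    Pk <- P[, seq_len(kk), drop = FALSE]
    Qk <- Q[, seq_len(kk), drop = FALSE]
    coefs[[k]] <- Wk %*% solve(crossprod(Pk, Wk), t(Qk))
  }
  list(weights = W, x_loadings = P, y_loadings = Q, x_scores = Tm,
       coefs = coefs, n_lv_reached = a_reached)
}

# internal: resolve a wavelength mask to a logical vector over columns
resolve_mask <- function(mask, p) {
  if (is.null(mask)) return(rep(TRUE, p))
  if (is.logical(mask)) {
    if (length(mask) != p) stop("logical mask length must equal the number of wavelengths")
    return(mask)
  }
  if (is.numeric(mask)) { # column indices
    out <- rep(FALSE, p)
    out[mask] <- TRUE
    return(out)
  }
  stop("mask must be NULL, a logical vector, or column indices")
}

#' Fit a NIPALS partial least squares model
#'
#' Two-block PLS regression of component concentrations on absorbance
#' spectra. Both blocks are mean-centered internally; by default both
#' responses are modeled jointly (PLS2). An optional wavelength mask
#' restricts the predictors, as produced by the genetic-algorithm selectors.
#'
#' @param x Calibration spectra: a [spectral_matrix()] or numeric matrix
#'   (samples x wavelengths).
#' @param y Calibration concentrations: a concentration tibble (see
#'   [conc_table()]) or numeric matrix (samples x components, ug/mL).
#' @param n_lv Number of latent variables; must satisfy
#'   `n_lv <= min(n_samples - 1, n_selected_wavelengths)`.
#' @param mask Optional wavelength inclusion mask: logical vector over the
#'   full grid, or column indices. `NULL` keeps the full spectrum.
#'
#' @return An object of class `pls_model` with per-LV weights (`weights`),
#'   X/Y loadings, calibration scores, the `p x q` coefficient matrix
#'   (`coefficients`), centering vectors `x_mean`/`y_mean`, the mask and the
#'   grid. Successive score vectors are mutually orthogonal.
#'
#' @examples
#' g <- wavelength_grid(200, 210, 1)
#' S <- rbind(exp(-(g$labels - 203)^2 / 8), exp(-(g$labels - 207)^2 / 8))
#' C <- cbind(a = runif(8, 5, 25), b = runif(8, 5, 25))
#' sp <- spectral_matrix(C %*% S / 50, g)
#' m <- fit_pls(sp, C, n_lv = 2)
#' @export
fit_pls <- function(x, y, n_lv, mask = NULL) {
  X <- x_matrix(x)
  Y <- y_matrix(y)
  if (nrow(X) != nrow(Y)) stop("x and y must have the same number of samples")
  if (inherits(x, "spectral_matrix") && is.data.frame(y)) conc_table(y, x)
  mask <- resolve_mask(mask, ncol(X))
  k_sel <- sum(mask)
  if (k_sel < 1) stop("mask selects no wavelengths")
  if (n_lv < 1) stop("`n_lv` must be >= 1")
  if (n_lv > min(nrow(X) - 1, k_sel)) {
    stop("`n_lv` must be <= min(n_samples - 1, n_selected_wavelengths) = ",
         min(nrow(X) - 1, k_sel))
  }
  if (any(apply(Y, 2, stats::sd) == 0)) stop("zero-variance Y column")
  Xm <- X[, mask, drop = FALSE]
  x_mean <- colMeans(Xm)
  y_mean <- colMeans(Y)
  fit <- nipals_core(sweep(Xm, 2, x_mean), sweep(Y, 2, y_mean), n_lv)
  comp <- colnames(Y)
  if (is.null(comp)) comp <- paste0("y", seq_len(ncol(Y)))
  structure(
    list(
      n_lv = n_lv,
      weights = fit$weights, x_loadings = fit$x_loadings,
      y_loadings = fit$y_loadings, x_scores = fit$x_scores,
      coefficients = fit$coefs[[n_lv]],
      coef_per_lv = fit$coefs,
      x_mean = x_mean, y_mean = y_mean,
      mask = mask,
      grid = if (inherits(x, "spectral_matrix")) x$grid else NULL,
      component_names = comp,
      n = nrow(X)
    ),
    class = "pls_model"
  )
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d LVs, %d/%d wavelengths, responses: %s\n",
              x$n_lv, sum(x$mask), length(x$mask),
              paste(x$component_names, collapse = ", ")))
  invisible(x)
}

#' Predict concentrations from a PLS model
#'
#' @param object A [fit_pls()] model.
#' @param newdata A [spectral_matrix()] or numeric matrix on the same grid.
#' @param n_lv Optional LV count `<= object$n_lv` (nested model prediction).
#' @param ... Unused.
#' @return A concentration tibble (`sample_id` + one column per component).
#' @export
predict.pls_model <- function(object, newdata, n_lv = object$n_lv, ...) {
  X <- x_matrix(newdata)
  if (inherits(newdata, "spectral_matrix") && !is.null(object$grid) &&
      !isTRUE(all.equal(newdata$grid$labels, object$grid$labels))) {
    stop("grid mismatch between model and new data")
  }
  if (ncol(X) != length(object$mask)) {
    stop("new data has ", ncol(X), " wavelengths; model expects ", length(object$mask))
  }
  if (n_lv > object$n_lv) stop("`n_lv` exceeds the fitted latent-variable count")
  B <- object$coef_per_lv[[n_lv]]
  Yh <- sweep(X[, object$mask, drop = FALSE], 2, object$x_mean) %*% B
  Yh <- sweep(Yh, 2, object$y_mean, `+`)
  ids <- if (inherits(newdata, "spectral_matrix")) newdata$sample_ids else
    paste0("s", seq_len(nrow(X)))
  conc_from_matrix(Yh, ids, object$component_names)
}

#' Leave-one-out cross-validation of PLS
#'
#' Refits the model with each calibration sample held out and pools squared
#' prediction errors over samples and responses:
#' `RMSECV_k = sqrt(sum(err^2) / (n * q))` for each candidate LV count
#' `k = 1..max_lv`. The selected LV count attains the minimum RMSECV, ties
#' broken toward fewer latent variables.
#'
#' @inheritParams fit_pls
#' @param max_lv Largest LV count to consider (`<= n - 2`).
#' @return An object of class `cv_curve`: tibble with columns `n_lv` and
#'   `rmsecv`; attribute `selected_lv`.
#' @export
loocv <- function(x, y, max_lv, mask = NULL) {
  X <- x_matrix(x)
  Y <- y_matrix(y)
  n <- nrow(X); q <- ncol(Y)
  mask <- resolve_mask(mask, ncol(X))
  if (max_lv > n - 2) stop("`max_lv` must be <= n - 2 = ", n - 2)
  if (max_lv < 1) stop("`max_lv` must be >= 1")
  if (max_lv > sum(mask)) stop("`max_lv` exceeds the number of selected wavelengths")
  Xm <- X[, mask, drop = FALSE]
  sse <- numeric(max_lv)
  for (i in seq_len(n)) {
    x_mean <- colMeans(Xm[-i, , drop = FALSE])
    y_mean <- colMeans(Y[-i, , drop = FALSE])
    fit <- nipals_core(sweep(Xm[-i, , drop = FALSE], 2, x_mean),
                       sweep(Y[-i, , drop = FALSE], 2, y_mean), max_lv,
                       strict = FALSE)
    xi <- Xm[i, ] - x_mean
    for (k in seq_len(max_lv)) {
      pred <- drop(xi %*% fit$coefs[[k]]) + y_mean
      sse[k] <- sse[k] + sum((pred - Y[i, ])^2)
    }
  }
  rmsecv <- sqrt(sse / (n * q))
  out <- tibble::tibble(n_lv = seq_len(max_lv), rmsecv = rmsecv)
  structure(out,
            class = c("cv_curve", class(out)),
            selected_lv = which.min(rmsecv)) # which.min takes the first (fewest-LV) tie
}

#' Selected latent-variable count of a CV curve
#' @param cv A [loocv()] result.
#' @return Integer LV count minimizing RMSECV (fewest-LV tie break).
#' @export
selected_lv <- function(cv) attr(cv, "selected_lv")

#' Plot an RMSECV curve
#' @param object A [loocv()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n_lv, y = .data$rmsecv)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = selected_lv(object), linetype = 2) +
    ggplot2::labs(x = "latent variables", y = "RMSECV (ug/mL)")
}

#' @rdname tidy.pls_model
#' @export
glance.pls_model <- function(x, ...) {
  tibble::tibble(n_lv = x$n_lv, n = x$n,
                 n_wavelengths = sum(x$mask),
                 p_total = length(x$mask))
}

#' Tidy PLS coefficients
#'
#' @param x A [fit_pls()] model.
#' @param ... Unused.
#' @return `tidy()`: a tibble with one row per (wavelength, component)
#'   coefficient; `glance()`: a one-row model summary.
#' @export
tidy.pls_model <- function(x, ...) {
  wl <- if (!is.null(x$grid)) x$grid$labels[x$mask] else which(x$mask)
  tibble::tibble(
    wavelength_nm = rep(wl, times = length(x$component_names)),
    component = rep(x$component_names, each = sum(x$mask)),
    coefficient = as.vector(x$coefficients)
  )
}
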