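test_that("noiseless rank-2 bilinear data are fit exactly with 2 LVs", {
  fx <- bilinear_fixture(n = 12)
  fit <- fit_pls(fx$spectra, fx$conc, n_lv = 2)
  pred <- predict(fit, fx$spectra)
  err <- as.matrix(pred[-1]) - as.matrix(fx$conc[-1])
  expect_lt(rmse(as.vector(err), 0 * as.vector(err)), 1e-8)
  # score orthogonality
  G <- crossprod(fit$x_scores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
})

test_that("full-rank PLS with max LVs equals ordinary least squares", {
  set.seed(11)
  n <- 20; p <- 6
  X <- matrix(rnorm(n * p), n, p)
  Y <- cbind(X %*% rnorm(p) + rnorm(n, 0, 0.1),
             X %*% rnorm(p) + rnorm(n, 0, 0.1))
  fit <- fit_pls(X, Y, n_lv = p)
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  B_ols <- solve(crossprod(Xc), crossprod(Xc, Yc)) # normal-equations oracle
  pred_pls <- as.matrix(predict(fit, X)[-1])
  pred_ols <- Xc %*% B_ols + rep(1, n) %*% t(colMeans(Y))
  expect_lt(max(abs(pred_pls - pred_ols)), 1e-6)
})

test_that("predictions are exact on centering identities and linear in X", {
  fx <- bilinear_fixture(n = 10)
  fit <- fit_pls(fx$spectra, fx$conc, n_lv = 2)
  # mean spectrum predicts mean concentration
  at_mean <- predict(fit, rbind(colMeans(fx$spectra$absorbance)))
  expect_equal(unlist(at_mean[-1]), fit$y_mean, tolerance = 1e-10, ignore_attr = TRUE)
  # linearity at a = 0.3
  X1 <- fx$spectra$absorbance[1, , drop = FALSE]
  X2 <- fx$spectra$absorbance[2, , drop = FALSE]
  mix <- predict(fit, 0.3 * X1 + 0.7 * X2)
  y1 <- predict(fit, X1); y2 <- predict(fit, X2)
  expect_equal(as.matrix(mix[-1]), 0.3 * as.matrix(y1[-1]) + 0.7 * as.matrix(y2[-1]),
               tolerance = 1e-10)
})

test_that("duplicated columns leave predictions finite and matching", {
  set.seed(3)
  X <- matrix(rnorm(30), 10, 3)
  Xdup <- cbind(X, X[, 3])
  Y <- cbind(a = X %*% c(1, -1, 2) + rnorm(10, 0, 0.05))
  # at the full usable rank both models are the projection onto the same
  # column space, so the duplicate carries no extra information
  f1 <- fit_pls(X, Y, n_lv = 3)
  f2 <- fit_pls(Xdup, Y, n_lv = 3)
  p1 <- as.matrix(predict(f1, X)[-1])
  p2 <- as.matrix(predict(f2, Xdup)[-1])
  expect_true(all(is.finite(p2)))
  expect_equal(p1, p2, tolerance = 1e-8)
})

test_that("rank deficiency and invalid inputs raise errors", {
  fx <- bilinear_fixture(n = 8)
  expect_error(fit_pls(fx$spectra, fx$conc, n_lv = 3), "rank deficiency")
  expect_error(fit_pls(fx$spectra, fx$conc, n_lv = 9), "n_lv")
  const_y <- dplyr::mutate(fx$conc, component_b = 7)
  expect_error(fit_pls(fx$spectra, const_y, n_lv = 1), "zero-variance")
  fit <- fit_pls(fx$spectra, fx$conc, n_lv = 2)
  other <- bilinear_fixture(n = 3, grid = small_grid(2))
  expect_error(predict(fit, other$spectra), "grid mismatch|wavelengths")
})

test_that("calibration RMSEC is non-increasing in the number of LVs", {
  conc <- design_concentrations(multilevel_design())
  sp <- simulate_mixtures(conc, noise = noise_spec(seed = 4), grid = small_grid())
  rmsec <- vapply(1:6, function(k) {
    fit <- fit_pls(sp, conc, n_lv = k)
    pred <- predict(fit, sp)
    rmse(as.vector(as.matrix(pred[-1])), as.vector(as.matrix(conc[-1])))
  }, numeric(1))
  expect_true(all(diff(rmsec) <= 1e-10))
})

test_that("LOO-CV matches a naive refit loop and recovers planted rank", {
  fx <- bilinear_fixture(n = 9)
  noisy <- simulate_mixtures(fx$conc, noise = noise_spec(additive_sd = 0.005, seed = 2),
                             grid = fx$grid)
  cv <- loocv(noisy, fx$conc, max_lv = 4)
  # naive oracle: refit n times per LV count with stats-only code
  X <- noisy$absorbance; Y <- as.matrix(fx$conc[-1])
  n <- nrow(X)
  for (k in c(1, 3)) {
    sse <- 0
    for (i in seq_len(n)) {
      f <- fit_pls(X[-i, ], Y[-i, ], n_lv = k)
      pred <- as.matrix(predict(f, X[i, , drop = FALSE])[-1])
      sse <- sse + sum((pred - Y[i, ])^2)
    }
    expect_equal(cv$rmsecv[k], sqrt(sse / (n * ncol(Y))), tolerance = 1e-10)
  }
  # noiseless planted rank 2: minimum at 2 LVs, tiny RMSECV
  cv0 <- loocv(fx$spectra, fx$conc, max_lv = 4)
  expect_equal(selected_lv(cv0), 2)
  expect_lt(cv0$rmsecv[2], 1e-6)
})

test_that("loocv handles the minimal three-sample case and bad max_lv", {
  fx <- bilinear_fixture(n = 3)
  cv <- loocv(fx$spectra, fx$conc, max_lv = 1)
  expect_equal(nrow(cv), 1)
  expect_error(loocv(fx$spectra, fx$conc, max_lv = 2), "n - 2")
})

test_that("noise-free end-to-end PLS recovery is within 0.1%", {
  b <- make_study(5, noise = noise_free(), grid = small_grid())
  fit <- fit_pls(b$calibration$spectra, b$calibration$concentrations, n_lv = 2)
  rep <- evaluation_report(predict(fit, b$validation_lhs$spectra),
                           b$validation_lhs$concentrations)
  expect_true(all(rep$mean_r_pct > 99.9 & rep$mean_r_pct < 100.1))
})
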