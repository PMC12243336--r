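test_that("Savitzky-Golay reproduces polynomials up to the filter order", {
  g <- wavelength_grid(200, 230, 0.5)
  l <- g$labels
  cubic <- spectral_matrix(rbind((l - 210)^3 / 1e3 + 1), g)
  sm <- savgol(cubic, window = 11, poly = 3, deriv = 0)
  expect_lt(max(abs(sm$absorbance - cubic$absorbance)), 1e-9)
  expect_equal(sm$stage, "smoothed")

  line <- spectral_matrix(rbind(0.2 + 0.03 * l), g)
  d1 <- savgol(line, deriv = 1)
  expect_lt(max(abs(d1$absorbance - 0.03)), 1e-9) # exact slope, incl. edges
  expect_equal(d1$stage, "derivative1")
})

test_that("the filter equals a brute-force local cubic fit at every point", {
  g <- wavelength_grid(200, 219, 0.5)
  x <- withr::with_seed(5, cumsum(rnorm(grid_points(g), 0, 0.05)) + 0.5)
  sp <- spectral_matrix(rbind(abs(x)), g)
  # oracle: least-squares cubic over the 11-point window centered at each
  # interior point (edges: nearest full window), derivative via polynomial
  oracle <- function(v, n, p, m, ts) {
    N <- length(v); h <- (n - 1) / 2
    vapply(seq_len(N), function(i) {
      c0 <- min(max(i, h + 1), N - h)
      idx <- (c0 - h):(c0 + h)
      tt <- (idx - i) * ts
      beta <- qr.solve(outer(tt, 0:p, `^`), v[idx])
      beta[m + 1] * factorial(m)
    }, numeric(1))
  }
  for (m in 0:2) {
    got <- savgol(sp, window = 11, poly = 3, deriv = m)$absorbance[1, ]
    want <- oracle(sp$absorbance[1, ], 11, 3, m, g$step_nm)
    expect_lt(max(abs(got - want)), 1e-10)
  }
})

test_that("savgol rejects invalid window configurations", {
  fx <- bilinear_fixture(n = 2, grid = small_grid(5))
  expect_error(savgol(fx$spectra, window = 10), "odd")
  expect_error(savgol(fx$spectra, window = 31), "exceeds")
  expect_error(savgol(fx$spectra, window = 5, poly = 5), "poly")
  expect_error(savgol(fx$spectra, deriv = 3), "deriv")
})

test_that("SNV gives zero mean, unit SD rows and is affine invariant", {
  fx <- bilinear_fixture(n = 6)
  z <- snv(fx$spectra)
  expect_lt(max(abs(rowMeans(z$absorbance))), 1e-10)
  expect_equal(apply(z$absorbance, 1, sd), rep(1, 6), ignore_attr = TRUE)

  shifted <- fx$spectra
  shifted$absorbance <- 3.7 * fx$spectra$absorbance + 0.25
  expect_equal(snv(shifted)$absorbance, z$absorbance, tolerance = 1e-10)

  three <- spectral_matrix(rbind(c(1, 2, 3)), wavelength_grid(200, 202, 1))
  expect_equal(snv(three)$absorbance[1, ], c(-1, 0, 1), ignore_attr = TRUE)

  flat <- spectral_matrix(rbind(rep(1, 3)), wavelength_grid(200, 202, 1),
                          sample_ids = "flat")
  expect_error(snv(flat), "flat")
})

test_that("the pipeline composes steps in order and the empty pipeline is identity", {
  fx <- bilinear_fixture(n = 5)
  expect_equal(preprocess_pipeline(fx$spectra, character(0)), fx$spectra)
  manual <- snv(savgol(savgol(fx$spectra, deriv = 0), deriv = 1))
  piped <- preprocess_pipeline(fx$spectra, c("savgol", "derivative", "snv"))
  expect_equal(piped$absorbance, manual$absorbance)
  expect_equal(piped$stage, "snv")
  expect_error(preprocess_pipeline(fx$spectra, "wavelet"), "unknown step")
})

test_that("the default pipeline lowers PLS calibration error on noisy spectra", {
  conc <- design_concentrations(multilevel_design())
  noisy <- simulate_mixtures(conc,
                             noise = noise_spec(additive_sd = 0.01,
                                                baseline_slope_sd = 5e-4, seed = 9),
                             grid = small_grid())
  rmsec_of <- function(x) {
    fit <- fit_pls(x, conc, n_lv = 2)
    pred <- predict(fit, x)
    rmse(as.vector(as.matrix(pred[-1])), as.vector(as.matrix(conc[-1])))
  }
  expect_lt(rmsec_of(preprocess_pipeline(noisy)), rmsec_of(noisy))
})

test_that("PCA scores match the covariance eigen-decomposition and conserve energy", {
  fx <- bilinear_fixture(n = 8)
  ps <- pca_summary(fx$spectra)
  xc <- scale(fx$spectra$absorbance, scale = FALSE)
  ev <- eigen(stats::cov(xc), symmetric = TRUE)
  scores <- as.matrix(ps$scores[paste0("PC", 1:2)])
  want <- xc %*% ev$vectors[, 1:2]
  for (j in 1:2) { # sign-indeterminate
    expect_lt(min(max(abs(scores[, j] - want[, j])),
                  max(abs(scores[, j] + want[, j]))), 1e-8)
  }
  # energy conservation and ordering
  expect_equal(sum(scores^2) / sum(xc^2) * 100, sum(ps$variance_pct[1:2]),
               tolerance = 1e-8)
  expect_true(all(diff(ps$variance_pct) <= 1e-12))
  expect_equal(sum(ps$variance_pct), 100, tolerance = 1e-9)
})

test_that("rank-1 data put 100% of variance on PC1", {
  g <- small_grid(5)
  base <- exp(-(g$labels - 220)^2 / 100)
  sp <- spectral_matrix(outer(c(1, 2, 3.5), base), g)
  ps <- pca_summary(sp)
  expect_equal(ps$variance_pct[1], 100, tolerance = 1e-9)
  expect_error(pca_summary(spectral_matrix(rbind(base), g)), "2 samples")
})
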