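test_that("the 70/15/15 partition rule gives the canonical sizes", {
  expect_equal(lengths(partition_70_15_15(25, seed = 1)),
               c(train = 18L, val = 4L, test = 3L))
  expect_equal(lengths(partition_70_15_15(20, seed = 1)),
               c(train = 14L, val = 3L, test = 3L))
  p <- partition_70_15_15(25, seed = 7)
  expect_setequal(c(p$train, p$val, p$test), 1:25)
  expect_equal(anyDuplicated(c(p$train, p$val, p$test)), 0)
  expect_identical(partition_70_15_15(25, seed = 7), p) # reproducible
  expect_error(partition_70_15_15(2, 1), ">= 3")
})

test_that("the analytic Jacobian matches central finite differences", {
  set.seed(14)
  p <- 5; h <- 3; q <- 2; n <- 7
  m <- ann_init(p, h, q, seed = 2)
  w <- m[c("W1", "b1", "W2", "b2")]
  X <- matrix(runif(n * p, -1, 1), n, p)
  Y <- matrix(runif(n * q, -1, 1), n, q)
  jac <- spectracal:::ann_jacobian(w, X, Y)
  theta <- spectracal:::pack_theta(w$W1, w$b1, w$W2, w$b2)
  eps <- 1e-6
  J_fd <- vapply(seq_along(theta), function(i) {
    tp <- theta; tp[i] <- tp[i] + eps
    tm <- theta; tm[i] <- tm[i] - eps
    ep <- as.vector(spectracal:::ann_forward(
      spectracal:::unpack_theta(tp, p, h, q), X)$Yhat - Y)
    em <- as.vector(spectracal:::ann_forward(
      spectracal:::unpack_theta(tm, p, h, q), X)$Yhat - Y)
    (ep - em) / (2 * eps)
  }, numeric(n * q))
  denom <- pmax(abs(J_fd), 1)
  expect_lt(max(abs(jac$J - J_fd) / denom), 1e-6)
})

test_that("LM training converges on a noise-free 1-D quadratic and is monotone", {
  set.seed(3)
  x <- matrix(seq(-1, 1, length.out = 30))
  y <- matrix(x^2 * 1.5 - 0.3)
  m <- ann_init(1, 6, 1, seed = 5)
  m <- train_lm(m, x, y, epochs = 500, goal = 1e-6)
  expect_lt(min(m$record$mse), 1e-4)
  expect_true(all(diff(m$record$mse) < 0)) # accepted steps strictly decrease MSE
})

test_that("zero-epoch training returns the initial weights unchanged", {
  m0 <- ann_init(4, 3, 2, seed = 9)
  m1 <- train_lm(m0, matrix(runif(20, -1, 1), 5, 4), matrix(runif(10, -1, 1), 5, 2),
                 epochs = 0)
  expect_identical(m1$W1, m0$W1)
  expect_identical(m1$b2, m0$b2)
  expect_equal(nrow(m1$record), 1)
})

test_that("prediction follows the forward identity and feature-permutation symmetry", {
  fx <- bilinear_fixture(n = 8, grid = small_grid(5))
  m <- fit_ann(fx$spectra, fx$conc, epochs = 5, seed = 2, n_restarts = 1)
  # zero weights: constant output = unscale(b2)
  z <- m
  z$members <- NULL
  z$W1[] <- 0; z$b1[] <- 0; z$W2[] <- 0; z$b2 <- c(0.2, -0.4)
  pred <- predict(z, fx$spectra)
  want <- spectracal:::minmax_invert(rbind(c(0.2, -0.4)), m$y_scaling)
  for (i in 1:nrow(pred)) {
    expect_equal(unlist(pred[i, -1]), want[1, ], ignore_attr = TRUE, tolerance = 1e-12)
  }
  # permuting input features together with W1 columns leaves output unchanged
  perm <- sample(ncol(fx$spectra$absorbance))
  zp <- z
  zp$W1 <- m$W1[, perm]; zp$W2 <- m$W2; zp$b1 <- m$b1; zp$b2 <- m$b2
  zp$x_scaling <- list(min = m$x_scaling$min[perm], max = m$x_scaling$max[perm])
  base <- z; base$W1 <- m$W1; base$W2 <- m$W2; base$b1 <- m$b1; base$b2 <- m$b2
  p1 <- predict(base, fx$spectra$absorbance)
  p2 <- predict(zp, fx$spectra$absorbance[, perm])
  expect_equal(as.matrix(p1[-1]), as.matrix(p2[-1]), tolerance = 1e-12)
})

test_that("the trained committee reaches r >= 0.999 on noise-free mixtures", {
  b <- make_study(3, noise = noise_free(), grid = small_grid())
  m <- fit_ann(b$calibration$spectra, b$calibration$concentrations,
               epochs = 300, goal = 1e-12, seed = 4)
  test_idx <- m$partition$test
  pred <- predict(m, b$calibration$spectra)
  act <- b$calibration$concentrations
  for (cn in components(act)) {
    expect_gte(stats::cor(pred[[cn]][test_idx], act[[cn]][test_idx]), 0.999)
  }
  # end-to-end recovery band on the external validation set
  er <- evaluation_report(predict(m, b$validation_lhs$spectra),
                          b$validation_lhs$concentrations)
  expect_true(all(er$mean_r_pct > 99.9 & er$mean_r_pct < 100.1))
})

test_that("the hidden-neuron sweep reports one row per size", {
  fx <- bilinear_fixture(n = 12, grid = small_grid(6))
  sw <- hidden_sweep(fx$spectra, fx$conc, sizes = c(2, 4), epochs = 20,
                     seed = 1, n_restarts = 1)
  expect_equal(sw$n_hidden, c(2, 4))
  expect_true(all(is.finite(sw$train_mse)))
})
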