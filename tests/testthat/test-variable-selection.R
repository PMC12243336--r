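test_that("penalized fitness equals RMSECV plus the normalized-count penalty", {
  fx <- bilinear_fixture(n = 10, grid = small_grid(2))
  noisy <- simulate_mixtures(fx$conc, noise = noise_spec(additive_sd = 0.01, seed = 8),
                             grid = fx$grid)
  p <- grid_points(fx$grid)
  mask <- rep(c(TRUE, FALSE), length.out = p)
  base <- penalized_fitness(mask, noisy, fx$conc, n_lv = 2, lambda = 0)
  cv <- loocv(noisy, fx$conc, max_lv = 2, mask = mask)
  expect_equal(base, cv$rmsecv[2], tolerance = 1e-12)
  with_pen <- penalized_fitness(mask, noisy, fx$conc, n_lv = 2, lambda = 0.05)
  expect_equal(with_pen, base + 0.05 * sum(mask) / p, tolerance = 1e-12)
  expect_error(penalized_fitness(c(1), noisy, fx$conc, n_lv = 2), "fewer wavelengths")
})

test_that("the penalty arithmetic matches the hand example", {
  # RMSECV 0.30, k = 30, p = 301, lambda = 0.05 -> 0.304983...
  expect_equal(0.30 + 0.05 * 30 / 301, 0.3049834, tolerance = 1e-7)
  # monotone penalty: same RMSECV, half the mask is strictly fitter
  expect_lt(0.30 + 0.05 * 150 / 301 * 0 + 0.05 * 15 / 301,
            0.30 + 0.05 * 30 / 301)
})

test_that("ICOMP matches its closed forms and is zero iff spherical", {
  # q = 1: complexity identically zero
  e1 <- matrix(rnorm(30), 30, 1)
  s1 <- icomp_score(e1)
  expect_equal(s1$complexity, 0, tolerance = 1e-12)
  expect_equal(s1$total, s1$minus2_loglik, tolerance = 1e-9)
  # planted diag(1, 4) covariance: C1 = ln 2.5 - 0.5 ln 4
  E <- cbind(rep(c(1, -1), 4),            # orthogonal sign patterns so that
             rep(c(2, -2), each = 4))     # E'E / n = diag(1, 4) exactly
  s2 <- icomp_score(E)
  expect_equal(s2$residual_cov, diag(c(1, 4)), tolerance = 1e-12)
  expect_equal(s2$complexity, log(2.5) - 0.5 * log(4), tolerance = 1e-9) # 0.22314
  # eigenvalue form cross-check on a random covariance
  set.seed(21)
  Er <- matrix(rnorm(200), 100, 2) %*% matrix(c(2, 1, 0, 0.5), 2, 2)
  sr <- icomp_score(Er)
  ev <- eigen(crossprod(Er) / 100, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sr$complexity, 1 * log(mean(ev)) - 0.5 * sum(log(ev)), tolerance = 1e-9)
  expect_equal(sr$total, sr$minus2_loglik + 2 * sr$complexity, tolerance = 1e-9)
  expect_gt(sr$complexity, 0)
  # spherical residuals: complexity 0
  sph <- icomp_score(rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)) * 0.3)
  expect_equal(sph$complexity, 0, tolerance = 1e-12)
})

test_that("ICOMP complexity is strictly positive on random non-spherical covariances", {
  for (s in 1:20) {
    E <- withr::with_seed(s, matrix(rnorm(60), 30, 2) %*%
                            matrix(stats::runif(4, -1, 1) + c(1, 0, 0, 1), 2, 2))
    sc <- icomp_score(E)
    ev <- eigen(sc$residual_cov, only.values = TRUE)$values
    if (abs(ev[1] - ev[2]) > 1e-8) expect_gt(sc$complexity, 0)
  }
})

test_that("the GA is elitist-monotone, deterministic, and fixed at degenerate settings", {
  fit_count <- function(mask) sum(mask) + 0.001 * sum(which(mask)) # deterministic toy
  cfg <- ga_config(population = 10, generations = 15, seed = 4)
  r1 <- run_ga(fit_count, 30, cfg)
  r2 <- run_ga(fit_count, 30, cfg)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$best_mask, r2$best_mask)
  expect_true(all(diff(r1$history$best) <= 1e-12))
  expect_true(any(r1$best_mask)) # repair rule: never all-zero

  # mutation 0 and identical population: nothing can change
  frozen <- run_ga(function(mask) 1, 20,
                   ga_config(population = 4, generations = 5, mutation_rate = 0, seed = 1))
  expect_equal(nrow(frozen$history), 5)
  expect_equal(unique(frozen$history$best), 1)

  # callback errors surface with the offending mask
  expect_error(run_ga(function(mask) stop("boom"), 10,
                      ga_config(population = 4, generations = 1, seed = 1)),
               "fitness callback failed on mask")
})

test_that("GA recovers planted informative wavelengths in >= 90% of seeded runs", {
  fx <- planted_fixture(n = 16, p = 60, k_info = 5, noise_sd = 0.03, seed = 2)
  hits <- vapply(1:20, function(s) {
    fitness <- function(mask) {
      if (sum(mask) < 2) return(Inf)
      penalized_fitness(mask, fx$X, fx$y, n_lv = 2, lambda = 0.05)
    }
    r <- run_ga(fitness, ncol(fx$X),
                ga_config(population = 20, generations = 30, seed = 100 + s))
    sum(fx$informative %in% which(r$best_mask))
  }, numeric(1))
  expect_gte(mean(hits >= 4), 0.9)
})

test_that("ga_pls multi-restart returns the best restart and shrinks with lambda", {
  fx <- planted_fixture(n = 14, p = 40, k_info = 4, noise_sd = 0.03, seed = 5)
  cfg <- ga_config(population = 12, generations = 12, n_lv = 2, seed = 9, n_restarts = 3)
  multi <- ga_pls(fx$X, fx$y, cfg)
  singles <- vapply(multi$restarts, `[[`, numeric(1), "best_fitness")
  expect_equal(multi$best_fitness, min(singles))
  expect_length(singles, 3)
  # single restart equals a direct run_ga with the penalized fitness
  cfg1 <- ga_config(population = 12, generations = 12, n_lv = 2, seed = 9)
  direct <- run_ga(function(mask) {
    if (sum(mask) < 2) return(Inf)
    penalized_fitness(mask, fx$X, fx$y, n_lv = 2, lambda = cfg1$penalty_lambda)
  }, ncol(fx$X), cfg1)
  one <- ga_pls(fx$X, fx$y, cfg1)
  expect_equal(one$best_fitness, direct$best_fitness)
  expect_identical(one$best_mask, direct$best_mask)
  # selected fraction shrinks as lambda grows
  k_at <- vapply(c(0, 0.05, 0.5), function(lam) {
    cfgl <- ga_config(population = 12, generations = 12, n_lv = 2, seed = 10,
                      penalty_lambda = lam)
    sum(ga_pls(fx$X, fx$y, cfgl)$best_mask)
  }, numeric(1))
  expect_true(all(diff(k_at) <= 0))
})

test_that("ga_icomp_pls beats or matches the full spectrum and reproduces by seed", {
  fx <- bilinear_fixture(n = 14, grid = small_grid(3))
  noisy <- simulate_mixtures(fx$conc, noise = noise_spec(additive_sd = 0.005, seed = 3),
                             grid = fx$grid)
  cfg <- ga_config(population = 12, generations = 10, n_lv = 2, seed = 6)
  res <- ga_icomp_pls(noisy, fx$conc, cfg)
  expect_true(any(res$mask))
  full <- icomp_score(spectracal:::loo_errors(noisy$absorbance, as.matrix(fx$conc[-1]), 2))
  expect_lte(res$icomp$total, full$total + 1e-9)
  res2 <- ga_icomp_pls(noisy, fx$conc, cfg)
  expect_identical(res$mask, res2$mask)
  expect_equal(res$icomp$total, res2$icomp$total)
  # parsimony without losing more than 10% LOO RMSE vs full spectrum
  rmse_of <- function(mask) {
    E <- spectracal:::loo_errors(noisy$absorbance[, mask, drop = FALSE],
                                 as.matrix(fx$conc[-1]), 2)
    sqrt(mean(E^2))
  }
  expect_lt(sum(res$mask), grid_points(fx$grid))
  expect_lt(rmse_of(res$mask), rmse_of(rep(TRUE, grid_points(fx$grid))) * 1.10)
})

test_that("window-based selection expands blocks onto the wavelength grid", {
  fit_k <- function(mask) sum(mask)
  r <- run_ga(fit_k, 10, ga_config(population = 6, generations = 5,
                                   window_size = 4, seed = 2))
  m <- r$best_mask
  expect_length(m, 10)
  # bits within a block are identical (last block truncates to 2)
  expect_equal(length(unique(m[1:4])), 1)
  expect_equal(length(unique(m[5:8])), 1)
  expect_equal(length(unique(m[9:10])), 1)
})
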