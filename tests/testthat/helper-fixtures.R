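# Shared fixtures: everything is generated in code at test time.

# small grid keeps model fits fast while exercising the same code paths
small_grid <- function(step = 1) wavelength_grid(200, 260, step)

# noiseless rank-2 bilinear data from the default component pair
bilinear_fixture <- function(n = 12, seed = 42, grid = small_grid()) {
  conc <- withr::with_seed(seed, tibble::tibble(
    sample_id = sprintf("m%02d", seq_len(n)),
    component_a = runif(n, 5, 25),
    component_b = runif(n, 5, 25)
  ))
  list(
    spectra = simulate_mixtures(conc, grid = grid),
    conc = conc,
    grid = grid
  )
}

# planted-signal data: only `k_info` of `p` variables carry concentration
# information, the rest are i.i.d. noise
planted_fixture <- function(n = 16, p = 100, k_info = 5, noise_sd = 0.02, seed = 1) {
  withr::with_seed(seed, {
    y <- cbind(a = runif(n, 5, 25), b = runif(n, 5, 25))
    informative <- sort(sample.int(p, k_info))
    L <- matrix(runif(k_info * 2, 0.5, 1.5), k_info, 2)
    X <- matrix(rnorm(n * p, 0, noise_sd), n, p)
    X[, informative] <- X[, informative] + y %*% t(L) / 30
    list(X = X, y = y, informative = informative)
  })
}
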