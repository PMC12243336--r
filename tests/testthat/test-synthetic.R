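test_that("pure spectra follow the Gaussian band model", {
  g <- wavelength_grid(200, 260, 0.2)
  single <- component_spec("x", tibble::tibble(center_nm = 230, sigma_nm = 5, height = 2),
                           molar_scale = 0.1)
  s <- pure_spectrum(single, g)
  expect_equal(s[match(230, g$labels)], 0.1 * 2, tolerance = 1e-12)
  expect_true(all(s >= 0))
  # symmetric about the band center
  i <- match(230, g$labels)
  expect_equal(s[(i - 20):(i - 1)], rev(s[(i + 1):(i + 20)]), tolerance = 1e-12)
  expect_error(component_spec("bad", tibble::tibble(center_nm = 1, sigma_nm = 0, height = 1)),
               "sigma")
})

test_that("the default components overlap strongly and stay in the linear range", {
  g <- wavelength_grid(200, 260, 0.2)
  specs <- default_components()
  sa <- pure_spectrum(specs[[1]], g); sb <- pure_spectrum(specs[[2]], g)
  cosine <- sum(sa * sb) / sqrt(sum(sa^2) * sum(sb^2))
  expect_gt(cosine, 0.7)
  # 15 ug/mL peaks at 0.5 AU by the molar-scale normalization
  expect_equal(max(15 * sa), 0.5, tolerance = 1e-9)
  expect_equal(max(15 * sb), 0.5, tolerance = 1e-9)
  # worst-case 25 + 25 ug/mL mixture stays within a plausible linear range
  expect_lt(max(25 * sa + 25 * sb), 1.7)
})

test_that("noise-free mixing is exactly linear (superposition)", {
  g <- small_grid(2)
  ca <- tibble::tibble(sample_id = "a", component_a = 7, component_b = 0)
  cb <- tibble::tibble(sample_id = "b", component_a = 0, component_b = 11)
  cab <- tibble::tibble(sample_id = "ab", component_a = 7, component_b = 11)
  s <- function(conc) simulate_mixtures(conc, grid = g)$absorbance
  expect_equal(s(cab), s(ca) + s(cb), tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(simulate_mixtures(dplyr::mutate(cab, component_a = -1), grid = g),
               "non-negative")
})

test_that("design concentrations with 2 LVs give machine-precision PLS fit", {
  conc <- design_concentrations(multilevel_design())
  sp <- simulate_mixtures(conc, grid = small_grid())
  fit <- fit_pls(sp, conc, n_lv = 2)
  pred <- predict(fit, sp)
  expect_lt(rmse(as.vector(as.matrix(pred[-1])), as.vector(as.matrix(conc[-1]))), 1e-8)
})

test_that("the additive noise generator has the nominal SD on blank spectra", {
  blanks <- tibble::tibble(sample_id = sprintf("b%03d", 1:200),
                           component_a = 0, component_b = 0)
  sp <- simulate_mixtures(blanks, noise = noise_spec(additive_sd = 0.002,
                                                     scatter_sd = 0, baseline_slope_sd = 0,
                                                     seed = 12),
                          grid = small_grid(), floor_at_zero = FALSE)
  expect_gt(sd(as.vector(sp$absorbance)), 0.0018)
  expect_lt(sd(as.vector(sp$absorbance)), 0.0022)
})

test_that("study bundles have the canonical sizes and reproduce bit-exactly", {
  b <- make_study(11, grid = small_grid(5))
  expect_equal(nrow(b$calibration$concentrations), 25)
  expect_equal(nrow(b$validation_lhs$concentrations), 13)
  expect_equal(nrow(b$validation_mc$concentrations), 13)
  all_conc <- rbind(as.matrix(b$calibration$concentrations[-1]),
                    as.matrix(b$validation_lhs$concentrations[-1]),
                    as.matrix(b$validation_mc$concentrations[-1]))
  expect_true(all(all_conc >= 5 & all_conc <= 25))
  occ <- coverage_report(b$plans$lhs, 13)$occupancy
  expect_true(all(occ$count == 1L))
  b2 <- make_study(11, grid = small_grid(5))
  expect_identical(b$calibration$spectra$absorbance, b2$calibration$spectra$absorbance)
  expect_identical(b$validation_mc$spectra$absorbance, b2$validation_mc$spectra$absorbance)
})

test_that("the plasma surrogate degrades recovery of a model trained without it", {
  g <- small_grid()
  b <- make_study(9, noise = noise_spec(additive_sd = 0.002, scatter_sd = 0,
                                        baseline_slope_sd = 0),
                  grid = g, plasma = TRUE)
  fit <- fit_pls(b$calibration$spectra, b$calibration$concentrations, n_lv = 3)
  dev_of <- function(set) {
    er <- evaluation_report(predict(fit, set$spectra), set$concentrations)
    mean(abs(er$mean_r_pct - 100))
  }
  expect_gt(dev_of(b$plasma), dev_of(b$validation_lhs))
})

test_that("write_study emits the CSV dialects and a manifest", {
  dir <- withr::local_tempdir()
  b <- make_study(2, grid = small_grid(10))
  write_study(b, dir)
  expect_true(file.exists(file.path(dir, "calibration_spectra.csv")))
  back <- read_spectra_csv(file.path(dir, "calibration_spectra.csv"))
  expect_equal(back$absorbance, b$calibration$spectra$absorbance,
               ignore_attr = TRUE)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_true(man$synthetic)
  expect_equal(man$seed, 2L)
})
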