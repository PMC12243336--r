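# Synthetic two-component UV mixture generator. Pure spectra are sums of
# Gaussian bands chosen to reproduce the strong-overlap regime of closely
# related UV chromophores in 200-260 nm; mixtures follow Beer-Lambert
# additivity with optional instrument-like noise. These are generator
# parameters, not claims about any real drug pair.

#' Define a pure-component spectral model
#'
#' A component is a sum of Gaussian absorption bands scaled to a
#' per-(ug/mL) molar scale: the unit-concentration spectrum is
#' `s(lambda) = molar_scale * sum_b height_b * exp(-(lambda - center_b)^2 / (2 sigma_b^2))`.
#'
#' @param name Component identifier.
#' @param bands Data frame with columns `center_nm`, `sigma_nm` (> 0) and
#'   `height` (>= 0), one row per band.
#' @param molar_scale Absorbance per ug/mL applied to the summed bands;
#'   `NULL` (default) normalizes so that 15 ug/mL gives a 0.5 AU peak on
#'   200-260 nm (typical bench-UV mid-range absorbance).
#' @return A list of class `component_spec`.
#' @export
component_spec <- function(name, bands, molar_scale = NULL) {
  bands <- tibble::as_tibble(bands)
  stopifnot(all(c("center_nm", "sigma_nm", "height") %in% names(bands)))
  if (nrow(bands) == 0) stop("component needs at least one band")
  if (any(bands$sigma_nm <= 0)) stop("band sigma must be > 0")
  if (any(bands$height < 0)) stop("band height must be >= 0")
  if (is.null(molar_scale)) {
    ref <- wavelength_grid(200, 260, 0.2)
    peak <- max(band_sum(bands, ref$labels))
    if (peak == 0) stop("all-zero component spectrum")
    molar_scale <- 0.5 / (15 * peak)
  }
  structure(list(name = name, bands = bands, molar_scale = molar_scale),
            class = "component_spec")
}

band_sum <- function(bands, lambda) {
  rowSums(vapply(seq_len(nrow(bands)), function(b) {
    bands$height[b] * exp(-(lambda - bands$center_nm[b])^2 / (2 * bands$sigma_nm[b]^2))
  }, numeric(length(lambda))))
}

#' Default overlapping component pair
#'
#' Two strongly overlapping UV absorbers on 200-260 nm (cosine similarity of
#' the normalized pure spectra > 0.9): component A with bands at 210 nm
#' (sigma 8, height 1.0) and 240 nm (sigma 12, height 0.35); component B at
#' 205 nm (sigma 6, height 1.2) and 225 nm (sigma 10, height 0.5).
#'
#' @return A named list of two [component_spec()]s.
#' @export
default_components <- function() {
  list(
    component_a = component_spec(
      "component_a",
      tibble::tibble(center_nm = c(210, 240), sigma_nm = c(8, 12), height = c(1.0, 0.35))
    ),
    component_b = component_spec(
      "component_b",
      tibble::tibble(center_nm = c(205, 225), sigma_nm = c(6, 10), height = c(1.2, 0.5))
    )
  )
}

#' Evaluate a unit-concentration pure spectrum
#'
#' @param spec A [component_spec()].
#' @param grid A [wavelength_grid()].
#' @return Numeric vector of absorbances (AU per ug/mL) over the grid;
#'   non-negative.
#' @export
pure_spectrum <- function(spec, grid) {
  stopifnot(inherits(spec, "component_spec"), inherits(grid, "wavelength_grid"))
  spec$molar_scale * band_sum(spec$bands, grid$labels)
}

#' Instrument noise model
#'
#' @param additive_sd Additive Gaussian noise SD (AU). Default 0.002.
#' @param scatter_sd SD of the per-sample multiplicative scatter factor
#'   (applied as `1 + N(0, scatter_sd)`). Default 0.01.
#' @param baseline_slope_sd SD of the per-sample linear baseline slope
#'   (AU/nm). Default 1e-4.
#' @param interferent Add a broad random matrix-interferent band around
#'   200-220 nm (a plasma-like surrogate: residual matrix absorption after
#'   protein precipitation) and double the additive noise. Default FALSE.
#' @param seed Integer seed.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(additive_sd = 0.002, scatter_sd = 0.01,
                       baseline_slope_sd = 1e-4, interferent = FALSE, seed = 1) {
  stopifnot(additive_sd >= 0, scatter_sd >= 0, baseline_slope_sd >= 0)
  structure(list(additive_sd = additive_sd, scatter_sd = scatter_sd,
                 baseline_slope_sd = baseline_slope_sd,
                 interferent = interferent, seed = seed),
            class = "noise_spec")
}

#' Noise-free noise specification
#' @return A `noise_spec` with every noise source off; under it
#'   [simulate_mixtures()] is exactly linear in the concentrations.
#' @export
noise_free <- function() noise_spec(0, 0, 0, interferent = FALSE)

#' Simulate mixture absorption spectra
#'
#' Beer-Lambert mixing: `A = C S' (1 + scatter) + baseline + noise`, where
#' `S` holds the unit-concentration pure spectra. With all noise sources at
#' zero the map is exactly linear in the concentrations (superposition
#' holds), so exact-recovery regimes can be constructed at will.
#'
#' @param concentrations Concentration tibble (`sample_id` + one column per
#'   component, ug/mL).
#' @param specs List of [component_spec()]s, one per component column (in
#'   order). Default [default_components()].
#' @param noise A [noise_spec()]. Default [noise_free()].
#' @param grid A [wavelength_grid()]. Default 200-260 nm at 0.2 nm.
#' @param floor_at_zero Clamp noise-driven negative absorbances at 0 so the
#'   result carries the raw stage tag (default TRUE). With
#'   `floor_at_zero = FALSE` the unclamped Gaussian noise is kept -- useful
#'   for characterizing the noise model itself -- and the result is tagged
#'   `"centered"` when negatives occur, since raw-stage spectra are
#'   non-negative by contract.
#' @return A [spectral_matrix()] (stage `"raw"` unless unclamped noise left
#'   negative entries).
#' @export
simulate_mixtures <- function(concentrations, specs = default_components(),
                              noise = noise_free(),
                              grid = wavelength_grid(200, 260, 0.2),
                              floor_at_zero = TRUE) {
  conc <- conc_table(concentrations)
  comp <- components(conc)
  if (length(comp) != length(specs)) stop("need one component_spec per component column")
  C <- conc_matrix(conc)
  S <- vapply(specs, pure_spectrum, numeric(grid_points(grid)), grid = grid)
  A <- C %*% t(S)
  n <- nrow(A); p <- ncol(A)
  if (noise$additive_sd > 0 || noise$scatter_sd > 0 ||
      noise$baseline_slope_sd > 0 || noise$interferent) {
    A <- withr::with_seed(noise$seed, {
      out <- A
      if (noise$scatter_sd > 0) {
        out <- out * (1 + stats::rnorm(n, 0, noise$scatter_sd))
      }
      if (noise$baseline_slope_sd > 0) {
        slopes <- stats::rnorm(n, 0, noise$baseline_slope_sd)
        out <- out + outer(slopes, grid$labels - grid$start_nm)
      }
      if (noise$interferent) {
        amp <- stats::runif(n, 0, 0.05)
        out <- out + outer(amp, exp(-(grid$labels - 210)^2 / (2 * 15^2)))
      }
      add_sd <- noise$additive_sd * (if (noise$interferent) 2 else 1)
      if (add_sd > 0) out <- out + matrix(stats::rnorm(n * p, 0, add_sd), n, p)
      out
    })
  }
  if (floor_at_zero) A <- pmax(A, 0)
  spectral_matrix(A, grid, sample_ids = conc$sample_id,
                  stage = if (all(A >= 0)) "raw" else "centered")
}

#' Generate a complete synthetic study bundle
#'
#' The full data layout of a two-component calibration study: a 25-mixture
#' five-level calibration design over 5-25 ug/mL, a 13-point Latin
#' hypercube validation set, a matched 13-point Monte Carlo validation set,
#' and (optionally) a plasma-surrogate set re-simulated with a broad
#' interferent band. All sets share the pure-component specs and grid;
#' sub-seeds are derived deterministically from `seed`, so the same seed
#' yields a byte-identical bundle.
#'
#' @param seed Integer seed.
#' @param specs Component specs (default [default_components()]).
#' @param noise A [noise_spec()]; its `seed` field is overridden by derived
#'   sub-seeds. Default [noise_spec()] (typical bench noise).
#' @param grid Wavelength grid. Default 200-260 nm at 0.2 nm.
#' @param n_strata LHS strata / validation size. Default 13.
#' @param level_values Calibration levels. Default `seq(5, 25, 5)`.
#' @param plasma Also generate the plasma-surrogate set. Default FALSE.
#' @return A list of class `study_bundle`: elements `calibration`,
#'   `validation_lhs`, `validation_mc` (and `plasma` if requested), each a
#'   list with `spectra` ([spectral_matrix()]) and `concentrations`
#'   (tibble); plus `grid`, `specs`, `noise`, `seed`.
#' @export
make_study <- function(seed = 1, specs = default_components(),
                       noise = noise_spec(), grid = wavelength_grid(200, 260, 0.2),
                       n_strata = 13, level_values = seq(5, 25, 5),
                       plasma = FALSE) {
  comp <- names(specs)
  design <- multilevel_design(n_levels = length(level_values),
                              level_values = level_values,
                              component_names = comp)
  cal_conc <- design_concentrations(design)
  bounds <- stats::setNames(replicate(length(comp), range(level_values),
                                      simplify = FALSE), comp)
  lhs_plan <- lhs_sample(n_strata, length(comp), bounds, seed = seed * 13 + 1)
  mc_plan <- mc_sample(n_strata, length(comp), bounds, seed = seed * 13 + 2)
  sub_noise <- function(k, interferent = noise$interferent) {
    ns <- noise
    ns$seed <- seed * 13 + k
    ns$interferent <- interferent
    ns
  }
  mk <- function(conc, k, interferent = FALSE) {
    list(spectra = simulate_mixtures(conc, specs, sub_noise(k, interferent), grid),
         concentrations = conc_table(conc))
  }
  lhs_conc <- tibble::as_tibble(lhs_plan)[c("sample_id", comp)]
  mc_conc <- tibble::as_tibble(mc_plan)[c("sample_id", comp)]
  out <- list(
    calibration = mk(cal_conc, 3),
    validation_lhs = mk(lhs_conc, 4),
    validation_mc = mk(mc_conc, 5),
    design = design,
    plans = list(lhs = lhs_plan, mc = mc_plan),
    grid = grid, specs = specs, noise = noise, seed = seed
  )
  if (plasma) {
    plasma_conc <- lhs_conc
    plasma_conc$sample_id <- sub("^val", "pls", plasma_conc$sample_id)
    out$plasma <- mk(plasma_conc, 6, interferent = TRUE)
  }
  structure(out, class = "study_bundle")
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf("<study_bundle> seed %d: %d calibration + %d LHS / %d MC validation mixtures%s\n",
              x$seed, nrow(x$calibration$concentrations),
              nrow(x$validation_lhs$concentrations),
              nrow(x$validation_mc$concentrations),
              if (!is.null(x$plasma)) sprintf(" + %d plasma-surrogate", nrow(x$plasma$concentrations)) else ""))
  invisible(x)
}

#' Write a study bundle to disk
#'
#' Writes each set's spectra and concentrations in the package CSV dialects
#' plus a JSON manifest (seed, component bands -- flagged as synthetic
#' stand-ins -- and noise settings).
#'
#' @param bundle A [make_study()] bundle.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(bundle, dir) {
  stopifnot(inherits(bundle, "study_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sets <- intersect(c("calibration", "validation_lhs", "validation_mc", "plasma"),
                    names(bundle))
  for (s in sets) {
    write_spectra_csv(bundle[[s]]$spectra, file.path(dir, paste0(s, "_spectra.csv")))
    write_concentrations_csv(bundle[[s]]$concentrations,
                             file.path(dir, paste0(s, "_concentrations.csv")))
  }
  manifest <- list(
    seed = bundle$seed,
    synthetic = TRUE,
    note = "pure-component bands are synthetic stand-ins, not measured spectra",
    grid = bundle$grid[c("start_nm", "end_nm", "step_nm")],
    noise = unclass(bundle$noise),
    components = lapply(bundle$specs, function(sp) {
      list(name = sp$name, molar_scale = sp$molar_scale,
           bands = as.data.frame(sp$bands))
    })
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
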