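# End-to-end orchestration: run every calibration model on a synthetic
# study bundle and tabulate the comparison, and the LHS-vs-Monte-Carlo
# sampling experiment.

#' @importFrom rlang .data :=
#' @importFrom stats predict
NULL

model_choices <- c("pls", "ga_pls", "ga_icomp_pls", "ann", "mcr_als")

#' Run a complete calibration study
#'
#' Generates a synthetic study bundle ([make_study()]), optionally
#' preprocesses the spectra, selects the PLS latent-variable count by
#' leave-one-out cross-validation, fits every requested model on the
#' calibration set, predicts the LHS validation set, and tabulates RMSEC,
#' RMSEP, %RE, %RSD and r per model and component. Deterministic given the
#' seed: every stochastic stage uses a sub-seed derived from it.
#'
#' MCR-ALS is always fitted on the raw (unpreprocessed) absorbance block of
#' calibration + validation jointly -- derivative/SNV stages break the
#' non-negativity its bilinear model requires -- and quantified through
#' calibration regression of the resolved contributions.
#'
#' @param models Subset of `"pls"`, `"ga_pls"`, `"ga_icomp_pls"`, `"ann"`,
#'   `"mcr_als"` (at least one).
#' @param seed Integer master seed.
#' @param noise A [noise_spec()].
#' @param grid A [wavelength_grid()].
#' @param preprocessing Optional character vector of [preprocess_pipeline()]
#'   steps applied to X before the PLS/GA/ANN models (never MCR).
#' @param max_lv Largest LV count offered to CV selection. Default 8.
#' @param ga Optional [ga_config()] shared by both GA flavors (seed and
#'   n_lv fields are overridden by derived values).
#' @param ann_epochs,ann_hidden ANN training budget and hidden size.
#' @param mcr_tol MCR convergence tolerance. Default 0.01.
#' @param bundle Optional pre-built [make_study()] bundle (overrides `seed`,
#'   `noise`, `grid` for data generation).
#' @return An object of class `study_result`: `table` (tibble: `model`,
#'   `component`, `rmsec`, `rmsep`, `mean_r_pct`, `re_pct`, `rsd_pct`, `r`),
#'   `models`
#'   (fitted objects), `n_lv`, `bundle`, `seed`.
#' @export
run_study <- function(models = model_choices, seed = 1, noise = noise_spec(),
                      grid = wavelength_grid(200, 260, 0.2),
                      preprocessing = NULL, max_lv = 8, ga = NULL,
                      ann_epochs = 500, ann_hidden = 6, mcr_tol = 0.01,
                      bundle = NULL) {
  models <- match.arg(models, model_choices, several.ok = TRUE)
  if (is.null(bundle)) bundle <- make_study(seed, noise = noise, grid = grid)
  cal <- bundle$calibration; val <- bundle$validation_lhs
  prep <- function(sp) {
    if (is.null(preprocessing)) sp else preprocess_pipeline(sp, preprocessing)
  }
  x_cal <- prep(cal$spectra); x_val <- prep(val$spectra)
  y_cal <- cal$concentrations; y_val <- val$concentrations
  n <- nrow(y_cal)
  cv <- loocv(x_cal, y_cal, max_lv = min(max_lv, n - 2))
  n_lv <- selected_lv(cv)
  if (is.null(ga)) ga <- ga_config()
  fitted <- list()
  rows <- list()
  eval_model <- function(name, pred_cal, pred_val) {
    cal_rep <- evaluation_report(pred_cal, y_cal, kind = "rmsec")
    val_rep <- evaluation_report(pred_val, y_val, kind = "rmsep")
    dplyr::bind_cols(
      tibble::tibble(model = name),
      dplyr::select(cal_rep, "component", "rmsec"),
      dplyr::select(val_rep, "rmsep", "mean_r_pct", "re_pct", "rsd_pct", "r")
    )
  }
  for (m in models) {
    if (m == "pls") {
      fit <- fit_pls(x_cal, y_cal, n_lv = n_lv)
      rows[[m]] <- eval_model(m, predict(fit, x_cal), predict(fit, x_val))
      fitted[[m]] <- fit
    } else if (m == "ga_pls") {
      cfg <- ga
      cfg$n_lv <- n_lv # LV count from full-spectrum CV, held fixed in the search
      cfg$seed <- seed * 13 + 7
      sel <- ga_pls(x_cal, y_cal, config = cfg)
      fit <- fit_pls(x_cal, y_cal, n_lv = min(n_lv, sum(sel$best_mask)),
                     mask = sel$best_mask)
      rows[[m]] <- eval_model(m, predict(fit, x_cal), predict(fit, x_val))
      fitted[[m]] <- list(selection = sel, model = fit)
    } else if (m == "ga_icomp_pls") {
      cfg <- ga; cfg$n_lv <- n_lv; cfg$seed <- seed * 13 + 8
      sel <- ga_icomp_pls(x_cal, y_cal, config = cfg)
      rows[[m]] <- eval_model(m, predict(sel$model, x_cal), predict(sel$model, x_val))
      fitted[[m]] <- sel
    } else if (m == "ann") {
      fit <- fit_ann(x_cal, y_cal, n_hidden = ann_hidden, epochs = ann_epochs,
                     seed = seed * 13 + 9)
      rows[[m]] <- eval_model(m, predict(fit, x_cal), predict(fit, x_val))
      fitted[[m]] <- fit
    } else if (m == "mcr_als") {
      n_cal <- nrow(cal$spectra$absorbance)
      D <- rbind(cal$spectra$absorbance, val$spectra$absorbance)
      joint <- spectral_matrix(pmax(D, 0), bundle$grid,
                               sample_ids = c(cal$spectra$sample_ids,
                                              val$spectra$sample_ids))
      res <- mcr_als(joint, k = length(components(y_cal)), tol = mcr_tol)
      preds <- quantify_from_mcr(res, y_cal, cal_idx = seq_len(n_cal))
      rows[[m]] <- eval_model(m, preds[seq_len(n_cal), ],
                              preds[n_cal + seq_len(nrow(y_val)), ])
      fitted[[m]] <- res
    }
  }
  structure(
    list(table = dplyr::bind_rows(rows), models = fitted, n_lv = n_lv,
         cv = cv, bundle = bundle, seed = seed),
    class = "study_result"
  )
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> seed %d, %d LVs\n", x$seed, x$n_lv))
  print(as.data.frame(x$table), digits = 4)
  invisible(x)
}

#' Compare LHS and Monte Carlo validation sampling
#'
#' Mirrors the study layout in which one calibration set exists and only
#' the validation strategy varies: a single calibration set is simulated
#' and a PLS model fitted once (LV count by leave-one-out CV); then, for
#' each of `n_repeats` derived seeds, a fresh Latin hypercube plan and a
#' fresh Monte Carlo plan of the same size are drawn, their mixtures
#' simulated, and the pooled validation RMSEP recorded per method together
#' with stratum-occupancy diagnostics. Holding the calibration model fixed
#' isolates the variability contributed by validation-set placement, which
#' is what distinguishes the two sampling strategies.
#'
#' @param n_repeats Number of repeats (>= 2). Default 50.
#' @param seed Integer master seed.
#' @param noise A [noise_spec()]; moderate additive noise (e.g. 0.005 AU)
#'   makes the stability contrast visible.
#' @param grid A [wavelength_grid()].
#' @param n_strata Validation size / LHS strata. Default 13.
#' @return A list of class `sampling_comparison`: `results` (tibble:
#'   `repeat_id`, `method`, `rmsep`, `n_empty_strata`, `min_distance`),
#'   `summary` (per-method mean/SD of RMSEP and empty-stratum rate) and
#'   `n_lv`.
#' @export
compare_sampling <- function(n_repeats = 50, seed = 1,
                             noise = noise_spec(additive_sd = 0.005),
                             grid = wavelength_grid(200, 260, 0.2),
                             n_strata = 13) {
  if (n_repeats < 2) stop("`n_repeats` must be >= 2")
  bundle <- make_study(seed, noise = noise, grid = grid, n_strata = n_strata)
  x_cal <- bundle$calibration$spectra
  y_cal <- bundle$calibration$concentrations
  n_lv <- selected_lv(loocv(x_cal, y_cal, max_lv = min(6, nrow(y_cal) - 2)))
  fit <- fit_pls(x_cal, y_cal, n_lv = n_lv)
  comp <- names(bundle$specs)
  bounds <- range(attr(bundle$design, "level_values"))
  sub_seeds <- withr::with_seed(seed, matrix(sample.int(2147483646, n_repeats * 4),
                                             n_repeats, 4))
  rows <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    per_method <- purrr::map_dfr(c(lhs = "lhs", mc = "mc"), .id = "method",
      function(meth) {
        plan <- if (meth == "lhs") {
          lhs_sample(n_strata, length(comp), bounds, seed = sub_seeds[r, 1])
        } else {
          mc_sample(n_strata, length(comp), bounds, seed = sub_seeds[r, 2])
        }
        conc <- conc_table(tibble::as_tibble(plan)[c("sample_id", comp)])
        ns <- noise
        ns$seed <- sub_seeds[r, if (meth == "lhs") 3 else 4]
        sp <- simulate_mixtures(conc, bundle$specs, ns, grid)
        pred <- predict(fit, sp)
        cov <- coverage_report(plan, n_bins = n_strata)
        tibble::tibble(
          rmsep = rmse(as.vector(conc_matrix(pred)), as.vector(conc_matrix(conc))),
          n_empty_strata = sum(cov$n_empty$n_empty),
          min_distance = cov$min_distance
        )
      })
    rows[[r]] <- dplyr::bind_cols(tibble::tibble(repeat_id = r), per_method)
  }
  results <- dplyr::bind_rows(rows)
  structure(
    list(
      results = results,
      summary = dplyr::summarise(
        dplyr::group_by(results, .data$method),
        mean_rmsep = mean(.data$rmsep), sd_rmsep = stats::sd(.data$rmsep),
        empty_strata_rate = mean(.data$n_empty_strata > 0),
        mean_min_distance = mean(.data$min_distance),
        .groups = "drop"
      ),
      n_lv = n_lv
    ),
    class = "sampling_comparison"
  )
}

#' @export
print.sampling_comparison <- function(x, ...) {
  cat("<sampling_comparison>\n")
  print(as.data.frame(x$summary), digits = 4)
  invisible(x)
}

#' Plot the sampling-comparison RMSEP distributions
#' @param object A [compare_sampling()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sampling_comparison <- function(object, ...) {
  ggplot2::ggplot(object$results,
                  ggplot2::aes(x = .data$method, y = .data$rmsep)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "validation sampling method", y = "RMSEP (ug/mL)")
}
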