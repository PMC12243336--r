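#' Multilevel multifactorial calibration design
#'
#' Builds the coded calibration design for a two-component system: every
#' combination of the coded levels for each factor. At the default five
#' levels this is the classical 25-run set (the 5x5 full factorial, which at
#' two factors coincides with the cyclic multilevel construction), with codes
#' -2..2 mapped in order onto the supplied concentration levels.
#'
#' @param n_levels Number of concentration levels (>= 2).
#' @param n_factors Number of mixture components; only 2 is supported (the
#'   target system is binary).
#' @param level_values Strictly increasing concentrations (ug/mL), one per
#'   level. Default `seq(5, 25, length.out = n_levels)`.
#' @param component_names Names for the two components.
#'
#' @return A tibble of class `mixture_design` with columns `sample_id`, one
#'   coded-level column `code_<component>` per factor, and one decoded
#'   concentration column per component. Attributes `level_values` and
#'   `level_codes` record the code-to-concentration map.
#'
#' @examples
#' d <- multilevel_design()
#' nrow(d) # 25
#' @export
multilevel_design <- function(n_levels = 5, n_factors = 2,
                              level_values = seq(5, 25, length.out = n_levels),
                              component_names = c("component_a", "component_b")) {
  if (n_factors != 2) stop("only 2-factor (binary mixture) designs are supported")
  if (n_levels < 2) stop("`n_levels` must be >= 2")
  if (length(level_values) != n_levels) stop("`level_values` must have length `n_levels`")
  if (is.unsorted(level_values, strictly = TRUE)) {
    stop("`level_values` must be strictly increasing")
  }
  if (length(component_names) != n_factors) stop("need one name per factor")
  # centered integer codes, e.g. -2..2 for 5 levels
  codes <- seq_len(n_levels) - 1 - (n_levels - 1) / 2
  full <- expand.grid(code_1 = codes, code_2 = codes, KEEP.OUT.ATTRS = FALSE)
  decode <- function(code) level_values[match(code, codes)]
  out <- tibble::tibble(
    sample_id = sprintf("cal%02d", seq_len(nrow(full)))
  )
  out[[paste0("code_", component_names[1])]] <- full$code_1
  out[[paste0("code_", component_names[2])]] <- full$code_2
  out[[component_names[1]]] <- decode(full$code_1)
  out[[component_names[2]]] <- decode(full$code_2)
  structure(out,
            class = c("mixture_design", class(out)),
            level_values = level_values,
            level_codes = codes)
}

#' Concentration table of a mixture design
#'
#' @param design A [multilevel_design()].
#' @return A concentration tibble (`sample_id` + component columns) suitable
#'   for [simulate_mixtures()].
#' @export
design_concentrations <- function(design) {
  stopifnot(inherits(design, "mixture_design"))
  comp <- setdiff(names(design), c("sample_id", grep("^code_", names(design), value = TRUE)))
  conc_table(design[c("sample_id", comp)])
}

new_sampling_plan <- function(points, method, bounds, seed, n_strata = NA_integer_,
                              prefix = "val") {
  colnames(points) <- names(bounds)
  out <- tibble::as_tibble(as.data.frame(points))
  out <- dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("%s%02d", prefix, seq_len(nrow(points)))), out
  )
  structure(out,
            class = c("sampling_plan", class(out)),
            method = method, bounds = bounds, seed = seed,
            n_strata = n_strata)
}

check_bounds <- function(bounds, n_dims) {
  if (is.numeric(bounds) && length(bounds) == 2) {
    bounds <- replicate(n_dims, bounds, simplify = FALSE)
  }
  if (length(bounds) != n_dims) stop("need one (low, high) pair per dimension")
  if (is.null(names(bounds)) || any(names(bounds) == "")) {
    names(bounds) <- if (n_dims == 2) c("component_a", "component_b") else paste0("dim", seq_len(n_dims))
  }
  for (b in bounds) {
    if (length(b) != 2 || !is.numeric(b) || b[1] >= b[2]) {
      stop("each bound must be a numeric (low, high) pair with low < high")
    }
  }
  bounds
}

#' Latin hypercube validation sampling
#'
#' Draws one point per stratum per dimension: each axis is cut into
#' `n_strata` equal-width intervals ("equal probability" under the uniform
#' marginal), the strata are permuted independently per dimension, and the
#' position within each stratum is uniform. The default 13 strata mirror a
#' roughly 2:1 calibration:validation split against a 25-run design.
#'
#' @param n_strata Number of strata = number of points (>= 1).
#' @param n_dims Number of dimensions (components).
#' @param bounds A (low, high) pair applied to every dimension, or a list of
#'   per-dimension pairs (ug/mL). Default `c(5, 25)`.
#' @param seed Integer seed; the plan is exactly reproducible from
#'   `(method, n, bounds, seed)`.
#'
#' @return A tibble of class `sampling_plan` with `sample_id` plus one column
#'   per dimension; attributes `method`, `bounds`, `seed`, `n_strata`.
#' @examples
#' p <- lhs_sample(13, 2, c(5, 25), seed = 1)
#' coverage_report(p, 13)$occupancy
#' @export
lhs_sample <- function(n_strata = 13, n_dims = 2, bounds = c(5, 25), seed = 1) {
  if (n_strata < 1) stop("`n_strata` must be >= 1")
  bounds <- check_bounds(bounds, n_dims)
  unit <- withr::with_seed(seed, lhs::randomLHS(n_strata, n_dims))
  pts <- vapply(seq_len(n_dims), function(j) {
    b <- bounds[[j]]
    b[1] + unit[, j] * (b[2] - b[1])
  }, numeric(n_strata))
  if (n_strata == 1) pts <- matrix(pts, nrow = 1)
  new_sampling_plan(pts, "lhs", bounds, seed, n_strata = n_strata)
}

#' Monte Carlo validation sampling
#'
#' i.i.d. uniform points over the bounds; the unstratified counterpart to
#' [lhs_sample()] used in the sampling-strategy comparison.
#'
#' @param n_points Number of points (0 gives an empty plan).
#' @inheritParams lhs_sample
#' @return A `sampling_plan` tibble (see [lhs_sample()]).
#' @export
mc_sample <- function(n_points = 13, n_dims = 2, bounds = c(5, 25), seed = 1) {
  if (n_points < 0) stop("`n_points` must be >= 0")
  bounds <- check_bounds(bounds, n_dims)
  unit <- withr::with_seed(seed, matrix(stats::runif(n_points * n_dims),
                                        nrow = n_points, ncol = n_dims))
  pts <- vapply(seq_len(n_dims), function(j) {
    b <- bounds[[j]]
    b[1] + unit[, j] * (b[2] - b[1])
  }, numeric(n_points))
  if (n_points <= 1) pts <- matrix(pts, nrow = n_points, ncol = n_dims)
  new_sampling_plan(pts, "monte_carlo", bounds, seed)
}

#' Space-coverage diagnostics for a sampling plan
#'
#' Bins each dimension of the plan into `n_bins` equal-width intervals over
#' its bounds and counts occupancy, and reports the minimum pairwise
#' Euclidean distance between points. An LHS plan binned at its own stratum
#' count has occupancy exactly 1 everywhere; Monte Carlo plans typically
#' leave strata empty.
#'
#' @param plan A `sampling_plan` (or any tibble with `sample_id` + numeric
#'   columns plus a `bounds` attribute).
#' @param n_bins Number of bins per dimension (>= 1).
#' @return A list with `occupancy` (tibble: `dimension`, `bin`, `count`),
#'   `n_empty` (tibble: empty-bin count per dimension) and `min_distance`.
#' @export
coverage_report <- function(plan, n_bins) {
  if (n_bins < 1) stop("`n_bins` must be >= 1")
  dims <- setdiff(names(plan), "sample_id")
  pts <- as.matrix(plan[dims])
  if (nrow(pts) == 0) stop("empty sampling plan")
  bounds <- attr(plan, "bounds")
  occ <- purrr::map_dfr(seq_along(dims), function(j) {
    b <- if (!is.null(bounds)) bounds[[j]] else range(pts[, j])
    brk <- seq(b[1], b[2], length.out = n_bins + 1)
    # points on [low, high]; right edge closed so the max lands in the last bin
    hits <- pmin(pmax(findInterval(pts[, j], brk, rightmost.closed = TRUE), 1L), n_bins)
    counts <- as.integer(tabulate(hits, nbins = n_bins))
    tibble::tibble(dimension = dims[j], bin = seq_len(n_bins), count = counts)
  })
  min_d <- if (nrow(pts) < 2) NA_real_ else min(stats::dist(pts))
  list(
    occupancy = occ,
    n_empty = dplyr::summarise(dplyr::group_by(occ, .data$dimension),
                               n_empty = sum(.data$count == 0L), .groups = "drop"),
    min_distance = min_d
  )
}

#' Plot a 2-D sampling plan
#' @param object A `sampling_plan` with two dimensions.
#' @param ... Unused.
#' @return A ggplot object (space-filling scatter).
#' @export
autoplot.sampling_plan <- function(object, ...) {
  dims <- setdiff(names(object), "sample_id")
  stopifnot(length(dims) == 2)
  ggplot2::ggplot(object, ggplot2::aes(x = .data[[dims[1]]], y = .data[[dims[2]]])) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(title = paste0("validation points (", attr(object, "method"), ")"),
                  x = paste0(dims[1], " (ug/mL)"), y = paste0(dims[2], " (ug/mL)"))
}
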