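#' Construct a uniform wavelength grid
#'
#' A wavelength grid is the axis every spectrum in a study shares. Grids are
#' uniform by construction: `start_nm`, `end_nm` and `step_nm` fully determine
#' the label vector, and every downstream function refuses spectra whose
#' column count disagrees with the grid it was built on. The default
#' acquisition window for overlapping UV work in this package is 200-260 nm
#' at 0.2 nm, i.e. 301 points.
#'
#' @param start_nm First wavelength (nm).
#' @param end_nm Last wavelength (nm); must be >= `start_nm`.
#' @param step_nm Increment (nm); must be > 0 and divide the span to within
#'   1e-6 nm.
#'
#' @return An object of class `wavelength_grid`: a list with fields
#'   `start_nm`, `end_nm`, `step_nm` and `labels` (strictly increasing,
#'   uniformly spaced wavelengths in nm).
#'
#' @examples
#' g <- wavelength_grid(200, 260, 0.2)
#' length(g$labels) # 301
#' @export
wavelength_grid <- function(start_nm, end_nm, step_nm) {
  stopifnot(is.numeric(start_nm), is.numeric(end_nm), is.numeric(step_nm))
  if (step_nm <= 0) stop("`step_nm` must be positive, got ", step_nm)
  if (end_nm < start_nm) stop("`end_nm` (", end_nm, ") must be >= `start_nm` (", start_nm, ")")
  span <- end_nm - start_nm
  n_steps <- round(span / step_nm)
  if (abs(span - n_steps * step_nm) > 1e-6) {
    stop("`step_nm` = ", step_nm, " does not divide the span ", span,
         " nm to within 1e-6 nm")
  }
  labels <- start_nm + step_nm * seq(0, n_steps)
  structure(
    list(start_nm = start_nm, end_nm = end_nm, step_nm = step_nm, labels = labels),
    class = "wavelength_grid"
  )
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("<wavelength_grid> %g-%g nm, step %g nm (%d points)\n",
              x$start_nm, x$end_nm, x$step_nm, length(x$labels)))
  invisible(x)
}

#' Number of points in a wavelength grid
#' @param grid A [wavelength_grid()].
#' @return Integer point count.
#' @export
grid_points <- function(grid) {
  stopifnot(inherits(grid, "wavelength_grid"))
  length(grid$labels)
}

valid_stages <- c("raw", "smoothed", "derivative1", "derivative2", "snv", "centered")

#' Construct a spectral matrix
#'
#' The samples-by-wavelengths absorbance block that is the X of every
#' calibration model, bound to the [wavelength_grid()] it was measured on.
#' Raw-stage spectra must be non-negative; derivative and SNV stages may not
#' be.
#'
#' @param absorbance Numeric matrix, one row per sample, one column per grid
#'   point (absorbance units).
#' @param grid The [wavelength_grid()] the columns live on.
#' @param sample_ids Character vector of sample identifiers; defaults to
#'   rownames or `s1, s2, ...`.
#' @param stage Processing stage tag, one of `"raw"`, `"smoothed"`,
#'   `"derivative1"`, `"derivative2"`, `"snv"`, `"centered"`.
#'
#' @return An object of class `spectral_matrix`.
#' @examples
#' g <- wavelength_grid(200, 204, 2)
#' spectral_matrix(matrix(runif(6), 2, 3), g)
#' @export
spectral_matrix <- function(absorbance, grid, sample_ids = NULL, stage = "raw") {
  stopifnot(inherits(grid, "wavelength_grid"))
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  stage <- match.arg(stage, valid_stages)
  if (ncol(absorbance) != grid_points(grid)) {
    stop("absorbance has ", ncol(absorbance), " columns but the grid has ",
         grid_points(grid), " points")
  }
  if (!all(is.finite(absorbance))) stop("absorbance contains non-finite entries")
  if (stage == "raw" && any(absorbance < 0)) {
    stop("raw-stage absorbance must be non-negative")
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(absorbance)
    if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(absorbance)))
  }
  if (length(sample_ids) != nrow(absorbance)) {
    stop("length(sample_ids) != number of spectra")
  }
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  dimnames(absorbance) <- NULL
  rownames(absorbance) <- sample_ids
  structure(
    list(absorbance = absorbance, grid = grid,
         sample_ids = as.character(sample_ids), stage = stage),
    class = "spectral_matrix"
  )
}

#' @export
print.spectral_matrix <- function(x, ...) {
  cat(sprintf("<spectral_matrix> %d spectra x %d wavelengths (%g-%g nm), stage '%s'\n",
              nrow(x$absorbance), ncol(x$absorbance),
              x$grid$start_nm, x$grid$end_nm, x$stage))
  invisible(x)
}

#' @export
dim.spectral_matrix <- function(x) dim(x$absorbance)

# internal: new spectral_matrix reusing metadata, skipping raw-stage check
replace_absorbance <- function(spectra, absorbance, stage = spectra$stage) {
  out <- spectra
  rownames(absorbance) <- spectra$sample_ids
  out$absorbance <- absorbance
  out$stage <- stage
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a spectral matrix into a long tibble
#'
#' @param x A [spectral_matrix()].
#' @param ... Unused.
#' @return A tibble with columns `sample_id`, `wavelength_nm`, `absorbance`
#'   and `stage`.
#' @export
tidy.spectral_matrix <- function(x, ...) {
  tibble::tibble(
    sample_id = rep(x$sample_ids, each = grid_points(x$grid)),
    wavelength_nm = rep(x$grid$labels, times = length(x$sample_ids)),
    absorbance = as.vector(t(x$absorbance)),
    stage = x$stage
  )
}

#' Plot spectra as overlaid traces
#'
#' @param object A [spectral_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spectral_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$wavelength_nm, y = .data$absorbance,
                                   group = .data$sample_id)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = "wavelength (nm)",
                  y = if (object$stage %in% c("derivative1", "derivative2")) {
                    "d absorbance (AU/nm^d)"
                  } else "absorbance (AU)",
                  title = paste0("spectra (stage: ", object$stage, ")"))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# ---- concentration tables ----------------------------------------------------

#' Validate a concentration table
#'
#' Concentration tables are plain tibbles: a `sample_id` column plus one
#' numeric column per component, concentrations in ug/mL. This checks the
#' contract every model relies on (non-negative, finite, unique ids) and
#' returns the table unchanged.
#'
#' @param x A data frame with `sample_id` and numeric component columns.
#' @param spectra Optional [spectral_matrix()] whose `sample_ids` must align
#'   one-to-one (same order) with `x$sample_id`.
#' @return `x` as a tibble, invisibly validated.
#' @export
conc_table <- function(x, spectra = NULL) {
  x <- tibble::as_tibble(x)
  if (!"sample_id" %in% names(x)) stop("concentration table needs a `sample_id` column")
  comp <- setdiff(names(x), "sample_id")
  if (length(comp) == 0) stop("concentration table has no component columns")
  vals <- as.matrix(x[comp])
  if (!is.numeric(vals)) stop("component columns must be numeric")
  if (!all(is.finite(vals))) stop("concentrations contain non-finite entries")
  if (any(vals < 0)) stop("concentrations must be non-negative")
  if (anyDuplicated(x$sample_id)) stop("sample_id values must be unique")
  if (!is.null(spectra)) {
    if (!identical(as.character(x$sample_id), spectra$sample_ids)) {
      stop("concentration table sample_ids do not align with the spectral matrix")
    }
  }
  x
}

#' Component names of a concentration table
#' @param x A concentration table (see [conc_table()]).
#' @return Character vector of component column names.
#' @export
components <- function(x) setdiff(names(x), "sample_id")

# internal: numeric matrix view of a concentration table
conc_matrix <- function(x) {
  m <- as.matrix(x[components(x)])
  rownames(m) <- x$sample_id
  m
}

# internal: rebuild a concentration tibble from a matrix
conc_from_matrix <- function(m, sample_ids, component_names) {
  out <- tibble::as_tibble(as.data.frame(m))
  names(out) <- component_names
  dplyr::bind_cols(tibble::tibble(sample_id = sample_ids), out)
}

# ---- CSV dialects ------------------------------------------------------------

#' Read and write the spectra CSV dialect
#'
#' Spectra are stored wide, column-per-sample, matching instrument exports:
#' first column `wavelength_nm` (strictly increasing), then one numeric
#' column per sample. The roundtrip `write_spectra_csv()` then
#' `read_spectra_csv()` is lossless at full double precision.
#'
#' @param path File path.
#' @return `read_spectra_csv()` returns a [spectral_matrix()] (stage `"raw"`
#'   if non-negative, otherwise the stage given in `stage`).
#' @param stage Stage tag to assign on read; defaults to `"raw"` unless the
#'   data are negative anywhere, in which case reading fails for `"raw"`.
#' @export
read_spectra_csv <- function(path, stage = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (names(df)[1] != "wavelength_nm") {
    stop("first column must be named 'wavelength_nm', got '", names(df)[1], "'")
  }
  if (ncol(df) < 2) stop("spectra CSV has no sample columns")
  num <- suppressWarnings(vapply(df, as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1) num <- matrix(num, nrow = 1, dimnames = list(NULL, names(df)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-numeric cell at row ", bad[1, 1], ", column '", colnames(num)[bad[1, 2]], "'")
  }
  wl <- num[, 1]
  if (anyDuplicated(wl)) {
    stop("duplicated wavelength row: ", wl[duplicated(wl)][1], " nm")
  }
  if (is.unsorted(wl, strictly = TRUE)) stop("wavelengths must be strictly increasing")
  step <- if (length(wl) > 1) (wl[length(wl)] - wl[1]) / (length(wl) - 1) else 1
  if (length(wl) > 2 && max(abs(diff(wl) - step)) > 1e-6) {
    stop("wavelengths are not uniformly spaced")
  }
  grid <- wavelength_grid(wl[1], wl[length(wl)], step)
  ab <- t(num[, -1, drop = FALSE])
  if (is.null(stage)) stage <- if (all(ab >= 0)) "raw" else "snv"
  spectral_matrix(ab, grid, sample_ids = colnames(df)[-1], stage = stage)
}

#' @rdname read_spectra_csv
#' @param spectra A [spectral_matrix()].
#' @export
write_spectra_csv <- function(spectra, path) {
  stopifnot(inherits(spectra, "spectral_matrix"))
  df <- data.frame(wavelength_nm = spectra$grid$labels, check.names = FALSE)
  ab <- t(spectra$absorbance)
  colnames(ab) <- spectra$sample_ids
  df <- cbind(df, as.data.frame(ab, check.names = FALSE))
  # format() at 17 significant digits keeps the roundtrip bit-exact
  utils::write.csv(
    data.frame(lapply(df, function(col) format(col, digits = 17, trim = TRUE,
                                               scientific = FALSE)),
               check.names = FALSE),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Read and write the concentrations CSV dialect
#'
#' One row per sample: header `sample_id,<component>,...`, values in ug/mL.
#'
#' @param path File path.
#' @return `read_concentrations_csv()` returns a concentration tibble (see
#'   [conc_table()]).
#' @export
read_concentrations_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  conc_table(df)
}

#' @rdname read_concentrations_csv
#' @param conc A concentration table.
#' @export
write_concentrations_csv <- function(conc, path) {
  conc <- conc_table(conc)
  utils::write.csv(conc, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- centering ---------------------------------------------------------------

#' Column mean-centering
#'
#' Removes the column mean from a spectral matrix, a concentration table, or
#' a plain matrix, returning both the centered block and the means so the
#' operation can be undone (and applied to new data at prediction time).
#'
#' @param x A [spectral_matrix()], concentration table, or numeric matrix.
#' @return A list with elements `centered` (same type as `x`) and `means`
#'   (named numeric vector of column means).
#' @examples
#' mean_center(matrix(c(1, 3, 3, 1), 2, 2))
#' @export
mean_center <- function(x) UseMethod("mean_center")

#' @export
mean_center.matrix <- function(x) {
  if (nrow(x) < 1) stop("cannot center an empty matrix")
  mu <- colMeans(x)
  list(centered = sweep(x, 2, mu), means = mu)
}

#' @export
mean_center.spectral_matrix <- function(x) {
  cc <- mean_center(x$absorbance)
  list(centered = replace_absorbance(x, cc$centered, stage = "centered"),
       means = cc$means)
}

#' @export
mean_center.data.frame <- function(x) {
  x <- conc_table(x)
  cc <- mean_center(conc_matrix(x))
  list(centered = conc_from_matrix(cc$centered, x$sample_id, components(x)),
       means = cc$means)
}
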