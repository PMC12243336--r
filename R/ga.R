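# Genetic-algorithm wavelength selection. Two fitness flavors are provided:
# penalized leave-one-out RMSECV (classical GA-PLS) and an information
# complexity (ICOMP) score on the LOO residual covariance (GA-ICOMP-PLS).

#' Genetic-algorithm configuration
#'
#' @param population Population size (>= 2). Default 30.
#' @param generations Number of generations. Default 50 (the ICOMP flavor's
#'   default; [ga_pls()] uses 100).
#' @param mutation_rate Per-bit flip probability in \[0, 1\]. Default 0.01.
#' @param crossover Crossover operator; only `"uniform"` is implemented.
#' @param elitism Number of best chromosomes carried over unchanged (>= 1
#'   guarantees monotone best-so-far fitness). Default 1.
#' @param penalty_lambda Sparsity penalty coefficient for
#'   [penalized_fitness()]. Default 0.05.
#' @param window_size Wavelengths per selectable block; 1 selects individual
#'   wavelengths, larger values select contiguous spectral windows (last
#'   block may truncate).
#' @param n_lv Latent-variable count held fixed during the search (the GA
#'   selects wavelengths, not model size).
#' @param seed Integer seed; a run is exactly reproducible from its config.
#' @param n_restarts Independent restarts for [ga_pls()] (>= 1).
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(population = 30, generations = 50, mutation_rate = 0.01,
                      crossover = "uniform", elitism = 1, penalty_lambda = 0.05,
                      window_size = 1, n_lv = 2, seed = 1, n_restarts = 1) {
  if (population < 2) stop("`population` must be >= 2")
  if (mutation_rate < 0 || mutation_rate > 1) stop("`mutation_rate` must be in [0, 1]")
  crossover <- match.arg(crossover, "uniform")
  if (window_size < 1) stop("`window_size` must be >= 1")
  if (elitism < 0 || elitism >= population) stop("`elitism` must be in [0, population)")
  if (n_restarts < 1) stop("`n_restarts` must be >= 1")
  structure(list(population = population, generations = generations,
                 mutation_rate = mutation_rate, crossover = crossover,
                 elitism = elitism, penalty_lambda = penalty_lambda,
                 window_size = window_size, n_lv = n_lv, seed = seed,
                 n_restarts = n_restarts),
            class = "ga_config")
}

# internal: expand a block-level gene vector to a per-wavelength mask
expand_windows <- function(genes, n_bits, window_size) {
  if (window_size == 1) return(genes)
  rep(genes, each = window_size)[seq_len(n_bits)]
}

# internal: held-out prediction errors (pred - actual) at a fixed LV count
loo_errors <- function(Xm, Y, n_lv) {
  n <- nrow(Xm)
  E <- matrix(0, n, ncol(Y))
  for (i in seq_len(n)) {
    x_mean <- colMeans(Xm[-i, , drop = FALSE])
    y_mean <- colMeans(Y[-i, , drop = FALSE])
    fit <- nipals_core(sweep(Xm[-i, , drop = FALSE], 2, x_mean),
                       sweep(Y[-i, , drop = FALSE], 2, y_mean), n_lv,
                       strict = FALSE)
    pred <- drop((Xm[i, ] - x_mean) %*% fit$coefs[[n_lv]]) + y_mean
    E[i, ] <- pred - Y[i, ]
  }
  E
}

#' Penalized cross-validation fitness for wavelength masks
#'
#' The classical GA-PLS objective: leave-one-out RMSECV of a PLS model on
#' the masked spectra, plus a sparsity penalty `lambda * k / p` where `k` is
#' the selected wavelength count and `p` the total. The normalized count
#' keeps `lambda` scale-free; the default `lambda = 0.05` trades roughly
#' 0.05 ug/mL of cross-validated error against selecting the full spectrum.
#'
#' @param mask Logical wavelength-inclusion vector (or indices).
#' @param x,y Calibration spectra and concentrations (see [fit_pls()]).
#' @param n_lv Fixed latent-variable count.
#' @param lambda Penalty coefficient (>= 0).
#' @return Scalar fitness (lower is better).
#' @export
penalized_fitness <- function(mask, x, y, n_lv, lambda = 0.05) {
  X <- x_matrix(x)
  Y <- y_matrix(y)
  mask <- resolve_mask(mask, ncol(X))
  k <- sum(mask)
  if (k < 1) stop("mask selects no wavelengths")
  if (k < n_lv) stop("mask selects fewer wavelengths (", k, ") than latent variables (", n_lv, ")")
  if (lambda < 0) stop("`lambda` must be >= 0")
  E <- loo_errors(X[, mask, drop = FALSE], Y, n_lv)
  rmsecv <- sqrt(sum(E^2) / length(E))
  rmsecv + lambda * k / length(mask)
}

#' Information-complexity (ICOMP) score of a residual matrix
#'
#' `ICOMP = -2 log L + 2 C(Sigma)` for the profiled Gaussian likelihood of
#' an `n x q` residual matrix with `Sigma = E'E / n`, using Bozdogan's C1
#' covariance complexity
#' `C1(Sigma) = (q/2) log(tr(Sigma)/q) - (1/2) log det(Sigma)` -- the
#' arithmetic-over-geometric mean of the eigenvalues, zero iff the residual
#' covariance is spherical and strictly positive otherwise. Lower is better:
#' the score rewards small *and* well-conditioned residual covariance.
#'
#' @param residuals Numeric `n x q` matrix of prediction errors, `n > q`.
#' @return An object of class `icomp_score`: list with `minus2_loglik`,
#'   `complexity`, `total` (`= minus2_loglik + 2 * complexity`),
#'   `residual_cov` and `ridged` (TRUE if a 1e-12 ridge was needed for a
#'   singular covariance).
#' @examples
#' icomp_score(matrix(rnorm(40), 20, 2))
#' @export
icomp_score <- function(residuals) {
  E <- as.matrix(residuals)
  n <- nrow(E); q <- ncol(E)
  if (n <= q) stop("need more residual rows than columns (n > q)")
  if (!all(is.finite(E))) stop("residuals contain non-finite values")
  Sig <- crossprod(E) / n
  ridged <- FALSE
  ev <- eigen(Sig, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    Sig <- Sig + diag(1e-12, q)
    ev <- pmax(ev, 0) + 1e-12
    ridged <- TRUE
  }
  logdet <- sum(log(ev))
  minus2 <- n * q * log(2 * pi) + n * logdet + n * q
  complexity <- (q / 2) * log(sum(ev) / q) - logdet / 2
  complexity <- max(complexity, 0) # guard tiny negative rounding
  structure(list(minus2_loglik = minus2, complexity = complexity,
                 total = minus2 + 2 * complexity,
                 residual_cov = Sig, ridged = ridged),
            class = "icomp_score")
}

#' @export
print.icomp_score <- function(x, ...) {
  cat(sprintf("<icomp_score> total %.4f (-2logL %.4f, complexity %.4f%s)\n",
              x$total, x$minus2_loglik, x$complexity,
              if (x$ridged) ", ridged" else ""))
  invisible(x)
}

#' Run a genetic-algorithm search over binary wavelength masks
#'
#' Size-2 tournament selection, uniform crossover, per-bit mutation, and
#' elitism. The initial population is random masks at 50% density plus one
#' all-ones chromosome, so the full-spectrum baseline is always in the
#' search space. All-zero chromosomes are repaired by flipping one uniformly
#' random bit. With `elitism >= 1` the best-so-far fitness is monotone
#' non-increasing across generations.
#'
#' @param fitness Function taking a logical mask of length `n_bits` and
#'   returning a scalar (lower is better). Errors in the callback are
#'   re-raised with the offending mask attached.
#' @param n_bits Number of wavelengths.
#' @param config A [ga_config()].
#' @return An object of class `ga_result`: list with `best_mask` (logical),
#'   `best_fitness`, `history` (tibble: `generation`, `best`, `mean`,
#'   `mean_k`) and `config`.
#' @export
run_ga <- function(fitness, n_bits, config = ga_config()) {
  stopifnot(inherits(config, "ga_config"))
  n_genes <- ceiling(n_bits / config$window_size)
  eval_fit <- function(genes) {
    mask <- expand_windows(genes, n_bits, config$window_size)
    tryCatch(fitness(mask), error = function(e) {
      stop("fitness callback failed on mask [",
           paste(which(mask), collapse = ","), "]: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  withr::with_seed(config$seed, {
    repair <- function(genes) {
      if (!any(genes)) genes[sample.int(n_genes, 1)] <- TRUE
      genes
    }
    pop <- lapply(seq_len(config$population), function(i) {
      repair(stats::runif(n_genes) < 0.5)
    })
    pop[[1]] <- rep(TRUE, n_genes) # full-spectrum baseline
    fit <- vapply(pop, eval_fit, numeric(1))
    history <- vector("list", config$generations)
    for (g in seq_len(config$generations)) {
      ord <- order(fit)
      elite <- pop[ord[seq_len(config$elitism)]]
      elite_fit <- fit[ord[seq_len(config$elitism)]]
      tournament <- function() {
        ij <- sample.int(config$population, 2, replace = TRUE)
        pop[[ij[which.min(fit[ij])]]]
      }
      children <- lapply(seq_len(config$population - config$elitism), function(i) {
        p1 <- tournament(); p2 <- tournament()
        pick <- stats::runif(n_genes) < 0.5 # uniform crossover
        child <- ifelse(pick, p1, p2)
        flip <- stats::runif(n_genes) < config$mutation_rate
        repair(xor(child, flip))
      })
      pop <- c(elite, children)
      fit <- c(elite_fit, vapply(children, eval_fit, numeric(1)))
      k <- vapply(pop, function(genes) {
        sum(expand_windows(genes, n_bits, config$window_size))
      }, numeric(1))
      history[[g]] <- tibble::tibble(generation = g, best = min(fit),
                                     mean = mean(fit), mean_k = mean(k))
    }
    best_i <- which.min(fit)
    structure(
      list(best_mask = expand_windows(pop[[best_i]], n_bits, config$window_size),
           best_fitness = fit[best_i],
           history = dplyr::bind_rows(history),
           config = config),
      class = "ga_result"
    )
  })
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("<ga_result> best fitness %.6g, %d/%d wavelengths selected\n",
              x$best_fitness, sum(x$best_mask), length(x$best_mask)))
  invisible(x)
}

#' Plot GA convergence history
#' @param object A `ga_result`.
#' @param ... Unused.
#' @return A ggplot object (best and mean fitness per generation).
#' @export
autoplot.ga_result <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, c("best", "mean"),
                            names_to = "series", values_to = "fitness")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$generation, y = .data$fitness,
                                   linetype = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "generation", y = "fitness (lower is better)")
}

#' @rdname tidy.ga_result
#' @export
glance.ga_result <- function(x, ...) {
  tibble::tibble(best_fitness = x$best_fitness,
                 n_selected = sum(x$best_mask),
                 n_bits = length(x$best_mask),
                 generations = x$config$generations,
                 population = x$config$population)
}

#' Tidy a GA run history
#' @param x A `ga_result`.
#' @param ... Unused.
#' @return `tidy()`: the per-generation history tibble; `glance()`: a
#'   one-row summary.
#' @export
tidy.ga_result <- function(x, ...) x$history

#' GA-PLS wavelength selection (penalized RMSECV, multi-restart)
#'
#' Runs [run_ga()] with the [penalized_fitness()] objective, optionally over
#' several independent restarts (different derived seeds), and returns the
#' restart with the lowest fitness. Masks selecting fewer wavelengths than
#' the fixed LV count are assigned infinite fitness rather than erroring, so
#' the search can pass through them.
#'
#' @inheritParams fit_pls
#' @param config A [ga_config()]; the penalized flavor defaults to 100
#'   generations.
#' @return A `ga_result` with an extra element `restarts` (list of all
#'   per-restart `ga_result`s).
#' @export
ga_pls <- function(x, y, config = ga_config(generations = 100)) {
  X <- x_matrix(x)
  Y <- y_matrix(y)
  fitness <- function(mask) {
    if (sum(mask) < config$n_lv) return(Inf)
    penalized_fitness(mask, X, Y, n_lv = config$n_lv, lambda = config$penalty_lambda)
  }
  runs <- lapply(seq_len(config$n_restarts), function(r) {
    cfg <- config
    cfg$seed <- config$seed + r - 1
    run_ga(fitness, ncol(X), cfg)
  })
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "best_fitness"))]]
  best$restarts <- runs
  best
}

#' GA-ICOMP-PLS wavelength selection
#'
#' The hybrid selector: a GA over wavelength masks scored by the
#' information-complexity criterion ([icomp_score()]) of the leave-one-out
#' PLS residuals on the masked spectra, so the criterion sees generalization
#' error rather than calibration fit. Both responses are modeled jointly
#' (q = 2); with a single response the complexity term vanishes identically
#' and ICOMP reduces to the likelihood. Because the full-spectrum chromosome
#' seeds the initial population, the returned ICOMP never exceeds the
#' full-spectrum ICOMP on the same data.
#'
#' @inheritParams fit_pls
#' @param config A [ga_config()]; defaults are population 30, 50
#'   generations, 1% bit-flip mutation, uniform crossover.
#' @return A list of class `ga_icomp_result`: `mask` (logical), `icomp` (the
#'   best [icomp_score()]), `model` (PLS refit on the selected wavelengths),
#'   `ga` (the underlying `ga_result`).
#' @export
ga_icomp_pls <- function(x, y, config = ga_config()) {
  X <- x_matrix(x)
  Y <- y_matrix(y)
  fitness <- function(mask) {
    if (sum(mask) < config$n_lv) return(Inf)
    icomp_score(loo_errors(X[, mask, drop = FALSE], Y, config$n_lv))$total
  }
  ga <- run_ga(fitness, ncol(X), config)
  score <- icomp_score(loo_errors(X[, ga$best_mask, drop = FALSE], Y, config$n_lv))
  model <- fit_pls(x, y, n_lv = config$n_lv, mask = ga$best_mask)
  structure(list(mask = ga$best_mask, icomp = score, model = model, ga = ga),
            class = "ga_icomp_result")
}

#' @export
print.ga_icomp_result <- function(x, ...) {
  cat(sprintf("<ga_icomp_result> ICOMP %.4f, %d/%d wavelengths\n",
              x$icomp$total, sum(x$mask), length(x$mask)))
  invisible(x)
}
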