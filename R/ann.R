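# Small feed-forward network (tanh hidden layer, linear output) trained by
# Levenberg-Marquardt with an analytic Jacobian. Inputs and outputs are
# min-max scaled to [-1, 1]; scaling is fitted on the training partition only.

#' 70/15/15 random partition
#'
#' Shuffles `1..n` by seed and splits into training, validation and test
#' sets with sizes `round-half-up(0.70 n)`, `round-half-up(0.15 n)` and the
#' remainder; for the canonical 25-sample calibration set this gives
#' 18/4/3.
#'
#' @param n Number of samples (>= 3).
#' @param seed Integer seed.
#' @return A list with integer index vectors `train`, `val`, `test`
#'   (disjoint, covering `1..n`).
#' @examples
#' lengths(partition_70_15_15(25, seed = 1)) # 18 4 3
#' @export
partition_70_15_15 <- function(n, seed = 1) {
  if (n < 3) stop("`n` must be >= 3")
  n_train <- floor(0.70 * n + 0.5)
  n_val <- floor(0.15 * n + 0.5)
  n_test <- n - n_train - n_val
  idx <- withr::with_seed(seed, sample.int(n))
  list(train = sort(idx[seq_len(n_train)]),
       val = sort(idx[n_train + seq_len(n_val)]),
       test = sort(idx[n_train + n_val + seq_len(n_test)]))
}

# ---- scaling -----------------------------------------------------------------

minmax_fit <- function(M) {
  lo <- apply(M, 2, min); hi <- apply(M, 2, max)
  if (any(hi <= lo)) {
    stop("constant feature(s) cannot be min-max scaled: column ",
         which(hi <= lo)[1])
  }
  list(min = lo, max = hi)
}

minmax_apply <- function(M, s) {
  sweep(sweep(M, 2, s$min), 2, (s$max - s$min) / 2, `/`) - 1
}

minmax_invert <- function(M, s) {
  sweep(sweep(M + 1, 2, (s$max - s$min) / 2, `*`), 2, s$min, `+`)
}

# ---- parameter packing -------------------------------------------------------

pack_theta <- function(W1, b1, W2, b2) c(as.vector(W1), b1, as.vector(W2), b2)

unpack_theta <- function(theta, p, h, q) {
  i <- 0
  W1 <- matrix(theta[i + seq_len(h * p)], h, p); i <- i + h * p
  b1 <- theta[i + seq_len(h)]; i <- i + h
  W2 <- matrix(theta[i + seq_len(q * h)], q, h); i <- i + q * h
  b2 <- theta[i + seq_len(q)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

ann_forward <- function(w, X) {
  A1 <- tanh(sweep(X %*% t(w$W1), 2, w$b1, `+`))
  list(A1 = A1, Yhat = sweep(A1 %*% t(w$W2), 2, w$b2, `+`))
}

# residual vector (column-major over outputs) and its analytic Jacobian
ann_jacobian <- function(w, X, Y) {
  n <- nrow(X); p <- ncol(X); h <- length(w$b1); q <- length(w$b2)
  fwd <- ann_forward(w, X)
  e <- as.vector(fwd$Yhat - Y)
  n_par <- h * p + h + q * h + q
  J <- matrix(0, n * q, n_par)
  D <- 1 - fwd$A1^2 # tanh'
  for (o in seq_len(q)) {
    rows <- (o - 1) * n + seq_len(n)
    Mo <- sweep(D, 2, w$W2[o, ], `*`) # n x h
    # dW1: column (k-1)*h + j  <-  Mo[,j] * X[,k]
    J[rows, seq_len(h * p)] <-
      Mo[, rep(seq_len(h), p), drop = FALSE] * X[, rep(seq_len(p), each = h), drop = FALSE]
    J[rows, h * p + seq_len(h)] <- Mo # db1
    for (j in seq_len(h)) { # dW2[o,j]: vec index (j-1)*q + o
      J[rows, h * p + h + (j - 1) * q + o] <- fwd$A1[, j]
    }
    J[rows, h * p + h + q * h + o] <- 1 # db2
  }
  list(e = e, J = J, mse = mean(e^2))
}

#' Initialize a feed-forward network
#'
#' Architecture `n_inputs - n_hidden - n_outputs` with tanh ("tansig")
#' hidden activation and identity ("purelin") output. Weights are uniform
#' in \[-0.5, 0.5\] from the seed, with the input-layer weights further
#' scaled by `1/n_inputs`: hidden pre-activations of \[-1, 1\]-scaled
#' spectra then start small, so the initial network is close to linear and
#' the interpolation ripple its random nonlinear component would otherwise
#' leave behind after training is negligible regardless of how many
#' wavelengths feed the net.
#'
#' @param n_inputs,n_hidden,n_outputs Layer sizes (default hidden size 6).
#' @param seed Integer seed for weight initialization.
#' @return A list of class `ann_model` with weights, placeholder identity
#'   scalings and empty training record.
#' @export
ann_init <- function(n_inputs, n_hidden = 6, n_outputs = 2, seed = 1) {
  w <- withr::with_seed(seed, {
    list(W1 = matrix(stats::runif(n_hidden * n_inputs, -0.5, 0.5) / n_inputs,
                     n_hidden, n_inputs),
         b1 = stats::runif(n_hidden, -0.5, 0.5),
         W2 = matrix(stats::runif(n_outputs * n_hidden, -0.5, 0.5), n_outputs, n_hidden),
         b2 = stats::runif(n_outputs, -0.5, 0.5))
  })
  structure(
    list(layer_sizes = c(n_inputs, n_hidden, n_outputs),
         W1 = w$W1, b1 = w$b1, W2 = w$W2, b2 = w$b2,
         x_scaling = NULL, y_scaling = NULL,
         component_names = NULL, grid = NULL,
         record = NULL, partition = NULL, seed = seed),
    class = "ann_model"
  )
}

#' Levenberg-Marquardt training on scaled data
#'
#' One epoch = one accepted LM step `(J'J + mu I) delta = J'e`. The damping
#' `mu` is divided by 10 on an accepted step and multiplied by 10 on a
#' rejected one (retrying within the epoch); training stops at `epochs`
#' accepted steps, at `goal` MSE, or when `mu` overflows `mu_max`. Accepted
#' steps strictly decrease the training MSE.
#'
#' @param model An [ann_init()] model.
#' @param x_scaled,y_scaled Training blocks already scaled to \[-1, 1\].
#' @param epochs Maximum accepted steps (>= 0). Default 500.
#' @param goal Target MSE; 0 disables.
#' @param mu_init,mu_max Initial and overflow damping values.
#' @return The model with updated weights and a `record` tibble
#'   (`epoch`, `mse`, `mu`).
#' @export
train_lm <- function(model, x_scaled, y_scaled, epochs = 500, goal = 0,
                     mu_init = 1e-3, mu_max = 1e10) {
  stopifnot(inherits(model, "ann_model"))
  X <- as.matrix(x_scaled); Y <- as.matrix(y_scaled)
  p <- model$layer_sizes[1]; h <- model$layer_sizes[2]; q <- model$layer_sizes[3]
  stopifnot(ncol(X) == p, ncol(Y) == q, nrow(X) == nrow(Y))
  w <- model[c("W1", "b1", "W2", "b2")]
  theta <- pack_theta(w$W1, w$b1, w$W2, w$b2)
  mu <- mu_init
  rec <- list(tibble::tibble(epoch = 0L, mse = mean((ann_forward(w, X)$Yhat - Y)^2),
                             mu = mu))
  epoch <- 0L
  while (epoch < epochs) {
    jac <- ann_jacobian(w, X, Y)
    if (!all(is.finite(jac$J))) stop("non-finite Jacobian during LM training")
    if (jac$mse <= goal) break
    g <- crossprod(jac$J, jac$e)
    JtJ <- crossprod(jac$J)
    accepted <- FALSE
    while (!accepted && mu <= mu_max) {
      delta <- tryCatch(solve(JtJ + diag(mu, ncol(JtJ)), g),
                        error = function(e) NULL)
      if (!is.null(delta)) {
        theta_try <- theta - as.vector(delta)
        w_try <- unpack_theta(theta_try, p, h, q)
        mse_try <- mean((ann_forward(w_try, X)$Yhat - Y)^2)
        if (is.finite(mse_try) && mse_try < jac$mse) {
          theta <- theta_try; w <- w_try
          mu <- max(mu / 10, 1e-20)
          accepted <- TRUE
          break
        }
      }
      mu <- mu * 10
    }
    if (!accepted) break # mu overflow: converged as far as LM can go
    epoch <- epoch + 1L
    rec[[length(rec) + 1]] <- tibble::tibble(epoch = epoch,
                                             mse = mean((ann_forward(w, X)$Yhat - Y)^2),
                                             mu = mu)
    if (rec[[length(rec)]]$mse <= goal) break
  }
  model$W1 <- w$W1; model$b1 <- w$b1; model$W2 <- w$W2; model$b2 <- w$b2
  model$record <- dplyr::bind_rows(rec)
  model
}

#' Fit the feed-forward calibration network
#'
#' High-level wrapper: partitions the samples 70/15/15 by seed, fits the
#' min-max \[-1, 1\] scalings on the training partition, initializes weights
#' from the seed, trains with [train_lm()] on the training partition and
#' records validation/test MSE. Early stopping is off by default (a fixed
#' epoch budget is used); pass `early_stop = TRUE` to stop when validation
#' MSE fails to improve for `patience` accepted steps.
#'
#' By default the fit is a small committee: `n_restarts` networks trained
#' from different (seed-derived) initializations on the same partition, and
#' predictions averaged over the members. Interpolating networks carry an
#' initialization-dependent ripple between training points; averaging a few
#' members cancels most of it, which matters for a heavily
#' over-parameterized net trained on a couple of dozen mixtures.
#' `n_restarts = 1` gives the classical single network.
#'
#' @inheritParams fit_pls
#' @param n_hidden Hidden-layer size. Default 6.
#' @param epochs Maximum accepted LM steps. Default 500.
#' @param goal Target training MSE on the scaled data.
#' @param seed Integer seed (partition + weight init).
#' @param partition Logical; FALSE trains on all samples (no hold-out).
#' @param early_stop Enable patience-based early stopping on validation MSE.
#' @param patience Accepted steps without validation improvement tolerated.
#' @param n_restarts Committee size (>= 1). Default 3.
#' @return An `ann_model` with trained weights (the member with the lowest
#'   training MSE), the full `members` list used for prediction averaging,
#'   scalings, `record`, `partition`, and per-set MSE in `set_mse`.
#' @export
fit_ann <- function(x, y, n_hidden = 6, epochs = 500, goal = 1e-10, seed = 1,
                    partition = TRUE, early_stop = FALSE, patience = 25,
                    n_restarts = 3) {
  X <- x_matrix(x)
  Y <- y_matrix(y)
  n <- nrow(X)
  if (n_restarts < 1) stop("`n_restarts` must be >= 1")
  part <- if (partition) partition_70_15_15(n, seed) else
    list(train = seq_len(n), val = integer(0), test = integer(0))
  xs <- minmax_fit(X[part$train, , drop = FALSE])
  ys <- minmax_fit(Y[part$train, , drop = FALSE])
  Xs <- minmax_apply(X, xs); Ys <- minmax_apply(Y, ys)
  train_one <- function(init_seed) {
    model <- ann_init(ncol(X), n_hidden, ncol(Y), seed = init_seed)
    model$x_scaling <- xs; model$y_scaling <- ys
    if (early_stop && length(part$val) > 0) {
      best_val <- Inf; wait <- 0; done <- 0
      chunk <- 10L
      while (done < epochs && wait < patience) {
        model <- train_lm(model, Xs[part$train, , drop = FALSE],
                          Ys[part$train, , drop = FALSE],
                          epochs = min(chunk, epochs - done), goal = goal)
        steps <- max(model$record$epoch)
        if (steps == 0) break
        done <- done + steps
        w <- model[c("W1", "b1", "W2", "b2")]
        val_mse <- mean((ann_forward(w, Xs[part$val, , drop = FALSE])$Yhat -
                           Ys[part$val, , drop = FALSE])^2)
        if (val_mse < best_val - 1e-15) { best_val <- val_mse; wait <- 0 } else {
          wait <- wait + steps
        }
      }
      model
    } else {
      train_lm(model, Xs[part$train, , drop = FALSE],
               Ys[part$train, , drop = FALSE], epochs = epochs, goal = goal)
    }
  }
  members <- lapply(seq_len(n_restarts), function(k) {
    train_one(seed + (k - 1) * 7919) # distinct derived init seeds
  })
  best <- members[[which.min(vapply(members, function(m) min(m$record$mse), numeric(1)))]]
  model <- best
  model$members <- lapply(members, function(m) m[c("W1", "b1", "W2", "b2")])
  model$component_names <- if (is.null(colnames(Y))) paste0("y", seq_len(ncol(Y))) else colnames(Y)
  model$grid <- if (inherits(x, "spectral_matrix")) x$grid else NULL
  model$partition <- part
  committee <- function(Xblock) {
    Reduce(`+`, lapply(model$members, function(w) ann_forward(w, Xblock)$Yhat)) /
      length(model$members)
  }
  model$set_mse <- purrr::map_dbl(part, function(idx) {
    if (length(idx) == 0) return(NA_real_)
    mean((committee(Xs[idx, , drop = FALSE]) - Ys[idx, , drop = FALSE])^2)
  })
  model
}

#' @export
print.ann_model <- function(x, ...) {
  cat(sprintf("<ann_model> %s net (tanh/linear)%s\n",
              paste(x$layer_sizes, collapse = "-"),
              if (!is.null(x$record)) sprintf(", %d accepted LM steps, train MSE %.3g",
                                              max(x$record$epoch), min(x$record$mse))
              else " (untrained)"))
  invisible(x)
}

#' Predict concentrations from the network
#'
#' `yhat = unscale(W2 tanh(W1 scale(x) + b1) + b2)`; deterministic.
#'
#' @param object A trained [fit_ann()] model.
#' @param newdata A [spectral_matrix()] or matrix with matching width.
#' @param ... Unused.
#' @return A concentration tibble.
#' @export
predict.ann_model <- function(object, newdata, ...) {
  X <- x_matrix(newdata)
  if (ncol(X) != object$layer_sizes[1]) {
    stop("new data width ", ncol(X), " does not match the input layer (",
         object$layer_sizes[1], ")")
  }
  if (is.null(object$x_scaling)) stop("model has no fitted scalings")
  Xs <- minmax_apply(X, object$x_scaling)
  members <- if (!is.null(object$members)) object$members else
    list(object[c("W1", "b1", "W2", "b2")])
  Yh_s <- Reduce(`+`, lapply(members, function(w) ann_forward(w, Xs)$Yhat)) /
    length(members)
  Yh <- minmax_invert(Yh_s, object$y_scaling)
  ids <- if (inherits(newdata, "spectral_matrix")) newdata$sample_ids else
    paste0("s", seq_len(nrow(X)))
  conc_from_matrix(Yh, ids, object$component_names)
}

#' Hidden-neuron sweep
#'
#' Re-fits the network across hidden-layer sizes and reports validation MSE
#' (scaled units), reproducing the model-size selection procedure on any
#' data set.
#'
#' @inheritParams fit_ann
#' @param sizes Hidden sizes to try. Default `2:10`.
#' @param ... Further arguments passed to [fit_ann()].
#' @return A tibble with `n_hidden`, `train_mse`, `val_mse`, `test_mse`.
#' @export
hidden_sweep <- function(x, y, sizes = 2:10, epochs = 100, seed = 1, ...) {
  purrr::map_dfr(sizes, function(h) {
    m <- fit_ann(x, y, n_hidden = h, epochs = epochs, seed = seed, ...)
    tibble::tibble(n_hidden = h,
                   train_mse = m$set_mse[["train"]],
                   val_mse = m$set_mse[["val"]],
                   test_mse = m$set_mse[["test"]])
  })
}

#' @rdname tidy.ann_model
#' @export
glance.ann_model <- function(x, ...) {
  tibble::tibble(n_inputs = x$layer_sizes[1], n_hidden = x$layer_sizes[2],
                 n_outputs = x$layer_sizes[3],
                 epochs = if (is.null(x$record)) 0L else max(x$record$epoch),
                 train_mse = if (is.null(x$record)) NA_real_ else min(x$record$mse))
}

#' Tidy the ANN training record
#' @param x A trained `ann_model`.
#' @param ... Unused.
#' @return `tidy()`: the epoch-wise `record` tibble; `glance()`: a one-row
#'   architecture/fit summary.
#' @export
tidy.ann_model <- function(x, ...) {
  if (is.null(x$record)) stop("model is untrained")
  x$record
}
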