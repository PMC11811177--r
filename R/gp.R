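# Gaussian-process regression surrogate.
#
# Matern 5/2 kernel with unit signal variance and one length-scale per
# input dimension, inputs rescaled to the unit box, observation jitter
# `noise_alpha` on the diagonal. Hyperparameters (log length-scales) are
# chosen by maximizing the log marginal likelihood with L-BFGS-B, restarted
# from random log-uniform initializations. Targets are optionally centered
# and scaled (normalize_y); predictions are mapped back to the original
# scale. Exact duplicate inputs are merged by averaging their targets so
# the Cholesky factorization stays well-posed at small jitter.

#' Gaussian-process configuration
#'
#' @param noise_alpha Observation noise variance added to the kernel
#'   diagonal (default `1e-6`).
#' @param normalize_y Center/scale targets internally (default `TRUE`).
#' @param n_restarts Random restarts of the kernel-hyperparameter optimizer
#'   (default 5).
#' @param length_scale Initial (or fixed) per-dimension length-scales on the
#'   unit-box scale.
#' @param length_scale_bounds Log-uniform search interval for each
#'   length-scale (default `[1e-2, 1e3]`).
#' @param optimize_hyperparams If `FALSE`, `length_scale` is used as-is
#'   (needed for closed-form verification).
#' @return An object of class `gp_config`.
#' @export
gp_config <- function(noise_alpha = 1e-6, normalize_y = TRUE, n_restarts = 5L,
                      length_scale = 1, length_scale_bounds = c(1e-2, 1e3),
                      optimize_hyperparams = TRUE) {
  if (noise_alpha <= 0)
    stop_input("noise_alpha must be > 0", class = "boclahe_argument_error")
  if (n_restarts < 1L)
    stop_input("n_restarts must be >= 1", class = "boclahe_argument_error")
  structure(list(noise_alpha = noise_alpha, normalize_y = isTRUE(normalize_y),
                 n_restarts = as.integer(n_restarts),
                 length_scale = length_scale,
                 length_scale_bounds = length_scale_bounds,
                 optimize_hyperparams = isTRUE(optimize_hyperparams)),
            class = "gp_config")
}

# Matern 5/2 kernel matrix between scaled input matrices A (n x d), B (m x d).
matern52 <- function(A, B, ls) {
  d2 <- matrix(0, nrow(A), nrow(B))
  for (j in seq_len(ncol(A)))
    d2 <- d2 + outer(A[, j] / ls[j], B[, j] / ls[j], `-`)^2
  r <- sqrt(pmax(d2, 0)) * sqrt(5)
  (1 + r + r^2 / 3) * exp(-r)
}

gp_lml <- function(Xs, y, ls, alpha) {
  n <- length(y)
  K <- matern52(Xs, Xs, ls)
  diag(K) <- diag(K) + alpha
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(-Inf)
  a <- backsolve(L, backsolve(L, y, transpose = TRUE))
  -0.5 * sum(y * a) - sum(log(diag(L))) - n / 2 * log(2 * pi)
}

#' Fit a Gaussian-process surrogate
#'
#' @param X Numeric matrix of input points (rows) on the original scale,
#'   or a vector for 1D problems.
#' @param y Numeric vector of targets.
#' @param cfg A [gp_config()].
#' @param bounds Optional 2-row matrix (`rbind(lower, upper)`) or list of
#'   `c(lower, upper)` per dimension used to rescale inputs to the unit
#'   box; defaults to the data range.
#' @param seed Seed for the restart initializations (default 1).
#' @return An object of class `gp_model`.
#' @export
gp_fit <- function(X, y, cfg = gp_config(), bounds = NULL, seed = 1L) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1L)
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y) || nrow(X) < 1L)
    stop_input("X and y sizes must match, with at least one point",
               class = "boclahe_argument_error")
  if (anyNA(X) || anyNA(y) || !all(is.finite(y)))
    stop_input("NaN/NA in training data", class = "boclahe_argument_error")

  if (is.null(bounds)) {
    lo <- apply(X, 2L, min); hi <- apply(X, 2L, max)
  } else {
    b <- if (is.list(bounds)) do.call(cbind, bounds) else as.matrix(bounds)
    lo <- b[1L, ]; hi <- b[2L, ]
  }
  span <- ifelse(hi - lo > 0, hi - lo, 1)

  # merge exact duplicate rows by averaging targets
  key <- apply(X, 1L, paste, collapse = "\r")
  if (anyDuplicated(key)) {
    y <- as.numeric(tapply(y, key, mean)[unique(key)])
    X <- X[!duplicated(key), , drop = FALSE]
  }
  Xs <- sweep(sweep(X, 2L, lo), 2L, span, "/")

  y_mean <- 0; y_sd <- 1
  if (cfg$normalize_y) {
    y_mean <- mean(y)
    s <- stats::sd(y)
    if (length(y) > 1L && is.finite(s) && s > 0) y_sd <- s  # constant targets: center only
  }
  yn <- (y - y_mean) / y_sd

  d <- ncol(X)
  ls0 <- rep_len(cfg$length_scale, d)
  if (cfg$optimize_hyperparams && nrow(Xs) > 1L) {
    lb <- log(cfg$length_scale_bounds[1L]); ub <- log(cfg$length_scale_bounds[2L])
    neg <- function(th) -gp_lml(Xs, yn, exp(th), cfg$noise_alpha)
    starts <- with_seed(seed, c(
      list(log(clamp(ls0, exp(lb), exp(ub)))),
      lapply(seq_len(cfg$n_restarts), function(i)
        stats::runif(d, lb, ub))))
    best <- NULL
    for (th0 in starts) {
      fit <- tryCatch(
        stats::optim(th0, neg, method = "L-BFGS-B", lower = lb, upper = ub),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
    }
    ls <- if (is.null(best)) ls0 else exp(best$par)
  } else {
    ls <- ls0
  }

  K <- matern52(Xs, Xs, ls)
  diag(K) <- diag(K) + cfg$noise_alpha
  L <- chol(K)
  alpha_vec <- backsolve(L, backsolve(L, yn, transpose = TRUE))
  structure(list(Xs = Xs, X = X, y = y, yn = yn, chol = L,
                 alpha_vec = alpha_vec, length_scale = ls,
                 y_mean = y_mean, y_sd = y_sd,
                 lo = lo, span = span, cfg = cfg),
            class = "gp_model")
}

#' Posterior mean and standard deviation of a fitted GP
#'
#' @param model A [gp_fit()] result.
#' @param x A single point (vector) or matrix of points on the original
#'   scale.
#' @return A list with numeric vectors `mean` and `sd` (`sd >= 0`).
#' @export
gp_predict <- function(model, x) {
  if (!inherits(model, "gp_model"))
    stop_input("model is not a fitted gp_model", class = "boclahe_state_error")
  if (is.null(dim(x))) x <- matrix(x, ncol = ncol(model$Xs), byrow = TRUE)
  xs <- sweep(sweep(as.matrix(x), 2L, model$lo), 2L, model$span, "/")
  Kst <- matern52(xs, model$Xs, model$length_scale)
  mu <- as.numeric(Kst %*% model$alpha_vec)
  v <- backsolve(model$chol, t(Kst), transpose = TRUE)
  var <- pmax(1 + model$cfg$noise_alpha - colSums(v^2), 0)
  list(mean = mu * model$y_sd + model$y_mean,
       sd = sqrt(var) * model$y_sd)
}
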