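# Acquisition functions and the inner acquisition maximizer.

#' Acquisition specification
#'
#' @param kind `"ucb"` (upper confidence bound, the default) or `"ei"`
#'   (expected improvement).
#' @param kappa UCB exploration constant (default 2.576).
#' @param xi EI exploration margin (default 0.01).
#' @return An object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(kind = c("ucb", "ei"), kappa = 2.576, xi = 0.01) {
  kind <- match.arg(kind)
  if (kappa <= 0) stop_input("kappa must be > 0", class = "boclahe_argument_error")
  if (xi < 0) stop_input("xi must be >= 0", class = "boclahe_argument_error")
  structure(list(kind = kind, kappa = kappa, xi = xi),
            class = "acquisition_spec")
}

#' Acquisition value at a posterior (mean, sd)
#'
#' UCB: `mean + kappa * sd`. EI: `(mean - best - xi) * pnorm(z) +
#' sd * dnorm(z)` with `z = (mean - best - xi) / sd`, and 0 where `sd = 0`.
#' Vectorized over `mean`/`sd`.
#'
#' @param mean,sd Posterior mean(s) and standard deviation(s) (`sd >= 0`).
#' @param spec An [acquisition_spec()].
#' @param best_so_far Incumbent best objective value (EI only).
#' @return Numeric vector of acquisition values.
#' @export
acquisition_value <- function(mean, sd, spec = acquisition_spec(),
                              best_so_far = -Inf) {
  if (any(sd < 0))
    stop_input("sd must be >= 0", class = "boclahe_argument_error")
  if (spec$kind == "ucb") return(mean + spec$kappa * sd)
  imp <- mean - best_so_far - spec$xi
  out <- numeric(length(mean))
  pos <- sd > 0
  z <- imp[pos] / sd[pos]
  out[pos] <- imp[pos] * stats::pnorm(z) + sd[pos] * stats::dnorm(z)
  out
}

#' Propose the next point to evaluate
#'
#' Maximizes the acquisition over the box by scoring 1,000 seeded uniform
#' random candidates, then running bounded local refinement (L-BFGS-B) from
#' the best 5; deterministic given `seed`.
#'
#' @param model A fitted [gp_fit()] model.
#' @param bounds List of `c(lower, upper)` per dimension (or 2-row matrix).
#' @param spec An [acquisition_spec()].
#' @param seed Integer seed for the candidate draw.
#' @param n_candidates Number of random candidates (default 1000).
#' @return Numeric vector (one value per dimension), inside the bounds.
#' @export
suggest_next <- function(model, bounds, spec = acquisition_spec(), seed = 1L,
                         n_candidates = 1000L) {
  b <- if (is.list(bounds)) do.call(cbind, bounds) else as.matrix(bounds)
  lo <- b[1L, ]; hi <- b[2L, ]
  d <- length(lo)
  best_y <- max(model$y)
  acq <- function(x) {
    p <- gp_predict(model, x)
    acquisition_value(p$mean, p$sd, spec, best_y)
  }
  cand <- with_seed(seed, matrix(stats::runif(n_candidates * d, rep(lo, each = n_candidates),
                                              rep(hi, each = n_candidates)),
                                 n_candidates, d))
  vals <- acq(cand)
  top <- order(vals, decreasing = TRUE)[seq_len(min(5L, n_candidates))]
  best_x <- cand[top[1L], ]
  best_v <- vals[top[1L]]
  for (i in top) {
    fit <- tryCatch(
      stats::optim(cand[i, ], function(x) -acq(matrix(x, 1L)),
                   method = "L-BFGS-B", lower = lo, upper = hi),
      error = function(e) NULL)
    if (!is.null(fit) && -fit$value > best_v) {
      best_v <- -fit$value
      best_x <- fit$par
    }
  }
  clamp(best_x, lo, hi)
}
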