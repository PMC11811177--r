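# Sequential Bayesian optimization loop: seeded random initialization,
# then fit-GP / maximize-acquisition / evaluate rounds. All randomness is
# derived from one seed, so a full run is reproducible bit-for-bit.

#' Search-space bounds for the CLAHE parameters
#'
#' Defaults are the standard search box: clip limit in `[1, 255]`, tile
#' grid in `[8, 32]`.
#'
#' @param clip_limit Length-2 numeric `c(lower, upper)`.
#' @param tile_grid Length-2 numeric `c(lower, upper)`.
#' @return Named list of intervals, class `bo_bounds`.
#' @export
default_bounds <- function(clip_limit = c(1, 255), tile_grid = c(8, 32)) {
  for (b in list(clip_limit, tile_grid))
    if (length(b) != 2L || b[1L] >= b[2L])
      stop_input("each bound must be c(lower, upper) with lower < upper",
                 class = "boclahe_argument_error")
  structure(list(clip_limit = as.numeric(clip_limit),
                 tile_grid = as.numeric(tile_grid)),
            class = "bo_bounds")
}

#' Optimization settings
#'
#' Defaults mirror the standard run configuration: 25 random initial
#' samples followed by 25 Bayesian-optimization iterations, UCB
#' acquisition with kappa 2.576 (EI with xi 0.01 available by flag).
#'
#' @param init_points Random evaluations before the GP loop (>= 1).
#' @param n_iter Bayesian-optimization rounds (>= 0).
#' @param seed Master seed for the whole run.
#' @param acquisition An [acquisition_spec()].
#' @return An object of class `opt_settings`.
#' @export
opt_settings <- function(init_points = 25L, n_iter = 25L, seed = 1L,
                         acquisition = acquisition_spec()) {
  if (init_points < 1L)
    stop_input("init_points must be >= 1", class = "boclahe_argument_error")
  if (n_iter < 0L)
    stop_input("n_iter must be >= 0", class = "boclahe_argument_error")
  structure(list(init_points = as.integer(init_points),
                 n_iter = as.integer(n_iter), seed = as.integer(seed),
                 acquisition = acquisition),
            class = "opt_settings")
}

#' Run Bayesian optimization of a black-box objective over a box
#'
#' `init_points` seeded uniform-random evaluations, then `n_iter` rounds of
#' (fit GP on all data, maximize acquisition, evaluate). If the objective
#' raises an error, the run aborts with a condition of class
#' `boclahe_eval_error` whose `trace` field preserves the partial trace.
#'
#' @param eval_fn Function taking a named numeric vector of parameters and
#'   returning a scalar objective (larger = better).
#' @param bounds A [default_bounds()]-style named list of `c(lower, upper)`.
#' @param settings An [opt_settings()].
#' @param gp_cfg A [gp_config()].
#' @return An object of class `bo_trace`: data frame `trace` (iteration,
#'   phase, one column per parameter, value), `best_params`, `best_value`.
#' @export
bo_optimize <- function(eval_fn, bounds = default_bounds(),
                        settings = opt_settings(), gp_cfg = gp_config()) {
  b <- do.call(cbind, lapply(bounds, as.numeric))
  pnames <- names(bounds)
  lo <- b[1L, ]; hi <- b[2L, ]
  d <- length(lo)
  n_total <- settings$init_points + settings$n_iter

  X <- matrix(NA_real_, n_total, d, dimnames = list(NULL, pnames))
  y <- rep(NA_real_, n_total)
  phase <- rep(c("init", "bo"), c(settings$init_points, settings$n_iter))

  evaluate <- function(i, x) {
    names(x) <- pnames
    X[i, ] <<- x
    val <- tryCatch(as.numeric(eval_fn(x)), error = function(e) {
      stop(errorCondition(
        paste0("objective evaluation failed at iteration ", i, ": ",
               conditionMessage(e)),
        trace = build_trace(X[seq_len(i - 1L), , drop = FALSE],
                            y[seq_len(i - 1L)], phase[seq_len(i - 1L)]),
        class = c("boclahe_eval_error", "boclahe_error", "error", "condition")))
    })
    y[i] <<- val
  }

  init <- with_seed(derive_seed(settings$seed, 0L),
                    matrix(stats::runif(settings$init_points * d,
                                        rep(lo, each = settings$init_points),
                                        rep(hi, each = settings$init_points)),
                           settings$init_points, d))
  for (i in seq_len(settings$init_points)) evaluate(i, init[i, ])

  for (t in seq_len(settings$n_iter)) {
    i <- settings$init_points + t
    model <- gp_fit(X[seq_len(i - 1L), , drop = FALSE], y[seq_len(i - 1L)],
                    gp_cfg, bounds = b,
                    seed = derive_seed(settings$seed, 100L + t))
    x_next <- suggest_next(model, b, settings$acquisition,
                           seed = derive_seed(settings$seed, 200L + t))
    evaluate(i, x_next)
  }

  build_trace(X, y, phase)
}

build_trace <- function(X, y, phase) {
  tr <- data.frame(iteration = seq_along(y), phase = phase,
                   X, value = y, check.names = FALSE)
  best_i <- if (length(y)) which.max(y) else NA_integer_
  structure(list(trace = tr,
                 best_params = if (length(y)) X[best_i, ] else NULL,
                 best_value = if (length(y)) y[best_i] else NA_real_),
            class = "bo_trace")
}

#' @export
print.bo_trace <- function(x, ...) {
  cat(sprintf("Bayesian-optimization trace: %d evaluations (%d init + %d bo)\n",
              nrow(x$trace), sum(x$trace$phase == "init"),
              sum(x$trace$phase == "bo")))
  cat("best value:", format(x$best_value), "at",
      paste(sprintf("%s = %.4f", names(x$best_params), x$best_params),
            collapse = ", "), "\n")
  invisible(x)
}
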