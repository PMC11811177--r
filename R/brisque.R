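# No-reference BRISQUE-style quality pipeline.
#
# Stage 1: MSCN (mean-subtracted contrast-normalized) coefficients —
# locally normalized luminance using 7x7 Gaussian local statistics.
# Stage 2: 36 natural-scene-statistics features — per scale (original and
# 2x box-downsampled): a symmetric generalized Gaussian (GGD) fit of the
# MSCN field (shape, variance) plus asymmetric generalized Gaussian (AGGD)
# fits of the four pairwise-product fields (horizontal, vertical, and both
# diagonals), each contributing (shape, mean, left variance, right
# variance). Fits use the standard moment-matching estimator with the
# generalized-Gaussian ratio function tabulated over shape in [0.2, 10].
# Stage 3: instead of the original trained support-vector regressor (whose
# weights are unavailable), the score is a Mahalanobis distance to
# reference feature statistics; the packaged default statistics come from a
# pristine synthetic phantom corpus. Lower = better, 0 = at the reference.

# --- generalized-Gaussian ratio table -------------------------------------

# rho(a) = Gamma(2/a)^2 / (Gamma(1/a) Gamma(3/a)), precomputed on a dense
# shape grid; moment-matching inverts it by nearest lookup.
ggd_ratio_grid <- local({
  gam <- seq(0.2, 10, by = 0.001)
  list(gam = gam,
       rho = exp(2 * lgamma(2 / gam) - lgamma(1 / gam) - lgamma(3 / gam)))
})

ggd_shape_from_ratio <- function(r) {
  ggd_ratio_grid$gam[which.min((ggd_ratio_grid$rho - r)^2)]
}

# --- MSCN ------------------------------------------------------------------

#' Mean-subtracted contrast-normalized coefficients
#'
#' `(pixel - local mean) / (local sd + 1)` with local statistics from a 7x7
#' Gaussian window (sigma = 7/6), symmetric border padding; the stabilizer 1
#' is on the 0-255 intensity scale.
#'
#' @param image Numeric matrix, intensities in 0-255, at least 7x7.
#' @return Numeric matrix of the same shape.
#' @export
mscn <- function(image) {
  assert_gray_image(image)
  if (nrow(image) < 7L || ncol(image) < 7L)
    stop_input("image must be at least 7x7", class = "boclahe_size_error")
  x <- matrix(as.numeric(image), nrow(image))
  k <- gaussian_kernel_1d(7L, 7 / 6)
  mu <- conv2_sep(x, k, "same")
  sd_loc <- sqrt(pmax(conv2_sep(x * x, k, "same") - mu^2, 0))
  (x - mu) / (sd_loc + 1)
}

# --- GGD / AGGD fitting ----------------------------------------------------

# Symmetric GGD moment-matching fit: shape and variance.
fit_ggd <- function(samples) {
  v <- mean(samples^2)
  if (v == 0)
    stop_input("zero-variance input", class = "boclahe_degenerate_error")
  r <- mean(abs(samples))^2 / v
  list(shape = ggd_shape_from_ratio(r), variance = v)
}

#' Fit an asymmetric generalized Gaussian by moment matching
#'
#' Left/right second moments and the mean absolute deviation are inverted
#' through the tabulated generalized-Gaussian ratio function (shape grid
#' `[0.2, 10]`).
#'
#' @param samples Numeric vector, at least 100 values with nonzero variance.
#' @return An object of class `aggd_params`: `shape`, `scale_left`,
#'   `scale_right` (GGD scale parameters), `mean_offset` (the distribution
#'   mean implied by the asymmetry), plus `var_left`/`var_right` (the left
#'   and right second moments used as BRISQUE features).
#' @export
fit_aggd <- function(samples) {
  samples <- as.numeric(samples)
  if (length(samples) < 100L)
    stop_input("need at least 100 samples", class = "boclahe_argument_error")
  if (stats::var(samples) == 0 || all(samples == 0))
    stop_input("zero-variance input", class = "boclahe_degenerate_error")
  left <- samples[samples < 0]
  right <- samples[samples >= 0]
  sigma_l <- sqrt(if (length(left)) mean(left^2) else 0)
  sigma_r <- sqrt(if (length(right)) mean(right^2) else 0)
  # one-sided degenerate case: fall back to tiny opposite mass
  eps <- 1e-12
  sigma_l <- max(sigma_l, eps); sigma_r <- max(sigma_r, eps)
  gamma_hat <- sigma_l / sigma_r
  r_hat <- mean(abs(samples))^2 / mean(samples^2)
  R_hat <- r_hat * (gamma_hat^3 + 1) * (gamma_hat + 1) / (gamma_hat^2 + 1)^2
  a <- ggd_shape_from_ratio(R_hat)
  conv <- sqrt(gamma(1 / a) / gamma(3 / a))
  bl <- sigma_l * conv
  br <- sigma_r * conv
  structure(list(shape = a, scale_left = bl, scale_right = br,
                 mean_offset = (br - bl) * gamma(2 / a) / gamma(1 / a),
                 var_left = sigma_l^2, var_right = sigma_r^2),
            class = "aggd_params")
}

# --- features --------------------------------------------------------------

aggd_feature_block <- function(field) {
  h <- field[, -ncol(field)] * field[, -1L]                       # horizontal
  v <- field[-nrow(field), ] * field[-1L, ]                       # vertical
  d1 <- field[-nrow(field), -ncol(field)] * field[-1L, -1L]       # down-right
  d2 <- field[-nrow(field), -1L] * field[-1L, -ncol(field)]       # down-left
  unlist(lapply(list(h, v, d1, d2), function(p) {
    f <- fit_aggd(as.numeric(p))
    c(f$shape, f$mean_offset, f$var_left, f$var_right)
  }))
}

scale_features <- function(image) {
  field <- mscn(image)
  g <- fit_ggd(as.numeric(field))
  c(g$shape, g$variance, aggd_feature_block(field))
}

#' BRISQUE feature vector (36 values)
#'
#' Two scales: the original image and its 2x box-downsampled version; each
#' contributes 2 MSCN GGD features and 4x4 pairwise-product AGGD features.
#'
#' @param image Numeric matrix, intensities in 0-255, at least 32x32.
#' @return Numeric vector of exactly 36 finite values.
#' @export
brisque_features <- function(image) {
  assert_gray_image(image)
  if (nrow(image) < 32L || ncol(image) < 32L)
    stop_input("image must be at least 32x32", class = "boclahe_size_error")
  x <- matrix(as.numeric(image), nrow(image))
  f <- tryCatch(
    c(scale_features(x), scale_features(box_downsample2(x))),
    boclahe_degenerate_error = function(e) NULL)
  if (is.null(f)) {
    # perfectly flat image: all MSCN mass at 0; report the degenerate
    # shape/variance pattern instead of failing, stabilizers keep it finite
    f <- rep(c(10, 0), 18L)
  }
  stopifnot(length(f) == 36L, all(is.finite(f)))
  f
}

# --- quality model and score ----------------------------------------------

#' Construct a quality model from reference statistics
#'
#' @param mean Numeric vector of 36 reference feature means.
#' @param cov 36x36 positive-definite covariance of the reference features.
#' @return An object of class `quality_model`.
#' @export
quality_model <- function(mean, cov) {
  mean <- as.numeric(mean)
  cov <- as.matrix(cov)
  if (length(mean) != 36L || !all(dim(cov) == 36L))
    stop_input("model must have a 36-vector mean and 36x36 covariance",
               class = "boclahe_model_error")
  ch <- tryCatch(chol(cov), error = function(e) NULL)
  if (is.null(ch))
    stop_input("covariance is not positive definite",
               class = "boclahe_model_error")
  structure(list(mean = mean, cov = cov, chol = ch), class = "quality_model")
}

#' Build a quality model from a corpus of images
#'
#' Feature covariance is shrunk toward its diagonal
#' (`(1 - shrink) * S + shrink * diag(S)`) plus a small ridge so the model
#' stays positive definite with modest corpora.
#'
#' @param images List of grayscale matrices.
#' @param shrink Diagonal shrinkage weight in `[0, 1]`.
#' @param ridge Ridge added to the diagonal (relative to mean variance).
#' @return A [quality_model()].
#' @export
build_quality_model <- function(images, shrink = 0.3, ridge = 1e-4) {
  feats <- t(vapply(images, brisque_features, numeric(36L)))
  mu <- colMeans(feats)
  S <- stats::cov(feats)
  S <- (1 - shrink) * S + shrink * diag(diag(S))
  diag(S) <- diag(S) + ridge * mean(diag(S)) + 1e-12
  quality_model(mu, S)
}

#' Load a quality model from JSON
#'
#' @param path JSON file with fields `mean` (36 numbers) and `cov`
#'   (36x36 numbers).
#' @return A [quality_model()].
#' @export
read_quality_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  quality_model(obj$mean, obj$cov)
}

#' Write a quality model to JSON
#' @param model A [quality_model()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_quality_model <- function(model, path) {
  jsonlite::write_json(list(mean = model$mean, cov = model$cov), path,
                       digits = NA)
  invisible(path)
}

.boclahe_env <- new.env(parent = emptyenv())

#' Packaged default quality model
#'
#' Reference statistics of a pristine synthetic phantom corpus (60 phantoms
#' with varied geometry and mild noise), shipped with the package. The
#' corpus is synthetic: scores are distances to clean-phantom statistics,
#' not to the natural-image statistics of the original trained BRISQUE
#' model (see the methods vignette).
#'
#' @return A [quality_model()].
#' @export
default_quality_model <- function() {
  if (is.null(.boclahe_env$default_model)) {
    path <- system.file("extdata", "quality_model_synthetic.json",
                        package = "boclahe")
    if (path == "")
      stop_input("packaged quality model not found", class = "boclahe_model_error")
    .boclahe_env$default_model <- read_quality_model(path)
  }
  .boclahe_env$default_model
}

# The deterministic corpus behind the shipped default model; kept in code so
# the JSON under inst/extdata can always be regenerated.
default_model_corpus <- function() {
  specs <- list()
  set <- 0L
  for (fill in c(120, 140, 160)) for (bg in c(30, 45)) {
    for (k in 1:10) {
      set <- set + 1L
      specs[[set]] <- phantom_spec(background_level = bg, lung_fill = fill,
                                   rib_count = 4L + (k %% 3L),
                                   rib_amplitude = 10 + 2 * (k %% 2L),
                                   noise_sigma = 2, seed = 1000L + set)
    }
  }
  lapply(specs, function(s) generate_phantom(s)$image)
}

#' BRISQUE-style quality score
#'
#' Mahalanobis distance of a 36-feature vector to the model's reference
#' statistics; non-negative, 0 at the reference mean, lower = better.
#'
#' @param features A 36-vector from [brisque_features()], or an image
#'   matrix (features are computed first).
#' @param model A [quality_model()]; defaults to the packaged synthetic
#'   reference model.
#' @return Non-negative scalar.
#' @export
brisque_score <- function(features, model = default_quality_model()) {
  if (is.matrix(features)) features <- brisque_features(features)
  if (length(features) != 36L || !all(is.finite(features)))
    stop_input("features must be 36 finite values",
               class = "boclahe_argument_error")
  if (!inherits(model, "quality_model"))
    stop_input("model must be a quality_model", class = "boclahe_model_error")
  d <- features - model$mean
  z <- backsolve(model$chol, d, transpose = TRUE)
  sqrt(sum(z^2))
}
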