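# Internal numeric and RNG helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Deterministic half-up rounding. base::round() rounds half to even, which
# makes lookup tables depend on the platform's tie behaviour; every intensity
# rounding in the package goes through this helper instead.
round_half_up <- function(x) floor(x + 0.5)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Derive a child seed from a parent seed and a stream index. All randomness
# in the package flows from one user seed through this map; results stay
# below 2^31 so they are valid R integer seeds.
derive_seed <- function(seed, stream) {
  s <- (as.double(seed) %% 2147483647)
  as.integer((s * 48271 + as.double(stream) * 9973 + 1) %% 2147483647)
}

# Evaluate `expr` under a local RNG state: seeds, runs, then restores the
# caller's .Random.seed so library calls never perturb user randomness.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

stop_input <- function(..., class = "boclahe_error") {
  stop(errorCondition(paste0(...), class = c(class, "boclahe_error")))
}

assert_gray_image <- function(img, arg = "image") {
  if (!is.matrix(img) || !is.numeric(img))
    stop_input(arg, " must be a numeric matrix", class = "boclahe_argument_error")
  if (nrow(img) < 1L || ncol(img) < 1L)
    stop_input(arg, " must be non-empty", class = "boclahe_argument_error")
  if (anyNA(img) || any(img < 0) || any(img > 255))
    stop_input(arg, " must have values in [0, 255]", class = "boclahe_argument_error")
  invisible(TRUE)
}

assert_mask <- function(mask, img = NULL, arg = "mask") {
  if (!is.matrix(mask) || !is.logical(mask))
    stop_input(arg, " must be a logical matrix", class = "boclahe_argument_error")
  if (!is.null(img) && !identical(dim(mask), dim(img)))
    stop_input(arg, " dimensions must match the image",
               class = "boclahe_consistency_error")
  invisible(TRUE)
}

# Normalized 1D Gaussian kernel of odd length `size`.
gaussian_kernel_1d <- function(size, sigma) {
  stopifnot(size >= 1, size %% 2 == 1, sigma > 0)
  h <- (size - 1L) / 2L
  k <- exp(-((-h:h)^2) / (2 * sigma^2))
  k / sum(k)
}

# Separable 2D convolution with a 1D kernel applied along rows then columns.
# mode "valid" keeps only fully-covered windows; mode "same" pads by
# symmetric (edge-inclusive) reflection first.
conv2_sep <- function(x, kernel, mode = c("valid", "same")) {
  mode <- match.arg(mode)
  k <- length(kernel)
  h <- (k - 1L) %/% 2L
  if (mode == "same") x <- pad_symmetric(x, h)
  x <- conv_axis(x, kernel, 1L)
  conv_axis(x, kernel, 2L)
}

# Valid-mode convolution along one axis via shifted weighted sums.
conv_axis <- function(x, kernel, axis) {
  k <- length(kernel)
  if (axis == 1L) {
    n <- nrow(x)
    if (n < k) stop_input("image smaller than kernel", class = "boclahe_size_error")
    out <- kernel[1L] * x[1L:(n - k + 1L), , drop = FALSE]
    if (k > 1L) for (j in 2L:k)
      out <- out + kernel[j] * x[j:(n - k + j), , drop = FALSE]
    out
  } else {
    t(conv_axis(t(x), kernel, 1L))
  }
}

# Symmetric padding (MATLAB-style, border row/col included in reflection).
pad_symmetric <- function(x, h) {
  if (h == 0L) return(x)
  n <- nrow(x); m <- ncol(x)
  if (h > n || h > m)
    stop_input("image smaller than padding width", class = "boclahe_size_error")
  ri <- c(h:1, 1:n, n:(n - h + 1L))
  ci <- c(h:1, 1:m, m:(m - h + 1L))
  x[ri, ci, drop = FALSE]
}

# 2x box downsampling by averaging disjoint 2x2 blocks (odd trailing
# row/column dropped).
box_downsample2 <- function(x) {
  n <- 2L * (nrow(x) %/% 2L)
  m <- 2L * (ncol(x) %/% 2L)
  if (n < 2L || m < 2L)
    stop_input("image too small to downsample", class = "boclahe_size_error")
  x <- x[1:n, 1:m, drop = FALSE]
  (x[seq(1L, n, 2L), seq(1L, m, 2L)] + x[seq(2L, n, 2L), seq(1L, m, 2L)] +
     x[seq(1L, n, 2L), seq(2L, m, 2L)] + x[seq(2L, n, 2L), seq(2L, m, 2L)]) / 4
}

mask_bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  list(rows = range(idx[, 1L]), cols = range(idx[, 2L]))
}
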