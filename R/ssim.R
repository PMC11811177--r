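# Full-reference structural similarity (SSIM).
#
# SSIM(x, y) = mean over windows of l^alpha * c^beta * s^gamma, where the
# luminance (l), contrast (c) and structure (s) terms are computed from
# Gaussian-weighted local moments. Defaults are the universal ones:
# 11x11 Gaussian window with sigma 1.5, alpha = beta = gamma = 1,
# C1 = (K1 L)^2, C2 = (K2 L)^2, C3 = C2 / 2 with K1 = 0.01, K2 = 0.03,
# L = 255. Windows are "valid": only fully-covered positions contribute.

#' SSIM configuration
#'
#' @param alpha,beta,gamma Exponents of the luminance, contrast and
#'   structure terms (defaults 1). Non-integer exponents require the
#'   structure term to stay positive.
#' @param window Odd window side length (default 11).
#' @param sigma Gaussian window standard deviation in pixels (default 1.5).
#' @param K1,K2 Stabilization fractions of the dynamic range.
#' @param L Dynamic range of the intensities (255 for 8-bit).
#' @return An object of class `ssim_config`.
#' @export
ssim_config <- function(alpha = 1, beta = 1, gamma = 1,
                        window = 11L, sigma = 1.5,
                        K1 = 0.01, K2 = 0.03, L = 255) {
  if (alpha < 0 || beta < 0 || gamma < 0)
    stop_input("exponents must be >= 0", class = "boclahe_argument_error")
  if (window < 3L || window %% 2L == 0L)
    stop_input("window must be odd and >= 3", class = "boclahe_argument_error")
  if (K1 <= 0 || K2 <= 0 || L <= 0 || sigma <= 0)
    stop_input("constants must be > 0", class = "boclahe_argument_error")
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 window = as.integer(window), sigma = sigma,
                 C1 = (K1 * L)^2, C2 = (K2 * L)^2, C3 = (K2 * L)^2 / 2,
                 L = L),
            class = "ssim_config")
}

#' Structural similarity index between two images
#'
#' With a mask, both images are first cropped to the mask's tight bounding
#' box, so only windows fully inside that box contribute.
#'
#' @param x,y Numeric matrices of identical shape, intensities in 0-255.
#' @param cfg An [ssim_config()].
#' @param mask Optional logical matrix restricting the evaluation region.
#' @return An object of class `ssim_result`: `score` in `[-1, 1]` plus the
#'   mean `luminance`, `contrast` and `structure` terms.
#' @export
ssim <- function(x, y, cfg = ssim_config(), mask = NULL) {
  if (!identical(dim(x), dim(y)))
    stop_input("x and y must have identical shape",
               class = "boclahe_argument_error")
  assert_gray_image(x, "x")
  assert_gray_image(y, "y")
  if (!is.null(mask)) {
    assert_mask(mask, x)
    bb <- mask_bbox(mask)
    if (is.null(bb))
      stop_input("mask is empty", class = "boclahe_argument_error")
    x <- x[bb$rows[1L]:bb$rows[2L], bb$cols[1L]:bb$cols[2L], drop = FALSE]
    y <- y[bb$rows[1L]:bb$rows[2L], bb$cols[1L]:bb$cols[2L], drop = FALSE]
  }
  if (nrow(x) < cfg$window || ncol(x) < cfg$window)
    stop_input("image smaller than the SSIM window",
               class = "boclahe_size_error")
  x <- matrix(as.numeric(x), nrow(x)); y <- matrix(as.numeric(y), nrow(y))
  k <- gaussian_kernel_1d(cfg$window, cfg$sigma)

  mu_x <- conv2_sep(x, k, "valid")
  mu_y <- conv2_sep(y, k, "valid")
  sxx <- pmax(conv2_sep(x * x, k, "valid") - mu_x^2, 0)
  syy <- pmax(conv2_sep(y * y, k, "valid") - mu_y^2, 0)
  sxy <- conv2_sep(x * y, k, "valid") - mu_x * mu_y
  sx <- sqrt(sxx); sy <- sqrt(syy)

  l <- (2 * mu_x * mu_y + cfg$C1) / (mu_x^2 + mu_y^2 + cfg$C1)
  cterm <- (2 * sx * sy + cfg$C2) / (sxx + syy + cfg$C2)
  s <- (sxy + cfg$C3) / (sx * sy + cfg$C3)

  pw <- function(base, e) {
    if (e == 1) base
    else if (e == round(e)) base^e
    else sign(base) * abs(base)^e  # keeps odd symmetry for fractional e
  }
  score <- mean(pw(l, cfg$alpha) * pw(cterm, cfg$beta) * pw(s, cfg$gamma))
  structure(list(score = score,
                 luminance = mean(l), contrast = mean(cterm),
                 structure = mean(s)),
            class = "ssim_result")
}

#' @export
print.ssim_result <- function(x, ...) {
  cat(sprintf("SSIM %.6f (l %.4f, c %.4f, s %.4f)\n",
              x$score, x$luminance, x$contrast, x$structure))
  invisible(x)
}
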