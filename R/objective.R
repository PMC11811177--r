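# Scalar optimization objective: weighted combination of structural
# fidelity (SSIM against the pre-enhancement image, inside the mask) and
# standalone perceptual quality (BRISQUE-style distance of the enhanced
# region, rescaled by brisque_norm so both terms share a magnitude).
# Larger is better.

#' Objective configuration
#'
#' @param w_ssim Weight of the SSIM term (higher SSIM is better).
#' @param w_brisque Weight of the quality-distance penalty (lower distance
#'   is better, so it enters with a minus sign).
#' @param brisque_norm Positive scale constant dividing the raw quality
#'   distance to bring it to SSIM-like magnitude (default 100).
#' @param ssim Optional [ssim_config()].
#' @param quality_model Optional [quality_model()]; defaults to the packaged
#'   synthetic reference model.
#' @return An object of class `objective_config`.
#' @export
objective_config <- function(w_ssim = 1, w_brisque = 1, brisque_norm = 100,
                             ssim = ssim_config(), quality_model = NULL) {
  if (w_ssim < 0 || w_brisque < 0)
    stop_input("weights must be >= 0", class = "boclahe_argument_error")
  if (w_ssim == 0 && w_brisque == 0)
    stop_input("at least one weight must be > 0",
               class = "boclahe_argument_error")
  if (brisque_norm <= 0)
    stop_input("brisque_norm must be > 0", class = "boclahe_argument_error")
  structure(list(w_ssim = w_ssim, w_brisque = w_brisque,
                 brisque_norm = brisque_norm, ssim = ssim,
                 quality_model = quality_model),
            class = "objective_config")
}

#' Combined SSIM/BRISQUE enhancement objective
#'
#' `w_ssim * SSIM(original, enhanced, mask) -
#'  w_brisque * brisque_score(enhanced bounding-box region) / brisque_norm`.
#'
#' @param original,enhanced Numeric matrices of identical shape (0-255).
#' @param mask Logical matrix; SSIM and the quality score are evaluated on
#'   its tight bounding box.
#' @param cfg An [objective_config()].
#' @return A scalar (larger = better) with attribute `components`, a named
#'   vector holding the raw `ssim` and `brisque` values.
#' @export
objective <- function(original, enhanced, mask, cfg = objective_config()) {
  if (!identical(dim(original), dim(enhanced)))
    stop_input("original and enhanced must have identical shape",
               class = "boclahe_argument_error")
  assert_mask(mask, original)
  bb <- mask_bbox(mask)
  if (is.null(bb))
    stop_input("mask is empty", class = "boclahe_argument_error")
  s <- ssim(original, enhanced, cfg$ssim, mask)$score
  crop <- enhanced[bb$rows[1L]:bb$rows[2L], bb$cols[1L]:bb$cols[2L],
                   drop = FALSE]
  model <- if (is.null(cfg$quality_model)) default_quality_model()
           else cfg$quality_model
  b <- brisque_score(brisque_features(crop), model)
  value <- cfg$w_ssim * s - cfg$w_brisque * b / cfg$brisque_norm
  attr(value, "components") <- c(ssim = s, brisque = b)
  value
}
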