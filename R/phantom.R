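# Synthetic chest-phantom generator.
#
# Portable neonatal chest radiographs are private clinical data, so every
# other module in the package is exercised against a deterministic phantom:
# two bright elliptical lung fields on a darker thorax, smooth periodic
# rib-like bands inside the lung fields, optional low-contrast lesion discs,
# and additive rounded/clipped noise. The generator returns the image, the
# ground-truth lung mask, and a lesion map.

#' Phantom recipe
#'
#' Describes a synthetic chest radiograph. Defaults emulate a low-dose
#' portable neonatal film: a dark thorax background, two bright lung fields,
#' five rib-like bands, and mild detector noise.
#'
#' @param width,height Image size in pixels (>= 32).
#' @param background_level Thorax intensity outside the lung fields (0-255).
#' @param lung_fill Base lung-field intensity (0-255).
#' @param lung_ellipses Two-row matrix, one row per lung, columns
#'   `center_row_frac`, `center_col_frac`, `semi_axis_row_frac`,
#'   `semi_axis_col_frac` (all fractions of the image size in (0, 1)).
#' @param rib_count Number of sinusoidal rib bands across the image height
#'   (>= 0); bands only modulate pixels inside the lung mask.
#' @param rib_amplitude Peak intensity delta of the rib bands.
#' @param lesions List of lesions, each `c(center_row, center_col, radius_px,
#'   contrast_delta)` in pixels / intensity units (0-based centers).
#' @param noise_sigma Standard deviation of the additive per-pixel noise.
#' @param seed Default seed used when [generate_phantom()] is called without
#'   an explicit one.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(width = 128L, height = 128L,
                         background_level = 40, lung_fill = 140,
                         lung_ellipses = default_lung_ellipses(),
                         rib_count = 5L, rib_amplitude = 12,
                         lesions = list(), noise_sigma = 4, seed = 1L) {
  spec <- list(width = as.integer(width), height = as.integer(height),
               background_level = background_level, lung_fill = lung_fill,
               lung_ellipses = lung_ellipses, rib_count = as.integer(rib_count),
               rib_amplitude = rib_amplitude, lesions = lesions,
               noise_sigma = noise_sigma, seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

default_lung_ellipses <- function() {
  m <- rbind(c(0.55, 0.30, 0.30, 0.16),
             c(0.55, 0.70, 0.30, 0.16))
  colnames(m) <- c("center_row_frac", "center_col_frac",
                   "semi_axis_row_frac", "semi_axis_col_frac")
  m
}

validate_phantom_spec <- function(spec) {
  bad <- function(field) {
    stop_input("invalid phantom spec field: ", field,
               class = "boclahe_config_error")
  }
  if (spec$width < 32L) bad("width")
  if (spec$height < 32L) bad("height")
  for (f in c("background_level", "lung_fill")) {
    v <- spec[[f]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 255) bad(f)
  }
  e <- spec$lung_ellipses
  if (!is.matrix(e) || nrow(e) != 2L || ncol(e) != 4L) bad("lung_ellipses")
  if (any(e <= 0) || any(e >= 1)) bad("lung_ellipses")
  if (spec$rib_count < 0L) bad("rib_count")
  if (!is.numeric(spec$rib_amplitude) || spec$rib_amplitude < 0) bad("rib_amplitude")
  if (!is.list(spec$lesions)) bad("lesions")
  for (les in spec$lesions) {
    if (length(les) != 4L || les[3L] <= 0) bad("lesions")
    if (les[1L] < 0 || les[1L] > spec$height - 1 ||
        les[2L] < 0 || les[2L] > spec$width - 1) bad("lesions")
  }
  if (!is.numeric(spec$noise_sigma) || spec$noise_sigma < 0) bad("noise_sigma")
  invisible(spec)
}

#' Generate one synthetic chest phantom
#'
#' Pure function of `(spec, seed)`: the image is `background_level` outside
#' the union of the two lung ellipses and `lung_fill` plus rib/lesion
#' modulation inside; independent Gaussian noise is added, then intensities
#' are rounded half-up and clipped to `[0, 255]`.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed for the noise realization (defaults to
#'   `spec$seed`).
#' @return A list with integer-matrix `image`, logical `mask` (lung fields),
#'   and logical `lesion_map` (lesion discs), all of identical shape
#'   (rows x cols, 0-based (row, col) convention in lesion coordinates).
#' @export
generate_phantom <- function(spec, seed = spec$seed) {
  validate_phantom_spec(spec)
  h <- spec$height; w <- spec$width
  rr <- matrix(0:(h - 1L), h, w)          # 0-based row coordinate per pixel
  cc <- matrix(0:(w - 1L), h, w, byrow = TRUE)

  mask <- matrix(FALSE, h, w)
  for (i in 1:2) {
    e <- spec$lung_ellipses[i, ]
    cr <- e[1L] * (h - 1); ccn <- e[2L] * (w - 1)
    ar <- e[3L] * h; ac <- e[4L] * w
    mask <- mask | (((rr - cr) / ar)^2 + ((cc - ccn) / ac)^2 <= 1)
  }

  img <- matrix(spec$background_level, h, w)
  img[mask] <- spec$lung_fill
  if (spec$rib_count > 0L && spec$rib_amplitude > 0) {
    ribs <- spec$rib_amplitude * sin(2 * pi * spec$rib_count * rr / h)
    img[mask] <- img[mask] + ribs[mask]
  }

  lesion_map <- matrix(FALSE, h, w)
  for (les in spec$lesions) {
    disc <- (rr - les[1L])^2 + (cc - les[2L])^2 <= les[3L]^2
    img[disc] <- img[disc] + les[4L]
    lesion_map <- lesion_map | disc
  }

  if (spec$noise_sigma > 0) {
    noise <- with_seed(seed, matrix(stats::rnorm(h * w, 0, spec$noise_sigma), h, w))
    img <- img + noise
  }
  img <- clamp(round_half_up(img), 0, 255)
  storage.mode(img) <- "integer"
  list(image = img, mask = mask, lesion_map = lesion_map)
}

#' Generate a batch of phantoms differing only in noise realization
#'
#' Item `i` is reproducible in isolation: it uses a child seed derived from
#' `(seed, i)`, so `phantom_batch(spec, n, seed)[[i]]` equals
#' `generate_phantom(spec, derived-seed-for-i)`.
#'
#' @param spec A [phantom_spec()].
#' @param n Number of phantoms (>= 1).
#' @param seed Batch seed.
#' @return List of `n` phantom triples (see [generate_phantom()]).
#' @export
phantom_batch <- function(spec, n, seed = spec$seed) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop_input("n must be >= 1", class = "boclahe_argument_error")
  lapply(seq_len(n), function(i)
    generate_phantom(spec, seed = phantom_item_seed(seed, i)))
}

#' Seed used for item `i` of [phantom_batch()]
#' @param seed Batch seed.
#' @param i Item index (1-based).
#' @return Integer child seed.
#' @export
phantom_item_seed <- function(seed, i) derive_seed(seed, i)

#' Spec of a low-contrast-lesion phantom
#'
#' The benchmark scene for enhancement experiments: default chest geometry
#' plus two faint lesion discs (one brighter, one darker than the lung
#' field) whose contrast is close to the noise floor.
#'
#' @param ... Overrides passed to [phantom_spec()].
#' @return A `phantom_spec`.
#' @export
lesion_phantom_spec <- function(...) {
  args <- list(...)
  defaults <- list(
    lesions = list(c(58, 38, 7, 14), c(75, 90, 6, -12)),
    noise_sigma = 4)
  phantom_spec_args <- utils::modifyList(defaults, args)
  do.call(phantom_spec, phantom_spec_args)
}

#' Write a phantom triple to PNG files
#'
#' @param phantom A triple from [generate_phantom()].
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Invisibly, the three file paths.
#' @export
write_phantom <- function(phantom, dir, prefix = "phantom") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c(".png", "_mask.png", "_lesions.png")))
  write_gray_image(phantom$image, paths[1L])
  write_gray_image(255L * phantom$mask, paths[2L])
  write_gray_image(255L * phantom$lesion_map, paths[3L])
  invisible(paths)
}
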