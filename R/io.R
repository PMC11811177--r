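# PNG input/output. Images are plain integer matrices on the 0-255 scale,
# masks are logical matrices; both use (row, col) indexing with the top-left
# pixel at [1, 1] (0-based in coordinate arguments).

#' Load a grayscale image from PNG
#'
#' 8-bit grayscale files round-trip bit-exactly. 16-bit files are linearly
#' rescaled to 0-255. RGB files are converted with the integer BT.601 luma
#' `round(0.299 R + 0.587 G + 0.114 B)`; an alpha channel is ignored.
#'
#' @param path PNG file path.
#' @return Integer matrix with values in 0-255.
#' @export
load_gray_image <- function(path) {
  if (!file.exists(path))
    stop_input("cannot read image: ", path, class = "boclahe_input_error")
  arr <- tryCatch(png::readPNG(path),
                  error = function(e) stop_input(
                    "unreadable or unsupported PNG: ", path,
                    class = "boclahe_input_error"))
  # readPNG normalizes to [0,1]; round(x * 255) is the identity for 8-bit
  # payloads and the linear rescale for 16-bit ones.
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3L] >= 3L) {
      ch <- round_half_up(arr[, , 1:3] * 255)
      img <- round_half_up(0.299 * ch[, , 1L] + 0.587 * ch[, , 2L] +
                             0.114 * ch[, , 3L])
    } else {
      img <- round_half_up(arr[, , 1L] * 255)  # gray + alpha
    }
  } else {
    img <- round_half_up(arr * 255)
  }
  storage.mode(img) <- "integer"
  img
}

#' Write a grayscale image as 8-bit PNG
#'
#' @param image Numeric matrix, values in 0-255 (rounded half-up on write).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gray_image <- function(image, path) {
  assert_gray_image(image)
  png::writePNG(round_half_up(image) / 255, path)
  invisible(path)
}

#' Load a binary mask from PNG
#'
#' Any nonzero pixel is foreground. Multi-channel files are reduced by
#' "any channel nonzero".
#'
#' @param path PNG file path.
#' @return Logical matrix.
#' @export
load_mask <- function(path) {
  if (!file.exists(path))
    stop_input("cannot read mask: ", path, class = "boclahe_input_error")
  arr <- tryCatch(png::readPNG(path),
                  error = function(e) stop_input(
                    "unreadable or unsupported PNG: ", path,
                    class = "boclahe_input_error"))
  if (length(dim(arr)) == 3L) {
    nch <- min(dim(arr)[3L], 3L)  # ignore alpha
    m <- apply(arr[, , seq_len(nch), drop = FALSE] > 0, c(1, 2), any)
  } else {
    m <- arr > 0
  }
  m
}

#' Write a binary mask as 8-bit PNG (255 = foreground)
#'
#' @param mask Logical matrix.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_mask <- function(mask, path) {
  assert_mask(mask)
  png::writePNG(mask * 1.0, path)
  invisible(path)
}
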