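test_that("histogram counts partition the region", {
  expect_identical(compute_histogram(matrix(7L, 3, 4))[8L], 12L)
  h <- compute_histogram(matrix(c(0L, 1L, 1L, 255L), 2, 2))
  expect_identical(h[c(1L, 2L, 256L)], c(1L, 2L, 1L))
  expect_identical(sum(h), 4L)
  set.seed(1)
  r <- matrix(sample(0:255, 300, TRUE), 15, 20)
  expect_identical(sum(compute_histogram(r)), 300L)
  expect_error(compute_histogram(matrix(numeric(0), 0, 0)),
               class = "boclahe_argument_error")
})

test_that("clipping preserves mass and matches the step-by-step oracle", {
  h <- rep(2L, 256)
  expect_identical(clip_and_redistribute(h, 4L), h)  # compliant: unchanged

  spike <- integer(256); spike[1L] <- 8L
  expect_identical(clip_and_redistribute(spike, 4L),
                   oracle_redistribute(spike, 4L))

  set.seed(42)
  for (i in 1:50) {
    h <- as.integer(rpois(256, lambda = sample(c(0.5, 3, 40), 1)))
    clip <- sample(1:30, 1)
    out <- clip_and_redistribute(h, clip)
    expect_identical(sum(out), sum(h))
    expect_identical(out, oracle_redistribute(h, clip))
  }
  expect_error(clip_and_redistribute(rep(-1L, 256), 4L),
               class = "boclahe_argument_error")
  expect_error(clip_and_redistribute(rep(1L, 256), 0L),
               class = "boclahe_argument_error")
})

test_that("tile LUT follows the cdf_min-subtracted equalization formula", {
  one_bin <- integer(256); one_bin[101L] <- 50L
  expect_identical(build_tile_lut(one_bin, 50L), 0:255)  # degenerate: identity

  uniform <- rep(4L, 256)
  lut <- build_tile_lut(uniform, 1024L)
  expect_true(all(abs(lut - 0:255) <= 1))

  set.seed(7)
  for (i in 1:30) {
    h <- as.integer(rpois(256, 5))
    if (sum(h) == 0) next
    lut <- build_tile_lut(h, sum(h))
    expect_true(all(diff(lut) >= 0))
    expect_true(all(lut >= 0 & lut <= 255))
  }
  expect_error(build_tile_lut(rep(1L, 256), 99L),
               class = "boclahe_consistency_error")
})

test_that("constant images pass through CLAHE unchanged", {
  img <- matrix(100L, 40, 56)
  for (clip in c(1, 4, 255))
    expect_identical(clahe(img, clahe_params(clip, 8)), img)
})

test_that("grid 1 with clip 255 reduces to global histogram equalization", {
  set.seed(3)
  for (i in 1:5) {
    p <- generate_phantom(random_phantom_spec(i))
    expect_identical(clahe(p$image, clahe_params(255, 1)),
                     oracle_global_he(p$image))
  }
})

test_that("clahe matches the brute-force per-pixel oracle exactly", {
  set.seed(21)
  for (i in 1:6) {
    p <- generate_phantom(random_phantom_spec(i))
    clip <- runif(1, 1, 255)
    grid <- runif(1, 8, 32)
    expect_identical(clahe(p$image, clahe_params(clip, grid)),
                     oracle_clahe(p$image, clip, grid))
  }
  # uneven tile sizes: 61 and 53 are prime, every tile boundary is ragged
  img <- matrix(sample(0:255, 61 * 53, TRUE), 61, 53)
  expect_identical(clahe(img, clahe_params(30, 9)), oracle_clahe(img, 30, 9))
})

test_that("output is always in range with preserved shape", {
  set.seed(5)
  for (i in 1:10) {
    img <- matrix(sample(0:255, 48 * 40, TRUE), 48, 40)
    out <- clahe(img, clahe_params(runif(1, 1, 255), runif(1, 8, 32)))
    expect_identical(dim(out), dim(img))
    expect_true(all(out >= 0L & out <= 255L))
  }
  expect_error(clahe(matrix(1L, 5, 5), clahe_params(2, 8)),
               class = "boclahe_size_error")
})

test_that("masked application composites CLAHE of the bounding box", {
  p <- generate_phantom(small_spec(seed = 2L))
  params <- clahe_params(4, 8)
  all_true <- matrix(TRUE, nrow(p$image), ncol(p$image))
  expect_identical(apply_clahe_masked(p$image, all_true, params),
                   clahe(p$image, params))

  all_false <- matrix(FALSE, nrow(p$image), ncol(p$image))
  expect_warning(out <- apply_clahe_masked(p$image, all_false, params),
                 "empty mask")
  expect_true(all(out == p$image))
  expect_true(isTRUE(attr(out, "empty_mask")))

  out <- apply_clahe_masked(p$image, p$mask, params)
  expect_identical(out[!p$mask], p$image[!p$mask])
  idx <- which(p$mask, arr.ind = TRUE)
  rr <- range(idx[, 1]); cc <- range(idx[, 2])
  crop_enh <- clahe(p$image[rr[1]:rr[2], cc[1]:cc[2]], params)
  sub_mask <- p$mask[rr[1]:rr[2], cc[1]:cc[2]]
  expect_identical(out[rr[1]:rr[2], cc[1]:cc[2]][sub_mask],
                   crop_enh[sub_mask])
})

test_that("masked application never alters pixels outside the mask (fuzz)", {
  set.seed(8)
  for (i in 1:10) {
    img <- matrix(sample(0:255, 64 * 64, TRUE), 64, 64)
    mask <- matrix(runif(64 * 64) < 0.4, 64, 64)
    # guarantee the bounding box can hold the tile grid
    mask[10:60, 10:60][sample(51 * 51, 30)] <- TRUE
    out <- apply_clahe_masked(img, mask, clahe_params(runif(1, 1, 255), 8))
    expect_identical(out[!mask], img[!mask])
  }
})
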