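test_that("noiseless construction places exact levels inside/outside lungs", {
  p <- generate_phantom(flat_spec())
  expect_true(all(p$image[p$mask] == 120L))
  expect_true(all(p$image[!p$mask] == 30L))
  expect_identical(dim(p$image), dim(p$mask))
  expect_identical(dim(p$image), dim(p$lesion_map))
})

test_that("generator is a pure function of (spec, seed)", {
  sp <- small_spec(seed = 5L)
  a <- generate_phantom(sp, seed = 99L)
  b <- generate_phantom(sp, seed = 99L)
  expect_identical(a, b)
  c <- generate_phantom(sp, seed = 100L)
  expect_false(identical(a$image, c$image))
  expect_identical(a$mask, c$mask)  # only the noise realization differs
})

test_that("lesion disc shifts mean intensity by exactly its contrast delta", {
  sp <- flat_spec(lesions = list(c(35, 20, 5, 40)))
  p <- generate_phantom(sp)
  expect_gt(sum(p$lesion_map), 0)
  expect_equal(mean(p$image[p$lesion_map]) - 120, 40)
})

test_that("mask area equals brute-force point-in-ellipse count", {
  sp <- small_spec()
  p <- generate_phantom(sp)
  count <- 0L
  for (r in 0:(sp$height - 1)) for (c in 0:(sp$width - 1)) {
    inside <- FALSE
    for (i in 1:2) {
      e <- sp$lung_ellipses[i, ]
      dr <- (r - e[1] * (sp$height - 1)) / (e[3] * sp$height)
      dc <- (c - e[2] * (sp$width - 1)) / (e[4] * sp$width)
      if (dr^2 + dc^2 <= 1) inside <- TRUE
    }
    if (inside) count <- count + 1L
  }
  expect_identical(sum(p$mask), count)
})

test_that("intensities stay in range under heavy noise and lesions", {
  sp <- small_spec(noise_sigma = 60, lesions = list(c(30, 30, 8, 120)))
  p <- generate_phantom(sp)
  expect_true(all(p$image >= 0L & p$image <= 255L))
  expect_true(is.integer(p$image))
})

test_that("batch items are independently reproducible and differ in noise", {
  sp <- small_spec(noise_sigma = 5)
  batch <- phantom_batch(sp, 3L, seed = 7L)
  expect_length(batch, 3L)
  solo <- generate_phantom(sp, seed = phantom_item_seed(7L, 2L))
  expect_identical(batch[[2L]], solo)
  expect_false(identical(batch[[1L]]$image, batch[[2L]]$image))

  batch0 <- phantom_batch(flat_spec(), 3L, seed = 7L)
  expect_identical(batch0[[1L]], batch0[[3L]])  # no noise: all identical
})

test_that("batch noise averages back to the noiseless phantom", {
  sp <- small_spec(noise_sigma = 5, rib_count = 0L, rib_amplitude = 0,
                   background_level = 40, lung_fill = 140)
  base_mean <- mean(generate_phantom(small_spec(
    noise_sigma = 0, rib_count = 0L, rib_amplitude = 0,
    background_level = 40, lung_fill = 140))$image)
  batch <- phantom_batch(sp, 50L, seed = 3L)
  tol <- 3 * 5 / sqrt(64 * 64)
  for (p in batch)
    expect_lt(abs(mean(p$image) - base_mean), tol)
})

test_that("invalid spec fields are rejected by name", {
  expect_error(phantom_spec(width = 16L), "width",
               class = "boclahe_config_error")
  expect_error(phantom_spec(lung_fill = 300), "lung_fill",
               class = "boclahe_config_error")
  expect_error(phantom_spec(lesions = list(c(1000, 10, 5, 10))), "lesions",
               class = "boclahe_config_error")
  expect_error(phantom_spec(noise_sigma = -1), "noise_sigma",
               class = "boclahe_config_error")
  expect_error(phantom_batch(small_spec(), 0L),
               class = "boclahe_argument_error")
})
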