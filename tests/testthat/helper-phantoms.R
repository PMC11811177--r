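# Small phantom specs used across tests (64x64 keeps oracles fast).

small_spec <- function(...) {
  args <- utils::modifyList(
    list(width = 64L, height = 64L, noise_sigma = 4, seed = 11L),
    list(...))
  do.call(phantom_spec, args)
}

flat_spec <- function(...) {
  small_spec(noise_sigma = 0, rib_count = 0L, rib_amplitude = 0,
             background_level = 30, lung_fill = 120, ...)
}

random_phantom_spec <- function(seed) {
  # moderate noise keeps the intensity range inside (0, 255): no clipping
  small_spec(noise_sigma = stats::runif(1, 2, 8), seed = seed,
             rib_count = sample(3:6, 1),
             rib_amplitude = stats::runif(1, 8, 16),
             background_level = stats::runif(1, 30, 60),
             lung_fill = stats::runif(1, 120, 170))
}
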