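# Shared fixtures: tiny configurations keep every unit test at 32x32 input
# with a quarter-width backbone; models are cached per session because
# building one is cheap but not free.

tiny_cfg <- function(..., input_size = 32L, width_multiplier = 0.25,
                     seed = 3L) {
  model_config(input_size = input_size, width_multiplier = width_multiplier,
               seed = seed, ...)
}

.model_cache <- new.env(parent = emptyenv())

cached_model <- function(key, builder) {
  if (is.null(.model_cache[[key]])) .model_cache[[key]] <- builder()
  .model_cache[[key]]
}

tiny_full_model <- function() {
  cached_model("full32", function() build_variant(tiny_cfg()))
}

tiny_base_model <- function() {
  cached_model("base32", function()
    build_variant(tiny_cfg(use_fpn = FALSE, use_sp = FALSE, use_se = FALSE)))
}

rand_img <- function(size, seed = 1L) {
  set.seed(seed)
  array(runif(size * size * 3L), dim = c(size, size, 3L))
}

# A labeled dataset of tiny placeholder images (2x2), one list entry per
# class count: label bookkeeping tests do not need realistic pixels.
dummy_dataset <- function(counts) {
  cls <- leaf_classes()$class
  labels <- rep(cls, times = counts)
  images <- lapply(seq_along(labels), function(i)
    array(runif(12), dim = c(2L, 2L, 3L)))
  leaf_dataset(images, labels)
}

# Small synthetic leaf dataset for end-to-end tests.
small_leaf_ds <- function(n_per_class = 2L, size = 32L, seed = 5L,
                          clutter = 0.1) {
  generate_dataset(synthetic_config(per_class_counts = rep(n_per_class, 9L),
                                    image_size = size, seed = seed,
                                    clutter_level = clutter))
}
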