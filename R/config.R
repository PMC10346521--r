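#' Architectural configuration of a leaf-maturity classifier
#'
#' Collects every architectural hyperparameter of the classifier family:
#' the input resolution, backbone width multiplier, the pointwise-convolution
#' stages tapped for the feature pyramid, the pyramid width, the
#' squeeze-and-excitation bottleneck ratio, the spatial-attention kernel and
#' the three ablation flags. The defaults describe the full enhanced model:
#' a width-1.0 depthwise-separable backbone at 224x224 input, taps after
#' pointwise stages 1, 3, 5, 11 and 13, a 64-channel pyramid, spatial
#' attention on P2 and a ratio-32 bias-free SE block on P1.
#'
#' @param input_size input resolution in pixels; must be divisible by 32
#'   (the backbone's stride chain reduces resolution fivefold by factor 2).
#' @param width_multiplier multiplies every backbone channel width; the
#'   pyramid width is not affected.
#' @param n_classes number of output classes (nine maturity-by-position
#'   labels by default).
#' @param pyramid_channels channel width of every pyramid level.
#' @param tap_points indices (1..13) of the pointwise stages whose ReLU
#'   outputs become C1..C5; must be strictly increasing.
#' @param se_ratio SE bottleneck divisor; must divide `pyramid_channels`.
#' @param se_bias logical; add biases to the two SE dense maps (off by
#'   default — the bias-free form is what the variant's parameter total
#'   accounts for).
#' @param sp_kernel spatial-attention convolution kernel size in pixels.
#' @param use_fpn,use_sp,use_se ablation flags. Attention flags require
#'   `use_fpn`.
#' @param seed integer seed for weight initialization.
#' @return an object of class `leafnet_config`.
#' @export
model_config <- function(input_size = 224L, width_multiplier = 1,
                         n_classes = 9L, pyramid_channels = 64L,
                         tap_points = c(1L, 3L, 5L, 11L, 13L),
                         se_ratio = 32L, se_bias = FALSE, sp_kernel = 3L,
                         use_fpn = TRUE, use_sp = TRUE, use_se = TRUE,
                         seed = 1L) {
  input_size <- as.integer(input_size)
  if (input_size < 32L || input_size %% 32L != 0L)
    stopf("input_size must be a positive multiple of 32, got %d", input_size)
  if (width_multiplier <= 0)
    stopf("width_multiplier must be positive")
  tap_points <- as.integer(tap_points)
  if (any(tap_points < 1L | tap_points > 13L) ||
      any(diff(tap_points) <= 0L))
    stopf("tap_points must be strictly increasing indices in [1, 13]")
  pyramid_channels <- as.integer(pyramid_channels)
  if (pyramid_channels <= 0L) stopf("pyramid_channels must be positive")
  se_ratio <- as.integer(se_ratio)
  if (pyramid_channels %% se_ratio != 0L)
    stopf("se_ratio (%d) must divide pyramid_channels (%d)",
          se_ratio, pyramid_channels)
  if ((use_sp || use_se) && !use_fpn)
    stopf("use_sp/use_se require use_fpn: attention acts on pyramid levels")
  structure(list(
    input_size = input_size,
    width_multiplier = width_multiplier,
    n_classes = as.integer(n_classes),
    pyramid_channels = pyramid_channels,
    tap_points = tap_points,
    se_ratio = se_ratio,
    se_bias = isTRUE(se_bias),
    sp_kernel = as.integer(sp_kernel),
    use_fpn = isTRUE(use_fpn),
    use_sp = isTRUE(use_sp),
    use_se = isTRUE(use_se),
    seed = as.integer(seed)
  ), class = "leafnet_config")
}

#' @export
print.leafnet_config <- function(x, ...) {
  flags <- c(if (x$use_fpn) "FPN", if (x$use_sp) "SP", if (x$use_se) "SE")
  cat(sprintf(
    "<leafnet_config> input %dx%d, width x%.2f, %d classes, variant: %s\n",
    x$input_size, x$input_size, x$width_multiplier, x$n_classes,
    if (length(flags)) paste(c("base", flags), collapse = "+") else "base"))
  invisible(x)
}

#' Read or write a model configuration as YAML
#'
#' @param path file path.
#' @return `read_model_config()` returns a `leafnet_config`;
#'   `write_model_config()` returns `path` invisibly.
#' @export
read_model_config <- function(path) {
  do.call(model_config, yaml::read_yaml(path))
}

#' @rdname read_model_config
#' @param config a `leafnet_config`.
#' @export
write_model_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Backbone channel schedule: stem + 13 pointwise output widths, before the
# width multiplier.
BASE_CHANNELS <- c(32L, 64L, 128L, 128L, 256L, 256L, 512L,
                   512L, 512L, 512L, 512L, 512L, 1024L, 1024L)
# Depthwise stride per separable block (stem itself has stride 2).
BLOCK_STRIDES <- c(1L, 2L, 1L, 2L, 1L, 2L, 1L, 1L, 1L, 1L, 1L, 2L, 1L)

backbone_channels <- function(cfg) {
  as.integer(round(BASE_CHANNELS * cfg$width_multiplier))
}

# Spatial size of each pointwise stage output for a given input size.
block_spatial <- function(cfg) {
  s <- cfg$input_size %/% 2L  # after stem
  out <- integer(13L)
  for (b in 1:13) {
    s <- s %/% BLOCK_STRIDES[b]
    out[b] <- s
  }
  out
}
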