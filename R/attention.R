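#' Squeeze-and-excitation channel attention
#'
#' Applies the three-stage SE recalibration to a feature map: *squeeze*
#' (global average pooling of each H x W channel to a scalar), *excitation*
#' (a bottleneck pair of dense maps, ReLU then sigmoid, producing one weight
#' in (0, 1) per channel) and *scale* (channelwise multiplication of the
#' input by the weights). The output has the shape of the input and is
#' elementwise bounded by it.
#'
#' @param x an H x W x C feature-map array.
#' @param weights list with `w1` (C x C/ratio) and `w2` (C/ratio x C) dense
#'   maps, optionally `b1`, `b2` bias vectors.
#' @param ratio bottleneck divisor; checked against the shapes of `weights`
#'   (must divide C). Defaults to the ratio implied by `weights`.
#' @return an H x W x C array.
#' @seealso [sp_block()] for the spatial counterpart.
#' @export
se_block <- function(x, weights, ratio = NULL) {
  d <- dim(x)
  if (length(d) != 3L) stopf("x must be an H x W x C array")
  C <- d[3L]
  mid <- ncol(weights$w1)
  if (!is.null(ratio)) {
    if (C %% ratio != 0L)
      stopf("se ratio (%d) must divide the channel count (%d)", ratio, C)
    if (mid != C %/% ratio)
      stopf("weights imply bottleneck width %d, ratio %d requires %d",
            mid, ratio, C %/% ratio)
  }
  if (nrow(weights$w1) != C || ncol(weights$w2) != C)
    stopf("SE weight shapes do not match %d channels", C)
  xm <- img_to_mat(x)
  sq <- matrix(colMeans(xm), 1L)
  z1 <- sq %*% weights$w1
  if (!is.null(weights$b1)) z1 <- z1 + matrix(weights$b1, 1L)
  z2 <- relu(z1) %*% weights$w2
  if (!is.null(weights$b2)) z2 <- z2 + matrix(weights$b2, 1L)
  w <- sigmoid(z2)[1L, ]
  mat_to_img(sweep(xm, 2L, w, `*`), d[1L], d[2L])
}

#' Spatial attention
#'
#' Computes, at every spatial location, the mean and the maximum over
#' channels, concatenates the two H x W maps into a two-channel map,
#' convolves it with a single same-padded K x K filter (with bias) and
#' applies a sigmoid, yielding an H x W attention map in (0, 1) that is
#' broadcast-multiplied over all channels of the input.
#'
#' @param x an H x W x C feature-map array.
#' @param weights list with `w`, the convolution kernel as a K x K x 2 array
#'   (channel 1 acts on the mean map, channel 2 on the max map), and `b`,
#'   a scalar bias.
#' @return an H x W x C array.
#' @seealso [se_block()]
#' @export
sp_block <- function(x, weights) {
  d <- dim(x)
  if (length(d) != 3L) stopf("x must be an H x W x C array")
  H <- d[1L]; W <- d[2L]
  wk <- weights$w
  K <- dim(wk)[1L]
  if (length(dim(wk)) != 3L || dim(wk)[2L] != K || dim(wk)[3L] != 2L)
    stopf("weights$w must be a K x K x 2 array")
  xm <- img_to_mat(x)
  mn <- rowMeans(xm)
  mx <- rowmax_cpp(xm)$max
  M <- cbind(mn, mx)
  # flatten kernel to the internal (K*K*2) x 1 layout: kh fastest, then kw,
  # then input channel
  wmat <- matrix(as.vector(wk), ncol = 1L)
  cv <- conv_fwd(M, H, W, 1L, wmat, K, 1L, bias = weights$b)
  s <- sigmoid(cv$y[, 1L])
  mat_to_img(xm * s, H, W)
}

#' The attention map of a spatial-attention block
#'
#' Returns the H x W sigmoid weight map that [sp_block()] multiplies into
#' its input, for inspection and testing.
#'
#' @inheritParams sp_block
#' @return an H x W matrix with entries in (0, 1).
#' @export
sp_attention_map <- function(x, weights) {
  d <- dim(x)
  xm <- img_to_mat(x)
  M <- cbind(rowMeans(xm), rowmax_cpp(xm)$max)
  wmat <- matrix(as.vector(weights$w), ncol = 1L)
  cv <- conv_fwd(M, d[1L], d[2L], 1L, wmat, dim(weights$w)[1L], 1L,
                 bias = weights$b)
  matrix(sigmoid(cv$y[, 1L]), d[1L], d[2L])
}

#' Initialize attention-block weights
#'
#' He-normal initialization matching what [build_variant()] uses internally.
#'
#' @param channels channel count C of the feature map.
#' @param ratio SE bottleneck divisor.
#' @param bias add SE biases.
#' @param kernel SP kernel size.
#' @param seed integer seed.
#' @return for `init_se_weights()` a list with `w1`, `w2` (and biases when
#'   requested); for `init_sp_weights()` a list with `w` (K x K x 2) and `b`.
#' @export
init_se_weights <- function(channels, ratio = 32L, bias = FALSE, seed = 1L) {
  if (channels %% ratio != 0L)
    stopf("se ratio (%d) must divide the channel count (%d)", ratio, channels)
  set.seed(seed)
  mid <- channels %/% ratio
  out <- list(w1 = he_init(channels, mid, channels),
              w2 = he_init(mid, channels, mid))
  if (bias) {
    out$b1 <- rep(0, mid)
    out$b2 <- rep(0, channels)
  }
  out
}

#' @rdname init_se_weights
#' @export
init_sp_weights <- function(kernel = 3L, seed = 1L) {
  set.seed(seed)
  list(w = array(stats::rnorm(kernel * kernel * 2L, 0,
                              sqrt(2 / (kernel * kernel * 2L))),
                 dim = c(kernel, kernel, 2L)),
       b = 0)
}
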