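# Layer primitives over the internal matrix layout: activations are
# (H*W*N) x C matrices, row index h + H*(w + W*n). Convolution weights are
# (K*K*Cin) x Cout matrices, row index kh + K*(kw + K*cin); depthwise
# weights are (K*K) x C. Stride-1 convolutions use symmetric "same"
# zero-padding; stride-2 use asymmetric (0 top/left, 1 bottom/right)
# padding so even sizes halve exactly.

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, 0, sqrt(2 / fan_in)), nrow, ncol)
}

bn_init <- function(C, prefix) {
  out <- list(rep(1, C), rep(0, C), rep(0, C), rep(1, C))
  names(out) <- paste0(prefix, c("_gamma", "_beta", "_mean", "_var"))
  out
}

conv_pads <- function(K, stride) {
  if (stride == 1L) {
    p <- (K - 1L) %/% 2L
    c(p, p)                      # pad_top, pad_left (symmetric)
  } else {
    c(0L, 0L)                    # asymmetric: implicit extra pad bottom/right
  }
}

conv_out_size <- function(H, K, stride, pad_top) {
  pad_bottom <- if (stride == 1L) pad_top else K - 2L  # 1 for K=3, s=2
  (H + pad_top + pad_bottom - K) %/% stride + 1L
}

# Standard KxK convolution via im2col + GEMM. Returns y and the column
# matrix (needed for the weight gradient).
conv_fwd <- function(X, H, W, N, Wmat, K, stride, bias = NULL) {
  pads <- conv_pads(K, stride)
  Ho <- conv_out_size(H, K, stride, pads[1L])
  Wo <- conv_out_size(W, K, stride, pads[2L])
  if (K == 1L && stride == 1L) {
    y <- X %*% Wmat
    cols <- X
  } else {
    cols <- im2col_cpp(X, H, W, N, K, stride, pads[1L], pads[2L], Ho, Wo)
    y <- cols %*% Wmat
  }
  if (!is.null(bias)) y <- colaffine_cpp(y, rep(1, length(bias)), bias)
  list(y = y, cols = cols, Ho = Ho, Wo = Wo)
}

conv_bwd <- function(dY, cache, H, W, N, Wmat, K, stride, bias = FALSE,
                     need_dx = TRUE) {
  pads <- conv_pads(K, stride)
  dW <- crossprod(cache$cols, dY)
  db <- if (bias) colSums(dY) else NULL
  dX <- NULL
  if (need_dx) {
    if (K == 1L && stride == 1L) {
      dX <- tcrossprod(dY, Wmat)
    } else {
      dcols <- tcrossprod(dY, Wmat)
      dX <- col2im_cpp(dcols, H, W, N, nrow(Wmat) %/% (K * K), K, stride,
                       pads[1L], pads[2L], cache$Ho, cache$Wo)
    }
  }
  list(dx = dX, dw = dW, db = db)
}

dw_fwd <- function(X, H, W, N, Wt, K, stride) {
  pads <- conv_pads(K, stride)
  Ho <- conv_out_size(H, K, stride, pads[1L])
  Wo <- conv_out_size(W, K, stride, pads[2L])
  y <- dwconv_fwd_cpp(X, H, W, N, Wt, K, stride, pads[1L], pads[2L], Ho, Wo)
  list(y = y, Ho = Ho, Wo = Wo)
}

dw_bwd <- function(X, dY, H, W, N, Wt, K, stride, Ho, Wo) {
  pads <- conv_pads(K, stride)
  dwconv_bwd_cpp(X, dY, H, W, N, Wt, K, stride, pads[1L], pads[2L], Ho, Wo)
}

BN_EPS <- 1e-3
# moving-statistics decay: 0.8 burns in reliable inference statistics within
# a few dozen optimizer steps, which matters at the short training budgets
# this package targets
BN_MOMENTUM <- 0.8

# Global average pooling: (H*W*N) x C -> N x C.
gap_fwd <- function(x, hw, N) {
  blockcolsum_cpp(x, hw) / hw
}

gap_bwd <- function(dg, hw, N) {
  blockexpand_cpp(dg, hw, 1 / hw)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

cross_entropy <- function(probs, targets) {
  p <- probs[cbind(seq_len(nrow(probs)), targets)]
  -mean(log(pmax(p, 1e-12)))
}
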