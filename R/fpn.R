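#' Build a feature pyramid from backbone taps
#'
#' Projects each tap C1..C5 to the pyramid width with a biased 1x1
#' convolution (the lateral connection), then fuses top-down: the top level
#' P5 is the lateral of C5, and every lower level is its lateral plus the
#' bilinearly 2x-upsampled level above, `Pi = lateral(Ci) + up2(P(i+1))`.
#' Fusion is elementwise addition, so the pyramid adds no parameters beyond
#' the laterals.
#'
#' @param taps list of H x W x C arrays, finest first (C1..C5); each level's
#'   spatial size must be exactly twice the next level's.
#' @param config a [model_config()] (only `pyramid_channels` is used).
#' @param weights optional list of per-level lateral weights, each a list
#'   with `w` (Ci x pyramid_channels) and `b` (length pyramid_channels);
#'   initialized from `config$seed` when omitted.
#' @return list of arrays P1..P5, each with `pyramid_channels` channels and
#'   the spatial size of its tap; the lateral weights are attached as
#'   attribute `"weights"`.
#' @export
build_fpn <- function(taps, config, weights = NULL) {
  nl <- length(taps)
  pc <- config$pyramid_channels
  dims <- lapply(taps, dim)
  if (is.null(weights)) {
    set.seed(config$seed)
    weights <- lapply(dims, function(d)
      list(w = he_init(d[3L], pc, d[3L]), b = rep(0, pc)))
  }
  L <- vector("list", nl)
  for (i in seq_len(nl)) {
    xm <- img_to_mat(taps[[i]])
    L[[i]] <- colaffine_cpp(xm %*% weights[[i]]$w,
                            rep(1, length(weights[[i]]$b)), weights[[i]]$b)
  }
  P <- vector("list", nl)
  P[[nl]] <- L[[nl]]
  for (i in rev(seq_len(nl - 1L))) {
    hi <- dims[[i + 1L]][1L]; wi <- dims[[i + 1L]][2L]
    ho <- dims[[i]][1L]; wo <- dims[[i]][2L]
    if (2L * hi != ho || 2L * wi != wo)
      stopf(paste0("pyramid level P%d: upsampled size %dx%d does not match ",
                   "lateral size %dx%d"), i, 2L * hi, 2L * wi, ho, wo)
    up <- bilinear_resize_cpp(P[[i + 1L]], hi, wi, 1L, ho, wo)
    P[[i]] <- L[[i]] + up
  }
  out <- lapply(seq_len(nl), function(i)
    mat_to_img(P[[i]], dims[[i]][1L], dims[[i]][2L]))
  names(out) <- paste0("P", seq_len(nl))
  attr(out, "weights") <- weights
  out
}

#' Bilinear 2x upsampling
#'
#' Doubles the spatial resolution of a feature map by bilinear
#' interpolation with the half-pixel (align-corners-off) convention —
#' parameter-free, as required for the pyramid's parameter accounting.
#'
#' @param x an H x W x C array.
#' @return a 2H x 2W x C array.
#' @export
upsample2x <- function(x) {
  d <- dim(x)
  mat_to_img(bilinear_resize_cpp(img_to_mat(x), d[1L], d[2L], 1L,
                                 2L * d[1L], 2L * d[2L]),
             2L * d[1L], 2L * d[2L])
}
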