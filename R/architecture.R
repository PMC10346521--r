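#' Build the depthwise-separable backbone
#'
#' Constructs the thirteen-stage depthwise-separable backbone (a 3x3 stride-2
#' stem followed by thirteen depthwise + pointwise stages, each convolution
#' followed by batch normalization and ReLU) and exposes the five tap
#' activations C1..C5 taken after the pointwise ReLUs named by
#' `config$tap_points`. At 224x224 input with width 1.0 the taps have
#' spatial sizes 112, 56, 28, 14, 7 and channel widths 64, 128, 256, 512,
#' 1024.
#'
#' @param config a [model_config()].
#' @return an object of class `leafnet_backbone`; pass it to
#'   [backbone_taps()] to obtain tap activations for an image.
#' @export
build_backbone <- function(config) {
  stopifnot(inherits(config, "leafnet_config"))
  set.seed(config$seed)
  structure(list(config = config, params = init_backbone_params(config)),
            class = "leafnet_backbone")
}

#' Tap activations of a backbone
#'
#' Runs the backbone forward (inference mode) and returns the five tap
#' feature maps as H x W x C arrays named C1..C5.
#'
#' @param backbone a `leafnet_backbone` or `leafnet_model`.
#' @param image an `input_size` x `input_size` x 3 array in `[0, 1]`.
#' @return named list of five arrays.
#' @export
backbone_taps <- function(backbone, image) {
  cfg <- backbone$config
  check_image_input(image, cfg$input_size)
  fw <- net_forward(backbone$params, cfg, img_to_mat(image), 1L,
                    training = FALSE, keep = FALSE, backbone_only = TRUE)
  sp <- block_spatial(cfg)[cfg$tap_points]
  out <- lapply(seq_along(fw$taps), function(i)
    mat_to_img(fw$taps[[i]], sp[i], sp[i]))
  names(out) <- paste0("C", seq_along(out))
  out
}

#' Assemble a classifier variant
#'
#' Builds one of the ablation variants controlled by the `use_fpn`,
#' `use_sp` and `use_se` flags of the configuration:
#' the plain backbone classifier (global average pooling plus a dense
#' softmax layer on C5), the feature-pyramid variant (head on the fused P1
#' through BatchNorm, global average pooling and a dense softmax layer),
#' and the attention variants (spatial attention applied to P2 before its
#' top-down fusion into P1; squeeze-and-excitation applied to the fused P1).
#'
#' @param config a [model_config()].
#' @return an object of class `leafnet_model`.
#' @export
build_variant <- function(config) {
  stopifnot(inherits(config, "leafnet_config"))
  set.seed(config$seed)
  params <- init_backbone_params(config)
  ch <- backbone_channels(config)
  pc <- config$pyramid_channels
  if (config$use_fpn) {
    tap_ch <- ch[config$tap_points + 1L]
    for (i in seq_along(tap_ch)) {
      params[[paste0("lat", i, "_w")]] <- he_init(tap_ch[i], pc, tap_ch[i])
      params[[paste0("lat", i, "_b")]] <- rep(0, pc)
    }
    if (config$use_sp) {
      k <- config$sp_kernel
      params$sp_w <- he_init(k * k * 2L, 1L, k * k * 2L)
      params$sp_b <- 0
    }
    if (config$use_se) {
      mid <- pc %/% config$se_ratio
      params$se_w1 <- he_init(pc, mid, pc)
      params$se_w2 <- he_init(mid, pc, mid)
      if (config$se_bias) {
        params$se_b1 <- rep(0, mid)
        params$se_b2 <- rep(0, pc)
      }
    }
    params <- c(params, bn_init(pc, "head_bn"))
    feat_ch <- pc
  } else {
    feat_ch <- ch[14L]
  }
  params$fc_w <- he_init(feat_ch, config$n_classes, feat_ch)
  params$fc_b <- rep(0, config$n_classes)
  structure(list(config = config, params = params), class = "leafnet_model")
}

init_backbone_params <- function(cfg) {
  ch <- backbone_channels(cfg)
  p <- list()
  p$stem_w <- he_init(9L * 3L, ch[1L], 9L * 3L)
  p <- c(p, bn_init(ch[1L], "stem_bn"))
  for (b in 1:13) {
    cin <- ch[b]
    cout <- ch[b + 1L]
    p[[paste0("dw", b, "_w")]] <- he_init(9L, cin, 9L)
    p <- c(p, bn_init(cin, paste0("dw", b, "_bn")))
    p[[paste0("pw", b, "_w")]] <- he_init(cin, cout, cin)
    p <- c(p, bn_init(cout, paste0("pw", b, "_bn")))
  }
  p
}

#' Count model parameters
#'
#' Total number of parameters, trainable and non-trainable alike: batch-norm
#' moving means and variances are included, matching how deep-learning
#' frameworks report model size.
#'
#' @param model a `leafnet_model`, `leafnet_backbone`, or a plain named list
#'   of numeric arrays.
#' @return integer total.
#' @export
count_parameters <- function(model) {
  params <- if (is.list(model) && !is.null(model$params)) model$params else model
  stopifnot(is.list(params))
  sum(vapply(params, length, integer(1L)))
}

TRAINABLE_EXCLUDE <- "_(mean|var)$"

trainable_names <- function(params) {
  nm <- names(params)
  nm[!grepl(TRAINABLE_EXCLUDE, nm)]
}

check_image_input <- function(image, size) {
  d <- dim(image)
  if (is.null(d) || length(d) != 3L || d[3L] != 3L)
    stopf("expected an H x W x 3 image array")
  if (d[1L] != size || d[2L] != size)
    stopf("expected a %dx%d input, got %dx%d", size, size, d[1L], d[2L])
  invisible(TRUE)
}

# Full forward pass. X is the (S*S*N) x 3 input batch. Returns probs plus
# taps / pyramid / feature map and, when keep = TRUE, the caches needed for
# the backward pass. When training = TRUE batch statistics are used for BN
# (via fused BN+ReLU kernels that avoid materializing the normalized
# tensor) and their moving-average updates are returned in `bn_new`.
net_forward <- function(params, cfg, X, N, training = FALSE, keep = FALSE,
                        backbone_only = FALSE, want_maps = FALSE) {
  S <- cfg$input_size
  cache <- list()
  bn_new <- list()

  # batch-norm followed by optional ReLU; in training mode returns the
  # pieces the fused backward kernel needs (pre-BN tensor, mu, inv)
  run_bn <- function(x, prefix, act) {
    g <- params[[paste0(prefix, "_gamma")]]
    be <- params[[paste0(prefix, "_beta")]]
    if (training) {
      m <- nrow(x)
      mom <- bn_moments_cpp(x)
      inv <- 1 / sqrt(mom$var + BN_EPS)
      a <- bn_act_fwd_cpp(x, mom$mu, inv, g, be, act)
      bn_new[[paste0(prefix, "_mean")]] <<-
        BN_MOMENTUM * params[[paste0(prefix, "_mean")]] +
        (1 - BN_MOMENTUM) * mom$mu
      bn_new[[paste0(prefix, "_var")]] <<-
        BN_MOMENTUM * params[[paste0(prefix, "_var")]] +
        (1 - BN_MOMENTUM) * mom$var * m / max(m - 1, 1)
      list(a = a, x = x, mu = mom$mu, inv = inv)
    } else {
      mv <- params[[paste0(prefix, "_var")]]
      mm <- params[[paste0(prefix, "_mean")]]
      scale <- g / sqrt(mv + BN_EPS)
      y <- colaffine_cpp(x, scale, be - mm * scale)
      if (act) y <- relu_cpp(y)
      list(a = y)
    }
  }

  # stem (direct convolution: 3 input channels, no im2col)
  pads <- conv_pads(3L, 2L)
  Ho <- conv_out_size(S, 3L, 2L, pads[1L])
  stem_y <- conv_direct_fwd_cpp(X, S, S, N, params$stem_w, 3L, 2L,
                                pads[1L], pads[2L], Ho, Ho)
  bns <- run_bn(stem_y, "stem_bn", act = TRUE)
  a <- bns$a
  if (keep) cache$stem <- c(list(input = X, Ho = Ho), bns)
  h <- Ho

  taps <- vector("list", length(cfg$tap_points))
  tap_at <- match(1:13, cfg$tap_points)
  blocks <- if (keep) vector("list", 13L) else NULL
  for (b in 1:13) {
    s <- BLOCK_STRIDES[b]
    xin <- a
    hin <- h
    dw <- dw_fwd(xin, hin, hin, N, params[[paste0("dw", b, "_w")]], 3L, s)
    bnd <- run_bn(dw$y, paste0("dw", b, "_bn"), act = TRUE)
    pw <- bnd$a %*% params[[paste0("pw", b, "_w")]]
    bnp <- run_bn(pw, paste0("pw", b, "_bn"), act = TRUE)
    a <- bnp$a
    h <- dw$Ho
    if (!is.na(tap_at[b])) taps[[tap_at[b]]] <- a
    if (keep) blocks[[b]] <- list(xin = xin, hin = hin, bnd = bnd,
                                  bnp = bnp, h = h)
  }
  if (keep) cache$blocks <- blocks
  if (backbone_only) return(list(taps = taps))

  pyramid <- NULL
  sp_cache <- NULL
  se_cache <- NULL
  sp_out <- NULL
  se_out <- NULL
  if (cfg$use_fpn) {
    sp_sizes <- block_spatial(cfg)[cfg$tap_points]
    nl <- length(taps)
    L <- vector("list", nl)
    for (i in seq_len(nl))
      L[[i]] <- taps[[i]] %*% params[[paste0("lat", i, "_w")]]
    P <- vector("list", nl)
    lb <- params[[paste0("lat", nl, "_b")]]
    P[[nl]] <- colaffine_cpp(L[[nl]], rep(1, length(lb)), lb)
    for (i in rev(seq_len(nl - 1L))) {
      si <- sp_sizes[i + 1L]
      so <- sp_sizes[i]
      if (2L * si != so)
        stopf("pyramid level P%d: upsampled size %d does not match lateral size %d",
              i, 2L * si, so)
      src <- P[[i + 1L]]
      if (i == 1L && cfg$use_sp) {
        spb <- sp_attention_fwd(src, si, N, params$sp_w, params$sp_b,
                                cfg$sp_kernel, keep)
        sp_out <- spb$y
        if (keep) sp_cache <- spb
        src <- spb$y
      }
      P[[i]] <- fpn_fuse_cpp(src, si, si, N, so, so, L[[i]],
                             params[[paste0("lat", i, "_b")]])
    }
    feat <- P[[1L]]
    if (cfg$use_se) {
      seb <- se_attention_fwd(feat, sp_sizes[1L]^2, N, params, cfg, keep)
      se_out <- seb$y
      if (keep) se_cache <- seb
      feat <- seb$y
    }
    hw <- sp_sizes[1L]^2
    bnh <- run_bn(feat, "head_bn", act = FALSE)
    if (keep) cache$head_bn <- bnh
    g <- gap_fwd(bnh$a, hw, N)
    pyramid <- P
    if (keep) {
      cache$taps <- taps
      cache$P <- P
      cache$sp <- sp_cache
      cache$se <- se_cache
      cache$feat <- feat
      cache$hw <- hw
    }
  } else {
    feat <- a
    hw <- h * h
    g <- gap_fwd(feat, hw, N)
    if (keep) {
      cache$feat <- feat
      cache$hw <- hw
    }
  }
  logits <- colaffine_cpp(g %*% params$fc_w, rep(1, length(params$fc_b)),
                          params$fc_b)
  probs <- softmax_rows(logits)
  if (keep) {
    cache$g <- g
    cache$probs <- probs
    cache$N <- N
  }
  out <- list(probs = probs, bn_new = bn_new)
  if (keep) out$cache <- cache
  if (want_maps) {
    out$taps <- taps
    out$pyramid <- pyramid
    out$sp_out <- sp_out
    out$se_out <- se_out
    out$feat <- feat
  }
  out
}

# Spatial attention inside the network graph. x: (h*h*N) x C.
sp_attention_fwd <- function(x, h, N, w, b, K, keep) {
  mn <- rowMeans(x)
  rm <- rowmax_cpp(x)
  M <- cbind(mn, rm$max)
  cv <- conv_fwd(M, h, h, N, w, K, 1L, bias = b)
  s <- sigmoid(cv$y)
  y <- x * s[, 1L]
  out <- list(y = y, s = s)
  if (keep) {
    out$x <- x
    out$cv <- cv
    out$idx <- rm$idx
    out$h <- h
    out$N <- N
  }
  out
}

sp_attention_bwd <- function(dy, cache, w, K) {
  x <- cache$x
  s <- cache$s[, 1L]
  C <- ncol(x)
  dx <- dy * s
  dsv <- rowSums(dy * x)
  dz <- matrix(dsv * s * (1 - s), ncol = 1L)
  cb <- conv_bwd(dz, cache$cv, cache$h, cache$h, cache$N, w, K, 1L,
                 bias = TRUE, need_dx = TRUE)
  dM <- cb$dx
  dx <- dx + dM[, 1L] / C
  ridx <- cbind(seq_len(nrow(x)), cache$idx)
  dx[ridx] <- dx[ridx] + dM[, 2L]
  list(dx = dx, dw = cb$dw, db = cb$db)
}

# Squeeze-and-excitation inside the network graph. x: (hw*N) x C.
se_attention_fwd <- function(x, hw, N, params, cfg, keep) {
  sq <- gap_fwd(x, hw, N)
  z1 <- sq %*% params$se_w1
  if (cfg$se_bias) z1 <- sweep(z1, 2L, params$se_b1, `+`)
  r1 <- relu(z1)
  z2 <- r1 %*% params$se_w2
  if (cfg$se_bias) z2 <- sweep(z2, 2L, params$se_b2, `+`)
  w <- sigmoid(z2)
  y <- blockscale_cpp(x, w, hw)
  out <- list(y = y)
  if (keep) {
    out$x <- x
    out$sq <- sq
    out$z1 <- z1
    out$r1 <- r1
    out$w <- w
    out$hw <- hw
    out$N <- N
  }
  out
}

se_attention_bwd <- function(dy, cache, params, cfg) {
  hw <- cache$hw
  N <- cache$N
  dwvec <- blockcolsum_prod_cpp(dy, cache$x, hw)
  dz2 <- dwvec * cache$w * (1 - cache$w)
  dw2 <- crossprod(cache$r1, dz2)
  dr1 <- tcrossprod(dz2, params$se_w2)
  dz1 <- dr1 * (cache$z1 > 0)
  dw1 <- crossprod(cache$sq, dz1)
  dsq <- tcrossprod(dz1, params$se_w1)
  dx <- se_bwd_dx_cpp(dy, cache$w, dsq, hw, 1 / hw)
  out <- list(dx = dx, dw1 = dw1, dw2 = dw2)
  if (cfg$se_bias) {
    out$db1 <- colSums(dz1)
    out$db2 <- colSums(dz2)
  }
  out
}

# Backward pass matching net_forward(keep = TRUE, training = TRUE).
# targets: integer class indices (1-based). Returns gradients for every
# trainable parameter.
net_backward <- function(params, cfg, cache, targets) {
  N <- cache$N
  grads <- list()
  probs <- cache$probs
  dZ <- probs
  dZ[cbind(seq_len(N), targets)] <- dZ[cbind(seq_len(N), targets)] - 1
  dZ <- dZ / N
  grads$fc_w <- crossprod(cache$g, dZ)
  grads$fc_b <- colSums(dZ)
  dg <- tcrossprod(dZ, params$fc_w)

  sp_sizes <- if (cfg$use_fpn) block_spatial(cfg)[cfg$tap_points] else NULL
  dtaps <- NULL
  if (cfg$use_fpn) {
    hb <- cache$head_bn
    bnb <- bn_act_bwd_gap_cpp(dg, cache$hw, hb$x, hb$a, hb$mu, hb$inv,
                              params$head_bn_gamma, FALSE)
    grads$head_bn_gamma <- bnb$dgamma
    grads$head_bn_beta <- bnb$dbeta
    d <- bnb$dx
    if (cfg$use_se) {
      seb <- se_attention_bwd(d, cache$se, params, cfg)
      grads$se_w1 <- seb$dw1
      grads$se_w2 <- seb$dw2
      if (cfg$se_bias) {
        grads$se_b1 <- seb$db1
        grads$se_b2 <- seb$db2
      }
      d <- seb$dx
    }
    nl <- length(cache$taps)
    dL <- vector("list", nl)
    dP <- d  # gradient at P1
    for (i in seq_len(nl - 1L)) {
      dL[[i]] <- dP
      si <- sp_sizes[i + 1L]
      so <- sp_sizes[i]
      dup <- bilinear_resize_bwd_cpp(dP, si, si, N, so, so)
      if (i == 1L && cfg$use_sp) {
        spb <- sp_attention_bwd(dup, cache$sp, params$sp_w, cfg$sp_kernel)
        grads$sp_w <- spb$dw
        grads$sp_b <- spb$db
        dup <- spb$dx
      }
      dP <- dup
    }
    dL[[nl]] <- dP
    dtaps <- vector("list", nl)
    for (i in seq_len(nl)) {
      grads[[paste0("lat", i, "_w")]] <- crossprod(cache$taps[[i]], dL[[i]])
      grads[[paste0("lat", i, "_b")]] <- colSums(dL[[i]])
      dtaps[[i]] <- tcrossprod(dL[[i]], params[[paste0("lat", i, "_w")]])
    }
    da <- NULL
  } else {
    da <- gap_bwd(dg, cache$hw, N)
  }

  tap_at <- match(1:13, cfg$tap_points)
  for (b in 13:1) {
    blk <- cache$blocks[[b]]
    g <- if (is.null(da))
      matrix(0, nrow(blk$bnp$a), ncol(blk$bnp$a)) else da
    if (!is.na(tap_at[b]) && !is.null(dtaps))
      g <- g + dtaps[[tap_at[b]]]
    # pointwise: (ReLU o BN) fused backward, then the 1x1 matmul
    bnb <- bn_act_bwd_cpp(g, blk$bnp$x, blk$bnp$a, blk$bnp$mu, blk$bnp$inv,
                          params[[paste0("pw", b, "_bn_gamma")]], TRUE)
    grads[[paste0("pw", b, "_bn_gamma")]] <- bnb$dgamma
    grads[[paste0("pw", b, "_bn_beta")]] <- bnb$dbeta
    g <- bnb$dx
    grads[[paste0("pw", b, "_w")]] <- crossprod(blk$bnd$a, g)
    g <- tcrossprod(g, params[[paste0("pw", b, "_w")]])
    # depthwise: fused (ReLU o BN) backward, then the depthwise conv
    bnb <- bn_act_bwd_cpp(g, blk$bnd$x, blk$bnd$a, blk$bnd$mu, blk$bnd$inv,
                          params[[paste0("dw", b, "_bn_gamma")]], TRUE)
    grads[[paste0("dw", b, "_bn_gamma")]] <- bnb$dgamma
    grads[[paste0("dw", b, "_bn_beta")]] <- bnb$dbeta
    g <- bnb$dx
    db <- dw_bwd(blk$xin, g, blk$hin, blk$hin, cache$N,
                 params[[paste0("dw", b, "_w")]], 3L, BLOCK_STRIDES[b],
                 blk$h, blk$h)
    grads[[paste0("dw", b, "_w")]] <- db$dw
    da <- db$dx
  }
  # stem: fused (ReLU o BN) backward, then the stem conv (no input grad)
  st <- cache$stem
  bnb <- bn_act_bwd_cpp(da, st$x, st$a, st$mu, st$inv,
                        params$stem_bn_gamma, TRUE)
  grads$stem_bn_gamma <- bnb$dgamma
  grads$stem_bn_beta <- bnb$dbeta
  S <- cfg$input_size
  pads <- conv_pads(3L, 2L)
  grads$stem_w <- conv_direct_dw_cpp(st$input, bnb$dx, S, S, cache$N,
                                     3L, 2L, pads[1L], pads[2L],
                                     st$Ho, st$Ho)
  grads
}

#' @export
print.leafnet_model <- function(x, ...) {
  cfg <- x$config
  flags <- c(if (cfg$use_fpn) "FPN", if (cfg$use_sp) "SP", if (cfg$use_se) "SE")
  cat(sprintf("<leafnet_model> %s, input %d, width x%.2f, %s parameters\n",
              if (length(flags)) paste(c("backbone", flags), collapse = "+")
              else "backbone",
              cfg$input_size, cfg$width_multiplier,
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Classify images with a fitted model
#'
#' @param object a `leafnet_model`.
#' @param images a single image array or list of `input_size` square RGB
#'   arrays in `[0, 1]`.
#' @param type `"prob"` for the softmax matrix, `"class"` for label indices.
#' @param batch_size forward-pass batch size.
#' @param ... unused.
#' @return an N x n_classes probability matrix (rows sum to 1) or an
#'   integer vector of predicted class indices.
#' @export
predict.leafnet_model <- function(object, images, type = c("prob", "class"),
                                  batch_size = 32L, ...) {
  type <- match.arg(type)
  if (is.array(images) && length(dim(images)) == 3L) images <- list(images)
  cfg <- object$config
  for (im in images) check_image_input(im, cfg$input_size)
  n <- length(images)
  out <- matrix(NA_real_, n, cfg$n_classes)
  starts <- seq(1L, n, by = batch_size)
  for (s in starts) {
    idx <- s:min(s + batch_size - 1L, n)
    X <- as_batch(images[idx])
    fw <- net_forward(object$params, cfg, X, length(idx))
    out[idx, ] <- fw$probs
  }
  if (type == "class") max.col(out, ties.method = "first") else out
}
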