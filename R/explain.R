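# Gradient-free model explanations: Score-CAM class activation maps and the
# max-activation overlay used to compare ablation variants.

# Resolve a named activation tap of the model for one image. "feat" is the
# final pre-head feature map (SE output in the full variant, C5 in the
# plain backbone classifier).
model_activation <- function(model, image, layer) {
  cfg <- model$config
  check_image_input(image, cfg$input_size)
  fw <- net_forward(model$params, cfg, img_to_mat(image), 1L,
                    want_maps = TRUE)
  sizes <- block_spatial(cfg)[cfg$tap_points]
  pick <- function(m, h) mat_to_img(m, h, h)
  lt <- tolower(layer)
  if (lt == "feat") {
    h <- if (cfg$use_fpn) sizes[1L] else block_spatial(cfg)[13L]
    return(pick(fw$feat, h))
  }
  if (grepl("^c[1-5]$", lt)) {
    i <- as.integer(substring(lt, 2L))
    return(pick(fw$taps[[i]], sizes[i]))
  }
  if (grepl("^p[1-5]$", lt)) {
    if (!cfg$use_fpn) stopf("layer '%s' requires a pyramid variant", layer)
    i <- as.integer(substring(lt, 2L))
    return(pick(fw$pyramid[[i]], sizes[i]))
  }
  if (lt == "sp") {
    if (is.null(fw$sp_out)) stopf("model has no spatial-attention block")
    return(pick(fw$sp_out, sizes[2L]))
  }
  if (lt == "se") {
    if (is.null(fw$se_out)) stopf("model has no SE block")
    return(pick(fw$se_out, sizes[1L]))
  }
  stopf("unknown layer '%s' (use feat, c1..c5, p1..p5, sp, se)", layer)
}

#' Score-CAM class activation map
#'
#' Gradient-free class activation mapping: each channel of the chosen
#' activation layer is bilinearly upsampled to input size, min-max
#' normalized to `[0, 1]` (a constant channel becomes an all-zero mask) and
#' used to mask the input image; the masked copies are forward-passed and
#' the target class's softmax scores, soft-maxed over channels, become the
#' channel weights. The map is `ReLU` of the weighted channel sum,
#' upsampled to input resolution and min-max normalized. No gradients are
#' required anywhere.
#'
#' @param model a fitted `leafnet_model`.
#' @param image an input-sized H x W x 3 array in `[0, 1]`.
#' @param target_class class index in 1..n_classes (or canonical label).
#' @param layer activation tap name: `"feat"` (default, the feature map
#'   just before global average pooling), `"c1"`..`"c5"`, `"p1"`..`"p5"`,
#'   `"sp"`, `"se"`.
#' @param batch_size how many masked copies per forward pass; the result
#'   is batch-size invariant.
#' @return an H x W heatmap matrix in `[0, 1]` (all zero when the weighted
#'   sum has no positive part).
#' @export
score_cam <- function(model, image, target_class, layer = "feat",
                      batch_size = 16L) {
  cfg <- model$config
  if (is.character(target_class))
    target_class <- match(target_class, leaf_classes()$class)
  if (is.na(target_class) || target_class < 1L ||
      target_class > cfg$n_classes)
    stopf("target_class out of range")
  A <- model_activation(model, image, layer)
  d <- dim(A)
  K <- d[3L]
  S <- cfg$input_size
  masked <- vector("list", K)
  for (k in seq_len(K)) {
    up <- resize_plane(A[, , k], S)
    m <- minmax01(up)
    masked[[k]] <- image * array(rep(m, 3L), dim = c(S, S, 3L))
  }
  scores <- numeric(K)
  for (s in seq(1L, K, by = batch_size)) {
    idx <- s:min(s + batch_size - 1L, K)
    fw <- net_forward(model$params, cfg, as_batch(masked[idx]), length(idx))
    scores[idx] <- fw$probs[, target_class]
  }
  alpha <- exp(scores - max(scores))
  alpha <- alpha / sum(alpha)
  cam <- matrix(0, d[1L], d[2L])
  for (k in seq_len(K)) cam <- cam + alpha[k] * A[, , k]
  cam <- relu(cam)
  minmax01(resize_plane(cam, S))
}

resize_plane <- function(m, size) {
  d <- dim(m)
  out <- bilinear_resize_cpp(matrix(as.vector(m), ncol = 1L),
                             d[1L], d[2L], 1L, size, size)
  matrix(out[, 1L], size, size)
}

#' Warm/cool colormap for heatmaps
#'
#' Maps values in `[0, 1]` from cool blue through cyan, green and yellow to
#' warm red, so regions the model attends to render hot.
#'
#' @param values numeric vector/matrix in `[0, 1]`.
#' @return an array (or matrix) with a trailing RGB dimension.
#' @export
heat_colormap <- function(values) {
  ramp <- grDevices::colorRamp(c("#00007F", "#0000FF", "#00FFFF",
                                 "#00FF00", "#FFFF00", "#FF0000"))
  rgb <- ramp(clip01(as.vector(values))) / 255
  d <- dim(values)
  if (is.null(d)) d <- length(values)
  array(rgb, dim = c(d, 3L))
}

#' Blend a heatmap over an image
#'
#' `out = (1 - alpha) * image + alpha * colormap(heatmap)`, clipped to
#' `[0, 1]`.
#'
#' @param image an H x W x 3 array.
#' @param heatmap an H x W matrix in `[0, 1]`.
#' @param alpha blend weight in `[0, 1]`.
#' @param colormap colormap function (heatmap -> H x W x 3 array).
#' @return an H x W x 3 array.
#' @export
blend_heatmap <- function(image, heatmap, alpha = 0.5,
                          colormap = heat_colormap) {
  if (alpha < 0 || alpha > 1) stopf("alpha must lie in [0, 1]")
  d <- dim(image)
  if (length(dim(heatmap)) != 2L || any(dim(heatmap) != d[1:2]))
    stopf("heatmap shape %s does not match image %dx%d",
          paste(dim(heatmap), collapse = "x"), d[1L], d[2L])
  colored <- colormap(heatmap)
  clip01((1 - alpha) * image + alpha * colored)
}

#' Maximum-activation overlay
#'
#' Takes the per-position maximum over all channels of the chosen
#' activation layer, upsamples the resulting 2-D map to input resolution,
#' min-max normalizes it, colormaps it and alpha-blends it with the input
#' image — the visualization used to compare what each ablation variant
#' attends to.
#'
#' @inheritParams score_cam
#' @param alpha blend weight.
#' @return the blended H x W x 3 array; the normalized heatmap is attached
#'   as attribute `"heatmap"`.
#' @export
max_activation_overlay <- function(model, image, layer = "feat",
                                   alpha = 0.5) {
  A <- model_activation(model, image, layer)
  mx <- apply(A, c(1L, 2L), max)
  hm <- minmax01(resize_plane(mx, model$config$input_size))
  out <- blend_heatmap(image, hm, alpha)
  attr(out, "heatmap") <- hm
  out
}
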