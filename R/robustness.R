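#' Perturbation specification
#'
#' Describes one robustness condition: the perturbation kind, its
#' intensity, and the fraction of the evaluation set it is applied to.
#' Intensities follow the evaluation protocol: Gaussian noise standard
#' deviations 0.1 and 0.5 (in normalized pixel units), brightness factors
#' 0.8 and 1.2, occlusion area ratios 0.3 and 0.5, each crossed with
#' dataset proportions 0.3, 0.7 and 1.0.
#'
#' @param kind one of `"gaussian_noise"`, `"brightness"`, `"occlusion"`.
#' @param intensity noise sigma, brightness factor, or occluded area ratio.
#' @param proportion fraction of the evaluated set perturbed, in (0, 1].
#' @param seed integer seed for subset selection and per-image randomness.
#' @return an object of class `leafnet_perturbation`.
#' @export
perturbation_spec <- function(kind = c("gaussian_noise", "brightness",
                                       "occlusion"),
                              intensity, proportion = 1, seed = 1L) {
  kind <- match.arg(kind)
  if (intensity < 0) stopf("intensity must be >= 0")
  if (kind == "occlusion" && intensity > 1)
    stopf("occlusion ratio must lie in [0, 1]")
  if (proportion <= 0 || proportion > 1)
    stopf("proportion must lie in (0, 1]")
  structure(list(kind = kind, intensity = intensity,
                 proportion = proportion, seed = as.integer(seed)),
            class = "leafnet_perturbation")
}

#' Additive Gaussian pixel noise
#'
#' Adds i.i.d. `N(0, sigma^2)` noise to every pixel and channel, then clips
#' to `[0, 1]`. Deterministic given the seed.
#'
#' @param image an array with values in `[0, 1]`.
#' @param sigma noise standard deviation in normalized pixel units.
#' @param seed integer seed.
#' @return the perturbed array.
#' @export
add_gaussian_noise <- function(image, sigma, seed = 1L) {
  if (sigma < 0) stopf("sigma must be >= 0")
  if (sigma == 0) return(image)
  set.seed(seed)
  clip01(image + array(stats::rnorm(length(image), 0, sigma),
                       dim = dim(image)))
}

#' Multiplicative brightness adjustment
#'
#' @param image an array with values in `[0, 1]`.
#' @param factor positive multiplicative factor; results are clipped to
#'   `[0, 1]`.
#' @return the adjusted array.
#' @export
adjust_brightness <- function(image, factor) {
  if (factor <= 0) stopf("factor must be positive")
  clip01(image * factor)
}

#' Occlude a square image region
#'
#' Blacks out one axis-aligned square patch of side
#' `round(sqrt(ratio * H * W))`, placed uniformly at random fully inside
#' the image, so the zeroed-pixel fraction equals `ratio` up to
#' side-rounding error.
#'
#' @param image an H x W x C array.
#' @param ratio occluded area fraction in `[0, 1]`.
#' @param seed integer seed for patch placement.
#' @return the occluded array.
#' @export
occlude <- function(image, ratio, seed = 1L) {
  if (ratio < 0 || ratio > 1) stopf("ratio must lie in [0, 1]")
  if (ratio == 0) return(image)
  d <- dim(image)
  H <- d[1L]; W <- d[2L]
  side <- round(sqrt(ratio * H * W))
  side <- min(side, H, W)
  set.seed(seed)
  r0 <- sample.int(H - side + 1L, 1L)
  c0 <- sample.int(W - side + 1L, 1L)
  image[r0:(r0 + side - 1L), c0:(c0 + side - 1L), ] <- 0
  image
}

#' Apply a perturbation spec to one image
#'
#' @param image an image array in `[0, 1]`.
#' @param spec a [perturbation_spec()].
#' @param seed overriding seed (defaults to the spec's).
#' @return the perturbed image.
#' @export
apply_perturbation <- function(image, spec, seed = spec$seed) {
  switch(spec$kind,
         gaussian_noise = add_gaussian_noise(image, spec$intensity, seed),
         brightness = adjust_brightness(image, spec$intensity),
         occlusion = occlude(image, spec$intensity, seed))
}

#' Stratified selection of the perturbed subset
#'
#' Chooses `round(proportion * n_class)` items within every class, so the
#' perturbed fraction matches the requested proportion class by class to
#' within rounding.
#'
#' @param ds a [leaf_dataset()].
#' @param proportion fraction in (0, 1].
#' @param seed integer seed.
#' @return integer vector of selected item indices.
#' @export
select_perturb_indices <- function(ds, proportion, seed = 1L) {
  picked <- integer(0)
  for (cl in levels(ds$labels)) {
    idx <- which(ds$labels == cl)
    if (!length(idx)) next
    k <- round(proportion * length(idx))
    if (k == 0L) next
    set.seed(derive_seed(seed, "perturb", match(cl, levels(ds$labels))))
    picked <- c(picked, idx[sample.int(length(idx), k)])
  }
  sort(picked)
}

#' Run the perturbation-robustness grid
#'
#' For every spec, a class-stratified random subset of the evaluation set
#' (of size `proportion * n`) is perturbed while the remaining images stay
#' intact; the model then classifies the full set and per-class accuracy is
#' tabulated. With a zero-intensity spec at proportion 1 the table reduces
#' to the clean per-class accuracy.
#'
#' @param model a fitted `leafnet_model`.
#' @param ds a non-empty labeled [leaf_dataset()]; images are resized to
#'   the model input if needed (perturbations are applied after resizing).
#' @param specs a [perturbation_spec()] or list of them.
#' @param batch_size forward-pass batch size.
#' @return a tidy data.frame with columns `kind`, `intensity`,
#'   `proportion`, `class`, `accuracy`, `n`.
#' @export
run_robustness <- function(model, ds, specs, batch_size = 32L) {
  if (inherits(specs, "leafnet_perturbation")) specs <- list(specs)
  if (length(ds$images) == 0L) stopf("evaluation set is empty")
  size <- model$config$input_size
  ds <- resize_dataset(ds, size)
  y <- dataset_targets(ds)
  out <- list()
  for (spec in specs) {
    imgs <- ds$images
    sel <- select_perturb_indices(ds, spec$proportion, spec$seed)
    for (i in sel)
      imgs[[i]] <- apply_perturbation(ds$images[[i]], spec,
                                      seed = derive_seed(spec$seed, "img", i))
    pred <- integer(length(imgs))
    for (s in seq(1L, length(imgs), by = batch_size)) {
      idx <- s:min(s + batch_size - 1L, length(imgs))
      fw <- net_forward(model$params, model$config, as_batch(imgs[idx]),
                        length(idx))
      pred[idx] <- max.col(fw$probs, ties.method = "first")
    }
    for (cl in levels(ds$labels)) {
      ci <- which(as.integer(ds$labels) == match(cl, levels(ds$labels)))
      if (!length(ci)) next
      out[[length(out) + 1L]] <- data.frame(
        kind = spec$kind, intensity = spec$intensity,
        proportion = spec$proportion, class = cl,
        accuracy = mean(pred[ci] == y[ci]), n = length(ci),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
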