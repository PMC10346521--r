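#' Stratified train/validation/test split
#'
#' Splits a dataset 7:2:1 (by default) within every class. Per class of
#' size n the training partition receives `round(0.7 * n)` items and the
#' validation partition `round(0.2 * n)` items, both under R's
#' round-half-to-even rule, with the remainder going to the test partition;
#' assignment is randomized by `seed`. Items are ordered by their stable
#' ids before shuffling, so the split does not depend on storage order.
#'
#' @param ds a [leaf_dataset()]; every class must be non-empty.
#' @param ratios numeric length-3 vector summing to 1.
#' @param seed integer seed.
#' @return list with elements `train`, `val`, `test` (each a
#'   `leaf_dataset` with its split tag set) and `all`, the input dataset
#'   with a split tag per item.
#' @export
stratified_split <- function(ds, ratios = c(0.7, 0.2, 0.1), seed = 1L) {
  stopifnot(inherits(ds, "leaf_dataset"))
  if (abs(sum(ratios) - 1) > 1e-8 || length(ratios) != 3L)
    stopf("ratios must be three numbers summing to 1")
  counts <- table(ds$labels)
  empty <- names(counts)[counts == 0L]
  if (length(empty))
    stopf("class '%s' has no items", empty[1L])
  split <- character(length(ds$images))
  for (cl in levels(ds$labels)) {
    idx <- which(ds$labels == cl)
    idx <- idx[order(ds$ids[idx])]
    n <- length(idx)
    ntr <- round(ratios[1L] * n)
    nva <- round(ratios[2L] * n)
    nte <- n - ntr - nva
    if (nte < 0L) { nva <- nva + nte; nte <- 0L }
    set.seed(derive_seed(seed, "split", match(cl, levels(ds$labels))))
    idx <- idx[sample.int(n)]
    split[idx] <- rep(c("train", "val", "test"), times = c(ntr, nva, nte))
  }
  all <- ds
  all$split <- split
  list(train = subset_dataset(all, which(split == "train")),
       val = subset_dataset(all, which(split == "val")),
       test = subset_dataset(all, which(split == "test")),
       all = all)
}

#' Offline six-fold augmentation of a training set
#'
#' Expands every image into six items: the original plus five
#' label-preserving variants — 90 and 270 degree rotations, a horizontal
#' mirror, a brightness rescale by a factor drawn uniformly from
#' `[0.8, 1.2]`, and additive Gaussian pixel noise with standard deviation
#' 0.02 (clipped to `[0, 1]`). Randomness is drawn from a per-image seed
#' derived from `seed` and the item id, so the expansion is reproducible
#' item by item. Intended for the training partition only; validation and
#' test data are never augmented.
#'
#' @param ds a [leaf_dataset()].
#' @param seed integer seed.
#' @return a `leaf_dataset` with `6 * length(ds)` items.
#' @export
augment <- function(ds, seed = 1L) {
  stopifnot(inherits(ds, "leaf_dataset"))
  n <- length(ds$images)
  if (n == 0L) return(ds)
  images <- vector("list", 6L * n)
  labels <- character(6L * n)
  ids <- character(6L * n)
  variants <- c("orig", "rot90", "rot270", "mirror", "bright", "noise")
  for (i in seq_len(n)) {
    img <- ds$images[[i]]
    set.seed(derive_seed(seed, "augment", i))
    u <- stats::runif(1L, 0.8, 1.2)
    noise <- array(stats::rnorm(length(img), 0, 0.02), dim = dim(img))
    out <- list(img,
                rotate_image(img, 90L),
                rotate_image(img, 270L),
                mirror_image(img),
                clip01(img * u),
                clip01(img + noise))
    for (v in seq_along(out)) {
      k <- (i - 1L) * 6L + v
      images[[k]] <- out[[v]]
      labels[k] <- as.character(ds$labels[i])
      ids[k] <- paste0(ds$ids[i], "_", variants[v])
    }
  }
  leaf_dataset(images, labels,
               split = if (!is.null(ds$split)) rep(ds$split, each = 6L),
               ids = ids)
}

#' Rotate an image by a right angle
#'
#' @param img an H x W x C array.
#' @param degrees one of 90, 180, 270 (counter-clockwise).
#' @return the rotated array.
#' @export
rotate_image <- function(img, degrees) {
  d <- dim(img)
  out <- switch(as.character(degrees %% 360L),
    "0" = img,
    "90" = aperm(img, c(2L, 1L, 3L))[d[2L]:1, , , drop = FALSE],
    "180" = img[d[1L]:1, d[2L]:1, , drop = FALSE],
    "270" = aperm(img, c(2L, 1L, 3L))[, d[1L]:1, , drop = FALSE],
    stopf("degrees must be a multiple of 90"))
  out
}

#' Mirror an image horizontally
#'
#' @param img an H x W x C array.
#' @return the left-right flipped array.
#' @export
mirror_image <- function(img) {
  img[, dim(img)[2L]:1, , drop = FALSE]
}

#' Bilinearly resize an image to the model input size
#'
#' Uses bilinear interpolation with the half-pixel (align-corners-off)
#' convention. Interpolation is a convex combination, so values stay inside
#' `[0, 1]`.
#'
#' @param image an H x W x 3 array.
#' @param size target square side in pixels.
#' @return a `size` x `size` x 3 array.
#' @export
resize_to_input <- function(image, size = 224L) {
  d <- dim(image)
  if (is.null(d) || length(d) != 3L || d[3L] != 3L)
    stopf("expected an H x W x 3 image")
  if (d[1L] == size && d[2L] == size) return(image)
  mat_to_img(bilinear_resize_cpp(img_to_mat(image), d[1L], d[2L], 1L,
                                 size, size), size, size)
}

#' Resize every image in a dataset
#'
#' @param ds a [leaf_dataset()].
#' @param size target square side.
#' @return the dataset with all images resized.
#' @export
resize_dataset <- function(ds, size) {
  ds$images <- lapply(ds$images, resize_to_input, size = size)
  ds
}

#' Write a dataset as a PNG tree with a CSV manifest
#'
#' Writes images into one directory per class and a `manifest.csv` with
#' columns `path`, `label` and `split`.
#'
#' @param ds a [leaf_dataset()].
#' @param dir output directory (created if missing).
#' @return the manifest data.frame, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(ds$images)
  paths <- character(n)
  for (i in seq_len(n)) {
    cl <- as.character(ds$labels[i])
    cld <- file.path(dir, cl)
    dir.create(cld, showWarnings = FALSE)
    paths[i] <- file.path(cl, paste0(ds$ids[i], ".png"))
    png::writePNG(ds$images[[i]], file.path(dir, paths[i]))
  }
  manifest <- data.frame(path = paths, label = as.character(ds$labels),
                         split = if (is.null(ds$split)) NA_character_
                                 else ds$split,
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$path), ]
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir dataset directory containing `manifest.csv`.
#' @return a [leaf_dataset()].
#' @export
read_dataset <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"),
                       stringsAsFactors = FALSE)
  images <- lapply(manifest$path, function(p) {
    img <- png::readPNG(file.path(dir, p))
    if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
    img[, , 1:3, drop = FALSE]
  })
  split <- manifest$split
  if (all(is.na(split))) split <- NULL
  leaf_dataset(images, manifest$label, split = split,
               ids = sub("\\.png$", "", basename(manifest$path)))
}
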