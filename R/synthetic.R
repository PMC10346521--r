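#' The nine leaf maturity classes
#'
#' Canonical class table: stalk position (lower, middle, upper) crossed with
#' ripeness stage (under-mature, mature, over-mature), ordered by position
#' then maturity stage.
#'
#' @return a data.frame with columns `class` (the canonical label string),
#'   `position` and `maturity`.
#' @export
leaf_classes <- function() {
  positions <- c("lower", "middle", "upper")
  maturities <- c("under", "mature", "over")
  g <- expand.grid(maturity = maturities, position = positions,
                   stringsAsFactors = FALSE)[, 2:1]
  g <- g[order(match(g$position, positions), match(g$maturity, maturities)), ]
  rownames(g) <- NULL
  data.frame(class = paste(g$position, g$maturity, sep = "_"),
             position = g$position, maturity = g$maturity,
             stringsAsFactors = FALSE)
}

#' Field-survey per-class sample counts
#'
#' The nine per-class image counts of the field campaign the synthetic
#' generator emulates, in canonical class order. They sum to 2,159.
#'
#' @return named integer vector of length 9.
#' @export
field_class_counts <- function() {
  cls <- leaf_classes()$class
  counts <- c(lower_under = 215L, lower_mature = 298L, lower_over = 200L,
              middle_under = 248L, middle_mature = 279L, middle_over = 194L,
              upper_under = 251L, upper_mature = 255L, upper_over = 219L)
  counts[cls]
}

#' Configuration of the synthetic leaf-image generator
#'
#' @param per_class_counts nine non-negative counts in canonical class order
#'   (named or unnamed); defaults to the field-survey counts.
#' @param image_size square image side in pixels (>= 32).
#' @param seed integer seed controlling every random element.
#' @param clutter_level background clutter intensity in `[0, 1]`: 0 gives a
#'   plain soil background, 1 a dense cover of weed-like green blobs.
#' @return an object of class `leafnet_synth_config`.
#' @export
synthetic_config <- function(per_class_counts = field_class_counts(),
                             image_size = 224L, seed = 1L,
                             clutter_level = 0.2) {
  if (length(per_class_counts) != 9L || any(per_class_counts < 0))
    stopf("per_class_counts must be nine non-negative counts")
  image_size <- as.integer(image_size)
  if (image_size < 32L) stopf("image_size must be >= 32")
  if (clutter_level < 0 || clutter_level > 1)
    stopf("clutter_level must lie in [0, 1]")
  structure(list(per_class_counts = as.integer(per_class_counts),
                 image_size = image_size, seed = as.integer(seed),
                 clutter_level = clutter_level),
            class = "leafnet_synth_config")
}

# Class appearance: maturity sets the lamina colour (green -> yellow-green
# -> yellow-brown with necrotic spots); position sets leaf size and aspect
# (lower leaves large and broad, upper leaves small and slender).
MATURITY_RGB <- list(
  under  = c(0.18, 0.52, 0.16),
  mature = c(0.52, 0.60, 0.14),
  over   = c(0.66, 0.48, 0.10)
)
POSITION_GEOM <- list(
  lower  = list(a = 0.44, b = 0.30),
  middle = list(a = 0.36, b = 0.22),
  upper  = list(a = 0.27, b = 0.15)
)

#' Generate one synthetic leaf image
#'
#' Draws an elliptical leaf with a midrib and lateral veins over a cluttered
#' soil-and-weeds background. The ripeness stage controls the lamina colour
#' along the green-to-yellow-brown axis (over-mature leaves also carry dark
#' necrotic spots); the stalk position controls leaf size and aspect ratio.
#' The image is fully deterministic given `(cls, seed, size)`.
#'
#' @param cls a class label string (see [leaf_classes()]), or a row index
#'   1..9 into the canonical class table.
#' @param seed integer seed.
#' @param size square image side in pixels.
#' @param clutter_level background clutter intensity in `[0, 1]`.
#' @return a `size` x `size` x 3 array with values in `[0, 1]`.
#' @export
generate_leaf_image <- function(cls, seed, size = 224L,
                                clutter_level = 0.2) {
  tbl <- leaf_classes()
  if (is.numeric(cls)) cls <- tbl$class[cls]
  row <- tbl[tbl$class == cls, ]
  if (nrow(row) != 1L) stopf("unknown class '%s'", cls)
  set.seed(derive_seed(seed, "leafimg", match(cls, tbl$class), size))
  S <- as.integer(size)

  # background: brownish soil with smooth mottle plus weed-like green blobs
  u <- (seq_len(S) - 0.5) / S
  gx <- matrix(u, S, S)
  gy <- t(gx)
  soil <- c(0.38, 0.30, 0.20)
  img <- array(0, dim = c(S, S, 3L))
  mottle <- 0.06 * sin(2 * pi * (3 * gx + runif(1))) *
    cos(2 * pi * (2 * gy + runif(1)))
  for (k in 1:3) img[, , k] <- soil[k] + mottle
  nblob <- round(2 + clutter_level * 14)
  for (i in seq_len(nblob)) {
    cx <- runif(1); cy <- runif(1)
    r <- runif(1, 0.03, 0.10)
    blob <- exp(-(((gx - cx)^2 + (gy - cy)^2) / (2 * r^2)))
    wcol <- c(runif(1, 0.05, 0.25), runif(1, 0.35, 0.60), runif(1, 0.05, 0.2))
    for (k in 1:3) img[, , k] <- img[, , k] * (1 - 0.8 * blob) +
        0.8 * blob * wcol[k]
  }

  # leaf: rotated ellipse
  geom <- POSITION_GEOM[[row$position]]
  a <- geom$a * (1 + runif(1, -0.08, 0.08))
  b <- geom$b * (1 + runif(1, -0.08, 0.08))
  th <- runif(1, -pi / 5, pi / 5)
  cx <- 0.5 + runif(1, -0.05, 0.05)
  cy <- 0.5 + runif(1, -0.05, 0.05)
  xr <- (gx - cx) * cos(th) + (gy - cy) * sin(th)
  yr <- -(gx - cx) * sin(th) + (gy - cy) * cos(th)
  dd <- (xr / a)^2 + (yr / b)^2
  inside <- dd <= 1
  edge <- pmax(0, pmin(1, (1.06 - dd) / 0.12))  # soft rim

  base <- MATURITY_RGB[[row$maturity]]
  lam <- list()
  jitter <- runif(3, -0.03, 0.03)
  for (k in 1:3) lam[[k]] <- clip01(base[k] + jitter[k] + 0.05 * (1 - dd))

  # veins: dark midrib along the major axis plus oblique laterals
  vein <- exp(-(yr / 0.012)^2)
  nlat <- 5L
  for (j in seq_len(nlat)) {
    off <- (j / (nlat + 1) - 0.5) * 2 * a * 0.9
    d_lat <- abs((yr) - 0.55 * (xr - off))
    vein <- vein + 0.7 * exp(-(d_lat / 0.010)^2) * (abs(xr - off) < a * 0.5)
  }
  vein <- pmin(vein, 1)

  for (k in 1:3) {
    leafcol <- lam[[k]] * (1 - 0.45 * vein)
    img[, , k] <- img[, , k] * (1 - edge * inside) +
      leafcol * edge * inside
  }

  # necrotic spots on over-mature leaves
  if (row$maturity == "over") {
    nsp <- 6L
    for (i in seq_len(nsp)) {
      sx <- runif(1, -0.6, 0.6) * a; sy <- runif(1, -0.6, 0.6) * b
      r <- runif(1, 0.015, 0.035)
      spot <- exp(-(((xr - sx)^2 + (yr - sy)^2) / (2 * r^2))) * inside
      for (k in 1:3) img[, , k] <- img[, , k] * (1 - 0.7 * spot) +
          0.7 * spot * c(0.30, 0.18, 0.05)[k]
    }
  }

  img <- img + array(stats::rnorm(S * S * 3L, 0, 0.015), dim = c(S, S, 3L))
  clip01(img)
}

#' Generate a labeled synthetic dataset
#'
#' Generates exactly the requested number of images per class and shuffles
#' them with the configuration seed. Item ids are stable
#' (`<class>_<index>`), so downstream splitting is invariant to storage
#' order.
#'
#' @param config a [synthetic_config()].
#' @return a `leaf_dataset`: list with `images` (list of arrays), `labels`
#'   (factor over the nine canonical classes) and `ids` (character).
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "leafnet_synth_config"))
  cls <- leaf_classes()$class
  images <- list()
  labels <- character(0)
  ids <- character(0)
  for (i in seq_along(cls)) {
    n <- config$per_class_counts[i]
    if (n == 0L) next
    for (j in seq_len(n)) {
      images[[length(images) + 1L]] <-
        generate_leaf_image(cls[i], derive_seed(config$seed, "item", i, j),
                            config$image_size, config$clutter_level)
      labels <- c(labels, cls[i])
      ids <- c(ids, sprintf("%s_%04d", cls[i], j))
    }
  }
  set.seed(derive_seed(config$seed, "shuffle"))
  ord <- sample.int(length(images))
  leaf_dataset(images[ord], labels[ord], ids = ids[ord])
}

#' Construct a leaf dataset object
#'
#' @param images list of H x W x 3 arrays in `[0, 1]`.
#' @param labels character vector or factor of class labels.
#' @param split optional character vector of `train`/`val`/`test` tags.
#' @param ids optional stable item identifiers.
#' @return an object of class `leaf_dataset`.
#' @export
leaf_dataset <- function(images, labels, split = NULL, ids = NULL) {
  if (length(images) != length(labels))
    stopf("images and labels must have the same length")
  labels <- factor(as.character(labels), levels = leaf_classes()$class)
  if (anyNA(labels)) stopf("labels outside the nine-class set")
  if (!is.null(split)) {
    if (length(split) != length(images))
      stopf("split must tag every item")
    if (!all(split %in% c("train", "val", "test")))
      stopf("split tags must be train/val/test")
  }
  if (is.null(ids) && length(images))
    ids <- sprintf("item_%05d", seq_along(images))
  structure(list(images = images, labels = labels, split = split, ids = ids),
            class = "leaf_dataset")
}

#' @export
print.leaf_dataset <- function(x, ...) {
  cat(sprintf("<leaf_dataset> %d images", length(x$images)))
  if (length(x$images)) {
    d <- dim(x$images[[1L]])
    cat(sprintf(", %dx%dx%d", d[1L], d[2L], d[3L]))
  }
  if (!is.null(x$split))
    cat(sprintf(" (train %d / val %d / test %d)",
                sum(x$split == "train"), sum(x$split == "val"),
                sum(x$split == "test")))
  cat("\n")
  if (length(x$images)) print(table(x$labels))
  invisible(x)
}

#' @export
length.leaf_dataset <- function(x) length(x$images)

subset_dataset <- function(ds, idx) {
  leaf_dataset(ds$images[idx], ds$labels[idx],
               split = if (!is.null(ds$split)) ds$split[idx],
               ids = ds$ids[idx])
}
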