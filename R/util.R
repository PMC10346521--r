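#' Derive a reproducible sub-seed from a global seed
#'
#' Every stochastic component (data generation, splitting, augmentation,
#' training shuffles, perturbation placement) draws its own seed from one
#' global seed through this hash, so a single `--seed` fans out to all
#' modules deterministically. The result always lies in `[1, 2^31 - 2]`.
#'
#' @param seed integer global seed.
#' @param ... further integers (or strings, hashed by character codes)
#'   identifying the consumer.
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  parts <- list(...)
  h <- as.double(seed) %% 2147483647
  for (p in parts) {
    if (is.character(p)) p <- sum(utf8ToInt(paste(p, collapse = "")))
    for (v in as.double(p)) {
      h <- (h * 48271 + v + 1) %% 2147483647
    }
  }
  as.integer(h %% 2147483645 + 1)
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) {
  if (is.matrix(x)) return(relu_cpp(x))
  x[x < 0] <- 0
  x
}

#' @noRd
stopf <- function(...) stop(sprintf(...), call. = FALSE)

# Convert one H x W x C image array to the internal (H*W) x C matrix layout.
img_to_mat <- function(img) {
  d <- dim(img)
  matrix(img, d[1L] * d[2L], d[3L])
}

mat_to_img <- function(m, H, W) {
  array(m, dim = c(H, W, ncol(m)))
}

# Stack a list of equally sized H x W x C images into one (H*W*N) x C matrix.
as_batch <- function(images) {
  d <- dim(images[[1L]])
  do.call(rbind, lapply(images, img_to_mat))
}

# Min-max normalize to [0, 1]; a constant map collapses to all zeros.
minmax01 <- function(x, tol = 1e-12) {
  lo <- min(x)
  hi <- max(x)
  if (!is.finite(lo) || !is.finite(hi) || hi - lo < tol) {
    x[] <- 0
    return(x)
  }
  (x - lo) / (hi - lo)
}
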