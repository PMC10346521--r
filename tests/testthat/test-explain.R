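test_that("with a single activation channel the CAM is score-independent", {
  # a one-channel pyramid: softmax over one masked score is always 1, so
  # the heatmap must equal the normalized positive part of that channel
  m <- cached_model("k1", function()
    build_variant(tiny_cfg(pyramid_channels = 1L, se_ratio = 1L)))
  img <- rand_img(32, seed = 6)
  hm <- score_cam(m, img, target_class = 2, layer = "p1")
  A <- leafnet:::model_activation(m, img, "p1")
  ref <- leafnet:::minmax01(leafnet:::resize_plane(pmax(A[, , 1], 0), 32))
  expect_equal(hm, ref, tolerance = 1e-10)
  hm2 <- score_cam(m, img, target_class = 7, layer = "p1")
  expect_equal(hm, hm2, tolerance = 1e-10)
})

test_that("vectorized Score-CAM equals a naive one-channel-at-a-time loop", {
  m <- cached_model("k8", function()
    build_variant(tiny_cfg(pyramid_channels = 8L, se_ratio = 2L, seed = 13)))
  img <- rand_img(32, seed = 14)
  target <- 4L
  hm <- score_cam(m, img, target, layer = "feat", batch_size = 5)

  # independent oracle: loop channels, mask, score through predict()
  A <- leafnet:::model_activation(m, img, "feat")
  K <- dim(A)[3]
  scores <- numeric(K)
  for (k in seq_len(K)) {
    up <- leafnet:::resize_plane(A[, , k], 32)
    rng <- range(up)
    mask <- if (diff(rng) < 1e-12) up * 0 else (up - rng[1]) / diff(rng)
    masked <- img * array(rep(mask, 3), dim = c(32, 32, 3))
    scores[k] <- predict(m, masked)[1, target]
  }
  alpha <- exp(scores - max(scores))
  alpha <- alpha / sum(alpha)
  cam <- matrix(0, dim(A)[1], dim(A)[2])
  for (k in seq_len(K)) cam <- cam + alpha[k] * A[, , k]
  cam <- pmax(cam, 0)
  up <- leafnet:::resize_plane(cam, 32)
  rng <- range(up)
  ref <- if (diff(rng) < 1e-12) up * 0 else (up - rng[1]) / diff(rng)
  expect_equal(hm, ref, tolerance = 1e-5)
})

test_that("Score-CAM is invariant to the masking batch size", {
  m <- tiny_full_model()
  img <- rand_img(32, seed = 15)
  h1 <- score_cam(m, img, 1, batch_size = 1)
  h2 <- score_cam(m, img, 1, batch_size = 64)
  expect_equal(h1, h2, tolerance = 1e-12)
})

test_that("heatmaps satisfy the range contract without NaNs", {
  m <- tiny_full_model()
  for (s in c(3, 4)) {
    hm <- score_cam(m, rand_img(32, seed = s), target_class = s)
    expect_false(anyNA(hm))
    expect_gte(min(hm), 0)
    expect_lte(max(hm), 1)
    expect_true(max(hm) == 1 || all(hm == 0))
  }
  expect_error(score_cam(m, rand_img(32), 99), "out of range")
  expect_error(score_cam(m, rand_img(32), 1, layer = "nope"), "unknown layer")
})

test_that("blending follows the exact convex combination", {
  img <- array(0.25, dim = c(8, 8, 3))
  hm <- matrix(0.5, 8, 8)
  expect_equal(blend_heatmap(img, hm, alpha = 0), img)
  flat_cm <- function(h) array(rep(h, 3), dim = c(dim(h), 3))
  expect_equal(blend_heatmap(img, hm, alpha = 1, colormap = flat_cm),
               array(0.5, dim = c(8, 8, 3)))
  mid <- blend_heatmap(img, hm, alpha = 0.5, colormap = flat_cm)
  expect_true(all(abs(mid - (0.5 * 0.25 + 0.5 * 0.5)) < 1e-12))
  expect_error(blend_heatmap(img, matrix(0, 4, 4), 0.5), "does not match")
  expect_error(blend_heatmap(img, hm, 1.5), "alpha")
})

test_that("bilinear upsampling preserves the location of an isolated peak", {
  hot <- matrix(0, 8, 8)
  hot[6, 3] <- 1
  up <- leafnet:::minmax01(leafnet:::resize_plane(hot, 32))
  peak <- which(up == max(up), arr.ind = TRUE)[1, ]
  # half-pixel mapping sends source cell (6, 3) to rows 21-24 / cols 9-12
  expect_true(peak[1] >= 21 && peak[1] <= 24)
  expect_true(peak[2] >= 9 && peak[2] <= 12)
})

test_that("the max-activation overlay honors shape, range and blending", {
  m <- tiny_full_model()
  img <- rand_img(32, seed = 16)
  out <- max_activation_overlay(m, img, layer = "feat", alpha = 0.4)
  hm <- attr(out, "heatmap")
  expect_equal(dim(out), c(32L, 32L, 3L))
  expect_gte(min(hm), 0)
  expect_lte(max(hm), 1)
  # single-channel constant activation gives a uniform (all-zero) heatmap
  A <- leafnet:::model_activation(m, img, "feat")
  mx <- apply(A, c(1, 2), max)
  expect_equal(dim(mx), dim(A)[1:2])
  passthrough <- max_activation_overlay(m, img, layer = "feat", alpha = 0)
  expect_equal(as.vector(passthrough), as.vector(img), tolerance = 1e-12)
})
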