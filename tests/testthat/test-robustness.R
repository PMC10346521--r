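test_that("gaussian noise has the requested strength and is seed-stable", {
  img <- array(0.5, dim = c(64, 64, 3))
  expect_identical(add_gaussian_noise(img, 0, seed = 1), img)
  n1 <- add_gaussian_noise(img, 0.1, seed = 42)
  n2 <- add_gaussian_noise(img, 0.1, seed = 42)
  expect_identical(n1, n2)
  # at sigma 0.1 around 0.5 clipping is negligible: sample sd matches sigma
  expect_lt(abs(sd(n1 - img) - 0.1), 0.01)
  expect_true(min(n1) >= 0 && max(n1) <= 1)
  expect_error(add_gaussian_noise(img, -0.1), ">= 0")
})

test_that("brightness adjustment multiplies and clips", {
  img <- array(0.5, dim = c(8, 8, 3))
  expect_identical(adjust_brightness(img, 1), img)
  expect_true(all(abs(adjust_brightness(img, 0.8) - 0.4) < 1e-12))
  bright <- adjust_brightness(array(0.9, dim = c(8, 8, 3)), 1.2)
  expect_true(all(bright == 1))
  expect_error(adjust_brightness(img, 0), "positive")
})

test_that("occlusion blacks out the requested area fraction", {
  set.seed(1)
  img <- array(runif(224 * 224 * 3, min = 0.2, max = 1), dim = c(224, 224, 3))
  expect_identical(occlude(img, 0, seed = 1), img)

  occ <- occlude(img, 0.5, seed = 7)
  zeros <- sum(occ[, , 1] == 0)
  expect_equal(zeros, 158L^2)  # round(sqrt(0.5 * 224^2)) = 158
  expect_lt(abs(zeros / (224 * 224) - 0.5), 0.01)

  dark <- occlude(img, 1, seed = 3)
  expect_true(all(dark == 0))
  expect_error(occlude(img, 1.5), "\\[0, 1\\]")
})

test_that("perturbed-subset selection is stratified and reproducible", {
  counts <- c(20L, rep(10L, 8L))  # 100 items
  ds <- dummy_dataset(counts)
  sel <- select_perturb_indices(ds, 0.3, seed = 4)
  expect_equal(length(sel), 30L)
  per_class <- table(ds$labels[sel])
  expect_equal(as.vector(per_class), as.vector(round(0.3 * counts)))
  expect_identical(sel, select_perturb_indices(ds, 0.3, seed = 4))
  # per-class deviation from the exact proportion is below one item
  expect_true(all(abs(as.vector(per_class) - 0.3 * counts) < 1))
})

test_that("perturbation specs validate their fields", {
  expect_error(perturbation_spec("occlusion", 1.5), "ratio")
  expect_error(perturbation_spec("gaussian_noise", 0.1, proportion = 0),
               "proportion")
  s <- perturbation_spec("brightness", 0.8, proportion = 0.7, seed = 2)
  expect_s3_class(s, "leafnet_perturbation")
})

test_that("an identity spec reproduces the clean per-class accuracy", {
  ds <- small_leaf_ds(n_per_class = 2L, size = 32L, seed = 23)
  m <- tiny_full_model()
  tbl <- run_robustness(m, ds, perturbation_spec("gaussian_noise", 0,
                                                 proportion = 1, seed = 1))
  expect_equal(nrow(tbl), 9L)
  pred <- predict(m, ds$images, type = "class")
  clean <- sapply(levels(ds$labels), function(cl) {
    idx <- which(as.character(ds$labels) == cl)
    mean(pred[idx] == as.integer(ds$labels)[idx])
  })
  expect_equal(tbl$accuracy, as.vector(clean[tbl$class]))
})

test_that("the robustness grid emits one row per spec and class", {
  ds <- small_leaf_ds(n_per_class = 2L, size = 32L, seed = 24)
  specs <- list(perturbation_spec("brightness", 0.8, 0.7, seed = 1),
                perturbation_spec("occlusion", 0.3, 1, seed = 2))
  tbl <- run_robustness(tiny_full_model(), ds, specs)
  expect_equal(nrow(tbl), 18L)
  expect_setequal(unique(tbl$kind), c("brightness", "occlusion"))
  expect_true(all(tbl$accuracy >= 0 & tbl$accuracy <= 1))
  expect_true(all(tbl$n == 2L))
  expect_error(run_robustness(tiny_full_model(),
                              leaf_dataset(list(), character(0)), specs),
               "empty")
})

test_that("all perturbations preserve shape and the [0,1] range", {
  set.seed(9)
  img <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  for (spec in list(perturbation_spec("gaussian_noise", 0.5, seed = 1),
                    perturbation_spec("brightness", 1.2),
                    perturbation_spec("occlusion", 0.3, seed = 1))) {
    out <- apply_perturbation(img, spec)
    expect_identical(dim(out), dim(img))
    expect_true(min(out) >= 0 && max(out) <= 1)
  }
})
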