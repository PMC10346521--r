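test_that("stratified 7:2:1 split of the field counts yields 1,511 training items", {
  ds <- dummy_dataset(field_class_counts())
  sp <- stratified_split(ds, seed = 1)
  expect_equal(length(sp$train$images), 1511L)
  expect_equal(length(sp$train$images) + length(sp$val$images) +
                 length(sp$test$images), 2159L)
  # per-class train allocation follows round-half-to-even of 0.7 n
  tr_counts <- as.vector(table(sp$train$labels))
  expect_equal(tr_counts, as.vector(round(0.7 * field_class_counts())))
})

test_that("a class of ten splits 7/2/1", {
  counts <- rep(10L, 9L)
  sp <- stratified_split(dummy_dataset(counts), seed = 3)
  expect_equal(as.vector(table(sp$train$labels)), rep(7L, 9L))
  expect_equal(as.vector(table(sp$val$labels)), rep(2L, 9L))
  expect_equal(as.vector(table(sp$test$labels)), rep(1L, 9L))
})

test_that("the split partitions the dataset without duplication", {
  ds <- dummy_dataset(c(5L, 8L, 13L, 21L, 3L, 7L, 11L, 2L, 9L))
  sp <- stratified_split(ds, seed = 5)
  ids <- c(sp$train$ids, sp$val$ids, sp$test$ids)
  expect_setequal(ids, ds$ids)
  expect_equal(anyDuplicated(ids), 0L)
})

test_that("the split depends on item ids, not storage order", {
  ds <- dummy_dataset(rep(10L, 9L))
  sp1 <- stratified_split(ds, seed = 11)
  perm <- sample(length(ds$images))
  ds2 <- leaf_dataset(ds$images[perm], ds$labels[perm], ids = ds$ids[perm])
  sp2 <- stratified_split(ds2, seed = 11)
  a1 <- setNames(sp1$all$split, sp1$all$ids)
  a2 <- setNames(sp2$all$split, sp2$all$ids)
  expect_identical(a1[sort(names(a1))], a2[sort(names(a2))])
})

test_that("an empty class aborts the split with its name", {
  counts <- field_class_counts()
  counts["middle_over"] <- 0L
  expect_error(stratified_split(dummy_dataset(counts), seed = 1),
               "middle_over")
})

test_that("offline augmentation expands 1,511 items to 9,066", {
  ds <- dummy_dataset(field_class_counts())
  sp <- stratified_split(ds, seed = 1)
  aug <- augment(sp$train, seed = 2)
  expect_equal(length(aug$images), 9066L)
  # every class histogram scales by exactly six
  expect_equal(as.vector(table(aug$labels)),
               6L * as.vector(table(sp$train$labels)))
  # every original appears exactly once
  expect_equal(sum(grepl("_orig$", aug$ids)), 1511L)
})

test_that("augmentation preserves labels, multiplies by six, and is seed-stable", {
  ds <- dummy_dataset(c(2L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L))
  aug <- augment(ds, seed = 9)
  expect_equal(length(aug$images), 60L)
  expect_equal(as.character(aug$labels), rep(as.character(ds$labels), each = 6))
  expect_identical(augment(ds, seed = 9)$images, aug$images)
  empty <- subset_empty <- leaf_dataset(list(), character(0))
  expect_equal(length(augment(empty, seed = 1)$images), 0L)
})

test_that("augmentation variants are the advertised transforms", {
  set.seed(42)
  img <- array(runif(4 * 4 * 3), dim = c(4, 4, 3))
  ds <- leaf_dataset(list(img), "upper_mature", ids = "x")
  aug <- augment(ds, seed = 21)
  expect_identical(aug$images[[1]], img)
  expect_identical(aug$images[[2]], rotate_image(img, 90))
  expect_identical(aug$images[[3]], rotate_image(img, 270))
  expect_identical(aug$images[[4]], mirror_image(img))
  # brightness variant is a clipped scalar multiple of the original
  ratio <- aug$images[[5]] / img
  expect_lt(diff(range(ratio[aug$images[[5]] < 1])), 1e-9)
  # noise variant differs but stays in range
  expect_false(identical(aug$images[[6]], img))
  expect_true(min(aug$images[[6]]) >= 0 && max(aug$images[[6]]) <= 1)
})

test_that("right-angle rotations and mirroring are exact inverses", {
  img <- array(runif(6 * 4 * 3), dim = c(6, 4, 3))
  expect_identical(rotate_image(rotate_image(img, 90), 270), img)
  expect_identical(mirror_image(mirror_image(img)), img)
  expect_identical(rotate_image(img, 180),
                   rotate_image(rotate_image(img, 90), 90))
})

test_that("bilinear resize honors the sampling contract", {
  img <- array(runif(224 * 224 * 3), dim = c(224, 224, 3))
  expect_identical(resize_to_input(img, 224), img)

  cst <- array(0.37, dim = c(448, 448, 3))
  out <- resize_to_input(cst, 224)
  expect_equal(dim(out), c(224L, 224L, 3L))
  expect_true(all(abs(out - 0.37) < 1e-12))

  # 2x2 checkerboard upsampled to 4x4: corner pixels keep the source values
  # under the half-pixel convention
  chk <- array(0, dim = c(2, 2, 3))
  chk[1, 1, ] <- 1
  chk[2, 2, ] <- 1
  up <- resize_to_input(chk, 4)
  expect_equal(up[1, 1, 1], 1)
  expect_equal(up[4, 4, 1], 1)
  expect_equal(up[1, 4, 1], 0)
  expect_equal(up[4, 1, 1], 0)

  expect_error(resize_to_input(array(0, c(4, 4, 2)), 8), "H x W x 3")
})
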