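test_that("confusion matrix counts land in the right cells", {
  cls <- leaf_classes()$class
  cm <- confusion(cls, cls)
  expect_true(all(diag(cm) == 1L))
  expect_equal(sum(cm), 9L)

  cm2 <- confusion(c(1L, 2L, 3L), c(1L, 1L, 1L))
  expect_equal(sum(cm2[, 1]), 3L)

  set.seed(31)
  truth <- sample(cls, 200, replace = TRUE)
  pred <- sample(cls, 200, replace = TRUE)
  expect_equal(sum(confusion(truth, pred)), 200L)

  expect_error(confusion(c("lower_under"), c("mystery")), "outside")
  expect_error(confusion(cls, cls[1:3]), "same length")
})

test_that("classification metrics reproduce direct arithmetic", {
  cm <- matrix(c(1L, 0L, 1L, 2L), 2, 2,
               dimnames = list(truth = c("a", "b"), predicted = c("a", "b")))
  r <- classification_metrics(cm)
  expect_equal(r$accuracy, 3 / 4)
  expect_equal(r$per_class$precision[1], 1.0)
  expect_equal(r$per_class$recall[1], 0.5)
  expect_equal(r$per_class$f1[1], 2 / 3)

  diag9 <- diag(3L, 9)
  dimnames(diag9) <- list(leaf_classes()$class, leaf_classes()$class)
  rp <- classification_metrics(diag9)
  expect_equal(rp$accuracy, 1)
  expect_equal(rp$macro_f1, 1)
})

test_that("0/0 precision or recall scores zero with a warning", {
  cm <- matrix(c(2L, 0L, 1L, 0L), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  expect_warning(r <- classification_metrics(cm), "undefined")
  expect_equal(r$per_class$recall[2], 0)
})

test_that("macro metrics are invariant under class relabeling", {
  set.seed(5)
  truth <- sample(leaf_classes()$class, 120, replace = TRUE)
  pred <- sample(leaf_classes()$class, 120, replace = TRUE)
  m1 <- classification_metrics(confusion(truth, pred))
  perm <- sample(9)
  relab <- setNames(leaf_classes()$class[perm], leaf_classes()$class)
  m2 <- classification_metrics(confusion(relab[truth], relab[pred]))
  expect_equal(m1$macro_f1, m2$macro_f1)
  expect_equal(m1$accuracy, m2$accuracy)
})

test_that("average precision matches hand-enumerated PR steps", {
  expect_equal(average_precision(c(0.9, 0.8, 0.7, 0.6), c(1, 1, 0, 0)), 1)
  expect_equal(average_precision(c(0.9, 0.8, 0.7), c(1, 0, 1)),
               (1 + 2 / 3) / 2)
  # rank statistic: strictly monotone rescaling changes nothing
  s <- runif(30)
  l <- rbinom(30, 1, 0.4)
  if (sum(l) == 0) l[1] <- 1
  expect_equal(average_precision(s, l), average_precision(exp(3 * s), l))
  expect_error(average_precision(c(1, 2), c(0, 0)), "positive")
})

test_that("the step estimator agrees with threshold enumeration", {
  # independent oracle: walk every distinct score threshold, trace the PR
  # curve and accumulate area as sum of precision * recall increments
  brute_ap <- function(scores, labels) {
    npos <- sum(labels)
    area <- 0
    prev_recall <- 0
    for (t in sort(unique(scores), decreasing = TRUE)) {
      sel <- scores >= t
      tp <- sum(labels[sel])
      prec <- tp / sum(sel)
      recall <- tp / npos
      area <- area + prec * (recall - prev_recall)
      prev_recall <- recall
    }
    area
  }
  set.seed(77)
  for (rep in 1:30) {
    n <- sample(3:20, 1)
    scores <- runif(n)                    # distinct almost surely
    labels <- rbinom(n, 1, 0.5)
    if (sum(labels) == 0) labels[sample(n, 1)] <- 1
    expect_equal(average_precision(scores, labels), brute_ap(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("mAP averages one-vs-rest APs and skips empty classes", {
  set.seed(8)
  n <- 40
  truth <- sample(leaf_classes()$class[1:4], n, replace = TRUE)
  prob <- matrix(runif(n * 9), n, 9,
                 dimnames = list(NULL, leaf_classes()$class))
  expect_warning(r <- mean_ap(prob, truth), "without positives")
  expect_equal(sum(is.na(r$per_class_ap)), 5L)
  expect_equal(r$map, mean(r$per_class_ap, na.rm = TRUE))

  # perfect scores give mAP 1
  onehot <- diag(9)[match(truth, leaf_classes()$class), ]
  colnames(onehot) <- leaf_classes()$class
  expect_warning(rp <- mean_ap(onehot, truth))
  expect_equal(rp$map, 1)
})

test_that("metric report ties the pieces together on a tiny model", {
  ds <- small_leaf_ds(n_per_class = 2L, size = 32L, seed = 16)
  rep <- suppressWarnings(metrics_report(tiny_full_model(), ds))
  expect_equal(sum(rep$confusion), 18L)
  expect_true(rep$accuracy >= 0 && rep$accuracy <= 1)
  expect_true(all(rep$per_class$f1 <=
                    pmax(rep$per_class$precision, rep$per_class$recall) + 1e-12))
})

test_that("throughput measurement returns a positive rate", {
  imgs <- list(rand_img(32, 1), rand_img(32, 2))
  fps <- measure_fps(tiny_base_model(), imgs, n = 2)
  expect_true(is.finite(fps) && fps > 0)
  expect_error(measure_fps(tiny_base_model(), imgs, n = 0), ">= 1")
})
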