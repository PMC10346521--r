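test_that("plateau schedule follows the halving rule", {
  st <- list(best = Inf, wait = 0L, lr = 1e-3)
  for (l in c(1.0, 0.9, 0.8)) st <- plateau_update(st, l)
  expect_equal(st$lr, 1e-3)           # steady improvement: untouched

  st <- list(best = Inf, wait = 0L, lr = 1e-3)
  for (l in c(1.0, rep(1.0, 5))) st <- plateau_update(st, l)
  expect_equal(st$lr, 5e-4)           # five stalled epochs: halved once

  st <- list(best = Inf, wait = 0L, lr = 1e-3)
  for (l in c(1.0, rep(1.0, 10))) st <- plateau_update(st, l)
  expect_equal(st$lr, 2.5e-4)         # ten stalled epochs: quartered
})

test_that("plateau schedule matches a direct simulation on random sequences", {
  simulate <- function(losses, lr0, patience, factor) {
    best <- Inf; wait <- 0L; lr <- lr0
    for (l in losses) {
      if (l < best) { best <- l; wait <- 0L }
      else {
        wait <- wait + 1L
        if (wait >= patience) { lr <- lr * factor; wait <- 0L }
      }
    }
    lr
  }
  set.seed(99)
  for (rep in 1:25) {
    losses <- round(runif(sample(5:40, 1), 0.5, 1.5), 2)  # rounded: many ties
    patience <- sample(2:6, 1)
    st <- list(best = Inf, wait = 0L, lr = 1)
    for (l in losses) st <- plateau_update(st, l, patience, 0.5)
    expect_equal(st$lr, simulate(losses, 1, patience, 0.5))
  }
})

test_that("training records one step per batch and a non-increasing lr", {
  ds <- small_leaf_ds(n_per_class = 1L, size = 32L, seed = 8)
  m <- tiny_full_model()
  res <- train(m, ds, ds, train_config(epochs = 1, batch_size = 32, seed = 1))
  expect_equal(res$history$steps, 1L)  # nine images, one batch, one step

  res3 <- train(m, ds, ds, train_config(epochs = 3, batch_size = 4, seed = 1))
  expect_equal(nrow(res3$history), 3L)
  expect_equal(utils::tail(res3$history$steps, 1), 3L * ceiling(9 / 4))
  expect_true(all(diff(res3$history$lr) <= 0))
})

test_that("training on an easy tiny set reduces the loss", {
  ds <- small_leaf_ds(n_per_class = 3L, size = 32L, seed = 12, clutter = 0)
  m <- build_variant(tiny_cfg(seed = 21))
  res <- train(m, ds, ds, train_config(epochs = 5, learning_rate = 2e-3,
                                       seed = 2))
  h <- res$history
  expect_lt(utils::tail(h$train_loss, 1), h$train_loss[1])
  expect_equal(nrow(h), 5L)
})

test_that("empty datasets are rejected", {
  empty <- leaf_dataset(list(), character(0))
  ds <- small_leaf_ds(1L, 32L, seed = 1)
  expect_error(train(tiny_full_model(), empty, ds, train_config(epochs = 1)),
               "non-empty")
})

test_that("the optimizer grid reports one summarized row per cell", {
  ds <- small_leaf_ds(n_per_class = 1L, size = 32L, seed = 14)
  builder <- function() build_variant(tiny_cfg(seed = 31))
  g1 <- optimizer_grid(builder, ds, ds, optimizers = "adam",
                       learning_rates = 5e-4,
                       cfg = train_config(epochs = 1, seed = 1))
  expect_equal(nrow(g1), 1L)

  g <- optimizer_grid(builder, ds, ds,
                      optimizers = c("sgd", "adam"),
                      learning_rates = c(5e-3, 5e-4),
                      cfg = train_config(epochs = 2, seed = 1))
  expect_equal(nrow(g), 4L)
  expect_true(all(is.na(g$error)))
  hists <- attr(g, "histories")
  expect_equal(length(hists), 4L)
  for (i in seq_len(4)) {
    expect_equal(nrow(hists[[i]]), 2L)
    # the summary is the final-five-epoch mean of the validation metrics
    expect_equal(g$final_acc[i], mean(utils::tail(hists[[i]]$val_acc, 5)))
    expect_equal(g$final_loss[i], mean(utils::tail(hists[[i]]$val_loss, 5)))
  }
})

test_that("per-cell failures do not abort the grid", {
  ds <- small_leaf_ds(n_per_class = 1L, size = 32L, seed = 14)
  bad_builder <- function() stop("builder exploded")
  g <- optimizer_grid(bad_builder, ds, ds, optimizers = "adam",
                      learning_rates = 5e-4,
                      cfg = train_config(epochs = 1))
  expect_equal(nrow(g), 1L)
  expect_match(g$error[1], "exploded")
  expect_true(is.na(g$final_acc[1]))
  expect_error(optimizer_grid(bad_builder, ds, ds, optimizers = character(0)),
               "non-empty")
})

test_that("a fixed batch yields a reproducible loss under fixed weights", {
  ds <- small_leaf_ds(n_per_class = 1L, size = 32L, seed = 20)
  m <- tiny_full_model()
  X <- leafnet:::as_batch(ds$images)
  y <- as.integer(ds$labels)
  f1 <- leafnet:::net_forward(m$params, m$config, X, length(y), training = TRUE)
  f2 <- leafnet:::net_forward(m$params, m$config, X, length(y), training = TRUE)
  expect_identical(leafnet:::cross_entropy(f1$probs, y),
                   leafnet:::cross_entropy(f2$probs, y))
})
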