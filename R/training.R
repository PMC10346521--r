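#' Training protocol configuration
#'
#' Mirrors the study's training protocol: minibatches of 32, 30 epochs,
#' categorical cross-entropy, and a reduce-on-plateau schedule that halves
#' the learning rate after five consecutive epochs without a strict
#' decrease of the validation loss. The optimizer grid spans SGD, RMSprop
#' and Adam at initial learning rates 5e-3, 5e-4 and 5e-5; the default cell
#' is Adam at 5e-4, the combination the study settled on.
#'
#' @param batch_size minibatch size.
#' @param epochs number of epochs.
#' @param optimizer one of `"adam"`, `"rmsprop"`, `"sgd"`.
#' @param learning_rate initial learning rate.
#' @param plateau_patience epochs without improvement before halving.
#' @param plateau_factor multiplicative learning-rate decay on plateau.
#' @param seed integer seed controlling shuffling (and any weight draws).
#' @return an object of class `leafnet_train_config`.
#' @export
train_config <- function(batch_size = 32L, epochs = 30L,
                         optimizer = c("adam", "rmsprop", "sgd"),
                         learning_rate = 5e-4, plateau_patience = 5L,
                         plateau_factor = 0.5, seed = 1L) {
  optimizer <- match.arg(optimizer)
  if (batch_size < 1L) stopf("batch_size must be >= 1")
  if (plateau_factor <= 0 || plateau_factor >= 1)
    stopf("plateau_factor must lie in (0, 1)")
  if (learning_rate <= 0) stopf("learning_rate must be positive")
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), optimizer = optimizer,
                 learning_rate = learning_rate,
                 plateau_patience = as.integer(plateau_patience),
                 plateau_factor = plateau_factor, seed = as.integer(seed)),
            class = "leafnet_train_config")
}

#' Reduce-on-plateau learning-rate update
#'
#' Pure one-step update of the plateau schedule state. An epoch improves
#' when its validation loss is strictly lower than the best seen so far
#' (ties count as non-improvement); improvement resets the counter and the
#' best. Once `patience` consecutive non-improving epochs accumulate, the
#' learning rate is multiplied by `factor` and the counter resets.
#'
#' @param state list with `best` (best validation loss so far, `Inf`
#'   initially), `wait` (non-improving epochs since the last improvement or
#'   decay) and `lr` (current learning rate).
#' @param val_loss this epoch's validation loss.
#' @param patience consecutive non-improving epochs tolerated.
#' @param factor decay multiplier in (0, 1).
#' @return the updated state list.
#' @export
plateau_update <- function(state, val_loss, patience = 5L, factor = 0.5) {
  stopifnot(state$lr > 0)
  if (val_loss < state$best) {
    state$best <- val_loss
    state$wait <- 0L
  } else {
    state$wait <- state$wait + 1L
    if (state$wait >= patience) {
      state$lr <- state$lr * factor
      state$wait <- 0L
    }
  }
  state
}

opt_init <- function(optimizer, params, names) {
  st <- list(kind = optimizer, t = 0L)
  if (optimizer %in% c("adam", "rmsprop"))
    st$v <- lapply(params[names], function(p) p * 0)
  if (optimizer == "adam")
    st$m <- lapply(params[names], function(p) p * 0)
  st
}

opt_step <- function(st, params, grads, lr) {
  eps <- 1e-7
  if (st$kind == "sgd") {
    for (nm in names(grads))
      params[[nm]] <- params[[nm]] - lr * grads[[nm]]
  } else if (st$kind == "rmsprop") {
    rho <- 0.9
    for (nm in names(grads)) {
      st$v[[nm]] <- rho * st$v[[nm]] + (1 - rho) * grads[[nm]]^2
      params[[nm]] <- params[[nm]] - lr * grads[[nm]] / (sqrt(st$v[[nm]]) + eps)
    }
  } else {
    b1 <- 0.9; b2 <- 0.999
    st$t <- st$t + 1L
    bc1 <- 1 - b1^st$t
    bc2 <- 1 - b2^st$t
    for (nm in names(grads)) {
      st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * grads[[nm]]
      st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * grads[[nm]]^2
      mhat <- st$m[[nm]] / bc1
      vhat <- st$v[[nm]] / bc2
      params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(state = st, params = params)
}

dataset_targets <- function(ds) as.integer(ds$labels)

#' Train a classifier variant
#'
#' Minimizes categorical cross-entropy with minibatch gradient descent
#' under the configured optimizer, applying the reduce-on-plateau schedule
#' on the validation loss after every epoch. Data order is deterministic
#' given the seed; a non-finite loss aborts with a diagnostic.
#'
#' @param model a `leafnet_model` from [build_variant()].
#' @param train_ds,val_ds non-empty [leaf_dataset()]s whose images match
#'   the model input size.
#' @param cfg a [train_config()].
#' @param verbose print one line per epoch.
#' @return list with `model` (fitted) and `history`, a data.frame with one
#'   row per epoch: train/val loss and accuracy, learning rate, and the
#'   cumulative optimizer step count.
#' @export
train <- function(model, train_ds, val_ds, cfg = train_config(),
                  verbose = FALSE) {
  stopifnot(inherits(model, "leafnet_model"),
            inherits(cfg, "leafnet_train_config"))
  if (length(train_ds$images) == 0L || length(val_ds$images) == 0L)
    stopf("training and validation sets must be non-empty")
  mcfg <- model$config
  for (im in train_ds$images[1]) check_image_input(im, mcfg$input_size)
  params <- model$params
  tn <- trainable_names(params)
  opt <- opt_init(cfg$optimizer, params, tn)
  y_tr <- dataset_targets(train_ds)
  y_va <- dataset_targets(val_ds)
  n <- length(train_ds$images)
  state <- list(best = Inf, wait = 0L, lr = cfg$learning_rate)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     train_acc = numeric(0), val_loss = numeric(0),
                     val_acc = numeric(0), lr = numeric(0),
                     steps = integer(0))
  steps <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    set.seed(derive_seed(cfg$seed, "epoch", epoch))
    ord <- sample.int(n)
    starts <- seq(1L, n, by = cfg$batch_size)
    tl <- 0; tc <- 0
    for (s in starts) {
      idx <- ord[s:min(s + cfg$batch_size - 1L, n)]
      X <- as_batch(train_ds$images[idx])
      fw <- net_forward(params, mcfg, X, length(idx), training = TRUE,
                        keep = TRUE)
      loss <- cross_entropy(fw$probs, y_tr[idx])
      if (!is.finite(loss))
        stopf("non-finite training loss at epoch %d; try a lower learning rate",
              epoch)
      grads <- net_backward(params, mcfg, fw$cache, y_tr[idx])
      res <- opt_step(opt, params, grads, state$lr)
      opt <- res$state
      params <- res$params
      for (nm in names(fw$bn_new)) params[[nm]] <- fw$bn_new[[nm]]
      steps <- steps + 1L
      tl <- tl + loss * length(idx)
      tc <- tc + sum(max.col(fw$probs, ties.method = "first") == y_tr[idx])
    }
    ev <- evaluate_params(params, mcfg, val_ds$images, y_va, cfg$batch_size)
    hist <- rbind(hist, data.frame(
      epoch = epoch, train_loss = tl / n, train_acc = tc / n,
      val_loss = ev$loss, val_acc = ev$acc, lr = state$lr, steps = steps))
    if (verbose)
      message(sprintf(
        "epoch %2d  loss %.4f acc %.3f | val loss %.4f acc %.3f | lr %.2e",
        epoch, tl / n, tc / n, ev$loss, ev$acc, state$lr))
    state <- plateau_update(state, ev$loss, cfg$plateau_patience,
                            cfg$plateau_factor)
  }
  model$params <- params
  list(model = model, history = hist)
}

evaluate_params <- function(params, mcfg, images, targets, batch_size = 32L) {
  n <- length(images)
  loss <- 0; correct <- 0
  for (s in seq(1L, n, by = batch_size)) {
    idx <- s:min(s + batch_size - 1L, n)
    X <- as_batch(images[idx])
    fw <- net_forward(params, mcfg, X, length(idx))
    loss <- loss + cross_entropy(fw$probs, targets[idx]) * length(idx)
    correct <- correct +
      sum(max.col(fw$probs, ties.method = "first") == targets[idx])
  }
  list(loss = loss / n, acc = correct / n)
}

#' Evaluate a model on a labeled dataset
#'
#' @param model a `leafnet_model`.
#' @param ds a [leaf_dataset()].
#' @param batch_size forward-pass batch size.
#' @return list with `loss` (mean cross-entropy) and `acc` (accuracy).
#' @export
evaluate <- function(model, ds, batch_size = 32L) {
  evaluate_params(model$params, model$config, ds$images,
                  dataset_targets(ds), batch_size)
}

#' Run the optimizer / learning-rate grid
#'
#' Trains one model per grid cell (optimizer x initial learning rate) and
#' summarizes each with the mean accuracy and loss over the final five
#' epochs (or all epochs when fewer than five were run). Per-cell failures
#' are caught and reported as `NA` rows rather than aborting the grid.
#'
#' @param builder zero-argument function returning a fresh
#'   `leafnet_model` (a fresh model per cell keeps cells independent).
#' @param train_ds,val_ds datasets passed to [train()].
#' @param optimizers character vector of optimizer names.
#' @param learning_rates numeric vector of initial learning rates.
#' @param cfg base [train_config()]; its optimizer and learning rate are
#'   overridden per cell.
#' @return data.frame with one row per cell: `optimizer`, `learning_rate`,
#'   `final_acc`, `final_loss` (final-five-epoch means of the validation
#'   metrics) and `error` (message or `NA`); the per-cell histories are
#'   attached as the `"histories"` attribute.
#' @export
optimizer_grid <- function(builder, train_ds, val_ds,
                           optimizers = c("sgd", "rmsprop", "adam"),
                           learning_rates = c(5e-3, 5e-4, 5e-5),
                           cfg = train_config()) {
  if (!length(optimizers) || !length(learning_rates))
    stopf("grid must be non-empty")
  cells <- expand.grid(optimizer = optimizers,
                       learning_rate = learning_rates,
                       stringsAsFactors = FALSE)
  histories <- vector("list", nrow(cells))
  out <- cells
  out$final_acc <- NA_real_
  out$final_loss <- NA_real_
  out$error <- NA_character_
  for (i in seq_len(nrow(cells))) {
    ccfg <- cfg
    ccfg$optimizer <- cells$optimizer[i]
    ccfg$learning_rate <- cells$learning_rate[i]
    res <- tryCatch(train(builder(), train_ds, val_ds, ccfg),
                    error = function(e) e)
    if (inherits(res, "error")) {
      out$error[i] <- conditionMessage(res)
      next
    }
    h <- res$history
    histories[[i]] <- h
    last <- utils::tail(h, 5L)
    out$final_acc[i] <- mean(last$val_acc)
    out$final_loss[i] <- mean(last$val_loss)
  }
  attr(out, "histories") <- histories
  out
}
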