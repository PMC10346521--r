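#' Confusion matrix over the nine maturity classes
#'
#' @param truth,pred label vectors (factors, class strings, or 1-based
#'   integer indices into the canonical class table); equal length.
#' @param labels class level set; defaults to the canonical nine classes.
#' @return a square integer matrix, rows = true class, columns = predicted
#'   class.
#' @export
confusion <- function(truth, pred, labels = leaf_classes()$class) {
  if (length(truth) != length(pred))
    stopf("truth and pred must have the same length")
  to_fac <- function(x) {
    if (is.numeric(x)) x <- labels[x]
    f <- factor(as.character(x), levels = labels)
    if (anyNA(f)) stopf("labels outside the class set")
    f
  }
  tf <- to_fac(truth)
  pf <- to_fac(pred)
  m <- table(truth = tf, predicted = pf)
  matrix(as.integer(m), nrow(m), ncol(m),
         dimnames = list(truth = labels, predicted = labels))
}

#' Classification metrics from a confusion matrix
#'
#' Computes accuracy (trace over total), per-class one-vs-rest precision
#' `TP/(TP+FP)`, recall `TP/(TP+FN)` and their harmonic mean F1, plus the
#' unweighted (macro) means over classes. A class with an undefined ratio
#' (0/0) scores 0 with a warning.
#'
#' @param cm a confusion matrix from [confusion()]; total must be positive.
#' @return list with `accuracy`, `per_class` (data.frame with class,
#'   precision, recall, f1, support) and `macro_precision`, `macro_recall`,
#'   `macro_f1`.
#' @export
classification_metrics <- function(cm) {
  total <- sum(cm)
  if (total <= 0) stopf("confusion matrix is empty")
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe_div <- function(num, den, what) {
    out <- ifelse(den > 0, num / den, 0)
    if (any(den == 0))
      warning(sprintf("%s undefined (0/0) for %d class(es); scored as 0",
                      what, sum(den == 0)), call. = FALSE)
    out
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  pr <- precision + recall
  f1 <- ifelse(pr > 0, 2 * precision * recall / pr, 0)
  list(accuracy = sum(tp) / total,
       per_class = data.frame(class = rownames(cm), precision = precision,
                              recall = recall, f1 = f1,
                              support = rowSums(cm), row.names = NULL,
                              stringsAsFactors = FALSE),
       macro_precision = mean(precision),
       macro_recall = mean(recall),
       macro_f1 = mean(f1))
}

#' Average precision of one class
#'
#' Non-interpolated step estimator of the area under the precision-recall
#' curve: items are ranked by descending score (ties broken by original
#' index, stable) and AP is the mean, over the positives, of the precision
#' at each positive's rank.
#'
#' @param scores numeric per-item scores for the class.
#' @param labels binary (0/1 or logical) relevance labels; at least one
#'   positive.
#' @return the AP in `[0, 1]`.
#' @export
average_precision <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels))
    stopf("scores and labels must have the same length")
  npos <- sum(labels)
  if (npos == 0L) stopf("average precision needs at least one positive")
  ord <- order(-scores)  # stable: ties keep original index order
  lab <- labels[ord]
  cumtp <- cumsum(lab)
  prec_at <- cumtp / seq_along(lab)
  sum(prec_at[lab == 1L]) / npos
}

#' Mean average precision over classes
#'
#' One-vs-rest AP per class averaged without weights. Classes with no
#' positive item are excluded with a warning.
#'
#' @param prob matrix of per-item class probabilities (items x classes).
#' @param truth true labels (factor/character/integer) matching the
#'   columns of `prob`.
#' @param labels class level set; defaults to `colnames(prob)` or the
#'   canonical nine classes.
#' @return list with `map` and `per_class_ap` (named, `NA` for excluded
#'   classes).
#' @export
mean_ap <- function(prob, truth, labels = NULL) {
  if (is.null(labels))
    labels <- colnames(prob)
  if (is.null(labels))
    labels <- leaf_classes()$class[seq_len(ncol(prob))]
  if (is.numeric(truth)) truth <- labels[truth]
  tf <- factor(as.character(truth), levels = labels)
  ap <- rep(NA_real_, length(labels))
  names(ap) <- labels
  for (k in seq_along(labels)) {
    pos <- tf == labels[k]
    if (!any(pos)) next
    ap[k] <- average_precision(prob[, k], pos)
  }
  if (anyNA(ap))
    warning(sprintf("%d class(es) without positives excluded from mAP",
                    sum(is.na(ap))), call. = FALSE)
  list(map = mean(ap, na.rm = TRUE), per_class_ap = ap)
}

#' Full metric report for a model on a labeled dataset
#'
#' @param model a `leafnet_model`.
#' @param ds a [leaf_dataset()].
#' @param batch_size forward-pass batch size.
#' @return list with the confusion matrix, the [classification_metrics()]
#'   fields, and `map`.
#' @export
metrics_report <- function(model, ds, batch_size = 32L) {
  prob <- predict(model, ds$images, batch_size = batch_size)
  colnames(prob) <- leaf_classes()$class[seq_len(ncol(prob))]
  pred <- max.col(prob, ties.method = "first")
  cm <- confusion(as.integer(ds$labels), pred,
                  labels = colnames(prob))
  cls <- classification_metrics(cm)
  mp <- mean_ap(prob, as.integer(ds$labels), labels = colnames(prob))
  c(list(confusion = cm), cls, list(map = mp$map,
                                    per_class_ap = mp$per_class_ap))
}

#' Measure inference throughput
#'
#' Wall-clock frames per second, `N / t`. Hardware-dependent and
#' informational only.
#'
#' @param model a `leafnet_model`.
#' @param images list of input-sized images (recycled to `n`).
#' @param n number of images to time.
#' @return frames per second (positive numeric).
#' @export
measure_fps <- function(model, images, n = length(images)) {
  if (n < 1L) stopf("n must be >= 1")
  if (is.array(images)) images <- list(images)
  imgs <- rep(images, length.out = n)
  t0 <- Sys.time()
  invisible(predict(model, imgs))
  dt <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  n / max(dt, .Machine$double.eps)
}

#' Write a metric report to disk
#'
#' The scalar metrics go to `<stem>.json`, the per-class table to
#' `<stem>_per_class.csv`, the confusion matrix to `<stem>_confusion.csv`.
#'
#' @param report output of [metrics_report()].
#' @param stem output path stem.
#' @return invisibly, the paths written.
#' @export
write_metrics_report <- function(report, stem) {
  pj <- paste0(stem, ".json")
  jsonlite::write_json(list(accuracy = report$accuracy,
                            macro_precision = report$macro_precision,
                            macro_recall = report$macro_recall,
                            macro_f1 = report$macro_f1,
                            map = report$map),
                       pj, auto_unbox = TRUE, digits = NA)
  pc <- paste0(stem, "_per_class.csv")
  write.csv(report$per_class, pc, row.names = FALSE)
  pm <- paste0(stem, "_confusion.csv")
  write.csv(as.data.frame(report$confusion), pm, row.names = TRUE)
  invisible(c(pj, pc, pm))
}
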