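# Leave-one-out (jack-knife) evaluation and confusion metrics.

#' Accuracy, sensitivity, specificity from confusion counts
#'
#' \eqn{Acc = (TP+TN)/(TP+FP+TN+FN)}, \eqn{Se = TP/(TP+FN)},
#' \eqn{Sp = TN/(TN+FP)}, each reported in percent. A zero denominator yields
#' \code{NA} with a warning rather than a silent zero.
#'
#' @param tp,fp,tn,fn non-negative confusion counts (positive = murmur).
#' @return named numeric vector \code{c(accuracy, sensitivity, specificity)}
#'   in percent.
#' @examples
#' classification_metrics(tp = 58, fp = 2, tn = 22, fn = 4)
#' @export
classification_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  ratio <- function(num, den, what) {
    if (den == 0) { warning(what, " undefined: zero denominator", call. = FALSE); NA_real_ }
    else 100 * num / den
  }
  c(accuracy = ratio(tp + tn, tp + fp + tn + fn, "accuracy"),
    sensitivity = ratio(tp, tp + fn, "sensitivity"),
    specificity = ratio(tn, tn + fp, "specificity"))
}

#' Jack-knife evaluation of the murmur classifier
#'
#' Leave-one-out: for each of the n samples a fresh network is trained on the
#' other n-1 (with the \eqn{\pm 1} feature scaling fitted on those n-1 rows
#' only, unless \code{scale_per_fold = FALSE}, which fits one global scaler —
#' the leakier variant kept for comparison), and the held-out sample is
#' scored by the network that never saw it. The n held-out 0/1 verdicts form
#' the confusion matrix.
#'
#' @param x n x 10 feature matrix.
#' @param y 0/1 labels (1 = murmur); both classes must be present.
#' @param control a [mlp_control()]; fold f trains with seed
#'   \code{control$seed + f} so the whole evaluation is reproducible.
#' @param hidden hidden-layer size (default 10).
#' @param scale_per_fold fit the feature scaler inside each fold
#'   (default TRUE).
#' @return object of class \code{"pcg_jackknife"}: per-sample \code{score},
#'   \code{label}, \code{truth}; \code{confusion} (tp/fp/tn/fn);
#'   \code{metrics} (percent); \code{n_models}; \code{fold_status}.
#' @export
pcg_jackknife <- function(x, y, control = mlp_control(), hidden = 10L,
                          scale_per_fold = TRUE) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 samples", call. = FALSE)
  if (length(unique(y)) < 2L) stop("both classes must be present", call. = FALSE)
  global_scaler <- if (!scale_per_fold) fit_feature_scaler(x) else NULL
  score <- numeric(n)
  fold_status <- character(n)
  single_class_folds <- integer(0)
  for (f in seq_len(n)) {
    xt <- x[-f, , drop = FALSE]
    yt <- y[-f]
    if (length(unique(yt)) < 2L) single_class_folds <- c(single_class_folds, f)
    ctl <- control
    ctl$seed <- control$seed + f
    if (scale_per_fold) {
      fit <- pcg_mlp(xt, yt, hidden = hidden, control = ctl, scale = TRUE)
      score[f] <- predict(fit, x[f, , drop = FALSE], type = "score")
    } else {
      fit <- pcg_mlp(apply_feature_scaler(global_scaler, xt), yt,
                     hidden = hidden, control = ctl, scale = FALSE)
      score[f] <- predict(fit, apply_feature_scaler(global_scaler,
                                                    x[f, , drop = FALSE]),
                          type = "score")
    }
    fold_status[f] <- fit$status
  }
  label <- as.numeric(score > 0.5)
  tp <- sum(label == 1 & y == 1); fp <- sum(label == 1 & y == 0)
  tn <- sum(label == 0 & y == 0); fn <- sum(label == 0 & y == 1)
  structure(list(score = score, label = label, truth = y,
                 confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
                 metrics = classification_metrics(tp, fp, tn, fn),
                 n_models = n, fold_status = fold_status,
                 single_class_folds = single_class_folds,
                 scale_per_fold = scale_per_fold),
            class = "pcg_jackknife")
}

#' @export
print.pcg_jackknife <- function(x, ...) {
  cat(sprintf("Jack-knife evaluation: %d networks, one per held-out sample\n",
              x$n_models))
  cm <- x$confusion
  cat(sprintf("  confusion: TP=%d FP=%d TN=%d FN=%d\n",
              cm["tp"], cm["fp"], cm["tn"], cm["fn"]))
  m <- x$metrics
  cat(sprintf("  accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%\n",
              m["accuracy"], m["sensitivity"], m["specificity"]))
  if (length(x$single_class_folds))
    cat(sprintf("  note: %d fold(s) trained on a single class\n",
                length(x$single_class_folds)))
  invisible(x)
}

#' @export
summary.pcg_jackknife <- function(object, ...) {
  print(object)
  cat(sprintf("  fold training status: %s\n",
              paste(names(table(object$fold_status)),
                    table(object$fold_status), sep = ":", collapse = ", ")))
  invisible(object)
}
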