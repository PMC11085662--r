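#' Construct a confusion matrix
#'
#' @param tp,fp,fn,tn Nonnegative counts.
#' @return Object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  .stop_if(any(c(tp, fp, fn, tn) < 0), "counts must be nonnegative")
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn),
            class = "confusion_matrix")
}

.as_slot_matrix <- function(x, o_max = O_MAX) {
  # accept o_max x N or N x o_max; canonicalize to N x o_max
  if (is.vector(x)) x <- matrix(x, ncol = o_max, byrow = TRUE)
  if (nrow(x) == o_max && ncol(x) != o_max) x <- t(x)
  x
}

#' Top-n slot accuracy
#'
#' Fraction of correct primary/non-primary decisions over the first `n`
#' score-ranked object slots of every image, pooled over all decisions.
#'
#' @param predictions Probability matrix, images x 5 slots (a 5 x N
#'   matrix from [nn_forward()] is accepted and transposed).
#' @param targets Matching 0/1 matrix.
#' @param threshold Decision threshold.
#' @param n Number of leading slots to score, `1 <= n <= 5`.
#' @return Fraction in [0, 1].
#' @export
topn_accuracy <- function(predictions, targets, threshold = 0.5, n = O_MAX) {
  .stop_if(n < 1 || n > O_MAX, "n must lie in [1, ", O_MAX, "]")
  p <- .as_slot_matrix(predictions)
  t <- .as_slot_matrix(targets)
  .stop_if(any(dim(p) != dim(t)), "prediction/target shape mismatch")
  sel <- seq_len(n)
  mean((p[, sel, drop = FALSE] >= threshold) ==
         (t[, sel, drop = FALSE] > 0.5))
}

#' Per-slot confusion matrices
#'
#' @inheritParams topn_accuracy
#' @return List of 5 `confusion_matrix` objects, one per object slot;
#'   each sums to the number of images.
#' @export
confusion_by_slot <- function(predictions, targets, threshold = 0.5) {
  p <- .as_slot_matrix(predictions)
  t <- .as_slot_matrix(targets)
  .stop_if(any(dim(p) != dim(t)), "prediction/target length mismatch")
  lapply(seq_len(ncol(p)), function(k) {
    pred <- p[, k] >= threshold
    pos <- t[, k] > 0.5
    confusion_matrix(tp = sum(pred & pos), fp = sum(pred & !pos),
                     fn = sum(!pred & pos), tn = sum(!pred & !pos))
  })
}

#' Metrics derived from a confusion matrix
#'
#' Standard definitions; any metric with a zero denominator is reported
#' as 0 and named in the `undefined` attribute.
#'
#' @param cm A [confusion_matrix()] (or list with `tp`, `fp`, `fn`, `tn`).
#' @return Named list: `accuracy`, `precision`, `recall`, `specificity`,
#'   `f1`, `mcc`, `fp_rate`, `fn_rate`; attribute `undefined` names the
#'   zero-denominator metrics.
#' @export
derived_metrics <- function(cm) {
  tp <- cm$tp; fp <- cm$fp; fn <- cm$fn; tn <- cm$tn
  .stop_if(tp + fp + fn + tn == 0, "all-zero confusion matrix")
  undef <- character()
  div <- function(num, den, name) {
    if (den == 0) { undef <<- c(undef, name); return(0) }
    num / den
  }
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  out <- list(
    accuracy = (tp + tn) / (tp + fp + fn + tn),
    precision = div(tp, tp + fp, "precision"),
    recall = div(tp, tp + fn, "recall"),
    specificity = div(tn, tn + fp, "specificity"),
    f1 = div(2 * tp, 2 * tp + fp + fn, "f1"),
    mcc = div(tp * tn - fp * fn, mcc_den, "mcc"),
    fp_rate = div(fp, fp + tn, "fp_rate"),
    fn_rate = div(fn, fn + tp, "fn_rate"))
  attr(out, "undefined") <- undef
  out
}

#' Precision-recall curve and area under it
#'
#' Scores are micro-pooled (all slots flattened). One (recall, precision)
#' point is computed for each distinct score used as the decision
#' threshold (`score >= threshold`), plus an anchor at recall 0 with the
#' precision of the strictest threshold; the area is the trapezoid rule
#' over recall.
#'
#' @param scores Numeric scores (any shape).
#' @param targets Matching 0/1 targets; both classes must be present.
#' @param macro If `TRUE`, average per-slot curves' areas instead of
#'   pooling (scores must then be images x 5 matrices).
#' @return List with `curve` (data frame `threshold`, `recall`,
#'   `precision`) and `auc`.
#' @export
pr_curve_auc <- function(scores, targets, macro = FALSE) {
  if (macro) {
    p <- .as_slot_matrix(scores)
    t <- .as_slot_matrix(targets)
    aucs <- vapply(seq_len(ncol(p)), function(k) {
      if (length(unique(t[, k] > 0.5)) < 2) return(NA_real_)
      pr_curve_auc(p[, k], t[, k])$auc
    }, numeric(1))
    return(list(curve = NULL, auc = mean(aucs, na.rm = TRUE)))
  }
  s <- as.numeric(scores)
  t <- as.numeric(targets) > 0.5
  .stop_if(!any(t) || all(t), "targets contain a single class")
  thr <- sort(unique(s), decreasing = TRUE)
  pts <- t(vapply(thr, function(th) {
    pred <- s >= th
    tp <- sum(pred & t)
    c(recall = tp / sum(t),
      precision = if (sum(pred) == 0) 1 else tp / sum(pred))
  }, numeric(2)))
  curve <- data.frame(threshold = thr, recall = pts[, "recall"],
                      precision = pts[, "precision"])
  r <- c(0, curve$recall)
  p <- c(curve$precision[1], curve$precision)
  auc <- sum(diff(r) * (p[-1] + p[-length(p)]) / 2)
  list(curve = curve, auc = auc)
}

#' Full evaluation report
#'
#' Computes the complete per-slot and top-n metric suite on a test set:
#' per-slot confusion matrices, top-n accuracy and mean BCE loss for
#' n = 1..5, metrics of the pooled top-n confusion counts, and the
#' micro-pooled precision-recall curve with its area.
#'
#' @param predictions Probability matrix (images x 5 or 5 x N).
#' @param targets Matching 0/1 matrix.
#' @param threshold Decision threshold used for all counts.
#' @return Object of class `eval_report`.
#' @export
evaluation_report <- function(predictions, targets, threshold = 0.5) {
  p <- .as_slot_matrix(predictions)
  t <- .as_slot_matrix(targets)
  cms <- confusion_by_slot(p, t, threshold)
  topn <- lapply(seq_len(O_MAX), function(n) {
    sel <- seq_len(n)
    pooled <- list(tp = sum(vapply(cms[sel], `[[`, 0, "tp")),
                   fp = sum(vapply(cms[sel], `[[`, 0, "fp")),
                   fn = sum(vapply(cms[sel], `[[`, 0, "fn")),
                   tn = sum(vapply(cms[sel], `[[`, 0, "tn")))
    c(list(n = n,
           accuracy = topn_accuracy(p, t, threshold, n),
           loss = bce_loss(p[, sel, drop = FALSE], t[, sel, drop = FALSE])),
      derived_metrics(pooled)[-1])
  })
  pr <- if (length(unique(as.numeric(t) > 0.5)) == 2) {
    pr_curve_auc(p, t)
  } else {
    list(curve = NULL, auc = NA_real_)
  }
  structure(list(confusion = cms,
                 topn = do.call(rbind, lapply(topn, as.data.frame)),
                 pr_curve = pr$curve, pr_auc = pr$auc,
                 threshold = threshold, n_images = nrow(p)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("eval_report on", x$n_images, "images (threshold",
      format(x$threshold), ")\n")
  cat(sprintf("  top-%d accuracy: %.4f  loss: %.4f\n",
              x$topn$n, x$topn$accuracy, x$topn$loss), sep = "")
  if (!is.na(x$pr_auc)) cat(sprintf("  PR-AUC: %.4f\n", x$pr_auc))
  invisible(x)
}

#' Write an evaluation report to JSON
#'
#' @param report An `eval_report`.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_eval_report <- function(report, path) {
  obj <- list(threshold = report$threshold, n_images = report$n_images,
              topn = report$topn, pr_auc = report$pr_auc,
              confusion = lapply(report$confusion, unclass),
              pr_curve = report$pr_curve)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
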