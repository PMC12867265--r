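# Nine-metric binary evaluation: SN, SP, ACC, BACC, PREC, F1, MCC, AUC, AUPR.
# AUC uses midrank handling of ties (each tied positive-negative pair counts
# 0.5); AUPR is the step-interpolated area under the precision-recall curve.
# Metrics with a zero denominator are reported as 0 and flagged, so batch
# experiment tables never abort mid-run.

#' Confusion counts at a threshold
#'
#' Probabilities greater than or equal to the threshold are predicted
#' positive (ties to positive).
#'
#' @param y_true Binary truth vector (0/1).
#' @param probs Predicted probabilities.
#' @param threshold Decision threshold.
#' @return List with integer fields TP, FP, TN, FN.
#' @export
confusion <- function(y_true, probs, threshold = 0.5) {
  if (length(y_true) != length(probs)) {
    stop("y_true and probs must have equal length", call. = FALSE)
  }
  pred <- probs >= threshold
  y <- y_true == 1L
  list(TP = sum(pred & y), FP = sum(pred & !y),
       TN = sum(!pred & !y), FN = sum(!pred & y))
}

auc_rank <- function(y_true, scores) {
  pos <- scores[y_true == 1L]
  neg <- scores[y_true == 0L]
  if (length(pos) == 0L || length(neg) == 0L) return(NA_real_)
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

aupr_step <- function(y_true, scores) {
  n_pos <- sum(y_true == 1L)
  if (n_pos == 0L || all(y_true == 1L)) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  y <- y_true[ord]
  tp <- cumsum(y == 1L)
  prec <- tp / seq_along(y)
  rec <- tp / n_pos
  # step interpolation: area = sum over recall increments of precision there
  d_rec <- diff(c(0, rec))
  sum(prec * d_rec)
}

#' Compute the nine-metric evaluation report
#'
#' Sensitivity, specificity, accuracy, balanced accuracy, precision, F1,
#' Matthews correlation coefficient, ROC AUC (rank-based, ties at 0.5 per
#' pair) and area under the precision-recall step curve. Metrics whose
#' denominator is zero are reported as 0 and listed in the `undefined`
#' attribute; AUC/AUPR are `NA` (and flagged) when only one class is
#' present.
#'
#' @param y_true Binary truth vector.
#' @param probs Predicted probabilities (or scores, for AUC/AUPR).
#' @param threshold Decision threshold for the thresholded metrics.
#' @return A `metric_report`: named numeric vector of the nine metrics with
#'   an `undefined` character attribute and a `counts` attribute (TP, FP,
#'   TN, FN).
#' @export
compute_metrics <- function(y_true, probs, threshold = 0.5) {
  cc <- confusion(y_true, probs, threshold)
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  undefined <- character()
  tp <- cc$TP; fp <- cc$FP; tn <- cc$TN; fn <- cc$FN
  sn <- safe_div(tp, tp + fn)
  sp <- safe_div(tn, tn + fp)
  acc <- safe_div(tp + tn, tp + fp + tn + fn)
  bacc <- if (is.na(sn) || is.na(sp)) NA_real_ else (sn + sp) / 2
  prec <- safe_div(tp, tp + fp)
  f1 <- safe_div(2 * tp, 2 * tp + fp + fn)
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den else NA_real_
  auc <- auc_rank(y_true, probs)
  aupr <- aupr_step(y_true, probs)
  out <- c(SN = sn, SP = sp, ACC = acc, BACC = bacc, PREC = prec, F1 = f1,
           MCC = mcc, AUC = auc, AUPR = aupr)
  undefined <- names(out)[is.na(out)]
  out[is.na(out) & names(out) %in% c("SN", "SP", "ACC", "BACC", "PREC",
                                     "F1", "MCC")] <- 0
  structure(out, undefined = undefined,
            counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
            class = c("metric_report", "numeric"))
}

#' @export
print.metric_report <- function(x, ...) {
  v <- unclass(x)
  attributes(v) <- list(names = names(x))
  print(round(v, 4))
  und <- attr(x, "undefined")
  if (length(und) > 0L) cat("undefined (reported as 0/NA):",
                            paste(und, collapse = ", "), "\n")
  invisible(x)
}

#' Metric report from explicit confusion counts
#'
#' Convenience wrapper for worked examples: builds a degenerate score vector
#' realizing the given counts and evaluates [compute_metrics()] on it (AUC
#' and AUPR then reflect the binary predictions, not a ranking).
#'
#' @param TP,FP,TN,FN Non-negative integer counts.
#' @return A `metric_report`.
#' @export
metrics_from_counts <- function(TP, FP, TN, FN) {
  y <- c(rep(1L, TP), rep(0L, FP), rep(0L, TN), rep(1L, FN))
  p <- c(rep(1, TP), rep(1, FP), rep(0, TN), rep(0, FN))
  compute_metrics(y, p, threshold = 0.5)
}

#' Stratified k-fold cross-validation indices
#'
#' Splits a sample set into k folds that are class-balanced within one
#' sample, disjoint, and jointly exhaustive. Assignment is by seeded
#' per-class shuffle followed by round-robin fold allocation.
#'
#' @param data A [sample_set()].
#' @param k Number of folds (>= 2).
#' @param seed Integer shuffle seed.
#' @return List of k elements, each `list(train = idx, test = idx)`.
#' @export
stratified_kfold <- function(data, k = 10L, seed = 1L) {
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  counts <- label_counts(data)
  if (any(counts < k)) {
    stop("each class needs at least k members (have ",
         paste(counts, collapse = "/"), ", k = ", k, ")", call. = FALSE)
  }
  fold_of <- integer(nrow(data))
  with_seed(derive_seed(seed, "kfold"), {
    for (lab in c(1L, 0L)) {
      cls <- which(data$label == lab)
      cls <- sample(cls)
      # opposite round-robin directions per class, so the remainder samples
      # of the two classes land on complementary folds and fold totals stay
      # as even as possible (1190 samples at k = 10 give 119 per fold)
      order_k <- if (lab == 1L) seq_len(k) else rev(seq_len(k))
      fold_of[cls] <- rep_len(order_k, length(cls))
    }
  })
  lapply(seq_len(k), function(f) {
    list(train = which(fold_of != f), test = which(fold_of == f))
  })
}
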