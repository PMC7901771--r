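#' Confusion counts from labels and predictions
#'
#' @param truth integer 0/1 true labels (1 = pseudouridine site).
#' @param predicted integer 0/1 predicted labels.
#' @return A one-row tibble with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(truth, predicted) {
  if (length(truth) != length(predicted) || length(truth) == 0L) {
    abort("truth and predicted must be equal-length, non-empty 0/1 vectors")
  }
  tibble::tibble(
    tp = sum(truth == 1 & predicted == 1),
    tn = sum(truth == 0 & predicted == 0),
    fp = sum(truth == 0 & predicted == 1),
    fn = sum(truth == 1 & predicted == 0)
  )
}

#' Classification metrics from confusion counts
#'
#' Computes sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy
#' `(TP+TN)/(TP+TN+FP+FN)` and the Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. A metric whose
#' denominator is zero (e.g. sensitivity on a fold with no positives) is
#' flagged undefined and returned as `NA` rather than `NaN`, so degenerate
#' folds cannot silently poison cross-validation means.
#'
#' @param counts a one-row data frame with `tp`, `tn`, `fp`, `fn`
#'   (e.g. from [confusion_counts()]); alternatively pass the four counts
#'   directly.
#' @param tp,tn,fp,fn individual counts, used when `counts` is missing.
#' @return A one-row tibble: `sensitivity`, `specificity`, `accuracy`,
#'   `mcc`.
#' @examples
#' compute_metrics(tp = 80, fn = 20, tn = 73, fp = 27)
#' @export
compute_metrics <- function(counts, tp, tn, fp, fn) {
  if (missing(counts)) {
    counts <- tibble::tibble(tp = tp, tn = tn, fp = fp, fn = fn)
  }
  tp <- as.numeric(counts$tp); tn <- as.numeric(counts$tn)
  fp <- as.numeric(counts$fp); fn <- as.numeric(counts$fn)
  if (any(c(tp, tn, fp, fn) < 0) || tp + tn + fp + fn < 1) {
    abort("confusion counts must be non-negative with at least one sample")
  }
  safe_div <- function(num, den) ifelse(den == 0, NA_real_, num / den)
  mcc_den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  tibble::tibble(
    sensitivity = safe_div(tp, tp + fn),
    specificity = safe_div(tn, tn + fp),
    accuracy = (tp + tn) / (tp + tn + fp + fn),
    mcc = ifelse(mcc_den == 0, NA_real_, (tp * tn - fp * fn) / sqrt(mcc_den))
  )
}

#' ROC curve and area under it
#'
#' Builds the ROC point list by sweeping every distinct score as a
#' threshold (tied scores collapse to one step, giving the usual diagonal
#' segment) and integrates it by the trapezoid rule, which equals the rank
#' (Mann-Whitney) statistic. Scores are probabilities — or any monotone
#' score — for the positive class.
#'
#' @param scores numeric positive-class scores.
#' @param labels integer 0/1 labels; both classes must be present.
#' @return An object of class `psi_roc`: list with `auc` and `points`, a
#'   tibble of `threshold`, `fpr`, `tpr` from (0,0) to (1,1).
#' @examples
#' roc_auc(c(.9, .8, .3, .1), c(1, 1, 0, 0))$auc
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    abort("scores and labels must have equal length")
  }
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) {
    abort("ROC needs at least one positive and one negative label")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  keep <- c(diff(s) != 0, TRUE)  # last index of each tied block
  tpr <- c(0, cumsum(y == 1)[keep] / npos)
  fpr <- c(0, cumsum(y == 0)[keep] / nneg)
  thr <- c(Inf, s[keep])
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  structure(
    list(auc = auc,
         points = tibble::tibble(threshold = thr, fpr = fpr, tpr = tpr)),
    class = "psi_roc"
  )
}

#' @export
print.psi_roc <- function(x, ...) {
  cat("<psi_roc> AUC = ", signif(x$auc, 4), " (",
      nrow(x$points), " points)\n", sep = "")
  invisible(x)
}

#' @method autoplot psi_roc
#' @export
autoplot.psi_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC (AUC = %.3f)", object$auc)
    )
}

#' Relative improvement of one metric over another
#'
#' `100 * (new - old) / old`, the arithmetic used when comparing a
#' predictor against a published baseline. With `digits` set, the value is
#' truncated toward zero at that many decimals — the convention the
#' comparison tables follow (e.g. 16.3467 prints as 16.34).
#'
#' @param new,old metric values on the same scale; `old` must be non-zero.
#' @param digits optional decimal places for truncated display.
#' @return The percentage improvement; `NA` (with a warning) if `old` is 0.
#' @examples
#' relative_improvement(85.61, 71.18, digits = 2)
#' @export
relative_improvement <- function(new, old, digits = NULL) {
  out <- ifelse(old == 0, NA_real_, 100 * (new - old) / old)
  if (any(old == 0)) {
    warn("relative improvement is undefined for a zero baseline")
  }
  if (!is.null(digits)) {
    out <- trunc(out * 10^digits) / 10^digits
  }
  out
}

#' Published benchmark and independent-set results of existing predictors
#'
#' Reported evaluation metrics of prior pseudouridine-site predictors
#' (iRNA-PseU, PseUI, iPseU-CNN, XGboost, iPseU-Layer) on the HS_990,
#' SC_628 and MM_944 benchmark sets and the HS_200 and SC_200 independent
#' sets, treated as constants for comparison tables. AC, SN, SP are
#' percentages; MCC is on [-1, 1].
#'
#' @return Tibble with `predictor`, `dataset`, `ac`, `sn`, `sp`, `mcc`.
#' @export
published_benchmarks <- function() {
  tribble_rows <- list(
    # dataset, predictor, ac, sn, sp, mcc
    list("SC_628", "iRNA-PseU", 64.49, 64.65, 64.33, 0.29),
    list("SC_628", "PseUI", 65.13, 62.74, 67.52, 0.30),
    list("SC_628", "iPseU-CNN", 68.15, 66.84, 69.45, 0.37),
    list("SC_628", "XGboost", 68.15, 66.84, 69.45, 0.37),
    list("SC_628", "iPseU-Layer", 89.34, 84.68, 93.76, 0.79),
    list("HS_990", "iRNA-PseU", 60.40, 61.01, 59.80, 0.21),
    list("HS_990", "PseUI", 64.24, 64.85, 63.64, 0.28),
    list("HS_990", "iPseU-CNN", 66.68, 65.00, 68.78, 0.34),
    list("HS_990", "XGboost", 65.44, 63.64, 67.24, 0.31),
    list("HS_990", "iPseU-Layer", 79.70, 71.18, 88.22, 0.60),
    list("MM_944", "iRNA-PseU", 69.07, 73.31, 64.83, 0.38),
    list("MM_944", "PseUI", 70.44, 74.58, 66.31, 0.41),
    list("MM_944", "iPseU-CNN", 71.81, 74.79, 69.11, 0.44),
    list("MM_944", "XGboost", 72.03, 76.48, 67.57, 0.45),
    list("MM_944", "iPseU-Layer", 80.08, 77.92, 81.82, 0.60),
    list("SC_200", "iRNA-PseU", 60.00, 63.00, 57.00, 0.20),
    list("SC_200", "PseUI", 68.50, 65.00, 72.00, 0.37),
    list("SC_200", "iPseU-CNN", 73.50, 68.76, 77.42, 0.47),
    list("SC_200", "iPseU-Layer", 72.50, 68.00, 77.00, 0.45),
    list("HS_200", "iRNA-PseU", 61.50, 58.00, 65.00, 0.23),
    list("HS_200", "PseUI", 65.50, 63.00, 68.00, 0.31),
    list("HS_200", "iPseU-CNN", 69.00, 77.72, 60.81, 0.40),
    list("HS_200", "iPseU-Layer", 71.00, 63.00, 79.00, 0.43)
  )
  purrr::map_dfr(tribble_rows, function(r) {
    tibble::tibble(dataset = r[[1]], predictor = r[[2]], ac = r[[3]],
                   sn = r[[4]], sp = r[[5]], mcc = r[[6]])
  })
}

#' Comparison table against published predictors
#'
#' Binds this package's metrics to published rows for the same dataset and
#' appends relative-improvement columns for our rows against a reference
#' competitor (by default the published predictor with the highest
#' accuracy, the comparison the literature makes). Metrics absent on either
#' side stay `NA`. Improvements are truncated to 2 decimals, the table
#' convention.
#'
#' @param ours tibble with `predictor`, `dataset` and any of `ac`, `sn`,
#'   `sp`, `mcc` (AC/SN/SP as percentages).
#' @param published tibble in the [published_benchmarks()] layout; may be
#'   empty.
#' @param reference optional published predictor name to compare against.
#' @return Tibble of published rows then ours, with `impr_ac`, `impr_sn`,
#'   `impr_sp`, `impr_mcc` on our rows.
#' @export
comparison_table <- function(ours, published = published_benchmarks(),
                             reference = NULL) {
  cols <- c("ac", "sn", "sp", "mcc")
  for (cc in cols) {
    if (is.null(ours[[cc]])) ours[[cc]] <- NA_real_
    if (nrow(published) > 0 && is.null(published[[cc]])) {
      published[[cc]] <- NA_real_
    }
  }
  published <- published[published$dataset %in% unique(ours$dataset), , drop = FALSE]
  out <- dplyr::bind_rows(
    dplyr::mutate(published, source = "published"),
    dplyr::mutate(ours, source = "ours")
  )
  for (cc in cols) out[[paste0("impr_", cc)]] <- NA_real_
  if (nrow(published) > 0) {
    for (d in unique(ours$dataset)) {
      pub_d <- published[published$dataset == d, , drop = FALSE]
      if (nrow(pub_d) == 0) next
      ref <- if (is.null(reference)) {
        pub_d[which.max(pub_d$ac), , drop = FALSE]
      } else {
        pub_d[pub_d$predictor == reference, , drop = FALSE]
      }
      if (nrow(ref) == 0) next
      ours_rows <- which(out$source == "ours" & out$dataset == d)
      for (cc in cols) {
        if (is.na(ref[[cc]][1]) || ref[[cc]][1] == 0) next
        out[[paste0("impr_", cc)]][ours_rows] <- suppressWarnings(
          relative_improvement(out[[cc]][ours_rows], ref[[cc]][1], digits = 2)
        )
      }
    }
  }
  tibble::as_tibble(out)
}
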