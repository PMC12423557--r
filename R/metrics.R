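#' Confusion rates from labels and hard predictions
#'
#' True-positive rate = TP / (TP + FN); true-negative rate = TN / (TN + FP);
#' false-positive rate = FP / (FP + TN); false-negative rate = FN / (FN + TP).
#' Rates with a zero denominator are `NA`, never 0.
#'
#' @param labels Logical (or 0/1) true labels.
#' @param predictions Logical (or 0/1) predicted labels.
#' @return One-row tibble with `tpr`, `tnr`, `fpr`, `fnr`, and the four
#'   underlying counts.
#' @export
confusion_rates <- function(labels, predictions) {
  labels <- as.logical(labels)
  predictions <- as.logical(predictions)
  stopifnot(length(labels) == length(predictions), !anyNA(labels),
            !anyNA(predictions))
  tp <- sum(labels & predictions)
  fn <- sum(labels & !predictions)
  tn <- sum(!labels & !predictions)
  fp <- sum(!labels & predictions)
  rate <- function(num, den) if (den == 0L) NA_real_ else num / den
  tibble::tibble(
    tpr = rate(tp, tp + fn), tnr = rate(tn, tn + fp),
    fpr = rate(fp, fp + tn), fnr = rate(fn, fn + tp),
    tp = tp, fn = fn, tn = tn, fp = fp
  )
}

#' Rank-based AUC
#'
#' The probability that a uniformly drawn positive outscores a uniformly
#' drawn negative, with ties counting one half — identical to the area under
#' the ROC curve by trapezoidal integration. Constant scores give 0.5.
#'
#' @param labels Logical (or 0/1) true labels; both classes must be present.
#' @param scores Numeric scores, higher = more positive.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(labels, scores) {
  labels <- as.logical(labels)
  stopifnot(length(labels) == length(scores), all(is.finite(scores)))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present to compute AUC", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Aggregate per-GO metrics records
#'
#' Unweighted means of TPR/TNR/AUC across GO accessions, plus a breakdown by
#' positive-sample-fraction bin for small-fraction reporting. An optional
#' positives-weighted mean is available.
#'
#' @param records Tibble of per-GO metrics with columns `go_accession`,
#'   `n_positive`, `positive_fraction`, `tpr`, `tnr`, `auc` (e.g. from
#'   [fit_go_models()] via [glance()]).
#' @param fraction_breaks Bin edges for the positive-fraction breakdown.
#' @param weight `"none"` (unweighted, default) or `"positives"`.
#' @return List with `overall` (one-row tibble) and `by_fraction` (per-bin
#'   tibble whose counts partition the records).
#' @export
summarize_metrics <- function(records,
                              fraction_breaks = c(0, 0.02, 0.05, 0.10, 1),
                              weight = c("none", "positives")) {
  weight <- match.arg(weight)
  stopifnot(nrow(records) > 0)
  w <- if (weight == "none") rep(1, nrow(records)) else records$n_positive
  wmean <- function(x) sum(x * w, na.rm = TRUE) / sum(w[!is.na(x)])
  overall <- tibble::tibble(
    n_go = nrow(records),
    mean_tpr = wmean(records$tpr),
    mean_tnr = wmean(records$tnr),
    mean_auc = wmean(records$auc)
  )
  bin <- cut(records$positive_fraction, breaks = fraction_breaks,
             include.lowest = TRUE)
  by_fraction <- records |>
    dplyr::mutate(fraction_bin = bin) |>
    dplyr::group_by(.data$fraction_bin) |>
    dplyr::summarise(
      n_go = dplyr::n(),
      mean_tpr = mean(.data$tpr, na.rm = TRUE),
      mean_tnr = mean(.data$tnr, na.rm = TRUE),
      mean_auc = mean(.data$auc, na.rm = TRUE),
      .groups = "drop"
    )
  list(overall = overall, by_fraction = by_fraction)
}
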