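#' Classification metrics from confusion counts
#'
#' Computes sensitivity, specificity, accuracy and the Matthews correlation
#' coefficient from the four confusion counts of a binary classifier:
#' \deqn{SN = TP/(TP+FN), \quad SP = TN/(TN+FP),}
#' \deqn{ACC = (TP+TN)/(TP+TN+FP+FN),}
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN) /
#'   \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}.}
#' MCC equals the Pearson correlation of the predicted and true binary labels
#' and is the preferred summary under class imbalance. When any factor of the
#' MCC denominator is zero the coefficient is undefined; it is reported as 0
#' with `mcc_defined = FALSE` (a common convention). `SN` is `NA` when there
#' are no positives and `SP` is `NA` when there are no negatives.
#'
#' @param tp,tn,fp,fn Non-negative confusion counts (vectors recycle
#'   element-wise).
#' @return A tibble with columns `TP`, `TN`, `FP`, `FN`, `SN`, `SP`, `ACC`,
#'   `MCC`, `mcc_defined`.
#' @examples
#' compute_metrics(tp = 190, tn = 829, fp = 1, fn = 15)
#' @export
compute_metrics <- function(tp, tn, fp, fn) {
  counts <- vctrs::vec_recycle_common(TP = tp, TN = tn, FP = fp, FN = fn)
  tp <- as.numeric(counts$TP); tn <- as.numeric(counts$TN)
  fp <- as.numeric(counts$FP); fn <- as.numeric(counts$FN)
  if (any(c(tp, tn, fp, fn) < 0)) abort("confusion counts must be >= 0")
  total <- tp + tn + fp + fn
  if (any(total == 0)) abort("all-zero confusion counts")

  sn <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  sp <- ifelse(tn + fp > 0, tn / (tn + fp), NA_real_)
  acc <- (tp + tn) / total
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  defined <- denom > 0
  mcc <- ifelse(defined, (tp * tn - fp * fn) / sqrt(denom), 0)
  tibble(
    TP = tp, TN = tn, FP = fp, FN = fn,
    SN = sn, SP = sp, ACC = acc, MCC = mcc,
    mcc_defined = defined
  )
}

#' Confusion counts from truth and prediction vectors
#'
#' @param truth,predicted Equal-length label vectors (factor, character or
#'   logical).
#' @param positive Label value counted as the positive class.
#' @return A one-row tibble `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(truth, predicted, positive = "positive") {
  if (length(truth) != length(predicted)) abort("length mismatch")
  t_pos <- as.character(truth) == positive
  p_pos <- as.character(predicted) == positive
  tibble(
    TP = sum(t_pos & p_pos),
    TN = sum(!t_pos & !p_pos),
    FP = sum(!t_pos & p_pos),
    FN = sum(t_pos & !p_pos)
  )
}

#' Reconstruct confusion counts from per-class accuracies
#'
#' Given class sizes and the reported per-class accuracies (sensitivity and
#' specificity), rebuilds integer confusion counts by rounding
#' `TP = round(SN * n_pos)` and `TN = round(SP * n_neg)`. Useful for checking
#' published metric tables that report rates rather than raw counts.
#'
#' @param sn,sp Reported sensitivity and specificity.
#' @param n_pos,n_neg Class sizes.
#' @return A one-row tibble `TP`, `TN`, `FP`, `FN`.
#' @examples
#' counts <- reconstruct_confusion(sn = 0.927, sp = 0.999,
#'                                 n_pos = 205, n_neg = 830)
#' compute_metrics(counts$TP, counts$TN, counts$FP, counts$FN)
#' @export
reconstruct_confusion <- function(sn, sp, n_pos, n_neg) {
  tp <- round(sn * n_pos)
  tn <- round(sp * n_neg)
  tibble(TP = tp, TN = tn, FP = n_neg - tn, FN = n_pos - tp)
}
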