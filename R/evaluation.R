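# Performance metrics, the minimum-performance gate, and percent inter-rater
# agreement.

#' Confusion counts from gold and predicted labels
#'
#' @param truth,pred character/factor vectors of equal length.
#' @param positive the label treated as positive (default `"positive"`).
#' @return Named integer vector `c(tp, fp, tn, fn)`.
#' @export
confusion_counts <- function(truth, pred, positive = "positive") {
  if (length(truth) != length(pred))
    stop("truth and pred must have the same length")
  truth <- as.character(truth) == positive
  pred <- as.character(pred) == positive
  c(tp = sum(truth & pred), fp = sum(!truth & pred),
    tn = sum(!truth & !pred), fn = sum(truth & !pred))
}

#' Sensitivity, specificity, PPV and accuracy
#'
#' A metric whose denominator is zero is returned as `NA` (flagged
#' undefined), not an error.
#'
#' @param counts named vector with elements `tp`, `fp`, `tn`, `fn`
#'   (see [confusion_counts()]).
#' @return Named numeric vector `c(sensitivity, specificity, ppv, accuracy)`,
#'   each in `[0, 1]` or `NA`.
#' @examples
#' classification_metrics(c(tp = 9, fp = 2, tn = 18, fn = 1))
#' @export
classification_metrics <- function(counts) {
  counts <- counts[c("tp", "fp", "tn", "fn")]
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative tp/fp/tn/fn")
  tp <- counts[["tp"]]; fp <- counts[["fp"]]
  tn <- counts[["tn"]]; fn <- counts[["fn"]]
  total <- tp + fp + tn + fn
  if (total == 0) stop("empty confusion table")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  c(sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    ppv = ratio(tp, tp + fp),
    accuracy = (tp + tn) / total)
}

#' Minimum performance gate
#'
#' TRUE iff every one of the four metrics is defined and at least
#' `threshold` (boundary inclusive). When it fails, the reasons (metrics
#' below threshold or undefined) are attached as attribute `"reason"`.
#'
#' @param metrics named numeric vector from [classification_metrics()].
#' @param threshold minimum acceptable value for each metric (default 0.85).
#' @return Logical scalar, with a `"reason"` attribute when FALSE.
#' @export
performance_gate <- function(metrics, threshold = 0.85) {
  stopifnot(threshold > 0, threshold <= 1)
  need <- c("sensitivity", "specificity", "ppv", "accuracy")
  miss <- setdiff(need, names(metrics))
  if (length(miss)) stop("missing metric(s): ", paste(miss, collapse = ", "))
  m <- metrics[need]
  reasons <- character()
  if (anyNA(m))
    reasons <- paste0(names(m)[is.na(m)], " undefined")
  low <- !is.na(m) & m < threshold
  if (any(low))
    reasons <- c(reasons, sprintf("%s = %.4f < %.2f", names(m)[low], m[low],
                                  threshold))
  pass <- length(reasons) == 0L
  if (!pass) attr(pass, "reason") <- reasons
  pass
}

#' Percent inter-rater agreement
#'
#' Simple percent agreement: 100 times the fraction of positions where the
#' two label vectors coincide.
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @return Percentage in `[0, 100]`.
#' @examples
#' percent_agreement(rep(c("p", "n"), c(170, 26)),
#'                   rep(c("p", "n", "p"), c(170, 13, 13)))
#' @export
percent_agreement <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors differ in length (", length(labels_a), " vs ",
         length(labels_b), ")")
  if (length(labels_a) == 0L) stop("cannot compute agreement on empty vectors")
  100 * mean(as.character(labels_a) == as.character(labels_b))
}

#' Cohen's kappa (optional chance-corrected agreement)
#'
#' Offered alongside [percent_agreement()]; percent agreement is the
#' primary reported measure.
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @return Kappa statistic.
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors differ in length")
  lv <- union(unique(as.character(labels_a)), unique(as.character(labels_b)))
  a <- factor(as.character(labels_a), levels = lv)
  b <- factor(as.character(labels_b), levels = lv)
  tab <- table(a, b) / length(a)
  po <- sum(diag(tab))
  pe <- sum(rowSums(tab) * colSums(tab))
  if (pe == 1) return(1)
  (po - pe) / (1 - pe)
}
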