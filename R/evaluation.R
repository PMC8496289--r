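#' Label markers as true positives around known QTLs
#'
#' A marker is labelled positive when it lies on the same chromosome and
#' within `window_cM` (inclusive) of a truth QTL position. With the default
#' window 0 only the QTL markers themselves are positive — appropriate when
#' the truth markers are part of the scanned panel.
#'
#' @param result An `AssociationResult` (or any data.frame with `marker_id`,
#'   `chrom`, `pos_cM`).
#' @param truth Data frame with columns `marker_id`, `chromosome`,
#'   `position_cM` (as in a `SimulatedPhenotype` `$truth`), or a character
#'   vector of truth marker ids present in the result.
#' @param window_cM Matching window in centimorgan (default 0).
#' @return Logical vector, one label per marker row of `result`.
#' @export
match_truth <- function(result, truth, window_cM = 0) {
  if (is.character(truth)) {
    if (!all(truth %in% result$marker_id))
      stop("truth marker(s) absent from the map: ",
           paste(setdiff(truth, result$marker_id), collapse = ", "))
    truth <- data.frame(marker_id = truth,
                        chromosome = result$chrom[match(truth, result$marker_id)],
                        position_cM = result$pos_cM[match(truth, result$marker_id)])
  }
  if (is.list(truth) && !is.data.frame(truth))
    truth <- data.frame(marker_id = truth$qtl_ids,
                        chromosome = truth$chromosome,
                        position_cM = truth$position_cM)
  if (!all(truth$marker_id %in% result$marker_id))
    stop("truth marker(s) absent from the map: ",
         paste(setdiff(truth$marker_id, result$marker_id), collapse = ", "))
  labels <- rep(FALSE, nrow(result))
  for (k in seq_len(nrow(truth))) {
    hit <- result$chrom == truth$chromosome[k] &
      abs(result$pos_cM - truth$position_cM[k]) <= window_cM
    labels <- labels | hit
  }
  labels
}

#' Recall, precision and F-measure of significance calls
#'
#' Recall = TP/(TP+FN), precision = TP/(TP+FP), and the F-measure is the
#' harmonic mean \eqn{2 / (\mathrm{Recall}^{-1} + \mathrm{Precision}^{-1})}.
#' With no significant calls precision is undefined and reported as `NA`;
#' the F-measure is 0 whenever recall is 0.
#'
#' @param labels Logical truth labels per marker.
#' @param significant_calls Logical significance calls, same length (NAs
#'   treated as not-called).
#' @return List with `recall`, `precision`, `f_measure`, and the confusion
#'   counts `tp`, `fp`, `fn`.
#' @export
confusion_metrics <- function(labels, significant_calls) {
  stopifnot(length(labels) == length(significant_calls))
  if (!any(labels)) stop("no positive labels: truth required")
  calls <- !is.na(significant_calls) & significant_calls
  tp <- sum(calls & labels)
  fp <- sum(calls & !labels)
  fn <- sum(!calls & labels)
  recall <- tp / (tp + fn)
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  f <- if (recall == 0) 0 else 2 / (1 / recall + 1 / precision)
  list(recall = recall, precision = precision, f_measure = f,
       tp = tp, fp = fp, fn = fn)
}

#' Area under the ROC curve by the Mann-Whitney statistic
#'
#' The AUC is computed as the probability that a randomly chosen positive
#' marker outscores a randomly chosen negative one, with ties counted 0.5 —
#' the rank (Mann-Whitney) form, which equals trapezoidal integration of
#' the ROC curve.
#'
#' @param scores Numeric scores (e.g. \eqn{-\log_{10} p}); NAs dropped with
#'   their labels.
#' @param labels Logical labels, same length.
#' @return Scalar AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  ok <- !is.na(scores)
  scores <- scores[ok]
  labels <- as.logical(labels[ok])
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stop("both a positive and a negative label are required")
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Score one scan against simulation truth
#'
#' Convenience wrapper: labels markers with [match_truth()], then computes
#' recall/precision/F (at the scan's FDR calls), AUC of the
#' \eqn{-\log_{10} p} ranking, and the genomic inflation factor, for each
#' requested test of the scan.
#'
#' @param result An `AssociationResult`.
#' @param truth Truth specification (see [match_truth()]).
#' @param tests Tests to score; default all tests present in `result`.
#' @param window_cM Matching window (default 0).
#' @return Data frame with one row per test: `test`, `recall`, `precision`,
#'   `f_measure`, `auc`, `lambda_gc`.
#' @export
evaluate_scan <- function(result, truth, tests = attr(result, "tests"),
                          window_cM = 0) {
  labels <- match_truth(result, truth, window_cM)
  lam <- attr(result, "lambda_gc")
  rows <- lapply(tests, function(tn) {
    cm <- confusion_metrics(labels, result[[paste0("sig_", tn)]])
    data.frame(test = tn,
               recall = cm$recall, precision = cm$precision,
               f_measure = cm$f_measure,
               auc = roc_auc(result[[paste0("neglog10p_", tn)]], labels),
               lambda_gc = unname(lam[tn]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
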