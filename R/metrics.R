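# Evaluation protocol: F1 for region classification; TPR at a fixed FPR via
# neutral-percentile thresholds; sweep localization success rate and
# detection accuracy. The per-replicate scan score used for thresholding is
# the maximum of the selection profile.

#' Detection threshold from neutral calibration scores
#'
#' Nearest-rank `(1 - fpr)` percentile of the neutral per-replicate scores
#' (profile maxima). A replicate is called positive iff its score is
#' strictly greater than the threshold, so with scores 1..100 and
#' `fpr = 0.05` the threshold is 95 and exactly five calibration scores
#' exceed it.
#'
#' @param neutral_scores numeric vector of scores from neutral replicates.
#' @param fpr target false positive rate in (0, 1), default 0.05.
#' @return the threshold score.
#' @export
threshold_at_fpr <- function(neutral_scores, fpr = 0.05) {
  neutral_scores <- neutral_scores[!is.na(neutral_scores)]
  if (!length(neutral_scores)) stop("no neutral scores supplied")
  if (fpr <= 0 || fpr >= 1) stop("fpr must be in (0, 1)")
  s <- sort(neutral_scores)
  s[max(1L, ceiling((1 - fpr) * length(s)))]
}

#' True positive rate at a threshold
#'
#' @param scores per-replicate scores of the selection class.
#' @param threshold detection threshold (positives are `score > threshold`).
#' @return fraction of scores strictly above the threshold.
#' @export
tpr <- function(scores, threshold) {
  scores <- scores[!is.na(scores)]
  if (!length(scores)) stop("no scores supplied")
  mean(scores > threshold)
}

#' Sweep localization success rate
#'
#' Fraction of replicates whose reported sweep location lies within `e_bp`
#' of the true target (inclusive boundary).
#'
#' @param reported_locs reported locations in bp.
#' @param true_target true sweep position in bp.
#' @param e_bp maximum distance counted as success (> 0); the conventional
#'   choice is 1% of the region length.
#' @return success rate in `[0, 1]`.
#' @export
success_rate <- function(reported_locs, true_target, e_bp) {
  if (e_bp <= 0) stop("e_bp must be > 0")
  d <- abs(reported_locs - true_target)
  mean(!is.na(d) & d <= e_bp)  # an unlocalized replicate is a failure
}

#' Sweep detection accuracy
#'
#' Mean distance between the reported and the true sweep location, as a
#' percentage of the region length (lower is better).
#'
#' @param reported_locs reported locations in bp.
#' @param true_target true sweep position in bp.
#' @param region_len region length in bp.
#' @return mean distance in percent of `region_len`.
#' @export
detection_accuracy <- function(reported_locs, true_target, region_len) {
  if (region_len <= 0) stop("region_len must be > 0")
  mean(abs(reported_locs - true_target), na.rm = TRUE) / region_len * 100
}

#' F1 score for binary classification
#'
#' `2 * precision * recall / (precision + recall)`, with 0 returned when
#' either precision or recall is zero (or undefined).
#'
#' @param truth true labels (logical or the positive-class value).
#' @param predicted predicted labels of the same type.
#' @param positive value treated as the positive class.
#' @return F1 in `[0, 1]`.
#' @export
f1_score <- function(truth, predicted, positive = TRUE) {
  t <- truth == positive
  p <- predicted == positive
  tp <- sum(t & p)
  prec <- if (sum(p)) tp / sum(p) else 0
  rec <- if (sum(t)) tp / sum(t) else 0
  if (prec + rec == 0) return(0)
  2 * prec * rec / (prec + rec)
}

#' Evaluate a genome-scan experiment
#'
#' Applies the full protocol to per-replicate scan results: calibrates the
#' threshold on the neutral scores at the requested FPR, computes the TPR of
#' the selection scores, and summarizes localization with the success rate
#' (distance `e_bp`, default 1% of the region) and the detection accuracy.
#'
#' @param neutral_scores profile maxima of the neutral replicates.
#' @param selection_scores profile maxima of the sweep replicates.
#' @param reported_locs reported sweep locations (bp) of the sweep
#'   replicates; optional (localization metrics are skipped when missing).
#' @param true_target true sweep position in bp.
#' @param region_len region length in bp.
#' @param fpr target false positive rate.
#' @param e_bp success-rate distance; defaults to `0.01 * region_len`.
#' @return an `eval_report` list.
#' @export
evaluate_scan <- function(neutral_scores, selection_scores,
                          reported_locs = NULL, true_target = NULL,
                          region_len = NULL, fpr = 0.05, e_bp = NULL) {
  thr <- threshold_at_fpr(neutral_scores, fpr)
  rep <- list(n_neutral = length(neutral_scores),
              n_selection = length(selection_scores),
              fpr_level = fpr, threshold = thr,
              tpr = tpr(selection_scores, thr))
  if (!is.null(reported_locs) && !is.null(true_target) &&
      !is.null(region_len)) {
    if (is.null(e_bp)) e_bp <- 0.01 * region_len
    rep$e_bp <- e_bp
    rep$success_rate <- success_rate(reported_locs, true_target, e_bp)
    rep$detection_accuracy_pct <-
      detection_accuracy(reported_locs, true_target, region_len)
  }
  structure(rep, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("scan evaluation (%d neutral / %d selection replicates)\n",
              x$n_neutral, x$n_selection))
  cat(sprintf("  threshold at FPR %.0f%%: %.4f -> TPR %.1f%%\n",
              100 * x$fpr_level, x$threshold, 100 * x$tpr))
  if (!is.null(x$success_rate))
    cat(sprintf("  success rate (e = %g bp): %.1f%%; accuracy %.2f%% of L\n",
                x$e_bp, 100 * x$success_rate, x$detection_accuracy_pct))
  invisible(x)
}
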