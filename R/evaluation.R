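normalize_truth <- function(truth) {
  if (is.logical(truth)) return(truth)
  if (is.numeric(truth)) {
    if (!all(truth %in% c(0, 1))) stop("numeric truth must be 0/1", call. = FALSE)
    return(truth == 1)
  }
  truth <- as.character(truth)
  if (!all(truth %in% c("benign", "malignant")))
    stop("truth labels must be 'benign'/'malignant' (or logical/0-1)", call. = FALSE)
  truth == "malignant"
}

#' ROC curve of scored patches
#'
#' Malignant is the positive class. One operating point per distinct score
#' threshold, plus the (0,0) and (1,1) endpoints; the curve is monotone
#' nondecreasing in both coordinates.
#'
#' @param scores numeric malignant-class scores.
#' @param truth class labels: logical (TRUE = malignant), 0/1, or
#'   "benign"/"malignant" strings.
#' @return data.frame with columns \code{fpr}, \code{tpr},
#'   \code{threshold}.
#' @export
roc_curve <- function(scores, truth) {
  truth <- normalize_truth(truth)
  if (length(scores) != length(truth)) stop("length mismatch", call. = FALSE)
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  np <- sum(truth); nn <- sum(!truth)
  if (np == 0 || nn == 0)
    stop("both classes must be present to form a ROC curve", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; t <- truth[ord]
  tp <- cumsum(t); fp <- cumsum(!t)
  last <- c(s[-1] != s[-length(s)], TRUE)  # last index of each tied block
  data.frame(fpr = c(0, fp[last] / nn),
             tpr = c(0, tp[last] / np),
             threshold = c(Inf, s[last]))
}

#' Area under the ROC curve
#'
#' Trapezoidal area under \code{\link{roc_curve}}. With tied scores
#' half-weighted, this equals the rank statistic
#' \code{P(score+ > score-) + 0.5 P(score+ = score-)}.
#'
#' @inheritParams roc_curve
#' @return AUC in \code{[0, 1]}.
#' @export
roc_auc <- function(scores, truth) {
  rc <- roc_curve(scores, truth)
  sum(diff(rc$fpr) * (utils::head(rc$tpr, -1) + utils::tail(rc$tpr, -1)) / 2)
}

#' Threshold classification metrics
#'
#' Accuracy, precision and recall at a fixed operating threshold
#' (malignant = positive, predicted positive iff score >= threshold).
#' Precision is reported as 0 and flagged when no positives are predicted.
#'
#' @inheritParams roc_curve
#' @param threshold operating point, default 0.5.
#' @return list with \code{acc}, \code{precision}, \code{recall} and
#'   \code{precision_defined}.
#' @export
threshold_metrics <- function(scores, truth, threshold = 0.5) {
  truth <- normalize_truth(truth)
  pred <- scores >= threshold
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  fn <- sum(!pred & truth); tn <- sum(!pred & !truth)
  prec_def <- (tp + fp) > 0
  list(acc = (tp + tn) / length(truth),
       precision = if (prec_def) tp / (tp + fp) else 0,
       recall = tp / (tp + fn),
       precision_defined = prec_def)
}

#' Full evaluation report
#'
#' The four criteria used throughout: AUC, ACC, precision and recall, plus
#' the ROC operating points.
#'
#' @inheritParams threshold_metrics
#' @return list classed \code{"eval_report"} with fields \code{auc},
#'   \code{acc}, \code{precision}, \code{recall}, \code{roc},
#'   \code{threshold}, \code{precision_defined}.
#' @export
evaluate_scores <- function(scores, truth, threshold = 0.5) {
  rc <- roc_curve(scores, truth)
  tm <- threshold_metrics(scores, truth, threshold)
  structure(list(auc = roc_auc(scores, truth), acc = tm$acc,
                 precision = tm$precision, recall = tm$recall,
                 precision_defined = tm$precision_defined,
                 roc = rc, threshold = threshold),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: AUC %.3f, ACC %.3f, precision %.3f, recall %.3f (thr %.2f)>\n",
              x$auc, x$acc, x$precision, x$recall, x$threshold))
  invisible(x)
}
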