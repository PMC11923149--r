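# Protein-centric F-score and per-class AUPR.

#' Protein-centric F-score (plain and F-max)
#'
#' Each protein carries one true label and one predicted label with a
#' confidence. At a confidence threshold t the protein's predicted set
#' is its label if the confidence reaches t, else empty. Precision is
#' averaged over proteins with a non-empty prediction, recall over all
#' proteins, and the F-score is their harmonic mean. \code{fmax} is the
#' maximum over a threshold sweep (the convention of protein-function
#' prediction benchmarks); \code{f1} is the value at threshold 0, where
#' every protein predicts and the score reduces to accuracy for
#' single-label prediction.
#'
#' @param predLabels predicted labels.
#' @param confidences prediction confidences in [0, 1].
#' @param truthLabels true labels (same length).
#' @param thresholds threshold grid; default 0 plus all distinct
#'   confidences.
#' @return list with \code{f1}, \code{fmax}, \code{bestThreshold} and
#'   the sweep \code{curve} (threshold, precision, recall, f).
#' @export
proteinCentricF1 <- function(predLabels, confidences, truthLabels,
                             thresholds = NULL) {
  stopifnot(length(predLabels) == length(truthLabels),
            length(confidences) == length(predLabels))
  if (is.null(thresholds))
    thresholds <- sort(unique(c(0, confidences)))
  correct <- predLabels == truthLabels
  n <- length(predLabels)
  rows <- lapply(thresholds, function(t) {
    covered <- confidences >= t
    prec <- if (any(covered)) mean(correct[covered]) else 0
    rec <- sum(correct & covered) / n
    f <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    data.frame(threshold = t, precision = prec, recall = rec, f = f)
  })
  curve <- do.call(rbind, rows)
  best <- which.max(curve$f)
  list(f1 = curve$f[curve$threshold == 0][1],
       fmax = curve$f[best], bestThreshold = curve$threshold[best],
       curve = curve)
}

# area under one precision-recall curve by step interpolation:
# sum over descending-score cut points of (R_i - R_{i-1}) * P_i,
# tie groups collapsed to their last rank
.aupr_one <- function(scores, positive) {
  P <- sum(positive)
  if (P == 0L) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; pos <- positive[ord]
  tp <- cumsum(pos)
  k <- seq_along(s)
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  prec <- (tp / k)[last_of_tie]
  rec <- (tp / P)[last_of_tie]
  sum((rec - c(0, rec[-length(rec)])) * prec)
}

#' Per-class area under the precision-recall curve
#'
#' One-vs-rest per class over that class's score column, area by step
#' interpolation. Classes without positives in the truth are excluded
#' (reported as NA) and noted.
#'
#' @param scores N x C score matrix (e.g. softmax probabilities).
#' @param truths integer true class indices (1..C).
#' @param classNames optional class names for the result.
#' @return list with \code{perClass} (named vector, NA for classes
#'   without positives) and \code{macro} (unweighted mean over reported
#'   classes).
#' @export
perClassAUPR <- function(scores, truths, classNames = NULL) {
  C <- ncol(scores)
  vals <- vapply(seq_len(C), function(c)
    .aupr_one(scores[, c], truths == c), numeric(1))
  if (!is.null(classNames)) names(vals) <- classNames
  if (anyNA(vals))
    message(sum(is.na(vals)), " class(es) without positives excluded from AUPR")
  list(perClass = vals, macro = mean(vals, na.rm = TRUE))
}
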