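#' Segmentation agreement metrics
#'
#' `diceCoefficient` computes the Dice similarity coefficient
#' `2|A and B| / (|A| + |B|)`; `maskIoU` the intersection over union
#' `|A and B| / |A or B|`. Both are defined as 1 when the two masks are
#' both empty (so background-only tiles do not produce NaN in batch
#' evaluation), and satisfy the identity `dsc = 2 iou / (1 + iou)`.
#'
#' @param a,b logical masks of equal dimensions.
#' @return a fraction in [0, 1].
#' @examples
#' a <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
#' diceCoefficient(a, a)
#' @export
diceCoefficient <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask dimensions differ")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}

#' @rdname diceCoefficient
#' @export
maskIoU <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask dimensions differ")
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' Average precision of a confidence ranking
#'
#' Area under the precision-recall curve over all score thresholds,
#' computed by the rank-based sum `sum_k precision(k) * delta-recall(k)`
#' with tied scores entering a threshold together. Constant scores give a
#' single PR point, so the AP equals the prevalence of positives.
#'
#' @param scores numeric confidences (higher = more positive).
#' @param truth logical vector of the same length; must contain at least
#'   one positive.
#' @return a fraction in [0, 1].
#' @export
averagePrecision <- function(scores, truth) {
  if (length(scores) != length(truth)) stop("length mismatch")
  truth <- as.logical(truth)
  P <- sum(truth)
  if (P == 0) stop("average precision undefined without positives")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; t <- truth[o]
  cut <- cumsum(rle(s)$lengths)     # last index of each distinct threshold
  tp <- cumsum(t)[cut]
  n <- cut
  prec <- tp / n
  rec <- tp / P
  sum(prec * diff(c(0, rec)))
}

#' Confusion matrix for 3-class TSR scores
#'
#' @param truth,pred integer vectors with values in {0, 1, 2}; equal
#'   lengths.
#' @return 3 x 3 integer matrix (rows = truth, columns = prediction) with
#'   dimnames `"0".."2"` and attribute `perClassAccuracy` (diagonal over
#'   row sums; NaN for absent classes).
#' @export
scoreConfusionMatrix <- function(truth, pred) {
  if (length(truth) != length(pred)) stop("length mismatch")
  if (any(!(c(truth, pred) %in% 0:2))) stop("labels outside {0,1,2}")
  m <- matrix(0L, 3, 3, dimnames = list(truth = 0:2, pred = 0:2))
  for (i in seq_along(truth))
    m[truth[i] + 1L, pred[i] + 1L] <- m[truth[i] + 1L, pred[i] + 1L] + 1L
  attr(m, "perClassAccuracy") <- diag(m) / rowSums(m)
  m
}

#' Select slides for extrinsic review by score-ratio quantiles
#'
#' Keeps the slides whose TSR score ratio falls in the lower or upper tail
#' of the empirical distribution. Tails use the inverse-CDF (type-1)
#' empirical quantile computed from each end: the lower tail is
#' `ratio <= sorted[ceiling(n * lowQ)]` and the upper tail is
#' `ratio >= sorted[n - ceiling(n * (1 - highQ)) + 1]`, so `n = 20` slides
#' with distinct ratios yield exactly one slide per 5% tail. When all
#' ratios are equal the quantiles degenerate and every slide is selected,
#' with a warning.
#'
#' @param ratios data.frame with columns `slide_id` and `ratio`, or a
#'   named numeric vector.
#' @param lowQ,highQ tail probabilities (defaults 0.05 and 0.95).
#' @return character vector of selected slide ids.
#' @export
selectExtrinsicSlides <- function(ratios, lowQ = 0.05, highQ = 0.95) {
  if (is.data.frame(ratios)) {
    ids <- as.character(ratios$slide_id)
    r <- ratios$ratio
  } else {
    ids <- names(ratios)
    r <- as.numeric(ratios)
  }
  if (length(r) == 0) stop("empty ratio table")
  n <- length(r)
  s <- sort(r)
  ceil <- function(x) as.integer(ceiling(x - 1e-9))  # guard fp noise
  lo <- s[max(1L, ceil(n * lowQ))]
  hi <- s[n - max(1L, ceil(n * (1 - highQ))) + 1L]
  if (lo >= hi)
    warning("degenerate quantiles: tails overlap, selecting all slides")
  ids[r <= lo | r >= hi]
}

#' Sample patches for manual review
#'
#' Draws a uniform sample without replacement from the available patches:
#' at least `nMin` but strictly fewer than `nMax` per slide, capped at the
#' number available (with a warning when fewer than `nMin` exist).
#' Deterministic per seed.
#'
#' @param patchIds vector of candidate patch identifiers.
#' @param nMin,nMax sampling bounds (defaults 10 and 30; the sample size
#'   is `min(nMax - 1, max(nMin, available))`, capped at `available`).
#' @param seed integer seed.
#' @return subset of `patchIds`.
#' @export
sampleReviewPatches <- function(patchIds, nMin = 10L, nMax = 30L,
                                seed = 1L) {
  avail <- length(patchIds)
  size <- min(nMax - 1L, max(nMin, avail), avail)
  if (avail < nMin)
    warning(sprintf("only %d patches available (minimum requested %d)",
                    avail, nMin))
  withr::with_seed(seed, patchIds[sample.int(avail, size)])
}

#' Evaluate a segmenter backend against ground truth
#'
#' Convenience wrapper: runs [segmentPatch()] over a labeled patch set and
#' returns per-patch Dice and IoU for the tumor and stroma classes plus
#' overall pixel accuracy against the ground-truth rasters.
#'
#' @param backend a [SegmenterBackend-class].
#' @param patches a [PatchSet-class] with ground-truth rasters.
#' @return data.frame with one row per patch: `dice_tumor`,
#'   `dice_stroma`, `iou_tumor`, `iou_stroma`, `pixel_accuracy`.
#' @export
evaluateSegmenter <- function(backend, patches) {
  stopifnot(is(patches, "PatchSet"), length(patches@truth) > 0)
  n <- nrow(patches@origins)
  out <- data.frame(dice_tumor = numeric(n), dice_stroma = numeric(n),
                    iou_tumor = numeric(n), iou_stroma = numeric(n),
                    pixel_accuracy = numeric(n))
  for (i in seq_len(n)) {
    pred <- segmentPatch(backend, patches@images[[i]])
    tr <- patches@truth[[i]]
    out$dice_tumor[i] <- diceCoefficient(pred == 1L, tr == 1L)
    out$dice_stroma[i] <- diceCoefficient(pred == 2L, tr == 2L)
    out$iou_tumor[i] <- maskIoU(pred == 1L, tr == 1L)
    out$iou_stroma[i] <- maskIoU(pred == 2L, tr == 2L)
    out$pixel_accuracy[i] <- mean(pred == tr)
  }
  out
}
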