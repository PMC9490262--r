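#' Summarize patch-level TSR predictions within the interface
#'
#' Counts predicted TSR scores of the stroma patches lying within the
#' tumor-stroma interface and reduces them to one feature row per slide:
#' the normalized score distribution (`ratio_0/1/2`), the mean score
#' (`ratio_1 + 2 * ratio_2`) and the population standard deviation, per
#' criterion, each patch entering with equal weight. A patch is "within
#' the interface" iff more than `minOverlap` of its downsampled footprint
#' intersects the interface mask (default `minOverlap = 0`: any overlap).
#'
#' @param prediction a [SlidePrediction-class].
#' @param interface an [InterfaceResult-class] (or a logical mask at
#'   scale `r`).
#' @param r scale factor of the interface mask; taken from `interface`
#'   when it is an [InterfaceResult-class].
#' @param minOverlap fraction in [0, 1); a patch is included when its
#'   footprint overlap with the interface strictly exceeds this.
#' @return one-row data.frame: `slide_id`, `n_interface_patches`,
#'   `undefined` (TRUE when no stroma patch touches the interface; ratio
#'   columns are then NA rather than silently zero), and per criterion
#'   `<crit>_ratio0/1/2`, `<crit>_mean`, `<crit>_sd`.
#' @export
summarizeSlide <- function(prediction, interface, r = NULL,
                           minOverlap = 0) {
  stopifnot(is(prediction, "SlidePrediction"))
  if (is(interface, "InterfaceResult")) {
    r <- interface@r
    imask <- interface@interfaceMask
  } else {
    if (is.null(r)) stop("r required when interface is a plain mask")
    imask <- interface
  }
  preds <- prediction@predictions
  ps <- prediction@patchSize
  block <- max(1L, round(ps * r))
  h <- nrow(imask); w <- ncol(imask)
  stroma <- which(preds$class == "stroma" & !is.na(preds$fibrosis))
  inInterface <- logical(length(stroma))
  for (k in seq_along(stroma)) {
    i <- stroma[k]
    y0 <- floor(preds$y[i] * r); x0 <- floor(preds$x[i] * r)
    rows <- (y0 + 1L):min(y0 + block, h)
    cols <- (x0 + 1L):min(x0 + block, w)
    inInterface[k] <- mean(imask[rows, cols]) > minOverlap
  }
  sel <- stroma[inInterface]
  row <- data.frame(slide_id = prediction@slideId,
                    n_interface_patches = length(sel),
                    undefined = length(sel) == 0L)
  for (crit in .criteria) {
    if (length(sel) == 0L) {
      vals <- c(NA_real_, NA_real_, NA_real_, NA_real_, NA_real_)
    } else {
      sc <- preds[[crit]][sel]
      ratio <- tabulate(sc + 1L, nbins = 3L) / length(sc)
      vals <- c(ratio, ratio[2] + 2 * ratio[3],
                sqrt(mean((sc - mean(sc))^2)))      # population SD
    }
    names(vals) <- paste0(crit, c("_ratio0", "_ratio1", "_ratio2",
                                  "_mean", "_sd"))
    row <- cbind(row, as.data.frame(as.list(vals)))
  }
  row
}

#' Join per-slide feature rows to a clinical table
#'
#' Inner join of slide-level TSR feature rows to per-case clinical
#' records, via an optional slide-to-case mapping (default: slide id is
#' the case id). Unmatched ids on either side are reported as an
#' attribute. Several slides per case are an error unless
#' `aggregate = "mean"`, in which case numeric feature columns are
#' averaged per case.
#'
#' @param features data.frame of rows from [summarizeSlide()].
#' @param clinical data.frame with a `case_id` column.
#' @param mapping optional data.frame with columns `slide_id`, `case_id`.
#' @param aggregate `"error"` (default) or `"mean"`.
#' @return joined data.frame (one row per matched case) with attribute
#'   `unmatched` listing dropped slide and case ids.
#' @export
buildCohortTable <- function(features, clinical, mapping = NULL,
                             aggregate = c("error", "mean")) {
  aggregate <- match.arg(aggregate)
  if (is.null(mapping))
    mapping <- data.frame(slide_id = features$slide_id,
                          case_id = features$slide_id)
  feats <- merge(features, mapping, by = "slide_id")
  if (anyDuplicated(feats$case_id)) {
    if (aggregate == "error")
      stop("multiple slides map to one case; use aggregate = 'mean'")
    num <- vapply(feats, is.numeric, logical(1))
    num["case_id"] <- FALSE
    agg <- stats::aggregate(feats[num], by = list(case_id = feats$case_id),
                            FUN = mean)
    feats <- agg
  }
  joined <- merge(feats, clinical, by = "case_id")
  attr(joined, "unmatched") <- list(
    slides = setdiff(feats$case_id, clinical$case_id),
    cases = setdiff(clinical$case_id, feats$case_id))
  joined
}
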