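#' Stitch patch-level predictions into a slide-level multilabel mask
#'
#' Down-samples patch results by the scale factor `r` and writes each
#' patch's dominant tissue class into the corresponding block of the slide
#' mask; area not covered by any patch stays background. Patches must tile
#' the slide without overlap at the inference stride (overlap is rejected).
#'
#' @param prediction a [SlidePrediction-class] (or a data.frame with
#'   columns `x`, `y`, `class` plus a `patchSize` argument).
#' @param slideDim integer c(height, width) of the slide in pixels.
#' @param r scale factor in (0, 1]; default 1/128. `patchSize * r` must be
#'   >= 1 so each patch maps to at least one mask pixel.
#' @param patchSize required when `prediction` is a plain data.frame.
#' @return a [SlideMask-class] of dimensions `ceiling(slideDim * r)`.
#' @export
stitchPatches <- function(prediction, slideDim, r = 1 / 128,
                          patchSize = NULL) {
  if (is(prediction, "SlidePrediction")) {
    preds <- prediction@predictions
    patchSize <- prediction@patchSize
    slideId <- prediction@slideId
  } else {
    preds <- prediction
    if (is.null(patchSize)) stop("patchSize required for data.frame input")
    slideId <- "slide"
  }
  stopifnot(r > 0, r <= 1)
  block <- round(patchSize * r)
  if (block < 1L) stop("patchSize * r must be >= 1")
  h <- ceiling(slideDim[1] * r); w <- ceiling(slideDim[2] * r)
  labels <- matrix(0L, h, w)
  covered <- matrix(FALSE, h, w)
  code <- c(background = 0L, tumor = 1L, stroma = 2L)
  if (nrow(preds) > 0) {
    ## reject overlap at full resolution
    ox <- preds$x; oy <- preds$y
    o <- order(oy, ox)
    ox <- ox[o]; oy <- oy[o]
    for (i in seq_len(nrow(preds) - 1L)) {
      same <- which(abs(oy - oy[i]) < patchSize & abs(ox - ox[i]) < patchSize)
      if (length(same) > 1L)
        stop("overlapping patches: stitching requires non-overlapping tiling")
    }
  }
  for (i in seq_len(nrow(preds))) {
    y0 <- floor(preds$y[i] * r); x0 <- floor(preds$x[i] * r)
    rows <- (y0 + 1L):min(y0 + block, h)
    cols <- (x0 + 1L):min(x0 + block, w)
    labels[rows, cols] <- code[[preds$class[i]]]
    covered[rows, cols] <- TRUE
  }
  new("SlideMask", labels = labels, r = r, slideId = slideId)
}

#' Detect tumor-stroma interface regions by mathematical morphology
#'
#' Implements the morphological interface formula on a slide-level
#' multilabel mask. With `I_T` and `I_S` the binary tumor and stroma
#' images and `S` the structuring element:
#' \deqn{Tumor_{core} = C(I_T, S)}
#' \deqn{Stroma_{core} = C(I_S, S)}
#' \deqn{ROI_{interface} = \mathrm{and}(\mathrm{xor}[D(Stroma_{core}, S),
#'   E(Stroma_{core}, S)], Stroma_{core}, D(Tumor_{core}, S))}
#' where C, E and D are morphological closing, erosion and dilation. The
#' XOR of dilation and erosion is the morphological gradient band of the
#' stroma core; intersecting it with the stroma core and the dilated tumor
#' core keeps the stroma-side band that touches tumor. Connected
#' components of the result are labeled (8-connectivity by default) and
#' sorted by decreasing pixel count, ties broken by scan-order id.
#'
#' @param mask a [SlideMask-class].
#' @param selem structuring element from [structuringElement()]
#'   (default disk of radius 2); one element is used for all three
#'   operators unless per-operator overrides are given.
#' @param closeSelem optional override for the two closings.
#' @param connectivity 8 (default) or 4 for component labeling.
#' @return an [InterfaceResult-class]. Empty tumor or stroma yields an
#'   empty interface, not an error.
#' @examples
#' lab <- matrix(0L, 32, 32); lab[, 1:16] <- 1L; lab[, 17:32] <- 2L
#' m <- new("SlideMask", labels = lab, r = 1/128, slideId = "s")
#' detectInterface(m)
#' @export
detectInterface <- function(mask, selem = structuringElement("disk", 2L),
                            closeSelem = selem, connectivity = 8) {
  stopifnot(is(mask, "SlideMask"))
  IT <- mask@labels == 1L
  IS <- mask@labels == 2L
  tumorCore <- binClose(IT, closeSelem)
  stromaCore <- binClose(IS, closeSelem)
  band <- xor(binDilate(stromaCore, selem), binErode(stromaCore, selem))
  interface <- band & stromaCore & binDilate(tumorCore, selem)
  lab <- connectedComponents(interface, connectivity = connectivity)
  cmp <- componentTable(lab)
  cmp <- cmp[order(-cmp$size, cmp$id), , drop = FALSE]
  rownames(cmp) <- NULL
  new("InterfaceResult", interfaceMask = interface, components = cmp,
      r = mask@r, slideId = mask@slideId)
}

#' Top-k largest interface components
#'
#' @param result an [InterfaceResult-class].
#' @param k number of components to keep (default 5).
#' @return data.frame of the first `min(k, count)` components by pixel
#'   count (ties broken by smaller scan-order id).
#' @export
topComponents <- function(result, k = 5L) {
  stopifnot(is(result, "InterfaceResult"))
  if (k < 1L) stop("k must be >= 1")
  utils::head(result@components, k)
}
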