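#' Segment one patch into background/tumor/stroma
#'
#' @param backend a [SegmenterBackend-class] implementation.
#' @param image numeric RGB array [y, x, 3] in [0, 1].
#' @return integer matrix [y, x] over {0 = background, 1 = tumor,
#'   2 = stroma}, same spatial dimensions as the input.
#' @export
setGeneric("segmentPatch", function(backend, image)
  standardGeneric("segmentPatch"))

#' Score one patch for a TSR criterion
#'
#' @param backend a [TSRScorerBackend-class] implementation.
#' @param image numeric RGB array [y, x, 3] in [0, 1].
#' @return list with `score` (integer in {0, 1, 2}) and `prob`
#'   (numeric 3-vector named `p0`/`p1`/`p2`, nonnegative, summing to 1,
#'   with `which.max(prob) - 1 == score`).
#' @export
setGeneric("scorePatch", function(backend, image)
  standardGeneric("scorePatch"))

## ---- accessors -----------------------------------------------------------

#' @rdname PhantomSlide-class
#' @param x object to access.
#' @export
setGeneric("slideImage", function(x) standardGeneric("slideImage"))
#' @rdname PhantomSlide-class
#' @export
setGeneric("tumorMask", function(x) standardGeneric("tumorMask"))
#' @rdname PhantomSlide-class
#' @export
setGeneric("stromaMask", function(x) standardGeneric("stromaMask"))
#' @rdname PhantomSlide-class
#' @export
setGeneric("tsrMaps", function(x) standardGeneric("tsrMaps"))
#' @rdname PhantomSlide-class
#' @export
setGeneric("slideLabel", function(x) standardGeneric("slideLabel"))

#' @rdname PatchSet-class
#' @param x object to access.
#' @export
setGeneric("patchOrigins", function(x) standardGeneric("patchOrigins"))
#' @rdname PatchSet-class
#' @export
setGeneric("patchImages", function(x) standardGeneric("patchImages"))
#' @rdname PatchSet-class
#' @export
setGeneric("patchLabels", function(x) standardGeneric("patchLabels"))
#' @rdname PatchSet-class
#' @export
setGeneric("backgroundFrac", function(x) standardGeneric("backgroundFrac"))
#' @rdname PatchSet-class
#' @export
setGeneric("patchTruth", function(x) standardGeneric("patchTruth"))
#' @rdname PatchSet-class
#' @export
setGeneric("nPatches", function(x) standardGeneric("nPatches"))

#' @rdname SlideMask-class
#' @param x object to access.
#' @export
setGeneric("maskLabels", function(x) standardGeneric("maskLabels"))
#' @rdname SlideMask-class
#' @export
setGeneric("maskScale", function(x) standardGeneric("maskScale"))

#' @rdname InterfaceResult-class
#' @param x object to access.
#' @export
setGeneric("interfaceMask", function(x) standardGeneric("interfaceMask"))
#' @rdname InterfaceResult-class
#' @export
setGeneric("interfaceComponents", function(x)
  standardGeneric("interfaceComponents"))

#' @rdname SlidePrediction-class
#' @param x object to access.
#' @export
setGeneric("patchPredictions", function(x)
  standardGeneric("patchPredictions"))

#' @rdname SyntheticCohort-class
#' @param x object to access.
#' @export
setGeneric("cohortClinical", function(x) standardGeneric("cohortClinical"))
#' @rdname SyntheticCohort-class
#' @export
setGeneric("cohortExpression", function(x)
  standardGeneric("cohortExpression"))
#' @rdname SyntheticCohort-class
#' @export
setGeneric("plantedGenes", function(x) standardGeneric("plantedGenes"))
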