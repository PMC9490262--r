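#' @rdname PhantomSlide-class
setMethod("slideImage", "PhantomSlide", function(x) x@image)
#' @rdname PhantomSlide-class
setMethod("tumorMask", "PhantomSlide", function(x) x@tumorMask)
#' @rdname PhantomSlide-class
setMethod("stromaMask", "PhantomSlide", function(x) x@stromaMask)
#' @rdname PhantomSlide-class
setMethod("tsrMaps", "PhantomSlide", function(x) x@tsrMaps)
#' @rdname PhantomSlide-class
setMethod("slideLabel", "PhantomSlide", function(x) x@label)

#' @rdname PatchSet-class
setMethod("patchOrigins", "PatchSet", function(x) x@origins)
#' @rdname PatchSet-class
setMethod("patchImages", "PatchSet", function(x) x@images)
#' @rdname PatchSet-class
setMethod("patchLabels", "PatchSet", function(x) x@labels)
#' @rdname PatchSet-class
setMethod("backgroundFrac", "PatchSet", function(x) x@backgroundFrac)
#' @rdname PatchSet-class
setMethod("patchTruth", "PatchSet", function(x) x@truth)
#' @rdname PatchSet-class
setMethod("nPatches", "PatchSet", function(x) nrow(x@origins))

#' @rdname SlideMask-class
setMethod("maskLabels", "SlideMask", function(x) x@labels)
#' @rdname SlideMask-class
setMethod("maskScale", "SlideMask", function(x) x@r)

#' @rdname InterfaceResult-class
setMethod("interfaceMask", "InterfaceResult", function(x) x@interfaceMask)
#' @rdname InterfaceResult-class
setMethod("interfaceComponents", "InterfaceResult",
          function(x) x@components)

#' @rdname SlidePrediction-class
setMethod("patchPredictions", "SlidePrediction", function(x) x@predictions)

#' @rdname SyntheticCohort-class
setMethod("cohortClinical", "SyntheticCohort", function(x) x@clinical)
#' @rdname SyntheticCohort-class
setMethod("cohortExpression", "SyntheticCohort", function(x) x@expression)
#' @rdname SyntheticCohort-class
setMethod("plantedGenes", "SyntheticCohort", function(x) x@plantedGenes)

## ---- show methods --------------------------------------------------------

setMethod("show", "PhantomSlide", function(object) {
  d <- dim(object@image)
  cat(sprintf("PhantomSlide (%s-like) %dx%d px, seed %d\n",
              object@label, d[2], d[1], object@seed))
  cat(sprintf("  tumor: %.1f%%  stroma: %.1f%%  background: %.1f%%\n",
              100 * mean(object@tumorMask), 100 * mean(object@stromaMask),
              100 * mean(!object@tumorMask & !object@stromaMask)))
})

setMethod("show", "PatchSet", function(object) {
  cat(sprintf("PatchSet: %d patches of %dx%d px from slide '%s'\n",
              nrow(object@origins), object@patchSize, object@patchSize,
              object@slideId))
  if (nrow(object@labels) > 0)
    cat("  labeled:", paste(names(object@labels), collapse = ", "), "\n")
})

setMethod("show", "SlideMask", function(object) {
  d <- dim(object@labels)
  cat(sprintf("SlideMask '%s' %dx%d at r = %g\n",
              object@slideId, d[2], d[1], object@r))
  cat(sprintf("  tumor: %d px  stroma: %d px  background: %d px\n",
              sum(object@labels == 1L), sum(object@labels == 2L),
              sum(object@labels == 0L)))
})

setMethod("show", "InterfaceResult", function(object) {
  cat(sprintf("InterfaceResult '%s': %d interface px in %d components\n",
              object@slideId, sum(object@interfaceMask),
              nrow(object@components)))
})

setMethod("show", "SlidePrediction", function(object) {
  p <- object@predictions
  cat(sprintf("SlidePrediction '%s': %d patches (%d stroma-dominant)\n",
              object@slideId, nrow(p), sum(p$class == "stroma")))
})

setMethod("show", "SyntheticCohort", function(object) {
  cat(sprintf(
    "SyntheticCohort: %d cases, %d genes (%d planted), log HR %.3g\n",
    nrow(object@clinical), nrow(object@expression),
    length(object@plantedGenes), object@plantedLogHr))
})

setMethod("show", "SegmenterBackend", function(object) {
  cat(sprintf("<%s> segmenter backend '%s' v%s\n",
              class(object), object@name, object@version))
})

setMethod("show", "TSRScorerBackend", function(object) {
  cat(sprintf("<%s> TSR scorer backend '%s' v%s (%s)\n",
              class(object), object@name, object@version, object@criterion))
})
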