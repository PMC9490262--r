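#' @describeIn PatchSet-class subset the patches by index or logical
#'   vector.
#' @param i index vector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "PatchSet", function(x, i, j, ..., drop = FALSE) {
  if (is.logical(i)) i <- which(i)
  new("PatchSet", slideId = x@slideId, patchSize = x@patchSize,
      origins = x@origins[i, , drop = FALSE],
      images = x@images[i],
      backgroundFrac = x@backgroundFrac[i],
      labels = if (nrow(x@labels) > 0) x@labels[i, , drop = FALSE]
               else x@labels,
      truth = if (length(x@truth) > 0) x@truth[i] else x@truth)
})

#' Pool patch sets from several slides
#'
#' Concatenates patches (e.g. HGSOC-like and SBOT-like training material)
#' into one set. All inputs must share the patch size; labels are pooled
#' when every input carries them, dropped otherwise.
#'
#' @param ... [PatchSet-class] objects.
#' @param slideId identifier for the pooled set (default
#'   `"pooled"`).
#' @return a [PatchSet-class].
#' @export
combinePatchSets <- function(..., slideId = "pooled") {
  sets <- list(...)
  stopifnot(length(sets) > 0,
            all(vapply(sets, is, logical(1), "PatchSet")))
  ps <- unique(vapply(sets, function(s) s@patchSize, integer(1)))
  if (length(ps) != 1L) stop("patch sizes differ")
  haveLabels <- all(vapply(sets, function(s) nrow(s@labels) > 0,
                           logical(1)))
  haveTruth <- all(vapply(sets, function(s) length(s@truth) > 0,
                          logical(1)))
  new("PatchSet", slideId = slideId, patchSize = ps,
      origins = do.call(rbind, lapply(sets, function(s) s@origins)),
      images = do.call(c, lapply(sets, function(s) s@images)),
      backgroundFrac = do.call(c, lapply(sets,
                                         function(s) s@backgroundFrac)),
      labels = if (haveLabels)
        do.call(rbind, lapply(sets, function(s) s@labels))
      else data.frame(),
      truth = if (haveTruth) do.call(c, lapply(sets, function(s) s@truth))
              else list())
}
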