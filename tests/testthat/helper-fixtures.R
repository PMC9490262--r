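## Shared fixtures, memoized per test run: phantom generation and backend
## fitting are the expensive steps, and many tests only need one slide.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache))
    assign(key, expr, envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

testSlide <- function(seed = 7, label = "HGSOC", size = 1024L, blobs = 2L) {
  key <- sprintf("slide_%s_%d_%d_%d", label, seed, size, blobs)
  cached(key, generatePhantomSlide(phantomConfig(
    width = size, height = size, tumorBlobCount = blobs,
    label = label, seed = seed)))
}

testPatches <- function(seed = 7, label = "HGSOC", size = 1024L,
                        stride = 256L) {
  key <- sprintf("patches_%s_%d_%d_%d", label, seed, size, stride)
  cached(key, generateLabeledPatches(
    testSlide(seed, label, size),
    tilingConfig(patchSize = 256L, stride = stride)))
}

## pooled labeled training material: 2 HGSOC + 1 SBOT phantom
trainingPatches <- function() {
  cached("train", combinePatchSets(
    testPatches(1, "HGSOC", stride = 128L),
    testPatches(2, "HGSOC", stride = 128L),
    testPatches(3, "SBOT", stride = 128L)))
}

homogeneousStroma <- function(patches, criterion = "fibrosis",
                              minPurity = 0.75) {
  lab <- patchLabels(patches)
  patches[lab$class == "stroma" & !is.na(lab[[criterion]]) &
            lab[[paste0(criterion, "_purity")]] >= minPurity &
            lab$stroma_frac >= 0.75]
}

testSegmenter <- function() {
  cached("segmenter", fitReferenceSegmenter(trainingPatches()))
}

testScorers <- function() {
  cached("scorers", {
    hom <- homogeneousStroma(trainingPatches())
    sapply(c("fibrosis", "cellularity", "orientation"), function(cr)
      fitReferenceTsrScorer(hom, cr), simplify = FALSE)
  })
}

## mock backends exercising the contracts without any model
setClass("ConstantSegmenter", contains = "SegmenterBackend",
         representation(value = "integer"))
setMethod("segmentPatch", "ConstantSegmenter", function(backend, image) {
  matrix(backend@value, dim(image)[1], dim(image)[2])
})

setClass("ConstantScorer", contains = "TSRScorerBackend",
         representation(value = "integer"))
setMethod("scorePatch", "ConstantScorer", function(backend, image) {
  prob <- c(p0 = 0, p1 = 0, p2 = 0)
  prob[backend@value + 1L] <- 1
  list(score = backend@value, prob = prob)
})

constantSegmenter <- function(value = 2L)
  new("ConstantSegmenter", name = "const", version = "0",
      value = as.integer(value))
constantScorer <- function(criterion, value = 0L)
  new("ConstantScorer", name = "const", version = "0",
      criterion = criterion, value = as.integer(value))

## a broken backend for contract-violation surfacing
setClass("BrokenSegmenter", contains = "SegmenterBackend")
setMethod("segmentPatch", "BrokenSegmenter", function(backend, image) {
  matrix(7L, 2, 2)    # wrong dims and labels
})
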