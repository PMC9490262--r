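#' @import methods
NULL

## Raster conventions used throughout the package:
##  - RGB images are numeric arrays [row (y), col (x), channel] in [0, 1].
##  - Binary masks are logical matrices [y, x].
##  - Label rasters are integer matrices with 0 = background, 1 = tumor,
##    2 = stroma.
##  - Pixel coordinates are 0-based, x rightwards, y downwards, with
##    half-open extents [origin, origin + size).

#' Tiling configuration
#'
#' Parameters controlling sliding-window patch extraction from a slide:
#' patch edge length, sampling stride, the downsample factor at which
#' foreground (tissue) is detected, and the maximum tolerated background
#' fraction for a patch to survive.
#'
#' @slot patchSize integer, patch edge length in pixels.
#' @slot stride integer, grid stride in pixels; `0 < stride <= patchSize`.
#' @slot fgDownsample integer, downsample factor for slide-level foreground
#'   detection.
#' @slot maxBackgroundFrac numeric in (0, 1], patches whose recomputed
#'   full-resolution background fraction exceeds this are excluded.
#' @exportClass TilingConfig
setClass("TilingConfig",
  representation(
    patchSize = "integer",
    stride = "integer",
    fgDownsample = "integer",
    maxBackgroundFrac = "numeric"
  )
)

setValidity("TilingConfig", function(object) {
  msg <- NULL
  if (length(object@patchSize) != 1L || object@patchSize < 1L)
    msg <- c(msg, "patchSize must be a positive integer")
  if (length(object@stride) != 1L || object@stride < 1L ||
      object@stride > object@patchSize)
    msg <- c(msg, "stride must satisfy 0 < stride <= patchSize")
  if (object@fgDownsample < 1L)
    msg <- c(msg, "fgDownsample must be >= 1")
  if (object@maxBackgroundFrac <= 0 || object@maxBackgroundFrac > 1)
    msg <- c(msg, "maxBackgroundFrac must be in (0, 1]")
  if (is.null(msg)) TRUE else msg
})

#' Create a tiling configuration
#'
#' @param patchSize patch edge length in pixels (default 256).
#' @param stride sampling stride in pixels; defaults to `patchSize`
#'   (non-overlapping inference tiling). Use 128 with the default patch size
#'   to reproduce the half-overlapping training-set extraction.
#' @param fgDownsample downsample factor for slide-level tissue detection
#'   (default 128).
#' @param maxBackgroundFrac maximum background fraction for a surviving
#'   patch (default 0.5).
#' @return A [TilingConfig-class] object.
#' @examples
#' tilingConfig(patchSize = 256, stride = 128)
#' @export
tilingConfig <- function(patchSize = 256L, stride = patchSize,
                         fgDownsample = 128L, maxBackgroundFrac = 0.5) {
  new("TilingConfig",
      patchSize = as.integer(patchSize), stride = as.integer(stride),
      fgDownsample = as.integer(fgDownsample),
      maxBackgroundFrac = as.numeric(maxBackgroundFrac))
}

#' Phantom slide configuration
#'
#' Parameters of the synthetic slide generator. A phantom emulates an
#' H&E-like section with three texturally distinct tissue classes
#' (tumor, stroma, background) and, on HGSOC-like slides, a spatial
#' tumor-stroma reaction (TSR) gradient: stroma close to tumor carries high
#' scores, stroma far from tumor carries score 0. Score rendering maps the
#' fibrosis score to a base stroma color and superimposes criterion-specific
#' texture (fibrous streaks for fibrosis, dark nuclei-like dots for
#' cellularity, oriented stripes for orientation).
#'
#' @slot width,height slide dimensions in pixels (each >= 512).
#' @slot tumorBlobCount number of tumor islands; must be >= 1 for
#'   HGSOC-like slides.
#' @slot label `"HGSOC"` (TSR present) or `"SBOT"` (borderline control,
#'   all TSR scores identically 0).
#' @slot backgroundRgb,tumorRgb base colors in [0, 1].
#' @slot stromaRgbByScore 3 x 3 matrix, row s+1 is the base color of stroma
#'   with score s; rows pairwise separated by construction.
#' @slot noiseAmp per-pixel Gaussian noise SD added to every channel.
#' @slot scoreThresholds two increasing distances (pixels from the nearest
#'   tumor pixel): score 2 within the first, 1 within the second, 0 beyond.
#' @slot stripeFreq,dotDensity,fiberAmp texture parameters (cycles/px,
#'   dots/px scale, additive amplitude).
#' @slot hardMode logical; if TRUE the stroma base colors are pulled toward
#'   each other to stress classifiers.
#' @slot seed integer RNG seed; generation is bit-reproducible per seed.
#' @exportClass PhantomConfig
setClass("PhantomConfig",
  representation(
    width = "integer", height = "integer",
    tumorBlobCount = "integer",
    label = "character",
    backgroundRgb = "numeric", tumorRgb = "numeric",
    stromaRgbByScore = "matrix",
    noiseAmp = "numeric",
    scoreThresholds = "numeric",
    stripeFreq = "numeric", dotDensity = "numeric", fiberAmp = "numeric",
    hardMode = "logical",
    seed = "integer"
  )
)

setValidity("PhantomConfig", function(object) {
  msg <- NULL
  if (object@width < 512L || object@height < 512L)
    msg <- c(msg, "width and height must be >= 512")
  if (!object@label %in% c("HGSOC", "SBOT"))
    msg <- c(msg, "label must be 'HGSOC' or 'SBOT'")
  if (object@label == "HGSOC" && object@tumorBlobCount < 1L)
    msg <- c(msg, "an HGSOC-like slide needs at least one tumor blob")
  if (object@tumorBlobCount < 0L)
    msg <- c(msg, "tumorBlobCount must be >= 0")
  if (!identical(dim(object@stromaRgbByScore), c(3L, 3L)))
    msg <- c(msg, "stromaRgbByScore must be a 3x3 matrix (rows = scores 0..2)")
  if (length(object@scoreThresholds) != 2L ||
      diff(object@scoreThresholds) <= 0)
    msg <- c(msg, "scoreThresholds must be two increasing distances")
  if (is.null(msg)) TRUE else msg
})

#' Phantom slide
#'
#' A synthetic slide with ground truth: the rendered RGB image, disjoint
#' binary tumor and stroma masks, and three integer TSR score maps
#' (fibrosis, cellularity, orientation; values 0/1/2) defined exactly on
#' stroma pixels (NA elsewhere). SBOT-like slides have all score maps
#' identically 0 on stroma.
#'
#' @slot image numeric array [y, x, 3] in [0, 1].
#' @slot tumorMask,stromaMask logical matrices; pairwise disjoint.
#' @slot tsrMaps named list of three integer matrices
#'   (`fibrosis`, `cellularity`, `orientation`).
#' @slot label `"HGSOC"` or `"SBOT"`.
#' @slot seed integer seed the slide was generated with.
#' @slot config the generating [PhantomConfig-class].
#' @exportClass PhantomSlide
setClass("PhantomSlide",
  representation(
    image = "array",
    tumorMask = "matrix", stromaMask = "matrix",
    tsrMaps = "list",
    label = "character",
    seed = "integer",
    config = "PhantomConfig"
  )
)

setValidity("PhantomSlide", function(object) {
  msg <- NULL
  d <- dim(object@image)
  if (length(d) != 3L || d[3] != 3L)
    msg <- c(msg, "image must be a [y, x, 3] array")
  if (!identical(dim(object@tumorMask), d[1:2]) ||
      !identical(dim(object@stromaMask), d[1:2]))
    msg <- c(msg, "masks must match image dimensions")
  if (any(object@tumorMask & object@stromaMask))
    msg <- c(msg, "tumorMask and stromaMask must be disjoint")
  if (!identical(sort(names(object@tsrMaps)),
                 sort(c("fibrosis", "cellularity", "orientation"))))
    msg <- c(msg, "tsrMaps must be named fibrosis/cellularity/orientation")
  for (nm in names(object@tsrMaps)) {
    m <- object@tsrMaps[[nm]]
    if (!identical(dim(m), d[1:2])) {
      msg <- c(msg, sprintf("tsrMaps$%s dims mismatch", nm))
      next
    }
    if (!identical(!is.na(m), unname(object@stromaMask)))
      msg <- c(msg, sprintf(
        "tsrMaps$%s must be defined exactly on stroma pixels", nm))
    if (any(!is.na(m) & !(m %in% 0:2)))
      msg <- c(msg, sprintf("tsrMaps$%s values must be in {0,1,2}", nm))
  }
  if (object@label == "SBOT" &&
      any(vapply(object@tsrMaps, function(m) any(m > 0, na.rm = TRUE),
                 logical(1))))
    msg <- c(msg, "SBOT-like slides must have all TSR scores 0")
  if (is.null(msg)) TRUE else msg
})

#' A set of image patches extracted from one slide
#'
#' Records the patch grid (0-based pixel origins at level 0), the cropped
#' patch images, the per-patch background fraction, and — when produced by
#' [generateLabeledPatches()] — ground-truth class/score labels and
#' per-patch label rasters.
#'
#' @slot slideId character scalar.
#' @slot patchSize integer patch edge length.
#' @slot origins integer matrix n x 2, columns `x`, `y` (0-based).
#' @slot images list of n numeric arrays [size, size, 3].
#' @slot backgroundFrac numeric vector of length n in [0, 1].
#' @slot labels data.frame with 0 or n rows; when labeled it has columns
#'   `class` (background/tumor/stroma) and `fibrosis`, `cellularity`,
#'   `orientation` (modal stroma score, NA for patches without stroma).
#' @slot truth list of length 0 or n of integer label rasters (0/1/2).
#' @exportClass PatchSet
setClass("PatchSet",
  representation(
    slideId = "character",
    patchSize = "integer",
    origins = "matrix",
    images = "list",
    backgroundFrac = "numeric",
    labels = "data.frame",
    truth = "list"
  )
)

setValidity("PatchSet", function(object) {
  msg <- NULL
  n <- nrow(object@origins)
  if (ncol(object@origins) != 2L)
    msg <- c(msg, "origins must have two columns (x, y)")
  if (length(object@images) != n)
    msg <- c(msg, "one image per origin required")
  if (length(object@backgroundFrac) != n)
    msg <- c(msg, "one backgroundFrac per origin required")
  if (n > 0 && any(object@backgroundFrac < 0 | object@backgroundFrac > 1))
    msg <- c(msg, "backgroundFrac must be in [0, 1]")
  if (nrow(object@labels) %not_in% c(0L, n))
    msg <- c(msg, "labels must have 0 or n rows")
  if (length(object@truth) %not_in% c(0L, n))
    msg <- c(msg, "truth must have length 0 or n")
  if (is.null(msg)) TRUE else msg
})

`%not_in%` <- function(x, table) !(x %in% table)

#' Slide-level multilabel mask
#'
#' The stitched tumor/stroma segmentation of a slide at a downsample scale
#' `r`: an integer raster with 0 = background, 1 = tumor, 2 = stroma. The
#' tumor and stroma indicator images used by the interface formula are
#' `maskLabels(x) == 1` and `maskLabels(x) == 2`.
#'
#' @slot labels integer matrix [y, x] over {0, 1, 2}.
#' @slot r numeric scale factor in (0, 1]; mask dims = ceiling(slide dims * r).
#' @slot slideId character scalar.
#' @exportClass SlideMask
setClass("SlideMask",
  representation(labels = "matrix", r = "numeric", slideId = "character")
)

setValidity("SlideMask", function(object) {
  msg <- NULL
  if (object@r <= 0 || object@r > 1)
    msg <- c(msg, "r must be in (0, 1]")
  if (any(!(object@labels %in% 0:2)))
    msg <- c(msg, "labels must be 0 (background), 1 (tumor) or 2 (stroma)")
  if (is.null(msg)) TRUE else msg
})

#' Structuring element for morphological operations
#'
#' A flat binary structuring element used by closing, erosion and dilation
#' in tumor-stroma interface detection. `"disk"` includes offsets with
#' Euclidean norm <= radius; `"square"` is the full (2r+1) x (2r+1) window.
#'
#' @param shape `"disk"` or `"square"`.
#' @param radius integer >= 1, in pixels at the mask scale.
#' @return A 0/1 matrix of odd dimensions with attribute `shape`.
#' @examples
#' structuringElement("disk", 2)
#' @export
structuringElement <- function(shape = c("disk", "square"), radius = 2L) {
  shape <- match.arg(shape)
  radius <- as.integer(radius)
  if (radius < 1L) stop("radius must be >= 1")
  off <- -radius:radius
  kern <- switch(shape,
    disk = outer(off, off, function(a, b) as.numeric(a^2 + b^2 <= radius^2)),
    square = matrix(1, 2L * radius + 1L, 2L * radius + 1L))
  attr(kern, "shape") <- shape
  attr(kern, "radius") <- radius
  kern
}

#' Tumor-stroma interface detection result
#'
#' @slot interfaceMask logical matrix at the [SlideMask-class] scale.
#' @slot components data.frame with columns `id` (scan-order component
#'   label), `size` (pixel count), `xmin`, `xmax`, `ymin`, `ymax`
#'   (0-based bounding box), sorted by decreasing size with ties broken by
#'   smaller id.
#' @slot r numeric scale factor inherited from the input mask.
#' @slot slideId character scalar.
#' @exportClass InterfaceResult
setClass("InterfaceResult",
  representation(
    interfaceMask = "matrix",
    components = "data.frame",
    r = "numeric",
    slideId = "character"
  )
)

setValidity("InterfaceResult", function(object) {
  msg <- NULL
  cmp <- object@components
  need <- c("id", "size", "xmin", "xmax", "ymin", "ymax")
  if (!all(need %in% names(cmp)))
    msg <- c(msg, "components must have id/size/xmin/xmax/ymin/ymax")
  else {
    if (nrow(cmp) > 0 && is.unsorted(-cmp$size))
      msg <- c(msg, "components must be sorted by non-increasing size")
    if (sum(cmp$size) != sum(object@interfaceMask))
      msg <- c(msg, "component sizes must partition the interface mask")
  }
  if (is.null(msg)) TRUE else msg
})

#' Backend contracts for patch-level models
#'
#' `SegmenterBackend` is the contract for patch tumor/stroma segmentation:
#' a backend maps an RGB patch to a per-pixel label raster over
#' {0 = background, 1 = tumor, 2 = stroma} of the same spatial dimensions
#' (generic [segmentPatch()]). `TSRScorerBackend` is the contract for
#' single-criterion TSR scoring: a backend maps an RGB patch to a score in
#' {0, 1, 2} together with a 3-vector of class probabilities summing to 1
#' (generic [scorePatch()]). Trained deep models can be dropped in by
#' subclassing either contract; the package ships classical reference
#' implementations ([fitReferenceSegmenter()], [fitReferenceTsrScorer()]).
#'
#' @slot name,version backend metadata.
#' @aliases TSRScorerBackend-class
#' @exportClass SegmenterBackend
setClass("SegmenterBackend",
  representation("VIRTUAL", name = "character", version = "character"))

#' @slot criterion for scorers: one of fibrosis/cellularity/orientation.
#' @rdname SegmenterBackend-class
#' @exportClass TSRScorerBackend
setClass("TSRScorerBackend",
  representation("VIRTUAL", name = "character", version = "character",
                 criterion = "character"))

#' Reference segmenter: pixelwise linear discriminant on color + texture
#' @slot model fitted `MASS::lda` object.
#' @slot varRadius window radius of the local-SD texture feature.
#' @keywords internal
#' @exportClass LDASegmenter
setClass("LDASegmenter", contains = "SegmenterBackend",
  representation(model = "ANY", varRadius = "integer"))

#' Reference TSR scorer: patch-summary linear discriminant
#' @slot model fitted `MASS::lda` object.
#' @keywords internal
#' @exportClass LDATSRScorer
setClass("LDATSRScorer", contains = "TSRScorerBackend",
  representation(model = "ANY"))

#' Per-patch predictions for one slide
#'
#' Output of [predictSlide()]: one row per surviving patch with its
#' dominant tissue class and, for stroma-dominant patches, the three TSR
#' scores and class probabilities; plus the per-patch label rasters.
#'
#' @slot slideId character scalar.
#' @slot patchSize integer.
#' @slot predictions data.frame with columns `x`, `y`, `class`,
#'   `fibrosis`, `cellularity`, `orientation` and probability columns
#'   `<criterion>_p0/_p1/_p2` (scores NA for non-stroma patches).
#' @slot classMasks list of integer label rasters, one per patch.
#' @exportClass SlidePrediction
setClass("SlidePrediction",
  representation(
    slideId = "character",
    patchSize = "integer",
    predictions = "data.frame",
    classMasks = "list"
  )
)

#' Synthetic cohort with planted clinical and molecular effects
#'
#' A generated cohort for validating the association stage: survival with a
#' planted fibrosis-group hazard effect, and an expression matrix in which
#' a chosen fraction of genes depends monotonically on the per-case
#' fibrosis score while all others are independent noise.
#'
#' @slot clinical data.frame: `case_id`, `time` (months), `event` (0/1),
#'   `age` (years), `stage` (3/4), `debulking` (optimal/suboptimal),
#'   `fibrosis_score` (continuous), `fibrosis_group` (low/high).
#' @slot expression numeric matrix genes x cases.
#' @slot plantedGenes character vector of gene ids with planted dependence.
#' @slot plantedLogHr numeric, the planted log hazard ratio (high vs low).
#' @exportClass SyntheticCohort
setClass("SyntheticCohort",
  representation(
    clinical = "data.frame",
    expression = "matrix",
    plantedGenes = "character",
    plantedLogHr = "numeric"
  )
)

setValidity("SyntheticCohort", function(object) {
  msg <- NULL
  cl <- object@clinical
  need <- c("case_id", "time", "event", "age", "stage", "debulking",
            "fibrosis_score", "fibrosis_group")
  if (!all(need %in% names(cl)))
    msg <- c(msg, paste("clinical must have columns:",
                        paste(need, collapse = ", ")))
  else if (any(cl$time <= 0))
    msg <- c(msg, "survival times must be positive")
  if (any(!is.finite(object@expression)))
    msg <- c(msg, "expression must be finite")
  if (!all(object@plantedGenes %in% rownames(object@expression)))
    msg <- c(msg, "plantedGenes must be a subset of the gene universe")
  if (is.null(msg)) TRUE else msg
})
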