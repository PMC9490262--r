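## Validation studies on synthetic material. These bundle the package's
## standard phantom/cohort protocols so that tests, scripts and users run
## the identical procedure.

#' Fit reference backends on a set of training phantoms
#'
#' The standard training protocol: labeled patches are pooled from
#' HGSOC-like and SBOT-like phantoms (sliding window with half-patch
#' stride), the segmenter is fitted on the pixel rasters, and the three
#' criterion scorers on the homogeneous stroma patches (label purity and
#' stroma fraction at least `minPurity`), emulating training material
#' from single-score annotated regions.
#'
#' @param hgsocSeeds,sbotSeeds phantom seeds per class (defaults: three
#'   HGSOC-like and two SBOT-like slides, enough interface length that
#'   every score class is represented among homogeneous patches).
#' @param size training slide edge length (default 1024).
#' @param patchSize,stride sliding-window geometry (defaults 256 / 128).
#' @param minPurity homogeneity cut for scorer training (default 0.75).
#' @return list with `segmenter`, `scorers` (named list of three), and
#'   the pooled `patches`.
#' @export
fitPhantomBackends <- function(hgsocSeeds = c(1L, 2L, 3L),
                               sbotSeeds = c(4L, 5L),
                               size = 1024L, patchSize = 256L,
                               stride = 128L, minPurity = 0.75) {
  tile <- tilingConfig(patchSize = patchSize, stride = stride)
  mk <- function(seed, label)
    generateLabeledPatches(generatePhantomSlide(phantomConfig(
      width = size, height = size, tumorBlobCount = 2L,
      label = label, seed = seed)), tile)
  sets <- c(lapply(hgsocSeeds, mk, label = "HGSOC"),
            lapply(sbotSeeds, mk, label = "SBOT"))
  patches <- do.call(combinePatchSets, sets)
  segmenter <- fitReferenceSegmenter(patches)
  scorers <- sapply(c("fibrosis", "cellularity", "orientation"),
                    function(cr) {
      lab <- patchLabels(patches)
      hom <- patches[lab$class == "stroma" & !is.na(lab[[cr]]) &
                       lab[[paste0(cr, "_purity")]] >= minPurity &
                       lab$stroma_frac >= minPurity]
      fitReferenceTsrScorer(hom, cr)
    }, simplify = FALSE)
  list(segmenter = segmenter, scorers = scorers, patches = patches)
}

#' Evaluate reference backends on held-out phantoms
#'
#' Generates held-out phantoms, evaluates segmentation (pixel accuracy;
#' dataset-level Dice and IoU pooled over all held-out pixels per tissue
#' class, then averaged over the tumor and stroma classes; pixel-level
#' average precision of the tumor class from the collapsed posterior) and
#' per-criterion TSR scoring accuracy on homogeneous stroma patches.
#'
#' @param backends result of [fitPhantomBackends()].
#' @param hgsocSeeds,sbotSeeds held-out phantom seeds.
#' @param size,minPurity as in [fitPhantomBackends()].
#' @return list: `pixel_accuracy`, `dice`, `iou`, `ap`,
#'   `tsr_accuracy` (named per criterion), `n_patches`,
#'   `n_tsr_patches`.
#' @export
evaluatePhantomBackends <- function(backends, hgsocSeeds = c(42L, 43L),
                                    sbotSeeds = 44L, size = 1024L,
                                    minPurity = 0.75) {
  tile <- tilingConfig(patchSize = 256L, stride = 128L)
  mk <- function(seed, label)
    generateLabeledPatches(generatePhantomSlide(phantomConfig(
      width = size, height = size, tumorBlobCount = 2L,
      label = label, seed = seed)), tile)
  held <- do.call(combinePatchSets,
                  c(lapply(hgsocSeeds, mk, label = "HGSOC"),
                    lapply(sbotSeeds, mk, label = "SBOT")))
  ## pooled pixel tallies per class across all held-out patches
  inter <- pred <- truth <- c(tumor = 0, stroma = 0)
  correct <- total <- 0
  for (i in seq_len(nPatches(held))) {
    m <- segmentPatch(backends$segmenter, patchImages(held)[[i]])
    tr <- patchTruth(held)[[i]]
    for (nm in c("tumor", "stroma")) {
      cl <- if (nm == "tumor") 1L else 2L
      inter[nm] <- inter[nm] + sum(m == cl & tr == cl)
      pred[nm] <- pred[nm] + sum(m == cl)
      truth[nm] <- truth[nm] + sum(tr == cl)
    }
    correct <- correct + sum(m == tr)
    total <- total + length(tr)
  }
  dice <- 2 * inter / (pred + truth)
  iou <- inter / (pred + truth - inter)
  ## pixel-level AP of the tumor class on a subsample of patches
  apIdx <- seq(1, nPatches(held), by = 4)
  aps <- vapply(apIdx, function(i) {
    tr <- patchTruth(held)[[i]]
    if (!any(tr == 1L)) return(NA_real_)
    post <- segmentPosterior(backends$segmenter, patchImages(held)[[i]])
    averagePrecision(as.vector(post[, , 2]), as.vector(tr == 1L))
  }, numeric(1))
  lab <- patchLabels(held)
  tsr <- vapply(names(backends$scorers), function(cr) {
    hom <- held[lab$class == "stroma" & !is.na(lab[[cr]]) &
                  lab[[paste0(cr, "_purity")]] >= minPurity &
                  lab$stroma_frac >= minPurity]
    pred <- vapply(seq_len(nPatches(hom)), function(i)
      scorePatch(backends$scorers[[cr]], patchImages(hom)[[i]])$score,
      integer(1))
    mean(pred == patchLabels(hom)[[cr]])
  }, numeric(1))
  list(pixel_accuracy = correct / total,
       dice = mean(dice),
       iou = mean(iou),
       ap = mean(aps, na.rm = TRUE),
       tsr_accuracy = tsr,
       n_patches = nPatches(held),
       n_tsr_patches = sum(lab$class == "stroma" & !is.na(lab$fibrosis)))
}

#' Run the full pipeline on one phantom and score it against truth
#'
#' Tiles the phantom (fixed L threshold 95: phantom glass is near-white),
#' runs the backends, stitches at scale `r`, detects the interface and
#' summarizes TSR features; then compares the interface with the
#' ground-truth boundary band at the working resolution. The truth mask
#' is the majority ground-truth class per patch stitched at the same
#' `r`; the band is truth-stroma within the structuring-element radius of
#' truth-tumor, the far field is truth-stroma beyond twice the radius.
#'
#' @param slide a [PhantomSlide-class].
#' @param backends result of [fitPhantomBackends()].
#' @param r working scale (default 1/8 for 2048-px phantoms).
#' @param radius disk structuring-element radius (default 2).
#' @param patchSize inference tile size (default 256, non-overlapping).
#' @param lThreshold fixed foreground L threshold (default 95).
#' @return list: `features` (the [summarizeSlide()] row), `bandHit`,
#'   `bandSize`, `farHit`, `farSize` (pixel counts), `interface`,
#'   `mask`.
#' @export
analyzePhantomSlide <- function(slide, backends, r = 1 / 8,
                                radius = 2L, patchSize = 256L,
                                lThreshold = 95) {
  dims <- dim(slideImage(slide))[1:2]
  tile <- tilingConfig(patchSize = patchSize, stride = patchSize)
  pats <- extractPatches(slideImage(slide), tile, threshold = lThreshold,
                         slideId = sprintf("phantom_seed%d", slide@seed))
  pred <- predictSlide(pats, backends$segmenter, backends$scorers)
  mask <- stitchPatches(pred, dims, r = r)
  selem <- structuringElement("disk", radius)
  iface <- detectInterface(mask, selem)
  feats <- summarizeSlide(pred, iface)
  ## truth at working resolution
  tp <- generateLabeledPatches(slide, tile)
  tdf <- data.frame(x = patchOrigins(tp)[, 1], y = patchOrigins(tp)[, 2],
                    class = patchLabels(tp)$class)
  tl <- maskLabels(stitchPatches(tdf, dims, r = r, patchSize = patchSize))
  im <- interfaceMask(iface)
  if (any(tl == 1L)) {
    d <- EBImage::distmap(matrix(as.numeric(tl != 1L), nrow(tl)))
    band <- tl == 2L & d <= radius
    far <- tl == 2L & d > 2 * radius
  } else {
    band <- far <- matrix(FALSE, nrow(tl), ncol(tl))
  }
  list(features = feats,
       bandHit = sum(im & band), bandSize = sum(band),
       farHit = sum(im & far), farSize = sum(far),
       interface = iface, mask = mask)
}

#' Phantom end-to-end study
#'
#' The package's standard end-to-end validation: train reference backends
#' on five 1024-px phantoms, then run the assembled pipeline
#' (tile, segment, score, stitch, interface, summarize) over `nHgsoc`
#' HGSOC-like and `nSbot` SBOT-like 2048-px phantoms and score interface
#' recovery against ground truth.
#'
#' @param nHgsoc,nSbot number of evaluation phantoms (defaults 10 / 3).
#' @param seed base seed; slide seeds are derived from it.
#' @param slideSize evaluation phantom edge length (default 2048).
#' @param r,radius working scale and SE radius (defaults 1/8, 2).
#' @param backends optional prefitted result of [fitPhantomBackends()].
#' @return list: `bandRecall` and `farRate` (pooled over HGSOC slides),
#'   `hgsocMeanFibrosis`, `sbotMeanFibrosis` (per-slide vectors),
#'   `perSlideRecall`.
#' @export
phantomEndToEndStudy <- function(nHgsoc = 10L, nSbot = 3L, seed = 1L,
                                 slideSize = 2048L, r = 1 / 8,
                                 radius = 2L, backends = NULL) {
  if (is.null(backends))
    backends <- fitPhantomBackends(hgsocSeeds = seed + c(0L, 1L, 2L),
                                   sbotSeeds = seed + c(3L, 4L))
  runOne <- function(s, label) {
    slide <- generatePhantomSlide(phantomConfig(
      width = slideSize, height = slideSize, tumorBlobCount = 2L,
      label = label, seed = s))
    analyzePhantomSlide(slide, backends, r = r, radius = radius)
  }
  hg <- lapply(seed + 100L + seq_len(nHgsoc), runOne, label = "HGSOC")
  sb <- lapply(seed + 200L + seq_len(nSbot), runOne, label = "SBOT")
  list(
    bandRecall = sum(vapply(hg, `[[`, numeric(1), "bandHit")) /
      sum(vapply(hg, `[[`, numeric(1), "bandSize")),
    farRate = sum(vapply(hg, `[[`, numeric(1), "farHit")) /
      max(1, sum(vapply(hg, `[[`, numeric(1), "farSize"))),
    perSlideRecall = vapply(hg, function(x) x$bandHit / x$bandSize,
                            numeric(1)),
    hgsocMeanFibrosis = vapply(hg, function(x) x$features$fibrosis_mean,
                               numeric(1)),
    sbotMeanFibrosis = vapply(sb, function(x) x$features$fibrosis_mean,
                              numeric(1)))
}

#' Cox parameter-recovery study
#'
#' Repeatedly generates cohorts with a planted fibrosis-group hazard and
#' refits the univariate Cox model.
#'
#' @param nReps replicates (default 50).
#' @param nCases cases per cohort (default 400).
#' @param plantedLogHr planted log hazard ratio (default 0.69).
#' @param seed base seed.
#' @return list: `logHr` (estimates), `coverage` (fraction of 95% CIs
#'   containing the planted HR), `p` (two-sided p-values).
#' @export
coxRecoveryStudy <- function(nReps = 50L, nCases = 400L,
                             plantedLogHr = 0.69, seed = 1L) {
  fits <- lapply(seq_len(nReps), function(i) {
    co <- generateCohort(nCases = nCases, nGenes = 2L,
                         plantedLogHr = plantedLogHr,
                         seed = seed * 1000L + i)
    cl <- cohortClinical(co)
    coxFit(cl, cl$fibrosis_group)
  })
  hr <- vapply(fits, function(f) f$hr, numeric(1))
  lo <- vapply(fits, function(f) f$ci_low, numeric(1))
  hi <- vapply(fits, function(f) f$ci_high, numeric(1))
  truthHr <- exp(plantedLogHr)
  list(logHr = log(hr),
       coverage = mean(lo <= truthHr & truthHr <= hi),
       p = vapply(fits, function(f) f$p, numeric(1)))
}

#' Molecular recovery study
#'
#' Generates cohorts with planted gene-score correlations and one planted
#' gene set, and measures how often the planted set is top-ranked with
#' FDR < `alpha` in over-representation analysis of the positively
#' correlated genes.
#'
#' @param nReps replicates (default 20).
#' @param nCases,nGenes cohort dimensions (defaults 200 / 1000).
#' @param nSets size of the gene-set collection including the planted set
#'   (default 20).
#' @param setSize genes per set (default 40).
#' @param alpha FDR threshold for calling the planted set (default 0.05).
#' @param seed base seed.
#' @return list: `topRate` (fraction of replicates with the planted set
#'   ranked first at FDR < alpha), `plantedMedianRho`, `nullQ95Rho`
#'   (from the last replicate), `selectedFrac` (per replicate, fraction
#'   of genes selected at nominal 0.05 in a matched null cohort).
#' @export
molecularRecoveryStudy <- function(nReps = 20L, nCases = 200L,
                                   nGenes = 1000L, nSets = 20L,
                                   setSize = 40L, alpha = 0.05,
                                   seed = 1L) {
  top <- logical(nReps)
  nullFrac <- numeric(nReps)
  plantedMedianRho <- nullQ95Rho <- NA_real_
  for (i in seq_len(nReps)) {
    s <- seed * 1000L + i
    co <- generateCohort(nCases = nCases, nGenes = nGenes,
                         plantedGeneFrac = 0.1, seed = s)
    cl <- cohortClinical(co)
    sc <- stats::setNames(cl$fibrosis_score, cl$case_id)
    rows <- spearmanGeneScan(cohortExpression(co), sc)
    isPlanted <- rows$gene %in% plantedGenes(co)
    plantedMedianRho <- stats::median(abs(rows$rho[isPlanted]))
    nullQ95Rho <- stats::quantile(abs(rows$rho[!isPlanted]), 0.95,
                                  names = FALSE)
    sel <- selectCorrelatedGenes(rows)
    universe <- rows$gene
    sets <- withr::with_seed(s, {
      planted <- sample(plantedGenes(co), setSize)
      decoys <- lapply(seq_len(nSets - 1L), function(j)
        sample(setdiff(universe, plantedGenes(co)), setSize))
      c(list(planted_set = planted),
        stats::setNames(decoys, sprintf("decoy%02d", seq_len(nSets - 1L))))
    })
    enr <- oraEnrichment(sel$positive, sets, universe)
    top[i] <- enr$gene_set[1] == "planted_set" && enr$fdr[1] < alpha
    ## matched null cohort for type-I calibration of the nominal cut
    nullCo <- generateCohort(nCases = nCases, nGenes = nGenes,
                             plantedGeneFrac = 0, seed = s + 500000L)
    ncl <- cohortClinical(nullCo)
    nrows <- spearmanGeneScan(
      cohortExpression(nullCo),
      stats::setNames(ncl$fibrosis_score, ncl$case_id))
    nsel <- selectCorrelatedGenes(nrows)
    nullFrac[i] <- (length(nsel$positive) + length(nsel$negative)) / nGenes
  }
  list(topRate = mean(top), plantedMedianRho = plantedMedianRho,
       nullQ95Rho = nullQ95Rho, selectedFrac = nullFrac)
}
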