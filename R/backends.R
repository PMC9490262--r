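## ---- feature extraction --------------------------------------------------

## per-pixel features: R, G, B and the local SD of the gray channel in a
## (2r+1)^2 box window, computed via box-filtered first and second moments
pixelFeatures <- function(image, varRadius = 2L) {
  h <- dim(image)[1]; w <- dim(image)[2]
  gray <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  k <- matrix(1, 2L * varRadius + 1L, 2L * varRadius + 1L)
  k <- k / sum(k)
  m1 <- EBImage::filter2(gray, k)
  m2 <- EBImage::filter2(gray^2, k)
  lsd <- sqrt(pmax(m2 - m1^2, 0))
  cbind(r = as.vector(image[, , 1]), g = as.vector(image[, , 2]),
        b = as.vector(image[, , 3]), lsd = as.vector(lsd))
}

## patch-summary features for TSR scoring: mean and quartile color (the
## per-channel median tracks the dominant tint even in mixed patches),
## gray SD, edge density (mean absolute gradient), directional anisotropy
## of the gradient energy, and the fraction of dark (nuclei-like) pixels
patchSummaryFeatures <- function(image) {
  gray <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  gx <- gray[, -1, drop = FALSE] - gray[, -ncol(gray), drop = FALSE]
  gy <- gray[-1, , drop = FALSE] - gray[-nrow(gray), , drop = FALSE]
  ex <- mean(abs(gx)); ey <- mean(abs(gy))
  mu <- mean(gray); sg <- stats::sd(as.vector(gray))
  q <- vapply(1:3, function(ch)
    stats::quantile(image[, , ch], c(0.25, 0.5, 0.75), names = FALSE),
    numeric(3))
  c(meanR = mean(image[, , 1]), meanG = mean(image[, , 2]),
    meanB = mean(image[, , 3]),
    q25R = q[1, 1], medR = q[2, 1], q75R = q[3, 1],
    q25G = q[1, 2], medG = q[2, 2], q75G = q[3, 2],
    q25B = q[1, 3], medB = q[2, 3], q75B = q[3, 3],
    sdGray = sg,
    edgeDensity = (ex + ey) / 2,
    anisotropy = (ex - ey) / (ex + ey + 1e-12),
    darkFrac = mean(gray < mu - 2 * sg))
}

## ---- reference segmenter -------------------------------------------------

#' Fit the reference tumor/stroma segmenter
#'
#' A pixelwise mixture discriminant classifier on per-pixel color
#' (R, G, B) plus a local-variance texture feature, trained on
#' ground-truth label rasters. Each tissue class may be multimodal in
#' color (stroma carries one tint per TSR score), so the training pixels
#' of every class are first split into up to `subclasses` k-means
#' clusters and a linear discriminant is fitted over the subclass labels;
#' predictions are collapsed back to the parent class. It is a classical,
#' CPU-scale stand-in exposing the same [SegmenterBackend-class] contract
#' that a trained deep segmentation model would implement. Fitting is
#' deterministic given `seed` (used for pixel subsampling and k-means
#' initialization).
#'
#' @param patches a [PatchSet-class] carrying ground-truth rasters
#'   (e.g. from [generateLabeledPatches()]).
#' @param varRadius window radius of the texture feature (default 2).
#' @param maxPixelsPerClass training subsample cap per class
#'   (default 20000).
#' @param subclasses maximum k-means subclasses per class (default 3).
#' @param seed integer seed for the subsample.
#' @return an [LDASegmenter-class] backend.
#' @examples
#' slide <- generatePhantomSlide(phantomConfig(width = 512, height = 512,
#'                                             tumorBlobCount = 1, seed = 5))
#' ps <- generateLabeledPatches(slide, tilingConfig(patchSize = 128))
#' seg <- fitReferenceSegmenter(ps)
#' @export
fitReferenceSegmenter <- function(patches, varRadius = 2L,
                                  maxPixelsPerClass = 20000L,
                                  subclasses = 3L, seed = 1L) {
  stopifnot(is(patches, "PatchSet"))
  if (length(patches@truth) == 0L)
    stop("patches carry no ground-truth label rasters")
  feats <- do.call(rbind, lapply(patches@images, pixelFeatures,
                                 varRadius = varRadius))
  labs <- unlist(lapply(patches@truth, as.vector))
  classes <- sort(unique(labs))
  if (length(classes) < 2L)
    stop("training labels contain a single class; need at least 2")
  fit <- withr::with_seed(seed, {
    sub <- character(0)
    rows <- integer(0)
    for (cl in classes) {
      idx <- which(labs == cl)
      if (length(idx) > maxPixelsPerClass)
        idx <- sample(idx, maxPixelsPerClass)
      k <- min(subclasses, max(1L, length(idx) %/% 50L))
      ## a rough partition is enough to split color modes; convergence
      ## warnings on noise-dominated clusters are expected and harmless
      cluster <- if (k > 1L)
        suppressWarnings(
          stats::kmeans(feats[idx, , drop = FALSE], centers = k,
                        nstart = 3L, iter.max = 200L,
                        algorithm = "MacQueen"))$cluster
      else rep(1L, length(idx))
      sub <- c(sub, paste(cl, cluster, sep = "."))
      rows <- c(rows, idx)
    }
    MASS::lda(feats[rows, , drop = FALSE], grouping = factor(sub))
  })
  new("LDASegmenter", name = "reference-lda", version = "1",
      model = fit, varRadius = as.integer(varRadius))
}

#' @rdname segmentPatch
setMethod("segmentPatch", "LDASegmenter", function(backend, image) {
  d <- dim(image)
  feats <- pixelFeatures(image, backend@varRadius)
  sub <- stats::predict(backend@model, feats)$class
  parent <- as.integer(sub("\\..*$", "", as.character(sub)))
  matrix(parent, d[1], d[2])
})

#' Per-pixel class posteriors of the reference segmenter
#'
#' Collapses the subclass discriminant posteriors to the three tissue
#' classes. Used for threshold-free evaluation (e.g. pixel-level average
#' precision); not part of the [SegmenterBackend-class] contract.
#'
#' @param backend an [LDASegmenter-class].
#' @param image numeric RGB array [y, x, 3] in [0, 1].
#' @return numeric array [y, x, 3]: posterior probability of background,
#'   tumor and stroma per pixel.
#' @export
segmentPosterior <- function(backend, image) {
  stopifnot(is(backend, "LDASegmenter"))
  d <- dim(image)
  feats <- pixelFeatures(image, backend@varRadius)
  post <- stats::predict(backend@model, feats)$posterior
  parent <- as.integer(sub("\\..*$", "", colnames(post)))
  out <- array(0, dim = c(d[1], d[2], 3))
  for (cl in 0:2) {
    cols <- which(parent == cl)
    if (length(cols) > 0)
      out[, , cl + 1L] <- matrix(rowSums(post[, cols, drop = FALSE]),
                                 d[1], d[2])
  }
  out
}

## ---- reference TSR scorer ------------------------------------------------

#' Fit the reference TSR scorer for one criterion
#'
#' A patch-level linear discriminant classifier on summary texture
#' features (mean color, gray SD, edge density, gradient anisotropy, dark
#' fraction), standing in for a trained deep classifier behind the
#' [TSRScorerBackend-class] contract. Training requires all three score
#' classes to be represented.
#'
#' @param patches a labeled [PatchSet-class]; only stroma-class patches
#'   with a non-missing label for `criterion` are used.
#' @param criterion `"fibrosis"`, `"cellularity"` or `"orientation"`.
#' @return an [LDATSRScorer-class] backend.
#' @export
fitReferenceTsrScorer <- function(patches,
                                  criterion = c("fibrosis", "cellularity",
                                                "orientation")) {
  stopifnot(is(patches, "PatchSet"))
  criterion <- match.arg(criterion)
  lab <- patches@labels
  if (nrow(lab) == 0L) stop("patches carry no labels")
  use <- lab$class == "stroma" & !is.na(lab[[criterion]])
  y <- lab[[criterion]][use]
  missing <- setdiff(0:2, unique(y))
  if (length(missing) > 0L)
    stop(sprintf("score class(es) %s not represented in training labels",
                 paste(missing, collapse = ", ")))
  x <- t(vapply(patches@images[use], patchSummaryFeatures, numeric(16)))
  fit <- MASS::lda(x, grouping = factor(y, levels = 0:2))
  new("LDATSRScorer", name = "reference-lda", version = "1",
      criterion = criterion, model = fit)
}

#' @rdname scorePatch
setMethod("scorePatch", "LDATSRScorer", function(backend, image) {
  f <- patchSummaryFeatures(image)
  x <- matrix(f, nrow = 1, dimnames = list(NULL, names(f)))
  pr <- stats::predict(backend@model, x)
  prob <- as.numeric(pr$posterior[1, as.character(0:2)])
  prob <- prob / sum(prob)
  names(prob) <- c("p0", "p1", "p2")
  list(score = unname(which.max(prob)) - 1L, prob = prob)
})

## ---- contract checks and slide prediction --------------------------------

checkSegmentation <- function(mask, image, backend) {
  d <- dim(image)
  if (!is.matrix(mask) || !identical(dim(mask), d[1:2]))
    stop(sprintf("backend '%s' violated the segmenter contract: %s",
                 backend@name, "output dimensions differ from input"))
  if (any(!(mask %in% 0:2)))
    stop(sprintf("backend '%s' violated the segmenter contract: %s",
                 backend@name, "labels outside {0,1,2}"))
  mask
}

checkScore <- function(res, backend) {
  if (!is.list(res) || is.null(res$score) || is.null(res$prob) ||
      length(res$prob) != 3L || any(res$prob < 0) ||
      abs(sum(res$prob) - 1) > 1e-6 ||
      which.max(res$prob) - 1L != res$score)
    stop(sprintf("backend '%s' violated the scorer contract", backend@name))
  res
}

#' Run segmentation and TSR scoring over the patches of one slide
#'
#' Feeds every patch to the segmenter backend, assigns the patch its
#' dominant tissue class (majority pixel label over tissue pixels, ties
#' broken toward stroma; background only when the patch contains no tissue
#' pixels), and attaches the three TSR criterion scores to stroma-dominant
#' patches by running the scorer backends. Contract violations by a
#' backend are surfaced as errors, never silently corrected.
#'
#' @param patches a [PatchSet-class].
#' @param segmenter a [SegmenterBackend-class].
#' @param scorers named list of three [TSRScorerBackend-class] objects
#'   (`fibrosis`, `cellularity`, `orientation`).
#' @return a [SlidePrediction-class].
#' @export
predictSlide <- function(patches, segmenter, scorers) {
  stopifnot(is(patches, "PatchSet"), is(segmenter, "SegmenterBackend"))
  stopifnot(all(.criteria %in% names(scorers)))
  for (crit in .criteria)
    stopifnot(is(scorers[[crit]], "TSRScorerBackend"))
  n <- nrow(patches@origins)
  masks <- vector("list", n)
  cls <- character(n)
  score <- matrix(NA_integer_, n, 3, dimnames = list(NULL, .criteria))
  prob <- matrix(NA_real_, n, 9)
  colnames(prob) <- as.vector(t(outer(.criteria, c("p0", "p1", "p2"),
                                      paste, sep = "_")))
  for (i in seq_len(n)) {
    img <- patches@images[[i]]
    m <- checkSegmentation(segmentPatch(segmenter, img), img, segmenter)
    masks[[i]] <- m
    nT <- sum(m == 1L); nS <- sum(m == 2L)
    cls[i] <- if (nT + nS == 0L) "background"
              else if (nT > nS) "tumor" else "stroma"  # ties -> stroma
    if (cls[i] == "stroma") {
      for (crit in .criteria) {
        res <- checkScore(scorePatch(scorers[[crit]], img), scorers[[crit]])
        score[i, crit] <- res$score
        prob[i, paste(crit, c("p0", "p1", "p2"), sep = "_")] <- res$prob
      }
    }
  }
  preds <- data.frame(x = patches@origins[, 1], y = patches@origins[, 2],
                      class = cls, score, prob, row.names = NULL)
  new("SlidePrediction", slideId = patches@slideId,
      patchSize = patches@patchSize, predictions = preds,
      classMasks = masks)
}
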