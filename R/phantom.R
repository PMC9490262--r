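#' Create a phantom slide configuration
#'
#' Default texture parameters give widely separated base colors for the
#' four (class, score) combinations, so that the reference classifiers are
#' expected to succeed; `hardMode = TRUE` narrows the separations for
#' robustness testing. The TSR gradient is planted by distance from the
#' tumor mask: stroma within `scoreThresholds[1]` pixels of the nearest
#' tumor pixel scores 2, within `scoreThresholds[2]` scores 1, and 0
#' beyond, which concentrates high scores in a band along the invasive
#' tumor front.
#'
#' @param width,height slide dimensions in pixels (>= 512).
#' @param tumorBlobCount number of tumor islands (>= 1 for HGSOC-like).
#' @param label `"HGSOC"` (TSR gradient planted) or `"SBOT"` (all scores 0).
#' @param seed integer RNG seed.
#' @param backgroundRgb,tumorRgb,stromaRgbByScore base colors; see
#'   [PhantomConfig-class].
#' @param noiseAmp per-channel Gaussian noise SD (default 0.02).
#' @param scoreThresholds distances in pixels for scores 2 and 1
#'   (default c(192, 448): wide enough that 256-px patches dominated by a
#'   single score class exist on every slide, narrow enough that scores
#'   still grade the invasive front).
#' @param stripeFreq orientation-stripe frequency in cycles/pixel.
#' @param dotDensity cellularity dot probability scale per pixel.
#' @param fiberAmp fibrosis streak amplitude.
#' @param hardMode narrow the stroma color separation (default FALSE).
#' @return A [PhantomConfig-class] object.
#' @examples
#' cfg <- phantomConfig(label = "HGSOC", seed = 7)
#' @export
phantomConfig <- function(width = 1024L, height = 1024L,
                          tumorBlobCount = 3L,
                          label = c("HGSOC", "SBOT"),
                          seed = 1L,
                          backgroundRgb = c(0.97, 0.97, 0.96),
                          tumorRgb = c(0.45, 0.25, 0.55),
                          stromaRgbByScore = rbind(
                            c(0.92, 0.80, 0.86),
                            c(0.80, 0.58, 0.68),
                            c(0.66, 0.36, 0.50)),
                          noiseAmp = 0.02,
                          scoreThresholds = c(192, 448),
                          stripeFreq = 1 / 12, dotDensity = 0.03,
                          fiberAmp = 0.03,
                          hardMode = FALSE) {
  label <- match.arg(label)
  if (hardMode) {
    ## pull score colors toward their mean: ~3x smaller separation
    ctr <- colMeans(stromaRgbByScore)
    stromaRgbByScore <- sweep(stromaRgbByScore, 2, ctr, "-") / 3 +
      rep(ctr, each = 3)
  }
  new("PhantomConfig",
      width = as.integer(width), height = as.integer(height),
      tumorBlobCount = as.integer(tumorBlobCount), label = label,
      backgroundRgb = backgroundRgb, tumorRgb = tumorRgb,
      stromaRgbByScore = stromaRgbByScore, noiseAmp = noiseAmp,
      scoreThresholds = as.numeric(scoreThresholds),
      stripeFreq = stripeFreq, dotDensity = dotDensity,
      fiberAmp = fiberAmp, hardMode = hardMode,
      seed = as.integer(seed))
}

#' Generate a phantom slide with ground truth
#'
#' Renders a synthetic H&E-like slide: a wobbly elliptical tissue region on
#' a bright background, smooth tumor blobs inside the tissue, and stroma
#' filling the remaining tissue. On HGSOC-like slides each stroma pixel is
#' assigned TSR scores 2/1/0 by distance from the nearest tumor pixel
#' (thresholds from the config), so high scores form a band along the
#' tumor border; SBOT-like slides carry score 0 everywhere. Generation is
#' bit-reproducible for a fixed config (the seed is part of the config and
#' the global RNG state is left untouched).
#'
#' @param config a [PhantomConfig-class].
#' @return A [PhantomSlide-class].
#' @examples
#' slide <- generatePhantomSlide(phantomConfig(width = 512, height = 512,
#'                                             tumorBlobCount = 2, seed = 3))
#' slide
#' @export
generatePhantomSlide <- function(config) {
  stopifnot(is(config, "PhantomConfig"))
  validObject(config)
  withr::with_seed(config@seed, .renderPhantom(config))
}

.renderPhantom <- function(config) {
  w <- config@width; h <- config@height
  xs <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)   # pixel centers
  ys <- matrix(rep(seq_len(h) - 0.5, times = w), h, w)
  cx <- w / 2; cy <- h / 2
  theta <- atan2(ys - cy, xs - cx)

  ## tissue: wobbly ellipse covering most of the slide
  ph <- stats::runif(2, 0, 2 * pi)
  wob <- 1 + 0.07 * sin(4 * theta + ph[1]) + 0.04 * sin(7 * theta + ph[2])
  tissue <- ((xs - cx) / (0.46 * w))^2 + ((ys - cy) / (0.46 * h))^2 <= wob^2

  ## tumor: smooth blobs at random positions inside the tissue core
  tumor <- matrix(FALSE, h, w)
  nb <- config@tumorBlobCount
  if (nb > 0L) {
    bx <- cx + stats::runif(nb, -0.22, 0.22) * w
    by <- cy + stats::runif(nb, -0.22, 0.22) * h
    br <- stats::runif(nb, 0.10, 0.15) * min(w, h)
    bp <- stats::runif(nb, 0, 2 * pi)
    for (i in seq_len(nb)) {
      bt <- atan2(ys - by[i], xs - bx[i])
      rr <- br[i] * (1 + 0.12 * sin(3 * bt + bp[i]))
      tumor <- tumor | ((xs - bx[i])^2 + (ys - by[i])^2 <= rr^2)
    }
    tumor <- tumor & tissue
  }
  stroma <- tissue & !tumor

  ## TSR score maps from the Euclidean distance to the nearest tumor pixel
  if (any(tumor)) {
    dist <- EBImage::distmap(matrix(as.numeric(!tumor), h, w))
  } else {
    dist <- matrix(Inf, h, w)
  }
  scoreOf <- function() {
    s <- matrix(NA_integer_, h, w)
    if (config@label == "SBOT") {
      s[stroma] <- 0L
    } else {
      v <- ifelse(dist <= config@scoreThresholds[1], 2L,
                  ifelse(dist <= config@scoreThresholds[2], 1L, 0L))
      s[stroma] <- v[stroma]
    }
    s
  }
  maps <- list(fibrosis = scoreOf(), cellularity = scoreOf(),
               orientation = scoreOf())

  ## render: base colors + criterion-specific texture + noise
  img <- array(0, dim = c(h, w, 3))
  fib <- maps$fibrosis
  for (ch in 1:3) {
    plane <- matrix(config@backgroundRgb[ch], h, w)
    plane[tumor] <- config@tumorRgb[ch]
    sc <- fib[stroma]
    plane[stroma] <- config@stromaRgbByScore[sc + 1L, ch]
    img[, , ch] <- plane
  }
  ## orientation: brightness stripes, amplitude scaled by the score
  stripe <- sin(2 * pi * config@stripeFreq *
                (xs * cos(pi / 5) + ys * sin(pi / 5)))
  oamp <- matrix(0, h, w)
  oamp[stroma] <- 0.015 * maps$orientation[stroma]
  ## fibrosis: horizontal fiber streaks in the red channel
  fiber <- sin(2 * pi * (1 / 7) * ys + stats::runif(1, 0, 2 * pi))
  famp <- matrix(0, h, w)
  famp[stroma] <- config@fiberAmp * fib[stroma]
  ## cellularity: dark nuclei-like dots, density scaled by the score
  du <- matrix(stats::runif(h * w), h, w)
  dprob <- matrix(0, h, w)
  dprob[stroma] <- config@dotDensity * maps$cellularity[stroma] / 2
  dots <- du < dprob
  for (ch in 1:3) {
    plane <- img[, , ch] + oamp * stripe
    if (ch == 1L) plane <- plane + famp * fiber
    plane[dots] <- plane[dots] - 0.3
    plane <- plane + matrix(stats::rnorm(h * w, 0, config@noiseAmp), h, w)
    img[, , ch] <- pmin(pmax(plane, 0), 1)
  }

  new("PhantomSlide", image = img, tumorMask = tumor, stromaMask = stroma,
      tsrMaps = maps, label = config@label, seed = config@seed,
      config = config)
}

#' Extract labeled training patches from a phantom slide
#'
#' Applies a sliding window to the phantom and labels every grid patch from
#' the ground truth: the patch class is the majority pixel class among
#' background/tumor/stroma, and each TSR criterion label is the modal score
#' over the patch's stroma pixels (ties resolved toward the lower score;
#' NA when the patch contains no stroma). Partial tiles at the right and
#' bottom edges are dropped, so the patch count follows the grid
#' arithmetic `floor((dim - patchSize) / stride) + 1` per axis.
#'
#' @param slide a [PhantomSlide-class].
#' @param tile a [TilingConfig-class]; only `patchSize` and `stride` are
#'   used (no background exclusion is applied to training patches).
#' @return A [PatchSet-class] with `labels` and per-patch ground-truth
#'   label rasters in `truth`. Besides the class and modal criterion
#'   scores, `labels` records `stroma_frac` (fraction of stroma pixels)
#'   and per-criterion `<crit>_purity` (fraction of stroma pixels holding
#'   the modal score): purity near 1 marks the homogeneous patches that
#'   emulate single-score annotated regions, the material on which patch
#'   scorers are trained and evaluated.
#' @examples
#' slide <- generatePhantomSlide(phantomConfig(width = 512, height = 512,
#'                                             tumorBlobCount = 1, seed = 2))
#' ps <- generateLabeledPatches(slide, tilingConfig(patchSize = 256))
#' nPatches(ps)
#' @export
generateLabeledPatches <- function(slide, tile = tilingConfig()) {
  stopifnot(is(slide, "PhantomSlide"), is(tile, "TilingConfig"))
  d <- dim(slide@image)
  if (tile@patchSize > d[1] || tile@patchSize > d[2])
    stop("patchSize exceeds slide dimensions")
  grid <- tileGrid(d[2], d[1], tile@patchSize, tile@stride)
  labelRaster <- matrix(0L, d[1], d[2])
  labelRaster[slide@tumorMask] <- 1L
  labelRaster[slide@stromaMask] <- 2L

  n <- nrow(grid)
  images <- vector("list", n)
  truth <- vector("list", n)
  bg <- numeric(n)
  cls <- character(n)
  stromaFrac <- numeric(n)
  scores <- matrix(NA_integer_, n, 3,
                   dimnames = list(NULL,
                                   c("fibrosis", "cellularity", "orientation")))
  purity <- matrix(NA_real_, n, 3,
                   dimnames = list(NULL, paste0(colnames(scores), "_purity")))
  ps <- tile@patchSize
  for (i in seq_len(n)) {
    rows <- (grid$y[i] + 1L):(grid$y[i] + ps)
    cols <- (grid$x[i] + 1L):(grid$x[i] + ps)
    images[[i]] <- slide@image[rows, cols, , drop = FALSE]
    tr <- labelRaster[rows, cols, drop = FALSE]
    truth[[i]] <- tr
    counts <- tabulate(tr + 1L, nbins = 3L)       # background, tumor, stroma
    bg[i] <- counts[1] / (ps * ps)
    stromaFrac[i] <- counts[3] / (ps * ps)
    cls[i] <- c("background", "tumor", "stroma")[which.max(counts)]
    inStroma <- tr == 2L
    if (any(inStroma)) {
      for (crit in colnames(scores)) {
        sc <- slide@tsrMaps[[crit]][rows, cols][inStroma]
        tab <- tabulate(sc + 1L, nbins = 3L)
        scores[i, crit] <- which.max(tab) - 1L    # ties -> lower score
        purity[i, paste0(crit, "_purity")] <- max(tab) / sum(tab)
      }
    }
  }
  labels <- data.frame(class = cls, scores, stroma_frac = stromaFrac,
                       purity, stringsAsFactors = FALSE)
  new("PatchSet", slideId = sprintf("phantom_seed%d", slide@seed),
      patchSize = ps, origins = as.matrix(grid), images = images,
      backgroundFrac = bg, labels = labels, truth = truth)
}

## 0-based row-major tile grid; partial edge tiles dropped
tileGrid <- function(width, height, patchSize, stride) {
  x0 <- seq.int(0L, width - patchSize, by = stride)
  y0 <- seq.int(0L, height - patchSize, by = stride)
  data.frame(x = rep(x0, times = length(y0)),
             y = rep(y0, each = length(x0)))
}
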