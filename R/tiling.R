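#' Lightness channel of an RGB raster
#'
#' Converts sRGB to CIE LAB (D65 white point) and returns the L channel in
#' [0, 100]. Tissue on a bright-field slide is darker (lower L) than the
#' glass background, so thresholding L separates foreground from
#' background.
#'
#' @param image numeric array [y, x, 3] in [0, 1].
#' @return numeric matrix [y, x] of L values.
#' @export
labLightness <- function(image) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  d <- dim(image)
  rgb <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
               as.vector(image[, , 3]))
  L <- grDevices::convertColor(rgb, from = "sRGB", to = "Lab")[, 1]
  matrix(L, d[1], d[2])
}

## block-mean downsample by an integer factor; trailing remainder cropped
downsampleMean <- function(image, factor) {
  factor <- as.integer(factor)
  if (factor <= 1L) return(image)
  d <- dim(image)
  h <- (d[1] %/% factor) * factor
  w <- (d[2] %/% factor) * factor
  nch <- if (length(d) == 3L) d[3] else 1L
  out <- array(0, dim = c(h %/% factor, w %/% factor, nch))
  for (ch in seq_len(nch)) {
    plane <- if (length(d) == 3L) image[seq_len(h), seq_len(w), ch]
             else image[seq_len(h), seq_len(w)]
    a <- array(plane, dim = c(factor, h %/% factor, w))
    m <- colMeans(a)                                 # (h/f) x w
    a2 <- array(t(m), dim = c(factor, w %/% factor, h %/% factor))
    out[, , ch] <- t(colMeans(a2))
  }
  if (length(d) == 3L) out else out[, , 1]
}

#' Detect tissue foreground by LAB lightness thresholding
#'
#' Converts the image from RGB to LAB and thresholds the L (lightness)
#' channel: a pixel is foreground (tissue) iff its L value is below the
#' threshold. The threshold is either chosen automatically by Otsu's
#' bimodal method on the L histogram (default) or supplied as a fixed
#' value.
#'
#' @param image numeric RGB array [y, x, 3] in [0, 1].
#' @param method `"otsu"` (automatic bimodal threshold) or `"fixed"`.
#' @param threshold fixed L threshold in [0, 100]; required for
#'   `method = "fixed"`.
#' @param downsample integer factor; if > 1 the image is block-mean
#'   downsampled before detection (the slide-level default workflow uses
#'   factor 128).
#' @return logical matrix (at the downsampled scale when
#'   `downsample > 1`) with attribute `"threshold"` holding the L cutoff
#'   used.
#' @examples
#' img <- array(runif(64 * 64 * 3), dim = c(64, 64, 3))
#' fg <- detectForeground(img, method = "fixed", threshold = 50)
#' @export
detectForeground <- function(image, method = c("otsu", "fixed"),
                             threshold = NULL, downsample = 1L) {
  method <- match.arg(method)
  if (length(image) == 0L) stop("empty image")
  if (downsample > 1L) image <- downsampleMean(image, downsample)
  L <- labLightness(image)
  thr <- switch(method,
    fixed = {
      if (is.null(threshold)) stop("method 'fixed' requires a threshold")
      threshold
    },
    otsu = 100 * EBImage::otsu(EBImage::Image(L / 100), range = c(0, 1))
  )
  fg <- L < thr
  attr(fg, "threshold") <- thr
  fg
}

#' Extract tiled patches from a slide image
#'
#' Enumerates sliding-window positions row-major on the stride lattice
#' (partial tiles at the right/bottom edges are dropped), optionally skips
#' tiles whose footprint on a provided downsampled foreground mask contains
#' no tissue at all, and then recomputes the background fraction of every
#' remaining tile at full patch resolution with the same L-threshold rule.
#' Tiles with background fraction above `maxBackgroundFrac` are excluded.
#'
#' @param image numeric RGB array [y, x, 3] in [0, 1].
#' @param config a [TilingConfig-class].
#' @param fgMask optional logical foreground mask at scale
#'   `1 / config@fgDownsample` of the slide (as from [detectForeground()]);
#'   used only as a fast path to skip all-background tiles. The surviving
#'   set is decided by the full-resolution rule in all cases.
#' @param threshold L threshold used for the full-resolution background
#'   recomputation; defaults to the threshold stored on `fgMask`, or to an
#'   Otsu threshold of the downsampled slide when no mask is given.
#' @param slideId identifier recorded on the returned set.
#' @return A [PatchSet-class] (unlabeled).
#' @examples
#' img <- array(0.3, dim = c(512, 512, 3))     # uniformly dark "tissue"
#' ps <- extractPatches(img, tilingConfig(patchSize = 256),
#'                      threshold = 50)
#' nPatches(ps)
#' @export
extractPatches <- function(image, config = tilingConfig(), fgMask = NULL,
                           threshold = NULL, slideId = "slide") {
  stopifnot(is(config, "TilingConfig"))
  d <- dim(image)
  if (config@patchSize > d[1] || config@patchSize > d[2])
    stop("patchSize exceeds slide dimensions")
  if (is.null(threshold)) {
    if (!is.null(attr(fgMask, "threshold"))) {
      threshold <- attr(fgMask, "threshold")
    } else {
      ds <- min(config@fgDownsample, d[1] %/% 2L, d[2] %/% 2L)
      tmp <- detectForeground(image, method = "otsu",
                              downsample = max(ds, 1L))
      threshold <- attr(tmp, "threshold")
      if (is.null(fgMask)) fgMask <- tmp
    }
  }
  grid <- tileGrid(d[2], d[1], config@patchSize, config@stride)
  ps <- config@patchSize
  f <- config@fgDownsample
  keep <- logical(nrow(grid))
  bg <- rep(NA_real_, nrow(grid))
  images <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    rows <- (grid$y[i] + 1L):(grid$y[i] + ps)
    cols <- (grid$x[i] + 1L):(grid$x[i] + ps)
    if (!is.null(fgMask)) {
      mrows <- max(1L, floor(grid$y[i] / f) + 1L):
        min(nrow(fgMask), ceiling((grid$y[i] + ps) / f))
      mcols <- max(1L, floor(grid$x[i] / f) + 1L):
        min(ncol(fgMask), ceiling((grid$x[i] + ps) / f))
      if (!any(fgMask[mrows, mcols])) next       # footprint has no tissue
    }
    patch <- image[rows, cols, , drop = FALSE]
    frac <- mean(labLightness(patch) >= threshold)
    if (frac <= config@maxBackgroundFrac) {
      keep[i] <- TRUE
      bg[i] <- frac
      images[[i]] <- patch
    }
  }
  new("PatchSet", slideId = slideId, patchSize = ps,
      origins = as.matrix(grid[keep, , drop = FALSE]),
      images = images[keep], backgroundFrac = bg[keep],
      labels = data.frame(), truth = list())
}

#' Patch manifest as a data frame
#'
#' @param patches a [PatchSet-class].
#' @return data.frame with `slide_id`, `x`, `y`, `size`,
#'   `background_frac`, plus label columns when present.
#' @export
patchManifest <- function(patches) {
  stopifnot(is(patches, "PatchSet"))
  out <- data.frame(slide_id = patches@slideId,
                    x = patches@origins[, 1], y = patches@origins[, 2],
                    size = patches@patchSize,
                    background_frac = patches@backgroundFrac,
                    row.names = NULL)
  if (nrow(patches@labels) > 0) out <- cbind(out, patches@labels)
  out
}

#' Write patches as PNG files plus a CSV manifest
#'
#' Files are named `{slide}_{x}_{y}.png`; pixel values survive the
#' round-trip exactly at 8-bit depth.
#'
#' @param patches a [PatchSet-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest data frame (with a `file` column).
#' @export
writePatches <- function(patches, dir) {
  stopifnot(is(patches, "PatchSet"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  man <- patchManifest(patches)
  files <- sprintf("%s_%d_%d.png", patches@slideId, man$x, man$y)
  for (i in seq_len(nrow(man)))
    png::writePNG(patches@images[[i]], file.path(dir, files[i]))
  man$file <- files
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}
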