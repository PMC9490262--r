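## Binary morphology wrappers. EBImage performs grayscale max/min
## filtering, which on 0/1 rasters coincides with binary dilation/erosion
## under the "ignore out-of-bounds neighbors" border convention (dilation
## takes the max, erosion the min, over the part of the structuring element
## that falls inside the image).

binDilate <- function(mask, kern) {
  storage.mode(mask) <- "double"
  EBImage::dilate(mask, kern) > 0.5
}

binErode <- function(mask, kern) {
  storage.mode(mask) <- "double"
  EBImage::erode(mask, kern) > 0.5
}

binClose <- function(mask, kern) binErode(binDilate(mask, kern), kern)

#' Connected components of a binary mask
#'
#' Labels the connected foreground components of a binary raster. Component
#' ids follow raster scan order (row by row, left to right) of the first
#' pixel encountered in each component, starting at 1.
#'
#' @param mask logical matrix.
#' @param connectivity 8 (default) or 4.
#' @return integer matrix of the same dimensions: 0 for background,
#'   component id otherwise.
#' @examples
#' m <- matrix(FALSE, 5, 5); m[1:2, 1:2] <- TRUE; m[4, 4] <- TRUE
#' connectedComponents(m)
#' @export
connectedComponents <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  mask <- mask & !is.na(mask)
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  if (!any(mask)) return(lab)
  ## iterative min-label propagation over neighbor shifts
  lab[mask] <- seq_len(sum(mask))
  shifts <- list(c(0L, 1L), c(0L, -1L), c(1L, 0L), c(-1L, 0L))
  if (connectivity == 8)
    shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L), c(-1L, 1L), c(-1L, -1L)))
  repeat {
    prev <- lab
    for (s in shifts) {
      dy <- s[1]; dx <- s[2]
      ys <- max(1L, 1L - dy):min(h, h - dy)
      xs <- max(1L, 1L - dx):min(w, w - dx)
      src <- lab[ys, xs, drop = FALSE]
      dsty <- ys + dy; dstx <- xs + dx
      dst <- lab[dsty, dstx, drop = FALSE]
      upd <- dst > 0L & src > 0L & src < dst
      if (any(upd)) {
        dst[upd] <- src[upd]
        lab[dsty, dstx] <- dst
      }
    }
    if (identical(prev, lab)) break
  }
  ## relabel compactly in scan order (row-major first encounter)
  ord <- order(row(lab)[lab > 0L], col(lab)[lab > 0L])
  first <- unique(lab[lab > 0L][ord])
  lab[lab > 0L] <- match(lab[lab > 0L], first)
  lab
}

componentTable <- function(lab) {
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids) == 0L)
    return(data.frame(id = integer(), size = integer(),
                      xmin = integer(), xmax = integer(),
                      ymin = integer(), ymax = integer()))
  rows <- lapply(ids, function(id) {
    idx <- which(lab == id, arr.ind = TRUE)
    data.frame(id = id, size = nrow(idx),
               xmin = min(idx[, 2]) - 1L, xmax = max(idx[, 2]) - 1L,
               ymin = min(idx[, 1]) - 1L, ymax = max(idx[, 1]) - 1L)
  })
  do.call(rbind, rows)
}
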