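#' Read and write raster masks as single-channel PNG
#'
#' Binary masks are stored as 0/255; integer score or label rasters store
#' the value itself (0, 1, 2) with 255 encoding undefined (NA). PNG is
#' lossless at 8-bit depth, so round-trips are exact.
#'
#' @param mask logical matrix (`type = "binary"`) or integer matrix with
#'   values in 0..2 and NA (`type = "score"`).
#' @param path file path.
#' @param type `"binary"` or `"score"`.
#' @return `readMaskPng` returns the mask; `writeMaskPng` returns the path
#'   invisibly.
#' @export
writeMaskPng <- function(mask, path, type = c("binary", "score")) {
  type <- match.arg(type)
  v <- switch(type,
    binary = ifelse(mask, 255L, 0L),
    score = {
      m <- mask
      m[is.na(m)] <- 255L
      m
    })
  png::writePNG(v / 255, path)
  invisible(path)
}

#' @rdname writeMaskPng
#' @export
readMaskPng <- function(path, type = c("binary", "score")) {
  type <- match.arg(type)
  v <- png::readPNG(path)
  if (length(dim(v)) == 3L) v <- v[, , 1]
  iv <- matrix(as.integer(round(v * 255)), nrow(v), ncol(v))
  switch(type,
    binary = iv > 0L,
    score = {
      iv[iv == 255L] <- NA_integer_
      iv
    })
}

#' Write and read an RGB slide image as PNG
#'
#' @param image numeric array [y, x, 3] in [0, 1].
#' @param path file path.
#' @return `readSlidePng` returns the image array; `writeSlidePng` the
#'   path, invisibly.
#' @export
writeSlidePng <- function(image, path) {
  png::writePNG(image, path)
  invisible(path)
}

#' @rdname writeSlidePng
#' @export
readSlidePng <- function(path) {
  v <- png::readPNG(path)
  if (length(dim(v)) == 2L) v <- array(rep(v, 3), dim = c(dim(v), 3))
  if (dim(v)[3] > 3L) v <- v[, , 1:3]
  v
}

#' Export a phantom slide to plain files
#'
#' Writes `<prefix>.png` (RGB image), `<prefix>_tumor.png` and
#' `<prefix>_stroma.png` (binary masks), and one score-map PNG per TSR
#' criterion (`<prefix>_fibrosis.png`, ...; values 0/1/2, 255 = undefined).
#'
#' @param slide a [PhantomSlide-class].
#' @param prefix output path prefix.
#' @return invisibly, the written file paths.
#' @export
writePhantomSlide <- function(slide, prefix) {
  stopifnot(is(slide, "PhantomSlide"))
  paths <- c(image = paste0(prefix, ".png"),
             tumor = paste0(prefix, "_tumor.png"),
             stroma = paste0(prefix, "_stroma.png"))
  writeSlidePng(slide@image, paths["image"])
  writeMaskPng(slide@tumorMask, paths["tumor"], "binary")
  writeMaskPng(slide@stromaMask, paths["stroma"], "binary")
  for (crit in names(slide@tsrMaps)) {
    p <- paste0(prefix, "_", crit, ".png")
    writeMaskPng(slide@tsrMaps[[crit]], p, "score")
    paths[crit] <- p
  }
  invisible(paths)
}

#' Export a synthetic cohort to plain files
#'
#' Writes the clinical table as CSV and the expression matrix as TSV with
#' genes in rows.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "SyntheticCohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  clin <- file.path(dir, "clinical.csv")
  expr <- file.path(dir, "expression.tsv")
  utils::write.csv(cohort@clinical, clin, row.names = FALSE)
  utils::write.table(
    data.frame(gene = rownames(cohort@expression), cohort@expression,
               check.names = FALSE),
    expr, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(clinical = clin, expression = expr))
}
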