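#' Polygon ROI annotation with TSR sub-scores
#'
#' One pathologist-annotated region of interest: its boundary polygon
#' (0-based level-0 pixel coordinates) and a list of scored sub-region
#' polygons, each carrying a criterion (fibrosis/cellularity/orientation)
#' and a score in {0, 1, 2}. The file dialect is a GeoJSON
#' FeatureCollection: one feature per polygon with properties `roi_id` and
#' either `object_type: "boundary"` or `criterion` + `score`. This mirrors
#' how annotation tools such as QuPath export regions, so real exports can
#' be adapted with a property rename.
#'
#' @slot roiId character scalar.
#' @slot boundary numeric matrix n x 2 of (x, y) vertices (open form).
#' @slot subRegions list of `list(polygon =, criterion =, score =)` in file
#'   order (later polygons take precedence on overlap).
#' @exportClass ROIAnnotation
setClass("ROIAnnotation",
  representation(roiId = "character", boundary = "matrix",
                 subRegions = "list"))

.criteria <- c("fibrosis", "cellularity", "orientation")

setValidity("ROIAnnotation", function(object) {
  msg <- NULL
  if (ncol(object@boundary) != 2L || nrow(object@boundary) < 3L)
    msg <- c(msg, "boundary must be an n x 2 matrix with n >= 3")
  for (sr in object@subRegions) {
    if (!sr$criterion %in% .criteria)
      msg <- c(msg, sprintf("roi '%s': unknown criterion '%s'",
                            object@roiId, sr$criterion))
    if (!sr$score %in% 0:2)
      msg <- c(msg, sprintf("roi '%s': score %s outside {0,1,2}",
                            object@roiId, format(sr$score)))
  }
  if (is.null(msg)) TRUE else msg
})

## drop a repeated closing vertex; error on degenerate/self-intersecting rings
normalizePolygon <- function(poly, roiId) {
  poly <- as.matrix(poly)
  if (nrow(poly) >= 2L && all(poly[1, ] == poly[nrow(poly), ]))
    poly <- poly[-nrow(poly), , drop = FALSE]
  if (nrow(poly) < 3L)
    stop(sprintf("roi '%s': polygon with fewer than 3 distinct vertices",
                 roiId))
  if (selfIntersects(poly))
    stop(sprintf("roi '%s': self-intersecting polygon", roiId))
  poly
}

## proper crossing test between all pairs of non-adjacent edges
selfIntersects <- function(poly) {
  n <- nrow(poly)
  idx <- cbind(seq_len(n), c(seq_len(n)[-1], 1L))
  cross <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (j == i + 1L || (i == 1L && j == n)) next   # edges share a vertex
      p1 <- poly[idx[i, 1], ]; p2 <- poly[idx[i, 2], ]
      q1 <- poly[idx[j, 1], ]; q2 <- poly[idx[j, 2], ]
      d1 <- cross(p1[1], p1[2], p2[1], p2[2], q1[1], q1[2])
      d2 <- cross(p1[1], p1[2], p2[1], p2[2], q2[1], q2[2])
      d3 <- cross(q1[1], q1[2], q2[1], q2[2], p1[1], p1[2])
      d4 <- cross(q1[1], q1[2], q2[1], q2[2], p2[1], p2[2])
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0)) &&
          d1 != 0 && d2 != 0 && d3 != 0 && d4 != 0)
        return(TRUE)
    }
  }
  FALSE
}

## even-odd (crossing-number) point-in-polygon, vectorized over points
pointsInPolygonEO <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Parse a TSR annotation file
#'
#' Reads the GeoJSON dialect described in [ROIAnnotation-class] and
#' validates every polygon (closed, simple) and every score/criterion.
#' Parse errors name the offending `roi_id`.
#'
#' @param path path to a GeoJSON FeatureCollection.
#' @return list of [ROIAnnotation-class], one per `roi_id`, in first-seen
#'   order.
#' @export
parseAnnotations <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$features)) stop("not a GeoJSON FeatureCollection")
  rois <- list()
  for (feat in doc$features) {
    props <- feat$properties
    roiId <- props$roi_id
    if (is.null(roiId)) stop("feature without roi_id")
    coords <- feat$geometry$coordinates[[1]]
    poly <- do.call(rbind, lapply(coords, function(v)
      c(as.numeric(v[[1]]), as.numeric(v[[2]]))))
    poly <- normalizePolygon(poly, roiId)
    if (identical(props$object_type, "boundary")) {
      rois[[roiId]] <- new("ROIAnnotation", roiId = roiId, boundary = poly,
                           subRegions = if (is.null(rois[[roiId]])) list()
                                        else rois[[roiId]]@subRegions)
    } else {
      crit <- props$criterion
      score <- props$score
      if (is.null(crit) || !crit %in% .criteria)
        stop(sprintf("roi '%s': unknown criterion '%s'", roiId,
                     if (is.null(crit)) "<missing>" else crit))
      if (is.null(score) || !score %in% 0:2)
        stop(sprintf("roi '%s': score %s outside {0,1,2}", roiId,
                     if (is.null(score)) "<missing>" else format(score)))
      sr <- list(polygon = poly, criterion = crit,
                 score = as.integer(score))
      if (is.null(rois[[roiId]]))
        rois[[roiId]] <- new("ROIAnnotation", roiId = roiId,
                             boundary = matrix(numeric(), 0, 2),
                             subRegions = list(sr))
      else
        rois[[roiId]]@subRegions <- c(rois[[roiId]]@subRegions, list(sr))
    }
  }
  for (roi in rois) {
    if (nrow(roi@boundary) < 3L)
      stop(sprintf("roi '%s': no boundary polygon", roi@roiId))
    validObject(roi)
  }
  unname(rois)
}

#' Write annotations in the GeoJSON dialect
#'
#' Inverse of [parseAnnotations()]; vertices survive the round-trip
#' exactly.
#'
#' @param rois list of [ROIAnnotation-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeAnnotations <- function(rois, path) {
  toRing <- function(poly) {
    closed <- rbind(poly, poly[1, ])
    list(lapply(seq_len(nrow(closed)),
                function(i) as.numeric(closed[i, ])))
  }
  feats <- list()
  for (roi in rois) {
    feats[[length(feats) + 1L]] <- list(
      type = "Feature",
      geometry = list(type = "Polygon", coordinates = toRing(roi@boundary)),
      properties = list(roi_id = roi@roiId, object_type = "boundary"))
    for (sr in roi@subRegions)
      feats[[length(feats) + 1L]] <- list(
        type = "Feature",
        geometry = list(type = "Polygon",
                        coordinates = toRing(sr$polygon)),
        properties = list(roi_id = roi@roiId, criterion = sr$criterion,
                          score = sr$score))
  }
  doc <- list(type = "FeatureCollection", features = feats)
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

## bounding-box pixel grid of an ROI (0-based integer box)
roiBBox <- function(roi) {
  x0 <- floor(min(roi@boundary[, 1])); x1 <- ceiling(max(roi@boundary[, 1]))
  y0 <- floor(min(roi@boundary[, 2])); y1 <- ceiling(max(roi@boundary[, 2]))
  list(x0 = x0, y0 = y0, width = x1 - x0, height = y1 - y0)
}

roiPixelCenters <- function(bbox) {
  px <- rep(bbox$x0 + seq_len(bbox$width) - 0.5, each = bbox$height)
  py <- rep(bbox$y0 + seq_len(bbox$height) - 0.5, times = bbox$width)
  list(px = px, py = py)
}

#' Rasterize TSR scores of one criterion over an ROI
#'
#' Produces an integer score mask over the ROI bounding box: each pixel
#' (tested at its center with the even-odd rule) takes the score of the
#' sub-region containing it; pixels in no scored sub-region are NA
#' (undefined). On overlap, polygons later in file order overwrite earlier
#' ones, with a warning.
#'
#' @param roi an [ROIAnnotation-class].
#' @param criterion one of `"fibrosis"`, `"cellularity"`, `"orientation"`.
#' @return integer matrix [height, width] over the bounding box, with
#'   attributes `x0`, `y0` (0-based origin of the box).
#' @export
rasterizeScores <- function(roi, criterion) {
  stopifnot(is(roi, "ROIAnnotation"))
  criterion <- match.arg(criterion, .criteria)
  srs <- Filter(function(sr) sr$criterion == criterion, roi@subRegions)
  if (length(srs) == 0L)
    stop(sprintf("roi '%s': criterion '%s' has no sub-regions",
                 roi@roiId, criterion))
  bbox <- roiBBox(roi)
  ctr <- roiPixelCenters(bbox)
  mask <- matrix(NA_integer_, bbox$height, bbox$width)
  written <- matrix(FALSE, bbox$height, bbox$width)
  overlapped <- FALSE
  for (sr in srs) {
    inside <- pointsInPolygonEO(ctr$px, ctr$py, sr$polygon)
    if (any(inside & written)) overlapped <- TRUE
    mask[inside] <- sr$score
    written <- written | matrix(inside, bbox$height, bbox$width)
  }
  if (overlapped)
    warning(sprintf("roi '%s': overlapping sub-regions; later polygons win",
                    roi@roiId))
  attr(mask, "x0") <- bbox$x0
  attr(mask, "y0") <- bbox$y0
  mask
}

#' Derive tumor and stroma training masks from an annotated ROI
#'
#' The stroma mask is the union of all scored sub-regions (any criterion,
#' any score); the tumor mask is the remaining tissue inside the ROI
#' boundary: `tissue AND boundary AND NOT stroma`. The two masks are
#' disjoint by construction.
#'
#' @param roi an [ROIAnnotation-class].
#' @param tissueMask logical matrix covering the ROI bounding box (same
#'   dimensions as the rasterized box).
#' @return list with logical matrices `tumor` and `stroma` plus the box
#'   origin (`x0`, `y0`).
#' @export
deriveTumorStroma <- function(roi, tissueMask) {
  stopifnot(is(roi, "ROIAnnotation"))
  bbox <- roiBBox(roi)
  if (!all(dim(tissueMask) == c(bbox$height, bbox$width)))
    stop("tissueMask must cover the ROI bounding box")
  ctr <- roiPixelCenters(bbox)
  boundaryIn <- matrix(pointsInPolygonEO(ctr$px, ctr$py, roi@boundary),
                       bbox$height, bbox$width)
  stroma <- matrix(FALSE, bbox$height, bbox$width)
  for (sr in roi@subRegions)
    stroma <- stroma |
      matrix(pointsInPolygonEO(ctr$px, ctr$py, sr$polygon),
             bbox$height, bbox$width)
  stroma <- stroma & boundaryIn
  tumor <- tissueMask & boundaryIn & !stroma
  list(tumor = tumor, stroma = stroma, x0 = bbox$x0, y0 = bbox$y0)
}
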