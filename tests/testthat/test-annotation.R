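squarePoly <- function(x0, y0, side) {
  rbind(c(x0, y0), c(x0 + side, y0), c(x0 + side, y0 + side),
        c(x0, y0 + side))
}

makeRoi <- function(roiId = "roi1", boundary = squarePoly(0, 0, 64),
                    subRegions = list()) {
  new("ROIAnnotation", roiId = roiId, boundary = boundary,
      subRegions = subRegions)
}

writeRoiFile <- function(rois) {
  f <- withr::local_tempfile(fileext = ".geojson",
                             .local_envir = parent.frame())
  writeAnnotations(rois, f)
  f
}

test_that("a simple annotation file parses to one ROI with one sub-region", {
  roi <- makeRoi(subRegions = list(
    list(polygon = squarePoly(8, 8, 16), criterion = "fibrosis",
         score = 2L)))
  f <- writeRoiFile(list(roi))
  parsed <- parseAnnotations(f)
  expect_length(parsed, 1)
  expect_equal(parsed[[1]]@roiId, "roi1")
  expect_length(parsed[[1]]@subRegions, 1)
  expect_equal(parsed[[1]]@subRegions[[1]]$criterion, "fibrosis")
  expect_equal(parsed[[1]]@subRegions[[1]]$score, 2L)
})

test_that("invalid scores, criteria and polygons are rejected by roi id", {
  base <- list(type = "Feature",
               geometry = list(type = "Polygon",
                               coordinates = list(list(
                                 c(0, 0), c(64, 0), c(64, 64), c(0, 64),
                                 c(0, 0)))),
               properties = list(roi_id = "roiX",
                                 object_type = "boundary"))
  bad <- base
  bad$properties <- list(roi_id = "roiX", criterion = "fibrosis", score = 3)
  f <- withr::local_tempfile(fileext = ".geojson")
  writeLines(jsonlite::toJSON(
    list(type = "FeatureCollection", features = list(base, bad)),
    auto_unbox = TRUE), f)
  expect_error(parseAnnotations(f), "roiX.*score 3")

  bad$properties <- list(roi_id = "roiX", criterion = "density", score = 1)
  writeLines(jsonlite::toJSON(
    list(type = "FeatureCollection", features = list(base, bad)),
    auto_unbox = TRUE), f)
  expect_error(parseAnnotations(f), "roiX.*criterion 'density'")

  ## self-intersecting bow-tie boundary
  bow <- base
  bow$geometry$coordinates <- list(list(c(0, 0), c(10, 10), c(10, 0),
                                        c(0, 10), c(0, 0)))
  writeLines(jsonlite::toJSON(
    list(type = "FeatureCollection", features = list(bow)),
    auto_unbox = TRUE), f)
  expect_error(parseAnnotations(f), "roiX.*self-intersecting")
})

test_that("write -> parse round-trip reproduces vertices exactly", {
  set.seed(9)
  ## irregular convex polygon with non-integer vertices
  ang <- sort(runif(7, 0, 2 * pi))
  poly <- cbind(100 + 40 * cos(ang), 80 + 30 * sin(ang))
  roi <- makeRoi(boundary = poly, subRegions = list(
    list(polygon = squarePoly(90.5, 70.25, 10.125),
         criterion = "cellularity", score = 1L)))
  parsed <- parseAnnotations(writeRoiFile(list(roi)))
  expect_equal(parsed[[1]]@boundary, poly)
  expect_equal(parsed[[1]]@subRegions[[1]]$polygon,
               squarePoly(90.5, 70.25, 10.125))
})

test_that("a full-ROI polygon rasterizes to a constant mask", {
  roi <- makeRoi(subRegions = list(
    list(polygon = squarePoly(0, 0, 64), criterion = "fibrosis",
         score = 1L)))
  m <- rasterizeScores(roi, "fibrosis")
  expect_equal(dim(m), c(64L, 64L))
  expect_true(all(m == 1L))
})

test_that("disjoint scored squares match the pixel-count and PIP oracles", {
  a <- squarePoly(4, 4, 16)      # 16x16 px when sampled at centers
  b <- squarePoly(32, 40, 20)
  roi <- makeRoi(subRegions = list(
    list(polygon = a, criterion = "orientation", score = 0L),
    list(polygon = b, criterion = "orientation", score = 2L)))
  m <- rasterizeScores(roi, "orientation")
  expect_equal(sum(m == 0L, na.rm = TRUE), 16 * 16)
  expect_equal(sum(m == 2L, na.rm = TRUE), 20 * 20)
  ## brute-force even-odd scan over every pixel center
  for (px in seq_len(64)) {
    for (py in c(5, 12, 41, 55)) {
      want <- if (bfPointInPolygon(px - 0.5, py - 0.5, a)) 0L
              else if (bfPointInPolygon(px - 0.5, py - 0.5, b)) 2L
              else NA_integer_
      expect_identical(m[py, px], want)
    }
  }
})

test_that("rasterization errors and overlap semantics", {
  roi <- makeRoi(subRegions = list(
    list(polygon = squarePoly(0, 0, 32), criterion = "fibrosis",
         score = 0L),
    list(polygon = squarePoly(16, 0, 32), criterion = "fibrosis",
         score = 2L)))
  expect_error(rasterizeScores(roi, "cellularity"), "no sub-regions")
  expect_warning(m <- rasterizeScores(roi, "fibrosis"), "overlapping")
  ## later polygon wins on the overlap strip
  expect_true(all(m[1:32, 17:32] == 2L))
  expect_true(all(m[1:32, 1:16] == 0L))
  ## idempotent and deterministic
  expect_identical(m, suppressWarnings(rasterizeScores(roi, "fibrosis")))
})

test_that("tumor/stroma derivation follows the region algebra", {
  tissue <- matrix(TRUE, 64, 64)
  ## fully covered ROI -> no tumor
  full <- makeRoi(subRegions = list(
    list(polygon = squarePoly(0, 0, 64), criterion = "fibrosis",
         score = 1L)))
  ts <- deriveTumorStroma(full, tissue)
  expect_false(any(ts$tumor))
  ## no scored polygons -> all tissue inside the ROI is tumor
  none <- makeRoi()
  ts2 <- deriveTumorStroma(none, tissue)
  expect_false(any(ts2$stroma))
  expect_true(all(ts2$tumor))
  expect_error(deriveTumorStroma(none, matrix(TRUE, 10, 10)),
               "bounding box")
})

test_that("mixed derivation equals the boolean set-algebra oracle", {
  set.seed(3)
  tissue <- matrix(runif(64 * 64) < 0.9, 64, 64)
  sub1 <- squarePoly(2, 2, 20)
  sub2 <- squarePoly(30, 25, 25)
  roi <- makeRoi(subRegions = list(
    list(polygon = sub1, criterion = "fibrosis", score = 2L),
    list(polygon = sub2, criterion = "cellularity", score = 1L)))
  ts <- deriveTumorStroma(roi, tissue)
  ## oracle: per-pixel brute-force point-in-polygon plus set ops
  for (px in seq(2, 64, by = 7)) {
    for (py in seq(3, 64, by = 9)) {
      inB <- bfPointInPolygon(px - 0.5, py - 0.5, roi@boundary)
      inS <- bfPointInPolygon(px - 0.5, py - 0.5, sub1) ||
        bfPointInPolygon(px - 0.5, py - 0.5, sub2)
      expect_identical(ts$stroma[py, px], inB && inS)
      expect_identical(ts$tumor[py, px], tissue[py, px] && inB && !inS)
    }
  }
  ## invariants: disjoint, inside tissue-and-boundary
  expect_false(any(ts$tumor & ts$stroma))
  expect_true(all(!(ts$tumor | ts$stroma) | tissue |
                    ts$stroma))  # tumor subset of tissue
})
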