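flatImage <- function(rgb, h = 64, w = 64) {
  array(rep(rgb, each = h * w), dim = c(h, w, 3))
}

test_that("foreground detection handles uniform images", {
  white <- flatImage(c(1, 1, 1))
  purple <- flatImage(c(0.45, 0.25, 0.55))
  expect_false(any(detectForeground(white, "fixed", threshold = 90)))
  expect_true(all(detectForeground(purple, "fixed", threshold = 90)))
  expect_error(detectForeground(array(numeric(0), c(0, 0, 3))),
               "empty image")
})

test_that("automatic threshold splits a bimodal image like the L oracle", {
  img <- flatImage(c(1, 1, 1))
  img[, 33:64, ] <- rep(c(0.90, 0.75, 0.80), each = 64 * 32)  # pink half
  fg <- detectForeground(img, "otsu")
  ## oracle: recompute L per pixel from the closed-form sRGB -> Lab path
  Lw <- bfLightness(1, 1, 1)
  Lp <- bfLightness(0.90, 0.75, 0.80)
  thr <- attr(fg, "threshold")
  expect_true(Lp < thr && thr < Lw)
  expect_identical(unname(fg[, 1:32]), matrix(FALSE, 64, 32))
  expect_identical(unname(fg[, 33:64]), matrix(TRUE, 64, 32))
})

test_that("lightness matches the closed-form oracle", {
  set.seed(2)
  img <- array(runif(16 * 16 * 3), dim = c(16, 16, 3))
  L <- labLightness(img)
  Lo <- matrix(bfLightness(as.vector(img[, , 1]), as.vector(img[, , 2]),
                           as.vector(img[, , 3])), 16, 16)
  ## convertColor and the closed-form path use slightly different sRGB
  ## primary roundings; agreement to ~0.2 L units validates the channel
  expect_equal(L, Lo, tolerance = 0.01)
})

test_that("tiling grid arithmetic and all-tissue extraction", {
  img <- flatImage(c(0.45, 0.25, 0.55), 1024, 1024)
  ps <- extractPatches(img, tilingConfig(patchSize = 256, stride = 256),
                       threshold = 90, slideId = "t")
  expect_equal(nPatches(ps), 16L)
  expect_true(all(backgroundFrac(ps) == 0))
  ps2 <- extractPatches(img, tilingConfig(patchSize = 256, stride = 128),
                        threshold = 90)
  expect_equal(nPatches(ps2), 49L)
  expect_error(extractPatches(img, tilingConfig(patchSize = 2048)),
               "exceeds slide dimensions")
})

test_that("all-background slides yield no patches", {
  img <- flatImage(c(1, 1, 1), 512, 512)
  ps <- extractPatches(img, tilingConfig(patchSize = 256, stride = 256),
                       threshold = 90)
  expect_equal(nPatches(ps), 0L)
})

test_that("background exclusion matches the exhaustive per-tile oracle", {
  ## slide with a vertical white stripe of varying width per tile row
  set.seed(4)
  img <- flatImage(c(0.45, 0.25, 0.55), 512, 512)
  img[, 193:512, ] <- 1                     # white right part
  cfg <- tilingConfig(patchSize = 128, stride = 64,
                      maxBackgroundFrac = 0.5)
  thr <- 90
  ps <- extractPatches(img, cfg, threshold = thr, slideId = "s")
  ## oracle: enumerate every grid tile, recompute the L-threshold
  ## background fraction from the raw pixels, apply the 50% rule
  keep <- 0L
  for (y0 in seq(0, 512 - 128, by = 64)) {
    for (x0 in seq(0, 512 - 128, by = 64)) {
      tile <- img[(y0 + 1):(y0 + 128), (x0 + 1):(x0 + 128), ]
      L <- bfLightness(as.vector(tile[, , 1]), as.vector(tile[, , 2]),
                       as.vector(tile[, , 3]))
      if (mean(L >= thr) <= 0.5) keep <- keep + 1L
    }
  }
  expect_equal(nPatches(ps), keep)
  expect_true(all(backgroundFrac(ps) <= 0.5))
})

test_that("patch origins lie on the stride lattice without duplicates", {
  sl <- testSlide(7, "HGSOC", 1024L)
  ps <- extractPatches(slideImage(sl),
                       tilingConfig(patchSize = 256, stride = 128),
                       threshold = 90)
  org <- patchOrigins(ps)
  expect_true(all(org %% 128 == 0))
  expect_false(any(duplicated(org)))
})

test_that("tightening the background cap never adds patches", {
  img <- flatImage(c(0.45, 0.25, 0.55), 512, 512)
  img[, 250:512, ] <- 1
  counts <- vapply(c(0.8, 0.5, 0.3, 0.1), function(mx) {
    nPatches(extractPatches(
      img, tilingConfig(patchSize = 128, stride = 128,
                        maxBackgroundFrac = mx), threshold = 90))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("patch PNG round-trip preserves 8-bit pixel values exactly", {
  sl <- testSlide(7, "HGSOC", 512L)
  ## quantize to the 8-bit lattice the lossless format stores
  img <- round(slideImage(sl)[1:64, 1:64, , drop = FALSE] * 255) / 255
  dir <- withr::local_tempdir()
  f <- file.path(dir, "p.png")
  writeSlidePng(img, f)
  expect_equal(readSlidePng(f), img)
  ## mask round-trips
  m <- tumorMask(sl)[1:64, 1:64]
  writeMaskPng(m, file.path(dir, "m.png"), "binary")
  expect_identical(readMaskPng(file.path(dir, "m.png"), "binary"),
                   unname(m))
  sc <- tsrMaps(sl)$fibrosis[1:64, 1:64]
  writeMaskPng(sc, file.path(dir, "s.png"), "score")
  expect_identical(readMaskPng(file.path(dir, "s.png"), "score"),
                   unname(sc))
})

test_that("writePatches emits one PNG per patch plus a manifest", {
  sl <- testSlide(7, "HGSOC", 512L)
  ps <- extractPatches(slideImage(sl),
                       tilingConfig(patchSize = 256, stride = 256),
                       threshold = 90, slideId = "sl7")
  dir <- withr::local_tempdir()
  man <- writePatches(ps, dir)
  expect_true(all(file.exists(file.path(dir, man$file))))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_equal(nrow(man), nPatches(ps))
  expect_match(man$file[1], "^sl7_\\d+_\\d+\\.png$")
})
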