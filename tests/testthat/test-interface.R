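slideMaskOf <- function(labels, r = 1 / 128) {
  new("SlideMask", labels = labels, r = r, slideId = "test")
}

test_that("a single stroma patch stitches to one block", {
  pred <- data.frame(x = 0, y = 0, class = "stroma")
  m <- stitchPatches(pred, c(1024, 1024), r = 1 / 128, patchSize = 256)
  lab <- maskLabels(m)
  expect_equal(dim(lab), c(8L, 8L))
  expect_true(all(lab[1:2, 1:2] == 2L))
  expect_true(all(lab[-(1:2), ] == 0L) && all(lab[, -(1:2)] == 0L))
})

test_that("empty predictions stitch to an all-background mask", {
  pred <- data.frame(x = numeric(0), y = numeric(0),
                     class = character(0))
  m <- stitchPatches(pred, c(512, 512), r = 1 / 128, patchSize = 256)
  expect_true(all(maskLabels(m) == 0L))
})

test_that("overlapping patches are rejected", {
  pred <- data.frame(x = c(0, 128), y = c(0, 0),
                     class = c("tumor", "stroma"))
  expect_error(stitchPatches(pred, c(512, 512), r = 1 / 128,
                             patchSize = 256),
               "non-overlapping")
})

test_that("stitched phantom mask tracks the downsampled ground truth", {
  ps <- testPatches(7, "HGSOC", 1024L, stride = 256L)
  seg <- testSegmenter()
  pred <- predictSlide(ps, seg, testScorers())
  mask <- stitchPatches(pred, c(1024, 1024), r = 1 / 8)
  ## truth at the same granularity, with the same dominant-class rule the
  ## pipeline applies (majority over tissue pixels; background only when
  ## the patch holds no tissue at all)
  dominant <- vapply(patchTruth(ps), function(tr) {
    nT <- sum(tr == 1L); nS <- sum(tr == 2L)
    if (nT + nS == 0L) "background" else if (nT > nS) "tumor" else "stroma"
  }, character(1))
  tdf <- data.frame(x = patchOrigins(ps)[, 1], y = patchOrigins(ps)[, 2],
                    class = dominant)
  tmask <- stitchPatches(tdf, c(1024, 1024), r = 1 / 8, patchSize = 256)
  expect_gte(mean(maskLabels(mask) == maskLabels(tmask)), 0.95)
})

test_that("empty tumor or stroma yields an empty interface", {
  onlyS <- matrix(2L, 32, 32)
  onlyT <- matrix(1L, 32, 32)
  expect_equal(sum(interfaceMask(detectInterface(slideMaskOf(onlyS)))), 0)
  expect_equal(sum(interfaceMask(detectInterface(slideMaskOf(onlyT)))), 0)
  empty <- detectInterface(slideMaskOf(matrix(0L, 16, 16)))
  expect_equal(nrow(interfaceComponents(empty)), 0L)
})

test_that("half-tumor/half-stroma mask matches the brute-force oracle", {
  lab <- matrix(0L, 64, 64)
  lab[, 1:32] <- 1L
  lab[, 33:64] <- 2L
  se <- structuringElement("disk", 2)
  got <- interfaceMask(detectInterface(slideMaskOf(lab), se))
  expect_identical(got, bfInterface(lab, se))
  expect_gt(sum(got), 0)
})

test_that("interface equals the oracle on random structured masks", {
  set.seed(21)
  for (rep in 1:10) {
    lab <- randomLabelRaster(48, 48)
    se <- structuringElement(sample(c("disk", "square"), 1),
                             sample(1:3, 1))
    got <- detectInterface(slideMaskOf(lab), se)
    expect_identical(interfaceMask(got), bfInterface(lab, se))
  }
})

test_that("interface is nested in the stroma core and its dilation", {
  set.seed(33)
  se <- structuringElement("disk", 2)
  for (rep in 1:20) {
    lab <- randomLabelRaster(40, 40)
    got <- interfaceMask(detectInterface(slideMaskOf(lab), se))
    Sc <- bfClose(lab == 2L, se)
    expect_true(all(!got | Sc))                    # interface within core
    expect_true(all(!Sc | bfDilate(lab == 2L, se)))  # core within dilation
  }
})

test_that("components are sorted by size with scan-order tie-breaks", {
  m <- matrix(0L, 16, 16)
  m[2, 2:4] <- 2L          # will not matter: use interface mask directly
  ## construct an InterfaceResult through detectInterface on a crafted mask
  lab <- matrix(0L, 20, 20)
  lab[9:12, ] <- 1L                       # central tumor band
  lab[5:8, 1:4] <- 2L; lab[5:8, 9:12] <- 2L; lab[14:17, 3:8] <- 2L
  res <- detectInterface(slideMaskOf(lab), structuringElement("disk", 1))
  cmp <- interfaceComponents(res)
  expect_true(all(diff(cmp$size) <= 0))
  ties <- split(cmp$id, cmp$size)
  for (g in ties) expect_true(all(diff(g) > 0))
  ## sizes partition the mask
  expect_equal(sum(cmp$size), sum(interfaceMask(res)))
})

test_that("component labeling agrees with a flood-fill recount", {
  set.seed(5)
  for (rep in 1:8) {
    m <- randomMask(24, 24, 0.35)
    for (conn in c(8, 4)) {
      got <- connectedComponents(m, conn)
      want <- bfComponents(m, conn)
      ## same partition: sizes per component and identical pixel grouping
      expect_equal(sort(tabulate(got[got > 0])),
                   sort(tabulate(want[want > 0])))
      key <- paste(got[m], want[m])
      expect_equal(length(unique(key)), max(got))
    }
  }
})

test_that("topComponents truncates and preserves order", {
  lab <- matrix(0L, 30, 30)
  lab[15:16, ] <- 1L
  lab[12:14, 1:5] <- 2L; lab[12:14, 10:12] <- 2L; lab[18:20, 20:28] <- 2L
  res <- detectInterface(slideMaskOf(lab), structuringElement("disk", 1))
  cmp <- interfaceComponents(res)
  expect_lte(nrow(topComponents(res, 5)), 5)
  expect_equal(topComponents(res, 2), utils::head(cmp, 2))
  expect_equal(nrow(topComponents(res, 100)), nrow(cmp))
  expect_error(topComponents(res, 0), "k must be")
})

test_that("interface on downsampled truth recovers the boundary band", {
  ## block-downsampled ground truth (majority class per block), then the
  ## interface formula; band = stroma within the SE radius of tumor
  sl <- testSlide(7, "HGSOC", 1024L)
  f <- 8L
  lab0 <- matrix(0L, 1024, 1024)
  lab0[tumorMask(sl)] <- 1L
  lab0[stromaMask(sl)] <- 2L
  ds <- matrix(0L, 128, 128)
  for (by in seq_len(128)) {
    rows <- ((by - 1) * f + 1):(by * f)
    for (bx in seq_len(128)) {
      blk <- lab0[rows, ((bx - 1) * f + 1):(bx * f)]
      ds[by, bx] <- as.integer(names(which.max(table(blk))))
    }
  }
  rad <- 2L
  res <- detectInterface(slideMaskOf(ds, r = 1 / 8),
                         structuringElement("disk", rad))
  im <- interfaceMask(res)
  tum <- which(ds == 1L, arr.ind = TRUE)
  str <- which(ds == 2L, arr.ind = TRUE)
  dmin <- vapply(seq_len(nrow(str)), function(i)
    sqrt(min((str[i, 1] - tum[, 1])^2 + (str[i, 2] - tum[, 2])^2)),
    numeric(1))
  band <- str[dmin <= rad, , drop = FALSE]
  far <- str[dmin > 2 * rad, , drop = FALSE]
  expect_gte(mean(im[band]), 0.9)
  expect_lte(mean(im[far]), 0.1)
})
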