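test_that("reference segmenter reaches 99% pixel accuracy held out", {
  seg <- testSegmenter()
  held <- testPatches(42, "HGSOC", 1024L, stride = 256L)
  ev <- evaluateSegmenter(seg, held)
  expect_gte(mean(ev$pixel_accuracy), 0.99)
})

test_that("segmentation output honors the backend contract", {
  seg <- testSegmenter()
  img <- patchImages(trainingPatches())[[1]]
  m <- segmentPatch(seg, img)
  expect_identical(dim(m), dim(img)[1:2])
  expect_true(all(m %in% 0:2))
  ## posterior collapse is a proper distribution
  post <- segmentPosterior(seg, img[1:32, 1:32, , drop = FALSE])
  expect_equal(apply(post, c(1, 2), sum),
               matrix(1, 32, 32), tolerance = 1e-9)
})

test_that("segmenter fitting is deterministic and rejects one class", {
  train <- trainingPatches()
  a <- fitReferenceSegmenter(train, seed = 3)
  b <- fitReferenceSegmenter(train, seed = 3)
  img <- patchImages(train)[[5]]
  expect_identical(segmentPatch(a, img), segmentPatch(b, img))
  ## single-class training set: pure background rasters
  bg <- train[1:2]
  bg@truth <- list(matrix(0L, 256, 256), matrix(0L, 256, 256))
  expect_error(fitReferenceSegmenter(bg), "single class")
})

test_that("TSR scorer separates held-out homogeneous phantom patches", {
  scorers <- testScorers()
  held <- combinePatchSets(testPatches(42, "HGSOC", 1024L, 128L),
                           testPatches(43, "SBOT", 1024L, 128L))
  for (crit in c("fibrosis", "cellularity", "orientation")) {
    hom <- homogeneousStroma(held, crit)
    lab <- patchLabels(hom)
    pred <- vapply(seq_len(nPatches(hom)), function(i)
      scorePatch(scorers[[crit]], patchImages(hom)[[i]])$score,
      integer(1))
    expect_gte(mean(pred == lab[[crit]]), 0.95)
  }
})

test_that("scorer probabilities are normalized and argmax-consistent", {
  scorers <- testScorers()
  held <- testPatches(42, "HGSOC", 1024L, stride = 256L)
  for (i in seq_len(min(nPatches(held), 8))) {
    res <- scorePatch(scorers$fibrosis, patchImages(held)[[i]])
    expect_equal(sum(res$prob), 1, tolerance = 1e-6)
    expect_true(all(res$prob >= 0))
    expect_equal(unname(which.max(res$prob)) - 1L, res$score)
  }
})

test_that("SBOT-like patches get modal prediction 0", {
  scorers <- testScorers()
  held <- homogeneousStroma(testPatches(43, "SBOT", 1024L, 128L))
  pred <- vapply(seq_len(nPatches(held)), function(i)
    scorePatch(scorers$fibrosis, patchImages(held)[[i]])$score,
    integer(1))
  expect_equal(as.integer(names(which.max(table(pred)))), 0L)
})

test_that("scorer fitting rejects a missing score class by name", {
  train <- trainingPatches()
  lab <- patchLabels(train)
  noTwo <- train[!(lab$class == "stroma" & !is.na(lab$fibrosis) &
                     lab$fibrosis == 2L)]
  expect_error(fitReferenceTsrScorer(noTwo, "fibrosis"), "2")
})

test_that("predictSlide attaches scores only to stroma-dominant patches", {
  ps <- testPatches(7, "HGSOC", 1024L, stride = 256L)
  pred <- predictSlide(ps, constantSegmenter(1L),
                       list(fibrosis = constantScorer("fibrosis", 2L),
                            cellularity = constantScorer("cellularity"),
                            orientation = constantScorer("orientation")))
  p <- patchPredictions(pred)
  expect_true(all(p$class == "tumor"))
  expect_true(all(is.na(p$fibrosis)))

  pred2 <- predictSlide(ps, constantSegmenter(2L),
                        list(fibrosis = constantScorer("fibrosis", 2L),
                             cellularity = constantScorer("cellularity"),
                             orientation = constantScorer("orientation")))
  p2 <- patchPredictions(pred2)
  expect_true(all(p2$class == "stroma"))
  expect_true(all(p2$fibrosis == 2L))
  expect_true(all(p2$fibrosis_p2 == 1))
})

test_that("empty patch sets give empty predictions", {
  ps <- testPatches(7, "HGSOC", 1024L, stride = 256L)
  empty <- ps[integer(0)]
  pred <- predictSlide(empty, constantSegmenter(2L),
                       list(fibrosis = constantScorer("fibrosis"),
                            cellularity = constantScorer("cellularity"),
                            orientation = constantScorer("orientation")))
  expect_equal(nrow(patchPredictions(pred)), 0L)
})

test_that("slide prediction equals running the backends patch by patch", {
  seg <- testSegmenter()
  scorers <- testScorers()
  ps <- testPatches(42, "HGSOC", 1024L, stride = 256L)[1:6]
  pred <- patchPredictions(predictSlide(ps, seg, scorers))
  for (i in seq_len(6)) {
    m <- segmentPatch(seg, patchImages(ps)[[i]])
    nT <- sum(m == 1L); nS <- sum(m == 2L)
    cls <- if (nT + nS == 0L) "background"
           else if (nT > nS) "tumor" else "stroma"
    expect_equal(pred$class[i], cls)
    if (cls == "stroma") {
      res <- scorePatch(scorers$fibrosis, patchImages(ps)[[i]])
      expect_equal(pred$fibrosis[i], res$score)
    }
  }
})

test_that("backend contract violations surface as errors", {
  ps <- testPatches(7, "HGSOC", 1024L, stride = 256L)[1:2]
  broken <- new("BrokenSegmenter", name = "broken", version = "0")
  expect_error(
    predictSlide(ps, broken,
                 list(fibrosis = constantScorer("fibrosis"),
                      cellularity = constantScorer("cellularity"),
                      orientation = constantScorer("orientation"))),
    "violated the segmenter contract")
})

test_that("pipeline results depend on backends only through contracts", {
  ## a constant mock must flow through stitching and summarization the
  ## same way the fitted reference backends do
  ps <- testPatches(7, "HGSOC", 1024L, stride = 256L)
  pred <- predictSlide(ps, constantSegmenter(2L),
                       list(fibrosis = constantScorer("fibrosis", 1L),
                            cellularity = constantScorer("cellularity"),
                            orientation = constantScorer("orientation")))
  mask <- stitchPatches(pred, c(1024, 1024), r = 1 / 8)
  expect_true(all(maskLabels(mask) %in% c(0L, 2L)))
  sm <- summarizeSlide(pred, matrix(TRUE, 128, 128), r = 1 / 8)
  expect_equal(sm$fibrosis_ratio1, 1)
  expect_equal(sm$fibrosis_mean, 1)
})
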