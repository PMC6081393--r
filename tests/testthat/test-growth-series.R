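# Series planning and growth-guided plate generation.

test_that("series planning follows the compound growth law", {
  det <- fixtureDetection()
  mf0 <- planSeries(det, growthModel(g = 0))
  expect_equal(nrow(mf0), 6)                     # default series size
  expect_true(all(mf0$targetA == det@ellipse@a))
  expect_true(all(mf0$targetB == det@ellipse@b))

  mf <- planSeries(det, growthModel(g = 0.02, nPlates = 6,
                                    intervalWeeks = 365.25 / 12 / 7))
  expect_equal(mf$growthFactor[5], 1.02^5, tolerance = 1e-12)
  expect_true(all(diff(mf$targetA) > 0))
  expect_true(all(diff(mf$targetGap) < 0))
  expect_equal(mf$targetGap[6], 0)
  expect_equal(mf$targetGap[1], gapChordWidth(det), tolerance = 1e-9)
})

test_that("closure schedule is monotone and reaches zero", {
  m <- growthModel(nPlates = 6)
  fr <- closureFraction(m, 1:6)
  expect_true(all(diff(fr) <= 0))
  expect_equal(fr[6], 0)
  expect_equal(closureFraction(growthModel(nPlates = 1), 1), 0)
  expect_equal(closureFraction(growthModel(closureSchedule = "none"), 1:4),
               rep(1, 4))
})

test_that("zero growth without closure produces identical plates", {
  gen <- fixtureMaxilla()
  det <- fixtureDetection()
  res <- generateSeries(gen$mesh, det,
                        growthModel(g = 0, nPlates = 3,
                                    closureSchedule = "none"),
                        plateSpec(voxelPitch = 0.4), pin = FALSE,
                        smooth = FALSE)
  vols <- res$manifest$volume
  expect_lt(max(abs(vols - vols[1])) / vols[1], 1e-6)
  expect_true(all(res$manifest$watertight))
})

test_that("series expands monotonically, closes the gap and does not rotate", {
  # fine mesh: the 0.5 mm closure check needs sub-bin gap measurement
  gen <- fixtureMaxilla(resolution = 0.5)
  det <- detectRidge(gen$mesh, nBins = 270L)
  model <- growthModel(g = 0.02, nPlates = 6, intervalWeeks = 2)
  res <- generateSeries(gen$mesh, det, model, plateSpec(voxelPitch = 0.4),
                        pin = FALSE, smooth = FALSE)
  expect_true(all(res$manifest$watertight))
  dets <- lapply(res$warped, detectRidge, nBins = 270L)
  aVals <- vapply(dets, function(d) d@ellipse@a, numeric(1))
  bVals <- vapply(dets, function(d) d@ellipse@b, numeric(1))
  expect_true(all(diff(aVals) > 0.1))
  expect_true(all(diff(bVals) > 0.1))
  # gap follows the closure schedule within 0.5 mm
  detsBr <- lapply(res$anatomies, detectRidge, nBins = 270L)
  gaps <- vapply(detsBr, gapChordWidth, numeric(1))
  expect_lt(max(abs(gaps - res$manifest$targetGap)), 0.5)
  expect_lte(gaps[6], 0.8)                       # full closure at resolution
  # greater-segment principal axis: no active rotation
  ax <- function(d) {
    p <- d@crests[[1]]@points
    pr <- prcomp(p)$rotation[, 1]
    pr * sign(pr[which.max(abs(pr))])
  }
  a1 <- ax(dets[[1]])
  rots <- vapply(dets[-1], function(d)
    acos(min(1, abs(sum(a1 * ax(d))))) * 180 / pi, numeric(1))
  expect_lt(max(rots), 2)
})

test_that("warp scales the crest to the target ellipse", {
  gen <- fixtureMaxilla()
  det <- fixtureDetection()
  w <- warpToEllipse(gen$mesh, det, 1.05)
  dw <- detectRidge(w)
  expect_equal(dw@ellipse@a, det@ellipse@a * 1.05, tolerance = 0.01)
  expect_equal(dw@ellipse@b, det@ellipse@b * 1.05, tolerance = 0.01)
  expect_identical(warpToEllipse(gen$mesh, det, 1), gen$mesh)
})
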