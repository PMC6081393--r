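# Occlusal frame, crest extraction and ellipse fitting.

test_that("occlusal frame recovers the canonical pose normal", {
  gen <- fixtureMaxilla()
  fr <- computeOcclusalFrame(gen$mesh)
  ang <- acos(min(1, abs(sum(fr@axes[, 3] * gen$truth@occlusalNormal))))
  expect_lt(ang * 180 / pi, 2)
  # sign rule: crest above the vault centroid
  q <- (sweep(meshVertices(gen$mesh), 2, fr@origin) %*% fr@axes)[, 3]
  crest <- do.call(rbind, gen$truth@crest)
  qc <- (sweep(crest, 2, fr@origin) %*% fr@axes)[, 3]
  expect_gt(median(qc), median(q))
})

test_that("frame estimation is equivariant under rigid motion", {
  gen <- fixtureMaxilla()
  R <- randomRotation(101)
  rot <- transformMesh(gen$mesh, rotation = R, translation = c(5, -3, 11))
  fr0 <- computeOcclusalFrame(gen$mesh)
  fr1 <- computeOcclusalFrame(rot)
  ang <- acos(min(1, abs(sum(fr1@axes[, 3] * (R %*% fr0@axes[, 3])))))
  expect_lt(ang * 180 / pi, 2)
})

test_that("flat plate normal is recovered up to the sign rule", {
  g <- expand.grid(x = 0:10, y = 0:10)
  v <- cbind(g$x, g$y, 0)
  f <- do.call(rbind, lapply(0:9, function(j) do.call(rbind, lapply(0:9,
    function(i) {
      a <- j * 11 + i + 1; b <- a + 1; c2 <- a + 12; d <- a + 11
      rbind(c(a, b, c2), c(a, c2, d))
    }))))
  plate <- triangleMesh(v, f)
  fr <- computeOcclusalFrame(plate)
  expect_equal(abs(unname(fr@axes[3, 3])), 1, tolerance = 1e-9)
})

test_that("degenerate collinear geometry raises a frame error", {
  v <- cbind(seq_len(30), 0, 0) + 1e-12
  m <- new("TriangleMesh", vertices = v,
           faces = matrix(c(1L, 2L, 3L), 1, 3), name = "", metadata = list())
  expect_error(computeOcclusalFrame(m), "degenerate")
})

test_that("per-bin crest maxima agree with an exhaustive scan", {
  gen <- generateCleftMaxilla(anatomyParams(resolution = 1.6))
  m <- gen$mesh
  fr <- computeOcclusalFrame(m)
  crests <- extractCrest(m, fr, nBins = 60L)
  # independent brute-force oracle over all vertices
  q <- (sweep(meshVertices(m), 2, fr@origin) %*% fr@axes)
  w <- q[, 3]
  qs <- quantile(w, c(0.10, 0.98), names = FALSE)
  th <- qs[1] + 0.55 * (qs[2] - qs[1])
  cand <- which(w >= th)
  cuv <- colMeans(q[cand, 1:2, drop = FALSE])
  ang <- atan2(q[cand, 2] - cuv[2], q[cand, 1] - cuv[1])
  rad <- sqrt((q[cand, 1] - cuv[1])^2 + (q[cand, 2] - cuv[2])^2)
  keep <- rad >= 0.35 * median(rad) & rad <= 1.8 * median(rad)
  cand <- cand[keep]; ang <- ang[keep]; rad <- rad[keep]
  bin <- pmin(59, floor((ang + pi) / (2 * pi) * 60))
  oracle <- vapply(sort(unique(bin)), function(k) {
    sel <- which(bin == k)
    sel[order(-w[cand[sel]], rad[sel], cand[sel])[1]]
  }, integer(1))
  oraclePts <- meshVertices(m)[cand[oracle], , drop = FALSE]
  # every detected (pre-smoothing tolerance) crest point must be within the
  # smoothing displacement of an oracle per-bin maximum
  det <- do.call(rbind, lapply(crests, function(cc) cc@points))
  dd <- namplate:::cpp_point_polyline_distance(det, oraclePts)
  expect_lt(max(apply(det, 1, function(p)
    min(sqrt(rowSums(sweep(oraclePts, 2, p)^2))))), 1.6)
})

test_that("crest detection tracks ground truth and cleft continuity", {
  gen <- fixtureMaxilla()
  det <- fixtureDetection()
  expect_length(det@crests, 2)
  expect_equal(det@crests[[1]]@segmentLabel, "greater")
  truthCrest <- do.call(rbind, gen$truth@crest)
  pts <- do.call(rbind, lapply(det@crests, function(cc) cc@points))
  d <- namplate:::cpp_point_polyline_distance(pts, truthCrest)
  expect_lt(mean(d), 1.0)
  # crest points lie on the mesh surface
  expect_lt(max(pointMeshDistance(pts, gen$mesh)), 0.1)
  # arc params strictly monotone
  for (cc in det@crests) expect_true(all(diff(cc@arcParam) > 0) ||
                                       all(diff(cc@arcParam) < 0))

  gen0 <- generateCleftMaxilla(anatomyParams(cleftWidth = 0, resolution = 0.8))
  det0 <- detectRidge(gen0$mesh)
  expect_length(det0@crests, 1)
  expect_length(det0@gapSpan, 0)
})

test_that("ellipse fit is exact on noise-free conics", {
  pts <- ellipseSample(8, a = 15, b = 10)
  fit <- fitEllipse(pts)
  expect_equal(fit$ellipse@a, 15, tolerance = 1e-6)
  expect_equal(fit$ellipse@b, 10, tolerance = 1e-6)
  expect_equal(fit$ellipse@center, c(0, 0), tolerance = 1e-6)
  expect_lt(fit$rmsResidual, 1e-6)
  # rotated, shifted
  pts2 <- ellipseSample(12, a = 21, b = 17, theta = 0.7, center = c(3, -4))
  fit2 <- fitEllipse(pts2)
  expect_equal(fit2$ellipse@theta, 0.7, tolerance = 1e-6)
  expect_equal(fit2$ellipse@center, c(3, -4), tolerance = 1e-6)
  # circle degeneracy
  fit3 <- fitEllipse(ellipseSample(10, a = 12, b = 12))
  expect_equal(fit3$ellipse@a, 12, tolerance = 1e-9)
  expect_equal(fit3$ellipse@b, 12, tolerance = 1e-9)
  expect_lt(fit3$rmsResidual, 1e-9)
})

test_that("ellipse fit rejects degenerate input", {
  expect_error(fitEllipse(ellipseSample(4, 15, 10)), "at least 5")
  line <- cbind(1:10, 2 * (1:10) + 1)
  expect_error(fitEllipse(line))
})

test_that("noisy ellipse fit matches a nonlinear least-squares oracle", {
  set.seed(202)
  pts <- ellipseSample(100, a = 15, b = 10, tmax = 2 * pi) +
    matrix(rnorm(200, 0, 0.2), ncol = 2)
  fit <- fitEllipse(pts)
  expect_lt(abs(fit$ellipse@a - 15), 0.3)
  expect_lt(abs(fit$ellipse@b - 10), 0.3)
  # oracle: geometric least squares from the true parameters
  obj <- function(par) {
    ell <- new("EllipseParams", center = par[1:2], a = max(par[3:4]),
               b = min(par[3:4]), theta = par[5] %% pi)
    sum(pointToEllipseDistance(pts, ell)^2)
  }
  opt <- optim(c(0, 0, 15, 10, 0), obj, control = list(maxit = 2000,
                                                       reltol = 1e-12))
  oracleRMS <- sqrt(opt$value / nrow(pts))
  expect_lt(fit$rmsResidual, oracleRMS * 1.10)
})

test_that("ellipse fit is scale-equivariant", {
  set.seed(77)
  base <- ellipseSample(40, a = 19, b = 14, theta = 0.4, center = c(2, 1)) +
    matrix(rnorm(80, 0, 0.1), ncol = 2)
  f1 <- fitEllipse(base)
  for (s in c(0.5, 3, 17)) {
    f2 <- fitEllipse(base * s)
    expect_equal(f2$ellipse@a, f1$ellipse@a * s, tolerance = 1e-9)
    expect_equal(f2$ellipse@b, f1$ellipse@b * s, tolerance = 1e-9)
    expect_equal(f2$ellipse@center, f1$ellipse@center * s, tolerance = 1e-9)
    expect_equal(f2$ellipse@theta, f1$ellipse@theta, tolerance = 1e-9)
  }
})

test_that("detection is equivariant under rigid motion", {
  gen <- fixtureMaxilla()
  det0 <- fixtureDetection()
  R <- randomRotation(55)
  tr <- c(-4, 8, 2)
  rot <- transformMesh(gen$mesh, rotation = R, translation = tr)
  det1 <- detectRidge(rot)
  p0 <- do.call(rbind, lapply(det0@crests, function(cc) cc@points))
  p0r <- sweep(p0 %*% t(R), 2, tr, "+")
  p1 <- do.call(rbind, lapply(det1@crests, function(cc) cc@points))
  d <- namplate:::cpp_point_polyline_distance(p1, p0r)
  expect_lt(max(d), 0.5)
  expect_equal(det1@ellipse@a, det0@ellipse@a, tolerance = 0.05)
})

test_that("gap span is geometrically consistent with the cleft width", {
  gen <- generateCleftMaxilla(anatomyParams(cleftWidth = 10, resolution = 0.8))
  det <- detectRidge(gen$mesh)
  expect_length(det@gapSpan, 2)
  span <- (det@gapSpan[2] - det@gapSpan[1]) %% (2 * pi)
  mid <- det@gapSpan[1] + span / 2
  rloc <- namplate:::.ellipseRadiusAt(det@ellipse, mid)
  expect_equal(span * rloc, 10, tolerance = 2 / 10)
  expect_equal(gapChordWidth(det), 10, tolerance = 2 / 10)
})

test_that("detection JSON round trip is lossless", {
  det <- fixtureDetection()
  f <- tempfile(fileext = ".json")
  writeDetection(det, f)
  det2 <- readDetection(f)
  expect_equal(det2@ellipse@a, det@ellipse@a)
  expect_equal(det2@frame@axes, det@frame@axes)
  expect_equal(det2@gapSpan, det@gapSpan)
  expect_equal(length(det2@crests), length(det@crests))
  expect_equal(det2@crests[[1]]@points, det@crests[[1]]@points)
})

test_that("gap presence tracks cleft width on a small cohort", {
  for (cw in c(0, 3, 6)) {
    gen <- generateCleftMaxilla(anatomyParams(cleftWidth = cw,
                                              resolution = 0.8, seed = cw))
    det <- detectRidge(gen$mesh)
    if (cw == 0) expect_length(det@gapSpan, 0)
    else expect_length(det@gapSpan, 2)
  }
})
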