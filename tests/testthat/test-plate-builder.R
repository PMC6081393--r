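# Bridging, shell construction, pin/hole booleans and smoothing.

test_that("bridge regions are non-empty, disjoint and deterministic", {
  gen <- fixtureMaxilla()
  det <- fixtureDetection()
  r1 <- selectBridgeRegions(gen$mesh, det)
  expect_gt(length(r1@greaterFaces), 0)
  expect_gt(length(r1@smallerFaces), 0)
  expect_length(intersect(r1@greaterFaces, r1@smallerFaces), 0)
  r2 <- selectBridgeRegions(gen$mesh, det)
  expect_identical(r1@greaterFaces, r2@greaterFaces)
  expect_identical(r1@smallerFaces, r2@smallerFaces)
  # regions sit on opposite sides of the gap
  ep <- gapEndpoints(det)
  cg <- colMeans(meshVertices(gen$mesh)[unique(as.vector(
    meshFaces(gen$mesh)[r1@greaterFaces, ])), , drop = FALSE])
  cs <- colMeans(meshVertices(gen$mesh)[unique(as.vector(
    meshFaces(gen$mesh)[r1@smallerFaces, ])), , drop = FALSE])
  expect_lt(sum((cg - ep[1, ])^2), sum((cg - ep[2, ])^2))
  expect_lt(sum((cs - ep[2, ])^2), sum((cs - ep[1, ])^2))

  # seeds at the ground-truth cleft margins produce regions containing them
  f <- meshFaces(gen$mesh); v <- meshVertices(gen$mesh)
  cent <- (v[f[, 1], ] + v[f[, 2], ] + v[f[, 3], ]) / 3
  lm <- gen$truth@landmarks
  sG <- which.min(rowSums(sweep(cent, 2, landmarkPoint(lm, "SA"))^2))
  sS <- which.min(rowSums(sweep(cent, 2, landmarkPoint(lm, "SAp"))^2))
  rs <- selectBridgeRegions(gen$mesh, det, seeds = c(sG, sS))
  expect_true(sG %in% rs@greaterFaces)
  expect_true(sS %in% rs@smallerFaces)
  expect_error(selectBridgeRegions(gen$mesh, det, seeds = c(sS, sG)),
               "wrong side")

  gen0 <- generateCleftMaxilla(anatomyParams(cleftWidth = 0, resolution = 0.8))
  det0 <- detectRidge(gen0$mesh)
  expect_error(selectBridgeRegions(gen0$mesh, det0), "gap")
})

test_that("bridging closes the gap along the ellipse without touching the rest", {
  gen <- fixtureMaxilla()
  det <- fixtureDetection()
  m <- gen$mesh
  br <- bridgeGap(m, det)
  expect_true(validateMesh(br)@isWatertight)
  expect_gt(meshVolume(br), meshVolume(m))
  # untouched vertices are bit-identical
  moved <- rowSums(meshVertices(br) != meshVertices(m)) > 0
  expect_gt(sum(!moved), 0.8 * nrow(meshVertices(m)))
  expect_identical(meshVertices(br)[!moved, ], meshVertices(m)[!moved, ])
  # the bridge spine follows the ellipse arc: the highest bridged points
  # over the gap interval lie within 0.5 mm of the arc (in plane)
  pol <- namplate:::.archPolar(meshVertices(br), det)
  span <- (det@gapSpan[2] - det@gapSpan[1]) %% (2 * pi)
  lam <- ((pol$theta - det@gapSpan[1]) %% (2 * pi)) / span
  inGap <- lam > 0.15 & lam < 0.85
  spine <- vapply(split(seq_along(lam)[inGap],
                        cut(lam[inGap], breaks = 8)), function(ix)
    ix[which.max(pol$w[ix])], integer(1))
  d <- pointToEllipseDistance(pol$uv[spine, , drop = FALSE], det@ellipse)
  expect_lt(max(d), 0.5)

  # no cleft: identity
  gen0 <- generateCleftMaxilla(anatomyParams(cleftWidth = 0, resolution = 0.8))
  det0 <- detectRidge(gen0$mesh)
  expect_identical(bridgeGap(gen0$mesh, det0), gen0$mesh)
})

test_that("plate shell is watertight with faithful intaglio and full wall", {
  fx <- fixturePlate()
  pl <- fx$plate
  r <- validateMesh(pl)
  expect_true(r@isWatertight)
  expect_true(r@isManifold)
  expect_gt(r@volume, 0)
  nv <- pl@metadata$shell$nv
  v <- meshVertices(pl)
  # intaglio equals the anatomy surface region
  expect_lt(max(pointMeshDistance(v[seq_len(nv), ], fx$bridged)), 0.05)
  # wall thickness along the offset equals the configured thickness
  wall <- sqrt(rowSums((v[nv + seq_len(nv), ] - v[seq_len(nv), ])^2))
  expect_gte(min(wall), 0.8 * 2.0 - 1e-9)
  expect_equal(max(wall), 2.0, tolerance = 1e-9)
})

test_that("spherical-cap shell volume matches the closed form within 2%", {
  R <- 20; alpha <- pi / 4; t <- 2
  cap <- meshIcosphere(radius = R, refine = 5)
  v <- meshVertices(cap); f <- meshFaces(cap)
  keep <- which(v[f[, 1], 3] > R * cos(alpha) &
                  v[f[, 2], 3] > R * cos(alpha) &
                  v[f[, 3], 3] > R * cos(alpha))
  shell <- offsetShell(cap, keep, thickness = t)
  expect_true(validateMesh(shell)@isWatertight)
  # radial offset of on-sphere vertices is a similarity with factor
  # s = (R+t)/R, so the exact shell volume is (s^3 - 1) times the cone
  # volume from the sphere center over the retained region
  a <- v[f[keep, 1], ]; b <- v[f[keep, 2], ]; cc <- v[f[keep, 3], ]
  coneVol <- sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) +
                 a[, 2] * (b[, 3] * cc[, 1] - b[, 1] * cc[, 3]) +
                 a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
  analytic <- coneVol * (((R + t) / R)^3 - 1)
  expect_equal(meshVolume(shell), analytic, tolerance = 0.02)
  # and the discrete region closely matches the nominal spherical cap
  capVol <- function(r) 2 * pi / 3 * r^3 * (1 - cos(alpha))
  expect_equal(meshVolume(shell), capVol(R + t) - capVol(R), tolerance = 0.06)
})

test_that("offset collapse on too-tight curvature is reported", {
  # an egg-crate surface whose feature scale is far below the thickness
  n <- 60
  g <- expand.grid(x = seq(-5, 5, length.out = n), y = seq(0, 10, length.out = n))
  v <- cbind(g$x, g$y, 1.5 * sin(4 * g$x) * sin(4 * g$y))
  f <- do.call(rbind, lapply(seq_len(n - 1), function(j)
    do.call(rbind, lapply(seq_len(n - 1), function(i) {
      a <- (j - 1) * n + i; b <- a + 1; c2 <- a + n + 1; d <- a + n
      rbind(c(a, b, c2), c(a, c2, d))
    }))))
  surf <- triangleMesh(v, f)
  expect_error(offsetShell(surf, seq_len(nrow(f)), thickness = 5),
               "offset collapse")
})

test_that("ventilation hole changes genus by one with prism-exact volume", {
  fx <- fixturePlate()
  sp <- plateSpec(holeRadius = 1.5, voxelPitch = 0.3)
  ho <- addVentilationHole(fx$plate, sp)
  rh <- validateMesh(ho)
  expect_true(rh@isWatertight)
  expect_true(rh@isManifold)
  expect_equal(meshGenus(ho), meshGenus(fx$plate) + 1L)
  expect_equal(eulerCharacteristic(ho), eulerCharacteristic(fx$plate) - 2L)
  dV <- validateMesh(fx$plate)@volume - rh@volume
  expect_equal(dV, pi * 1.5^2 * 2.0, tolerance = 0.10)
  # off-plate hole
  spBad <- plateSpec(holeArc = pi, holeInset = 3)
  expect_error(addVentilationHole(fx$plate, spBad), "placement")
})

test_that("retention pin union is watertight with bounded volume gain", {
  fx <- fixturePlate()
  sp <- plateSpec(voxelPitch = 0.3)
  pinned <- addRetentionPin(fx$plate, sp)
  r <- validateMesh(pinned)
  expect_true(r@isWatertight)
  expect_true(r@isManifold)
  vCyl <- pi * sp@pinRadius^2 * sp@pinLength
  dV <- r@volume - validateMesh(fx$plate)@volume
  expect_gt(dV, 0)
  expect_lt(dV, vCyl)
  # voxel-volume oracle agrees with the tetrahedron sum on the union
  expect_equal(voxelVolume(pinned, pitch = 0.3), r@volume, tolerance = 0.02)

  # fully embedded pin: identity
  spTiny <- plateSpec(pinRadius = 0.3, pinLength = 1.2, pinElevation = 90,
                      voxelPitch = 0.3)
  expect_identical(addRetentionPin(fx$plate, spTiny), fx$plate)
})

test_that("Taubin smoothing reduces roughness at near-constant volume", {
  fx <- fixturePlate()
  sp <- plateSpec(smoothingIterations = 20, voxelPitch = 0.3)
  # roughen the outer surface
  pl <- fx$plate
  nv <- pl@metadata$shell$nv
  v <- meshVertices(pl)
  set.seed(3)
  v[nv + seq_len(nv), ] <- v[nv + seq_len(nv), ] +
    matrix(rnorm(3 * nv, 0, 0.02), ncol = 3)
  rough <- triangleMesh(v, meshFaces(pl), metadata = pl@metadata)
  roughness <- function(m) {
    fn <- faceNormals(m)
    adj <- namplate:::.faceAdjacency(m)
    devs <- unlist(lapply(seq_along(adj), function(i)
      1 - fn[adj[[i]], , drop = FALSE] %*% fn[i, ]))
    sqrt(mean(devs^2))
  }
  sm <- smoothPlate(rough, sp)
  expect_lt(roughness(sm), roughness(rough))
  expect_lt(abs(meshVolume(sm) - meshVolume(rough)) / meshVolume(rough), 0.01)
  # zero iterations: identity
  sp0 <- plateSpec(smoothingIterations = 0)
  expect_identical(smoothPlate(rough, sp0), rough)
  # intaglio clamp holds
  dmove <- sqrt(rowSums((meshVertices(sm)[seq_len(nv), ] -
                           v[seq_len(nv), ])^2))
  expect_lte(max(dmove), 0.05 + 1e-9)
})

test_that("plate fits the next-month anatomy it was built against", {
  gen <- fixtureMaxilla()
  det <- fixtureDetection()
  grown <- warpToEllipse(gen$mesh, det, 1.02)
  detG <- detectRidge(grown)
  brG <- bridgeGap(grown, detG)
  plG <- buildPlate(brG, detG, plateSpec(voxelPitch = 0.3))
  nv <- plG@metadata$shell$nv
  intag <- meshVertices(plG)[seq_len(nv), ]
  # intaglio touches but does not penetrate the grown anatomy
  inside <- pointsInsideMesh(intag, brG)
  pen <- pointMeshDistance(intag[inside, , drop = FALSE], brG)
  expect_lt(max(c(0, pen)), 0.05)
})
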