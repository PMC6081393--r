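# Synthetic cleft-maxilla generator and its ground truth.

test_that("default synthetic maxilla is watertight, single component", {
  gen <- fixtureMaxilla()
  r <- validateMesh(gen$mesh)
  expect_true(r@isWatertight)
  expect_true(r@isManifold)
  expect_equal(r@nComponents, 1L)
  expect_gt(r@volume, 0)
})

test_that("ground-truth crest points are mesh vertices and distances sane", {
  gen <- fixtureMaxilla()
  crest <- do.call(rbind, gen$truth@crest)
  expect_lt(max(pointMeshDistance(crest, gen$mesh)), 1e-6)
  d <- computeDistances(gen$truth@landmarks)
  expect_true(all(d > 0))
  # MT is the exact midpoint of T-Tp
  lm <- gen$truth@landmarks
  mt <- landmarkMT(lm)
  expect_equal(sqrt(sum((landmarkPoint(lm, "T") - mt)^2)),
               sqrt(sum((landmarkPoint(lm, "Tp") - mt)^2)))
})

test_that("default dimensions land inside the neonatal reference ranges", {
  # printed first-impression min-max ranges of the reference cohort
  gen <- generateCleftMaxilla(anatomyParams(resolution = 0.5))
  d <- computeDistances(gen$truth@landmarks)
  expect_gt(d$d_A_MT, 25.5);  expect_lt(d$d_A_MT, 34.1)
  expect_gt(d$d_L_Lp, 27.5);  expect_lt(d$d_L_Lp, 34.3)
  expect_gt(d$d_SA_SAp, 5.2); expect_lt(d$d_SA_SAp, 19.8)
  expect_gt(d$d_T_Tp, 32.3);  expect_lt(d$d_T_Tp, 36.4)
  expect_gt(d$d_SD_SDp, 11.7); expect_lt(d$d_SD_SDp, 27.4)
})

test_that("cleft width is honored and zero width degenerates cleanly", {
  p10 <- anatomyParams(cleftWidth = 10, resolution = 0.8)
  gen <- generateCleftMaxilla(p10)
  d <- computeDistances(gen$truth@landmarks)
  expect_equal(d$d_SA_SAp, 10, tolerance = 0.8 / 10)
  # measured on the output mesh: nearest surface points at SA/SAp coincide
  lm <- gen$truth@landmarks
  expect_lt(max(pointMeshDistance(rbind(landmarkPoint(lm, "SA"),
                                        landmarkPoint(lm, "SAp")),
                                  gen$mesh)), 0.8)

  gen0 <- generateCleftMaxilla(anatomyParams(cleftWidth = 0, resolution = 0.8))
  expect_identical(landmarkPoint(gen0$truth@landmarks, "SA"),
                   landmarkPoint(gen0$truth@landmarks, "SAp"))
  expect_length(gen0$truth@crest, 1)
  expect_true(validateMesh(gen0$mesh)@isWatertight)
})

test_that("cleft span exceeding the arch extent is a parameter error", {
  expect_error(generateCleftMaxilla(anatomyParams(cleftWidth = 45,
                                                  cleftAngle = 80)),
               "arch extent")
})

test_that("generation is deterministic by seed", {
  p <- anatomyParams(resolution = 1.2, noiseSigma = 0.3, seed = 7)
  g1 <- generateCleftMaxilla(p)
  g2 <- generateCleftMaxilla(p)
  expect_identical(meshVertices(g1$mesh), meshVertices(g2$mesh))
  p2 <- p; p2@seed <- 8
  g3 <- generateCleftMaxilla(p2)
  expect_false(identical(meshVertices(g1$mesh), meshVertices(g3$mesh)))
})

test_that("growAnatomy follows the compound growth law", {
  p <- anatomyParams()
  expect_identical(growAnatomy(p, 5, 0), p)
  g <- growAnatomy(p, 5, 0.02)
  expect_equal(g@ellipseA / p@ellipseA, 1.02^5, tolerance = 1e-12)
  expect_equal(g@ellipseB / p@ellipseB, 1.02^5, tolerance = 1e-12)
  # chained monthly application equals the single application
  chain <- p
  for (i in 1:5) chain <- growAnatomy(chain, 1, 0.02)
  expect_equal(chain@ellipseA, g@ellipseA, tolerance = 1e-12)
})

test_that("cohorts are reproducible and degenerate cases collapse", {
  cp <- cohortParams(nSubjects = 3, sd = c(ellipseA = 0, ellipseB = 0,
                                           cleftWidth = 0),
                     growthMean = 0, growthSD = 0, cleftReduction = 0,
                     resolution = 1.5, seed = 11)
  co <- generateCohort(cp)
  expect_length(co, 3)
  d1 <- computeDistances(co[[1]]$pre$truth@landmarks)
  for (s in co) {
    expect_identical(computeDistances(s$pre$truth@landmarks), d1)
    dd <- unlist(computeDistances(s$post$truth@landmarks)) -
      unlist(computeDistances(s$pre$truth@landmarks))
    expect_equal(unname(dd), rep(0, 7))
  }
  co2 <- generateCohort(cp)
  expect_identical(meshVertices(co2[[2]]$pre$mesh),
                   meshVertices(co[[2]]$pre$mesh))
  cp2 <- cohortParams(nSubjects = 3, seed = 12, resolution = 1.5)
  co3 <- generateCohort(cp2)
  expect_false(identical(meshVertices(co3[[1]]$pre$mesh),
                         meshVertices(co[[1]]$pre$mesh)))
})

test_that("built-in cleft reduction is recovered from ground truth", {
  cp <- cohortParams(nSubjects = 5, cleftReduction = 6, resolution = 1.2,
                     seed = 3)
  co <- generateCohort(cp)
  pre <- vapply(co, function(s) computeDistances(s$pre$truth@landmarks)$d_SA_SAp,
                numeric(1))
  post <- vapply(co, function(s) computeDistances(s$post$truth@landmarks)$d_SA_SAp,
                 numeric(1))
  ch <- pairedChange(pre, post)
  expect_equal(ch$summary$mean, -6, tolerance = 1.2 / 6)
})

test_that("cohort sample means match the configured distributions", {
  cp <- cohortParams(nSubjects = 100, resolution = 2.5, seed = 5)
  co <- generateCohort(cp)
  for (pn in c("ellipseA", "ellipseB", "cleftWidth")) {
    draws <- vapply(co, function(s) slot(s$preParams, pn), numeric(1))
    se <- cp$sd[[pn]] / sqrt(100)
    expect_lt(abs(mean(draws) - cp$mean[[pn]]), 2 * se)
  }
})
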