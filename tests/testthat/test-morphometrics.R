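# Landmark distances, cohort summaries and exact Wilcoxon tests.

.lmFrom <- function(overrides) {
  base <- list(A = c(0, 30, 0), P = c(0, 24, 0), SA = c(-4, 26, 0),
               SAp = c(5, 25, 0), L = c(-14, 15, 0), Lp = c(14, 15, 0),
               T = c(-17, 0, 0), Tp = c(17, 0, 0), SD = c(-5, 12, -2),
               SDp = c(9, 12, -2))
  base[names(overrides)] <- overrides
  landmarkSet(base)
}

test_that("the seven distances follow from closed forms", {
  lm <- .lmFrom(list())
  d <- computeDistances(lm)
  expect_equal(d$d_A_MT, 30)     # MT = midpoint(T, Tp) = origin
  expect_equal(d$d_T_Tp, 34)
  expect_equal(d$d_L_Lp, 28)
  expect_equal(d$d_A_P, 6)
  expect_equal(d$d_SA_SAp, sqrt(81 + 1))
  nms <- c("A", "P", "SA", "SAp", "L", "Lp", "T", "Tp", "SD", "SDp")
  lm0 <- landmarkSet(lapply(setNames(vector("list", 10), nms),
                            function(x) c(1, 2, 3)))
  expect_equal(unname(unlist(computeDistances(lm0))), rep(0, 7))
})

test_that("landmark sets validate their names and completeness", {
  expect_error(landmarkSet(list(A = c(0, 0, 0))), "missing landmark")
  pts <- .lmFrom(list())@points
  rownames(pts)[1] <- "XX"
  expect_error(landmarkSet(pts), "unknown landmark")
})

test_that("summaries use type-7 quartiles and sample sd", {
  s <- summarizeDistances(c(5, 5, 5, 5))
  expect_equal(unname(unlist(s)), c(5, 5, 5, 5, 5, 5, 0))
  s2 <- summarizeDistances(1:5)
  expect_equal(s2$q1, 2); expect_equal(s2$median, 3)
  expect_equal(s2$q3, 4); expect_equal(s2$mean, 3)
  set.seed(9)
  x <- rnorm(7, 20, 4)
  s3 <- summarizeDistances(x)
  # sort-and-interpolate oracle for type-7 quartiles
  xs <- sort(x)
  q7 <- function(p) { h <- (7 - 1) * p + 1
    xs[floor(h)] + (h - floor(h)) * (xs[ceiling(h)] - xs[floor(h)]) }
  expect_equal(s3$q1, q7(0.25), tolerance = 1e-12)
  expect_equal(s3$median, q7(0.5), tolerance = 1e-12)
  expect_equal(s3$q3, q7(0.75), tolerance = 1e-12)
  expect_equal(s3$sd, sqrt(sum((x - mean(x))^2) / 6), tolerance = 1e-12)
  expect_error(summarizeDistances(numeric(0)), "at least one")
  expect_equal(unname(formatSummaryRow(s2)["mean"]), "3.0")
})

test_that("paired changes are elementwise with exact mean identity", {
  ch <- pairedChange(c(10, 12), c(7, 9))
  expect_equal(ch$differences, c(-3, -3))
  expect_equal(ch$summary$mean, -3)
  set.seed(4)
  pre <- rnorm(11); post <- rnorm(11)
  ch2 <- pairedChange(pre, post)
  expect_equal(ch2$summary$mean, mean(post) - mean(pre), tolerance = 1e-12)
  expect_error(pairedChange(1:3, 1:4), "equal length")
})

test_that("exact signed-rank p equals full enumeration", {
  # canonical cases
  expect_equal(wilcoxonSignedRank(c(0), c(1))$pExact, 1.0)
  r6 <- wilcoxonSignedRank(rep(0, 6), 1:6)
  expect_equal(r6$pExact, 2 / 64)
  expect_equal(r6$W, 21)
  # seeded random cases, including ties and zeros, n <= 10
  set.seed(31)
  for (rep in 1:12) {
    n <- sample(3:10, 1)
    pre <- round(rnorm(n, 20, 3), 1)
    post <- round(pre + rnorm(n, -1, 2), 1)
    if (all(post == pre)) post[1] <- pre[1] + 0.5
    res <- wilcoxonSignedRank(pre, post)
    expect_equal(res$pExact, signedRankEnumeration(pre, post),
                 tolerance = 1e-12)
    # asymptotic p is a sane approximation
    expect_gte(res$pAsymptotic, 0); expect_lte(res$pAsymptotic, 1)
  }
  expect_error(wilcoxonSignedRank(1:4, 1:4), "degenerate")
  expect_error(wilcoxonSignedRank(rep(0, 30), rnorm(30), mode = "exact"),
               "n <= 25")
})

test_that("signed-rank p is invariant to pair order and sign flips", {
  set.seed(12)
  pre <- rnorm(8); post <- pre + rnorm(8)
  p0 <- wilcoxonSignedRank(pre, post)$pExact
  for (i in 1:5) {
    o <- sample(8)
    expect_equal(wilcoxonSignedRank(pre[o], post[o])$pExact, p0)
  }
  expect_equal(wilcoxonSignedRank(post, pre)$pExact, p0)
})

test_that("Pratt zero handling is available and recorded", {
  pre <- c(1, 2, 3, 4, 5)
  post <- c(1, 4, 5, 3, 8)
  rEx <- wilcoxonSignedRank(pre, post, zeroHandling = "exclude")
  rPr <- wilcoxonSignedRank(pre, post, zeroHandling = "pratt")
  expect_match(rEx$methodNote, "excluded")
  expect_match(rPr$methodNote, "Pratt")
  expect_equal(rEx$n, 4); expect_equal(rPr$n, 4)
})

test_that("exact rank-sum p equals full enumeration", {
  expect_equal(wilcoxonRankSumExact(c(1, 2), c(3, 4))$pExact, 2 / 6,
               tolerance = 1e-12)
  expect_equal(wilcoxonRankSumExact(c(1, 2, 3), c(1, 2, 3))$pExact, 1.0)
  set.seed(8)
  for (rep in 1:10) {
    n1 <- sample(2:7, 1); n2 <- sample(2:7, 1)
    g1 <- round(rnorm(n1, 10, 3), 1); g2 <- round(rnorm(n2, 12, 3), 1)
    expect_equal(wilcoxonRankSumExact(g1, g2)$pExact,
                 rankSumEnumeration(g1, g2), tolerance = 1e-12)
  }
  expect_error(wilcoxonRankSumExact(rnorm(11), rnorm(10)), "n <= 20")
  expect_error(wilcoxonRankSumExact(numeric(0), 1:3), "non-empty")
})

test_that("box-plot statistics follow the 1.5 IQR rule", {
  b <- boxplotStats(1:5)
  expect_equal(c(b$q1, b$median, b$q3), c(2, 3, 4))
  expect_equal(c(b$whiskerLow, b$whiskerHigh), c(1, 5))
  bc <- boxplotStats(rep(4, 6))
  expect_equal(bc$q1, bc$q3)
  expect_length(bc$outliers, 0)
  set.seed(77)
  x <- c(rnorm(20, 10, 1), 30, -15)
  bo <- boxplotStats(x)
  s <- summarizeDistances(x); iqr <- s$q3 - s$q1
  expect_setequal(bo$outliers, x[x < s$q1 - 1.5 * iqr | x > s$q3 + 1.5 * iqr])
  inside <- x[x >= s$q1 - 1.5 * iqr & x <= s$q3 + 1.5 * iqr]
  expect_equal(bo$whiskerLow, min(inside))
  expect_equal(bo$whiskerHigh, max(inside))
})

test_that("null cohorts at n = 7 keep type-I behaviour", {
  # zero true change measured by two observers with placement noise:
  # distances of the same anatomy re-measured with jittered landmarks
  gen <- fixtureMaxilla()
  base <- gen$truth@landmarks@points
  set.seed(2024)
  pvals <- replicate(100, {
    meas <- function() {
      vapply(1:7, function(s) {
        lm <- landmarkSet(base + matrix(rnorm(30, 0, 0.3), 10, 3))
        computeDistances(lm)$d_SA_SAp
      }, numeric(1))
    }
    wilcoxonSignedRank(meas(), meas())$pExact
  })
  expect_gte(mean(pvals >= 0.05), 0.90)
})

test_that("cohort reports assemble summaries and tests per distance", {
  set.seed(5)
  pre <- as.data.frame(matrix(rnorm(7 * 7, 20, 3), 7, 7))
  names(pre) <- names(distanceLabels())
  post <- pre - 2 + matrix(rnorm(49, 0, 0.5), 7, 7)
  rep <- cohortReport(pre, post)
  expect_equal(nrow(rep$summaries), 21)
  expect_equal(nrow(rep$tests), 7)
  sa <- rep$summaries[rep$summaries$distance == "SA - SA'" &
                        rep$summaries$row == "difference", ]
  expect_equal(sa$mean, mean(post$d_SA_SAp - pre$d_SA_SAp))
  expect_true(all(rep$tests$pExact <= 1 & rep$tests$pExact >= 0))
})
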