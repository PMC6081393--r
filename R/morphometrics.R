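# Landmark morphometrics: the seven inter-landmark distances, cohort
# summaries, paired changes and exact Wilcoxon tests.

#' Construct a LandmarkSet
#'
#' @param points named list or matrix of 3D points; must contain exactly
#'   the ten stored landmarks A, P, SA, SAp, L, Lp, T, Tp, SD, SDp
#' @return a \linkS4class{LandmarkSet}
#' @export
landmarkSet <- function(points) {
  nm <- landmarkNames()
  if (is.matrix(points)) {
    pts <- points
  } else {
    missing <- setdiff(nm, names(points))
    if (length(missing))
      stop("missing landmark(s): ", paste(missing, collapse = ", "))
    pts <- do.call(rbind, points[nm])
  }
  extra <- setdiff(rownames(pts), nm)
  if (length(extra))
    stop("unknown landmark name(s): ", paste(extra, collapse = ", "))
  pts <- pts[nm, , drop = FALSE]
  new("LandmarkSet", points = matrix(as.numeric(pts), ncol = 3,
                                     dimnames = list(nm, c("x", "y", "z"))))
}

#' Derived landmark MT
#'
#' MT is the dissecting point on the connecting line between the tuberal
#' areas: exactly the midpoint of T and Tp.  It is always derived, never
#' stored.
#' @param lm a \linkS4class{LandmarkSet}
#' @return length-3 point (mm)
#' @export
landmarkMT <- function(lm) {
  (lm@points["T", ] + lm@points["Tp", ]) / 2
}

#' Access one landmark
#' @param lm a \linkS4class{LandmarkSet}
#' @param name landmark name (one of the ten stored names, or "MT")
#' @return length-3 point (mm)
#' @export
landmarkPoint <- function(lm, name) {
  if (name == "MT") return(landmarkMT(lm))
  if (!name %in% landmarkNames()) stop("unknown landmark: ", name)
  lm@points[name, ]
}

.distancePairs <- function() {
  list(d_A_MT = c("A", "MT"), d_L_Lp = c("L", "Lp"),
       d_SA_SAp = c("SA", "SAp"), d_T_Tp = c("T", "Tp"),
       d_SD_SDp = c("SD", "SDp"), d_A_P = c("A", "P"),
       d_SA_SD = c("SA", "SD"))
}

#' Distance labels as printed in cohort reports
#' @return named character vector mapping internal column names to labels
#' @export
distanceLabels <- function() {
  c(d_A_MT = "A - MT", d_L_Lp = "L - L'", d_SA_SAp = "SA - SA'",
    d_T_Tp = "T - T'", d_SD_SDp = "SD - SD'", d_A_P = "A - P",
    d_SA_SD = "SA - SD")
}

#' Compute the seven inter-landmark distances
#'
#' Euclidean 3D distances for the pairs A-MT, L-L', SA-SA', T-T', SD-SD',
#' A-P and SA-SD; MT is derived first as midpoint(T, Tp).
#'
#' @param lm a \linkS4class{LandmarkSet}
#' @return one-row data.frame with columns d_A_MT, d_L_Lp, d_SA_SAp,
#'   d_T_Tp, d_SD_SDp, d_A_P, d_SA_SD (mm)
#' @export
computeDistances <- function(lm) {
  stopifnot(is(lm, "LandmarkSet"))
  d <- vapply(.distancePairs(), function(pair) {
    p <- landmarkPoint(lm, pair[1]); q <- landmarkPoint(lm, pair[2])
    sqrt(sum((p - q)^2))
  }, numeric(1))
  as.data.frame(as.list(d))
}

#' Seven-column cohort summary of one distance
#'
#' Quartiles use linear interpolation of order statistics (quantile
#' type 7); sd is the sample standard deviation (n - 1 denominator).
#' Values are kept at full precision; use \code{\link{formatSummaryRow}}
#' for the printed one-decimal presentation.
#'
#' @param values numeric vector (mm), n >= 1
#' @return one-row data.frame with columns min, q1, median, mean, q3,
#'   max, sd
#' @export
summarizeDistances <- function(values) {
  if (length(values) < 1) stop("need at least one value")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  data.frame(min = min(values), q1 = q[1], median = q[2],
             mean = mean(values), q3 = q[3], max = max(values),
             sd = if (length(values) > 1) sd(values) else 0)
}

#' @rdname summarizeDistances
#' @param row a summary row from \code{summarizeDistances}
#' @param digits decimals in the printed presentation
#' @export
formatSummaryRow <- function(row, digits = 1) {
  vapply(row, function(x) formatC(round(x, digits), format = "f",
                                  digits = digits), character(1))
}

#' Paired changes between two impressions
#'
#' @param pre,post numeric vectors of equal length in paired order (mm)
#' @return list with \code{differences} (post - pre) and \code{summary}
#'   (a \code{\link{summarizeDistances}} row of the differences)
#' @export
pairedChange <- function(pre, post) {
  if (length(pre) != length(post))
    stop("pre and post must have equal length")
  d <- post - pre
  list(differences = d, summary = summarizeDistances(d))
}

# exact null distribution of 2*W (doubled midrank sum of "positive" pairs)
# via generating-function convolution over all 2^n sign assignments
.signedRankDist <- function(ranks2) {
  maxs <- sum(ranks2)
  p <- numeric(maxs + 1); p[1] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), p[seq_len(maxs + 1 - r)])
    p <- (p + shifted) / 2
  }
  p  # p[k+1] = P(2W = k)
}

#' Wilcoxon signed-rank test for paired impressions
#'
#' Zero differences are excluded by default (classical Wilcoxon; Pratt's
#' method ranks them first and then drops them).  Ties receive midranks.
#' The exact mode computes the two-sided p over the full enumeration null
#' of all 2^n sign assignments of the ranked absolute differences,
#' \eqn{p = P(|W - E[W]| \ge |w_{obs} - E[W]|)}; the asymptotic mode uses
#' the normal approximation with tie-corrected variance and continuity
#' correction.
#'
#' @param pre,post paired numeric vectors
#' @param mode "exact" (n <= 25 after zero exclusion) or "asymptotic"
#' @param zeroHandling "exclude" or "pratt"
#' @return list with n (pairs used), W (signed-rank statistic, sum of
#'   ranks of positive differences), pExact, pAsymptotic, methodNote
#' @export
wilcoxonSignedRank <- function(pre, post, mode = c("exact", "asymptotic"),
                               zeroHandling = c("exclude", "pratt")) {
  mode <- match.arg(mode); zeroHandling <- match.arg(zeroHandling)
  if (length(pre) != length(post)) stop("pre and post must have equal length")
  d <- post - pre
  nZero <- sum(d == 0)
  if (all(d == 0)) stop("degenerate data: all paired differences are zero")
  if (zeroHandling == "exclude") {
    d <- d[d != 0]
    r <- rank(abs(d))
  } else {
    r <- rank(abs(d))          # zeros ranked lowest, then dropped (Pratt)
    r <- r[d != 0]
    d <- d[d != 0]
  }
  n <- length(d)
  W <- sum(r[d > 0])
  EW <- sum(r) / 2
  pExact <- NA_real_
  if (mode == "exact") {
    if (n > 25) stop("exact mode limited to n <= 25 nonzero pairs")
    r2 <- as.integer(round(2 * r))
    dist <- .signedRankDist(r2)
    w2 <- round(2 * W); e2 <- sum(r2) / 2
    dev <- abs(w2 - e2)
    k <- 0:(length(dist) - 1)
    pExact <- sum(dist[abs(k - e2) >= dev - 1e-9])
    pExact <- min(1, pExact)
  }
  ties <- table(r)
  varW <- sum(r^2) / 4  # equals n(n+1)(2n+1)/24 without ties, midranks handled
  z <- W - EW
  cc <- min(abs(z), 0.5) * sign(z)
  zstat <- if (varW > 0) (z - cc) / sqrt(varW) else 0
  pAsym <- min(1, 2 * pnorm(-abs(zstat)))
  list(n = n, W = W, pExact = pExact, pAsymptotic = pAsym,
       methodNote = sprintf("%d zero difference(s) %s; midranks for ties",
                            nZero,
                            if (zeroHandling == "exclude") "excluded"
                            else "ranked then dropped (Pratt)"))
}

# exact distribution of the doubled rank sum of group 1 over all
# choose(N, n1) assignments: dp over (group-1 count, doubled rank sum)
.rankSumDist <- function(ranks2, n1) {
  maxs <- sum(ranks2)
  dp <- matrix(0, nrow = n1 + 1, ncol = maxs + 1)
  dp[1, 1] <- 1
  for (r in ranks2) {
    for (k in min(n1, 1e9):1) {
      nz <- which(dp[k, ] > 0)
      if (length(nz))
        dp[k + 1, nz + r] <- dp[k + 1, nz + r] + dp[k, nz]
    }
  }
  dp[n1 + 1, ] / choose(length(ranks2), n1)
}

#' Exact Wilcoxon rank-sum test (two independent groups)
#'
#' Two-sided exact p by enumeration of all rank assignments: with
#' midranks r over the pooled sample, \eqn{p = P(|W_1 - E[W_1]| \ge
#' |w_{obs} - E[W_1]|)} over all \eqn{\binom{N}{n_1}} subsets.
#'
#' @param group1,group2 numeric vectors; combined length <= 20
#' @return list with n1, n2, W (rank sum of group 1), pExact
#' @export
wilcoxonRankSumExact <- function(group1, group2) {
  n1 <- length(group1); n2 <- length(group2)
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty")
  if (n1 + n2 > 20) stop("exact mode limited to combined n <= 20")
  pooled <- c(group1, group2)
  r <- rank(pooled)
  W <- sum(r[seq_len(n1)])
  r2 <- as.integer(round(2 * r))
  dist <- .rankSumDist(r2, n1)
  e2 <- n1 * sum(r2) / (n1 + n2)
  w2 <- round(2 * W)
  k <- 0:(length(dist) - 1)
  p <- sum(dist[abs(k - e2) >= abs(w2 - e2) - 1e-9])
  list(n1 = n1, n2 = n2, W = W, pExact = min(1, p))
}

#' Box-plot statistics
#'
#' Box borders are the 1st and 3rd quartiles, the bar is the median;
#' whiskers extend to the most extreme values within 1.5 IQR of the box,
#' values beyond are listed as outliers.
#'
#' @param values numeric vector, n >= 1
#' @return list with min, q1, median, q3, max, whiskerLow, whiskerHigh,
#'   outliers; serializable to plot-ready JSON via \code{jsonlite}
#' @export
boxplotStats <- function(values) {
  if (length(values) < 1) stop("need at least one value")
  s <- summarizeDistances(values)
  iqr <- s$q3 - s$q1
  lowFence <- s$q1 - 1.5 * iqr; highFence <- s$q3 + 1.5 * iqr
  inside <- values[values >= lowFence & values <= highFence]
  list(min = s$min, q1 = s$q1, median = s$median, q3 = s$q3, max = s$max,
       whiskerLow = min(inside), whiskerHigh = max(inside),
       outliers = sort(values[values < lowFence | values > highFence]))
}

#' Cohort report for paired impressions
#'
#' Builds the per-distance seven-column summaries of impression 1,
#' impression 2 and their paired differences, plus exact signed-rank
#' p-values — the analysis layout used to evaluate molding therapy.
#'
#' @param preTable,postTable data.frames of per-subject distances (columns
#'   as in \code{\link{computeDistances}}), paired by row
#' @return list with \code{summaries} (data.frame: distance, row
#'   ("impression 1"/"impression 2"/"difference"), seven summary columns)
#'   and \code{tests} (data.frame: distance, n, W, pExact, pAsymptotic)
#' @export
cohortReport <- function(preTable, postTable) {
  stopifnot(identical(names(preTable), names(postTable)),
            nrow(preTable) == nrow(postTable))
  cols <- intersect(names(.distancePairs()), names(preTable))
  sumRows <- list(); testRows <- list()
  for (cn in cols) {
    pre <- preTable[[cn]]; post <- postTable[[cn]]
    ch <- pairedChange(pre, post)
    lab <- distanceLabels()[[cn]]
    sumRows[[length(sumRows) + 1]] <-
      cbind(distance = lab, row = "impression 1", summarizeDistances(pre))
    sumRows[[length(sumRows) + 1]] <-
      cbind(distance = lab, row = "impression 2", summarizeDistances(post))
    sumRows[[length(sumRows) + 1]] <-
      cbind(distance = lab, row = "difference", ch$summary)
    tst <- tryCatch(wilcoxonSignedRank(pre, post, mode = "exact"),
                    error = function(e) NULL)
    testRows[[length(testRows) + 1]] <- data.frame(
      distance = lab,
      n = if (is.null(tst)) NA_integer_ else tst$n,
      W = if (is.null(tst)) NA_real_ else tst$W,
      pExact = if (is.null(tst)) NA_real_ else tst$pExact,
      pAsymptotic = if (is.null(tst)) NA_real_ else tst$pAsymptotic)
  }
  list(summaries = do.call(rbind, sumRows), tests = do.call(rbind, testRows))
}
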