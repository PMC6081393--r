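# Automatic detection of the edentulous alveolar crest and the arch
# ellipse.  The detector is deliberately self-contained: polar max-height
# profiles about the arch centroid, followed by a direct least-squares
# ellipse fit with geometric residuals.  The detection result is a
# serializable contract: a user confirms or corrects it by editing the
# JSON and re-running downstream stages.

#' Estimate the occlusal reference frame of a cast
#'
#' The occlusal normal w is the least-variance principal direction of the
#' vertex positions.  Its sign is fixed by the cast's planar cut base:
#' the dominant cluster of coplanar outward face normals (the scanned
#' cast's flat underside) is oriented to -w, which puts the alveolar
#' crest at larger w than the palatal vault.  The in-plane axes u, v
#' complete a right-handed orthonormal triple.
#'
#' @param mesh a non-empty TriangleMesh
#' @return an \linkS4class{OcclusalFrame}
#' @export
computeOcclusalFrame <- function(mesh) {
  v <- mesh@vertices
  if (nrow(v) < 3) stop("mesh too small for frame estimation")
  pc <- prcomp(v, center = TRUE, scale. = FALSE)
  if (pc$sdev[2] < 1e-9 * max(pc$sdev[1], 1))
    stop("degenerate (collinear) geometry: occlusal frame undefined")
  w <- pc$rotation[, 3]
  fa <- .faceNormalsArea(mesh)
  dots <- as.vector(fa$normals %*% w)
  aPlus <- sum(fa$area[dots > 0.95])
  aMinus <- sum(fa$area[dots < -0.95])
  if (aPlus > aMinus) { w <- -w; dots <- -dots }
  else if (aPlus == aMinus && w[which.max(abs(w))] < 0) { w <- -w; dots <- -dots }
  # refine against the cast's planar cut base: the dominant coplanar
  # normal cluster opposite the crest defines the support plane exactly
  base <- dots < -0.95
  if (sum(fa$area[base]) > 0.15 * sum(fa$area)) {
    nb <- colSums(fa$normals[base, , drop = FALSE] * fa$area[base])
    nb <- nb / sqrt(sum(nb^2))
    w <- -nb
  }
  u <- pc$rotation[, 1]
  u <- u - sum(u * w) * w
  u <- u / sqrt(sum(u^2))
  # deterministic sign for u: positive third moment of projections
  pu <- as.vector(sweep(v, 2, colMeans(v)) %*% u)
  m3 <- sum(pu^3)
  if (m3 < 0 || (m3 == 0 && u[which.max(abs(u))] < 0)) u <- -u
  vv <- c(w[2] * u[3] - w[3] * u[2],
          w[3] * u[1] - w[1] * u[3],
          w[1] * u[2] - w[2] * u[1])
  new("OcclusalFrame", origin = colMeans(v),
      axes = cbind(u = u, v = vv, w = w))
}

# project vertices into frame coordinates (columns u, v, w)
.frameCoords <- function(points, frame) {
  sweep(points, 2, frame@origin) %*% frame@axes
}

#' Extract the alveolar crest as polar max-height profiles
#'
#' Vertices above a height threshold (a fixed fraction of the vertical
#' extent) are binned by angle about their in-plane centroid; in each
#' angular bin the crest point is the candidate with the largest
#' w-coordinate within the radial band (ties broken by smaller radius,
#' then lower vertex index).  Runs of empty bins split the crest into
#' segments; runs shorter than \code{minGapBins} are ignored as noise.
#' Each segment is smoothed with a 3-point moving average.
#'
#' @param mesh a TriangleMesh
#' @param frame an \linkS4class{OcclusalFrame}
#' @param nBins number of angular bins (>= 36)
#' @param heightFrac crest height threshold as a fraction of the P10-P98
#'   vertical extent
#' @param minGapBins minimum empty-bin run treated as a real gap
#' @return list of \linkS4class{CrestCurve} (1 = continuous arch,
#'   2 = cleft arch), ordered greater segment first
#' @export
extractCrest <- function(mesh, frame, nBins = 180L, heightFrac = 0.55,
                         minGapBins = 3L) {
  if (nBins < 36) stop("nBins must be >= 36")
  q <- .frameCoords(mesh@vertices, frame)
  w <- q[, 3]
  qs <- quantile(w, c(0.10, 0.98), names = FALSE)
  th <- qs[1] + heightFrac * (qs[2] - qs[1])
  cand <- which(w >= th)
  if (length(cand) < 2) stop("crest detection failure: fewer than 2 candidates")
  cuv <- colMeans(q[cand, 1:2, drop = FALSE])
  du <- q[cand, 1] - cuv[1]; dv <- q[cand, 2] - cuv[2]
  ang <- atan2(dv, du)
  rad <- sqrt(du^2 + dv^2)
  medr <- median(rad)
  band <- rad >= 0.35 * medr & rad <= 1.8 * medr
  cand <- cand[band]; ang <- ang[band]; rad <- rad[band]
  if (length(cand) < 2) stop("crest detection failure: empty radial band")
  bin <- pmin(nBins - 1L, floor((ang + pi) / (2 * pi) * nBins))
  best <- rep(NA_integer_, nBins)
  for (k in sort(unique(bin))) {
    sel <- which(bin == k)
    o <- order(-w[cand[sel]], rad[sel], cand[sel])
    best[k + 1L] <- sel[o[1]]
  }
  # drop off-crest bins (taper at the arch ends, cleft-margin ramps):
  # a crest point must reach near the typical crest height
  occ0 <- !is.na(best)
  crestHts <- w[cand[best[occ0]]]
  medw <- median(crestHts)
  tol <- max(0.5, 6 * stats::mad(crestHts))
  low <- which(occ0)[crestHts < medw - tol]
  best[low] <- NA_integer_
  occupied <- !is.na(best)
  if (sum(occupied) < 2) stop("crest detection failure: fewer than 2 populated bins")
  # circular runs of empty bins; ignore runs shorter than minGapBins
  occ <- occupied
  r <- rle(occ)
  if (length(r$lengths) > 1 && r$values[1] == r$values[length(r$values)]) {
    # merge circular wrap for run analysis via rotation to a boundary
    start <- which(diff(c(occ[nBins], occ)) != 0)[1]
    if (is.na(start)) start <- 1L
  } else start <- 1L
  rot <- function(x, s) if (s == 1) x else c(x[s:nBins], x[1:(s - 1)])
  occR <- rot(occ, start)
  idxR <- rot(seq_len(nBins), start)
  rr <- rle(occR)
  ends <- cumsum(rr$lengths); begins <- ends - rr$lengths + 1
  # segments = occupied bins between real gaps; empty runs shorter than
  # minGapBins do not split (sampling noise)
  realGap <- !rr$values & rr$lengths >= minGapBins
  segId <- cumsum(realGap)
  curSeg <- list()
  for (j in seq_along(rr$lengths)) {
    if (realGap[j]) next
    bins <- idxR[begins[j]:ends[j]]
    bins <- bins[occ[bins]]
    if (!length(bins)) next
    key <- as.character(segId[j])
    curSeg[[key]] <- c(curSeg[[key]], bins)
  }
  # circular closure: if no real gap at the rotation boundary, first and
  # last groups are the same segment
  if (length(curSeg) > 1 && !realGap[1] && !realGap[length(rr$lengths)] &&
      segId[length(rr$lengths)] != segId[1]) {
    ks <- names(curSeg)
    curSeg[[ks[1]]] <- c(curSeg[[ks[length(ks)]]], curSeg[[ks[1]]])
    curSeg[[ks[length(ks)]]] <- NULL
  }
  segs <- Filter(function(s) length(s) >= 3, curSeg)
  if (!length(segs)) stop("crest detection failure: no crest segment")
  # keep at most the two longest segments
  if (length(segs) > 2) {
    lens <- vapply(segs, length, integer(1))
    segs <- segs[order(-lens)[1:2]]
  }
  binCenter <- function(k) -pi + (k - 0.5) * 2 * pi / nBins
  mkCurve <- function(bins, label) {
    # unwrap bin angles monotonically
    th <- binCenter(bins)
    th <- th[1] + cumsum(c(0, (diff(th) + pi) %% (2 * pi) - pi))
    o <- order(th)
    th <- th[o]; bins <- bins[o]
    vid <- cand[best[bins]]
    pts <- mesh@vertices[vid, , drop = FALSE]
    if (nrow(pts) >= 3) {
      sm <- pts
      n <- nrow(pts)
      sm[2:(n - 1), ] <- (pts[1:(n - 2), ] + pts[2:(n - 1), ] + pts[3:n, ]) / 3
      # keep smoothed points on the surface: cap the displacement
      d <- sqrt(rowSums((sm - pts)^2))
      far <- d > 0.09
      if (any(far)) {
        s <- 0.09 / d[far]
        sm[far, ] <- pts[far, ] + (sm[far, ] - pts[far, ]) * s
      }
      pts <- sm
    }
    new("CrestCurve", points = pts, segmentLabel = label, arcParam = th)
  }
  arcLen <- function(bins) {
    vid <- cand[best[bins]]
    pts <- mesh@vertices[vid, , drop = FALSE]
    if (nrow(pts) < 2) return(0)
    sum(sqrt(rowSums(diff(pts)^2)))
  }
  if (length(segs) == 1) return(list(mkCurve(segs[[1]], "greater")))
  lens <- vapply(segs, arcLen, numeric(1))
  o <- order(-lens)
  list(mkCurve(segs[[o[1]]], "greater"), mkCurve(segs[[o[2]]], "smaller"))
}

# ---- ellipse fitting -------------------------------------------------------

#' Direct least-squares ellipse fit
#'
#' Algebraic fit of a conic constrained to ellipses (numerically stable
#' partitioned formulation of the direct least-squares method), followed
#' by a geometric residual: the RMS of true point-to-ellipse distances
#' computed by per-point nearest-point iteration.  Deterministic, needs
#' no initialization.
#'
#' @param points n x 2 matrix of occlusal-plane coordinates (n >= 5, not
#'   collinear)
#' @return list with \code{ellipse} (an \linkS4class{EllipseParams}) and
#'   \code{rmsResidual} (mm)
#' @export
fitEllipse <- function(points) {
  points <- matrix(as.numeric(points), ncol = 2)
  if (nrow(points) < 5) stop("ellipse fit needs at least 5 points")
  x <- points[, 1]; y <- points[, 2]
  # center/scale for conditioning; the fit is equivariant so parameters
  # are mapped back exactly
  mx <- mean(x); my <- mean(y)
  sc <- mean(sqrt((x - mx)^2 + (y - my)^2))
  if (sc == 0) stop("degenerate point set")
  xs <- (x - mx) / sc; ys <- (y - my) / sc
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  if (rcond(S3) < 1e-14) stop("collinear or degenerate points: cannot fit ellipse")
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  M2 <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M2)
  V <- Re(ev$vectors)
  cond <- 4 * V[1, ] * V[3, ] - V[2, ]^2
  ok <- which(cond > 0)
  if (!length(ok)) stop("no ellipse solution (points fit a hyperbola)")
  a1 <- V[, ok[1]]
  conic <- c(a1, as.vector(Tm %*% a1))
  ell <- .conicToEllipse(conic)
  # map back from normalized coordinates
  centerN <- ell$center
  thetaN <- ell$theta
  center <- centerN * sc + c(mx, my)
  axes <- c(ell$a, ell$b) * sc
  ep <- new("EllipseParams", center = center, a = axes[1], b = axes[2],
            theta = thetaN %% pi)
  d <- pointToEllipseDistance(points, ep)
  list(ellipse = ep, rmsResidual = sqrt(mean(d^2)))
}

.conicToEllipse <- function(co) {
  A <- co[1]; B <- co[2]; C <- co[3]; D <- co[4]; E <- co[5]; F <- co[6]
  disc <- B^2 - 4 * A * C
  if (disc >= 0) stop("conic is not an ellipse")
  M <- matrix(c(2 * A, B, B, 2 * C), 2, 2)
  center <- solve(M, -c(D, E))
  F0 <- F + (D * center[1] + E * center[2]) / 2
  Q <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  eg <- eigen(Q, symmetric = TRUE)
  lam <- eg$values
  ax2 <- -F0 / lam
  if (any(ax2 <= 0)) stop("conic is not a real ellipse")
  ax <- sqrt(ax2)
  o <- order(-ax)                       # semi-major first
  aMaj <- ax[o[1]]; bMin <- ax[o[2]]
  vMaj <- eg$vectors[, o[1]]
  theta <- atan2(vMaj[2], vMaj[1]) %% pi
  list(center = center, a = aMaj, b = bMin, theta = theta)
}

#' Evaluate points on an ellipse
#' @param ellipse an \linkS4class{EllipseParams}
#' @param t parametric angles (radians, measured in the ellipse frame)
#' @return n x 2 matrix
#' @export
ellipsePoints <- function(ellipse, t) {
  ct <- cos(ellipse@theta); st <- sin(ellipse@theta)
  px <- ellipse@a * cos(t); py <- ellipse@b * sin(t)
  cbind(ellipse@center[1] + ct * px - st * py,
        ellipse@center[2] + st * px + ct * py)
}

#' True geometric distance from points to an ellipse
#'
#' Nearest-point search per point: coarse parametric sampling refined by
#' Newton iterations on the stationarity condition.
#'
#' @param points n x 2 matrix
#' @param ellipse an \linkS4class{EllipseParams}
#' @return numeric vector of unsigned distances
#' @export
pointToEllipseDistance <- function(points, ellipse) {
  points <- matrix(as.numeric(points), ncol = 2)
  ct <- cos(ellipse@theta); st <- sin(ellipse@theta)
  a <- ellipse@a; b <- ellipse@b
  # into ellipse frame
  dx <- points[, 1] - ellipse@center[1]; dy <- points[, 2] - ellipse@center[2]
  px <- ct * dx + st * dy
  py <- -st * dx + ct * dy
  t0 <- seq(0, 2 * pi, length.out = 91)[-91]
  out <- numeric(nrow(points))
  for (i in seq_len(nrow(points))) {
    x <- px[i]; y <- py[i]
    d2 <- (a * cos(t0) - x)^2 + (b * sin(t0) - y)^2
    t <- t0[which.min(d2)]
    for (it in 1:30) {
      gct <- cos(t); gst <- sin(t)
      g <- (a^2 - b^2) * gct * gst - x * a * gst + y * b * gct
      gp <- (a^2 - b^2) * cos(2 * t) - x * a * gct - y * b * gst
      if (abs(gp) < 1e-14) break
      step <- g / gp
      step <- max(-0.2, min(0.2, step))
      t <- t - step
      if (abs(step) < 1e-14) break
    }
    out[i] <- sqrt((a * cos(t) - x)^2 + (b * sin(t) - y)^2)
  }
  out
}

# ---- composition -----------------------------------------------------------

#' Detect the alveolar ridge of a cast
#'
#' Composes frame estimation, crest extraction and ellipse fitting.  Crest
#' arc parameters are re-expressed about the fitted ellipse center;
#' \code{gapSpan} is the angular interval of the cleft (the maximal empty
#' arc between the two crest segments that is not the posterior arch
#' opening), empty when the crest is continuous.
#'
#' @param mesh a maxilla-like TriangleMesh
#' @param nBins,heightFrac,minGapBins passed to \code{\link{extractCrest}}
#' @return a \linkS4class{DetectionResult}
#' @export
detectRidge <- function(mesh, nBins = 180L, heightFrac = 0.55,
                        minGapBins = 3L) {
  frame <- computeOcclusalFrame(mesh)
  crests <- extractCrest(mesh, frame, nBins = nBins,
                         heightFrac = heightFrac, minGapBins = minGapBins)
  pts2 <- do.call(rbind, lapply(crests, function(cc)
    .frameCoords(cc@points, frame)[, 1:2, drop = FALSE]))
  fit <- fitEllipse(pts2)
  ell <- fit$ellipse
  # re-express arc parameters about the ellipse center
  reparam <- function(cc) {
    uv <- .frameCoords(cc@points, frame)[, 1:2, drop = FALSE]
    th <- atan2(uv[, 2] - ell@center[2], uv[, 1] - ell@center[1])
    th <- th[1] + cumsum(c(0, (diff(th) + pi) %% (2 * pi) - pi))
    if (length(th) > 1) {
      # arc parameters are ordering bookkeeping: flatten local angle
      # reversals (coarse meshes) onto the global crest direction
      if (th[length(th)] >= th[1]) th <- cummax(th) else th <- cummin(th)
      dir <- if (th[length(th)] >= th[1]) 1 else -1
      th <- th + dir * 1e-9 * (seq_along(th) - 1)
    }
    new("CrestCurve", points = cc@points, segmentLabel = cc@segmentLabel,
        arcParam = th)
  }
  crests <- lapply(crests, reparam)
  gap <- numeric(0)
  if (length(crests) == 2) {
    # candidate gaps: the two inter-segment arcs; the cleft is the shorter
    aG <- crests[[1]]@arcParam %% (2 * pi)
    aS <- crests[[2]]@arcParam %% (2 * pi)
    # endpoints in circular order
    pts <- c(utils::head(aG, 1), utils::tail(aG, 1),
             utils::head(aS, 1), utils::tail(aS, 1))
    segOf <- c(1, 1, 2, 2)
    o <- order(pts)
    spans <- list()
    for (k in 1:4) {
      i1 <- o[k]; i2 <- o[if (k == 4) 1 else k + 1]
      if (segOf[i1] != segOf[i2]) {
        lo <- pts[i1]; hi <- pts[i2]
        width <- (hi - lo) %% (2 * pi)
        spans[[length(spans) + 1]] <- c(lo, lo + width)
      }
    }
    if (length(spans)) {
      widths <- vapply(spans, function(s) s[2] - s[1], numeric(1))
      gap <- spans[[which.min(widths)]]
    }
  }
  new("DetectionResult", frame = frame, crests = crests, ellipse = ell,
      rmsResidual = fit$rmsResidual, gapSpan = gap)
}

#' Cleft gap endpoints and chordal width of a detection
#'
#' @param detection a \linkS4class{DetectionResult}
#' @return \code{gapEndpoints}: 2 x 3 matrix of the crest endpoints
#'   bounding the cleft (greater-segment side first); \code{gapChordWidth}:
#'   their 3D distance (mm); both NULL/0 when there is no gap
#' @export
gapEndpoints <- function(detection) {
  if (length(detection@gapSpan) == 0) return(NULL)
  ends <- lapply(detection@crests, function(cc) {
    rbind(cc@points[1, ], cc@points[nrow(cc@points), ])
  })
  allPts <- do.call(rbind, ends)
  lab <- rep(vapply(detection@crests, slot, character(1), "segmentLabel"),
             each = 2)
  lo <- detection@gapSpan[1] %% (2 * pi)
  hi <- detection@gapSpan[2] %% (2 * pi)
  uv <- .frameCoords(allPts, detection@frame)[, 1:2, drop = FALSE]
  th <- atan2(uv[, 2] - detection@ellipse@center[2],
              uv[, 1] - detection@ellipse@center[1]) %% (2 * pi)
  dlo <- abs((th - lo + pi) %% (2 * pi) - pi)
  dhi <- abs((th - hi + pi) %% (2 * pi) - pi)
  p1 <- which.min(dlo); p2 <- which.min(dhi)
  out <- allPts[c(p1, p2), , drop = FALSE]
  if (lab[p2] == "greater" && lab[p1] != "greater") out <- out[2:1, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname gapEndpoints
#' @export
gapChordWidth <- function(detection) {
  ep <- gapEndpoints(detection)
  if (is.null(ep)) return(0)
  sqrt(sum((ep[1, ] - ep[2, ])^2))
}

# ---- serialization ---------------------------------------------------------

#' Write / read a DetectionResult as editable JSON
#'
#' The JSON file is the "confirm or correct" contract: a user may adjust
#' the ellipse, crest points or gap interval in the file and re-run the
#' downstream plate stages on the edited detection.
#'
#' @param detection a \linkS4class{DetectionResult}
#' @param path JSON file path
#' @return \code{writeDetection}: path, invisibly; \code{readDetection}:
#'   a \linkS4class{DetectionResult}
#' @export
writeDetection <- function(detection, path) {
  obj <- list(
    frame = list(origin = detection@frame@origin,
                 axes = detection@frame@axes),
    ellipse = list(center = detection@ellipse@center,
                   a = detection@ellipse@a, b = detection@ellipse@b,
                   theta = detection@ellipse@theta),
    rmsResidual = detection@rmsResidual,
    gapSpan = detection@gapSpan,
    crests = lapply(detection@crests, function(cc)
      list(segmentLabel = cc@segmentLabel, arcParam = cc@arcParam,
           points = cc@points)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname writeDetection
#' @export
readDetection <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  frame <- new("OcclusalFrame", origin = as.numeric(obj$frame$origin),
               axes = matrix(as.numeric(t(obj$frame$axes)), 3, 3,
                             byrow = TRUE,
                             dimnames = list(NULL, c("u", "v", "w"))))
  ell <- new("EllipseParams", center = as.numeric(obj$ellipse$center),
             a = obj$ellipse$a, b = obj$ellipse$b, theta = obj$ellipse$theta)
  crests <- lapply(seq_len(length(obj$crests$segmentLabel)), function(i)
    new("CrestCurve",
        points = matrix(as.numeric(obj$crests$points[[i]]),
                        ncol = 3),
        segmentLabel = obj$crests$segmentLabel[i],
        arcParam = as.numeric(obj$crests$arcParam[[i]])))
  new("DetectionResult", frame = frame, crests = crests, ellipse = ell,
      rmsResidual = obj$rmsResidual,
      gapSpan = as.numeric(obj$gapSpan %||% numeric(0)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
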