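# Parametric synthetic neonatal cleft maxilla with known ground truth.
#
# The cast is a watertight height-field solid: an alveolar ridge with
# Gaussian cross-section swept along a planar ellipse arc (the dental
# arch), interrupted over the cleft span, a depressed palatal vault
# inside the arch, a flat plateau outside it, and a flat base closing
# the solid from below.  The mesh is a structured polar fan grid about
# the arch center, so the crest ring at arch scale s = 1 consists of
# exact mesh vertices.

.smoothstep <- function(x) {
  x <- pmin(1, pmax(0, x))
  x * x * (3 - 2 * x)
}

#' Construct synthetic-anatomy parameters
#'
#' Defaults emulate a neonatal unilateral cleft maxilla of median
#' dimensions: arch length A-MT about 27.8 mm, tuberal width T-T' about
#' 34.4 mm, transversal width L-L' about 31.7 mm, anterior cleft width
#' 10.8 mm and posterior hard-palate cleft about 21.8 mm.
#'
#' @param ellipseA anterior-posterior semi-axis (mm)
#' @param ellipseB transversal semi-axis (mm)
#' @param ridgeHeight crest elevation above the palatal plateau (mm)
#' @param ridgeHalfwidth ridge half-thickness (mm)
#' @param cleftWidth target SA-SAp gap (mm); 0 gives a continuous arch
#' @param cleftAngle cleft-center position on the arch (degrees from the
#'   anterior midline, positive = patient's left)
#' @param segmentShift displacement of the smaller segment (mm, length 3)
#' @param palateDepth vault depression (mm)
#' @param resolution target edge length (mm)
#' @param noiseSigma Gaussian vertex jitter along the surface normal (mm)
#' @param seed RNG seed
#' @param archSpan arch half-span (degrees)
#' @param sdWidening posterior cleft (SD-SDp) excess width over the
#'   anterior cleft (mm)
#' @return an \linkS4class{AnatomyParams}
#' @export
anatomyParams <- function(ellipseA = 20.7, ellipseB = 18.3,
                          ridgeHeight = 6, ridgeHalfwidth = 3,
                          cleftWidth = 10.8, cleftAngle = 25,
                          segmentShift = c(0, 0, 0), palateDepth = 4,
                          resolution = 0.5, noiseSigma = 0, seed = 1,
                          archSpan = 110, sdWidening = 11) {
  new("AnatomyParams", ellipseA = ellipseA, ellipseB = ellipseB,
      ridgeHeight = ridgeHeight, ridgeHalfwidth = ridgeHalfwidth,
      cleftWidth = cleftWidth, cleftAngle = cleftAngle,
      segmentShift = as.numeric(segmentShift), palateDepth = palateDepth,
      resolution = resolution, noiseSigma = noiseSigma, seed = seed,
      archSpan = archSpan, sdWidening = sdWidening)
}

# arch geometry helpers: phi measured from the anterior midline,
# positive toward the patient's left; in-plane point (x, y) =
# s * (b sin phi, a cos phi)
.archPoint <- function(phi, a, b, s = 1) {
  cbind(s * b * sin(phi), s * a * cos(phi))
}

.archRadius <- function(phi, a, b) sqrt((b * sin(phi))^2 + (a * cos(phi))^2)

# half-span (radians) whose chord across the arc at center phic equals w
.chordHalfSpan <- function(w, phic, a, b, s = 1) {
  if (w <= 0) return(0)
  chord <- function(h) {
    p <- .archPoint(phic + h, a, b, s); q <- .archPoint(phic - h, a, b, s)
    sqrt(sum((p - q)^2))
  }
  hmax <- 80 * pi / 180
  if (chord(hmax) < w) stop("requested span exceeds the arch extent")
  uniroot(function(h) chord(h) - w, c(1e-9, hmax), tol = 1e-12)$root
}

# internal analytic description shared by the mesh builder and landmarks
.anatomyModel <- function(p) {
  a <- p@ellipseA; b <- p@ellipseB
  phimax <- p@archSpan * pi / 180
  t0 <- p@palateDepth + 2          # plateau height above the flat base
  sv <- 0.72                       # vault extent in arch scale
  hw <- p@ridgeHalfwidth
  side <- if (p@cleftAngle >= 0) 1 else -1
  phic <- p@cleftAngle * pi / 180
  if (p@cleftWidth > 0) {
    h <- .chordHalfSpan(p@cleftWidth, phic, a, b)
    phi1 <- phic - h; phi2 <- phic + h
    wt <- p@resolution / .archRadius(phic, a, b)
    if (phi1 - wt < -phimax + 5 * pi / 180 ||
        phi2 + wt > phimax - 5 * pi / 180)
      stop("cleft span exceeds the arch extent")
  } else {
    phi1 <- phi2 <- phic; wt <- 0
  }
  mask <- function(phi) {
    if (p@cleftWidth == 0) return(rep(1, length(phi)))
    cut <- .smoothstep((phi - phi1) / wt + 0.5) *
      .smoothstep((phi2 - phi) / wt + 0.5)
    1 - cut
  }
  # smaller-segment displacement weight (1 on the ridge past the cleft)
  shiftW <- function(phi, dmm) {
    if (p@cleftWidth == 0 || all(p@segmentShift == 0))
      return(rep(0, length(phi)))
    along <- if (side > 0) .smoothstep((phi - phi1) / max(phi2 - phi1, 1e-9))
             else .smoothstep((phi2 - phi) / max(phi2 - phi1, 1e-9))
    along * exp(-(dmm / (2.5 * hw))^2)
  }
  distToArch <- function(x, y) {
    phi <- atan2(x / b, y / a)      # arch parameter of the ray through (x,y)
    r <- .archRadius(phi, a, b)
    s <- sqrt((x / b)^2 + (y / a)^2)
    d <- abs(s - 1) * r
    out <- abs(phi) > phimax
    if (any(out)) {
      ep <- .archPoint(sign(phi[out]) * phimax, a, b)
      d[out] <- sqrt((x[out] - ep[, 1])^2 + (y[out] - ep[, 2])^2)
      phi[out] <- sign(phi[out]) * phimax
    }
    list(d = d, phi = phi, s = s)
  }
  ztop <- function(x, y) {
    da <- distToArch(x, y)
    ridge <- p@ridgeHeight * exp(-(da$d / hw)^2) * mask(da$phi)
    vault <- ifelse(da$s < sv,
                    p@palateDepth * cos(pi * da$s / (2 * sv))^2, 0)
    t0 + ridge - vault
  }
  crestZ <- function(phi) t0 + p@ridgeHeight * mask(phi)
  list(a = a, b = b, phimax = phimax, t0 = t0, sv = sv, side = side,
       phi1 = phi1, phi2 = phi2, wt = wt, mask = mask, ztop = ztop,
       crestZ = crestZ, shiftW = shiftW, distToArch = distToArch)
}

.anatomyLandmarks <- function(p, mdl) {
  a <- p@ellipseA; b <- p@ellipseB
  place <- function(phi, s = 1, onCrest = TRUE) {
    xy <- .archPoint(phi, a, b, s)
    z <- if (onCrest) mdl$crestZ(phi) else mdl$ztop(xy[1], xy[2])
    pt <- c(xy[1], xy[2], z)
    da <- mdl$distToArch(xy[1], xy[2])
    pt + mdl$shiftW(da$phi, da$d) * p@segmentShift
  }
  # with the cleft on the patient's left (side > 0) the greater segment
  # covers [-phimax, phi1]; mirrored otherwise
  onGreater <- function(phi) if (mdl$side > 0) phi <= mdl$phi1 else phi >= mdl$phi2
  phiA <- 0
  if (p@cleftWidth > 0 && !onGreater(0)) {
    phiA <- if (mdl$side > 0) mdl$phi1 - mdl$wt - 2 * pi / 180
            else mdl$phi2 + mdl$wt + 2 * pi / 180
  }
  saG <- if (mdl$side > 0) mdl$phi1 else mdl$phi2   # margin on greater side
  saS <- if (mdl$side > 0) mdl$phi2 else mdl$phi1
  sSD <- 0.62
  cSD <- p@cleftWidth + p@sdWidening
  hSD <- tryCatch(.chordHalfSpan(cSD, p@cleftAngle * pi / 180, a, b, sSD),
                  error = function(e) 80 * pi / 180)
  phicR <- p@cleftAngle * pi / 180
  sdG <- if (mdl$side > 0) phicR - hSD else phicR + hSD
  sdS <- if (mdl$side > 0) phicR + hSD else phicR - hSD
  landmarkSet(list(
    A  = place(phiA),
    P  = place(0, s = 0.65, onCrest = FALSE),
    SA = place(saG), SAp = place(saS),
    L  = place(-pi / 3), Lp = place(pi / 3),
    T  = place(-mdl$phimax), Tp = place(mdl$phimax),
    SD = place(sdG, s = sSD, onCrest = FALSE),
    SDp = place(sdS, s = sSD, onCrest = FALSE)))
}

#' Generate a synthetic cleft maxilla with ground truth
#'
#' Deterministic given \code{params@seed}.  The mesh is watertight and
#' single-component; a positive cleft width interrupts the alveolar
#' ridge over the cleft span while the underlying palatal shelf stays
#' closed.  Ground-truth landmarks are placed by construction: A at the
#' anterior crest of the greater segment, SA/SAp at the cleft margins on
#' the crest, L/Lp at +-60 degrees of arc, T/Tp at the posterior arch
#' ends, P on the midline behind A, SD/SDp flanking the posterior
#' hard-palate cleft.
#'
#' @param params an \linkS4class{AnatomyParams}
#' @return list with \code{mesh} (a \linkS4class{TriangleMesh}) and
#'   \code{truth} (a \linkS4class{GroundTruth})
#' @export
generateCleftMaxilla <- function(params) {
  stopifnot(is(params, "AnatomyParams"))
  validObject(params)
  p <- params
  mdl <- .anatomyModel(p)
  a <- p@ellipseA; b <- p@ellipseB
  rmax <- max(a, b)
  sOut <- 1 + 2 * p@ridgeHalfwidth / min(a, b)
  ds <- p@resolution / rmax
  sLev <- seq(ds, sOut, by = ds)
  sLev <- sLev[abs(sLev - 1) > 0.3 * ds]
  sLev <- sort(unique(c(sLev, 1, sOut)))
  nr <- length(sLev)
  nphi <- as.integer(ceiling(2 * pi * rmax / p@resolution))
  phi <- -pi + 2 * pi * (seq_len(nphi) - 1) / nphi

  # top surface vertices: center + nr rings of nphi
  ringXY <- lapply(sLev, function(s) .archPoint(phi, a, b, s))
  xs <- c(0, unlist(lapply(ringXY, function(m) m[, 1])))
  ys <- c(0, unlist(lapply(ringXY, function(m) m[, 2])))
  zs <- mdl$ztop(xs, ys)
  da <- mdl$distToArch(xs, ys)
  sw <- mdl$shiftW(da$phi, da$d)
  top <- cbind(xs + sw * p@segmentShift[1],
               ys + sw * p@segmentShift[2],
               zs + sw * p@segmentShift[3])
  nTop <- nrow(top)

  # deterministic surface noise (top surface interior only)
  if (p@noiseSigma > 0) {
    rs <- .seedScope(p@seed)
    on.exit(.seedRestore(rs), add = TRUE)
    jit <- rnorm(nTop, 0, p@noiseSigma)
    jit[(nTop - nphi + 1):nTop] <- 0    # keep the outer rim clean
    top[, 3] <- top[, 3] + jit
  }

  # bottom: center + copy of the outer ring at z = 0
  botCenter <- c(0, 0, 0)
  outer <- ringXY[[nr]]
  bot <- cbind(outer[, 1], outer[, 2], 0)
  verts <- rbind(top, botCenter, bot)
  idTopC <- 1L
  idTop <- function(j, i) 1L + (j - 1L) * nphi + i       # ring j, slot i
  idBotC <- nTop + 1L
  idBot <- function(i) nTop + 1L + i
  nxt <- c(seq_len(nphi)[-1], 1L)

  faces <- vector("list", nr + 2)
  i <- seq_len(nphi)
  # top fan (normals up: counter-clockwise seen from +z means decreasing phi)
  faces[[1]] <- cbind(idTopC, idTop(1L, i), idTop(1L, nxt[i]))
  for (j in seq_len(nr - 1)) {
    aI <- idTop(j, i); bI <- idTop(j, nxt[i])
    cI <- idTop(j + 1L, nxt[i]); dI <- idTop(j + 1L, i)
    faces[[j + 1]] <- rbind(cbind(aI, cI, bI), cbind(aI, dI, cI))
  }
  # bottom fan (normals down)
  faces[[nr + 1]] <- cbind(idBotC, idBot(nxt[i]), idBot(i))
  # wall between top outer ring and bottom ring
  tI <- idTop(nr, i); tN <- idTop(nr, nxt[i])
  bI2 <- idBot(i); bN <- idBot(nxt[i])
  faces[[nr + 2]] <- rbind(cbind(tI, bI2, bN), cbind(tI, bN, tN))
  mesh <- triangleMesh(verts, do.call(rbind, faces),
                       name = sprintf("synthetic-maxilla-seed%g", p@seed),
                       metadata = list(kind = "synthetic-maxilla",
                                       crestRing = nr - which(sLev == 1),
                                       params = p))
  if (meshVolume(mesh) < 0)
    mesh <- triangleMesh(verts, do.call(rbind, faces)[, c(1, 3, 2)],
                         name = mesh@name, metadata = mesh@metadata)

  # ground-truth crest: vertices of the s = 1 ring, outside the cleft ramp
  jCrest <- which(sLev == 1)
  crestIdx <- idTop(jCrest, i)
  m <- mdl$mask(phi)
  inArch <- abs(phi) <= mdl$phimax
  keep <- inArch & m >= 0.99
  ord <- order(phi)
  crest <- list()
  if (p@cleftWidth > 0) {
    gSel <- if (mdl$side > 0) keep & phi <= mdl$phi1 else keep & phi >= mdl$phi2
    sSel <- keep & !gSel
    crest$greater <- verts[crestIdx[ord][gSel[ord]], , drop = FALSE]
    crest$smaller <- verts[crestIdx[ord][sSel[ord]], , drop = FALSE]
  } else {
    crest$greater <- verts[crestIdx[ord][keep[ord]], , drop = FALSE]
  }
  major <- max(a, b); minor <- min(a, b)
  truth <- new("GroundTruth",
               landmarks = .anatomyLandmarks(p, mdl),
               ellipse = new("EllipseParams", center = c(0, 0), a = major,
                             b = minor,
                             theta = if (a >= b) pi / 2 else 0),
               crest = crest, occlusalNormal = c(0, 0, 1))
  list(mesh = mesh, truth = truth)
}

.seedScope <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed %% .Machine$integer.max))
  old
}

.seedRestore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Apply months of arch growth to anatomy parameters
#'
#' Scales both ellipse semi-axes by (1 + g)^months; all other fields are
#' unchanged unless a new cleft width is supplied by the closure schedule.
#'
#' @param params an \linkS4class{AnatomyParams}
#' @param months months of growth (>= 0)
#' @param g monthly relative growth fraction (> -1)
#' @param newCleftWidth optional replacement cleft width (mm)
#' @return updated \linkS4class{AnatomyParams}
#' @export
growAnatomy <- function(params, months, g, newCleftWidth = NULL) {
  stopifnot(months >= 0, g > -1)
  f <- (1 + g)^months
  params@ellipseA <- params@ellipseA * f
  params@ellipseB <- params@ellipseB * f
  if (!is.null(newCleftWidth)) params@cleftWidth <- newCleftWidth
  validObject(params)
  params
}

#' Cohort generator parameters
#'
#' Describes a cohort of subjects for the paired two-impression design:
#' anatomy parameters are drawn per subject from truncated normal
#' distributions, the second impression applies a per-subject
#' multiplicative arch growth and a cleft-width reduction.
#'
#' @param nSubjects number of subjects (>= 1)
#' @param mean,sd,lower,upper named numeric vectors of per-parameter
#'   distributions; names must be AnatomyParams fields (e.g. "ellipseA",
#'   "cleftWidth").  Unnamed parameters stay at their defaults.
#' @param growthMean,growthSD distribution of the per-subject total
#'   multiplicative arch change between impressions (e.g. 0.08 = +8\%)
#' @param cleftReduction cleft-width reduction between impressions (mm)
#' @param resolution mesh resolution for all subjects (mm)
#' @param seed RNG seed
#' @return an object of class \code{CohortParams} (list)
#' @export
cohortParams <- function(nSubjects = 7,
                         mean = c(ellipseA = 20.7, ellipseB = 18.3,
                                  cleftWidth = 10.8),
                         sd = c(ellipseA = 1.2, ellipseB = 1.2,
                                cleftWidth = 3.5),
                         lower = c(ellipseA = 17, ellipseB = 15,
                                   cleftWidth = 4),
                         upper = c(ellipseA = 25, ellipseB = 22,
                                   cleftWidth = 20),
                         growthMean = 0.08, growthSD = 0.02,
                         cleftReduction = 6, resolution = 0.5, seed = 1) {
  if (nSubjects < 1) stop("nSubjects must be >= 1")
  if (any(sd < 0) || growthSD < 0) stop("standard deviations must be >= 0")
  structure(list(nSubjects = as.integer(nSubjects), mean = mean, sd = sd,
                 lower = lower, upper = upper, growthMean = growthMean,
                 growthSD = growthSD, cleftReduction = cleftReduction,
                 resolution = resolution, seed = seed),
            class = "CohortParams")
}

.rtrunc <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- rnorm(1, mean, sd)
      if (x >= lower && x <= upper) { out[i] <- x; break }
    }
  }
  out
}

#' Generate a paired pre/post synthetic cohort
#'
#' Emulates the two-impression molding-study design: impression 1 at the
#' start of therapy, impression 2 after per-subject arch growth and a
#' cleft-width reduction.  Reproducible by seed.
#'
#' @param cohort a \code{\link{cohortParams}} object
#' @return list of per-subject records, each with \code{pre}, \code{post}
#'   (mesh + truth lists from \code{\link{generateCleftMaxilla}}),
#'   \code{preParams}, \code{postParams}, \code{growth}
#' @export
generateCohort <- function(cohort) {
  stopifnot(inherits(cohort, "CohortParams"))
  rs <- .seedScope(cohort$seed)
  on.exit(.seedRestore(rs), add = TRUE)
  n <- cohort$nSubjects
  draws <- list()
  for (pn in names(cohort$mean)) {
    lo <- if (pn %in% names(cohort$lower)) cohort$lower[[pn]] else -Inf
    hi <- if (pn %in% names(cohort$upper)) cohort$upper[[pn]] else Inf
    sdv <- if (pn %in% names(cohort$sd)) cohort$sd[[pn]] else 0
    draws[[pn]] <- .rtrunc(n, cohort$mean[[pn]], sdv, lo, hi)
  }
  growth <- .rtrunc(n, cohort$growthMean, cohort$growthSD,
                    max(-0.5, cohort$growthMean - 4 * max(cohort$growthSD, 1e-9)),
                    cohort$growthMean + 4 * max(cohort$growthSD, 1e-9))
  subjectSeeds <- floor(runif(n, 1, 2^30))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    args <- lapply(draws, `[`, i)
    args$resolution <- cohort$resolution
    args$seed <- subjectSeeds[i]
    preP <- do.call(anatomyParams, args)
    postP <- growAnatomy(preP, months = 1, g = growth[i],
                         newCleftWidth = max(0, preP@cleftWidth -
                                                  cohort$cleftReduction))
    postP@seed <- subjectSeeds[i] + 1e6   # distinct noise draw per impression
    out[[i]] <- list(pre = generateCleftMaxilla(preP),
                     post = generateCleftMaxilla(postP),
                     preParams = preP, postParams = postP,
                     growth = growth[i])
  }
  out
}
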