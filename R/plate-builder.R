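# Molding-plate construction: cleft bridging along the fitted ellipse,
# shell offsetting, retention pin (boolean union), ventilation hole
# (structured-shell surgery) and Taubin smoothing.

#' Construct plate parameters
#'
#' Dimensional defaults (thickness, pin, hole) are clinical placeholders;
#' they are configuration values, not anatomically derived ones.
#'
#' @param thickness shell thickness (mm)
#' @param trimHeight vestibular trim: how far below the crest the plate
#'   skirt extends (mm)
#' @param pinRadius,pinLength retention pin dimensions (mm)
#' @param pinPosition pin arc position on the ellipse (radians, 0 =
#'   anterior midline)
#' @param pinElevation pin axis elevation above the occlusal plane (deg)
#' @param holeRadius ventilation hole radius (mm)
#' @param holeArc,holeInset hole position: arc angle (radians) and radial
#'   inset as a fraction of the local ellipse radius
#' @param smoothingIterations Taubin iterations
#' @param voxelPitch boolean-engine grid pitch (mm)
#' @return a \linkS4class{PlateSpec}
#' @export
plateSpec <- function(thickness = 2.0, trimHeight = 4.0, pinRadius = 1.5,
                      pinLength = 10, pinPosition = 0, pinElevation = 45,
                      holeRadius = 1.0, holeArc = 0, holeInset = 0.45,
                      smoothingIterations = 5, voxelPitch = 0.2) {
  sp <- new("PlateSpec", thickness = thickness, trimHeight = trimHeight,
            pinRadius = pinRadius, pinLength = pinLength,
            pinPosition = pinPosition, pinElevation = pinElevation,
            holeRadius = holeRadius, holeArc = holeArc,
            holeInset = holeInset,
            smoothingIterations = smoothingIterations,
            smoothingMethod = "taubin", voxelPitch = voxelPitch)
  validObject(sp)
  sp
}

# radius of the ellipse boundary along direction angle th from its center
.ellipseRadiusAt <- function(ellipse, th) {
  d1 <- cos(th - ellipse@theta); d2 <- sin(th - ellipse@theta)
  1 / sqrt((d1 / ellipse@a)^2 + (d2 / ellipse@b)^2)
}

# per-vertex polar coordinates about the detection ellipse center, in the
# occlusal frame: list(theta, r, rEll, sRel, w, uv)
.archPolar <- function(vertices, detection) {
  q <- .frameCoords(vertices, detection@frame)
  du <- q[, 1] - detection@ellipse@center[1]
  dv <- q[, 2] - detection@ellipse@center[2]
  th <- atan2(dv, du)
  r <- sqrt(du^2 + dv^2)
  rE <- .ellipseRadiusAt(detection@ellipse, th)
  list(theta = th, r = r, rEll = rE, sRel = r / rE, w = q[, 3], uv = q[, 1:2])
}

#' Select bridging regions on the two alveolar segments
#'
#' In automatic mode the regions are the faces within \code{radius} of
#' the two crest endpoints bounding the cleft gap.  User seeds (face
#' indices, one per segment) instead grow breadth-first geodesic disks of
#' the same radius; the manual option exists because segment size and
#' configuration differ between patients.
#'
#' @param mesh the cast TriangleMesh
#' @param detection a \linkS4class{DetectionResult} with non-empty gap
#' @param seeds optional integer vector of length 2: a seed face on the
#'   greater and on the smaller segment
#' @param radius region radius (mm)
#' @return a \linkS4class{BridgeRegions} (greater, smaller)
#' @export
selectBridgeRegions <- function(mesh, detection, seeds = NULL, radius = 3) {
  ep <- gapEndpoints(detection)
  if (is.null(ep)) stop("no cleft: detection has an empty gap span")
  f <- mesh@faces; v <- mesh@vertices
  cent <- (v[f[, 1], ] + v[f[, 2], ] + v[f[, 3], ]) / 3
  dG <- sqrt(rowSums(sweep(cent, 2, ep[1, ])^2))
  dS <- sqrt(rowSums(sweep(cent, 2, ep[2, ])^2))
  if (is.null(seeds)) {
    g <- which(dG <= radius & dG < dS)
    s <- which(dS <= radius & dS <= dG)
  } else {
    if (length(seeds) != 2) stop("seeds must give one face per segment")
    if (dG[seeds[1]] > dS[seeds[1]] || dS[seeds[2]] > dG[seeds[2]])
      stop("seed face lies on the wrong side of the gap")
    grow <- function(seed) {
      adj <- .faceAdjacency(mesh)
      sel <- logical(nrow(f)); sel[seed] <- TRUE
      frontier <- seed
      while (length(frontier)) {
        nb <- unique(unlist(adj[frontier]))
        nb <- nb[!sel[nb]]
        nb <- nb[sqrt(rowSums(sweep(cent[nb, , drop = FALSE], 2,
                                    cent[seed, ])^2)) <= radius]
        sel[nb] <- TRUE
        frontier <- nb
      }
      which(sel)
    }
    g <- grow(seeds[1]); s <- grow(seeds[2])
    s <- setdiff(s, g)
  }
  if (!length(g) || !length(s))
    stop("bridge region selection failed: empty region")
  new("BridgeRegions", greaterFaces = as.integer(g),
      smallerFaces = as.integer(s))
}

.faceAdjacency <- function(mesh) {
  f <- mesh@faces
  n <- nrow(mesh@vertices)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- pmin(e[, 1], e[, 2]) * (n + 1) + pmax(e[, 1], e[, 2])
  fid <- rep(seq_len(nrow(f)), 3)
  sp <- split(fid, key)
  adj <- vector("list", nrow(f))
  for (grp in sp) {
    if (length(grp) < 2) next
    for (a in grp) adj[[a]] <- c(adj[[a]], setdiff(grp, a))
  }
  adj
}

#' Bridge the cleft along the fitted ellipse
#'
#' Virtual cleft closure: vertices in the gap channel are raised along
#' the occlusal normal to a loft that blends the crest heights at the two
#' cleft margins and whose spine follows the ellipse arc over the gap —
#' the "guiding track" into which the alveolar growth can expand.  The
#' mesh topology is untouched and every vertex outside the channel keeps
#' its position bit-identically, so watertightness is preserved.  With
#' \code{targetGap > 0} a central channel of that chordal width is left
#' open (used by the plate series for progressive closure).
#'
#' @param mesh the cast TriangleMesh (watertight)
#' @param detection a \linkS4class{DetectionResult}
#' @param regions optional \linkS4class{BridgeRegions} (defaults to
#'   \code{\link{selectBridgeRegions}} in automatic mode); the loft
#'   half-width is estimated from the region extent
#' @param targetGap residual chordal gap width to leave open (mm)
#' @return bridged TriangleMesh
#' @export
bridgeGap <- function(mesh, detection, regions = NULL, targetGap = 0) {
  if (length(detection@gapSpan) == 0) return(mesh)
  if (is.null(regions)) regions <- selectBridgeRegions(mesh, detection)
  ep <- gapEndpoints(detection)
  pol <- .archPolar(mesh@vertices, detection)
  g1 <- detection@gapSpan[1]; g2 <- detection@gapSpan[2]
  span <- (g2 - g1) %% (2 * pi)
  lam <- ((pol$theta - g1) %% (2 * pi)) / span
  inGap <- lam >= 0 & lam <= 1
  # loft half-width from the bridge regions' radial extent
  fidx <- c(regions@greaterFaces, regions@smallerFaces)
  vr <- unique(as.vector(mesh@faces[fidx, ]))
  hwB <- max(1, median(abs(pol$r[vr] - pol$rEll[vr])) * 2.5)
  radial <- abs(pol$r - pol$rEll)
  sel <- inGap & radial < 3 * hwB
  if (!any(sel)) return(mesh)
  # crest heights near the margins (median of the adjacent crest points,
  # robust against the margin ramp), in frame w
  epw <- vapply(detection@crests, function(cc) {
    qw <- .frameCoords(cc@points, detection@frame)[, 3]
    dist1 <- colSums((t(cc@points) - ep[1, ])^2)
    dist2 <- colSums((t(cc@points) - ep[2, ])^2)
    near <- order(pmin(dist1, dist2))[seq_len(min(5, length(qw)))]
    median(qw[near])
  }, numeric(1))
  labs <- vapply(detection@crests, slot, character(1), "segmentLabel")
  epw <- epw[order(match(labs, c("greater", "smaller")))]
  wTarget <- epw[1] + (epw[2] - epw[1]) * lam[sel]
  prof <- exp(-(radial[sel] / hwB)^2)
  dw <- pmax(0, (wTarget - pol$w[sel])) * prof
  if (targetGap > 0) {
    # leave a central channel of chordal width targetGap open
    chord <- sqrt(sum((ep[1, ] - ep[2, ])^2))
    halfFrac <- min(0.5, targetGap / max(chord, 1e-9) / 2)
    mid <- 0.5
    edge <- 0.08
    cmask <- 1 - (.smoothstep((lam[sel] - (mid - halfFrac)) / edge) *
                    .smoothstep(((mid + halfFrac) - lam[sel]) / edge))
    dw <- dw * cmask
  }
  v2 <- mesh@vertices
  wAxis <- detection@frame@axes[, 3]
  v2[sel, ] <- v2[sel, ] + outer(dw, wAxis)
  triangleMesh(v2, mesh@faces, name = paste0(mesh@name, "+bridge"),
               metadata = mesh@metadata)
}

# ---- shell offsetting ------------------------------------------------------

#' Offset an open surface region into a watertight shell
#'
#' The intaglio is the selected surface region itself (reversed
#' orientation); the outer surface offsets every vertex by
#' \code{thickness} along its area-weighted normal; side walls close each
#' boundary loop.  Offsetting that would flip a face (local curvature
#' radius below the thickness) raises an error.
#'
#' @param mesh source TriangleMesh
#' @param faceIdx faces forming the region (indices into the mesh)
#' @param thickness offset distance (mm)
#' @param metadata extra metadata stored on the shell
#' @return watertight TriangleMesh with shell metadata (\code{shell$nv}
#'   region vertices: intaglio vertices 1..nv, outer nv+1..2nv; intaglio
#'   faces first, then the matching outer faces, then walls)
#' @export
offsetShell <- function(mesh, faceIdx, thickness, metadata = list()) {
  f <- mesh@faces[faceIdx, , drop = FALSE]
  used <- sort(unique(as.vector(f)))
  remap <- integer(nrow(mesh@vertices)); remap[used] <- seq_along(used)
  rf <- matrix(remap[f], ncol = 3)
  rv <- mesh@vertices[used, , drop = FALSE]
  region <- triangleMesh(rv, rf)
  n <- vertexNormals(region)
  nv <- nrow(rv)
  fn <- .faceNormalsArea(region)$normals
  flipped <- function(outer) {
    a <- outer[rf[, 1], , drop = FALSE]
    cr <- .rowCross(outer[rf[, 2], , drop = FALSE] - a,
                    outer[rf[, 3], , drop = FALSE] - a)
    rowSums(cr * fn) <= 0
  }
  # clamped offset: where creases sharper than the thickness would fold
  # the outer surface, the offset direction field is smoothed over the
  # neighborhood until no face flips (full thickness is preserved along
  # the smoothed directions, so the wall never thins below the offset)
  outer <- rv + thickness * n
  badFrac <- mean(flipped(outer))
  if (badFrac > 0.2) {
    b1 <- which(flipped(outer))[1]
    stop(sprintf(paste("offset collapse: thickness %.2f mm exceeds the",
                       "geometry scale (%.0f%% of faces fold) near",
                       "(%.1f, %.1f, %.1f)"), thickness, 100 * badFrac,
                 rv[rf[b1, 1], 1], rv[rf[b1, 1], 2], rv[rf[b1, 1], 3]))
  }
  tries <- 0
  while (any(flipped(outer)) && tries < 12) {
    n <- cpp_taubin_smooth(n, rf, 0.6, 0, 2L, rep(-1, nv))
    n <- n / pmax(sqrt(rowSums(n^2)), .Machine$double.xmin)
    outer <- rv + thickness * n
    tries <- tries + 1
  }
  if (any(flipped(outer))) {
    # narrow grooves: blend the offset field toward the mean region normal
    # (a constant-direction offset is a translation and can never fold)
    meanN <- colSums(vertexNormals(region))
    meanN <- meanN / sqrt(sum(meanN^2))
    for (beta in c(0.3, 0.6, 1)) {
      n2 <- (1 - beta) * n + beta * matrix(meanN, nv, 3, byrow = TRUE)
      n2 <- n2 / pmax(sqrt(rowSums(n2^2)), .Machine$double.xmin)
      outer <- rv + thickness * n2
      if (!any(flipped(outer))) break
    }
  }
  if (any(bad <- flipped(outer))) {
    b1 <- which(bad)[1]
    stop(sprintf(paste("offset collapse: thickness %.2f mm exceeds local",
                       "curvature near (%.1f, %.1f, %.1f)"), thickness,
                 rv[rf[b1, 1], 1], rv[rf[b1, 1], 2], rv[rf[b1, 1], 3]))
  }
  # boundary directed edges of the region
  ei <- .edgeInfo(region)
  cnt <- table(ei$ukey)
  bsel <- ei$ukey %in% as.numeric(names(cnt)[cnt == 1])
  be <- ei$edges[bsel, , drop = FALSE]
  if (nrow(be) == 0) stop("region has no boundary: cannot build a shell")
  u <- be[, 1]; vtx <- be[, 2]
  walls <- rbind(cbind(u, vtx, vtx + nv), cbind(u, vtx + nv, u + nv))
  faces <- rbind(rf[, c(1, 3, 2)],          # intaglio, reversed
                 rf + nv,                   # outer
                 walls)
  shellMeta <- c(metadata,
                 list(shell = list(nv = nv, nf = nrow(rf),
                                   thickness = thickness,
                                   boundaryVerts = sort(unique(as.vector(be))))))
  triangleMesh(rbind(rv, outer), faces, name = paste0(mesh@name, "-shell"),
               metadata = shellMeta)
}

#' Build a molding plate from a bridged cast
#'
#' The intaglio surface is the anatomical surface over the arch: all
#' upward-facing faces inside the arch footprint, plus the vestibular
#' skirt down to \code{trimHeight} below the crest.  The outer surface
#' offsets the intaglio by \code{thickness} along the vertex normals; side
#' walls close the shell.  The intaglio therefore deviates from the cast
#' surface only by floating-point noise.
#'
#' @param bridged watertight TriangleMesh (output of
#'   \code{\link{bridgeGap}}, or the cast itself for a continuous arch)
#' @param detection a \linkS4class{DetectionResult} of the cast
#' @param spec a \linkS4class{PlateSpec}
#' @return watertight shell TriangleMesh with shell metadata
#' @export
buildPlate <- function(bridged, detection, spec) {
  pol <- .archPolar(bridged@vertices, detection)
  crestPts <- do.call(rbind, lapply(detection@crests, slot, "points"))
  crestW <- median(.frameCoords(crestPts, detection@frame)[, 3])
  fa <- .faceNormalsArea(bridged)
  wAxis <- detection@frame@axes[, 3]
  up <- as.vector(fa$normals %*% wAxis) > 0.05
  f <- bridged@faces
  vKeep <- (pol$sRel <= 1.02 | pol$w >= crestW - spec@trimHeight) &
    pol$sRel <= 1.30
  fKeep <- up & vKeep[f[, 1]] & vKeep[f[, 2]] & vKeep[f[, 3]]
  if (!any(fKeep)) stop("no intaglio region found")
  # largest connected component of the kept faces
  idx <- which(fKeep)
  sub <- triangleMesh(bridged@vertices, f[idx, , drop = FALSE])
  comp <- cpp_vertex_components(nrow(bridged@vertices), sub@faces)
  fComp <- comp[f[idx, 1]]
  main <- as.integer(names(which.max(table(fComp))))
  idx <- idx[fComp == main]
  meta <- list(frame = detection@frame, ellipse = detection@ellipse,
               crestW = crestW, spec = spec)
  plate <- offsetShell(bridged, idx, spec@thickness, metadata = meta)
  plate@name <- paste0(bridged@name, "-plate")
  plate
}

#' Add the retention pin (boolean union)
#'
#' A capped cylinder at the pin arc position, its axis tilted anteriorly
#' by \code{pinElevation} degrees from the occlusal plane, is united with
#' the plate.  The pin anchors the extraoral buccal tapes.  A fully
#' embedded pin leaves the plate unchanged; a fully detached pin is a
#' placement error.  The union is computed by the voxel-backed boolean
#' engine and therefore remeshes the plate.
#'
#' @param plate watertight plate TriangleMesh with frame metadata
#' @param spec a \linkS4class{PlateSpec}
#' @return watertight TriangleMesh
#' @export
addRetentionPin <- function(plate, spec) {
  md <- plate@metadata
  if (is.null(md$frame)) stop("plate lacks frame metadata")
  frame <- md$frame; ell <- md$ellipse
  thp <- spec@pinPosition
  rE <- .ellipseRadiusAt(ell, thp)
  target2 <- ell@center + rE * c(cos(thp), sin(thp))
  elev <- spec@pinElevation * pi / 180
  dirUV <- c(cos(thp), sin(thp))
  dir3 <- cos(elev) * (frame@axes[, 1] * dirUV[1] +
                         frame@axes[, 2] * dirUV[2]) +
    sin(elev) * frame@axes[, 3]
  # anchor on the outward-facing skin aligned with the pin axis (never the
  # intaglio), nearest the pin arc position at crest level
  q <- .frameCoords(plate@vertices, frame)
  vn <- vertexNormals(plate)
  facing <- as.vector(vn %*% dir3) >= 0.5
  if (!any(facing)) stop("pin placement error: no plate surface faces the pin")
  d2 <- (q[, 1] - target2[1])^2 + (q[, 2] - target2[2])^2 +
    0.25 * (q[, 3] - md$crestW)^2
  d2[!facing] <- Inf
  anchor <- plate@vertices[which.min(d2), ]
  # embed the base just inside the shell without piercing the intaglio:
  # the cylinder's lowest point stays above thickness below the outer skin
  sinEl <- max(abs(sin(elev)), 0.3)
  th <- if (!is.null(md$spec)) md$spec@thickness else 2
  embed <- min(2 * th, max(0.5, 0.8 * (th - spec@pinRadius * abs(cos(elev))) /
                                  sinEl))
  base <- anchor - embed * dir3
  pin <- meshCylinder(base = base, axis = dir3, radius = spec@pinRadius,
                      length = spec@pinLength, n = 32)
  inside <- pointsInsideMesh(pin@vertices, plate)
  if (all(inside)) return(plate)            # absorbed union: identity
  if (!any(inside)) {
    # vertices may straddle without containing: check center samples too
    mid <- sweep(pin@vertices, 2, colMeans(pin@vertices), function(a, b)
      (a + b) / 2)
    if (!any(pointsInsideMesh(mid, plate)))
      stop("pin placement error: pin does not touch the plate")
  }
  out <- booleanMesh(plate, pin, op = "union", pitch = spec@voxelPitch)
  out@name <- paste0(plate@name, "+pin")
  keep <- md[setdiff(names(md), "shell")]
  out@metadata <- keep
  out
}

#' Voxel-backed boolean operations on watertight meshes
#'
#' Signed z-distance fields are sampled per solid on a shared grid
#' (column ray casting), combined (union: max; intersection: min;
#' difference: min(A, -B)), and the zero level set is extracted by
#' marching tetrahedra, which guarantees a watertight result.  Accuracy
#' is on the order of the grid pitch laterally and sub-pitch vertically.
#'
#' @param meshA,meshB watertight TriangleMesh solids
#' @param op "union", "intersection" or "difference" (A minus B)
#' @param pitch grid pitch (mm)
#' @return watertight TriangleMesh
#' @export
booleanMesh <- function(meshA, meshB, op = c("union", "intersection",
                                             "difference"),
                        pitch = 0.2) {
  op <- match.arg(op)
  # grid origin offset by an irrational pitch fraction so that flat faces
  # of either solid never coincide with grid planes
  lo <- pmin(apply(meshA@vertices, 2, min), apply(meshB@vertices, 2, min)) -
    (3 + 0.31830989) * pitch
  hi <- pmax(apply(meshA@vertices, 2, max), apply(meshB@vertices, 2, max)) +
    3 * pitch
  nx <- as.integer(ceiling((hi[1] - lo[1]) / pitch)) + 1L
  ny <- as.integer(ceiling((hi[2] - lo[2]) / pitch)) + 1L
  nz <- as.integer(ceiling((hi[3] - lo[3]) / pitch)) + 1L
  clamp <- 2 * pitch
  fA <- cpp_zdist_field(cpp_column_crossings(meshA@vertices, meshA@faces,
                                             lo[1], lo[2], pitch, nx, ny),
                        lo[3], pitch, nx, ny, nz, clamp)
  fB <- cpp_zdist_field(cpp_column_crossings(meshB@vertices, meshB@faces,
                                             lo[1], lo[2], pitch, nx, ny),
                        lo[3], pitch, nx, ny, nz, clamp)
  fld <- switch(op,
                union = pmax(fA, fB),
                intersection = pmin(fA, fB),
                difference = pmin(fA, -fB))
  res <- cpp_marching_tets(fld, nx, ny, nz, lo[1], lo[2], lo[3], pitch)
  cleanMesh(triangleMesh(res$vertices, res$faces,
                         name = sprintf("boolean-%s", op)))
}

#' Carve a user-supplied tool out of a plate
#'
#' Region removal ("grinding") by boolean difference with an arbitrary
#' watertight tool mesh; no automatic grinding heuristic is attempted.
#'
#' @param plate watertight plate TriangleMesh
#' @param tool watertight tool TriangleMesh
#' @param pitch engine pitch (mm)
#' @return carved TriangleMesh
#' @export
carveTool <- function(plate, tool, pitch = 0.2) {
  out <- booleanMesh(plate, tool, op = "difference", pitch = pitch)
  out@metadata <- plate@metadata[setdiff(names(plate@metadata), "shell")]
  out@name <- paste0(plate@name, "+carve")
  out
}

#' Add the ventilation hole (structured-shell surgery)
#'
#' A through-channel along the occlusal normal at the hole position:
#' matching intaglio/outer face pairs inside the hole radius are removed
#' and the rims stitched with an inner wall.  Exact: genus increases by
#' one and the removed volume is the prism between the two surfaces.
#' Requires an unremeshed shell plate (apply before the pin union).
#'
#' @param plate shell TriangleMesh from \code{\link{buildPlate}}
#' @param spec a \linkS4class{PlateSpec}
#' @return watertight TriangleMesh with genus + 1
#' @export
addVentilationHole <- function(plate, spec) {
  md <- plate@metadata
  sh <- md$shell
  if (is.null(sh)) stop("ventilation hole requires a structured shell plate")
  frame <- md$frame; ell <- md$ellipse
  rE <- .ellipseRadiusAt(ell, spec@holeArc)
  c2 <- ell@center + spec@holeInset * rE * c(cos(spec@holeArc),
                                             sin(spec@holeArc))
  nv <- sh$nv; nf <- sh$nf
  q <- .frameCoords(plate@vertices[seq_len(nv), , drop = FALSE], frame)
  f <- plate@faces
  intag <- f[seq_len(nf), , drop = FALSE]            # reversed region faces
  centUV <- cbind((q[intag[, 1], 1] + q[intag[, 2], 1] + q[intag[, 3], 1]) / 3,
                  (q[intag[, 1], 2] + q[intag[, 2], 2] + q[intag[, 3], 2]) / 3)
  hit <- which(sqrt((centUV[, 1] - c2[1])^2 + (centUV[, 2] - c2[2])^2) <=
                 spec@holeRadius)
  if (!length(hit))
    stop("hole placement error: no plate surface at the hole position")
  if (any(intag[hit, ] %in% sh$boundaryVerts))
    stop("hole placement error: hole channel reaches the plate rim")
  keepI <- setdiff(seq_len(nf), hit)
  newIntag <- intag[keepI, , drop = FALSE]
  newOuter <- f[nf + keepI, , drop = FALSE]
  oldWalls <- f[(2 * nf + 1):nrow(f), , drop = FALSE]
  # rim of the remaining intaglio: directed edges now unmatched
  rim <- local({
    e <- rbind(newIntag[, c(1, 2)], newIntag[, c(2, 3)], newIntag[, c(3, 1)])
    n <- nrow(plate@vertices)
    key <- pmin(e[, 1], e[, 2]) * (n + 1) + pmax(e[, 1], e[, 2])
    cnt <- table(key)
    onHole <- key %in% as.numeric(names(cnt)[cnt == 1])
    # exclude the outer boundary rim (belongs to the old walls)
    eOld <- e[onHole, , drop = FALSE]
    eOld[!(eOld[, 1] %in% sh$boundaryVerts &
             eOld[, 2] %in% sh$boundaryVerts), , drop = FALSE]
  })
  if (nrow(rim) < 3) stop("hole placement error: degenerate hole rim")
  u <- rim[, 1]; vtx <- rim[, 2]
  holeWall <- rbind(cbind(vtx, u, u + nv), cbind(vtx, u + nv, vtx + nv))
  newFaces <- rbind(newIntag, newOuter, oldWalls, holeWall)
  out <- triangleMesh(plate@vertices, newFaces, name = paste0(plate@name, "+hole"),
                      metadata = plate@metadata)
  out@metadata$shell <- NULL  # face blocks no longer contiguous for reuse
  # probe: the hole axis must pass without surface intersection
  wax <- frame@axes[, 3]
  center3 <- frame@origin + frame@axes[, 1] * c2[1] + frame@axes[, 2] * c2[2]
  tseq <- seq(min(q[, 3]) - 5, max(.frameCoords(plate@vertices, frame)[, 3]) + 5,
              length.out = 40)
  probe <- t(vapply(tseq, function(t) center3 + t * wax, numeric(3)))
  if (any(pointsInsideMesh(probe, out)))
    stop("hole placement error: channel is not through-going")
  out
}

#' Taubin smoothing of a plate
#'
#' lambda/mu Taubin fairing (lambda = 0.5, mu = -0.53), which smooths
#' without the shrinkage of plain Laplacian smoothing.  Vertices lying on
#' the intaglio (within 0.15 mm of the reference anatomy, when given) are
#' clamped to at most 0.05 mm displacement so the fit is preserved.
#'
#' All vertices carry a displacement budget (\code{maxDisplacement}) so
#' fairing removes roughness without eroding the plate form.
#'
#' @param plate watertight TriangleMesh
#' @param spec a \linkS4class{PlateSpec}
#' @param reference optional anatomy TriangleMesh whose nearby vertices
#'   are treated as intaglio and clamped
#' @param maxDisplacement displacement budget for non-intaglio vertices (mm)
#' @return smoothed TriangleMesh
#' @export
smoothPlate <- function(plate, spec, reference = NULL,
                        maxDisplacement = 0.2) {
  if (spec@smoothingIterations == 0) return(plate)
  clamp <- rep(maxDisplacement, nrow(plate@vertices))
  if (!is.null(reference)) {
    d <- pointMeshDistance(plate@vertices, reference)
    clamp[d < 0.15] <- 0.05
  } else if (!is.null(plate@metadata$shell)) {
    clamp[seq_len(plate@metadata$shell$nv)] <- 0.05
  }
  v2 <- cpp_taubin_smooth(plate@vertices, plate@faces, 0.5, -0.53,
                          as.integer(spec@smoothingIterations), clamp)
  triangleMesh(v2, plate@faces, name = paste0(plate@name, "+smooth"),
               metadata = plate@metadata)
}

#' Full plate pipeline for one cast
#'
#' bridge -> shell -> ventilation hole -> retention pin -> smoothing,
#' with a \linkS4class{MeshReport} log per stage.  The hole is carved
#' before the pin union because the exact shell surgery requires the
#' structured plate, while the pin union remeshes it.
#'
#' @param cast watertight cast TriangleMesh
#' @param detection its \linkS4class{DetectionResult}
#' @param spec a \linkS4class{PlateSpec}
#' @param targetGap residual bridge channel width (mm)
#' @return list with \code{plate}, \code{stages} (named list of meshes)
#'   and \code{reports} (named list of MeshReports)
#' @export
buildPlatePipeline <- function(cast, detection, spec, targetGap = 0) {
  stages <- list()
  bridged <- if (length(detection@gapSpan))
    bridgeGap(cast, detection, targetGap = targetGap) else cast
  stages$bridged <- bridged
  plate <- buildPlate(bridged, detection, spec)
  stages$plate <- plate
  holed <- addVentilationHole(plate, spec)
  stages$hole <- holed
  pinned <- addRetentionPin(holed, spec)
  stages$pin <- pinned
  smoothed <- smoothPlate(pinned, spec, reference = bridged)
  stages$smooth <- smoothed
  list(plate = smoothed, stages = stages,
       reports = lapply(stages, validateMesh))
}
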