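# Mesh construction, cleaning, validation and geometric primitives.

landmarkNames <- function() c("A", "P", "SA", "SAp", "L", "Lp", "T", "Tp", "SD", "SDp")

#' Construct a TriangleMesh
#'
#' @param vertices n x 3 numeric matrix (mm)
#' @param faces m x 3 matrix of 1-based vertex indices
#' @param name free-text identifier
#' @param metadata optional construction metadata list
#' @param clean merge duplicate vertices and drop degenerate/duplicate
#'   faces (see \code{\link{cleanMesh}})
#' @return a \linkS4class{TriangleMesh}
#' @export
triangleMesh <- function(vertices, faces, name = "", metadata = list(),
                         clean = FALSE) {
  vertices <- matrix(as.numeric(vertices), ncol = 3,
                     nrow = NROW(vertices), dimnames = NULL)
  faces <- matrix(as.integer(faces), ncol = 3, nrow = NROW(faces),
                  dimnames = NULL)
  m <- new("TriangleMesh", vertices = vertices, faces = faces, name = name,
           metadata = metadata)
  if (clean) m <- cleanMesh(m)
  m
}

#' @rdname triangleMesh
#' @param mesh a TriangleMesh
#' @export
meshVertices <- function(mesh) mesh@vertices

#' @rdname triangleMesh
#' @export
meshFaces <- function(mesh) mesh@faces

#' Merge duplicate vertices and drop degenerate faces
#'
#' Vertices closer than \code{tol} are merged (grid-rounding, tolerance
#' well below scanner resolution but above float noise); faces that
#' reference a vertex twice, have (numerically) zero area, or duplicate
#' another face are removed.
#'
#' @param mesh a TriangleMesh
#' @param tol merge tolerance in mm
#' @return cleaned TriangleMesh
#' @export
cleanMesh <- function(mesh, tol = 1e-6) {
  v <- mesh@vertices; f <- mesh@faces
  if (nrow(v) == 0) return(mesh)
  rv <- round(v / tol)
  key <- paste(rv[, 1], rv[, 2], rv[, 3], sep = ",")
  first <- !duplicated(key)
  remap <- match(key, key[first])
  v2 <- v[first, , drop = FALSE]
  if (nrow(f) > 0) {
    f2 <- matrix(remap[f], ncol = 3)
    bad <- f2[, 1] == f2[, 2] | f2[, 1] == f2[, 3] | f2[, 2] == f2[, 3]
    f2 <- f2[!bad, , drop = FALSE]
    if (nrow(f2) > 0) {
      a <- v2[f2[, 1], , drop = FALSE]
      ar <- .rowCross(v2[f2[, 2], , drop = FALSE] - a,
                      v2[f2[, 3], , drop = FALSE] - a)
      area2 <- sqrt(rowSums(ar^2))
      f2 <- f2[area2 > (tol^2), , drop = FALSE]
    }
    if (nrow(f2) > 0) {
      lo <- pmin(f2[, 1], f2[, 2], f2[, 3])
      hi <- pmax(f2[, 1], f2[, 2], f2[, 3])
      mid <- f2[, 1] + f2[, 2] + f2[, 3] - lo - hi
      fk <- paste(lo, mid, hi, sep = "-")
      f2 <- f2[!duplicated(fk), , drop = FALSE]
    }
  } else f2 <- f
  used <- sort(unique(as.vector(f2)))
  if (length(used) && length(used) < nrow(v2)) {
    remap2 <- integer(nrow(v2)); remap2[used] <- seq_along(used)
    v2 <- v2[used, , drop = FALSE]
    f2 <- matrix(remap2[f2], ncol = 3)
  }
  triangleMesh(v2, f2, name = mesh@name, metadata = mesh@metadata)
}

.rowCross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

.faceNormalsArea <- function(mesh) {
  v <- mesh@vertices; f <- mesh@faces
  a <- v[f[, 1], , drop = FALSE]
  cr <- .rowCross(v[f[, 2], , drop = FALSE] - a, v[f[, 3], , drop = FALSE] - a)
  area <- sqrt(rowSums(cr^2)) / 2
  n <- cr / pmax(2 * area, .Machine$double.xmin)
  list(normals = n, area = area)
}

#' Face and vertex normals
#' @param mesh a TriangleMesh
#' @return \code{faceNormals}: m x 3 unit normals; \code{vertexNormals}:
#'   n x 3 area-weighted unit vertex normals
#' @export
faceNormals <- function(mesh) .faceNormalsArea(mesh)$normals

#' @rdname faceNormals
#' @export
vertexNormals <- function(mesh) {
  fa <- .faceNormalsArea(mesh)
  f <- mesh@faces
  n <- matrix(0, nrow(mesh@vertices), 3)
  w <- fa$normals * fa$area
  for (j in 1:3) {
    for (k in 1:3) {
      s <- rowsum(w[, k], f[, j])
      idx <- as.integer(rownames(s))
      n[idx, k] <- n[idx, k] + s
    }
  }
  len <- sqrt(rowSums(n^2))
  n / pmax(len, .Machine$double.xmin)
}

#' Signed mesh volume (tetrahedron sum)
#'
#' Valid as an enclosed volume only for watertight meshes with outward
#' orientation; the signed sum is returned regardless.
#' @param mesh a TriangleMesh
#' @return volume in mm^3
#' @export
meshVolume <- function(mesh) {
  v <- mesh@vertices; f <- mesh@faces
  if (nrow(f) == 0) return(0)
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  ccol <- v[f[, 3], , drop = FALSE]
  sum(rowSums(a * .rowCross(b, ccol))) / 6
}

#' Total surface area
#' @param mesh a TriangleMesh
#' @return area in mm^2
#' @export
meshSurfaceArea <- function(mesh) sum(.faceNormalsArea(mesh)$area)

# directed and undirected edge bookkeeping
.edgeInfo <- function(mesh) {
  f <- mesh@faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  lo <- pmin(e[, 1], e[, 2]); hi <- pmax(e[, 1], e[, 2])
  n <- nrow(mesh@vertices)
  ukey <- lo * (n + 1) + hi
  dkey <- e[, 1] * (n + 1) + e[, 2]
  list(edges = e, ukey = ukey, dkey = dkey)
}

#' Validate a mesh
#'
#' Computes manifoldness, watertightness (every edge shared by exactly two
#' consistently wound faces), boundary loop count, connected components,
#' bounding box, surface area and the signed-tetrahedron volume (reported
#' only when watertight).
#'
#' @param mesh a TriangleMesh
#' @return a \linkS4class{MeshReport}
#' @export
validateMesh <- function(mesh) {
  v <- mesh@vertices; f <- mesh@faces
  if (nrow(f) == 0) {
    return(new("MeshReport", isManifold = FALSE, isWatertight = FALSE,
               nBoundaryLoops = 0L, nComponents = 0L,
               bbox = rbind(rep(NA_real_, 3), rep(NA_real_, 3)),
               volume = NA_real_, surfaceArea = 0))
  }
  ei <- .edgeInfo(mesh)
  uk <- unique(ei$ukey)
  idx <- match(ei$ukey, uk)
  counts <- tabulate(idx, nbins = length(uk))
  # manifold: undirected multiplicity <= 2 and, where 2, opposite directions
  dupDirected <- anyDuplicated(ei$dkey) > 0
  manifold <- all(counts <= 2) && !dupDirected
  boundarySel <- counts[idx] == 1
  watertight <- manifold && !any(boundarySel)
  nLoops <- 0L
  if (any(boundarySel)) {
    be <- ei$edges[boundarySel, , drop = FALSE]
    nLoops <- .countLoops(be)
  }
  comp <- cpp_vertex_components(nrow(v), f)
  usedv <- unique(as.vector(f))
  ncomp <- length(unique(comp[usedv]))
  vol <- if (watertight) meshVolume(mesh) else NA_real_
  new("MeshReport", isManifold = manifold, isWatertight = watertight,
      nBoundaryLoops = as.integer(nLoops), nComponents = as.integer(ncomp),
      bbox = rbind(apply(v, 2, min), apply(v, 2, max)),
      volume = vol, surfaceArea = meshSurfaceArea(mesh))
}

# count closed loops in a set of boundary edges (each vertex degree 2 in
# a clean manifold boundary; stray chains count as one loop each)
.countLoops <- function(edges) {
  if (nrow(edges) == 0) return(0L)
  verts <- unique(as.vector(edges))
  idx <- match(as.vector(edges), verts)
  e <- matrix(idx, ncol = 2)
  p <- seq_along(verts)
  find <- function(i) { while (p[i] != i) { p[i] <<- p[p[i]]; i <- p[i] }; i }
  for (r in seq_len(nrow(e))) {
    a <- find(e[r, 1]); b <- find(e[r, 2])
    if (a != b) p[a] <- b
  }
  length(unique(vapply(seq_along(verts), find, integer(1))))
}

#' Euler characteristic and genus
#' @param mesh a TriangleMesh (genus meaningful for closed connected meshes)
#' @return integer Euler characteristic V - E + F
#' @export
eulerCharacteristic <- function(mesh) {
  f <- mesh@faces
  if (nrow(f) == 0) return(0L)
  ei <- .edgeInfo(mesh)
  nV <- length(unique(as.vector(f)))
  nE <- length(unique(ei$ukey))
  as.integer(nV - nE + nrow(f))
}

#' @rdname eulerCharacteristic
#' @export
meshGenus <- function(mesh) as.integer((2L - eulerCharacteristic(mesh)) / 2L)

#' Rigidly transform or scale a mesh
#' @param mesh a TriangleMesh
#' @param rotation 3 x 3 rotation matrix
#' @param translation length-3 vector (mm)
#' @param scale scalar scale factor
#' @return transformed TriangleMesh
#' @export
transformMesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0),
                          scale = 1) {
  v <- scale * (mesh@vertices %*% t(rotation))
  v <- sweep(v, 2, translation, "+")
  triangleMesh(v, mesh@faces, name = mesh@name, metadata = mesh@metadata)
}

#' Voxel-integrated volume (independent of the tetrahedron sum)
#'
#' Integrates the solid column-wise on a regular xy grid by ray casting;
#' used as an independent volume oracle for boolean operations.
#' @param mesh a watertight TriangleMesh
#' @param pitch grid pitch in mm
#' @return volume in mm^3
#' @export
voxelVolume <- function(mesh, pitch = 0.2) {
  v <- mesh@vertices
  lo <- apply(v, 2, min) - pitch
  hi <- apply(v, 2, max) + pitch
  nx <- max(2L, ceiling((hi[1] - lo[1]) / pitch) + 1L)
  ny <- max(2L, ceiling((hi[2] - lo[2]) / pitch) + 1L)
  cr <- cpp_column_crossings(v, mesh@faces, lo[1], lo[2], pitch, nx, ny)
  cpp_column_volume(cr, pitch)
}

#' Minimum distance from points to a mesh surface
#' @param points n x 3 matrix
#' @param mesh a TriangleMesh
#' @return numeric vector of distances (mm)
#' @export
pointMeshDistance <- function(points, mesh) {
  points <- matrix(as.numeric(points), ncol = 3)
  cpp_point_mesh_distance_fast(points, mesh@vertices, mesh@faces)
}

#' Are points inside a watertight mesh?
#' @param points n x 3 matrix
#' @param mesh a watertight TriangleMesh
#' @return logical vector
#' @export
pointsInsideMesh <- function(points, mesh) {
  points <- matrix(as.numeric(points), ncol = 3)
  # deterministic jitter dodges exact edge/vertex ray hits
  points[, 1] <- points[, 1] + 1.23e-7
  points[, 2] <- points[, 2] + 3.17e-7
  cpp_points_inside(points, mesh@vertices, mesh@faces)
}

# ---- primitives ------------------------------------------------------------

#' Geometric primitives
#'
#' Axis-aligned box, capped cylinder and icosphere meshes, watertight with
#' outward orientation.
#'
#' @param min,max box corners (length-3, mm)
#' @return a watertight TriangleMesh
#' @export
meshBox <- function(min = c(0, 0, 0), max = c(1, 1, 1)) {
  g <- as.matrix(expand.grid(x = c(min[1], max[1]), y = c(min[2], max[2]),
                             z = c(min[3], max[3])))
  # vertex order: binary xyz
  quads <- rbind(
    c(1, 3, 4, 2),  # z = min, outward -z
    c(5, 6, 8, 7),  # z = max
    c(1, 2, 6, 5),  # y = min
    c(3, 7, 8, 4),  # y = max
    c(1, 5, 7, 3),  # x = min
    c(2, 4, 8, 6))  # x = max
  f <- do.call(rbind, lapply(seq_len(nrow(quads)), function(i) {
    q <- quads[i, ]
    rbind(q[c(1, 2, 3)], q[c(1, 3, 4)])
  }))
  triangleMesh(g, f, name = "box")
}

#' @rdname meshBox
#' @param base center of the bottom cap (length-3)
#' @param axis cylinder axis direction (length-3)
#' @param radius cylinder radius (mm)
#' @param length cylinder length (mm)
#' @param n number of circumferential segments
#' @export
meshCylinder <- function(base = c(0, 0, 0), axis = c(0, 0, 1), radius = 1,
                         length = 1, n = 32) {
  axis <- axis / sqrt(sum(axis^2))
  # orthonormal basis
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- ref - sum(ref * axis) * axis; u <- u / sqrt(sum(u^2))
  w <- c(axis[2] * u[3] - axis[3] * u[2],
         axis[3] * u[1] - axis[1] * u[3],
         axis[1] * u[2] - axis[2] * u[1])
  th <- 2 * pi * (seq_len(n) - 1) / n
  ring <- outer(cos(th), u) + outer(sin(th), w)
  bot <- sweep(radius * ring, 2, base, "+")
  top <- sweep(bot, 2, length * axis, "+")
  cb <- base; ct <- base + length * axis
  v <- rbind(bot, top, cb, ct)
  ib <- seq_len(n); it <- n + seq_len(n); icb <- 2 * n + 1; ict <- 2 * n + 2
  nx <- c(seq_len(n)[-1], 1)
  side <- rbind(cbind(ib, ib[nx], it[nx]), cbind(ib, it[nx], it))
  capb <- cbind(icb, ib[nx], ib)
  capt <- cbind(ict, it, it[nx])
  triangleMesh(v, rbind(side, capb, capt), name = "cylinder")
}

#' @rdname meshBox
#' @param center sphere center (length-3)
#' @param refine number of 4-to-1 subdivision rounds of the icosahedron
#' @export
meshIcosphere <- function(center = c(0, 0, 0), radius = 1, refine = 3) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (r in seq_len(refine)) {
    mid <- new.env(hash = TRUE)
    vlist <- lapply(seq_len(nrow(v)), function(i) v[i, ])
    getMid <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      id <- mid[[key]]
      if (!is.null(id)) return(id)
      m <- (vlist[[i]] + vlist[[j]]) / 2
      m <- m / sqrt(sum(m^2))
      vlist[[length(vlist) + 1]] <<- m
      id <- length(vlist)
      mid[[key]] <- id
      id
    }
    nf <- matrix(0L, nrow(f) * 4, 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- getMid(a, b); bc <- getMid(b, cc); ca <- getMid(cc, a)
      nf[(i - 1) * 4 + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                       c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- do.call(rbind, vlist); f <- nf
  }
  triangleMesh(sweep(radius * v, 2, center, "+"), f, name = "icosphere")
}
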