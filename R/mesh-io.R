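# Mesh and landmark file input/output.
#
# STL binary: 80-byte header, uint32 triangle count, then per-triangle
# 12 float32 (normal + 3 vertices) + uint16 attribute.  STL ASCII and a
# minimal OBJ (v/f records) are also supported.  Landmarks travel in
# sidecar JSON ([{"name":"SA","x":..,"y":..,"z":..}]) or CSV
# (header name,x,y,z); primed landmark names use the ASCII suffix "p".

#' Read a triangle mesh (STL binary/ASCII or OBJ)
#'
#' The mesh is cleaned on read: duplicate vertices are merged at 1e-6 mm
#' and degenerate faces dropped.  Coordinates are interpreted in mm;
#' \code{units} rescales on read.
#'
#' @param path file path
#' @param units one of "mm", "cm", "m", or a numeric scale factor to mm
#' @return a \linkS4class{TriangleMesh}
#' @export
readMesh <- function(path, units = "mm") {
  if (!file.exists(path)) stop("file not found: ", path)
  scale <- if (is.numeric(units)) units else
    switch(units, mm = 1, cm = 10, m = 1000,
           stop("unknown units: ", units))
  ext <- tolower(tools::file_ext(path))
  mesh <- if (ext == "obj") .readOBJ(path) else .readSTL(path)
  if (nrow(mesh@faces) == 0) stop("empty mesh: ", path)
  if (scale != 1)
    mesh <- triangleMesh(mesh@vertices * scale, mesh@faces, name = mesh@name)
  cleanMesh(mesh)
}

.readSTL <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb"); on.exit(close(con))
  head <- readBin(con, "raw", n = min(sz, 80))
  headTxt <- rawToChar(head[head != as.raw(0)])
  isAscii <- grepl("^\\s*solid", headTxt)
  if (isAscii && sz > 84) {
    # binary files may also start with "solid": check the count arithmetic
    cntRaw <- readBin(con, "integer", n = 1, size = 4, endian = "little")
    if (!is.na(cntRaw) && sz == 84 + 50 * as.numeric(cntRaw)) isAscii <- FALSE
  }
  close(con); on.exit(NULL)
  if (isAscii) return(.readSTLAscii(path))
  if (sz < 84) stop("truncated STL (file size ", sz, " < 84 bytes)")
  con <- file(path, "rb"); on.exit(close(con))
  invisible(readBin(con, "raw", n = 80))
  n <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  expect <- 84 + 50 * as.numeric(n)
  if (sz != expect)
    stop("truncated/corrupt binary STL: expected ", expect,
         " bytes for ", n, " triangles, found ", sz,
         " (failure at byte offset ", min(sz, expect), ")")
  raw <- readBin(con, "raw", n = 50 * n)
  dim(raw) <- c(50, n)
  flo <- readBin(as.vector(raw[1:48, ]), "numeric", n = 12 * n, size = 4,
                 endian = "little")
  tri <- matrix(flo, nrow = 12)  # per column: normal(3), v1, v2, v3
  verts <- matrix(as.vector(tri[4:12, ]), ncol = 3, byrow = TRUE)
  faces <- matrix(seq_len(3 * n), ncol = 3, byrow = TRUE)
  triangleMesh(verts, faces, name = basename(path))
}

.readSTLAscii <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
  if (length(vl) == 0) stop("no vertices in ASCII STL: ", path)
  if (length(vl) %% 3 != 0)
    stop("corrupt ASCII STL (vertex count ", length(vl),
         " not a multiple of 3): ", path)
  nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p) {
    x <- suppressWarnings(as.numeric(p[2:4]))
    if (anyNA(x)) stop("unparseable vertex line in ", path)
    x
  }))
  faces <- matrix(seq_len(nrow(nums)), ncol = 3, byrow = TRUE)
  triangleMesh(nums, faces, name = basename(path))
}

.readOBJ <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vl <- txt[startsWith(txt, "v ")]
  fl <- txt[startsWith(txt, "f ")]
  v <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
    as.numeric(p[2:4])))
  f <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(p) {
    idx <- as.integer(vapply(strsplit(p[-1], "/"), `[`, character(1), 1))
    if (length(idx) != 3) stop("only triangular OBJ faces are supported")
    idx
  }))
  if (is.null(v)) v <- matrix(numeric(0), 0, 3)
  if (is.null(f)) f <- matrix(integer(0), 0, 3)
  triangleMesh(v, f, name = basename(path))
}

#' Write a triangle mesh
#'
#' Round trip read(write(m)) preserves topology exactly and coordinates to
#' 1e-5 mm (binary STL stores float32).
#'
#' @param mesh a non-empty TriangleMesh
#' @param path output path
#' @param format "stl-binary", "stl-ascii" or "obj"
#' @return \code{path}, invisibly
#' @export
writeMesh <- function(mesh, path, format = c("stl-binary", "stl-ascii", "obj")) {
  format <- match.arg(format)
  if (nrow(mesh@faces) == 0) stop("refusing to write an empty mesh")
  v <- mesh@vertices; f <- mesh@faces
  fn <- .faceNormalsArea(mesh)$normals
  if (format == "stl-binary") {
    con <- file(path, "wb"); on.exit(close(con))
    writeBin(c(charToRaw(sprintf("%-79s", substr(paste0("namplate ", mesh@name), 1, 79))), as.raw(0)), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    tri <- rbind(t(fn), t(v[f[, 1], , drop = FALSE]),
                 t(v[f[, 2], , drop = FALSE]), t(v[f[, 3], , drop = FALSE]))
    raw12 <- writeBin(as.vector(tri), raw(), size = 4, endian = "little")
    dim(raw12) <- c(48, nrow(f))
    attrib <- matrix(as.raw(0), 2, nrow(f))
    writeBin(as.vector(rbind(raw12, attrib)), con)
  } else if (format == "stl-ascii") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(paste("solid", mesh@name), con)
    for (i in seq_len(nrow(f))) {
      writeLines(c(sprintf("  facet normal %.9g %.9g %.9g", fn[i, 1], fn[i, 2], fn[i, 3]),
                   "    outer loop",
                   sprintf("      vertex %.9g %.9g %.9g",
                           v[f[i, ], 1], v[f[i, ], 2], v[f[i, ], 3]),
                   "    endloop", "  endfacet"), con)
    }
    writeLines(paste("endsolid", mesh@name), con)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  }
  invisible(path)
}

# ---- landmarks -------------------------------------------------------------

#' Read and write landmark files
#'
#' JSON (a list of objects with fields name, x, y, z) or CSV with header
#' \code{name,x,y,z}.  Only the ten stored landmark names are accepted;
#' MT is derived, never stored.  Round trips are exact to 1e-9 mm.
#'
#' @param path landmark file (.json or .csv)
#' @return a \linkS4class{LandmarkSet} if all ten landmarks are present,
#'   otherwise a named list of 3D points
#' @export
readLandmarks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    rec <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    if (!all(c("name", "x", "y", "z") %in% names(rec)))
      stop("landmark JSON must have fields name, x, y, z")
    df <- data.frame(name = as.character(rec$name), x = rec$x, y = rec$y,
                     z = rec$z, stringsAsFactors = FALSE)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!identical(names(df)[1:4], c("name", "x", "y", "z")))
      stop("landmark CSV must have header name,x,y,z")
  }
  if (anyNA(df[, c("x", "y", "z")]))
    stop("missing coordinate in landmark file: ", path)
  bad <- setdiff(df$name, landmarkNames())
  if (length(bad))
    stop("unknown landmark name(s): ", paste(bad, collapse = ", "),
         if ("MT" %in% bad) " (MT is derived, never stored)" else "")
  if (anyDuplicated(df$name))
    stop("duplicate landmark name(s): ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
  pts <- lapply(seq_len(nrow(df)), function(i) c(df$x[i], df$y[i], df$z[i]))
  names(pts) <- df$name
  if (all(landmarkNames() %in% df$name)) return(landmarkSet(pts))
  pts
}

#' @rdname readLandmarks
#' @param landmarks a \linkS4class{LandmarkSet} or named list of 3D points
#' @param format "json" or "csv" (default from file extension)
#' @export
writeLandmarks <- function(landmarks, path, format = NULL) {
  if (is(landmarks, "LandmarkSet")) {
    p <- landmarks@points
    df <- data.frame(name = rownames(p), x = p[, 1], y = p[, 2], z = p[, 3],
                     stringsAsFactors = FALSE)
  } else {
    if ("MT" %in% names(landmarks))
      stop("MT is derived and is never stored in landmark files")
    df <- data.frame(name = names(landmarks),
                     x = vapply(landmarks, `[`, numeric(1), 1),
                     y = vapply(landmarks, `[`, numeric(1), 2),
                     z = vapply(landmarks, `[`, numeric(1), 3),
                     stringsAsFactors = FALSE)
  }
  if (is.null(format))
    format <- if (tolower(tools::file_ext(path)) == "csv") "csv" else "json"
  if (format == "json") {
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  } else {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
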