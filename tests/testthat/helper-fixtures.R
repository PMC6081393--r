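# Shared fixtures: programmatic STL files and cached synthetic anatomies.

.fixtureCache <- new.env(parent = emptyenv())

# default synthetic maxilla + detection, generated once per test run
fixtureMaxilla <- function(resolution = 0.8) {
  key <- sprintf("maxilla-%g", resolution)
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- generateCleftMaxilla(
      anatomyParams(resolution = resolution))
  .fixtureCache[[key]]
}

fixtureDetection <- function(resolution = 0.8) {
  key <- sprintf("det-%g", resolution)
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- detectRidge(fixtureMaxilla(resolution)$mesh)
  .fixtureCache[[key]]
}

fixturePlate <- function() {
  if (is.null(.fixtureCache$plate)) {
    gen <- fixtureMaxilla()
    det <- fixtureDetection()
    br <- bridgeGap(gen$mesh, det)
    .fixtureCache$plate <- list(
      bridged = br,
      plate = buildPlate(br, det, plateSpec(voxelPitch = 0.3)))
  }
  .fixtureCache$plate
}

# write a unit cube as binary STL, optionally duplicating some facets
writeCubeSTLBinary <- function(path, duplicate = 0) {
  cube <- meshBox(c(0, 0, 0), c(1, 1, 1))
  v <- meshVertices(cube); f <- meshFaces(cube)
  if (duplicate > 0) f <- rbind(f, f[seq_len(duplicate), , drop = FALSE])
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(rep(as.raw(0), 80), con)
  writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
  for (i in seq_len(nrow(f))) {
    tri <- rbind(c(0, 0, 0), v[f[i, 1], ], v[f[i, 2], ], v[f[i, 3], ])
    writeBin(as.vector(t(tri)), con, size = 4, endian = "little")
    writeBin(as.raw(c(0, 0)), con)
  }
  invisible(path)
}

writeCubeSTLAscii <- function(path) {
  cube <- meshBox(c(0, 0, 0), c(1, 1, 1))
  writeMesh(cube, path, format = "stl-ascii")
  invisible(path)
}

# exact sample points on an ellipse (no noise)
ellipseSample <- function(n, a, b, theta = 0, center = c(0, 0),
                          tmax = 2 * pi) {
  t <- seq(0, tmax, length.out = n + 1)[-(n + 1)]
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  pts <- cbind(a * cos(t), b * sin(t)) %*% t(R)
  sweep(pts, 2, center, "+")
}

randomRotation <- function(seed) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# brute-force exact signed-rank two-sided p over all 2^n sign vectors
signedRankEnumeration <- function(pre, post) {
  d <- post - pre
  d <- d[d != 0]
  r <- rank(abs(d))
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.vector(signs %*% r)
  EW <- sum(r) / 2
  W <- sum(r[d > 0])
  mean(abs(Ws - EW) >= abs(W - EW) - 1e-9)
}

# brute-force exact rank-sum two-sided p over all C(N, n1) assignments
rankSumEnumeration <- function(g1, g2) {
  n1 <- length(g1); N <- n1 + length(g2)
  r <- rank(c(g1, g2))
  E <- n1 * (N + 1) / 2
  W <- sum(r[seq_len(n1)])
  Ws <- apply(combn(N, n1), 2, function(i) sum(r[i]))
  mean(abs(Ws - E) >= abs(W - E) - 1e-9)
}
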