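# Central S4 containers.  All coordinates are millimetres.

#' Indexed triangle mesh
#'
#' Carrier of maxillary casts, bridged models and molding plates.
#' Vertices are an n x 3 numeric matrix in mm, faces an m x 3 integer
#' matrix of 1-based vertex indices.  The optional \code{metadata} list
#' carries construction information (e.g. shell structure of a plate);
#' it is not part of the geometric identity of the object.
#'
#' @slot vertices numeric matrix, n x 3, mm
#' @slot faces integer matrix, m x 3, 1-based vertex indices
#' @slot name free-text identifier
#' @slot metadata list of construction metadata
#' @export
setClass("TriangleMesh",
  representation(vertices = "matrix", faces = "matrix",
                 name = "character", metadata = "list"),
  prototype(vertices = matrix(numeric(0), 0, 3),
            faces = matrix(integer(0), 0, 3),
            name = "", metadata = list()),
  validity = function(object) {
    v <- object@vertices; f <- object@faces
    if (ncol(v) != 3) return("vertices must have 3 columns")
    if (ncol(f) != 3) return("faces must have 3 columns")
    if (nrow(f) > 0) {
      if (!is.numeric(f)) return("faces must be numeric/integer")
      if (min(f) < 1 || max(f) > nrow(v))
        return("face index out of range")
      if (any(f[, 1] == f[, 2] | f[, 1] == f[, 3] | f[, 2] == f[, 3]))
        return("face references the same vertex twice")
    }
    TRUE
  })

#' Mesh validation report
#'
#' @slot isManifold every edge shared by at most two faces, with the two
#'   incident faces traversing it in opposite directions
#' @slot isWatertight closed 2-manifold (no boundary edges)
#' @slot nBoundaryLoops number of boundary loops
#' @slot nComponents number of connected components
#' @slot bbox 2 x 3 matrix (min and max corner, mm)
#' @slot volume signed-tetrahedron volume in mm^3 (NA unless watertight)
#' @slot surfaceArea total face area in mm^2
#' @export
setClass("MeshReport",
  representation(isManifold = "logical", isWatertight = "logical",
                 nBoundaryLoops = "integer", nComponents = "integer",
                 bbox = "matrix", volume = "numeric", surfaceArea = "numeric"))

#' Fitted dental-arch ellipse in the occlusal plane
#'
#' Parameters of the alveolar-arch ellipse: center in occlusal-plane
#' (u, v) coordinates, semi-major axis \code{a}, semi-minor axis
#' \code{b}, and major-axis rotation \code{theta} in radians,
#' canonicalized to [0, pi).
#'
#' @slot center numeric length 2 (mm)
#' @slot a semi-major axis (mm)
#' @slot b semi-minor axis (mm)
#' @slot theta rotation of the major axis (radians in [0, pi))
#' @export
setClass("EllipseParams",
  representation(center = "numeric", a = "numeric", b = "numeric",
                 theta = "numeric"),
  validity = function(object) {
    if (length(object@center) != 2) return("center must have length 2")
    if (!(object@a >= object@b && object@b > 0)) return("need a >= b > 0")
    if (object@theta < 0 || object@theta >= pi)
      return("theta must lie in [0, pi)")
    TRUE
  })

#' Occlusal reference frame
#'
#' Right-handed orthonormal frame estimated from a cast: \code{u}, \code{v}
#' span the occlusal plane, \code{w} is the occlusal normal oriented so
#' that the alveolar crest has larger w-coordinate than the palatal vault.
#'
#' @slot origin numeric length 3 (mm)
#' @slot axes 3 x 3 matrix with columns u, v, w
#' @export
setClass("OcclusalFrame",
  representation(origin = "numeric", axes = "matrix"),
  validity = function(object) {
    if (length(object@origin) != 3) return("origin must have length 3")
    A <- object@axes
    if (!all(dim(A) == c(3, 3))) return("axes must be 3 x 3")
    if (max(abs(crossprod(A) - diag(3))) > 1e-9)
      return("axes must be orthonormal to 1e-9")
    if (det(A) < 0) return("axes must be right-handed")
    TRUE
  })

#' Detected alveolar crest polyline
#'
#' @slot points n x 3 matrix of crest points on the cast surface (mm)
#' @slot segmentLabel "greater" or "smaller"
#' @slot arcParam strictly monotone arc parameter (radians)
#' @export
setClass("CrestCurve",
  representation(points = "matrix", segmentLabel = "character",
                 arcParam = "numeric"),
  validity = function(object) {
    if (nrow(object@points) != length(object@arcParam))
      return("points and arcParam lengths differ")
    if (length(object@arcParam) > 1) {
      d <- diff(object@arcParam)
      if (!(all(d > 0) || all(d < 0))) return("arcParam must be strictly monotone")
    }
    if (!object@segmentLabel %in% c("greater", "smaller"))
      return("segmentLabel must be 'greater' or 'smaller'")
    TRUE
  })

#' Result of automatic alveolar-ridge detection
#'
#' Composes the occlusal frame, crest polylines, fitted ellipse, geometric
#' fit residual and the angular extent of the cleft gap.  Serializable to
#' JSON so a user can confirm or correct the detection by editing the file
#' and re-running downstream stages.
#'
#' @slot frame an \linkS4class{OcclusalFrame}
#' @slot crests list of \linkS4class{CrestCurve}
#' @slot ellipse an \linkS4class{EllipseParams}
#' @slot rmsResidual RMS point-to-ellipse distance (mm)
#' @slot gapSpan numeric length 0 (no cleft) or 2: start/end arc angles of
#'   the cleft interval, radians about the ellipse center
#' @export
setClass("DetectionResult",
  representation(frame = "OcclusalFrame", crests = "list",
                 ellipse = "EllipseParams", rmsResidual = "numeric",
                 gapSpan = "numeric"),
  validity = function(object) {
    if (object@rmsResidual < 0) return("rmsResidual must be >= 0")
    if (!length(object@gapSpan) %in% c(0L, 2L))
      return("gapSpan must have length 0 or 2")
    if (!all(vapply(object@crests, is, logical(1), class2 = "CrestCurve")))
      return("crests must be CrestCurve objects")
    TRUE
  })

#' Named anatomical landmarks of the cleft maxilla
#'
#' Ten stored landmarks: A (most anterior point of the greater segment),
#' P (papilla incisiva), SA/SAp (shortest connection over the anterior
#' cleft), L/Lp (sulcus lateralis), T/Tp (tubera), SD/SDp (shortest
#' connection over the posterior hard-palate cleft).  Primed names use the
#' ASCII suffix "p".  MT, the midpoint of the T-Tp line, is always derived
#' via \code{\link{landmarkMT}} and never stored.
#'
#' @slot points 10 x 3 numeric matrix with rownames A, P, SA, SAp, L, Lp,
#'   T, Tp, SD, SDp (mm)
#' @export
setClass("LandmarkSet",
  representation(points = "matrix"),
  validity = function(object) {
    p <- object@points
    if (!identical(rownames(p), landmarkNames()))
      return(paste("rownames must be exactly:",
                   paste(landmarkNames(), collapse = ", ")))
    if (ncol(p) != 3 || !is.numeric(p) || anyNA(p))
      return("points must be a complete 10 x 3 numeric matrix")
    TRUE
  })

#' Parameters of the synthetic neonatal cleft maxilla
#'
#' The generator sweeps an alveolar ridge of Gaussian cross-section along
#' a planar ellipse arc, interrupts it over the cleft span, depresses the
#' palatal vault inside the arch and closes the solid with a flat base.
#'
#' @slot ellipseA anterior-posterior semi-axis (mm)
#' @slot ellipseB transversal semi-axis (mm)
#' @slot ridgeHeight crest elevation above the palatal plateau (mm)
#' @slot ridgeHalfwidth alveolar ridge half-thickness (mm)
#' @slot cleftWidth target SA-SAp gap (mm, >= 0; 0 means no cleft)
#' @slot cleftAngle angular position of the cleft center on the arch
#'   (degrees from the anterior midline, positive = patient's left)
#' @slot segmentShift lateral+vertical displacement of the smaller
#'   segment (mm, length-3 vector)
#' @slot palateDepth vault depression (mm)
#' @slot resolution target edge length (mm)
#' @slot noiseSigma Gaussian vertex jitter along the surface normal (mm)
#' @slot seed RNG seed
#' @slot archSpan half-span of the arch arc (degrees; the arch covers
#'   -archSpan..archSpan with tubera at the ends)
#' @slot sdWidening how much wider the posterior hard-palate cleft
#'   (SD-SDp) is than the anterior cleft (mm)
#' @export
setClass("AnatomyParams",
  representation(ellipseA = "numeric", ellipseB = "numeric",
                 ridgeHeight = "numeric", ridgeHalfwidth = "numeric",
                 cleftWidth = "numeric", cleftAngle = "numeric",
                 segmentShift = "numeric", palateDepth = "numeric",
                 resolution = "numeric", noiseSigma = "numeric",
                 seed = "numeric", archSpan = "numeric",
                 sdWidening = "numeric"),
  validity = function(object) {
    pos <- c(ellipseA = object@ellipseA, ellipseB = object@ellipseB,
             ridgeHeight = object@ridgeHeight,
             ridgeHalfwidth = object@ridgeHalfwidth,
             palateDepth = object@palateDepth,
             resolution = object@resolution, archSpan = object@archSpan)
    if (any(pos <= 0))
      return(paste("must be > 0:", paste(names(pos)[pos <= 0], collapse = ", ")))
    if (object@cleftWidth < 0) return("cleftWidth must be >= 0")
    if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
    if (length(object@segmentShift) != 3) return("segmentShift must have length 3")
    if (object@archSpan >= 180) return("archSpan must be < 180 degrees")
    TRUE
  })

#' Ground truth of a generated synthetic maxilla
#'
#' @slot landmarks a \linkS4class{LandmarkSet} placed by construction
#' @slot ellipse the true arch \linkS4class{EllipseParams} in the occlusal
#'   plane
#' @slot crest list of per-segment crest polylines (n x 3 matrices whose
#'   points are mesh vertices)
#' @slot occlusalNormal unit length-3 vector
#' @export
setClass("GroundTruth",
  representation(landmarks = "LandmarkSet", ellipse = "EllipseParams",
                 crest = "list", occlusalNormal = "numeric"),
  validity = function(object) {
    if (abs(sqrt(sum(object@occlusalNormal^2)) - 1) > 1e-9)
      return("occlusalNormal must be a unit vector")
    TRUE
  })

#' Molding-plate construction parameters
#'
#' Dimensional defaults are clinical placeholders: the plate thickness and
#' the pin/hole dimensions are configuration values, not measured ones.
#'
#' @slot thickness shell thickness (mm)
#' @slot trimHeight how far below the crest the vestibular skirt of the
#'   plate extends (mm, measured along the occlusal normal)
#' @slot pinRadius retention pin radius (mm)
#' @slot pinLength retention pin length (mm)
#' @slot pinPosition arc angle of the pin base on the ellipse (radians,
#'   0 = anterior midline)
#' @slot pinElevation pin axis elevation above the occlusal plane (degrees)
#' @slot holeRadius ventilation hole radius (mm)
#' @slot holeArc arc angle of the ventilation hole (radians)
#' @slot holeInset radial position of the hole center as a fraction of the
#'   local ellipse radius (0 = arch center, 1 = on the crest)
#' @slot smoothingIterations Taubin iterations for the final smoothing
#' @slot smoothingMethod only "taubin"
#' @slot voxelPitch grid pitch of the voxel-backed boolean engine (mm)
#' @export
setClass("PlateSpec",
  representation(thickness = "numeric", trimHeight = "numeric",
                 pinRadius = "numeric", pinLength = "numeric",
                 pinPosition = "numeric", pinElevation = "numeric",
                 holeRadius = "numeric", holeArc = "numeric",
                 holeInset = "numeric", smoothingIterations = "numeric",
                 smoothingMethod = "character", voxelPitch = "numeric"),
  validity = function(object) {
    if (object@thickness <= 0) return("thickness must be > 0")
    if (object@smoothingMethod != "taubin")
      return("smoothingMethod must be 'taubin'")
    if (object@smoothingIterations < 0)
      return("smoothingIterations must be >= 0")
    if (object@voxelPitch <= 0) return("voxelPitch must be > 0")
    TRUE
  })

#' Faces selected for bridging on the two alveolar segments
#'
#' @slot greaterFaces integer face indices on the greater segment
#' @slot smallerFaces integer face indices on the smaller segment
#' @export
setClass("BridgeRegions",
  representation(greaterFaces = "integer", smallerFaces = "integer"),
  validity = function(object) {
    if (length(object@greaterFaces) == 0 || length(object@smallerFaces) == 0)
      return("both regions must be non-empty")
    if (length(intersect(object@greaterFaces, object@smallerFaces)) > 0)
      return("regions must be disjoint")
    TRUE
  })

#' Growth model for plate series planning
#'
#' \code{g} is the monthly relative growth fraction applied to the arch
#' ellipse axes.  The default of 0.02/month is explicitly a documented
#' placeholder: the underlying longitudinal growth value belongs to
#' anatomical reference data that is not shipped with this package, so
#' any real clinical use must supply a measured value.
#'
#' @slot g monthly relative growth fraction (> -1)
#' @slot nPlates number of plates in the series (default 6)
#' @slot intervalWeeks weeks between consecutive plates
#' @slot closureSchedule "linear": fraction of the initial gap remaining
#'   at plate k is (nPlates - k) / (nPlates - 1), reaching 0 at the last
#'   plate
#' @export
setClass("GrowthModel",
  representation(g = "numeric", nPlates = "numeric",
                 intervalWeeks = "numeric", closureSchedule = "character"),
  validity = function(object) {
    if (object@g <= -1) return("g must be > -1")
    if (object@nPlates < 1) return("nPlates must be >= 1")
    if (object@intervalWeeks <= 0) return("intervalWeeks must be > 0")
    if (object@closureSchedule != "linear")
      return("closureSchedule must be 'linear'")
    TRUE
  })

# ---- show methods ----------------------------------------------------------

setMethod("show", "TriangleMesh", function(object) {
  cat("TriangleMesh", if (nzchar(object@name)) sQuote(object@name) else "",
      "\n  ", nrow(object@vertices), "vertices,", nrow(object@faces),
      "faces\n")
})

setMethod("show", "MeshReport", function(object) {
  cat("MeshReport\n",
      "  manifold:      ", object@isManifold, "\n",
      "  watertight:    ", object@isWatertight, "\n",
      "  boundary loops:", object@nBoundaryLoops, "\n",
      "  components:    ", object@nComponents, "\n",
      "  surface area:  ", format(object@surfaceArea), "mm^2\n",
      "  volume:        ", format(object@volume), "mm^3\n")
})

setMethod("show", "EllipseParams", function(object) {
  cat(sprintf("EllipseParams: center (%.3f, %.3f) mm, a = %.3f, b = %.3f, theta = %.4f rad\n",
              object@center[1], object@center[2], object@a, object@b, object@theta))
})

setMethod("show", "DetectionResult", function(object) {
  cat("DetectionResult\n  crest segments:", length(object@crests),
      "\n  rms residual:", format(object@rmsResidual), "mm\n  gap:",
      if (length(object@gapSpan)) sprintf("[%.3f, %.3f] rad", object@gapSpan[1],
                                          object@gapSpan[2]) else "none", "\n")
})

setMethod("show", "LandmarkSet", function(object) {
  cat("LandmarkSet (10 stored landmarks + derived MT)\n")
  print(round(object@points, 3))
})
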