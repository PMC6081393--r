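# Growth-driven plate series: plan target ellipses and residual gaps,
# warp the cast's crest region to each target, and run the plate
# pipeline per plate.

#' Construct a growth model
#'
#' @param g monthly relative growth fraction (default 0.02 is a
#'   documented placeholder, not a measured value)
#' @param nPlates number of plates (default 6)
#' @param intervalWeeks weeks between consecutive plates (default 2)
#' @param closureSchedule "linear" (fraction of the initial gap remaining
#'   at plate k is (nPlates - k)/(nPlates - 1), reaching 0 at the last
#'   plate) or "none" (no virtual closure)
#' @return a \linkS4class{GrowthModel}
#' @export
growthModel <- function(g = 0.02, nPlates = 6, intervalWeeks = 2,
                        closureSchedule = c("linear", "none")) {
  closureSchedule <- match.arg(closureSchedule)
  gm <- new("GrowthModel", g = g, nPlates = nPlates,
            intervalWeeks = intervalWeeks,
            closureSchedule = closureSchedule)
  validObject(gm)
  gm
}

setValidity("GrowthModel", function(object) {
  if (object@g <= -1) return("g must be > -1")
  if (object@nPlates < 1) return("nPlates must be >= 1")
  if (object@intervalWeeks <= 0) return("intervalWeeks must be > 0")
  if (!object@closureSchedule %in% c("linear", "none"))
    return("closureSchedule must be 'linear' or 'none'")
  TRUE
})

.WEEKS_PER_MONTH <- 365.25 / 12 / 7   # 4.345

#' Remaining-gap fraction at plate k
#' @param model a \linkS4class{GrowthModel}
#' @param k plate index (1-based)
#' @return fraction of the initial gap remaining (0..1)
#' @export
closureFraction <- function(model, k) {
  if (model@closureSchedule == "none") return(rep(1, length(k)))
  n <- model@nPlates
  if (n == 1) return(rep(0, length(k)))
  pmax(0, (n - k) / (n - 1))
}

#' Plan a plate series (targets only)
#'
#' Plate k targets the detected ellipse scaled by
#' (1 + g)^(k * intervalWeeks / 4.345) (month = 365.25/12/7 weeks) and a
#' residual gap of initial gap x closure fraction.  Deterministic.
#'
#' @param detection a \linkS4class{DetectionResult}
#' @param model a \linkS4class{GrowthModel}
#' @return a \code{SeriesManifest}: data.frame with columns index,
#'   growthFactor, targetA, targetB, targetGap, file, volume, watertight
#' @export
planSeries <- function(detection, model) {
  k <- seq_len(model@nPlates)
  fac <- (1 + model@g)^(k * model@intervalWeeks / .WEEKS_PER_MONTH)
  gap0 <- gapChordWidth(detection)
  mf <- data.frame(index = k, growthFactor = fac,
                   targetA = detection@ellipse@a * fac,
                   targetB = detection@ellipse@b * fac,
                   targetGap = gap0 * closureFraction(model, k),
                   file = NA_character_, volume = NA_real_,
                   watertight = NA)
  class(mf) <- c("SeriesManifest", "data.frame")
  mf
}

#' Radially warp a cast's crest region to a scaled arch ellipse
#'
#' In-plane radial scaling about the detected ellipse center, blended
#' from no displacement at the palatal center to full scaling at and
#' beyond the crest; the warp realizes passive growth guidance of the
#' arch without rotating the segments.
#'
#' @param mesh cast TriangleMesh
#' @param detection its \linkS4class{DetectionResult}
#' @param factor in-plane scale factor applied at the crest
#' @return warped TriangleMesh
#' @export
warpToEllipse <- function(mesh, detection, factor) {
  if (factor == 1) return(mesh)
  pol <- .archPolar(mesh@vertices, detection)
  blend <- .smoothstep((pol$sRel - 0.5) / 0.35)
  scale <- 1 + (factor - 1) * blend
  uAxis <- detection@frame@axes[, 1]; vAxis <- detection@frame@axes[, 2]
  cen3 <- detection@frame@origin +
    uAxis * detection@ellipse@center[1] + vAxis * detection@ellipse@center[2]
  du <- pol$uv[, 1] - detection@ellipse@center[1]
  dv <- pol$uv[, 2] - detection@ellipse@center[2]
  disp <- (scale - 1) * (outer(du, uAxis) + outer(dv, vAxis))
  triangleMesh(mesh@vertices + disp, mesh@faces,
               name = sprintf("%s-warp%.4f", mesh@name, factor),
               metadata = mesh@metadata)
}

#' Generate the full plate series
#'
#' For each planned plate the cast is warped so its crest matches the
#' target ellipse, re-detected, bridged down to the target residual gap,
#' and passed through the plate pipeline (shell, ventilation hole,
#' retention pin, smoothing).  A failed plate aborts with the manifest of
#' completed ones attached to the error condition.
#'
#' @param cast watertight cast TriangleMesh
#' @param detection its \linkS4class{DetectionResult}
#' @param model a \linkS4class{GrowthModel}
#' @param spec a \linkS4class{PlateSpec}
#' @param outDir optional directory: plates written as plate_01.stl, ...
#'   with a manifest.json
#' @param pin,hole,smooth stage toggles (all TRUE by default)
#' @return list with \code{manifest} (SeriesManifest), \code{plates}
#'   (list of TriangleMesh), \code{anatomies} (warped+bridged target
#'   anatomy per plate, i.e. the intaglio target), \code{warped} (the
#'   warped casts before bridging, for segment-orientation checks),
#'   \code{elapsed} (seconds)
#' @export
generateSeries <- function(cast, detection, model, spec, outDir = NULL,
                           pin = TRUE, hole = TRUE, smooth = TRUE) {
  t0 <- proc.time()[["elapsed"]]
  mf <- planSeries(detection, model)
  plates <- list(); anatomies <- list(); warpedCasts <- list()
  for (k in mf$index) {
    res <- tryCatch({
      warped <- warpToEllipse(cast, detection, mf$growthFactor[k])
      detK <- detectRidge(warped)
      bridged <- if (length(detK@gapSpan))
        bridgeGap(warped, detK, targetGap = mf$targetGap[k]) else warped
      plate <- buildPlate(bridged, detK, spec)
      if (hole) plate <- addVentilationHole(plate, spec)
      if (pin) plate <- addRetentionPin(plate, spec)
      if (smooth) plate <- smoothPlate(plate, spec, reference = bridged)
      list(plate = plate, anatomy = bridged, warped = warped)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      stop(structure(class = c("seriesError", "error", "condition"),
                     list(message = sprintf("plate %d failed: %s", k,
                                            conditionMessage(res)),
                          call = sys.call(), manifest = mf,
                          plates = plates)))
    }
    rep <- validateMesh(res$plate)
    mf$volume[k] <- rep@volume
    mf$watertight[k] <- rep@isWatertight
    plates[[k]] <- res$plate
    anatomies[[k]] <- res$anatomy
    warpedCasts[[k]] <- res$warped
    if (!is.null(outDir)) {
      if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
      fn <- file.path(outDir, sprintf("plate_%02d.stl", k))
      writeMesh(res$plate, fn, format = "stl-binary")
      mf$file[k] <- fn
    }
  }
  elapsed <- proc.time()[["elapsed"]] - t0
  if (!is.null(outDir)) {
    jsonlite::write_json(as.data.frame(mf), file.path(outDir, "manifest.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  list(manifest = mf, plates = plates, anatomies = anatomies,
       warped = warpedCasts, elapsed = elapsed)
}
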