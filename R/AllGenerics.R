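#' @rdname ImageScene-class
#' @param object an object
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))

#' @rdname ImageScene-class
#' @param name channel name
#' @export
setGeneric("getChannel", function(object, name) standardGeneric("getChannel"))

#' @rdname ImageScene-class
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname ImageScene-class
#' @export
setGeneric("sceneId", function(object) standardGeneric("sceneId"))

#' @rdname SceneTruth-class
#' @param object an object
#' @export
setGeneric("cellMask", function(object) standardGeneric("cellMask"))

#' @rdname SceneTruth-class
#' @export
setGeneric("mitoMask", function(object) standardGeneric("mitoMask"))

#' @rdname SceneTruth-class
#' @export
setGeneric("trueEnrichment", function(object) standardGeneric("trueEnrichment"))

#' @rdname MMFit-class
#' @param object an object
#' @export
setGeneric("kcat", function(object) standardGeneric("kcat"))

#' @rdname MMFit-class
#' @export
setGeneric("Km", function(object) standardGeneric("Km"))

#' @rdname MMFit-class
#' @export
setGeneric("Vmax", function(object) standardGeneric("Vmax"))

#' @rdname MMFit-class
#' @export
setGeneric("catalyticEfficiency",
  function(object) standardGeneric("catalyticEfficiency"))

#' @rdname TiltSeries-class
#' @param object an object
#' @export
setGeneric("tiltAngles", function(object) standardGeneric("tiltAngles"))

setMethod("channelNames", "ImageScene", function(object) names(object@channels))
setMethod("getChannel", "ImageScene", function(object, name) {
  if (!name %in% names(object@channels))
    stop("unknown channel '", name, "' in scene '", object@sceneId, "'")
  object@channels[[name]]
})
setMethod("pixelSize", "ImageScene", function(object) object@pixelSize)
setMethod("sceneId", "ImageScene", function(object) object@sceneId)

setMethod("cellMask", "SceneTruth", function(object) object@cellMask)
setMethod("mitoMask", "SceneTruth", function(object) object@mitoMask)
setMethod("trueEnrichment", "SceneTruth", function(object) object@trueEnrichment)

setMethod("kcat", "MMFit", function(object) object@kcat)
setMethod("Km", "MMFit", function(object) object@Km)
setMethod("Vmax", "MMFit", function(object) object@Vmax)
setMethod("catalyticEfficiency", "MMFit", function(object) object@kcatOverKm)

setMethod("tiltAngles", "TiltSeries", function(object) object@angles)

setMethod("show", "ImageScene", function(object) {
  d <- dim(object@channels[[1L]])
  cat("ImageScene '", object@sceneId, "': ",
      paste(d, collapse = " x "), " px, channels: ",
      paste(names(object@channels), collapse = ", "),
      ", pixel size ", object@pixelSize, " um/px\n", sep = "")
})

setMethod("show", "SceneTruth", function(object) {
  cat("SceneTruth: enrichment ", object@trueEnrichment,
      ", footprint ", round(object@footprint, 2), " um^2, ",
      length(object@skeleton), " branches in ",
      object@nComponents, " component(s)\n", sep = "")
})

setMethod("show", "ProgressCurveSet", function(object) {
  cat("ProgressCurveSet: ", length(object@times), " time points x ",
      length(object@substrateConcs), " substrate concentrations (",
      min(object@substrateConcs), "-", max(object@substrateConcs),
      " uM), [E] = ", object@enzymeConc, " uM\n", sep = "")
})

setMethod("show", "MMFit", function(object) {
  cat("Michaelis-Menten fit:\n",
      "  Vmax = ", signif(object@Vmax, 4), " uM/min (SE ",
      signif(object@se[["Vmax"]], 3), ")\n",
      "  Km   = ", signif(object@Km, 4), " uM (SE ",
      signif(object@se[["Km"]], 3), ")\n",
      "  kcat = ", signif(object@kcat, 4), " min^-1",
      ", kcat/Km = ", signif(object@kcatOverKm, 4), " uM^-1 min^-1\n",
      sep = "")
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = "; "), "\n")
})

setMethod("show", "SkeletonGraph", function(object) {
  cat("SkeletonGraph: ", length(object@branches), " branches, ",
      sum(object@nodes$type == "junction"), " junctions, ",
      sum(object@nodes$type == "endpoint"), " endpoints, ",
      object@nComponents, " component(s)\n", sep = "")
})

setMethod("show", "TiltSeries", function(object) {
  cat("TiltSeries residues ", object@span[1L], "-", object@span[2L], ": ",
      length(object@angles), " frames, mean tilt ",
      round(mean(object@angles), 2), " deg (SD ",
      round(sd(object@angles), 2), ")\n", sep = "")
})
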