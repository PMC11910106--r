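#' @import methods
#' @importFrom stats aggregate coef lm median pf pt quantile residuals rnorm rpois runif sd setNames var vcov
#' @importFrom utils head read.csv tail write.csv packageVersion
#' @importFrom tools md5sum
NULL

#' ImageScene: a multi-channel confocal scene
#'
#' Container for one segmented-cell field of view. Channels are named
#' intensity arrays (2D matrices, or 3D arrays with z as the third
#' dimension) sharing a common shape. The three channels used throughout
#' the package are \code{pink1} (the mCherry-tagged reporter), \code{tom20}
#' (outer-membrane mitochondrial marker) and \code{membrane} (a
#' plasma-membrane probe used to delineate the transfected cell).
#'
#' @slot channels named list of numeric arrays, all with identical dimensions
#' @slot pixelSize numeric, lateral pixel size in micrometres per pixel
#' @slot zStep numeric, axial step in micrometres (0.25 by default)
#' @slot sceneId character scene identifier
#' @export
setClass("ImageScene",
  representation(
    channels = "list",
    pixelSize = "numeric",
    zStep = "numeric",
    sceneId = "character"
  ),
  prototype(zStep = 0.25, sceneId = "scene")
)

setValidity("ImageScene", function(object) {
  ch <- object@channels
  if (length(ch) == 0L) return("at least one channel required")
  if (is.null(names(ch)) || any(!nzchar(names(ch))))
    return("channels must be named")
  dims <- lapply(ch, dim)
  if (any(vapply(dims, is.null, logical(1L))))
    return("channels must be matrices or arrays")
  d0 <- dims[[1L]]
  for (d in dims) if (!identical(d, d0)) return("all channels must share shape")
  if (any(vapply(ch, function(x) any(x < 0), logical(1L))))
    return("channel intensities must be nonnegative")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    return("pixelSize must be a single positive number")
  TRUE
})

#' SceneTruth: ground truth emitted with a synthetic scene
#'
#' @slot cellMask logical matrix, true cell area
#' @slot mitoMask logical matrix, true mitochondrial area
#' @slot trueEnrichment numeric, generating mito/cytosol intensity ratio
#' @slot skeleton list of branch polylines (n x 2 integer matrices, row/col)
#' @slot summedBranchLength numeric, micrometres
#' @slot meanBranchLength numeric, micrometres
#' @slot footprint numeric, square micrometres
#' @slot nComponents integer, connected components of the generating network
#' @slot seed integer seed the scene was drawn with
#' @export
setClass("SceneTruth",
  representation(
    cellMask = "matrix",
    mitoMask = "matrix",
    trueEnrichment = "numeric",
    skeleton = "list",
    summedBranchLength = "numeric",
    meanBranchLength = "numeric",
    footprint = "numeric",
    nComponents = "integer",
    seed = "integer"
  )
)

setValidity("SceneTruth", function(object) {
  if (!is.logical(object@cellMask) || !is.logical(object@mitoMask))
    return("masks must be logical matrices")
  if (!identical(dim(object@cellMask), dim(object@mitoMask)))
    return("masks must share shape")
  if (any(object@mitoMask & !object@cellMask))
    return("mitoMask must be contained in cellMask")
  if (object@trueEnrichment <= 0) return("trueEnrichment must be > 0")
  TRUE
})

#' ProgressCurveSet: fluorogenic protease assay time courses
#'
#' Time x substrate-concentration matrices of raw fluorescence (RFU) for an
#' internally quenched (IQ) peptide cleavage assay, together with matched
#' no-enzyme blank wells and the proteinase-K full-digest endpoint
#' fluorescence change per substrate concentration used for RFU-to-µM
#' calibration.
#'
#' @slot times numeric, minutes, strictly increasing
#' @slot substrateConcs numeric, micromolar, strictly increasing, > 0
#' @slot rfu matrix time x concentration
#' @slot blankRfu matrix time x concentration (no-enzyme background)
#' @slot fullDigestDelta numeric, maximum fluorescence change per
#'   concentration after complete proteinase-K digestion
#' @slot enzymeConc numeric, enzyme concentration in micromolar
#' @export
setClass("ProgressCurveSet",
  representation(
    times = "numeric",
    substrateConcs = "numeric",
    rfu = "matrix",
    blankRfu = "matrix",
    fullDigestDelta = "numeric",
    enzymeConc = "numeric"
  )
)

setValidity("ProgressCurveSet", function(object) {
  if (any(diff(object@times) <= 0)) return("times must be strictly increasing")
  if (any(object@substrateConcs <= 0) || any(diff(object@substrateConcs) <= 0))
    return("substrateConcs must be positive and strictly increasing")
  nt <- length(object@times); ns <- length(object@substrateConcs)
  if (!identical(dim(object@rfu), c(nt, ns)))
    return("rfu must be a times x concentrations matrix")
  if (!identical(dim(object@blankRfu), c(nt, ns)))
    return("blankRfu must match rfu in shape")
  if (length(object@fullDigestDelta) != ns)
    return("fullDigestDelta needs one value per concentration")
  if (length(object@enzymeConc) != 1L || object@enzymeConc <= 0)
    return("enzymeConc must be a single positive number")
  TRUE
})

#' MMFit: Michaelis-Menten fit result
#'
#' @slot Vmax numeric, micromolar per minute
#' @slot Km numeric, micromolar
#' @slot kcat numeric, per minute (Vmax / enzyme concentration)
#' @slot kcatOverKm numeric, per micromolar per minute
#' @slot se named numeric, standard errors for Vmax and Km
#' @slot residuals numeric fit residuals (velocity scale)
#' @slot converged logical
#' @slot flags character vector of fit warnings (e.g. Km at bound)
#' @export
setClass("MMFit",
  representation(
    Vmax = "numeric",
    Km = "numeric",
    kcat = "numeric",
    kcatOverKm = "numeric",
    se = "numeric",
    residuals = "numeric",
    converged = "logical",
    flags = "character"
  )
)

#' SkeletonGraph: branch graph of a one-pixel-wide skeleton
#'
#' @slot nodes data.frame with columns row, col, type ("endpoint" or
#'   "junction")
#' @slot branches list of branch polylines (n x 2 matrices of row/col pixel
#'   coordinates)
#' @slot branchLengths numeric, micrometres (orthogonal step = pixel size,
#'   diagonal step = sqrt(2) x pixel size)
#' @slot nComponents integer, connected components including isolated pixels
#' @slot pixelSize numeric, micrometres per pixel
#' @export
setClass("SkeletonGraph",
  representation(
    nodes = "data.frame",
    branches = "list",
    branchLengths = "numeric",
    nComponents = "integer",
    pixelSize = "numeric"
  )
)

setValidity("SkeletonGraph", function(object) {
  if (length(object@branches) != length(object@branchLengths))
    return("one length per branch required")
  if (length(object@branchLengths) && any(object@branchLengths <= 0))
    return("branch lengths must be positive")
  TRUE
})

#' TiltSeries: per-frame helix tilt angles for one residue span
#'
#' @slot span integer length-2, first and last residue of the analysed span
#' @slot angles numeric, degrees in [0, 90], one per frame
#' @slot replicate character replicate label per frame
#' @export
setClass("TiltSeries",
  representation(
    span = "integer",
    angles = "numeric",
    replicate = "character"
  )
)

setValidity("TiltSeries", function(object) {
  if (length(object@span) != 2L) return("span must be (first, last)")
  if (length(object@angles) == 0L) return("at least one frame required")
  if (any(object@angles < 0 | object@angles > 90))
    return("angles must lie in [0, 90] degrees")
  if (length(object@replicate) != length(object@angles))
    return("one replicate label per frame required")
  TRUE
})
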