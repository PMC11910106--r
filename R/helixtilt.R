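#' Residue span presets for PINK1 tilt analysis
#'
#' Named residue spans used throughout the tilt analysis: \code{tm}, the
#' transmembrane helix (residues 89-118); \code{soluble}, the adjacent
#' soluble helix (residues 119-135); and \code{tm_alphafold}, the
#' AlphaFold-predicted transmembrane boundaries (92-118).
#'
#' @return named list of integer length-2 vectors
#' @export
spanPresets <- function() {
  list(tm = c(89L, 118L),
       soluble = c(119L, 135L),
       tm_alphafold = c(92L, 118L))
}

# a trajectory frame: one representative backbone point (C-alpha) per residue
.makeFrame <- function(residueIds, coords, replicate = "rep1",
                       frameIndex = 1L) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L || nrow(coords) != length(residueIds))
    stop("coords must be an n x 3 matrix matching residueIds")
  if (any(!is.finite(coords))) stop("coordinates must be finite")
  list(residueIds = as.integer(residueIds), coords = coords,
       replicate = replicate, frameIndex = frameIndex)
}

#' Build an ideal alpha-helix
#'
#' Canonical geometry: 1.5 Angstrom rise and 100 degrees of twist per
#' residue on a 2.3 Angstrom radius, with the helix axis along +z.
#'
#' @param nRes number of residues
#' @param rise rise per residue, Angstrom
#' @param twist twist per residue, degrees
#' @param radius helix radius, Angstrom
#' @return nRes x 3 coordinate matrix
#' @export
idealHelix <- function(nRes, rise = 1.5, twist = 100, radius = 2.3) {
  if (nRes < 3L) stop("need at least 3 residues")
  i <- seq_len(nRes) - 1L
  ang <- i * twist * pi / 180
  cbind(x = radius * cos(ang), y = radius * sin(ang), z = i * rise)
}

#' Principal-axis direction of a helix span
#'
#' Best-fit line through the span's representative coordinates in the
#' orthogonal-distance sense: the leading principal axis of the centred
#' coordinate set. The sign is chosen so the axis points from the first
#' residue of the span towards the last.
#'
#' @param frame a trajectory frame (list with \code{residueIds} and
#'   \code{coords}) as produced by \code{\link{synthHelixTrajectory}} or
#'   \code{\link{readFrames}}
#' @param span integer length-2, first and last residue
#' @return unit 3-vector
#' @export
helixAxis <- function(frame, span) {
  span <- as.integer(span)
  want <- span[1L]:span[2L]
  if (length(want) < 3L) stop("span must cover at least 3 residues")
  hit <- match(want, frame$residueIds)
  if (anyNA(hit))
    stop("span residues missing from frame: ",
         paste(want[is.na(hit)], collapse = ", "))
  xyz <- frame$coords[hit, , drop = FALSE]
  centred <- sweep(xyz, 2L, colMeans(xyz))
  ax <- svd(centred, nu = 0L, nv = 1L)$v[, 1L]
  ax <- ax / sqrt(sum(ax^2))
  endToEnd <- xyz[nrow(xyz), ] - xyz[1L, ]
  if (sum(ax * endToEnd) < 0) ax <- -ax
  ax
}

#' Tilt angle between a helix axis and the membrane normal
#'
#' acos of the absolute dot product, in degrees; folding by the absolute
#' value maps antiparallel axes onto [0, 90].
#'
#' @param axis 3-vector (need not be normalised)
#' @param normal membrane normal 3-vector (default +z)
#' @return angle in degrees in [0, 90]
#' @export
tiltAngle <- function(axis, normal = c(0, 0, 1)) {
  na <- sqrt(sum(axis^2)); nn <- sqrt(sum(normal^2))
  if (na == 0 || nn == 0) stop("zero vector has no direction")
  cosang <- abs(sum(axis * normal)) / (na * nn)
  acos(min(max(cosang, -1), 1)) * 180 / pi
}

#' Per-frame tilt-angle series for a residue span
#'
#' @param frames list of trajectory frames
#' @param span integer length-2 residue span (see
#'   \code{\link{spanPresets}})
#' @param normal membrane normal (default +z: the bilayer lies in the xy
#'   plane)
#' @return a \linkS4class{TiltSeries}
#' @export
tiltSeries <- function(frames, span, normal = c(0, 0, 1)) {
  if (!length(frames)) stop("at least one frame required")
  angles <- vapply(frames, function(f)
    tiltAngle(helixAxis(f, span), normal), numeric(1L))
  reps <- vapply(frames, function(f)
    as.character(f$replicate %||% "rep1"), character(1L))
  new("TiltSeries", span = as.integer(span), angles = angles,
      replicate = reps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarise a tilt series
#'
#' @param series a \linkS4class{TiltSeries}
#' @return list(mean, sd, n, perReplicate data.frame)
#' @export
tiltSummary <- function(series) {
  stopifnot(is(series, "TiltSeries"))
  per <- aggregate(series@angles, list(replicate = series@replicate),
                   function(x) c(mean = mean(x), n = length(x)))
  perdf <- data.frame(replicate = per$replicate,
                      mean = per$x[, "mean"], n = per$x[, "n"])
  list(mean = mean(series@angles),
       sd = sd(series@angles),
       n = length(series@angles),
       perReplicate = perdf)
}

#' Synthetic tilted-helix trajectory
#'
#' Frames of an ideal alpha-helix rotated about the y axis by a known tilt,
#' with independent Gaussian coordinate noise per frame: a validation
#' fixture with exact ground truth.
#'
#' @param tilt true tilt in degrees, within [0, 90]
#' @param nFrames number of frames
#' @param noiseSigma per-coordinate Gaussian noise SD, Angstrom
#' @param span residue span to label the helix with (default the
#'   transmembrane preset 89-118)
#' @param seed RNG seed
#' @param replicate replicate label carried by every frame
#' @return list of frames
#' @export
synthHelixTrajectory <- function(tilt, nFrames = 100L, noiseSigma = 0.3,
                                 span = c(89L, 118L), seed = 1L,
                                 replicate = "rep1") {
  if (length(tilt) != 1L || tilt < 0 || tilt > 90)
    stop("'tilt' must lie in [0, 90] degrees")
  if (nFrames < 1L) stop("'nFrames' must be >= 1")
  .assertScalar(noiseSigma, "noiseSigma", nonneg = TRUE)
  resIds <- span[1L]:span[2L]
  base <- idealHelix(length(resIds))
  th <- tilt * pi / 180
  rotY <- matrix(c(cos(th), 0, sin(th),
                   0, 1, 0,
                   -sin(th), 0, cos(th)), 3L, 3L, byrow = TRUE)
  tilted <- base %*% t(rotY)
  .withSeed(seed, {
    lapply(seq_len(nFrames), function(i) {
      xyz <- tilted
      if (noiseSigma > 0)
        xyz <- xyz + matrix(rnorm(length(xyz), 0, noiseSigma),
                            nrow(xyz), 3L)
      .makeFrame(resIds, xyz, replicate = replicate, frameIndex = i)
    })
  })
}

#' Write frames as PDB files
#'
#' One PDB file per frame (\code{frame_0001.pdb}, ...) with one C-alpha
#' atom per residue, for round-tripping through standard structure tools.
#'
#' @param frames list of frames
#' @param dir output directory (created if needed)
#' @return invisibly, the file paths
#' @export
writeFrames <- function(frames, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_along(frames), function(i) {
    f <- frames[[i]]
    path <- file.path(dir, sprintf("frame_%04d.pdb", i))
    n <- length(f$residueIds)
    bio3d::write.pdb(
      file = path,
      xyz = as.numeric(t(f$coords)),
      type = rep("ATOM", n),
      resno = f$residueIds,
      resid = rep("ALA", n),
      eleno = seq_len(n),
      elety = rep("CA", n),
      chain = rep("A", n))
    path
  }, character(1L))
  invisible(paths)
}

#' Read trajectory frames from PDB files
#'
#' Accepts a directory of single-model PDB files (ordered by file name) or
#' one multi-model PDB. Only C-alpha atoms are used; each residue
#' contributes its C-alpha position as the representative backbone point.
#'
#' @param path directory or PDB file
#' @param replicate replicate label for all frames read
#' @return list of frames
#' @export
readFrames <- function(path, replicate = "rep1") {
  frameFromXyz <- function(resno, xyz, i)
    .makeFrame(resno, matrix(xyz, ncol = 3L, byrow = TRUE),
               replicate = replicate, frameIndex = i)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.pdb$", full.names = TRUE))
    if (!length(files)) stop("no PDB files found in ", path)
    lapply(seq_along(files), function(i) {
      pdb <- bio3d::read.pdb(files[i])
      ca <- bio3d::atom.select(pdb, "calpha")
      frameFromXyz(pdb$atom$resno[ca$atom], pdb$xyz[ca$xyz], i)
    })
  } else {
    pdb <- bio3d::read.pdb(path, multi = TRUE)
    ca <- bio3d::atom.select(pdb, "calpha")
    nModels <- nrow(pdb$xyz)
    lapply(seq_len(nModels), function(i)
      frameFromXyz(pdb$atom$resno[ca$atom], pdb$xyz[i, ca$xyz], i))
  }
}
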