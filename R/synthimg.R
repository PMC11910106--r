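#' Scene generator configuration
#'
#' Builds and validates the configuration for the synthetic confocal-scene
#' generator. A scene holds one transfected cell rendered into three
#' channels: \code{pink1} (reporter; mean intensity inside mitochondria is
#' \code{enrichment} times the cytosolic mean), \code{tom20} (mitochondrial
#' marker) and \code{membrane} (cell-delineation probe: cell fill plus a
#' brighter rim). Rendering order is: piecewise-constant signal, point-spread
#' blur, z-stack replication with defocus away from the focal slice, additive
#' low-frequency illumination background, Poisson shot noise at
#' \code{photonGain}, then additive Gaussian read noise.
#'
#' @param fieldShape integer length-2, field size in pixels (rows, cols)
#' @param nSlices integer, z-stack depth (>= 1)
#' @param zStep numeric, axial step in micrometres
#' @param pixelSize numeric, micrometres per pixel
#' @param cellRadius numeric, mean cell radius in micrometres
#' @param cellIrregularity numeric, amplitude of the low-order radial
#'   perturbation of the cell outline (dimensionless)
#' @param mitoMode "networked" (branching tubular network) or "fragmented"
#'   (many short disconnected tubules)
#' @param mitoTubuleWidth numeric, tubule width in pixels
#' @param mitoTotalLength numeric, target total skeleton length in
#'   micrometres
#' @param enrichment numeric > 0, true mito/cytosol reporter intensity ratio
#' @param cytosolLevel numeric, cytosolic reporter intensity
#' @param markerLevel numeric, tom20 intensity inside mitochondria
#' @param membraneLevel numeric, membrane-channel cell fill intensity (the
#'   rim is rendered at 2.5x this level)
#' @param backgroundAmplitude numeric, peak amplitude of the nonuniform
#'   illumination background
#' @param backgroundScale numeric, correlation length of the background
#'   field in pixels
#' @param psfSigma numeric, in-focus Gaussian PSF sigma in pixels
#' @param axialSigma numeric, sigma of the Gaussian axial response in
#'   micrometres (confocal optical sectioning; out-of-focus slices are
#'   attenuated by exp(-dz^2 / (2 axialSigma^2)))
#' @param photonGain numeric, photons per intensity unit for shot noise
#' @param readNoiseSigma numeric, Gaussian read noise SD (intensity units)
#' @param seed integer RNG seed
#' @return a validated list of class \code{SceneConfig}
#' @export
sceneConfig <- function(fieldShape = c(192L, 192L),
                        nSlices = 5L,
                        zStep = 0.25,
                        pixelSize = 0.1,
                        cellRadius = 7,
                        cellIrregularity = 0.08,
                        mitoMode = c("networked", "fragmented"),
                        mitoTubuleWidth = 4,
                        mitoTotalLength = 120,
                        enrichment = 1,
                        cytosolLevel = 100,
                        markerLevel = 200,
                        membraneLevel = 80,
                        backgroundAmplitude = 20,
                        backgroundScale = 40,
                        psfSigma = 1,
                        axialSigma = 0.4,
                        readNoiseSigma = 2,
                        photonGain = 4,
                        seed = 1L) {
  mitoMode <- match.arg(mitoMode)
  if (length(fieldShape) != 2L || any(fieldShape < 16))
    stop("configuration error in 'fieldShape': need two dimensions >= 16")
  if (length(nSlices) != 1L || nSlices < 1)
    stop("configuration error in 'nSlices': must be >= 1")
  .assertScalar(zStep, "zStep", positive = TRUE)
  .assertScalar(pixelSize, "pixelSize", positive = TRUE)
  .assertScalar(cellRadius, "cellRadius", positive = TRUE)
  .assertScalar(cellIrregularity, "cellIrregularity", nonneg = TRUE)
  .assertScalar(mitoTubuleWidth, "mitoTubuleWidth", positive = TRUE)
  .assertScalar(mitoTotalLength, "mitoTotalLength", positive = TRUE)
  if (length(enrichment) != 1L || !is.finite(enrichment) || enrichment <= 0)
    stop("configuration error in 'enrichment': must be > 0")
  .assertScalar(cytosolLevel, "cytosolLevel", positive = TRUE)
  .assertScalar(markerLevel, "markerLevel", positive = TRUE)
  .assertScalar(membraneLevel, "membraneLevel", positive = TRUE)
  .assertScalar(backgroundAmplitude, "backgroundAmplitude", nonneg = TRUE)
  .assertScalar(backgroundScale, "backgroundScale", positive = TRUE)
  .assertScalar(psfSigma, "psfSigma", nonneg = TRUE)
  .assertScalar(axialSigma, "axialSigma", positive = TRUE)
  .assertScalar(readNoiseSigma, "readNoiseSigma", nonneg = TRUE)
  .assertScalar(photonGain, "photonGain", nonneg = TRUE)
  cfg <- list(
    fieldShape = as.integer(fieldShape), nSlices = as.integer(nSlices),
    zStep = zStep, pixelSize = pixelSize, cellRadius = cellRadius,
    cellIrregularity = cellIrregularity, mitoMode = mitoMode,
    mitoTubuleWidth = mitoTubuleWidth, mitoTotalLength = mitoTotalLength,
    enrichment = enrichment, cytosolLevel = cytosolLevel,
    markerLevel = markerLevel, membraneLevel = membraneLevel,
    backgroundAmplitude = backgroundAmplitude,
    backgroundScale = backgroundScale, psfSigma = psfSigma,
    axialSigma = axialSigma,
    readNoiseSigma = readNoiseSigma, photonGain = photonGain,
    seed = as.integer(seed))
  class(cfg) <- "SceneConfig"
  cfg
}

#' Read a scene configuration from a YAML file
#'
#' Every field of \code{\link{sceneConfig}} may appear as a top-level key;
#' missing keys take the defaults.
#'
#' @param path YAML file path
#' @return a \code{SceneConfig}
#' @export
readSceneConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sceneConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("configuration error: unknown field(s) ", paste(bad, collapse = ", "))
  do.call(sceneConfig, vals)
}

# low-frequency illumination field in [0, 1] * amplitude: bilinear
# interpolation of a coarse random grid with node spacing ~ scalePx
.backgroundField <- function(h, w, scalePx, amplitude) {
  if (amplitude <= 0) return(matrix(0, h, w))
  gh <- max(2L, ceiling(h / scalePx) + 1L)
  gw <- max(2L, ceiling(w / scalePx) + 1L)
  g <- matrix(rnorm(gh * gw), gh, gw)
  ry <- seq(1, gh, length.out = h); rx <- seq(1, gw, length.out = w)
  y0 <- pmin(floor(ry), gh - 1L); x0 <- pmin(floor(rx), gw - 1L)
  fy <- ry - y0; fx <- rx - x0
  sm <- g[y0, x0] * ((1 - fy) %o% (1 - fx)) +
    g[y0 + 1L, x0] * (fy %o% (1 - fx)) +
    g[y0, x0 + 1L] * ((1 - fy) %o% fx) +
    g[y0 + 1L, x0 + 1L] * (fy %o% fx)
  sm <- (sm - min(sm)) / max(max(sm) - min(sm), .Machine$double.eps)
  amplitude * sm
}

# cell outline: disk perturbed by a low-order Fourier series in polar angle
.makeCellMask <- function(h, w, radiusPx, irregularity) {
  cy <- h / 2 + runif(1, -0.03, 0.03) * h
  cx <- w / 2 + runif(1, -0.03, 0.03) * w
  amp <- runif(3, 0.4, 1)
  phase <- runif(3, 0, 2 * pi)
  row <- matrix(seq_len(h), h, w)
  col <- matrix(seq_len(w), h, w, byrow = TRUE)
  dy <- row - cy; dx <- col - cx
  theta <- atan2(dy, dx)
  pert <- irregularity * (amp[1] * cos(2 * theta + phase[1]) +
                          amp[2] * cos(3 * theta + phase[2]) +
                          amp[3] * cos(4 * theta + phase[3]))
  r <- radiusPx * (1 + pert)
  mask <- (dx^2 + dy^2) <= r^2
  mask
}

# random tubule growth; walks a queue of tubule segments inside 'allowed'
# until the target skeleton length is laid down. networked mode branches
# (spawned branches share their parent's component id); fragmented mode
# scatters short independent segments. returns branch polylines (continuous
# coordinates, 1 px steps), per-branch component ids, and steps laid.
.growNetwork <- function(allowed, totalSteps, mode) {
  h <- nrow(allowed); w <- ncol(allowed)
  inside <- function(p) {
    r <- round(p[1]); c <- round(p[2])
    r >= 1 && r <= h && c >= 1 && c <= w && allowed[r, c]
  }
  ok <- which(allowed, arr.ind = TRUE)
  if (nrow(ok) == 0L) stop("cell too small to host a mitochondrial network")
  turnSd <- if (mode == "networked") 0.15 else 0.08
  branchProb <- if (mode == "networked") 0.02 else 0
  segLimit <- function() if (mode == "fragmented")
    round(runif(1, 8, 20)) else round(runif(1, 60, 140))
  polylines <- list(); compIds <- integer(0)
  stepsDone <- 0L; nextComp <- 0L; nextBranch <- 0L
  # self-avoidance bookkeeping: per-pixel branch id, component id, and the
  # global step at which the pixel was laid down
  occB <- matrix(0L, h, w); occC <- matrix(0L, h, w); occS <- matrix(0L, h, w)
  avoid <- which(outer((-4):4, (-4):4, function(a, b) a^2 + b^2) <= 16,
                 arr.ind = TRUE) - 5L
  clear <- function(p, comp, branch, stepInBranch) {
    r0 <- round(p[1L]); c0 <- round(p[2L])
    for (i in seq_len(nrow(avoid))) {
      r <- r0 + avoid[i, 1L]; c <- c0 + avoid[i, 2L]
      if (r < 1L || r > h || c < 1L || c > w) next
      b <- occB[r, c]
      if (b == 0L) next
      if (b == branch && stepsDone - occS[r, c] <= 8L) next
      if (occC[r, c] == comp && stepInBranch <= 6L) next
      return(FALSE)
    }
    TRUE
  }
  stamp <- function(p, comp, branch) {
    r <- round(p[1L]); c <- round(p[2L])
    occB[r, c] <<- branch; occC[r, c] <<- comp; occS[r, c] <<- stepsDone
  }
  queue <- list()
  spawnSeed <- function() {
    for (tries in 1:50) {
      start <- as.numeric(ok[sample.int(nrow(ok), 1L), ])
      nextComp <<- nextComp + 1L
      if (clear(start, nextComp, -1L, 99L)) break
    }
    list(pos = start, angle = runif(1, 0, 2 * pi), comp = nextComp)
  }
  if (mode == "networked") for (i in 1:2) queue[[i]] <- spawnSeed()
  while (stepsDone < totalSteps) {
    if (length(queue) == 0L) queue[[1L]] <- spawnSeed()
    wk <- queue[[1L]]; queue[[1L]] <- NULL
    path <- matrix(wk$pos, 1L, 2L)
    limit <- segLimit()
    pos <- wk$pos; angle <- wk$angle
    nextBranch <- nextBranch + 1L
    branch <- nextBranch
    stepInBranch <- 0L
    stamp(pos, wk$comp, branch)
    while (limit > 0L && stepsDone < totalSteps) {
      angle <- angle + rnorm(1, 0, turnSd)
      cand <- pos + c(sin(angle), cos(angle))
      tries <- 0L
      while ((!inside(cand) ||
              !clear(cand, wk$comp, branch, stepInBranch + 1L)) &&
             tries < 12L) {
        angle <- angle + runif(1, -pi / 2, pi / 2)
        cand <- pos + c(sin(angle), cos(angle))
        tries <- tries + 1L
      }
      if (!inside(cand) || !clear(cand, wk$comp, branch, stepInBranch + 1L))
        break
      pos <- cand
      path <- rbind(path, cand)
      stepsDone <- stepsDone + 1L
      stepInBranch <- stepInBranch + 1L
      limit <- limit - 1L
      stamp(pos, wk$comp, branch)
      if (branchProb > 0 && runif(1) < branchProb && length(queue) < 24L)
        queue[[length(queue) + 1L]] <-
          list(pos = pos,
               angle = angle + sample(c(-1, 1), 1L) * runif(1, pi / 3, pi / 2),
               comp = wk$comp)
    }
    if (nrow(path) > 1L) {
      polylines[[length(polylines) + 1L]] <- path
      compIds <- c(compIds, wk$comp)
    }
  }
  list(polylines = polylines, compIds = compIds, steps = stepsDone)
}

.rasterPolylines <- function(polylines, h, w) {
  m <- matrix(FALSE, h, w)
  for (p in polylines) {
    r <- pmin(pmax(round(p[, 1]), 1L), h)
    c <- pmin(pmax(round(p[, 2]), 1L), w)
    m[cbind(r, c)] <- TRUE
  }
  m
}

.discBrush <- function(widthPx) {
  sz <- max(3L, as.integer(round(widthPx)))
  if (sz %% 2L == 0L) sz <- sz + 1L
  EBImage::makeBrush(sz, shape = "disc")
}

#' Generate one synthetic confocal scene with ground truth
#'
#' Renders the configured cell into a three-channel scene (z-stack when
#' \code{nSlices > 1}) and returns it together with the exact masks and
#' network statistics the generator used, so downstream estimates can be
#' scored against known truth. With \code{psfSigma = 0}, zero background
#' and zero noise the channels are piecewise constant and the mean reporter
#' intensity over the mitochondrial mask is exactly \code{enrichment} times
#' the mean over the cytosolic remainder of the cell.
#'
#' @param config a \code{\link{sceneConfig}}
#' @return list with elements \code{scene} (\linkS4class{ImageScene}) and
#'   \code{truth} (\linkS4class{SceneTruth})
#' @export
generateScene <- function(config) {
  if (!inherits(config, "SceneConfig"))
    stop("configuration error: 'config' must come from sceneConfig()")
  .withSeed(config$seed, {
    h <- config$fieldShape[1L]; w <- config$fieldShape[2L]
    radiusPx <- config$cellRadius / config$pixelSize
    cell <- .makeCellMask(h, w, radiusPx, config$cellIrregularity)
    margin <- ceiling(config$mitoTubuleWidth / 2) + 2L
    allowed <- EBImage::erode(
      EBImage::Image(cell * 1), .discBrush(2L * margin + 1L)) > 0.5
    allowed <- matrix(as.logical(allowed), h, w)
    totalSteps <- round(config$mitoTotalLength / config$pixelSize)
    net <- .growNetwork(allowed, totalSteps, config$mitoMode)
    skelRaster <- .rasterPolylines(net$polylines, h, w)
    mito <- EBImage::dilate(EBImage::Image(skelRaster * 1),
                            .discBrush(config$mitoTubuleWidth)) > 0.5
    mito <- matrix(as.logical(mito), h, w) & cell

    cyt <- cell & !mito
    pink1 <- matrix(0, h, w)
    pink1[cyt] <- config$cytosolLevel
    pink1[mito] <- config$enrichment * config$cytosolLevel
    tom20 <- matrix(0, h, w)
    tom20[cyt] <- 0.1 * config$markerLevel
    tom20[mito] <- config$markerLevel
    rim <- cell & !(matrix(as.logical(
      EBImage::erode(EBImage::Image(cell * 1), .discBrush(7L)) > 0.5), h, w))
    membrane <- matrix(0, h, w)
    membrane[cell] <- config$membraneLevel
    membrane[rim] <- 2.5 * config$membraneLevel

    channels <- list(pink1 = pink1, tom20 = tom20, membrane = membrane)
    if (config$psfSigma > 0)
      channels <- lapply(channels, EBImage::gblur, sigma = config$psfSigma)
    channels <- lapply(channels, function(x) {
      x <- as.matrix(x); x[x < 0] <- 0; x })

    # z-stack: the scene is a thin structure at the focal plane; slices
    # away from focus receive a defocus-blurred and axially attenuated
    # copy (Gaussian axial response, sigma = axialSigma um), emulating
    # confocal optical sectioning
    focal <- ceiling(config$nSlices / 2)
    stack <- function(img) {
      if (config$nSlices == 1L) return(img)
      arr <- array(0, dim = c(h, w, config$nSlices))
      for (s in seq_len(config$nSlices)) {
        dz <- abs(s - focal)
        att <- exp(-(dz * config$zStep)^2 / (2 * config$axialSigma^2))
        sl <- if (dz == 0) img else
          att * as.matrix(EBImage::gblur(img, sigma = 1.2 * dz))
        sl[sl < 0] <- 0
        arr[, , s] <- sl
      }
      arr
    }
    channels <- lapply(channels, stack)

    noisify <- function(x) {
      bg <- .backgroundField(h, w, config$backgroundScale,
                             config$backgroundAmplitude)
      addNoise <- function(sl) {
        sl <- sl + bg
        if (config$photonGain > 0)
          sl <- rpois(length(sl), lambda = pmax(sl, 0) * config$photonGain) /
            config$photonGain
        if (config$readNoiseSigma > 0)
          sl <- sl + rnorm(length(sl), 0, config$readNoiseSigma)
        matrix(pmax(sl, 0), h, w)
      }
      if (length(dim(x)) == 3L) {
        for (s in seq_len(dim(x)[3L])) x[, , s] <- addNoise(x[, , s])
        x
      } else addNoise(x)
    }
    channels <- lapply(channels, noisify)

    # true network stats are measured on the generating centerline
    # skeleton with the same graph semantics the morphology module uses,
    # so that recovery through imaging + segmentation is well defined
    trueSkel <- skeletonizeMask(skelRaster)
    trueGraph <- skeletonToGraph(trueSkel, config$pixelSize)
    nBranches <- length(trueGraph@branchLengths)
    summed <- sum(trueGraph@branchLengths)
    truth <- new("SceneTruth",
      cellMask = cell, mitoMask = mito,
      trueEnrichment = config$enrichment,
      skeleton = net$polylines,
      summedBranchLength = summed,
      meanBranchLength = if (nBranches) summed / nBranches else 0,
      footprint = sum(mito) * config$pixelSize^2,
      nComponents = trueGraph@nComponents,
      seed = as.integer(config$seed))
    scene <- new("ImageScene", channels = channels,
                 pixelSize = config$pixelSize, zStep = config$zStep,
                 sceneId = paste0("scene_seed", config$seed))
    list(scene = scene, truth = truth)
  })
}

#' Generate a deterministic batch of scenes
#'
#' Per-scene seeds are derived from the master seed so that scene \code{i}
#' is identical whatever the batch size, mirroring per-cell acquisition in
#' an imaging experiment.
#'
#' @param config a \code{\link{sceneConfig}} (its own seed is ignored)
#' @param n number of scenes (>= 1)
#' @param seed master seed
#' @return list of \code{list(scene, truth)} pairs
#' @export
generateBatch <- function(config, n, seed) {
  if (length(n) != 1L || n < 1) stop("'n' must be >= 1")
  lapply(seq_len(n), function(i) {
    cfg <- config
    cfg$seed <- .deriveSeed(seed, i)
    generateScene(cfg)
  })
}

#' Write a scene and its ground truth to disk
#'
#' The image goes to \code{<id>.tif} as a multi-page 32-bit float TIFF with
#' pages ordered channel-major (all z of \code{pink1}, then \code{tom20},
#' then \code{membrane}); masks go to \code{<id>_cellmask.tif} and
#' \code{<id>_mitomask.tif}; scalar ground truth and layout metadata go to
#' \code{<id>_truth.csv}.
#'
#' @param pair list(scene, truth) from \code{\link{generateScene}}
#' @param dir output directory (created if needed)
#' @return invisibly, the image path
#' @export
writeScene <- function(pair, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scene <- pair$scene; truth <- pair$truth
  id <- sceneId(scene)
  scale <- max(vapply(scene@channels, max, numeric(1L)), 1)
  pages <- list()
  for (nm in c("pink1", "tom20", "membrane")) {
    x <- scene@channels[[nm]]
    if (length(dim(x)) == 3L) {
      for (s in seq_len(dim(x)[3L]))
        pages[[length(pages) + 1L]] <- x[, , s] / scale
    } else pages[[length(pages) + 1L]] <- x / scale
  }
  imgPath <- file.path(dir, paste0(id, ".tif"))
  tiff::writeTIFF(pages, imgPath, bits.per.sample = 32L)
  tiff::writeTIFF(truth@cellMask * 1,
                  file.path(dir, paste0(id, "_cellmask.tif")))
  tiff::writeTIFF(truth@mitoMask * 1,
                  file.path(dir, paste0(id, "_mitomask.tif")))
  nz <- length(pages) / 3L
  write.csv(data.frame(
    scene_id = id, pixel_size = pixelSize(scene), z_step = scene@zStep,
    n_slices = nz, intensity_scale = scale,
    true_enrichment = truth@trueEnrichment,
    true_summed_branch_length = truth@summedBranchLength,
    true_mean_branch_length = truth@meanBranchLength,
    true_footprint = truth@footprint,
    n_components = truth@nComponents, seed = truth@seed),
    file.path(dir, paste0(id, "_truth.csv")), row.names = FALSE)
  invisible(imgPath)
}

#' Read a scene written by \code{\link{writeScene}}
#'
#' @param dir directory holding the files
#' @param id scene identifier
#' @return list(scene, truth); skeleton polylines are not round-tripped
#' @export
readScene <- function(dir, id) {
  meta <- read.csv(file.path(dir, paste0(id, "_truth.csv")))
  pages <- tiff::readTIFF(file.path(dir, paste0(id, ".tif")), all = TRUE)
  nz <- meta$n_slices
  scale <- meta$intensity_scale
  grab <- function(k) {
    sl <- lapply(seq_len(nz), function(s) pages[[(k - 1L) * nz + s]] * scale)
    if (nz == 1L) sl[[1L]] else {
      arr <- array(0, dim = c(dim(sl[[1L]]), nz))
      for (s in seq_len(nz)) arr[, , s] <- sl[[s]]
      arr
    }
  }
  channels <- list(pink1 = grab(1L), tom20 = grab(2L), membrane = grab(3L))
  cm <- tiff::readTIFF(file.path(dir, paste0(id, "_cellmask.tif"))) > 0.5
  mm <- tiff::readTIFF(file.path(dir, paste0(id, "_mitomask.tif"))) > 0.5
  scene <- new("ImageScene", channels = channels,
               pixelSize = meta$pixel_size, zStep = meta$z_step,
               sceneId = as.character(meta$scene_id))
  truth <- new("SceneTruth", cellMask = cm, mitoMask = mm,
               trueEnrichment = meta$true_enrichment,
               skeleton = list(),
               summedBranchLength = meta$true_summed_branch_length,
               meanBranchLength = meta$true_mean_branch_length,
               footprint = meta$true_footprint,
               nComponents = as.integer(meta$n_components),
               seed = as.integer(meta$seed))
  list(scene = scene, truth = truth)
}
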