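#' Maximum-intensity projection
#'
#' Collapses a z-stack to 2D by taking, at every pixel, the maximum
#' intensity across slices. A 2D input is returned unchanged.
#'
#' @param stack numeric matrix (2D) or 3D array with z as third dimension
#' @return numeric matrix
#' @export
maxProject <- function(stack) {
  d <- dim(stack)
  if (is.null(d) || length(d) < 2L) stop("'stack' must be a matrix or 3D array")
  if (length(d) == 2L) return(stack)
  if (d[3L] < 1L) stop("'stack' must contain at least one slice")
  out <- stack[, , 1L]
  if (d[3L] > 1L)
    for (s in 2:d[3L]) out <- pmax(out, stack[, , s])
  out
}

#' Wide-Gaussian background correction
#'
#' Estimates the nonuniform illumination background as a wide Gaussian blur
#' of the image itself and subtracts it, clipping at zero. This acts as a
#' high-pass filter: it flattens slowly varying illumination while
#' preserving structures smaller than \code{sigma}, and is used here to
#' make Otsu segmentation robust to uneven illumination.
#'
#' @param image numeric matrix
#' @param sigma Gaussian standard deviation in pixels (default 10)
#' @return nonnegative numeric matrix of the same shape
#' @export
backgroundCorrect <- function(image, sigma = 10) {
  .assertScalar(sigma, "sigma", positive = TRUE)
  if (is.null(dim(image)) || length(dim(image)) != 2L)
    stop("'image' must be a 2D matrix")
  radius <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  fit <- min(dim(image))
  if (radius > fit) radius <- fit - (1L - fit %% 2L)  # largest odd <= fit
  bg <- as.matrix(EBImage::gblur(image, sigma = sigma, radius = radius))
  out <- image - bg
  out[out < 0] <- 0
  out
}

#' Otsu threshold
#'
#' Exhaustively maximizes the between-class variance over the edges of an
#' \code{nBins}-bin histogram spanning the image's min-max range. Ties are
#' broken by the lowest maximizing bin edge, making the result
#' deterministic. Foreground is \code{image > threshold}.
#'
#' @param image numeric matrix (or vector) with at least two distinct values
#' @param nBins number of histogram bins (default 256)
#' @return the threshold intensity (a bin edge)
#' @export
otsuThreshold <- function(image, nBins = 256L) {
  x <- as.numeric(image)
  if (!length(x)) stop("empty image")
  lo <- min(x); hi <- max(x)
  if (hi <= lo)
    stop("degenerate input: constant image has no Otsu threshold")
  breaks <- seq(lo, hi, length.out = nBins + 1L)
  idx <- pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L), nBins)
  counts <- tabulate(idx, nbins = nBins)
  centers <- (breaks[-1L] + breaks[-(nBins + 1L)]) / 2
  n <- length(x)
  w1 <- cumsum(counts)[-nBins]                 # class 1 = bins 1..k
  m1 <- cumsum(counts * centers)[-nBins]
  w2 <- n - w1
  mu1 <- ifelse(w1 > 0, m1 / w1, 0)
  mu2 <- ifelse(w2 > 0, (sum(counts * centers) - m1) / w2, 0)
  sigmaB <- w1 * w2 * (mu1 - mu2)^2
  k <- which.max(sigmaB)                        # which.max takes first maximum
  breaks[k + 1L]
}

#' Segment the transfected cell from the membrane-probe channel
#'
#' Otsu-thresholds the (background-corrected) membrane channel, fills
#' holes, and keeps the largest connected component, matching a
#' one-transfected-cell-per-field analysis.
#'
#' @param membrane numeric matrix
#' @return logical mask
#' @export
segmentCell <- function(membrane) {
  thr <- otsuThreshold(membrane)
  fg <- EBImage::Image((membrane > thr) * 1)
  fg <- EBImage::fillHull(fg)
  lab <- EBImage::bwlabel(fg)
  labm <- as.matrix(lab)
  if (max(labm) == 0) stop("degenerate input: no foreground found")
  sizes <- tabulate(labm[labm > 0])
  matrix(labm == which.max(sizes), nrow(membrane), ncol(membrane))
}

#' Segment mitochondria from the marker channel
#'
#' Otsu-thresholds the (background-corrected) TOM20 channel and intersects
#' the foreground with the cell mask. The threshold is computed from the
#' intensity histogram of the pixels inside the cell mask: the analysis is
#' per transfected cell, and letting the large extracellular area dominate
#' the histogram would push the Otsu split into the foreground mode and
#' clip dim tubules.
#'
#' After thresholding, the mask is completed by hysteresis: pixels above
#' \code{hysteresis} times the threshold that are 8-connected to the Otsu
#' foreground are included. High-pass background correction suppresses
#' tubules in locally dense network regions (their neighbourhood mean
#' approaches their own intensity), and hysteresis recovers these dim
#' stretches without admitting cytosolic pixels. \code{hysteresis = 1}
#' disables the completion.
#'
#' @param tom20 numeric matrix
#' @param cellMask logical mask from \code{\link{segmentCell}}
#' @param hysteresis fraction of the Otsu threshold used as the weak
#'   threshold for connected completion (default 0.5)
#' @return logical mask contained in \code{cellMask}
#' @export
segmentMitochondria <- function(tom20, cellMask, hysteresis = 0.5) {
  if (!any(cellMask)) stop("precondition failed: empty cell mask")
  thr <- otsuThreshold(tom20[cellMask])
  strong <- (tom20 > thr) & cellMask
  if (hysteresis >= 1 || !any(strong)) return(strong)
  weak <- (tom20 > hysteresis * thr) & cellMask
  lab <- as.matrix(EBImage::bwlabel(EBImage::Image(weak * 1)))
  keep <- unique(lab[strong])
  keep <- keep[keep > 0]
  matrix(lab %in% keep, nrow(tom20), ncol(tom20)) & weak
}

#' Mitochondrial enrichment ratio
#'
#' Divides the mean reporter intensity inside the mitochondrial mask by the
#' mean reporter intensity in the cell outside the mitochondrial mask. A
#' ratio above 1 indicates mitochondrial enrichment of the reporter; below
#' 1, cytosolic enrichment. To limit partial-volume bias from the
#' microscope PSF, the mitochondrial measurement mask may be eroded by
#' \code{erodePx} (falling back to the full mask if erosion empties it) and
#' a guard ring of \code{guardPx} around the mitochondria may be excluded
#' from the cytosolic region. Reported areas always refer to the original
#' segmentation masks.
#'
#' @param pink1 numeric matrix, reporter channel (projected,
#'   background-offset corrected)
#' @param mitoMask logical mitochondrial mask
#' @param cellMask logical cell mask
#' @param pixelSize micrometres per pixel (for the reported areas)
#' @param guardPx width in pixels of the excluded ring around mitochondria
#' @param erodePx erosion radius in pixels for the mitochondrial
#'   measurement mask
#' @return one-row data.frame: ratio, mito_mean, cyto_mean, cell_area,
#'   mito_area (areas in square micrometres)
#' @export
enrichmentRatio <- function(pink1, mitoMask, cellMask, pixelSize = 1,
                            guardPx = 2L, erodePx = 1L) {
  mitoMask <- mitoMask & cellMask
  if (!any(cellMask)) stop("precondition failed: empty cell mask")
  if (!any(mitoMask)) stop("precondition failed: empty mitochondrial mask")
  h <- nrow(pink1); w <- ncol(pink1)
  mitoMeasure <- mitoMask
  if (erodePx > 0) {
    er <- matrix(as.logical(EBImage::erode(
      EBImage::Image(mitoMask * 1), .discBrush(2L * erodePx + 1L)) > 0.5), h, w)
    if (any(er)) mitoMeasure <- er
  }
  guard <- mitoMask
  if (guardPx > 0) {
    guard <- matrix(as.logical(EBImage::dilate(
      EBImage::Image(mitoMask * 1), .discBrush(2L * guardPx + 1L)) > 0.5), h, w)
  }
  cytoMeasure <- cellMask & !guard
  if (!any(cytoMeasure)) cytoMeasure <- cellMask & !mitoMask
  if (!any(cytoMeasure))
    stop("undefined ratio: cytosolic region is empty")
  mitoMean <- mean(pink1[mitoMeasure])
  cytoMean <- mean(pink1[cytoMeasure])
  if (cytoMean <= 0)
    stop("undefined ratio: cytosolic mean intensity is zero")
  data.frame(
    ratio = mitoMean / cytoMean,
    mito_mean = mitoMean,
    cyto_mean = cytoMean,
    cell_area = sum(cellMask) * pixelSize^2,
    mito_area = sum(mitoMask) * pixelSize^2)
}

#' Segmentation quality control
#'
#' Automated stand-in for manual rejection of bad segmentations: the cell
#' must occupy 2--85\% of the field, the mitochondria 0.5--70\% of the
#' cell, and the cell mask must not touch more than 25\% of the field
#' border.
#'
#' @param cellMask,mitoMask logical masks of identical shape
#' @param limits optional named list overriding \code{cellAreaRange} (field
#'   fraction), \code{mitoAreaRange} (cell fraction) and
#'   \code{borderFraction}
#' @return list(pass = logical, reasons = character vector)
#' @export
qcCheck <- function(cellMask, mitoMask, limits = list()) {
  stopifnot(identical(dim(cellMask), dim(mitoMask)))
  lim <- list(cellAreaRange = c(0.02, 0.85),
              mitoAreaRange = c(0.005, 0.70),
              borderFraction = 0.25)
  lim[names(limits)] <- limits
  reasons <- character(0)
  fieldArea <- length(cellMask)
  cellArea <- sum(cellMask)
  cellFrac <- cellArea / fieldArea
  if (cellFrac < lim$cellAreaRange[1L] || cellFrac > lim$cellAreaRange[2L])
    reasons <- c(reasons, "cell_area_out_of_range")
  mitoFrac <- if (cellArea > 0) sum(mitoMask & cellMask) / cellArea else 0
  if (mitoFrac < lim$mitoAreaRange[1L] || mitoFrac > lim$mitoAreaRange[2L])
    reasons <- c(reasons, "mito_area_out_of_range")
  border <- c(cellMask[1L, ], cellMask[nrow(cellMask), ],
              cellMask[, 1L], cellMask[, ncol(cellMask)])
  if (mean(border) > lim$borderFraction)
    reasons <- c(reasons, "cell_touches_border")
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Quantify mitochondrial enrichment for one scene
#'
#' Full per-cell pipeline: maximum-intensity projection of each channel
#' (when the scene is a z-stack), wide-Gaussian background correction
#' (\code{bgSigma}) of the segmentation channels, Otsu segmentation of the
#' cell (membrane channel) and of the mitochondria (TOM20 channel), the
#' enrichment ratio on the reporter projection after subtracting the
#' extracellular background offset, and quality control. The high-pass
#' corrected images drive segmentation only; the reporter ratio is measured
#' on the projection minus the median extracellular intensity, so that the
#' diffuse cytosolic reporter pool is retained as signal.
#'
#' @param scene an \linkS4class{ImageScene}
#' @param bgSigma background-correction sigma in pixels (default 10)
#' @param project if FALSE, quantify each z slice separately and report the
#'   mean ratio over slices instead of projecting first
#' @param guardPx,erodePx see \code{\link{enrichmentRatio}}
#' @param qcLimits see \code{\link{qcCheck}}
#' @return one-row data.frame (scene_id, ratio, mito_mean, cyto_mean,
#'   cell_area, mito_area, qc_pass, qc_reasons)
#' @export
quantifyScene <- function(scene, bgSigma = 10, project = TRUE,
                          guardPx = 2L, erodePx = 1L, qcLimits = list()) {
  stopifnot(is(scene, "ImageScene"))
  id <- sceneId(scene)
  run2d <- function(pink1, tom20, membrane) {
    membraneC <- backgroundCorrect(membrane, bgSigma)
    tom20C <- backgroundCorrect(tom20, bgSigma)
    cell <- segmentCell(membraneC)
    # a structureless marker channel (degenerate Otsu input) yields an
    # empty mask and is rejected by QC rather than aborting the batch
    mito <- tryCatch(segmentMitochondria(tom20C, cell),
                     error = function(e) cell & FALSE)
    qc <- qcCheck(cell, mito, qcLimits)
    if (!any(mito)) {
      return(list(row = data.frame(ratio = NA_real_, mito_mean = NA_real_,
                                   cyto_mean = NA_real_,
                                   cell_area = sum(cell) * pixelSize(scene)^2,
                                   mito_area = 0),
                  qc = list(pass = FALSE,
                            reasons = unique(c(qc$reasons,
                                               "mito_area_out_of_range")))))
    }
    offset <- if (any(!cell)) median(pink1[!cell]) else 0
    pink1C <- pmax(pink1 - offset, 0)
    row <- enrichmentRatio(pink1C, mito, cell, pixelSize(scene),
                           guardPx = guardPx, erodePx = erodePx)
    list(row = row, qc = qc, cell = cell, mito = mito)
  }
  res <- tryCatch({
    if (project) {
      run2d(maxProject(getChannel(scene, "pink1")),
            maxProject(getChannel(scene, "tom20")),
            maxProject(getChannel(scene, "membrane")))
    } else {
      p <- getChannel(scene, "pink1")
      if (length(dim(p)) == 2L) {
        run2d(p, getChannel(scene, "tom20"), getChannel(scene, "membrane"))
      } else {
        per <- lapply(seq_len(dim(p)[3L]), function(s)
          run2d(p[, , s], getChannel(scene, "tom20")[, , s],
                getChannel(scene, "membrane")[, , s]))
        rows <- do.call(rbind, lapply(per, `[[`, "row"))
        qcs <- lapply(per, `[[`, "qc")
        list(row = data.frame(ratio = mean(rows$ratio),
                              mito_mean = mean(rows$mito_mean),
                              cyto_mean = mean(rows$cyto_mean),
                              cell_area = mean(rows$cell_area),
                              mito_area = mean(rows$mito_area)),
             qc = list(pass = all(vapply(qcs, `[[`, logical(1L), "pass")),
                       reasons = unique(unlist(lapply(qcs, `[[`, "reasons")))))
      }
    }
  }, error = function(e) stop("scene '", id, "': ", conditionMessage(e),
                              call. = FALSE))
  out <- cbind(data.frame(scene_id = id), res$row)
  out$qc_pass <- res$qc$pass
  out$qc_reasons <- paste(res$qc$reasons, collapse = ";")
  attr(out, "masks") <- list(cell = res$cell, mito = res$mito)
  out
}

#' Quantify a batch of scenes
#'
#' @param pairs list of \code{list(scene, truth)} (truth optional) or of
#'   \linkS4class{ImageScene} objects
#' @param ... passed to \code{\link{quantifyScene}}
#' @return data.frame with one row per scene; the attribute
#'   \code{"summary"} holds the mean/median/SD of the ratio over QC-passing
#'   scenes
#' @export
quantifyBatch <- function(pairs, ...) {
  rows <- lapply(pairs, function(p) {
    scene <- if (is(p, "ImageScene")) p else p$scene
    r <- quantifyScene(scene, ...)
    attr(r, "masks") <- NULL
    if (!is.null(p$truth) && !is(p, "ImageScene"))
      r$true_enrichment <- trueEnrichment(p$truth)
    r
  })
  out <- do.call(rbind, rows)
  ok <- out$qc_pass & !is.na(out$ratio)
  attr(out, "summary") <- data.frame(
    n = nrow(out), n_pass = sum(ok),
    mean_ratio = mean(out$ratio[ok]),
    median_ratio = median(out$ratio[ok]),
    sd_ratio = sd(out$ratio[ok]))
  out
}
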