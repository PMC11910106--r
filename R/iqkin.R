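#' Simulate internally quenched protease progress curves
#'
#' Integrates substrate depletion under Michaelis-Menten kinetics,
#' dS/dt = -kcat * E * S / (Km + S), with a fixed-step fourth-order
#' Runge-Kutta scheme (step 0.01 min), and renders raw plate-reader
#' fluorescence as baseline + drift + fluorCoeff * product, with optional
#' Gaussian read noise. Matched no-enzyme blank wells carry the same
#' baseline and drift, and the proteinase-K full-digest endpoint change is
#' \code{fluorCoeff * S0} per concentration.
#'
#' @param kcat turnover number, per minute
#' @param Km Michaelis constant, micromolar
#' @param enzymeConc enzyme concentration, micromolar (0.8 by default)
#' @param substrateConcs substrate concentrations, micromolar
#' @param times sampling times in minutes (default every 3 min over 150)
#' @param fluorCoeff fluorescence yield, RFU per micromolar product
#' @param baseline instrument baseline, RFU
#' @param drift common linear drift, RFU per minute (also in the blanks)
#' @param noiseSigma Gaussian noise SD in RFU (0 = noiseless)
#' @param seed RNG seed
#' @param step integration step in minutes
#' @return a \linkS4class{ProgressCurveSet}
#' @export
simulateProgressCurves <- function(kcat, Km, enzymeConc = 0.8,
                                   substrateConcs = c(0.1, 0.3, 1, 3, 10,
                                                      30, 100),
                                   times = seq(0, 150, by = 3),
                                   fluorCoeff = 12, baseline = 50,
                                   drift = 0.05, noiseSigma = 0, seed = 1L,
                                   step = 0.01) {
  .assertScalar(kcat, "kcat", positive = TRUE)
  .assertScalar(Km, "Km", positive = TRUE)
  .assertScalar(enzymeConc, "enzymeConc", positive = TRUE)
  .assertScalar(fluorCoeff, "fluorCoeff", positive = TRUE)
  .assertScalar(noiseSigma, "noiseSigma", nonneg = TRUE)
  .assertScalar(step, "step", positive = TRUE)
  if (any(substrateConcs <= 0)) stop("'substrateConcs' must be > 0")
  substrateConcs <- sort(substrateConcs)
  S <- .integrateMM(kcat * enzymeConc, Km, substrateConcs, times, step)
  P <- sweep(-S, 2L, substrateConcs, `+`)        # product = S0 - S(t)
  .withSeed(seed, {
    rfu <- baseline + drift * times + fluorCoeff * P
    blank <- matrix(baseline + drift * times, length(times),
                    length(substrateConcs))
    fullDigest <- fluorCoeff * substrateConcs
    if (noiseSigma > 0) {
      rfu <- rfu + rnorm(length(rfu), 0, noiseSigma)
      blank <- blank + rnorm(length(blank), 0, noiseSigma)
      fullDigest <- fullDigest + rnorm(length(fullDigest), 0, noiseSigma)
    }
    new("ProgressCurveSet", times = as.numeric(times),
        substrateConcs = as.numeric(substrateConcs),
        rfu = rfu, blankRfu = blank,
        fullDigestDelta = as.numeric(fullDigest),
        enzymeConc = enzymeConc)
  })
}

# RK4 substrate depletion for a vector of starting concentrations;
# returns a times x concentrations matrix of S(t)
.integrateMM <- function(Vmax, Km, s0, times, step) {
  f <- function(s) -Vmax * s / (Km + s)
  tEnd <- max(times)
  nSteps <- ceiling(tEnd / step + 1e-9)
  S <- s0
  out <- matrix(NA_real_, length(times), length(s0))
  grab <- which(abs(times - 0) < step / 2)
  if (length(grab)) out[grab, ] <- rep(S, each = length(grab))
  t <- 0
  for (i in seq_len(nSteps)) {
    h <- min(step, tEnd - t)
    k1 <- f(S)
    k2 <- f(S + h / 2 * k1)
    k3 <- f(S + h / 2 * k2)
    k4 <- f(S + h * k3)
    S <- pmax(S + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4), 0)
    t <- t + h
    grab <- which(abs(times - t) < step / 2)
    if (length(grab)) out[grab, ] <- rep(S, each = length(grab))
  }
  if (anyNA(out)) stop("internal error: sampling times not covered")
  out
}

#' Subtract matched blank wells
#'
#' Removes the no-enzyme background fluorescence from every time point and
#' substrate concentration; the blank matrix of the returned set is zeroed.
#'
#' @param curves a \linkS4class{ProgressCurveSet}
#' @return a \linkS4class{ProgressCurveSet} with corrected \code{rfu}
#' @export
blankSubtract <- function(curves) {
  stopifnot(is(curves, "ProgressCurveSet"))
  if (!identical(dim(curves@rfu), dim(curves@blankRfu)))
    stop("blank matrix does not match the signal matrix")
  curves@rfu <- curves@rfu - curves@blankRfu
  curves@blankRfu <- curves@blankRfu * 0
  curves
}

#' RFU-to-concentration calibration slope
#'
#' Least-squares line of the full-digest endpoint fluorescence change
#' against substrate concentration. The intercept absorbs plate offsets and
#' is reported as an attribute, but conversion uses the slope alone.
#'
#' @param fullDigestDelta maximum fluorescence change per concentration
#'   after complete digestion (RFU)
#' @param substrateConcs micromolar, same length
#' @return slope in RFU per micromolar, with attributes \code{intercept}
#'   and \code{se}
#' @export
calibrationSlope <- function(fullDigestDelta, substrateConcs) {
  if (length(fullDigestDelta) != length(substrateConcs) ||
      length(substrateConcs) < 2L)
    stop("need at least 2 matched (concentration, delta-F) points")
  fit <- lm(fullDigestDelta ~ substrateConcs)
  slope <- unname(coef(fit)[2L])
  se <- suppressWarnings(unname(sqrt(diag(vcov(fit)))[2L]))
  structure(slope, intercept = unname(coef(fit)[1L]), se = se)
}

#' Initial velocity from a progress curve
#'
#' Fits a line to the early part of a blank-subtracted fluorescence time
#' course and converts the slope to micromolar per minute with the
#' full-digest calibration slope. The fit window is the longest initial
#' span over which estimated substrate conversion stays at or below
#' \code{maxConversion}, but never fewer than \code{minPoints} points; if
#' the conversion cap is exceeded within the minimum window the result is
#' flagged \code{high_conversion}.
#'
#' @param times minutes
#' @param rfu blank-subtracted fluorescence, same length
#' @param slopeCal calibration slope in RFU per micromolar
#' @param s0 substrate concentration of this well, micromolar
#' @param maxConversion fraction of substrate allowed to convert within
#'   the fit window (default 0.1)
#' @param minPoints minimum points in the fit window (default 5)
#' @return velocity in micromolar per minute, with attributes
#'   \code{window} (points used) and \code{high_conversion}
#' @export
initialVelocity <- function(times, rfu, slopeCal, s0,
                            maxConversion = 0.1, minPoints = 5L) {
  if (length(times) != length(rfu))
    stop("'times' and 'rfu' must have equal length")
  if (length(times) < minPoints)
    stop("insufficient data: need at least ", minPoints, " time points")
  .assertScalar(slopeCal, "slopeCal", positive = TRUE)
  .assertScalar(s0, "s0", positive = TRUE)
  conversion <- (rfu - rfu[1L]) / (as.numeric(slopeCal) * s0)
  okTo <- which(cummax(conversion) > maxConversion)[1L]
  window <- if (is.na(okTo)) length(times) else okTo - 1L
  highConv <- window < minPoints
  window <- max(window, minPoints)
  fit <- lm(rfu[seq_len(window)] ~ times[seq_len(window)])
  v <- unname(coef(fit)[2L]) / as.numeric(slopeCal)
  structure(v, window = window, high_conversion = highConv)
}

#' Fit the Michaelis-Menten model to initial velocities
#'
#' Nonlinear least squares of v = Vmax * S / (Km + S) using
#' Levenberg-Marquardt, initialised at Vmax = max(v) and Km = the substrate
#' concentration at half-maximal velocity (linearly interpolated). The
#' turnover number is kcat = Vmax / [E].
#'
#' @param s substrate concentrations, micromolar (>= 4 distinct values)
#' @param v initial velocities, micromolar per minute
#' @param enzymeConc enzyme concentration, micromolar
#' @return an \linkS4class{MMFit}
#' @export
fitMM <- function(s, v, enzymeConc) {
  if (length(s) != length(v)) stop("'s' and 'v' must have equal length")
  if (length(unique(s)) < 4L)
    stop("need at least 4 distinct substrate concentrations")
  .assertScalar(enzymeConc, "enzymeConc", positive = TRUE)
  ord <- order(s)
  s <- s[ord]; v <- v[ord]
  vmax0 <- max(v)
  if (vmax0 <= 0) stop("fit error: all velocities are non-positive")
  half <- vmax0 / 2
  km0 <- tryCatch({
    above <- which(v >= half)[1L]
    if (is.na(above) || above == 1L) s[1L]
    else {
      f <- (half - v[above - 1L]) / (v[above] - v[above - 1L])
      s[above - 1L] + f * (s[above] - s[above - 1L])
    }
  }, error = function(e) median(s))
  if (!is.finite(km0) || km0 <= 0) km0 <- median(s)
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ Vmax * s / (Km + s),
                      start = list(Vmax = vmax0, Km = km0),
                      lower = c(Vmax = 1e-12, Km = 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("fit error: Michaelis-Menten fit did not converge (",
           conditionMessage(e), "); starts Vmax=", signif(vmax0, 3),
           " Km=", signif(km0, 3), call. = FALSE))
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e)
    c(Vmax = NA_real_, Km = NA_real_))
  flags <- character(0)
  if (est[["Km"]] < min(s) / 100 || est[["Km"]] > max(s) * 100)
    flags <- c(flags, "Km_outside_data_range")
  new("MMFit",
      Vmax = unname(est[["Vmax"]]), Km = unname(est[["Km"]]),
      kcat = unname(est[["Vmax"]]) / enzymeConc,
      kcatOverKm = unname(est[["Vmax"]]) / enzymeConc / unname(est[["Km"]]),
      se = c(Vmax = unname(se[1L]), Km = unname(se[2L])),
      residuals = as.numeric(residuals(fit)),
      converged = TRUE, flags = flags)
}

#' Catalytic efficiency ratio between two fits
#'
#' @param fitA,fitB \linkS4class{MMFit} objects (numerator, denominator)
#' @return (kcat/Km)_A / (kcat/Km)_B
#' @export
efficiencyRatio <- function(fitA, fitB) {
  stopifnot(is(fitA, "MMFit"), is(fitB, "MMFit"))
  if (!isTRUE(fitA@converged) || !isTRUE(fitB@converged))
    stop("both fits must have converged")
  if (fitB@kcatOverKm == 0)
    stop("undefined ratio: denominator efficiency is zero")
  fitA@kcatOverKm / fitB@kcatOverKm
}

#' Analyze a progress-curve set end to end
#'
#' Blank subtraction, full-digest calibration, per-concentration initial
#' velocities, and the Michaelis-Menten fit.
#'
#' @param curves a \linkS4class{ProgressCurveSet}
#' @param ... passed to \code{\link{initialVelocity}}
#' @return list(fit = \linkS4class{MMFit}, velocities = data.frame(s, v,
#'   high_conversion), slope = calibration slope)
#' @export
analyzeCurveSet <- function(curves, ...) {
  stopifnot(is(curves, "ProgressCurveSet"))
  corrected <- blankSubtract(curves)
  slope <- calibrationSlope(corrected@fullDigestDelta,
                            corrected@substrateConcs)
  vel <- lapply(seq_along(corrected@substrateConcs), function(j)
    initialVelocity(corrected@times, corrected@rfu[, j], slope,
                    corrected@substrateConcs[j], ...))
  vdf <- data.frame(
    s = corrected@substrateConcs,
    v = vapply(vel, as.numeric, numeric(1L)),
    high_conversion = vapply(vel, attr, logical(1L), "high_conversion"))
  list(fit = fitMM(vdf$s, vdf$v, corrected@enzymeConc),
       velocities = vdf, slope = slope)
}

#' Write a progress-curve set as a long-format plate CSV
#'
#' Columns: time_min, substrate_uM, replicate, rfu, is_blank,
#' is_full_digest. Full-digest rows carry the endpoint delta in \code{rfu}
#' with \code{time_min = NA}.
#'
#' @param curves a \linkS4class{ProgressCurveSet}
#' @param path output CSV path
#' @param replicate replicate label
#' @return invisibly, \code{path}
#' @export
writePlateCsv <- function(curves, path, replicate = "rep1") {
  stopifnot(is(curves, "ProgressCurveSet"))
  long <- function(mat, isBlank) {
    do.call(rbind, lapply(seq_along(curves@substrateConcs), function(j)
      data.frame(time_min = curves@times,
                 substrate_uM = curves@substrateConcs[j],
                 replicate = replicate, rfu = mat[, j],
                 is_blank = isBlank, is_full_digest = FALSE)))
  }
  df <- rbind(long(curves@rfu, FALSE), long(curves@blankRfu, TRUE),
              data.frame(time_min = NA_real_,
                         substrate_uM = curves@substrateConcs,
                         replicate = replicate,
                         rfu = curves@fullDigestDelta,
                         is_blank = FALSE, is_full_digest = TRUE))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a long-format plate CSV
#'
#' @param path CSV written by \code{\link{writePlateCsv}} (or any file with
#'   the same columns)
#' @param enzymeConc enzyme concentration in micromolar
#' @return named list of \linkS4class{ProgressCurveSet}, one per replicate
#' @export
readPlateCsv <- function(path, enzymeConc = 0.8) {
  df <- read.csv(path)
  need <- c("time_min", "substrate_uM", "replicate", "rfu", "is_blank",
            "is_full_digest")
  if (!all(need %in% names(df)))
    stop("plate CSV must have columns: ", paste(need, collapse = ", "))
  out <- lapply(split(df, df$replicate), function(d) {
    fd <- d[d$is_full_digest, ]
    ts <- d[!d$is_full_digest, ]
    concs <- sort(unique(ts$substrate_uM))
    times <- sort(unique(ts$time_min))
    grab <- function(isBlank) {
      m <- matrix(NA_real_, length(times), length(concs))
      sub <- ts[ts$is_blank == isBlank, ]
      m[cbind(match(sub$time_min, times), match(sub$substrate_uM, concs))] <-
        sub$rfu
      m
    }
    new("ProgressCurveSet", times = times, substrateConcs = concs,
        rfu = grab(FALSE), blankRfu = grab(TRUE),
        fullDigestDelta = fd$rfu[match(concs, fd$substrate_uM)],
        enzymeConc = enzymeConc)
  })
  out
}
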