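#' Brown-Forsythe one-way ANOVA
#'
#' Unequal-variance one-way ANOVA using the Brown-Forsythe F* statistic,
#' F* = sum n_i (ybar_i - ybar)^2 / sum (1 - n_i/N) s_i^2, with df1 = k - 1
#' and Satterthwaite denominator degrees of freedom
#' 1/df2 = sum c_i^2 / (n_i - 1), where c_i is the i-th group's share of
#' the denominator. This is the omnibus test reported alongside group
#' comparisons when group variances cannot be assumed equal.
#'
#' @param values numeric observations
#' @param groups group labels, same length
#' @return an object of class \code{htest} with the F* statistic, both
#'   degrees of freedom and the p-value
#' @export
brownForsytheAnova <- function(values, groups) {
  groups <- factor(groups)
  if (length(values) != length(groups))
    stop("'values' and 'groups' must have equal length")
  k <- nlevels(groups)
  if (k < 2L) stop("need at least 2 groups")
  ni <- tabulate(groups)
  if (any(ni < 2L)) stop("every group needs at least 2 observations")
  N <- sum(ni)
  mi <- tapply(values, groups, mean)
  vi <- tapply(values, groups, var)
  if (all(vi == 0)) stop("degenerate input: all group variances are zero")
  grand <- mean(values)
  num <- sum(ni * (mi - grand)^2)
  wi <- (1 - ni / N) * vi
  den <- sum(wi)
  Fstar <- num / den
  ci <- wi / den
  df2 <- 1 / sum(ci^2 / (ni - 1))
  df1 <- k - 1
  p <- pf(Fstar, df1, df2, lower.tail = FALSE)
  structure(list(
    statistic = c("F*" = Fstar),
    parameter = c(df1 = df1, df2 = df2),
    p.value = p,
    method = "Brown-Forsythe one-way ANOVA (Satterthwaite df)",
    data.name = paste(deparse(substitute(values)), "by",
                      deparse(substitute(groups)))),
    class = "htest")
}

#' Sidak multiplicity adjustment
#'
#' p_adj = 1 - (1 - p)^m for m comparisons, clipped to 1; the input order
#' is preserved and the adjustment is monotone.
#'
#' @param pValues numeric vector of p-values in [0, 1]
#' @param m number of comparisons (defaults to \code{length(pValues)})
#' @return adjusted p-values, same order
#' @export
sidakAdjust <- function(pValues, m = length(pValues)) {
  if (any(!is.finite(pValues)) || any(pValues < 0) || any(pValues > 1))
    stop("p-values must lie in [0, 1]")
  if (m < 1L) stop("'m' must be >= 1")
  pmin(1 - (1 - pValues)^m, 1)
}

#' Paired t test
#'
#' Two-sided paired t test: t = mean(d) / (sd(d)/sqrt(n)) on the pairwise
#' differences d = a - b, with n - 1 degrees of freedom.
#'
#' @param a,b paired numeric vectors of equal length >= 2
#' @return an object of class \code{htest}
#' @export
pairedT <- function(a, b) {
  if (length(a) != length(b)) stop("'a' and 'b' must have equal length")
  if (length(a) < 2L) stop("need at least 2 pairs")
  d <- a - b
  sdd <- sd(d)
  if (sdd == 0)
    stop("degenerate input: zero variance of the pairwise differences")
  n <- length(d)
  tstat <- mean(d) / (sdd / sqrt(n))
  df <- n - 1
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  structure(list(
    statistic = c(t = tstat),
    parameter = c(df = df),
    p.value = p,
    estimate = c("mean difference" = mean(d)),
    method = "Paired t test (two-sided)",
    data.name = "a versus b"),
    class = "htest")
}

#' Normalize densitometry values to a reference condition
#'
#' Divides every value by the reference value so the reference maps to
#' exactly 1, as in immunoblot densitometry normalised to the wild type.
#'
#' @param values named numeric vector, or unnamed with \code{labels}
#' @param reference name of the reference condition
#' @param labels optional condition labels when \code{values} is unnamed
#' @return normalised values, names preserved
#' @export
normalizeToReference <- function(values, reference, labels = names(values)) {
  if (is.null(labels)) stop("condition labels are required")
  names(values) <- labels
  if (!reference %in% labels)
    stop("reference condition '", reference, "' not present")
  ref <- values[[reference]]
  if (!is.finite(ref) || ref == 0)
    stop("reference value must be finite and nonzero")
  values / ref
}
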