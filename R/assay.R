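#' Fit a linear standard curve
#'
#' Ordinary least squares of response on known amount, as used for free
#' 4-MU fluorescence and BCA protein standards.
#'
#' @param x known amounts (nmol or mg/mL), at least two distinct values.
#' @param y measured responses (fluorescence or absorbance).
#' @return \code{StandardCurve} list: slope, intercept, r2.
#' @examples
#' fitStandardCurve(0:4, 2 * (0:4) + 1)
#' @export
fitStandardCurve <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(unique(x)) < 2) stop("at least two distinct x values required")
  fit <- stats::lm(y ~ x)
  ssTot <- sum((y - mean(y))^2)
  r2 <- if (ssTot == 0) 1 else 1 - sum(stats::resid(fit)^2) / ssTot
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]), r2 = r2,
                 n = length(x)),
            class = "StandardCurve")
}

#' Back-calculate enzyme activity from a fluorometric response
#'
#' Released 4-MU = (response - intercept) / slope; activity = released
#' amount per unit time per mg protein. Negative back-calculated amounts are
#' flagged and emitted as zero with a warning. Units: nmol/min/mg (default,
#' as reported per assay figure conventions) or nmol/h/mg (factor 60).
#'
#' @param response measured fluorescence (vectorized).
#' @param curve a [fitStandardCurve()] result.
#' @param timeMin incubation time in minutes (> 0).
#' @param proteinMg protein mass in mg (> 0).
#' @param unit \code{"nmol_min_mg"} or \code{"nmol_h_mg"}.
#' @return numeric activities.
#' @export
enzymeActivity <- function(response, curve, timeMin, proteinMg,
                           unit = c("nmol_min_mg", "nmol_h_mg")) {
  unit <- match.arg(unit)
  stopifnot(inherits(curve, "StandardCurve"))
  if (curve$slope == 0) stop("standard-curve slope must be non-zero")
  if (any(timeMin <= 0) || any(proteinMg <= 0))
    stop("incubation time and protein mass must be positive")
  released <- (response - curve$intercept) / curve$slope
  neg <- released < 0
  if (any(neg)) {
    warning(sprintf("%d negative back-calculated amount(s) emitted as 0",
                    sum(neg)))
    released[neg] <- 0
  }
  act <- released / timeMin / proteinMg
  if (unit == "nmol_h_mg") act <- act * 60
  act
}

#' Activities for every unknown well of an assay plate
#'
#' Fits the standard curve from the plate's standard wells and back-
#' calculates each unknown well's normalized activity.
#'
#' @param plate data.frame as produced by [simulateAssayPlate()] /
#'   [readPlate()].
#' @param unit see [enzymeActivity()].
#' @return data.frame(sample_id, activity) plus the curve in attribute
#'   \code{"curve"}.
#' @export
assayActivities <- function(plate, unit = "nmol_min_mg") {
  st <- plate[plate$role == "standard", ]
  un <- plate[plate$role == "unknown", ]
  curve <- fitStandardCurve(st$known_amount, st$response)
  act <- enzymeActivity(un$response, curve, un$time_min, un$protein_mg,
                        unit = unit)
  structure(data.frame(sample_id = un$sample_id, activity = act,
                       stringsAsFactors = FALSE),
            curve = curve)
}

#' Replicate summary: mean and sample SD
#'
#' @param values replicate measurements (n >= 2 for a defined SD).
#' @param label optional group label.
#' @return \code{AssaySummary} list: label, n, mean, sd (sample SD, n - 1
#'   denominator; NA with a warning when n < 2). Values are kept at full
#'   precision; round only at report time.
#' @examples
#' groupSummary(c(6.66, 6.74, 6.87))  # mean 6.75, sd 0.11 at 2 dp
#' @export
groupSummary <- function(values, label = NA_character_) {
  n <- length(values)
  s <- if (n < 2) {
    warning("fewer than 2 replicates: SD undefined")
    NA_real_
  } else stats::sd(values)
  structure(list(label = label, n = n, mean = mean(values), sd = s),
            class = "AssaySummary")
}

.pooledT <- function(meanA, sdA, nA, meanB, sdB, nB) {
  df <- nA + nB - 2
  sp2 <- ((nA - 1) * sdA^2 + (nB - 1) * sdB^2) / df
  se <- sqrt(sp2 * (1 / nA + 1 / nB))
  diff <- meanA - meanB
  if (se == 0) {
    t <- if (diff == 0) 0 else Inf * sign(diff)
    if (is.infinite(t)) warning("zero pooled variance with unequal means")
  } else t <- diff / se
  list(t = t, df = df)
}

.tailP <- function(t, df, tails) {
  if (tails == "two") {
    if (is.infinite(t)) 0 else 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  } else {
    # one-tailed: tests mean_a > mean_b (upregulation in the first group)
    if (is.infinite(t)) { if (t > 0) 0 else 1 }
    else stats::pt(t, df, lower.tail = FALSE)
  }
}

#' Two-sample t-test on raw replicate values
#'
#' Pooled-variance Student t by default (df = n1 + n2 - 2), two-tailed by
#' default; the one-tailed mode tests for upregulation in the first group.
#' Welch's unequal-variance form is available as an option.
#'
#' @param a,b numeric replicate vectors (>= 2 values each).
#' @param tails \code{"two"} or \code{"one"}.
#' @param variance \code{"pooled"} or \code{"welch"}.
#' @return \code{TTestResult} list: t, df, tails, variance, p.
#' @examples
#' twoSampleT(c(2.64, 3.02, 3.26), c(2.48, 2.57, 5.68))$p  # ~0.60
#' @export
twoSampleT <- function(a, b, tails = c("two", "one"),
                       variance = c("pooled", "welch")) {
  tails <- match.arg(tails); variance <- match.arg(variance)
  if (length(a) < 2 || length(b) < 2)
    stop("at least 2 values per group are required")
  tFromSummary(mean(a), stats::sd(a), length(a),
               mean(b), stats::sd(b), length(b),
               tails = tails, variance = variance)
}

#' Two-sample t-test from summary statistics
#'
#' Identical to [twoSampleT()] on raw vectors with matching summaries; used
#' when only the published mean, SD and n are available (e.g. normalized
#' Western band intensities reported as mean +/- SD).
#'
#' @param meanA,sdA,nA first-group mean, sample SD and size.
#' @param meanB,sdB,nB second-group mean, sample SD and size.
#' @inheritParams twoSampleT
#' @return \code{TTestResult} list: t, df, tails, variance, p.
#' @examples
#' tFromSummary(0.90, 0.20, 3, 0.61, 0.20, 3, tails = "one")$p  # ~0.07
#' @export
tFromSummary <- function(meanA, sdA, nA, meanB, sdB, nB,
                         tails = c("two", "one"),
                         variance = c("pooled", "welch")) {
  tails <- match.arg(tails); variance <- match.arg(variance)
  if (nA < 2 || nB < 2) stop("n must be >= 2 in each group")
  if (sdA < 0 || sdB < 0) stop("sd must be >= 0")
  if (variance == "pooled") {
    td <- .pooledT(meanA, sdA, nA, meanB, sdB, nB)
  } else {
    va <- sdA^2 / nA; vb <- sdB^2 / nB
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (nA - 1) + vb^2 / (nB - 1))
    diff <- meanA - meanB
    td <- if (se == 0) list(t = if (diff == 0) 0 else Inf * sign(diff),
                            df = nA + nB - 2)
          else list(t = diff / se, df = df)
  }
  structure(list(t = td$t, df = td$df, tails = tails, variance = variance,
                 p = .tailP(td$t, td$df, tails)),
            class = "TTestResult")
}

#' Normalize target band intensities by a loading control
#'
#' @param target target-protein band intensities, paired by lane.
#' @param control loading-control band intensities (> 0).
#' @return per-lane ratios target / control.
#' @export
normalizeBands <- function(target, control) {
  if (length(target) != length(control))
    stop("target and control must be paired by lane")
  bad <- which(control <= 0)
  if (length(bad))
    stop(sprintf("non-positive control intensity at lane %d", bad[1]))
  target / control
}
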