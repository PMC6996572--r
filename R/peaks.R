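# Peak detection and area-under-the-curve quantification on the slice axis.
# Integration uses the trapezoid rule on the integer slice grid (unit
# spacing, x = slice number 1..n) without resampling to the mass axis.

profileVector <- function(profile) {
  if (is(profile, "MigrationProfile")) profile@values else as.numeric(profile)
}

#' Total area under a migration profile
#'
#' Trapezoidal integral of the trace over the slice index `1..n`.
#' @param profile a [MigrationProfile] or numeric vector (length >= 2).
#' @return scalar area (slice x intensity units).
#' @examples
#' totalAuc(c(0, 1, 0))   # 1
#' totalAuc(rep(1, 64))   # 63
#' @export
totalAuc <- function(profile) {
  v <- profileVector(profile)
  n <- length(v)
  if (n < 2L)
    cplxError("profile must have length >= 2", "cplx_validation_error")
  sum((v[-1] + v[-n]) / 2)
}

# Trapezoid integral of the piecewise-linear trace between fractional slice
# positions lo..hi.
trapzSegment <- function(v, lo, hi) {
  n <- length(v)
  lo <- max(1, min(lo, n)); hi <- max(1, min(hi, n))
  if (hi <= lo) return(0)
  at <- function(x) {
    i <- floor(x); f <- x - i
    if (i >= n) v[n] else v[i] * (1 - f) + v[i + 1] * f
  }
  knots <- unique(c(lo, seq(ceiling(lo), floor(hi)), hi))
  heights <- vapply(knots, at, numeric(1))
  sum(diff(knots) * (heights[-1] + heights[-length(heights)]) / 2)
}

movingAverage3 <- function(v) {
  n <- length(v)
  s <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1, i - 1):min(n, i + 1)
    s[i] <- mean(v[j])
  }
  s
}

#' Detect peaks in a migration profile
#'
#' Finds local maxima of the 3-point moving-average-smoothed trace whose
#' height is at least `minProminence` times the profile maximum, keeps
#' centers at least `minSeparation` slices apart (taller peaks win), refines
#' each center by parabolic interpolation on the raw trace, and sets the
#' integration bounds at the flanking minima of the smoothed trace (or the
#' window edges). If a calibration curve is supplied the apparent native
#' mass of each center is reported.
#'
#' @param profile a [MigrationProfile] or numeric vector.
#' @param minProminence minimum peak height as a fraction of the profile
#'   maximum (default 0.1).
#' @param minSeparation minimum distance between peak centers in slices
#'   (default 2).
#' @param curve optional [CalibrationCurve] for apparent masses.
#' @param subject,condition metadata copied into the output.
#' @return data.frame with one row per peak: `subject`, `condition`,
#'   `center_slice`, `apparent_mass_kda`, `left_slice`, `right_slice`,
#'   `auc`, `prominence`; zero rows for an all-zero or flat profile.
#' @export
detectPeaks <- function(profile, minProminence = 0.1, minSeparation = 2,
                        curve = NULL, subject = NA_character_,
                        condition = NA_character_) {
  if (is(profile, "MigrationProfile")) {
    if (is.na(subject)) subject <- profile@subject
    if (is.na(condition)) condition <- profile@condition
  }
  v <- profileVector(profile)
  n <- length(v)
  empty <- data.frame(subject = character(0), condition = character(0),
                      center_slice = numeric(0),
                      apparent_mass_kda = numeric(0),
                      left_slice = integer(0), right_slice = integer(0),
                      auc = numeric(0), prominence = numeric(0))
  if (n < 3L || max(v) <= 0) return(empty)
  s <- movingAverage3(v)
  cand <- which(s[2:(n - 1)] > s[1:(n - 2)] & s[2:(n - 1)] >= s[3:n]) + 1L
  cand <- cand[s[cand] >= minProminence * max(s)]
  if (!length(cand)) return(empty)
  cand <- cand[order(-s[cand], cand)]
  kept <- integer(0)
  for (i in cand)
    if (!length(kept) || all(abs(kept - i) >= minSeparation))
      kept <- c(kept, i)
  kept <- sort(kept)
  rows <- lapply(kept, function(i) {
    # parabolic refinement on the raw trace
    center <- i
    if (i > 1L && i < n) {
      denom <- v[i - 1] - 2 * v[i] + v[i + 1]
      if (denom < 0) {
        delta <- 0.5 * (v[i - 1] - v[i + 1]) / denom
        center <- i + max(-0.5, min(0.5, delta))
      }
    }
    left <- i
    while (left > 1L && s[left - 1] < s[left]) left <- left - 1L
    right <- i
    while (right < n && s[right + 1] < s[right]) right <- right + 1L
    data.frame(subject = subject, condition = condition,
               center_slice = center,
               apparent_mass_kda = if (is.null(curve)) NA_real_
                                   else massAt(curve, center),
               left_slice = left, right_slice = right,
               auc = trapzSegment(v, left, right),
               prominence = v[i] / max(v))
  })
  do.call(rbind, rows)
}

#' Area of a profile inside a mass window
#'
#' Trapezoidal integral of the trace restricted to the slice interval
#' covering `centerKda * (1 +/- toleranceFraction)` (see
#' [massWindowToSlices()]), together with the fraction it represents of the
#' total area. This is the windowed quantification used to express, e.g.,
#' the amount of a module found at the mass of the fully assembled complex.
#'
#' @param profile a [MigrationProfile] or numeric vector.
#' @param curve a [CalibrationCurve].
#' @param centerKda window center in kDa.
#' @param toleranceFraction relative window half-width (default 0.10).
#' @return list with `auc`, `fraction_of_total`, and the `window` bounds.
#' @export
windowedAuc <- function(profile, curve, centerKda,
                        toleranceFraction = 0.10) {
  v <- profileVector(profile)
  w <- massWindowToSlices(curve, centerKda, toleranceFraction,
                          nSlices = length(v))
  auc <- trapzSegment(v, w[["lo"]], w[["hi"]])
  tot <- totalAuc(v)
  list(auc = auc,
       fraction_of_total = if (tot > 0) auc / tot else NA_real_,
       window = w)
}

#' Cross-condition windowed peak ratio
#'
#' Ratio (in percent) of the windowed area of profile A to the windowed
#' area of profile B, each restricted to its own mass window. Both profiles
#' must share a common scale (jointly normalized), so the percentage is a
#' relative abundance. Undefined (NA with `defined = FALSE`) when the
#' denominator area is zero.
#'
#' @param profileA,profileB [MigrationProfile]s or numeric vectors on a
#'   common scale.
#' @param windowAKda,windowBKda window centers in kDa for A and B.
#' @param curve a [CalibrationCurve].
#' @param toleranceFraction relative window half-width (default 0.10).
#' @return scalar percentage with attribute `defined`.
#' @export
crossConditionPeakRatio <- function(profileA, windowAKda, profileB,
                                    windowBKda, curve,
                                    toleranceFraction = 0.10) {
  a <- windowedAuc(profileA, curve, windowAKda, toleranceFraction)$auc
  b <- windowedAuc(profileB, curve, windowBKda, toleranceFraction)$auc
  if (b <= 0) {
    out <- NA_real_
    attr(out, "defined") <- FALSE
    return(out)
  }
  out <- 100 * a / b
  attr(out, "defined") <- TRUE
  out
}

#' Two-factor comparison of replicate AUCs
#'
#' Thin contract over standard routines: fits a two-factor linear model
#' (subject x condition) to replicate AUC values with [stats::aov()] and
#' reports the per-subject condition contrast with Sidak-adjusted p-values
#' via the emmeans package, mirroring a two-way ANOVA with Sidak's multiple
#' comparisons test. Subjects with an empty condition cell are excluded
#' with a warning.
#'
#' @param aucTable data.frame with columns `subject`, `condition`, `auc`
#'   (one row per replicate).
#' @param alpha significance level for the `significant` flag
#'   (default 0.05).
#' @return data.frame with one row per subject: `estimate` (condition
#'   difference), `p_adj` (Sidak-adjusted), `significant`.
#' @export
compareGroups <- function(aucTable, alpha = 0.05) {
  need <- c("subject", "condition", "auc")
  if (!all(need %in% colnames(aucTable)))
    cplxError("aucTable needs subject, condition, auc",
              "cplx_validation_error")
  tab <- table(aucTable$subject, aucTable$condition)
  bad <- rownames(tab)[apply(tab, 1, function(x) any(x < 2))]
  if (length(bad)) {
    warning(sprintf(
      "excluding subject(s) with fewer than 2 replicates per cell: %s",
      paste(bad, collapse = ", ")), call. = FALSE)
    aucTable <- aucTable[!(aucTable$subject %in% bad), , drop = FALSE]
  }
  if (!nrow(aucTable))
    cplxError("no subject has complete replicate cells",
              "cplx_validation_error")
  aucTable$subject <- factor(aucTable$subject)
  aucTable$condition <- factor(aucTable$condition)
  singleSubject <- nlevels(aucTable$subject) < 2L
  fit <- if (singleSubject) aov(auc ~ condition, data = aucTable)
         else aov(auc ~ subject * condition, data = aucTable)
  emm <- emmeans::emmeans(fit, if (singleSubject) ~condition
                               else ~condition | subject)
  ctr <- emmeans::contrast(emm, "revpairwise",
                           by = if (singleSubject) NULL else "subject")
  s <- summary(ctr, by = NULL, adjust = "sidak")
  out <- data.frame(
    subject = if (singleSubject) levels(aucTable$subject) else
      as.character(s$subject),
    estimate = s$estimate,
    p_adj = s$p.value)
  out$significant <- out$p_adj < alpha
  out[order(out$subject), , drop = FALSE]
}
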