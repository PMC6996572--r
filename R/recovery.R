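# Parameter-recovery harness: runs the full pipeline on a simulated
# reciprocal pair and compares what it recovers against the scenario truth.

#' Recover planted species masses from a simulated experiment
#'
#' Runs the complete analysis on one simulated reciprocal labeling pair:
#' simulates the two lanes, fits the calibration from the scenario's
#' standards, builds jointly normalized per-protein profiles, detects peaks
#' in every quantifiable profile and assigns each peak to the nearest
#' planted species (among the species containing that protein with non-zero
#' abundance in that condition). Peaks whose apparent mass is more than
#' `massTolerance` away (relative) from their nearest candidate species are
#' counted as spurious.
#'
#' @param scenario a [GroundTruthScenario].
#' @param noise a [NoiseModel].
#' @param seeds two integer seeds for the reciprocal pair.
#' @param massTolerance relative apparent-mass tolerance for matching a
#'   peak to a species (default 0.05).
#' @param minProminence,minSeparation passed to [detectPeaks()].
#' @return list with `species` (data.frame: one row per planted species x
#'   condition with non-zero abundance, its planted mass, the median
#'   recovered apparent mass over member proteins, and the member detection
#'   counts), `spuriousRate` (fraction of detected peaks not matching any
#'   candidate species), `curve` and `profiles`.
#' @export
speciesRecovery <- function(scenario, noise = NoiseModel(),
                            seeds = c(1L, 2L), massTolerance = 0.05,
                            minProminence = 0.1, minSeparation = 2) {
  sim <- simulateReciprocalPair(scenario, noise, seeds)
  curve <- fitCalibration(scenarioStandards(scenario))
  ps <- buildProfiles(sim$tables, sim$design)
  conds <- scenario@conditions
  # candidate species per protein x condition
  candidates <- function(prot, cond) {
    keep <- vapply(scenario@species, function(s)
      prot %in% names(s@composition) &&
        cond %in% names(s@abundance) && s@abundance[[cond]] > 0,
      logical(1))
    scenario@species[keep]
  }
  assigned <- list()
  nPeaks <- 0L
  nSpurious <- 0L
  for (prot in names(scenario@proteins)) {
    for (cond in conds) {
      key <- paste(prot, cond, sep = "|")
      if (!key %in% names(ps@profiles)) next
      prof <- ps@profiles[[key]]
      if (!prof@quantifiable || max(prof@values) <= 0) next
      pk <- detectPeaks(prof, minProminence = minProminence,
                        minSeparation = minSeparation, curve = curve)
      if (!nrow(pk)) next
      cands <- candidates(prot, cond)
      for (i in seq_len(nrow(pk))) {
        nPeaks <- nPeaks + 1L
        if (!length(cands)) { nSpurious <- nSpurious + 1L; next }
        dist <- vapply(cands, function(s)
          abs(log10(pk$apparent_mass_kda[i]) - log10(s@massKda)),
          numeric(1))
        best <- cands[[which.min(dist)]]
        relErr <- abs(pk$apparent_mass_kda[i] - best@massKda) / best@massKda
        if (relErr > massTolerance) { nSpurious <- nSpurious + 1L; next }
        skey <- paste(best@name, cond, sep = "|")
        assigned[[skey]] <- c(assigned[[skey]], pk$apparent_mass_kda[i])
      }
    }
  }
  rows <- list()
  for (sp in scenario@species) {
    for (cond in conds) {
      if (!(cond %in% names(sp@abundance)) || sp@abundance[[cond]] <= 0)
        next
      skey <- paste(sp@name, cond, sep = "|")
      hits <- assigned[[skey]]
      rows[[skey]] <- data.frame(
        species = sp@name, condition = cond, mass_kda = sp@massKda,
        abundance = sp@abundance[[cond]],
        n_members = length(sp@composition),
        n_detected = length(hits),
        recovered_kda = if (length(hits)) median(hits) else NA_real_)
    }
  }
  species <- do.call(rbind, rows)
  rownames(species) <- NULL
  list(species = species,
       spuriousRate = if (nPeaks) nSpurious / nPeaks else 0,
       curve = curve, profiles = ps)
}
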