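# Shared fixtures and independent oracles used across the test files.

# Independent OLS oracle: explicit normal equations, no lm().
olsOracle <- function(x, y) {
  X <- cbind(1, x)
  as.numeric(solve(t(X) %*% X, t(X) %*% y))
}

noiseOff <- function(peakSigma = 1.0)
  NoiseModel(sigmaLn = 0, detectionLimit = 0, peakSigma = peakSigma)

# Minimal one-species scenario: a single protein reported by one peptide.
oneSpeciesScenario <- function(massKda = 1000,
                               abundance = c(control = 1e6, mutant = 1e6),
                               calibration = c(a = 3.7, b = -0.036)) {
  GroundTruthScenario(
    species = list(SpeciesDefinition("S", c(P1 = 1), massKda, abundance)),
    proteins = list(ProteinGenerativeModel("P1", nPeptides = 1L,
                                           response = 1)),
    calibration = calibration)
}

# One species per protein at well-separated masses, with planted
# mutant/control log2 ratios; every protein has >= 3 peptides.
ratioScenario <- function(ratios = c(RP1 = -3, RP2 = -1, RP3 = 0,
                                     RP4 = 1)) {
  masses <- c(1600, 800, 400, 120, 60)[seq_along(ratios)]
  base <- 4e5
  species <- mapply(function(p, r, m)
    SpeciesDefinition(paste0("sp_", p), setNames(1, p), m,
                      c(control = base, mutant = base * 2^r)),
    names(ratios), ratios, masses, SIMPLIFY = FALSE)
  proteins <- lapply(names(ratios), function(p)
    ProteinGenerativeModel(p, nPeptides = 4L))
  GroundTruthScenario(species = species, proteins = proteins,
                      calibration = c(a = 3.7, b = -0.036))
}

# Tiny in-memory peptide table builder.
ptable <- function(..., nSlices = 64L) {
  PeptideSliceTable(data.frame(...), nSlices = nSlices)
}

reciprocalDesign <- function(conditions = c("control", "mutant")) {
  LabelingDesign(data.frame(
    experiment_id = c("exp1", "exp2"),
    heavy_condition = c(conditions[2], conditions[1]),
    light_condition = c(conditions[1], conditions[2])))
}

# Normalized ground-truth condition profiles (same joint normalization as
# buildProfiles applies).
expectedNormalizedProfiles <- function(scenario, proteinId,
                                       noise = NoiseModel()) {
  gt <- groundTruthProfile(scenario, proteinId, noise)
  m <- max(gt)
  if (m > 0) gt <- gt / m
  gt
}
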