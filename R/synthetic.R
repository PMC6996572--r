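# Ground-truth generator: simulates two-condition, reciprocally labelled
# SILAC complexome lanes (and co-IP experiments) from an explicit species
# model, so every downstream stage can be validated by parameter recovery.
#
# All randomness goes through R's Mersenne-Twister generator with inversion
# normals (set explicitly, so fixtures are stable across R versions that
# keep these generators).

setScenarioSeed <- function(seed) {
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
}

# Discretized Gaussian band shape: mass fraction of a species landing in
# slice k. Sums to ~1 when the center is well inside the lane.
phiSlice <- function(slices, mu, sigma) {
  pnorm(slices + 0.5, mean = mu, sd = sigma) -
    pnorm(slices - 0.5, mean = mu, sd = sigma)
}

speciesCenter <- function(scenario, sp) {
  a <- scenario@calibration[["a"]]
  b <- scenario@calibration[["b"]]
  mu <- (log10(sp@massKda) - a) / b
  if (mu < 1 || mu > scenario@nSlices) {
    warning(sprintf(
      "species '%s' (%.4g kDa) migrates outside the lane; clipping",
      sp@name, sp@massKda), call. = FALSE)
    mu <- min(max(mu, 1), scenario@nSlices)
  }
  mu
}

# Noise-free expected intensities of one condition: long-form
# (protein_id, peptide_id, slice, intensity), duplicate keys summed over
# species.
expectedCondition <- function(scenario, condition, noise) {
  rows <- list()
  for (sp in scenario@species) {
    ab <- if (condition %in% names(sp@abundance))
      sp@abundance[[condition]] else 0
    if (ab <= 0) next
    mu <- speciesCenter(scenario, sp)
    k <- seq_len(scenario@nSlices)
    phi <- phiSlice(k, mu, noise@peakSigma)
    keep <- phi > 1e-12
    if (!any(keep)) next
    k <- k[keep]; phi <- phi[keep]
    for (prot in names(sp@composition)) {
      pm <- scenario@proteins[[prot]]
      copies <- sp@composition[[prot]]
      base <- ab * copies * pm@response            # one value per peptide
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = prot,
        peptide_id = rep(paste0(prot, "_pep", seq_len(pm@nPeptides)),
                         times = length(k)),
        slice = rep(k, each = pm@nPeptides),
        intensity = as.vector(outer(base, phi)))
    }
  }
  if (!length(rows))
    return(data.frame(protein_id = character(0), peptide_id = character(0),
                      slice = integer(0), intensity = numeric(0)))
  df <- do.call(rbind, rows)
  agg <- stats::aggregate(intensity ~ protein_id + peptide_id + slice,
                          data = df, FUN = sum)
  agg[order(agg$protein_id, agg$peptide_id, agg$slice), , drop = FALSE]
}

#' Noise-free expected condition profile of a protein
#'
#' The generative expectation of the per-slice summed-peptide intensity of
#' one protein in each condition (before noise and censoring): the quantity
#' the profile builder should recover. Used as the ground truth in
#' parameter-recovery tests.
#'
#' @param scenario a [GroundTruthScenario].
#' @param proteinId protein of interest.
#' @param noise a [NoiseModel] (only the band spread is used).
#' @return numeric matrix `nSlices x 2` with the condition names as columns.
#' @export
groundTruthProfile <- function(scenario, proteinId, noise = NoiseModel()) {
  out <- matrix(0, nrow = scenario@nSlices, ncol = 2,
                dimnames = list(NULL, scenario@conditions))
  for (cond in scenario@conditions) {
    df <- expectedCondition(scenario, cond, noise)
    df <- df[df$protein_id == proteinId, , drop = FALSE]
    if (nrow(df)) {
      v <- tapply(df$intensity, df$slice, sum)
      out[as.integer(names(v)), cond] <- as.numeric(v)
    }
  }
  out
}

#' Planted condition log2 ratio of a protein
#'
#' The generative mutant-to-control (second vs first condition) log2
#' abundance ratio of a protein, defined where the protein's expected signal
#' is non-zero in both conditions.
#' @inheritParams groundTruthProfile
#' @return scalar log2 ratio (NA when undefined).
#' @export
plantedLog2Ratio <- function(scenario, proteinId, noise = NoiseModel()) {
  gt <- groundTruthProfile(scenario, proteinId, noise)
  tot <- colSums(gt)
  if (any(tot == 0)) return(NA_real_)
  log2(tot[[scenario@conditions[2]]] / tot[[scenario@conditions[1]]])
}

#' Simulate one complexome lane (one experiment, both channels)
#'
#' For every species, member protein, peptide and slice the expected
#' intensity is `abundance(condition of the channel) x copies x response x
#' phi(slice; center, sigma)` where `phi` is a discretized Gaussian band at
#' the slice position implied by the species mass under the generating
#' migration law. Observed intensities are the expectation times lognormal
#' noise `exp(N(0, sigmaLn^2))`, censored below the detection limit
#' (censored cells are dropped: zero means unobserved). Deterministic given
#' `seed`.
#'
#' @param scenario a [GroundTruthScenario].
#' @param design a [LabelingDesign] containing `experimentId`.
#' @param experimentId which experiment of the design to simulate.
#' @param noise a [NoiseModel].
#' @param seed integer seed for this lane.
#' @return A [PeptideSliceTable] with both channels of the lane.
#' @export
simulateLane <- function(scenario, design, experimentId,
                         noise = NoiseModel(), seed = 1L) {
  d <- designTable(design)
  row <- d[d$experiment_id == experimentId, , drop = FALSE]
  if (nrow(row) != 1L)
    cplxError(sprintf("experiment '%s' not in design", experimentId),
              "cplx_lookup_error")
  chans <- c(H = row$heavy_condition, L = row$light_condition)
  parts <- lapply(names(chans), function(ch) {
    df <- expectedCondition(scenario, chans[[ch]], noise)
    if (!nrow(df)) return(NULL)
    cbind(experiment_id = experimentId, channel = ch, df)
  })
  df <- do.call(rbind, parts)
  if (is.null(df) || !nrow(df))
    return(PeptideSliceTable(
      data.frame(experiment_id = character(0), channel = character(0),
                 protein_id = character(0), peptide_id = character(0),
                 slice = integer(0), intensity = numeric(0)),
      nSlices = scenario@nSlices))
  # canonical order before drawing noise, so the draw sequence is stable
  df <- df[order(df$channel, df$protein_id, df$peptide_id, df$slice), ,
           drop = FALSE]
  setScenarioSeed(seed)
  if (noise@sigmaLn > 0)
    df$intensity <- df$intensity * exp(rnorm(nrow(df), 0, noise@sigmaLn))
  obs <- vapply(scenario@proteins, function(p) min(p@observability),
                numeric(1))
  if (any(obs < 1)) {
    pmod <- scenario@proteins
    pepIdx <- as.integer(sub(".*_pep", "", df$peptide_id))
    pObs <- mapply(function(prot, j) pmod[[prot]]@observability[j],
                   df$protein_id, pepIdx)
    df <- df[stats::runif(nrow(df)) < pObs, , drop = FALSE]
  }
  df <- df[df$intensity >= noise@detectionLimit, , drop = FALSE]
  PeptideSliceTable(df, nSlices = scenario@nSlices)
}

#' Simulate a reciprocal labeling pair of experiments
#'
#' Experiment `exp1` labels the second condition (the "mutant") heavy;
#' `exp2` swaps the assignment. Noise is drawn independently per experiment
#' from the two seeds.
#'
#' @inheritParams simulateLane
#' @param seeds integer vector of two seeds, one per experiment.
#' @return list with `tables` (named list of two [PeptideSliceTable]s) and
#'   `design` (a reciprocal [LabelingDesign]).
#' @export
simulateReciprocalPair <- function(scenario, noise = NoiseModel(),
                                   seeds = c(1L, 2L)) {
  stopifnot(length(seeds) == 2L)
  conds <- scenario@conditions
  design <- LabelingDesign(data.frame(
    experiment_id = c("exp1", "exp2"),
    heavy_condition = c(conds[2], conds[1]),
    light_condition = c(conds[1], conds[2])))
  tables <- list(
    exp1 = simulateLane(scenario, design, "exp1", noise, seeds[1]),
    exp2 = simulateLane(scenario, design, "exp2", noise, seeds[2]))
  list(tables = tables, design = design)
}

#' Reference two-condition scenario
#'
#' A ready-made ground-truth model of a control cell line versus a mutant
#' devoid of complex III, patterned on the respiratory-chain species whose
#' apparent masses the underlying experimental system exhibits. In the
#' control, complex I N-module subunits migrate exclusively within
#' respirasome supercomplexes (2,110 kDa) under digitonin, or in the free
#' holo-complex (1,002 kDa) under DDM; the mutant lacks all complex-III-
#' containing species and instead accumulates a pre-complex-I intermediate
#' (991 kDa digitonin / 812 kDa DDM, stabilized by the assembly factor
#' NDUFAF2), a small residual amount (6.1% of the control) of N-module
#' signal at the free holo-complex mass (1,172 kDa digitonin / 1,002 kDa
#' DDM), low-mass NDUFV1/NDUFV2 species (37 kDa), and CYC1/UQCR10-containing
#' intermediates. Complex II (156 kDa) is halved in the mutant; ATP synthase
#' (700 kDa) and the internal-control proteins (citrate synthase, TOM20,
#' TOM22) are planted at equal abundance in both conditions.
#'
#' The generating migration law is `log10(kDa) = 3.7 - 0.036 * slice` over
#' 64 slices, placing all planted masses inside the lane.
#'
#' @param detergent `"digitonin"` (preserves supercomplexes) or `"DDM"`
#'   (individual complexes).
#' @return A [GroundTruthScenario].
#' @seealso [scenarioStandards()], [scenarioModules()] for the matching
#'   fixtures.
#' @export
defaultScenario <- function(detergent = c("digitonin", "DDM")) {
  detergent <- match.arg(detergent)
  cI_N <- c(NDUFS1 = 1, NDUFV1 = 1, NDUFV2 = 1)
  cI_QND <- c(NDUFS3 = 1, NDUFA9 = 1, NDUFB11 = 1, NDUFB8 = 1)
  cIII <- c(UQCRC1 = 2, UQCRC2 = 2, CYC1 = 2, UQCRFS1 = 2, UQCR10 = 2,
            UQCRB = 2, UQCRQ = 2, UQCRH = 2, `MT-CYB` = 2)
  cIV <- c(COX4I1 = 1, COX5A = 1, HIGD1A = 1, `MT-CO2` = 1, COX5B = 1,
           COX6C = 1, COX6B1 = 1, NDUFA4 = 1)
  cV <- c(ATP5A1 = 1, ATP5B = 1, ATP5C1 = 1, ATP5E = 1,
          ATP5F1 = 1, ATP5H = 1, ATP5J = 1, ATP5O = 1)
  ab <- function(control, mutant) c(control = control, mutant = mutant)

  species <- list(
    SpeciesDefinition("cIV_free", cIV, 220, ab(4e5, 1.2e5)),
    SpeciesDefinition("pre_cI",
                      c(cI_QND, NDUFAF2 = 1),
                      if (detergent == "digitonin") 991 else 812,
                      ab(0, 8e5)),
    SpeciesDefinition("cI_holo_residual", cI_N,
                      if (detergent == "digitonin") 1172 else 1002,
                      ab(0, 6.1e4)),
    SpeciesDefinition("N_small", c(NDUFV1 = 1, NDUFV2 = 1), 37,
                      ab(0, 3e5)),
    SpeciesDefinition("cyc1_uqcr10_high", c(CYC1 = 1, UQCR10 = 1), 750,
                      ab(0, 1.5e5)),
    SpeciesDefinition("cyc1_uqcr10_low", c(CYC1 = 1, UQCR10 = 1), 150,
                      ab(0, 2e5)),
    SpeciesDefinition("cII", c(SDHA = 1, SDHB = 1, SDHC = 1), 156,
                      ab(5e5, 2.5e5)),
    SpeciesDefinition("cV", cV, 700, ab(8e5, 8e5)),
    SpeciesDefinition("CS_dimer", c(CS = 2), 90, ab(5e5, 5e5)),
    SpeciesDefinition("TOM_core", c(TOM20 = 1, TOM22 = 1), 450,
                      ab(4e5, 4e5)),
    SpeciesDefinition("cIII2_holo", cIII, 485, ab(6e5, 0)))
  if (detergent == "digitonin") {
    species <- c(species, list(
      SpeciesDefinition("respirasome", c(cI_N, cI_QND, cIII, cIV), 2110,
                        ab(1e6, 0), detergentScope = "digitonin")))
  } else {
    species <- c(species, list(
      SpeciesDefinition("cI_holo", c(cI_N, cI_QND), 1002, ab(1e6, 0),
                        detergentScope = "DDM")))
  }
  prot <- sort(unique(unlist(lapply(species,
                                    function(s) names(s@composition)))))
  nPep <- rep_len(c(4L, 5L, 3L, 6L), length(prot))
  proteins <- mapply(function(p, n) ProteinGenerativeModel(p, n),
                     prot, nPep, SIMPLIFY = FALSE)
  GroundTruthScenario(species = species, proteins = proteins,
                      calibration = c(a = 3.7, b = -0.036),
                      conditions = c("control", "mutant"),
                      nSlices = 64L, detergent = detergent)
}

#' Fixtures matching a scenario
#'
#' `scenarioStandards()` builds a [StandardsTable] from well-characterized
#' planted complexes by inverting the generating migration law (so a
#' noise-free fit recovers the generating coefficients exactly);
#' `scenarioModules()` returns the [ModuleAnnotation] of the assembly
#' modules planted by [defaultScenario()].
#'
#' @param scenario a [GroundTruthScenario].
#' @return A [StandardsTable] or [ModuleAnnotation].
#' @export
scenarioStandards <- function(scenario) {
  a <- scenario@calibration[["a"]]; b <- scenario@calibration[["b"]]
  pick <- c("respirasome", "cI_holo", "cV", "cIII2_holo", "TOM_core",
            "cIV_free", "cII", "CS_dimer")
  sp <- scenario@species[names(scenario@species) %in% pick]
  StandardsTable(data.frame(
    name = vapply(sp, function(s) s@name, character(1)),
    slice_center = vapply(sp, function(s) (log10(s@massKda) - a) / b,
                          numeric(1)),
    mass_kda = vapply(sp, function(s) s@massKda, numeric(1))))
}

#' @rdname scenarioStandards
#' @export
scenarioModules <- function(scenario) {
  ModuleAnnotation(data.frame(
    module_name = c(rep("N", 3), "Q", "ND2", "ND4", "ND5",
                    rep("cIV_early", 3), rep("cIV_MTCO2", 3), "cIV_MTCO3",
                    rep("cV_F1", 4), rep("cV_stalk", 4)),
    protein_id = c("NDUFS1", "NDUFV1", "NDUFV2", "NDUFS3", "NDUFA9",
                   "NDUFB11", "NDUFB8",
                   "COX4I1", "COX5A", "HIGD1A",
                   "MT-CO2", "COX5B", "COX6C", "COX6B1",
                   "ATP5A1", "ATP5B", "ATP5C1", "ATP5E",
                   "ATP5F1", "ATP5H", "ATP5J", "ATP5O")))
}

#' Simulate a reciprocal SILAC immunopurification pair
#'
#' Protein-level model of an anti-bait co-IP read out by SILAC: each
#' protein's observed log2 heavy/light ratio is its planted oriented effect
#' (mutant vs control) plus independent Gaussian noise, with the orientation
#' flipped between the two reciprocal experiments. Background proteins have
#' a planted effect of zero.
#'
#' @param baitComplex character vector of bait-complex protein ids (planted
#'   effect taken from `effects`, default 0).
#' @param background number of additional null background proteins.
#' @param effects named numeric vector of planted per-protein log2 effects.
#' @param sigma standard deviation of the per-experiment log2 ratio noise.
#' @param seeds two integer seeds (one per experiment).
#' @param conditions the two condition names (reference first).
#' @return list with `tables` (named list of two data.frames with columns
#'   experiment_id, protein_id, channel, intensity) and `design`
#'   (a reciprocal [LabelingDesign]).
#' @export
simulateIP <- function(baitComplex = character(0), background = 200L,
                       effects = numeric(0), sigma = 0.3,
                       seeds = c(1L, 2L),
                       conditions = c("control", "mutant")) {
  if (any(!is.finite(effects)))
    cplxError("planted effects must be finite", "cplx_validation_error")
  prots <- unique(c(baitComplex, names(effects),
                    if (background > 0)
                      sprintf("bg%03d", seq_len(background))))
  eff <- setNames(numeric(length(prots)), prots)
  eff[names(effects)] <- effects
  design <- LabelingDesign(data.frame(
    experiment_id = c("exp1", "exp2"),
    heavy_condition = c(conditions[2], conditions[1]),
    light_condition = c(conditions[1], conditions[2])))
  base <- 1e6
  mkTable <- function(experimentId, orientedSign, seed) {
    setScenarioSeed(seed)
    obs <- orientedSign * (eff + rnorm(length(eff), 0, sigma))
    df <- data.frame(
      experiment_id = experimentId,
      protein_id = rep(prots, each = 2L),
      channel = rep(c("H", "L"), times = length(prots)),
      intensity = as.vector(rbind(base * 2^obs, rep(base, length(prots)))))
    df[order(df$protein_id, df$channel), , drop = FALSE]
  }
  # exp1: mutant heavy -> H/L ratio is the oriented effect;
  # exp2: mutant light -> H/L ratio is the negated oriented effect.
  tables <- list(exp1 = mkTable("exp1", 1, seeds[1]),
                 exp2 = mkTable("exp2", -1, seeds[2]))
  list(tables = tables, design = design)
}
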