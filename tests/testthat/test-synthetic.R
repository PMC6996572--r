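test_that("noise-free lane reproduces the discretized Gaussian exactly", {
  sc <- oneSpeciesScenario(massKda = 1000)
  des <- reciprocalDesign()
  tab <- simulateLane(sc, des, "exp1", noiseOff(), seed = 1L)
  v <- buildProteinProfile(tab, "P1", "exp1", "H")
  mu <- (log10(1000) - 3.7) / -0.036
  k <- seq_len(64)
  phi <- pnorm(k + 0.5, mu, 1) - pnorm(k - 0.5, mu, 1)
  expected <- 1e6 * phi
  expected[expected < 1e-12 * 1e6] <- 0   # generator drops negligible mass
  expect_equal(as.numeric(v), expected, tolerance = 1e-9)
  expect_equal(which.max(v), round(mu))
})

test_that("species masses map to the calibrated peak position", {
  # a holo-complex-I-like species at 1,172 kDa must peak at the slice whose
  # calibrated mass is 1,172 kDa under the generating law
  sc <- oneSpeciesScenario(massKda = 1172)
  tab <- simulateLane(sc, reciprocalDesign(), "exp1", noiseOff(), 1L)
  v <- buildProteinProfile(tab, "P1", "exp1", "H")
  mu <- (log10(1172) - 3.7) / -0.036
  expect_equal(which.max(v), round(mu))
  curve <- CalibrationCurve(3.7, -0.036)
  pk <- detectPeaks(as.numeric(v) / max(v), curve = curve)
  expect_equal(nrow(pk), 1L)
  expect_lt(abs(pk$apparent_mass_kda - 1172) / 1172, 0.05)
})

test_that("simulation is deterministic given the seed", {
  sc <- defaultScenario("digitonin")
  des <- reciprocalDesign()
  t1 <- simulateLane(sc, des, "exp1", NoiseModel(), seed = 7L)
  t2 <- simulateLane(sc, des, "exp1", NoiseModel(), seed = 7L)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writePeptideTable(t1, p1)
  writePeptideTable(t2, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  t3 <- simulateLane(sc, des, "exp1", NoiseModel(), seed = 8L)
  expect_false(identical(peptideData(t1), peptideData(t3)))
})

test_that("a reciprocal pair swaps channel contents when noise is off", {
  sc <- ratioScenario(c(RP1 = -2, RP2 = 0.5))
  sim <- simulateReciprocalPair(sc, noiseOff(), seeds = c(1L, 2L))
  expect_true(isReciprocal(sim$design))
  d1 <- peptideData(sim$tables$exp1)
  d2 <- peptideData(sim$tables$exp2)
  # exp2 equals exp1 with H and L exchanged
  d2sw <- d2
  d2sw$channel <- ifelse(d2$channel == "H", "L", "H")
  d2sw$experiment_id <- "exp1"
  o <- function(d) {
    d <- d[order(d$channel, d$protein_id, d$peptide_id, d$slice), ]
    rownames(d) <- NULL
    d
  }
  expect_equal(o(d2sw), o(d1), tolerance = 1e-12)
})

test_that("planted condition ratios survive orientation in both experiments", {
  sc <- ratioScenario(c(RP1 = -2))   # mutant = 0.25 x control
  sim <- simulateReciprocalPair(sc, noiseOff(), seeds = c(1L, 2L))
  r1 <- sharedPeptideRatio(sim$tables$exp1, sim$design, "RP1", "exp1")
  r2 <- sharedPeptideRatio(sim$tables$exp2, sim$design, "RP1", "exp2")
  expect_equal(as.numeric(r1), -2, tolerance = 1e-9)
  expect_equal(as.numeric(r2), -2, tolerance = 1e-9)
})

test_that("the discretized band shape integrates to one", {
  # a Gaussian tail beyond z sigma holds ~Phi(-z) mass, so 1e-6 accuracy
  # needs the center >= 5 sigma inside the lane (Phi(-5) ~ 3e-7)
  for (sigma in c(0.5, 1, 2)) {
    for (mu in seq(0.5 + 5 * sigma, 64.5 - 5 * sigma, length.out = 7)) {
      k <- seq_len(64)
      phi <- pnorm(k + 0.5, mu, sigma) - pnorm(k - 0.5, mu, sigma)
      expect_lt(abs(sum(phi) - 1), 1e-6)
    }
  }
})

test_that("expected channel sums scale linearly with species abundance", {
  sc1 <- oneSpeciesScenario(abundance = c(control = 2e5, mutant = 1e5))
  sc2 <- oneSpeciesScenario(abundance = c(control = 6e5, mutant = 3e5))
  des <- reciprocalDesign()
  s1 <- peptideData(simulateLane(sc1, des, "exp1", noiseOff(), 1L))
  s2 <- peptideData(simulateLane(sc2, des, "exp1", noiseOff(), 1L))
  for (ch in c("H", "L"))
    expect_equal(sum(s2$intensity[s2$channel == ch]),
                 3 * sum(s1$intensity[s1$channel == ch]),
                 tolerance = 1e-9)
})

test_that("label swap leaves oriented condition profiles invariant", {
  sc <- ratioScenario(c(RP1 = -1, RP2 = 1))
  sim <- simulateReciprocalPair(sc, noiseOff(), seeds = c(1L, 2L))
  o1 <- orientExperiment(sim$tables$exp1, sim$design, "exp1")
  o2 <- orientExperiment(sim$tables$exp2, sim$design, "exp2")
  for (p in names(o1))
    expect_equal(o1[[p]], o2[[p]], tolerance = 1e-9)
})

test_that("default scenarios plant the documented species structure", {
  dig <- defaultScenario("digitonin")
  spd <- speciesTable(dig)
  resp <- spd[spd$species == "respirasome", ]
  expect_equal(resp$mass_kda, 2110)
  expect_gt(resp$abundance_control, 0)
  expect_equal(resp$abundance_mutant, 0)
  expect_equal(spd$mass_kda[spd$species == "pre_cI"], 991)

  ddm <- defaultScenario("DDM")
  spdd <- speciesTable(ddm)
  expect_equal(spdd$mass_kda[spdd$species == "pre_cI"], 812)
  expect_false("respirasome" %in% spdd$species)
  expect_equal(spdd$mass_kda[spdd$species == "cI_holo"], 1002)

  # internal-control proteins: equal planted abundance in both conditions
  for (ctrl in c("CS_dimer", "TOM_core", "cV")) {
    expect_equal(spd$abundance_control[spd$species == ctrl],
                 spd$abundance_mutant[spd$species == ctrl])
  }
  # the residual holo-complex is planted at 6.1% of the control respirasome
  expect_equal(spd$abundance_mutant[spd$species == "cI_holo_residual"] /
                 resp$abundance_control, 0.061)
})

test_that("matching fixtures invert the generating migration law", {
  sc <- defaultScenario("digitonin")
  st <- scenarioStandards(sc)
  curve <- fitCalibration(st)
  expect_equal(curve@intercept, 3.7, tolerance = 1e-9)
  expect_equal(curve@slope, -0.036, tolerance = 1e-9)
  mods <- scenarioModules(sc)
  expect_setequal(moduleMembers(mods, "N"), c("NDUFS1", "NDUFV1", "NDUFV2"))
  expect_setequal(moduleMembers(mods, "cIV_MTCO2"),
                  c("MT-CO2", "COX5B", "COX6C"))
})

test_that("the IP simulator plants oriented effects", {
  # strong depletion: 32-fold lower in the mutant
  sim <- simulateIP(effects = c(UQCRC2 = -5), background = 5L,
                    sigma = 0.1, seeds = c(3L, 4L))
  pts <- orientedIpRatios(sim$tables, sim$design)
  row <- pts[pts$protein_id == "UQCRC2", ]
  expect_lt(abs(row$x + 5), 0.5)
  expect_lt(abs(row$y + 5), 0.5)
  # zero effect, zero noise -> exact (0, 0)
  sim0 <- simulateIP(effects = c(P = 0), background = 0L, sigma = 0,
                     seeds = c(1L, 2L))
  pts0 <- orientedIpRatios(sim0$tables, sim0$design)
  expect_identical(unname(c(pts0$x, pts0$y)), c(0, 0))
})

test_that("IP effects are recovered at the normal-theory accuracy", {
  eff <- setNames(rep(c(-5, -3, 0, 2), 50), sprintf("E%03d", 1:200))
  sigma <- 0.3
  sim <- simulateIP(effects = eff, background = 0L, sigma = sigma,
                    seeds = c(21L, 22L))
  pts <- orientedIpRatios(sim$tables, sim$design)
  err <- abs(pts$mean_log2 - eff[pts$protein_id])
  # mean of two experiments: sd = sigma/sqrt(2); 3-sd band covers ~99.7%
  expect_gte(mean(err <= 3 * sigma / sqrt(2)), 0.99)
  expect_lt(max(err), 4.5 * sigma / sqrt(2))
})
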