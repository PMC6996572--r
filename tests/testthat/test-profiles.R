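miniTable <- function() {
  # peptide A observed in slice 2 only; peptide B in slices 1 and 2
  ptable(experiment_id = "exp1", channel = "H", protein_id = "P",
         peptide_id = c("A", "B", "B"), slice = c(2L, 1L, 2L),
         intensity = c(2, 1, 1), nSlices = 3L)
}

test_that("peptide aggregation sums per slice or picks the top peptide", {
  tab <- miniTable()
  expect_equal(as.numeric(buildProteinProfile(tab, "P", "exp1", "H", "sum")),
               c(1, 3, 0))
  # B is observed in 2 slices vs A's 1 -> B's vector wins
  expect_equal(as.numeric(buildProteinProfile(tab, "P", "exp1", "H",
                                              "top_peptide")), c(1, 1, 0))
  v <- buildProteinProfile(tab, "ABSENT", "exp1", "H")
  expect_equal(as.numeric(v), c(0, 0, 0))
  expect_true(attr(v, "unobserved"))
})

test_that("top-peptide ties break by total intensity, then peptide id", {
  tab <- ptable(experiment_id = "e", channel = "H", protein_id = "P",
                peptide_id = c("A", "A", "B", "B"),
                slice = c(1L, 2L, 1L, 2L), intensity = c(1, 1, 2, 1),
                nSlices = 3L)
  expect_equal(as.numeric(buildProteinProfile(tab, "P", "e", "H",
                                              "top_peptide")), c(2, 1, 0))
  tie <- ptable(experiment_id = "e", channel = "H", protein_id = "P",
                peptide_id = c("A", "A", "B", "B"),
                slice = c(1L, 2L, 1L, 2L), intensity = c(1, 1, 1, 1),
                nSlices = 3L)
  # equal slice counts and totals -> lexicographically smaller id (A)
  expect_equal(as.numeric(buildProteinProfile(tie, "P", "e", "H",
                                              "top_peptide")), c(1, 1, 0))
})

test_that("orientation maps channels to conditions per the design", {
  des <- reciprocalDesign()   # exp1: mutant heavy, exp2: control heavy
  tab1 <- ptable(experiment_id = "exp1", channel = c("H", "L"),
                 protein_id = "P", peptide_id = "p", slice = 1L,
                 intensity = c(10, 20), nSlices = 2L)
  o1 <- orientExperiment(tab1, des, "exp1")
  expect_equal(unname(o1$P[1, "mutant"]), 10)
  expect_equal(unname(o1$P[1, "control"]), 20)
  tab2 <- ptable(experiment_id = "exp2", channel = c("H", "L"),
                 protein_id = "P", peptide_id = "p", slice = 1L,
                 intensity = c(10, 20), nSlices = 2L)
  o2 <- orientExperiment(tab2, des, "exp2")
  expect_equal(unname(o2$P[1, "control"]), 10)
  expect_equal(unname(o2$P[1, "mutant"]), 20)
  expect_error(orientExperiment(tab1, des, "nope"),
               class = "cplx_lookup_error")
})

test_that("joint normalization preserves ratios and flags empty pairs", {
  nj <- normalizeJoint(c(0, 4, 2), c(0, 1, 1))
  expect_equal(nj$a, c(0, 1, 0.5))
  expect_equal(nj$b, c(0, 0.25, 0.25))
  expect_false(attr(nj, "unquantifiable"))
  eq <- normalizeJoint(c(1, 2), c(1, 2))
  expect_equal(max(eq$a), 1)
  expect_equal(max(eq$b), 1)
  # any nonzero cross-ratio is unchanged
  a <- c(0.3, 2.5, 1.1); b <- c(0.7, 0.1, 3.3)
  nj2 <- normalizeJoint(a, b)
  expect_equal(nj2$a / nj2$b, a / b)
  z <- normalizeJoint(c(0, 0), c(0, 0))
  expect_true(attr(z, "unquantifiable"))
  expect_equal(z$a, c(0, 0))
})

test_that("shared-peptide ratios are exact without noise and flagged without overlap", {
  des <- reciprocalDesign()
  tab <- ptable(experiment_id = "exp1",
                channel = rep(c("H", "L"), each = 3),
                protein_id = "P", peptide_id = rep(c("a", "a", "b"), 2),
                slice = rep(c(1L, 2L, 2L), 2),
                intensity = c(1, 2, 4, 1, 2, 4), nSlices = 3L)
  expect_equal(as.numeric(sharedPeptideRatio(tab, des, "P", "exp1")), 0)
  quarter <- ptable(experiment_id = "exp1",
                    channel = rep(c("H", "L"), each = 3),
                    protein_id = "P", peptide_id = rep(c("a", "a", "b"), 2),
                    slice = rep(c(1L, 2L, 2L), 2),
                    intensity = c(0.25 * c(1, 2, 4), 1, 2, 4), nSlices = 3L)
  # mutant (heavy in exp1) at a quarter of control -> log2 = -2
  expect_equal(as.numeric(sharedPeptideRatio(quarter, des, "P", "exp1")), -2)
  disjoint <- ptable(experiment_id = "exp1", channel = c("H", "L"),
                     protein_id = "P", peptide_id = "a", slice = c(1L, 3L),
                     intensity = c(5, 5), nSlices = 3L)
  r <- sharedPeptideRatio(disjoint, des, "P", "exp1")
  expect_true(is.na(r))
  expect_false(attr(r, "defined"))
})

test_that("the median shared-cell ratio concentrates at the planted value", {
  # 30 shared cells, lognormal noise sigma = 0.2 per channel, truth -2
  set.seed(515)
  inside <- replicate(500, {
    ctrl <- 1e4 * exp(rnorm(30, 0, 0.2))
    mut <- 0.25 * 1e4 * exp(rnorm(30, 0, 0.2))
    abs(log2(median(mut / ctrl)) + 2) <= 0.15
  })
  # asymptotic sd of the median: 1.2533 * (0.2 * sqrt(2) / ln 2) / sqrt(30)
  sdMed <- sqrt(pi / 2) * 0.2 * sqrt(2) / log(2) / sqrt(30)
  predicted <- 2 * pnorm(0.15 / sdMed) - 1
  expect_lt(abs(mean(inside) - predicted), 0.05)
  expect_gte(mean(inside), 0.85)
})

test_that("reciprocal merging uses the exact two-point SEM", {
  pr <- mergeReciprocal(c(0.4, 1), c(0.6, 1), subject = "P",
                        condition = "control")
  expect_equal(profileValues(pr), c(0.5, 1))
  expect_equal(profileSem(pr), c(0.1, 0))
  expect_equal(profileN(pr), 2L)
  same <- mergeReciprocal(c(0.2, 0.8), c(0.2, 0.8))
  expect_identical(profileSem(same), c(0, 0))
  single <- mergeReciprocal(c(0.3, 0.9))
  expect_equal(profileValues(single), c(0.3, 0.9))
  expect_identical(profileSem(single), c(0, 0))
  expect_equal(profileN(single), 1L)
  expect_error(mergeReciprocal(c(1, 2), c(1, 2, 3)),
               class = "cplx_validation_error")
})

test_that("built profiles are jointly normalized with reciprocal SEM", {
  sc <- ratioScenario(c(RP1 = -1, RP2 = 0))
  sim <- simulateReciprocalPair(sc, NoiseModel(), seeds = c(31L, 32L))
  ps <- buildProfiles(sim$tables, sim$design)
  for (p in c("RP1", "RP2")) {
    ctrl <- getProfile(ps, p, "control")
    mut <- getProfile(ps, p, "mutant")
    expect_equal(max(c(profileValues(ctrl), profileValues(mut))), 1,
                 tolerance = 1e-9)
    expect_equal(profileN(ctrl), 2L)
    expect_true(all(profileSem(ctrl) >= 0))
  }
})

test_that("module averaging equals the brute-force member mean", {
  v1 <- c(0, 1, 0, 0); v2 <- c(1, 0, 0, 0)
  ps <- ProfileSet(list(
    MigrationProfile("P1", "control", v1),
    MigrationProfile("P2", "control", v2)), nSlices = 4L)
  ann <- ModuleAnnotation(data.frame(module_name = "M",
                                     protein_id = c("P1", "P2", "P3")))
  expect_message(mp <- moduleProfile(ps, ann, "M", renormalize = FALSE),
                 "P3")
  expect_equal(profileValues(getProfile(mp, "M", "control")),
               (v1 + v2) / 2, tolerance = 1e-12)
  single <- moduleProfile(
    ProfileSet(list(MigrationProfile("P1", "control", v1)), nSlices = 4L),
    ModuleAnnotation(data.frame(module_name = "M", protein_id = "P1")),
    "M", renormalize = FALSE)
  expect_equal(profileValues(getProfile(single, "M", "control")), v1)
  empty <- ProfileSet(list(MigrationProfile("X", "control", v1)),
                      nSlices = 4L)
  expect_error(suppressMessages(moduleProfile(empty, ann, "M")),
               class = "cplx_empty_module_error")
})

test_that("module means match an independent averaging oracle on real lanes", {
  sc <- defaultScenario("digitonin")
  sim <- simulateReciprocalPair(sc, NoiseModel(), seeds = c(41L, 42L))
  ps <- buildProfiles(sim$tables, sim$design)
  mods <- scenarioModules(sc)
  mp <- suppressMessages(moduleProfile(ps, mods, "cV_F1",
                                       renormalize = FALSE))
  members <- moduleMembers(mods, "cV_F1")
  for (cc in c("control", "mutant")) {
    oracle <- rowMeans(vapply(members, function(p)
      profileValues(getProfile(ps, p, cc)), numeric(64)))
    expect_equal(profileValues(getProfile(mp, "cV_F1", cc)), oracle,
                 tolerance = 1e-12)
  }
})

test_that("heatmap rows are scaled to unit maximum and zeros retained", {
  tab <- ptable(experiment_id = "e", channel = "H",
                protein_id = c("P", "P", "Q"),
                peptide_id = c("a", "a", "q"), slice = c(1L, 2L, 3L),
                intensity = c(8, 4, 2), nSlices = 4L)
  m <- heatmapMatrix(tab, c("P", "Q", "Z"), "e", "H")
  expect_equal(unname(m["P", ]), c(1, 0.5, 0, 0))
  expect_equal(max(m["P", ]), 1.0)
  expect_equal(unname(m["Z", ]), rep(0, 4))
  expect_true(all(m >= 0 & m <= 1))
})
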