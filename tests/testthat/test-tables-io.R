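test_that("a well-formed peptide table round-trips through disk unchanged", {
  tab <- ptable(
    experiment_id = "exp1",
    channel = rep(c("H", "L"), each = 3),
    protein_id = "CS",
    peptide_id = rep(c("CS_pep1", "CS_pep2", "CS_pep3"), 2),
    slice = c(40L, 41L, 42L, 40L, 41L, 42L),
    intensity = c(125000, 3300.5, 17, 99000, 2800.25, 21))
  expect_equal(nrow(peptideData(tab)), 6L)
  path <- withr::local_tempfile(fileext = ".tsv")
  writePeptideTable(tab, path)
  back <- readPeptideTable(path)
  expect_equal(peptideData(back), peptideData(tab))
  expect_equal(nSlices(back), 64L)
})

test_that("peptide table validation names the offending row", {
  mk <- function(slice, channel = "H", intensity = 10) {
    path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
    df <- data.frame(experiment_id = "e", channel = channel,
                     protein_id = "P", peptide_id = "p",
                     slice = slice, intensity = intensity)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  expect_error(readPeptideTable(mk(65L)), "row 1",
               class = "cplx_validation_error")
  expect_error(readPeptideTable(mk(5L, channel = "X")), "unknown channel",
               class = "cplx_validation_error")
  expect_error(readPeptideTable(mk(5L, intensity = -1)),
               "negative intensity", class = "cplx_validation_error")
  # missing column
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("experiment_id\tchannel\tprotein_id\tslice\tintensity",
               "e\tH\tP\t5\t10"), path)
  expect_error(readPeptideTable(path), "peptide_id",
               class = "cplx_validation_error")
})

test_that("duplicate keys are an error, never collapsed", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(experiment_id = "e", channel = "H", protein_id = "P",
                   peptide_id = "p", slice = c(5L, 5L),
                   intensity = c(10, 20))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readPeptideTable(path), "row 2",
               class = "cplx_duplicate_key_error")
})

test_that("standards reader enforces the fit minimum and tolerates jitter", {
  mk <- function(df) {
    path <- withr::local_tempfile(fileext = ".tsv",
                                  .local_envir = parent.frame())
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  two <- data.frame(name = c("a", "b"), slice_center = c(10, 20),
                    mass_kda = c(1000, 100))
  expect_error(readStandards(mk(two)), class = "cplx_underdetermined_error")
  jitter <- data.frame(name = c("a", "b", "c", "d"),
                       slice_center = c(10, 20, 21, 30),
                       mass_kda = c(1000, 180, 200, 10))
  expect_warning(st <- readStandards(mk(jitter)), "jitter")
  expect_s4_class(st, "StandardsTable")
  expect_equal(standardsData(st)$slice_center, c(10, 20, 21, 30))
})

test_that("module reader returns the annotation and enforces uniqueness", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(module_name = "N", protein_id = "NDUFS1"),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- readModules(path)
  expect_equal(nrow(annotationData(ann)), 1L)
  expect_equal(moduleMembers(ann, "N"), "NDUFS1")
  expect_error(ModuleAnnotation(data.frame(
    module_name = c("N", "Q"), protein_id = c("NDUFS1", "NDUFS1"))),
    "at most one module")
})

test_that("a non-reciprocal design is accepted with a warning flag", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(experiments = data.frame(
    experiment_id = c("exp1", "exp2"),
    heavy_condition = c("mutant", "mutant"),
    light_condition = c("control", "control"))), path, auto_unbox = TRUE)
  expect_warning(des <- readDesign(path), "not a reciprocal")
  expect_false(isReciprocal(des))
  # and the reciprocal one round-trips silently
  path2 <- withr::local_tempfile(fileext = ".json")
  writeDesign(reciprocalDesign(), path2)
  expect_silent(des2 <- readDesign(path2))
  expect_true(isReciprocal(des2))
})

test_that("writers are deterministic and schema-stable", {
  prof <- ProfileSet(list(
    MigrationProfile("P1", "control", c(0, 0.5, 1, rep(0, 61)),
                     c(0, 0.01, 0.02, rep(0, 61)), nExperiments = 2L),
    MigrationProfile("P1", "mutant", c(0, 0.25, 0.5, rep(0, 61)),
                     c(0, 0.01, 0.01, rep(0, 61)), nExperiments = 2L)))
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeProfiles(prof, p1)
  writeProfiles(prof, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  header <- strsplit(readLines(p1, n = 1), "\t")[[1]]
  expect_identical(header, c("protein_id", "condition", "slice", "mean",
                             "sem"))
  # empty peak list -> header-only TSV
  pe <- withr::local_tempfile(fileext = ".tsv")
  writePeaks(detectPeaks(numeric(64)), pe)
  expect_length(readLines(pe), 1L)
})

test_that("profiles round-trip through the TSV writer", {
  v <- numeric(64); v[10:14] <- c(0.125, 0.5, 1, 0.5, 0.125)
  prof <- ProfileSet(list(
    MigrationProfile("P1", "control", v, nExperiments = 1L),
    MigrationProfile("P1", "mutant", v / 2, nExperiments = 1L)))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeProfiles(prof, path)
  back <- readProfiles(path)
  expect_equal(profileValues(getProfile(back, "P1", "control")), v)
  expect_equal(profileValues(getProfile(back, "P1", "mutant")), v / 2)
})
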