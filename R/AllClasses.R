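# S4 classes for the core data containers. Validity methods enforce the
# invariants that the readers and simulators rely on; all user code should go
# through the accessors rather than @ slots.

PEPTIDE_COLUMNS <- c("experiment_id", "channel", "protein_id", "peptide_id",
                     "slice", "intensity")

cplxError <- function(message, class) {
  stop(structure(
    class = c(class, "cplx_error", "error", "condition"),
    list(message = message, call = NULL)
  ))
}

#' @rdname PeptideSliceTable
#' @export
setClass("PeptideSliceTable",
  representation(data = "data.frame", nSlices = "integer"),
  validity = function(object) {
    d <- object@data
    if (!identical(colnames(d), PEPTIDE_COLUMNS))
      return(sprintf("columns must be exactly {%s}",
                     paste(PEPTIDE_COLUMNS, collapse = ", ")))
    if (length(object@nSlices) != 1L || is.na(object@nSlices) ||
        object@nSlices < 1L)
      return("nSlices must be a single positive integer")
    if (nrow(d) == 0L) return(TRUE)
    if (!all(d$channel %in% c("H", "L")))
      return("channel must be 'H' or 'L'")
    if (any(d$slice < 1L | d$slice > object@nSlices))
      return("slice out of [1, nSlices] range")
    if (any(d$intensity < 0)) return("negative intensity")
    key <- paste(d$experiment_id, d$channel, d$protein_id, d$peptide_id,
                 d$slice, sep = "\r")
    if (anyDuplicated(key))
      return("duplicate (experiment, channel, protein, peptide, slice) key")
    TRUE
  }
)

#' Long-form per-slice peptide intensity table
#'
#' The sole quantitative input of the pipeline: one row per experiment,
#' SILAC channel, protein, peptide and gel slice, holding a non-negative
#' intensity in arbitrary units. A zero intensity is equivalent to an absent
#' row ("not observed"); rows with zero intensity are dropped on
#' construction and writers never emit them. The
#' (experiment, channel, protein, peptide, slice) key must be unique --
#' duplicated keys are an error, never silently collapsed.
#'
#' @param data data.frame with columns `experiment_id`, `channel` (`"H"` or
#'   `"L"`), `protein_id`, `peptide_id`, `slice` (integer in `[1, nSlices]`)
#'   and `intensity` (non-negative).
#' @param nSlices number of slices the lane was cut into (default 64; slice 1
#'   is the top of the gel, i.e. the largest native mass).
#' @return A `PeptideSliceTable` object.
#' @seealso [readPeptideTable()], [simulateLane()]
#' @examples
#' tab <- PeptideSliceTable(data.frame(
#'   experiment_id = "exp1", channel = "H", protein_id = "CS",
#'   peptide_id = "CS_pep1", slice = 40L, intensity = 1e5))
#' nSlices(tab)
#' @export
PeptideSliceTable <- function(data, nSlices = 64L) {
  data <- as.data.frame(data)[, PEPTIDE_COLUMNS]
  data$experiment_id <- as.character(data$experiment_id)
  data$channel <- as.character(data$channel)
  data$protein_id <- as.character(data$protein_id)
  data$peptide_id <- as.character(data$peptide_id)
  data$slice <- as.integer(data$slice)
  data$intensity <- as.numeric(data$intensity)
  data <- data[data$intensity > 0, , drop = FALSE]
  o <- order(data$experiment_id, data$channel, data$protein_id,
             data$peptide_id, data$slice)
  data <- data[o, , drop = FALSE]
  rownames(data) <- NULL
  new("PeptideSliceTable", data = data, nSlices = as.integer(nSlices))
}

#' @rdname LabelingDesign
#' @export
setClass("LabelingDesign",
  representation(design = "data.frame"),
  validity = function(object) {
    d <- object@design
    need <- c("experiment_id", "heavy_condition", "light_condition")
    if (!all(need %in% colnames(d)))
      return("design needs experiment_id, heavy_condition, light_condition")
    if (anyDuplicated(d$experiment_id)) return("duplicated experiment_id")
    if (any(d$heavy_condition == d$light_condition))
      return("heavy and light condition identical within an experiment")
    conds <- sort(unique(c(d$heavy_condition, d$light_condition)))
    if (length(conds) != 2L)
      return("exactly two conditions are required overall")
    TRUE
  }
)

#' SILAC labeling design
#'
#' Maps each experiment to the biological condition carried by its heavy and
#' light channel. A valid reciprocal pair consists of two experiments with
#' swapped heavy/light assignments; [isReciprocal()] reports whether the
#' design is such a pair.
#'
#' @param design data.frame with columns `experiment_id`, `heavy_condition`,
#'   `light_condition`. Exactly two distinct conditions overall.
#' @return A `LabelingDesign` object.
#' @examples
#' des <- LabelingDesign(data.frame(
#'   experiment_id = c("exp1", "exp2"),
#'   heavy_condition = c("mutant", "control"),
#'   light_condition = c("control", "mutant")))
#' isReciprocal(des)
#' @export
LabelingDesign <- function(design) {
  design <- as.data.frame(design)
  design$experiment_id <- as.character(design$experiment_id)
  design$heavy_condition <- as.character(design$heavy_condition)
  design$light_condition <- as.character(design$light_condition)
  rownames(design) <- NULL
  new("LabelingDesign", design = design)
}

#' @rdname StandardsTable
#' @export
setClass("StandardsTable",
  representation(standards = "data.frame"),
  validity = function(object) {
    d <- object@standards
    need <- c("name", "slice_center", "mass_kda")
    if (!all(need %in% colnames(d)))
      return("standards need name, slice_center, mass_kda")
    if (nrow(d) < 3L)
      return("at least 3 standards are required to fit a calibration")
    if (any(d$mass_kda <= 0)) return("masses must be positive")
    if (any(d$slice_center < 1)) return("slice_center must be >= 1")
    TRUE
  }
)

#' Native-mass calibration standards
#'
#' Migration positions (slice centers) of complexes of known native mass,
#' used to fit the slice-to-log10(mass) calibration curve. At least three
#' standards are required; masses are expected to decrease with increasing
#' slice center (the fit itself rejects an inverted orientation), but
#' positional jitter that locally breaks monotonicity is tolerated with a
#' warning by the reader.
#'
#' @param standards data.frame with columns `name`, `slice_center`,
#'   `mass_kda`. Sorted by `slice_center` on construction.
#' @return A `StandardsTable` object.
#' @seealso [fitCalibration()]
#' @export
StandardsTable <- function(standards) {
  standards <- as.data.frame(standards)
  standards$name <- as.character(standards$name)
  standards$slice_center <- as.numeric(standards$slice_center)
  standards$mass_kda <- as.numeric(standards$mass_kda)
  standards <- standards[order(standards$slice_center), , drop = FALSE]
  rownames(standards) <- NULL
  new("StandardsTable", standards = standards)
}

#' @rdname ModuleAnnotation
#' @export
setClass("ModuleAnnotation",
  representation(annotation = "data.frame"),
  validity = function(object) {
    d <- object@annotation
    if (!all(c("module_name", "protein_id") %in% colnames(d)))
      return("annotation needs module_name, protein_id")
    if (anyDuplicated(d$protein_id))
      return("a protein may belong to at most one module")
    TRUE
  }
)

#' Assembly-module annotation
#'
#' Assigns proteins to predefined assembly modules (e.g. the complex I
#' N/Q/ND modules, the complex IV early / MT-CO2 / MT-CO3 modules or the
#' ATP synthase F1 and peripheral-stalk modules) whose member profiles are
#' averaged by [moduleProfile()]. Within one annotation set a protein may
#' belong to at most one module.
#'
#' @param annotation data.frame with columns `module_name`, `protein_id`.
#' @return A `ModuleAnnotation` object.
#' @export
ModuleAnnotation <- function(annotation) {
  annotation <- as.data.frame(annotation)
  annotation$module_name <- as.character(annotation$module_name)
  annotation$protein_id <- as.character(annotation$protein_id)
  annotation <- annotation[order(annotation$module_name,
                                 annotation$protein_id), , drop = FALSE]
  rownames(annotation) <- NULL
  new("ModuleAnnotation", annotation = annotation)
}

#' @rdname CalibrationCurve
#' @export
setClass("CalibrationCurve",
  representation(intercept = "numeric", slope = "numeric",
                 residualSd = "numeric", nStandards = "integer"),
  validity = function(object) {
    if (length(object@intercept) != 1L || length(object@slope) != 1L)
      return("intercept and slope must be scalars")
    if (!is.finite(object@slope) || object@slope >= 0)
      return("slope must be negative (mass decreases down the gel)")
    if (object@nStandards < 3L) return("nStandards must be >= 3")
    TRUE
  }
)

#' Slice-to-native-mass calibration curve
#'
#' Log-linear calibration `log10(mass_kda) = intercept + slope * slice`
#' fitted by ordinary least squares on complex standards. The slope is
#' negative by construction: slice 1 is the top of the gel where the largest
#' species run.
#'
#' @param intercept intercept in log10(kDa).
#' @param slope slope in log10(kDa) per slice; must be negative.
#' @param residualSd residual standard deviation of the fit in log10(kDa).
#' @param nStandards number of standards the curve was fitted on.
#' @return A `CalibrationCurve` object.
#' @seealso [fitCalibration()], [massAt()], [sliceAt()]
#' @export
CalibrationCurve <- function(intercept, slope, residualSd = 0,
                             nStandards = 3L) {
  new("CalibrationCurve", intercept = as.numeric(intercept),
      slope = as.numeric(slope), residualSd = as.numeric(residualSd),
      nStandards = as.integer(nStandards))
}

#' @rdname MigrationProfile
#' @export
setClass("MigrationProfile",
  representation(subject = "character", condition = "character",
                 values = "numeric", sem = "numeric",
                 nExperiments = "integer", quantifiable = "logical"),
  validity = function(object) {
    if (length(object@values) != length(object@sem))
      return("values and sem must have equal length")
    if (any(object@values < -1e-12)) return("values must be non-negative")
    if (any(object@sem < -1e-12)) return("sem must be non-negative")
    if (object@nExperiments == 1L && any(object@sem != 0))
      return("sem must be all-zero when nExperiments == 1")
    TRUE
  }
)

#' Migration profile of a protein or module
#'
#' An intensity-versus-slice trace for one subject (protein or module) in
#' one condition: the per-slice mean across reciprocal labeling experiments
#' together with the per-slice SEM and the number of experiments averaged.
#' Profiles produced by [buildProfiles()] are jointly normalized so that the
#' maximum over the two conditions' mean traces equals 1, preserving the
#' relative scale between conditions.
#'
#' @param subject protein or module identifier.
#' @param condition condition name.
#' @param values numeric vector of per-slice means (length `nSlices`).
#' @param sem numeric vector of per-slice SEMs (zeros when a single
#'   experiment is available).
#' @param nExperiments number of experiments averaged.
#' @param quantifiable `FALSE` when the subject was not observed at all.
#' @return A `MigrationProfile` object.
#' @export
MigrationProfile <- function(subject, condition, values,
                             sem = numeric(length(values)),
                             nExperiments = 1L, quantifiable = TRUE) {
  new("MigrationProfile", subject = as.character(subject),
      condition = as.character(condition), values = as.numeric(values),
      sem = as.numeric(sem), nExperiments = as.integer(nExperiments),
      quantifiable = isTRUE(quantifiable))
}

#' @rdname ProfileSet
#' @export
setClass("ProfileSet",
  representation(profiles = "list", nSlices = "integer"),
  validity = function(object) {
    ok <- vapply(object@profiles, is, logical(1), class2 = "MigrationProfile")
    if (!all(ok)) return("all elements must be MigrationProfile objects")
    len <- vapply(object@profiles, function(p) length(p@values), integer(1))
    if (length(len) && any(len != object@nSlices))
      return("all profiles must have length nSlices")
    TRUE
  }
)

#' Collection of migration profiles
#'
#' A keyed collection of [MigrationProfile] objects (key
#' `"subject|condition"`), the return type of [buildProfiles()] and
#' [moduleProfile()].
#'
#' @param profiles list of `MigrationProfile` objects.
#' @param nSlices slice count shared by all profiles.
#' @return A `ProfileSet` object.
#' @export
ProfileSet <- function(profiles = list(), nSlices = 64L) {
  names(profiles) <- vapply(profiles, function(p)
    paste(p@subject, p@condition, sep = "|"), character(1))
  new("ProfileSet", profiles = profiles, nSlices = as.integer(nSlices))
}

# ---- generator-side classes -------------------------------------------------

#' @rdname SpeciesDefinition
#' @export
setClass("SpeciesDefinition",
  representation(name = "character", composition = "numeric",
                 massKda = "numeric", abundance = "numeric",
                 detergentScope = "character"),
  validity = function(object) {
    if (object@massKda <= 0) return("massKda must be positive")
    if (is.null(names(object@composition)) || !length(object@composition))
      return("composition must be a named protein -> copy-number map")
    if (any(object@composition <= 0)) return("copy numbers must be positive")
    if (is.null(names(object@abundance)))
      return("abundance must be named by condition")
    if (any(object@abundance < 0)) return("abundances must be non-negative")
    TRUE
  }
)

#' Native species definition for the generator
#'
#' One native complex species of the ground-truth model: its subunit
#' composition (protein copy numbers), native mass, per-condition abundance
#' in arbitrary intensity units, and the detergents under which it exists
#' (mild digitonin preserves supercomplexes; the stronger DDM dissociates
#' them into individual complexes).
#'
#' @param name species name.
#' @param composition named numeric vector, protein_id -> copy number.
#' @param massKda native mass in kDa.
#' @param abundance named numeric vector, condition -> abundance (arbitrary
#'   units); a species with all-zero abundance is inert.
#' @param detergentScope subset of `c("digitonin", "DDM")`.
#' @return A `SpeciesDefinition` object.
#' @export
SpeciesDefinition <- function(name, composition, massKda, abundance,
                              detergentScope = c("digitonin", "DDM")) {
  new("SpeciesDefinition", name = name, composition = composition,
      massKda = as.numeric(massKda), abundance = abundance,
      detergentScope = detergentScope)
}

#' @rdname ProteinGenerativeModel
#' @export
setClass("ProteinGenerativeModel",
  representation(proteinId = "character", nPeptides = "integer",
                 response = "numeric", observability = "numeric"),
  validity = function(object) {
    if (object@nPeptides < 1L) return("nPeptides must be >= 1")
    if (length(object@response) != object@nPeptides)
      return("one response factor per peptide required")
    if (any(object@response <= 0)) return("response factors must be positive")
    if (any(object@observability < 0 | object@observability > 1))
      return("observability must be in [0, 1]")
    TRUE
  }
)

#' Peptide-level generative model of a protein
#'
#' Models peptide-level heterogeneity of the MS signal: each protein is
#' reported by `nPeptides` abstract peptides with fixed positive response
#' factors (flyability) and a per-peptide detection probability applied per
#' slice.
#'
#' @param proteinId protein identifier.
#' @param nPeptides number of peptides reporting this protein.
#' @param response positive per-peptide response factors (recycled).
#' @param observability per-peptide detection probability per slice.
#' @return A `ProteinGenerativeModel` object.
#' @export
ProteinGenerativeModel <- function(proteinId, nPeptides = 4L,
                                   response = NULL, observability = 1) {
  nPeptides <- as.integer(nPeptides)
  if (is.null(response))
    response <- rep_len(c(1.0, 0.7, 1.3, 0.9, 1.1, 0.8), nPeptides)
  new("ProteinGenerativeModel", proteinId = proteinId,
      nPeptides = nPeptides, response = rep_len(response, nPeptides),
      observability = rep_len(observability, nPeptides))
}

#' @rdname NoiseModel
#' @export
setClass("NoiseModel",
  representation(sigmaLn = "numeric", detectionLimit = "numeric",
                 peakSigma = "numeric"),
  validity = function(object) {
    if (object@sigmaLn < 0) return("sigmaLn must be >= 0")
    if (object@detectionLimit < 0) return("detectionLimit must be >= 0")
    if (object@peakSigma <= 0) return("peakSigma must be > 0")
    TRUE
  }
)

#' Measurement-noise model of the generator
#'
#' Multiplicative lognormal intensity noise with detection-limit censoring
#' (values below the limit are censored to zero, i.e. dropped) and a
#' Gaussian migration spread shared by all species.
#'
#' @param sigmaLn standard deviation of the log-intensity noise
#'   (default 0.2).
#' @param detectionLimit intensity floor below which a value is unobserved
#'   (default 100, on the arbitrary-unit scale of [defaultScenario()]).
#' @param peakSigma migration band spread in slice units (default 1.0).
#' @return A `NoiseModel` object.
#' @export
NoiseModel <- function(sigmaLn = 0.2, detectionLimit = 100, peakSigma = 1.0) {
  new("NoiseModel", sigmaLn = as.numeric(sigmaLn),
      detectionLimit = as.numeric(detectionLimit),
      peakSigma = as.numeric(peakSigma))
}

#' @rdname GroundTruthScenario
#' @export
setClass("GroundTruthScenario",
  representation(species = "list", proteins = "list",
                 calibration = "numeric", conditions = "character",
                 nSlices = "integer", detergent = "character"),
  validity = function(object) {
    if (length(object@calibration) != 2L ||
        !all(c("a", "b") %in% names(object@calibration)))
      return("calibration must be c(a = ..., b = ...)")
    if (object@calibration[["b"]] >= 0)
      return("generating slope b must be negative")
    if (length(object@conditions) != 2L)
      return("exactly two conditions are required")
    prot <- unique(unlist(lapply(object@species,
                                 function(s) names(s@composition))))
    if (!all(prot %in% names(object@proteins)))
      return("every composition protein needs a generative model")
    TRUE
  }
)

#' Ground-truth scenario for lane simulation
#'
#' The complete generative model of a two-condition complexome experiment:
#' the native species with their compositions, masses and per-condition
#' abundances; the peptide-level protein models; the generating migration
#' law `log10(mass_kda) = a + b * slice` (b < 0); and the slice count.
#'
#' @param species list of [SpeciesDefinition] objects.
#' @param proteins list of [ProteinGenerativeModel] objects (named by
#'   protein on construction).
#' @param calibration named numeric `c(a = , b = )` of the generating
#'   log-linear migration law.
#' @param conditions character vector of the two condition names; the first
#'   is treated as the reference ("control") by convention.
#' @param nSlices number of slices per lane.
#' @param detergent solubilization condition this scenario emulates.
#' @return A `GroundTruthScenario` object.
#' @seealso [defaultScenario()], [simulateLane()]
#' @export
GroundTruthScenario <- function(species, proteins, calibration,
                                conditions = c("control", "mutant"),
                                nSlices = 64L, detergent = "digitonin") {
  names(species) <- vapply(species, function(s) s@name, character(1))
  names(proteins) <- vapply(proteins, function(p) p@proteinId, character(1))
  new("GroundTruthScenario", species = species, proteins = proteins,
      calibration = calibration, conditions = conditions,
      nSlices = as.integer(nSlices), detergent = detergent)
}
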