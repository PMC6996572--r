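# Generics, accessors and show methods.

#' Number of gel slices
#' @param x a PeptideSliceTable, ProfileSet or GroundTruthScenario.
#' @return integer slice count.
#' @export
setGeneric("nSlices", function(x) standardGeneric("nSlices"))

#' @rdname nSlices
#' @export
setMethod("nSlices", "PeptideSliceTable", function(x) x@nSlices)

#' @rdname nSlices
#' @export
setMethod("nSlices", "ProfileSet", function(x) x@nSlices)

#' @rdname nSlices
#' @export
setMethod("nSlices", "GroundTruthScenario", function(x) x@nSlices)

#' Underlying long-form peptide data
#' @param x a PeptideSliceTable.
#' @return data.frame with the canonical six columns.
#' @export
setGeneric("peptideData", function(x) standardGeneric("peptideData"))

#' @rdname peptideData
#' @export
setMethod("peptideData", "PeptideSliceTable", function(x) x@data)

#' Design table of a LabelingDesign
#' @param x a LabelingDesign.
#' @return data.frame with experiment_id, heavy_condition, light_condition.
#' @export
setGeneric("designTable", function(x) standardGeneric("designTable"))

#' @rdname designTable
#' @export
setMethod("designTable", "LabelingDesign", function(x) x@design)

#' Condition names of a design or scenario
#' @param x a LabelingDesign or GroundTruthScenario.
#' @return character vector of condition names.
#' @export
setGeneric("conditionNames", function(x) standardGeneric("conditionNames"))

#' @rdname conditionNames
#' @export
setMethod("conditionNames", "LabelingDesign", function(x)
  sort(unique(c(x@design$heavy_condition, x@design$light_condition))))

#' @rdname conditionNames
#' @export
setMethod("conditionNames", "GroundTruthScenario", function(x) x@conditions)

#' Is the design a reciprocal labeling pair?
#'
#' TRUE when the design contains exactly two experiments with swapped
#' heavy/light condition assignments.
#' @param x a LabelingDesign.
#' @return logical flag.
#' @export
setGeneric("isReciprocal", function(x) standardGeneric("isReciprocal"))

#' @rdname isReciprocal
#' @export
setMethod("isReciprocal", "LabelingDesign", function(x) {
  d <- x@design
  nrow(d) == 2L && d$heavy_condition[1] == d$light_condition[2] &&
    d$light_condition[1] == d$heavy_condition[2]
})

#' Standards data of a StandardsTable
#' @param x a StandardsTable.
#' @return data.frame sorted by slice_center.
#' @export
setGeneric("standardsData", function(x) standardGeneric("standardsData"))

#' @rdname standardsData
#' @export
setMethod("standardsData", "StandardsTable", function(x) x@standards)

#' Annotation data of a ModuleAnnotation
#' @param x a ModuleAnnotation.
#' @return data.frame with module_name, protein_id.
#' @export
setGeneric("annotationData", function(x) standardGeneric("annotationData"))

#' @rdname annotationData
#' @export
setMethod("annotationData", "ModuleAnnotation", function(x) x@annotation)

#' Members of one module
#' @param x a ModuleAnnotation.
#' @param module module name.
#' @return character vector of protein ids.
#' @export
setGeneric("moduleMembers", function(x, module)
  standardGeneric("moduleMembers"))

#' @rdname moduleMembers
#' @export
setMethod("moduleMembers", "ModuleAnnotation", function(x, module)
  x@annotation$protein_id[x@annotation$module_name == module])

#' Profile accessors
#'
#' `profileValues()`, `profileSem()`, `profileSubject()`,
#' `profileCondition()` and `profileN()` read the slots of a
#' [MigrationProfile]; `getProfile()` extracts one profile from a
#' [ProfileSet] by subject and condition.
#'
#' @param x a MigrationProfile or ProfileSet.
#' @name profile-accessors
NULL

#' @rdname profile-accessors
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))
#' @rdname profile-accessors
#' @export
setMethod("profileValues", "MigrationProfile", function(x) x@values)

#' @rdname profile-accessors
#' @export
setGeneric("profileSem", function(x) standardGeneric("profileSem"))
#' @rdname profile-accessors
#' @export
setMethod("profileSem", "MigrationProfile", function(x) x@sem)

#' @rdname profile-accessors
#' @export
setGeneric("profileSubject", function(x) standardGeneric("profileSubject"))
#' @rdname profile-accessors
#' @export
setMethod("profileSubject", "MigrationProfile", function(x) x@subject)

#' @rdname profile-accessors
#' @export
setGeneric("profileCondition", function(x)
  standardGeneric("profileCondition"))
#' @rdname profile-accessors
#' @export
setMethod("profileCondition", "MigrationProfile", function(x) x@condition)

#' @rdname profile-accessors
#' @export
setGeneric("profileN", function(x) standardGeneric("profileN"))
#' @rdname profile-accessors
#' @export
setMethod("profileN", "MigrationProfile", function(x) x@nExperiments)

#' @rdname profile-accessors
#' @param subject subject (protein or module) id.
#' @param condition condition name.
#' @export
setGeneric("getProfile", function(x, subject, condition)
  standardGeneric("getProfile"))

#' @rdname profile-accessors
#' @export
setMethod("getProfile", "ProfileSet", function(x, subject, condition) {
  key <- paste(subject, condition, sep = "|")
  if (is.null(x@profiles[[key]]))
    cplxError(sprintf("no profile for subject '%s', condition '%s'",
                      subject, condition), "cplx_lookup_error")
  x@profiles[[key]]
})

#' @rdname profile-accessors
#' @export
setGeneric("profileSubjects", function(x) standardGeneric("profileSubjects"))

#' @rdname profile-accessors
#' @export
setMethod("profileSubjects", "ProfileSet", function(x)
  unique(vapply(x@profiles, function(p) p@subject, character(1),
                USE.NAMES = FALSE)))

#' Species table of a scenario
#'
#' Flat summary of the planted species: name, mass, and one abundance
#' column per condition.
#' @param x a GroundTruthScenario.
#' @return data.frame with one row per species.
#' @export
setGeneric("speciesTable", function(x) standardGeneric("speciesTable"))

#' @rdname speciesTable
#' @export
setMethod("speciesTable", "GroundTruthScenario", function(x) {
  conds <- x@conditions
  rows <- lapply(x@species, function(s) {
    ab <- vapply(conds, function(cc)
      if (cc %in% names(s@abundance)) s@abundance[[cc]] else 0, numeric(1))
    cbind(data.frame(species = s@name, mass_kda = s@massKda,
                     n_proteins = length(s@composition)),
          as.data.frame(as.list(setNames(ab, paste0("abundance_", conds)))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
})

# ---- show methods -----------------------------------------------------------

setMethod("show", "PeptideSliceTable", function(object) {
  d <- object@data
  cat(sprintf("PeptideSliceTable: %d rows, %d slices\n", nrow(d),
              object@nSlices))
  cat(sprintf("  experiments: %s\n",
              paste(unique(d$experiment_id), collapse = ", ")))
  cat(sprintf("  proteins: %d, peptides: %d\n",
              length(unique(d$protein_id)),
              length(unique(paste(d$protein_id, d$peptide_id)))))
})

setMethod("show", "LabelingDesign", function(object) {
  cat("LabelingDesign (", if (isReciprocal(object)) "reciprocal pair"
      else "not a reciprocal pair", ")\n", sep = "")
  print(object@design)
})

setMethod("show", "StandardsTable", function(object) {
  cat(sprintf("StandardsTable: %d standards, %.0f-%.0f kDa\n",
              nrow(object@standards), min(object@standards$mass_kda),
              max(object@standards$mass_kda)))
})

setMethod("show", "ModuleAnnotation", function(object) {
  tab <- table(object@annotation$module_name)
  cat(sprintf("ModuleAnnotation: %d modules, %d proteins\n",
              length(tab), nrow(object@annotation)))
})

setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf(
    "CalibrationCurve: log10(kDa) = %.4f %+.4f * slice (n = %d, sd = %.3g)\n",
    object@intercept, object@slope, object@nStandards, object@residualSd))
})

setMethod("show", "MigrationProfile", function(object) {
  cat(sprintf(
    "MigrationProfile '%s' [%s]: %d slices, max %.3g, n = %d%s\n",
    object@subject, object@condition, length(object@values),
    if (length(object@values)) max(object@values) else NA_real_,
    object@nExperiments,
    if (object@quantifiable) "" else " (unquantifiable)"))
})

setMethod("show", "ProfileSet", function(object) {
  cat(sprintf("ProfileSet: %d profiles (%d subjects), %d slices\n",
              length(object@profiles), length(profileSubjects(object)),
              object@nSlices))
})

setMethod("show", "GroundTruthScenario", function(object) {
  cat(sprintf(
    "GroundTruthScenario (%s): %d species, %d proteins, %d slices\n",
    object@detergent, length(object@species), length(object@proteins),
    object@nSlices))
  cat(sprintf("  conditions: %s; law: log10(kDa) = %.3f %+.4f * slice\n",
              paste(object@conditions, collapse = " vs "),
              object@calibration[["a"]], object@calibration[["b"]]))
})
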