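# Migration profiles: peptide aggregation per slice, orientation of SILAC
# channels to biological conditions, joint normalization within the mixed
# lane, merging of reciprocal experiments, module averaging and heatmap
# matrices.

#' Raw per-slice intensity vector of one protein in one sample
#'
#' Aggregates the peptides of `proteinId` observed in one sample (one
#' experiment x channel) into a per-slice intensity vector. `method = "sum"`
#' (the default used for traces) sums all peptides per slice;
#' `method = "top_peptide"` (the heatmap convention) returns the vector of
#' the single most frequently observed peptide of that sample -- the peptide
#' with a non-zero intensity in the most slices, ties broken by larger total
#' intensity, then by lexicographically smaller peptide id.
#'
#' An unobserved protein yields a zero vector carrying
#' `attr(, "unobserved") = TRUE`.
#'
#' @param table a [PeptideSliceTable].
#' @param proteinId protein of interest.
#' @param experimentId,channel the sample.
#' @param method `"sum"` or `"top_peptide"`.
#' @return numeric vector of length `nSlices(table)`.
#' @export
buildProteinProfile <- function(table, proteinId, experimentId, channel,
                                method = c("sum", "top_peptide")) {
  method <- match.arg(method)
  d <- peptideData(table)
  d <- d[d$protein_id == proteinId & d$experiment_id == experimentId &
           d$channel == channel, , drop = FALSE]
  out <- numeric(nSlices(table))
  if (!nrow(d)) {
    attr(out, "unobserved") <- TRUE
    return(out)
  }
  if (method == "top_peptide") {
    nSlicesObs <- tapply(d$slice, d$peptide_id, function(s) length(unique(s)))
    total <- tapply(d$intensity, d$peptide_id, sum)
    ids <- names(nSlicesObs)
    o <- order(-as.numeric(nSlicesObs), -as.numeric(total), ids)
    d <- d[d$peptide_id == ids[o[1]], , drop = FALSE]
  }
  v <- tapply(d$intensity, d$slice, sum)
  out[as.integer(names(v))] <- as.numeric(v)
  attr(out, "unobserved") <- FALSE
  out
}

#' Orient one experiment's channels to conditions
#'
#' Assigns each protein's heavy-channel vector to the design's heavy
#' condition and the light-channel vector to the light condition, so that
#' downstream code never sees channels. Applying the orientation to an
#' already oriented result is the identity.
#'
#' @param table a [PeptideSliceTable].
#' @param design a [LabelingDesign].
#' @param experimentId experiment to orient.
#' @param method peptide aggregation method, see [buildProteinProfile()].
#' @param proteins optional protein subset (default: all observed).
#' @return named list (per protein) of `nSlices x 2` matrices with the two
#'   condition names as columns.
#' @export
orientExperiment <- function(table, design, experimentId,
                             method = c("sum", "top_peptide"),
                             proteins = NULL) {
  method <- match.arg(method)
  d <- designTable(design)
  row <- d[d$experiment_id == experimentId, , drop = FALSE]
  if (nrow(row) != 1L)
    cplxError(sprintf("experiment '%s' not in design", experimentId),
              "cplx_lookup_error")
  chanOf <- setNames(c("H", "L"), c(row$heavy_condition,
                                    row$light_condition))
  conds <- sort(names(chanOf))
  if (is.null(proteins)) {
    pd <- peptideData(table)
    proteins <- sort(unique(pd$protein_id[pd$experiment_id == experimentId]))
  }
  out <- lapply(proteins, function(p) {
    m <- vapply(conds, function(cc)
      as.numeric(buildProteinProfile(table, p, experimentId, chanOf[[cc]],
                                     method = method)),
      numeric(nSlices(table)))
    colnames(m) <- conds
    m
  })
  names(out) <- proteins
  out
}

#' Jointly normalize a condition pair
#'
#' Divides both per-condition vectors by the single maximum over their
#' concatenation, setting the maximum to 1.0 while preserving every intra-
#' and inter-condition intensity ratio. When both vectors are all-zero the
#' pair is returned unchanged with `attr(, "unquantifiable") = TRUE`.
#'
#' @param a,b numeric vectors of equal length (typically the control and
#'   mutant trace of one protein in one lane).
#' @return list with elements `a` and `b` and the `unquantifiable`
#'   attribute.
#' @export
normalizeJoint <- function(a, b) {
  stopifnot(length(a) == length(b))
  m <- max(c(a, b))
  out <- if (m <= 0) list(a = a, b = b)
         else list(a = a / m, b = b / m)
  attr(out, "unquantifiable") <- m <= 0
  out
}

#' Oriented shared-peptide condition ratio of one experiment
#'
#' The mutant-to-control (second vs first condition of the design) abundance
#' ratio of a protein in one mixed lane, computed as the median over all
#' peptide-slice cells quantified in both channels of the ratio
#' (mutant-channel intensity / control-channel intensity), reported as log2.
#' When no cell is shared between the channels the ratio is undefined and
#' `NA` is returned with `attr(, "defined") = FALSE` (such proteins are
#' reported per-sample only, as done for subunits found in just one cell
#' line).
#'
#' @param table a [PeptideSliceTable].
#' @param design a [LabelingDesign].
#' @param proteinId protein of interest.
#' @param experimentId experiment to use.
#' @param reference condition used as the denominator (default: the
#'   alphabetically first condition of the design).
#' @return scalar log2 ratio with attributes `defined` and `nShared`.
#' @export
sharedPeptideRatio <- function(table, design, proteinId, experimentId,
                               reference = NULL) {
  d <- designTable(design)
  row <- d[d$experiment_id == experimentId, , drop = FALSE]
  if (nrow(row) != 1L)
    cplxError(sprintf("experiment '%s' not in design", experimentId),
              "cplx_lookup_error")
  conds <- conditionNames(design)
  if (is.null(reference)) reference <- conds[1]
  other <- setdiff(conds, reference)
  chanOf <- setNames(c("H", "L"), c(row$heavy_condition,
                                    row$light_condition))
  pd <- peptideData(table)
  pd <- pd[pd$protein_id == proteinId & pd$experiment_id == experimentId, ,
           drop = FALSE]
  num <- pd[pd$channel == chanOf[[other]], ]
  den <- pd[pd$channel == chanOf[[reference]], ]
  key <- function(x) paste(x$peptide_id, x$slice, sep = "\r")
  shared <- intersect(key(num), key(den))
  if (!length(shared)) {
    out <- NA_real_
    attr(out, "defined") <- FALSE
    attr(out, "nShared") <- 0L
    return(out)
  }
  r <- num$intensity[match(shared, key(num))] /
       den$intensity[match(shared, key(den))]
  out <- log2(median(r))
  attr(out, "defined") <- TRUE
  attr(out, "nShared") <- length(shared)
  out
}

#' Merge reciprocal experiments into a mean/SEM profile
#'
#' Per-slice mean and SEM over experiment traces that have already been
#' oriented to conditions and jointly normalized per experiment. With the
#' usual two reciprocal experiments the SEM is the exact two-point formula
#' `|x1 - x2| / 2`; with a single experiment the SEM is identically zero.
#'
#' @param x1 numeric vector (experiment 1), or a matrix with one column per
#'   experiment.
#' @param x2 optional numeric vector (experiment 2).
#' @param subject,condition metadata for the resulting profile.
#' @return A [MigrationProfile].
#' @export
mergeReciprocal <- function(x1, x2 = NULL, subject = "subject",
                            condition = "condition") {
  m <- if (is.matrix(x1)) x1 else
    if (is.null(x2)) matrix(x1, ncol = 1) else {
      if (length(x1) != length(x2))
        cplxError("experiment vectors have mismatched lengths",
                  "cplx_validation_error")
      cbind(x1, x2)
    }
  n <- ncol(m)
  mean_ <- rowMeans(m)
  sem <- if (n == 1L) numeric(nrow(m))
         else if (n == 2L) abs(m[, 1] - m[, 2]) / 2
         else apply(m, 1, sd) / sqrt(n)
  MigrationProfile(subject, condition, mean_, sem, nExperiments = n,
                   quantifiable = any(mean_ > 0))
}

#' Build merged, normalized migration profiles for all proteins
#'
#' The full per-protein profile pipeline: for each experiment, peptide
#' intensities are aggregated per slice ([buildProteinProfile()]), channels
#' are oriented to conditions ([orientExperiment()]) and the two condition
#' traces are jointly normalized within the mixed lane
#' ([normalizeJoint()]); the per-experiment traces are then merged into
#' mean/SEM profiles ([mergeReciprocal()]) and finally re-normalized so the
#' maximum over the two condition means is exactly 1.
#'
#' @param tables named list of [PeptideSliceTable]s (one per experiment) or
#'   a single table containing several experiments.
#' @param design a [LabelingDesign] covering all experiments.
#' @param method peptide aggregation method, see [buildProteinProfile()].
#' @param proteins optional protein subset.
#' @return A [ProfileSet] keyed by `subject|condition`.
#' @export
buildProfiles <- function(tables, design, method = c("sum", "top_peptide"),
                          proteins = NULL) {
  method <- match.arg(method)
  if (is(tables, "PeptideSliceTable")) tables <- list(tables)
  ns <- nSlices(tables[[1]])
  des <- designTable(design)
  conds <- conditionNames(design)
  expOf <- lapply(tables, function(t) unique(peptideData(t)$experiment_id))
  if (is.null(proteins))
    proteins <- sort(unique(unlist(lapply(tables, function(t)
      peptideData(t)$protein_id))))
  oriented <- list()  # [[experiment]][[protein]] -> nSlices x 2 matrix
  for (i in seq_along(tables))
    for (e in intersect(expOf[[i]], des$experiment_id))
      oriented[[e]] <- orientExperiment(tables[[i]], design, e,
                                        method = method,
                                        proteins = proteins)
  profs <- list()
  for (p in proteins) {
    perExp <- lapply(oriented, function(o) {
      m <- o[[p]]
      nj <- normalizeJoint(m[, conds[1]], m[, conds[2]])
      if (attr(nj, "unquantifiable")) NULL else cbind(nj$a, nj$b)
    })
    perExp <- Filter(Negate(is.null), perExp)
    if (!length(perExp)) {
      for (cc in conds)
        profs[[length(profs) + 1L]] <-
          MigrationProfile(p, cc, numeric(ns), quantifiable = FALSE)
      next
    }
    merged <- lapply(seq_along(conds), function(j)
      mergeReciprocal(do.call(cbind, lapply(perExp, function(m) m[, j])),
                      subject = p, condition = conds[j]))
    peak <- max(vapply(merged, function(pr) max(pr@values), numeric(1)))
    for (pr in merged) {
      profs[[length(profs) + 1L]] <- MigrationProfile(
        pr@subject, pr@condition, pr@values / peak, pr@sem / peak,
        nExperiments = pr@nExperiments, quantifiable = TRUE)
    }
  }
  ProfileSet(profs, nSlices = ns)
}

#' Per-protein oriented condition ratios across experiments
#'
#' Summarizes [sharedPeptideRatio()] over all experiments of the design:
#' one oriented log2 ratio per experiment plus their mean.
#'
#' @inheritParams buildProfiles
#' @return data.frame with one row per protein: per-experiment log2 ratios,
#'   `mean_log2`, and `n_defined` (experiments with a defined ratio).
#' @export
conditionRatios <- function(tables, design, proteins = NULL) {
  if (is(tables, "PeptideSliceTable")) tables <- list(tables)
  des <- designTable(design)
  if (is.null(proteins))
    proteins <- sort(unique(unlist(lapply(tables, function(t)
      peptideData(t)$protein_id))))
  expTab <- list()
  for (t in tables)
    for (e in intersect(unique(peptideData(t)$experiment_id),
                        des$experiment_id))
      expTab[[e]] <- t
  rows <- lapply(proteins, function(p) {
    r <- vapply(names(expTab), function(e)
      as.numeric(sharedPeptideRatio(expTab[[e]], design, p, e)),
      numeric(1))
    data.frame(protein_id = p,
               as.list(setNames(r, paste0("log2_", names(expTab)))),
               mean_log2 = if (all(is.na(r))) NA_real_
                           else mean(r, na.rm = TRUE),
               n_defined = sum(!is.na(r)),
               check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Module-averaged migration profile
#'
#' Averages the normalized mean traces of a module's member proteins
#' (unweighted per-slice mean) per condition, with the SEM taken across
#' members; member proteins without a quantifiable profile are skipped with
#' a message, and a module with no observed member is an error. The module
#' pair is jointly re-normalized so the maximum over the two condition
#' means is 1, preserving the relative scale between conditions.
#'
#' @param profiles a [ProfileSet] of per-protein profiles (from
#'   [buildProfiles()]).
#' @param annotation a [ModuleAnnotation].
#' @param moduleName module to average.
#' @param renormalize jointly rescale the module pair to max 1
#'   (default TRUE).
#' @return A [ProfileSet] with one profile per condition, subject =
#'   `moduleName`.
#' @export
moduleProfile <- function(profiles, annotation, moduleName,
                          renormalize = TRUE) {
  members <- moduleMembers(annotation, moduleName)
  if (!length(members))
    cplxError(sprintf("module '%s' has no annotated members", moduleName),
              "cplx_empty_module_error")
  keys <- names(profiles@profiles)
  conds <- sort(unique(vapply(profiles@profiles,
                              function(p) p@condition, character(1))))
  used <- character(0)
  perCond <- list()
  for (cc in conds) {
    cols <- list()
    for (p in members) {
      key <- paste(p, cc, sep = "|")
      if (key %in% keys && profiles@profiles[[key]]@quantifiable) {
        cols[[p]] <- profiles@profiles[[key]]@values
        used <- union(used, p)
      }
    }
    perCond[[cc]] <- cols
  }
  if (!length(used))
    cplxError(sprintf("module '%s': no member protein observed", moduleName),
              "cplx_empty_module_error")
  skipped <- setdiff(members, used)
  if (length(skipped))
    message(sprintf("module '%s': skipping unobserved member(s) %s",
                    moduleName, paste(skipped, collapse = ", ")))
  out <- list()
  for (cc in conds) {
    m <- do.call(cbind, perCond[[cc]])
    if (is.null(m)) m <- matrix(0, nrow = profiles@nSlices, ncol = 1)
    nm <- ncol(m)
    mean_ <- rowMeans(m)
    sem <- if (nm > 1L) apply(m, 1, sd) / sqrt(nm) else numeric(nrow(m))
    out[[cc]] <- list(mean = mean_, sem = sem, n = nm)
  }
  peak <- max(vapply(out, function(x) max(x$mean), numeric(1)))
  scale <- if (renormalize && peak > 0) peak else 1
  # for a module profile the SEM is across members, so the profile's n
  # records the member count averaged in that condition
  ProfileSet(lapply(conds, function(cc)
    MigrationProfile(moduleName, cc, out[[cc]]$mean / scale,
                     out[[cc]]$sem / scale,
                     nExperiments = out[[cc]]$n,
                     quantifiable = any(out[[cc]]$mean > 0))),
    nSlices = profiles@nSlices)
}

#' Per-sample heatmap matrix
#'
#' One row per subject: the trace of the most frequently observed peptide of
#' that sample ([buildProteinProfile()] with `method = "top_peptide"`),
#' scaled to a row maximum of 1 (all-zero rows are retained). The matrix is
#' meant for the black (0) / yellow (0.5) / red (1) rendering of
#' [plotHeatmap()].
#'
#' @param table a [PeptideSliceTable].
#' @param subjects character vector of protein ids (rows).
#' @param experimentId,channel the sample.
#' @return numeric matrix `length(subjects) x nSlices`, values in `[0, 1]`.
#' @export
heatmapMatrix <- function(table, subjects, experimentId, channel) {
  m <- t(vapply(subjects, function(p) {
    v <- as.numeric(buildProteinProfile(table, p, experimentId, channel,
                                        method = "top_peptide"))
    if (max(v) > 0) v / max(v) else v
  }, numeric(nSlices(table))))
  rownames(m) <- subjects
  colnames(m) <- seq_len(nSlices(table))
  m
}
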