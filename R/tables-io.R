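# On-disk interchange. All tabular artifacts are TSV (tab-separated, UTF-8,
# '.' decimal, no quoting); the labeling design is JSON. Writers are
# deterministic: fixed column order, rows sorted by their declared keys,
# floats formatted to 6 significant digits with sprintf (locale-independent),
# so identical inputs yield byte-identical files.

fmtNum <- function(x) {
  out <- sprintf("%.6g", x)
  out[!is.finite(x)] <- "NA"
  out
}

writeTsv <- function(df, path, numeric_cols) {
  for (cc in numeric_cols) df[[cc]] <- fmtNum(df[[cc]])
  lines <- c(paste(colnames(df), collapse = "\t"),
             if (nrow(df)) do.call(paste, c(unname(as.list(df)), sep = "\t")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

requireColumns <- function(df, cols, what, path) {
  missing <- setdiff(cols, colnames(df))
  if (length(missing))
    cplxError(sprintf("%s '%s': missing column(s) %s", what, path,
                      paste(missing, collapse = ", ")),
              "cplx_validation_error")
}

#' Read a per-slice peptide intensity table
#'
#' Reads a TSV with header columns exactly `experiment_id`, `channel`,
#' `protein_id`, `peptide_id`, `slice`, `intensity` and validates it into a
#' [PeptideSliceTable]. Duplicate keys are an error (they are never
#' collapsed by summation); out-of-range slices, unknown channels and
#' negative intensities raise validation errors identifying the offending
#' row number.
#'
#' @param path path to a TSV file.
#' @param nSlices number of slices of the lane (default 64).
#' @return A [PeptideSliceTable].
#' @export
readPeptideTable <- function(path, nSlices = 64L) {
  df <- read.delim(path, sep = "\t", header = TRUE, quote = "",
                   stringsAsFactors = FALSE,
                   colClasses = "character")
  requireColumns(df, PEPTIDE_COLUMNS, "peptide table", path)
  df <- df[, PEPTIDE_COLUMNS]
  df$slice <- suppressWarnings(as.integer(df$slice))
  df$intensity <- suppressWarnings(as.numeric(df$intensity))
  badRow <- function(test, msg) {
    i <- which(test)
    if (length(i))
      cplxError(sprintf("peptide table '%s': %s at row %d", path, msg, i[1]),
                "cplx_validation_error")
  }
  badRow(is.na(df$slice), "non-integer slice")
  badRow(df$slice < 1L | df$slice > nSlices,
         sprintf("slice out of [1, %d]", nSlices))
  badRow(is.na(df$intensity) | df$intensity < 0, "negative intensity")
  badRow(!(df$channel %in% c("H", "L")), "unknown channel")
  key <- paste(df$experiment_id, df$channel, df$protein_id, df$peptide_id,
               df$slice, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    cplxError(sprintf(
      "peptide table '%s': duplicate (experiment, channel, protein, peptide, slice) key at row %d",
      path, dup[1]), "cplx_duplicate_key_error")
  PeptideSliceTable(df, nSlices = nSlices)
}

#' Write a peptide table
#'
#' Rows are sorted by the table key; zero-intensity rows are never present
#' (zero means "not observed").
#' @param x a [PeptideSliceTable].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writePeptideTable <- function(x, path) {
  writeTsv(peptideData(x), path, numeric_cols = "intensity")
}

#' Read calibration standards
#'
#' TSV with columns `name`, `slice_center`, `mass_kda`. Fewer than three
#' standards is an under-determined error; masses that do not decrease
#' monotonically with slice position produce a warning only (positional
#' jitter is tolerated by the least-squares fit).
#'
#' @param path path to a TSV file.
#' @return A [StandardsTable], sorted by slice center.
#' @export
readStandards <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, quote = "",
                   stringsAsFactors = FALSE)
  requireColumns(df, c("name", "slice_center", "mass_kda"),
                 "standards table", path)
  if (nrow(df) < 3L)
    cplxError(sprintf(
      "standards table '%s': %d standards; at least 3 are required",
      path, nrow(df)), "cplx_underdetermined_error")
  if (any(df$mass_kda <= 0))
    cplxError(sprintf("standards table '%s': non-positive mass", path),
              "cplx_validation_error")
  st <- StandardsTable(df)
  m <- standardsData(st)$mass_kda
  if (any(diff(m) >= 0))
    warning("standards masses are not strictly decreasing with slice; ",
            "treating as positional jitter", call. = FALSE)
  st
}

#' @rdname readStandards
#' @param x a [StandardsTable].
#' @export
writeStandards <- function(x, path) {
  writeTsv(standardsData(x), path, numeric_cols = c("slice_center",
                                                    "mass_kda"))
}

#' Read a module annotation
#'
#' TSV with columns `module_name`, `protein_id`; a protein may belong to at
#' most one module.
#' @param path path to a TSV file.
#' @return A [ModuleAnnotation].
#' @export
readModules <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, quote = "",
                   stringsAsFactors = FALSE, colClasses = "character")
  requireColumns(df, c("module_name", "protein_id"), "module table", path)
  ModuleAnnotation(df)
}

#' @rdname readModules
#' @param x a [ModuleAnnotation].
#' @export
writeModules <- function(x, path) {
  writeTsv(annotationData(x), path, numeric_cols = character(0))
}

#' Read a labeling design
#'
#' JSON of the form
#' `{"experiments": [{"experiment_id": ..., "heavy_condition": ...,
#' "light_condition": ...}, ...]}`. A design whose experiments do not form a
#' reciprocal pair (swapped heavy/light assignments) is accepted with a
#' "not reciprocal" warning.
#'
#' @param path path to a JSON file.
#' @return A [LabelingDesign].
#' @export
readDesign <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.null(obj$experiments))
    cplxError(sprintf("design '%s': missing 'experiments' key", path),
              "cplx_validation_error")
  des <- LabelingDesign(obj$experiments)
  if (!isReciprocal(des))
    warning("labeling design is not a reciprocal pair", call. = FALSE)
  des
}

#' @rdname readDesign
#' @param x a [LabelingDesign].
#' @export
writeDesign <- function(x, path) {
  jsonlite::write_json(list(experiments = designTable(x)), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write migration profiles
#'
#' Deterministic TSV with columns `protein_id` (the subject: protein or
#' module), `condition`, `slice`, `mean`, `sem`, sorted by (subject,
#' condition, slice).
#' @param x a [ProfileSet].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeProfiles <- function(x, path) {
  rows <- lapply(x@profiles, function(p)
    data.frame(protein_id = p@subject, condition = p@condition,
               slice = seq_along(p@values), mean = p@values, sem = p@sem))
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protein_id = character(0), condition = character(0),
               slice = integer(0), mean = numeric(0), sem = numeric(0))
  df <- df[order(df$protein_id, df$condition, df$slice), , drop = FALSE]
  writeTsv(df, path, numeric_cols = c("mean", "sem"))
}

#' Read migration profiles written by [writeProfiles()]
#' @param path TSV path.
#' @param nSlices slice count of the profiles.
#' @return A [ProfileSet].
#' @export
readProfiles <- function(path, nSlices = 64L) {
  df <- read.delim(path, sep = "\t", header = TRUE, quote = "",
                   stringsAsFactors = FALSE)
  requireColumns(df, c("protein_id", "condition", "slice", "mean", "sem"),
                 "profile table", path)
  keys <- unique(df[, c("protein_id", "condition")])
  profs <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$protein_id == keys$protein_id[i] &
                df$condition == keys$condition[i], ]
    sub <- sub[order(sub$slice), ]
    values <- sem <- numeric(nSlices)
    values[sub$slice] <- sub$mean
    sem[sub$slice] <- sub$sem
    MigrationProfile(keys$protein_id[i], keys$condition[i], values, sem,
                     nExperiments = if (any(sem > 0)) 2L else 1L)
  })
  ProfileSet(profs, nSlices = nSlices)
}

#' Write a peak table
#'
#' Deterministic TSV with fixed columns (subject, condition, center_slice,
#' apparent_mass_kda, left_slice, right_slice, auc, prominence), sorted by
#' (subject, condition, center_slice). An empty peak list yields a
#' header-only file.
#' @param peaks data.frame as returned by [detectPeaks()].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writePeaks <- function(peaks, path) {
  cols <- c("subject", "condition", "center_slice", "apparent_mass_kda",
            "left_slice", "right_slice", "auc", "prominence")
  for (cc in setdiff(cols, colnames(peaks)))
    peaks[[cc]] <- if (cc %in% c("subject", "condition"))
      character(nrow(peaks)) else rep(NA_real_, nrow(peaks))
  peaks <- peaks[, cols, drop = FALSE]
  peaks <- peaks[order(peaks$subject, peaks$condition, peaks$center_slice),
                 , drop = FALSE]
  writeTsv(peaks, path,
           numeric_cols = c("center_slice", "apparent_mass_kda", "auc",
                            "prominence"))
}

#' Write an enrichment (co-IP) table
#'
#' Deterministic TSV with columns protein_id, x, y, mean_log2,
#' n_experiments, consistent, class, sorted by protein_id.
#' @param points data.frame as returned by [classifyInteractors()].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeEnrichment <- function(points, path) {
  cols <- c("protein_id", "x", "y", "mean_log2", "n_experiments",
            "consistent", "class")
  points <- points[, cols, drop = FALSE]
  points <- points[order(points$protein_id), , drop = FALSE]
  writeTsv(points, path, numeric_cols = c("x", "y", "mean_log2"))
}
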