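# Scoring of reciprocal-labeling SILAC immunopurification experiments:
# per-protein oriented log2 ratio pairs and interactor classification.

#' Oriented per-protein co-IP log2 ratios
#'
#' For each protein and experiment, sums the channel intensities, forms the
#' mutant-to-control ratio (second vs first condition, oriented through the
#' labeling design) and reports it as log2. `x` is the oriented ratio of
#' the first experiment, `y` that of the second (equivalently, the reversed
#' heavy/light ratio of the reciprocal experiment, so genuine effects fall
#' on the scatter diagonal). Proteins quantified in only one experiment are
#' carried with `n_experiments = 1`; a protein with a zero denominator
#' channel in an experiment has an undefined ratio there.
#'
#' @param ipTables list of per-experiment data.frames with columns
#'   `experiment_id`, `protein_id`, `channel`, `intensity` (as produced by
#'   [simulateIP()]).
#' @param design a [LabelingDesign].
#' @param reference condition used as the denominator (default: the
#'   alphabetically first condition).
#' @param method `"intensity"` sums channel intensities per protein (the
#'   default, matching the protein-level generative model);
#'   `"peptide_median"` takes the median over per-row channel ratios when
#'   tables carry multiple rows (e.g. peptides) per protein and channel.
#' @return data.frame with columns `protein_id`, `x`, `y`, `mean_log2`,
#'   `n_experiments`.
#' @export
orientedIpRatios <- function(ipTables, design, reference = NULL,
                             method = c("intensity", "peptide_median")) {
  method <- match.arg(method)
  des <- designTable(design)
  conds <- conditionNames(design)
  if (is.null(reference)) reference <- conds[1]
  other <- setdiff(conds, reference)
  expIds <- des$experiment_id
  ratioOne <- function(df, experimentId) {
    row <- des[des$experiment_id == experimentId, , drop = FALSE]
    chanOf <- setNames(c("H", "L"), c(row$heavy_condition,
                                      row$light_condition))
    df <- df[df$experiment_id == experimentId, , drop = FALSE]
    prots <- sort(unique(df$protein_id))
    vapply(prots, function(p) {
      num <- df$intensity[df$protein_id == p &
                            df$channel == chanOf[[other]]]
      den <- df$intensity[df$protein_id == p &
                            df$channel == chanOf[[reference]]]
      if (!length(num) || !length(den) || sum(den) == 0) return(NA_real_)
      if (method == "intensity") log2(sum(num) / sum(den))
      else {
        k <- min(length(num), length(den))
        log2(median(num[seq_len(k)] / den[seq_len(k)]))
      }
    }, numeric(1))
  }
  perExp <- list()
  for (df in ipTables)
    for (e in intersect(unique(df$experiment_id), expIds))
      perExp[[e]] <- ratioOne(df, e)
  perExp <- perExp[intersect(expIds, names(perExp))]
  prots <- sort(unique(unlist(lapply(perExp, names))))
  getr <- function(r, p) if (p %in% names(r)) r[[p]] else NA_real_
  x <- vapply(prots, function(p) getr(perExp[[1]], p), numeric(1))
  y <- if (length(perExp) > 1L)
    vapply(prots, function(p) getr(perExp[[2]], p), numeric(1))
  else rep(NA_real_, length(prots))
  m <- cbind(x, y)
  data.frame(protein_id = prots, x = x, y = y,
             mean_log2 = rowMeans(m, na.rm = TRUE),
             n_experiments = rowSums(!is.na(m)))
}

#' Classify interactor changes from oriented ratio pairs
#'
#' A pair is `consistent` when the two oriented ratios share a sign or both
#' lie inside the unchanged band (`|ratio| < threshold`); single-experiment
#' proteins are treated as consistent. Sign-discordant pairs beyond the
#' band are `inconsistent`; otherwise the class follows the mean oriented
#' log2 ratio: `depleted` at or below `-threshold`, `enriched` at or above
#' `threshold`, `unchanged` in between.
#'
#' @param points data.frame from [orientedIpRatios()].
#' @param changedThresholdLog2 magnitude of the mean log2 ratio required to
#'   call a change (default 1.0, i.e. two-fold).
#' @return the input with added `consistent` (logical) and `class`
#'   (factor: depleted / enriched / unchanged / inconsistent).
#' @export
classifyInteractors <- function(points, changedThresholdLog2 = 1.0) {
  thr <- changedThresholdLog2
  x <- points$x; y <- points$y
  both <- !is.na(x) & !is.na(y)
  consistent <- rep(TRUE, nrow(points))
  consistent[both] <- (x[both] * y[both] >= 0) |
    (abs(x[both]) < thr & abs(y[both]) < thr)
  cls <- ifelse(!consistent, "inconsistent",
         ifelse(points$mean_log2 <= -thr, "depleted",
         ifelse(points$mean_log2 >= thr, "enriched", "unchanged")))
  points$consistent <- consistent
  points$class <- factor(cls, levels = c("depleted", "enriched",
                                         "unchanged", "inconsistent"))
  points
}

#' Reciprocal co-IP enrichment scatter
#'
#' Scatter of the experiment-1 oriented log2 ratio (x) against the
#' experiment-2 ratio on the reversed-orientation axis (y), so true effects
#' fall on the diagonal; point class is mapped to colour. Proteins
#' quantified in a single experiment are plotted on the corresponding axis
#' with a distinct shape. The classed table should be written alongside
#' with [writeEnrichment()].
#'
#' @param points classed data.frame from [classifyInteractors()].
#' @param file optional path; when given the plot is saved there (PDF/PNG
#'   by extension).
#' @return a ggplot object, invisibly when `file` is given.
#' @export
enrichmentScatter <- function(points, file = NULL) {
  df <- points
  df$single <- df$n_experiments < 2L
  df$x[is.na(df$x)] <- 0
  df$y[is.na(df$y)] <- 0
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        colour = .data$class,
                                        shape = .data$single)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey85") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey85") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(
      depleted = "#2166ac", enriched = "#b2182b",
      unchanged = "grey50", inconsistent = "#f4a582"), drop = FALSE) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 4),
                                guide = "none") +
    ggplot2::labs(x = "experiment 1, oriented log2 ratio",
                  y = "experiment 2, oriented log2 ratio (reversed axis)",
                  colour = NULL) +
    ggplot2::theme_classic()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 5, height = 4.5)
    return(invisible(p))
  }
  p
}
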