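# Divergence shrinkage: how much of the healthy type I ~ type IIa proteome
# divergence survives in disease, measured by maintained/lost significance
# and fold-change attenuation between the control contrast and the disease
# cross-contrast.

#' Partition control divergence proteins by disease significance
#'
#' Intersects the control contrast's significant proteins with the disease
#' contrast's tested universe and splits them into those that maintain
#' significance in disease and those that lose it. Fold-change pairs and
#' attenuation statistics are attached.
#'
#' @param control_results,disease_results `diffabund` results computed on
#'   overlapping protein universes.
#' @param alpha significance level (composite pi-value) for both contrasts.
#' @return A `shrinkage_report` list: `control_daps`, `identified_in_disease`,
#'   `maintained`, `lost`, `fc_pairs` (data frame `protein`, `control_fc`,
#'   `disease_fc`, `attenuated`, `sign_flip`), `attenuation_count`,
#'   `attenuation_ratio` (median `|disease|/|control|` over maintained
#'   proteins) and `attenuation_ratio_all` (same over all identified).
#' @export
partition_maintained <- function(control_results, disease_results, alpha = 0.05) {
  ctrl_sig <- significant_hits(control_results, alpha)
  universe <- disease_results$protein
  identified <- intersect(ctrl_sig$protein, universe)
  if (!length(identified))
    warning("disjoint universes: no control hit identified in disease", call. = FALSE)
  dis_sig <- significant_hits(disease_results, alpha)
  maintained <- intersect(identified, dis_sig$protein)
  lost <- setdiff(identified, maintained)
  fc_pairs <- data.frame(
    protein = identified,
    control_fc = ctrl_sig$log2fc[match(identified, ctrl_sig$protein)],
    disease_fc = disease_results$log2fc[match(identified, universe)],
    stringsAsFactors = FALSE)
  fc_pairs$attenuated <- abs(fc_pairs$disease_fc) < abs(fc_pairs$control_fc)
  fc_pairs$sign_flip <- sign(fc_pairs$disease_fc) != sign(fc_pairs$control_fc) &
    fc_pairs$disease_fc != 0
  att_all <- if (nrow(fc_pairs))
    foldchange_attenuation(fc_pairs$control_fc, fc_pairs$disease_fc)
  else list(attenuation_count = 0L, attenuation_ratio = NA_real_)
  mp <- fc_pairs[fc_pairs$protein %in% maintained, , drop = FALSE]
  ratio_maint <- if (nrow(mp))
    foldchange_attenuation(mp$control_fc, mp$disease_fc)$attenuation_ratio
  else NA_real_
  structure(list(control_daps = ctrl_sig$protein,
                 identified_in_disease = identified,
                 maintained = maintained, lost = lost,
                 fc_pairs = fc_pairs,
                 attenuation_count = att_all$attenuation_count,
                 attenuation_ratio = ratio_maint,
                 attenuation_ratio_all = att_all$attenuation_ratio,
                 alpha = alpha),
            class = "shrinkage_report")
}

#' @export
print.shrinkage_report <- function(x, ...) {
  cat(sprintf("<shrinkage_report> control DAPs: %d; identified in disease: %d\n",
              length(x$control_daps), length(x$identified_in_disease)))
  cat(sprintf("maintained: %d  lost: %d  attenuated: %d/%d  median |FC| ratio (maintained): %.3f\n",
              length(x$maintained), length(x$lost), x$attenuation_count,
              nrow(x$fc_pairs), x$attenuation_ratio))
  invisible(x)
}

#' Fold-change attenuation between two contrasts
#'
#' @param control_fc,disease_fc paired log2 fold changes per protein; at
#'   least one control value must be nonzero.
#' @return List with `attenuation_count` (pairs with `|disease| < |control|`,
#'   strict), `attenuation_ratio` (median of `|disease| / |control|` over
#'   pairs with nonzero control fc), and `pairs` (per-protein table with
#'   `ratio`, `attenuated`, `sign_flip`).
#' @export
foldchange_attenuation <- function(control_fc, disease_fc) {
  if (length(control_fc) != length(disease_fc))
    stop_invalid("fold-change vectors differ in length")
  if (!length(control_fc) || all(control_fc == 0))
    stop_invalid("undefined ratio: all control fold changes are zero")
  nz <- control_fc != 0
  ratio <- ifelse(nz, abs(disease_fc) / abs(control_fc), NA_real_)
  pairs <- data.frame(control_fc = control_fc, disease_fc = disease_fc,
                      ratio = ratio,
                      attenuated = abs(disease_fc) < abs(control_fc),
                      sign_flip = sign(disease_fc) != sign(control_fc) &
                        disease_fc != 0)
  list(attenuation_count = sum(pairs$attenuated),
       attenuation_ratio = stats::median(ratio, na.rm = TRUE),
       pairs = pairs)
}

#' Per-group summary and ANOVA/Tukey for a single protein
#'
#' Extracts one protein's log2 values across fibre groups (e.g. condition x
#' subtype cells), reports median and interquartile range per group, and the
#' one-way ANOVA with Tukey HSD from [anova_tukey()].
#'
#' @param pm a log2-scale `protein_matrix`.
#' @param protein protein-group id (or gene symbol, matched via `genes`).
#' @param groups named character vector mapping fibre ids to group labels.
#' @return List with `summary` (data frame `group`, `n`, `median`, `iqr`)
#'   and `test` (the [anova_tukey()] result).
#' @export
protein_group_stats <- function(pm, protein, groups) {
  row <- if (protein %in% rownames(pm$values)) protein
         else names(pm$genes)[match(protein, pm$genes)]
  if (is.na(row) || is.null(row))
    stop_invalid("protein '%s' not found", protein)
  groups <- groups[!is.na(groups) & names(groups) %in% colnames(pm$values)]
  v <- pm$values[row, names(groups)]
  by_group <- split(unname(v)[!is.na(v)], groups[!is.na(v)])
  by_group <- by_group[lengths(by_group) > 0]
  if (length(by_group) < 2L || any(lengths(by_group) < 2L))
    stop_invalid("insufficient data: protein '%s' needs >= 2 groups with >= 2 fibres",
                 protein)
  summ <- data.frame(group = names(by_group),
                     n = lengths(by_group),
                     median = vapply(by_group, stats::median, 1),
                     iqr = vapply(by_group, stats::IQR, 1),
                     row.names = NULL)
  list(summary = summ, test = anova_tukey(by_group))
}
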