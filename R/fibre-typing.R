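# MYH-isoform based fibre typing.
# Slow (type I) fibres are MYH7-dominant, fast IIa fibres MYH2-dominant and
# fast IIx fibres MYH1-dominant; mixtures are hybrids. Typing uses the
# relative raw-scale LFQ of the three isoforms within each fibre.

MYH_CANONICAL <- c(I = "MYH7", IIa = "MYH2", IIx = "MYH1")

#' Relative MYH7 / MYH2 / MYH1 abundance for one fibre
#'
#' Raw-scale (back-transformed if the matrix is log2) LFQ of each isoform is
#' divided by the sum of the three. A missing isoform contributes zero.
#'
#' @param pm a `protein_matrix` whose gene symbols include MYH7/MYH2/MYH1.
#' @param fibre_id fibre to evaluate.
#' @return Named numeric vector `c(rel7, rel2, rel1)` summing to 1.
#' @export
myh_relative_abundance <- function(pm, fibre_id) {
  if (!fibre_id %in% colnames(pm$values))
    stop_invalid("fibre '%s' not in matrix", fibre_id)
  raw <- raw_values(pm)[, fibre_id]
  iso <- vapply(c("MYH7", "MYH2", "MYH1"), function(g) {
    rows <- which(pm$genes == g)
    if (!length(rows)) return(NA_real_)
    v <- raw[rows]
    if (all(is.na(v))) NA_real_ else sum(v, na.rm = TRUE)
  }, 1)
  if (all(is.na(iso)))
    stop_invalid("untypeable fibre '%s': no MYH7/MYH2/MYH1 quantified", fibre_id)
  iso[is.na(iso)] <- 0
  rel <- iso / sum(iso)
  stats::setNames(rel, c("rel7", "rel2", "rel1"))
}

#' Assign a fibre subtype from MYH relative abundances
#'
#' If the dominant isoform's fraction reaches `pure_threshold` the fibre gets
#' the pure label (MYH7 -> I, MYH2 -> IIa, MYH1 -> IIx); otherwise the hybrid
#' label of the top two isoforms in canonical order (I/IIa, IIa/IIx). The
#' non-adjacent combination (MYH7 and MYH1 dominant with MYH2 lowest) is
#' still labelled by its top two (I/IIx) and reported via a message.
#'
#' @param rel7,rel2,rel1 fractions in `[0, 1]` summing to 1.
#' @param pure_threshold dominant fraction required for a pure call
#'   (default 0.7).
#' @return Label in `{"I", "I/IIa", "IIa", "IIa/IIx", "IIx", "I/IIx"}`.
#' @export
assign_fibre_type <- function(rel7, rel2, rel1, pure_threshold = 0.7) {
  rel <- c(rel7, rel2, rel1)
  if (any(!is.finite(rel)) || any(rel < -1e-9) || abs(sum(rel) - 1) > 1e-9)
    stop_invalid("fractions must be in [0,1] and sum to 1")
  names(rel) <- c("I", "IIa", "IIx")
  top <- order(rel, decreasing = TRUE)
  if (rel[top[1]] >= pure_threshold) return(names(rel)[top[1]])
  pair <- sort(top[1:2])  # canonical order I < IIa < IIx
  lab <- paste(names(rel)[pair], collapse = "/")
  if (identical(names(rel)[pair], c("I", "IIx")))
    message("non-adjacent hybrid (MYH7+MYH1 dominant) labelled ", lab)
  lab
}

#' Type every fibre in a protein matrix
#'
#' @param pm a `protein_matrix`.
#' @param pure_threshold dominant-isoform fraction for a pure call.
#' @return Data frame (`fibre_type_calls`): `fibre_id`, `rel7`, `rel2`,
#'   `rel1`, `label`, `threshold`. Untypeable fibres (no MYH isoform
#'   quantified) are omitted with a warning.
#' @export
fibre_types <- function(pm, pure_threshold = 0.7) {
  rows <- lapply(colnames(pm$values), function(fid) {
    rel <- tryCatch(myh_relative_abundance(pm, fid), error = function(e) NULL)
    if (is.null(rel)) return(NULL)
    data.frame(fibre_id = fid, rel7 = rel[["rel7"]], rel2 = rel[["rel2"]],
               rel1 = rel[["rel1"]],
               label = assign_fibre_type(rel[["rel7"]], rel[["rel2"]],
                                         rel[["rel1"]], pure_threshold),
               threshold = pure_threshold, stringsAsFactors = FALSE)
  })
  dropped <- colnames(pm$values)[vapply(rows, is.null, TRUE)]
  if (length(dropped))
    warning("untypeable fibres omitted: ", paste(dropped, collapse = ", "),
            call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("fibre_type_calls", "data.frame")
  out
}

#' Order typed fibres by MYH7 fraction and summarise composition
#'
#' @param calls a [fibre_types()] result.
#' @param annotations optional annotation data frame (`fibre_id`,
#'   `condition`) for a per-condition composition table.
#' @return List with `ordered` (calls sorted by `rel7` descending) and
#'   `composition` (subtype relative frequency, overall or per condition).
#' @export
rank_fibre_types <- function(calls, annotations = NULL) {
  if (!nrow(calls)) stop_invalid("no fibre type calls supplied")
  ordered <- calls[order(-calls$rel7), , drop = FALSE]
  rownames(ordered) <- NULL
  if (is.null(annotations)) {
    comp <- proportions(table(label = calls$label))
  } else {
    cond <- annotations$condition[match(calls$fibre_id, annotations$fibre_id)]
    comp <- proportions(table(condition = cond, label = calls$label), margin = 1)
  }
  list(ordered = ordered, composition = comp)
}

#' Sensitivity sweep of the pure-call threshold
#'
#' Recomputes subtype composition over a grid of `pure_threshold` values, to
#' show how the pure/hybrid split depends on the (unreported) threshold.
#'
#' @param pm a `protein_matrix`.
#' @param thresholds numeric vector of thresholds to sweep.
#' @return Data frame: `threshold`, one column per observed label with its
#'   relative frequency.
#' @export
fibre_type_sweep <- function(pm, thresholds = seq(0.5, 0.9, by = 0.05)) {
  rows <- lapply(thresholds, function(th) {
    calls <- suppressWarnings(fibre_types(pm, pure_threshold = th))
    tab <- proportions(table(calls$label))
    cbind(data.frame(threshold = th), as.data.frame(t(as.matrix(tab))))
  })
  labs <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (l in setdiff(labs, names(r))) r[[l]] <- 0
    r[labs]
  })
  do.call(rbind, rows)
}
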