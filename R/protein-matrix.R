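#' Construct a protein quantification matrix
#'
#' Container for a protein-group x fibre intensity matrix with per-fibre
#' annotations. Values may be on the raw LFQ or log2 scale (tracked by the
#' `log2` flag); missing (not quantified) entries are `NA`, distinct from
#' measured zeros, which are not admitted.
#'
#' @param values numeric matrix, protein groups in rows (rownames = ids),
#'   fibres in columns (colnames = fibre ids); `NA` = not quantified.
#' @param annotations data frame with at least `fibre_id`, `participant`,
#'   `condition`; one row per fibre column. Optional columns (e.g. `srx_pct`)
#'   are carried along.
#' @param genes optional character vector of gene symbols per protein row.
#' @param log2 logical: are `values` log2-transformed?
#' @return A `protein_matrix` object.
#' @export
protein_matrix <- function(values, annotations, genes = NULL, log2 = FALSE) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop_invalid("protein ids (rownames) must be present and unique")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop_invalid("fibre ids (colnames) must be present and unique")
  need <- c("fibre_id", "participant", "condition")
  miss <- setdiff(need, names(annotations))
  if (length(miss))
    stop_invalid("annotations missing columns: %s", paste(miss, collapse = ", "))
  if (!all(annotations$fibre_id %in% colnames(values)))
    stop_invalid("every annotated fibre must exist in the matrix")
  annotations <- annotations[match(colnames(values), annotations$fibre_id), ,
                             drop = FALSE]
  if (anyNA(annotations$fibre_id))
    stop_invalid("every matrix fibre needs an annotation row")
  rownames(annotations) <- NULL
  if (is.null(genes)) genes <- rownames(values)
  structure(list(values = values, annotations = annotations,
                 genes = stats::setNames(as.character(genes), rownames(values)),
                 log2 = isTRUE(log2)),
            class = "protein_matrix")
}

#' @export
print.protein_matrix <- function(x, ...) {
  cat(sprintf("<protein_matrix> %d protein groups x %d fibres (%s scale), %.1f%% missing\n",
              nrow(x$values), ncol(x$values),
              if (x$log2) "log2 LFQ" else "raw LFQ",
              100 * mean(is.na(x$values))))
  cat("conditions:", paste(sprintf("%s (%d)", names(table(x$annotations$condition)),
                                   table(x$annotations$condition)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.protein_matrix <- function(x) dim(x$values)

#' Subset a protein matrix by fibres and/or proteins
#'
#' @param pm a `protein_matrix`.
#' @param fibres,proteins character vectors of ids to keep (default: all).
#' @return A `protein_matrix`.
#' @export
subset_matrix <- function(pm, fibres = NULL, proteins = NULL) {
  fibres <- fibres %||% colnames(pm$values)
  proteins <- proteins %||% rownames(pm$values)
  protein_matrix(pm$values[proteins, fibres, drop = FALSE],
                 pm$annotations[pm$annotations$fibre_id %in% fibres, , drop = FALSE],
                 genes = pm$genes[proteins], log2 = pm$log2)
}

#' Combine protein matrices sharing a protein universe
#'
#' Column-binds cohorts (e.g. control and disease) measured on the same
#' protein rows; annotations are stacked.
#'
#' @param ... `protein_matrix` objects with identical rownames and scale.
#' @return A `protein_matrix`.
#' @export
combine_matrices <- function(...) {
  pms <- list(...)
  if (length(pms) < 2L) return(pms[[1]])
  ref <- rownames(pms[[1]]$values)
  for (pm in pms[-1]) {
    if (!identical(rownames(pm$values), ref))
      stop_invalid("matrices must share an identical protein universe")
    if (!identical(pm$log2, pms[[1]]$log2))
      stop_invalid("matrices must be on the same scale")
  }
  ann <- do.call(rbind, lapply(pms, function(p) {
    common <- Reduce(intersect, lapply(pms, function(q) names(q$annotations)))
    p$annotations[, common, drop = FALSE]
  }))
  protein_matrix(do.call(cbind, lapply(pms, `[[`, "values")), ann,
                 genes = pms[[1]]$genes, log2 = pms[[1]]$log2)
}

#' Read a DIA protein-group (PG) matrix with fibre annotations
#'
#' Parses the tab-separated protein-group quantification table written by DIA
#' search software: protein-group and gene columns followed by one intensity
#' column per run. Blank entries and zero intensities are treated as not
#' quantified (`NA`), per label-free convention. Run columns are matched to
#' the annotation table's `fibre_id`; unmatched runs are dropped with a
#' warning. Duplicated protein-group ids are disambiguated deterministically
#' by suffixing `.2`, `.3`, ... in file order, with a message.
#'
#' @param path PG-matrix TSV path.
#' @param annotation_path CSV with columns `fibre_id`, `participant`,
#'   `condition`.
#' @param id_col,gene_col column names holding protein-group ids and gene
#'   symbols.
#' @return A raw-scale `protein_matrix`.
#' @export
read_pg_matrix <- function(path, annotation_path,
                           id_col = "Protein.Group", gene_col = "Genes") {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!id_col %in% names(raw))
    stop_invalid("format error: no '%s' column in %s", id_col, path)
  meta_cols <- intersect(c(id_col, gene_col, "Protein.Ids", "Protein.Names",
                           "First.Protein.Description"), names(raw))
  run_cols <- setdiff(names(raw), meta_cols)
  if (!length(run_cols))
    stop_invalid("format error: no run columns in %s", path)
  if (anyDuplicated(run_cols))
    stop_invalid("format error: duplicated run columns in %s", path)
  ids <- as.character(raw[[id_col]])
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    message("disambiguating duplicated protein-group ids: ",
            paste(dup, collapse = ", "))
    ids <- make.unique(ids, sep = ".")
  }
  vals <- as.matrix(raw[, run_cols, drop = FALSE])
  storage.mode(vals) <- "double"
  vals[!is.na(vals) & vals == 0] <- NA  # zeros = not quantified
  rownames(vals) <- ids
  annot <- utils::read.csv(annotation_path, stringsAsFactors = FALSE)
  matched <- intersect(run_cols, annot$fibre_id)
  un_run <- setdiff(run_cols, matched)
  un_ann <- setdiff(annot$fibre_id, matched)
  if (length(un_run))
    warning("runs without annotation excluded: ",
            paste(un_run, collapse = ", "), call. = FALSE)
  if (length(un_ann))
    warning("annotated fibres without a run column: ",
            paste(un_ann, collapse = ", "), call. = FALSE)
  genes <- if (gene_col %in% names(raw)) as.character(raw[[gene_col]]) else ids
  protein_matrix(vals[, matched, drop = FALSE],
                 annot[annot$fibre_id %in% matched, , drop = FALSE],
                 genes = genes, log2 = FALSE)
}

#' Log2-transform a raw-scale protein matrix
#'
#' @param pm a raw-scale `protein_matrix`; present values must be positive.
#' @return The matrix on log2 scale; missing entries stay missing.
#' @export
log2_transform <- function(pm) {
  if (pm$log2) stop_invalid("matrix is already log2-transformed")
  bad <- which(!is.na(pm$values) & pm$values <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop_invalid("nonpositive intensity at protein '%s', fibre '%s'",
                 rownames(pm$values)[bad[1, 1]], colnames(pm$values)[bad[1, 2]])
  pm$values <- log2(pm$values)
  pm$log2 <- TRUE
  pm
}

# back-transform helper: raw-scale values whatever the working scale
raw_values <- function(pm) if (pm$log2) 2^pm$values else pm$values

#' Per-fibre quantified-protein counts
#'
#' @param pm a `protein_matrix`.
#' @return List with `counts` (named integer vector per fibre), `mean`, `sd`.
#' @export
protein_counts <- function(pm) {
  counts <- colSums(!is.na(pm$values))
  list(counts = counts, mean = mean(counts), sd = stats::sd(counts))
}

#' Flag outlier fibres by PCA on complete-case proteins
#'
#' PCA (centred, unscaled) is run on the submatrix of proteins quantified in
#' every fibre — the deterministic reading of running PCA while omitting
#' missing values. A fibre is flagged when its Euclidean distance from the
#' componentwise median point in the PC1-PC2 plane, divided by the median
#' absolute deviation of all fibres' distances, exceeds `k_mad`. If the MAD
#' is zero, only fibres at nonzero distance can be flagged (and only when
#' `k_mad` is finite).
#'
#' @param pm a log2-scale `protein_matrix` with >= 3 fibres.
#' @param k_mad outlier threshold in MAD units (default 5).
#' @return A `qc_report` list: `counts` (per-fibre protein counts), `pca`
#'   (data frame `fibre_id`, `pc1`, `pc2`, `dist_mad`, `outlier`), and
#'   `outliers` (character vector of flagged fibre ids).
#' @export
pca_outliers <- function(pm, k_mad = 5) {
  if (!pm$log2) stop_invalid("run pca_outliers on the log2-scale matrix")
  if (ncol(pm$values) < 3L) stop_invalid("need at least 3 fibres")
  complete <- !apply(is.na(pm$values), 1, any)
  if (sum(complete) < 2L)
    stop_invalid(paste("insufficient data: fewer than 2 complete-case proteins;",
                       "imputation is out of scope"))
  sub <- t(pm$values[complete, , drop = FALSE])  # fibres x proteins
  keep <- apply(sub, 2, function(v) stats::var(v) > 0)
  if (!any(keep)) {
    pcs <- matrix(0, nrow(sub), 2)
  } else {
    pr <- stats::prcomp(sub[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
    pcs <- pr$x[, seq_len(min(2, ncol(pr$x))), drop = FALSE]
    if (ncol(pcs) < 2) pcs <- cbind(pcs, 0)
  }
  centre <- apply(pcs, 2, stats::median)
  d <- sqrt((pcs[, 1] - centre[1])^2 + (pcs[, 2] - centre[2])^2)
  s <- stats::mad(d)
  scaled <- if (s > 0) d / s else ifelse(d > 0, Inf, 0)
  flag <- is.finite(k_mad) & scaled > k_mad
  report <- data.frame(fibre_id = colnames(pm$values),
                       pc1 = pcs[, 1], pc2 = pcs[, 2],
                       dist_mad = scaled, outlier = flag)
  rownames(report) <- NULL
  structure(list(counts = protein_counts(pm)$counts, pca = report,
                 outliers = report$fibre_id[report$outlier]),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d fibres, %.0f (+/- %.0f) proteins/fibre, %d outlier(s)\n",
              length(x$counts), mean(x$counts), stats::sd(x$counts),
              length(x$outliers)))
  if (length(x$outliers)) cat("outliers:", paste(x$outliers, collapse = ", "), "\n")
  invisible(x)
}
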