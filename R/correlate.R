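# Same-fibre integration of myosin SRX state with the proteome: presence
# filtering, unadjusted Spearman correlation overall and per fibre subtype,
# and hierarchical clustering of subtype correlation profiles.

#' Restrict to dual-data fibres and well-observed proteins
#'
#' Keeps fibres that carry both an SRX measurement and a proteome column,
#' drops listed outlier fibres, then keeps proteins quantified in at least
#' `min_n_all` of the retained fibres. Idempotent.
#'
#' @param pm a `protein_matrix`.
#' @param srx named numeric vector of SRX percentages by fibre id.
#' @param outliers character vector of fibre ids to drop (e.g. from
#'   [pca_outliers()]).
#' @param min_n_all minimum number of fibres a protein must be quantified in
#'   (default 22).
#' @return A filtered `protein_matrix`.
#' @export
filter_dual <- function(pm, srx, outliers = character(), min_n_all = 22) {
  dual <- intersect(colnames(pm$values), names(srx)[is.finite(srx)])
  dual <- setdiff(dual, outliers)
  if (!length(dual))
    stop_invalid("insufficient data: no fibres with both SRX and proteome data")
  sub <- pm$values[, dual, drop = FALSE]
  keep <- rowSums(!is.na(sub)) >= min_n_all
  subset_matrix(pm, fibres = dual, proteins = rownames(sub)[keep])
}

# cache of permutation index matrices for exact p-values
.perm_cache <- new.env(parent = emptyenv())

perm_matrix <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  build <- function(v) {
    if (length(v) == 1L) return(matrix(v, 1, 1))
    do.call(rbind, lapply(seq_along(v), function(i)
      cbind(v[i], build(v[-i]))))
  }
  m <- build(seq_len(n))
  .perm_cache[[key]] <- m
  m
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Average ranks for ties. The two-sided p-value is computed by full
#' permutation enumeration for `n <= 9` and by the t-approximation
#' (`t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2` df) otherwise.
#'
#' @param x,y paired numeric vectors, complete observations, `n >= 4`.
#' @return List with `rho`, `p`, `n`.
#' @export
spearman_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop_invalid("insufficient data: need n >= 4 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop_invalid("undefined correlation: zero variance")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 9L) {
    rxs <- (rx - mean(rx)) / stats::sd(rx)
    rys <- (ry - mean(ry)) / stats::sd(ry)
    pm <- perm_matrix(n)
    rho_all <- (matrix(rys[pm], nrow(pm)) %*% rxs) / (n - 1)
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
  }
  list(rho = rho, p = p, n = n)
}

#' Correlate SRX percentage with protein abundance across fibres
#'
#' Per protein, unadjusted Spearman correlation between log2 abundance and
#' same-fibre SRX percent (and, symmetrically, DRX percent), within a scope:
#' all dual fibres, or one fibre subtype. Subtype scopes require a protein to
#' be quantified in at least `min_n_subtype` fibres of that subtype; hybrid
#' fibres belong to scope "all" only.
#'
#' @param pm a filtered log2-scale `protein_matrix` (see [filter_dual()]).
#' @param srx named SRX percentages by fibre id.
#' @param types optional [fibre_types()] calls (needed for subtype scopes).
#' @param scope one of `"all"`, `"typeI"`, `"typeIIa"`.
#' @param min_n_subtype presence floor within a subtype scope (default 10).
#' @param drx optional named DRX percentages; defaults to `100 - srx`.
#' @param alpha unadjusted significance level for the `significant` flag.
#' @return A `srx_correlations` data frame: `protein`, `scope`, `rho`, `p_raw`,
#'   `n`, `significant`, plus `rho_drx`, `p_drx` for the DRX correlation.
#' @export
correlate_srx <- function(pm, srx, types = NULL, scope = c("all", "typeI", "typeIIa"),
                          min_n_subtype = 10, drx = NULL, alpha = 0.05) {
  scope <- match.arg(scope)
  fibres <- intersect(colnames(pm$values), names(srx)[is.finite(srx)])
  if (scope != "all") {
    if (is.null(types)) stop_invalid("subtype scope requires fibre type calls")
    want <- if (scope == "typeI") "I" else "IIa"
    fibres <- intersect(fibres, types$fibre_id[types$label == want])
  }
  if (length(fibres) < 4L)
    stop_invalid("insufficient data: scope '%s' has fewer than 4 fibres", scope)
  floor_n <- if (scope == "all") 4L else max(4L, min_n_subtype)
  srx_v <- srx[fibres]
  drx_v <- if (is.null(drx)) 100 - srx_v else drx[fibres]
  rows <- lapply(rownames(pm$values), function(pr) {
    v <- pm$values[pr, fibres]
    ok <- !is.na(v)
    if (sum(ok) < floor_n) return(NULL)
    cs <- tryCatch(spearman_cor(v[ok], srx_v[ok]), error = function(e) NULL)
    if (is.null(cs)) return(NULL)
    cd <- tryCatch(spearman_cor(v[ok], drx_v[ok]), error = function(e) NULL)
    data.frame(protein = pr, scope = scope, rho = cs$rho, p_raw = cs$p,
               n = cs$n, significant = cs$p < alpha,
               rho_drx = if (is.null(cd)) NA_real_ else cd$rho,
               p_drx = if (is.null(cd)) NA_real_ else cd$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    stop_invalid("no protein passed the presence floor in scope '%s'", scope)
  rownames(out) <- NULL
  class(out) <- c("srx_correlations", "data.frame")
  out
}

#' Hierarchically cluster subtype correlation profiles
#'
#' Agglomerative clustering of per-protein `(rho_typeI, rho_typeIIa)`
#' profiles, for proteins whose SRX correlation is significant in at least
#' one subtype. Deterministic given `k` (or `cut_height`); the dendrogram is
#' also serialised as Newick text.
#'
#' @param typeI,typeIIa `srx_correlations` results for the two subtypes.
#' @param k number of clusters (ignored when `cut_height` given).
#' @param cut_height optional dendrogram cut height.
#' @param linkage,metric agglomeration method and distance metric.
#' @return List with `profiles` (data frame `protein`, `rho_typeI`,
#'   `rho_typeIIa`, `cluster`), `hclust`, and `newick`.
#' @export
cluster_srx_profiles <- function(typeI, typeIIa, k = 2, cut_height = NULL,
                                 linkage = "complete", metric = "euclidean") {
  common <- intersect(typeI$protein, typeIIa$protein)
  sig <- typeI$significant[match(common, typeI$protein)] |
         typeIIa$significant[match(common, typeIIa$protein)]
  common <- common[sig]
  if (length(common) < 2L)
    stop_invalid("need at least 2 proteins with significant subtype correlations")
  prof <- cbind(rho_typeI = typeI$rho[match(common, typeI$protein)],
                rho_typeIIa = typeIIa$rho[match(common, typeIIa$protein)])
  rownames(prof) <- common
  hc <- stats::hclust(stats::dist(prof, method = metric), method = linkage)
  if (is.null(cut_height)) {
    if (k > length(common)) stop_invalid("k exceeds the number of proteins")
    cl <- stats::cutree(hc, k = k)
  } else {
    cl <- stats::cutree(hc, h = cut_height)
  }
  newick <- ape::write.tree(ape::as.phylo(hc))
  list(profiles = data.frame(protein = common,
                             rho_typeI = prof[, 1], rho_typeIIa = prof[, 2],
                             cluster = unname(cl), row.names = NULL),
       hclust = hc, newick = newick)
}
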