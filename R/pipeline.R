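#' Run the full synthetic-data analysis pipeline
#'
#' End-to-end driver: simulates a control cohort plus attenuated disease
#' cohorts, writes the raw input files (trace CSV, PG-matrix TSV, annotation
#' CSV), then runs every analysis stage off those files — decay fitting, QC,
#' fibre typing, pseudo-bulk differential abundance (subtype, SRX-cluster,
#' disease contrasts), SRX-proteome correlation with profile clustering, and
#' the divergence-shrinkage report — writing one TSV per stage. Fully
#' deterministic given `seed`.
#'
#' @param out_dir output directory (created if needed).
#' @param seed master integer seed.
#' @param truth control-cohort [synthetic_truth()] parameters.
#' @param lambda disease attenuation of subtype effects.
#' @param k_mad PCA outlier threshold.
#' @param pure_threshold fibre-typing pure-call threshold.
#' @param min_n_all,min_n_subtype correlation presence floors.
#' @param alpha composite significance level.
#' @param n_control_disease_phase number of control participants reused in
#'   the disease-phase contrasts.
#' @return Invisibly, a list with the main in-memory results (`fits`, `qc`,
#'   `types`, `diffabund`, `correlations`, `shrinkage`, `srx_anova`,
#'   `files`).
#' @export
run_pipeline <- function(out_dir, seed = 1, truth = synthetic_truth(),
                         lambda = 0.3, k_mad = 5, pure_threshold = 0.7,
                         min_n_all = 22, min_n_subtype = 10, alpha = 0.05,
                         n_control_disease_phase = 3) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(out_dir, f)

  ## --- simulate ------------------------------------------------------------
  cohort <- simulate_cohort(truth, seed = seed)
  universe <- cohort$protein_truth
  srx_sim <- simulate_srx(cohort, seed = seed)
  disease <- simulate_disease(universe, truth, seed = seed, lambda = lambda)
  dis_srx <- lapply(disease, simulate_srx, seed = seed)

  all_cohorts <- c(list(control = cohort), disease)
  all_srx <- c(srx_sim$srx, dis_srx$acta1$srx, dis_srx$tnnt1$srx)
  params <- decay_params_from_srx(all_srx, truth, seed = seed)
  sim_tr <- simulate_traces(params, grid = mant_timegrid(),
                            sigma = truth$trace_sigma, seed = seed)
  write_traces(sim_tr$traces, path("traces.csv"))
  write_tsv(sim_tr$truth, path("truth_decay.tsv"))

  pm_all <- combine_matrices(cohort$pm, disease$acta1$pm, disease$tnnt1$pm)
  pg <- data.frame(Protein.Group = rownames(pm_all$values),
                   Genes = unname(pm_all$genes),
                   round(2^pm_all$values, 4), check.names = FALSE)
  write_tsv(pg, path("pg_matrix.tsv"))
  utils::write.csv(pm_all$annotations, path("annotations.csv"),
                   row.names = FALSE, quote = FALSE)
  write_tsv(do.call(rbind, lapply(all_cohorts, function(co) co$fibre_truth)),
            path("truth_fibres.tsv"))
  write_tsv(universe, path("truth_proteins.tsv"))

  ## --- decay fitting -------------------------------------------------------
  traces <- read_traces(path("traces.csv"))
  fits <- fit_decay_traces(traces)
  write_tsv(fits, path("decay_fits.tsv"))
  srx_hat <- stats::setNames(fits$srx_pct, fits$fibre_id)

  ## --- proteome QC ---------------------------------------------------------
  pm <- log2_transform(read_pg_matrix(path("pg_matrix.tsv"),
                                      path("annotations.csv")))
  qc <- tryCatch(pca_outliers(pm, k_mad = k_mad), error = function(e) {
    # no protein complete across every fibre (possible under heavy dropout):
    # QC proceeds on counts alone with no outlier removal
    message("PCA outlier screen skipped: ", conditionMessage(e))
    counts <- protein_counts(pm)$counts
    structure(list(counts = counts,
                   pca = data.frame(fibre_id = colnames(pm$values),
                                    pc1 = NA_real_, pc2 = NA_real_,
                                    dist_mad = NA_real_, outlier = FALSE),
                   outliers = character()), class = "qc_report")
  })
  write_tsv(cbind(qc$pca, n_proteins = unname(qc$counts[qc$pca$fibre_id])),
            path("qc.tsv"))
  keep <- setdiff(colnames(pm$values), qc$outliers)
  pm <- subset_matrix(pm, fibres = keep)

  ## --- fibre typing --------------------------------------------------------
  types <- fibre_types(pm, pure_threshold = pure_threshold)
  write_tsv(types, path("fibre_types.tsv"))

  ann <- pm$annotations
  cond_of <- stats::setNames(pm_all$annotations$condition,
                             pm_all$annotations$fibre_id)
  label_of <- stats::setNames(types$label, types$fibre_id)
  ctrl_fibres <- ann$fibre_id[ann$condition == "control"]
  disease_phase_parts <- utils::tail(truth$participants, n_control_disease_phase)

  grp <- function(fibres, want_label, name) {
    g <- stats::setNames(rep(NA_character_, length(fibres)), fibres)
    g[label_of[fibres] %in% want_label] <- name
    g
  }

  ## --- differential abundance ----------------------------------------------
  da <- list()
  # control type I vs type IIa, paired by participant, full control cohort
  g_ctrl <- c(grp(ctrl_fibres, "I", "typeI"), grp(ctrl_fibres, "IIa", "typeIIa"))
  g_ctrl <- g_ctrl[!is.na(g_ctrl)]
  da$control_typeI_vs_typeIIa <-
    diffabund_contrast(pm, g_ctrl, c("typeI", "typeIIa"), paired = TRUE,
                       alpha = alpha)
  # SRX high vs low clusters within control fibres
  da$srx_high_vs_low <-
    srx_cluster_contrast(subset_matrix(pm, fibres = intersect(ctrl_fibres,
                                                              names(srx_hat))),
                         srx_hat, alpha = alpha)
  # disease-phase contrasts (subset of control participants)
  ctrl_sub <- ann$fibre_id[ann$condition == "control" &
                             ann$participant %in% disease_phase_parts]
  acta1_fibres <- ann$fibre_id[ann$condition == "ACTA1"]
  tnnt1_fibres <- ann$fibre_id[ann$condition == "TNNT1"]
  g <- c(grp(acta1_fibres, "I", "ACTA1_I"), grp(ctrl_sub, "I", "control_I"))
  da$ACTA1_I_vs_control_I <-
    diffabund_contrast(pm, g[!is.na(g)], c("ACTA1_I", "control_I"),
                       alpha = alpha)
  g <- c(grp(tnnt1_fibres, "IIa", "TNNT1_IIa"), grp(ctrl_sub, "IIa", "control_IIa"))
  da$TNNT1_IIa_vs_control_IIa <-
    diffabund_contrast(pm, g[!is.na(g)], c("TNNT1_IIa", "control_IIa"),
                       alpha = alpha)
  g <- c(grp(ctrl_sub, "I", "typeI"), grp(ctrl_sub, "IIa", "typeIIa"))
  da$control3_typeI_vs_typeIIa <-
    diffabund_contrast(pm, g[!is.na(g)], c("typeI", "typeIIa"), paired = TRUE,
                       alpha = alpha)
  g <- c(grp(acta1_fibres, "I", "ACTA1_I"), grp(tnnt1_fibres, "IIa", "TNNT1_IIa"))
  da$ACTA1_I_vs_TNNT1_IIa <-
    diffabund_contrast(pm, g[!is.na(g)], c("ACTA1_I", "TNNT1_IIa"),
                       alpha = alpha)
  for (nm in names(da))
    write_tsv(as.data.frame(da[[nm]]), path(sprintf("diffabund_%s.tsv", nm)))

  ## --- SRX ~ proteome correlation ------------------------------------------
  pm_ctrl <- subset_matrix(pm, fibres = ctrl_fibres)
  filtered <- filter_dual(pm_ctrl, srx_hat, outliers = qc$outliers,
                          min_n_all = min_n_all)
  corr <- list(all = correlate_srx(filtered, srx_hat, scope = "all",
                                   alpha = alpha))
  corr$typeI <- correlate_srx(filtered, srx_hat, types = types,
                              scope = "typeI", min_n_subtype = min_n_subtype,
                              alpha = alpha)
  corr$typeIIa <- correlate_srx(filtered, srx_hat, types = types,
                                scope = "typeIIa", min_n_subtype = min_n_subtype,
                                alpha = alpha)
  write_tsv(do.call(rbind, lapply(corr, as.data.frame)),
            path("srx_correlations.tsv"))
  clus <- tryCatch(cluster_srx_profiles(corr$typeI, corr$typeIIa, k = 2),
                   error = function(e) NULL)
  if (!is.null(clus)) {
    write_tsv(clus$profiles, path("srx_profile_clusters.tsv"))
    writeLines(clus$newick, path("srx_profile_dendrogram.nwk"))
  }

  ## --- divergence shrinkage ------------------------------------------------
  shrink <- partition_maintained(da$control3_typeI_vs_typeIIa,
                                 da$ACTA1_I_vs_TNNT1_IIa, alpha = alpha)
  write_tsv(cbind(shrink$fc_pairs,
                  maintained = shrink$fc_pairs$protein %in% shrink$maintained),
            path("shrinkage.tsv"))

  ## --- SRX homogenisation across conditions --------------------------------
  srx_by_cond <- split(unname(srx_hat), cond_of[names(srx_hat)])
  srx_anova <- anova_tukey(srx_by_cond)
  write_tsv(data.frame(condition = names(srx_by_cond),
                       n = lengths(srx_by_cond),
                       mean_srx = vapply(srx_by_cond, mean, 1),
                       sd_srx = vapply(srx_by_cond, stats::sd, 1),
                       anova_F = srx_anova$F, anova_p = srx_anova$p),
            path("srx_by_condition.tsv"))

  invisible(list(fits = fits, qc = qc, types = types, diffabund = da,
                 correlations = corr, clusters = clus, shrinkage = shrink,
                 srx_anova = srx_anova,
                 files = list.files(out_dir, full.names = FALSE)))
}
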