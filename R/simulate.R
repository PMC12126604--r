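# Synthetic-data generator with known ground truth.
# Emulates the cohorts the pipeline consumes: MANT-ATP decay traces on the
# acquisition grid, fibre-level log2 LFQ matrices with participant effects,
# MYH-driven subtypes, subtype-specific effects, abundance-dependent dropout,
# protein-coupled SRX values, and attenuated disease cohorts.

#' Ground-truth parameter set for the synthetic cohort generator
#'
#' Defaults describe a healthy control cohort: 8 participants with 9 dual
#' (SRX + proteome) fibres each, a 1500-protein universe detected at roughly
#' 780 proteins per fibre, a broad SRX spread (mean 54.5, SD 32 percent), and
#' 150 proteins with genuine type I vs type IIa effects.
#'
#' @param condition condition label for the cohort.
#' @param n_proteins size of the protein universe (includes the 3 MYH rows).
#' @param participants participant ids.
#' @param fibres_per_participant dual fibres per participant.
#' @param composition named subtype probabilities (`I`, `I/IIa`, `IIa`, and
#'   optionally `IIa/IIx`, `IIx`).
#' @param mu_mean,mu_sd mean and SD of protein baseline log2 LFQ `mu_p`.
#' @param tau_range per-protein measurement SD `tau_p` drawn uniformly from
#'   this range (log2 units).
#' @param participant_sd SD of the additive participant random effect
#'   (log2 units, independent per protein and participant).
#' @param n_effect number of proteins with a true type I vs type IIa effect.
#' @param delta_range magnitude range of the subtype effect `delta_p`
#'   (log2 units; half the effects are up in type I, half up in type IIa).
#' @param n_disease_module number of proteins in the shared disease module
#'   (down-regulated in every disease condition).
#' @param gamma_range magnitude range of the (negative) disease-module
#'   effect (log2 units).
#' @param dropout_midpoint,dropout_slope logistic detection model: an entry
#'   of value `v` is observed with probability
#'   `plogis((v - midpoint + fibre_shift) / slope)`.
#' @param fibre_quality_sd SD of the per-fibre detection shift (log2 units),
#'   emulating fibre-to-fibre differences in recovered material.
#' @param myh_fractions named list of MYH7/MYH2/MYH1 mixture fractions per
#'   subtype.
#' @param myh_log2_total log2 of the summed MYH raw intensity.
#' @param myh_noise_sd per-isoform log2 measurement SD.
#' @param srx_base,srx_sd mean and SD of the SRX percentage distribution.
#' @param couplings data frame (`protein`, `scope`, `beta`) of SRX-protein
#'   coupling weights on the standardised scale; scope is one of `all`,
#'   `typeI`, `typeIIa`. `NULL` installs a small default set (created after
#'   the universe is drawn).
#' @param t1_range,t2_range ranges of the fast and slow decay time constants
#'   (s) per fibre.
#' @param trace_sigma Gaussian frame noise SD for simulated traces.
#' @return A `synthetic_truth` parameter list.
#' @export
synthetic_truth <- function(condition = "control",
                            n_proteins = 1500,
                            participants = sprintf("C%d", 1:8),
                            fibres_per_participant = 9,
                            composition = c(I = 0.40, `I/IIa` = 0.15, IIa = 0.45),
                            mu_mean = 12, mu_sd = 2.2,
                            tau_range = c(0.35, 0.65),
                            participant_sd = 0.3,
                            n_effect = 150,
                            delta_range = c(0.8, 2.0),
                            n_disease_module = 60,
                            gamma_range = c(0.6, 1.5),
                            dropout_midpoint = 11.8, dropout_slope = 1.5,
                            fibre_quality_sd = 1.5,
                            myh_fractions = list(
                              I = c(0.92, 0.06, 0.02),
                              `I/IIa` = c(0.48, 0.48, 0.04),
                              IIa = c(0.03, 0.92, 0.05),
                              `IIa/IIx` = c(0.02, 0.56, 0.42),
                              IIx = c(0.02, 0.08, 0.90)),
                            myh_log2_total = 17, myh_noise_sd = 0.25,
                            srx_base = 54.5, srx_sd = 32,
                            couplings = NULL,
                            t1_range = c(1.5, 4), t2_range = c(100, 200),
                            trace_sigma = 0.02) {
  if (any(composition < 0) || abs(sum(composition) - 1) > 1e-9)
    stop_invalid("composition must be nonnegative and sum to 1")
  if (tau_range[1] < 0 || participant_sd < 0 || myh_noise_sd < 0 ||
      srx_sd < 0 || trace_sigma < 0)
    stop_invalid("all SDs must be nonnegative")
  structure(as.list(environment()), class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> '%s': %d participants x %d fibres, %d proteins (%d with effects)\n",
              x$condition, length(x$participants), x$fibres_per_participant,
              x$n_proteins, x$n_effect))
  cat(sprintf("SRX %.1f +/- %.1f%%; detection midpoint %.1f (log2)\n",
              x$srx_base, x$srx_sd, x$dropout_midpoint))
  invisible(x)
}

#' Draw the protein universe shared by control and disease cohorts
#'
#' Assigns baselines, per-protein noise SDs, effect-set membership with
#' subtype effect sizes, disease-module membership, and the three MYH
#' isoform rows. Reusing the returned table across cohorts keeps the
#' universe (and hence contrast comparability) fixed.
#'
#' @param truth a [synthetic_truth()] parameter set.
#' @param seed integer seed.
#' @return Data frame (`protein_truth`): `protein`, `gene`, `mu`, `tau`,
#'   `delta` (signed type I minus type IIa effect; 0 outside the effect set),
#'   `in_effect_set`, `gamma` (signed disease-module effect; 0 outside),
#'   `is_myh`.
#' @export
protein_universe <- function(truth, seed = 1) {
  with_seed(seed, {
    n <- truth$n_proteins
    ids <- sprintf("PG%04d", seq_len(n))
    genes <- sprintf("GENE%04d", seq_len(n))
    myh_rows <- (n - 2):n
    genes[myh_rows] <- c("MYH7", "MYH2", "MYH1")
    mu <- stats::rnorm(n, truth$mu_mean, truth$mu_sd)
    mu[myh_rows] <- NA  # MYH rows follow the subtype mixture model instead
    tau <- stats::runif(n, truth$tau_range[1], truth$tau_range[2])
    ordinary <- setdiff(seq_len(n), myh_rows)
    n_eff <- min(truth$n_effect, length(ordinary))
    eff <- sort(sample(ordinary, n_eff))
    delta <- numeric(n)
    magn <- stats::runif(n_eff, truth$delta_range[1], truth$delta_range[2])
    sgn <- rep(c(1, -1), length.out = n_eff)
    delta[eff] <- magn * sgn
    n_mod <- min(truth$n_disease_module, length(ordinary) - n_eff)
    mod <- sort(sample(setdiff(ordinary, eff), n_mod))
    gamma <- numeric(n)
    gamma[mod] <- -stats::runif(n_mod, truth$gamma_range[1],
                                truth$gamma_range[2])
    data.frame(protein = ids, gene = genes, mu = mu, tau = tau,
               delta = delta, in_effect_set = seq_len(n) %in% eff,
               gamma = gamma, is_myh = seq_len(n) %in% myh_rows,
               stringsAsFactors = FALSE)
  })
}

# default SRX-protein couplings: a small metabolic block positively coupled
# in every fibre plus one SGCD-like protein with divergent subtype coupling
default_couplings <- function(universe) {
  ord <- universe[!universe$is_myh, ]
  eff_up_I <- utils::head(ord$protein[ord$delta > 0], 6)
  if (!length(eff_up_I)) eff_up_I <- utils::head(ord$protein, 6)
  neutral <- ord$protein[ord$delta == 0]
  sgcd_like <- if (length(neutral)) neutral[1]
               else ord$protein[order(abs(ord$delta))][1]
  rbind(
    data.frame(protein = eff_up_I, scope = "all", beta = 0.18),
    data.frame(protein = sgcd_like, scope = "typeI", beta = 0.5),
    data.frame(protein = sgcd_like, scope = "typeIIa", beta = -0.5))
}

subtype_score <- function(label) {
  # signed weight turning delta into the type I minus type IIa difference
  c(I = 0.5, `I/IIa` = 0, IIa = -0.5, `IIa/IIx` = -0.5, IIx = -0.5)[label]
}

#' Simulate a single-fibre proteome cohort with known truth
#'
#' Log2 value of protein p in fibre f:
#' `mu_p + u_{participant(f), p} + delta_p * s(subtype(f)) + disease_scale *
#' gamma_p + N(0, tau_p)`, where `s` is +1/2 for type I, -1/2 for type IIa
#' (and faster types) and 0 for hybrids. MYH7/MYH2/MYH1 rows are generated
#' from subtype-specific mixture fractions of a common raw total. Each entry
#' is then observed with logistic abundance-dependent probability (plus a
#' per-fibre detection shift), emulating label-free dropout.
#'
#' @param truth a [synthetic_truth()] parameter set.
#' @param seed integer seed (full determinism, including dropout masks).
#' @param universe optional [protein_universe()] table to reuse; drawn from
#'   `seed` when `NULL`.
#' @param effect_scale multiplier on every `delta_p` (the disease
#'   attenuation lambda when generating disease cohorts).
#' @param disease_scale multiplier on the shared disease-module effect
#'   `gamma_p` (0 for control cohorts, 1 for disease).
#' @param sign_flip protein ids whose effect direction is inverted in this
#'   cohort (MYBPC2-like cases).
#' @return A `synthetic_cohort` list: `pm` (log2 `protein_matrix` with
#'   dropout), `complete_values` (pre-dropout matrix), `fibre_truth`
#'   (`fibre_id`, `participant`, `condition`, `subtype`), `protein_truth`
#'   (with the cohort's effective `delta_used`), and `truth` (the parameter
#'   set).
#' @export
simulate_cohort <- function(truth = synthetic_truth(), seed = 1,
                            universe = NULL, effect_scale = 1,
                            disease_scale = 0, sign_flip = character()) {
  if (length(truth$participants) < 2L)
    stop_invalid("need at least 2 participants")
  if (length(truth$composition) < 2L)
    stop_invalid("need at least 2 subtypes in the composition")
  if (is.null(universe)) universe <- protein_universe(truth, seed = seed)
  delta_used <- universe$delta * effect_scale
  flip <- universe$protein %in% sign_flip
  delta_used[flip] <- -delta_used[flip]

  with_seed(sub_seed(seed, 1), {
    parts <- truth$participants
    fibres <- data.frame(
      fibre_id = sprintf("%s_f%02d",
                         rep(parts, each = truth$fibres_per_participant),
                         seq_len(truth$fibres_per_participant)),
      participant = rep(parts, each = truth$fibres_per_participant),
      condition = truth$condition, stringsAsFactors = FALSE)
    nf <- nrow(fibres)
    fibres$subtype <- sample(names(truth$composition), nf, replace = TRUE,
                             prob = truth$composition)
    np <- nrow(universe)
    ordinary <- which(!universe$is_myh)
    # participant random effects: independent per protein x participant
    u <- matrix(stats::rnorm(np * length(parts), 0, truth$participant_sd),
                np, length(parts), dimnames = list(universe$protein, parts))
    s <- subtype_score(fibres$subtype)
    vals <- matrix(NA_real_, np, nf,
                   dimnames = list(universe$protein, fibres$fibre_id))
    base <- universe$mu + disease_scale * universe$gamma
    for (j in seq_len(nf)) {
      vals[ordinary, j] <- base[ordinary] +
        u[ordinary, fibres$participant[j]] +
        delta_used[ordinary] * s[j] +
        stats::rnorm(length(ordinary), 0, universe$tau[ordinary])
    }
    # MYH rows from subtype mixture fractions of a common raw total
    myh_rows <- which(universe$is_myh)  # order: MYH7, MYH2, MYH1
    for (j in seq_len(nf)) {
      frac <- truth$myh_fractions[[fibres$subtype[j]]]
      vals[myh_rows, j] <- truth$myh_log2_total + log2(frac) +
        stats::rnorm(3, 0, truth$myh_noise_sd)
    }
    # abundance-dependent logistic dropout with a per-fibre quality shift
    shift <- stats::rnorm(nf, 0, truth$fibre_quality_sd)
    pdet <- stats::plogis(sweep(vals - truth$dropout_midpoint, 2, -shift) /
                            truth$dropout_slope)
    observed <- matrix(stats::runif(np * nf) < pdet, np, nf)
    obs_vals <- vals
    obs_vals[!observed] <- NA

    pm <- protein_matrix(obs_vals,
                         fibres[, c("fibre_id", "participant", "condition")],
                         genes = universe$gene, log2 = TRUE)
    universe$delta_used <- delta_used
    structure(list(pm = pm, complete_values = vals, fibre_truth = fibres,
                   protein_truth = universe, truth = truth),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> '%s': ", x$truth$condition))
  print(x$pm)
  invisible(x)
}

#' Simulate protein-coupled SRX percentages for a cohort
#'
#' `srx_pct = clip(base + srx_sd * eta, 0, 100)` with
#' `eta = sum_p beta_{p, scope(fibre)} * z_p(fibre) + N(0, noise_sd)`, where
#' `z_p` is the fibre's standardised (pre-dropout) log2 abundance of protein
#' p, and scope-specific weights (`typeI`, `typeIIa`) add to the `all`
#' weights, enabling divergent couplings. `noise_sd` defaults to the
#' complement `sqrt(max(0, 1 - sum(beta^2)))` so that eta has roughly unit
#' variance. DRX is emitted as `100 - SRX`.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param seed integer seed.
#' @param couplings coupling table (`protein`, `scope`, `beta`); defaults to
#'   the truth's table or, failing that, [default_couplings] on the cohort's
#'   universe.
#' @param base,sd SRX mean and SD (percent); default from the truth.
#' @param noise_sd residual SD of eta (standardised scale).
#' @return List with `srx` and `drx` (named vectors by fibre id), `couplings`
#'   (the table used) and `noise_sd`.
#' @export
simulate_srx <- function(cohort, seed = 1, couplings = NULL,
                         base = NULL, sd = NULL, noise_sd = NULL) {
  truth <- cohort$truth
  couplings <- couplings %||% truth$couplings %||%
    default_couplings(cohort$protein_truth)
  base <- base %||% truth$srx_base
  sd <- sd %||% truth$srx_sd
  bad <- setdiff(couplings$protein, rownames(cohort$complete_values))
  if (length(bad))
    stop_invalid("coupling proteins not in the universe: %s",
                 paste(bad, collapse = ", "))
  if (is.null(noise_sd)) {
    # complement per fibre scope; use the largest total loading for safety
    load2 <- max(vapply(c("typeI", "typeIIa"), function(sc) {
      sum(couplings$beta[couplings$scope %in% c("all", sc)]^2)
    }, 1))
    noise_sd <- sqrt(max(0, 1 - load2))
  }
  if (noise_sd < 0) stop_invalid("noise_sd must be nonnegative")
  z <- t(scale(t(cohort$complete_values[unique(couplings$protein), ,
                                        drop = FALSE])))
  scope_of <- c(I = "typeI", IIa = "typeIIa")[cohort$fibre_truth$subtype]
  with_seed(sub_seed(seed, 2), {
    eta <- vapply(seq_len(ncol(z)), function(j) {
      sc <- scope_of[j]
      keep <- couplings$scope == "all" |
        (!is.na(sc) & couplings$scope == sc)
      sum(couplings$beta[keep] * z[couplings$protein[keep], j])
    }, 1)
    eta <- eta + stats::rnorm(length(eta), 0, noise_sd)
    srx <- pmin(100, pmax(0, base + sd * eta))
    names(srx) <- colnames(z)
    list(srx = srx, drx = 100 - srx, couplings = couplings,
         noise_sd = noise_sd)
  })
}

#' Simulate MANT-ATP chase traces from known decay parameters
#'
#' Normalised fluorescence is the double-exponential model plus i.i.d.
#' Gaussian frame noise, re-anchored so frame 0 equals 1. Raw ROI and
#' background frames are synthesised consistently (three ROI series whose
#' background-subtracted mean reproduces the normalised trace exactly).
#'
#' @param params data frame with `fibre_id`, `P1`, `T1`, `P2`, `T2`.
#' @param grid acquisition time grid (s), e.g. [mant_timegrid()].
#' @param sigma Gaussian frame noise SD (unitless fluorescence).
#' @param seed integer seed.
#' @param t0_signal,background raw-scale signal at time 0 and constant
#'   background level used to synthesise ROI frames.
#' @return List with `traces` (named list of [decay_trace] objects carrying
#'   raw ROI/background frames) and `truth` (the parameter table with
#'   `sigma`).
#' @export
simulate_traces <- function(params, grid = mant_timegrid(), sigma = 0.02,
                            seed = 1, t0_signal = 1000, background = 100) {
  if (sigma < 0) stop_invalid("sigma must be nonnegative")
  need <- c("fibre_id", "P1", "T1", "P2", "T2")
  if (!all(need %in% names(params)))
    stop_invalid("params must have columns %s", paste(need, collapse = ", "))
  check_times(grid)
  with_seed(sub_seed(seed, 3), {
    traces <- lapply(seq_len(nrow(params)), function(i) {
      p <- params[i, ]
      y <- decay_model(grid, c(P1 = p$P1, T1 = p$T1, P2 = p$P2, T2 = p$T2))
      if (sigma > 0) y <- y + stats::rnorm(length(grid), 0, sigma)
      y <- y / y[1]  # re-anchor so frame 0 is exactly 1
      # three ROI series with zero-mean jitter so the ROI mean is exact
      d1 <- stats::rnorm(length(grid), 0, 2)
      d2 <- stats::rnorm(length(grid), 0, 2)
      signal <- background + y * t0_signal
      roi <- cbind(signal + d1, signal + d2, signal - d1 - d2)
      normalise_trace(roi, rep(background, length(grid)), grid,
                      fibre_id = p$fibre_id)
    })
    names(traces) <- params$fibre_id
    truth <- params[, need]
    truth$sigma <- sigma
    list(traces = traces, truth = truth)
  })
}

#' Decay parameters consistent with target SRX percentages
#'
#' Builds a per-fibre decay parameter table with `P2 = srx/100` and the
#' amplitude sum constrained to one (`P1 = 1 - P2`), so DRX = 100 - SRX
#' exactly; time constants are drawn uniformly from the truth's ranges.
#'
#' @param srx named vector of SRX percentages by fibre id.
#' @param truth a [synthetic_truth()] parameter set (time-constant ranges).
#' @param seed integer seed.
#' @return Data frame `fibre_id`, `P1`, `T1`, `P2`, `T2`.
#' @export
decay_params_from_srx <- function(srx, truth = synthetic_truth(), seed = 1) {
  with_seed(sub_seed(seed, 4), {
    n <- length(srx)
    data.frame(fibre_id = names(srx),
               P1 = 1 - srx / 100,
               T1 = stats::runif(n, truth$t1_range[1], truth$t1_range[2]),
               P2 = srx / 100,
               T2 = stats::runif(n, truth$t2_range[1], truth$t2_range[2]),
               stringsAsFactors = FALSE)
  })
}

#' Simulate attenuated disease cohorts sharing the control universe
#'
#' Generates ACTA1-like (type-I-enriched) and TNNT1-like (type-IIa-enriched)
#' cohorts on the same protein universe as a control cohort, with every
#' subtype effect scaled by `lambda` (optionally sign-flipped for listed
#' proteins), the shared disease module switched on, and the SRX distribution
#' homogenised: shifted by `srx_shift` and its spread scaled by `srx_scale`.
#' Defaults emulate the observed disease regimes: SRX 38.4 +/- 8.6 percent
#' (ACTA1-like) and 33.0 +/- 14.8 (TNNT1-like) against a 54.5 +/- 32 control.
#'
#' @param universe [protein_universe()] table of the control cohort.
#' @param control_truth the control [synthetic_truth()] parameter set.
#' @param seed integer seed.
#' @param lambda attenuation of subtype effects, in `[0, 1]`.
#' @param sign_flip protein ids whose subtype effect flips direction in
#'   disease.
#' @param participants_per_condition participant ids per condition.
#' @param fibres_per_participant dual fibres per disease participant.
#' @param acta1_composition,tnnt1_composition subtype composition skews.
#' @param srx_shift,srx_scale named per-condition SRX mean shift (percent)
#'   and SD scale relative to the control regime.
#' @param disease_scale multiplier on the shared disease module (default 1).
#' @return List of two `synthetic_cohort` objects (`acta1`, `tnnt1`), each
#'   with its own truth tables.
#' @export
simulate_disease <- function(universe, control_truth = synthetic_truth(),
                             seed = 1, lambda = 0.3,
                             sign_flip = character(),
                             participants_per_condition = list(
                               ACTA1 = sprintf("NM%d", 1:3),
                               TNNT1 = sprintf("NM%d", 4:6)),
                             fibres_per_participant = 6,
                             acta1_composition = c(I = 0.75, `I/IIa` = 0.15, IIa = 0.10),
                             tnnt1_composition = c(I = 0.10, `I/IIa` = 0.25, IIa = 0.65),
                             srx_shift = c(ACTA1 = 38.4 - 54.5, TNNT1 = 33.0 - 54.5),
                             srx_scale = c(ACTA1 = 8.6 / 32, TNNT1 = 14.8 / 32),
                             disease_scale = 1) {
  if (!is.numeric(lambda) || lambda < 0 || lambda > 1)
    stop_invalid("lambda must lie in [0, 1]")
  make <- function(cond, comp, off) {
    tr <- control_truth
    tr$condition <- cond
    tr$participants <- participants_per_condition[[cond]]
    tr$fibres_per_participant <- fibres_per_participant
    tr$composition <- comp
    tr$srx_base <- control_truth$srx_base + srx_shift[[cond]]
    tr$srx_sd <- control_truth$srx_sd * srx_scale[[cond]]
    simulate_cohort(tr, seed = sub_seed(seed, off), universe = universe,
                    effect_scale = lambda, disease_scale = disease_scale,
                    sign_flip = sign_flip)
  }
  list(acta1 = make("ACTA1", acta1_composition, 10),
       tnnt1 = make("TNNT1", tnnt1_composition, 11))
}
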