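---
title: "Single-fibre myosin state and proteome co-profiling: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-fibre myosin state and proteome co-profiling: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myosrx)
```

This vignette is the package's account of its science: the models it fits,
the parameters that matter, the numerical choices behind them, what the
synthetic-data generator does and does not emulate, and the limitations a
user should keep in mind.

## The decay model and its identifiability

A MANT-ATP chase reports nucleotide turnover of myosin heads. After
background subtraction, ROI averaging and anchoring at the first chase
frame, normalised fluorescence is modelled as

$$f(t) = 1 - P_1\,(1 - e^{-t/T_1}) - P_2\,(1 - e^{-t/T_2}), \qquad T_1 \le T_2 .$$

The fast amplitude $P_1$ (time constant $T_1$, seconds, typically a few
seconds) is interpreted as the DRX fraction; the slow amplitude $P_2$
($T_2$, typically 1–5 minutes) as the SRX fraction. Reported percentages
are simply $100\,P_1$ and $100\,P_2$: the fit is *unconstrained*, so the
amplitudes may exceed $[0,1]$ and are not renormalised to sum to one —
`drx_pct + srx_pct` equals $100(P_1+P_2)$, not necessarily 100. The
components are always relabelled so that $T_1 \le T_2$, which is what makes
"$P_1$ = fast = DRX" well defined.

**Defaults.** Starting values $(P_1, T_1, P_2, T_2) = (0.5,\,2\,\mathrm{s},\,
0.5,\,150\,\mathrm{s})$ reflect typical fast/slow relaxed-state time scales;
time constants are bounded to $(10^{-3}, 10^5)$ s purely for solver
stability. Both are configurable. The default acquisition grid images every
5 s to 90 s and every 10 s to 390 s (49 frames); the total duration is
configurable because "five further minutes" versus "five minutes total" is
an ambiguity of such protocols — we take the longer reading, and nothing
downstream depends on it.

**The two ridges.** With 4 free parameters the model is unidentifiable in
two regimes that matter in practice. When the true $P_2 \approx 0$ the slow
component is free to mimic a linear drift ($T_2 \to \infty$ with
$P_2/T_2$ fixed) or to cancel against the fast component
($T_1 \to T_2$ with large opposite amplitudes); either can beat the honest
optimum by a noise-level margin of residual sum of squares while reporting
absurd SRX percentages. `fit_decay()` therefore fits from several
deterministic starts plus (a) the same objective with time constants
confined to the *identifiable window* — no faster than a fifth of the first
frame interval, no slower than five acquisition spans, and separated by at
least a factor 2 — and (b) a nested single-exponential fit whose phantom
second amplitude is pinned to exactly zero. Among all candidates whose RSS
lies inside the optimum's 99% joint confidence region (F-based tolerance),
the best *resolvable* fit is reported; an unresolvable fit wins only when it
is decisively better. On noiseless traces this procedure recovers parameters
to machine precision (tested to $10^{-6}$ over a $5^4$ truth grid), and on
noisy traces it removes the wild amplitude excursions while leaving the
maximum-likelihood answer untouched whenever it is identifiable.

**SRX clusters.** Fibres are grouped by fitted SRX%: low ($\le 35$), high
($\ge 65$), otherwise mid. Both boundaries are inclusive, exactly as the
thresholds are written.

## Proteome QC

The DIA PG matrix is parsed with blank *and zero* intensities treated as
"not quantified" (label-free convention: a zero is absence of evidence, not
a measured zero). PCA for outlier screening runs on the complete-case
protein submatrix — the only deterministic reading of "PCA omitting missing
values" that needs no imputation (imputation is deliberately out of scope).
Because "outlier by visual inspection" is not reproducible, we substitute an
explicit rule: a fibre is flagged when its distance from the componentwise
median in the PC1–PC2 plane exceeds `k_mad` (default 5) median absolute
deviations of those distances. Under heavy dropout a cohort may have no
protein complete across every fibre; `pca_outliers()` then refuses, and
`run_pipeline()` degrades gracefully to count-based QC with no outlier
removal.

## Fibre typing

Each fibre's raw-scale (back-transformed) LFQ of MYH7, MYH2 and MYH1 is
converted to relative fractions; a missing isoform contributes zero. If the
dominant fraction reaches `pure_threshold` (default 0.7) the fibre is called
pure (I, IIa or IIx); otherwise it takes the hybrid label of its top two
isoforms in canonical order (I/IIa, IIa/IIx). The non-adjacent combination
(MYH7 + MYH1 dominant) is labelled I/IIx and reported, since it usually
indicates a data problem. The 0.7 default reproduces the three classes seen
in healthy human cohorts (I, I/IIa, IIa, with no pure IIx) on realistic
mixtures; `fibre_type_sweep()` exposes the sensitivity to this choice.

A margin note: with independent per-isoform log2 measurement noise
$\sigma$, a pure fibre generated at dominant fraction $d$ is miscalled when
the noise moves its realised fraction below the threshold. At
$\sigma = 0.3$ and $d = 0.8$ that margin is only about 2.5 standard
deviations, so "100% accuracy" is a statement about comfortable margins, not
a theorem at the boundary. The generator's default `myh_noise_sd = 0.25`
reflects single-fibre MYH quantification repeatability, and the package's
accuracy tests run at that default.

## Pseudo-bulk differential abundance

Single fibres from one participant are not independent replicates. All
contrasts therefore aggregate to one **median** log2 LFQ per protein per
(participant, group) cell before testing; medians are taken on the log2
scale, the scale on which the data are analysed. Hybrid fibres are excluded
from pure-subtype contrasts but kept in composition summaries.

Cells are then quantile normalised. The reference distribution is built
from complete rows (cross-column means of sorted values; afterwards all
columns share one multiset over those rows, with ties receiving the mean of
their target quantiles); entries in rows with missing cells are mapped by
interpolating the reference at the value's rank within its column — a rule
that preserves within-column rank order everywhere.

The two-group fit uses empirical-Bayes variance moderation: per protein a
pooled (unpaired) or participant-blocked (paired) variance $s_g^2$ on
$d_g$ degrees of freedom, a prior $(d_0, s_0^2)$ estimated from the log
sample variances by method of moments (with the standard trigamma-inverse
solve), posterior variance
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$, and
$t = \mathrm{log_2FC} / (\tilde s_g \sqrt{v_g})$ on $d_0 + d_g$ degrees of
freedom. Two degenerate cases are handled explicitly: when all sample
variances are identical the common value *is* the prior (the log-scale bias
correction assumes chi-square sampling noise that is manifestly absent),
and with fewer than 5 usable proteins the fit falls back to ordinary t with
a message. The control type I ∼ type IIa contrast is paired by participant;
disease-versus-control contrasts are unpaired, matching the cohort
structure. The SRX contrast aggregates per (participant, SRX cluster) and
keeps only participants containing both clusters, fitted paired.

Significance is the composite π-value $\pi = p^{|\mathrm{log_2FC}|}$
(equivalently $10^{-s}$ with $s = |\mathrm{log_2FC}|\cdot(-\log_{10} p)$),
called strictly below 0.05 and left **unadjusted** for multiple testing.
That is a deliberate screening choice for small dual-assay cohorts — it
finds patterns, it does not confirm biology — and no correction is offered
because offering one would misrepresent what these lists are for.

## Same-fibre SRX ∼ proteome correlation

Fibres must carry both a decay fit and a proteome column ("dual" data);
outliers are removed and proteins must be present in at least 22 dual
fibres (at least 10 per subtype for subtype-scoped analyses). Correlations
are Spearman with average ranks; p-values come from full permutation
enumeration for $n \le 9$ and the t-approximation otherwise, two-sided,
unadjusted. DRX correlations are emitted alongside (with DRX $= 100 -$ SRX
they are exact sign flips). Proteins significant in at least one subtype
have their $(\rho_{\mathrm{I}}, \rho_{\mathrm{IIa}})$ profiles clustered
hierarchically (complete linkage, Euclidean distance); because "clusters by
visual inspection" is not reproducible, the cut is an explicit `k` or
height, and the dendrogram is serialised as Newick text.

## Divergence shrinkage

The healthy type I ∼ type IIa divergence is compared with the disease
cross-contrast (ACTA1-type I versus TNNT1-type IIa). Control significant
proteins found in the disease contrast's tested universe are split into
*maintained* (still significant) and *lost*. Fold-change attenuation is
computed two ways, and they answer different questions:

* over **all identified pairs** — the unbiased estimate of the generative
  attenuation (with effects scaled by $\lambda = 0.3$, the median
  $|\mathrm{FC}_{disease}|/|\mathrm{FC}_{control}|$ recovers ≈ 0.3);
* over **maintained proteins only** — the headline `attenuation_ratio` of
  the report. This one is *selection-biased upward*: a protein stays
  significant in a noisy 3-versus-3 contrast mostly when noise pushed its
  apparent fold change up, so the maintained-only ratio lands far above the
  generative $\lambda$ (≈ 0.8 under default cohorts). Both are reported;
  conclusions about attenuation magnitude should use the all-pairs ratio.

Sign flips (a protein significant in both contrasts with opposite
direction, the MYBPC2-like case) are counted separately from attenuation,
because they are a different phenomenon.

## The synthetic-data generator

Every input the pipeline consumes can be generated with known ground truth:
decay traces on the acquisition grid, a PG matrix with annotations, subtype
labels, SRX couplings, and attenuated disease cohorts. The defaults are the
study conditions the package is designed around:

* control: 8 participants × 9 dual fibres; disease: 3 ACTA1-like + 3
  TNNT1-like participants × 6 fibres;
* a 1500-protein universe with baselines $\mu_p \sim N(12, 2.2^2)$ log2
  LFQ, per-protein noise $\tau_p \sim U(0.35, 0.65)$, additive participant
  effects (SD 0.3) independent per protein × participant;
* 150 proteins with true type I − type IIa effects of $|{\delta}| \in
  [0.8, 2]$ log2 units (half up in each direction), plus a 60-protein
  disease module down-regulated in every disease condition;
* logistic abundance-dependent dropout (midpoint 11.8, slope 1.5 log2
  units) with a per-fibre detection shift (SD 1.5) emulating variable
  recovered material — together ≈ 780 detected proteins per control fibre
  with a realistic spread;
* MYH rows generated from subtype mixture fractions of a common raw total,
  with log2 noise 0.25;
* SRX $= \mathrm{clip}(\mathrm{base} + \mathrm{SD}\cdot\eta,\,0,\,100)$
  where $\eta$ combines standardised protein abundances through coupling
  weights $\beta$ (scope-specific weights create divergent, SGCD-like
  couplings) plus residual noise; control regime 54.5 ± 32%, disease
  regimes 38.4 ± 8.6% and 33.0 ± 14.8%;
* decay parameters per fibre with $P_2 = \mathrm{SRX}/100$ and
  $P_1 + P_2 = 1$ (so DRX $= 100 -$ SRX exactly), $T_1 \sim U(1.5, 4)$ s,
  $T_2 \sim U(100, 200)$ s, frame noise $\sigma = 0.02$;
* disease effects $\delta' = \lambda\,\delta$ with $\lambda = 0.3$ and
  type-I- / type-IIa-skewed compositions.

Everything is deterministic under one master seed, including dropout masks;
truth tables sufficient to recompute expected outputs are emitted alongside.

**What it does not emulate.** Peptide-level quantification and
between-protein intensity correlation structure (values are independent
given participant and subtype), batch/acquisition-order effects,
fibre-size covariates, segment-to-segment molecular gradients within a
fibre, and real biological covariance between SRX and whole pathways rather
than a handful of coupled proteins. Passing tests on these cohorts
therefore demonstrate that the *procedures* are correct and calibrated —
type-I error, parameter recovery, monotonicity, determinism — not that real
muscle data will be as well behaved.

**Problem sizes.** The shipped tests and the acceptance script run the
default cohorts above (about 1500 proteins × 108 fibres end-to-end, 625
noiseless grid fits, 200-trace noisy recovery, 500-protein null
calibrations). These sizes give stable Monte-Carlo behaviour while keeping
a full run in well under a minute on one core.

## Known limitations

* SRX% from a single 49-frame trace carries a few percentage points of
  irreducible error, growing toward the extremes where one amplitude is
  small; fibres whose slow component is genuinely unidentifiable get the
  best resolvable answer, not a flag-free guarantee.
* The unadjusted composite threshold trades specificity for sensitivity by
  design; hit lists are screening output.
* Complete-case PCA can be starved by heavy dropout (handled by degrading
  to count-based QC).
* The maintained/lost split inherits the power of a 3-versus-3 contrast;
  its counts are seed-sensitive in a way the all-pairs attenuation ratio is
  not.
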