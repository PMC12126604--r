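# myosrx

Joint analysis of myosin relaxed-state measurements and same-fibre
proteomics in single skeletal muscle fibres.

Skeletal muscle fibres come in slow (type I, MYH7-dominant) and fast
(type IIa/IIx, MYH2/MYH1-dominant) subtypes with very different metabolic and
contractile programmes. Within a resting fibre, myosin heads sit in either
the super-relaxed state (SRX, very slow ATP turnover) or the
disordered-relaxed state (DRX, an order of magnitude faster). `myosrx`
implements a complete workflow for studies that measure **both** quantities
in the *same* fibre — a MANT-ATP chase fluorescence assay on one fibre
segment and label-free DIA proteomics on the other — so that myosin
biochemical state can be related directly to the fibre's proteome, in health
and in disease cohorts such as *ACTA1*- and *TNNT1*-mutation nemaline
myopathy.

It is aimed at muscle physiologists and proteomics analysts who have
per-fibre fluorescence decay traces and a DIA protein-group (PG) matrix, and
at methodologists who want a fully synthetic, ground-truth-known testbed for
this class of single-fibre dual-assay designs.

## The models at the core

**Decay model.** Normalised chase fluorescence is fitted, unconstrained, by

    f(t) = 1 − P1 (1 − e^(−t/T1)) − P2 (1 − e^(−t/T2)),   T1 ≤ T2

where `P1` is the fast (DRX) amplitude and `P2` the slow (SRX) amplitude;
`DRX% = 100·P1`, `SRX% = 100·P2`. Fitting is multi-start
Levenberg–Marquardt with a resolvability rule that protects against the two
unidentifiable ridges of this model (see the methods vignette).

**Differential abundance.** Fibres are aggregated to one median log2 LFQ
value per protein per (participant, group) — pseudo-bulk — then quantile
normalised and tested with an empirical-Bayes moderated t: the posterior
variance is `s̃²_g = (d0·s0² + d_g·s_g²)/(d0 + d_g)` with the prior
`(d0, s0²)` estimated by method of moments from the log sample variances.
Significance is the composite π-value `π = p^|log2FC|`, called at π < 0.05
(unadjusted, by design).

**Integration.** Same-fibre SRX% is correlated with protein abundance
(Spearman, average ranks, exact permutation p for n ≤ 9) overall and per
fibre subtype, after the presence filters (≥22 fibres overall, ≥10 per
subtype). "Divergence shrinkage" in disease is quantified by the
maintained/lost split of control type I ∼ type IIa proteins in the disease
cross-contrast and by fold-change attenuation.

## Worked example

```r
library(myosrx)

grid <- mant_timegrid()               # 0,5,...,90,100,...,390 s (49 frames)
sim  <- simulate_traces(
  data.frame(fibre_id = "fibre_01", P1 = 0.42, T1 = 2.2, P2 = 0.51, T2 = 155),
  grid = grid, sigma = 0.02, seed = 7)
fit <- fit_decay(sim$traces$fibre_01)
fit
#> <decay_fit> fibre 'fibre_01'
#>       P1       T1       P2       T2
#>   0.4224   2.5098   0.4900 141.5467
#> DRX: 42.2%  SRX: 49.0%  RSS: 0.0167
srx_class(fit)
#> [1] "mid"
```

The fitted SRX of 49.0% recovers the generating truth of 51% to within the
noise of a single 49-frame trace, and 49% falls between the low (≤35%) and
high (≥65%) SRX cluster boundaries, hence `"mid"`.

The whole pipeline — simulate control + disease cohorts, fit every decay,
QC, type fibres, run all contrasts, correlate SRX with the proteome, and
quantify shrinkage — runs off one seed:

```r
out <- run_pipeline(file.path(tempdir(), "demo"), seed = 1)
out$shrinkage
#> <shrinkage_report> control DAPs: 129; identified in disease: 125
#> maintained: 21  lost: 104  attenuated: 121/125  median |FC| ratio (maintained): 0.834
out$diffabund$control_typeI_vs_typeIIa
#> <diffabund> typeI vs typeIIa: 1345 proteins tested, 115 significant (pi < 0.05)
#> prior df d0 = 2.87, prior variance s0^2 = 0.131
```

Of 129 control type I ∼ type IIa differentially abundant proteins, 125 are
testable in the disease cross-contrast; only 21 remain significant there and
121/125 show a smaller absolute fold change — the disease cohorts were
generated with subtype effects attenuated to λ = 0.3, and the median
fold-change ratio over all identified pairs recovers it (≈ 0.33).

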