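---
title: "Methods: invasion-associated gene signatures for chemosensitivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: invasion-associated gene signatures for chemosensitivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invasig)
```

## The problem and the model

Tumour cell lines differ widely in their ability to invade through a matrigel
barrier, and that invasive potential is only weakly structured by tissue of
origin: within-group variation in invaded cell counts (ICC) dominates
between-group variation. `invasig` implements a three-way integration
analysis around this phenotype:

1. **Invasion-associated (IA) probe discovery.** Each probe's expression
   profile across the cell-line panel is correlated (Pearson) with the
   invasion profile on two independent microarray platforms. A probe is
   called invasion-associated when it is significant on the discovery
   platform (two-sided $p < p_{disc}$, default 0.05) *and* its mapped
   partner on the confirmation platform is significant in the *same
   direction* (two-sided $p < 2\alpha$ with matching sign, equivalent to a
   one-sided test at $\alpha$, default 0.025). The confirmation-stage false
   discovery rate is estimated in closed form:
   $$\widehat{FDR} = \frac{m \,\alpha}{k},$$
   where $m$ probes entered confirmation and $k$ passed. Under the null the
   confirmation stage passes a probe with probability $\alpha$ (the sign
   constraint halves the two-sided level), so $m\alpha$ is the expected
   false-positive count.
2. **Gene–drug correlation profiling.** For each IA probe and each active
   drug, the Pearson correlation between expression and drug sensitivity
   ($-\log_{10}\mathrm{GI}_{50}$; higher = more sensitive) over the shared
   cell lines. Per-drug counts of significant probes (raw $p < 0.05$) and
   mechanism-class mean counts summarise which drug families are most
   predictable from invasion biology.
3. **Signature derivation.** Four sequential, idempotent filters: (i)
   intersection of the significant-probe sets of the selected drugs, (ii)
   restriction to the primary chip, (iii) retention of probes whose raw-scale
   expression SD ranks in the top 10% of *all* probes on the chip, (iv)
   direction consistency — the correlation sign for every in-scope drug must
   match its mechanism class (positive for targeted-therapy agents, negative
   for tubulin-binding agents). Surviving probes collapse to one probe per
   gene (largest SD wins).
4. **Validation.** The risk score of a sample is the unweighted mean of its
   signature-gene expression. Labelled cell-line panels are compared by a
   two-sample t-test; survival cohorts are dichotomised at the cohort-mean
   score and analysed with Kaplan–Meier curves, the log-rank test and
   multivariate Cox regression (Efron tie handling).

## Preprocessing choices

All correlations operate on **normal scores**: a value with average rank $r$
among $m$ non-missing observations maps to $\Phi^{-1}(r/(m+1))$ (the van der
Waerden convention; ties share averaged ranks, missing values propagate, and
each correlation uses pairwise-complete observations). The exact rank-normal
variant is not uniquely determined by the field's usage; $r/(m+1)$ is
standard and bounded away from $\pm\infty$. The transform is applied to
expression by construction and — by default, switchable in the config — also
to the invasion and drug-sensitivity profiles, because the ICC distribution
is heavy-tailed (log-normal-like, two orders of magnitude of range) and raw
Pearson correlations on such profiles are outlier-driven. The switch is
logged so the choice is auditable per run.

ANOVA on invasion heterogeneity is computed on the raw ICC scale (the
phenotype's native scale), not on normal scores.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `p_discovery` | 0.05 | two-sided stage-1 threshold |
| `p_confirmation` | 0.025 | one-sided, sign-consistent stage-2 level; also the FDR numerator rate |
| `p_gene_drug` | 0.05 | per-cell gene–drug significance (raw, uncorrected) |
| `sd_quantile` | 0.9 | SD filter keeps the top $1 - q$ of all probes |
| platform roles | A = discovery | which platform anchors stage 1 (configurable, logged) |

No multiple-testing correction is applied to the per-cell gene–drug
p-values; the formula-based FDR applies to the IA screen only. This is a
fidelity-over-optimality choice and is stated in the output log.

Ambiguities resolved as package design choices:

- **Many-to-many probe maps**: a discovery probe is confirmed by its *best*
  partner — largest $|r_{confirm}|$ among sign-consistent partners — and the
  partner used is recorded. Deterministic and reproducible.
- **FDR denominator counts probe pairs, not genes** (probes and genes differ
  whenever several probes annotate one gene; the collapse to genes happens
  only at signature derivation, where the max-SD probe represents the gene).
- **SD-filter reference population is the whole chip**, not the candidate
  set: "SD ranking within the top 10%" reads most naturally as a rank among
  all probes, and the full-chip population is the stricter interpretation.
  The cutoff uses a ceiling count and a $\ge$ comparison so boundary
  behaviour is deterministic.
- **Cohort risk scores** default to per-gene z-scoring within the cohort
  before averaging. The score formula is a raw average, but applying a
  signature across array generations is undefined without putting genes on a
  common scale; both modes are exposed and tested.
- **Welch's t-test by default** (pooled-variance Student's available):
  validation panels are small and group variances are not credibly equal.
- **Config format** is JSON (nested key/value); every CLI flag overrides its
  config key, and each stochastic stage logs its seed, so a full run is
  reproducible from one artifact.

## The synthetic world

The generator encodes the statistical structure the pipeline is meant to
detect, at the scale of the motivating design: 53 solid-tumour cell lines in
8 tissue groups, two probe-mapped platforms, ~100 drugs in mechanism
classes, and survival cohorts in the hundreds.

- **One latent invasion axis $z$** per cell line drives everything
  invasion-related: $ICC = \exp(\log 800 + \delta_g + 0.8 z)$ with
  group offsets $\delta_g \sim N(0, 0.15^2)$, so ICC spans roughly
  130–5,500 and within-group variance dominates between-group variance.
  Planted IA probes have population correlation $\pm$`effect_r` with $z$ on
  both platforms with matching sign; platform B applies an independent
  per-probe affine distortion, so cross-platform agreement is a sign
  property, not a value property — exactly what the sign-consistency rule
  requires.
- **A second, independent latent $d$** represents the drug-response axis.
  Planted signature probes load on both: `effect_r` (0.6) on $z$ and 0.63 on
  $d$; planted drug classes load on $d$ at 0.95 with a class sign (+1
  targeted, −1 tubulin-binding, reproducing the observed mechanism
  sign-flip). The planted gene–drug population correlation is therefore
  $0.63 \times 0.95 \approx 0.6$ — the same magnitude as the invasion
  effect. The separation of $d$ from $z$ matters: if drugs loaded on $z$
  itself, every probe that passed the IA screen by chance would inherit a
  real drug correlation, and *exact* signature recovery would be impossible
  in principle rather than merely underpowered.
- **Signature probes get raw-scale SD 2.5** against a log-normal(0, 0.4)
  null SD distribution. In a unit-variance world the pipeline's own top-10%
  SD filter would reject 90% of planted markers; informative genes in real
  expression data are high-variance, and the generator mirrors that.
- **Inactive drugs** are constant across all lines (the floor-response
  pattern); the panel defaults plant 7 of 106, so the active set is 99.
- **Validation panels** shift each signature gene of the sensitive group by
  `score_shift`$/\sqrt{g}$, so the mean risk score moves by `score_shift`
  null-score standard deviations.
- **Survival cohorts** draw exponential event times with hazard
  $\propto \exp(\beta x)$, where $x$ is the standardised risk score or,
  optionally, the high/low indicator at the cohort-mean threshold (the
  "hazard ratio on the dichotomised score" reading). Censoring is
  independent uniform on $(0, b)$ with $b$ solved numerically for the
  requested censoring fraction. Covariates are independent of the score by
  construction, so multivariate adjustment should not absorb the signature
  effect.

All generators are pure functions of (parameters, seed): they restore the
caller's RNG state, and the same seed reproduces bit-identical outputs.

**What a green test does not establish.** The world has a single invasion
axis, Gaussian noise, no batch effects, no probe-level intensity artefacts,
no correlation structure among null genes, and covariates independent of the
score. Real panels violate all of these; green parameter-recovery tests
certify the statistical machinery, not robustness to those violations.

## Numerical conventions

- Correlations are computed by masked explicit sums (one matrix pass,
  arbitrary missingness); $|r|$ is clamped to 1 before the t transform;
  p-values use $t = r\sqrt{(n-2)/(1-r^2)}$ with $n-2$ df.
- Probes (or drugs) with fewer than three complete pairs, or zero variance,
  are dropped and logged rather than propagated as NaN.
- ANOVA with all-equal groups returns $F = 0$, $p = 1$ (0/0 resolved to 0).
- Cox fits flag — rather than raise — non-convergence, separation
  (|coef| > 15) or fitter warnings; the guard `events >= covariates + 5` can
  be lifted for deliberate small worked examples.
- The log-rank statistic is the unstratified two-group chi-square on 1 df;
  groups with zero events warn but still contribute.

## Known limitations

- The signature filters assume the in-scope drugs' mechanism classes fully
  determine expected correlation signs; mixed-mechanism compounds need an
  explicit per-drug sign map.
- The FDR estimator is the closed-form $m\alpha/k$; no permutation-based
  alternative is provided.
- The pipeline treats probe→gene annotation as given; it does not
  re-annotate probe sets against current genome builds.
- Heat-map clustering/ordering (display concerns) and raw-array
  preprocessing are out of scope.
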