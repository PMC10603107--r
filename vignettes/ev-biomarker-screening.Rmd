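---
title: "From EV proteomes to a screening panel: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From EV proteomes to a screening panel: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exoscreen)
```

## The problem

High grade serous ovarian carcinoma (HGSOC) is usually detected late, yet
it is curable when found while still confined to the fallopian tube (FT),
its presumed tissue of origin. A blood test for pre-symptomatic screening
must clear a hard epidemiological bar: at a population prevalence around 1
in 2500 (postmenopausal women), even a 99% specific test produces mostly
false positives, so screening panels are evaluated at a *forced*
specificity of 99.8% and judged by their positive predictive value (PPV)
at that operating point.

`exoscreen` implements the complete analysis chain behind this kind of
biomarker program: (1) a replicate-aware filtering cascade that reduces
label-free proteomic abundance tables of extracellular-vesicle (EV)
preparations to a short ranked list of candidate transmembrane surface
proteins shared between the healthy lineage and the carcinoma; (2)
single-marker ROC statistics, including kernel-smoothed ROC curves and
the ROC arc-length statistic; (3) multi-marker combination by exhaustive
logistic-subset search under the Akaike Information Criterion (AIC); and
(4) screening performance: Youden cutoffs, sensitivity at forced
specificity, and PPV at prevalence. A synthetic-data module generates
study-shaped inputs with known ground truth so every stage is testable
without access to raw mass-spectrometry data.

## The filtering cascade

The discovery design has two lineages (FT and HGSOC), each observed both
as cell lines and as short-term tissue explants. Detection is decided per
*unit* (one cell line, or one tissue-explant set) from biological
replicates:

* HGSOC cell lines (3 replicates): detected in at least 2 of 3;
* FT cell lines (2 replicates): detected in both;
* tissue-explant sets: detected in all replicates of the set.

"Detected" means a non-missing, nonzero intensity. Label-free tables
distinguish an empty cell (not measured) from a measured zero; both fail
the detection rule, but only empty cells are excluded from fold-change
means. The cascade then proceeds:

1. **Lineage sets.** Within a lineage, the cell-line detected sets are
   combined (union by default) and intersected with the union of the
   lineage's tissue sets, so every member has evidence both in culture
   and in tissue. The union default reads "proteins found in the group"
   inclusively, maximizing sensitivity at the discovery stage; an
   intersection mode is available via
   `filter_config(cell_aggregation = "intersection")`.
2. **Core proteome.** The intersection of the two lineage sets — proteins
   carried by EVs of both the healthy lineage and the carcinoma.
3. **Transmembrane intersection** with a predicted-transmembrane
   reference list (candidates must be displayable on the EV surface for
   immunocapture).
4. **Common-EV subtraction** of a top-100 ubiquitous EV-protein list
   (markers must not be generic EV cargo).
5. **Fold-change filter.** `log2((mean HGSOC + c) / (mean FT + c))` with
   pseudocount `c = 1` after per-sample total-intensity normalization,
   retaining proteins at or above −0.58 — i.e. present in the healthy
   lineage and holding steady or rising with disease. The boundary is
   inclusive. Means pool all samples of a lineage by default
   (`fc_basis = "pooled"`); tissue-only and cell-only bases are available.
6. **Manual exclusion** of literature-flagged common EV proteins missed
   by the list subtraction.

Each stage records its parameters, input/output counts, and dropped
identifiers in a `filter_trace` (`tidy()`, `autoplot()`, JSON-lines
serialization). Results are invariant to row/column permutations of the
input, and every stage output is a subset of its input.

Choices the data did not dictate: the normalization (total intensity to
the median sample total) removes loading differences and is standard for
label-free comparisons; the pseudocount guards `log2` against zero means
and is negligible at the scale of normalized intensities; ranking ties
break lexicographically by identifier so reruns are bit-identical.

## Single-marker statistics

The empirical ROC curve is the threshold sweep over all distinct scores,
with tied case/control values taking simultaneous diagonal steps. This
convention makes the trapezoidal AUC equal `U/(n1·n0)` with the midrank
Mann–Whitney U *exactly*, an identity the test suite checks to 1e-12.
Standard errors use the Hanley–McNeil formula with a normal 95% interval
truncated to [0, 1]; one-tailed p-values against AUC = 0.5 come from the
Mann–Whitney test (exact enumeration when both groups have ≤ 8
observations without ties, tie-corrected normal approximation otherwise).
These SE/CI/p conventions are this package's documented defaults, not a
claim about any particular historical software.

**The ROC arc-length statistic.** A marker whose cases sit in *both*
tails of the control distribution can have AUC near 0.5 yet still carry
signal. The arc length of the ROC curve separates these cases: it is 2
for perfect monotone separation, √2 for an uninformative diagonal, and
remains large for informative non-monotone markers. Markers are
classified *monotone* when the smoothed curve's length reaches 2 − ε
(ε = 0.02, since a smooth estimate never attains 2 exactly) with AUC
> 0.8 or < 0.2, and *non-monotone* when the length exceeds 1.6 with AUC
in [0.35, 0.65]; monotone takes precedence if both fire.

The smoothed curve estimates each group's score distribution with a
Gaussian-kernel CDF (Silverman bandwidths per group by default) and
traces `(1 − F̂₀(c), 1 − F̂₁(c))` over a 2001-point threshold grid
spanning the data ± 4 bandwidths. This parametric-in-threshold evaluation
traces the same curve as inverting the control CDF on an FPR grid, while
avoiding numerical root finding. With zero variance in a group the
estimator falls back to the empirical curve with a warning. Classification
pairs the smoothed length with the empirical AUC — the length needs the
smooth estimate, while the empirical AUC keeps the U identity.

The IHC `h_score()` helper (0–300, the intensity-weighted percent-area
sum) supports the tissue-validation arm of such studies.

## Multi-marker combination and screening performance

For a panel of k candidate markers, `exhaustive_search()` fits a logistic
regression of case status on the natural-log intensities of every
non-empty subset (2^k − 1 models; 127 for the seven-marker panel) and
selects the minimum-AIC model, breaking ties toward fewer markers and
then lexicographic names. The natural log is a convention: changing the
log base rescales coefficients without affecting ranking, sensitivity,
specificity, or PPV, so printed coefficients are only comparable within a
base.

Perfect separation deserves care at screening-study sizes: with 10 cases
and 20 controls and single-marker AUCs approaching 1, the logistic MLE
frequently does not exist. Diverging fits are detected (non-convergence
or slopes beyond ±15 on the log scale) and refitted with a weak ridge
penalty (λ = 1e-4, slopes only), flagged via `$separation`. The reported
log-likelihood and AIC are always the *unpenalized* ones evaluated at the
returned coefficients, so AIC comparisons remain on a single scale.

The fitted model's intercept-free linear term `Σ βᵢ log(xᵢ)` is the
combined marker score. Downstream statistics use only score ranks, so
dropping the intercept changes nothing. Operating points:

* `youden_cutoff()` maximizes J = sensitivity + specificity − 1 over
  midpoints of adjacent distinct scores, ties toward higher specificity,
  then the lower cutoff;
* `sensitivity_at_specificity()` finds the smallest cutoff whose
  empirical specificity meets the target. With 20 controls, a 0.998
  target tolerates no false positive, so the cutoff lands at the control
  maximum (empirical specificity 1.0) — the literal reading of "forcing"
  a specificity beyond the resolution of the control set;
* `ppv()` is the exact Bayes formula
  `s·p / (s·p + (1 − q)(1 − p))`. Reported PPVs plug in the *nominal*
  forced specificity (0.998), the convention under which screening
  operating points are quoted — plugging in the small-sample empirical
  specificity of 1.0 would report PPV = 1 and overstate a 20-control
  experiment.
* `evaluate_fixed_combination()` applies a frozen model to an independent
  panel without refitting — the validation step that separates a
  discovery estimate from a confirmation.

## The synthetic-data generator

`generate_abundance_study()` *plants membership first and draws
intensities second*. Each protein is assigned a fate (core, single
lineage, cell-line-only, tissue-only; transmembrane or not; common-EV or
not; fold-change pass/fail; manually excluded or not), and presence,
absence, and lineage mean intensities are generated to realize that fate.
Consequently the cascade's set logic is exactly verifiable: at zero
dropout the pipeline recovers the planted stage sets identically, and at
the default configuration it reproduces the flow 1193/1309 lineage
proteins → 985 core → 75 transmembrane → 66 after common-EV subtraction →
47 past the fold-change filter → 45 final candidates. Intensities are
log-normal (per-protein base abundance around log(1e6), replicate noise
sdlog 0.25); fold-change passers draw planted log2 targets in [0, 3] and
failers in [−3, −1.2], leaving ≈ 0.6 log2 units of margin around the
−0.58 threshold — about 4.5 standard deviations of the realized
group-mean noise, so the planted counts survive sampling variation.
Replicate dropout is applied only where the detection rules tolerate it
(one replicate of a 3-replicate cell-line unit).

`generate_marker_panel()` models chip fluorescence log-normally: controls
`exp(N(μ₀, σ₀))`, cases `exp(N(μ₀ + δ, σ₁))`, so each marker's true AUC
is `Φ(δ/√(σ₀² + σ₁²))` in closed form. The default seven-marker panel
sets δ = √2·Φ⁻¹(AUC) to the published single-marker AUCs (0.85–0.98)
with 10 cases and 20 controls — the study's conditions.
`generate_multicancer_panel()` adds 12 non-ovarian cancer classes (5
samples each) drawn from the control distribution (optionally shifted),
emulating a cross-cancer specificity experiment of 90 samples.

What the generator does *not* emulate: correlated markers on one chip,
batch and plate effects, heavy-tailed or censored fluorescence,
peptide-level missingness structure, or biological covariance among
proteins. Passing tests on synthetic data therefore validate the
*arithmetic and set logic* of the pipeline, not the biological
performance of any marker set on real plasma.

## Problem sizes and numerical choices

The test suite runs the generator at two scales: a reduced cascade
(260 proteins, planted flow 120 → 30 → 25 → 18 → 16) for unit tests, and
the full study shape (2057 proteins × 45 samples) for the end-to-end
count check. Distributional checks use n up to 2000–5000 per group,
where the smoothed AUC sits within 0.02 of the binormal closed form and
the empirical AUC within 0.01 of truth. Monte-Carlo checks (AIC subset
recovery, null p-value calibration) use 50 and 500 seeded replicates
respectively. All randomness flows through explicit integer seeds;
rerunning any function with the same seed reproduces its output
byte-for-byte.

## Known limitations

* Protein identifiers are opaque keys; accession↔symbol mapping must
  happen upstream.
* The cascade starts from a protein-level table: no peptide inference,
  FDR control, or spectra handling.
* No covariate-adjusted or multi-reader ROC; no partial AUC.
* Multi-class (cancer-type) panels are handled by per-marker group
  comparisons, not a multi-class classifier.
* With 20 controls, "specificity 0.998" is an extrapolation beyond the
  empirical resolution (1/20); the package implements the literal forced
  cutoff and reports the nominal target in the PPV, but a larger control
  set is the only real fix.
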