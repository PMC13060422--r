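---
title: "Regional motif diversity scores: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional motif diversity scores: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical models implemented in `rmdskit`,
the parameters that matter, the reasoning behind the design choices that
were genuinely open, and what the built-in simulators do and do not
emulate.

## The regional motif diversity score

Cell-free DNA fragments end where nucleases cut, and the cut-site sequence
preference makes the k-mer at each fragment's 5′ terminus informative. The
package bins the genome into fixed-width windows and computes, per bin
*j*, the normalized Shannon entropy of end-motif usage:

$$\mathrm{rMDS}_j = \frac{\sum_{i=1}^{4^k} -P_{i,j}\,\log P_{i,j}}{\log(4^k)},
\qquad 0 \cdot \log 0 := 0,$$

where $P_{i,j}$ is the relative frequency of motif $i$ among the fragment
ends whose terminal base falls in bin $j$. The score is 1 exactly when all
$4^k$ motifs are equally used and 0 when a single motif carries every end.
It is invariant to the logarithm base (the normalizer cancels it) and to
any permutation of the motif lexicon; natural logs are used internally
only so intermediates are reproducible. No pseudocounts are added:
zero-count motifs contribute zero, matching the definitional formula
literally.

Each sample's profile is then z-scored across its own defined bins,
$Z_j = (\mathrm{rMDS}_j - \mu)/\sigma$ with the *population* standard
deviation. At thousands of bins the population/sample distinction is
negligible, but fixing it makes the transform exact and testable. Bins
with fewer than `min_ends` ends (default 100) are treated as missing and
excluded from $\mu$ and $\sigma$; emitting zeros for undersampled bins
would fabricate signal, and excluding missing bins from the moments is the
only self-consistent choice once they are missing.

### Motif extraction conventions

Every fragment contributes two ends. For the informative `five_prime`
side, the upstream end motif is the reference sequence `[start, start+k)`
and the downstream end motif is the reverse complement of
`[end-k, end)` — the double-strand convention of the end-motif literature,
since the downstream 5′ terminus lies on the minus strand. The
`three_prime` control is defined as the per-fragment reverse complement of
the 5′ pair, which makes it composition-matched: any confounding driven by
regional base composition appears in both, while nuclease preference
appears only at the 5′ side. Each end is tallied into the bin containing
its own terminal base (not the fragment midpoint), because the score
measures end diversity *at a locus*. Ends whose k-window crosses a
chromosome boundary are skipped and counted (`n_edge_skipped`); windows
containing non-ACGT bases are discarded and counted (`n_discarded`); ends
in masked bins are counted as `n_masked`. The conservation identity
`counts + discards + edge-skips + masked = 2 × fragments` is asserted in
the tests and makes silent loss impossible.

Coordinates are 0-based half-open (BED convention) throughout. Fragment
QC keeps records with mapping quality ≥ 30 and length in the inclusive
range 50–350 bp (the mono- to di-nucleosomal range); the bounds are read
as inclusive since the source convention gives no bracket semantics. A
missing mapq column passes that rule (fragment inputs are typically
pre-filtered) and is flagged in the filter log.

### Masking

Blacklist handling is two-fold: fragments overlapping a blacklist interval
are removed record-wise, and a bin is masked when more than 50% of its
width is blacklisted. A mappability track, when supplied, masks bins whose
mean mappability falls below 0.9. Both thresholds are package choices — no
normative values exist for them — and both are configurable arguments of
`load_layout()`.

## Batch correction with a preserved covariate

For each bin, `fit_correction()` fits by ordinary least squares

$$y = \mu + X_{\text{batch}}\beta_{\text{batch}} +
      X_{\text{preserve}}\beta_{\text{preserve}} + \varepsilon$$

with sum-to-zero contrasts on every factor, and `apply_correction()`
subtracts only $X_{\text{batch}}\hat\beta_{\text{batch}}$. Including the
response term in the fit prevents the batch coefficients from absorbing
biology; never subtracting it preserves that biology. Sum contrasts make
the batch terms mean-zero over levels, so the corrected grand level is
unchanged, and they give a natural encoding for factor levels unseen at
fit time: the zero vector, i.e. a grand-mean-only correction, emitted with
a warning. The model is fit once on an analysis set and the frozen
coefficients can be applied to held-out samples — nothing is re-estimated
from new data, which the test suite asserts by perturbing held-out rows.
Rank-deficient designs (e.g. a batch factor aliased with the response)
are refused with the aliased terms named, rather than silently dropped.

Standardization is per-bin z-scoring across samples (population SD,
zero-variance bins dropped with a message), and dimensionality reduction
is truncated SVD without centering on the already-standardized matrix.
Component signs are canonicalized by making each component's
largest-magnitude loading positive, so embeddings are identical across
runs and platforms. Group separation is quantified by the silhouette
score $(b-a)/\max(a,b)$ per sample with Euclidean distances, computed on
the corrected feature space (not on a 2-D visualization embedding, whose
layout is not part of the tested contract); samples in singleton groups
score 0 by convention.

## Moderated differential testing

Longitudinal designs repeat measurements within patients, so per-bin
tests use generalized least squares under block-equicorrelated errors:
within a patient, residuals share a common correlation $\rho$. A single
consensus $\hat\rho$ is used for all bins — the duplicate-correlation
strategy — estimated by a one-way random-intercept ANOVA decomposition of
the OLS residuals per bin, clipped to $(-0.99, 0.99)$, and pooled on the
Fisher-z scale. This is tractable at thousands of bins where per-bin
mixed models are not, and reduces exactly to OLS at $\rho = 0$ (asserted
to 1e-10 in the tests).

Residual variances are moderated by the standard empirical-Bayes scheme:
a scaled inverse-$\chi^2$ prior $(d_0, s_0^2)$ is fitted by matching the
moments of $\log s^2$ (mean and variance, with the digamma/trigamma
corrections for the $\log \chi^2$ distribution; the trigamma inverse is
solved by Newton iteration), posterior variances are
$\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$, and the moderated t has
$d_0 + d$ degrees of freedom. When the variance of $\log s^2$ is at or
below its sampling floor, $d_0 = \infty$ and the test becomes a
pooled-variance z-test; `prior_df = Inf` forces this limit explicitly.
The implementation is authored here and cross-checked in the test suite
against limma's `lmFit(block=, correlation=) + eBayes` route, which
implements the same model independently.

Clinical covariates enter as fixed effects: numeric covariates as-is,
categorical ones one-hot against their first level, with levels carrying
fewer than 2 samples collapsed to `"other"` (a warning names them).
Timepoint is *not* in the default design — the tested contrast is a
global response effect — but can be passed as an ordinary covariate by
callers who want it; the choice is left open because either reading of
the repeated-measures design is defensible.

Multiple testing uses Storey q-values by default: $\hat\pi_0$ from the
$\lambda$-grid 0.05–0.95 with a df-3 smoothing spline evaluated at
$\lambda = 0.95$, and monotone step-up q-values scaled by $\hat\pi_0$;
`method = "bh"` gives Benjamini–Hochberg (equivalently $\pi_0 = 1$).
Bins at q < 0.1 are called differential.

## Region clustering and telomere enrichment

Significant bins are clustered on their value vectors across samples
(ordered by response group, patient, timepoint) with Ward linkage on
Euclidean distances, cut to exactly `n_clusters` (default 3). Cluster
labels are renumbered by descending size because dendrogram order is an
implementation detail that does not survive reimplementation. Trajectory
summaries collapse bins to per-sample means, then to per-patient means,
and report across-patient means with 95% t-intervals per
(cluster, group, timepoint) stratum — patient-level aggregation first, so
patients with many samples do not dominate.

Telomere proximity of a bin is `min(mid, L - mid)` for the bin midpoint
and chromosome length L. The null distribution comes from bins of the
layout's width placed uniformly at random, chromosomes drawn proportional
to length; null bins may overlap each other or real bins, since no
exclusion rule is normative and uniform placement is the cleanest null.
Two tests are reported: a one-sided Mann–Whitney U (observed distances
stochastically smaller than null) and a permutation test whose statistic
is the *mean* distance (chosen for power against location shifts;
`statistic = "median"` is available), with the add-one correction
$p = (1 + \#\{\text{perm} \le \text{obs}\})/(n_{\text{perm}} + 1)$ so p
can never be 0.

## Classification harness

Features are the first 6 truncated-SVD components of the corrected,
standardized matrix. The default classifier is ridge-regularized logistic
regression (deterministic, dependency-light); any object implementing
`fit(x, y)` / `predict(model, x)` probabilities can be plugged in, since
the contract under test is the harness, not the learner. All validation
schemes split at the patient level — no patient appears in both train and
test — with repeated k-fold stratified by response (avoiding single-class
folds at small n), leave-one-institute-out, and random patient holdout.
Under `correction_policy = "refit"`, batch correction, standardization
and SVD are fitted on training samples only and applied frozen to the
test side; `"global"` uses a matrix corrected upstream; `"none"` skips
correction and exists to measure what the correction buys.

Patient-level predictions take the probability of the patient's most
recent available timepoint (Screen < Day0 < AdjWk1; unknown timepoints
sort first). Patients whose only sample is Screen are scored from Screen
rather than excluded — the less wasteful reading of an ambiguous rule —
and such patients are identifiable from the prediction table. The
decision threshold is 0.5 with ties resolved to the positive class, and
sensitivity at 95% specificity is the maximum sensitivity over thresholds
whose specificity is at least 0.95 (0 if only the degenerate all-negative
threshold qualifies).

## The simulators

`simulate_cohort()` writes fragment BED files against a toy reference so
that the counting code must *read sequence* to recover the planted
distributions — the simulator cannot shortcut the extraction module. Per
bin and sample, motif usage follows a Dirichlet-multinomial with
concentration $\alpha = \alpha_0 \cdot m_b \cdot t_{\text{batch}}$
($\alpha_0$ = `base_concentration`, $m_b$ a per-bin log-normal tilt shared
by all samples, $t$ a per-(institute, library date) log-normal tilt), and
non-responders multiply $\alpha$ by `effect_delta` at the effect bins —
scaling the concentration changes the expected entropy of the realized
usage, which is exactly what rMDS measures. Upstream (5′) ends are placed
at reference positions whose k-mer equals the drawn motif; downstream
ends are matched by nearest-position search within the 50–350 bp length
window, falling back to the uncontrolled position at the target length
when the drawn motif is absent in-window (~30% of downstream ends on a
uniform toy reference, which mildly attenuates planted effects and is
accounted for in the test effect sizes). Timepoint dynamics are fixed
piecewise multipliers per trajectory label (effect at the first and last
timepoints only; constant; constant with opposite sign) — qualitative
shapes, since no parametric trajectory form is normative.

`simulate_rmds_matrix()` generates samples × bins Z-rMDS-scale matrices
directly for the statistical calibrations whose bin counts (2,000) exceed
a desk-scale toy genome. Its residual model is
$u_{pb} + e$: patient effects are per (patient, bin), shared across a
patient's timepoints but independent across bins, with
$\mathrm{Var}(u) = \text{icc}$ and $\mathrm{Var}(e) = 1 - \text{icc}$ so
effects are in total-residual-SD units. Patient effects are deliberately
*not* genome-wide intercepts: a Z-rMDS profile is centered within sample,
so a global per-patient shift cannot exist in the data this emulates, and
planting one induces perfect cross-bin test dependence that no per-bin
FDR procedure is expected to survive. Batch structure can be planted as
constant per-institute offsets, per-(institute, bin) tilts, or
per-(date-combination, bin) tilts; the last gives a batch subspace of
rank up to 9, which is what makes the with/without-correction contrast in
the classification tests meaningful.

What the simulators do **not** emulate: nucleosome-positioned coverage,
GC bias, sequencing error, realistic chromatin-driven motif landscapes,
or copy-number structure. Passing tests therefore demonstrate that the
algorithms do what they claim under controlled conditions — not that the
biological effect sizes of any real cohort are reproduced. No effect
sizes in physical units are available to calibrate against, so the
simulator defaults (base_concentration 5, bin_variation_sd 0.3,
effect_delta 0.5, batch_tilt_sd 0.05, fragment length 166 ± 20 bp,
coverage 300 fragments/bin) are scientific plausibility choices fixed
once: cfDNA motif diversity is high but not maximal, regional tilts are
stable and modest, batch perturbations are small relative to biology, and
166 bp is the canonical mononucleosomal cfDNA mode.

## Problem sizes and numerical choices

The test and pipeline scales are package choices made for desk-scale
reproducibility: toy genomes of 1–2 chromosomes × 1–5 Mb with 100 kb bins
(10–100 bins) wherever fragments are placed and sequence is read, and
matrix-level cohorts of up to 40 patients × 3 timepoints × 2,000 bins for
the correction, differential, and classification calibrations. The
telomere null is exercised at 10,000 random bins (100,000 in the
examples above) and the classification schemes at 5-fold × 10 rounds.
Other numerical fixtures: entropy oracle agreement is asserted to 1e-12;
GLS = OLS at $\rho = 0$ to 1e-10; SVD explained variances against an
independent eigen decomposition to 1e-8; hierarchical clustering ties are
broken by input index (documented, deterministic); random-number state is
saved and restored around every seeded generator so library calls do not
perturb caller RNG.

## Known limitations

- BAM flag logic (proper pairing, supplementary alignments) is out of
  scope; inputs are fragment intervals that already passed upstream
  alignment QC.
- Per-sample quality weights are accepted in the GLS fit but not
  estimated; there is no arrayWeights analogue.
- The batch model is linear; no empirical-Bayes shrinkage of batch
  parameters or reference-free batch inference.
- The sliding-window track reports raw rMDS; cross-sample normalization
  of tracks is the caller's responsibility, matching the per-bin
  pipeline's division of labor.
- Null bins in the telomere test ignore masking; on heavily masked real
  genomes a mask-aware null would be more faithful.
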