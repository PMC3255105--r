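---
title: "Methods: simulated SELDI profiling and oblique classification trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated SELDI profiling and oblique classification trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selditree)
```

## Scope and the role of simulation

`selditree` re-implements a serum SELDI-TOF-MS analysis that
discriminates node-positive from node-negative colorectal-cancer
patients: preprocessing, Biomarker-Wizard-style two-pass peak
detection and clustering, univariate screening, an oblique
classification tree, and confusion-matrix evaluation. The raw spectra
behind the original study were never deposited; what survives in print
are the class-conditional summary statistics of 22 differential peaks
(mean ± SD of normalized intensity per class, keyed by m/z), the
cohort sizes (70/75 training, 35/30 blind test), the assay
reproducibility (mass CV 0.03%; intensity CV 17.2% intra-assay, 19.5%
inter-assay), the 46-cluster count, the fixed five-peak decision
function with its printed coefficients and thresholds, and the
performance table.

Those printed quantities are treated as the *generative model*: the
package simulates cohorts from them and pushes the simulation through
the re-implemented pipeline. A green test therefore establishes that
the pipeline is a faithful implementation of the stated world — it
cannot establish anything new about real sera, and it inherits every
idealization listed below.

## The synthetic-spectrum generator

`generator_config()` describes the stochastic world:

* **Planted peaks.** The 22 differential panel peaks at their printed
  class-conditional `Normal(mean, sd)` intensities, censored at zero
  (negative draws are set to 0 — a zero-measured concentration, not a
  resampled one; true truncation would shift the low-mean peaks'
  expectations measurably, the censored model preserves them to within
  a fraction of a standard error). Plus 24 nuisance peaks with equal
  class means, bringing the planted total to the reported 46 common
  clusters. Nuisance positions are spaced > 1% apart and > 1% from
  every panel peak; their intensities span the same range as the panel
  (sum ≈ 334 normalized units) with a 20% biological CV, so that total
  ion current is dominated by class-independent content and TIC
  normalization does not distort class contrasts by more than a couple
  of percent.
* **Peak shape.** Gaussian with σ = 0.08% of m/z. A wider default
  (0.2%) was considered and rejected: the closest printed peak pairs
  (7,597/7,620 and 5,786/5,808) sit only ~0.3–0.4% apart, and at
  σ = 0.2% the smaller member is an unresolvable shoulder, making the
  46-cluster outcome physically impossible. σ = 0.08% corresponds to a
  mass resolution (m/FWHM) of ≈ 530, realistic for SELDI in the
  3–16 kDa range where most of the panel lives.
* **Baseline.** A two-parameter decaying exponential,
  `30 · exp(−(m/z − 1000)/3000)`, highest at low mass, standing in for
  energy-absorbing-molecule (matrix) noise. The analysis window starts
  at 2,000 Da precisely because the region below is baseline-dominated.
* **Noise and reproducibility.** Additive Gaussian noise
  (`noise_sd = 0.01` normalized units, so the smallest retained-class
  panel heights ~0.2 sit at S/N ≈ 20 and the m/z 7,504 node-positive
  mean 0.034 is properly sub-threshold); a single multiplicative mass
  jitter per spectrum with SD 0.03% (the printed mass CV); an
  independent per-peak multiplicative intensity error with SD 17%
  (intra-assay CV — it must be per-peak, not per-spectrum, because a
  common per-spectrum factor would be removed exactly by TIC
  normalization); and a per-(chip, peak) effect with SD 9%, chosen so
  total between-chip variation √(0.17² + 0.09²) ≈ 19.2% matches the
  printed 19.5% inter-assay CV.
* **Grid.** Uniform 1 Da spacing from 1,000 to 20,000 Da. The original
  instrument's digitization is unstated; the grid is a configurable
  stand-in, not an asserted fact.

What the generator deliberately does **not** model: chip-surface
chemistry, isotope envelopes, peak-shape asymmetry, correlated peak
intensities (only marginal moments are printed; independence is the
simplest consistent model and a correlation hook exists for robustness
experiments), m/z-dependent noise, or day-to-day drift.

## Preprocessing

Order of operations is fixed as **subtract → window → normalize**,
matching the published wording ("normalized by total ion current after
background subtraction") and ensuring sub-2,000 Da matrix noise never
influences the normalization target.

* Baseline estimate: rolling minimum over ± 200 points followed by a
  rolling mean of the same width; clipped to `[0, intensity]`;
  corrected intensity is clipped at zero. On the pure synthetic
  baseline the residual inside the analysis window stays below 5% of
  the baseline amplitude; isolated narrow peaks lose < 1% of height.
* Window: 2,000–20,000 Da inclusive.
* TIC normalization: each spectrum is scaled so its within-window TIC
  equals the cohort mean pre-normalization TIC (the vendor convention;
  intensities stay on the panel's scale). Scale factors are recorded in
  spectrum metadata; zero-TIC spectra are excluded with a warning. The
  operation is idempotent and scale-equivariant.

## Two-pass peak detection and clustering

The vendor software's settings are public; its algorithms are not.
The re-implementation fixes each unstated piece explicitly:

* **Noise** (`estimate_noise()`): 1.4826 × median absolute deviation of
  the running-median-detrended raw trace, in 151-point blocks, each
  block's value replaced by the minimum over itself and its two
  neighbours (true noise varies slowly; peaks can only inflate a block,
  and dense groups of wide peaks — e.g. 14,869/15,006/15,089 — can
  inflate a whole block past its own peaks' S/N).
* **Peaks** (`detect_peaks()`): local maxima of a 5-point-smoothed
  trace; height = apex intensity above a 601-point running median (the
  window is wide enough that the densest planted group covers less than
  half of it, keeping the local reference honest); S/N = smoothed
  height over raw-trace noise; maxima within 1.5 assumed peak sigmas
  merge into the higher one. First pass keeps S/N ≥ 3.
* **Clustering** (`first_pass_filter()`): greedy agglomeration within
  a 0.5% total mass window (± 0.25% around the seed), seeds in
  descending peak-support order with ties to the smaller m/z, at most
  one member peak per spectrum per cluster (nearest to the seed) — this
  is what keeps the 0.30%-separated pair 7,597/7,620 from merging.
  Clusters present in ≥ 20% of spectra are retained ("minimum peak
  threshold", read as a prevalence fraction, the vendor's documented
  meaning).
* **Completion** (`cluster_and_complete()`): final windows are centre
  ± 0.25%, trimmed at midpoints so they never overlap; empty cells get
  the window maximum (above the same local reference), flagged when its
  S/N < 2. The matrix is complete by construction; flagged cells are
  real measurements, mirroring the vendor's estimate-in-all-spectra
  behaviour. Height is apex intensity, not fitted area — whether the
  original used areas is unknowable from print.

## Univariate screening and QC

Pooled-variance Student t (the analysis names the Student test; Welch
is available as an option), two-sided p-values, no multiple-testing
correction (mirroring the original; a Bonferroni column is emitted for
transparency). Two significance levels are surfaced rather than
reconciled: the stated strict 10⁻⁴ and the 0.05 actually used by the
printed peak table. Note the printed panel's T column is not
reproducible from its own means/SDs at n = 70/75 under either pooled
or Welch formulas (e.g. m/z 7,970 gives t ≈ 30.1, not the printed
61.2); the package reports its own correctly derived statistic and
makes no attempt to match that column.

Replicate QC (`qc_cv()`) matches detected peaks to target m/z within
± 0.25% and reports mass and intensity CVs: intra-assay = mean of
within-chip CVs, inter-assay = CV across all replicates pooled over
chips (the aggregation is unstated in print; pooling is our convention
and is what makes inter ≥ intra by construction). With the default
generator, 5 × 5 replicates land at ≈ 0.03% mass CV and ≈ 15%/19%
intensity CVs.

## The oblique tree

* **Splits.** Axis-parallel candidates are scanned exhaustively
  (midpoints between consecutive distinct values, ties to the smaller
  threshold). The oblique search over `w·x ≤ t`: for two candidate
  features and ≤ 64 samples it is *exact* — every distinct ordering of
  the projections is enumerated via the critical direction angles
  defined by sample pairs — which makes the small-instance oracle
  equivalence hold by construction; otherwise cyclic coordinate descent
  runs from the best axis split plus seeded random restarts (20 by
  default), with a fixed per-coordinate step grid and backward deletion
  of near-zero coefficients. Axis splits are always in the candidate
  set, so the oblique result never falls below the best axis split.
  Trained coefficients are scaled to unit maximum magnitude; the
  published tree's printed coefficients are stored verbatim.
* **Priors and costs** default to equal/unit and enter as per-class
  sample weights (the vendor exposes both; no values are printed).
* **Stopping and pruning.** Growth to purity, `min_node_size`
  (default 5) or `max_depth`; then minimal cost-complexity pruning with
  the penalty chosen by stratified 10-fold cross-validation under the
  1-SE rule. Everything is deterministic given the fit seed.
* **Published tree topology.** The printed description gives both
  splitters and the three terminal labels but not which child of the
  root carries the second splitter. Both candidate topologies were
  checked against the printed class-mean vectors; only "second splitter
  = left child" routes each class's mean to its own terminal, and that
  topology is hard-coded. Samples exactly on a threshold route left.
* **Importance.** Each split's realized Gini decrease is shared across
  its features by |coefficient|; every other feature earns the node's
  decrease times its surrogate association λ (the adjusted agreement of
  its best axis split with the primary left/right assignment). This is
  a deterministic simplification of CART's surrogate-decrease
  definition. Scores are scaled so the top feature is exactly 100.
  Importance is computed on the returned (pruned) model; whether the
  original importance table used the pruned or maximal tree is
  unstated.

## Evaluation

Counts are exact integers; percentages are full-precision internally
and rounded to two decimals only when printed (so 32/35 prints as
91.43). PPV is reported as not-applicable when nothing is predicted
positive. The experiment driver evaluates both the freshly trained
tree and the published fixed tree; simulation-based acceptance anchors
to the latter, because the vendor's trainer cannot be replicated
bit-for-bit while the printed decision function can be applied
exactly.

On feature vectors drawn directly from the printed class-conditional
distributions the published tree's margins exceed 3σ on both
splitters, so the printed performance figures act as lower bounds and
the simulated cohorts essentially saturate them. On fully rendered
spectra the additional 17% technical error widens the class spread and
the fixed tree concedes a few blind-test errors — a useful reminder
that the simulation meets the printed figures *because* it is built
from the printed distributions, not as independent validation.

## Numerical and engineering choices

* JSON (not YAML) for configurations and serialized trees: plain,
  diffable, no extra parser. Tree JSON carries a schema version;
  mismatches are explicit errors.
* Native spectrum format is per-spectrum CSV plus a cohort manifest
  (the original vendor format is proprietary); a minimal read-only
  mzML reader (uncompressed or zlib, 32/64-bit little-endian floats)
  is included for interoperability.
* Rolling minima use the van Herk O(n) algorithm; noise blocks are
  interpolated linearly between centres; all RNG flows through
  explicitly passed seeds (sub-seeds are derived arithmetically and
  stay below 2³¹).
* Scale-down note: the heaviest property suite (46 clusters across 10
  seeds) runs the full 145-spectrum pipeline ten times (~2.5 min);
  other Monte-Carlo suites use reduced acquisition windows where only
  the property under test, not cohort geometry, matters.

## Known limitations

* Independence across peaks is almost surely wrong for real sera
  (shared proteolytic fragments, shared binding chemistry); only
  marginal moments are printed, so nothing better is identifiable.
* The printed summary statistics already mix biological and technical
  variance; the generator adds technical error on top when rendering
  spectra, making rendered cohorts slightly *harder* than the printed
  world — conservative for lower-bound acceptance checks, but not a
  calibrated error model.
* The oblique optimizer is a reconstruction; it reproduces the
  *published* tree's behaviour exactly (the tree is stored, not
  refitted) but will not generally rediscover identical coefficients
  from data, and no attempt is made to.
* Printed T statistics and the 10⁻⁴ significance claim are internally
  inconsistent with the printed table; both are surfaced, neither is
  "fixed".
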