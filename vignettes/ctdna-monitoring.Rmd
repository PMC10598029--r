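---
title: "Dual-assay ctDNA quantification and molecular response monitoring"
author: "plasmatrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-assay ctDNA quantification and molecular response monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmatrack)
```

## The problem

Patients with aggressive metastatic carcinoma — the motivating setting is
cancer of unknown primary (CUP) treated with combined PD-1/CTLA-4 checkpoint
blockade — need response assessment earlier and more sensitively than
three-monthly imaging can provide. Circulating tumor DNA (ctDNA), the
tumor-derived fraction of plasma cell-free DNA (ccfDNA), falls and rises
with tumor burden on a time scale of weeks. `plasmatrack` implements a
complete, testable analysis chain for a dual-assay ctDNA monitoring design:

1. a **targeted route**: ultra-deep sequencing of a patient-specific panel
   of hotspot mutations, with unique molecular identifiers (UMIs)
   collapsing PCR duplicates into consensus molecules, yielding per-locus
   variant allele fractions (VAFs);
2. a **genome-wide route**: shallow whole-genome sequencing (sWGS) binned
   into fixed windows, from which a hidden Markov model estimates the
   plasma tumor fraction (TFx) and a copy-number profile.

Both routes are converted to a common unit — haploid genome equivalents per
millilitre of plasma (hGE/ml) — and the **molecular response** is the ratio
of first-follow-up to baseline ctDNA.

Because the motivating trial's raw sequencing and clinical data are under
controlled access, the package ships a first-class synthetic-data generator
(`simulate_cohort()`) that reproduces the statistical structure the
analysis assumes, so every downstream stage runs and is tested end-to-end
from code alone.

## The quantification model

### Targeted route

Reads sharing a UMI at a locus derive from one original plasma molecule.
`collapse_umi()` calls one consensus allele per (UMI, locus) family when
the majority fraction is at least `f_min` (default 0.75) and the family
holds at least `s_min` reads (default 1; these minima are package
defaults, exposed in the configuration, since assay protocols differ).
For a clonal heterozygous mutation on a diploid background, a plasma
tumor fraction `TFx` produces an expected VAF of `TFx / 2`; subclonality
and local copy number scale this as
`VAF = TFx * clonal_fraction * m / t` with `m` mutated of `t` total local
copies (the default `m/t = 1/2` is configurable — published protocols are
generally silent on the copy-number background of tracked hotspots).

`mean_vaf()` averages the per-locus VAFs that reach the ultra-deep
detection floor of 0.1%. Three outcomes are kept distinct: *detected*
(mean over passing loci), *not detected* (covered loci, none passing —
evidence of absence at assay sensitivity) and *not evaluable* (no usable
coverage). Loci that matched-normal sequencing reveals as inherited
heterozygous polymorphisms (`classify_germline()`: normal VAF ≥ 0.25
germline, ≤ 0.02 somatic, otherwise ambiguous and excluded with a
warning) must be removed before averaging, since a germline locus sits
near 50% VAF regardless of tumor burden.

### Genome-wide route

Bin counts are corrected in `correct_bins()`: a loess fit of count against
GC content removes amplification bias; division by a panel-of-normals
per-bin median (`normal_reference()`, built from healthy-donor sWGS the
same way) removes recurrent technical structure; log2 against the sample
median centres a copy-neutral genome at 0. Bins with mappability < 0.9 or
a degenerate reference are masked.

Plasma is a mixture: a fraction `TFx` of fragments from tumor cells with
integer copy number `c`, the rest from diploid cells. The expected log2
ratio of state `c` is

```
m(c) = log2( (TFx * c + 2 * (1 - TFx)) / 2 )
```

(`expected_log2()`). A five-state HMM (`c` in 0…4) with Normal emissions
`N(m(c), sigma^2)`, a sticky transition matrix (self-transition 0.99) and
shared `sigma` is fit by EM (`fit_hmm_em()`): scaled forward–backward
E-step, then a one-dimensional numerical M-step over `TFx` with `sigma`
profiled out in closed form, restarted over a grid of initial tumor
fractions; the best log-likelihood wins and Viterbi decoding gives the
final states. `arm_calls()` summarises decoded bins per chromosome arm
(gain/loss when at least half an arm's unmasked bins agree; an arm
reaching the threshold in both directions is *complex*) and the
**aneuploidy score** is the count of arms with a non-neutral call.
Estimates at or below `tfx_min = 0.04` are reported as not detected —
copy-number signal below a 4% tumor fraction is not reliably separable
from noise at shallow coverage.

### Numerical choices in the HMM

Three choices deserve explanation because the design was genuinely open:

* **Normal rather than Student-t emissions.** Heavier-tailed emissions
  are more robust to outlier bins but complicate the closed-form variance
  update; with loess + panel-of-normals correction upstream, residuals in
  simulation are close to Gaussian. The simplification is deliberate and
  documented; `sigma` is shared across states.
* **A state-distance parsimony prior.** The likelihood is exactly
  invariant under halving `TFx` while moving states from {1,3} to {0,4}
  (both give identical emission means), so the raw MLE cannot distinguish
  a 30% tumor fraction with single-copy events from a 15% fraction with
  homozygous deletions and amplifications. Transition and initial
  probabilities therefore down-weight entering state `c` by
  `exp(-penalty * |c - 2|)` (default `penalty = 2`), preferring the
  explanation closest to diploid. Penalty 1 proved too weak to break
  noise-driven ties at low tumor fraction; 2 and 3 behave identically on
  recovery grids, so the smaller value is the default.
* **Restart grid extended above 0.5.** EM restarts run from
  {0.05, …, 0.5} plus coarse high-burden restarts {0.65, 0.8}. Without
  the latter, every restart falls into the mirror basin when the true
  fraction exceeds one half (a planted 0.8 came back as 0.398 from all
  ten low restarts), biasing follow-up samples of progressing patients.
* Degenerate inputs: a decoded path that is entirely copy-neutral carries
  no copy-number evidence, and the fit reports `TFx = 0` rather than the
  (unidentifiable) EM value; the singular state `c = 0` at `TFx = 1` is
  clamped at a log2 floor of −8; EM convergence is declared at an
  absolute log-likelihood change below 1e−4 with a 50-iteration cap, and
  an unconverged fit is returned flagged, not discarded.

### Common unit and route policy

One haploid genome weighs ≈ 3.3 pg, so `hge_per_ml()` converts
`mean VAF × ccfDNA [pg/ml] / 3.3` and `TFx × ccfDNA [pg/ml] / 6.6`; under
the heterozygous assumption `mean VAF × 2 = TFx` the two routes agree
exactly (a package invariant tested to 1e−12). The targeted route is more
sensitive and has priority when both assays yield a measurement; once a
patient's route is fixed at baseline, follow-ups reuse it
(`choose_route()`, `quantify_samples()`), so longitudinal ratios compare
like with like. A follow-up in which the fixed route no longer detects
disease is a measured clearance (0 hGE/ml); if the other assay still sees
disease, the sample is flagged discordant.

`molecular_response()` classifies the first-follow-up/baseline ratio
against a cut-off. The default cut-off is 1.0 — any decline counts as
molecular response — because the motivating study shows its response
cut-off only graphically, without a printed value; the parameter is
exposed for sites that calibrate their own.

## Clinical scores and cohort statistics

* `stratify_tmb()`: tumor mutational burden high strictly above
  12 mutations/Mb (the strict inequality follows the trial's abstract
  wording; the boundary is pinned by a unit test and configurable).
* `classify_msi()` (MSI-high at ≥ 10%), `classify_pdl1()` (CPS or TPS ≥ 1),
  `classify_hrd()` (< 30 negative, 30–50 intermediate, > 50 positive;
  boundary values fall into the intermediate band).
* `metastasis_burden_score()`: sum of target-lesion diameters in cm plus
  banded points for the number of affected organs and per-organ metastasis
  counts, tertile-classified over the cohort (`classify_burden()`, ties to
  the lower class). The default bands (1/2/3 points for 1, 2–3, ≥ 4
  organs; 1/2/3 for 1, 2–5, > 5 metastases) are package assumptions —
  the original scoring table is not public — and the weight table is a
  required, documented configuration in any real analysis.
* `orr_exact_ci()` implements the Clopper–Pearson interval from beta
  quantiles; `fisher_exact_2x2()` the two-sided exact test under the
  probability-mass rule. Both are cross-checked in the test suite against
  independent enumeration and the reference implementations in `stats`.
* `km_logrank_cox()` wraps the `survival` package for product-limit
  medians, the log-rank test and Cox hazard ratios — routine statistics
  deliberately delegated, not re-implemented. No multiplicity adjustment
  is applied anywhere, matching exploratory trial practice.
* `median_split()` dichotomizes a biomarker at the cohort median —
  published prognostic cut-offs of this kind (e.g. a ccfDNA threshold of
  5.2 ng/ml) are cohort medians, not constants, and are recomputed per
  cohort.

### Trial design: Lachin–Foulkes sample size

`lachin_foulkes_n()` implements the log-rank sample-size computation for
exponential survival with uniform staggered entry: the probability that a
patient entering uniformly during accrual `R` and followed to `R + F`
has an observed event is

```
P(event; lambda) = 1 - exp(-lambda F) * (1 - exp(-lambda R)) / (lambda R)
```

and the required total size solves the power equation with null variance
taken at the allocation-weighted average hazard and alternative variance
at the per-group hazards (the hazard-difference statistic of the original
method; a log-hazard-ratio variant and an exponential dropout hazard are
also exposed). Under a design with hazard ratio 0.65, control median 2.18
months, two-sided α 0.05, 80% power, 24-month accrual and 12-month
minimal follow-up this computation yields 179 patients with 177 expected
events (the log-scale variant: 172/170). Published trial protocols often
report larger figures for nominally identical assumptions because of
group-sequential inflation or dropout allowances that the methods prose
does not restate; this function computes the stated assumptions and
nothing else, and reports its event probabilities so any such allowance
can be layered on explicitly.

## What the synthetic cohort emulates — and what it does not

`sim_config()` fixes the study conditions once:

* **Genome**: 22 autosomes × 2 arms × 20 bins by default — an abstraction
  of 1-Mb binning at roughly one third of hg19 resolution, chosen so that
  arm-level decoding near the 4% detection floor has a meaningful number
  of bins per arm while a full cohort analysis stays in the tens of
  seconds. Per-bin GC and mappability are drawn once from a genome seed
  shared by all samples of a run.
* **Counts**: negative binomial with mean 5000 and size 2000 per diploid
  bin, giving a corrected log2-ratio spread of ≈ 0.045 — the noise scale
  at which the recovery properties below are stated, and comparable to
  well-behaved shallow-WGS bins at trial-like depth. GC bias (linear and
  quadratic coefficients) is off by default and switched on in the tests
  that exercise the correction.
* **Tumors**: two trackable hotspot SNVs per patient (15% of tumors have
  none and depend on the genome-wide route); arm alteration probability
  0.2; TMB uniform on 13.3–22.8 (high stratum, ~16% of patients) or
  0–7.84 mutations/Mb.
* **Plasma**: ccfDNA log-normal with median 5.2 and IQR ≈ 2.3–14.9 ng/ml
  (a distributional convenience fitted to published summary statistics,
  not ground truth); baseline TFx log-normal with median 0.15 clamped to
  [0.02, 0.7]; within-patient ccfDNA drift between timepoints is mild
  (sdlog 0.15), so response ratios reflect tumor dynamics.
* **Trajectories**: responders clear ctDNA by first follow-up (40%) or
  decline to ≈ 0.25× per interval; progressors rise ≈ 3× (truncated above
  1); radiologically stable disease declines mildly (≈ 0.7×), following
  the observation that on-treatment stabilization shows falling ctDNA.
  Sampling every 3 months, up to 3 follow-ups;
  early-discontinuation patients contribute a baseline only.
* **Outcomes**: exponential survival with stratum PFS medians 2.18/3.35
  months (the trial's own design assumption) and OS medians 3.6/18.3,
  administratively censored at 24 months.

What passing tests on this generator do **not** show about real plasma
data: fragment-size structure and size selection, sequencing batch and
index-hopping artifacts, CHIP (clonal hematopoiesis) variants that mimic
low-VAF somatic signal, subclonal copy-number mixtures, focal events
smaller than an arm, and non-exponential survival. The generator is the
statistical null bed for the pipeline's correctness, not a claim about
biology.

## Worked example

```{r example}
cfg <- sim_config()
cohort <- simulate_cohort(12, cfg, seed = 7)
pipeline <- run_cohort_pipeline(cohort)
pipeline$detection
head(pipeline$response)
```

Agreement between the classified molecular response and the generating
trajectory class is the package's end-to-end acceptance property (≥ 95%
over a 50-patient cohort; see `tests/testthat/test-acceptance.R`).

## Problem sizes used in the shipped checks

Recovery of planted tumor fractions is asserted on 400-bin profiles with
emission noise 0.05 over 20 replicates per level {0.05, …, 0.5}
(tolerance ± 0.05, ≥ 90% of replicates, null estimates ≤ 0.04); Viterbi
decoding is compared against exhaustive enumeration of all 5^6 paths on
6-bin instances; the end-to-end cohort check uses 50 patients on the
default genome; survival-median recovery uses a 500-patient cohort on a
reduced 4-chromosome genome. These sizes are the package's chosen
desk-scale study conditions and are fixed in the test code.

## Known limitations

* The HMM has no subclone fraction or ploidy parameter: `TFx` is a single
  clonal mixture fraction against a diploid background, which matches the
  quantification use but under-models tumors with genome doubling.
* Sex chromosomes are not handled; the simulated genome is autosomal.
* The Fisher test and exact intervals are small-cohort tools; for large
  cohorts asymptotic methods would be preferable.
* HRD scores, TMB, MSI, CPS/TPS are consumed as numbers; their
  computation from raw sequencing is out of scope.
* The molecular-response cut-off (default 1.0) is a policy parameter, not
  an estimated quantity; calibrating it against outcomes requires a
  cohort with follow-up, which the package's statistics modules can then
  analyse.
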