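# plasmatrack

Dual-assay quantification of circulating tumor DNA (ctDNA) and
longitudinal molecular-response monitoring for oncology cohorts, with a
built-in synthetic-data generator so the whole pipeline is testable
without access-controlled patient data.

## Who this is for

Translational groups running liquid-biopsy monitoring alongside a trial —
the motivating setting is cancer of unknown primary (CUP) under combined
PD-1/CTLA-4 checkpoint blockade — who quantify ctDNA two ways:

* **Targeted**: ultra-deep sequencing of patient-specific hotspot
  mutations with UMI (unique molecular identifier) barcoding; reads are
  collapsed to consensus molecules and per-locus variant allele fractions
  (VAF ≥ 0.1%) are averaged per sample.
* **Genome-wide**: shallow whole-genome sequencing binned into fixed
  windows; after GC/mappability correction against a panel of normals, a
  five-state hidden Markov model fit by EM estimates the plasma tumor
  fraction (TFx, detection floor 4%) and a copy-number profile, from
  which arm-level calls and an aneuploidy score are derived.

## The model in brief

Plasma DNA is a mixture of a tumor fraction `TFx` with integer copy
number `c` and diploid normal DNA, so a bin's expected log2 ratio is

    m(c) = log2( (TFx·c + 2(1 − TFx)) / 2 )

and a clonal heterozygous hotspot has expected `VAF = TFx / 2`. Each
haploid genome weighs ≈ 3.3 pg, hence

    hGE/ml = mean VAF × ccfDNA[pg/ml] / 3.3  =  TFx × ccfDNA[pg/ml] / 6.6

— identical by construction whenever `mean VAF × 2 = TFx`. The targeted
route has priority when both assays measure; a patient's route is fixed
at baseline and reused for all follow-ups. Molecular response is the
ratio of first-follow-up to baseline hGE/ml (clearance → ratio 0;
default cut-off 1.0).

Clinical stratifiers (TMB > 12 mut/Mb, MSI ≥ 10%, PD-L1 CPS/TPS ≥ 1, HRD
<30/30–50/>50, a tertile-classified metastasis burden score) and cohort
statistics (Clopper–Pearson exact intervals, Fisher's exact test,
Kaplan–Meier/log-rank/Cox via the `survival` package, and the
Lachin–Foulkes log-rank sample-size computation for exponential survival
with uniform accrual) complete the trial analysis.

## Worked example

```r
library(plasmatrack)

# trial-style response statistics
ci <- orr_exact_ci(5, 31)
sprintf("ORR %.1f%% (95%% CI %.1f-%.1f%%)", ci$orr_pct, ci$lower_pct, ci$upper_pct)
#> "ORR 16.1% (95% CI 5.5-33.7%)"
fisher_exact_2x2(matrix(c(3, 2, 2, 24), 2, byrow = TRUE))
#> 0.0199  (responders by TMB stratum, 3/5 vs 2/26)

# synthetic cohort end-to-end: simulate, quantify, classify
cohort   <- simulate_cohort(12, sim_config(), seed = 7)
pipeline <- run_cohort_pipeline(cohort)
pipeline$detection
#>     method n_detected n_total fraction_pct
#> 1 targeted         10      12     83.33333
#> 2     swgs         12      12    100.00000
#> 3 combined         12      12    100.00000
head(subset(pipeline$response, class != "not_evaluable"), 3)
#>   patient_id        route baseline_hge followup_hge     ratio                 class
#> 2       P002 targeted_vaf     35.76402     30.80318 0.8612898    molecular_response
#> 3       P003 targeted_vaf     12.30379      0.00000 0.0000000    molecular_response
#> 4       P004 targeted_vaf    153.03030    353.20848 2.3080950 molecular_progression
```

`baseline_hge`/`followup_hge` are ctDNA concentrations in haploid genome
equivalents per ml plasma; `ratio` below the cut-off (here P003's
complete clearance) classifies the patient as a molecular responder at
the first follow-up, three simulated months into treatment.

## Layout

* `R/sim_cohort.R` — synthetic tumors, UMI reads, bin counts,
  trajectories, full cohorts (`simulate_*`, `run_cohort_pipeline`)
* `R/panel_design.R` — hotspot selection and 2× probe tiling, BED I/O
* `R/umi_vaf.R` — UMI consensus collapse, mean VAF, germline filtering
* `R/swgs_tfx.R` — bin correction, HMM/EM tumor fraction, arm calls,
  aneuploidy score
* `R/ctdna_quant.R` — hGE/ml conversion, route policy, molecular response,
  detection accounting
* `R/clinical_scores.R` — TMB/MSI/PD-L1/HRD strata, metastasis burden
* `R/cohort_stats.R` — exact intervals, Fisher, survival wrappers,
  Lachin–Foulkes design
* `vignettes/ctdna-monitoring.Rmd` — the methods vignette (model,
  assumptions, numerical choices, generator conditions, limitations)
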