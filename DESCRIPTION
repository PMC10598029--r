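Package: plasmatrack
Title: Dual-Assay Circulating Tumor DNA Quantification and Molecular
    Response Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies circulating tumor DNA (ctDNA) in plasma by two
    complementary assays and tracks it longitudinally during therapy.
    The targeted route collapses unique-molecular-identifier (UMI) read
    families at patient-specific hotspot loci into consensus molecules
    and averages variant allele fractions; the genome-wide route
    estimates tumor fraction from GC- and mappability-corrected shallow
    whole-genome bin counts with a hidden Markov model fit by
    expectation-maximization, from which arm-level copy-number calls and
    an aneuploidy score are derived. Both assays are converted to
    haploid genome equivalents per millilitre of plasma under a shared
    priority rule, and on-treatment molecular response is scored as the
    ratio of first follow-up to baseline ctDNA. Companion tools design
    tiled hybrid-capture hotspot panels, compute clinical stratifiers
    (tumor mutational burden, microsatellite instability, PD-L1,
    homologous recombination deficiency, metastasis burden), run cohort
    response and survival statistics including exact binomial intervals
    and a Lachin-Foulkes log-rank sample-size calculation, and simulate
    complete synthetic cohorts so the whole pipeline is testable without
    access-controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
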