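# Gene symbols used to label simulated hotspot variants; drawn from genes
# recurrently mutated in carcinomas so synthetic panels look like real ones.
.gene_pool <- c(
  "TP53", "KRAS", "NRAS", "PIK3CA", "CDKN2A", "CDKN2B", "STK11", "KEAP1",
  "ARID1A", "SMAD4", "PTEN", "APC", "BRAF", "EGFR", "ERBB2", "MYC",
  "CCND1", "FGFR1", "FGFR2", "FGFR3", "NOTCH1", "NF1", "RB1", "ATM",
  "BRCA1", "BRCA2", "CHEK2", "IDH1", "IDH2", "CTNNB1", "KMT2D", "KMT2C",
  "TERT", "AKT1", "MTOR", "GNAS", "SF3B1", "KDM6A", "FBXW7", "RNF43",
  "POLE")

#' Configuration for the synthetic cohort generator
#'
#' Bundles every tunable of the simulator with defaults chosen to emulate a
#' relapsed/refractory carcinoma-of-unknown-primary immunotherapy cohort:
#' a miniature diploid genome observed through noisy GC-biased bin counts,
#' hotspot variants read out as UMI consensus family counts, ~16% TMB-high
#' patients, response-dependent ctDNA trajectories and exponential survival
#' by stratum.
#'
#' @param n_chrom number of (autosomal) chromosomes in the miniature genome.
#' @param bins_per_arm bins per chromosome arm (two arms per chromosome).
#' @param bin_size bin width in bp (bookkeeping only).
#' @param genome_seed seed fixing the genome-level covariates (GC,
#'   mappability) shared by every sample of a run.
#' @param snv_count hotspot variants per tumor (default 2, the panel design
#'   target).
#' @param prob_no_snv probability a tumor carries no trackable somatic
#'   point variant and is quantifiable only through copy number.
#' @param arm_alteration_prob per-arm probability of an arm-level
#'   copy-number alteration.
#' @param p_gain probability an altered arm is a gain (copy 3) rather than
#'   a loss (copy 1).
#' @param max_copy maximal simulated integer copy number.
#' @param p_tmb_high fraction of TMB-high patients (default 0.16).
#' @param tmb_high_range,tmb_low_range uniform TMB ranges (mutations/Mb)
#'   for the two strata.
#' @param p_response_high,p_response_low objective-response probability by
#'   TMB stratum.
#' @param baseline_tfx_meanlog,baseline_tfx_sdlog log-normal baseline tumor
#'   fraction; clamped to `[0.02, 0.7]`.
#' @param decline_factor_meanlog,decline_factor_sdlog per-interval
#'   multiplicative change of tumor fraction for partial decliners.
#' @param progression_factor_meanlog,progression_factor_sdlog same for
#'   progressors (truncated above 1).
#' @param stable_factor_meanlog,stable_factor_sdlog same for radiologically
#'   stable patients (mild decline: on-treatment stabilization shows up as
#'   decreasing ctDNA).
#' @param p_clearance probability a responder clears ctDNA completely by
#'   the first follow-up.
#' @param ccfdna_meanlog,ccfdna_sdlog log-normal total ccfDNA concentration
#'   (ng/ml plasma); defaults reproduce a median of 5.2 with interquartile
#'   range roughly 2.3-14.9.
#' @param ccf_drift_sd within-patient log-scale drift of ccfDNA between
#'   timepoints.
#' @param plasma_ml_range uniform plasma volume range (ml).
#' @param umi_depth consensus families simulated per locus.
#' @param umi_error_rate per-read sequencing/PCR error probability.
#' @param family_size reads per UMI family in read-level simulation.
#' @param false_family_rate per-family probability that errors fabricate an
#'   alt consensus family at consensus level.
#' @param mean_depth expected reads per copy-neutral bin.
#' @param nb_size negative-binomial size (dispersion) of bin counts.
#' @param gc_lin,gc_quad linear and quadratic GC bias coefficients around
#'   GC 0.45.
#' @param pfs_median_low,pfs_median_high exponential PFS medians (months)
#'   by TMB stratum.
#' @param os_median_low,os_median_high exponential OS medians (months).
#' @param censor_months administrative censoring time.
#' @param followup_interval months between successive plasma samples.
#' @param max_followups maximal follow-up samples per patient.
#' @param n_normals healthy donors simulated for the panel of normals.
#' @return named list of class `"sim_config"`.
#' @export
sim_config <- function(n_chrom = 22, bins_per_arm = 20, bin_size = 1e6,
                       genome_seed = 42,
                       snv_count = 2, prob_no_snv = 0.15,
                       arm_alteration_prob = 0.2, p_gain = 0.5,
                       max_copy = 4,
                       p_tmb_high = 0.16,
                       tmb_high_range = c(13.3, 22.8),
                       tmb_low_range = c(0, 7.84),
                       p_response_high = 0.6, p_response_low = 0.077,
                       baseline_tfx_meanlog = log(0.15),
                       baseline_tfx_sdlog = 0.5,
                       decline_factor_meanlog = log(0.25),
                       decline_factor_sdlog = 0.3,
                       progression_factor_meanlog = log(3),
                       progression_factor_sdlog = 0.3,
                       stable_factor_meanlog = log(0.7),
                       stable_factor_sdlog = 0.15,
                       p_clearance = 0.4,
                       ccfdna_meanlog = log(5.2), ccfdna_sdlog = 1.383,
                       ccf_drift_sd = 0.15,
                       plasma_ml_range = c(4.3, 14.2),
                       umi_depth = 2000, umi_error_rate = 1e-3,
                       family_size = 3, false_family_rate = 1e-4,
                       mean_depth = 5000, nb_size = 2000,
                       gc_lin = 0, gc_quad = 0,
                       pfs_median_low = 2.18, pfs_median_high = 3.35,
                       os_median_low = 3.6, os_median_high = 18.3,
                       censor_months = 24,
                       followup_interval = 3, max_followups = 3,
                       n_normals = 8) {
  cfg <- as.list(environment())
  if (cfg$prob_no_snv < 0 || cfg$prob_no_snv > 1)
    stop("prob_no_snv must lie in [0, 1]")
  if (cfg$arm_alteration_prob < 0 || cfg$arm_alteration_prob > 1)
    stop("arm_alteration_prob must lie in [0, 1]")
  if (cfg$umi_error_rate < 0 || cfg$umi_error_rate > 0.01)
    stop("umi_error_rate must lie in [0, 0.01]")
  if (cfg$p_tmb_high < 0 || cfg$p_tmb_high > 1)
    stop("p_tmb_high must lie in [0, 1]")
  if (cfg$max_copy < 3) stop("max_copy must be >= 3")
  if (diff(cfg$tmb_high_range) < 0 || diff(cfg$tmb_low_range) < 0)
    stop("TMB ranges must be increasing")
  class(cfg) <- "sim_config"
  cfg
}

#' Miniature genome layout shared by every simulated sample
#'
#' Bin coordinates are deterministic; per-bin GC and mappability are drawn
#' once from `config$genome_seed` so all samples and normals of a run see
#' the same genome-level covariates.
#'
#' @param config a [sim_config()].
#' @return data.frame: `chrom`, `arm`, `start`, `end`, `gc`, `mappability`.
#' @export
sim_genome <- function(config = sim_config()) {
  chroms <- paste0("chr", seq_len(config$n_chrom))
  layout <- expand.grid(bin = seq_len(config$bins_per_arm),
                        arm = c("p", "q"), chrom = chroms,
                        stringsAsFactors = FALSE)
  layout <- layout[order(match(layout$chrom, chroms),
                         layout$arm, layout$bin), ]
  idx <- stats::ave(seq_len(nrow(layout)), layout$chrom,
                    FUN = seq_along)
  layout$start <- as.integer((idx - 1) * config$bin_size)
  layout$end <- as.integer(idx * config$bin_size)
  set.seed(config$genome_seed)
  layout$gc <- stats::runif(nrow(layout), 0.3, 0.7)
  layout$mappability <- ifelse(stats::runif(nrow(layout)) < 0.05,
                               stats::runif(nrow(layout), 0.5, 0.9),
                               stats::runif(nrow(layout), 0.92, 1.0))
  rownames(layout) <- NULL
  layout[, c("chrom", "arm", "start", "end", "gc", "mappability")]
}

#' Simulate one tumor
#'
#' Draws a TMB stratum (or honors a requested one), hotspot point variants
#' with tissue VAFs and an arm-level copy-number profile on the miniature
#' genome. A tumor with neither point variants nor copy-number alterations
#' is ctDNA-silent and flagged as such; unless `allow_silent` is set, a
#' variant-free tumor is guaranteed at least one altered arm so the
#' genome-wide assay has something to see.
#'
#' @param seed integer seed; identical (seed, config) gives an identical
#'   tumor.
#' @param config a [sim_config()].
#' @param patient_id identifier carried through all outputs.
#' @param tmb_stratum `"high"`, `"low"` or `NULL` (drawn with
#'   `p_tmb_high`).
#' @param snv_count override for the number of point variants (e.g. 0).
#' @param allow_silent allow a tumor with no somatic signal at all.
#' @return list of class `"sim_tumor"`: `patient_id`, `snvs` (data.frame
#'   `gene`, `chrom`, `pos`, `ref`, `alt`, `clonal_fraction`,
#'   `tissue_vaf`), `cna` (data.frame `chrom`, `arm`, `copy_number`),
#'   `tmb`, `tmb_stratum`, `ctdna_silent`.
#' @export
simulate_tumor <- function(seed, config = sim_config(), patient_id = "P1",
                           tmb_stratum = NULL, snv_count = NULL,
                           allow_silent = FALSE) {
  set.seed(seed)
  genome <- sim_genome(config)
  set.seed(seed)  # genome generation must not perturb the tumor draw
  if (is.null(tmb_stratum))
    tmb_stratum <- if (stats::runif(1) < config$p_tmb_high) "high" else "low"
  rng <- if (tmb_stratum == "high") config$tmb_high_range else
    config$tmb_low_range
  tmb <- stats::runif(1, rng[1], rng[2])

  if (is.null(snv_count)) {
    snv_count <- if (stats::runif(1) < config$prob_no_snv) 0L else
      config$snv_count
  }
  arm_key <- unique(genome[, c("chrom", "arm")])
  altered <- stats::runif(nrow(arm_key)) < config$arm_alteration_prob
  copy <- ifelse(altered,
                 ifelse(stats::runif(nrow(arm_key)) < config$p_gain,
                        pmin(3L, config$max_copy), 1L), 2L)
  if (snv_count == 0 && all(copy == 2L) && !allow_silent) {
    copy[sample(length(copy), 1)] <- 3L
  }
  cna <- data.frame(chrom = arm_key$chrom, arm = arm_key$arm,
                    copy_number = as.integer(copy),
                    stringsAsFactors = FALSE)

  if (snv_count > 0) {
    bases <- c("A", "C", "G", "T")
    # unique loci: one per distinct bin
    pick <- sample(nrow(genome), snv_count)
    pos <- genome$start[pick] +
      as.integer(floor(stats::runif(snv_count) * config$bin_size))
    ref <- sample(bases, snv_count, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1),
                  character(1))
    cf <- c(1, stats::runif(max(0, snv_count - 1), 0.5, 1))[seq_len(snv_count)]
    snvs <- data.frame(gene = sample(.gene_pool, snv_count),
                       chrom = genome$chrom[pick], pos = pos,
                       ref = ref, alt = unname(alt),
                       clonal_fraction = cf,
                       tissue_vaf = pmin(0.95, cf *
                                           stats::runif(snv_count, 0.2, 0.6)),
                       stringsAsFactors = FALSE)
  } else {
    snvs <- data.frame(gene = character(), chrom = character(),
                       pos = integer(), ref = character(),
                       alt = character(), clonal_fraction = numeric(),
                       tissue_vaf = numeric())
  }
  structure(list(patient_id = patient_id, snvs = snvs, cna = cna,
                 tmb = tmb, tmb_stratum = tmb_stratum,
                 ctdna_silent = nrow(snvs) == 0 && all(cna$copy_number == 2L)),
            class = "sim_tumor")
}

#' Simulate UMI-tagged reads at a tumor's hotspot loci
#'
#' Each locus receives `depth` original molecules (UMI families) of
#' `family_size` reads. A molecule carries the variant allele with
#' probability `VAF_true = true_tfx * clonal_fraction * m / t`, where `m/t`
#' is the mutated over total local allele count (default heterozygous
#' diploid, `1/2`); every read then suffers an independent allele-flipping
#' error with probability `error_rate`.
#'
#' @param tumor a [simulate_tumor()] result with at least one variant.
#' @param true_tfx tumor fraction of the plasma sample in `[0, 1]`.
#' @param depth UMI families per locus (>= 1).
#' @param error_rate per-read error probability in `[0, 0.01]`.
#' @param seed integer seed.
#' @param family_size reads per family.
#' @param panel optional panel data.frame (`chrom`, `start`, `end`); loci
#'   outside it raise an error.
#' @param mut_copies,total_copies local allele-count model for the variant
#'   (defaults 1 and 2).
#' @return data.frame of reads: `umi`, `chrom`, `pos`, `ref`, `alt`,
#'   `allele`.
#' @export
simulate_umi_reads <- function(tumor, true_tfx, depth = 2000,
                               error_rate = 1e-3, seed = 1,
                               family_size = 3, panel = NULL,
                               mut_copies = 1, total_copies = 2) {
  if (depth < 1) stop("depth must be >= 1")
  if (error_rate < 0 || error_rate > 0.01)
    stop("error_rate must lie in [0, 0.01]")
  if (true_tfx < 0 || true_tfx > 1) stop("true_tfx must lie in [0, 1]")
  snvs <- tumor$snvs
  if (nrow(snvs) == 0) stop("tumor has no point variants to read out")
  if (!is.null(panel)) {
    for (i in seq_len(nrow(snvs))) {
      hit <- panel$chrom == snvs$chrom[i] & panel$start <= snvs$pos[i] &
        panel$end > snvs$pos[i]
      if (!any(hit))
        stop("locus ", snvs$chrom[i], ":", snvs$pos[i], " outside panel")
    }
  }
  set.seed(seed)
  out <- vector("list", nrow(snvs))
  for (i in seq_len(nrow(snvs))) {
    vaf_true <- true_tfx * snvs$clonal_fraction[i] *
      mut_copies / total_copies
    molecule_is_alt <- stats::runif(depth) < vaf_true
    true_allele <- ifelse(molecule_is_alt, snvs$alt[i], snvs$ref[i])
    reads_true <- rep(true_allele, each = family_size)
    flip <- stats::runif(depth * family_size) < error_rate
    other <- ifelse(reads_true == snvs$ref[i], snvs$alt[i], snvs$ref[i])
    allele <- ifelse(flip, other, reads_true)
    out[[i]] <- data.frame(
      umi = rep(sprintf("UMI%06d", seq_len(depth)), each = family_size),
      chrom = snvs$chrom[i], pos = snvs$pos[i],
      ref = snvs$ref[i], alt = snvs$alt[i], allele = allele,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# GC bias curve applied to expected bin depth
.gc_bias <- function(gc, config) {
  pmax(0.05, 1 + config$gc_lin * (gc - 0.45) +
         config$gc_quad * (gc - 0.45)^2)
}

#' Simulate genome-binned read counts for one plasma sample
#'
#' Expected depth per bin is proportional to the plasma mixture
#' `(true_tfx * c + 2 (1 - true_tfx)) / 2` of the bin's tumor copy number
#' `c` against the diploid background, modulated by the configured GC bias;
#' counts are negative-binomial around that expectation.
#'
#' @param tumor a [simulate_tumor()] result (its `cna` defines per-arm
#'   copy numbers); pass `NULL` for a copy-neutral (healthy) genome.
#' @param true_tfx tumor fraction in `[0, 1]`.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return data.frame: `chrom`, `arm`, `start`, `end`, `gc`,
#'   `mappability`, `count`.
#' @export
simulate_bin_counts <- function(tumor, true_tfx, config = sim_config(),
                                seed = 1) {
  if (true_tfx < 0 || true_tfx > 1) stop("true_tfx must lie in [0, 1]")
  genome <- sim_genome(config)
  if (is.null(tumor)) {
    copy <- rep(2L, nrow(genome))
  } else {
    key <- paste(genome$chrom, genome$arm)
    ckey <- paste(tumor$cna$chrom, tumor$cna$arm)
    copy <- tumor$cna$copy_number[match(key, ckey)]
  }
  mix <- (true_tfx * copy + 2 * (1 - true_tfx)) / 2
  mu <- config$mean_depth * mix * .gc_bias(genome$gc, config)
  set.seed(seed)
  genome$count <- stats::rnbinom(nrow(genome), mu = mu,
                                 size = config$nb_size)
  genome
}

#' Simulate a longitudinal tumor-fraction trajectory
#'
#' @param response_class one of `"clearance"`, `"partial_decline"`,
#'   `"stable"`, `"progression"`.
#' @param baseline_tfx starting tumor fraction (> 0 unless the disease is
#'   undetectable throughout).
#' @param n_followups number of follow-up timepoints.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return numeric vector of length `n_followups + 1`: tumor fraction at
#'   baseline and each follow-up. Clearance reaches 0 at the first
#'   follow-up; progression factors are truncated above 1.
#' @export
simulate_trajectory <- function(response_class, baseline_tfx,
                                n_followups = 1, config = sim_config(),
                                seed = 1) {
  classes <- c("clearance", "partial_decline", "stable", "progression")
  if (!response_class %in% classes)
    stop("response_class must be one of: ", paste(classes, collapse = ", "))
  set.seed(seed)
  if (response_class == "clearance")
    return(c(baseline_tfx, rep(0, n_followups)))
  par <- switch(response_class,
    partial_decline = c(config$decline_factor_meanlog,
                        config$decline_factor_sdlog),
    stable = c(config$stable_factor_meanlog, config$stable_factor_sdlog),
    progression = c(config$progression_factor_meanlog,
                    config$progression_factor_sdlog))
  fac <- stats::rlnorm(n_followups, par[1], par[2])
  if (response_class == "progression") fac <- pmax(fac, 1.05)
  tfx <- baseline_tfx * cumprod(c(1, fac))[-1]
  c(baseline_tfx, pmin(tfx, 0.95))
}

#' Simulate a complete synthetic cohort
#'
#' Generates patients (tumors, clinical covariates, survival), longitudinal
#' plasma samples with true tumor fractions following response-dependent
#' trajectories, per-sample hotspot consensus family counts and binned
#' read counts, a healthy-donor panel of normals, and the patient-specific
#' capture panel — everything the analysis pipeline consumes, optionally
#' written to disk in the package's plain-text formats.
#'
#' The TMB-high count is fixed at `round(p_tmb_high * n_patients)` and
#' assigned to a random patient subset, mirroring a stratified design.
#' Radiologic best response is drawn per stratum; responders follow
#' clearance or partial-decline trajectories, progressors rising ones, and
#' stable disease declines mildly. Early-discontinuation patients
#' contribute a baseline sample only.
#'
#' @param n_patients number of patients (>= 2).
#' @param config a [sim_config()].
#' @param seed integer master seed.
#' @param outdir optional directory; when given, writes `panel.bed`,
#'   `samples.csv`, `clinical.csv`, `lesions.csv`, `variants/<sample>.tsv`,
#'   `bins/<sample>.tsv` and `normals/normal<i>.tsv`.
#' @return list of class `"sim_cohort"`: `patients` (clinical data.frame),
#'   `samples`, `lesions`, `tumors` (named list), `variant_obs` (named list
#'   of per-sample observation data.frames), `bin_counts` (named list),
#'   `normals` (list), `panel` (probe data.frame), `truth` (per-patient
#'   trajectory class and per-sample true tumor fraction).
#' @export
simulate_cohort <- function(n_patients, config = sim_config(), seed = 1,
                            outdir = NULL) {
  if (n_patients < 2) stop("n_patients must be >= 2")
  set.seed(seed)
  n_high <- round(config$p_tmb_high * n_patients)
  strata <- rep("low", n_patients)
  if (n_high > 0) strata[sample(n_patients, n_high)] <- "high"
  ids <- sprintf("P%03d", seq_len(n_patients))

  patients <- list(); samples <- list(); lesions <- list()
  tumors <- list(); variant_obs <- list(); bin_counts <- list()
  truth_pat <- list(); truth_smp <- list()

  resp_levels <- c("CR", "PR", "SD", "PD", "early_discontinuation")
  for (i in seq_len(n_patients)) {
    pid <- ids[i]
    pseed <- (seed + 7919L * i) %% .Machine$integer.max
    tumor <- simulate_tumor(pseed, config, patient_id = pid,
                            tmb_stratum = strata[i])
    tumors[[pid]] <- tumor

    set.seed(pseed + 1L)
    p_resp <- if (strata[i] == "high") config$p_response_high else
      config$p_response_low
    responder <- stats::runif(1) < p_resp
    if (responder) {
      response <- sample(c("CR", "PR"), 1)
      traj_class <- if (stats::runif(1) < config$p_clearance) "clearance"
                    else "partial_decline"
    } else {
      response <- sample(c("SD", "PD", "early_discontinuation"), 1,
                         prob = c(0.1, 0.5, 0.4))
      traj_class <- switch(response, SD = "stable",
                           PD = "progression",
                           early_discontinuation = "progression")
    }
    n_fu <- if (response == "early_discontinuation") 0L else
      sample(seq_len(config$max_followups), 1)
    baseline_tfx <- min(0.7, max(0.02, stats::rlnorm(
      1, config$baseline_tfx_meanlog, config$baseline_tfx_sdlog)))
    tfx_series <- simulate_trajectory(traj_class, baseline_tfx, n_fu,
                                      config, seed = pseed + 2L)

    # survival: exponential by stratum, administratively censored
    set.seed(pseed + 3L)
    med_pfs <- if (strata[i] == "high") config$pfs_median_high else
      config$pfs_median_low
    med_os <- if (strata[i] == "high") config$os_median_high else
      config$os_median_low
    pfs_raw <- stats::rexp(1, log(2) / med_pfs)
    os_raw <- stats::rexp(1, log(2) / med_os)
    pfs <- min(pfs_raw, config$censor_months)
    os <- min(os_raw, config$censor_months)

    # lesions: organ count roughly as observed in such cohorts
    n_org <- sample(1:5, 1, prob = c(0.26, 0.29, 0.29, 0.13, 0.03))
    org_names <- sample(c("liver", "lung", "bone", "lymph_node",
                          "peritoneum", "pleura", "soft_tissue",
                          "adrenal"), n_org)
    for (o in org_names) {
      n_met <- sample(1:8, 1)
      n_target <- sample(1:2, 1)
      lesions[[length(lesions) + 1L]] <- data.frame(
        patient_id = pid, organ = o, n_metastases = n_met,
        diameter_mm = round(stats::runif(n_target, 10, 60), 1),
        stringsAsFactors = FALSE)
    }

    patients[[i]] <- data.frame(
      patient_id = pid, tmb = tumor$tmb, tmb_stratum = strata[i],
      ecog = sample(0:2, 1, prob = c(0.39, 0.51, 0.10)),
      msi_fraction = stats::runif(1, 0, 0.05),
      cps = if (stats::runif(1) < 0.5) round(stats::rexp(1, 1 / 5), 1)
            else NA_real_,
      tps = if (stats::runif(1) < 0.4) round(stats::rexp(1, 1 / 5), 1)
            else NA_real_,
      hrd_score = round(stats::rlnorm(1, log(22), 0.45), 1),
      response = response,
      pfs_months = round(max(pfs, 0.03), 2),
      pfs_event = as.integer(pfs_raw <= config$censor_months),
      os_months = round(max(os, 0.03), 2),
      os_event = as.integer(os_raw <= config$censor_months),
      stringsAsFactors = FALSE)
    truth_pat[[i]] <- data.frame(patient_id = pid,
                                 trajectory_class = traj_class,
                                 responder = responder,
                                 stringsAsFactors = FALSE)

    # plasma samples and assay readouts
    ccf_base <- stats::rlnorm(1, config$ccfdna_meanlog, config$ccfdna_sdlog)
    for (t in seq_along(tfx_series)) {
      sid <- sprintf("%s_T%d", pid, t - 1L)
      tp <- (t - 1L) * config$followup_interval
      ccf <- if (t == 1) ccf_base else
        ccf_base * stats::rlnorm(1, 0, config$ccf_drift_sd)
      samples[[length(samples) + 1L]] <- data.frame(
        patient_id = pid, sample_id = sid, timepoint = tp,
        true_tfx = tfx_series[t],
        ccfdna_ng_per_ml = round(ccf, 3),
        plasma_ml = round(stats::runif(1, config$plasma_ml_range[1],
                                       config$plasma_ml_range[2]), 1),
        stringsAsFactors = FALSE)
      truth_smp[[length(truth_smp) + 1L]] <- data.frame(
        sample_id = sid, true_tfx = tfx_series[t],
        stringsAsFactors = FALSE)

      sseed <- (pseed + 101L * t) %% .Machine$integer.max
      if (nrow(tumor$snvs) > 0) {
        variant_obs[[sid]] <- .simulate_family_counts(
          tumor, tfx_series[t], config, sseed)
      }
      bin_counts[[sid]] <- simulate_bin_counts(tumor, tfx_series[t],
                                               config, sseed + 1L)
    }
  }

  normals <- lapply(seq_len(config$n_normals), function(j) {
    simulate_bin_counts(NULL, 0, config,
                        seed = (seed + 7717L * j) %% .Machine$integer.max)
  })

  # patient-specific capture panel from the tissue variant lists
  tissue_variants <- do.call(rbind, lapply(tumors, function(tm) {
    if (nrow(tm$snvs) == 0) return(NULL)
    data.frame(patient_id = tm$patient_id, gene = tm$snvs$gene,
               chrom = tm$snvs$chrom, pos = tm$snvs$pos,
               ref = tm$snvs$ref, alt = tm$snvs$alt,
               tissue_vaf = tm$snvs$tissue_vaf, stringsAsFactors = FALSE)
  }))
  hs <- select_hotspots(tissue_variants, k_per_patient = config$snv_count,
                        all_patients = ids)
  panel <- tile_probes(hs$regions)$probes

  cohort <- structure(list(
    patients = do.call(rbind, patients),
    samples = do.call(rbind, samples),
    lesions = do.call(rbind, lesions),
    tumors = tumors, variant_obs = variant_obs, bin_counts = bin_counts,
    normals = normals, panel = panel,
    truth = list(patients = do.call(rbind, truth_pat),
                 samples = do.call(rbind, truth_smp)),
    config = config), class = "sim_cohort")
  rownames(cohort$patients) <- rownames(cohort$samples) <- NULL

  if (!is.null(outdir)) write_cohort(cohort, outdir)
  cohort
}

# consensus-level readout: alt families ~ Binomial(depth, VAF_true), plus a
# small false-family floor from residual consensus errors
.simulate_family_counts <- function(tumor, true_tfx, config, seed) {
  set.seed(seed)
  snvs <- tumor$snvs
  vaf_true <- true_tfx * snvs$clonal_fraction / 2
  alt <- stats::rbinom(nrow(snvs), config$umi_depth, vaf_true)
  fp <- stats::rbinom(nrow(snvs), config$umi_depth - alt,
                      config$false_family_rate)
  data.frame(chrom = snvs$chrom, pos = snvs$pos, ref = snvs$ref,
             alt = snvs$alt, total_families = config$umi_depth,
             alt_families = alt + fp,
             vaf = (alt + fp) / config$umi_depth,
             stringsAsFactors = FALSE)
}

#' Write a simulated cohort to disk in the pipeline's input formats
#'
#' @param cohort a [simulate_cohort()] result.
#' @param outdir output directory (created if absent).
#' @return `outdir`, invisibly.
#' @export
write_cohort <- function(cohort, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(outdir, "variants"), showWarnings = FALSE)
  dir.create(file.path(outdir, "bins"), showWarnings = FALSE)
  dir.create(file.path(outdir, "normals"), showWarnings = FALSE)
  write_panel_bed(cohort$panel, file.path(outdir, "panel.bed"))
  utils::write.csv(cohort$patients, file.path(outdir, "clinical.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$samples[, c("patient_id", "sample_id",
                                      "timepoint", "ccfdna_ng_per_ml",
                                      "plasma_ml")],
                   file.path(outdir, "samples.csv"), row.names = FALSE)
  utils::write.csv(cohort$lesions, file.path(outdir, "lesions.csv"),
                   row.names = FALSE)
  for (sid in names(cohort$variant_obs))
    write_variant_tsv(cohort$variant_obs[[sid]][, c(
      "chrom", "pos", "ref", "alt", "total_families", "alt_families")],
      file.path(outdir, "variants", paste0(sid, ".tsv")))
  for (sid in names(cohort$bin_counts))
    write_bins_tsv(cohort$bin_counts[[sid]],
                   file.path(outdir, "bins", paste0(sid, ".tsv")))
  for (j in seq_along(cohort$normals))
    write_bins_tsv(cohort$normals[[j]],
                   file.path(outdir, "normals",
                             sprintf("normal%02d.tsv", j)))
  invisible(outdir)
}

#' Run the full quantification pipeline on a simulated (or loaded) cohort
#'
#' For every patient: mean VAF from the hotspot observations at each
#' timepoint, tumor-fraction estimation from bin counts where it is needed
#' (always at baseline, to establish detection by both assays, and at
#' follow-ups for patients whose fixed route is the genome-wide one),
#' route selection with baseline priority, conversion to hGE/ml and
#' molecular response classification.
#'
#' @param cohort a `"sim_cohort"` (or a structurally identical list built
#'   from files read back with the package readers).
#' @param tfx_min detection floor for the genome-wide route (default 0.04).
#' @param vaf_min detection floor for the targeted route (default 0.001).
#' @param cutoff molecular-response ratio cut-off (default 1.0).
#' @param ... passed to [fit_hmm_em()].
#' @return list: `measurements` (per-sample data.frame from
#'   [quantify_samples()]), `response` (per-patient data.frame from
#'   [molecular_response()]), `detection` (cohort [detection_summary()]),
#'   `flags` (per-patient detection flags).
#' @export
run_cohort_pipeline <- function(cohort, tfx_min = 0.04, vaf_min = 0.001,
                                cutoff = 1.0, ...) {
  pon <- normal_reference(cohort$normals)
  samples <- cohort$samples
  assays <- list(); flags <- list()
  for (pid in unique(samples$patient_id)) {
    ps <- samples[samples$patient_id == pid, , drop = FALSE]
    ps <- ps[order(ps$timepoint), , drop = FALSE]
    mv <- lapply(ps$sample_id, function(sid) {
      obs <- cohort$variant_obs[[sid]]
      if (is.null(obs))
        list(status = "not_evaluable", mean_vaf = NA_real_)
      else mean_vaf(obs, vaf_min = vaf_min)
    })
    targeted_status <- vapply(mv, `[[`, character(1), "status")
    mvaf <- vapply(mv, `[[`, numeric(1), "mean_vaf")

    # baseline sWGS always (detection accounting); follow-ups only when the
    # genome-wide route is the patient's fixed quantification route
    swgs_base <- estimate_tfx(cohort$bin_counts[[ps$sample_id[1]]], pon,
                              tfx_min = tfx_min, ...)
    need_followup_swgs <- targeted_status[1] != "detected"
    tfx <- rep(NA_real_, nrow(ps)); swgs_det <- rep(NA, nrow(ps))
    tfx[1] <- swgs_base$tfx; swgs_det[1] <- swgs_base$detected
    if (nrow(ps) > 1) {
      for (t in 2:nrow(ps)) {
        if (need_followup_swgs) {
          fit <- estimate_tfx(cohort$bin_counts[[ps$sample_id[t]]], pon,
                              tfx_min = tfx_min, ...)
          tfx[t] <- fit$tfx; swgs_det[t] <- fit$detected
        } else {
          tfx[t] <- NA_real_; swgs_det[t] <- FALSE
        }
      }
    }
    assays[[length(assays) + 1L]] <- data.frame(
      patient_id = pid, sample_id = ps$sample_id,
      timepoint = ps$timepoint,
      ccfdna_ng_per_ml = ps$ccfdna_ng_per_ml,
      targeted_status = targeted_status, mean_vaf = mvaf,
      swgs_detected = swgs_det, tfx = tfx, stringsAsFactors = FALSE)
    flags[[length(flags) + 1L]] <- data.frame(
      patient_id = pid,
      detected_targeted = targeted_status[1] == "detected",
      detected_swgs = isTRUE(swgs_det[1]), stringsAsFactors = FALSE)
  }
  assays <- do.call(rbind, assays)
  flags <- do.call(rbind, flags)
  meas <- quantify_samples(assays)
  resp <- molecular_response(meas, cutoff = cutoff)
  list(measurements = meas, response = resp,
       detection = detection_summary(flags), flags = flags)
}
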