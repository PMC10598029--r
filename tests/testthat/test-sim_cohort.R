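test_that("tumor simulation honors forced configuration and is reproducible", {
  cfg <- small_config(arm_alteration_prob = 0)
  tm <- simulate_tumor(1, cfg, snv_count = 2, allow_silent = TRUE)
  expect_equal(nrow(tm$snvs), 2L)
  expect_true(all(tm$cna$copy_number == 2L))
  expect_true(tm$snvs$clonal_fraction[1] == 1)
  expect_true(all(tm$snvs$clonal_fraction > 0 &
                    tm$snvs$clonal_fraction <= 1))
  # unique loci
  expect_equal(anyDuplicated(tm$snvs[, c("chrom", "pos")]), 0L)
  expect_identical(tm, simulate_tumor(1, cfg, snv_count = 2,
                                      allow_silent = TRUE))
  expect_false(identical(tm, simulate_tumor(2, cfg, snv_count = 2,
                                            allow_silent = TRUE)))
  # a variant-free tumor gets a copy-number alteration unless silence is allowed
  tm0 <- simulate_tumor(3, cfg, snv_count = 0)
  expect_true(any(tm0$cna$copy_number != 2L))
  tm0s <- simulate_tumor(3, cfg, snv_count = 0, allow_silent = TRUE)
  expect_true(tm0s$ctdna_silent)
  expect_error(sim_config(umi_error_rate = 0.5), "umi_error_rate")
  expect_error(sim_config(prob_no_snv = 2), "prob_no_snv")
})

test_that("TMB-high prior reproduces the intended stratum distribution", {
  cfg <- small_config()
  set.seed(1)
  tmb <- vapply(1:300, function(i)
    simulate_tumor(1000 + i, cfg, tmb_stratum = "high")$tmb, numeric(1))
  expect_gte(median(tmb), 13.3)
  expect_lte(median(tmb), 22.8)
  expect_true(all(tmb >= 13.3 & tmb <= 22.8))
  tmb_low <- vapply(1:50, function(i)
    simulate_tumor(2000 + i, cfg, tmb_stratum = "low")$tmb, numeric(1))
  expect_true(all(tmb_low <= 7.84))
})

test_that("UMI read simulation follows the binomial VAF model", {
  cfg <- small_config()
  tm <- simulate_tumor(4, cfg, snv_count = 2)
  tm$snvs$clonal_fraction <- 1

  # no tumor DNA and no errors: no alternative alleles anywhere
  r <- simulate_umi_reads(tm, true_tfx = 0, depth = 500, error_rate = 0,
                          seed = 5)
  expect_equal(sum(r$allele == r$alt), 0L)

  # mean VAF x 2 recovers the tumor fraction within Monte-Carlo error
  r <- simulate_umi_reads(tm, true_tfx = 0.02, depth = 10000,
                          error_rate = 0, seed = 6)
  cu <- collapse_umi(r)
  se <- sqrt(0.01 * 0.99 / 10000)
  expect_true(all(abs(cu$observations$vaf - 0.01) < 3 * se))

  expect_identical(simulate_umi_reads(tm, 0.1, depth = 100, seed = 7),
                   simulate_umi_reads(tm, 0.1, depth = 100, seed = 7))

  # loci must lie on the panel when one is supplied
  panel <- data.frame(chrom = tm$snvs$chrom, start = tm$snvs$pos - 60,
                      end = tm$snvs$pos + 61)
  expect_silent(simulate_umi_reads(tm, 0.1, depth = 10, seed = 1,
                                   panel = panel))
  expect_error(simulate_umi_reads(tm, 0.1, depth = 10, seed = 1,
                                  panel = panel[1, ]), "outside panel")
  expect_error(simulate_umi_reads(tm, 0.1, depth = 0, seed = 1), "depth")
  expect_error(simulate_umi_reads(tm, 0.1, error_rate = 0.5, seed = 1),
               "error_rate")
})

test_that("bin-count simulation carries the copy-number mixture expectation", {
  cfg <- small_config(nb_size = 5000)
  # copy-neutral: flat counts (no GC bias configured)
  bc0 <- simulate_bin_counts(NULL, 0, cfg, seed = 3)
  expect_lt(sd(bc0$count) / mean(bc0$count), 0.05)

  # a c = 4 arm at tfx = 0.5 sits at 1.5x the diploid background
  tm <- simulate_tumor(5, cfg, snv_count = 1, allow_silent = TRUE)
  tm$cna$copy_number <- 2L
  tm$cna$copy_number[1] <- 4L
  reps <- vapply(1:30, function(s) {
    bc <- simulate_bin_counts(tm, 0.5, cfg, seed = 100 + s)
    key <- paste(bc$chrom, bc$arm)
    aber <- key == paste(tm$cna$chrom[1], tm$cna$arm[1])
    mean(bc$count[aber]) / mean(bc$count[!aber])
  }, numeric(1))
  expect_equal(mean(reps), 1.5, tolerance = 0.02)

  expect_identical(simulate_bin_counts(tm, 0.3, cfg, seed = 9),
                   simulate_bin_counts(tm, 0.3, cfg, seed = 9))
})

test_that("trajectories respect their class contracts", {
  cfg <- small_config()
  tr <- simulate_trajectory("clearance", 0.2, 3, cfg, seed = 1)
  expect_equal(tr, c(0.2, 0, 0, 0))
  tr <- simulate_trajectory("progression", 0.1, 3, cfg, seed = 2)
  expect_true(all(diff(tr) > 0))
  # responders decline by the first follow-up in nearly all draws
  ratios <- vapply(1:200, function(s)
    simulate_trajectory("partial_decline", 0.2, 1, cfg, seed = s)[2] / 0.2,
    numeric(1))
  expect_gte(mean(ratios < 1), 0.95)
  expect_error(simulate_trajectory("other", 0.1, 1, cfg), "response_class")
})

test_that("cohort generation is deterministic with fixed stratum counts", {
  cfg <- small_config()
  co <- simulate_cohort(31, cfg, seed = 2)
  expect_equal(sum(co$patients$tmb_stratum == "high"), 5L)  # round(0.16*31)
  expect_equal(nrow(co$patients), 31L)
  # timepoints strictly increasing per patient
  for (pid in unique(co$samples$patient_id)) {
    tp <- co$samples$timepoint[co$samples$patient_id == pid]
    expect_true(all(diff(tp) > 0) || length(tp) == 1)
  }
  co2 <- simulate_cohort(31, cfg, seed = 2)
  expect_identical(co$patients, co2$patients)
  expect_identical(co$samples, co2$samples)
  expect_identical(co$bin_counts, co2$bin_counts)
  expect_error(simulate_cohort(1, cfg), "n_patients")
})

test_that("emitted files round-trip through the package readers", {
  cfg <- small_config()
  co <- simulate_cohort(6, cfg, seed = 4)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  panel <- read_panel_bed(file.path(dir, "panel.bed"))
  expect_equal(panel[, c("chrom", "start", "end")],
               co$panel[, c("chrom", "start", "end")], ignore_attr = TRUE)
  sid <- names(co$variant_obs)[1]
  back <- read_variant_tsv(file.path(dir, "variants",
                                     paste0(sid, ".tsv")))
  expect_equal(back$alt_families, co$variant_obs[[sid]]$alt_families)
  expect_equal(back$vaf, co$variant_obs[[sid]]$vaf)
  bins <- read_bins_tsv(file.path(dir, "bins", paste0(sid, ".tsv")))
  expect_equal(bins$count, co$bin_counts[[sid]]$count)
  clin <- utils::read.csv(file.path(dir, "clinical.csv"))
  expect_equal(clin$patient_id, co$patients$patient_id)
  samp <- utils::read.csv(file.path(dir, "samples.csv"))
  expect_equal(nrow(samp), nrow(co$samples))
})

test_that("simulated survival recovers the stratum medians at scale", {
  cfg <- small_config(max_followups = 1)
  co <- simulate_cohort(500, cfg, seed = 10)
  km <- km_logrank_cox(co$patients$pfs_months, co$patients$pfs_event,
                       co$patients$tmb_stratum)
  med_high <- km$medians$median[km$medians$group == "high"]
  med_low <- km$medians$median[km$medians$group == "low"]
  expect_lt(abs(med_low - 2.18) / 2.18, 0.2)
  expect_lt(abs(med_high - 3.35) / 3.35, 0.2)
})

test_that("simulated ccfDNA matches the cohort's concentration summary", {
  cfg <- small_config()
  co <- simulate_cohort(400, cfg, seed = 12)
  base <- co$samples$ccfdna_ng_per_ml[co$samples$timepoint == 0]
  expect_equal(median(base), 5.2, tolerance = 0.25)
  iqr <- quantile(base, c(0.25, 0.75))
  expect_equal(unname(iqr[1]), 2.3, tolerance = 0.3)
  expect_equal(unname(iqr[2]), 14.9, tolerance = 0.3)
})
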