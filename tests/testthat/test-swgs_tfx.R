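test_that("expected log2 ratio matches the mixture model", {
  expect_equal(expected_log2(0, c(0, 1, 2, 3, 4)), rep(0, 5))
  expect_equal(expected_log2(0.7, 2), 0)
  expect_equal(expected_log2(0.5, 3), log2(2.5 / 2))
  expect_equal(round(expected_log2(0.5, 3), 4), 0.3219)
  expect_equal(expected_log2(1, 0), -8)        # clamped singular state
  expect_equal(expected_log2(1, 0, floor = -12), -12)
  expect_error(expected_log2(1.5, 2), "tfx")
  expect_error(expected_log2(0.5, -1), "copy numbers")
})

test_that("forward-backward posteriors are normalized and likelihood matches enumeration", {
  set.seed(21)
  for (rep in 1:4) {
    prof <- sim_log2_profile(tfx = runif(1, 0.1, 0.4), n_bins = 6,
                             frac_gain = 0.4, frac_loss = 0.2,
                             sigma = 0.06, seed = 100 + rep)
    tfx <- runif(1, 0.05, 0.5); sigma <- runif(1, 0.03, 0.1)
    fb <- forward_backward(prof$x, tfx, sigma)
    expect_true(all(abs(rowSums(fb$gamma) - 1) < 1e-10))
    bf <- brute_force_hmm(prof$x, tfx, sigma)
    expect_equal(fb$loglik, bf$loglik, tolerance = 1e-9)
  }
})

test_that("Viterbi decoding equals exhaustive path enumeration", {
  set.seed(33)
  for (rep in 1:4) {
    prof <- sim_log2_profile(tfx = 0.3, n_bins = 6, frac_gain = 0.3,
                             frac_loss = 0.3, sigma = 0.08,
                             seed = 200 + rep)
    tfx <- runif(1, 0.1, 0.5); sigma <- runif(1, 0.04, 0.1)
    vp <- viterbi_path(prof$x, tfx, sigma)
    bf <- brute_force_hmm(prof$x, tfx, sigma)
    expect_equal(vp, bf$path)
  }
})

test_that("EM log-likelihood is non-decreasing and recovers planted parameters", {
  prof <- sim_log2_profile(0.3, n_bins = 400, sigma = 0.05, seed = 5)
  fit <- fit_hmm_em(prof$x)
  expect_true(all(diff(fit$loglik_trace) > -1e-3))
  expect_gt(fit$tfx, 0.25)
  expect_lt(fit$tfx, 0.35)
  expect_gte(mean(fit$states == prof$states), 0.95)
  expect_equal(fit$sigma, 0.05, tolerance = 0.2)
})

test_that("all-neutral data yields no tumor fraction", {
  set.seed(9)
  x <- rnorm(300, 0, 0.05)
  fit <- fit_hmm_em(x)
  expect_lte(fit$tfx, 0.04)
  expect_true(all(fit$states == 2))
})

test_that("mirrored log2 ratios give mirrored calls and matching tumor fraction", {
  prof <- sim_log2_profile(0.12, n_bins = 400, sigma = 0.05, seed = 13)
  fit <- fit_hmm_em(prof$x)
  fit_m <- fit_hmm_em(-prof$x)
  expect_lt(abs(fit_m$tfx - fit$tfx), 0.02)
  # gains become losses and vice versa
  expect_gte(mean((4 - fit$states) == fit_m$states), 0.95)
})

test_that("detection rate is monotone in true tumor fraction", {
  rate <- sapply(c(0.01, 0.02, 0.04, 0.08, 0.16), function(tf) {
    mean(sapply(1:3, function(s) {
      prof <- sim_log2_profile(tf, n_bins = 300, sigma = 0.05,
                               seed = 300 + 17 * s)
      fit_hmm_em(prof$x)$tfx > 0.04
    }))
  })
  expect_true(all(diff(rate) >= 0))
})

test_that("GC correction flattens biased profiles against the normal panel", {
  # enough bins that per-decile medians resolve below the tolerance
  cfg <- sim_config(n_chrom = 4, bins_per_arm = 25, nb_size = 5e4)
  pon <- make_pon(cfg)
  flat <- simulate_bin_counts(NULL, 0, cfg, seed = 77)
  cb <- correct_bins(flat, pon)
  expect_true(all(abs(cb$log2r[!cb$masked]) < 0.1))
  expect_equal(attr(cb, "n_masked"), sum(cb$masked))

  # quadratic GC bias injected into a copy-neutral sample
  cfg_b <- sim_config(n_chrom = 4, bins_per_arm = 25, nb_size = 5e4,
                      gc_lin = 0.8, gc_quad = 2)
  biased <- simulate_bin_counts(NULL, 0, cfg_b, seed = 78)
  cb <- correct_bins(biased, pon)
  ok <- !cb$masked
  dec <- cut(cb$gc[ok], breaks = quantile(cb$gc[ok], 0:10 / 10),
             include.lowest = TRUE)
  med <- tapply(cb$log2r[ok], dec, median)
  expect_true(all(abs(med) < 0.05))

  bad <- flat[-1, ]
  expect_error(correct_bins(bad, pon), "layout differs")
})

test_that("arm calls follow the fraction rule and feed the aneuploidy score", {
  bins <- expand.grid(bin = 1:10, arm = c("p", "q"),
                      chrom = c("chr1", "chr2"),
                      stringsAsFactors = FALSE)
  bins$masked <- FALSE
  neutral <- rep(2L, nrow(bins))
  ac <- arm_calls(bins, neutral)
  expect_equal(ac$aneuploidy_score, 0L)

  # whole-chromosome gain contributes both arms
  st <- neutral
  st[bins$chrom == "chr1"] <- 3L
  ac <- arm_calls(bins, st)
  expect_equal(ac$aneuploidy_score, 2L)
  expect_setequal(ac$arm_calls$call[ac$arm_calls$chrom == "chr1"], "gain")

  # 60% of one arm altered passes the 0.5 rule; 40% does not
  p2 <- which(bins$chrom == "chr2" & bins$arm == "p")
  st <- neutral
  st[p2[1:6]] <- 1L
  expect_equal(arm_calls(bins, st)$aneuploidy_score, 1L)
  st <- neutral
  st[p2[1:4]] <- 1L
  expect_equal(arm_calls(bins, st)$aneuploidy_score, 0L)

  # an arm both half-gained and half-lost is complex and counts once
  st <- neutral
  st[bins$chrom == "chr2" & bins$arm == "q"] <- c(rep(1L, 5), rep(3L, 5))
  ac <- arm_calls(bins, st)
  expect_equal(ac$arm_calls$call[ac$arm_calls$chrom == "chr2" &
                                   ac$arm_calls$arm == "q"], "complex")
  expect_equal(ac$aneuploidy_score, 1L)

  # fully masked arm drops out of the denominator
  bins$masked[bins$chrom == "chr1" & bins$arm == "p"] <- TRUE
  ac <- arm_calls(bins, neutral[!bins$masked])
  expect_equal(ac$excluded_arms, "chr1|p")
  expect_equal(nrow(ac$arm_calls), 3L)
})

test_that("end-to-end estimation recovers simulated copy-number genomes", {
  cfg <- sim_config(n_chrom = 8, bins_per_arm = 15)
  pon <- make_pon(cfg)
  tm <- simulate_tumor(2, cfg, snv_count = 2)
  bc <- simulate_bin_counts(tm, 0.3, cfg, seed = 40)
  res <- estimate_tfx(bc, pon)
  expect_true(res$detected)
  expect_lt(abs(res$tfx - 0.3), 0.05)
  true_as <- sum(tm$cna$copy_number != 2)
  expect_equal(res$aneuploidy_score, true_as)
})

test_that("bin tables round-trip through the TSV reader", {
  cfg <- small_config()
  bc <- simulate_bin_counts(NULL, 0, cfg, seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_bins_tsv(bc, path)
  back <- read_bins_tsv(path)
  expect_equal(back$count, bc$count)
  expect_equal(back$gc, bc$gc, tolerance = 1e-12)
})
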