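test_that("hGE/ml conversion follows the 3.3 / 6.6 pg rules", {
  expect_equal(hge_per_ml(mean_vaf = 0, ccfdna_ng_per_ml = 5), 0)
  # 1% mean VAF at 3.3 ng/ml (= 3300 pg/ml): 0.01 * 3300 / 3.3 = 10
  expect_equal(hge_per_ml(mean_vaf = 0.01, ccfdna_ng_per_ml = 3.3), 10)
  # 2% TFx at 6.6 ng/ml: 0.02 * 6600 / 6.6 = 20
  expect_equal(hge_per_ml(tfx = 0.02, ccfdna_ng_per_ml = 6.6), 20)
  expect_error(hge_per_ml(mean_vaf = 0.1, tfx = 0.2,
                          ccfdna_ng_per_ml = 1), "exactly one")
  expect_error(hge_per_ml(ccfdna_ng_per_ml = 1), "exactly one")
  expect_error(hge_per_ml(mean_vaf = 0.1, ccfdna_ng_per_ml = 0), "> 0")
})

test_that("the two routes agree exactly when mean VAF x 2 equals TFx", {
  set.seed(4)
  for (rep in 1:25) {
    v <- runif(1, 0, 0.5); ccf <- runif(1, 0.5, 300)
    expect_equal(hge_per_ml(mean_vaf = v, ccfdna_ng_per_ml = ccf),
                 hge_per_ml(tfx = 2 * v, ccfdna_ng_per_ml = ccf),
                 tolerance = 1e-12)
  }
  # linearity in both arguments
  expect_equal(hge_per_ml(mean_vaf = 0.02, ccfdna_ng_per_ml = 7),
               2 * hge_per_ml(mean_vaf = 0.01, ccfdna_ng_per_ml = 7))
  expect_equal(hge_per_ml(tfx = 0.1, ccfdna_ng_per_ml = 14),
               2 * hge_per_ml(tfx = 0.1, ccfdna_ng_per_ml = 7))
})

test_that("route choice honors targeted priority and baseline fixation", {
  expect_equal(choose_route("detected", TRUE)$route, "targeted_vaf")
  expect_equal(choose_route("not_detected", TRUE)$route, "swgs_tfx")
  expect_equal(choose_route("not_evaluable", FALSE)$route, "undetected")
  # fixed route is kept; discordance flagged when only the other assay sees
  cr <- choose_route("not_detected", TRUE, fixed_route = "targeted_vaf")
  expect_equal(cr$route, "targeted_vaf")
  expect_true(cr$discordant)
  cr <- choose_route("detected", FALSE, fixed_route = "swgs_tfx")
  expect_equal(cr$route, "swgs_tfx")
  expect_true(cr$discordant)
  expect_false(choose_route("detected", TRUE,
                            fixed_route = "targeted_vaf")$discordant)
})

make_assays <- function() {
  data.frame(
    patient_id = rep(c("A", "B", "C"), each = 2),
    sample_id = paste0(rep(c("A", "B", "C"), each = 2), c("_T0", "_T1")),
    timepoint = rep(c(0, 3), 3),
    ccfdna_ng_per_ml = c(3.3, 3.3, 6.6, 6.6, 5, 5),
    targeted_status = c("detected", "detected",
                        "not_evaluable", "not_evaluable",
                        "not_detected", "not_detected"),
    mean_vaf = c(0.05, 0.005, NA, NA, NA, NA),
    swgs_detected = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    tfx = c(0.2, 0.1, 0.3, 0.02, NA, NA))
}

test_that("sample quantification fixes one route per patient", {
  m <- quantify_samples(make_assays())
  expect_equal(m$route[m$patient_id == "A"], rep("targeted_vaf", 2))
  expect_equal(m$route[m$patient_id == "B"], rep("swgs_tfx", 2))
  expect_equal(m$route[m$patient_id == "C"], rep("undetected", 2))
  # A: 0.05 * 3300 / 3.3 = 50, follow-up 5
  expect_equal(m$hge_per_ml[m$sample_id == "A_T0"], 50)
  expect_equal(m$hge_per_ml[m$sample_id == "A_T1"], 5)
  # B: TFx route, follow-up below floor counts as cleared on that route
  expect_equal(m$hge_per_ml[m$sample_id == "B_T0"], 0.3 * 6600 / 6.6)
  expect_equal(m$hge_per_ml[m$sample_id == "B_T1"], 0)
  expect_true(all(is.na(m$hge_per_ml[m$patient_id == "C"])))
})

test_that("molecular response classifies ratio against the cut-off", {
  m <- quantify_samples(make_assays())
  mr <- molecular_response(m)
  expect_equal(mr$class[mr$patient_id == "A"], "molecular_response")
  expect_equal(mr$ratio[mr$patient_id == "A"], 0.1)
  # clearance: ratio 0 is always a molecular response
  expect_equal(mr$ratio[mr$patient_id == "B"], 0)
  expect_equal(mr$class[mr$patient_id == "B"], "molecular_response")
  expect_equal(mr$class[mr$patient_id == "C"], "not_evaluable")

  # identity and rising timelines
  tl <- data.frame(patient_id = "X", timepoint = c(0, 3),
                   route = "targeted_vaf", hge_per_ml = c(10, 10))
  mr <- molecular_response(tl)
  expect_equal(mr$ratio, 1)
  expect_equal(mr$class, "molecular_progression")
  tl$hge_per_ml <- c(10, 100)
  mr <- molecular_response(tl)
  expect_equal(mr$ratio, 10)
  expect_equal(mr$class, "molecular_progression")
  # zero baseline is not evaluable
  tl$hge_per_ml <- c(0, 10)
  expect_equal(molecular_response(tl)$class, "not_evaluable")
  expect_error(molecular_response(tl, cutoff = 0), "cutoff")
})

test_that("molecular response is invariant to plasma-volume bookkeeping", {
  # concentrations are per ml, so the sampled plasma volume cancels
  tl <- data.frame(patient_id = "X", timepoint = c(0, 3),
                   route = "targeted_vaf", hge_per_ml = c(80, 20))
  for (vol in c(4.3, 10, 14.2)) {
    total <- tl
    total$hge_total <- total$hge_per_ml * vol
    expect_equal(molecular_response(total)$ratio, 0.25)
  }
})

test_that("detection accounting reports per-method and union fractions", {
  flags <- data.frame(patient_id = 1:4,
                      detected_targeted = c(TRUE, TRUE, FALSE, FALSE),
                      detected_swgs = c(TRUE, FALSE, TRUE, FALSE))
  ds <- detection_summary(flags)
  expect_equal(ds$n_detected, c(2L, 2L, 3L))
  expect_equal(ds$fraction_pct, 100 * c(2, 2, 3) / 4)

  flags$detected_targeted <- flags$detected_swgs <- FALSE
  expect_equal(detection_summary(flags)$fraction_pct, c(0, 0, 0))

  # union dominates each single assay on random cohorts
  set.seed(8)
  for (rep in 1:10) {
    flags <- data.frame(patient_id = 1:30,
                        detected_targeted = runif(30) < runif(1),
                        detected_swgs = runif(30) < runif(1))
    ds <- detection_summary(flags)
    expect_gte(ds$n_detected[3], max(ds$n_detected[1:2]))
  }
})

test_that("median split dichotomizes at the cohort median", {
  x <- c(1, 2, 3, 10, 20, 30)
  ms <- median_split(x)
  expect_equal(ms$cutoff, median(x))
  expect_equal(as.character(ms$class),
               c("low", "low", "low", "high", "high", "high"))
})
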