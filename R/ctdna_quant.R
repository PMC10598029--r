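#' Convert an assay readout into ctDNA haploid genome equivalents per ml
#'
#' One haploid genome weighs about 3.3 pg, so the tumor-derived share of the
#' circulating DNA mass converts directly into genome copies. For the
#' targeted route the mean VAF is multiplied by the total ccfDNA
#' concentration (pg/ml) and divided by 3.3; for the genome-wide route the
#' tumor fraction is divided by 6.6, because under the heterozygous-mutation
#' assumption the expected relation is mean VAF x 2 = TFx, and the two
#' routes then agree exactly.
#'
#' @param mean_vaf mean variant allele fraction of the sample (targeted
#'   route); supply exactly one of `mean_vaf` and `tfx`.
#' @param tfx tumor fraction from copy-number profiling (genome-wide route).
#' @param ccfdna_ng_per_ml total ccfDNA concentration in ng per ml plasma
#'   (> 0); converted internally to pg/ml.
#' @return ctDNA concentration in haploid genome equivalents per ml plasma.
#' @export
hge_per_ml <- function(mean_vaf = NULL, tfx = NULL, ccfdna_ng_per_ml) {
  if (is.null(mean_vaf) == is.null(tfx))
    stop("supply exactly one of mean_vaf and tfx")
  if (any(ccfdna_ng_per_ml <= 0)) stop("ccfdna_ng_per_ml must be > 0")
  pg_per_ml <- ccfdna_ng_per_ml * 1000
  if (!is.null(mean_vaf)) {
    if (any(mean_vaf < 0 | mean_vaf > 1)) stop("mean_vaf must lie in [0, 1]")
    mean_vaf * pg_per_ml / 3.3
  } else {
    if (any(tfx < 0 | tfx > 1)) stop("tfx must lie in [0, 1]")
    tfx * pg_per_ml / 6.6
  }
}

#' Choose the quantification route for a sample
#'
#' The targeted hotspot assay is more sensitive and takes priority whenever
#' it yields a measurement; the genome-wide route is the fallback for
#' patients without trackable somatic point mutations. Once a patient's
#' route has been fixed at baseline it is reused for every follow-up so the
#' longitudinal series stays internally comparable; if the fixed route
#' misses disease that the other assay still sees, the sample is recorded
#' as cleared on the fixed route and the discordance is flagged.
#'
#' @param targeted_status `"detected"`, `"not_detected"` or
#'   `"not_evaluable"` (from [mean_vaf()]).
#' @param swgs_detected logical; tumor fraction above the detection floor.
#' @param fixed_route route fixed at baseline (`"targeted_vaf"` or
#'   `"swgs_tfx"`), or `NULL` at baseline.
#' @return list: `route` (`"targeted_vaf"`, `"swgs_tfx"` or
#'   `"undetected"`), `discordant` (logical).
#' @export
choose_route <- function(targeted_status, swgs_detected,
                         fixed_route = NULL) {
  targeted_ok <- identical(targeted_status, "detected")
  if (is.null(fixed_route)) {
    route <- if (targeted_ok) "targeted_vaf"
      else if (isTRUE(swgs_detected)) "swgs_tfx"
      else "undetected"
    return(list(route = route, discordant = FALSE))
  }
  available <- c(targeted_vaf = targeted_ok,
                 swgs_tfx = isTRUE(swgs_detected))
  other <- setdiff(names(available), fixed_route)
  list(route = fixed_route,
       discordant = !available[[fixed_route]] && available[[other]])
}

#' Quantify ctDNA for a table of samples with per-patient route consistency
#'
#' Applies [choose_route()] at each patient's baseline (earliest timepoint)
#' and converts every sample on that patient's fixed route into hGE/ml via
#' [hge_per_ml()]. A follow-up where the fixed route detects nothing is a
#' measured clearance (0 hGE/ml); patients undetected by both assays at
#' baseline get route `"undetected"` and no measurements.
#'
#' @param assays data.frame with one row per sample: `patient_id`,
#'   `sample_id`, `timepoint` (months), `ccfdna_ng_per_ml`,
#'   `targeted_status`, `mean_vaf` (NA unless detected), `swgs_detected`,
#'   `tfx`.
#' @return data.frame: input columns plus `route`, `hge_per_ml`,
#'   `discordant`.
#' @export
quantify_samples <- function(assays) {
  req <- c("patient_id", "sample_id", "timepoint", "ccfdna_ng_per_ml",
           "targeted_status", "mean_vaf", "swgs_detected", "tfx")
  miss <- setdiff(req, names(assays))
  if (length(miss) > 0) stop("assays is missing columns: ",
                             paste(miss, collapse = ", "))
  out <- list()
  for (pid in unique(assays$patient_id)) {
    pa <- assays[assays$patient_id == pid, , drop = FALSE]
    pa <- pa[order(pa$timepoint), , drop = FALSE]
    base <- choose_route(pa$targeted_status[1], pa$swgs_detected[1])
    pa$route <- base$route
    pa$discordant <- FALSE
    pa$hge_per_ml <- NA_real_
    if (base$route != "undetected") {
      for (i in seq_len(nrow(pa))) {
        cr <- choose_route(pa$targeted_status[i], pa$swgs_detected[i],
                           fixed_route = base$route)
        pa$discordant[i] <- cr$discordant
        pa$hge_per_ml[i] <- if (base$route == "targeted_vaf") {
          v <- if (identical(pa$targeted_status[i], "detected"))
            pa$mean_vaf[i] else 0
          hge_per_ml(mean_vaf = v,
                     ccfdna_ng_per_ml = pa$ccfdna_ng_per_ml[i])
        } else {
          tf <- if (isTRUE(pa$swgs_detected[i])) pa$tfx[i] else 0
          hge_per_ml(tfx = tf, ccfdna_ng_per_ml = pa$ccfdna_ng_per_ml[i])
        }
      }
    }
    out[[length(out) + 1L]] <- pa
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Molecular response from a patient's ctDNA timeline
#'
#' The molecular response is the ratio of the first follow-up to the
#' baseline ctDNA concentration, both on the patient's fixed route. Ratios
#' below `cutoff` are molecular responses (a complete clearance is a ratio
#' of 0), ratios at or above it molecular progression. Patients without a
#' quantifiable baseline or without any follow-up are not evaluable.
#'
#' @param measurements data.frame from [quantify_samples()] (needs
#'   `patient_id`, `timepoint`, `route`, `hge_per_ml`).
#' @param cutoff ratio separating response from progression (default 1.0,
#'   i.e. any decline counts as molecular response).
#' @return data.frame with one row per patient: `patient_id`, `route`,
#'   `baseline_hge`, `followup_hge`, `ratio`, `class`
#'   (`"molecular_response"`, `"molecular_progression"`,
#'   `"not_evaluable"`).
#' @export
molecular_response <- function(measurements, cutoff = 1.0) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  out <- list()
  for (pid in unique(measurements$patient_id)) {
    pm <- measurements[measurements$patient_id == pid, , drop = FALSE]
    pm <- pm[order(pm$timepoint), , drop = FALSE]
    route <- pm$route[1]
    row <- data.frame(patient_id = pid, route = route,
                      baseline_hge = NA_real_, followup_hge = NA_real_,
                      ratio = NA_real_, class = "not_evaluable",
                      stringsAsFactors = FALSE)
    if (route != "undetected" && nrow(pm) >= 2 &&
        !is.na(pm$hge_per_ml[1]) && pm$hge_per_ml[1] > 0) {
      b <- pm$hge_per_ml[1]; f <- pm$hge_per_ml[2]
      ratio <- f / b
      row$baseline_hge <- b; row$followup_hge <- f; row$ratio <- ratio
      row$class <- if (ratio < cutoff) "molecular_response"
                   else "molecular_progression"
    }
    out[[length(out) + 1L]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-assay and combined ctDNA detection fractions over a cohort
#'
#' @param flags data.frame with one row per patient: `patient_id`,
#'   `detected_targeted`, `detected_swgs` (logicals).
#' @return data.frame with rows `targeted`, `swgs`, `combined`:
#'   `n_detected`, `n_total`, `fraction_pct`. Combined means detected by
#'   either assay.
#' @export
detection_summary <- function(flags) {
  req <- c("patient_id", "detected_targeted", "detected_swgs")
  miss <- setdiff(req, names(flags))
  if (length(miss) > 0) stop("flags is missing columns: ",
                             paste(miss, collapse = ", "))
  n <- nrow(flags)
  k_t <- sum(flags$detected_targeted)
  k_s <- sum(flags$detected_swgs)
  k_c <- sum(flags$detected_targeted | flags$detected_swgs)
  data.frame(method = c("targeted", "swgs", "combined"),
             n_detected = c(k_t, k_s, k_c),
             n_total = n,
             fraction_pct = 100 * c(k_t, k_s, k_c) / n,
             stringsAsFactors = FALSE)
}

#' Split a cohort at its median
#'
#' Dichotomizes a biomarker at the cohort median, the convention used for
#' prognostic ccfDNA and ctDNA cut-offs; published numeric cut-offs of this
#' kind are a given cohort's median, not universal constants.
#'
#' @param x numeric vector.
#' @param na.rm drop missing values when locating the median (default TRUE).
#' @return list: `cutoff` (the median) and `class` (factor `"low"`/`"high"`,
#'   values at or above the median are `"high"`).
#' @export
median_split <- function(x, na.rm = TRUE) {
  cutoff <- stats::median(x, na.rm = na.rm)
  cls <- factor(ifelse(x >= cutoff, "high", "low"), levels = c("low", "high"))
  list(cutoff = cutoff, class = cls)
}
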