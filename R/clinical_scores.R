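#' Default weight table for the metastasis burden score
#'
#' Banded points for the number of affected organs and, per organ, for the
#' number of metastases it carries. These defaults are an explicit package
#' assumption (1/2/3 points for 1, 2-3, >= 4 organs; 1/2/3 points for 1,
#' 2-5, > 5 metastases per organ) and should be replaced by a site's own
#' calibrated table where one exists.
#'
#' @return list with functions `organ_points(n_organs)` and
#'   `metastasis_points(n_mets)`.
#' @export
default_burden_weights <- function() {
  list(
    organ_points = function(n_organs) {
      ifelse(n_organs >= 4, 3L, ifelse(n_organs >= 2, 2L, 1L))
    },
    metastasis_points = function(n_mets) {
      ifelse(n_mets > 5, 3L, ifelse(n_mets >= 2, 2L, 1L))
    })
}

#' Metastasis burden score of one patient
#'
#' The raw score is the sum of all target-lesion diameters (in cm) plus
#' banded points for how many organs are affected and, per organ, for how
#' many metastases it carries — so both wide dissemination and bulky
#' individual lesions raise the score.
#'
#' @param lesions data.frame for one patient: `organ`, `n_metastases`,
#'   `diameter_mm` (target-lesion diameter; one row per target lesion, and
#'   organs may appear on several rows). `n_metastases` is the organ's
#'   total metastasis count and is read from the organ's first row.
#' @param weights weight table, see [default_burden_weights()].
#' @param diameter_unit unit of the `diameter_mm` column, `"mm"` (default)
#'   or `"cm"`; diameters enter the score in cm.
#' @return numeric raw burden score.
#' @export
metastasis_burden_score <- function(lesions,
                                    weights = default_burden_weights(),
                                    diameter_unit = c("mm", "cm")) {
  diameter_unit <- match.arg(diameter_unit)
  stopifnot(is.data.frame(lesions))
  if (nrow(lesions) == 0)
    stop("at least one measurable target lesion is required")
  req <- c("organ", "n_metastases", "diameter_mm")
  miss <- setdiff(req, names(lesions))
  if (length(miss) > 0) stop("lesions is missing columns: ",
                             paste(miss, collapse = ", "))
  if (any(lesions$diameter_mm <= 0)) stop("diameters must be > 0")
  diam_cm <- if (diameter_unit == "mm") lesions$diameter_mm / 10
             else lesions$diameter_mm
  organs <- lesions[!duplicated(lesions$organ), , drop = FALSE]
  sum(diam_cm) +
    weights$organ_points(nrow(organs)) +
    sum(weights$metastasis_points(organs$n_metastases))
}

#' Tertile classification of burden scores
#'
#' Splits a cohort's raw burden scores at its tertiles into low,
#' intermediate and high classes. Values exactly on a cut point go to the
#' lower class, so a cohort of 3k distinct scores splits k/k/k.
#'
#' @param raw_scores numeric vector of raw burden scores for the cohort.
#' @return list: `class` (factor `low`/`intermediate`/`high`), `cutoffs`
#'   (the two tertile boundaries).
#' @export
classify_burden <- function(raw_scores) {
  q <- stats::quantile(raw_scores, c(1 / 3, 2 / 3), na.rm = TRUE,
                       names = FALSE)
  cls <- ifelse(raw_scores <= q[1], "low",
                ifelse(raw_scores <= q[2], "intermediate", "high"))
  list(class = factor(cls, levels = c("low", "intermediate", "high")),
       cutoffs = q)
}

#' Stratify tumor mutational burden
#'
#' @param tmb mutations per megabase (vectorised); `NA` is not evaluable.
#' @param cutoff stratification cut-off (default 12 mutations/Mb); the high
#'   stratum is strictly above the cut-off.
#' @return factor with levels `low`, `high` (`NA` preserved).
#' @export
stratify_tmb <- function(tmb, cutoff = 12) {
  if (any(tmb < 0, na.rm = TRUE)) stop("tmb must be >= 0")
  factor(ifelse(tmb > cutoff, "high", "low"), levels = c("low", "high"))
}

#' Classify microsatellite instability
#'
#' @param msi_fraction fraction of unstable microsatellite sites in
#'   `[0, 1]`.
#' @param cutoff MSI-high at or above this fraction (default 0.10).
#' @return factor with levels `MSS`, `MSI-high`.
#' @export
classify_msi <- function(msi_fraction, cutoff = 0.10) {
  if (any(msi_fraction < 0 | msi_fraction > 1, na.rm = TRUE))
    stop("msi_fraction must lie in [0, 1]")
  factor(ifelse(msi_fraction >= cutoff, "MSI-high", "MSS"),
         levels = c("MSS", "MSI-high"))
}

#' Classify PD-L1 expression status
#'
#' Positive when either the combined positive score (CPS) or the tumor
#' proportion score (TPS) reaches `cutoff`; unknown when both are missing.
#'
#' @param cps combined positive score (may be `NA`).
#' @param tps tumor proportion score (may be `NA`).
#' @param cutoff positivity threshold (default 1).
#' @return character vector: `"positive"`, `"negative"` or `"unknown"`.
#' @export
classify_pdl1 <- function(cps, tps, cutoff = 1) {
  n <- max(length(cps), length(tps))
  cps <- rep_len(cps, n); tps <- rep_len(tps, n)
  best <- pmax(cps, tps, na.rm = TRUE)
  out <- ifelse(is.na(cps) & is.na(tps), "unknown",
                ifelse(best >= cutoff, "positive", "negative"))
  out
}

#' Classify homologous recombination deficiency status
#'
#' @param hrd_score non-negative HRD score estimate.
#' @param negative_below scores strictly below this are negative
#'   (default 30).
#' @param positive_above scores strictly above this are positive
#'   (default 50); the closed interval between the bounds is intermediate.
#' @return factor with levels `negative`, `intermediate`, `positive`.
#' @export
classify_hrd <- function(hrd_score, negative_below = 30,
                         positive_above = 50) {
  if (any(hrd_score < 0, na.rm = TRUE)) stop("hrd_score must be >= 0")
  cls <- ifelse(hrd_score < negative_below, "negative",
                ifelse(hrd_score > positive_above, "positive",
                       "intermediate"))
  factor(cls, levels = c("negative", "intermediate", "positive"))
}
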