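#' Overall response rate with exact (Clopper-Pearson) confidence interval
#'
#' The exact two-sided binomial interval from beta quantiles:
#' `lower = qbeta(a/2, k, n - k + 1)`, `upper = qbeta(1 - a/2, k + 1, n - k)`,
#' with the boundary cases `k = 0` and `k = n` pinned to 0 and 1. Values are
#' returned as percentages at full precision; round only for reporting.
#'
#' @param k number of responders (CR + PR), `0 <= k <= n`.
#' @param n number of evaluable patients, `n >= 1`.
#' @param level confidence level (default 0.95).
#' @return list: `orr_pct`, `lower_pct`, `upper_pct`, `k`, `n`.
#' @export
orr_exact_ci <- function(k, n, level = 0.95) {
  if (n < 1) stop("n must be >= 1")
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  a <- 1 - level
  lower <- if (k == 0) 0 else stats::qbeta(a / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - a / 2, k + 1, n - k)
  list(orr_pct = 100 * k / n, lower_pct = 100 * lower,
       upper_pct = 100 * upper, k = k, n = n)
}

#' Fisher's exact test for a 2x2 table (two-sided, probability-mass rule)
#'
#' Conditions on both margins and sums the hypergeometric probabilities of
#' every table as or less probable than the observed one — the dominant
#' two-sided convention. Degenerate tables (a zero row or column margin)
#' carry no information and return p = 1.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("tab must be 2x2")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("tab must hold non-negative integers")
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  if (r1 == 0 || r1 == N || c1 == 0 || c1 == N) return(1)
  support <- max(0, r1 + c1 - N):min(r1, c1)
  probs <- stats::dhyper(support, c1, N - c1, r1)
  p_obs <- stats::dhyper(tab[1, 1], c1, N - c1, r1)
  # tolerance guards ties against floating-point noise
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Kaplan-Meier, log-rank and Cox summaries for a grouped cohort
#'
#' Routine survival plumbing delegated to the survival package: product-
#' limit medians (with 95% CIs), survival at a landmark time, the two-sided
#' log-rank test and a Cox proportional-hazards fit for the group effect.
#'
#' @param time follow-up times (> 0).
#' @param event event indicators (1/TRUE = event, 0/FALSE = censored).
#' @param group factor (or coercible); with a single level only the
#'   product-limit medians are returned, with 2 or more the log-rank test
#'   and Cox fit are added (first level is the reference).
#' @param landmark optional time at which per-group survival is reported
#'   (e.g. 12 for one-year rates).
#' @return list: `medians` (data.frame `group`, `n`, `events`, `median`,
#'   `lower`, `upper`; `NA` median means not reached), `logrank_p`, `hr`,
#'   `hr_lower`, `hr_upper`, `landmark` (data.frame, if requested).
#' @export
km_logrank_cox <- function(time, event, group, landmark = NULL) {
  if (any(time <= 0)) stop("times must be > 0")
  group <- droplevels(as.factor(group))
  sv <- survival::Surv(time, as.integer(event))
  fit <- if (nlevels(group) < 2) survival::survfit(sv ~ 1)
         else survival::survfit(sv ~ group)
  st <- summary(fit)$table
  if (is.null(dim(st))) st <- matrix(st, nrow = 1,
                                     dimnames = list(NULL, names(st)))
  medians <- data.frame(group = levels(group),
                        n = st[, "records"], events = st[, "events"],
                        median = st[, "median"],
                        lower = st[, "0.95LCL"], upper = st[, "0.95UCL"],
                        stringsAsFactors = FALSE)
  rownames(medians) <- NULL
  out <- list(medians = medians, logrank_p = NA_real_, hr = NA_real_,
              hr_lower = NA_real_, hr_upper = NA_real_)
  if (nlevels(group) >= 2) {
    sd <- survival::survdiff(sv ~ group)
    out$logrank_p <- stats::pchisq(sd$chisq, df = nlevels(group) - 1,
                                   lower.tail = FALSE)
    cx <- survival::coxph(sv ~ group)
    ci <- stats::confint(cx)
    out$hr <- unname(exp(stats::coef(cx)))[1]
    out$hr_lower <- exp(ci[1, 1]); out$hr_upper <- exp(ci[1, 2])
  }
  if (!is.null(landmark)) {
    sm <- summary(fit, times = landmark, extend = TRUE)
    out$landmark <- data.frame(group = levels(group), time = landmark,
                               survival = sm$surv,
                               stringsAsFactors = FALSE)
  }
  out
}

# probability that a subject experiences the event during the study:
# exponential event hazard lam and dropout hazard eta, entry uniform over
# the accrual period, observation until accrual + followup
.event_probability <- function(lam, accrual, followup, dropout = 0) {
  a <- lam + dropout
  lam / a * (1 - exp(-a * followup) * (1 - exp(-a * accrual)) / (a * accrual))
}

#' Lachin-Foulkes sample size for the log-rank test under exponential
#' survival
#'
#' Computes the total sample size needed to detect a hazard ratio between
#' two exponential survival curves with uniform staggered entry, following
#' Lachin & Foulkes (1986). The test statistic is the difference of hazard
#' estimates; the null variance uses the average hazard and the alternative
#' variance the per-group hazards, each scaled by the group's probability
#' of an observed event (which integrates exposure over the uniform entry
#' distribution). The expected number of events at the end of follow-up is
#' reported alongside.
#'
#' @param hr hazard ratio to detect (treatment vs control), in `(0, 1)`.
#' @param median_control median survival of the control group in months
#'   (> 0); the treatment median is `median_control / hr`.
#' @param accrual_months uniform accrual period.
#' @param followup_months minimal follow-up after the accrual period ends.
#' @param alpha two-sided significance level (default 0.05).
#' @param power target power (default 0.80).
#' @param ratio allocation ratio treatment:control (default 1).
#' @param dropout_hazard exponential loss-to-follow-up hazard per month
#'   (default 0).
#' @param scale `"difference"` (default, the hazard-difference statistic of
#'   the original method) or `"log"` (log-hazard-ratio statistic).
#' @return list: `n_total` (smallest integer total sample size achieving
#'   the power), `n_events` (expected events, rounded), `n_raw`,
#'   `n_per_group`, `event_probabilities`.
#' @export
lachin_foulkes_n <- function(hr, median_control, accrual_months,
                             followup_months, alpha = 0.05, power = 0.80,
                             ratio = 1, dropout_hazard = 0,
                             scale = c("difference", "log")) {
  scale <- match.arg(scale)
  if (hr <= 0 || hr >= 1) stop("hr must lie in (0, 1)")
  if (median_control <= 0) stop("median_control must be > 0")
  if (accrual_months <= 0 || followup_months < 0)
    stop("accrual and follow-up must be positive")
  lam_c <- log(2) / median_control
  lam_t <- lam_c * hr
  q_c <- 1 / (1 + ratio); q_t <- ratio / (1 + ratio)
  za <- stats::qnorm(1 - alpha / 2)
  zb <- stats::qnorm(power)
  p_c <- .event_probability(lam_c, accrual_months, followup_months,
                            dropout_hazard)
  p_t <- .event_probability(lam_t, accrual_months, followup_months,
                            dropout_hazard)
  lam_bar <- q_c * lam_c + q_t * lam_t
  p_bar <- .event_probability(lam_bar, accrual_months, followup_months,
                              dropout_hazard)
  if (scale == "difference") {
    phi <- function(lam, p) lam^2 / p
    num <- (za * sqrt(phi(lam_bar, p_bar) * (1 / q_c + 1 / q_t)) +
            zb * sqrt(phi(lam_c, p_c) / q_c + phi(lam_t, p_t) / q_t))^2
    n_raw <- num / (lam_c - lam_t)^2
  } else {
    num <- (za * sqrt((1 / q_c + 1 / q_t) / p_bar) +
            zb * sqrt(1 / (q_c * p_c) + 1 / (q_t * p_t)))^2
    n_raw <- num / log(hr)^2
  }
  n_total <- ceiling(n_raw)
  events <- n_raw * (q_c * p_c + q_t * p_t)
  list(n_total = n_total, n_events = round(events), n_raw = n_raw,
       n_per_group = ceiling(n_raw * c(control = q_c, treatment = q_t)),
       event_probabilities = c(control = p_c, treatment = p_t,
                               pooled = p_bar))
}
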