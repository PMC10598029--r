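#' Expected log2 read-count ratio of a copy state in admixed plasma
#'
#' Plasma DNA is a two-component mixture: a fraction `tfx` of fragments
#' derives from tumor cells with integer copy number `c` and the remainder
#' from diploid normal cells. The expected depth ratio against a diploid
#' reference is therefore `(tfx * c + 2 * (1 - tfx)) / 2`, and its log2 is
#' the emission mean used by the copy-number HMM.
#'
#' @param tfx tumor fraction in `[0, 1]`.
#' @param c integer copy number (vectorised), `c >= 0`.
#' @param floor lower bound applied to the log2 ratio; the homozygous
#'   deletion state at `tfx = 1` is `-Inf` analytically and is clamped here
#'   (default -8).
#' @return numeric vector of expected log2 ratios.
#' @export
expected_log2 <- function(tfx, c, floor = -8) {
  if (tfx < 0 || tfx > 1) stop("tfx must lie in [0, 1]")
  if (any(c < 0)) stop("copy numbers must be >= 0")
  mix <- (tfx * c + 2 * (1 - tfx)) / 2
  out <- ifelse(mix <= 0, floor, log2(mix))
  pmax(out, floor)
}

# transition matrix: sticky diagonal; off-diagonal mass shared in proportion
# to exp(-penalty * |c - 2|), which breaks the exact likelihood tie between
# (tfx, moderate states) and (tfx/2, extreme states) in favor of the
# parsimonious explanation closer to diploid
.hmm_transitions <- function(states, p_stay, penalty) {
  k <- length(states)
  w <- exp(-penalty * abs(states - 2))
  A <- matrix(0, k, k)
  for (j in seq_len(k)) {
    off <- w; off[j] <- 0
    A[j, ] <- (1 - p_stay) * off / sum(off)
    A[j, j] <- p_stay
  }
  A
}

.hmm_init <- function(states, penalty) {
  w <- exp(-penalty * abs(states - 2))
  w / sum(w)
}

#' Scaled forward-backward pass for the copy-number HMM
#'
#' @param x numeric vector of observed log2 ratios.
#' @param tfx tumor fraction defining the emission means.
#' @param sigma emission standard deviation (shared across states).
#' @param states integer copy states (default `0:4`).
#' @param p_stay self-transition probability (default 0.99).
#' @param penalty state-distance penalty on entering non-neutral states
#'   (default 2).
#' @return list: `gamma` (bins x states posterior matrix, rows sum to 1),
#'   `loglik` (observed-data log-likelihood), `alpha`, `beta` (scaled).
#' @export
forward_backward <- function(x, tfx, sigma, states = 0:4, p_stay = 0.99,
                             penalty = 2) {
  n <- length(x); k <- length(states)
  mu <- expected_log2(tfx, states)
  B <- vapply(seq_len(k), function(j) stats::dnorm(x, mu[j], sigma),
              numeric(n))
  B <- matrix(B, nrow = n)
  A <- .hmm_transitions(states, p_stay, penalty)
  pi0 <- .hmm_init(states, penalty)

  alpha <- matrix(0, n, k); scal <- numeric(n)
  a <- pi0 * B[1, ]
  scal[1] <- sum(a)
  if (scal[1] <= 0) scal[1] <- .Machine$double.xmin
  alpha[1, ] <- a / scal[1]
  for (t in 2:n) {
    a <- (alpha[t - 1, ] %*% A) * B[t, ]
    scal[t] <- sum(a)
    if (scal[t] <= 0) scal[t] <- .Machine$double.xmin
    alpha[t, ] <- a / scal[t]
  }
  beta <- matrix(0, n, k)
  beta[n, ] <- 1
  for (t in (n - 1):1) {
    b <- A %*% (B[t + 1, ] * beta[t + 1, ])
    beta[t, ] <- b / scal[t + 1]
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  list(gamma = gamma, loglik = sum(log(scal)), alpha = alpha, beta = beta)
}

#' Viterbi decoding of the copy-number HMM
#'
#' @inheritParams forward_backward
#' @return integer vector of decoded copy states (values from `states`).
#' @export
viterbi_path <- function(x, tfx, sigma, states = 0:4, p_stay = 0.99,
                         penalty = 2) {
  n <- length(x); k <- length(states)
  mu <- expected_log2(tfx, states)
  logB <- vapply(seq_len(k),
                 function(j) stats::dnorm(x, mu[j], sigma, log = TRUE),
                 numeric(n))
  logB <- matrix(logB, nrow = n)
  logA <- log(.hmm_transitions(states, p_stay, penalty))
  logpi <- log(.hmm_init(states, penalty))

  delta <- matrix(-Inf, n, k); psi <- matrix(0L, n, k)
  delta[1, ] <- logpi + logB[1, ]
  for (t in 2:n) {
    for (j in seq_len(k)) {
      cand <- delta[t - 1, ] + logA[, j]
      psi[t, j] <- which.max(cand)
      delta[t, j] <- cand[psi[t, j]] + logB[t, j]
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  for (t in (n - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  states[path]
}

#' Fit the tumor-fraction HMM by expectation-maximization
#'
#' Emissions are Normal with state means [expected_log2()] and one shared
#' standard deviation. The E-step is a scaled forward-backward pass; the
#' M-step maximizes the expected complete-data log-likelihood over `tfx` by
#' one-dimensional numerical search with the emission variance profiled out
#' in closed form. The EM is restarted from every value of `init_tfx_grid`
#' and the fit with the best log-likelihood is kept; final states come from
#' Viterbi decoding. A fit whose decoded path is entirely copy-neutral
#' carries no copy-number evidence and is reported with `tfx = 0`.
#'
#' @param log2r numeric vector of corrected log2 ratios (masked bins already
#'   removed), or a data.frame from [correct_bins()] with columns `log2r`
#'   and `masked`.
#' @param states integer copy states (default `0:4`, i.e. homozygous
#'   deletion to amplification).
#' @param init_tfx_grid tumor-fraction restart grid (default
#'   `seq(0.05, 0.5, by = 0.05)` plus coarse high-burden restarts 0.65 and
#'   0.8; without the latter the EM cannot escape the mirror basin at
#'   `tfx / 2` when the true tumor fraction exceeds one half).
#' @param max_iter maximal EM iterations per restart (default 50).
#' @param tol absolute log-likelihood convergence tolerance (default 1e-4).
#' @param p_stay HMM self-transition probability (default 0.99).
#' @param penalty state-distance penalty, see [forward_backward()].
#' @param min_bins minimal number of usable bins (default 50).
#' @return object of class `"tfx_fit"`: list with `tfx`, `sigma`, `loglik`,
#'   `states` (decoded per bin), `posterior` (bins x states), `converged`,
#'   `n_iter`, `loglik_trace` (per-iteration log-likelihoods of the kept
#'   restart), `restarts` (per-restart summary data.frame).
#' @export
fit_hmm_em <- function(log2r, states = 0:4,
                       init_tfx_grid = c(seq(0.05, 0.5, by = 0.05),
                                         0.65, 0.8),
                       max_iter = 50, tol = 1e-4, p_stay = 0.99,
                       penalty = 2, min_bins = 50) {
  if (is.data.frame(log2r)) {
    if (!all(c("log2r", "masked") %in% names(log2r)))
      stop("data.frame input needs columns log2r and masked")
    log2r <- log2r$log2r[!log2r$masked]
  }
  x <- log2r[is.finite(log2r)]
  if (length(x) < min_bins)
    stop("need at least ", min_bins, " usable bins, got ", length(x))

  run_em <- function(tfx0) {
    tfx <- tfx0
    sigma <- max(stats::sd(x), 1e-3)
    ll_old <- -Inf; converged <- FALSE; it <- 0
    fb <- NULL; trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      fb <- forward_backward(x, tfx, sigma, states, p_stay, penalty)
      # profiled expected complete-data log-likelihood as a function of tfx
      qfun <- function(tf) {
        mu <- expected_log2(tf, states)
        res2 <- vapply(seq_along(states),
                       function(j) (x - mu[j])^2, numeric(length(x)))
        s2 <- sum(fb$gamma * res2) / length(x)
        -length(x) / 2 * log(max(s2, 1e-12))
      }
      opt <- stats::optimize(qfun, interval = c(0, 1), maximum = TRUE,
                             tol = 1e-6)
      # never move to a worse point than the current tfx (guards EM ascent)
      tfx_new <- if (opt$objective >= qfun(tfx)) opt$maximum else tfx
      mu <- expected_log2(tfx_new, states)
      res2 <- vapply(seq_along(states),
                     function(j) (x - mu[j])^2, numeric(length(x)))
      sigma <- sqrt(max(sum(fb$gamma * res2) / length(x), 1e-8))
      tfx <- tfx_new
      trace <- c(trace, fb$loglik)
      if (is.finite(ll_old) && abs(fb$loglik - ll_old) < tol) {
        converged <- TRUE
        break
      }
      ll_old <- fb$loglik
    }
    fb <- forward_backward(x, tfx, sigma, states, p_stay, penalty)
    list(tfx = tfx, sigma = sigma, loglik = fb$loglik, gamma = fb$gamma,
         converged = converged, n_iter = it,
         loglik_trace = c(trace, fb$loglik))
  }

  fits <- lapply(init_tfx_grid, run_em)
  lls <- vapply(fits, function(f) f$loglik, numeric(1))
  best <- fits[[which.max(lls)]]
  path <- viterbi_path(x, best$tfx, best$sigma, states, p_stay, penalty)
  tfx_out <- if (all(path == 2)) 0 else best$tfx
  structure(list(
    tfx = tfx_out, sigma = best$sigma, loglik = best$loglik,
    states = path, posterior = best$gamma, converged = best$converged,
    n_iter = best$n_iter, loglik_trace = best$loglik_trace,
    restarts = data.frame(init_tfx = init_tfx_grid, loglik = lls,
                          tfx = vapply(fits, `[[`, numeric(1), "tfx"),
                          converged = vapply(fits, `[[`, logical(1),
                                             "converged"))),
    class = "tfx_fit")
}

#' @export
print.tfx_fit <- function(x, ...) {
  cat("Tumor-fraction HMM fit\n")
  cat(sprintf("  TFx: %.4f  sigma: %.4f  loglik: %.2f  converged: %s\n",
              x$tfx, x$sigma, x$loglik, x$converged))
  cat("  decoded states:", paste(names(table(x$states)), as.integer(table(x$states)),
                                 sep = ":", collapse = "  "), "\n")
  invisible(x)
}

#' Build a panel-of-normals bin reference
#'
#' Each healthy-donor sample is GC-corrected by loess and scaled to its own
#' median; the per-bin median across donors is the diploid reference every
#' tumor sample is normalized against. Bins with low mappability or a zero
#' reference median are masked for all downstream samples.
#'
#' @param normals list of bin data.frames, each with `chrom`, `arm`,
#'   `start`, `end`, `gc`, `mappability`, `count`, identical bin layout.
#' @param min_mappability bins below this are masked (default 0.9).
#' @param gc_span loess span for the GC fit (default 0.75).
#' @return data.frame: bin layout columns plus `median_corrected` and
#'   `masked`.
#' @export
normal_reference <- function(normals, min_mappability = 0.9,
                             gc_span = 0.75) {
  if (length(normals) < 3) stop("need at least 3 normal samples")
  layout <- normals[[1]][, c("chrom", "arm", "start", "end", "gc",
                             "mappability")]
  for (nb in normals[-1]) {
    if (nrow(nb) != nrow(layout) ||
        !all(nb$chrom == layout$chrom & nb$start == layout$start))
      stop("bin layout differs between normal samples")
  }
  corrected <- vapply(normals, function(nb) .gc_correct(nb, gc_span),
                      numeric(nrow(layout)))
  layout$median_corrected <- apply(matrix(corrected, nrow = nrow(layout)),
                                   1, stats::median)
  layout$masked <- layout$mappability < min_mappability |
    !is.finite(layout$median_corrected) | layout$median_corrected <= 0
  layout
}

# loess GC correction; returns counts divided by the fitted GC trend and
# scaled to median 1
.gc_correct <- function(bins, gc_span = 0.75) {
  ct <- bins$count
  if (length(unique(bins$gc)) < 5) {
    fit <- rep(stats::median(ct), length(ct))
  } else {
    lo <- stats::loess(ct ~ gc, data = data.frame(ct = ct, gc = bins$gc),
                       span = gc_span, degree = 2,
                       family = "symmetric")
    fit <- stats::predict(lo, newdata = data.frame(gc = bins$gc))
  }
  fit[!is.finite(fit) | fit <= 0] <- stats::median(ct)
  r <- ct / fit
  r / stats::median(r[r > 0])
}

#' GC-correct and normalize a sample against the panel of normals
#'
#' The sample's bin counts are loess-corrected for GC bias, divided by the
#' panel-of-normals per-bin median and expressed as log2 ratios against the
#' sample's own median, so a copy-neutral genome sits at 0.
#'
#' @param bins data.frame with `chrom`, `arm`, `start`, `end`, `gc`,
#'   `mappability`, `count` for one sample.
#' @param pon reference from [normal_reference()]; bin layout must match.
#' @param gc_span loess span (default 0.75).
#' @return `bins` with added columns `log2r` (NA where masked) and `masked`;
#'   attribute `n_masked` records the mask size.
#' @export
correct_bins <- function(bins, pon, gc_span = 0.75) {
  if (nrow(bins) != nrow(pon) ||
      !all(bins$chrom == pon$chrom & bins$start == pon$start))
    stop("bin layout differs between sample and panel of normals")
  corr <- .gc_correct(bins, gc_span)
  ratio <- corr / pon$median_corrected
  masked <- pon$masked | !is.finite(ratio) | ratio <= 0
  med <- stats::median(ratio[!masked])
  out <- bins
  out$log2r <- ifelse(masked, NA_real_, log2(ratio / med))
  out$masked <- masked
  attr(out, "n_masked") <- sum(masked)
  out
}

#' Arm-level copy-number calls and the aneuploidy score
#'
#' A chromosome arm is called gained (lost) when at least `arm_fraction_min`
#' of its unmasked bins decode to a state above (below) diploid. An arm
#' where both directions reach the threshold is `"complex"` and counts as
#' altered. The aneuploidy score is the number of arms with a non-neutral
#' call; arms whose bins are entirely masked are excluded from the
#' denominator and listed.
#'
#' @param bins data.frame from [correct_bins()] (needs `chrom`, `arm`,
#'   `masked`).
#' @param states decoded copy states for the unmasked bins, in bin order
#'   (e.g. `fit$states` from [fit_hmm_em()]).
#' @param arm_fraction_min fraction of an arm's bins that must agree for an
#'   arm-level call (default 0.5).
#' @return list: `arm_calls` (data.frame `chrom`, `arm`, `n_bins`,
#'   `frac_gain`, `frac_loss`, `call`), `aneuploidy_score` (integer),
#'   `excluded_arms` (character).
#' @export
arm_calls <- function(bins, states, arm_fraction_min = 0.5) {
  unmasked <- !bins$masked
  if (sum(unmasked) != length(states))
    stop("states must have one entry per unmasked bin")
  full_states <- rep(NA_integer_, nrow(bins))
  full_states[unmasked] <- states
  key <- paste(bins$chrom, bins$arm, sep = "|")
  arms <- unique(key)
  out <- list(); excluded <- character()
  for (a in arms) {
    idx <- which(key == a & unmasked)
    parts <- strsplit(a, "|", fixed = TRUE)[[1]]
    if (length(idx) == 0) { excluded <- c(excluded, a); next }
    st <- full_states[idx]
    fg <- mean(st > 2); fl <- mean(st < 2)
    call <- if (fg >= arm_fraction_min && fl >= arm_fraction_min) "complex"
      else if (fg >= arm_fraction_min) "gain"
      else if (fl >= arm_fraction_min) "loss"
      else "neutral"
    out[[length(out) + 1L]] <- data.frame(
      chrom = parts[1], arm = parts[2], n_bins = length(idx),
      frac_gain = fg, frac_loss = fl, call = call,
      stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, out)
  rownames(calls) <- NULL
  list(arm_calls = calls,
       aneuploidy_score = sum(calls$call != "neutral"),
       excluded_arms = excluded)
}

#' One-call tumor-fraction estimation from raw bin counts
#'
#' Convenience wrapper: normalizes a sample against the panel of normals,
#' fits the HMM by EM, decodes states, derives arm-level calls and applies
#' the detection floor.
#'
#' @inheritParams correct_bins
#' @param tfx_min detection floor on the estimated tumor fraction
#'   (default 0.04); estimates at or below it are reported as not detected.
#' @param ... passed to [fit_hmm_em()].
#' @return list of class `"tfx_result"`: `tfx`, `detected`, `sigma`,
#'   `loglik`, `converged`, `fit` (the `"tfx_fit"`), `bins` (corrected),
#'   `arm_calls`, `aneuploidy_score`.
#' @export
estimate_tfx <- function(bins, pon, tfx_min = 0.04, gc_span = 0.75, ...) {
  cb <- correct_bins(bins, pon, gc_span)
  fit <- fit_hmm_em(cb$log2r[!cb$masked], ...)
  ac <- arm_calls(cb, fit$states)
  structure(list(tfx = fit$tfx, detected = fit$tfx > tfx_min,
                 sigma = fit$sigma, loglik = fit$loglik,
                 converged = fit$converged, fit = fit, bins = cb,
                 arm_calls = ac$arm_calls,
                 aneuploidy_score = ac$aneuploidy_score),
            class = "tfx_result")
}

#' @export
print.tfx_result <- function(x, ...) {
  cat(sprintf("TFx %.4f (%s), aneuploidy score %d, sigma %.4f\n",
              x$tfx, if (x$detected) "detected" else "not detected",
              x$aneuploidy_score, x$sigma))
  invisible(x)
}

#' Read / write bin-count tables
#'
#' Plain TSV with fixed columns `chrom`, `arm`, `start`, `end`, `gc`,
#' `mappability`, `count`.
#'
#' @param x bin data.frame.
#' @param path file path.
#' @return `read_bins_tsv` returns the data.frame; `write_bins_tsv` returns
#'   `path` invisibly.
#' @export
write_bins_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bins_tsv
#' @export
read_bins_tsv <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  req <- c("chrom", "arm", "start", "end", "gc", "mappability", "count")
  miss <- setdiff(req, names(x))
  if (length(miss) > 0) stop("bin TSV missing columns: ",
                             paste(miss, collapse = ", "))
  x
}
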