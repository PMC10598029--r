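#' Collapse UMI-tagged reads into consensus molecules
#'
#' Groups reads by (UMI, locus) and calls one consensus molecule per group:
#' the majority allele, provided the majority fraction is at least `f_min`
#' and the family holds at least `s_min` reads. Families failing either rule
#' are discarded and counted. Collapsing PCR duplicates this way removes
#' amplification and sequencing artifacts before any allele fraction is
#' computed.
#'
#' @param reads data.frame with one row per read: `umi`, `chrom`, `pos`,
#'   `ref`, `alt`, `allele` (the observed base, compared literally against
#'   `ref`/`alt`; anything else counts as "other"). A `sample_id` column is
#'   carried through if present.
#' @param f_min minimal majority fraction within a family for a consensus
#'   call (default 0.75).
#' @param s_min minimal family size in reads (default 1; raise to 3 for
#'   stricter duplex-free consensus).
#'
#' @return list with `observations` (data.frame per locus: `chrom`, `pos`,
#'   `ref`, `alt`, `total_families`, `alt_families`, `vaf`; `vaf` is `NA`
#'   where `total_families` is 0), `families` (per consensus molecule:
#'   `umi`, `chrom`, `pos`, `allele`, `family_size`) and `n_discarded`.
#' @export
collapse_umi <- function(reads, f_min = 0.75, s_min = 1) {
  stopifnot(is.data.frame(reads))
  if (nrow(reads) == 0) {
    return(list(observations = data.frame(
      chrom = character(), pos = integer(), ref = character(),
      alt = character(), total_families = integer(),
      alt_families = integer(), vaf = numeric()),
      families = data.frame(), n_discarded = 0L))
  }
  req <- c("umi", "chrom", "pos", "ref", "alt", "allele")
  miss <- setdiff(req, names(reads))
  if (length(miss) > 0) stop("reads is missing columns: ",
                             paste(miss, collapse = ", "))
  key <- paste(reads$umi, reads$chrom, reads$pos, sep = "\r")
  tab <- table(key, reads$allele)
  sizes <- as.integer(rowSums(tab))
  jmax <- max.col(tab, ties.method = "first")  # deterministic tie-break
  maxn <- tab[cbind(seq_len(nrow(tab)), jmax)]
  first <- reads[match(rownames(tab), key), , drop = FALSE]
  fam <- data.frame(umi = first$umi, chrom = first$chrom, pos = first$pos,
                    ref = first$ref, alt = first$alt,
                    allele = colnames(tab)[jmax],
                    family_size = sizes,
                    majority_fraction = as.numeric(maxn) / sizes,
                    stringsAsFactors = FALSE)
  keep <- fam$majority_fraction >= f_min & fam$family_size >= s_min
  n_discarded <- sum(!keep)
  fam <- fam[keep, , drop = FALSE]
  rownames(fam) <- NULL

  loci <- unique(reads[, c("chrom", "pos", "ref", "alt")])
  loci <- loci[order(loci$chrom, loci$pos), , drop = FALSE]
  obs <- do.call(rbind, lapply(seq_len(nrow(loci)), function(i) {
    fl <- fam[fam$chrom == loci$chrom[i] & fam$pos == loci$pos[i], ,
              drop = FALSE]
    total <- nrow(fl)
    altn <- sum(fl$allele == loci$alt[i])
    data.frame(chrom = loci$chrom[i], pos = loci$pos[i],
               ref = loci$ref[i], alt = loci$alt[i],
               total_families = total, alt_families = altn,
               vaf = if (total > 0) altn / total else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(obs) <- NULL
  list(observations = obs,
       families = fam[, c("umi", "chrom", "pos", "allele", "family_size")],
       n_discarded = n_discarded)
}

#' Mean variant allele fraction of a sample over its panel loci
#'
#' Averages per-locus consensus VAFs over loci whose VAF reaches the
#' ultra-deep detection floor `vaf_min` (default 0.1%). Loci below the floor
#' are treated as noise and excluded from the mean; a sample with covered
#' loci but none passing is reported as `"not_detected"`, which is distinct
#' from a mean of zero. A sample with zero consensus families at every locus
#' cannot be assessed at all and is `"not_evaluable"`.
#'
#' @param observations data.frame as returned in
#'   `collapse_umi()$observations` (needs `total_families`, `vaf`).
#'   Restrict to loci classified somatic before calling (see
#'   [classify_germline()]).
#' @param vaf_min detection threshold on per-locus VAF (default 0.001).
#' @return list: `status` (`"detected"`, `"not_detected"` or
#'   `"not_evaluable"`), `mean_vaf` (numeric, `NA` unless detected),
#'   `n_loci_passing`, `n_loci_covered`.
#' @export
mean_vaf <- function(observations, vaf_min = 0.001) {
  stopifnot(is.data.frame(observations))
  covered <- observations[!is.na(observations$vaf) &
                          observations$total_families > 0, , drop = FALSE]
  if (nrow(covered) == 0)
    return(list(status = "not_evaluable", mean_vaf = NA_real_,
                n_loci_passing = 0L, n_loci_covered = 0L))
  pass <- covered[covered$vaf >= vaf_min, , drop = FALSE]
  if (nrow(pass) == 0)
    return(list(status = "not_detected", mean_vaf = NA_real_,
                n_loci_passing = 0L, n_loci_covered = nrow(covered)))
  list(status = "detected", mean_vaf = mean(pass$vaf),
       n_loci_passing = nrow(pass), n_loci_covered = nrow(covered))
}

#' Classify a tracked locus as somatic or germline
#'
#' A variant picked from tumor tissue can turn out to be an inherited
#' heterozygous polymorphism; such loci sit near 50% VAF in matched normal
#' (mononuclear-cell) sequencing and must be excluded from ctDNA
#' quantification. The call is made from the normal-tissue VAF alone:
#' `>= germline_min` is germline, `<= somatic_max` is somatic, anything in
#' between is ambiguous (excluded from the mean VAF, with a warning upstream).
#'
#' @param normal_vaf VAF of the locus in matched normal DNA; `NA` if no
#'   normal is available.
#' @param germline_min threshold above which the locus is germline
#'   (default 0.25).
#' @param somatic_max threshold below which the locus is somatic
#'   (default 0.02).
#' @return one of `"somatic"`, `"germline"`, `"ambiguous"`, `"unknown"`
#'   (no normal available); vectorised over `normal_vaf`.
#' @export
classify_germline <- function(normal_vaf, germline_min = 0.25,
                              somatic_max = 0.02) {
  if (germline_min <= somatic_max)
    stop("germline_min must exceed somatic_max")
  out <- rep("unknown", length(normal_vaf))
  out[!is.na(normal_vaf) & normal_vaf >= germline_min] <- "germline"
  out[!is.na(normal_vaf) & normal_vaf <= somatic_max] <- "somatic"
  out[!is.na(normal_vaf) & normal_vaf > somatic_max &
        normal_vaf < germline_min] <- "ambiguous"
  out
}

#' Read / write per-sample variant observation tables
#'
#' Plain TSV with fixed columns `chrom`, `pos`, `ref`, `alt`,
#' `total_families`, `alt_families` (plus any extras, preserved).
#'
#' @param x data.frame of observations.
#' @param path file path.
#' @return `read_variant_tsv` returns the data.frame with a recomputed
#'   `vaf` column; `write_variant_tsv` returns `path` invisibly.
#' @export
write_variant_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_variant_tsv
#' @export
read_variant_tsv <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  req <- c("chrom", "pos", "ref", "alt", "total_families", "alt_families")
  miss <- setdiff(req, names(x))
  if (length(miss) > 0) stop("variant TSV missing columns: ",
                             paste(miss, collapse = ", "))
  if (any(x$alt_families > x$total_families))
    stop("alt_families exceeds total_families")
  x$vaf <- ifelse(x$total_families > 0,
                  x$alt_families / x$total_families, NA_real_)
  x
}
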