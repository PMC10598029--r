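#' Select hotspot regions for a patient-specific capture panel
#'
#' Picks, for every patient, the `k_per_patient` somatic tissue variants with
#' the highest tissue variant allele fraction (VAF) and builds a symmetric
#' window around each as a capture target. Patients with fewer than
#' `k_per_patient` somatic variants contribute all they have and are flagged
#' as under-covered; patients with no somatic variants contribute nothing and
#' are flagged as well.
#'
#' @param variants data.frame with columns `patient_id`, `gene`, `chrom`,
#'   `pos` (0-based variant position), `ref`, `alt`, `tissue_vaf` (in
#'   `[0, 1]`). One row per somatic variant. Patients present in the cohort
#'   but without any somatic variant may be listed via `all_patients`.
#' @param k_per_patient number of hotspot variants to retain per patient
#'   (default 2). Ties on `tissue_vaf` are broken by (`chrom`, `pos`)
#'   ascending so selection is deterministic.
#' @param flank half-width in bp of the region built around each variant
#'   position (default 30, i.e. a 61 bp target containing the variant).
#' @param all_patients optional character vector of every patient in the
#'   cohort; patients absent from `variants` are then flagged as having no
#'   trackable somatic variant.
#' @param always_include optional data.frame of fixed regions (`chrom`,
#'   `start`, `end`, `gene`) appended for every design, e.g. the full exon
#'   set of a recurrently mutated tumor suppressor.
#'
#' @return list with components `regions` (data.frame: `patient_id`, `gene`,
#'   `chrom`, `start`, `end`, `anchor_pos`, `tissue_vaf`; 0-based half-open
#'   intervals) and `flagged` (data.frame: `patient_id`, `n_variants`,
#'   `reason` one of `"no_somatic_variants"`, `"under_covered"`).
#' @export
select_hotspots <- function(variants, k_per_patient = 2, flank = 30,
                            all_patients = NULL, always_include = NULL) {
  stopifnot(is.data.frame(variants))
  req <- c("patient_id", "chrom", "pos", "tissue_vaf")
  miss <- setdiff(req, names(variants))
  if (length(miss) > 0)
    stop("variants is missing columns: ", paste(miss, collapse = ", "))
  if (k_per_patient < 1) stop("k_per_patient must be >= 1")
  if (flank < 0) stop("flank must be >= 0")
  if (is.null(all_patients)) all_patients <- unique(variants$patient_id)
  if (length(all_patients) == 0) stop("empty cohort: no patients supplied")
  if (nrow(variants) > 0 &&
      (any(variants$tissue_vaf < 0) || any(variants$tissue_vaf > 1)))
    stop("tissue_vaf must lie in [0, 1]")
  if (!"gene" %in% names(variants)) variants$gene <- NA_character_

  regions <- list()
  flagged <- list()
  for (pid in all_patients) {
    pv <- variants[variants$patient_id == pid, , drop = FALSE]
    if (nrow(pv) == 0) {
      flagged[[length(flagged) + 1L]] <- data.frame(
        patient_id = pid, n_variants = 0L,
        reason = "no_somatic_variants", stringsAsFactors = FALSE)
      next
    }
    # highest VAF first; ties by genomic coordinate ascending
    ord <- order(-pv$tissue_vaf, pv$chrom, pv$pos)
    keep <- pv[ord[seq_len(min(k_per_patient, nrow(pv)))], , drop = FALSE]
    if (nrow(pv) < k_per_patient) {
      flagged[[length(flagged) + 1L]] <- data.frame(
        patient_id = pid, n_variants = nrow(pv),
        reason = "under_covered", stringsAsFactors = FALSE)
    }
    regions[[length(regions) + 1L]] <- data.frame(
      patient_id = keep$patient_id, gene = keep$gene, chrom = keep$chrom,
      start = pmax(0L, as.integer(keep$pos) - as.integer(flank)),
      end = as.integer(keep$pos) + as.integer(flank) + 1L,
      anchor_pos = as.integer(keep$pos), tissue_vaf = keep$tissue_vaf,
      stringsAsFactors = FALSE)
  }
  regions <- if (length(regions)) do.call(rbind, regions) else
    data.frame(patient_id = character(), gene = character(),
               chrom = character(), start = integer(), end = integer(),
               anchor_pos = integer(), tissue_vaf = numeric())
  if (!is.null(always_include) && nrow(always_include) > 0) {
    fixed <- data.frame(patient_id = "cohort", gene = always_include$gene,
                        chrom = always_include$chrom,
                        start = as.integer(always_include$start),
                        end = as.integer(always_include$end),
                        anchor_pos = NA_integer_, tissue_vaf = NA_real_,
                        stringsAsFactors = FALSE)
    regions <- rbind(regions, fixed)
  }
  flagged <- if (length(flagged)) do.call(rbind, flagged) else
    data.frame(patient_id = character(), n_variants = integer(),
               reason = character())
  rownames(regions) <- NULL
  list(regions = regions, flagged = flagged)
}

#' Tile fixed-length capture probes across target regions
#'
#' Places `probe_len`-bp probes on a regular grid of step
#' `probe_len / tiling`, with the first probe starting
#' `probe_len * (1 - 1/tiling)` upstream of the region start, so that every
#' base of the target is covered by at least `tiling` probes with the minimal
#' number of probes under this step rule. Overlapping probes from different
#' regions are kept as designed (no merging).
#'
#' @param regions data.frame with `chrom`, `start`, `end` (0-based
#'   half-open), e.g. the `regions` element of [select_hotspots()].
#' @param probe_len probe length in bp (default 120).
#' @param tiling required per-base probe coverage, 1 or 2 (default 2).
#' @param max_region_len regions longer than this are rejected (default
#'   10000 bp); hotspot targets are expected to be short.
#'
#' @return list with `probes` (data.frame `chrom`, `start`, `end`, `name`,
#'   sorted by (`chrom`, `start`)) and `coverage` (list: `n_probes`,
#'   `target_bases`, `spanned_bases` = unique bases under any probe,
#'   `min_coverage` over target bases).
#' @export
tile_probes <- function(regions, probe_len = 120, tiling = 2,
                        max_region_len = 10000) {
  stopifnot(is.data.frame(regions))
  if (!all(c("chrom", "start", "end") %in% names(regions)))
    stop("regions must have chrom, start, end")
  if (!tiling %in% c(1L, 2L)) stop("tiling must be 1 or 2")
  if (probe_len < tiling) stop("probe_len too small for requested tiling")
  if (nrow(regions) > 0) {
    len <- regions$end - regions$start
    if (any(len < 1)) stop("regions must have length >= 1")
    if (any(len > max_region_len))
      stop("region longer than max_region_len (", max_region_len, " bp)")
  }
  step <- probe_len %/% tiling
  probes <- list()
  for (i in seq_len(nrow(regions))) {
    s <- regions$start[i]; e <- regions$end[i]
    first <- s - (probe_len - step)
    starts <- seq(from = first, to = e - 1L, by = step)
    starts <- starts[starts < e]       # grid probes whose start precedes end
    probes[[i]] <- data.frame(chrom = regions$chrom[i],
                              start = as.integer(starts),
                              end = as.integer(starts + probe_len),
                              stringsAsFactors = FALSE)
  }
  probes <- if (length(probes)) do.call(rbind, probes) else
    data.frame(chrom = character(), start = integer(), end = integer())
  probes <- probes[order(probes$chrom, probes$start, probes$end), ,
                   drop = FALSE]
  rownames(probes) <- NULL
  probes$name <- if (nrow(probes)) sprintf("probe_%04d", seq_len(nrow(probes)))
                 else character()

  cov <- .probe_coverage(regions, probes)
  list(probes = probes,
       coverage = list(n_probes = nrow(probes),
                       target_bases = cov$target_bases,
                       spanned_bases = cov$spanned_bases,
                       min_coverage = cov$min_coverage))
}

# per-base bookkeeping over target bases; regions are short so brute force
# counting is fine and doubles as the design's own audit
.probe_coverage <- function(regions, probes) {
  target_bases <- 0L
  min_cov <- Inf
  for (i in seq_len(nrow(regions))) {
    bases <- seq.int(regions$start[i], regions$end[i] - 1L)
    target_bases <- target_bases + length(bases)
    p <- probes[probes$chrom == regions$chrom[i], , drop = FALSE]
    if (nrow(p) == 0) { min_cov <- 0; next }
    cnt <- vapply(bases, function(b) sum(p$start <= b & p$end > b), integer(1))
    min_cov <- min(min_cov, cnt)
  }
  spanned <- 0L
  for (ch in unique(probes$chrom)) {
    p <- probes[probes$chrom == ch, , drop = FALSE]
    p <- p[order(p$start, p$end), , drop = FALSE]
    cur_s <- cur_e <- NULL
    for (j in seq_len(nrow(p))) {
      if (is.null(cur_s)) { cur_s <- p$start[j]; cur_e <- p$end[j]; next }
      if (p$start[j] <= cur_e) cur_e <- max(cur_e, p$end[j]) else {
        spanned <- spanned + (cur_e - cur_s); cur_s <- p$start[j]; cur_e <- p$end[j]
      }
    }
    if (!is.null(cur_s)) spanned <- spanned + (cur_e - cur_s)
  }
  list(target_bases = target_bases,
       spanned_bases = as.integer(spanned),
       min_coverage = if (is.finite(min_cov)) as.integer(min_cov) else 0L)
}

#' Write a probe panel as a BED6 file
#'
#' Intervals are written 0-based half-open as designed; overlapping probes
#' are preserved, never merged. `read_panel_bed(write_panel_bed(x))`
#' round-trips the intervals exactly.
#'
#' @param probes data.frame with `chrom`, `start`, `end` and optionally
#'   `name`; extra columns are ignored.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel_bed <- function(probes, path) {
  stopifnot(is.data.frame(probes))
  if (nrow(probes) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  bed <- data.frame(
    chrom = probes$chrom,
    start = as.integer(probes$start),
    end = as.integer(probes$end),
    name = if ("name" %in% names(probes)) probes$name else ".",
    score = 0L,
    strand = ".",
    stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED panel file
#'
#' Accepts BED3 to BED6. Malformed lines (fewer than three fields,
#' non-numeric or inverted coordinates) raise an error naming the line
#' number.
#'
#' @param path BED file path.
#' @return data.frame `chrom`, `start`, `end`, `name` (`"."` if absent),
#'   0-based half-open.
#' @export
read_panel_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    if (!nzchar(lines[i])) next
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("malformed BED line ", i, ": fewer than 3 fields")
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end))
      stop("malformed BED line ", i, ": non-integer coordinates")
    if (end <= start || start < 0)
      stop("malformed BED line ", i, ": invalid interval [", f[2], ", ", f[3], ")")
    out[[i]] <- data.frame(chrom = f[1], start = start, end = end,
                           name = if (length(f) >= 4) f[4] else ".",
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
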