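#' Apply DMR retention rules to candidate regions
#'
#' Turns candidate regions from [scan_candidate_regions()] into a final DMR
#' table by enforcing the retention rules: absolute mean percent methylation
#' difference of at least `pmd_min` percentage points, first-to-last-CpG
#' length greater than `len_min_bp`, and no gap between consecutive member
#' sites larger than `gap_max_bp`. A candidate containing an over-long gap is
#' split at every such gap, and each fragment is re-validated against the
#' scan rules (trimmed to significant endpoints, at least `min_sites` sites,
#' UP tail probability at most `alpha_region`) before the PMD and length
#' filters are applied, so no fragment survives on the strength of sites it
#' no longer contains.
#'
#' @param candidates Candidate-region data.frame from
#'   [scan_candidate_regions()].
#' @param sites The site-result data.frame the candidates were scanned from
#'   (row indices in `candidates$first_idx`/`last_idx` refer to it).
#' @param pmd_min Minimum |mean PMD| in percentage points (default 20).
#' @param len_min_bp Regions must be strictly longer than this many bp,
#'   first to last member CpG inclusive (default 250).
#' @param gap_max_bp Maximum allowed distance between consecutive member
#'   sites (default 200).
#' @param alpha_site,alpha_region,min_sites Scan parameters used when
#'   re-validating gap-split fragments; use the values the candidates were
#'   scanned with.
#' @return A DMR data.frame (class `dmr_set`) with the candidate columns plus
#'   `length_bp`, `max_gap_bp`; zero rows if nothing survives.
#' @export
filter_regions <- function(candidates, sites, pmd_min = 20,
                           len_min_bp = 250, gap_max_bp = 200,
                           alpha_site = 0.05, alpha_region = 0.05,
                           min_sites = 5) {
  stopifnot(is.data.frame(candidates), is.data.frame(sites))
  rows <- list()
  for (i in seq_len(nrow(candidates))) {
    idx <- candidates$first_idx[i]:candidates$last_idx[i]
    pos <- sites$pos[idx]
    frag_bounds <- split_at_gaps(pos, gap_max_bp)
    for (f in frag_bounds) {
      fi <- idx[f[1]:f[2]]
      fi <- trim_to_significant(fi, sites$p, alpha_site)
      if (length(fi) < min_sites) next
      up_p <- up_tail_probability(k = length(fi),
                                  log_x = sum(log(sites$p[fi])))
      if (up_p > alpha_region) next
      pmd <- mean(sites$pmd[fi])
      len <- sites$pos[fi[length(fi)]] - sites$pos[fi[1]] + 1L
      gaps <- diff(sites$pos[fi])
      if (abs(pmd) < pmd_min || len <= len_min_bp) next
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = sites$chrom[fi[1]], start_pos = sites$pos[fi[1]],
        end_pos = sites$pos[fi[length(fi)]],
        first_idx = fi[1], last_idx = fi[length(fi)],
        k = length(fi), up_p = up_p, mean_pmd = pmd,
        direction = if (pmd > 0) "hyper" else "hypo",
        length_bp = len,
        max_gap_bp = if (length(gaps)) max(gaps) else 0L,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_dmrs()
  out <- out[order(out$chrom, out$start_pos), , drop = FALSE]
  out <- out[!duplicated(out[c("chrom", "start_pos", "end_pos")]), ,
             drop = FALSE]
  rownames(out) <- NULL
  as_dmr_set(out)
}

empty_dmrs <- function() {
  data.frame(chrom = character(), start_pos = integer(), end_pos = integer(),
             first_idx = integer(), last_idx = integer(), k = integer(),
             up_p = numeric(), mean_pmd = numeric(), direction = character(),
             length_bp = integer(), max_gap_bp = integer(),
             stringsAsFactors = FALSE)
}

as_dmr_set <- function(d) {
  class(d) <- unique(c("dmr_set", class(d)))
  d
}

#' @export
print.dmr_set <- function(x, ...) {
  cat(sprintf("DMR set: %d regions (%d hyper, %d hypo)\n", nrow(x),
              sum(x$direction == "hyper"), sum(x$direction == "hypo")))
  if (nrow(x) > 0) {
    cat(sprintf("span: %d-%d bp, sites: %d-%d, |mean PMD|: %.1f-%.1f\n",
                min(x$length_bp), max(x$length_bp), min(x$k), max(x$k),
                min(abs(x$mean_pmd)), max(abs(x$mean_pmd))))
    print.data.frame(utils::head(as.data.frame(x), 6))
    if (nrow(x) > 6) cat(sprintf("... and %d more\n", nrow(x) - 6))
  }
  invisible(x)
}

#' @method summary dmr_set
#' @export
summary.dmr_set <- function(object, ...) {
  data.frame(n = nrow(object),
             n_hyper = sum(object$direction == "hyper"),
             n_hypo = sum(object$direction == "hypo"),
             median_length_bp = if (nrow(object)) stats::median(object$length_bp) else NA,
             median_sites = if (nrow(object)) stats::median(object$k) else NA,
             mean_abs_pmd = if (nrow(object)) mean(abs(object$mean_pmd)) else NA)
}

# Fragment index bounds (local, 1-based within the candidate) after cutting
# every inter-site gap > gap_max_bp.
split_at_gaps <- function(pos, gap_max_bp) {
  if (length(pos) == 1L) return(list(c(1L, 1L)))
  cut <- which(diff(pos) > gap_max_bp)
  starts <- c(1L, cut + 1L)
  ends <- c(cut, length(pos))
  lapply(seq_along(starts), function(i) c(starts[i], ends[i]))
}

trim_to_significant <- function(idx, p, alpha_site) {
  sig <- which(p[idx] <= alpha_site)
  if (length(sig) == 0) return(integer(0))
  idx[sig[1]:sig[length(sig)]]
}

#' Intersect pairwise and multi-control DMR sets
#'
#' Implements the final-set rule of the two-stage design: a DMR from the
#' multi-control comparison is retained only if it is corroborated by a
#' same-direction DMR from the designated pairwise comparison, overlapping it
#' by at least `min_overlap_bp`. Coordinates come from the multi-control DMR.
#' When the site results of the designated reporting comparison are supplied,
#' `reported_pmd` is recomputed as the mean per-site PMD of that comparison
#' over the retained DMR's coordinates, which is the convention used for all
#' reported PMD values.
#'
#' @param pairwise_dmrs,multicontrol_dmrs Filtered, direction-labeled DMR
#'   data.frames from [filter_regions()].
#' @param min_overlap_bp Minimum overlap in bp (default 50).
#' @param reporting_sites Optional site-result table of the reporting
#'   (pairwise) comparison for `reported_pmd`; `NA` otherwise.
#' @return The retained multi-control DMRs with a `reported_pmd` column.
#' @export
intersect_dmr_sets <- function(pairwise_dmrs, multicontrol_dmrs,
                               min_overlap_bp = 50, reporting_sites = NULL) {
  if (nrow(multicontrol_dmrs) == 0 || nrow(pairwise_dmrs) == 0) {
    out <- multicontrol_dmrs[integer(0), , drop = FALSE]
    out$reported_pmd <- numeric(0)
    return(as_dmr_set(out))
  }
  gm <- dmr_granges(multicontrol_dmrs)
  gp <- dmr_granges(pairwise_dmrs)
  hits <- GenomicRanges::findOverlaps(gm, gp, minoverlap = min_overlap_bp)
  same_dir <- multicontrol_dmrs$direction[S4Vectors::queryHits(hits)] ==
    pairwise_dmrs$direction[S4Vectors::subjectHits(hits)]
  keep <- sort(unique(S4Vectors::queryHits(hits)[same_dir]))
  out <- multicontrol_dmrs[keep, , drop = FALSE]
  out$reported_pmd <- if (is.null(reporting_sites))
    rep(NA_real_, nrow(out)) else
    vapply(seq_len(nrow(out)), function(i) {
      inreg <- reporting_sites$chrom == out$chrom[i] &
        reporting_sites$pos >= out$start_pos[i] &
        reporting_sites$pos <= out$end_pos[i]
      if (any(inreg)) mean(reporting_sites$pmd[inreg]) else NA_real_
    }, numeric(1))
  rownames(out) <- NULL
  as_dmr_set(out)
}

# GRanges from 1-based inclusive DMR coordinates.
dmr_granges <- function(d) {
  GenomicRanges::GRanges(d$chrom,
                         IRanges::IRanges(start = d$start_pos,
                                          end = d$end_pos))
}
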