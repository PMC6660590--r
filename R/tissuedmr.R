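#' Call tissue-specific DMRs by a one-to-many comparison
#'
#' Compares one target methylome against the remaining samples of a panel
#' treated as a single pooled group. Only sites covered in the target and in
#' at least `min_nontarget_present` of the non-target samples are tested (the
#' default, panel size minus one, generalizes the 4-of-5 rule used with a
#' six-tissue panel). Site testing uses the grouped binomial
#' likelihood-ratio test ([site_test_group()]); region calling and filtering
#' then proceed exactly as in the case/control analysis
#' ([scan_candidate_regions()] + [filter_regions()]), with the same default
#' thresholds. A `"hyper"` direction means the target is more methylated
#' than the panel (tissue-hypermethylated), `"hypo"` the reverse.
#'
#' @param mat A harmonized [MethylomeMatrix] containing the panel.
#' @param target Target sample name (error if absent).
#' @param others Non-target sample names (default: all other samples).
#' @param min_nontarget_present Presence rule threshold (default
#'   `length(others) - 1`).
#' @param min_coverage Reads needed for a sample to count as present
#'   (default 1).
#' @param alpha_site,alpha_region,min_sites,max_window_sites Scan parameters
#'   (see [scan_candidate_regions()]).
#' @param pmd_min,len_min_bp,gap_max_bp Filter thresholds (see
#'   [filter_regions()]).
#' @return A DMR data.frame; attribute `site_tests` holds the per-site
#'   results the regions were scanned from.
#' @export
call_tissue_dmrs <- function(mat, target, others = NULL,
                             min_nontarget_present = NULL,
                             min_coverage = 1,
                             alpha_site = 0.05, alpha_region = 0.05,
                             min_sites = 5, max_window_sites = 10000,
                             pmd_min = 20, len_min_bp = 250,
                             gap_max_bp = 200) {
  stopifnot(inherits(mat, "MethylomeMatrix"))
  sample_index(mat, target)  # errors when absent
  if (is.null(others)) others <- setdiff(mat$samples, target)
  stopifnot(length(others) >= 1, !(target %in% others))
  if (is.null(min_nontarget_present))
    min_nontarget_present <- max(1L, length(others) - 1L)
  sites <- site_test_group(mat, target, others,
                           min_refs_present = min_nontarget_present,
                           min_coverage = min_coverage)
  cand <- scan_candidate_regions(sites, alpha_site, alpha_region, min_sites,
                                 max_window_sites)
  dmrs <- filter_regions(cand, sites, pmd_min, len_min_bp, gap_max_bp,
                         alpha_site, alpha_region, min_sites)
  attr(dmrs, "site_tests") <- sites
  attr(dmrs, "target") <- target
  dmrs
}
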