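#' Run the full case/control DMR analysis
#'
#' Orchestrates the two-stage DMR discovery design: (1) a pairwise Fisher
#' exact scan of the case against the designated reporting control gives DMR
#' set P; (2) a logistic-regression scan of the case against all controls as
#' a group (sites must be covered in every sample) gives DMR set M; (3) the
#' final set is the same-direction intersection of M with P
#' ([intersect_dmr_sets()]), with reported PMD values recomputed from the
#' designated pairwise comparison. With a single control the multi-control
#' comparison degenerates to the pairwise one (P = M, final = P). If
#' annotation tracks are supplied the final set is annotated; if `out_dir`
#' is given all intermediate sets, the annotation table and a JSON parameter
#' manifest are written there.
#'
#' Each final DMR also gets a `coverage_anomaly` flag, true when some
#' control's mean coverage over the region falls below a quarter of that
#' control's genome-wide mean -- a hint that the multi-control evidence may
#' rest on thin data and the pairwise comparison deserves a direct look.
#'
#' @param x A harmonized [MethylomeMatrix], or a named character vector of
#'   count-file paths (read with [read_cpg_counts()] and harmonized).
#' @param case Case sample name.
#' @param controls Character vector of control sample names (>= 1).
#' @param reporting_control Control used for the pairwise comparison and for
#'   reported PMD values (default: first control).
#' @param min_coverage,alpha_site,alpha_region,min_sites,max_window_sites
#'   Site-test and scan parameters (see [scan_candidate_regions()]).
#' @param pmd_min,len_min_bp,gap_max_bp Filter thresholds (see
#'   [filter_regions()]).
#' @param min_overlap_bp Minimum overlap for the set intersection and for
#'   annotation rules (default 50).
#' @param segments,gene_models,tissue_dmr_sets Optional annotation tracks
#'   (see [annotate_dmrs()]).
#' @param enhancer_states,promoter_kb Annotation parameters.
#' @param dialect Count-file dialect when `x` is a vector of paths.
#' @param out_dir Optional output directory.
#' @param verbose Emit one structured message per stage (default TRUE).
#' @return An `athero_dmr_result` list: `pairwise`, `multicontrol`, `final`
#'   (DMR data.frames), `annotation` (or NULL), `site_tests` (per-site
#'   tables for both comparisons) and `params`.
#' @export
run_athero_analysis <- function(x, case, controls,
                                reporting_control = controls[1],
                                min_coverage = 1, alpha_site = 0.05,
                                alpha_region = 0.05, min_sites = 5,
                                max_window_sites = 10000,
                                pmd_min = 20, len_min_bp = 250,
                                gap_max_bp = 200, min_overlap_bp = 50,
                                segments = NULL, gene_models = NULL,
                                tissue_dmr_sets = NULL,
                                enhancer_states = c(3, 8, 9, 10),
                                promoter_kb = 5,
                                dialect = "bismark-cov",
                                out_dir = NULL, verbose = TRUE) {
  mat <- resolve_matrix(x, dialect)
  stopifnot(length(case) == 1, length(controls) >= 1,
            reporting_control %in% controls)
  for (s in c(case, controls)) sample_index(mat, s)
  say <- function(...) if (verbose) message(sprintf(...))

  sitesP <- site_test_pair(mat, case, reporting_control, min_coverage)
  if (nrow(sitesP) == 0) stop("zero shared sites between case and control")
  say("stage=sitetests_pairwise n_sites=%d n_skipped=%d", nrow(sitesP),
      attr(sitesP, "n_skipped"))
  candP <- scan_candidate_regions(sitesP, alpha_site, alpha_region,
                                  min_sites, max_window_sites)
  P <- filter_regions(candP, sitesP, pmd_min, len_min_bp, gap_max_bp,
                      alpha_site, alpha_region, min_sites)
  say("stage=pairwise_dmrs n_candidates=%d n_dmrs=%d", nrow(candP), nrow(P))

  if (length(controls) > 1) {
    sitesM <- site_test_group(mat, case, controls,
                              min_refs_present = length(controls),
                              min_coverage = min_coverage)
    say("stage=sitetests_multicontrol n_sites=%d n_skipped=%d",
        nrow(sitesM), attr(sitesM, "n_skipped"))
    candM <- scan_candidate_regions(sitesM, alpha_site, alpha_region,
                                    min_sites, max_window_sites)
    M <- filter_regions(candM, sitesM, pmd_min, len_min_bp, gap_max_bp,
                        alpha_site, alpha_region, min_sites)
    say("stage=multicontrol_dmrs n_candidates=%d n_dmrs=%d", nrow(candM),
        nrow(M))
  } else {
    sitesM <- sitesP
    M <- P
    say("stage=multicontrol_dmrs degenerate single-control: M = P")
  }

  final <- intersect_dmr_sets(P, M, min_overlap_bp,
                              reporting_sites = sitesP)
  say("stage=intersection n_pairwise=%d n_multicontrol=%d n_final=%d",
      nrow(P), nrow(M), nrow(final))
  final$coverage_anomaly <- coverage_anomaly_flag(mat, final, controls)

  annotation <- NULL
  if (!is.null(segments) || !is.null(gene_models) ||
      !is.null(tissue_dmr_sets)) {
    annotation <- annotate_dmrs(final, segments, gene_models,
                                tissue_dmr_sets, enhancer_states,
                                min_overlap_bp, promoter_kb)
    say("stage=annotation n_dmrs=%d", nrow(annotation))
  }

  params <- list(case = case, controls = controls,
                 reporting_control = reporting_control,
                 min_coverage = min_coverage, alpha_site = alpha_site,
                 alpha_region = alpha_region, min_sites = min_sites,
                 max_window_sites = max_window_sites, pmd_min = pmd_min,
                 len_min_bp = len_min_bp, gap_max_bp = gap_max_bp,
                 min_overlap_bp = min_overlap_bp,
                 enhancer_states = enhancer_states,
                 promoter_kb = promoter_kb,
                 chromosomes = unique(mat$chrom),
                 package_version = as.character(utils::packageVersion("updmr")))
  res <- structure(list(pairwise = P, multicontrol = M, final = final,
                        annotation = annotation,
                        site_tests = list(pairwise = sitesP,
                                          multicontrol = sitesM),
                        params = params),
                   class = "athero_dmr_result")
  if (!is.null(out_dir)) write_athero_outputs(res, out_dir)
  res
}

#' @export
print.athero_dmr_result <- function(x, ...) {
  cat("Case/control DMR analysis\n")
  cat(sprintf("  case: %s  controls: %s (reporting pair vs %s)\n",
              x$params$case, paste(x$params$controls, collapse = ", "),
              x$params$reporting_control))
  cat(sprintf("  pairwise DMRs: %d   multi-control DMRs: %d   final: %d\n",
              nrow(x$pairwise), nrow(x$multicontrol), nrow(x$final)))
  if (nrow(x$final)) {
    cat(sprintf("  final: %d hyper / %d hypo, median length %d bp\n",
                sum(x$final$direction == "hyper"),
                sum(x$final$direction == "hypo"),
                stats::median(x$final$length_bp)))
  }
  invisible(x)
}

#' @method summary athero_dmr_result
#' @export
summary.athero_dmr_result <- function(object, ...) {
  rbind(cbind(set = "pairwise", summary.dmr_set(object$pairwise)),
        cbind(set = "multicontrol", summary.dmr_set(object$multicontrol)),
        cbind(set = "final", summary.dmr_set(object$final)))
}

#' Run one-to-many tissue DMR analyses over a panel
#'
#' Calls [call_tissue_dmrs()] once per target sample. Requires a panel of at
#' least three samples; named targets must exist in the matrix.
#'
#' @param x A harmonized [MethylomeMatrix] or named vector of count-file
#'   paths.
#' @param targets Samples to use as targets (default: every sample).
#' @param ... Passed to [call_tissue_dmrs()].
#' @param dialect Count-file dialect when `x` holds paths.
#' @param out_dir Optional directory; per-target BED files are written as
#'   `tissue_<target>.bed`.
#' @param verbose Emit a message per target.
#' @return Named list of per-target DMR data.frames.
#' @export
run_tissue_analysis <- function(x, targets = NULL, ...,
                                dialect = "bismark-cov", out_dir = NULL,
                                verbose = TRUE) {
  mat <- resolve_matrix(x, dialect)
  if (length(mat$samples) < 3)
    stop("tissue panel needs at least 3 samples")
  if (is.null(targets)) targets <- mat$samples
  for (s in targets) sample_index(mat, s)
  res <- lapply(targets, function(tg) {
    d <- call_tissue_dmrs(mat, tg, ...)
    if (verbose) message(sprintf("stage=tissue target=%s n_dmrs=%d", tg,
                                 nrow(d)))
    d
  })
  names(res) <- targets
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (tg in targets)
      write_dmr_bed(res[[tg]], file.path(out_dir,
                                         paste0("tissue_", tg, ".bed")))
  }
  res
}

resolve_matrix <- function(x, dialect) {
  if (inherits(x, "MethylomeMatrix")) return(x)
  if (is.character(x)) {
    if (is.null(names(x)) || any(!nzchar(names(x))))
      stop("file paths must be named by sample")
    missing <- x[!file.exists(x)]
    if (length(missing))
      stop(sprintf("missing input file(s): %s",
                   paste(missing, collapse = ", ")))
    return(harmonize_samples(lapply(x, read_cpg_counts, dialect = dialect)))
  }
  stop("'x' must be a MethylomeMatrix or a named vector of file paths")
}

coverage_anomaly_flag <- function(mat, dmrs, controls) {
  if (nrow(dmrs) == 0) return(logical(0))
  ci <- vapply(controls, function(s) sample_index(mat, s), integer(1))
  gw_mean <- colMeans(mat$total[, ci, drop = FALSE], na.rm = TRUE)
  vapply(seq_len(nrow(dmrs)), function(i) {
    inreg <- mat$chrom == dmrs$chrom[i] & mat$pos >= dmrs$start_pos[i] &
      mat$pos <= dmrs$end_pos[i]
    if (!any(inreg)) return(FALSE)
    reg_mean <- colMeans(mat$total[inreg, ci, drop = FALSE], na.rm = TRUE)
    any(!is.na(reg_mean) & reg_mean < 0.25 * gw_mean)
  }, logical(1))
}

write_athero_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_dmr_bed(res$pairwise, file.path(out_dir, "pairwise.bed"))
  write_dmr_bed(res$multicontrol, file.path(out_dir, "multicontrol.bed"))
  fin <- res$final
  if (!is.null(res$annotation)) {
    ann_cols <- setdiff(names(res$annotation), names(fin))
    fin <- cbind(fin, res$annotation[, ann_cols, drop = FALSE])
    utils::write.table(res$annotation,
                       file.path(out_dir, "final_annotation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_dmr_bed(fin, file.path(out_dir, "final.bed"))
  jsonlite::write_json(res$params, file.path(out_dir, "params.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
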