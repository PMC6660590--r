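#' Read a per-sample CpG count file
#'
#' Reads a bisulfite-sequencing CpG count table in one of two text dialects
#' and returns a genome-ordered count table. Coordinates are kept 1-based
#' internally (the position of the CpG cytosine on the + strand); all
#' interval output written by the package is 0-based half-open BED.
#'
#' Dialects:
#' \describe{
#'   \item{`bismark-cov`}{6 columns `chrom start end meth_pct n_meth
#'     n_unmeth`, 1-based with `start == end`. The percentage column is
#'     recomputed from the counts, never trusted.}
#'   \item{`bedgraph-counts`}{4 columns `chrom start0 n_meth n_unmeth`, with
#'     `start0` the 0-based position of the cytosine.}
#' }
#'
#' Lines whose counts sum to zero are dropped. Files that are not sorted by
#' (chrom, pos) are sorted with a warning; a malformed line raises an error
#' naming its line number.
#'
#' @param path Path to the count file.
#' @param dialect One of `"bismark-cov"` (default) or `"bedgraph-counts"`.
#' @param min_coverage Drop sites with fewer total reads (default 1).
#' @return A data.frame with columns `chrom`, `pos` (1-based integer),
#'   `n_meth`, `n_unmeth`, sorted by (chrom, pos).
#' @export
read_cpg_counts <- function(path, dialect = c("bismark-cov",
                                              "bedgraph-counts"),
                            min_coverage = 1) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0)
    return(data.frame(chrom = character(), pos = integer(),
                      n_meth = integer(), n_unmeth = integer(),
                      stringsAsFactors = FALSE))
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  want <- if (dialect == "bismark-cov") 6L else 4L
  bad <- which(nf != want)
  if (length(bad))
    stop(sprintf("malformed line %d in '%s': expected %d fields, got %d",
                 bad[1], path, want, nf[bad[1]]))
  m <- matrix(unlist(fields), ncol = want, byrow = TRUE)
  if (dialect == "bismark-cov") {
    pos <- suppressWarnings(as.integer(m[, 2]))
    n_meth <- suppressWarnings(as.numeric(m[, 5]))
    n_unmeth <- suppressWarnings(as.numeric(m[, 6]))
  } else {
    pos <- suppressWarnings(as.integer(m[, 2])) + 1L  # 0-based -> 1-based
    n_meth <- suppressWarnings(as.numeric(m[, 3]))
    n_unmeth <- suppressWarnings(as.numeric(m[, 4]))
  }
  bad <- which(is.na(pos) | is.na(n_meth) | is.na(n_unmeth) |
               n_meth < 0 | n_unmeth < 0)
  if (length(bad))
    stop(sprintf("malformed line %d in '%s': non-numeric or negative field",
                 bad[1], path))
  d <- data.frame(chrom = m[, 1], pos = pos,
                  n_meth = as.integer(round(n_meth)),
                  n_unmeth = as.integer(round(n_unmeth)),
                  stringsAsFactors = FALSE)
  d <- d[d$n_meth + d$n_unmeth >= max(1, min_coverage), , drop = FALSE]
  o <- order(d$chrom, d$pos)
  if (is.unsorted(o)) {
    warning(sprintf("'%s' was not sorted by (chrom, pos); sorting", path))
    d <- d[o, , drop = FALSE]
  }
  rownames(d) <- NULL
  d
}

#' Harmonize per-sample CpG tables into a methylome matrix
#'
#' Aligns two or more per-sample CpG count tables onto a common set of
#' genome-ordered sites. Sites whose coordinates differ by exactly 1 bp
#' across samples -- the same CpG reported from opposite strands by different
#' pre-processing routines -- are unified to the smaller coordinate. The
#' correction is purely coordinate reconciliation: no counts are merged, and
#' when a single sample itself carries both members of a 1-bp pair (a genuine
#' CpCpG ambiguity) the pair is left untouched with a warning. Only isolated
#' pairs are unified: a run of three or more consecutive positions is left
#' as-is.
#'
#' @param tables Named list (length >= 2) of count tables as returned by
#'   [read_cpg_counts()]; names become sample names.
#' @return A [MethylomeMatrix].
#' @export
harmonize_samples <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 2,
            !is.null(names(tables)), all(nzchar(names(tables))))
  tables <- lapply(tables, function(d) {
    stopifnot(all(c("chrom", "pos", "n_meth", "n_unmeth") %in% names(d)))
    d <- d[order(d$chrom, d$pos), , drop = FALSE]
    if (anyDuplicated(paste(d$chrom, d$pos)))
      stop("duplicate (chrom, pos) within one sample")
    d
  })
  all_keys <- unique(do.call(rbind, lapply(tables, function(d)
    d[c("chrom", "pos")])))
  all_keys <- all_keys[order(all_keys$chrom, all_keys$pos), , drop = FALSE]
  shift <- shift_map(all_keys, tables)
  tables <- lapply(tables, function(d) {
    key <- paste(d$chrom, d$pos)
    hit <- match(key, shift$from)
    d$pos[!is.na(hit)] <- shift$to_pos[hit[!is.na(hit)]]
    d[order(d$chrom, d$pos), , drop = FALSE]
  })
  sites <- unique(do.call(rbind, lapply(tables, function(d)
    d[c("chrom", "pos")])))
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  key <- paste(sites$chrom, sites$pos)
  ns <- length(tables)
  meth <- matrix(NA_integer_, nrow(sites), ns)
  total <- matrix(NA_integer_, nrow(sites), ns)
  for (j in seq_len(ns)) {
    d <- tables[[j]]
    i <- match(paste(d$chrom, d$pos), key)
    meth[i, j] <- d$n_meth
    total[i, j] <- d$n_meth + d$n_unmeth
  }
  new_methylome_matrix(names(tables), sites$chrom, sites$pos, meth, total)
}

# Identify isolated cross-sample 1-bp pairs and map the larger coordinate to
# the smaller one. Pairs present together within any one sample are excluded
# (warned about).
shift_map <- function(all_keys, tables) {
  from <- character(0); to_pos <- integer(0)
  for (ch in unique(all_keys$chrom)) {
    pos <- all_keys$pos[all_keys$chrom == ch]
    d <- diff(pos)
    cand <- which(d == 1L)
    if (length(cand) == 0) next
    # isolated: not part of a longer run of consecutive coordinates
    prev_ok <- c(Inf, d)[cand] > 1L       # gap before the pair
    next_ok <- c(d, Inf)[cand + 1L] > 1L  # gap after the pair
    iso <- cand[prev_ok & next_ok]
    for (i in iso) {
      p_lo <- pos[i]; p_hi <- pos[i + 1L]
      same <- vapply(tables, function(t) {
        tp <- t$pos[t$chrom == ch]
        (p_lo %in% tp) && (p_hi %in% tp)
      }, logical(1))
      if (any(same)) {
        warning(sprintf(
          "sample '%s' carries both %s:%d and %s:%d; pair left unmerged",
          names(tables)[which(same)[1]], ch, p_lo, ch, p_hi))
      } else {
        from <- c(from, paste(ch, p_hi))
        to_pos <- c(to_pos, p_lo)
      }
    }
  }
  list(from = from, to_pos = to_pos)
}

new_methylome_matrix <- function(samples, chrom, pos, meth, total) {
  stopifnot(length(chrom) == length(pos), nrow(meth) == length(pos),
            identical(dim(meth), dim(total)), ncol(meth) == length(samples))
  colnames(meth) <- colnames(total) <- samples
  structure(list(samples = samples, chrom = chrom, pos = as.integer(pos),
                 meth = meth, total = total),
            class = "MethylomeMatrix")
}

#' @export
print.MethylomeMatrix <- function(x, ...) {
  cat(sprintf("MethylomeMatrix: %d CpG sites x %d samples (%s)\n",
              length(x$pos), length(x$samples),
              paste(x$samples, collapse = ", ")))
  cat(sprintf("chromosomes: %s\n", paste(unique(x$chrom), collapse = ", ")))
  pres <- round(100 * colMeans(!is.na(x$total)), 1)
  cat("site presence (%):", paste(sprintf("%s=%s", x$samples, pres),
                                  collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.MethylomeMatrix <- function(x) c(length(x$pos), length(x$samples))

sample_index <- function(mat, name) {
  i <- match(name, mat$samples)
  if (is.na(i)) stop(sprintf("sample '%s' not in matrix (has: %s)", name,
                             paste(mat$samples, collapse = ", ")))
  i
}

#' Write a DMR set as a BED6+ file
#'
#' Writes DMRs in 0-based half-open BED with six standard columns (name =
#' linked gene or ".", score = rounded |mean PMD|, strand = ".") followed by
#' `n_sites`, `up_p`, `mean_pmd`, `direction`, `enhancer_overlap_bp` and
#' `tissue_overlaps`. Numeric fields are printed with full precision so that
#' [read_dmr_bed()] round-trips them bit-exactly.
#'
#' @param dmrs A DMR data.frame (from [filter_regions()] or downstream),
#'   sorted; annotation columns (`gene_name`, `enh_overlap_bp`,
#'   `tissue_overlaps`) are used when present.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dmr_bed <- function(dmrs, path) {
  header <- paste(c("#chrom", "start", "end", "name", "score", "strand",
                    "n_sites", "up_p", "mean_pmd", "direction",
                    "enhancer_overlap_bp", "tissue_overlaps"),
                  collapse = "\t")
  if (nrow(dmrs) == 0) { writeLines(header, path); return(invisible(path)) }
  gene <- if ("gene_name" %in% names(dmrs)) dmrs$gene_name else "."
  enh <- if ("enh_overlap_bp" %in% names(dmrs)) dmrs$enh_overlap_bp else "."
  tis <- if ("tissue_overlaps" %in% names(dmrs)) dmrs$tissue_overlaps else "."
  gene[is.na(gene)] <- "."
  body <- paste(dmrs$chrom, dmrs$start_pos - 1L, dmrs$end_pos, gene,
                round(abs(dmrs$mean_pmd)), ".", dmrs$k,
                sprintf("%.17g", dmrs$up_p), sprintf("%.17g", dmrs$mean_pmd),
                dmrs$direction, enh, tis, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a DMR BED file written by [write_dmr_bed()]
#'
#' @param path Path to the BED6+ file.
#' @return A DMR data.frame with 1-based inclusive `start_pos`/`end_pos` and
#'   the extra columns restored.
#' @export
read_dmr_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  empty <- data.frame(chrom = character(), start_pos = integer(),
                      end_pos = integer(), gene_name = character(),
                      k = integer(), up_p = numeric(), mean_pmd = numeric(),
                      direction = character(), enh_overlap_bp = numeric(),
                      tissue_overlaps = character(), stringsAsFactors = FALSE)
  if (length(lines) == 0) return(empty)
  m <- matrix(unlist(strsplit(lines, "\t")), ncol = 12, byrow = TRUE)
  data.frame(chrom = m[, 1], start_pos = as.integer(m[, 2]) + 1L,
             end_pos = as.integer(m[, 3]),
             gene_name = ifelse(m[, 4] == ".", NA_character_, m[, 4]),
             k = as.integer(m[, 7]), up_p = as.numeric(m[, 8]),
             mean_pmd = as.numeric(m[, 9]), direction = m[, 10],
             enh_overlap_bp = suppressWarnings(as.numeric(m[, 11])),
             tissue_overlaps = m[, 12], stringsAsFactors = FALSE)
}

#' Read a chromatin state segmentation BED
#'
#' Expects `chrom start end state` with 0-based half-open coordinates, the
#' state field either a bare number (1-18) or a chromHMM-style label such as
#' `"9_EnhA1"` whose leading digits give the state number.
#'
#' @param path Path to the segmentation BED.
#' @return A data.frame with columns `chrom`, `start` (0-based), `end`
#'   (exclusive), `state` (integer), `label`, sorted by (chrom, start).
#' @export
read_chromatin_segments <- function(path) {
  d <- utils::read.table(path, header = FALSE, sep = "\t",
                         col.names = c("chrom", "start", "end", "label"),
                         colClasses = c("character", "integer", "integer",
                                        "character"))
  state <- suppressWarnings(as.integer(sub("^([0-9]+).*$", "\\1", d$label)))
  if (any(is.na(state)))
    stop("segmentation state labels must start with a state number")
  d$state <- state
  d <- d[order(d$chrom, d$start), c("chrom", "start", "end", "state",
                                    "label")]
  if (any(d$start >= d$end)) stop("segmentation has start >= end")
  rownames(d) <- NULL
  d
}

#' Read gene models from a refFlat table
#'
#' Parses the 11-column refFlat format (geneName, name, chrom, strand,
#' txStart, txEnd, cdsStart, cdsEnd, exonCount, exonStarts, exonEnds);
#' coordinates are 0-based half-open. A transcript is flagged protein-coding
#' when `cdsStart < cdsEnd`.
#'
#' @param path Path to the refFlat file.
#' @return A data.frame with columns `gene_name`, `transcript_id`, `chrom`,
#'   `strand`, `tx_start`, `tx_end`, `is_coding`.
#' @export
read_refflat <- function(path) {
  d <- utils::read.table(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (ncol(d) < 8) stop("refFlat table needs at least 8 columns")
  out <- data.frame(gene_name = d[[1]], transcript_id = d[[2]],
                    chrom = d[[3]], strand = d[[4]],
                    tx_start = as.integer(d[[5]]), tx_end = as.integer(d[[6]]),
                    is_coding = as.integer(d[[7]]) < as.integer(d[[8]]),
                    stringsAsFactors = FALSE)
  stopifnot(all(out$strand %in% c("+", "-")),
            all(out$tx_start < out$tx_end))
  out
}

#' Write a per-sample CpG count table
#'
#' Inverse of [read_cpg_counts()]; useful for making synthetic panels
#' round-trip through the real readers.
#'
#' @param d A count table with `chrom`, `pos`, `n_meth`, `n_unmeth`.
#' @param path Output path.
#' @param dialect Output dialect, as in [read_cpg_counts()].
#' @return `path`, invisibly.
#' @export
write_cpg_counts <- function(d, path, dialect = c("bismark-cov",
                                                  "bedgraph-counts")) {
  dialect <- match.arg(dialect)
  tot <- d$n_meth + d$n_unmeth
  lines <- if (dialect == "bismark-cov") {
    paste(d$chrom, d$pos, d$pos, sprintf("%.6g", 100 * d$n_meth / tot),
          d$n_meth, d$n_unmeth, sep = "\t")
  } else {
    paste(d$chrom, d$pos - 1L, d$n_meth, d$n_unmeth, sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_cpg_counts
#' @param segments A segmentation data.frame (`chrom`, `start`, `end`,
#'   `state`, optionally `label`).
#' @export
write_chromatin_segments <- function(segments, path) {
  lab <- if ("label" %in% names(segments)) segments$label else
    as.character(segments$state)
  writeLines(paste(segments$chrom, segments$start, segments$end, lab,
                   sep = "\t"), path)
  invisible(path)
}

#' @rdname write_cpg_counts
#' @param genes A gene-model data.frame as from [read_refflat()].
#' @export
write_refflat <- function(genes, path) {
  cds_start <- ifelse(genes$is_coding, genes$tx_start, genes$tx_end)
  cds_end <- genes$tx_end
  writeLines(paste(genes$gene_name, genes$transcript_id, genes$chrom,
                   genes$strand, genes$tx_start, genes$tx_end,
                   cds_start, cds_end, 1L,
                   paste0(genes$tx_start, ","), paste0(genes$tx_end, ","),
                   sep = "\t"), path)
  invisible(path)
}
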