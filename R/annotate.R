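#' Overlap in base pairs between two half-open intervals
#'
#' @param a,b Intervals as length-2 numeric vectors `c(start, end)` (half
#'   open, `start < end`) or length-3 vectors / lists `c(chrom, start, end)`;
#'   with chromosomes given, intervals on different chromosomes overlap by 0.
#' @return Non-negative integer overlap length.
#' @examples
#' overlap_bp(c(100, 200), c(150, 300))  # 50
#' overlap_bp(c(100, 200), c(200, 300))  # 0, half-open abutment
#' @export
overlap_bp <- function(a, b) {
  pa <- parse_interval(a); pb <- parse_interval(b)
  if (!is.na(pa$chrom) && !is.na(pb$chrom) && pa$chrom != pb$chrom)
    return(0L)
  max(0L, as.integer(min(pa$end, pb$end) - max(pa$start, pb$start)))
}

parse_interval <- function(x) {
  if (length(x) == 3)
    list(chrom = as.character(x[[1]]), start = as.numeric(x[[2]]),
         end = as.numeric(x[[3]]))
  else if (length(x) == 2)
    list(chrom = NA_character_, start = as.numeric(x[[1]]),
         end = as.numeric(x[[2]]))
  else stop("interval must be c(start, end) or c(chrom, start, end)")
}

#' Flag DMRs that coincide with tissue-specific DMRs
#'
#' For each DMR and each tissue, reports whether any single tissue DMR
#' overlaps it by at least `min_overlap_bp` (50 bp by default), together with
#' the largest single-interval overlap. The rule is deliberately
#' per-interval, not summed: two tissue DMRs each overlapping 30 bp do not
#' make a 60 bp overlap (contrast [annotate_enhancer()], where overlap is
#' totalled).
#'
#' @param dmrs DMR data.frame (1-based inclusive `start_pos`/`end_pos`).
#' @param tissue_dmr_sets Named list of tissue DMR data.frames.
#' @param min_overlap_bp Minimum single-interval overlap (default 50).
#' @return A data.frame with, per tissue `t`, columns `<t>_overlap_bp` (max
#'   single-interval overlap) and `<t>_flag`, plus `tissue_overlaps`, a
#'   compact `tissue:bp` summary string ("." when none pass).
#' @export
annotate_tissue_overlap <- function(dmrs, tissue_dmr_sets,
                                    min_overlap_bp = 50) {
  stopifnot(is.list(tissue_dmr_sets), !is.null(names(tissue_dmr_sets)))
  n <- nrow(dmrs)
  out <- data.frame(row.names = seq_len(max(n, 0)))
  gd <- if (n) dmr_granges(dmrs) else NULL
  for (tis in names(tissue_dmr_sets)) {
    ov <- integer(n)
    td <- tissue_dmr_sets[[tis]]
    if (n > 0 && nrow(td) > 0) {
      gt <- dmr_granges(td)
      hits <- GenomicRanges::findOverlaps(gd, gt)
      if (length(hits)) {
        w <- GenomicRanges::width(IRanges::pintersect(
          gd[S4Vectors::queryHits(hits)], gt[S4Vectors::subjectHits(hits)]))
        mx <- tapply(w, S4Vectors::queryHits(hits), max)
        ov[as.integer(names(mx))] <- as.integer(mx)
      }
    }
    out[[paste0(tis, "_overlap_bp")]] <- ov
    out[[paste0(tis, "_flag")]] <- ov >= min_overlap_bp
  }
  out$tissue_overlaps <- vapply(seq_len(n), function(i) {
    hit <- names(tissue_dmr_sets)[vapply(names(tissue_dmr_sets), function(t)
      out[[paste0(t, "_flag")]][i], logical(1))]
    if (length(hit) == 0) "." else
      paste(vapply(hit, function(t)
        sprintf("%s:%d", t, out[[paste0(t, "_overlap_bp")]][i]),
        character(1)), collapse = ",")
  }, character(1))
  rownames(out) <- NULL
  out
}

#' Enhancer-chromatin overlap of DMRs
#'
#' Sums, per DMR, the base pairs overlapping segmentation intervals in the
#' designated enhancer states of an 18-state chromatin segmentation (states
#' 3, 8, 9 and 10 by default) and flags DMRs whose total reaches
#' `min_total_bp` (50 bp by default). Unlike the tissue rule, overlap here is
#' a total across segments.
#'
#' @param dmrs DMR data.frame (1-based inclusive coordinates).
#' @param segments Segmentation data.frame from [read_chromatin_segments()]
#'   (0-based half-open, non-overlapping within a segmentation).
#' @param enhancer_states Integer states counted as enhancer chromatin
#'   (default `c(3, 8, 9, 10)`).
#' @param min_total_bp Total overlap needed for the flag (default 50).
#' @return A data.frame with `enh_overlap_bp` and `is_enhancer_dmr`.
#' @export
annotate_enhancer <- function(dmrs, segments,
                              enhancer_states = c(3, 8, 9, 10),
                              min_total_bp = 50) {
  unknown <- setdiff(unique(segments$state), 1:18)
  if (length(unknown))
    warning(sprintf("segmentation contains unknown state(s) %s; ignored",
                    paste(unknown, collapse = ",")))
  seg <- segments[segments$state %in% intersect(enhancer_states, 1:18), ,
                  drop = FALSE]
  n <- nrow(dmrs)
  ov <- integer(n)
  if (n > 0 && nrow(seg) > 0) {
    gd <- dmr_granges(dmrs)
    gs <- GenomicRanges::GRanges(seg$chrom,
                                 IRanges::IRanges(start = seg$start + 1L,
                                                  end = seg$end))
    hits <- GenomicRanges::findOverlaps(gd, gs)
    if (length(hits)) {
      w <- GenomicRanges::width(IRanges::pintersect(
        gd[S4Vectors::queryHits(hits)], gs[S4Vectors::subjectHits(hits)]))
      tot <- tapply(w, S4Vectors::queryHits(hits), sum)
      ov[as.integer(names(tot))] <- as.integer(tot)
    }
  }
  data.frame(enh_overlap_bp = ov, is_enhancer_dmr = ov >= min_total_bp)
}

#' Assign a gene to each DMR by region precedence
#'
#' Builds, per transcript, a promoter window (TSS +/- `window_kb` kb,
#' strand-aware: the TSS is `tx_start` on the + strand and the last
#' transcribed base on the - strand) and a gene-body region (from the
#' promoter window's downstream edge to the TES). Each DMR is assigned in
#' order of precedence: promoter window, then gene body, then intergenic.
#' Within the highest-precedence category showing any overlap, protein-coding
#' genes are preferred over non-coding ones; among those, the gene with the
#' largest overlap wins (per gene, the maximum across its transcripts), ties
#' broken by lexicographic gene name. Intergenic DMRs are linked to the
#' nearest TSS within `nearest_cap_bp` (still labeled intergenic, overlap 0),
#' or to "." when none is near enough.
#'
#' @param dmrs DMR data.frame (1-based inclusive coordinates).
#' @param gene_models Gene-model data.frame from [read_refflat()].
#' @param window_kb Promoter half-window around the TSS, kb (default 5).
#' @param nearest_cap_bp Cap for nearest-TSS linking of intergenic DMRs
#'   (default 1e6).
#' @return A data.frame with `gene_name`, `gene_category` (one of
#'   `"promoter"` = TSS +/- window, `"genebody"`, `"intergenic"`) and
#'   `gene_overlap_bp`.
#' @export
map_gene <- function(dmrs, gene_models, window_kb = 5,
                     nearest_cap_bp = 1e6) {
  n <- nrow(dmrs)
  out <- data.frame(gene_name = rep(".", n),
                    gene_category = rep("intergenic", n),
                    gene_overlap_bp = integer(n), stringsAsFactors = FALSE)
  if (n == 0 || nrow(gene_models) == 0) return(out)
  w <- as.integer(window_kb * 1000)
  g <- gene_models
  # 0-based half-open region definitions, strand-aware
  tss0 <- ifelse(g$strand == "+", g$tx_start, g$tx_end - 1L)
  prom_s <- pmax(ifelse(g$strand == "+", g$tx_start - w, g$tx_end - w), 0L)
  prom_e <- ifelse(g$strand == "+", g$tx_start + w, g$tx_end + w)
  body_s <- ifelse(g$strand == "+", g$tx_start + w, g$tx_start)
  body_e <- ifelse(g$strand == "+", g$tx_end, g$tx_end - w)
  has_body <- body_s < body_e
  gd <- dmr_granges(dmrs)
  # best gene per DMR among transcripts `sub` with regions [starts0, ends0)
  assign_category <- function(starts0, ends0, sub) {
    res <- data.frame(gene = rep(NA_character_, n), ov = rep(NA_integer_, n),
                      stringsAsFactors = FALSE)
    if (!length(sub)) return(res)
    gr <- GenomicRanges::GRanges(g$chrom[sub],
                                 IRanges::IRanges(start = starts0[sub] + 1L,
                                                  end = ends0[sub]))
    hits <- GenomicRanges::findOverlaps(gd, gr)
    if (!length(hits)) return(res)
    q <- S4Vectors::queryHits(hits)
    tix <- sub[S4Vectors::subjectHits(hits)]
    ovl <- GenomicRanges::width(IRanges::pintersect(
      gd[q], gr[S4Vectors::subjectHits(hits)]))
    h <- data.frame(q = q, gene = g$gene_name[tix],
                    coding = g$is_coding[tix], ov = as.integer(ovl),
                    stringsAsFactors = FALSE)
    # gene-level overlap: max across transcripts of the same gene
    agg <- stats::aggregate(ov ~ q + gene + coding, data = h, FUN = max)
    for (qi in unique(agg$q)) {
      cand <- agg[agg$q == qi, , drop = FALSE]
      if (any(cand$coding)) cand <- cand[cand$coding, , drop = FALSE]
      cand <- cand[order(-cand$ov, cand$gene), , drop = FALSE]
      res$gene[qi] <- cand$gene[1]
      res$ov[qi] <- cand$ov[1]
    }
    res
  }
  prom <- assign_category(prom_s, prom_e, seq_len(nrow(g)))
  body <- assign_category(body_s, body_e, which(has_body))
  use_prom <- !is.na(prom$gene)
  use_body <- !use_prom & !is.na(body$gene)
  out$gene_name[use_prom] <- prom$gene[use_prom]
  out$gene_category[use_prom] <- "promoter"
  out$gene_overlap_bp[use_prom] <- prom$ov[use_prom]
  out$gene_name[use_body] <- body$gene[use_body]
  out$gene_category[use_body] <- "genebody"
  out$gene_overlap_bp[use_body] <- body$ov[use_body]
  # intergenic: nearest TSS within the cap
  inter <- which(!use_prom & !use_body)
  for (i in inter) {
    same <- which(g$chrom == dmrs$chrom[i])
    if (!length(same)) next
    tss1 <- tss0[same] + 1L  # 1-based TSS coordinate
    d <- pmax(dmrs$start_pos[i] - tss1, tss1 - dmrs$end_pos[i], 0L)
    j <- order(d, g$gene_name[same])[1]
    if (d[j] <= nearest_cap_bp) out$gene_name[i] <- g$gene_name[same[j]]
  }
  out
}

#' Annotate a DMR set against all available tracks
#'
#' Convenience wrapper joining [annotate_tissue_overlap()],
#' [annotate_enhancer()] and [map_gene()] results onto the DMR table; tracks
#' that are `NULL` are skipped.
#'
#' @param dmrs DMR data.frame.
#' @param segments Optional segmentation (see [annotate_enhancer()]).
#' @param gene_models Optional gene models (see [map_gene()]).
#' @param tissue_dmr_sets Optional named list of tissue DMR sets.
#' @param enhancer_states,min_overlap_bp,promoter_kb Rule parameters; see
#'   the individual annotators.
#' @return The DMR data.frame with a `dmr_id` column and all annotation
#'   columns appended.
#' @export
annotate_dmrs <- function(dmrs, segments = NULL, gene_models = NULL,
                          tissue_dmr_sets = NULL,
                          enhancer_states = c(3, 8, 9, 10),
                          min_overlap_bp = 50, promoter_kb = 5) {
  out <- as.data.frame(dmrs)
  out <- cbind(dmr_id = if (nrow(out)) sprintf("dmr_%04d", seq_len(nrow(out)))
               else character(0), out, stringsAsFactors = FALSE)
  if (!is.null(segments))
    out <- cbind(out, annotate_enhancer(dmrs, segments, enhancer_states,
                                        min_overlap_bp))
  if (!is.null(gene_models))
    out <- cbind(out, map_gene(dmrs, gene_models, promoter_kb))
  if (!is.null(tissue_dmr_sets))
    out <- cbind(out, annotate_tissue_overlap(dmrs, tissue_dmr_sets,
                                              min_overlap_bp))
  out
}
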