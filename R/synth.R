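#' Configuration for the synthetic methylome generator
#'
#' Describes a synthetic multi-sample CpG methylome: CpG spacing follows a
#' two-level mixture (tight CpG clusters with geometric within-cluster gaps,
#' separated by long between-cluster gaps, mimicking CpG-island-like
#' clustering); the baseline methylation landscape is piecewise-constant
#' with region means drawn from a Beta distribution (default Beta(8, 2),
#' i.e. a ~80% methylated genome with occasional hypomethylated blocks, as
#' in somatic tissue); per-site read depth is negative binomial (default
#' mean 30, dispersion 0.2, so low- and zero-coverage sites occur and
#' exercise the skipping paths); methylated read counts are binomial.
#' Planted differentially methylated regions shift the methylation fraction
#' of the affected samples by `delta_pmd` percentage points over a block of
#' evenly spaced sites inserted between background clusters.
#'
#' @param n_sites Total number of CpG sites, planted sites included
#'   (default 5000).
#' @param samples Sample names; the first is the conventional case
#'   (default `c("case", "ctlA", "ctlB", "ctlC")`).
#' @param chrom Chromosome name (default `"chrS"`).
#' @param baseline_shape1,baseline_shape2 Beta parameters of region means
#'   (default 8, 2).
#' @param region_mean_sites Mean length, in sites, of a constant-methylation
#'   background region (default 50).
#' @param within_gap_mean,between_gap_mean Mean within-cluster and
#'   between-cluster CpG gap in bp (defaults 20 and 1500).
#' @param cluster_mean_sites Mean CpG cluster size in sites (default 15).
#' @param coverage_mean,coverage_dispersion Negative-binomial read-depth
#'   parameters (defaults 30 and 0.2); dispersion 0 gives Poisson.
#' @param planted Optional data.frame with one row per planted region:
#'   `n_sites`, `spacing_bp` (even inter-site spacing), `delta_pmd`
#'   (percentage points, sign = direction: positive means the affected
#'   samples are hypermethylated relative to the rest).
#' @param affected_samples Samples carrying the planted shift (default: the
#'   first sample).
#' @param seed RNG seed used by [generate_methylome_panel()] unless
#'   overridden there.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_sites = 5000,
                         samples = c("case", "ctlA", "ctlB", "ctlC"),
                         chrom = "chrS",
                         baseline_shape1 = 8, baseline_shape2 = 2,
                         region_mean_sites = 50,
                         within_gap_mean = 20, between_gap_mean = 1500,
                         cluster_mean_sites = 15,
                         coverage_mean = 30, coverage_dispersion = 0.2,
                         planted = NULL, affected_samples = samples[1],
                         seed = 1) {
  if (!is.null(planted)) {
    stopifnot(is.data.frame(planted),
              all(c("n_sites", "spacing_bp", "delta_pmd") %in%
                  names(planted)),
              all(abs(planted$delta_pmd) <= 98), all(planted$n_sites >= 1))
    if (sum(planted$n_sites) > n_sites)
      stop("planted sites exceed n_sites")
  }
  stopifnot(length(samples) >= 1, all(affected_samples %in% samples),
            coverage_mean > 0, n_sites >= 1)
  structure(list(n_sites = n_sites, samples = samples, chrom = chrom,
                 baseline_shape1 = baseline_shape1,
                 baseline_shape2 = baseline_shape2,
                 region_mean_sites = region_mean_sites,
                 within_gap_mean = within_gap_mean,
                 between_gap_mean = between_gap_mean,
                 cluster_mean_sites = cluster_mean_sites,
                 coverage_mean = coverage_mean,
                 coverage_dispersion = coverage_dispersion,
                 planted = planted, affected_samples = affected_samples,
                 seed = seed),
            class = "synth_config")
}

#' Generate a synthetic methylome panel with planted DMRs
#'
#' Draws a multi-sample CpG count matrix from a [synth_config()] world and
#' returns it together with a truth table of the planted regions. The
#' generator is deterministic under a fixed seed and leaves the caller's
#' global RNG state untouched.
#'
#' @param config A [synth_config()].
#' @param seed Seed (default `config$seed`).
#' @return A list with `matrix` (a [MethylomeMatrix]), `truth` (one row per
#'   planted region: `chrom`, `start_pos`, `end_pos`, `n_sites`,
#'   `delta_pmd`, `direction`, `first_idx`, `last_idx`) and `p_baseline`
#'   (the per-site reference methylation fractions).
#' @export
generate_methylome_panel <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(seed, {
    cf <- config
    n_planted <- if (is.null(cf$planted)) 0L else sum(cf$planted$n_sites)
    n_bg <- cf$n_sites - n_planted
    if (n_planted > 0 && n_bg < nrow(cf$planted) + 1L)
      stop("infeasible config: planted sites leave too few background sites")
    gaps <- sim_gaps(n_bg, cf$within_gap_mean, cf$between_gap_mean,
                     cf$cluster_mean_sites)
    pos_bg <- cumsum(c(1000L, gaps))
    # background landscape: piecewise-constant Beta region means
    p_site <- numeric(0)
    while (length(p_site) < n_bg) {
      len <- 1L + stats::rgeom(1, 1 / cf$region_mean_sites)
      p_site <- c(p_site, rep(stats::rbeta(1, cf$baseline_shape1,
                                           cf$baseline_shape2), len))
    }
    p_site <- pmin(pmax(p_site[seq_len(n_bg)], 0.01), 0.99)
    pos <- pos_bg; delta <- numeric(n_bg)
    truth <- NULL
    if (n_planted > 0) {
      # insert each planted block after a random background cut point,
      # offset by a wide gap so blocks never merge into background signal
      np <- nrow(cf$planted)
      cuts <- sort(sample(seq_len(max(n_bg - 1L, 1L)), np))
      blocks <- vector("list", np)
      d_frac <- cf$planted$delta_pmd / 100
      for (b in seq_len(np)) {
        ns <- cf$planted$n_sites[b]
        pref <- stats::rbeta(1, cf$baseline_shape1, cf$baseline_shape2)
        pref <- if (d_frac[b] > 0) min(max(pref, 0.01), 0.99 - d_frac[b])
                else min(max(pref, 0.01 - d_frac[b]), 0.99)
        blocks[[b]] <- list(n = ns, p_ref = pref, delta = d_frac[b])
      }
      new_pos <- integer(0); new_p <- numeric(0); new_delta <- numeric(0)
      truth_rows <- list()
      last <- 0L; offset <- 0L
      for (b in seq_len(np)) {
        seg <- (last + 1L):cuts[b]
        new_pos <- c(new_pos, pos_bg[seg] + offset)
        new_p <- c(new_p, p_site[seg])
        new_delta <- c(new_delta, numeric(length(seg)))
        # planted block 3 kb downstream of the last emitted background site
        bp <- pos_bg[cuts[b]] + offset + 3000L +
          cf$planted$spacing_bp[b] * (seq_len(blocks[[b]]$n) - 1L)
        first_idx <- length(new_pos) + 1L
        new_pos <- c(new_pos, bp)
        new_p <- c(new_p, rep(blocks[[b]]$p_ref, blocks[[b]]$n))
        new_delta <- c(new_delta, rep(blocks[[b]]$delta, blocks[[b]]$n))
        truth_rows[[b]] <- data.frame(
          chrom = cf$chrom, start_pos = bp[1], end_pos = bp[length(bp)],
          n_sites = blocks[[b]]$n, delta_pmd = cf$planted$delta_pmd[b],
          direction = if (d_frac[b] > 0) "hyper" else "hypo",
          first_idx = first_idx, last_idx = first_idx + blocks[[b]]$n - 1L,
          stringsAsFactors = FALSE)
        # background resumes 3 kb after the block's last site
        offset <- bp[length(bp)] + 3000L - pos_bg[cuts[b] + 1L]
        last <- cuts[b]
      }
      if (last < n_bg) {
        seg <- (last + 1L):n_bg
        new_pos <- c(new_pos, pos_bg[seg] + offset)
        new_p <- c(new_p, p_site[seg])
        new_delta <- c(new_delta, numeric(length(seg)))
      }
      pos <- new_pos; p_site <- new_p; delta <- new_delta
      truth <- do.call(rbind, truth_rows)
    }
    if (is.null(truth))
      truth <- data.frame(chrom = character(), start_pos = integer(),
                          end_pos = integer(), n_sites = integer(),
                          delta_pmd = numeric(), direction = character(),
                          first_idx = integer(), last_idx = integer(),
                          stringsAsFactors = FALSE)
    ns <- length(cf$samples)
    n <- length(pos)
    size <- if (cf$coverage_dispersion > 0) 1 / cf$coverage_dispersion else
      Inf
    cov <- matrix(if (is.finite(size))
      stats::rnbinom(n * ns, mu = cf$coverage_mean, size = size)
      else stats::rpois(n * ns, cf$coverage_mean), n, ns)
    p_mat <- matrix(p_site, n, ns)
    aff <- cf$samples %in% cf$affected_samples
    p_mat[, aff] <- pmin(pmax(p_mat[, aff] + delta, 0.005), 0.995)
    meth <- matrix(stats::rbinom(n * ns, as.vector(cov),
                                 as.vector(p_mat)), n, ns)
    absent <- cov == 0
    meth[absent] <- NA_integer_; cov[absent] <- NA_integer_
    mat <- new_methylome_matrix(cf$samples, rep(cf$chrom, n), pos,
                                meth, cov)
    list(matrix = mat, truth = truth, p_baseline = p_site)
  })
}

# geometric-gap cluster process: gaps within a cluster ~ 2 + Geom, clusters
# separated by ~ between_gap_mean gaps
sim_gaps <- function(n_sites, within_gap_mean, between_gap_mean,
                     cluster_mean_sites) {
  if (n_sites <= 1) return(integer(0))
  n_gaps <- n_sites - 1L
  between <- stats::rbinom(n_gaps, 1, 1 / cluster_mean_sites) == 1
  gaps <- integer(n_gaps)
  gaps[!between] <- 2L + stats::rgeom(sum(!between),
                                      1 / max(within_gap_mean - 2, 1))
  gaps[between] <- 200L + stats::rgeom(sum(between),
                                       1 / max(between_gap_mean - 200, 1))
  gaps
}

#' Synthetic segmentation and gene-model fixtures
#'
#' Builds a random but gap-free, non-overlapping 18-state chromatin
#' segmentation over a synthetic chromosome, and a small engineered refFlat
#' gene table that exercises every branch of the gene-assignment precedence:
#' a promoter-vs-body conflict between two + strand coding genes, a
#' non-coding gene competing inside a coding gene's body, a - strand gene
#' (promoter window anchored at `tx_end`), and a short gene whose body
#' region is empty.
#'
#' @param seed RNG seed for the segmentation (gene models are fixed).
#' @param chrom Chromosome name (default `"chrS"`).
#' @param chrom_len Chromosome length in bp (default 120000).
#' @return A list with `segments` (0-based half-open, `state` in 1..18) and
#'   `genes` (a gene-model data.frame as from [read_refflat()]).
#' @export
generate_annotation_fixtures <- function(seed = 1, chrom = "chrS",
                                         chrom_len = 120000) {
  segments <- with_seed(seed, {
    starts <- 0L; ends <- integer(0); states <- integer(0)
    cur <- 0L
    while (cur < chrom_len) {
      len <- 200L + stats::rgeom(1, 1 / 800)
      nxt <- min(cur + len, chrom_len)
      states <- c(states, sample(1:18, 1))
      ends <- c(ends, nxt)
      if (nxt < chrom_len) starts <- c(starts, nxt)
      cur <- nxt
    }
    data.frame(chrom = chrom, start = starts, end = ends, state = states,
               label = paste0(states, "_state"), stringsAsFactors = FALSE)
  })
  genes <- data.frame(
    gene_name = c("GENEA", "GENEB", "GENENC", "GENEM", "GENES"),
    transcript_id = c("ta1", "tb1", "tnc1", "tm1", "ts1"),
    chrom = chrom,
    strand = c("+", "+", "+", "-", "+"),
    tx_start = c(20000L, 22000L, 21000L, 50000L, 70000L),
    tx_end = c(28000L, 40000L, 30000L, 60000L, 72000L),
    is_coding = c(TRUE, TRUE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  list(segments = segments, genes = genes)
}

#' Score called DMRs against a planted truth table
#'
#' A truth region counts as recovered when some called DMR of the same
#' direction overlaps it reciprocally by at least `min_reciprocal` of each
#' interval's length; called DMRs matching no truth region under the same
#' criterion are false discoveries.
#'
#' @param calls Called DMR data.frame.
#' @param truth Truth table from [generate_methylome_panel()].
#' @param min_reciprocal Reciprocal-overlap fraction (default 0.5).
#' @return A list with `sensitivity` (NA when `truth` is empty),
#'   `false_discoveries` (count), `n_truth`, `n_calls` and `matched`
#'   (logical per truth row).
#' @export
evaluate_recovery <- function(calls, truth, min_reciprocal = 0.5) {
  n_t <- nrow(truth); n_c <- nrow(calls)
  matched_t <- logical(n_t); matched_c <- logical(n_c)
  for (i in seq_len(n_t)) {
    for (j in seq_len(n_c)) {
      if (truth$chrom[i] != calls$chrom[j]) next
      if (truth$direction[i] != calls$direction[j]) next
      ov <- min(truth$end_pos[i], calls$end_pos[j]) -
        max(truth$start_pos[i], calls$start_pos[j]) + 1L
      if (ov <= 0) next
      lt <- truth$end_pos[i] - truth$start_pos[i] + 1L
      lc <- calls$end_pos[j] - calls$start_pos[j] + 1L
      if (ov >= min_reciprocal * lt && ov >= min_reciprocal * lc) {
        matched_t[i] <- TRUE; matched_c[j] <- TRUE
      }
    }
  }
  list(sensitivity = if (n_t == 0) NA_real_ else mean(matched_t),
       false_discoveries = sum(!matched_c), n_truth = n_t, n_calls = n_c,
       matched = matched_t)
}

# run expr under a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
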