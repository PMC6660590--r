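# Independent oracles used across the suite. These deliberately take the
# slow, literal route (full enumeration, per-bp counting, glm fits) so they
# share no code path with the implementation they check.

# Brute-force candidate-region scan: enumerate every window of >= min_sites
# consecutive sites, keep those with significant endpoints and UP tail
# probability <= alpha_region, take the union of qualifying site-index
# intervals (overlapping or abutting intervals merge), trim ends to
# significant sites, and score the merged span.
oracle_scan <- function(sites, alpha_site = 0.05, alpha_region = 0.05,
                        min_sites = 5) {
  out <- lapply(split(seq_len(nrow(sites)), factor(sites$chrom,
                                                   unique(sites$chrom))),
                function(idx) {
    p <- sites$p[idx]
    n <- length(p)
    qa <- integer(0); qb <- integer(0)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        k <- j - i + 1
        if (k < min_sites) next
        if (p[i] > alpha_site || p[j] > alpha_site) next
        if (up_tail_probability(k = k, log_x = sum(log(p[i:j]))) >
            alpha_region) next
        qa <- c(qa, i); qb <- c(qb, j)
      }
    }
    if (!length(qa)) return(NULL)
    # union of index intervals, merging overlap or abutment
    o <- order(qa, qb); qa <- qa[o]; qb <- qb[o]
    ma <- qa[1]; mb <- qb[1]; res <- NULL
    for (t in seq_along(qa)[-1]) {
      if (qa[t] <= mb + 1) mb <- max(mb, qb[t])
      else { res <- rbind(res, c(ma, mb)); ma <- qa[t]; mb <- qb[t] }
    }
    res <- rbind(res, c(ma, mb))
    do.call(rbind, lapply(seq_len(nrow(res)), function(r) {
      a <- res[r, 1]; b <- res[r, 2]
      sig <- which(p[a:b] <= alpha_site)
      a2 <- a + sig[1] - 1; b2 <- a + sig[length(sig)] - 1
      data.frame(chrom = sites$chrom[idx[1]],
                 start_pos = sites$pos[idx[a2]], end_pos = sites$pos[idx[b2]],
                 first_idx = idx[a2], last_idx = idx[b2],
                 k = b2 - a2 + 1L,
                 up_p = up_tail_probability(k = b2 - a2 + 1,
                                            log_x = sum(log(p[a2:b2]))),
                 mean_pmd = mean(sites$pmd[idx[a2:b2]]),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, c(out[!vapply(out, is.null, logical(1))],
                          list(make.row.names = FALSE)))
  if (is.null(out)) return(NULL)
  out$direction <- ifelse(out$mean_pmd > 0, "hyper", "hypo")
  rownames(out) <- NULL
  out
}

# Two-sided Fisher exact p by explicit table enumeration with choose(),
# independent of dhyper().
oracle_fisher_enum <- function(m1, u1, m2, u2) {
  n1 <- m1 + u1; n2 <- m2 + u2; K <- m1 + m2
  xs <- max(0, K - n2):min(n1, K)
  pr <- choose(n1, xs) * choose(n2, K - xs) / choose(n1 + n2, K)
  obs <- pr[xs == m1]
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# LRT p-value by an actual binomial glm fit, one row per sample.
oracle_glm_lrt <- function(case, refs) {
  m <- c(case[1], vapply(refs, `[`, numeric(1), 1))
  u <- c(case[2], vapply(refs, `[`, numeric(1), 2))
  grp <- factor(c("case", rep("ref", length(refs))))
  fit1 <- stats::glm(cbind(m, u) ~ grp, family = stats::binomial())
  fit0 <- stats::glm(cbind(m, u) ~ 1, family = stats::binomial())
  stats::pchisq(max(fit0$deviance - fit1$deviance, 0), df = 1,
                lower.tail = FALSE)
}

# LRT p by direct maximization of the two binomial likelihoods on a fine
# probability grid (no glm machinery at all).
oracle_grid_lrt <- function(case, refs) {
  m1 <- case[1]; n1 <- sum(case)
  m2 <- sum(vapply(refs, `[`, numeric(1), 1))
  n2 <- sum(vapply(refs, function(r) sum(r), numeric(1)))
  grid <- seq(1e-6, 1 - 1e-6, length.out = 20001)
  ll <- function(m, n, p) m * log(p) + (n - m) * log(1 - p)
  l1 <- max(ll(m1, n1, grid)) + max(ll(m2, n2, grid))
  l0 <- max(ll(m1, n1, grid) + ll(m2, n2, grid))
  stats::pchisq(2 * (l1 - l0), df = 1, lower.tail = FALSE)
}

# Per-bp membership count of interval overlap (1-based inclusive DMR vs
# 0-based half-open segments).
oracle_bp_overlap <- function(dmr_start, dmr_end, seg_start0, seg_end0) {
  bp <- dmr_start:dmr_end
  sum(vapply(bp, function(b) any(b > seg_start0 & b <= seg_end0),
             logical(1)))
}

# Random site-result table for scanner property tests: mixture of null and
# small p-values over clustered positions.
random_sites <- function(n, seed, frac_small = 0.25) {
  set.seed(seed)
  data.frame(chrom = "chrT",
             pos = cumsum(sample(c(2:60, 150, 300), n, replace = TRUE)),
             p = ifelse(runif(n) < frac_small, runif(n, 1e-6, 0.05),
                        runif(n)),
             pmd = rnorm(n, 0, 30), stringsAsFactors = FALSE)
}

# Small deterministic methylome matrix builder for io/test fixtures.
make_matrix <- function(samples, chrom, pos, meth, total) {
  tabs <- lapply(seq_along(samples), function(j) {
    keep <- !is.na(total[, j])
    data.frame(chrom = chrom[keep], pos = pos[keep],
               n_meth = meth[keep, j],
               n_unmeth = total[keep, j] - meth[keep, j],
               stringsAsFactors = FALSE)
  })
  names(tabs) <- samples
  harmonize_samples(tabs)
}
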