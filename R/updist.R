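#' Tail probability of the Uniform Product distribution
#'
#' Computes \eqn{P(\prod_{i=1}^{k} U_i \le x)} for independent
#' \eqn{U_i \sim \mathrm{Uniform}(0,1)}, i.e. the probability that a product of
#' \eqn{k} independent uniform p-values is as small or smaller than an observed
#' product \eqn{x}. This is the joint probability used to score a run of
#' consecutive per-CpG p-values as a candidate differentially methylated
#' region: small values indicate a run of p-values jointly more extreme than
#' expected by chance.
#'
#' The closed form is
#' \deqn{P(\prod U_i \le x) = x \sum_{j=0}^{k-1} \frac{(-\ln x)^j}{j!},}
#' the upper regularized incomplete gamma function evaluated at shape \eqn{k}
#' and \eqn{-\ln x} (since \eqn{-\ln \prod U_i} is Gamma(k, 1) distributed).
#' The sum is accumulated in log space, so the function is stable for
#' \eqn{x} down to 1e-300 and beyond (pass `log_x` for products that underflow
#' a double) and for \eqn{k} in the thousands.
#'
#' @param x Product of the k p-values, in (0, 1]. Ignored when `log_x` is
#'   given.
#' @param k Number of p-values in the product (positive integer).
#' @param log_x Optional natural log of the product, for products too small to
#'   represent as a double (e.g. the sum of `log(p)` over a long run).
#' @return The tail probability, a single number in (0, 1].
#' @examples
#' up_tail_probability(0.3, k = 1)            # a single uniform: 0.3
#' up_tail_probability(0.01, k = 2)           # 0.01 * (1 - log(0.01))
#' up_tail_probability(0.05^5, k = 5)         # run of five 0.05s
#' up_tail_probability(k = 20, log_x = -150)  # underflow-safe interface
#' @export
up_tail_probability <- function(x, k, log_x = NULL) {
  if (length(k) != 1L || !is.finite(k) || k < 1 || k != floor(k))
    stop("'k' must be a single positive integer")
  if (is.null(log_x)) {
    if (length(x) != 1L || !is.finite(x) || x <= 0 || x > 1)
      stop("'x' must be a single value in (0, 1]")
    log_x <- log(x)
  } else {
    if (length(log_x) != 1L || is.na(log_x) || log_x > 0)
      stop("'log_x' must be a single value <= 0")
  }
  s <- -log_x                       # -ln x, the Gamma(k,1) deviate
  if (s == 0) return(1)
  j <- seq_len(k) - 1               # 0 .. k-1
  # log of term_j = -s + j*log(s) - log(j!); j = 0 gives -s since s > 0
  log_terms <- -s + j * log(s) - lgamma(j + 1)
  m <- max(log_terms)
  p <- exp(m + log(sum(exp(log_terms - m))))
  min(max(p, .Machine$double.xmin), 1)
}

#' Scan ordered site p-values for candidate DMRs
#'
#' Slides over the genome-ordered per-CpG test results of one or more
#' chromosomes and finds every window of at least `min_sites` consecutive
#' sites that (i) begins and ends with a site significant at `alpha_site` and
#' (ii) has a Uniform Product tail probability of its p-value product at most
#' `alpha_region`. Overlapping or abutting qualifying windows are merged into
#' maximal regions; each merged region is trimmed inward so that its first and
#' last member sites are significant, and its reported `up_p` is recomputed
#' over the full merged span with [up_tail_probability()].
#'
#' Internally the qualifying test uses the equivalence
#' \eqn{P(\prod p \le x) \le \alpha \iff \sum -\ln p_i \ge Q^{-1}(k, \alpha)}
#' (the upper incomplete gamma quantile), so each window is screened in O(1)
#' from a cumulative sum of \eqn{-\ln p}. The forward scan from each
#' significant left endpoint is capped at `max_window_sites` sites; windows
#' longer than the cap are never considered (see the methods vignette for why
#' this cannot matter on realistic inputs).
#'
#' @param sites A data.frame of per-site test results with columns `chrom`,
#'   `pos` (1-based, sorted within chromosome), `p` and `pmd` (signed percent
#'   methylation difference), as produced by [site_test_pair()] or
#'   [site_test_group()].
#' @param alpha_site Significance level a window's first and last site must
#'   reach (default 0.05).
#' @param alpha_region Significance level for the window's UP tail probability
#'   (default 0.05).
#' @param min_sites Minimum number of consecutive sites in a window
#'   (default 5).
#' @param max_window_sites Cap on the number of sites in any single considered
#'   window (default 10000).
#' @return A data.frame of candidate regions with columns `chrom`,
#'   `start_pos`, `end_pos` (1-based positions of the first/last member CpG),
#'   `first_idx`, `last_idx` (row indices into `sites`), `k` (member count),
#'   `up_p`, `mean_pmd` (unweighted mean of member `pmd`) and `direction`
#'   (`"hyper"` if `mean_pmd > 0` else `"hypo"`). Zero rows when nothing
#'   qualifies.
#' @seealso [filter_regions()] for the retention rules applied downstream.
#' @export
scan_candidate_regions <- function(sites, alpha_site = 0.05,
                                   alpha_region = 0.05, min_sites = 5,
                                   max_window_sites = 10000) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "p", "pmd") %in% names(sites)))
  if (nrow(sites) == 0) return(empty_candidates())
  if (any(is.na(sites$p)) || any(sites$p <= 0 | sites$p > 1))
    stop("site p-values must be in (0, 1] with no missing values")
  out <- lapply(split(seq_len(nrow(sites)), factor(sites$chrom,
                                                   unique(sites$chrom))),
                function(idx) {
    s <- sites[idx, , drop = FALSE]
    if (is.unsorted(s$pos, strictly = TRUE))
      stop("'sites' must be strictly ordered by position within chromosome")
    regs <- scan_chrom(s$p, alpha_site, alpha_region, min_sites,
                       max_window_sites)
    if (nrow(regs) == 0) return(empty_candidates())
    k <- regs$b - regs$a + 1L
    data.frame(
      chrom = s$chrom[1],
      start_pos = s$pos[regs$a],
      end_pos = s$pos[regs$b],
      first_idx = idx[regs$a],
      last_idx = idx[regs$b],
      k = k,
      up_p = vapply(seq_len(nrow(regs)), function(i)
        up_tail_probability(k = k[i],
                            log_x = sum(log(s$p[regs$a[i]:regs$b[i]]))),
        numeric(1)),
      mean_pmd = vapply(seq_len(nrow(regs)), function(i)
        mean(s$pmd[regs$a[i]:regs$b[i]]), numeric(1)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  out$direction <- ifelse(out$mean_pmd > 0, "hyper", "hypo")
  rownames(out) <- NULL
  out
}

empty_candidates <- function() {
  data.frame(chrom = character(), start_pos = integer(), end_pos = integer(),
             first_idx = integer(), last_idx = integer(), k = integer(),
             up_p = numeric(), mean_pmd = numeric(), direction = character(),
             stringsAsFactors = FALSE)
}

# One-chromosome scan on a p-value vector. Returns a data.frame of merged
# site-index intervals (a, b), both endpoints significant.
scan_chrom <- function(p, alpha_site, alpha_region, min_sites,
                       max_window_sites) {
  n <- length(p)
  none <- data.frame(a = integer(), b = integer())
  if (n < min_sites) return(none)
  sig <- which(p <= alpha_site)
  if (length(sig) < 2L) return(none)
  cs <- c(0, cumsum(-log(p)))
  a <- integer(0); b <- integer(0)
  for (i in sig) {
    js <- sig[sig >= i + min_sites - 1L & sig <= i + max_window_sites - 1L]
    if (length(js) == 0L) next
    k <- js - i + 1L
    s <- cs[js + 1L] - cs[i]
    ok <- stats::pgamma(s, shape = k, lower.tail = FALSE) <= alpha_region
    if (any(ok)) { a <- c(a, i); b <- c(b, max(js[ok])) }
  }
  if (length(a) == 0L) return(none)
  merge_index_intervals(a, b)
}

# Union of site-index intervals; intervals that overlap or abut (next start
# <= previous end + 1) collapse into one maximal interval.
merge_index_intervals <- function(a, b) {
  o <- order(a, b)
  a <- a[o]; b <- b[o]
  ma <- a[1]; mb <- b[1]
  ra <- integer(0); rb <- integer(0)
  for (i in seq_along(a)[-1]) {
    if (a[i] <= mb + 1L) mb <- max(mb, b[i])
    else { ra <- c(ra, ma); rb <- c(rb, mb); ma <- a[i]; mb <- b[i] }
  }
  data.frame(a = c(ra, ma), b = c(rb, mb))
}
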