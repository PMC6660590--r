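#' Fisher's exact test at a single CpG site
#'
#' Two-sided Fisher exact test (point-probability method, as in
#' \code{\link[stats]{fisher.test}}) on the 2x2 table of methylated and
#' unmethylated read counts in a case and a reference sample, together with
#' the signed percent methylation difference (PMD).
#'
#' @param case,ref Length-2 integer vectors `c(n_meth, n_unmeth)` of read
#'   counts in the case and reference sample.
#' @param min_coverage Minimum total reads each sample must have at the site;
#'   below it the site is skipped and `NULL` is returned (default 1).
#' @return A list with `p_value` (two-sided exact p in (0, 1]), `pmd`
#'   (100 * (case fraction - reference fraction), percentage points),
#'   `n_case`, `n_ref` (total reads used), or `NULL` if coverage is
#'   insufficient.
#' @examples
#' fisher_site_test(c(10, 0), c(0, 10))   # p ~ 1.08e-5, pmd = +100
#' fisher_site_test(c(5, 5), c(5, 5))     # p = 1, pmd = 0
#' @export
fisher_site_test <- function(case, ref, min_coverage = 1) {
  check_counts(case); check_counts(ref)
  n1 <- sum(case); n2 <- sum(ref)
  if (n1 < max(1, min_coverage) || n2 < max(1, min_coverage)) return(NULL)
  list(p_value = unname(fisher_p_vec(case[1], case[2], ref[1], ref[2])),
       pmd = unname(100 * (case[1] / n1 - ref[1] / n2)),
       n_case = unname(n1), n_ref = unname(n2))
}

#' Logistic-regression test of one sample against a reference group
#'
#' Fits (in closed form) the binomial logistic model with response
#' methylated-vs-unmethylated read and a single case/reference group
#' indicator, and tests the group coefficient with a 1-df likelihood-ratio
#' test against the intercept-only model. With grouped binomial counts and a
#' single indicator the LRT statistic is exactly the G-statistic of the
#' pooled 2x2 table, which is what is computed here; agreement with
#' `glm(..., family = binomial)` is checked in the test suite.
#'
#' Under complete separation (the case fraction and the pooled reference
#' fraction are both 0 or 1, and differ) the model deviance is still finite
#' but the fitted coefficient is not; following the usual Haldane correction,
#' 0.5 is added to each of the four pooled cells before computing the
#' statistic, and the result is flagged with `separated = TRUE`.
#'
#' @param case Length-2 integer vector `c(n_meth, n_unmeth)`.
#' @param refs A list of length-2 count vectors, one per reference sample.
#' @param min_coverage Minimum total reads required in the case and in each
#'   counted reference sample (default 1); reference samples below it are
#'   dropped before testing, and `NULL` is returned if the case fails or no
#'   reference remains.
#' @return A list with `p_value` (LRT p in (0, 1]), `pmd` (100 * (case
#'   fraction minus the unweighted mean of per-reference-sample fractions)),
#'   `n_case`, `n_ref` (pooled reference reads), `separated` flag; or `NULL`
#'   if coverage is insufficient.
#' @examples
#' logistic_site_test(c(8, 2), list(c(2, 8), c(3, 7), c(2, 8)))
#' logistic_site_test(c(10, 0), list(c(0, 10)))  # separation fallback
#' @export
logistic_site_test <- function(case, refs, min_coverage = 1) {
  check_counts(case)
  stopifnot(is.list(refs), length(refs) >= 1)
  for (r in refs) check_counts(r)
  n1 <- sum(case)
  keep <- vapply(refs, function(r) sum(r) >= max(1, min_coverage), logical(1))
  if (n1 < max(1, min_coverage) || !any(keep)) return(NULL)
  refs <- refs[keep]
  m2 <- sum(vapply(refs, `[`, numeric(1), 1))
  u2 <- sum(vapply(refs, `[`, numeric(1), 2))
  r <- logistic_lrt_vec(case[1], case[2], m2, u2)
  ref_frac <- mean(vapply(refs, function(x) x[1] / sum(x), numeric(1)))
  list(p_value = unname(r$p), pmd = unname(100 * (case[1] / n1 - ref_frac)),
       n_case = unname(n1), n_ref = unname(m2 + u2),
       separated = unname(r$separated))
}

#' Per-site tests between two samples of a methylome matrix
#'
#' Runs [fisher_site_test()] at every CpG site where both samples meet the
#' coverage floor, returning a genome-ordered site-result table ready for
#' [scan_candidate_regions()].
#'
#' @param mat A [MethylomeMatrix].
#' @param case,ref Sample names in `mat`.
#' @param min_coverage Minimum reads per sample per site (default 1).
#' @return A data.frame with columns `chrom`, `pos`, `p`, `pmd`, `n_case`,
#'   `n_ref`; an attribute `n_skipped` records how many sites were dropped
#'   for coverage/absence.
#' @export
site_test_pair <- function(mat, case, ref, min_coverage = 1) {
  stopifnot(inherits(mat, "MethylomeMatrix"))
  ci <- sample_index(mat, case); ri <- sample_index(mat, ref)
  n1 <- mat$total[, ci]; n2 <- mat$total[, ri]
  use <- !is.na(n1) & !is.na(n2) & n1 >= max(1, min_coverage) &
    n2 >= max(1, min_coverage)
  m1 <- mat$meth[use, ci]; m2 <- mat$meth[use, ri]
  n1 <- n1[use]; n2 <- n2[use]
  res <- data.frame(chrom = mat$chrom[use], pos = mat$pos[use],
                    p = fisher_p_vec(m1, n1 - m1, m2, n2 - m2),
                    pmd = 100 * (m1 / n1 - m2 / n2),
                    n_case = n1, n_ref = n2, stringsAsFactors = FALSE)
  attr(res, "n_skipped") <- sum(!use)
  res
}

#' Per-site logistic tests of one sample against a sample group
#'
#' Runs the grouped-binomial likelihood-ratio test (see
#' [logistic_site_test()]) at every CpG site where the case sample and at
#' least `min_refs_present` reference samples meet the coverage floor.
#' Reference reads are pooled under a single group indicator; the PMD is the
#' case fraction minus the unweighted mean of the present reference samples'
#' fractions, so one deeply covered reference cannot dominate the difference.
#'
#' @param mat A [MethylomeMatrix].
#' @param case Case sample name.
#' @param refs Character vector of reference sample names.
#' @param min_refs_present Number of reference samples that must be present
#'   at a site for it to be tested (default: all of them).
#' @param min_coverage Minimum reads for a sample to count as present
#'   (default 1).
#' @return A data.frame with columns `chrom`, `pos`, `p`, `pmd`, `n_case`,
#'   `n_ref`, `n_refs_present`, `separated`; attribute `n_skipped` as in
#'   [site_test_pair()].
#' @export
site_test_group <- function(mat, case, refs,
                            min_refs_present = length(refs),
                            min_coverage = 1) {
  stopifnot(inherits(mat, "MethylomeMatrix"), length(refs) >= 1,
            min_refs_present >= 1, min_refs_present <= length(refs))
  ci <- sample_index(mat, case)
  ris <- vapply(refs, function(s) sample_index(mat, s), integer(1))
  n1 <- mat$total[, ci]
  tot_r <- mat$total[, ris, drop = FALSE]
  meth_r <- mat$meth[, ris, drop = FALSE]
  present <- !is.na(tot_r) & tot_r >= max(1, min_coverage)
  use <- !is.na(n1) & n1 >= max(1, min_coverage) &
    rowSums(present) >= min_refs_present
  m1 <- mat$meth[use, ci]; n1 <- n1[use]
  pres <- present[use, , drop = FALSE]
  tot_r <- tot_r[use, , drop = FALSE]; meth_r <- meth_r[use, , drop = FALSE]
  tot_r[!pres] <- NA; meth_r[!pres] <- NA
  M <- rowSums(meth_r, na.rm = TRUE); N <- rowSums(tot_r, na.rm = TRUE)
  r <- logistic_lrt_vec(m1, n1 - m1, M, N - M)
  ref_frac <- rowMeans(meth_r / tot_r, na.rm = TRUE)
  res <- data.frame(chrom = mat$chrom[use], pos = mat$pos[use],
                    p = r$p, pmd = 100 * (m1 / n1 - ref_frac),
                    n_case = n1, n_ref = N,
                    n_refs_present = rowSums(pres),
                    separated = r$separated, stringsAsFactors = FALSE)
  attr(res, "n_skipped") <- sum(!use)
  res
}

check_counts <- function(x) {
  if (!is.numeric(x) || length(x) != 2L || any(is.na(x)) || any(x < 0) ||
      any(x != floor(x)))
    stop("counts must be a length-2 non-negative integer vector")
  invisible(x)
}

# Vectorized two-sided Fisher exact p (point-probability rule: sum of
# hypergeometric point probabilities <= observed, with the conventional
# (1 + 1e-7) relative tolerance for ties). Duplicate tables are computed
# once; groups are put in a canonical order first so that swapping case and
# reference returns a bit-identical p-value.
fisher_p_vec <- function(m1, u1, m2, u2) {
  swap <- (m1 + u1 > m2 + u2) | (m1 + u1 == m2 + u2 & m1 > m2)
  if (any(swap)) {
    tm <- m1[swap]; tu <- u1[swap]
    m1[swap] <- m2[swap]; u1[swap] <- u2[swap]
    m2[swap] <- tm; u2[swap] <- tu
  }
  n1 <- m1 + u1; n2 <- m2 + u2; K <- m1 + m2; U <- u1 + u2
  key <- paste(m1, u1, m2, u2)
  uk <- !duplicated(key)
  p_unique <- mapply(function(m1, n1, n2, K, U) {
    x <- max(0, n1 - U):min(n1, K)
    d <- stats::dhyper(x, K, U, n1)
    min(1, sum(d[d <= d[x == m1] * (1 + 1e-7)]))
  }, m1[uk], n1[uk], n2[uk], K[uk], U[uk])
  pmax(unname(p_unique[match(key, key[uk])]), .Machine$double.xmin)
}

# Vectorized 1-df LRT (G-statistic) for two pooled binomial groups, with the
# Haldane +0.5 fallback under complete separation.
logistic_lrt_vec <- function(m1, u1, m2, u2) {
  n1 <- m1 + u1; n2 <- m2 + u2
  p1 <- m1 / n1; p2 <- m2 / n2
  separated <- (p1 %in% c(0, 1)) & (p2 %in% c(0, 1)) & (p1 != p2)
  if (any(separated)) {
    m1[separated] <- m1[separated] + 0.5; u1[separated] <- u1[separated] + 0.5
    m2[separated] <- m2[separated] + 0.5; u2[separated] <- u2[separated] + 0.5
    n1 <- m1 + u1; n2 <- m2 + u2
  }
  pp <- (m1 + m2) / (n1 + n2)
  g2 <- 2 * (xlogy(m1, m1 / n1) + xlogy(u1, u1 / n1) +
             xlogy(m2, m2 / n2) + xlogy(u2, u2 / n2) -
             xlogy(m1 + m2, pp) - xlogy(u1 + u2, 1 - pp))
  g2 <- pmax(g2, 0)  # guard tiny negative rounding
  p <- stats::pchisq(g2, df = 1, lower.tail = FALSE)
  list(p = pmax(p, .Machine$double.xmin), separated = separated)
}

xlogy <- function(x, y) ifelse(x == 0, 0, x * log(y))
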