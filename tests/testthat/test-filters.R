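# Build a site table and its single spanning candidate in one step.
cand_from <- function(pos, p, pmd, chrom = "chr1") {
  sites <- data.frame(chrom = chrom, pos = pos, p = p, pmd = pmd,
                      stringsAsFactors = FALSE)
  k <- length(pos)
  cand <- data.frame(chrom = chrom, start_pos = pos[1], end_pos = pos[k],
                     first_idx = 1L, last_idx = k, k = k,
                     up_p = up_tail_probability(k = k, log_x = sum(log(p))),
                     mean_pmd = mean(pmd),
                     direction = if (mean(pmd) > 0) "hyper" else "hypo",
                     stringsAsFactors = FALSE)
  list(sites = sites, cand = cand)
}

test_that("each retention rule rejects exactly its violators", {
  good_p <- rep(0.001, 6)
  # compliant region: 6 sites over 400 bp, PMD 35, gaps 80 -> retained
  x <- cand_from(seq(1000, 1400, by = 80), good_p, rep(35, 6))
  expect_equal(nrow(filter_regions(x$cand, x$sites)), 1)
  # length 240 bp (<= 250) with everything else fine -> rejected
  x <- cand_from(seq(1000, 1240, by = 48), good_p, rep(35, 6))
  expect_equal(nrow(filter_regions(x$cand, x$sites)), 0)
  # mean PMD 18 (< 20) -> rejected
  x <- cand_from(seq(1000, 1400, by = 80), good_p, rep(18, 6))
  expect_equal(nrow(filter_regions(x$cand, x$sites)), 0)
  # the same magnitude hypomethylated passes (absolute-value rule)
  x <- cand_from(seq(1000, 1400, by = 80), good_p, rep(-35, 6))
  out <- filter_regions(x$cand, x$sites)
  expect_equal(out$direction, "hypo")
  # a 250 bp gap splits the region; both 3-site fragments die at min_sites
  x <- cand_from(c(1000, 1080, 1160, 1410, 1490, 1570), good_p, rep(35, 6))
  expect_equal(nrow(filter_regions(x$cand, x$sites)), 0)
  # non-significant endpoints are trimmed; 4 significant sites < min_sites
  x <- cand_from(seq(1000, 1400, by = 80),
                 c(0.5, 0.001, 0.001, 0.001, 0.001, 0.5), rep(35, 6))
  expect_equal(nrow(filter_regions(x$cand, x$sites)), 0)
  # fewer than 5 sites -> rejected outright
  x <- cand_from(seq(1000, 1300, by = 100), rep(0.001, 4), rep(35, 4))
  expect_equal(nrow(filter_regions(x$cand, x$sites)), 0)
})

test_that("gap splitting re-validates fragments and keeps survivors", {
  # 12 sites with one 300 bp gap in the middle; each 6-site half spans
  # 400 bp with strong sites and PMD 40 -> two DMRs
  pos <- c(seq(1000, 1400, by = 80), seq(1700, 2100, by = 80))
  x <- cand_from(pos, rep(0.001, 12), rep(40, 12))
  out <- filter_regions(x$cand, x$sites)
  expect_equal(nrow(out), 2)
  expect_equal(out$start_pos, c(1000, 1700))
  expect_equal(out$end_pos, c(1400, 2100))
  expect_true(all(out$max_gap_bp <= 200))
  expect_true(all(out$k >= 5))
  # member sites of every output are a subset of the input candidate's
  expect_true(all(out$first_idx >= x$cand$first_idx &
                  out$last_idx <= x$cand$last_idx))
})

test_that("filtering is order-independent", {
  set.seed(5)
  s <- random_sites(120, 17)
  cand <- scan_candidate_regions(s)
  if (nrow(cand) >= 2) {
    a <- filter_regions(cand, s, pmd_min = 5, len_min_bp = 50)
    b <- filter_regions(cand[rev(seq_len(nrow(cand))), ], s,
                        pmd_min = 5, len_min_bp = 50)
    expect_equal(as.data.frame(a), as.data.frame(b))
  } else {
    succeed("scan produced < 2 candidates for this seed")
  }
})

test_that("DMR set intersection respects overlap, direction, reporting PMD", {
  mk <- function(start, end, dir, first = 1L, last = 8L) {
    data.frame(chrom = "chr1", start_pos = start, end_pos = end,
               first_idx = first, last_idx = last, k = 8L, up_p = 1e-6,
               mean_pmd = ifelse(dir == "hyper", 40, -40), direction = dir,
               length_bp = end - start + 1L, max_gap_bp = 100L,
               stringsAsFactors = FALSE)
  }
  multi <- mk(1000, 1600, "hyper")
  pair <- mk(1200, 1900, "hyper")
  rep_sites <- data.frame(chrom = "chr1", pos = seq(1000, 1600, by = 100),
                          p = 0.01, pmd = 33)
  out <- intersect_dmr_sets(pair, multi, reporting_sites = rep_sites)
  # coordinates from the multi-control DMR, PMD from the reporting pair
  expect_equal(nrow(out), 1)
  expect_equal(out$start_pos, 1000)
  expect_equal(out$end_pos, 1600)
  expect_equal(out$reported_pmd, 33)
  # opposite direction -> dropped
  expect_equal(nrow(intersect_dmr_sets(mk(1200, 1900, "hypo"), multi)), 0)
  # 30 bp overlap (< 50) -> dropped
  expect_equal(nrow(intersect_dmr_sets(mk(1571, 1900, "hyper"), multi)), 0)
  # exactly 50 bp -> kept
  expect_equal(nrow(intersect_dmr_sets(mk(1551, 1900, "hyper"), multi)), 1)
  # self-intersection is the identity when the overlap floor allows it
  both <- rbind(mk(1000, 1600, "hyper"), mk(5000, 5400, "hypo"))
  self <- intersect_dmr_sets(both, both, min_overlap_bp = 50)
  expect_equal(as.data.frame(self)[names(both)], both)
})
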