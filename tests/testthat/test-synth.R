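test_that("generator is deterministic and respects its config", {
  pl <- data.frame(n_sites = c(10, 12), spacing_bp = c(50, 40),
                   delta_pmd = c(40, -40))
  cf <- synth_config(n_sites = 2000, planted = pl, seed = 5)
  g1 <- generate_methylome_panel(cf)
  g2 <- generate_methylome_panel(cf)
  expect_identical(g1$matrix$pos, g2$matrix$pos)
  expect_identical(g1$matrix$meth, g2$matrix$meth)
  expect_identical(g1$truth, g2$truth)
  # a different seed gives different data
  g3 <- generate_methylome_panel(cf, seed = 6)
  expect_false(identical(g1$matrix$meth, g3$matrix$meth))
  # truth bookkeeping: one row per region, indices point at the block
  expect_equal(nrow(g1$truth), 2)
  expect_equal(g1$truth$n_sites, c(10, 12))
  expect_equal(g1$matrix$pos[g1$truth$first_idx], g1$truth$start_pos)
  expect_equal(g1$matrix$pos[g1$truth$last_idx], g1$truth$end_pos)
  # planted blocks keep their configured spacing
  idx <- g1$truth$first_idx[1]:g1$truth$last_idx[1]
  expect_true(all(diff(g1$matrix$pos[idx]) == 50))
  # positions strictly increasing; sites present somewhere
  expect_true(all(diff(g1$matrix$pos) > 0))
  expect_true(all(rowSums(!is.na(g1$matrix$total)) >= 1))
  # caller's RNG state is untouched
  set.seed(99); before <- .Random.seed
  invisible(generate_methylome_panel(cf))
  expect_identical(before, .Random.seed)
})

test_that("zero planted regions give an empty truth table and ~0 DMRs", {
  cf <- synth_config(n_sites = 2000, seed = 11)
  gen <- generate_methylome_panel(cf)
  expect_equal(nrow(gen$truth), 0)
  res <- run_athero_analysis(gen$matrix, "case", c("ctlA", "ctlB", "ctlC"),
                             verbose = FALSE)
  expect_lte(nrow(res$final), 1)
})

test_that("infeasible planted configs are rejected", {
  expect_error(synth_config(n_sites = 10,
                            planted = data.frame(n_sites = 20,
                                                 spacing_bp = 50,
                                                 delta_pmd = 40)),
               "exceed")
})

test_that("background fractions and planted PMDs match their targets", {
  cf <- synth_config(n_sites = 3000,
                     planted = data.frame(n_sites = 30, spacing_bp = 20,
                                          delta_pmd = 40), seed = 21)
  gen <- generate_methylome_panel(cf)
  mat <- gen$matrix
  bg <- setdiff(seq_along(mat$pos), gen$truth$first_idx[1]:gen$truth$last_idx[1])
  # control-sample fraction at background sites ~ configured landscape
  frac <- mat$meth[bg, 2] / mat$total[bg, 2]
  expect_equal(mean(frac, na.rm = TRUE), mean(gen$p_baseline),
               tolerance = 0.02)
  # planted block: case-vs-control empirical PMD within 3 SE of delta
  idx <- gen$truth$first_idx[1]:gen$truth$last_idx[1]
  pmd_hat <- 100 * (mean(mat$meth[idx, 1] / mat$total[idx, 1], na.rm = TRUE) -
                    mean(mat$meth[idx, 2] / mat$total[idx, 2], na.rm = TRUE))
  se <- 100 * sqrt(2 * 0.25 / (30 * 30))  # conservative binomial SE bound
  expect_lt(abs(pmd_hat - 40), 3 * se + 5)
})

test_that("recovery scoring handles the degenerate cases", {
  empty_truth <- data.frame(chrom = character(), start_pos = integer(),
                            end_pos = integer(), n_sites = integer(),
                            delta_pmd = numeric(), direction = character(),
                            first_idx = integer(), last_idx = integer())
  empty_calls <- empty_truth[, c("chrom", "start_pos", "end_pos",
                                 "direction")]
  r <- evaluate_recovery(empty_calls, empty_truth)
  expect_true(is.na(r$sensitivity))
  expect_equal(r$false_discoveries, 0)
  truth <- data.frame(chrom = "chrS", start_pos = 100L, end_pos = 600L,
                      n_sites = 10L, delta_pmd = 40, direction = "hyper",
                      first_idx = 1L, last_idx = 10L)
  exact <- data.frame(chrom = "chrS", start_pos = 100L, end_pos = 600L,
                      direction = "hyper")
  expect_equal(evaluate_recovery(exact, truth)$sensitivity, 1)
  # opposite-direction call neither matches nor counts as recovery
  flip <- transform(exact, direction = "hypo")
  r2 <- evaluate_recovery(flip, truth)
  expect_equal(r2$sensitivity, 0)
  expect_equal(r2$false_discoveries, 1)
  # a call far from any truth is a false discovery
  stray <- data.frame(chrom = "chrS", start_pos = 9000L, end_pos = 9500L,
                      direction = "hyper")
  expect_equal(evaluate_recovery(rbind(exact, stray),
                                 truth)$false_discoveries, 1)
  # reciprocal criterion: a huge call covering a small truth fails 50%
  big <- data.frame(chrom = "chrS", start_pos = 1L, end_pos = 5000L,
                    direction = "hyper")
  expect_equal(evaluate_recovery(big, truth)$sensitivity, 0)
})
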