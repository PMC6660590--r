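mk_dmr <- function(start, end, chrom = "chrS", dir = "hyper") {
  data.frame(chrom = chrom, start_pos = start, end_pos = end,
             first_idx = 1L, last_idx = 5L, k = 5L, up_p = 1e-5,
             mean_pmd = ifelse(dir == "hyper", 30, -30), direction = dir,
             length_bp = end - start + 1L, max_gap_bp = 50L,
             stringsAsFactors = FALSE)
}

test_that("overlap_bp follows half-open interval arithmetic", {
  expect_equal(overlap_bp(c(100, 200), c(150, 300)), 50)
  expect_equal(overlap_bp(c(100, 200), c(200, 300)), 0)  # abutting
  expect_equal(overlap_bp(c(100, 200), c(100, 200)), 100)
  expect_equal(overlap_bp(c(100, 200), c(400, 500)), 0)
  # symmetric
  expect_equal(overlap_bp(c(150, 300), c(100, 200)), 50)
  # chromosomes respected
  expect_equal(overlap_bp(list("chr1", 100, 200), list("chr2", 100, 200)), 0)
  expect_equal(overlap_bp(list("chr1", 100, 200), list("chr1", 150, 250)), 50)
})

test_that("tissue-DMR overlap rule is per single interval", {
  dmr <- mk_dmr(1000, 1500)
  sets <- list(
    monocyte = mk_dmr(1100, 1220),              # 121 bp overlap -> flag
    skm = mk_dmr(1471, 1600),                   # 30 bp -> no flag
    aorta = rbind(mk_dmr(980, 1029), mk_dmr(1471, 1600)),  # 30 + 30, each <50
    heart = mk_dmr(1451, 1700))                 # exactly 50 -> flag
  ann <- annotate_tissue_overlap(dmr, sets)
  expect_true(ann$monocyte_flag)
  expect_equal(ann$monocyte_overlap_bp, 121)
  expect_false(ann$skm_flag)
  expect_false(ann$aorta_flag)   # per-interval rule: 30+30 does not sum
  expect_equal(ann$aorta_overlap_bp, 30)
  expect_true(ann$heart_flag)
  expect_equal(ann$heart_overlap_bp, 50)
  expect_equal(ann$tissue_overlaps, "monocyte:121,heart:50")
})

test_that("enhancer overlap sums across segments and matches per-bp count", {
  # segments (0-based half-open): state 9 at [1000,1100), state 10 at
  # [1100,1130), state 1 at [1130,1500)
  seg <- data.frame(chrom = "chrS", start = c(1000L, 1100L, 1130L),
                    end = c(1100L, 1130L, 1500L), state = c(9L, 10L, 1L))
  # DMR 1-based 1071..1500 overlaps state 9 by 30, state 10 by 30 -> 60
  dmr <- mk_dmr(1071, 1500)
  ann <- annotate_enhancer(dmr, seg)
  expect_equal(ann$enh_overlap_bp, 60)
  expect_true(ann$is_enhancer_dmr)
  expect_equal(ann$enh_overlap_bp,
               oracle_bp_overlap(1071, 1500, seg$start[1], seg$end[1]) +
               oracle_bp_overlap(1071, 1500, seg$start[2], seg$end[2]))
  # 30 + 19 = 49 < 50 -> no flag
  ann2 <- annotate_enhancer(mk_dmr(1071, 1119), seg)
  expect_equal(ann2$enh_overlap_bp, 49)
  expect_false(ann2$is_enhancer_dmr)
  # promoter-state DMR: zero enhancer overlap
  expect_equal(annotate_enhancer(mk_dmr(1200, 1400), seg)$enh_overlap_bp, 0)
  # containment: overlap equals DMR length
  expect_equal(annotate_enhancer(mk_dmr(1011, 1060), seg)$enh_overlap_bp, 50)
  # unknown state numbers are ignored with a warning
  segu <- rbind(seg, data.frame(chrom = "chrS", start = 2000L, end = 3000L,
                                state = 25L))
  expect_warning(annotate_enhancer(dmr, segu), "unknown state")
})

test_that("enhancer totals match brute-force per-bp counts on random data", {
  set.seed(77)
  for (rep in 1:15) {
    bounds <- sort(sample(0:10000, 21))
    seg <- data.frame(chrom = "chrS", start = bounds[-21], end = bounds[-1],
                      state = sample(1:18, 20, replace = TRUE))
    s <- sample(1:9000, 1); e <- s + sample(50:900, 1)
    got <- annotate_enhancer(mk_dmr(s, e), seg)$enh_overlap_bp
    enh <- seg[seg$state %in% c(3, 8, 9, 10), ]
    want <- sum(vapply(seq_len(nrow(enh)), function(i)
      oracle_bp_overlap(s, e, enh$start[i], enh$end[i]), numeric(1)))
    expect_equal(got, want, label = sprintf("rep %d", rep))
  }
})

test_that("gene assignment honors precedence, coding priority, strand, ties", {
  fx <- generate_annotation_fixtures(seed = 2)
  g <- fx$genes
  # GENEA + coding tx 20000-28000: promoter window [15000,25000)
  # GENEB + coding tx 22000-40000: promoter [17000,27000), body [27000,40000)
  # GENENC non-coding tx 21000-30000: promoter [16000,26000), body [26000,30000)
  # GENEM - coding tx 50000-60000: promoter [55000,65000), body [50000,55000)
  # GENES + coding tx 70000-72000: promoter [65000,75000), empty body

  # promoter beats body whatever the overlap sizes: a DMR covering GENEB's
  # body [27000,40000) bp-wise but touching GENEA's promoter edge
  a <- map_gene(mk_dmr(24001, 30000), g)
  expect_equal(a$gene_category, "promoter")
  # within the promoter category, largest overlap wins: GENEB's promoter
  # window (1-based 17001..27000) overlaps 3000 bp, GENEA's only 1000 bp
  expect_equal(a$gene_name, "GENEB")
  expect_equal(a$gene_overlap_bp, 3000)

  # coding priority inside one category: DMR in GENEB body & GENENC body,
  # 28001..29800: GENENC overlap 1800, GENEB overlap 1800 -> coding wins;
  # make the non-coding overlap larger and coding still wins
  b <- map_gene(mk_dmr(29001, 29900), g)
  expect_equal(b$gene_category, "genebody")
  expect_equal(b$gene_name, "GENEB")

  # strand-aware promoter: DMR at 63000-63500 sits in GENEM's promoter
  # (anchored at tx_end 60000) and nothing else
  m <- map_gene(mk_dmr(63001, 63500), g)
  expect_equal(m$gene_name, "GENEM")
  expect_equal(m$gene_category, "promoter")
  expect_equal(m$gene_overlap_bp, 500)

  # short gene: body is empty but the promoter window still applies
  s <- map_gene(mk_dmr(74001, 74500), g)
  expect_equal(s$gene_name, "GENES")
  expect_equal(s$gene_category, "promoter")

  # intergenic with nearest-TSS link, and beyond the cap -> "."
  i <- map_gene(mk_dmr(100000, 100400), g)
  expect_equal(i$gene_category, "intergenic")
  expect_equal(i$gene_name, "GENES")   # nearest TSS at 70000
  expect_equal(i$gene_overlap_bp, 0)
  far <- map_gene(mk_dmr(100000, 100400), g, nearest_cap_bp = 10000)
  expect_equal(far$gene_name, ".")

  # deterministic under permutation of the gene table
  set.seed(9)
  dmrs <- rbind(mk_dmr(24001, 30000), mk_dmr(63001, 63500),
                mk_dmr(29001, 29900), mk_dmr(100000, 100400))
  base <- map_gene(dmrs, g)
  for (r in 1:5)
    expect_equal(map_gene(dmrs, g[sample(nrow(g)), ]), base)
})

test_that("lexicographic tie-break picks the alphabetically first gene", {
  g <- data.frame(gene_name = c("ZZZ", "AAA"), transcript_id = c("t1", "t2"),
                  chrom = "chrS", strand = "+", tx_start = c(10000L, 10000L),
                  tx_end = c(20000L, 20000L), is_coding = TRUE,
                  stringsAsFactors = FALSE)
  a <- map_gene(mk_dmr(9001, 9500), g)   # equal promoter overlaps
  expect_equal(a$gene_name, "AAA")
})

test_that("DMR fully inside one promoter window maps to that gene", {
  fx <- generate_annotation_fixtures(seed = 4)
  a <- map_gene(mk_dmr(16001, 16400), fx$genes)
  expect_equal(a$gene_name, "GENEA")
  expect_equal(a$gene_category, "promoter")
  expect_equal(a$gene_overlap_bp, 400)
})

test_that("annotate_dmrs joins all tracks with stable ids", {
  fx <- generate_annotation_fixtures(seed = 5)
  dmrs <- rbind(mk_dmr(16001, 16400), mk_dmr(63001, 63500, dir = "hypo"))
  ann <- annotate_dmrs(dmrs, segments = fx$segments,
                       gene_models = fx$genes,
                       tissue_dmr_sets = list(aorta = mk_dmr(16001, 16400)))
  expect_equal(ann$dmr_id, c("dmr_0001", "dmr_0002"))
  expect_true(all(c("enh_overlap_bp", "is_enhancer_dmr", "gene_name",
                    "gene_category", "aorta_flag", "tissue_overlaps") %in%
                  names(ann)))
  expect_true(ann$aorta_flag[1])
  expect_false(ann$aorta_flag[2])
  # flag definition is exactly the >= 50 bp total rule
  expect_equal(ann$is_enhancer_dmr, ann$enh_overlap_bp >= 50)
})
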