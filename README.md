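# updmr

Differentially methylated region (DMR) calling from whole-genome bisulfite
sequencing CpG count tables, built around the Uniform Product (UP)
joint-probability statistic.

## Who this is for

Anyone with per-sample CpG methylation count files (bismark coverage or a
count bedGraph) who wants regional methylation differences between
conditions — one case versus one control, one case versus a control group,
or one tissue versus a panel of others — together with reproducible,
rule-based annotation of the resulting regions against chromatin-state
segmentations and gene models.

## The method

1. **Site tests.** Each CpG is tested for differential methylation:
   two-sided Fisher's exact test on the 2×2 methylated/unmethylated read
   table for two samples, or a binomial logistic regression with a
   case/group indicator (1-df likelihood-ratio test) for one sample versus
   a pooled group. Each test also yields the percent methylation
   difference, PMD = 100·(case fraction − mean reference fraction).

2. **UP scan.** For a run of *k* consecutive site p-values with product
   *x*, the joint tail probability under the null is

   P(∏ᵢ Uᵢ ≤ x) = x · Σⱼ₌₀^{k−1} (−ln x)ʲ / j!  =  Q(k, −ln x),

   the upper regularized incomplete gamma function. Every window of ≥ 5
   consecutive sites that begins and ends with a site significant at 0.05
   and has UP tail probability ≤ 0.05 qualifies; overlapping qualifying
   windows merge into maximal candidate regions.

3. **Filters.** Candidates are kept only with mean |PMD| ≥ 20 percentage
   points, length > 250 bp, and no inter-site gap > 200 bp (over-long gaps
   split the candidate; each fragment is re-validated from scratch).

4. **Intersection.** The final case/control set contains the multi-control
   DMRs corroborated by a same-direction pairwise DMR (≥ 50 bp overlap),
   with reported PMD recomputed from the designated pairwise comparison.

5. **Tissue calling and annotation.** One-to-many tissue DMRs (site tested
   only when covered in the target and ≥ 4 of 5 non-targets, for a
   six-sample panel); annotation with tissue-DMR overlaps (per-interval
   ≥ 50 bp rule), enhancer-chromatin overlaps (summed ≥ 50 bp rule over
   states 3/8/9/10 of an 18-state segmentation), and gene assignment by
   precedence (TSS ± 5 kb window, then gene body, then intergenic;
   protein-coding first, largest overlap, deterministic tie-breaks).

See `vignettes/updmr-methods.Rmd` for the full account, including every
choice the method's description leaves open.

## Worked example

Simulate a 4-sample panel (case + 3 controls, 30× coverage, 5,000 CpGs)
with one hypermethylated and one hypomethylated region planted (|PMD| = 40,
10 CpGs, 450 bp), then run the full two-stage analysis:

```r
library(updmr)

pl  <- data.frame(n_sites = 10, spacing_bp = 50, delta_pmd = c(40, -40))
cfg <- synth_config(n_sites = 5000, planted = pl, seed = 7)
gen <- generate_methylome_panel(cfg)

res <- run_athero_analysis(gen$matrix, "case", c("ctlA", "ctlB", "ctlC"))
print(res)
#> Case/control DMR analysis
#>   case: case  controls: ctlA, ctlB, ctlC (reporting pair vs ctlA)
#>   pairwise DMRs: 2   multi-control DMRs: 2   final: 2
#>   final: 1 hyper / 1 hypo, median length 451 bp

as.data.frame(res$final)[, c("chrom", "start_pos", "end_pos", "k", "up_p",
                             "mean_pmd", "reported_pmd", "direction")]
#>   chrom start_pos end_pos  k         up_p  mean_pmd reported_pmd direction
#> 1  chrS     15510   15960 10 2.454357e-47  40.90525     37.44629     hyper
#> 2  chrS    136049  136499 10 2.275668e-42 -45.30786    -46.10061      hypo

evaluate_recovery(res$final, gen$truth)[c("sensitivity",
                                          "false_discoveries")]
#> $sensitivity
#> [1] 1
#> $false_discoveries
#> [1] 0
```

Both planted regions come back at their planted coordinates and directions;
`up_p` is the joint UP probability of the region's site p-values,
`mean_pmd` the mean per-site PMD of the multi-control comparison, and
`reported_pmd` the same quantity recomputed from the case-vs-ctlA pair.
With `out_dir =` the run also writes BED files for all three DMR sets, an
annotation table, and a JSON parameter manifest.

A thin command-line front end over the same functions is included at
`inst/cli/updmr.R` (`simulate`, `athero`, `tissue`, `annotate`,
`evaluate` subcommands).

## Acceptance script

`scripts/acceptance.R` re-runs the package's full computation from scratch
against the installed package: it generates a synthetic case/control panel
and a six-tissue panel under the given seed, executes the two-stage DMR
analysis with annotation and the one-to-many tissue analysis, reports
recovery against the planted truth on stderr, and writes the JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
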