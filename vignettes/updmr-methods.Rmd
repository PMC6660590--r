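---
title: "Calling differentially methylated regions with the Uniform Product statistic"
author: "updmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling differentially methylated regions with the Uniform Product statistic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(updmr)
```

## The problem

Whole-genome bisulfite sequencing yields, per CpG site and sample, a count of
methylated and unmethylated reads. Regional methylation differences between
conditions -- e.g. atherosclerotic versus control aorta, or one tissue versus
a panel of others -- are biologically far more interpretable than single-site
differences, but a "region" is not directly observed: it must be assembled
from runs of consistently differential sites. `updmr` implements a complete
region-calling chain: per-site tests, a joint-probability scan over runs of
consecutive site p-values, explicit retention filters, a two-stage
pairwise/multi-control intersection design, one-to-many tissue-specific
calling, and rule-based annotation against chromatin-state segmentations and
gene models.

## Site-level tests

For two samples, each CpG is tested with the two-sided Fisher exact test on
the 2x2 table of methylated/unmethylated read counts. For one sample against
a group, a binomial logistic regression is fit with a single case/reference
indicator and tested by a 1-df likelihood-ratio test. Two details are worth
stating because they are invisible in the output:

* With grouped binomial counts and a single indicator, the logistic LRT
  statistic equals the G-statistic of the pooled 2x2 table exactly, so the
  implementation computes it in closed form (vectorised over the genome);
  the test suite verifies agreement with `glm(..., family = binomial)` to
  1e-6 and with a grid maximization of the two binomial likelihoods.
* Under complete separation (case and pooled reference fractions both
  saturated at 0 or 1, and different) the deviance is finite but the fitted
  coefficient is not; the package applies the Haldane correction (+0.5 to
  each pooled cell) and flags the site, so downstream consumers can see
  which p-values came from the fallback path.

The percent methylation difference (PMD) attached to every test is the case
fraction minus the *unweighted mean of per-reference-sample fractions*, in
percentage points. Pooling reference reads instead would let one deeply
sequenced reference dominate the reported difference; the unweighted mean
treats reference individuals symmetrically. (The pooled counts still drive
the test itself, which is a statement about read-level evidence.)

The Fisher test uses the point-probability (minimum-likelihood) two-sided
rule, the same convention as `stats::fisher.test`. The site tests are run in
both directions of effect, so a one-sided choice would have no principled
orientation.

## The Uniform Product statistic

If the per-site null p-values are independent Uniform(0,1), the product of
$k$ consecutive p-values $x = \prod_{i=1}^{k} p_i$ has tail probability

$$P\left(\prod_{i=1}^{k} U_i \le x\right)
  = x \sum_{j=0}^{k-1} \frac{(-\ln x)^j}{j!}
  = Q(k, -\ln x),$$

where $Q$ is the upper regularized incomplete gamma function (equivalently,
$-\ln \prod U_i \sim \mathrm{Gamma}(k, 1)$). `up_tail_probability()`
implements the series directly in log space with a log-sum-exp reduction, so
it is stable for products down to (and far below) the double-precision
underflow limit -- callers can pass `log_x` = $\sum \ln p_i$ instead of the
product itself -- and for $k$ in the thousands. The independent
`pgamma()` route is used only to cross-check the series in the tests and as
a fast screening threshold inside the scanner (below); every *reported*
p-value comes from the package's own series.

A useful property worth spelling out: at fixed $x < 1$ the tail probability
*increases* with $k$, because a product of more uniforms is stochastically
smaller. Joint significance of a long run therefore requires a product far
smaller than that of a short run.

## The candidate scan

`scan_candidate_regions()` declares a window of consecutive sites
*qualifying* when (i) it has at least `min_sites` (default 5) members,
(ii) its first and last site are individually significant at `alpha_site`
(default 0.05), and (iii) its UP tail probability is at most `alpha_region`
(default 0.05). The endpoint rule prevents a strong core from dragging
flanking null sites into a region.

The defining rules say nothing about how overlapping qualifying windows
become one region. The package's choice: all qualifying windows that overlap
or abut (in site index) are merged transitively into a maximal region, the
region is trimmed inward so its ends are significant sites (a no-op
immediately after merging, but load-bearing after gap splitting -- see
below), and the reported `up_p` is recomputed over the full merged span.
This rule is deterministic, order-independent, and checkable against a
brute-force oracle that enumerates every window; the test suite does exactly
that on random sequences, and the merged span's `up_p` is reported as-is
(it is not re-thresholded, and can exceed `alpha_region` in principle).

Implementation note: screening every window with the $O(k)$ series would
make the scan quadratic-times-$k$. Instead the scanner precomputes the
cumulative sum of $-\ln p$ and uses the equivalence
$Q(k, S) \le \alpha \iff S \ge Q^{-1}(k, \alpha)$, turning each window
check into one comparison. A `max_window_sites` cap (default 10,000 sites)
bounds the forward scan from each significant left endpoint; for a window of
$10^4$ null sites to qualify, its log-product would have to undershoot its
expectation by hundreds of standard deviations, so the cap cannot change
results on data of realistic size, and it does not bind in any of the
oracle-equivalence tests.

## Retention filters

`filter_regions()` applies the three retention rules: mean |PMD| at least
20 percentage points, first-to-last-CpG length strictly greater than 250 bp,
and no inter-site gap above 200 bp. Region length is defined by the member
CpGs (the evidence), not by any padded interval.

A candidate containing an over-long gap is *split at every such gap* rather
than discarded whole: the defining phrasing ("no gaps > 200 bp") is
ambiguous between the two readings, and splitting preserves signal while
every fragment is re-validated from scratch -- trimmed to significant
endpoints, required to have `min_sites` members and a qualifying UP
probability -- before the PMD and length rules are applied. Nothing survives
on the strength of sites it no longer contains.

## The two-stage intersection design

The case/control analysis runs twice: the case against a designated control
individually (Fisher; DMR set *P*) and the case against all controls as a
group (logistic; DMR set *M*, computed over sites covered in every sample).
The final set is the same-direction intersection: multi-control DMRs
corroborated by a pairwise DMR overlapping at least `min_overlap_bp`
(default 50 bp, the only overlap magnitude the method states anywhere; the
defining description says only "identified in both", so the threshold is
surfaced as a parameter rather than hidden). Final coordinates come from the
multi-control DMR; reported PMD values are recomputed from the designated
pairwise comparison over those coordinates, so a reader always sees the
difference between the two individuals, not a group-averaged quantity.

With a single control the second stage is the same comparison as the first,
so the pipeline sets *M = P* rather than re-testing with a different
statistic.

Each final DMR carries a `coverage_anomaly` flag marking regions where some
control's coverage falls below a quarter of its genome-wide mean. No
automatic fallback is taken -- the right response (e.g. trusting the
pairwise comparison) is a judgment call -- but the flag makes such regions
auditable.

## Tissue-specific calling

`call_tissue_dmrs()` compares one target methylome against the rest of a
panel pooled as a single reference group ("one to many"). Sites must be
covered in the target and in at least `min_nontarget_present` non-target
samples -- default panel size minus one, which generalizes the 4-of-5 rule
used with a six-tissue panel. Scanning and filtering are identical to the
case/control analysis, on the reading that "the same approach" carries the
thresholds over unchanged. Direction is from the target's perspective:
"hypo" means the target is less methylated than the panel.

## Annotation rules

Two overlap conventions coexist deliberately, mirroring a real asymmetry in
how the rules are stated:

* **Tissue DMR overlap** is per single interval: a DMR is flagged for a
  tissue only if *one* tissue DMR overlaps it by >= 50 bp. Two 30 bp
  overlaps do not sum to 60.
* **Enhancer chromatin overlap** is a total: base pairs overlapping any
  segment in the enhancer states (3, 8, 9, 10 of an 18-state segmentation)
  are summed, and 30 + 25 bp does reach the 50 bp flag.

Gene assignment builds, per transcript, a promoter window (TSS +/- 5 kb;
strand-aware, so on the minus strand the window is anchored at `tx_end`) and
a gene-body region (promoter window edge to the TES; empty for transcripts
shorter than the half-window). Precedence is promoter, then body, then
intergenic; within the highest-precedence category with any overlap,
protein-coding genes are preferred, then largest overlap (per gene, the
maximum across its transcripts), then lexicographic gene name -- every step
deterministic, so permuting the gene table cannot change an assignment.
Intergenic DMRs are linked to the nearest TSS within 1 Mb but remain
labeled intergenic; this is a documented approximation standing in for
web-service-based region-gene association, which is out of scope.

## The synthetic world

`generate_methylome_panel()` draws the data all recovery claims are tested
on. Its defaults describe one fixed world:

| Feature | Default | Why |
|---|---|---|
| CpG spacing | clusters with geometric within-cluster gaps (mean ~20 bp, cluster mean 15 sites), between-cluster gaps ~1.5 kb | CpG-island-like clustering; regions of >= 5 sites within 200 bp gaps arise naturally |
| Baseline methylation | piecewise-constant region means ~ Beta(8, 2), regions ~50 sites | a ~80% methylated somatic genome with occasional hypomethylated blocks |
| Coverage | negative binomial, mean 30, dispersion 0.2 | realistic WGBS depth; produces zero- and low-coverage sites that exercise the skipping and presence-rule paths |
| Reads | binomial at the site/sample fraction | the sampling model the site tests assume |
| Planted DMRs | explicit blocks (e.g. 10 sites, 50 bp spacing, |PMD| 40) inserted 3 kb clear of background | known truth for sensitivity/false-discovery scoring |

The generator is deterministic under a seed and leaves the caller's RNG
state untouched. What it does *not* emulate -- and what a green recovery
test therefore does not establish robustness against -- includes spatial
correlation of methylation beyond piecewise-constant blocks, biological
replicate variability (all null samples share one landscape, so between-
individual overdispersion is absent), bisulfite conversion errors, mapping
artifacts, and copy-number or SNP confounders. The null calibration of the
site tests is likewise checked under the clean binomial null only.

## Numerical choices

* All internal coordinates are 1-based positions of the CpG cytosine;
  all interval files written are 0-based half-open BED. The BED writer
  prints numeric fields with `%.17g` so a write/read round trip is
  bit-exact.
* Cross-sample coordinate harmonization unifies only *isolated* 1-bp pairs
  (no neighbor within 1 bp on either side) not co-occurring within any one
  sample; counts are never merged. This makes `harmonize_samples()`
  idempotent.
* p-values are clamped into (0, 1] (`.Machine$double.xmin` floor) so the
  scan's log-products are always finite.
* The Fisher implementation canonicalizes the group order before
  enumeration, making case/reference symmetry bit-exact rather than
  merely within rounding.
* Ties in the two-sided Fisher sum use the conventional (1 + 1e-7)
  relative tolerance, matching the reference implementation.

## Known limitations

* No overdispersion / beta-binomial modeling: with biological replicates in
  the reference group, the binomial logistic test is anti-conservative to
  an extent the package does not estimate.
* No multiple-testing correction across windows or regions; the 0.05 levels
  are per-window, by design fidelity, and genome-wide calibration is the
  user's responsibility.
* The window-merging rule, the 50 bp intersection threshold and the
  split-at-gap behavior are this package's documented resolutions of
  genuinely underdetermined points; all are parameters, and the defaults
  are what the test suite pins down.
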