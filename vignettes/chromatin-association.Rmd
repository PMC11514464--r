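---
title: "Chromatin association analytics for broad ChIP-seq domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromatin association analytics for broad ChIP-seq domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromassoc)
```

## The problem this package addresses

Proteins of the nuclear lamina and their interactors (lamin A/C, LAP2α,
lamin B1) bind chromatin in megabase-scale "broad domains" rather than
sharp peaks. Studies of such proteins typically call enrichment domains
with a broad-domain peak caller, then ask downstream questions that are
about interval arithmetic and association statistics rather than about
read processing:

* How many bases do two domain sets share, and how does their overlap with
  constitutive lamina-associated domains (cLADs) partition the genome
  (base-pair Venn classes)?
* Is the number of genes of interest (e.g. differentially expressed genes,
  DEGs) overlapping a domain set higher or lower than expected by chance?
* How are the distances from genes to their nearest domain distributed,
  and do two gene classes differ in that distribution?
* Which genes are "bound" when binding is scored by averaging windowed
  log2(ChIP/input) signal over the gene body?
* What does the signal look like on a common meta-region axis across
  domains, or around transcription start sites (TSS)?

`chromassoc` implements these analytics as composable functions over
`GRanges` containers, together with threshold rules for expression tables,
ChIP-qPCR batch normalization, and a seeded synthetic-data generator so
that every stage is testable end to end without external data.

## Statistical procedures

### Region-randomization overlap permutation test

The observed statistic is the number of query genes sharing at least 1 bp
with the merged region set. Under the null, the regions are re-placed
uniformly over the genome `n_perm` times (1000 by default), each region
keeping its length; the test reports

* the Z-score \((\mathrm{obs} - \overline{\mathrm{perm}}) / \mathrm{sd}(\mathrm{perm})\),
* the empirical p-value with the +1 pseudocount convention,
  \(p = (\#\{\mathrm{perm} \ge \mathrm{obs}\} + 1)/(n_{\mathrm{perm}} + 1)\),
  so the smallest attainable value at 1000 permutations is
  \(1/1001 \approx 0.001\), and
* the one-sided \(\alpha = 0.05\) critical value of the permuted
  distribution (the "red line" of permutation histograms).

Randomization is genome-wide and unmasked: the chromosome is chosen with
probability proportional to its number of valid start positions for the
region's length, the start uniformly among them, and randomized regions
may overlap one another. No per-chromosome constraint or assembly-gap
mask is applied; with domain sets covering up to 20% of the genome,
rejection sampling against self-overlap would bias the null, so it is
deliberately not used.

The default `alternative = "auto"` tests in the direction of the observed
deviation, which is the convention of permutation-histogram figures; note
that under the null this auto-selected one-sided p rejects at roughly
twice the nominal rate, as any data-directed one-sided test does.
Calibration claims in the test suite therefore fix
`alternative = "greater"`, the direction these studies test; under an
independence null its rejection rate at \(\alpha = 0.05\) sits inside the
exact binomial 99% interval over 200 simulated data sets.

### Windowed binding score and the top-decile rule

A gene's binding score is computed by tiling the gene body with 10 bp
windows (final partial window retained), averaging the log2-ratio signal
within each window, and dividing the sum of window values by the number
of windows analysed. Windows and genes with no covered bases are treated
as missing, not zero. Genes are ranked by descending score and the top
10% (`max(1, floor(fraction * n))` genes) are flagged "bound"; ties are
broken deterministically by (score descending, gene id ascending), so the
bound set is invariant to input row order. The minimum score among bound
genes is reported alongside the flags, since that cutoff is the
interpretable quantity.

### Distances and the KS family

Closest distances are unsigned edge-to-edge gaps in bp, scanning both
chromosomal directions, 0 on overlap. A query on a chromosome with no
reference interval is reported as "no neighbour" and excluded from
distributions (with a count) rather than given a pseudo-distance. One
boundary case is worth stating: an exactly abutting pair (`[100,200)` vs
`[200,300)`) shares zero bases yet has gap 0, so distance 0 is implied by,
but does not imply, a 1 bp overlap.

Distance histograms use a first class of exactly 0 (overlapping), then
half-open classes `(lo, hi]` with default edges 10 kb, 100 kb, 1 Mb, and
an open-ended final class. Kolmogorov–Smirnov comparisons always run on
the raw distances — binning is presentation only. The asymptotic
two-sided p comes from `stats::ks.test(exact = FALSE)`; an exact option
enumerates all label assignments (correct under the heavy ties that
zero-inflated distance samples have) and is feasible for small samples.
Families of KS tests are corrected with Hochberg's step-up procedure
(`stats::p.adjust`), applied per declared family.

### Expression threshold rules

The boundary conventions follow the usual wording of such filters and are
each unit-tested at the boundary:

| rule | boundary |
|---|---|
| low-count filter | expected counts strictly > 5 in **all** libraries |
| expressed | FPKM ≥ 0.5 (inclusive) in **all** replicates |
| DEG fold change | abs(log2FC) strictly > 1.5 |
| DEG p-value | strictly < 0.05 |
| DEG expression | CPM ≥ 10 (inclusive) in ≥ 1 library of the comparison |

### ChIP-qPCR

Percent-input values are normalized per (locus, biological replicate) by
dividing by the group mean, which removes multiplicative batch effects
exactly: the normalized group mean is 1 and rescaling a whole batch is a
no-op. IgG control rows are excluded from the normalizer by default
(they are still divided by it); `include_igg = TRUE` averages over all
rows instead. Fold enrichment is the specific/IgG ratio per technical
replicate, summarized as mean ± sd with the sample (n − 1) denominator.
A thin helper wraps the two-tailed equal-variance two-sample t-test used
to compare conditions on normalized values.

## Signal profiles

Two profile layouts are provided, both returning a region × bin matrix
with per-cell covered-base counts:

* **Scaled meta-region profiles**: each region body is split into
  `body_bins` (default 100, i.e. body = 100%) equal-length bins and each
  flank spans exactly one region-length split into `flank_bins` bins.
  When the length is not divisible by the bin count the remainder bases
  go to the leftmost bins — a deterministic rule chosen and documented
  here because heat-mapping tools differ in their interpolation and do
  not document it precisely.
* **Anchor-centred profiles**: fixed-width bins around single positions,
  typically the strand-aware TSS, with `flank_bp` (default 50 kb) per
  side.

Minus-strand regions/anchors are flipped so columns always read 5′→3′
(strand affects profiles only; all overlap and distance operations are
strand-blind). Bases with no track step are missing and excluded from
bin means under the default `exclude_missing` policy; `zero_fill` treats
them as 0 instead. Bases beyond chromosome ends are always missing.
Column aggregation (mean or median per bin over non-missing rows) gives
the summary curves drawn above heatmaps.

## The synthetic-data generator

`sim_config()` fixes the study conditions the generator emulates:

* a 3 × 10 Mb toy genome (layout is part of the config, not the random
  draw);
* broad domains drawn uniformly from 1–3 Mb, placed without overlap at a
  coverage target of 15% of the genome — the middle of the 11–20% range
  such domain sets occupy — with the final length clipped so realized
  coverage equals the target;
* 600 genes of 2–20 kb, 215 of them DEGs (80 up, 135 down), with 60% of
  the down-DEGs planted fully inside the "knockout" domain set and
  planted-outside genes placed clear of domains;
* a DE table built so the threshold rules recover exactly the planted DEG
  set (each non-DEG fails exactly one rule, with margins at every
  boundary);
* a log2-ratio track tiled in 100 bp steps with plateau 0.8 inside
  domains, background −0.2 outside, Gaussian noise sd 0.3 — values chosen
  so that top-decile bound genes score in a realistic 0.3–0.9 range;
* a qPCR table with multiplicative batch factors per biological replicate
  and a 3-fold planted enrichment at positive loci.

`make_fixture()` additionally draws a second, independent domain set as
the "wildtype" condition, so relocalization toward down-DEGs exists in
the knockout set only; the wildtype overlap with DEGs is at chance. This
is a simplification of redrawing domains biased toward gene-dense
regions: it produces the same qualitative structure (a domain set
covering most down-DEGs versus one that does not) while keeping every
planted parameter directly recoverable. Every generator is a pure
function of (config, seed); fixtures are byte-identical across runs.

What the generator does **not** emulate: mappability and assembly gaps,
GC or gene-density covariates of domain placement, autocorrelated signal
noise, peak-calling uncertainty, and library-level count noise (the DE
table is constructed, not fit). Passing tests therefore demonstrate
correctness of the analytics under a clean null and a clean planted
effect, not robustness to those real-data artefacts.

## Numerical and design choices

* Coordinates are BED-native 0-based half-open at I/O and `GRanges`
  1-based closed internally; conversion happens only in the readers and
  writers.
* Book-ended intervals merge (as `bedtools merge` does); base-pair totals
  are unaffected.
* Venn partitions are computed exactly via `disjoin` membership classes;
  the classes are disjoint and sum to the merged union length by
  construction, and this conservation is property-tested.
* The permutation loop runs on plain numeric arrays (drawing the same
  placements as `randomize_regions`) to keep 1000 randomizations at
  interactive speed; the observed statistic goes through the same
  `GRanges` path as all other overlap counts.
* Degenerate permuted distributions (sd = 0) yield a missing Z-score with
  a warning; the empirical p remains valid.
* The test suite runs everything at desk scale: oracle equivalence on
  ≤ 10 kb chromosomes against per-base bitmask oracles, null calibration
  with 200 data sets × 200 permutations on a 3 × 1 Mb genome, and
  planted-effect recovery with 135-gene sets over 20 seeds on the full
  3 × 10 Mb layout. These sizes are the package's own choice of
  desk-scale defaults and are stated here so results are reproducible.

## Known limitations

* Randomization offers no masking or per-chromosome constraint; on real
  assemblies with large unmappable regions the null is slightly liberal.
* The exact KS option is limited to small samples by design (enumeration
  is capped); large tied samples fall back to the asymptotic p, which is
  approximate under ties.
* `read_bed`/`read_bedgraph` are deliberate minimal readers for BED3/6
  and 4-column bedGraph with strict validation; they do not accept
  bigWig/BigBed (convert first) or GTF.
* The pipeline consumes a differential-expression table; it does not fit
  expression models.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1)
fx <- make_fixture(cfg, "fixture")
down <- fx$genes[S4Vectors::mcols(fx$genes)$class == "down"]
permutation_overlap_test(down, fx$domains_ko, n_perm = 1000, seed = 2)
```

See the README for the numbers this prints and how
`scripts/acceptance.R` re-derives the headline quantities from scratch.
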