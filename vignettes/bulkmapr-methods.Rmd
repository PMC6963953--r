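---
title: "Bulked-segregant mapping with bulkmapr: models, defaults and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bulked-segregant mapping with bulkmapr: models, defaults and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bulkmapr)
library(data.table)
```

## The problem

A cross between two inbred parents that differ in a trait of interest --
here the motivating system is leafy-head formation in Chinese cabbage, but
nothing in the package is crop-specific -- segregates in the F2. Pooling the
DNA (BSA-Seq) or RNA (BSR-Seq) of the most extreme individuals on each side
of the phenotype and sequencing the two pools turns linkage into an allele
frequency signal: markers linked to a causal locus are enriched for one
parental allele in one bulk and depleted in the other, while unlinked
markers sit near the F2 expectation of 1/2 in both.

The per-bulk statistic is the **SNP-index**, the fraction of reads carrying
the allele of the "trait" parent at a biallelic site,

$$\mathrm{index} = \frac{\mathrm{alt\ depth}}{\mathrm{ref\ depth} +
\mathrm{alt\ depth}},$$

and the mapping signal is the **delta(SNP-index)**, the difference between
the two bulks, which has expectation 0 away from the trait locus and a
mode-dependent extreme at it. For a fully penetrant recessive trait with
50-individual bulks, the trait bulk is fixed (index 1) and the opposite bulk
sits at 1/3 (the 1:2:1 F2 conditioned on not showing the recessive
phenotype), so the expected delta at the causal marker is $1 - 1/3 = 2/3$.
That expectation is one of the package's acceptance checks.

## The scan

`bsa_scan()` chains the pieces; each is exported on its own.

**Filtering** (`filter_variants`). Sites are kept when both bulks have total
depth strictly greater than `min_depth` (default 5 -- "depth > 5x" read
literally, so a depth of exactly 5 is removed) and, by default, when the two
parents are homozygous for opposite alleles, the only configuration
informative in an F2. Input and retained counts are logged so a run can be
audited.

**Windowing** (`window_scan`). Windows of `window_size` (default 100 kb)
advance by `step` (default 10 kb); a window's statistic is the mean delta of
the variants in `[center - w/2, center + w/2)`. The defaults are package
decisions, not published values: reported candidate-region sizes of exactly
0.1 Mb are consistent with a 100 kb window, and a 10 kb step gives a
smoothly overlapping grid. Windows holding fewer than `min_variants`
(default 3) variants are *missing* (`NA`), never zero -- a window with no
data carries no evidence of absence of signal.

**Smoothing.** A LOESS curve (degree 1, span 0.3 per chromosome, direct
surface so constants are reproduced exactly) is fitted to the non-missing
window means and evaluated at the same centers. Span and degree are design
choices; span 0.3 keeps a 10 Mb chromosome's smoother bandwidth near 3 Mb,
wide enough to suppress window-level noise without flattening a QTL peak.
Chromosomes with fewer than 10 non-missing windows skip smoothing (the raw
means are used) because a local regression on so few points is not
meaningful.

**Threshold** (`null_threshold`). The published description of the
threshold ("LOESS regression ... p-value <= 0.01") is ambiguous between a
LOESS-residual quantile and a simulated confidence band. The package
implements the simulated reading, in the style of QTL-seq confidence
intervals: under the no-QTL null both bulks' allele frequencies are 1/2, so
at each retained variant both bulks' alt counts are redrawn as
Binomial(observed depth, 1/2), the window-mean delta is recomputed on the
identical grid, and the per-window threshold is the `confidence` quantile
(default 0.99) of |window mean| over `null_reps` replicates (default
10000). The raw quantile track is then LOESS-smoothed with the same
settings as the observed track. This null conditions on the observed
depths, so deeper regions automatically get tighter thresholds; it does
*not* model bulk-composition noise (the finite-sample drift of the true
pooled frequency around 1/2), which is why genome-wide false-positive
control is checked empirically (below) rather than assumed.

**Region calling** (`call_regions`). Maximal runs of consecutive
non-missing windows with |smoothed delta| above the threshold become
regions spanning the outermost window edges; runs separated by exactly one
*missing* window are merged (a single data gap should not split a peak),
while a below-threshold window with data always separates. Both signs are
called, since the trait allele may come from either parent, and the sign is
reported. Sizes are reported as `(end - start) / 1e6` rounded to two
decimals at the reporting layer only; raw bp are kept.

SNPs and small indels are scanned separately by default (`by_type = TRUE`),
matching the field's habit of reporting SNP-index and indel-index regions
side by side; a combined scan is a flag away.

## Annotation and the conjunctive step

`genes_in_regions()` assigns gene models to regions by the any-overlap
rule: one shared base pair suffices. The published analysis does not state
whether genes had to be contained; since the real annotation is not
reproducible here either way, the permissive rule was chosen once and is
stated in the output. A gene overlapping two regions counts once in the
de-duplicated candidate set and once per region in the per-region tallies,
so per-region counts can sum to more than the set size. The conjunctive
step (`conjunctive_intersect`) is a plain set intersection of the DNA- and
RNA-derived candidate gene sets, stable-sorted, with the regions of origin
attached -- this is the step that pins a shared candidate gene in a
two-assay design.

## Differential expression between bulks

Each bulk is one pooled library, so there are no replicates and no
within-group dispersion estimate. Following the fixed-dispersion
convention for such designs, the test is an **exact conditional NB test**:
under the null both counts share one NB mean with dispersion $\phi = 0.1$;
conditioning on the sum $s = a + b$ removes the mean (the conditional law
is the negative hypergeometric with shape $1/\phi$ on each side), and the
two-sided p-value sums the conditional probabilities of all splits no more
probable than the observed one. The implementation evaluates the
conditional through `dnbinom`; the test suite checks it to 1e-12 against an
independent combinatorial enumeration for every split with $a + b \le 50$.

Library sizes are normalized by simple total-count scaling to the geometric
mean (TMM is deliberately out of scope); log2 fold changes use a 0.5
pseudo-count on the normalized means to avoid infinities (the source
analysis does not state its pseudo-count; 0.5 is the common choice). FDR is
Benjamini-Hochberg, implemented directly (step-up with enforced
monotonicity) and cross-checked against `stats::p.adjust` and a loop-based
oracle. Calls use `log2fc >= 1` inclusive and `fdr < 0.05` strict, exactly
as printed in the motivating study; positive log2fc means higher in bulk A
(the trait bulk).

**A saturation property worth knowing.** With $\phi$ fixed at 0.1, the
conditional law of $x/s$ tends to Beta$(10, 10)$ as counts grow, so a
4-fold change ($|$log2FC$| = 2$) can never achieve a p-value much below
$\approx 0.006$, no matter how deep the sequencing. Whether such genes
survive BH at 5% then depends on how many true positives share the ranking:
with 5% of genes DE the BH cutoff sits near 0.0025 and most 4-fold genes
are masked; with 20% DE the cutoff clears 0.006 and power rises above 50%.
The package's power test therefore runs at a 20% DE fraction -- it
documents the sensitivity of the test itself, not a claim that any
particular study design reaches it. The type-I test (no DE genes,
dispersion 0.1, 2000 genes) runs at the defaults and is essentially exact.

`fpkm()` implements fragments per kilobase per million mapped fragments,
$10^9 c / (N \ell)$, and `ddct()` the $2^{-\Delta\Delta C_T}$ rule with a
named reference gene and a calibrator sample/part whose value is 1 by
construction; technical replicates are averaged before any delta.

## The simulator: a stated world

The generator exists so every downstream stage is testable without the
unreleased sequencing data. Its defaults *are* the stated experimental
conditions of the motivating design and are not tuned:

* F2 population of 323 individuals; 50 + 50 phenotype bulks.
* Pooled depth Poisson with mean 75x per bulk (the deep F2 bulks; the
  recovery tests use 30x as their own stated condition), per-read miscall
  0.001 (Q30-grade).
* Marker grid every 50 kb, indel fraction 0.2 (roughly the observed
  indel:SNP ratio), tagged deterministically so the map carries no
  randomness.
* Genetic map uniform at 4 cM/Mb (no published map exists; any positive
  rate exercises the machinery), gametes built marker-to-marker with the
  Haldane map function $r = (1 - e^{-2d/100})/2$.
* Expression: NB with dispersion 0.1, lognormal baselines (median ~150),
  library sizes mirroring the two F2 RNA bulks (62.66M / 52.15M), DE genes
  shifted $\pm$log2FC/2 so the between-bulk ratio is exactly
  $2^{\mathrm{log2fc}}$.

The trait is monogenic in simulation even though the motivating trait is
polygenic; a single causal locus is what recovery tests need to define
ground truth. Penetrance is symmetric misclassification --
$P(\mathrm{trait}\mid\mathrm{susceptible}) = \pi$ and
$P(\mathrm{trait}\mid\mathrm{other}) = 1 - \pi$ -- so $\pi = 0.5$
decouples phenotype from genotype entirely and both bulks drift to allele
frequency 1/2; one-sided incomplete penetrance would instead leave the
recessive bulk fixed, which is not the behaviour the null-drift property
requires.

What the simulator does **not** emulate: read-level errors in sequence
context, mapping bias, multi-allelic sites, structural variation, linkage
between the expression layer and the DNA layer beyond the placement of DE
genes inside or outside the causal region, and polygenic architectures. A
green recovery test therefore establishes that the statistic and its
threshold behave as designed under the sampling model -- not that the
pipeline is robust to alignment artefacts it never sees.

All randomness descends from a single integer seed per design object
(sub-streams are fixed offsets), and the same seed reproduces outputs
bit-for-bit; this determinism is itself under test.

## Numerical and edge-case choices

* Zero-total-depth rows cannot reach `compute_index` (the depth filter
  guarantees depth >= 1); an assertion guards the invariant.
* Quantiles of the Monte-Carlo null use R's default type-7 definition;
  the enumeration oracle in the test suite uses the inverse-CDF
  definition, and the two are compared at a replicate count chosen so the
  discrete quantile resolves (the exact 99% point at depth 10 sits 0.0018
  above a CDF jump, so the empirical CDF needs a standard error well
  under 0.002).
* Ties in the exact test are included with a relative tolerance of 1e-12
  so mathematically symmetric splits are never dropped by floating-point
  jitter.
* `filter_variants` treats `min_depth` as an exclusive bound ("> 5x"
  literally); a site at exactly 5x is removed.
* Chromosome ordering is natural (alphabetic prefix, then embedded
  integer), so `A2` precedes `A10` and scaffolds follow chromosomes.
* Run configuration files are JSON (jsonlite), not YAML: the package keeps
  its dependency set to what a standard Bioconductor installation
  guarantees.
* In the recovery/type-I test geometry (markers every 50 kb, 100 kb
  window) a window can hold at most 2 markers, so those tests set
  `min_variants = 2`; the package default stays 3 for denser variant maps.

## What the tests establish

The suite covers: F2 segregation (1:2:1 by chi-square at n = 10000),
between-chromosome independence, the 2/3 causal-delta expectation (averaged
over 200 simulated experiments; the single-run sd of ~0.06 makes a
one-draw check meaningless), exact round-trips of the VCF/GFF3/TSV
formats, order-invariance of the scan, enumeration oracles for the exact
test, BH, and the null quantile, and two 20-seed properties: a recessive
locus at 30x with 50+50 bulks is recovered in >= 90% of runs, and a
no-locus world calls zero regions in >= 95% of runs at 99% confidence.
Monte-Carlo replicate counts inside tests are scaled (2000 for the 20-seed
properties) to keep the suite around a minute; the package defaults are
unchanged.

## Limitations

Fixed-dispersion testing understates uncertainty when real biological
replicates exist -- with replicates, use a dispersion-estimating framework
instead. The simulated null threshold conditions on depth but not on bulk
composition, so at very low depth with small bulks the genome-wide
false-positive rate can exceed the nominal level; the 20-seed type-I
property documents the operating point. Region boundaries are window edges,
so localization is limited by `window_size`, and on short, strongly linked
chromosomes a single QTL legitimately lifts the whole chromosome above the
threshold.
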