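---
title: "Models and methods behind irscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind irscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irscreen)
```

# The measurement model

A splicing-reporter screen couples a pooled knockout library to a
minigene whose splicing outcome is sequenced directly. The reporter
modeled here is a three-part minigene — a 161 nt upstream exon, a
1,943 nt intron and a 163 nt downstream exon — transcribed from an
inducible promoter. After reverse transcription and amplification, each
sequenced fragment yields a read pair: read 1 (210 cycles) starts with a
10 nt UMI and then crosses the junction that diagnoses the outcome
(exon–exon if the intron was spliced, exon–intron if it was retained);
read 2 (85 cycles) contains the guide that identifies the perturbation.

Outcome classification is by junction *k*-mer: the last *k*/2 nt of
exon 2 concatenated with the first *k*/2 nt of exon 3 (EE) or of the
intron (IE), with *k* = 20 by default. The reporter generator resamples
until both *k*-mers are unique within their transcripts and absent from
the other isoform, so exact matching is unambiguous; reads matching both
or neither are discarded as unassigned. Matching is exact by default
(`max_mismatch = 0`), which keeps the pipeline deterministic; a
substitution-tolerant mode is available for noisier data. UMI
deduplication is exact-match on the `(guide, UMI)` key — no 1-edit
clustering — which is the simplest contract consistent with collapsing
PCR duplicates and is a documented limitation for error-rich libraries.
A key carrying conflicting outcomes is resolved by majority vote, and an
exact tie drops the key: a conflicted molecule is evidence of template
switching or index hopping and should not vote either way.

# Screen statistics

Per guide and replicate, with IE and EE the deduplicated molecule
counts:

$$\mathrm{PIR} = 100\cdot\frac{IE}{IE+EE},\qquad
  \Delta\mathrm{PIR} = \mathrm{PIR}_{guide}-\mathrm{PIR}_{intergenic}.$$

Guides with fewer than 10 molecules are excluded before any statistic is
computed. The baseline $\mathrm{PIR}_{intergenic}$ aggregates the
intergenic/non-targeting controls of the same replicate; the default is
the **median** (robust to controls with dropout-depressed counts), with
`mean` and count-weighted `pooled` alternatives selectable.

The significance threshold is an empirical-null exceedance rate, not a
Benjamini–Hochberg procedure: the lower-tail threshold at FDR $q$ is the
order statistic at index $\lceil qn\rceil$ of the $n$ sorted control
$\Delta$PIRs, so that at most $qn$ controls fall **strictly** below it.
Ties at the threshold never count as exceeding. Thresholds are computed
per replicate and per cell line; a guide's replicate deltas are never
averaged before thresholding, because the gene rule below demands
per-replicate evidence.

A gene (or gene-pair construct) is a hit when all three hold in *every*
technical replicate, plus the expression gate:

* expression at least 0.1 FPKM (for a pair construct, the *minimum* of
  the two genes' FPKM — a conservative choice, since a construct cannot
  act through an unexpressed partner);
* at least 2 guides strictly beyond the threshold;
* at least 50% of the guides with data beyond the threshold.

With the default four guides per gene the last two criteria coincide,
but they are checked independently so that guide dropout behaves
sensibly. Direction consistency is inherent to the one-tailed
qualification: hits are suppressors or promoters, never a mixture. Genes
reached only through a hit pair construct are appended to the
single-gene hit list flagged `from_pair`; a gene hit both ways keeps its
single-gene evidence, and a gene hit through several pairs keeps the
pair with the stronger $|\overline{\Delta\mathrm{PIR}}|$. Hits are
ranked by the average $\Delta$PIR across cell lines, ascending, ties
broken alphabetically.

Cross-cell-line overlap uses Fisher's exact test on the 2×2 membership
table over a gene universe (default: genes with data in both lines).
The reported odds ratio is the sample OR $(both\cdot neither)/(a\cdot
b)$ — the common convention for screen overlap statements — rather than
the conditional MLE. The two-sided p sums hypergeometric outcome
probabilities not exceeding the observed one (with the conventional
$1+10^{-7}$ relative slack against floating-point ties). The p-value is
computed over the whole hypergeometric support at once, which makes
exhaustive verification sweeps cheap; the test suite checks it against
`stats::fisher.test` and against an independent combination-counting
enumeration for every 2×2 table with universe up to 60.

# What the screen generator emulates

The generator's defaults are the study conditions of the screen design
it mirrors: four guides per gene or gene pair, ~500 intergenic and
non-targeting controls, a baseline PIR of 90 (the reporter's retention
is deliberately high, so the screen is sensitive to retention
*promoters* — effects pushing PIR down), two technical replicates, a
210/85-cycle paired layout and 10 nt UMIs.

Choices the design left open, fixed here once:

* **Molecule counts** per guide are negative binomial (mean 500, size
  10 — moderate library-representation overdispersion).
* **Outcomes** are Bernoulli per molecule with
  $p_g=\mathrm{clamp}(\mathrm{baseline}+\Delta\mathrm{PIR}_{true},0,100)/100$;
  pair constructs add the effects of their two genes.
* **PCR duplication** is a per-molecule geometric copy count with mean
  `duplication_rate`; copies share the UMI. Replicates are independent
  library preparations.
* **Read-1 layout**: UMI first, then a segment beginning a fixed 100 nt
  upstream of the exon 2 3′ end, so the junction sits mid-read. The
  guide sits at a fixed offset 25 in read 2.
* **FPKM** is log-normal (median 30), so at defaults essentially every
  gene clears the 0.1 FPKM gate and expression filtering only bites when
  configured to.

`simulate_guide_counts()` is the exact count-level marginalization of
the molecule-level generator (negative-binomial totals, binomial IE) and
is used for large calibration simulations; the molecule/FASTQ path
exercises the full readout. What the generator does **not** emulate:
sequencing errors, guide-level off-target structure, chimeric reads,
cell-barcode demultiplexing, or fitness effects coupling guide abundance
to phenotype. Passing tests therefore certify the statistics and the
readout contract, not robustness to those artifacts.

## Calibration check

On an all-null screen, the fraction of targeting guides strictly beyond
the 10% lower-tail threshold should sit near 0.10. Two binomial noise
sources enter: the targeting guides' own sampling (800 guides) *and* the
threshold, an empirical quantile of 500 controls. The calibration test
therefore bounds the fraction by
$0.10 + 3\sqrt{q(1-q)(1/n_{target}+1/n_{controls})}$ — the SE of the
difference of two empirical exceedance rates. A bound using only the
targeting term is measurably too tight: the threshold-estimation noise
(≈1.3 points at these sizes) exceeds the targeting noise (≈1.1).

# Intron-level IR ratios

For an annotated intron, $\mathrm{IR} = I/(I+E)$ with $I$ and $E$ the
supplied intronic and exonic abundances; a zero denominator is an
explicit *undefined* marker, never 0. The standard detection filter
retains introns with IR ≥ 0.05 (inclusive) in at least one sample;
undefined ratios never qualify. This module consumes abundance tables —
it does not re-implement alignment, mappability masking or
transcript-model-aware exonic counting, because the quantity of interest
is the ratio and its filter, not the aligner.

Differential retention between two conditions reports the difference of
mean ratios and a two-sided Fisher's exact test on the pooled, rounded
$(I, E)$ counts. This is an explicit substitute for a model-based
(negative-binomial) differential test, and every output row carries
`test = "fisher_pooled"` so downstream users cannot mistake it for one:
pooled-count Fisher ignores biological replicate dispersion and will be
anticonservative for overdispersed data.

Interval arithmetic is 0-based half-open throughout; BED files are read
natively (via `rtracklayer`) and converted at the boundary. An intron is
*bound* when a CLIP peak overlaps it by at least `min_overlap_bp`
(`overlap = max(0, min(end) − max(start))`, so abutting intervals never
overlap). Strand checking defaults off — processed peak files are often
effectively unstranded — behind a flag. Polypyrimidine-tract strength is
the C/T(U) fraction of the 20 nt immediately upstream of the 3′ splice
site on the sense strand; purine-interrupted (low-scoring) tracts are
weak U2AF2 substrates.

# RNA-FISH speckle quantification

Per cell image stack (channels DAPI, SON, FISH):

1. **Nuclei**: Gaussian smooth the DAPI channel (σ = 2 px), global Otsu
   threshold, fill holes, drop components under `min_area` or touching
   the border. Manual ImageJ-style thresholding is replaced by Otsu
   because it is deterministic and parameter-light; σ and `min_area` are
   exposed.
2. **Speckles**: per nucleus, Otsu on that nucleus's SON pixels,
   intersected with the nucleus — the speckle mask is a subset of the
   nuclei by construction. A small histogram Otsu is implemented for
   pixel subsets and cross-checked against `EBImage::otsu` on full
   images.
3. **Ratio**: mean FISH over the speckle pixels divided by mean FISH
   over nucleus-minus-speckles. Means, not integrated intensities, so
   the ratio is independent of mask areas and of any positive rescaling
   of the channel; an undefined marker results when either pixel set is
   empty. No nucleolar exclusion is applied to the nucleoplasm
   denominator.
4. **Positivity and pattern**: a cell is FISH-positive when its nuclear
   mean exceeds the non-nucleus background mean by more than
   `positivity_k` (default 3) background SDs; only positive cells are
   classified and counted. Among them, ratio ≥ `ratio_cutoff` (default
   1.5) is "Speckle", otherwise "Diffused". The cutoff operationalizes
   what is normally a by-eye call and is a tunable, not a measured
   constant; at the simulator's conditions the two classes sit near
   ratios 3 and 1, far from it on either side.

The image generator draws one elliptical nucleus per cell (axis ratio
0.8) with speckle disks placed wholly inside it, constant channel
baselines plus Gaussian noise, and a configurable FISH speckle
enrichment; "Diffused" cells get uniform nuclear FISH. It does not model
z-stacks, uneven illumination, touching nuclei or nucleoli — the
segmentation is validated on geometry the assumptions fit, and real
micrographs will need the exposed knobs.

# Numerical and interface choices

* Coordinates: 0-based half-open internally; 1-based conversion only at
  the `GRanges`/BED boundary.
* The empirical threshold uses a plain order statistic (no
  interpolation): with 500 controls the difference from interpolated
  quantiles is below the binomial noise, and the order-statistic form
  makes the "at most $qn$ controls exceed" guarantee exact.
* All generators are deterministic given their seed, and FASTQ/TIFF
  emission is byte-identical across runs with the same seed.
* Simulation sizes in the test suite (200 genes × 4 guides, 500
  controls, ~500 molecules per guide, 20 seeds for calibration; 50-cell
  image cohorts) are the package's desk-scale rendering of the screen's
  statistical regime: large enough that the binomial and quantile
  asymptotics the thresholds rely on are in force, small enough to run
  routinely.
* Fisher's p is computed in-package (summation over the support, as
  described) and verified against `stats::fisher.test`; the sample OR
  convention and the `fisher_pooled` tag are recorded in outputs where
  relevant.

# Known limitations

Exact-match UMI collapsing slightly undercounts molecules at high
sequencing-error rates; the pooled-count differential IR test is not a
replicate-aware model; the positivity gate and `ratio_cutoff` are
operational definitions that should be re-examined against pilot images
for a new probe or cell line; and the hit rule treats replicates as
exchangeable technical replicates — biological replicates would warrant
a hierarchical treatment this package does not attempt.
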