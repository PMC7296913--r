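---
title: "Methods: differential H2Aub1 analysis and Polycomb mark classification"
author: "h2aubDiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential H2Aub1 analysis and Polycomb mark classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

`h2aubDiff` implements the downstream analysis used to study the interplay
of H2A monoubiquitination (H2Aub1, deposited by PRC1), H3K27 trimethylation
(H3K27me3, deposited by PRC2), the H3K27me3 demethylase REF6, and the
deubiquitinases UBP12/13 in *Arabidopsis*. Its inputs are already-processed
sequencing artifacts — fragment intervals per ChIP replicate, peak calls,
differential-expression tables, responsiveness scores — and its outputs are
the derived biology: coverage-scaled enrichment, differential H2Aub1 and
H3K27me3 peaks between a mutant and wild type, deubiquitinase target genes,
per-gene mark categories and PRC1-dependency classes, CTCTGYTY motif
clusters, and REF6~H2Aub1 co-enrichment regressions. Read processing,
alignment, peak calling (MACS2) and DE model fitting (DESeq2) are upstream
of this package and out of scope.

## Coverage-scaled fragment counts

All quantification uses one scaling rule. For a region (a 50-bp genome bin,
or a derived gene region), the scaled count is

$$\mathrm{scaled} = \frac{\text{fragments overlapping the region} + 1}
                         {\text{library total base coverage} / 10^9}.$$

Scaling by the summed fragment *bases* rather than the fragment count keeps
libraries with different fragment lengths comparable; the pseudocount keeps
every value positive so log-scale analysis is always defined. A fragment is
counted once in every bin it overlaps (coverage semantics, not midpoint
assignment). Replicates are scaled first and averaged afterwards, and
mutant − wild-type differentials are taken only on replicate-averaged
values. Derived gene regions are strand-aware: the "first 1 kb" of a
minus-strand gene is measured from its high-coordinate end, genes shorter
than 1 kb contribute their whole body, and the 20% regions use
`floor(width * 0.2)` bp (deterministic integer arithmetic).

## The M-A differential enrichment model

Differential peaks between mutant and wild type are called with an
MAnorm-style model, reimplemented here:

1. Peak calls of the two samples are merged into one catalogue; a catalogue
   peak is *common* if it overlaps peaks of both samples (>= 1 bp),
   otherwise unique to one sample.
2. Fragments are reduced to single positions (the 5' end shifted by half
   the fragment length, i.e. the midpoint) and counted in a 1000-bp window
   centred on each catalogue peak's midpoint.
3. With pseudocount 0.5, $M = \log_2\frac{a + 0.5}{b + 0.5}$ and
   $A = \tfrac12 \log_2\left[(a + 0.5)(b + 0.5)\right]$.
4. A robust line $M = \alpha + \beta A$ is fitted on the *common* peaks
   (Huber-weighted IRLS, $k = 1.345$ on the MAD scale, at most 50
   iterations, tolerance $10^{-8}$), under the assumption that common peaks
   are on average equally enriched. A bootstrap (100 resamples, median
   coefficients) stabilizes the fit; the resample count is exposed as the
   `nSimulations` parameter.
5. $M_{norm} = M - (\alpha + \beta A)$; rescaled counts are back-solved
   from $(M_{norm}, A)$ and a two-sided exact binomial test of the rounded
   split against equal probability gives the p-value. Peaks pass at
   `p < 0.05` and `|M_norm| > 0` (both configurable).

Only peaks significant in *both* replicate comparisons with the same
direction, overlapping by >= 1 bp, are kept ("real" differential peaks);
concordant peaks are merged by union so the merged peak can span both
replicate calls. Significance is filtered per replicate comparison first
and concordance required afterwards. Target genes are protein-coding genes
whose first 1 kb overlaps a concordant peak of H2Aub1 *increase*, minus any
gene whose first 1 kb also overlaps a peak of decrease.

Because the test conditions on the within-window total, the model is
exactly calibrated under a Poisson null (a Poisson split is binomial), which
the type-I acceptance check exploits. The exact test is slightly
conservative for small windows due to discreteness.

## Mark classification

A gene carries a mark iff at least one replicate-concordant peak overlaps
the first 1 kb of its body (binary presence; magnitude never enters).
The four categories — `not_marked`, `h2aub_only`, `both`, `k27_only` —
partition the universe. H3K27me3-marked genes whose first 1 kb overlaps a
concordant *decreased*-H3K27me3 peak in a PRC1 mutant are PRC1-dependent;
other marked genes are PRC1-independent; unmarked genes are `non_k27`
regardless of peak overlap.

## Motifs and REF6

CTCTGYTY (Y = C/T) is scanned on both strands (reverse-complement hits are
reported on the minus strand at their own coordinates; `N` never matches).
A motif *cluster* is a maximal run of >= 4 hits whose first-to-last extent
fits in 600 bp; overlapping cluster intervals are merged and recounted. The
window criterion slides per motif (maximal-run convention) rather than
tiling the genome — the coarser tiling convention would miss runs straddling
tile boundaries. Motif membership in peaks and windows is judged by the
motif's leftmost coordinate, an unambiguous convention for 8-mers at
boundaries.

The windowed co-enrichment analysis builds one record per 50-bp bin:
scaled H2Aub1, scaled REF6, and the number of motif starts in the 600-bp
window centred on the bin centre. Ordinary least squares of
$\log_{10}(\mathrm{REF6})$ on $\log_{10}(\mathrm{H2Aub1})$ is fitted within
motif-count strata (0, 1, 2, 3, 4, 5+), or pooled.

## Statistics

* Gene-set overlap: fold over the chance expectation $|A||B|/N$ with an
  upper-tail hypergeometric p.
* Mann-Whitney U, two-sided, exact by enumeration for tie-free samples
  with $n_x + n_y \le 12$, otherwise normal approximation with continuity
  and tie correction.
* Up/down asymmetry: one-degree Pearson chi-square against an equal split.
* Bonferroni with a *fixed, caller-specified* family size (default
  $m = 6$, the number of pairwise comparisons among four groups).
* Expression by mark: additive two-factor linear model
  `expression ~ h2aub + k27` (no interaction) on the fpkm scale; estimated
  marginal means average the two levels of the other factor with equal
  weight (the standard EMM definition — the weighting convention was an
  open choice and equal weights were adopted). Post hoc pairwise cell
  contrasts are Bonferroni-corrected with the same fixed family size.
* DE filtering: `|log2FC| >= 1` and adjusted `p < 0.05` plus a CPM flag;
  externally produced tables analysed at `|log2FC| >= 4` keep that cutoff
  via the `lfcCutoff` parameter.

# The synthetic study generator

`generateStudy()` produces a miniature study with known ground truth for
every downstream stage. Defaults define the package's reference
conditions: two 400-kb chromosomes; 200 non-overlapping genes (1–3 kb)
placed in equal slots; mark categories at 10% H2Aub1-only, 7% both, 18%
H3K27me3-only; two ChIP replicates per antibody and genotype plus one flat
H3 control per genotype; fragment length 200 bp; background fragment-start
rate 0.02/bp; enrichment fold 8; 20 planted targets; 3 planted H2Aub1-loss
genes; motif density 0.5/kb with 3 planted clusters.

Fragment placement is homogeneous Poisson background plus per-region
Poisson enrichment over the first kilobase of marked genes, with
gene-to-gene enrichment variation (log-normal, sd 0.75 in log2) — real
peaks vary in strength, and this variation is what makes the intercept and
slope of the M~A normalization line jointly identifiable. Planted targets
are drawn from genes *without* wild-type H2Aub1 (a gene gaining the mark is
one not already saturated with it), with about three quarters carrying
H3K27me3, as expected for PRC2-associated deubiquitinase targets; their
first-kilobase H2Aub1 rate in the mutant is exactly `enrichment_fold` times
the wild-type rate, and K27-marked targets lose their H3K27me3 enrichment
there. Peaks are emitted per replicate with jittered boundaries (Gaussian,
sd 30 bp) so concordance logic is genuinely exercised. REF6 libraries
follow per-bin rates $10^{c + s\,\log_{10}(\text{local H2Aub1 rate})}$
with the genotype-specific H2Aub1 rate model, so genes gaining H2Aub1 also
gain REF6. The DE table plants upregulation (+2 log2) at targets plus a
roughly 3:1 up/down asymmetry among non-targets, with adjusted p-values
from a z-test on three simulated Poisson replicates per genotype;
responsiveness scores are Poisson with a +40 mean shift for H2Aub1-marked
genes.

For the log-log slope recovery, `simulateRef6Coupling()` is a dedicated
fixture: one 2.5-Mb chromosome of 1-kb constant-rate blocks whose H2Aub1
rate is log10-normal (mean $10^{-0.4}$/bp, sd 0.4), REF6 following the
planted slope exactly, and motifs placed independently of both rates so
motif strata share the slope. Block-level variation keeps per-bin Poisson
noise small relative to the planted signal; with bin-level variation,
errors-in-variables attenuation would bias the recovered slope well below
the planted value. The residual attenuation from counting noise and the +1
pseudocount is about 0.01–0.015 at these rates, within the ±0.05 recovery
band.

What the generator does *not* emulate: mappability and GC structure,
fragment-length variation, peak-shape heterogeneity, chromatin-state
autocorrelation beyond the planted blocks, and biological replicate
overdispersion. Passing recovery tests therefore demonstrates correctness
of the computational pipeline under its stated model, not performance on
real chromatin.

# Numerical and design choices

* **Coordinates.** All in-memory intervals are `GRanges` (1-based,
  closed), the idiom of the Bioconductor stack this package builds on; BED
  (0-based, half-open) and GFF3 conversions happen at the I/O boundary via
  `rtracklayer`. A single internal convention avoids off-by-one drift.
* **"Merged" concordant peaks are unions**, not intersections, so a merged
  differential peak can span both replicate calls.
* **Degenerate fits.** An exact linear fit (zero residual scale)
  short-circuits the Huber iteration; a constant-response regression
  returns slope 0 with $R^2 = 0$; strata with fewer than 3 records or zero
  predictor variance are errors.
* **Ties and zeros.** The 0.5 pseudocount in M/A guards zero counts; the
  +1 in coverage scaling guards empty bins; identical tied samples in the
  Mann-Whitney test return p = 1.
* **Annotation multiplicity.** A peak overlapping several genes'
  first-kilobase regions annotates to all of them; no disambiguation
  policy is applied.
* **Determinism.** The generator seeds the RNG from its config and
  restores the caller's RNG state; the pipeline's only stochastic step
  (the normalization bootstrap) is seeded from the pipeline config, so
  identical inputs and seed give byte-identical outputs.

## Problem sizes

The test-suite fixtures use a 200-kb single-chromosome study with 40 genes
for module-level checks and the 200-gene reference study for recovery
checks; the slope-recovery fixture uses 50,000 bins (2.5 Mb). These sizes
give comfortable Monte-Carlo margins for every planted effect while keeping
the suite quick to run.

# Limitations

* The M-A normalization assumes common peaks are, on average, equally
  enriched; a genuine global shift between conditions is absorbed into the
  intercept and read as the normalization factor, not as biology.
* With common peaks spanning a narrow intensity range the normalization
  line's slope is poorly identified; the generator plants per-gene
  enrichment variation for this reason, and real analyses should check the
  A-range of common peaks.
* The exact binomial test is conservative for low-count windows.
* Presence calls are binary peak overlaps; borderline enrichment below the
  peak caller's threshold is invisible to the categorization.
* Designs with more than two replicate comparisons are reduced by
  consecutive pairwise concordance.
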