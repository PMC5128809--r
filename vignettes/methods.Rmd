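---
title: "Methods: competitive recruitment and pan-genome analysis of cryptic sister genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: competitive recruitment and pan-genome analysis of cryptic sister genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panrecruit)
```

## The problem

Some of the most abundant marine picoeukaryotes exist as pairs of cryptic
sister species: genomes divergent enough to behave as separate gene pools
(orthologous genes only ~78% identical) yet carrying *identical* rRNA marker
sequences, so amplicon metabarcoding cannot tell them apart. Whole-metagenome
shotgun reads can, provided the analysis keeps only signal that is specific
to one genome. `panrecruit` implements that analysis as a reusable pipeline:

1. **Competitive recruitment** — map each read against both reference
   genomes and keep only reads that clearly prefer one of them.
2. **Abundance** — turn genome-specific read counts into relative genomic
   abundances and per-sample dominance classes.
3. **Orthology** — identify ortholog pairs, flag near-identical conserved
   genes (which must be masked), and summarize collinearity.
4. **Pan-genome** — find dispensable genes and the contiguous cassettes they
   form, quantify sub-population coverage depletion, and check that cassette
   breakpoints coincide across samples.
5. **Niche statistics** — relate the two genomes' abundances to
   environmental covariates.

Because the real survey data are tens of millions of reads across >100
ocean stations, the package ships a synthetic-study generator that emulates
the relevant structure at desk scale with complete ground truth, and every
stage is validated against that truth.

## Competitive recruitment

Reads are mapped with a seed-and-extend mapper: exact k-mers (default
`k = 15`) nominate candidate loci on either strand, and every candidate is
scored by gapless full-length comparison; identity is
$100 \times \mathrm{matches} / \mathrm{columns}$. A read is *mapped* when its
best identity reaches `min_identity` (default 95%), and *specific* to a
genome when that identity beats the best placement on the other genome by at
least `specificity_margin` identity points (default 3). Reads that map well
to both genomes — conserved genes, rRNA-like regions — are *ambiguous* and
contribute to neither genome. The four outcomes (specific-to-A,
specific-to-B, ambiguous, unmapped) partition every read set.

Two deliberate simplifications. The mapper is gapless: the simulator's
divergence model is substitution-only, and gapless scoring makes the mapper
*provably* equivalent to exhaustive all-position alignment at the defaults —
with 60-bp reads, any placement at ≥95% identity has at most 3 mismatches,
which cannot destroy all 46 15-mer seed windows. The validation suite checks
this equivalence read by read against a brute-force scorer
(`validate_mapper_oracle()`). Second, within-genome multi-mapping keeps the
single best locus, with deterministic ties (lowest chromosome, lowest start,
forward strand): the two reference genomes are the object of interest, not
internal repeats.

At ~78% nucleotide identity the margin rule separates the genomes cleanly: a
100-bp read from a diverged region places on the wrong genome far below the
95% floor, while reads from planted >99%-identity conserved genes differ by
under 3 points between genomes and are flagged ambiguous >99% of the time
(`validate_specificity()`).

## Abundance and dominance

The relative genomic abundance of genome $g$ in sample $s$ is

$$A_{g,s} = 100 \times \frac{N^{\mathrm{spec}}_{g,s} - N^{\mathrm{cons}}_{g,s}}
{N^{\mathrm{total}}_s} \times \frac{L_g}{L_g - L^{\mathrm{cons}}_g}$$

where $N^{\mathrm{spec}}$ counts genome-specific reads (genic plus
intergenic; a genic-only mode exists), $N^{\mathrm{cons}}$ removes reads
assigned to masked conserved genes, and the final factor rescales for the
masked fraction of the genome so that masking does not bias the estimate
(configurable off via `mask_correct = FALSE`). Reads are assigned to the
gene containing their start position — every read counted exactly once,
deterministically.

Per-sample dominance follows the survey's printed rules, all housed in
`threshold_config()`: a sample is below the detection floor when the two
genomes together do not exceed 0.01% of its reads (strict); one genome is
dominant when it takes more than 70% (strict) of their summed specific
reads; the genomes co-occur when both shares lie in [40%, 60%] (inclusive).
Share patterns covered by neither printed rule (e.g. 65/35) get an explicit
`mixed` class rather than being forced into one of the others.

Gene detection — the basis of the pan-genome stage — requires at least 2
specific reads *and* at least 20% of the gene length covered. The rule is
deliberately conservative in both directions: at ≥5× coverage a 900-bp gene
is detected with probability ~1, while a truly absent gene needs two
independent false mappings landing on it.

## Orthology, conserved genes, synteny

Ortholog pairs are reciprocal best hits over all-vs-all gene comparisons: a
shared-k-mer prefilter (k = 12, ≥3 shared) nominates candidates, which are
aligned globally (match +1, mismatch −1, gap −2; identity =
matches/columns). Identity is computed on nucleotide gene sequences — the
simulator is nucleotide-level, and one identity arithmetic serves generator,
mapper and orthology alike; published protein-level identity figures are
therefore descriptive context here, not targets. Pairs above 99% identity
(strict) form the conserved-gene mask consumed by the abundance and
pan-genome stages.

Synteny blocks chain pairs that are rank-adjacent on both genomes (at most
one intervening gene on either side, consistent orientation) within one
chromosome pair; blocks need ≥3 genes. A relocated gene is a different
chromosome pair — or a rank outlier within the same one — so it lands
outside blocks without fragmenting its host chain; when two predecessors
could extend a chain, the longer block wins. Each genome's genes then split
into collinear (in blocks), shared outside blocks, and genome-specific
fractions summing to one; on a simulated pair with 5% translocated and 5%
genome-specific genes the summary recovers 90/5/5 within two points.

## Pan-genome: dispensable genes, cassettes, depletion, borders

The dispensable-gene filter chain mirrors the survey design. Only samples
where at least `completeness_min` of a genome's (non-conserved) genes are
detected are *eligible* — this gate removes shallow samples whose
non-detections are coverage artifacts. A gene is dispensable when it is
detected in ≥4 eligible samples, undetected in ≥5, and shows an expression
signal in ≥6 samples. The expression filter consumes a boolean per-gene,
per-sample signal; the continuous activity value feeds only the
dispensable-vs-core contrast (group means plus a two-sided
Mann–Whitney–Wilcoxon test), keeping the filter and the descriptive
statistic separate. Whether the six expression samples must themselves be
eligible is not constrained; the package counts them over all samples with
expression data (the eligibility gate exists to protect *absence* calls,
which expression does not make).

Maximal runs of rank-adjacent dispensable genes form cassettes (≥2 genes;
isolated calls are reported as singletons). Two coverage-level analyses
probe population structure beneath presence/absence:

* **Depletion.** A gene's depletion ratio is its mean depth over the median
  mean-depth of non-dispensable genes on the same chromosome in the same
  sample (≥5 baseline genes with signal required, otherwise the state is
  `undefined`). Ratios ≤0.1 mean absent, ≥0.8 present, in between
  `partial` — the signature of a cassette carried by only part of the
  population. The thresholds leave a wide partial band because the quantity
  of interest (carrier frequency) varies continuously.
* **Borders.** For samples lacking a cassette, the two breakpoints are
  estimated as the window boundary with the largest depth change within
  ±1000 bp of each annotated edge on a 200-bp windowed depth track, and
  compared across samples. A simple maximal-difference change point is
  enough at this scale — the depth falls from baseline to ~0 within one
  read length of the true edge — so no HMM or segmentation machinery is
  used. Estimates that agree across oceans to within a window indicate a
  single ancestral loss breakpoint.

Long dispensable blocks at the end of the outlier chromosome are ordinary
cassettes to the algorithm; no special-casing.

## Niche statistics

Group comparisons use a two-sided Mann–Whitney–Wilcoxon test: exact when
the pooled sample size is ≤16 without ties, otherwise the normal
approximation with tie and continuity corrections (delegated to
`stats::wilcox.test`; an independent complete-enumeration oracle verifies
both the exact branch and, in the validation suite, the type-I error rate).
`niche_summary()` contrasts samples where genome A dominates against those
where genome B dominates — co-occurring, mixed and below-floor samples are
excluded — reporting per-parameter means, ranges, raw p-values and
Benjamini–Hochberg-adjusted values alongside (the adjustment is reported,
not substituted). PCA standardizes each parameter and decomposes the
correlation matrix; rows with missing values are dropped with a count,
zero-variance parameters with a warning, and each component's sign is fixed
so its largest-magnitude loading is positive, making results reproducible
to the sign. Metabarcode concordance correlates amplicon counts with the
*sum* of the two genomic abundances, since the marker cannot separate the
genomes.

## The synthetic study and what it does (not) show

`simulate_genome_pair()` builds genome A as random sequence — regular
chromosomes at GC 0.48, one outlier chromosome at 0.44 with genes half as
long — and derives genome B by i.i.d. per-site substitution at rate
$1 - \mathrm{target}$ (default target 0.78). Conserved genes are substituted
at 0.002 so they sit clearly above the strict >99% mask threshold; they are
planted on regular chromosomes, matching the biology of outlier chromosomes
whose genes are atypical and non-conserved. Genes are single-exon with
uniform intergenic spacing, and the divergence model has no indels — intron
structure and indel handling exercise nothing in this analysis, and the
substitution-only model keeps identity arithmetic exact for the oracles.
Optional fractions of translocated and genome-specific genes exercise the
synteny summary.

Stations carry a latent ecotype (balanced), with type-B stations 3 °C warmer
on average (18.4 vs 21.4 °C, sd 2 — the thermal niche contrast the analysis
must recover). The genome-B share of each sample is a logistic link of the
latent ecotype plus standardized temperature and depth; the ecotype
coefficient dominates by default so that selecting genome-dominant samples
recovers the planted offset instead of an inflated, selection-biased one.
Oxygen falls with temperature, PAR decays with depth, nutrients are richer
in cold water — enough correlation structure for a meaningful PCA. Each
sample's summed two-genome fraction is uniform on [0, 3%] of its reads;
reads are drawn multinomially (genome A / genome B / GC-matched random
background), uniformly within a genome except that cells lacking a cassette
never yield reads overlapping it, with i.i.d. substitution errors (default
1%) and constant placeholder qualities. Every stage emits its ground truth
(ortholog table, conserved and dispensable flags, mixture fractions, read
origins encoded in read names), and identical seeds reproduce byte-identical
FASTA/FASTQ/GFF3/TSV outputs.

What passing these tests shows: the estimators are correct and well
calibrated under the stated model. What they do not show: robustness to
indels and structural variation, within-genome repeats, contamination by
related taxa (background here is random sequence, which is maximally
distinguishable), uneven coverage from library or amplification bias, or
quality-dependent error. Those belong to the mapper-and-QC layer of a real
survey, not to the inference logic validated here.

## Validation scenarios and scale choices

The `validate_*()` family builds each benchmark from scratch and measures
recovery; `scripts/acceptance.R` reports the same numbers as JSON. Problem
sizes are the package's chosen desk scale: two genomes of 4 × 50 kb with 30
genes per chromosome; 30 samples × 100,000 reads for mixture recovery;
14 samples at ~14× genome-A coverage for the dispensable scenario (three
cassettes of 2, 3 and 7 genes, each absent from 6 samples); 50 replicate
samples for depletion at carrier frequency 0.5 over a 20× baseline; 8
samples (6 absent) for border consistency; 200 enumeration instances and
1000 null replicates for the rank test; 100 replicate station series for
niche recovery.

One scaling note: the dispensable scenario sets `completeness_min = 0.85`
instead of the 0.98 default. On real genomes dispensable genes are ~2% of
~6000, so a sample missing a whole cassette still clears 98% completeness;
at desk scale the planted cassettes are 12 of 120 genes (10%), and a 0.98
gate would disqualify exactly the cassette-absent samples the filter needs
to see. The filter thresholds themselves (≥4 detected / ≥5 absent / ≥6
expressed) are the published values and are never altered. Similarly, the
cassette scenarios place cassettes away from planted conserved genes
(`pick_cassette_ranks()`): conserved genes are masked from the pan-genome
analysis by design, so a cassette overlapping one would be unrecoverable for
a reason the estimator cannot see. In that scenario, cassette genes are
expressed in every sample where they are present (`active_fraction = 1`,
consistent with the observation that dispensable genes are the more active
group); the rejection path of the expression filter is exercised separately
by unit tests.

## Numerical conventions and degenerate inputs

Coordinates are 0-based half-open internally; GFF3 export converts to
1-based inclusive. Identity is always matches over alignment columns, in
percent. Threshold comparisons follow the printed wording: dominance share
and the conserved-gene cutoff are strict (`>`), the co-occurrence window,
completeness gate and the three dispensable sample counts are inclusive
(`>=`), the abundance floor excludes equality ("more than"). Unmapped reads
are values, not errors; an empty gene set, a missing totals entry, too few
eligible samples, or an empty contrast group raise errors naming the
shortfall. Zero-baseline depletion is `undefined` and flagged rather than
silently dropped. All randomness flows through R's RNG, so a single
`set.seed()`/seed argument reproduces any object in the package exactly.
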