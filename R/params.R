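#' Recruitment parameters
#'
#' Settings of the competitive read mapper and specificity filter. Two sister
#' genomes at ~78% nucleotide identity are cleanly separable at the defaults:
#' an exact 15-mer seed survives up to three substitutions in a 60-bp read,
#' reads below 95% identity are left unmapped, and a read is genome-specific
#' only when its best identity beats the best placement on the other genome by
#' at least `specificity_margin` identity points.
#'
#' @param k seed k-mer length (11-31).
#' @param min_identity minimum percent identity for a read to count as mapped.
#' @param min_fraction minimum aligned fraction of the read. The mapper is
#'   gapless and full-length, so placements always span the whole read; the
#'   parameter is kept for interface completeness and validated.
#' @param specificity_margin identity-point margin over the competing genome
#'   required to call a read genome-specific.
#' @return A list of class `recruit_params`.
#' @export
recruit_params <- function(k = 15, min_identity = 95, min_fraction = 0.8,
                           specificity_margin = 3) {
  stopifnot(k >= 11, k <= 31, min_identity >= 0, min_identity <= 100,
            min_fraction > 0, min_fraction <= 1, specificity_margin >= 0)
  structure(list(k = as.integer(k), min_identity = min_identity,
                 min_fraction = min_fraction,
                 specificity_margin = specificity_margin),
            class = "recruit_params")
}

#' Threshold configuration for abundance and pan-genome calls
#'
#' Houses every decision threshold of the downstream analysis. The defaults
#' follow the study design this package reproduces: a sample counts a genome
#' as present only above an abundance floor of 0.01% of its reads, a genome is
#' dominant when it takes more than 70% of the two genomes' summed specific
#' reads, the two genomes co-occur when both shares lie in \[40%, 60%\], the
#' pan-genome analysis is restricted to samples where at least 98% of a
#' genome's (non-conserved) genes are detected, and a gene is dispensable when
#' it is detected in at least 4 eligible samples, undetected in at least 5,
#' and carries an expression signal in at least 6 samples.
#'
#' @param abundance_floor percent of total sample reads below which the two
#'   genomes together are called absent.
#' @param dominance_share share of summed specific reads above which one
#'   genome is dominant (strict `>`).
#' @param co_low,co_high share window (inclusive) for co-occurrence.
#' @param completeness_min fraction of genes that must be detected for a
#'   sample to be eligible for pan-genome analysis.
#' @param min_detect_samples,min_absent_samples minimum numbers of eligible
#'   samples in which a dispensable gene is detected / undetected.
#' @param min_expressed_samples minimum number of samples with an expression
#'   signal for a dispensable gene.
#' @param detect_min_reads,detect_min_covered_fraction per-sample detection
#'   rule: a gene is detected when it has at least this many specific reads
#'   and at least this covered fraction of its length. The defaults (2, 0.2)
#'   make a gene at >=5x coverage detected with probability ~1 while an absent
#'   gene needs two independent false mappings.
#' @param depletion_absent_max,depletion_present_min depletion-ratio cutoffs
#'   for calling a gene absent (ratio <= max) or present (ratio >= min) in a
#'   sample; intermediate ratios are "partial" (sub-population presence).
#' @param min_baseline_genes minimum number of non-dispensable genes with
#'   nonzero depth required to compute a chromosome baseline depth.
#' @return A list of class `threshold_config`.
#' @export
threshold_config <- function(abundance_floor = 0.01, dominance_share = 0.70,
                             co_low = 0.40, co_high = 0.60,
                             completeness_min = 0.98,
                             min_detect_samples = 4L, min_absent_samples = 5L,
                             min_expressed_samples = 6L,
                             detect_min_reads = 2L,
                             detect_min_covered_fraction = 0.2,
                             depletion_absent_max = 0.1,
                             depletion_present_min = 0.8,
                             min_baseline_genes = 5L) {
  fr <- c(dominance_share, co_low, co_high, completeness_min,
          detect_min_covered_fraction)
  stopifnot(all(fr >= 0 & fr <= 1), abundance_floor >= 0, co_low < co_high,
            min_detect_samples >= 0, min_absent_samples >= 0,
            min_expressed_samples >= 0, detect_min_reads >= 0,
            depletion_absent_max >= 0,
            depletion_absent_max < depletion_present_min)
  structure(list(abundance_floor = abundance_floor,
                 dominance_share = dominance_share,
                 co_low = co_low, co_high = co_high,
                 completeness_min = completeness_min,
                 min_detect_samples = as.integer(min_detect_samples),
                 min_absent_samples = as.integer(min_absent_samples),
                 min_expressed_samples = as.integer(min_expressed_samples),
                 detect_min_reads = as.integer(detect_min_reads),
                 detect_min_covered_fraction = detect_min_covered_fraction,
                 depletion_absent_max = depletion_absent_max,
                 depletion_present_min = depletion_present_min,
                 min_baseline_genes = as.integer(min_baseline_genes)),
            class = "threshold_config")
}
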