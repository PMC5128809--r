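#' Gene-by-sample read counts, covered fractions and mean depths
#'
#' Consumes genome-specific mapping records only. A read is assigned to the
#' gene containing its start position (half-open interval test); intergenic
#' reads count toward the per-sample genome total but toward no gene. Covered
#' fraction is the union of read intervals clipped to the gene; mean depth is
#' aligned bases over gene length.
#'
#' @param records data frame from [competitive_filter()], with a `sample_id`
#'   column; only rows with `specific == TRUE` and matching `genome_id` are
#'   used.
#' @param genome the `annotated_genome` the records refer to.
#' @param sample_ids sample universe (columns of the matrices); defaults to
#'   the samples present in `records`.
#' @return Object of class `gene_sample_matrix`: matrices `counts`, `covered`
#'   and `depth` (genes x samples, rows in genome gene order) plus
#'   `genome_total`, the per-sample number of specific reads (genic +
#'   intergenic).
#' @export
gene_read_counts <- function(records, genome, sample_ids = NULL) {
  stopifnot(inherits(genome, "annotated_genome"),
            "sample_id" %in% names(records))
  recs <- records[records$specific %in% TRUE &
                    records$genome_id %in% genome$genome_id, , drop = FALSE]
  if (nrow(recs) > 0) {
    bad <- !(recs$chrom_id %in% names(genome$chromosomes))
    if (any(bad))
      stop(sprintf("mapping references unknown chromosome '%s'",
                   recs$chrom_id[which(bad)[1]]))
  }
  if (is.null(sample_ids)) sample_ids <- sort(unique(records$sample_id))
  genes <- genome$genes
  ng <- nrow(genes)
  dims <- list(genes$gene_id, sample_ids)
  counts <- matrix(0L, ng, length(sample_ids), dimnames = dims)
  covered <- matrix(0, ng, length(sample_ids), dimnames = dims)
  depth <- matrix(0, ng, length(sample_ids), dimnames = dims)
  genome_total <- setNames(integer(length(sample_ids)), sample_ids)
  for (sid in sample_ids) {
    r <- recs[recs$sample_id == sid, , drop = FALSE]
    genome_total[sid] <- nrow(r)
    if (nrow(r) == 0) next
    for (cid in unique(r$chrom_id)) {
      rc <- r[r$chrom_id == cid, , drop = FALSE]
      gsel <- which(genes$chrom_id == cid)
      if (length(gsel) == 0) next
      gsub <- genes[gsel, , drop = FALSE]
      # start-position assignment
      gi <- findInterval(rc$start, gsub$start)
      ok <- gi >= 1 & gi <= nrow(gsub)
      ok[ok] <- rc$start[ok] < gsub$end[gi[ok]]
      if (any(ok)) {
        tab <- table(gi[ok])
        counts[gsel[as.integer(names(tab))], sid] <-
          counts[gsel[as.integer(names(tab))], sid] + as.integer(tab)
      }
      # coverage-based covered fraction and mean depth
      ir <- IRanges::IRanges(start = rc$start + 1L,
                             width = rc$aligned_length)
      L <- nchar(genome$chromosomes[[cid]])
      cov <- IRanges::coverage(IRanges::restrict(ir, start = 1L, end = L),
                               width = L)
      v <- IRanges::Views(cov, start = gsub$start + 1L, end = gsub$end)
      depth[gsel, sid] <- IRanges::viewSums(v) / (gsub$end - gsub$start)
      red <- IRanges::reduce(ir)
      gir <- IRanges::IRanges(start = gsub$start + 1L, end = gsub$end)
      ov <- IRanges::findOverlaps(gir, red)
      if (length(ov) > 0) {
        inter <- IRanges::pintersect(gir[S4Vectors::queryHits(ov)],
                                     red[S4Vectors::subjectHits(ov)])
        cb <- tapply(IRanges::width(inter), S4Vectors::queryHits(ov), sum)
        gidx <- as.integer(names(cb))
        covered[gsel[gidx], sid] <- as.numeric(cb) /
          (gsub$end[gidx] - gsub$start[gidx])
      }
    }
  }
  structure(list(counts = counts, covered = covered, depth = depth,
                 genome_total = genome_total, genome_id = genome$genome_id),
            class = "gene_sample_matrix")
}

#' @export
print.gene_sample_matrix <- function(x, ...) {
  cat(sprintf("gene_sample_matrix '%s': %d genes x %d samples, %s specific reads\n",
              x$genome_id, nrow(x$counts), ncol(x$counts),
              format(sum(x$genome_total), big.mark = ",")))
  invisible(x)
}

#' Per-sample gene detection calls
#'
#' A gene is detected in a sample when it has at least `detect_min_reads`
#' specific reads and at least `detect_min_covered_fraction` of its length
#' covered.
#'
#' @param gsm a [gene_read_counts()] result.
#' @param cfg a [threshold_config()].
#' @return Logical genes x samples matrix.
#' @export
detect_genes <- function(gsm, cfg = threshold_config()) {
  gsm$counts >= cfg$detect_min_reads &
    gsm$covered >= cfg$detect_min_covered_fraction
}

#' Relative genomic abundance and dominance classes
#'
#' Relative abundance of a genome in a sample is 100 x (its specific reads,
#' excluding reads assigned to masked conserved genes) / (total reads in the
#' sample). By default the numerator is rescaled by
#' `genome length / (genome length - masked gene length)` so that masking
#' does not bias the estimate; set `mask_correct = FALSE` for the raw
#' definition. Shares are each genome's fraction of the two genomes' summed
#' (corrected) specific reads.
#'
#' @param gsm_a,gsm_b [gene_read_counts()] results for the two genomes.
#' @param totals named vector of total reads per sample.
#' @param conserved a [conserved_genes()] result (the mask).
#' @param genomes list with the two `annotated_genome`s (`a`, `b`); needed
#'   for the mask correction.
#' @param cfg a [threshold_config()].
#' @param mask_correct rescale for the masked genome fraction (default TRUE).
#' @param genic_only count only reads assigned to (non-conserved) genes in
#'   the numerator instead of all specific reads.
#' @return Data frame of class `abundance_table`: `sample_id`, `abund_a`,
#'   `abund_b` (percent of total reads), `share_a`, `share_b`, `class`.
#' @export
relative_abundance <- function(gsm_a, gsm_b, totals, conserved, genomes,
                               cfg = threshold_config(),
                               mask_correct = TRUE, genic_only = FALSE) {
  sample_ids <- colnames(gsm_a$counts)
  if (!all(sample_ids %in% names(totals)))
    stop("totals missing for samples: ",
         paste(setdiff(sample_ids, names(totals)), collapse = ", "))
  totals <- totals[sample_ids]
  if (any(totals <= 0)) stop("totals must be positive")
  numerator <- function(gsm, cons_ids, genome) {
    cons_ids <- intersect(cons_ids, rownames(gsm$counts))
    cons <- if (length(cons_ids))
      colSums(gsm$counts[cons_ids, , drop = FALSE]) else 0
    num <- if (genic_only)
      colSums(gsm$counts) - cons
    else gsm$genome_total[sample_ids] - cons
    if (mask_correct) {
      L <- sum(nchar(genome$chromosomes))
      g <- genome$genes
      Lm <- sum((g$end - g$start)[g$gene_id %in% cons_ids])
      num <- num * L / (L - Lm)
    }
    num
  }
  num_a <- numerator(gsm_a, conserved$gene_a, genomes$a)
  num_b <- numerator(gsm_b, conserved$gene_b, genomes$b)
  abund_a <- 100 * num_a / totals
  abund_b <- 100 * num_b / totals
  both <- num_a + num_b
  share_a <- ifelse(both > 0, num_a / both, NA_real_)
  out <- data.frame(sample_id = sample_ids, abund_a = unname(abund_a),
                    abund_b = unname(abund_b), share_a = unname(share_a),
                    share_b = unname(1 - share_a), stringsAsFactors = FALSE)
  out$class <- classify_dominance(out$abund_a, out$abund_b, cfg)
  class(out) <- c("abundance_table", "data.frame")
  out
}

#' Dominance classification of a sample
#'
#' Implements the printed survey rules: a sample is `below_floor` when the
#' two genomes together do not exceed `abundance_floor` percent of its reads;
#' otherwise a genome is dominant when its share of the summed specific reads
#' exceeds `dominance_share` (strict), the genomes co-occur when both shares
#' lie within \[`co_low`, `co_high`\], and remaining share patterns (not
#' covered by the printed rules) are `mixed`.
#'
#' @param abund_a,abund_b relative abundances in percent of total reads.
#' @param cfg a [threshold_config()].
#' @return Factor with levels `A_dominant`, `B_dominant`, `co_occurring`,
#'   `mixed`, `below_floor`.
#' @export
classify_dominance <- function(abund_a, abund_b, cfg = threshold_config()) {
  stopifnot(all(abund_a >= 0), all(abund_b >= 0),
            length(abund_a) == length(abund_b))
  total <- abund_a + abund_b
  share_a <- ifelse(total > 0, abund_a / total, 0.5)
  out <- rep("mixed", length(abund_a))
  out[share_a > cfg$dominance_share] <- "A_dominant"
  out[(1 - share_a) > cfg$dominance_share] <- "B_dominant"
  co <- share_a >= cfg$co_low & share_a <= cfg$co_high &
    (1 - share_a) >= cfg$co_low & (1 - share_a) <= cfg$co_high
  out[co] <- "co_occurring"
  out[total <= cfg$abundance_floor] <- "below_floor"
  factor(out, levels = c("A_dominant", "B_dominant", "co_occurring",
                         "mixed", "below_floor"))
}

#' Per-sample gene-detection completeness and eligibility
#'
#' Fraction of a genome's genes detected in each sample, with conserved
#' (masked) genes excluded from numerator and denominator. Samples at or
#' above `completeness_min` are eligible for pan-genome analysis.
#'
#' @param detection logical genes x samples matrix from [detect_genes()].
#' @param genome the `annotated_genome`.
#' @param conserved_ids conserved gene ids of this genome (excluded).
#' @param cfg a [threshold_config()].
#' @return Data frame `sample_id`, `fraction_detected`, `eligible`.
#' @export
sample_completeness <- function(detection, genome, conserved_ids = character(0),
                                cfg = threshold_config()) {
  keep <- setdiff(rownames(detection), conserved_ids)
  frac <- colMeans(detection[keep, , drop = FALSE])
  data.frame(sample_id = colnames(detection),
             fraction_detected = unname(frac),
             eligible = unname(frac >= cfg$completeness_min),
             stringsAsFactors = FALSE)
}
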