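#' Specification of a synthetic cryptic genome pair
#'
#' Parameters of the two-genome simulator. The defaults describe a scaled-down
#' analogue of a pair of cryptic picoalgal sister genomes: four chromosomes of
#' 50 kb with 30 single-exon genes each, ~78% mean nucleotide identity between
#' orthologs, a handful of near-identical (>99%) conserved genes, and one
#' outlier chromosome with lower GC content and shorter genes.
#'
#' @param n_chromosomes number of chromosomes per genome.
#' @param chromosome_length chromosome length in bases.
#' @param genes_per_chromosome number of (single-exon, non-overlapping) genes
#'   laid out with uniform intergenic spacing on each chromosome.
#' @param target_nt_identity expected nucleotide identity between ortholog
#'   pairs, in (0, 1]; genome B is derived from genome A by i.i.d. per-site
#'   substitution at rate `1 - target_nt_identity`.
#' @param conserved_gene_count number of genes forced to >99% identity
#'   (substituted at `1 - conserved_identity` instead); planted on regular
#'   chromosomes only, since outlier-chromosome genes are atypical and
#'   non-conserved.
#' @param conserved_identity identity of conserved genes, in (0.99, 1].
#' @param gc_regular,gc_outlier GC fraction of regular and outlier
#'   chromosomes; `gc_outlier` must be below `gc_regular`.
#' @param outlier_chromosome_index which chromosome is the outlier (default:
#'   the last one).
#' @param outlier_gene_length_factor gene-length multiplier on the outlier
#'   chromosome, in (0, 1] (outlier genes are shorter).
#' @param gene_length length in bases of genes on regular chromosomes.
#' @param translocation_fraction fraction of regular-chromosome genes whose
#'   copy in genome B is relocated (breaking collinearity while keeping the
#'   ortholog relationship).
#' @param specific_fraction fraction of gene slots made genome-specific: the
#'   genome-B copy is replaced by unrelated random sequence, so both members
#'   lose their ortholog.
#' @param seed integer seed; a fixed seed makes the generated pair
#'   byte-identical across runs.
#' @return A list of class `genome_pair_spec`.
#' @export
genome_pair_spec <- function(n_chromosomes = 4, chromosome_length = 50000,
                             genes_per_chromosome = 30,
                             target_nt_identity = 0.78,
                             conserved_gene_count = 5,
                             conserved_identity = 0.998,
                             gc_regular = 0.48, gc_outlier = 0.44,
                             outlier_chromosome_index = n_chromosomes,
                             outlier_gene_length_factor = 0.5,
                             gene_length = 900,
                             translocation_fraction = 0,
                             specific_fraction = 0,
                             seed = 1) {
  stopifnot(n_chromosomes >= 1, chromosome_length > 0,
            genes_per_chromosome >= 1,
            target_nt_identity > 0, target_nt_identity <= 1,
            conserved_identity > 0.99, conserved_identity <= 1,
            gc_outlier < gc_regular, gc_regular > 0, gc_regular < 1,
            gc_outlier > 0,
            outlier_chromosome_index >= 1,
            outlier_chromosome_index <= n_chromosomes,
            outlier_gene_length_factor > 0, outlier_gene_length_factor <= 1,
            gene_length > 0,
            translocation_fraction >= 0, translocation_fraction < 1,
            specific_fraction >= 0, specific_fraction < 1,
            conserved_gene_count <= n_chromosomes * genes_per_chromosome)
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chromosome_length = as.integer(chromosome_length),
                 genes_per_chromosome = as.integer(genes_per_chromosome),
                 target_nt_identity = target_nt_identity,
                 conserved_gene_count = as.integer(conserved_gene_count),
                 conserved_identity = conserved_identity,
                 gc_regular = gc_regular, gc_outlier = gc_outlier,
                 outlier_chromosome_index = as.integer(outlier_chromosome_index),
                 outlier_gene_length_factor = outlier_gene_length_factor,
                 gene_length = as.integer(gene_length),
                 translocation_fraction = translocation_fraction,
                 specific_fraction = specific_fraction,
                 seed = as.integer(seed)),
            class = "genome_pair_spec")
}

new_annotated_genome <- function(genome_id, chromosomes, genes) {
  stopifnot(is.character(chromosomes), !is.null(names(chromosomes)),
            is.data.frame(genes))
  structure(list(genome_id = genome_id, chromosomes = chromosomes,
                 genes = genes),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("annotated_genome '%s': %d chromosomes (%s bp), %d genes\n",
              x$genome_id, length(x$chromosomes),
              format(sum(nchar(x$chromosomes)), big.mark = ","),
              nrow(x$genes)))
  invisible(x)
}

# uniform-spacing single-exon gene layout; 0-based half-open coordinates
gene_layout <- function(chromosome_length, n_genes, gene_length) {
  gap <- (chromosome_length - n_genes * gene_length) %/% (n_genes + 1L)
  if (gap < 1)
    stop(sprintf(paste0("chromosome of %d bp is too short for %d genes of ",
                        "%d bp"), chromosome_length, n_genes, gene_length))
  start <- gap * seq_len(n_genes) + gene_length * (seq_len(n_genes) - 1L)
  data.frame(start = as.integer(start),
             end = as.integer(start + gene_length))
}

#' Simulate a pair of cryptic sister genomes with planted truth
#'
#' Generates genome A as random sequence (outlier chromosome at its own GC),
#' lays out ordered single-exon genes, then derives genome B by i.i.d.
#' per-site substitution at rate `1 - target_nt_identity` -- conserved genes
#' are substituted at `1 - conserved_identity` instead -- and optionally
#' relocates a fraction of genome-B genes (translocations) or replaces a
#' fraction with unrelated sequence (genome-specific genes). Gene order is
#' otherwise perfectly collinear. The planted ortholog table is returned as
#' ground truth for scoring downstream orthology and recruitment.
#'
#' @param spec a [genome_pair_spec()].
#' @return A list of class `genome_pair` with elements `genome_a`, `genome_b`
#'   (each an `annotated_genome`), and `orthologs`, a data frame of planted
#'   pairs (`gene_a`, `gene_b`, `conserved`, `translocated`; genome-specific
#'   slots are absent from the table).
#' @export
simulate_genome_pair <- function(spec) {
  stopifnot(inherits(spec, "genome_pair_spec"))
  set.seed(spec$seed)
  nc <- spec$n_chromosomes
  chrom_ids <- sprintf("chr%d", seq_len(nc))
  outlier <- spec$outlier_chromosome_index

  chroms_a <- character(nc)
  genes <- vector("list", nc)
  for (i in seq_len(nc)) {
    gc <- if (i == outlier) spec$gc_outlier else spec$gc_regular
    chroms_a[i] <- cpp_random_dna(spec$chromosome_length, gc)
    gl <- if (i == outlier)
      as.integer(round(spec$gene_length * spec$outlier_gene_length_factor))
    else spec$gene_length
    lay <- gene_layout(spec$chromosome_length, spec$genes_per_chromosome, gl)
    genes[[i]] <- data.frame(
      chrom_id = chrom_ids[i], start = lay$start, end = lay$end,
      strand = sample(c("+", "-"), nrow(lay), replace = TRUE),
      outlier_flag = i == outlier, stringsAsFactors = FALSE)
  }
  names(chroms_a) <- chrom_ids
  genes <- do.call(rbind, genes)
  n_genes <- nrow(genes)
  genes$slot <- seq_len(n_genes)

  # assign disjoint roles: conserved, genome-specific, translocated;
  # conserved genes sit on regular chromosomes only (the outlier chromosome
  # carries atypical, non-conserved genes)
  pool <- seq_len(n_genes)
  cons_pool <- pool[!genes$outlier_flag]
  if (spec$conserved_gene_count > length(cons_pool))
    stop("conserved_gene_count exceeds the number of regular-chromosome genes")
  conserved_slots <- sort(sample(cons_pool, spec$conserved_gene_count))
  pool <- setdiff(pool, conserved_slots)
  n_specific <- round(spec$specific_fraction * n_genes)
  specific_slots <- sort(sample(pool, n_specific))
  pool <- setdiff(pool, specific_slots)
  regular_pool <- pool[!genes$outlier_flag[pool]]  # equal gene lengths only
  n_trans <- round(spec$translocation_fraction * n_genes)
  if (n_trans > length(regular_pool)) n_trans <- length(regular_pool)
  if (n_trans == 1) n_trans <- 0  # a lone gene cannot move anywhere
  trans_slots <- sort(sample(regular_pool, n_trans))

  # genome B: substitute, then replace specific slots, then relocate
  sub_rate <- 1 - spec$target_nt_identity
  cons_rate <- 1 - spec$conserved_identity
  chroms_b <- chroms_a
  for (i in seq_len(nc)) {
    on_chrom <- genes$chrom_id == chrom_ids[i]
    cons_here <- genes[on_chrom & genes$slot %in% conserved_slots, ]
    chroms_b[i] <- cpp_mutate_ranges(chroms_a[i], sub_rate,
                                     as.integer(cons_here$start),
                                     as.integer(cons_here$end),
                                     rep(cons_rate, nrow(cons_here)))
  }
  gc_of <- function(i) if (i == outlier) spec$gc_outlier else spec$gc_regular
  for (s in specific_slots) {
    g <- genes[s, ]
    ci <- match(g$chrom_id, chrom_ids)
    substr(chroms_b[ci], g$start + 1L, g$end) <-
      cpp_random_dna(g$end - g$start, gc_of(ci))
  }
  # cyclic relocation of translocated gene sequences among their slots
  b_source <- seq_len(n_genes)  # b_source[j] = A slot whose sequence sits in B slot j
  if (n_trans >= 2) {
    rotated <- c(trans_slots[-1], trans_slots[1])
    seqs <- vapply(trans_slots, function(s) {
      g <- genes[s, ]
      substr(chroms_b[match(g$chrom_id, chrom_ids)], g$start + 1L, g$end)
    }, character(1))
    for (j in seq_along(trans_slots)) {
      dest <- rotated[j]
      g <- genes[dest, ]
      substr(chroms_b[match(g$chrom_id, chrom_ids)], g$start + 1L, g$end) <-
        seqs[j]
      b_source[dest] <- trans_slots[j]
    }
  }

  id_a <- sprintf("A_g%03d", seq_len(n_genes))
  id_b <- sprintf("B_g%03d", seq_len(n_genes))
  ortho_of_a <- rep(NA_character_, n_genes)
  ortho_of_a[b_source] <- id_b  # A slot b_source[j] pairs with B slot j
  ortho_of_a[specific_slots] <- NA_character_
  keep <- setdiff(seq_len(n_genes), specific_slots)
  ortho_of_b <- rep(NA_character_, n_genes)
  ortho_of_b[keep] <- id_a[b_source[keep]]

  base <- data.frame(chrom_id = genes$chrom_id, start = genes$start,
                     end = genes$end, strand = genes$strand,
                     outlier_flag = genes$outlier_flag,
                     dispensable_truth = FALSE, stringsAsFactors = FALSE)
  genes_a <- cbind(data.frame(gene_id = id_a, stringsAsFactors = FALSE), base)
  genes_a$ortholog_id <- ortho_of_a
  genes_a$conserved_truth <- seq_len(n_genes) %in% conserved_slots
  genes_a$specific_truth <- seq_len(n_genes) %in% specific_slots
  genes_b <- cbind(data.frame(gene_id = id_b, stringsAsFactors = FALSE), base)
  genes_b$ortholog_id <- ortho_of_b
  genes_b$conserved_truth <- seq_len(n_genes) %in% conserved_slots
  genes_b$specific_truth <- seq_len(n_genes) %in% specific_slots

  orthologs <- data.frame(
    gene_a = id_a[b_source[keep]], gene_b = id_b[keep],
    conserved = b_source[keep] %in% conserved_slots,
    translocated = b_source[keep] %in% trans_slots,
    stringsAsFactors = FALSE)
  orthologs <- orthologs[order(orthologs$gene_a), , drop = FALSE]
  rownames(orthologs) <- NULL

  structure(list(
    genome_a = new_annotated_genome("A", chroms_a, genes_a),
    genome_b = new_annotated_genome("B", chroms_b, genes_b),
    orthologs = orthologs, spec = spec), class = "genome_pair")
}

#' @export
print.genome_pair <- function(x, ...) {
  cat(sprintf("genome_pair: %d planted ortholog pairs (%d conserved)\n",
              nrow(x$orthologs), sum(x$orthologs$conserved)))
  print(x$genome_a); print(x$genome_b)
  invisible(x)
}

#' Extract gene sequences from an annotated genome
#'
#' @param genome an `annotated_genome`.
#' @param gene_ids optional subset of gene ids (default: all genes).
#' @return Named character vector of forward-strand gene sequences.
#' @export
gene_sequences <- function(genome, gene_ids = NULL) {
  g <- genome$genes
  if (!is.null(gene_ids)) g <- g[match(gene_ids, g$gene_id), , drop = FALSE]
  out <- substr(genome$chromosomes[g$chrom_id], g$start + 1L, g$end)
  names(out) <- g$gene_id
  out
}

#' Measured GC fraction of sequences
#'
#' @param x a character vector of sequences or an `annotated_genome` (per
#'   chromosome).
#' @return Named numeric vector of GC fractions.
#' @export
gc_content <- function(x) {
  if (inherits(x, "annotated_genome")) x <- x$chromosomes
  vapply(x, function(s) {
    b <- strsplit(s, "")[[1]]
    mean(b %in% c("G", "C", "g", "c"))
  }, numeric(1))
}

# internal consistency checks used by tests and IO
validate_annotated_genome <- function(genome) {
  g <- genome$genes
  stopifnot(all(g$chrom_id %in% names(genome$chromosomes)),
            all(g$start < g$end),
            all(g$end <= nchar(genome$chromosomes[g$chrom_id])),
            all(g$start >= 0))
  for (cid in unique(g$chrom_id)) {
    gc <- g[g$chrom_id == cid, ]
    stopifnot(!is.unsorted(gc$start),
              all(gc$start[-1] >= gc$end[-nrow(gc)]))
  }
  invisible(TRUE)
}
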