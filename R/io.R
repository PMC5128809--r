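#' Write an annotated genome to FASTA and GFF3
#'
#' Internal coordinates are 0-based half-open; the GFF3 export converts to
#' the standard 1-based inclusive convention. Ground-truth annotations
#' (`ortholog_id`, `dispensable_truth`, `conserved_truth`, `outlier_flag`)
#' travel as GFF3 attributes so downstream stages can be scored from files
#' alone.
#'
#' @param genome an `annotated_genome`.
#' @param fasta_path,gff3_path output paths.
#' @return Invisibly, the genome.
#' @export
write_annotated_genome <- function(genome, fasta_path, gff3_path) {
  dna <- DNAStringSet(genome$chromosomes)
  writeXStringSet(dna, fasta_path)
  g <- genome$genes
  gr <- GRanges(seqnames = g$chrom_id,
                ranges = IRanges::IRanges(start = g$start + 1L, end = g$end),
                strand = g$strand)
  mcols(gr) <- S4Vectors::DataFrame(
    type = "gene", ID = g$gene_id,
    ortholog_id = ifelse(is.na(g$ortholog_id), "none", g$ortholog_id),
    dispensable_truth = tolower(as.character(g$dispensable_truth)),
    conserved_truth = tolower(as.character(g$conserved_truth)),
    outlier_flag = tolower(as.character(g$outlier_flag)))
  rtracklayer::export(gr, gff3_path, format = "gff3")
  invisible(genome)
}

#' Read an annotated genome from FASTA and GFF3
#'
#' @param fasta_path,gff3_path files written by [write_annotated_genome()]
#'   (or any FASTA plus gene-typed GFF3).
#' @param genome_id label of the genome.
#' @return An `annotated_genome` with 0-based half-open gene coordinates.
#' @export
read_annotated_genome <- function(fasta_path, gff3_path, genome_id) {
  dna <- readDNAStringSet(fasta_path)
  chroms <- setNames(as.character(dna),
                     vapply(strsplit(names(dna), "\\s+"), `[[`, "", 1))
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  mc <- as.data.frame(mcols(gr))
  pick <- function(col, default) {
    if (col %in% names(mc)) mc[[col]] else rep(default, length(gr))
  }
  genes <- data.frame(
    gene_id = pick("ID", sprintf("gene%04d", seq_along(gr))),
    chrom_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    outlier_flag = pick("outlier_flag", "false") == "true",
    ortholog_id = pick("ortholog_id", "none"),
    conserved_truth = pick("conserved_truth", "false") == "true",
    dispensable_truth = pick("dispensable_truth", "false") == "true",
    stringsAsFactors = FALSE)
  genes$ortholog_id[genes$ortholog_id == "none"] <- NA_character_
  ord <- order(match(genes$chrom_id, names(chroms)), genes$start)
  genome <- new_annotated_genome(genome_id, chroms, genes[ord, ])
  validate_annotated_genome(genome)
  genome
}

#' Write reads to FASTQ
#'
#' Read origin is already encoded in the read names; qualities are a constant
#' placeholder (`I`).
#'
#' @param reads named character vector of read sequences.
#' @param path output FASTQ path.
#' @return Invisibly, the path.
#' @export
write_reads_fastq <- function(reads, path) {
  dna <- DNAStringSet(reads)
  quals <- BStringSet(vapply(nchar(reads), function(n)
    paste(rep("I", n), collapse = ""), ""))
  writeXStringSet(dna, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Read a FASTQ file as a named character vector
#'
#' @param path FASTQ path.
#' @return Named character vector of read sequences.
#' @export
read_reads_fastq <- function(path) {
  dna <- readDNAStringSet(path, format = "fastq")
  setNames(as.character(dna), names(dna))
}

#' Write a data frame (or matrix) as TSV
#'
#' @param x data frame or matrix; matrices are written with row names in a
#'   leading `id` column.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_tsv <- function(x, path) {
  if (is.matrix(x))
    x <- data.frame(id = rownames(x), x, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
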