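#' Find ortholog pairs between two annotated genomes
#'
#' All-vs-all gene comparison with a shared k-mer prefilter, global
#' (Needleman-Wunsch) alignment of candidate gene pairs (match +1, mismatch
#' -1, gap -2), and reciprocal-best-hit pairing above a minimum identity.
#' Identity is computed on the nucleotide gene sequences as
#' `matches / alignment columns x 100`.
#'
#' @param genome_a,genome_b `annotated_genome` objects.
#' @param min_ortholog_identity minimum percent identity for a pair.
#' @param prefilter_k k-mer length of the candidate prefilter.
#' @param min_shared_kmers minimum shared k-mers to align a candidate pair.
#' @return Data frame of class `ortholog_pairs`: `gene_a`, `gene_b`,
#'   `identity`, `alignment_length`; each gene appears in at most one pair.
#' @export
find_orthologs <- function(genome_a, genome_b, min_ortholog_identity = 60,
                           prefilter_k = 12, min_shared_kmers = 3) {
  seqs_a <- gene_sequences(genome_a)
  seqs_b <- gene_sequences(genome_b)
  if (length(seqs_a) == 0 || length(seqs_b) == 0)
    stop("empty gene set")
  cand <- kmer_candidates(seqs_a, seqs_b, prefilter_k, min_shared_kmers)
  if (nrow(cand) == 0)
    return(empty_ortholog_pairs())
  aln <- align_pairs(seqs_a[cand$gene_a], seqs_b[cand$gene_b])
  cand$identity <- aln$identity
  cand$alignment_length <- aln$alignment_length
  cand <- cand[cand$identity >= min_ortholog_identity, , drop = FALSE]
  if (nrow(cand) == 0)
    return(empty_ortholog_pairs())
  # reciprocal best hits, deterministic tie-break on gene ids
  cand <- cand[order(-cand$identity, cand$gene_a, cand$gene_b), ]
  best_ab <- cand[!duplicated(cand$gene_a), , drop = FALSE]
  best_ba <- cand[!duplicated(cand$gene_b), , drop = FALSE]
  key <- paste(best_ab$gene_a, best_ab$gene_b)
  rbh <- best_ab[key %in% paste(best_ba$gene_a, best_ba$gene_b), ,
                 drop = FALSE]
  rbh <- rbh[order(rbh$gene_a), c("gene_a", "gene_b", "identity",
                                  "alignment_length")]
  rownames(rbh) <- NULL
  class(rbh) <- c("ortholog_pairs", "data.frame")
  rbh
}

empty_ortholog_pairs <- function() {
  out <- data.frame(gene_a = character(0), gene_b = character(0),
                    identity = numeric(0), alignment_length = integer(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("ortholog_pairs", "data.frame")
  out
}

# candidate gene pairs sharing at least min_shared k-mers
kmer_candidates <- function(seqs_a, seqs_b, k, min_shared) {
  kmers_of <- function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, 1:(n - k + 1), k:n))
  }
  tab_of <- function(seqs) {
    kl <- lapply(seqs, kmers_of)
    data.frame(kmer = unlist(kl, use.names = FALSE),
               gene = rep(names(seqs), vapply(kl, length, 0L)),
               stringsAsFactors = FALSE)
  }
  tab_a <- tab_of(seqs_a)
  tab_b <- tab_of(seqs_b)
  m <- merge(tab_a, tab_b, by = "kmer", suffixes = c("_a", "_b"))
  if (nrow(m) == 0)
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      stringsAsFactors = FALSE))
  counts <- as.data.frame(table(m$gene_a, m$gene_b),
                          stringsAsFactors = FALSE)
  counts <- counts[counts$Freq >= min_shared, , drop = FALSE]
  data.frame(gene_a = counts$Var1, gene_b = counts$Var2,
             stringsAsFactors = FALSE)
}

# global alignment of paired sequences; identity = matches / columns
align_pairs <- function(a, b) {
  stopifnot(length(a) == length(b))
  mat <- nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                      baseOnly = TRUE)
  identity <- numeric(length(a))
  alen <- integer(length(a))
  for (i in seq_along(a)) {
    aln <- pairwiseAlignment(a[[i]], b[[i]], type = "global",
                             substitutionMatrix = mat, gapOpening = 0,
                             gapExtension = 2)
    pa <- strsplit(as.character(alignedPattern(aln)), "")[[1]]
    pb <- strsplit(as.character(alignedSubject(aln)), "")[[1]]
    alen[i] <- length(pa)
    identity[i] <- 100 * sum(pa == pb & pa != "-") / alen[i]
  }
  list(identity = identity, alignment_length = alen)
}

#' Highly conserved genes to mask from genome-specific signals
#'
#' Genes of ortholog pairs above the identity threshold (strict `>`). These
#' are the genes a competitive mapper cannot attribute to one genome; the
#' abundance module removes them from its numerators, and they are excluded
#' from completeness and dispensable-gene analysis.
#'
#' @param pairs an `ortholog_pairs` data frame from [find_orthologs()].
#' @param threshold percent identity above which a pair is conserved.
#' @return List with `gene_a`, `gene_b` (ids per genome) and `all` (union).
#' @export
conserved_genes <- function(pairs, threshold = 99) {
  sel <- pairs$identity > threshold
  list(gene_a = pairs$gene_a[sel], gene_b = pairs$gene_b[sel],
       all = c(pairs$gene_a[sel], pairs$gene_b[sel]))
}

#' Chain ortholog pairs into synteny blocks and summarize collinearity
#'
#' Orders genes by genomic rank on each genome and greedily chains pairs that
#' are rank-adjacent on both genomes (at most one intervening gene) on the
#' same chromosome pair with a consistent orientation. Pairs in blocks of at
#' least `min_block_genes` genes are collinear; remaining pairs are shared
#' outside syntenic blocks; unpaired genes are genome-specific.
#'
#' @param pairs `ortholog_pairs` from [find_orthologs()].
#' @param genome_a,genome_b the annotated genomes.
#' @param min_block_genes minimum genes per block.
#' @return List with `blocks` (data frame `block_id`, `chrom_a`, `chrom_b`,
#'   `n_genes`, `orientation`, `genes_a`, `genes_b`), `pair_block` (block id
#'   per pair, `NA` outside blocks) and `summary` (per genome: fractions
#'   `collinear`, `shared_outside`, `specific`, summing to 1).
#' @export
synteny_blocks <- function(pairs, genome_a, genome_b, min_block_genes = 3) {
  ga <- genome_a$genes
  gb <- genome_b$genes
  rank_in <- function(g) {
    r <- integer(nrow(g))
    for (cid in unique(g$chrom_id)) {
      sel <- which(g$chrom_id == cid)
      r[sel[order(g$start[sel])]] <- seq_along(sel)
    }
    r
  }
  ga$rank <- rank_in(ga)
  gb$rank <- rank_in(gb)
  p <- pairs
  p$chrom_a <- ga$chrom_id[match(p$gene_a, ga$gene_id)]
  p$rank_a <- ga$rank[match(p$gene_a, ga$gene_id)]
  p$chrom_b <- gb$chrom_id[match(p$gene_b, gb$gene_id)]
  p$rank_b <- gb$rank[match(p$gene_b, gb$gene_id)]
  # chain within each chromosome pair, so a translocated gene (a different
  # chromosome pair) interrupts no host chain. A pair may also chain past one
  # immediately preceding interloper (rank-gap tolerance 1 on both genomes);
  # when both predecessors are compatible the longer block wins, so a single
  # relocated gene does not hijack the chain.
  p <- p[order(p$chrom_a, p$chrom_b, p$rank_a), , drop = FALSE]
  n <- nrow(p)
  block <- integer(n)
  if (n > 0) {
    bid <- 1L
    block[1] <- bid
    bsize <- c(1L)
    bdir <- c(0L)
    for (i in seq_len(n)[-1]) {
      compat <- function(j) {
        if (j < 1) return(NA_integer_)
        if (p$chrom_a[i] != p$chrom_a[j] || p$chrom_b[i] != p$chrom_b[j])
          return(NA_integer_)
        da <- p$rank_a[i] - p$rank_a[j]
        db <- p$rank_b[i] - p$rank_b[j]
        if (da < 1 || da > 2 || abs(db) < 1 || abs(db) > 2)
          return(NA_integer_)
        b <- block[j]
        if (bdir[b] != 0L && sign(db) != bdir[b]) return(NA_integer_)
        b
      }
      cand <- c(compat(i - 1L), compat(i - 2L))
      cand <- cand[!is.na(cand)]
      if (length(cand) > 0) {
        b <- cand[which.max(bsize[cand])]
        block[i] <- b
        bsize[b] <- bsize[b] + 1L
        j <- max(which(block[seq_len(i - 1)] == b))
        bdir[b] <- sign(p$rank_b[i] - p$rank_b[j])
      } else {
        bid <- bid + 1L
        block[i] <- bid
        bsize[bid] <- 1L
        bdir[bid] <- 0L
      }
    }
  }
  p$block <- block
  sizes <- table(p$block)
  keep <- as.integer(names(sizes)[sizes >= min_block_genes])
  p$block[!(p$block %in% keep)] <- NA_integer_
  blocks <- do.call(rbind, lapply(stats::na.omit(unique(p$block)),
                                  function(b) {
    q <- p[p$block %in% b, , drop = FALSE]
    dirs <- sign(diff(q$rank_b))
    data.frame(block_id = b, chrom_a = q$chrom_a[1], chrom_b = q$chrom_b[1],
               n_genes = nrow(q),
               orientation = if (all(dirs >= 0)) "same" else "inverted",
               genes_a = paste(q$gene_a, collapse = ","),
               genes_b = paste(q$gene_b, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  if (is.null(blocks))
    blocks <- data.frame(block_id = integer(0), chrom_a = character(0),
                         chrom_b = character(0), n_genes = integer(0),
                         orientation = character(0), genes_a = character(0),
                         genes_b = character(0), stringsAsFactors = FALSE)
  in_block_a <- p$gene_a[!is.na(p$block)]
  in_block_b <- p$gene_b[!is.na(p$block)]
  summ <- function(g, paired, inblock) {
    n <- nrow(g)
    coll <- sum(g$gene_id %in% inblock) / n
    shared <- sum(g$gene_id %in% paired & !(g$gene_id %in% inblock)) / n
    spec <- sum(!(g$gene_id %in% paired)) / n
    c(collinear = coll, shared_outside = shared, specific = spec)
  }
  summary <- rbind(a = summ(ga, p$gene_a, in_block_a),
                   b = summ(gb, p$gene_b, in_block_b))
  list(blocks = blocks,
       pair_block = setNames(p$block, paste(p$gene_a, p$gene_b)),
       summary = summary)
}
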