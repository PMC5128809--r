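#' Build a k-mer index of a genome
#'
#' Indexes every forward-strand k-mer of every chromosome. Reverse-strand
#' placements are found by querying the reverse complement, so a lookup
#' reports hits on both strands.
#'
#' @param genome an `annotated_genome`.
#' @param k k-mer length (11-31, at most the shortest chromosome).
#' @return An object of class `kmer_index`.
#' @export
build_index <- function(genome, k = 15) {
  stopifnot(inherits(genome, "annotated_genome"))
  ptr <- cpp_build_index(names(genome$chromosomes),
                         unname(genome$chromosomes), as.integer(k))
  structure(list(ptr = ptr, genome_id = genome$genome_id, k = as.integer(k),
                 chrom_ids = names(genome$chromosomes),
                 chrom_lengths = nchar(genome$chromosomes)),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  st <- cpp_index_stats(x$ptr)
  cat(sprintf("kmer_index '%s': k=%d, %d chromosomes, %s seed positions\n",
              x$genome_id, x$k, length(x$chrom_ids),
              format(st$n_positions, big.mark = ",")))
  invisible(x)
}

#' Look up a k-mer in an index
#'
#' @param index a [build_index()] result.
#' @param kmer a length-`k` sequence.
#' @return Data frame of hits: `chrom_id`, `pos` (0-based, forward strand),
#'   `strand` (`+` if the forward genome sequence equals the k-mer, `-` if
#'   its reverse complement does). Empty when the k-mer is absent.
#' @export
kmer_lookup <- function(index, kmer) {
  stopifnot(inherits(index, "kmer_index"))
  hits <- cpp_lookup(index$ptr, toupper(kmer))
  data.frame(chrom_id = index$chrom_ids[hits$chrom], pos = hits$pos,
             strand = hits$strand, stringsAsFactors = FALSE)
}

#' Competitively map reads against two genomes
#'
#' Seed-and-extend mapping: exact k-mer seed hits on either strand nominate
#' candidate loci, every candidate is scored by gapless full-length
#' alignment, and the best locus per genome is kept (ties broken by lowest
#' chromosome, lowest start, forward strand). Identity is
#' `matches / alignment columns x 100`.
#'
#' @param reads character vector of reads (named by read id) or a
#'   `DNAStringSet`.
#' @param index_a,index_b [build_index()] objects of the two genomes
#'   (`index_b` may be `NULL` for single-genome recruitment).
#' @param params a [recruit_params()]; `k` must match the indexes.
#' @return Data frame with one row per read: `read_id`, `read_length`, and
#'   per genome `*_chrom`, `*_start` (0-based), `*_strand`, `*_matches`,
#'   `*_identity` (`NA` where no seeded candidate exists).
#' @export
map_reads <- function(reads, index_a, index_b = NULL,
                      params = recruit_params()) {
  if (inherits(reads, "DNAStringSet")) {
    nm <- names(reads)
    reads <- as.character(reads)
    names(reads) <- nm
  }
  stopifnot(inherits(index_a, "kmer_index"),
            is.null(index_b) || inherits(index_b, "kmer_index"))
  if (params$k != index_a$k ||
      (!is.null(index_b) && params$k != index_b$k))
    stop("params$k does not match the index k")
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%06d", seq_along(reads))
  hits <- cpp_map_reads(unname(reads), index_a$ptr,
                        if (is.null(index_b)) NULL else index_b$ptr)
  out <- data.frame(read_id = ids, stringsAsFactors = FALSE)
  out$read_length <- hits$read_length
  out$a_chrom <- index_a$chrom_ids[hits$a_chrom]
  out$a_start <- hits$a_start
  out$a_strand <- hits$a_strand
  out$a_matches <- hits$a_matches
  out$a_identity <- hits$a_identity
  if (is.null(index_b)) {
    out$b_chrom <- NA_character_
    out$b_start <- NA_real_
    out$b_strand <- NA_character_
    out$b_matches <- NA_integer_
    out$b_identity <- NA_real_
  } else {
    out$b_chrom <- index_b$chrom_ids[hits$b_chrom]
    out$b_start <- hits$b_start
    out$b_strand <- hits$b_strand
    out$b_matches <- hits$b_matches
    out$b_identity <- hits$b_identity
  }
  attr(out, "genome_ids") <- c(a = index_a$genome_id,
                               b = if (is.null(index_b)) NA_character_
                                   else index_b$genome_id)
  out
}

#' Map a single read
#'
#' @inheritParams map_reads
#' @param read one read sequence.
#' @return One-row data frame as in [map_reads()].
#' @export
map_read <- function(read, index_a, index_b = NULL,
                     params = recruit_params()) {
  stopifnot(length(read) == 1)
  if (nchar(read) < params$k)
    stop("read is shorter than the seed length k")
  map_reads(read, index_a, index_b, params)
}

#' Genome-specificity filter on competitive mappings
#'
#' Partitions reads into specific-to-A, specific-to-B, ambiguous, and
#' unmapped. A read is mapped when its best identity on either genome reaches
#' `min_identity`; a mapped read is specific when its best-genome identity
#' beats the best placement on the other genome by at least
#' `specificity_margin` identity points (or the other genome has no seeded
#' placement at all).
#'
#' @param hits data frame from [map_reads()].
#' @param params a [recruit_params()].
#' @return Data frame with one row per read: `read_id`, `status` (factor
#'   `specific_a` / `specific_b` / `ambiguous` / `unmapped`), `genome_id`,
#'   `chrom_id`, `start`, `strand`, `aligned_length`, `identity`,
#'   `best_other_identity`, `specific`.
#' @export
competitive_filter <- function(hits, params = recruit_params()) {
  ia <- ifelse(is.na(hits$a_identity), -Inf, hits$a_identity)
  ib <- ifelse(is.na(hits$b_identity), -Inf, hits$b_identity)
  best_a <- ia >= ib  # ties go to A, but a tie is never specific
  identity <- pmax(ia, ib)
  other <- pmin(ia, ib)
  mapped <- identity >= params$min_identity
  specific <- mapped & (is.infinite(other) |
                          (identity - other) >= params$specificity_margin)
  status <- rep("unmapped", nrow(hits))
  status[mapped & !specific] <- "ambiguous"
  status[specific & best_a] <- "specific_a"
  status[specific & !best_a] <- "specific_b"
  gids <- attr(hits, "genome_ids")
  pick <- function(col_a, col_b, na) {
    out <- rep(na, nrow(hits))
    out[mapped & best_a] <- hits[[col_a]][mapped & best_a]
    out[mapped & !best_a] <- hits[[col_b]][mapped & !best_a]
    out
  }
  out <- data.frame(
    read_id = hits$read_id,
    status = factor(status, levels = c("specific_a", "specific_b",
                                       "ambiguous", "unmapped")),
    genome_id = ifelse(!mapped, NA_character_,
                       ifelse(best_a, gids[["a"]], gids[["b"]])),
    chrom_id = pick("a_chrom", "b_chrom", NA_character_),
    start = pick("a_start", "b_start", NA_real_),
    strand = pick("a_strand", "b_strand", NA_character_),
    aligned_length = ifelse(mapped, hits$read_length, NA_integer_),
    identity = ifelse(mapped, identity, NA_real_),
    best_other_identity = ifelse(mapped & is.finite(other), other, NA_real_),
    specific = specific, stringsAsFactors = FALSE)
  out
}

#' Windowed recruitment profile (depth and identity track)
#'
#' Tiles each chromosome with half-open windows and reports, per window, the
#' depth contributed by genome-specific reads (aligned bases overlapping the
#' window divided by window width) and a 1%-binned identity histogram of the
#' reads starting in the window.
#'
#' @param records filtered records from [competitive_filter()] (one sample);
#'   only rows specific to `genome` are used.
#' @param genome the `annotated_genome` the records refer to.
#' @param window window width in bases (> 0).
#' @return List with `depth` (data frame `chrom_id`, `start`, `end`,
#'   `depth`) and `identity_hist` (data frame `chrom_id`, `start`,
#'   `identity_bin`, `n_reads`).
#' @export
recruitment_profile <- function(records, genome, window = 200) {
  if (window <= 0) stop("window must be positive")
  window <- as.integer(window)
  recs <- records[records$specific %in% TRUE &
                    records$genome_id %in% genome$genome_id, , drop = FALSE]
  depth_rows <- list()
  hist_rows <- list()
  for (cid in names(genome$chromosomes)) {
    L <- nchar(genome$chromosomes[[cid]])
    ws <- seq.int(0L, L - 1L, by = window)
    we <- pmin(ws + window, L)
    r <- recs[recs$chrom_id == cid, , drop = FALSE]
    if (nrow(r) > 0) {
      ir <- IRanges::IRanges(start = r$start + 1L,
                             width = r$aligned_length)
      cov <- IRanges::coverage(ir, width = L)
      v <- IRanges::Views(cov, start = ws + 1L, end = we)
      depth <- IRanges::viewSums(v) / (we - ws)
      widx <- findInterval(r$start, ws)
      bin <- floor(r$identity)
      tab <- table(widx, bin)
      if (length(tab) > 0) {
        df <- as.data.frame(tab, stringsAsFactors = FALSE)
        df <- df[df$Freq > 0, , drop = FALSE]
        hist_rows[[cid]] <- data.frame(
          chrom_id = cid, start = ws[as.integer(df$widx)],
          identity_bin = as.integer(df$bin), n_reads = df$Freq,
          stringsAsFactors = FALSE)
      }
    } else {
      depth <- rep(0, length(ws))
    }
    depth_rows[[cid]] <- data.frame(chrom_id = cid, start = ws, end = we,
                                    depth = as.numeric(depth),
                                    stringsAsFactors = FALSE)
  }
  list(depth = do.call(rbind, c(depth_rows, list(make.row.names = FALSE))),
       identity_hist = if (length(hist_rows))
         do.call(rbind, c(hist_rows, list(make.row.names = FALSE)))
       else data.frame(chrom_id = character(0), start = integer(0),
                       identity_bin = integer(0), n_reads = integer(0)))
}
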