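#' Sub-population model of dispensable gene cassettes
#'
#' A cassette is a run of contiguous genes that is gained or lost as a unit.
#' Each simulated cell carries each cassette independently with its carrier
#' frequency; cells lacking a cassette contribute no reads from the cassette
#' interval, producing the coverage-depletion signature the pan-genome module
#' detects.
#'
#' @param genome an `annotated_genome`.
#' @param cassettes list of cassette definitions, each a list with `chrom_id`,
#'   `gene_ids` (contiguous in gene order on that chromosome), and
#'   `carrier_frequency` in \[0, 1\].
#' @return A list of class `population_model`; each cassette gains `start` /
#'   `end` base coordinates (first gene start, last gene end) and an id.
#' @export
population_model <- function(genome, cassettes) {
  stopifnot(inherits(genome, "annotated_genome"), is.list(cassettes))
  out <- vector("list", length(cassettes))
  for (i in seq_along(cassettes)) {
    cs <- cassettes[[i]]
    stopifnot(!is.null(cs$chrom_id), !is.null(cs$gene_ids),
              !is.null(cs$carrier_frequency),
              cs$carrier_frequency >= 0, cs$carrier_frequency <= 1)
    on_chrom <- genome$genes[genome$genes$chrom_id == cs$chrom_id, ]
    ranks <- match(cs$gene_ids, on_chrom$gene_id)
    if (anyNA(ranks))
      stop(sprintf("cassette %d: unknown gene ids on %s", i, cs$chrom_id))
    if (!identical(sort(ranks), seq(min(ranks), max(ranks))))
      stop(sprintf("cassette %d: gene ids are not contiguous in gene order",
                   i))
    rows <- on_chrom[sort(ranks), ]
    out[[i]] <- list(id = sprintf("cassette_%02d", i),
                     chrom_id = cs$chrom_id,
                     gene_ids = rows$gene_id,
                     carrier_frequency = cs$carrier_frequency,
                     start = min(rows$start), end = max(rows$end))
  }
  structure(list(genome_id = genome$genome_id, cassettes = out),
            class = "population_model")
}

#' Draw per-cell cassette genotypes
#'
#' @param genome an `annotated_genome`.
#' @param model a [population_model()].
#' @param n_cells number of cells to simulate.
#' @param seed optional integer seed.
#' @return Logical matrix `n_cells x n_cassettes` (TRUE = carries cassette),
#'   columns named by cassette id.
#' @export
apply_population_variants <- function(genome, model, n_cells, seed = NULL) {
  stopifnot(inherits(model, "population_model"), n_cells >= 1)
  if (!is.null(seed)) set.seed(seed)
  g <- vapply(model$cassettes,
              function(cs) rbinom(n_cells, 1L, cs$carrier_frequency) == 1L,
              logical(n_cells))
  g <- matrix(g, nrow = n_cells,
              dimnames = list(NULL,
                              vapply(model$cassettes, `[[`, "", "id")))
  g
}

# valid 0-based read start segments per chromosome, excluding any start whose
# read would overlap a forbidden interval; forbidden = data.frame(chrom_id,
# start, end) in 0-based half-open coordinates
read_start_segments <- function(genome, read_length, forbidden = NULL) {
  segs <- lapply(names(genome$chromosomes), function(cid) {
    L <- nchar(genome$chromosomes[[cid]])
    if (L < read_length) return(NULL)
    ir <- IRanges::IRanges(start = 1L, end = L - read_length + 1L)
    if (!is.null(forbidden)) {
      f <- forbidden[forbidden$chrom_id == cid, , drop = FALSE]
      if (nrow(f) > 0) {
        bad <- IRanges::IRanges(start = pmax(1L, f$start - read_length + 2L),
                                end = pmin(L - read_length + 1L, f$end))
        ir <- IRanges::setdiff(ir, bad)
      }
    }
    if (length(ir) == 0) return(NULL)
    data.frame(chrom_id = cid, lo = IRanges::start(ir) - 1L,
               n = IRanges::width(ir), stringsAsFactors = FALSE)
  })
  do.call(rbind, segs)
}

# uniform draw of n read start positions over the allowed segments
sample_read_starts <- function(segments, n) {
  if (is.null(segments) || nrow(segments) == 0)
    stop("no valid read start positions")
  idx <- sample.int(nrow(segments), n, replace = TRUE, prob = segments$n)
  data.frame(chrom_id = segments$chrom_id[idx],
             start = segments$lo[idx] +
               floor(runif(n) * segments$n[idx]),
             stringsAsFactors = FALSE)
}

#' Simulate a shotgun read set for one sample
#'
#' Reads are drawn from genome A, genome B and a random-sequence background
#' ("other taxa") according to the sample's true mixture fractions
#' (multinomial). Reads from cells lacking a cassette are never drawn from an
#' interval overlapping that cassette. Substitution errors are i.i.d. per
#' base; read origin is encoded in the read name as
#' `sampleID|origin|chrom|pos|serial`.
#'
#' @param sample one row of a station table from [simulate_station_series()]
#'   (or any list with `sample_id`, `total_reads`, `true_fraction_a`,
#'   `true_fraction_b`, `background_fraction`).
#' @param genomes list with elements `a` and `b` (`annotated_genome`s).
#' @param genotypes optional list with per-cell cassette genotype matrices
#'   (`a`, `b`) from [apply_population_variants()].
#' @param models optional list with the matching [population_model()]s.
#' @param read_length read length in bases.
#' @param error_rate substitution error rate in \[0, 0.1\].
#' @param background_gc GC fraction of background reads.
#' @param seed optional integer seed.
#' @return List with `reads` (named character vector) and `truth` (data frame
#'   `read_id`, `sample_id`, `origin`, `chrom_id`, `start`, `strand`).
#' @export
simulate_reads <- function(sample, genomes, genotypes = NULL, models = NULL,
                           read_length = 100, error_rate = 0.01,
                           background_gc = 0.48, seed = NULL) {
  stopifnot(error_rate >= 0, error_rate <= 0.1)
  if (!is.null(seed)) set.seed(seed)
  for (g in genomes)
    if (length(g$chromosomes) == 0 || all(nchar(g$chromosomes) == 0))
      stop("empty genome")
  min_len <- min(vapply(genomes, function(g) min(nchar(g$chromosomes)), 0))
  if (read_length > min_len)
    stop("read_length exceeds the shortest chromosome")

  fr <- c(a = sample$true_fraction_a, b = sample$true_fraction_b,
          bg = sample$background_fraction)
  stopifnot(abs(sum(fr) - 1) < 1e-9)
  n_total <- sample$total_reads
  counts <- as.vector(rmultinom(1, n_total, fr))
  names(counts) <- names(fr)

  pieces_seq <- character(0)
  pieces_truth <- list()
  for (org in c("a", "b")) {
    ng <- counts[[org]]
    if (ng == 0) next
    genome <- genomes[[org]]
    gt <- genotypes[[org]]
    mod <- models[[org]]
    if (is.null(gt) || is.null(mod) || length(mod$cassettes) == 0) {
      segs <- read_start_segments(genome, read_length)
      pos <- sample_read_starts(segs, ng)
    } else {
      cell <- sample.int(nrow(gt), ng, replace = TRUE)
      key <- apply(gt, 1, function(r) paste(as.integer(r), collapse = ""))
      pos_list <- list()
      for (kk in unique(key[cell])) {
        nk <- sum(key[cell] == kk)
        absent <- which(strsplit(kk, "")[[1]] == "0")
        forb <- NULL
        if (length(absent) > 0)
          forb <- do.call(rbind, lapply(mod$cassettes[absent], function(cs)
            data.frame(chrom_id = cs$chrom_id, start = cs$start,
                       end = cs$end, stringsAsFactors = FALSE)))
        segs <- read_start_segments(genome, read_length, forb)
        pos_list[[kk]] <- sample_read_starts(segs, nk)
      }
      pos <- do.call(rbind, pos_list)
      rownames(pos) <- NULL
    }
    seqs <- substr(genome$chromosomes[pos$chrom_id], pos$start + 1L,
                   pos$start + read_length)
    strand <- sample(c("+", "-"), ng, replace = TRUE)
    flip <- strand == "-"
    if (any(flip)) seqs[flip] <- cpp_revcomp(seqs[flip])
    pieces_seq <- c(pieces_seq, unname(seqs))
    pieces_truth[[org]] <- data.frame(
      sample_id = sample$sample_id, origin = toupper(org),
      chrom_id = pos$chrom_id, start = pos$start, strand = strand,
      stringsAsFactors = FALSE)
  }
  nbg <- counts[["bg"]]
  if (nbg > 0) {
    blob <- cpp_random_dna(nbg * read_length, background_gc)
    starts <- (seq_len(nbg) - 1L) * read_length + 1L
    pieces_seq <- c(pieces_seq, substring(blob, starts,
                                          starts + read_length - 1L))
    pieces_truth[["bg"]] <- data.frame(
      sample_id = sample$sample_id, origin = "bg", chrom_id = ".",
      start = -1L, strand = "*", stringsAsFactors = FALSE)[rep(1, nbg), ]
  }
  truth <- do.call(rbind, pieces_truth)
  rownames(truth) <- NULL
  n <- nrow(truth)
  truth$read_id <- sprintf("%s|%s|%s|%d|%06d", truth$sample_id, truth$origin,
                           truth$chrom_id, truth$start, seq_len(n))
  reads <- pieces_seq
  if (error_rate > 0 && n > 0) {
    blob <- cpp_mutate(paste(reads, collapse = ""), error_rate)
    starts <- (seq_len(n) - 1L) * read_length + 1L
    reads <- substring(blob, starts, starts + read_length - 1L)
  }
  names(reads) <- truth$read_id
  truth <- truth[, c("read_id", "sample_id", "origin", "chrom_id", "start",
                     "strand")]
  list(reads = reads, truth = truth)
}
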