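test_that("k-mer index stores every forward seed and honours lookups", {
  g <- toy_genome(chrom_len = 100, gene_bounds = list(c(10L, 60L)), seed = 4)
  idx <- build_index(g, k = 15)
  st <- panrecruit:::cpp_index_stats(idx$ptr)
  expect_equal(st$n_positions, 100 - 15 + 1)  # L - k + 1 forward seeds
  # substring oracle on random draws, forward and reverse strand
  set.seed(6)
  for (i in 1:10) {
    pos <- sample(0:(100 - 15), 1)
    kmer <- substr(g$chromosomes[[1]], pos + 1, pos + 15)
    hits <- kmer_lookup(idx, kmer)
    fwd <- hits[hits$strand == "+", ]
    expect_true(pos %in% fwd$pos)
    for (j in seq_len(nrow(fwd)))
      expect_identical(substr(g$chromosomes[[fwd$chrom_id[j]]],
                              fwd$pos[j] + 1, fwd$pos[j] + 15), kmer)
    rc_hits <- kmer_lookup(idx, revcomp_str(kmer))
    expect_true(pos %in% rc_hits$pos[rc_hits$strand == "-"])
  }
  # absent k-mer (left out of a small alphabet draw is hard; use a k-mer
  # from an unrelated random sequence and verify the substring oracle)
  probe <- strrep("AC", 8)
  probe <- substr(probe, 1, 15)
  hits <- kmer_lookup(idx, probe)
  for (j in seq_len(nrow(hits))) {
    s <- substr(g$chromosomes[[hits$chrom_id[j]]], hits$pos[j] + 1,
                hits$pos[j] + 15)
    expect_true(s == probe || s == revcomp_str(probe))
  }
  expect_error(build_index(g, k = 150), "k")
  expect_error(build_index(g, k = 5), "k must be")
})

test_that("exact and mutated reads map to the planted locus", {
  p <- default_pair()
  idx_a <- build_index(p$genome_a)
  idx_b <- build_index(p$genome_b)
  read <- substr(p$genome_a$chromosomes[["chr1"]], 1001, 1100)
  h <- map_read(read, idx_a, idx_b)
  expect_equal(h$a_identity, 100)
  expect_equal(h$a_start, 1000)
  expect_identical(h$a_chrom, "chr1")
  # five substitutions: identity 95.0
  r5 <- read
  for (pos in c(5, 25, 45, 65, 85))
    substr(r5, pos, pos) <- chartr("ACGT", "CAGT",
                                   chartr("ACGT", "GTAC",
                                          substr(r5, pos, pos)))
  mism <- sum(charToRaw(r5) != charToRaw(read))
  h5 <- map_read(r5, idx_a, idx_b)
  expect_equal(h5$a_identity, 100 - mism)
  expect_equal(h5$a_start, 1000)
  expect_error(map_read(substr(read, 1, 10), idx_a), "shorter")
})

test_that("a read and its reverse complement give the same placement", {
  p <- default_pair()
  idx_a <- build_index(p$genome_a)
  set.seed(12)
  starts <- sample(0:(50000 - 100), 25)
  reads <- substr(rep(p$genome_a$chromosomes[["chr3"]], 25), starts + 1,
                  starts + 100)
  h_f <- map_reads(reads, idx_a)
  h_r <- map_reads(unname(revcomp_str(reads)), idx_a)
  expect_equal(h_f$a_chrom, h_r$a_chrom)
  expect_equal(h_f$a_start, h_r$a_start)
  expect_equal(h_f$a_identity, h_r$a_identity)
  expect_true(all(h_f$a_strand != h_r$a_strand))
})

test_that("reads from one genome recruit to it, and the filter partitions", {
  p <- default_pair()
  idx_a <- build_index(p$genome_a)
  idx_b <- build_index(p$genome_b)
  set.seed(13)
  n <- 2000
  chrom <- sample(names(p$genome_a$chromosomes), n, replace = TRUE)
  starts <- sample(0:(50000 - 100), n, replace = TRUE)
  reads <- substr(p$genome_a$chromosomes[chrom], starts + 1, starts + 100)
  hits <- map_reads(unname(reads), idx_a, idx_b)
  best_a <- !is.na(hits$a_identity) &
    (is.na(hits$b_identity) | hits$a_identity >= hits$b_identity)
  expect_gte(mean(best_a), 0.99)
  recs <- competitive_filter(hits)
  expect_false(anyNA(recs$status))
  expect_equal(sum(table(recs$status)), n)  # exhaustive partition
  expect_true(all(recs$specific[recs$status %in%
                                  c("specific_a", "specific_b")]))
  expect_false(any(recs$specific[recs$status %in%
                                   c("ambiguous", "unmapped")]))
})

test_that("specificity rules apply the identity margin exactly", {
  fake <- data.frame(read_id = c("r1", "r2", "r3"), read_length = 100L,
                     a_chrom = "chr1", a_start = 0, a_strand = "+",
                     a_matches = c(100L, 99L, 90L),
                     a_identity = c(100, 99, 90),
                     b_chrom = "chr1", b_start = 0, b_strand = "+",
                     b_matches = c(78L, 98L, 80L),
                     b_identity = c(78, 98, 80),
                     stringsAsFactors = FALSE)
  attr(fake, "genome_ids") <- c(a = "A", b = "B")
  recs <- competitive_filter(fake, recruit_params())
  # 100 vs 78 (margin 3): specific; 99 vs 98: ambiguous; 90: below min_identity
  expect_equal(as.character(recs$status),
               c("specific_a", "ambiguous", "unmapped"))
})

test_that("recruitment profile reports window depth and identity bins", {
  g <- toy_genome(chrom_len = 20000, gene_bounds = list(c(500L, 1400L)),
                  seed = 21)
  none <- data.frame(read_id = character(0), status = character(0),
                     genome_id = character(0), chrom_id = character(0),
                     start = numeric(0), strand = character(0),
                     aligned_length = integer(0), identity = numeric(0),
                     best_other_identity = numeric(0), specific = logical(0),
                     stringsAsFactors = FALSE)
  prof0 <- recruitment_profile(none, g, window = 1000)
  expect_true(all(prof0$depth$depth == 0))
  one <- data.frame(read_id = "r1", status = "specific_a", genome_id = "T",
                    chrom_id = "chr1", start = 100, strand = "+",
                    aligned_length = 100L, identity = 99,
                    best_other_identity = NA_real_, specific = TRUE,
                    stringsAsFactors = FALSE)
  prof1 <- recruitment_profile(one, g, window = 1000)
  expect_equal(prof1$depth$depth[1], 0.1)  # 100 aligned bases / 1000
  expect_equal(prof1$identity_hist$identity_bin, 99L)
  expect_error(recruitment_profile(one, g, window = 0), "window")
  # uniform 10x simulation: most windows within 3 sigma of 10
  set.seed(22)
  n <- 2000  # 2000 * 100 bp / 20 kb = 10x
  starts <- sample(0:(20000 - 100), n, replace = TRUE)
  unif <- data.frame(read_id = sprintf("r%04d", 1:n), status = "specific_a",
                     genome_id = "T", chrom_id = "chr1", start = starts,
                     strand = "+", aligned_length = 100L, identity = 100,
                     best_other_identity = NA_real_, specific = TRUE,
                     stringsAsFactors = FALSE)
  prof <- recruitment_profile(unif, g, window = 1000)
  sigma <- sqrt(10 * 100 / 1000)
  inner <- prof$depth$depth
  expect_gte(mean(abs(inner - 10) <= 3 * sigma), 0.9)
})
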