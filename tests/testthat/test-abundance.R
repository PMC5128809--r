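rec_row <- function(read_id, sample_id, chrom = "chr1", start,
                    genome_id = "T", len = 100L, specific = TRUE) {
  data.frame(read_id = read_id, status = "specific_a",
             genome_id = genome_id, chrom_id = chrom, start = start,
             strand = "+", aligned_length = len, identity = 99,
             best_other_identity = NA_real_, specific = specific,
             sample_id = sample_id, stringsAsFactors = FALSE)
}

test_that("reads are assigned to genes by start position", {
  g <- toy_genome()  # genes [500,1000) and [1200,1700) on a 2 kb chromosome
  empty <- rec_row("r", "s1", start = 0)[0, ]
  gsm0 <- gene_read_counts(empty, g, "s1")
  expect_true(all(gsm0$counts == 0))
  recs <- rbind(
    rec_row("r1", "s1", start = 600),   # fully inside gene 1
    rec_row("r2", "s1", start = 950),   # starts in gene 1, ends outside
    rec_row("r3", "s1", start = 1150),  # intergenic start: no gene
    rec_row("r4", "s1", start = 250))   # intergenic
  gsm <- gene_read_counts(recs, g, "s1")
  expect_equal(unname(gsm$counts[, "s1"]), c(2L, 0L))
  expect_equal(unname(gsm$genome_total["s1"]), 4L)
  # covered fraction: 100/500 for one fully-contained read
  gsm1 <- gene_read_counts(rec_row("r1", "s1", start = 600), g, "s1")
  expect_equal(unname(gsm1$covered["T_g01", "s1"]), 0.2)
  expect_equal(unname(gsm1$depth["T_g01", "s1"]), 100 / 500)
  bad <- rec_row("r9", "s1", chrom = "chrZ", start = 5)
  expect_error(gene_read_counts(bad, g, "s1"), "unknown chromosome")
})

test_that("uniform coverage recovers the simulated depth per gene", {
  g <- toy_genome(chrom_len = 30000,
                  gene_bounds = lapply(seq(1000, 26000, by = 2500),
                                       function(s) c(s, s + 900L)))
  set.seed(51)
  n <- 3000  # 3000 * 100 / 30000 = 10x
  recs <- rec_row(sprintf("r%04d", 1:n), "s1",
                  start = sample(0:(30000 - 100), n, replace = TRUE))
  gsm <- gene_read_counts(recs, g, "s1")
  sigma <- sqrt(10 * 100 / 900)
  expect_true(all(abs(gsm$depth[, "s1"] - 10) <= 3 * sigma))
  expect_lt(abs(mean(gsm$depth[, "s1"]) - 10), 1)
  # column-sum invariant: genic counts never exceed the genome total
  expect_lte(sum(gsm$counts[, "s1"]), gsm$genome_total[["s1"]])
})

test_that("detection applies the read and coverage thresholds jointly", {
  counts <- matrix(c(0L, 5L, 2L, 1L), 4, 1,
                   dimnames = list(sprintf("g%d", 1:4), "s1"))
  covered <- matrix(c(0, 0.6, 0.2, 0.9), 4, 1, dimnames = dimnames(counts))
  gsm <- toy_gsm(counts, covered)
  det <- detect_genes(gsm, threshold_config())
  expect_equal(unname(det[, 1]), c(FALSE, TRUE, TRUE, FALSE))
  # monotonicity: a stricter read threshold never enlarges the detected set
  set.seed(8)
  counts <- matrix(rpois(300, 2), 30, 10,
                   dimnames = list(sprintf("g%02d", 1:30),
                                   sprintf("s%02d", 1:10)))
  covered <- matrix(runif(300), 30, 10, dimnames = dimnames(counts))
  gsm2 <- toy_gsm(counts, covered)
  d1 <- detect_genes(gsm2, threshold_config(detect_min_reads = 2))
  d2 <- detect_genes(gsm2, threshold_config(detect_min_reads = 4))
  expect_true(all(d1 | !d2))
})

test_that("relative abundance is specific reads over sample totals", {
  counts <- matrix(c(300L, 150L), 2, 1,
                   dimnames = list(c("A_g001", "A_g002"), "s1"))
  gsm_a <- toy_gsm(counts, genome_total = c(s1 = 500L), genome_id = "A")
  gsm_b <- toy_gsm(counts * 0L, genome_total = c(s1 = 0L), genome_id = "B")
  g <- toy_genome("A")
  rownames(gsm_a$counts) <- rownames(gsm_b$counts) <- g$genes$gene_id
  ab <- relative_abundance(gsm_a, gsm_b, c(s1 = 10000),
                           conserved = list(gene_a = character(0),
                                            gene_b = character(0)),
                           genomes = list(a = g, b = g),
                           mask_correct = FALSE)
  expect_equal(ab$abund_a, 5.0)  # 500 / 10000
  expect_equal(ab$abund_b, 0)
  expect_equal(ab$share_a, 1)
  # all reads ambiguous: zero abundance for both genomes
  gsm_a0 <- toy_gsm(counts * 0L, genome_total = c(s1 = 0L), genome_id = "A")
  ab0 <- relative_abundance(gsm_a0, gsm_b, c(s1 = 10000),
                            conserved = list(gene_a = character(0),
                                             gene_b = character(0)),
                            genomes = list(a = g, b = g))
  expect_equal(ab0$abund_a + ab0$abund_b, 0)
  expect_error(relative_abundance(gsm_a, gsm_b, c(zz = 1),
                                  conserved = list(gene_a = character(0),
                                                   gene_b = character(0)),
                                  genomes = list(a = g, b = g)),
               "totals missing")
  # conserved-gene reads leave the numerator
  ab_m <- relative_abundance(gsm_a, gsm_b, c(s1 = 10000),
                             conserved = list(gene_a = "A_g01",
                                              gene_b = character(0)),
                             genomes = list(a = g, b = g),
                             mask_correct = FALSE)
  expect_equal(ab_m$abund_a, (500 - 300) / 10000 * 100)
})

test_that("dominance classes follow the printed rules", {
  cfg <- threshold_config()
  expect_equal(as.character(classify_dominance(0.50, 0.10, cfg)),
               "A_dominant")   # share 0.833
  expect_equal(as.character(classify_dominance(0.020, 0.018, cfg)),
               "co_occurring") # shares 0.526 / 0.474
  expect_equal(as.character(classify_dominance(0.004, 0.002, cfg)),
               "below_floor")  # sum 0.006 <= 0.01
  expect_equal(as.character(classify_dominance(0.65, 0.35, cfg)), "mixed")
})

test_that("sample completeness gates on the 98% detection fraction", {
  det <- matrix(FALSE, 100, 3,
                dimnames = list(sprintf("g%03d", 1:100),
                                c("s1", "s2", "s3")))
  det[1:98, "s1"] <- TRUE
  det[1:97, "s2"] <- TRUE
  g <- toy_genome()
  sc <- sample_completeness(det, g, character(0), threshold_config())
  expect_equal(sc$fraction_detected, c(0.98, 0.97, 0))
  expect_equal(sc$eligible, c(TRUE, FALSE, FALSE))
  # conserved genes leave numerator and denominator
  det2 <- det
  det2[99:100, "s2"] <- TRUE  # 99 of 100 detected, 97 of 98 non-conserved
  sc2 <- sample_completeness(det2, g, c("g099", "g100"), threshold_config())
  expect_equal(sc2$fraction_detected[2], 97 / 98)
})
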