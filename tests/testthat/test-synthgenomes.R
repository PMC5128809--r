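small_spec <- function(conserved_gene_count = 2, ...) {
  genome_pair_spec(n_chromosomes = 2, chromosome_length = 10000,
                   genes_per_chromosome = 6,
                   conserved_gene_count = conserved_gene_count, ...)
}

test_that("a fixed seed reproduces the genome pair byte for byte", {
  p1 <- simulate_genome_pair(small_spec(seed = 7))
  p2 <- simulate_genome_pair(small_spec(seed = 7))
  expect_identical(p1$genome_a, p2$genome_a)
  expect_identical(p1$genome_b, p2$genome_b)
  expect_identical(p1$orthologs, p2$orthologs)
  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  dir.create(d1, showWarnings = FALSE); dir.create(d2, showWarnings = FALSE)
  write_annotated_genome(p1$genome_a, file.path(d1, "a.fna"),
                         file.path(d1, "a.gff3"))
  write_annotated_genome(p2$genome_a, file.path(d2, "a.fna"),
                         file.path(d2, "a.gff3"))
  expect_identical(readLines(file.path(d1, "a.fna")),
                   readLines(file.path(d2, "a.fna")))
  expect_identical(readLines(file.path(d1, "a.gff3")),
                   readLines(file.path(d2, "a.gff3")))
})

test_that("zero divergence gives identical ortholog sequences", {
  p <- simulate_genome_pair(small_spec(target_nt_identity = 1,
                                       conserved_gene_count = 0, seed = 3))
  sa <- gene_sequences(p$genome_a)
  sb <- gene_sequences(p$genome_b)
  ids <- mapply(function(a, b) mean(charToRaw(sa[[a]]) == charToRaw(sb[[b]])),
                p$orthologs$gene_a, p$orthologs$gene_b)
  expect_equal(unname(ids), rep(1, nrow(p$orthologs)))
})

test_that("planted ortholog identity matches the divergence target", {
  p <- default_pair()  # target 0.78
  sa <- gene_sequences(p$genome_a)
  sb <- gene_sequences(p$genome_b)
  o <- p$orthologs
  ids <- 100 * mapply(function(a, b)
    mean(charToRaw(sa[[a]]) == charToRaw(sb[[b]])), o$gene_a, o$gene_b)
  expect_lt(abs(mean(ids[!o$conserved]) - 78), 2)
  expect_true(all(ids[o$conserved] > 99))
})

test_that("genome annotation invariants hold across seeds", {
  for (s in c(1, 17, 23)) {
    p <- simulate_genome_pair(small_spec(seed = s))
    expect_true(panrecruit:::validate_annotated_genome(p$genome_a))
    expect_true(panrecruit:::validate_annotated_genome(p$genome_b))
    g <- p$genome_a$genes
    expect_true(all(g$outlier_flag == (g$chrom_id == "chr2")))
  }
})

test_that("the outlier chromosome has measurably lower GC and shorter genes", {
  p <- default_pair()
  gc <- gc_content(p$genome_a)
  out_chr <- unique(p$genome_a$genes$chrom_id[p$genome_a$genes$outlier_flag])
  expect_true(all(gc[out_chr] < gc[setdiff(names(gc), out_chr)]))
  g <- p$genome_a$genes
  expect_lt(mean((g$end - g$start)[g$outlier_flag]),
            mean((g$end - g$start)[!g$outlier_flag]))
})

test_that("an overfull chromosome raises a sizing error", {
  expect_error(simulate_genome_pair(
    genome_pair_spec(n_chromosomes = 1, chromosome_length = 1000,
                     genes_per_chromosome = 2, gene_length = 600,
                     outlier_gene_length_factor = 1,
                     conserved_gene_count = 0, seed = 1)),
    "too short")
})

test_that("per-cell cassette carriage follows the carrier frequency", {
  p <- simulate_genome_pair(small_spec(seed = 5))
  g1 <- p$genome_a$genes[p$genome_a$genes$chrom_id == "chr1", ]
  cassette <- list(chrom_id = "chr1", gene_ids = g1$gene_id[2:4])
  for (f in c(0, 1)) {
    m <- population_model(p$genome_a, list(c(cassette,
                                             carrier_frequency = f)))
    gt <- apply_population_variants(p$genome_a, m, 500, seed = 11)
    expect_equal(unname(colMeans(gt)), f)
  }
  m <- population_model(p$genome_a, list(c(cassette,
                                           carrier_frequency = 0.5)))
  gt <- apply_population_variants(p$genome_a, m, 10000, seed = 11)
  expect_lt(abs(mean(gt) - 0.5), 0.02)
})

test_that("a non-contiguous cassette definition is rejected", {
  p <- simulate_genome_pair(small_spec(seed = 5))
  g1 <- p$genome_a$genes[p$genome_a$genes$chrom_id == "chr1", ]
  expect_error(population_model(p$genome_a, list(
    list(chrom_id = "chr1", gene_ids = g1$gene_id[c(1, 3)],
         carrier_frequency = 0.5))), "contiguous")
})

test_that("station series honours the link and the mixture constraints", {
  # zero coefficients: constant genome-B share
  pr0 <- simulate_station_series(
    12, niche_params(beta0 = 0.4, beta_temp = 0, beta_depth = 0,
                     beta_ecotype = 0, total_fraction_range = c(0.02, 0.02)),
    seed = 2)
  share <- pr0$true_fraction_b / (pr0$true_fraction_a + pr0$true_fraction_b)
  expect_equal(share, rep(plogis(0.4), 12))
  # fractions are a partition of the read pool
  pr <- simulate_station_series(30, niche_params(), seed = 3)
  expect_equal(pr$true_fraction_a + pr$true_fraction_b +
                 pr$background_fraction, rep(1, 30))
  # planted 3 degC offset between latent ecotypes, sd 2
  pr2 <- simulate_station_series(200, niche_params(), seed = 4)
  d <- mean(pr2$temperature[pr2$ecotype == "B"]) -
    mean(pr2$temperature[pr2$ecotype == "A"])
  expect_lt(abs(d - 3), 1.5)
  expect_error(simulate_station_series(1), "at least 2")
})

test_that("read simulation respects origins, errors and cassette absence", {
  p <- simulate_genome_pair(small_spec(seed = 5))
  genomes <- list(a = p$genome_a, b = p$genome_b)
  prof <- list(sample_id = "sX", total_reads = 20000L,
               true_fraction_a = 0.05, true_fraction_b = 0,
               background_fraction = 0.95)
  rs <- simulate_reads(prof, genomes, read_length = 100, error_rate = 0,
                       seed = 8)
  expect_equal(length(rs$reads), 20000L)
  expect_false(any(rs$truth$origin == "B"))
  # error-free reads equal the reference substring at their recorded origin
  ta <- rs$truth[rs$truth$origin == "A", ][1:50, ]
  for (i in seq_len(nrow(ta))) {
    ref <- substr(p$genome_a$chromosomes[[ta$chrom_id[i]]],
                  ta$start[i] + 1, ta$start[i] + 100)
    obs <- unname(rs$reads[ta$read_id[i]])
    if (ta$strand[i] == "-") obs <- unname(revcomp_str(obs))
    expect_identical(obs, ref)
  }
  # origin counts are multinomial around the planted fraction
  n_a <- sum(rs$truth$origin == "A")
  expect_lt(abs(n_a - 1000), 3 * sqrt(20000 * 0.05 * 0.95))
  # reads from non-carrier cells never overlap the absent cassette
  g1 <- p$genome_a$genes[p$genome_a$genes$chrom_id == "chr1", ]
  mod <- population_model(p$genome_a, list(
    list(chrom_id = "chr1", gene_ids = g1$gene_id[2:4],
         carrier_frequency = 0)))
  gt <- apply_population_variants(p$genome_a, mod, 50, seed = 1)
  rs2 <- simulate_reads(prof, genomes, genotypes = list(a = gt, b = NULL),
                        models = list(a = mod, b = NULL), read_length = 100,
                        error_rate = 0.01, seed = 9)
  cs <- mod$cassettes[[1]]
  ta2 <- rs2$truth[rs2$truth$origin == "A" & rs2$truth$chrom_id == "chr1", ]
  overlaps <- ta2$start < cs$end & (ta2$start + 100) > cs$start
  expect_false(any(overlaps))
  expect_error(simulate_reads(prof, genomes, error_rate = 0.5), "error_rate")
})

test_that("expression signal follows the activation probability", {
  p <- simulate_genome_pair(small_spec(seed = 5))
  genes <- p$genome_a$genes
  sids <- sprintf("s%02d", 1:10)
  e1 <- simulate_expression(genes, sids, active_fraction = 1, seed = 2)
  expect_true(all(e1$expressed))
  e0 <- simulate_expression(genes, sids, active_fraction = 0, seed = 2)
  expect_false(any(e0$expressed))
  e <- simulate_expression(genes, sids, active_fraction = 0.6, seed = 2)
  per_gene <- rowSums(e$expressed)
  expect_true(all(abs(per_gene - 6) <= 3 * sqrt(10 * 0.6 * 0.4) + 1e-9))
  expect_true(all(e$activity >= 0 & e$activity <= 1))
})
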