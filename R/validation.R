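# End-to-end validation scenarios: each builds a synthetic study with known
# ground truth, runs the analysis through the package's public surface, and
# returns the measured recovery quantities. The testthat suite asserts on
# these numbers and scripts/acceptance.R reports them.

abundance_from_truth <- function(profiles, cfg = threshold_config()) {
  ab <- data.frame(sample_id = profiles$sample_id,
                   abund_a = 100 * profiles$true_fraction_a,
                   abund_b = 100 * profiles$true_fraction_b,
                   stringsAsFactors = FALSE)
  ab$share_a <- ifelse(ab$abund_a + ab$abund_b > 0,
                       ab$abund_a / (ab$abund_a + ab$abund_b), NA)
  ab$share_b <- 1 - ab$share_a
  ab$class <- classify_dominance(ab$abund_a, ab$abund_b, cfg)
  structure(ab, class = c("abundance_table", "data.frame"))
}

# exact two-sided MWW p by complete enumeration (tie-free inputs);
# independent oracle for the wilcox-based mww_test
enumerate_mww <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  u_of <- function(x, y) sum(outer(x, y, ">"))
  u_obs <- u_of(a, b)
  u_null <- apply(utils::combn(length(pooled), na), 2, function(idx)
    u_of(pooled[idx], pooled[-idx]))
  list(U = u_obs,
       p_value = min(1, 2 * min(mean(u_null <= u_obs),
                                mean(u_null >= u_obs))))
}

#' Mixture-recovery benchmark
#'
#' Simulates the default survey (30 samples, 100,000 reads of 100 bp at 1%
#' substitution error, per-genome true fractions between 0 and 3%), runs the
#' full recruitment pipeline, and compares estimated relative genomic
#' abundances with the planted mixture fractions.
#'
#' @param seed integer seed.
#' @param n_samples,total_reads scenario size.
#' @return List: `table` (per sample and genome: truth and estimate, both in
#'   percent), `pearson_r` (truth vs estimate, pooled over genomes),
#'   `max_rel_err` and `median_rel_err` (relative errors where truth >=
#'   0.1%), `n`.
#' @export
validate_mixture <- function(seed = 1, n_samples = 30, total_reads = 1e5) {
  study <- simulate_study(
    genome_pair_spec(seed = seed + 1),
    n_samples = n_samples,
    niche = niche_params(total_reads = total_reads,
                         total_fraction_range = c(0, 0.03)),
    read_length = 100, error_rate = 0.01, seed = seed + 2)
  res <- run_survey(study)
  tab <- data.frame(
    sample_id = rep(study$profiles$sample_id, 2),
    genome = rep(c("A", "B"), each = n_samples),
    truth = 100 * c(study$profiles$true_fraction_a,
                    study$profiles$true_fraction_b),
    estimate = c(res$abundance$abund_a, res$abundance$abund_b),
    stringsAsFactors = FALSE)
  sel <- tab$truth >= 0.1
  rel <- abs(tab$estimate[sel] - tab$truth[sel]) / tab$truth[sel]
  list(table = tab, abundance = res$abundance,
       pearson_r = cor(tab$truth, tab$estimate),
       max_rel_err = max(rel), median_rel_err = median(rel),
       n = sum(sel))
}

#' Conserved-gene specificity benchmark
#'
#' Draws reads strictly inside the planted >99%-identity conserved genes and
#' checks that the competitive filter flags them ambiguous, and that the
#' orthology stage recovers exactly the planted conserved set (the mask the
#' abundance numerator excludes).
#'
#' @param seed integer seed.
#' @param n_reads reads drawn from conserved gene intervals.
#' @return List: `ambiguous_fraction`, `set_equal_a`, `set_equal_b`,
#'   `n_conserved_true`, `n_conserved_called`, `n`.
#' @export
validate_specificity <- function(seed = 1, n_reads = 2000) {
  pair <- simulate_genome_pair(genome_pair_spec(seed = seed + 1))
  orth <- find_orthologs(pair$genome_a, pair$genome_b)
  cons <- conserved_genes(orth)
  truth <- pair$orthologs
  genes <- pair$genome_a$genes
  cg <- genes[genes$gene_id %in% truth$gene_a[truth$conserved], ]
  set.seed(seed + 2)
  pick <- sample(nrow(cg), n_reads, replace = TRUE)
  starts <- cg$start[pick] +
    floor(runif(n_reads) * (cg$end[pick] - cg$start[pick] - 100 + 1))
  reads <- substr(pair$genome_a$chromosomes[cg$chrom_id[pick]],
                  starts + 1, starts + 100)
  reads <- vapply(reads, cpp_mutate, "", rate = 0.01, USE.NAMES = FALSE)
  idx_a <- build_index(pair$genome_a)
  idx_b <- build_index(pair$genome_b)
  recs <- competitive_filter(map_reads(reads, idx_a, idx_b))
  list(ambiguous_fraction = mean(recs$status == "ambiguous"),
       set_equal_a = setequal(cons$gene_a, truth$gene_a[truth$conserved]),
       set_equal_b = setequal(cons$gene_b, truth$gene_b[truth$conserved]),
       n_conserved_true = sum(truth$conserved),
       n_conserved_called = length(cons$gene_a),
       n = n_reads)
}

#' Dominance-rule benchmark on hand-built boundary cases
#'
#' Twelve abundance pairs covering every boundary of the printed rules: the
#' strict 70% dominance share, the inclusive 40-60% co-occurrence window,
#' and the strict 0.01% abundance floor.
#'
#' @return List: `table` (abundances, expected and assigned class),
#'   `n_correct`, `n`.
#' @export
validate_dominance_rules <- function() {
  cases <- data.frame(
    abund_a = c(0.50, 0.10, 0.020, 0.018, 0.004, 0.008, 0.009, 0.70,
                0.701, 0.60, 0.65, 0),
    abund_b = c(0.10, 0.50, 0.018, 0.020, 0.002, 0.002, 0.0011, 0.30,
                0.299, 0.40, 0.35, 0),
    expected = c("A_dominant", "B_dominant", "co_occurring", "co_occurring",
                 "below_floor", "below_floor", "A_dominant", "mixed",
                 "A_dominant", "co_occurring", "mixed", "below_floor"),
    stringsAsFactors = FALSE)
  cases$assigned <- as.character(
    classify_dominance(cases$abund_a, cases$abund_b, threshold_config()))
  list(table = cases, n_correct = sum(cases$assigned == cases$expected),
       n = nrow(cases))
}

# shared scaffolding of the cassette scenarios: cassettes placed away from
# conserved genes, genome A dominating each sample so its genes sit at the
# requested coverage
cassette_study <- function(seed, n_samples, freqs_fn, total_reads,
                           genome_spec, chroms, sizes, near_end) {
  pair0 <- simulate_genome_pair(genome_spec)
  defs <- lapply(seq_along(chroms), function(i)
    list(chrom_id = chroms[i],
         ranks = pick_cassette_ranks(pair0$genome_a, chroms[i], sizes[i],
                                     near_end = near_end[i]),
         freq = freqs_fn(i)))
  simulate_study(
    genome_spec, cassettes = defs, n_samples = n_samples,
    niche = niche_params(beta_temp = 0, beta_depth = 0, beta_ecotype = 0,
                         beta0 = -3, total_fraction_range = c(0.75, 0.75),
                         total_reads = total_reads),
    read_length = 100, error_rate = 0.01, n_cells = 200,
    active_fraction = 1, seed = seed)
}

#' Dispensable-gene recovery benchmark
#'
#' Plants three cassettes (2, 3 and 7 genes; the 7-gene block at the outlier
#' chromosome end) across 14 eligible samples at >=10x genome-A coverage,
#' each cassette fully absent from 6 samples, and scores the dispensable
#' calls at the printed filter thresholds (detected in >=4, absent in >=5,
#' expressed in >=6 samples). The completeness gate is scaled to 0.85 for
#' this desk-scale genome, where the planted cassettes are 10% of all genes
#' (the 0.98 default reflects real genomes where dispensable genes are ~2%).
#'
#' @param seed integer seed.
#' @return List: `precision`, `recall`, `n_called`, `n_planted`,
#'   `cassettes` (called cassette table), `cassette_exact` (called
#'   memberships equal planted memberships), `n_eligible`.
#' @export
validate_dispensable <- function(seed = 1) {
  n <- 14
  absent <- list(1:6, 5:10, 8:13)
  freqs_fn <- function(i) {
    f <- rep(1, n)
    f[absent[[i]]] <- 0
    f
  }
  study <- cassette_study(seed + 3, n, freqs_fn, total_reads = 40000,
                          genome_spec = genome_pair_spec(seed = seed + 1),
                          chroms = c("chr2", "chr3", "chr4"),
                          sizes = c(2, 3, 7),
                          near_end = c(FALSE, FALSE, TRUE))
  cfg <- threshold_config(completeness_min = 0.85)
  res <- run_survey(study, cfg = cfg, do_pangenome = TRUE)
  truth_ids <- study$pair$genome_a$genes$gene_id[
    study$pair$genome_a$genes$dispensable_truth]
  called <- res$dispensable_a$gene_id[res$dispensable_a$dispensable]
  planted_sets <- lapply(study$cassettes, `[[`, "gene_ids")
  called_sets <- strsplit(res$cassettes_a$cassettes$genes, ",")
  list(precision = if (length(called)) mean(called %in% truth_ids) else NA,
       recall = mean(truth_ids %in% called),
       n_called = length(called), n_planted = length(truth_ids),
       cassettes = res$cassettes_a$cassettes,
       singletons = res$cassettes_a$singletons,
       cassette_exact = length(called_sets) == length(planted_sets) &&
         all(vapply(planted_sets, function(s)
           any(vapply(called_sets, setequal, TRUE, s)), TRUE)),
       n_eligible = length(res$eligible_a))
}

#' Sub-population depletion benchmark
#'
#' A three-gene cassette at carrier frequency 0.5 over a 20x genome-A
#' baseline, replicated across independent samples; measures the depletion
#' ratio and state of the cassette genes.
#'
#' @param seed integer seed.
#' @param n_rep number of replicate samples.
#' @return List: `ratios` (per replicate, mean over cassette genes),
#'   `partial_fraction` (replicates with every cassette gene "partial"),
#'   `mean_ratio`, `in_band_fraction` (mean ratio within 0.5 +/- 0.15), `n`.
#' @export
validate_depletion <- function(seed = 1, n_rep = 50) {
  gs <- genome_pair_spec(n_chromosomes = 2, genes_per_chromosome = 25,
                         conserved_gene_count = 3, seed = seed + 1)
  study <- cassette_study(seed + 3, n_rep, function(i) 0.5,
                          total_reads = 25000, genome_spec = gs,
                          chroms = "chr1", sizes = 3, near_end = FALSE)
  res <- run_survey(study)
  cas <- study$cassettes[[1]]
  disp_ids <- study$pair$genome_a$genes$gene_id[
    study$pair$genome_a$genes$dispensable_truth]
  per_rep <- vapply(study$profiles$sample_id, function(sid) {
    d <- lapply(cas$gene_ids, function(g)
      depletion_profile(res$gsm_a, study$pair$genome_a, g, sid, disp_ids))
    d <- do.call(rbind, d)
    c(ratio = mean(d$depletion_ratio),
      all_partial = as.numeric(all(d$state == "partial")))
  }, numeric(2))
  ratios <- per_rep["ratio", ]
  list(ratios = unname(ratios),
       partial_fraction = mean(per_rep["all_partial", ] == 1),
       mean_ratio = mean(ratios),
       in_band_fraction = mean(abs(ratios - 0.5) <= 0.15),
       n = n_rep)
}

#' Cassette-border consistency benchmark
#'
#' A three-gene cassette fully absent from 6 of 8 samples at 20x coverage;
#' breakpoints are re-estimated from 200-bp windowed depth tracks in every
#' absent sample and compared with the planted cassette edges.
#'
#' @param seed integer seed.
#' @param window window width in bases.
#' @return List: `estimates`, `true_start`, `true_end`, `max_edge_error`
#'   (largest |estimate - truth| over samples and edges, bases),
#'   `max_deviation` (largest pairwise spread between samples, bases),
#'   `window`, `n_absent`.
#' @export
validate_borders <- function(seed = 1, window = 200) {
  n <- 8
  absent <- 1:6
  gs <- genome_pair_spec(n_chromosomes = 2, genes_per_chromosome = 25,
                         conserved_gene_count = 3, seed = seed + 1)
  freqs_fn <- function(i) {
    f <- rep(1, n)
    f[absent] <- 0
    f
  }
  study <- cassette_study(seed + 3, n, freqs_fn, total_reads = 25000,
                          genome_spec = gs, chroms = "chr1", sizes = 3,
                          near_end = FALSE)
  res <- run_survey(study, window = window)
  cas <- study$cassettes[[1]]
  bc <- border_consistency(
    res$tracks_a[study$profiles$sample_id[absent]], cas, window = window)
  err <- abs(bc$estimates$position -
               ifelse(bc$estimates$edge == "start", cas$start, cas$end))
  list(estimates = bc$estimates, true_start = cas$start,
       true_end = cas$end, max_edge_error = max(err),
       max_deviation = bc$max_deviation, window = window,
       n_absent = length(absent))
}

#' Rank-test correctness benchmark
#'
#' Compares [mww_test()] with complete-enumeration oracles on random
#' tie-free instances and measures the type-I error rate on null samples.
#'
#' @param seed integer seed.
#' @param n_instances random small instances for the enumeration check.
#' @param n_null null replicates (n = 8 vs 8) for the type-I error rate.
#' @return List: `agreement` (fraction of instances with exactly matching U
#'   and p), `type1_rate` (fraction of null replicates with p < 0.05),
#'   `n_instances`, `n_null`.
#' @export
validate_mww <- function(seed = 1, n_instances = 200, n_null = 1000) {
  set.seed(seed + 1)
  agree <- logical(n_instances)
  for (i in seq_len(n_instances)) {
    na <- sample(1:5, 1)
    nb <- sample(1:5, 1)
    v <- sample(10000, na + nb)
    a <- v[seq_len(na)]
    b <- v[-seq_len(na)]
    r <- mww_test(a, b)
    o <- enumerate_mww(a, b)
    agree[i] <- r$U == o$U && abs(r$p_value - o$p_value) < 1e-12
  }
  set.seed(seed + 2)
  p_null <- replicate(n_null, mww_test(rnorm(8), rnorm(8))$p_value)
  list(agreement = mean(agree), type1_rate = mean(p_null < 0.05),
       n_instances = n_instances, n_null = n_null)
}

#' Niche-recovery benchmark
#'
#' Replicated station series with the planted 3 degC offset (sd 2) between
#' the two genome-dominant groups; measures the power of the temperature
#' contrast and the recovered mean difference.
#'
#' @param seed integer seed.
#' @param n_rep replicates.
#' @param n_samples samples per replicate (two balanced latent groups).
#' @return List: `power` (fraction of replicates with two-sided p < 0.05),
#'   `mean_diff` (mean recovered B - A temperature difference, degC),
#'   `planted_diff`, `n_rep`.
#' @export
validate_niche <- function(seed = 1, n_rep = 100, n_samples = 30) {
  out <- vapply(seq_len(n_rep), function(i) {
    pr <- simulate_station_series(
      n_samples, niche_params(total_fraction_range = c(0.005, 0.03)),
      seed = seed + 10 + i)
    ab <- abundance_from_truth(pr)
    ns <- niche_summary(ab, pr, parameters = "temperature")
    c(p = ns$p_value, diff = ns$mean_b - ns$mean_a)
  }, numeric(2))
  list(power = mean(out["p", ] < 0.05), mean_diff = mean(out["diff", ]),
       planted_diff = 3, n_rep = n_rep)
}

#' Metabarcode-concordance benchmark
#'
#' Poisson amplicon counts proportional to the summed true genome fractions
#' over 30 stations, correlated against the summed relative genomic
#' abundances.
#'
#' @param seed integer seed.
#' @param n_samples stations.
#' @return List: `spearman_rho`, `pearson_r`, `n`.
#' @export
validate_barcode <- function(seed = 1, n_samples = 30) {
  pr <- simulate_station_series(
    n_samples, niche_params(total_fraction_range = c(0.001, 0.03)),
    seed = seed + 1)
  ab <- abundance_from_truth(pr)
  bc <- simulate_barcode_counts(pr, barcode_total = 1e5, seed = seed + 2)
  barcode_correlation(bc, ab)
}

#' Mapper-vs-exhaustive-alignment benchmark
#'
#' On 5-kb genomes with 60-bp reads, the seeded gapless mapper is provably
#' equivalent to exhaustive all-position alignment at the default thresholds
#' (any placement above 95% identity keeps an intact 15-mer seed); this
#' benchmark verifies the equivalence read by read against a brute-force
#' scorer.
#'
#' @param seed integer seed.
#' @param n_reads reads to check.
#' @return List: `agreement` (fraction of reads whose mapped/unmapped state
#'   and identity match the brute-force optimum on both genomes), `n`.
#' @export
validate_mapper_oracle <- function(seed = 1, n_reads = 500) {
  gs <- genome_pair_spec(n_chromosomes = 1, chromosome_length = 5000,
                         genes_per_chromosome = 4, conserved_gene_count = 0,
                         seed = seed + 1)
  pair <- simulate_genome_pair(gs)
  idx_a <- build_index(pair$genome_a)
  idx_b <- build_index(pair$genome_b)
  len <- 60
  set.seed(seed + 2)
  src <- sample(c("a", "b"), n_reads, replace = TRUE)
  starts <- sample(0:(5000 - len), n_reads, replace = TRUE)
  chrom_a <- pair$genome_a$chromosomes[[1]]
  chrom_b <- pair$genome_b$chromosomes[[1]]
  reads <- ifelse(src == "a", substr(chrom_a, starts + 1, starts + len),
                  substr(chrom_b, starts + 1, starts + len))
  reads <- vapply(reads, cpp_mutate, "", rate = 0.01, USE.NAMES = FALSE)
  hits <- map_reads(reads, idx_a, idx_b)
  # brute-force: best match count over every position and strand
  brute_best <- function(read, chrom) {
    g <- charToRaw(chrom)
    n <- length(g) - len + 1L
    M <- matrix(g[outer(seq_len(n) - 1L, seq_len(len), "+") + 0L], n, len)
    rr <- charToRaw(read)
    rc <- charToRaw(as.character(cpp_revcomp(read)))
    max(max(rowSums(M == matrix(rr, n, len, byrow = TRUE))),
        max(rowSums(M == matrix(rc, n, len, byrow = TRUE))))
  }
  min_id <- recruit_params()$min_identity
  norm <- function(matches) {
    matches <- as.integer(matches)
    ifelse(!is.na(matches) & 100 * matches / len >= min_id, matches,
           NA_integer_)
  }
  ba <- norm(vapply(reads, brute_best, 0, chrom = chrom_a,
                    USE.NAMES = FALSE))
  bb <- norm(vapply(reads, brute_best, 0, chrom = chrom_b,
                    USE.NAMES = FALSE))
  ma <- norm(hits$a_matches)
  mb <- norm(hits$b_matches)
  same <- function(x, y) (is.na(x) & is.na(y)) | (!is.na(x) & !is.na(y) &
                                                    x == y)
  list(agreement = mean(same(ma, ba) & same(mb, bb)), n = n_reads)
}
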