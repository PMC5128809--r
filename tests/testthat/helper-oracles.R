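# Independent oracles and shared fixtures. The oracles deliberately use
# different algorithms (exhaustive scans, combinatorial enumeration) from the
# implementation paths they check.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, fn) {
  if (!exists(name, envir = fixture_cache))
    assign(name, fn(), envir = fixture_cache)
  get(name, envir = fixture_cache)
}

# canonical desk-scale genome pair shared across test files
default_pair <- function() {
  cached("default_pair",
         function() simulate_genome_pair(genome_pair_spec(seed = 101)))
}

default_orthologs <- function() {
  cached("default_orthologs", function() {
    p <- default_pair()
    find_orthologs(p$genome_a, p$genome_b)
  })
}

revcomp_str <- function(s) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(s, function(x)
           paste(rev(strsplit(x, "")[[1]]), collapse = ""), ""))
}

# hand-built annotated genome for unit tests of interval logic
toy_genome <- function(genome_id = "T", chrom_len = 2000,
                       gene_bounds = list(c(500L, 1000L), c(1200L, 1700L)),
                       seed = 99) {
  set.seed(seed)
  chrom <- paste(sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE),
                 collapse = "")
  genes <- data.frame(
    gene_id = sprintf("%s_g%02d", genome_id, seq_along(gene_bounds)),
    chrom_id = "chr1",
    start = vapply(gene_bounds, function(b) as.integer(b[1]), 0L),
    end = vapply(gene_bounds, function(b) as.integer(b[2]), 0L),
    strand = "+", outlier_flag = FALSE, dispensable_truth = FALSE,
    ortholog_id = NA_character_, conserved_truth = FALSE,
    specific_truth = FALSE, stringsAsFactors = FALSE)
  panrecruit:::new_annotated_genome(genome_id, c(chr1 = chrom), genes)
}

# --- brute-force mapping oracle ---------------------------------------------
# best gapless full-length placement of a read over every position of every
# chromosome on both strands: returns the maximum match count

oracle_embed_genome <- function(genome, read_len) {
  lapply(genome$chromosomes, function(chrom) {
    g <- charToRaw(chrom)
    n <- length(g) - read_len + 1L
    matrix(g[outer(seq_len(n) - 1L, seq_len(read_len), "+") + 0L],
           n, read_len)
  })
}

oracle_best_matches <- function(read, embedded) {
  len <- nchar(read)
  rr <- charToRaw(read)
  rc <- charToRaw(revcomp_str(read))
  best <- -1L
  for (M in embedded) {
    n <- nrow(M)
    m1 <- max(rowSums(M == matrix(rr, n, len, byrow = TRUE)))
    m2 <- max(rowSums(M == matrix(rc, n, len, byrow = TRUE)))
    best <- max(best, m1, m2)
  }
  as.integer(best)
}

# --- Mann-Whitney-Wilcoxon enumeration oracle -------------------------------
# exact two-sided p by enumerating every assignment of the pooled values to
# the two groups (tie-free inputs only)

oracle_mww <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  na <- length(a)
  u_of <- function(x, y) sum(outer(x, y, ">"))
  u_obs <- u_of(a, b)
  combos <- utils::combn(length(pooled), na)
  u_null <- apply(combos, 2, function(idx)
    u_of(pooled[idx], pooled[-idx]))
  p_le <- mean(u_null <= u_obs)
  p_ge <- mean(u_null >= u_obs)
  list(U = u_obs, p_value = min(1, 2 * min(p_le, p_ge)))
}

# abundance table built directly from ground-truth fractions (bypassing the
# read level) for statistics-only tests
truth_abundance <- function(profiles, cfg = threshold_config()) {
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

# minimal gene_sample_matrix for rule-level tests
toy_gsm <- function(counts, covered = NULL, depth = NULL,
                    genome_id = "T", genome_total = NULL) {
  if (is.null(covered)) covered <- (counts > 0) * 1
  if (is.null(depth)) depth <- counts / 10
  if (is.null(genome_total)) genome_total <- colSums(counts)
  structure(list(counts = counts, covered = covered, depth = depth,
                 genome_total = genome_total, genome_id = genome_id),
            class = "gene_sample_matrix")
}
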