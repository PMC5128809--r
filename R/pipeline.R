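#' Simulate a full synthetic survey with known ground truth
#'
#' Wires the generator stages together: a cryptic genome pair, a station
#' series with environmental covariates and true mixture fractions, planted
#' dispensable-gene cassettes with per-sample carrier frequencies, and a
#' metatranscriptomic signal. Reads are not generated here (they can be
#' large); [study_sample_reads()] draws them per sample, and [run_survey()]
#' drives the whole analysis.
#'
#' @param genome_spec a [genome_pair_spec()] (its own `seed` controls the
#'   genome pair).
#' @param cassettes optional list of planted cassettes on genome A, each a
#'   list with `chrom_id`, `ranks` (contiguous gene ranks on that
#'   chromosome) and `freq` (carrier frequency: a scalar or one value per
#'   sample).
#' @param n_samples number of samples.
#' @param niche a [niche_params()].
#' @param read_length,error_rate read simulation settings.
#' @param n_cells cells drawn per sample when cassettes are present.
#' @param active_fraction probability of an expression signal for a present
#'   gene.
#' @param seed integer seed driving stations, expression and reads.
#' @return A list of class `synthetic_study`.
#' @export
simulate_study <- function(genome_spec = genome_pair_spec(),
                           cassettes = NULL, n_samples = 30,
                           niche = niche_params(), read_length = 100,
                           error_rate = 0.01, n_cells = 100,
                           active_fraction = 0.8, seed = 1) {
  pair <- simulate_genome_pair(genome_spec)
  profiles <- simulate_station_series(n_samples, niche, seed = seed)
  genes_a <- pair$genome_a$genes
  cass <- list()
  freq <- NULL
  if (!is.null(cassettes) && length(cassettes) > 0) {
    freq <- matrix(1, length(cassettes), n_samples,
                   dimnames = list(sprintf("cassette_%02d",
                                           seq_along(cassettes)),
                                   profiles$sample_id))
    for (i in seq_along(cassettes)) {
      cs <- cassettes[[i]]
      on_chrom <- genes_a[genes_a$chrom_id == cs$chrom_id, , drop = FALSE]
      on_chrom <- on_chrom[order(on_chrom$start), , drop = FALSE]
      stopifnot(all(cs$ranks >= 1), all(cs$ranks <= nrow(on_chrom)),
                identical(as.integer(sort(cs$ranks)),
                          seq(min(cs$ranks), max(cs$ranks))))
      ids <- on_chrom$gene_id[sort(cs$ranks)]
      f <- cs$freq
      if (length(f) == 1) f <- rep(f, n_samples)
      stopifnot(length(f) == n_samples, all(f >= 0), all(f <= 1))
      freq[i, ] <- f
      cass[[i]] <- list(id = rownames(freq)[i], chrom_id = cs$chrom_id,
                        gene_ids = ids,
                        start = min(on_chrom$start[sort(cs$ranks)]),
                        end = max(on_chrom$end[sort(cs$ranks)]))
      if (any(f < 1))
        genes_a$dispensable_truth[genes_a$gene_id %in% ids] <- TRUE
    }
    pair$genome_a$genes <- genes_a
  }
  presence <- matrix(1, nrow(genes_a), n_samples,
                     dimnames = list(genes_a$gene_id, profiles$sample_id))
  if (!is.null(freq))
    for (i in seq_along(cass))
      presence[cass[[i]]$gene_ids, ] <-
        matrix((freq[i, ] > 0) * 1, length(cass[[i]]$gene_ids),
               n_samples, byrow = TRUE)
  expression <- simulate_expression(genes_a, profiles$sample_id,
                                    active_fraction = active_fraction,
                                    presence = presence, seed = seed + 1L)
  structure(list(pair = pair, profiles = profiles, cassettes = cass,
                 cassette_freq = freq, expression = expression,
                 read_length = as.integer(read_length),
                 error_rate = error_rate, n_cells = as.integer(n_cells),
                 background_gc = genome_spec$gc_regular,
                 seed = as.integer(seed)),
            class = "synthetic_study")
}

#' Pick contiguous cassette gene ranks that avoid conserved genes
#'
#' Planted cassettes must not overlap planted conserved genes (conserved
#' genes are masked from the pan-genome analysis). Returns the first -- or,
#' with `near_end = TRUE`, the last -- window of `n_genes` consecutive
#' non-conserved gene ranks on the chromosome.
#'
#' @param genome an `annotated_genome` with a `conserved_truth` column.
#' @param chrom_id chromosome to place the cassette on.
#' @param n_genes cassette length in genes.
#' @param near_end place the cassette at the chromosome end (the typical
#'   location of long dispensable blocks on the outlier chromosome).
#' @return Integer vector of gene ranks on that chromosome.
#' @export
pick_cassette_ranks <- function(genome, chrom_id, n_genes,
                                near_end = FALSE) {
  g <- genome$genes[genome$genes$chrom_id == chrom_id, , drop = FALSE]
  g <- g[order(g$start), , drop = FALSE]
  free <- !g$conserved_truth
  n <- nrow(g)
  starts <- seq_len(n - n_genes + 1)
  ok <- vapply(starts, function(s) all(free[s:(s + n_genes - 1)]),
               logical(1))
  if (!any(ok))
    stop("no conserved-free window of that length on ", chrom_id)
  s <- if (near_end) max(starts[ok]) else starts[ok][ceiling(sum(ok) / 2)]
  seq(s, s + n_genes - 1)
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(paste0("synthetic_study: %d samples, %d planted cassettes, ",
                     "%d bp reads at %.1f%% error\n"),
              nrow(x$profiles), length(x$cassettes), x$read_length,
              100 * x$error_rate))
  print(x$pair)
  invisible(x)
}

#' Draw the read set of one study sample
#'
#' @param study a [simulate_study()] result.
#' @param i sample index (row of `study$profiles`).
#' @return As [simulate_reads()]: list with `reads` and `truth`.
#' @export
study_sample_reads <- function(study, i) {
  profile <- study$profiles[i, ]
  genotypes <- NULL
  models <- NULL
  if (length(study$cassettes) > 0) {
    defs <- lapply(seq_along(study$cassettes), function(j)
      list(chrom_id = study$cassettes[[j]]$chrom_id,
           gene_ids = study$cassettes[[j]]$gene_ids,
           carrier_frequency = study$cassette_freq[j, i]))
    model_a <- population_model(study$pair$genome_a, defs)
    genotypes <- list(a = apply_population_variants(
      study$pair$genome_a, model_a, study$n_cells,
      seed = study$seed + 1000L + i), b = NULL)
    models <- list(a = model_a, b = NULL)
  }
  simulate_reads(profile,
                 genomes = list(a = study$pair$genome_a,
                                b = study$pair$genome_b),
                 genotypes = genotypes, models = models,
                 read_length = study$read_length,
                 error_rate = study$error_rate,
                 background_gc = study$background_gc,
                 seed = study$seed + 5000L + i)
}

combine_gsm <- function(gsms, genome_id) {
  structure(list(
    counts = do.call(cbind, lapply(gsms, `[[`, "counts")),
    covered = do.call(cbind, lapply(gsms, `[[`, "covered")),
    depth = do.call(cbind, lapply(gsms, `[[`, "depth")),
    genome_total = do.call(c, unname(lapply(gsms, `[[`, "genome_total"))),
    genome_id = genome_id), class = "gene_sample_matrix")
}

#' Run the full survey analysis on a synthetic study
#'
#' For every sample: simulate reads, map them competitively against both
#' genomes, apply the specificity filter, and accumulate gene-by-sample
#' matrices. Then: orthology and conserved-gene masking, relative abundance
#' and dominance classes, detection, completeness, and (optionally) the
#' pan-genome stage (dispensable calls and cassette clustering) and windowed
#' depth tracks of genome A for border analysis.
#'
#' @param study a [simulate_study()] result.
#' @param params a [recruit_params()].
#' @param cfg a [threshold_config()].
#' @param window optional window width (bases); when set, per-sample depth
#'   tracks of genome A are kept.
#' @param do_pangenome run the dispensable/cassette stage (needs enough
#'   eligible samples).
#' @param mask_correct passed to [relative_abundance()].
#' @return List with `orthologs`, `conserved`, `gsm_a`, `gsm_b`,
#'   `abundance`, `detection_a`, `detection_b`, `completeness_a`,
#'   `completeness_b`, `read_status` (per-sample read counts by filter
#'   status), and when requested `dispensable_a`, `cassettes_a`, `tracks_a`.
#' @export
run_survey <- function(study, params = recruit_params(),
                       cfg = threshold_config(), window = NULL,
                       do_pangenome = FALSE, mask_correct = TRUE) {
  pair <- study$pair
  idx_a <- build_index(pair$genome_a, params$k)
  idx_b <- build_index(pair$genome_b, params$k)
  orth <- find_orthologs(pair$genome_a, pair$genome_b)
  cons <- conserved_genes(orth)
  sample_ids <- study$profiles$sample_id
  gsms_a <- list()
  gsms_b <- list()
  tracks_a <- list()
  status_rows <- list()
  for (i in seq_along(sample_ids)) {
    sid <- sample_ids[i]
    rs <- study_sample_reads(study, i)
    hits <- map_reads(rs$reads, idx_a, idx_b, params)
    recs <- competitive_filter(hits, params)
    recs$sample_id <- sid
    status_rows[[sid]] <- as.data.frame(t(as.matrix(table(recs$status))))
    gsms_a[[sid]] <- gene_read_counts(recs, pair$genome_a, sid)
    gsms_b[[sid]] <- gene_read_counts(recs, pair$genome_b, sid)
    if (!is.null(window))
      tracks_a[[sid]] <- recruitment_profile(recs, pair$genome_a,
                                             window)$depth
  }
  gsm_a <- combine_gsm(gsms_a, pair$genome_a$genome_id)
  gsm_b <- combine_gsm(gsms_b, pair$genome_b$genome_id)
  read_status <- do.call(rbind, status_rows)
  read_status <- data.frame(sample_id = rownames(read_status), read_status,
                            row.names = NULL, stringsAsFactors = FALSE)
  totals <- setNames(study$profiles$total_reads, sample_ids)
  abundance <- relative_abundance(gsm_a, gsm_b, totals, cons,
                                  genomes = list(a = pair$genome_a,
                                                 b = pair$genome_b),
                                  cfg = cfg, mask_correct = mask_correct)
  det_a <- detect_genes(gsm_a, cfg)
  det_b <- detect_genes(gsm_b, cfg)
  comp_a <- sample_completeness(det_a, pair$genome_a, cons$gene_a, cfg)
  comp_b <- sample_completeness(det_b, pair$genome_b, cons$gene_b, cfg)
  out <- list(orthologs = orth, conserved = cons, gsm_a = gsm_a,
              gsm_b = gsm_b, abundance = abundance, detection_a = det_a,
              detection_b = det_b, completeness_a = comp_a,
              completeness_b = comp_b, read_status = read_status)
  if (!is.null(window)) out$tracks_a <- tracks_a
  if (do_pangenome) {
    eligible <- comp_a$sample_id[comp_a$eligible]
    keep <- setdiff(rownames(det_a), cons$gene_a)
    calls <- call_dispensable(det_a[keep, , drop = FALSE],
                              study$expression$expressed, eligible, cfg)
    out$eligible_a <- eligible
    out$dispensable_a <- calls
    out$cassettes_a <- cluster_cassettes(calls, pair$genome_a, det_a,
                                         eligible)
  }
  out
}
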