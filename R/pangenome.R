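#' Call dispensable genes with the stringent filter chain
#'
#' A gene is dispensable when, over the eligible samples (those passing the
#' completeness gate), it is detected in at least `min_detect_samples` and
#' undetected in at least `min_absent_samples`, and it carries an expression
#' signal in at least `min_expressed_samples` samples (counted over all
#' samples with expression data). Conserved (masked) genes should be excluded
#' upstream via eligibility of the detection matrix rows, and samples failing
#' the completeness gate are ignored entirely.
#'
#' @param detection logical genes x samples matrix from [detect_genes()].
#' @param expressed logical genes x samples expression-signal matrix.
#' @param eligible_samples character vector of eligible sample ids.
#' @param cfg a [threshold_config()].
#' @return Data frame of class `dispensable_calls`: `gene_id`,
#'   `n_samples_detected`, `n_samples_absent`, `n_samples_expressed`,
#'   `dispensable`.
#' @export
call_dispensable <- function(detection, expressed, eligible_samples,
                             cfg = threshold_config()) {
  need <- cfg$min_detect_samples + cfg$min_absent_samples
  eligible_samples <- intersect(eligible_samples, colnames(detection))
  if (length(eligible_samples) < need)
    stop(sprintf(paste0("need at least %d eligible samples (%d to detect + ",
                        "%d absent), got %d"),
                 need, cfg$min_detect_samples, cfg$min_absent_samples,
                 length(eligible_samples)))
  det <- detection[, eligible_samples, drop = FALSE]
  n_det <- rowSums(det)
  n_abs <- length(eligible_samples) - n_det
  genes <- rownames(detection)
  n_expr <- setNames(rep(0L, length(genes)), genes)
  common <- intersect(genes, rownames(expressed))
  n_expr[common] <- rowSums(expressed[common, , drop = FALSE])
  out <- data.frame(gene_id = genes,
                    n_samples_detected = unname(n_det),
                    n_samples_absent = unname(n_abs),
                    n_samples_expressed = unname(n_expr),
                    stringsAsFactors = FALSE)
  out$dispensable <- out$n_samples_detected >= cfg$min_detect_samples &
    out$n_samples_absent >= cfg$min_absent_samples &
    out$n_samples_expressed >= cfg$min_expressed_samples
  class(out) <- c("dispensable_calls", "data.frame")
  out
}

#' Cluster dispensable genes into cassettes
#'
#' Maximal runs of rank-adjacent dispensable genes on one chromosome become
#' cassettes (two or more genes); isolated dispensable genes are reported as
#' singletons. When a detection matrix and eligible sample set are supplied,
#' each cassette also gets its absence pattern: the eligible samples in which
#' every member gene is undetected.
#'
#' @param calls a [call_dispensable()] result.
#' @param genome the `annotated_genome` (provides gene order and
#'   coordinates).
#' @param detection optional detection matrix for absence patterns.
#' @param eligible_samples optional eligible sample ids.
#' @return List with `cassettes` (data frame `cassette_id`, `chrom_id`,
#'   `start`, `end`, `n_genes`, `genes` (comma-joined), `n_absent_samples`),
#'   `singletons` (gene ids), and `absence` (cassettes x eligible samples
#'   logical matrix, or NULL).
#' @export
cluster_cassettes <- function(calls, genome, detection = NULL,
                              eligible_samples = NULL) {
  disp <- calls$gene_id[calls$dispensable]
  genes <- genome$genes
  runs <- list()
  singles <- character(0)
  for (cid in unique(genes$chrom_id)) {
    g <- genes[genes$chrom_id == cid, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    is_disp <- g$gene_id %in% disp
    r <- rle(is_disp)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      ids <- g$gene_id[starts[j]:ends[j]]
      if (length(ids) >= 2)
        runs[[length(runs) + 1L]] <- list(
          chrom_id = cid, gene_ids = ids,
          start = g$start[starts[j]], end = g$end[ends[j]])
      else singles <- c(singles, ids)
    }
  }
  absence <- NULL
  n_absent <- rep(NA_integer_, length(runs))
  if (!is.null(detection) && !is.null(eligible_samples) && length(runs)) {
    eligible_samples <- intersect(eligible_samples, colnames(detection))
    absence <- t(vapply(runs, function(cs) {
      colSums(detection[cs$gene_ids, eligible_samples, drop = FALSE]) == 0
    }, logical(length(eligible_samples))))
    if (length(eligible_samples) == 1) absence <- t(absence)
    dimnames(absence) <- list(sprintf("cassette_%02d", seq_along(runs)),
                              eligible_samples)
    n_absent <- rowSums(absence)
  }
  cassettes <- if (length(runs))
    data.frame(cassette_id = sprintf("cassette_%02d", seq_along(runs)),
               chrom_id = vapply(runs, `[[`, "", "chrom_id"),
               start = vapply(runs, `[[`, 0, "start"),
               end = vapply(runs, `[[`, 0, "end"),
               n_genes = vapply(runs, function(x) length(x$gene_ids), 0L),
               genes = vapply(runs,
                              function(x) paste(x$gene_ids, collapse = ","),
                              ""),
               n_absent_samples = as.integer(n_absent),
               stringsAsFactors = FALSE)
  else
    data.frame(cassette_id = character(0), chrom_id = character(0),
               start = numeric(0), end = numeric(0), n_genes = integer(0),
               genes = character(0), n_absent_samples = integer(0),
               stringsAsFactors = FALSE)
  list(cassettes = cassettes, singletons = singles, absence = absence)
}

#' Depletion ratio of a gene in a sample
#'
#' Ratio of the gene's mean read depth to the chromosome's baseline depth
#' (median mean-depth of non-dispensable genes on the same chromosome in the
#' same sample). Ratios at or below `depletion_absent_max` are `absent`, at
#' or above `depletion_present_min` are `present`, intermediate ratios are
#' `partial` -- the signature of presence in only a sub-population.
#'
#' @param gsm a [gene_read_counts()] result (the `depth` matrix is used).
#' @param genome the `annotated_genome`.
#' @param gene_id,sample_id the cell to profile.
#' @param dispensable_ids gene ids excluded from the baseline.
#' @param cfg a [threshold_config()].
#' @return One-row data frame: `gene_id`, `sample_id`, `depth`, `baseline`,
#'   `depletion_ratio`, `state` (`present` / `partial` / `absent` /
#'   `undefined`).
#' @export
depletion_profile <- function(gsm, genome, gene_id, sample_id,
                              dispensable_ids = character(0),
                              cfg = threshold_config()) {
  stopifnot(gene_id %in% rownames(gsm$depth),
            sample_id %in% colnames(gsm$depth))
  cid <- genome$genes$chrom_id[match(gene_id, genome$genes$gene_id)]
  base_ids <- genome$genes$gene_id[genome$genes$chrom_id == cid]
  base_ids <- setdiff(base_ids, c(dispensable_ids, gene_id))
  base_depths <- gsm$depth[base_ids, sample_id]
  usable <- base_depths[base_depths > 0]
  depth <- gsm$depth[gene_id, sample_id]
  if (length(usable) < cfg$min_baseline_genes) {
    return(data.frame(gene_id = gene_id, sample_id = sample_id,
                      depth = depth, baseline = NA_real_,
                      depletion_ratio = NA_real_, state = "undefined",
                      stringsAsFactors = FALSE))
  }
  baseline <- median(base_depths)
  if (baseline <= 0)
    return(data.frame(gene_id = gene_id, sample_id = sample_id,
                      depth = depth, baseline = baseline,
                      depletion_ratio = NA_real_, state = "undefined",
                      stringsAsFactors = FALSE))
  ratio <- depth / baseline
  state <- if (ratio <= cfg$depletion_absent_max) "absent"
  else if (ratio >= cfg$depletion_present_min) "present"
  else "partial"
  data.frame(gene_id = gene_id, sample_id = sample_id, depth = depth,
             baseline = baseline, depletion_ratio = ratio, state = state,
             stringsAsFactors = FALSE)
}

#' Cassette border consistency across samples
#'
#' For each sample in which a cassette is absent, estimates the two
#' breakpoints as the window boundary with the largest depth change within
#' `search` bases of each annotated cassette edge, on the windowed
#' genome-specific depth track. Reports the per-sample estimates and the
#' maximum pairwise deviation between samples -- planted cassettes lost
#' through a single ancestral breakpoint give deviations within one window.
#'
#' @param tracks named list (by sample id) of depth tracks -- the `depth`
#'   element of [recruitment_profile()] results, all computed at the same
#'   window width.
#' @param cassette list or one-row data frame with `chrom_id`, `start`,
#'   `end` (annotated cassette coordinates).
#' @param window window width of the tracks, in bases.
#' @param search half-width of the search region around each edge, in bases.
#' @return List with `estimates` (data frame `sample_id`, `edge`,
#'   `position`), `deviation_per_edge` and `max_deviation` (bases).
#' @export
border_consistency <- function(tracks, cassette, window = 200,
                               search = 1000) {
  if (length(tracks) < 2)
    stop("border consistency needs at least 2 samples with the cassette absent")
  est <- list()
  for (sid in names(tracks)) {
    tr <- tracks[[sid]]
    tr <- tr[tr$chrom_id == cassette$chrom_id, , drop = FALSE]
    tr <- tr[order(tr$start), , drop = FALSE]
    if (nrow(tr) < 2) next
    bounds <- tr$start[-1]
    delta <- diff(tr$depth)
    for (edge in c("start", "end")) {
      target <- cassette[[edge]]
      sel <- which(abs(bounds - target) <= search)
      pos <- NA_real_
      if (length(sel) > 0 && any(delta[sel] != 0)) {
        cand <- sel[abs(delta[sel]) == max(abs(delta[sel]))]
        # ties: nearest to the annotated edge, then lowest coordinate
        cand <- cand[order(abs(bounds[cand] - target), bounds[cand])]
        pos <- bounds[cand[1]]
      }
      est[[length(est) + 1L]] <- data.frame(
        sample_id = sid, edge = edge, position = pos,
        stringsAsFactors = FALSE)
    }
  }
  estimates <- do.call(rbind, est)
  dev <- vapply(c("start", "end"), function(e) {
    p <- estimates$position[estimates$edge == e]
    p <- p[!is.na(p)]
    if (length(p) < 2) return(NA_real_)
    max(p) - min(p)
  }, numeric(1))
  list(estimates = estimates, deviation_per_edge = dev,
       max_deviation = if (all(is.na(dev))) NA_real_
       else max(dev, na.rm = TRUE))
}

#' Transcriptomic activity contrast between dispensable and core genes
#'
#' Group means of the per-gene relative activity plus a two-sided
#' Mann-Whitney-Wilcoxon test of the dispensable-vs-core difference.
#'
#' @param activity named numeric vector of per-gene activity.
#' @param calls a [call_dispensable()] result.
#' @return List: `mean_dispensable`, `mean_core`, `U`, `p_value`,
#'   `n_dispensable`, `n_core`.
#' @export
dispensable_expression_contrast <- function(activity, calls) {
  disp <- intersect(calls$gene_id[calls$dispensable], names(activity))
  core <- intersect(calls$gene_id[!calls$dispensable], names(activity))
  if (length(disp) == 0 || length(core) == 0)
    stop("both the dispensable and the core group must be non-empty")
  mt <- mww_test(activity[disp], activity[core])
  list(mean_dispensable = mean(activity[disp]),
       mean_core = mean(activity[core]),
       U = mt$U, p_value = mt$p_value,
       n_dispensable = length(disp), n_core = length(core))
}
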