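#' Two-sided Mann-Whitney-Wilcoxon test
#'
#' Exact null distribution when the pooled sample size is at most 16 and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity corrections. `U` is the number of (a, b) pairs with a > b
#' (ties counting one half).
#'
#' @param values_a,values_b numeric vectors (both non-empty).
#' @return List of class `mww_test`: `U`, `p_value`, `n_a`, `n_b`, `exact`.
#' @export
mww_test <- function(values_a, values_b) {
  if (length(values_a) == 0 || length(values_b) == 0)
    stop("both groups must be non-empty")
  ties <- anyDuplicated(c(values_a, values_b)) > 0
  exact <- !ties && (length(values_a) + length(values_b)) <= 16
  wt <- suppressWarnings(wilcox.test(values_a, values_b, exact = exact,
                                     correct = TRUE))
  structure(list(U = unname(wt$statistic), p_value = wt$p.value,
                 n_a = length(values_a), n_b = length(values_b),
                 exact = exact),
            class = "mww_test")
}

#' @export
print.mww_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney-Wilcoxon: U = %g (n = %d, %d), two-sided p = %.4g (%s)\n",
              x$U, x$n_a, x$n_b, x$p_value,
              if (x$exact) "exact" else "normal approximation"))
  invisible(x)
}

#' PCA of environmental covariates
#'
#' Z-score standardization per parameter followed by spectral decomposition
#' of the correlation matrix (via [stats::prcomp()] on scaled data). Rows
#' with missing values are dropped (with a message), zero-variance parameters
#' are dropped with a warning, and each component's sign is fixed so its
#' largest-magnitude loading is positive.
#'
#' @param profiles data frame of samples (e.g. from
#'   [simulate_station_series()]).
#' @param parameters character vector of numeric columns to use (>= 2).
#' @param tests optional [niche_summary()] result used to flag parameters
#'   that discriminate the two genome-dominant groups (BH-adjusted p < 0.05).
#' @return List of class `pca_env`: `loadings` (parameters x components,
#'   orthonormal columns), `scores` (samples x components),
#'   `var_explained` (fractions summing to 1), `n_dropped_rows`,
#'   `significant` (named logical or NULL).
#' @export
pca_env <- function(profiles, parameters, tests = NULL) {
  stopifnot(length(parameters) >= 2,
            all(parameters %in% names(profiles)))
  x <- as.matrix(profiles[, parameters, drop = FALSE])
  rownames(x) <- if ("sample_id" %in% names(profiles)) profiles$sample_id
  else rownames(profiles)
  keep <- stats::complete.cases(x)
  if (any(!keep))
    message(sprintf("dropping %d rows with missing values", sum(!keep)))
  x <- x[keep, , drop = FALSE]
  if (nrow(x) < 3) stop("need at least 3 complete samples")
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance parameters: ",
            paste(colnames(x)[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  if (ncol(x) < 2) stop("need at least 2 non-constant parameters")
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  loadings <- sweep(pc$rotation, 2, flip, `*`)
  scores <- sweep(pc$x, 2, flip, `*`)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  sig <- NULL
  if (!is.null(tests)) {
    sig <- setNames(rep(NA, ncol(x)), colnames(x))
    m <- match(colnames(x), tests$parameter)
    sig[!is.na(m)] <- tests$p_adjusted[m[!is.na(m)]] < 0.05
  }
  structure(list(loadings = loadings, scores = scores, var_explained = ve,
                 n_dropped_rows = sum(!keep), significant = sig),
            class = "pca_env")
}

#' Environmental niche summary of the two genome-dominant groups
#'
#' Splits samples by dominance class (`A_dominant` vs `B_dominant`;
#' co-occurring, mixed and below-floor samples are excluded) and reports, per
#' environmental parameter, the group means and ranges and a two-sided
#' Mann-Whitney-Wilcoxon test, with Benjamini-Hochberg adjustment across
#' parameters.
#'
#' @param abundance an `abundance_table` (needs `sample_id` and `class`).
#' @param profiles sample table with the environmental columns.
#' @param parameters parameter columns to test; defaults to the standard
#'   covariates present in `profiles`.
#' @param cfg a [threshold_config()] (unused thresholds are ignored; kept so
#'   classification and summary share one configuration object).
#' @return Data frame of class `niche_summary`: per parameter the group
#'   means, minima, maxima, `n_a`, `n_b`, `U`, `p_value`, `p_adjusted`.
#' @export
niche_summary <- function(abundance, profiles,
                          parameters = NULL, cfg = threshold_config()) {
  merged <- merge(as.data.frame(abundance)[, c("sample_id", "class")],
                  profiles, by = "sample_id")
  if (is.null(parameters))
    parameters <- intersect(c("temperature", "oxygen", "depth", "PAR",
                              "nitrate", "phosphate", "chlorophyll",
                              "salinity"), names(profiles))
  stopifnot(length(parameters) >= 1)
  ga <- merged[merged$class == "A_dominant", , drop = FALSE]
  gb <- merged[merged$class == "B_dominant", , drop = FALSE]
  if (nrow(ga) == 0 || nrow(gb) == 0)
    stop("need at least one A-dominant and one B-dominant sample")
  rows <- lapply(parameters, function(pm) {
    va <- ga[[pm]][!is.na(ga[[pm]])]
    vb <- gb[[pm]][!is.na(gb[[pm]])]
    mt <- mww_test(va, vb)
    data.frame(parameter = pm, mean_a = mean(va), mean_b = mean(vb),
               min_a = min(va), max_a = max(va), min_b = min(vb),
               max_b = max(vb), n_a = length(va), n_b = length(vb),
               U = mt$U, p_value = mt$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  class(out) <- c("niche_summary", "data.frame")
  out
}

#' Concordance between metabarcode and metagenomic abundance
#'
#' Correlates per-sample marker-amplicon relative abundance (which cannot
#' separate the two genomes) with the sum of the two relative genomic
#' abundances.
#'
#' @param barcode named numeric vector of barcode counts (or relative
#'   abundances) per sample.
#' @param abundance an `abundance_table`.
#' @return List: `spearman_rho`, `pearson_r`, `n`. Both correlations are `NA`
#'   with a warning when either vector is constant.
#' @export
barcode_correlation <- function(barcode, abundance) {
  common <- intersect(names(barcode), abundance$sample_id)
  if (length(common) < 3)
    stop("need at least 3 samples with both measurements")
  x <- as.numeric(barcode[common])
  y <- abundance$abund_a[match(common, abundance$sample_id)] +
    abundance$abund_b[match(common, abundance$sample_id)]
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant vector: correlation undefined")
    return(list(spearman_rho = NA_real_, pearson_r = NA_real_,
                n = length(common)))
  }
  list(spearman_rho = cor(x, y, method = "spearman"),
       pearson_r = cor(x, y, method = "pearson"),
       n = length(common))
}
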