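#' Niche parameters of the synthetic station series
#'
#' Controls how environmental covariates are drawn and how they set the
#' mixture of the two genomes in each sample. Stations carry a latent ecotype
#' label (balanced Bernoulli); type-B stations are on average
#' `temp_offset` degC warmer (defaults 18.4 vs 21.4 degC, sd 2 -- the 3 degC
#' niche contrast the analysis is meant to recover). The genome-B share of
#' each sample is a logistic link of the latent ecotype and of standardized
#' temperature and depth. The ecotype coefficient dominates by default:
#' which genome rules a station reflects its (unobserved) biogeography, with
#' temperature and depth modulating -- this keeps the temperature contrast
#' between genome-dominant groups at the planted offset instead of being
#' inflated by selecting on a temperature-driven share. Oxygen decreases
#' with temperature,
#' PAR decays with depth, and nutrients are richer in cold water, giving the
#' PCA a realistic correlation structure.
#'
#' @param temp_mean_a mean temperature (degC) of type-A stations.
#' @param temp_offset mean temperature offset (degC) of type-B stations.
#' @param temp_sd within-type temperature standard deviation (degC).
#' @param beta0,beta_temp,beta_depth logistic-link coefficients on the
#'   standardized covariates for the genome-B share.
#' @param beta_ecotype logistic-link coefficient on the latent ecotype
#'   (+1 for type-B stations, -1 for type-A).
#' @param dcm_prob probability that a sample is from the deep chlorophyll
#'   maximum (DCM) rather than the surface.
#' @param total_fraction_range range (fractions of all reads) from which each
#'   sample's summed two-genome fraction is drawn uniformly.
#' @param total_reads metagenomic reads per sample.
#' @return A list of class `niche_params`.
#' @export
niche_params <- function(temp_mean_a = 18.4, temp_offset = 3, temp_sd = 2,
                         beta0 = 0, beta_temp = 1, beta_depth = 0.5,
                         beta_ecotype = 6, dcm_prob = 0.5,
                         total_fraction_range = c(0, 0.03),
                         total_reads = 1e5) {
  stopifnot(temp_sd > 0, dcm_prob >= 0, dcm_prob <= 1,
            length(total_fraction_range) == 2,
            total_fraction_range[1] >= 0, total_fraction_range[2] <= 1,
            total_fraction_range[1] <= total_fraction_range[2],
            total_reads >= 1)
  structure(list(temp_mean_a = temp_mean_a, temp_offset = temp_offset,
                 temp_sd = temp_sd, beta0 = beta0, beta_temp = beta_temp,
                 beta_depth = beta_depth, beta_ecotype = beta_ecotype,
                 dcm_prob = dcm_prob,
                 total_fraction_range = total_fraction_range,
                 total_reads = as.integer(total_reads)),
            class = "niche_params")
}

#' Simulate a station series with environmental covariates and true mixtures
#'
#' @param n_samples number of station-depth samples (>= 2).
#' @param params a [niche_params()].
#' @param seed optional integer seed.
#' @return Data frame with one row per sample: `sample_id`, `depth_layer`,
#'   `depth` (m), `temperature` (degC), `oxygen` (uM), `PAR`
#'   (mol quanta m-2 d-1), `nitrate`, `phosphate` (uM), `chlorophyll`
#'   (mg m-3), `salinity` (PSU), `total_reads`, the ground-truth mixture
#'   (`true_fraction_a`, `true_fraction_b`, `background_fraction`) and the
#'   latent `ecotype` label.
#' @export
simulate_station_series <- function(n_samples, params = niche_params(),
                                    seed = NULL) {
  if (n_samples < 2) stop("n_samples must be at least 2")
  stopifnot(inherits(params, "niche_params"))
  if (!is.null(seed)) set.seed(seed)
  p <- params
  ecotype <- sample(c("A", "B"), n_samples, replace = TRUE)
  temperature <- p$temp_mean_a + p$temp_offset * (ecotype == "B") +
    rnorm(n_samples, 0, p$temp_sd)
  depth_layer <- ifelse(runif(n_samples) < p$dcm_prob, "DCM", "surface")
  depth <- ifelse(depth_layer == "surface", runif(n_samples, 5, 10),
                  pmax(20, rnorm(n_samples, 70, 20)))
  oxygen <- pmax(5, 280 - 4.5 * (temperature - 15) + rnorm(n_samples, 0, 10))
  PAR <- 38 * exp(-depth / 25) * exp(rnorm(n_samples, 0, 0.3))
  nitrate <- pmax(0.01, 8 - 0.3 * (temperature - 15) + 2 * depth / 50 +
                    rnorm(n_samples, 0, 1.5))
  phosphate <- pmax(0.005, nitrate / 16 + rnorm(n_samples, 0, 0.05))
  chlorophyll <- pmax(0.01, 0.2 + 0.4 * (depth_layer == "DCM") +
                        rnorm(n_samples, 0, 0.1))
  salinity <- rnorm(n_samples, 35.5, 0.8)

  zt <- if (sd(temperature) > 0) scale(temperature)[, 1] else temperature * 0
  zd <- if (sd(depth) > 0) scale(depth)[, 1] else depth * 0
  share_b <- plogis(p$beta0 + p$beta_ecotype * ifelse(ecotype == "B", 1, -1) +
                      p$beta_temp * zt + p$beta_depth * zd)
  total <- runif(n_samples, p$total_fraction_range[1],
                 p$total_fraction_range[2])
  true_a <- total * (1 - share_b)
  true_b <- total * share_b
  if (all(true_a + true_b == 0))
    warning("degenerate link: all true genome fractions are zero")
  data.frame(
    sample_id = sprintf("s%02d", seq_len(n_samples)),
    depth_layer = depth_layer, depth = depth, temperature = temperature,
    oxygen = oxygen, PAR = PAR, nitrate = nitrate, phosphate = phosphate,
    chlorophyll = chlorophyll, salinity = salinity,
    total_reads = p$total_reads, true_fraction_a = true_a,
    true_fraction_b = true_b, background_fraction = 1 - true_a - true_b,
    ecotype = ecotype, stringsAsFactors = FALSE)
}

#' Simulate a per-gene, per-sample metatranscriptomic signal
#'
#' Emits a boolean expression signal (consumed by the dispensable-gene
#' filter) and a continuous relative activity value per gene (consumed by the
#' dispensable-vs-core activity contrast). A gene is expressed in a sample
#' with probability `active_fraction`, optionally multiplied by a per-cell
#' presence probability matrix so genes absent from a sample's population
#' leave no transcriptomic trace. Activities are normal draws truncated to
#' \[0, 1\] with separate means for dispensable and core genes.
#'
#' @param genes gene table of an `annotated_genome` (needs `gene_id` and
#'   `dispensable_truth` columns).
#' @param sample_ids character vector of sample ids.
#' @param active_fraction probability that a (present) gene yields an
#'   expression signal in a sample.
#' @param presence optional genes x samples matrix of presence probabilities
#'   multiplying `active_fraction`.
#' @param activity_mean_core,activity_mean_dispensable,activity_sd parameters
#'   of the per-gene activity draw.
#' @param seed optional integer seed.
#' @return List with `expressed` (logical genes x samples matrix) and
#'   `activity` (named numeric vector per gene).
#' @export
simulate_expression <- function(genes, sample_ids, active_fraction = 0.8,
                                presence = NULL,
                                activity_mean_core = 0.56,
                                activity_mean_dispensable = 0.73,
                                activity_sd = 0.15, seed = NULL) {
  stopifnot(active_fraction >= 0, active_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  ng <- nrow(genes)
  ns <- length(sample_ids)
  prob <- matrix(active_fraction, ng, ns,
                 dimnames = list(genes$gene_id, sample_ids))
  if (!is.null(presence)) {
    stopifnot(identical(dim(presence), dim(prob)))
    prob <- prob * presence
  }
  expressed <- matrix(runif(ng * ns) < prob, ng, ns,
                      dimnames = dimnames(prob))
  mu <- ifelse(genes$dispensable_truth, activity_mean_dispensable,
               activity_mean_core)
  activity <- pmin(1, pmax(0, rnorm(ng, mu, activity_sd)))
  names(activity) <- genes$gene_id
  list(expressed = expressed, activity = activity)
}

#' Simulate metabarcode (amplicon) counts proportional to genome abundance
#'
#' The marker sequence is identical between the two genomes, so barcode
#' counts track their summed abundance: counts are Poisson draws with mean
#' `barcode_total * (true_fraction_a + true_fraction_b)`.
#'
#' @param profiles station table from [simulate_station_series()].
#' @param barcode_total amplicon reads per sample.
#' @param seed optional integer seed.
#' @return Named integer vector of barcode counts per sample.
#' @export
simulate_barcode_counts <- function(profiles, barcode_total = 1e5,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lambda <- barcode_total * (profiles$true_fraction_a +
                               profiles$true_fraction_b)
  setNames(rpois(nrow(profiles), lambda), profiles$sample_id)
}
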