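#' Simulation configuration for the synthetic herd generator
#'
#' Collects every knob of the synthetic-data module with defaults matching
#' the study conditions the pipeline is designed for: a commercial-scale
#' Holstein research herd with 26 cow trial levels, 2 lactations, heifer
#' feed-conversion trials of 70 d, cow test periods spanning 100--240 days in
#' milk, and RFI variance components of 1.16 (additive) and 1.55 (residual)
#' kg^2 of DM/d for cows.
#'
#' @param n_founders number of founder animals (unknown parents).
#' @param n_generations total number of generations including founders.
#' @param n_per_generation offspring per non-founder generation
#'   (default: \code{n_founders}).
#' @param n_sires number of sires used per generation; sires are reused
#'   across dams to create half-sib families (default: 1 per ~20 offspring).
#' @param n_snps number of simulated SNP markers.
#' @param maf_range founder minor-allele-frequency range, within (0, 0.5].
#' @param n_chromosomes autosome count markers are cycled over.
#' @param n_trials_cow number of cow trial levels (pen x year x season).
#' @param n_lactations number of lactation classes.
#' @param n_trials_heifer number of heifer feed-conversion trials.
#' @param sigma_a2 named vector of additive genetic variances per trait.
#' @param sigma_e2 named vector of animal-level residual variances per trait.
#' @param genetic_covariance 2x2 genetic covariance K for
#'   (RFI_heifer, RFI_cow); defaults to the diagonal implied by
#'   \code{sigma_a2} with correlation 0.42.
#' @param outlier_rate fraction of daily cow records perturbed into
#'   > 3 SD outliers (default 0.02, so screening removes well under 5%).
#' @param day_sd day-level noise SD, named per daily trait.
#' @param seed integer seed for all generator randomness.
#' @return an object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(n_founders = 80,
                       n_generations = 4,
                       n_per_generation = n_founders,
                       n_sires = max(1L, ceiling(n_per_generation / 20)),
                       n_snps = 500,
                       maf_range = c(0.05, 0.5),
                       n_chromosomes = 29,
                       n_trials_cow = 26,
                       n_lactations = 2,
                       n_trials_heifer = 8,
                       sigma_a2 = c(rfi_heifer = 0.222, rfi_cow = 1.16),
                       sigma_e2 = c(rfi_heifer = 0.518, rfi_cow = 1.55),
                       genetic_covariance = NULL,
                       outlier_rate = 0.02,
                       day_sd = c(dmi = 1.0, my = 2.0, fat_pct = 0.25,
                                  prot_pct = 0.08, bw = 8.0),
                       seed = 1L) {
  stopifnot(n_founders >= 2, n_generations >= 1, n_per_generation >= 1,
            n_sires >= 1, n_snps >= 1, n_trials_cow >= 1, n_lactations >= 1,
            n_trials_heifer >= 1, outlier_rate >= 0, outlier_rate <= 1)
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must be an increasing pair within (0, 0.5]")
  }
  if (any(sigma_a2 < 0) || any(sigma_e2 < 0)) {
    stop("variance components must be non-negative")
  }
  if (is.null(genetic_covariance)) {
    sa <- sigma_a2[c("rfi_heifer", "rfi_cow")]
    r <- 0.42
    genetic_covariance <- matrix(
      c(sa[1], r * sqrt(sa[1] * sa[2]), r * sqrt(sa[1] * sa[2]), sa[2]),
      2, 2, dimnames = list(c("rfi_heifer", "rfi_cow"),
                            c("rfi_heifer", "rfi_cow")))
  }
  K <- genetic_covariance
  if (!isTRUE(all.equal(K, t(K))) || any(diag(K) < 0)) {
    stop("genetic_covariance must be symmetric with non-negative diagonal")
  }
  if (all(diag(K) > 0)) {
    rg <- K[1, 2] / sqrt(K[1, 1] * K[2, 2])
    if (abs(rg) > 1 + 1e-12) {
      stop("genetic_covariance implies |genetic correlation| > 1")
    }
  }
  cfg <- list(n_founders = as.integer(n_founders),
              n_generations = as.integer(n_generations),
              n_per_generation = as.integer(n_per_generation),
              n_sires = as.integer(n_sires),
              n_snps = as.integer(n_snps),
              maf_range = maf_range,
              n_chromosomes = as.integer(n_chromosomes),
              n_trials_cow = as.integer(n_trials_cow),
              n_lactations = as.integer(n_lactations),
              n_trials_heifer = as.integer(n_trials_heifer),
              sigma_a2 = sigma_a2,
              sigma_e2 = sigma_e2,
              genetic_covariance = K,
              outlier_rate = outlier_rate,
              day_sd = day_sd,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}
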