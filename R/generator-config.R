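#' Species-level ground-truth parameter table
#'
#' Builds and validates the table of species-level parameters that drives
#' every synthetic-data generator: allometric intercepts and slopes for SMR
#' and MMR, the speed-length power law, length-weight coefficients,
#' caudal-fin aspect ratio, family and body-shape labels, daily resting
#' hours, and the length range over which size-resolved estimates are made.
#'
#' Intercepts are log10 metabolic rates at 1 g (g O2 per day), so
#' `a_smr = log10(0.004)` means an SMR of 0.004 g O2 per day for a 1 g fish.
#' Slopes are mass-scaling exponents on the log10-log10 scale.
#'
#' @param species_id character vector of species labels.
#' @param a_smr,a_mmr log10 intercepts (rate at 1 g) for SMR and MMR.
#' @param b_smr,b_mmr mass-scaling exponents; must lie in (0, 1.5).
#' @param a_v,b_v intercept and slope of log10 field swimming speed
#'   (cm s-1) against log10 fork length (cm).
#' @param lw_a,lw_b length-weight coefficients, `W = lw_a * L^lw_b` (g, cm).
#' @param aspect_ratio caudal-fin aspect ratio (dimensionless).
#' @param family,body_shape grouping labels for the maximum-speed model.
#' @param rest_hours hours per day spent resting, in \[0, 24\].
#' @param length_min,length_max size range (cm) for the estimate grid.
#' @return A `data.frame` with one row per species, class
#'   `"fishamr_species"`.
#' @export
species_truth <- function(species_id,
                          a_smr, b_smr, a_mmr, b_mmr,
                          a_v, b_v,
                          lw_a = 0.02, lw_b = 3,
                          aspect_ratio = 1.5,
                          family = "FamA", body_shape = "fusiform",
                          rest_hours = 12,
                          length_min = 5, length_max = 30) {
  out <- data.frame(
    species_id = as.character(species_id),
    a_smr = a_smr, b_smr = b_smr,
    a_mmr = a_mmr, b_mmr = b_mmr,
    a_v = a_v, b_v = b_v,
    lw_a = lw_a, lw_b = lw_b,
    aspect_ratio = aspect_ratio,
    family = as.character(family),
    body_shape = as.character(body_shape),
    rest_hours = rest_hours,
    length_min = length_min, length_max = length_max,
    stringsAsFactors = FALSE
  )
  validate_species_truth(out)
  class(out) <- c("fishamr_species", "data.frame")
  out
}

validate_species_truth <- function(x) {
  if (anyDuplicated(x$species_id))
    stop_input("duplicated species_id in species table")
  if (any(x$b_smr <= 0 | x$b_smr >= 1.5) || any(x$b_mmr <= 0 | x$b_mmr >= 1.5))
    stop_input("scaling exponents b_smr, b_mmr must lie in (0, 1.5)")
  if (any(x$a_mmr <= x$a_smr))
    stop_input("a_mmr must exceed a_smr (MMR above SMR at 1 g)")
  if (any(x$lw_a <= 0))
    stop_input("length-weight coefficient lw_a must be positive")
  if (any(x$rest_hours < 0 | x$rest_hours > 24))
    stop_input("rest_hours must lie in [0, 24]")
  if (any(x$length_min <= 0 | x$length_max <= x$length_min))
    stop_input("species length range must satisfy 0 < length_min < length_max")
  invisible(x)
}

#' Default six-species ground truth
#'
#' A fixed table of six synthetic reef-fish-like species spanning the
#' parameter ranges typical of shallow-water tropical fishes: SMR at 1 g
#' near 0.003-0.004 g O2 d-1, MMR roughly three-fold higher, mass-scaling
#' exponents near 0.70 (SMR) and 0.77 (MMR), and speed-length slopes
#' between 0.2 and 0.9. Families and body shapes define four groups for
#' the maximum-speed model.
#'
#' @return A `"fishamr_species"` data frame with six rows.
#' @export
default_species_truth <- function() {
  species_truth(
    species_id  = c("sp_A", "sp_B", "sp_C", "sp_D", "sp_E", "sp_F"),
    a_smr = log10(c(0.0033, 0.0038, 0.0042, 0.0041, 0.0028, 0.0038)),
    b_smr = c(0.68, 0.70, 0.76, 0.73, 0.70, 0.70),
    a_mmr = log10(c(0.0124, 0.0091, 0.0103, 0.0146, 0.0129, 0.0080)),
    b_mmr = c(0.77, 0.77, 0.77, 0.78, 0.77, 0.77),
    a_v   = c(0.60, 0.75, 0.80, 0.55, 0.70, 0.85),
    b_v   = c(0.60, 0.45, 0.40, 0.90, 0.55, 0.20),
    lw_a  = c(0.014, 0.025, 0.019, 0.022, 0.027, 0.024),
    lw_b  = c(3.05, 3.00, 2.96, 2.90, 2.95, 3.00),
    aspect_ratio = c(1.9, 1.1, 1.6, 3.1, 2.6, 1.3),
    family = c("FamA", "FamB", "FamC", "FamC", "FamD", "FamC"),
    body_shape = c("fusiform", "compressed", "compressed",
                   "fusiform", "compressed", "compressed"),
    rest_hours = 12,
    length_min = c(10, 5, 5, 10, 10, 4),
    length_max = c(45, 18, 22, 40, 35, 16)
  )
}

#' Random species ground truth drawn around global allometric parameters
#'
#' Draws `n` species whose SMR/MMR intercept and slope offsets come from
#' zero-mean normal distributions around stated global values. This is the
#' generating process the hierarchical metabolic-rate model assumes, so it
#' is the natural fixture for parameter-recovery and coverage studies.
#'
#' @param n number of species.
#' @param seed integer seed.
#' @param b_mean global mass-scaling exponent (applies to SMR and MMR).
#' @param b_sd standard deviation of species-by-rate-type slope offsets.
#' @param a_smr_mean,a_mmr_mean global log10 intercepts at 1 g.
#' @param a_sd standard deviation of species-by-rate-type intercept offsets.
#' @inheritParams species_truth
#' @return A `"fishamr_species"` data frame with `n` rows.
#' @export
random_species_truth <- function(n, seed,
                                 b_mean = 0.75, b_sd = 0.03,
                                 a_smr_mean = log10(0.004),
                                 a_mmr_mean = log10(0.012),
                                 a_sd = 0.1,
                                 a_v = 0.7, b_v = 0.5) {
  with_seed(seed, {
    species_truth(
      species_id = sprintf("sp_%02d", seq_len(n)),
      a_smr = a_smr_mean + stats::rnorm(n, 0, a_sd),
      b_smr = b_mean + stats::rnorm(n, 0, b_sd),
      a_mmr = a_mmr_mean + stats::rnorm(n, 0, a_sd),
      b_mmr = b_mean + stats::rnorm(n, 0, b_sd),
      a_v = a_v, b_v = b_v
    )
  })
}

#' Configuration for the synthetic-data generators
#'
#' Bundles the species ground-truth table with sample sizes, covariate
#' ranges, residual scales, Student-t degrees of freedom, the SMR/MMR
#' within-individual correlation, the outlier fraction, and the seed.
#' Every generator takes one of these and is deterministic given it.
#'
#' @param species a `"fishamr_species"` table (see [species_truth()]).
#' @param n_individuals individuals per species and table: a single count
#'   applied to every table, or a named list with any of `mr`,
#'   `respirometry`, `speed`, `maxspeed` (missing entries fall back to
#'   10).
#' @param mass_range mass range (g) for respirometry individuals, sampled
#'   log-uniformly.
#' @param sigma_mr residual SD of log10 metabolic rate (log10 units).
#' @param sigma_v,sigma_vmax residual scale of log10 field / maximum
#'   swimming speed; the field-speed default (0.37) matches the dispersion
#'   typical of stereo-video speed data.
#' @param nu_v,nu_vmax Student-t degrees of freedom (> 2) for the speed and
#'   maximum-speed residuals.
#' @param rho within-individual correlation of log10 SMR and log10 MMR
#'   residuals.
#' @param outlier_fraction fraction of respirometry cycles (or speed
#'   records) replaced by gross low readings, in \[0, 1).
#' @param n_cycles respirometry cycles per trial (first cycle is the
#'   post-chase maximum).
#' @param recovery_cycles cycles over which the post-chase elevation decays
#'   back to the standard rate.
#' @param sd_activity SD of the half-normal proportional activity bumps on
#'   post-recovery cycles (0 gives an exactly flat standard-rate plateau).
#' @param cycle_minutes closed-phase duration per cycle (min).
#' @param chamber_volumes range (L) from which chamber volumes are drawn.
#' @param census list: `sites` (labels), `transects_per_site`, `area` (m2),
#'   `fish_per_transect`, and `rel_abundance` (per-species shares, summing
#'   to 1; default uniform).
#' @param calibration list: `error_intercept` (cm), `error_slope`
#'   (cm per m of camera distance), `sd` (cm), `distance_range` (m),
#'   `true_length_range` (cm), `n` (number of paired measurements).
#' @param maxspeed list of maximum-swim-speed truth parameters: global
#'   intercept `a` and length slope `b` (log10 scale), aspect-ratio
#'   coefficient `c_ar`, and the SDs `sd_a`, `sd_b` of the
#'   family-by-body-shape intercept/slope offsets.
#' @param seed integer seed recorded in, and governing, every generated
#'   table.
#' @return A list of class `"fishamr_config"`.
#' @export
generator_config <- function(species = default_species_truth(),
                             n_individuals = 10,
                             mass_range = c(5, 500),
                             sigma_mr = 0.05,
                             sigma_v = 0.37,
                             sigma_vmax = 0.05,
                             nu_v = 5,
                             nu_vmax = 10,
                             rho = 0.5,
                             outlier_fraction = 0,
                             n_cycles = 150,
                             recovery_cycles = 30,
                             sd_activity = 0.1,
                             cycle_minutes = 8,
                             chamber_volumes = c(0.38, 4.4),
                             census = list(),
                             calibration = list(),
                             maxspeed = list(),
                             seed = 1L) {
  validate_species_truth(species)
  if (sigma_mr < 0 || sigma_v < 0 || sigma_vmax < 0)
    stop_input("residual SDs must be non-negative")
  if (nu_v <= 2 || nu_vmax <= 2)
    stop_input("Student-t degrees of freedom must exceed 2 (finite variance)")
  if (mass_range[1] <= 0 || mass_range[2] <= mass_range[1])
    stop_input("mass_range must satisfy 0 < min < max")
  if (outlier_fraction < 0 || outlier_fraction >= 1)
    stop_input("outlier_fraction must lie in [0, 1)")
  if (rho < -1 || rho > 1) stop_input("rho must lie in [-1, 1]")
  if (n_cycles < 2) stop_input("n_cycles must be at least 2")

  census_defaults <- list(
    sites = c("site_1", "site_2", "site_3"),
    transects_per_site = 3L,
    area = 50,
    fish_per_transect = 40L,
    rel_abundance = NULL
  )
  census <- utils::modifyList(census_defaults, census)
  if (is.null(census$rel_abundance)) {
    census$rel_abundance <- rep(1 / nrow(species), nrow(species))
  }
  if (length(census$rel_abundance) != nrow(species))
    stop_input("census rel_abundance must have one share per species")
  if (abs(sum(census$rel_abundance) - 1) > 1e-6)
    stop_input("census rel_abundance must sum to 1")

  calib_defaults <- list(error_intercept = 0.5, error_slope = 0.1,
                         sd = 0.2, distance_range = c(0.5, 8),
                         true_length_range = c(5, 40), n = 200L)
  calibration <- utils::modifyList(calib_defaults, calibration)

  maxspeed_defaults <- list(a = 1.0, b = 0.5, c_ar = 0.1,
                            sd_a = 0.08, sd_b = 0.04)
  maxspeed <- utils::modifyList(maxspeed_defaults, maxspeed)

  if (is.list(n_individuals)) {
    unknown <- setdiff(names(n_individuals),
                       c("mr", "respirometry", "speed", "maxspeed"))
    if (length(unknown))
      stop_input("unknown n_individuals entries: %s",
                 paste(unknown, collapse = ", "))
    n_individuals <- utils::modifyList(
      list(mr = 10L, respirometry = 10L, speed = 10L, maxspeed = 10L),
      lapply(n_individuals, as.integer))
  } else {
    n <- as.integer(n_individuals)
    n_individuals <- list(mr = n, respirometry = n, speed = n,
                          maxspeed = n)
  }
  if (any(unlist(n_individuals) < 1))
    stop_input("n_individuals must be at least 1")

  structure(
    list(species = species,
         n_individuals = n_individuals,
         mass_range = mass_range,
         sigma_mr = sigma_mr, sigma_v = sigma_v, sigma_vmax = sigma_vmax,
         nu_v = nu_v, nu_vmax = nu_vmax, rho = rho,
         outlier_fraction = outlier_fraction,
         n_cycles = as.integer(n_cycles),
         recovery_cycles = as.integer(recovery_cycles),
         sd_activity = sd_activity,
         cycle_minutes = cycle_minutes,
         chamber_volumes = chamber_volumes,
         census = census, calibration = calibration,
         maxspeed = maxspeed,
         seed = as.integer(seed)),
    class = "fishamr_config"
  )
}
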