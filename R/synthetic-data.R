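# Synthetic-data generators.
#
# Each generator is a pure function of its configuration (which carries the
# seed), emulating one of the five input tables the pipeline consumes, with
# the statistical structure the downstream models assume and with known
# ground truth attached as attributes for recovery tests.
#
# Sub-seeds: each generator offsets the configured seed by a fixed constant
# so the tables are mutually independent yet jointly reproducible.

SEED_OFFSETS <- c(mr = 1L, respirometry = 2L, speed = 3L,
                  maxspeed = 4L, census = 5L, calibration = 6L)

sub_seed <- function(config, what) config$seed + SEED_OFFSETS[[what]]

# Correlated individual-level residuals for log10 SMR and log10 MMR.
draw_mr_residuals <- function(n, sigma, rho) {
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  cbind(smr = sigma * z1, mmr = sigma * z2)
}

#' Generate paired SMR/MMR observations
#'
#' Draws, per species, `n_individuals` body masses log-uniformly over the
#' configured range, then log10 SMR and log10 MMR from normal distributions
#' centred on the species allometric lines with residual SD `sigma_mr`.
#' The two residuals of one individual are correlated with the configured
#' `rho`, reflecting the within-individual co-variation of standard and
#' maximum rates.
#'
#' @param config a [generator_config()].
#' @return A data frame with columns `individual_id`, `species_id`, `mass`
#'   (g), `smr`, `mmr` (g O2 d-1), with the species ground-truth table
#'   attached as attribute `"truth"`.
#' @export
generate_mr_observations <- function(config) {
  stopifnot(inherits(config, "fishamr_config"))
  sp <- config$species
  with_seed(sub_seed(config, "mr"), {
    rows <- lapply(seq_len(nrow(sp)), function(i) {
      n <- config$n_individuals$mr
      mass <- runif_log(n, config$mass_range[1], config$mass_range[2])
      eps <- draw_mr_residuals(n, config$sigma_mr, config$rho)
      data.frame(
        individual_id = sprintf("%s_%03d", sp$species_id[i], seq_len(n)),
        species_id = sp$species_id[i],
        mass = mass,
        smr = 10^(sp$a_smr[i] + sp$b_smr[i] * log10(mass) + eps[, "smr"]),
        mmr = 10^(sp$a_mmr[i] + sp$b_mmr[i] * log10(mass) + eps[, "mmr"]),
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "truth") <- sp
    out
  })
}

# Post-chase elevation profile: 1 at cycle 1, decaying quadratically to 0 at
# recovery_cycles, exactly 0 afterwards (so the zero-noise plateau sits on
# the true standard rate).
recovery_decay <- function(cycle, recovery_cycles) {
  pmax(0, 1 - (cycle - 1) / recovery_cycles)^2
}

#' Generate intermittent-closed respirometry trials
#'
#' Builds per-cycle oxygen-decline records for each individual: the first
#' closed cycle encodes the individual's maximum rate (post-chase), the
#' following cycles decay back towards the standard rate over
#' `recovery_cycles`, and later cycles sit on the standard-rate plateau
#' plus non-negative half-normal activity bumps (spontaneous movement can
#' only raise oxygen uptake, so the lower envelope is the standard rate).
#' A configured fraction of post-recovery cycles is replaced by gross low
#' readings (multiplicative factors well below 0.5), emulating flush or
#' probe faults that the extraction's outlier rule must remove.
#'
#' @param config a [generator_config()].
#' @return A data frame with one row per cycle: `individual_id`,
#'   `species_id`, `mass` (g), `chamber_volume` (L), `cycle`, `o2_slope`
#'   (mg O2 L-1 min-1, magnitude of decline), `duration` (min).
#'   Attributes: `"truth"` (per-individual true SMR/MMR) and
#'   `"outliers"` (individual_id, cycle of every injected outlier).
#' @export
generate_respirometry_trials <- function(config) {
  stopifnot(inherits(config, "fishamr_config"))
  sp <- config$species
  vol_rng <- config$chamber_volumes
  with_seed(sub_seed(config, "respirometry"), {
    trials <- list(); truths <- list(); outs <- list()
    for (i in seq_len(nrow(sp))) {
      n <- config$n_individuals$respirometry
      mass <- runif_log(n, config$mass_range[1], config$mass_range[2])
      eps <- draw_mr_residuals(n, config$sigma_mr, config$rho)
      smr_i <- 10^(sp$a_smr[i] + sp$b_smr[i] * log10(mass) + eps[, "smr"])
      mmr_i <- 10^(sp$a_mmr[i] + sp$b_mmr[i] * log10(mass) + eps[, "mmr"])
      mmr_i <- pmax(mmr_i, smr_i * 1.05)  # chase always elevates the rate
      # chamber sized to the fish, clamped to the configured hardware range
      vol <- pmin(vol_rng[2], pmax(vol_rng[1], 8 * mass / 1000))
      if (any(vol <= mass / 1000))
        stop_input("chamber volume does not exceed fish volume")
      for (f in seq_len(n)) {
        id <- sprintf("%s_%03d", sp$species_id[i], f)
        cyc <- seq_len(config$n_cycles)
        decay <- recovery_decay(cyc, config$recovery_cycles)
        rate <- smr_i[f] * (1 + (mmr_i[f] / smr_i[f] - 1) * decay)
        bump <- abs(stats::rnorm(config$n_cycles, 0, config$sd_activity))
        rate[-1] <- rate[-1] * (1 + bump[-1])
        rate[1] <- mmr_i[f]
        out_cyc <- integer(0)
        if (config$outlier_fraction > 0) {
          eligible <- cyc[cyc > config$recovery_cycles]
          n_out <- round(config$outlier_fraction * config$n_cycles)
          n_out <- min(n_out, length(eligible))
          if (n_out > 0) {
            out_cyc <- sort(sample(eligible, n_out))
            rate[out_cyc] <- rate[out_cyc] *
              stats::runif(n_out, 0.05, 0.25)
          }
        }
        eff_vol <- vol[f] - mass[f] / 1000
        trials[[id]] <- data.frame(
          individual_id = id, species_id = sp$species_id[i],
          mass = mass[f], chamber_volume = vol[f],
          cycle = cyc,
          o2_slope = rate * 1000 / (1440 * eff_vol),
          duration = config$cycle_minutes,
          stringsAsFactors = FALSE
        )
        truths[[id]] <- data.frame(
          individual_id = id, species_id = sp$species_id[i],
          mass = mass[f], smr = smr_i[f], mmr = mmr_i[f],
          stringsAsFactors = FALSE
        )
        if (length(out_cyc))
          outs[[id]] <- data.frame(individual_id = id, cycle = out_cyc,
                                   stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, trials)
    rownames(out) <- NULL
    attr(out, "truth") <- {
      tr <- do.call(rbind, truths); rownames(tr) <- NULL; tr
    }
    attr(out, "outliers") <- if (length(outs)) {
      o <- do.call(rbind, outs); rownames(o) <- NULL; o
    } else {
      data.frame(individual_id = character(0), cycle = integer(0))
    }
    out
  })
}

#' Generate field swimming-speed observations
#'
#' Draws fork lengths log-uniformly over each species' length range and
#' log10 swimming speed from a location-scale Student-t around the species
#' speed-length line: heavy tails at small `nu_v` mimic the occasional
#' burst or mis-tracked individual in stereo-video data. A configured
#' fraction of observations is additionally replaced by gross low readings.
#'
#' @param config a [generator_config()].
#' @return Data frame `individual_id`, `species_id`, `length` (cm),
#'   `v_field` (cm s-1), `n_segments`, `time_period`; species truth in
#'   attribute `"truth"`.
#' @export
generate_speed_observations <- function(config) {
  stopifnot(inherits(config, "fishamr_config"))
  if (config$nu_v <= 2) stop_input("nu_v must exceed 2")
  sp <- config$species
  with_seed(sub_seed(config, "speed"), {
    rows <- lapply(seq_len(nrow(sp)), function(i) {
      n <- config$n_individuals$speed
      len <- runif_log(n, sp$length_min[i], sp$length_max[i])
      mu <- sp$a_v[i] + sp$b_v[i] * log10(len)
      v <- 10^(mu + config$sigma_v * stats::rt(n, config$nu_v))
      if (config$outlier_fraction > 0) {
        n_out <- round(config$outlier_fraction * n)
        if (n_out > 0) {
          idx <- sample(n, n_out)
          v[idx] <- v[idx] * stats::runif(n_out, 0.05, 0.25)
        }
      }
      data.frame(
        individual_id = sprintf("%s_v%03d", sp$species_id[i], seq_len(n)),
        species_id = sp$species_id[i],
        length = len, v_field = v,
        n_segments = sample(3:5, n, replace = TRUE),
        time_period = "day",
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "truth") <- sp
    out
  })
}

#' Generate maximum-swimming-speed records
#'
#' Emulates a flume-trial compilation: per species, lengths over the species
#' range and log10 maximum speed from
#' `(a + a_g) + (b + b_g) * log10(length) + c_ar * AR` plus Student-t noise,
#' where the group g is the family-by-body-shape combination. Group
#' intercept/slope offsets are drawn once (from `sd_a`, `sd_b`) under the
#' configured seed and echoed in the `"truth"` attribute.
#'
#' @param config a [generator_config()].
#' @return Data frame `record_id`, `species_id`, `family`, `body_shape`,
#'   `group`, `length` (cm), `aspect_ratio`, `vmax` (cm s-1). Attributes:
#'   `"truth"` (globals + per-group offsets) and `"metadata"` (including a
#'   warning flag when only one group is present).
#' @export
generate_maxspeed_records <- function(config) {
  stopifnot(inherits(config, "fishamr_config"))
  if (config$nu_vmax <= 2) stop_input("nu_vmax must exceed 2")
  sp <- config$species
  ms <- config$maxspeed
  groups <- unique(paste(sp$family, sp$body_shape, sep = ":"))
  with_seed(sub_seed(config, "maxspeed"), {
    offs <- data.frame(
      group = groups,
      a_g = stats::rnorm(length(groups), 0, ms$sd_a),
      b_g = stats::rnorm(length(groups), 0, ms$sd_b),
      stringsAsFactors = FALSE
    )
    rows <- lapply(seq_len(nrow(sp)), function(i) {
      n <- config$n_individuals$maxspeed
      g <- paste(sp$family[i], sp$body_shape[i], sep = ":")
      og <- offs[offs$group == g, ]
      len <- runif_log(n, sp$length_min[i], sp$length_max[i])
      mu <- (ms$a + og$a_g) + (ms$b + og$b_g) * log10(len) +
        ms$c_ar * sp$aspect_ratio[i]
      data.frame(
        record_id = sprintf("%s_m%03d", sp$species_id[i], seq_len(n)),
        species_id = sp$species_id[i],
        family = sp$family[i], body_shape = sp$body_shape[i], group = g,
        length = len, aspect_ratio = sp$aspect_ratio[i],
        vmax = 10^(mu + config$sigma_vmax * stats::rt(n, config$nu_vmax)),
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "truth") <- list(a = ms$a, b = ms$b, c_ar = ms$c_ar,
                               groups = offs)
    attr(out, "metadata") <- list(
      n_groups = length(groups),
      single_group_warning = length(groups) < 2
    )
    out
  })
}

#' Generate visual-census records
#'
#' For each site and transect, draws species abundances from a multinomial
#' over the configured relative abundances and integer total lengths
#' uniformly over each species' length range, recording the transect area.
#'
#' @param config a [generator_config()].
#' @return Data frame `site`, `transect`, `area` (m2), `species_id`,
#'   `total_length` (cm, nearest 1 cm), `count`.
#' @export
generate_census <- function(config) {
  stopifnot(inherits(config, "fishamr_config"))
  cz <- config$census
  if (length(cz$sites) == 0) stop_input("census site list is empty")
  sp <- config$species
  with_seed(sub_seed(config, "census"), {
    rows <- list(); k <- 0L
    for (site in cz$sites) {
      for (tr in seq_len(cz$transects_per_site)) {
        counts <- as.integer(stats::rmultinom(1, cz$fish_per_transect,
                                              cz$rel_abundance))
        for (i in seq_len(nrow(sp))) {
          if (counts[i] == 0) next
          lens <- sample(seq(ceiling(sp$length_min[i]),
                             floor(sp$length_max[i])),
                         counts[i], replace = TRUE)
          tab <- table(lens)
          k <- k + 1L
          rows[[k]] <- data.frame(
            site = site, transect = sprintf("%s_t%d", site, tr),
            area = cz$area, species_id = sp$species_id[i],
            total_length = as.integer(names(tab)),
            count = as.integer(tab),
            stringsAsFactors = FALSE
          )
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate stereo-video length-calibration measurements
#'
#' Pairs of (true length, measured length, camera distance) in which the
#' measurement error grows linearly with distance from the nearest camera:
#' `measured = true + intercept + slope * distance + noise`.
#'
#' @param config a [generator_config()]; the error model lives in
#'   `config$calibration`.
#' @return Data frame `true_length`, `measured_length` (cm),
#'   `distance` (m), with the true error model in attribute `"truth"`.
#' @export
generate_calibration_set <- function(config) {
  stopifnot(inherits(config, "fishamr_config"))
  cal <- config$calibration
  with_seed(sub_seed(config, "calibration"), {
    n <- cal$n
    true_len <- stats::runif(n, cal$true_length_range[1],
                             cal$true_length_range[2])
    dist <- stats::runif(n, cal$distance_range[1], cal$distance_range[2])
    meas <- true_len + cal$error_intercept + cal$error_slope * dist +
      stats::rnorm(n, 0, cal$sd)
    out <- data.frame(true_length = true_len, measured_length = meas,
                      distance = dist)
    attr(out, "truth") <- list(intercept = cal$error_intercept,
                               slope = cal$error_slope, sd = cal$sd)
    out
  })
}
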