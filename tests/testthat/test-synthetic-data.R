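# Synthetic-data generators: determinism, zero-noise exactness, and
# recovery of configured moments by independent estimators.

test_that("every generator is deterministic given the config seed", {
  cfg <- generator_config(species = two_species(), n_individuals = 8,
                          outlier_fraction = 0.05, n_cycles = 40,
                          seed = 42)
  gens <- list(generate_mr_observations, generate_respirometry_trials,
               generate_speed_observations, generate_maxspeed_records,
               generate_census, generate_calibration_set)
  for (g in gens) expect_identical(g(cfg), g(cfg))
})

test_that("zero-noise metabolic rates sit exactly on the allometric line", {
  sp <- species_truth("solo", a_smr = log10(0.004), b_smr = 0.75,
                      a_mmr = log10(0.012), b_mmr = 0.78,
                      a_v = 0.7, b_v = 0.5)
  cfg <- generator_config(species = sp, n_individuals = 20, sigma_mr = 0,
                          seed = 11)
  obs <- generate_mr_observations(cfg)
  expect_equal(obs$smr, 0.004 * obs$mass^0.75, tolerance = 1e-12)
  expect_equal(obs$mmr, 0.012 * obs$mass^0.78, tolerance = 1e-12)
})

test_that("least-squares slope recovers the configured exponent at n = 500", {
  sp <- species_truth("solo", a_smr = log10(0.004), b_smr = 0.75,
                      a_mmr = log10(0.012), b_mmr = 0.78,
                      a_v = 0.7, b_v = 0.5)
  cfg <- generator_config(species = sp, n_individuals = 500,
                          sigma_mr = 0.05, seed = 21)
  obs <- generate_mr_observations(cfg)
  ols <- stats::coef(lm(log10(smr) ~ log10(mass), data = obs))
  expect_lt(abs(ols[2] - 0.75), 0.02)
})

test_that("respirometry trials encode truth in first cycle and lower envelope", {
  cfg <- generator_config(species = two_species(), n_individuals = 3,
                          n_cycles = 60, sigma_mr = 0, sd_activity = 0,
                          seed = 5)
  tr <- generate_respirometry_trials(cfg)
  truth <- attr(tr, "truth")
  obs <- summarize_trials(tr)
  m <- merge(obs, truth, by = "individual_id")
  expect_equal(m$smr.x, m$smr.y, tolerance = 1e-12)
  expect_equal(m$mmr.x, m$mmr.y, tolerance = 1e-12)
})

test_that("injected gross outliers are flagged by the MAD rule", {
  cfg <- generator_config(species = two_species(), n_individuals = 2,
                          n_cycles = 100, outlier_fraction = 0.05,
                          seed = 9)
  tr <- generate_respirometry_trials(cfg)
  injected <- attr(tr, "outliers")
  expect_gte(nrow(injected), 1)
  for (id in unique(injected$individual_id)) {
    cyc <- tr[tr$individual_id == id, ]
    cyc <- cyc[order(cyc$cycle), ]
    pool_cycles <- cyc$cycle[-1]
    keep <- fishamr:::mad_keep(cyc$o2_slope[-1])
    flagged <- pool_cycles[!keep]
    expect_true(all(injected$cycle[injected$individual_id == id]
                    %in% flagged))
  }
})

test_that("speed residuals are heavy-tailed at low degrees of freedom", {
  sp <- species_truth("solo", a_smr = log10(0.004), b_smr = 0.75,
                      a_mmr = log10(0.012), b_mmr = 0.78,
                      a_v = 0.7, b_v = 0.5)
  cfg <- generator_config(species = sp, n_individuals = 2000,
                          sigma_v = 0.1, nu_v = 3, seed = 31)
  obs <- generate_speed_observations(cfg)
  resid <- log10(obs$v_field) - (0.7 + 0.5 * log10(obs$length))
  z <- (resid - mean(resid)) / sd(resid)
  kurt <- mean(z^4) - 3
  expect_gt(kurt, 0)
})

test_that("zero-scale speeds fall exactly on the power line", {
  sp <- two_species()
  cfg <- generator_config(species = sp, n_individuals = 10, sigma_v = 0,
                          seed = 3)
  obs <- generate_speed_observations(cfg)
  for (i in 1:2) {
    o <- obs[obs$species_id == sp$species_id[i], ]
    expect_equal(o$v_field, 10^sp$a_v[i] * o$length^sp$b_v[i],
                 tolerance = 1e-12)
  }
})

test_that("aspect ratio shifts log10 vmax by exactly its coefficient", {
  base <- two_species()
  shifted <- base
  shifted$aspect_ratio <- base$aspect_ratio + 1
  mk <- function(sp) generator_config(
    species = sp, n_individuals = 5, sigma_vmax = 0,
    maxspeed = list(c_ar = 0.05), seed = 8)
  v0 <- generate_maxspeed_records(mk(base))
  v1 <- generate_maxspeed_records(mk(shifted))
  expect_equal(log10(v1$vmax) - log10(v0$vmax), rep(0.05, nrow(v0)),
               tolerance = 1e-12)
})

test_that("within-group OLS recovers the group slope of the maxspeed model", {
  cfg <- generator_config(species = two_species(), n_individuals = 500,
                          sigma_vmax = 0.05, seed = 13)
  rec <- generate_maxspeed_records(cfg)
  truth <- attr(rec, "truth")
  for (g in unique(rec$group)) {
    r <- rec[rec$group == g, ]
    b_true <- truth$b + truth$groups$b_g[truth$groups$group == g]
    ols <- stats::coef(lm(log10(vmax) ~ log10(length), data = r))
    expect_lt(abs(ols[2] - b_true), 0.05)
  }
})

test_that("census counts follow the configured relative abundances", {
  sp <- species_truth(
    species_id = c("a", "b", "c"),
    a_smr = log10(0.004), b_smr = 0.75,
    a_mmr = log10(0.012), b_mmr = 0.78, a_v = 0.7, b_v = 0.5)
  cfg <- generator_config(
    species = sp, seed = 17,
    census = list(sites = "s1", transects_per_site = 1L,
                  fish_per_transect = 1000L,
                  rel_abundance = c(0.5, 0.3, 0.2)))
  cz <- generate_census(cfg)
  shares <- tapply(cz$count, cz$species_id, sum) / sum(cz$count)
  expect_lt(max(abs(shares[c("a", "b", "c")] - c(0.5, 0.3, 0.2))), 0.05)
})

test_that("a single-fish census yields a single record with count 1", {
  sp <- species_truth("solo", a_smr = log10(0.004), b_smr = 0.75,
                      a_mmr = log10(0.012), b_mmr = 0.78,
                      a_v = 0.7, b_v = 0.5)
  cfg <- generator_config(
    species = sp, seed = 2,
    census = list(sites = "s1", transects_per_site = 1L,
                  fish_per_transect = 1L, rel_abundance = 1))
  cz <- generate_census(cfg)
  expect_equal(nrow(cz), 1)
  expect_equal(cz$count, 1L)
})

test_that("calibration pairs follow the configured error model", {
  cfg <- generator_config(
    species = two_species(), seed = 4,
    calibration = list(error_intercept = 0.5, error_slope = 0.1, sd = 0,
                       n = 50L))
  cal <- generate_calibration_set(cfg)
  expect_equal(cal$measured_length - cal$true_length,
               0.5 + 0.1 * cal$distance, tolerance = 1e-12)
})

test_that("generated log-scale residual moments match configuration", {
  sp <- species_truth("solo", a_smr = log10(0.004), b_smr = 0.75,
                      a_mmr = log10(0.012), b_mmr = 0.78,
                      a_v = 0.7, b_v = 0.5)
  cfg <- generator_config(species = sp, n_individuals = 2000,
                          sigma_mr = 0.05, seed = 23)
  obs <- generate_mr_observations(cfg)
  resid <- log10(obs$smr) - (log10(0.004) + 0.75 * log10(obs$mass))
  n <- length(resid)
  expect_lt(abs(mean(resid)), 3 * 0.05 / sqrt(n))
  expect_lt(abs(sd(resid) - 0.05), 3 * 0.05 / sqrt(2 * n))
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(species = two_species(), sigma_mr = -1),
               "SD")
  expect_error(generator_config(species = two_species(), nu_v = 2),
               "exceed 2")
  expect_error(generator_config(species = two_species(),
                                mass_range = c(10, 5)), "mass_range")
  expect_error(species_truth("x", a_smr = -2, b_smr = 0.75, a_mmr = -2.5,
                             b_mmr = 0.78, a_v = 0.7, b_v = 0.5),
               "a_mmr")
})
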