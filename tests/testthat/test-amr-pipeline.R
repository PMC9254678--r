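# AMRfield / FAS / FSA algebra and the size-resolved estimate grid.

test_that("length-weight conversion follows the power law", {
  expect_equal(length_to_weight(1, 0.02, 3), 0.02)
  expect_equal(length_to_weight(10, 0.02, 3), 20)
  expect_equal(length_to_weight(7, 0.02, 0), 0.02)
  expect_error(length_to_weight(-1, 0.02, 3), "positive")
})

test_that("AMRfield hits SMR at rest and MMR at maximum speed", {
  set.seed(101)
  for (i in 1:50) {
    smr <- 10^runif(1, -3, 0)
    mmr <- smr * runif(1, 1, 10)
    vmax <- runif(1, 10, 200)
    expect_lt(abs(amr_field(smr, mmr, vmax, 0) - smr) / smr, 1e-12)
    expect_lt(abs(amr_field(smr, mmr, vmax, vmax) - mmr) / mmr, 1e-12)
  }
})

test_that("AMRfield at half the maximum speed is the geometric mean", {
  expect_equal(as.numeric(amr_field(0.01, 0.04, 100, 50)), 0.02)
  set.seed(202)
  for (i in 1:200) {
    smr <- 10^runif(1, -4, 0)
    mmr <- smr * runif(1, 1, 20)
    vmax <- runif(1, 5, 300)
    got <- as.numeric(amr_field(smr, mmr, vmax, vmax / 2))
    expect_equal(got, sqrt(smr * mmr), tolerance = 1e-12)
  }
})

test_that("AMRfield is monotone and log-linear in the relative speed", {
  smr <- 0.01; mmr <- 0.05; vmax <- 120
  v <- seq(0, 240, by = 10)
  amr <- amr_field(smr, mmr, vmax, v)
  expect_true(all(diff(amr) > 0))
  # equal speed increments multiply the rate by a constant factor
  ratios <- amr[-1] / amr[-length(amr)]
  expect_equal(ratios, rep(10^((10 / vmax) * log10(mmr / smr)),
                           length(ratios)), tolerance = 1e-10)
  # extrapolation past vmax is represented and counted, not capped
  expect_gt(max(amr), mmr)
  expect_equal(attr(amr, "n_extrapolated"), sum(v > vmax))
  expect_error(amr_field(0.05, 0.01, 100, 10), "at least smr")
})

test_that("factorial aerobic scope is the MMR/SMR ratio", {
  expect_equal(fas(0.01, 0.01), 1)
  expect_equal(fas(0.04, 0.01), 4)
  # ratio of published-scale medians for a 1 g piscivore-like case
  expect_equal(fas(0.0124, 0.0033), 3.7575758, tolerance = 1e-6)
  expect_error(fas(0.04, 0), "positive")
})

test_that("FSA follows the time-weighted scope algebra", {
  for (t in c(0, 3, 12, 24)) expect_equal(fsa(0.02, 0.02, t), 1)
  expect_equal(fsa(3 * 0.01, 0.01, 12), 2)
  expect_equal(fsa(5 * 0.01, 0.01, 24), 1)
  expect_equal(fsa(2 * 0.01, 0.01, 0), 2)
  # increasing in amr, decreasing in rest hours when amr > smr
  expect_gt(fsa(0.03, 0.01, 12), fsa(0.02, 0.01, 12))
  expect_gt(fsa(0.03, 0.01, 6), fsa(0.03, 0.01, 18))
  expect_error(fsa(0.02, 0.01, 25), "rest_hours")
})

test_that("the AMRfield mass-scaling exponent interpolates the component exponents", {
  b_smr <- 0.70; b_mmr <- 0.80
  mass <- 10^seq(0, 3, length.out = 50)
  smr <- 0.004 * mass^b_smr
  mmr <- 0.012 * mass^b_mmr
  # size-constant relative speed: exponent strictly between the two
  r <- 0.4
  amr <- amr_field(smr, mmr, 100, r * 100)
  slope <- coef(lm(log10(amr) ~ log10(mass)))[2]
  expect_gt(slope, b_smr)
  expect_lt(slope, b_mmr)
  # relative speed rising with size: exponent can exceed the MMR exponent
  r2 <- 0.2 + (0.9 - 0.2) * log10(mass) / 3
  amr2 <- amr_field(smr, mmr, 100, r2 * 100)
  slope2 <- coef(lm(log10(amr2) ~ log10(mass)))[2]
  expect_gt(slope2, b_mmr)
})

test_that("degenerate fits collapse the size grid to closed-form values", {
  traits <- two_species()
  mr_fit <- degenerate_fit(
    "mr", a = 0, b = 0,
    groups = c("alpha:mmr", "alpha:smr", "beta:mmr", "beta:smr"),
    a_g = c(log10(0.012), log10(0.004), log10(0.010), log10(0.003)),
    b_g = c(0.75, 0.75, 0.75, 0.75))
  speed_fit <- degenerate_fit("speed", a = 0.7, b = 0.5,
                              groups = c("alpha", "beta"))
  maxspeed_fit <- degenerate_fit(
    "maxspeed", a = 1.0, b = 0.5,
    groups = c("FamA:fusiform", "FamB:compressed"), c_ar = 0.1, nu = 10)

  est <- species_size_estimates(mr_fit, speed_fit, maxspeed_fit, traits,
                                n_iter = 100, seed = 1)
  expect_true(all(est$amr_sd == 0))
  expect_true(all(est$fsa_sd == 0))
  # closed-form check for one cell
  row <- est[est$species_id == "alpha" & est$length == 10, ]
  mass <- length_to_weight(10, traits$lw_a[1], traits$lw_b[1])
  smr <- 10^(log10(0.004) + 0.75 * log10(mass))
  mmr <- 10^(log10(0.012) + 0.75 * log10(mass))
  vf <- 10^(0.7 + 0.5 * log10(10))
  vmax <- 10^(1.0 + 0.5 * log10(10) + 0.1 * traits$aspect_ratio[1])
  expect_equal(row$amr_mean, as.numeric(amr_field(smr, mmr, vmax, vf)),
               tolerance = 1e-12)
  expect_equal(row$fas_mean, mmr / smr, tolerance = 1e-12)
  expect_equal(row$fsa_mean, as.numeric(fsa(amr_field(smr, mmr, vmax, vf),
                                            smr, 12)), tolerance = 1e-12)

  # components all increasing and FAS size-constant: AMR non-decreasing
  for (s in traits$species_id) {
    expect_true(all(diff(est$amr_mean[est$species_id == s]) >= 0))
  }
})

test_that("size-grid estimates are deterministic given the seed", {
  set.seed(44)
  obs <- data.frame(
    individual_id = sprintf("i%03d", 1:40),
    species_id = rep(c("alpha", "beta"), each = 20),
    mass = rep(10^seq(log10(5), log10(400), length.out = 20), 2))
  obs$smr <- 10^(log10(0.004) + 0.72 * log10(obs$mass) +
                   rnorm(40, 0, 0.05))
  obs$mmr <- obs$smr * 3
  mr_fit <- fit_mr_model(obs, fast_settings(), seed = 2)
  cfg <- generator_config(species = two_species(), n_individuals = 30,
                          seed = 33)
  speed_fit <- fit_speed_model(generate_speed_observations(cfg),
                               fast_settings(), seed = 3)
  maxspeed_fit <- fit_maxspeed_model(generate_maxspeed_records(cfg),
                                     fast_settings(), seed = 4)
  e1 <- suppressWarnings(species_size_estimates(
    mr_fit, speed_fit, maxspeed_fit, two_species(), n_iter = 200,
    seed = 9))
  e2 <- suppressWarnings(species_size_estimates(
    mr_fit, speed_fit, maxspeed_fit, two_species(), n_iter = 200,
    seed = 9))
  expect_identical(e1, e2)
  expect_true(all(e1$smr_med <= e1$mmr_med))
  expect_true(all(e1$amr_lo <= e1$amr_hi))
  expect_true(all(e1$fas_mean >= 1))
})
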