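# Hierarchical Bayesian fits: sampler determinism, conjugate-limit
# correctness, recovery on constructed data, prediction contracts, and
# Bayesian R2.

make_mr_line <- function(n = 20, a = log10(0.004), b = 0.75,
                         fas = 3, sigma = 0, seed = 42) {
  # two identical species on exact allometric lines
  set.seed(seed)
  mass <- 10^runif(2 * n, log10(5), log10(500))
  noise <- if (sigma > 0) rnorm(2 * n, 0, sigma) else 0
  data.frame(
    individual_id = sprintf("i%03d", seq_len(2 * n)),
    species_id = rep(c("alpha", "beta"), each = n),
    mass = mass,
    smr = 10^(a + b * log10(mass) + noise),
    mmr = fas * 10^(a + b * log10(mass) + noise))
}

test_that("fits are reproducible given data and seed", {
  obs <- make_mr_line(n = 10, sigma = 0.05)
  s <- fast_settings()
  f1 <- fit_mr_model(obs, s, seed = 3)
  f2 <- fit_mr_model(obs, s, seed = 3)
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_mr_model(obs, s, seed = 4)
  expect_false(identical(f3$draws, f1$draws))
})

test_that("posterior summaries are invariant to input row order", {
  obs <- make_mr_line(n = 10, sigma = 0.05)
  s <- fast_settings()
  f1 <- fit_mr_model(obs, s, seed = 5)
  f2 <- fit_mr_model(obs[rev(seq_len(nrow(obs))), ], s, seed = 5)
  expect_identical(f1$summary, f2$summary)
})

test_that("the known-sigma vague-prior posterior matches the conjugate form", {
  set.seed(8)
  n <- 60
  mass <- 10^runif(n, log10(5), log10(500))
  sigma <- 0.05
  obs <- data.frame(individual_id = sprintf("i%02d", 1:n),
                    species_id = "solo", mass = mass,
                    smr = 10^(log10(0.004) + 0.75 * log10(mass) +
                                rnorm(n, 0, sigma)),
                    mmr = 10^(log10(0.012) + 0.75 * log10(mass) +
                                rnorm(n, 0, sigma)))
  s <- fit_settings(chains = 2, adapt = 500, burnin = 500, iter = 2500,
                    hierarchical = FALSE, sigma_fixed = sigma,
                    a_prior_sd = 100, b_prior_mean = 0, b_prior_sd = 100,
                    on_nonconvergence = "ignore")
  fit <- fit_mr_model(obs, s, seed = 6)

  # analytic normal posterior on the same stacked design
  X <- cbind(1, rep(log10(mass), 2))
  y <- c(log10(obs$smr), log10(obs$mmr))
  prior_prec <- diag(1 / 100^2, 2)
  V <- solve(crossprod(X) / sigma^2 + prior_prec)
  m <- V %*% (crossprod(X, y) / sigma^2)
  post_sd <- sqrt(diag(V))

  got <- fit$summary[match(c("a", "b"), fit$summary$parameter), ]
  expect_lt(abs(got$mean[1] - m[1]) / abs(m[1]), 0.02)
  expect_lt(abs(got$mean[2] - m[2]) / abs(m[2]), 0.02)
  expect_lt(abs(got$sd[1] - post_sd[1]) / post_sd[1], 0.05)
  expect_lt(abs(got$sd[2] - post_sd[2]) / post_sd[2], 0.05)
})

test_that("species slope posteriors concentrate at truth on a clean line", {
  sp <- two_species()
  cfg <- generator_config(species = sp, n_individuals = 40,
                          sigma_v = 1e-3, seed = 19)
  obs <- generate_speed_observations(cfg)
  fit <- fit_speed_model(obs, fast_settings(), seed = 7)
  co <- group_coefficients(fit)
  for (i in 1:2) {
    got <- co$slope_mean[co$group == sp$species_id[i]]
    expect_lt(abs(got - sp$b_v[i]), 0.02)
  }
})

test_that("the aspect-ratio coefficient is recovered on near-noiseless data", {
  # groups must contain species with different aspect ratios so that the
  # coefficient is identified within groups, not only across them
  sp <- species_truth(
    species_id = c("a1", "a2", "b1", "b2"),
    a_smr = log10(0.004), b_smr = 0.75,
    a_mmr = log10(0.012), b_mmr = 0.78, a_v = 0.7, b_v = 0.5,
    aspect_ratio = c(1.0, 2.2, 1.4, 3.0),
    family = c("FamA", "FamA", "FamB", "FamB"),
    body_shape = c("fusiform", "fusiform", "compressed", "compressed"))
  cfg <- generator_config(species = sp, n_individuals = 40,
                          sigma_vmax = 1e-3,
                          maxspeed = list(c_ar = 0.05), seed = 20)
  rec <- generate_maxspeed_records(cfg)
  fit <- fit_maxspeed_model(rec, fast_settings(), seed = 8)
  c_hat <- fit$summary$mean[fit$summary$parameter == "c_ar"]
  expect_lt(abs(c_hat - 0.05), 0.01)
})

test_that("prediction returns expected-value draws and closed-form medians", {
  obs <- make_mr_line(n = 15, sigma = 1e-4)
  fit <- fit_mr_model(obs, fast_settings(), seed = 9)
  med <- predict_expected(
    fit, data.frame(species_id = "alpha", mass = 100, rate_type = "smr"),
    median_flag = TRUE)
  expect_equal(med, 0.004 * 100^0.75, tolerance = 0.005)

  draws <- predict_expected(
    fit, data.frame(species_id = "alpha", mass = 100, rate_type = "smr"))
  # the median of a monotone transform is the transform of the median
  expect_equal(median(draws[, 1]), med, tolerance = 1e-12)

  expect_error(predict_expected(
    fit, data.frame(species_id = "nope", mass = 10, rate_type = "smr")),
    "unknown group")
})

test_that("degenerate posteriors predict the point value", {
  fit <- degenerate_fit("mr", a = log10(0.004), b = 0.75,
                        groups = c("alpha:mmr", "alpha:smr"))
  med <- predict_expected(
    fit, data.frame(species_id = "alpha", mass = 100, rate_type = "smr"),
    median_flag = TRUE)
  expect_equal(med, 0.004 * 100^0.75, tolerance = 1e-12)
  draws <- predict_expected(
    fit, data.frame(species_id = "alpha", mass = 100, rate_type = "smr"))
  expect_equal(sd(draws[, 1]), 0)
})

test_that("unseen groups are predicted marginally with wider intervals", {
  cfg <- generator_config(species = two_species(), n_individuals = 30,
                          sigma_vmax = 0.05, seed = 22)
  rec <- generate_maxspeed_records(cfg)
  fit <- fit_maxspeed_model(rec, fast_settings(), seed = 10)
  known <- predict_expected(
    fit, data.frame(family = "FamA", body_shape = "fusiform",
                    length = 15, aspect_ratio = 1.5), seed = 2)
  unseen <- predict_expected(
    fit, data.frame(family = "FamZ", body_shape = "eel",
                    length = 15, aspect_ratio = 1.5), seed = 2)
  expect_gt(sd(log10(unseen[, 1])), sd(log10(known[, 1])))
})

test_that("Bayesian R2 stays in [0,1) and separates signal from noise", {
  clean <- make_mr_line(n = 15, sigma = 1e-4)
  fit_clean <- fit_mr_model(clean, fast_settings(), seed = 11)
  r2c <- bayes_r2(fit_clean)
  expect_true(all(r2c$draws >= 0 & r2c$draws < 1))
  expect_gt(r2c$median, 0.99)

  # flat truth: speeds independent of length
  set.seed(13)
  noise <- data.frame(
    individual_id = sprintf("i%03d", 1:200),
    species_id = rep(c("alpha", "beta"), each = 100),
    length = 10^runif(200, log10(5), log10(40)),
    v_field = 10^rnorm(200, 1.2, 0.3))
  fit_noise <- fit_speed_model(noise, fast_settings(), seed = 12)
  r2n <- bayes_r2(fit_noise)
  expect_true(all(r2n$draws >= 0 & r2n$draws < 1))
  expect_lt(r2n$median, 0.1)
})

test_that("input contracts are enforced", {
  obs <- make_mr_line(n = 5)
  one <- obs[obs$species_id == "alpha", ]
  expect_error(fit_mr_model(one, fit_settings()), "at least 2 species")
  bad <- obs; bad$smr[1] <- -1
  expect_error(fit_mr_model(bad, fit_settings()), "positive")
})
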