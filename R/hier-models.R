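# Hierarchical Bayesian allometric regressions (JAGS backend).
#
# Three model families share one sampler harness:
#   * metabolic rate:  log10 MR ~ Normal((a + a_g) + (b + b_g) x, sigma),
#     groups g = species x rate-type (SMR/MMR) cells;
#   * field speed:     log10 v ~ Student-t(nu, (a + a_g) + (b + b_g) x, sigma),
#     groups g = species;
#   * maximum speed:   log10 vmax ~ Student-t(nu, (a + a_g) + (b + b_g) x
#     + c_ar AR, sigma), groups g = family x body-shape.
# x is log10 mass (g) or log10 length (cm); all rates g O2 d-1, speeds
# cm s-1.

#' Sampler and prior settings for the hierarchical fits
#'
#' The global slope prior defaults to the informative Normal(0.75, 0.1)
#' used for the metabolic scaling exponent; every other prior is weakly
#' informative: intercepts Normal(0, 5), group-offset SDs and residual SD
#' half-Normal(0, 1), Student-t degrees of freedom Gamma(2, 0.1) truncated
#' above 2, aspect-ratio coefficient Normal(0, 5).
#'
#' @param chains number of MCMC chains.
#' @param adapt,burnin,iter adaptation, burn-in, and retained iterations
#'   per chain.
#' @param thin thinning interval.
#' @param b_prior_mean,b_prior_sd global-slope prior.
#' @param a_prior_sd global-intercept prior SD.
#' @param sigma_prior_sd,group_sd_prior_sd half-normal scales for the
#'   residual SD and the group-offset SDs.
#' @param ar_prior_sd prior SD of the aspect-ratio coefficient.
#' @param nu_shape,nu_rate Gamma prior on the t degrees of freedom.
#' @param sigma_fixed if non-NULL, the residual SD is held at this value
#'   (known-sigma fits).
#' @param hierarchical if FALSE, group offsets are dropped and a single
#'   pooled regression is fitted.
#' @param likelihood `"normal"` or `"t"`; `NULL` uses each model's default.
#' @param rhat_max,ess_min convergence thresholds (split R-hat, bulk ESS
#'   summed over chains) applied to every monitored parameter.
#' @param on_nonconvergence `"stop"` (raise a condition carrying the fit),
#'   `"warn"`, or `"ignore"`.
#' @return A list of class `"fishamr_settings"`.
#' @export
fit_settings <- function(chains = 4, adapt = 1000, burnin = 1000,
                         iter = 2500,
                         thin = 1,
                         b_prior_mean = 0.75, b_prior_sd = 0.1,
                         a_prior_sd = 5,
                         sigma_prior_sd = 1, group_sd_prior_sd = 1,
                         ar_prior_sd = 5,
                         nu_shape = 2, nu_rate = 0.1,
                         sigma_fixed = NULL,
                         hierarchical = TRUE,
                         likelihood = NULL,
                         rhat_max = 1.01, ess_min = 400,
                         on_nonconvergence = c("stop", "warn", "ignore")) {
  structure(
    list(chains = chains, adapt = adapt, burnin = burnin, iter = iter,
         thin = thin,
         b_prior_mean = b_prior_mean, b_prior_sd = b_prior_sd,
         a_prior_sd = a_prior_sd,
         sigma_prior_sd = sigma_prior_sd,
         group_sd_prior_sd = group_sd_prior_sd,
         ar_prior_sd = ar_prior_sd,
         nu_shape = nu_shape, nu_rate = nu_rate,
         sigma_fixed = sigma_fixed,
         hierarchical = hierarchical,
         likelihood = likelihood,
         rhat_max = rhat_max, ess_min = ess_min,
         on_nonconvergence = match.arg(on_nonconvergence)),
    class = "fishamr_settings"
  )
}

# Assemble the JAGS model string for a given structure.
jags_model_string <- function(likelihood, hierarchical, has_ar,
                              sigma_fixed) {
  lik <- if (likelihood == "t") {
    "y[i] ~ dt(mu[i], tau, nu)"
  } else {
    "y[i] ~ dnorm(mu[i], tau)"
  }
  mu <- if (hierarchical) {
    paste0("mu[i] <- a_sp[g[i]] + b_sp[g[i]] * x[i]",
           if (has_ar) " + c_ar * ar[i]" else "")
  } else {
    paste0("mu[i] <- a + b * x[i]", if (has_ar) " + c_ar * ar[i]" else "")
  }
  # group coefficients are centred on the globals (hierarchical centering
  # mixes far better than global + offset here); offsets are derived nodes.
  # With an aspect-ratio term, AR is split into group means (entering the
  # group-intercept prior mean) and within-group deviations (entering mu):
  # an exact rewrite that lets c_ar mix at the group level.
  a_sp_prior <- if (has_ar) "dnorm(a + c_ar * ar_g[j], tau_ag)"
                else "dnorm(a, tau_ag)"
  a_g_def <- if (has_ar) "a_sp[j] - a - c_ar * ar_g[j]" else "a_sp[j] - a"
  group_block <- if (hierarchical) paste0("
  for (j in 1:G) {
    a_sp[j] ~ ", a_sp_prior, "
    b_sp[j] ~ dnorm(b, tau_bg)
    a_g[j] <- ", a_g_def, "
    b_g[j] <- b_sp[j] - b
  }
  sd_ag ~ dnorm(0, pow(group_sd_prior_sd, -2)) T(0,)
  sd_bg ~ dnorm(0, pow(group_sd_prior_sd, -2)) T(0,)
  tau_ag <- pow(sd_ag, -2)
  tau_bg <- pow(sd_bg, -2)") else ""
  sigma_block <- if (is.null(sigma_fixed)) "
  sigma ~ dnorm(0, pow(sigma_prior_sd, -2)) T(0,)" else ""
  nu_block <- if (likelihood == "t") "
  nu ~ dgamma(nu_shape, nu_rate) T(2,)" else ""
  ar_block <- if (has_ar) "
  c_ar ~ dnorm(0, pow(ar_prior_sd, -2))" else ""
  paste0("model {
  for (i in 1:N) {
    ", lik, "
    ", mu, "
  }", group_block, "
  a ~ dnorm(0, pow(a_prior_sd, -2))
  b ~ dnorm(b_prior_mean, pow(b_prior_sd, -2))",
  sigma_block, "
  tau <- pow(sigma, -2)", nu_block, ar_block, "
}")
}

# Shared sampler harness. df must carry columns y, x, group (factor) and
# optionally ar. Returns a "fishamr_fit".
run_jags_fit <- function(df, model_name, likelihood, settings, seed,
                         has_ar = FALSE) {
  # canonical row order: posteriors are invariant to input permutation
  ord <- order(df$group, df$x, df$y)
  df <- df[ord, , drop = FALSE]
  hierarchical <- settings$hierarchical
  glev <- levels(droplevels(factor(df$group)))
  # sample on centred covariates (decorrelates intercepts from slopes and
  # the aspect-ratio coefficient); draws are mapped back afterwards
  x_bar <- mean(df$x)
  ar_bar <- if (has_ar) mean(df$ar) else 0
  data <- list(
    y = df$y, x = df$x - x_bar, N = nrow(df),
    a_prior_sd = settings$a_prior_sd,
    b_prior_mean = settings$b_prior_mean,
    b_prior_sd = settings$b_prior_sd
  )
  if (hierarchical) {
    data$g <- as.integer(factor(df$group, levels = glev))
    data$G <- length(glev)
    data$group_sd_prior_sd <- settings$group_sd_prior_sd
  }
  if (has_ar) {
    arc <- df$ar - ar_bar
    if (hierarchical) {
      gi <- as.integer(factor(df$group, levels = glev))
      ar_g <- tapply(arc, gi, mean)[as.character(seq_along(glev))]
      data$ar <- arc - ar_g[gi]      # within-group deviations
      data$ar_g <- as.numeric(ar_g)  # group means, centred overall
    } else {
      data$ar <- arc
    }
    data$ar_prior_sd <- settings$ar_prior_sd
  }
  if (is.null(settings$sigma_fixed)) {
    data$sigma_prior_sd <- settings$sigma_prior_sd
  } else {
    data$sigma <- settings$sigma_fixed
  }
  if (likelihood == "t") {
    data$nu_shape <- settings$nu_shape
    data$nu_rate <- settings$nu_rate
  }
  monitors <- c("a", "b")
  if (hierarchical) monitors <- c(monitors, "a_g", "b_g", "sd_ag", "sd_bg")
  if (is.null(settings$sigma_fixed)) monitors <- c(monitors, "sigma")
  if (likelihood == "t") monitors <- c(monitors, "nu")
  if (has_ar) monitors <- c(monitors, "c_ar")

  inits <- lapply(seq_len(settings$chains), function(k) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer(seed) + 17L * k)
  })
  mstr <- jags_model_string(likelihood, hierarchical, has_ar,
                            settings$sigma_fixed)
  jm <- rjags::jags.model(textConnection(mstr), data = data, inits = inits,
                          n.chains = settings$chains,
                          n.adapt = settings$adapt, quiet = TRUE)
  stats::update(jm, settings$burnin, progress.bar = "none")
  samp <- rjags::coda.samples(jm, monitors, n.iter = settings$iter,
                              thin = settings$thin, progress.bar = "none")
  # map draws back to the uncentred parameterisation:
  #   a        <- a - b * x_bar - c_ar * ar_bar
  #   a_g[j]   <- a_g[j] - b_g[j] * x_bar
  samp <- lapply(samp, function(ch) {
    m <- as.matrix(ch)
    shift <- m[, "b"] * x_bar
    if (has_ar) shift <- shift + m[, "c_ar"] * ar_bar
    m[, "a"] <- m[, "a"] - shift
    if (hierarchical) {
      for (j in seq_along(glev)) {
        m[, sprintf("a_g[%d]", j)] <- m[, sprintf("a_g[%d]", j)] -
          m[, sprintf("b_g[%d]", j)] * x_bar
      }
    }
    coda::mcmc(m, start = stats::start(ch), thin = coda::thin(ch))
  })
  samp <- coda::mcmc.list(samp)

  pars <- colnames(samp[[1]])
  rhat <- vapply(pars, function(p) {
    split_rhat(sapply(samp, function(ch) as.numeric(ch[, p])))
  }, numeric(1))
  ess <- coda::effectiveSize(samp)[pars]
  draws <- do.call(rbind, lapply(samp, as.matrix))
  qs <- t(apply(draws, 2, stats::quantile, c(0.025, 0.5, 0.975)))
  summary <- data.frame(
    parameter = pars,
    mean = colMeans(draws), sd = apply(draws, 2, stats::sd),
    q2.5 = qs[, 1], median = qs[, 2], q97.5 = qs[, 3],
    rhat = rhat, ess = as.numeric(ess),
    row.names = NULL, stringsAsFactors = FALSE
  )
  converged <- all(rhat <= settings$rhat_max, na.rm = TRUE) &&
    all(ess >= settings$ess_min, na.rm = TRUE)

  fit <- structure(
    list(model = model_name, likelihood = likelihood,
         draws = draws, mcmc = samp, group_levels = glev,
         hierarchical = hierarchical, has_ar = has_ar,
         data = df, settings = settings, seed = seed,
         summary = summary, converged = converged),
    class = "fishamr_fit"
  )
  if (!converged) {
    worst <- summary$parameter[which.max(summary$rhat)]
    msg <- sprintf(
      "%s model did not meet convergence thresholds (max split R-hat %.4f at %s, min ESS %.0f)",
      model_name, max(rhat, na.rm = TRUE), worst, min(ess, na.rm = TRUE))
    if (settings$on_nonconvergence == "stop") {
      cond <- structure(
        class = c("fishamr_convergence_error", "error", "condition"),
        list(message = msg, call = sys.call(-1), fit = fit))
      stop(cond)
    } else if (settings$on_nonconvergence == "warn") {
      warning(msg, call. = FALSE)
    }
  }
  fit
}

#' @export
print.fishamr_fit <- function(x, ...) {
  cat("<fishamr_fit>", x$model, "model,", x$likelihood, "likelihood\n")
  cat(sprintf("  %d draws (%d chains), %d observations, %d group(s)\n",
              nrow(x$draws), x$settings$chains, nrow(x$data),
              length(x$group_levels)))
  cat("  converged:", x$converged, "\n")
  core <- x$summary[x$summary$parameter %in%
                      c("a", "b", "sigma", "nu", "c_ar"), ]
  print(core, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Fit the hierarchical metabolic-rate allometry
#'
#' Models log10 SMR and log10 MMR jointly against log10 body mass with a
#' Normal likelihood. Each species-by-rate-type cell gets its own
#' intercept and slope offset around the global intercept and the global
#' mass-scaling exponent, whose prior is the informative Normal(0.75, 0.1).
#'
#' @param obs data frame with columns `individual_id`, `species_id`,
#'   `mass` (g), `smr`, `mmr` (g O2 d-1).
#' @param settings a [fit_settings()].
#' @param seed integer seed; fits are reproducible given it.
#' @return A `"fishamr_fit"` with groups `species:smr` / `species:mmr`.
#' @export
fit_mr_model <- function(obs, settings = fit_settings(), seed = 1) {
  stopifnot(all(c("species_id", "mass", "smr", "mmr") %in% names(obs)))
  if (any(obs$smr <= 0 | obs$mmr <= 0))
    stop_input("metabolic rates must be positive")
  if (settings$hierarchical) {
    sp <- unique(obs$species_id)
    if (length(sp) < 2)
      stop_input("need at least 2 species for the hierarchical fit")
    miss <- sp[vapply(sp, function(s) {
      any(is.na(obs$smr[obs$species_id == s])) ||
        any(is.na(obs$mmr[obs$species_id == s]))
    }, logical(1))]
    if (length(miss))
      stop_input("species missing a rate type: %s",
                 paste(miss, collapse = ", "))
  }
  long <- data.frame(
    y = c(log10(obs$smr), log10(obs$mmr)),
    x = rep(log10(obs$mass), 2),
    group = c(paste0(obs$species_id, ":smr"),
              paste0(obs$species_id, ":mmr")),
    stringsAsFactors = FALSE
  )
  run_jags_fit(long, "mr", likelihood = settings$likelihood %||% "normal",
               settings = settings, seed = seed)
}

#' Fit the hierarchical field swimming-speed regression
#'
#' Models log10 field swimming speed against log10 fork length with a
#' robust Student-t likelihood (stereo-video data include outliers);
#' species-level intercept and slope offsets around the global line.
#'
#' @param obs data frame with columns `species_id`, `length` (cm),
#'   `v_field` (cm s-1).
#' @inheritParams fit_mr_model
#' @return A `"fishamr_fit"` with species groups and a `nu` posterior.
#' @export
fit_speed_model <- function(obs, settings = fit_settings(), seed = 1) {
  stopifnot(all(c("species_id", "length", "v_field") %in% names(obs)))
  if (any(obs$length <= 0 | obs$v_field <= 0))
    stop_input("lengths and speeds must be positive")
  if (settings$hierarchical && length(unique(obs$species_id)) < 2)
    stop_input("need at least 2 species for the hierarchical fit")
  n_per <- table(obs$species_id)
  if (any(n_per < 10))
    warning("fewer than 10 speed observations for: ",
            paste(names(n_per)[n_per < 10], collapse = ", "),
            call. = FALSE)
  df <- data.frame(y = log10(obs$v_field), x = log10(obs$length),
                   group = obs$species_id, stringsAsFactors = FALSE)
  run_jags_fit(df, "speed", likelihood = settings$likelihood %||% "t",
               settings = settings, seed = seed)
}

#' Fit the hierarchical maximum swimming-speed regression
#'
#' Models log10 maximum swimming speed against log10 body length and caudal
#' aspect ratio, with Student-t residuals and intercept/slope offsets for
#' each family-by-body-shape group. The aspect ratio enters linearly with a
#' single global coefficient.
#'
#' @param records data frame with columns `family`, `body_shape`,
#'   `length` (cm), `aspect_ratio`, `vmax` (cm s-1).
#' @inheritParams fit_mr_model
#' @return A `"fishamr_fit"` with family:body-shape groups and a summarized
#'   aspect-ratio coefficient `c_ar`.
#' @export
fit_maxspeed_model <- function(records, settings = fit_settings(),
                               seed = 1) {
  stopifnot(all(c("family", "body_shape", "length", "aspect_ratio", "vmax")
                %in% names(records)))
  grp <- paste(records$family, records$body_shape, sep = ":")
  if (settings$hierarchical && length(unique(grp)) < 2)
    stop_input("need at least 2 family:body-shape groups")
  df <- data.frame(y = log10(records$vmax), x = log10(records$length),
                   group = grp, ar = records$aspect_ratio,
                   stringsAsFactors = FALSE)
  run_jags_fit(df, "maxspeed", likelihood = settings$likelihood %||% "t",
               settings = settings, seed = seed, has_ar = TRUE)
}

# Per-draw linear predictor mu for new covariate rows.
# newdata columns: x (log10 covariate), group, and ar when the model has it.
mu_draws <- function(fit, newdata, seed = 1) {
  d <- fit$draws
  n_draws <- nrow(d)
  out <- matrix(NA_real_, n_draws, nrow(newdata))
  for (r in seq_len(nrow(newdata))) {
    mu <- d[, "a"] + d[, "b"] * newdata$x[r]
    if (fit$hierarchical) {
      gi <- match(newdata$group[r], fit$group_levels)
      if (is.na(gi)) {
        if (fit$model != "maxspeed")
          stop_input("unknown group '%s' for the %s model",
                     newdata$group[r], fit$model)
        # marginal prediction for an unseen group: offsets drawn from the
        # group-level distribution, widening the interval
        off <- with_seed(seed + r, {
          cbind(stats::rnorm(n_draws, 0, d[, "sd_ag"]),
                stats::rnorm(n_draws, 0, d[, "sd_bg"]))
        })
        mu <- mu + off[, 1] + off[, 2] * newdata$x[r]
      } else {
        mu <- mu + d[, sprintf("a_g[%d]", gi)] +
          d[, sprintf("b_g[%d]", gi)] * newdata$x[r]
      }
    }
    if (fit$has_ar) mu <- mu + d[, "c_ar"] * newdata$ar[r]
    out[, r] <- mu
  }
  out
}

# Translate user-facing covariates to the internal (x, group, ar) frame.
prediction_frame <- function(fit, covariates) {
  if (fit$model == "mr") {
    stopifnot(all(c("species_id", "mass", "rate_type") %in%
                    names(covariates)))
    data.frame(x = log10(covariates$mass),
               group = paste0(covariates$species_id, ":",
                              tolower(covariates$rate_type)),
               stringsAsFactors = FALSE)
  } else if (fit$model == "speed") {
    stopifnot(all(c("species_id", "length") %in% names(covariates)))
    data.frame(x = log10(covariates$length), group = covariates$species_id,
               stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("family", "body_shape", "length", "aspect_ratio") %in%
                    names(covariates)))
    data.frame(x = log10(covariates$length),
               group = paste(covariates$family, covariates$body_shape,
                             sep = ":"),
               ar = covariates$aspect_ratio, stringsAsFactors = FALSE)
  }
}

#' Posterior prediction of the expected response on the natural scale
#'
#' Returns draws of `10^mu`, the posterior of the *expected* response
#' (mean field speed, expected SMR/MMR/vmax) at the supplied covariates.
#' Residual observation noise is excluded by default because downstream
#' quantities use the expected value; set `include_residual = TRUE` for
#' posterior-predictive draws.
#'
#' @param fit a `"fishamr_fit"`.
#' @param covariates data frame; for the metabolic-rate model columns
#'   `species_id`, `mass`, `rate_type` (`"smr"`/`"mmr"`); for the speed
#'   model `species_id`, `length`; for the maximum-speed model `family`,
#'   `body_shape`, `length`, `aspect_ratio`. Unknown groups are an error
#'   except for the maximum-speed model, where they are predicted
#'   marginally.
#' @param median_flag if TRUE return the posterior median (vector, one per
#'   covariate row) instead of draws.
#' @param include_residual add residual noise per draw (posterior
#'   predictive).
#' @param seed seed used only for unseen-group offsets and residual noise.
#' @return A draws matrix (draws x rows) or a median vector, natural scale.
#' @export
predict_expected <- function(fit, covariates, median_flag = FALSE,
                             include_residual = FALSE, seed = 1) {
  nd <- prediction_frame(fit, covariates)
  mu <- mu_draws(fit, nd, seed = seed)
  if (include_residual) {
    sigma <- fit_sigma(fit)
    noise <- with_seed(seed, {
      if (fit$likelihood == "t") {
        matrix(stats::rt(length(mu), df = fit$draws[, "nu"]) * sigma,
               nrow(mu), ncol(mu))
      } else {
        matrix(stats::rnorm(length(mu), 0, sigma), nrow(mu), ncol(mu))
      }
    })
    mu <- mu + noise
  }
  out <- 10^mu
  if (median_flag) apply(out, 2, stats::median) else out
}

fit_sigma <- function(fit) {
  if ("sigma" %in% colnames(fit$draws)) fit$draws[, "sigma"]
  else rep(fit$settings$sigma_fixed, nrow(fit$draws))
}

#' Per-group summed coefficients
#'
#' Species-level (or group-level) intercepts and slopes are the sums of the
#' global parameter and the group offset, computed draw-wise so their
#' posterior covariance is preserved.
#'
#' @param fit a hierarchical `"fishamr_fit"`.
#' @return Data frame: `group`, posterior mean/median/95% CI of the summed
#'   intercept and slope.
#' @export
group_coefficients <- function(fit) {
  if (!fit$hierarchical) stop_input("fit has no group structure")
  d <- fit$draws
  rows <- lapply(seq_along(fit$group_levels), function(j) {
    a <- d[, "a"] + d[, sprintf("a_g[%d]", j)]
    b <- d[, "b"] + d[, sprintf("b_g[%d]", j)]
    data.frame(group = fit$group_levels[j],
               intercept_mean = mean(a),
               intercept_median = stats::median(a),
               intercept_q2.5 = stats::quantile(a, 0.025),
               intercept_q97.5 = stats::quantile(a, 0.975),
               slope_mean = mean(b),
               slope_median = stats::median(b),
               slope_q2.5 = stats::quantile(b, 0.025),
               slope_q97.5 = stats::quantile(b, 0.975),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Bayesian R-squared
#'
#' Per posterior draw, the variance of the fitted linear predictor over the
#' data divided by itself plus the residual variance implied by the draw's
#' sigma (scaled by nu/(nu-2) for Student-t likelihoods), following the
#' fitted-variance definition of Gelman et al. (2019).
#'
#' @param fit a `"fishamr_fit"`.
#' @return List: `draws` (one R2 per posterior draw, each in \[0, 1)),
#'   `median`, `ci` (equal-tailed 95%).
#' @export
bayes_r2 <- function(fit) {
  mu <- mu_draws(fit, fit$data)
  var_mu <- apply(mu, 1, stats::var)
  sigma <- fit_sigma(fit)
  res_var <- sigma^2
  if (fit$likelihood == "t") {
    nu <- fit$draws[, "nu"]
    res_var <- res_var * nu / (nu - 2)
  }
  r2 <- var_mu / (var_mu + res_var)
  list(draws = r2, median = stats::median(r2),
       ci = stats::quantile(r2, c(0.025, 0.975)))
}

#' Long-format posterior draws table
#'
#' @param fit a `"fishamr_fit"`.
#' @return Data frame `chain`, `draw`, `parameter`, `value`, suitable for
#'   CSV serialization.
#' @export
draws_long <- function(fit) {
  per_chain <- nrow(fit$draws) / fit$settings$chains
  data.frame(
    chain = rep(rep(seq_len(fit$settings$chains), each = per_chain),
                times = ncol(fit$draws)),
    draw = rep(rep(seq_len(per_chain), fit$settings$chains),
               times = ncol(fit$draws)),
    parameter = rep(colnames(fit$draws), each = nrow(fit$draws)),
    value = as.vector(fit$draws),
    stringsAsFactors = FALSE
  )
}
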