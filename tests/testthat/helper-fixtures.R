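# Shared fixtures: small configurations and fast sampler settings.

# Two-species table with simple round numbers, used where species identity
# does not matter.
two_species <- function(...) {
  species_truth(
    species_id = c("alpha", "beta"),
    a_smr = log10(c(0.004, 0.003)), b_smr = c(0.75, 0.70),
    a_mmr = log10(c(0.012, 0.010)), b_mmr = c(0.78, 0.77),
    a_v = c(0.7, 0.8), b_v = c(0.5, 0.4),
    family = c("FamA", "FamB"),
    body_shape = c("fusiform", "compressed"),
    ...
  )
}

# Reduced sampler settings for tests where only point recovery matters.
fast_settings <- function(...) {
  fit_settings(chains = 2, adapt = 400, burnin = 400, iter = 800,
               on_nonconvergence = "ignore", ...)
}

# Degenerate fit object whose posterior is a point mass: every draw equals
# the supplied coefficients. Mirrors the documented "fishamr_fit" layout.
degenerate_fit <- function(model, a, b, groups, a_g = NULL, b_g = NULL,
                           sigma = 0, nu = NULL, c_ar = NULL,
                           n_draws = 50) {
  a_g <- a_g %||% rep(0, length(groups))
  b_g <- b_g %||% rep(0, length(groups))
  cols <- c(a = a, b = b)
  for (j in seq_along(groups)) {
    cols[sprintf("a_g[%d]", j)] <- a_g[j]
    cols[sprintf("b_g[%d]", j)] <- b_g[j]
  }
  cols["sd_ag"] <- 0; cols["sd_bg"] <- 0
  cols["sigma"] <- sigma
  if (!is.null(nu)) cols["nu"] <- nu
  if (!is.null(c_ar)) cols["c_ar"] <- c_ar
  draws <- matrix(rep(cols, each = n_draws), n_draws,
                  dimnames = list(NULL, names(cols)))
  structure(
    list(model = model, likelihood = if (is.null(nu)) "normal" else "t",
         draws = draws, group_levels = groups, hierarchical = TRUE,
         has_ar = !is.null(c_ar), data = NULL,
         settings = fit_settings(chains = 1), seed = 1,
         summary = data.frame(), converged = TRUE),
    class = "fishamr_fit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
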