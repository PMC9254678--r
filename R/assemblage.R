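# Assemblage scale-up: per-individual rates from the size grid, summed to
# areal metabolic demand per transect and site.

# Nearest-cm lookup (half-up rounding, matching census convention).
round_half_up <- function(x) floor(x + 0.5)

#' Per-individual SMR and AMRfield for a census record
#'
#' Looks up the species x nearest-cm cell of the size-resolved estimate
#' grid and returns its median SMR and mean AMRfield.
#'
#' @param record one-row census data frame (`species_id`, `total_length`).
#' @param estimates a [species_size_estimates()] table.
#' @return Named numeric vector `c(smr, amr)`, g O2 d-1 per individual.
#' @export
individual_rates <- function(record, estimates) {
  len <- round_half_up(record$total_length)
  hit <- estimates$species_id == record$species_id &
    estimates$length == len
  if (!any(hit)) {
    # clamp to the species' grid edge if the census length falls outside
    sp_rows <- estimates[estimates$species_id == record$species_id, ]
    if (nrow(sp_rows) == 0)
      stop_input("species '%s' absent from the estimate grid (record: %s)",
                 record$species_id,
                 paste(record[1, intersect(c("site", "transect"),
                                           names(record))], collapse = "/"))
    stop_input(
      "length %s cm outside the %s estimate grid (%d-%d cm)",
      format(len), record$species_id, min(sp_rows$length),
      max(sp_rows$length))
  }
  row <- estimates[hit, ][1, ]
  c(smr = row$smr_med, amr = row$amr_mean)
}

#' Site-level areal metabolic demand
#'
#' Per transect, sums `count x rate` over records and divides by the
#' transect area; per site, reports the mean and SD across transect
#' densities (transect areas may differ, so densities are averaged rather
#' than counts pooled). The AMR/SMR ratio is computed from the site means.
#'
#' @param census census data frame (`site`, `transect`, `area`,
#'   `species_id`, `total_length`, `count`).
#' @param estimates a [species_size_estimates()] table.
#' @return Data frame, one row per site: `site`, `n_transects`,
#'   `smr_mean`, `smr_sd`, `amr_mean`, `amr_sd` (g O2 m-2 d-1), `ratio`.
#' @export
site_totals <- function(census, estimates) {
  stopifnot(all(c("site", "transect", "area", "species_id", "total_length",
                  "count") %in% names(census)))
  if (any(census$area <= 0)) stop_input("transect area must be positive")
  if (any(census$count < 1)) stop_input("counts must be at least 1")
  rates <- t(vapply(seq_len(nrow(census)), function(r) {
    individual_rates(census[r, ], estimates)
  }, c(smr = 0, amr = 0)))
  census$smr_tot <- census$count * rates[, "smr"]
  census$amr_tot <- census$count * rates[, "amr"]

  out <- lapply(split(census, census$site), function(cs) {
    by_tr <- split(cs, cs$transect)
    dens <- t(vapply(by_tr, function(tr) {
      c(smr = sum(tr$smr_tot) / tr$area[1],
        amr = sum(tr$amr_tot) / tr$area[1])
    }, c(smr = 0, amr = 0)))
    data.frame(
      site = cs$site[1], n_transects = nrow(dens),
      smr_mean = mean(dens[, "smr"]),
      smr_sd = if (nrow(dens) > 1) stats::sd(dens[, "smr"]) else 0,
      amr_mean = mean(dens[, "amr"]),
      amr_sd = if (nrow(dens) > 1) stats::sd(dens[, "amr"]) else 0,
      ratio = mean(dens[, "amr"]) / mean(dens[, "smr"]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-site species relative abundances
#'
#' Counts summed across transects within a site, normalized to 1.
#'
#' @param census census data frame (`site`, `species_id`, `count`).
#' @return Data frame `site`, `species_id`, `share` (shares sum to 1 per
#'   site), in long format for stacked-bar plotting.
#' @export
relative_abundance <- function(census) {
  stopifnot(all(c("site", "species_id", "count") %in% names(census)))
  agg <- stats::aggregate(count ~ site + species_id, data = census, sum)
  out <- do.call(rbind, lapply(split(agg, agg$site), function(s) {
    data.frame(site = s$site, species_id = s$species_id,
               share = s$count / sum(s$count), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
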