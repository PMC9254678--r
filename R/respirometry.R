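# Respirometry extraction: per-cycle oxygen-decline slopes -> SMR and MMR.

#' Whole-animal oxygen uptake rate from one closed cycle
#'
#' Converts the oxygen-decline slope of a sealed respirometry cycle into a
#' whole-animal uptake rate, using the effective water volume (chamber
#' minus fish, assuming a tissue density of 1 g ml-1):
#' `rate = slope * (volume - mass/1000) * 1440 / 1000` g O2 per day.
#'
#' @param o2_slope decline slope, mg O2 L-1 min-1 (magnitude).
#' @param chamber_volume chamber volume including tubing and pumps, L.
#' @param mass fish mass, g.
#' @param individual_id optional label used in error messages.
#' @return Oxygen uptake rate, g O2 d-1 (whole-animal, not mass-specific).
#' @export
mo2_from_cycle <- function(o2_slope, chamber_volume, mass,
                           individual_id = NULL) {
  if (any(o2_slope < 0)) stop_input("o2_slope must be non-negative")
  eff <- chamber_volume - mass / 1000
  if (any(eff <= 0)) {
    stop_input("effective chamber volume is not positive%s",
               if (is.null(individual_id)) "" else
                 paste0(" for individual ", individual_id))
  }
  o2_slope * eff * 1440 / 1000
}

# Outlier rule: retain rates within median +/- k * scaled MAD of the pool.
# Returns a logical keep-mask. A zero MAD (flat plateau) keeps exact ties
# with the median only, which is the intended behaviour on noiseless data.
mad_keep <- function(rates, k = 3) {
  med <- stats::median(rates)
  s <- stats::mad(rates)  # scaled by 1.4826
  abs(rates - med) <= k * s
}

#' Standard metabolic rate from a cycle series
#'
#' The standard rate is the mean of the lowest `lowest_fraction` of cycle
#' rates after outlier removal. The first cycle (the post-chase maximum
#' measurement) is excluded from the pool by default. Outliers are rates
#' outside median +/- `mad_k` scaled-MAD of the pool. The pool size for the
#' lowest fraction is `ceiling(lowest_fraction * n)` so small trials keep
#' at least one value.
#'
#' @param rates per-cycle uptake rates, g O2 d-1, in time order.
#' @param lowest_fraction fraction of lowest rates averaged (default 0.10).
#' @param exclude_first drop the first cycle from the pool (default TRUE).
#' @param mad_k multiplier of the scaled MAD defining the outlier band.
#' @return SMR, g O2 d-1.
#' @export
extract_smr <- function(rates, lowest_fraction = 0.10,
                        exclude_first = TRUE, mad_k = 3) {
  pool <- if (exclude_first) rates[-1] else rates
  if (length(pool) < 10)
    stop_input("need at least 10 cycles in the SMR pool, got %d",
               length(pool))
  keep <- mad_keep(pool, mad_k)
  if (!any(keep))
    stop_input("outlier removal rejected every cycle")
  pool <- pool[keep]
  n_low <- ceiling(lowest_fraction * length(pool))
  mean(sort(pool)[seq_len(n_low)])
}

#' Maximum metabolic rate from a cycle series
#'
#' The maximum rate is the rate of the first closed cycle, measured
#' immediately after exhaustive exercise.
#'
#' @param rates per-cycle uptake rates, g O2 d-1, in time order.
#' @return MMR, g O2 d-1.
#' @export
extract_mmr <- function(rates) {
  if (length(rates) < 1) stop_input("empty trial: no cycles")
  rates[1]
}

#' Summarize one respirometry trial into an SMR/MMR observation
#'
#' Converts each cycle's decline slope to a whole-animal rate, then extracts
#' SMR and MMR. If noise drives the extracted SMR above the MMR the trial is
#' flagged invalid (`NULL` return with a message) rather than silently kept.
#'
#' @param trial data frame with one row per cycle, columns
#'   `individual_id`, `species_id`, `mass`, `chamber_volume`, `cycle`,
#'   `o2_slope`; rows in cycle order.
#' @param ... passed to [extract_smr()].
#' @return A one-row data frame (`individual_id`, `species_id`, `mass`,
#'   `smr`, `mmr`), or `NULL` if the trial violates `smr <= mmr`.
#' @export
summarize_trial <- function(trial, ...) {
  stopifnot(all(c("individual_id", "mass", "chamber_volume",
                  "o2_slope") %in% names(trial)))
  trial <- trial[order(trial$cycle), ]
  id <- trial$individual_id[1]
  rates <- mo2_from_cycle(trial$o2_slope, trial$chamber_volume[1],
                          trial$mass[1], individual_id = id)
  smr <- extract_smr(rates, ...)
  mmr <- extract_mmr(rates)
  if (smr > mmr) {
    message("trial ", id, " excluded: extracted SMR exceeds MMR")
    return(NULL)
  }
  data.frame(individual_id = id,
             species_id = trial$species_id[1],
             mass = trial$mass[1], smr = smr, mmr = mmr,
             stringsAsFactors = FALSE)
}

#' Summarize all trials in a cycle table
#'
#' @param trials data frame of cycles for many individuals (the format
#'   written by [generate_respirometry_trials()]).
#' @param ... passed to [extract_smr()].
#' @return Data frame of SMR/MMR observations, one row per retained
#'   individual; excluded individual ids in attribute `"excluded"`.
#' @export
summarize_trials <- function(trials, ...) {
  by_id <- split(trials, trials$individual_id)
  res <- lapply(by_id, summarize_trial, ...)
  excluded <- names(res)[vapply(res, is.null, logical(1))]
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}
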