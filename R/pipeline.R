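# End-to-end orchestration: configuration I/O, input validation, and the
# reproducible pipeline run (respirometry -> model fits -> size-grid
# estimates -> assemblage summary) with a JSON manifest.

#' Write a generator configuration to YAML
#'
#' @param config a [generator_config()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "fishamr_config"))
  lst <- unclass(config)
  lst$species <- lapply(seq_len(nrow(config$species)), function(i)
    as.list(config$species[i, ]))
  yaml::write_yaml(lst, path, precision = 15L)
  invisible(path)
}

#' Read a generator configuration from YAML
#'
#' @param path a YAML file written by [write_config()].
#' @return A validated [generator_config()].
#' @export
read_config <- function(path) {
  lst <- yaml::read_yaml(path)
  sp <- do.call(rbind, lapply(lst$species, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  args <- lst[setdiff(names(lst), "species")]
  args$species <- do.call(species_truth, as.list(sp))
  do.call(generator_config, args)
}

# Expected columns per input table.
TABLE_SCHEMAS <- list(
  respirometry = c("individual_id", "species_id", "mass", "chamber_volume",
                   "cycle", "o2_slope", "duration"),
  speeds = c("individual_id", "species_id", "length", "v_field"),
  maxspeeds = c("family", "body_shape", "length", "aspect_ratio", "vmax"),
  census = c("site", "transect", "area", "species_id", "total_length",
             "count"),
  calibration = c("true_length", "measured_length", "distance"),
  mr = c("individual_id", "species_id", "mass", "smr", "mmr")
)

violation <- function(table, row, issue) {
  data.frame(table = table, row = row, issue = issue,
             stringsAsFactors = FALSE)
}

check_rows <- function(tab, name, cond, issue) {
  bad <- which(!cond)
  if (length(bad)) violation(name, bad, issue) else NULL
}

#' Validate pipeline input tables
#'
#' Checks each supplied CSV against its documented schema and the type
#' invariants (positive masses and areas, chamber volume exceeding fish
#' volume, SMR not above MMR, counts at least 1, non-negative camera
#' distances). Reports violations without mutating the data.
#'
#' @param paths named list or character vector of CSV paths; recognized
#'   names: `respirometry`, `speeds`, `maxspeeds`, `census`,
#'   `calibration`, `mr`.
#' @return Data frame with columns `table`, `row`, `issue` (zero rows when
#'   everything is clean).
#' @export
validate_inputs <- function(paths) {
  unknown <- setdiff(names(paths), names(TABLE_SCHEMAS))
  if (length(unknown))
    stop_input("unknown table name(s): %s", paste(unknown, collapse = ", "))
  out <- list()
  for (name in names(paths)) {
    path <- paths[[name]]
    if (!file.exists(path)) stop_input("cannot read file: %s", path)
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    missing <- setdiff(TABLE_SCHEMAS[[name]], names(tab))
    if (length(missing)) {
      out[[length(out) + 1L]] <- violation(
        name, NA_integer_,
        paste("missing columns:", paste(missing, collapse = ", ")))
      next
    }
    out[[length(out) + 1L]] <- switch(
      name,
      respirometry = rbind(
        check_rows(tab, name, tab$mass > 0, "mass must be positive"),
        check_rows(tab, name, tab$chamber_volume > tab$mass / 1000,
                   "chamber volume must exceed fish volume"),
        check_rows(tab, name, tab$o2_slope >= 0,
                   "o2_slope must be non-negative")),
      speeds = rbind(
        check_rows(tab, name, tab$length > 0, "length must be positive"),
        check_rows(tab, name, tab$v_field >= 0,
                   "v_field must be non-negative")),
      maxspeeds = rbind(
        check_rows(tab, name, tab$length > 0, "length must be positive"),
        check_rows(tab, name, tab$vmax > 0, "vmax must be positive")),
      census = rbind(
        check_rows(tab, name, tab$area > 0, "area must be positive"),
        check_rows(tab, name, tab$count >= 1, "count must be at least 1"),
        check_rows(tab, name, tab$total_length >= 1,
                   "total_length must be at least 1 cm")),
      calibration = rbind(
        check_rows(tab, name, tab$distance >= 0,
                   "distance must be non-negative"),
        check_rows(tab, name, tab$true_length > 0,
                   "true_length must be positive")),
      mr = rbind(
        check_rows(tab, name, tab$smr > 0, "smr must be positive"),
        check_rows(tab, name, tab$smr <= tab$mmr,
                   "smr must not exceed mmr"))
    )
  }
  out <- do.call(rbind, out)
  if (is.null(out)) out <- violation(character(0), integer(0), character(0))
  rownames(out) <- NULL
  out
}

#' Write the five synthetic input tables to CSV
#'
#' @param config a [generator_config()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
simulate_tables <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- list(
    respirometry = generate_respirometry_trials(config),
    speeds = generate_speed_observations(config),
    maxspeeds = generate_maxspeed_records(config),
    census = generate_census(config),
    calibration = generate_calibration_set(config)
  )
  paths <- vapply(names(tables), function(n) {
    p <- file.path(dir, paste0(n, ".csv"))
    utils::write.csv(tables[[n]], p, row.names = FALSE)
    p
  }, character(1))
  write_config(config, file.path(dir, "config.yml"))
  invisible(paths)
}

#' Run the full estimation pipeline
#'
#' Generates (or reads) the input tables, extracts SMR/MMR from the
#' respirometry cycles, fits the three hierarchical regressions, builds the
#' per-species size grid of AMRfield/FAS/FSA, scales the census to
#' site-level areal demand, and writes every output table plus a JSON
#' manifest (seed, package version, input hashes, convergence
#' diagnostics). Identical config and seed give byte-identical outputs.
#'
#' @param config a [generator_config()]; its species table doubles as the
#'   trait config for the size grid.
#' @param output_dir directory for all outputs (created if needed).
#' @param inputs optional named list of CSV paths (`respirometry`,
#'   `speeds`, `maxspeeds`, `census`) substituting any generated table.
#' @param settings a [fit_settings()] shared by the three model fits.
#' @param n_iter posterior iterations for the size-grid propagation.
#' @return The manifest, invisibly (a list).
#' @export
run_pipeline <- function(config, output_dir,
                         inputs = NULL,
                         settings = fit_settings(),
                         n_iter = 1000) {
  stopifnot(inherits(config, "fishamr_config"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed

  input_dir <- file.path(output_dir, "inputs")
  paths <- as.list(simulate_tables(config, input_dir))
  if (!is.null(inputs)) paths[names(inputs)] <- inputs

  issues <- validate_inputs(paths[c("respirometry", "speeds", "maxspeeds",
                                    "census")])
  if (nrow(issues) > 0) {
    stop_input("input validation failed (%d violation(s)); first: %s row %s: %s",
               nrow(issues), issues$table[1], issues$row[1],
               issues$issue[1])
  }

  read_in <- function(n) utils::read.csv(paths[[n]],
                                         stringsAsFactors = FALSE)
  trials <- read_in("respirometry")
  speeds <- read_in("speeds")
  maxspeeds <- read_in("maxspeeds")
  census <- read_in("census")

  mr_obs <- summarize_trials(trials)
  utils::write.csv(mr_obs, file.path(output_dir, "mr_observations.csv"),
                   row.names = FALSE)

  mr_fit <- fit_mr_model(mr_obs, settings, seed = seed)
  speed_fit <- fit_speed_model(speeds, settings, seed = seed + 1)
  maxspeed_fit <- fit_maxspeed_model(maxspeeds, settings, seed = seed + 2)
  for (f in list(mr_fit, speed_fit, maxspeed_fit)) {
    utils::write.csv(f$summary,
                     file.path(output_dir,
                               paste0("fit_", f$model, "_summary.csv")),
                     row.names = FALSE)
  }

  estimates <- species_size_estimates(mr_fit, speed_fit, maxspeed_fit,
                                      traits = config$species,
                                      n_iter = n_iter, seed = seed + 3)
  utils::write.csv(estimates, file.path(output_dir, "estimates.csv"),
                   row.names = FALSE)

  sites <- site_totals(census, estimates)
  utils::write.csv(sites, file.path(output_dir, "site_totals.csv"),
                   row.names = FALSE)
  shares <- relative_abundance(census)
  utils::write.csv(shares,
                   file.path(output_dir, "relative_abundance.csv"),
                   row.names = FALSE)

  manifest <- list(
    seed = seed,
    package_version = as.character(utils::packageVersion("fishamr")),
    inputs = as.list(stats::setNames(
      tools::md5sum(unlist(paths[c("respirometry", "speeds", "maxspeeds",
                                   "census")])),
      c("respirometry", "speeds", "maxspeeds", "census"))),
    outputs = as.list(stats::setNames(
      tools::md5sum(file.path(
        output_dir, c("mr_observations.csv", "estimates.csv",
                      "site_totals.csv"))),
      c("mr_observations", "estimates", "site_totals"))),
    n_trials_excluded = length(attr(mr_obs, "excluded")),
    convergence = list(
      mr = list(converged = mr_fit$converged,
                max_rhat = max(mr_fit$summary$rhat, na.rm = TRUE)),
      speed = list(converged = speed_fit$converged,
                   max_rhat = max(speed_fit$summary$rhat, na.rm = TRUE)),
      maxspeed = list(converged = maxspeed_fit$converged,
                      max_rhat = max(maxspeed_fit$summary$rhat,
                                     na.rm = TRUE))),
    n_extrapolated = sum(estimates$n_extrapolated)
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
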