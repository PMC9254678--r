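# Stereo-video processing: calibration error model, distance-corrected
# lengths, and segment swimming speeds from 3D tracks.

#' Fit the length-measurement error model for a stereo-video system
#'
#' Stereo-video length measurements drift with distance from the nearest
#' camera. Given calibration pairs of true and measured lengths, fits the
#' least-squares regression of (measured - true) on camera distance.
#'
#' @param calibration data frame with columns `true_length`,
#'   `measured_length` (cm) and `distance` (m).
#' @return A list of class `"fishamr_error_model"`: `intercept` (cm),
#'   `slope` (cm per m), `sigma` (residual SD, cm), `n`.
#' @export
fit_error_model <- function(calibration) {
  stopifnot(all(c("true_length", "measured_length", "distance")
                %in% names(calibration)))
  if (nrow(calibration) < 3)
    stop_input("need at least 3 calibration measurements")
  if (length(unique(calibration$distance)) < 2)
    stop_input("calibration distances are degenerate (single distance)")
  err <- calibration$measured_length - calibration$true_length
  fit <- stats::lm(err ~ distance, data = calibration)
  rss <- sum(stats::residuals(fit)^2)
  structure(
    list(intercept = unname(stats::coef(fit)[1]),
         slope = unname(stats::coef(fit)[2]),
         sigma = sqrt(rss / (nrow(calibration) - 2)),
         n = nrow(calibration)),
    class = "fishamr_error_model"
  )
}

#' Apply the distance-dependent correction to a measurement
#'
#' Subtracts the modelled error at the measurement's camera distance:
#' `corrected = measured - (intercept + slope * distance)`. Applied
#' identically to fish lengths and to displacement distances.
#'
#' @param measurement measured value, cm.
#' @param distance distance from the nearest camera, m.
#' @param error_model a [fit_error_model()] result (or a list with
#'   `intercept` and `slope`).
#' @return Corrected measurement, cm. Negative corrected values raise an
#'   input error (never a silent clamp).
#' @export
apply_correction <- function(measurement, distance, error_model) {
  corrected <- measurement -
    (error_model$intercept + error_model$slope * distance)
  if (any(corrected < 0))
    stop_input("correction produced a negative length/distance")
  corrected
}

#' Segment swimming speeds from a 3D track
#'
#' For each consecutive pair of track points, the straight-line (chord)
#' displacement is corrected for the stereo-video distance error (using the
#' segment's mean camera distance) and divided by the elapsed time.
#' Segments whose duration falls outside the accepted window are dropped
#' with a message.
#'
#' @param points data frame for one individual with columns `time` (s),
#'   `x`, `y`, `z` (cm) and `distance_to_camera` (m), in time order.
#' @param error_model a [fit_error_model()] result; use
#'   `list(intercept = 0, slope = 0)` for an ideal system.
#' @param window accepted segment duration range, s (default 3-5).
#' @return Numeric vector of segment speeds, cm s-1.
#' @export
track_speed <- function(points, error_model = list(intercept = 0, slope = 0),
                        window = c(3, 5)) {
  stopifnot(all(c("time", "x", "y", "z") %in% names(points)))
  if (nrow(points) < 2) stop_input("need at least 2 track points")
  dt <- diff(points$time)
  if (any(dt <= 0)) stop_input("track timestamps must be strictly increasing")
  disp <- sqrt(diff(points$x)^2 + diff(points$y)^2 + diff(points$z)^2)
  cam <- points$distance_to_camera %||% rep(0, nrow(points))
  mean_cam <- (cam[-1] + cam[-length(cam)]) / 2
  in_window <- dt >= window[1] & dt <= window[2]
  if (any(!in_window))
    message(sum(!in_window), " segment(s) dropped: duration outside [",
            window[1], ", ", window[2], "] s")
  if (!any(in_window)) stop_input("no track segment within the time window")
  corrected <- apply_correction(disp[in_window], mean_cam[in_window],
                                error_model)
  corrected / dt[in_window]
}

#' Summarize repeated measurements of one filmed individual
#'
#' Final length and field swimming speed are the arithmetic means of the
#' three repeated length measurements and of the 3-5 consecutive segment
#' speeds.
#'
#' @param lengths exactly 3 corrected length replicates, cm.
#' @param segment_speeds 3 to 5 segment speeds, cm s-1.
#' @param individual_id,species_id,time_period labels carried through.
#' @return One-row data frame: `individual_id`, `species_id`, `length`,
#'   `v_field`, `n_segments`, `time_period`.
#' @export
summarize_individual <- function(lengths, segment_speeds,
                                 individual_id = "ind", species_id = NA,
                                 time_period = NA) {
  if (length(lengths) != 3)
    stop_input("expected exactly 3 length replicates, got %d",
               length(lengths))
  if (length(segment_speeds) < 3 || length(segment_speeds) > 5)
    stop_input("expected 3 to 5 segment speeds, got %d",
               length(segment_speeds))
  if (any(lengths <= 0)) stop_input("lengths must be positive")
  if (any(segment_speeds < 0)) stop_input("speeds must be non-negative")
  data.frame(individual_id = individual_id, species_id = species_id,
             length = mean(lengths), v_field = mean(segment_speeds),
             n_segments = length(segment_speeds),
             time_period = time_period, stringsAsFactors = FALSE)
}
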