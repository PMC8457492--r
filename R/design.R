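#' Stimulus design configuration for the distance-duration plane
#'
#' The reference sound travels `reference_distance` degrees of arc in
#' `reference_duration` milliseconds (default 21.17 deg / 800 ms, a speed of
#' 26.46 deg/s). Target sounds differ from the reference by Weber fractions of
#' duration and travelled distance, laid out along `n_orientations` straight
#' lines through the origin of the (W_duration, W_distance) plane, with
#' `n_levels` magnitudes per orientation (the middle level is the reference
#' itself) repeated `n_reps` times each.
#'
#' @param reference_distance Travelled arc of the reference sound, degrees.
#' @param reference_duration Duration of the reference sound, milliseconds.
#' @param n_orientations Number of equally spaced plane orientations.
#' @param n_levels Levels per orientation; must be odd so the middle level is
#'   the null stimulus.
#' @param n_reps Repetitions of each level.
#' @param ratio_extreme Extreme speed-ratio factor of the level ladder; the
#'   target speeds on the pure axes span
#'   `[reference/ratio_extreme, reference * ratio_extreme]`.
#' @param n_blocks Number of experimental blocks trials are dealt into.
#' @param speaker_span Span of the speaker array, degrees (trial metadata).
#' @param n_speakers Number of speakers in the array (trial metadata).
#' @param seed Integer seed controlling trial order randomisation.
#' @return An object of class `design_config`.
#' @seealso [build_design()]
#' @export
design_config <- function(reference_distance = 21.17,
                          reference_duration = 800,
                          n_orientations = 8,
                          n_levels = 9,
                          n_reps = 6,
                          ratio_extreme = 4,
                          n_blocks = 6,
                          speaker_span = 50,
                          n_speakers = 24,
                          seed = 1L) {
  if (!is.numeric(reference_distance) || reference_distance <= 0) {
    stop_audspeed("reference_distance must be > 0", "audspeed_domain_error")
  }
  if (!is.numeric(reference_duration) || reference_duration <= 0) {
    stop_audspeed("reference_duration must be > 0", "audspeed_domain_error")
  }
  if (n_levels < 3 || n_levels %% 2 != 1) {
    stop_audspeed("n_levels must be odd (the middle level is the null stimulus)",
                  "audspeed_domain_error")
  }
  if (ratio_extreme <= 1) {
    stop_audspeed("ratio_extreme must be > 1", "audspeed_domain_error")
  }
  if (n_orientations < 4) {
    stop_audspeed("n_orientations must be >= 4", "audspeed_domain_error")
  }
  if (n_reps < 1) {
    stop_audspeed("n_reps must be >= 1", "audspeed_domain_error")
  }
  if (n_blocks < 1) {
    stop_audspeed("n_blocks must be >= 1", "audspeed_domain_error")
  }
  structure(list(reference_distance = reference_distance,
                 reference_duration = reference_duration,
                 n_orientations = as.integer(n_orientations),
                 n_levels = as.integer(n_levels),
                 n_reps = as.integer(n_reps),
                 ratio_extreme = ratio_extreme,
                 n_blocks = as.integer(n_blocks),
                 speaker_span = speaker_span,
                 n_speakers = as.integer(n_speakers),
                 seed = as.integer(seed)),
            class = "design_config")
}

#' @export
print.design_config <- function(x, ...) {
  cat("2AFC speed-discrimination design\n")
  cat(sprintf("  reference: %.2f deg in %.0f ms (%.4f deg/s)\n",
              x$reference_distance, x$reference_duration, reference_speed(x)))
  cat(sprintf("  %d orientations x %d levels x %d reps = %d trials, %d blocks\n",
              x$n_orientations, x$n_levels, x$n_reps,
              x$n_orientations * x$n_levels * x$n_reps, x$n_blocks))
  cat(sprintf("  speed-ratio ladder on [1/%g, %g], seed %d\n",
              x$ratio_extreme, x$ratio_extreme, x$seed))
  invisible(x)
}

#' Reference speed of a design, degrees per second
#'
#' @param config A [design_config()].
#' @return Numeric scalar, degrees/second (full precision, not rounded).
#' @export
reference_speed <- function(config) {
  config$reference_distance / (config$reference_duration / 1000)
}

#' Equally spaced plane orientations
#'
#' Orientation angles in degrees, measured from the positive distance
#' (vertical) axis toward the positive duration (horizontal) axis, covering
#' `[0, 180)` in equal steps.
#'
#' @param n_orientations Number of orientations.
#' @return Numeric vector of angles in degrees.
#' @export
orientation_angles <- function(n_orientations = 8) {
  seq(0, 180, length.out = n_orientations + 1)[seq_len(n_orientations)]
}

# Unit direction of an orientation in (w_duration, w_distance) coordinates.
orientation_direction <- function(angle) {
  a <- angle * pi / 180
  c(w_duration = sin(a), w_distance = cos(a))
}

#' Cue offsets of a point on a plane orientation
#'
#' Maps a signed magnitude along an orientation line to Weber-fraction cue
#' offsets `(w_duration, w_distance) = magnitude * (sin angle, cos angle)`.
#' Magnitude 0 is the reference point.
#'
#' @param orientation_angle Angle in degrees from the distance (vertical) axis.
#' @param magnitude Signed displacement along the orientation (Weber units).
#' @return A list with components `w_duration` and `w_distance`.
#' @export
cue_offsets <- function(orientation_angle, magnitude) {
  d <- orientation_direction(orientation_angle)
  w_t <- magnitude * d[["w_duration"]]
  w_d <- magnitude * d[["w_distance"]]
  if (any(w_t <= -1)) {
    stop_audspeed("magnitude drives w_duration <= -1 (non-positive target duration)",
                  "audspeed_domain_error")
  }
  if (any(w_d <= -1)) {
    stop_audspeed("magnitude drives w_distance <= -1 (non-positive target distance)",
                  "audspeed_domain_error")
  }
  list(w_duration = unname(w_t), w_distance = unname(w_d))
}

#' Target speed implied by cue offsets
#'
#' @param w_duration,w_distance Weber fractions of duration and distance
#'   (each > -1). Vectorised.
#' @param config A [design_config()] supplying the reference stimulus.
#' @return Target speed in degrees/second:
#'   `reference_distance * (1 + w_distance) / (reference_duration * (1 + w_duration))`.
#' @export
target_speed <- function(w_duration, w_distance, config = design_config()) {
  if (any(w_duration <= -1) || any(w_distance <= -1)) {
    stop_audspeed("cue offsets must each be > -1", "audspeed_domain_error")
  }
  config$reference_distance * (1 + w_distance) /
    ((config$reference_duration / 1000) * (1 + w_duration))
}

#' Experimental condition label of an orientation
#'
#' The four named conditions are the cardinal and diagonal lines of the plane:
#' 0 deg manipulates distance only (`spatial`), 90 deg duration only
#' (`temporal`), 45 deg both in direct proportion so speed is constant
#' (`coherent`), 135 deg both in inverse proportion (`opposite`). Every other
#' orientation is `unnamed`.
#'
#' @param orientation_angle Angle in degrees, in `[0, 180)`. Vectorised.
#' @return Character vector of condition labels.
#' @export
label_condition <- function(orientation_angle) {
  if (any(orientation_angle < 0 | orientation_angle >= 180)) {
    stop_audspeed("orientation angle must lie in [0, 180)", "audspeed_domain_error")
  }
  tol <- 1e-9
  out <- rep("unnamed", length(orientation_angle))
  out[abs(orientation_angle - 0) < tol] <- "spatial"
  out[abs(orientation_angle - 90) < tol] <- "temporal"
  out[abs(orientation_angle - 45) < tol] <- "coherent"
  out[abs(orientation_angle - 135) < tol] <- "opposite"
  out
}

#' Level magnitudes along one orientation
#'
#' Levels follow a geometric ladder of speed-ratio factors
#' `f_k = ratio_extreme^(k/h)`, `k = -h..h`, `h = (n_levels - 1)/2`. Where the
#' whole ladder is attainable on the orientation line (the pure axes and every
#' orientation with a negative direction component) the magnitude solves the
#' speed-ratio equation exactly, so the target speed at level `k` is
#' `reference * f_k`. On orientations where speed is invariant or nearly so
#' along the line (the coherent diagonal and its first-quadrant neighbours,
#' where some factors are geometrically unattainable) the same ladder is
#' applied to the dominant cue component instead (`1 + w = f_k`).
#'
#' @param orientation_angle Angle in degrees.
#' @param config A [design_config()].
#' @return Numeric vector of `n_levels` signed magnitudes (middle level 0).
#' @export
level_magnitudes <- function(orientation_angle, config = design_config()) {
  h <- (config$n_levels - 1L) / 2L
  f <- config$ratio_extreme^(seq(-h, h) / h)
  d <- orientation_direction(orientation_angle)
  s <- d[["w_duration"]]
  co <- d[["w_distance"]]
  # Exact solve of (1 + m*co)/(1 + m*s) = f for each factor.
  denom <- co - f * s
  m_exact <- ifelse(abs(denom) < 1e-12, NA_real_, (f - 1) / denom)
  ok <- all(is.finite(m_exact)) &&
    all(m_exact * s > -1 + 1e-9) &&
    all(m_exact * co > -1 + 1e-9) &&
    (all(diff(m_exact) > 0) || all(diff(m_exact) < 0))
  if (ok) {
    return(m_exact)
  }
  # Dominant-cue factor ladder fallback.
  dom <- if (abs(co) >= abs(s)) co else s
  m <- (f - 1) / dom
  if (any(m * s <= -1) || any(m * co <= -1)) {
    stop_audspeed(sprintf("infeasible level grid on orientation %g deg",
                          orientation_angle),
                  "audspeed_domain_error")
  }
  m
}

#' Build the full randomized trial schedule
#'
#' Crosses every orientation with its level ladder and `n_reps` repetitions,
#' assigns a random motion direction and start offset to each trial, shuffles
#' the rows with the configuration seed, and deals them round-robin into
#' blocks. The same seed always yields the identical schedule.
#'
#' @param config A [design_config()].
#' @param subject_id Identifier stamped on every row.
#' @return A data frame of class `trial_schedule` with columns `subject_id`,
#'   `block`, `orientation_deg`, `condition`, `level_index`, `magnitude`,
#'   `w_duration`, `w_distance`, `target_speed_deg_s`, `motion_direction`,
#'   `start_offset`, `rep`.
#' @examples
#' design <- build_design(design_config(seed = 7))
#' nrow(design)  # 432
#' round(range(design$target_speed_deg_s), 2)
#' @export
build_design <- function(config = design_config(), subject_id = "S1") {
  angles <- orientation_angles(config$n_orientations)
  rows <- lapply(angles, function(a) {
    m <- level_magnitudes(a, config)
    d <- orientation_direction(a)
    data.frame(orientation_deg = a,
               condition = label_condition(a),
               level_index = seq_along(m) - 1L,
               magnitude = m,
               w_duration = m * d[["w_duration"]],
               w_distance = m * d[["w_distance"]])
  })
  grid <- do.call(rbind, rows)
  grid <- grid[rep(seq_len(nrow(grid)), each = config$n_reps), , drop = FALSE]
  grid$rep <- rep(seq_len(config$n_reps), times = config$n_orientations * config$n_levels)
  grid$target_speed_deg_s <- target_speed(grid$w_duration, grid$w_distance, config)
  n <- nrow(grid)
  grid <- with_seed(config$seed, {
    grid$motion_direction <- sample(c("leftward", "rightward"), n, replace = TRUE)
    grid$start_offset <- sample(0:2, n, replace = TRUE)
    grid[sample.int(n), , drop = FALSE]
  })
  grid$block <- rep_len(seq_len(config$n_blocks), n)
  grid$subject_id <- subject_id
  grid <- grid[, c("subject_id", "block", "orientation_deg", "condition",
                   "level_index", "magnitude", "w_duration", "w_distance",
                   "target_speed_deg_s", "motion_direction", "start_offset",
                   "rep")]
  rownames(grid) <- NULL
  class(grid) <- c("trial_schedule", "data.frame")
  attr(grid, "config") <- config
  grid
}

#' Read or write a trial schedule / response table as CSV
#'
#' Plain UTF-8 CSV with a header, `.` decimal separator, angles in decimal
#' degrees and speeds in degrees/second.
#'
#' @param x A trial schedule or response data frame.
#' @param path File path.
#' @return `write_trials()` returns `path` invisibly; `read_trials()` a data
#'   frame.
#' @export
write_trials <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
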