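#' Signed radial coordinate in the Weber plane
#'
#' The magnitude is the radial distance `sqrt(w_duration^2 + w_distance^2)`
#' from the reference point. Under the default `"speed"` sign rule the sign
#' is that of the veridical speed difference, `sign(w_distance - w_duration)`
#' (positive r means the target is physically faster); on the constant-speed
#' coherent line, where that difference vanishes, the sign falls back to the
#' plane y-coordinate, `sign(w_distance)`. The `"y_rule"` option applies the
#' y-coordinate rule everywhere (negating r only where `w_distance < 0`),
#' which leaves the temporal condition — lying along `w_distance = 0` —
#' degenerate; it is retained as an explicit alternative convention.
#'
#' @param w_duration,w_distance Weber coordinates. Vectorised.
#' @param sign_rule `"speed"` (default) or `"y_rule"`.
#' @param tol Tolerance for treating the speed difference as zero.
#' @return Signed radial values, 0 exactly at the reference point.
#' @export
radial_coordinate <- function(w_duration, w_distance,
                              sign_rule = c("speed", "y_rule"), tol = 1e-9) {
  sign_rule <- match.arg(sign_rule)
  mag <- sqrt(w_duration^2 + w_distance^2)
  s <- if (sign_rule == "speed") {
    diffv <- w_distance - w_duration
    ifelse(abs(diffv) > tol, sign(diffv),
           ifelse(w_distance < -tol, -1, 1))
  } else {
    ifelse(w_distance < -tol, -1, 1)
  }
  ifelse(mag == 0, 0, s * mag)
}

#' Fit the per-condition psychometric function on the radial axis
#'
#' Pools a condition's trials, computes the signed radial coordinate per
#' trial, aggregates "faster" proportions and fits a cumulative Gaussian.
#' Observers that follow the "shorter = faster" temporal assumption produce
#' decreasing ("inverted") curves — hence negative signed JNDs — in the
#' conditions where the assumption misleads.
#'
#' @param responses A response table (one subject, or pre-filtered).
#' @param condition One of `"spatial"`, `"temporal"`, `"coherent"`,
#'   `"opposite"`.
#' @param sign_rule Passed to [radial_coordinate()].
#' @param ... Passed to [fit_psychometric()].
#' @return A `psych_fit` on the signed-r axis.
#' @export
fit_condition <- function(responses, condition,
                          sign_rule = c("speed", "y_rule"), ...) {
  sign_rule <- match.arg(sign_rule)
  if (!condition %in% c("spatial", "temporal", "coherent", "opposite")) {
    stop_audspeed("condition must be one of the four named plane orientations",
                  "audspeed_domain_error")
  }
  series <- aggregate_proportions(responses, axis = "r", condition = condition,
                                  sign_rule = sign_rule)
  fit_psychometric(series, ..., strict = FALSE)
}

#' Per-condition signed JNDs for a cohort
#'
#' Batch runner over subjects and the four named conditions, producing the
#' JND record table that feeds the group statistics.
#'
#' @param responses A response table with `subject_id` (and optionally
#'   `group`) columns.
#' @param sign_rule Passed to [radial_coordinate()].
#' @param ... Passed to [fit_psychometric()].
#' @return A data frame with one row per subject x condition: `subject_id`,
#'   `group`, `condition`, `jnd_signed`, `r_squared`, `gof_p`, `valid`,
#'   `substituted`.
#' @export
fit_condition_jnds <- function(responses, sign_rule = c("speed", "y_rule"), ...) {
  sign_rule <- match.arg(sign_rule)
  has_group <- "group" %in% names(responses)
  subjects <- unique(responses$subject_id)
  conds <- c("spatial", "temporal", "coherent", "opposite")
  rows <- lapply(subjects, function(sid) {
    sub <- responses[responses$subject_id == sid, , drop = FALSE]
    do.call(rbind, lapply(conds, function(cn) {
      f <- fit_condition(sub, cn, sign_rule = sign_rule, ...)
      data.frame(subject_id = sid,
                 group = if (has_group) sub$group[1] else NA_character_,
                 condition = cn,
                 jnd_signed = f$jnd_signed,
                 r_squared = f$r_squared, gof_p = f$gof_p,
                 valid = f$valid, substituted = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Convert negative JNDs to the precision scale
#'
#' Inverted psychometric curves yield negative signed JNDs that cannot enter
#' a precision analysis directly. Within each group, every negative JND is
#' converted as `jnd_conv = jnd_signed - min(JND) + max(JND)`, where the min
#' and max are taken over all of the group's signed JNDs (across conditions);
#' non-negative JNDs pass through unchanged. After conversion, low values
#' always mean good speed-discrimination precision, and every converted value
#' is at least the group's largest unconverted one — an inverted curve is
#' always "worse".
#'
#' @param records A data frame with `jnd_signed` and a grouping column.
#' @param group_col Name of the grouping column (default `"group"`).
#' @return `records` with a `jnd_conv` column added.
#' @export
convert_negative_jnds <- function(records, group_col = "group") {
  records <- as.data.frame(records)
  if (nrow(records) == 0) {
    stop_audspeed("no JND records to convert", "audspeed_grouping_error")
  }
  records$jnd_conv <- NA_real_
  for (g in unique(records[[group_col]])) {
    idx <- which(records[[group_col]] == g)
    j <- records$jnd_signed[idx]
    if (length(j) == 0 || any(!is.finite(j))) {
      stop_audspeed(sprintf("group '%s' has missing or non-finite JNDs", g),
                    "audspeed_grouping_error")
    }
    records$jnd_conv[idx] <- ifelse(j < 0, j - min(j) + max(j), j)
  }
  records
}
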