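#' Cue-weighted noisy observer parameters
#'
#' An observer answers "faster" when a weighted combination of noisy internal
#' cue estimates exceeds zero. On each trial the internal cues are
#' `w_t_hat = w_duration + e_t` and `w_d_hat = w_distance + e_d` with
#' `e ~ N(0, noise_sd)` i.i.d. (Weber units), and the derived speed cue is
#' `w_v_hat = (1 + w_d_hat)/(1 + w_t_hat) - 1`. The decision variable is
#'
#' `D = weight_speed * w_v_hat - weight_duration * w_t_hat +
#'      weight_distance * spatial_sign * w_d_hat`
#'
#' with response "faster" iff `D > 0` (exact ties are resolved by a fair
#' coin). `spatial_sign = +1` is the veridical spatial mapping (longer
#' distance reads as faster); `-1` is the inverted "shorter = faster"
#' heuristic. With probability `lapse` the response is replaced by a fair
#' coin flip.
#'
#' @param weight_speed,weight_duration,weight_distance Non-negative cue
#'   weights; at least one must be positive.
#' @param spatial_sign `+1` or `-1`.
#' @param noise_sd Internal noise standard deviation per cue, Weber units.
#' @param lapse Probability in `[0, 0.5]` of a uniformly random response.
#' @param label Optional descriptive label.
#' @return An object of class `observer_params`.
#' @export
observer_params <- function(weight_speed = 0,
                            weight_duration = 0,
                            weight_distance = 0,
                            spatial_sign = 1,
                            noise_sd = 0.3,
                            lapse = 0.02,
                            label = NULL) {
  w <- c(weight_speed, weight_duration, weight_distance)
  if (any(w < 0) || all(w == 0)) {
    stop_audspeed("cue weights must be non-negative with at least one > 0",
                  "audspeed_domain_error")
  }
  if (!spatial_sign %in% c(-1, 1)) {
    stop_audspeed("spatial_sign must be +1 or -1", "audspeed_domain_error")
  }
  if (lapse < 0 || lapse > 0.5) {
    stop_audspeed("lapse must lie in [0, 0.5]", "audspeed_domain_error")
  }
  if (noise_sd < 0) {
    stop_audspeed("noise_sd must be >= 0", "audspeed_domain_error")
  }
  structure(list(weight_speed = weight_speed,
                 weight_duration = weight_duration,
                 weight_distance = weight_distance,
                 spatial_sign = spatial_sign,
                 noise_sd = noise_sd,
                 lapse = lapse,
                 label = label %||% "custom"),
            class = "observer_params")
}

#' @export
print.observer_params <- function(x, ...) {
  cat(sprintf("observer '%s': weights (speed %.2f, duration %.2f, distance %.2f), ",
              x$label, x$weight_speed, x$weight_duration, x$weight_distance))
  cat(sprintf("spatial sign %+d, noise sd %.2f, lapse %.2f\n",
              x$spatial_sign, x$noise_sd, x$lapse))
  invisible(x)
}

#' Named observer presets
#'
#' `duration_only`, `distance_only` and `speed_only` are single-cue observers
#' (weight vector `(0,1,0)`, `(0,0,1)` and `(1,0,0)` over
#' speed/duration/distance, all veridical). `eb_like` is duration-dominant
#' with the inverted spatial heuristic (`spatial_sign = -1`); `sc_like` is a
#' mixed duration-dominant veridical observer.
#'
#' @param name One of `"duration_only"`, `"distance_only"`, `"speed_only"`,
#'   `"eb_like"`, `"sc_like"`.
#' @param noise_sd,lapse Overrides applied to the preset.
#' @return An [observer_params()] object.
#' @export
observer_preset <- function(name, noise_sd = 0.3, lapse = 0.02) {
  presets <- list(
    duration_only = list(0, 1, 0, +1),
    distance_only = list(0, 0, 1, +1),
    speed_only    = list(1, 0, 0, +1),
    eb_like       = list(0.1, 1.2, 0.3, -1),
    sc_like       = list(0.15, 1.0, 0.1, +1)
  )
  if (!name %in% names(presets)) {
    stop_audspeed(sprintf("unknown observer preset '%s'", name),
                  "audspeed_lookup_error")
  }
  p <- presets[[name]]
  observer_params(weight_speed = p[[1]], weight_duration = p[[2]],
                  weight_distance = p[[3]], spatial_sign = p[[4]],
                  noise_sd = noise_sd, lapse = lapse, label = name)
}

#' Simulate 2AFC responses of a cue-weighted observer
#'
#' Generates one "faster"/"slower" answer per trial of `design` under the
#' decision model documented in [observer_params()]. Trials whose noisy
#' internal duration or distance cue falls at or below -1 (a non-positive
#' internal quantity) have their noise redrawn, so output cues are always
#' valid. Identical seeds give identical response tables.
#'
#' @param design A trial schedule from [build_design()] (or any data frame
#'   with `w_duration` and `w_distance` columns).
#' @param observer An [observer_params()] object.
#' @param seed Integer seed.
#' @return `design` with an added `response` column (`"faster"`/`"slower"`)
#'   and class `response_table`.
#' @export
simulate_responses <- function(design, observer, seed = 1L) {
  if (nrow(design) == 0) {
    stop_audspeed("design has no trials", "audspeed_domain_error")
  }
  n <- nrow(design)
  out <- with_seed(seed, {
    e_t <- stats::rnorm(n, 0, observer$noise_sd)
    e_d <- stats::rnorm(n, 0, observer$noise_sd)
    wt_hat <- design$w_duration + e_t
    wd_hat <- design$w_distance + e_d
    bad <- which(wt_hat <= -1 | wd_hat <= -1)
    while (length(bad) > 0) {
      wt_hat[bad] <- design$w_duration[bad] + stats::rnorm(length(bad), 0, observer$noise_sd)
      wd_hat[bad] <- design$w_distance[bad] + stats::rnorm(length(bad), 0, observer$noise_sd)
      bad <- which(wt_hat <= -1 | wd_hat <= -1)
    }
    wv_hat <- (1 + wd_hat) / (1 + wt_hat) - 1
    D <- observer$weight_speed * wv_hat -
      observer$weight_duration * wt_hat +
      observer$weight_distance * observer$spatial_sign * wd_hat
    faster <- D > 0
    ties <- D == 0
    if (any(ties)) {
      faster[ties] <- stats::runif(sum(ties)) < 0.5
    }
    if (observer$lapse > 0) {
      lapsed <- stats::runif(n) < observer$lapse
      faster[lapsed] <- stats::runif(sum(lapsed)) < 0.5
    }
    faster
  })
  res <- as.data.frame(design)
  res$response <- ifelse(out, "faster", "slower")
  class(res) <- c("response_table", "data.frame")
  attr(res, "observer") <- observer
  res
}

#' Simulate a cohort of jittered observers
#'
#' Each subject receives the base observer's weights and noise multiplied by
#' independent log-normal jitter (`exp(N(0, jitter_sd))`), its own trial-order
#' randomisation, and its own response noise, all derived deterministically
#' from `seed`.
#'
#' @param config A [design_config()]; each subject gets its own shuffle seed.
#' @param n_subjects Number of subjects in the cohort.
#' @param observer Base [observer_params()] (or preset name).
#' @param group Cohort label stamped on every subject.
#' @param jitter_sd Standard deviation of the log-normal parameter jitter.
#' @param seed Integer seed for the whole cohort.
#' @return A `response_table` data frame covering all subjects.
#' @export
simulate_cohort <- function(config, n_subjects, observer, group = "G1",
                            jitter_sd = 0.2, seed = 1L) {
  if (is.character(observer)) {
    observer <- observer_preset(observer)
  }
  tables <- lapply(seq_len(n_subjects), function(i) {
    s_i <- stage_seed(seed, i)
    obs_i <- with_seed(stage_seed(s_i, 1), {
      jit <- function(v) v * exp(stats::rnorm(1, 0, jitter_sd))
      observer_params(
        weight_speed = jit(observer$weight_speed),
        weight_duration = jit(observer$weight_duration),
        weight_distance = jit(observer$weight_distance),
        spatial_sign = observer$spatial_sign,
        noise_sd = jit(observer$noise_sd),
        lapse = observer$lapse,
        label = sprintf("%s_jittered", observer$label))
    })
    cfg_i <- config
    cfg_i$seed <- stage_seed(s_i, 2)
    des <- build_design(cfg_i, subject_id = sprintf("%s%02d", group, i))
    resp <- simulate_responses(des, obs_i, seed = stage_seed(s_i, 3))
    resp$group <- group
    resp
  })
  out <- do.call(rbind, tables)
  class(out) <- c("response_table", "data.frame")
  out
}
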