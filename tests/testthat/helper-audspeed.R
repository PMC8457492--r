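# Shared fixtures, all generated in code.

# Exact proportion series sampled from a cumulative Gaussian.
exact_series <- function(pse = 0, sigma = 0.3,
                         x = seq(-0.6, 0.6, length.out = 9), n = 60) {
  data.frame(x = x, p_faster = pnorm((x - pse) / sigma), n = n)
}

# Points sampled exactly on a general ellipse. theta_deg is the axial angle
# of the major axis measured from the positive distance (vertical) axis.
ellipse_points <- function(a, b, theta_deg = 0, center = c(0, 0), n = 16,
                           phase = 0.3) {
  t <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)] + phase
  alpha <- (90 - theta_deg) * pi / 180  # math angle of the major axis
  x0 <- a * cos(t)
  y0 <- b * sin(t)
  data.frame(
    w_duration = center[1] + x0 * cos(alpha) - y0 * sin(alpha),
    w_distance = center[2] + x0 * sin(alpha) + y0 * cos(alpha))
}

# Independent exhaustive sign-flip p-value for the one-sample permutation t.
enumerate_signflip_p <- function(d) {
  n <- length(d)
  tstat <- function(v) {
    s <- sd(v)
    if (s == 0) {
      if (mean(v) == 0) 0 else sign(mean(v)) * Inf
    } else {
      mean(v) / (s / sqrt(n))
    }
  }
  t_obs <- tstat(d)
  grid <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  tt <- apply(grid, 1, function(s) tstat(d * s))
  mean(abs(tt) >= abs(t_obs) - 1e-12)
}

# Independent exhaustive label-shuffle p-value for the two-sample Welch t.
enumerate_shuffle_p <- function(a, b) {
  pool <- c(a, b)
  n <- length(pool)
  na <- length(a)
  welch <- function(xa, xb) {
    se2 <- var(xa) / length(xa) + var(xb) / length(xb)
    dm <- mean(xa) - mean(xb)
    if (se2 == 0) (if (dm == 0) 0 else sign(dm) * Inf) else dm / sqrt(se2)
  }
  t_obs <- welch(a, b)
  idx <- combn(n, na)
  tt <- apply(idx, 2, function(i) welch(pool[i], pool[-i]))
  mean(abs(tt) >= abs(t_obs) - 1e-12)
}

# Single-observer simulation through per-orientation fitting, substitution,
# contour construction and ellipse fitting.
observer_ellipse <- function(preset, n_reps = 60, seed = 11,
                             noise_sd = 0.3, lapse = 0.02) {
  des <- build_design(design_config(n_reps = n_reps, seed = seed))
  obs <- observer_preset(preset, noise_sd = noise_sd, lapse = lapse)
  resp <- simulate_responses(des, obs, seed = seed + 100)
  fits <- fit_orientation_jnds(resp)
  fits <- substitute_worst(fits, by = "subject_id", metric = "abs")
  fit_ellipse(contour_points(fits))
}

# Long-format null JND table for ANOVA calibration tests.
null_anova_table <- function(n_per_group = 10, conds = c("a", "b", "c", "d")) {
  d <- expand.grid(subject_id = sprintf("s%02d", seq_len(2 * n_per_group)),
                   condition = conds, stringsAsFactors = FALSE)
  d$group <- ifelse(match(d$subject_id, unique(d$subject_id)) <= n_per_group,
                    "G1", "G2")
  d$jnd_conv <- rnorm(nrow(d))
  d
}
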