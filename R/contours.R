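#' Build the discrimination-contour point set
#'
#' Each plane orientation contributes two points at plus and minus its JND
#' magnitude along the orientation direction, so `n_orientations` fits give
#' `2 * n_orientations` points (16 with the default 8 orientations),
#' symmetric about the origin by construction.
#'
#' An alternative reconstruction (`method = "projection"`) uses, for each
#' oblique orientation, separate fits of the "faster" proportion against the
#' `w_duration` and `w_distance` projections; the pure-axis orientations (for
#' which one projection is degenerate) always use the magnitude fit.
#'
#' @param fits Per-orientation fits for one subject, as returned by
#'   [fit_orientation_jnds()] (after [substitute_worst()]): a data frame with
#'   `orientation_deg` and `jnd_signed`.
#' @param responses Response table of the same subject; only needed for
#'   `method = "projection"`.
#' @param method `"magnitude"` (default) or `"projection"`.
#' @return A data frame of class `contour_set` with columns `w_duration`,
#'   `w_distance`, `orientation_deg`, `substituted`.
#' @export
contour_points <- function(fits, responses = NULL,
                           method = c("magnitude", "projection")) {
  method <- match.arg(method)
  if (any(is.na(fits$jnd_signed))) {
    stop_audspeed("contour construction requires a JND for every orientation (run substitute_worst first)",
                  "audspeed_completeness_error")
  }
  if (anyDuplicated(fits$orientation_deg)) {
    stop_audspeed("exactly one fit per orientation is required",
                  "audspeed_completeness_error")
  }
  rows <- lapply(seq_len(nrow(fits)), function(i) {
    ang <- fits$orientation_deg[i]
    d <- orientation_direction(ang)
    if (method == "projection" && !label_condition(ang) %in% c("spatial", "temporal")) {
      sub <- responses[abs(responses$orientation_deg - ang) < 1e-9, , drop = FALSE]
      fx <- fit_psychometric(aggregate_proportions(sub, axis = "w_duration"),
                             strict = FALSE)
      fy <- fit_psychometric(aggregate_proportions(sub, axis = "w_distance"),
                             strict = FALSE)
      jx <- abs(fx$jnd_signed)
      jy <- abs(fy$jnd_signed)
      if (!is.finite(jx) || !is.finite(jy)) {
        stop_audspeed(sprintf("projection fits failed on orientation %g deg", ang),
                      "audspeed_completeness_error")
      }
      px <- sign(d[["w_duration"]]) * jx
      py <- sign(d[["w_distance"]]) * jy
    } else {
      j <- abs(fits$jnd_signed[i])
      px <- j * d[["w_duration"]]
      py <- j * d[["w_distance"]]
    }
    data.frame(w_duration = c(px, -px), w_distance = c(py, -py),
               orientation_deg = ang,
               substituted = isTRUE(fits$substituted[i]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("contour_set", "data.frame")
  out
}

# Halir & Flusser numerically stable direct least-squares ellipse fit.
# Returns conic coefficients (A, B, C, D, E, F) with the ellipse constraint
# B^2 - 4AC < 0 built in.
fit_conic_direct <- function(x, y) {
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  # Keep real eigenvectors only, pick the one satisfying 4ac - b^2 > 0.
  V <- Re(ev$vectors)
  cond <- 4 * V[1, ] * V[3, ] - V[2, ]^2
  keep <- which(cond > 0)
  if (length(keep) == 0) {
    stop_audspeed("direct ellipse fit failed (degenerate point set)",
                  "audspeed_not_an_ellipse")
  }
  a1 <- V[, keep[1]]
  c(a1, as.numeric(Tm %*% a1))
}

# Plain algebraic conic fit: smallest-singular-vector solution of the general
# conic design matrix, with no ellipse-specific constraint. Emulates generic
# conic-fitting routines that can and do return hyperbolas on some point sets.
fit_conic_plain <- function(x, y) {
  D <- cbind(x^2, x * y, y^2, x, y, 1)
  sv <- svd(D)
  sv$v[, ncol(sv$v)]
}

# Geometric parameters of a conic known to be an ellipse.
conic_geometry <- function(cf) {
  A <- cf[1]; B <- cf[2]; C <- cf[3]; D <- cf[4]; E <- cf[5]; F <- cf[6]
  disc <- B^2 - 4 * A * C
  if (!is.finite(disc) || disc >= 0) {
    stop_audspeed("conic is not an ellipse (hyperbola, parabola or degenerate)",
                  "audspeed_not_an_ellipse")
  }
  M0 <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  Mm <- matrix(c(A, B / 2, D / 2, B / 2, C, E / 2, D / 2, E / 2, F), 3, 3)
  center <- tryCatch(solve(2 * M0, -c(D, E)),
                     error = function(e) stop_audspeed(
                       "degenerate ellipse (singular centre system)",
                       "audspeed_not_an_ellipse"))
  ev <- eigen(M0, symmetric = TRUE)
  g <- -det(Mm) / det(M0)
  ax2 <- g / ev$values
  if (any(!is.finite(ax2)) || any(ax2 <= 0)) {
    stop_audspeed("conic is degenerate or imaginary, not a real ellipse",
                  "audspeed_not_an_ellipse")
  }
  semi <- sqrt(ax2)
  major_i <- which.max(semi)
  v <- ev$vectors[, major_i]
  alpha <- atan2(v[2], v[1]) * 180 / pi      # math angle from +x (duration) axis
  theta <- (90 - alpha) %% 180               # axial angle from +y (distance) axis
  list(center = c(w_duration = center[1], w_distance = center[2]),
       semi_major = max(semi), semi_minor = min(semi),
       theta_deg = theta)
}

#' Fit an ellipse to a discrimination contour
#'
#' The default method is the direct least-squares fit with the built-in
#' ellipse constraint, which always returns an ellipse when the point set is
#' non-degenerate. `method = "conic"` performs a plain algebraic conic fit
#' and then classifies the conic, raising a `audspeed_not_an_ellipse`
#' condition when the best-fitting conic is a hyperbola, parabola or
#' degenerate — point sets rejected this way are excluded from orientation
#' analyses downstream rather than halting a cohort run.
#'
#' @param points A `contour_set` or any data frame / 2-column matrix with
#'   `w_duration` (x) and `w_distance` (y) coordinates; at least 6 points,
#'   not all collinear.
#' @param method `"direct"` (default) or `"conic"`.
#' @return An object of class `ellipse_fit`: `center`, `semi_major`,
#'   `semi_minor`, `theta_deg` (axial angle of the major axis in `[0, 180)`,
#'   measured from the positive distance axis so that 0 is duration-dominant,
#'   45 speed-dominant and 90 distance-dominant), and the 6 `conic`
#'   coefficients.
#' @export
fit_ellipse <- function(points, method = c("direct", "conic")) {
  method <- match.arg(method)
  if (is.matrix(points)) {
    points <- data.frame(w_duration = points[, 1], w_distance = points[, 2])
  }
  x <- points$w_duration
  y <- points$w_distance
  if (length(x) < 6) {
    stop_audspeed("need at least 6 points to fit an ellipse",
                  "audspeed_domain_error")
  }
  # Centre and scale for numerical conditioning; transform the conic back.
  mx <- mean(x); my <- mean(y)
  sc <- max(stats::sd(x), stats::sd(y), 1e-12)
  u <- (x - mx) / sc
  v <- (y - my) / sc
  cf_n <- tryCatch(
    if (method == "direct") fit_conic_direct(u, v) else fit_conic_plain(u, v),
    error = function(e) {
      if (inherits(e, "audspeed_not_an_ellipse")) stop(e)
      stop_audspeed("ellipse fit failed (degenerate point set)",
                    "audspeed_not_an_ellipse")
    })
  A <- cf_n[1]; B <- cf_n[2]; C <- cf_n[3]; D <- cf_n[4]; E <- cf_n[5]; F <- cf_n[6]
  # Un-normalise: substitute u = (x - mx)/sc, v = (y - my)/sc.
  cf <- c(A / sc^2,
          B / sc^2,
          C / sc^2,
          D / sc - 2 * A * mx / sc^2 - B * my / sc^2,
          E / sc - 2 * C * my / sc^2 - B * mx / sc^2,
          F + A * mx^2 / sc^2 + B * mx * my / sc^2 + C * my^2 / sc^2 -
            D * mx / sc - E * my / sc)
  geom <- conic_geometry(cf)
  structure(c(geom, list(conic = cf, method = method, n_points = length(x))),
            class = "ellipse_fit")
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf("ellipse fit (%s): centre (%.4f, %.4f), semi-axes (%.4f, %.4f), ",
              x$method, x$center[1], x$center[2], x$semi_major, x$semi_minor))
  cat(sprintf("major axis %.2f deg from the distance axis\n", x$theta_deg))
  invisible(x)
}

#' Axial (modulo-180) angular difference
#'
#' Ellipse orientation is an axial quantity: 0 and 180 degrees name the same
#' axis. The axial difference of two orientations is the acute angle between
#' their axes, in `[0, 90]`.
#'
#' @param theta_a,theta_b Angles in degrees. Vectorised.
#' @return Degrees in `[0, 90]`.
#' @export
axial_difference <- function(theta_a, theta_b) {
  d <- abs(theta_a - theta_b) %% 180
  pmin(d, 180 - d)
}

#' Wrap an angle difference into the axial range (-90, 90]
#'
#' @param x Angle(s) in degrees.
#' @return Equivalent axial angle(s) in `(-90, 90]`.
#' @export
axial_wrap <- function(x) {
  w <- x %% 180
  ifelse(w > 90, w - 180, w)
}
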