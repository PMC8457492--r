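#' Aggregate "faster" proportions along a stimulus axis
#'
#' Filters a response table by orientation and/or condition and tabulates the
#' proportion of "faster" answers at each distinct value of the chosen
#' stimulus coordinate.
#'
#' @param responses A response table from [simulate_responses()] (or a data
#'   frame with the same columns).
#' @param axis Which coordinate to aggregate on: the signed magnitude along
#'   the orientation, one of the raw Weber coordinates, or the signed radial
#'   distance `r` (see [radial_coordinate()]).
#' @param orientation Optional orientation angle (degrees) to keep.
#' @param condition Optional condition label to keep.
#' @param sign_rule Sign convention for the `r` axis, passed to
#'   [radial_coordinate()].
#' @return A data frame of class `proportion_series` with columns `x`,
#'   `p_faster`, `n`, ordered by `x`, and an `axis_label` attribute.
#' @export
aggregate_proportions <- function(responses,
                                  axis = c("magnitude", "w_duration",
                                           "w_distance", "r"),
                                  orientation = NULL,
                                  condition = NULL,
                                  sign_rule = c("speed", "y_rule")) {
  axis <- match.arg(axis)
  sign_rule <- match.arg(sign_rule)
  keep <- rep(TRUE, nrow(responses))
  if (!is.null(orientation)) {
    keep <- keep & abs(responses$orientation_deg - orientation) < 1e-9
  }
  if (!is.null(condition)) {
    keep <- keep & responses$condition == condition
  }
  sel <- responses[keep, , drop = FALSE]
  if (nrow(sel) == 0) {
    stop_audspeed("no trials match the orientation/condition selection",
                  "audspeed_selection_error")
  }
  x <- switch(axis,
              magnitude = sel$magnitude,
              w_duration = sel$w_duration,
              w_distance = sel$w_distance,
              r = radial_coordinate(sel$w_duration, sel$w_distance,
                                    sign_rule = sign_rule))
  key <- round(x, 10)
  faster <- sel$response == "faster"
  agg_n <- tapply(faster, key, length)
  agg_k <- tapply(faster, key, sum)
  xs <- as.numeric(names(agg_n))
  ord <- order(xs)
  out <- data.frame(x = xs[ord],
                    p_faster = as.numeric(agg_k[ord] / agg_n[ord]),
                    n = as.integer(agg_n[ord]))
  attr(out, "axis_label") <- axis
  class(out) <- c("proportion_series", "data.frame")
  out
}

#' Fit a cumulative Gaussian psychometric function
#'
#' Fits `p(x) = Phi((x - pse) / sigma)` to a proportion series by
#' count-weighted least squares on the proportions (the default) or by
#' count-weighted Bernoulli maximum likelihood, with `sigma` free to take
#' either sign: a decreasing ("inverted") curve yields a negative signed JND.
#' The two-parameter curve has no lapse term, so with lapsing observers the
#' far tails of a wide constant-stimuli grid never reach 0/1 exactly; the
#' least-squares objective is insensitive to those tail lapses, whereas plain
#' Bernoulli likelihood inflates `|sigma|` substantially there (which is why
#' `"ls"` is the default). Goodness of fit is the squared correlation between
#' observed and fitted proportions, tested by the F statistic of the
#' observed-on-fitted regression with `(1, k - 2)` degrees of freedom.
#'
#' A fit is marked invalid (rather than raising, when `strict = FALSE`) if
#' there are fewer than 3 distinct stimulus values, the optimiser fails, or
#' the curve is essentially flat (`|sigma|` beyond `sigma_ceiling` times the
#' largest `|x|`).
#'
#' @param series A `proportion_series` from [aggregate_proportions()], or any
#'   data frame with columns `x`, `p_faster`, `n`.
#' @param method `"ls"` (count-weighted least squares, default) or `"ml"`
#'   (count-weighted Bernoulli maximum likelihood).
#' @param sigma_ceiling Flat-curve ceiling as a multiple of `max(abs(x))`.
#' @param strict If `TRUE`, degenerate input (fewer than 3 distinct `x`)
#'   raises an error; if `FALSE` it returns an invalid fit, as batch callers
#'   require.
#' @return An object of class `psych_fit`: a list with `pse`, `jnd_signed`,
#'   `r_squared`, `gof_p`, `valid`, `substituted`, `n_points`, `method`.
#' @export
fit_psychometric <- function(series, method = c("ls", "ml"),
                             sigma_ceiling = 10, strict = TRUE) {
  method <- match.arg(method)
  x <- series$x
  p <- series$p_faster
  n <- series$n
  fin <- is.finite(x) & is.finite(p) & is.finite(n) & n >= 1
  x <- x[fin]; p <- p[fin]; n <- n[fin]
  k <- length(unique(x))
  invalid <- function() {
    structure(list(pse = NA_real_, jnd_signed = NA_real_,
                   r_squared = NA_real_, gof_p = NA_real_,
                   valid = FALSE, substituted = FALSE,
                   n_points = k, method = method),
              class = "psych_fit")
  }
  if (k < 3) {
    if (strict) {
      stop_audspeed("need at least 3 distinct stimulus values to fit",
                    "audspeed_degeneracy_error")
    }
    return(invalid())
  }
  eps <- 1e-9
  nll <- function(par) {
    mu <- par[1]
    sigma <- par[2]
    q <- pmin(pmax(stats::pnorm((x - mu) / sigma), eps), 1 - eps)
    -sum(n * (p * log(q) + (1 - p) * log(1 - q)))
  }
  ssq <- function(par) {
    q <- stats::pnorm((x - par[1]) / par[2])
    sum(n * (p - q)^2)
  }
  obj <- if (method == "ml") nll else ssq
  # Probit-regression start values, then one optimisation per slope sign.
  z <- stats::qnorm(pmin(pmax(p, 0.01), 0.99))
  sl <- tryCatch(stats::coef(stats::lm(z ~ x, weights = n)),
                 error = function(e) c(0, 0))
  span <- max(abs(x))
  sig0 <- if (is.finite(sl[2]) && abs(sl[2]) > 1e-8) 1 / abs(sl[2]) else span
  sig0 <- min(max(sig0, span / 100), sigma_ceiling * span)
  mu0 <- if (is.finite(sl[2]) && abs(sl[2]) > 1e-8) -sl[1] / sl[2] else
    stats::weighted.mean(x, n)
  mu0 <- min(max(mu0, min(x)), max(x))
  best <- NULL
  for (sgn in c(1, -1)) {
    fit <- tryCatch(
      stats::optim(c(mu0, sgn * sig0), obj, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) {
      best <- fit
    }
  }
  if (is.null(best) || !is.finite(best$value)) {
    return(invalid())
  }
  pse <- best$par[1]
  sigma <- best$par[2]
  fitted <- stats::pnorm((x - pse) / sigma)
  r2 <- if (stats::sd(p) < eps || stats::sd(fitted) < eps) NA_real_ else
    stats::cor(p, fitted)^2
  gof_p <- if (is.na(r2)) NA_real_ else {
    if (1 - r2 < 1e-15) 0 else
      stats::pf(r2 / (1 - r2) * (k - 2), 1, k - 2, lower.tail = FALSE)
  }
  valid <- is.finite(sigma) && abs(sigma) > 0 &&
    abs(sigma) <= sigma_ceiling * span && !is.na(r2)
  structure(list(pse = pse, jnd_signed = sigma, r_squared = r2,
                 gof_p = gof_p, valid = valid, substituted = FALSE,
                 n_points = k, method = method),
            class = "psych_fit")
}

#' @export
print.psych_fit <- function(x, ...) {
  if (!x$valid) {
    cat("psychometric fit: invalid (flat or failed)\n")
  } else {
    cat(sprintf("psychometric fit: PSE %.4f, signed JND %.4f%s, R^2 %.3f (p %.3g)\n",
                x$pse, x$jnd_signed,
                if (x$jnd_signed < 0) " [inverted]" else "",
                x$r_squared, x$gof_p))
  }
  invisible(x)
}

#' Is a psychometric fit's goodness of fit significant?
#'
#' @param fit A `psych_fit`.
#' @param alpha Significance level (default 0.05).
#' @return `TRUE` iff the fit's R-squared p-value is below `alpha`.
#' @export
gof_significant <- function(fit, alpha = 0.05) {
  isTRUE(fit$gof_p < alpha)
}

#' Substitute failed fits with the worst JND of their cell
#'
#' Within each cell of `by`, fits that are invalid or whose goodness of fit is
#' not significant receive the signed JND of the cell member with the poorest
#' precision. What "poorest" means depends on the analysis the fits feed:
#'
#' * `metric = "conv"` — the candidate whose converted JND (see
#'   [convert_negative_jnds()]) is largest, ties resolved in favour of the
#'   inverted (more negative) candidate. This is the ordering for radial
#'   per-condition fits, where an inverted curve means failed speed
#'   discrimination.
#' * `metric = "abs"` — the candidate with the largest `|jnd_signed|`. This
#'   is the ordering for per-orientation contour fits, where the slope sign
#'   only encodes which end of the line reads as "faster" and precision along
#'   the line is the JND magnitude.
#'
#' Valid significant fits are never altered.
#'
#' @param fits A data frame with columns `jnd_signed`, `valid`, `gof_p`, plus
#'   the columns named in `by`.
#' @param by Character vector of grouping columns defining the substitution
#'   cells (e.g. `"subject_id"` for per-orientation contour fits,
#'   `c("group", "condition")` for radial condition fits).
#' @param alpha Significance level of the goodness-of-fit gate.
#' @param metric Ordering that defines the worst candidate (see above).
#' @return `fits` with `jnd_signed` replaced and `substituted = TRUE` on
#'   substituted rows.
#' @export
substitute_worst <- function(fits, by, alpha = 0.05,
                             metric = c("conv", "abs")) {
  metric <- match.arg(metric)
  fits <- as.data.frame(fits)
  if (!"substituted" %in% names(fits)) {
    fits$substituted <- FALSE
  }
  cell <- interaction(fits[, by, drop = FALSE], drop = TRUE)
  for (cl in levels(cell)) {
    idx <- which(cell == cl)
    good <- idx[fits$valid[idx] & !is.na(fits$gof_p[idx]) &
                  fits$gof_p[idx] < alpha]
    bad <- setdiff(idx, good)
    if (length(bad) == 0) next
    if (length(good) == 0) {
      stop_audspeed(sprintf("no valid significant fit to substitute from in cell '%s'", cl),
                    "audspeed_substitution_error")
    }
    j <- fits$jnd_signed[good]
    score <- if (metric == "conv") {
      ifelse(j < 0, j - min(j) + max(j), j)
    } else {
      abs(j)
    }
    worst <- good[order(-score, j)][1]
    fits$jnd_signed[bad] <- fits$jnd_signed[worst]
    fits$substituted[bad] <- TRUE
  }
  fits
}

#' Per-orientation psychometric fits on the magnitude axis
#'
#' Convenience batch runner: for each subject and plane orientation in a
#' response table, aggregates "faster" proportions against the signed
#' magnitude and fits a cumulative Gaussian.
#'
#' @param responses A response table.
#' @param ... Passed to [fit_psychometric()] (`strict` is forced to `FALSE`).
#' @return A data frame with one row per subject x orientation: `subject_id`,
#'   (`group` if present), `orientation_deg`, `condition`, `pse`,
#'   `jnd_signed`, `r_squared`, `gof_p`, `valid`, `substituted`.
#' @export
fit_orientation_jnds <- function(responses, ...) {
  has_group <- "group" %in% names(responses)
  combos <- unique(responses[, c("subject_id", "orientation_deg")])
  combos <- combos[order(combos$subject_id, combos$orientation_deg), , drop = FALSE]
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sid <- combos$subject_id[i]
    ang <- combos$orientation_deg[i]
    sub <- responses[responses$subject_id == sid, , drop = FALSE]
    series <- aggregate_proportions(sub, axis = "magnitude", orientation = ang)
    f <- fit_psychometric(series, ..., strict = FALSE)
    data.frame(subject_id = sid,
               group = if (has_group) sub$group[1] else NA_character_,
               orientation_deg = ang,
               condition = label_condition(ang),
               pse = f$pse, jnd_signed = f$jnd_signed,
               r_squared = f$r_squared, gof_p = f$gof_p,
               valid = f$valid, substituted = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Serialize psychometric fits to JSON
#'
#' @param fits A data frame of fits (e.g. from [fit_orientation_jnds()]).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_fits_json <- function(fits, path) {
  jsonlite::write_json(as.data.frame(fits), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
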