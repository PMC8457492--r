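# Permutation inference and effect sizes for cohort JND / orientation tables.

# Exact small-sample correction factor for Hedges' g.
hedges_correction <- function(df) {
  if (df <= 1) return(NA_real_)
  exp(lgamma(df / 2) - log(sqrt(df / 2)) - lgamma((df - 1) / 2))
}

new_perm_test <- function(statistic, p_value, n_iterations, ci_95,
                          effect_size, effect_label, seed, method,
                          exact = FALSE, degenerate = FALSE) {
  structure(list(statistic = statistic, p_value = p_value,
                 n_iterations = n_iterations, ci_95 = ci_95,
                 effect_size = effect_size, effect_label = effect_label,
                 seed = seed, method = method, exact = exact,
                 degenerate = degenerate),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("%s: statistic %.4f, p %s%.4g (%s), %s %.3f, 95%% CI [%.3f, %.3f]\n",
              x$method, x$statistic, if (x$exact) "(exact) " else "",
              x$p_value,
              if (x$exact) "full enumeration" else
                sprintf("%d iterations", x$n_iterations),
              x$effect_label, x$effect_size, x$ci_95[1], x$ci_95[2]))
  invisible(x)
}

t_from_d <- function(d) {
  n <- length(d)
  m <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    if (m == 0) 0 else sign(m) * Inf
  } else {
    m / (s / sqrt(n))
  }
}

# t statistics for all columns of a sign matrix applied to d (vectorised).
t_signflip <- function(d, signs) {
  n <- length(d)
  X <- d * signs
  m <- colMeans(X)
  s2 <- (colSums(X^2) - n * m^2) / (n - 1)
  s2[s2 < 0] <- 0
  tt <- ifelse(s2 == 0, ifelse(m == 0, 0, sign(m) * Inf),
               m / sqrt(s2 / n))
  tt
}

#' One-sample permutation t-test by sign flipping
#'
#' Tests whether `values` differ from `target` using the one-sample t
#' statistic, with the null distribution generated by random sign flips of
#' the differences. When the full set of `2^n` sign patterns is small enough
#' (at most 16384) it is enumerated exhaustively and the p-value is exact.
#' With `axial = TRUE` the differences are first wrapped into the axial range
#' `(-90, 90]`, the appropriate scale for ellipse orientations (defined
#' modulo 180 degrees).
#'
#' @param values Numeric vector, n >= 2.
#' @param target Null value.
#' @param n_iter Random sign-flip iterations when not exhaustive.
#' @param seed Integer seed.
#' @param axial Wrap differences axially before testing.
#' @param mode `"auto"` (exact when feasible), `"exact"`, or `"sampled"`.
#' @return A `perm_test` with the t statistic, two-sided permutation p-value,
#'   Hedges' g on the differences (exact small-sample correction) and a
#'   t-based 95% CI on the mean difference.
#' @export
perm_t_one_sample <- function(values, target = 0, n_iter = 5000, seed = 1L,
                              axial = FALSE, mode = c("auto", "exact", "sampled")) {
  mode <- match.arg(mode)
  n <- length(values)
  if (n < 2) {
    stop_audspeed("need at least 2 values", "audspeed_domain_error")
  }
  d <- values - target
  if (axial) d <- axial_wrap(d)
  m <- mean(d)
  s <- stats::sd(d)
  g <- if (s == 0) NA_real_ else (m / s) * hedges_correction(n - 1)
  ci <- if (s == 0) c(m, m) else
    m + c(-1, 1) * stats::qt(0.975, n - 1) * s / sqrt(n)
  if (all(d == 0)) {
    return(new_perm_test(0, 1, n_iter, ci, 0, "hedges_g", seed,
                         "one-sample permutation t (sign flips)",
                         exact = TRUE))
  }
  t_obs <- t_from_d(d)
  exact <- switch(mode, auto = 2^n <= 16384, exact = TRUE, sampled = FALSE)
  eps <- 1e-12
  if (exact) {
    signs <- (-1)^(floor(outer(seq_len(n), 0:(2^n - 1),
                               function(i, j) j / 2^(i - 1))) %% 2)
    tt <- t_signflip(d, signs)
    p <- mean(abs(tt) >= abs(t_obs) - eps)
    n_used <- 2^n
  } else {
    tt <- with_seed(seed, {
      signs <- matrix(sample(c(-1, 1), n * n_iter, replace = TRUE), n, n_iter)
      t_signflip(d, signs)
    })
    p <- (sum(abs(tt) >= abs(t_obs) - eps) + 1) / (n_iter + 1)
    n_used <- n_iter
  }
  new_perm_test(t_obs, p, n_used, ci, g, "hedges_g", seed,
                "one-sample permutation t (sign flips)", exact = exact)
}

#' Two-sample permutation t-test by label shuffling
#'
#' Welch t statistic with the null distribution generated by reassigning the
#' pooled observations to the two groups. When the number of distinct splits
#' `choose(na + nb, na)` is at most 16384, all splits are enumerated and the
#' p-value is exact. Hedges' g uses the pooled SD with the exact small-sample
#' correction; a zero pooled SD is flagged as degenerate.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param n_iter Random label shuffles when not exhaustive.
#' @param seed Integer seed.
#' @param mode `"auto"`, `"exact"`, or `"sampled"`.
#' @return A `perm_test`.
#' @export
perm_t_two_sample <- function(a, b, n_iter = 5000, seed = 1L,
                              mode = c("auto", "exact", "sampled")) {
  mode <- match.arg(mode)
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) {
    stop_audspeed("each group needs at least 2 values", "audspeed_domain_error")
  }
  welch <- function(xa, xb) {
    va <- stats::var(xa); vb <- stats::var(xb)
    se2 <- va / length(xa) + vb / length(xb)
    dm <- mean(xa) - mean(xb)
    if (se2 == 0) {
      if (dm == 0) 0 else sign(dm) * Inf
    } else {
      dm / sqrt(se2)
    }
  }
  t_obs <- welch(a, b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  degenerate <- sp2 == 0
  g <- if (degenerate) NA_real_ else
    (mean(a) - mean(b)) / sqrt(sp2) * hedges_correction(na + nb - 2)
  va <- stats::var(a); vb <- stats::var(b)
  se2 <- va / na + vb / nb
  df_w <- if (se2 == 0) na + nb - 2 else
    se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  ci <- mean(a) - mean(b) + c(-1, 1) * stats::qt(0.975, df_w) * sqrt(se2)
  if (degenerate && t_obs == 0) {
    return(new_perm_test(0, 1, n_iter, ci, NA_real_, "hedges_g", seed,
                         "two-sample permutation t (label shuffles)",
                         exact = TRUE, degenerate = TRUE))
  }
  pool <- c(a, b)
  n <- na + nb
  eps <- 1e-12
  n_splits <- choose(n, na)
  exact <- switch(mode, auto = n_splits <= 16384, exact = TRUE, sampled = FALSE)
  if (exact) {
    idx <- utils::combn(n, na)
    tt <- apply(idx, 2, function(i) welch(pool[i], pool[-i]))
    p <- mean(abs(tt) >= abs(t_obs) - eps)
    n_used <- n_splits
  } else {
    tt <- with_seed(seed, {
      replicate(n_iter, {
        i <- sample.int(n, na)
        welch(pool[i], pool[-i])
      })
    })
    p <- (sum(abs(tt) >= abs(t_obs) - eps) + 1) / (n_iter + 1)
    n_used <- n_iter
  }
  new_perm_test(t_obs, p, n_used, ci, g, "hedges_g", seed,
                "two-sample permutation t (label shuffles)",
                exact = exact, degenerate = degenerate)
}

# Sums of squares of the balanced two-way mixed design.
# Y: subjects x conditions matrix; g: group factor over rows.
mixed_anova_ss <- function(Y, g) {
  N <- nrow(Y); b <- ncol(Y)
  gm <- mean(Y)
  s <- rowMeans(Y)
  ng <- tabulate(g)
  mg <- rowsum(s, g)[, 1] / ng
  ck <- colMeans(Y)
  cell <- rowsum(Y, g) / ng
  a <- nlevels(g)
  ss_group <- b * sum(ng * (mg - gm)^2)
  ss_subj <- b * sum((s - mg[as.integer(g)])^2)
  ss_cond <- N * sum((ck - gm)^2)
  ss_int <- sum(ng * (sweep(sweep(cell, 1, mg), 2, ck) + gm)^2)
  ss_tot <- sum((Y - gm)^2)
  ss_err <- ss_tot - ss_group - ss_subj - ss_cond - ss_int
  list(group = ss_group, subj = ss_subj, cond = ss_cond, int = ss_int,
       err = max(ss_err, 0), tot = ss_tot,
       df = c(group = a - 1, subj = N - a, cond = b - 1,
              int = (a - 1) * (b - 1), err = (N - a) * (b - 1)))
}

anova_f <- function(ss) {
  df <- ss$df
  safe_f <- function(num, dfn, den, dfd) {
    msn <- num / dfn
    msd <- den / dfd
    if (msd == 0) {
      if (msn == 0) 0 else Inf
    } else {
      msn / msd
    }
  }
  c(Group = safe_f(ss$group, df[["group"]], ss$subj, df[["subj"]]),
    Condition = safe_f(ss$cond, df[["cond"]], ss$err, df[["err"]]),
    `Group:Condition` = safe_f(ss$int, df[["int"]], ss$err, df[["err"]]))
}

#' Permutation mixed-design ANOVA
#'
#' Classical F statistics of a balanced two-way mixed design (one
#' between-subjects factor, one within-subjects factor), with permutation
#' p-values. The between-subjects effect is tested by permuting group labels
#' across subjects; the within-subjects effect and the interaction are tested
#' by permuting condition labels independently within each subject (the
#' subject effect is held fixed by construction, so this is equivalent to
#' permuting subject-centred residuals). Partial eta squared is reported per
#' effect against its own error term.
#'
#' @param data A data frame in long format.
#' @param dv,subject,group,condition Column names of the dependent variable
#'   and the design factors.
#' @param n_iter Permutation iterations (default 5000).
#' @param seed Integer seed.
#' @return An object of class `perm_anova`: a data frame with one row per
#'   effect (`Group`, `Condition`, `Group:Condition`) and columns `F`, `df1`,
#'   `df2`, `p_perm`, `partial_eta_sq`, plus `n_iterations` and `seed`
#'   attributes.
#' @export
perm_mixed_anova <- function(data, dv = "jnd_conv", subject = "subject_id",
                             group = "group", condition = "condition",
                             n_iter = 5000, seed = 1L) {
  data <- as.data.frame(data)
  subj <- factor(data[[subject]])
  cond <- factor(data[[condition]])
  grp <- factor(data[[group]])
  tab <- table(subj, cond)
  if (any(tab != 1)) {
    offenders <- rownames(tab)[apply(tab != 1, 1, any)]
    stop_audspeed(sprintf("unbalanced design: subjects without exactly one value per condition: %s",
                          paste(offenders, collapse = ", ")),
                  "audspeed_layout_error")
  }
  g_by_subj <- tapply(as.character(grp), subj, function(v) unique(v))
  if (any(lengths(g_by_subj) != 1)) {
    stop_audspeed("each subject must belong to exactly one group",
                  "audspeed_layout_error")
  }
  Y <- tapply(data[[dv]], list(subj, cond), mean)
  g <- factor(unlist(g_by_subj)[rownames(Y)])
  N <- nrow(Y); b <- ncol(Y)
  ss <- mixed_anova_ss(Y, g)
  F_obs <- anova_f(ss)
  peta <- c(Group = ss$group / (ss$group + ss$subj),
            Condition = ss$cond / (ss$cond + ss$err),
            `Group:Condition` = ss$int / (ss$int + ss$err))
  peta[!is.finite(peta)] <- 0
  s_means <- rowMeans(Y)
  counts <- with_seed(seed, {
    hits <- c(Group = 0, Condition = 0, `Group:Condition` = 0)
    eps <- 1e-12
    df <- ss$df
    gm <- mean(Y)
    for (it in seq_len(n_iter)) {
      # Between: permute group labels over subjects.
      g_p <- g[sample.int(N)]
      ng <- tabulate(g_p)
      mg <- rowsum(s_means, g_p)[, 1] / ng
      ssg <- b * sum(ng * (mg - gm)^2)
      sss <- b * sum((s_means - mg[as.integer(g_p)])^2)
      Fg <- if (sss == 0) (if (ssg == 0) 0 else Inf) else
        (ssg / df[["group"]]) / (sss / df[["subj"]])
      # Within: permute condition labels within each subject.
      Yp <- Y
      for (i in seq_len(N)) {
        Yp[i, ] <- Y[i, sample.int(b)]
      }
      ssp <- mixed_anova_ss(Yp, g)
      Fp <- anova_f(ssp)
      hits["Group"] <- hits["Group"] + (Fg >= F_obs["Group"] - eps)
      hits["Condition"] <- hits["Condition"] +
        (Fp["Condition"] >= F_obs["Condition"] - eps)
      hits["Group:Condition"] <- hits["Group:Condition"] +
        (Fp["Group:Condition"] >= F_obs["Group:Condition"] - eps)
    }
    hits
  })
  p_perm <- (counts + 1) / (n_iter + 1)
  out <- data.frame(effect = names(F_obs),
                    F = unname(F_obs),
                    df1 = unname(ss$df[c("group", "cond", "int")]),
                    df2 = unname(ss$df[c("subj", "err", "err")]),
                    p_perm = unname(p_perm),
                    partial_eta_sq = unname(peta))
  attr(out, "n_iterations") <- n_iter
  attr(out, "seed") <- seed
  class(out) <- c("perm_anova", "data.frame")
  out
}

#' @export
print.perm_anova <- function(x, ...) {
  cat(sprintf("permutation mixed ANOVA (%d iterations)\n",
              attr(x, "n_iterations")))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Chi-square test of a 2x2 count table
#'
#' Pearson chi-square without continuity correction (matching the closed form
#' `sum((O - E)^2 / E)`), with Cramer's V and a Wald 95% CI on the difference
#' of row proportions. A zero row or column margin triggers the Haldane
#' continuity fallback (0.5 added to every cell), flagged on the result.
#'
#' @param counts A 2x2 matrix: rows are the two stimulus points, columns the
#'   "faster"/"slower" counts.
#' @param seed Unused, kept for result provenance.
#' @return A `perm_test`-style result with `statistic` (chi-square, 1 df),
#'   `p_value`, `effect_size` (Cramer's V) and `ci_95` on the proportion
#'   difference.
#' @export
chi_square_counts <- function(counts, seed = NA_integer_) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2)) || any(counts < 0)) {
    stop_audspeed("counts must be a non-negative 2x2 matrix",
                  "audspeed_domain_error")
  }
  degenerate <- any(rowSums(counts) == 0) || any(colSums(counts) == 0)
  work <- if (degenerate) counts + 0.5 else counts
  N <- sum(work)
  E <- outer(rowSums(work), colSums(work)) / N
  stat <- sum((work - E)^2 / E)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  v <- sqrt(stat / N)
  p1 <- work[1, 1] / sum(work[1, ])
  p2 <- work[2, 1] / sum(work[2, ])
  se <- sqrt(p1 * (1 - p1) / sum(work[1, ]) + p2 * (1 - p2) / sum(work[2, ]))
  ci <- (p1 - p2) + c(-1, 1) * stats::qnorm(0.975) * se
  new_perm_test(stat, p, NA_integer_, ci, v, "cramers_v", seed,
                "chi-square (2x2, no continuity correction)",
                degenerate = degenerate)
}

#' Corner comparison of "faster" proportions at two plane points
#'
#' Builds the 2x2 point-by-response contingency table from the trials at two
#' cue-offset points (e.g. the shorter-duration/longer-distance corner versus
#' the longer-duration/shorter-distance corner of the opposite diagonal) and
#' tests independence with [chi_square_counts()].
#'
#' @param responses A response table.
#' @param point_a,point_b Numeric length-2 vectors `(w_duration, w_distance)`.
#' @param tol Matching tolerance on the cue coordinates.
#' @return A `perm_test`-style chi-square result.
#' @export
chi_square_corner <- function(responses, point_a, point_b, tol = 1e-6) {
  pick <- function(p) {
    responses[abs(responses$w_duration - p[1]) < tol &
                abs(responses$w_distance - p[2]) < tol, , drop = FALSE]
  }
  ta <- pick(point_a)
  tb <- pick(point_b)
  if (nrow(ta) == 0 || nrow(tb) == 0) {
    stop_audspeed("both plane points must have trials", "audspeed_selection_error")
  }
  counts <- rbind(a = c(faster = sum(ta$response == "faster"),
                        slower = sum(ta$response == "slower")),
                  b = c(faster = sum(tb$response == "faster"),
                        slower = sum(tb$response == "slower")))
  chi_square_counts(counts)
}

#' Bonferroni adjustment
#'
#' @param p_values Numeric p-values.
#' @param m Family size, at least `length(p_values)`.
#' @return `pmin(1, p * m)`.
#' @export
adjust_bonferroni <- function(p_values, m = length(p_values)) {
  if (m < length(p_values)) {
    stop_audspeed("family size m must be >= the number of p-values",
                  "audspeed_domain_error")
  }
  pmin(1, p_values * m)
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper around [stats::shapiro.test()] for report completeness.
#'
#' @param values Numeric vector, 3 <= n <= 5000, non-constant.
#' @return A list with `statistic` (W) and `p_value`.
#' @export
shapiro_wilk <- function(values) {
  n <- length(values)
  if (n < 3 || n > 5000) {
    stop_audspeed("Shapiro-Wilk requires 3 <= n <= 5000", "audspeed_domain_error")
  }
  if (stats::sd(values) == 0) {
    stop_audspeed("Shapiro-Wilk is undefined for constant input",
                  "audspeed_degeneracy_error")
  }
  res <- stats::shapiro.test(values)
  list(statistic = unname(res$statistic), p_value = res$p.value)
}
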