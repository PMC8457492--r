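#' End-to-end analysis configuration
#'
#' Bundles the stimulus design, the simulated cohort description and the
#' analysis switches into one object. The YAML serialisation of this
#' structure is the on-disk configuration format.
#'
#' @param design A [design_config()].
#' @param n_per_group Subjects simulated per group.
#' @param groups Named list mapping group labels to observer preset names
#'   (or [observer_params()] objects).
#' @param jitter_sd Log-normal SD of per-subject parameter jitter.
#' @param alpha Significance level used throughout.
#' @param n_iter Permutation iterations for all permutation tests.
#' @param sign_rule Radial sign convention, see [radial_coordinate()].
#' @param contour_method Contour construction, see [contour_points()].
#' @param ellipse_method Ellipse fitting, see [fit_ellipse()].
#' @param seed Global seed; fans out deterministically to every stage.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(design = design_config(),
                            n_per_group = 10,
                            groups = list(EB = "eb_like", SC = "sc_like"),
                            jitter_sd = 0.2,
                            alpha = 0.05,
                            n_iter = 5000,
                            sign_rule = "speed",
                            contour_method = "magnitude",
                            ellipse_method = "direct",
                            seed = 1L) {
  for (g in names(groups)) {
    if (is.character(groups[[g]])) {
      observer_preset(groups[[g]])  # validates the preset name
    }
  }
  structure(list(design = design, n_per_group = as.integer(n_per_group),
                 groups = groups, jitter_sd = jitter_sd, alpha = alpha,
                 n_iter = as.integer(n_iter), sign_rule = sign_rule,
                 contour_method = contour_method,
                 ellipse_method = ellipse_method, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the [pipeline_config()] arguments; the `design` key
#' holds [design_config()] arguments. Missing keys take their defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  dc <- do.call(design_config, raw$design %||% list())
  args <- raw[setdiff(names(raw), "design")]
  do.call(pipeline_config, c(list(design = dc), args))
}

#' Run the full analysis pipeline on simulated cohorts
#'
#' Executes design generation, observer simulation, per-orientation
#' psychometric fitting with worst-JND substitution, contour construction and
#' ellipse fitting, radial per-condition fitting with JND conversion, and the
#' group statistics battery (orientation t-tests against the three dominant
#' orientations, group comparison, permutation mixed ANOVA with post hocs,
#' and the corner chi-square). Subjects whose contour does not admit an
#' ellipse are excluded from the orientation statistics only and listed in
#' the report.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, CSV/JSON artifacts and a
#'   text summary are written there.
#' @return A list of class `pipeline_report` with elements `responses`,
#'   `orientation_fits`, `contours`, `ellipses`, `excluded_subjects`,
#'   `jnd_records`, `orientation_tests`, `group_orientation_test`, `anova`,
#'   `posthoc_condition`, `posthoc_group_by_condition`, `normality`,
#'   `corner_chisq`, `config`, `seed`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stages <- function(k) stage_seed(config$seed, k)

  ## simulate cohorts
  responses <- do.call(rbind, lapply(seq_along(config$groups), function(i) {
    gname <- names(config$groups)[i]
    obs <- config$groups[[i]]
    if (is.character(obs)) obs <- observer_preset(obs)
    simulate_cohort(config$design, config$n_per_group, obs, group = gname,
                    jitter_sd = config$jitter_sd, seed = stages(i))
  }))

  ## per-orientation fits -> contours -> ellipses
  ofits <- fit_orientation_jnds(responses)
  ofits <- substitute_worst(ofits, by = "subject_id", alpha = config$alpha,
                            metric = "abs")
  subjects <- unique(ofits$subject_id)
  contours <- lapply(subjects, function(sid) {
    contour_points(ofits[ofits$subject_id == sid, , drop = FALSE],
                   responses = responses[responses$subject_id == sid, , drop = FALSE],
                   method = config$contour_method)
  })
  names(contours) <- subjects
  ellipses <- lapply(subjects, function(sid) {
    tryCatch(fit_ellipse(contours[[sid]], method = config$ellipse_method),
             audspeed_not_an_ellipse = function(e) NULL)
  })
  names(ellipses) <- subjects
  excluded <- subjects[vapply(ellipses, is.null, logical(1))]
  theta <- vapply(ellipses[setdiff(subjects, excluded)],
                  function(e) e$theta_deg, numeric(1))
  subj_group <- ofits$group[match(names(theta), ofits$subject_id)]

  ## orientation statistics per group, Bonferroni over the three references
  dominant <- c(duration = 0, speed = 45, distance = 90)
  orientation_tests <- lapply(unique(subj_group), function(g) {
    th <- theta[subj_group == g]
    tests <- lapply(dominant, function(ref) {
      perm_t_one_sample(th, target = ref, n_iter = config$n_iter,
                        seed = stages(10), axial = TRUE)
    })
    p_adj <- adjust_bonferroni(vapply(tests, function(t) t$p_value, numeric(1)),
                               m = length(dominant))
    for (i in seq_along(tests)) tests[[i]]$p_adjusted <- p_adj[i]
    tests
  })
  names(orientation_tests) <- unique(subj_group)
  group_orientation_test <- if (length(unique(subj_group)) == 2) {
    gl <- unique(subj_group)
    perm_t_two_sample(axial_wrap(theta[subj_group == gl[1]]),
                      axial_wrap(theta[subj_group == gl[2]]),
                      n_iter = config$n_iter, seed = stages(11))
  } else {
    NULL
  }

  ## radial condition fits -> conversion -> ANOVA
  cfits <- fit_condition_jnds(responses, sign_rule = config$sign_rule)
  cfits <- substitute_worst(cfits, by = c("group", "condition"),
                            alpha = config$alpha)
  jnd_records <- convert_negative_jnds(cfits)
  normality <- lapply(split(jnd_records$jnd_conv, jnd_records$group),
                      shapiro_wilk)
  anova <- perm_mixed_anova(jnd_records, n_iter = config$n_iter,
                            seed = stages(12))

  ## post hocs: condition pairs (paired over all subjects), group per condition
  conds <- c("spatial", "temporal", "coherent", "opposite")
  wide <- tapply(jnd_records$jnd_conv,
                 list(jnd_records$subject_id, jnd_records$condition), mean)
  pairs <- utils::combn(conds, 2)
  posthoc_condition <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    t <- perm_t_one_sample(wide[, a] - wide[, b], target = 0,
                           n_iter = config$n_iter, seed = stages(20 + i))
    t$comparison <- sprintf("%s vs %s", a, b)
    t
  })
  for (t in seq_along(posthoc_condition)) {
    posthoc_condition[[t]]$p_adjusted <-
      adjust_bonferroni(posthoc_condition[[t]]$p_value, m = ncol(pairs))
  }
  groups_present <- unique(jnd_records$group)
  posthoc_group <- if (length(groups_present) == 2) {
    res <- lapply(conds, function(cn) {
      sel <- jnd_records[jnd_records$condition == cn, , drop = FALSE]
      t <- perm_t_two_sample(sel$jnd_conv[sel$group == groups_present[1]],
                             sel$jnd_conv[sel$group == groups_present[2]],
                             n_iter = config$n_iter, seed = stages(30))
      t$p_adjusted <- adjust_bonferroni(t$p_value, m = length(conds))
      t$comparison <- cn
      t
    })
    names(res) <- conds
    res
  } else {
    NULL
  }

  ## corner chi-square on the opposite-diagonal extremes, per group
  opp <- responses[responses$condition == "opposite", , drop = FALSE]
  corner_up <- opp[which.min(opp$w_duration), c("w_duration", "w_distance")]
  corner_dn <- opp[which.max(opp$w_duration), c("w_duration", "w_distance")]
  corner_chisq <- lapply(groups_present, function(g) {
    chi_square_corner(responses[responses$group == g, , drop = FALSE],
                      as.numeric(corner_up), as.numeric(corner_dn))
  })
  names(corner_chisq) <- groups_present

  report <- structure(list(responses = responses,
                           orientation_fits = ofits,
                           contours = contours,
                           ellipses = ellipses,
                           excluded_subjects = excluded,
                           ellipse_theta = theta,
                           jnd_records = jnd_records,
                           orientation_tests = orientation_tests,
                           group_orientation_test = group_orientation_test,
                           anova = anova,
                           posthoc_condition = posthoc_condition,
                           posthoc_group_by_condition = posthoc_group,
                           normality = normality,
                           corner_chisq = corner_chisq,
                           config = config,
                           seed = config$seed),
                      class = "pipeline_report")
  if (!is.null(out_dir)) {
    write_report(report, out_dir)
  }
  report
}

#' Write a pipeline report bundle to disk
#'
#' Emits `responses.csv`, `orientation_fits.csv`, `jnd_records.csv`,
#' `ellipses.json`, `stats.json` and a human-readable `summary.txt`. Every
#' file records the seed and configuration hash that produced it.
#'
#' @param report A `pipeline_report` from [run_pipeline()].
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(report$config)
  stamp <- sprintf("seed %d, config %s", report$seed, hash)
  write_trials(report$responses, file.path(out_dir, "responses.csv"))
  utils::write.csv(report$orientation_fits,
                   file.path(out_dir, "orientation_fits.csv"), row.names = FALSE)
  utils::write.csv(report$jnd_records,
                   file.path(out_dir, "jnd_records.csv"), row.names = FALSE)
  ell <- lapply(names(report$ellipses), function(sid) {
    e <- report$ellipses[[sid]]
    if (is.null(e)) {
      list(subject_id = sid, valid = FALSE)
    } else {
      list(subject_id = sid, valid = TRUE,
           center = as.numeric(e$center), semi_major = e$semi_major,
           semi_minor = e$semi_minor, theta_deg = e$theta_deg)
    }
  })
  jsonlite::write_json(list(provenance = stamp, ellipses = ell),
                       file.path(out_dir, "ellipses.json"),
                       auto_unbox = TRUE, digits = NA)
  flat_test <- function(t) {
    list(statistic = t$statistic, p_value = t$p_value,
         p_adjusted = t$p_adjusted %||% NA,
         effect_size = t$effect_size, effect_label = t$effect_label,
         ci_95 = t$ci_95, exact = t$exact,
         comparison = t$comparison %||% NA)
  }
  stats_out <- list(
    provenance = stamp,
    orientation_tests = lapply(report$orientation_tests,
                               function(g) lapply(g, flat_test)),
    group_orientation_test =
      if (is.null(report$group_orientation_test)) NULL else
        flat_test(report$group_orientation_test),
    anova = as.data.frame(report$anova),
    posthoc_condition = lapply(report$posthoc_condition, flat_test),
    posthoc_group_by_condition =
      if (is.null(report$posthoc_group_by_condition)) NULL else
        lapply(report$posthoc_group_by_condition, flat_test),
    normality = report$normality,
    corner_chisq = lapply(report$corner_chisq, flat_test),
    excluded_subjects = report$excluded_subjects)
  jsonlite::write_json(stats_out, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  con <- file(file.path(out_dir, "summary.txt"), "w")
  on.exit(close(con))
  writeLines(c(sprintf("audspeed pipeline report (%s)", stamp), ""), con)
  sink(con)
  print(report)
  sink()
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("pipeline report: %d subjects, %d trials, seed %d\n",
              length(unique(x$responses$subject_id)), nrow(x$responses),
              x$seed))
  if (length(x$excluded_subjects)) {
    cat("  subjects without a fittable ellipse (excluded from orientation stats):",
        paste(x$excluded_subjects, collapse = ", "), "\n")
  }
  for (g in names(x$orientation_tests)) {
    th <- x$ellipse_theta[names(x$ellipse_theta) %in%
                            x$orientation_fits$subject_id[x$orientation_fits$group == g]]
    cat(sprintf("  group %s: mean axial ellipse orientation %.2f deg (n = %d)\n",
                g, mean(axial_wrap(th)), length(th)))
    for (ref in names(x$orientation_tests[[g]])) {
      t <- x$orientation_tests[[g]][[ref]]
      cat(sprintf("    vs %s-dominant: t = %.2f, p = %.4f (Bonferroni %.4f), g = %.2f\n",
                  ref, t$statistic, t$p_value, t$p_adjusted, t$effect_size))
    }
  }
  cat("  permutation mixed ANOVA on converted JNDs:\n")
  for (i in seq_len(nrow(x$anova))) {
    cat(sprintf("    %s: F = %.2f, p = %.4f, partial eta^2 = %.3f\n",
                x$anova$effect[i], x$anova$F[i], x$anova$p_perm[i],
                x$anova$partial_eta_sq[i]))
  }
  for (g in names(x$corner_chisq)) {
    t <- x$corner_chisq[[g]]
    cat(sprintf("  corner chi-square (%s): chi^2 = %.2f, p = %.4g, V = %.3f\n",
                g, t$statistic, t$p_value, t$effect_size))
  }
  invisible(x)
}
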