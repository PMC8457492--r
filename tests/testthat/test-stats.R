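test_that("one-sample sign-flip test handles null and extreme data", {
  res <- perm_t_one_sample(rep(5, 6), target = 5)
  expect_equal(res$p_value, 1)
  expect_equal(res$statistic, 0)

  withr::with_seed(2, {
    shifted <- 10 + rnorm(10, sd = 0.01)
    res <- perm_t_one_sample(shifted, target = 0, mode = "sampled",
                             n_iter = 2000, seed = 3)
    expect_lt(res$p_value, 0.01)  # near the permutation floor
    exact <- perm_t_one_sample(shifted, target = 0)  # auto-exact at n = 10
    expect_true(exact$exact)
    expect_equal(exact$p_value, 2 / 1024)  # only the all-flip patterns tie
  })
})

test_that("auto-exact sign-flip p matches independent enumeration", {
  withr::with_seed(4, {
    for (i in 1:5) {
      d <- rnorm(sample(5:10, 1), mean = 0.4)
      res <- perm_t_one_sample(d, target = 0)
      expect_true(res$exact)
      expect_equal(res$p_value, enumerate_signflip_p(d), tolerance = 1e-12)
    }
  })
})

test_that("sampled sign-flip p approaches the exact p", {
  withr::with_seed(6, {
    d <- rnorm(10, mean = 0.5)
    p_exact <- perm_t_one_sample(d)$p_value
    p_samp <- perm_t_one_sample(d, mode = "sampled", n_iter = 10000,
                                seed = 7)$p_value
    expect_lt(abs(p_exact - p_samp), 0.01)
  })
})

test_that("axial wrapping makes orientation comparisons modulo 180", {
  th <- c(178, 179, 1, 2, 177)  # all within a few degrees of the 0-axis
  res <- perm_t_one_sample(th, target = 0, axial = TRUE)
  expect_lt(abs(res$statistic), 2)  # wrapped differences straddle zero
  # a tight cluster at 45 deg is far from 0 but indistinguishable from 45
  th45 <- c(40, 44, 48, 43, 46)
  res0 <- perm_t_one_sample(th45, target = 0, axial = TRUE)
  expect_gt(abs(res0$statistic), 10)
  expect_equal(res0$p_value, 2 / 32)  # sign-flip floor at n = 5
  res45 <- perm_t_one_sample(th45, target = 45, axial = TRUE)
  expect_gt(res45$p_value, 0.5)
})

test_that("Hedges g uses the exact small-sample correction", {
  d <- c(0.1, 0.5, 0.9, 1.3)
  res <- perm_t_one_sample(d, target = 0)
  n <- 4
  J <- exp(lgamma((n - 1) / 2) - log(sqrt((n - 1) / 2)) - lgamma((n - 2) / 2))
  expect_equal(res$effect_size, mean(d) / sd(d) * J, tolerance = 1e-12)
})

test_that("two-sample label-shuffle test: exact mode and degeneracy", {
  res <- perm_t_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$p_value, 1)

  withr::with_seed(8, {
    a <- rnorm(4); b <- rnorm(4) + 2
    res <- perm_t_two_sample(a, b)  # 70 splits: exact
    expect_true(res$exact)
    expect_equal(res$p_value, enumerate_shuffle_p(a, b), tolerance = 1e-12)
  })

  deg <- perm_t_two_sample(c(0, 0, 0), c(1, 1, 1))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$effect_size))
  expect_lt(deg$p_value, 0.2)  # all-same split count over choose(6,3)
})

test_that("8+8 label shuffles are enumerated exactly", {
  withr::with_seed(9, {
    a <- rnorm(8); b <- rnorm(8) + 1
    res <- perm_t_two_sample(a, b)
    expect_true(res$exact)
    expect_equal(res$n_iterations, choose(16, 8))
    expect_equal(res$p_value, enumerate_shuffle_p(a, b), tolerance = 1e-12)
  })
})

test_that("mixed ANOVA F and partial eta^2 match a reference decomposition", {
  withr::with_seed(10, {
    d <- null_anova_table(n_per_group = 5)
    d$jnd_conv <- d$jnd_conv +
      2 * (d$group == "G2") + 1.5 * (d$condition == "b")
    res <- perm_mixed_anova(d, n_iter = 200, seed = 11)
    # reference: aov with subject error stratum
    d$subject_id <- factor(d$subject_id)
    d$group <- factor(d$group); d$condition <- factor(d$condition)
    ref <- summary(aov(jnd_conv ~ group * condition +
                         Error(subject_id / condition), data = d))
    f_group <- ref[["Error: subject_id"]][[1]]["group", "F value"]
    f_cond <- ref[["Error: subject_id:condition"]][[1]]["condition", "F value"]
    f_int <- ref[["Error: subject_id:condition"]][[1]]["group:condition", "F value"]
    expect_equal(res$F, c(f_group, f_cond, f_int), tolerance = 1e-8)
    expect_true(all(res$partial_eta_sq >= 0 & res$partial_eta_sq <= 1))
  })
})

test_that("mixed ANOVA permutation p responds to injected effects", {
  withr::with_seed(12, {
    # a pure group shift drives the Group p to its floor in every table while
    # leaving the Condition p distributed like a null p-value
    p_cond <- replicate(20, {
      d <- null_anova_table(n_per_group = 8)
      d$jnd_conv <- d$jnd_conv + 5 * (d$group == "G2")
      res <- perm_mixed_anova(d, n_iter = 200, seed = sample.int(1e6, 1))
      expect_equal(res$p_perm[res$effect == "Group"], 1 / 201,
                   tolerance = 1e-12)
      res$p_perm[res$effect == "Condition"]
    })
    expect_lt(mean(p_cond < 0.05), 0.25)
    expect_gt(mean(p_cond), 0.25)
  })
})

test_that("a constant table yields zero F for every effect", {
  d <- null_anova_table(n_per_group = 4)
  d$jnd_conv <- 1
  res <- perm_mixed_anova(d, n_iter = 100, seed = 14)
  expect_equal(res$F, c(0, 0, 0))
  expect_equal(res$partial_eta_sq, c(0, 0, 0))
})

test_that("unbalanced layouts are rejected with the offending subjects", {
  d <- null_anova_table(n_per_group = 3)
  d <- d[-1, ]
  err <- tryCatch(perm_mixed_anova(d), condition = identity)
  expect_s3_class(err, "audspeed_layout_error")
  expect_match(conditionMessage(err), "s01")
})

test_that("permutation results are reproducible and relabeling-invariant", {
  withr::with_seed(15, {
    d <- null_anova_table(n_per_group = 6)
    a <- perm_mixed_anova(d, n_iter = 300, seed = 16)
    b <- perm_mixed_anova(d, n_iter = 300, seed = 16)
    expect_identical(a$p_perm, b$p_perm)
    # relabeling groups does not change the two-sided p
    d2 <- d; d2$group <- ifelse(d$group == "G1", "G2", "G1")
    c <- perm_mixed_anova(d2, n_iter = 300, seed = 16)
    expect_equal(a$F, c$F, tolerance = 1e-12)
  })
})

test_that("chi-square matches the closed form and flags degeneracies", {
  expect_equal(chi_square_counts(matrix(c(30, 30, 30, 30), 2))$statistic, 0)
  perfect <- chi_square_counts(matrix(c(60, 0, 0, 60), 2))
  expect_equal(perfect$effect_size, 1)

  counts <- matrix(c(40, 15, 20, 45), 2)  # rows: points; cols: faster/slower
  res <- chi_square_counts(counts)
  E <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  expect_equal(res$statistic, sum((counts - E)^2 / E), tolerance = 1e-12)
  expect_equal(res$effect_size, sqrt(res$statistic / sum(counts)))
  expect_false(res$degenerate)

  zero_margin <- chi_square_counts(matrix(c(10, 5, 0, 0), 2))
  expect_true(zero_margin$degenerate)
  expect_error(chi_square_counts(matrix(1:6, 3, 2)),
               class = "audspeed_domain_error")
})

test_that("corner comparison recovers the temporal-assumption asymmetry", {
  des <- build_design(design_config(n_reps = 30, seed = 17))
  obs <- observer_preset("duration_only")
  r <- simulate_responses(des, obs, seed = 18)
  opp <- r[r$condition == "opposite", ]
  up <- unlist(opp[which.min(opp$w_duration), c("w_duration", "w_distance")])
  dn <- unlist(opp[which.max(opp$w_duration), c("w_duration", "w_distance")])
  res <- chi_square_corner(r, up, dn)
  expect_lt(res$p_value, 0.001)
  expect_gt(res$effect_size, 0.5)
  expect_error(chi_square_corner(r, c(9, 9), dn),
               class = "audspeed_selection_error")
})

test_that("Bonferroni adjustment clamps and preserves order", {
  expect_equal(adjust_bonferroni(0.01, m = 4), 0.04)
  expect_equal(adjust_bonferroni(0.5, m = 4), 1)
  p <- c(0.001, 0.02, 0.2)
  expect_equal(order(adjust_bonferroni(p)), order(p))
  expect_error(adjust_bonferroni(c(0.1, 0.2), m = 1),
               class = "audspeed_domain_error")
})

test_that("Shapiro-Wilk wrapper guards its domain", {
  withr::with_seed(19, {
    x <- rnorm(50)
    res <- shapiro_wilk(x)
    ref <- shapiro.test(x)
    expect_equal(res$statistic, unname(ref$statistic))
    expect_equal(res$p_value, ref$p.value)
    # strongly skewed samples are detected
    expon <- replicate(40, shapiro_wilk(rexp(50))$p_value < 0.05)
    expect_gt(mean(expon), 0.9)
  })
  expect_error(shapiro_wilk(c(1, 2)), class = "audspeed_domain_error")
  expect_error(shapiro_wilk(rep(1, 10)), class = "audspeed_degeneracy_error")
})
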