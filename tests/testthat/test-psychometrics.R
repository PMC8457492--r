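test_that("proportion aggregation counts faster responses per level", {
  r <- data.frame(subject_id = "s", orientation_deg = 90,
                  condition = "temporal",
                  magnitude = rep(c(-0.2, 0.2), each = 6),
                  w_duration = rep(c(-0.2, 0.2), each = 6), w_distance = 0,
                  response = c(rep("faster", 3), rep("slower", 3),
                               rep("faster", 1), rep("slower", 5)))
  s <- aggregate_proportions(r, axis = "magnitude", orientation = 90)
  expect_equal(s$x, c(-0.2, 0.2))
  expect_equal(s$p_faster, c(0.5, 1 / 6))
  expect_equal(s$n, c(6L, 6L))
  expect_error(aggregate_proportions(r, orientation = 45),
               class = "audspeed_selection_error")
})

test_that("a pure-axis filter on the orthogonal coordinate is degenerate", {
  r <- data.frame(subject_id = "s", orientation_deg = 90,
                  condition = "temporal", magnitude = c(-0.2, 0, 0.2),
                  w_duration = c(-0.2, 0, 0.2), w_distance = 0,
                  response = "faster")
  s <- aggregate_proportions(r, axis = "w_distance", condition = "temporal")
  expect_equal(nrow(s), 1)
  expect_equal(s$x, 0)
})

test_that("noiseless observer produces a step function at the reference", {
  des <- build_design(design_config(n_reps = 4, seed = 1))
  obs <- observer_preset("duration_only", noise_sd = 1e-12, lapse = 0)
  r <- simulate_responses(des, obs, seed = 2)
  s <- aggregate_proportions(r, axis = "magnitude", orientation = 90)
  expect_true(all(s$p_faster[s$x < 0] == 1))
  expect_true(all(s$p_faster[s$x > 0] == 0))
})

test_that("exact cumulative-Gaussian proportions are recovered", {
  for (method in c("ls", "ml")) {
    f <- fit_psychometric(exact_series(pse = 0, sigma = 0.3), method = method)
    expect_equal(f$pse, 0, tolerance = 1e-3)
    expect_equal(f$jnd_signed, 0.3, tolerance = 1e-3)
    expect_true(f$valid)
    expect_equal(f$r_squared, 1, tolerance = 1e-6)
  }
})

test_that("mirrored proportions flip the sign of the fitted JND", {
  s <- exact_series(pse = 0.1, sigma = 0.25)
  s$p_faster <- 1 - s$p_faster
  f <- fit_psychometric(s)
  expect_equal(f$jnd_signed, -0.25, tolerance = 1e-3)
  expect_equal(f$pse, 0.1, tolerance = 1e-3)
})

test_that("flat data yield an invalid fit and degenerate input errors", {
  s <- exact_series()
  s$p_faster <- 0.5
  f <- fit_psychometric(s)
  expect_false(f$valid)
  expect_false(gof_significant(f))
  bad <- data.frame(x = c(0, 0, 0), p_faster = c(0.2, 0.5, 0.9), n = 10)
  expect_error(fit_psychometric(bad), class = "audspeed_degeneracy_error")
  expect_false(fit_psychometric(bad, strict = FALSE)$valid)
})

test_that("goodness-of-fit gate: perfect curves pass, noise rarely does", {
  f <- fit_psychometric(exact_series())
  expect_true(gof_significant(f))
  # null responses (fair coin at every level): false-positive rate near alpha
  rate <- with(list(x = seq(-1, 1, length.out = 9)), {
    withr::with_seed(31, mean(replicate(400, {
      p <- rbinom(9, 20, 0.5) / 20
      g <- fit_psychometric(data.frame(x = x, p_faster = p, n = 20),
                            strict = FALSE)
      gof_significant(g)
    })))
  })
  expect_gt(rate, 0.015)
  expect_lt(rate, 0.11)
})

test_that("fitted sign tracks the direction of the generating curve", {
  x <- seq(-0.8, 0.8, length.out = 9)
  withr::with_seed(5, {
    for (sg in c(1, -1)) {
      p_true <- pnorm(sg * x / 0.3)
      k <- rbinom(9, 60, p_true)
      f <- fit_psychometric(data.frame(x = x, p_faster = k / 60, n = 60),
                            strict = FALSE)
      expect_true(f$valid)
      expect_equal(sign(f$jnd_signed), sg)
    }
  })
})

test_that("worst-JND substitution follows the cell ordering rules", {
  cells <- data.frame(subject_id = "s",
                      orientation_deg = c(0, 45, 90),
                      jnd_signed = c(0.2, 0.5, NA),
                      valid = c(TRUE, TRUE, FALSE),
                      gof_p = c(0.01, 0.01, NA))
  out <- substitute_worst(cells, by = "subject_id")
  expect_equal(out$jnd_signed[3], 0.5)
  expect_true(out$substituted[3])
  expect_false(any(out$substituted[1:2]))

  # signed candidates: the worst is the one whose converted value is largest
  j <- c(-0.1, 0.4)
  conv <- ifelse(j < 0, j - min(j) + max(j), j)  # independent arithmetic
  cells2 <- data.frame(subject_id = "s", orientation_deg = c(0, 45, 90),
                       jnd_signed = c(j, NA),
                       valid = c(TRUE, TRUE, FALSE),
                       gof_p = c(0.01, 0.01, NA))
  out2 <- substitute_worst(cells2, by = "subject_id")
  expect_equal(out2$jnd_signed[3], j[which.max(conv)])

  # magnitude ordering for contour cells
  out3 <- substitute_worst(cells2, by = "subject_id", metric = "abs")
  expect_equal(out3$jnd_signed[3], 0.4)

  # all significant: no-op
  ok <- data.frame(subject_id = "s", orientation_deg = c(0, 45),
                   jnd_signed = c(0.2, 0.3), valid = TRUE, gof_p = 0.001)
  expect_equal(substitute_worst(ok, by = "subject_id")$jnd_signed,
               ok$jnd_signed)

  # no valid fit anywhere in the cell
  none <- data.frame(subject_id = "s", orientation_deg = c(0, 45),
                     jnd_signed = NA_real_, valid = FALSE, gof_p = NA_real_)
  expect_error(substitute_worst(none, by = "subject_id"),
               class = "audspeed_substitution_error")
})

test_that("substitution cells are independent across groups", {
  cells <- data.frame(group = rep(c("A", "B"), each = 2),
                      condition = "spatial",
                      jnd_signed = c(0.2, NA, 0.9, NA),
                      valid = c(TRUE, FALSE, TRUE, FALSE),
                      gof_p = c(0.01, NA, 0.01, NA))
  out <- substitute_worst(cells, by = c("group", "condition"))
  expect_equal(out$jnd_signed, c(0.2, 0.2, 0.9, 0.9))
})

test_that("batch orientation fitting covers every subject-orientation cell", {
  des <- build_design(design_config(n_reps = 10, seed = 3))
  obs <- observer_preset("sc_like")
  r <- simulate_responses(des, obs, seed = 4)
  fits <- fit_orientation_jnds(r)
  expect_equal(nrow(fits), 8)
  expect_setequal(fits$orientation_deg, orientation_angles(8))
  expect_true(all(c("pse", "jnd_signed", "gof_p", "valid") %in% names(fits)))
})
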