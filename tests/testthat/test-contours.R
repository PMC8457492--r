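test_that("contour construction mirrors one point pair per orientation", {
  fits <- data.frame(subject_id = "s",
                     orientation_deg = orientation_angles(8),
                     jnd_signed = 1, substituted = FALSE)
  pts <- contour_points(fits)
  expect_equal(nrow(pts), 16)
  rad <- sqrt(pts$w_duration^2 + pts$w_distance^2)
  expect_equal(rad, rep(1, 16))
  # symmetric about the origin
  expect_equal(sum(pts$w_duration), 0, tolerance = 1e-12)
  expect_equal(sum(pts$w_distance), 0, tolerance = 1e-12)

  fits$jnd_signed[fits$orientation_deg == 0] <- 3
  pts <- contour_points(fits)
  on_axis <- pts[abs(pts$orientation_deg) < 1e-9, ]
  expect_equal(sort(on_axis$w_distance), c(-3, 3))
  expect_equal(on_axis$w_duration, c(0, 0), tolerance = 1e-12)

  fits$jnd_signed[1] <- NA
  expect_error(contour_points(fits), class = "audspeed_completeness_error")
  expect_error(contour_points(rbind(fits, fits)),
               class = "audspeed_completeness_error")
})

test_that("exact ellipse samples are recovered to high precision", {
  pts <- ellipse_points(a = 3, b = 1, theta_deg = 0)
  e <- fit_ellipse(pts)
  expect_equal(e$theta_deg, 0, tolerance = 1e-6)
  expect_equal(e$semi_major, 3, tolerance = 1e-6)
  expect_equal(e$semi_minor, 1, tolerance = 1e-6)
  expect_equal(as.numeric(e$center), c(0, 0), tolerance = 1e-8)

  e30 <- fit_ellipse(ellipse_points(a = 3, b = 1, theta_deg = 30))
  expect_equal(e30$theta_deg, 30, tolerance = 1e-6)
})

test_that("random ellipses are recovered by both fitting routes", {
  withr::with_seed(17, {
    for (i in 1:40) {
      a <- runif(1, 1.2, 5)
      b <- a / runif(1, 1.2, 5)
      th <- runif(1, 0, 180)
      ctr <- runif(2, -0.5, 0.5)
      pts <- ellipse_points(a, b, th, center = ctr, phase = runif(1, 0, pi))
      for (method in c("direct", "conic")) {
        e <- fit_ellipse(pts, method = method)
        expect_equal(axial_difference(e$theta_deg, th), 0, tolerance = 1e-5)
        expect_equal(e$semi_major, a, tolerance = 1e-6 * a)
        expect_equal(e$semi_minor, b, tolerance = 1e-6 * a)
        expect_equal(as.numeric(e$center), ctr, tolerance = 1e-6)
      }
    }
  })
})

test_that("ellipse fitting is invariant to point order and reflection", {
  withr::with_seed(3, {
    pts <- ellipse_points(2, 1, 70, phase = 0.7)
    e1 <- fit_ellipse(pts)
    e2 <- fit_ellipse(pts[sample.int(nrow(pts)), ])
    e3 <- fit_ellipse(data.frame(w_duration = -pts$w_duration,
                                 w_distance = -pts$w_distance))
    expect_equal(e1$theta_deg, e2$theta_deg, tolerance = 1e-8)
    expect_equal(e1$theta_deg, e3$theta_deg, tolerance = 1e-8)
    expect_equal(e1$semi_major, e3$semi_major, tolerance = 1e-8)
  })
})

test_that("orientation survives moderate multiplicative noise", {
  withr::with_seed(23, {
    errs <- replicate(100, {
      th <- runif(1, 0, 180)
      pts <- ellipse_points(3, 1.2, th, n = 16, phase = runif(1, 0, pi))
      noisy <- pts * (1 + matrix(rnorm(32, 0, 0.05), 16, 2))
      axial_difference(fit_ellipse(noisy)$theta_deg, th)
    })
    expect_lt(median(errs), 5)
  })
})

test_that("non-elliptical point sets are rejected by the conic route", {
  x <- c(seq(0.2, 3, length.out = 8), -seq(0.2, 3, length.out = 8))
  hyper <- data.frame(w_duration = x, w_distance = 1 / x)  # xy = 1
  expect_error(fit_ellipse(hyper, method = "conic"),
               class = "audspeed_not_an_ellipse")
  line <- data.frame(w_duration = 1:8, w_distance = 2 * (1:8))
  expect_error(fit_ellipse(line), class = "audspeed_not_an_ellipse")
  expect_error(fit_ellipse(ellipse_points(1, 1)[1:5, ]),
               class = "audspeed_domain_error")
})

test_that("axial differences wrap modulo 180 degrees", {
  expect_equal(axial_difference(0, 180), 0)
  expect_equal(axial_difference(10, 170), 20)
  expect_equal(axial_difference(45, 90), 45)
  expect_equal(axial_difference(179, 1), 2)
  expect_equal(axial_wrap(c(179, 91, 90, 45)), c(-1, -89, 90, 45))
})

test_that("single-cue simulated observers produce substituted flat orientations", {
  des <- build_design(design_config(n_reps = 40, seed = 6))
  obs <- observer_preset("duration_only")
  r <- simulate_responses(des, obs, seed = 66)
  fits <- fit_orientation_jnds(r)
  # the spatial orientation carries no duration information: not significant
  spatial <- fits[fits$orientation_deg == 0, ]
  expect_false(isTRUE(spatial$gof_p < 0.05))
  subbed <- substitute_worst(fits, by = "subject_id", metric = "abs")
  expect_true(subbed$substituted[subbed$orientation_deg == 0])
  # substituted value is the largest magnitude among significant fits
  sig <- fits$valid & !is.na(fits$gof_p) & fits$gof_p < 0.05
  expect_equal(abs(subbed$jnd_signed[subbed$orientation_deg == 0]),
               max(abs(fits$jnd_signed[sig])))
})
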