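p2 <- function(theta_deg) (3 * cos(theta_deg * pi / 180)^2 - 1) / 2

test_that("a system identical to the reference yields a zero-change point", {
  ref <- make_response_system(theta = 40, n_solutes = 0, seed = 1,
                              n_frames = 10)
  sys <- make_response_system(theta = 40, n_solutes = 4, seed = 1,
                              n_frames = 10, k_on = 2, k_off = 1)
  curve <- build_response_curve(list(sys), ref,
                                binding_criterion(0.3, 1), label = "ch")
  expect_s3_class(curve, "response_curve")
  expect_equal(nrow(curve), 1)
  expect_equal(curve$delta_s, 0, tolerance = 1e-12)  # same cone angle
  expect_gt(curve$x, 0)
})

test_that("response curves match generator ground truth pointwise", {
  theta_ref <- 40
  ref <- make_response_system(theta_ref, n_solutes = 0, seed = 5,
                              n_frames = 30)
  thetas <- c(42, 44, 46)
  rates <- list(c(0.5, 2), c(1, 1), c(2, 0.5))
  systems <- purrr::map2(thetas, seq_along(thetas), function(th, i) {
    make_response_system(th, n_solutes = 6 * i, seed = 100 + i,
                         n_frames = 30, k_on = rates[[i]][1],
                         k_off = rates[[i]][2])
  })
  curve <- build_response_curve(systems, ref, binding_criterion(0.3, 1))
  # x: time-averaged bound count per lipid straight from the bound flags
  expected_x <- vapply(systems, function(s) {
    mean(rowSums(s$ground_truth$bound)) / 40
  }, numeric(1))
  expect_equal(sort(curve$x), sort(expected_x), tolerance = 1e-12)
  expected_ds <- vapply(systems, function(s) {
    s$ground_truth$analytic_S - p2(theta_ref)
  }, numeric(1))
  expect_equal(curve$delta_s[order(curve$x)][order(order(expected_x))],
               expected_ds, tolerance = 1e-9)
  # permutation invariance of the assembled curve
  curve2 <- build_response_curve(rev(systems), ref,
                                 binding_criterion(0.3, 1))
  expect_equal(as.data.frame(curve2), as.data.frame(curve))
})

test_that("curve assembly validates its inputs", {
  ref <- make_response_system(40, n_solutes = 0, seed = 1, n_frames = 10)
  sys <- make_response_system(42, n_solutes = 3, seed = 2, n_frames = 10)
  expect_error(build_response_curve(list(sys), sys,
                                    binding_criterion(0.3, 1)),
               "solute-free")
  expect_error(
    build_response_curve(list(list(traj = sys, frame_range = 99:100)), ref,
                         binding_criterion(0.3, 1)),
    "frame_range")
})

test_that("a noiseless line through the origin is recovered exactly", {
  curve <- response_curve(data.frame(x = c(0.01, 0.02),
                                     delta_s = c(-0.002, -0.004)),
                          label = "alpha")
  fit <- fit_response_slope(curve)
  expect_equal(fit$slope, -0.2, tolerance = 1e-12)
  expect_equal(glance(fit)$n_points, 2)
  td <- tidy(fit)
  expect_equal(td$term, "slope")
  expect_equal(td$estimate, -0.2, tolerance = 1e-12)
  # single point: defined slope, undefined stderr
  single <- response_curve(data.frame(x = 0.1, delta_s = -0.03), "alpha")
  sfit <- fit_response_slope(single)
  expect_equal(sfit$slope, -0.3, tolerance = 1e-12)
  expect_true(is.na(sfit$slope_stderr))
  zero <- response_curve(data.frame(x = c(0, 0), delta_s = c(0, 0)), "a")
  expect_error(fit_response_slope(zero), "undefined")
})

test_that("slope fitting is equivariant under scaling of the response", {
  set.seed(11)
  curve <- response_curve(data.frame(x = runif(6, 0.01, 0.2),
                                     delta_s = rnorm(6, -0.01, 0.002)),
                          label = "beta")
  f1 <- fit_response_slope(curve)
  scaled <- curve
  scaled$delta_s <- 3 * curve$delta_s
  f2 <- fit_response_slope(scaled)
  expect_equal(f2$slope, 3 * f1$slope, tolerance = 1e-12)
})

test_that("the slope standard error is calibrated over 1000 replicates", {
  true_slope <- -0.25
  x <- seq(0.02, 0.2, length.out = 10)
  sigma <- 0.004
  fits <- vapply(1:1000, function(s) {
    set.seed(s)
    y <- true_slope * x + rnorm(10, sd = sigma)
    f <- fit_response_slope(
      response_curve(data.frame(x = x, delta_s = y), "a"))
    c(f$slope, f$slope_stderr)
  }, numeric(2))
  emp_sd <- sd(fits[1, ])
  mean_se <- mean(fits[2, ])
  expect_lt(abs(mean(fits[1, ]) - true_slope), 2 * emp_sd / sqrt(1000))
  # reported formula stderr matches the empirical scatter within 10%
  expect_lt(abs(mean_se - emp_sd) / emp_sd, 0.1)
  # and matches the closed form sigma / sqrt(sum x^2) within 10%
  expect_lt(abs(mean_se - sigma / sqrt(sum(x^2))) / (sigma / sqrt(sum(x^2))),
            0.1)
})

test_that("curve comparison: identity, scaling and constant offset", {
  set.seed(21)
  curve <- response_curve(data.frame(x = seq(0.05, 0.5, 0.05),
                                     delta_s = -0.1 * seq(0.05, 0.5, 0.05) +
                                       rnorm(10, sd = 0.001)),
                          label = "alpha")
  self <- compare_curves(curve, curve)
  expect_equal(self$slope_ratio, 1, tolerance = 1e-12)
  expect_equal(self$rms_deviation, 0, tolerance = 1e-12)
  doubled <- curve
  doubled$delta_s <- 2 * curve$delta_s
  expect_equal(compare_curves(doubled, curve)$slope_ratio, 2,
               tolerance = 1e-12)
  offset <- curve
  offset$delta_s <- curve$delta_s + 0.005
  cmp <- compare_curves(offset, curve)
  expect_equal(cmp$rms_deviation, 0.005, tolerance = 1e-12)
  far <- response_curve(data.frame(x = c(10, 20), delta_s = c(-1, -2)),
                        label = "alpha")
  expect_error(compare_curves(curve, far), "disjoint")
  other <- response_curve(data.frame(x = 0.1, delta_s = -0.01), "beta")
  expect_error(compare_curves(curve, other), "label")
})

test_that("experimental CSV curves round-trip through the reader", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x_kind,label,x,delta_s,stderr",
               "bound_per_lipid,alpha,0.05,-0.004,0.001",
               "bound_per_lipid,alpha,0.10,-0.009,0.001",
               "bound_per_lipid,alpha,0.20,-0.018,0.002"), path)
  curve <- read_response_curve(path)
  expect_s3_class(curve, "response_curve")
  expect_equal(curve$source[1], "experiment")
  expect_equal(nrow(curve), 3)
  fit <- fit_response_slope(curve)
  expect_equal(fit$slope, -0.09, tolerance = 0.02)
})
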