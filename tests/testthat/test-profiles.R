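test_that("a uniform system gives a flat profile at the expected density", {
  traj <- gen_density_system(function(z) rep(1, length(z)),
                             z_range = c(-5, 5), n_particles = 1000,
                             n_frames = 20, seed = 8)
  prof <- density_profile(traj, seq_len(1000), bin_width = 0.5)
  inside <- abs(prof$z) < 5
  expected <- 1000 / (4 * 4 * 10)
  expect_equal(mean(prof$density[inside]), expected, tolerance = 0.02)
  # chi-squared goodness of fit of the raw counts against uniformity
  counts <- prof$density[inside] * 0.5 * attr(prof, "area") *
    attr(prof, "n_frames")
  gof <- stats::chisq.test(round(counts))
  expect_gt(gof$p.value, 0.01)
})

test_that("a single static particle occupies exactly one bin", {
  top <- topology(tibble::tibble(atom_name = "P1", element = "P",
                                 residue_name = "PRT", residue_id = 1,
                                 molecule_id = 1))
  traj <- trajectory(top, list(matrix(c(1, 1, 1.0), 1, 3)), c(4, 4, 8))
  prof <- density_profile(traj, 1L)
  expect_equal(sum(prof$density > 0), 1)
  hot <- prof$z[prof$density > 0]
  expect_lt(abs(hot - 1.0), 1 / 30)
})

test_that("count conservation holds exactly and survives rebinning", {
  traj <- gen_density_system(function(z) exp(-z^2), z_range = c(-4, 4),
                             n_particles = 500, n_frames = 7, seed = 5)
  for (w in c(1 / 30, 1 / 15)) {
    prof <- density_profile(traj, seq_len(500), bin_width = w)
    total <- sum(prof$density) * w * attr(prof, "area") * attr(prof, "n_frames")
    expect_equal(total, 500 * 7, tolerance = 1e-12)
  }
})

test_that("PMF of a uniform profile is identically zero", {
  prof <- new_density_profile(z = (seq(-30, 29) + 0.5) / 30,
                              density = rep(3.2, 60))
  pmf <- pmf_from_density(prof, temperature = 298)
  expect_true(all(abs(pmf$pmf) < 1e-12))
})

test_that("a density ratio of e costs exactly kB T", {
  w <- 1 / 30
  prof <- new_density_profile(z = c(0.5, 1.5) * w,
                              density = c(exp(1), 1))
  pmf <- pmf_from_density(prof, temperature = 298,
                          reference_region = c(0, w))
  dpmf <- pmf$pmf[2] - pmf$pmf[1]
  expect_equal(dpmf, 0.008314462618 * 298, tolerance = 1e-9)
  expect_equal(dpmf, 2.478, tolerance = 1e-3)
})

test_that("a Gaussian density yields a parabolic PMF", {
  traj <- gen_density_system(function(z) exp(-z^2 / (2 * 1.2^2)),
                             z_range = c(-5, 5), n_particles = 2000,
                             n_frames = 10, seed = 12)
  prof <- density_profile(traj, seq_len(2000), bin_width = 0.2)
  pmf <- pmf_from_density(prof, temperature = 298,
                          reference_region = c(-0.5, 0.5))
  well <- !is.na(pmf$pmf) & abs(pmf$z) < 2.5
  fit <- lm(pmf$pmf[well] ~ I(pmf$z[well]^2))
  expect_gt(summary(fit)$r.squared, 0.99)
  # curvature = kB T / (2 sigma^2)
  expect_equal(unname(coef(fit)[2]), 0.008314462618 * 298 / (2 * 1.2^2),
               tolerance = 0.1)
})

test_that("Boltzmann inversion round-trips the density", {
  set.seed(4)
  w <- 1 / 30
  dens <- c(runif(40, 0.1, 5), 0, 0, runif(8, 0.1, 5))
  prof <- new_density_profile(z = (seq_along(dens) - 0.5) * w, density = dens)
  pmf <- pmf_from_density(prof, temperature = 310)
  rho_ref <- attr(pmf, "rho_ref")
  back <- rho_ref * exp(-pmf$pmf / (0.008314462618 * 310))
  defined <- !is.na(pmf$pmf)
  expect_equal(back[defined], dens[defined], tolerance = 1e-10)
  expect_true(all(is.na(pmf$pmf[!defined])))
  # zero-density bins are NA, never infinite
  expect_false(any(is.infinite(pmf$pmf)))
})

test_that("PMF shape is invariant under density rescaling", {
  set.seed(6)
  w <- 0.1
  dens <- runif(30, 0.5, 4)
  p1 <- pmf_from_density(new_density_profile((seq(30) - 0.5) * w, dens))
  p2 <- pmf_from_density(new_density_profile((seq(30) - 0.5) * w, 7.3 * dens))
  expect_equal(p1$pmf, p2$pmf, tolerance = 1e-10)
})

test_that("PMF averages to zero over the reference region", {
  set.seed(9)
  dens <- runif(50, 0.2, 3)
  prof <- new_density_profile((seq(50) - 25.5) * 0.1, dens)
  pmf <- pmf_from_density(prof, reference_region = c(-1, 1))
  in_ref <- pmf$z >= -1 & pmf$z <= 1
  expect_equal(mean(pmf$pmf[in_ref]), 0, tolerance = 1e-12)
})

test_that("symmetrization averages leaflets and is an involution", {
  w <- 1 / 30
  # delta at +z: half-weight deltas at +/- z after symmetrization
  z <- (seq(-15, 14) + 0.5) * w
  dens <- rep(0, 30)
  dens[z > 0][3] <- 4
  prof <- new_density_profile(z, dens)
  sym <- symmetrize_profile(prof)
  hot <- sym$density > 0
  expect_equal(sum(hot), 2)
  expect_equal(sym$density[hot], c(2, 2))
  expect_equal(sort(abs(sym$z[hot]))[1], sort(abs(sym$z[hot]))[2])
  # symmetric input unchanged; applying twice is a no-op
  sym2 <- symmetrize_profile(sym)
  expect_equal(sym2$density, sym$density, tolerance = 1e-14)
  # output invariant under z -> -z for arbitrary input
  set.seed(3)
  rnd <- new_density_profile(z, runif(30))
  s <- symmetrize_profile(rnd)
  expect_equal(s$density, rev(s$density), tolerance = 1e-14)
})

test_that("profile stages validate their inputs", {
  traj <- gen_density_system(function(z) rep(1, length(z)),
                             z_range = c(-2, 2), n_particles = 10,
                             n_frames = 2, seed = 1)
  expect_error(density_profile(traj, integer()), "empty")
  expect_error(density_profile(traj, 1L, bin_width = 0), "> 0")
  prof <- density_profile(traj, seq_len(10))
  expect_error(pmf_from_density(prof, reference_region = c(2, 1)),
               "increasing")
  expect_error(pmf_from_density(prof, reference_region = c(30, 40)),
               "reference region")
})

test_that("membrane half-width is recovered from the lipid slab density", {
  traj <- gen_membrane_system(n_lipids = 400, n_solutes = 0, n_waters = 50,
                              slab_halfwidth = 1.8, n_frames = 5, seed = 14)
  h <- estimate_membrane_halfwidth(traj)
  expect_lt(abs(h - 1.8), 0.25)
})
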