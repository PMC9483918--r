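test_that("the bound-fraction threshold is inclusive", {
  # 4 of 5 heavy atoms within the cutoff: bound at f = 0.8, not at f = 0.9
  lip <- matrix(c(2, 2, 0), 1, 3, byrow = TRUE)
  sol <- rbind(c(2, 2, 0.2), c(2, 2.2, 0.1), c(2.2, 2, 0.15),
               c(2, 1.9, 0.25), c(2, 2, 2))
  top <- topology(tibble::tibble(
    atom_name = c("L1", paste0("C", 1:5)), element = "C",
    residue_name = c("LIP", rep("ETI", 5)),
    residue_id = c(1, rep(2, 5)), molecule_id = c(1, rep(2, 5))))
  traj <- trajectory(top, list(rbind(lip, sol)), c(6, 6, 6))
  solutes <- list(2:6)
  expect_true(assign_bound(traj, 1, solutes, 1L,
                           binding_criterion(0.4, 0.8)))
  expect_false(assign_bound(traj, 1, solutes, 1L,
                            binding_criterion(0.4, 0.9)))
})

test_that("assign_bound equals the brute-force all-pairs oracle", {
  for (seed in 1:50) {
    fx <- random_binding_fixture(seed, n_solutes = 8, atoms_per = 2)
    crit <- binding_criterion(runif(1, 0.2, 0.8), sample(c(0.5, 1), 1))
    expect_identical(
      assign_bound(fx$traj, 1, fx$solutes, fx$lipids, crit),
      unname(brute_assign_bound(fx$traj, 1, fx$solutes, fx$lipids, crit)))
  }
})

test_that("bound time series matches the generator's ground truth", {
  traj <- gen_membrane_system(n_lipids = 60, n_solutes = 12, k_on = 1,
                              k_off = 1, n_waters = 30, n_frames = 40,
                              seed = 21)
  sel <- attr(traj$topology, "selections")
  solutes <- split(sel$solutes,
                   traj$topology$molecule_id[match(sel$solutes,
                                                   traj$topology$atom_id)])
  # the generator places bound solutes within 0.17 nm of a lipid atom and
  # free ones at least bulk_margin - cluster radius = 0.38 nm away
  series <- bound_timeseries(traj, solutes, sel$lipids,
                             binding_criterion(0.3, 1))
  expect_equal(series$n_bound, rowSums(traj$ground_truth$bound))
  # constant series when unbinding is impossible
  allb <- gen_membrane_system(n_lipids = 30, n_solutes = 5, k_on = 2,
                              k_off = 0, n_waters = 10, n_frames = 15,
                              seed = 22)
  sel2 <- attr(allb$topology, "selections")
  sol2 <- split(sel2$solutes,
                allb$topology$molecule_id[match(sel2$solutes,
                                                allb$topology$atom_id)])
  s2 <- bound_timeseries(allb, sol2, sel2$lipids, binding_criterion(0.3, 1))
  expect_true(all(s2$n_bound == 5))
})

test_that("criterion surface is monotone and steps at the two populations", {
  fx <- two_population_fixture()
  surf <- criterion_scan(fx$traj, fx$solutes, fx$lipids,
                         distance_grid = seq(0.1, 1, by = 0.1),
                         fraction_grid = seq(0.1, 1, by = 0.1))
  m <- surf$n_bound_mean
  expect_true(all(diff(m) >= 0))          # non-decreasing in cutoff
  expect_true(all(t(diff(t(m))) <= 0))    # non-increasing in fraction
  # plateau: for intermediate cutoffs every fraction binds exactly n_deep
  plateau_rows <- which(surf$distance_grid >= 0.3 & surf$distance_grid <= 0.9)
  expect_true(all(m[plateau_rows, ] == fx$n_deep))
  # selected criterion lies inside the plateau (counts the deep population)
  crit <- select_criterion(surf)
  expect_false(crit$degenerate)
  expect_equal(
    m[match(crit$distance_cutoff, surf$distance_grid),
      match(crit$bound_fraction, surf$fraction_grid)],
    fx$n_deep)
})

test_that("criterion scan validates grids and empty systems give zeros", {
  fx <- two_population_fixture(n_deep = 0, n_far = 3)
  surf <- criterion_scan(fx$traj, fx$solutes, fx$lipids,
                         distance_grid = c(0.1, 0.2, 0.3),
                         fraction_grid = c(0.3, 0.6, 1.0))
  expect_true(all(surf$n_bound_mean == 0))
  expect_error(criterion_scan(fx$traj, fx$solutes, fx$lipids,
                              distance_grid = c(0.1, 0.2),
                              fraction_grid = c(0.3, 0.6, 1.0)),
               "at least 3")
  expect_error(criterion_scan(fx$traj, fx$solutes, fx$lipids,
                              distance_grid = c(-0.1, 0.2, 0.3),
                              fraction_grid = c(0.3, 0.6, 1.0)), "> 0")
})

test_that("degenerate surfaces fall back to the deterministic tie-break", {
  # strictly linear surface in both axes: constant gradient everywhere
  surf <- structure(list(distance_grid = c(0.2, 0.4, 0.6),
                         fraction_grid = c(0.2, 0.6, 1.0),
                         n_bound_mean = outer(1:3, 1:3, "+")),
                    class = "criterion_surface")
  expect_warning(crit <- select_criterion(surf), "degenerate")
  expect_true(crit$degenerate)
  expect_equal(crit$distance_cutoff, 0.2)  # smallest cutoff ...
  expect_equal(crit$bound_fraction, 1.0)   # ... then largest fraction
})

test_that("a single exactly flat interior cell is selected", {
  m <- outer(1:5, 1:5, function(i, j) (i - 3)^2 + (j - 3)^2)
  surf <- structure(list(distance_grid = seq(0.2, 1, 0.2),
                         fraction_grid = seq(0.2, 1, 0.2),
                         n_bound_mean = m + 10),
                    class = "criterion_surface")
  # gradient vanishes only at the bowl center (interior node 3,3)
  crit <- select_criterion(surf)
  expect_equal(crit$distance_cutoff, 0.6)
  expect_equal(crit$bound_fraction, 0.6)
})

test_that("equilibration splitting finds the plateau onset", {
  set.seed(31)
  stationary <- tibble::tibble(n_bound = rpois(200, 10))
  eq <- equilibration_split(stationary)
  expect_true(eq$converged)
  expect_equal(eq$equilibration_end_index, 0)
  # relaxation that plateaus at ~40% of the series: the split point must
  # fall after the start and before the half-way cutoff, and tightening
  # the block resolution pushes it further into the ramp
  n <- 300
  relax <- tibble::tibble(
    n_bound = 20 * pmin(seq_len(n) / (0.4 * n), 1) + rnorm(n, sd = 0.5))
  eqr <- equilibration_split(relax)
  expect_true(eqr$converged)
  expect_gt(eqr$equilibration_end_index, 0)
  expect_lt(eqr$equilibration_end_index, 0.5 * n)
  eqr20 <- equilibration_split(relax, n_blocks = 20)
  expect_gte(eqr20$equilibration_end_index, eqr$equilibration_end_index)
  expect_lt(abs(eqr20$equilibration_end_index - 0.4 * n), 0.15 * n)
  # a monotone drift never converges
  drift <- tibble::tibble(n_bound = seq_len(200) + rnorm(200, sd = 0.1))
  expect_false(equilibration_split(drift)$converged)
  expect_error(equilibration_split(tibble::tibble(n_bound = 1:5)),
               "too short")
})

test_that("binding normalizations: bound per lipid and bulk concentration", {
  series <- tibble::tibble(time = 0:9, n_bound = rep(20, 10))
  attr(series, "n_total_solutes") <- 22
  attr(series, "n_lipids") <- 200
  attr(series, "n_waters") <- 1110
  expect_equal(bound_per_lipid(series), 0.1)
  expect_equal(bulk_concentration(series), 2 / 1110 * 55500)
  all_bound <- series
  all_bound$n_bound <- rep(22, 10)
  expect_equal(bulk_concentration(all_bound), 0)
  zero <- series
  zero$n_bound <- rep(0, 10)
  expect_equal(bound_per_lipid(zero), 0)
  attr(series, "n_waters") <- 0
  expect_error(bulk_concentration(series), "n_waters")
})

test_that("stationary bound fraction is recovered from the fixture", {
  traj <- gen_membrane_system(n_lipids = 40, n_solutes = 20, k_on = 1,
                              k_off = 1, dt = 0.5, n_waters = 200,
                              n_frames = 200, seed = 41)
  sel <- attr(traj$topology, "selections")
  solutes <- split(sel$solutes,
                   traj$topology$molecule_id[match(sel$solutes,
                                                   traj$topology$atom_id)])
  series <- bound_timeseries(traj, solutes, sel$lipids,
                             binding_criterion(0.3, 1))
  bpl <- bound_per_lipid(series)
  expect_equal(bpl, mean(rowSums(traj$ground_truth$bound)) / 40,
               tolerance = 1e-12)
  # within 3 pooled standard errors of the two-state equilibrium
  nb <- rowSums(traj$ground_truth$bound)
  bm <- tapply(nb, ceiling(seq_along(nb) / 40), mean)
  se <- sd(bm) / sqrt(length(bm))
  expect_lt(abs(mean(nb) - 10), 3 * se + 1e-9)
  # bulk concentration consistent with the unbound fraction
  conc <- bulk_concentration(series)
  expect_equal(conc, mean(20 - nb) / 200 * 55500, tolerance = 1e-12)
})
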