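# Synthetic trajectory generators.
#
# Every generator is seeded, restores the caller's RNG state, and attaches a
# ground-truth record to the trajectory so downstream analyses can be tested
# against known answers rather than against themselves.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# uniform directions on the unit sphere
runif_sphere <- function(n) {
  ct <- runif(n, -1, 1)
  st <- sqrt(1 - ct^2)
  phi <- runif(n, 0, 2 * pi)
  cbind(st * cos(phi), st * sin(phi), ct)
}

#' Generate a C-H bond orientation trajectory
#'
#' Creates a trajectory of carbon-hydrogen atom pairs whose bond vectors are
#' drawn from a chosen orientation distribution relative to the z axis (the
#' membrane normal), with closed-form order parameters:
#' * `fixed_angle`: every bond at polar angle `theta`, fixed azimuth;
#'   S = (3 cos^2 theta - 1)/2 exactly.
#' * `cone`: polar angle `theta`, azimuth uniform (free precession on a
#'   cone); S = (3 cos^2 theta - 1)/2 exactly.
#' * `uniform_isotropic`: directions uniform on the sphere; S = 0.
#'
#' @param mode `"fixed_angle"`, `"cone"` or `"uniform_isotropic"`.
#' @param theta polar angle in degrees (ignored for isotropic).
#' @param n_bonds number of C-H pairs per frame.
#' @param n_frames number of frames.
#' @param seed integer RNG seed.
#' @param bond_length C-H bond length, nm.
#' @param box box edge lengths, nm.
#' @return An `md_trajectory`; its `ground_truth` holds the analytic order
#'   parameter (`analytic_S`) and the bond table (`bonds`) for
#'   [compute_order_parameters()].
#' @export
gen_orientation_trajectory <- function(mode = c("fixed_angle", "cone",
                                                "uniform_isotropic"),
                                       theta = 0, n_bonds = 100,
                                       n_frames = 10, seed = 1,
                                       bond_length = 0.109,
                                       box = c(5, 5, 5)) {
  mode <- match.arg(mode)
  if (theta < 0 || theta > 180) abort("theta must be in [0, 180] degrees")
  if (n_bonds < 1 || n_frames < 1) abort("counts must be >= 1")
  th <- theta * pi / 180
  with_seed(seed, {
    carbons <- cbind(runif(n_bonds, 0, box[1]), runif(n_bonds, 0, box[2]),
                     runif(n_bonds, 0, box[3]))
    coords <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      dirs <- switch(mode,
        fixed_angle = matrix(c(sin(th), 0, cos(th)), n_bonds, 3, byrow = TRUE),
        cone = {
          phi <- runif(n_bonds, 0, 2 * pi)
          cbind(sin(th) * cos(phi), sin(th) * sin(phi),
                rep(cos(th), n_bonds))
        },
        uniform_isotropic = runif_sphere(n_bonds))
      xyz <- matrix(0, 2 * n_bonds, 3)
      xyz[seq(1, 2 * n_bonds, 2), ] <- carbons
      xyz[seq(2, 2 * n_bonds, 2), ] <- carbons + bond_length * dirs
      coords[[f]] <- xyz
    }
    cid <- seq(1, 2 * n_bonds, 2)
    hid <- seq(2, 2 * n_bonds, 2)
    top <- topology(tibble(
      atom_name = rep(c("C2", "H2"), n_bonds),
      element = rep(c("C", "H"), n_bonds),
      residue_name = "CHB",
      residue_id = rep(seq_len(n_bonds), each = 2),
      molecule_id = rep(seq_len(n_bonds), each = 2)))
    analytic_S <- if (mode == "uniform_isotropic") 0 else
      (3 * cos(th)^2 - 1) / 2
    trajectory(top, coords, box,
               ground_truth = list(
                 kind = "orientation", mode = mode, theta_deg = theta,
                 analytic_S = analytic_S,
                 bonds = tibble(label = "ch", carbon = cid, hydrogen = hid)))
  })
}

#' Generate a membrane slab system with two-state solute binding kinetics
#'
#' Builds a pseudo-lipid point-cloud slab occupying |z| < `slab_halfwidth`
#' (atoms labelled with phosphate-oxygen stand-ins O13/O14 plus a generic
#' carbon), rigid multi-atom solutes switching between a bound state
#' (cluster placed in contact with a randomly chosen lipid atom) and a free
#' state (uniform in the bulk water region) via a discrete-time two-state
#' Markov chain with switching probabilities 1 - exp(-k dt), and water
#' oxygens filling the bulk. No excluded volume is enforced.
#'
#' The realized per-frame bound flags are returned as ground truth, along
#' with the stationary bound fraction k_on / (k_on + k_off).
#'
#' @param n_lipids pseudo-lipids (3 atoms each).
#' @param n_solutes solute molecules.
#' @param solute_atoms heavy atoms per solute molecule.
#' @param box box edge lengths, nm.
#' @param slab_halfwidth membrane half-thickness, nm (< box_z / 2).
#' @param k_on,k_off binding/unbinding rates, 1/ns.
#' @param n_waters water oxygens in the bulk.
#' @param dt frame spacing, ns.
#' @param n_frames number of frames.
#' @param seed integer RNG seed.
#' @param bulk_margin gap between the slab edge and the free-solute region,
#'   nm; guarantees free solutes are never within contact range of lipids.
#' @return An `md_trajectory` with named selections `lipids`,
#'   `phosphate_oxygens`, `solutes`, `waters`; `ground_truth$bound` is the
#'   n_frames x n_solutes logical matrix of realized states.
#' @export
gen_membrane_system <- function(n_lipids = 200, n_solutes = 10,
                                solute_atoms = 5, box = c(6, 6, 12),
                                slab_halfwidth = 2, k_on = 1, k_off = 1,
                                n_waters = 100, dt = 0.1, n_frames = 100,
                                seed = 1, bulk_margin = 0.5) {
  if (k_on < 0 || k_off < 0) abort("rates must be >= 0")
  if (slab_halfwidth >= box[3] / 2) abort("slab_halfwidth must be < box_z/2")
  if (n_lipids < 1) abort("need at least one lipid")
  lipid_atoms_per <- 3L
  n_lip_atoms <- n_lipids * lipid_atoms_per
  n_sol_atoms <- n_solutes * solute_atoms
  with_seed(seed, {
    lip_xyz <- cbind(runif(n_lip_atoms, 0, box[1]),
                     runif(n_lip_atoms, 0, box[2]),
                     runif(n_lip_atoms, -slab_halfwidth, slab_halfwidth))
    # rigid solute geometries: offsets in a 0.12 nm sphere around the center
    offsets <- lapply(seq_len(n_solutes), function(i) {
      if (solute_atoms == 1) return(matrix(0, 1, 3))
      r <- 0.12 * runif(solute_atoms)^(1 / 3)
      r[1] <- 0
      runif_sphere(solute_atoms) * r
    })
    p_bind <- 1 - exp(-k_on * dt)
    p_unbind <- 1 - exp(-k_off * dt)
    pi_bound <- if (k_on + k_off > 0) k_on / (k_on + k_off) else 0
    bound <- matrix(FALSE, n_frames, n_solutes)
    if (n_solutes > 0) {
      state <- runif(n_solutes) < pi_bound
      for (f in seq_len(n_frames)) {
        if (f > 1) {
          flip <- runif(n_solutes)
          state <- ifelse(state, flip >= p_unbind, flip < p_bind)
        }
        bound[f, ] <- state
      }
    }
    z_free_lo <- slab_halfwidth + bulk_margin
    z_free_hi <- box[3] / 2 - 0.05
    if (z_free_lo >= z_free_hi) abort("no bulk region left for free solutes")
    coords <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      xyz <- matrix(0, n_lip_atoms + n_sol_atoms + n_waters, 3)
      xyz[seq_len(n_lip_atoms), ] <- lip_xyz
      if (n_solutes > 0) {
        for (m in seq_len(n_solutes)) {
          if (bound[f, m]) {
            host <- lip_xyz[sample.int(n_lip_atoms, 1), ]
            center <- host + 0.05 * runif_sphere(1)[1, ] * runif(1)
          } else {
            side <- sample(c(-1, 1), 1)
            center <- c(runif(1, 0, box[1]), runif(1, 0, box[2]),
                        side * runif(1, z_free_lo, z_free_hi))
          }
          rows <- n_lip_atoms + (m - 1) * solute_atoms + seq_len(solute_atoms)
          xyz[rows, ] <- sweep(offsets[[m]], 2, center, "+")
        }
      }
      if (n_waters > 0) {
        wz <- sample(c(-1, 1), n_waters, TRUE) *
          runif(n_waters, slab_halfwidth + 0.1, box[3] / 2)
        rows <- n_lip_atoms + n_sol_atoms + seq_len(n_waters)
        xyz[rows, ] <- cbind(runif(n_waters, 0, box[1]),
                             runif(n_waters, 0, box[2]), wz)
      }
      coords[[f]] <- xyz
    }
    lip_names <- rep(c("O13", "O14", "C1"), n_lipids)
    top <- topology(
      tibble(
        atom_name = c(lip_names,
                      rep(paste0("C", seq_len(max(1, solute_atoms))),
                          n_solutes)[seq_len(n_sol_atoms)],
                      rep("OW", n_waters)),
        element = c(rep(c("O", "O", "C"), n_lipids),
                    rep("C", n_sol_atoms), rep("O", n_waters)),
        residue_name = c(rep("LIP", n_lip_atoms), rep("ETI", n_sol_atoms),
                         rep("SOL", n_waters)),
        residue_id = c(rep(seq_len(n_lipids), each = lipid_atoms_per),
                       rep(n_lipids + seq_len(max(0, n_solutes)),
                           each = solute_atoms)[seq_len(n_sol_atoms)],
                       n_lipids + n_solutes + seq_len(n_waters)),
        molecule_id = c(rep(seq_len(n_lipids), each = lipid_atoms_per),
                        rep(n_lipids + seq_len(max(0, n_solutes)),
                            each = solute_atoms)[seq_len(n_sol_atoms)],
                        n_lipids + n_solutes + seq_len(n_waters))),
      selections = list(
        lipids = seq_len(n_lip_atoms),
        phosphate_oxygens = which(lip_names %in% c("O11", "O12", "O13", "O14")),
        solutes = n_lip_atoms + seq_len(n_sol_atoms),
        waters = n_lip_atoms + n_sol_atoms + seq_len(n_waters)))
    trajectory(top, coords, box, times = (seq_len(n_frames) - 1) * dt * 1000,
               ground_truth = list(
                 kind = "membrane", bound = bound,
                 stationary_bound_fraction = pi_bound,
                 n_lipids = n_lipids, n_solutes = n_solutes,
                 n_waters = n_waters, slab_halfwidth = slab_halfwidth,
                 bulk_margin = bulk_margin, k_on = k_on, k_off = k_off,
                 dt = dt))
  })
}

#' Generate particles sampled from a prescribed density profile
#'
#' Particle z coordinates are i.i.d. draws from the normalized target
#' profile (via inverse-CDF sampling on a fine grid); x and y are uniform
#' in the box cross-section.
#'
#' @param density_fn vectorized non-negative function of z (relative
#'   density, need not be normalized).
#' @param z_range length-2 numeric, the support to sample (nm); also sets
#'   the box height.
#' @param n_particles particles per frame.
#' @param n_frames number of frames.
#' @param seed integer RNG seed.
#' @param box_xy cross-section edge length, nm.
#' @return An `md_trajectory` of single-atom particles (selection
#'   `particles`); ground truth records the normalized profile on the
#'   sampling grid.
#' @export
gen_density_system <- function(density_fn, z_range = c(-5, 5),
                               n_particles = 1000, n_frames = 10, seed = 1,
                               box_xy = 4) {
  zg <- seq(z_range[1], z_range[2], length.out = 4001)
  fz <- density_fn(zg)
  if (any(!is.finite(fz)) || any(fz < 0)) {
    abort("density_fn must be finite and non-negative on z_range")
  }
  dz <- zg[2] - zg[1]
  cdf <- cumsum(c(0, (fz[-1] + fz[-length(fz)]) / 2 * dz))
  if (!is.finite(cdf[length(cdf)]) || cdf[length(cdf)] <= 0) {
    abort("density_fn does not integrate to a finite positive value")
  }
  cdf <- cdf / cdf[length(cdf)]
  box <- c(box_xy, box_xy, diff(z_range))
  with_seed(seed, {
    coords <- lapply(seq_len(n_frames), function(f) {
      u <- runif(n_particles)
      z <- approx(cdf, zg, xout = u, ties = "ordered")$y
      cbind(runif(n_particles, 0, box_xy), runif(n_particles, 0, box_xy), z)
    })
    top <- topology(
      tibble(atom_name = "P1", element = "P", residue_name = "PRT",
             residue_id = seq_len(n_particles),
             molecule_id = seq_len(n_particles)),
      selections = list(particles = seq_len(n_particles)))
    trajectory(top, coords, box,
               ground_truth = list(kind = "density", z_grid = zg,
                                   target_density = fz / max(fz)))
  })
}

#' Generate a scripted permeation trajectory
#'
#' Marker atoms follow linear interpolation between scripted (time, z)
#' waypoints, sampled every `dt`; z is wrapped into the primary box centered
#' at 0 so scripts may describe unwrapped paths.
#'
#' @param script a data frame with columns `marker` (integer id), `time`
#'   (ns, strictly increasing per marker) and `z` (nm, unwrapped).
#' @param dt sampling interval, ns.
#' @param box_z box height, nm.
#' @param box_xy cross-section edge, nm.
#' @return An `md_trajectory` of marker atoms (selection `markers`), one
#'   per distinct `marker`; ground truth stores the script.
#' @export
gen_permeation_trajectory <- function(script, dt = 0.1, box_z = 10,
                                      box_xy = 4) {
  script <- as_tibble(script)
  if (!all(c("marker", "time", "z") %in% names(script))) {
    abort("script needs columns marker, time, z")
  }
  bad <- script |>
    dplyr::group_by(.data$marker) |>
    dplyr::summarise(ok = !is.unsorted(.data$time, strictly = TRUE))
  if (!all(bad$ok)) abort("waypoint times must be strictly increasing per marker")
  markers <- sort(unique(script$marker))
  times <- seq(min(script$time), max(script$time), by = dt)
  zmat <- vapply(markers, function(m) {
    wp <- script[script$marker == m, ]
    approx(wp$time, wp$z, xout = times, rule = 2)$y
  }, numeric(length(times)))
  zmat <- matrix(zmat, nrow = length(times))
  box <- c(box_xy, box_xy, box_z)
  coords <- lapply(seq_along(times), function(i) {
    cbind(seq_along(markers) * box_xy / (length(markers) + 1),
          box_xy / 2,
          wrap_centered(zmat[i, ], box_z))
  })
  top <- topology(
    tibble(atom_name = "N14", element = "N", residue_name = "MRK",
           residue_id = seq_along(markers),
           molecule_id = seq_along(markers)),
    selections = list(markers = seq_along(markers)))
  trajectory(top, coords, box, times = times * 1000,
             ground_truth = list(kind = "permeation",
                                 script = as.data.frame(script),
                                 marker_ids = markers))
}
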