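#' Number-density profile along the membrane normal
#'
#' For every frame in range, coordinates are centered on the reference
#' group (by default the lipid center of mass) and the z positions of the
#' selected atoms accumulated into a histogram with bin edges anchored at
#' integer multiples of `bin_width` (so leaflet symmetrization is exact).
#' Counts are normalized to a time-averaged number density by
#' frames x bin volume, with bin volume = bin_width x <box_x * box_y>.
#'
#' @param traj an `md_trajectory`.
#' @param selection integer atom ids to histogram.
#' @param bin_width nm; the default 1/30 nm is 1/3 Angstrom.
#' @param center_selection atom ids of the centering reference (`NULL` to
#'   skip centering, e.g. for pre-centered synthetic systems).
#' @param frame_range frames to analyze (`NULL` = all).
#' @param selection_label label carried into the result.
#' @return Tibble of class `density_profile` with columns z (bin centers,
#'   nm) and density (nm^-3); attributes bin_width, n_frames, n_atoms,
#'   area, selection_label.
#' @export
density_profile <- function(traj, selection, bin_width = 1 / 30,
                            center_selection = NULL, frame_range = NULL,
                            selection_label = "selection") {
  validate_trajectory(traj)
  if (length(selection) == 0) abort("selection is empty")
  if (!is.finite(bin_width) || bin_width <= 0) abort("bin_width must be > 0")
  frames <- resolve_frames(traj, frame_range)
  if (!is.null(center_selection)) {
    sub <- traj
    sub$coords <- traj$coords[frames]
    sub$box <- traj$box[frames, , drop = FALSE]
    sub$times <- traj$times[frames]
    traj <- center_coordinates(sub, center_selection, axis = "z")
    frames <- seq_along(traj$coords)
  }
  half_span <- max(traj$box[frames, 3]) / 2
  n_half <- ceiling(half_span / bin_width)
  edges <- seq(-n_half, n_half) * bin_width
  counts <- numeric(length(edges) - 1)
  for (f in frames) {
    z <- wrap_centered(traj$coords[[f]][selection, 3], traj$box[f, 3])
    idx <- pmin(pmax(floor(z / bin_width) + n_half + 1, 1), length(counts))
    tab <- tabulate(idx, nbins = length(counts))
    counts <- counts + tab
  }
  area <- mean(traj$box[frames, 1] * traj$box[frames, 2])
  density <- counts / (length(frames) * bin_width * area)
  out <- tibble(z = (edges[-1] + edges[-length(edges)]) / 2,
                density = density)
  attr(out, "bin_width") <- bin_width
  attr(out, "n_frames") <- length(frames)
  attr(out, "n_atoms") <- length(selection)
  attr(out, "area") <- area
  attr(out, "selection_label") <- selection_label
  class(out) <- c("density_profile", class(out))
  out
}

#' Construct a density profile from values
#'
#' Mainly for tests and for re-loading serialized profiles.
#'
#' @param z bin centers (uniform grid), nm.
#' @param density number densities, nm^-3.
#' @param area box cross-section, nm^2.
#' @param n_frames frames represented.
#' @param selection_label label.
#' @return A `density_profile`.
#' @export
new_density_profile <- function(z, density, area = 1, n_frames = 1,
                                selection_label = "manual") {
  if (any(density < 0)) abort("density must be >= 0")
  w <- unique(round(diff(z), 12))
  if (length(w) != 1) abort("bin centers must form a uniform grid")
  out <- tibble(z = z, density = density)
  attr(out, "bin_width") <- w
  attr(out, "n_frames") <- n_frames
  attr(out, "n_atoms") <- NA_integer_
  attr(out, "area") <- area
  attr(out, "selection_label") <- selection_label
  class(out) <- c("density_profile", class(out))
  out
}

#' Potential of mean force by Boltzmann inversion
#'
#' PMF(z) = -kB T ln(rho(z) / rho_ref). The reference density rho_ref is
#' the geometric mean of the positive densities inside `reference_region`,
#' which makes the PMF average exactly zero over the sampled reference
#' bins. Bins with zero density have an undefined PMF and are reported as
#' `NA`, never +/-Inf.
#'
#' @param profile a `density_profile`.
#' @param temperature K.
#' @param reference_region length-2 z interval (nm) taken as the free-energy
#'   zero; default `NULL` uses the outermost 20% of sampled z on each side
#'   (bulk water).
#' @return Tibble of class `pmf_profile` with columns z, pmf (kJ/mol, `NA`
#'   where undefined); attributes temperature, reference_region, rho_ref.
#' @export
pmf_from_density <- function(profile, temperature = 298,
                             reference_region = NULL) {
  stopifnot(inherits(profile, "density_profile"))
  sampled <- profile$z[profile$density > 0]
  if (length(sampled) == 0) abort("profile has no sampled bins")
  if (is.null(reference_region)) {
    lo <- range(sampled)
    w <- diff(lo) * 0.2
    ref_bins <- (profile$z <= lo[1] + w | profile$z >= lo[2] - w) &
      profile$density > 0
  } else {
    if (length(reference_region) != 2 ||
        reference_region[1] >= reference_region[2]) {
      abort("reference_region must be an increasing z interval")
    }
    ref_bins <- profile$z >= reference_region[1] &
      profile$z <= reference_region[2] & profile$density > 0
  }
  if (!any(ref_bins)) abort("no sampled density inside the reference region")
  rho_ref <- exp(mean(log(profile$density[ref_bins])))
  pmf <- ifelse(profile$density > 0,
                -.kB * temperature * log(profile$density / rho_ref),
                NA_real_)
  out <- tibble(z = profile$z, pmf = pmf)
  attr(out, "temperature") <- temperature
  attr(out, "reference_region") <- if (is.null(reference_region)) {
    range(profile$z[ref_bins])
  } else reference_region
  attr(out, "rho_ref") <- rho_ref
  class(out) <- c("pmf_profile", class(out))
  out
}

#' Leaflet-symmetrize a density profile
#'
#' Averages density(z) with density(-z) on a symmetric grid. Because bin
#' edges are anchored at integer multiples of the bin width, bins pair
#' exactly.
#'
#' @param profile a `density_profile`.
#' @return A symmetrized `density_profile`.
#' @export
symmetrize_profile <- function(profile) {
  stopifnot(inherits(profile, "density_profile"))
  w <- attr(profile, "bin_width")
  n_half <- max(round(abs(profile$z) / w - 0.5)) + 1
  centers <- (seq(-n_half, n_half - 1) + 0.5) * w
  lookup <- function(z) {
    i <- match(round(z / w - 0.5), round(profile$z / w - 0.5))
    ifelse(is.na(i), 0, profile$density[i])
  }
  dens <- (lookup(centers) + lookup(-centers)) / 2
  out <- tibble(z = centers, density = dens)
  for (a in c("bin_width", "n_frames", "n_atoms", "area", "selection_label")) {
    attr(out, a) <- attr(profile, a)
  }
  class(out) <- c("density_profile", class(out))
  out
}

#' Estimate the membrane half-width from the lipid density
#'
#' Computes the symmetrized lipid number-density profile and returns the
#' outermost |z| at which it falls to 50% of its plateau (maximum) value,
#' by linear interpolation between bins.
#'
#' @param traj an `md_trajectory`.
#' @param lipid_selection lipid atom ids (default: the `lipids` named
#'   selection).
#' @param frame_range frames to analyze.
#' @param bin_width histogram bin width, nm.
#' @return Half-width in nm.
#' @export
estimate_membrane_halfwidth <- function(traj, lipid_selection = NULL,
                                        frame_range = NULL,
                                        bin_width = 0.1) {
  if (is.null(lipid_selection)) {
    lipid_selection <- attr(traj$topology, "selections")$lipids
  }
  if (is.null(lipid_selection)) abort("no lipid selection available")
  prof <- density_profile(traj, lipid_selection, bin_width = bin_width,
                          center_selection = lipid_selection,
                          frame_range = frame_range,
                          selection_label = "lipids")
  prof <- symmetrize_profile(prof)
  plateau <- max(prof$density)
  half <- plateau / 2
  pos <- prof[prof$z >= 0, ]
  below <- which(pos$density < half)
  above <- which(pos$density >= half)
  if (length(above) == 0 || length(below) == 0) return(max(abs(prof$z)))
  i <- max(above)
  if (i == nrow(pos)) return(pos$z[i])
  # interpolate between the last bin above half and the next below
  z1 <- pos$z[i]; z2 <- pos$z[i + 1]
  d1 <- pos$density[i]; d2 <- pos$density[i + 1]
  z1 + (half - d1) / (d2 - d1) * (z2 - z1)
}
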