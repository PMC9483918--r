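#' Membrane-binding criterion
#'
#' A solute molecule is declared membrane-bound when at least a fraction
#' `bound_fraction` of its heavy atoms lie within `distance_cutoff`
#' (minimum image, inclusive) of any lipid atom.
#'
#' @param distance_cutoff nm, > 0.
#' @param bound_fraction in (0, 1].
#' @param degenerate internal flag set by [select_criterion()] when the
#'   criterion surface was degenerate.
#' @return A list of class `binding_criterion`.
#' @export
binding_criterion <- function(distance_cutoff, bound_fraction,
                              degenerate = FALSE) {
  if (!is.finite(distance_cutoff) || distance_cutoff <= 0) {
    abort("distance_cutoff must be > 0")
  }
  if (!is.finite(bound_fraction) || bound_fraction <= 0 || bound_fraction > 1) {
    abort("bound_fraction must be in (0, 1]")
  }
  structure(list(distance_cutoff = distance_cutoff,
                 bound_fraction = bound_fraction, degenerate = degenerate),
            class = "binding_criterion")
}

#' @export
print.binding_criterion <- function(x, ...) {
  cat(sprintf("<binding_criterion: d <= %.3g nm, fraction >= %.3g%s>\n",
              x$distance_cutoff, x$bound_fraction,
              if (isTRUE(x$degenerate)) ", degenerate surface" else ""))
  invisible(x)
}

# Per-frame nearest-lipid distance of each heavy solute atom, plus the
# molecule index of each atom. Returns list(dist, mol, n_heavy_per_mol).
solute_lipid_distances <- function(traj, frame, solutes, lipids, rmax) {
  xyz <- traj$coords[[frame]]
  box <- traj$box[frame, ]
  heavy <- lapply(solutes, function(ids) {
    ids[traj$topology$element[match(ids, traj$topology$atom_id)] != "H"]
  })
  n_heavy <- lengths(heavy)
  if (any(n_heavy == 0)) abort("solute molecule with zero heavy atoms")
  atoms <- unlist(heavy, use.names = FALSE)
  d <- pbc_nearest_dist(xyz[atoms, , drop = FALSE],
                        xyz[lipids, , drop = FALSE], box, rmax = rmax)
  list(dist = d, mol = rep(seq_along(heavy), n_heavy), n_heavy = n_heavy)
}

#' Assign bound/unbound state to solute molecules in one frame
#'
#' @param traj an `md_trajectory`.
#' @param frame frame index.
#' @param solutes list of integer atom-id vectors, one per solute molecule
#'   (see [molecule_groups()]); hydrogens are ignored.
#' @param lipids integer atom ids of all lipid atoms.
#' @param criterion a [binding_criterion()].
#' @return Logical vector, one entry per solute molecule.
#' @export
assign_bound <- function(traj, frame, solutes, lipids, criterion) {
  validate_trajectory(traj)
  if (length(lipids) == 0) abort("lipid selection is empty")
  if (length(solutes) == 0) return(logical(0))
  sd <- solute_lipid_distances(traj, frame, solutes, lipids,
                               rmax = criterion$distance_cutoff)
  within <- sd$dist <= criterion$distance_cutoff
  frac <- tapply(within, sd$mol, mean)
  as.vector(frac >= criterion$bound_fraction)
}

#' Bound-molecule count time series
#'
#' Applies [assign_bound()] to every frame in range and records the counts
#' with frame times.
#'
#' @inheritParams assign_bound
#' @param frame_range frames to analyze (`NULL` = all).
#' @param n_lipids,n_waters system composition recorded for the
#'   normalizations ([bound_per_lipid()], [bulk_concentration()]); by
#'   default counted from the topology's `lipids`/`waters` named selections
#'   (molecules, not atoms).
#' @return Tibble of class `bound_series` with columns time (ps), n_bound;
#'   attributes n_total_solutes, n_lipids, n_waters.
#' @export
bound_timeseries <- function(traj, solutes, lipids, criterion,
                             frame_range = NULL, n_lipids = NULL,
                             n_waters = NULL) {
  frames <- resolve_frames(traj, frame_range)
  n_bound <- vapply(frames, function(f) {
    sum(assign_bound(traj, f, solutes, lipids, criterion))
  }, integer(1))
  sel <- attr(traj$topology, "selections")
  count_mols <- function(ids) {
    if (is.null(ids)) return(NA_integer_)
    length(unique(traj$topology$molecule_id[match(ids, traj$topology$atom_id)]))
  }
  if (is.null(n_lipids)) n_lipids <- count_mols(sel$lipids)
  if (is.null(n_waters)) n_waters <- count_mols(sel$waters)
  out <- tibble(time = traj$times[frames], n_bound = n_bound)
  attr(out, "n_total_solutes") <- length(solutes)
  attr(out, "n_lipids") <- n_lipids
  attr(out, "n_waters") <- n_waters
  attr(out, "criterion") <- criterion
  class(out) <- c("bound_series", class(out))
  out
}

#' Scan the bound count over a grid of binding criteria
#'
#' Computes the time-averaged number of bound molecules at every node of a
#' (distance cutoff, bound fraction) grid. The surface is non-decreasing in
#' the cutoff and non-increasing in the fraction by construction; both are
#' asserted.
#'
#' @inheritParams bound_timeseries
#' @param distance_grid increasing cutoffs, nm (>= 3 values, all > 0).
#' @param fraction_grid increasing fractions in (0, 1] (>= 3 values).
#' @return A list of class `criterion_surface` with elements distance_grid,
#'   fraction_grid and n_bound_mean (distance x fraction matrix).
#' @export
criterion_scan <- function(traj, solutes, lipids,
                           distance_grid = seq(0.1, 1, by = 0.1),
                           fraction_grid = seq(0.1, 1, by = 0.1),
                           frame_range = NULL) {
  if (length(distance_grid) < 3 || length(fraction_grid) < 3) {
    abort("criterion grids need at least 3 points each")
  }
  if (any(distance_grid <= 0)) abort("distance cutoffs must be > 0")
  if (any(fraction_grid <= 0 | fraction_grid > 1)) {
    abort("fractions must be in (0, 1]")
  }
  distance_grid <- sort(distance_grid)
  fraction_grid <- sort(fraction_grid)
  frames <- resolve_frames(traj, frame_range)
  acc <- matrix(0, length(distance_grid), length(fraction_grid))
  rmax <- max(distance_grid)
  for (f in frames) {
    sd <- solute_lipid_distances(traj, f, solutes, lipids, rmax = rmax)
    for (i in seq_along(distance_grid)) {
      within <- sd$dist <= distance_grid[i]
      frac <- tapply(within, sd$mol, mean)
      # counts bound molecules at every fraction threshold at once
      acc[i, ] <- acc[i, ] + vapply(fraction_grid,
                                    function(fr) sum(frac >= fr), numeric(1))
    }
  }
  surface <- structure(
    list(distance_grid = distance_grid, fraction_grid = fraction_grid,
         n_bound_mean = acc / length(frames)),
    class = "criterion_surface")
  stopifnot(all(diff_nonneg(surface$n_bound_mean, 1)),
            all(diff_nonneg(-surface$n_bound_mean, 2)))
  surface
}

diff_nonneg <- function(m, margin) {
  d <- if (margin == 1) diff(m) else t(diff(t(m)))
  length(d) == 0 || all(d >= -1e-12)
}

#' Long tidy view of a criterion surface
#' @param x a `criterion_surface`.
#' @param ... unused.
#' @method as_tibble criterion_surface
#' @export
as_tibble.criterion_surface <- function(x, ...) {
  tidyr::expand_grid(distance_cutoff = x$distance_grid,
                     bound_fraction = x$fraction_grid) |>
    dplyr::mutate(n_bound_mean = as.vector(t(x$n_bound_mean)))
}

#' Select the binding criterion at the point of weakest dependence
#'
#' Finds the grid node where the magnitude of the finite-difference
#' gradient of the time-averaged bound count is minimal (the "minimum of
#' the gradient" rule); both axes are normalized by their grid span so
#' distance and fraction are commensurate. Central differences are used in
#' the interior, one-sided at the edges. Ties are broken by smallest
#' cutoff, then largest fraction. A surface whose gradient magnitude is
#' constant yields the tie-break node with `degenerate = TRUE`
#' and a warning.
#'
#' @param surface a `criterion_surface`.
#' @return A [binding_criterion()].
#' @export
select_criterion <- function(surface) {
  stopifnot(inherits(surface, "criterion_surface"))
  m <- surface$n_bound_mean
  u <- (surface$distance_grid - min(surface$distance_grid)) /
    diff(range(surface$distance_grid))
  v <- (surface$fraction_grid - min(surface$fraction_grid)) /
    diff(range(surface$fraction_grid))
  gu <- apply(m, 2, function(col) num_gradient(col, u))
  gv <- t(apply(m, 1, function(row) num_gradient(row, v)))
  g <- sqrt(gu^2 + gv^2)
  gmin <- min(g)
  tol <- 1e-12 * max(1, max(abs(m)))
  cand <- which(g <= gmin + tol, arr.ind = TRUE)
  # smallest cutoff first, then largest fraction
  ord <- order(cand[, 1], -cand[, 2])
  pick <- cand[ord[1], ]
  degenerate <- nrow(cand) == length(g)
  if (degenerate) {
    warn("criterion surface is degenerate (constant gradient); tie-break node returned")
  }
  binding_criterion(surface$distance_grid[pick[1]],
                    surface$fraction_grid[pick[2]],
                    degenerate = degenerate)
}

# gradient of y sampled at x (central in the interior, one-sided at ends)
num_gradient <- function(y, x) {
  n <- length(y)
  g <- numeric(n)
  g[1] <- (y[2] - y[1]) / (x[2] - x[1])
  g[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    g[i] <- (y[i + 1] - y[i - 1]) / (x[i + 1] - x[i - 1])
  }
  g
}

#' Detect the end of equilibration in a bound-count series
#'
#' Returns the smallest index t* such that the means of the two halves of
#' the series after t* differ by less than twice their pooled block
#' standard error; the series is declared unconverged if no such index
#' exists before 50% of its length.
#'
#' @param series a `bound_series` (or any data frame with an `n_bound`
#'   column).
#' @param n_blocks blocks per half for the pooled standard error.
#' @return A list with `equilibration_end_index` (0-based offset into the
#'   series: 0 means equilibrated from the start) and `converged`.
#' @export
equilibration_split <- function(series, n_blocks = 5) {
  x <- series$n_bound
  n <- length(x)
  if (n < 10) abort("series too short (need >= 10 points)")
  block_se <- function(v) {
    nb <- min(n_blocks, length(v))
    bm <- tapply(v, ceiling(seq_along(v) / (length(v) / nb)), mean)
    sd(bm) / sqrt(length(bm))
  }
  for (t_star in 0:floor(n / 2 - 1)) {
    rest <- x[(t_star + 1):n]
    half <- floor(length(rest) / 2)
    a <- rest[seq_len(half)]
    b <- rest[(half + 1):length(rest)]
    pooled <- sqrt(block_se(a)^2 + block_se(b)^2)
    if (is.finite(pooled) && abs(mean(a) - mean(b)) < 2 * pooled) {
      return(list(equilibration_end_index = t_star, converged = TRUE))
    }
  }
  list(equilibration_end_index = NA_integer_, converged = FALSE)
}

#' Time-averaged bound molecules per lipid
#'
#' @param series a `bound_series`.
#' @param frame_range optional subset of rows (indices into the series).
#' @return Dimensionless ratio.
#' @export
bound_per_lipid <- function(series, frame_range = NULL) {
  rows <- if (is.null(frame_range)) seq_len(nrow(series)) else frame_range
  n_lipids <- attr(series, "n_lipids")
  if (is.null(n_lipids) || is.na(n_lipids) || n_lipids <= 0) {
    abort("series lacks a positive n_lipids")
  }
  mean(series$n_bound[rows]) / n_lipids
}

#' Bulk solute concentration with respect to water
#'
#' c = <n_total - n_bound> / n_waters x 55,500 mM, the pure-water molarity
#' convention.
#'
#' @inheritParams bound_per_lipid
#' @return Concentration in mM.
#' @export
bulk_concentration <- function(series, frame_range = NULL) {
  rows <- if (is.null(frame_range)) seq_len(nrow(series)) else frame_range
  n_waters <- attr(series, "n_waters")
  n_total <- attr(series, "n_total_solutes")
  if (is.null(n_waters) || is.na(n_waters) || n_waters <= 0) {
    abort("series lacks a positive n_waters")
  }
  mean(n_total - series$n_bound[rows]) / n_waters * .WATER_MOLARITY_MM
}
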