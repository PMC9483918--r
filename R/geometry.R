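#' Minimum-image distance under orthorhombic periodicity
#'
#' @param a,b numeric 3-vectors (nm), or matrices with 3 columns for
#'   row-wise distances.
#' @param box numeric 3-vector of orthorhombic box edge lengths (nm).
#' @return Euclidean distance(s) between the nearest periodic images.
#' @export
minimum_image_distance <- function(a, b, box) {
  box <- as.numeric(box)
  if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0)) {
    abort("box must be 3 positive finite edge lengths")
  }
  a <- rbind(a); b <- rbind(b)
  if (any(!is.finite(a)) || any(!is.finite(b))) abort("coordinates must be finite")
  d <- a - b
  d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
  unname(sqrt(rowSums(d^2)))
}

# Wrap coordinates into the primary box centered at 0: [-L/2, L/2).
wrap_centered <- function(x, box) {
  x - box * floor(x / box + 0.5)
}

# Minimum-image difference along one axis.
min_image_diff <- function(dx, box_l) {
  dx - box_l * round(dx / box_l)
}

# Periodic cell-grid neighbor search.
#
# For each query point, computes counts of reference points within `cutoff`
# (strict or inclusive) and/or the distance to the nearest reference point.
# Cells have edge >= cutoff (capped at the box size); distances are always
# minimum-image, so the grid only prunes and cannot change results.
#
# query, ref: matrices n x 3 (nm); box: 3-vector.
# Returns list(count = integer n, nearest = numeric n (Inf if none within
# the searched shell when the grid prunes; exact when n_cells <= 3)).
pbc_neighbor_search <- function(query, ref, box, cutoff, strict = TRUE,
                                want_nearest = FALSE) {
  nq <- nrow(query)
  count <- integer(nq)
  nearest <- rep(Inf, nq)
  if (nrow(ref) == 0 || nq == 0) {
    return(list(count = count, nearest = nearest))
  }
  ncell <- pmax(1L, pmin(64L, as.integer(floor(box / cutoff))))
  cell_of <- function(xyz) {
    ix <- floor(xyz[, 1] / box[1] * ncell[1]) %% ncell[1]
    iy <- floor(xyz[, 2] / box[2] * ncell[2]) %% ncell[2]
    iz <- floor(xyz[, 3] / box[3] * ncell[3]) %% ncell[3]
    as.integer(ix + ncell[1] * (iy + ncell[2] * iz))
  }
  qcell <- cell_of(query)
  rcell <- cell_of(ref)
  ref_by_cell <- split(seq_len(nrow(ref)), rcell)
  # neighbor cell offsets, deduplicated for tiny grids
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  for (qc in unique(qcell)) {
    qi <- which(qcell == qc)
    cx <- qc %% ncell[1]
    cy <- (qc %/% ncell[1]) %% ncell[2]
    cz <- qc %/% (ncell[1] * ncell[2])
    ncx <- (cx + offs[, 1]) %% ncell[1]
    ncy <- (cy + offs[, 2]) %% ncell[2]
    ncz <- (cz + offs[, 3]) %% ncell[3]
    ncells <- unique(as.integer(ncx + ncell[1] * (ncy + ncell[2] * ncz)))
    ri <- unlist(ref_by_cell[as.character(ncells)], use.names = FALSE)
    if (is.null(ri) || length(ri) == 0) next
    d2 <- matrix(0, length(qi), length(ri))
    for (ax in 1:3) {
      dd <- outer(query[qi, ax], ref[ri, ax], "-")
      dd <- dd - box[ax] * round(dd / box[ax])
      d2 <- d2 + dd * dd
    }
    d <- sqrt(d2)
    count[qi] <- if (strict) rowSums(d < cutoff) else rowSums(d <= cutoff)
    if (want_nearest) nearest[qi] <- apply(d, 1, min)
  }
  list(count = count, nearest = nearest)
}

# Distance from each query point to the nearest reference point, exact up to
# rmax (beyond rmax the value may be Inf).
pbc_nearest_dist <- function(query, ref, box, rmax) {
  pbc_neighbor_search(query, ref, box, cutoff = rmax, strict = FALSE,
                      want_nearest = TRUE)$nearest
}

# Unwrap a group of coordinates along all axes around a periodic anchor
# (circular mean), then return the mass-weighted arithmetic center.
# Valid for groups that are contiguous within half a box edge of the anchor
# in the unwrapped configuration (e.g. a bilayer slab split by wrapping).
pbc_group_center <- function(xyz, box, mass) {
  tot <- sum(mass)
  if (tot <= 0) abort("zero total mass in reference group")
  com <- numeric(3)
  for (ax in 1:3) {
    theta <- 2 * pi * xyz[, ax] / box[ax]
    anchor <- atan2(sum(mass * sin(theta)), sum(mass * cos(theta))) *
      box[ax] / (2 * pi)
    unwrapped <- anchor + min_image_diff(xyz[, ax] - anchor, box[ax])
    com[ax] <- sum(mass * unwrapped) / tot
  }
  com
}

#' Center trajectory coordinates on a reference group
#'
#' Shifts every frame so that the mass-weighted center of the reference
#' group lies at coordinate 0 along the chosen axis, then wraps all atoms
#' into the primary box centered at the origin. The reference group is
#' unwrapped across periodic boundaries before its center of mass is
#' computed, so a bilayer split by wrapping is handled correctly. Other
#' axes are untouched (beyond wrapping).
#'
#' @param traj an `md_trajectory`.
#' @param reference integer atom ids of the reference group (e.g. all lipid
#'   atoms).
#' @param axis `"x"`, `"y"` or `"z"` (default; the membrane normal).
#' @return The centered trajectory.
#' @export
center_coordinates <- function(traj, reference, axis = "z") {
  validate_trajectory(traj)
  ax <- match(match.arg(axis, c("x", "y", "z")), c("x", "y", "z"))
  if (length(reference) == 0) abort("reference selection is empty")
  mass <- traj$topology$mass[match(reference, traj$topology$atom_id)]
  for (i in seq_along(traj$coords)) {
    xyz <- traj$coords[[i]]
    box <- traj$box[i, ]
    com <- pbc_group_center(xyz[reference, , drop = FALSE], box, mass)
    xyz[, ax] <- xyz[, ax] - com[ax]
    for (a in 1:3) xyz[, a] <- wrap_centered(xyz[, a], box[a])
    traj$coords[[i]] <- xyz
  }
  traj
}
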