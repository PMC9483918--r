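#' Define a set of labelled C-H bonds
#'
#' @param label segment label (e.g. `"alpha"`, `"beta"`).
#' @param carbon,hydrogen integer atom ids, pairwise.
#' @return Tibble with columns label, carbon, hydrogen.
#' @export
ch_bond_set <- function(label, carbon, hydrogen) {
  if (length(carbon) == 0 || length(carbon) != length(hydrogen)) {
    abort("carbon and hydrogen id vectors must be non-empty and equal length")
  }
  if (anyDuplicated(hydrogen)) {
    abort("a hydrogen may appear in at most one C-H pair")
  }
  tibble(label = label, carbon = as.integer(carbon),
         hydrogen = as.integer(hydrogen))
}

#' Build C-H bond definitions from atom names
#'
#' Pairs carbons and hydrogens within each residue of a given residue name,
#' in the order given, yielding one labelled bond set.
#'
#' @param topology an `md_topology`.
#' @param label segment label.
#' @param residue_name residue to search.
#' @param carbon_name carbon atom name.
#' @param hydrogen_names one or more hydrogen atom names attached to that
#'   carbon.
#' @return Tibble as from [ch_bond_set()].
#' @export
ch_bonds_from_names <- function(topology, label, residue_name, carbon_name,
                                hydrogen_names) {
  rows <- topology[topology$residue_name == residue_name, ]
  out <- purrr::map_dfr(split(rows, rows$residue_id), function(res) {
    cid <- res$atom_id[res$atom_name == carbon_name]
    if (length(cid) != 1) return(NULL)
    hid <- res$atom_id[match(hydrogen_names, res$atom_name)]
    hid <- hid[!is.na(hid)]
    if (length(hid) == 0) return(NULL)
    tibble(label = label, carbon = cid, hydrogen = hid)
  })
  if (nrow(out) == 0) abort("no matching C-H pairs found")
  out
}

#' Compute C-H bond order parameters
#'
#' For each bond label, computes S_CH = < (3 cos^2 theta - 1) / 2 > where
#' theta is the angle between the C-H bond vector and the membrane normal
#' (the z axis), averaged over all frames in range, all molecules and all
#' equivalent hydrogens sharing the label. The uncertainty is estimated by
#' block averaging over `n_blocks` equal time blocks:
#' stderr = sd(block means) / sqrt(n_blocks).
#'
#' Note the ensemble average uses cos^2 theta — the second Legendre
#' polynomial — which is the standard NMR order-parameter definition and
#' bounds S to [-0.5, 1].
#'
#' @param traj an `md_trajectory`.
#' @param bonds tibble with columns label, carbon, hydrogen (see
#'   [ch_bond_set()]).
#' @param frame_range frame indices (vector or length-2 inclusive range);
#'   `NULL` for all frames.
#' @param n_blocks time blocks for the stderr estimate.
#' @param per_hydrogen if `TRUE`, return one row per (label, hydrogen
#'   position) instead of pooling equivalent hydrogens.
#' @return Tibble of class `order_parameter_result` with columns label, S,
#'   stderr, n_samples.
#' @export
compute_order_parameters <- function(traj, bonds, frame_range = NULL,
                                     n_blocks = 5, per_hydrogen = FALSE) {
  validate_trajectory(traj)
  bonds <- as_tibble(bonds)
  if (nrow(bonds) == 0) abort("bond set is empty")
  if (!all(c("label", "carbon", "hydrogen") %in% names(bonds))) {
    abort("bonds needs columns label, carbon, hydrogen")
  }
  ok <- bonds$carbon %in% traj$topology$atom_id &
    bonds$hydrogen %in% traj$topology$atom_id
  if (!all(ok)) abort("bond atom ids not present in topology")
  frames <- resolve_frames(traj, frame_range)
  if (per_hydrogen) {
    bonds$label <- paste0(bonds$label, "_",
                          traj$topology$atom_name[bonds$hydrogen])
  }
  # per-frame P2 for every pair, frames x pairs
  p2 <- matrix(NA_real_, length(frames), nrow(bonds))
  for (k in seq_along(frames)) {
    f <- frames[k]
    xyz <- traj$coords[[f]]
    box <- traj$box[f, ]
    d <- xyz[bonds$hydrogen, , drop = FALSE] - xyz[bonds$carbon, , drop = FALSE]
    for (ax in 1:3) d[, ax] <- min_image_diff(d[, ax], box[ax])
    len2 <- rowSums(d^2)
    if (any(len2 == 0)) {
      bad <- which(len2 == 0)[1]
      abort(sprintf(
        "coincident C and H positions (frame %d, pair %d)", f, bad))
    }
    p2[k, ] <- (3 * d[, 3]^2 / len2 - 1) / 2
  }
  block_id <- ceiling(seq_along(frames) / (length(frames) / min(n_blocks, length(frames))))
  out <- purrr::map_dfr(unique(bonds$label), function(lab) {
    cols <- which(bonds$label == lab)
    v <- p2[, cols, drop = FALSE]
    bm <- tapply(rowMeans(v), block_id, mean)
    tibble(label = lab, S = mean(v),
           stderr = if (length(bm) > 1) sd(bm) / sqrt(length(bm)) else NA_real_,
           n_samples = length(v))
  })
  class(out) <- c("order_parameter_result", class(out))
  out
}

#' Order-parameter change relative to a reference system
#'
#' Computes dS = S - S_ref per label with uncertainties propagated in
#' quadrature.
#'
#' @param result,reference `order_parameter_result` tibbles with matching
#'   labels.
#' @return Tibble with columns label, delta_S, stderr.
#' @export
delta_order_parameter <- function(result, reference) {
  if (!setequal(result$label, reference$label)) {
    abort("result and reference labels do not match")
  }
  ref <- reference[match(result$label, reference$label), ]
  tibble(label = result$label,
         delta_S = result$S - ref$S,
         stderr = sqrt(result$stderr^2 + ref$stderr^2))
}
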