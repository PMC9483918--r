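#' Solute-lipid contact statistics
#'
#' Two atoms are in contact when their minimum-image distance is strictly
#' smaller than `cutoff` (default 0.325 nm). Over all frames in range, for
#' every solute molecule flagged bound by the binding criterion, contacts
#' are counted per (solute heavy atom, lipid atom) pair; the results are
#' the mean number of contacts per bound molecule-frame and the percentage
#' of contacts whose lipid atom is a phosphate oxygen.
#'
#' @param traj an `md_trajectory`.
#' @param solutes list of atom-id vectors, one per solute molecule.
#' @param lipids lipid atom ids (all atoms).
#' @param phosphate_oxygens atom ids of the lipid phosphate oxygens; must
#'   be a subset of `lipids`.
#' @param criterion a [binding_criterion()] deciding which molecules count.
#' @param cutoff contact distance, nm (strict `<`).
#' @param frame_range frames to analyze.
#' @return Tibble of class `contact_stats` with columns
#'   contacts_per_bound_molecule, phosphate_fraction (percent),
#'   n_bound_frames_molecules, n_contacts, cutoff. When no molecule is
#'   ever bound the counts are 0 and the statistics `NA` (an explicit
#'   "no bound molecules" result).
#' @export
contact_stats <- function(traj, solutes, lipids, phosphate_oxygens,
                          criterion, cutoff = 0.325, frame_range = NULL) {
  validate_trajectory(traj)
  if (!all(phosphate_oxygens %in% lipids)) {
    abort("phosphate_oxygens must be a subset of the lipid selection")
  }
  frames <- resolve_frames(traj, frame_range)
  total_contacts <- 0
  phosphate_contacts <- 0
  bound_mol_frames <- 0
  for (f in frames) {
    flags <- assign_bound(traj, f, solutes, lipids, criterion)
    if (!any(flags)) next
    bound_mol_frames <- bound_mol_frames + sum(flags)
    xyz <- traj$coords[[f]]
    box <- traj$box[f, ]
    heavy <- unlist(lapply(solutes[flags], function(ids) {
      ids[traj$topology$element[match(ids, traj$topology$atom_id)] != "H"]
    }), use.names = FALSE)
    q <- xyz[heavy, , drop = FALSE]
    total_contacts <- total_contacts +
      sum(pbc_neighbor_search(q, xyz[lipids, , drop = FALSE], box,
                              cutoff, strict = TRUE)$count)
    if (length(phosphate_oxygens) > 0) {
      phosphate_contacts <- phosphate_contacts +
        sum(pbc_neighbor_search(q, xyz[phosphate_oxygens, , drop = FALSE],
                                box, cutoff, strict = TRUE)$count)
    }
  }
  out <- tibble(
    contacts_per_bound_molecule = if (bound_mol_frames > 0) {
      total_contacts / bound_mol_frames
    } else NA_real_,
    phosphate_fraction = if (total_contacts > 0) {
      100 * phosphate_contacts / total_contacts
    } else NA_real_,
    n_bound_frames_molecules = bound_mol_frames,
    n_contacts = total_contacts,
    cutoff = cutoff)
  attr(out, "no_bound_molecules") <- bound_mol_frames == 0
  class(out) <- c("contact_stats", class(out))
  out
}
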