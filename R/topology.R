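#' Construct a topology
#'
#' A topology is a tibble with one row per atom and a fixed set of columns.
#' Atom ids are 1-based and dense (1..n); every atom belongs to exactly one
#' molecule. Named selections are stored as an attribute: a list of integer
#' atom-id vectors keyed by label.
#'
#' @param atoms data frame with columns `atom_name`, `element`,
#'   `residue_name`, `residue_id`, `molecule_id`, and optionally
#'   `charge` (elementary charges), `mass` (amu), `atom_id`. If `atom_id`
#'   is absent, row order defines ids 1..n.
#' @param selections named list of integer atom-id vectors.
#' @return A tibble of class `md_topology`.
#' @export
topology <- function(atoms, selections = list()) {
  atoms <- as_tibble(atoms)
  required <- c("atom_name", "element", "residue_name", "residue_id", "molecule_id")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0) {
    abort(paste0("topology atoms missing column(s): ", paste(missing, collapse = ", ")))
  }
  n <- nrow(atoms)
  if (n == 0) abort("topology must contain at least one atom")
  if (!"atom_id" %in% names(atoms)) atoms$atom_id <- seq_len(n)
  if (anyDuplicated(atoms$atom_id) || !all(sort(atoms$atom_id) == seq_len(n))) {
    abort("atom_id must be unique and dense from 1")
  }
  if (!"charge" %in% names(atoms)) atoms$charge <- 0
  if (!"mass" %in% names(atoms)) atoms$mass <- 1
  if (anyNA(atoms$molecule_id)) abort("every atom needs a molecule_id")
  atoms <- atoms[order(atoms$atom_id),
                 c("atom_id", "atom_name", "element", "residue_name",
                   "residue_id", "molecule_id", "charge", "mass")]
  for (lab in names(selections)) {
    ids <- selections[[lab]]
    if (!all(ids %in% atoms$atom_id)) {
      abort(paste0("selection '", lab, "' references unknown atom ids"))
    }
    selections[[lab]] <- as.integer(sort(unique(ids)))
  }
  structure(atoms, selections = selections,
            class = c("md_topology", class(atoms)))
}

#' Select atom ids from a topology
#'
#' @param topology an `md_topology`.
#' @param residue_name,atom_name,element optional character vectors; atoms
#'   must match all supplied filters.
#' @param label name of a stored named selection; overrides the filters.
#' @return Integer vector of atom ids.
#' @export
select_atoms <- function(topology, residue_name = NULL, atom_name = NULL,
                         element = NULL, label = NULL) {
  if (!is.null(label)) {
    sel <- attr(topology, "selections")[[label]]
    if (is.null(sel)) abort(paste0("no named selection '", label, "'"))
    return(sel)
  }
  keep <- rep(TRUE, nrow(topology))
  if (!is.null(residue_name)) keep <- keep & topology$residue_name %in% residue_name
  if (!is.null(atom_name)) keep <- keep & topology$atom_name %in% atom_name
  if (!is.null(element)) keep <- keep & topology$element %in% element
  as.integer(topology$atom_id[keep])
}

#' Group atoms of selected molecules
#'
#' Splits the atoms of all molecules containing at least one atom matching
#' the filter into a list of integer atom-id vectors, one per molecule.
#'
#' @inheritParams select_atoms
#' @param heavy_only drop hydrogens (element `"H"`).
#' @return Named list of integer atom-id vectors keyed by molecule id.
#' @export
molecule_groups <- function(topology, residue_name = NULL, label = NULL,
                            heavy_only = FALSE) {
  ids <- select_atoms(topology, residue_name = residue_name, label = label)
  mols <- unique(topology$molecule_id[match(ids, topology$atom_id)])
  rows <- topology$molecule_id %in% mols
  if (heavy_only) rows <- rows & topology$element != "H"
  split(as.integer(topology$atom_id[rows]), topology$molecule_id[rows])
}

validate_topology <- function(topology) {
  stopifnot(inherits(topology, "md_topology"))
  invisible(topology)
}
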