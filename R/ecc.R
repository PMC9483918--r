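#' Scale partial charges (electronic continuum correction)
#'
#' The simplest ECC treatment of electronic polarizability scales the
#' partial charges of the selected atoms by a constant factor, 0.75 by
#' default (approximately 1/sqrt(epsilon_el) for water). Scaling is
#' scope-based and never silently touches atoms outside the scope, so a
#' solute can be corrected while a separately parameterized lipid model is
#' left alone.
#'
#' @param topology an `md_topology`.
#' @param atom_scope integer atom ids to scale; must be non-empty (an
#'   explicit no-op has to be requested, not accidental).
#' @param factor scaling factor in (0, 1].
#' @return The topology with scaled charges; the per-molecule net-charge
#'   report is attached as attribute `charge_report` (see
#'   [charge_report()]).
#' @export
scale_charges <- function(topology, atom_scope, factor = 0.75) {
  validate_topology(topology)
  if (length(atom_scope) == 0) abort("atom_scope is empty")
  if (!all(atom_scope %in% topology$atom_id)) {
    abort("atom_scope references unknown atom ids")
  }
  if (!is.finite(factor) || factor <= 0 || factor > 1) {
    abort("factor must be in (0, 1]")
  }
  before <- topology
  rows <- match(atom_scope, topology$atom_id)
  topology$charge[rows] <- topology$charge[rows] * factor
  attr(topology, "charge_report") <- charge_report(before, topology)
  topology
}

#' Per-molecule net charge before/after a charge edit
#'
#' @param before,after `md_topology` objects with identical atoms.
#' @return Tibble with columns molecule_id, residue_name, net_charge_before,
#'   net_charge_after.
#' @export
charge_report <- function(before, after) {
  tibble(molecule_id = before$molecule_id, residue_name = before$residue_name,
         qb = before$charge, qa = after$charge) |>
    dplyr::group_by(.data$molecule_id) |>
    dplyr::summarise(residue_name = dplyr::first(.data$residue_name),
                     net_charge_before = sum(.data$qb),
                     net_charge_after = sum(.data$qa),
                     .groups = "drop")
}

#' Read or write a charge map
#'
#' A charge map is JSON keyed `"<residue_name>:<atom_name>"` with numeric
#' charge values (elementary charges).
#'
#' @param path JSON file.
#' @return Named numeric vector.
#' @export
read_charge_map <- function(path) {
  if (!file.exists(path)) abort(paste0("cannot read charge map: ", path))
  unlist(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname read_charge_map
#' @param map named numeric vector keyed `"residue:atom"`.
#' @export
write_charge_map <- function(map, path) {
  jsonlite::write_json(as.list(map), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Apply a charge map to a topology
#'
#' @param topology an `md_topology`.
#' @param map named numeric vector keyed `"residue:atom"` (see
#'   [read_charge_map()]).
#' @param strict error when an atom has no entry (default fills 0).
#' @return The topology with charges filled in.
#' @export
apply_charge_map <- function(topology, map, strict = FALSE) {
  key <- paste0(topology$residue_name, ":", topology$atom_name)
  q <- unname(map[key])
  if (strict && anyNA(q)) {
    abort(paste0("no charge-map entry for: ",
                 paste(unique(key[is.na(q)]), collapse = ", ")))
  }
  topology$charge <- ifelse(is.na(q), 0, q)
  topology
}

#' Read or write a minimal ITP atoms section
#'
#' Parses only the `[ atoms ]` section of a GROMACS-style itp file
#' (columns: nr, type, resnr, residue, atom, cgnr, charge, mass).
#'
#' @param path itp file.
#' @return Tibble with columns atom_id, atom_name, residue_name, charge,
#'   mass.
#' @export
read_itp_atoms <- function(path) {
  if (!file.exists(path)) abort(paste0("cannot read itp file: ", path))
  lines <- readLines(path)
  lines <- sub(";.*", "", lines)
  starts <- grep("^\\s*\\[\\s*atoms\\s*\\]", lines)
  if (length(starts) == 0) abort("no [ atoms ] section found")
  body <- lines[(starts[1] + 1):length(lines)]
  nxt <- grep("^\\s*\\[", body)
  if (length(nxt) > 0) body <- body[seq_len(nxt[1] - 1)]
  body <- trimws(body)
  body <- body[nzchar(body)]
  f <- strsplit(body, "\\s+")
  purrr::map_dfr(f, function(x) {
    tibble(atom_id = as.integer(x[1]), atom_name = x[5],
           residue_name = x[4],
           charge = if (length(x) >= 7) as.numeric(x[7]) else 0,
           mass = if (length(x) >= 8) as.numeric(x[8]) else NA_real_)
  })
}

#' @rdname read_itp_atoms
#' @param atoms data frame as returned by `read_itp_atoms()` (an
#'   `md_topology` also works).
#' @export
write_itp_atoms <- function(atoms, path) {
  lines <- c(
    "[ atoms ]",
    ";  nr type resnr residue atom cgnr charge mass",
    sprintf("%5d %6s %5d %6s %6s %5d %12.8f %10.4f",
            atoms$atom_id, atoms$atom_name,
            if ("residue_id" %in% names(atoms)) atoms$residue_id else 1L,
            atoms$residue_name, atoms$atom_name, atoms$atom_id,
            atoms$charge,
            if ("mass" %in% names(atoms)) atoms$mass else 0))
  writeLines(lines, path)
  invisible(path)
}
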