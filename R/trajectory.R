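#' Construct a trajectory
#'
#' An `md_trajectory` bundles a topology with an ordered sequence of frames.
#' Each frame holds an n_atoms x 3 coordinate matrix (nm), an orthorhombic
#' box (3 edge lengths, nm) and a time stamp (ps). Triclinic boxes are not
#' supported.
#'
#' @param topology an `md_topology`.
#' @param coords list of n_atoms x 3 numeric matrices, one per frame.
#' @param box numeric matrix n_frames x 3 of box edge lengths (nm), or a
#'   single 3-vector recycled over frames.
#' @param times numeric frame times (ps), non-decreasing. Defaults to
#'   0, 1, 2, ...
#' @param ground_truth optional list of generator ground-truth records
#'   (see the synthetic generators); carried as metadata.
#' @return An object of class `md_trajectory`.
#' @export
trajectory <- function(topology, coords, box, times = NULL,
                       ground_truth = NULL) {
  validate_topology(topology)
  if (!is.list(coords) || length(coords) == 0) {
    abort("coords must be a non-empty list of coordinate matrices")
  }
  n_atoms <- nrow(topology)
  coords <- lapply(coords, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 3) abort("coordinate matrices must have 3 columns")
    if (nrow(m) != n_atoms) {
      abort(sprintf(
        "frame has %d positions but topology has %d atoms", nrow(m), n_atoms))
    }
    if (any(!is.finite(m))) abort("coordinates must be finite")
    dimnames(m) <- NULL
    storage.mode(m) <- "double"
    m
  })
  n_frames <- length(coords)
  if (is.null(dim(box))) box <- matrix(as.numeric(box), n_frames, 3, byrow = TRUE)
  box <- as.matrix(box)
  if (nrow(box) == 1 && n_frames > 1) box <- box[rep(1, n_frames), , drop = FALSE]
  if (nrow(box) != n_frames || ncol(box) != 3) {
    abort("box must be a 3-vector or an n_frames x 3 matrix")
  }
  if (any(!is.finite(box)) || any(box <= 0)) abort("box edges must be positive")
  dimnames(box) <- NULL
  if (is.null(times)) times <- as.numeric(seq_len(n_frames) - 1)
  if (length(times) != n_frames) abort("times must have one entry per frame")
  if (is.unsorted(times)) abort("frame times must be non-decreasing")
  structure(
    list(topology = topology, coords = coords, box = box,
         times = as.numeric(times), ground_truth = ground_truth),
    class = "md_trajectory")
}

validate_trajectory <- function(traj) {
  if (!inherits(traj, "md_trajectory")) abort("expected an md_trajectory")
  invisible(traj)
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("<md_trajectory: %d atoms, %d frames, box %s nm>\n",
              nrow(x$topology), length(x$coords),
              paste(signif(x$box[1, ], 4), collapse = " x ")))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an `md_trajectory`.
#' @export
n_frames <- function(traj) length(traj$coords)

# Resolve a frame range (1-based inclusive indices); NULL means all frames.
resolve_frames <- function(traj, frame_range) {
  nf <- n_frames(traj)
  if (is.null(frame_range)) return(seq_len(nf))
  fr <- as.integer(frame_range)
  if (length(fr) == 2) fr <- seq.int(fr[1], fr[2])
  if (length(fr) == 0 || any(fr < 1 | fr > nf)) {
    abort("frame_range is empty or outside the trajectory")
  }
  fr
}

#' Long tidy view of a trajectory
#'
#' @param x an `md_trajectory`.
#' @param ... unused.
#' @return Tibble with columns frame, time, atom_id, x, y, z.
#' @method as_tibble md_trajectory
#' @export
as_tibble.md_trajectory <- function(x, ...) {
  purrr::map_dfr(seq_along(x$coords), function(i) {
    tibble(frame = i, time = x$times[i], atom_id = x$topology$atom_id,
           x = x$coords[[i]][, 1], y = x$coords[[i]][, 2],
           z = x$coords[[i]][, 3])
  })
}

#' Read or write the JSON trajectory fixture format
#'
#' A plain-text schema used for synthetic trajectories and test fixtures:
#' an object with an `atoms` table (atom_id, atom_name, element,
#' residue_name, residue_id, molecule_id, charge, mass), an optional
#' `selections` map, an optional `ground_truth` record, and a `frames`
#' array of objects with `time` (ps), `box` (3 edge lengths, nm) and
#' `positions` (n_atoms x 3, nm).
#'
#' @param path file path.
#' @return `read_trajectory_json()` returns an `md_trajectory`;
#'   `write_trajectory_json()` returns `path` invisibly.
#' @export
read_trajectory_json <- function(path) {
  if (!file.exists(path)) abort(paste0("cannot read trajectory file: ", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$frames) || length(obj$frames) == 0 ||
      (is.data.frame(obj$frames) && nrow(obj$frames) == 0)) {
    abort(paste0("trajectory file contains no frames: ", path))
  }
  top <- topology(as_tibble(obj$atoms),
                  selections = lapply(obj$selections, as.integer))
  frames <- obj$frames
  if (is.data.frame(frames)) frames <- split(frames, seq_len(nrow(frames)))
  coords <- unname(lapply(frames, function(f) {
    p <- f$positions
    if (is.list(p) && !is.matrix(p)) p <- p[[1]]
    matrix(as.numeric(as.matrix(p)), ncol = 3)
  }))
  box <- do.call(rbind, lapply(frames, function(f) as.numeric(unlist(f$box))))
  times <- vapply(frames, function(f) as.numeric(f$time), numeric(1))
  trajectory(top, coords, box, times, ground_truth = obj$ground_truth)
}

#' @rdname read_trajectory_json
#' @param traj an `md_trajectory`.
#' @export
write_trajectory_json <- function(traj, path) {
  validate_trajectory(traj)
  obj <- list(
    atoms = as.data.frame(traj$topology),
    selections = attr(traj$topology, "selections"),
    ground_truth = traj$ground_truth,
    frames = purrr::map(seq_along(traj$coords), function(i) {
      list(time = traj$times[i], box = traj$box[i, ],
           positions = traj$coords[[i]])
    }))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a GRO coordinate file
#'
#' Parses the fixed-width GROMACS GRO format (positions in nm). Only
#' orthorhombic boxes (3 box-vector components) are supported; triclinic
#' box lines raise an error. Elements are inferred from the first letter
#' of the atom name; partial charges and masses default to 0 and 1 and can
#' be filled in from a charge map (see [apply_charge_map()]). Molecules are
#' taken as contiguous runs of a single residue id.
#'
#' @param path GRO file path.
#' @return An `md_trajectory` with one frame.
#' @export
read_gro <- function(path) {
  if (!file.exists(path)) abort(paste0("cannot read file: ", path))
  lines <- readLines(path)
  if (length(lines) < 3) abort(paste0("malformed GRO file: ", path))
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n) || n < 1 || length(lines) < n + 3) {
    abort(paste0("malformed GRO file: ", path))
  }
  al <- lines[3:(2 + n)]
  resid <- as.integer(substr(al, 1, 5))
  resname <- trimws(substr(al, 6, 10))
  aname <- trimws(substr(al, 11, 15))
  x <- as.numeric(substr(al, 21, 28))
  y <- as.numeric(substr(al, 29, 36))
  z <- as.numeric(substr(al, 37, 44))
  boxv <- as.numeric(strsplit(trimws(lines[n + 3]), "\\s+")[[1]])
  if (length(boxv) > 3 && any(boxv[4:length(boxv)] != 0)) {
    abort("triclinic boxes are not supported; orthorhombic input required")
  }
  if (length(boxv) < 3 || any(boxv[1:3] <= 0)) abort("invalid GRO box line")
  # molecule ids: contiguous runs of one residue id
  mol <- cumsum(c(1L, as.integer(resid[-1] != resid[-n])))
  top <- topology(tibble(
    atom_name = aname, element = toupper(substr(aname, 1, 1)),
    residue_name = resname, residue_id = resid, molecule_id = mol))
  trajectory(top, list(cbind(x, y, z)), boxv[1:3], times = 0)
}

#' Write a single frame as a GRO file
#'
#' @param traj an `md_trajectory`.
#' @param path output path.
#' @param frame frame index to write.
#' @export
write_gro <- function(traj, path, frame = 1) {
  validate_trajectory(traj)
  xyz <- traj$coords[[frame]]
  top <- traj$topology
  lines <- c(
    sprintf("generated by membindr, t= %.3f", traj$times[frame]),
    sprintf("%5d", nrow(top)),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
            top$residue_id %% 100000, top$residue_name,
            substr(top$atom_name, 1, 5), top$atom_id %% 100000,
            xyz[, 1], xyz[, 2], xyz[, 3]),
    sprintf("%10.5f%10.5f%10.5f", traj$box[frame, 1], traj$box[frame, 2],
            traj$box[frame, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' Load a trajectory from standard files
#'
#' Dispatches on file extension: `.json` (package fixture format), `.gro`,
#' or `.pdb` (requires the bio3d package) for the topology; additional
#' trajectory files (fixture `.json`) contribute frames in file order. All
#' frames must match the topology atom count.
#'
#' @param topology_path coordinate/topology file (`.gro`, `.pdb`, `.json`).
#' @param trajectory_paths optional character vector of further frame files.
#' @return An `md_trajectory`.
#' @export
load_trajectory <- function(topology_path, trajectory_paths = character()) {
  base <- read_structure(topology_path)
  for (p in trajectory_paths) {
    extra <- read_structure(p)
    if (nrow(extra$topology) != nrow(base$topology)) {
      abort(sprintf(
        "atom count mismatch: topology has %d atoms, %s has %d",
        nrow(base$topology), p, nrow(extra$topology)))
    }
    base$coords <- c(base$coords, extra$coords)
    base$box <- rbind(base$box, extra$box)
    t0 <- tail(base$times, 1)
    base$times <- c(base$times, t0 + extra$times + 1)
  }
  trajectory(base$topology, base$coords, base$box, base$times,
             ground_truth = base$ground_truth)
}

read_structure <- function(path) {
  if (!file.exists(path)) abort(paste0("cannot read file: ", path))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    json = read_trajectory_json(path),
    gro = read_gro(path),
    pdb = read_pdb_structure(path),
    abort(paste0("unsupported trajectory format: .", ext,
                 " (supported: json, gro, pdb)")))
}

read_pdb_structure <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    abort("reading PDB files requires the bio3d package")
  }
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  n <- nrow(a)
  mol <- cumsum(c(1L, as.integer(a$resno[-1] != a$resno[-n])))
  elem <- ifelse(is.na(a$elesy) | a$elesy == "",
                 toupper(substr(trimws(a$elety), 1, 1)), trimws(a$elesy))
  top <- topology(tibble(
    atom_name = trimws(a$elety), element = elem,
    residue_name = trimws(a$resid), residue_id = a$resno, molecule_id = mol))
  # PDB coordinates are in Angstrom; box from CRYST1 if present, else padded
  xyz <- cbind(a$x, a$y, a$z) / 10
  box <- c(diff(range(xyz[, 1])), diff(range(xyz[, 2])), diff(range(xyz[, 3]))) + 1
  trajectory(top, list(xyz), pmax(box, 1), times = 0)
}
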