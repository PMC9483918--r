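# Independent brute-force oracles. These deliberately avoid the package's
# minimum-image and neighbor-search code paths: distances are found by
# enumerating all 27 periodic images explicitly.

image_dist <- function(a, b, box) {
  shifts <- expand.grid(i = -1:1, j = -1:1, k = -1:1)
  min(apply(shifts, 1, function(s) {
    sqrt(sum((a - (b + s * box))^2))
  }))
}

# per-molecule bound flags by exhaustive all-pairs distance enumeration
brute_assign_bound <- function(traj, frame, solutes, lipids, criterion) {
  xyz <- traj$coords[[frame]]
  box <- traj$box[frame, ]
  elem <- traj$topology$element
  vapply(solutes, function(ids) {
    heavy <- ids[elem[ids] != "H"]
    n_in <- sum(vapply(heavy, function(a) {
      any(vapply(lipids, function(l) {
        image_dist(xyz[a, ], xyz[l, ], box) <= criterion$distance_cutoff
      }, logical(1)))
    }, logical(1)))
    n_in / length(heavy) >= criterion$bound_fraction
  }, logical(1))
}

# exhaustive pair-contact counts (strict <); returns list(total, subset)
brute_contacts <- function(traj, frame, solute_atoms, lipids, subset,
                           cutoff) {
  xyz <- traj$coords[[frame]]
  box <- traj$box[frame, ]
  total <- 0L
  sub <- 0L
  for (a in solute_atoms) {
    for (l in lipids) {
      if (image_dist(xyz[a, ], xyz[l, ], box) < cutoff) {
        total <- total + 1L
        if (l %in% subset) sub <- sub + 1L
      }
    }
  }
  list(total = total, subset = sub)
}

# a small random solute/slab system used by several oracle comparisons
random_binding_fixture <- function(seed, n_solutes = 20, atoms_per = 3) {
  set.seed(seed)
  box <- c(4, 4, 8)
  n_lip <- 40
  lip <- cbind(runif(n_lip, 0, 4), runif(n_lip, 0, 4), runif(n_lip, -1, 1))
  sol <- do.call(rbind, lapply(seq_len(n_solutes), function(m) {
    center <- c(runif(1, 0, 4), runif(1, 0, 4), runif(1, -4, 4))
    sweep(matrix(rnorm(atoms_per * 3, sd = 0.1), atoms_per, 3), 2, center, "+")
  }))
  top <- topology(tibble::tibble(
    atom_name = c(rep("L1", n_lip), rep("C1", n_solutes * atoms_per)),
    element = "C",
    residue_name = c(rep("LIP", n_lip), rep("ETI", n_solutes * atoms_per)),
    residue_id = c(seq_len(n_lip), rep(n_lip + seq_len(n_solutes),
                                       each = atoms_per)),
    molecule_id = c(seq_len(n_lip), rep(n_lip + seq_len(n_solutes),
                                        each = atoms_per))))
  traj <- trajectory(top, list(rbind(lip, sol)), box)
  solutes <- split(n_lip + seq_len(n_solutes * atoms_per),
                   rep(seq_len(n_solutes), each = atoms_per))
  list(traj = traj, solutes = solutes, lipids = seq_len(n_lip))
}
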