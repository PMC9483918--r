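# Membrane fixture with head-group C-H reporter bonds at a controlled
# angle appended, so response curves have exact pointwise ground truth:
# delta_S against a reference at theta_ref is P2(theta) - P2(theta_ref)
# and bound-per-lipid comes from the generator's bound flags.
make_response_system <- function(theta, n_solutes, seed, n_frames = 40,
                                 k_on = 1, k_off = 1, n_lipids = 40,
                                 n_waters = 200, n_bonds = 30) {
  mem <- gen_membrane_system(n_lipids = n_lipids, n_solutes = n_solutes,
                             solute_atoms = 3, k_on = k_on, k_off = k_off,
                             n_waters = n_waters, n_frames = n_frames,
                             seed = seed)
  ori <- gen_orientation_trajectory("cone", theta = theta,
                                    n_bonds = n_bonds, n_frames = n_frames,
                                    seed = seed + 1000)
  n_mem <- nrow(mem$topology)
  mem_top <- tibble::as_tibble(mem$topology)
  ori_top <- tibble::as_tibble(ori$topology)
  ori_top$atom_id <- ori_top$atom_id + n_mem
  ori_top$residue_id <- ori_top$residue_id + max(mem_top$residue_id)
  ori_top$molecule_id <- ori_top$molecule_id + max(mem_top$molecule_id)
  sels <- attr(mem$topology, "selections")
  top <- topology(dplyr::bind_rows(mem_top, ori_top), selections = sels)
  coords <- lapply(seq_len(n_frames), function(f) {
    rbind(mem$coords[[f]], ori$coords[[f]])
  })
  bonds <- ori$ground_truth$bonds
  bonds$carbon <- bonds$carbon + n_mem
  bonds$hydrogen <- bonds$hydrogen + n_mem
  gt <- mem$ground_truth
  gt$analytic_S <- ori$ground_truth$analytic_S
  gt$bonds <- bonds
  trajectory(top, coords, mem$box, mem$times, ground_truth = gt)
}

two_population_fixture <- function(n_deep = 6, n_far = 4) {
  set.seed(99)
  box <- c(5, 5, 14)
  n_lip <- 120
  lip <- cbind(runif(n_lip, 0, 5), runif(n_lip, 0, 5), runif(n_lip, -1, 1))
  place <- function(n, deep) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      center <- if (deep) {
        lip[sample.int(n_lip, 1), ] + rnorm(3, sd = 0.05)
      } else {
        c(runif(1, 0, 5), runif(1, 0, 5), sample(c(-1, 1), 1) * runif(1, 5, 6.5))
      }
      rbind(center, center + c(0.08, 0, 0), center + c(0, 0.08, 0))
    }))
  }
  sol <- rbind(place(n_deep, TRUE), place(n_far, FALSE))
  n_sol <- n_deep + n_far
  top <- topology(tibble::tibble(
    atom_name = c(rep("L1", n_lip), rep("C1", 3 * n_sol)),
    element = "C",
    residue_name = c(rep("LIP", n_lip), rep("ETI", 3 * n_sol)),
    residue_id = c(seq_len(n_lip), rep(n_lip + seq_len(n_sol), each = 3)),
    molecule_id = c(seq_len(n_lip), rep(n_lip + seq_len(n_sol), each = 3))))
  traj <- trajectory(top, list(rbind(lip, sol)), box)
  list(traj = traj,
       solutes = split(n_lip + seq_len(3 * n_sol),
                       rep(seq_len(n_sol), each = 3)),
       lipids = seq_len(n_lip), n_deep = n_deep)
}

single_contact_fixture <- function(lipid_dist = 0.30) {
  top <- topology(
    tibble::tibble(
      atom_name = c("O13", "C1", "C1"), element = c("O", "C", "C"),
      residue_name = c("LIP", "LIP", "ETI"),
      residue_id = c(1, 1, 2), molecule_id = c(1, 1, 2)),
    selections = list(phosphate_oxygens = 1L))
  xyz <- rbind(c(2, 2, 2), c(2, 2, 4.5), c(2, 2, 2 + lipid_dist))
  list(traj = trajectory(top, list(xyz), c(6, 6, 6)),
       solutes = list(3L), lipids = 1:2)
}

crossing_script <- function() {
  rbind(
    # marker 1: one clean +z -> -z crossing
    data.frame(marker = 1, time = c(0, 10), z = c(4, -4)),
    # marker 2: bounce (enters the membrane, returns to the entry side)
    data.frame(marker = 2, time = c(0, 4, 8, 10), z = c(4, 1, 4, 4)),
    # marker 3: three full crossings interleaved with two bounces
    data.frame(marker = 3,
               time = c(0, 3, 6, 9, 12, 15, 18, 21, 24),
               z = c(4, -4, -1, -4, 4, 1, 4, -4, -4)))
}
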