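test_that("occupancy reflects constructed contact geometry exactly", {
  # with one lipid per leaflet the upper headgroup sits at (0, 0, 19.25);
  # park the peptide bead 3 A below it in every / no / alternating frames
  near <- cbind(0, 0, 16.25)
  far <- cbind(0, 0, 29)
  always <- make_membrane_traj(n_upper = 1, n_lower = 1,
                               peptide = near, n_frames = 4)
  occ <- residue_occupancy(always, cutoff = 4, groups = "headgroup",
                           leaflet = "upper", trailing_fraction = 1)
  expect_equal(occ$occupancy_pct, 100)
  never <- make_membrane_traj(n_upper = 1, n_lower = 1,
                              peptide = far, n_frames = 4)
  expect_equal(residue_occupancy(never, cutoff = 4,
                                 trailing_fraction = 1)$occupancy_pct, 0)
  alt <- make_membrane_traj(n_upper = 1, n_lower = 1,
                            peptide = list(near, far, near, far),
                            n_frames = 4)
  expect_equal(residue_occupancy(alt, cutoff = 4, groups = "headgroup",
                                 trailing_fraction = 1)$occupancy_pct, 50)
})

test_that("contacts honour minimum-image distances across the box edge", {
  box <- c(40, 40, 60)
  traj <- make_membrane_traj(n_upper = 1, n_lower = 1, box = box,
                             peptide = cbind(0, 0, 0), n_frames = 1)
  hg <- which(traj$beads$role == "headgroup")[1]
  # place the upper headgroup near +x edge and the peptide near -x edge
  traj$coords[hg, , 1] <- c(19.5, 0, 0)
  traj$coords[traj$beads$role == "peptide", , 1] <- c(-19.5, 0, 0)
  occ <- residue_occupancy(traj, cutoff = 2, groups = "headgroup",
                           trailing_fraction = 1)
  expect_equal(occ$occupancy_pct, 100) # wrapped distance is 1 A
})

test_that("occupancy is monotone in the cutoff and bounded by group unions", {
  spec <- bilayer_spec(lipid_counts = c(PC = 10, PS = 10), box_xy = 40,
                       peptide = list(n_residues = 3, depth = 15),
                       n_frames = 4, frame_jitter = 0.2, seed = 3L)
  traj <- generate_bilayer_trajectory(spec)
  cuts <- c(3, 5, 8, 12)
  occs <- vapply(cuts, function(ct) {
    residue_occupancy(traj, cutoff = ct, groups = "headgroup",
                      trailing_fraction = 1)$occupancy_pct
  }, numeric(3))
  for (r in 1:3) expect_true(all(diff(occs[r, ]) >= 0))
  u <- residue_occupancy(traj, cutoff = 6,
                         groups = c("headgroup:PC", "headgroup:PS",
                                    "headgroup:PC+headgroup:PS"),
                         trailing_fraction = 1)
  pc <- u$occupancy_pct[u$group == "headgroup:PC"]
  ps <- u$occupancy_pct[u$group == "headgroup:PS"]
  un <- u$occupancy_pct[u$group == "headgroup:PC+headgroup:PS"]
  expect_true(all(un >= pmax(pc, ps)))
})

test_that("occupancy equals the all-pairs oracle on small frames", {
  set.seed(41)
  for (i in 1:4) {
    traj <- make_membrane_traj(n_upper = 2, n_lower = 1,
                               box = c(25, 25, 50),
                               peptide = lapply(1:3, function(f) {
                                 cbind(runif(2, -10, 10),
                                       runif(2, -10, 10),
                                       runif(2, -22, 22))
                               }),
                               n_frames = 3)
    got <- residue_occupancy(traj, cutoff = 6, groups = "headgroup",
                             trailing_fraction = 1)
    expect_identical(got$occupancy_pct,
                     oracle_occupancy(traj, 6, "headgroup"))
  }
})

test_that("group contrasts report signed per-residue differences", {
  spec <- bilayer_spec(lipid_counts = c(PC = 8, PS = 8), box_xy = 40,
                       peptide = list(n_residues = 2, depth = 16),
                       n_frames = 2, seed = 9L)
  traj <- generate_bilayer_trajectory(spec)
  tab <- residue_occupancy(traj, cutoff = 8,
                           groups = c("headgroup:PC", "headgroup:PS"),
                           trailing_fraction = 1)
  same <- occupancy_contrast(tab, "headgroup:PC", "headgroup:PC")
  expect_true(all(same$delta_pct == 0))
  expect_error(occupancy_contrast(tab, "headgroup:PC", "sterol"),
               "not present")
  # constructed: residue touches only PS in 3 of 4 frames, PC in 1
  ps_pos <- cbind(0, 0, 16.25)
  traj2 <- make_membrane_traj(n_upper = 2, n_lower = 2,
                              species = c("PS", "PC"),
                              peptide = ps_pos, n_frames = 4)
  hg <- which(traj2$beads$role == "headgroup")
  ps_hg <- hg[traj2$beads$residue_name[hg] == "PS"][1]
  pc_hg <- hg[traj2$beads$residue_name[hg] == "PC"][1]
  pep <- which(traj2$beads$role == "peptide")
  for (f in 1:3) traj2$coords[pep, , f] <- traj2$coords[ps_hg, , f] + c(0, 0, -2)
  traj2$coords[pep, , 4] <- traj2$coords[pc_hg, , 4] + c(0, 0, -2)
  tab2 <- residue_occupancy(traj2, cutoff = 3,
                            groups = c("headgroup:PS", "headgroup:PC"),
                            trailing_fraction = 1)
  d <- occupancy_contrast(tab2, "headgroup:PS", "headgroup:PC")
  expect_equal(d$delta_pct, 50) # 75% - 25%
})

test_that("invalid occupancy queries are rejected", {
  traj <- make_membrane_traj(n_upper = 2, n_lower = 2,
                             peptide = cbind(0, 0, 0), n_frames = 2)
  expect_error(residue_occupancy(traj, cutoff = 0), "cutoff")
  expect_error(residue_occupancy(traj, groups = "solvent"),
               "unknown lipid group")
  nopep <- make_membrane_traj(n_upper = 2, n_lower = 2)
  expect_error(residue_occupancy(nopep), "no peptide")
})
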