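test_that("leaflet assignment splits symmetric bilayers and honours the tie rule", {
  traj <- make_membrane_traj(n_upper = 6, n_lower = 6)
  leaf <- assign_leaflets(traj)
  expect_equal(sum(leaf == "upper"), 6)
  expect_equal(sum(leaf == "lower"), 6)
  # all lipids in one plane: z >= median puts everything upper
  flat <- make_membrane_traj(n_upper = 4, n_lower = 0,
                             planes = c(10, -10))
  expect_true(all(assign_leaflets(flat) == "upper"))
  single <- make_membrane_traj(n_upper = 1, n_lower = 0)
  expect_equal(unname(assign_leaflets(single)), "upper")
})

test_that("order parameter hits its analytic anchors and bounds", {
  expect_equal(bond_order_parameter(c(0, 0, 1)), 1)
  expect_equal(bond_order_parameter(c(0, 0, -2.5)), 1)
  expect_equal(bond_order_parameter(c(1, 1, 0)), -0.5)
  # isotropic directions average to zero
  set.seed(12)
  v <- matrix(rnorm(3 * 20000), ncol = 3)
  s <- bond_order_parameter(v)
  expect_lt(abs(mean(s)), 3 * sd(s) / sqrt(length(s)))
  expect_true(all(s >= -0.5 - 1e-12 & s <= 1 + 1e-12))
  expect_error(bond_order_parameter(c(0, 0, 0)), "zero-length")
})

test_that("chain order parameter is exactly 1 for untilted noise-free chains", {
  spec <- bilayer_spec(lipid_counts = c(DPPC = 9), box_xy = 40,
                       chain_tilt_noise = 0, frame_jitter = 0,
                       n_frames = 2)
  prof <- order_parameter(generate_bilayer_trajectory(spec))
  expect_equal(prof$mean_scd, rep(1, 4))
  expect_equal(prof$carbon, 1:4)
})

test_that("pore scan finds the bottleneck of constructed water columns", {
  zb <- c(-19.25, 19.25)
  # no water inside the membrane: no pathway, radius 0
  dry <- make_membrane_traj(waters = cbind(0, 0, 25))
  expect_equal(pore_radius_profile(dry, z_bounds = zb)$min_radius, 0)
  # constant cylinder r = 6
  cyl <- make_membrane_traj(waters = disk_channel_waters(6, zb, 60))
  est <- pore_radius_profile(cyl, z_bounds = zb)
  expect_lt(abs(est$min_radius - 6), 0.5)
  expect_true(all(est$slabs$radius >= est$min_radius))
  # hourglass: mouths 8, waist 3
  hour <- disk_channel_waters(function(z) {
    approx(c(-19.25, 0, 19.25), c(8, 3, 8), xout = z)$y
  }, zb, 50, seed = 100)
  hg <- make_membrane_traj(waters = hour)
  expect_lt(abs(pore_radius_profile(hg, z_bounds = zb)$min_radius - 3),
            0.5)
  expect_error(pore_radius_profile(dry, z_bounds = c(5, 5)),
               "zero slabs")
})

test_that("finer slabs cannot overestimate the bottleneck of a noise-free cylinder", {
  zb <- c(-19.25, 19.25)
  cyl <- make_membrane_traj(waters = disk_channel_waters(5, zb, 80,
                                                         seed = 9))
  widths <- c(4, 2, 1, 0.5)
  est <- vapply(widths, function(w) {
    pore_radius_profile(cyl, slab_width = w, z_bounds = zb)$min_radius
  }, numeric(1))
  expect_true(all(diff(est) <= 1e-9))
})

test_that("randomized channel radii are recovered within the sampling bound", {
  # channels below ~10 waters per slab are undersampled and the
  # bottleneck statistic biases low; the guarantee targets channels at
  # the generator's water density, radius >= 3 A
  set.seed(77)
  zb <- c(-19.25, 19.25)
  for (i in 1:6) {
    r <- runif(1, 3, 8)
    n <- max(5L, round(0.5 * pi * r^2))
    traj <- make_membrane_traj(waters = disk_channel_waters(
      r, zb, n, seed = 500 + i))
    est <- pore_radius_profile(traj, z_bounds = zb)$min_radius
    expect_lt(abs(est - r), max(0.5, 2 / sqrt(n)))
  }
})

test_that("trailing-window pore statistics follow constructed inputs", {
  zb <- c(-19.25, 19.25)
  dry <- make_membrane_traj(waters = cbind(0, 0, 25), n_frames = 5)
  expect_equal(mean_pore_radius(dry, z_bounds = zb)$mean, 0)
  wet <- disk_channel_waters(6, zb, 60)
  full <- make_membrane_traj(waters = wet, n_frames = 4)
  mp <- mean_pore_radius(full, trailing_fraction = 1, z_bounds = zb)
  expect_lt(abs(mp$mean - 6), 0.5)
  expect_lt(mp$sd, 0.5)
  # channel in exactly half of the analyzed frames: mean halves
  outside <- cbind(runif(nrow(wet), -5, 5), runif(nrow(wet), -5, 5),
                   25 + runif(nrow(wet), 0, 5))
  half <- make_membrane_traj(
    waters = list(wet, outside, wet, outside), n_frames = 4)
  mh <- mean_pore_radius(half, trailing_fraction = 1, z_bounds = zb)
  expect_lt(abs(mh$mean - mp$mean / 2), 0.3)
  expect_error(mean_pore_radius(full, trailing_fraction = 0), "0, 1")
})

test_that("thickness and area per lipid follow the constructed geometry", {
  t385 <- make_membrane_traj(n_upper = 9, n_lower = 9,
                             planes = c(19.25, -19.25))
  expect_equal(thickness(t385), 38.5)
  t416 <- make_membrane_traj(n_upper = 9, n_lower = 9,
                             planes = c(20.8, -20.8))
  expect_equal(thickness(t416), 41.6)
  apl <- area_per_lipid(make_membrane_traj(n_upper = 60, n_lower = 60,
                                           box = c(60, 60, 80)))
  expect_equal(apl$upper, 60)
  expect_equal(apl$lower, 60)
  # doubling the box area doubles the value; asymmetric counts scale
  apl2 <- area_per_lipid(make_membrane_traj(
    n_upper = 60, n_lower = 30, box = c(60 * sqrt(2), 60 * sqrt(2), 80)))
  expect_equal(apl2$upper, 120)
  expect_equal(apl2$lower, 240)
})

test_that("thickness and area per lipid are translation invariant", {
  traj <- make_membrane_traj(n_upper = 8, n_lower = 8)
  shifted <- traj
  shifted$coords <- traj$coords + 7.3
  expect_equal(thickness(shifted), thickness(traj))
  expect_equal(area_per_lipid(shifted), area_per_lipid(traj))
})

test_that("peptide fate classification reproduces the four observed outcomes", {
  planes <- c(19.25, -19.25)
  n <- 20
  expect_equal(classify_outcome(rep(-21, n), rep(0, n), planes),
               "lower_leaflet_equilibrium")
  expect_equal(classify_outcome(rep(0, n), rep(6, n), planes),
               "pore_formation")
  expect_equal(classify_outcome(rep(0, n), rep(0, n), planes),
               "insertion")
  expect_equal(classify_outcome(rep(22, n), rep(0, n), planes),
               "return")
  # no pore record means no sustained pore
  expect_equal(classify_outcome(rep(0, n), NULL, planes), "insertion")
  # transient pore below the persistence threshold
  pr <- c(rep(6, 5), rep(0, 15))
  expect_equal(classify_outcome(rep(0, n), pr, planes,
                                trailing_fraction = 1), "insertion")
  expect_error(classify_outcome(numeric(0), NULL, planes), "empty")
  expect_error(classify_outcome(rep(0, n), NULL, c(4, -4), margin = 5),
               "margins overlap")
})

test_that("classification is total over random admissible inputs", {
  set.seed(31)
  labels <- c("lower_leaflet_equilibrium", "pore_formation",
              "insertion", "return")
  for (i in 1:100) {
    com <- runif(15, -35, 35)
    pore <- pmax(0, rnorm(15, 1, 2))
    out <- classify_outcome(com, pore, c(19.25, -19.25))
    expect_true(out %in% labels)
  }
})
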