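th310 <- thermo_params(310.15)

test_that("stage planning covers the span contiguously with truncation", {
  p <- plan_stages(0, 40, 5, 25, 1)
  expect_equal(nrow(p$stages), 8)
  expect_equal(p$stages$start, seq(0, 35, 5))
  expect_equal(p$stages$end, seq(5, 40, 5))
  expect_equal(p$direction, "forward")
  expect_equal(nrow(plan_stages(0, 5, 5, 25, 1)$stages), 1)
  tr <- plan_stages(0, 12, 5, 25, 1)$stages
  expect_equal(tr$start, c(0, 5, 10))
  expect_equal(tr$end, c(5, 10, 12))
  bk <- plan_stages(40, 0, 5, 25, 1)
  expect_equal(bk$direction, "backward")
  expect_equal(bk$stages$start[1], 40)
  expect_error(plan_stages(3, 3, 5, 25, 1), "zero-length")
})

test_that("Jarzynski estimator matches direct evaluation", {
  expect_equal(jarzynski_free_energy(rep(3, 7), th310), 3)
  # two-point ensemble, brute force
  expect_equal(jarzynski_free_energy(c(0, 10), th310),
               naive_jarzynski(c(0, 10), th310), tolerance = 1e-12)
  # second-cumulant closed form for Gaussian works
  set.seed(101)
  w <- rnorm(1e5, mean = 5, sd = 0.5)
  est <- jarzynski_free_energy(w, th310)
  closed <- 5 - th310$beta * 0.5^2 / 2
  # delta-method standard error of the estimate
  x <- exp(-th310$beta * w)
  se <- sd(x) / (sqrt(length(w)) * mean(x)) / th310$beta
  expect_lt(abs(est - closed), 3 * se)
  expect_error(jarzynski_free_energy(numeric(0)), "empty")
  expect_error(jarzynski_free_energy(c(1, NA)), "non-finite")
})

test_that("log-sum-exp scheme equals the naive form and survives overflow", {
  set.seed(2)
  for (i in 1:25) {
    w <- rnorm(25, mean = runif(1, -5, 5), sd = runif(1, 0.1, 2))
    expect_lt(abs(jarzynski_free_energy(w, th310) -
                    naive_jarzynski(w, th310)), 1e-10)
  }
  # naive form underflows here; the estimate must stay finite and
  # respect the min-work bound
  big <- c(5000, 5001, 5002)
  est <- jarzynski_free_energy(big, th310)
  expect_true(is.finite(est))
  expect_lte(est, min(big) + log(3) / th310$beta)
})

test_that("estimator obeys the Jensen and min-work bounds and shifts with constants", {
  set.seed(3)
  for (i in 1:50) {
    w <- rnorm(sample(2:40, 1), mean = runif(1, -3, 3),
               sd = runif(1, 0.05, 3))
    est <- jarzynski_free_energy(w, th310)
    expect_lte(est, mean(w) + 1e-12)
    expect_lte(est, min(w) + log(length(w)) / th310$beta + 1e-12)
    c0 <- runif(1, -10, 10)
    expect_equal(jarzynski_free_energy(w + c0, th310), est + c0,
                 tolerance = 1e-10)
  }
})

test_that("representative replica is the closest to the Jarzynski average", {
  mk <- function(w, id) {
    structure(list(time = c(0, 1), lambda = c(0, 5), position = c(0, 5),
                   work = c(0, w), stage_id = 1L,
                   replica_id = as.integer(id), seed = NA_integer_),
              class = "work_trace")
  }
  expect_equal(select_representative_replica(list(mk(2.2, 1)), th310), 1)
  # all equal: documented tie-break, lowest id
  expect_equal(select_representative_replica(
    list(mk(1, 3), mk(1, 1), mk(1, 2)), th310), 1)
  # enumerate all three distances by brute force
  ws <- c(1, 2, 10)
  dF <- naive_jarzynski(ws, th310)
  best <- which.min(abs(ws - dF))
  got <- select_representative_replica(
    list(mk(1, 1), mk(2, 2), mk(10, 3)), th310)
  expect_equal(got, best)
  expect_error(select_representative_replica(list(), th310), "empty")
})

test_that("stage profiles collapse correctly for degenerate ensembles", {
  cfg <- langevin_config(temperature = 0)
  tr <- simulate_steered_pull(cfg, 0, 5)
  grid <- seq(0, 5, 0.5)
  # N = 1: profile equals that replica's (interpolated) work curve
  prof <- jarzynski_profile(list(tr), grid, th310)
  expect_equal(prof$free_energy,
               approx(tr$lambda, tr$work, xout = grid)$y,
               tolerance = 1e-10)
  # identical replicas: same collapse
  prof2 <- jarzynski_profile(list(tr, tr, tr), grid, th310)
  expect_equal(prof2$free_energy, prof$free_energy, tolerance = 1e-10)
  expect_error(jarzynski_profile(list(tr), seq(0, 9, 1), th310),
               "outside the stage")
  t2 <- simulate_steered_pull(cfg, 5, 10, stage_id = 2L)
  expect_error(jarzynski_profile(list(tr, t2), grid, th310),
               "single stage")
})

test_that("flat-landscape stage profiles average to zero along the stage", {
  # the pointwise estimator corrects dissipation: averaged over many
  # independent 25-replica ensembles the profile is flat to within 10%
  # of the mean dissipated work
  cfg <- langevin_config()
  grid <- seq(0, 5, 0.5)
  reps <- 50
  acc <- matrix(0, nrow = length(grid), ncol = reps)
  wdiss <- 0
  for (r in seq_len(reps)) {
    e <- generate_work_ensemble(cfg, 0, 5, 25, seed = 9000 + r)
    acc[, r] <- jarzynski_profile(e, grid, th310)$free_energy
    wdiss <- wdiss + mean(vapply(e, function(t) tail(t$work, 1),
                                 numeric(1)))
  }
  wdiss <- wdiss / reps
  expect_gt(wdiss, 0)
  expect_lt(max(abs(rowMeans(acc))), 0.1 * wdiss)
})

test_that("staged runs are seed-deterministic and continuous across stages", {
  plan <- plan_stages(0, 10, 5, 6, 1)
  cfg <- langevin_config()
  p1 <- run_asmd(plan, cfg, th310, seed = 4)
  p2 <- run_asmd(plan, cfg, th310, seed = 4)
  expect_identical(p1$free_energy, p2$free_energy)
  expect_identical(p1$replica_chain, p2$replica_chain)
  expect_equal(p1$free_energy[1], 0)
  expect_length(p1$replica_chain, 2)
  expect_length(p1$stage_boundaries, 1)
  # grid strictly monotone: stage joins share no duplicated point, so
  # the boundary jump is zero by construction
  expect_true(all(diff(p1$grid) > 0))
  expect_true(all(is.finite(p1$free_energy)))
})

test_that("more replicas reduce the staged estimate error in expectation", {
  cfg <- langevin_config()
  err <- function(n, seed) {
    e <- generate_work_ensemble(cfg, 0, 5, n, seed = seed)
    abs(jarzynski_free_energy(
      vapply(e, function(t) tail(t$work, 1), numeric(1)), th310))
  }
  seeds <- 301:306
  e25 <- mean(vapply(seeds, function(s) err(25, s), numeric(1)))
  e250 <- mean(vapply(seeds, function(s) err(250, s), numeric(1)))
  expect_lt(e250, e25)
})

test_that("hysteresis of a profile against itself is zero", {
  plan <- plan_stages(0, 10, 5, 4, 1)
  p <- run_asmd(plan, langevin_config(), th310, seed = 8)
  h <- hysteresis(p, p)
  expect_equal(h$max, 0)
  expect_equal(h$mean, 0)
  q <- pmf_profile(seq(100, 110, 1), rep(0, 11))
  expect_error(hysteresis(p, q), "disjoint")
})

test_that("protocol accounting reproduces the staged-design arithmetic", {
  plan <- plan_stages(0, 40, 5, 25, 1)
  acc <- protocol_accounting(plan, n_peptides = 3, n_membranes = 3)
  expect_equal(acc$per_replica_ns, rep(5, 8))
  expect_equal(acc$per_stage_ns, rep(125, 8))
  expect_equal(acc$per_simulation_ns, 1000)
  expect_equal(acc$campaign_ns, 9000)
  one <- protocol_accounting(plan_stages(0, 7, 7, 1, 3.5))
  expect_equal(one$per_simulation_ns, 2)
})

test_that("experiment matrix enumerates peptide-membrane systems plus controls", {
  m <- plan_experiment_matrix(c("Arg9", "MAP", "TP2"),
                              c("M1", "M2", "M3"))
  expect_equal(nrow(m), 12)
  expect_equal(sum(m$control), 3)
  expect_equal(nrow(plan_experiment_matrix(character(0), c("M1", "M2", "M3"))), 3)
  expect_equal(nrow(plan_experiment_matrix("P", "M", include_controls = FALSE)), 1)
  expect_error(plan_experiment_matrix("P", character(0)), "non-empty")
})
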