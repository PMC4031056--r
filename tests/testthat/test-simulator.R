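test_that("identical seeds give bit-identical trajectories", {
  p <- sim_params(n_molecules = 3, box_side = 6, n_frames = 20,
                  timestep_ps = 1, frame_interval_ps = 10, seed = 42)
  a <- simulate_aggregation(p)
  b <- simulate_aggregation(p)
  for (i in seq_along(a$trajectory$frames)) {
    expect_identical(a$trajectory$frames[[i]]$xyz,
                     b$trajectory$frames[[i]]$xyz)
  }
  expect_identical(a$ground_truth$events, b$ground_truth$events)
  p2 <- p; p2$seed <- 43L
  c <- simulate_aggregation(p2)
  expect_false(identical(a$trajectory$frames[[5]]$xyz,
                         c$trajectory$frames[[5]]$xyz))
})

test_that("free diffusion recovers the target D within 10%", {
  p <- sim_params(n_molecules = 27, box_side = 30, well_depth = 0,
                  k_off_target = 0, D_target = 1e-10, n_frames = 400,
                  timestep_ps = 25, frame_interval_ps = 25, seed = 3)
  sim <- simulate_aggregation(p)
  est <- diffusion_coefficient_msd(sim$trajectory)
  expect_false(est$poor_fit)
  expect_equal(est$D_m2s, 1e-10, tolerance = 0.1)
})

test_that("irreversible sticky binding drives 8 molecules into one cluster", {
  p <- sim_params(n_molecules = 8, box_side = 6, bead_radius = 0.4,
                  D_target = 1e-9, k_off_target = 0, n_frames = 300,
                  timestep_ps = 0.5, frame_interval_ps = 100, seed = 17)
  sim <- simulate_aggregation(p)
  series <- contact_timeseries(sim$trajectory, cutoff = p$contact_radius)
  os <- oligomer_timeseries(series)
  last <- nrow(os$molecule_size)
  expect_equal(os$free_fraction[last], 0)
  expect_true(all(os$molecule_size[last, ] == 8L))
  # free-monomer fraction never needs to rise: smoothed decay
  sm <- stats::filter(os$free_fraction, rep(1 / 20, 20), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_true(all(diff(sm) < 0.15))
})

test_that("maximally separated initial placements hit the lattice optimum", {
  min_center_dist <- function(p) {
    set.seed(p$seed)
    f <- make_initial_configuration(p)
    top <- bead_topology(p$n_molecules, p$beads_per_molecule)
    centers <- t(vapply(seq_len(p$n_molecules), function(m) {
      colMeans(f$xyz[top$atoms$molecule == m, , drop = FALSE])
    }, numeric(3)))
    prs <- which(upper.tri(diag(p$n_molecules)), arr.ind = TRUE)
    min(minimum_image_distance(centers[prs[, 1], , drop = FALSE],
                               centers[prs[, 2], , drop = FALSE],
                               f$box))
  }
  p4 <- sim_params(n_molecules = 4, box_side = 10, seed = 1)
  expect_equal(min_center_dist(p4), 10 * sqrt(2) / 2, tolerance = 1e-9)
  p1 <- sim_params(n_molecules = 1, box_side = 10, seed = 1)
  set.seed(1)
  f1 <- make_initial_configuration(p1)
  expect_equal(colMeans(f1$xyz), c(5, 5, 5))
  p8 <- sim_params(n_molecules = 8, box_side = 10, seed = 1)
  expect_equal(min_center_dist(p8), 5, tolerance = 1e-9)
})

test_that("simulator energy log matches the analysis decomposition exactly", {
  p <- sim_params(n_molecules = 2, box_side = 5, mode = "ljc",
                  beads_per_molecule = 3, bead_radius = 0.2,
                  charge = c(0.5, -0.5, 0), lj_epsilon = 0.4,
                  n_frames = 8, timestep_ps = 1, frame_interval_ps = 10,
                  solvent = list(n = 25, charge = 0, sigma = 0.3,
                                 epsilon = 0.6, radius = 0.15),
                  seed = 7)
  sim <- simulate_aggregation(p)
  np <- nonbonded_params(cutoff = p$cutoff, eps_rf = p$eps_rf)
  en <- energy_decomposition_series(sim$trajectory, np)
  gt <- sim$ground_truth$energies
  for (col in c("E_pp", "E_ps", "E_ss", "E_total")) {
    expect_equal(en[[col]], gt[[col]], tolerance = 1e-6)
  }
  expect_true(any(gt$E_ss != 0) && any(gt$E_ps != 0))
})

test_that("ground-truth events agree with the contact-run detector", {
  p <- sim_params(n_molecules = 2, box_side = 6, D_target = 1e-9,
                  k_off_target = 1e8, n_frames = 3000, timestep_ps = 0.5,
                  frame_interval_ps = 20, seed = 11)
  sim <- simulate_aggregation(p)
  series <- contact_timeseries(sim$trajectory, cutoff = p$contact_radius)
  detected <- detect_complexes(series, min_lifetime_ns = 0.1)
  truth <- sim$ground_truth$events
  truth <- truth[truth$lifetime_ns >= 0.1, ]
  expect_lte(abs(nrow(detected) - nrow(truth)), 1)
})

test_that("simulation output files round-trip through the readers", {
  dir <- withr::local_tempdir()
  p <- sim_params(n_molecules = 2, box_side = 6, n_frames = 5,
                  timestep_ps = 1, frame_interval_ps = 10, seed = 23)
  sim <- simulate_aggregation(p, output_dir = dir)
  top <- read_topology(file.path(dir, "topology.tsv"), "internal")
  traj <- read_trajectory(file.path(dir, "trajectory.xyzx"), top,
                          "internal")
  expect_equal(length(traj$frames), 5L)
  expect_identical(traj$frames[[3]]$xyz, sim$trajectory$frames[[3]]$xyz)
  ev <- utils::read.delim(file.path(dir, "events.tsv"))
  expect_true(all(c("mol_i", "mol_j", "t_bind_ps") %in% names(ev)))
})

test_that("the timestep guard warns when the well cannot be resolved", {
  expect_warning(
    sim_params(n_molecules = 2, box_side = 6, D_target = 1e-9,
               timestep_ps = 10),
    "timestep"
  )
})

test_that("thermal well escape times follow the first-passage prediction", {
  # shallow well so that escape is fast enough to sample
  p <- sim_params(n_molecules = 2, box_side = 8, D_target = 1e-9,
                  mode = "well", well_depth = 5, n_frames = 2,
                  timestep_ps = 0.5,
                  frame_interval_ps = 50000, seed = 31)
  pred_ns <- mfpt_dissociation_time(p)
  lives <- c()
  for (s in 1:40) {
    p$seed <- 1000L + s
    sim <- simulate_aggregation(p)
    ev <- sim$ground_truth$events
    if (nrow(ev) > 0 && !ev$censored[1]) {
      lives <- c(lives, ev$lifetime_ns[1])
    }
  }
  expect_gt(length(lives), 20)
  expect_equal(mean(lives), pred_ns, tolerance = 0.5)
})
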