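test_that("the persistence rule admits runs of at least 1 ns", {
  # 13 consecutive 100-ps frames in contact = 1.2 ns -> one event
  v <- c(rep(FALSE, 5), rep(TRUE, 13), rep(FALSE, 10))
  ev <- detect_complexes(stub_contact_series(v))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$lifetime_ns, 1.2)
  expect_false(ev$censored)
  expect_equal(ev$t_start_ps, 500)
  expect_equal(ev$t_end_ps, 1700)

  # 5 frames = 0.4 ns -> below the 1-ns rule, no event
  v2 <- c(rep(FALSE, 5), rep(TRUE, 5), rep(FALSE, 10))
  expect_equal(nrow(detect_complexes(stub_contact_series(v2))), 0L)

  # contact through the final frame -> censored event
  v3 <- c(rep(FALSE, 10), rep(TRUE, 101))
  ev3 <- detect_complexes(stub_contact_series(v3))
  expect_equal(nrow(ev3), 1L)
  expect_true(ev3$censored)
  expect_equal(ev3$lifetime_ns, 10)
})

test_that("complex detection is idempotent and ignores leading free frames", {
  set.seed(81)
  v <- runif(400) < 0.5
  s <- stub_contact_series(v)
  ev1 <- detect_complexes(s)
  expect_identical(detect_complexes(s), ev1)
  padded <- stub_contact_series(c(rep(FALSE, 50), v))
  ev2 <- detect_complexes(padded)
  ev2$t_start_ps <- ev2$t_start_ps - 5000
  ev2$t_end_ps <- ev2$t_end_ps - 5000
  expect_equal(ev2, ev1, ignore_attr = TRUE)
})

test_that("complex detection refuses bad inputs", {
  s <- stub_contact_series(rep(TRUE, 20))
  s$frame_interval <- NA_real_
  expect_error(detect_complexes(s), "non-uniform")
  expect_error(detect_complexes(stub_contact_series(rep(TRUE, 20)),
                                min_lifetime_ns = 0.05),
               "frame interval")
})

test_that("kinetics summary separates dissociating and censored complexes", {
  ev <- data.frame(mol_i = c(1L, 1L), mol_j = c(2L, 2L),
                   t_start_ps = c(1000, 10000),
                   t_end_ps = c(3000, 14000),
                   lifetime_ns = c(2, 4), censored = c(FALSE, FALSE))
  ks <- kinetics_summary(ev, 0, 20000, molecules = 1:2)
  expect_equal(ks$mean_dissociation_ns, 3)
  expect_equal(ks$censored_fraction, 0)
  expect_false(ks$censored_only)
  # association: both molecules wait 1 ns, then 7 ns after dissociating
  expect_equal(ks$mean_association_ns, 4)
  expect_equal(ks$n_association_waits, 4L)
  # survival curve: starts at 1, non-increasing, ends at 0
  expect_equal(ks$survival$fraction[1], 1)
  expect_true(all(diff(ks$survival$fraction) <= 0))
  expect_equal(ks$survival$fraction[nrow(ks$survival)], 0)

  # all complexes censored: dissociation mean undefined but flagged
  ev2 <- transform(ev, censored = TRUE)
  ks2 <- kinetics_summary(ev2, 0, 20000, molecules = 1:2)
  expect_true(ks2$censored_only)
  expect_true(is.na(ks2$mean_dissociation_ns))
  expect_equal(ks2$censored_fraction, 1)
  expect_equal(ks2$never_dissociate_fraction, 1)
})

test_that("Smoluchowski waiting time evaluates the closed form", {
  expect_equal(smoluchowski_association_time(2.0, 6.9e-10, 6e-3), 16.0,
               tolerance = 3e-3)
  t1 <- smoluchowski_association_time(1.5, 5e-10, 6e-3)
  expect_equal(smoluchowski_association_time(1.5, 5e-10, 12e-3), t1 / 2)
  expect_error(smoluchowski_association_time(0, 1e-9, 6e-3), "positive")
  expect_equal(smoluchowski_kon(1, 1), 4 * pi * 1e-9)
})

test_that("MSD fit recovers D of a pure random walk within 10%", {
  set.seed(91)
  n_mol <- 40
  F <- 500
  dt <- 100
  D_nm2ps <- 1e-4  # 1e-10 m^2/s
  top <- bead_topology(n_mol, 1, radius = 0.1)
  steps <- array(rnorm(F * n_mol * 3, sd = sqrt(2 * D_nm2ps * dt)),
                 c(F, n_mol, 3))
  pos <- apply(steps, c(2, 3), cumsum)
  frames <- lapply(seq_len(F), function(f) {
    frame(matrix(pos[f, , ], ncol = 3) %% 50, c(50, 50, 50),
          (f - 1) * dt)
  })
  traj <- trajectory(top, frames)
  est <- diffusion_coefficient_msd(traj)
  expect_false(est$poor_fit)
  expect_equal(est$D_m2s, 1e-10, tolerance = 0.1)
})

test_that("ballistic motion is flagged as a poor diffusive fit", {
  top <- bead_topology(1, 1, radius = 0.1)
  frames <- lapply(0:99, function(i) {
    frame(matrix(c(1 + 0.01 * i, 1, 1), 1), c(50, 50, 50), i * 100)
  })
  est <- diffusion_coefficient_msd(trajectory(top, frames))
  expect_true(est$poor_fit)
  expect_gt(est$alpha, 1.5)
})

test_that("radius of gyration of cube corners is a*sqrt(3)", {
  a <- 1.3
  xyz <- as.matrix(expand.grid(c(-a, a), c(-a, a), c(-a, a))) + 10
  top <- bead_topology(1, 8, radius = 0.1)
  expect_equal(radius_of_gyration(frame(xyz, c(50, 50, 50)), top, 1),
               a * sqrt(3))
  # invariant under wrapping the molecule across the boundary
  xyz2 <- sweep(xyz, 2, c(40.5, 0, 0), `+`) %% 50
  expect_equal(radius_of_gyration(frame(xyz2, c(50, 50, 50)), top, 1),
               a * sqrt(3))
})
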