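test_that("pair energies evaluate the closed forms", {
  plain <- nonbonded_params(electrostatics = "plain_cutoff")
  rf <- nonbonded_params(electrostatics = "reaction_field", eps_rf = 65)
  # two +1e charges at 1 nm, Coulomb only
  expect_equal(pair_energy(1, 1, 1, 0.3, 0, plain), 138.935458,
               tolerance = 1e-6)
  # Lennard-Jones: zero at sigma, -eps at the minimum
  expect_equal(pair_energy(0.3, 0, 0, 0.3, 0.8, plain), 0)
  expect_equal(pair_energy(2^(1 / 6) * 0.3, 0, 0, 0.3, 0.8, plain), -0.8)
  # reaction-field Coulomb vanishes exactly at the cutoff
  expect_equal(pair_energy(1.4, 1, -1, 0, 0, rf), 0)
  # and is continuous approaching it
  expect_lt(abs(pair_energy(1.4 - 1e-9, 1, -1, 0, 0, rf)), 1e-6)
  # beyond the cutoff everything is zero
  expect_equal(pair_energy(1.5, 1, 1, 0.3, 0.8, rf), 0)
  expect_error(pair_energy(0, 1, 1, 0.3, 0.8, rf), "positive")
  expect_error(nonbonded_params(eps_rf = 0.5), "eps_rf")
})

test_that("reaction field converges to plain cutoff as eps_rf -> eps_inner", {
  r <- seq(0.2, 1.3, by = 0.1)
  plain <- nonbonded_params(electrostatics = "plain_cutoff")
  near <- nonbonded_params(eps_rf = 1 + 1e-9)
  e_rf <- pair_energy(r, 0.5, -0.8, 0, 0, near)
  # the limit is the plain Coulomb shifted by -f q1 q2 c_rf, c_rf -> 1/rc
  e_plain_shifted <- pair_energy(r, 0.5, -0.8, 0, 0, plain) -
    138.935458 * 0.5 * (-0.8) / 1.4
  expect_equal(e_rf, e_plain_shifted, tolerance = 1e-6)
})

test_that("a 3-atom system equals hand-summed pair energies", {
  at <- data.frame(
    name = c("P", "S1", "S2"), element = "X", resid = 1L,
    resname = c("PRO", "SOL", "SOL"), molecule = 1:3,
    group = c("protein", "solvent", "solvent"),
    charge = c(0.4, -0.3, -0.1), sigma = c(0.3, 0.25, 0.25),
    epsilon = c(0.6, 0.4, 0.4), stringsAsFactors = FALSE
  )
  top <- topology(at)
  f <- frame(rbind(c(1, 1, 1), c(1.5, 1, 1), c(1, 1.8, 1)), c(6, 6, 6))
  params <- nonbonded_params()
  hand_pair <- function(i, j, r) {
    pair_energy(r, at$charge[i], at$charge[j],
                sqrt(at$sigma[i] * at$sigma[j]),
                sqrt(at$epsilon[i] * at$epsilon[j]), params)
  }
  e <- frame_energy_decomposition(f, top, params)
  expect_equal(e$E_pp, 0)
  expect_equal(e$E_ps, hand_pair(1, 2, 0.5) + hand_pair(1, 3, 0.8))
  expect_equal(e$E_ss, hand_pair(2, 3, sqrt(0.5^2 + 0.8^2)))
  expect_equal(e$E_total, e$E_pp + e$E_ps + e$E_ss)
})

test_that("decomposition closure and rigid invariance hold on random frames", {
  set.seed(171)
  top <- bead_topology(3, 4, radius = 0.15, charge = c(0.2, -0.2, 0.1, -0.1),
                       sigma = 0.3, epsilon = 0.5)
  top$atoms$group[9:12] <- "solvent"
  params <- nonbonded_params(cutoff = 1.2)
  for (i in 1:10) {
    xyz <- matrix(runif(36, 0, 4), ncol = 3)
    f <- frame(xyz, c(4, 4, 4))
    e <- frame_energy_decomposition(f, top, params)
    expect_equal(e$E_pp + e$E_ps + e$E_ss, e$E_total, tolerance = 1e-12)
    shifted <- frame(sweep(xyz, 2, c(1.7, -2.2, 0.9), `+`), f$box)
    e2 <- frame_energy_decomposition(shifted, top, params)
    expect_equal(e2$E_total, e$E_total, tolerance = 1e-9)
    wrapped <- frame(xyz %% 4, f$box)
    e3 <- frame_energy_decomposition(wrapped, top, params)
    expect_equal(e3$E_total, e$E_total, tolerance = 1e-9)
  }
})

test_that("bonded 1-2 and 1-3 pairs are excluded from nonbonded sums", {
  top <- bead_topology(1, 3, radius = 0.15, charge = 0.5, sigma = 0.3,
                       epsilon = 0.5)
  f <- frame(rbind(c(1, 1, 1), c(1.3, 1, 1), c(1.6, 1, 1)), c(6, 6, 6))
  e <- frame_energy_decomposition(f, top, nonbonded_params())
  expect_equal(e$E_total, 0)  # all three pairs are 1-2 or 1-3
})

test_that("delta E averages aggregated minus monomeric frames", {
  n_frames <- 50
  sizes <- c(rep(list(rep(4L, 4)), 25), rep(list(rep(1L, 4)), 25))
  os <- stub_oligomer_series(sizes)
  en <- data.frame(E_pp = rep(c(-8, -1), each = 25),
                   E_ps = rep(c(-1, -2), each = 25),
                   E_ss = rep(c(-1, -1), each = 25))
  en$E_total <- en$E_pp + en$E_ps + en$E_ss
  res <- delta_E_aggregation(os, en)
  expect_equal(res$n_trajectories, 1L)
  expect_equal(unname(res$delta["E_total"]), -6)
  expect_equal(unname(res$delta["E_pp"]), -7)
  expect_equal(unname(res$delta["E_ps"]), 1)
  expect_equal(unname(res$delta["E_pp"] + res$delta["E_ps"] +
                        res$delta["E_ss"]),
               unname(res$delta["E_total"]))
})

test_that("trajectories need more than 20 snapshots of both states", {
  mk <- function(n_agg, n_mono) {
    sizes <- c(rep(list(rep(4L, 4)), n_agg), rep(list(rep(1L, 4)), n_mono),
               rep(list(c(2L, 2L, 1L, 1L)), 5))
    os <- stub_oligomer_series(sizes)
    n <- n_agg + n_mono + 5
    en <- data.frame(E_pp = rnorm(n), E_ps = rnorm(n), E_ss = rnorm(n))
    en$E_total <- en$E_pp + en$E_ps + en$E_ss
    list(os = os, en = en)
  }
  set.seed(181)
  a <- mk(25, 19)  # 19 monomeric snapshots: excluded
  res <- delta_E_aggregation(a$os, a$en)
  expect_equal(res$n_trajectories, 0L)
  expect_true(all(is.na(res$delta)))
  b <- mk(25, 20)  # exactly 20 is still not "more than 20"
  expect_equal(delta_E_aggregation(b$os, b$en)$n_trajectories, 0L)
  d <- mk(25, 21)
  expect_equal(delta_E_aggregation(d$os, d$en)$n_trajectories, 1L)
})
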