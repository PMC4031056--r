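test_that("minimum-image distance matches brute force over 27 images", {
  box <- c(1, 1, 1)
  expect_equal(minimum_image_distance(c(0.05, 0, 0), c(0.95, 0, 0), box),
               0.10)
  expect_equal(minimum_image_distance(c(0.3, 0.3, 0.3), c(0.3, 0.3, 0.3),
                                      box), 0)
  expect_equal(minimum_image_distance(c(0, 0, 0), c(0.5, 0.5, 0.5), box),
               sqrt(3) / 2)
  set.seed(21)
  for (i in 1:50) {
    b <- runif(3, 0.5, 3)
    x1 <- runif(3, -3, 6); x2 <- runif(3, -3, 6)
    expect_equal(minimum_image_distance(x1, x2, b),
                 min_image_27(x1 - b * floor(x1 / b),
                              x2 - b * floor(x2 / b), b),
                 tolerance = 1e-12)
  }
})

test_that("contact rule is boundary-inclusive at the cutoff", {
  top <- bead_topology(2, 1, radius = 0.05)
  near <- frame(rbind(c(1, 1, 1), c(1.39, 1, 1)), c(5, 5, 5))
  far <- frame(rbind(c(1, 1, 1), c(1.41, 1, 1)), c(5, 5, 5))
  cg <- frame_contacts(near, top, cutoff = 0.4)
  expect_equal(cg$n_contacts, 1L)
  expect_equal(nrow(cg$edges), 1L)
  expect_equal(frame_contacts(far, top, cutoff = 0.4)$n_contacts, 0L)
})

test_that("hydrogens bonded to heavy atoms are contact-eligible", {
  at <- data.frame(
    name = c("C1", "H1", "C1", "H1"),
    element = c("C", "H", "C", "H"),
    resid = 1L, resname = "MOL", molecule = c(1L, 1L, 2L, 2L),
    group = "protein", stringsAsFactors = FALSE
  )
  top <- topology(at, bonds = rbind(c(1L, 2L), c(3L, 4L)))
  # only the two hydrogens are within the cutoff
  f <- frame(rbind(c(1, 1, 1), c(1.1, 1, 1),
                   c(1.6, 1, 1), c(1.5, 1, 1)), c(6, 6, 6))
  expect_equal(frame_contacts(f, top, cutoff = 0.4)$n_contacts, 1L)
  # without bond information hydrogens are ineligible until attached
  top2 <- topology(at)
  expect_equal(frame_contacts(f, top2, cutoff = 0.4)$n_contacts, 0L)
  # the proximity fallback restores their attachment
  top3 <- assign_bonded_heavy(top2, f)
  expect_equal(frame_contacts(f, top3, cutoff = 0.4)$n_contacts, 1L)
})

test_that("cell list and all-pairs scans agree on random periodic frames", {
  set.seed(31)
  for (i in 1:100) {
    n_mol <- sample(2:5, 1)
    beads <- sample(5:15, 1)
    side <- runif(1, 1.5, 4)
    rf <- random_bead_frame(n_mol, beads, side)
    cutoff <- runif(1, 0.2, min(0.45, side / 2 * 0.9))
    a <- frame_contacts(rf$frame, rf$topology, cutoff, method = "cell",
                        residue_map = TRUE)
    b <- frame_contacts(rf$frame, rf$topology, cutoff, method = "brute",
                        residue_map = TRUE)
    expect_identical(a$n_contacts, b$n_contacts)
    expect_identical(a$edges, b$edges)
    expect_identical(a$residue_pairs, b$residue_pairs)
  }
})

test_that("contacts are invariant to rigid translation and box wrapping", {
  set.seed(41)
  rf <- random_bead_frame(4, 10, 3)
  ref <- frame_contacts(rf$frame, rf$topology, 0.4)
  shift <- c(1.23, -4.56, 7.89)
  shifted <- frame(sweep(rf$frame$xyz, 2, shift, `+`), rf$frame$box)
  wrapped_xyz <- rf$frame$xyz
  sel <- rf$topology$atoms$molecule == 2
  wrapped_xyz[sel, 1] <- wrapped_xyz[sel, 1] + 3  # wrap molecule 2 by a box
  wrapped <- frame(wrapped_xyz, rf$frame$box)
  for (f2 in list(shifted, wrapped)) {
    cg <- frame_contacts(f2, rf$topology, 0.4)
    expect_identical(cg$n_contacts, ref$n_contacts)
    expect_identical(cg$edges, ref$edges)
  }
})

test_that("molecule- and residue-level contact counts are symmetric", {
  set.seed(51)
  rf <- random_bead_frame(3, 12, 2.5)
  cg <- frame_contacts(rf$frame, rf$topology, 0.4, residue_map = TRUE)
  expect_identical(cg$residue_pairs, t(cg$residue_pairs))
  expect_true(all(cg$edges$mol_i < cg$edges$mol_j))
  expect_equal(sum(cg$edges$n_contacts), cg$n_contacts)
})

test_that("a cutoff at half the box side falls back with a warning", {
  rf <- random_bead_frame(2, 3, 1.0, seed = 6)
  expect_warning(frame_contacts(rf$frame, rf$topology, cutoff = 0.55),
                 "half the smallest box side")
})

test_that("log-rescaled contact map sets zero at the most-contacted pair", {
  top <- bead_topology(2, 2, radius = 0.05)
  # one frame: residue pair (1,1) once, (2,2) ten times cannot be made in
  # one frame; accumulate over frames instead
  mk <- function(d11, d22) {
    frame(rbind(c(1, 1, 1), c(5, 1, 1),
                c(1 + d11, 1, 1), c(5 + d22, 1, 1)), c(10, 10, 10))
  }
  near <- 0.2; far <- 2
  frames <- c(replicate(1, mk(near, far), simplify = FALSE),
              replicate(10, mk(far, near), simplify = FALSE))
  frames <- lapply(seq_along(frames), function(i) {
    frame(frames[[i]]$xyz, frames[[i]]$box, (i - 1) * 100)
  })
  traj <- trajectory(top, frames)
  series <- contact_timeseries(traj, cutoff = 0.4, residue_map = TRUE)
  m <- mean_residue_contact_map(series)
  expect_equal(m$counts["1", "1"], 1)
  expect_equal(m$counts["2", "2"], 10)
  expect_equal(m$transformed["2", "2"], 0)
  expect_equal(m$transformed["1", "1"], log(10))
  # uniform counts give an all-zero transform
  u <- m
  series2 <- series
  series2$residue_pair_sum[] <- 4
  expect_true(all(mean_residue_contact_map(series2)$transformed == 0))
  # zero-count pairs are handled by the pseudo-count, not -Inf
  expect_true(all(is.finite(m$transformed)))
})
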