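test_that("internal dialect round-trips trajectories bit-identically", {
  set.seed(42)
  top <- bead_topology(3, 4, radius = 0.2)
  frames <- lapply(0:9, function(i) {
    frame(matrix(runif(36, 0, 5), ncol = 3), c(5, 5, 5), time = i * 100)
  })
  traj <- trajectory(top, frames)
  path <- withr::local_tempfile(fileext = ".xyzx")
  write_trajectory(traj, path)
  back <- read_trajectory(path, top, format = "internal")
  expect_equal(length(back$frames), 10L)
  expect_identical(back$frame_interval, 100)
  for (i in 1:10) {
    expect_identical(back$frames[[i]]$xyz, traj$frames[[i]]$xyz)
    expect_identical(back$frames[[i]]$box, traj$frames[[i]]$box)
  }
})

test_that("internal topology round-trips exactly", {
  top <- bead_topology(2, 3, radius = 0.3, charge = c(0.25, -0.5, 0.25))
  top$sequences <- c("ABC", "ABC")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_topology(top, path)
  back <- read_topology(path, format = "internal")
  expect_identical(back$atoms, top$atoms)
  expect_identical(back$bonds, top$bonds)
  expect_identical(back$sequences, top$sequences)
})

test_that("PDB round trip is exact to the format's printed precision", {
  set.seed(7)
  top <- bead_topology(2, 5, radius = 0.2)
  frames <- lapply(0:2, function(i) {
    frame(matrix(runif(30, 0, 8), ncol = 3), c(8, 8, 8), time = i * 100)
  })
  traj <- trajectory(top, frames)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(traj, path, format = "pdb")
  back <- read_trajectory(path, top, format = "pdb")
  expect_equal(length(back$frames), 3L)
  dev <- max(abs(back$frames[[2]]$xyz - traj$frames[[2]]$xyz))
  expect_lte(dev, 5e-4)  # PDB prints 3 decimals in Angstrom
  expect_equal(back$frames[[1]]$box, c(8, 8, 8), tolerance = 1e-6)
})

test_that("GRO round trip holds box and coordinates to 3 decimals in nm", {
  set.seed(8)
  top <- bead_topology(2, 2, radius = 0.2)
  traj <- trajectory(top, list(
    frame(matrix(runif(12, 0, 4), ncol = 3), c(4, 4, 4), 0),
    frame(matrix(runif(12, 0, 4), ncol = 3), c(4, 4, 4), 100)
  ))
  path <- withr::local_tempfile(fileext = ".gro")
  write_trajectory(traj, path, format = "gro")
  back <- read_trajectory(path, top, format = "gro")
  expect_equal(length(back$frames), 2L)
  expect_lte(max(abs(back$frames[[1]]$xyz - traj$frames[[1]]$xyz)), 5e-4)
})

test_that("multi-chain PDB becomes one molecule per chain", {
  top <- bead_topology(4, 6, radius = 0.2)
  top$atoms$resname <- "GLY"
  top$atoms$name <- "CA"
  top$atoms$element <- "C"
  traj <- trajectory(top, list(frame(matrix(runif(72, 0, 9), ncol = 3),
                                     c(9, 9, 9), 0)))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(traj, path, format = "pdb")
  back <- read_topology(path, format = "pdb")
  expect_equal(length(unique(back$atoms$molecule)), 4L)
  expect_equal(max(back$atoms$resid), 6L)
})

test_that("elements are inferred from atom names when the column is absent", {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00",
    "ATOM      3  OD1 ASP A   2       2.000   1.000   0.000  1.00  0.00",
    "ATOM      4  SG  CYS A   2       3.000   1.000   0.000  1.00  0.00",
    "END")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, path)
  top <- read_topology(path, format = "pdb")
  expect_equal(top$atoms$element, c("N", "C", "O", "S"))
})

test_that("readers tolerate trailing whitespace and blank lines", {
  top <- bead_topology(1, 2, radius = 0.2)
  traj <- trajectory(top, list(frame(matrix(1:6 / 10, ncol = 3),
                                     c(3, 3, 3), 0)))
  path <- withr::local_tempfile(fileext = ".xyzx")
  write_trajectory(traj, path)
  txt <- readLines(path)
  writeLines(c(txt, "", "   ", ""), path)
  back <- read_trajectory(path, top, format = "internal")
  expect_identical(back$frames[[1]]$xyz, traj$frames[[1]]$xyz)
})

test_that("contract violations raise informative errors", {
  top <- bead_topology(1, 2, radius = 0.2)
  f <- frame(matrix(1:6 / 10, ncol = 3), c(3, 3, 3), 0)
  # non-monotone times
  expect_error(trajectory(top, list(f, frame(f$xyz, f$box, 0))),
               "increasing")
  # atom-count mismatch
  traj <- trajectory(top, list(f))
  path <- withr::local_tempfile(fileext = ".xyzx")
  write_trajectory(traj, path)
  expect_error(read_trajectory(path, bead_topology(1, 3), "internal"),
               "mismatch")
  # triclinic boxes unsupported
  expect_error(frame(matrix(1:6 / 10, ncol = 3),
                     c(3, 0.1, 0, 0, 3, 0, 0, 0, 3)), "triclinic")
  # missing molecule assignment is never silently one molecule
  at <- data.frame(name = "CA", element = "C", resid = 1L,
                   resname = "GLY", molecule = NA_integer_,
                   group = "protein")
  expect_error(topology(at), "molecule")
})

test_that("an empty trajectory writes a valid empty file", {
  top <- bead_topology(1, 1)
  traj <- structure(list(topology = top, frames = list(),
                         frame_interval = NA_real_),
                    class = "trajectory")
  path <- withr::local_tempfile(fileext = ".xyzx")
  write_trajectory(traj, path)
  expect_true(file.exists(path))
  expect_equal(length(readLines(path)), 0L)
})
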