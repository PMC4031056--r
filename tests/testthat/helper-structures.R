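# shared fixtures, built in code

villin_sequence <- "MLSDEDFKAVFGMTRSAFANLPLWKQQNLKKEKGLF"

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# NeRF chain extension: place D bonded to C with |CD| = r, angle B-C-D and
# dihedral A-B-C-D
place_atom <- function(A, B, C, r, angle, dihedral) {
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  n <- cross3(B - A, bc); n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  ang <- pi - angle
  d <- r * c(cos(ang), sin(ang) * cos(dihedral), sin(ang) * sin(dihedral))
  C + d[1] * bc + d[2] * m + d[3] * n
}

# poly-alanine backbone (N, CA, C, O per residue) at given phi/psi, built
# from ideal bond lengths and angles; coordinates in nm
build_backbone <- function(L, phi = -57, psi = -47) {
  deg <- pi / 180
  coords <- vector("list", L)
  N <- c(0, 0, 0); CA <- c(1.458, 0, 0)
  C <- place_atom(c(0, 1, 0), N, CA, 1.525, 111.2 * deg, phi * deg)
  for (i in seq_len(L)) {
    if (i > 1) {
      prev <- coords[[i - 1]]
      N <- place_atom(prev$N, prev$CA, prev$C, 1.329, 116.2 * deg,
                      psi * deg)
      CA <- place_atom(prev$CA, prev$C, N, 1.458, 121.7 * deg, pi)
      C <- place_atom(prev$C, N, CA, 1.525, 111.2 * deg, phi * deg)
      coords[[i - 1]]$O <- place_atom(N, prev$CA, prev$C, 1.231,
                                      122.7 * deg, pi)
    }
    coords[[i]] <- list(N = N, CA = CA, C = C)
  }
  coords[[L]]$O <- place_atom(coords[[L]]$N, coords[[L]]$CA, coords[[L]]$C,
                              1.231, 120.8 * deg, (psi + 180) * deg)
  xyz <- do.call(rbind, lapply(coords, function(r) {
    rbind(r$N, r$CA, r$C, r$O)
  }))
  at <- data.frame(
    name = rep(c("N", "CA", "C", "O"), L),
    element = rep(c("N", "C", "C", "O"), L),
    resid = rep(seq_len(L), each = 4L), resname = "ALA",
    molecule = 1L, group = "protein", stringsAsFactors = FALSE
  )
  list(topology = topology(at), frame = frame(xyz / 10, c(100, 100, 100)))
}

# random multi-molecule bead frame for contact property tests
random_bead_frame <- function(n_molecules, beads, box_side, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  top <- bead_topology(n_molecules, beads, radius = 0.1)
  xyz <- matrix(runif(n_molecules * beads * 3L, 0, box_side),
                ncol = 3L)
  list(topology = top, frame = frame(xyz, rep(box_side, 3L)))
}

# brute-force minimum-image distance over all 27 periodic translations
min_image_27 <- function(x1, x2, box) {
  best <- Inf
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    d <- x1 - (x2 + c(i, j, k) * box)
    best <- min(best, sqrt(sum(d * d)))
  }
  best
}

# contact-series stub for kinetics tests: one molecule pair with a given
# per-frame contact indicator
stub_contact_series <- function(contact, dt_ps = 100, n_molecules = 2L,
                                pair = c(1L, 2L)) {
  F <- length(contact)
  mols <- seq_len(n_molecules)
  prs <- which(upper.tri(matrix(0, n_molecules, n_molecules)),
               arr.ind = TRUE)
  pairs <- cbind(mols[prs[, 1L]], mols[prs[, 2L]])
  counts <- matrix(0L, F, nrow(pairs))
  p <- which(pairs[, 1L] == pair[1L] & pairs[, 2L] == pair[2L])
  counts[, p] <- as.integer(contact)
  structure(list(times = (seq_len(F) - 1L) * dt_ps, molecules = mols,
                 pairs = pairs, counts = counts,
                 total = rowSums(counts), frame_interval = dt_ps),
            class = "contact_series")
}

# oligomer-series stub from a per-frame vector of component size layouts
stub_oligomer_series <- function(size_rows, dt_ps = 100) {
  m <- do.call(rbind, size_rows)
  structure(list(times = (seq_len(nrow(m)) - 1L) * dt_ps,
                 molecules = seq_len(ncol(m)),
                 membership = m * 0L, molecule_size = m,
                 free_fraction = rowMeans(m == 1L),
                 n_molecules = ncol(m)),
            class = "oligomer_series")
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# brute-force RMSD minimization over rotation space: coarse Euler grid
# followed by Nelder-Mead refinement
grid_refine_rmsd <- function(A, B) {
  A <- sweep(A, 2, colMeans(A)); B <- sweep(B, 2, colMeans(B))
  euler <- function(p) {
    cx <- cos(p[1]); sx <- sin(p[1])
    cy <- cos(p[2]); sy <- sin(p[2])
    cz <- cos(p[3]); sz <- sin(p[3])
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  obj <- function(p) sqrt(mean(rowSums((A %*% t(euler(p)) - B)^2)))
  g <- seq(0, 2 * pi, length.out = 9)[-9]
  best <- NULL; bestv <- Inf
  for (a in g) for (b in g[g < pi + 0.1]) for (c in g) {
    v <- obj(c(a, b, c))
    if (v < bestv) { bestv <- v; best <- c(a, b, c) }
  }
  stats::optim(best, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))$value
}

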