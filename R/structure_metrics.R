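#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Least-squares superposition of `mobile` onto `reference` with a proper
#' rotation (det = +1), via singular value decomposition of the covariance
#' matrix. Distances keep the unit of the input coordinates.
#'
#' @param mobile,reference numeric matrices, one point per row, equal row
#'   counts, at least 3 non-collinear points
#' @return list with `rotation` (3x3), `translation` (length 3, applied
#'   after rotation of the centered mobile set), `rmsd`, and `transformed`
#'   (the superposed mobile coordinates)
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference)) {
    stop(sprintf("point-count mismatch: mobile has %d, reference has %d",
                 nrow(mobile), nrow(reference)))
  }
  if (nrow(mobile) < 3L) stop("need at least 3 points")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2L, cm)
  B <- sweep(reference, 2L, cr)
  scale <- max(svd(A)$d[1L], svd(B)$d[1L], .Machine$double.eps)
  if (svd(A)$d[2L] / scale < 1e-9 && svd(B)$d[2L] / scale < 1e-9) {
    stop("degenerate (collinear) point sets: rotation is underdetermined")
  }
  H <- crossprod(A, B)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  transformed <- A %*% t(rot) + matrix(cr, nrow(A), 3L, byrow = TRUE)
  list(rotation = rot, translation = cr,
       rmsd = sqrt(mean(rowSums((transformed - reference)^2))),
       transformed = transformed)
}

#' Backbone RMSD of one molecule from a reference frame
#'
#' Superposes the backbone heavy atoms (N, CA, C, O) of the molecule onto
#' the reference with [kabsch_superpose()] and reports the fitted RMSD in
#' Angstrom (coordinates are stored in nm).
#'
#' @param frame a frame
#' @param reference the reference frame (same topology layout)
#' @param topology the matching topology
#' @param molecule molecule id; the reference is indexed with the same
#'   atom selection unless `reference_molecule` is given
#' @param reference_molecule molecule id within the reference frame
#' @return RMSD in Angstrom
#' @export
backbone_rmsd <- function(frame, reference, topology, molecule = NULL,
                          reference_molecule = NULL) {
  at <- topology$atoms
  if (is.null(molecule)) molecule <- molecules_of_group(topology)[1L]
  if (is.null(reference_molecule)) reference_molecule <- molecule
  bbsel <- function(m) {
    which(at$molecule == m & at$is_backbone & at$is_heavy)
  }
  kabsch_superpose(frame$xyz[bbsel(molecule), , drop = FALSE] * 10,
                   reference$xyz[bbsel(reference_molecule), , drop = FALSE] *
                     10)$rmsd
}

# Backbone atom coordinates (Angstrom) per residue of one molecule,
# as a list of L x 3 matrices with NA rows where an atom is missing.
backbone_coords_A <- function(frame, topology, molecule) {
  at <- topology$atoms
  sel <- at$molecule == molecule & at$group == "protein"
  L <- max(at$resid[sel])
  get <- function(name) {
    m <- matrix(NA_real_, L, 3L)
    idx <- which(sel & at$name == name)
    m[at$resid[idx], ] <- frame$xyz[idx, , drop = FALSE] * 10
    m
  }
  list(N = get("N"), CA = get("CA"), C = get("C"), O = get("O"), L = L)
}

#' Alpha-helix labels by the Kabsch-Sander hydrogen-bond rules
#'
#' Backbone amide hydrogens are reconstructed 1.0 Angstrom from N opposite
#' the preceding carbonyl C=O. The Kabsch-Sander electrostatic hydrogen-bond
#' energy E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN) kcal/mol
#' defines a bond when E < -0.5 kcal/mol. A 4-turn at residue i exists when
#' N-H of residue i+4 bonds the C=O of residue i; two consecutive 4-turns
#' (at i-1 and i) label residues i..i+3 as alpha-helical ('H'). Only the
#' 'H' state is assigned (3-10 and pi helices and strands are not).
#'
#' @param frame a frame
#' @param topology the matching topology
#' @param molecule molecule id
#' @return logical vector, one entry per residue, TRUE where alpha-helical
#' @export
alpha_labels <- function(frame, topology, molecule) {
  bb <- backbone_coords_A(frame, topology, molecule)
  L <- bb$L
  complete <- !apply(is.na(bb$N) | is.na(bb$CA) | is.na(bb$C) | is.na(bb$O),
                     1L, any)
  if (any(!complete)) {
    warning("residue(s) with missing backbone atoms skipped: ",
            paste(which(!complete), collapse = ", "))
  }
  # amide H of residue i, i >= 2: anti to the C=O of residue i - 1
  H <- matrix(NA_real_, L, 3L)
  for (i in 2:L) {
    if (!complete[i] || !complete[i - 1L]) next
    co <- bb$C[i - 1L, ] - bb$O[i - 1L, ]
    H[i, ] <- bb$N[i, ] + co / sqrt(sum(co^2))
  }
  hbond <- function(donor, acceptor) {
    # N-H of `donor` to C=O of `acceptor`
    if (donor < 2L || donor > L || acceptor < 1L) return(FALSE)
    if (!complete[donor] || !complete[acceptor] || anyNA(H[donor, ])) {
      return(FALSE)
    }
    dist <- function(a, b) sqrt(sum((a - b)^2))
    r_on <- dist(bb$O[acceptor, ], bb$N[donor, ])
    r_ch <- dist(bb$C[acceptor, ], H[donor, ])
    r_oh <- dist(bb$O[acceptor, ], H[donor, ])
    r_cn <- dist(bb$C[acceptor, ], bb$N[donor, ])
    if (min(r_on, r_ch, r_oh, r_cn) < 0.5) return(TRUE)  # clash: bonded
    e <- 0.084 * 332 * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
    e < -0.5
  }
  turn4 <- rep(FALSE, L)
  for (i in seq_len(max(0L, L - 4L))) turn4[i] <- hbond(i + 4L, i)
  helix <- rep(FALSE, L)
  for (i in 2:max(2L, L - 4L)) {
    if (turn4[i - 1L] && turn4[i]) helix[i:(i + 3L)] <- TRUE
  }
  helix
}

#' Count residues in alpha-helical conformation
#'
#' @param frame a frame
#' @param topology the matching topology
#' @param molecule molecule id(s); default all protein molecules (counts
#'   are summed)
#' @return integer count of residues labeled 'H' by [alpha_labels()]
#' @export
count_alpha_residues <- function(frame, topology, molecule = NULL) {
  if (is.null(molecule)) molecule <- molecules_of_group(topology)
  sum(vapply(molecule, function(m) sum(alpha_labels(frame, topology, m)),
             numeric(1)))
}

#' Summed distances between core phenylalanine side-chain centers of mass
#'
#' For the three core positions (default 7, 11 and 18 of the 36-residue
#' villin headpiece), computes the mass-weighted center of mass of each
#' side chain's heavy atoms (C-beta included) and returns the sum of the
#' three pairwise distances in Angstrom. 18.0 Angstrom in the native
#' villin headpiece structure; larger values indicate a disrupted
#' hydrophobic core.
#'
#' @param frame a frame
#' @param topology the matching topology
#' @param phe_positions 1-based residue positions (length >= 2)
#' @param molecule molecule id (default: first protein molecule)
#' @return sum of pairwise center-of-mass distances, Angstrom
#' @export
sum_phe_distances <- function(frame, topology, phe_positions = c(7, 11, 18),
                              molecule = NULL) {
  at <- topology$atoms
  if (is.null(molecule)) molecule <- molecules_of_group(topology)[1L]
  coms <- t(vapply(phe_positions, function(pos) {
    sel <- which(at$molecule == molecule & at$resid == pos &
                   !at$is_backbone & at$is_heavy)
    if (length(sel) == 0L) {
      stop("no side-chain heavy atoms at position ", pos)
    }
    w <- at$mass[sel] / sum(at$mass[sel])
    colSums(frame$xyz[sel, , drop = FALSE] * w)
  }, numeric(3)))
  total <- 0
  for (a in seq_len(nrow(coms) - 1L)) {
    for (b in (a + 1L):nrow(coms)) {
      total <- total + sqrt(sum((coms[a, ] - coms[b, ])^2))
    }
  }
  total * 10  # nm -> Angstrom
}

#' Per-frame foldedness record of one molecule
#'
#' @param trajectory a trajectory
#' @param reference reference frame for the backbone RMSD
#' @param molecule molecule id (default: first protein molecule)
#' @param phe_positions core positions for [sum_phe_distances()]
#' @param reference_molecule molecule id within the reference frame
#' @return data.frame with `time_ps`, `rmsd_A`, `n_alpha`, `sum_phe_A`
#' @export
foldedness_timeseries <- function(trajectory, reference, molecule = NULL,
                                  phe_positions = c(7, 11, 18),
                                  reference_molecule = NULL) {
  top <- trajectory$topology
  if (is.null(molecule)) molecule <- molecules_of_group(top)[1L]
  rows <- lapply(trajectory$frames, function(f) {
    data.frame(
      time_ps = f$time,
      rmsd_A = backbone_rmsd(f, reference, top, molecule,
                             reference_molecule),
      n_alpha = count_alpha_residues(f, top, molecule),
      sum_phe_A = sum_phe_distances(f, top, phe_positions, molecule)
    )
  })
  do.call(rbind, rows)
}
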