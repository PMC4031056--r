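#' @useDynLib aggtraj, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

AVOGADRO <- 6.02214076e23

#' Cubic box side length from protein concentration
#'
#' Side of the cubic simulation box holding `n_molecules` solute copies at
#' molar concentration `conc`: \eqn{(n / (c N_A))^{1/3}} converted to nm.
#' At 6 mM, 4 copies give a 10.34 nm box; at 9.2 mM, 8 copies give 11.30 nm.
#'
#' @param n_molecules number of solute molecules (>= 1)
#' @param conc molar concentration (mol/L)
#' @return box side length, nm
#' @export
box_side_from_concentration <- function(n_molecules, conc) {
  if (n_molecules < 1 || conc <= 0) {
    stop("n_molecules must be >= 1 and conc > 0")
  }
  vol_L <- n_molecules / (conc * AVOGADRO)
  vol_nm3 <- vol_L * 1e-3 * 1e27  # L -> m^3 -> nm^3
  vol_nm3^(1 / 3)
}

carbonylatable <- c("K", "R", "P")

#' Net formal charge of a peptide sequence at neutral pH
#'
#' Lysine and arginine contribute +1, aspartate and glutamate -1, histidine
#' 0 and the zwitterionic termini net 0. Carbonylated positions (K to
#' aminoadipic semialdehyde, R/P to glutamic semialdehyde) carry neutral
#' aldehyde products and contribute 0.
#'
#' @param sequence one-letter amino-acid string
#' @param carbonylation_map integer vector of 1-based carbonylated
#'   positions; each must hold K, R or P
#' @return integer net charge in elementary charges
#' @export
net_formal_charge <- function(sequence, carbonylation_map = integer(0)) {
  aa <- strsplit(toupper(sequence), "")[[1L]]
  if (!all(aa %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]])) {
    stop("sequence contains letters outside the 20-letter amino-acid alphabet")
  }
  if (length(carbonylation_map) > 0L) {
    if (any(carbonylation_map < 1L | carbonylation_map > length(aa))) {
      stop("carbonylation position out of range")
    }
    bad <- !(aa[carbonylation_map] %in% carbonylatable)
    if (any(bad)) {
      stop("carbonylation position(s) ",
           paste(carbonylation_map[bad], collapse = ", "),
           " do not hold K, R or P")
    }
    aa[carbonylation_map] <- "x"  # neutral semialdehyde product
  }
  sum(aa %in% c("K", "R")) - sum(aa %in% c("D", "E"))
}

#' Positions of carbonylatable residues (K, R, P)
#' @param sequence one-letter amino-acid string
#' @return integer vector of 1-based positions
#' @export
carbonylatable_positions <- function(sequence) {
  which(strsplit(toupper(sequence), "")[[1L]] %in% carbonylatable)
}

#' Counter-ion plan for a solvated box
#'
#' Background salt contributes `round(salt_conc * box_volume * N_A)` pairs
#' of Na+ and Cl-; charge neutrality adds `|net charge| * n_molecules`
#' extra ions of the neutralizing species (Cl- for positive solutes, Na+
#' for negative).
#'
#' @param sequence solute sequence (one-letter)
#' @param carbonylation_map carbonylated positions, as in
#'   [net_formal_charge()]
#' @param n_molecules solute copies in the box
#' @param salt_conc molar NaCl concentration
#' @param box_side box side, nm
#' @return list with `n_na`, `n_cl`, `net_charge_per_molecule`
#' @export
counter_ion_plan <- function(sequence, carbonylation_map = integer(0),
                             n_molecules, salt_conc, box_side) {
  q <- net_formal_charge(sequence, carbonylation_map)
  vol_L <- (box_side^3) * 1e-27 * 1e3  # nm^3 -> m^3 -> L
  n_salt <- round(salt_conc * vol_L * AVOGADRO)
  excess <- abs(q) * n_molecules
  list(
    n_na = n_salt + if (q < 0) excess else 0L,
    n_cl = n_salt + if (q > 0) excess else 0L,
    net_charge_per_molecule = q
  )
}

#' Filter a structural ensemble by backbone RMSD
#'
#' Keeps members whose backbone RMSD from the reference lies within one
#' standard deviation of the ensemble mean (boundaries inclusive), the rule
#' used to select starting structures for multi-copy boxes.
#'
#' @param ensemble a trajectory (>= 2 frames) of a single protein molecule
#' @param reference a frame holding the reference coordinates
#' @param topology optional topology; defaults to `ensemble$topology`
#' @return list with `kept` (integer frame indices), `rmsd` (all RMSDs, in
#'   the coordinate unit of the frames), `mean`, `sd`
#' @export
filter_ensemble_by_rmsd <- function(ensemble, reference, topology = NULL) {
  if (length(ensemble$frames) < 2L) {
    stop("ensemble must contain at least 2 frames")
  }
  top <- if (is.null(topology)) ensemble$topology else topology
  bb <- which(top$atoms$is_backbone & top$atoms$is_heavy &
                top$atoms$group == "protein")
  if (length(bb) < 3L) stop("fewer than 3 backbone heavy atoms in topology")
  ref_xyz <- reference$xyz[bb, , drop = FALSE]
  rmsd <- vapply(ensemble$frames, function(f) {
    kabsch_superpose(f$xyz[bb, , drop = FALSE], ref_xyz)$rmsd
  }, numeric(1))
  mu <- mean(rmsd)
  sigma <- stats::sd(rmsd)
  kept <- which(rmsd >= mu - sigma & rmsd <= mu + sigma)
  if (length(kept) == 0L) stop("degenerate ensemble: no frame within one sd")
  list(kept = kept, rmsd = rmsd, mean = mu, sd = sigma)
}
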