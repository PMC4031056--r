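#' Build a system topology
#'
#' A topology is the static description of a simulated system: an ordered
#' atom table partitioned into molecules, each molecule an ordered list of
#' residues. All downstream analyses (contacts, SASA, energetics, structure
#' metrics) consume this in-memory model, never raw files.
#'
#' @param atoms data.frame with one row per atom. Required columns:
#'   `name` (atom name, e.g. "CA"), `element` (chemical symbol), `resid`
#'   (1-based residue number within its molecule), `resname` (3-letter or
#'   bead residue name), `molecule` (1-based molecule index), `group` (one
#'   of `"protein"`, `"solvent"`, `"ion"`). Optional columns: `is_heavy`
#'   (derived from `element != "H"` when absent), `is_backbone` (derived
#'   from standard backbone atom names when absent), `bonded_heavy`
#'   (row index of the heavy atom a hydrogen is attached to; `NA` for heavy
#'   atoms), `charge` (elementary charges), `sigma` (nm), `epsilon`
#'   (kJ/mol), `radius` (van der Waals radius, nm; overrides the element
#'   table in SASA calculations), `mass` (u; derived from `element` when
#'   absent).
#' @param sequences optional character vector of one-letter sequences, one
#'   per protein molecule.
#' @param bonds optional two-column integer matrix of bonded atom pairs
#'   (row indices into `atoms`); used for bonded exclusions in energetics
#'   and for hydrogen attachment.
#' @return an object of class `"topology"`.
#' @export
topology <- function(atoms, sequences = NULL, bonds = NULL) {
  required <- c("name", "element", "resid", "resname", "molecule", "group")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0L) {
    stop("atom table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (!all(atoms$group %in% c("protein", "solvent", "ion"))) {
    stop("atom group must be one of 'protein', 'solvent', 'ion'")
  }
  if (anyNA(atoms$molecule)) {
    stop("every atom must be assigned to a molecule (found NA in 'molecule'); ",
         "supply a molecule map rather than relying on a default")
  }
  if (is.null(atoms$is_heavy)) atoms$is_heavy <- atoms$element != "H"
  if (is.null(atoms$is_backbone)) {
    atoms$is_backbone <- is_backbone_name(atoms$name)
  }
  if (is.null(atoms$mass)) atoms$mass <- element_mass(atoms$element)
  if (is.null(atoms$bonded_heavy)) atoms$bonded_heavy <- NA_integer_
  if (!is.null(bonds)) {
    bonds <- matrix(as.integer(bonds), ncol = 2L)
    atoms$bonded_heavy <- attach_hydrogens_from_bonds(atoms, bonds)
  }
  top <- structure(
    list(atoms = atoms, sequences = sequences, bonds = bonds),
    class = "topology"
  )
  top
}

#' @export
print.topology <- function(x, ...) {
  nmol <- length(unique(x$atoms$molecule))
  cat(sprintf("<topology: %d atoms, %d molecules (%d protein)>\n",
              nrow(x$atoms), nmol,
              length(unique(x$atoms$molecule[x$atoms$group == "protein"]))))
  invisible(x)
}

n_atoms <- function(topology) nrow(topology$atoms)

#' Molecule indices belonging to a group
#' @param topology a topology
#' @param group atom group label
#' @return sorted integer vector of molecule indices
#' @export
molecules_of_group <- function(topology, group = "protein") {
  sort(unique(topology$atoms$molecule[topology$atoms$group == group]))
}

# Backbone membership by PDB v3 atom naming. Amide/alpha hydrogens and the
# C-terminal OXT belong to the backbone group; everything else is side chain.
is_backbone_name <- function(name) {
  name %in% c("N", "CA", "C", "O", "OXT", "OT1", "OT2",
              "H", "H1", "H2", "H3", "HN", "HA", "HA1", "HA2", "HA3")
}

element_mass_table <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  "NA" = 22.990, CL = 35.45, "F" = 18.998, X = 100.0
)

element_mass <- function(element) {
  m <- element_mass_table[toupper(element)]
  m[is.na(m)] <- 100.0  # unknown/bead elements: arbitrary uniform mass
  unname(m)
}

# Bondi van der Waals radii (nm), used by the SASA module.
bondi_radius_table <- c(
  H = 0.120, C = 0.170, N = 0.155, O = 0.152, S = 0.180, P = 0.180,
  "F" = 0.147, CL = 0.175, "NA" = 0.227, X = 0.20
)

element_radius <- function(element) {
  r <- bondi_radius_table[toupper(element)]
  r[is.na(r)] <- 0.20
  unname(r)
}

attach_hydrogens_from_bonds <- function(atoms, bonds) {
  bonded_heavy <- rep(NA_integer_, nrow(atoms))
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1L]; j <- bonds[k, 2L]
    if (!atoms$is_heavy[i] && atoms$is_heavy[j]) bonded_heavy[i] <- j
    if (!atoms$is_heavy[j] && atoms$is_heavy[i]) bonded_heavy[j] <- i
  }
  h_unassigned <- which(!atoms$is_heavy & is.na(bonded_heavy))
  if (length(h_unassigned) > 0L) {
    stop("hydrogen atom(s) without a bonded heavy atom: rows ",
         paste(utils::head(h_unassigned, 5L), collapse = ", "))
  }
  bonded_heavy
}

#' Assign hydrogens to heavy atoms by proximity
#'
#' Fallback used when a topology carries no bond list: each hydrogen is
#' attached to the nearest heavy atom of the same residue within 0.12 nm in
#' the supplied frame (typically frame 1).
#'
#' @param topology a topology
#' @param frame a frame providing coordinates (nm)
#' @param max_bond_length nm; attachment threshold
#' @return the topology with `bonded_heavy` filled in
#' @export
assign_bonded_heavy <- function(topology, frame, max_bond_length = 0.12) {
  atoms <- topology$atoms
  hyd <- which(!atoms$is_heavy & is.na(atoms$bonded_heavy))
  for (i in hyd) {
    same_res <- which(atoms$is_heavy &
                        atoms$molecule == atoms$molecule[i] &
                        atoms$resid == atoms$resid[i])
    if (length(same_res) == 0L) next
    d <- sqrt(colSums((t(frame$xyz[same_res, , drop = FALSE]) -
                         frame$xyz[i, ])^2))
    j <- which.min(d)
    if (d[j] <= max_bond_length) atoms$bonded_heavy[i] <- same_res[j]
  }
  if (anyNA(atoms$bonded_heavy[!atoms$is_heavy])) {
    warning("some hydrogens could not be attached to a heavy atom; ",
            "they are excluded from contact analysis")
  }
  topology$atoms <- atoms
  topology
}

#' Construct a single trajectory frame
#'
#' @param xyz numeric matrix, one row per atom, columns x/y/z in nm
#' @param box numeric length-3 vector of orthorhombic box side lengths (nm)
#' @param time time stamp in ps
#' @return an object of class `"frame"`
#' @export
frame <- function(xyz, box, time = 0) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L) stop("xyz must have 3 columns")
  box <- as.numeric(box)
  if (length(box) == 9L) {
    m <- matrix(box, 3L, 3L)
    if (any(abs(m[upper.tri(m) | lower.tri(m)]) > 1e-12)) {
      stop("triclinic boxes are not supported (off-diagonal box elements found)")
    }
    box <- diag(m)
  }
  if (length(box) != 3L || any(box <= 0)) {
    stop("box must be 3 positive side lengths (nm)")
  }
  structure(list(time = as.numeric(time), xyz = unname(xyz), box = box),
            class = "frame")
}

#' Construct a trajectory
#'
#' @param topology a topology whose atom count matches every frame
#' @param frames list of frames, time-ordered
#' @return an object of class `"trajectory"` with `frame_interval` (ps)
#'   computed from the frame times (NA for fewer than 2 frames).
#' @export
trajectory <- function(topology, frames) {
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (length(times) > 1L) {
    if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
    dt <- diff(times)
    if (max(abs(dt - dt[1])) > 1e-6 * abs(dt[1])) {
      warning("frame spacing is not uniform; kinetics analyses will refuse ",
              "this trajectory")
      interval <- NA_real_
    } else {
      interval <- dt[1]
    }
  } else {
    interval <- NA_real_
  }
  nat <- n_atoms(topology)
  for (f in frames) {
    if (nrow(f$xyz) != nat) {
      stop(sprintf("frame has %d atoms but topology has %d", nrow(f$xyz), nat))
    }
  }
  structure(list(topology = topology, frames = frames,
                 frame_interval = interval),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %d frames, %d atoms, interval %s ps>\n",
              length(x$frames), n_atoms(x$topology),
              format(x$frame_interval)))
  invisible(x)
}

#' @export
length.trajectory <- function(x) length(x$frames)

frame_times <- function(trajectory) {
  vapply(trajectory$frames, function(f) f$time, numeric(1))
}

#' Build a coarse-grained bead topology
#'
#' Convenience constructor for the synthetic-data module and for tests:
#' `n_molecules` identical linear chains of `beads_per_molecule` beads, one
#' bead per "residue", all protein-group heavy atoms.
#'
#' @param n_molecules number of molecules
#' @param beads_per_molecule beads (residues) per molecule
#' @param radius bead van der Waals radius, nm
#' @param charge,sigma,epsilon optional per-bead nonbonded parameters,
#'   recycled across beads
#' @return a topology with consecutive beads of each chain bonded
#' @export
bead_topology <- function(n_molecules, beads_per_molecule = 1L,
                          radius = 0.5, charge = 0, sigma = 2 * radius,
                          epsilon = 0.5) {
  n <- n_molecules * beads_per_molecule
  atoms <- data.frame(
    name = rep(paste0("B", seq_len(beads_per_molecule)), n_molecules),
    element = "X",
    resid = rep(seq_len(beads_per_molecule), n_molecules),
    resname = "BEA",
    molecule = rep(seq_len(n_molecules), each = beads_per_molecule),
    group = "protein",
    is_heavy = TRUE,
    is_backbone = FALSE,
    charge = rep_len(charge, n),
    sigma = rep_len(sigma, n),
    epsilon = rep_len(epsilon, n),
    radius = rep_len(radius, n),
    stringsAsFactors = FALSE
  )
  bonds <- NULL
  if (beads_per_molecule > 1L) {
    b <- lapply(seq_len(n_molecules), function(m) {
      off <- (m - 1L) * beads_per_molecule
      cbind(off + seq_len(beads_per_molecule - 1L),
            off + 1L + seq_len(beads_per_molecule - 1L))
    })
    bonds <- do.call(rbind, b)
  }
  topology(atoms, bonds = bonds)
}
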