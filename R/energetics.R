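COULOMB_F <- 138.935458  # kJ mol^-1 nm e^-2

#' Nonbonded interaction parameters
#'
#' @param cutoff pair cutoff for both Lennard-Jones and Coulomb terms, nm
#' @param electrostatics `"plain_cutoff"` (truncated Coulomb) or
#'   `"reaction_field"` (medium beyond the cutoff modeled as a dielectric
#'   continuum; the Coulomb term is then exactly zero at the cutoff)
#' @param eps_rf reaction-field dielectric constant (must exceed
#'   `eps_inner`)
#' @param eps_inner dielectric constant inside the cutoff sphere
#' @return list of validated parameters with the derived reaction-field
#'   constants `k_rf` (nm^-3) and `c_rf` (nm^-1)
#' @export
nonbonded_params <- function(cutoff = 1.4,
                             electrostatics = c("reaction_field",
                                                "plain_cutoff"),
                             eps_rf = 65, eps_inner = 1) {
  electrostatics <- match.arg(electrostatics)
  if (cutoff <= 0) stop("cutoff must be positive")
  if (electrostatics == "reaction_field" && eps_rf <= eps_inner) {
    stop("reaction field requires eps_rf > eps_inner")
  }
  k_rf <- if (electrostatics == "reaction_field") {
    (eps_rf - eps_inner) / ((2 * eps_rf + eps_inner) * cutoff^3)
  } else {
    0
  }
  list(cutoff = cutoff, electrostatics = electrostatics,
       eps_rf = eps_rf, eps_inner = eps_inner,
       k_rf = k_rf, c_rf = 1 / cutoff + k_rf * cutoff^2)
}

#' Nonbonded pair energy
#'
#' Lennard-Jones 4 eps ((sigma/r)^12 - (sigma/r)^6) plus Coulomb
#' f q_i q_j / r, with the reaction-field correction
#' f q_i q_j (1/r + k_rf r^2 - c_rf) when enabled. Zero beyond the cutoff.
#' Vectorized over `r` and the per-pair parameters.
#'
#' @param r pair distance(s), nm (> 0)
#' @param q_i,q_j partial charges, e
#' @param sigma_ij combined Lennard-Jones sigma, nm
#' @param eps_ij combined Lennard-Jones epsilon, kJ/mol
#' @param params a [nonbonded_params()] list
#' @return energy, kJ/mol
#' @export
pair_energy <- function(r, q_i, q_j, sigma_ij, eps_ij,
                        params = nonbonded_params()) {
  if (any(r <= 0)) stop("pair distance must be positive")
  sr6 <- (sigma_ij / r)^6
  lj <- 4 * eps_ij * (sr6 * sr6 - sr6)
  coul <- if (params$electrostatics == "reaction_field") {
    COULOMB_F * q_i * q_j *
      (1 / r + params$k_rf * r^2 - params$c_rf) / params$eps_inner
  } else {
    COULOMB_F * q_i * q_j / (r * params$eps_inner)
  }
  ifelse(r > params$cutoff, 0, lj + coul)
}

# rows (i, j) of atom pairs within `2 + extra` bonds of each other
bonded_exclusions <- function(topology, n_atoms) {
  bonds <- topology$bonds
  if (is.null(bonds) || nrow(bonds) == 0L) {
    return(matrix(integer(0), 0L, 2L))
  }
  nb <- vector("list", n_atoms)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1L]; j <- bonds[k, 2L]
    nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
  }
  out <- list()
  for (i in seq_len(n_atoms)) {
    one <- nb[[i]]
    two <- unique(unlist(nb[one]))
    ex <- setdiff(unique(c(one, two)), i)
    ex <- ex[ex > i]
    if (length(ex)) out[[length(out) + 1L]] <- cbind(i, ex)
  }
  if (length(out) == 0L) return(matrix(integer(0), 0L, 2L))
  do.call(rbind, out)
}

#' Group-decomposed nonbonded energy of one frame
#'
#' Sums [pair_energy()] over all minimum-image atom pairs within the
#' cutoff, assigning each pair to the protein-protein (pp),
#' protein-solvent (ps) or solvent-solvent (ss) class by the group labels
#' of its atoms (ions count as solvent). Pairs separated by one or two
#' bonds are excluded when the topology carries a bond list; no 1-4
#' scaling is applied. Lennard-Jones parameters combine geometrically.
#'
#' @param frame a frame
#' @param topology the matching topology with `charge`, `sigma`, `epsilon`
#'   columns
#' @param params a [nonbonded_params()] list
#' @return object of class `"energy_decomposition"`: list with `time`,
#'   `E_pp`, `E_ps`, `E_ss`, `E_total` (kJ/mol); the three components sum
#'   to the total by construction
#' @export
frame_energy_decomposition <- function(frame, topology,
                                       params = nonbonded_params()) {
  at <- topology$atoms
  need <- c("charge", "sigma", "epsilon")
  if (!all(need %in% names(at)) ||
      anyNA(at$charge) || anyNA(at$sigma) || anyNA(at$epsilon)) {
    stop("energetics requires charge, sigma and epsilon for every atom")
  }
  n <- nrow(at)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  excl <- bonded_exclusions(topology, n)
  if (nrow(excl) > 0L) {
    key <- idx[, 1L] + n * idx[, 2L]
    bad <- key %in% (excl[, 1L] + n * excl[, 2L])
    idx <- idx[!bad, , drop = FALSE]
  }
  d <- sweep_min_image(frame$xyz[idx[, 1L], , drop = FALSE] -
                         frame$xyz[idx[, 2L], , drop = FALSE], frame$box)
  r <- sqrt(rowSums(d * d))
  within <- r <= params$cutoff
  idx <- idx[within, , drop = FALSE]
  r <- r[within]
  i <- idx[, 1L]; j <- idx[, 2L]
  e <- pair_energy(r, at$charge[i], at$charge[j],
                   sqrt(at$sigma[i] * at$sigma[j]),
                   sqrt(at$epsilon[i] * at$epsilon[j]), params)
  is_p_i <- at$group[i] == "protein"
  is_p_j <- at$group[j] == "protein"
  E_pp <- sum(e[is_p_i & is_p_j])
  E_ss <- sum(e[!is_p_i & !is_p_j])
  E_ps <- sum(e[xor(is_p_i, is_p_j)])
  structure(list(time = frame$time, E_pp = E_pp, E_ps = E_ps, E_ss = E_ss,
                 E_total = E_pp + E_ps + E_ss),
            class = "energy_decomposition")
}

#' Energy decomposition over a trajectory
#'
#' @param trajectory a trajectory with nonbonded parameters in its
#'   topology
#' @param params a [nonbonded_params()] list
#' @return data.frame with `time_ps`, `E_pp`, `E_ps`, `E_ss`, `E_total`
#'   (kJ/mol, nonbonded terms only)
#' @export
energy_decomposition_series <- function(trajectory,
                                        params = nonbonded_params()) {
  rows <- lapply(trajectory$frames, function(f) {
    e <- frame_energy_decomposition(f, trajectory$topology, params)
    data.frame(time_ps = e$time, E_pp = e$E_pp, E_ps = e$E_ps,
               E_ss = e$E_ss, E_total = e$E_total)
  })
  do.call(rbind, rows)
}

#' Potential-energy difference between aggregated and monomeric states
#'
#' For each trajectory, frames in which all molecules form one single
#' assembly are "aggregated" and frames in which every molecule is a free
#' monomer are "non-aggregated"; the per-trajectory estimate is the mean
#' energy of the former minus the mean of the latter, for the total and
#' each group component. Trajectories are included only when both states
#' hold strictly more than `min_snapshots` frames. The result is the
#' unweighted mean across qualifying trajectories, with the sample
#' standard deviation.
#'
#' @param states an `oligomer_series` or list of them (one per trajectory)
#' @param energies a data.frame from [energy_decomposition_series()] (or
#'   any frame-aligned data.frame with columns `E_pp`, `E_ps`, `E_ss`,
#'   `E_total`), or a list of them
#' @param min_snapshots snapshot threshold; a trajectory qualifies only
#'   with more than this many frames of each state
#' @return list with `delta` (named means: E_pp, E_ps, E_ss, E_total),
#'   `sd`, `n_trajectories`, and `per_trajectory` (data.frame with the
#'   per-trajectory deltas and state counts, including non-qualifying
#'   ones flagged by `qualified`)
#' @export
delta_E_aggregation <- function(states, energies, min_snapshots = 20) {
  if (inherits(states, "oligomer_series")) states <- list(states)
  if (is.data.frame(energies)) energies <- list(energies)
  if (length(states) != length(energies)) {
    stop("need one energy table per oligomer series")
  }
  comps <- c("E_pp", "E_ps", "E_ss", "E_total")
  rows <- mapply(function(os, en) {
    if (nrow(os$membership) != nrow(en)) {
      stop("states and energies are not frame-aligned")
    }
    n <- os$n_molecules
    agg <- rowSums(os$molecule_size == n) == n
    mono <- rowSums(os$molecule_size == 1L) == n
    qualified <- sum(agg) > min_snapshots && sum(mono) > min_snapshots
    d <- vapply(comps, function(cc) {
      if (sum(agg) == 0L || sum(mono) == 0L) NA_real_
      else mean(en[[cc]][agg]) - mean(en[[cc]][mono])
    }, numeric(1))
    data.frame(n_aggregated = sum(agg), n_monomeric = sum(mono),
               qualified = qualified, t(d))
  }, states, energies, SIMPLIFY = FALSE)
  per_traj <- do.call(rbind, rows)
  ok <- per_traj$qualified
  if (!any(ok)) {
    return(list(delta = stats::setNames(rep(NA_real_, 4L), comps),
                sd = stats::setNames(rep(NA_real_, 4L), comps),
                n_trajectories = 0L, per_trajectory = per_traj))
  }
  sub <- per_traj[ok, comps, drop = FALSE]
  list(
    delta = colMeans(sub),
    sd = if (nrow(sub) > 1L) apply(sub, 2L, stats::sd)
         else stats::setNames(rep(NA_real_, 4L), comps),
    n_trajectories = sum(ok),
    per_trajectory = per_traj
  )
}
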