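#' Parameters for the synthetic aggregation simulator
#'
#' Defines a Brownian-dynamics system of `n_molecules` identical
#' bead-molecules diffusing in a periodic cubic box, with a short-range
#' sticky interaction between designated beads. Defaults emulate a
#' multi-copy protein box at millimolar concentration: 4 molecules at 6 mM
#' (10.34 nm box), a monomer diffusion coefficient of 1.2e-10 m^2/s,
#' 100-ps frame spacing and a dissociation rate near 2.2e7 /s (45 ns mean
#' bound time).
#'
#' Unbinding is controlled in one of three modes: `"markov"` (a bound pair
#' loses its attraction at the exact Poisson rate `k_off_target`, giving
#' exactly exponential ground-truth lifetimes; `k_off_target = 0` makes
#' binding irreversible), `"well"` (purely thermal escape from the
#' attractive well; see [mfpt_dissociation_time()] for the matching
#' first-passage prediction), and `"ljc"` (all interactions are
#' Lennard-Jones + Coulomb with the parameters in the topology; used to
#' validate the energy-decomposition analysis, optionally with explicit
#' solvent beads).
#'
#' @param n_molecules molecule count
#' @param conc_mM protein concentration, mM; sets the box via
#'   [box_side_from_concentration()] unless `box_side` is given
#' @param box_side box side, nm (overrides `conc_mM`)
#' @param beads_per_molecule beads per linear chain molecule
#' @param bead_radius nm
#' @param D_target molecule (center-of-mass) diffusion coefficient, m^2/s
#' @param well_depth sticky well depth, kJ/mol
#' @param k_off_target dissociation rate, /s (markov mode)
#' @param mode `"markov"`, `"well"` or `"ljc"`
#' @param sticky_positions bead positions carrying the attraction
#'   (default: all beads)
#' @param timestep_ps integration step
#' @param frame_interval_ps spacing of saved frames (multiple of the step)
#' @param n_frames saved frames (the initial configuration included)
#' @param seed RNG seed recorded with the run
#' @param kT thermal energy, kJ/mol (2.494 at 300 K)
#' @param k_rep core repulsion spring constant, kJ/mol/nm^2
#' @param well_flat flat-bottom width beyond bead contact, nm
#' @param well_switch switching width over which the well rises to 0, nm
#' @param r_release separation (nm) a pair whose attraction was switched
#'   off by a Markov unbinding event must reach before it can bind again;
#'   defaults to 1 nm beyond the outer well edge (capped at 45% of the
#'   box side) so that a fired dissociation is committed rather than
#'   immediately recrossed
#' @param charge,lj_sigma,lj_epsilon per-bead nonbonded parameters (ljc
#'   mode; recycled)
#' @param solvent optional list for ljc mode: `n`, `radius`, `charge`,
#'   `sigma`, `epsilon`
#' @param electrostatics,eps_rf ljc-mode Coulomb treatment, as in
#'   [nonbonded_params()]
#' @param cutoff ljc-mode pair cutoff, nm
#' @return validated list of class `"sim_params"`
#' @export
sim_params <- function(n_molecules = 4L, conc_mM = 6, box_side = NULL,
                       beads_per_molecule = 1L, bead_radius = 0.5,
                       D_target = 1.2e-10, well_depth = 25,
                       k_off_target = 2.2e7,
                       mode = c("markov", "well", "ljc"),
                       sticky_positions = NULL, timestep_ps = 5,
                       frame_interval_ps = 100, n_frames = 500L,
                       seed = 1L, kT = 2.494, k_rep = 500,
                       well_flat = 0.2, well_switch = 0.25,
                       r_release = NULL, charge = 0, lj_sigma = NULL, lj_epsilon = 0.5,
                       solvent = NULL,
                       electrostatics = "reaction_field", eps_rf = 65,
                       cutoff = 1.4) {
  mode <- match.arg(mode)
  if (is.null(box_side)) {
    box_side <- box_side_from_concentration(n_molecules, conc_mM * 1e-3)
  }
  if (box_side <= 4 * bead_radius) {
    stop("box side must exceed 4 bead radii")
  }
  ratio <- frame_interval_ps / timestep_ps
  if (abs(ratio - round(ratio)) > 1e-9) {
    stop("frame interval must be a multiple of the timestep")
  }
  stopifnot(n_molecules >= 1, beads_per_molecule >= 1, bead_radius > 0,
            D_target > 0, timestep_ps > 0, n_frames >= 2, kT > 0)
  if (mode == "markov" && k_off_target < 0) {
    stop("k_off_target must be >= 0 (0 means irreversible binding)")
  }
  if (is.null(sticky_positions)) {
    sticky_positions <- seq_len(beads_per_molecule)
  }
  if (is.null(lj_sigma)) lj_sigma <- 2 * bead_radius
  r_core <- 2 * bead_radius
  # overdamped integration must resolve the switching region: the drift
  # from the maximal well force and the per-step diffusive displacement
  # both need to stay well below the switch width
  D_nm2ps <- D_target * 1e6 * beads_per_molecule
  f_max <- well_depth * pi / (2 * well_switch)
  drift <- D_nm2ps / kT * f_max * timestep_ps
  if (mode != "ljc" && (drift > well_switch / 3 ||
                        sqrt(4 * D_nm2ps * timestep_ps) > well_switch)) {
    warning("timestep too coarse for the sticky-well geometry: reduce ",
            "timestep_ps or widen well_switch to avoid integration leaks")
  }
  structure(list(
    n_molecules = as.integer(n_molecules), conc_mM = conc_mM,
    box_side = box_side, beads_per_molecule = as.integer(beads_per_molecule),
    bead_radius = bead_radius, D_target = D_target,
    well_depth = well_depth, k_off_target = k_off_target, mode = mode,
    sticky_positions = as.integer(sticky_positions),
    timestep_ps = timestep_ps, frame_interval_ps = frame_interval_ps,
    n_frames = as.integer(n_frames), seed = as.integer(seed), kT = kT,
    k_rep = k_rep, r_core = r_core, r_on = r_core + well_flat,
    well_switch = well_switch,
    r_release = if (is.null(r_release)) {
      min(r_core + well_flat + well_switch + 1.0, 0.45 * box_side)
    } else {
      r_release
    },
    contact_radius = r_core + well_flat + well_switch,
    bond_length = 2 * bead_radius, k_bond = 1000,
    charge = charge, lj_sigma = lj_sigma, lj_epsilon = lj_epsilon,
    solvent = solvent, electrostatics = electrostatics, eps_rf = eps_rf,
    cutoff = cutoff
  ), class = "sim_params")
}

# evenly spread lattice centers: simple cubic for k^3, bcc for 2k^3,
# fcc for 4k^3; otherwise a maximin relaxation of random points
lattice_centers <- function(n, L) {
  if (n == 1L) return(matrix(L / 2, 1L, 3L))
  grid3 <- function(k) {
    g <- (seq_len(k) - 0.5) / k
    as.matrix(expand.grid(g, g, g))
  }
  k <- round(n^(1 / 3))
  if (k^3 == n) return(grid3(k) * L)
  k <- round((n / 2)^(1 / 3))
  if (2 * k^3 == n) {
    base <- grid3(k)
    return(rbind(base, (base + 0.5 / k) %% 1) * L)
  }
  k <- round((n / 4)^(1 / 3))
  if (4 * k^3 == n) {
    base <- (as.matrix(expand.grid(seq_len(k), seq_len(k), seq_len(k))) -
               1) / k
    fcc <- rbind(base,
                 sweep(base, 2L, c(0, 0.5, 0.5) / k, `+`),
                 sweep(base, 2L, c(0.5, 0, 0.5) / k, `+`),
                 sweep(base, 2L, c(0.5, 0.5, 0) / k, `+`))
    return((fcc %% 1) * L)
  }
  # maximin relaxation from random starting points
  X <- matrix(stats::runif(3 * n), n, 3L) * L
  for (it in seq_len(400L)) {
    moved <- FALSE
    for (i in seq_len(n)) {
      d <- sweep_min_image(X[-i, , drop = FALSE] -
                             X[rep(i, n - 1L), , drop = FALSE], rep(L, 3L))
      r <- sqrt(rowSums(d * d))
      j <- which.min(r)
      target <- L / (n^(1 / 3))
      if (r[j] < target) {
        X[i, ] <- (X[i, ] - 0.05 * d[j, ] / r[j] * L / n^(1 / 3)) %% L
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  X
}

#' Initial configuration: maximally separated, randomly oriented molecules
#'
#' Molecule centers are placed on the lattice (simple cubic, bcc or fcc
#' when the count fits one exactly) that maximizes the minimal periodic
#' center distance; chains are oriented along random directions drawn from
#' the current RNG state. Orientations are re-drawn (up to `max_attempts`)
#' until no intermolecular bead pair overlaps.
#'
#' @param params a [sim_params()] list
#' @param max_attempts orientation re-draws before giving up
#' @return a [frame()] holding the bead coordinates
#' @export
make_initial_configuration <- function(params, max_attempts = 1e4) {
  L <- params$box_side
  n <- params$n_molecules
  B <- params$beads_per_molecule
  centers <- lattice_centers(n, L)
  for (attempt in seq_len(max_attempts)) {
    xyz <- matrix(0, n * B, 3L)
    for (m in seq_len(n)) {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      offs <- (seq_len(B) - (B + 1) / 2) * params$bond_length
      xyz[(m - 1L) * B + seq_len(B), ] <-
        centers[rep(m, B), ] + outer(offs, u)
    }
    if (n == 1L) return(frame(xyz, rep(L, 3L), 0))
    ok <- TRUE
    mols <- rep(seq_len(n), each = B)
    prs <- brute_force_pairs(xyz, rep(L, 3L), params$r_core * 0.999)
    if (nrow(prs) > 0L && any(mols[prs[, 1L]] != mols[prs[, 2L]])) {
      ok <- FALSE
    }
    if (ok) return(frame(xyz, rep(L, 3L), 0))
  }
  stop("could not place molecules without overlap after ", max_attempts,
       " attempts")
}

build_sim_topology <- function(params) {
  top <- bead_topology(params$n_molecules, params$beads_per_molecule,
                       radius = params$bead_radius,
                       charge = params$charge, sigma = params$lj_sigma,
                       epsilon = params$lj_epsilon)
  if (!is.null(params$solvent)) {
    s <- params$solvent
    ns <- s$n
    sa <- data.frame(
      name = "SV", element = "X", resid = 1L, resname = "SOL",
      molecule = params$n_molecules + seq_len(ns), group = "solvent",
      is_heavy = TRUE, is_backbone = FALSE,
      charge = rep_len(if (is.null(s$charge)) 0 else s$charge, ns),
      sigma = rep_len(if (is.null(s$sigma)) 0.3 else s$sigma, ns),
      epsilon = rep_len(if (is.null(s$epsilon)) 0.5 else s$epsilon, ns),
      radius = rep_len(if (is.null(s$radius)) 0.15 else s$radius, ns),
      mass = 18, bonded_heavy = NA_integer_,
      stringsAsFactors = FALSE
    )
    at <- rbind(top$atoms, sa[names(top$atoms)])
    bonds <- top$bonds
    top <- topology(at)
    top$bonds <- bonds
  }
  top
}

#' Run the Brownian-dynamics aggregation simulator
#'
#' Overdamped Langevin dynamics: per step each bead receives a
#' deterministic displacement (D / kT) F dt and a Gaussian displacement of
#' variance 2 D dt per axis. The ground truth records every
#' binding/unbinding event of the generator's own bound-state bookkeeping
#' and the per-frame group-decomposed interaction energies. Deterministic
#' for a fixed `params$seed`.
#'
#' @param params a [sim_params()] list
#' @param output_dir optional directory; when given, the trajectory
#'   (internal dialect, `trajectory.xyzx`), topology (`topology.tsv`) and
#'   ground-truth tables (`events.tsv`, `energies.tsv`) are written there
#' @return list with `trajectory`, `topology` and `ground_truth` (list of
#'   `events`, `energies`, `params`)
#' @export
simulate_aggregation <- function(params, output_dir = NULL) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  top <- build_sim_topology(params)
  at <- top$atoms
  n_prot <- params$n_molecules * params$beads_per_molecule
  f0 <- make_initial_configuration(params)
  xyz0 <- f0$xyz
  if (!is.null(params$solvent)) {
    ns <- params$solvent$n
    sx <- place_solvent(xyz0, rep(params$box_side, 3L),
                        if (is.null(params$solvent$radius)) 0.15
                        else params$solvent$radius,
                        params$bead_radius, ns)
    xyz0 <- rbind(xyz0, sx)
  }
  sticky <- rep(FALSE, nrow(at))
  sticky[seq_len(n_prot)] <-
    at$resid[seq_len(n_prot)] %in% params$sticky_positions
  D_mol_nm2ps <- params$D_target * 1e6  # m^2/s -> nm^2/ps
  D_bead <- rep(D_mol_nm2ps * params$beads_per_molecule, nrow(at))
  if (!is.null(params$solvent)) {
    Ds <- if (is.null(params$solvent$D)) 4 * D_mol_nm2ps else
      params$solvent$D * 1e6
    D_bead[(n_prot + 1L):nrow(at)] <- Ds
  }
  bonds <- if (is.null(top$bonds)) matrix(0L, 0L, 2L) else top$bonds
  excl <- bonded_exclusions(top, nrow(at))
  if (nrow(excl) == 0L) excl <- matrix(0L, 0L, 2L)
  lj_mode <- params$mode == "ljc"
  np <- nonbonded_params(cutoff = params$cutoff,
                         electrostatics = params$electrostatics,
                         eps_rf = params$eps_rf)
  k_off_per_ps <- if (params$mode == "markov") {
    params$k_off_target * 1e-12
  } else {
    -1
  }
  save_every <- as.integer(round(params$frame_interval_ps /
                                   params$timestep_ps))
  n_steps <- (params$n_frames - 1L) * save_every
  res <- bd_simulate_cpp(
    xyz0, as.integer(at$molecule), sticky,
    as.integer(at$group == "protein"), rep(params$box_side, 3L),
    D_bead, params$timestep_ps, n_steps, save_every, params$kT,
    params$well_depth, params$r_core, params$k_rep, params$r_on,
    params$well_switch, bonds, params$k_bond, params$bond_length, excl,
    k_off_per_ps, params$r_release, lj_mode,
    at$charge, at$sigma, at$epsilon, np$cutoff, np$k_rf, np$c_rf,
    np$electrostatics == "reaction_field", 0
  )
  frames <- lapply(seq_along(res$times), function(i) {
    frame(matrix(res$frames[i, ], ncol = 3L, byrow = TRUE),
          rep(params$box_side, 3L), res$times[i])
  })
  traj <- trajectory(top, frames)
  events <- data.frame(
    mol_i = res$ev_i, mol_j = res$ev_j, t_bind_ps = res$ev_bind,
    t_unbind_ps = res$ev_unbind, censored = is.na(res$ev_unbind)
  )
  events$lifetime_ns <- (ifelse(events$censored,
                                res$times[length(res$times)],
                                events$t_unbind_ps) -
                           events$t_bind_ps) / 1000
  events <- events[order(events$t_bind_ps), , drop = FALSE]
  energies <- data.frame(
    time_ps = res$times, E_pp = res$energy[, 1L], E_ps = res$energy[, 2L],
    E_ss = res$energy[, 3L],
    E_total = rowSums(res$energy)
  )
  gt <- list(events = events, energies = energies, params = params)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_trajectory(traj, file.path(output_dir, "trajectory.xyzx"))
    write_topology(top, file.path(output_dir, "topology.tsv"))
    utils::write.table(events, file.path(output_dir, "events.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(energies, file.path(output_dir, "energies.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  list(trajectory = traj, topology = top, ground_truth = gt)
}

place_solvent <- function(protein_xyz, box, r_solv, r_prot, n_solvent,
                          max_attempts = 1e4) {
  out <- matrix(0, n_solvent, 3L)
  placed <- 0L
  attempts <- 0L
  while (placed < n_solvent) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("could not place solvent without overlap after ", max_attempts,
           " attempts")
    }
    p <- stats::runif(3) * box
    dp <- sweep_min_image(protein_xyz -
                            matrix(p, nrow(protein_xyz), 3L, byrow = TRUE),
                          box)
    if (min(rowSums(dp * dp)) < (r_prot + r_solv)^2) next
    if (placed > 0L) {
      ds <- sweep_min_image(out[seq_len(placed), , drop = FALSE] -
                              matrix(p, placed, 3L, byrow = TRUE), box)
      if (min(rowSums(ds * ds)) < (2 * r_solv)^2) next
    }
    placed <- placed + 1L
    out[placed, ] <- p
  }
  out
}

#' Simulator with attraction restricted to designated sticky residues
#'
#' Oracle system for the propensity analysis: only beads at
#' `sticky_positions` attract, so the true interaction-propensity ranking
#' is known by construction.
#'
#' @param params a [sim_params()] list
#' @param sticky_positions bead positions that attract
#' @param ... passed to [simulate_aggregation()]
#' @return as [simulate_aggregation()]
#' @export
make_sticky_profile_system <- function(params, sticky_positions, ...) {
  params$sticky_positions <- as.integer(sticky_positions)
  simulate_aggregation(params, ...)
}

# radial sticky pair potential (kJ/mol)
sticky_potential_u <- function(r, params) {
  u <- numeric(length(r))
  core <- r < params$r_core
  u[core] <- 0.5 * params$k_rep * (params$r_core - r[core])^2
  inwell <- r < params$r_on
  u[inwell] <- u[inwell] - params$well_depth
  sw <- r >= params$r_on & r < params$r_on + params$well_switch
  s <- (r[sw] - params$r_on) / params$well_switch
  u[sw] <- u[sw] - params$well_depth * 0.5 * (1 + cos(pi * s))
  u
}

#' Mean first-passage dissociation time of the attractive well
#'
#' Closed-form (quadrature) mean first-passage time of the relative radial
#' coordinate of a bound pair from the well bottom to the escape radius,
#' for overdamped dynamics in the sticky potential U(r):
#' \deqn{\tau = \frac{1}{D_{rel}} \int_{r_0}^{r_{esc}}
#'   \frac{e^{U(y)/kT}}{y^2} \int_0^y x^2 e^{-U(x)/kT} dx\, dy}
#' This is the reference against which the well-mode simulator's
#' dissociation rate can be calibrated; [well_depth_for_koff()] inverts it.
#'
#' @param params a [sim_params()] list (the sticky geometry, well depth,
#'   kT and D_target are used; the relative diffusion coefficient is twice
#'   the molecular one)
#' @param r_escape escape radius, nm (default: outer well edge)
#' @return expected dissociation time, ns
#' @export
mfpt_dissociation_time <- function(params,
                                   r_escape = params$r_on +
                                     params$well_switch) {
  D_rel <- 2 * params$D_target * 1e6  # nm^2/ps
  beta <- 1 / params$kT
  inner <- function(y) {
    vapply(y, function(yy) {
      stats::integrate(function(x) {
        x^2 * exp(-beta * sticky_potential_u(x, params))
      }, 0, yy, rel.tol = 1e-8)$value
    }, numeric(1))
  }
  outer_int <- stats::integrate(function(y) {
    exp(beta * sticky_potential_u(y, params)) / y^2 * inner(y)
  }, params$r_core, r_escape, rel.tol = 1e-7)$value
  outer_int / D_rel / 1000  # ps -> ns
}

#' Well depth achieving a target thermal dissociation rate
#'
#' @param k_off_target_s target dissociation rate, /s
#' @param params a [sim_params()] list; its `well_depth` is ignored
#' @param interval search interval for the depth, kJ/mol
#' @return well depth, kJ/mol
#' @export
well_depth_for_koff <- function(k_off_target_s, params,
                                interval = c(0.5, 60)) {
  target_ns <- 1e9 / k_off_target_s
  f <- function(eps) {
    params$well_depth <- eps
    log(mfpt_dissociation_time(params)) - log(target_ns)
  }
  stats::uniroot(f, interval)$root
}

#' Planted bound-state energy gap of the sticky Hamiltonian
#'
#' Thermal expectation of the sticky pair potential over the bound region
#' (pair distance up to `r_max`), by radial quadrature:
#' \deqn{g = \frac{\int_0^{r_{max}} U(r)\, r^2 e^{-U(r)/kT} dr}
#'             {\int_0^{r_{max}} r^2 e^{-U(r)/kT} dr}}
#' For a bound single-bead molecule pair this is the energy gap the
#' simulator plants between the bound and the free (U = 0) state, the
#' ground truth for the aggregated-minus-monomeric energy estimator.
#'
#' @param params a [sim_params()] list
#' @param r_max outer edge of the bound region, nm (default: the
#'   generator's contact radius)
#' @return expected bound-state pair energy, kJ/mol
#' @export
planted_energy_gap <- function(params, r_max = params$contact_radius) {
  beta <- 1 / params$kT
  w <- function(r) r^2 * exp(-beta * sticky_potential_u(r, params))
  num <- stats::integrate(function(r) {
    sticky_potential_u(r, params) * w(r)
  }, 0, r_max, rel.tol = 1e-9)$value
  den <- stats::integrate(w, 0, r_max, rel.tol = 1e-9)$value
  num / den
}
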