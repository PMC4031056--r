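#' Detect molecule-pair complexes with a persistence rule
#'
#' A complex is a maximal run of consecutive frames over which a molecule
#' pair is in atomic contact (at least one atomic contact per frame), of
#' duration at least `min_lifetime_ns` (default 1 ns). Shorter runs are
#' discarded. A qualifying run still in contact at the final frame is
#' recorded as censored: its true lifetime is unobserved. The lifetime of a
#' run spanning k frames is (k - 1) frame intervals.
#'
#' @param series a `contact_series` with uniform frame spacing
#' @param min_lifetime_ns persistence threshold, ns; must be at least one
#'   frame interval
#' @return data.frame of events: `mol_i`, `mol_j`, `t_start_ps`,
#'   `t_end_ps`, `lifetime_ns`, `censored`
#' @export
detect_complexes <- function(series, min_lifetime_ns = 1) {
  dt_ps <- series$frame_interval
  if (is.na(dt_ps)) {
    stop("contact series has non-uniform frame spacing; complex detection ",
         "requires a constant frame interval")
  }
  if (min_lifetime_ns * 1000 < dt_ps) {
    stop("min_lifetime must be at least one frame interval")
  }
  F <- nrow(series$counts)
  out <- list()
  for (p in seq_len(nrow(series$pairs))) {
    v <- series$counts[, p] > 0L
    if (!any(v)) next
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      life_ns <- (r$lengths[k] - 1L) * dt_ps / 1000
      if (life_ns < min_lifetime_ns) next
      out[[length(out) + 1L]] <- data.frame(
        mol_i = series$pairs[p, 1L], mol_j = series$pairs[p, 2L],
        t_start_ps = series$times[starts[k]],
        t_end_ps = series$times[ends[k]],
        lifetime_ns = life_ns,
        censored = ends[k] == F
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(mol_i = integer(0), mol_j = integer(0),
                      t_start_ps = numeric(0), t_end_ps = numeric(0),
                      lifetime_ns = numeric(0), censored = logical(0)))
  }
  ev <- do.call(rbind, out)
  ev[order(ev$t_start_ps, ev$mol_i, ev$mol_j), , drop = FALSE]
}

#' Association/dissociation kinetics summary
#'
#' Dissociation waiting time is the mean lifetime over dissociating
#' (non-censored) complexes; the censored fraction is the share of
#' complexes that never dissociate within the trajectory. Association
#' waiting times are measured per molecule from the trajectory start, or
#' from the end of its previous bound interval, to the start of its next
#' bound interval. The survival curve gives the fraction of complexes with
#' lifetime exceeding each threshold.
#'
#' @param events event table from [detect_complexes()]
#' @param t_start_ps,t_end_ps trajectory time span, ps
#' @param molecules molecule ids present (defaults to those in `events`)
#' @return list with `mean_association_ns`, `mean_dissociation_ns`,
#'   `censored_fraction`, `censored_only` (TRUE when no complex ever
#'   dissociated, leaving the dissociation mean undefined), `n_events`,
#'   `survival` (data.frame `tau_ns`, `fraction`), and
#'   `never_dissociate_fraction` (survival at the longest observable
#'   lifetime, equal to the censored fraction)
#' @export
kinetics_summary <- function(events, t_start_ps, t_end_ps,
                             molecules = NULL) {
  n_events <- nrow(events)
  diss <- events$lifetime_ns[!events$censored]
  censored_fraction <- if (n_events > 0L) mean(events$censored) else NA_real_
  mean_diss <- if (length(diss) > 0L) mean(diss) else NA_real_

  if (is.null(molecules)) molecules <- unique(c(events$mol_i, events$mol_j))
  assoc_waits <- numeric(0)
  for (m in molecules) {
    sel <- events$mol_i == m | events$mol_j == m
    if (!any(sel)) next
    iv <- events[sel, c("t_start_ps", "t_end_ps")]
    iv <- iv[order(iv$t_start_ps), , drop = FALSE]
    # merge overlapping bound intervals (a molecule can be in several
    # complexes at once)
    merged <- iv[1L, , drop = FALSE]
    if (nrow(iv) > 1L) {
      for (k in 2:nrow(iv)) {
        last <- nrow(merged)
        if (iv$t_start_ps[k] <= merged$t_end_ps[last]) {
          merged$t_end_ps[last] <- max(merged$t_end_ps[last], iv$t_end_ps[k])
        } else {
          merged <- rbind(merged, iv[k, ])
        }
      }
    }
    free_from <- t_start_ps
    for (k in seq_len(nrow(merged))) {
      assoc_waits <- c(assoc_waits, (merged$t_start_ps[k] - free_from) / 1000)
      free_from <- merged$t_end_ps[k]
    }
  }
  mean_assoc <- if (length(assoc_waits) > 0L) mean(assoc_waits) else NA_real_

  taus <- sort(unique(c(0, events$lifetime_ns)))
  surv <- vapply(taus, function(tau) mean(events$lifetime_ns > tau),
                 numeric(1))
  if (n_events > 0L) surv[1L] <- 1  # S(0) = 1 by convention
  max_obs <- (t_end_ps - t_start_ps) / 1000
  never <- if (n_events > 0L) mean(events$censored) else NA_real_

  list(
    mean_association_ns = mean_assoc,
    mean_dissociation_ns = mean_diss,
    censored_fraction = censored_fraction,
    censored_only = n_events > 0L && all(events$censored),
    n_events = n_events,
    n_association_waits = length(assoc_waits),
    survival = data.frame(tau_ns = taus, fraction = surv),
    never_dissociate_fraction = never,
    max_observable_lifetime_ns = max_obs
  )
}

#' Diffusion-limited (Smoluchowski) association rate and waiting time
#'
#' For spheres of combined interaction radius R and relative diffusion
#' coefficient D, the diffusion-limited association rate constant is
#' k_on = 4 pi R D. The mean association waiting time at molar
#' concentration c is 1 / (k_on c N_A). R is conventionally taken as twice
#' the monomer radius of gyration and D as the relative (pair) diffusion
#' coefficient, i.e. twice the monomer diffusion coefficient.
#'
#' @param R_nm combined interaction radius, nm
#' @param D_rel_m2s relative diffusion coefficient, m^2/s
#' @param conc_M molar concentration
#' @return waiting time in ns (`smoluchowski_association_time`) or rate
#'   constant in m^3/s (`smoluchowski_kon`)
#' @export
smoluchowski_association_time <- function(R_nm, D_rel_m2s, conc_M) {
  if (any(c(R_nm, D_rel_m2s, conc_M) <= 0)) {
    stop("R, D and concentration must all be positive")
  }
  kon <- smoluchowski_kon(R_nm, D_rel_m2s)          # m^3/s
  number_density <- conc_M * 1e3 * AVOGADRO          # molecules / m^3
  1 / (kon * number_density) * 1e9                   # s -> ns
}

#' @rdname smoluchowski_association_time
#' @export
smoluchowski_kon <- function(R_nm, D_rel_m2s) {
  4 * pi * (R_nm * 1e-9) * D_rel_m2s
}

# unwrapped center-of-mass paths, one matrix (frames x 3) per molecule
unwrapped_com_paths <- function(trajectory, molecules) {
  at <- trajectory$topology$atoms
  F <- length(trajectory$frames)
  lapply(molecules, function(m) {
    sel <- which(at$molecule == m)
    w <- at$mass[sel] / sum(at$mass[sel])
    X <- trajectory$frames[[1L]]$xyz[sel, , drop = FALSE]
    com <- matrix(0, F, 3L)
    com[1L, ] <- colSums(X * w)
    for (f in 2:F) {
      Y <- trajectory$frames[[f]]$xyz[sel, , drop = FALSE]
      d <- sweep_min_image(Y - X, trajectory$frames[[f]]$box)
      X <- X + d
      com[f, ] <- colSums(X * w)
    }
    com
  })
}

#' Diffusion coefficient from mean-squared displacement
#'
#' Computes molecule center-of-mass paths with periodic unwrapping, the
#' time- and molecule-averaged MSD over a window of lag times, and the
#' Einstein-relation estimate D = slope / 6 from a linear fit of MSD
#' against lag. A log-log slope far from 1 (|slope - 1| > 0.3) flags the
#' fit as poor (e.g. ballistic or confined motion).
#'
#' @param trajectory a trajectory with at least 3 frames
#' @param molecules molecule ids (default: all protein molecules)
#' @param max_lag_fraction largest lag as a fraction of the trajectory
#'   length (default 0.25)
#' @return list with `D_m2s`, `slope_nm2_ps`, `alpha` (log-log slope),
#'   `poor_fit`, `msd` (data.frame `lag_ps`, `msd_nm2`)
#' @export
diffusion_coefficient_msd <- function(trajectory, molecules = NULL,
                                      max_lag_fraction = 0.25) {
  if (is.null(molecules)) {
    molecules <- molecules_of_group(trajectory$topology, "protein")
  }
  F <- length(trajectory$frames)
  if (F < 3L) stop("need at least 3 frames")
  dt <- trajectory$frame_interval
  if (is.na(dt)) stop("non-uniform frame spacing")
  paths <- unwrapped_com_paths(trajectory, molecules)
  lags <- seq_len(max(2L, floor(F * max_lag_fraction)))
  msd <- vapply(lags, function(L) {
    mean(vapply(paths, function(p) {
      d <- p[(1L + L):F, , drop = FALSE] - p[1L:(F - L), , drop = FALSE]
      mean(rowSums(d * d))
    }, numeric(1)))
  }, numeric(1))
  lag_ps <- lags * dt
  fit <- stats::lm(msd ~ lag_ps)
  slope <- unname(stats::coef(fit)[2L])
  alpha <- unname(stats::coef(stats::lm(log(msd) ~ log(lag_ps)))[2L])
  list(
    D_m2s = slope / 6 * 1e-6,  # nm^2/ps -> m^2/s
    slope_nm2_ps = slope,
    alpha = alpha,
    poor_fit = abs(alpha - 1) > 0.3,
    msd = data.frame(lag_ps = lag_ps, msd_nm2 = msd)
  )
}

#' Radius of gyration of a molecule in one frame
#'
#' Mass-weighted, computed after making the molecule whole across periodic
#' boundaries (atoms unwrapped relative to the first atom).
#'
#' @param frame a frame
#' @param topology the matching topology
#' @param molecule molecule id
#' @return radius of gyration, nm
#' @export
radius_of_gyration <- function(frame, topology, molecule) {
  sel <- which(topology$atoms$molecule == molecule)
  X <- frame$xyz[sel, , drop = FALSE]
  d <- sweep_min_image(X - X[rep(1L, nrow(X)), , drop = FALSE], frame$box)
  X <- X[rep(1L, nrow(X)), , drop = FALSE] + d
  w <- topology$atoms$mass[sel] / sum(topology$atoms$mass[sel])
  com <- colSums(X * w)
  sqrt(sum(w * rowSums((X - matrix(com, nrow(X), 3L, byrow = TRUE))^2)))
}
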