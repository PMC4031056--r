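#' Per-residue intermolecular interaction propensity
#'
#' For each frame t and residue group g (side chains by sequence position,
#' one collective backbone group), the propensity is the contact fraction
#' normalized by the solvent-accessibility fraction at that time point:
#' \deqn{p_g(t) = \frac{c_g(t) / \sum_g c_g(t)}{s_g(t) / \sum_g s_g(t)}}
#' where c is the number of intermolecular atomic contacts formed by the
#' group and s its SASA. Frames without any contact are skipped; the
#' per-trajectory time averages are then averaged over trajectories
#' without weighting. A group whose contacts are exactly proportional to
#' its surface exposure has propensity 1 at every frame.
#'
#' @param contact_groups frames-by-groups matrix of contact counts (the
#'   `group_counts` element of a contact_series built with
#'   `residue_map = TRUE`), or a list of such matrices (one per
#'   trajectory)
#' @param sasa_groups frames-by-groups matrix (or list) of group SASA
#'   values, frame-aligned with `contact_groups`
#' @return object of class `"propensity_profile"`: data.frame with
#'   `group`, `propensity` (mean over trajectories), `sd` (across
#'   trajectories, NA for a single one), `n_trajectories`
#' @export
interaction_propensity <- function(contact_groups, sasa_groups) {
  if (!is.list(contact_groups)) contact_groups <- list(contact_groups)
  if (!is.list(sasa_groups)) sasa_groups <- list(sasa_groups)
  if (length(contact_groups) != length(sasa_groups)) {
    stop("need one SASA matrix per contact matrix")
  }
  per_traj <- mapply(function(cg, sg) {
    if (!all(dim(cg) == dim(sg))) {
      stop("contact and SASA series are not frame-aligned")
    }
    tot_s <- rowSums(sg)
    if (any(tot_s <= 0)) stop("frame with zero total SASA")
    tot_c <- rowSums(cg)
    use <- which(tot_c >= 1)
    if (length(use) == 0L) {
      return(rep(NA_real_, ncol(cg)))
    }
    p <- (cg[use, , drop = FALSE] / tot_c[use]) /
      (sg[use, , drop = FALSE] / tot_s[use])
    colMeans(p)
  }, contact_groups, sasa_groups, SIMPLIFY = FALSE)
  mat <- do.call(rbind, per_traj)
  labels <- colnames(contact_groups[[1L]])
  if (is.null(labels)) labels <- as.character(seq_len(ncol(mat)))
  out <- data.frame(
    group = labels,
    propensity = colMeans(mat, na.rm = TRUE),
    sd = if (nrow(mat) > 1L) apply(mat, 2L, stats::sd, na.rm = TRUE)
         else NA_real_,
    n_trajectories = nrow(mat),
    row.names = NULL
  )
  class(out) <- c("propensity_profile", "data.frame")
  out
}

#' Propensity profile straight from a trajectory
#'
#' Convenience wrapper: runs the contact analysis with residue grouping,
#' Shrake-Rupley SASA on every frame, and [interaction_propensity()].
#'
#' @param trajectories a trajectory or list of trajectories
#' @param cutoff contact cutoff, nm
#' @param probe_radius,n_points SASA parameters
#' @return a `propensity_profile`
#' @export
propensity_profile <- function(trajectories, cutoff = 0.4,
                               probe_radius = 0.14, n_points = 960L) {
  if (inherits(trajectories, "trajectory")) {
    trajectories <- list(trajectories)
  }
  cg <- list(); sg <- list()
  for (k in seq_along(trajectories)) {
    traj <- trajectories[[k]]
    series <- contact_timeseries(traj, cutoff = cutoff, residue_map = TRUE)
    cg[[k]] <- series$group_counts
    sg[[k]] <- t(vapply(traj$frames, function(f) {
      sasa_by_residue_group(f, traj$topology, probe_radius = probe_radius,
                            n_points = n_points)
    }, numeric(ncol(series$group_counts))))
  }
  interaction_propensity(cg, sg)
}
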