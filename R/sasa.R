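# quasi-uniform unit-sphere quadrature points (golden-spiral lattice)
sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * k
  z <- 1 - 2 * k / n
  r <- sqrt(pmax(0, 1 - z * z))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area by the Shrake-Rupley method
#'
#' Each atom is assigned a sphere of radius r_vdw + probe sampled with a
#' quasi-uniform point lattice; the accessible area is the fraction of
#' points not occluded by any neighboring sphere times the sphere area.
#' Radii come from the Bondi van der Waals table by element, overridden by
#' a `radius` column in the atom table when present. Periodic images are
#' considered for occlusion.
#'
#' @param frame a frame
#' @param topology the matching topology
#' @param probe_radius probe (solvent) radius, nm; 0.14 nm emulates water
#' @param n_points quadrature points per atom (>= 92)
#' @param atoms optional integer subset of atom rows to evaluate (other
#'   atoms still occlude); default: all protein atoms
#' @return numeric vector of per-atom areas (nm^2), one per entry of
#'   `atoms`, with the attribute `"atoms"` carrying the selection
#' @export
shrake_rupley_sasa <- function(frame, topology, probe_radius = 0.14,
                               n_points = 960L, atoms = NULL) {
  if (probe_radius < 0) stop("probe radius must be >= 0")
  if (n_points < 92L) stop("use at least 92 quadrature points")
  at <- topology$atoms
  if (is.null(atoms)) atoms <- which(at$group == "protein")
  radii <- if (!is.null(at$radius)) {
    ifelse(is.na(at$radius), element_radius(at$element), at$radius)
  } else {
    element_radius(at$element)
  }
  pts <- sphere_points(n_points)
  X <- frame$xyz
  box <- frame$box
  # occluders: every atom (protein, solvent, ion all exclude solvent)
  occ_all <- seq_len(nrow(X))
  area <- numeric(length(atoms))
  max_r <- max(radii) + probe_radius
  for (k in seq_along(atoms)) {
    i <- atoms[k]
    ri <- radii[i] + probe_radius
    d <- sweep_min_image(X[occ_all, , drop = FALSE] -
                           X[rep(i, length(occ_all)), , drop = FALSE], box)
    d2 <- rowSums(d * d)
    within <- which(d2 < (ri + max_r)^2 & occ_all != i)
    within <- within[sqrt(d2[within]) <
                       ri + radii[occ_all[within]] + probe_radius]
    if (length(within) == 0L) {
      area[k] <- 4 * pi * ri^2
      next
    }
    P <- pts * ri  # points relative to atom center
    nb_d <- d[within, , drop = FALSE]
    nb_r2 <- (radii[occ_all[within]] + probe_radius)^2
    free <- rep(TRUE, n_points)
    for (j in seq_along(within)) {
      dd <- P - matrix(nb_d[j, ], n_points, 3L, byrow = TRUE)
      free <- free & (rowSums(dd * dd) > nb_r2[j])
      if (!any(free)) break
    }
    area[k] <- 4 * pi * ri^2 * sum(free) / n_points
  }
  attr(area, "atoms") <- atoms
  area
}

#' Per-residue-group SASA of the protein content
#'
#' Pools atoms of identical molecules by sequence position: side chains by
#' 1-based position, backbone atoms into one collective group, matching
#' the grouping of the contact analyses.
#'
#' @param frame a frame
#' @param topology the matching topology
#' @param ... passed to [shrake_rupley_sasa()]
#' @return named numeric vector of group areas (nm^2), labels as in
#'   [contact_timeseries()] group columns (positions then `"bb"`)
#' @export
sasa_by_residue_group <- function(frame, topology, ...) {
  sel <- which(topology$atoms$group == "protein")
  area <- shrake_rupley_sasa(frame, topology, atoms = sel, ...)
  gidx <- residue_group_index(topology)[sel]
  labels <- residue_group_labels(topology)
  out <- vapply(seq_along(labels), function(g) sum(area[gidx == g]),
                numeric(1))
  stats::setNames(out, labels)
}
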