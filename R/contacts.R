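#' Minimum-image distance under orthorhombic periodic boundaries
#'
#' @param x1,x2 numeric length-3 vectors, or matrices with one point per
#'   row (nm)
#' @param box length-3 box side lengths (nm)
#' @return Euclidean distance(s) to the nearest periodic image
#' @export
minimum_image_distance <- function(x1, x2, box) {
  m1 <- rbind(x1); m2 <- rbind(x2)
  if (nrow(m1) != nrow(m2)) {
    if (nrow(m1) == 1L) m1 <- m1[rep(1L, nrow(m2)), , drop = FALSE]
    else if (nrow(m2) == 1L) m2 <- m2[rep(1L, nrow(m1)), , drop = FALSE]
    else stop("x1 and x2 must have matching numbers of points")
  }
  d <- sweep_min_image(m1 - m2, box)
  out <- sqrt(rowSums(d * d))
  if (length(out) == 1L) unname(out) else out
}

# displacement matrix -> minimum-image displacement matrix
sweep_min_image <- function(d, box) {
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

eligible_contact_atoms <- function(topology) {
  at <- topology$atoms
  which(at$group == "protein" & (at$is_heavy | !is.na(at$bonded_heavy)))
}

# residue-group index of each atom: side chains pooled by sequence position
# (1..L), one collective backbone group (L + 1)
residue_group_index <- function(topology) {
  at <- topology$atoms
  L <- max(at$resid[at$group == "protein"])
  ifelse(at$is_backbone, L + 1L, at$resid)
}

residue_group_labels <- function(topology) {
  L <- max(topology$atoms$resid[topology$atoms$group == "protein"])
  c(as.character(seq_len(L)), "bb")
}

#' Intermolecular atomic contacts in one frame
#'
#' Counts unordered pairs of eligible atoms (heavy atoms, or hydrogens
#' bonded to them) from *different* protein molecules whose minimum-image
#' distance is at or below `cutoff` (default 0.4 nm, boundary inclusive).
#' Solvent and ions never participate. A cell-list neighbor search is used
#' when the box accommodates at least 3 cells per axis, otherwise an
#' all-pairs scan; both give identical counts.
#'
#' @param frame a frame
#' @param topology the matching topology
#' @param cutoff contact cutoff, nm
#' @param method `"auto"`, `"cell"` or `"brute"`
#' @param residue_map also accumulate the residue-group contact-pair matrix
#'   (side chains by position plus one collective backbone group)
#' @return object of class `"contact_graph"`: list with `time`, `molecules`
#'   (protein molecule ids), `edges` (data.frame mol_i, mol_j, n_contacts),
#'   `n_contacts` (total atomic contacts), and when `residue_map = TRUE`
#'   also `residue_pairs` (symmetric group-by-group matrix) and
#'   `group_counts` (per-group participation counts).
#' @export
frame_contacts <- function(frame, topology, cutoff = 0.4,
                           method = c("auto", "cell", "brute"),
                           residue_map = FALSE) {
  method <- match.arg(method)
  if (cutoff <= 0) stop("cutoff must be positive")
  sel <- eligible_contact_atoms(topology)
  mol <- topology$atoms$molecule[sel]
  X <- frame$xyz[sel, , drop = FALSE]
  box <- frame$box
  if (cutoff >= min(box) / 2 && method != "brute") {
    warning("cutoff >= half the smallest box side; falling back to an ",
            "all-pairs scan")
    method <- "brute"
  }
  ncell <- pmax(1L, floor(box / cutoff))
  if (method == "auto") method <- if (all(ncell >= 3L)) "cell" else "brute"
  if (method == "cell" && any(ncell < 3L)) method <- "brute"

  pairs <- if (method == "cell") {
    cell_list_pairs(X, box, cutoff, ncell)
  } else {
    brute_force_pairs(X, box, cutoff)
  }
  # keep intermolecular pairs only
  keep <- mol[pairs[, 1L]] != mol[pairs[, 2L]]
  pairs <- pairs[keep, , drop = FALSE]

  mols <- molecules_of_group(topology, "protein")
  mi <- pmin(mol[pairs[, 1L]], mol[pairs[, 2L]])
  mj <- pmax(mol[pairs[, 1L]], mol[pairs[, 2L]])
  edges <- if (nrow(pairs) > 0L) {
    agg <- table(paste(mi, mj, sep = "-"))
    ij <- do.call(rbind, strsplit(names(agg), "-"))
    data.frame(mol_i = as.integer(ij[, 1L]), mol_j = as.integer(ij[, 2L]),
               n_contacts = as.integer(agg), row.names = NULL)
  } else {
    data.frame(mol_i = integer(0), mol_j = integer(0),
               n_contacts = integer(0))
  }
  out <- list(time = frame$time, molecules = mols, edges = edges,
              n_contacts = nrow(pairs))
  if (residue_map) {
    gidx <- residue_group_index(topology)[sel]
    labels <- residue_group_labels(topology)
    G <- length(labels)
    M <- matrix(0L, G, G, dimnames = list(labels, labels))
    if (nrow(pairs) > 0L) {
      gi <- gidx[pairs[, 1L]]; gj <- gidx[pairs[, 2L]]
      for (k in seq_along(gi)) {
        M[gi[k], gj[k]] <- M[gi[k], gj[k]] + 1L
        if (gi[k] != gj[k]) M[gj[k], gi[k]] <- M[gj[k], gi[k]] + 1L
      }
    }
    out$residue_pairs <- M
    out$group_counts <- stats::setNames(
      tabulate(c(gidx[pairs[, 1L]], gidx[pairs[, 2L]]), nbins = G), labels)
  }
  structure(out, class = "contact_graph")
}

brute_force_pairs <- function(X, box, cutoff) {
  n <- nrow(X)
  if (n < 2L) return(matrix(integer(0), 0L, 2L))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  d <- X[idx[, 1L], , drop = FALSE] - X[idx[, 2L], , drop = FALSE]
  d <- sweep_min_image(d, box)
  hit <- rowSums(d * d) <= cutoff^2
  cbind(idx[hit, 1L], idx[hit, 2L])
}

cell_list_pairs <- function(X, box, cutoff, ncell) {
  n <- nrow(X)
  if (n < 2L) return(matrix(integer(0), 0L, 2L))
  Xw <- X
  for (k in 1:3) Xw[, k] <- X[, k] - box[k] * floor(X[, k] / box[k])
  ci <- pmin(floor(Xw[, 1L] / box[1L] * ncell[1L]), ncell[1L] - 1L)
  cj <- pmin(floor(Xw[, 2L] / box[2L] * ncell[2L]), ncell[2L] - 1L)
  ck <- pmin(floor(Xw[, 3L] / box[3L] * ncell[3L]), ncell[3L] - 1L)
  cid <- 1L + ci + ncell[1L] * (cj + ncell[2L] * ck)
  members <- split(seq_len(n), cid)
  occupied <- as.integer(names(members))
  # half-space neighbor offsets (13) + the cell itself
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[offs[, 3L] > 0L | (offs[, 3L] == 0L & offs[, 2L] > 0L) |
                 (offs[, 3L] == 0L & offs[, 2L] == 0L & offs[, 1L] > 0L), ,
               drop = FALSE]
  acc_i <- list(); acc_j <- list(); nacc <- 0L
  push <- function(ii, jj) {
    nacc <<- nacc + 1L
    acc_i[[nacc]] <<- ii; acc_j[[nacc]] <<- jj
  }
  cut2 <- cutoff^2
  for (c1 in occupied) {
    A <- members[[as.character(c1)]]
    # within-cell pairs
    if (length(A) > 1L) {
      idx <- which(upper.tri(matrix(0, length(A), length(A))),
                   arr.ind = TRUE)
      d <- X[A[idx[, 1L]], , drop = FALSE] - X[A[idx[, 2L]], , drop = FALSE]
      d <- sweep_min_image(d, box)
      hit <- rowSums(d * d) <= cut2
      if (any(hit)) push(A[idx[hit, 1L]], A[idx[hit, 2L]])
    }
    k0 <- (c1 - 1L)
    i0 <- k0 %% ncell[1L]
    j0 <- (k0 %/% ncell[1L]) %% ncell[2L]
    l0 <- k0 %/% (ncell[1L] * ncell[2L])
    for (o in seq_len(nrow(offs))) {
      i1 <- (i0 + offs[o, 1L]) %% ncell[1L]
      j1 <- (j0 + offs[o, 2L]) %% ncell[2L]
      l1 <- (l0 + offs[o, 3L]) %% ncell[3L]
      c2 <- 1L + i1 + ncell[1L] * (j1 + ncell[2L] * l1)
      B <- members[[as.character(c2)]]
      if (is.null(B) || c2 == c1) next
      d1 <- X[rep(A, times = length(B)), , drop = FALSE] -
        X[rep(B, each = length(A)), , drop = FALSE]
      d1 <- sweep_min_image(d1, box)
      hit <- rowSums(d1 * d1) <= cut2
      if (any(hit)) {
        push(rep(A, times = length(B))[hit], rep(B, each = length(A))[hit])
      }
    }
  }
  if (nacc == 0L) return(matrix(integer(0), 0L, 2L))
  cbind(unlist(acc_i), unlist(acc_j))
}

#' Contact time series over a trajectory
#'
#' Runs [frame_contacts()] on every frame and stores the per-molecule-pair
#' atomic contact counts in a compact matrix form consumed by the oligomer
#' and kinetics analyses.
#'
#' @param trajectory a trajectory
#' @param cutoff contact cutoff, nm
#' @param residue_map accumulate per-frame residue-group counts and the
#'   summed residue-pair matrix (needed by the propensity and contact-map
#'   analyses)
#' @param method neighbor-search method passed to [frame_contacts()]
#' @return object of class `"contact_series"`: `times` (ps), `molecules`,
#'   `pairs` (P x 2 matrix of molecule pairs), `counts` (frames x P contact
#'   counts), `total` (per-frame totals), `frame_interval` (ps); with
#'   `residue_map = TRUE` also `group_counts` (frames x groups) and
#'   `residue_pair_sum` (group x group, summed over frames).
#' @export
contact_timeseries <- function(trajectory, cutoff = 0.4,
                               residue_map = FALSE,
                               method = "auto") {
  mols <- molecules_of_group(trajectory$topology, "protein")
  nm <- length(mols)
  prs <- which(upper.tri(matrix(0, nm, nm)), arr.ind = TRUE)
  pairs <- cbind(mols[prs[, 1L]], mols[prs[, 2L]])
  pair_key <- paste(pairs[, 1L], pairs[, 2L], sep = "-")
  F <- length(trajectory$frames)
  counts <- matrix(0L, F, nrow(pairs))
  graphs_groups <- NULL
  residue_pair_sum <- NULL
  group_counts <- NULL
  if (residue_map) {
    labels <- residue_group_labels(trajectory$topology)
    residue_pair_sum <- matrix(0, length(labels), length(labels),
                               dimnames = list(labels, labels))
    group_counts <- matrix(0L, F, length(labels),
                           dimnames = list(NULL, labels))
  }
  for (f in seq_len(F)) {
    cg <- frame_contacts(trajectory$frames[[f]], trajectory$topology,
                         cutoff = cutoff, method = method,
                         residue_map = residue_map)
    if (nrow(cg$edges) > 0L) {
      key <- paste(cg$edges$mol_i, cg$edges$mol_j, sep = "-")
      counts[f, match(key, pair_key)] <- cg$edges$n_contacts
    }
    if (residue_map) {
      residue_pair_sum <- residue_pair_sum + cg$residue_pairs
      group_counts[f, ] <- cg$group_counts
    }
  }
  structure(list(
    times = frame_times(trajectory), molecules = mols, pairs = pairs,
    counts = counts, total = rowSums(counts),
    frame_interval = trajectory$frame_interval,
    group_counts = group_counts, residue_pair_sum = residue_pair_sum
  ), class = "contact_series")
}

#' Pooled residue-pair contact map over trajectories
#'
#' Sums the residue-group contact-pair matrices of several contact series
#' (built with `residue_map = TRUE`) and emits the log-rescaled map used
#' for sequence-wise contact heat maps: `log(max(m) / m)`, i.e. the
#' negative logarithm of the counts shifted so the most-contacted residue
#' pair maps to 0 and the least-contacted pair to the largest value.
#' Zero-count pairs receive a pseudo-count (default 0.5) before the
#' logarithm, which is undefined at zero.
#'
#' @param series_list a contact_series or list of them
#' @param pseudo_count replacement for zero counts
#' @return list with `counts` (summed matrix) and `transformed`
#' @export
mean_residue_contact_map <- function(series_list, pseudo_count = 0.5) {
  if (inherits(series_list, "contact_series")) {
    series_list <- list(series_list)
  }
  for (s in series_list) {
    if (is.null(s$residue_pair_sum)) {
      stop("contact series was built without residue_map = TRUE")
    }
  }
  m <- Reduce(`+`, lapply(series_list, `[[`, "residue_pair_sum"))
  m2 <- m
  m2[m2 == 0] <- pseudo_count
  transformed <- log(max(m2)) - log(m2)
  list(counts = m, transformed = transformed)
}
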