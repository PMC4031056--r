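# connected components by union-find; edges index into 1..n
components_from_edges <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(edges) > 0L) {
    for (k in seq_len(nrow(edges))) {
      ri <- find(edges[k, 1L]); rj <- find(edges[k, 2L])
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

species_names <- c("monomer", "dimer", "trimer", "tetramer", "larger")

size_to_species <- function(size) {
  ifelse(size >= 5L, "larger", species_names[pmin(size, 5L)])
}

#' Classify the oligomeric state of one frame
#'
#' Molecules are grouped into connected components of the molecule-level
#' contact graph; a free monomer is a singleton component.
#'
#' @param contact_graph a `contact_graph` from [frame_contacts()]
#' @return object of class `"oligomer_state"`: `time`, `membership`
#'   (component index per molecule), `sizes` (component sizes),
#'   `species_counts` (named counts of monomer/dimer/trimer/tetramer/
#'   larger components), `free_fraction` (fraction of molecules that are
#'   free monomers)
#' @export
classify_oligomers <- function(contact_graph) {
  mols <- contact_graph$molecules
  n <- length(mols)
  e <- contact_graph$edges
  edges <- cbind(match(e$mol_i, mols), match(e$mol_j, mols))
  membership <- components_from_edges(n, edges)
  sizes <- as.integer(table(membership))
  counts <- table(factor(size_to_species(sizes), levels = species_names))
  structure(list(
    time = contact_graph$time,
    membership = stats::setNames(membership, mols),
    sizes = sizes,
    species_counts = counts,
    free_fraction = sum(sizes == 1L) / n
  ), class = "oligomer_state")
}

#' Oligomer states over a contact series
#'
#' @param series a `contact_series` from [contact_timeseries()]
#' @return object of class `"oligomer_series"`: `times`, `membership`
#'   (frames x molecules component indices), `molecule_species` (frames x
#'   molecules species label of the component each molecule belongs to),
#'   `free_fraction` per frame
#' @export
oligomer_timeseries <- function(series) {
  n <- length(series$molecules)
  F <- nrow(series$counts)
  membership <- matrix(0L, F, n)
  msize <- matrix(0L, F, n)
  for (f in seq_len(F)) {
    live <- series$counts[f, ] > 0L
    edges <- cbind(match(series$pairs[live, 1L], series$molecules),
                   match(series$pairs[live, 2L], series$molecules))
    mem <- components_from_edges(n, edges)
    membership[f, ] <- mem
    sz <- as.integer(table(mem))
    msize[f, ] <- sz[mem]
  }
  structure(list(
    times = series$times, molecules = series$molecules,
    membership = membership, molecule_size = msize,
    free_fraction = rowMeans(msize == 1L),
    n_molecules = n
  ), class = "oligomer_series")
}

#' Species fractions of protein content over time
#'
#' Fraction of *molecules* (not assemblies) residing in each species per
#' frame. Given several trajectories' series, the per-frame fractions are
#' averaged without weighting.
#'
#' @param x an `oligomer_series`, or a list of them with equal lengths
#' @return data.frame with `time_ps` and one column per species
#'   (monomer, dimer, trimer, tetramer, larger); rows sum to 1
#' @export
species_fraction_timeseries <- function(x) {
  if (inherits(x, "oligomer_series")) x <- list(x)
  per_traj <- lapply(x, function(os) {
    sapply(species_names, function(sp) {
      rowMeans(matrix(size_to_species(os$molecule_size) == sp,
                      nrow = nrow(os$molecule_size)))
    })
  })
  avg <- Reduce(`+`, per_traj) / length(per_traj)
  if (is.null(dim(avg))) avg <- matrix(avg, nrow = 1L,
                                       dimnames = list(NULL, species_names))
  data.frame(time_ps = x[[1L]]$times, avg, check.names = FALSE)
}
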