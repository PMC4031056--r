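#' Read a topology from file
#'
#' Supported formats: `"pdb"` (chains become molecules; parsed with bio3d),
#' `"gro"` (GROMACS coordinate file; molecules inferred from residue
#' numbering, see Details) and `"internal"` (the package's own text dialect,
#' written by [write_topology()], which round-trips exactly).
#'
#' @details For GRO input, a new protein molecule starts whenever the
#' residue number decreases; residues named `SOL`/`WAT`/`HOH` become
#' one-molecule solvent entries and `NA+`/`CL-`/`NA`/`CL` ions one-molecule
#' ion entries. When this inference is ambiguous for your file, pass an
#' explicit `molecule_map`. PDB files without chain identifiers are
#' rejected rather than silently treated as one molecule.
#'
#' @param path file path
#' @param format one of `"pdb"`, `"gro"`, `"internal"`
#' @param molecule_map optional integer vector, one molecule index per atom,
#'   overriding the format's own molecule inference
#' @return a [topology()]
#' @export
read_topology <- function(path, format = c("pdb", "gro", "internal"),
                          molecule_map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
    pdb = read_topology_pdb(path, molecule_map),
    gro = read_topology_gro(path, molecule_map),
    internal = read_topology_internal(path)
  )
}

read_topology_pdb <- function(path, molecule_map = NULL) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  element <- at$elesy
  if (is.null(element) || all(is.na(element) | trimws(element) == "")) {
    element <- bio3d::atom2ele(pdb)
  } else {
    blank <- is.na(element) | trimws(element) == ""
    if (any(blank)) element[blank] <- bio3d::atom2ele(pdb)[blank]
    element <- trimws(element)
  }
  if (is.null(molecule_map)) {
    chain <- at$chain
    if (anyNA(chain) || any(trimws(chain) == "")) {
      stop("PDB file has atoms without a chain identifier; supply ",
           "'molecule_map' to assign molecules explicitly")
    }
    molecule_map <- match(chain, unique(chain))
  }
  resname <- trimws(at$resid)  # bio3d: 'resid' holds the residue *name*
  solvent_res <- c("HOH", "WAT", "SOL", "TIP3", "SPC")
  ion_res <- c("NA", "CL", "NA+", "CL-", "SOD", "CLA", "K", "MG", "CA2")
  group <- ifelse(resname %in% solvent_res, "solvent",
                  ifelse(resname %in% ion_res, "ion", "protein"))
  # residue numbering re-based to 1 within each molecule
  resnum <- at$resno
  for (m in unique(molecule_map)) {
    sel <- molecule_map == m
    resnum[sel] <- resnum[sel] - min(resnum[sel]) + 1L
  }
  atoms <- data.frame(
    name = trimws(at$elety), element = element, resid = resnum,
    resname = resname, molecule = molecule_map, group = group,
    stringsAsFactors = FALSE
  )
  sequences <- tryCatch({
    vapply(sort(unique(molecule_map[group == "protein"])), function(m) {
      sel <- molecule_map == m & group == "protein" & atoms$name == "CA"
      paste(bio3d::aa321(resname[sel]), collapse = "")
    }, character(1))
  }, error = function(e) NULL)
  topology(atoms, sequences = sequences)
}

guess_element <- function(name) {
  nm <- toupper(gsub("[0-9'+-]", "", trimws(name)))
  two <- substr(nm, 1L, 2L)
  out <- ifelse(two %in% c("CL", "NA", "MG", "FE", "ZN", "BR"), two,
                substr(nm, 1L, 1L))
  out[out == ""] <- "X"
  out
}

read_topology_gro <- function(path, molecule_map = NULL) {
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(trimws(lines) != "")))]
  nat <- as.integer(trimws(lines[2L]))
  if (is.na(nat)) stop("malformed GRO file: line 2 is not an atom count")
  rows <- lines[3:(2L + nat)]
  resno <- as.integer(substr(rows, 1L, 5L))
  resname <- trimws(substr(rows, 6L, 10L))
  name <- trimws(substr(rows, 11L, 15L))
  if (anyNA(resno)) {
    stop("malformed GRO file: unreadable residue number at line ",
         2L + which(is.na(resno))[1L])
  }
  solvent_res <- c("SOL", "WAT", "HOH")
  ion_res <- c("NA", "CL", "NA+", "CL-")
  group <- ifelse(resname %in% solvent_res, "solvent",
                  ifelse(resname %in% ion_res, "ion", "protein"))
  if (is.null(molecule_map)) {
    molecule_map <- integer(nat)
    mol <- 0L
    prev_res <- -Inf
    prev_key <- ""
    for (i in seq_len(nat)) {
      key <- paste(resno[i], resname[i])
      new_res <- key != prev_key
      if (i == 1L || (group[i] != "protein" && new_res) ||
          (group[i] == "protein" && new_res && resno[i] < prev_res)) {
        mol <- mol + 1L
      }
      molecule_map[i] <- mol
      if (new_res) prev_res <- resno[i]
      prev_key <- key
    }
  }
  resid <- resno
  for (m in unique(molecule_map)) {
    sel <- molecule_map == m
    resid[sel] <- resid[sel] - min(resid[sel]) + 1L
  }
  atoms <- data.frame(
    name = name, element = guess_element(name), resid = resid,
    resname = resname, molecule = molecule_map, group = group,
    stringsAsFactors = FALSE
  )
  topology(atoms)
}

topo_num_cols <- c("charge", "sigma", "epsilon", "radius", "mass")

#' Write a topology in the internal dialect
#'
#' Plain-text, tab-separated, diffable; [read_topology()] with
#' `format = "internal"` reproduces the object exactly.
#'
#' @param topology a topology
#' @param path output path
#' @export
write_topology <- function(topology, path) {
  at <- topology$atoms
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# aggtraj-topology 1", con)
  writeLines(sprintf("natoms\t%d", nrow(at)), con)
  if (!is.null(topology$sequences)) {
    writeLines(sprintf("sequence\t%s", topology$sequences), con)
  }
  cols <- names(at)
  writeLines(paste(c("atoms:", cols), collapse = "\t"), con)
  num_fmt <- function(x) {
    ifelse(is.na(x), "NA", vapply(as.numeric(x),
                                  function(v) sprintf("%.17g", v),
                                  character(1)))
  }
  tab <- at[cols]
  for (cc in cols) {
    if (cc %in% topo_num_cols) tab[[cc]] <- num_fmt(tab[[cc]])
    else if (is.numeric(tab[[cc]]) || is.logical(tab[[cc]])) {
      tab[[cc]] <- ifelse(is.na(tab[[cc]]), "NA", as.character(tab[[cc]]))
    }
  }
  writeLines(do.call(paste, c(unname(as.list(tab)), sep = "\t")), con)
  if (!is.null(topology$bonds)) {
    writeLines(sprintf("bonds\t%d", nrow(topology$bonds)), con)
    writeLines(paste(topology$bonds[, 1L], topology$bonds[, 2L], sep = "\t"),
               con)
  }
  invisible(path)
}

read_topology_internal <- function(path) {
  lines <- readLines(path)
  lines <- lines[trimws(lines) != "" | seq_along(lines) == 1L]
  if (!startsWith(lines[1L], "# aggtraj-topology")) {
    stop("not an internal-dialect topology file (bad header line 1)")
  }
  nat <- as.integer(strsplit(lines[2L], "\t")[[1L]][2L])
  i <- 3L
  sequences <- character(0)
  while (startsWith(lines[i], "sequence\t")) {
    sequences <- c(sequences, sub("^sequence\t", "", lines[i]))
    i <- i + 1L
  }
  if (!startsWith(lines[i], "atoms:")) {
    stop("malformed internal topology: expected 'atoms:' header at line ", i)
  }
  cols <- strsplit(lines[i], "\t")[[1L]][-1L]
  rows <- strsplit(lines[(i + 1L):(i + nat)], "\t")
  mat <- do.call(rbind, rows)
  atoms <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(atoms) <- cols
  for (cc in c("resid", "molecule", "bonded_heavy")) {
    atoms[[cc]] <- suppressWarnings(as.integer(atoms[[cc]]))
  }
  for (cc in c("is_heavy", "is_backbone")) atoms[[cc]] <- atoms[[cc]] == "TRUE"
  for (cc in intersect(topo_num_cols, cols)) {
    atoms[[cc]] <- suppressWarnings(as.numeric(atoms[[cc]]))
  }
  bonds <- NULL
  j <- i + nat + 1L
  if (j <= length(lines) && startsWith(lines[j], "bonds\t")) {
    nb <- as.integer(strsplit(lines[j], "\t")[[1L]][2L])
    if (nb > 0L) {
      bm <- do.call(rbind, strsplit(lines[(j + 1L):(j + nb)], "\t"))
      bonds <- matrix(as.integer(bm), ncol = 2L)
    }
  }
  top <- topology(atoms, sequences = if (length(sequences)) sequences,
                  bonds = NULL)
  top$bonds <- bonds
  top$atoms$bonded_heavy <- atoms$bonded_heavy
  top
}

#' Read a trajectory from file
#'
#' @param path file path
#' @param topology the matching topology (atom counts are checked)
#' @param format `"pdb"` (multi-MODEL), `"gro"` (concatenated blocks) or
#'   `"internal"` (extended-XYZ-like dialect written by
#'   [write_trajectory()])
#' @param box optional fallback box side lengths (nm) for formats lacking
#'   box records (e.g. PDB without CRYST1)
#' @return a [trajectory()]
#' @export
read_trajectory <- function(path, topology,
                            format = c("pdb", "gro", "internal"),
                            box = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  frames <- switch(format,
    pdb = read_frames_pdb(path, box),
    gro = read_frames_gro(path),
    internal = read_frames_internal(path)
  )
  nat <- n_atoms(topology)
  for (f in frames) {
    if (nrow(f$xyz) != nat) {
      stop(sprintf(
        "atom-count mismatch: topology has %d atoms, frame has %d",
        nat, nrow(f$xyz)))
    }
  }
  trajectory(topology, frames)
}

read_frames_pdb <- function(path, box = NULL) {
  lines <- readLines(path)
  cryst <- grep("^CRYST1", lines, value = TRUE)
  if (length(cryst) > 0L) {
    a <- as.numeric(substr(cryst[1L], 7L, 15L))
    b <- as.numeric(substr(cryst[1L], 16L, 24L))
    c_ <- as.numeric(substr(cryst[1L], 25L, 33L))
    angles <- c(as.numeric(substr(cryst[1L], 34L, 40L)),
                as.numeric(substr(cryst[1L], 41L, 47L)),
                as.numeric(substr(cryst[1L], 48L, 54L)))
    if (any(abs(angles - 90) > 1e-3)) {
      stop("triclinic cells are not supported (CRYST1 angles != 90)")
    }
    box <- c(a, b, c_) / 10  # A -> nm
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
  n_models <- nrow(xyz)
  if (is.null(box)) {
    span <- apply(matrix(xyz[1L, ], ncol = 3L, byrow = TRUE), 2L,
                  function(v) diff(range(v))) / 10
    box <- span + 100
    warning("PDB file has no CRYST1 record; using a box large enough to ",
            "make periodic images irrelevant")
  }
  lapply(seq_len(n_models), function(i) {
    frame(matrix(xyz[i, ], ncol = 3L, byrow = TRUE) / 10, box,
          time = (i - 1))
  })
}

read_frames_gro <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n && trimws(lines[i]) == "") i <- i + 1L
  while (i <= n) {
    title <- lines[i]
    nat <- as.integer(trimws(lines[i + 1L]))
    rows <- lines[(i + 2L):(i + 1L + nat)]
    x <- as.numeric(substr(rows, 21L, 28L))
    y <- as.numeric(substr(rows, 29L, 36L))
    z <- as.numeric(substr(rows, 37L, 44L))
    boxline <- as.numeric(strsplit(trimws(lines[i + 2L + nat]), "\\s+")[[1L]])
    if (length(boxline) > 3L && any(abs(boxline[-(1:3)]) > 1e-12)) {
      stop("triclinic cells are not supported (GRO box line has ",
           "off-diagonal components)")
    }
    tm <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    time <- if (length(tm)) as.numeric(sub("t=\\s*", "", tm)) else
      length(frames)
    frames[[length(frames) + 1L]] <- frame(cbind(x, y, z), boxline[1:3], time)
    i <- i + 3L + nat
    while (i <= n && trimws(lines[i]) == "") i <- i + 1L
  }
  frames
}

read_frames_internal <- function(path) {
  lines <- readLines(path)
  lines <- lines[trimws(lines) != ""]
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    nat <- as.integer(trimws(lines[i]))
    if (is.na(nat)) stop("malformed internal trajectory at line ", i,
                         ": expected an atom count")
    hdr <- lines[i + 1L]
    time <- as.numeric(sub(".*t=([-0-9.eE+]+).*", "\\1", hdr))
    boxm <- regmatches(hdr, regexpr("box=\\s*[-0-9.eE+ ]+", hdr))
    box <- as.numeric(strsplit(sub("box=\\s*", "", boxm), "\\s+")[[1L]])[1:3]
    rows <- strsplit(lines[(i + 2L):(i + 1L + nat)], "\\s+")
    m <- do.call(rbind, lapply(rows, function(r) as.numeric(r[2:4])))
    frames[[length(frames) + 1L]] <- frame(m, box, time)
    i <- i + 2L + nat
  }
  frames
}

#' Write a trajectory to file
#'
#' The internal dialect is extended-XYZ-like plain text: per frame an
#' atom-count line, a header line `t=<ps> box=<a> <b> <c>` (nm), then one
#' `name x y z` line per atom printed with 17 significant digits, so that
#' reading the file back reproduces coordinates bit-identically. PDB output
#' is written in Angstrom with the format's 3-decimal precision (round trip
#' exact to 5e-4 nm); GRO in nm with 3 decimals.
#'
#' @param trajectory a trajectory
#' @param path output path
#' @param format `"internal"`, `"pdb"` or `"gro"`
#' @export
write_trajectory <- function(trajectory, path,
                             format = c("internal", "pdb", "gro")) {
  format <- match.arg(format)
  switch(format,
    internal = write_trajectory_internal(trajectory, path),
    pdb = write_trajectory_pdb(trajectory, path),
    gro = write_trajectory_gro(trajectory, path)
  )
  invisible(path)
}

write_trajectory_internal <- function(trajectory, path) {
  con <- file(path, "w")
  on.exit(close(con))
  names_ <- trajectory$topology$atoms$name
  for (f in trajectory$frames) {
    writeLines(as.character(nrow(f$xyz)), con)
    writeLines(sprintf("t=%.17g box=%.17g %.17g %.17g",
                       f$time, f$box[1L], f$box[2L], f$box[3L]), con)
    writeLines(sprintf("%s %.17g %.17g %.17g", names_,
                       f$xyz[, 1L], f$xyz[, 2L], f$xyz[, 3L]), con)
  }
}

write_trajectory_pdb <- function(trajectory, path) {
  at <- trajectory$topology$atoms
  con <- file(path, "w")
  on.exit(close(con))
  chains <- rep_len(c(LETTERS, letters, 0:9), max(at$molecule))[at$molecule]
  for (k in seq_along(trajectory$frames)) {
    f <- trajectory$frames[[k]]
    if (k == 1L) {
      writeLines(sprintf(
        "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
        f$box[1L] * 10, f$box[2L] * 10, f$box[3L] * 10, 90, 90, 90), con)
    }
    writeLines(sprintf("MODEL     %4d", k), con)
    nm <- ifelse(nchar(at$name) < 4L, paste0(" ", at$name), at$name)
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(at)) %% 100000L, substr(nm, 1L, 4L),
      substr(at$resname, 1L, 3L), chains, at$resid,
      f$xyz[, 1L] * 10, f$xyz[, 2L] * 10, f$xyz[, 3L] * 10, 1, 0,
      substr(at$element, 1L, 2L)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
}

write_trajectory_gro <- function(trajectory, path) {
  at <- trajectory$topology$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (f in trajectory$frames) {
    writeLines(sprintf("aggtraj frame t= %.6f", f$time), con)
    writeLines(sprintf("%5d", nrow(at)), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       at$resid %% 100000L, substr(at$resname, 1L, 5L),
                       substr(at$name, 1L, 5L),
                       seq_len(nrow(at)) %% 100000L,
                       f$xyz[, 1L], f$xyz[, 2L], f$xyz[, 3L]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f",
                       f$box[1L], f$box[2L], f$box[3L]), con)
  }
}
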