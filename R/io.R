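#' Write a system snapshot as a LAMMPS data file
#'
#' Molecular-style data file with `Atoms # molecular` (id mol type x y z)
#' plus `Velocities` and `Bonds` sections; the topology companion to the
#' dump trajectory format.
#'
#' @param state A `cg_system`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_lammps_data <- function(state, path) {
  n <- nrow(state$pos)
  nb <- nrow(state$bonds)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "LAMMPS data file generated by demicellr",
    "",
    paste(n, "atoms"),
    paste(nb, "bonds"),
    paste(length(BEAD_TYPES), "atom types"),
    paste(1, "bond types"),
    "",
    paste(0, state$L, "xlo xhi"),
    paste(0, state$L, "ylo yhi"),
    paste(0, state$L, "zlo zhi"),
    "",
    "Atoms # molecular",
    ""), con)
  writeLines(sprintf("%d %d %d %.10g %.10g %.10g %d %d %d",
                     seq_len(n), state$mol, state$types,
                     state$pos[, 1], state$pos[, 2], state$pos[, 3],
                     state$img[, 1], state$img[, 2], state$img[, 3]), con)
  writeLines(c("", "Velocities", ""), con)
  writeLines(sprintf("%d %.10g %.10g %.10g", seq_len(n),
                     state$vel[, 1], state$vel[, 2], state$vel[, 3]), con)
  if (nb) {
    writeLines(c("", "Bonds", ""), con)
    writeLines(sprintf("%d 1 %d %d", seq_len(nb),
                       state$bonds[, 1], state$bonds[, 2]), con)
  }
  invisible(path)
}

# Species from bead composition: used when reading formats that do not
# carry species names.
infer_species <- function(tags) {
  n_ec <- sum(tags == "EC")
  if (length(tags) == 60 && sum(tags == "A") == 30) {
    return(switch(as.character(n_ec),
                  "1" = "A30B30", "2" = "A30(B15)2", "3" = "A30(B10)3",
                  paste0("copolymer_", n_ec, "ec")))
  }
  if (all(tags == "C")) return("C3")
  if (identical(tags, "T")) return("T")
  if (identical(tags, "X")) return("X")
  "fragment"
}

#' Read a LAMMPS data file written by [write_lammps_data()]
#'
#' @param path Input file.
#' @return A `cg_system`; per-molecule species are inferred from bead
#'   composition.
#' @export
read_lammps_data <- function(path) {
  lines <- readLines(path)
  grab <- function(pat) as.numeric(sub(paste0("\\s*", pat, ".*"), "",
                                       lines[grep(pat, lines)[1]]))
  n <- grab("atoms")
  nb <- grab("bonds")
  xhi <- as.numeric(strsplit(trimws(lines[grep("xlo xhi", lines)[1]]),
                             "\\s+")[[1]][2])
  sect <- function(name, ncol, nrow) {
    i <- grep(paste0("^", name), lines)[1]
    if (is.na(i) || nrow == 0) return(NULL)
    block <- lines[(i + 2):(i + 1 + nrow)]
    m <- do.call(rbind, lapply(strsplit(trimws(block), "\\s+"), as.numeric))
    m[order(m[, 1]), , drop = FALSE]
  }
  atoms <- sect("Atoms", 9, n)
  vels <- sect("Velocities", 4, n)
  bonds <- sect("Bonds", 4, nb)
  img <- if (ncol(atoms) >= 9) atoms[, 7:9, drop = FALSE] else
    matrix(0, n, 3)
  state <- list(
    pos = atoms[, 4:6, drop = FALSE],
    img = matrix(as.integer(img), n, 3),
    vel = if (!is.null(vels)) vels[, 2:4, drop = FALSE] else matrix(0, n, 3),
    types = as.integer(atoms[, 3]),
    bonds = if (!is.null(bonds))
      matrix(as.integer(bonds[, 3:4]), ncol = 2) else
        matrix(integer(0), ncol = 2),
    mol = as.integer(atoms[, 2]),
    L = xhi, time = 0
  )
  mols <- sort(unique(state$mol))
  state$mol_species <- vapply(mols, function(m)
    infer_species(TYPE_TAGS[state$types[state$mol == m]]), "")
  state$mol_offset <- vapply(mols, function(m)
    min(which(state$mol == m)) - 1L, 0L)
  state$phi <- n / xhi^3
  class(state) <- "cg_system"
  state
}

#' Write a trajectory in the LAMMPS dump dialect
#'
#' Atom style `id mol type x y z ix iy iz` per frame (image flags included
#' so displacement analyses can unwrap the coordinates). Timesteps are the
#' frame times divided by `dt`.
#'
#' @param traj A `cg_trajectory` (or a single `cg_system`, written as one
#'   frame).
#' @param path Output file.
#' @param dt Integration step used to convert times to step numbers.
#' @return `path`, invisibly.
#' @export
write_lammps_dump <- function(traj, path, dt = 0.006) {
  if (inherits(traj, "cg_system")) {
    traj <- list(frames = list(list(pos = traj$pos, img = traj$img,
                                    time = traj$time)),
                 state = traj)
  }
  st <- traj$state
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in traj$frames) {
    n <- nrow(fr$pos)
    types <- if (!is.null(fr$types)) fr$types else st$types
    writeLines(c("ITEM: TIMESTEP",
                 format(round(fr$time / dt), scientific = FALSE),
                 "ITEM: NUMBER OF ATOMS",
                 as.character(n),
                 "ITEM: BOX BOUNDS pp pp pp",
                 paste(0, st$L), paste(0, st$L), paste(0, st$L),
                 "ITEM: ATOMS id mol type x y z ix iy iz"), con)
    writeLines(sprintf("%d %d %d %.10g %.10g %.10g %d %d %d",
                       seq_len(n), st$mol, types,
                       fr$pos[, 1], fr$pos[, 2], fr$pos[, 3],
                       fr$img[, 1], fr$img[, 2], fr$img[, 3]), con)
  }
  invisible(path)
}

#' Read a LAMMPS dump trajectory
#'
#' Reads the dialect written by [write_lammps_dump()]. Dump files carry no
#' bond topology, so supply the matching data file via `topology` when the
#' downstream analysis needs bonds (clustering of depolymerizing systems).
#'
#' @param path Dump file.
#' @param dt Integration step to convert step numbers back to times.
#' @param topology Optional path of a LAMMPS data file with the bonds.
#' @return A `cg_trajectory`.
#' @export
read_lammps_dump <- function(path, dt = 0.006, topology = NULL) {
  lines <- readLines(path)
  starts <- grep("^ITEM: TIMESTEP", lines)
  frames <- vector("list", length(starts))
  L <- NA_real_
  first_state <- NULL
  for (f in seq_along(starts)) {
    i <- starts[f]
    step <- as.numeric(lines[i + 1])
    n <- as.integer(lines[i + 3])
    L <- as.numeric(strsplit(trimws(lines[i + 5]), "\\s+")[[1]][2])
    rows <- lines[(i + 9):(i + 8 + n)]
    m <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"), as.numeric))
    m <- m[order(m[, 1]), , drop = FALSE]
    frames[[f]] <- list(pos = m[, 4:6, drop = FALSE],
                        img = matrix(as.integer(m[, 7:9]), n, 3),
                        time = step * dt,
                        types = as.integer(m[, 3]))
    if (f == 1) {
      first_state <- list(mol = as.integer(m[, 2]),
                          types = as.integer(m[, 3]), n = n)
    }
  }
  if (!is.null(topology)) {
    state <- read_lammps_data(topology)
  } else {
    mol <- first_state$mol
    state <- list(pos = frames[[1]]$pos, img = frames[[1]]$img,
                  vel = matrix(0, first_state$n, 3),
                  types = first_state$types,
                  bonds = matrix(integer(0), ncol = 2),
                  mol = mol, L = L, time = frames[[1]]$time)
    mols <- sort(unique(mol))
    state$mol_species <- vapply(mols, function(m2)
      infer_species(TYPE_TAGS[state$types[mol == m2]]), "")
    state$mol_offset <- vapply(mols, function(m2)
      min(which(mol == m2)) - 1L, 0L)
    state$phi <- first_state$n / L^3
    class(state) <- "cg_system"
  }
  fin <- frames[[length(frames)]]
  state$pos <- fin$pos
  state$img <- fin$img
  state$time <- fin$time
  structure(list(frames = frames, state = state, ledger = NULL,
                 events = NULL),
            class = "cg_trajectory")
}

#' Write a snapshot as extended XYZ
#'
#' One frame per call: comment line carries the box length and time;
#' columns are species tag, x, y, z, molecule id, and image flags.
#'
#' @param state A `cg_system`.
#' @param path Output file.
#' @param append Append as an additional frame.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(state, path, append = FALSE) {
  n <- nrow(state$pos)
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  writeLines(c(as.character(n),
               sprintf('Lattice="%.8g 0 0 0 %.8g 0 0 0 %.8g" Time=%.8g Properties=species:S:1:pos:R:3:mol:I:1:image:I:3',
                       state$L, state$L, state$L, state$time)), con)
  writeLines(sprintf("%s %.10g %.10g %.10g %d %d %d %d",
                     TYPE_TAGS[state$types],
                     state$pos[, 1], state$pos[, 2], state$pos[, 3],
                     state$mol,
                     state$img[, 1], state$img[, 2], state$img[, 3]), con)
  invisible(path)
}

#' Read an extended XYZ snapshot written by [write_xyz()]
#'
#' @param path Input file.
#' @return A `cg_system` without bonds (species inferred from composition).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  L <- as.numeric(sub('.*Lattice="([0-9.eE+-]+) .*', "\\1", lines[2]))
  tm <- suppressWarnings(as.numeric(sub('.*Time=([0-9.eE+-]+).*', "\\1",
                                        lines[2])))
  if (is.na(tm)) tm <- 0
  m <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  tags <- vapply(m, `[[`, "", 1)
  num <- do.call(rbind, lapply(m, function(r) as.numeric(r[-1])))
  mol <- as.integer(num[, 4])
  state <- list(pos = num[, 1:3, drop = FALSE],
                img = matrix(as.integer(num[, 5:7]), n, 3),
                vel = matrix(0, n, 3),
                types = unname(BEAD_TYPES[tags]),
                bonds = matrix(integer(0), ncol = 2),
                mol = mol, L = L, time = tm)
  mols <- sort(unique(mol))
  state$mol_species <- vapply(mols, function(m2)
    infer_species(tags[mol == m2]), "")
  state$mol_offset <- vapply(mols, function(m2)
    min(which(mol == m2)) - 1L, 0L)
  state$phi <- n / L^3
  class(state) <- "cg_system"
  state
}
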