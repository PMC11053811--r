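#' Edge length of the cubic simulation box
#'
#' The box is sized so that the total bead number density equals `phi`
#' (beads per sigma^3): `L = (n_beads / phi)^(1/3)`.
#'
#' @param n_beads Total number of beads.
#' @param phi Bead number density (dimensionless in reduced units).
#' @return Box edge length in sigma.
#' @export
box_length <- function(n_beads, phi) {
  if (n_beads < 1) stop("n_beads must be >= 1")
  if (phi <= 0 || phi > 1) stop("phi must be in (0, 1]")
  (n_beads / phi)^(1 / 3)
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

random_unit_vector <- function() {
  repeat {
    v <- stats::rnorm(3)
    n2 <- sum(v * v)
    if (n2 > 1e-12) return(v / sqrt(n2))
  }
}

# Grow one molecule as a random walk over its bond tree with bond length
# `blen`, rejecting growth steps that put a bead closer than `min_dist` to a
# non-bonded bead of the same molecule.
place_molecule <- function(tmpl, origin, blen = 0.97, min_dist = 0.8,
                           max_step_tries = 60, L = Inf) {
  n <- tmpl$n_beads
  pos <- matrix(NA_real_, n, 3)
  pos[1, ] <- origin
  if (n == 1L) return(pos)
  # children in bond order: templates list bonds so that the first index of
  # a bond is always already placed when walking in row order
  for (k in seq_len(nrow(tmpl$bonds))) {
    i <- tmpl$bonds[k, 1]; j <- tmpl$bonds[k, 2]
    if (is.na(pos[j, 1]) && !is.na(pos[i, 1])) {
      anchor <- i; new <- j
    } else if (is.na(pos[i, 1]) && !is.na(pos[j, 1])) {
      anchor <- j; new <- i
    } else if (is.na(pos[i, 1]) && is.na(pos[j, 1])) {
      stop("template bonds are not in growth order")
    } else next
    placed <- which(!is.na(pos[, 1]))
    placed <- placed[placed != anchor]
    ok <- FALSE
    for (t in seq_len(max_step_tries)) {
      cand <- pos[anchor, ] + blen * random_unit_vector()
      if (length(placed)) {
        # minimum image: a long walk can wrap around the periodic box
        dx <- abs(pos[placed, 1] - cand[1]) %% L; dx <- pmin(dx, L - dx)
        dy <- abs(pos[placed, 2] - cand[2]) %% L; dy <- pmin(dy, L - dy)
        dz <- abs(pos[placed, 3] - cand[3]) %% L; dz <- pmin(dz, L - dz)
        if (min(dx * dx + dy * dy + dz * dz) < min_dist^2) next
      }
      pos[new, ] <- cand
      ok <- TRUE
      break
    }
    if (!ok) return(NULL)
  }
  pos
}

#' Assemble a random initial configuration
#'
#' Places molecules as random walks (bond length about 0.97 sigma) at random
#' positions and orientations in a cubic periodic box sized for the requested
#' bead density, enforcing a minimum non-bonded insertion distance of
#' `min_dist`. Residual soft overlaps are acceptable because the push-off
#' stage of [run_protocol()] relaxes the initial conformation. Velocities are
#' drawn from the Maxwell-Boltzmann distribution at temperature `tstar` with
#' the centre-of-mass momentum removed. The result is deterministic for a
#' fixed seed.
#'
#' @param template_counts Named integer vector, e.g.
#'   `c("A30B30" = 1000, "C3" = 2000)`; names are species accepted by
#'   [build_template()].
#' @param phi Total bead number density (default 0.12, the density at which
#'   most chains assemble into micelles).
#' @param seed Integer seed (mandatory: runs must be reproducible).
#' @param tstar Temperature for the initial velocities (default 1.8).
#' @param min_dist Minimum insertion distance between non-bonded beads.
#' @param max_attempts Placement attempts per molecule before giving up.
#' @return A `cg_system` object: list with `pos` (n x 3, wrapped into
#'   `[0, L)`), `img` (integer image flags; unwrapped = pos + img * L),
#'   `vel`, `types` (integer codes, see [BEAD_TYPES]), `bonds` (m x 2),
#'   `mol` (per-bead molecule id), `mol_species` (per-molecule species name),
#'   `mol_offset` (per-molecule index of the bead before its first), `L`,
#'   `phi`, `time`.
#' @export
assemble_system <- function(template_counts, phi = 0.12, seed,
                            tstar = 1.8, min_dist = 0.8, max_attempts = 200) {
  if (missing(seed)) stop("seed is required")
  counts <- template_counts[template_counts > 0]
  if (!length(counts)) stop("at least one species count must be >= 1")
  tmpls <- lapply(names(counts), build_template)
  names(tmpls) <- names(counts)
  n_total <- sum(vapply(tmpls, `[[`, 0L, "n_beads") * counts)
  L <- box_length(n_total, phi)

  pos <- matrix(NA_real_, n_total, 3)
  types <- integer(n_total)
  mol <- integer(n_total)
  bonds <- vector("list", sum(counts))
  mol_species <- character(sum(counts))
  mol_offset <- integer(sum(counts))

  with_local_seed(seed, {
    offset <- 0L
    mol_id <- 0L
    for (sp in names(counts)) {
      tmpl <- tmpls[[sp]]
      for (rep in seq_len(counts[[sp]])) {
        mol_id <- mol_id + 1L
        placed_ok <- FALSE
        # soft-overlap tolerance: if the box is too crowded at the nominal
        # insertion distance, retry with a progressively smaller one (the
        # push-off stage relaxes residual overlaps)
        for (attempt in seq_len(max_attempts)) {
          dist_now <- min_dist *
            c(1, 1, 1, 0.9, 0.8)[min(5L, 1L + attempt %/% 50L)]
          origin <- stats::runif(3, 0, L)
          mp <- place_molecule(tmpl, origin, min_dist = dist_now, L = L)
          if (is.null(mp)) next
          # check against already placed beads (minimum image)
          if (offset > 0L) {
            prev <- pos[seq_len(offset), , drop = FALSE]
            ok <- TRUE
            for (b in seq_len(nrow(mp))) {
              dx <- abs(prev[, 1] - (mp[b, 1] %% L)); dx <- pmin(dx, L - dx)
              dy <- abs(prev[, 2] - (mp[b, 2] %% L)); dy <- pmin(dy, L - dy)
              dz <- abs(prev[, 3] - (mp[b, 3] %% L)); dz <- pmin(dz, L - dz)
              if (min(dx * dx + dy * dy + dz * dz) < dist_now^2) {
                ok <- FALSE
                break
              }
            }
            if (!ok) next
          }
          idx <- offset + seq_len(tmpl$n_beads)
          pos[idx, ] <- mp %% L
          types[idx] <- tmpl$types
          mol[idx] <- mol_id
          if (nrow(tmpl$bonds)) bonds[[mol_id]] <- tmpl$bonds + offset
          mol_species[mol_id] <- sp
          mol_offset[mol_id] <- offset
          offset <- offset + tmpl$n_beads
          placed_ok <- TRUE
          break
        }
        if (!placed_ok) {
          stop("packing failure: could not place molecule ", mol_id,
               " (", sp, ") after ", max_attempts, " attempts at phi = ", phi)
        }
      }
    }
    vel <- matrix(stats::rnorm(3 * n_total, sd = sqrt(tstar)), n_total, 3)
  })
  vel <- sweep(vel, 2, colMeans(vel))  # zero net momentum
  bonds <- do.call(rbind, bonds[!vapply(bonds, is.null, TRUE)])
  if (is.null(bonds)) bonds <- matrix(integer(0), ncol = 2)
  storage.mode(bonds) <- "integer"
  structure(list(
    pos = pos, img = matrix(0L, n_total, 3), vel = vel, types = types,
    bonds = bonds, mol = mol, mol_species = mol_species,
    mol_offset = mol_offset, L = L, phi = phi, time = 0
  ), class = "cg_system")
}

#' @export
print.cg_system <- function(x, ...) {
  cat("<cg_system> ", nrow(x$pos), " beads, ", nrow(x$bonds), " bonds, ",
      length(x$mol_species), " molecules, L = ", signif(x$L, 5),
      " sigma, t = ", signif(x$time, 6), " tau\n", sep = "")
  invisible(x)
}

#' Unwrapped bead coordinates
#'
#' @param state A `cg_system`.
#' @return n x 3 matrix `pos + img * L` (continuous trajectories for MSD).
#' @export
unwrapped_positions <- function(state) {
  state$pos + state$img * state$L
}

#' Instantaneous kinetic temperature
#'
#' Equipartition estimate `sum(m v^2) / (3 N)` with m = 1, k_B = 1.
#'
#' @param state A `cg_system`.
#' @return Temperature in reduced units.
#' @export
kinetic_temperature <- function(state) {
  sum(state$vel^2) / (3 * nrow(state$pos))
}

#' Insert trigger molecules into an assembled snapshot
#'
#' Adds `n_triggers` single-bead T-type molecules at uniformly random void
#' positions (at least `min_dist` from every existing bead, minimum image).
#' The box is unchanged, so the total bead density rises accordingly.
#'
#' @param state A `cg_system`, typically a post-micellization snapshot.
#' @param n_triggers Number of trigger beads to insert.
#' @param seed Integer seed.
#' @param tstar Temperature for the new beads' velocities.
#' @param min_dist Minimum insertion distance.
#' @param max_attempts Attempts per trigger before failing.
#' @return The augmented `cg_system` (phi recomputed from the new bead count).
#' @export
insert_triggers <- function(state, n_triggers, seed, tstar = 1.8,
                            min_dist = 0.8, max_attempts = 2000) {
  if (missing(seed)) stop("seed is required")
  if (n_triggers == 0) return(state)
  L <- state$L
  n0 <- nrow(state$pos)
  newpos <- matrix(NA_real_, n_triggers, 3)
  with_local_seed(seed, {
    allpos <- state$pos
    for (k in seq_len(n_triggers)) {
      ok <- FALSE
      for (attempt in seq_len(max_attempts)) {
        cand <- stats::runif(3, 0, L)
        dx <- abs(allpos[, 1] - cand[1]); dx <- pmin(dx, L - dx)
        dy <- abs(allpos[, 2] - cand[2]); dy <- pmin(dy, L - dy)
        dz <- abs(allpos[, 3] - cand[3]); dz <- pmin(dz, L - dz)
        if (min(dx * dx + dy * dy + dz * dz) >= min_dist^2) {
          newpos[k, ] <- cand
          allpos <- rbind(allpos, cand)
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("trigger insertion failed after ", max_attempts,
                    " attempts (box too crowded)")
    }
    newvel <- matrix(stats::rnorm(3 * n_triggers, sd = sqrt(tstar)),
                      n_triggers, 3)
  })
  mol0 <- length(state$mol_species)
  state$pos <- rbind(state$pos, newpos)
  state$img <- rbind(state$img, matrix(0L, n_triggers, 3))
  state$vel <- rbind(state$vel, newvel)
  state$types <- c(state$types, rep(BEAD_TYPES[["T"]], n_triggers))
  state$mol <- c(state$mol, mol0 + seq_len(n_triggers))
  state$mol_species <- c(state$mol_species, rep("T", n_triggers))
  state$mol_offset <- c(state$mol_offset, n0 + seq_len(n_triggers) - 1L)
  state$phi <- nrow(state$pos) / L^3
  state
}

#' Stoichiometric trigger count for a species mix
#'
#' One trigger per end-cap: `chains x end-caps per chain` summed over
#' copolymer species.
#'
#' @param template_counts Named counts as in [assemble_system()].
#' @return Integer trigger count.
#' @export
stoichiometric_triggers <- function(template_counts) {
  total <- 0L
  for (sp in names(template_counts)) {
    tmpl <- build_template(sp)
    total <- total + template_counts[[sp]] * length(tmpl$endcap_indices)
  }
  as.integer(total)
}
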