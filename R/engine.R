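#' Truncated and shifted Lennard-Jones pair energy
#'
#' `U(r) = 4 eps [ (1/r)^12 - (1/r)^6 - (1/rc)^12 + (1/rc)^6 ]` up to the
#' cutoff rc and 0 beyond it (sigma = 1). The shift makes the
#' potential continuous (zero) at the cutoff; with `rc = 2^(1/6)` this is the
#' purely repulsive Weeks-Chandler-Andersen form shifted by eps.
#'
#' @param r Pair distance(s) in sigma; must be positive.
#' @param eps_ij Well depth in epsilon.
#' @param rc_ij Cutoff distance in sigma.
#' @return Energy in epsilon units (vectorized over `r`).
#' @export
lj_pair_energy <- function(r, eps_ij = 1, rc_ij = 2.5) {
  if (any(r <= 0)) stop("overlap singularity: r must be > 0")
  s6 <- r^-6
  sc6 <- rc_ij^-6
  u <- 4 * eps_ij * (s6^2 - s6 - sc6^2 + sc6)
  u[r > rc_ij] <- 0
  u
}

#' FENE bond energy
#'
#' `U(r) = -0.5 k R0^2 ln(1 - (r/R0)^2)` below the maximum extension `R0`;
#' the bond is inextensible beyond `R0`, so any r at or past `R0` is
#' unphysical and raises an error.
#'
#' @param r Bond length(s) in sigma (non-negative).
#' @param k Spring constant (default 25 eps/sigma^2).
#' @param R0 Maximum extension (default 1.5 sigma).
#' @return Energy in epsilon units (vectorized over `r`).
#' @export
fene_bond_energy <- function(r, k = 25, R0 = 1.5) {
  if (any(r < 0)) stop("r must be non-negative")
  if (any(r >= R0)) {
    stop("FENE bond overstretched: r = ",
         paste(signif(r[r >= R0], 5), collapse = ", "), " >= R0 = ", R0)
  }
  -0.5 * k * R0^2 * log(1 - (r / R0)^2)
}

#' Simulation protocol settings
#'
#' Bundles integrator and staging parameters. The reference protocol is a
#' push-off stage with all cutoffs truncated to `2^(1/6)` sigma (purely
#' repulsive, to relax the random initial conformation), an equilibration
#' stage, and a production stage; `scale_factor` divides the reference step
#' counts (2e6 / 30e6 / 3e8) so the same protocol can be run at desk scale.
#'
#' @param dt Integration step in tau (default 0.006).
#' @param tstar Thermostat temperature `k_B T / eps` (default 1.8).
#' @param gamma Langevin friction in 1/tau (default 1.0; the absolute time
#'   scale of the kinetics depends on this choice).
#' @param n_pushoff,n_equil,n_prod Stage step counts (before scaling).
#' @param snapshot_every Steps between stored trajectory frames.
#' @param scale_factor Divisor applied to the three stage lengths.
#' @param bonded_lj Should bonded pairs also feel the LJ pair term
#'   (Kremer-Grest convention)? Default `TRUE`.
#' @return A `simulation_protocol` object.
#' @export
simulation_protocol <- function(dt = 0.006, tstar = 1.8, gamma = 1.0,
                                n_pushoff = 2e6, n_equil = 30e6, n_prod = 3e8,
                                snapshot_every = 1e4, scale_factor = 1,
                                bonded_lj = TRUE) {
  stopifnot(dt > 0, tstar > 0, gamma >= 0, scale_factor >= 1,
            n_pushoff >= 0, n_equil >= 0, n_prod >= 0)
  structure(list(
    dt = dt, tstar = tstar, gamma = gamma,
    n_pushoff = as.integer(round(n_pushoff / scale_factor)),
    n_equil = as.integer(round(n_equil / scale_factor)),
    n_prod = as.integer(round(n_prod / scale_factor)),
    snapshot_every = as.integer(snapshot_every),
    scale_factor = scale_factor, bonded_lj = bonded_lj
  ), class = "simulation_protocol")
}

#' Forces on every bead
#'
#' Evaluates the full force field (pair LJ via a cell list with the
#' minimum-image convention, plus FENE bonds) and returns the per-bead force
#' array. Newton's third law holds pairwise, so the forces sum to zero up to
#' rounding.
#'
#' @param state A `cg_system`.
#' @param table An `interaction_table`.
#' @param bonded_lj Apply the LJ pair term to bonded pairs as well.
#' @return n x 3 force matrix (epsilon/sigma units).
#' @export
compute_forces <- function(state, table, bonded_lj = TRUE) {
  .forces_cpp(state$pos, state$types, state$bonds, table$eps, table$rcut,
              state$L, table$fene_k, table$fene_R0, bonded_lj)
}

#' Total potential energy of a configuration
#'
#' @inheritParams compute_forces
#' @return Scalar energy in epsilon units.
#' @export
potential_energy <- function(state, table, bonded_lj = TRUE) {
  .potential_energy_cpp(state$pos, state$types, state$bonds, table$eps,
                        table$rcut, state$L, table$fene_k, table$fene_R0,
                        bonded_lj)
}

#' Advance the system with Langevin dynamics
#'
#' Integrates `n_steps` of BAOAB-split Langevin dynamics (velocity Verlet
#' plus an exact Ornstein-Uhlenbeck velocity update) at the protocol's
#' temperature and friction, under cubic periodic boundaries. With
#' `gamma = 0` the thermostat is off and the integrator is plain (symplectic)
#' velocity Verlet. Wrapped positions and image flags are both maintained.
#' Deterministic for a fixed seed.
#'
#' @param state A `cg_system`.
#' @param protocol A `simulation_protocol` (only `dt`, `tstar`, `gamma`,
#'   `bonded_lj` are used here).
#' @param table An `interaction_table`; pass a push-off table (see
#'   [pushoff_table()]) for the repulsive stage.
#' @param n_steps Number of integration steps.
#' @param seed Integer seed for the thermostat noise.
#' @param limit_disp Optional per-step displacement cap in sigma (0 = off);
#'   used during push-off to defuse residual overlaps of the random initial
#'   configuration.
#' @return The advanced `cg_system` (time incremented by `n_steps * dt`).
#' @export
step_langevin <- function(state, protocol, table, n_steps, seed,
                          limit_disp = 0) {
  if (missing(seed)) stop("seed is required")
  if (n_steps == 0) return(state)
  out <- .advance_cpp(state$pos, state$img, state$vel, state$types,
                      state$bonds, table$eps, table$rcut, state$L,
                      table$fene_k, table$fene_R0, protocol$bonded_lj,
                      as.integer(n_steps), protocol$dt, protocol$gamma,
                      protocol$tstar, as.double(seed), limit_disp)
  state$pos <- out$pos
  state$img <- out$img
  state$vel <- out$vel
  state$time <- state$time + n_steps * protocol$dt
  state
}

#' Push-off variant of an interaction table
#'
#' All cutoffs truncated to `2^(1/6)` sigma (shifted, purely repulsive), as
#' used in the initial stage to remove bias from the random starting
#' conformation.
#'
#' @param table An `interaction_table`.
#' @return The modified table.
#' @export
pushoff_table <- function(table) {
  table$rcut[] <- 2^(1 / 6)
  table
}

#' Run the three-stage simulation protocol
#'
#' Stage 1 (push-off) integrates with all pair cutoffs at `2^(1/6)` sigma;
#' stages 2 (equilibration) and 3 (production) use the full interaction
#' table. Snapshots are collected every `snapshot_every` steps during
#' production (plus the frame at the start of production). If a reaction
#' system is attached, reaction sweeps are interleaved with integration
#' during production (see [attach_reactions()]).
#'
#' @param state A `cg_system`.
#' @param protocol A `simulation_protocol`.
#' @param table An `interaction_table`.
#' @param seed Integer seed.
#' @param reactions Optional reaction system created by [attach_reactions()].
#' @param progress Print stage progress.
#' @return A `cg_trajectory`: list with `frames` (list of snapshots: `pos`,
#'   `img`, `time`, plus `bonds`/`types` when reactions are active), `state`
#'   (final `cg_system`), `ledger` (depolymerization ledger or `NULL`), and
#'   `events` (reaction event data frame or `NULL`).
#' @export
run_protocol <- function(state, protocol, table, seed, reactions = NULL,
                         progress = FALSE) {
  if (missing(seed)) stop("seed is required")
  seeds <- derive_seeds(seed, 4L)
  if (protocol$n_pushoff > 0) {
    if (progress) message("push-off: ", protocol$n_pushoff, " steps")
    state <- step_langevin(state, protocol, pushoff_table(table),
                           protocol$n_pushoff, seeds[1], limit_disp = 0.05)
  }
  if (protocol$n_equil > 0) {
    if (progress) message("equilibration: ", protocol$n_equil, " steps")
    state <- step_langevin(state, protocol, table, protocol$n_equil, seeds[2])
  }
  run_production(state, protocol, table, seeds[3], reactions,
                 reaction_seed = seeds[4], progress = progress)
}

# Production stage: integrate in chunks of snapshot_every steps, optionally
# interleaving reaction sweeps every `attempt_every` steps.
run_production <- function(state, protocol, table, seed, reactions = NULL,
                           reaction_seed = seed + 1, progress = FALSE) {
  frames <- list()
  record <- function(state) {
    fr <- list(pos = state$pos, img = state$img, time = state$time)
    if (!is.null(reactions)) {
      fr$bonds <- state$bonds
      fr$types <- state$types
    }
    fr
  }
  frames[[1]] <- record(state)
  n_prod <- protocol$n_prod
  if (n_prod > 0) {
    chunk <- if (is.null(reactions)) protocol$snapshot_every else
      min(protocol$snapshot_every, reactions$params$attempt_every)
    n_chunks <- ceiling(n_prod / chunk)
    sub_seeds <- derive_seeds(seed, n_chunks)
    steps_done <- 0L
    next_snap <- protocol$snapshot_every
    for (ck in seq_len(n_chunks)) {
      n_now <- min(chunk, n_prod - steps_done)
      state <- step_langevin(state, protocol, table, n_now, sub_seeds[ck])
      steps_done <- steps_done + n_now
      if (!is.null(reactions) &&
          steps_done %% reactions$params$attempt_every == 0L) {
        res <- reaction_sweep(state, reactions)
        state <- res$state
        reactions <- res$reactions
      }
      if (steps_done >= next_snap) {
        frames[[length(frames) + 1L]] <- record(state)
        next_snap <- next_snap + protocol$snapshot_every
      }
      if (progress && ck %% max(1L, n_chunks %/% 10L) == 0L) {
        message("production: ", steps_done, "/", n_prod, " steps")
      }
    }
  }
  structure(list(frames = frames, state = state,
                 ledger = reactions$ledger, events = reactions$events),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat("<cg_trajectory> ", length(x$frames), " frames, final t = ",
      signif(x$state$time, 6), " tau\n", sep = "")
  invisible(x)
}

# Derive n reproducible child seeds below 2^31 from one integer seed.
derive_seeds <- function(seed, n) {
  with_local_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}
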