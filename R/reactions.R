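#' Reaction parameters for stochastic depolymerization
#'
#' Two reaction channels drive head-to-tail depolymerization of the
#' hydrophobic blocks: (a) end-cap scission, in which the bond between the
#' end-cap and its B-type neighbour breaks with probability `rp_t` per sweep
#' whenever at least one active trigger bead lies within `r_cutoff` of the
#' end-cap; and (b) spontaneous propagation, in which the exposed terminal
#' hydrophobic bond of an uncapped branch breaks with probability `rp_b` per
#' sweep, no stimulus required. At most one bond per branch can break per
#' sweep (strict head-to-tail order).
#'
#' @param rp_t Per-sweep scission probability of a trigger-activated end-cap
#'   bond (study values: 1e-2, 1e-3, 1e-4).
#' @param rp_b Per-sweep scission probability of an exposed hydrophobic bond
#'   (study values: 1e-3, 1e-4).
#' @param r_cutoff Trigger proximity radius in sigma (default 1).
#' @param attempt_every Integration steps between reaction sweeps. The
#'   absolute reaction rate scales with this cadence; comparisons between
#'   architectures assume an identical cadence.
#' @param consume_trigger If `TRUE` (default) the nearest participating
#'   trigger becomes inert (type X) when an end-cap bond breaks, so each
#'   trigger acts once and stoichiometric counts are meaningful.
#' @param detached_bead_fate `"keep_type"` (default: detached end-cap/B
#'   monomers stay hydrophobic) or `"inert"` (retyped to X).
#' @return A `reaction_params` object.
#' @export
reaction_params <- function(rp_t = 1e-4, rp_b = 1e-3, r_cutoff = 1,
                            attempt_every = 100, consume_trigger = TRUE,
                            detached_bead_fate = c("keep_type", "inert")) {
  detached_bead_fate <- match.arg(detached_bead_fate)
  stopifnot(rp_t >= 0, rp_t <= 1, rp_b >= 0, rp_b <= 1, r_cutoff > 0,
            attempt_every >= 1)
  structure(list(rp_t = rp_t, rp_b = rp_b, r_cutoff = r_cutoff,
                 attempt_every = as.integer(attempt_every),
                 consume_trigger = consume_trigger,
                 detached_bead_fate = detached_bead_fate),
            class = "reaction_params")
}

copolymer_species <- function() c("A30B30", "A30(B15)2", "A30(B10)3")

is_copolymer <- function(species) {
  species %in% copolymer_species() | grepl("^A30", species)
}

# Per-branch scission order: for every hydrophobic branch, the ordered list
# of global bead indices from the end-cap inward, ending with the junction A
# bead. Bond k of the branch joins beads k and k+1 of this list; breaking
# bond k detaches bead k. The branch is fully depolymerized after
# `length(beads) - 1` breaks.
build_branch_registry <- function(state) {
  branches <- list()
  for (m in seq_along(state$mol_species)) {
    sp <- state$mol_species[m]
    if (!is_copolymer(sp)) next
    tmpl <- build_template(sp)
    off <- state$mol_offset[m]
    for (b in tmpl$branches) {
      beads <- c(b, 30L) + off  # EC ... first-B, junction A bead
      branches[[length(branches) + 1L]] <- list(
        mol = m, beads = beads, n_scissile = length(beads) - 1L, broken = 0L)
    }
  }
  branches
}

#' Attach a depolymerization reaction system
#'
#' Builds the branch registry (the per-branch head-to-tail scission order)
#' and the depolymerization ledger for a system, ready to be passed to
#' [run_protocol()] or driven manually with [reaction_sweep()].
#'
#' @param state A `cg_system` containing copolymer chains (and usually
#'   trigger beads inserted by [insert_triggers()]).
#' @param params A `reaction_params` object.
#' @param seed Integer seed for the reaction Bernoulli draws.
#' @return A `reaction_system`: list with `params`, `branches`, `ledger`,
#'   `rng_seed`, `sweep_no`, and an event accumulator.
#' @export
attach_reactions <- function(state, params, seed) {
  if (missing(seed)) stop("seed is required")
  branches <- build_branch_registry(state)
  n_ec <- sum(state$types == BEAD_TYPES[["EC"]])
  n_scissile <- sum(vapply(branches, `[[`, 0L, "n_scissile"))
  ledger <- list(
    n_ec_0 = n_ec, n_ec_broken = 0L,
    n_b_0 = n_scissile, n_b_broken = 0L,
    series = data.frame(sweep = 0L, time = 0, frac_ec = 0, frac_b = 0)
  )
  class(ledger) <- "depoly_ledger"
  structure(list(params = params, branches = branches, ledger = ledger,
                 rng_seed = as.integer(seed), sweep_no = 0L,
                 event_list = list(), events = NULL),
            class = "reaction_system")
}

remove_bond <- function(state, i, j) {
  hit <- which((state$bonds[, 1] == i & state$bonds[, 2] == j) |
                 (state$bonds[, 1] == j & state$bonds[, 2] == i))
  if (!length(hit)) stop("bond ", i, "-", j, " not found")
  state$bonds <- state$bonds[-hit[1], , drop = FALSE]
  state
}

#' Attempt trigger-activated end-cap scissions
#'
#' One sweep of reaction channel (a): every intact end-cap bond whose
#' end-cap bead has at least one active trigger within `r_cutoff` (minimum
#' image) breaks with probability `rp_t` (one Bernoulli draw per bond, not
#' per trigger). On success the end-cap detaches as a free monomer and, if
#' `consume_trigger` is set, the nearest participating trigger becomes inert.
#'
#' @param state A `cg_system`.
#' @param reactions A `reaction_system`.
#' @return List with updated `state`, `reactions`, and `events` (data frame
#'   of scissions this call; zero rows when nothing was eligible).
#' @export
attempt_endcap_scission <- function(state, reactions) {
  params <- reactions$params
  t_idx <- which(state$types == BEAD_TYPES[["T"]])
  events <- empty_events()
  capped <- which(vapply(reactions$branches, function(b) b$broken == 0L, TRUE))
  if (!length(capped) || !length(t_idx)) {
    return(list(state = state, reactions = reactions, events = events))
  }
  L <- state$L
  tpos <- state$pos[t_idx, , drop = FALSE]
  for (bi in capped) {
    br <- reactions$branches[[bi]]
    ec <- br$beads[1]
    dx <- abs(tpos[, 1] - state$pos[ec, 1]); dx <- pmin(dx, L - dx)
    dy <- abs(tpos[, 2] - state$pos[ec, 2]); dy <- pmin(dy, L - dy)
    dz <- abs(tpos[, 3] - state$pos[ec, 3]); dz <- pmin(dz, L - dz)
    d2 <- dx * dx + dy * dy + dz * dz
    in_range <- d2 <= params$r_cutoff^2
    if (!any(in_range)) next
    if (stats::runif(1) >= params$rp_t) next
    # break the end-cap bond
    nb <- br$beads[2]
    state <- remove_bond(state, ec, nb)
    reactions$branches[[bi]]$broken <- 1L
    reactions$ledger$n_ec_broken <- reactions$ledger$n_ec_broken + 1L
    reactions$ledger$n_b_broken <- reactions$ledger$n_b_broken + 1L
    if (params$detached_bead_fate == "inert") {
      state$types[ec] <- BEAD_TYPES[["X"]]
    }
    if (params$consume_trigger) {
      cand <- which(in_range)
      nearest <- cand[which.min(d2[cand])]
      consumed <- t_idx[nearest]
      state$types[consumed] <- BEAD_TYPES[["X"]]
      keep <- state$types[t_idx] == BEAD_TYPES[["T"]]
      t_idx <- t_idx[keep]
      tpos <- tpos[keep, , drop = FALSE]
    }
    events <- rbind(events, data.frame(
      sweep = reactions$sweep_no, time = state$time, reaction = "endcap",
      bead_i = ec, bead_j = nb, mol = br$mol))
    if (!length(t_idx) && params$consume_trigger) break
  }
  list(state = state, reactions = reactions, events = events)
}

#' Attempt spontaneous head-to-tail propagation
#'
#' One sweep of reaction channel (b): for every branch whose end-cap has
#' already detached and which still has scissile bonds, the single exposed
#' terminal hydrophobic bond breaks with probability `rp_b`. Branches with an
#' intact end-cap have no eligible bond (cascade gating).
#'
#' @inheritParams attempt_endcap_scission
#' @return Same shape as [attempt_endcap_scission()].
#' @export
attempt_propagation <- function(state, reactions) {
  params <- reactions$params
  events <- empty_events()
  for (bi in seq_along(reactions$branches)) {
    br <- reactions$branches[[bi]]
    if (br$broken == 0L || br$broken >= br$n_scissile) next
    if (stats::runif(1) >= params$rp_b) next
    k <- br$broken + 1L
    i <- br$beads[k]; j <- br$beads[k + 1L]
    state <- remove_bond(state, i, j)
    reactions$branches[[bi]]$broken <- k
    reactions$ledger$n_b_broken <- reactions$ledger$n_b_broken + 1L
    if (params$detached_bead_fate == "inert") {
      state$types[i] <- BEAD_TYPES[["X"]]
    }
    events <- rbind(events, data.frame(
      sweep = reactions$sweep_no, time = state$time, reaction = "propagation",
      bead_i = i, bead_j = j, mol = br$mol))
  }
  list(state = state, reactions = reactions, events = events)
}

empty_events <- function() {
  data.frame(sweep = integer(0), time = numeric(0), reaction = character(0),
             bead_i = integer(0), bead_j = integer(0), mol = integer(0))
}

#' Run one full reaction sweep
#'
#' Executes the end-cap channel then the propagation channel under a
#' reproducible per-sweep RNG substream, and appends the sweep to the ledger
#' time series.
#'
#' @inheritParams attempt_endcap_scission
#' @return List with updated `state` and `reactions`.
#' @export
reaction_sweep <- function(state, reactions) {
  reactions$sweep_no <- reactions$sweep_no + 1L
  sweep_seed <- (reactions$rng_seed + 2654435.0 * reactions$sweep_no) %%
    (.Machine$integer.max - 1)
  res <- with_local_seed(as.integer(sweep_seed), {
    r1 <- attempt_endcap_scission(state, reactions)
    r2 <- attempt_propagation(r1$state, r1$reactions)
    list(state = r2$state, reactions = r2$reactions,
         events = rbind(r1$events, r2$events))
  })
  reactions <- res$reactions
  if (nrow(res$events)) {
    reactions$event_list[[length(reactions$event_list) + 1L]] <- res$events
  }
  led <- reactions$ledger
  fr <- ledger_fractions(led)
  led$series <- rbind(led$series, data.frame(
    sweep = reactions$sweep_no, time = res$state$time,
    frac_ec = fr[["frac_ec_broken"]], frac_b = fr[["frac_B_broken"]]))
  reactions$ledger <- led
  reactions$events <- do.call(rbind, reactions$event_list)
  list(state = res$state, reactions = reactions)
}

#' Depolymerization fractions
#'
#' Fraction of end-cap beads removed, `1 - [ec]_t / [ec]_0`, and fraction of
#' hydrophobic beads detached from their chains, `1 - [B]_t / [B]_0` (each
#' scissile bond detaches exactly one hydrophobic bead, so the bond and bead
#' fractions coincide).
#'
#' @param ledger A `depoly_ledger` (from a `reaction_system`).
#' @return Named numeric vector `c(frac_ec_broken, frac_B_broken)`.
#' @export
ledger_fractions <- function(ledger) {
  if (ledger$n_ec_0 == 0) stop("system has no end-caps")
  c(frac_ec_broken = ledger$n_ec_broken / ledger$n_ec_0,
    frac_B_broken = ledger$n_b_broken / ledger$n_b_0)
}

#' @export
print.reaction_system <- function(x, ...) {
  fr <- ledger_fractions(x$ledger)
  cat("<reaction_system> sweeps = ", x$sweep_no,
      ", frac end-caps broken = ", signif(fr[1], 4),
      ", frac hydrophobic broken = ", signif(fr[2], 4), "\n", sep = "")
  invisible(x)
}
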