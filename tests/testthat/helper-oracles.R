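# Independent oracles, deliberately written without reference to the
# package's own C++ paths: brute-force all-pairs forces, union-find
# clustering, and small state constructors.

# Assemble a cg_system by hand.
make_state <- function(pos, types, bonds = matrix(integer(0), ncol = 2),
                       mol = rep(1L, nrow(pos)), L,
                       species = NULL, vel = NULL) {
  pos <- as.matrix(pos)
  n <- nrow(pos)
  if (is.character(types)) types <- unname(BEAD_TYPES[types])
  mols <- sort(unique(mol))
  if (is.null(species)) species <- rep("fragment", length(mols))
  storage.mode(bonds) <- "integer"
  structure(list(
    pos = pos %% L, img = matrix(0L, n, 3),
    vel = if (is.null(vel)) matrix(0, n, 3) else vel,
    types = as.integer(types), bonds = bonds, mol = as.integer(mol),
    mol_species = species,
    mol_offset = vapply(mols, function(m) min(which(mol == m)) - 1L, 0L),
    L = L, phi = n / L^3, time = 0
  ), class = "cg_system")
}

# A straight copolymer chain along +y with its first A bead at `origin`;
# returns the template-ordered positions (A block then branches).
straight_chain_pos <- function(tmpl, origin, spacing = 0.97) {
  pos <- matrix(0, tmpl$n_beads, 3)
  pos[1, ] <- origin
  for (k in seq_len(nrow(tmpl$bonds))) {
    i <- tmpl$bonds[k, 1]; j <- tmpl$bonds[k, 2]
    pos[j, ] <- pos[i, ] + c(0, spacing, 0)
  }
  pos
}

min_image_vec <- function(d, L) d - L * round(d / L)

# O(n^2) all-pairs force evaluation (LJ truncated/shifted + FENE), written
# directly from the potential definitions.
bf_forces <- function(state, table, bonded_lj = TRUE) {
  n <- nrow(state$pos)
  f <- matrix(0, n, 3)
  L <- state$L
  bkey <- character(0)
  if (nrow(state$bonds)) {
    bkey <- paste(pmin(state$bonds[, 1], state$bonds[, 2]),
                  pmax(state$bonds[, 1], state$bonds[, 2]))
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- min_image_vec(state$pos[i, ] - state$pos[j, ], L)
      r2 <- sum(d * d)
      rc <- table$rcut[state$types[i], state$types[j]]
      is_bonded <- paste(min(i, j), max(i, j)) %in% bkey
      if (r2 <= rc^2 && (bonded_lj || !is_bonded)) {
        e <- table$eps[state$types[i], state$types[j]]
        s2 <- 1 / r2; s6 <- s2^3
        fr <- 24 * e * (2 * s6^2 - s6) * s2
        f[i, ] <- f[i, ] + fr * d
        f[j, ] <- f[j, ] - fr * d
      }
      if (is_bonded) {
        R0 <- table$fene_R0
        fr <- -table$fene_k / (1 - r2 / R0^2)
        f[i, ] <- f[i, ] + fr * d
        f[j, ] <- f[j, ] - fr * d
      }
    }
  }
  f
}

# Brute-force Stillinger partition of copolymer chains via union-find over
# all inter-chain hydrophobic bead pairs.
bf_chain_clusters <- function(state, cutoff = 1.5) {
  hyd <- which(state$types %in% BEAD_TYPES[c("B", "EC")])
  chains <- sort(unique(state$mol[hyd]))
  parent <- stats::setNames(chains, chains)
  find <- function(x) {
    while (parent[[as.character(x)]] != x) x <- parent[[as.character(x)]]
    x
  }
  L <- state$L
  for (a in seq_along(hyd)) {
    for (b in seq_len(a - 1)) {
      i <- hyd[a]; j <- hyd[b]
      if (state$mol[i] == state$mol[j]) next
      d <- min_image_vec(state$pos[i, ] - state$pos[j, ], L)
      if (sum(d * d) <= cutoff^2) {
        ri <- find(state$mol[i]); rj <- find(state$mol[j])
        if (ri != rj) parent[[as.character(ri)]] <- rj
      }
    }
  }
  roots <- vapply(chains, find, 0)
  # cluster labels; singletons = free chains
  sizes <- table(roots)
  lab <- rep(NA_integer_, length(chains))
  names(lab) <- chains
  nxt <- 0L
  for (r in names(sizes)[sizes >= 2]) {
    nxt <- nxt + 1L
    lab[roots == as.numeric(r)] <- nxt
  }
  lab
}

# Canonical form of a partition (micelle memberships as sorted signature).
partition_signature <- function(labels) {
  groups <- split(names(labels)[!is.na(labels)], labels[!is.na(labels)])
  groups <- lapply(groups, function(g) sort(as.integer(g)))
  sig <- sort(vapply(groups, paste, "", collapse = ","))
  paste(sig, collapse = "|")
}

# A static scene with `n` straight A30B30 chains, spaced far apart, and one
# trigger placed at `trigger_dist` from each chain's end-cap (no dynamics:
# reaction sweeps only).
chain_row_state <- function(n = 1, trigger_dist = 0.5, L = 6 * n + 70) {
  tmpl <- build_template("A30B30")
  pos <- NULL; types <- NULL; mol <- NULL; bonds <- NULL
  for (k in seq_len(n)) {
    p <- straight_chain_pos(tmpl, origin = c(3 + (k - 1) * 6, 1, 1))
    bonds <- rbind(bonds, tmpl$bonds + (k - 1L) * 60L)
    pos <- rbind(pos, p)
    types <- c(types, tmpl$types)
    mol <- c(mol, rep(k, 60))
  }
  # one trigger per chain near its end-cap (template bead 60)
  for (k in seq_len(n)) {
    ecpos <- pos[(k - 1) * 60 + 60, ]
    pos <- rbind(pos, ecpos + c(trigger_dist, 0, 0))
    types <- c(types, BEAD_TYPES[["T"]])
    mol <- c(mol, n + k)
  }
  make_state(pos, types, bonds = bonds, mol = mol, L = L,
             species = c(rep("A30B30", n), rep("T", n)))
}

# Synthetic full-scale loading-capacity fixture: `n_chains` micellized
# copolymer chains, `n_cargo` cargo trimers, a `frac_enc` share of them
# encapsulated.
lc_fixture <- function(n_chains, n_cargo, frac_enc) {
  mol <- c(rep(seq_len(n_chains), each = 60),
           rep(n_chains + seq_len(n_cargo), each = 3))
  state <- list(mol = mol,
                mol_species = c(rep("A30B30", n_chains),
                                rep("C3", n_cargo)))
  n_enc <- round(frac_enc * n_cargo)
  cargo_in <- stats::setNames(c(rep(TRUE, n_enc),
                                rep(FALSE, n_cargo - n_enc)),
                              n_chains + seq_len(n_cargo))
  a <- structure(list(
    chain_labels = stats::setNames(rep(1L, n_chains), seq_len(n_chains)),
    micelles = list(list(chains = seq_len(n_chains),
                         cargo = n_chains + seq_len(n_enc))),
    cargo_in = cargo_in),
    class = "micelle_assignment")
  list(state = state, assignment = a)
}
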