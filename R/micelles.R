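HYDROPHOBIC_TYPES <- c("B", "EC", "C")

# Per-bead attachment: a copolymer bead counts as part of its chain only if
# its bond-graph component contains an A bead (the hydrophilic block never
# depolymerizes, so the surviving chain is the component holding the A
# block). Detached monomers fail this test.
attached_to_chain <- function(state) {
  n <- nrow(state$pos)
  attached <- logical(n)
  if (nrow(state$bonds)) {
    g <- igraph::graph_from_edgelist(state$bonds, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
    a_comps <- unique(comp[state$types == BEAD_TYPES[["A"]]])
    attached <- comp %in% a_comps
  }
  attached
}

#' Identify micelles with the Stillinger contact criterion
#'
#' Two copolymer chains reside in the same micelle if any two nonbonded
#' hydrophobic beads (B or end-cap), one from each chain, are within
#' `cutoff` under the minimum-image convention. Micelles are the connected
#' components of this chain-contact graph (equivalent to density clustering
#' of bead contacts with a neighbourhood radius of `cutoff` and a minimum of
#' two points, projected to chains). Chains with no inter-chain hydrophobic
#' contact are free; chains whose hydrophobic beads have all detached can no
#' longer participate in micelles and are always free. Cargo molecules are
#' assigned to a micelle when any of their beads is within `cutoff` of any
#' hydrophobic bead of one of its member chains.
#'
#' @param state A `cg_system` snapshot (wrapped coordinates).
#' @param cutoff Contact distance in sigma (default 1.5).
#' @return A `micelle_assignment`: list with `chain_labels` (integer cluster
#'   id per copolymer molecule id, `NA` for free chains), `micelles` (list
#'   with `chains` and `cargo` molecule-id vectors per cluster), `cargo_in`
#'   (named logical per cargo molecule id), and bookkeeping used by
#'   [consolidate_pbc()].
#' @export
stillinger_clusters <- function(state, cutoff = 1.5) {
  n <- nrow(state$pos)
  if (n == 0) stop("empty snapshot")
  attached <- attached_to_chain(state)
  copoly <- is_copolymer(state$mol_species)
  chain_ids <- which(copoly)
  tagset <- BEAD_TYPES[c("B", "EC")]
  hb <- which(state$types %in% tagset & attached & copoly[state$mol])
  # eligible chains still own at least one bonded hydrophobic bead
  eligible <- intersect(chain_ids, unique(state$mol[hb]))
  labels <- rep(NA_integer_, length(state$mol_species))

  micelles <- list()
  if (length(hb) >= 2) {
    prs <- .pairs_within_cpp(state$pos[hb, , drop = FALSE], state$L, cutoff)
    if (nrow(prs)) {
      mi <- state$mol[hb[prs[, 1]]]
      mj <- state$mol[hb[prs[, 2]]]
      inter <- mi != mj
      if (any(inter)) {
        edges <- unique(cbind(pmin(mi[inter], mj[inter]),
                              pmax(mi[inter], mj[inter])))
        verts <- as.character(eligible)
        g <- igraph::graph_from_data_frame(
          data.frame(from = as.character(edges[, 1]),
                     to = as.character(edges[, 2])),
          directed = FALSE, vertices = verts)
        comp <- igraph::components(g)
        memb <- comp$membership
        sizes <- table(memb)
        cluster_ids <- as.integer(names(sizes)[sizes >= 2])
        lab <- 0L
        for (cid in cluster_ids) {
          lab <- lab + 1L
          members <- as.integer(names(memb)[memb == cid])
          labels[members] <- lab
          micelles[[lab]] <- list(chains = sort(members), cargo = integer(0))
        }
      }
    }
  }

  # cargo encapsulation: any cargo bead within cutoff of any hydrophobic bead
  # of a micellized chain
  cargo_mols <- sort(unique(state$mol[state$types == BEAD_TYPES[["C"]]]))
  cargo_in <- stats::setNames(rep(FALSE, length(cargo_mols)),
                              as.character(cargo_mols))
  if (length(cargo_mols) && length(micelles)) {
    mic_hb <- hb[!is.na(labels[state$mol[hb]])]
    cbeads <- which(state$mol %in% cargo_mols)
    sub <- c(mic_hb, cbeads)
    prs <- .pairs_within_cpp(state$pos[sub, , drop = FALSE], state$L, cutoff)
    if (nrow(prs)) {
      gi <- sub[prs[, 1]]
      gj <- sub[prs[, 2]]
      is_hb_i <- gi %in% mic_hb
      is_hb_j <- gj %in% mic_hb
      cross <- xor(is_hb_i, is_hb_j)
      if (any(cross)) {
        hbead <- ifelse(is_hb_i[cross], gi[cross], gj[cross])
        cbead <- ifelse(is_hb_i[cross], gj[cross], gi[cross])
        cmol <- state$mol[cbead]
        clab <- labels[state$mol[hbead]]
        for (k in seq_along(cmol)) {
          cm <- as.character(cmol[k])
          if (!cargo_in[[cm]]) {
            cargo_in[[cm]] <- TRUE
            micelles[[clab[k]]]$cargo <-
              union(micelles[[clab[k]]]$cargo, cmol[k])
          }
        }
      }
    }
  }

  structure(list(chain_labels = stats::setNames(labels[chain_ids],
                                                as.character(chain_ids)),
                 micelles = micelles, cargo_in = cargo_in,
                 eligible_chains = eligible, cutoff = cutoff),
            class = "micelle_assignment")
}

#' @export
print.micelle_assignment <- function(x, ...) {
  sizes <- vapply(x$micelles, function(m) length(m$chains), 0L)
  cat("<micelle_assignment> ", length(x$micelles), " micelle(s)",
      if (length(sizes)) paste0(" (N = ", paste(sizes, collapse = ", "), ")"),
      ", ", sum(is.na(x$chain_labels)), " free chain(s)\n", sep = "")
  invisible(x)
}

#' Consolidate a micelle across periodic boundaries
#'
#' Rebuilds continuous (unwrapped) coordinates for one micelle by walking its
#' intra-micelle proximity graph (bead contacts within the clustering cutoff
#' plus bonds) and translating each bead by the lattice vector that realizes
#' the minimum-image displacement from an already-placed neighbour. Up to a
#' rigid translation the result does not depend on the anchor bead.
#'
#' @param assignment A `micelle_assignment`.
#' @param state The `cg_system` the assignment was computed from.
#' @param cluster_id Which micelle to unwrap.
#' @param include_cargo Include member cargo beads (default `TRUE`).
#' @return List with `coords` (unwrapped positions), `beads` (global bead
#'   indices), `types`, `mol`.
#' @export
consolidate_pbc <- function(assignment, state, cluster_id,
                            include_cargo = TRUE) {
  mic <- assignment$micelles[[cluster_id]]
  mols <- mic$chains
  if (include_cargo) mols <- c(mols, mic$cargo)
  beads <- which(state$mol %in% mols & attached_to_chain_or_cargo(state))
  coords <- unwrap_bead_set(state, beads, assignment$cutoff)
  ext <- apply(coords, 2, function(v) diff(range(v)))
  if (any(ext > state$L / 2 + assignment$cutoff)) {
    warning("micelle spans more than half the box; unwrap may be ambiguous")
  }
  list(coords = coords, beads = beads, types = state$types[beads],
       mol = state$mol[beads])
}

# cargo beads are always "attached" (cargo does not depolymerize)
attached_to_chain_or_cargo <- function(state) {
  att <- attached_to_chain(state)
  att | state$types == BEAD_TYPES[["C"]]
}

unwrap_bead_set <- function(state, beads, cutoff) {
  n <- length(beads)
  pos <- state$pos[beads, , drop = FALSE]
  L <- state$L
  if (n == 1) return(pos)
  prs <- .pairs_within_cpp(pos, L, cutoff)
  edges <- if (nrow(prs)) prs[, 1:2, drop = FALSE] else
    matrix(integer(0), ncol = 2)
  bmap <- match(state$bonds, beads)
  dim(bmap) <- dim(state$bonds)
  bb <- bmap[stats::complete.cases(bmap), , drop = FALSE]
  edges <- rbind(edges, bb)
  adj <- vector("list", n)
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      i <- edges[k, 1]; j <- edges[k, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  out <- matrix(NA_real_, n, 3)
  placed <- logical(n)
  for (root in seq_len(n)) {
    if (placed[root]) next
    out[root, ] <- pos[root, ]
    placed[root] <- TRUE
    queue <- root
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      for (nb in adj[[cur]]) {
        if (placed[nb]) next
        d <- pos[nb, ] - (out[cur, ] %% L)
        d <- d - L * round(d / L)
        out[nb, ] <- out[cur, ] + d
        placed[nb] <- TRUE
        queue <- c(queue, nb)
      }
    }
  }
  out
}

#' Micelle mass distribution and preferential aggregation number
#'
#' `P(N)` is the fraction of micellized chains residing in micelles of
#' aggregation number `N` (free chains are excluded from the normalization);
#' `N_p` is the mode, with ties broken toward the smaller `N`. Accepts one or
#' several snapshots' assignments.
#'
#' @param assignments A `micelle_assignment` or a list of them.
#' @return List with `distribution` (data frame `N`, `P`), and `n_p`
#'   (`NA` when no micelle exists).
#' @export
mass_distribution <- function(assignments) {
  if (inherits(assignments, "micelle_assignment")) {
    assignments <- list(assignments)
  }
  sizes <- unlist(lapply(assignments, function(a)
    vapply(a$micelles, function(m) length(m$chains), 0L)))
  if (!length(sizes)) {
    return(list(distribution = data.frame(N = integer(0), P = numeric(0)),
                n_p = NA_integer_))
  }
  tab <- table(sizes)
  N <- as.integer(names(tab))
  chains_at_N <- N * as.integer(tab)
  P <- chains_at_N / sum(chains_at_N)
  n_p <- N[which.max(P)]  # which.max takes the first (smallest N) on ties
  list(distribution = data.frame(N = N, P = P), n_p = n_p)
}

#' Gyration and shape metrics of a bead set
#'
#' Mean squared gyration radius and relative shape anisotropy from the
#' gyration tensor `S = (1/n) sum (r - rbar)(r - rbar)^T`:
#' `Rg^2 = tr S = l1 + l2 + l3` and
#' `kappa^2 = 1 - 3 (l1 l2 + l2 l3 + l3 l1) / (l1 + l2 + l3)^2`, which is 0
#' for an isotropic (sphere-like) mass distribution and 1 for a rod.
#'
#' @param coords m x 3 matrix of (unwrapped) coordinates, m >= 2.
#' @return List with `rg2`, `kappa2`, `eigenvalues`.
#' @export
gyration_metrics <- function(coords) {
  if (nrow(coords) < 2) stop("need at least 2 beads")
  centered <- sweep(coords, 2, colMeans(coords))
  S <- crossprod(centered) / nrow(coords)
  ev <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  tr <- sum(ev)
  kappa2 <- 1 - 3 * (ev[1] * ev[2] + ev[2] * ev[3] + ev[3] * ev[1]) / tr^2
  list(rg2 = tr, kappa2 = kappa2, eigenvalues = ev)
}

#' Shape metrics of one micelle
#'
#' Unwraps the micelle and evaluates [gyration_metrics()] on a bead
#' selection. The default selection is copolymer beads only, which keeps the
#' molecular weight consistent between micelles of the same aggregation
#' number.
#'
#' @inheritParams consolidate_pbc
#' @param selector `"copolymer"` (default), `"core"` (hydrophobic copolymer
#'   beads), `"corona"` (A beads), or `"all"` (including cargo).
#' @return List with `rg2`, `kappa2`, `eigenvalues`, `n_beads`.
#' @export
micelle_shape <- function(assignment, state, cluster_id,
                          selector = c("copolymer", "core", "corona", "all")) {
  selector <- match.arg(selector)
  un <- consolidate_pbc(assignment, state, cluster_id, include_cargo = TRUE)
  keep <- switch(selector,
    copolymer = un$types != BEAD_TYPES[["C"]],
    core = un$types %in% BEAD_TYPES[c("B", "EC")],
    corona = un$types == BEAD_TYPES[["A"]],
    all = rep(TRUE, length(un$types)))
  # exclude stray trigger/inert beads from shape metrics
  keep <- keep & un$types != BEAD_TYPES[["T"]] & un$types != BEAD_TYPES[["X"]]
  m <- gyration_metrics(un$coords[keep, , drop = FALSE])
  m$n_beads <- sum(keep)
  m
}

#' Cargo encapsulation and loading capacity
#'
#' A cargo molecule is encapsulated when any of its beads is within the
#' clustering cutoff of any hydrophobic bead of a micellized copolymer
#' chain. The loading capacity is the w/w percentage of cargo in the loaded
#' carrier, `LC = 100 * m_cargo / (m_cargo + m_copolymer)` with bead counts
#' as masses (all beads have unit mass). With several snapshots the
#' quantities are averaged with the block-average method (`n_blocks`
#' blocks).
#'
#' @param assignments A `micelle_assignment` or list of them (one per
#'   snapshot).
#' @param state A `cg_system` (used for species bookkeeping; bead counts per
#'   molecule are architecture constants).
#' @param n_blocks Number of blocks for the block average (default 10).
#' @return An `encapsulation_report`: list with `frac_encapsulated`,
#'   `loading_capacity` (percent), `n_p`, standard errors `frac_se`,
#'   `lc_se` when more than one block is available.
#' @export
encapsulation_report <- function(assignments, state, n_blocks = 10) {
  if (inherits(assignments, "micelle_assignment")) {
    assignments <- list(assignments)
  }
  beads_per_mol <- tabulate(state$mol, nbins = length(state$mol_species))
  per_snap <- lapply(assignments, function(a) {
    n_cargo <- length(a$cargo_in)
    if (n_cargo == 0) stop("no cargo molecules present")
    enc <- sum(a$cargo_in)
    enc_ids <- as.integer(names(a$cargo_in)[a$cargo_in])
    mic_ids <- as.integer(names(a$chain_labels)[!is.na(a$chain_labels)])
    cargo_beads <- sum(beads_per_mol[enc_ids])
    copoly_beads <- sum(beads_per_mol[mic_ids])
    c(frac = enc / n_cargo,
      lc = if (cargo_beads + copoly_beads > 0)
        100 * cargo_beads / (cargo_beads + copoly_beads) else NA_real_)
  })
  m <- do.call(rbind, per_snap)
  nb <- max(1L, min(n_blocks, nrow(m)))
  blocks <- split(seq_len(nrow(m)), ceiling(seq_len(nrow(m)) * nb / nrow(m)))
  bmeans <- t(vapply(blocks, function(ix) colMeans(m[ix, , drop = FALSE]),
                     c(frac = 0, lc = 0)))
  md <- mass_distribution(assignments)
  out <- list(
    frac_encapsulated = mean(bmeans[, "frac"]),
    loading_capacity = mean(bmeans[, "lc"], na.rm = TRUE),
    n_p = md$n_p,
    frac_se = if (nrow(bmeans) > 1)
      stats::sd(bmeans[, "frac"]) / sqrt(nrow(bmeans)) else NA_real_,
    lc_se = if (nrow(bmeans) > 1)
      stats::sd(bmeans[, "lc"], na.rm = TRUE) / sqrt(nrow(bmeans)) else NA_real_
  )
  class(out) <- "encapsulation_report"
  out
}

#' @export
print.encapsulation_report <- function(x, ...) {
  cat("<encapsulation_report> encapsulated = ",
      signif(100 * x$frac_encapsulated, 4), "%, LC = ",
      signif(x$loading_capacity, 4), "% (w/w), N_p = ", x$n_p, "\n", sep = "")
  invisible(x)
}
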