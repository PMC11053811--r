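#' Build a molecule template
#'
#' Constructs the per-species bead/bond layout for the species used in the
#' depolymerizable-micelle model: the linear diblock `A30B30`, the miktoarm
#' stars `A30(B15)2` and `A30(B10)3` (30 hydrophilic A beads plus 30
#' hydrophobic beads split over 1, 2 or 3 branches), the three-bead cargo
#' `C3`, and the single-bead trigger `T`. The free end bead of every
#' hydrophobic block or branch carries the `EC` (end-cap) tag; for miktoarm
#' stars all hydrophobic branches attach to the last A bead (the junction).
#'
#' @param species_name One of `"A30B30"`, `"A30(B15)2"`, `"A30(B10)3"`,
#'   `"C3"`, `"T"`.
#' @param n_branches,branch_length Optional override of the hydrophobic
#'   branching for copolymers; `n_branches * branch_length` must equal 30.
#' @return An object of class `molecule_template`: a list with `species_name`,
#'   `types` (integer codes), `tags` (character), `bonds` (m x 2 integer
#'   matrix), `endcap_indices`, and `branches` (list of bead-index vectors,
#'   end-cap first, ending at the junction-adjacent hydrophobic bead).
#' @export
build_template <- function(species_name, n_branches = NULL, branch_length = NULL) {
  known <- c("A30B30", "A30(B15)2", "A30(B10)3", "C3", "T")
  if (!species_name %in% known && is.null(n_branches)) {
    stop("unknown species '", species_name, "'; expected one of ",
         paste(known, collapse = ", "))
  }
  if (species_name == "C3") {
    tmpl <- list(
      species_name = "C3",
      tags = c("C", "C", "C"),
      bonds = rbind(c(1L, 2L), c(2L, 3L)),
      endcap_indices = integer(0),
      branches = list()
    )
  } else if (species_name == "T") {
    tmpl <- list(
      species_name = "T",
      tags = "T",
      bonds = matrix(integer(0), ncol = 2),
      endcap_indices = integer(0),
      branches = list()
    )
  } else {
    if (is.null(n_branches)) {
      n_branches <- switch(species_name,
                           "A30B30" = 1L, "A30(B15)2" = 2L, "A30(B10)3" = 3L)
      branch_length <- 30L %/% n_branches
    }
    n_branches <- as.integer(n_branches)
    branch_length <- as.integer(branch_length)
    if (n_branches * branch_length != 30L) {
      stop("hydrophobic branch layout ", n_branches, " x ", branch_length,
           " does not total 30 beads")
    }
    n_a <- 30L
    tags <- c(rep("A", n_a),
              rep("B", n_branches * branch_length))
    bonds <- cbind(seq_len(n_a - 1L), seq.int(2L, n_a))
    branches <- vector("list", n_branches)
    endcaps <- integer(n_branches)
    nxt <- n_a
    for (b in seq_len(n_branches)) {
      idx <- nxt + seq_len(branch_length)
      # junction bond (A30 - first B of branch) then the intra-branch bonds
      bonds <- rbind(bonds, c(n_a, idx[1L]))
      if (branch_length > 1L) {
        bonds <- rbind(bonds, cbind(idx[-branch_length], idx[-1L]))
      }
      endcaps[b] <- idx[branch_length]
      tags[idx[branch_length]] <- "EC"
      # branch listed from the end-cap inward (the depolymerization order)
      branches[[b]] <- rev(idx)
      nxt <- nxt + branch_length
    }
    tmpl <- list(
      species_name = species_name,
      tags = tags,
      bonds = bonds,
      endcap_indices = endcaps,
      branches = branches
    )
  }
  storage.mode(tmpl$bonds) <- "integer"
  tmpl$types <- unname(BEAD_TYPES[tmpl$tags])
  tmpl$n_beads <- length(tmpl$tags)
  class(tmpl) <- "molecule_template"
  tmpl
}

#' @export
print.molecule_template <- function(x, ...) {
  cat("<molecule_template> ", x$species_name, ": ", x$n_beads, " beads, ",
      nrow(x$bonds), " bonds, ", length(x$endcap_indices), " end-cap(s)\n",
      sep = "")
  invisible(x)
}

#' Build the pairwise interaction table
#'
#' Assigns well depths and cutoffs for every bead-type pair. Attractive pairs
#' (B-B, B-C, C-C, T-T, B-T, T-C) use a cutoff of 2.5 sigma and a well depth
#' set through an effective pair temperature `T*`: with the thermostat fixed
#' at `k_B T = 1.8` epsilon, `eps_ij = 1.8 / T*_ij`, so a lower `T*` means a
#' deeper well (more attractive). Repulsive pairs (anything involving A or X)
#' use eps = 1 and the Weeks-Chandler-Andersen cutoff `2^(1/6)` sigma; the
#' potential is truncated and shifted to zero at its cutoff for every pair.
#' End-cap beads inherit the B row.
#'
#' @param tstar_map Named numeric vector of effective pair temperatures for
#'   the attractive pairs, names like `"BB"`, `"BC"`, `"CC"`, `"TT"`, `"BT"`,
#'   `"TC"` (order of the two letters does not matter). Defaults to the
#'   strong cargo-attraction condition: `T*_BB = 1.8`,
#'   `T*_BC = T*_CC = 1.4`, trigger pairs at 1.8.
#' @param eps_mapping `"inverse"` (default, `eps = 1.8 / T*`) or `"direct"`
#'   (`eps = T* / 1.8`).
#' @param fene_k,fene_R0 FENE bond parameters (25 eps/sigma^2 and 1.5 sigma).
#' @return An `interaction_table`: list with 6 x 6 matrices `eps` and `rcut`
#'   (indexed by [BEAD_TYPES]), `fene_k`, `fene_R0`, `tstar_map`.
#' @export
build_interaction_table <- function(tstar_map = NULL,
                                    eps_mapping = c("inverse", "direct"),
                                    fene_k = 25, fene_R0 = 1.5) {
  eps_mapping <- match.arg(eps_mapping)
  defaults <- c(BB = 1.8, BC = 1.4, CC = 1.4, TT = 1.8, BT = 1.8, CT = 1.8)
  tm <- defaults
  if (!is.null(tstar_map)) {
    names(tstar_map) <- vapply(names(tstar_map), normalize_pair_name, "")
    unknown <- setdiff(names(tstar_map), names(defaults))
    if (length(unknown)) {
      stop("unknown or non-attractive pair(s) in tstar_map: ",
           paste(unknown, collapse = ", "))
    }
    tm[names(tstar_map)] <- tstar_map
  }
  if (any(tm <= 0)) stop("T* must be positive")
  nt <- length(BEAD_TYPES)
  wca <- 2^(1 / 6)
  eps <- matrix(1, nt, nt, dimnames = list(names(BEAD_TYPES), names(BEAD_TYPES)))
  rcut <- matrix(wca, nt, nt, dimnames = dimnames(eps))
  eps_of <- function(tstar) {
    if (eps_mapping == "inverse") 1.8 / tstar else tstar / 1.8
  }
  set_pair <- function(a, b, tstar) {
    eps[a, b] <<- eps_of(tstar); eps[b, a] <<- eps[a, b]
    rcut[a, b] <<- 2.5; rcut[b, a] <<- 2.5
  }
  set_pair("B", "B", tm[["BB"]])
  set_pair("B", "C", tm[["BC"]])
  set_pair("C", "C", tm[["CC"]])
  set_pair("T", "T", tm[["TT"]])
  set_pair("B", "T", tm[["BT"]])
  set_pair("T", "C", tm[["CT"]])
  # end-caps are hydrophobic: copy B's interactions (incl. B-B -> EC-EC)
  eps["EC", ] <- eps["B", ]; eps[, "EC"] <- eps[, "B"]
  rcut["EC", ] <- rcut["B", ]; rcut[, "EC"] <- rcut[, "B"]
  eps["EC", "EC"] <- eps["B", "B"]; rcut["EC", "EC"] <- rcut["B", "B"]
  eps["EC", "B"] <- eps["B", "B"]; eps["B", "EC"] <- eps["B", "B"]
  rcut["EC", "B"] <- rcut["B", "B"]; rcut["B", "EC"] <- rcut["B", "B"]
  # X is inert: purely repulsive to everything
  eps["X", ] <- 1; eps[, "X"] <- 1
  rcut["X", ] <- wca; rcut[, "X"] <- wca
  structure(list(eps = eps, rcut = rcut, fene_k = fene_k, fene_R0 = fene_R0,
                 tstar_map = tm, eps_mapping = eps_mapping),
            class = "interaction_table")
}

normalize_pair_name <- function(nm) {
  parts <- strsplit(gsub("[-_ ]", "", nm), "")[[1]]
  paste(sort(parts), collapse = "")
}

#' @export
print.interaction_table <- function(x, ...) {
  cat("<interaction_table> FENE k =", x$fene_k, ", R0 =", x$fene_R0, "\n")
  cat("attractive pair T*:", paste(names(x$tstar_map), x$tstar_map,
                                   sep = "=", collapse = ", "), "\n")
  invisible(x)
}
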