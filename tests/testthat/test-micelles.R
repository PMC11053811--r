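# two straight A30B30 chains whose hydrophobic blocks face each other at
# lateral separation `gap`
two_chain_state <- function(gap, L = 80) {
  tmpl <- build_template("A30B30")
  p1 <- straight_chain_pos(tmpl, origin = c(10, 5, 10))
  p2 <- straight_chain_pos(tmpl, origin = c(10 + gap, 5, 10))
  make_state(rbind(p1, p2), c(tmpl$types, tmpl$types),
             bonds = rbind(tmpl$bonds, tmpl$bonds + 60L),
             mol = rep(1:2, each = 60), L = L,
             species = c("A30B30", "A30B30"))
}

test_that("the Stillinger contact rule decides micelle membership", {
  a_in <- stillinger_clusters(two_chain_state(1.4))
  expect_length(a_in$micelles, 1)
  expect_equal(a_in$micelles[[1]]$chains, 1:2)
  expect_equal(unname(a_in$chain_labels), c(1L, 1L))
  a_out <- stillinger_clusters(two_chain_state(1.6))
  expect_length(a_out$micelles, 0)
  expect_true(all(is.na(a_out$chain_labels)))
  expect_error(stillinger_clusters(make_state(matrix(nrow = 0, ncol = 3),
                                              integer(0), L = 5)),
               "empty")
})

test_that("clustering matches the brute-force union-find oracle", {
  for (trial in 1:12) {
    st <- assemble_system(c(A30B30 = 8), phi = 0.13, seed = 500 + trial,
                          max_attempts = 1000)
    got <- stillinger_clusters(st)$chain_labels
    want <- bf_chain_clusters(st)
    expect_equal(partition_signature(got), partition_signature(want))
  }
})

test_that("the partition is invariant under rigid translation of the box", {
  st <- assemble_system(c(A30B30 = 8), phi = 0.15, seed = 901)
  sig0 <- partition_signature(stillinger_clusters(st)$chain_labels)
  for (shift in list(c(3.1, 0, 0), c(7.7, 4.4, 9.2))) {
    st2 <- st
    st2$pos <- sweep(st$pos, 2, -shift) %% st$L
    expect_equal(partition_signature(stillinger_clusters(st2)$chain_labels),
                 sig0)
  }
})

test_that("chains without bonded hydrophobic beads are always free", {
  st <- two_chain_state(1.2)
  # detach every hydrophobic bead of chain 2 (drop its B-block bonds)
  keep <- !(st$bonds[, 1] > 60 + 29 | st$bonds[, 2] > 60 + 29)
  st$bonds <- st$bonds[keep, , drop = FALSE]
  a <- stillinger_clusters(st)
  expect_true(is.na(a$chain_labels[["2"]]))
  expect_length(a$micelles, 0)  # chain 1 alone cannot form a micelle
})

test_that("periodic consolidation restores continuous micelle coordinates", {
  # build a two-chain micelle, then translate it onto a box corner
  st <- two_chain_state(1.2, L = 130)
  a <- stillinger_clusters(st)
  un0 <- consolidate_pbc(a, st, 1)
  rg0 <- gyration_metrics(un0$coords[un0$types != BEAD_TYPES[["C"]], ])
  # interior micelle: unchanged coordinates
  expect_equal(un0$coords, st$pos[un0$beads, ], tolerance = 1e-12)
  # shifts chosen so the micelle straddles one or two box faces
  # (chains occupy x in [10, 11.2], y in [5, 63.2], z = 10)
  for (shift in list(c(119.3, 0, 0), c(0, 70, 0), c(119.3, 70, 0))) {
    st2 <- st
    st2$pos <- sweep(st$pos, 2, -shift) %% st$L
    a2 <- stillinger_clusters(st2)
    expect_length(a2$micelles, 1)
    un2 <- consolidate_pbc(a2, st2, 1)
    # wrapped extent was split across faces; unwrapped gap shrinks back
    raw_ext <- max(apply(st2$pos[un2$beads, ], 2, function(v) diff(range(v))))
    un_ext <- max(apply(un2$coords, 2, function(v) diff(range(v))))
    expect_lte(un_ext, raw_ext + 1e-9)
    # gyration identical to the interior reference (translation invariance)
    rg2 <- gyration_metrics(un2$coords)
    expect_equal(rg2$rg2, rg0$rg2, tolerance = 1e-9)
    expect_equal(rg2$kappa2, rg0$kappa2, tolerance = 1e-9)
  }
})

test_that("mass distribution normalizes over micellized chains only", {
  fake <- function(sizes, free = 0) {
    mic <- lapply(seq_along(sizes), function(i)
      list(chains = seq_len(sizes[i]), cargo = integer(0)))
    labels <- c(rep(seq_along(sizes), sizes), rep(NA_integer_, free))
    structure(list(micelles = mic,
                   chain_labels = stats::setNames(labels,
                                                  seq_along(labels)),
                   cargo_in = logical(0)),
              class = "micelle_assignment")
  }
  one <- mass_distribution(fake(5, free = 3))
  expect_equal(one$distribution$P, 1)
  expect_equal(one$distribution$N, 5)
  expect_equal(one$n_p, 5)
  multi <- mass_distribution(fake(c(2, 2, 6)))
  expect_equal(multi$distribution$P[multi$distribution$N == 2], 0.4)
  expect_equal(multi$distribution$P[multi$distribution$N == 6], 0.6)
  expect_equal(multi$n_p, 6)
  expect_equal(sum(multi$distribution$P), 1)
  none <- mass_distribution(fake(integer(0), free = 4))
  expect_equal(nrow(none$distribution), 0)
  expect_true(is.na(none$n_p))
  # ties break toward the smaller aggregation number (15 chains at each N)
  tie <- mass_distribution(fake(c(rep(3, 5), rep(5, 3))))
  expect_equal(tie$n_p, 3)
})

test_that("gyration metrics reproduce closed-form shapes", {
  # rod limit
  rod <- cbind(seq(0, 9), 0, 0)
  m <- gyration_metrics(rod)
  expect_equal(m$kappa2, 1, tolerance = 1e-12)
  # isotropic limit: regular tetrahedron
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  expect_equal(gyration_metrics(tet)$kappa2, 0, tolerance = 1e-12)
  # planar cross: Rg^2 = 1, kappa^2 = 0.25 (tensor diag(1/2, 1/2, 0))
  cross <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
  mc <- gyration_metrics(cross)
  expect_equal(mc$rg2, 1, tolerance = 1e-12)
  expect_equal(mc$kappa2, 0.25, tolerance = 1e-12)
  # invariance under rotation + translation
  theta <- 0.7
  R <- rbind(c(cos(theta), -sin(theta), 0),
             c(sin(theta), cos(theta), 0),
             c(0, 0, 1))
  moved <- sweep(cross %*% t(R), 2, c(5, -2, 3), "+")
  mm <- gyration_metrics(moved)
  expect_equal(mm$rg2, mc$rg2, tolerance = 1e-12)
  expect_equal(mm$kappa2, mc$kappa2, tolerance = 1e-12)
  expect_error(gyration_metrics(matrix(0, 1, 3)), "at least 2")
  # kappa2 stays in [0, 1] for random clouds
  set.seed(4)
  for (k in 1:20) {
    kk <- gyration_metrics(matrix(rnorm(30), 10, 3))$kappa2
    expect_gte(kk, 0)
    expect_lte(kk, 1)
  }
})


test_that("loading capacity reproduces the w/w worked examples", {
  # bound case: every cargo encapsulated, every chain micellized
  fx <- lc_fixture(1000, 2000, 1)
  r <- encapsulation_report(fx$assignment, fx$state)
  expect_equal(r$loading_capacity, 100 * 6000 / 66000, tolerance = 1e-9)
  expect_equal(r$frac_encapsulated, 1)
  # 82% of 2000 C3 -> LC close to 7.6% w/w
  fx <- lc_fixture(1000, 2000, 0.82)
  r <- encapsulation_report(fx$assignment, fx$state)
  expect_equal(r$loading_capacity, 7.6, tolerance = 0.02)
  # 82% of 4000 C3 -> LC close to 14.1% w/w
  fx <- lc_fixture(1000, 4000, 0.82)
  r <- encapsulation_report(fx$assignment, fx$state)
  expect_equal(r$loading_capacity, 14.1, tolerance = 0.01)
})

test_that("cargo within reach of a micelle core counts as encapsulated", {
  st <- two_chain_state(1.2)
  # a cargo trimer touching the core, and one far away in solution
  hb <- which(st$types == BEAD_TYPES[["B"]])[5]
  near <- sweep(matrix(c(0, 0, 0, 0, 0.97, 0, 0, 1.94, 0), 3, 3,
                       byrow = TRUE), 2, st$pos[hb, ] + c(1.2, 0, 0), "+")
  far <- near + 30
  tmplC <- build_template("C3")
  st2 <- make_state(rbind(st$pos, near, far),
                    c(st$types, rep(BEAD_TYPES[["C"]], 6)),
                    bonds = rbind(st$bonds, tmplC$bonds + 120L,
                                  tmplC$bonds + 123L),
                    mol = c(st$mol, rep(3L, 3), rep(4L, 3)), L = st$L,
                    species = c("A30B30", "A30B30", "C3", "C3"))
  a <- stillinger_clusters(st2)
  expect_true(a$cargo_in[["3"]])
  expect_false(a$cargo_in[["4"]])
  expect_equal(a$micelles[[1]]$cargo, 3)
  r <- encapsulation_report(a, st2)
  expect_equal(r$frac_encapsulated, 0.5)
  expect_equal(r$loading_capacity, 100 * 3 / 123, tolerance = 1e-9)
})
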