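test_that("pair and bond potentials match their closed forms", {
  # truncated/shifted LJ: zero at and beyond the cutoff
  expect_equal(lj_pair_energy(2.5, 1, 2.5), 0)
  expect_equal(lj_pair_energy(3.1, 1, 2.5), 0)
  # frozen values from direct evaluation of 4[(1/r)^12 - (1/r)^6 + shift]
  expect_equal(lj_pair_energy(1, 1, 2.5), 0.016316891, tolerance = 1e-6)
  expect_equal(lj_pair_energy(2^(1 / 6), 1, 2.5), -0.98368311,
               tolerance = 1e-6)
  expect_error(lj_pair_energy(0, 1, 2.5), "overlap")
  # FENE: -0.5 k R0^2 log(1 - (r/R0)^2)
  expect_equal(fene_bond_energy(0), 0)
  expect_equal(fene_bond_energy(0.75), -28.125 * log(0.75), tolerance = 1e-12)
  expect_equal(fene_bond_energy(0.75), 8.0911, tolerance = 1e-4)
  expect_error(fene_bond_energy(1.5), "overstretch")
  expect_error(fene_bond_energy(2.0), "overstretch")
})

test_that("forces obey Newton's third law and the potential minimum", {
  tab <- build_interaction_table()
  # two repulsive beads at the WCA minimum: zero force
  st <- make_state(rbind(c(2, 2, 2), c(2 + 2^(1 / 6), 2, 2)),
                   types = c("A", "A"), L = 10)
  f <- compute_forces(st, tab)
  expect_equal(max(abs(f)), 0, tolerance = 1e-10)
  # random dense states: total force is zero
  st2 <- assemble_system(c(A30B30 = 2, C3 = 3), seed = 5)
  f2 <- compute_forces(st2, tab)
  expect_equal(colSums(f2), c(0, 0, 0), tolerance = 1e-9)
})

test_that("cell-list forces equal the brute-force all-pairs reference", {
  tab <- build_interaction_table()
  set.seed(99)
  for (trial in 1:8) {
    n <- sample(20:50, 1)
    L <- 6
    # random beads of random species plus a few bonds between neighbours
    pos <- matrix(runif(3 * n, 0, L), n, 3)
    types <- sample(names(BEAD_TYPES), n, replace = TRUE)
    bonds <- matrix(integer(0), ncol = 2)
    for (k in seq_len(n - 1)) {
      d <- min_image_vec(pos[k, ] - pos[k + 1, ], L)
      if (sum(d^2) < 1.4^2 && runif(1) < 0.5) {
        bonds <- rbind(bonds, c(k, k + 1L))
      }
    }
    st <- make_state(pos, types, bonds = bonds, L = L)
    for (blj in c(TRUE, FALSE)) {
      expect_equal(compute_forces(st, tab, bonded_lj = blj),
                   bf_forces(st, tab, bonded_lj = blj), tolerance = 1e-10)
    }
  }
})

test_that("integration preserves identity, topology and bond bounds", {
  st <- assemble_system(c(A30B30 = 3, C3 = 4), seed = 21)
  tab <- build_interaction_table()
  proto <- simulation_protocol()
  out <- step_langevin(st, proto, pushoff_table(tab), 500, seed = 3,
                       limit_disp = 0.05)
  out <- step_langevin(out, proto, tab, 1500, seed = 4)
  expect_identical(out$types, st$types)
  expect_identical(out$mol, st$mol)
  expect_identical(out$bonds, st$bonds)
  expect_equal(nrow(out$pos), nrow(st$pos))
  d <- min_image_vec(out$pos[out$bonds[, 1], ] - out$pos[out$bonds[, 2], ],
                     out$L)
  expect_true(all(rowSums(d^2) < 1.5^2))
  expect_true(all(out$pos >= 0 & out$pos < out$L))
  expect_equal(out$time, st$time + 2000 * proto$dt)
  # unwrapped positions are continuous: pos + img*L never jumps by ~L
  expect_true(max(abs(unwrapped_positions(out) -
                        unwrapped_positions(st))) < out$L)
  # determinism
  out2 <- step_langevin(st, proto, pushoff_table(tab), 500, seed = 3,
                        limit_disp = 0.05)
  out2 <- step_langevin(out2, proto, tab, 1500, seed = 4)
  expect_identical(out, out2)
})

test_that("the thermostat holds the kinetic temperature near T* = 1.8", {
  st <- assemble_system(c(A30B30 = 3, C3 = 5), seed = 31)  # 195 beads
  tab <- build_interaction_table()
  proto <- simulation_protocol()
  st <- step_langevin(st, proto, pushoff_table(tab), 1000, seed = 1,
                      limit_disp = 0.05)
  st <- step_langevin(st, proto, tab, 4000, seed = 2)
  temps <- numeric(25)
  for (k in seq_along(temps)) {
    st <- step_langevin(st, proto, tab, 200, seed = 100 + k)
    temps[k] <- kinetic_temperature(st)
  }
  expect_equal(mean(temps), 1.8, tolerance = 0.02)
})

test_that("velocity Verlet conserves energy with the thermostat off", {
  # a single chain, pre-relaxed, then NVE
  st <- assemble_system(c(A30B30 = 1), phi = 0.05, seed = 3)
  tab <- build_interaction_table()
  proto <- simulation_protocol()
  st <- step_langevin(st, proto, pushoff_table(tab), 500, seed = 8,
                      limit_disp = 0.05)
  st <- step_langevin(st, proto, tab, 1500, seed = 9)
  nve <- simulation_protocol(gamma = 0)
  E <- numeric(6)
  E[1] <- potential_energy(st, tab) + 0.5 * sum(st$vel^2)
  for (k in 1:5) {
    st <- step_langevin(st, nve, tab, 1000, seed = k)
    E[k + 1] <- potential_energy(st, tab) + 0.5 * sum(st$vel^2)
  }
  # secular drift (linear trend) per 1000 steps, relative to the energy;
  # the bounded symplectic oscillation is not drift
  drift <- abs(stats::coef(stats::lm(E ~ seq_along(E)))[2]) / abs(mean(E))
  expect_lt(drift, 1e-4)
})

test_that("run_protocol stages and snapshot bookkeeping behave", {
  st <- assemble_system(c(A30B30 = 2), seed = 17)
  tab <- build_interaction_table()
  # push-off variant truncates every cutoff to 2^(1/6)
  pt <- pushoff_table(tab)
  expect_true(all(pt$rcut == 2^(1 / 6)))
  proto <- simulation_protocol(n_pushoff = 2e6, n_equil = 30e6, n_prod = 3e5,
                               scale_factor = 1000, snapshot_every = 100)
  expect_equal(proto$n_pushoff, 2000L)
  expect_equal(proto$n_equil, 30000L)
  expect_equal(proto$n_prod, 300L)
  proto2 <- simulation_protocol(n_pushoff = 200, n_equil = 300, n_prod = 400,
                                snapshot_every = 100)
  traj <- run_protocol(st, proto2, tab, seed = 5)
  expect_s3_class(traj, "cg_trajectory")
  expect_length(traj$frames, 400 / 100 + 1)
  expect_equal(traj$frames[[1]]$time, (200 + 300) * proto2$dt)
})
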