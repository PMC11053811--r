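
test_that("end-cap scission requires a trigger inside the cutoff", {
  st_in <- chain_row_state(trigger_dist = 0.9)
  st_out <- chain_row_state(trigger_dist = 1.1)
  prm <- reaction_params(rp_t = 1, rp_b = 0)
  r_in <- attach_reactions(st_in, prm, seed = 1)
  out <- attempt_endcap_scission(st_in, r_in)
  expect_equal(nrow(out$events), 1)
  expect_equal(ledger_fractions(out$reactions$ledger)[["frac_ec_broken"]], 1)
  # beyond 1 sigma: never fires, however many sweeps
  r_out <- attach_reactions(st_out, prm, seed = 1)
  cur <- list(state = st_out, reactions = r_out)
  for (k in 1:20) cur <- reaction_sweep(cur$state, cur$reactions)
  expect_equal(cur$reactions$ledger$n_ec_broken, 0L)
  # rp_t = 0: in range but never fires
  r0 <- attach_reactions(st_in, reaction_params(rp_t = 0, rp_b = 1), seed = 2)
  cur <- list(state = st_in, reactions = r0)
  for (k in 1:20) cur <- reaction_sweep(cur$state, cur$reactions)
  expect_equal(cur$reactions$ledger$n_b_broken, 0L)
})

test_that("propagation is gated by the end-cap and strictly head-to-tail", {
  st <- chain_row_state(trigger_dist = 0.5)
  prm <- reaction_params(rp_t = 1, rp_b = 1)
  rs <- attach_reactions(st, prm, seed = 3)
  # with the cap intact, the propagation channel alone has nothing to do
  p0 <- attempt_propagation(st, rs)
  expect_equal(nrow(p0$events), 0)
  # full sweeps: first removes EC (+1 immediate propagation), then exactly
  # one bond per sweep until the 30 hydrophobic beads are gone
  cur <- list(state = st, reactions = rs)
  n_bonds <- nrow(st$bonds)
  counts <- integer(0)
  repeat {
    cur <- reaction_sweep(cur$state, cur$reactions)
    counts <- c(counts, cur$reactions$ledger$n_b_broken)
    if (cur$reactions$ledger$n_b_broken == 30L) break
    if (length(counts) > 40) break
  }
  # sweep 1: EC scission, then the freshly exposed bond fires in the same
  # sweep (2 breaks); every later sweep breaks exactly one bond
  expect_equal(counts[1], 2L)
  expect_equal(diff(counts), rep(1L, length(counts) - 1))
  expect_length(counts, 29)
  fr <- ledger_fractions(cur$reactions$ledger)
  expect_equal(unname(fr), c(1, 1))
  # bead count conserved; bonds only removed; A block untouched
  expect_equal(nrow(cur$state$pos), nrow(st$pos))
  expect_equal(nrow(cur$state$bonds), n_bonds - 30L)
  a_bonds <- st$bonds[st$bonds[, 1] <= 29, , drop = FALSE]
  for (k in seq_len(nrow(a_bonds))) {
    expect_true(any(cur$state$bonds[, 1] == a_bonds[k, 1] &
                      cur$state$bonds[, 2] == a_bonds[k, 2]))
  }
  # audit: every break detached the then-terminal hydrophobic bead
  ev <- cur$reactions$events
  expect_equal(ev$bead_i, 60:31)  # end-cap first, inward to the junction
})

test_that("scission statistics follow the per-sweep Bernoulli model", {
  # well-mixed surrogate: every end-cap permanently in trigger range,
  # no dynamics; end-cap survival after s sweeps is (1 - rp_t)^s
  st <- chain_row_state(n = 12, trigger_dist = 0.5)
  rp <- 0.07
  sweeps <- 30
  reps <- 30
  broken <- matrix(0L, reps, sweeps)
  for (r in seq_len(reps)) {
    rs <- attach_reactions(st, reaction_params(rp_t = rp, rp_b = 0),
                           seed = 1000 + r)
    cur <- list(state = st, reactions = rs)
    for (s in seq_len(sweeps)) {
      cur <- reaction_sweep(cur$state, cur$reactions)
      broken[r, s] <- cur$reactions$ledger$n_ec_broken
    }
  }
  n_ec <- 12 * reps  # 360 independent end-cap survival chains
  for (s in c(5, 15, 30)) {
    p_broken <- 1 - (1 - rp)^s
    observed <- sum(broken[, s]) / n_ec
    se <- sqrt(p_broken * (1 - p_broken) / n_ec)
    expect_lt(abs(observed - p_broken), 4 * se + 1e-9)
  }
  # one-sweep scission count across replicates is Binomial(12, rp)
  first <- broken[, 1]
  expect_lt(abs(mean(first) - 12 * rp), 4 * sqrt(12 * rp * (1 - rp) / reps))
})

test_that("propagation counts match the sequential binomial oracle", {
  # single uncapped branch: after s propagation sweeps the number of broken
  # bonds beyond the first is Binomial(s, rp_b) truncated at 29
  st <- chain_row_state(trigger_dist = 0.5)
  rp_b <- 0.15
  sweeps <- 40
  reps <- 60
  extra <- integer(reps)
  for (r in seq_len(reps)) {
    rs <- attach_reactions(st, reaction_params(rp_t = 1, rp_b = rp_b),
                           seed = 2000 + r)
    cur <- list(state = st, reactions = rs)
    for (s in seq_len(sweeps)) cur <- reaction_sweep(cur$state, cur$reactions)
    # subtract the end-cap bond and the same-sweep first propagation draw
    extra[r] <- cur$reactions$ledger$n_b_broken - 1L
  }
  expected <- sweeps * rp_b
  se <- sqrt(sweeps * rp_b * (1 - rp_b) / reps)
  expect_lt(abs(mean(extra) - expected), 4 * se)
})

test_that("ledger fractions count end-caps and detached hydrophobic beads", {
  # 10 two-branch chains; break exactly 7 end-cap bonds, no propagation
  tmpl <- build_template("A30(B15)2")
  pos <- NULL; types <- NULL; mol <- NULL; bonds <- NULL
  for (k in 1:10) {
    p <- straight_chain_pos(tmpl, origin = c(3 + (k - 1) * 6, 1, 1))
    bonds <- rbind(bonds, tmpl$bonds + (k - 1L) * 60L)
    pos <- rbind(pos, p); types <- c(types, tmpl$types)
    mol <- c(mol, rep(k, 60))
  }
  # triggers next to the first 7 chains' FIRST end-cap only
  for (k in 1:7) {
    ec <- (k - 1) * 60 + tmpl$endcap_indices[1]
    pos <- rbind(pos, pos[ec, ] + c(0.5, 0, 0))
    types <- c(types, BEAD_TYPES[["T"]]); mol <- c(mol, 10 + k)
  }
  st <- make_state(pos, types, bonds = bonds, mol = mol, L = 80,
                   species = c(rep("A30(B15)2", 10), rep("T", 7)))
  rs <- attach_reactions(st, reaction_params(rp_t = 1, rp_b = 0), seed = 5)
  expect_equal(rs$ledger$n_ec_0, 20L)
  expect_equal(rs$ledger$n_b_0, 300L)  # every hydrophobic bead is scissile
  cur <- reaction_sweep(st, rs)
  fr <- ledger_fractions(cur$reactions$ledger)
  expect_equal(fr[["frac_ec_broken"]], 0.35)
  expect_equal(fr[["frac_B_broken"]], 7 / 300)
  # t = 0 fractions are (0, 0); full depolymerization reaches (1, 1)
  expect_equal(unname(ledger_fractions(rs$ledger)), c(0, 0))
})

test_that("trigger consumption caps scissions at the trigger budget", {
  # 3 chains share a single trigger placed near all three end-caps
  tmpl <- build_template("A30B30")
  pos <- NULL; types <- NULL; mol <- NULL; bonds <- NULL
  base <- c(5, 5, 5)
  for (k in 1:3) {
    p <- straight_chain_pos(tmpl, origin = c(2, 2, 2) + (k - 1) * c(30, 0, 0))
    # fold the end-cap of every chain next to a common point
    p[60, ] <- base + c(0.3 * k, 0, 0)
    p[59, ] <- p[60, ] + c(0, 0.9, 0)   # keep its bond intact length-wise
    bonds <- rbind(bonds, tmpl$bonds + (k - 1L) * 60L)
    pos <- rbind(pos, p); types <- c(types, tmpl$types)
    mol <- c(mol, rep(k, 60))
  }
  pos <- rbind(pos, base)
  types <- c(types, BEAD_TYPES[["T"]]); mol <- c(mol, 4L)
  st <- make_state(pos, types, bonds = bonds, mol = mol, L = 100,
                   species = c(rep("A30B30", 3), "T"))
  rs <- attach_reactions(st, reaction_params(rp_t = 1, rp_b = 0), seed = 6)
  cur <- list(state = st, reactions = rs)
  for (k in 1:10) cur <- reaction_sweep(cur$state, cur$reactions)
  expect_equal(cur$reactions$ledger$n_ec_broken, 1L)  # one trigger, one act
  expect_equal(sum(cur$state$types == BEAD_TYPES[["X"]]), 1L)
  # without consumption the same trigger activates all three
  rs2 <- attach_reactions(st, reaction_params(rp_t = 1, rp_b = 0,
                                              consume_trigger = FALSE),
                          seed = 6)
  cur2 <- list(state = st, reactions = rs2)
  for (k in 1:10) cur2 <- reaction_sweep(cur2$state, cur2$reactions)
  expect_equal(cur2$reactions$ledger$n_ec_broken, 3L)
})
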