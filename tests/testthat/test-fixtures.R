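# The reference models: they parse cleanly, simulate to completion, and
# satisfy their structural invariants.

test_that("every fixture parses, validates and simulates on defaults", {
  fixtures <- list(
    bcs_ex_increment(), bcs_ex_choice(), bcs_ex_combinators(),
    bcs_ex_bimolecular(xA = 1, xB = -1), bcs_ex_reactant(xA = 1, xB = -1),
    bcs_ex_clock(), bcs_ex_channel_list(),
    bcs_fixture_replication(L = 40),
    bcs_fixture_replication(L = 40, variant = "cooperative"),
    bcs_fixture_replication(L = 40, variant = "barrier", barrier_position = 25),
    bcs_fixture_dna_damage(),
    bcs_fixture_tcr(receptors = 2, kinases = 4, phosphatases = 4),
    bcs_fixture_tcr(receptors = 2, kinases = 4, phosphatases = 4, with_dwell = FALSE)
  )
  for (fx in fixtures) {
    expect_identical(nrow(bcs_validate(fx$model)), 0L, label = fx$name)
    log <- bcs_simulate(fx$model, seed = 1, max_transitions = 2000, max_time = 500)
    expect_true(bcs_termination(log) %in% c("deadlocked", "cap", "time"),
                label = fx$name)
  }
})

test_that("fixture defaults encode the reference configuration", {
  fx <- bcs_fixture_replication()
  expect_identical(fx$params$L, 300L)
  expect_true(all(fx$params$origins$q == 1))
  expect_true(all(fx$params$origins$fire == 0.015))
  fx2 <- bcs_fixture_dna_damage()
  expect_identical(fx2$params$k_dmg, 1e-4)
  expect_identical(unname(fx2$model$init$args[[1L]]), c(0, 0, 0))
  fx3 <- bcs_fixture_tcr()
  expect_identical(fx3$params$n_sites, 20L)
})

test_that("a single certain origin replicates every position exactly once", {
  fx <- bcs_fixture_replication(L = 10, origins = data.frame(position = 5, q = 1,
                                                             fire = 0.5))
  for (seed in 1:20) {
    log <- bcs_simulate(fx$model, seed = seed)
    expect_identical(bcs_termination(log), "deadlocked")
    expect_identical(sort(claimed_positions(log)), 1:10)
  }
})

test_that("an unlicensed chromosome never replicates", {
  fx <- bcs_fixture_replication(L = 10, origins = data.frame(position = 5, q = 0,
                                                             fire = 0.5))
  log <- bcs_simulate(fx$model, seed = 1)
  expect_identical(log$action, "nlicensed")
  expect_length(claimed_positions(log), 0L)
})

test_that("rightward forks passing the barrier always stall there first", {
  fx <- bcs_fixture_replication(L = 40, variant = "barrier", barrier_position = 25,
                                origins = data.frame(position = 10, q = 1, fire = 0.5))
  for (seed in 1:10) {
    log <- bcs_simulate(fx$model, seed = seed)
    stalls <- log[log$action == "stall", ]
    expect_identical(nrow(stalls), 1L)
    expect_identical(stalls$params[[1L]], 25)
    # the stall happens after claiming 25 and before claiming 26
    t_claim25 <- log$time[log$action == "chr![25]"]
    t_claim26 <- log$time[log$action == "chr![26]"]
    expect_true(t_claim25 < stalls$time && stalls$time < t_claim26)
  }
})

test_that("cooperative firing lets a beacon from one origin fire another", {
  fx <- bcs_fixture_replication(
    L = 60, variant = "cooperative", coop_rate = 5,
    origins = data.frame(position = c(20, 40), q = c(1, 1), fire = c(1, 1e-7)))
  got_coop <- vapply(1:8, function(seed) {
    log <- bcs_simulate(fx$model, seed = seed)
    sum(grepl("^coop\\?", log$action)) > 0
  }, logical(1))
  expect_true(any(got_coop))
})

test_that("molecules are conserved at every cell division", {
  fx <- bcs_fixture_dna_damage(k_dmg = 0.005)  # some damage so mA > 0 occurs
  for (seed in 1:5) {
    log <- bcs_simulate(fx$model, seed = seed, max_transitions = 1200)
    div <- log[grepl("^divide_done", log$action), ]
    expect_gt(nrow(div), 5L)
    for (p in div$params) {
      # params are (A, mA, d, A1, M1, A2, M2)
      expect_identical(p[[4L]] + p[[6L]], p[[1L]])
      expect_identical(p[[5L]] + p[[7L]], p[[2L]])
    }
  }
})

test_that("receptor phosphorylation count stays within 0..n_sites", {
  fx <- bcs_fixture_tcr(n_sites = 5, receptors = 3, kinases = 5, phosphatases = 5)
  log <- bcs_simulate(fx$model, seed = 4, max_transitions = 3000)
  rec <- log[log$process %in% c("R", "R_PROX", "R_BOUND", "R_CAT"), ]
  p <- vapply(rec$params, `[[`, numeric(1), 1L)
  expect_true(all(p >= 0 & p <= 5))
})

test_that("with kinase only, receptors become fully phosphorylated", {
  fx <- bcs_fixture_tcr(n_sites = 5, receptors = 2, kinases = 6, phosphatases = 0)
  log <- bcs_simulate(fx$model, seed = 2, max_time = 300, max_transitions = 5e4)
  frac <- bcs_phospho_fraction(log, n_sites = 5, receptors = 2)
  expect_gt(frac, 0.95)
})
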