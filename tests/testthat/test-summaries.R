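# Summary statistics and the explicit CTMC oracle, including the
# simulation-vs-CTMC distributional checks.

test_that("the pure two-state clock maps to a symmetric two-state chain", {
  ct <- bcs_ctmc(pure_clock_model(rs = 1))
  expect_length(ct$states, 2L)
  Q <- bcs_ctmc_generator(ct)
  expect_equal(Q, matrix(c(-1, 1, 1, -1), 2, 2))
  expect_equal(unname(bcs_ctmc_stationary(ct)), c(0.5, 0.5))
})

test_that("choice branch probabilities follow ra/(ra+rb) in the chain", {
  ct <- bcs_ctmc(bcs_ex_choice(ra = 1, rb = 3)$model)
  out <- ct$transitions[ct$transitions$from == ct$initial, ]
  p_a <- out$rate[out$action == "a"] / sum(out$rate)
  expect_equal(p_a, 1 / 4)
})

test_that("simulated holding times match the chain's exponential rates", {
  # single handshake pair: one candidate at rate rs*rr = 12, so the time to
  # the (only) event is Exp(12); CTMC absorption time is exactly 1/12
  m <- handshake_pair_model(rs = 3, rr = 4)
  ct <- bcs_ctmc(m)
  tau <- bcs_ctmc_absorption_times(ct)
  expect_equal(unname(tau[ct$initial]), 1 / 12)
  times <- vapply(1:400, function(s) bcs_simulate(m, seed = s)$time[[1L]],
                  numeric(1))
  se <- (1 / 12) / sqrt(400)
  expect_lt(abs(mean(times) - 1 / 12), 3 * se)

  # pure clock: every holding time is Exp(rs)
  log <- bcs_simulate(pure_clock_model(rs = 2), seed = 3, max_transitions = 4000)
  holds <- diff(c(0, log$time))
  expect_lt(abs(mean(holds) - 0.5), 3 * (0.5 / sqrt(length(holds))))
})

test_that("AB dissociation through the beacon clock matches the CTMC", {
  m <- bcs_ex_clock()$model
  ct <- bcs_ctmc(m, state_bound = 100)
  fp <- bcs_ctmc_first_passage(ct, function(s) !grepl("AB\\{", s))
  expected <- unname(fp[ct$initial])
  life <- vapply(1:200, function(s) {
    log <- bcs_simulate(m, seed = s, max_time = 80)
    log$time[grepl("^state\\?", log$action)][[1L]]
  }, numeric(1))
  # lifetimes are near-exponential; SE estimated from the sample
  se <- stats::sd(life) / sqrt(length(life))
  expect_lt(abs(mean(life) - expected), 3 * se)
})

test_that("timing profile of a single centred origin is a symmetric V", {
  L <- 11L
  fx <- bcs_fixture_replication(L = L, origins = data.frame(position = 6, q = 1,
                                                            fire = 2))
  b <- bcs_run_batch(fx$model, replicates = 40, seed = 10)
  prof <- bcs_replication_timing(b, L = L)
  expect_true(all(prof$complete))
  expect_identical(prof$position[which.min(prof$mean_time)], 6L)
  # symmetry about the origin within joint SEM
  for (k in 1:5) {
    d <- abs(prof$mean_time[6 + k] - prof$mean_time[6 - k])
    expect_lt(d, 3 * sqrt(prof$sem[6 + k]^2 + prof$sem[6 - k]^2))
  }
  # expected first-passage: position 6+k replicates k fork steps after the
  # origin, each step Exp(fork_rate); per-replicate differences average k/v
  v <- fx$params$fork_rate
  diffs <- vapply(b, function(log) {
    lt <- claimed_positions(log)
    tt <- log$time[grepl("^chr!\\[", log$action)]
    tt[match(11, lt)] - tt[match(6, lt)]
  }, numeric(1))
  expect_lt(abs(mean(diffs) - 5 / v), 3 * stats::sd(diffs) / sqrt(length(diffs)))
})

test_that("a single replicate yields an SEM flagged as NA", {
  fx <- bcs_fixture_replication(L = 8, origins = data.frame(position = 4, q = 1,
                                                            fire = 1))
  prof <- bcs_replication_timing(bcs_simulate(fx$model, seed = 1), L = 8)
  expect_true(all(is.na(prof$sem)))
  expect_true(all(prof$n_replicates == 1L))
})

test_that("positions unreplicated in some replicate are flagged incomplete", {
  fx <- bcs_fixture_replication(L = 8, origins = data.frame(position = 4, q = 0.5,
                                                            fire = 1))
  b <- bcs_run_batch(fx$model, replicates = 10, seed = 2)
  prof <- bcs_replication_timing(b, L = 8)
  # with q = 0.5 some replicates never replicate: those positions are flagged
  expect_true(any(!prof$complete))
})

test_that("ada trace: a lone non-dividing cell accumulates Ada linearly", {
  fx <- bcs_fixture_dna_damage(k_dmg = 1e-12, k_basal = 0.5, k_division = 1e-9)
  log <- bcs_simulate(fx$model, seed = 6, max_time = 200, max_transitions = 1e4)
  tr <- bcs_ada_trace(log, bin_width = 20)
  expect_true(all(tr$n_cells == 1))
  # Poisson counting: final-bin mean is ~0.5 * t with sd sqrt(0.5 * t)
  final <- tr$ada_per_cell[[nrow(tr)]]
  expect_lt(abs(final - 0.5 * 190), 3 * sqrt(0.5 * 200))
  expect_true(all(diff(tr$ada_per_cell) >= 0))
})

test_that("ada trace is identically zero without production or damage", {
  fx <- bcs_fixture_dna_damage(k_dmg = 1e-12, k_basal = 1e-12, k_division = 0.5)
  log <- bcs_simulate(fx$model, seed = 1, max_transitions = 400)
  tr <- bcs_ada_trace(log, bin_width = 5)
  expect_true(all(tr$ada_per_cell == 0))
  expect_true(all(tr$meada_per_cell == 0))
  expect_gt(max(tr$n_cells), 1)  # the population still grows
})

test_that("ada summaries reject empty logs and oversize burn-in", {
  m <- bcs_parse("S = {@c![1], 1}\nS")
  expect_error(bcs_ada_trace(bcs_simulate(m, seed = 1)), "empty")
  fx <- bcs_fixture_dna_damage()
  tr <- bcs_ada_trace(bcs_simulate(fx$model, seed = 1, max_transitions = 200))
  expect_error(bcs_ada_mean(tr, burn_in = 1e9), "burn_in")
})

test_that("phosphorylated fraction is the time-weighted site average", {
  log <- tibble::tibble(
    time = c(1, 3),
    action = c("phosphorylate", "dephosphorylate"),
    process = c("R_BOUND", "R_BOUND"),
    params = list(c(0, 0), c(1, 1))
  )
  # one of two sites occupied from t=1 to t=3, horizon T=3
  expect_equal(bcs_phospho_fraction(log, n_sites = 2, receptors = 1, burn_in = 0),
               (2 / 3) / 2)
  expect_equal(bcs_phospho_fraction(log, n_sites = 2, receptors = 1, burn_in = 2),
               1 / 2)
  expect_error(bcs_phospho_fraction(log, 2, 1, burn_in = 5), "burn_in")
})

test_that("the response coefficient recovers a known Hill curve", {
  r <- exp(seq(log(0.1), log(10), length.out = 9))
  dr <- tibble::tibble(ratio = r, mean_fraction = r^2 / (r^2 + 1))
  rc <- bcs_response_coefficient(dr)
  expect_equal(rc$hill, 2, tolerance = 1e-6)
  expect_equal(rc$rc, 9, tolerance = 1e-6)
  expect_equal(rc$ec50, 1, tolerance = 1e-6)
})

test_that("autoplot methods return ggplot objects", {
  fx <- bcs_fixture_replication(L = 8, origins = data.frame(position = 4, q = 1,
                                                            fire = 1))
  b <- bcs_run_batch(fx$model, replicates = 3, seed = 1)
  expect_s3_class(autoplot(bcs_replication_timing(b, L = 8)), "ggplot")
  tr <- bcs_ada_trace(bcs_simulate(bcs_fixture_dna_damage()$model, seed = 1,
                                   max_transitions = 300))
  expect_s3_class(autoplot(tr), "ggplot")
  dr <- tibble::tibble(ratio = c(0.5, 1, 2), mean_fraction = c(0.2, 0.5, 0.8),
                       sd = c(0.05, 0.05, 0.05), n = 3L)
  class(dr) <- c("bcs_dose_response", class(dr))
  expect_s3_class(autoplot(dr), "ggplot")
  expect_s3_class(autoplot(b[[1L]]), "ggplot")
})
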