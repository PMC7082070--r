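# The stochastic simulation loop: termination, caps, determinism, the
# replicate seeding scheme, and elementary distributional checks.

test_that("the gated model always stops at i=4, j=16, whatever the seed", {
  m <- gated_model(r = 2)
  for (seed in c(1, 7, 123, 9999)) {
    log <- bcs_simulate(m, seed = seed)
    expect_identical(nrow(log), 4L)
    expect_identical(bcs_termination(log), "deadlocked")
    expect_identical(bcs_final_state(log)$params[[1L]], c(4, 16))
  }
})

test_that("a single action fires once and the system deadlocks", {
  log <- bcs_simulate(bcs_parse("P = {a,1}\nP"), seed = 3)
  expect_identical(nrow(log), 1L)
  expect_identical(log$action, "a")
  expect_identical(bcs_termination(log), "deadlocked")
  expect_identical(nrow(bcs_final_state(log)), 0L)
})

test_that("event times are non-decreasing and start after zero", {
  log <- bcs_simulate(bcs_fixture_dna_damage()$model, seed = 2, max_transitions = 300)
  expect_true(all(diff(log$time) >= 0))
  expect_true(all(log$time > 0))
})

test_that("identical model + seed + replicate gives byte-identical logs", {
  m <- bcs_fixture_replication(L = 15)$model
  l1 <- bcs_simulate(m, seed = 5)
  l2 <- bcs_simulate(m, seed = 5)
  expect_identical(tidy(l1), tidy(l2))
  l3 <- bcs_simulate(m, seed = 6)
  expect_false(identical(tidy(l1), tidy(l3)))
})

test_that("transition and time caps terminate with the right flag", {
  m <- bcs_parse("P = {tick, 1}.P\nP")  # ticks forever
  log <- bcs_simulate(m, seed = 1, max_transitions = 25)
  expect_identical(nrow(log), 25L)
  expect_identical(bcs_termination(log), "cap")
  log2 <- bcs_simulate(m, seed = 1, max_time = 4)
  expect_identical(bcs_termination(log2), "time")
  expect_true(all(log2$time <= 4))
})

test_that("batches use seed + replicate - 1 and one replicate equals simulate", {
  m <- bcs_fixture_replication(L = 10)$model
  b <- bcs_run_batch(m, replicates = 3, seed = 40)
  expect_identical(tidy(b[[1L]]), tidy(bcs_simulate(m, seed = 40)))
  expect_identical(tidy(b[[2L]]), tidy(bcs_simulate(m, seed = 41)))
  expect_identical(vapply(b, function(l) attr(l, "replicate"), integer(1)), 1:3)
  b1 <- bcs_run_batch(m, replicates = 1, seed = 40)
  expect_identical(tidy(b1[[1L]]), tidy(b[[1L]]))
})

test_that("rate evaluation errors abort with action provenance", {
  m <- bcs_parse("P[i] = {shrink, i}.P[i-1]\nP[1]")
  expect_error(bcs_simulate(m, seed = 1), "shrink")
})

test_that("the symmetric two-state clock spends half its time in each state", {
  m <- pure_clock_model(rs = 1)
  t_end <- 4000
  log <- bcs_simulate(m, seed = 8, max_time = t_end)
  frac <- clock_state1_fraction(log, t_end)
  # the autocorrelated occupancy estimate has SE ~ sqrt(2 * tau / T) / 2
  # for relaxation time tau = 1/(2 rs)
  se <- sqrt(2 * 0.5 / t_end) / 2
  expect_lt(abs(frac - 0.5), 3 * se)
})

test_that("validation failures stop simulation up front", {
  m <- bcs_parse("P = {a,1}.Q[2]\nP")
  expect_error(bcs_simulate(m, seed = 1), "validation")
})
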