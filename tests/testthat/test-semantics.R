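# Operational semantics: derivative extraction via candidate enumeration,
# handshake pairing, beacon visibility, deadlock removal, and the
# equivalence of the incremental candidate pool with full re-enumeration.

test_that("choice offers both branches and commits to one", {
  cands <- bcs_initial_candidates("P = {a,1} + {b,2}\nP")
  expect_identical(nrow(cands), 2L)
  expect_setequal(cands$action, c("a", "b"))
  log <- bcs_simulate(bcs_parse("P = {a,1} + {b,2}\nP"), seed = 1)
  expect_identical(nrow(log), 1L)  # sibling branch discarded
})

test_that("parallel components proceed independently", {
  m <- bcs_parse("P = {a,1} || {b,2}\nP")
  cands <- bcs_initial_candidates(m)
  expect_identical(nrow(cands), 2L)
  log <- bcs_simulate(m, seed = 1)
  expect_setequal(log$action, c("a", "b"))  # taking one leaves the other running
})

test_that("handshake rate is exactly the product of send and receive rates", {
  cands <- bcs_initial_candidates(handshake_pair_model(rs = 3, rr = 4))
  expect_identical(nrow(cands), 1L)
  expect_identical(cands$kind, "handshake")
  expect_identical(cands$rate, 12)
  expect_length(cands$instances[[1L]], 2L)
  expect_identical(length(unique(cands$instances[[1L]])), 2L)
})

test_that("channel-list handshake matches computed channels and binds payloads", {
  cands <- bcs_initial_candidates(channel_list_model())
  expect_identical(nrow(cands), 1L)
  expect_identical(cands$action, "@3,4![2,9]")
  log <- bcs_simulate(channel_list_model(), seed = 5)
  recv <- log[grepl("\\?", log$action), ]
  expect_identical(recv$action, "@3,4?[2,9]")
  done <- log[log$process == "QDONE", ]
  expect_identical(done$params[[1L]], c(2, 9))  # a = 2, b = 9
})

test_that("mismatched channel names produce no handshake", {
  # sender channel altered from x+2 to x+1: (2,4) vs receiver (3,4)
  m <- bcs_parse("
P[x,y] = {@x+1,y+3![x+1,y+8], 1}
Q[i,j] = {@i+2,4?[i-1..i+1,j+8](a,b), 1}.QDONE[a,b]
QDONE[a,b] = {received, 1}
P[1,1] || Q[1,1]
")
  expect_identical(nrow(bcs_initial_candidates(m)), 0L)
  # payload length mismatch also prevents pairing
  m2 <- bcs_parse("
P[x,y] = {@x+2,y+3![x,y+1,x], 1}
Q[i,j] = {@i+2,4?[i-1..i+1,j+8](a,b), 1}
P[1,1] || Q[1,1]
")
  expect_identical(nrow(bcs_initial_candidates(m2)), 0L)
})

test_that("a single instance cannot handshake with itself", {
  m <- bcs_parse("P = {@c![1], 1} + {@c?[0..2](x), 1}\nP")
  expect_identical(nrow(bcs_initial_candidates(m)), 0L)
  log <- bcs_simulate(m, seed = 1)
  expect_identical(nrow(log), 0L)
  expect_identical(bcs_termination(log), "deadlocked")
})

test_that("beacon receive rate can depend on the received value", {
  # beacon pre-launched by a fast setup process; receiver rate = r*s
  m <- bcs_parse("
SETUP = {state![2], 1000}
AB = {state?[1..2](s), 0.5*s}
SETUP || AB
")
  log <- bcs_simulate(m, seed = 2)
  expect_identical(sum(grepl("^state\\?\\[2\\]$", log$action)), 1L)
  # the dissociation waiting time distribution is checked against the CTMC
  # oracle in test-summaries.R
})

test_that("beacon checks enable only while no matching beacon is active", {
  m <- bcs_parse("
P = {~c?[0..9], 1}.{done, 1}
Q = {c![5], 50}
P || Q
")
  # once Q launches (fast), P's check is disabled and P deadlocks
  log <- bcs_simulate(m, seed = 3)
  if (log$action[[1L]] == "c![5]") {
    expect_false(any(log$action == "done"))
  } else {
    expect_true(all(c("~c?[0..9]", "done") %in% log$action))
  }
  # with a kill, the check becomes enabled again
  m2 <- bcs_parse("
P = {~c?[0..9], 1}.{done, 1}
Q = {c![5], 1000}.{c#[5], 0.2}
P || Q
")
  log2 <- bcs_simulate(m2, seed = 4)
  expect_true(any(log2$action == "done"))
})

test_that("origin firing splits into two parallel fork instances", {
  fx <- bcs_fixture_replication(L = 9, origins = data.frame(position = 5, q = 1, fire = 5))
  log <- bcs_simulate(fx$model, seed = 1)
  expect_true(any(log$process == "FR"))
  expect_true(any(log$process == "FL"))
  # forks started from the origin position and moved outward
  fr <- log[log$process == "FR", ]
  expect_identical(min(vapply(fr$params, `[[`, numeric(1), 1L)), 5)
})

test_that("deadlocked processes are removed; waiting senders are retained", {
  # gate exhausted -> instance still reported in the final state, no candidates
  log <- bcs_simulate(gated_model(), seed = 9)
  fs <- bcs_final_state(log)
  expect_identical(fs$params[[1L]], c(4, 16))
  expect_identical(fs$n_candidates, 0L)
  # a lone handshake sender must wait: no candidates but instance retained
  m <- bcs_parse("S = {@c![1], 1}\nS")
  log2 <- bcs_simulate(m, seed = 1)
  expect_identical(nrow(log2), 0L)
  expect_identical(bcs_final_state(log2)$process, "S")
})

test_that("incremental candidate pool equals full re-enumeration at every step", {
  models <- list(
    increment = gated_model(),
    bimolecular = bcs_ex_bimolecular(xA = 1, xB = -1)$model,
    clock = bcs_ex_clock()$model,
    replication = bcs_fixture_replication(
      L = 12, origins = data.frame(position = c(4, 9), q = c(1, 0.5),
                                   fire = c(0.5, 0.5)))$model,
    cooperative = bcs_fixture_replication(
      L = 12, variant = "cooperative",
      origins = data.frame(position = c(4, 9), q = c(1, 1),
                           fire = c(0.5, 0.001)))$model,
    damage = bcs_fixture_dna_damage()$model,
    tcr = bcs_fixture_tcr(receptors = 2, kinases = 3, phosphatases = 3)$model
  )
  for (nm in names(models)) {
    expect_no_error(beaconr:::audit_simulate(models[[nm]], seed = 11, max_transitions = 150))
  }
})
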