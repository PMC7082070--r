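# Concrete syntax: combinator precedence, actions, sets, model structure,
# and the pretty-print round trip.

test_that("combinator precedence is prefix > choice > parallel", {
  t <- bcs_parse_term("{a,1} || {b,2}.{c,3} + {d,4}.{e,5}")
  expect_identical(t$type, "parallel")
  expect_length(t$comps, 2L)
  expect_identical(t$comps[[1L]]$type, "prefix")
  second <- t$comps[[2L]]
  expect_identical(second$type, "choice")
  expect_length(second$branches, 2L)
  for (b in second$branches) {
    expect_identical(b$type, "prefix")
    expect_identical(b$cont$type, "prefix")
    expect_null(b$cont$cont)
  }
})

test_that("a bare action is a single prefix with no continuation", {
  t <- bcs_parse_term("{a,1}")
  expect_identical(t$type, "prefix")
  expect_identical(t$action$kind, "local")
  expect_identical(t$action$label, "a")
  expect_null(t$cont)
})

test_that("set expressions honour subtraction > intersection > union", {
  s <- bcs_parse_set("0..2 U 8..15 I 4..9")
  expect_identical(s$op, "U")
  expect_identical(s$rhs$op, "I")
  s2 <- bcs_parse_set("0..3 U 6..7")
  expect_identical(s2$op, "U")
  expect_identical(s2$lhs$op, "range")
  s3 <- bcs_parse_set("0..9 I 2..5\\3")
  expect_identical(s3$op, "I")
  expect_identical(s3$rhs$op, "\\")
  # ranges with expression endpoints
  s4 <- bcs_parse_set("i-1..i+1")
  expect_identical(s4$op, "range")
  expect_identical(bcs_eval_set(s4, list(i = 5)), c(4, 5, 6))
})

test_that("every action variant parses to the right structure", {
  a <- bcs_parse_action("{@react?[i](j), 2}")
  expect_identical(a$kind, "hs_recv")
  expect_identical(a$bindings, "j")
  expect_length(a$channel, 1L)
  expect_length(a$sets, 1L)

  a <- bcs_parse_action("{chr?[0..9](x), 1}")
  expect_identical(a$kind, "b_recv")
  expect_identical(a$bindings, "x")

  a <- bcs_parse_action("{@x+1,y/2?[x-1..x+1,y+8](a,b), 1}")
  expect_identical(a$kind, "hs_recv")
  expect_length(a$channel, 2L)
  expect_length(a$sets, 2L)
  expect_identical(a$bindings, c("a", "b"))

  expect_identical(bcs_parse_action("{@c![i], 1}")$kind, "hs_send")
  expect_identical(bcs_parse_action("{c![i], 1}")$kind, "b_launch")
  expect_identical(bcs_parse_action("{c#[i], 1}")$kind, "b_kill")
  expect_identical(bcs_parse_action("{~c?[0..3], 1}")$kind, "b_check")
  expect_identical(bcs_parse_action("{go, 0.5}")$kind, "local")
})

test_that("invalid actions are syntax errors", {
  expect_error(bcs_parse_action("{@c![1](x), 1}"), "binding")
  expect_error(bcs_parse_action("{~c![1], 1}"), "sigil|communication")
  expect_error(bcs_parse_action("{a}"), "rate")
  expect_error(bcs_parse_action("{@c?[0..1,5](x), 1}"), "same length")
})

test_that("model structure: constants, definitions, initial system", {
  fx <- bcs_fixture_replication(L = 20)
  m <- fx$model
  expect_setequal(names(m$defs), c("ORI", "FR", "FL"))
  expect_true(all(m$init$process == "ORI"))
  expect_identical(nrow(bcs_validate(m)), 0L)

  m2 <- bcs_parse("k = 1e-4\nP = {a, k}\n3 * P")
  expect_identical(unname(m2$consts[["k"]]), 1e-4)
  expect_identical(m2$init$copies, 3L)
})

test_that("malformed models are rejected with informative errors", {
  expect_error(bcs_parse("P = {a,1}"), "system line")
  expect_error(bcs_parse(""), "empty model")
  expect_error(bcs_parse("P = {a,1\nP"), "syntax error")
  expect_error(bcs_parse("P = {a,1}\nP\nQ = {b,1}"), "final line|follow")
  expect_error(bcs_parse("P = {a,1}\nP || Q"), NA)  # parses; validation catches Q
  expect_gt(nrow(bcs_validate(bcs_parse("P = {a,1}\nP || Q"))), 0L)
})

test_that("comments and line continuations are handled", {
  m <- bcs_parse("
// a comment
r = 2  // trailing comment
P = {a, r} +
    {b, r}
P
")
  expect_identical(unname(m$consts[["r"]]), 2)
  expect_identical(m$defs$P$body$type, "choice")
})

test_that("pretty-printing any fixture model round-trips to an identical tree", {
  fixtures <- list(
    bcs_ex_increment(), bcs_ex_choice(), bcs_ex_combinators(),
    bcs_ex_bimolecular(), bcs_ex_reactant(), bcs_ex_clock(),
    bcs_ex_channel_list(),
    bcs_fixture_replication(L = 30),
    bcs_fixture_replication(L = 30, variant = "cooperative"),
    bcs_fixture_replication(L = 30, variant = "barrier", barrier_position = 15),
    bcs_fixture_dna_damage(),
    bcs_fixture_tcr(),
    bcs_fixture_tcr(with_dwell = FALSE)
  )
  for (fx in fixtures) {
    m1 <- fx$model
    m2 <- bcs_parse(bcs_pretty(m1))
    expect_identical(m2$defs, m1$defs, label = fx$name)
    expect_identical(unclass(m2$consts), unclass(m1$consts), label = fx$name)
    expect_identical(m2$init, m1$init, label = fx$name)
  }
})
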