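# Arithmetic, gate, rate and set evaluation.

test_that("arithmetic follows standard precedence and is exact", {
  expect_identical(bcs_eval_expr("i+1", list(i = 0)), 1)
  expect_identical(bcs_eval_expr("2*j", list(j = 8)), 16)
  expect_identical(bcs_eval_expr("1+2*3"), 7)
  expect_identical(bcs_eval_expr("-2^2"), -4)
  expect_identical(bcs_eval_expr("(1+2)*3"), 9)
  expect_identical(bcs_eval_expr("7/2"), 3.5)  # real division, no truncation
  expect_error(bcs_eval_expr("x/0", list(x = 1)), "finite")
  expect_error(bcs_eval_expr("x+1", list()), "cannot evaluate")
})

test_that("all six printed set identities hold exactly", {
  expect_identical(bcs_eval_set("0..3"), c(0, 1, 2, 3))
  expect_identical(bcs_eval_set("-1..2"), c(-1, 0, 1, 2))
  expect_identical(bcs_eval_set("0..3 U 6..7"), c(0, 1, 2, 3, 6, 7))
  expect_identical(bcs_eval_set("-1 U 0..3"), c(-1, 0, 1, 2, 3))
  expect_identical(bcs_eval_set("0..10 I 8..15"), c(8, 9, 10))
  expect_identical(bcs_eval_set("0..2 U 8..15 I 4..9"), c(0, 1, 2, 8, 9))
  expect_identical(bcs_eval_set("0..5\\3"), c(0, 1, 2, 4, 5))
  expect_identical(bcs_eval_set("0..5\\8"), c(0, 1, 2, 3, 4, 5))
})

test_that("set precedence: intersection binds before union", {
  # union(0..2, intersect(8..15, 4..9)), not intersect(union(..), 4..9)
  expect_identical(bcs_eval_set("0..2 U 8..15 I 4..9"),
                   as.numeric(sort(union(0:2, intersect(8:15, 4:9)))))
  expect_false(isTRUE(all.equal(bcs_eval_set("0..2 U 8..15 I 4..9"),
                                as.numeric(sort(intersect(union(0:2, 8:15), 4:9))))))
  # explicit parentheses override
  expect_identical(bcs_eval_set("(0..2 U 8..15) I 4..9"), c(8, 9))
})

test_that("degenerate sets: reversed ranges are empty, bad endpoints error", {
  expect_identical(bcs_eval_set("5..3"), numeric(0))
  expect_identical(bcs_eval_set("i-1..i+1", list(i = 0)), c(-1, 0, 1))
  expect_error(bcs_eval_set("0..2.5"), "integer")
  expect_error(bcs_eval_set("x..3", list()), "cannot evaluate")
})

test_that("gates evaluate boolean combinations with ~ binding tightest", {
  g <- bcs_parse_gate("i<5 & j<10")
  expect_false(bcs_eval_gate(g, list(i = 4, j = 16)))
  expect_true(bcs_eval_gate(g, list(i = 3, j = 8)))
  expect_false(bcs_eval_gate("~(i==0)", list(i = 0)))
  expect_true(bcs_eval_gate("~i==0 | j>5", list(i = 1, j = 0)))
  expect_true(bcs_eval_gate("i!=0 & (j<=2 | j>=8)", list(i = 1, j = 9)))
  expect_error(bcs_eval_gate("q<1", list()), "cannot evaluate")
})

test_that("rates must be positive finite numbers, with provenance on error", {
  expect_equal(bcs_eval_rate(bcs_parse_expr("r*s"), list(r = 0.3, s = 2)), 0.6)
  expect_equal(bcs_eval_rate(bcs_parse_expr("d*A*k"), list(d = 2, A = 3, k = 0.1)), 0.6)
  expect_error(bcs_eval_rate(bcs_parse_expr("0*x"), list(x = 5)), "must be > 0")
  expect_error(bcs_eval_rate(bcs_parse_expr("r-1"), list(r = 0.5), what = "rate of 'fire'"),
               "fire")
})

test_that("environment shadowing is binding > parameter > constant", {
  env <- bcs_env(constants = list(x = 1, y = 10, z = 100),
                 parameters = list(x = 2, y = 20),
                 bindings = list(x = 3))
  expect_identical(bcs_eval_expr("x", env), 3)
  expect_identical(bcs_eval_expr("y", env), 20)
  expect_identical(bcs_eval_expr("z", env), 100)
})
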