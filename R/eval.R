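# Evaluation of arithmetic, gate, rate and set expressions under an
# environment of binding variables, process parameters and global constants.
# Shadowing order is binding > parameter > constant, achieved by building the
# lookup list with constants first and bindings last (later entries win).

#' Build an evaluation environment
#'
#' @param constants,parameters,bindings Named numeric vectors or lists.
#'   Bindings shadow parameters, which shadow constants.
#' @return A named list suitable for the `env` argument of the `bcs_eval_*`
#'   functions.
#' @export
bcs_env <- function(constants = list(), parameters = list(), bindings = list()) {
  env <- as.list(constants)
  p <- as.list(parameters)
  env[names(p)] <- p
  b <- as.list(bindings)
  env[names(b)] <- b
  env
}

#' Parse an arithmetic expression
#'
#' @param text A single string, e.g. `"k*d*A"`.
#' @return An expression tree for [bcs_eval_expr()] / [bcs_eval_rate()].
#' @export
bcs_parse_expr <- function(text) {
  ps <- new_cursor(bcs_tokenize(text))
  e <- p_arith(ps)
  if (!at_end(ps)) {
    t <- pk(ps)
    bcs_syntax_error(sprintf("trailing input '%s' after expression", t$value),
                     t$line, t$col)
  }
  e
}

#' Parse a gate condition
#'
#' @param text A single string, e.g. `"i<5 & j<10"`.
#' @return An expression tree for [bcs_eval_gate()].
#' @export
bcs_parse_gate <- function(text) {
  ps <- new_cursor(bcs_tokenize(text))
  e <- p_bool(ps)
  if (!at_end(ps)) {
    t <- pk(ps)
    bcs_syntax_error(sprintf("trailing input '%s' after gate condition", t$value),
                     t$line, t$col)
  }
  e
}

eval_error <- function(what, msg) {
  stop(sprintf("cannot evaluate %s: %s", what, msg), call. = FALSE)
}

#' Evaluate an arithmetic expression
#'
#' Applies standard precedence (unary minus, then `^`, then `*` `/`, then
#' `+` `-`); division is real division.  The result must be a finite real.
#'
#' @param expr An expression tree from [bcs_parse_expr()] (or a string).
#' @param env A named list of values, see [bcs_env()].
#' @param what Label used in error messages.
#' @return A single finite numeric value.
#' @export
bcs_eval_expr <- function(expr, env = list(), what = "expression") {
  if (is.character(expr)) expr <- bcs_parse_expr(expr)
  v <- tryCatch(eval(expr, env, baseenv()), error = function(cnd) {
    eval_error(what, conditionMessage(cnd))
  })
  if (!is.numeric(v) || length(v) != 1L) {
    eval_error(what, "result is not a single number")
  }
  if (!is.finite(v)) {
    eval_error(what, "result is not finite (division by zero?)")
  }
  as.numeric(v)
}

#' Evaluate a gate condition
#'
#' @param gate An expression tree from [bcs_parse_gate()] (or a string).
#' @inheritParams bcs_eval_expr
#' @return `TRUE` or `FALSE`.
#' @export
bcs_eval_gate <- function(gate, env = list(), what = "gate") {
  if (is.character(gate)) gate <- bcs_parse_gate(gate)
  v <- tryCatch(eval(gate, env, baseenv()), error = function(cnd) {
    eval_error(what, conditionMessage(cnd))
  })
  if (!is.logical(v) || length(v) != 1L || is.na(v)) {
    eval_error(what, "gate did not evaluate to true/false")
  }
  v
}

#' Evaluate a rate expression
#'
#' Rates must evaluate to a strictly positive finite number; anything else is
#' a model error reported with the offending action and environment.
#'
#' @inheritParams bcs_eval_expr
#' @return A single positive numeric value.
#' @export
bcs_eval_rate <- function(expr, env = list(), what = "rate") {
  v <- bcs_eval_expr(expr, env, what)
  if (v <= 0) {
    vals <- paste(sprintf("%s=%s", names(env), vapply(env, format, character(1))),
                  collapse = ", ")
    eval_error(what, sprintf("rate evaluated to %s (must be > 0) with %s",
                             format(v), if (nzchar(vals)) vals else "empty environment"))
  }
  v
}

set_endpoint <- function(expr, env, what) {
  v <- bcs_eval_expr(expr, env, what)
  if (abs(v - round(v)) > 1e-9) {
    eval_error(what, sprintf("set endpoint %s is not an integer", format(v)))
  }
  round(v)
}

#' Evaluate a set expression
#'
#' Materialises the finite integer set denoted by a set expression.  A range
#' `a..b` with `a > b` evaluates to the empty set, which simply disables the
#' receive using it; non-integer endpoints are an error.
#'
#' @param set A set-expression tree from [bcs_parse_set()] (or a string).
#' @inheritParams bcs_eval_expr
#' @return A sorted numeric vector of integers (possibly empty).
#' @examples
#' bcs_eval_set("0..10 I 8..15")
#' bcs_eval_set("0..2 U 8..15 I 4..9")
#' @export
bcs_eval_set <- function(set, env = list(), what = "set expression") {
  if (is.character(set)) set <- bcs_parse_set(set)
  eval_set_node(set, env, what)
}

eval_set_node <- function(s, env, what) {
  switch(s$op,
    single = set_endpoint(s$value, env, what),
    range = {
      lo <- set_endpoint(s$lo, env, what)
      hi <- set_endpoint(s$hi, env, what)
      if (lo > hi) numeric(0) else as.numeric(seq(lo, hi))
    },
    "U" = sort(union(eval_set_node(s$lhs, env, what), eval_set_node(s$rhs, env, what))),
    "I" = sort(intersect(eval_set_node(s$lhs, env, what), eval_set_node(s$rhs, env, what))),
    "\\" = sort(setdiff(eval_set_node(s$lhs, env, what), eval_set_node(s$rhs, env, what)))
  )
}

# channel components: a bare identifier evaluates to its numeric value when
# bound in the environment and otherwise stays a symbolic name.  Symbolic and
# numeric components never match each other ("no crosstalk between channels").
eval_channel_component <- function(comp, env, what) {
  if (is.name(comp)) {
    nm <- as.character(comp)
    if (!is.null(env[[nm]])) {
      return(fmt_num(as.numeric(env[[nm]])))
    }
    return(paste0("'", nm))
  }
  fmt_num(bcs_eval_expr(comp, env, what))
}

# the evaluated channel identity: a single string key over all components
eval_channel_key <- function(channel, env, what = "channel") {
  paste(vapply(channel, eval_channel_component, character(1), env = env, what = what),
        collapse = ",")
}

# human-readable channel (no quote marker on symbolic names)
channel_display <- function(key) gsub("'", "", key, fixed = TRUE)
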