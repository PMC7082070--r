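# Concrete syntax of the bcs dialect.
#
# Line-oriented: `name = <number expr>` defines a global constant,
# `Name[p1,...] = <term>` defines a process, and the final line without `=`
# is the initial system (parallel composition, `N * P[args]` multiplicities
# allowed).  `//` comments run to end of line; `;` is accepted as a line
# separator.  Lines are joined with the previous line when either ends/starts
# mid-expression (trailing `=`, `+`, `||`, `,`, `.`, `->`).

bcs_two_char_ops <- c("->", "..", "||", "<=", ">=", "==", "!=")
bcs_one_char_ops <- strsplit("{}[]()+-*/^=!?#@~<>&|,.\\", "")[[1]]

bcs_syntax_error <- function(msg, line = NA, col = NA) {
  where <- if (!is.na(line)) sprintf(" at line %s, column %s", line, col) else ""
  stop(sprintf("bcs syntax error%s: %s", where, msg), call. = FALSE)
}

# Tokenize one logical line into a list of tokens (type, value, num, line, col).
bcs_tokenize <- function(text, line_no = 1L) {
  toks <- list()
  i <- 1L
  n <- nchar(text)
  num_re <- "^[0-9]+(\\.[0-9]+)?([eE][+-]?[0-9]+)?"
  name_re <- "^[A-Za-z_][A-Za-z0-9_]*"
  while (i <= n) {
    rest <- substr(text, i, n)
    ws <- regmatches(rest, regexpr("^[ \t\r]+", rest))
    if (length(ws) == 1L) {
      i <- i + nchar(ws)
      next
    }
    if (startsWith(rest, "//")) break
    m <- regmatches(rest, regexpr(num_re, rest))
    if (length(m) == 1L && nchar(m) > 0L) {
      toks[[length(toks) + 1L]] <- list(
        type = "num", value = m, num = as.numeric(m), line = line_no, col = i
      )
      i <- i + nchar(m)
      next
    }
    m <- regmatches(rest, regexpr(name_re, rest))
    if (length(m) == 1L && nchar(m) > 0L) {
      toks[[length(toks) + 1L]] <- list(
        type = "name", value = m, num = NA_real_, line = line_no, col = i
      )
      i <- i + nchar(m)
      next
    }
    two <- substr(rest, 1L, 2L)
    if (two %in% bcs_two_char_ops) {
      toks[[length(toks) + 1L]] <- list(
        type = "op", value = two, num = NA_real_, line = line_no, col = i
      )
      i <- i + 2L
      next
    }
    one <- substr(rest, 1L, 1L)
    if (one %in% bcs_one_char_ops) {
      toks[[length(toks) + 1L]] <- list(
        type = "op", value = one, num = NA_real_, line = line_no, col = i
      )
      i <- i + 1L
      next
    }
    bcs_syntax_error(sprintf("unexpected character '%s'", one), line_no, i)
  }
  toks
}

# ---- token cursor ----------------------------------------------------------

new_cursor <- function(toks) {
  ps <- new.env(parent = emptyenv())
  ps$toks <- toks
  ps$i <- 1L
  ps
}

pk <- function(ps, ahead = 0L) {
  j <- ps$i + ahead
  if (j > length(ps$toks)) NULL else ps$toks[[j]]
}

pk_val <- function(ps, ahead = 0L) {
  t <- pk(ps, ahead)
  if (is.null(t)) "" else t$value
}

adv <- function(ps) {
  t <- pk(ps)
  ps$i <- ps$i + 1L
  t
}

accept <- function(ps, value) {
  t <- pk(ps)
  if (!is.null(t) && t$type == "op" && t$value == value) {
    ps$i <- ps$i + 1L
    TRUE
  } else {
    FALSE
  }
}

expect <- function(ps, value, what = NULL) {
  t <- pk(ps)
  if (is.null(t) || t$value != value) {
    found <- if (is.null(t)) "end of line" else sprintf("'%s'", t$value)
    bcs_syntax_error(
      sprintf("expected '%s'%s but found %s", value,
              if (is.null(what)) "" else paste0(" (", what, ")"), found),
      if (is.null(t)) NA else t$line, if (is.null(t)) NA else t$col
    )
  }
  adv(ps)
}

cursor_save <- function(ps) ps$i
cursor_restore <- function(ps, i) ps$i <- i

at_end <- function(ps) ps$i > length(ps$toks)

# ---- arithmetic expressions (R call objects) -------------------------------

p_arith <- function(ps) p_add(ps)

p_add <- function(ps) {
  e <- p_mul(ps)
  repeat {
    if (accept(ps, "+")) {
      e <- call("+", e, p_mul(ps))
    } else if (accept(ps, "-")) {
      e <- call("-", e, p_mul(ps))
    } else {
      return(e)
    }
  }
}

p_mul <- function(ps) {
  e <- p_unary(ps)
  repeat {
    if (accept(ps, "*")) {
      e <- call("*", e, p_unary(ps))
    } else if (accept(ps, "/")) {
      e <- call("/", e, p_unary(ps))
    } else {
      return(e)
    }
  }
}

p_unary <- function(ps) {
  if (accept(ps, "-")) call("-", p_unary(ps)) else p_pow(ps)
}

p_pow <- function(ps) {
  e <- p_atom(ps)
  if (accept(ps, "^")) call("^", e, p_unary(ps)) else e
}

p_atom <- function(ps) {
  t <- pk(ps)
  if (is.null(t)) bcs_syntax_error("expected an expression but found end of line")
  if (t$type == "num") {
    adv(ps)
    return(t$num)
  }
  if (t$type == "name") {
    adv(ps)
    return(as.name(t$value))
  }
  if (t$value == "(") {
    adv(ps)
    e <- p_add(ps)
    expect(ps, ")")
    return(e)
  }
  bcs_syntax_error(sprintf("expected an expression but found '%s'", t$value),
                   t$line, t$col)
}

# ---- gate (boolean) expressions; '~' maps to R's '!' -----------------------

bcs_relops <- c("<=", "<", ">=", ">", "==", "!=")

p_bool <- function(ps) p_bor(ps)

p_bor <- function(ps) {
  e <- p_band(ps)
  while (accept(ps, "|")) e <- call("|", e, p_band(ps))
  e
}

p_band <- function(ps) {
  e <- p_bnot(ps)
  while (accept(ps, "&")) e <- call("&", e, p_bnot(ps))
  e
}

p_bnot <- function(ps) {
  if (accept(ps, "~")) call("!", p_bnot(ps)) else p_cmp(ps)
}

p_cmp <- function(ps) {
  # a parenthesis may open either a boolean group or an arithmetic operand;
  # try the boolean reading first and backtrack on failure
  if (pk_val(ps) == "(") {
    mark <- cursor_save(ps)
    e <- tryCatch({
      adv(ps)
      inner <- p_bor(ps)
      expect(ps, ")")
      inner
    }, error = function(cnd) NULL)
    if (!is.null(e) && !(pk_val(ps) %in% c(bcs_relops, "+", "-", "*", "/", "^"))) {
      return(e)
    }
    cursor_restore(ps, mark)
  }
  lhs <- p_add(ps)
  op <- pk_val(ps)
  if (!(op %in% bcs_relops)) {
    t <- pk(ps)
    bcs_syntax_error(
      sprintf("expected a comparison operator in gate but found '%s'",
              if (is.null(t)) "end of line" else op),
      if (is.null(t)) NA else t$line, if (is.null(t)) NA else t$col
    )
  }
  adv(ps)
  call(op, lhs, p_add(ps))
}

# ---- set expressions -------------------------------------------------------
# precedence: subtraction '\' > intersection 'I' > union 'U'; left-associative

p_set <- function(ps) p_sunion(ps)

p_sunion <- function(ps) {
  e <- p_sinter(ps)
  while (!is.null(pk(ps)) && pk(ps)$type == "name" && pk_val(ps) == "U") {
    adv(ps)
    e <- list(op = "U", lhs = e, rhs = p_sinter(ps))
  }
  e
}

p_sinter <- function(ps) {
  e <- p_ssub(ps)
  while (!is.null(pk(ps)) && pk(ps)$type == "name" && pk_val(ps) == "I") {
    adv(ps)
    e <- list(op = "I", lhs = e, rhs = p_ssub(ps))
  }
  e
}

p_ssub <- function(ps) {
  e <- p_satom(ps)
  while (accept(ps, "\\")) e <- list(op = "\\", lhs = e, rhs = p_satom(ps))
  e
}

p_satom <- function(ps) {
  if (pk_val(ps) == "(" ) {
    adv(ps)
    e <- p_sunion(ps)
    expect(ps, ")")
    return(e)
  }
  lo <- p_add(ps)
  if (accept(ps, "..")) {
    list(op = "range", lo = lo, hi = p_add(ps))
  } else {
    list(op = "single", value = lo)
  }
}

#' Parse a set expression
#'
#' Parses the integer-set sub-language used in handshake/beacon receives and
#' beacon checks: ranges `a..b`, singletons, union `U`, intersection `I` and
#' subtraction `\\`, with subtraction binding more strongly than intersection,
#' which binds more strongly than union.
#'
#' @param text A single string, e.g. `"0..2 U 8..15 I 4..9"`.
#' @return A set-expression syntax tree; evaluate it with [bcs_eval_set()].
#' @examples
#' bcs_eval_set(bcs_parse_set("0..3 U 6..7"))
#' @export
bcs_parse_set <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  ps <- new_cursor(bcs_tokenize(text))
  e <- p_set(ps)
  if (!at_end(ps)) {
    t <- pk(ps)
    bcs_syntax_error(sprintf("trailing input '%s' after set expression", t$value),
                     t$line, t$col)
  }
  structure(e, class = "bcs_set")
}

# ---- actions ---------------------------------------------------------------

bcs_action <- function(kind, channel = NULL, payload = NULL, sets = NULL,
                       bindings = character(), rate = NULL, label = NULL) {
  structure(
    list(kind = kind, channel = channel, payload = payload, sets = sets,
         bindings = bindings, rate = rate, label = label),
    class = "bcs_action"
  )
}

# expects the opening '{' as the current token
p_action <- function(ps) {
  open <- expect(ps, "{", "start of action")
  tilde <- accept(ps, "~")
  at <- accept(ps, "@")
  exprs <- list(p_add(ps))
  while (pk_val(ps) == ",") {
    # channel components; the final comma before the rate is detected below
    # by the sigil / closing brace that follows the list
    adv(ps)
    exprs[[length(exprs) + 1L]] <- p_add(ps)
  }
  sig <- pk_val(ps)
  if (sig == "}") {
    if (tilde || at) {
      bcs_syntax_error("'~' and '@' require a communication action", open$line, open$col)
    }
    if (length(exprs) != 2L) {
      bcs_syntax_error("a local action is written {label, rate}", open$line, open$col)
    }
    if (!is.name(exprs[[1L]])) {
      bcs_syntax_error("local action label must be an identifier", open$line, open$col)
    }
    adv(ps)
    return(bcs_action("local", label = as.character(exprs[[1L]]), rate = exprs[[2L]]))
  }
  if (!(sig %in% c("!", "?", "#"))) {
    t <- pk(ps)
    bcs_syntax_error(sprintf("expected '!', '?', '#' or '}' in action but found '%s'",
                             if (is.null(t)) "end of line" else sig),
                     if (is.null(t)) NA else t$line, if (is.null(t)) NA else t$col)
  }
  adv(ps)
  channel <- exprs
  kind <- if (tilde && sig == "?" && !at) {
    "b_check"
  } else if (at && sig == "!" && !tilde) {
    "hs_send"
  } else if (at && sig == "?" && !tilde) {
    "hs_recv"
  } else if (!at && !tilde && sig == "!") {
    "b_launch"
  } else if (!at && !tilde && sig == "#") {
    "b_kill"
  } else if (!at && !tilde && sig == "?") {
    "b_recv"
  } else {
    bcs_syntax_error(sprintf("invalid action sigil combination near '%s'", sig),
                     open$line, open$col)
  }
  expect(ps, "[", "start of payload")
  payload <- NULL
  sets <- NULL
  if (kind %in% c("hs_send", "b_launch", "b_kill")) {
    payload <- list(p_add(ps))
    while (accept(ps, ",")) payload[[length(payload) + 1L]] <- p_add(ps)
  } else {
    sets <- list(p_set(ps))
    while (accept(ps, ",")) sets[[length(sets) + 1L]] <- p_set(ps)
  }
  expect(ps, "]")
  bindings <- character()
  if (pk_val(ps) == "(") {
    if (!(kind %in% c("hs_recv", "b_recv"))) {
      bcs_syntax_error("binding variables are only allowed on a receive",
                       open$line, open$col)
    }
    adv(ps)
    repeat {
      t <- pk(ps)
      if (is.null(t) || t$type != "name") {
        bcs_syntax_error("expected a binding variable name",
                         if (is.null(t)) NA else t$line, if (is.null(t)) NA else t$col)
      }
      adv(ps)
      bindings <- c(bindings, t$value)
      if (!accept(ps, ",")) break
    }
    expect(ps, ")")
  }
  if (length(bindings) > 0L && length(bindings) != length(sets)) {
    bcs_syntax_error("binding list and set list must have the same length",
                     open$line, open$col)
  }
  expect(ps, ",", "rate separator")
  rate <- p_add(ps)
  expect(ps, "}", "end of action")
  bcs_action(kind, channel = channel, payload = payload, sets = sets,
             bindings = bindings, rate = rate)
}

#' Parse a single action
#'
#' Parses one brace-delimited action of the calculus: a local action
#' `{a, r}`, handshake send `{@c![i], r}`, handshake receive
#' `{@c?[set](x), r}`, beacon launch `{c![i], r}`, beacon kill `{c#[i], r}`,
#' beacon receive `{c?[set](x), r}` or beacon check `{~c?[set], r}`.
#' Channels may be comma-separated lists of expressions.
#'
#' @param text A single string containing one action.
#' @return A `bcs_action` object.
#' @export
bcs_parse_action <- function(text) {
  ps <- new_cursor(bcs_tokenize(text))
  a <- p_action(ps)
  if (!at_end(ps)) {
    t <- pk(ps)
    bcs_syntax_error(sprintf("trailing input '%s' after action", t$value), t$line, t$col)
  }
  a
}

# ---- process terms ---------------------------------------------------------
# precedence: prefix > choice > parallel

bcs_prefix <- function(gate, action, cont) {
  structure(list(type = "prefix", gate = gate, action = action, cont = cont),
            class = "bcs_term")
}
bcs_choice <- function(branches) {
  structure(list(type = "choice", branches = branches), class = "bcs_term")
}
bcs_parallel <- function(comps) {
  structure(list(type = "parallel", comps = comps), class = "bcs_term")
}
bcs_call <- function(name, args) {
  structure(list(type = "call", name = name, args = args), class = "bcs_term")
}

p_term <- function(ps) {
  comps <- list(p_choice_term(ps))
  while (accept(ps, "||")) comps[[length(comps) + 1L]] <- p_choice_term(ps)
  if (length(comps) == 1L) comps[[1L]] else bcs_parallel(comps)
}

p_choice_term <- function(ps) {
  branches <- list(p_seq(ps))
  while (accept(ps, "+")) branches[[length(branches) + 1L]] <- p_seq(ps)
  if (length(branches) == 1L) branches[[1L]] else bcs_choice(branches)
}

# one unit of a prefix chain
p_unit <- function(ps) {
  t <- pk(ps)
  if (is.null(t)) bcs_syntax_error("expected a process term but found end of line")
  if (t$value == "[") {
    adv(ps)
    gate <- p_bool(ps)
    expect(ps, "]")
    expect(ps, "->", "gate arrow")
    if (pk_val(ps) != "{") {
      t2 <- pk(ps)
      bcs_syntax_error("a gate must be followed by an action",
                       if (is.null(t2)) NA else t2$line, if (is.null(t2)) NA else t2$col)
    }
    return(list(what = "action", gate = gate, action = p_action(ps)))
  }
  if (t$value == "{") {
    return(list(what = "action", gate = NULL, action = p_action(ps)))
  }
  if (t$value == "(") {
    adv(ps)
    term <- p_term(ps)
    expect(ps, ")")
    return(list(what = "group", term = term))
  }
  if (t$type == "name") {
    adv(ps)
    args <- list()
    if (pk_val(ps) == "[") {
      adv(ps)
      args <- list(p_add(ps))
      while (accept(ps, ",")) args[[length(args) + 1L]] <- p_add(ps)
      expect(ps, "]")
    }
    return(list(what = "call", term = bcs_call(t$value, args)))
  }
  bcs_syntax_error(sprintf("expected a process term but found '%s'", t$value),
                   t$line, t$col)
}

p_seq <- function(ps) {
  units <- list(p_unit(ps))
  while (accept(ps, ".")) units[[length(units) + 1L]] <- p_unit(ps)
  n <- length(units)
  last <- units[[n]]
  cont <- switch(last$what,
    action = bcs_prefix(last$gate, last$action, NULL),
    call = last$term,
    group = last$term
  )
  if (n > 1L) {
    for (k in seq(n - 1L, 1L)) {
      u <- units[[k]]
      if (u$what != "action") {
        bcs_syntax_error("only an action (optionally gated) may prefix a continuation")
      }
      cont <- bcs_prefix(u$gate, u$action, cont)
    }
  }
  cont
}

#' Parse a process term
#'
#' @param text A single string containing a process term, e.g.
#'   `"{a,1} || {b,2}.{c,3} + {d,4}.{e,5}"`.
#' @return A `bcs_term` syntax tree.
#' @export
bcs_parse_term <- function(text) {
  ps <- new_cursor(bcs_tokenize(text))
  term <- p_term(ps)
  if (!at_end(ps)) {
    t <- pk(ps)
    bcs_syntax_error(sprintf("trailing input '%s' after process term", t$value),
                     t$line, t$col)
  }
  term
}

# ---- model parsing ---------------------------------------------------------

# split raw source into logical lines, joining continuations
bcs_logical_lines <- function(text) {
  raw <- unlist(strsplit(text, "\n", fixed = TRUE))
  raw <- sub("//.*$", "", raw)
  raw <- unlist(strsplit(raw, ";", fixed = TRUE))
  raw <- c(raw)
  out <- list()
  out_no <- integer()
  joiners_end <- c("=", "+", ",", ".", "->", "*")
  joiners_start <- c("||", "+", ".")
  for (k in seq_along(raw)) {
    ln <- trimws(raw[[k]])
    if (nchar(ln) == 0L) next
    join <- FALSE
    if (length(out) > 0L) {
      prev <- out[[length(out)]]
      ends <- regmatches(prev, regexpr("(\\|\\||->|[=+,.*])$", prev))
      starts <- regmatches(ln, regexpr("^(\\|\\||->|[+.])", ln))
      join <- length(ends) == 1L || length(starts) == 1L
    }
    if (join) {
      out[[length(out)]] <- paste(out[[length(out)]], ln)
    } else {
      out[[length(out) + 1L]] <- ln
      out_no <- c(out_no, k)
    }
  }
  list(lines = out, line_no = out_no)
}

# does the token stream contain a top-level '=' (assignment, not '==')?
has_assign <- function(toks) {
  any(vapply(toks, function(t) t$type == "op" && t$value == "=", logical(1)))
}

#' Parse a Beacon Calculus model
#'
#' Parses bcs source text into a model object holding global constants,
#' process definitions and the initial system line.  Definitions are written
#' one per line as `Name[p1,p2] = term` (or `name = number` for a constant);
#' the final line without `=` is the initial system: a `||`-separated list of
#' process instantiations, where `N * P[args]` starts `N` copies.
#'
#' @param text bcs source as a single string (or character vector of lines).
#' @return A `bcs_model` object with elements `consts` (named numeric),
#'   `defs` (named list of process definitions) and `init` (a tibble with
#'   columns `process`, `args` (list), `copies`).
#' @seealso [bcs_parse_file()], [bcs_validate()], [bcs_simulate()]
#' @examples
#' m <- bcs_parse("
#'   r = 1
#'   A[i,j] = [i<5 & j<10]->{changeParameters,r}.A[i+1,2*j]
#'   A[0,1]
#' ")
#' m
#' @export
bcs_parse <- function(text) {
  stopifnot(is.character(text))
  text <- paste(text, collapse = "\n")
  ll <- bcs_logical_lines(text)
  if (length(ll$lines) == 0L) stop("empty model: no definitions found", call. = FALSE)
  consts <- list()
  defs <- list()
  init <- NULL
  sys_seen_at <- NA_integer_
  for (k in seq_along(ll$lines)) {
    line <- ll$lines[[k]]
    line_no <- ll$line_no[[k]]
    toks <- bcs_tokenize(line, line_no)
    if (length(toks) == 0L) next
    if (!has_assign(toks)) {
      if (!is.na(sys_seen_at)) {
        bcs_syntax_error("more than one initial system line (line without '=')", line_no, 1)
      }
      sys_seen_at <- k
      init <- parse_system_line(toks, consts, line_no)
      next
    }
    if (!is.na(sys_seen_at)) {
      bcs_syntax_error("definitions may not follow the initial system line", line_no, 1)
    }
    ps <- new_cursor(toks)
    t <- pk(ps)
    if (is.null(t) || t$type != "name") {
      bcs_syntax_error("a definition must start with a name", line_no, 1)
    }
    lhs_name <- adv(ps)$value
    params <- character()
    has_params <- FALSE
    if (pk_val(ps) == "[") {
      has_params <- TRUE
      adv(ps)
      repeat {
        pt <- pk(ps)
        if (is.null(pt) || pt$type != "name") {
          bcs_syntax_error("expected a parameter name", line_no, 1)
        }
        adv(ps)
        params <- c(params, pt$value)
        if (!accept(ps, ",")) break
      }
      expect(ps, "]")
    }
    expect(ps, "=", "definition")
    rhs_start <- cursor_save(ps)
    if (!has_params) {
      # a parameterless RHS that is a closed numeric expression over the
      # constants seen so far defines a constant
      val <- tryCatch({
        e <- p_add(ps)
        if (!at_end(ps)) stop("trailing")
        v <- eval(e, consts, baseenv())
        if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) stop("non-numeric")
        v
      }, error = function(cnd) NULL)
      if (!is.null(val)) {
        if (lhs_name %in% names(consts)) {
          bcs_syntax_error(sprintf("constant '%s' redefined", lhs_name), line_no, 1)
        }
        consts[[lhs_name]] <- val
        next
      }
      cursor_restore(ps, rhs_start)
    }
    body <- p_term(ps)
    if (!at_end(ps)) {
      t2 <- pk(ps)
      bcs_syntax_error(sprintf("trailing input '%s' after process definition", t2$value),
                       t2$line, t2$col)
    }
    if (lhs_name %in% names(defs)) {
      bcs_syntax_error(sprintf("process '%s' redefined", lhs_name), line_no, 1)
    }
    defs[[lhs_name]] <- list(name = lhs_name, params = params, body = body)
  }
  if (is.na(sys_seen_at)) {
    stop("missing initial system line (final line without '=')", call. = FALSE)
  }
  if (sys_seen_at != length(ll$lines)) {
    stop("the initial system line must be the final line of the model", call. = FALSE)
  }
  structure(
    list(consts = unlist(consts) %||% stats::setNames(numeric(0), character(0)),
         defs = defs, init = init, source = text),
    class = "bcs_model"
  )
}

parse_system_line <- function(toks, consts, line_no) {
  ps <- new_cursor(toks)
  process <- character()
  copies <- integer()
  args <- list()
  repeat {
    mult <- 1L
    t <- pk(ps)
    if (!is.null(t) && t$type == "num" && pk_val(ps, 1L) == "*") {
      adv(ps)
      adv(ps)
      mult <- as.integer(t$num)
      if (is.na(mult) || mult < 1L || t$num != round(t$num)) {
        bcs_syntax_error("multiplicity must be a positive integer", t$line, t$col)
      }
      t <- pk(ps)
    }
    if (is.null(t) || t$type != "name") {
      bcs_syntax_error("expected a process name in the initial system line", line_no, 1)
    }
    adv(ps)
    nm <- t$value
    a <- numeric(0)
    if (pk_val(ps) == "[") {
      adv(ps)
      aexprs <- list(p_add(ps))
      while (accept(ps, ",")) aexprs[[length(aexprs) + 1L]] <- p_add(ps)
      expect(ps, "]")
      a <- vapply(aexprs, function(e) {
        v <- tryCatch(eval(e, consts, baseenv()), error = function(cnd) {
          bcs_syntax_error(sprintf(
            "cannot evaluate initial argument of '%s': %s", nm, conditionMessage(cnd)),
            line_no, 1)
        })
        as.numeric(v)
      }, numeric(1))
    }
    process <- c(process, nm)
    copies <- c(copies, mult)
    args[[length(args) + 1L]] <- a
    if (!accept(ps, "||")) break
  }
  if (!at_end(ps)) {
    t <- pk(ps)
    bcs_syntax_error(sprintf("trailing input '%s' in initial system line", t$value),
                     t$line, t$col)
  }
  tibble::tibble(process = process, args = args, copies = copies)
}

#' Parse a bcs model file
#'
#' @param path Path to a plain-text bcs model file.
#' @return A `bcs_model`; see [bcs_parse()].
#' @export
bcs_parse_file <- function(path) {
  bcs_parse(readLines(path, warn = FALSE))
}

#' @export
print.bcs_model <- function(x, ...) {
  cat(sprintf("<bcs_model> %d constant(s), %d process definition(s)\n",
              length(x$consts), length(x$defs)))
  if (length(x$consts)) {
    cat("constants: ",
        paste(sprintf("%s=%s", names(x$consts), format(x$consts)), collapse = ", "),
        "\n", sep = "")
  }
  for (d in x$defs) {
    cat(sprintf("  %s[%s]\n", d$name, paste(d$params, collapse = ",")))
  }
  cat("initial system: ",
      paste(sprintf("%s%s[%s]",
                    ifelse(x$init$copies > 1L, paste0(x$init$copies, " * "), ""),
                    x$init$process,
                    vapply(x$init$args, function(a) paste(format(a), collapse = ","),
                           character(1))),
            collapse = " || "), "\n", sep = "")
  invisible(x)
}
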