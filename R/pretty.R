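# Canonical printing of syntax trees.  The round-trip invariant is
# parse(pretty(parse(s))) structurally identical to parse(s).

fmt_num <- function(x) {
  if (x == floor(x) && abs(x) < 1e15) return(sprintf("%.0f", x))
  s <- format(x, digits = 15, scientific = NA, trim = TRUE)
  if (as.numeric(s) != x) s <- format(x, digits = 17, trim = TRUE)
  s
}

# arithmetic / gate expression printer; '!' is printed as the calculus's '~'
# precedence levels: | 1, & 2, ~ 3, relop 4, +- 5, */ 6, unary- 7, ^ 8
pp_expr <- function(e, parent_prec = 0L) {
  if (is.numeric(e)) {
    if (e < 0) return(wrap(paste0("-", fmt_num(-e)), 7L, parent_prec))
    return(fmt_num(e))
  }
  if (is.name(e)) return(as.character(e))
  if (!is.call(e)) stop("unexpected node in expression tree", call. = FALSE)
  op <- as.character(e[[1L]])
  if (op == "!") {
    return(wrap(paste0("~", pp_expr(e[[2L]], 3L)), 3L, parent_prec))
  }
  if (length(e) == 2L && op == "-") {
    return(wrap(paste0("-", pp_expr(e[[2L]], 7L)), 7L, parent_prec))
  }
  prec <- switch(op,
    "|" = 1L, "&" = 2L,
    "<" = 4L, "<=" = 4L, ">" = 4L, ">=" = 4L, "==" = 4L, "!=" = 4L,
    "+" = 5L, "-" = 5L, "*" = 6L, "/" = 6L, "^" = 8L,
    stop(sprintf("unexpected operator '%s' in expression tree", op), call. = FALSE)
  )
  # left-associative: right child at equal precedence needs parentheses
  # (for '^', right-associative, the left child does)
  lhs <- pp_expr(e[[2L]], if (op == "^") prec + 1L else prec)
  rhs <- pp_expr(e[[3L]], if (op == "^") prec else prec + 1L)
  sep <- if (prec %in% c(1L, 2L, 4L)) paste0(" ", op, " ") else op
  wrap(paste0(lhs, sep, rhs), prec, parent_prec)
}

wrap <- function(s, prec, parent_prec) {
  if (prec < parent_prec) paste0("(", s, ")") else s
}

# set expressions; precedence \ 3 > I 2 > U 1, left-associative
pp_set <- function(s, parent_prec = 0L) {
  if (s$op == "single") return(pp_expr(s$value, 5L))
  if (s$op == "range") {
    return(paste0(pp_expr(s$lo, 5L), "..", pp_expr(s$hi, 5L)))
  }
  prec <- switch(s$op, "U" = 1L, "I" = 2L, "\\" = 3L)
  lhs <- pp_set(s$lhs, prec)
  rhs <- pp_set(s$rhs, prec + 1L)
  sep <- if (s$op == "\\") "\\" else paste0(" ", s$op, " ")
  out <- paste0(lhs, sep, rhs)
  if (prec < parent_prec) paste0("(", out, ")") else out
}

pp_channel <- function(channel) {
  paste(vapply(channel, pp_expr, character(1), parent_prec = 5L), collapse = ",")
}

pp_action <- function(a) {
  if (a$kind == "local") {
    return(sprintf("{%s, %s}", a$label, pp_expr(a$rate)))
  }
  chan <- pp_channel(a$channel)
  bind <- if (length(a$bindings)) sprintf("(%s)", paste(a$bindings, collapse = ",")) else ""
  body <- switch(a$kind,
    hs_send = sprintf("@%s![%s]", chan,
                      paste(vapply(a$payload, pp_expr, character(1)), collapse = ",")),
    hs_recv = sprintf("@%s?[%s]%s", chan,
                      paste(vapply(a$sets, pp_set, character(1)), collapse = ","), bind),
    b_launch = sprintf("%s![%s]", chan,
                       paste(vapply(a$payload, pp_expr, character(1)), collapse = ",")),
    b_kill = sprintf("%s#[%s]", chan,
                     paste(vapply(a$payload, pp_expr, character(1)), collapse = ",")),
    b_recv = sprintf("%s?[%s]%s", chan,
                     paste(vapply(a$sets, pp_set, character(1)), collapse = ","), bind),
    b_check = sprintf("~%s?[%s]", chan,
                      paste(vapply(a$sets, pp_set, character(1)), collapse = ","))
  )
  sprintf("{%s, %s}", body, pp_expr(a$rate))
}

# term printer; precedence parallel 1 < choice 2 < prefix 3
pp_term <- function(t, parent_prec = 0L) {
  out <- switch(t$type,
    parallel = paste(vapply(t$comps, pp_term, character(1), parent_prec = 2L),
                     collapse = " || "),
    choice = paste(vapply(t$branches, pp_term, character(1), parent_prec = 3L),
                   collapse = " + "),
    call = if (length(t$args)) {
      sprintf("%s[%s]", t$name,
              paste(vapply(t$args, pp_expr, character(1)), collapse = ","))
    } else {
      t$name
    },
    prefix = {
      head <- if (is.null(t$gate)) {
        pp_action(t$action)
      } else {
        sprintf("[%s]->%s", pp_expr(t$gate), pp_action(t$action))
      }
      if (is.null(t$cont)) {
        head
      } else if (t$cont$type %in% c("prefix", "call")) {
        paste0(head, ".", pp_term(t$cont, 3L))
      } else {
        paste0(head, ".(", pp_term(t$cont, 0L), ")")
      }
    }
  )
  prec <- switch(t$type, parallel = 1L, choice = 2L, call = 3L, prefix = 3L)
  if (prec < parent_prec) paste0("(", out, ")") else out
}

#' Pretty-print a term, action, set expression or model
#'
#' Renders a syntax tree back to canonical bcs source.  Re-parsing the
#' printed text yields a structurally identical tree.
#'
#' @param x A `bcs_model`, `bcs_term`, `bcs_action` or `bcs_set` object.
#' @return A single string of bcs source.
#' @export
bcs_pretty <- function(x) {
  if (inherits(x, "bcs_model")) {
    lines <- character()
    for (nm in names(x$consts)) {
      lines <- c(lines, sprintf("%s = %s", nm, fmt_num(x$consts[[nm]])))
    }
    for (d in x$defs) {
      lhs <- if (length(d$params)) {
        sprintf("%s[%s]", d$name, paste(d$params, collapse = ","))
      } else {
        d$name
      }
      lines <- c(lines, sprintf("%s = %s", lhs, pp_term(d$body)))
    }
    sys <- paste(sprintf("%s%s",
      ifelse(x$init$copies > 1L, paste0(x$init$copies, " * "), ""),
      vapply(seq_len(nrow(x$init)), function(k) {
        a <- x$init$args[[k]]
        if (length(a)) {
          sprintf("%s[%s]", x$init$process[[k]],
                  paste(vapply(a, fmt_num, character(1)), collapse = ","))
        } else {
          x$init$process[[k]]
        }
      }, character(1))), collapse = " || ")
    return(paste(c(lines, sys), collapse = "\n"))
  }
  if (inherits(x, "bcs_term")) return(pp_term(x))
  if (inherits(x, "bcs_action")) return(pp_action(x))
  if (inherits(x, "bcs_set")) return(pp_set(x))
  stop("bcs_pretty() expects a bcs_model, bcs_term, bcs_action or bcs_set",
       call. = FALSE)
}
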