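# Static analysis over syntax trees: free names, arity checking, model
# validation diagnostics.

`%||%` <- function(x, y) if (is.null(x)) y else x

expr_vars <- function(e) {
  if (is.numeric(e)) character(0) else all.vars(e)
}

set_vars <- function(s) {
  switch(s$op,
    single = expr_vars(s$value),
    range = union(expr_vars(s$lo), expr_vars(s$hi)),
    union(set_vars(s$lhs), set_vars(s$rhs))
  )
}

# names whose numeric value an action needs; a channel component that is a
# bare identifier may stay symbolic, so it is not counted as a value
# reference.  For receives, the binding variables are in scope for the
# action's own rate expression.
action_vars <- function(a) {
  vars <- character(0)
  if (a$kind == "local") return(expr_vars(a$rate))
  for (comp in a$channel) {
    if (!is.name(comp)) vars <- union(vars, expr_vars(comp))
  }
  for (p in a$payload %||% list()) vars <- union(vars, expr_vars(p))
  for (s in a$sets %||% list()) vars <- union(vars, set_vars(s))
  rate_vars <- expr_vars(a$rate)
  if (a$kind %in% c("hs_recv", "b_recv")) {
    rate_vars <- setdiff(rate_vars, a$bindings)
  }
  union(vars, rate_vars)
}

#' Free value references of a process term
#'
#' Returns every parameter, binding-variable or constant name whose numeric
#' value the term needs, excluding binding variables within their own scope
#' (a receive's bindings are visible in its rate expression and in its
#' continuation).  Process names in calls and bare symbolic channel names are
#' not value references and are not returned.
#'
#' @param term A `bcs_term` (or a string, parsed with [bcs_parse_term()]).
#' @return A character vector of names, sorted.
#' @examples
#' bcs_free_names("[i<5]->{inc,r}.A[i+1]")
#' @export
bcs_free_names <- function(term) {
  if (is.character(term)) term <- bcs_parse_term(term)
  sort(term_vars(term, character(0)))
}

term_vars <- function(t, bound) {
  switch(t$type,
    prefix = {
      vars <- setdiff(union(
        if (is.null(t$gate)) character(0) else expr_vars(t$gate),
        action_vars(t$action)
      ), bound)
      inner_bound <- union(bound, t$action$bindings %||% character(0))
      if (!is.null(t$cont)) vars <- union(vars, term_vars(t$cont, inner_bound))
      vars
    },
    choice = Reduce(union, lapply(t$branches, term_vars, bound = bound), character(0)),
    parallel = Reduce(union, lapply(t$comps, term_vars, bound = bound), character(0)),
    call = setdiff(Reduce(union, lapply(t$args, expr_vars), character(0)), bound)
  )
}

term_calls <- function(t) {
  switch(t$type,
    prefix = if (is.null(t$cont)) list() else term_calls(t$cont),
    choice = do.call(c, lapply(t$branches, term_calls)),
    parallel = do.call(c, lapply(t$comps, term_calls)),
    call = list(list(name = t$name, arity = length(t$args)))
  )
}

# handshake send/receive actions with a single all-symbolic channel name,
# for the static payload-length cross-check
term_hs_signatures <- function(t) {
  sigs <- list()
  walk <- function(t) {
    switch(t$type,
      prefix = {
        a <- t$action
        if (a$kind %in% c("hs_send", "hs_recv") &&
            all(vapply(a$channel, is.name, logical(1)))) {
          len <- if (a$kind == "hs_send") length(a$payload) else length(a$sets)
          sigs[[length(sigs) + 1L]] <<- list(
            channel = paste(vapply(a$channel, as.character, character(1)),
                            collapse = ","),
            n = len, kind = a$kind
          )
        }
        if (!is.null(t$cont)) walk(t$cont)
      },
      choice = for (b in t$branches) walk(b),
      parallel = for (p in t$comps) walk(p),
      call = invisible(NULL)
    )
  }
  walk(t)
  sigs
}

diag_row <- function(type, where, message) {
  tibble::tibble(type = type, where = where, message = message)
}

#' Validate a parsed model
#'
#' Performs the static checks of the calculus: every process call and every
#' initial-system entry must name a defined process with matching arity;
#' every value reference in a definition body must be a formal parameter, a
#' binding variable in scope, or a global constant; and handshake sends and
#' receives sharing a literal channel name must agree on payload length
#' (where both ends are statically known).
#'
#' @param model A `bcs_model`.
#' @return A tibble of diagnostics with columns `type`, `where`, `message`;
#'   zero rows means the model is well-formed.
#' @export
bcs_validate <- function(model) {
  stopifnot(inherits(model, "bcs_model"))
  out <- list()
  arities <- vapply(model$defs, function(d) length(d$params), integer(1))
  for (d in model$defs) {
    for (cl in term_calls(d$body)) {
      if (!(cl$name %in% names(model$defs))) {
        out[[length(out) + 1L]] <- diag_row(
          "unresolved-name", d$name,
          sprintf("call to undefined process '%s'", cl$name))
      } else if (cl$arity != arities[[cl$name]]) {
        out[[length(out) + 1L]] <- diag_row(
          "arity", d$name,
          sprintf("call to '%s' with %d argument(s); definition has %d parameter(s)",
                  cl$name, cl$arity, arities[[cl$name]]))
      }
    }
    unbound <- setdiff(term_vars(d$body, d$params), names(model$consts))
    for (v in unbound) {
      out[[length(out) + 1L]] <- diag_row(
        "unbound-name", d$name,
        sprintf("'%s' is not a parameter, binding variable or constant", v))
    }
  }
  for (k in seq_len(nrow(model$init))) {
    nm <- model$init$process[[k]]
    if (!(nm %in% names(model$defs))) {
      out[[length(out) + 1L]] <- diag_row(
        "unresolved-name", "system line",
        sprintf("initial process '%s' is not defined", nm))
    } else if (length(model$init$args[[k]]) != arities[[nm]]) {
      out[[length(out) + 1L]] <- diag_row(
        "arity", "system line",
        sprintf("initial process '%s' given %d argument(s); definition has %d",
                nm, length(model$init$args[[k]]), arities[[nm]]))
    }
  }
  sigs <- do.call(c, c(lapply(model$defs, function(d) term_hs_signatures(d$body)),
                       list(list())))
  if (length(sigs)) {
    by_chan <- split(sigs, vapply(sigs, `[[`, character(1), "channel"))
    for (chan in names(by_chan)) {
      lens <- unique(vapply(by_chan[[chan]], `[[`, integer(1), "n"))
      if (length(lens) > 1L) {
        out[[length(out) + 1L]] <- diag_row(
          "handshake-length", chan,
          sprintf("handshake payload lengths on channel '%s' disagree: %s",
                  chan, paste(sort(lens), collapse = " vs ")))
      }
    }
  }
  if (length(out)) dplyr::bind_rows(out) else diag_row(character(), character(), character())
}

#' @importFrom generics glance
#' @export
generics::glance

#' Model summary at a glance
#'
#' @param x A `bcs_model`.
#' @param ... Unused.
#' @return A one-row tibble with counts of constants, definitions, initial
#'   process copies, and validation diagnostics.
#' @export
glance.bcs_model <- function(x, ...) {
  tibble::tibble(
    n_constants = length(x$consts),
    n_definitions = length(x$defs),
    n_initial = sum(x$init$copies),
    n_diagnostics = nrow(bcs_validate(x))
  )
}
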