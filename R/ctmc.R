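# Explicit CTMC expansion.
#
# A rated process-algebra model denotes a continuous-time Markov chain whose
# states are (multiset of process instances, active beacons) and whose
# transition rates are the candidate rates.  For models with a small
# reachable state space the chain can be built exhaustively and solved by
# linear algebra; the test-suite uses this as an independent oracle for the
# stochastic simulator (holding-time means, transition probabilities,
# stationary and absorption quantities).

copy_env_shallow <- function(e) {
  out <- new.env(parent = emptyenv())
  for (nm in ls(e)) assign(nm, e[[nm]], envir = out)
  out
}

copy_env_nested <- function(e) {
  out <- new.env(parent = emptyenv())
  for (nm in ls(e)) assign(nm, copy_env_shallow(e[[nm]]), envir = out)
  out
}

copy_state <- function(st) {
  st2 <- new.env(parent = emptyenv())
  st2$model <- st$model
  st2$consts <- st$consts
  st2$time <- st$time
  st2$nsteps <- st$nsteps
  st2$next_id <- st$next_id
  st2$tick <- st$tick
  st2$insts <- copy_env_shallow(st$insts)
  st2$beacons <- copy_env_nested(st$beacons)
  st2$hs_send_idx <- copy_env_nested(st$hs_send_idx)
  st2$hs_recv_idx <- copy_env_nested(st$hs_recv_idx)
  st2$bsub_idx <- copy_env_nested(st$bsub_idx)
  st2$cand_by_inst <- copy_env_shallow(st$cand_by_inst)
  st2$cp_cap <- st$cp_cap
  st2$cp_top <- st$cp_top
  st2$cp_free <- st$cp_free
  st2$cp_cand <- st$cp_cand
  st2$cp_rate <- st$cp_rate
  st2$cp_key <- st$cp_key
  st2$cp_active <- st$cp_active
  # the copy keeps no event history
  st2$ev_cap <- 64L
  st2$ev_n <- 0L
  st2$ev_time <- numeric(64L)
  st2$ev_action <- character(64L)
  st2$ev_process <- character(64L)
  st2$ev_params <- vector("list", 64L)
  st2
}

env_sig <- function(st, env) {
  keep <- setdiff(names(env), names(st$model$consts))
  keep <- sort(keep)
  if (length(keep) == 0L) return("")
  paste(sprintf("%s=%s", keep,
                vapply(env[keep], function(v) fmt_num(as.numeric(v)), character(1))),
        collapse = ",")
}

inst_sig <- function(st, inst) {
  sprintf("%s{%s}<%s>", inst$defname, env_sig(st, inst$env), pp_term(inst$term))
}

state_key <- function(st) {
  isigs <- sort(vapply(ls(st$insts), function(k) inst_sig(st, st$insts[[k]]),
                       character(1)))
  bsigs <- character(0)
  for (ck in sort(ls(st$beacons))) {
    pks <- sort(ls(st$beacons[[ck]]))
    if (length(pks)) bsigs <- c(bsigs, sprintf("%s=[%s]", ck, paste(pks, collapse = ";")))
  }
  paste(c(paste(isigs, collapse = " | "), paste(bsigs, collapse = " ")), collapse = " ## ")
}

#' Build the explicit CTMC of a model
#'
#' Exhaustively expands the reachable state space of a model by repeatedly
#' enumerating and applying every enabled candidate, producing the states
#' and the transition-rate edges of the continuous-time Markov chain the
#' model denotes.  Intended for small models (test oracles, inspection);
#' expansion stops with an error if more than `state_bound` states are
#' reachable.
#'
#' @param model A `bcs_model` or bcs source text.
#' @param state_bound Maximum number of states to expand.
#' @return A `bcs_ctmc`: list with `states` (character signatures),
#'   `transitions` (tibble `from`, `to`, `rate`, `action`), and `initial`
#'   (index of the initial state).
#' @seealso [bcs_ctmc_generator()], [bcs_ctmc_stationary()],
#'   [bcs_ctmc_absorption_times()]
#' @examples
#' ctmc <- bcs_ctmc("P = {a,1} + {b,3}\nP")
#' ctmc$transitions
#' @export
bcs_ctmc <- function(model, state_bound = 5000L) {
  if (is.character(model)) model <- bcs_parse(model)
  st0 <- init_state(model)
  key0 <- state_key(st0)
  states <- key0
  index <- new.env(parent = emptyenv())
  index[[key0]] <- 1L
  frontier <- list(st0)
  from <- integer(0)
  to <- integer(0)
  rate <- numeric(0)
  action <- character(0)
  while (length(frontier) > 0L) {
    st <- frontier[[1L]]
    frontier <- frontier[-1L]
    i <- index[[state_key(st)]]
    slots <- active_slots(st)
    slots <- slots[order(st$cp_key[slots])]
    for (s in slots) {
      cand <- st$cp_cand[[s]]
      st2 <- copy_state(st)
      apply_candidate(st2, s, st$time)
      k2 <- state_key(st2)
      j <- index[[k2]]
      if (is.null(j)) {
        states <- c(states, k2)
        j <- length(states)
        if (j > state_bound) {
          stop(sprintf("reachable state space exceeds state_bound = %d", state_bound),
               call. = FALSE)
        }
        index[[k2]] <- j
        frontier[[length(frontier) + 1L]] <- st2
      }
      from <- c(from, i)
      to <- c(to, j)
      rate <- c(rate, cand$rate)
      action <- c(action, paste(cand$labels, collapse = " & "))
    }
  }
  structure(
    list(states = states,
         transitions = tibble::tibble(from = from, to = to, rate = rate,
                                      action = action),
         initial = 1L),
    class = "bcs_ctmc"
  )
}

#' @export
print.bcs_ctmc <- function(x, ...) {
  cat(sprintf("<bcs_ctmc> %d state(s), %d transition(s)\n",
              length(x$states), nrow(x$transitions)))
  invisible(x)
}

#' Transitions of an explicit CTMC as a tibble
#'
#' @param x A `bcs_ctmc`.
#' @param ... Unused.
#' @return The transition tibble with state signatures attached.
#' @export
tidy.bcs_ctmc <- function(x, ...) {
  dplyr::mutate(x$transitions,
                from_state = x$states[from],
                to_state = x$states[to])
}

#' @rdname bcs_ctmc
#' @param x A `bcs_ctmc`.
#' @param ... Unused.
#' @export
glance.bcs_ctmc <- function(x, ...) {
  Q <- bcs_ctmc_generator(x)
  tibble::tibble(
    n_states = length(x$states),
    n_transitions = nrow(x$transitions),
    n_absorbing = sum(abs(diag(Q)) < .Machine$double.eps)
  )
}

#' Generator matrix of an explicit CTMC
#'
#' @param ctmc A `bcs_ctmc`.
#' @return The dense generator matrix Q (off-diagonal rates, rows summing
#'   to zero).
#' @export
bcs_ctmc_generator <- function(ctmc) {
  n <- length(ctmc$states)
  if (n > 3000L) stop("generator matrix would be too large; use the transition tibble",
                      call. = FALSE)
  Q <- matrix(0, n, n)
  tr <- ctmc$transitions
  for (k in seq_len(nrow(tr))) {
    Q[tr$from[[k]], tr$to[[k]]] <- Q[tr$from[[k]], tr$to[[k]]] + tr$rate[[k]]
  }
  diag(Q) <- diag(Q) - rowSums(Q)
  Q
}

#' Stationary distribution of an irreducible explicit CTMC
#'
#' Solves pi Q = 0 with pi summing to one.
#'
#' @param ctmc A `bcs_ctmc` whose chain is irreducible.
#' @return A numeric vector of stationary probabilities over `ctmc$states`.
#' @export
bcs_ctmc_stationary <- function(ctmc) {
  Q <- bcs_ctmc_generator(ctmc)
  n <- nrow(Q)
  A <- rbind(t(Q), rep(1, n))
  b <- c(numeric(n), 1)
  pi <- stats::setNames(as.numeric(qr.solve(A, b)), ctmc$states)
  pi
}

#' Expected absorption times of an explicit CTMC
#'
#' For every transient state, the expected time until the chain reaches any
#' absorbing state (a state with no outgoing transition), by solving the
#' linear first-passage system on the generator.
#'
#' @param ctmc A `bcs_ctmc` with at least one absorbing state.
#' @return A named numeric vector over states (0 for absorbing states).
#' @export
bcs_ctmc_absorption_times <- function(ctmc) {
  Q <- bcs_ctmc_generator(ctmc)
  absorbing <- abs(diag(Q)) < .Machine$double.eps
  if (!any(absorbing)) stop("chain has no absorbing state", call. = FALSE)
  tt <- which(!absorbing)
  tau <- numeric(length(ctmc$states))
  if (length(tt)) {
    tau[tt] <- solve(Q[tt, tt, drop = FALSE], rep(-1, length(tt)))
  }
  stats::setNames(tau, ctmc$states)
}

#' Expected first-passage times to a set of states
#'
#' For every state outside the target set, the expected time until the
#' chain first enters the target set, by a linear solve on the generator
#' restricted to the non-target states.
#'
#' @param ctmc A `bcs_ctmc`.
#' @param target Either integer state indices or a predicate function over
#'   state signature strings selecting the target set.
#' @return A named numeric vector over states (0 on the target set).
#' @export
bcs_ctmc_first_passage <- function(ctmc, target) {
  n <- length(ctmc$states)
  if (is.function(target)) {
    target <- which(vapply(ctmc$states, target, logical(1)))
  }
  target <- as.integer(target)
  if (length(target) == 0L) stop("empty target set", call. = FALSE)
  Q <- bcs_ctmc_generator(ctmc)
  tt <- setdiff(seq_len(n), target)
  tau <- numeric(n)
  if (length(tt)) {
    tau[tt] <- solve(Q[tt, tt, drop = FALSE], rep(-1, length(tt)))
  }
  stats::setNames(tau, ctmc$states)
}

# ---- audit: incremental candidate pool vs full re-enumeration --------------

pool_signature <- function(st) {
  slots <- active_slots(st)
  sort(vapply(slots, function(s) {
    cand <- st$cp_cand[[s]]
    sprintf("%s|%.12g|%s|%s", cand$kind, cand$rate,
            paste(sort(cand$labels), collapse = "+"),
            paste(sort(cand$procs), collapse = "+"))
  }, character(1)))
}

# rebuild the candidate set of st's instances and beacons from scratch in a
# fresh state and return its signature
fresh_signature <- function(st) {
  st2 <- new_state(st$model)
  for (ck in ls(st$beacons)) {
    store <- new.env(parent = emptyenv())
    for (pk in ls(st$beacons[[ck]])) store[[pk]] <- st$beacons[[ck]][[pk]]
    st2$beacons[[ck]] <- store
  }
  for (k in ls(st$insts)) {
    inst <- st$insts[[k]]
    create_instance(st2, inst$term, inst$env, inst$defname)
  }
  pool_signature(st2)
}

# run a simulation, checking after every transition that the incrementally
# maintained candidate pool equals a full re-enumeration (testing hook)
audit_simulate <- function(model, seed = 1L, max_transitions = 100L) {
  if (is.character(model)) model <- bcs_parse(model)
  set.seed(as.integer(seed))
  st <- init_state(model)
  step <- 0L
  repeat {
    sig_inc <- pool_signature(st)
    sig_full <- fresh_signature(st)
    if (!identical(sig_inc, sig_full)) {
      stop(sprintf(
        "candidate pool diverged from full re-enumeration at step %d:\nincremental: %s\nfull: %s",
        step, paste(sig_inc, collapse = " ; "), paste(sig_full, collapse = " ; ")),
        call. = FALSE)
    }
    slots <- active_slots(st)
    if (length(slots) == 0L || step >= max_transitions) break
    rates <- st$cp_rate[slots]
    total <- sum(rates)
    dt <- -log(stats::runif(1L)) / total
    u2 <- stats::runif(1L)
    ord <- order(st$cp_key[slots])
    slots <- slots[ord]
    cum <- cumsum(st$cp_rate[slots])
    j <- findInterval(u2 * total, cum, left.open = TRUE) + 1L
    if (j > length(slots)) j <- length(slots)
    apply_candidate(st, slots[[j]], st$time + dt)
    step <- step + 1L
  }
  step
}
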