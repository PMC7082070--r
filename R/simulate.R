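# Exact stochastic simulation over the candidate pool.
#
# Each step draws exactly two uniforms: one for the exponential waiting time
# at the total propensity, one for candidate selection proportional to rate,
# taken over candidates in canonical order (instance id, then action
# position, then creation order).  Identical (model, seed, replicate) runs
# therefore produce byte-identical logs.

#' Simulate a Beacon Calculus model
#'
#' Runs one exact stochastic simulation of the continuous-time Markov chain
#' a model denotes.  At every step the enabled candidates are the gated-true
#' local actions, beacon launches/kills, matched handshake send/receive
#' pairs (rate = send rate x receive rate), receivable active beacons, and
#' beacon checks with no matching active beacon.  The waiting time is drawn
#' from an exponential at the total rate and a candidate is chosen with
#' probability proportional to its rate.  The run stops when no candidate is
#' enabled (every remaining process is deadlocked), when `max_transitions`
#' events have been performed, or when the clock would pass `max_time`.
#'
#' @param model A `bcs_model` from [bcs_parse()], or bcs source text.
#' @param seed Integer seed; the same seed reproduces the same log exactly.
#' @param max_transitions Cap on the number of transitions (default `1e6`).
#' @param max_time Optional cap on simulated time (default `Inf`).
#' @param replicate Replicate index recorded on the log (default 1).
#' @return A `bcs_eventlog`: a tibble with columns `time`, `action`,
#'   `process` and `params` (list column of parameter values at the moment
#'   of the action), sorted by ascending time, one row per participating
#'   process (a handshake writes two rows at the same time).  Attributes:
#'   `termination` (`"deadlocked"`, `"cap"` or `"time"`), `final_state`
#'   (tibble of surviving process instances; at deadlock these are exactly
#'   the processes removed as deadlocked), `final_beacons`, `seed`,
#'   `replicate`.
#' @examples
#' m <- bcs_parse("
#'   r = 1
#'   A[i,j] = [i<5 & j<10]->{changeParameters,r}.A[i+1,2*j]
#'   A[0,1]
#' ")
#' log <- bcs_simulate(m, seed = 1)
#' log
#' bcs_final_state(log)
#' @export
bcs_simulate <- function(model, seed = 1L, max_transitions = 1e6,
                         max_time = Inf, replicate = 1L) {
  if (is.character(model)) model <- bcs_parse(model)
  stopifnot(inherits(model, "bcs_model"))
  if (max_transitions < 1) stop("max_transitions must be >= 1", call. = FALSE)
  if (!isTRUE(attr(model, "validated"))) {
    diags <- bcs_validate(model)
    if (nrow(diags) > 0L) {
      stop(paste(c("model failed validation:",
                   sprintf("  [%s] %s: %s", diags$type, diags$where, diags$message)),
                 collapse = "\n"), call. = FALSE)
    }
  }
  set.seed(as.integer(seed))
  st <- init_state(model)
  termination <- "deadlocked"
  repeat {
    slots <- active_slots(st)
    if (length(slots) == 0L) {
      termination <- "deadlocked"
      break
    }
    if (st$nsteps >= max_transitions) {
      termination <- "cap"
      break
    }
    rates <- st$cp_rate[slots]
    total <- sum(rates)
    dt <- -log(stats::runif(1L)) / total
    u2 <- stats::runif(1L)
    if (st$time + dt > max_time) {
      st$time <- max_time
      termination <- "time"
      break
    }
    ord <- order(st$cp_key[slots])
    slots <- slots[ord]
    cum <- cumsum(st$cp_rate[slots])
    j <- findInterval(u2 * total, cum, left.open = TRUE) + 1L
    if (j > length(slots)) j <- length(slots)
    apply_candidate(st, slots[[j]], st$time + dt)
  }
  n <- st$ev_n
  log <- tibble::tibble(
    time = st$ev_time[seq_len(n)],
    action = st$ev_action[seq_len(n)],
    process = st$ev_process[seq_len(n)],
    params = st$ev_params[seq_len(n)]
  )
  structure(log,
            class = c("bcs_eventlog", class(log)),
            termination = termination,
            final_state = state_instances(st),
            final_beacons = state_beacons(st),
            seed = as.integer(seed),
            replicate = as.integer(replicate))
}

#' Run replicate simulations
#'
#' Replicate `r` is simulated with seed `seed + r - 1`, so a batch is fully
#' reproducible from its base seed and replicates are independent.
#'
#' @inheritParams bcs_simulate
#' @param replicates Number of independent replicates.
#' @return A list of `bcs_eventlog`s (class `bcs_batch`).
#' @export
bcs_run_batch <- function(model, replicates = 1L, seed = 1L,
                          max_transitions = 1e6, max_time = Inf) {
  if (is.character(model)) model <- bcs_parse(model)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  if (!isTRUE(attr(model, "validated"))) {
    diags <- bcs_validate(model)
    if (nrow(diags) > 0L) {
      stop(paste(c("model failed validation:",
                   sprintf("  [%s] %s: %s", diags$type, diags$where, diags$message)),
                 collapse = "\n"), call. = FALSE)
    }
    attr(model, "validated") <- TRUE
  }
  out <- lapply(seq_len(replicates), function(r) {
    bcs_simulate(model, seed = seed + r - 1L, max_transitions = max_transitions,
                 max_time = max_time, replicate = r)
  })
  structure(out, class = "bcs_batch")
}

#' Final system state of a simulation
#'
#' @param log A `bcs_eventlog` from [bcs_simulate()].
#' @return A tibble of the process instances present when the run stopped
#'   (columns `id`, `process`, `params`, `n_candidates`); at deadlock these
#'   are the instances removed from the system because no action remained.
#' @export
bcs_final_state <- function(log) {
  stopifnot(inherits(log, "bcs_eventlog"))
  attr(log, "final_state")
}

#' Active beacons at the end of a simulation
#'
#' @inheritParams bcs_final_state
#' @return A tibble with columns `channel` and `payload`.
#' @export
bcs_final_beacons <- function(log) {
  stopifnot(inherits(log, "bcs_eventlog"))
  attr(log, "final_beacons")
}

#' Termination condition of a simulation
#'
#' @inheritParams bcs_final_state
#' @return `"deadlocked"`, `"cap"` or `"time"`.
#' @export
bcs_termination <- function(log) {
  stopifnot(inherits(log, "bcs_eventlog"))
  attr(log, "termination")
}

#' @export
print.bcs_eventlog <- function(x, ...) {
  cat(sprintf("<bcs_eventlog> %d event(s), t = 0 .. %s, stopped: %s (seed %d, replicate %d)\n",
              nrow(x),
              if (nrow(x)) format(max(x$time), digits = 6) else "0",
              attr(x, "termination"), attr(x, "seed"), attr(x, "replicate")))
  NextMethod()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' Event log as a plain tibble
#'
#' @param x A `bcs_eventlog`.
#' @param ... Unused.
#' @return The event table as a tibble without simulation attributes.
#' @export
tidy.bcs_eventlog <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("time", "action", "process", "params")])
}

#' One-row summary of a simulation
#'
#' @param x A `bcs_eventlog`.
#' @param ... Unused.
#' @return A tibble with the event count, duration, termination condition
#'   and number of surviving instances.
#' @export
glance.bcs_eventlog <- function(x, ...) {
  tibble::tibble(
    n_events = nrow(x),
    duration = if (nrow(x)) max(x$time) else 0,
    termination = attr(x, "termination"),
    n_final_instances = nrow(attr(x, "final_state")),
    n_final_beacons = nrow(attr(x, "final_beacons")),
    seed = attr(x, "seed"),
    replicate = attr(x, "replicate")
  )
}

#' Enabled transitions of a model's initial state
#'
#' Enumerates the candidate transitions of the system's initial state:
#' useful for inspecting what a model can do first, and used by the explicit
#' CTMC expander.
#'
#' @param model A `bcs_model` or bcs source text.
#' @return A tibble with columns `kind`, `rate`, `action`, `instances`,
#'   `processes`.
#' @export
bcs_initial_candidates <- function(model) {
  if (is.character(model)) model <- bcs_parse(model)
  st <- init_state(model)
  state_candidates(st)
}
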