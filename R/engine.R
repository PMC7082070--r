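# Operational semantics and runtime state.
#
# A live system is a multiset of process instances (each a term plus an
# environment of parameter values), a store of active beacons, and a clock.
# For every instance we extract its *derivatives* once at creation time: the
# (gate, action, continuation) triples it can currently offer.  Because an
# instance's environment never changes in place (parameters only change
# through recursion, which replaces the instance), gates, local rates,
# evaluated channel identities, payloads and receive sets are all fixed per
# instance and are cached on the derivative.
#
# The enabled-candidate set is maintained incrementally in a flat pool:
#   - local actions, beacon launches and kills: one candidate per derivative;
#   - handshakes: one candidate per (sender instance, receiver instance)
#     pair with matching channel identity and member-wise payload membership,
#     at rate (send rate) * (receive rate with bindings set to the payload);
#   - beacon receives: one candidate per (instance, matching active beacon);
#   - beacon checks: one candidate iff no matching beacon is active.
# Applying a transition invalidates exactly the candidates touching the
# participating instances, plus (when the beacon store changed) the
# beacon-dependent candidates on the affected channel.  This is behaviourally
# identical to full re-enumeration after every transition, which the
# brute-force CTMC expander in the test-suite checks directly.

DEPTH_LIMIT <- 1000L

new_state <- function(model) {
  st <- new.env(parent = emptyenv())
  st$model <- model
  st$consts <- as.list(model$consts)
  st$time <- 0
  st$nsteps <- 0L
  st$next_id <- 1L
  st$tick <- 0
  st$insts <- new.env(parent = emptyenv())
  st$beacons <- new.env(parent = emptyenv())
  st$hs_send_idx <- new.env(parent = emptyenv())
  st$hs_recv_idx <- new.env(parent = emptyenv())
  st$bsub_idx <- new.env(parent = emptyenv())
  st$cand_by_inst <- new.env(parent = emptyenv())
  # candidate pool (flat, slot-reusing)
  st$cp_cap <- 256L
  st$cp_top <- 0L
  st$cp_free <- integer(0)
  st$cp_cand <- vector("list", 256L)
  st$cp_rate <- numeric(256L)
  st$cp_key <- numeric(256L)
  st$cp_active <- logical(256L)
  # event log (grown by doubling)
  st$ev_cap <- 1024L
  st$ev_n <- 0L
  st$ev_time <- numeric(1024L)
  st$ev_action <- character(1024L)
  st$ev_process <- character(1024L)
  st$ev_params <- vector("list", 1024L)
  st
}

# ---- derivative extraction -------------------------------------------------

compress_set_display <- function(v) {
  if (length(v) == 0L) return("")
  if (length(v) == 1L) return(fmt_num(v))
  if (all(diff(v) == 1)) return(sprintf("%s..%s", fmt_num(v[1L]), fmt_num(v[length(v)])))
  paste(vapply(v, fmt_num, character(1)), collapse = " U ")
}

# Derivatives of a (term, env); `pos` numbers the action positions for the
# canonical candidate order.  Each derivative carries the threads its
# continuation activates; `bind` marks the thread that receives binding
# variables.
ders_of <- function(st, term, env, defname, depth = 0L) {
  if (depth > DEPTH_LIMIT) {
    stop(sprintf("process '%s' unfolds without performing an action (recursive call cycle?)",
                 defname), call. = FALSE)
  }
  pos <- 0L
  out <- list()
  emit <- function(d) {
    pos <<- pos + 1L
    d$pos <- pos
    out[[length(out) + 1L]] <<- d
  }
  walk <- function(t, env, wrap_threads, depth) {
    switch(t$type,
      prefix = {
        if (!is.null(t$gate) &&
            !bcs_eval_gate(t$gate, env, sprintf("gate in '%s'", defname))) {
          return(invisible(NULL))
        }
        a <- t$action
        own <- if (is.null(t$cont)) {
          list()
        } else {
          list(list(term = t$cont, env = env, bind = TRUE))
        }
        threads <- c(own, wrap_threads)
        d <- list(kind = a$kind, threads = threads, env = env)
        what <- sprintf("rate of %s action in '%s'",
                        if (a$kind == "local") sprintf("'%s'", a$label) else a$kind,
                        defname)
        if (a$kind == "local") {
          d$label <- a$label
          d$rate <- bcs_eval_rate(a$rate, env, what)
        } else {
          d$chanKey <- eval_channel_key(a$channel, env,
                                        sprintf("channel in '%s'", defname))
          if (a$kind %in% c("hs_send", "b_launch", "b_kill")) {
            d$payload <- vapply(a$payload, bcs_eval_expr, numeric(1), env = env,
                                what = sprintf("payload in '%s'", defname))
            d$rate <- bcs_eval_rate(a$rate, env, what)
            sig <- switch(a$kind, hs_send = "!", b_launch = "!", b_kill = "#")
            pre <- if (a$kind == "hs_send") "@" else ""
            d$label <- sprintf("%s%s%s[%s]", pre, channel_display(d$chanKey), sig,
                               paste(vapply(d$payload, fmt_num, character(1)),
                                     collapse = ","))
          } else {
            d$sets <- lapply(a$sets, eval_set_node, env = env,
                             what = sprintf("receive set in '%s'", defname))
            d$bindings <- a$bindings
            d$rate_expr <- a$rate
            d$rate_what <- what
            if (a$kind == "b_check") {
              d$rate <- bcs_eval_rate(a$rate, env, what)
              d$label <- sprintf("~%s?[%s]", channel_display(d$chanKey),
                                 paste(vapply(d$sets, compress_set_display,
                                              character(1)), collapse = ","))
            }
          }
        }
        emit(d)
      },
      choice = for (b in t$branches) walk(b, env, wrap_threads, depth),
      parallel = {
        for (k in seq_along(t$comps)) {
          others <- t$comps[-k]
          extra <- lapply(others, function(o) list(term = o, env = env, bind = FALSE))
          walk(t$comps[[k]], env, c(wrap_threads, extra), depth)
        }
      },
      call = {
        uf <- unfold_call(st, t, env)
        walk(uf$term, uf$env, wrap_threads, depth + 1L)
      }
    )
  }
  walk(term, env, list(), depth)
  out
}

unfold_call <- function(st, t, env) {
  def <- st$model$defs[[t$name]]
  if (is.null(def)) {
    stop(sprintf("call to undefined process '%s'", t$name), call. = FALSE)
  }
  if (length(t$args) != length(def$params)) {
    stop(sprintf("call to '%s' with %d argument(s); definition has %d parameter(s)",
                 t$name, length(t$args), length(def$params)), call. = FALSE)
  }
  vals <- lapply(t$args, bcs_eval_expr, env = env,
                 what = sprintf("argument of '%s'", t$name))
  new_env <- st$consts
  new_env[def$params] <- vals
  list(term = def$body, env = new_env, defname = def$name)
}

# ---- instances -------------------------------------------------------------

inst_params <- function(st, defname, env) {
  def <- st$model$defs[[defname]]
  if (is.null(def) || length(def$params) == 0L) return(numeric(0))
  unname(vapply(def$params, function(p) as.numeric(env[[p]]), numeric(1)))
}

# Turn a continuation thread into zero or more new instances: parallel
# components split, calls unfold (changing the originating definition name),
# and an absent continuation activates nothing.
activate_thread <- function(st, term, env, defname, depth = 0L) {
  if (is.null(term)) return(invisible(NULL))
  if (depth > DEPTH_LIMIT) {
    stop("process unfolds without performing an action (recursive call cycle?)",
         call. = FALSE)
  }
  switch(term$type,
    parallel = {
      for (comp in term$comps) activate_thread(st, comp, env, defname, depth + 1L)
    },
    call = {
      uf <- unfold_call(st, term, env)
      activate_thread(st, uf$term, uf$env, uf$defname, depth + 1L)
    },
    {
      create_instance(st, term, env, defname)
    }
  )
  invisible(NULL)
}

create_instance <- function(st, term, env, defname) {
  id <- st$next_id
  st$next_id <- id + 1L
  ders <- ders_of(st, term, env, defname)
  inst <- list(
    id = id, defname = defname, term = term, env = env,
    params = inst_params(st, defname, env),
    ders = ders,
    hs_send_chans = character(0), hs_recv_chans = character(0),
    bsub_chans = character(0)
  )
  key <- as.character(id)
  # register communication indices
  for (d in ders) {
    if (d$kind == "hs_send") {
      idx_add(st$hs_send_idx, d$chanKey, key)
      inst$hs_send_chans <- union(inst$hs_send_chans, d$chanKey)
    } else if (d$kind == "hs_recv") {
      idx_add(st$hs_recv_idx, d$chanKey, key)
      inst$hs_recv_chans <- union(inst$hs_recv_chans, d$chanKey)
    } else if (d$kind %in% c("b_recv", "b_check")) {
      idx_add(st$bsub_idx, d$chanKey, key)
      inst$bsub_chans <- union(inst$bsub_chans, d$chanKey)
    }
  }
  assign(key, inst, envir = st$insts)
  st$cand_by_inst[[key]] <- integer(0)
  add_inst_candidates(st, inst)
  invisible(id)
}

idx_add <- function(idx, chanKey, key) {
  e <- idx[[chanKey]]
  if (is.null(e)) {
    e <- new.env(parent = emptyenv())
    idx[[chanKey]] <- e
  }
  e[[key]] <- TRUE
}

idx_del <- function(idx, chanKey, key) {
  e <- idx[[chanKey]]
  if (!is.null(e) && !is.null(e[[key]])) rm(list = key, envir = e)
}

idx_keys <- function(idx, chanKey) {
  e <- idx[[chanKey]]
  if (is.null(e)) character(0) else ls(e)
}

# ---- candidate pool --------------------------------------------------------

pool_grow <- function(st) {
  new_cap <- st$cp_cap * 2L
  length(st$cp_cand) <- new_cap
  st$cp_rate <- c(st$cp_rate, numeric(st$cp_cap))
  st$cp_key <- c(st$cp_key, numeric(st$cp_cap))
  st$cp_active <- c(st$cp_active, logical(st$cp_cap))
  st$cp_cap <- new_cap
}

pool_add <- function(st, cand) {
  if (length(st$cp_free)) {
    slot <- st$cp_free[[length(st$cp_free)]]
    st$cp_free <- st$cp_free[-length(st$cp_free)]
  } else {
    if (st$cp_top >= st$cp_cap) pool_grow(st)
    st$cp_top <- st$cp_top + 1L
    slot <- st$cp_top
  }
  st$tick <- st$tick + 1
  st$cp_cand[[slot]] <- cand
  st$cp_rate[[slot]] <- cand$rate
  # canonical order: (owning instance id, action position, creation order)
  st$cp_key[[slot]] <- cand$insts[[1L]] * 1e8 + cand$pos * 1e4 + (st$tick %% 1e4)
  st$cp_active[[slot]] <- TRUE
  for (iid in cand$insts) {
    key <- as.character(iid)
    st$cand_by_inst[[key]] <- c(st$cand_by_inst[[key]], slot)
  }
  slot
}

pool_deactivate <- function(st, slot) {
  if (!st$cp_active[[slot]]) return(invisible(NULL))
  st$cp_active[[slot]] <- FALSE
  st$cp_rate[[slot]] <- 0
  cand <- st$cp_cand[[slot]]
  for (iid in cand$insts) {
    key <- as.character(iid)
    lst <- st$cand_by_inst[[key]]
    if (!is.null(lst)) st$cand_by_inst[[key]] <- lst[lst != slot]
  }
  st$cp_cand[slot] <- list(NULL)
  st$cp_free <- c(st$cp_free, slot)
  invisible(NULL)
}

# ---- candidate construction ------------------------------------------------

payload_in_sets <- function(payload, sets) {
  if (length(payload) != length(sets)) return(FALSE)
  for (k in seq_along(payload)) {
    if (!(payload[[k]] %in% sets[[k]])) return(FALSE)
  }
  TRUE
}

beacon_payloads <- function(st, chanKey) {
  e <- st$beacons[[chanKey]]
  if (is.null(e)) list() else as.list(e)
}

beacon_matches <- function(st, chanKey, sets) {
  out <- list()
  for (p in beacon_payloads(st, chanKey)) {
    if (payload_in_sets(p, sets)) out[[length(out) + 1L]] <- p
  }
  out
}

recv_rate <- function(d, payload) {
  env <- d$env
  if (length(d$bindings)) env[d$bindings] <- as.list(payload)
  bcs_eval_rate(d$rate_expr, env, d$rate_what)
}

recv_label <- function(d, payload, handshake) {
  sprintf("%s%s?[%s]", if (handshake) "@" else "", channel_display(d$chanKey),
          paste(vapply(payload, fmt_num, character(1)), collapse = ","))
}

make_hs_candidate <- function(st, s_inst, s_der, r_inst, r_der) {
  if (s_inst$id == r_inst$id) return(invisible(NULL))
  if (!payload_in_sets(s_der$payload, r_der$sets)) return(invisible(NULL))
  rr <- recv_rate(r_der, s_der$payload)
  cand <- list(
    kind = "handshake",
    insts = c(s_inst$id, r_inst$id),
    pos = s_der$pos,
    rate = s_der$rate * rr,
    payload = s_der$payload,
    labels = c(s_der$label, recv_label(r_der, s_der$payload, TRUE)),
    procs = c(s_inst$defname, r_inst$defname),
    params = list(s_inst$params, r_inst$params),
    threads = c(s_der$threads,
                bind_threads(r_der$threads, r_der$bindings, s_der$payload)),
    defnames = c(rep(s_inst$defname, length(s_der$threads)),
                 rep(r_inst$defname, length(r_der$threads))),
    beacon = NULL
  )
  pool_add(st, cand)
}

bind_threads <- function(threads, bindings, payload) {
  if (length(bindings) == 0L) return(threads)
  lapply(threads, function(th) {
    if (isTRUE(th$bind)) th$env[bindings] <- as.list(payload)
    th
  })
}

make_simple_candidate <- function(st, inst, d, kind, payload = NULL,
                                  rate = d$rate, label = d$label) {
  beacon <- NULL
  if (kind == "beacon-launch") beacon <- list(op = "launch", chanKey = d$chanKey, payload = d$payload)
  if (kind == "beacon-kill") beacon <- list(op = "kill", chanKey = d$chanKey, payload = d$payload)
  threads <- if (!is.null(payload)) bind_threads(d$threads, d$bindings, payload) else d$threads
  cand <- list(
    kind = kind,
    insts = inst$id,
    pos = d$pos,
    rate = rate,
    labels = label,
    procs = inst$defname,
    params = list(inst$params),
    threads = threads,
    defnames = rep(inst$defname, length(threads)),
    beacon = beacon
  )
  pool_add(st, cand)
}

# beacon-dependent candidates (receives and checks) of one instance on one
# channel, built against the current beacon store
add_beacon_candidates <- function(st, inst, chanKey = NULL) {
  for (d in inst$ders) {
    if (!is.null(chanKey) && (is.null(d$chanKey) || d$chanKey != chanKey)) next
    if (d$kind == "b_recv") {
      for (p in beacon_matches(st, d$chanKey, d$sets)) {
        make_simple_candidate(st, inst, d, "beacon-receive", payload = p,
                              rate = recv_rate(d, p), label = recv_label(d, p, FALSE))
      }
    } else if (d$kind == "b_check") {
      if (length(beacon_matches(st, d$chanKey, d$sets)) == 0L) {
        make_simple_candidate(st, inst, d, "beacon-check")
      }
    }
  }
  invisible(NULL)
}

add_inst_candidates <- function(st, inst) {
  for (d in inst$ders) {
    switch(d$kind,
      local = make_simple_candidate(st, inst, d, "local"),
      b_launch = make_simple_candidate(st, inst, d, "beacon-launch"),
      b_kill = make_simple_candidate(st, inst, d, "beacon-kill"),
      hs_send = {
        for (rkey in idx_keys(st$hs_recv_idx, d$chanKey)) {
          r_inst <- st$insts[[rkey]]
          for (rd in r_inst$ders) {
            if (rd$kind == "hs_recv" && rd$chanKey == d$chanKey) {
              make_hs_candidate(st, inst, d, r_inst, rd)
            }
          }
        }
      },
      hs_recv = {
        for (skey in idx_keys(st$hs_send_idx, d$chanKey)) {
          s_inst <- st$insts[[skey]]
          for (sd in s_inst$ders) {
            if (sd$kind == "hs_send" && sd$chanKey == d$chanKey) {
              make_hs_candidate(st, s_inst, sd, inst, d)
            }
          }
        }
      },
      invisible(NULL)
    )
  }
  add_beacon_candidates(st, inst)
  invisible(NULL)
}

remove_instance <- function(st, id) {
  key <- as.character(id)
  inst <- st$insts[[key]]
  if (is.null(inst)) return(invisible(NULL))
  slots <- st$cand_by_inst[[key]]
  for (s in slots) pool_deactivate(st, s)
  for (ck in inst$hs_send_chans) idx_del(st$hs_send_idx, ck, key)
  for (ck in inst$hs_recv_chans) idx_del(st$hs_recv_idx, ck, key)
  for (ck in inst$bsub_chans) idx_del(st$bsub_idx, ck, key)
  rm(list = key, envir = st$insts)
  rm(list = key, envir = st$cand_by_inst)
  invisible(NULL)
}

# drop + rebuild the beacon-dependent candidates on one channel after the
# beacon store changed
refresh_beacon_channel <- function(st, chanKey) {
  for (key in idx_keys(st$bsub_idx, chanKey)) {
    inst <- st$insts[[key]]
    if (is.null(inst)) next
    slots <- st$cand_by_inst[[key]]
    for (s in slots) {
      cand <- st$cp_cand[[s]]
      if (!is.null(cand) && cand$kind %in% c("beacon-receive", "beacon-check")) {
        d <- inst$ders[[which(vapply(inst$ders, `[[`, integer(1), "pos") == cand$pos)]]
        if (!is.null(d$chanKey) && d$chanKey == chanKey) pool_deactivate(st, s)
      }
    }
    add_beacon_candidates(st, inst, chanKey)
  }
  invisible(NULL)
}

# ---- event logging ---------------------------------------------------------

log_event <- function(st, time, action, process, params) {
  n <- st$ev_n + 1L
  if (n > st$ev_cap) {
    st$ev_time <- c(st$ev_time, numeric(st$ev_cap))
    st$ev_action <- c(st$ev_action, character(st$ev_cap))
    st$ev_process <- c(st$ev_process, character(st$ev_cap))
    length(st$ev_params) <- st$ev_cap * 2L
    st$ev_cap <- st$ev_cap * 2L
  }
  st$ev_time[[n]] <- time
  st$ev_action[[n]] <- action
  st$ev_process[[n]] <- process
  st$ev_params[[n]] <- params
  st$ev_n <- n
}

# ---- applying a candidate --------------------------------------------------

apply_candidate <- function(st, slot, new_time) {
  cand <- st$cp_cand[[slot]]
  st$time <- new_time
  st$nsteps <- st$nsteps + 1L
  for (k in seq_along(cand$insts)) {
    log_event(st, new_time, cand$labels[[k]], cand$procs[[k]], cand$params[[k]])
  }
  threads <- cand$threads
  defnames <- cand$defnames
  beacon <- cand$beacon
  for (id in cand$insts) remove_instance(st, id)
  if (!is.null(beacon)) {
    ck <- beacon$chanKey
    pkey <- paste(vapply(beacon$payload, fmt_num, character(1)), collapse = ",")
    store <- st$beacons[[ck]]
    changed <- FALSE
    if (beacon$op == "launch") {
      if (is.null(store)) {
        store <- new.env(parent = emptyenv())
        st$beacons[[ck]] <- store
      }
      if (is.null(store[[pkey]])) {
        store[[pkey]] <- beacon$payload
        changed <- TRUE
      }
    } else {
      if (!is.null(store) && !is.null(store[[pkey]])) {
        rm(list = pkey, envir = store)
        changed <- TRUE
      }
    }
    if (changed) refresh_beacon_channel(st, ck)
  }
  for (k in seq_along(threads)) {
    th <- threads[[k]]
    activate_thread(st, th$term, th$env, defnames[[k]])
  }
  invisible(NULL)
}

# ---- state construction and views -----------------------------------------

init_state <- function(model) {
  st <- new_state(model)
  for (k in seq_len(nrow(model$init))) {
    nm <- model$init$process[[k]]
    def <- model$defs[[nm]]
    if (is.null(def)) {
      stop(sprintf("initial process '%s' is not defined", nm), call. = FALSE)
    }
    args <- model$init$args[[k]]
    if (length(args) != length(def$params)) {
      stop(sprintf("initial process '%s' given %d argument(s); definition has %d",
                   nm, length(args), length(def$params)), call. = FALSE)
    }
    env <- st$consts
    env[def$params] <- as.list(args)
    for (copy in seq_len(model$init$copies[[k]])) {
      activate_thread(st, def$body, env, nm)
    }
  }
  st
}

active_slots <- function(st) {
  which(st$cp_active[seq_len(st$cp_top)])
}

state_instances <- function(st) {
  keys <- ls(st$insts)
  insts <- lapply(keys, function(k) st$insts[[k]])
  ids <- vapply(insts, `[[`, integer(1), "id")
  ord <- order(ids)
  insts <- insts[ord]
  tibble::tibble(
    id = ids[ord],
    process = vapply(insts, `[[`, character(1), "defname"),
    params = lapply(insts, `[[`, "params"),
    n_candidates = vapply(insts, function(x) {
      length(st$cand_by_inst[[as.character(x$id)]])
    }, integer(1))
  )
}

state_beacons <- function(st) {
  out <- list()
  for (ck in ls(st$beacons)) {
    for (p in beacon_payloads(st, ck)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        channel = channel_display(ck),
        payload = list(p)
      )
    }
  }
  if (length(out)) dplyr::bind_rows(out) else {
    tibble::tibble(channel = character(), payload = list())
  }
}

# Enabled candidates of the current state as a tibble (inspection & oracle).
state_candidates <- function(st) {
  slots <- active_slots(st)
  slots <- slots[order(st$cp_key[slots])]
  cands <- st$cp_cand[slots]
  tibble::tibble(
    kind = vapply(cands, `[[`, character(1), "kind"),
    rate = vapply(cands, `[[`, numeric(1), "rate"),
    action = vapply(cands, function(cd) cd$labels[[1L]], character(1)),
    instances = lapply(cands, `[[`, "insts"),
    processes = lapply(cands, `[[`, "procs")
  )
}
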