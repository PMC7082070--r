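# Figure-level summary statistics computed from event logs: replication
# timing profiles, per-cell Ada/meAda traces for the growing-population
# damage model, and phosphorylation dose-response curves.

as_log_list <- function(logs) {
  if (inherits(logs, "bcs_eventlog")) return(list(logs))
  if (inherits(logs, "bcs_batch") || is.list(logs)) return(logs)
  stop("expected a bcs_eventlog, bcs_batch or list of event logs", call. = FALSE)
}

# ---- replication timing ----------------------------------------------------

launch_times <- function(log, channel = "chr") {
  re <- sprintf("^%s!\\[(-?[0-9]+)\\]$", channel)
  hit <- grepl(re, log$action)
  tibble::tibble(
    position = as.integer(sub(re, "\\1", log$action[hit])),
    time = log$time[hit]
  )
}

#' Replication timing profile
#'
#' For each chromosomal position, the mean time at which it was replicated
#' (the time of its `chr` beacon launch) across replicate simulations,
#' together with the standard error of the mean.  Positions not replicated
#' in every replicate are flagged (`complete = FALSE`); with a single
#' replicate the SEM is undefined and returned as `NA`.
#'
#' @param logs A `bcs_batch` (or list of event logs, or a single log) from a
#'   replication fixture.
#' @param L Chromosome length in positions.
#' @param channel Beacon channel carrying replicated positions.
#' @return A `bcs_timing_profile` tibble with columns `position`,
#'   `mean_time`, `sem`, `n_replicates`, `complete`.
#' @export
bcs_replication_timing <- function(logs, L, channel = "chr") {
  logs <- as_log_list(logs)
  n_logs <- length(logs)
  if (n_logs == 0L) stop("no event logs supplied", call. = FALSE)
  per_rep <- lapply(seq_along(logs), function(r) {
    lt <- launch_times(logs[[r]], channel)
    lt <- dplyr::slice_min(dplyr::group_by(lt, position), time, n = 1L,
                           with_ties = FALSE)
    dplyr::mutate(dplyr::ungroup(lt), replicate = r)
  })
  all_times <- dplyr::bind_rows(per_rep)
  prof <- dplyr::summarise(
    dplyr::group_by(all_times, position),
    mean_time = mean(time),
    sem = if (dplyr::n() > 1L) stats::sd(time) / sqrt(dplyr::n()) else NA_real_,
    n_replicates = dplyr::n(),
    .groups = "drop"
  )
  prof <- dplyr::left_join(tibble::tibble(position = seq_len(L)), prof,
                           by = "position")
  prof$n_replicates[is.na(prof$n_replicates)] <- 0L
  prof$complete <- prof$n_replicates == n_logs
  structure(prof, class = c("bcs_timing_profile", class(prof)),
            L = L, n_logs = n_logs)
}

# ---- growing-population Ada trace ------------------------------------------

# piecewise-constant time average of value segments over equal-width bins
bin_time_average <- function(times, values, t_end, bin_width) {
  edges <- seq(0, t_end, by = bin_width)
  if (edges[length(edges)] < t_end) edges <- c(edges, t_end)
  n_bins <- length(edges) - 1L
  brk <- sort(unique(c(times, edges)))
  brk <- brk[brk <= t_end]
  if (brk[length(brk)] < t_end) brk <- c(brk, t_end)
  seg_lo <- brk[-length(brk)]
  seg_hi <- brk[-1L]
  seg_val <- values[findInterval(seg_lo, times)]
  bin_of <- findInterval(seg_lo, edges, rightmost.closed = TRUE)
  num <- tapply((seg_hi - seg_lo) * seg_val, factor(bin_of, levels = seq_len(n_bins)),
                sum, default = 0)
  den <- tapply(seg_hi - seg_lo, factor(bin_of, levels = seq_len(n_bins)),
                sum, default = 0)
  tibble::tibble(time = edges[-1L], value = as.numeric(num) / as.numeric(den))
}

#' Mean Ada and meAda per live cell over time
#'
#' Reconstructs, from the event log of the DNA-damage model, the live-cell
#' census (each completed division adds one cell; cells never die) and the
#' total Ada and meAda molecule counts (`generate_Ada` adds an Ada;
#' `generate_meAda` converts one Ada to one meAda; segregation moves
#' molecules between daughters without changing totals), then returns the
#' time-binned, time-weighted average number of molecules per live cell.
#'
#' @param logs A `bcs_eventlog`, `bcs_batch` or list of logs from
#'   [bcs_fixture_dna_damage()].
#' @param bin_width Width of the time bins (same units as the rate
#'   constants).
#' @return A `bcs_population_trace` tibble with columns `replicate`, `time`
#'   (bin right edge), `ada_per_cell`, `meada_per_cell`, `n_cells` (at bin
#'   end).
#' @export
bcs_ada_trace <- function(logs, bin_width = 10) {
  logs <- as_log_list(logs)
  out <- lapply(seq_along(logs), function(r) {
    log <- logs[[r]]
    if (nrow(log) == 0L) stop("empty event log", call. = FALSE)
    t_end <- max(log$time)
    dA <- (log$action == "generate_Ada") - (log$action == "generate_meAda")
    dM <- as.numeric(log$action == "generate_meAda")
    dN <- as.numeric(grepl("^divide_done", log$action))
    times <- c(0, log$time)
    A <- c(0, cumsum(dA))
    M <- c(0, cumsum(dM))
    N <- c(1, 1 + cumsum(dN))
    ada <- bin_time_average(times, A / N, t_end, bin_width)
    mea <- bin_time_average(times, M / N, t_end, bin_width)
    ncell <- N[findInterval(ada$time, times)]
    tibble::tibble(replicate = r, time = ada$time,
                   ada_per_cell = ada$value, meada_per_cell = mea$value,
                   n_cells = ncell)
  })
  trace <- dplyr::bind_rows(out)
  structure(trace, class = c("bcs_population_trace", class(trace)),
            bin_width = bin_width)
}

#' Time-averaged Ada per cell
#'
#' The time-weighted average of the mean-Ada-per-cell trace after a burn-in,
#' per replicate colony, and its average across replicates.
#'
#' @param trace A `bcs_population_trace` from [bcs_ada_trace()].
#' @param burn_in Time to discard from the start of each trace (the initial
#'   cell starts with zero Ada, so the population needs a couple of
#'   generations to reach the basal balance).
#' @return A one-row tibble with `mean_ada`, `sd_ada` (between replicates),
#'   `n_replicates`.
#' @export
bcs_ada_mean <- function(trace, burn_in = 0) {
  stopifnot(inherits(trace, "bcs_population_trace"))
  kept <- trace[trace$time > burn_in, , drop = FALSE]
  if (nrow(kept) == 0L) {
    stop("burn_in leaves no data (burn_in >= simulated time)", call. = FALSE)
  }
  per_rep <- tapply(kept$ada_per_cell, kept$replicate, mean)
  tibble::tibble(
    mean_ada = mean(per_rep),
    sd_ada = if (length(per_rep) > 1L) stats::sd(per_rep) else NA_real_,
    n_replicates = length(per_rep)
  )
}

# ---- phosphorylation dose-response ----------------------------------------

#' Steady-state phosphorylated fraction of a receptor log
#'
#' Tracks the total number of phosphorylated sites over time
#' (`phosphorylate` events add one, `dephosphorylate` events remove one)
#' and returns its time-weighted mean over `(burn_in, T]`, divided by the
#' total number of sites.
#'
#' @param log A `bcs_eventlog` from [bcs_fixture_tcr()].
#' @param n_sites,receptors Sites per receptor and receptor count.
#' @param burn_in Time discarded as equilibration; defaults to half the
#'   simulated time (the package's stationarity heuristic: the second half
#'   of the trace is treated as stationary).
#' @return The fraction in `[0, 1]`.
#' @export
bcs_phospho_fraction <- function(log, n_sites, receptors, burn_in = NULL) {
  if (nrow(log) == 0L) stop("empty event log", call. = FALSE)
  t_end <- max(log$time)
  if (is.null(burn_in)) burn_in <- t_end / 2
  if (burn_in >= t_end) {
    stop("burn_in is not smaller than the simulated time", call. = FALSE)
  }
  dP <- (log$action == "phosphorylate") - (log$action == "dephosphorylate")
  times <- c(0, log$time)
  P <- c(0, cumsum(dP))
  seg <- unique(c(burn_in, times[times > burn_in], t_end))
  seg <- sort(seg)
  vals <- P[findInterval(seg[-length(seg)], times)]
  widths <- diff(seg)
  mean_P <- sum(vals * widths) / sum(widths)
  mean_P / (n_sites * receptors)
}

#' Phosphorylation dose-response across kinase:phosphatase ratios
#'
#' @param batches A list of `bcs_batch` objects (one per ratio), each from
#'   the same receptor model simulated at a different kinase:phosphatase
#'   ratio.
#' @param ratios Numeric vector of kinase:phosphatase ratios, one per
#'   batch (defaults to the names of `batches`).
#' @param n_sites,receptors Sites per receptor and receptor count.
#' @param burn_in Passed to [bcs_phospho_fraction()].
#' @return A `bcs_dose_response` tibble with columns `ratio`,
#'   `mean_fraction`, `sd`, `n`.
#' @export
bcs_dose_response <- function(batches, ratios = NULL, n_sites, receptors,
                              burn_in = NULL) {
  if (is.null(ratios)) ratios <- as.numeric(names(batches))
  stopifnot(length(ratios) == length(batches), !anyNA(ratios))
  rows <- lapply(seq_along(batches), function(k) {
    fr <- vapply(as_log_list(batches[[k]]), bcs_phospho_fraction, numeric(1),
                 n_sites = n_sites, receptors = receptors, burn_in = burn_in)
    tibble::tibble(ratio = ratios[[k]], mean_fraction = mean(fr),
                   sd = if (length(fr) > 1L) stats::sd(fr) else NA_real_,
                   n = length(fr))
  })
  dr <- dplyr::arrange(dplyr::bind_rows(rows), ratio)
  structure(dr, class = c("bcs_dose_response", class(dr)))
}

#' Response coefficient of a dose-response curve
#'
#' Fits a Hill curve `f = r^h / (r^h + r0^h)` to the measured points by
#' linear regression of `logit(f)` on `log(r)` (fractions are clamped away
#' from 0 and 1 by `eps` before the logit) and returns the response
#' coefficient `RC = 81^(1/h)`: the ratio of inputs giving 90% and 10% of
#' the maximal response.  `RC = 81` is a hyperbolic (Michaelian) response;
#' smaller values mean steeper, more switch-like (ultrasensitive) curves.
#'
#' @param dose_response A `bcs_dose_response` (or tibble with columns
#'   `ratio` and `mean_fraction`).
#' @param eps Clamping margin for fractions at 0 or 1.
#' @return A one-row tibble with `hill` (fitted Hill coefficient), `rc`
#'   (response coefficient) and `ec50` (ratio at half response).
#' @export
bcs_response_coefficient <- function(dose_response, eps = 0.005) {
  f <- pmin(pmax(dose_response$mean_fraction, eps), 1 - eps)
  x <- log(dose_response$ratio)
  y <- log(f / (1 - f))
  fit <- stats::lm(y ~ x)
  h <- unname(stats::coef(fit)[[2L]])
  tibble::tibble(hill = h, rc = 81^(1 / h),
                 ec50 = exp(-unname(stats::coef(fit)[[1L]]) / h))
}
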