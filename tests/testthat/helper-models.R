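# Shared model sources and small helpers for the test-suite.  All fixtures
# are built in code; nothing is read from disk.

# gated increment/double model: always deadlocks at i=4, j=16
gated_model <- function(r = 1) bcs_ex_increment(r)$model

# two-process channel-list handshake: channel (3,4), payload (2,9)
channel_list_model <- function() bcs_ex_channel_list()$model

# pure two-state clock without beacons (symmetric rates)
pure_clock_model <- function(rs = 1) {
  bcs_parse(sprintf("
rs = %s
C[s] = {flip, rs}.C[3-s]
C[1]
", rs))
}

# single handshake pair: one candidate at rate rs*rr
handshake_pair_model <- function(rs = 3, rr = 4) {
  bcs_parse(sprintf("
S = {@c![1], %s}
R = {@c?[1](x), %s}
S || R
", rs, rr))
}

# n independent co-located reactant pairs, pair k living on positions around
# 1000*k so pairs can never interact; each pair has four unit-rate moves and
# one handshake at rate rr (send rate 1).  The position doubles as the
# handshake channel (the calculus's computed-channel idiom), so reactants
# can only pair when co-located
bimolecular_pairs_model <- function(n_pairs, r = 1, rr = 2) {
  sys <- paste(sprintf("A[%d] || B[%d]", 1000L * seq_len(n_pairs),
                       1000L * seq_len(n_pairs)), collapse = " || ")
  bcs_parse(sprintf("
r = %s
rr = %s
A[i] = {moveLeft, r}.A[i-1] + {moveRight, r}.A[i+1] + {@i![i], 1}
B[i] = {moveLeft, r}.B[i-1] + {moveRight, r}.B[i+1] + {@i?[i](x), rr}.AB[x]
AB[i] = {unbind, r}.(A[i] || B[i])
%s
", fmt(r), fmt(rr), sys))
}

fmt <- function(x) format(x, digits = 15)

# first event of each reactant pair in a bimolecular_pairs_model log,
# classified as reaction (TRUE) or diffusion step (FALSE)
pair_first_events <- function(log) {
  is_react <- grepl("^@", log$action)
  val <- vapply(seq_len(nrow(log)), function(k) {
    if (is_react[[k]]) {
      as.numeric(sub("^@(-?[0-9]+)[!?].*$", "\\1", log$action[[k]]))
    } else {
      log$params[[k]][[1L]]
    }
  }, numeric(1))
  pair <- round(val / 1000)
  first <- !duplicated(pair)
  # a handshake writes two rows; drop the receiver row of the same pair
  keep <- first & pair >= 1
  tibble::tibble(pair = pair[keep], react = is_react[keep])
}

# positions claimed (chr beacon launches) in a replication log
claimed_positions <- function(log) {
  hits <- grepl("^chr!\\[", log$action)
  as.integer(sub("^chr!\\[(-?[0-9]+)\\]$", "\\1", log$action[hits]))
}

# time-weighted fraction of time the pure clock spends in state 1
clock_state1_fraction <- function(log, t_end) {
  s <- vapply(log$params, `[[`, numeric(1), 1L)
  times <- c(0, log$time, t_end)
  states <- c(1, 3 - s)  # params hold the state before the flip
  sum(diff(times) * (states == 1)) / t_end
}
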