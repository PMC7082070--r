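# beaconr

Parse and simulate **Beacon Calculus** models of biological systems in R.

The Beacon Calculus is a stochastic process algebra: each component of a
system (an origin of replication, a cell, an enzyme) is a *process* with
numeric parameters that performs actions at exponential rates. Actions are
combined by prefix (sequence), choice and parallel composition, may be
gated on parameter conditions, and communicate in two ways:

* **handshakes** — synchronous, two-party exchanges over matching
  (possibly computed) channels, occurring at the product of the send and
  receive rates;
* **beacons** — persistent asynchronous broadcasts that stay active until
  killed, can be received any number of times, and whose *absence* can
  gate an action (a beacon check).

A model with rated actions denotes a continuous-time Markov chain.
`beaconr` simulates that chain exactly with a Gillespie-type stochastic
simulation algorithm — at each step the waiting time is drawn from an
exponential at the total propensity and an enabled transition is chosen
with probability proportional to its rate — and returns a tidy event log
(one row per participating process: time, action, process, parameter
values), plus an explicit CTMC expander for small models that the test
suite uses as an independent oracle.

The package is aimed at quantitative/systems biologists who want compact,
executable models of interacting components without writing the
combinatorial reaction network by hand. It ships generators for three
worked model families: stochastic DNA replication (origins, forks and
beacon bookkeeping, including cooperative-firing and fork-barrier
variants), the *E. coli* Ada response to DNA methylation damage in a
growing cell population, and multisite receptor phosphorylation with
kinases and phosphatases, whose dose-response is ultrasensitive exactly
when enzymes dwell after catalysis.

## The dialect

Models are plain text (see `docs/grammar.md` for the full EBNF). One
definition per line; `name = number` defines a constant; the final line
without `=` is the initial system, where `N * P[args]` starts `N` copies;
`//` comments. Example actions: `{step, r}` (local), `{@c![i], r}`
(handshake send), `{@c?[0..9](x), r}` (handshake receive binding `x`),
`{chr![i], r}` / `{chr#[i], r}` / `{~chr?[i], r}` (beacon launch / kill /
check). Receive sets support ranges and `U`, `I`, `\` (union,
intersection, subtraction — `\` binds tightest, then `I`, then `U`).

## A worked example

A process that increments `i` and doubles `j` while `i<5` and `j<10` hold:

```r
library(beaconr)
m <- bcs_parse("
r = 1
A[i,j] = [i<5 & j<10]->{changeParameters, r}.A[i+1, 2*j]
A[0,1]
")
log <- bcs_simulate(m, seed = 1)
log
#> <bcs_eventlog> 4 event(s), t = 0 .. 3.54121, stopped: deadlocked (seed 1, replicate 1)
#> # A tibble: 4 × 4
#>    time action           process params
#>   <dbl> <chr>            <chr>   <list>
#> 1  1.33 changeParameters A       <dbl [2]>
#> 2  1.88 changeParameters A       <dbl [2]>
#> 3  3.48 changeParameters A       <dbl [2]>
#> 4  3.54 changeParameters A       <dbl [2]>
bcs_final_state(log)$params[[1]]
#> [1]  4 16
```

Four gated actions fire and the process deadlocks at `i = 4, j = 16`: the
gate still allows `i` (4 < 5) but not `j` (16 ≥ 10), so no action remains
and the simulation stops.

A replication timing profile from a 50 kb chromosome with one certain
origin in the middle (fork steps claim positions through `chr` beacons, so
every position is replicated exactly once):

```r
fx <- bcs_fixture_replication(L = 50, origins = data.frame(position = 25, q = 1, fire = 0.5))
b <- bcs_run_batch(fx$model, replicates = 20, seed = 1)
prof <- bcs_replication_timing(b, L = 50)
prof[c(1, 13, 25, 37, 50), ]
#> # A tibble: 5 × 5
#>   position mean_time   sem n_replicates complete
#>      <int>     <dbl> <dbl>        <int> <lgl>
#> 1        1     15.9  0.597           20 TRUE
#> 2       13      9.48 0.432           20 TRUE
#> 3       25      2.52 0.249           20 TRUE
#> 4       37      9.89 0.721           20 TRUE
#> 5       50     17.2  0.723           20 TRUE
autoplot(prof)
```

The profile is the expected symmetric V: the origin fires after ~2.5 time
units on average and positions further away replicate later, at about one
fork step (1/1.8 time units) per kb.

Other entry points: `bcs_fixture_dna_damage()` + `bcs_ada_trace()` /
`bcs_ada_mean()` for the growing-population damage model;
`bcs_fixture_tcr()` + `bcs_dose_response()` / `bcs_response_coefficient()`
for phosphorylation ultrasensitivity; `bcs_ctmc()` with
`bcs_ctmc_stationary()` / `bcs_ctmc_first_passage()` for explicit chains;
`write_event_log()` / `read_event_log()` for the TSV event tables; and the
`exec/bcs` script (`bcs run`, `bcs fixtures`, `bcs summarize`) for shell
use. The methods vignette (`vignettes/beacon-calculus.Rmd`) documents the
semantics decisions, the default constants of every model and their
rationale.

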