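---
title: "The Beacon Calculus in beaconr: semantics, simulation and the reference models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Beacon Calculus in beaconr: semantics, simulation and the reference models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beaconr)
```

## The calculus

The Beacon Calculus is a stochastic process algebra for systems of
interacting components. Each component is a *process* carrying a finite
list of numeric parameters; a process performs *actions*, each an ordered
pair `{a, r}` of a label and a positive rate. Three combinators build
behaviour:

* **prefix** `{a,ra}.{b,rb}` — perform `a`, then `b`;
* **choice** `{a,ra} + {b,rb}` — perform exactly one branch, `a` with
  probability `ra/(ra+rb)`;
* **parallel** `{a,ra} || {b,rb}` — both proceed concurrently.

Prefix binds more strongly than choice, which binds more strongly than
parallel. Gated actions `[i<5]->{a,r}` are available only while the
condition over parameters holds. Processes recurse with changed parameters
(`A[i,j] = ...A[i+1, 2*j]`), which is how movement, counts and state
changes are modelled.

Communication is either synchronous or asynchronous:

* A **handshake** pairs a send `{@c![v], rs}` with a receive
  `{@c?[S](x), rr}` on a matching channel; it always involves exactly two
  distinct process instances and occurs at the product rate `rs*rr`. The
  transmitted value must be a member of the receiver's set `S`; it is bound
  to `x` for the rest of the receiving process, including the receive's own
  rate expression. Channels and payloads may be comma-separated lists of
  expressions, so processes can compute whom they talk to.
* A **beacon** is a persistent broadcast: `{c![v], r}` launches it,
  `{c#[v], r}` kills it, `{c?[S](x), r}` receives it (any number of times,
  without consuming it) and `{~c?[S], r}` is a *check*, enabled only while
  no matching beacon is active.

A process with no performable action now and no action that could ever
become enabled is deadlocked and removed; the simulation stops when no
enabled action remains anywhere.

A model with rated actions denotes a continuous-time Markov chain (CTMC)
whose states are (multiset of live process instances, set of active
beacons). `bcs_simulate()` samples paths of that chain exactly:
at each step it enumerates every enabled *candidate* — gated-true local
actions, beacon launches/kills, matched handshake pairs, receivable active
beacons, and checks with no matching beacon — draws the waiting time from
an exponential at the total rate, and picks a candidate with probability
proportional to its rate. `bcs_ctmc()` builds the same chain explicitly
for small models, which the test-suite uses as an independent oracle
(holding times, branch frequencies, first-passage times computed by linear
algebra must match simulation within Monte-Carlo error).

## Semantic decisions

Points the informal language description leaves open were resolved as
follows; each is locked in by tests.

* **Channel identity.** A channel is the tuple of its evaluated
  components. A component that is a bare identifier evaluates numerically
  when the name is bound (parameter, binding variable, constant) and
  otherwise stays symbolic; symbolic and numeric components never match
  each other, so there is no crosstalk between `chr` and a computed channel
  `3`. This makes both idioms in the language work: fixed named channels
  (`chr`), and parameter-valued channels (a modification count `m` used as
  the channel name).
* **Licensing probabilities as rates.** The origin-licensing choice uses
  `q` and `1-q` directly as the rates of the two branches, which yields
  licensing probability exactly `q`; the branches are gated (`[q>0]`,
  `[q<1]`) so the degenerate values 0 and 1 stay legal even though a rate
  itself must be strictly positive.
* **Gates** attach to the single action they prefix; a false gate removes
  that derivative from the candidate set and nothing else.
* **Binding scope.** A receive's binding variables scope over the entire
  continuation *and* the receive's own rate expression (so a beacon
  carrying a state `s` can be received at rate `r*s`). They do not leak
  into sibling parallel components.
* **Self-communication.** One instance never satisfies both ends of a
  handshake; two components of the same original definition are distinct
  instances and may handshake.
* **Multiplicity.** Identical opportunities (two receivers for one sender,
  two matching beacons) are separate candidates, so total propensity is
  additive, mirroring reaction multiplicity in the stochastic simulation
  algorithm.
* **Deadlock removal** is conservative: an instance is dropped only when it
  has no derivative at all; a blocked check or a waiting sender is kept,
  because a beacon kill or a new partner could re-enable it. Termination is
  decided by candidate emptiness, so retained-but-blocked instances never
  stall a run, and the final state reports exactly the processes removed as
  deadlocked.

## The simulation engine

Because an instance's environment never changes in place (parameters change
only through recursion, which replaces the instance), every gate truth
value, local rate, evaluated channel tuple, payload and receive set is
fixed for the instance's lifetime. The engine therefore extracts each
instance's derivatives once, and maintains the candidate set
*incrementally*: applying a transition invalidates only the candidates
touching the participating instances, plus — when the beacon store changed —
the beacon-dependent candidates on the affected channel. This is
behaviourally identical to re-enumerating everything after every
transition; an audit mode re-derives the full candidate set from scratch
after each step and asserts equality, and runs over every reference model
in the test-suite.

Reproducibility: each replicate uses one generator seeded with
`base_seed + replicate - 1`, and every step consumes exactly two uniform
draws (waiting time, candidate selection). Candidates are ordered
canonically (owning instance id, then action position, then creation
order), so a given model text, seed and replicate index always produce a
byte-identical event log.

The event log has one row per participating process — time, action label
(with channel and transmitted values for communications), process
definition name, and the parameter values at the moment of the action — in
ascending time; a handshake writes two rows at the same instant. Logs
round-trip through a four-column TSV (`write_event_log()` /
`read_event_log()`) with times at 10 significant digits.

## Numerical choices

* Rates must evaluate to strictly positive finite reals; anything else
  aborts the run naming the action and the environment it was evaluated
  in. Division is real division throughout.
* Set-range endpoints must be integers (tolerance `1e-9` for accumulated
  float error); a reversed range `a..b` with `a > b` is the *empty set*,
  not an error, because ranges with expression endpoints (`i-1..i+1`) can
  transiently invert at domain boundaries, and an empty receive set simply
  disables the receive.
* Arithmetic supports `+ - * /`, unary minus, parentheses and `^`; gates
  support the six comparisons with `&`, `|` and `~` (not), `~` binding
  tightest.

## The reference models and their constants

The package generates three families of biological models. The prose
descriptions fix their structure and a handful of numbers (the uniform
origin firing rate 0.015, the low/high damage rates `1e-4` and `0.01`, 20
phosphosites per receptor, a basal Ada level of 1.25 molecules per cell);
the remaining rate constants are this package's own defaults, chosen once
to satisfy the stated relationships and kept overridable as generator
arguments.

**DNA replication** (`bcs_fixture_replication()`). Origins license with
probability `q`, fire at rate `fire` through a beacon check on their own
position, and split into rightward/leftward forks. Forks check the position
ahead and claim it by launching a `chr` beacon, so every position is
replicated exactly once. Fork step rate defaults to 1.8 positions per
minute (with 1 position = 1 kb, in the measured range for budding yeast
forks); the default layout is six evenly spaced, always-licensed origins
firing at 0.015/min on a 300 kb chromosome. The *claim* launch runs at a
bookkeeping rate of `1e7`, which makes the window between a fork's check
and its claim ~`1e-7` time units; the probability that two converging forks
both enter the same position is a few times `1e-7` per convergence event
and does not occur at test scale. The barrier variant stalls rightward
forks at a chosen coordinate at rate `fork_rate/10` (a stall lasts on
average ten steps); the cooperative variant lets an unfired origin receive
a `coop` beacon from an origin that fired within 50 kb at rate
`coop_rate/distance` (default numerator 0.4), guarded against zero
distance by excluding the origin's own position from the receive sets.

**DNA methylation damage** (`bcs_fixture_dna_damage()`). A cell tracks Ada
(`A`), methylated Ada (`mA`) and damage sites (`d`). The time unit is
minutes. Division at `k_division = 0.02` (50-minute generations, slow
*E. coli* growth) and basal production `k_basal = 0.025` give the two
relationships the system is known for: about one Ada produced per
generation, and a basal population average of
`k_basal/k_division = 1.25` molecules per cell. Positive feedback of meAda
on its own gene is a saturating Hill-type term
`k_basal + k_max * mA/(mA + K_A)` with `k_max = 0.25` (10-fold maximal
induction) and `K_A = 2`; repair is mass-action `k_me*d*A` with
`k_me = 0.05`, fast relative to a generation once any Ada exists, and it
consumes the damage (`d` decreases by one as one Ada becomes meAda). At
division, each Ada and each meAda molecule segregates to a daughter by an
independent rate-symmetric binary choice (molecule counts are conserved
exactly), and the damage sites follow one daughter chosen by a symmetric
coin flip — methylation damage sits on DNA, so it is not partitioned
per-molecule by the four segregation counters, which track proteins only.

**Multisite phosphorylation** (`bcs_fixture_tcr()`). Receptors with 20
sites are modified by kinases and phosphatases that become proximal via a
handshake, bind at a rate proportional to the number of modifiable sites,
catalyse, and — in the dwell variant — pass through a briefly inert
proximal state before they can rebind. The default kinetics
(`k_prox = 0.05`, `k_leave = 1`, `k_bind = 1` per site, `k_unbind = 1`,
`k_cat = 10`, `k_dwell = 0.25`) put the two variants on the two sides of
the processivity boundary: with the dwell, an enzyme usually leaves before
rebinding (distributive kinetics — the receptor performs a biased random
walk over its sites, which is ultrasensitive in the kinase:phosphatase
ratio), while without the dwell an enzyme rebinds almost immediately and
modifies many sites per visit (processive kinetics, which flattens the
response towards a Michaelian curve). The kinetic scheme is exactly
symmetric under swapping kinase with phosphatase and `p` with `n-p`, so
the dose-response passes through one half at ratio one.

**Steady state** for the dose-response is operationalised as discarding a
burn-in and time-averaging the phosphorylated fraction over the remainder;
the default burn-in is half the simulated horizon, i.e. the second half of
the trace is treated as stationary. This is a documented heuristic, not an
estimator of mixing time; for the default kinetics the fraction
equilibrates well before the midpoint of the horizons used.

## What the generators do and do not emulate

The generators reproduce the *structure* of the biological systems — the
exactly-once invariant of replication, conservation of molecules at
division, bounded per-receptor phosphorylation — and rate constants chosen
to sit in the biologically reported regimes. They do not emulate:
measured per-origin licensing probabilities and firing times (those are
external datasets, so quantitative agreement with experimental
chromosome-II timing profiles is out of scope — the shape properties of the
profile stand in for it); replication fork collapse or death of cells;
extrinsic noise in enzyme copy numbers. Passing tests therefore validate
the calculus, the simulator and the models' internal logic, not parameter
fits to laboratory data.

## Problem sizes

The test-suite and the acceptance script size their simulations so the
whole suite runs in minutes on one core: probability laws use 10^4 draws
(3-standard-error bands); CTMC-oracle comparisons use a few hundred
replicates of models with at most ~100 states; replication invariants use
100 seeds at L = 300 with six origins; the damage model uses 6 colonies
capped at 2500 transitions in the test-suite and 16 colonies capped at 3000
in the acceptance script (several hundred cells each, ~6 generations past
the 100-minute burn-in); the dose-response uses 6 receptors, 24 enzymes,
seven ratio points and 6 replicates per point. These are the package's validation
configurations; all of them are arguments, and nothing prevents running the
fixtures at full published scale.

## Known limitations

* The claim-rate construction makes double replication astronomically
  unlikely rather than impossible; an atomic check-and-launch would need a
  new primitive in the calculus.
* The explicit CTMC expander deep-copies engine state per edge and is
  intended for oracle-sized models (thousands of states at most).
* `bcs_response_coefficient()` fits a two-parameter Hill curve by logit
  regression; strongly asymmetric dose-responses would need a richer model.
* Constants are global and must be defined before use; there is no module
  system or include mechanism in the dialect.
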