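# Programmatic generators of the reference models.  Each generator returns a
# `bcs_fixture`: the bcs source text, the parameter values used, and the
# parsed model.  Defaults reproduce the reference configuration of each
# model; every rate constant is an overridable argument.

new_fixture <- function(name, params, source) {
  model <- bcs_parse(source)
  diags <- bcs_validate(model)
  if (nrow(diags) > 0L) {
    stop(sprintf("internal error: fixture '%s' failed validation", name),
         call. = FALSE)
  }
  attr(model, "validated") <- TRUE
  structure(list(name = name, params = params, source = source, model = model),
            class = "bcs_fixture")
}

#' @export
print.bcs_fixture <- function(x, ...) {
  cat(sprintf("<bcs_fixture> %s\n", x$name))
  cat(sprintf("parameters: %s\n",
              paste(sprintf("%s=%s", names(x$params),
                            vapply(x$params, function(v) paste(format(v), collapse = "/"),
                                   character(1))),
                    collapse = ", ")))
  cat(x$source)
  invisible(x)
}

# ---- language-overview examples -------------------------------------------

#' Worked examples of the calculus
#'
#' Small models exercising one language feature each:
#' \describe{
#'   \item{`bcs_ex_increment()`}{A process that increments `i` and doubles
#'     `j` while a gate `i<5 & j<10` holds; from `i=0, j=1` it always
#'     deadlocks at `i=4, j=16`.}
#'   \item{`bcs_ex_choice()`}{`P = {a,ra} + {b,rb}`; action `a` is chosen
#'     with probability `ra/(ra+rb)`.}
#'   \item{`bcs_ex_combinators()`}{The precedence example
#'     `{a,ra} || {b,rb}.{c,rc} + {d,rd}.{e,re}`.}
#'   \item{`bcs_ex_bimolecular()`}{Two reactants diffusing on a line that
#'     react through a handshake when co-located; when both sit on the same
#'     position the probability that the next event is the reaction is
#'     `rr/(4*r + rr)`.}
#'   \item{`bcs_ex_reactant()`}{The same reaction with a single parametric
#'     reactant process, identity encoded in a parameter.}
#'   \item{`bcs_ex_clock()`}{A two-state clock broadcasting its state on a
#'     beacon; a complex AB dissociates at rate `r*s` where `s` is the
#'     received state.}
#'   \item{`bcs_ex_channel_list()`}{Two processes that handshake over the
#'     computed two-component channel `3,4`, binding the transmitted values
#'     `2` and `9`.}
#' }
#'
#' @param r,ra,rb,rr,rs Rate constants (see each model's source).
#' @param copies Number of copies of `P` in the initial system
#'   (`bcs_ex_choice`).
#' @param xA,xB Starting positions of the two reactants.
#' @return A `bcs_fixture` (list with `name`, `params`, `source`, `model`).
#' @name language_examples
NULL

#' @rdname language_examples
#' @export
bcs_ex_increment <- function(r = 1) {
  new_fixture("increment-double", list(r = r), sprintf("
r = %s
A[i,j] = [i<5 & j<10]->{changeParameters, r}.A[i+1, 2*j]
A[0,1]
", fmt_num(r)))
}

#' @rdname language_examples
#' @export
bcs_ex_choice <- function(ra = 1, rb = 2, copies = 1L) {
  new_fixture("choice", list(ra = ra, rb = rb, copies = copies), sprintf("
ra = %s
rb = %s
P = {a, ra} + {b, rb}
%d * P
", fmt_num(ra), fmt_num(rb), as.integer(copies)))
}

#' @rdname language_examples
#' @export
bcs_ex_combinators <- function() {
  new_fixture("combinators", list(), "
P = {a,1} || {b,2}.{c,3} + {d,4}.{e,5}
P
")
}

#' @rdname language_examples
#' @export
bcs_ex_bimolecular <- function(r = 1, rr = 10, xA = 5, xB = -5) {
  new_fixture("bimolecular", list(r = r, rr = rr, xA = xA, xB = xB), sprintf("
r = %s
rr = %s
A[i] = {moveLeft, r}.A[i-1] + {moveRight, r}.A[i+1] + {@react![i], 1}
B[i] = {moveLeft, r}.B[i-1] + {moveRight, r}.B[i+1] + {@react?[i](x), rr}.AB[x]
AB[i] = {unbind, r}.(A[i] || B[i])
A[%s] || B[%s]
", fmt_num(r), fmt_num(rr), fmt_num(xA), fmt_num(xB)))
}

#' @rdname language_examples
#' @export
bcs_ex_reactant <- function(r = 1, rr = 10, xA = 5, xB = -5) {
  new_fixture("parametric-reactant", list(r = r, rr = rr, xA = xA, xB = xB), sprintf("
r = %s
rr = %s
R[x,i] = {moveLeft, r}.R[x-1,i] + {moveRight, r}.R[x+1,i]
  + [i==0]->{@react![x], 1}
  + [i==1]->{@react?[x](y), rr}.AB[y]
AB[x] = {unbind, r}.(R[x,0] || R[x,1])
R[%s,0] || R[%s,1]
", fmt_num(r), fmt_num(rr), fmt_num(xA), fmt_num(xB)))
}

#' @rdname language_examples
#' @export
bcs_ex_clock <- function(rs = 2, r = 0.5) {
  new_fixture("clock", list(rs = rs, r = r), sprintf("
rs = %s
r = %s
u = 1000
C[s] = {switch, rs}.{state#[s], u}.{state![3-s], u}.C[3-s]
CSTART[s] = {state![s], u}.C[s]
AB = {state?[1..2](s), r*s}
CSTART[1] || AB
", fmt_num(rs), fmt_num(r)))
}

#' @rdname language_examples
#' @export
bcs_ex_channel_list <- function() {
  new_fixture("channel-list", list(x = 1, y = 1, i = 1, j = 1), "
P[x,y] = {@x+2,y+3![x+1,y+8], 1}
Q[i,j] = {@i+2,4?[i-1..i+1,j+8](a,b), 1}.QDONE[a,b]
QDONE[a,b] = {received, 1}
P[1,1] || Q[1,1]
")
}

# ---- DNA replication -------------------------------------------------------

default_origins <- function(L) {
  pos <- round(seq(0.08, 0.92, length.out = 6L) * L)
  tibble::tibble(position = pos, q = 1, fire = 0.015)
}

#' DNA replication model (origins, forks, beacons)
#'
#' Origins of replication at chosen chromosomal positions are licensed with
#' probability `q` (modelled as the exclusive choice between a `licensed`
#' action at rate `q` and an `nlicensed` action at rate `1-q`); an
#' unlicensed origin deadlocks.  A licensed origin fires at rate `fire`
#' through a beacon check on channel `chr` at its own position, so it cannot
#' fire after a passing fork has replicated it.  Firing claims the origin's
#' position (launching a `chr` beacon) and starts a rightward (`FR`) and
#' leftward (`FL`) replication fork.  A fork verifies through a beacon check
#' that the position ahead is unreplicated, steps there at rate `fork_rate`,
#' and claims it by launching `chr` at that position; the claim action runs
#' at the very fast bookkeeping rate `claim_rate` so the check-then-claim
#' window is negligible.  Replication is complete when every process has
#' deadlocked, and the `chr` beacon-launch times are the per-position
#' replication times.
#'
#' Variants: `"cooperative"` adds a firing pathway where an origin receives
#' a `coop` beacon launched by another origin within `coop_range` positions,
#' at a rate `coop_rate / distance` (inversely proportional to the
#' distance); `"barrier"` makes rightward forks at `barrier_position` stall
#' (action `stall` at rate `stall_rate`) before continuing.
#'
#' @param L Chromosome length in positions (1 position = 1 kb).
#' @param origins Tibble/data frame with columns `position`, `q` (licensing
#'   probability in `[0,1]`) and `fire` (firing rate); defaults to six
#'   evenly-spread always-licensed origins with firing rate 0.015.
#' @param variant `"base"`, `"cooperative"` or `"barrier"`.
#' @param fork_rate Fork step rate per position.
#' @param claim_rate Bookkeeping rate of the position-claim beacon launch.
#' @param coop_range,coop_rate Cooperative-firing neighbourhood (positions)
#'   and rate numerator.
#' @param barrier_position,stall_rate Barrier location and stall rate
#'   (default one tenth of the fork step rate, i.e. a stall lasts on average
#'   ten times as long as one step).
#' @return A `bcs_fixture`.
#' @export
bcs_fixture_replication <- function(L = 300L,
                                    origins = default_origins(L),
                                    variant = c("base", "cooperative", "barrier"),
                                    fork_rate = 1.8,
                                    claim_rate = 1e7,
                                    coop_range = 50L,
                                    coop_rate = 0.4,
                                    barrier_position = 200L,
                                    stall_rate = fork_rate / 10) {
  variant <- match.arg(variant)
  origins <- tibble::as_tibble(origins)
  stopifnot(all(c("position", "q", "fire") %in% names(origins)))
  if (any(origins$position < 1 | origins$position > L)) {
    stop("origin positions must lie within 1..L", call. = FALSE)
  }
  if (any(origins$q < 0 | origins$q > 1)) {
    stop("licensing probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(origins$fire <= 0) || fork_rate <= 0 || stall_rate <= 0) {
    stop("rates must be positive", call. = FALSE)
  }
  header <- sprintf("L = %d\nv = %s\nclaim = %s\n",
                    as.integer(L), fmt_num(fork_rate), fmt_num(claim_rate))
  ori <- switch(variant,
    base = paste0(
      "ORI[i,q,fire] = [q>0]->{licensed, q}.{~chr?[i], fire}.{chr![i], claim}.(FR[i] || FL[i])\n",
      "  + [q<1]->{nlicensed, 1-q}\n"),
    cooperative = sprintf(paste0(
      "cc = %s\n",
      "w = %d\n",
      "ORI[i,q,fire] = [q>0]->{licensed, q}.ORIL[i,fire] + [q<1]->{nlicensed, 1-q}\n",
      "ORIL[i,fire] = {~chr?[i], fire}.FIRE[i]\n",
      "  + {coop?[i-w..i-1](x), cc/(i-x)}.{~chr?[i], claim}.FIRE[i]\n",
      "  + {coop?[i+1..i+w](x), cc/(x-i)}.{~chr?[i], claim}.FIRE[i]\n",
      "FIRE[i] = {coop![i], claim}.{chr![i], claim}.(FR[i] || FL[i])\n"),
      fmt_num(coop_rate), as.integer(coop_range)),
    barrier = sprintf(paste0(
      "rfb = %d\n",
      "sr = %s\n",
      "ORI[i,q,fire] = [q>0]->{licensed, q}.{~chr?[i], fire}.{chr![i], claim}.(FR[i] || FL[i])\n",
      "  + [q<1]->{nlicensed, 1-q}\n"),
      as.integer(barrier_position), fmt_num(stall_rate))
  )
  fr <- if (variant == "barrier") {
    paste0(
      "FR[i] = [i<L & i!=rfb]->{~chr?[i+1], v}.{chr![i+1], claim}.FR[i+1]\n",
      "  + [i==rfb]->{stall, sr}.FRGO[i]\n",
      "FRGO[i] = [i<L]->{~chr?[i+1], v}.{chr![i+1], claim}.FR[i+1]\n")
  } else {
    "FR[i] = [i<L]->{~chr?[i+1], v}.{chr![i+1], claim}.FR[i+1]\n"
  }
  fl <- "FL[i] = [i>1]->{~chr?[i-1], v}.{chr![i-1], claim}.FL[i-1]\n"
  sys <- paste(sprintf("ORI[%d,%s,%s]", as.integer(origins$position),
                       vapply(origins$q, fmt_num, character(1)),
                       vapply(origins$fire, fmt_num, character(1))),
               collapse = " || ")
  new_fixture(paste0("dna-replication-", variant),
              list(L = L, origins = origins, variant = variant,
                   fork_rate = fork_rate, claim_rate = claim_rate,
                   coop_range = coop_range, coop_rate = coop_rate,
                   barrier_position = barrier_position, stall_rate = stall_rate),
              paste0(header, ori, fr, fl, sys, "\n"))
}

# ---- DNA methylation damage response ---------------------------------------

#' DNA methylation damage response in a growing cell population
#'
#' A `CELL[A, mA, d]` process tracks Ada molecules (`A`), methylated Ada
#' (`mA`) and unrepaired methylation-damage sites (`d`).  Ada is generated
#' at a basal rate that scales to saturation with `mA`
#' (`k_basal + k_max * mA/(mA + K_A)`, the positive feedback of meAda on its
#' own gene); damage is repaired by converting one Ada into one meAda at a
#' mass-action rate `k_me * d * A`; damage arrives at rate `k_dmg`; the cell
#' divides at rate `k_division`.  Division continues as
#' `DIV[A, mA, d, A1, M1, A2, M2]`: each Ada and each meAda molecule
#' independently segregates to daughter 1 or daughter 2 through a
#' rate-symmetric binary choice, and the damage sites follow one daughter
#' chosen by a rate-symmetric coin flip; the dividing cell then restarts as
#' two daughter `CELL` processes.  The initial system is one cell with no
#' Ada, no meAda and no damage.
#'
#' With the default constants the basal steady state of the population mean
#' is `k_basal / k_division = 1.25` Ada molecules per cell, reached after a
#' couple of generations.
#'
#' @param k_dmg DNA damage rate (default `1e-4`, the low-damage condition;
#'   use `0.01` for high damage).
#' @param k_basal Basal Ada production rate per cell.
#' @param k_division Cell division rate (1/mean generation time).
#' @param k_me Repair (Ada methylation) rate constant per damage-Ada pair.
#' @param k_max Maximal extra Ada production from meAda feedback.
#' @param K_A meAda count at half-maximal feedback.
#' @param k_seg Rate of each per-molecule segregation step during division.
#' @return A `bcs_fixture`; the initial system is `CELL[0,0,0]`.
#' @export
bcs_fixture_dna_damage <- function(k_dmg = 1e-4,
                                   k_basal = 0.025,
                                   k_division = 0.02,
                                   k_me = 0.05,
                                   k_max = 0.25,
                                   K_A = 2,
                                   k_seg = 10) {
  stopifnot(k_dmg > 0, k_basal > 0, k_division > 0, k_me > 0, k_seg > 0)
  src <- sprintf("
kdmg = %s
kbasal = %s
kdiv = %s
kme = %s
kmax = %s
kA = %s
kseg = %s
CELL[A,mA,d] = {generate_Ada, kbasal + kmax*mA/(mA+kA)}.CELL[A+1,mA,d]
  + [d>0 & A>0]->{generate_meAda, kme*d*A}.CELL[A-1,mA+1,d-1]
  + {damage, kdmg}.CELL[A,mA,d+1]
  + {divide, kdiv}.DIV[A,mA,d,0,0,0,0]
DIV[A,mA,d,A1,M1,A2,M2] = [A1+A2<A]->{segregate_Ada1, kseg}.DIV[A,mA,d,A1+1,M1,A2,M2]
  + [A1+A2<A]->{segregate_Ada2, kseg}.DIV[A,mA,d,A1,M1,A2+1,M2]
  + [M1+M2<mA]->{segregate_meAda1, kseg}.DIV[A,mA,d,A1,M1+1,A2,M2]
  + [M1+M2<mA]->{segregate_meAda2, kseg}.DIV[A,mA,d,A1,M1,A2,M2+1]
  + [A1+A2==A & M1+M2==mA]->{divide_done1, kseg}.(CELL[A1,M1,d] || CELL[A2,M2,0])
  + [A1+A2==A & M1+M2==mA]->{divide_done2, kseg}.(CELL[A1,M1,0] || CELL[A2,M2,d])
CELL[0,0,0]
", fmt_num(k_dmg), fmt_num(k_basal), fmt_num(k_division), fmt_num(k_me),
   fmt_num(k_max), fmt_num(K_A), fmt_num(k_seg))
  new_fixture("dna-damage",
              list(k_dmg = k_dmg, k_basal = k_basal, k_division = k_division,
                   k_me = k_me, k_max = k_max, K_A = K_A, k_seg = k_seg),
              src)
}

# ---- multisite phosphorylation ---------------------------------------------

#' Multisite receptor phosphorylation with kinases and phosphatases
#'
#' Receptors `R[p]` carry `p` phosphorylated sites out of `n_sites`.
#' Enzymes `ENZYME[e]` are kinases (`e=0`) or phosphatases (`e=1`).  An
#' enzyme becomes proximal to a receptor by a handshake on channel
#' `proximalEnzyme` transmitting `e`; the enzyme process then deadlocks
#' while the receptor carries on as `R_PROX[p,e]`.  A proximal enzyme
#' either leaves (releasing the enzyme back into the system) or binds, a
#' kinase at rate `k_bind * (n_sites - p)` (proportional to free sites),
#' a phosphatase at rate `k_bind * p` (proportional to occupied sites).
#' Bound (`R_BOUND`), the enzyme unbinds or catalyses: a kinase
#' phosphorylates (`p+1`), a phosphatase dephosphorylates (`p-1`).  With
#' the dwell (`with_dwell = TRUE`) catalysis leads to `R_CAT`, where the
#' enzyme stays proximal but is briefly inert: it can only leave or, once
#' the inert period ends (rate `k_dwell`), return to the proximal state.
#' Removing the dwell sends the receptor straight back to `R_PROX` with
#' every other rate unchanged, which makes single enzyme visits effectively
#' processive and destroys the ultrasensitivity of the dose-response.
#'
#' @param n_sites Phosphorylation sites per receptor (default 20).
#' @param with_dwell Keep the post-catalysis inert period?
#' @param kinases,phosphatases,receptors Copy numbers in the initial system.
#' @param k_prox Handshake receive rate of enzyme arrival (send rate is 1).
#' @param k_leave Rate at which a proximal (or inert) enzyme leaves.
#' @param k_bind Per-site binding rate.
#' @param k_unbind Unbinding rate from the bound state.
#' @param k_cat Catalysis rate.
#' @param k_dwell Rate at which the post-catalysis inert period ends.
#' @return A `bcs_fixture`.
#' @export
bcs_fixture_tcr <- function(n_sites = 20L,
                            with_dwell = TRUE,
                            kinases = 12L,
                            phosphatases = 12L,
                            receptors = 6L,
                            k_prox = 0.05,
                            k_leave = 1,
                            k_bind = 1,
                            k_unbind = 1,
                            k_cat = 10,
                            k_dwell = 0.25) {
  stopifnot(n_sites >= 1, receptors >= 1, kinases + phosphatases >= 1)
  cat_cont <- if (with_dwell) "R_CAT" else "R_PROX"
  rcat <- if (with_dwell) {
    "R_CAT[p,e] = {enzLeave, koff}.(R[p] || ENZYME[e]) + {rebind, kdwell}.R_PROX[p,e]\n"
  } else {
    ""
  }
  sys <- c(
    if (kinases >= 1) sprintf("%d * ENZYME[0]", as.integer(kinases)),
    if (phosphatases >= 1) sprintf("%d * ENZYME[1]", as.integer(phosphatases)),
    sprintf("%d * R[0]", as.integer(receptors))
  )
  src <- sprintf("
n = %d
kprox = %s
koff = %s
kbind = %s
kunbind = %s
kcat = %s
kdwell = %s
ENZYME[e] = {@proximalEnzyme![e], 1}
R[p] = {@proximalEnzyme?[0..1](e), kprox}.R_PROX[p,e]
R_PROX[p,e] = {enzLeave, koff}.(R[p] || ENZYME[e])
  + [e==0 & p<n]->{bind, kbind*(n-p)}.R_BOUND[p,e]
  + [e==1 & p>0]->{bind, kbind*p}.R_BOUND[p,e]
R_BOUND[p,e] = {unbind, kunbind}.R_PROX[p,e]
  + [e==0]->{phosphorylate, kcat}.%s[p+1,e]
  + [e==1]->{dephosphorylate, kcat}.%s[p-1,e]
%s%s
", as.integer(n_sites), fmt_num(k_prox), fmt_num(k_leave), fmt_num(k_bind),
   fmt_num(k_unbind), fmt_num(k_cat), fmt_num(k_dwell),
   cat_cont, cat_cont, rcat, paste(sys, collapse = " || "))
  new_fixture(sprintf("tcr-%s", if (with_dwell) "dwell" else "nodwell"),
              list(n_sites = n_sites, with_dwell = with_dwell,
                   kinases = kinases, phosphatases = phosphatases,
                   receptors = receptors, k_prox = k_prox, k_leave = k_leave,
                   k_bind = k_bind, k_unbind = k_unbind, k_cat = k_cat,
                   k_dwell = k_dwell),
              src)
}
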