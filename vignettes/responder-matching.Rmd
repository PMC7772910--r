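---
title: "Responder-network matching: model, solvers, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Responder-network matching: model, solvers, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aedmatch)
```

## The matching model

During an out-of-hospital cardiac arrest, survival falls steeply with every
minute before defibrillation, so a responder network should dispatch the
volunteers who can *arrive* soonest — not the ones who merely *stand*
closest. `aedmatch` models one dispatch decision as a three-index
assignment: each selected triple (user *i*, AED *j*, emergency *k*) means
"volunteer *i* collects defibrillator *j* and takes it to emergency *k*",
with travel time

$$t_{ijk} = \frac{d(u_i, a_j) + d(a_j, e_k)}{v_i},$$

where $v_i$ is the volunteer's walking speed. The constraints are: a user
serves at most one emergency, an AED is carried by at most one user, and
the volunteer's phone — their navigation device — must stay powered for the
whole trip, i.e. $t_{ijk} \le \mathrm{battery\ level}_i / \mathrm{consumption\ rate}_i$.
Emergencies may receive any number of responders (unless capped).

Minimizing total travel time directly has a degenerate optimum (dispatch
nobody), so the objective is inverted: maximize
$\sum (T_{\max} + 1 - t_{ijk})\, x_{ijk}$, where $T_{\max}$ is the largest
enumerated travel time. The `+ 1` matters: with the bare maximum the
slowest feasible path has zero weight and the solver may arbitrarily drop
it; with `+ 1` every feasible match is strictly valuable. The same constant
$T_{\max} + 1$ serves as the sentinel `MaxEdgeWeight` marking dummy and
infeasible cells in the Hungarian matrix, so sentinel cells can never be
confused with real paths.

Note the objective is a *weighted* trade-off, not "maximize count, then
minimize time": a single very fast match can in principle outscore two slow
ones. On realistic geometry the optimum is count-maximal in practice (the
test suite verifies count agreement across solvers on a 36-scenario
benchmark), but pathological battery-filtered instances exist where it is
not, and the package reproduces the stated objective rather than papering
over it.

## The three solvers

**Iterative Hungarian (`bm`).** AEDs and emergencies are combined into one
column group (one column per (AED, emergency) pair), giving a 2-D cost
matrix of travel times; battery-infeasible cells are sentineled, users with
no feasible cell are dropped, and the matrix is padded square with
sentinel-weighted dummy rows/columns. A minimum-cost perfect assignment is
solved (via `clue::solve_LSAP`), post-filtered (drop sentinel pairs;
resolve duplicate AEDs keeping the lower travel time), matched users/AEDs
are sentineled out, and the solve repeats until an iteration accepts
nothing new. Termination is bounded by min(*n*, *m*) productive iterations.

**One-shot exact solve (`ilp`).** The package's environment offers no
mixed-integer-programming backend, so exactness is achieved structurally
rather than by a generic solver. Without fairness or caps, emergencies are
unconstrained, so an optimal solution pairs each chosen (user, AED) with
that pair's best emergency; the residual problem is a rectangular
maximum-weight bipartite matching with weights $T_{\max}+1-t$ (zero where
no feasible path), which a linear-sum-assignment solve answers to proven
optimality — this reduction is exact, not heuristic. With caps the solver
switches to an exact depth-first branch-and-bound over users with an
admissible bound (sum of the largest per-user best values, truncated to the
number of unused AEDs). Battery infeasibility is handled by *filtering*
variables out before solving, never by constraints, which keeps the plain
and sliced formulations comparable. An exhaustive no-pruning recursion
(`brute_force_match`, guarded to $n\,m\,o \le 200$) provides the
independent optimality oracle; the test suite checks solver-vs-oracle
equality on 100+ seeded instances.

**Travel-time slicing (`ppilp`).** The full problem over, say, 2.19 million
candidate paths is sliced into ascending travel-time bands
(`travel_time_interval`, default 100 s, up to `horizon`, default 1000 s —
the final band is clamped to the horizon even when the interval does not
divide it). Before each band, paths of previously matched users or AEDs and
battery-infeasible paths are filtered out; the band is solved exactly and
its matches are fixed. Iteration stops at the horizon or as soon as no
unmatched feasible path remains, whichever comes first. Slicing is a
speed/quality trade: each band's solve is small and near responders are
dispatched first, but a band may commit a pairing a global solve would have
arranged differently. Consequently, when match counts agree, the sliced
total time can only *equal or exceed* the one-shot optimum — a structural
fact worth stating plainly, since the sliced method's advantage is
processing speed and early dispatch, not total-time quality. The band
constant $T_{\max}+1$ is inherited from the full path set (not recomputed
per band) so all bands price time on the same scale; with
`travel_time_interval = horizon` the method reduces exactly to the one-shot
solve. Guidance: larger intervals suit sparse (rural) regions, smaller
intervals dense cities.

## Max-min fairness and caps

Time-only matching is greedy across simultaneous emergencies: if one
emergency is nearer to everyone, it absorbs every responder. With
`fairness = TRUE` the solver first maximizes
$\mathrm{MinPair} = \min_k f(k)$, the smallest per-emergency match count
(including counts carried over from earlier bands, so multi-band fairness
is cumulative — the only reading that can equalize counts across bands),
then re-optimizes travel time with MinPair held at its optimum. The
lexicographic order is deliberate: on the showcase scenario the fair
solution (2/2 split, 260 s) must override the time-optimal one (4/0,
240 s), which a weighted single objective cannot guarantee.

Stage 1 is solved by a greedy balanced seed plus branch-and-bound with a
water-filling bound (how high can the minimum count still rise given the
remaining users, unused AEDs, and an additions budget); stage 2 enumerates
AED-to-emergency plans depth-first with count-deficit and value pruning,
solving each surviving plan as a user-to-column assignment. Both stages are
exact (oracle-verified); the cost is exponential in the *AED* count rather
than the user count, which fits this domain — defibrillators are the scarce
resource. Fairness solves with up to a few dozen AEDs are interactive;
beyond that, expect the stage-2 enumeration to dominate runtime. With a
single emergency, MinPair equals the total match count, so fairness then
means "maximize the number of responders dispatched, then minimize time".

`cap` bounds each emergency's match count ($\sum_{ij} x_{ijk} \le$ cap,
cumulative across bands), for dispatchers who stop alerting once enough
responders are en route.

## Distances, coordinates and numerical choices

Positions are planar meters by default; geographic mode interprets x/y as
lon/lat and uses the haversine formula. Distances go through a provider:
`euclidean` (default), `manhattan_grid` (L1, optional block quantization),
or `matrix` — precomputed route distances attached to the scenario, the
hook for real map routing, and the only mode in which asymmetry is allowed.
The legacy radius baseline (`radius_select`, default 500 m, inclusive
boundary) is provided for comparison only; it deliberately exhibits the
straight-line fallacy.

Battery units are a ratio: any consistent (level, per-second rate) pair
works, percent points being the convention; the boundary case
powered time = travel time counts as feasible (the device dies on arrival,
after navigation is done). Travel times are doubles in seconds; selections
that tie are broken lexicographically by (user, AED, emergency) id, with
floating-point comparisons at a 1e-9 tolerance inside the branch-and-bound.
All solvers are deterministic: identical scenario + options yield
byte-identical saved matches.

Degenerate inputs (no users, no feasible paths, horizon below every travel
time) yield empty match sets, never errors; an all-infeasible cost matrix
is an empty-result signal rather than an exception.

## The synthetic world

No public registry of responder positions, AED locations and arrest calls
exists, so scenarios are simulated. The generator places entities in a
square area — urban: 2 km × 2 km with 70% of users/AEDs clustered (normal,
sd = side/10) around emergency hotspots; rural: 10 km × 10 km, uniform —
with walking speeds U(1.0, 1.6) m/s, battery levels U(20, 100)% and
consumption rates U(0.002, 0.02)%/s. These defaults make a realistic
minority of candidate paths fail the battery filter (worst-case powered
time 1000 s against urban trips up to ~4000 s). The benchmark suite
reproduces the published 36-case grid (50/2/1 up to 1750/250/5 plus the
hand-built showcase); row seeds derive from the base seed and row index
only, so appending rows never perturbs earlier scenarios. Everything is
Mersenne-Twister under an explicit seed and leaves the global RNG state
untouched.

What the generator does *not* emulate: road networks, elevation, traffic,
population rasters, or responder availability patterns over the day. A
green test on synthetic scenarios therefore establishes algorithmic
correctness (constraints, optimality, determinism, cross-method agreement),
not field performance of a deployed system; route realism is delegated to
the matrix distance mode for users who have real routing data.

The showcase scenario is constructed exactly: four users collocated with
their own AEDs on a 60 m circle around emergency 1, with law-of-cosines
angles placing their routes to emergency 2 at exactly 70 m (users 1–2) and
80 m (users 3–4), all 32 paths battery-feasible. Time-only matching sends
all four to emergency 1 (total 240 s, one emergency covered); fairness
splits them 2/2 (total 260 s, both covered).

## Known limitations

* The inverted-time objective does not formally guarantee maximum
  cardinality (see above); count agreement is an empirical property of
  realistic geometry, verified per fixture.
* The sliced method's total time can exceed the one-shot optimum by small
  margins (observed ≤ ~2% on the benchmark suite); claims that it is
  "equal or less" can only hold with equality when counts agree.
* Fairness solving is exponential in the AED count; it is intended for the
  moderate instance sizes where the fairness question arises (simultaneous
  emergencies competing for nearby responders), not for region-scale
  inputs.
* Wall-clock timings in run reports are informational; they are
  hardware-bound and never asserted.
* No re-matching of in-transit responders, no moving-user tracking, no
  multimodal travel.
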