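# aedmatch

Matching volunteer responders and defibrillators to out-of-hospital cardiac
arrests.

## The problem

When a cardiac arrest is reported, a responder network system (RNS) alerts
registered volunteers near the patient. Deployed systems notify *everyone*
within a fixed radius (typically 500 m) — which over-alerts in dense cities,
ignores that straight-line distance is not walking distance (a 100 m
straight line can be a 600 m route), and says nothing about which automated
external defibrillator (AED) each responder should pick up, so several
volunteers race for the same device while others stand idle.

`aedmatch` replaces radius alerting with constrained assignment. For users
*i = 1..n*, AEDs *j = 1..m* and emergencies *k = 1..o*, the travel time of
the candidate path (i, j, k) is

    t_ijk = ( d(user_i, aed_j) + d(aed_j, emergency_k) ) / walking_speed_i

and a binary decision x_ijk selects the triple, subject to

* each user matched at most once: Σ_jk x_ijk ≤ 1,
* each AED matched at most once: Σ_ik x_ijk ≤ 1,
* battery feasibility: paths with t_ijk exceeding the phone's remaining
  powered-on time (battery level ÷ consumption rate) are filtered out,

maximizing the inverted-time objective Σ (big − t_ijk) x_ijk with
big = max(t) + 1, so every feasible match is valuable and faster matches are
preferred. Three solvers share this formulation:

* **`bm`** — iterative Hungarian matching of users against combined
  (AED, emergency) columns with sentinel-weighted dummy padding and
  post-filtering;
* **`ilp`** — the one-shot exact solve (a provably exact reduction to a
  rectangular assignment problem, or branch-and-bound when caps/fairness
  apply);
* **`ppilp`** — the travel-time-sliced variant: solve small exact problems
  in ascending time bands (e.g. 100 s, 200 s, … 1000 s), pre-filtering
  matched users/AEDs before each band. Near responders are dispatched by
  tiny, fast solves.

Because time-only matching is greedy — it can send every responder to the
nearest emergency and leave a simultaneous one unattended — an optional
**max-min fairness** objective lexicographically maximizes
MinPair = min_k Σ_ij x_ijk (the worst-served emergency's match count)
before optimizing time, and a per-emergency cap Σ_ij x_ijk ≤ cap is
available.

Intended users: EMS / health-informatics researchers studying responder
dispatch policies, and developers of RNS platforms who need a reference
matching engine with a verifiable optimality story.

## Worked example

```r
library(aedmatch)

scn <- generate_scenario(50, 2, 1, seed = 7)   # 50 users, 2 AEDs, 1 emergency
scn
#> <rns_scenario> 50 users (50 available), 2 AEDs (2 functional), 1 emergencies
#>   coordinates: planar_m; distance matrix: none

ms <- match_responders(scn, method = "ppilp",
  options = solver_options("ppilp", travel_time_interval = 500, horizon = 5000))
ms
#> <match_set: ppilp> 2 match(es), total match time 2419.11 s
#>   per emergency: e1=2 (1 covered)
#>   user_id aed_id emergency_id travel_time
#> 1   u0021  a0001           e1     790.044
#> 2   u0050  a0002           e1    1629.069
```

Only two volunteers are dispatched — one per AED — and each is told which
defibrillator to collect; the 48 others are not alerted. The travel times
are seconds of walking, AED pickup included.

The greedy-vs-fair contrast on the 4-user / 4-AED / 2-emergency showcase
scenario (every responder is 60 s from emergency `e1`, 70–80 s from `e2`):

```r
cmp <- run_compare(special_case_scenario(),
  options = solver_options("ppilp", travel_time_interval = 100,
                           horizon = 1000, fairness = TRUE))
cmp$table
#>  method n_matches total_match_time unique_emergencies_covered timing_s
#>      bm         4              240                          1    0.006
#>     ilp         4              240                          1    0.001
#>   ppilp         4              260                          2    0.005
```

Time-only matching (`bm`, `ilp`) sends all four responders to `e1` and
leaves `e2` unattended; with fairness (applied here to `ppilp`) the
responders split 2/2 at a 20 s total-time premium.

A thin command-line wrapper over the same functions ships in
`inst/cli/aedmatch.R` (subcommands `generate`, `suite`, `match`,
`compare`).

## Acceptance script

`scripts/acceptance.R` regenerates the benchmark scenario suite at reduced
scale (the 36-case grid capped at 200 users / 50 AEDs / 5 emergencies),
runs all three methods on every scenario, and prints the per-case
comparison (match counts, total match times, unique emergencies covered)
plus the greedy-vs-fair showcase result:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Scope

No live phone/AED-registry feeds, no map-routing API calls (precomputed
route-distance matrices are supported instead), no service layer, and no
reproduction of hardware-bound wall-clock timings. See the methods vignette
(`vignettes/responder-matching.Rmd`) for the model details, generator
assumptions and known limitations.
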