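---
title: "Planning cooperative follow-up networks: model, algorithm, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning cooperative follow-up networks: model, algorithm, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coopselect)
```

## The planning problem

After discharge, patients need scheduled follow-up — some visits at a
community facility, some at home. A general hospital delegates this work to
a two-tier community network: regional medical centers (RMCs) hold the
contracting authority, and each primary health center (PHC) is subordinate
to exactly one RMC. Contracting any facility under an RMC triggers that
RMC's annual contracting fee once, no matter how many of its PHCs
participate.

The decision has four coupled parts: which facilities to select (`x`),
which RMC contracts that implies (`y`), how community demand points are
allocated to facilities (`z`), and how much annual service capacity to
provision at each facility (`w`). Two costs are minimized jointly:

* **Patient cost** `f1`: over all patient types `k`, facilities `i` and
  communities `j`, the travel cost of facility visits
  (`F_k1 * h1_per_dist * d_ij`) plus the patient-side cost of receiving
  home visits (`F_k2 * h2_base`), weighted by `n_j * p_jk` and the
  assignment `z_ij`.
* **Hospital cost** `f2`: the contracting bill `C1 * sum(y)`, the service
  delivery cost (`F_k1 * c1_base` per facility visit plus
  `F_k2 * c2_per_dist * d_ij` per home visit, staff travel being
  distance-proportional), and the capacity provisioning bill
  `C2 * (F_k1 e_k1 + F_k2 e_k2) * n_j * p_jk`.

Constraints: every community is assigned to exactly one facility;
assignment implies selection; selection implies a contract at the
supervising RMC; a facility's induced workload may not exceed its
provisioned capacity `w_i`.

Because `w_i` is itself a decision variable whose only effect on the
objectives is through the `C2` term — which is driven by the assignment,
not by `w` — the cheapest feasible choice is always `w_i` equal to the
induced workload. The package fixes `w` at that value when it constructs
plans; an optional exogenous `capacity_cap` reintroduces a binding ceiling
for scenarios where facilities have hard throughput limits.

## Default parameters

`default_parameters()` returns the baseline single-type setting used by
the synthetic studies:

| parameter | meaning | value | unit |
|---|---|---|---|
| `C1` | contracting an RMC, per year | 10,000 | currency/year |
| `C2` | one capacity unit | 50 | currency/unit |
| `F1`, `F2` | facility / home visits | 6, 10 | visits/(patient·year) |
| `e1`, `e2` | capacity per facility / home visit | 2, 3 | units/visit |
| `c1_base` | hospital cost per facility visit | 80 | currency/visit |
| `c2_per_dist` | hospital cost per home visit | 60·d | currency/visit |
| `h1_per_dist` | patient travel per facility visit | 30·d | currency/visit |
| `h2_base` | patient cost per home visit | 50 | currency/visit |

Currency and distance are deliberately abstract units; no conversion layer
is provided. One patient-year of follow-up consumes
`F1*e1 + F2*e2 = 42` capacity units — a handy sanity number that several
tests lean on. Distance-dependent costs default to the affine forms above;
fully general per-(facility, community, type) cost tables can be supplied
as overrides when calibrated data exist.

Travel distance is Euclidean when computed from coordinates. Real road
networks are not modeled; an explicit distance matrix can be passed in
instead and always takes precedence, which is the supported route for road
distances.

## Proximity allocation and repair

Given a selection, each community is served by the nearest selected
facility; distance ties break toward the facility earlier in file order,
which keeps every operation deterministic. With a `capacity_cap`,
communities are processed in decreasing annual workload and each takes the
nearest selected facility whose residual capacity absorbs its whole
workload — a community is never split, matching the binary assignment.
The processing order is a design choice (largest-first packs tight
instances more reliably and is deterministic); the model itself does not
dictate one.

The evolutionary representation is a vector of random keys in `[0,1]`, one
per facility, decoded at threshold 0.5. After decoding, two repairs apply:

1. an all-zero selection force-selects the facility with the largest key
   (repair can only remove facilities, so the empty selection needs its
   own rule);
2. any selected facility that receives no community under proximity
   allocation is deselected and its key pushed below threshold. Removed
   facilities served nothing, so the allocation itself needs no recompute.

Random keys were chosen over a raw binary encoding so that the standard
simulated-binary-crossover (index 2) and polynomial-mutation (index 5)
operators apply literally; a pure binary mode (uniform crossover, per-gene
bit flip) is available through `engine_config(operator = "binary")` for
comparison.

## NSGA-II configuration

Defaults: population 100, 500 generations, crossover probability 0.9,
mutation probability `1/n` per gene. Parent selection runs 100 independent
probabilistic binary tournaments per generation; the individual with the
better (rank, crowding) pair wins with probability 0.9. A "tournament of
100 individuals" reading would make every tournament span the whole
population and collapse diversity, so the 100-independent-binary reading
is the implemented one. Environmental selection is the usual
(mu+lambda) truncation by non-dominated rank and then crowding distance.
The reported front is the final population's first front, deduplicated by
selection vector.

Evaluation of a decoded selection is memoized within a run: the
decode–repair–allocate–evaluate map depends only on the decoded selection,
so the cache changes nothing but wall time.

## Exact oracle and validation sizes

`enumerate_front()` enumerates every non-empty selection (guarded at 16
facilities), applies the identical plan construction, deduplicates by
repaired selection and keeps the non-dominated set. The test suite uses it
to require, on 25 seeded miniatures of the district generator (at most 10
facilities and 10 communities each), that every objective vector the
engine returns is exactly Pareto-optimal and that 20 seeds jointly recover
at least 90% of each exact front. Those engine runs use population 100 for
100 generations — on instances with at most `2^10 - 1` selections that
budget samples the space many times over, and it keeps the whole
validation suite to a few minutes.

## Indicator protocols

Two deliberately distinct protocols:

* **Benchmarking** (`indicator_report()`, `run_benchmark()`): all runs'
  fronts are pooled into a union reference front; min–max normalization
  uses that pool's bounds, so the reference front spans the unit square;
  hypervolume is measured against `(1.2, 1.2)`, IGD against the normalized
  reference front, and spacing as the sample standard deviation of
  nearest-neighbor distances (Euclidean by default, Manhattan available —
  the literature has both variants and neither is canonical). Results are
  reported per run with mean ± standard deviation.
* **Sensitivity** (`sensitivity_hv()`, `run_sensitivity()`): hypervolumes
  are computed in *raw* objective units against a single global reference
  point shared by every scenario of a sweep — the component-wise maximum
  of the pooled scenario fronts (an optional relative margin can inflate
  it; the default is the exact maximum). Sharing the point is what makes
  the per-level hypervolumes comparable; raw units are used because the
  quantity of interest is the absolute trade-off surface, not a
  normalized score. Sweeps reuse the same seed list at every level so
  that hypervolume differences reflect the parameter, not sampling noise.
  With common seeds and pooled per-level fronts over three seeds the
  declines along the `C1`, `C2`, `F1` and `F2` sweeps are monotone; the
  acceptance suite runs these at 150 generations, again a size chosen to
  keep a 16-run sweep within minutes at district scale.

The 2-D hypervolume is an exact sort-and-sweep over the non-dominated
subset; tests cross-check it against a `1e6`-sample Monte-Carlo estimate
of the dominated area.

## The synthetic district generator

No instance data for the motivating district are published, so
`generate_instance()` emulates its structure: `wuhou_like_config()` gives
29 candidate RMCs each supervising one to three PHCs scattered around it,
28 communities totalling 726 discharged patients per year, and the default
parameters. Four dense communities in the eastern core carry an expected
60% of the patients (a Dirichlet-multinomial split keeps the total exact);
the remaining communities are scattered uniformly. The 60% share and the
one-to-three PHC range are the generator's own calibration of the
qualitative "few dense, many sparse" pattern — the source setting reports
the pattern, not the numbers.

What the generator does *not* emulate: road-network travel times,
correlated demand across neighboring communities, heterogeneous per-type
case mixes in the preset (it uses a single patient type, as the baseline
parameterization does), and any capacity ceilings. Passing tests on
generated instances therefore validates the optimization machinery, not
the calibration of any real district.

## Numerical choices and degenerate inputs

* Type-mix rows must sum to 1 within `1e-9`; distances must be
  non-negative; capacity feasibility uses a `1e-9` slack.
* Distance and crowding ties break deterministically (file order /
  stable order), so every run is reproducible from its seed.
* A selection that decodes to all-zero is never evaluated as such — the
  argmax-key facility is forced in.
* One-facility instances short-circuit to the single forced plan.
* Objective matching against the exact oracle uses an absolute `1e-6`
  tolerance, far below any cost scale in the instances.

## Limitations

Assignments are binary (no community splitting), costs are linear in
distance and volume, demand is deterministic, and the planning horizon is
a single year. The comparison algorithms sometimes used as external
baselines (strength-Pareto and decomposition-based solvers) are not
implemented; `run_benchmark()` scores their fronts when supplied from
outside. Hypervolume beyond two objectives is out of scope.
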