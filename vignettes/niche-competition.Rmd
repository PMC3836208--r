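---
title: "The niche-competition model of T-cell homeostasis and its transformation-assay screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The niche-competition model of T-cell homeostasis and its transformation-assay screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Mature T cells depend on prohomeostatic stimuli delivered by
antigen-presenting cells when a T-cell receptor (TCR) engages a
self-peptide–MHC complex (spMHC). `tniche` treats each distinct spMHC as a
*niche* supplying such stimuli ("resources") at a constant rate, and each
TCR-defined clone as competing for them. To model oncogenic transformation
assays, every clone is represented by two *species* — its healthy cells and
its preleukemic (oncogene-transduced) cells — which share a preferred niche
but may differ in all competition parameters.

Three equations define the dynamics. A niche `j` with supply `p_j` splits
its resources among species in proportion to affinity-weighted abundance:

$$r_{ij}(t) = \frac{a_{ij}\,c_i(t)}{\sum_k a_{kj}\,c_k(t)}\; p_j
\quad\text{if } \textstyle\sum_k a_{kj} c_k(t) > 0,\qquad 0
\text{ otherwise.}$$

The acquired resources set a time-varying carrying capacity through the
resource-utilization efficiency $v_i$ (cells sustainable per resource unit
per hour):

$$k_i(t) = v_i \sum_j r_{ij}(t),$$

and abundances follow logistic growth with minimum cell-cycle time $\tau$:

$$\frac{dc_i}{dt} = \frac{c_i}{\tau}\Bigl(1 - \frac{c_i}{k_i}\Bigr)
\quad\text{if } k_i > 0,\qquad 0 \text{ if } k_i = 0.$$

Because $k_i \propto c_i$ (a species' intake scales with its own
abundance), the per-capita growth rate depends only on the *relative*
competitive position, and the total pool is bounded by
$\max_i v_i \cdot \sum_j p_j$.

The affinity matrix `A` has a preferred-niche structure: clone `i` prefers
niche `i` (this pairing requires `n = q`), with affinity `s + u` there and
`u` everywhere else, separately parameterized for healthy (`s_h`, `u_h`,
`v_h`) and preleukemic (`s_p`, `u_p`, `v_p`) species. Biologically, `s` is
read as affinity for cognate self-peptide, `u` as affinity for MHC itself
(or reliance on public resources such as IL-7), and `v` as growth-signal
utilization efficiency.

## Parameters, units and defaults

| parameter | default | unit / meaning |
|---|---|---|
| `q = n` | 100 | clones and niches (one preferred niche per clone) |
| `p_j` | 100 | resource units per niche per hour |
| `tau` | 8 | h; minimum cell-cycle time of vigorously proliferating T cells |
| `s_h` | 1 | healthy specific affinity (0.2 and 5 probe niche-regulation strictness) |
| `u_h` | 1/n = 0.01 | healthy unspecific affinity |
| `v_h` | 1 | healthy efficiency; makes `v_p` a relative measure |
| `s_p, u_p, v_p` | = healthy | varied as fold-changes in the screen |

Resource allocation depends on relative affinities only (rescaling a niche
column of `A` changes nothing), so one affinity may be anchored freely:
`u_h = 1/n` is the reference. With these defaults the physiological pool
holds $v_h \sum_j p_j = 10^4$ cells, 100 per clone — a deliberately scaled
miniature (real murine repertoires have ~10^6 clones and ~10^8 cells; the
100-clone system preserves the ~100 cells/niche ratio and the niche-based
regulation structure).

## In-silico transplantation

`make_initial_state()` emulates transplantation of 500 cells into an empty
system. Scenarios P1, P10 and P100 make 1, 10 or 100 of them preleukemic
(the experimentally transduced fraction is unknown). Polyclonal grafts
place the preleukemic cells one per clone in species `q+1..q+n_pre`; the
healthy remainder is distributed over all `q` healthy species either
evenly (deterministic default: as equal as possible, remainder to the
lowest clone indices) or by a seeded uniform multinomial draw, which
reproduces the randomized protocol. Monoclonal grafts put everything into
clone 1. The even default was chosen because the steady state is
independent of initial abundances for all species present (a property the
test suite verifies rather than assumes), making determinism free of cost.

## Integration and the steady-state criterion

The engine is a Dormand–Prince 5(4) adaptive stepper with fourth-order
dense output, implemented in compiled code (`src/engine.cpp`) with
tolerances `rtol = 1e-8`, `atol = 1e-10`. Steady state is declared from
states sampled on a fixed hourly checkpoint grid: the run converges at the
first checkpoint where the relative change of every species over the
preceding hour falls below `1e-6`. Tying the criterion to a fixed grid
(rather than to internal solver steps) keeps it well-defined regardless of
step-size adaptation. Runs that do not meet the criterion by `t_max`
(default `1e6` h) are flagged, not failed, and classified from the capped
state.

Numerical choices worth knowing:

* **Abundance floor.** The logistic never reaches 0 in finite time, so
  abundances below `1e-9` cells are clamped to exactly 0 at checkpoints.
  This lets the zero branches of the equations engage, and prevents a
  species decaying forever at a constant relative rate from blocking the
  convergence criterion. The relative-change denominator uses
  `max(previous, floor)`, so extinct species compare cleanly.
* **Forward invariance.** A species at exactly 0 has derivative exactly 0
  in all integrator stages; negative round-off excursions are clamped at
  checkpoints.
* **Events.** Proportional cell kills are applied at checkpoint times; the
  recorded state at the event time is the pre-kill state, and integration
  restarts from the post-kill state, which also resets any previously
  declared convergence.
* **Cross-checks.** The engine is validated in the tests against the
  closed-form scalar logistic (single species, single niche, where
  `k = v p` is constant) and against an independent `deSolve::lsoda`
  integration of the same right-hand side composed from the package's own
  R-level equation functions.

## The class-reduced fast path

The screen integrates ~4×10^5 systems, so the default path exploits an
exact symmetry. Under even allocation the 200-species system partitions
into exchangeable classes: monoclonal runs involve only {healthy clone 1,
preleukemic clone 1} × {preferred niche, the `n−1` others}; polyclonal runs
involve {healthy clones with a seeded preleukemic sibling, healthy clones
without, seeded preleukemic species} × {niches preferred by seeded clones,
the rest}. Members of a class see identical dynamics, so the system reduces
to 2–3 ODEs with class-aggregated affinities (for one niche, the summed
affinity of all members of a species class; for one member, its summed
affinity over all niches of a niche class).

Within-class initial abundances are not perfectly equal under even
allocation (e.g. P10 polyclonal: 80 unpaired healthy clones start with 5
cells and 10 with 4); the reduced system starts each class at its mean.
Because the steady state does not depend on initial abundances of species
that are present, the reduced and full systems converge to the same steady
state — which is what the screen classifies. This equivalence is enforced
in the acceptance tests on 200 randomly drawn grid points
(`method = "reduced"` vs `method = "full"` in `evaluate_parameter_set()`),
with totals and preleukemic fractions agreeing to 1e-4.

## The screen and its classification

`make_fold_grid()` generates the 41 fold-changes `1.2^k`, `k = −20..20`
(20% relative spacing, exactly centred on 1, spanning ~1/38.3 to ~38.3).
The screen crosses this grid over `s_p`, `u_p`, `v_p` for each scenario —
206,763 parameter sets for the standard three-scenario screen — and runs
the monoclonal and polyclonal transplant for each. Outcomes are classified
against the physiological reference `v_h Σp_j`:

* monoclonal *premalignant*: total ≥ 300% of reference AND preleukemic
  share ≥ 80%;
* polyclonal *controlled*: total ≤ 120% of reference AND share ≤ 50%;
* *consistent* = premalignant (mono) AND controlled (poly).

The "at least/at most" wording is taken as inclusive; an empty system has
preleukemic share 0 by convention (trivially controlled, never
premalignant). Records are emitted in deterministic (scenario, `s_h`,
lexicographic grid) order; slices are persisted per `s_fold` value when an
output directory is given, making interrupted sweeps resumable.

## Post-processing

`summarize_consistent()` reports, per scenario: the consistent-set count,
the minimum `v_fold`, whether all `u_fold` (and `s_fold`) are below 1, the
fraction of sets with `s_fold < u_fold` (specific affinity decreased more
strongly than unspecific), and octant membership by the sign pattern of the
log folds — fold exactly 1 counts as neither decreased nor increased, a
relevant distinction because the grid contains 1 exactly.
`fit_uv_band()` operationalizes the tight `u`–`v` relation among consistent
sets as a minimal enclosing parallel band in log–log space: the common
slope is least-squares fitted through the per-`v_fold` midpoints of the
`log u_fold` range and the two intercepts are the extreme residuals. The
band is descriptive, not inferential — no fitting procedure is implied by
the phenomenon itself.

## What the tests do and do not show

The simulated assay is deterministic and uses a deliberately miniaturized
repertoire with homogeneous niches, a single fully effective oncogenic hit,
and no heterogeneity within the preleukemic compartment. Passing tests
therefore demonstrate internal correctness (equations, integration,
classification, symmetry reduction) and reproduction of the model-level
findings — the physiological steady state of 100 cells/clone, recovery
from a 99% kill, the consistent region's size (to within a few percent)
and its characterization (u decreased everywhere, s decreased in P10/P100,
v increased at least ~3.6-fold, count ordering across
`s_h ∈ {0.2, 1, 5}`). They do not validate the biological hypothesis
itself, multi-hit oncogenesis, B-cell dynamics, heterogeneous niches, or
stochastic clonal extinction — all outside this model class.

Problem sizes used by the test suite are the production sizes: full 41³
grids per scenario at `s_h = 1` and additional full P100 grids at
`s_h = 0.2` and `5` (the robustness comparison is made within one scenario,
where the count ordering is already expressed). The consistent-set count of
this implementation is within a few percent of the reported 1050; residual
differences trace to unreported details of the original convergence
checking and solver, not to the classification thresholds, which are exact.
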