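---
title: "State space grids: models, measures, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{State space grids: models, measures, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssgrid)
```

## The data model

`ssgrid` works on *trajectories*: ordered streams of coded events, each with
an onset in seconds and one category per coding dimension. The coding scheme
is assumed mutually exclusive and exhaustive within each dimension, and the
stream itself exhaustive in time — an event lasts until the next one starts
(the last until the session offset), so the system occupies exactly one
joint state at every instant. This is the natural model for unitized
observational coding (e.g. one code per verbal thought unit plus the
speaker), and it is what makes durations well-defined without storing them:
durations are onset differences, so all measures are invariant to
translating the clock.

Three consequences of this model are enforced rather than assumed:

* onsets must be strictly increasing and the offset must exceed the last
  onset (every event has positive duration);
* missing category values are rejected, not imputed — a gap would break the
  "some state at every instant" premise that dispersion and the duration
  entropy rely on;
* sub-second event durations are flagged with a warning but accepted. Time
  units of at least one second are the usual recommendation for coded
  interaction; enforcing it as an error would reject legitimately
  fine-grained data, so the reader only warns.

Files are read in two dialects: a GridWare-style tab-separated `.trj`
(header `Onset`, one dimension per column, final row = terminal offset) and
a long-format CSV/TSV carrying a `trajectory_id` column. Because exported
`.trj` files vary in whether the terminal row repeats the last categories,
the reader ignores any labels on that row. The writer formats onsets with
three decimals; the simulator generates onsets on the millisecond grid, so
write–read round-trips are exact for everything the package produces. Data
with meaningful sub-millisecond structure would lose digits on rewrite —
out of scope for frame-based video coding.

## From events to visits

A *visit* is a maximal run of consecutive events in the same cell, computed
by run-length collapse. Visits, not events, are the unit of dynamics: the
move from one visit's cell to the next (always a different cell) is a
*transition*, and a sequence of $v$ visits has exactly $v-1$ transitions.
Collapse conserves both time and event counts exactly, which the test suite
asserts to $10^{-9}$ against a separately coded event-loop oracle.

Time windows are half-open $[t_0, t_1)$, so adjacent windows partition the
session with no instant counted twice. An event straddling $t_0$ is kept
with its onset clipped to $t_0$: the system must start the window in some
state, and dropping the straddler would create a gap. The alternative
(dropping boundary events) is not used anywhere; per-cell durations of
adjacent slices therefore add up exactly to the full-trajectory durations,
which is both a test invariant and the practical guarantee behind
windowed-measure tables.

## Structure measures and their numerical conventions

**Dispersion.** $D = 1 - \frac{n\sum_i p_i^2 - 1}{n-1}$, where $p_i$ is
cell $i$'s share of total duration and $n$ is the cell count *of the defined
state space* — visited or not, and never including any display padding.
Using all defined cells is what makes the anchors exact: $D = 0$ for
single-cell occupancy and $D = 1$ for a uniform spread over all $n$ cells.
A 1-cell space leaves $D$ undefined, so spaces require $n \ge 2$.

**Entropies.** All three entropies use the Shannon form
$H = -\sum q \ln q$ in natural log. The log base is a genuine convention
choice; natural log is adopted because it reproduces the standard worked
example: visit proportions $\{0.2, 0.2, 0.2, 0.1, 0.1, 0.1, 0.1\}$ give
$H = 1.89$ nats. Zero-probability terms contribute zero
($0\ln 0 := 0$), so unvisited cells never enter. Transition entropy is
computed over the empirical distribution of distinct ordered
$(\text{from}, \text{to})$ cell pairs; this is one reasonable reading of a
measure whose exact estimator differs between software packages, and it is
flagged as a compatibility caveat — comparisons across tools should
recompute rather than mix sources. A single-visit sequence has no
transitions and `transition_entropy()` refuses it rather than returning 0.

**Pooling.** Pooled measures over a collection sum tallies (visits,
durations, transition types) before forming proportions. Transitions are
never counted across trajectory boundaries: pooled transitions are
$\sum_t (v_t - 1)$.

Reported values are never rounded internally; any 2-decimal display is
presentation only.

## Attractor quantification

**Return statistics.** An excursion runs from leaving a region (the end of
the last inside visit) to next entering it (the start of the next inside
visit); its return time is the elapsed time outside and its return visits
the number of outside visits. A trailing excursion that never returns is
*censored*: it is counted in `n_excursions` (so exits always equal
completed + censored) but excluded from the means, and its count is
reported so users can judge the truncation. Including censored spells in
the mean would bias return times toward the session end; dropping them
silently would hide how often the system left for good.

**Winnowing.** Starting from all visited cells, each screen removes the
cell(s) of minimal total duration — ties removed together, so the procedure
is invariant to cell ordering — and recomputes a heterogeneity score over
the survivors: with expected duration $E$ = (remaining total)/(remaining
count), $\chi^2$-style $\sum (O - E)^2 / E$. Screening stops when fewer
than two cells would remain. The *uniform*-expectation reading (rather than
a row-by-column independence expectation) is implemented; both appear in
the literature's sketches of the procedure, and the uniform form is the one
consistent with screening on total durations alone. The selected screen is
the last one whose proportional heterogeneity increase over its predecessor
is at least `stop_ratio` (default 0.5); a screen-0 selection means no
removal produced a marked separation. The stopping rule is an explicit
operationalization knob — the full screen log is always returned so any
alternative rule can be applied post hoc without recomputation. Duration
ties use an absolute tolerance of $10^{-12}$ s.

## Visualization

Plot specifications are pure data (node positions, radii, order, arrows)
separated from rendering, so a figure can be serialized to JSON, nudged by
hand via per-node offsets, and re-rendered identically. Node size encodes
event duration by area with a visibility floor:
$r^2 = r_{\min}^2 + (r_{\max}^2 - r_{\min}^2)\, d / d_{\max}$, which keeps
the radius strictly increasing in duration while guaranteeing every event
stays visible. Within-cell jitter is seeded, drawn one $(dx, dy)$ pair per
node in event order so a node's position does not change as later events
are added — that is what keeps nodes fixed across cumulative movie frames —
and clamped so no disc crosses its cell boundary. The optional padding row
and column some SSG displays add are drawn off-scale in gray when requested
and are never part of the state space or any measure.

## The synthetic generator

The simulator is a semi-Markov model: an embedded Markov chain over cells
(row-stochastic, zero diagonal — a visit ends only by changing cell, so
"staying put" is dwell time, never self-transition mass) plus a dwell-time
distribution per visit. Defaults: exponential dwells (memoryless, the
standard null model for continuous-time state occupancy), with gamma
available for over-dispersed dwells and fixed for deterministic ones.
Attractors are planted through per-cell attraction weights, an optional
same-row stickiness multiplier (modelling runs of same-type talk), and
per-cell dwell means. All randomness flows from one explicit seed and the
global RNG state is restored afterwards.

The two-team meeting fixture emulates 55-minute coded meetings on a
5-speaker × 7-behavior grid with 4-second mean dwells (sentence-length
thought units) and a 0.2 visit-splitting probability so events outnumber
visits, as in real unitized codings. The `"concentrated"` team has unequal
speaker weights (two dominant speakers, one quiet) and strong relational-row
stickiness; the `"even"` team shares the floor uniformly. These parameters
are fixed as the package's study conditions, not tuned: they are meant to
land multi-party meetings in the flexible-interaction regime (dispersion
above 0.9) with a visibly larger spread of speaker time shares for the
concentrated team, which the tests check at a fixed seed.

What the generator does *not* emulate: codes with serial dependence beyond
first order, nonstationarity within a session (phase transitions), coder
disagreement/noise, or missing data. Passing tests on synthetic data
therefore demonstrate the *measures* are computed correctly and recover
planted structure — not that any particular real team behaves like the
model.

## Problem sizes and tolerances in the test suite

The suite runs 100-file I/O round-trips, 100-trajectory oracle-equivalence
sweeps (5–40 events each), 1000 random duration vectors for the dispersion
formula, one 10,000-visit chain for stationary-distribution and
transition-recovery checks, and 50 seeded planted-attractor runs of 120
visits; these sizes give stable statistics while keeping the full suite in
the low minutes on one core. Real-valued comparisons use $10^{-9}$;
counting measures are compared exactly.

## Known limitations

* Only two-dimensional grids: higher-dimensional joint codings must be
  collapsed or crossed into two dimensions first.
* Transition-entropy compatibility across software is not guaranteed (see
  above); dispersion and visit/duration entropy are formula-exact.
* No statistical inference (between-team tests, bootstrap bands) — measure
  tables are exported as CSV for analysis elsewhere.
* No fitting of the semi-Markov model to observed data; the generator is
  for simulation only.
* The winnowing stop rule is heuristic by construction; use the screen log
  when attractor membership matters.
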