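---
title: "Dynamic segmentation and stigmergic activity modelling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic segmentation and stigmergic activity modelling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stigmar)
```

## The problem and the model

A smart home instrumented with binary motion and door sensors emits a stream
of timestamped events. Online activity recognition must label *every* event
with the activity of daily living in progress, using only the stream's past.
The method implemented here decomposes into an offline phase (fitted
statistics), an online segmentation rule, a feature construction, and a
pluggable classifier.

### Offline phase: the correlation model

Fitted on labelled training data by `fit_correlation_model()`:

* **SCM** — the sensor correlation matrix. `MI(Si, Sj)` is the fraction of
  sliding windows of `ws` consecutive events (stride 1) that contain at
  least one event of each sensor. Counting joint *presence* rather than
  adjacency makes the measure robust to route variation within an activity:
  two sensors used by the same activity correlate even if rarely triggered
  back-to-back. The matrix is symmetric with entries in [0, 1].
* **SCT** — per-sensor correlation thresholds. The floorplan-informed rule
  takes, for each sensor, the SCM value of its *geographically critical*
  neighbour (`key_sensor` mode). Because that choice requires layout
  knowledge that data alone cannot supply, the package also offers a
  layout-free surrogate: the k-th largest off-diagonal value of the sensor's
  SCM row (`sct_rank` mode). With `k` roughly the number of same-area
  neighbours, the threshold sits just below the weakest same-area
  correlation, which is the intent of the original rule.
* **MTI** — for each *ordered* pair of sensors observed in consecutive
  events, the mean plus twice the standard deviation of the inter-event
  gaps. The ordered reading matters: the gap distribution of "kitchen then
  hallway" need not match "hallway then kitchen". Pairs never observed in
  training fall back to the global mean + 2 sd over all consecutive gaps —
  an unseen transition should not truncate every window that meets it.
* **MTS** — per functional area, the mean plus twice the standard deviation
  of the durations of the activity instances assigned to that area.
  Activities without a configured area are assigned to the area where the
  majority of their own training events fire (with a warning); areas with no
  instances receive the global 2-sigma duration.

### Online segmentation

For the newest event `E_i`, the window starts as `{E_{i-1}, E_i}` — the
previous event is admitted unconditionally, exactly as the procedure's
initialization prescribes, even when it would fail the checks. Candidates
`E_j` are then scanned backwards from `E_{i-2}`; each must pass the sensor
correlation check (`SCM(Sj, Si) >= SCT(Si)`, with `Sj == Si` always passing)
and the time correlation check (gap to the current head within
`MTI(Sj, Sfirst)`, window span within `MTS` of the target's area, equality
passing on both). The first failure stops the scan: correlation is required
of the *contiguous* past, not of any correlated event anywhere in history.
The very first stream event yields the singleton window.

Fixed-size (`ws` events) and fixed-interval (`dt` seconds) windows are
provided as the standard baselines.

### Stigmergic features

Each ON/OPEN event in the window is a *trigger*; its activation runs from
the ON time to the first subsequent OFF/CLOSE of the same sensor, capped at
the window end time `Te` (and equal to `Te` when no OFF arrives in time —
the sensor is still active). Triggers trace a directed path through the
sensors; the edge into the first trigger comes from the last sensor
activated before the window (a self-loop at the start of a stream). Each
activation deposits, on its incoming edge, the intensity

$$I \;=\; \sum_{t=t_s}^{t_e-1} (1-\rho)^{T_e-t-1}
      \;=\; \frac{(1-\rho)^{T_e-t_e} - (1-\rho)^{T_e-t_s}}{\rho},$$

with the `rho = 0` limit `te - ts`. Repeated edges accumulate by summation
and the matrix is not normalized: total pheromone mass is itself
informative (it is the decay-discounted occupancy of the window). The
flattened S x S matrix is the classifier input; the baseline feature vector
keeps only per-sensor activation durations.

## Tunable parameters

| parameter | units | default | rationale |
|---|---|---|---|
| `ws` (SCM window) | events | 15 | the strongest fixed-window setting for duration features in our experiments and a common choice for event-based windowing; exposed because no principled universal value exists |
| `sct_rank` / `key_sensor` | — | rank 1 | rank mode needs no floorplan; choose k near the same-area neighbour count (the mini-home tests use k = 2 for 3-sensor areas) |
| `rho` | per `time_step` | 0.1 | strong enough that context older than ~1 min (at 1 s steps) is heavily discounted, weak enough that a typical window retains structure; `rho = 0` recovers pure durations |
| `time_step` | seconds | 1 | the natural grid for second-resolution logs |
| `ws` (fixed baseline) | events | 20 | the best fixed-window setting for non-volatile network features in our experiments |
| `dt` (time baseline) | seconds | 60 | of the order of short ADLs |
| `max_lookback` | events | 200 | the procedure itself has no cap; the cap bounds worst-case online latency when thresholds are degenerate (e.g. an all-zero SCT row). At 200 it is far above every window the tests produce |
| `sd_type` | — | population | see numerical choices |

## The simulator, and what passing tests do not show

`simulate_stream()` emulates the statistical structure the method exploits:
sensors grouped into functional areas; activities that random-walk over
their own area's sensors with log-normal dwells (mean 8 s); ON/OFF pairs per
firing; activity durations drawn per activity (normal, one to five minutes,
truncated positive); exponential inter-activity gaps (mean 180 s) with a few
unannotated "wander" firings; and a cross-area noise rate `epsilon`
(default 0.05) for mislocated firings. Everything is a deterministic
function of the seed, and begin/end annotations are written exactly as in
CASAS logs.

It does *not* emulate: multi-resident interleaving, sensor failures or
chatter, diurnal schedule structure, activities spanning several areas, or
realistic human mobility. Tests passing on this generator therefore
demonstrate the *mechanics* (the statistics recover the generating
parameters; segmentation respects its gates; features encode what they
claim) and the method's *qualitative* behaviour (dynamic windows plus
volatile network features dominating the baselines), not field performance
on real homes.

Test problem sizes are the package's own choice for tight feedback loops:
statistical properties use 150–200 simulated activity instances
(4,000–7,000 events); the cross-validated ordering checks use five seeds of
120 instances with 5-fold contiguous cross-validation.

## Numerical choices

* **Standard deviation** in the 2-sigma thresholds is the population form
  (divide by n), with a single observation defined as spread 0; it is the
  plug-in moment of the observed distribution, is deterministic, and never
  produces NA. The sample form is available via `sd_type = "sample"`.
* **Boundary equality passes** both time gates (a gap exactly equal to MTI
  keeps the candidate), matching the `>= 0` formulation of the checks.
* **Grid flooring**: times are floored to the `time_step` grid before the
  decay computation, so exponents are integers and the closed form equals
  the explicit sum to machine precision (verified to 1e-12 relative on
  random tuples). The `rho = 0` branch consequently returns the grid
  duration, identical to `te - ts` for whole-second data.
* **Zero-denominator metrics**: a class never predicted gets precision 0
  (with a warning), keeping the support-weighted means defined.
* **Overlapping annotation spans** resolve to the innermost (most recently
  opened) activity, with a warning — deterministic and auditable; an `end`
  without a `begin` is an error; a `begin` left open at the stream end is a
  warning.
* **Timestamps** are real seconds from the stream's first midnight, so
  windows and durations crossing midnight are correct; the per-day clock is
  kept as a display field.

## Design decisions where the procedure is silent

* **Activation closure** (`te`): the first subsequent same-sensor OFF at or
  before `Te`, else `Te`. This is the only reading that reproduces the
  documented example weights, including the final edge whose activation is
  still open at the window end.
* **Previous-location lookback** for the first edge uses the global stream,
  not just the window — again required by the documented example — and
  falls back to a self-loop at the stream start.
* **Cross-validation folds are contiguous time blocks**, with the offline
  statistics refitted per fold on training blocks only and training targets
  whose windows cross a fold boundary dropped. Shuffled folds would leak
  near-duplicate neighbouring events between train and test. Held-out events
  may use earlier events (of any fold) as window *context*: that is the
  online deployment condition, and no label information flows.
* **Reference classifier**: multinomial logistic regression on flattened
  features (softmax-linked single-layer network, L2 decay 1e-4), trained
  full-batch under a fixed seed — deterministic, seconds on one CPU. The
  published pipeline tops this with a convolutional-recurrent network whose
  architecture is unspecified; the classifier slot accepts any `fit`/
  `predict` pair, so such a model can be plugged in without touching the
  rest.
* **Per-event classification**: every event's window is classified by
  default; a subsample can be taken via the `targets` argument.

## Known limitations

* The SCM costs O(N·S) per fit and the per-event segmentation is a scan
  bounded by `max_lookback`; both are fine for tens of thousands of events
  in pure R but a large deployment would want the inner loops compiled.
* The rank-mode SCT is a surrogate: on floorplans with very unequal area
  sizes a per-sensor `key_sensor` map remains preferable.
* Sensors never seen in training have no SCM row support (their
  correlations are 0), so they only ever form minimal windows.
* The simulator's single-resident assumption means the package's evidence
  for multi-resident streams is exactly none.
* Door sensors are treated like motion sensors (uniform binary semantics);
  dwell-like OPEN periods (a door left open) inflate their activation
  durations, which the volatilization rate mitigates but does not remove.
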