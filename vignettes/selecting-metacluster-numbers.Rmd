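---
title: "Selecting metacluster numbers by unimodality profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting metacluster numbers by unimodality profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inflectr)
```

## The problem

Unsupervised clustering of mass-cytometry data has no natural stopping rule.
FlowSOM-style pipelines first *overcluster* events into a grid of SOM nodes
and then merge nodes into a user-chosen number of metaclusters; too few
metaclusters mix distinct cell populations, too many fragment real
populations and dilute statistical power in downstream abundance testing.

inflectr turns the choice into a measurement. Its premise: a metacluster that
captures one cell population shows, for every marker, a distribution that is
*unimodal* and *narrow*. A metacluster that mixes populations shows
multimodal or broad marker distributions. Scoring every candidate
metaclustering by the fraction of marker distributions that pass both checks
yields a curve that rises steeply while real populations are being separated
and plateaus once they are; the knee of that curve is the optimal
metacluster number.

## The procedure

For a dataset of events $\times$ markers on the $\operatorname{arcsinh}(x/5)$
scale:

1. **Overcluster** into $k$ SOM nodes (`train_som()`, online learning on a
   rectangular grid with a bubble neighbourhood). $k$ should comfortably
   exceed any plausible population count — around 200 by default — so that
   even small subsets occupy their own nodes.
2. **Metacluster** the $k$ node prototype vectors into $m$ groups for every
   target $m$ in a schedule (`build_schedule()`), either by Ward linkage on
   Minkowski distances cut from a single dendrogram (`hierarchical_metacluster()`)
   or by Monti-style consensus resampling (`consensus_metacluster()`). The
   consensus backend caps targets at $\lfloor 0.9k \rfloor$ because each
   resample must retain more items than clusters.
3. **Score** each endpoint (`evaluate_metaclustering()`): for every
   metacluster $c$ and QC marker $j$, the marker's distribution over the
   metacluster's events passes if the Hartigan dip test does not reject
   unimodality at level $\alpha$ *and* the interquartile range is at most a
   threshold on the transformed scale. The unimodality fraction
   $U = \#\text{passes} / (m_\text{realized} \cdot n_\text{markers})$
   condenses the $m \times n$ pass/fail matrix to one number; the set
   $\{(m_i, U_i)\}$ over the schedule is the unimodality set.
4. **Locate the knee** (`find_inflection()`): fit a four-parameter logistic
   to the unimodality set, evaluate it on the integer grid spanning the
   targets, and apply the Salvador–Chan L-method — for every candidate split,
   fit a straight line to each side and take the split minimising the
   length-weighted total RMSE. The knee's x-coordinate is the optimal
   metacluster number.

## The dip statistic

No dip-test implementation is depended upon; the statistic is computed
exactly in compiled code (`dip_statistic()`). The dip of a sample is the
smallest sup-norm distance between its empirical CDF and any unimodal CDF —
any distribution function convex left of its mode and concave right of it,
with an atom permitted at the mode. Feasibility of a distance $d$ reduces to
chord conditions on the ECDF jump points: the greatest convex minorant of the
upper tube bounds must clear the lower bounds on the prefix left of the mode,
and mirrored on the suffix. Because the convex-side requirement grows and the
concave-side requirement shrinks as the mode moves right, the optimal mode
position is found by binary search with $O(n)$ evaluations, $O(n \log n)$
overall. The implementation is verified in the test suite to $10^{-10}$
against an independent reference that enumerates every chord directly, and
hits the analytic anchors $D = 0.25$ for $n = 2$ and two equal point masses,
and $D = 1/(2n)$ for equally spaced samples.

p-values are calibrated against the dip's distribution under uniform
samples of the same size — the standard reference, as the uniform is the
asymptotically least favourable unimodal distribution. The default `"table"`
mode interpolates a bundled quantile table (pre-computed once by seeded Monte
Carlo over a log-spaced grid of sample sizes, linear in $\sqrt{n}\,D$ within
a row and in $\log n$ across rows; regenerate with
`tools/make_dip_null_table.R`). `"montecarlo"` mode draws fresh uniform
nulls. The two agree within 0.02 across the tested $(D, n)$ grid.

A consequence worth knowing: calibrating against the uniform makes the test
*conservative* for lighter-tailed unimodal data. For standard-Gaussian
samples of $n = 500$ the measured rejection rate at $\alpha = 0.05$ is
essentially zero, not near-nominal. For this application the
conservativeness is benign — it only delays marginal failures, and the
planted-bimodality tests show power $\approx 1$ at the separations the
method is meant to detect.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `cofactor` | 5 | arcsinh cofactor; the mass-cytometry convention |
| `som_k` | 200 | SOM nodes; "overcluster" scale, well above any expected population count |
| `som_epochs` | 10 | training passes; learning rate 0.05 → 0.01, radius 2/3-quantile → 0 |
| `backend` | hierarchical | `consensus` trades ~10–50× runtime for resampling robustness |
| `minkowski_order` | 2 | distance exponent; 2 is classical Ward (other orders are a logged heuristic) |
| `alpha` | 0.05 | dip-test level; *raising* it is stricter (a cell passes when $p \ge \alpha$) |
| `iqr_threshold` | 2 | IQR limit on the transformed scale |
| `min_events` | 5 | smaller cells are flagged and counted as passes — the dip cannot reject at such sizes |
| `knee_mode` | fitted | `raw` applies the L-method to the points directly |

The QC markers default to the clustering markers; a separate list can be
configured when some channels are clustered on but not judged.

## Numerical and design choices

* **Quartiles** use linear interpolation of order statistics (position
  $p(n-1)+1$); a boundary IQR exactly at the threshold passes. The convention
  matters only for cells sitting on the threshold, so it is fixed and
  documented.
* **$U$'s denominator** counts realized (non-empty) metaclusters only: a
  target $m$ may strand ids on empty SOM nodes, and counting phantom rows
  would reward fragmentation.
* **Ward variant**: proper Ward on squared distances (`ward.D2`), recorded in
  the run metadata. Cuts for all targets come from one dendrogram, so they
  are nested by construction.
* **Consensus defaults** (100 resamples, item fraction 0.8, inner
  Ward/Euclidean, final average linkage on $1 - \text{consensus}$) follow the
  conventions of the established consensus-clustering tooling. Node pairs
  never co-drawn get consensus 0 and a warning to raise `reps`.
* **Sigmoid fit**: bounded Levenberg–Marquardt with $A \in [0,1]$,
  $K \in [A,1]$, $B \in (0,10]$, $M$ within the evaluated range, initialized
  from the data. A degenerate (constant) curve or optimizer failure returns
  `converged = FALSE` and the caller falls back to raw mode rather than
  erroring.
* **L-method ties** resolve to the smallest $m$: fewer clusters preserve
  statistical power. Fitted mode evaluates the sigmoid on the dense integer
  grid spanning the targets, so sparse schedules still yield integer knees;
  this choice is recorded in the knee summary.
* **Seeding**: one global seed fans out deterministically (SOM at
  `seed + 1`, per-target consensus and QC seeds as functions of the target),
  so reruns — serial or multithreaded across targets — are byte-identical.
* **Prime SOM sizes** above 20 are rounded up to the next composite so the
  grid keeps two dimensions; small primes keep a `1 x k` strip.

## What the synthetic generator does and does not emulate

`generate_mixture()` draws Gaussian populations directly on the transformed
scale, truncated at zero (transformed mass-cytometry counts are
non-negative; a population "negative" for a marker becomes a half-Gaussian
with its mode at zero, which is still unimodal). Deliberate bimodality is
planted by shifting a random half of a population's events on one marker.
`as_raw_counts()` maps fixtures back through $\sinh$ for exercising the
ingestion path, and the frozen `benchmark_scenario()` specs (8 well-separated
populations; the same with one bimodal marker; 20 populations with two rare
ones at weight 0.005) are constants under version control.

Real mass-cytometry data differ in ways the generator does not model:
correlated markers, heavy tails and zero-inflation beyond truncation,
acquisition artifacts (doublets, bead events, spillover), and population
sizes spanning four orders of magnitude. Passing the synthetic recovery tests
therefore demonstrates that the machinery — overclustering, scoring, knee
detection — behaves as designed under its own assumptions, not that the
default thresholds are optimal for any particular panel.

Problem sizes throughout the test-bench (20,000–50,000 events, 5–10 markers,
SOM grids of 100 nodes, schedules to m = 30) are chosen as the smallest
sizes at which the populations, rare subsets and planted bimodality are
resolvable with comfortable margins; the same scenarios scale up unchanged.

## Known limitations

* The dip test needs tens of events to reject; metaclusters below
  `min_events` pass by fiat (flagged), so extremely fragmented endpoints are
  scored optimistically.
* Markers with substantial density straddling zero (conventional flow, CITE
  ADTs) can trip the unimodality check for reasons unrelated to clustering;
  the ingestion path warns on negative raw values.
* The L-method assumes one knee. Curves that never plateau (schedule capped
  too low) or are flat from the start (data already unimodal everywhere)
  yield a degenerate profile; the flat case warns and returns the smallest
  candidate.
* Consensus metaclustering is the slow path; its value shows on small or
  noisy node sets, not on the clean synthetic benchmarks.
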