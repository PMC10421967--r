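---
title: "Inferring NCO event lengths and counts from gene conversion tracts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring NCO event lengths and counts from gene conversion tracts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The observation model

A meiotic non-crossover (NCO) event is a latent interval: a chromosome `C`,
a 1-based start `M`, and an integer length `L >= 1`, covering
`[M, M + L - 1]` inclusive.  We observe it only through gene conversions at
the transmitting parent's informative (heterozygous, QC-passing) markers.
Every informative marker inside the event is converted independently with
penetrance `p`; the converted set `S` is the gene conversion tract, and
events with `S` empty are invisible.  Three consequences drive the design:

* short events are under-detected, so the observed tract lengths are a
  biased sample of event lengths;
* the span of a tract only lower-bounds its event's length;
* the number of observed tracts understates the number of events by the
  factor `Pr(S != 0)`.

All inference is built on two precomputable functions of event length `x`,

* `D(x) = Pr(S != 0 | L = x)`, averaging `1 - (1-p)^n` over every placement
  of the event inside a chromosome (`n` = markers overlapped), pooled over
  chromosomes and over parents weighted by their meiosis counts, and
* `T_t(x) = Pr(O = o_t | L = x)` for each observed tract `t`, summing
  `p^{|s_t|} (1-p)^{n - |s_t|}` over the placements that cover the tract,

because the conditional probability of an observed tract under a length
distribution `f` reduces to `sum_x T_t(x) f(x) / sum_x D(x) f(x)`: the
placement normalization cancels, and `f` is the distribution of *all*
events, not just detected ones.

Events are placed uniformly over the `sum_c (len_c - x + 1)` start
positions at which they fit inside a chromosome.  This is the simplest
normalizable uniform-placement convention; the simulator uses the same
measure, which matters — if generator and likelihood disagreed about the
placement measure the estimates would be inconsistent.  Penetrance is held
constant across event lengths and positions; `estimate_penetrance()`
implements the boundary-exclusion estimator (converted non-boundary markers
over informative markers strictly between each tract's outermost converted
markers), which is unbiased exactly because the two boundary markers are
converted by construction.

## Exact kernels

`detection_function()` is exact, not Monte Carlo.  The sum of
`(1-p)^{n(m,x)}` over window starts `m` is updated from `x` to `x + 1` by
correcting only windows whose right edge gains a marker, driven by a
schedule of marker pairs closer than `X_max`.  Two refinements keep this
linear in practice: once `(1-p)^c` underflows to zero, further markers
behind a window edge cannot change anything (for `p = 1` only adjacent
marker pairs matter at all), and the schedule is generated in bounded
chunks of the `x` axis so memory never scales with marker count times
window length.  `tract_function()` exploits that the unconverted-marker
count inside a placement splits into independent left-of-tract and
right-of-tract parts, making the placement sum a cross-correlation of two
step vectors — computed directly when small and by FFT with power-of-two
padding when large.  The test suite pins both against brute-force
enumeration over all placements on randomized small genomes at `1e-12`,
and checks the completeness identity (the tract functions of all producible
tracts sum to `D`).

## Length model and weight duality

Event lengths are modelled as `L - 1 ~ NB(size r, mean m - 1)`, so `L >= 1`
with mean `m`; `r = 1` is the geometric distribution, and dispersion may
also be given as `k` with component variance `m^2 k` (the parameterization
used in the recovery experiments).  A zero-truncated rather than shifted
NB would be the main alternative; the shift keeps `L = 1` attainable for
every `r` and nests the geometric exactly, and at the bp scales involved
the two differ negligibly.

A mixture carries two weight systems: `alpha` over all events and
`alpha_hat` over detected events, linked by the per-component detection
masses `d_i = sum_x D(x) f_i(x)` (`alpha_hat_i` is proportional to
`alpha_i d_i`).  The likelihood is naturally parameterized in
`alpha_hat`; scientific summaries (mean event length, event counts) use
`alpha`.  `attach_weights()` converts in either direction.

Infinite sums over `x` are truncated where every component's upper-tail
mass falls below `tail_tol = 1e-9` (the default used everywhere).  The
tabulated `X_max` starts from the observed spans inflated by `1/p` and is
extended on the fly whenever the fitted mixture's truncation point
outgrows the table, up to the shortest chromosome and a 64 kb ceiling
(`nco_control(X_max_cap = )`).  Inside the M-step the objective returns a
large penalty for parameter vectors putting more than 10% of their mass
beyond the table, so the search cannot wander into untabulated tails
between extensions.

## EM algorithm and numerics

The E-step computes per-tract membership weights from `alpha_hat` and the
per-component tract probabilities; the M-step sets `alpha_hat` to the mean
membership weights and maximizes each component's weighted log-probability
over `(log(m - 1), log r)` by Nelder–Mead (inner tolerance `1e-10`,
geometric components optimize `log(m - 1)` only).  If the inner search
fails to improve a component its previous parameters are kept, so the EM
log-likelihood trace is monotone by construction; the trace is checked
against that guarantee (slack `1e-8`) on every fitted object in the tests.
Convergence is declared when the Euclidean norm of the relative changes of
`(alpha_hat, log m, log r)` drops below `1e-7` (denominators are guarded
with `max(|old|, 1)` since `log r = 0` exactly at the geometric).  Two
EM steps per cycle feed a SQUAREM-style extrapolation whose candidate is
kept only if one further EM step from it does not lower the likelihood;
this cuts iteration counts several-fold without touching the monotone
guarantee.  Overparameterized fits that drift along flat likelihood ridges
are stopped by a stall guard (relative likelihood gain below `1e-10` over
four consecutive steps) or the iteration cap (200 by default; informative
fits converge far earlier).

Component pmfs over the tabulated grid are evaluated by the one-term NB
recurrence (a `cumprod`), asserted equal to `dnbinom` to `1e-10`; the inner
M-step objective is a small compiled kernel over the sparse tract-function
matrix.  Initialization places component means at evenly spaced quantiles
of the observed spans inflated by `1/p`, log-spaced apart, sizes at 1,
uniform `alpha_hat`; the starting means are floored at `max(span)/200` so
no observed tract starts with zero probability (with many single-marker
tracts the span quantiles alone can be pathologically small).  Additional
random restarts (log-normal jitter, driven by the seed) are available via
`nco_control(restarts = )`; the well-separated simulation designs fit
reliably from the deterministic start, so the default is 1.  Components
whose detected-space weight collapses below `1e-6` are dropped with a
warning and the smaller model is refitted.

## Model selection, counts, uncertainty

`nco_select()` walks geometric → 1 NB (LRT on 1 df) → n vs n+1 NB (3 df
per added component: one weight, two parameters), stopping at the first
p ≥ 0.05.  The chi-square reference is the conventional Wilks
approximation; for mixture boundaries it is approximate, which is why its
finite-sample error rate is itself measured in the acceptance tests rather
than assumed.  The geometric-vs-NB test is a regular interior hypothesis
(`r = 1` inside `r > 0`).

The expected number of events behind `n` observed tracts is the
inverse-detection plug-in `n / Pr(S != 0)` with
`Pr(S != 0) = sum_i alpha_i d_i`, divided by the meiosis count for a
per-meiosis rate.  Uncertainty comes from `nco_boot()`: resample tracts
with replacement (same size, realized as per-tract multiplicity weights so
the kernel table is reused untouched), refit each resample warm-starting at
the full-data estimate (penetrance held fixed at the full-data value; for a
single-component model one M-step from the warm start is already the
complete ML refit because there are no latent membership weights), and take
percentile intervals of the replicate summaries — the simplest interval
consistent with resampling, deliberately not BCa.

## The simulator

`nco_simulate()` draws events from the underlying mixture (`alpha`), places
them uniformly with the kernel's measure, converts overlapped markers by
independent Bernoulli trials at the penetrance, and emits a tract per
detected event, recording every event (detected or not) with its component,
position and length as ground truth.  Marker maps come from
`synth_markers()`: a homogeneous process at a target mean spacing, a
clustered model with log-normal gaps pinned to a mean/median pair
(real heterozygous-marker sets are strongly clustered; the human-like
reference has mean gap 1465 bp but median 754 bp, and the clustering
carries real information — tight marker pairs are what identify the
dispersion of short events), or candidate sites thinned by the
heterozygosity probability `2f(1-f)` from allele frequencies.  The
generator reproduces the features the estimator relies on — placement
measure, Bernoulli conversion, detection censoring — but not features of
real data such as recombination hotspots (non-uniform placement),
length-dependent penetrance, tract-calling errors or phasing switch
errors; passing the recovery tests therefore validates the estimator under
its own model assumptions, not robustness to their violation.
`e1_grid()`/`e2_grid()` enumerate the single-component (63) and
two-component (147) experiment designs; the seven dispersion levels
`k ∈ {0.125, 0.25, 0.5, 1, 2, 4, 8}` span under- to strongly
over-dispersed components around `k = 1`.  Two-component datasets draw a
fixed tract quota per component (equal detected-space weights by
construction).

## Problem sizes used in the checks

The validation experiments are scaled-down versions of the full published
designs, chosen once: kernel-vs-enumeration on 50 random genomes of
≤ 300 bp; recovery at means {100, 300, 1000} bp × penetrance {0.5, 1} with
`k = 0.5`, 1000 tracts and 20 replicates per cell on a 10 Mb chromosome
with clustered markers (mean gap 1465 bp, median 754 bp); variance scaling at 1000 vs 4000 tracts with
30 replicates; coverage with 100 datasets × 100 bootstrap replicates
(mean 300, penetrance 1, 300 tracts on a sparse 1000 bp-spacing map,
binomial acceptance band around the nominal 95%); selection error rates from 100 geometric and
50 two-component replicates.  The full-scale reference experiments
(200 replicates per cell, 2940 coverage datasets × 200 bootstraps) run with
the same functions by raising the counts — `cmd_coverage()` and
`cmd_simulate(preset = "e1"/"e2")` expose them directly.

## Known limitations

* Identifiability depends on the marker map: when the mean event length is
  far below the typical marker gap (e.g. 100 bp events on a map with
  1465 bp mean spacing) almost every detected tract is a single marker and
  the likelihood is nearly flat in the mean over ±10% even at tens of
  thousands of tracts.  Estimates are then driven by the few multi-marker
  tracts; expect wide bootstrap intervals, and treat point estimates in
  that regime with caution.  The recovery checks in the test suite use a
  dense map for exactly this reason.
* Penetrance is a single constant; length- or position-dependent
  conversion probabilities bias the estimates in proportion to their
  deviation from that assumption.
* Uniform placement ignores hotspots; detection corrections are therefore
  genome-wide averages.
* The chi-square reference for added mixture components is approximate.
* The bootstrap interval for the *number of events* quantifies the
  uncertainty of the inverse-detection factor `1/Pr(S != 0)`, not the
  binomial realization noise of how many events happened to occur behind
  the observed tracts.  When detection is low (sparse maps — the regime
  the method is for) the former dominates and coverage is nominal; when
  detection approaches 1 the interval narrows faster than the realization
  noise and can undercover the realized event total.
* Tract calling is assumed correct and complete upstream; the model does
  not account for miscalled or merged tracts.
* Multi-parent data share one penetrance and pool detection by meiosis
  count; parent-specific penetrance is not modelled.
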