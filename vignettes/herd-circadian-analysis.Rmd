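---
title: "Herd welfare from the 24 h periodicity intensity of collar-accelerometer activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Herd welfare from the 24 h periodicity intensity of collar-accelerometer activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A regular circadian rhythm — the roughly 24 h sleep–wake and feeding cycle —
is a marker of good health in cattle, and disruptions to it can precede overt
health problems. For newborn calves wearing collar accelerometers, the raw
movement record itself is hard to read: activity peaks every day whether the
animal is thriving or not. What carries the welfare signal is the *strength*
of the 24 h component of activity, tracked over time: strong and stable in a
well-acclimatised, unstressed calf; weak in a newborn still acclimatising, a
sick animal, or a herd reacting to a stressor. Because herds synchronise to
shared cues (feeding, bedding, light), the per-animal rhythm-strength traces
of a healthy herd rise and fall together — which both reveals herd-level
events and makes an individual animal's departure from the herd pattern
detectable.

`herdrhythm` implements this analysis end to end: raw triaxial streams to
per-animal rhythm-strength traces to herd synchrony, plus a ground-truthed
synthetic herd generator. The numbered scripts under `analysis/` run the whole
chain on the synthetic herd and write every table under `results/`.

## Pre-processing raw streams

Collars record x, y, z acceleration in g at a nominal 12.5 Hz. The chain in
`preprocess_stream()` is:

1. **Signal vector magnitude** $\sqrt{x^2+y^2+z^2}$ per sample. The Euclidean
   norm is invariant under rotation of the sensor, so a collar slipping around
   the neck does not change the series (a property the tests check directly
   with random rotation matrices).
2. **Butterworth band-pass**, design order 4, band 0.5–20 Hz, applied
   forward–backward (`signal::filtfilt`) so the zero-phase result does not
   shift activity bouts in time. The nominal 20 Hz upper edge exceeds the
   Nyquist frequency of 12.5 Hz data (6.25 Hz); `bandpass()` clamps the
   applied edge to $0.99 \times$ Nyquist and logs the effective band. The
   clamp preserves the filter's purpose — removing baseline drift below
   0.5 Hz and out-of-band noise — while staying well defined at any sampling
   rate. (Filter libraries differ in whether they accept a super-Nyquist
   edge silently; clamping is this package's documented choice, not an
   inference about anyone else's code.)
3. **Rectification** (absolute value), then **60 s epoch means** on a regular
   grid with half-open bins $[t_0 + k\,\ell,\ t_0 + (k+1)\,\ell)$, so every
   sample lands in exactly one epoch. An epoch holding fewer than half of the
   expected `epoch_len × rate` samples is flagged `missing`; gaps are flagged
   rows, never absent rows, so downstream grids stay regular. The majority
   rule is symmetric and simple; nothing in the analysis is sensitive to its
   exact value because windows below half coverage are dropped anyway (below).

Timestamps are treated as UTC throughout with no daylight-saving adjustment:
a civil 23/25 h day would distort the 24 h target period. Irregular sampling
is tolerated — binning is timestamp-driven — but a median inter-sample gap
deviating more than 5% from the nominal rate triggers a warning.

## The periodicity-intensity statistic

For a window of epoch values $y_i$ at times $t_i$, `intensity_at_period()`
fits by least squares

$$ y_i \sim \mu + \beta_1 \sin(2\pi t_i / P) + \beta_2 \cos(2\pi t_i / P), \qquad P = 24\,\mathrm{h}, $$

and reports the coefficient of determination $R^2$ — the fraction of
within-window variance explained by the best-fitting 24 h sinusoid. This is
the standard-normalised Lomb–Scargle periodogram evaluated at the single
frequency $1/P$, which makes it:

* **bounded in $[0,1]$** by construction, matching the intended reading
  (1 = perfectly regular, 0 = aperiodic);
* **invariant** under affine transforms $a\,y + b$ of the window;
* **indifferent to missing epochs** — absent points are simply left out of
  the fit, which is what collar-off gaps require (a binned FFT would need
  imputation and suffer leakage on gappy grids);
* **exact at the target frequency** — no periodogram-bin mismatch.

Conventions: a zero-variance window scores 0 (there is no rhythm in a flat
line), and a window with fewer than 3 usable epochs or a degenerate basis
scores 0. Detrending is mean-removal only (the fit's intercept); the
band-pass already removed slow drift at the raw stage, and no linear detrend
is applied.

`sliding_trace()` slides a 7-day window in 15-min steps: anchors at
$t_0 + k\,s$ for $k = 0,\dots,\lfloor(\mathrm{span}-W)/s\rfloor$, each anchor
being the **window start**. Seven days per window gives seven full cycles of
the 24 h target — enough to separate the diurnal component from slower
trends while still localising changes to within a week. Windows whose
non-missing coverage falls below `min_coverage` (default 0.5) keep their
anchor with a missing value, so all animals stay on comparable grids for
herd alignment.

Implementation note: the sliding evaluation computes each window's moment
sums (counts, $\sum y$, $\sum y^2$, the trigonometric cross-moments) from
cumulative sums, then solves the centered $2\times2$ normal equations in
closed form — $O(1)$ per anchor, $O(n)$ per animal. Degeneracy guards are
relative to the uncentered moments so cancellation error in a long constant
window cannot masquerade as rhythm. The tests pin this path against an
independent `stats::lm` fit and a brute-force periodogram to $10^{-9}$.

## Herd analysis

* **Alignment** (`align_traces()`): union anchor grid by date and time;
  animals carry missing values outside their own logging span, so staggered
  births and battery-end truncation are explicit.
* **Exclusion** (`exclude_missing()`): an animal whose missing fraction over
  its *own* span exceeds `max_missing_frac` is flagged (never deleted). The
  study removed 5 of 24 animals for collar-off gaps without naming a
  threshold; the default here is 0.2, explicit and configurable, because any
  default is a policy and this one must be testable. Raising the threshold
  never excludes a previously included animal (a tested invariant).
* **Aggregate** (`herd_aggregate()`): per anchor, the sum of non-missing
  included intensities — the top line of the stacked graph — plus the
  contributing-animal count. The count channel distinguishes "the herd's
  welfare fell" from "loggers ended": the aggregate inevitably sags as
  batteries die, and consumers should restrict attention to anchors with
  enough contributors (`aggregate_trough()` defaults to half the maximum
  count). Whether the original stacked graphs ignored or zero-filled
  post-logging anchors is unknowable from the figures; exposing the count is
  this package's answer.
* **Trough timing and back-dating** (`aggregate_trough()`,
  `event_lag_bound()`): anchors mark window starts, but a synchronous welfare
  event manifests in every window that covers it, and the evidence for a
  window is complete only at its end. `aggregate_trough()` therefore reports
  both the trough's anchor and its `observed` time (anchor + window length);
  a point stressor is back-dated from the observed time by up to one window
  length (7 days at the defaults). On the default synthetic herd the shared
  dip starting 2 May surfaces as a trough whose evidence completes around
  8 May — the week-long lag this windowing necessarily produces.
* **Sub-group validation** (`subgroup_check()`): stacked graphs can show
  peaks and troughs driven by a few animals; rebuilding the aggregate from
  sub-groups and comparing shapes guards against that. Agreement is scored by
  Pearson correlation with the herd aggregate over common anchors — the
  simplest quantitative surrogate for visual shape comparison, and logged as
  such. Both schemes are provided: overlapping contiguous id ranges (the
  reproduction mode; the default ranges rescale the 1–5 / 1–10 / 6–15 /
  11–19 / 16–19 pattern to the herd size) and seeded random partitions. The
  id ordering behind "contiguous" ranges is arbitrary — ids carry no meaning
  — and in the synthetic herd id order coincides with birth cohort, so
  contiguous groups there partly contrast cohorts while random partitions
  isolate the shared-shape question; on real herds with arbitrary numbering
  the two behave alike.
* **Deviation detection** (`detect_deviation()`): each anchor's value is
  standardised against the leave-one-out herd mean and s.d. — the animal is
  removed from its own reference so it cannot mask its own deviation — and
  maximal runs of at least `min_duration` anchors with $|z|$ above the
  threshold are flagged. Defaults: $|z| > 2$, runs of 4 anchors (1 h), at
  least 3 comparator animals per anchor.

## The synthetic herd

The generator exists so that every stage above is testable against known
ground truth without any data download. Animal $i$'s activity envelope is

$$ \lambda_i(t) = \mathrm{rest} + a_i\,\mathrm{ramp}_i(t)\,w(t)\,\frac{1 + \sin(2\pi t/86400 + \phi_i)}{2} $$

with a linear acclimatisation ramp from birth to day 14, a herd-shared
welfare curve $w(t) \in [0,1]$ (optionally with an abrupt dip: fast fall,
hold, slower recovery), and a per-animal phase $\phi_i$ jittered with s.d.
0.2 rad around a common value — herds synchronise to shared zeitgebers, so
phases are nearly common. Activity is amplitude-modulated noise, not
simulated gait: the pipeline consumes only magnitude statistics, so only the
envelope's spectral content matters. The diurnal shape is a raised sinusoid
rather than a square day/night gate because a smooth envelope keeps the
amplitude-monotonicity property well posed.

Defaults mirror the study herd: 24 animals in four staggered birth cohorts
(5 born 2 Mar, 4 born 14 Mar, 4 born 21 Mar, 11 born 5 Apr 2019), collars on
1–5 days after birth, ~60 days logged per animal at 12.5 Hz, a shared
depth-0.6, 3-day welfare dip starting 2 May, and 5 animals given three
well-separated collar-off gaps totalling 35% of their span — the animals the
exclusion rule should remove. Values the source conditions do not fix were
chosen once as field-plausible and not revisited: resting envelope 0.05 g,
base diurnal amplitude 0.3 g with ±30% per-animal spread, epoch-mode
observation noise 0.10 g (about the rectified-mean scale a calf collar
yields), raw-mode sensor noise 0.02 g. Collar-on times are snapped to the
15-min trace step so per-animal anchors align by date and time, as epoching
real deployments produces anyway.

Two output modes: `"epoch"` samples the envelope directly at 60 s resolution
(fast; used for herd-scale work and most tests) and `"raw"` emits 12.5 Hz
triaxial samples as a slowly wandering gravity unit vector plus zero-mean
burst noise with per-axis s.d. $\lambda_i(t)$ plus sensor noise — this mode
exercises the full pre-processing chain, including rotation invariance.
Everything is deterministic under `(seed, animal_index)`.

What the simulator does **not** emulate: behavioural bout structure
(rumination, suckling, feeding visits), activity-type composition, weather
and husbandry events other than the single shared dip, sensor clock drift,
and any dependence of phase on age. Passing tests therefore show that the
pipeline recovers rhythm strength, shared dips, gap-driven exclusions and
private deviations from *envelope-level* ground truth; they do not certify
behaviour on real calf data, whose welfare signal may be weaker, less
sinusoidal and confounded in ways the envelope model cannot produce.

## Problem sizes and runtime choices

The test suite and `scripts/acceptance.R` run the statistic's limit checks at
full scale (7-day, 10 080-epoch windows; 1000 noise replicates), the oracle
comparisons on 50 windows up to 2016 epochs, rotation invariance on a ~2 h
raw stream with 100 rotations, amplitude recovery on 14-day single-animal
runs over 10 seeds, and the dip/sub-group scenario on a 19-animal, 30-day
epoch-mode herd over 10 seeds — sizes at which every check completes in
seconds while keeping at least seven full windows of post-ramp data in every
trace. The dip scenario uses a common-span herd (one cohort, no gap animals,
no ramp) so the trough and sub-group comparisons measure the shared welfare
signal rather than cohort composition; the full staggered default herd is
exercised by the exclusion check and the `analysis/` workflow.

## Known limitations

* The PSD normalisation the original analysis used is not published; the
  $R^2$/Lomb–Scargle definition here is validated by its limit behaviour,
  not by agreement with the original implementation's code.
* The epoch length is fixed at 60 s by default; the choice of epoch lengths
  between 1 min and 1 h is left to the user (`epoch_len`), with no automatic
  selection criterion.
* Agreement-by-correlation treats shape globally; two aggregates can
  correlate well while disagreeing on one peak's timing. The report also
  carries per-group peak/trough anchors for that reason.
* With fewer than ~4 comparator animals the leave-one-out z-scores are too
  noisy to be useful; `detect_deviation()` refuses rather than guesses.
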