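---
title: "The tactus tracking model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The tactus tracking model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tactus)
```

This vignette explains the model the package implements, the choices made
where the design was genuinely open, and what the synthetic test passages
do and do not establish about real music.

## The model

The input is an onset sequence: strictly increasing event times in
milliseconds. Nothing else about the music — pitch, loudness, duration —
is observed. The model's premise is that a listener entertains several
competing *tactus hypotheses*, each an isochronous pulse with a phase
$\rho$ (the time of one beat) and a period $\delta$ (the inter-beat
interval). A hypothesis predicts the beat grid
$p_k = \rho + k\delta$, $k \in \mathbb{Z}$, clipped to the portion of the
passage heard so far (the projection extends backward as well as forward
from $\rho$).

Processing is strictly causal. At each onset, in order:

**Spawning.** Every earlier onset $r_a$ paired with the current onset
$r_b$ proposes the hypothesis $(\rho = r_a,\ \delta = r_b - r_a)$,
admitted when $187 \le \delta \le 1500$ ms — the 320–40 bpm range within
which listeners report a tactus. Each admitted hypothesis becomes an
agent (a *tracker*) identified by the onset pair $(a, b)$ and carrying
its full history of parameters and scores.

**Correction.** Expressive timing means onsets drift off any fixed grid,
so tracker parameters must adapt. Each projected beat in the context
window (6000 ms ending at the current onset) is matched to its nearest
onset in the window, ties going to the earlier onset. The signed error is
attenuated by distance,

$$ce_k = m\,(r_k - p_k)\; d^{\,|p_k - r_k| / \delta},
  \qquad m = 2,\; d = 10^{-4},$$

so that a beat with no nearby onset contributes almost nothing:
$|ce_k|$ peaks at distance $\delta / \ln(1/d) \approx 0.109\,\delta$ and
decays beyond it. An ordinary least-squares line of $ce_k$ against the
integer beat index $k$ is fitted; the corrected hypothesis is
$(\rho + \text{intercept},\ \delta + \text{slope})$. Regressing on the
beat index (rather than on the beat time) is what makes the slope
directly a period increment in ms-per-beat and the intercept, extrapolated
to $k = 0$, a phase shift; it is the unique abscissa for which
"slope corrects the period, intercept corrects the phase" is literally
true. The regression is unweighted — the attenuation in $ce_k$ already
down-weights distant matches — and applied once per tracker per onset;
repetition across onsets, not iteration within one, is what refines the
fit. With fewer than two projected beats in the window the correction is
zero (a line needs two points). A corrected period that would become
non-positive is clamped to the smallest positive double; this can only
happen on degenerate inputs.

**Scoring.** A good tactus has most of its beats on events and most
events on beats. With each windowed beat matched to its nearest windowed
onset, the soft hit count is
$\mathit{hits} = \sum_k 0.01^{\,|p_k - r_k|/\delta}$ and the congruency
is precision times sensitivity:

$$\mathit{congruency} =
  \frac{\mathit{hits}}{\#\text{beats}} \times
  \frac{\mathit{hits}}{\#\text{onsets}} \in [0, 1].$$

All three quantities are counted inside the same window
$[\max(r_0,\ \mathit{now} - 6000),\ \mathit{now}]$, keeping the score a
proper ratio. Two numerical details matter. First, window and projection
bounds are inclusive with a $10^{-6}$ ms tolerance, so a beat that falls
exactly on the passage boundary is counted under floating-point
arithmetic (the worked example in the README depends on this). Second,
several beats may legitimately match the same onset, which can push the
sensitivity term marginally above one; the final score is clamped to
$[0, 1]$. A hypothesis projecting no beat into the window scores 0 rather
than erroring, so freshly spawned long-period trackers remain comparable.

**Collapsing.** Trackers whose corrected parameters have converged onto
the same pulse are duplicates. Two hypotheses are *similar* when their
periods differ by at most 2% of their mean and their phases agree modulo
the mean period (circular distance at most 2% of the mean period). After
each step the oldest tracker of each similarity class survives — creation
order, then lower $(a, b)$ — and the newer ones are discarded whole.
The 2% radii are implementation parameters (the model's definition does
not quantify "too similar"); they are configurable in `tht_config()`.
The phase test is circular because phases offset by whole periods
describe the same pulse, while a half-period offset is a genuinely
distinct, counter-phase tactus that must not be merged.

The per-step top score is recorded *during* the pass, so the clarity
curve is exactly what a causal observer would have reported even when the
then-leader is later collapsed away; the returned tracker histories are
those of the post-collapse survivors.

## Outputs

`tht_table()` flattens every surviving tracker state into the standard
table (columns `a, b, onset_index, onset_time, period, phase, score`);
files are written at 6 significant digits, the table's display
convention. `clarity_curve()` and `overall_clarity()` give the
pulse-clarity signal and its mean. `clarity_dips()` summarizes valleys:
maximal runs at least `min_depth` (default 0.2) below the curve's
plateau. The depth threshold separates genuine clarity losses from
scoring noise; see the limitations section for where that noise comes
from.

`extract_beats_naive()` walks the processed onsets and lets each
inter-onset segment $[r_t, r_{t+1})$ be owned by the hypothesis that led
after $r_t$ was processed, emitting its projected beats in that segment
(and up to the final onset for the last segment). Beats are emitted
predictively from hypothesis parameters — never snapped to onsets — so no
future information leaks in. Segments are projected with a 5 ms seam
overlap at their boundaries and duplicates closer than 10 ms are merged
keeping the earlier: when the leader's beats sit exactly on the onsets,
a boundary beat would otherwise fall between two segments whenever the
owning parameters differ by a hair on either side.

`extract_beats_adapted()` targets tapping-like output with two changes.
A challenger replaces the incumbent only after outscoring it continuously
for more than 3000 ms of onset time (an incumbent that disappears by
collapse is replaced immediately); and the emitted period is the
hypothesis period doubled as often as needed to exceed 375 ms, the
fastest comfortable tapping rate (160 bpm). A single doubling is not
always enough — 187 ms doubles to 374 — hence "as often as needed". When
doubling, the emitted grid keeps either the hypothesis phase or the phase
offset by one original period, whichever lies closer on average to the
last emitted beats; this continuity rule resolves the ambiguity of which
half of the fast grid to keep. Finally, an emitted beat closer than
375 ms to the previous one is suppressed. That guard can only act at
adoption seams — within a segment the doubled period already exceeds the
floor — and is what makes the output's inter-beat intervals exceed the
floor unconditionally.

## Synthetic passages

The generators are deterministic and return valid onset sequences; they
exist so the model's dynamics can be probed without any audio front-end.

* `stim_isochronous(n, ioi, phase)` — the baseline; clarity 1.
* `stim_period_change()` — 12 onsets at 500 ms then 24 more at 250 ms
  (11.5 s total). The founding tracker loses congruency after the change
  and a fast tracker takes over; clarity dips and recovers.
* `stim_phase_change()` — a 500 ms grid whose phase jumps forward half a
  period at one third and again at two thirds of the passage (the second
  jump restores the original phase, two half periods making a whole).
  Defaults use 42 onsets so each constant-phase section (7 s) outlasts
  the 6 s context window; only then can the clarity plateau re-establish
  between the two valleys. Phase jumps are implemented as inserted gaps,
  keeping times strictly increasing.
* `stim_rallentando(n = 30, ioi0 = 400, factor = 1.03)` — each interval
  is the previous one times `factor`; the default slows from 400 ms to
  about 916 ms. See limitations: this default is a *strong* rallentando
  that the correction cannot follow end-to-end.
* `stim_mixed_patterns()` — five subpatterns over a 500 ms tactus (plain
  pulse, pickup figure, 3-3-2 tresillo, half-time figure, syncopated
  run), each repeated four times. Mixed patterns carry less pulse
  evidence than a plain pulse, so overall clarity is strictly lower.
* `jitter_onsets(onsets, amplitude, seed)` — uniform ±`amplitude`
  perturbation emulating motor/expressive noise; amplitude must stay
  below half the smallest interval so ordering is preserved.

What passing on these fixtures shows — and does not. The fixtures are
noise-free (or uniformly jittered) grids with abrupt, scripted changes.
They exercise the model's dynamics: spawning, correction convergence,
collapse, leadership changes, hysteresis. They do not contain expressive
micro-timing correlated with musical structure, tempo curves, silence, or
onset-detection errors, so green tests here do not certify behavior on
performed music; for that the model must be fed real onset data.

## Evaluation statistic

`intertap_cv()` computes the coefficient of variability of a tapping
annotation: intervals strictly larger than 3000 ms (a beat slower than
20 bpm — in practice, pauses) are discarded, and CV = sd/mean of the
survivors. Dividing by the mean makes the statistic relative to the
tapping rate the annotator chose, hence invariant under time translation
and uniform scaling. The sample (n−1) standard deviation is used;
`sd_type = "population"` is available since the convention is not
universal. At least two intervals must survive the filter, otherwise the
CV is undefined; `mean_intertap_cv()` averages the defined per-annotator
CVs and reports, rather than zero-fills, the excluded annotators.

## Numerical choices, in one place

* All internal times are milliseconds as doubles; unit conversion happens
  only at the I/O boundary (`read_onsets()`, `write_times()`; seconds are
  written at 3 decimals, the annotation-file convention).
* Projection/window bounds inclusive with tolerance $10^{-6}$ ms.
* Nearest-onset ties break toward the earlier onset, everywhere.
* Congruency clamped to $[0, 1]$; no projected beats → score 0.
* Regression on integer beat index; unweighted; one pass per onset;
  fewer than two points → zero correction; non-positive corrected period
  clamped to the smallest positive double.
* Collapse order: creation step, then lexicographic $(a, b)$; the first
  survivor of each class is kept. Top-score ties also resolve to the
  older tracker.
* Beat emission: 5 ms segment seam, 10 ms duplicate merge (naive);
  375 ms floor guard (adapted).
* Duplicate onset times are rejected, not merged: matching assumes
  distinct event times, and merging is a preprocessing concern.
* No tracker-count cap by default; `max_trackers` exists for very long
  inputs and logs when it prunes.

Problem sizes used in the test suite are small by design — passages of
30–60 onsets and a few hundred randomized oracle instances — which is
ample for a model whose state after each onset depends only on a 6 s
window.

## Known limitations

**Tempo drift has a hard following limit.** The corrected error ignores
matches beyond roughly a tenth of a period, so per-onset tempo increments
must stay well inside that range *cumulatively across the window* for the
regression to see a consistent slope. Measured on this implementation, a
single tracker follows a progressive slowdown of about 0.5% per onset
(`factor = 1.005`) indefinitely — its period glides while it keeps the
top spot — but at 3% per onset (the default `stim_rallentando()`), where
the interval more than doubles over the passage, every tracker stalls:
once its lag exceeds the attenuation range the correction goes silent,
clarity drops, and leadership hops across freshly spawned trackers. This
is a property of the local, distance-gated correction, not a bug; a
listener's experience of an extreme rallentando arguably also fragments.

**Plateau noise at window-commensurate tempi.** The $m = 2$ multiplier
corrects double the observed error, so on perfect data a small parameter
error overshoots and flips sign each step, decaying only through the
attenuation term — a persistent ±0.001 ms wobble. Harmless, except when
the context window length is an exact multiple of the period (e.g.
250 ms into 6000 ms): then the window boundary sits exactly on a beat and
an onset, and the wobble toggles them in and out of the window, making
the score oscillate between about 0.92 and 1 instead of settling at 1.
This is why `clarity_dips()` uses a depth threshold, and why the
period-change passage's recovered plateau is read as "exceeds 0.95"
rather than "equals 1".

**Scope.** No audio, MIDI parsing or onset detection; no beat-metric
suite (F-measure, Cemgil, continuity and relatives belong to dedicated
evaluation packages); the model is batch-causal, not a real-time API.
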