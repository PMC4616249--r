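---
title: "Methods: variability analysis of fast operant lever pressing"
author: "operantVar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variability analysis of fast operant lever pressing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented by `operantVar`, the
defaults of every tunable parameter, and the reasoning behind each
numerical choice that the task description left open.

## The task model

A training session is a stream of timestamped lever presses, magazine
head entries and reinforcer deliveries. Reinforcement follows a *covert*
minimum-frequency rule: a sequence of presses earns a pellet when three
consecutive inter-press intervals (IPIs) sum below
$3/f_{\mathrm{target}}$ seconds. Sessions escalate the target as
0 (free), 0.375, 0.75, 0.75, 1.5, 3, 3, 4.5, 4.5 Hz; at the 4.5-Hz end
target the bound is $3/4.5 = 0.667$ s, conventionally printed as
"660 ms". A target of 0 Hz is represented as an infinite bound: any
three consecutive IPIs qualify.

All times are seconds from session start (single time base; no
millisecond fields). Every analysis window is half-open $[a, b)$: an
event exactly at $a$ belongs to the window, one at $b$ does not, so
adjacent windows partition time.

## Sequence segmentation and features

A boundary falls between consecutive presses when the interval exceeds
the **gap threshold** (default 2 s, the valley of the bimodal IPI
distribution; 1/2 s = 0.5 Hz on the frequency axis) *or* a head entry
lies strictly between them. Runs of $\ge 2$ presses are sequences;
single presses are counted as isolated and excluded from features, which
are undefined for one press. Features: frequency $= 1/\overline{\mathrm{IPI}}$
(Hz), duration $=$ last $-$ first press (s), length $=$ press count.

Two variants of the 3-IPI scan exist deliberately:

* **online rule** (`resetOnHit = TRUE`): after a hit the window restarts,
  so one burst cannot draw multiple pellets from overlapping windows.
  This is the reinforcement engine and stamps reinforcer events.
* **analysis rule** (`resetOnHit = FALSE`): every stride-1 window of
  three consecutive IPIs is scored. Session-level statistics (mean
  signed distance of window sums from the end-target bound, RMS spread
  around the bound, percent of sequences containing the end target) use
  this variant, because they describe *all* three-consecutive-IPI sums.
  The spread is a standard deviation *around the target* (centered on
  the bound, not on the sample mean), so a session hitting the bound
  exactly scores 0.

Windows never span sequence boundaries: an IPI above 2 s could never be
part of a sub-second triple, and head-entry splits would otherwise leak
across bouts. Whether the original controller reused IPIs across
overlapping windows is unknowable from the task description, hence the
exposed flag.

"A magazine check immediately after a press" means the next recorded
*animal action* (press or head entry) is a head entry; reinforcer
deliveries are ignored because they are not actions of the animal.

## Variability statistics

The Fano factor of a sample is the sample variance over the sample mean.
We use the $n-1$ variance denominator throughout (unbiased; the choice
is stated here because nothing in the task description fixes it).
Session statistics need $\ge 2$ trials, otherwise they are reported as
missing, never as zero.

Sliding-window FF traces use windows of 3, 5 or 7 consecutive trials
(default 5) shifted by one trial. Windows do not cross session
boundaries even though a plotted trace may look continuous: mixing
sessions would blend different schedule targets into one window. Trials
are ordered by sequence start time within a session and by session index
across sessions.

The matched-sequence filter keeps sequences with duration in
$[0.2, 2]$ s (inclusive — "0.2–2 s" reads as a closed range) and
frequency strictly above 2 Hz ("higher than 2 Hz" reads strict).

## Spike-train analysis

Per sequence trial: sequence window $[t_{\mathrm{first}},
t_{\mathrm{last}})$, baseline window $[t_{\mathrm{first}}-5,
t_{\mathrm{first}}-2)$ (exactly 3 s), and 1-s flanks centered on the
first and last press. Trials whose baseline would precede the session
start are dropped, not truncated, so baseline durations are constant.
The baseline window is applied uniformly even when a previous sequence
intrudes into it. Rates (not counts) enter the across-trial FF, because
sequence-window durations vary per trial; calibration tests that rely on
the Poisson FF = 1 identity therefore use fixed-duration windows only.

PETHs average spike counts in 20-ms bins shifted by 1 ms across trials,
aligned to the first press of each sequence (the alignment event is not
otherwise specified; the first press is the sequence-initiation event),
over $[-5, +2]$ s. Baseline statistics come from bins centered in
$[-5, -2)$.

### Modulation thresholds

The classification rule is: positive modulation if $\ge 20$ consecutive
bins outside the baseline region exceed the upper threshold, negative if
$\ge 20$ consecutive bins fall below the lower threshold; if both fire,
the longer excursion wins; ties go to positive.

The phrase "a threshold of 99% above baseline activity" admits three
readings, exposed as `thresholdMethod`:

* `"relative"` (default): thresholds are proportions of the baseline
  mean rate — upper $= 1.99 \times$ baseline mean, lower
  $= 0.05 \times$ baseline mean (near-silencing).
* `"percentile"`: 99th / 5th empirical percentiles of baseline bin
  rates.
* `"zscore"`: baseline mean $+ 2.326\,\mathrm{SD}$ / $- 1.645\,\mathrm{SD}$.

The relative reading is the default for a measured reason: with 20-ms
bins stepped 1 ms, adjacent bins share 95% of their data, so excursions
below a 5th-percentile bound persist for $\ge 20$ consecutive shifts
often enough that a flat Poisson unit at 10 Hz (100 trials) is labeled
"negative" in roughly 40% of simulations. That violates the basic
calibration requirement that null units be labeled "none"; under the
relative reading the measured false-positive rate across 200 simulated
null units is below 5% (see the calibration tests), while a 3$\times$
rate step of 500 ms on a 10-Hz baseline is detected in 100% of
simulated units at 100 trials.

Sequence-relatedness is a separate paired $t$-test between per-trial
baseline and sequence rates at $\alpha = 0.05$; it needs $\ge 2$ trials
and nonzero difference variance, otherwise it is reported missing.

## Unit stability

All sessions' waveform snippets of a unit are pooled to compute common
principal axes (via `stats::prcomp`); each session's snippets are then
projected onto the first two axes. For each consecutive session pair and
each component, the unit passes when the later centroid lies within the
earlier centroid $\pm k \times$ the *earlier* session's cluster SD
(default $k = 1.96$); a unit is stable when every pair passes in both
components. The bound is inclusive ("comprised within the interval"),
implemented with a $10^{-9}$ relative tolerance so that a displacement
of exactly $1.96\,\mathrm{SD}$ passes regardless of floating-point
rounding. PCA signs are fixed (largest-magnitude loading positive) so
stored projections are reproducible. The decision is invariant to global
rescaling of the waveforms. Units recorded on non-contiguous sessions
are evaluated over consecutive recorded pairs and flagged.

## Variability coupling

Behavioral FF traces (frequency, duration) and neural FF traces are
built over the *same* trial axis — the sequences whose baseline window
fits in the session — with the same window size. The region-level neural
trace is the across-unit mean of per-unit window FFs (an aggregation the
task description leaves open; a per-unit mode is available through the
lower-level functions). Pairs are matched by window center within
session; Pearson $r$ is computed per session when $\ge 3$ pairs with
nonzero variance exist.

Significance uses the smallest-session rule: the critical $|r|$ of a
two-sided $t$-test at $\alpha$ with the *smallest* session's pair count
is applied to every session of the animal, guarding against sample-size
bias. Within-animal pooling uses the unweighted mean of Fisher-z
transforms (the transformation is prescribed, weights are not;
$n-3$ weighting is available). Both per-session correlations and the
concatenated whole-training correlation are reported, since either could
be the intended summary.

## Bootstrap inference

`bootstrapDiffMeans` resamples each group independently with replacement
at its own size (default 100,000 resamples) and reports the percentile
interval of the mean difference; "5% confidence intervals" is read as
the two-sided 95% interval (2.5/97.5 percentiles), with a one-sided
5/95 mode as an option. The two-sided p-value imposes the null by
resampling both groups from the pooled data (the standard bootstrap
hypothesis test). The shortcut of re-centering the independent-group
draws on zero is available as `nullMethod = "recentered"`, but it is
anti-conservative at small samples: its measured type-I error at
$n = 8$ per group is 0.089, at the edge of the acceptable band, whereas
the pooled null calibrates near 0.05 (the calibration suite runs 500
Monte-Carlo repetitions of 2,000 resamples). Results are deterministic
given a seed.

## The synthetic-data generator

The generator is first-class, tested code: it defines the conditions
under which the analysis chain is validated.

**Behavior.** Each session draws sequences as bouts of lognormal IPIs
(median $m_s$, log-SD $\sigma_s$) truncated below the 2-s gap threshold,
separated by pauses of $2.05 + \mathrm{Exp}$ seconds, with a head entry
after a sequence with probability 0.25. Because pauses exceed the gap
threshold, IPIs never reach it, and head entries fall only between
bouts, segmentation recovers the generated partition *exactly*, which
makes parameter-recovery tests exact at the partition level. Defaults
(9 sessions, 600 s each): targets as in the escalating schedule;
$m_s$: 0.65, 0.58, 0.50, 0.44, 0.37, 0.31, 0.27, 0.24, 0.22 s;
$\sigma_s$: 0.45 → 0.15 (programmed decrease of frequency variability);
sequence rate 1.8 → 3.5 per min. $m_s$ and $\sigma_s$ were chosen so
that $P(\mathrm{IPI} \ge 2\,\mathrm{s}) < 1\%$ in every session — the
generator warns when a parameterization violates this, since truncation
would then distort the IPI model.

Sequence length is $2 + \mathrm{NegBin}(\mu_s, \theta_s)$ with mean
$\mu_s$ rising 0.8 → 7 and dispersion size $\theta_s$ falling 50 → 1.5.
A pure shifted-Poisson length model cannot produce the programmed
*increase* of duration variability here: duration FF scales with the
mean IPI, which falls threefold across sessions, while the Poisson
variance-to-mean ratio of the length is bounded by 1 — so the duration
FF would fall no matter how the Poisson mean moves. The negative
binomial (with the Poisson as its large-size limit) adds the needed
dispersion knob; frequency and duration variability are thus controlled
by different knobs ($\sigma_s$ vs $\theta_s$), mirroring the design in
which the two features are experimentally dissociated.

**Spikes.** Each unit fires as a Poisson process at baseline rate
$\lambda$ (default 6 Hz) outside sequences and $\lambda g_i$ inside
sequence $i$, with per-trial gain

$$g_i = \exp\!\big(\beta z_i + \varepsilon_i - (\sigma_{g,s}^2 +
\beta^2)/2\big), \qquad \varepsilon_i \sim N(0, \sigma_{g,s}),$$

where $z_i$ is the session-standardized frequency deviation of sequence
$i$. The correction term keeps $E[g] = 1$, so mean rates stay flat
across sessions even as the gain dispersion $\sigma_{g,s}$ (default
0.9 → 0.2) falls — the programmed decrease of neural trial-to-trial
variability at constant rate. $\beta > 0$ couples the gain to behavioral
frequency deviations, producing frequency-specific FF coupling;
$\beta = 0$ is the uncoupled null. Waveform snippets are a fixed
biphasic template plus Gaussian noise, with an optional per-session
drift vector for instability tests; snippets are capped at 200 per
session.

All randomness flows from one master seed through fixed integer
substreams (behavior, spikes per profile animal), so fixtures are
byte-reproducible.

**What the generator does not emulate.** Real sessions contain isolated
presses, post-reinforcement retrieval pauses, satiety drift within a
session, bursty non-Poisson spiking, electrode noise correlated across
units, and IPI distributions with heavier tails than a truncated
lognormal. Passing recovery tests therefore show that the analysis chain
correctly extracts the statistical structure it targets when that
structure is present — not that real recordings contain it.

## Problem sizes and defaults used by the test suite

The suite validates at desk scale, chosen once: behavioral recovery over
20 seeds of 1 animal × 9 × 600-s sessions (roughly 15–40 sequences per
session); neural recovery over 3 seeds × 6 units; classifier calibration
over 200 null units × 60 trials and detection over 20 step units × 100
trials; bootstrap calibration over 500 × 2,000 resamples. The `tiny`
fixture profile (2 sessions, 1 animal, 4 units) drives the end-to-end
pipeline tests; the `default` profile reproduces the full study scale
(20 behavioral animals, 7 recorded at 18 M1 + 10 DS units).

## Known limitations

* The online reset rule and the count-target reinforcement moment
  (decided at bout termination) are implementation choices where the
  task description is silent; both are flagged above and exposed as
  options where sensible.
* The consecutive-bin modulation rule is applied to heavily overlapping
  bins; its run-length statistics are calibrated empirically, not
  analytically.
* Sliding-window FF traces are autocorrelated by construction; the
  smallest-session critical-$r$ rule guards against sample-size bias but
  not against window-overlap autocorrelation, which is inherent to the
  published procedure.
* `sessionDuration` must come from the manifest (or caller); event logs
  alone cannot distinguish a short session from an idle tail.
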