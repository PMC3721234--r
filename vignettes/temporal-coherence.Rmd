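---
title: "Stochastic figure-ground stimuli and the temporal coherence model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic figure-ground stimuli and the temporal coherence model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfgmodel)
```

## The stimulus

A stochastic figure-ground (SFG) stimulus is a rapid sequence of random
multi-tone chords. Each chord lasts 25 or 50 ms, abuts the next with no gap,
and contains a random number of pure-tone components (uniform on 5--15,
mean 10) drawn without replacement from a fixed pool of 129 frequencies
spaced 1/24 octave apart between 179 and 7246 Hz. In figure-present trials a
subset of components -- the *figure* -- repeats across consecutive chords:
its *coherence* is the number of repeated components (1--8) and its
*duration* the number of chords over which they repeat (2--12). Listeners
hear the figure pop out of the random cloud even though every individual
chord is statistically identical to the background.

Because the figure is added on top of an independently drawn background,
figure-present chords would on average carry more components. Figure-absent
trials therefore receive the same number of *control* components, redrawn on
every chord so that no coherent pattern forms: the two trial classes are
matched in component counts and differ only in cross-chord coherence.

`sample_sfg_trial()` implements this matched protocol. Variants cover all
six experimental designs:

* **static figures** (25 or 50 ms chords, the baseline designs),
* **ramped figures** whose components all step upward by 2 or 5 pool steps
  per chord,
* **isolated figures** presented without the surrounding background-only
  chords,
* **noise-interleaved chords** separated by broadband bursts of 50--500 ms
  set 12 dB above the chord-sequence RMS,
* **AXB triplets** in which two of three figure-bearing stimuli share a
  figure and the listener must identify the odd one.

Rendering (`render_waveform()`) sums equal-amplitude sine components per
chord, shapes each chord with a 10 ms raised-cosine edge, calibrates noise
bursts against the measured RMS of the chord segments (so the realized
level difference is exactly the nominal one), and peak-normalizes. Segment
boundaries are placed by cumulative rounding so total length in samples is
exact even when one chord is not an integer number of samples (25 ms at
44.1 kHz). Tone phases start at zero at each chord onset; since every
analysis below works on envelopes, phase randomization would change
nothing downstream.

One design detail deserves a note: if a figure component collides with a
background component already drawn at the same frequency, the *background*
tone is redrawn from the unused pool. This keeps the figure identical from
chord to chord (the defining property of the stimulus) while preserving the
exact per-chord component count; resampling the figure instead would break
cross-chord identity.

## The model

The temporal coherence model holds that channels whose activity fluctuates
together over time are bound into one perceptual stream. It has two stages.

**Stage 1: spectrotemporal analysis.** `compute_spectrogram()` produces a
log-frequency auditory spectrogram: a bank of constant-Q Gaussian band-pass
filters (default 24 channels/octave between 125 and 8000 Hz, bandwidth one
channel spacing so adjacent filters cross at -3 dB), each followed by
envelope extraction. The implementation does band-pass filtering, Hilbert
envelope, envelope low-pass (150 Hz) and resampling to the 400 Hz frame
rate in a single exact step: the FFT coefficients inside the channel's
passband are demodulated to baseband and inverse-transformed at the frame
rate. The narrow default bandwidth represents a sharpened tonotopic
representation (as cortical models assume after lateral inhibition); the
`filter_q` knob gives broader, cochlea-like filters if wanted.

On top of the spectrogram, `apply_spectral_scale()` filters each time frame
along the frequency axis with a band-pass kernel tuned to a ripple density
(8 cycles/octave by default; 4 for the steep ramped variant), and
`rate_filter()` convolves each channel envelope with complex Gabor kernels
centered at modulation rates of 2--40 Hz (Q = 1, four cycles long,
zero-mean, unit gain at the center rate). Together these approximate one
(rate, scale) slice of a full cortical spectrotemporal filter bank; the
experiments only ever use a single scale, so the full 2-D decomposition is
out of scope.

The scale stage feeds its *signed* ripple response (the real part of the
analytic signal along frequency) to the rate filters. This matters for
ramped figures: a trajectory sweeping at $v$ octaves/s through a ripple
filter of density $s$ cycles/octave imposes a coherent temporal oscillation
at $s\,v$ Hz on every channel along its path (for the 2-step ramp,
$8 \times 1.67 \approx 13$ Hz, aliased against the 20 Hz chord rate to
~7 Hz). The magnitude of the ripple response -- the non-negative view that
`apply_spectral_scale()` returns by default for display -- discards exactly
that oscillation, and with it the model's sensitivity to moving figures.

**Stage 2: coherence.** `coherence_matrix()` computes, for every channel
pair and window position, the magnitude of the windowed inner product of
the complex rate outputs, normalized by the windowed channel powers, and
keeps the maximum over windows. `max_cross_correlation()` then takes the
largest off-diagonal entry among pairs more than two channels apart
(adjacent channels are coherent through simple filter overlap). The
figure-minus-ground difference of this statistic, averaged over Monte-Carlo
draws (`model_response()`), is the model response.

### Numerical choices in the coherence stage

Three parameters are deliberate departures from the most naive reading, and
each is forced by the structure of tone-cloud stimuli:

* **Regularized normalization** (`lambda_ref`, model default 1). Under
  plain per-window normalization, any two channels whose only activity is
  one shared chord have correlation exactly 1 -- all tones of a chord gate
  on and off together -- so the off-diagonal maximum of *any* tone cloud
  saturates at 1 and the figure adds nothing. Adding
  $\lambda$ = (mean windowed channel power) to each channel's power in the
  denominator acts as a detection threshold against the stimulus's own
  activity level: only pairs that are both coherent *and* well above the
  reference power approach 1. A figure sustained over several chords
  accumulates severalfold the power of a one-chord coincidence, which is
  precisely what makes it salient. Entries stay within [0, 1], and
  `lambda_ref = 0` recovers the plain normalized correlation (useful for
  the algebraic contracts: an exact channel copy then scores 1).
* **Window length of 4 cycles** of each rate, equal to the rate kernel's
  support. A shorter window cannot resolve anything the kernel has not
  already smoothed together, and windowed correlations of oversmoothed
  signals are uniformly high regardless of the input.
* **Adjacency exclusion of 2 channels** when taking the maximum, because
  the channel and scale filters spread a single tone over roughly that
  footprint.

Near-silent channel windows (power below 1e-8 of the mean) score 0, never
NaN. Windows advance by half their length; when a stimulus is shorter than
one window (slow rates on trimmed figure-only snippets) a single
full-signal window is used, with a warning.

Rate-filter convolutions zero-pad the envelope: a stimulus is silent
outside its own extent, so the filters see genuine onsets at the edges. An
earlier variant padded by edge replication; on 350 ms figure-only snippets
that fabricates up to a second of sustained activity under the 2.5 Hz
kernel and measurably inflates slow-rate responses, so it was discarded.

### Monte-Carlo protocol

`model_response()` evaluates each (coherence, duration) cell with paired
draws: the figure trial and its ground counterpart share the seed, hence
the background, onset and window, and differ only in whether the extra
components repeat. Pairing leaves both class means untouched in
expectation but removes the shared background variability from their
difference, roughly halving the Monte-Carlo error of delta at a given
n_iter. Coherence-0 cells (ground vs ground, the null calibration) use
independent draws, since paired draws would be literally identical.

For the two baseline designs the whole stimulus is analyzed; for the
ramped, isolated and noise-interleaved designs only the figure window is
fed to the model, since the surrounding background-only chords contribute
little but Monte-Carlo noise. `run_experiment()` wires the per-design
grids, rates, scales and window policies together.

## Parameters at a glance

| parameter | default | meaning |
|---|---|---|
| chord_duration_ms | 50 (25 in exp 3) | chord length |
| components 5--15 | uniform | background tones per chord |
| coherence | 0--8 | repeated figure components |
| duration | 2--12 chords | figure length |
| onset jitter | 15--20 chords | chords before figure onset (750--1000 ms) |
| ramp_ms | 10 | raised-cosine chord edge |
| noise_level_db | +12 | noise bursts re chord RMS |
| channels/octave | 24 | spectrogram resolution |
| frame_rate_hz | 400 | envelope sampling (10x the fastest rate) |
| rates_hz | 2.5--40 | modulation filter centers, per design |
| scale | 8 (4 for exp 4b) | ripple density, cycles/octave |
| window_cycles | 4 | coherence window per rate |
| lambda_ref | 1 | normalization regularizer |
| n_iter | 100 | Monte-Carlo draws per cell (500 = full protocol) |

## What the simulations show, and at what scale

At desk scale (n_iter = 100; the full protocol uses 500) the package's test
suite verifies, end to end: the generator's statistics (pool size, exact
durations, component density, onset law, noise calibration); that the best
rate matches the figure presentation rate -- 20 Hz for 50 ms chords (whole
stimulus and isolated figures alike), 40 Hz for 25 ms chords, 10 Hz for the
2-step ramp; that the model response increases with coherence and with
duration (the monotonicity checks use n_iter = 200, because a Spearman rank
statistic demands the exact ordering of cell means whose true adjacent gaps
at short durations are ~1e-3); that ground-vs-ground responses are
statistically zero; and that 50 ms interleaved noise weakens but does not
abolish the response.

Two Monte-Carlo caveats at this scale. First, for the ramped design the
10 Hz and 20 Hz responses are separated by only a few times the standard
error at n_iter = 100, so the argmax rate lands on 10 Hz in roughly three
runs out of four and occasionally on a neighboring rate; at n_iter = 300
it is 10 Hz consistently. Second, per-cell deltas at the smallest
coherences and durations are within a standard error of zero, as the
psychophysics would lead one to expect (those cells are near threshold for
listeners too).

## What the generator does and does not emulate

The synthesized stimuli reproduce the published stimulus statistics
exactly: frequency pool, chord timing, component-count law, figure
embedding, onset jitter, count-matched controls, ramps, isolation, noise
interleaving, AXB structure. They do not emulate anything about
presentation or listeners: no loudness calibration in dB SPL, no headphone
or room acoustics, no binaural cues, no attention or training effects.
Model-behaviour comparisons are therefore qualitative -- response surfaces
and best rates, not fitted d' values. The d' utilities
(`d_prime_yesno()`, `d_prime_axb()`, `summarize_conditions()`) analyze
response tables from human sessions; the AXB conversion uses the
differencing-model approximation $d' = \sqrt{2}\,z(p_c)$, with the
log-linear (+0.5) correction throughout so ceiling-level hit rates stay
finite.

## Known limitations

* The front end is an engineering stand-in for a full cortical model:
  no middle-ear filtering, hair-cell dynamics or explicit lateral
  inhibition, and a single spectral scale rather than the full rate-scale
  decomposition. Channel count, bandwidth and frame rate are exposed in
  `frontend_config()` for sensitivity analysis.
* Rate filters are direction-agnostic; upward and downward ripple
  selectivity is not separated.
* The coherence statistic is an extreme-value statistic (a maximum over
  thousands of channel pairs), so its Monte-Carlo noise is heavier-tailed
  than a mean; argmax-over-rates comparisons near ties need a few hundred
  iterations to stabilize.
* The model response is a salience index, not a trial-by-trial ideal
  observer; no attempt is made to map delta onto d' quantitatively.
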