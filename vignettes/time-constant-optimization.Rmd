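---
title: "Optimizing hearing-aid compression speed with a contracting random search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimizing hearing-aid compression speed with a contracting random search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hafit)
```

## The problem

Wide-dynamic-range compression (WDRC) is the standard amplification scheme in
hearing aids: each frequency channel applies more gain to soft sounds than to
loud ones, squeezing speech into the reduced dynamic range of an impaired ear.
Prescription rules fix the *static* part of the compressor — insertion gains at
the 65- and 85-dB-SPL anchor levels and compression thresholds — but leave its
*dynamics* (attack and release times, jointly the "compression speed") to
convention. For listeners with high compression ratios, compression speed
measurably affects the speech envelope and hence intelligibility.

`hafit` implements a simulation-based fitting chain for the dynamics: a
five-channel hearing-aid (HA) simulator amplifies speech-like stimuli under a
candidate set of per-channel attack/release times, a hearing-loss (HL)
simulator degrades the result according to the listener's audiogram, a
pluggable objective scores the outcome, and a contracting random search (RS)
tunes all ten time constants at once to maximize the score. In the study this
chain reproduces, the objective was the recognition score of a French
automatic-speech-recognition system over 50 recorded words; that recognizer
(and its training corpus) are deliberately out of scope here, replaced by a
scorer interface with two desk-scale implementations.

## The optimization loop

Candidates live on a 10-ms grid inside global ranges of 10–500 ms (attack) and
300–2000 ms (release) — values conventionally associated with *slow*
compression, chosen because high compression ratios with fast dynamics distort
the speech envelope. Each RS thread runs `N` iterations (default 1000):

1. draw every parameter uniformly from the grid inside its current range,
   centered on the incumbent;
2. evaluate: amplify → degrade → score;
3. accept the candidate if its score is strictly higher than the incumbent's,
   or equal with strictly higher mean log-likelihood (the secondary
   criterion); otherwise keep the incumbent;
4. contract every range width by `(initial_width - 2*stepsize)/N`, so after
   `N` iterations the width is exactly `2*stepsize`.

Four independent threads (default seeds 1–4) are run sequentially and the best
thread wins, ties broken by log-likelihood then by lowest thread index. If
supplied defaults (attack 200/100/100/100/100 ms, release
2000/1500/1200/1000/1000 ms) are not strictly beaten, they are retained — a
search over a noisy objective can legitimately fail to improve on them.

Two points the contraction law leaves open were fixed as follows. Ranges are
**re-centered on the incumbent** after every iteration and clipped to the
global bounds ("reduced around the baseline"); the alternative — fixed centers
— would make early lucky draws permanent. And the continuous widths from the
contraction law are kept exact; only the candidate grid is discrete.

## The hearing-aid simulator

Each channel (edges 0.1, 0.7, 1.4, 2.8, 5.6, 8 kHz) contains two dynamic-range
compressors in series: the WDRC stage and a limiter.

**Static curve.** The WDRC gain (dB) is a single compressive segment through
the two anchors `(65, IG65)` and `(85, IG85)`, giving compression ratio
`CR = 20/(20 + IG85 - IG65)`; below the compression threshold the gain is
constant at its value at CT. This two-anchor construction is the natural
closed form consistent with how the gains are prescribed.

**Dynamics.** The channel envelope is the Hilbert magnitude of the band
signal, converted to dB SPL and smoothed by a one-pole filter whose pole
switches between an attack and a release value depending on the sign of the
level change. The poles are calibrated in closed form to the ANSI-style
settling criteria on 55↔90 dB SPL steps: a nominal attack time `T` means the
tracked level is within 3 dB of the final level `T` seconds after an upward
step (`tau = T/ln(35/3)`), and a nominal release time means within 4 dB after
a downward step (`tau = T/ln(35/4)`). This convention is directly measurable
with `make_level_step()` + `envelope_follower()` + `measure_settling_time()`,
which is how the tests pin it.

**Filterbank.** Analysis filters are zero-phase with the *squared* Butterworth
magnitude (order 16 by default) — the response forward–backward filtering
would give — applied spectrally with generous zero-padding. Squared low- and
high-pass Butterworth responses at a shared edge sum to exactly one, so the
five bands reconstruct in-band magnitude almost perfectly (the identity
configuration passes tones between 150 Hz and 7 kHz within 0.5 dB; within
half an octave of the outer 0.1/8-kHz limits the deliberate band-limiting
shows). The steep order also keeps below-threshold gain boosts from leaking
coherently between adjacent channels, which is what bounds the measured
65/85-dB anchor error below 0.2 dB. Zero-phase filtering means zero group
delay: output length equals input length by construction.

**Limiter.** Unity gain below its threshold (default 100 dB SPL), 10:1 above,
with fast fixed dynamics (5/50 ms); `threshold = Inf` disables it.

## The hearing-loss simulator

Two perceptual consequences of sensorineural loss are simulated from the
audiogram; spectral smearing is intentionally absent (it weakened the
score–intelligibility association in the work this follows).

**Loudness recruitment** (applied first): per band, the smoothed envelope
level `L` is expanded about the normal dynamic ceiling `C` (default 100 dB
SPL): `L' = C - alpha*(C - L)` with `alpha = C/(C - HL_b)`. A band with 50 dB
of loss gets `alpha = 2`: a 75-dB tone (halfway through the impaired range)
maps to 50 dB SPL, the ceiling maps to itself, and near-threshold sounds are
driven toward inaudibility — the classic envelope-expansion account of
abnormally steep loudness growth. Recruitment bands default to the five HA
channels; the envelope cutoff is 32 Hz (fast enough to follow syllables,
slow enough to leave the carrier intact).

**Threshold elevation** (applied second): a zero-phase filter whose magnitude
at every audiometric frequency is `-HL(f)` dB, interpolated linearly on
log-frequency. The order recruitment-then-filter is fixed and documented: the
stages do not commute, and the expansion is defined on presented levels,
before audibility is removed.

Audiograms sparse in frequency are completed by a degree-3 least-squares
polynomial in `log2(frequency)` — log because audiometric frequencies are
log-spaced; fitting in linear frequency would let the 4–8-kHz points dominate
the octaves that carry most speech information. Predictions are clamped to
[-10, 120] dB HL since cubic extrapolation can diverge.

## Objectives

`proxy_scorer()` is an envelope-correlation intelligibility proxy in the
spirit of STOI: Pearson correlation between clean and degraded band envelopes
(five bands, 32-Hz smoothed, decimated to ~200 Hz), clipped to [0, 1],
averaged over bands and items, times 100. Its `mean_loglik` is the mean log
of the per-item values — a stand-in that exercises the tie-break path, not an
acoustic likelihood. It is deterministic, gain-invariant, scores identity at
100 and independent noise near 0, and never (in expectation) rewards added
noise.

`oracle_scorer()` is a synthetic objective with a brute-force-certifiable
unique maximizer on the grid, used to test the optimizer itself: score
`100 - sum(|AT-AT*|/w_at + |RT-RT*|/w_rt)` floored at zero, log-likelihood
`-distance` so the floored region still orders correctly.

A real recognizer can be plugged in by implementing a `score()` method; the
intended adapter contract is JSON-lines over a subprocess (WAV path in,
hypothesis and log-likelihood out). No recognizer ships here.

## Synthetic inputs

`make_speech_surrogate()` stands in for recorded word lists: alternating
vowel-like segments (harmonic complexes with two random formant resonances,
f0 100–160 Hz) and consonant-like high-pass noise bursts 12 dB below the
vowels, 90–160 ms each, under a 4-Hz syllabic modulation, presented at 65 dB
SPL by default (a conventional conversational level; the source study does
not state its presentation level). This reproduces the envelope statistics
that compression dynamics act on — segment-rate level fluctuations and
consonant/vowel contrast — but none of the phonetic content a real recognizer
needs; a green proxy-scored run therefore establishes that the chain
preserves envelope structure, not that words are recognizable.

`synth_audiogram()` generates sloping, age-related-looking profiles with
seven-frequency pure-tone averages in conventional clinical bands (mild
20–34, moderate 35–49, moderately severe 50–64, severe 65–80 dB HL),
standing in for published audiogram sets that are plotted but never
tabulated. Thresholds rise 6–12 dB/octave above 1 kHz with ±2 dB jitter,
rounded to 5-dB audiometric steps.

The digital calibration convention is full-scale sine ≡ 100 dB SPL
(configurable); the source chain never states its calibration, and every
level-dependent stage references this convention consistently, so only the
headroom above the stimuli depends on it.

## Numerical choices and degenerate inputs

* FFT sizes are powers of two with ≥ fs/4 samples of zero-padding; circular
  wrap-around of the zero-phase filter tails lands in the discarded pad.
* Envelope levels are floored ~180 dB below full scale so silence stays
  finite in the dB domain; the envelope smoother starts at the first sample's
  level to avoid a spurious onset transient.
* Exact score ties keep the incumbent (strict-inequality reading of the
  acceptance rule); cross-thread ties resolve to the lowest thread index.
* Silent stimuli score 0 and are flagged `degenerate` rather than producing
  NaN correlations; zero-variance envelopes contribute 0.
* A disabled limiter is a bit-near-exact passthrough, tested as such.

## Known limitations

* The proxy objective is smooth and nearly noiseless, unlike a word-level
  recognition score, which is integer-valued over 50 items; optimizer
  behaviour on plateaus is exercised through the tie-break path and the
  oracle, not through a genuinely discrete objective.
* The filterbank trades channel isolation against reconstruction near the
  outer band limits; within half an octave of 0.1 and 8 kHz the identity
  configuration deviates by up to a few dB (documented, tested only in-band).
* No microphone/receiver transfer functions, feedback, noise reduction, or
  real-time constraints; "threads" are sequential restarts.
* Severity bands and surrogate-speech parameters are implementation choices
  documented above, not published values.
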