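---
title: "Energy-envelope speech detection for voice dosimetry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy-envelope speech detection for voice dosimetry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phonodose)
```

## The detection model

`phonodose` detects phonation frame by frame from signal energy alone. A
recording is resampled to 16 kHz mono and cut into 32 ms analysis frames
(512 samples). The feature for frame $j$ is its mean power under a
rectangular window,
$$\hat{E}_j = \frac{1}{N}\sum_{n} s_{j,n}^2 ,$$
and the decision compares it with an adaptive threshold formed from the
current and three preceding frame energies plus a bias:
$$AT_j = \sum_{i=0}^{3} a_i \hat{E}_{j-i} + b, \qquad
  d_j = \mathbf{1}\!\left[\hat{E}_j > AT_j\right].$$

The rationale is that speech onsets raise $\hat{E}_j$ faster than the
threshold (which is anchored partly in the recent past), while sustained
background energy raises the threshold along with the signal. The model has
exactly five free parameters and no spectral features, which keeps it cheap
enough for real-time ambulatory use and — because energy carries no
linguistic content — privacy-preserving by construction.

Assumptions worth making explicit:

* the microphone gain is roughly stable within a session (the coefficients
  are fitted per recording, so absolute level only matters within one
  session);
* silence frames carry materially less energy than phonation frames;
* 32 ms frames are short against utterance durations, so frame-level
  decisions approximate segment boundaries to within one hop.

### Conventions at the edges

Three details of the rule are underdetermined by the verbal description and
were fixed as follows:

* **Warm-up frames** ($j \le 3$): missing $\hat{E}_{j-i}$ terms are taken
  as zero. This keeps the decision track exactly as long as the frame
  count and is trivially testable.
* **Ties**: $\hat{E}_j = AT_j$ is classified nonspeech (strict
  exceedance). Ties occur with probability zero on real audio but must be
  deterministic for the degenerate inputs the tests exercise.
* **Current-frame term**: the $i = 0$ term is included by default;
  `include_current = FALSE` removes it, making the threshold purely
  predictive. Both variants are exposed because the summation's lower limit
  is a modelling choice, not a mathematical necessity.

Energy is the *mean* (not the sum) of squared samples so that the bias $b$
has the same scale regardless of frame length. Two useful invariants follow
and are property-tested: scaling all samples by $c$ scales every
$\hat{E}_j$ by $c^2$ and leaves decisions unchanged when $b = 0$; and with
$a_0 = 0$, decisions are pointwise non-increasing in $b$.

### Hop and frame membership

The hop defaults to the frame length (non-overlapping frames) — the
simplest consistent reading of a fixed 32 ms frame size — but is
configurable down to any positive value not exceeding the frame length.
Rasterizing labeled intervals onto the grid marks a frame as speech iff its
*centre* lies inside an interval: centre membership is unbiased at
boundaries, so a label edge misplaces at most one frame.

## Coefficient fitting

The five parameters are fitted by a real-valued genetic algorithm
maximizing pooled frame agreement over labeled training utterances
(`fitness`). The GA uses:

| parameter | default | rationale |
|---|---|---|
| population | 50 | small search space (5 genes) saturates quickly |
| generations | 200 | trace typically flat after ~50 |
| selection | tournament, size 3 | standard, scale-free |
| crossover | BLX-$\alpha$, $\alpha = 0.5$, rate 0.9 | explores outside parental hyper-box |
| mutation | per-gene Gaussian, rate 0.2, $\sigma$ = 10% of bound width | keeps late-stage diversity |
| elitism | 1 | makes best-so-far fitness monotone |
| bounds | $a_i \in [-2, 2]$, $b \in [-0.1, 0.1]$ | samples in $[-1,1]$ imply $\hat{E}_j \le 1$ |

These are repository defaults for a standard elitist real-valued GA; all
are overridable through `ga_config()`. A fixed seed fully determines a run.

Two points deserve emphasis. First, the coefficients are *not identifiable*:
many $(a, b)$ produce identical decision boundaries on a finite training
set. The recovery criterion is therefore decision agreement (the fitted
detector reproduces the generating detector's decisions), not coefficient
distance. Second, the verbal definition of accuracy ("predicted speech
frames over labeled speech frames") reads like recall, while overall
frame agreement is what a two-class evaluation normally means;
`frame_accuracy` returns agreement, recall and precision side by side, and
agreement is the fitness and the headline metric.

Training material is drawn by `split_utterances`: windows of 10 s are
sampled without replacement from a lattice of utterance-length slots, which
makes train/test windows disjoint by construction (default 25 training and
5 held-out test utterances per recording, fitted per session).

## Noise mixing and logMMSE enhancement

`mix_at_snr` scales the noise so the whole-signal power ratio hits the
requested SNR *exactly*:
$g = \sqrt{P_\text{clean} / (P_\text{noise}\,10^{\text{SNR}/10})}$. SNR is
defined over the whole clean signal rather than speech-active frames only,
because that definition needs no labels and is exactly reproducible;
speech-active SNR can be computed afterwards from the labels if desired.
Noise shorter than the speech is looped, and a seed-controlled random
offset selects the crop.

`logmmse` implements the log-spectral-amplitude MMSE estimator: Hann STFT
(32 ms frames, 50% overlap), noise PSD initialized from the first 6 frames,
a-posteriori SNR $\gamma$ capped at 40 dB, decision-directed a-priori SNR
$$\xi_k = \alpha\, G_{k-1}^2 \gamma_{k-1} + (1-\alpha)\max(\gamma_k - 1, 0),
  \qquad \alpha = 0.98,$$
floored at $-25$ dB, and per-bin gain
$$G = \frac{\xi}{1+\xi} \exp\!\left(\tfrac12 E_1(v)\right),
  \qquad v = \frac{\xi\gamma}{1+\xi},$$
with $E_1$ the exponential integral (`pracma::expint_E1`). Gains are capped
at 1 and floored at 0.1; the noise PSD is updated (smoothing 0.98) in
frames whose mean log-likelihood ratio falls below 0.15. These are the
standard published settings for this estimator; all are exposed in
`nr_params()`.

Numerical choices in the resynthesis: the signal is zero-padded by one hop
at *both* ends so every true sample is covered by overlapping windows at
full weight, and overlap-add divides by the accumulated window sum. Without
the tail pad, the final samples sit under a decaying window edge and the
division amplifies spectral leakage there by orders of magnitude. With it,
`gain_floor = 1` reconstructs the input to machine precision, which is the
regression test for the transform chain.

On stationary noise the recursion drives $\xi$ to its floor and the gain to
its floor, giving roughly $-20\log_{10}(0.1) = 20$ dB of suppression
(measured: ~18 dB on white noise). On babble the noise tracker confuses
competing speech with target speech, which is exactly why crowd noise is
the hard archetype.

## Dosimetry metrics

* `phonation_ratio`: speech frames over total frames.
* `ratio_over_time`: cumulative (ratio over $[0, t]$) or sliding (ratio
  over the trailing window, default 60 s). Sliding is the display default
  because a lecture break shows up as a dip toward zero, which the
  cumulative curve smears out.
* `to_segments`: run-length encoding of the track into alternating
  speech/nonspeech segments tiling the session.
* `duration_histogram`: left-closed right-open bins, by default 10
  log-spaced bins per decade over [0.032 s, 1000 s], with flagged
  under/overflow rows so totals are always conserved.

Percentages are reported to one decimal place. The ratio and accuracy
computations are deliberately hop-agnostic: they are defined on frames, so
the same counts arise for any hop setting.

## The synthetic fixture generator

`make_lecture` emulates a teacher's lecture at desk scale: alternating
voiced utterances and true silences. Utterances are harmonic series at a
per-utterance fundamental drawn uniformly from 100–250 Hz (typical adult
speech), with 4 Hz syllabic amplitude modulation and 10 ms attack/release
ramps; silences are exact zeros, so the ground-truth labels are exact by
construction. Utterance lengths are log-normal with median 3 s; pause
lengths are log-normal whose location is solved from the target speech
fraction (default 2/3, matching a 1.5 s median pause), and the schedule is
redrawn — at most 200 times before erroring — until the realized fraction
is within 5 percentage points of the target. With these defaults most
segments are a few seconds long, the qualitative shape expected of
continual lecturing.

What the generator does *not* emulate: natural speech spectra and
coarticulation, room reverberation, microphone handling noise, competing
speakers in the clean recording, and gradual level drift. Consequently a
high end-to-end accuracy on fixtures (typically >99%) demonstrates that
the pipeline is implemented correctly and that the GA can solve the
detection geometry, not that real classroom recordings would score as
high; real recordings present much smaller speech/silence energy contrast.
`make_fixture_suite` writes the full experimental grid — 3 clean lectures ×
4 noise archetypes × 3 SNR levels (0, 3, 5 dB) plus the clean and noise
files — with a checksum manifest, each mixture's manifest entry recording
the SNR achieved before 16-bit quantization.

## Problem sizes and runtime

The test suite and the acceptance script run at desk scale by design: the
end-to-end check fits 25 + 5 utterances of 10 s from a 300 s fixture
(~9,400 frames) with the full GA (50 × 200), which takes a few seconds;
oracle-equivalence suites use 1,000+ randomized instances of 10–60 frames;
the noise-reduction comparison uses a 60 s fixture at 0 dB white noise. A
full run of everything completes in well under a minute on one CPU.

## Known limitations

* WAV support covers 16-bit PCM and 32-bit IEEE float RIFF files (the
  formats the recorder chain produces); exotic chunks are skipped, not
  interpreted.
* The detector is strictly energy-based: a loud video clip or a nearby
  speaker is indistinguishable from the wearer's phonation. Speaker
  identification and beamforming are out of scope.
* logMMSE helps little against babble (competing speech statistics match
  the target's); the directional tests therefore use stationary white
  noise.
* SPL-calibrated vocal dose measures (cycle dose, distance dose) require
  calibrated hardware and are not computed.
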