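---
title: "Event-driven auditory feature extraction: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-driven auditory feature extraction: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strfeast)
```

# The model

`strfeast` implements an event-driven auditory front end in five stages.

**1. CAR-FAC cochlea.** Sound passes through a cascade of asymmetric
resonators. Each channel is a two-state coupled-form resonator

$$z_1' = r(a_0 z_1 - c_0 z_2) + x,\qquad
  z_2' = r(c_0 z_1 + a_0 z_2),\qquad
  y = g\,(x + h z_2'),$$

with $a_0 = \cos\theta$, $c_0 = \sin\theta$, $\theta = 2\pi f_{pole}/f_s$,
and each channel filtering its predecessor's output. Channel characteristic
frequencies follow the Greenwood position–frequency map
$f = 165.4\,(10^{2.1x} - 1)$ sampled at equally spaced cochlear positions, so
CFs decrease from channel 1 (base) to channel $N$ (apex) and equal
channel-index spans cover equal log-frequency spans. Fast-acting compression
(FAC) modulates each resonator's radius $r = r_1 + \Delta r\,\mathrm{nlf}(v)\,b$
through an outer-hair-cell velocity nonlinearity and a 4-stage AGC smoothing
loop driven by the inner-hair-cell output; with FAC off the cascade is
exactly linear. The inner hair cell is a half-wave rectifier followed by two
one-pole smoothers; lateral inhibition then subtracts kernel-weighted
neighbours (floored at zero) to sharpen spectral contrast before spike
generation.

**2. LIF spike encoding.** Each channel's lateral-inhibited IHC output drives
leaky integrate-and-fire neurons:

$$v[t] = v[t-1] + c_{LIF}(d[t] - v[t-1]),\qquad c_{LIF} = 1/(f_s\,\tau_{LIF}),$$

spiking when $v$ strictly exceeds the threshold and resetting to $V_{reset}$
in the same sample. The spike rate grows with drive ($\mathrm{ISI}\approx
\theta_{thr}\tau_{LIF}/d$ for constant drive $d$ well above threshold), so the
stream encodes per-channel amplitude, and rising/falling envelopes produce
shrinking/stretching inter-spike intervals — the code the later stages read.

**3. Time-surface event contexts.** Around each spike an event context (E_C)
is built: the `k` most recent spikes of the channel (anchor included) define
a window which is resampled onto `n_samples` grid points; the value at each
grid point is the exponential decay from the most recent selected spike. 2-D
contexts stack `scale` adjacent channels (sharing the anchor channel's
window, causal spikes only, zero rows for missing channels/history) and so
capture joint spectrotemporal structure — harmonic/formant patterns across
channels, amplitude trajectories within channels.

**4. FEAST.** Feature Extraction using Adaptive Selection Thresholds is
unsupervised competitive learning. Each of $m$ neurons holds weights the
shape of an E_C and a threshold $V_{th}\in[0,1]$ on cosine similarity.
During learning, the most similar neuron whose similarity reaches its own
threshold wins: its threshold rises by $\Delta I$ and its weights move
toward the context, $W \leftarrow (1-\eta)W + \eta\,EC$. When nobody wins,
every threshold falls by $\Delta E$. Winners specialise; global decay keeps
every neuron competitive, balancing firing rates. After training the
thresholds are frozen and ignored: each event's argmax-similarity neuron
emits one spike per bank into its feature map.

**5. Features and evaluation.** Feature maps (or raw cochlear spikes for the
baseline) are counted into `n_bins` equal time bins per (bin, channel,
neuron) cell, flattened, L2-normalised, and classified with a linear model
whose regularisation constant is chosen by cross-validation on the training
split only.

# Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `n_channels` | 64 | cochlear channels, Greenwood-spaced over `cf_range` |
| `cf_range` | 100–8000 Hz | speech band at `fs` = 16 kHz |
| `zeta_min`, `zeta_max` | 0.07, 0.25 | relative damping range (quiet vs loud) |
| `pole_shift` | `c(0.90, 0.04)` | pole as fraction of CF (see below) |
| `tau_lif` | 10 ms | LIF membrane time constant |
| `thresholds` | 4e-4 | single medium firing threshold; three-level layouts available |
| `k` | 4 | spikes per channel per context |
| `n_samples` | 32 | resampled context length |
| `scales` | 5, 13, 25, 37 | 2-D context channel counts (≈ one harmonic up to a formant group) |
| `delta_i`, `delta_e`, `eta` | 0.001, 0.003, 0.001 | FEAST threshold up/down steps and mixing rate |
| `epochs` | 10 | training passes |
| `n_bins` | 5 | time bins per utterance |

# Numerical and design choices

**Pole placement.** The cumulative response of a resonator cascade peaks
above each stage's pole frequency, so a filterbank whose poles sit exactly
at the nominal CFs responds maximally one to two channels away from a pure
tone's nominal channel. Each pole is therefore placed at
`cf * (0.90 + 0.04 * cf/(fs/2))` with relative damping 0.07. These constants
were calibrated once against the analytic cascade transfer function
(`cascade_gain()`, the design oracle) so that over a dense grid of tones in
the speech band the argmax-energy channel's CF is within one channel spacing
of the stimulus; the time-domain simulation is then tested against the same
property independently.

**Nyquist edge.** The default CF range tops out at `fs/2`, where the highest
resonator degenerates ($\theta = \pi$, zero feedback path) but remains
stable; poles are additionally capped at `0.995 * fs/2`. Analyses in this
package stay below 6.5 kHz where the bank is well behaved.

**Free CAR-FAC constants.** The source text for this design names the blocks
but not their difference equations or constants. The IHC smoothing cutoff
(3 kHz), IHC output gain (0.15, set so speech-band input at amplitude ~0.2
drives the default LIF threshold at a few hundred spikes/s per active
channel), AGC time constants (2/8/32/128 ms), AGC strength (30) and the OHC
velocity nonlinearity ($1/(1+(1000\,v + 0.04)^2)$) were fixed once to produce
qualitatively correct behaviour — level-dependent gain that is monotone
non-increasing in input amplitude — and are user-configurable.

**Resampled-context decay units.** A context descriptor should encode the
*relative* timing pattern of its spikes, not the absolute window duration: a
syllabic onset at 2 Hz and at 4 Hz produce the same shrinking-interval
signature at different time scales, and the contract requires that uniformly
dilated spike patterns give identical contexts. A decay constant fixed in
real samples cannot satisfy that, so the exponential decay of the resampled
profile is computed in *grid* units with constant
`tau_grid = (n_samples-1)/(k-1)` (the mean spike spacing on the grid; evenly
spaced spikes decay to $e^{-1}$ between grid-aligned spikes). The raw
time-surface value `time_surface_value()` keeps the real-time closed form
$\exp(-\Delta t/\tau_v)$ with $\tau_v = f_s \times 10^{-3}$ samples (1 ms).

**Ties and clamping.** FEAST winners require similarity ≥ threshold
(inclusive, so a neuron at $V_{th}=0$ stays eligible); ties break to the
lowest neuron index; thresholds clamp to $[0,1]$ (cosine range). Weight
updates are convex combinations, so weights remain inside the coordinate
hull of the initialisation and the presented contexts — a tested invariant.

**Missing history.** 1-D contexts with fewer than `k` channel spikes are
skipped (a short context would distort learning); 2-D rows for missing
channels or short history are zero-filled to preserve geometry; the anchor
channel itself must have full history. Skip counts are reported.

**Convergence sizing.** With $\eta = 0.001$, a neuron that wins $w$ times
retains $(1-\eta)^w$ of its random initialisation; shedding 90% takes about
2,300 wins. Prototype-recovery experiments are therefore sized at ≥250
samples per prototype for 10 epochs, so the closed-form analysis predicts
recovery cosines well above the 0.95 assertion. The default 10 epochs with
an optional early stop (mean $|\Delta W| < 10^{-5}$) operationalises
"train until converged".

**Classifier.** No SVM implementation is available in the supported
dependency set, so "linear kernel with optimal regularisation" is realised
as ridge-penalised multinomial logistic regression (glmnet), with the
penalty chosen by 5-fold cross-validation on the training set only and
deterministic fold assignment from the seed. Both are linear decision rules
with a CV-tuned regulariser; no claim of margin equivalence is made.

# What the synthetic data emulates — and what it does not

`make_dataset()` generates isolated-utterance audio with the statistical
structure the method exploits: a harmonic source (stacked harmonics of a
declining $f_0$, $1/h$ roll-off, random phases), Lorentzian formant gains
along class-specific piecewise-linear two-formant trajectories spread around
the (F1, F2) vowel plane, a syllabic-rate raised-cosine envelope (3–5 Hz),
10 ms edge ramps, white noise at 30 dB SNR, and variable duration
(0.25–0.45 s). "Speakers" are multiplicative log-normal jitter on $f_0$
(σ = 0.15) and formants (σ = 0.05), and train/test splits are
speaker-disjoint. Everything derives from per-utterance recorded seeds.

It does **not** emulate consonants, coarticulation, channel/room effects,
amplitude variation across recordings, or realistic noise spectra. Classes
are separable by construction. A green end-to-end test therefore establishes
that the pipeline transmits formant-trajectory and envelope information
through spikes, contexts, FEAST and binning without distortion — not that
any particular accuracy would transfer to real speech corpora.

# Known limitations

- Binaural operation means two independent monaural instances; there is no
  interaural processing.
- The AGC has no cross-channel spatial smoothing; compression is per channel.
- The fixed-point emulation mode quantises state uniformly per block
  (configurable word/fraction bits); it is a verification aid, not a
  bit-exact replica of any hardware pipeline.
- Feature maps omit events whose context was skipped (insufficient history),
  so the first `k-1` spikes of every channel never appear in feature space.
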