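---
title: "Spiking speech networks and oscillation analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spiking speech networks and oscillation analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikeosc)
```

# The neuron model

The package simulates adaptive leaky integrate-and-fire (AdLIF) neurons in
their dimensionless form: membrane potential $u$ with threshold 1 and rest 0,
coupled to an adaptation current $w$. With decay factors
$\alpha = e^{-\Delta t/\tau_u}$ and $\beta = e^{-\Delta t/\tau_w}$, each step
computes

$$u_t = \alpha\,(u_{t-1} - s_{t-1}) + (1-\alpha)\,(I_t - w_{t-1}),$$
$$w_t = \beta\,(w_{t-1} + b\,s_{t-1}) + (1-\beta)\,a\,u_{t-1},$$
$$s_t = [u_t \ge 1],$$

from the zero initial state. The four parameters have physiological ranges
enforced by projection after every optimizer step: $\tau_u \in [3, 25]$ ms,
$\tau_w \in [30, 350]$ ms, $a \in [-0.5, 5]$, $b \in [0, 2]$. Setting
$a = b = 0$ removes the adaptation current entirely and recovers a plain LIF
neuron; the `sfa_enabled` mask does this per neuron. Subthreshold stability
is guarded by a closed-form spectral-radius check on the $2\times 2$ linear
map (`subthreshold_stable()`); over the admissible box the radius stays
below 1, so projection alone suffices. The equivalent spike-response-model
view is available through `srm_kernels()`, which reports the membrane
response to a unit input pulse (exponential decay for LIF; a peak followed
by an adaptation undershoot when $a, b > 0$) and to an emitted spike (the
reset deflection $-\alpha$ followed by recovery).

Two-variable systems of this kind sit between descriptive LIF models and
conductance-based models: they reproduce spike-frequency adaptation — both
the subthreshold coupling ($a$) and the spike-triggered increment ($b$) —
at a cost compatible with backpropagation-through-time training.

## Surrogate gradient

The threshold derivative is zero almost everywhere, so reverse-mode
accumulation replaces it with the boxcar surrogate
$\partial s_t/\partial u_t := 0.5\cdot[|u_t - 1| \le 0.5]$
(`boxcar_surrogate()`). The forward pass is exact; only the backward pass is
relaxed. The full backward-through-time recursion (including the reset path
$s_{t-1} \to u_t$, the adaptation jump $s_{t-1} \to w_t$ and the recurrent
path $s_{t-1} \to I_t$) is implemented in compiled code alongside the
forward loop; all parameter gradients ($W$, $V$, $\tau_u$, $\tau_w$, $a$,
$b$) come out of the same pass. Everything is double precision; the
differentiable (non-spiking) parts of the pipeline are verified against
central finite differences to $10^{-10}$, and the spiking forward dynamics
against independently coded scalar loops.

# Network structure

Layers receive the stimulus $I_t^l = W^l s_t^{l-1} + V^l s_{t-1}^l$. The
recurrent diagonal is structurally zero (no autapses; the reset term already
provides self-inhibition). Connectivity is thinned by fixed random binary
masks drawn once from `mask_seed`; masks, Dale signs and the zero diagonal
are never touched by training (gradients are masked, and the invariant is
asserted in the test suite). Under Dale's law every neuron's outgoing
weights share one sign. The excitatory count for E/I ratio $r$ is
$\lceil N r/(1+r)\rceil$ — half at $r = 1$, one in four at $r = 0.33$ — and
training operates on magnitudes with signs imposed, so a weight can shrink
through zero but never flip sign. Auditory nerve fibers are all excitatory.

Feedforward weights are initialized zero-mean normal with standard deviation
`w_gain / sqrt(n_inputs)`. Binary spike inputs are sparse (typical input
rates give only a few percent of active presynaptic neurons per step), so a
gain of 1 would leave membrane fluctuations an order of magnitude below
threshold and the boxcar surrogate — which is only nonzero for
$u \in [0.5, 1.5]$ — would pass no gradient at all: a silent network cannot
be rescued by the rate regularizer. The default `w_gain = 4` targets
fluctuations of order the threshold at those input rates (the
fluctuation-driven initialization idea); neuron parameters are initialized
heterogeneously, uniform over their admissible ranges (with $a$ drawn from
$[0, 2]$ to start well inside the stable region).

## Firing-rate regularization

Rates are computed per utterance over its true duration,
$f_{b,n} = T_b^{-1}\sum_t s_{b,t,n}$, and penalized outside
$[f_\min, f_\max]$ with hinges, averaged as `1/(B L)` over utterances and
layers and `1/N_l` within a layer. Defaults: $f_\min = 0.5$ Hz and
$f_\max$ the Nyquist rate $1000/(2\Delta t)$ Hz. The nerve layer is included
by default (`reg_include_nerve`), and the combination weight with the CTC
loss defaults to 1 — the relative weighting is a free design constant, not
something the task pins down.

# The speech pipeline

The waveform-to-symbol architecture is: log-Mel filterbank (80 bins, 25 ms
Hamming window, hop of 1/2/5 ms — the hop *is* the simulation step), a
single 2-D convolution over (time, Mel) with a $(7,7)$ kernel producing
`channels x (n_mels - 6)` signals (1,184 at the default 16 channels and 80
bins), layer normalization per frame, channel dropout (0.15) and Leaky-ReLU;
one LIF nerve fiber per signal (trainable $\tau_u$ only); a stack of
recurrent AdLIF layers; average pooling of the last layer's spikes over
40 ms windows down to 25 Hz; two Leaky-ReLU FC layers and a log-softmax
projection to the blank-augmented class set; CTC loss and greedy decoding
(argmax, collapse repeats, drop blanks), scored by the edit-distance error
rate.

One bookkeeping choice deserves a note: a $(7,7)$ kernel with a time
padding of 7 would lengthen the frame sequence by 8, which contradicts the
architecture's stated invariant of an unchanged frame count. The
convolution therefore uses symmetric "same" time padding (3 on each side),
which preserves the invariant exactly; the feature dimension is unpadded,
giving the $80 - 7 + 1 = 74$ positions per channel.

The seven-bin kernel footprint mirrors measured auditory tuning sharpness:
each nerve fiber integrates energy over about seven adjacent Mel bands, a
rough analog of inner-hair-cell to nerve convergence, and the Mel axis
itself stands in for the cochlea's tonotopy.

CTC needs frames at a rate where alignments remain tractable; pooling to
25 Hz before the readout keeps that property for every admissible
$\Delta t$ since the kernel is always 40 ms. Time steps above 5 ms would
blur below typical refractory timescales, and the 2 ms step keeps the whole
gamma range (up to 150 Hz) below the 250 Hz Nyquist rate for the
oscillation analysis.

## Training

Adam (default learning rate $5\times 10^{-3}$) over every parameter group:
CNN kernel/bias and layer-norm gain/offset, per-fiber $\tau_u$, layer
weights and neuron parameters ($\tau_w$, $a$, $b$ trainable only on
adapting neurons), and the readout head. After each step neuron parameters
are projected back into their boxes. Batches are zero-padded to the longest
utterance; CTC frames, firing rates and regularization gradients are
restricted to each utterance's true length. A fixed seed makes runs
bit-reproducible (initialization, shuffling and channel dropout all derive
from it). Divergence (non-finite loss) aborts with a diagnostic rather than
continuing.

# The oscillation toolkit

Population signals sum a layer's binary spikes per time step — the model's
analog of an EEG electrode over a synchronized population — and are
z-scored over time (population standard deviation, so a two-valued series
normalizes to exactly $\pm 1$). A constant series has no normalization and
is rejected as degenerate.

Band decomposition uses zero-phase FIR filtering (windowed-sinc Hamming
design, forward-backward application). The filter order is chosen so the
transition width is at most a quarter of the band's width and at least
three cycles of the low band edge fit, capped at a third of the signal
length when signals are short; half the filter span is trimmed from each
end before any metric is computed. The transition-width rule matters: with
the common three-cycle rule alone, a 6 Hz theta component leaks into the
8--13 Hz alpha filter's pass-band and corrupts band attribution. Delta-band
analysis (low edge 0.5 Hz) genuinely requires signals of six seconds or
more; on shorter signals the cap applies and delta results should be read
with caution.

Phase and envelope come from the FFT analytic signal. Coupling is
quantified two ways: the modulation index (KL divergence of the phase-binned
amplitude profile from uniform, normalized by $\log n_{bins}$; 18 bins of
20° by convention) and the mean vector length
$|T^{-1}\sum_t A_t e^{i\varphi_t}|$. Significance uses cut-and-swap
surrogates: the amplitude series is cut at a uniform random interior point
and the two segments are swapped — a circular rotation that preserves the
amplitude marginal exactly while destroying phase alignment — and a
Gaussian (moment) fit to the surrogate distribution gives an upper-tail
p-value. A coupling is declared only when *both* metrics fall below 0.05,
a deliberately conservative dual rule. No multiple-comparison correction is
applied across scenarios, mirroring common practice for this analysis.

Scenario enumeration covers intra-layer couplings (each population with
itself) and inter-layer couplings (phase of an earlier population against
the amplitude of every strictly later one): 4 populations give
$4 + 6 = 10$ relations, crossed with $4 \times 2$ band pairs and the
utterance set — 5,120 scenarios at 64 utterances.

## Calibration behavior

On independent noise the Gaussian fit is slightly anticonservative for both
metrics (their nulls are right-skewed), giving single-metric false-positive
rates near 6--7.5% at the nominal 5% (the modulation index sits at the high end); the dual-metric rule lands near 2%.
This is a property of the prescribed Gaussian-fit procedure, not of the
implementation — empirical-quantile p-values would calibrate exactly but
would change the method. The figures are recomputed by the test suite and
the acceptance script, not quoted.

# Synthetic data: what it emulates and what it does not

`gen_pac_signal()` plants ground-truth coupling: an amplitude-modulated
carrier $(1 + d\cos\varphi_t)\cos(2\pi f_{amp} t)$ plus the modulating
component $\cos\varphi_t$ and Gaussian noise at a set SNR. The modulating
phase is quasi-periodic: its frequency wanders as a smooth
Ornstein-Uhlenbeck process (default sd 0.4 Hz, correlation time 0.3 s).
This matters doubly. Physiological rhythms are not clock-like; and for a
strictly periodic phase the cut-and-swap surrogate is *blind* — rotating a
periodic envelope merely phase-shifts it against the phase series, leaving
both coupling metrics unchanged, so no surrogate test could detect the
coupling. A heavy-tailed jitter (white frequency noise) is also unsuitable:
its Lorentzian line shape leaks phase-coherent energy into neighboring
bands and corrupts band attribution. The smooth wander keeps the line
inside its band with fast-decaying tails.

The tone corpus replaces phoneme-labeled speech: each utterance
concatenates pure tones (one per transcript symbol; 4 symbols at 400--3200
Hz by default) with jittered durations (100--160 ms), short gaps, 5 ms
amplitude ramps and a -30 dB white noise floor. It preserves the claim
structure — CTC training on symbol sequences through the full spiking
stack — at desk scale, but *not* speech acoustics: tones are narrowband,
so the trained network's response to broadband inputs differs from a
speech-trained network's. Concretely, white noise excites more auditory
nerve fibers than any single tone does, and the trained model's mean rate
on white noise exceeds its rate on tone utterances even though the
speech-like babble noise does sit below them; passing tests on this corpus
demonstrate the pipeline's mechanics and trainability, not speech-level
selectivity. Babble-like noise is emulated as a sum of narrowband
(300--3400 Hz) processes amplitude-modulated at syllabic rates (2--6 Hz),
giving the low-frequency envelope structure real babble has, without
licensed recordings.

# Problem sizes

The test suite and acceptance script run at sizes chosen for a single CPU:
a 200-utterance tone corpus trained for 8 epochs with the desk-scale
configuration (`tone_task_config()`: 5 ms step, 40 Mel bins, 8 CNN
channels = 272 fibers, two 128-neuron layers, 128 readout features), 500
calibration trials with 500 surrogates each, and 100 detection seeds at 5 s
per signal. The full-scale defaults (2 ms step, 80 bins, 16 channels, three
512-neuron layers, 10,000 surrogates) are what `pipeline_config()` and
`pac_test()` expose; nothing in the code depends on the reduced sizes.

# Known limitations

- Greedy CTC decoding only; no beam search or language model.
- No trainable axonal delays and no moving-threshold adaptation variant;
  feedback is layer-wise recurrence only.
- The Gaussian-fit p-value inherits the slight anticonservativeness noted
  above; exact zeros are impossible by construction (report values below
  `1/n_surrogates` as such when summarizing).
- Dale-constrained training uses the same initialization as unconstrained
  training with signs imposed afterwards, which is known to be a weak
  point of sign-constrained networks.
- The WAV codec reads and writes 16-bit PCM mono only.
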