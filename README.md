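# spikeosc

Spiking speech networks and neural oscillation analysis in R.

`spikeosc` is for computational neuroscientists who want to study how
brain-like rhythms — and in particular cross-frequency coupling — emerge in
spiking neural networks trained on auditory tasks, without GPU-scale
infrastructure. It provides two tightly coupled toolkits:

1. **A trainable spiking speech pipeline.** Adaptive leaky
   integrate-and-fire (AdLIF) neurons in dimensionless form,

   ```
   u_t = α (u_{t-1} − s_{t-1}) + (1 − α)(I_t − w_{t-1})
   w_t = β (w_{t-1} + b s_{t-1}) + (1 − β) a u_{t-1}
   s_t = [u_t ≥ 1],        α = exp(−Δt/τ_u),  β = exp(−Δt/τ_w)
   ```

   with parameters projected into physiological ranges
   (τ_u ∈ [3, 25] ms, τ_w ∈ [30, 350] ms, a ∈ [−0.5, 5], b ∈ [0, 2]),
   assembled into a waveform-to-symbol architecture: log-Mel frontend →
   auditory CNN → LIF nerve fibers → recurrent spiking layers (fixed binary
   connectivity masks, optional Dale's-law sign constraints) → 25 Hz
   pooling → CTC loss with greedy decoding. Training is
   backpropagation-through-time with a boxcar surrogate for the spike
   threshold (∂s/∂u := 0.5·[|u − 1| ≤ 0.5]), plus a firing-rate
   regularizer that keeps neurons between 0.5 Hz and the Nyquist rate.

2. **An oscillation-analysis toolkit.** EEG-like population signals (summed
   spikes, z-scored), zero-phase FIR band decomposition into the canonical
   delta/theta/alpha/beta and low/high-gamma bands, and phase-amplitude
   coupling quantified by the modulation index (normalized KL of the
   phase-binned amplitude profile) and the mean vector length
   |mean(A·e^{iφ})|, each tested against cut-and-swap surrogate nulls with
   Gaussian-fit p-values and a conservative dual-metric significance rule.

Synthetic generators supply every input at desk scale: coupled-oscillation
signals with known ground truth, Poisson rasters, a tone-sequence corpus
standing in for phoneme-labeled speech, and uniform/babble-like noise.

## Worked example 1: detect planted phase-amplitude coupling

```r
library(spikeosc)

sig <- gen_pac_signal(pac_gen_spec(f_phase = 6, f_amp = 55, depth = 1,
                                   snr_db = 10, duration = 5, seed = 1))
ps <- structure(list(raw = sig$x,
                     normalized = (sig$x - mean(sig$x)) / sd(sig$x),
                     dt = 2, fs = sig$fs, layer_id = "demo",
                     utterance_id = 1L), class = "population_signal")
res <- pac_test(ps, phase_band = "theta", amplitude_band = "low_gamma",
                n_surrogates = 1000, rng_seed = 1)
```

This prints (via the fields of `res`):

```
mi = 0.0786 (p = 0.007585), mvl = 0.3936 (p = 0.02457), significant = TRUE
```

The theta-phase (4–8 Hz) of the signal significantly modulates its
low-gamma (30–80 Hz) envelope by both metrics, so the dual rule declares
coupling — as it should, since the generator planted a depth-1 modulation
of a 55 Hz carrier by a quasi-periodic 6 Hz rhythm. The same test on a
`depth = 0` signal gives `mi = 0.0002 (p = 0.075), mvl = 0.0025
(p = 0.969), significant = FALSE`: no coupling is invented.

## Worked example 2: train the pipeline on the tone corpus

```r
corpus <- gen_tone_corpus(tone_task_spec(n_utterances = 200, seed = 7))
ds <- lapply(corpus, function(u) list(wave = u$wave, labels = u$labels))
fit <- train_pipeline(ds, tone_task_config(seed = 2), epochs = 8,
                      batch_size = 8, lr = 5e-3, seed = 3)
evaluate_pipeline(fit, ds)$ser
```

Per-epoch progress is printed; the run ends around

```
epoch 7: loss 0.109 (ctc 0.022, reg 0.086), SER 0.1%
epoch 8: loss 0.091 (ctc 0.017, reg 0.074), SER 0.1%
```

and the held-in evaluation returns a symbol error rate near 1% — the
surrogate-gradient network has learned to transcribe tone sequences through
its spiking layers (about 80 s of training on one CPU). `simulate_pipeline()`
then dumps per-layer spike rasters for the oscillation toolkit, and
`enumerate_scenarios()` + `pac_test()` + `coupling_report()` run the full
intra-/inter-layer coupling survey (10 relations × 8 band pairs per
utterance).

Command-line wrappers over these functions live in `inst/scripts/`
(`spikeosc-train`, `spikeosc-eval`, `spikeosc-simulate`,
`spikeosc-analyze-pac`, `spikeosc-gen-data`).

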