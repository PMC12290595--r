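---
title: "Online functional connectivity estimation with connstream"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Online functional connectivity estimation with connstream}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connstream)
```

## The problem

Functional connectivity in EEG/MEG quantifies the statistical interdependence
of activity recorded at different sensors or reconstructed sources. It is
almost always estimated *offline*, after the recording has ended. connstream
implements the estimation *online*: data arrive block by block, stimulus
triggers are detected on the fly, trials are cut and screened, and every
accepted trial refines the current all-to-all connectivity network. The design
goal is that the per-trial update cost does not depend on how many trials have
been accumulated — only then can the estimate keep up with an ongoing
acquisition.

The central objects are

* **trials (epochs)** — fixed-length `channels × samples` segments time-locked
  to a stimulus event; the sampling unit of all across-trial estimators;
* a **spectral accumulator** — running across-trial sums of every per-trial
  spectral statistic any implemented metric needs;
* a **connectivity network** — an undirected edge list over all
  `n(n−1)/2` channel pairs with per-edge weight, optional signed value and lag.

## The estimators

For one trial, each channel's tapered spectrum $X_i(f)$ is the one-sided DFT
of the windowed, zero-padded signal. Cross- and power spectral densities are
$S_{ij}(f) = X_i(f)\,\overline{X_j(f)}$ and $S_{ii}(f) = |X_i(f)|^2$; by this
sign convention a positive phase of $S_{ij}$ means channel $j$ lags channel
$i$. With $N$ trials and per-trial values $S_{ij}^{(k)}$, the spectral metrics
are computed from sums over trials:

* **Coherency** $\mathrm{COHY}_{ij}(f) = \sum_k S_{ij}^{(k)} \big/
  \sqrt{\sum_k S_{ii}^{(k)}\sum_k S_{jj}^{(k)}}$, with **coherence**
  $\mathrm{COH} = |\mathrm{COHY}|$ and **imaginary coherency**
  $\mathrm{IMAGCOHY} = \Im(\mathrm{COHY})$;
* **Phase-locking value** $\mathrm{PLV} = \frac{1}{N}\big|\sum_k
  S_{ij}^{(k)}/|S_{ij}^{(k)}|\big|$;
* **Phase-lag index** $\mathrm{PLI} = \frac{1}{N}\big|\sum_k
  \mathrm{sign}\,\Im S_{ij}^{(k)}\big|$, its **unbiased squared** variant
  $\mathrm{USPLI} = \big[(\sum_k s_k)^2 - \sum_k s_k^2\big]/[N(N-1)]$ with
  $s_k = \mathrm{sign}\,\Im S_{ij}^{(k)}$, the **weighted** variant
  $\mathrm{WPLI} = |\sum_k \Im S_{ij}^{(k)}| / \sum_k |\Im S_{ij}^{(k)}|$, and
  the **debiased squared weighted** variant
  $\mathrm{DSWPLI} = \big[(\sum_k \Im S^{(k)})^2 - \sum_k (\Im S^{(k)})^2\big]
  \big/ \big[(\sum_k |\Im S^{(k)}|)^2 - \sum_k (\Im S^{(k)})^2\big]$.

The two time-domain metrics average per-trial estimates: **COR** is the mean
per-trial Pearson correlation (a raw dot-product mode without demeaning or
variance normalization is available as `correlation(mode = "dot")`), and
**XCOR** averages the per-trial normalized cross-correlation *functions*
(computed by zero-padded FFT convolution) and then reports the maximum
absolute value and its signed lag. Averaging the functions before taking the
maximum, and taking the absolute maximum rather than the signed one, are
package conventions: the multi-trial rule is only defined here for a single
trial in the pipeline this design follows.

Metrics based on $\Im S_{ij}$ discard instantaneous (zero-lag) coupling and
are therefore robust against volume conduction / field spread, at the price of
discarding part of the signal; this trade-off is what the simulation
experiments below exercise.

## The accumulator algebra

Every spectral metric above is a function of seven across-trial sums per pair
and bin ($\sum S_{ij}$, $\sum S_{ij}/|S_{ij}|$, $\sum \mathrm{sign}\,\Im S$,
$\sum \Im S$, $\sum (\Im S)^2$, $\sum |\Im S|$, the count of trials with
$\Im S \ne 0$) plus $\sum S_{ii}$ per channel. `accumulate_trial()` updates
all of them for every trial, because their cost is negligible next to the FFT:
as a consequence, **switching between spectral metrics never touches raw
data**, regardless of storage mode. The USPLI count term makes the unbiased
estimator exact also when some trials have an exactly zero imaginary part
(those trials contribute $s_k = 0$, so $\sum s_k^2$ is the nonzero count, not
$N$).

Degenerate denominators — zero accumulated power for coherency, all-zero
imaginary sums for WPLI/DSWPLI, zero-variance channels for COR/XCOR — yield 0
plus a machine-readable flag (`degenerate` attributes, network `flags`),
never `NaN`: a streaming consumer must not crash on a flat channel.

`sign(0)` is defined as 0, which matters for the PLI family at exactly zero
lag. `Conj` symmetry means only pairs $i<j$ (lexicographic) are stored;
values for $(j,i)$ follow by conjugation or sign flip.

## The engine and its determinism contract

`connectivity_engine()` holds the accumulator plus, with `storage_mode = TRUE`,
a cache of per-trial tapered spectra and epochs. The cache stores
`channels × bins` spectra rather than per-pair CSDs — $O(CF)$ against
$O(C^2F)$ memory per trial — and pair products are recomputed on demand; this
is the right trade-off when memory load over hundreds of trials matters.
Storage is needed only for (a) the moving-average horizon, where the sums over
the last $H$ trials are rebuilt from cached spectra in fixed order when the
window slides (no floating-point subtraction, so the result is bit-identical
to a batch over those $H$ trials), and (b) the time-domain metrics.

Instead of prescribing a thread architecture, the package states a
**determinism contract**: per-trial contributions are reduced strictly in
trial-arrival order. Under that contract the engine after $N$ `add_trial()`
calls is bit-identical to `batch_connectivity()` over the same epochs — the
central oracle of the test suite. Parallel implementations keep the contract
by partitioning the *pair space* (embarrassingly independent, bit-identical);
partitioning *trials* and summing partial accumulators reproduces the integer
sums exactly but the real sums only up to floating-point associativity, which
is why the canonical order is sequential.

Per-trial cost constancy is asserted by instrumentation (the engine counts
FFT columns per trial), not wall clock, so the property is testable on any
machine.

## The streaming front end

* **Events** are rising transitions of the trigger channel from a value
  $\le 0$ to one $> 0$, detected across block boundaries via the carried
  previous value; a positive trigger at the very first stream sample counts.
  The trigger polarity/debounce convention is the package's own choice (the
  acquisition convention it models does not pin one down) and is documented
  as such.
* **Epoch windows** are half-open `[start, end)` in 0-based absolute samples
  with `start = event + round(tmin·fs)`; this makes epoching independent of
  how the stream was chunked into blocks, which is tested by re-chunking.
* **FIR filtering** uses Hann-windowed-sinc ("cosine") designs with an odd
  tap count, hence exactly linear phase and an integer group delay
  `(n_taps−1)/2`; the streaming path runs block-wise overlap-add and emits
  the output advanced by the group delay, so filtered samples stay
  time-aligned with the input. Equivalence with direct convolution of the
  concatenated stream is an oracle test. A Chebyshev-window design was left
  out: the cosine design is the default in the modeled pipeline and the only
  one required.
* **Artifact rejection** uses the maximum absolute amplitude over a channel
  subset (not peak-to-peak), with an exclusion window removed before
  scanning so a stimulus artifact does not trigger rejection.
* **Covariance** estimates are emitted every `n_target` samples
  (denominator $n-1$, per-channel means removed) and the accumulation
  restarts, modeling noise tracking over a session.
* A user-supplied **linear operator** (e.g. an inverse operator mapping
  sensors to sources) can be applied per block or epoch; its construction is
  out of scope, it is consumed as a plain matrix.

Resting-state streams are handled by `stream_as_trials()`: sliding windows of
fixed length and step are emitted as pseudo-trials, so the same across-trial
machinery covers spontaneous data.

## The synthetic ground truth

`simulate_two_label_dataset()` emulates a two-region evoked simulation: label
1 drives 2 dipoles with $A\sin(2\pi f_0 t)$, label 2 drives 4 dipoles with
$A\sin(2\pi f_0 t + \varphi)$; defaults $f_0 = 18$ Hz, $\varphi = 90^\circ$,
$A = 10$ (standing for 10 nAm), $f_s = 600$ Hz, 160 ms trials, 200 trials,
SNR 11.85 dB. Dipoles within a label share one time course. The sources are
mapped to sensors by a mixing matrix — identity by default, so unit tests
have exact sensor-level ground truth, or the shipped fixed 10×6 random
matrix (`leakage_mixing_matrix()`, a synthetic stand-in for a forward
solution) when instantaneous leakage between channels is wanted. Gaussian
noise is scaled per channel so each channel's nominal SNR in dB equals the
target (the average over channels then equals it too; the averaging domain is
a package choice). Trials are trial-locked (same absolute phase each trial);
`phase_jitter = TRUE` adds a common random offset per trial while preserving
the inter-label lag, emulating rhythms that are phase-locked to each other
but not to the stimulus.

With $\varphi = 90^\circ$ and no noise the true coherency between the labels
at the $f_0$ bin is exactly $\mp i$: all frequency-domain metrics equal 1
there, and the coherency phase is 90°. These closed-form values are what the
acceptance script recomputes.

What the simulator deliberately does **not** model: realistic lead fields and
cortical geometry, background brain activity (noise is white sensor noise),
inter-trial amplitude variability, and non-sinusoidal rhythms. Passing tests
therefore demonstrate correctness of the estimators and the streaming
machinery under controlled conditions, not performance on real recordings.

## Numerical and design choices

* Time-to-sample conversion is `round(t·fs)` (R's round-half-to-even at exact
  ties, which never arises for the default grids). FFT length `nfft` must be
  at least the trial length; trials are zero-padded, never segmented — with
  `nfft = fs` (600-bin FFT at 600 Hz) the resolution is exactly 1 Hz/bin and
  an 18–30 Hz band is 13 bins averaged. Band averages are arithmetic means of
  per-bin metric values (not of band-averaged CSDs); signed metrics are
  averaged signed and the magnitude is taken only for edge weights, where
  the signed value is retained alongside.
* Thresholding keeps the `ceiling(p·E)` largest of the `E` existing edges,
  with ties at the cutoff broken by ascending `(i, j)` — fully deterministic.
  Normalization divides by the maximum edge weight and is idempotent;
  all-zero networks pass through with a flag.
* The FFT backend is `stats::fft`/`mvfft`; any correct DFT gives identical
  results since all metrics are scale-free ratios (whether one scales CSDs by
  window power is irrelevant for the same reason, so no such scaling is
  applied).
* Seeds control all randomness in the simulator, and seeded noise generation
  restores the caller's RNG state.

## Convergence experiments

`convergence_experiment()` fixes the `k` strongest edges of the normalized
network at the maximum trial count and tracks the mean weight of those same
edges over networks computed from the first $n$ trials. The curve measures
how quickly the finally-detected structure is established, *not* whether it
is correct. `convergence_trials()` reports the first evaluated count within
5% (by default) of the final value.

Two behaviors of this experiment are worth knowing. First, the spread of a
null-pair coherence estimate decays as $1/\sqrt{N}$ (the test suite verifies
the log–log slope $-0.5 \pm 0.1$ over $N = 8{:}128$, 200 Monte-Carlo
replicates with 2-channel white-noise trials of 64 samples). Second, when the
analysis band contains many noise-only bins, band-averaged COH carries a
positive bias on those bins that itself decays like $1/\sqrt{N}$, so the COH
curve drifts slowly upward long after its top-edge *ranking* is stable,
whereas IMAGCOHY's signed noise bins average toward zero. On the default
leakage simulation (10 sensors, band 0–50 Hz, top-20 edges, grid
10:200 by 10) COH first reaches its final value before IMAGCOHY, matching the
qualitative claim that metrics using the full CSD converge faster than those
projected onto the imaginary part — but this is a single-realization
statement: across other noise seeds the ordering can tie or reverse at this
desk scale (6 sources, 10 sensors). The acceptance test runs the generator's
default conditions and should be read with that caveat.

Problem sizes throughout the test suite (trial counts up to 200, 2–32
channels, 600-bin FFTs, 20 seeded replicates for the recovery check, 200
Monte-Carlo replicates for the slope check) were chosen as the smallest sizes
at which the statistical assertions are stable.

## Worked example

```{r example, eval = FALSE}
library(connstream)

sim <- simulate_two_label_dataset(simulation_spec(seed = 1))
eng <- connectivity_engine(6, fs = 600, metric = "IMAGCOHY",
                           fmin = 18, fmax = 18, nfft = 600,
                           storage_mode = TRUE)
for (e in sim$epochs) net <- add_trial(eng, e)
net <- normalize_by_max(net)
glance(net)
threshold_top_fraction(net, 0.25)
autoplot(net)

# switch metric on the fly; no raw data are revisited
switch_metric(eng, "COH") |> normalize_by_max() |> glance()
```

## Known limitations

* COR/XCOR and the moving-average horizon need `storage_mode = TRUE`; the
  horizon slide costs $O(H)$ per update (still independent of the total
  trial count).
* All epochs fed to one engine must share the channel count; XCOR
  additionally requires equal epoch lengths.
* Empty networks (no trials yet) are valid values, not errors, so a
  `switch_metric()` before any data returns zero edges.
* The package does not implement source estimation, noise projections
  (SSP-like), multitaper spectra, Hilbert-phase time-resolved connectivity,
  or effective-connectivity measures.
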