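---
title: "Laminar GLIF networks: model, training and coding analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Laminar GLIF networks: model, training and coding analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glifnet)
```

# What this package models

`glifnet` implements, at desk scale, the full computational loop of a
data-style laminar model of mouse primary visual cortex: a spatially
structured spiking network of generalized leaky integrate-and-fire neurons
with after-spike currents (GLIF\(_3\)), driven through an LGN-style
spatiotemporal filter bank, trained on five visual tasks by
backpropagation-through-time with a surrogate gradient under biological
constraints (Dale's law, firing-rate and membrane-voltage regularization,
small layer-5 readout pools), and characterized with the population-coding
statistics used for such models: cross-validated PCA eigenspectra with
power-law fits, the discriminability index \(d'\) and its noise-covariance
geometry, a subsampling-robust branching-ratio estimator, and Fano factors.

Everything runs on a single CPU in minutes. The large data artifacts that a
full-scale study uses (a measured connectome, atlas neuron fits, a
17,400-filter LGN model, natural-image datasets, handwritten digits, an
empirical noise distribution) are replaced by *synthetic stand-ins*
generated in code from explicit parameters and seeds; each stand-in is
described below together with what it does and does not emulate.

# Neuron model

The membrane dynamics follow the exponential-Euler discrete form on a 1-ms
grid:

\[
v_j(t+1) = \alpha_j v_j(t) + \frac{1-\alpha_j}{g_j}\Big(I^e_j(t+1) +
\textstyle\sum_m I^m_j(t+1) + g_j E_{L,j} + I^{syn}_j(t)\Big)
- z_j(t)\,(v_{th,j}-E_{L,j})
\]

with \(\alpha = e^{-\delta t/\tau}\), \(\tau = C/g\), and a *soft reset*:
spiking subtracts the fixed amount \(v_{th}-E_L\) instead of clamping the
potential, which keeps the map gradient-friendly. Spikes are
\(z(t) = H(v(t)-v_{th})\), forced to zero for \(\lceil t_{ref}\rceil\) steps
after each spike (the membrane continues to integrate during
refractoriness). Two after-spike currents per neuron follow
\(I^m(t+1) = f_m I^m(t) + z(t)\,\delta I^m\) with
\(f_m = e^{-k_m \delta t}\), giving spike-frequency adaptation (negative
increments) or facilitation (positive increments).

The coefficient of the bracketed current term is \((1-\alpha)\tau/C =
(1-\alpha)/g\), the unique choice for which a constant current \(I\) gives
the steady state \(v^\ast = E_L + I/g\); the package's fixed-point tests pin
this down. Initial conditions are zero in resting-relative units, i.e.
\(v(0)=E_L\) with all currents and spikes zero: a literal 0 mV start would
sit far above threshold in the absolute-voltage formulation.

Synapses are alpha-function shaped with integer conduction delays in
\([1,4]\) ms:

\[
C^{rise}_j(t+1) = e^{-\delta t/\tau_{syn}} C^{rise}_j(t) +
\frac{e}{\tau_{syn}} \sum_i W^{rec}_{ji}\, z_i(t+1-d_{ij}), \qquad
I^{syn}_j(t+1) = e^{-\delta t/\tau_{syn}}\big(I^{syn}_j(t) +
C^{rise}_j(t)\big),
\]

one accumulator pair per distinct \(\tau_{syn}\) among a neuron's inputs
(\(\tau_{syn}\) depends on the pre/post class pair; the default table uses
5 ms for excitatory and 8 ms for inhibitory presynaptic classes). The
\(e/\tau_{syn}\) factor is the alpha-function normalization, so a unit
spike through weight \(w\) produces a current transient peaking near \(w\)
about \(\tau_{syn}\) ms after arrival. A spike with delay \(d\) first enters
the rise accumulator \(d\) steps after emission.

**Neuron-type library.** Eight hand-specified GLIF\(_3\) parameter sets
(4 excitatory, 4 inhibitory; \(\tau \in [5,30]\) ms, \(t_{ref}\in[2,5]\) ms,
after-spike decay rates \(1/30\) and \(1/300\) per ms with signed
increments) stand in for large atlas-derived fit collections. They provide
*diversity*, not biological point estimates; the no-diversity control
collapses them to one type per sign.

# Noise model

Each neuron receives two noise currents drawn from a common zero-centered
heavy-tailed base distribution: *quick* noise redrawn independently every
millisecond (scale \(q\)) and *slow* noise drawn once per 600-ms trial and
frozen (scale \(s\)), mimicking fast synaptic stochasticity and slow network
state drift respectively. Defaults are \(q = s = 2\).

The base distribution stands in for an empirical noise-amplitude
distribution decoded from awake-mouse V1 recordings, which is unavailable
here. We use a Student-t with 3 degrees of freedom, truncated at ±50 scale
units, multiplied by 50 pA. The df follows the requirement of a symmetric,
positive-excess-kurtosis (heavy-tailed) law with finite variance; the 50-pA
scale was chosen once so that \(q=s=2\) produces millivolt-scale membrane
jitter and trial-to-trial rate mixing (Fano factors above 1) in the default
networks — a qualitative, not quantitative, match. All tests that depend on
tail behavior use this one fixture.

# Synthetic connectome

Neurons occupy uniform positions on a disc per layer (default layers L2/3,
L4, L5; 80% excitatory). A pair at lateral distance \(d\) connects with
probability \(p_0[\text{pre},\text{post}] \cdot e^{-d/\sigma_d}\). Two
conventions required a decision because the measured-table formulation
leaves them open:

* **Decay form.** "Exponentially decaying" is implemented literally as
  \(e^{-d/\sigma_d}\) (not a Gaussian), \(\sigma_d = 75\) µm by default.
* **Anchoring.** The base probabilities are interpreted as the connection
  probability *at distance zero*. Measured tables are anchored at pairs
  within ~75 µm; converting between the two conventions only rescales
  \(p_0\), which is a config matrix anyway.

The default class set is deliberately small — one excitatory and one
inhibitory class per layer — with a generic laminar motif (dense
within-layer connectivity, stronger local inhibition, an
L4e→L2/3e→L5e feedforward path) on a 150-µm-radius sheet. Weight magnitudes
are log-normal per presynaptic sign (heavier inhibition), signed by the
presynaptic class (Dale's law), with delays uniform on \(\{1,\dots,4\}\) ms.
Desk-scale calibration: base probabilities and weight scales were chosen
once so that a few-hundred-neuron network has mean in-degree ~10 and
recurrent input is a noticeable fraction of rheobase, i.e. the network is
neither silent nor runaway under stimulus drive. No periodic boundary is
used; edge effects are accepted at this scale.

LGN input innervates all layers with layer-dependent density (all of L4,
half of L2/3 and L5), mirroring the qualitative thalamocortical pattern and
giving every layer a learnable input pathway at desk scale.

Control variants reproduce the standard ablation table: `no_lgn` injects
scaled pixels (factor 0.04) directly; `no_diversity` collapses the type
library; `no_laminar` rewires the *same number* of edges uniformly at
random; `rsnn` additionally replaces all neurons by one LIF type (10-ms
membrane constant, 5-ms refractory period, no after-spike currents) and
drops the sign constraint; `rsnn_ei` keeps Dale's law.

# Visual front end

Images are converted to grayscale and scaled affinely from \([0,255]\) into
\([-Int, Int]\) with \(Int = 2\). The front end is a small bank of four
filter classes (sustained-ON/OFF with a 50-ms exponential low-pass,
transient-ON/OFF and OFF/ON with a 20/40-ms biphasic kernel) on
difference-of-Gaussians spatial receptive fields tiling the central oval of
the raster — a 208-unit stand-in for a filter model three orders of
magnitude larger. Kernel lobes are normalized so the sustained class has
unit DC gain and the transient class exactly zero DC gain; outputs are
rectified at zero and interpreted as firing rates in Hz (gain chosen so
full-contrast stimuli evoke tens-to-hundreds of Hz). What this stand-in
does *not* emulate: temporal-frequency subtypes, measured filter
parameters, and retinal nonlinearities; conclusions about absolute
orientation tuning or acuity therefore do not transfer.

# Tasks and readout

Five generators produce 600-ms trials (movie + per-50-ms-chunk targets +
response windows): fine orientation discrimination (100-ms drifting grating
at 0.05 cycles/degree, 2 Hz drift, orientation uniform on
\([43^\circ,47^\circ]\) at \(0.1^\circ\) precision, target =
orientation > 45°), 10-class glyph classification, visual change detection
for texture images and for static gratings (100-ms presentations, 200-ms
gray gaps, 50% change probability, response window starting 150 ms after
onset; network state and image identity carry over between trials), and
evidence accumulation (seven 50-ms left/right cues with 10-ms gaps,
majority-side target). The evidence-accumulation delay is shortened to
140 ms so that cues, delay and a trailing 50-ms response window tile
exactly 600 ms — the nominal cue/gap/delay timings of the corresponding
behavioral protocol do not fit a 600-ms trial, so the delay absorbs the
difference and is configurable. One degree of visual angle maps to 4 pixels
by default (configurable); orientation information in the default raster
was verified to be linearly decodable from the front-end rates.

Decisions are read from pools of excitatory L5 neurons (default 15 pools of
30; desk-scale tests use fewer/smaller): the pool rate
\(r = \frac{1}{T_{resp} N_{readout}}\sum_{t,j} z_j(t)\) is compared to
\(r_0 = 0.01\) spikes/neuron/ms for binary tasks, and pools compete by
argmax for classification and evidence. Pools are colocated (55-µm spheres,
centers ≥150 µm apart) or distributed; a ridge-regularized global linear
readout over all neurons is provided as the upper-bound baseline.

# Training

The non-existing derivative \(\partial z/\partial v\) is replaced by the
Gaussian pseudo-derivative
\(\psi = \frac{\gamma_{pd}}{v_{th}-E_L} e^{-(v_{sc}/\sigma_p)^2}\),
\(v_{sc} = (v-v_{th})/(v_{th}-E_L)\), with \(\gamma_{pd}=0.5\) and
\(\sigma_p=0.28\); zero during refractoriness. The loss is

\[
L = L_{CE} + \lambda_f L_{rate} + \lambda_v L_{v}, \qquad
\lambda_f = 0.1,\ \lambda_v = 10^{-5},
\]

with the binary cross-entropy on chunk rates
\(-\sum_m [T^{(m)}\log\sigma(\theta(r^{(m)}-r_0)) +
(1-T^{(m)})\log\sigma(\theta(r_0-r^{(m)}))]\) (trainable positive scale
\(\theta\)); for multi-pool tasks a standard softmax cross-entropy over
\(\theta r_k\) is used, since the printed binary form does not cover them.
\(L_{rate}\) is a quantile-weighted Huber distance between the sorted
per-neuron mean rates and a sample from a target rate distribution
(log-normal, median 4 Hz — matching the scale of reported mean cortical
rates; the original target-rate table is unavailable). The printed form of
this term is ambiguous about whether the Huber value is multiplied or
divided by the width \(\kappa = 0.002\); we multiply, following the
worked-example convention — the choice only rescales \(\lambda_f\).
\(L_v\) penalizes excursions beyond one \(|E_L|\) from rest,
\(([u-1]^+)^2 + ([-u-1]^+)^2\) with \(u = (v-E_L)/|E_L|\); the sign of the
second rectifier is chosen so the term vanishes at rest (the printed form
does not).

The backward pass is a hand-derived adjoint recursion through the unrolled
dynamics (membrane, after-spike currents, delayed alpha synapses), batched
over trials. Its correctness is established two ways: (i) a *soft* forward
mode replaces the threshold by the smooth antiderivative of \(\psi\),
making the system differentiable end-to-end; the adjoint gradient then
matches central finite differences to relative error \(<10^{-4}\);
(ii) loss decreases monotonically on a deterministic separable toy task.
Optimization is plain SGD (the optimizer is not specified in the printed
methods); after every update weights are sign-clipped — an excitatory
weight pushed negative is set to 0 and vice versa — so Dale's law is
invariant under training; input weights stay nonnegative; \(\theta\) stays
positive. Gradients are masked to the existing edge set: no connections are
created or deleted.

During training each trial is simulated independently from reset initial
conditions (change-detection *stimulus identity* still chains within the
generator); at evaluation time change-detection trials chain both identity
and network state. The mismatch is a desk-scale simplification: chaining
membrane state across the lanes of an interleaved SGD batch has no
well-defined ordering.

Training is noiseless by default, with the data-driven noise applied at
test time; a noise model can be supplied to train with noise. Two desk-scale
lessons are baked into the defaults. First, gradient flow requires readout
neurons whose membrane visits the responsive zone of the pseudo-derivative:
with thalamic input restricted to L4, small networks leave L5 readouts
~20 mV from threshold and gradients die, which is why the default input map
innervates all layers. Second, single weight updates are capped elementwise
(`max_dw`, default 0.5 pA): with heavy-tailed noise or borderline learning
rates an occasional trial produces gradients orders of magnitude above
typical, and one uncapped step can undo hundreds of good ones.

**What desk-scale training can and cannot show.** At full scale this family
of models reaches behavioral-range accuracy on all five tasks. At a few
hundred neurons the attainable accuracy is bounded by the *front end*, not
by the learner: for the fine orientation task, a nonnegative
(Dale-feasible) linear readout applied directly to the filter-bank rates
during the post-offset response window — an oracle that skips the spiking
network entirely — reaches about 80% held-out accuracy, because a 208-unit
center-surround bank retains only limited phase-invariant orientation
signal once the grating is gone. Surrogate-gradient SGD through the
200-neuron spiking bottleneck recovers a substantial fraction of this
ceiling (roughly 0.65 versus the 0.5 chance level within 200 steps). The
training tests therefore assert the qualitative property — held-out
accuracy strictly above the untrained baseline and clearly above chance
with decreasing loss — rather than a full-scale accuracy figure.

# Coding analyses

* **cvPCA.** Eigenvectors from the SVD of one repeat (centered by its
  column means, applied to both repeats); cross-validated eigenvalues are
  the cross-repeat products of projections, divided by \(S-1\) so that
  coincident repeats reproduce the ordinary PCA variance spectrum exactly.
  Repeated-trial data are split into random halves, averaged within half,
  and the spectrum averaged over 10 splits.
* **Power-law fits.** OLS in \(\log_{10}\)–\(\log_{10}\) space over every
  window from the \(n_{min}\in[1,20]\), \(n_{max}\in[301,\cdot]\) grids
  (adapted for short spectra), keeping the window with maximal \(R^2\) and
  flagging fits that never exceed \(R^2 = 0.99\). Prefix-sum OLS makes the
  grid search O(grid) rather than O(grid × window).
* **\(d'\).** After PLS reduction to 5 label-covariant dimensions
  (delegated to `mixOmics::pls`), \((d')^2 = \Delta\mu^\top\Sigma^{-1}
  \Delta\mu\) with \(\Sigma\) the condition-averaged noise covariance
  (1/(N−1) estimator); eigendecomposition of \(\Sigma\) yields the
  signal-to-noise decomposition \(\sum_\beta |\Delta\mu\cdot
  e_\beta|^2/\lambda_\beta\), an exact identity tested to machine
  precision. Singular \(\Sigma\) falls back to a pseudo-inverse (rank
  tolerance \(10^{-10}\)) with a warning; after 5-D PLS reduction with more
  trials than dimensions this path is rarely taken. The shuffled variant
  permutes each neuron's responses across trials within class.
* **Branching ratio.** Lag-\(k\) regression slopes \(m_k\) of the
  (subsampled) population count series, fitted by \(m_k = b\,m^k\) with
  `minpack.lm::nlsLM` initialized from the log-linear slope. Stationary
  subsampling enters only through \(b\), which is what makes the estimator
  subsampling-robust where the naive lag-1 slope is biased low; both are
  exposed so the bias is testable.
* **Fano factor.** Variance/mean of 10-ms window counts across repeated
  identical trials, averaged over windows, then over neurons with nonzero
  mean.

# Problem sizes and numerical choices

The test suite and the end-to-end pipeline run at sizes chosen for
single-CPU turnaround: networks of 120–450 neurons, trials of 200–600 ms,
tens-to-hundreds of training steps, eigenspectrum analyses on tens of
stimuli, branching runs of 1.2–100 s of simulated time. All sizes scale up
through configuration objects without code changes. Degenerate inputs are
handled explicitly: non-finite membrane state aborts with a diagnostic;
non-finite loss aborts training; zero noise scales short-circuit to exact
zeros; empty pools, mismatched shapes and invalid configs raise errors
rather than propagating.

# What passing tests do and do not show

The synthetic fixtures make every claim *mechanistically* testable —
estimator identities, planted-parameter recovery, invariances, schedule
arithmetic, bitwise simulator equivalence against scalar oracles. They do
not validate biological parameter values: the connectome motif, filter
bank, neuron library and noise law are stand-ins with realistic *structure*
but invented *numbers*. Results that depend on those numbers (absolute
accuracies, exact eigenspectrum exponents of simulated networks, absolute
Fano factors) should be read as demonstrations of the machinery, not as
predictions about cortex.
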