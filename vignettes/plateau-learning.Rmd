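---
title: "Dendritic plateau-potential learning in multi-compartment spiking networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dendritic plateau-potential learning in multi-compartment spiking networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlifsnn)
```

# The model

`mlifsnn` simulates a three-layer feedforward spiking network whose units
are multi-compartment leaky integrate-and-fire (MLIF) neurons. A hidden
neuron has three compartments — a basal dendrite collecting feedforward
input, an apical dendrite collecting top-down feedback from the output
layer, and a soma; an output neuron has only a basal dendrite and a soma.
All communication between layers is by binary spikes at 1 ms resolution:
rates are the only code, and membrane potentials never cross a layer
boundary.

Presynaptic spike trains are low-pass filtered by the double-exponential
kernel

$$K(t) = \frac{e^{-t/\tau_l} - e^{-t/\tau_s}}{\tau_l - \tau_s}\,\Theta(t),
\qquad \tau_l = 10\ \mathrm{ms},\ \tau_s = 3\ \mathrm{ms},$$

truncated to a 10 ms window (ten 1-ms taps, a spike contributing from the
step after it occurs) so that the floating-point reference and the
digital-register implementation compute the same quantity. The neglected
tail is below $e^{-1}$ of the slow exponential's peak. The dendritic
potentials are affine/linear maps of the filtered traces,
$V^{0b} = W^0 x + b^0$, $V^{0a} = Y s^1$, $V^{1b} = W^1 s^0 + b^1$, and
the soma performs one forward-Euler step per millisecond,

$$V^0 \leftarrow V^0 + \bigl(g_l(V_{res}-V^0) + g_b(V^{0b}-V^0)
  + g_a(V^{0a}-V^0)\bigr)/C_m,$$

with the output soma receiving in addition a conductance-based teaching
current $I = g_E(E_E - V^1) + g_I(E_I - V^1)$. Voltages convert to rates
through $\phi = \phi_{max}\,\sigma(V)$ and spikes are drawn per
millisecond as Bernoulli$(\phi\,dt)$ (reference backend) or read from a
pre-generated lookup table (hardware backend). The parameter defaults
(`network_params()`) are: $dt = 1$ ms, $\phi_{max} = 0.2$ spikes/ms,
$E_E = 12$, $E_I = -12$, $g_d = g_b = 0.6$, $g_a = 0$, $g_l = 0.1$,
$V_{res} = 0$, $C_m = 1$, unstable time $\Delta t = 30$ ms,
$\eta^0 = \eta^1 = 0.01$, $P^0 = 20/\phi_{max}$,
$P^1 = 20/\phi_{max}^2$. With $g_a = 0$ the apical compartment does not
move the somatic voltage; it exists purely to carry the learning signal.
The $g_a(V^{0a}-V^0)$ term is implemented as written and activates if
$g_a$ is configured nonzero.

# The two-phase learning rule

A training trial lasts 200 ms. During the *forward phase* (first 100 ms)
the teaching current is zero. During the *target phase* (second 100 ms)
each output soma is nudged: for classification the labeled output gets
$(g_E, g_I) = (1, 0)$ and all others $(0, 1)$. Within each phase, the
first $\Delta t = 30$ ms are discarded while voltages settle, and the
remaining 70 samples are averaged. The *plateau potential* of a hidden
neuron is the sigmoid of its windowed apical mean,
$\alpha = \sigma(\overline{V^{0a}})$, computed once per phase. Weights
update once, at the end of the target phase:

$$\Delta W^0 \propto \eta^0 P^0 \frac{g_b}{g_l+g_b+g_a}
  (\alpha^t - \alpha^f)\,\phi_{max}\,\sigma'(\overline{V^{0f}})
  \otimes \bar{x}^f,$$

and analogously for the output layer with the rate difference
$(\bar\phi^{1t} - \bar\phi^{1f})$, $\bar\phi = \phi_{max}
\sigma(\overline{V^1})$, in place of the plateau difference. Bias updates
drop the presynaptic factor. The feedback matrix $Y$ is never modified.
Each neuron's update uses only its own phase averages and the presynaptic
trace — memory per neuron is $O(1)$ in trial length.

Three conventions in this rule were genuinely open and are configurable
(`learning_config()`); the defaults are the ones under which the system
learns:

* **Update sign** (`update_sign`, default `+1`): applying the update term
  with a leading minus, so that $\alpha^t > \alpha^f$ *decreases* the
  weight, drives the forward-phase output away from the nudged target —
  the output error then grows until the sigmoid saturates and accuracy
  stays at chance (we verified this empirically at both small and large
  initializations). The default applies the update in the descent
  direction: forward statistics move toward the nudged ones, which is the
  convention of the segregated-dendrite learning literature this model
  belongs to. `update_sign = -1` selects the opposite convention.
* **Presynaptic statistics** (`presyn_stat`, default `"sum"`): the
  digital accumulator design scales the apical and somatic potentials by
  $1/70$ as they are accumulated, so their finished sums are means; the
  presynaptic traces $\bar{x}^f$ and $\bar{s}^{0f}$ have no such scaler
  and arrive as 70-sample window *sums*. The distinction matters: it
  rescales every weight (not bias) update by the window length. With
  per-sample means throughout (`presyn_stat = "mean"`), the
  discriminative component of the output-layer updates is of order
  $\eta^1 P^1 \phi_{max}^2 \sigma'^2 \sum_j \bar{s}^{0}_j{}^2 \approx
  10^{-4}$ per trial, giving a learning time constant of several thousand
  trials — far beyond the 2000 trials of the classification experiment;
  we measured exactly this stagnation. With window sums, the same
  experiments converge in a few hundred epochs.
* **Averaging window** (`plateau_window_mode`): `"phase"` (default)
  averages everything past the unstable time, 70 samples at the defaults,
  matching the accumulate-and-scale implementation; `"delta"` averages
  only the last $\Delta t$ ms.

# Initialization

The weight scales at initialization are not physical parameters but they
decide whether the network is alive. The filtered traces live on a scale
of $\le \phi_{max} \sum_\tau K(\tau) \approx 0.1$, so feedforward weights
of scale $w$ produce dendritic potentials of scale
$w \cdot 0.06\sqrt{n_{in}}$; for those to reach the sigmoid's sensitive
range ($|V| \sim 1$) with 8-channel inputs, $w \sim 1$ is needed. The
defaults of `build_network()` are $W^0, W^1 \sim U(-1, 1)$,
$Y \sim U(-4, 4)$, $b^0 = +2$, $b^1 = 0$:

* $W \sim U(-0.1, 0.1)$ (a plausible-looking guess) leaves all voltages
  at $O(0.01)$, every rate pinned to $\phi_{max}/2$, and the plateau
  differences buried in sampling noise — nothing learns.
* $Y \sim U(-4, 4)$ makes the nudged output layer move the apical means
  by $O(1)$, so plateau differences are resolvable against the
  70-sample averaging noise within a few trials.
* $b^0 = +2$ starts the hidden layer in an active regime. This improves
  the reproduction fit and, more importantly, routes the rate code
  through spikes rather than through a silent-layer bias solution, which
  is what makes the network legitimately sensitive to spike-drop noise.

# The experiments

**Classification.** Four 8-channel patterns, every channel at 20 or
200 Hz: even channels high (the pattern family's canonical example), its
complement, first half high, second half high; labels 1–4. An epoch
presents each pattern once for one 200 ms training trial. Testing runs a
1000 ms forward-only readout and predicts the output with the most
spikes (ties to the lowest index). An `8x10x4` network (120 synapses)
reaches 100% accuracy after 500 epochs in all of 10 seeds; the
`test-acceptance` suite asserts at least 8 of 10.

**Reproduction.** An `8x10x8` network (160 synapses) is trained for 300
epochs to reproduce a single random frequency pattern
($r_j \sim U(20, 200)$ Hz). Teaching is graded: the paper-family
literature specifies nudging only for the one-hot case, so the package
derives the conductances from the rule's own fixed point. At convergence
the forward somatic voltage settles at $V^* = g_E E_E + (1-g_E) E_I$
(with $g_I = 1 - g_E$); demanding that the converged forward rate equal
the target rate $r$ gives

$$g_E = \frac{\mathrm{logit}(r / \phi_{max} \cdot 10^{-3}\mathrm{Hz}^{-1})
  - E_I}{E_E - E_I}.$$

A linear encoding such as $g_E = r/200$ converges instead to a
sigmoid-distorted rate map (up to tens of Hz of systematic error at
mid-range rates — the fixed point above makes this exact). The readout
window for rate estimation is 4000 ms: a window of $T$ seconds measures a
channel at rate $r$ with standard error $\sqrt{r/T}$ Hz, i.e. an MAE
floor of about 8 Hz at $T = 1$ s across the 20–200 Hz range — larger
than the network's own error; at $T = 4$ s the estimator floor (~4 Hz)
sits below it. Median over 10 seeds: MAE $\approx$ 3.8 Hz,
$R^2 \approx 0.99$.

**Drop noise.** Noise thins spikes independently with probability $p$.
The default application point is the *inter-layer transmission*: the
input rasters entering the hidden basal dendrites and the hidden soma
spikes entering the output basal dendrites, while each output neuron's
spike counter still sees its own soma. Two observations fix this choice.
Thinning only the input rasters of a trained network barely degrades it
at any drop probability — input perturbations are absorbed by sigmoid
saturation and by the bias-borne component of the drive (we measured MAE
changes of under 1 Hz at $p = 0.5$ across all initializations tried); a
noise protocol under which the headline robustness experiment shows no
effect cannot be the intended one. Thinning every soma's output
including the output layer's own counters simply scales the measured
rates by $1-p$, which at $p = 0.5$ overshoots any plausible degradation
(MAE $\approx$ 55 Hz, negative $R^2$). Transmission thinning lies
between: the median MAE rises monotonically from ~4 to ~17 Hz and $R^2$
falls monotonically from 0.99 to ~0.82 as $p$ goes 0 to 0.5. The
degradation at $p = 0.5$ remains somewhat smaller than the reference
hardware reported; the acceptance test asserts the reference band and
documents the shortfall rather than widening the band.

# The hardware-emulation backend

The `"hw"` backend reproduces, bit for bit, the arithmetic of a
fixed-point digital implementation:

* **24-bit sign-magnitude fixed point** (`fx_quantize()`, `fx_encode()`):
  1 sign bit, 7 integer bits, 16 fraction bits; value
  $(-1)^{sign}(integer + fraction/2^{16})$. All rounding is truncation
  toward zero — what a right-shifting barrel shifter does — applied
  uniformly, and out-of-range values saturate rather than wrap.
* **Shift multiplication** (`shift_mul()`): a product $a \cdot b$ with
  $a \in [0, 1)$ is the sum of $b$ right-shifted by the positions of
  $a$'s set fraction bits, each shift truncating. The error obeys
  $|{\rm shift\_mul}(a,b) - ab| \le 2^{-16}|b| + 16 \cdot 2^{-16}$,
  verified against an exact integer oracle on $10^5$ random pairs.
  Constant-by-variable products (PWL slopes, $\phi_{max}$, $1/70$) use
  the same shift-add scheme with the constant's bits fixed.
* **Piecewise-linear nonlinearities** (`pwl_sigmoid5()`,
  `pwl_dsigmoid6()`): the sigmoid as five segments with borders
  $(-3.4, -1.3, 1.3, 3.4)$ clipped to $[0,1]$, its derivative as six
  segments with borders $(-3.2, -2, 0, 2, 3.2)$ clipped below at 0.
  Every slope is a single power of two, so a slope multiplication is one
  shift. The published coefficient table prints border magnitudes only
  and repeats rows for the derivative; the segment layout used here is
  the unique increasing-border reading consistent with the shapes of
  $\sigma$ and its even, bump-shaped derivative (positive-flank slopes
  negated). `fit_pwl()` reproduces such tables by deterministic
  coordinate descent on the stated grids (borders step 0.1,
  slopes/intercepts step 0.01) from a least-squares warm start; a joint
  enumeration over 5–6 segments is combinatorially infeasible.
* **Lookup-table Poisson sampling** (`poisson_lut_build()`): ten stored
  Bernoulli trains, one per 20 Hz segment of the 0–200 Hz range
  ($\lambda = 0.02, \dots, 0.2$ per ms), each required to pass a
  chi-square Poisson conformity check at significance 0.05 (counts per
  20 ms window, categories pooled to expectation $\ge 5$; failing trains
  are regenerated). Sampling maps a rate to
  $\min(9, \lfloor r/20 \rfloor)$, reads one bit at the neuron's address
  and advances the address with wrap-around. Stored trains are 4096 bits
  — a 200 ms trial never rereads a bit. Two consequences of the table
  design are surfaced rather than hidden: rates below 20 Hz (including
  exactly 0) still read the $\lambda = 0.02$ train, a residual 20 Hz
  floor of the segmented table, and per-neuron addresses are initialized
  at distinct seeded offsets since neurons sharing a bin and an address
  would emit identical spike trains.

On identical input rasters, the somatic-voltage trace of a hidden neuron
simulated under the two backends agrees with $R^2 > 0.9999$ over 20
seeds (`compare_backends("mlif_trace")`); the dominant backend
difference is the PWL sigmoid's approximation error, visible in the rate
traces, not the voltage dynamics.

## What the error table does and does not reproduce

On a dense uniform grid over $[-8, 8]$ (step 0.01, spanning every
breakpoint and the clipping onset), the five-segment sigmoid reaches
RMSE 0.0113, MAE 0.0060, $R^2$ 0.99932 — matching the reference error
table's sigmoid row within its grid uncertainty. The derivative row of
that table (RMSE 0.0015, MAE $2.16 \times 10^{-4}$) is *not* attainable
under any dense-grid protocol: the best possible six-segment PWL of
$\sigma'$ on such a grid — free real coefficients, optimized breakpoints
— has RMSE $\approx 0.0036$, and the published coefficients give 0.0078.
The implied reference variance also differs by an order of magnitude
between the two rows, pointing to a non-uniform input distribution
(plausibly voltages recorded from a running simulation, which concentrate
in saturated regions where the PWL fit is nearly exact) that is not
specified. The package evaluates on the declared grid and reports the
discrepancy; the corresponding acceptance assertions are left failing by
design.

# Numerical choices and degenerate inputs

* Boundary values in `pwl_eval()` belong to the lower segment
  (`V <= N_i`), per the segment definition.
* Fixed-point encoding truncates toward zero; $-0$ and negatives that
  truncate to zero normalize to $+0$.
* `predict_class()` breaks ties toward the lowest index.
* Phase averages require both phases to have accumulated samples;
  finalizing an incomplete trial is a state error, not a silent zero.
* A degenerate all-zero spike train fails the chi-square conformity
  check with a finite p-value rather than erroring.
* The compiled trial loop and the plain-R reference loop consume RNG
  draws in the same fixed order (input, input-noise, hidden,
  hidden-noise, output, output-noise) and are exchangeable; the test
  suite asserts equality of spike rasters and weights between them.

# What the synthetic patterns do and do not emulate

The fixtures are frequency-coded rate patterns with independent Poisson
channels — the regime the model is designed for. They do not contain
temporal structure within a trial (no correlations between channels, no
rate modulation), so passing tests demonstrate rate-coding capacity, not
temporal-pattern learning. The classification fixture fixes one pattern
to the canonical even-channels-high layout and invents the other three
as its complement and the two half-field patterns; any four mutually
discriminable binary patterns behave equivalently. Problem sizes
(`8x10x4`, `8x10x8`, 500/300 epochs, 10 seeds) are the study's own; the
trainer also runs a `784x500x10` configuration unchanged, which the test
suite exercises for one trial.

# Known limitations

* Learning at the published rates depends on the presynaptic-sum
  convention; under strict per-sample means the experiments do not
  converge at the stated epoch counts (both conventions are available).
* The reproduction solution carries part of its drive in biases and
  saturated units, so its degradation under transmission noise at
  $p = 0.5$ (MAE $\approx$ 17 Hz) is milder than the reference
  hardware's reported value.
* No refractory period, axonal delays, conductance-based synapses, or
  continuous-time plasticity variants; two's-complement arithmetic and
  DSP-block emulation are out of scope.
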