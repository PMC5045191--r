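---
title: "Nonlinear Hebbian learning: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonlinear Hebbian learning: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

A sensory neuron with input vector $x$, weights $w$ and f-I curve $g$ fires at
rate $y = g(w^\top x)$. Hebbian plasticity that is linear in the pre-synaptic
activity and nonlinear in the post-synaptic rate, $\Delta w \propto x\,h(y)$,
combines with the f-I curve into an *effective Hebbian nonlinearity*
$f = h \circ g$:

$$\Delta w \propto x\, f(w^\top x), \qquad \|w\|_2 = 1 \text{ enforced by
multiplicative normalization after every update.}$$

Averaged over the input ensemble, these dynamics perform stochastic gradient
ascent on the projection-pursuit objective $R = \langle F(w^\top x)\rangle$
with $F(u) = \int_0^u f$. On whitened input (identity covariance) the variance
of every projection is fixed, so learning is driven entirely by higher-order
statistics: the weights move toward directions whose projected distribution
the objective favours — for most practically relevant $f$, long-tailed
("kurtotic") directions such as localized oriented edge filters in natural
scenes.

`nlhebb` implements this stack end to end: a family of `nonlinearity` objects
with evaluable $f$ and $F$ (`eval_f()`, `eval_F()`, `nl_compose()`,
`nl_negate()`, `activation_from_penalty()`); the selectivity machinery
(`selectivity_index()`, `critical_parameter()`, `objective_value()`,
`relative_objective()`, `objective_map()`); preprocessing
(`sample_patches()`, `fit_whitening()`, `powerlaw_whiten_images()`,
`concat_strabismus()`); single-neuron and network learning
(`learn_single_neuron()`, `network_learning()`); spike-based plasticity
(`simulate_triplet()`, `pairing_curve()`, `fit_quadratic_plasticity()`); and
synthetic data generators so that everything runs without external corpora.

# The selectivity index

Whether a nonlinearity can learn kurtotic features is summarized by

$$SI = \frac{\langle F(l)\rangle - \langle F(g)\rangle}{\sigma_F},$$

where $l$ is Laplacian and $g$ Gaussian, both unit variance (the Laplacian
uses scale $1/\sqrt 2$), and $\sigma_F(\cdot) = \sqrt{\langle F(\cdot)^2\rangle}$.
$SI > 0$ flags nonlinearities suited to learning long-tailed projections.

**Normalization convention.** We use the geometric mean
$\sigma_F = \sqrt{\sigma_F(l)\,\sigma_F(g)}$. A plain product
$\sigma_F(l)\sigma_F(g)$ is sometimes written instead, but it breaks the
multiplicative-scale invariance $SI(\alpha f) = SI(f)$ that the index is
meant to have; the geometric mean restores it exactly. Both conventions have
identical signs and zero crossings — every qualitative and crossing-based
result is convention-independent — and the plain product remains available
via `sigma_convention = "product"`.

**Quadrature.** SI integrals run over $[-12, 12]$ standard units with
absolute tolerance $10^{-10}$ per call, split piecewise at the
nonlinearity's kink points plus the Laplace cusp at zero; adaptive
integrators silently lose several digits on interior kinks otherwise. The
$\pm 12$ truncation leaves an absolute tail error up to $\sim 5\cdot10^{-5}$
for cubically growing $F$ under the Laplace density; this shifts the
quadratic-rectifier critical LTD factor by $\approx 3.5\cdot10^{-4}$,
irrelevant at the precision reported.

**Computed crossings.** With LTD threshold $\theta_1 = 1$, the quadratic
rectifier's SI crosses zero at $b^\ast \approx 2.403$ (closed-form moment
oracle: $b^\ast = \tfrac23\,\Delta E_3/\Delta E_2$ with truncated Laplace and
Gaussian moments), i.e. LTP threshold $\theta_2^\ast \approx 3.40$ — inside
the commonly quoted bound of $3.5$. The rectified-power family
$F(u) = u_+^r$ crosses at exactly $r = 2$, and the linear rectifier at
$\theta = 0$, both forced by symmetry. For the sigmoid
$f(u) = (1+e^{-2(u-a)})^{-1}$ our quadrature gives a crossing at
$|a^\ast| = 1.311$; a figure-level value of $\pm1.2$ is sometimes quoted for
this family. The 1.311 value is robust here (it is unchanged under wider
domains, both $\sigma_F$ conventions, and the centered odd
$-\tanh(u-a)$ variant), so the package reports the computed crossing and
flags the discrepancy rather than matching the quoted figure. Note also that
published tables sometimes print the sigmoid range conditions as
"$|a| > -1.2$" / "$|a| < -1.2$"; the intended reading is $|a|$ against the
positive value $1.2$.

**Cauchy activation.** The sparse-coding penalty $S(y) = \log(1+y^2)$ yields
the activation $g = T^{-1}$, $T(y) = y + 2\lambda y/(1+y^2)$ for $y \ge 0$.
$T'(y) = 1 + 2\lambda(1-y^2)/(1+y^2)^2$ attains its minimum $1 - \lambda/4$
at $y = \sqrt 3$, so $T$ is invertible exactly for $\lambda \le 4$; the
constructor refuses larger $\lambda$ instead of picking an inverse branch.
The inverse is computed by bisection (relative tolerance $10^{-10}$), and
$F$ has the closed form (substituting $v = T(y)$)
$F(u) = \tfrac{Y^2}{2} + \lambda\bigl(2 - \tfrac{2}{1+Y^2} - \log(1+Y^2)\bigr)$
with $Y = T^{-1}(u)$.

**Two "negative sigmoids".** The literature uses both the negated logistic
$-(1+e^{-2(u-a)})^{-1}$ and the centered odd form
$1 - 2/(1+e^{-2u}) = -\tanh(u)$. `nl_negative_sigmoid(a)` implements the
centered form $-\tanh(u-a)$; the negated logistic is
`nl_negate(nl_sigmoid(a))`. They differ by an additive constant in $f$,
which shifts $\sigma_F$ but not the SI numerator or its crossings.

# Learning dynamics

Single-neuron learning iterates
$w \leftarrow \mathrm{normalize}(w + \eta\,x\,f(w^\top x))$ over seeded,
per-epoch-shuffled passes. The inner loop is compiled; it is step-for-step
identical to iterating `hebbian_step()` and the two paths are cross-checked
in the tests.

**Learning-rate schedule.** With constant $\eta$ the weights reach a
stationary distribution around an objective maximum whose transverse spread
grows with $\eta d$ — at $d = 256$ a rate that explores quickly leaves the
final alignment at $|\cos| \approx 0.8$. The package therefore supports a
per-epoch schedule (`eta_schedule`); the dictionary-recovery studies use a
search phase at $\eta = 2\cdot10^{-3}$ followed by refinement at
$5\cdot10^{-4}$ and $2\cdot10^{-4}$. This is a solver choice, not a change
of model: the update rule is unchanged, only its step size anneals.

**Network model.** $K$ neurons share the input and inhibit each other
through non-negative lateral weights $V$ (zero diagonal, Dale's constraint).
Activity is the fixed point of
$\tau_u\,\dot u_j = -u_j + (w_j^\top x - \sum_{k\ne j} v_{jk} y_k)$,
$y_j = g(u_j)$, integrated by forward Euler from $u = 0$ with
$dt = \tau_u/10$, at most 200 iterations, and convergence threshold
$10^{-6}$ on $\max_j |\Delta u_j|$ (the ODE is given by the model; the
solver constants are ours). With no lateral weights the fixed point
$y = g(W^\top x)$ is returned directly, which also makes the $K = 1$ network
*exactly* (bit-for-bit) the single-neuron rule with $f = h \circ g$. Weight
updates are $\Delta w_j = \eta_w\,x\,h(y_j)$ (identity $h$ gives
$\Delta w \propto x y$) with per-column renormalization; the non-local term
$\sum_{k\neq j} w_k y_k y_j$ of the sparse-coding gradient is dropped, as is
standard. Lateral weights follow the anti-Hebbian rule
$\Delta v_{jk} = \eta_v (y_j - \langle y_j\rangle) y_k$, clamped at zero; at
its fixed point pairwise activity covariances vanish. $\langle y_j\rangle$
is an exponential moving average with horizon $\tau = 1000$ samples (the
moving-average form is unspecified in the source models; exponential is the
simplest online choice). $V$ starts at zero.

# Triplet STDP and its rate reduction

The minimal triplet rule is
$\dot w = A^+ y(t)\,\bar y_+(t^-)\,\bar x_+(t^-) - A^- x(t)\,\bar y_-(t^-)$
with $A^+ = 6.5\cdot10^{-3}$, $A^- = 5.3\cdot10^{-3}$ and trace time
constants 114.0, 16.8 and 33.7 ms. Traces are read strictly before a
spike's own increment; simultaneous pre/post spikes are processed pre first.
Two trace conventions are supported, because the printed rate-domain LTD
factor cannot be reproduced from the printed amplitudes under either:

* `"unit_area"` — increments of $1/\tau$ with $\tau$ in seconds, so each
  trace estimates its train's rate in Hz. Analytic Poisson drift:
  $A^+ x y^2 - A^- x y$, LTD factor $b = A^-/A^+ \approx 0.815$ Hz.
* `"jump_by_one"` — unit increments. Drift:
  $A^+\tau_+\tau_x\,x y^2 - A^-\tau_-\,x y$ ($\tau$ in seconds), LTD factor
  $b = A^-\tau_-/(A^+\tau_+\tau_x) \approx 14.35$ Hz.

A commonly quoted fit of the same model to pairing data is $b = 22.1$ Hz;
since neither convention yields it analytically, the package exposes both
conventions, lets $b$ be supplied directly to `nl_quadratic_plasticity()`,
and treats 22.1 Hz as an external constant. Composing the published
piecewise-linear cortical f-I fit (slope 143 Hz/nA, threshold 0.08 nA,
`nl_gif_fI()`) with $h(y) = y^2 - 22.1y$ gives a quadratic-rectifier
effective nonlinearity with LTD threshold 0.08 nA and LTP threshold
$0.08 + 22.1/143 \approx 0.23$ nA; only the ratio $b/a$ matters to the
learning dynamics. The event-driven simulator is validated against an
independent clock-driven integrator (exact per-bin exponential decay,
$dt = 0.01$ ms) and against the analytic Poisson drift of the pairing
protocol (pre rate 20 Hz).

# Preprocessing conventions

* Patches are flattened row-major, origin top-left, 0-based offsets.
* The $\pm90^\circ$ rotation augmentation is interpreted as an independent
  uniform choice among $\{-90^\circ, 0^\circ, +90^\circ\}$ per patch; a
  two-outcome $\{-90^\circ, +90^\circ\}$ variant is available
  (`rotation_outcomes = "two"`) since the published description is ambiguous
  about the identity outcome.
* Exact whitening uses the symmetric transform $M = R D^{-1/2} R^\top$ from
  the sample-covariance eigensystem; eigenvalues below $10^{-8}$ of the
  largest are excluded from inversion (their directions map to zero) — the
  rank-deficient case is unspecified in the source models.
* The approximate power-law filter multiplies each Fourier component by
  $f\,e^{-(f/f_0)^4}$, $f$ the radial frequency in cycles per image
  ($f_0 = 200$), computed from integer frequency indices with the standard
  half-spectrum symmetry so the result is FFT-layout independent; the DC
  term maps to zero. Natural images have spectra slightly steeper than
  $1/f$, so this filter leaves residual low-frequency variance — that
  residual is the point of the non-white-input studies.

# Synthetic data: what it does and does not emulate

The generative model draws $x = A s + \varepsilon$ with unit-norm (Gabor or
given) dictionary columns, i.i.d. latents (Laplacian for kurtotic structure,
excess kurtosis 3; Gaussian; or Bernoulli-Gaussian), optional per-feature
scales, and isotropic Gaussian pixel noise. It reproduces the single
property the theory turns on — a known set of directions with long-tailed
projections, everything else Gaussian — with full provenance for
plant-and-recover tests. It does **not** emulate natural images' scale
invariance, phase structure, occlusions or non-stationarity, so passing
recovery tests demonstrate correctness of the learning dynamics and
objective machinery, not fidelity of any particular receptive-field atlas.
The complex-cell front end (8×8 grid, 3.1-pixel spacing, 8 orientations,
quadrature-pair Gabors with $\sigma_x = 1.2$, $\sigma_y = 2.4$, $f = 0.3$;
512 dimensions) and the gammatone log-spectrogram pipeline (20 channels
equally spaced 0.2–4 kHz in Hz as printed, 4th-order kernels with
equivalent-rectangular-bandwidth widths — a filterbank convention, not a
claim about any corpus — absolute value, log with floor $10^{-5}$ of peak,
mean-pooled 50 Hz frames, 20×20 segments) provide the cross-modality input
shapes. Mean-pooling was chosen for the unstated downsampling step; channel
spacing is linear in Hz because that is what is printed, not the auditory
convention.

# Study conditions used by the packaged analyses

Chosen once as desk-scale but statistically meaningful conditions, and used
by the tests:

* Dictionary recovery: $16\times16$ patches ($d = 256$), $m = 64$ random
  Gabors, unit-variance Laplacian latents, pixel noise 0.1, $n = 50{,}000$
  samples, the annealed schedule above (60 epochs), 20 seeds. Success is
  $|\cos|$ > 0.9 against the whitened dictionary; the residual
  misalignment at convergence reflects finite-sample whitening noise and
  dictionary coherence, not the learning rule.
* Decorrelation study: $4\times4$ patches, four features with latent scales
  $(3, 1, 1, 1)$ and noise 0.2, deliberately **not** whitened so that the
  dominant feature correlates the $V = 0$ baseline's activities; $K = 10$,
  six epochs. The comparison statistic is the median absolute pairwise
  activity correlation on held-out samples.
* Translation invariance: exhaustive torus offsets of stationary synthetic
  images make the patch ensemble exactly translation invariant, so the
  objective map over interior receptive-field positions is flat up to
  envelope clipping; border positions fall off the plateau. Gabor size 4
  ($\sigma_x = 1.2$, $\sigma_y = 2.4$, $f = 0.25$), interior margin 5 px.

# Known limitations

* The GIF spiking neuron itself is not simulated; only its published
  piecewise-linear f-I fit enters, as a constant of the package.
* Gabor fitting is nonlinear least squares with FFT-seeded multi-starts
  (8 by default); like all such fits it can land in local minima for
  filters that are far from Gabor-shaped — by design those fall below the
  0.6 variance-explained acceptance gate. Orientation is identifiable only
  mod $\pi$ and phase mod $2\pi$; fits are canonicalized accordingly.
* `eval_F` for composed and tabulated nonlinearities integrates numerically
  per evaluation point (piecewise, cumulative over sorted points); it is
  accurate but not cheap inside tight loops — learning loops evaluate $f$,
  never $F$.
* Ensembles and states persist as CSV + JSON sidecars; no binary container
  dependency is required.
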