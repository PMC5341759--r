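---
title: "Predictive-coding circuits: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predictive-coding circuits: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(predcoding)
```

This vignette is the package's account of the science it implements: the
generative models, the two inference routes, the Hebbian learning rules, the
local-plasticity extension, and the numerical and design decisions behind
them.

## 1. The generative model and exact inference

A hidden feature $v$ (e.g. the diameter of an object) produces a noisy
observation $u$ (light intensity) through a map $g$:

$$v \sim N(v_p, \Sigma_p), \qquad u \mid v \sim N(g(v), \Sigma_u).$$

Because reflected light scales with area, the default map is $g(v) = v^2$;
linear maps $\theta v$ and gain-times-nonlinearity maps $\theta h(v)$ are
also supported (`nonlinear_map()`). Two simplifications are inherited
deliberately from the modelling tradition: the Gaussian observation model
admits negative intensities (no truncation is applied), and all noise is
Gaussian.

`exact_posterior()` computes $p(v\mid u) \propto p(v)\,p(u\mid v)$ on a
uniform grid, normalized with the trapezoidal rule; the integral of the
unnormalized density doubles as the estimate of the evidence $p(u)$.
Numerical choices:

* **Grid convention.** Uniform, both endpoints included; the default grid
  $0.01, 0.02, \dots, 5$ matches the worked example's domain.
* **Integration rule.** Trapezoidal (`pracma::trapz`). At the default step
  the difference from a Riemann sum is far below every test tolerance; the
  normalization invariant (integral $= 1$ within $10^{-6}$) is tested
  directly.
* **Underflow.** Under the square map the likelihood is astronomically small
  over most of the grid ($p(u{=}2 \mid v{=}3) < 10^{-10}$), so log densities
  are accumulated and exponentiated after subtracting their maximum. A
  posterior whose log density is $-\infty$ everywhere raises a
  degenerate-posterior error rather than returning NaNs.
* **Ties.** `posterior_argmax()` breaks exact ties toward the smallest grid
  value — an arbitrary but fixed convention.

With $v_p = 3$, $\Sigma_p = \Sigma_u = 1$, $u = 2$, the mode sits at
$v \approx 1.57$ (the real root of $2v^3 - 3v - 3 = 0$, the stationarity
condition of the log joint), i.e. $1.6$ to one decimal.

## 2. Free-energy inference and the three-node circuit

With a point-mass (delta) approximate posterior at $\phi$, minimizing the
Kullback–Leibler divergence to the true posterior reduces to maximizing

$$F = \ln p(\phi) + \ln p(u \mid \phi),$$

the joint log density. (The delta distribution's divergent entropy constant
cancels in every gradient and is not represented numerically; the package
keeps all finite constants so that `negative_free_energy()` returns
$\ln p(u, \phi)$ exactly, which makes the density-product oracle in the
tests exact rather than modulo-constant.) Gradient ascent
$\dot\phi = \partial F/\partial\phi$ is implemented in
`infer_phi_gradient()`.

The circuit formulation (`circuit_derivatives()`, `simulate_circuit()`)
replaces the precision-weighted errors by node dynamics

$$\dot\varepsilon_p = \phi - v_p - \Sigma_p \varepsilon_p, \qquad
  \dot\varepsilon_u = u - g(\phi) - \Sigma_u \varepsilon_u, \qquad
  \dot\phi = \varepsilon_u g'(\phi) - \varepsilon_p,$$

whose error fixed points are exactly the precision-weighted errors. Both
routes converge to the same $\phi$; the circuit converges more slowly
because the coupled excitatory/inhibitory loop has oscillatory modes that
must ring down. Quantitatively (and this is asserted in the tests): at the
standard settings the two routes agree within $0.05$ after 5 time units,
but the circuit's error activities only satisfy their fixed-point identities
to $\sim 10^{-2}$ after about 10 time units — at 5 units the residual is
still $\approx 0.02$.

**Integration.** All dynamics use hand-written fixed-step explicit Euler
(`euler_integrate()`), because the fixed-step update *is* the method being
modelled — each Euler step is one update of a rate neuron — and because the
integrator carries an overflow guard (state magnitude $> 10^8$ aborts with
an instability error naming the step) that turns divergence into a
diagnosable failure. `deSolve`'s fixed-step Euler is used as an independent
oracle in the test suite, never as the implementation. The default
$\Delta t = 0.01$ follows the worked exercises; the same step is reused for
the circuit simulation, where it is stated only for the gradient route, on
the grounds that both describe the same physical timescale. A first-order
method at this step has $\sim 2.5\%$ relative error over 5 time units on a
unit-rate exponential; this is irrelevant to fixed points (explicit Euler
preserves them exactly) but is why trajectory-level comparisons in the tests
use tolerances of a few percent.

## 3. Learning the scalar parameters

The gradients of $F$ with respect to $v_p$, $\Sigma_p$, $\Sigma_u$ are
Hebbian in the converged error activities:

$$\partial F/\partial v_p = \varepsilon_p, \quad
  \partial F/\partial \Sigma_p = \tfrac12(\varepsilon_p^2 - \Sigma_p^{-1}),
  \quad
  \partial F/\partial \Sigma_u = \tfrac12(\varepsilon_u^2 - \Sigma_u^{-1}).$$

`learn_parameters()` applies them once per trial. Design choices:

* **Convergence per trial** is a fixed integration horizon $T = 5$ (the
  exercises' horizon), not an adaptive stopping rule — simpler, and faithful
  to how the simulations are specified.
* **Variance floor.** Learned variances are clipped at 1 after every update:
  a variance near zero makes the error-node dynamics diverge or converge
  arbitrarily slowly. The clip is applied only to parameters with a nonzero
  learning rate, so configuring a fixed sub-unit variance is still possible.
* **Default rates** are 0.01 for every parameter (the one rate stated for
  the variance-learning exercise, reused globally for consistency).
* **Two trial semantics.** With `clamp_phi = FALSE` each trial is an
  observation $u$ and the full circuit is simulated. With
  `clamp_phi = TRUE` each trial is a direct sample of the feature $\phi$,
  errors are evaluated at their fixed points, and only the prior parameters
  are updated. The clamped mode exists because it is the setting in which
  the stationarity analysis is exact — $v_p \to \langle\phi\rangle$ and
  $\Sigma_p \to \langle(\phi - v_p)^2\rangle$ — and it mirrors the
  variance-learning experiment, whose generator also emits feature samples
  directly. Under full inference the learned prior describes the statistics
  of the *inferred* features, which are shrunk toward the prior; jointly
  learning both variances from observations alone splits the data variance
  between $\Sigma_p$ and $\Sigma_u$ and, with the floor at 1 and a
  generating variance of 2, pins both at the floor. The package demonstrates
  mean tracking under full inference and mean-and-variance recovery in
  clamped mode, and makes no stronger claim.

For learnable observation maps, $\partial F/\partial\theta =
\varepsilon_u\phi$ (linear) or $\varepsilon_u h(\phi)$ — again a product of
pre- and post-synaptic activity (`grad_theta()`,
`theta_circuit_derivatives()`).

## 4. Multivariate models and the hierarchy

`mv_model()` generalizes everything to vectors:
$\bar v \sim N(\bar v_p, \Sigma_p)$, $\bar u \mid \bar v \sim
N(\Theta h(\bar v), \Sigma_u)$ with $h$ element-wise, so stimuli are linear
combinations of (nonlinearly transformed) features. The gradients

$$\partial F/\partial\bar\phi = -\bar\varepsilon_p +
  h'(\bar\phi)\circ\Theta^T\bar\varepsilon_u, \qquad
  \partial F/\partial\Sigma = \tfrac12(\bar\varepsilon\bar\varepsilon^T -
  \Sigma^{-1}), \qquad
  \partial F/\partial\Theta = \bar\varepsilon_u h(\bar\phi)^T$$

are verified wholesale against central finite differences
(`finite_diff_gradient()`, `gradient_check_suite()`). One convention needs
care: the matrix-calculus rules treat the entries of a symmetric matrix as
free parameters, so the *joint* symmetric perturbation of $(i,j)$ and
$(j,i)$ measures twice the off-diagonal gradient. The finite-difference
checker offers both perturbation modes, and the covariance-gradient tests
assert $\mathrm{FD}_{\mathrm{sym}} = 2G - \mathrm{diag}(G)$.

`hier_stack()` chains the model into a hierarchy: level 1 is the sensory
input, each level predicts the one below through
$\Theta_i h(\bar\phi_{i+1})$, and the rules for dynamics and plasticity are
unchanged — only indexed per level. Boundary choices the chain itself leaves
open:

* the **top level** closes with a fixed Gaussian prior
  $(\bar v_p, \Sigma_{top})$;
* **level 1 is clamped** to the observation (its derivative is zero) — the
  bottom-up term of level 2 is driven by level 1's errors;
* $\bar\phi$ is **initialized at the top-down predicted means**
  (generalizing the scalar convention of starting at the prior mean), errors
  at zero.

With $h = \mathrm{identity}$ the converged state is the generalized
least-squares / normal-equations solution, which the tests verify to
$10^{-6}$ on instances up to $4\times4$ (integration horizon 300 time units
at $\Delta t = 0.005$; explicit Euler reproduces the fixed point exactly, so
the horizon only needs to outlast the slowest mode).

The $\Sigma$ updates use $\Sigma^{-1}$ — biologically awkward, since a
synapse cannot know the whole matrix; that is the motivation for the next
section. The matrix analogue of the variance floor clips eigenvalues at 1
and re-symmetrizes (`floor_covariance`), reducing to the scalar floor in one
dimension.

**Weight learning at scale.** `mv_learn_theta()` trains $\Theta$ by the
Hebbian rule with per-trial gradient-ascent inference. The shipped test uses
4 observations, 2 features with orthogonal true columns, noise sd 0.05,
model $\Sigma_u = 0.1 I$, $\alpha = 0.001$, inference at $\Delta t = 0.02$
for 5 time units, 5000 trials — a configuration chosen once as realistic for
this scale: the effective feature-space update gain is
$\alpha/\Sigma_u = 0.01$ per trial, and the inference step keeps
$\lambda\,\Delta t$ of the stiffest mode ($\lambda \approx
\|\Theta\|^2/\Sigma_u$) well inside Euler's stability region even when the
column norms transiently overshoot 1. Recovery is judged on least-squares
reconstructions of held-out observations (relative error $< 10\%$), not on
raw weights, because the solution is only identified up to rotation,
permutation and sign of the feature axes.

## 5. Local plasticity: learning variances without inverses

Pairing each error node with an inhibitory interneuron $e$,

$$\dot{\bar\varepsilon} = \mathrm{drive} - \bar e, \qquad
  \dot{\bar e} = \Sigma\bar\varepsilon - \bar e,$$

puts the fixed point at $\bar\varepsilon = \Sigma^{-1}\mathrm{drive}$,
$\bar e = \mathrm{drive}$: the division by $\Sigma$ is performed by the loop
dynamics, so the circuit can replace the error nodes of the hierarchical
network without changing what it computes (tested: converged $\varepsilon$
equals $\Sigma^{-1}$drive to $10^{-6}$). The weight update

$$\Delta\Sigma = \alpha(\bar\varepsilon\bar e^T - I)$$

reads only the two activities at the synapse's ends plus the weight itself,
and its stochastic fixed point is the covariance of the drives. Decisions:

* The subtracted "1" is the **identity matrix** in the matrix case — the
  only dimensionally consistent reading — so off-diagonal weights target raw
  covariances.
* The instantaneous update $\bar\varepsilon\bar e^T$ is not symmetric;
  $\Sigma$ is **re-symmetrized** after each step ($\tfrac12(\Sigma +
  \Sigma^T)$). The expected update is symmetric, so this removes only noise,
  and it preserves the covariance interpretation.
* The **variance floor** (eigenvalue clip at 1) is kept inside this circuit
  too. The floor is stated for the plain learning rules, not for this
  extension; keeping it is this package's choice, flagged as such, and it
  also guards the loop's timescale separation.
* **Timescales.** Drives are held constant within a trial and the loop is
  integrated for $T_{inner} = 20$ time units per trial ($\Delta t = 0.01$ by
  default, reused from the inference exercises since none is stated here) —
  the slowest mode decays at rate $\tfrac12$, so activities reach their
  fixed points to $\sim e^{-10}$ before each update, enforcing the
  fast-errors/slow-features separation operationally.
* **Stability.** `stability_analysis()` builds the linearized system matrix
  $\begin{pmatrix}0 & -I\\ \Sigma & -I\end{pmatrix}$; in the scalar case the
  trace is $-1$ and the determinant $\Sigma$, so both eigenvalues have
  negative real part for any $\Sigma > 0$ (at $\Sigma = 1$:
  $-\tfrac12 \pm \tfrac{\sqrt3}{2}i$). No step-size stability bound for
  $\alpha$ is derived here; $\alpha = 0.01$ is the stated rate, and
  divergence at aggressive rates is caught by the overflow guard rather than
  characterized.

Attention can be read as precision modulation: `modulate_precision()` scales
selected variances (equivalently, inhibits the corresponding interneurons),
raising the gain of the attended errors. It is a configuration of existing
operations, not a new mechanism.

## 6. What the synthetic data does and does not emulate

`trial_stream()` / `generate_trials()` draw i.i.d. Gaussian features or
drives with stated mean and (co)variance, minus a fixed top-down prediction
— exactly the generating process of the variance-learning experiment
(mean 5, variance 2, prediction 5) and its multivariate extension (the 2-D
tests use covariance $[[2, 0.8], [0.8, 1.5]]$). A single global seed fans
out to per-component sub-seeds by fixed offsets, so adding one consumer
never shifts another's draws, and every run is bit-reproducible.

This emulates stationary, Gaussian, trial-structured input. It does not
emulate natural stimuli: non-Gaussian statistics, temporal correlation
within trials, or nonstationary environments. Consequently the passing
tests show that the circuits implement their defining fixed-point and
learning equations, and that learning recovers the generating statistics
*under the model's own assumptions* — they do not show that the framework
extracts efficient features from natural images, a claim this package
deliberately does not evaluate.

## 7. Problem sizes, tolerances, known limitations

Simulation sizes used by the shipped tests and the acceptance script were
chosen to make Monte-Carlo error small relative to the quantities checked
while keeping each experiment the size a desk reproduction would use:
1000-trial scalar variance learning (stochastic fluctuation of the
trailing-200 mean is $\approx 0.13$ around 2, so single runs sit within the
stochastic tolerance band), 2000–5000-trial covariance learning, 5000-trial
weight learning, hierarchies up to $4\times4$. Stochastic assertions use
3-standard-error bands, with the standard error taken from batch means or
independent replicates rather than raw within-window variance, because
slow learning rates make consecutive trials strongly autocorrelated.

Known limitations:

* Inference is a point estimate (delta approximate posterior): no posterior
  uncertainty over features is represented beyond the exact grid posterior
  kept for the scalar case.
* Explicit Euler is first-order; trajectory shapes (not fixed points) carry
  $O(\Delta t)$ bias.
* The variance floor at 1 means generating variances below 1 are not
  recoverable by construction.
* Hierarchies are simulated with clamped inputs and separated timescales;
  the oscillatory regime of non-separated timescales is guarded against
  (instability errors), not analysed.
* No claim is made about which biological cell types implement the
  interneurons, or about cortical-layer anatomy.
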