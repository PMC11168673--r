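---
title: "Conductance-based dendritic integration as Bayesian inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conductance-based dendritic integration as Bayesian inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bayesdend)
```

## The model

`bayesdend` simulates a two-layer picture of a cortical pyramidal neuron.
Each dendritic compartment carries excitatory and inhibitory synaptic
conductances `g_exc = sum(w_exc * r)` and `g_inh = sum(w_inh * r)` (weights
in nS s, presynaptic rates in 1/s) plus a local leak. These combine into an
*effective reversal potential*

$$E^d = \frac{g_{exc}E^E + g_{inh}E^I + g_L E^L}{g_{exc} + g_{inh} + g_L},$$

the potential the compartment would relax to in isolation, and a local
conductance $g^d = g_{exc} + g_{inh} + g_L$. The statistical reading is that
each compartment holds a Gaussian *opinion* about the somatic potential:
$E^d$ is the opinion, and $g^d$ (attenuated by the dendro-somatic coupling
factor $\alpha = g^{sd}/(g^{ds} + g^d)$) is its precision, in units of the
exploration constant $\lambda_e$ (variance $= \lambda_e / \alpha g^d$). The
soma holds a Gaussian prior with mean $E_0$ and precision $g_0/\lambda_e$.

Multiplying prior and compartment opinions — precision-weighted Gaussian
fusion, or opinion pooling — gives a Gaussian posterior whose mean is the
conductance-weighted convex combination

$$\bar E_s = \frac{g_0 E_0 + \sum_i \alpha_i g_i^d E_i^d}
                   {g_0 + \sum_i \alpha_i g_i^d},
\qquad \bar g_s = g_0 + \sum_i \alpha_i g_i^d,$$

with posterior variance $\lambda_e/\bar g_s$. `pool_posterior()` implements
exactly this, and `grid_posterior_oracle()` provides an independent
brute-force check (pointwise product on a potential grid, trapezoid
normalisation) used throughout the tests.

The somatic membrane equation
$C\dot u_s = \bar g_s(\bar E_s - u_s) + \xi$, with white noise of spectral
density $2C\lambda_e$, is precisely an Ornstein–Uhlenbeck process whose
stationary law is that posterior and whose time constant is
$\tau = C/\bar g_s$: the membrane *samples* the posterior, and a stronger
(more reliable) stimulus both shifts the mean and tightens and speeds the
dynamics. `simulate_soma()` integrates this equation; `simulate_full()`
integrates the coupled soma–dendrite system with finite dendritic
capacitances, which collapses onto the reduced dynamics as $C_d \to 0$.

Learning treats a sample $u^*$ from a target potential distribution as data
and ascends $\lambda_e \log p(u^*\mid W, r)$:

$$\dot W^{E/I}_i \propto \alpha_i\Big[(u^* - \bar E_s)(E^{E/I} - \tilde E_i)
 + \tfrac{\alpha_i}{2}\big(\tfrac{\lambda_e}{\bar g_s}
 - (u^* - \bar E_s)^2\big)\Big] r_i,$$

with $\tilde E_i = \alpha_i \bar E_s + (1-\alpha_i)E_i^d$. The first term
corrects the pooled mean, the second matches the pooled variance; weights
are clipped at zero (conductances cannot be negative).
`weight_gradient()` is verified against central finite differences of the
log-score through the full pooling pipeline, which is the primary
correctness surface for the rule.

## Parameters that matter

* `lambda_e` (nS mV²) converts conductance into potential variance; 1 in
  the learning experiments, 100 in the finite-capacitance stimulus runs.
* `g0`, `E0` (nS, mV): somatic prior; defaults 0.25–1 nS at −70 mV.
* `g_sd`, `g_ds` (nS): coupling conductances. `Inf` is a first-class flag
  meaning $\alpha = 1$ exactly; the learning experiments run in this
  strong-coupling limit.
* `C` (pF): somatic capacitance; 0 flags the instantaneous limit in which
  the soma returns the MAP value (or a posterior sample) directly.
* `dt` (ms): Euler–Maruyama step, default 0.2; the stability guard
  requires `dt * g_bar / C < 1`.
* Detector banks: 70 units per modality, preferred orientations uniform on
  [−315°, 405°] (the stimulus variable is treated as a real line, no
  wrap-around), baseline/peak rates 0.75/16 s⁻¹, tuning concentration
  `kappa_deg2` (see below).

## What the synthetic stimuli emulate

All data are generated internally. A trial draws a ground-truth orientation
(or input rate), corrupts it with modality-specific Gaussian noise
(σ_V = 13.5°, σ_T = 28.5° for cues; 0.01875 and 0.3 s⁻¹ for rate
channels), maps cues through Gaussian tuning curves, optionally scales by a
stimulus contrast and mixes with background-driven rates
(r = γ r′ + (1−γ) r^b), and floors Gaussian-noised rates at a small
positive minimum. Unimodal trials silence one modality chosen by a fair
coin. What this does *not* emulate: spiking (all inputs are rates), learned
or heterogeneous tuning curves, temporal cue dynamics within a trial, and
any angular topology. Passing tests therefore demonstrate the internal
consistency of the model and its learning rule under idealised Gaussian
conditions, not performance on physiological data.

## Numerical choices

* All densities are computed in the log domain; `lambda_e` spans two orders
  of magnitude across configurations and naive products underflow. The grid
  oracle max-shifts before exponentiating and uses ±10 posterior SDs with
  4001 points.
* The stochastic integrator is Euler–Maruyama at fixed `dt`. A classical
  SDE scheme is used deliberately — its stationary mean/variance are exactly
  the quantities the posterior contract asserts; a higher-order
  deterministic solver would not improve those statistics. Constant-input
  segments are evaluated with a linear recursive filter, which makes a
  100 s trace at dt = 0.2 ms essentially free.
* The full two-compartment system is stiff when `C_d` is small, so
  noise-free runs use `lsoda`; with noise the fixed-step scheme requires
  `dt` to resolve `C_d / (g_d + g_ds)` and errors out otherwise.
* Rate schedules are piecewise-constant on the `dt` grid; all protocols are
  step stimuli.
* Weight updates clip at zero element-wise; batch updates average the
  per-trial gradients. A divergence guard aborts if any weight exceeds
  10³ times the largest initial weight.
* Decisions on the classification boundary tie towards the "≥" side.

## Design choices

* **Coupling factors.** Both coupling directions use the denominator
  `g_ds + g_d` (with the symmetric convention `g_sd = g_ds` the two
  published forms of the rule coincide); asymmetric coupling is accepted in
  the biophysics but the plasticity path assumes symmetry.
* **Activation reference.** Output rates are read out as
  ρ(u_s − u_ref) with the softplus ρ and `u_ref` at the resting potential
  (−70 mV), so the target rates 0.75 and 16 s⁻¹ map to target potentials of
  −69.9 and −54 mV. Referencing the activation at 0 mV would place *both*
  targets at or above the excitatory reversal potential — outside the
  reachable range of a conductance-based potential — and the variance term
  of the gradient then demonstrably inverts the learned mapping.
* **Tuning concentration.** The configured tables imply a detector tuning
  concentration of 6 deg⁻², i.e. a tuning SD of 0.4° against a detector
  spacing of 10.4°; with that value most cues fall between detectors and
  the bank is uninformative. The package default is
  `kappa_deg2 = 0.04` (tuning SD 5°, half the spacing), calibrated once by
  requiring the qualitative accuracy ordering of the discrimination task;
  the value remains a config scalar.
* **Instantaneous-soma training.** During learning the pooled state is
  computed in the C → 0 limit; stochasticity enters through the target
  samples and the input noise. The prior-adjusting afferent is one extra
  compartment with constant rate 1 s⁻¹ and plastic weights.
* **Batch sizes.** The rate-channel learning runs use per-trial updates;
  the discrimination task uses batches of 12.
* **Targets.** Discrimination targets are narrow Gaussians (SD 0.1 mV)
  around the role-dependent target potential; the rate-channel task samples
  targets from the target neuron's somatic posterior.
* **RNG.** Each experiment draws from named Mersenne-Twister streams
  (initialisation, cues, targets, membrane noise) derived from one master
  seed, so consuming more draws in one stream leaves the others unchanged.
* **Decision readout.** Test-time decisions use the MAP-mode instantaneous
  soma (noise-free readout); sampling-mode readout is available in
  `instantaneous_soma()`.

## Problem sizes

The test suite and the acceptance script run the discrimination experiment
at one tenth of the full protocol (40,000 training trials in batches of 12,
50,000 test trials) and the rate-channel learning at 11,000 trials; the
contrast sweep uses 41 log-spaced contrasts in [10⁻³, 10²] and the
stimulus-onset experiment 40 trials of 100 ms at dt = 0.2 ms. These sizes
keep a full run in minutes while preserving every ordinal result; the
ideal-observer gap of the trained network at this scale is a fraction of a
percentage point.

## Known limitations

* **Slow reliability separation.** At the configured learning rate the
  allocation of total synaptic weight across channels in proportion to
  their reliabilities is a shallow direction of the objective: the expected
  gradient along it is orders of magnitude smaller than along the
  mean-matching direction. Deterministic gradient flow at the configured
  step size moves the weight share only part-way towards the reliability
  ratio within the full trial budget, and the stochastic updates add a
  finite-step-size bias that inflates total conductance (reducing the
  learning rate tenfold removes most of that bias, at the cost of an even
  slower separation). The package reports the realised share, slope and
  variance-match numbers exactly as computed rather than the idealised
  fixed-point values.
* The plasticity path assumes symmetric, and in the experiments infinite,
  dendro-somatic coupling.
* Likelihoods and priors are Gaussian by construction; NMDA-type
  supra-linearities, spiking, and population readouts are out of scope.
* The psychometric fit is an unweighted-by-default least-squares probit;
  near-flat data are flagged rather than fitted.
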