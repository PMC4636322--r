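---
title: "Synaptic sampling: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synaptic sampling: models, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(synsampler)
```

## The model

Classical learning theory treats plasticity as convergence: network
parameters $\theta = (\theta_1,\dots,\theta_M)$ (synaptic efficacies,
connectivity) move to a point $\theta^*$ that maximizes the likelihood
$p_\mathcal{N}(\mathbf{x}\mid\theta)$ of the inputs $\mathbf{x}$. This
package implements the alternative this field has converged on calling
*synaptic sampling*: plasticity is a stochastic process whose **stationary
distribution** is the posterior over network configurations,

$$p^*(\theta \mid \mathbf{x}) \propto
  p_\mathcal{S}(\theta)\, p_\mathcal{N}(\mathbf{x}\mid\theta),$$

the product of a structural prior $p_\mathcal{S}$ (preferred weight
distributions, sparse connectivity) and the likelihood. Each parameter
follows the Langevin dynamics

$$d\theta_i = \Big( b(\theta_i)\,\partial_i \log p_\mathcal{S}(\theta)
  + b(\theta_i)\,\partial_i \log p_\mathcal{N}(\mathbf{x}\mid\theta)
  + T\, b'(\theta_i) \Big)\, dt + \sqrt{2\,T\,b(\theta_i)}\; d\mathcal{W}_i ,$$

where $b > 0$ is the learning rate (sampling speed), $T \ge 0$ a
temperature scaling the diffusion, and $d\mathcal{W}_i$ independent Wiener
increments. The zero-flux stationary solution of the corresponding
Fokker--Planck equation is $p^*(\theta)^{1/T}$ for *any* strictly positive,
twice-differentiable $b(\theta)$ — the $T b'(\theta)$ drift correction is
what makes the stationary law independent of the sampling speed. At $T = 1$
the network samples its posterior; as $T \to 0$ the dynamics degenerates to
MAP hill-climbing. The package verifies all of this numerically rather than
by proof: `fokker_planck_stationary()` integrates the stationary density
directly from drift and diffusion functions, `reference_posterior_density()`
computes the tempered posterior on a grid, and the test suite holds long
simulated chains against both.

For online learning, one input $x^n$ is visible at a time and the
likelihood score is multiplied by the dataset size $N$
(`discrete_step()`, one Euler--Maruyama step of the rule above;
`batch_step()` implements the exact sum over the dataset). The online rule
is an approximation valid for slow sampling speeds
($N \tau_x b \ll 1$); the package treats the discrete rule with
$\eta = b\,\Delta t$ as the ground-truth implementation because the
continuous rule is only ever realized that way.

## Tunable parameters

| parameter | meaning | default | units |
|---|---|---|---|
| `b` | learning rate / sampling speed | `1e-4` | s$^{-1}$ (scales all drift) |
| `temperature` | diffusion scale $T$ | 1 | — |
| `dt` | integration step | experiment-specific | s |
| `N` | online dataset-size multiplier | 100 | — |
| `clip_low` | lower parameter clamp | $-5$ | — |
| `max_step` / `max_jump` | clamp on instantaneous changes | $5b$ | — |
| prior $\mu,\sigma$ | Gaussian structural prior | $0.5, 1$ | — |
| `theta0` | weight-mapping offset | 3 | — |
| `alpha` | generative rate scale | $e^{-2}$ | — |

The clamps reproduce the reference implementation choices: parameters are
clipped at $-5$, and instantaneous changes at $5b$. In the spiking
simulator the $5b$ clamp applies to the event-driven likelihood jumps;
the continuous prior-plus-diffusion contribution is integrated per input
frame with the *exact* Ornstein--Uhlenbeck transition (the prior is
Gaussian, so the transition kernel is closed-form), which is both faster
and free of discretization error for any frame length. Clipping a whole
frame's diffusion increment at $5b$ would be a discretization artifact —
the continuous-time trajectory it approximates is never clamped — so the
clamp is not applied there.

## The three demonstration systems

**RBM with weight priors** (`rbm_*`, `train_generalization_experiment()`).
A restricted Boltzmann machine (binary units, symmetric weights) trained
with CD-5 contrastive-divergence gradients inserted into the sampling rule
($\eta = 10^{-4}$, $N = 100$, Gaussian noise $\sqrt{2\eta}\,\nu$ per
update; biases carry no prior). Test-set quality is measured by the *exact*
mean log-likelihood, enumerating all $2^H$ hidden states ($H = 9$ by
default). Under an uninformative prior the test log-likelihood collapses
with prolonged training (overfitting); under the bimodal mixture prior
$0.5\,\mathcal{N}(1, 0.15^2) + 0.5\,\mathcal{N}(0, 0.15^2)$ the weights
settle into the two modes and most of the decline is prevented. At the
reduced scale used here (196 visible units, synthetic stroke patterns)
both curves drift down slowly — the biases have no prior and diffuse — so
the "maintains its performance" verdict is implemented comparatively: the
bimodal decline must be under a quarter of the matched-seed uniform
decline. Across 5 seeds the uniform decline is roughly 100–125 nats and
the bimodal decline 16–30 nats.

**Spiking WTA circuit with structural plasticity** (`wta_network()`,
`simulate_network()`). Stochastic spike-response neurons,
$u_k = \sum_i w_{ki} x_i(t) + \beta_k$, divisive inhibition implemented
exactly as a softmax with total rate $\rho_{net} = 100$ Hz, EPSP kernel
$e^{-s/20\text{ms}} - e^{-s/2\text{ms}}$, and the stochastic STDP rule

$$d\theta_{ki} = b\Big(\tfrac{1}{\sigma^2}(\mu - \theta_{ki})
 + N\, w_{ki}\, S_k(t)\,\big(x_i(t) - \alpha e^{w_{ki}}\big)\Big) dt
 + \sqrt{2b}\, d\mathcal{W}_{ki},
 \qquad w_{ki} = e^{\theta_{ki} - \theta_0}.$$

The exponential mapping makes $\theta \le 0$ a *retracted* synapse: its
transmitting efficacy $\hat w = \max(0, w - e^{-\theta_0})$ is exactly
zero and its activity-dependent drift is suppressed by the factor $w$, so
retracted synapses evolve by prior and noise alone — and can regrow.
Structural statistics (formation events, survival curves, power-law and
two-term-exponential fits) live in `detect_events()`, `survival_curve()`
and `fit_survival()`, evaluated on a 30-minute presence grid. Survival is
*persistence*: a synapse that retracts at any grid point leaves the
surviving cohort for good, which makes survival curves monotone by
construction.

**Recurrent bimodal network with lesions** (`recurrent_wta_network()`,
`run_lesion_experiment()`). Two ensembles of WTA circuits receive
"auditory" and "visual" inputs respectively; all-to-all lateral synapses
(5 ms delay, no autapses) follow the same sampling rule. After training on
simultaneous class presentations, performance is probed with
auditory-only trials (visual afferents at 1 Hz, learning rate frozen) via
a nearest-class-centroid linear readout of time-averaged visual-ensemble
rates. Lesion 1 removes every visual-ensemble neuron whose probe response
prefers class 2; lesion 2 retracts all currently functional lateral
synapses and bans them from regrowing. Probe blocks begin with 16 unscored
settling trials so the homeostatic adaptation currents (time constants
12 s / 30 s) re-equilibrate to the probe condition before measurement.

## Interpretation choices where the reference description is underdetermined

Several constants are stated without their surrounding conventions; the
package fixes them by requiring the described *regime* to exist, and
records the alternatives:

- **Tuning curves.** Input neurons carry Gaussian tuning with
  $\sigma = 0.3$ over the unit cube. The radial-basis convention
  $\exp(-(d/\sigma)^2)$ is the default (`tuning_form = "radial"`). Under
  the normal-density convention $\exp(-d^2/2\sigma^2)$ (also available),
  more than three quarters of the 1000-input population responds above the
  STDP potentiation threshold ($\alpha e^{w}$ in trace units,
  $\approx 7.5$ Hz at small $w$) for *every* stimulus; functional
  connectivity then densifies from the prior's 69% towards saturation and
  the coexistence of persistent and transient synapse populations — the
  phenomenon under study — disappears.
- **Adaptation kernel.** The homeostatic current uses the
  double-exponential kernel normalized to unit integral, so
  $\gamma = -8$ means eight units of membrane potential per Hz of
  smoothed output rate. Unnormalized, a single output spike would deflect
  the membrane potential by $-2.6$ and one "won" stimulus presentation by
  roughly $-40$ — winner selection would then track each neuron's firing
  history instead of the stimulus, and no cluster selectivity forms.
- **Rate normalization** of the tuning-curve population is per pattern
  (population maximum $\mapsto$ 80 Hz); a per-neuron alternative is
  provided (`normalize = "per_neuron"`).
- **Lesion selection.** "Neurons encoding class 2" is operationalized as
  a higher mean probe-trial spike count for class 2 than class 1.
- **Readout.** A nearest-class-centroid discriminant — a linear readout
  neuron with weights $m_2 - m_1$ — retrained at every probe checkpoint.
  An unregularized least-squares readout overfits the small probe blocks.
- **Lateral delay** applies to transmission *and* to the presynaptic
  plasticity trace.

## Synthetic inputs, and what they do not show

No external data are consumed. `digit_pattern_generator()` produces
stroke-like binary images: each class is a family of near-centered strokes
with style variation (slant, curvature) and per-pixel flip noise, so pixel
statistics are bimodal at $\{0,1\}$ — the structure the bimodal weight
prior targets — and train/test prototype styles are disjoint.
`bimodal_pattern_generator()` produces paired stimuli: a temporally
structured rate trajectory over auditory channels (class-banded smooth
bumps, duration drawn from 320–520 ms per presentation) and a static
stroke image scaled to 0–50 Hz, with multiplicative amplitude jitter.
`cluster_world()` builds mixture-of-Gaussians sensory environments
(component means $\mathcal{N}(0.5, 0.2)$ per coordinate, covariances
$0.04 I + 0.01\xi$ symmetrized and floored to eigenvalue $10^{-4}$,
because the raw perturbed matrix is generically asymmetric or indefinite).

These generators reproduce the *statistical structure* the experiments
need — bimodal pixels, class structure across two modalities, cluster
worlds that can be enriched — but none of the covariances, correlations
or long-tailed variability of handwriting, speech, or natural sensory
streams. Passing tests therefore demonstrate the plasticity theory's
internal claims (stationary laws, regime orderings, compensation), not
performance on real data.

## Scales, time compression and numerical choices

Simulated durations follow the stated schedules (e.g. SE 3 h → EE 1 h →
5 h at 200 ms per presentation). A compression factor $c$ divides the
number of presentations and multiplies $b$ by $c$. Every dimensionless
quantity that governs formation and survival — $b\,t$, the diffusion
variance $2 b t$, the accumulated likelihood drift, the clip-to-jump
ratio, presentations per adaptation time constant — is invariant under
this rescaling; only the per-spike jump granularity grows, adding jump
noise that is negligible against the unit-scale prior at the factors used
($c = 10$ for the headline survival experiment, $c = 20$–$50$ for
in-suite ordering tests). The learning rate alone sets the model's
timescale, so this is a reparametrization, not an approximation of a
different model.

Other numerical commitments: time step 1 ms with Poisson spiking by
Bernoulli thinning (warning beyond $\rho\,dt > 0.2$); EPSP, lateral and
adaptation traces stored as exactly-decayed exponential pairs; softmax
rates computed with max-subtraction so $\sum_k \rho_k = \rho_{net}$ holds
to machine precision for arbitrary potentials; one R-level RNG stream
drives generators, simulator and noise in a fixed order, so every run is
bit-reproducible from its seed; chain validation uses 50 parallel scalar
chains (priors factorize), burn-in 1/6 of the run, thinning 100, retaining
$5\times10^4$ samples; power-law survival fits exclude lag 0 and are
initialized from a log–log regression; two-term exponential fits retry
from three start points and treat zero-variance curves as exact fits.

## Known limitations

- The online rule's bias relative to batch sampling grows with $N \tau_x b$;
  the package validates the regime it runs in, not the rule in general.
- Persistence-style survival depends on the presence grid; curves from
  different grids are not comparable (the learning-rate-scaling test
  scales its grid with the process for exactly this reason).
- The cross-modal association signal in the lesion experiment is weak at
  desk scale — winner rotation dilutes pairwise co-activity and caps the
  lateral weight equilibrium — so probe accuracies carry binomial noise
  and the compensation claims are evaluated on means over replicate
  sessions.
- Divisive inhibition is idealized (exact softmax); there are no
  conductance-based neurons, no learned inhibition, and no
  Metropolis-style correction of the discretized Langevin dynamics (the
  small-step regime is the contract).
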