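---
title: "Models and methods behind spectraldcm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spectraldcm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(spectraldcm)
```

# What the package computes

`spectraldcm` infers synaptic parameters of coupled neuronal populations
from the *cross-spectral density* (CSD) of oscillatory recordings — the
complex matrix of auto- and cross-spectra between channels as a function of
frequency. The pipeline has four layers:

1. **Forward models** mapping biophysical parameters to predicted CSDs
   (neural mass and neural field variants).
2. **Variational-Laplace inversion**: fitting a forward model to observed
   CSDs by maximising a free-energy bound on the log model evidence.
3. **Bayesian model reduction (BMR) and parametric empirical Bayes (PEB)**:
   closed-form scoring of reduced models and hierarchical group inference
   over subject-level posteriors.
4. **Laminar analyses**: current-source-density depth profiling and a
   layer-assignment model comparison for two-channel (superficial/deep)
   probe recordings.

Everything runs on synthetic data generated by the package itself, with
known ground truth; no empirical datasets ship with the package.

# The neural-mass forward model

`mass_model()` implements a four-population convolution-type mass model:
two pyramidal subpopulations plus excitatory and inhibitory interneuron
pools. Each population's mean depolarization $v_q$ (mV) obeys second-order
synaptic dynamics

$$\ddot v_q = \kappa_q f_q(v, U) - 2\kappa_q \dot v_q - \kappa_q^2 v_q,$$

where $\kappa_q$ (s$^{-1}$) is the postsynaptic rate constant and $f_q$
mixes presynaptic firing rates through ten signed connection gains
($a_{11}, a_{14}, a_{23}, a_{22}, a_{32}, a_{31}, a_{33}, a_{34}, a_{41},
a_{44}$):

$$
\begin{aligned}
f_1 &= a_{14}\sigma(v_4) - a_{11}\sigma(v_1) + U \\
f_2 &= a_{23}\sigma(v_3) - a_{22}\sigma(v_2) \\
f_3 &= -a_{32}\sigma(v_2) - a_{31}\sigma(v_1) - a_{33}\sigma(v_3) + a_{34}\sigma(v_4) \\
f_4 &= -a_{41}\sigma(v_1) - a_{44}\sigma(v_4)
\end{aligned}
$$

The firing-rate sigmoid is *centred*, $\sigma(v) = 1/(1+e^{-r(v-\eta)}) -
1/(1+e^{r\eta})$ with slope $r = 0.54$ mV$^{-1}$ and inflection $\eta = 0$,
so $\sigma(0) = 0$ and the origin is an exact fixed point at rest. This
choice makes linearisation exact at rest and is standard practice in
spectral model fitting; `fixed_point()` handles nonzero constant input by
Newton iteration.

**Why the second-order convolution form.** Writing the synaptic kernel as
$\kappa t e^{-\kappa t}$ gives precisely the damped second-order form
above; the package adopts it throughout and verifies it against
ODE-integration oracles in the test suite.

**Spectral predictions.** Linearising at rest gives the transfer function
$T(\omega) = C(i\omega I - J)^{-1}B$, where $B$ injects the exogenous input
$U$ (scaled by $\kappa$ and per-population input weights) and $C$ reads
channel-weighted depolarizations. The predicted CSD is

$$g_{lm}(\omega) = T_l(\omega)\, g_u(\omega)\, T_m(\omega)^\dagger + g_n(\omega),$$

with white-plus-pink input and channel-noise spectra $g_u(f) =
e^{\alpha_u} + e^{\beta_u}/f$ and $g_n(f) = e^{\alpha_n} + e^{\beta_n}/f$.
Two conventions deserve note:

* **The observation reads depolarization**, not its derivatives: LFP/MEG
  signals are conventionally treated as proxies of population potentials.
* **Channel noise enters every element of the CSD matrix**, not only the
  auto-spectra. This corresponds to a noise process shared across
  channels; the time-domain Welch oracle in the test suite simulates
  exactly that (one common noise trace added to all channels) and confirms
  the convention self-consistently. A per-channel independent noise model
  would instead contribute only to the diagonal; the shared form is the
  one the likelihood uses throughout.

**Default parameters.** Rate constants default to $\kappa = (500, 100,
100, 500)$ s$^{-1}$: a fast pair (2 ms, populations 1 and 4) and a slow
pair (10 ms, populations 2 and 3). Connection gains default to values
chosen once so that (i) the resting linearisation is stable, (ii) the
spectrum shows a gamma resonance near 50–60 Hz (fast pair) and a beta
resonance near 14 Hz (slow pair), and (iii) *every* gain has a measurable
spectral consequence — early drafts with weak self-inhibition on the fast
pair left $a_{11}$ and $a_{44}$ with essentially no influence on the
spectrum, which makes them unidentifiable for any inference scheme.
Observation weights are scaled so auto-spectra are order one, putting the
default channel-noise floor ($e^{\alpha_n} = 0.01$) about 20 dB below the
signal.

```{r mass-spectrum}
m <- laminar_model()
plot(predict_csd(m, seq(4, 100, 1)))
```

**Parameterisation for inference.** All positive parameters are stored as
prior-mean base values, and inference operates on dimensionless
*log-scalings*: $\kappa_q \mapsto \kappa_q e^{\theta_q}$ and so on.
Gaussian priors on $\theta$ then act multiplicatively and positivity is
automatic. Default prior variances are $1/4$ on kinetic and connection
scalings (one prior SD is about a $\pm 65\%$ change) and $1$ on the
spectral amplitudes, which are less constrained a priori.

# The neural-field variant

`field_model()` extends the circuit to a one-dimensional cortical patch
(default 10 mm). Lateral connectivity follows exponentially decaying
kernels $\alpha\, e^{-c|x|}$ with conduction delay $|x|/s$; the spatial
Fourier transform with delay has the closed form implemented in
`kernel_ft_field()`,

$$\tilde K(k, \omega) = \frac{2\alpha\,(c + i\omega/s)}{(c + i\omega/s)^2 + k^2},$$

validated against numerical quadrature of the defining integral. The patch
supports cosine modes $k_j = j\pi/L$ (32 by default, converged for the
default lead-field dispersion), and each mode's linearisation replaces the
point-source gains with kernel transforms normalised so that the $k = 0$,
$\omega = 0$ limit reproduces the point-source gain. The sensor sees the
patch through a Gaussian lead field $e^{-\varphi^2 k^2/2}$ and
per-population weights $q = (0.2, 0, 0.2, 0.6)$ — the inhibitory population
carries no dipole.

Defaults follow the field parameterisation used for visual-cortex gamma
work: $\kappa = (1/2, 1/35, 1/35, 1/2)$ ms$^{-1}$, kernel decays 2 mm$^{-1}$
(self) and 0.6 mm$^{-1}$ (lateral), conduction speed 0.3 m/s, lead
dispersion $\sqrt 2/16$ mm. Ten kernel amplitudes default to the values
(108, 45, 1.89, 162, 18, 45, 36, 18, 9) for
$\alpha_{11}, \alpha_{14}, \alpha_{12}, \alpha_{22}, \alpha_{21},
\alpha_{23}, \alpha_{33}, \alpha_{41}, \alpha_{32}$, with
$\alpha_{44} = 18$ adopted as a package default of the same magnitude as
the other inhibitory kernels. Two genuinely open choices are resolved as
configuration defaults and are easy to override:

* **Kernel signs.** The field connection set is not sign-annotated
  anywhere explicit, so the package fixes a default sign matrix: sources 1
  and 2 project inhibition, all self-connections are inhibitory (recurrent
  gain control), and the $1\leftarrow 4$ and $2\leftarrow 3$ kernels are
  the excitatory drives. This mirrors the mass-model topology where the
  two circuits overlap.
* **Population identities.** Which population index corresponds to which
  cell class is left to configuration; the machinery never depends on it.

# Variational Laplace

`vl_fit()` (wrapped by `dcm_fit()`) maximises the Laplace free energy

$$F = \ln p(y \mid \mu, \lambda) - \tfrac12 \varepsilon^\top \Pi_0
\varepsilon - \tfrac12 \ln\lvert\Sigma_0\rvert + \tfrac12
\ln\lvert\Sigma_q\rvert + (\text{the same for } \lambda),$$

over the posterior mean $\mu$ (Gauss–Newton steps with
Levenberg–Marquardt damping) and noise log-precisions $\lambda$ (damped
scalar Newton). The likelihood stacks the real parts of all
upper-triangular cross-spectra and the imaginary parts of the strictly
upper triangle (diagonal imaginary parts are identically zero) into one
residual vector with isotropic covariance $e^{-\lambda} I$ — a single
shared precision by default, optionally one per channel pair.

Numerical choices, all exposed through `dcm_settings()`:

* **Derivatives** by central finite differences with step $10^{-4}$ on the
  log-scaled parameters; the forward model is cheap and smooth, so this is
  both simple and accurate.
* **Damping** initialised at $1/8$, halved on acceptance, multiplied by 8
  on rejection; a step is accepted *only if it increases* $F$, which makes
  the recorded trajectory monotone non-decreasing by construction.
* **The $\lambda$ update maximises the same recorded objective** (the
  posterior-mean residual form above) rather than an expected-likelihood
  variant with curvature corrections. This keeps $F$ a single coherent
  function of $(\mu, \lambda)$ — so monotonicity is exact — and makes $F$
  equal to the exact log evidence on linear-Gaussian problems, which the
  suite asserts to $10^{-3}$ nats (and the posterior to $10^{-6}$).
* **Convergence** when $|\Delta F| < 0.01$ nats over 4 consecutive
  iterations, or after 64 iterations.
* The scheme contains no randomness: identical data and settings give
  bit-identical fits.

# Bayesian model reduction and PEB

`reduce_model()` implements the closed-form posterior and evidence change
under a replaced prior. With natural-parameter (precision) algebra, for
full prior $(\mu_0, \Pi_0)$, full posterior $(\mu_q, \Pi_q)$ and reduced
prior $(\mu_r, \Pi_r)$:

$$\Pi_p = \Pi_q + \Pi_r - \Pi_0, \qquad
\mu_p = \Pi_p^{-1}(\Pi_q\mu_q + \Pi_r\mu_r - \Pi_0\mu_0),$$

$$\Delta F = \tfrac12\left(\ln\frac{|\Pi_r|\,|\Pi_q|}{|\Pi_0|\,|\Pi_p|}\right)
+ \tfrac12\left(\mu_p^\top\Pi_p\mu_p - \mu_q^\top\Pi_q\mu_q
- \mu_r^\top\Pi_r\mu_r + \mu_0^\top\Pi_0\mu_0\right).$$

This is exact whenever the likelihood is Gaussian in the parameters, which
the suite verifies against direct conjugate refits on 50 random problems
(evidence to $10^{-6}$ nats, means to $10^{-8}$). An indefinite implied
precision $\Pi_p$ raises an "incompatible reduction" error. Parameters are
"switched off" with a prior variance of $10^{-8}$ rather than exactly zero,
keeping all precisions finite.

`peb_fit()` places a linear model over subjects' first-level parameters:
$\theta_i = (X_i \otimes W)\beta + \varepsilon_i$ with
$\varepsilon_i \sim N(0, \Sigma(\gamma))$, $W = I$ by default, covariates
mean-centred so the constant column is the group mean. Each subject's
contribution to the second-level free energy is a BMR evaluation that
swaps the subject's original prior for the empirical prior implied by
$(\beta, \gamma)$ — the data are never revisited. Because that contribution
is *exactly quadratic in $\beta$* for fixed $\gamma$, the $\beta$ step uses
closed-form gradients and curvature (a damped Newton step), while the
random-effect log-precision $\gamma$ (a single identity component by
default, hyperprior $N(0, 16)$) takes finite-difference Newton steps. Both
steps are accept-only-on-increase, so the second-level trajectory is also
monotone. The second-level parameter prior defaults to $N(0, 1)$ per
element.

`search_model_space()` scores on/off combinations of the group-effect
parameters by second-level BMR. Up to 16 free effects are enumerated
exhaustively ($\le 65{,}536$ closed-form evaluations); larger spaces are
first pruned by greedy backward elimination — repeatedly switching off the
parameter whose removal costs the least evidence — down to 16, then
enumerated. Literal enumeration of a 30-effect space ($2^{30}$ models) is
not tractable, so the greedy stage is an explicit approximation; with 10
group effects (the shipped analyses) the search is fully exhaustive.
Posterior model probabilities are softmax-normalised free energies;
`bayesian_model_average()` moment-matches the mixture of reduced
posteriors.

# Laminar analyses

`csd_profile()` is the standard estimator of current source density from
depth-resolved LFPs: the negative second spatial difference across
equally spaced contacts; sinks are negative. `first_active_sink()`
z-scores each contact against its pre-stimulus baseline and reports the
contact whose CSD first stays below $-2$ SD for at least 5 consecutive
samples — threshold and persistence are package defaults (the underlying
procedure is usually described only qualitatively) and are arguments.

`layer_assignment_comparison()` asks whether a two-channel recording is
labelled the right way up: it fits the two-channel laminar model with the
channels in the given order and again with the channels swapped, and
reports $\Delta F$, the log-evidence difference. Because the two fits are
deterministic, relabelling the input channels flips the sign of $\Delta F$
*exactly*. $|\Delta F| > 3$ is the conventional strong-evidence threshold.

# The synthetic-data generators

The generators define the package's study conditions:

* `simulate_subject()`: predicted CSD plus i.i.d. complex Gaussian noise
  on the stacked real/imaginary parts (Hermitian by construction). The
  default noise SD is 10% of the mean auto-spectral level — "moderate"
  noise. Default frequency grid: 4–100 Hz at 1 Hz, covering the gamma
  band with margin.
* `simulate_group()`: cohort of subjects whose log-scaling parameters
  follow $\theta_i = \beta^\top X_i + \varepsilon_i$ with random-effect SD
  0.1 (about 10% parameter variability) by default; unstable draws are
  resampled up to 10 times. Default cohort size in the shipped analyses is
  16 subjects — large enough for stable second-level estimates at desk
  scale.
* `simulate_laminar()`: the two-channel laminar model. The superficial
  channel reads the fast pair and peaks in the gamma band; the deep
  channel reads the slow pair (with a sign-flipped lead, as dipole
  orientation reverses across depth) and peaks in the beta/alpha range.
  One shared input drives both pairs, so the cross-spectrum is the
  shared-input term exactly. The fast-superficial/slow-deep motif is a
  fixture convention for generating spectrally distinct layers, not a
  biological claim.
* `simulate_depth_lfp()`: a Gaussian-in-depth, alpha-function-in-time
  sink signature superposed on temporally correlated (AR) noise. The AR
  coefficient (0.3) was chosen so that persistent baseline excursions past
  the default detection threshold are rare, as in trial-averaged evoked
  responses; with strongly autocorrelated noise, any
  threshold-plus-persistence rule triggers on noise alone.

All generators are deterministic given their seed.

# Benchmark designs and what they show

The end-to-end suites in `tests/testthat/test-acceptance.R` run at sizes
chosen for a single desk-scale CPU (the whole suite takes about a minute):

* **Parameter recovery** perturbs two randomly chosen connection gains by
  $\pm 0.5$ log units and fits the *two-channel* laminar configuration at
  2 Hz spectral resolution. The two-channel observation is used
  deliberately: a single auto-spectrum leaves several gains nearly
  unidentified (their credible intervals are honest but uninformative),
  which is a property of that observation model rather than of the
  inversion. Ten replicates check 90% credible-interval coverage
  ($\ge 8/10$) and truth correlation ($\ge 0.8$).
* **The laminar swap benchmark** runs ten seeds of the laminar generator
  at default (10%) noise and requires the correct assignment with
  $\Delta F > 3$ in at least 9.
* **PEB recovery** simulates 16 subjects with one covariate raising two of
  the ten connections by 0.4 log units per covariate SD, fits every
  subject, and requires the model search to give both true effects
  inclusion probability above 0.9 and the null effects a median below 0.5.

Passing these shows the machinery is internally consistent and correctly
calibrated *under the generators' assumptions*: linearised dynamics,
Gaussian observation noise of the modelled form, and cohorts that truly
follow the second-level linear model. Real recordings violate all three in
various ways (nonstationarity, non-Gaussian artefacts, model mismatch), so
these results bound what can be claimed about empirical data.

# Known limitations

* Spectral predictions are linearised around rest; strongly driven or
  near-unstable regimes where the sigmoid's curvature matters are out of
  scope, as is time-domain (evoked-response) fitting.
* The noise covariance is isotropic over the stacked residual within each
  component; frequency-correlated error models are not implemented.
* The field model's transfer recipe (normalised delayed-kernel transforms
  on a cosine-mode patch) is validated against its own quadrature and
  smoothness oracles, not against an external reference implementation.
* The greedy stage of large model-space searches is a heuristic; only the
  final $\le 16$-parameter stage is exhaustive.
* First-level fits are single-pass: empirical priors from the group level
  are not fed back to re-initialise subject inversions.
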