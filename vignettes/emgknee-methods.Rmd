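---
title: "Methods: an EMG-driven knee model, its identification, and sensitivity-based simplification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an EMG-driven knee model, its identification, and sensitivity-based simplification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgknee)
```

## The model

`emgknee` estimates active knee torque from four surface-EMG channels and
muscle geometry. Knee flexion torque is attributed to the long head of biceps
femoris (BF); extension torque to rectus femoris (RF), vastus lateralis (VL)
and vastus medialis (VM). Each muscle is a Hill-type muscle-tendon unit with
a fixed-length tendon:

* **Geometry.** With optimal fiber length $l_o$, optimal pennation $\varphi_o$
  and tendon length $l_t$, the fiber "height" $l_o \sin\varphi_o$ is
  conserved, so the fiber length is
  $l_m = \sqrt{(l_{mt}-l_t)^2 + (l_o\sin\varphi_o)^2}$ and the instantaneous
  pennation is $\varphi = \arcsin(l_o \sin\varphi_o / l_m)$. Fiber velocity
  follows by the chain rule,
  $v_m = \frac{l_{mt}-l_t}{l_m}\,\dot l_{mt}$, with $\dot l_{mt}$ estimated
  once per dataset by central differences and a zero-phase 6 Hz low-pass.
* **Activation.** Normalized EMG $u \in [0,1]$ maps to activation through
  $a = (e^{Au}-1)/(e^{A}-1)$, with $A \in [-3, 0.01]$ spanning strongly
  nonlinear to essentially linear. For $|A| < 10^{-6}$ the analytic identity
  limit is used.
* **Active force.** $F_{CE} = F_o\, f_L(\bar l)\, f_V(\bar v)\, a$ with
  $\bar l = l_m/l_o$ and $\bar v = v_m/(q_v l_o)$, $q_v \in [8,12]$ the
  velocity-scaling factor. $f_L$ is a two-sided bell: width $\Delta W$ and
  exponent $\nu$ differ between the ascending ($\bar l \le 1$) and descending
  limbs; $|\bar l - 1|$ is used inside the power so non-integer exponents are
  well defined. $f_V$ is the classic Hill hyperbola
  $0.3(\bar v + 1)/(0.3-\bar v)$ on the shortening side (clamped to 0 below
  $\bar v = -1$) and $(2.34\bar v + 0.039)/(1.3\bar v + 0.039)$ on the
  lengthening side, capped at its asymptote 1.8.
* **Passive force.** $f_{PE}$ is zero at and below $l_o$ and exponential in
  strain up to the maximum strain $\varepsilon_0$, where it equals 1 exactly;
  the shape constant $k_{PE}$ is 5 for young adults (6 for older) and is not
  identified.
* **Torque.** $\tau = \sum_{flexors} F^{mt} r - \sum_{extensors} F^{mt} r$,
  flexion positive. Moment arms enter as magnitudes; the sign is carried by
  the muscle's role. Both active and passive terms are projected by
  $\cos\varphi$.

The free parameters form a 26-vector: 6 shared function parameters
($A, \Delta W_{asc}, \nu_{asc}, \Delta W_{des}, \nu_{dec}, \varepsilon_0$)
plus 5 muscle-tendon parameters ($l_o, \varphi_o, F_o, q_v, l_t$) per muscle,
in the fixed order BF, RF, VL, VM (`param_names()`).

### Numerical choices in the model

* **Degenerate geometry.** Extreme chromosomes can make $l_{mt} \le l_t$.
  The along-tendon span is floored at 0 and the fiber length at
  $10^{-6} l_o$ (for parallel-fibered muscles), so the identification
  objective stays finite everywhere in the search box.
* **Linear continuation of the passive curve.** The exponential passive
  curve is only calibrated up to the maximum strain $\varepsilon_0$.
  Extrapolating it over the full identification box (optimal fiber length
  down to −50%, tendon length up to +20%) yields normalized fiber lengths
  near 4 and forces of order $e^{70}$, which destroy both the identification
  objective and the variance decomposition of the sensitivity analysis. The
  curve is therefore continued linearly (C1, tangent at
  $\bar l = 1+\varepsilon_0$). On $\bar l \le 1+\varepsilon_0$ — the entire
  physiologic operating range — the curve is evaluated exactly.
* **A → 0.** The activation map approaches the identity; the analytic limit
  is substituted below $|A| = 10^{-6}$.

The batch forward model (all chromosomes of a GA generation, or all rows of
a sensitivity design, in one call) is implemented in C++; a vectorized R
twin of the same arithmetic is kept and the two are compared in the test
suite (agreement to ~1e-14 relative).

## Signal conditioning

Raw sEMG (nominally 2000 Hz) is band-passed 20–450 Hz (2nd-order
Butterworth), full-wave rectified and low-passed at 6 Hz (4th-order
Butterworth) to form the linear envelope, then divided by the MVC envelope
peak and clipped to $[0,1]$. All filters are applied forward–backward (zero
phase): the analysis is offline, so acausal filtering is free and removes
group delay. The MVC normalization constant is the *envelope* maximum of the
MVC trial rather than the raw amplitude maximum, which is robust to
single-sample spikes. EMG and motion-capture-derived streams (nominally
200 Hz) are linearly interpolated onto a common uniform grid, by default
100 Hz — below both sensor rates and far above torque bandwidth.

## Identification

Identification minimizes the mean squared error between model and reference
torque over a bounded box: function parameters have fixed ranges
($A \in [-3, 0.01]$, $\Delta W \in [0.01, 1]$, $\nu \in [2,4]$,
$\varepsilon_0 \in [0.2, 0.6]$, $q_v \in [8,12]$); muscle-tendon parameters
are bounded relative to subject-scaled initial values (optimal fiber length
±50%; pennation, maximum force and tendon length ±20%). A generic-adult
initial set ships with the package (`default_initial_params()`) standing in
for subject-specific model scaling.

The optimizer is a real-coded genetic algorithm on floating-point
chromosomes: tournament selection (size 3), elitism (2), generation cap
1000 (default 500), early stop after 50 stalled generations. Full-model runs
use blend (BLX-α = 0.5) crossover and Gaussian mutation whose scale anneals
geometrically from 10% of each bound range down by `anneal_factor` over the
run — broad search early, fine exploitation late. Reduced-model runs switch
to simulated binary crossover (η = 15) and polynomial mutation (η = 20),
which preserve offspring diversity when few genes are free. Population size
defaults to 150. The generation budget can be split across independent
restarts (`restarts` in `ga_config()`), with the best chromosome overall
returned — a guard against a single unlucky basin in the multimodal
landscape. The GA is deterministic given its seed, bounds are enforced by
clipping after every variation step, and the subject's initial
(scaled-model) parameter values join the initial population as one
chromosome.

Fit quality is reported as RMSE (N m), NRMSE (RMSE as a percentage of the
*reference torque range* — the normalization is a package convention, stated
here because several alternatives exist) and $R^2$ about the reference mean.

### Identifiability

The torque objective constrains parameters only as well as the data excites
them. Two structural compensation channels matter: extensor maximum forces
trade off against each other when their activations are synchronous, and
$F_o$ trades off against the shared force-length curve when each fiber
operates over a narrow length range. The synthetic protocol (below) was
designed so that each muscle is active at multiple joint phases with
cycle-to-cycle amplitude variation; under those conditions the maximum
forces are recoverable to ~10% from noise-free data, while low-sensitivity
parameters (e.g. the velocity-scaling factors) are not — quantifying exactly
that structure is what the sensitivity analysis is for.

## Sensitivity analysis

With a fixed signal sequence and an identified optimum $\lambda_0$, the
scalar output studied is the disturbance functional
$Y(\lambda) = \frac{1}{N}\sum_n (\tau_n(\lambda) - \tau_n(\lambda_0))^2$ —
the output damage done by replacing the optimal parameters. Parameters are
sampled uniformly over the identification box from a scrambled Sobol'
sequence: two $P \times d$ matrices $A$ and $B$ (one $2d$-dimensional stream
split in half), plus pick matrices $AB^{(i)}$ ($A$ with column $i$ from $B$)
and, for screened pairs, $BA^{(ij)}$.

Estimators (all normalized by $\mathrm{Var}(Y)$ and $f_0$ estimated from
$f(A)$ with the plain $1/P$ moment formulas):

* first order: $S_i = \frac{1}{P}\sum_p f(B)_p\,(f(AB^{(i)})_p - f(A)_p) / \mathrm{Var}(Y)$
* total effect: $S_{Ti} = \frac{1}{P}\sum_p f(A)_p\,(f(A)_p - f(AB^{(i)})_p) / \mathrm{Var}(Y)$
* second order: $S_{ij} = \left[\frac{1}{P}\sum_p f(A)_p f(BA^{(ij)})_p - f_0^2\right]/\mathrm{Var}(Y) - S_i - S_j$

The per-parameter interaction index is $IN_i = S_{Ti} - S_i$ and the global
interaction index $IN = 1 - \sum_i S_i$; both are bookkeeping identities of
the estimates and are asserted exactly in the tests. Second-order indices
cost one extra model batch per pair, so they are computed only when
interactions are material: $IN$ above a gate (default 0.1) and then only for
pairs of parameters with $IN_i$ above a threshold (default 0.05).

The estimators are validated against analytic decompositions of the
Ishigami function ($a=7$, $b=0.1$: $S_1 = 0.3139$, $S_2 = 0.4424$,
$S_3 = 0$, $S_{T3} = 0.2437$), the product function $x_1 x_2$
($S_{12} = 1/7$) and additive functions ($IN \to 0$).

The Sobol' sequence itself is built in-package (no quasi-random generator is
available among the supported dependencies): a base-2 digital sequence with
31-bit resolution whose direction numbers come from primitive polynomials
over GF(2), found by deterministic exhaustive search in (degree, value)
order, with initial direction integers fixed by an internal deterministic
stream — so the unscrambled sequence is a reproducible package constant.
Randomization is a seeded per-dimension digital shift (XOR), which preserves
the dyadic stratification (asserted in the tests) while allowing independent
replicates. Latin-hypercube and plain uniform sampling are available as
alternatives for testing.

One property of this model class deserves a note: over the *full* Table-style
identification box, the variance of $Y$ is dominated by passive-stretch
geometry ($\varepsilon_0$, optimal fiber lengths, tendon lengths), because
tendon-length and fiber-length extremes put fibers far onto the passive
curve. Rankings are therefore geometry-heavy, and first-order indices are
small relative to totals (interactions: a long tendon only matters when the
fiber is also short). This is a genuine property of the disturbance
functional on this box, not an estimator artifact — the same estimators
reproduce the analytic oracles above.

## Sensitivity-based simplification

1. Average $S_i$ and $S_{Ti}$ over subjects; rank parameters by mean total
   effect (the primary criterion; ranking by mean first-order is available).
2. Parameters in any screened pair with a large second-order index are
   **mandatory**: they must be identified in every reduced model.
3. The simplest model identifies only the mandatory set; all other
   parameters are frozen at their cross-subject mean identified values.
4. Grow the identified set in ranking order: for each size $q$, re-identify
   (SBX + polynomial mutation) and record RMSE and the precision ratio
   $R = \mathrm{RMSE}_{full}/\mathrm{RMSE}_{reduced}$ — the fraction of the
   full model's accuracy the reduced model attains.
5. The $R$-vs-$q$ curve is reported; choosing "the" final $q$ is left to the
   application's accuracy/cost trade-off.

Free sets are nested in $q$ by construction, and every $q$ gets the same GA
budget so ratios compare like with like. $R$ is *not* forced to be monotone:
with a capped optimization budget, higher-dimensional searches can end
worse than lower-dimensional ones, and the sweep reports what happened. The
step-1 threshold (default 0.05 on mean $S_1$) only labels parameters
"high-sensitivity" for reporting; the mandatory set is defined by the
interaction screen, which is what sets the minimum usable $q$.

## The synthetic-subject generator

No public recordings match this four-muscle protocol, so the package ships a
generator that emulates the study conditions end to end from a known
ground-truth parameter vector:

* **Movement.** A smooth periodic knee angle (default
  $0.9 + 0.5\sin(2\pi t/4)$ rad, within the physiologic 0–2.3 rad range),
  emulating suspended-shank flexion/extension cycles.
* **Geometry.** Muscle-tendon length quadratic in knee angle, with moment
  arm $r = |dl_{mt}/d\theta|$ by the tendon-excursion principle, evaluated
  analytically; flexor and extensor slopes have opposite signs. Default
  slopes give human-scale knee moment arms (0.02–0.05 m). The constant term
  is anchored per subject so each fiber sits at its optimal length at the
  mid-range knee angle — the way a scaled musculoskeletal model couples
  geometry to muscle parameters; without this coupling, randomly drawn
  tendon and fiber lengths put some subjects' fibers far onto the passive
  curve, which is neither realistic nor comparable across subjects. The
  default protocol produces reference torques swinging both ways
  (about −40 to +15 N m), as balanced flexion/extension cycling should.
* **Excitation.** Per-muscle raised-cosine burst trains — two bursts per
  cycle at different joint phases, staggered across muscles, with a
  deterministic cycle-to-cycle amplitude modulation. Repeated voluntary
  contractions never repeat exactly; beyond realism, this variation provides
  the persistent excitation that makes maximum forces identifiable (a
  single identical burst per cycle leaves a flat compensation valley among
  the extensor forces — measurably so in this package's development).
* **EMG.** The target activation is inverted through the activation
  nonlinearity (using the subject's true $A$) to the normalized EMG $u(t)$,
  and the raw trace is band-limited Gaussian noise amplitude-modulated by
  $u(t)$, self-calibrated so a unit modulator yields a unit envelope; MVC
  trials are generated the same way at full drive. The envelope chain
  recovers $u$ with correlation ≥ 0.9, not exactly — so identification
  experiments distinguish the "clean" dataset (exact $u$, the noise-free
  condition) from the "pipeline" dataset (full signal chain).
* **Reference torque.** Computed by the package's own forward model from the
  true parameters (so the noise-free round trip is exact by construction),
  with optional multiplicative noise (default 5% where noise is wanted)
  standing in for inverse-dynamics error, which scales with load; an
  additive term is available.
* **Ground truth.** Drawn uniformly from the central 50% of each bound
  interval (margin 0.25 per side), so recovery is never clipped by the box.

What the generator does **not** emulate: biofidelic EMG spectra (no
motor-unit model), electrode crosstalk, geometry model error (the same
quadratic family generates and fits the data), soft-tissue artefact, or
non-cyclic movements. Passing recovery tests on synthetic subjects therefore
demonstrates the correctness and conditioning of the estimation machinery,
not field performance on real recordings.

## Problem sizes used by the test suite

The test and acceptance runs use sizes chosen to exercise every claim at
desk scale: synthetic trials of 6–12 s at 100 Hz, GA populations of 150
(capped 500 generations) for recovery experiments and 40–100 for structural
tests; Sobol' designs of $P = 2^{13}$–$2^{14}$ for the analytic oracles and
$P = 2^9$–$2^{10}$ for model-based designs; q sweeps over
$q \in \{4, 10, 16, 26\}$. The methods scale linearly in $P$, population and
trial length for larger studies.

## Known limitations

* Tendon compliance is ignored (fixed tendon length); activation dynamics
  (the first-order excitation-to-activation ODE) are not modelled — the
  activation map is memoryless.
* NRMSE normalization conventions differ across the literature; this package
  uses the reference range throughout.
* The GA's selection scheme, rates and population size are package defaults,
  not literature-fixed quantities; all are exposed in `ga_config()`.
* Sensitivity results are conditional on the movement data and the
  identification box; rankings from one protocol do not transfer
  automatically to another.
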