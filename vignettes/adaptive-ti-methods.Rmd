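---
title: "Adaptive serial-tempering thermodynamic integration: models, methods, and design choices"
author: "alchemTI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive serial-tempering thermodynamic integration: models, methods, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alchemTI)
```

## The problem

Alchemical free energy calculations estimate $\Delta G = G(1) - G(0)$ for a
Hamiltonian $U(r, \lambda)$ that interpolates between two end states as the
coupling parameter $\lambda$ runs from 0 to 1. Thermodynamic integration (TI)
writes this as

$$\Delta G = \int_0^1 \left\langle \frac{\partial U}{\partial \lambda}
\right\rangle_\lambda \, d\lambda ,$$

a quadrature over canonical ensemble averages of the generalized force
$\partial U/\partial\lambda$ at fixed $\lambda$. Two practical failure modes
dominate: (i) the sampling budget is spread poorly over $\lambda$, so
high-variance windows dominate the error; and (ii) slow conformational
degrees of freedom trap individual simulations in metastable states, so the
window averages are silently wrong even when their nominal error bars are
small.

This package implements, on analytic model systems, an adaptive
expanded-ensemble TI stack addressing both: serial tempering along
$\lambda$ (ST), variance-adaptive resampling (VAR), replica exchange (RE),
and a two-state torsion-scaling enhanced-sampling scheme that removes
torsional barriers in a "dummy" state (ACES-style $\gamma$-scaling). Every
component is exercised against a closed-form oracle, which is the reason the
model systems are toys: each claim the framework makes is separately
testable without molecular dynamics.

## Model systems and units

Everything is in reduced units: energies in $kT$ (inverse temperature
$\beta$ configurable, default 1), coordinates dimensionless. Three systems
ship with the package:

* **Harmonic** (`harmonic_model(k0, k1)`): $U = \tfrac12 k(\lambda) x^2$,
  $k(\lambda) = (1-\lambda)k_0 + \lambda k_1$. Free energy profile
  $G(\lambda) = \ln(k(\lambda)/k_0)/(2\beta)$, so
  $\Delta G = \ln(k_1/k_0)/(2\beta)$. With the default $k_0=1, k_1=4$,
  $\Delta G = \ln 2$. The conditional mean and variance of
  $\partial U/\partial\lambda$ are Gaussian moments in closed form.
* **Charging** (`charging_model(c, k0, k1)`):
  $U = \tfrac12 k(\lambda) x^2 + \lambda c x$, solvable by completing the
  square: $G(\lambda) = \ln k(\lambda)/(2\beta) - \lambda^2 c^2 /
  (2 k(\lambda))$. With $k_0 \ne k_1$ the variance of
  $\partial U/\partial\lambda$ changes by more than an order of magnitude
  along $\lambda$ (a factor of about 25 at the defaults $c=2, k_0=1,
  k_1=4$), which is what variance-adaptive resampling needs to demonstrate
  an effect. We note that the pure linear-charging variant ($k_0 = k_1$)
  has *constant* derivative variance ($\partial U/\partial\lambda = cx$ with
  $\lambda$-independent Gaussian $x$) and is therefore useless for that
  purpose; the $\lambda$-dependent spring constant is what makes the
  variance profile heterogeneous.
* **Torsion chain** (`torsion_model()`): $d$ periodic angles with cosine
  barriers $v_j (1 + \cos(n_j\theta_j - \delta_j))$, each multiplied by
  $\gamma$ when selected for scaling, plus a $\lambda$-coupled harmonic well
  on the collective coordinate $s = \mathrm{mean}(\sin\theta_j)$. A two-fold
  barrier ($n_j = 2$) gives a symmetric double well at $\theta = \pm\pi/2$
  with barrier height $2v_j$ — the standard kinetic trap. Scaling one angle
  mirrors single-torsion enhanced sampling (sACES); scaling several mirrors
  the multi-torsion variant (mACES).

These are deliberate surrogates for molecular systems, not approximations
of any particular force field: soft-core potentials, solvent, and real
torsion landscapes are out of scope. What the toys preserve is the
*structure* of the problem — a $\lambda$-dependent ensemble with
heterogeneous derivative variance and tunable kinetic traps.

## Sampling

The default sampler is Metropolis random-walk Monte Carlo (uniform
proposals of half-width `step_size`, acceptance
$\min(1, e^{-\beta\Delta U})$), chosen because its invariant distribution is
*exactly* the Boltzmann distribution: downstream statistical tests then
carry no integrator bias. A BAOAB-discretised Langevin integrator is
provided for realism; it has the usual $O(\Delta t^2)$ configurational bias
and is checked against the Metropolis moments, but it is not the validation
path. Each walker carries a private RNG stream derived from the master
seed, so replicas are independent and every run is reproducible
bit-for-bit.

Samples (step, window, $\gamma$-state, $\partial U/\partial\lambda$, $U$,
coordinate) are recorded every `record_interval` steps (default 1; dense
recording is cheap here and thinning is an analysis-time decision).

## Serial tempering along lambda

The $\lambda$ axis is discretised into `n_windows` equally spaced windows
(default 101, spacing $\Delta\lambda = 0.01$). A run starts with a
sequential scan visiting every window once (by default 2% of the total
budget), seeding per-window means of $\partial U/\partial\lambda$. The bias
profile is the negative integral of those means, accumulated by the
two-panel Simpson recursion

$$F_i = F_{i-2} - \frac{\Delta\lambda}{3}\,(y_{i-2} + 4 y_{i-1} + y_i),$$

with $F_1 = 0$ (gauge) and $F_2$ from a one-panel trapezoid — the
lowest-order consistent closure, whose $O(\Delta\lambda^3)$ one-panel error
is negligible at $\Delta\lambda = 0.01$. On the harmonic system's analytic
means the accumulated profile matches the closed form to about $10^{-8}$.

After the scan, the walker alternates `jump_interval` propagation steps
(default 100) with a heat-bath $\lambda$ jump: candidate window $j$ gets
log-weight $-\beta[U(r,\lambda_j) - U(r,\lambda_i) + F_j - F_i]$, and the
next window is drawn from the normalised weights over all $j \ne i$
(log-sum-exp with max subtraction; weights below $10^{-300}$ are treated as
zero; if every candidate is $-\infty$ the jump is declined). Because the
current window is excluded from the normalisation, the move is "forced";
this sampler does not by itself satisfy detailed balance exactly with
respect to the biased expanded ensemble. We keep it as the default because
the flat-histogram test shows the residual bias is far below detection at
$10^5$ jumps over 101 windows, and we provide
`heat_bath_jump(rule = "metropolized")`, which adds the Metropolized-Gibbs
acceptance factor $\min\{1, (1-p_i)/(1-p_j)\}$ and restores exact
invariance, for users who want the strict version. During the run the bias
is rebuilt from the running per-window means at the adaptation interval
(default every $10^4$ steps, scan data included at equal weight) — the bias
derives from the accumulated thermodynamics, with no visitation-penalty
(Wang–Landau style) term, so it converges to the negative free energy
profile rather than to whatever flattens a finite histogram.

## Variance-adaptive resampling

Per-window running moments of $\partial U/\partial\lambda$ use Welford
updates (chunk merges in the parallel form); the variance is the population
form $\langle x^2\rangle - \langle x\rangle^2$, which is what the target
definition uses — the $n$ vs $n-1$ distinction is irrelevant at the sample
sizes involved. Target probabilities are variance-proportional with a
floor: $P_i \propto \mathrm{Var}_i$, then
$P_i \leftarrow \max(0.1\,P_{\max}, P_i)$, then renormalise. Windows with
fewer than `min_samples` (default 10) observations have untrusted variances
and inherit the mean variance of the trusted windows; an all-zero variance
profile falls back to uniform. Jump probabilities are modified as
$P'(i\to j) \propto P(i\to j)\, P_t(j) / P_t(i)$ and renormalised over the
candidates (without renormalisation the modified numbers are not
probabilities).

For error propagation the package provides
$\sigma^2_{\Delta G} = \sum_i (\Delta\lambda_i^p / N_i)\, \sigma_i^2$ with
$p = 1$ by default, and a `delta_power = 2` switch. The first-power form is
the conventional per-window error budget used for allocation decisions; the
squared form is the actual variance of a quadrature sum with weights
$\propto \Delta\lambda$. The distinction matters in two places:

* **Allocation.** `neyman_allocation()` defaults to the true minimiser of
  the propagated variance at fixed total, $N_i \propto
  \sqrt{\Delta\lambda_i^p}\,\sigma_i$, which by Cauchy–Schwarz strictly
  beats uniform allocation whenever the variances are heterogeneous (under
  either $p$). The variance-proportional rule
  ($N_i \propto \Delta\lambda_i^p\,\sigma_i^2$, `rule = "variance"`) is also
  provided: it equalises the per-window contribution
  $\Delta\lambda_i\sigma_i^2/N_i$, which is an appealing "uniform marginal
  contribution" property, but for constant spacing its propagated total is
  algebraically *identical* to uniform allocation
  ($\sigma_i^2/N_i = \sum_j\sigma_j^2/N$ for every $i$). Equalising
  contributions and minimising the total are different objectives; the
  function exposes both and the documentation says which is which. The
  sampling-time *target probabilities* remain variance-proportional — that
  choice governs where a serial walker spends time, and its benefit
  (concentrating effort where the integrand is noisy) does not depend on
  the allocation identity above.
* **Per-run standard errors.** The sampling-quality diagnostic (below)
  needs a propagated SE on the same scale as the observed spread of
  independent $\Delta G$ estimates, so it combines per-window SEs with
  squared quadrature weights, $\mathrm{SE}^2_{\mathrm{run}} = \sum_i w_i^2
  \sigma_i^2 / N_{\mathrm{eff},i}$; the first-power form would inflate it
  by roughly $1/\sqrt{\Delta\lambda}$ and make the ratio meaningless.

Integer allocations use largest-remainder (Hamilton) rounding, sum exactly
to the requested total, and guarantee at least one sample per window.

## Replica exchange and torsion-scaling exchange

`n_replicas` walkers (default 8) run logically in parallel — execution is
serial, parallelism is a contract — and attempt exchanges every
`exchange_interval` steps (default 100) between fixed adjacent pairs
(1–2, 3–4, 5–6, 7–8). The acceptance criterion uses only true potential
energies, $\Delta U = U(r_n,\lambda_m) + U(r_m,\lambda_n) -
U(r_m,\lambda_m) - U(r_n,\lambda_n)$, accepted with
$\min(1, e^{-\beta\Delta U})$; bias terms never enter, so exchanges sample
the true thermodynamic ensemble. On acceptance the complete physical
payload — coordinates, velocities, $\lambda$ index, and $\gamma$ label —
swaps between the two replica slots; each slot's RNG stream stays put. For
the fixed-window reference ladder the alternating even/odd pairing is used;
since samples are keyed by window index, whole-state swaps are equivalent
to the conventional coordinate-swap formulation there.

The torsion-scaling component runs each replica as a two-state Hamiltonian
exchange between the physical state ($\gamma = 1$) and a dummy state
($\gamma = 0$) in which the scaled torsional barriers vanish. Flips are
proposed at the exchange interval at fixed coordinates and $\lambda$, and
accepted by the Metropolis criterion on the total Hamiltonian difference.
A physical-to-dummy flip never raises the energy and is always accepted;
the reverse pays the current torsional energy, which concentrates returns
near torsional minima — exactly the mechanism that carries barrier-free
conformational diversity back into the physical ensemble. Dummy-state
samples are flagged and excluded from every estimator: TI integrates along
the physical coordinate only. The direct mapping $\gamma(\lambda) =
\lambda$ is available as a config mode (`aces_mapping = "direct"`), in
which no exchange occurs, torsion scaling rides $\lambda$, and
$\partial U/\partial\lambda$ includes the scaled term's derivative. When
$\gamma$-flips and replica exchanges coincide, flips run first, then
swaps; both are logged.

## Estimation and diagnostics

TI uses composite Simpson quadrature over the per-window means (odd window
counts; an even count falls back to a trapezoid on the last panel with a
message), after discarding the first 10% of each walker's stream
(`burn_in`, configurable in $[0, 0.5]$).

The diagnostic stack per window: autocorrelation
$\rho_k = \mathrm{Cov}(X_t, X_{t+k})/\mathrm{Var}(X_t)$ with the biased
(divisor $N$) covariance about the overall series mean; statistical
inefficiency $g = 1 + 2\sum_k \rho_k$ truncated at the first lag where the
estimated autocorrelation is non-positive (the "decayed to zero"
prescription; a windowed-sum truncation would be less noisy for very long
correlation times but is not the default), floored at $g \ge 1$; effective
sample size $N_{\mathrm{eff}} = N/g$; efficiency $\eta = 1/g$; and
$\mathrm{SE} = s/\sqrt{N_{\mathrm{eff}}}$. For serially tempered runs a
window's series is the concatenation of its visits, which slightly distorts
the autocorrelation at visit boundaries; the effect is small at the default
jump interval and is accepted.

The sampling-quality ratio compares external reproducibility with internal
precision: $\sigma_{\bar A}$, the $(n-1)$-denominator standard deviation of
per-replicate $\Delta G$ estimates, divided by $\langle \mathrm{SE}\rangle$,
the mean per-replicate propagated SE. Near 1 indicates the replicas agree
as well as their internal error bars promise; the flag thresholds are
"ok" up to 2, "warning" in (2, 5], "severe" above 5. For adaptive runs the
replicates are the walkers (a walker's unvisited windows fall back to the
pooled mean, a conservative choice that shrinks the spread slightly); for
the fixed-window reference, where each walker pins one window, replicates
are contiguous time blocks of every window's stream (8 by default) — block
length far exceeds the correlation time at the problem sizes used, so
blocks are effectively independent.

## Orchestration

`run_samti()` executes: grid initialisation, prescan, initial bias and
variance estimates, replica launch at evenly spread starting windows
(replica $r$ at window $\mathrm{round}((r-1)(n-1)/(n_{\mathrm{rep}}-1))+1$ —
the even spread is our reading of "replica-specific $\lambda$
distribution", which is otherwise unspecified), then the main loop of
propagation chunks, jumps, statistics updates, adaptation-interval
refreshes, and exchange attempts, ending in TI along the physical
coordinate. Statistics (bias and variance estimates) are shared across
replicas through one global tracker; sharing convergence statistics across
replicas is explicitly permitted by the framework and converges faster than
per-replica adaptation at these problem sizes. The step budget is honoured
exactly: prescan plus main-loop steps over all replicas equals
`total_steps`, with integer remainders assigned to the first replicas.
`run_reference_ti()` is the conventional baseline: one walker per window
(21 by default), equal per-window budgets, no bias, optional neighbour
exchange along the ladder.

A worked example:

```{r example, eval = FALSE}
cfg <- run_config(model = harmonic_model(k0 = 1, k1 = 4),
                  total_steps = 1e6, var = TRUE, re = TRUE, seed = 1)
rep <- run_samti(cfg)
rep$dg            # pooled TI estimate; exact answer is log(2) = 0.6931
rep$sigma_abar    # spread of the 8 per-walker estimates
rep$quality$flag  # "ok" unless replicas disagree beyond their error bars
```

## What the synthetic generators do and do not show

`generate_fixture()` produces $\partial U/\partial\lambda$-like series with
known ground truth: white noise ($g = 1$), AR(1) with
$g = (1+\phi)/(1-\phi)$, and a trapped-replicate ensemble (half the
replicates pinned in each well) whose quality ratio is far above the severe
threshold. These, plus the analytic models, validate the estimators and
the adaptive machinery — they do not validate force fields, soft-core
functional forms, finite-timestep integrators, or the torsion-selection
problem for real ligands, all of which are outside this package's scope. A
passing suite shows the *algorithms* are correct, not that any particular
molecular application will converge.

## Numerical choices and degenerate inputs

* Log-sum-exp with max subtraction everywhere probabilities are formed;
  non-finite energies give $-\infty$ log-weights with a logged warning, and
  a jump with no finite candidate is declined.
* Angles wrap to $(-\pi, \pi]$; linear coordinates are unbounded.
* Constant (zero-variance) series are an error for autocorrelation-based
  estimators; windows with fewer than 10 samples or zero variance return
  `NA` diagnostics rather than fabricated numbers.
* All-zero variance profiles give uniform targets and allocations.
* A propagation step that produces a non-finite energy aborts with the
  offending step index.
* Population (biased) variance and covariance estimators throughout the
  running moments and autocorrelation; sample ($n-1$) standard deviations
  for replicate spreads and per-window SEs, matching each definition's
  printed form.

## Problem sizes used by the tests

The validation suite runs each method configuration on the harmonic system
with 8 replicas and $10^6$ total steps (pooled $\Delta G$ within
$3\sigma_{\bar A}$ of $\ln 2$); the flat-histogram check uses $10^5$ jumps
over 101 windows against the exact bias; the variance-target check uses
$10^7$ steps on the heterogeneous charging system (total-variation distance
to the floored analytic target below 0.05); the barrier-escape check uses a
$4\times10^5$-step budget at step size 0.1 on the 10 kT double well,
calibrated once by a pilot scan of crossing rates and then frozen. These
sizes were chosen so the full suite completes in a few minutes on one CPU
while leaving each statistical assertion a comfortable margin.

## Known limitations

* The shipped models are 1-D to 3-D toys; nothing here demonstrates
  performance on rugged high-dimensional landscapes.
* The forced-move heat-bath jump is kept as printed; its detailed-balance
  correction is available but not default (see above).
* Per-window series concatenation across visits mildly biases $g$ for
  tempered runs.
* The two-state $\gamma$-exchange spends most of its time in the dummy
  state when barriers are high (the physical fraction is
  $Z_{\mathrm{phys}}/(Z_{\mathrm{phys}} + Z_{\mathrm{dummy}})$); no
  free-energy offset between the states is applied, matching the plain
  Hamiltonian-difference criterion.
* BAR/MBAR-style estimators are not implemented; TI is the single
  estimation path.
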