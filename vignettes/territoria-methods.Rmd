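---
title: "Models and methods behind territoria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind territoria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(territoria)
```

`territoria` implements a statistical-mechanics view of animal space use:
home ranges are the stationary states of random walkers tethered to a
central place, and territories are the dynamically maintained exclusion
zones of scent-marking walkers. This vignette states the models, the
conventions and numerical choices the package commits to, and what its
synthetic-data validation does and does not demonstrate.

## 1. Home ranges as Boltzmann steady states

A central-place forager is modelled as overdamped diffusion with
diffusivity $D$ in a confining potential $U$ centred on its burrow
$x_c$. Only the dimensionless ratio $u(x) = U(x)/D$ enters the steady
state, which is Boltzmann:
$$p(x) \propto e^{-u(x - x_c)},$$
independent of the initial condition. `potential()` stores $u$ directly;
$D$ appears separately only in the dynamical generators and the
likelihood. The intrinsic home-range length is defined through the second
moment of the Boltzmann weight,
$$L = \sqrt{\frac{2\int_0^\infty x^2 e^{-u(x)}\,dx}
                 {\int_0^\infty e^{-u(x)}\,dx}},$$
i.e. $L^2$ is twice the stationary variance (`home_range_length()`), with
an equivalent reciprocal-space form via the curvature of the Fourier
transform of $e^{-u}$ at the origin (`home_range_length_kspace()`); the
two routes agree to $10^{-6}$ for every built-in family with a finite
second moment, and the package tests assert this.

Built-in families, with `L` in user length units:

* `harmonic` — $u = x^2/L^2$, Gaussian steady state with variance
  $L^2/2$; the length functional returns exactly `L`.
* `logarithmic` — $u = \ln(1 + x^2/L^2)$, a Lorentzian (Cauchy) steady
  state. Its *second moment diverges*, so `home_range_length()` raises
  the divergent-tail error for it; the windowed saturation MSD below is
  nevertheless finite and has an exact closed form. This is the family
  whose closed form the package ships as `msd_ss_logarithmic()`; a
  cubed-logarithm variant with finite moments is available as
  `log_cubed` and is handled by the quadrature pipeline.
* `box_erf` — a width-$L$ box convolved with a Gaussian
  (steady state $\propto \mathrm{erf}[a(x/L + 1/2)] -
  \mathrm{erf}[a(x/L - 1/2)]$, $a = \sqrt{6\pi/11}$): a smooth,
  flat-topped home range.
* `hard_box` — free diffusion between hard walls at $\pm L/2$;
  the length functional gives $L/\sqrt 6$.
* `multi_harmonic` — a reconstruction of a two-regime attraction: a
  piecewise quadratic, $C^1$-matched at a crossover radius `r0`, with
  inner and outer curvatures `s_in`, `s_out` (defaults 1, 5, `r0 = L`).
  Defaults put the stiffer restoring force far from the den, the
  qualitative picture of an animal that wanders freely near home and is
  pulled back firmly from excursions. This family is a plausible
  two-regime shape, not a literature-prescribed form.
* `custom` — tabulated $(x, u)$ pairs, linearly interpolated and
  extrapolated quadratically beyond the last point (so Gaussian-like
  tails are preserved and the normalization integral converges whenever
  the table's flanks curve upward).

## 2. Saturation of windowed mark–recapture MSD, and its inversion

Mark–recapture observes animals only inside a trapping window of side
$G$. For a population of tethered walkers with burrow centres uniformly
scattered, the steady-state mean-square displacement of capture–recapture
pairs restricted to the window is, per axis,
$$\langle \Delta x^2\rangle_{ss}
  = \frac{\int_0^G y^2 (G - y) f(y)\,dy}{\int_0^G (G - y) f(y)\,dy},
  \qquad f = e^{-u} * e^{-u},$$
with $f$ the self-convolution of the Boltzmann weight
(`self_convolution()`, `msd_ss_numeric()`). Two scales compete: the
home range $L$ and the probe $G$. Normalizing by $G^2/6$ (the value for
free walkers in the window) gives a monotone sigmoid in
$\zeta = L/G$ rising from 0 (walkers pinned at their burrows) to 1 (flat
potential): the saturation curve. Closed forms are implemented for the
harmonic (`msd_ss_harmonic()`) and logarithmic (`msd_ss_logarithmic()`)
families and verified against the quadrature pipeline to $10^{-5}$ over
$\zeta \in [10^{-2}, 10^2]$.

**Numerical conventions.** The harmonic closed form contains
$\sinh[(1/2\zeta)^2]$ and $e^{(1/2\zeta)^2}$ factors that overflow at
small $\zeta$ and cancel catastrophically at large $\zeta$; the package
evaluates the form with the exponential factored out (`expm1` for the
$1 - e^{-2u^2}$ term) and switches both families to their asymptotic
series ($1 - 7/(60\zeta^2)$ and $1 - 7/(120\zeta^2)$) for $\zeta > 20$,
where the direct expressions lose the monotone resolution on which
root-finding relies. The series were derived by expansion and checked
against 50-digit arithmetic.

**Inversion.** `invert_msd()` reads $\zeta$ off the curve: closed-form
families are solved by root bracketing in $\log\zeta$ on
$[10^{-3}, 10^3]$ (the curve is strictly monotone, so the root is
unique); tabulated curves from `build_saturation_curve()` are inverted
through a monotone (Hyman) spline of $\log\zeta$ against the curve
ordinate, which makes inversion an exact left inverse on the grid
itself. The measurement error on the observed MSD is propagated by
inverting at `msd` $\pm$ `err`, giving an asymmetric interval in $L$;
endpoints falling outside the invertible band degrade gracefully to the
pinned ($L = 0$) and flat-potential ($L = \infty$) limits rather than
failing, while an out-of-range *point* estimate is an error.

**2d convention.** For a square window with the same potential along
both axes the per-axis values add, so the normalizing constant is
$G^2/3$; rectangular windows and a different orthogonal potential are
supported in `msd_ss_numeric()`. The constant is stated explicitly
because only the per-axis normalization is canonical.

**Observed MSD.** `saturation_msd()` pools all capture pairs beyond a
user-chosen stationarity lag with equal weight (the alternative,
per-animal means first, is deliberately not the default; pooling matches
the defining triple integral). Pairs within an animal are strongly
correlated, so the reported standard error is clustered by animal, and
the recommended interval multiplies it by the $t$ quantile at
`n_animals - 1` degrees of freedom. In the package's own end-to-end
validation (200 tethered animals, burrows over $10G$, $\zeta = 0.4$, 50
replicates) these intervals cover the true $L$ in 94% of replicates.

## 3. Persistent walkers in a fixed territory

Inside fixed boundaries, a walker with speed $v$ and exponential heading
persistence of mean $T$ (memory $\phi(t) = (v^2/D)e^{-t/T}$,
$D = v^2 T$) has, per axis of a $\lambda_x \times \lambda_y$ rectangle
with no-flux walls and uniform initial condition, the eigenmode MSD
implemented in `confined_msd()`: plateau $\lambda^2/6$ per axis, weights
$(2n-1)^{-4}$, and mode frequencies
$\Theta_n = \sqrt{4 (2n-1)^2 \pi^2 \zeta_z^2 - 1}/(2T)$ with
$\zeta_z = vT/\lambda_z$. Below the threshold $\zeta_z = (2\pi)^{-1}$
the first-mode frequency is imaginary and the trigonometric terms
continue analytically to hyperbolic ones (evaluated in exponential form;
no complex arithmetic); above it the MSD rings: damped oscillations
around the plateau, a directly observable signature of persistent motion
in confinement (`oscillation_threshold()`).

Two conventions deserve emphasis:

* *Mode number.* The frequency carries the mode number $2n-1$, matching
  the $(2n-1)^{-4}$ weights. The variant carrying the bare summation
  index in the radicand coincides on the first mode — the one that sets
  the oscillation threshold — but was rejected because an exact
  dichotomous-velocity (telegrapher) walker simulated between reflecting
  walls reproduces the $(2n-1)$ form to Monte-Carlo precision (~1%)
  while deviating by ~7% from the alternative at intermediate times.
* *Per-axis speed.* The series is a per-axis telegrapher with speed $v$:
  at short times each axis is ballistic with $v^2 t^2$, so the 2d sum is
  $2v^2t^2$. An isotropic 2d walker of total speed $v_{tot}$ shares the
  velocity autocorrelation only; its exact separable counterpart is the
  diagonal walk with independent $\pm v_{tot}/\sqrt2$ components per
  axis (`generate_persistent(turning = "axis_telegrapher")`), which is
  what the generator-consistency tests use. The isotropic uniform-redraw
  walker differs from the separable series by up to ~14% at mid times
  and is provided for realism, not for validating the series.

The series is summed adaptively until the $(2n-1)^{-4}$ weight falls
below $10^{-12}$ of the accumulated sum (hard cap $10^5$ terms); terms
are evaluated in overflow-safe exponential form.

For circular arenas the package provides the effective-persistence
summary $\xi = -\mathcal{L}/[R \ln\langle\cos\theta\rangle]$
(`effective_persistence()`): 0 for uniform turning (Brownian limit),
$+\infty$ (returned as `Inf`) in the ballistic limit.

## 4. The territorial random walk

`trw_simulate()` runs scent-marking walkers on a periodic lattice:
every visited site receives (or refreshes) a mark that stays *active*
for $\mathcal{T}_A$ steps; active foreign marks elicit avoidance. Time
is discretized into sweeps — each walker attempts one hop per step in a
freshly shuffled order — so the hop time is the unit and the lattice
diffusivity is $D = 1/4$ site²/step. The spatial competition parameter
$Z = 4D\rho\mathcal{T}_A$ (`spatial_competition()`) compares the area a
walker covers during the active scent time with its per-capita share of
the terrain; by the Kac recurrence argument (mean return time to a site
of an $n$-site lattice equals $n$, verified by `kac_return_time()`),
$Z \gg 1$ means marks are refreshed before they fade and territories are
rigid.

Two response modes are provided:

* `full_exclusion` — the avoidance response is certain. The walker
  inspects the target site *before* hopping and never enters an actively
  marked foreign site; after an encounter its next hop is a full retreat,
  uniform over the neighbouring sites free of active foreign marks
  (staying put if there are none). Deposited marks erase other owners'
  marks on the site, so the actively marked areas are pairwise disjoint
  at every instant — the operational definition of territories. This
  semantics was chosen as the default for this mode because it, and not
  the land-then-respond alternative, yields the expected strong-
  competition phenomenology: utilization overlap vanishing as $Z$ grows
  and boundaries freezing as $\mathcal{T}_A \to \infty$. The alternative
  is available via `check = "after_landing"`.
* `alpha_family` — graded avoidance. The walker may enter foreign
  terrain (land-then-respond by default); the step after an encounter is
  biased toward the centroid of its own marked area with probability
  weights $l_\pm = \tfrac14\{1 \pm (2p - 1)\kappa_l\}$ (and the
  analogous vertical pair), where the bias
  $p(\tau) = \tfrac12[1 + \sqrt{1 - (\tau/\mathcal{T}_A)^\alpha}]$
  decays from 1 (fresh mark) to 1/2 (expired mark) with the age $\tau$
  of the encountered mark (`retreat_bias()`, `step_probabilities()`).
  $\alpha \to \infty$ is the step response of the full-retreat model;
  marks of different owners coexist, producing overlapping marked areas.
  `ignore_scent = TRUE` switches the response off entirely ($p \equiv
  1/2$), a free-walker null model.

Conventions the model needs but the general picture leaves open: a
walker's centroid is computed from minimal-image offsets of its active
marks relative to its current position; a walker sitting on its centroid
steps unbiased; refreshing affects only the occupied site; when multiple
foreign marks share the encountered site the youngest sets $p(\tau)$.
Utilization distributions are accumulated over the final
$2.5\,\mathcal{T}_A$ steps by default and normalized per owner.

### Territory edges in one dimension

`boundary_msd_1d()` runs the 1d full-exclusion model on a ring and
tracks the territory edges, defined as midpoints between the rightmost
active mark of an owner and the leftmost active mark of its right
neighbour (walkers cannot cross in single file, so the cyclic order is
conserved; minimal-image gaps keep the edge lift continuous when
expiring marks leave transient holes). Windows in which an owner has
lost all active marks are excluded and counted. In the
strong-competition regime the time-averaged edge MSD grows as
$\sqrt{t}$ — the tagged-particle signature of single-file exclusion —
over the decade of lags between the mark-renewal time and the crossover
to collective diffusion of the whole pattern. The packaged check uses a
ring of 1600 sites with 80 walkers ($\mathcal{T}_A = 100$,
$Z = 20$, $10^7$ steps, fit over lags $2\times10^4$–$2\times10^5$),
sizes chosen so that the single-file window spans a full decade before
the finite ring's collective mode takes over; fitted slopes across seeds
fall in 0.49–0.59.

## 5. Adiabatic boundary dynamics

On movement time scales territory boundaries are slow, so the many-body
problem reduces to one walker inside a pair of fluctuating edges
$(L_1, L_2)$ per axis whose probability obeys a Fokker–Planck equation
with diffusivity $K\varphi(t)$ and a spring of constant $\gamma$ pulling
the separation toward the equilibrium width $\bar L$ (the inverse
population density). `simulate_boundaries()` integrates the equivalent
stochastic system: separation and centroid decouple; the separation is
an Ornstein–Uhlenbeck-like process reflected at zero (edges never
exchange order) with stationary mean $\bar L$ and variance $2/\gamma$;
the centroid diffuses freely with mean-square displacement
$\int_0^t K\varphi(s)\,ds$. The modulations `sqrt_t`
($\varphi = c/\sqrt{t+1}$) and `t_over_log_t` ($\varphi = c/\ln(e+t)$)
reproduce the sub-diffusive boundary laws of the lattice model in 1d and
2d; their amplitude $c$ is a free scale, as the microscopic mapping is
known only up to proportionality. The Euler–Maruyama step must resolve
the relaxation rate ($dt \le 0.1/K\gamma$, enforced).

`compose_occupation()` forms the adiabatic product $P \approx W(x|L)\,
B(L)$ with $W$ the *long-time* (uniform) fixed-territory occupation —
the full space–time confined propagator is deliberately out of scope —
averaged over sampled boundary configurations. Configurations are
centred on their instantaneous midpoint by default: the centroid has no
stationary law (it diffuses), so only the occupation relative to the
territory centre is a well-defined steady map. Frozen boundaries
($K = 0$) recover the fixed-territory uniform exactly. Note that the
*stationary* spread of the edges is set by $\gamma$ alone ($2/\gamma$);
$K$ only sets how fast the boundary process mixes, so heavier occupation
tails are produced by softening the spring, not by raising $K$.

`k_from_ta()` encodes why borders stiffen with the active scent time: a
border only moves if the resident fails to revisit it before its marks
expire, so the border diffusivity is proportional to the probability of
*not* completing a round trip across the territory within
$\mathcal{T}_A$. In the leading first-passage mode this is
$e^{-\pi^2 D \mathcal{T}_A/(4L^2)}$ — exponential in
$\mathcal{T}_A$ — and the full eigenmode survival (`fp_survival()`)
confirms the leading-mode slope at long times. The same log-linear
behaviour emerges from the lattice model itself: measured border
diffusivities across a grid of $\mathcal{T}_A$ values correlate with
$\mathcal{T}_A$ at $r < -0.95$ on the log scale.

## 6. Trajectory statistics

`empirical_moment()` estimates the aggregate moments
$\langle|\Delta \mathbf{x}|^q\rangle(t)$. The default pools
displacements *from each animal's first fix* (the ensemble estimate):
this is the faithful reading of the aggregate-moment definition, and it
remains correct for aging walks whose increments are not stationary —
for a power-law $D(t)$ the time-window average destroys the anomalous
exponent entirely, which is easy to verify with the package's own
generator. The time-window (all-pairs) average is available via
`method = "pairs"` for stationary data. Zero lag returns 0 by
definition; empty lag bins are reported with `NA` and a warning, never
silently dropped. High-order moments probe the occupation tails and are
biased low under a finite observation window; the package warns (when
the window size is supplied) rather than corrects, since no closed
windowed correction is available beyond special cases.

`hurst_exponent()` applies the exact two-time relation
$$H(q) = \ln\!\left[\frac{\langle|\Delta x|^q\rangle(t_1)}
  {\langle|\Delta x|^q\rangle(t_2)}\right]\frac{1}{q\ln(t_1/t_2)}$$
on a grid of $q$, with percentile bootstrap bands from resampled
displacements; a set is flagged monofractal when all $H(q)$ intervals
overlap, and $\delta = 2 - H$ is reported alongside. The relation is
exact only under pure power-law scaling, and no principled rule fixes
$(t_1, t_2)$; the default takes the widest well-populated pair of lags
(at least 30 displacement pairs each) roughly the data's span apart, and
both lags are reported so sensitivity can be checked by rerunning with
explicit values.

`fit_steady_state()` fits the separable Boltzmann shape
$[U(x - x_c) + V(y - y_c)]/D$ (shared length, per-axis centres) to
thinned fixes by maximum likelihood. Only the ratio $U/D$ is
identifiable from the occupation histogram; `fit_likelihood()` recovers
$D$ as well by using the time structure:

* `homerange_smoluchowski` — the exact Ornstein–Uhlenbeck transition
  density between consecutive fixes of a harmonically tethered walker,
  parameters $(D, L, x_c, y_c)$. Maximization is direct-search simplex
  (Nelder–Mead) from Latin-hypercube multi-starts; percentile bootstrap
  over transition pairs gives the intervals. On synthetic data (5
  animals, 40 fixes each, thinning at two relaxation times) the 95%
  intervals cover the true $(D, L)$ in $\ge 90\%$ of replicates.
* `trw_adiabatic` — the stationary adiabatic territorial occupation:
  positions relative to the home-range centre follow the mixture of
  uniforms over the stationary edge separation, parameters
  $(\bar L, \gamma, x_c, y_c)$. In this long-time limit the fast
  movement parameters $(v, T)$ and the boundary diffusivity $K$ drop
  out of the stationary law, so the five-parameter dynamic likelihood
  reduces to this two-parameter spatial one; fitting the full
  five-parameter space–time density would require the time-dependent
  composed propagator, which is outside the package's scope.

## 7. Synthetic data: what it does and does not show

Every generator is seeded and bit-reproducible. `generate_tethered()`
integrates the overdamped tethered dynamics by Euler–Maruyama with step
$(L^2/D)/100$ and a warm-up of 20 relaxation times ($\tau = L^2/2D$), so
recorded fixes sample the stationary law (verified by goodness-of-fit);
burrow centres are uniform over a configurable extent, $10G$ in the
mark–recapture studies so that edge effects on the uniform-density
assumption stay below 1%. `generate_persistent()` implements
run-and-turn motion with specular reflection in boxes and circular
arenas (wrapped-Cauchy turning kernel with prescribed
$\langle\cos\theta\rangle$ in the arena). `generate_anomalous()` draws
Gaussian increments with variance $2\int D(s)\,ds$ evaluated exactly on
the fix grid — for Gaussian processes this is sampling without
discretization error — and a power-law $D(t) \propto t^{2H-1}$ yields
monofractal scaling with Hurst exponent $H$.

The generators emulate the *models*, not field data: no observation
error on positions, no irregular sampling gaps, no behavioural
heterogeneity between individuals, no landscape structure. Passing the
closed-loop tests therefore demonstrates the internal consistency of
estimators and theory under the models' own assumptions; it does not
certify performance on telemetry data, where those nuisances dominate.

## 8. Problem sizes used in the validation suite

The shipped tests run the closed-form checks at quadrature accuracy and
the stochastic checks at desk scale: 50 mark–recapture replicates of 200
animals; a $25\times25$ lattice with 16 walkers for $10^5$ steps
(disjointness audited at every recorded step); $3\times10^6$ hops for
the Kac recurrence ($>10^5$ returns); one $10^7$-step ring for the
single-file exponent; 30 likelihood-coverage replicates with 100
bootstrap resamples each; 250 walkers for the Hurst recoveries. These
sizes were chosen so each stochastic tolerance sits several standard
errors away from its pass boundary while the whole suite stays
convenient to run routinely.
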