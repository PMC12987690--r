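---
title: "Sparse multi-stage stationary treatment policies: model, estimators, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse multi-stage stationary treatment policies: model, estimators, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Micro-randomized trials (MRTs) in mobile health randomize a binary
treatment $A_t \in \{-1, +1\}$ at every one of $T$ decision points with a
known behavior policy $\mu_t(a \mid H_t)$, record a feature vector
$X_t \in \mathbb{R}^d$ at each stage, and observe a reward $R_t$.  A
*multi-stage stationary treatment policy* (MSTP) applies the same
stochastic decision rule at every stage:

$$\pi_\theta(a \mid X) \;=\; \frac{e^{\,a\,g(X,\theta)/\tau}}
  {1 + e^{\,a\,g(X,\theta)/\tau}},
  \qquad g(X, \theta) = \theta_0 + \textstyle\sum_{j=1}^d X_j \theta_j,
  \qquad \lVert\theta\rVert_2 \le 1 .$$

The scaling constant $\tau$ controls how close the stochastic rule is to
the deterministic rule $\mathrm{sign}(g)$; it is a fixed configuration
constant (default $0.2$), never optimized — smaller values destabilize the
numerics and larger ones drift far from the deterministic optimum.  The
unit-ball constraint makes the class compact; because the value of a
sigmoid policy improves as the parameter grows radially, final estimates
sit on the unit *sphere*.

The estimand is the policy value $V(\theta) =
\mathbb{E}_\theta \sum_{t=1}^T R_t$; the package reports the per-stage
average $\bar V = V/T$ so horizons are comparable.

# The AIPW loss

With step-wise importance weights
$\rho_{i,1:t} = \prod_{k\le t} \pi_\theta(A_{i,k}\mid X_{i,k}) /
\mu_k(A_{i,k}\mid H_{i,k})$ and any stage-wise augmentation model
$Q_t(x,a)$ with $U_t(x) = \sum_a \pi_\theta(a\mid x)\,Q_t(x,a)$, the loss is

$$\ell(\theta) = -\frac1n \sum_i \sum_t \Big\{
  \rho_{i,1:t}\,[R_{i,t} - Q_t(X_{i,t},A_{i,t})]
  + \rho_{i,1:(t-1)}\,U_t(X_{i,t}) \Big\},$$

an unbiased estimate of $-V(\theta)$ for *any* $Q$ because $U_t$ is the
exact $\pi_\theta$-expectation of $Q_t$ (the package computes $U_t$ by
enumerating both actions, so the cancellation is exact by construction,
and the test suite asserts it to machine precision).  A good $Q$ only
reduces variance.  Three augmentation methods are provided:

* `m = 0` — no augmentation (plain normalized IPW);
* `m = 1` — backward Q-learning: stage-wise lasso of the pseudo-response
  $R_{i,t} + \sum_a \pi_{\check\theta}(a\mid X_{i,t+1})
  \Phi(X_{i,t+1},a)^\top \hat\beta_{t+1}$ on $\Phi(X_{i,t},A_{i,t})$,
  fit from $t=T$ (where $\hat\beta_{T+1}=0$) down to $t=1$;
* `m = 2` — a variance-minimizing heuristic regressing the normalized
  weighted reward on a weight-contrast design, stage by stage.

The design is $\Phi(x,a) = (\phi(x),\, a\,\phi(x))$ with
$\phi(x) = (1, x)$, i.e. a main-effect block plus an action-interaction
block of total dimension $2(d+1)$.  All penalized fits use subject-level
cross-validation folds (never stage-level, respecting within-subject
dependence), select the penalty by minimum CV error, and are refit by
ordinary least squares on the selected support (intercept column always
retained).  Both lasso fits are delegated to `glmnet` with
`intercept = FALSE, standardize = FALSE` so the objective is exactly the
stated penalized least squares on the constructed design.

Weight stabilization is by *weighted importance sampling*: every
$\rho_{1:t}$ is divided by its cross-subject mean $\omega_{1:t}$, which is
treated as a function of $\theta$ (recomputed at every evaluated point).
Weights are accumulated in log space.  A hard cap on individual weights is
exposed but off by default — normalization, not truncation, is the
intended stabilizer.

# Estimation

The initial estimator $\check\theta$ minimizes the penalized
augmentation-free loss; the final estimator $\hat\theta$ minimizes the
augmented one, with the nuisance built at $\check\theta$:

$$\hat\theta = \arg\min_{\lVert\theta\rVert_2 \le 1}\;
  \ell(\theta) + \lambda_\theta \lVert\theta\rVert_1 .$$

The optimizer is proximal coordinate descent: each coordinate takes a
soft-threshold step against a local quadratic model built from symmetric
difference quotients of $\ell$, with the curvature floored at $10^{-2}$
(the loss is nonconvex; the floor prevents runaway steps in flat regions)
and enlarged geometrically until the step does not increase the penalized
objective, so the objective trace is non-increasing by construction.
After each full cycle the iterate is projected onto the unit ball; in the
(rare) event projection would undo the cycle's progress the previous
iterate is kept and the descent stops.  Multi-start (zero vector, the warm
start when available, seeded random unit vectors; default 5) guards
against local minima; ties are broken by smaller L1 norm, then start
order.  The final estimate is refit without the penalty on its support —
on the unit *sphere* for $\hat\theta$ (so $\lVert\hat\theta\rVert_2 = 1$
exactly), on the ball for $\check\theta$ — using BFGS on an embedded
parameterization with a tiny $(\lVert u\rVert-1)^2$ conditioning term that
only affects the (irrelevant) radial coordinate.

**Penalty selection.**  The reference method tunes
$\lambda_{\check\theta}, \lambda_\theta$ by cross-validation but does not
state the criterion.  The package scores candidates by the held-out
unpenalized normalized loss (negated held-out value) and then applies the
standard one-standard-error rule toward the *heavier* penalty.  The 1-SE
step matters: under pure-noise rewards the held-out value has expectation
zero for every $\theta$, so a plain argmin would select uniformly at
random; the 1-SE rule resolves the tie toward sparsity, which is the
behavior a sparse-policy method should have (and the test suite checks).
During the bootstrap all tuning parameters are frozen at their full-data
values.

# Inference

For valid per-coefficient inference despite the L1 penalty, the package
uses decorrelated-score one-step estimation.  A key structural point: on
the unit sphere the intercept is not a free parameter.  Inference is
carried out in the *sphere-profiled* parameterization
$\xi = \theta_{1:d}$, $\theta_0(\xi) = s\sqrt{1 - \lVert\xi\rVert^2}$ with
$s = \mathrm{sign}(\hat\theta_0)$, under which $\hat\xi$ is an interior
stationary point and the classical expansion applies.  (In the ambient
$d{+}1$ coordinates the constrained optimum has a nonvanishing radial
gradient and the one-step correction misbehaves — we verified this
numerically before settling on the profile; the intercept is therefore
reported with its sparse estimate only, without a CI.)  The special case
$\hat\theta_0 = 0$ puts the profile square root at its boundary; the
implementation clamps the square root at zero, which degrades the
symmetric quotient to the one-sided Newton quotient exactly in that case.

For each feature coordinate $j$:

1. $\hat w_j$ solves the Dantzig program
   $\min \lVert w\rVert_1$ s.t.
   $\lVert \nabla^2_{\xi_j \nu_j}\ell - w^\top \nabla^2_{\nu_j\nu_j}\ell
   \rVert_\infty \le \lambda_{w_j}$, solved exactly by a dense two-phase
   simplex written for this package (no LP solver ships with the supported
   stack); $\lambda_{w_j}$ is chosen per coordinate by subject-level CV on
   the out-of-fold infeasibility with a small L1 tiebreak.
2. The decorrelated score $\hat S_j = \nabla_{\xi_j}\ell -
   \hat w_j^\top \nabla_{\nu_j}\ell$ and information
   $\hat I_{j} = \nabla^2_{\xi_j\xi_j}\ell -
   \hat w_j^\top \nabla^2_{\nu_j \xi_j}\ell$ give the one-step estimate
   $\tilde\theta_j = \hat\theta_j - \hat S_j / \hat I_j$.
3. The headline CI is the percentile interval of $B$ trajectory-bootstrap
   replicates of $\tilde\theta_j$ (whole subjects resampled with
   replacement; replicates warm-started at the full-data estimates; failed
   replicates are skipped and counted, with more than 20% failures
   aborting the run).  The asymptotic-normal plug-in interval
   $\tilde\theta_j \pm z_{1-\alpha/2}\,\hat\sigma_j^{1/2} /
   (\sqrt n\,\lvert\hat I_j\rvert)$ — with $\hat\sigma_j$ from the sample
   covariance of per-subject score rows — is reported as a secondary
   output.

All derivatives are symmetric difference quotients (default step
$10^{-4}$), the numerically stable choice for this loss; perturbed points
are evaluated in the ambient loss (the ball constrains the estimator, not
the loss function, which is well defined everywhere).  For the per-subject
score rows and Hessians used in $\hat\sigma_j$ and the $\lambda_{w_j}$ CV,
the normalization constants $\omega$ are frozen at the full-data values at
$\hat\theta$, keeping the rows an exact i.i.d.-style decomposition; the
shared $\omega$ perturbation is $O(n^{-1/2})$ and common to all rows.
Empirical quantiles use the inverse-ECDF convention (`type = 1`).

# The synthetic scenarios

Two generative processes make every stage of the pipeline testable without
external data.  Initial states are $N(0, \Sigma)$ with
$\Sigma_{jj} = 4$, $\Sigma_{12} = 1$, and a $0.2$ band between adjacent
noise coordinates; only the first two features carry signal.  States
evolve through an exponentially weighted moving average
$\tilde X_t = 0.2\,\tilde X_{t-1} + 0.8\,X_t$ with $N(0, 0.4^2)$
innovations; Scenario 1 has a `tanh` interaction and a softplus reward
minus $0.5 A$, Scenario 2 a linear reward minus $0.6 A$; the behavior
policy is uniform ($\mu = 0.5$).  The stage-$t$ reward is realized through
the stage-$t{+}1$ state, so the returned features are deliberately
non-Markovian (rewards correlate with lagged states beyond the current
ones — tested).  This off-by-one alignment of reward and action is the
single most bug-prone point of the generator and is pinned by a test that
re-derives a full two-stage trace from the raw RNG stream.  The printed
form of the reward displays indexes the action as $A_{i,t}$ next to
$R_{i,t-1}$; the package reads this as the action of the *reward's own
stage* (the alternative would reference an action beyond the horizon at
the final stage).

For Scenario 2 at $T=1$ the optimal rule is available in closed form as a
sanity anchor: $\mathbb{E}[R \mid X, A] = 1.6X_1 + 0.3X_2 +
A\,(0.3X_1 + 0.2X_2 - 0.6)$, so treatment helps iff
$0.3X_1 + 0.2X_2 > 0.6$ and $\theta^* \propto (-0.6, 0.3, 0.2)$.  The
packaged grid search (`grid_search_theta_star`) recovers this direction;
for $T = 1$ it uses common random numbers with exact enumeration over the
binary action (a Rao–Blackwellized form of on-policy Monte Carlo), for
$T > 1$ plain on-policy simulation per grid point.

**What a green test establishes.**  The generators emulate the stated
world: Gaussian features with the stated covariance, EWMA dynamics, known
randomization, complete data, common horizon.  They do not emulate
real-MRT features such as missingness, availability windows, non-Gaussian
biomarkers, or unknown behavior policies, so green tests certify the
estimators' statistical behavior under the stated world, not robustness
beyond it.

# Numerical choices, in one place

* $\tau = 0.2$ fixed; difference step $h = 10^{-4}\max(1,\lVert\theta\rVert)$.
* Curvature floor $10^{-2}$; CD tolerance $10^{-4}$ on the max coordinate
  change; max 50 cycles (defaults).
* Policy-penalty grid: data-driven, $\lambda_{\max} =
  \lVert\nabla\ell(0)\rVert_\infty$ down 2.5 decades, 8 points (defaults).
* Dantzig tolerance grid per coordinate: $\lVert b\rVert_\infty$ times
  $10^{-0.5}$ … $10^{-2.5}$, 6 points.
* Simplex: Bland's rule, two phases, tolerance $10^{-9}$; exact on the
  package's problem sizes (cross-checked against an independent LP solver
  during development and against brute-force grids in the test suite).
* Degenerate inputs: constant pseudo-responses fall back to
  intercept-only fits; empty supports skip refitting; a failed support
  refit warns and returns the penalized estimate; near-singular
  decorrelated information ($|\hat I_j| < 10^{-8}$) warns.
* All randomness flows from one master seed through derived substreams
  (starts, folds, bootstrap); bootstrap replicate $b$ uses substream $b$,
  so results are bit-reproducible.

# Scaled-down test protocol

The reference simulation protocol ($d = 50$, $n$ up to 3200, $B = 100$
bootstrap draws, $W = 100$ replicates, 200,000-trajectory evaluation sets)
is a multi-hour batch job.  The shipped acceptance tests keep every
tolerance and acceptance band but shrink problem sizes to fit a single
CPU: dimension-free identities run at $d = 8$–$12$, the coverage study at
$W = 20$, $B = 30$, $n = 400$, $d = 10$ with the exact binomial band
recomputed for $W = 20$, and evaluation sets of 40,000–200,000 as noted in
the test file.  Sizes were fixed by budget arithmetic before the tests
were first run.

# Known limitations

* Only the linear basis for $\phi$ is implemented (splines/RBF variants
  would slot into `basis_spec`).
* Inference covers the feature coefficients; the intercept has no CI by
  construction of the sphere profile.
* The behavior policy must be known (MRT setting); observational-study
  extensions (estimated propensities) are out of scope.
* Long horizons stress the importance weights; normalization helps but the
  variance still grows with $T$, and the variance-minimizing augmentation
  (`m = 2`) is the least stable of the three as $T$ grows.
* Confidence intervals are per-coordinate, not simultaneous.
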