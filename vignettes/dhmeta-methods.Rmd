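---
title: "Methods: frequentist estimation of the Daniels-Hughes surrogate model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: frequentist estimation of the Daniels-Hughes surrogate model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`dhmeta` evaluates trial-level surrogacy: whether the treatment effect on a
candidate surrogate endpoint (say, the log hazard ratio for progression-free
survival) predicts the treatment effect on the clinical outcome of interest
(say, the log hazard ratio for overall survival) across randomized trials.
Each of $n$ studies contributes an estimate pair and a known within-study
covariance:

$$
\begin{pmatrix}\hat\theta_i\\ \hat\gamma_i\end{pmatrix} \sim
N\!\left(\begin{pmatrix}\theta_i\\ \gamma_i\end{pmatrix},
\begin{pmatrix}\sigma_i^2 & \rho_i\sigma_i\delta_i\\
\rho_i\sigma_i\delta_i & \delta_i^2\end{pmatrix}\right),
$$

and between studies the true effects are linked by a conditional linear
regression rather than a bivariate normal:

$$
\theta_i \mid \gamma_i \sim N(\alpha + \beta\gamma_i,\ \tau^2).
$$

The implied marginal model treats each $\gamma_i$ as a separate fixed
(incidental) parameter, so the parameter count $n + 3$ grows with the
number of studies. $\alpha \approx 0$, $\beta \neq 0$ and $\tau^2 \approx 0$
together indicate a useful surrogate; $\tau^2$ is the central — and
hardest — quantity. All effects are handled on the log (linear-predictor)
scale throughout; the package never exponentiates.

Two algebraically identical encodings of the likelihood are implemented:
the per-study bivariate normal density (`loglik_marginal()`) and the
factorization into $\hat\gamma_i \sim N(\gamma_i, \delta_i^2)$ times
$\hat\theta_i \mid \hat\gamma_i \sim N(\mu_i(\hat\gamma_i), v_i^2+\tau^2)$
with $\mu_i(\hat\gamma_i) = \alpha + \beta\gamma_i +
(\rho_i\sigma_i/\delta_i)(\hat\gamma_i-\gamma_i)$ and
$v_i^2 = \sigma_i^2(1-\rho_i^2)$ (`loglik_factorized()`). Their agreement
to $10^{-10}$ over randomized inputs is a permanent regression test of both.

## Maximum likelihood and certification

`fit_mle()` maximizes the likelihood by quasi-Newton iteration (`nlminb`
with exact analytic gradients) over $(\alpha, \beta, \log\tau^2,
\gamma_1,\dots,\gamma_n)$, so every coordinate is unconstrained;
$\log\hat\tau^2$ below $\log(10^{-8})$ is truncated to $\hat\tau^2 = 0$.
Because the optimization dimension grows with $n$, convergence claims from
the optimizer alone are not trusted. Every fit is certified by substituting
the solution into the full set of maximum-likelihood estimating equations:

* for each $\gamma_i$, the generalized-least-squares projection of
  $(\hat\theta_i - \alpha, \hat\gamma_i)$ onto the design vector
  $(\beta, 1)$ (computed by the closed-form $2\times 2$ adjoint — the
  determinant cancels, so no matrix is ever inverted);
* for $(\alpha, \beta)$, the weighted-regression-with-offset normal
  equations of the conditional model, solved in closed form;
* for $\tau^2$, the fixed-point form
  $\hat\tau^2 = \sum_i w_i\{(\hat\theta_i-\hat\mu_i)^2 - v_i^2\} / \sum_i w_i$
  with $w_i = (v_i^2+\hat\tau^2)^{-2}$, truncated at zero. At a truncated
  solution the equation is checked in the Karush-Kuhn-Tucker sense (the
  untruncated update at zero must be non-positive).

A fit is `converged` only when the maximum absolute residual is below the
tolerance ($10^{-6}$ by default). If certification fails, the solution is
polished by fixed-point sweeps of the same equations and up to three
jittered restarts are tried; remaining failure is flagged, never silently
accepted.

Starting values are the natural moment choices: $\gamma_i \leftarrow
\hat\gamma_i$, $(\alpha,\beta)$ from weighted least squares of
$\hat\theta$ on $\hat\gamma$ with weights $1/\sigma_i^2$, and $\tau^2$ from
one fixed-point step floored at $10^{-4}$.

## The incidental-parameters bias and its adjustment

Estimating one $\gamma_i$ per study biases the ML estimate of $\tau^2$
downward, a Neyman-Scott type effect. The mechanism is explicit here.
Writing $g_i = \rho_i\sigma_i/\delta_i$ for the *within-study gradient*
(the slope of $E(\hat\theta_i\mid\hat\gamma_i)$ inside study $i$) and
$\beta$ for the *between-study gradient*, the model-based
$\hat\gamma_{i,\mathrm{MLE}}$ is a weighted compromise
$b_i\gamma_i + (1-b_i)\hat\gamma_i + w_{1i}e_i$ with

$$
b_i \;=\; \frac{(\beta\delta_i-\rho_i\sigma_i)^2}
{(\beta\delta_i-\rho_i\sigma_i)^2 + \tau^2 + v_i^2} \;\in\; [0,1),
$$

so the residual entering the $\tau^2$ equation contracts:
$\hat\theta_i - \hat\mu_i = (1-b_i)\{e_i + (\beta-g_i)(\gamma_i-\hat\gamma_i)\}$,
and its expected square is $(1-b_i)(v_i^2+\tau^2)$ rather than
$v_i^2+\tau^2$. When $\beta = g_i$ the two gradients match, $b_i = 0$, and
plain maximum likelihood is already well behaved; the adjustment grows with
the squared gap between the gradients.

The bias-adjusted analysis (`fit_adjusted()`) replaces each squared
residual by $(1-b_i)^{-2}(\hat\theta_i-\hat\mu_i)^2$ in the $\tau^2$
update. This is the published form of the estimator that this package
implements; note that $(1-b_i)^{-2}$ is stronger than the factor
$(1-b_i)^{-1}$ that exactly restores the mean of the squared residual when
$\alpha$, $\beta$ and $\tau^2$ are held at their true values (the closed
form above, which the test suite verifies by Monte Carlo). The stronger
inflation partially compensates for the additional residual shrinkage
caused by estimating $\alpha$ and $\beta$, at the price of mild
overcorrection in the known-parameter thought experiment; in the
simulation study below it removes most, not all, of the downward bias
while plain ML can lose nearly half of a true $\tau^2 = 1$.

The adjusted fit iterates to a joint fixed point, starting at the MLE:
given the current $\tau^2$, maximize over $(\alpha,\beta,\gamma)$ under
that constraint; then update $\tau^2$ by the adjusted equation with $b_i$
evaluated at the *current* $(\hat\beta, \hat\tau^2)$; stop when the
$\tau^2$ change is below $10^{-8}$ (or after 200 rounds; a zero update
twice in a row is terminal). This full fixed-point reading was an open
design choice — evaluating the adjusted equation once at MLE quantities
followed by a single constrained refit is defensible too, and remains
available via `mode = "single_pass"`; the iterated version is the default
because the adjusted equation carries $\hat\tau^2$ on its own right-hand
side, which is the signature of a fixed-point scheme, and because the
iterate is then a self-consistent solution certifiable by the estimating
equations.

## Standard errors and intervals

Standard errors come from the numerically differentiated Hessian of the
negative log-likelihood (central differences of the analytic gradient,
relative step $10^{-5}$), inverted by a symmetric generalized inverse with
Jacobi pre-scaling and eigenvalue truncation at relative tolerance
$10^{-10}$. At $\hat\tau^2 = 0$ the $\log\tau^2$ coordinate carries no
curvature, so it is dropped — numerically equivalent to constraining
$\tau^2 = 0$. The adjusted analysis treats $\hat\tau^2_{\mathrm{adjusted}}$
as known when computing standard errors for $(\alpha, \beta)$, the common
meta-analytic approximation. Wald intervals use exact normal quantiles. No
confidence interval for $\tau^2$ is produced: a defensible interval for a
truncated variance component at or near the boundary needs
profile-likelihood machinery that is deliberately out of scope.

## The Bayesian comparator

`fit_bayes()` provides the conventional Bayesian analysis used as a
reference point: independent $N(0, 1000)$ priors for $\alpha$, $\beta$ and
every $\gamma_i$, a uniform prior on the between-study *standard
deviation* $\tau \sim U(0, 2)$, burn-in 1000, then 10,000 iterations
thinned by two. The sampler is Metropolis-within-Gibbs written directly in
R: under the factorized likelihood every $\gamma_i$ and the pair
$(\alpha,\beta)$ have conjugate normal full conditionals and are drawn
exactly, while $\tau$ takes a random-walk Metropolis step on the SD scale
(normal proposal, SD $0.1 \times$ the prior upper bound) reflected into
the prior support — the reflection keeps the proposal symmetric, so the
acceptance ratio is the likelihood ratio alone. A hand-rolled sampler was
chosen over a probabilistic-programming dependency because the
conditionals are conjugate except for one scalar, and it keeps the chain
bit-reproducible from a single seed. Posterior summaries report means,
medians, central 95% percentile intervals and 95% HPD intervals (shortest
sorted window). With few studies the posterior of $\tau^2$ is markedly
right-skewed, so mean/percentile and median/HPD summaries can disagree
noticeably; both are reported.

## The simulation engine and what it emulates

`make_scenarios()` enumerates the factorial design used for the bias and
coverage study: $n = 20$ studies; true $\gamma_i \sim U(-5, 5)$ redrawn
each replicate; within-study variances $\sigma_i^2 = \delta_i^2 = 0.05,
0.10, \dots, 1.00$ assigned one per study and held fixed across
replicates; $\beta \in \{0, 0.4, 0.8\}$; a shared $\rho_i \in
\{0, 0.4, 0.8\}$; $\tau^2 \in \{0, 0.5, 1\}$; $\alpha \in \{0, 0.25\}$ —
54 scenarios. Two interpretive choices deserve note. First, the twenty
printed variance values are read as a per-study grid within every dataset
(study $i$ gets $0.05i$), not as twenty separate designs: the 54-scenario
count only works under that reading. Second, the $\gamma_i$ are redrawn
every replicate, since they are described distributionally; an option pins
them for sensitivity checks. Because $\sigma_i = \delta_i$ throughout the
grid, the within-study gradient equals $\rho_i$, so scenarios with
$\beta = \rho$ are the benign matched-gradient cells and $\beta = 0,
\rho = 0.8$ (or vice versa) the hostile ones.

Seeding is counter-based: a master seed yields one seed per scenario and
one per (scenario, replicate) pair through an integer hash kept inside the
32-bit range, so any single replicate can be regenerated in isolation.

The generator emulates exactly the sampling model the estimators assume —
bivariate normal within studies with known covariance, a linear
conditional between-study law, independent studies. It does not emulate
features of real meta-analytic data such as misreported or estimated
within-study correlations, non-normal effect estimates from small trials,
selective publication, or correlation between study size and effect. Tests
passing on this generator therefore validate the estimation machinery
under its own assumptions; they are silent about robustness to violations
of those assumptions.

Desk-scale problem sizes are used in the test suite: certification on 100
fitted datasets, known-parameter unbiasedness with 10,000 Monte-Carlo
replicates per $\tau^2$ value, and the recovery/coverage experiments with
300-400 replicates per scenario. The full 54 scenarios at 1000 replicates
with all three methods reproduce at cluster scale with
`run_simulation(make_scenarios(1000, seed))` unchanged.

## Numerical choices

* Per-study $2\times 2$ inverses always go through the closed-form
  adjoint; determinants cancel in the projections, avoiding overflow even
  for enormous $\tau^2$.
* $|\rho_i|$ is bounded away from 1 by $10^{-6}$ at validation so
  $v_i^2 > 0$.
* $\hat\tau^2 < 10^{-8}$ is declared zero (the operational meaning of
  "$\log\hat\tau^2$ very large and negative").
* `alpha_beta_update()` refuses (numerically) constant $\gamma$ vectors
  rather than returning an arbitrary line through a singular design.
* A fit needs $n \ge 3$: with $n + 3$ parameters and $2n$ observations,
  $n = 2$ is under-identified.
* Non-converged replicates in simulations are counted and excluded from
  summaries, never crashed on and never silently kept.

## Limitations

The within-study correlations $\rho_i$ are taken as known inputs; deriving
them from individual patient data or bootstrap schemes is out of scope, and
the recommended practice when they are unknown is the shared-value
sensitivity scan in `run_sensitivity()`. Only one surrogate and one
outcome are modelled — no multi-surrogate, treatment-class or network
extensions. No prediction intervals, heterogeneity indices, Bayes factors
or formal surrogacy decision rules are produced. Confidence intervals for
$\tau^2$ are not offered. The Bayesian arm is a reference analysis with
one fixed prior family, not a general-purpose Bayesian toolkit.
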