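# dhmeta

Frequentist estimation of the Daniels–Hughes bivariate meta-analysis model
for trial-level surrogate endpoint evaluation.

## The problem

When the clinical outcome of interest (e.g., overall survival, OS) is slow
or hard to measure, trials often rely on a surrogate endpoint (e.g.,
progression-free survival, or response rate). Whether the surrogate is
*trial-level* valid is a meta-analytic question: across studies, does the
treatment effect on the surrogate predict the treatment effect on the
clinical outcome? Each of *n* studies supplies two estimated effects on
the log scale with a known within-study covariance,

```
(θ̂ᵢ, γ̂ᵢ) ~ N((θᵢ, γᵢ), [[σᵢ², ρᵢσᵢδᵢ], [ρᵢσᵢδᵢ, δᵢ²]]),
```

and the Daniels–Hughes model links the true effects by a conditional
regression between studies,

```
θᵢ | γᵢ ~ N(α + βγᵢ, τ²).
```

`α ≈ 0`, `β ≠ 0` and `τ² ≈ 0` together support surrogacy. The model
carries one fixed nuisance parameter `γᵢ` per study, so maximum likelihood
estimation of the between-study variance `τ²` suffers a Neyman–Scott type
downward bias — severe whenever the between-study gradient `β` differs
from the within-study gradients `ρᵢσᵢ/δᵢ`. This package provides:

* **`fit_mle()`** — numerical maximum likelihood over
  `(α, β, log τ², γ₁…γₙ)` with analytic gradients, and *certification* of
  every solution by substituting it into the closed-form estimating
  equations (γ-projection, weighted regression with offset, τ²
  fixed point), so optimizer convergence is verified, not assumed.
* **`fit_adjusted()`** — the bias-adjusted analysis: squared residuals in
  the τ² update are inflated by `(1 − bᵢ)⁻²`, where
  `bᵢ = (βδᵢ − ρᵢσᵢ)² / ((βδᵢ − ρᵢσᵢ)² + τ² + vᵢ²) ∈ [0, 1)` measures the
  gradient mismatch for study *i*; `(α, β, γ)` are then re-estimated with
  `τ²` constrained at the adjusted value, iterating to a joint fixed
  point.
* **`fit_bayes()`** — the conventional Bayesian comparator
  (`N(0, 1000)` priors for regression parameters, `τ ~ U(0, 2)`,
  Metropolis-within-Gibbs, percentile and HPD intervals).
* **`make_scenarios()` / `run_simulation()`** — the 54-scenario
  bias/coverage simulation engine (n = 20 studies, per-study variances
  0.05…1.00, β and shared ρ in {0, 0.4, 0.8}, τ² in {0, 0.5, 1}, α in
  {0, 0.25}), which also generates all test data.
* **`read_study_table()` / `run_sensitivity()`** — CSV input with explicit
  within-study correlations (a missing ρ is an error, never a silent 0)
  and the shared-ρ sensitivity scan used when correlations are unknown.

A thin command-line wrapper with `fit`, `sensitivity`, `simulate` and
`fixture` verbs is installed at `inst/cli/dhmeta`.

## Worked example

A synthetic 42-study table shaped like a response-rate/OS meta-analysis
(log odds ratios for the surrogate, log hazard ratios for the outcome,
negative within-study correlation). The correlations are treated as
unknown and scanned:

```r
library(dhmeta)
tab  <- make_fixture("example2_like", seed = 1)
sens <- run_sensitivity(tab, c(-0.1, -0.5, -0.9), method = "adjusted")
sens[, c("rho", "alpha", "beta", "tau2", "gradient_min", "gradient_max")]
#>    rho  alpha  beta    tau2 gradient_min gradient_max
#> 1 -0.1 -0.041 -0.31 0.00000       -0.072       -0.047
#> 2 -0.5 -0.098 -0.21 0.00055       -0.360       -0.233
#> 3 -0.9 -0.153 -0.10 0.02623       -0.647       -0.420
```

At `ρ = -0.1` the within-study gradients (−0.07 to −0.05) are close to the
fitted slope, the bias terms are near zero, and the adjusted analysis
agrees with plain maximum likelihood. At `ρ = -0.9` the gradients clash
with the slope and the two analyses separate sharply:

```r
tab9 <- tab; tab9$rho <- rep(-0.9, 42)
fit_mle(tab9)
#> Daniels-Hughes model fit (maximum likelihood), 42 studies
#>   alpha: -0.250 (-0.364, -0.135)
#>   beta : 0.043 (-0.129, 0.216)
#>   tau2 : 0.000 (truncated at 0)
#>   log-likelihood 50.5501; estimating-equation max residual 8.37e-11; converged
fit_adjusted(tab9)
#> Daniels-Hughes model fit (bias-adjusted), 42 studies
#>   alpha: -0.153 (-0.272, -0.033)
#>   beta : -0.101 (-0.284, 0.082)
#>   tau2 : 0.026
#>   log-likelihood 28.7388; estimating-equation max residual 1.44e-10; converged
```

Plain maximum likelihood truncates `τ̂²` to zero and loses the negative
slope entirely; the bias adjustment recovers `τ̂² > 0` and a slope with
the expected sign. The `estimating-equation max residual` line is the
certification: at a genuine solution it is at rounding level.

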