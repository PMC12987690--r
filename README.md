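# mstpolicy

Sparse **m**ulti-**s**tage stationary **t**reatment **p**olicies with
doubly robust estimation and valid per-coefficient inference.

## Who this is for

Biostatisticians analyzing micro-randomized trials (MRTs) — mobile-health
studies that randomize a binary treatment `A_t ∈ {−1, +1}` at every one of
`T` decision points with *known* probabilities — who want a single,
interpretable, sparse decision rule applied identically at every stage,
together with honest confidence intervals for each feature's coefficient
despite L1 selection in possibly high dimension.

## The method

The policy class is a scaled sigmoid of a linear score,

    π_θ(a | X) = exp(a·g(X,θ)/τ) / (1 + exp(a·g(X,θ)/τ)),
    g(X, θ) = θ0 + Σ_j X_j θ_j,   ‖θ‖₂ ≤ 1,   τ = 0.2 fixed,

and its value `V(θ) = E_θ[Σ_t R_t]` is estimated from off-policy MRT data
by an augmented inverse probability weighted (AIPW / doubly robust)
estimator with step-wise importance weights, weighted-importance-sampling
normalization, and one of three stage-wise augmentation (Q-function)
models (`m = 0` none, `m = 1` backward Q-learning lasso, `m = 2`
variance-minimizing lasso). The sparse policy is

    θ̂ = argmin ℓ(θ, η̂) + λ‖θ‖₁   s.t. ‖θ‖₂ ≤ 1,

found by proximal coordinate descent with per-cycle ball projection,
multi-start, cross-validated λ, and an unpenalized support refit that
lands on the unit sphere. Inference for each feature coefficient uses a
decorrelated score: a Dantzig-selector linear program gives the sparse
projection ŵ_j of coordinate j's score on the remaining scores, a
one-step (debiased) estimator `θ̃_j = θ̂_j − Ŝ_j / Î_j` removes the
selection bias, and its confidence interval is the percentile interval of
trajectory-bootstrap replicates (an asymptotic-normal plug-in interval is
reported alongside). On the unit sphere the intercept is profiled out
(`θ0 = ±√(1−‖ξ‖²)`), so CIs are produced for the `d` feature coefficients.

Two fully specified simulation scenarios (Gaussian features,
exponentially-weighted-moving-average state dynamics, non-Markovian
rewards, uniform behavior policy) make every stage testable without
external data. See `vignettes/mstp-methods.Rmd` for the complete account.

## Worked example

```r
library(mstpolicy)

sc  <- scenario_config(scenario = 2, n = 400, T = 2, d = 6, seed = 42)
ds  <- simulate_trajectories(sc)            # behavior-policy MRT data
cfg <- fit_config(seed = 42, n_lambda = 6, n_starts = 3, cv_folds = 3)
res <- infer(ds, tau = 0.2, method_m = 1, cfg = cfg, B = 40,
             alpha = 0.05, coords = c(1L, 2L, 3L))
res
#> <inference_result> B = 40 (failed 0), alpha = 0.05
#>  j theta_hat theta_tilde ci_lower ci_upper plugin_se
#>  1    0.6791      0.6799   0.5258   0.7350   0.03331
#>  2    0.2770      0.2779   0.1809   0.3471   0.04285
#>  3    0.0000      0.0466  -0.9115   0.1170   0.04153

evaluate_on_policy(sc, res$theta_hat, n_eval = 50000, seed = 7)$mean_average_reward
#> 1.039   # behavior policy: -0.001 under the same evaluation draws
```

Reading the output: features 1 and 2 truly drive the reward in this
scenario and their one-step CIs exclude zero; feature 3 is pure noise —
the sparse estimate sets it exactly to zero and its CI covers zero. The
learned policy lifts the per-stage average reward from ≈ 0 (uniform
random treatment) to ≈ 1.04.

## Command line

```sh
MSTP=$(Rscript -e 'cat(system.file("cli", "mstp.R", package = "mstpolicy"))')
Rscript $MSTP simulate --config sim.yaml --seed 1 --out data.csv
Rscript $MSTP fit      --config fit.yaml
Rscript $MSTP infer    --config infer.yaml
Rscript $MSTP evaluate --config eval.yaml
```

Configs are YAML (see `?read_run_config` for the recognized keys per
command); reports are JSON; datasets are long-format CSV with columns
`subject_id, stage, x1..xd, action, reward, behavior_prob`.

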