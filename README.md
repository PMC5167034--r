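# establishr

Predicting whether an introduced species will establish — and how well
that prediction can possibly be made — when the population is small
enough that demographic stochasticity matters and our knowledge of the
species' demographic traits is imperfect.

`establishr` is aimed at quantitative ecologists and biostatisticians
studying invasion dynamics in simulated or experimental systems. It
implements, end to end:

1. **An exact stochastic simulator** (Gillespie algorithm, compiled) of
   the competitive Lotka–Volterra birth–death process. An invader with
   intrinsic birth/death rates λ, μ and maximum population size N is
   introduced at n₀ = 40 individuals into a resident community sitting
   at its carrying capacity K_R = 10,000. A single noise coefficient
   δ = (λ + μ)/2 tunes demographic stochasticity while the mean
   dynamics stay fixed (r = 1/day, K = 10,000 for every δ ∈ [0.5, 5]).
   During the early invasion the resident barely moves
   (n_R > 0.99 K_R), so its competitive pressure is absorbed into a
   modified invader birth rate λ̄ = λ(1 − αK_R/N); the interaction
   strength α is the quantity of interest, with a deterministic
   bifurcation at α = 1 between establishment (α < 1) and extinction
   (α > 1).

2. **A diffusion-approximation likelihood** for discretely sampled,
   Poisson-thinned survey counts: Gaussian transitions with the
   logistic mean n(t) = K n₀ e^{rt} / (K + n₀(e^{rt} − 1)) and the
   moment-closure variance σ²(t) = M_t² ∫₀ᵗ H(n(s)) M_s⁻² ds
   (F = B − D, H = B + D, M_t = exp ∫ F′), evaluated in closed form,
   plus a Poisson observation term with mean f·n̄ for a search fraction
   f = 0.25.

3. **Metropolis–Hastings posterior sampling** of α and the latent
   abundances under four graded-knowledge scenarios: all single-species
   parameters known, or lognormal priors (width σ) on K, on K and N, or
   on K, N and r. α always carries a flat prior on [0, 2].

4. **Prediction metrics**: predictability (probability that a
   stochastic replicate matches the deterministic outcome),
   predictive ability (posterior mass of α on the correct side of 1,
   averaged over replicate introductions), and the precision/accuracy
   of the α estimate, each over (α, δ) grids or single pixels.

See the methods vignette (`vignettes/establishment-inference.Rmd`) for
the model, its assumptions and all numerical conventions.

## Worked example

Simulate one introduction at α = 0.8 (deterministic establishment),
moderate noise δ = 1.75, observe it 10 times over 4 days with a 25%
search fraction, and infer α with perfect knowledge of the
single-species parameters:

```r
library(establishr)

eff <- effective_params(params_from_delta(1.75), alpha = 0.8, K_R = 10000)
eff
#> Effective (competition-modified) invader parameters:
#>   lambda_bar = 1.45, mu = 1.25, N = 22500
#>   r_bar = 0.2, K_bar = 3103.45

obs <- simulate_observation_series(alpha = 0.8, delta = 1.75, seed = 101)
obs
#> Observation series: n0 = 40, d = 10 surveys over (0, 4] days, f = 0.25
#>  time observed latent
#>   0.0       40     40
#>   0.4       17     38
#>   ...
#>   4.0       25     77

pr  <- build_priors("ALL_FIXED", anchors = anchors_from_delta(1.75))
fit <- mh_sample(obs, pr, seed = 102)
posterior_summary(fit)
#> alpha: mean 0.768, SE 0.116, 95% CI [0.534, 0.984]
#> mass below 1: 0.983, above 1: 0.018 (ESS 1553)

predictive_ability(fit, true_alpha = 0.8)
#> [1] 0.9825
```

The posterior mean 0.768 sits near the generating α = 0.8; 98% of the
posterior mass lies below the bifurcation, i.e. for this realization an
establishment call would be made with high confidence. Averaged over
replicate introductions the picture is harsher — single noisy
realizations can place substantial mass on the wrong side — which is
exactly what the predictive-ability metrics quantify:

```r
predictive_ability_pixel(0.8, 1.75, "ALL_FIXED", n_real = 30, seed = 42)
#> ~0.81   (mean posterior mass on alpha < 1 over 30 introductions)
```

A command-line wrapper for simulation, inference and configured
experiment runs is provided at `inst/cli/estab-cli.R`.

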