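# phbayes

Hierarchical Bayesian modelling of pH kinetics in fresh meat products.

## The problem

The pH of fresh meat products falls during chilled storage as lactic acid
bacteria ferment, then levels off once the matrix buffers the acid. Because
pH both tracks and drives microbial spoilage, its trajectory is a cheap,
accurate spoilage indicator — but industrial monitoring data are sparse
(a handful of sampling days), come from multiple production batches with
different starting pH, and are collected under crossed preservation
treatments (potassium lactate dose, packaging atmosphere). `phbayes` is for
food microbiologists and predictive-microbiology modellers who want to fit
such data, compare model variants, and simulate pH under new preservation
conditions with honest uncertainty.

## The model

pH in batch *r* under condition *k* (lactate dose in % w/w, atmosphere
*p* ∈ {Air, MAP1 = 70%O₂–30%CO₂, MAP2 = 50%CO₂–50%N₂}) follows a
two-phase curve with breakpoint θ (days):

    m(t) = pH0_r − β_k · min(t, θ)
    ln β_k = λ · Lactate^n + δ_p
    pH0_r ~ N(μ_pH0, σ_pH0)          (batch random effect)
    Y_i   ~ N(m(t_i), σ_pH)          (measurement error)

Priors: μ_pH0 ~ N(5.84, 0.11) (literature values for fresh poultry
sausage), σ_pH0, σ_pH ~ half-N(0, 0.1), δ_p ~ U(−10, 10), λ ~ U(−1, 1);
four variants fix or free the scale exponent *n* (= 1 when fixed; U(−3, 3))
and the breakpoint θ (= 15 d when fixed; U(8, 22)), giving models M1–M4
with 7/8/8/9 free parameters, compared by DIC.

Inference is a purpose-built adaptive random-walk Metropolis-within-Gibbs
sampler (one block per parameter, conjugate Gibbs draws for the latent
batch values, log-scale proposals for standard deviations), with
Gelman–Rubin and Geweke convergence diagnostics.

## Worked example

```r
library(phbayes)

# deterministic kernel at the selected variant's point estimates:
# full lactate dose under air, day 15 (past the ~12.9-day breakpoint)
mean_ph(ph_params(), lactate = 2, atmosphere = "Air", day = 15, pH0 = 6.49)
#> [1] 5.550843

# fastest (zero lactate, CO2/N2) and slowest (full dose, high-O2) rates
acidification_rate(-0.095, 1, -2.339, lactate = 0)
#> [1] 0.09642401
acidification_rate(-0.095, 1, -2.487, lactate = 2)
#> [1] 0.06876915

# simulate a full study design (10 batches x 9 conditions x 4 days)
# and refit the free-breakpoint variant
sim <- simulate_ph_data(ph_design(), ph_params(), seed = 42)
fit <- fit_ph_model(sim, ph_variant("M3"),
                    mcmc_config(n_chains = 2, burn_in = 1000,
                                n_iterations = 4000, thinning = 4, seed = 7))
tidy(fit, latent = FALSE)
#> # A tibble: 9 × 4
#>   term       estimate conf.low conf.high
#> 1 mu_pH0       6.46     6.28      6.54
#> 2 sigma_pH0    0.0997   0.0546    0.230
#> 3 sigma_pH     0.144    0.134     0.155
#> 4 lambda      -0.0962  -0.121    -0.0729
#> 5 delta_Air   -2.44    -2.54     -2.36
#> 6 delta_MAP1  -2.53    -2.63     -2.44
#> 7 delta_MAP2  -2.39    -2.49     -2.31
#> 8 n            1        1         1
#> 9 theta       13.2     12.5      14.1
```

The posterior medians recover the generating truth (λ = −0.095, θ = 12.9,
μ_pH0 = 6.49, σ_pH = 0.15) within their 95% credibility intervals; the
first three `delta` rows show MAP2 accelerating acidification relative to
air and MAP1 slowing it, the pattern the model is built to quantify.

Downstream steps chain off the fit:

```r
diagnose(fit)                                   # Rhat + Geweke report
compute_dic(fit, sim)                           # model score
augment(fit, sim)                               # .fitted / .resid per row
band <- simulate_kinetics(fit, lactate = 1.5, atmosphere = "MAP2")
autoplot(band)                                  # median curve + 95% band
```

`run_ph_pipeline()` runs the whole workflow (fit all four variants,
diagnose, DIC table, winner summary, residuals, simulation scenarios) from
one config list or YAML file and writes plain CSV/JSON outputs.

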