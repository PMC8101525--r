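# curefrail

Mixture cure rate frailty models for right-censored survival data.

Cancer registries followed long enough routinely show a Kaplan–Meier curve
that flattens at a plateau well above zero: a fraction of patients —
*long-term survivors* — will never die of the disease under study. Cox-type
models, which assume everyone eventually experiences the event, are the
wrong tool there. `curefrail` is for analysts of such cohorts
(epidemiologists, biostatisticians working with cancer registry data). It
fits the mixture cure model

&nbsp;&nbsp;&nbsp;&nbsp;*S*<sub>pop</sub>(*t* | *x*) = *π*(*x*) + (1 − *π*(*x*)) *S*<sub>u</sub>(*t* | *x*)

with

* logistic **incidence**: π(x) = logit⁻¹(b₀ + x′b), the probability of being
  cured, so exp(bⱼ) is a cure odds ratio;
* Weibull proportional-hazards **latency** for the uncured, baseline
  cumulative hazard H₀(t) = λt^α;
* mean-one **gamma frailty** w ~ Gamma(θ, θ) multiplying the latency hazard
  (variance 1/θ; θ → ∞ is the frailty-free model), marginalised
  analytically, so the observed-data likelihood is exact:

&nbsp;&nbsp;&nbsp;&nbsp;*S*<sub>u</sub>(*t* | *x*) = (1 + H₀(t)e^{x′β}/θ)^{−θ}.

Inference is by maximum likelihood (multi-start BFGS + Newton polish, Wald
intervals) or by adaptive random-walk Metropolis–Hastings (weakly
informative normal priors, split-R̂/ESS diagnostics), with DIC/EAIC/EBIC
comparison, Kaplan–Meier plateau diagnosis of the cure fraction, odds-ratio
and cure-probability report tables, and a calibrated synthetic cohort
generator emulating a gastric-cancer registry population (event rate 57.5%,
plateau ≈ 0.3, mean follow-up ≈ 21.7 months).

## Worked example

```r
library(curefrail)

# a registry-like cohort: 1200 patients, ~57% deaths, cured fraction 0.3
d <- simulate_cohort(gastric_scenario(n = 1200), seed = 61)

# 1. is there a cured fraction at all?
km <- km_curve(d$time, d$event)
plateau_cure_fraction(km)
#> KM plateau cure-fraction estimate: 0.321
#> Last event at 120.536 months; 47 censored beyond it (sufficient follow-up)

# 2. classical fit
fit <- curefrail(survival::Surv(time, event) ~ chemotherapy + morphology +
                   metastasis, data = d, control = curefrail_control(seed = 1))
summary(fit)
#> Mixture cure rate frailty model — maximum likelihood fit
#>                         estimate     sd   lower   upper
#> cure_(Intercept)         -0.7901 0.1405 -1.0655 -0.5148
#> cure_chemotherapyyes      0.5867 0.1697  0.2541  0.9193
#> cure_morphologyneoplasm   0.9559 0.3396  0.2904  1.6214
#> cure_metastasisyes       -0.8823 0.1853 -1.2455 -0.5192
#> surv_chemotherapyyes     -0.3205 0.1364 -0.5878 -0.0533
#> surv_morphologyneoplasm  -0.8741 0.3274 -1.5159 -0.2323
#> surv_metastasisyes        0.2530 0.1275  0.0031  0.5028
#> shape                     0.8800 0.0537  0.7808  0.9917
#> scale                     0.2452 0.0256  0.1997  0.3010
#> theta                     1.7158 0.6461  0.8202  3.5893
#> log-likelihood: -2625.08  n = 1200

# cure odds ratio for chemotherapy (long-term survivors)
odds_ratio_summary(fit, "chemotherapyyes")
#> estimate    lower    upper
#> 1.798077 1.289339 2.507551

# 3. Bayesian fit and model comparison
bfit <- curefrail(survival::Surv(time, event) ~ chemotherapy + morphology +
                    metastasis, data = d, method = "bayes",
                  control = curefrail_control(seed = 1, n_chains = 2,
                                              n_iter = 10000, burn_in = 4000))
compare_ic(classical = fit, bayesian = bfit)
#>      classical bayesian
#> DIC   5250.159 5269.787
#> EAIC  5270.159 5282.670
#> EBIC  5321.060 5333.571
```

(The "classical" column uses the plug-in convention — deviance at the MLE
with `pd = 0` — so its DIC is a penalised-likelihood analogue, not a
posterior quantity; `information_criteria()` labels the convention.)

Interpretation: the plateau estimate (0.321) is the model-free cure-fraction
diagnosis; `cure_*` rows are incidence coefficients (their exponentials are
cure odds ratios — chemotherapy multiplies the odds of cure by ≈ 1.8 here),
`surv_*` rows are latency log hazard ratios among the uncured, and
shape/scale/theta are the Weibull baseline and frailty-variance (1/θ)
parameters. `run_pipeline()` chains these stages and writes the KM curve,
plateau report, all report tables and the posterior chains to a directory.

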