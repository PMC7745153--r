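# cudn

Model-based analysis of decision making under the threat of social
punishment. When a wrong choice can draw blame, people may make *better*
choices under uncertainty — not by becoming uniformly more deterministic,
but by selectively suppressing the component of decision noise that grows
with their estimation uncertainty. `cudn` implements the full behavioural
pipeline for studying this mechanism: task simulation, the CUDN
(control of uncertainty-induced decision noise) model family, per-subject
MAP fitting with Laplace model evidence, random-effects Bayesian model
selection, an ideal Bayesian observer benchmark, and the behavioural
statistics that summarize a cohort.

## The model

Agents face a 240-trial two-cue task with reciprocal correct probabilities
(p vs 1−p, reversing every 10–50 trials between the 0.2/0.3 and 0.7/0.8
ranges) and blockwise high (0.8/0.9) or low (0.1/0.2) conditional
probability of blame after a wrong choice. The CUDN model couples

- a 3-level binary hierarchical Gaussian filter tracking p(correct|cue),
  whose level-2 prediction variance σ̂₂⁽ᵏ⁾ is the trial's estimation
  uncertainty,
- a Rescorla–Wagner learner tracking the blame belief
  b⁽ᵏ⁾ = p(blame|wrong), updated only on wrong-choice trials, and
- a softmax response stage whose inverse temperature is modulated by both:

  log β⁽ᵏ⁾ = β₀ − (ζ − ν·b⁽ᵏ⁾)·σ̂₂⁽ᵏ⁾

ζ sets the degree of uncertainty-induced decision noise (UDN); ν sets how
strongly the blame belief suppresses it, in proportion to the current
uncertainty. The 16-model comparison space crosses four blame effects
(none, value, uncertainty-independent noise effect, interaction) with HGF
depth (2/3) and blame learning (learned/fixed).

## Worked example

```r
library(cudn)

# one synthetic session and its CUDN fit
sch <- generate_schedule(schedule_config(seed = 42))
ses <- simulate_session(sch, agent_params(), seed = 7)
mean(ses$choice == sch$good_cue)
#> [1] 0.6
fit <- fit_map(ses, cudn_spec(), n_restarts = 4, seed = 1)
round(fit$estimate, 3)
#>  beta0   zeta  omega  theta     nu  alpha
#>  0.798  0.534 -3.076  0.003  1.207  0.283
fit$log_evidence
#> [1] -146.2

# cohort-level behavioural contrasts
co <- simulate_cohort(20, seed = 11)
m  <- cohort_metrics(co)
contrast_high_low(m, "rt", test = "wilcoxon")
#> rt, high vs low blame (wilcoxon, n = 20)
#>   0.614 vs 0.591 (diff 0.023, 95% CI 0.013..0.033)
#>   statistic = 3.435, p = 0.0006356, effect size = 0.77

# ideal Bayesian observer benchmark
benchmark_good_choice(n_sessions = 100, seed = 3)
#> Ideal observer (greedy policy, hazard 0.0333): good choice 0.819 +/- 0.005 (100 sessions)
```

The fitted ν ≈ 1.2 recovers the simulated agent's positive blame-suppression
effect; the RT contrast shows the deliberation slowdown in high-blame
blocks; the observer benchmark is the performance ceiling of a
full-information hidden-Markov filter with a greedy policy (stochastic
policies — Thompson sampling, probability matching — are available and sit
substantially lower; see `benchmark_sensitivity()` and the methods
vignette).

Model comparison over a cohort:

```r
cf  <- fit_cohort(co$sessions, n_restarts = 3, seed = 2)   # 16 models
res <- bms(cf$evidence, seed = 3)                          # RFX-BMS
res$pep                                                    # protected EP
```

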