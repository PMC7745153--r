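---
title: "Modelling the control of uncertainty-induced decision noise under blame expectation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the control of uncertainty-induced decision noise under blame expectation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cudn)
```

# The task and the scientific question

`cudn` analyses behaviour in a probabilistic reversal learning task in which
wrong choices can be socially punished. On each of 240 trials the agent
chooses between two cues. Cue 1 yields a "correct" outcome with probability
$p$ and cue 2 with probability $1 - p$ (the contingency is *reciprocal*, so
observing either cue's outcome reveals the other's). Every 10–50 trials $p$
reverses between the $\{0.2, 0.3\}$ and $\{0.7, 0.8\}$ ranges. Independently,
in blocks of 20–40 trials, a wrong choice is punished by blame feedback with
high (0.8/0.9) or low (0.1/0.2) conditional probability, the block types
alternating. Mood is probed on a −3..3 scale every 8 trials (30 probes per
session).

The question the package operationalizes: when blame is likely, do agents
suppress the part of their decision noise that is driven by estimation
uncertainty? Choice stochasticity that grows with uncertainty produces random
exploration; in this task exploration has no informational value (both
outcomes are knowable), so suppressing it under threat is pure performance
optimization.

# The CUDN model family

## Perceptual stage

Two learning systems run in parallel.

**Cue–outcome learning (3-level binary HGF).** Level 1 is the binary outcome
$u^{(k)} \in \{0,1\}$ ("cue 1 was correct"), level 2 its logit-scale tendency
$x_2$, level 3 the log-volatility of $x_2$. Before outcome $k$ the model
predicts

$$\hat\mu_1^{(k)} = \mathrm{logistic}(\mu_2^{(k-1)}), \qquad
\hat\sigma_2^{(k)} = \sigma_2^{(k-1)} + \exp(\kappa \mu_3^{(k-1)} + \omega),$$

where $\hat\sigma_2^{(k)}$ is the trial's *estimation uncertainty*. After
observing $u^{(k)}$, with $\delta_1 = u^{(k)} - \hat\mu_1^{(k)}$:

$$\pi_2 = \frac{1}{\hat\sigma_2} + \hat\mu_1(1 - \hat\mu_1), \qquad
\mu_2 \leftarrow \mu_2 + \frac{\delta_1}{\pi_2}, \qquad
\sigma_2 \leftarrow \frac{1}{\pi_2},$$

and level 3 is updated from the volatility prediction error
$\delta_2 = (\sigma_2 + \Delta\mu_2^2)\,\hat\pi_2 - 1$ with
$w_2 = \exp(\kappa\mu_3 + \omega)\,\hat\pi_2$:

$$\pi_3 = \frac{1}{\sigma_3 + \vartheta} +
\tfrac{1}{2}\kappa^2 w_2\,(w_2 + (2w_2 - 1)\delta_2), \qquad
\mu_3 \leftarrow \mu_3 + \frac{\kappa w_2 \delta_2}{2\pi_3}, \qquad
\sigma_3 \leftarrow \frac{1}{\pi_3}.$$

This is the standard variational update set for the binary hierarchical
Gaussian filter; the 2-level variant freezes level 3 at its initial mean, so
the environment's volatility is the constant $\exp(\kappa\mu_{3,0} + \omega)$.
For fitting, $\kappa = 1$ and the initial states
($\mu_{2,0}=0$, $\mu_{3,0}=1$, $\sigma_{2,0}=\sigma_{3,0}=1$) are fixed —
the usual identifiability practice for one 240-trial session — while
$\omega$ and $\vartheta$ are free.

**Blame learning (Rescorla–Wagner).** The subjective conditional probability
of blame given a wrong choice, $b^{(k)} = p(\mathrm{blame}\,|\,w)^{(k)}$,
is updated by the delta rule on wrong-choice trials only (blame is
unobservable after correct choices):

$$b \leftarrow b + \alpha\,(\mathrm{blame}^{(k)} - b), \qquad b^{(0)} = 0.5.$$

The prediction error $\mathrm{blame}^{(k)} - b^{(k)}$ is the blame prediction
error (BPE). Both beliefs entering trial $k$'s decision are the pre-outcome
predictions; the package asserts the absence of look-ahead by a permutation
test on future feedback.

## Response stage

Choices follow a softmax over the cues' predicted correct probabilities
$(\hat\mu_1, 1 - \hat\mu_1)$ with a trial-wise inverse temperature. In the
CUDN (interaction) model

$$\log \beta^{(k)} = \beta_0 - \big(\zeta - \nu\, b^{(k)}\big)\,\hat\sigma_2^{(k)}.$$

$\zeta \ge 0$ is the degree of uncertainty-induced decision noise (UDN):
larger uncertainty lowers $\beta$ and randomizes choice. $\nu$ (sign-free) is
the degree to which the blame belief suppresses that effect, *in proportion
to the current uncertainty* — at $\nu b = \zeta$ the UDN is exactly
cancelled. The alternatives in the model space replace this interaction with

* an uncertainty-independent blame effect,
  $\log\beta = \beta_0 - \zeta\hat\sigma_2 + \nu b$;
* blame as a negative *value*: utility of cue $i$ is
  $\hat\mu_1(i) + \lambda\,(1-\hat\mu_1(i))\,b$ with $\lambda$ expected
  negative and $\log\beta = \beta_0 - \zeta\hat\sigma_2$;
* no blame effect at all.

Crossing the four blame effects with HGF depth (2/3 levels) and blame
learning (RW vs a fixed $b = 0.5$) gives the 16-model space
(`enumerate_model_space()`); the CUDN cell is
(interaction, 3 levels, RW). The `none` cells ignore the blame belief, so
their learning factor is behaviourally inert; they are retained to keep the
space a complete factorial.

# Fitting and model comparison

**MAP estimation.** Free parameters are estimated per subject by maximizing
log-likelihood plus log-prior in a transformed space (log for $\zeta$ and
$\vartheta$, logit for $\alpha$, identity otherwise) with Gaussian priors:
$\beta_0 \sim N(0,2)$, $\log\zeta \sim N(0,2)$, $\nu \sim N(0,2)$,
$\lambda \sim N(0,2)$, $\mathrm{logit}\,\alpha \sim N(0,1)$,
$\omega \sim N(-3,4)$, $\log\vartheta \sim N(-6,4)$. The optimizer is BFGS
with numerical gradients, relative tolerance $10^{-10}$, at most 500
iterations, and multiple restarts (first at the prior mean, the rest drawn
from the prior); on the fixtures used in the tests all restarts reach the
same optimum to within tolerance. Choice probabilities are floored at
$10^{-12}$ inside the likelihood; exponents of volatility terms are clipped
at $\pm 36$ and of $\log\beta$ at $\pm 350$ so the objective stays finite.

**Evidence.** The log model evidence is the Laplace approximation
$\log p(y\,|\,m) \approx \log p(y, \hat\theta) + \tfrac{d}{2}\log 2\pi -
\tfrac12 \log\det H$, with $H$ the negative Hessian of the log joint at the
MAP by central differences (step $10^{-4}$). If $H$ is not positive
definite, the package falls back to a BIC-style evidence
$\ell(\hat\theta) - \tfrac{d}{2}\log n$ with a warning.

**RFX-BMS equation sheet.** Treating each subject's generating model as a
draw from unknown population frequencies $r \sim \mathrm{Dir}(\alpha_0)$,
the variational posterior iterates

$$z_{nk} \propto \exp\!\big(\log p(y_n|m_k) + \psi(\alpha_k) -
\psi(\textstyle\sum_j \alpha_j)\big), \qquad
\alpha_k = \alpha_0 + \sum_n z_{nk},$$

with $\alpha_0 = 1$. Exceedance probabilities $\mathrm{EP}_k =
P(r_k = \max_j r_j)$ are computed by Monte-Carlo Dirichlet sampling
($10^6$ draws by default; the two-model case is cross-checked against the
Beta closed form $P(r_1 > \tfrac12)$). The Bayes omnibus risk compares the
alternative's variational free energy

$$F_1 = \sum_{nk} z_{nk} \log p(y_n|m_k) - \sum_{nk} z_{nk}\log z_{nk} +
\log C(\alpha_0 \mathbf 1) - \log C(\alpha), \qquad
C(a) = \frac{\Gamma(\sum_k a_k)}{\prod_k \Gamma(a_k)},$$

(the Dirichlet expectation terms cancel because $\alpha = \alpha_0 +
\sum_n z_n$) with the *exact* null evidence under equal frequencies,
$F_0 = \sum_n \log \frac{1}{K} \sum_k p(y_n|m_k)$, giving
$\mathrm{BOR} = 1/(1 + e^{F_1 - F_0})$ and the protected exceedance
probabilities $\mathrm{PEP} = \mathrm{EP}\,(1-\mathrm{BOR}) +
\mathrm{BOR}/K$.

# The ideal observer benchmark

The benchmark agent is a hidden-Markov filter that knows the generative
structure: latent states $s \in \{0.2, 0.3, 0.7, 0.8\}$ (cue 1's correct
probability), a per-trial hazard $h$ of jumping uniformly to one of the
opposite-side states (encoding the alternating-reversal design), and the
realized correct cue as its observation. The default hazard is $1/30$, the
reciprocal of the mean block length. The default policy is greedy (choose
cue 1 iff the predictive probability exceeds one half, ties uniform);
Thompson sampling on the side posterior and probability matching on the
predictive are provided as stochastic alternatives, and
`benchmark_sensitivity()` tabulates the good-choice proportion over hazards
and policies:

```{r sensitivity, eval = FALSE}
benchmark_sensitivity(hazards = c(1/50, 1/30, 1/15),
                      policies = c("greedy", "thompson", "matching"),
                      n_sessions = 100, seed = 1)
```

Two facts from this sweep matter for interpretation. The greedy benchmark is
almost flat in the hazard, and the *policy* dominates the result: greedy
sits far above the stochastic policies, which bracket a wide range. An
ideal-learner benchmark that lies close to human performance on this task
therefore implies a stochastic response stage whose noise level cannot be
reconstructed from the filter alone; the package keeps the fully specified
greedy filter as its default and treats the policy as an explicit knob
rather than silently calibrating a softmax temperature. `scripts/acceptance.R` recomputes the default benchmark from
scratch.

# The synthetic cohort generator

`simulate_cohort()` draws agents whose choices follow the CUDN generative
model, with per-subject parameters from `default_param_sampler()`:
$\beta_0 \sim N(1.5, 0.5^2)$, $\log\zeta \sim N(0, 0.4^2)$,
$\nu \sim N(1, 0.5^2)$ in the effect-present regime used by the recovery
studies, $\mathrm{logit}\,\alpha \sim N(-1.4, 0.5^2)$,
$\omega \sim N(-3, 0.5^2)$, $\log\vartheta \sim N(-6, 0.5^2)$. This regime
was chosen so that simulated cohorts perform in the human range of the task
(good-choice proportion around 0.65–0.70, accuracy near 0.58) while
expressing the blame effect. One root seed yields per-subject child seeds by
a fixed rule, so cohorts are bit-reproducible.

Two observables of the task are not part of the choice model and are
generated by documented stand-ins:

* **Response time**: $\mathrm{rt} = \exp(\mu_{rt} + \kappa_{rt} D + \epsilon)$
  seconds, $\epsilon \sim N(0, \sigma_{rt})$, with deliberation index
  $D = b^{(k)} \hat\sigma_2^{(k)}$ (defaults $\mu_{rt} = \log 0.55$,
  $\kappa_{rt} = 0.12$, $\sigma_{rt} = 0.25$). Expecting blame under
  uncertainty slows responses, giving the high-blame RT effect a generative
  counterpart the statistics stage can detect.
* **Mood**: on probe trials,
  $\mathrm{round}(\mathrm{clip}(m_0 - w_b b^{(k)} + w_o\,\bar c_8 +
  \epsilon, -3, 3))$ with $\bar c_8$ the correct rate over the last 8 trials
  (defaults $m_0 = 1.5$, $w_b = 2$, $w_o = 1$, $\epsilon \sim N(0, 0.5)$).
  The blame belief lowers mood by construction, so `mood_analysis()` has a
  recoverable target.

What the generator does *not* emulate: stimulus rendering and psychophysical
timing, sequential choice kernels (win-stay/lose-shift autocorrelation beyond
the model), attention lapses, and real between-subject heterogeneity beyond
the parameter distributions above. Passing recovery tests therefore show the
pipeline is self-consistent at the study's scale — not that real behaviour
is generated by this model.

# Numerical and design notes

* **Uncertainty timing.** On the logit scale the level-2 prediction variance
  $\hat\sigma_2$ has a *narrow* within-session range in this task and dips,
  rather than spikes, while beliefs cross 0.5 after a reversal (outcomes are
  most informative there, so precision gain is maximal). The uncertainty
  that is maximal just after reversals is the projection onto the outcome
  probability scale, $\approx (\hat\mu_1(1-\hat\mu_1))^2 \hat\sigma_2$,
  which the tests assert. The response model uses $\hat\sigma_2$ itself, as
  the model family defines.
* **Identifiability.** Because $\hat\sigma_2$ varies little within a
  session, $\beta_0$ and $\zeta$ trade off strongly, and the interaction
  ($\nu b \hat\sigma_2$) and additive ($\nu b$) blame effects are nearly
  collinear: a maximum-likelihood comparison of the true interaction model
  against the best-fitting additive model on cohorts simulated at the
  defaults yields on the order of 0.06 nats per subject of discriminating
  information. Rank-recovery of $\zeta$ and $\nu$ at 240 trials plateaus
  near 0.4–0.5 with stable optima, and the 16-model comparison separates the
  $\nu$-containing family clearly while ordering *within* the family only
  marginally. This limitation is intrinsic to the design size, and is
  consistent with the prior-sensitivity of the model selection that the
  susceptibility sweep (`prior_susceptibility()`) exposes.
* **Degenerate inputs.** Zero-variance paired contrasts return the exact
  null ($t = 0$, $p = 1$) or the certain alternative ($p = 0$) rather than
  failing; constant-mood subjects are excluded from the mood analysis with a
  message; conditions with no trials are flagged missing and excluded
  pairwise; non-positive HGF precisions raise an error naming parameter
  pathology, and the fitting objective treats them as rejection regions.
* **Problem sizes.** The shipped studies use 200 sessions for the observer
  benchmark, 30-subject cohorts for recovery, 150 agents for the
  direction checks, and 200–500 replicates for the calibration checks —
  sizes at which the Monte-Carlo error of each reported quantity is small
  relative to the effect being asserted.
* **Block structure choices.** Successive correct-probability blocks always
  flip the good cue (a reversal) with the magnitude re-drawn per block;
  blame blocks alternate high/low deterministically with random lengths;
  the final block of each kind may be truncated. Mood probes land every
  8th trial exactly.

# Reading results

`fit_cohort()` returns the subjects-by-models log evidence matrix; `bms()`
summarizes it as expected frequencies, EP, BOR and PEP; `cohort_metrics()`
plus `contrast_high_low()` reproduce the behavioural contrasts (paired t
for proportions, Wilcoxon for RT); `nu_performance_correlation()` relates
per-subject $\nu$ estimates to the high-minus-low enhancement with a 2-SD
trimmed sensitivity rerun; `reversal_curve()` gives the reversal-locked
learning curves with bootstrap bands. All statistics are computed by base R
(`t.test`, `wilcox.test`, `cor.test`, `lm`) on quantities the package
derives trial-by-trial.
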