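---
title: "Methods: life-course models of psychosocial adversity and epigenetic aging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: life-course models of psychosocial adversity and epigenetic aging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Psychosocial adversity — substance abuse by someone close, material
deprivation, physical or sexual abuse — recurs across the lifespan, and its
effect on biological aging may follow different temporal patterns. Life-course
epidemiology distinguishes four competing hypotheses: a **critical period**
(only one period matters), a **sensitive period** (both matter, one more), an
**accumulation** model (both matter equally), and a **pathway** model
(childhood adversity acts by raising the risk of adulthood adversity). This
package estimates the life-course effect of adversity on epigenetic age
acceleration (EAA) and identifies which hypothesis the data are most
compatible with.

Exposures are coded per period as three binary indicators (substance abuse by
someone close, material deprivation, pooled physical/sexual abuse) summed
into a cumulative score of 0–3. The outcome is a continuous EAA measure:
AgeAccelGrim (years) or DunedinPACE (years of biological aging per calendar
year).

## The model

The core outcome model is a simplex-weighted linear combination of the two
period exposures:

$$E(\mathrm{EAA}\mid \mathrm{Child},\mathrm{Adult}) \;=\; \beta_0 + \delta\,
\big(W_{c}\,\mathrm{Child} + W_{a}\,\mathrm{Adult}\big),
\qquad W_{c}+W_{a}=1,\; W_c \in [0,1].$$

$\delta$ is the life-course effect per unit weighted adversity; $W_c$ and
$W_a$ apportion it between periods. Constraining the weights to the simplex
encodes the *unidirectionality* assumption — both periods act in the
direction of the single signed effect $\delta$. The weight vector is compared
with five reference vectors $(W_c, W_a)$: critical childhood $(1,0)$,
critical adulthood $(0,1)$, accumulation $(0.5,0.5)$, sensitive childhood
$(0.67,0.33)$, sensitive adulthood $(0.33,0.67)$.

The model is fitted inside a marginal structural framework:

1. **IPTW.** Inverse-probability-of-treatment weights for the childhood
   exposure (given the baseline confounders: sex, age, parental education,
   nativity) and the adulthood exposure (given baseline confounders, the
   intermediate confounders — own education and household income — and the
   childhood exposure). Cumulative scores are modeled with multinomial
   logistic regression rather than proportional odds, which would add an
   ordinality assumption nothing in the design requires. Weights are
   stabilized by default (numerators: the marginal childhood distribution
   and the adulthood distribution given childhood), which controls weight
   variance without changing the estimand. The final analysis weight is the
   product of the total IPTW and the survey sampling weight.
2. **WFPBB.** The weighted sample is expanded into a synthetic target
   population by a weighted Pólya urn and an equal-size unit-weight sample
   is redrawn per replicate (default 200 replicates), so the Bayesian model
   can be fitted unweighted on each replicate.
3. **Posterior pooling.** Per-replicate posteriors are concatenated into one
   mixture posterior; posterior means, percentile 95% credible intervals,
   and $PP(\delta>0)$ (the fraction of pooled $\delta$ draws above zero) are
   read off the pooled draws.

### The verdict pipeline

The pathway hypothesis is tested first, by causal mediation: the randomized
interventional analogue of the natural indirect effect (rNIE) of childhood
adversity through adulthood adversity. Natural effects are unidentified here
because the mediator–outcome confounders (education, income) are themselves
affected by the exposure; the interventional analogues replace each
subject's mediator with a draw from its population distribution given
exposure. That distribution comes from a mediator model weighted by the
*childhood* IPTW times the sampling weight, which standardizes
$P(M=m\mid A=a)$ over the confounder distribution. The adulthood IPTW must
not enter the mediator model: its stabilization numerator
$P(A_2\mid A_1)$ would re-inject the observed, confounded
childhood–adulthood dependence, while an unstabilized or
marginally-stabilized version would flatten the causal dependence
entirely. The adulthood IPTW belongs in the outcome model, which
conditions on the mediator and uses the full final weight. With a weighted
outcome model $E[Y\mid A,M] = \theta_0 + \theta_1 A + \theta_2 M + \theta_3
AM$ (interaction on by default) and weighted mediator distribution
$P(M=m\mid A=a)$:

$$\mathrm{rNDE} = \sum_m \{E(Y\mid a,m) - E(Y\mid a^*,m)\}\,P(M=m\mid a^*),
\qquad
\mathrm{rNIE} = \sum_m E(Y\mid a,m)\,\{P(M=m\mid a)-P(M=m\mid a^*)\},$$

with $\mathrm{TE} = \mathrm{rNDE} + \mathrm{rNIE}$ exactly. The summation is
closed-form over the four mediator levels — no Monte-Carlo mediator draws
are needed. The default contrast is one unit of the childhood score
($a^*=0, a=1$). Confidence intervals are percentile bootstrap over subjects,
with the analysis weights re-estimated inside every resample so that their
sampling uncertainty propagates.

If the 95% rNIE interval excludes zero the verdict is **pathway**. Otherwise
the verdict is the reference vector minimizing the posterior-mean Euclidean
distance $ED = \sqrt{(W_c - r_c)^2 + (W_a - r_a)^2} = \sqrt{2}\,|W_c - r_c|$.
Both readings are always reported, so a pathway verdict can still be
inspected against the distance table.

## Priors, sampler, and numerical choices

The posterior is sampled by a Gibbs/Metropolis scheme:

- $(\beta_0, \delta)$: independent Normal$(0, 100^2)$ priors; the
  conditional posterior given $(w, \sigma^2)$ is bivariate normal and is
  sampled exactly.
- $\sigma^2$: Inverse-Gamma$(0.001, 0.001)$, weakly informative and exactly
  conjugate, so the scale update is a Gibbs draw. A half-normal prior on
  $\sigma$ was considered and rejected because it has no conjugate update in
  this blocking; at the sample sizes involved the two choices are
  numerically indistinguishable and the conjugate draw keeps the sampler
  exact against the closed-form oracle used in the tests.
- $w$ ($=W_c$): uniform on $[0,1]$ (Dirichlet$(1,1)$ on the weight pair),
  updated by random-walk Metropolis on $\mathrm{logit}(w)$ with the
  log-Jacobian $\log w(1-w)$; the step size adapts during warm-up toward a
  ~0.4 acceptance rate and is frozen afterwards.

Defaults are 1000 warm-up plus 1000 retained draws per replicate. All
likelihood quantities are computed from ten sufficient statistics of the
replicate ($n$, sums, cross-products), so one iteration costs the same at
$n = 100$ as at $n = 100{,}000$; 200 replicates of 2000 iterations take a
few seconds. Mixing is monitored by effective sample size (Geyer's initial
positive sequence); replicates with ESS below 50 raise a warning that is
aggregated, never silenced. When the effect is weak relative to the noise,
the $w$ posterior is close to its uniform prior and low ESS warnings for `w`
are expected — they indicate weak identification, not a sampler defect.

### WFPBB details

With weights rescaled to sum to the population size $N$, the urn starts
subject $i$ at mass $w_i - 1$ and each of the $N - n$ synthetic draws adds
mass $(N-n)/n$ to the drawn subject. The sequential urn is generated in one
shot through its Dirichlet-multinomial representation
($p \sim \mathrm{Dirichlet}\{(w_i-1)\,n/(N-n)\}$, counts
$\sim \mathrm{Multinomial}(N-n, p)$), which is exact and $O(n)$ per
replicate. Subjects with rescaled weight below one are floored at zero urn
mass (they still represent themselves). The replicate is then a simple
random sample of $n$ from the synthetic population, without replacement;
sampling with replacement is available as a flag.

The population size defaults to $\max\{\mathrm{round}(\sum w),\ 20n\}$. For
gross survey weights (each person representing $w_i$ people) the weight
total *is* the finite population size and the first term applies. For
weights normalized to unit mean — as this package's final analysis weights
typically are — the weight total equals the sample size, which would leave
no population to impute and silently discard the weighting; the 20-fold
floor keeps the Pólya posterior faithful to the relative weights, and the
replicate-mean identity $E[\bar{y}_{rep}] = \sum w_i y_i / \sum w_i$ (checked
by Monte Carlo in the tests) is invariant to the weight scale.

## The synthetic cohort generator

Restricted cohort data cannot ship with the package, so validation runs on
synthetic cohorts with known truth. Generation follows the assumed causal
ordering: baseline confounders → childhood adversity → intermediate
confounders → adulthood adversity → outcome. All exposure models are
logistic with intercepts calibrated in-sample so realized prevalences hit
their targets in expectation; each adulthood indicator depends on its
childhood counterpart through a configurable carryover log-odds (the pathway
mechanism). Sampling weights are log-normal with unit mean — strictly
positive and right-skewed like real survey weights.

Defaults emulate the motivating cohort of 970 Hispanic/Latino adults: 61.4%
female, 18.6% US-born, age 50.5 (SD 12.9) truncated to 23–80, parental and
own education above high school at 55.3%/63.1%, household income at or above
\$30,000 at 27.9%, childhood/adulthood material deprivation at 54.2%/52.0%,
an AgeAccelGrim-scale outcome (residual SD 3.8 years), and a life-course
truth of $\delta = 0.91$ years with an adulthood weight of 79%. Prevalences
not published for the remaining adversity types are set to plausible values
(childhood substance 35%, abuse 25%; adulthood substance 20%, abuse 10%,
reflecting the rarity of adult abuse). The DunedinPACE configuration
calibrates the intercept and residual SD in-sample to mean 1.08, SD 0.12.
Confounder effects default to moderate values (log-odds ~0.3 on exposures,
~0.5 outcome units on AgeAccelGrim) so that ignoring confounding visibly
biases naive estimates and the IPTW correction is genuinely exercised.

Two preset scenarios drive the validation suite. The **pathway** scenario
uses strong carryover (log-odds 2 per type), $\delta = 1$, childhood weight
0.3, unit residual SD. The **accumulation** scenario uses the same effect
and noise with equal weights and
severs *both* childhood-to-adulthood channels — the carryover and the
childhood effect on the intermediates — because the accumulation hypothesis
assumes independent exposure windows; leaving the intermediate channel open
would inject a small genuine indirect effect that belongs to neither
hypothesis cleanly. The unit residual SD is a power requirement, not a
convenience: separating the accumulation weight (0.5) from the
sensitive-period references (0.67/0.33) means resolving the period weight
to well within the 0.085 decision boundary, and at $n = 2000$,
$\delta = 1$ the weight's sampling SE is about 0.03 under a unit SD but
about 0.06 under twice that — a noise level at which no estimator can
classify the scenario reliably.

What the generator does not emulate: DNA-methylation measurement and the
construction of the epigenetic clocks themselves, the multistage survey
design behind real sampling weights, item-level missingness (the package
rejects missing values rather than imputing), and measurement error in
retrospectively reported childhood adversity. Passing tests therefore
demonstrate correctness of the estimation machinery under the assumed causal
structure, not robustness to those real-data features.

## Validation design

The test suite validates each stage against an independent oracle: hand
computations on a saturated one-confounder fixture for the IPTW, a
Monte-Carlo urn expectation and the Hájek mean identity for the WFPBB
(500 replicates on a 200-row sample), the noninformative conjugate
Bayesian linear regression closed form for the sampler with the weight
fixed (10,000 draws), the product-of-coefficients closed form for the
mediation (n = 10,000), and the algebraic identity
$ED = \sqrt{2}|w - r_c|$ for the distance. Frequentist behavior is checked
over repeated simulations: 20 cohorts of n = 2000 with 50 WFPBB replicates
× 1000 draws each for credible-interval coverage of a strong effect
($\delta = 1$, $w = 0.8$, $\sigma = 1$) and for calibration under the null,
and 20 cohorts per scenario (50 replicates × 500 draws, 100-resample
mediation bootstrap) for verdict stability. These sizes keep each block a
meaningful check at desk scale; they are the package's validation design,
not estimates anyone should reuse as study results.

## Known limitations

- Two periods only; extending to more periods requires a Dirichlet weight
  vector and a different Metropolis parameterization.
- The exposure–outcome link is linear in the weighted score; cumulative
  scores assume each adversity type contributes equally.
- Percentile credible intervals from the pooled mixture posterior have
  approximately nominal coverage by construction of the WFPBB but are not
  exact in small samples.
- The implied-weight comparison in the MSM cross-check is undefined when the
  period coefficients disagree in sign, and both the Bayesian and MSM weight
  estimates are unstable when the life-course effect is weak — agreement is
  only asserted (and only expected) under a strong signal.
- Positivity violations raise errors rather than being truncated away;
  truncation is available but deliberately opt-in.
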