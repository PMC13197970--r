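---
title: "Models and methods behind posticu"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind posticu}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(posticu)
```

posticu analyses 90-day care trajectories of ICU survivors discharged home:
who reconnects with primary care (PCP), who cycles through emergency
departments (ED) and readmissions, who dies early, and how much of the
difference in readmission risk between integrated (VA) and community (CCN)
discharge settings runs through early primary-care follow-up. The package
bundles three analysis engines — weekly state-sequence clustering,
competing-risk regression with marginal standardization, and Bayesian
counterfactual mediation — together with a seeded synthetic cohort generator,
because the administrative data such studies use cannot be redistributed.
Everything downstream operates on two tidy tables: one row per patient
(discharge covariates, facility, hospital type) and one row per dated care
event (`PCP`, `ED`, `READMIT` with an inpatient interval, `DEATH`).

## The synthetic cohort generator

The generator is first-class, tested code: it defines the study conditions
under which every other module is validated. It has two layers.

**Mediation layer.** Three linked Bernoulli outcomes are drawn per patient on
the logit scale, each with facility random intercepts (SD 0.15 by default):

* the mediator `M` — PCP visit as the *strictly first* post-discharge contact
  within 30 days, `logit P(M=1) = γ₀ + γ_A A + γ'C + u_f`;
* the outcome `Y` — any readmission within 90 days,
  `logit P(Y=1) = θ₀ + θ_A A + θ_M M + θ_{AM} A·M + θ'C + v_f`;
* death within 90 days, a third logistic model in `A` and covariates.

Here `A` is hospital type (VA = 1) and `C` standardized covariates. The
defaults (`sim_config()`) were calibrated once, by simulation, so that the
marginal rates sit near the published cohort's: 30-day first-contact PCP
follow-up about 15.6% (CCN) vs 20.5% (VA), 90-day readmission 23.9% vs
28.1%, 90-day death 7.2% vs 8.8%, and an embedded protective mediator effect
that is stronger for community patients (`θ_M = −0.25`, `θ_{AM} = +0.07` on
the log-odds scale). Because the generator draws `M` and `Y` from exactly the
two models the mediation module fits, the counterfactual estimands are known
in closed form given covariates; `true_mediation_effects()` averages them
over a fresh Monte-Carlo covariate draw and serves as the recovery oracle.

We deliberately did **not** implement the mediator as a hazard multiplier
inside a week-by-week event process with a latent class drawn first from
covariates alone. Under that construction the latent class is an
exposure-induced confounder of the mediator-outcome relation, so the
two-model natural-effects estimand no longer equals the generator's own
counterfactual truth, and recovery tests could only be passed by accident.
The two-layer design embeds the hospital-type → PCP → readmission structure
exactly as the downstream analyses assume, which is what the generator is
for.

**Trajectory layer.** A latent class — `delta`, `omicron`, `gamma`,
`epsilon`, `sigma` — is drawn from a multinomial logit on covariates,
hospital type and the realized `(death, Y, M)` indicators; `delta` is
structurally restricted to decedents. Class intercepts are calibrated so the
marginal shares reproduce the published five-cluster mixture
(5.9 / 5.0 / 7.8 / 7.9 / 73.4%). The class then shapes the event history:

* `delta` — early death (weekly geometric timing, median around day 20),
  minimal outpatient contact;
* `omicron` — recurrent readmission: three to four episodes of about eight
  days each;
* `gamma` — recurrent emergent care: four to six ED visits plus a short
  readmission;
* `epsilon` — sustained engagement: five to seven PCP-visit weeks;
* `sigma` — the large quiet majority with at most a stray visit.

Event placement always honours the drawn `M`, `Y` and death indicators
(acute events never precede a mediator PCP visit; a readmission episode is
always placed when `Y = 1`; nothing happens after the death day), so the
outcome codings recover the mediation layer exactly. Visit counts use
low-dispersion base-plus-binomial distributions rather than Poisson, and the
per-class intensities are deliberately denser than the published cluster
profiles: with 13-week sequences and a 73% quiet class, archetypes with only
one or two marked weeks are not separable by any distance on state
sequences, and the published study's cluster structure could not be
recovered at desk scale. What is anchored to the publication is the set of
shares, the death structure (the early-death class is uniformly fatal,
median survival about three weeks; other deaths are late), and the ordering
of intensities across classes — not the exact visit medians. Readmission
durations are near-deterministic around a per-class mean, since no
post-discharge length-of-stay model is reported for such cohorts.

## Weekly state sequences and clustering

Week `w` covers days `7(w−1)+1 … 7w`; day 0 is the discharge day and belongs
to no week. Each of the 13 weeks takes the highest-acuity state observed in
it, over the ordered alphabet `HOME < PCP < ED < READMIT < DEAD`; weeks
overlapped by an inpatient interval are `READMIT` even without a new
admission, and death is absorbing. Events past day 91 are truncated.

Dissimilarity is the longest-common-subsequence metric
`d(a,b) = |a| + |b| − 2·LCS(a,b)`, computed by dynamic programming in C++
over the deduplicated set of distinct sequences, each carrying its
multiplicity as a frequency weight. This is the standard LCS distance: a
true metric on equal-length sequences, cheap on mostly-quiet sequences, and
sensitive to both which states occur and how many weeks they occupy.

Clustering is frequency-weighted partitioning around medoids: greedy BUILD
initialization followed by steepest-descent SWAP on the weighted objective
`Σ w_i d(i, medoid(i))`, with ties always resolved to the lowest index. On
instances with at most 100 unique sequences, twenty seeded random restarts
are added; SWAP alone can stall in a local optimum on tiny instances
(observed on 2 of 60 random test instances), and at that scale the restarts
make the solution exhaustively optimal in practice while costing nothing.
At cohort scale BUILD is stable and no restarts are used. The number of
clusters is chosen by the weighted average silhouette width over k = 2…8
(an `override_k` argument allows an interpretability-based override).
Silhouette uses replication semantics — a unique sequence of weight w
behaves exactly like w identical rows, with `a(i)` denominated by `W_C − 1`
— so weighting a sequence and replicating it are interchangeable; true
singleton clusters get s = 0.

Cluster description follows three summaries: a per-cluster profile table
(median age, VA share, comorbidity, outcome proportions, hospital-free
days), a weekly state-density table (the tabular analogue of a
state-density plot), and the overrepresentation index
`OI(g,c) = (n_gc/n_c)/(n_g/N)`, optionally within a stratum such as a DRG
category. The cluster-share-weighted mean of the global OI is exactly 1 for
every group, which the tests assert as an algebraic identity.

## Competing risks and standardized risks

Each outcome is coded with its own competing events: for first-contact PCP
follow-up, an acute first contact (ED or readmission) or prior death
competes; for ED and readmission, prior death competes; death has no
competing event. Everyone else is administratively censored at the horizon.
Ties on the first-contact day are resolved against PCP (the visit must be
strictly first).

The Fine-Gray subdistribution-hazard model is fit by Newton-Raphson with
step-halving on the IPCW-weighted partial likelihood: subjects with a
competing event remain in the risk set after their event time with weight
`Ĝ(t−)/Ĝ(T_i−)`, where `Ĝ` is the Kaplan-Meier of the censoring
distribution evaluated at left limits (the convention that matches the
established reference implementation to six decimals on censored test
data). Ties are handled by Breslow's method. The score and information are
accumulated in a single ascending sweep in C++ (suffix sums as
total-minus-prefix), so a fit costs O(n·p²) per iteration and the
200-replication calibration checks run in seconds. Convergence is declared
at gradient max-norm below 1e−8, or when a full step no longer moves the
iterate (the numerical floor of the surface); the log-likelihood is
non-decreasing across accepted steps. Standard errors are model-based and
facility-clustered sandwich (cluster sums of per-subject score residuals;
the correction for estimating Ĝ is omitted, as is standard practice — with
purely administrative censoring it is exactly zero). Cause-specific Cox
models (competing events censored) are delegated to the survival package as
the secondary, etiologic analysis.

Cumulative incidence is `F₁(t|x) = 1 − exp(−H₁₀(t)·e^{x'β})` with the
Breslow baseline. Marginal standardization (g-computation) averages each
patient's predicted incidence under exposure set to VA and to community;
risks are reported in percent with risk differences and ratios, and
percentile bootstrap intervals from 200 model refits by default (patient
resampling; facility cluster bootstrap as a flag). A β = 0 fit reproduces
the Aalen-Johansen estimator within 0.005 at n = 10,000, which the
acceptance suite checks against the survival package's nonparametric
estimate. A toggle drops the ICU/hospital length-of-stay covariates, which
may sit on the causal pathway, as a sensitivity analysis.

## Bayesian mediation

The mediator model (30-day first-contact PCP follow-up) and outcome model
(90-day readmission, with a hospital-type-by-PCP interaction) are Bernoulli
regressions with logit link and facility random intercepts. Priors are
normal(0, 2.5) on standardized covariates (normal(0, 5) intercepts) and
half-normal(1) on the facility SD. Since the two likelihoods share no
parameters, the joint posterior factorizes; the two models are sampled
independently, which is exactly the "joint but uncorrelated" structure. The
models share the same facility-intercept structure but not the intercept
values; whether the published analysis shared them across models is
ambiguous, and sharing none is the conservative reading.

Sampling uses a Pólya-Gamma data-augmentation Gibbs sampler written in C++:
`ω_i ~ PG(1, η_i)` makes the conditional for all coefficients (fixed effects
and facility intercepts jointly) Gaussian, and the facility SD is updated by
slice sampling under its half-normal prior. The PG(1, z) draws use the
alternating-series rejection method, driven by R's RNG so chains are
reproducible under `set.seed()`. This conjugate sampler mixes well for
Bernoulli-logit models of this size — four chains of 1,000 warmup + 1,000
kept draws run in well under a minute at n = 20,000 — and is cross-checked
in the test suite against an independent MCMC engine (JAGS) on a small
fixture. Convergence is summarized by split-half R-hat and
autocorrelation-based effective sample sizes (thresholds 1.01 and 400,
configurable); posterior-predictive mean event rates are compared with the
observed rates.

Natural effects are computed by applying each posterior draw to the four
counterfactual exposure-mediator scenarios, averaging over patients with
their own facility-intercept draws:
`p(a,a′) = mean_i [ y_i(a,0) + m_i(a′)·(y_i(a,1) − y_i(a,0)) ]`.
That algebraically equivalent "mixture as base plus mediator shift" form is
used deliberately so that a structurally null mediator pathway produces
indirect effects that are exactly zero, not zero up to rounding. Reported
per draw, in percentage points: PNDE = p(1,0)−p(0,0), TNDE = p(1,1)−p(0,1),
community- and VA-indexed indirect effects NIE_CCN = p(0,1)−p(0,0) and
NIE_VA = p(1,1)−p(1,0), TE = p(1,1)−p(0,0), the mediator-setting contrasts
Δ_a, and the interaction contrast Δ₀ − Δ₁. The decompositions
TE = PNDE + NIE_VA and TE = TNDE + NIE_CCN hold exactly per draw. One
caution: with a logit link, removing the interaction term does *not* force
the two indirect effects to coincide on the risk scale — the exposure's
direct shift still enters through the nonlinearity — so the sensitivity
suite checks sign agreement and the exact equality that does hold once the
direct shift is removed.

`sensitivity_suite()` re-runs the decomposition without the interaction,
without the length-of-stay covariates, and with widened (normal(0, 10))
priors.

## Problem sizes, tolerances and reproducibility

Default analysis problem sizes were chosen to make every validation run
routine on a single core: class-share checks at n = 50,000; Fine-Gray
recovery at n = 10,000 with null-calibration over 200 replications at
n = 5,000; mediation recovery over 20 replications at n = 20,000 with
2 × (200 + 350) MCMC iterations; cluster-number recovery over 20 cohorts of
n = 5,000. The distance matrix is quadratic in the number of *unique*
sequences (roughly 1,100–1,500 at n = 5,000), which is what bounds the
clustering cost. All randomness flows through explicit seeds: the generator
takes one, PAM restarts take one, chains use `seed·1000 + chain`, and
`run_pipeline()` records every stage seed plus a configuration hash in
`run_log.yaml`.

What passing tests do and do not show: the generator emulates the tabular
structure, marginal rates, mixture geometry and mediation structure of a
real post-ICU cohort, but its covariates are mutually independent given
hospital type, its event counts are low-dispersion by design, urgent-care
visits are folded into ED, skilled-nursing and hospice pathways are absent,
and the mediation layer is, by construction, correctly specified for the
models fit here. Recovery under these conditions validates the machinery —
codings, likelihoods, samplers, counterfactual algebra — not the substantive
conclusions one would draw from real administrative data, where confounding,
measurement error and model misspecification remain live concerns.
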