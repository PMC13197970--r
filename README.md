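# posticu

Care-trajectory analysis for ICU survivors discharged home. After critical
illness, the 90 days following discharge decide a great deal: whether a
patient reconnects with primary care (PCP), cycles through emergency
departments (ED) and readmissions, or dies early — and health systems with
integrated primary care (such as VA medical centers) may shape those
trajectories differently from community hospitals. `posticu` is an R package
for biostatisticians and health-services researchers who want to run that
full analysis on patient-level discharge and event tables:

* **Weekly state sequences and clustering.** Each patient's 13 post-discharge
  weeks are coded over the acuity-ranked alphabet
  `HOME < PCP < ED < READMIT < DEAD` (death absorbing; the highest-acuity
  event defines a week). Dissimilarity is the longest-common-subsequence
  metric `d(a,b) = |a| + |b| − 2·LCS(a,b)`; distinct sequences are
  deduplicated with frequency weights and clustered by weighted partitioning
  around medoids (BUILD + steepest SWAP), with the number of clusters chosen
  by the weighted average silhouette width. Clusters are profiled with
  outcome tables, weekly state densities, hospital-free days, and the
  overrepresentation index `OI(g,c) = (n_gc/n_c)/(n_g/N)`.
* **Competing risks.** For each outcome (first-contact PCP follow-up, ED use,
  readmission, death) a Fine-Gray subdistribution-hazard model is fit by
  Newton–Raphson on the IPCW-weighted partial likelihood (competing-event
  subjects stay in the risk set with weight `Ĝ(t−)/Ĝ(T_i−)`), with Breslow
  ties, facility-clustered sandwich standard errors, and cause-specific Cox
  models as the secondary analysis. Marginal standardization (g-computation)
  converts fits into adjusted absolute risks, risk differences and risk
  ratios at 30 and 90 days with percentile-bootstrap intervals.
* **Bayesian mediation.** Two linked Bernoulli-logit models — 30-day
  first-contact PCP follow-up (mediator) and 90-day readmission (outcome,
  with a hospital-type × PCP interaction) — with facility random intercepts,
  sampled by a Pólya-Gamma Gibbs sampler. Posterior draws are pushed through
  the four counterfactual exposure–mediator scenarios to give the natural
  direct and indirect effects (community- and VA-indexed), the total effect,
  and the interaction contrast, with the decompositions
  `TE = PNDE + NIE_VA = TNDE + NIE_CCN` holding exactly per draw.
* **A seeded synthetic cohort generator.** The administrative data such
  studies use cannot be redistributed, so `generate_cohort()` draws cohorts
  with the same tabular schema, a five-class latent trajectory mixture, and
  an embedded hospital-type → PCP → readmission mediation structure whose
  ground-truth counterfactual effects `true_mediation_effects()` computes
  exactly. Every downstream module is validated against it.

All user-facing functions take tidy tables (one row per patient; one row per
dated event) and return tibbles; results have `tidy()`/`glance()` methods and
`autoplot()`/`plot_*()` graphics.

## Worked example

```r
library(posticu)
library(dplyr)

cohort <- generate_cohort(sim_config(n_patients = 4000), seed = 1)

# 1. trajectory clustering
sq <- build_state_sequences(cohort$events, cohort$patients)
dm <- sequence_distance_matrix(sq)
ks <- select_k(dm, k_range = 2:8)
ks
#> Cluster-number selection: best k = 5 by average silhouette
#>       k avg_silhouette
#>   1   2          0.715
#>   ...
#>   4   5          0.739   <- selected
lab <- cluster_assignments(ks$solutions$k5, dm)
cluster_profile(lab, cohort$patients, cohort$events) |>
  select(cluster, n, pcp90, ed90, readmit90, death90, median_hospital_free_days)
#>   cluster     n pcp90  ed90 readmit90 death90 median_hospital_free_days
#> 1       1  2976 0.192 0.164     0.153  0.0208                        90
#> 2       2   248 0.161 0.427     0.266  1.0000                        12
#> 3       3   319 1.000 0.078     0.031  0.0125                        90
#> 4       4   286 0.206 1.000     0.930  0.0245                        85
#> 5       5   171 0.211 0.199     1.000  0.0468                        64
```

The five recovered clusters are the five simulated archetypes: a large quiet
majority (cluster 1), an early-death group with a median of only 12
hospital-free days (2), a primary-care-engaged group (3), a recurrent
emergent-care group (4), and a recurrent-readmission group (5).

```r
# 2. adjusted risks for first-contact PCP follow-up
cd <- prepare_competing_data(cohort$events, cohort$patients, "pcp_first")
fg <- fine_gray_fit(cd)
tidy(fg) |> filter(term == "hospital_type")
#>   term          estimate std.error  shr conf.low conf.high
#> 1 hospital_type    0.207    0.0840 1.23     1.04      1.45
marginal_standardization(fg, t_set = c(30, 90), n_boot = 50, seed = 1) |>
  select(t, risk_va, risk_ccn, rd, rd_lo, rd_hi)
#>    t risk_va risk_ccn   rd rd_lo rd_hi
#> 1 30    18.3     15.2 3.14 0.409  5.21
#> 2 90    25.5     21.3 4.20 0.551  6.93
```

VA discharge carries a subdistribution hazard ratio of 1.23 for PCP-first
follow-up here; standardized over the cohort that is an absolute +3.1
percentage points at 30 days (bootstrap 95% CI 0.4–5.2).

```r
# 3. Bayesian mediation of readmission through early PCP follow-up
med <- fit_mediation(cohort$events, cohort$patients,
                     mediation_spec(chains = 2, warmup = 200, draws = 300),
                     seed = 1)
med
#> Bayesian mediation natural-effect decomposition (percentage points)
#>   effect                 mean      lo      hi
#> 1 pnde                  5.86    2.68   9.24
#> 3 nie_ccn              -0.359  -0.690 -0.098
#> 4 nie_va               -0.277  -0.670 -0.006
#> 5 te                    5.59    2.49   8.88
#> 8 interaction_contrast -1.70   -8.27   4.75
```

At this sample size the direct effect of discharge setting on 90-day
readmission (+5.9 pp) dwarfs the protective indirect effects through early
primary care (about −0.3 pp each): early follow-up helps, but explains
little of the between-system difference — the qualitative pattern the
machinery is designed to quantify.

`run_pipeline(run_config(...))` chains all stages
(simulate → sequences → cluster → risks → mediate → report) and writes CSV
artifacts plus a seed-stamped `run_log.yaml`; `inst/cli/posticu.R` exposes
the same stages as shell verbs.

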