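# cdrhythms

Circadian rhythm analysis of telephone call detail records (CDRs),
aimed at digital-phenotyping studies of social activity — in particular
cohorts of older adults whose daily calling routine is itself a health
signal.

Given one year of per-person call records (ego, alter, start time,
direction, duration, answered flag) plus a contact directory mapping
alters to social categories, the package estimates:

- **Daily rhythms** — the hourly call-fraction profile
  `f(t) = n(t) / Σ_u n(u)` over the 24 hours of the day, per ego and
  direction, and at the aggregate level.
- **Persistence** — with the window split into three 4-month periods
  T1–T3, the self-distance `D_self = √JSD(P_i^T, P_i^{T+1})` between an
  ego's successive rhythms is compared with the reference distance
  `D_ref = √JSD(P_i^T, P_j^T)` to every other ego in the same period
  (Jensen–Shannon divergence in base 2, so `√JSD ∈ [0, 1]`); the rhythm
  is persistent iff `⟨D_self⟩ / ⟨D_ref⟩ < 1`. An L2 metric variant and a
  Kolmogorov–Smirnov confirmation with Holm–Šidák correction are
  included.
- **Synchronization** — per ego and period, a two-sample KS test of
  outgoing vs incoming call times under the null that both directions
  follow the same daily law, plus the 12-month out-vs-in √JSD.
- **Alter specificity** — within six-hour bins (night/morning/afternoon/
  evening), the Shannon entropy of the ego's alter distribution relative
  to a null that shuffles call times within two-week blocks (preserving
  per-alter call counts exactly); plus top-2-alter call fractions and
  duration-by-category profiles.

Because CDR datasets of this kind are private, the package also ships a
seeded synthetic generator (`simulate_calls()`,
`simulate_reference_cohort()`) producing cohorts with known ground truth:
bimodal daily profiles, per-ego chronotypes, planted drift or
desynchronization, evening-concentrated alter preference, and
category-dependent durations.

## Worked example

```r
library(cdrhythms)

sim  <- simulate_reference_cohort(seed = 42)   # 21 egos, 12 months
prep <- preprocess_cdr(sim$dataset)            # window, answered, active egos
prep$summary_after
#>   direction n_egos total_calls    q1 median    q3
#> 1 outgoing      21       18772   630    704  1302
#> 2 incoming      21       15096   518    642   895

pers <- run_persistence(prep$dataset, prep$partition, "outgoing")
pers
#> <persistence_result> outgoing / sqrt_jsd: 21/21 egos persistent; KS family size 42
head(pers$results[, c("ego_id", "mean_d_self", "mean_d_ref", "persistent")], 4)
#>   ego_id mean_d_self mean_d_ref persistent
#> 1 ego01        0.115      0.355 TRUE
#> 2 ego02        0.233      0.437 TRUE
#> 3 ego03        0.138      0.380 TRUE
#> 4 ego04        0.179      0.504 TRUE

run_synchronization(prep$dataset, prep$partition)
#> <sync_result> 21/21 egos synchronized (family size 63, alpha 0.05)

ent <- entropy_profile(prep$dataset, prep$partition,
                       iterations = 200, seed = 7)
aggregate(h_rel ~ bin, ent[!is.na(ent$h_rel), ], mean)
#>         bin     h_rel
#> 1 afternoon 1.0895719
#> 2   evening 0.8260890
#> 3   morning 1.0737273
#> 4     night 0.8441554
```

Reading the numbers: every ego's mean self-distance (≈ 0.1–0.25) sits
well below its reference distance (≈ 0.35–0.5), so all rhythms are
persistent; every adjusted out-vs-in KS p-value exceeds 0.05, so placing
and receiving calls follow the same daily law; and the relative entropy
dips below 1 in the evening and night — calls at those hours concentrate
on specific alters (here, the generator's planted top-2 evening
preference), while the morning and afternoon alter mix looks
time-random.

The full pipeline, writing every stage's tables plus run metadata to a
directory, is:

```r
run_pipeline("calls.csv", "contacts.csv", "report/",
             iterations = 1000, seed = 1)
```

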