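---
title: "Circadian rhythms of telephone activity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circadian rhythms of telephone activity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdrhythms)
```

## The problem

Call detail records (CDRs) — one row per telephone call with the caller,
the contact (the *alter*), the start time, the direction, and the duration
— are a passive, unobtrusive trace of a person's social day. For older
adults in particular, the daily organization of social activity carries
health-relevant signal: a stable, synchronized social day reflects an
intact circadian routine, while drift or desynchronization can accompany
sleep disruption, isolation, or depression. `cdrhythms` turns a year of
CDRs per person (the *ego*) into four kinds of evidence:

1. **Daily rhythms** — the fraction of an ego's calls in each of the 24
   hours of the day.
2. **Persistence** — whether an ego's rhythm is more similar to its own
   rhythm a few months later than to other people's rhythms.
3. **Synchronization** — whether the ego places and receives calls
   according to the same daily law.
4. **Alter specificity** — whether particular times of day are reserved
   for particular contacts, beyond what a time-randomized null explains.

## Rhythm estimation

Time is coarse-grained into 24 one-hour slots (half-open, slot 0 =
midnight to 1 AM, local wall-clock taken at face value). For any stream of
calls the rhythm is the call-fraction vector

$$f(t) = \frac{n(t)}{\sum_{u=0}^{23} n(u)}, \qquad t = 0, \dots, 23,$$

where $n(t)$ counts calls in slot $t$. The estimator is computed at the
aggregate level (all egos pooled; by construction the count-weighted mean
of the ego rhythms) and per ego, per direction, and per period. A stream
with no calls yields an *empty* rhythm that propagates as missing — never
as a vector of zeros, which would masquerade as a flat rhythm. For
heat-map display, rhythms are unity-normalized to $(p - \min p) / (\max p
- \min p)$; a constant rhythm has no shape to rescale (the formula is
0/0), so it maps to zeros and carries a `constant` flag.

## Persistence

The 12-month window is split into three successive 4-month periods T1–T3
(day-aligned; when the day count is not divisible by three, the earlier
periods take the extra day). For each ego $i$ with per-period rhythms
$P_i^{T}$:

- **Self-distance** $D_{\text{self}} = \sqrt{\mathrm{JSD}(P_i^T,
  P_i^{T+1})}$ over the two successive pairs, averaged over the pairs.
- **Reference distance** $D_{\text{ref}} = \sqrt{\mathrm{JSD}(P_i^T,
  P_j^T)}$ against every other ego $j$ in the same period, averaged over
  all (other ego, period) combinations — 60 values in a 21-ego,
  three-period cohort.
- The rhythm is **persistent** iff $\langle D_{\text{self}} \rangle /
  \langle D_{\text{ref}} \rangle < 1$ (strict).

The Jensen–Shannon divergence uses base-2 logarithms with $0 \log 0 := 0$,
so $\mathrm{JSD} \in [0, 1]$ and its square root — a true metric — shares
that range; the bounded scale is what makes cohort averages around
0.2–0.4 interpretable. An L2 (Euclidean) distance is available as an
alternative metric and, on stationary synthetic cohorts, yields the same
verdict for ≥ 90 % of egos.

Two conventions deserve a note. The mean self-distance is taken over the
$N_T - 1 = 2$ successive pairs rather than the $N_T = 3$ periods; dividing
the same pair sum by the period count would only shrink every ego's value
by the same factor 2/3 and cannot change a persistence flag, but the
pair-count mean is the one that estimates "the average distance between
successive rhythms". `d_self(denominator = "periods")` exposes the
alternative. Egos with an empty per-period rhythm are excluded with a
logged reason rather than zero-filled: a zero-filled period would produce
a spuriously large self-distance.

Persistence is confirmed nonparametrically: for each ego and each pair of
successive periods, a two-sample Kolmogorov–Smirnov comparison of the raw
call times-of-day (fractional hours, which mitigates the heavy ties that
integer hour bins would create; a switch allows integer hours). The
family of 42 tests (21 egos × 2 pairs) is adjusted with the Holm–Šidák
step-down procedure, $p_{(i)}^{\text{adj}} = 1 - (1 - p_{(i)})^{m - i +
1}$ with a running maximum; `stats::p.adjust` offers Holm–Bonferroni but
not this variant, so it is implemented directly and oracle-tested.

## Synchronization

Per ego and per period, a KS comparison of outgoing versus incoming
times-of-day under the null that both directions follow the same law. The
family is all egos × periods (63 tests in the standard cohort), adjusted
jointly; an ego is *synchronized* when every adjusted p-value exceeds
0.05. Because the Methods-level family (63) and a successive-pairs
reading (42) are both defensible, the run metadata records both family
sizes rather than silently resolving the ambiguity. The 12-month
out-vs-in sqrt-JSD per ego summarizes the effect size behind the tests,
and a merged-direction persistence run shows whether the direction-free
rhythm persists.

## Alter specificity

Within each six-hour bin of the social day — night [00–06), morning
[06–12), afternoon [12–18), evening [18–24) — the **origin entropy** is
the base-2 Shannon entropy of the distribution of the ego's calls over
its alters. The **reference entropy** is the same quantity after
destroying any alter–time association: within each consecutive 14-day
block (anchored at the window start; a short trailing block is shuffled
as-is), the call timestamps of the ego × direction stream are randomly
permuted across the block's records. This permutation-based null
preserves exactly the timestamp multiset, the per-alter call counts, and
the total call count — only the pairing of alters to times is random.
Averaging the origin entropy over 1000 shuffle replicates gives
$\langle H_{\text{ref}} \rangle$, and the **relative entropy**
$H_{\text{rel}} = H_{\text{orig}} / \langle H_{\text{ref}} \rangle$ tends
to 0 when calls at that time of day concentrate on specific alters and to
1 when the alter mix is time-independent. When the reference entropy is
numerically zero (a single alter), the ratio is undefined and reported
missing. Cells with fewer than 5 calls are flagged `low_support`:
nocturnal bins are typically too sparse for the cohort mean to be
meaningful. Shuffling is per direction, for symmetry with every other
analysis in the package.

Complementary descriptive views: the per-bin fraction of calls involving
the ego's two most-contacted alters (ranked by call count over the full
window, ties broken by total duration then alter ID), and mean call
duration per social category per bin, with uncategorized alters assigned
to `other`.

## Preprocessing

The pipeline order is fixed: **window selection → unanswered-call removal
→ activity filter**. The 12-month analysis window is the day-aligned
interval during which the most egos were actively participating; an ego
counts for a candidate window only if it has at least one call in every
calendar month of it, so partially enrolled egos do not drag the window
onto their silent months. Candidate starts are anchored at observed call
days and ties break to the earliest start. Unanswered incoming calls say
nothing about when the ego chooses to communicate and are dropped.
"Active throughout" is operationalized as ≥ 1 outgoing **and** ≥ 1
incoming call in each of the three periods — an ego failing this would
have an undefined per-period distribution somewhere in the analysis; a
switch relaxes the rule to either direction. Whether the original filter
was per-period or per-month is not decidable from the narrative; the
per-period reading matches the T1–T3 framing and is the default. Cohort
summaries use type-7 (linear interpolation) quantiles.

## The synthetic generator

Real CDRs of this kind are private, so the package ships a generator
whose defaults *are* the study conditions the analysis expects, with
ground-truth labels for every property the analysis estimates:

- **Volume.** Per-ego daily rates drawn log-normally so that yearly
  totals have medians near 710 outgoing and 800 incoming calls
  (`rate_sdlog = 0.45` spreads the quartiles roughly 1.8-fold).
- **Shape.** A cohort-level bimodal profile (wrapped-Gaussian bumps at 10
  AM and 6 PM over a 0.08 baseline, an afternoon trough at 2 PM) with
  per-ego chronotype variation: peak positions jittered with SD 2 h,
  amplitudes 0.7–1.3, widths ±25 %. The jitter is essential, not
  cosmetic: real cohorts show acrophases from morning to night, and a
  perfectly homogeneous cohort would make the cross-ego reference
  distance collapse onto the self-distance, leaving persistence a coin
  flip. Optionally, leading egos are made nocturnal (outgoing peak at 2
  AM) to emulate night-owl cases.
- **Sampling.** Call times come from an inhomogeneous Poisson process,
  thinned against the piecewise-constant hourly intensity — exact for
  this intensity class and trivially verifiable. Day-to-day rate is
  homogeneous (no weekday/weekend structure; the analysis aggregates all
  days anyway).
- **Drift and desynchronization.** Drift rotates the profile circularly
  by a per-ego offset, cumulatively across periods — volume is conserved
  and only shape changes, isolating exactly what persistence measures.
  Desynchronization rotates the incoming profile against the outgoing
  one.
- **Alters.** Eight alters per ego with Zipf (1/rank) preference; in the
  evening and night bins the top-2 weights are multiplied by
  `evening_concentration` (default 3), planting the known
  alter-specificity pattern. Categories cycle family/friend for the top
  alters, then acquaintance/health-professional/other.
- **Durations.** Log-normal, with per-category log-locations (family
  highest, health professionals lowest) and a +0.03/hour log-slope, so
  durations rise through the day and close contacts get longer calls.
- **Unanswered calls.** Incoming calls are unanswered with probability
  0.1; outgoing calls are always "answered".
- **Silent egos.** `n_silent` egos receive one completely silent period,
  exercising the 26 → 21 activity-filter narrative by construction.

Everything flows from one seed (egos generated in roster order), so the
same config is byte-reproducible. What the generator does **not**
emulate: burstiness and correlated inter-event times, weekly or seasonal
structure, network turnover, or alter sets shared between egos. Passing
tests therefore demonstrate that the estimators recover planted structure
under Poisson sampling at realistic volumes — not that real elderly CDRs
contain such structure.

## Numerical choices and problem sizes

- Probability inputs to the divergence are validated to sum to 1 within
  1e-8; the JSD is clamped to [0, 1] against floating-point noise at the
  bounds.
- KS p-values are asymptotic (two-sided); with ~80–500 calls per sample
  the asymptotic approximation is adequate and exact-with-ties is
  unavailable anyway.
- The shuffle engine permutes period×bin labels within blocks rather than
  materializing shuffled datasets, making 1000 iterations over a 21-ego
  cohort a ~30 s computation; `shuffle_times()` provides the literal
  dataset-level shuffle for inspection and testing.
- The test suite runs its simulation checks on cohorts of 1–21 egos and
  100–1000 shuffle iterations, sizes chosen so the full suite completes
  in well under a minute while leaving the planted effects far above
  their detection thresholds.

## Limitations

Minute-precision wall-clock timestamps are assumed; daylight-saving
transitions are taken at face value because the social clock, not UTC, is
what entrains calling. The persistence verdict is relative to the cohort
(an ego is persistent *compared with the diversity of its peers*), so a
cohort of near-identical rhythms weakens the reference scale. The
synchronization test has limited power below ~100 calls per direction per
period. Conclusions about 4-month stability do not transfer automatically
to other period lengths.
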