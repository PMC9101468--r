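---
title: "Validating time-use assessment methods with simultaneous-activity crediting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating time-use assessment methods with simultaneous-activity crediting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(timeagree)
```

## The measurement problem

Time-use data for women in low-income rural settings are usually collected
with recall instruments: a 24-hour recall interview (R24H), or interviews
assisted by first-person wearable-camera images, either reviewed with the
respondent (image-assisted recall, IAR) or interpreted by the enumerator
alone (EII). The gold standard is continuous direct observation (OBS), which
is too burdensome for routine surveys. Validating the recall instruments
against observation is complicated by one structural feature of these days:
*multitasking*. Passive childcare, chatting with family, or listening to the
radio run continuously underneath foreground work such as cooking or
farming. Recall methods under-report exactly these background activities, so
a validation pipeline has to take a stance on how concurrent activities are
credited with time before any agreement statistic is computed.

`timeagree` implements that pipeline end to end: activity vocabulary and
timeslot grid, crediting, ICATUS-2016 aggregation, population descriptives,
an agreement/reliability suite, and a synthetic-cohort generator that makes
the whole chain testable without field data.

## The crediting rule

The day is discretized into fixed timeslots (default: 08:00-20:00 in 15-min
slots, 48 slots; early morning and late evening are typically unusable for
camera-based methods, so a standard 12-h window keeps all methods
comparable). Each slot holds the *set* of activities recorded in it. Four
activities in the default 44-activity catalog are flagged *simultaneous* —
care of the index child, care of other children or adults, chatting with
friends or family, and watching TV or listening to the radio. Crediting a
slot of length $T$ (minutes) works as follows:

* every simultaneous activity present receives the full $T$;
* the $n$ non-simultaneous activities present share $T$ equally, $T/n$ each;
* a slot with a single activity of either kind credits it the full $T$.

So a slot containing snacking, food preparation, and feeding the index child
credits caregiving 15 min and each of the other two 7.5 min:

```{r}
credit_timeslot(c("snacking", "food_preparation", "care_index_child"),
                default_catalog())
```

The traditional *sequential* convention — which presumes concurrent
activities actually happened one after the other — splits $T$ equally over
everything present and is available as `mode = "sequential"`. Comparing the
two modes on the same records quantifies how much the sequential convention
deflates time credited to background care and socializing. Per-slot credit
is conserved: sequential totals are always $T$; simultaneous-aware totals
are $T(s + [n>0])$ with $s$ simultaneous activities present. Note the
consequence that a division containing two simultaneous activities (MD4
holds both care activities) can legitimately be credited more than the
window length; per-*activity* totals are always bounded by the window.

Activities flagged `excluded` (resting/sleeping, study-related interactions)
are removed before crediting: they neither receive credit nor shrink the
splitting pool. They still count toward concurrency profiles by default,
since they are real recorded activities; `concurrency_profile(...,
count_excluded = FALSE)` switches this. Where the removal happens matters:
removing *after* splitting would dilute the credit of real activities
sharing a slot with an excluded one, which has no behavioural justification.

The default catalog's activity-to-division mapping is a reconstruction (a
fully published mapping is not available for this instrument class); it is
shipped as an editable CSV via `write_catalog()`/`read_catalog()` so a study
can substitute its own. Post-harvest processing is deliberately mapped to
domestic chores (MD3) rather than own production, following the
field-coding-consistency correction for this activity class; MD5 (volunteer
work) and MD6 (learning) are representable but empty by default.

## Descriptives and agreement statistics

`division_summary_table()` reports, per division and method, the median and
quartiles of credited minutes (percentile convention: linear interpolation
between order statistics, `quantile` type 7 — the most common default; the
choice is documented because quartiles of small samples depend on it),
non-participation (share of participants with zero credited minutes, judged
on the criterion method's credits by default), and the partaker-only median.

The agreement suite treats observation as the criterion and fixes the sign
convention as **criterion − test**, so positive bias = the recall method
underestimates. Its components:

* **Bland-Altman**: bias = mean difference, limits of agreement = bias
  ± multiplier × SD of differences (sample SD, $n-1$). The default
  multiplier is **2**, following the "± 2 SD" formulation common in this
  literature rather than 1.96; it is a parameter
  (`bland_altman(multiplier = 1.96)`) because both conventions circulate.
* **Threshold exceedance** (`threshold_counts()`): share of participants
  within 30 min of the criterion, or erring by more than 2 h (boundaries
  inclusive on "within").
* **Cronbach's alpha** with the two methods as a two-item scale, labelled on
  the Nunnally/Peterson benchmarks (<0.70 unacceptable … >0.95 suspect).
  Zero total variance is flagged undefined rather than returning a number.
* **Weighted Cohen's kappa** for ordinal median-concurrency agreement.
  The weight scheme is configurable (linear default, quadratic available)
  and recorded in every result, since the two can differ substantially and
  reports often omit which was used. Categories are the integer span of the
  union of both raters' values; half-integer medians (possible with an even
  slot count) are doubled to integers, which preserves order without
  inventing bins.
* **Wilcoxon signed-rank test**, implemented in-package: midranks for tied
  absolute differences, zeros handled by the classic *drop* rule (Pratt
  available), and an **exact** null distribution — enumerated through the
  generating function of the signed midranks — whenever the effective
  sample size is ≤ 12, else a normal approximation with tie and continuity
  corrections. All-zero differences are flagged "not testable". The exact
  path matters because credited minutes are multiples of small fractions of
  the slot length, so ties are the norm, and the standard implementations
  fall back to approximations precisely then.
* **Plot-shape diagnostics** (`shape_diagnostics()`): the field literature
  classifies Bland-Altman plots visually as cloud/fan/sloped. We
  operationalize this as two least-squares tests — difference on mean
  (proportional bias) and |residual| on mean (spread growing with the
  mean) — classified at a configurable alpha (default 0.05): neither
  significant → cloud; spread only → fan; slope only → sloped; both →
  fan+sloped. Exact linear relations (zero residuals) are classified
  directly rather than through a degenerate regression.

No multiple-testing correction is applied by default (raw p at 0.05, as is
conventional in these validation reports); the Wilcoxon p-values can be
post-processed with `p.adjust` if a study prefers Holm.

## The synthetic cohort generator

Because field deposits for this class of study are rarely usable at desk
scale, the generator is first-class, tested code, and its defaults *are*
the study conditions the rest of the package is validated under. It
emulates:

* a 48-slot observation day with **heavy multitasking**: each simultaneous
  activity is present in each slot independently with its configured
  probability (defaults `care_index_child` 0.65, `care_other_members` 0.30,
  `chatting` 0.40, `tv_radio` 0.10), and exactly one non-simultaneous
  *foreground* activity is always present, drawn from division weights
  (domestic chores dominating at 0.50) with Markov dwell persistence 0.7,
  plus a second foreground with probability 0.10. These values were chosen
  once so that the default preset lands near the observed regime of such
  cohorts — multi-activity slots in the 80-95% range and median concurrency
  around 3 — and are not calibrated to any statistic after the fact.
* **method-specific recall error** operating on *episodes* (maximal runs of
  consecutive slots), because omission plausibly affects whole activity
  bouts: each simultaneous-activity episode is dropped with `q_sim`, each
  foreground episode with `q_act`, and surviving foreground episodes are
  shifted by one slot with `p_shift`. Defaults order the methods as the
  field evidence does: `q_sim` 0.50 (R24H) > 0.35 (EII) > 0.15 (IAR) —
  recall misses background care and chat far more often than image-assisted
  recall, and enumerator-only interpretation sits in between. These rates
  are stated assumptions, not estimates; no quantitative recall-error rates
  exist to calibrate against. The preset's outputs are illustrative and
  only their qualitative ordering is asserted anywhere.
* **observation-day reactivity**: caregiving presence inflated (×1.15) and
  own-production weight deflated (×0.80) on observation days, so day-type
  comparisons have a known signal with a known sign.

Degraded records never contain activities absent from the truth in the same
slot, apart from configured one-slot shifts. Randomness is drawn from one
stream per participant (sub-seeds derived from the config seed), so cohorts
are reproducible and participant $i$'s data do not change when the cohort
grows.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: correlated omission across activities within
a participant (a tired respondent forgets everything at once), systematic
misclassification between divisions, duration distortion of recalled
episodes (only omission and one-slot shifts are modelled), between-
participant heterogeneity in activity prevalences, and seasonal structure.
Agreement statistics on real cohorts can be substantially worse-behaved.

## Analytic parameter recovery

In the tractable regime — no shifts, no second foreground, no missing
slots — the expected Bland-Altman bias has a closed form. Episodes are
dropped independently, so by linearity the expected credited minutes lost
in division $d$ are

$$E[\text{bias}_d] = T_{\text{tot}}\Big(q_{\text{sim}} \sum_{a \in d,\ \text{sim}} p_a \;+\; q_{\text{act}}\, w_d\Big)$$

with $T_{\text{tot}}$ the window minutes (720), $p_a$ the per-slot presence
probabilities and $w_d$ the foreground division weight. The dwell
persistence cancels: it shapes episode lengths but not the marginal
probability that a slot's minutes are lost. `expected_bias()` implements
this and rejects configs outside the regime, listing the offending
features. The test suite verifies the formula by brute-force enumeration on
a 4-slot grid and checks pipeline-estimated bias against it within 3
Monte-Carlo standard errors at cohort size 500, along with (exact, by
common-random-number coupling) monotonicity of the estimated bias in
$q_{\text{sim}}$.

## Numerical and design choices

* Credited minutes arise from halving/k-way splits of 15; sums are exact in
  binary for $k \in \{1,2,4\}$ and tested with tolerance $10^{-9}$
  otherwise.
* Complete-case rule: any record with a missing slot is excluded, and the
  pipeline analyzes only participants complete for *every* method, matching
  the validation design where each participant must supply all instruments.
* Problem sizes: test-suite simulations use cohorts of 60-500 participants
  and 200+ randomized oracle cases; these sizes give Monte-Carlo error
  comfortably inside the asserted bounds while keeping the default test run
  under a minute.
* The long activity-log CSV distinguishes an *observed-empty* slot (a row
  with the reserved code `NONE`) from a *missing* slot (no rows), so
  completeness survives round trips.
* Known limitations: the 44-activity mapping is a reconstruction; the shape
  classification inherits the power of its two component regressions (small
  cohorts will over-report "cloud"); and kappa on the full observed
  concurrency range is not comparable across cohorts with different ranges
  when linear weights are used.
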