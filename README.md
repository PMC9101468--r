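# timeagree

Validation tooling for time-use assessment methods, for researchers
comparing recall-based instruments — 24-hour recall (R24H), image-assisted
recall with wearable-camera photos (IAR), enumerator-only image
interpretation (EII) — against continuous direct observation (OBS) as the
criterion. The motivating setting is women's time use in low-income rural
contexts, where most of the day is multitasked: passive childcare, chatting,
or radio listening run underneath cooking, farming and other foreground
work, and recall methods systematically miss exactly those background
activities.

## What it computes

**Crediting.** The day is discretized into timeslots (default 08:00–20:00,
15-min slots, 48 slots). For a slot of length *T* holding a set of coded
activities, the simultaneous-aware rule credits every *simultaneous*
activity (care of the index child, care of other children/adults, chatting,
TV/radio in the default 44-activity catalog) the full *T*, while the *n*
non-simultaneous activities split *T* equally (*T/n* each); a lone activity
gets the full *T*. The traditional *sequential* rule (equal split over
everything) is available for comparison. Credits are summed into the nine
ICATUS-2016 major divisions per participant.

**Agreement suite**, with the sign convention criterion − test (positive
bias = the recall method underestimates):

- Bland–Altman bias and limits of agreement, LOA = bias ± *m*·SD(differences),
  default multiplier *m* = 2;
- threshold-exceedance counts (within 30 min; erring by > 2 h);
- Cronbach's alpha treating the two methods as a two-item scale, with
  Nunnally/Peterson benchmark labels;
- weighted Cohen's kappa (linear or quadratic) on ordinal median-concurrency
  values, with Landis–Koch labels;
- Wilcoxon signed-rank test with **exact** tied-data p-values for effective
  n ≤ 12 (generating-function enumeration over midranks; drop or Pratt zero
  rule), normal approximation with tie/continuity correction otherwise;
- Bland–Altman plot-shape diagnostics (cloud / fan / sloped / fan+sloped).

**Synthetic cohorts.** A configurable generator produces criterion-truth
schedules (heavy multitasking, Markov foreground persistence) and degrades
them with per-method episode-omission error models, plus observation-day
reactivity effects. A closed-form `expected_bias()` oracle supports
parameter-recovery testing.

## Worked example

Credit the worked timeslot — snacking (self-care), food preparation
(domestic chores) and feeding the index child (caregiving, simultaneous):

```r
library(timeagree)
credit_timeslot(c("snacking", "food_preparation", "care_index_child"),
                default_catalog())
#>         snacking food_preparation care_index_child
#>              7.5              7.5             15.0
```

Caregiving gets the full 15 minutes; the two non-simultaneous activities
split the slot 7.5/7.5.

Run the full pipeline on a synthetic cohort of 175 participants:

```r
cfg <- simulation_config(n_participants = 175, seed = 20)
rep <- run_pipeline(cfg)
print(rep$agreement$R24H)
#> Agreement vs criterion, method R24H (LOA multiplier 2):
#>  division   n  bias loa_low loa_high wilcoxon_p  alpha        label  shape
#>       MD1 175   1.0   -10.7     12.7  1.103e-02 0.9935      suspect    fan
#>       MD2 175   4.7   -24.9     34.3  4.448e-06 0.9816      suspect    fan
#>       MD3 175  48.4   -73.7    170.5  5.946e-24 0.9178         high  cloud
#>       MD4 175 401.2   146.5    656.0  1.800e-30 0.6927 unacceptable sloped
#>       MD7 175 151.5    32.1    270.9  1.663e-30 0.7873   acceptable  cloud
#>       MD8 175  36.9   -20.9     94.8  4.934e-28 0.9044         high    fan
#>       MD9 175   9.5   -41.6     60.5  9.868e-09 0.9689      suspect  cloud
```

Reading MD4 (caregiving): the 24-hour recall underestimates observed
caregiving by 401 min on average for this synthetic cohort, individual
disagreement spans roughly +147 to +656 min, the distributions differ
(Wilcoxon p ≪ 0.05), and inter-method reliability is unacceptable
(alpha 0.69) — the signature of recall dropping background care episodes,
which the generator's error model injects by construction. Divisions
without simultaneous activities (MD1, MD2, MD9) show small biases.
`run_pipeline(cfg, output_dir = "out")` additionally writes the summary,
agreement, reliability, concurrency and plot-data CSVs with a JSON
manifest.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/timeagree.R all --seed 5 --out out/
```

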