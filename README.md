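# awlr — attribute-weighted logistic regression for adverse drug event severity

Adverse drug events (ADEs) — harmful reactions to medication — range from
mild discomfort to death. Spontaneous-report databases such as the FDA's
FAERS record, for each event, the patient's demographics, the suspect drug
and its regimen, the indication, and the outcome. Flagging which reports
describe a *severe* event (death, disability, hospitalization or a
life-threatening condition, in the WHO sense) is a binary classification
problem for pharmacovigilance teams, and the cost of a missed severe event
is high: recall on the severe class matters more than raw accuracy.

Standard logistic regression treats every attribute as equally important.
`awlr` implements an attribute-weighted variant that measures each
attribute's relevance to severity with the chi-square statistic of its
attribute-by-severity contingency table,

```
χ²ᵢ = Σ (Oₖⱼ − Eₖⱼ)² / Eₖⱼ,   Eₖⱼ = M_Rk · M_Cj / M,
wᵢ  = χ²ᵢ · n / Σᵢ χ²ᵢ            (weights sum to the attribute count n)
```

and folds the weight of attribute *i* into the maximum-likelihood
coefficient βᵢ as a signed natural-log term:

```
logit(Y) = α + (β₁ + a·ln w₁)·x₁ + … + (βₙ + a·ln wₙ)·xₙ
```

where the sign *a* is chosen per coefficient so that the adjusted
coefficient always keeps βᵢ's sign (βᵢ > 0, wᵢ > 1 → +ln w; βᵢ > 0,
wᵢ < 1 → −ln w; and mirrored for βᵢ < 0): the direction of the log odds
ratio is preserved while the weight's magnitude is incorporated. The
intercept α is never weighted.

Around that core the package provides the full working pipeline:

* **Data preparation** — therapy duration in days, dose conversion to
  micrograms, standardization with training-split statistics, WHO severity
  labelling, exclusion logging (`prepare_ade()`, `compute_duration()`,
  `convert_dose()`, `label_severity()`).
* **Supervised discretization** — recursive minimum-entropy cuts with the
  Fayyad–Irani minimum-description-length stopping rule, used to discretize
  continuous attributes before weight computation (`discretize_mdlp()`).
* **Weighting schemes** — chi-square plus information-gain and
  Kullback–Leibler baselines, all normalized to sum to the attribute count
  (`attribute_weights()`, `chi_square()`, `ig_score()`, `kl_score()`).
* **Evaluation protocol** — balanced training samples (equal records per
  class), repeated splits testing every method on the identical held-out
  remainder, and accuracy / precision / recall / F-score with severe as the
  positive class (`balanced_split()`, `cross_validate()`).
* **Synthetic data** — a seeded generator of FAERS-like datasets with
  controllable attribute–severity association, whose defaults emulate a
  published osteoporosis ADE cohort (11956 severe / 8620 non-severe
  records), plus the cohort's published contingency tables as fixtures
  (`simulate_ade()`, `ade_sim_spec()`, `osteo_attribute_tables()`).

## Worked example

Simulate a cohort-like dataset, fit the weighted model, and compare it with
unweighted logistic regression under the balanced-sampling protocol:

```r
library(awlr)
d <- simulate_ade(ade_sim_spec(n = 5000), seed = 42)
m <- awlr_fit(d, weight_method = "chi2")
m$weights
#> Attribute weights (chi2), n = 6, sum(w) = 6
#>       attribute     raw weight
#>          gender  12.407  0.120
#>       drug_name 202.067  1.949
#>  dose_frequency 194.919  1.880
#>         disease  36.169  0.349
#>             age 130.846  1.262
#>        duration  45.642  0.440
```

Drug name and dose frequency carry most of the severity signal (weights
about 1.9 of an average 1), gender and disease stage almost none — the same
relevance ordering the published cohort shows. Each dummy coefficient is
then shifted away from zero by |ln w| of its attribute, e.g. `genderMale`
(β = 0.338, w = 0.12) becomes 0.338 + |ln 0.12| = 2.461 while keeping its
sign.

```r
cv <- cross_validate(d, methods = c("none", "chi2"), folds = 10,
                     n_per_class = 1750, seed = 7)
summary(cv)
#>   method    metric        q1    median        q3
#> 1   chi2  accuracy 0.7473333 0.7516667 0.7595000
#> 2   chi2 precision 0.7789806 0.7814060 0.7842735
#> 3   chi2    recall 0.9198072 0.9390885 0.9502629
#> 4   chi2   f_score 0.8455118 0.8514114 0.8578713
#> 5   none  accuracy 0.6345000 0.6390000 0.6406667
#> 6   none precision 0.8365185 0.8451009 0.8499146
#> 7   none    recall 0.6400088 0.6415425 0.6457055
#> 8   none   f_score 0.7273400 0.7287216 0.7308364
```

On this data the weighted model raises median recall from 0.64 to 0.94 and
F-score from 0.73 to 0.85 at a modest precision cost — the directional
pattern the method is designed for: fewer missed severe events. `plot(cv)`
draws the comparative boxplots.

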