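---
title: "Attribute-weighted logistic regression: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attribute-weighted logistic regression: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(awlr)
```

## The model

Logistic regression predicts the logit of a binary severity target from a
linear combination of attributes,

$$\mathrm{logit}(Y) = \alpha + \beta_1 x_1 + \dots + \beta_n x_n,$$

with $\alpha$ and the log odds ratios $\beta_i$ estimated by maximum
likelihood. The attribute-weighted variant implemented here measures each
attribute's relevance to the target with the chi-square statistic of its
attribute-by-severity contingency table,

$$\chi^2_i = \sum_{k,j} \frac{(O_{kj} - E_{kj})^2}{E_{kj}}, \qquad
E_{kj} = \frac{M_{Rk}\, M_{Cj}}{M},$$

normalizes the statistics so the weights sum to the number of attributes,
$w_i = \chi^2_i\, n / \sum_i \chi^2_i$, and shifts each fitted coefficient
by a signed log-weight term:

$$\mathrm{logit}(Y) = \alpha + (\beta_1 + a \ln w_1)\, x_1 + \dots +
(\beta_n + a \ln w_n)\, x_n.$$

The sign $a$ is chosen per coefficient so the adjusted coefficient keeps
the raw coefficient's sign: for $\beta_i > 0$ the term is $+\ln w_i$ when
$w_i > 1$ and $-\ln w_i$ when $w_i < 1$; mirrored for $\beta_i < 0$.
Algebraically the adjusted coefficient is
$\beta_i + \mathrm{sign}(\beta_i)\,|\ln w_i|$: the adjustment always moves
a coefficient *away* from zero, by a larger amount the further the weight
is from 1 in either direction. The direction of each attribute-severity
association (the sign of the log odds ratio) is therefore preserved by
construction; a defensive clip at $\pm 10^{-12}$ guards the contract for
pathological inputs and is counted when it fires. The intercept is never
weighted.

Two points follow from the arithmetic and are worth stating plainly.
First, the adjustment is *post hoc*: $\beta$ is the ordinary unweighted
maximum-likelihood estimate, and the weights enter only afterwards as
additive shifts — weights are not estimated inside the likelihood. Second,
a *low* weight ($w_i \ll 1$) also inflates a coefficient's magnitude,
since $|\ln w_i|$ is large; the scheme encodes "distance of relevance from
average", not relevance itself. Its practical effect is strongly
data-dependent (see *Limitations*).

### Edge cases

* $w_i = 1$: $\ln w_i = 0$, coefficient unchanged. With all weights 1 the
  model is exactly standard logistic regression (tested to $10^{-12}$).
* $\beta_i = 0$: left unadjusted; the sign rule enumerates only positive
  and negative coefficients.
* $w_i = 0$ (attribute with zero statistic, e.g. one whose discretization
  accepts no cut): the additive term is set to the literal constant
  $10^{-10}$. That constant is positive regardless of $\beta$'s sign, an
  oddity we preserve as the published rule; `zero_weight = "zero"` offers
  the alternative of leaving such coefficients untouched. With either
  option the effect on predictions is negligible.

### Categorical attributes

Categoricals are dummy-encoded with the first level as reference. The
method defines one weight per *attribute*, so every dummy coefficient of an
attribute shares that attribute's weight, with the sign rule evaluated per
coefficient. This preserves the one-weight-per-attribute semantics; the
alternative (per-level weights) would change the method into something
else.

## Estimation and numerical choices

* The unweighted fit uses the binomial GLM (IRLS) with relative
  convergence tolerance $10^{-8}$ and at most 100 iterations; perfect
  separation yields a warning and the capped estimate.
* Entropy and divergence quantities are in bits (base-2 logs) with
  $0 \log 0 := 0$.
* Contingency-table columns with zero marginal are dropped before the
  chi-square sum: their expected counts are zero and the cell term is
  undefined.
* Weight normalization requires a positive statistic total; if every
  attribute scores zero there is nothing to weight and the error says so.
* Ties in the discretization cut search are broken toward the smallest cut
  value, making every fit deterministic.

## Supervised discretization

Continuous attributes must be discretized before a contingency-table
statistic can be computed. `discretize_mdlp()` implements recursive
minimum-entropy partitioning with the Fayyad–Irani minimum description
length (MDL) stopping rule: candidate cuts are midpoints between
successive distinct values, the cut minimizing the size-weighted class
entropy of the two partitions is selected, and it is accepted only when
its information gain exceeds $(\log_2(N-1) + \Delta)/N$ with
$\Delta = \log_2(3^k - 2) - [kH - k_1H_1 - k_2H_2]$; accepted partitions
are recursed. Candidates are restricted to class-boundary midpoints, a
known exact optimization (the minimum-entropy cut always lies on a class
boundary); `boundary_only = FALSE` restores the full candidate set and a
property test asserts both searches select the same cut.

Only the *weight computation* consumes the discretized copies. The design
matrix of the logistic regression uses the standardized continuous values
(mean 0, sd 1): the two preparations run in parallel, mirroring the
method's published pipeline. An attribute whose discretization accepts no
cut (e.g. a dose amount that is constant in practice) carries no
detectable class signal at this granularity; it stays in the model with
weight 0 and is reported as non-discretizable.

Discretization (and weighting generally) is computed per training split,
not once globally, so no information from held-out records reaches the
weights. A global mode would be marginally cheaper; we default to the
leak-free reading. The same applies to standardization: statistics come
from the training portion and are reapplied to test data. Standardizing
once before splitting would be the literal reading of the published
pipeline; the per-split default is a deliberate, documented deviation that
avoids train–test leakage, and the functions accept externally supplied
reference statistics for anyone wanting the literal behaviour.

## Evaluation protocol

The protocol pairs *balanced sampling* with repeated evaluation: each fold
draws the same number of records per class (default 7000/7000 at cohort
scale — at the published class totals 11956/8620 this leaves 6576 test
records, a ~70:30 ratio) and tests on the untouched remainder, so training
is class-balanced while testing reflects the natural mix. "k folds" here
means k independent seeded repetitions (fold $f$ uses seed
$\mathrm{seed}+f$), because a fixed 7000-per-class training sample is
incompatible with partitioned k-fold arithmetic; a conventional stratified
k-fold mode is available via `mode = "kfold"`. Every method in a
comparison is fitted on the identical training split and scored on the
identical test split. Severe is the positive class; precision, recall or
F-score with a vanishing denominator is reported as 0 with a warning.

## The synthetic generator

`simulate_ade()` draws severity from a baseline prevalence, then each
attribute from class-conditional distributions: categorical values from
per-class probability vectors (either given directly or derived from a
marginal plus an association-strength scalar in $[0,1)$), age from a
truncated normal on $[0, 105]$ years, duration from a right-skewed
lognormal in days. The defaults emulate a published osteoporosis ADE
cohort: prevalence $0.581$ and $n = 20576$ (11956 severe / 8620
non-severe), categorical conditionals taken from the cohort's published
contingency tables (gender, drug name, dose frequency, disease stage; the
disease table's non-severe column is reconstructed by row-sum arithmetic
from the printed totals), age centred at 66 y (sd 12) with severe cases
4 y older, duration lognormal around 365 d (sdlog 1.2, capped at the
cohort maximum 8677 d) with a 0.25 log-shift for severe cases. The
continuous shifts are our choice — per-class age/duration distributions
are not published — picked once as clinically plausible magnitudes.

What the generator does *not* emulate: attribute–attribute correlation
(drug and dose frequency are drawn independently given severity, while in
reality regimens are drug-specific), report duplication, under-reporting,
and missingness. Tests passing on this generator therefore show the
pipeline is correct and that the method behaves as published on data with
the cohort's marginal structure — not that the method will improve recall
on any particular real dataset.

Test and example problem sizes (hundreds to a few thousand records,
10-fold protocol at $n = 5000$ with 1750 per class in training, keeping
the published ~70:30 train:test ratio) are chosen to exercise every code
path at desk scale.

## Limitations

* The recall benefit of the chi-square adjustment is an empirical property
  of the data, not a theorem. On cohort-like data (a few dominant
  attributes, several weak ones) it reproduces the published pattern —
  large recall and F-score gains for a small precision cost. On other
  shapes — e.g. data whose informative attributes are artificially tilted
  and whose noise attributes are exactly null — the same coefficient
  inflation can distort the decision boundary and *reduce* recall. Users
  should compare `weight_method = "chi2"` against `"none"` under
  `cross_validate()` on their own data before adopting the weighted model.
* The information-gain and Kullback–Leibler weighting schemes are baseline
  re-implementations composed from their standard definitions (mutual
  information; split-information-normalized per-value divergence), both
  normalized to the sum-to-$n$ contract so the $w \gtrless 1$ logic of the
  adjustment rule stays meaningful for every scheme. Unnormalized raw
  statistics are available via `normalize = FALSE`.
* Only binary targets are supported; multi-class discretization and
  multinomial models are out of scope, as are regularized or kernel
  logistic regressions and in-likelihood weight estimation.
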