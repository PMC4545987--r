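---
title: "Rasch evaluation of mixed-format questionnaires: models, diagnostics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rasch evaluation of mixed-format questionnaires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raschpro)
```

## The measurement model

`raschpro` evaluates patient-reported outcome questionnaires whose items mix
dichotomous and ordered polytomous response formats, as is typical of
respiratory quality-of-life instruments such as the SGRQ (Symptom, Activity
and Impact domains; 2- to 5-point option sets). The model is the Rasch
family for ordered categories. For an item $i$ with $m_i$ categories coded
$0,\dots,m_i-1$, difficulty $\delta_i$, and step thresholds
$\tau_{g1},\dots,\tau_{g(m_i-1)}$ belonging to the item's rating-scale group
$g$, the probability that a person with ability $\theta$ responds in
category $k$ is

$$
P(X = k) \;=\;
\frac{\exp \sum_{j \le k} (\theta - \delta_i - \tau_{gj})}
     {\sum_{h=0}^{m_i-1} \exp \sum_{j \le h} (\theta - \delta_i - \tau_{gj})},
\qquad \sum_j \tau_{gj} = 0 ,
$$

with the empty sum equal to zero. Items that share a response format share
one threshold set (the rating scale model); an item alone in its group has
its own thresholds (the partial credit model); a dichotomous group has its
single threshold fixed at zero, which reduces to the simple logistic Rasch
model. Domains are calibrated separately, each on its own logit metric.

Only the difference $\theta - \delta$ matters, so the scale origin is a
convention: item difficulties are mean-centered within each calibrated
domain and persons are free. This matches the reporting convention of
published item tables, where difficulties within a domain straddle zero.

## Estimation

Calibration is joint maximum likelihood (JMLE): alternating damped
Newton–Raphson updates of person measures, item difficulties, and group
thresholds, maximizing the joint likelihood over observed cells only
(missing responses contribute nothing to any likelihood, expectation, or
information sum — they are never imputed). Each Newton step is capped at 1
logit and halved while it would decrease the relevant likelihood slice.
After each sweep, group thresholds are recentered to sum to zero (the shift
is absorbed into the member items' difficulties, leaving every step
location $\delta_i + \tau_{gj}$ unchanged) and difficulties are recentered
to mean zero, sliding person measures along the model's translation-
invariance ridge so the likelihood is untouched. Iteration stops when the
largest absolute parameter change falls below `tol` (default 0.005 logits,
`rasch_control()`), or errors out if any parameter passes 30 logits.
Standard errors are inverse square roots of the observed information
accumulated over observed cells.

JMLE is used deliberately — it is the estimation family of the software
tradition these evaluations come from — and carries the known finite-test
outward bias in item difficulties of order $L/(L-1)$ for $L$ items. The
multiplicative $(L-1)/L$ correction is available
(`rasch_control(bias_correction = TRUE)`) but off by default, again for
comparability: recovery simulations show the uncorrected slope of estimated
on true difficulties near 1.05–1.08 at 20 items, inside the band the
package's own acceptance checks require.

Persons and items with zero or perfect raw scores carry no finite maximum
likelihood estimate. They are removed from iteration (iteratively, since
removing a person can render an item extreme) and reported; extreme persons
additionally receive finite extrapolated measures by solving for the
ability whose expected raw score equals the observed extreme moved inward
by 0.3 score points (`extreme_adjustment`, configurable). This mirrors
common practice; the 0.3-point convention matters mostly for ceiling/floor
and targeting statistics, which deliberately include these persons.

Two independent routes validate the calibrator, since no other Rasch
implementation is assumed available: `grid_search_jmle()` maximizes the
same joint likelihood by cyclic coordinate-wise search over a 0.01-logit
grid with no derivatives and no shared numerical code, and parameter
recovery on synthetic data checks the full loop against generating truth.

## Fit, reliability, dimensionality

Given a converged calibration, each observed cell has model mean $E$ and
variance $W$, residual $x - E$, and standardized residual
$z = (x - E)/\sqrt{W}$. Per item (and per person):

* **infit** $= \sum (x-E)^2 / \sum W$ — information-weighted, dominated by
  persons near the item's location;
* **outfit** $= \operatorname{mean}(z^2)$ — unweighted, outlier-sensitive.

Both are near 1 under fit; the operative band, read from
`rasch_criteria()`, classifies below 0.6 as overfitting and above 1.4 as
misfitting. Standardized ZSTD transforms are not computed — decisions here
are on mean squares.

Person reliability follows the true/observed variance decomposition
$R = \max(\mathrm{var}(\hat\theta) - \overline{SE^2},\,0)/
\mathrm{var}(\hat\theta)$ and separation $G = \sqrt{R/(1-R)}$; $R > 0.7$
counts as good internal consistency, $G$ of 1.5–2.0 acceptable and above
3.0 excellent. The closed form is exposed as
`separation_from_reliability()`, which also serves as a consistency check
on published reliability/separation pairs (0.86 implies 2.48, matching a
printed 2.50 within rounding).

Dimensionality is screened by principal component analysis of standardized
residuals: eigenvalues of the inter-item residual correlation matrix
(pairwise-complete), reported in item units so they sum to the number of
items. A first contrast near the 1.4–1.7 values seen on simulated
unidimensional data indicates noise; the flag threshold defaults to 3.0
eigenvalue units and is deliberately configuration, not a constant,
because practice accepts first contrasts up to the high 2s as
unidimensional and no single cut is canonical. Local independence is
screened by flagging item pairs with $|r| > 0.3$ between residual columns.
KR-20 (`kr20()`) covers the classical internal-consistency route for
all-dichotomous domains, computed with population variances on complete
rows so that it equals Cronbach's alpha on 0/1 data exactly.

## Targeting, coverage, gaps, ceiling and floor

The scale-level battery works off two point sets: person measures
(extrapolated extremes included) and item step locations
$\delta_i + \tau_{gj}$.

* **Targeting** is mean person measure minus mean item difficulty; 0 is
  perfect, $|t|$ between 0.5 and 1 slight mis-targeting, above 1
  substantial. (Published practice occasionally labels values inside the
  ±0.5 band as "slight difficulty"; the package follows the stated numeric
  bands.)
* **Range and coverage**: the threshold span $[\min, \max]$ over all step
  locations, the percentage of persons inside it (95% is the target), and
  the 2.5th–97.5th percentile person limits.
* **Gaps** operate on item difficulties — the mean of each item's step
  locations, which under the sum-zero constraint is $\delta_i$ itself —
  sorted ascending; adjacent differences of 1 logit or more are flagged.
* **Ceiling/floor**: percentages strictly above the highest / strictly
  below the lowest step location, flagged at 15%. Boundary persons count as
  in range, so floor + ceiling + coverage partition to exactly 100.
* **Threshold ordering**: a polytomous item is flagged disordered when any
  adjacent threshold pair fails to ascend strictly — the signature of a
  category that is almost never the most probable choice.

`wright_map()` renders the standard two-panel text display: a person
histogram (`#` symbols) against item threshold labels on a shared logit
axis, with polytomous thresholds labelled `item.2` … `item.m` and
dichotomous items by bare id.

## Differential item functioning

DIF compares an item's difficulty between two person subgroups at equal
trait level. The built-in splits are age (< 75 vs ≥ 75 years) and disease
severity (stages 0–II vs III–IV); because severity tabulations often merge
stages 0 and I, and occasionally attach stage II to either side, the split
is a configurable predicate rather than a constant (`split_groups()`).

The default method anchors person measures (and step thresholds) at the
pooled calibration and re-estimates only each item's difficulty within each
group; this is well identified at modest group sizes. The alternative
(`method = "separate"`) runs a full calibration per group and links them by
mean-item equating, matching the two-calibration scatter construction used
in published DIF figures. In both cases the decision rule is pure
magnitude: $|\hat\delta_A - \hat\delta_B| > 0.5$ logits flags the item, with
no significance test and no multiplicity adjustment, because that is the
published rule this battery reproduces. The operating characteristics that
rule buys are worth stating plainly: simulations at 150 persons per group
with 20 dichotomous items spread over $[-3, 3]$ logits detect a genuine
1-logit shift in ≥ 95% of replicates, but poorly informative tail items
(per-group standard errors of 0.27–0.40 logits) exceed the 0.5-logit
contrast by sampling noise alone in roughly 15% of item × replicate
combinations — a floor set largely by the items' information content
rather than by the estimator, since those standard errors follow from the
per-group sample size alone. A magnitude-only
rule at this sample size over-flags weakly informative items; users who
need a controlled false-positive rate should restrict attention to items
whose contrast also exceeds, say, twice its standard error.

## The synthetic generator

`generate_responses()` draws each cell from the category probabilities at
true parameters, so every pipeline stage can be verified by parameter
recovery. What it emulates, and the defaults chosen once for realism:

* **Structure**: `sgrq_like_spec()` — 6 polytomous Symptom items (4–5
  categories; which items carry 4 vs 5 options is illustrative, as the
  source instrument's exact pre-revision assignment is unpublished), 16
  dichotomous Activity items, 26 Impact items (3 polytomous). The two
  Symptom items conventionally excluded from calibration are available
  behind `include_excluded = TRUE` with an exclusion flag, so classical
  domain scoring can use the full instrument while calibration drops them.
* **Trait**: $\theta \sim N(0, 1.5^2)$ logits, matching the wide person
  spread such samples show.
* **Difficulties**: default to the published per-item calibrated values for
  the SGRQ-like structure (Activity spanning −6.4 to +4.5 logits), giving
  the generator the realistic long tail that stresses extreme-score
  handling; any layout within $[-7, 5]$ can be supplied.
* **Thresholds**: no published source prints them, so defaults are ordered
  and evenly spaced (±1.5 logits for 5-category sets, ±1 for 3/4-category)
  — illustrative by construction. Disordered-category scenarios are created
  by supplying reversed thresholds.
* **Covariates**: age $N(70.4, 7.9^2)$ years clamped to 46–88; stage
  frequencies 16.25/35.83/39.58/8.33% for 0–I/II/III/IV. Severity is linked
  to the trait by an additive +0.8-logit shift for stages III–IV (roughly
  half a trait SD — severe airflow limitation plausibly worsens reported
  status), so DIF studies can separate true trait differences, which
  anchoring must absorb, from injected item-level DIF. Both effects are
  configurable, including to zero.
* **Injections**: `inject_dif()` records exact group-specific difficulty
  shifts; `inject_second_dimension()` routes a subset of items to a second
  trait with configurable correlation (0 = orthogonal contamination).
* **Streams**: one seed, split into substreams for covariates/trait, the
  second dimension, and responses, so toggling an option never perturbs the
  parts it does not touch; the same seed and config are byte-reproducible.

What the generator does *not* emulate: response styles, missingness that
depends on status (only MCAR is available), local dependence from shared
item stems, and multidimensionality subtler than a discrete second trait.
Passing recovery and null-fit tests on these data therefore demonstrates
the estimator and diagnostics are correct under the model, not that any
real questionnaire fits it.

## Numerical choices and problem sizes

Convergence tolerance 0.005 logits (tightened to 1e-4 where a 0.02-logit
oracle comparison needs headroom), Newton step cap 1 logit with halving on
likelihood decrease, divergence guard at 30 logits, probabilities computed
through a log-sum-exp stabilized form exact to 1e-12 across ±10 logits.
Ties in report ordering break by item id so output is deterministic.
Degenerate inputs follow explicit conventions: zero-variance cells get
missing residuals, zero-variance measure sets report reliability 0 and are
flagged degenerate, constant residual columns are dropped from the PCA
with a warning, all-missing person-domains score missing rather than zero.

The verification suite runs at the design scales the checks are stated
for: an 8 × 5 grid-oracle comparison; ten replicates of 300 persons × 20
items for recovery (r ≥ 0.98, RMSE ≤ 0.3 logits, slope 0.90–1.15) and null
infit (0.9–1.1); twenty replicates of 150-per-group DIF injection; ten
paired replicates of 500 × 20 for dimensionality discrimination. The same
quantities are recomputed from scratch by `scripts/acceptance.R`.

## Known limitations

JMLE difficulties carry the finite-test bias discussed above; person
measures for very short domains (6 items) are coarse, which is visible as
modest person reliability in Symptom-like domains. The magnitude-only DIF
rule over-flags at small samples (quantified above). The dimensionality
cut is heuristic, and the residual-correlation screen flags redundancy as
readily as genuine secondary dimensions. None of these are defects of the
implementation; they are properties of the methods the package implements,
reproduced faithfully and measured by its own simulations.
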