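---
title: "Nutrient profiling of imitation products: model, estimator and generator design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nutrient profiling of imitation products: model, estimator and generator design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutriprofiler)
```

## The scoring model

The package implements the FSAm-NPS nutrient profiling model in its
pre-2023 form, the one under which plant-based meat and dairy imitation
products have been compared with their animal-based counterparts. Four
*negative* components are scored 0–10 points each by counting ladder
thresholds strictly exceeded: energy (kJ), total sugars (g), saturated
fatty acids (g), and sodium (mg). Three *positive* components are scored
0–5: fibre (g), protein (g), and FV% — the share of product mass from
fruits, vegetables, pulses, nuts and the rapeseed/walnut/olive oils. The
score is

$$\mathrm{FSAm\text{-}NPS} = \underbrace{P_E + P_{sug} + P_{SFA} + P_{Na}}_{N \in [0,40]}
  \; - \; \bigl(P_{fib} + P_{FV} + \mathbb{1}_{incl}\, P_{prot}\bigr),$$

an integer in $[-15, 40]$. Protein points count only when $N < 11$, or
$P_{FV} = 5$, or the product is a cheese (the *cheese rule*). Grades for
solid foods: A for $-15..-1$, B for $0..2$, C for $3..10$, D for
$11..18$, E for $19..40$; plant-based beverages are graded on the same
solid-food bands throughout (that is the convention under which both milk
groups come out modal grade B — the package applies it uniformly,
including to animal milk, where the source is silent).

Two unit conversions sit in front of the ladders, both boundary-sensitive
and therefore fixed explicitly: 4.184 kJ/kcal (thermochemical factor, not
4.2) and 400 mg sodium per g salt (EU labelling convention, salt =
2.5 × sodium). Nutrient inputs are used at declared precision with no
rounding before ladder lookup; points use strict inequalities, so fibre at
exactly 1.9 g earns 1 point, not 2. The fibre ladder is the AOAC ladder
(0.9/1.9/2.8/3.7/4.7); the ladder list is an argument (`ladders =`) so it
can be swapped.

Missing-data policy: a product missing any of the four negative components
cannot be scored and is *excluded*, with the missing fields reported; a
missing positive component (fibre, protein) is imputed as zero. This
asymmetry mirrors label reality — fibre is often simply not declared.

## The FV% estimator

FV% is estimated from the ordered ingredient list in two steps. A cheap
screen asks whether eligible content could reach 40% (the minimum that
earns any points); only products passing it are quantified. Eligibility is
form-based: fruits, vegetables, pulses and nuts count fresh/whole, as
juice, or dried; concentrates, powders, candied preparations and flours
never count; the three eligible oils count as oil; coconut counts only as
fresh coconut product, in no form besides. Dried produce counting (except
coconut) is this package's reading — the source rules name only coconut —
and is configurable at the lexicon level.

Where a label declares QUID percentages they are used directly. Where it
does not, each entry is bounded by declaration order: an undeclared entry
at rank $r$ cannot exceed $100/r$, nor the smallest declared percentage
above it, nor the mass left over after all declared percentages. The
screen uses the optimistic upper bound; quantification uses the midpoint
of $[0, \mathrm{upper}]$. This order-bound estimator is a stated
convention of this package, chosen because it is deterministic, auditable
and conservative; the original quantification procedure for undeclared
percentages is not described anywhere reproducible. Points follow the
ladder 0 (≤ 40), 1 (> 40), 2 (> 60), 5 (> 80) — note the screen boundary
is inclusive (40% may pass the screen) while points need strictly more
than 40%, so a product at exactly 40% passes the screen and still earns 0.

In practice imitation products declare their plant matter as protein
isolates, flours, starches and refined oils — every one an excluded form —
which is why the real cohort earned no FV points anywhere. The synthetic
ingredient templates reproduce that, and `inject_eligible = TRUE` exists
purely to exercise the positive path in tests.

## Comparison battery

All composition variables in branded-food data are right-skewed and fail
normality, so the battery is nonparametric throughout: summaries are
median (Q1, Q3) with linear-interpolation quantiles (R type 7 — the source
does not state a convention, so one is fixed for reproducibility);
two-group contrasts use the two-sided Mann–Whitney U (exact when both
groups have ≤ 8 observations and no ties, normal approximation with tie
correction otherwise; identical groups report p = 1); k-group contrasts
use Kruskal–Wallis with tie correction. Normality checking uses the
Lilliefors form of the Kolmogorov–Smirnov test, the appropriate variant
when mean and SD are estimated from the sample (for n of 3–4, below the
Lilliefors tables, a parametric KS is used and flagged).

The adjusted significance level defaults to `alpha_adjusted = 1e-4`, the
literal reading of "significance at 0.01%" as a Bonferroni-style
family-wide level. The phrase is genuinely ambiguous (0.01% vs 0.01
divided per family); rather than guess intent, the level is a config
value and every comparison row prints the alpha actually used.
Missing declarations are deleted pairwise — each nutrient is summarised
and compared over the products that declare it.

## The synthetic generator

The generator exists so the full pipeline can be exercised, at any n,
against a database whose group structure matches the published cohort: 14
groups (7 categories × plant/animal) with the published group sizes,
per-nutrient median (Q1, Q3) targets, main-ingredient mixtures, on-pack
claim/indicator prevalences, and per-nutrient label missingness.

Nutrients are drawn from quantile fits to the printed quartiles. The base
fit is lognormal — non-negative and right-skewed, matching what branded
data look like — with $\mu = \ln(\mathrm{med})$ and
$\sigma = (\ln q_3 - \ln q_1) / (2\,z_{0.75})$. Printed cells with $q_1 = 0$
or median 0 use a zero-inflated lognormal (zero mass 0.3 when only $q_1$
is 0, 0.6 when the median is 0, placing the printed quartiles on the
correct side of the zero mass). Incomplete printed cells are reconstructed
by documented fallbacks (missing $q_3$: symmetric spread above the median;
a lower quartile printed above its median: symmetric reflection), and such
cells are treated as structure, not as calibration targets — the printed
table does not determine their distribution.

The two label constraints SFA ≤ fat and sugars ≤ carbohydrate are enforced
by *quantile coupling*: each pair shares one uniform draw, so each member
keeps its own marginal quantile function exactly while the pair is
comonotone; where the two quantile curves cross in a far tail the
constrained member is capped. This is the one deliberate departure from
the obvious alternative (drawing SFA as a Beta fraction of fat): a
multiplicative fraction does not preserve the printed SFA median, while
coupling reproduces both marginal medians exactly — the property the
calibration checks actually need. Draws are rounded to one decimal, the
precision of on-pack declarations (rounding is monotone, so the
constraints survive it).

Beyond those two pairs, nutrients are drawn independently: the analyses
under test consume marginal medians and rank statistics, so marginal
fidelity is what matters. Consequently the generator does *not* emulate
energy–macronutrient consistency, brand-level recipe clustering, or
claim–composition dependence (products bearing a sugar claim are not made
lower-sugar). Passing tests therefore demonstrate the pipeline's
correctness on data with realistic margins and structure, not any claim
about joint distributions in real databases.

Label missingness is missing-completely-at-random per nutrient: 2% for
each negative component, 1% for protein/fat/carbohydrate, 20% for fibre
(fibre declaration is optional and frequently absent on-pack); these
rates are this package's choice, stated here once — the source reports
only that exclusions for missing negatives occurred, not their rate.
Determinism is contractual: one seed, byte-identical output files.

## Numerical and degenerate-input choices

* Strict threshold inequalities everywhere; no input rounding before
  lookup. Score bands are inclusive integer ranges as printed.
* Scores outside $[-15, 40]$ are impossible by construction; the grade
  function refuses them rather than clamping.
* Zero-variance samples: normality is reported non-normal (degenerate),
  Mann–Whitney reports p = 1 at the mean U.
* Empty inputs: empty product files round-trip to empty tables; groups of
  size 0 generate nothing; comparison strata without two usable groups
  are skipped with the reason recorded in the output row.
* The brute-force score-range search enumerates every combination of
  {0, each threshold + ε} per component crossed with all FV levels
  (≈ 2.1 M profiles) through the same vectorised engine the pipeline
  uses, and attains −15 and +40 exactly.

## Problem sizes used by the checks

Unit and property tests run at hundreds to thousands of cases; the oracle
equivalence and monotonicity suites use 10,000 random profiles against an
independently written linear-scan scorer; generator calibration is checked
at 50,000 products per group (medians within 2% relative or 0.05 absolute
near zero, prevalences within ±1 percentage point); the Kruskal–Wallis
null rejection rate is measured over 1,000 simulations at n = 15 per
group. These sizes make the binomial/median sampling noise comfortably
smaller than the asserted tolerances.

## Known limitations

* The order-bound FV estimator is a convention; against labels with rich
  QUID declarations it is exact, but with no declared percentages its
  midpoint quantification is coarse (it mainly matters whether a product
  crosses the 40/60/80 point boundaries).
* The 2023 revision of the Nutri-Score algorithm is deliberately not
  implemented; neither are beverage-specific bands.
* The generator's independence assumptions above; its claim draws are
  per-claim Bernoulli, so claim co-occurrence is not structured.
* The ingredient lexicon is a starting vocabulary, not a comprehensive
  ontology; unmatched names deliberately fall to the non-eligible class
  so FV% is never overstated by vocabulary gaps.
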