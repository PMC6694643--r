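---
title: "Familial aggregation, segregation and liability-threshold heritability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Familial aggregation, segregation and liability-threshold heritability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famline)
```

## The analysis this package implements

famline implements the classical genetic-epidemiology workup of a 1:1
matched case-control family study of a binary trait. Each proband (an
affected case, or a matched unaffected control) contributes a roster of
surveyed relatives — parents, siblings, offspring (first degree),
aunts/uncles (second degree), cousins (third degree) — each recorded as
affected or not. Three questions are asked of such data:

1. **Familial aggregation.** Is the trait more prevalent among relatives
   of cases than among relatives of controls, and does prevalence decline
   with the degree of relatedness?
2. **Mode of inheritance.** Is the sibling segregation ratio compatible
   with monogenic dominant (0.50) or recessive (0.25) inheritance, or does
   it fall below both, as expected for a polygenic threshold trait?
3. **Heritability of liability.** How much of the variance in the latent
   liability is attributable to additive genetic effects?

## The liability-threshold model

All estimators assume Falconer's threshold model: each individual carries
an unobserved liability $L \sim N(0, 1)$ and is affected iff $L > t$,
where $t$ is fixed by the population prevalence $K$ via
$t = \Phi^{-1}(1 - K)$. Two deviates summarise a prevalence $q$:

* the threshold deviate $x = \Phi^{-1}(1 - q)$, and
* the mean deviate of the affected, $a = \varphi(x) / q$ — the mean of the
  standard normal truncated above $x$.

`threshold_deviates()` computes both exactly; they satisfy $a q =
\varphi(x)$ and $a > x$ for all $q \in (0,1)$, and regenerate the classical
Falconer-table entries at table precision. Because historical analyses
read these values off printed lookup tables — whose granularity can move a
deviate by several hundredths — `deviates_from_table()` accepts an explicit
$(q \to x, a)$ mapping and returns it verbatim, without interpolation.
Interpolation is deliberately refused: it would smooth over exactly the
lookup discrepancies a replication is trying to expose. The two paths are
both first-class, selected by the `deviates` argument of `estimate_h2()`:
`"exact"` answers "what does normal theory give", `"table"` answers "what
did the original analysis compute".

## Falconer heritability from case-control family data

With $q_0$ the prevalence among control-family relatives, $q_1$ among
case-family relatives, $p_0 = 1 - q_0$, and deviates $x_0, a_0, x_1$, the
regression of relative liability on proband liability gives

$$ b = \frac{p_0\,(x_0 - x_1)}{a_0}, \qquad \hat h^2 = \frac{b}{r}, $$

where $r$ is the genetic similarity coefficient of the relative class
(1/2, 1/4, 1/8 for first/second/third degree). The control arm, rather
than the general population, supplies the reference threshold — the
appropriate correction when controls are selected to be unaffected.

Some published analyses multiply $b$ by a fixed 2 at *every* degree rather
than by $1/r$. Both conventions are implemented
(`multiplier = "one_over_r"` vs `"paper_fixed_2"`); they coincide at
$r = 1/2$ and differ by factors of 2 and 4 at the second and third degree.
The default is `one_over_r`, the formula as theory states it; the fixed-2
variant exists so published second/third-degree values can be reproduced
and the difference made visible rather than argued about.

The standard error is the literal evaluation of

$$ \mathrm{SE}(\hat h^2) = m \sqrt{ \frac{p_1}{A\,a_1^2}
   \left( \frac{p_0}{a_0} \right)^2 }, $$

with $A$ the number of case probands and $m$ the same multiplier applied
to $b$ (so the two modes stay internally consistent). $A$ is
user-settable because source papers often define it only loosely ("case
number"). The 95% interval is $\hat h^2 \pm 1.96\,\mathrm{SE}$. Estimates
outside $[0, 1]$ are returned unclamped with an `out_of_range` flag:
truncation would hide exactly the model misfit the flag reports.

## The modified-Weinberg segregation ratio

From sibship counts — $T$ total siblings, $R$ affected, $J$ sibships with
exactly one affected member, $Q$ with exactly two — the
ascertainment-corrected ("singles") estimator is

$$ \hat p = \frac{R - J}{T - J}. $$

Removing single-case sibships from numerator and denominator corrects for
ascertainment through affected members under complete ascertainment. Two
standard-error conventions are shipped because printed method sections and
the arithmetic actually carried out in published worked examples disagree
in the exponent of $(T - J)$ in the first term:

* `as_computed` (default):
  $\sqrt{(R-J)(T-R)/(T-J)^3 + 2Q(T-R)^2/(T-J)^4}$ — the binomial-style
  variance whose intermediate terms match published worked arithmetic;
* `as_printed`: the same with $(T-J)^2$ in the first term, as sometimes
  typeset; on realistic counts it yields errors an order of magnitude too
  large, which is precisely why both are kept visible.

`classify_inheritance()` applies the textbook thresholds: dominant if 0.50
falls in the 95% CI, recessive if 0.25 does, polygenic if the whole CI
lies below 0.25; exactly one match classifies, zero or several are
inconclusive. A degenerate table in which every sibship is a lone affected
member gives $R = J$ ($= T$); the estimator's numerator is then zero and
`segregation_ratio()` returns 0 rather than treating 0/0 as an error,
since "no secondary cases" is the statement such data make.

## The synthetic study generator

`simulate_study()` generates matched case-control family studies under the
same liability model the estimators assume, so every estimator can be
validated by parameter recovery with no external data. Probands are drawn
from the standard normal truncated above $t$ (cases) or below $t$
(controls — mirroring studies whose controls are screened to be
unaffected, not population-random). Each relative with similarity $r$ has
liability correlation $\rho = r h^2$ with the proband. Two relative
models:

* `conditional_on_proband` (default): relatives are drawn independently
  from $N(\rho L_p,\, 1 - \rho^2)$ given the proband. This is exactly the
  regression model under which the Falconer estimator is unbiased, so
  recovery tests are sharp tests of the implementation rather than of
  model mismatch.
* `full_mvn`: one joint draw per family with pairwise liability
  correlation $r_{ij} h^2$ from a fixed within-family relatedness matrix
  (parents unrelated to each other, siblings 1/2 to each other and to
  parents, aunts/uncles 1/2 within a parental side, and so on; the first
  parent slot is treated as the father for side assignment). This adds the
  relative-relative dependence real families have; proband-relative
  margins are identical to the conditional model.

Defaults are chosen as a realistic desk-scale study: $K = 0.2322$
(a common-disease prevalence of the order seen in adult hypertension
surveys), 342 families per arm, and a per-family structure of 2 parents +
2 siblings + 1 offspring, 4 second-degree and 3 third-degree relatives —
matching typical surveyed nuclear-family sizes of about 5 / 4.5 / 3
relatives per degree. One root seed derives a substream per family (the
root seed hashed with the family index), so enlarging the study or
changing the structure leaves existing families' draws untouched.

`expected_relative_prevalence()` is the closed-form companion: the
probability a relative is affected given the proband's arm, by 1-D
Gauss-style quadrature of $\Phi\!\big((\rho l - t)/\sqrt{1-\rho^2}\big)$
against the truncated proband density (`stats::integrate`,
`rel.tol = 1e-10`). Simulator and quadrature are cross-checked against
each other in the test suite within Monte-Carlo error.

`simulate_sibships()` feeds the segregation estimator: sibships with
pairwise liability correlation $h^2/2$ (independent Bernoulli($K$) sibs at
$h^2 = 0$), entered into the table under `complete` ascertainment (each
affected member detected with probability $\pi$, sibship enters if any is
detected) or `single` ascertainment (the small-$\pi$ limit: entry
probability proportional to the affected count, one proband per family).
Under complete ascertainment with $\pi = 1$ the singles estimator is
exactly unbiased for the per-sibling risk, which the suite verifies
against a complete-enumeration oracle for sibship sizes up to 3.

### What the generator does and does not emulate

It reproduces the sampling structure the estimators assume: truncated
proband selection, kinship-scaled liability correlation, fixed family
structure. It does **not** simulate shared household environment,
assortative mating, age/sex matching covariates, age-of-onset, or
diagnostic misclassification. Passing recovery tests therefore shows the
estimators are implemented correctly and are consistent under their own
model — not that real-data estimates are unconfounded. In particular,
shared environment inflates relative prevalence exactly as genetics does,
and the Falconer estimate absorbs it; this is a property of the method,
not of the implementation.

## Numerical and design choices

* Prevalences are kept as exact rationals of their counts and rounded only
  for display (2 decimals for percentages, 3 for ratios). This matters:
  feeding the exact rationals through the heritability formula reproduces
  published values to the third decimal, where pre-rounded inputs drift in
  the last digit.
* Table-mode deviate lookups match keys within `5e-5` in the pipeline —
  i.e. at the 4-decimal precision printed tables carry — and `1e-8` when
  called directly.
* The chi-square test for arm differences is the standard Pearson 2×2
  statistic (optional Yates correction), cross-checked against
  `stats::chisq.test`. A McNemar variant is provided for genuinely paired
  tables but is not on the default path, since class-level aggregation
  destroys pair identity.
* Degenerate inputs are loud: empty rosters, zero table margins, unknown
  relative classes, missing two-case counts ($Q$) and inconsistent sibship
  totals ($J \le R \le T$) all raise classed errors naming the offending
  input.
* The `full_mvn` conditional covariance is Cholesky-factored once per
  configuration; a non-positive-semi-definite relatedness matrix is a
  configuration error, not a silent repair.

## Problem sizes used in validation

The bundled study fixture (8599 relatives in 684 families, sibship totals
$T = 2013$, $R = 891$, $J = 580$, $Q = 163$) runs in milliseconds.
Recovery tests use 20,000 families per arm per heritability value
($h^2 \in \{0.2, 0.5, 0.8\}$, tolerance ±0.05); simulator/quadrature
agreement uses 15,000–20,000 families per arm at 3–3.5 Monte-Carlo
standard errors; the segregation enumeration check uses 200 replicates of
400 sibships. These sizes put Monte-Carlo error comfortably inside the
assertion tolerances while keeping the whole suite under half a minute.

## Known limitations

* No pedigree graph: relatives are class-labelled rows, not linked
  individuals, because the estimators consume only class-level counts.
* The heritability SE formula is evaluated as printed in the classical
  sources; it treats only the case-arm prevalence as noisy and is best
  read as an approximation. Published values computed from it are
  sometimes themselves inconsistent (see the package README's notes on
  reproducibility).
* No adjustment for shared environment; the heritability reported is the
  familial-aggregation upper bound the Falconer method yields.
* `classify_inheritance()` implements the textbook interval rule; it is a
  screen, not a likelihood-based segregation analysis.
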