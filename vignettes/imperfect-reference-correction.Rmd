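---
title: "Correcting diagnostic accuracy for an imperfect reference standard: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting diagnostic accuracy for an imperfect reference standard}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refcorrect)
```

## The problem

A diagnostic accuracy study cross-classifies a new binary *index test* (IT)
against a binary *reference standard* (RS) in a 2×2 table with cells
$a$ (IT+/RS+), $b$ (IT+/RS−), $c$ (IT−/RS+), $d$ (IT−/RS−), RS margins
$e = a+c$, $f = b+d$, IT margins $g = a+b$, $h = c+d$, total $N$. The
classical estimates $\widehat{Sn}_{IT} = a/e$ and $\widehat{Sp}_{IT} = d/f$
are only valid if the reference never errs. When the reference's own
sensitivity $Sn_{RS}$ and specificity $Sp_{RS}$ are known — typically from
earlier validation studies — algebraic *correction methods* re-estimate the
index test's accuracy without any probabilistic modelling of the latent
disease status. This package implements the three such methods that apply
to a binary IT with a known-imperfect RS under conditional independence,
together with the simulation apparatus needed to compare them.

## The estimators

All corrections require the reference's Youden index
$J = Sn_{RS} + Sp_{RS} - 1 \ne 0$; a reference with $J = 0$ is
uninformative and is rejected with a typed error.

**Staquet** (`staquet_correct()`, `staquet_prevalence()`):
$$\widehat{Sn} = \frac{g\,Sp_{RS} - b}{N(Sp_{RS}-1) + e},\qquad
  \widehat{Sp} = \frac{h\,Sn_{RS} - c}{N\,Sn_{RS} - e},\qquad
  \hat P = \frac{N(Sp_{RS}-1) + e}{N\,J}.$$
$\hat P$ is the misclassification-corrected (Rogan–Gladen-type) prevalence.

**Gart–Buck** (`gart_buck_correct()`) rewrites the same quantities through
the classical estimates and $\hat P$. The two routes are algebraically
identical; we deliberately keep both implementations and *test* the
equivalence (to $10^{-9}$ on the clinical fixtures and 1 000 randomized
tables) rather than collapsing them, since the agreement of two independent
computational paths is a strong guard against transcription errors in
either formula.

**Brenner** (`brenner_correct()`):
$$\widehat{Sn} = \frac{a\,Sn_{RS} + b(1-Sp_{RS})}{e\,Sn_{RS} + f(1-Sp_{RS})},\qquad
  \widehat{Sp} = \frac{c(1-Sn_{RS}) + d\,Sp_{RS}}{e(1-Sn_{RS}) + f\,Sp_{RS}}.$$
Both are convex combinations of observed proportions, hence always in
$[0,1]$ — which is precisely why Brenner cannot undo the attenuation caused
by reference error: on expected counts from the independence model with
prevalence 0.3 and scenario-one accuracies it returns
$Sn = 0.2346/0.372 \approx 0.63$ against a truth of $0.8$. The
probability-scale form (through $Prr$, $\widehat{Sn}_{IT}$,
$\widehat{Sp}_{IT}$) is exposed as `brenner_probability_form()` and the
count form asserts agreement with it whenever both are computable.

**Illogical estimates.** The Staquet estimators are ratios whose
denominators shrink to zero as the apparent prevalence approaches
$1 - Sp_{RS}$ (or $Sn_{RS}$); estimates can then fall outside $[0,1]$. We
never clamp: the raw value is stored, an `illogical` flag is set, and the
confidence interval is suppressed. A zero denominator, by contrast, raises
a typed error rather than a flag, because it indicates an inestimable study
configuration rather than an estimable-but-absurd value.

## Confidence intervals

Intervals use the Wilson score method (`wilson_interval()`), with the
effective denominator $n = e$ for sensitivity and $n = f$ for specificity —
for the classical estimator these are the actual binomial denominators, and
the corrected estimators inherit them as the natural effective sample
sizes. The coverage of these intervals for *corrected* estimates is not
studied here (interval coverage is a property of the interval procedure,
not of the point estimators being compared).

One genuinely open design point was the precision at which the interval is
evaluated. Recomputing the published clinical tables shows their corrected
intervals match Wilson evaluated at the point estimate *rounded to 2
decimal places*, while unadjusted intervals match the exact count ratio;
26 of the 27 printed interval pairs reproduce exactly under this hybrid
(the one exception, the dentine fluorescence-camera Brenner specificity
lower bound, is consistent with full precision instead — the source table
is internally inconsistent there). `analyze_case_study()` therefore offers
`ci_points = "published"` (default, reproduction-faithful) and
`ci_points = "full"` (full precision, the statistically cleaner choice for
new analyses). Point estimates are always carried at full precision;
rounding to 2 dp happens only in presentation.

## The synthetic-data generator

`cell_probabilities()` builds the joint cell distribution by the
fixed-effects dependence model: within the diseased class the joint
probability of (IT+, RS+) is $Sn_{IT}Sn_{RS} + \mathrm{cov}_d$ with the
complementary cells adjusted so the class distribution still sums to one,
and analogously with specificities and $\mathrm{cov}_{nd}$ in the
non-diseased class; the two class distributions are mixed by prevalence
$p$. Setting both covariances to zero recovers conditional independence
(the class-joint factorises, verified as a property test). Covariances are
*fixed across participants*; a subject-varying (random-effects) dependence
model is out of scope. Feasibility — all eight class-conditional cell
probabilities in $[0,1]$ — is exactly the band
$\max(-q_1q_2, -(1-q_1)(1-q_2)) \le \mathrm{cov} \le
 \min(q_1(1-q_2), (1-q_1)q_2)$
and is validated before construction and again before sampling, so an
infeasible configuration fails before any random draw.

Replicate tables are single multinomial draws of size $n$
(`sample_tables()`). Seeding derives one substream seed per replicate from
the scenario seed, so any prefix of the replicate sequence is reproducible
independently of the total number requested; sweeps likewise derive one
substream per grid point from the sweep seed. Whether the original study
re-used one stream per prevalence point is unstated; independent substreams
are the defensible default and are what the run manifest records.

**What the generator emulates and what it does not.** It reproduces the
stated generative world: multinomial sampling of the four cells at fixed
$(p, Sn_{IT}, Sp_{IT}, Sn_{RS}, Sp_{RS}, \mathrm{cov}_d, \mathrm{cov}_{nd})$,
with 200 replicates per condition and sample sizes spanning 50–1000 (the
default grid adds 80, explicitly discussed for small-sample artefacts, to
a 50-step grid). It does not emulate clustered sampling, covariates,
verification bias, spectrum effects, or uncertainty in the assumed
reference accuracy — so a green simulation test establishes the estimators'
behaviour under the model's assumptions, not robustness to their violation.

Predefined benchmark scenarios (`predefined_scenarios()`), all at
$p = 0.3$: RS better than IT (RS 0.9/0.9, IT 0.8/0.7); IT better than RS
(IT 0.9/0.9, RS 0.8/0.7); all accuracies 0.9; and a dependence scenario
(IT 0.8/0.8, RS 0.9/0.9, both covariances 0.05, within the feasibility
bound of 0.08).

## Performance evaluation

`evaluate_methods()` aggregates per method and measure across replicates:
mean, empirical SE, bias against the *generating* $Sn_{IT}/Sp_{IT}$ (never
the plug-in expectation), and MSE. Conventions, each of which was a
genuine choice:

* **Empirical SE** is the standard deviation of the replicate estimates
  (the Morris et al. simulation-study convention), not the SE of their
  mean.
* **MSE decomposition.** With the $n$-denominator variance,
  $\mathrm{MSE} = \mathrm{bias}^2 + \widehat{se}^2(m-1)/m$ holds exactly
  per stratum and is asserted as a test.
* **Illogical estimates are included** in the aggregates by default and
  counted in `n_illogical`. Inclusion is what lets a low-prevalence
  stratum's mean explode to astronomically large values — the honest
  signal that the correction has broken down there. `exclude_illogical`
  exists for sensitivity analyses; both counts are always reported so
  either convention can be recovered.
* **Degenerate replicates** (a zero margin or zero correction denominator
  at small $n p$) are dropped *for that method only* and counted in
  `n_dropped`; the source material is silent on this, and dropping with an
  explicit count is the only option that neither fabricates a value nor
  hides the event.

`sample_size_sweep()` and `prevalence_sweep()` run the evaluation over
grids (prevalence grid 0.01–0.99 by 0.01 by default; the endpoints 0 and 1
are excluded as degenerate multinomials). `export_summary()` writes the
long-format CSV used for plotting elsewhere; no plotting engine is
included by design.

## What the simulations establish

With seeds fixed in the test suite, scenario one at $n = 1000$, 200
replicates: the Staquet bias is within Monte-Carlo tolerance of zero for
both measures; the Brenner sensitivity bias magnitude exceeds 0.1 while its
specificity bias stays below 0.05; the classical sensitivity bias is
smaller in magnitude than Brenner's. Across prevalence, the Staquet mean
sensitivity stays within Monte-Carlo tolerance of the truth on
$[0.1, 0.9]$, the unadjusted and Brenner sensitivities rise monotonically
toward the truth as $p \to 1$ (and their specificities improve as
$p \to 0$), and at $p \le 0.02$ illogical Staquet estimates occur and are
surfaced in `n_illogical`. The published curves themselves are not
reproducible point-for-point (unknown seeds); these property checks, at the
stated scenario parameters, are the reproducible content.

## Clinical case studies

Five fixtures ship in `inst/extdata/clinical_case_studies.csv`: the HRA
cytology vs punch biopsy table (reference 0.74/0.91) and four
fluorescence-device vs visual-inspection tables for non-cavitated
(reference 0.796/0.799) and dentine (0.786/0.995) caries. The dental
counts were digitised from garbled typeset rows by enforcing consistency
with the printed margin totals (e.g. the LFpen non-cavitated positive row
must be 241/6 to satisfy column totals 351/32), and every fixture is
re-validated against those totals at load time. Two documented
discrepancies in the source are reported as computed, not as printed: the
HRA corrected prevalence (computed 0.227, printed 0.27) and its sample
prevalence (62/261 = 0.2375, printed 0.23).

## Numerical notes and limitations

* Tolerances: the Staquet/Gart–Buck equivalence is asserted at $10^{-9}$
  absolute; plug-in recovery on expected-count tables at $10^{-8}$;
  analytic identities at $10^{-12}$.
* Expected-count (fractional) tables are supported via
  `contingency_table(..., fractional = TRUE)`; observed tables must be
  whole counts.
* All methods assume the reference accuracy is *known exactly*;
  uncertainty in $(Sn_{RS}, Sp_{RS})$ propagates into the corrections and
  is not modelled here.
* Conditional dependence breaks all three corrections (they were derived
  under independence); the dependence scenario exists to demonstrate this,
  not to fix it. Latent class approaches, Staquet's second estimator pair
  (perfect specificities) and Brenner's dependent-tests pair are out of
  scope.
* Estimates are never clamped and illogical counts are never masked;
  anything that looks like an impossible number in the output is a finding
  about the method, not a bug in the arithmetic.
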