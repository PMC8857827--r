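---
title: "Customized versus table-based growth standards for predicting neonatal undernutrition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Customized versus table-based growth standards for predicting neonatal undernutrition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(customgrowth)
```

## The problem

In hypertensive disorders of pregnancy (HDP) the fetus is at elevated risk of
placental growth restriction, and clinical management hinges on identifying
fetuses that are small for gestational age (SGA, weight below the 10th
centile). Two families of growth standards compete for this job:

* **population (table-based) standards** — a sex-by-gestational-age grid of
  weight centile parameters estimated on a reference population; and
* **customized standards** — a per-pregnancy expected-weight curve built from
  maternal anthropometrics and fetal sex.

`customgrowth` implements both behind one interface, classifies neonatal
nutritional status from sex- and gestational-age-specific body-mass-index
(BMI) and ponderal-index (PI) references, and compares the two size
classifications as diagnostic tests for neonatal undernutrition.

## The customized standard

The ideal weight at 40 weeks (term optimal weight, grams) is linear in the
maternal covariates:

$$W_{40} = 1407.501 + 4.087\,\mathrm{age_y} + 6.506\,\mathrm{weight_{kg}}
 + 8.716\,\mathrm{height_{cm}} + 150.375\,[\mathrm{male}]$$

The expected weight at gestational age $t$ (decimal weeks) scales $W_{40}$ by
a cubic proportionality curve on the percent scale:

$$f(t) = 299.1 - 31.85\,t + 1.094\,t^2 - 0.01055\,t^3$$

so that $\hat W(t) = W_{40} \cdot f(t)/100$. A weight $w$ is converted to a
z-score through a fixed coefficient of variation,
$z = (w/\hat W(t) - 1)/\mathrm{CV}$ with $\mathrm{CV} = 0.12$, and the
centile is $\Phi(z)\times 100$.

Numerical choices:

* **The polynomial is used raw.** $f(40) = 100.3$, not 100. Renormalizing
  would be tidier but would break the published worked values (e.g.
  $f(34) = 66.21$), so the ~0.3% excess at term is accepted as the model's
  own behaviour.
* **Gestational age is continuous** (decimal weeks) for the polynomial; no
  flooring to completed weeks. Valid range \[20, 44\]; outside it the
  functions raise an error rather than extrapolate.
* **Sex is an enum** (male = 1, female = 0 internally); bare integers from
  files are decoded through one strict function to prevent inversion bugs.
* **Centile ties** at exactly the 10th or 90th centile classify as AGA
  ("between the 10th and 90th" read as inclusive); similarly exact-10th/90th
  nutrition centiles are "normal".

The prenatal classification uses the estimated fetal weight (EFW) at the
scan gestational age; a birthweight-at-birth mode is available
(`run_config(use_efw = FALSE)`), since the two gestational ages differ by up
to two weeks. EFW can be computed from biometry with a Hadlock-type log10
regression whose coefficients are configuration data
(`hadlock_coefficients()`), because they are not part of this package's
contribution.

## The table-based standard

`table_standard()` wraps any sex-by-gestational-age grid of location/scale
parameters (grams); the centile is $\Phi((w - \mu)/\sigma)\times 100$. Grids
are interpolated **linearly** between completed-week rows (the simplest
defensible choice; no spline fitting), and lookups outside the grid error
rather than extrapolate. The file format reserves an optional `skew` column
so a three-parameter published table can drop in later.

The packaged table (`demo_population_standard()`) is **synthetic**: term
medians 3250 g (male) / 3100 g (female) scaled by the same proportionality
curve, scale = 13.5% of location. Those values were chosen once, before any
acceptance measurement, to emulate the qualitative behaviour of a
multiethnic newborn standard — a lower median and wider spread than the
customized model predicts for the emulated population — and were never
tuned. No published standard's parameters are redistributed; a genuine table
can be supplied via `read_reference_table()`.

## Neonatal nutrition

BMI $= \mathrm{weight_{kg}}/\mathrm{length_m^2}$ and ponderal index
$= 100\,\mathrm{weight_g}/\mathrm{length_{cm}^3}$ are referenced against
embedded sex-by-completed-week tables (32–42 weeks) of means and SDs; the
centile is again $\Phi(z)\times 100$ with the exact per-row parameters as
printed (no pooling or smoothing across weeks — the reference's own choice
is unknown, so the printed rows are taken at face value). Gestational age at
birth is floored to completed weeks, the obstetric convention, because the
tables have integer-week rows while birth timing is continuous.

Undernourished is below the 10th centile; overnourished (above the 90th) is
flagged and **excluded from the undernutrition diagnostics**, as is any
record born outside the 32–42-week coverage (flagged and counted, never
silently dropped).

## Diagnostics

With SGA as the exposed group and AGA as non-exposed (LGA excluded), against
undernourished/normal outcomes:

* sensitivity, specificity, PPV, NPV with **Clopper–Pearson exact** CIs —
  exact intervals are defensible at the small positive counts these cohorts
  produce;
* LR± and the diagnostic odds ratio with log-normal CIs
  (DOR $= \mathrm{LR}^+/\mathrm{LR}^- = (tp\cdot tn)/(fp\cdot fn)$);
* Youden index $J = \mathrm{sens} + \mathrm{spec} - 1$ with a **seeded
  multinomial bootstrap** CI (2000 resamples) by default and a delta-method
  alternative — the reference analyses do not state their Youden CI method,
  so this is a documented reproduction caveat;
* relative risk with the Katz log-method CI, and the **Altman–Bland**
  comparison of two RRs (z-test on the log-scale difference). Note the test
  treats the two RRs as independent even when both come from the same
  cohort; this matches common published practice and is kept as the default,
  with the paired McNemar machinery available for the comparisons where
  pairing is well-defined;
* **McNemar** tests compare the two standards' sensitivity (on the
  outcome-positive subset) and specificity (outcome-negative subset): exact
  binomial below 25 discordant pairs, continuity-corrected chi-square above —
  a common convention, as the threshold is not specified by the sources this
  design follows;
* the chi-square comparison of SGA/LGA frequencies is Pearson without
  continuity correction, again deliberately reproducing the common
  (independence-assuming) practice; the statistically preferable paired test
  is `mcnemar_test()`.

Zero denominators never produce silent `NaN`: the metric is `NA` and listed
in the summary's `undefined` element. Continuity corrections (+0.5 to all
cells) are strictly opt-in and always emit a message.

## The synthetic cohort generator

`simulate_cohort()` states a world and sticks to it. Defaults emulate an HDP
cohort's marginals: maternal age $\mathcal N(32.6, 5.3^2)$ years, height
$\mathcal N(162.02, 6.16^2)$ cm, pregestational BMI
$\mathcal N(29.93, 6.52^2)$ kg/m² (maternal weight is derived from BMI and
height so covariates stay physiologically coherent), 49.2% male, gestational
age at birth $\mathcal N(37.7, 2.2^2)$ weeks truncated to \[32, 42\] (the
nutrition references' coverage). Truncated normals use inverse-CDF sampling,
so cohorts are exactly reproducible from the seed; replicate $r$ of a
Monte-Carlo run uses `seed + r`.

Two standard-normal latents drive the outcomes: $Z_w$ (fetal growth) and
$Z_n$ (nutrition), coupled by a Gaussian copula with correlation $\rho$
(default 0.6 — illustrative, not an estimate; the true coupling in HDP is
unknown). Then

* birthweight $= \hat W(t_{birth})\,(1 + \mathrm{CV}(Z_w + s))$, where $s$
  is `hdp_shift`, a mean shift in CV units mimicking placental restriction
  (0 by default; −0.8 in the stressed scenarios);
* EFW $= \hat W(t_{scan})\,(1 + \mathrm{CV}(Z_w + s))(1 + \varepsilon)$ with
  $t_{scan} = t_{birth} - U(0,2)$ and $\varepsilon \sim
  \mathcal N(0, 0.07^2)$ — 7% is the commonly cited random error of
  ultrasound EFW; neither source states a value, so it was fixed once here;
* birth length is solved so the configured nutrition index (BMI by default)
  lands exactly at $\Phi(Z_n)$ under the packaged reference for the
  newborn's sex and completed week; the other index is then induced, not
  controlled. Non-physical lengths (outside 30–65 cm) trigger a logged
  resample of $Z_n$.

What a green test does and does not establish: the generator reproduces the
*marginal* structure and a tunable size–nutrition coupling, so it can verify
nominal coverage (10% SGA / 10% undernourished when unshifted), copula
calibration, and the *direction* of the customized-vs-table sensitivity gap
under mis-specification. It does not emulate longitudinal growth
trajectories, Doppler physiology, measurement digit preference, or the real
(unknown) joint distribution of covariates — so quantitative agreement with
any published cohort's metric values is out of reach by design, and is not
asserted anywhere.

## Calibration checks and their stated worlds

* **Nominal coverage**: cohorts generated from each standard recover
  10% ± 2 Monte-Carlo SE SGA and undernutrition rates at $n = 10^4$.
* **Null calibration of the Altman–Bland test**: two independent cohorts per
  replicate with identical true RR = 1 (exposure 20%, outcome 10%), 2000
  replicates. The per-cohort size was fixed a priori at $n = 1000$ because
  the test is asymptotic: a calibration check is meaningful only in the
  regime where the log-normal approximation is intended to hold (expected
  ≥ ~20 events per exposure group).
* **Directionality**: with $\rho = 0.6$ and shift −0.8 at $n = 226$, the
  generating (customized) standard's sensitivity exceeds the mis-specified
  table's in > 95% of 500 replicates. The assertion is on the ordering, not
  a magnitude.

## Known limitations

* The Youden CI method and the exact/asymptotic McNemar switch are
  conventions, not reproductions of an identified original choice.
* The packaged population table is a synthetic stand-in; conclusions about
  any real published standard require loading that standard's table.
* Published cohort-level 2×2 tables for this problem are generally not
  printed, so only operating-point identities (LR±, DOR, Youden from
  sensitivity/specificity) are exactly reproducible; cohort-level CIs are
  not, and the package does not pretend otherwise.
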