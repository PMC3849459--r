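---
title: "Recommending laboratory tests from co-occurrence counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recommending laboratory tests from co-occurrence counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(labrec)
```

## The problem

Clinical laboratory information systems accumulate large volumes of order
records: per visit, a patient identifier, a service date and the codes of the
tests performed. Tests are not ordered independently — a clinician suspecting
diabetes will typically order an HbA1c *and* a fasting glucose together, so
the two codes co-occur far more often than chance. `labrec` exploits exactly
this structure: given the tests a patient has already taken, it ranks every
other test in the universe by how strongly the historical co-occurrence
pattern suggests it should also be taken.

The only inputs consumed are the patient number, the service date and the
test code; results, demographics and normal ranges are deliberately out of
scope.

## The weighting function

Let $T = \{t_1, \dots, t_M\}$ be the test universe and let a *case* (by
default one patient-visit) have taken the set $T_j$ with $k = |T_j|$. For a
candidate test $t_0 \notin T_j$, treat "$t_0$ taken" vs "$t_0$ not taken" as
the two classes of a naive Bayes classifier whose features are the taken
tests. With count-ratio estimates from training data,

$$\alpha = \Pr(t_0), \qquad
  \gamma_i = \Pr(t_i), \qquad
  \beta_i = \Pr(t_i \mid t_0),$$

the posterior log-odds of the "taken" class given the evidence $T_j$ is

$$w(t_0, p_j) \;=\; \log\frac{\alpha}{1-\alpha}
  \;+\; \sum_{i \in T_j} \log\frac{\beta_i\,(1-\alpha)}{\gamma_i - \alpha\beta_i},$$

because $\Pr(t_i \mid \neg t_0) = (\gamma_i - \alpha\beta_i)/(1-\alpha)$ by
total probability. Candidates are ranked by $w$, descending; exact ties break
by test code, ascending, so rankings are fully deterministic.

### Exact vs literal form

A simplified version of this score is often quoted as

$$w(t_0, p_j) \;=\; (k-1)\,\log\frac{1-\alpha}{\alpha}
  \;+\; \sum_{i \in T_j} \log\frac{\beta_i}{\gamma_i - \beta_i}.$$

Working the algebra through shows this simplification is not faithful to the
posterior-odds derivation on two counts: the prior coefficient ($(k-1)$ with
a flipped sign rather than $+1$; the two agree only at $\alpha = 1/2$), and
the evidence denominator ($\gamma_i - \beta_i$ rather than
$\gamma_i - \alpha\beta_i$), which goes *negative* precisely for positively
associated test pairs — the pairs the method lives on. `labrec` therefore
exposes both forms behind `weight_config(evidence_mode = )`:

* `"exact"` (default) — the derivation-consistent score above. It is
  verified in the test suite, to $10^{-9}$, against a brute-force posterior
  computed from products of the raw count probabilities, on a hundred small
  random instances.
* `"literal"` — the simplified form exactly as usually printed, with
  `prior_term()` supplying $(k-1)\log\frac{1-\alpha+\theta}{\alpha+\theta}$
  and the $\gamma-\beta$ denominator floored at `epsilon` where it is not
  positive.

Both produce complete rankings; only `"exact"` carries the Bayesian
interpretation. The sum runs over the case's taken tests only: "not taken"
events have no counts in the training matrix, and under naive-Bayes
independence an uninformative feature contributes a zero term anyway.

### The training matrix

All probabilities are ratios of counts held in a single symmetric $M \times M$
matrix built once from the training cases: off-diagonal cell $(a, b)$ counts
the cases containing both $a$ and $b$; the diagonal holds the marginal count
of each test (a convention that also makes $\beta = 1$ when conditioning a
test on itself). Counts are case-level and binary — a visit contributes at
most 1 to any cell, since every probability is defined over cases, not
records. The matrix serializes to a plain-text sidecar
(`write_training_matrix()`) with a bit-exact round trip, so evaluation never
needs to touch the raw records twice.

## Smoothing

Raw $\beta_i$ is zero whenever a pair was never seen together, which the log
turns into $-\infty$; and a candidate unseen in training has $\alpha = 0$.
Smoothing gives these unseen events non-zero mass. For $\beta$
(`smoothing_config(method = , param = )`, parameter in $[0,1]$):

| method | formula | parameter |
|---|---|---|
| Jelinek–Mercer | $(1-\lambda)\beta + \lambda\gamma$ | $\lambda$ |
| Dirichlet prior | $(\beta + \mu\gamma)/(1+\mu)$ | $\mu$, pseudocount normalized by the conditioning count |
| absolute discounting | $\max(c-\delta,0)/c_0 + \delta\gamma$ | $\delta$, applied to the raw counts $c, c_0$ |

All three return the raw $\beta$ at parameter 0 and protect zeros for any
positive parameter. Jelinek–Mercer and Dirichlet stay between $\beta$ and
$\gamma$; the discounting form is used as printed and may slightly exceed 1
(it is not renormalized — only the induced ranking matters, and
renormalizing would change no order). When the conditioning count is zero,
discounting degrades to the pure $\delta\gamma$ fallback, which is how every
smoother handles a candidate absent from training.

The prior log-odds is smoothed additively (Laplace):
$\log\frac{\alpha+\theta}{1-\alpha+\theta}$ with $\theta \in [0,1]$;
$\theta > 0$ keeps it finite at $\alpha \in \{0, 1\}$.

Defaults are Jelinek–Mercer with $\lambda = 0.2$ and $\theta = 0.5$ — the
region where top-X accuracy is typically best and stable on co-occurrence
data of this kind; both are one-line overrides and `parameter_sweep()`
regenerates the sensitivity curve for any data set.

## Evaluation framework

Because no interaction with clinicians is available, evaluation is
leave-one-out over visits:

1. **Split** (`split_cases()`): cases are partitioned at random into training
   and validation sides. The partition is over *patients*, so all visits of
   one patient land on one side; the training side is sized as close as
   possible to `round(train_fraction * N)` cases (exactly that when each
   patient has one case — both constraints cannot always hold together
   otherwise).
2. **Remove a label** (`remove_labels()`): per validation case one test is
   removed uniformly at random as the *golden standard*; the rest form the
   input. Cases with fewer than two tests are excluded (removal would leave
   no evidence) and counted.
3. **Rank** (`rank_candidates()`): candidates are the universe minus the
   input's tests — the removed test is therefore always a candidate. Input
   tests never seen in training contribute no evidence term and are skipped
   with a diagnostic count.
4. **Score** (`correct_rate()`): `CorrectRate_X` is the fraction of
   validation cases whose golden standard appears in the top $X$ of the
   ranking ($X \in \{1, 3\}$ by default, configurable). The top 3 contain
   the top 1, so `CorrectRate_1 <= CorrectRate_3` always.

`run_experiment()` chains the four stages under two independent seeds (split,
label choice), making each randomization separately reproducible;
`parameter_sweep()` repeats it over a smoothing-parameter grid with the seeds
held fixed so only the parameter varies.

## The synthetic generator

Real order records are protected health information, so the package ships a
generator (`synthetic_config()`, `generate_cases()`) that emulates the one
property the method relies on: *panels* of tests coupled through latent
conditions. Each of `n_conditions` conditions owns a disjoint panel of
`panel_size` tests; per visit each condition is present with `p_condition`,
each test of a present panel fires with `p_panel_test`, and every other test
fires with `noise_rate`. Empty visits are redrawn. Defaults — 500 visits,
$M = 20$ tests, 4 panels of 5, `p_condition = 0.5`, `p_panel_test = 0.9`,
`noise_rate = 0.02` — give strongly recoverable structure at trivial run
time. With `n_conditions = 0` the generator produces independence data, the
calibration baseline: any ranking is then uniform with respect to the held
out label, and the top-1 hit rate must sit at the analytic chance level
$X/(M-k)$ per case (`random_baseline()`), which the test suite checks to
within three Monte-Carlo standard errors.

What the generator does *not* model: test results and demographics,
overlapping panels, temporal dynamics across a patient's visits, and the
long-tailed code frequencies of real laboratory data (hundreds of codes,
many rare). Passing tests on synthetic data therefore demonstrate the
pipeline's correctness and its ability to recover planted associations — not
clinical performance on real records.

### Problem sizes used in the checks

The recovery check runs the generator defaults over 10 seeds: mean
`CorrectRate_3` is about 0.95 against a mean per-case chance level of about
0.33. Note a bound of the setting: with $k$ input tests the chance level is
$3/(M-k)$, about $1/4$ at these sizes, so no ranker can exceed it by more
than roughly fourfold — ratio-to-chance comparisons at small $M$ saturate
quickly. The training-fraction study (fractions 0.4/0.5/0.6, 30 seed pairs,
shared seeds across fractions) runs at 60 visits: that keeps the training
matrix on the rising part of its learning curve, where more training data
demonstrably helps; at 500 visits the counts saturate at every fraction and
the curve is flat. Mean hit rates are compared with a 0.01 tolerance on each
adjacent fraction, the Monte-Carlo noise floor of the study.

## Numerical choices

* Natural logarithms throughout; the base only rescales weights and cannot
  change a ranking.
* Any log numerator or denominator below `epsilon` (default $10^{-12}$) is
  floored there, so every weight is finite for every configuration with
  $\theta > 0$; floor events are counted on the result and reported under
  `options(labrec.verbose = TRUE)`.
* Ranking ties break lexicographically by test code (radix order, locale
  independent).
* Degenerate inputs fail loudly and early: empty record sets, cases outside
  the universe, a candidate already taken, $\theta = 0$ with
  $\alpha \in \{0,1\}$, an all-singleton validation set.

## Limitations

* The naive-Bayes independence assumption is knowingly wrong for panel
  data — it is what makes the score cheap, and in practice rankings survive
  it — but the weights are not calibrated probabilities; only their order is
  contractual.
* The training matrix is rebuilt from scratch per experiment; there is no
  incremental update path.
* Patient-level context beyond the current visit's tests (age, sex, results,
  visit history) is not used.
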