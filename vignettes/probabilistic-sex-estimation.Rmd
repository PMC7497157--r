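---
title: "Probabilistic sex estimation: models, PMarks, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic sex estimation: models, PMarks, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteosex)
```

## The problem

Metric sex estimation builds a classifier from a reference sample of
individuals of known sex and continuous skeletal measurements, then applies
it to unknown cases. Two families dominate the literature: linear
discriminant functions (LDF), usually published as an equation plus a single
cutoff, and binomial logistic regression, which returns a class probability
directly. Because sexual dimorphism is a continuum with overlap between the
sexes, a bare cutoff overstates certainty: scores barely past the cutoff
carry posteriors barely above 0.5. `osteosex` implements both families, a
common evaluation harness, and the bootstrap PMark procedure that restores
graded reporting to discriminant equations.

## The discriminant model

For sexes F and M with measurement vectors x, the two-group discriminant
direction is $\Sigma_w^{-1}(\mu_M - \mu_F)$, where $\Sigma_w$ is the pooled
within-group covariance with divisor $n_F + n_M - 2$. Two conventions pin
down the otherwise arbitrary affine freedom of the score:

- **Scale**: coefficients are rescaled so the pooled within-group variance
  of the score is exactly 1. Cutoffs and PMarks are only comparable across
  bootstrap refits on such a standardized axis, so the scaling is enforced,
  not optional.
- **Location**: the intercept places the midpoint of the two group score
  means at 0, and the sign convention puts males positive, so the classical
  rule is female < 0 < male and the cutoff score 0 corresponds to posterior
  0.5 under equal priors.

Posteriors are plug-in: each sex's scores are treated as unit-variance
normal around its group score mean, and Bayes' rule with priors
$(\pi_F, \pi_M)$ gives $P(M \mid D) \propto \pi_M\,\phi(D - \bar D_M)$.
Under equal priors this is a logistic function of $D$ with slope
$\bar D_M - \bar D_F$, which yields the closed-form inversion used
throughout: the score at which $P(M \mid D) = p$ is
$\ln\!\big(p/(1-p)\big) / (\bar D_M - \bar D_F)$. The default prior is
equal (uninformative), the usual choice when a cemetery or case population
offers no defensible sex ratio; informative priors shift the 0.5-posterior
point off score 0, and the package then computes it rather than assuming it.

Model assumptions (multivariate normality within sex, homogeneous
covariances, no gross outliers or collinearity) are checked by
`check_assumptions()`: VIF ($1/(1-R_j^2)$, sexes pooled), Box's M with the
$\chi^2$ approximation on $(k-1)p(p+1)/2$ degrees of freedom, classical
Mahalanobis distances against the $\chi^2_{p,0.975}$ quantile (reported both
pooled and within sex, since either convention appears in practice), and a
Box–Tidwell-style logit-linearity screen.

## The logistic model

`fit_logr()` fits $P_1 = 1/(1 + e^{-(b_0 + \sum b_i x_i)})$ by
Newton–Raphson/IRLS, with females coded 1 by default so the equation returns
P(Female) — the convention of most published humeral equations — and the
coding recorded in the model file so either convention can be loaded.
Convergence is declared when the largest coefficient step falls below 1e-8
or the relative log-likelihood change below 1e-10, capped at 100 iterations.
AIC counts the intercept as a parameter ($2k - 2\log L$ with $k = p + 1$).

Single skeletal measurements can (quasi-)separate a modest sample. Rather
than letting coefficients drift toward infinity, the fitter stops as soon as
any fitted |linear predictor| exceeds 30, warns, and returns
`converged = FALSE`. The sign of the linear predictor is still a valid
classifier in that state, and leave-one-out evaluation uses it, counting the
affected folds in `separated_folds`. The threshold 30 is far beyond any
probability resolution that matters (plogis(30) ≈ 1 − 1e-13) while
preventing overflow-scale coefficients.

## PMarks

A published equation plus cutoff cannot give future users posteriors; the
PMark procedure converts posterior levels into additional score cutoffs they
*can* use. For a level p (0.80 by default; 0.80/0.90/0.95 via
`multilevel_pmarks()`):

1. resample individuals with replacement (1000 iterations by default;
   unstratified, since the whole sample is the resampling unit — a
   stratified option exists);
2. refit the discriminant on the standardized axis;
3. find the score at which the replicate's posterior equals p;
4. report the mean (and SD) over replicates, one negative mark for females
   and one positive for males.

Step 3 is the one genuinely open design point. "The score of an individual
whose posterior is p" is not directly usable — observed individuals land
exactly at p with probability zero — so the default reads it as the
analytic inversion of the replicate's plug-in posterior, which is exact and
deterministic given the replicate. An interpolation variant
(`method = "interpolate"`), which linearly interpolates between the two
resampled individuals bracketing p, is provided for comparison; the two
agree up to sampling noise, but the interpolated variant is noisier and can
be undefined in replicates whose observed posteriors do not bracket p
(such replicates are dropped from its mean).

Because every replicate is midpoint-centred, the analytic cutoffs at
different levels share each replicate's score-mean separation, so PMark
magnitudes across levels are exactly proportional to the log-odds of the
levels, and female/male marks are exact mirror images. Nesting
(|PMark(0.8)| < |PMark(0.9)| < |PMark(0.95)|) follows by construction.

Resamples in which a sex retains fewer than two distinct individuals, or
whose pooled covariance is singular, are redrawn (counted in the result;
more than 10 × n_boot redraws aborts). The bootstrap is seeded and
bit-reproducible; the CLI makes the seed mandatory.

Classification with PMarks uses the five-category scale: score ≤ PMark_F →
F; between PMark_F and 0 → probable F; exactly 0 → indeterminate; between 0
and PMark_M → probable M; ≥ PMark_M → M. Boundary scores go to the stronger
category, and ties in posterior classification go to M (both events have
probability zero for continuous data; the rules just make behaviour
deterministic).

## Evaluation

`loocv()` refits on n−1 individuals and predicts the held-out case, for
every case; the procedure is deterministic and order-invariant. Accuracy is
reported at each requested decision probability: cases whose winning
probability is below the level are set aside as indeterminate and accuracy
is computed among the retained. `subthreshold_accuracy()` reports the
complementary view — how the plain 0.5 rule fares on exactly the cases a
threshold would set aside — so retained + sub-threshold always partitions
the sample.

Two predictive indices summarize calibration as well as accuracy, with
P the LOOCV probability of the class coded 1 and Y the 0/1 outcome:

- B index: $B = 1 - \tfrac1n\sum_i (P_i - Y_i)^2$. Note that the
  uninformative predictor P ≡ 0.5 gives B = 0.75, not 0; the formula is
  implemented as stated even though chance-level language sometimes
  suggests 0.
- Q index: $Q = \tfrac1n\sum_i \big(1 + \log_2 P_i^{Y_i}(1-P_i)^{1-Y_i}\big)$,
  which is 0 at chance, 1 for perfect confident prediction, and negative
  when worse than chance. Probabilities are clamped to [1e-15, 1 − 1e-15]
  before the logarithm so one separated fold cannot produce −Inf; the
  clamp is visible only when a fold predicts with essentially certainty
  and is wrong.

Both indices are invariant to swapping the class coding together with
P → 1 − P.

`sample_size_experiment()` draws subsamples of increasing size (default 10
up to n) with replacement and computes LOOCV accuracy *within* each
subsample. Whether the original design evaluated subsample models
internally or against the full sample is not documented anywhere we know
of; internal LOOCV is the only self-contained reading and is what the
package does — users comparing against externally-evaluated curves should
expect the internal curve to be noisier at small n. The default of 100
replicates per size stabilizes the mean while keeping the experiment
desk-scale (about 40 s for sizes 10–84 on one CPU). Degenerate draws (a sex
with fewer than 2 distinct individuals or fewer than 3 records, or a
subsample whose LOOCV cannot be fit because duplication makes a fold
singular) are redrawn and counted.

`welch_mean_difference()` wraps Welch's unequal-variance t test
(Satterthwaite df) and reports the M − F difference with a 90% CI by
default, the conventional descriptive companion to dimorphism tables.

## The synthetic generator

`default_population()` encodes a documented 19th-century Dutch humeral
reference series: 48 females and 36 males; per-sex means/SDs (mm) of
max length 311.8 (19.49) / 339.4 (19.33), head diameter 41.62 (2.312) /
49.34 (2.781), and epicondylar breadth 55.31 (3.282) / 63.75 (4.819); ages
from per-sex normals (48.73, SD 18.51; 52.89, SD 21.01) truncated to 19–84
years, carried for realism only. The series' inter-measurement correlations
are not published; the generator uses 0.5 for every pair — a moderate value
consistent with the reported VIFs of about 1.4–1.7 — and states openly that
this is a modelling choice, configurable via `default_population(correlation =)`.

What the generator emulates: per-sex multivariate normal measurements with
realistic dimorphism, the sample-size imbalance, and the positivity and
completeness invariants of real input. What it does not: measurement error
and interobserver variation, left/right substitution effects, non-normal or
mixture-shaped trait distributions, and the true correlation structure of
any particular skeletal series. Passing tests on synthetic data therefore
demonstrate correctness of the estimators and procedures under the stated
model, not the accuracy figures any real collection would produce; with
correlation fixed at 0.5 the two-variable models separate the synthetic
sexes somewhat more cleanly than the original series, so synthetic
accuracies and PMark magnitudes differ from the published ones in the
expected directions.

`generate_known_model_sample()` is the recovery harness: it draws data for
which a stated logistic law (sex Bernoulli given Gaussian covariates) or a
stated discriminant law (per-sex Gaussians, shared covariance, exact
standardized separation δ) is true, so fitters can be checked for
consistency (coefficients within 3 SE at n = 50,000) and the PMark pipeline
against the closed form ln(p/(1−p))/δ. This end-to-end recovery is the
package's primary self-test.

## Numerical choices and degenerate inputs

- Pooled covariance divisor n − 2; singularity guarded by a reciprocal
  condition number check (rcond < 1e-12 errors; no silent regularization).
- IRLS weights floored at 1e-12; the log-likelihood uses the stable form of
  log(1 + e^η) for large |η|.
- Model JSON is written with 17 significant digits so write/read round-trips
  are bit-exact; rounded published coefficients are a user's choice, never
  the serializer's.
- CSV ingestion requires a header, auto-detects comma/semicolon/tab,
  accepts female/f/0/w and male/m/1 (case-insensitive), applies listwise
  deletion over the selected variables only (no imputation), and errors on
  non-positive measurements, duplicate ids, unparseable sex values (with
  row numbers) or an empty sex group. All measurements are assumed mm; no
  unit conversion is attempted.
- LOOCV folds that cannot be fit propagate an error naming the fold;
  logistic folds that separate are flagged but classified by sign.

## Test and benchmark scale

The test suite builds all fixtures in code: toys of 6–20 individuals for
hand-checked oracles (pooled-covariance arithmetic, a grid-search likelihood
maximizer, a frozen step-by-step Box's M and Welch computation), the default
84-individual synthetic series for integration checks, n = 10,000 draws for
moment-convergence gates and n = 50,000 for parameter recovery, and
bootstrap runs of 40–200 iterations where only Monte-Carlo means are
needed. `scripts/acceptance.R` uses the full study conditions: the default
84-individual population, 1000 bootstrap iterations for PMarks, and the
sample-size experiment at 100 replicates per size. MASS's discriminant
implementation and `stats::glm` serve as independent cross-checks in the
tests; the package's own fitters are the implementation everywhere.

## Known limitations

- Two groups only; no QDA, nearest-neighbour discriminants, probit links,
  ordinal traits, stepwise selection, or k-fold alternatives to LOOCV.
- PMarks are defined for discriminant scores only; logistic equations
  already publish probabilities, which is precisely their advantage.
- The robust (MCD-style) outlier option is not implemented; the classical
  Mahalanobis screen is sensitive to the very outliers it hunts.
- Reproducing a published benchmark requires that study's reference data;
  summary moments are not sufficient to reconstruct individual-level
  results, and the package does not pretend otherwise
  (see `reproduce_reference_results()`).
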