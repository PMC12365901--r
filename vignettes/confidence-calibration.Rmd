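---
title: "Confidence-informed IDH calls: model, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confidence-informed IDH calls: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idhconf)
```

## The problem

IDH (isocitrate dehydrogenase) mutation status is a central molecular marker
in glioma: it stratifies diagnosis, prognosis and, increasingly, therapy.
Voxel-wise segmentation networks can predict it non-invasively from MRI by
labelling every tumor voxel as IDH-mutant (label 1) or IDH-wildtype
(label 2), against background 0. Two gaps remain between such a network's
raw output and a clinically usable call:

1. a per-voxel labelling must be reduced to one subject-level call, and
2. the call needs a *calibrated* confidence — a probability a clinician can
   take at face value, not a softmax score shaped by the training
   distribution.

`idhconf` implements the post-network half of that pipeline. It takes
per-fold label volumes (or pre-tallied voxel counts), and produces calls
plus calibrated confidence scores, evaluated under a strict two-stage
held-out protocol.

## From voxels to a subject call

With a `k`-fold cross-validated network there are `k` candidate labellings
per subject. They are combined voxel by voxel: the final label is the
plurality class over \{0, 1, 2\} across folds, exact ties resolved by the
fixed priority 2 > 1 > 0 and counted. The priority prefers calling tumor
over background and the prevalent wildtype class over the rare mutant one;
any deterministic rule would do, but this one is stated, logged, and
surfaced in the output rather than left to implementation accident.

From the ensembled volume the whole-tumor counts `(n_mutant, n_wildtype)`
give the **wildtype voxel fraction**

$$x = \frac{n_\mathrm{wildtype}}{n_\mathrm{mutant} + n_\mathrm{wildtype}},$$

and the subject is called wildtype iff `n_wildtype > n_mutant` — a majority
vote over voxel classes, equivalent to thresholding `x` at 0.5. An exact
50/50 tie is called wildtype (the positive and majority class) with
`tie_flag = TRUE`; ties are reported, never silently absorbed.

Everything downstream uses `x` as a *fraction in [0, 1]*. This is a real
modelling decision, not cosmetics: the logistic slope is scale-dependent,
and a zero-mean unit-variance prior is only "informative" when the
covariate lives on a bounded unit scale. Percent-scale input would make the
informative prior effectively flat. Percent I/O is converted at the
boundary.

## Calibrating the fraction into a confidence score

The calibration curve is the two-parameter logistic

$$P(y = 1 \mid x, \alpha, \beta) = \frac{1}{1 + e^{-(\alpha + \beta x)}},$$

with `y = 1` for IDH-wildtype (the positive class throughout; with that
convention recall and wildtype-class accuracy are the same number by
definition). Two fits of the same curve are provided:

* **LR** — maximum likelihood via `stats::glm`. Complete separation (a
  fraction threshold that splits the classes perfectly, under which the MLE
  diverges) is detected and flagged; the intended fallback is the Bayesian
  fit, whose priors regularize exactly this case.
* **BLR** — the posterior $p(\alpha, \beta \mid x, y) \propto
  \mathcal{L}(\alpha, \beta) \, N(\alpha; 0, \sigma^2) \, N(\beta; 0,
  \sigma^2)$, with the **informative** prior $\sigma^2 = 1$ (weights
  believed close to zero; regularizes the curve) and the
  **non-informative** prior $\sigma^2 = 1000$ (the data dominate; at large
  n the posterior concentrates at the MLE). The "1000" is a variance, not a
  standard deviation.

A Bayesian fit yields draws $\{(\alpha_s, \beta_s)\}$, and the reported
wildtype probability is the **posterior-predictive mean**
$\frac{1}{S}\sum_s \mathrm{logit}^{-1}(\alpha_s + \beta_s x)$. The mean —
rather than, say, the plug-in curve at the posterior mean — is the Bayes
estimate under squared-error loss, which is precisely the loss the Brier
score measures; the posterior median and a central 90% band are reported
alongside for transparency. The confidence in the *call* is the wildtype
probability when the call is wildtype and its complement otherwise, so it
is at least 0.5 whenever the call agrees with thresholding the probability.

### Posterior computation

The two-dimensional posterior is sampled by random-walk Metropolis:

* chains start at the posterior mode (BFGS on the log posterior);
* the proposal covariance is the inverse Hessian at the mode scaled by the
  classic $2.38^2/d$, with a global step-size factor adapted toward ~35%
  acceptance during warm-up;
* post-warm-up iterations are thinned 5:1 to tame random-walk
  autocorrelation;
* defaults: 4 chains, 1000 warm-up iterations, 2000 retained draws per
  chain, all seeded and reproducible.

Convergence is policed, not assumed: split-half R-hat must be below 1.01
for both parameters and effective sample sizes are reported. A fit whose
R-hat is still at or above 1.01 automatically doubles its draw budget (at
most twice, re-seeded deterministically); only after that does it raise a
non-convergence error carrying the diagnostics. For a smooth,
unimodal two-parameter posterior this sampler is entirely adequate;
gradient-based samplers would be overkill.

## Evaluation: the two-stage held-out protocol

Calibration curves are fitted **exclusively** on cohort A (the analogue of
a first held-out test group, TG-1) and evaluated on a disjoint cohort B
(the TG-2 analogue): no cohort-B datum influences any fit, so cohort B's
Brier score is an unbiased measure of calibration. Sharing a subject id
between cohorts is treated as data leakage and is a hard error listing the
offenders.

Four scoring methods are compared on cohort B by Brier score
$\frac{1}{n}\sum_i (p_i - y_i)^2$: the raw fraction `x` used as a
probability, LR, BLR(informative) and BLR(non-informative). Classification
quality is summarised by accuracy, per-truth-class accuracy, precision,
recall, F1 and midrank AUC (equivalent to the trapezoidal ROC area); since
every calibrated curve is monotone increasing in `x` whenever all posterior
slopes are positive, AUC is identical between raw and calibrated scores —
calibration changes probabilities, not ranks.

Multi-site overall cells are produced by count-weighted pooling
$\sum_i w_i v_i / \sum_i w_i$: site sizes for whole-cohort metrics,
truth-class counts for class-conditional metrics (wildtype counts for
precision/recall/F1, which are positive-class metrics). Full precision is
kept internally; rounding to one decimal happens only at the reporting
layer. The package also carries the published per-site table of the
reference multi-institution study so this arithmetic can be checked against
its printed overall cells; one printed cell (pooled mutant-class accuracy,
92.0) differs from the count-weighted arithmetic (91.9), and the package
reports the arithmetic.

## The synthetic cohort generator

The generator stands in for a trained network's outputs so every stage is
testable without MRI or GPU weights. Per subject it draws:

* a true label, wildtype with probability 1904/2481 (the composition of
  the reference 2,481-case cohort);
* a latent wildtype fraction from Beta(8, 2.5) for wildtype-truth subjects
  and Beta(2.5, 8) for mutant-truth — the two-sided concentration near 1
  and 0 reproduces the bimodal fraction histogram that makes the subject
  call easy and the raw fraction *overconfident in the middle*;
* a tumor size from log-normal(log 3000, 0.7) voxels;
* per-fold labellings: the base labelling assigns
  `round(fraction x size)` voxels label 2, and each fold flips each tumor
  voxel's class independently with probability 0.05, emulating fold
  disagreement.

The Beta and flip defaults were fixed once, from closed-form/large-sample
calculation, so that the default pipeline lands in the regime the method is
designed for — subject accuracy around 95–97% with the calibrated Brier
near 0.01–0.03 while the raw fraction's Brier is several times worse — a
qualitative echo of the reference study, never a reproduction claim. The
default cohort split is 1236 calibration subjects and 164 scored subjects,
mirroring the reference study's two held-out groups.

Randomness is split per subject from a prefix-stable seed stream: growing
the cohort never perturbs earlier subjects' draws, and one seed fixes the
entire pipeline bit-for-bit.

What the generator deliberately does **not** emulate: MRI intensities,
scanner and site effects, spatial error correlation within a tumor (flips
are independent across voxels and folds), per-site heterogeneity of the
fraction distribution, and any relationship between tumor size and class.
Tests passing on this cohort therefore validate the *pipeline arithmetic
and the calibration machinery*, not network performance on real images.
Blob geometry in emitted volumes (a filled ellipsoid at the volume center)
is likewise cosmetic — only counts matter downstream; it exists to exercise
the NIfTI path.

## Worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(seed = 1)      # simulate mode, 1236/164 split
res <- run_all(cfg, quiet = TRUE)
res
#> Two-stage held-out calibration
#>   cohort A: n=1236, accuracy 96.2%
#>   cohort B: n=164, accuracy 98.2%, AUC 1.00
#>   Brier on cohort B:
#>     raw                  0.0681
#>     lr                   0.0224
#>     blr_informative      0.0271
#>     blr_noninformative   0.0224
```

The ordering is the instructive part: the raw fraction, read as a
probability, is about three times worse calibrated than either fitted
curve, and the non-informative Bayesian fit tracks the
maximum-likelihood fit closely at this sample size while the informative
prior's shrinkage costs a little sharpness on a steep curve.

## Numerical and degenerate-case decisions

* Empty tumors (no voxel labelled 1 or 2) are excluded with a logged
  reason; fractions and votes are undefined for them by construction.
* Exact vote ties go to wildtype and are flagged; ensemble ties follow the
  2 > 1 > 0 priority and are tallied per subject.
* The likelihood is evaluated with an overflow-safe `log(1 + e^\eta)`;
  curve evaluation goes through `plogis`.
* Single-class cohorts make the curve unidentifiable (LR errors; AUC and
  precision are reported as undefined with a reason) rather than returning
  a number.
* Problem sizes in the shipped tests: parameter recovery at n = 5000,
  posterior coverage with 200 replicates of n = 500 under a reduced MCMC
  budget (2 chains, 500 + 500 draws, through the same code path), Brier
  consistency at n = 100 000, and the default 1236/164 pipeline.

## Limitations

* The calibration model has a single covariate; hierarchical or multi-site
  priors and additional covariates are out of scope.
* The Gaussian priors are shared by intercept and slope; nothing is claimed
  about heterogeneity of IDH status *within* a tumor — mixed voxel labels
  are treated purely as a fraction.
* Pooled metrics from per-site summaries are exact only for count-weighted
  averages; confusion-matrix pooling across cohorts is also available and
  preferred when record-level data exist.
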