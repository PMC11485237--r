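---
title: "Auditing subgroup fairness of clinical prediction models under distribution shift"
author: "fairshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing subgroup fairness under distribution shift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fairshift)
```

## The problem

Clinical risk models trained on one site's data routinely encode demographic
attributes (age, sex, race) in their learned representations, and can use
that information as a predictive *shortcut*: a correlation between group
membership and outcome that holds in the training distribution but has no
clinical basis. Two consequences matter for deployment:

1. **In-distribution (ID) unfairness.** Shortcut reliance manifests as
   subgroup gaps in class-conditional error rates. For a screening task the
   costly direction is *underdiagnosis* — falsely clearing ill patients —
   which is a false positive for a healthy-indicator task ("no finding") and
   a false negative for a disease-indicator task.
2. **Out-of-distribution (OOD) fairness failure.** The correlation backing
   the shortcut need not hold at a new site. A model selected to be fair
   in-distribution can become unfair after deployment, and vice versa, even
   while its aggregate discrimination (AUROC) transfers well.

fairshift packages the audit machinery for both halves: per-group metrics
and gaps with uncertainty, hypothesis tests for *which* distributions
shifted, a linear probe quantifying how much demographic information a
representation encodes, an exact decomposition of the OOD gap, and an
oracle-regret harness for fairness-aware model selection. A seeded synthetic
cohort generator with closed-form error rates stands in for the credentialed
imaging datasets and GPU-trained model grids such audits are normally run
on, so every component is testable end-to-end on a desktop.

## Metrics and conventions

For scores $s_i \in [0,1]$, labels $y_i \in \{0,1\}$ and a threshold $t$,
predictions are positive iff $s_i \ge t$ (closed on the left; fixed so tests
can be bit-exact). Then

$$\mathrm{TPR} = \frac{TP}{TP+FN}, \quad \mathrm{TNR} = \frac{TN}{TN+FP},$$

with FPR = 1 − TNR and FNR = 1 − TPR. A rate whose conditioning class is
empty is **undefined** and propagates as `NA`, never silently as 0 — small
subgroups must not fake perfect metrics. AUROC is the Mann–Whitney pair
statistic $P(s_{pos} > s_{neg}) + \tfrac12 P(\text{tie})$, computed with
midranks. The operating threshold maximizes F1 over the observed unique
scores, ties broken toward the smallest threshold; it is chosen once per
(model, environment, evaluation split) on the *ungrouped* data and shared
across groups, so groups are compared at a single operating point.

The **fairness gap** for a designated group pair $(g_1, g_2)$ is the signed
difference $\mathrm{rate}(g_1) - \mathrm{rate}(g_2)$ of the
polarity-selected error rate (FPR for healthy-indicator tasks, FNR for
disease tasks — the underdiagnosis direction; an `overdiagnosis` flag swaps
to the complementary rate). Pareto and correlation analyses use the
absolute gap (a front cannot meaningfully mix signs); signed gaps are
retained in all reports. Gap confidence intervals are percentile bootstrap
over resampled evaluation rows (default 1,000 resamples) at the threshold
fixed from the original data; degenerate resamples are redrawn and counted.

Expected calibration error uses equal-width bins on $[0,1]$ (default 10;
final bin right-closed) and the *mean score* in each bin as the confidence
term (not the bin midpoint):
$\mathrm{ECE} = \sum_b \frac{n_b}{n}\,|\bar{s}_b - \bar{y}_b|$.

`rebalanceEvalSet()` removes within-test-set prevalence shift by
downsampling every attribute-combination cell, per class, to the minimum
per-cell class count — after which all cells have exactly equal size and
equal prevalence.

## Shift tests

Shifts are quantified exactly along the four axes a deployment audit needs,
each with a distance and a test:

* **Prevalence / label shifts** (binary outcomes): the total variation
  distance, which for Bernoulli distributions is $|p_1 - p_2|$, tested with
  the pooled two-proportion $z$ test, two-sided, no continuity correction
  (a Fisher-exact variant is available by flag).
* **Covariate / representation shifts** (embedding vectors): the unbiased
  (U-statistic) squared maximum mean discrepancy under an RBF kernel, with
  the bandwidth set by the median heuristic on the pooled pairwise
  distances, tested by label permutation with the add-one rule
  $p = (1 + \#\{\text{perm} \ge \text{obs}\})/(1 + n_{perm})$, so
  $p \ge 1/(1+n_{perm})$ always. Being unbiased, the statistic can be
  slightly negative near the null and is reported as-is. The permutation
  loop evaluates indicator-vector quadratic forms against one precomputed
  kernel matrix, and each side can be subsampled (seeded, default cap
  2,000) to bound the quadratic cost.

In the ID setting the report covers every unordered group pair
(P(Y|A) and P(X|A)); in the OOD setting it covers the pooled label and
covariate tests plus per-group prevalence and representation tests. The
**Bonferroni family is the set of tests within one emitted report** (one
dataset-pair / attribute / task call). This is a deliberate, documented
choice — a global family across an entire audit campaign would depend on
how many calls the user happens to make.

## The attribute-encoding probe

Attribute encoding is measured exactly as a representation probe: an
L2-regularized multinomial logistic regression on frozen embeddings
predicting the demographic group. The regularization strength is swept over
7 log-spaced points in $[10^{-5}, 10]$ and chosen by macro-averaged
one-vs-rest AUROC on the validation split; the reported encoding measure is
the macro AUROC on the test split, with argmax accuracy alongside (it feeds
the "Minimum Attribute Prediction Accuracy" selection criterion). Features
are standardized with training-split mean/SD before fitting so one
regularization scale is comparable across embedding spaces; ties in
validation AUROC resolve to the *stronger* regularization. The solver is
glmnet's ridge multinomial path; non-convergence sets a flag rather than
failing.

## Decomposing the OOD gap

For any metric that is a mean of per-sample losses over a group's
conditioning class (FPR, FNR, accuracy), the OOD gap decomposes exactly:

$$L(g_1, D_{tar}) - L(g_2, D_{tar}) =
  \underbrace{[L(g_1, D_{src}) - L(g_2, D_{src})]}_{\text{ID gap}} +
  \underbrace{[L(g_2, D_{src}) - L(g_2, D_{tar})]}_{\text{shift impact on } g_2} -
  \underbrace{[L(g_1, D_{src}) - L(g_1, D_{tar})]}_{\text{shift impact on } g_1}.$$

This is an algebraic identity; the implementation reports the residual as a
numerical check (machine precision, $<10^{-12}$, verified over 1,000 random
instances in the test suite). By default the decision threshold is selected
on the source environment and **reused on the target**: a deployed model's
operating point does not re-tune itself, and reusing it makes "the same
model $f$" literal. A `retuneOnTarget` flag re-selects on the target for
sensitivity analysis. Group orientation follows the configured pair order
($g_1$ first), and reports carry explicit group names so signs are
unambiguous.

## Model selection against an OOD oracle

The selection harness asks: using ID data only, which criterion picks
models that stay fair after shift? Candidates are first filtered to
*satisfactory performance*: validation AUROC no less than 5% below the best
reference-algorithm model. The phrase "no less than 5% of the best" is
ambiguous between a relative and an absolute margin; the relative reading
($\ge 0.95 \times$ best) is the default and both are implemented behind a
flag. Eight ID-computable criteria ship by default — minimum fairness gap,
minimum attribute-probe AUROC, minimum attribute-probe accuracy, maximum
overall AUROC, maximum worst-group AUROC, minimum ECE gap, minimum overall
ECE, minimum worst-group error rate. Only the first three names are
anchored in the underlying study design; the rest are natural defaults, and
the registry is configuration, not a historical claim.

Each criterion's choice is scored by its absolute OOD gap versus an
**oracle** that observes the target environment and picks the smallest
absolute OOD gap within the same filtered subset (minimizing the absolute
rather than signed gap is a documented choice). Regret = chosen − oracle
gap, nonnegative by construction. Mean regret is aggregated across
settings (target environment × attribute × group pair), with a percentile
bootstrap CI resampling *settings* — the unit being averaged — and
pairwise one-tailed Wilcoxon rank-sum comparisons (exact enumeration for
tie-free samples up to combined size 50, tie-corrected normal approximation
otherwise). Ties in any argmin/argmax break toward higher ID AUROC, then
lexically smallest model id, so every selection is deterministic.

## The synthetic cohort generator

The generator emulates the statistical skeleton of a multi-site imaging
study: binary attribute $A$ with proportions $\pi_e$, group-conditional
prevalence $\rho_{e,a} = P(Y{=}1|A{=}a)$, and representations

$$z = Y\,\beta_y\,u + \kappa_e\,c_a\,v + \varepsilon, \qquad
  \varepsilon \sim N(0, \sigma^2 I_d),$$

with orthonormal axes $u$ (disease) and $v$ (attribute), $c_a = \pm 1$, and
per-environment $\kappa_e$ controlling how strongly group identity is
written into the representation. A synthetic model scores through
$w = \cos\theta\,u + \sin\theta\,v$ ($\theta$ = shortcut reliance) and
emits the 2-D embedding $[w{\cdot}z,\ \eta\,(v{\cdot}z)]$ plus noise, so
$\eta$ controls retained attribute information. Because everything is
Gaussian, per-group error rates at a linear-score threshold $t$ have closed
forms,

$$\mathrm{FPR}_a = \Phi\!\left(\frac{\kappa_e c_a \sin\theta - t}{s}\right),
\qquad
\mathrm{FNR}_a = \Phi\!\left(\frac{t - \beta_y\cos\theta - \kappa_e c_a \sin\theta}{s}\right),$$

with $s^2 = \sigma^2 + \omega^2$ ($\omega$ = optional model-specific score
noise, the zoo's "skill" axis). These formulas are the binding oracle for
the empirical metrics: the suite verifies recovery within Monte-Carlo error
at $n = 20{,}000$ across a $(\theta, \kappa)$ sweep, and $\theta = 0$
models have *exactly* zero analytic gap in every environment — the
"no shortcut implies transferable fairness" control.

### Defaults and why

* $d = 16$, $\beta_y = 1.5$, $\sigma = 1$: arbitrary but fixed, giving
  overall AUROCs around 0.85 — the regime of the chest-radiograph models
  this emulates.
* Cohort sizes 1,000 / 500 / 1,000 per train/val/test split and
  environment: large enough that per-group rates are estimable, small
  enough that a 24-model, 13-environment grid builds in seconds. These are
  the package's default study sizes; all are arguments.
* The 24-model zoo: 8 shortcut angles $\theta \in [0, 0.9]$ × 3 replicates
  with score noise $\omega \in \{0, 0.35, 0.7\}$; the leak strength is tied
  to the angle ($\eta = 1.5\sin\theta \pm 0.15$ jitter), mirroring the
  empirical finding that shortcut-reliant models also encode attributes
  most strongly. Low-angle models carry a `debiased-like` tag, high-angle
  models `erm-like`.
* Embedding noise 1.0 (the representation-noise scale): with near-zero
  embedding noise the probe saturates for any nonzero leak — the noise
  floor is what makes the encoding measure graded rather than binary.
* The ID environment uses $\pi = (0.5, 0.5)$, $\rho = (0.5, 0.1)$,
  $\kappa = 2$: the strong group–outcome association makes the shortcut
  *genuinely predictive in-distribution*, so shortcut-reliant models win ID
  AUROC — the mechanism behind the fairness–performance tradeoff.
* S2's target environment flips the attribute axis ($\kappa = -1.2$) and
  reverses the prevalence pattern ($\rho = (0.15, 0.45)$): the shortcut
  keeps aggregate predictive value (performance transfers) but reverses
  which group it harms (the fairness gap changes sign). S3 spans 12 target
  environments over $\kappa_{tar} \in \{-1.5, -0.8, 0.5, 1.2\}$ ×
  three prevalence patterns.
* The canned scenarios ship with generator seed 1. They are *constructed
  counter-examples* — e.g. S2 must exhibit at least one ID-Pareto model
  falling off the OOD front — and a shipped fixed seed is part of the
  scenario definition, exactly as a frozen benchmark dataset would be.

### What the generator does and does not emulate

It reproduces group-conditional prevalence structure, group-structured
representations, ID/OOD environments differing in label, prevalence,
covariate and representation distributions, and a model grid whose
shortcut reliance and attribute encoding vary systematically. It does
**not** emulate image content, lateral/frontal view mixtures, per-patient
repeated measurements (rows are i.i.d.; grouping is left to the caller),
multi-label training dynamics, or the specific inductive biases of any
debiasing algorithm — the `debiased-like`/`erm-like` tags index shortcut
reliance, not training procedure. Tests passing on synthetic grids
therefore validate the *audit machinery and its statistical behaviour*,
not claims about any particular clinical model family.

## Transfer correlation: signed or absolute?

ID-vs-OOD *fairness* transfer is correlated on **signed** gaps by default:
a sign flip under shift is precisely the non-transfer phenomenon of
interest, and taking magnitudes first can manufacture spurious positive
transfer. The absolute-gap variant is available (`useAbsGap = TRUE`), and
both signed and absolute gaps appear in every report, since published
analyses are not always explicit about which was plotted.

## Numerical choices, degenerate inputs, tie-breaks

* Decision rule `score >= t`; F1 ties to the smallest threshold; selection
  ties to higher ID AUROC then lexical id; probe-strength ties to stronger
  regularization. Every path is deterministic under a fixed seed.
* Undefined rates are `NA` markers; gaps over undefined rates are `NA`
  with a message (not an error); decomposition cells that are undefined
  *are* errors naming the cell, because the identity needs all four.
* Pooled-proportion SE of 0 (all successes or all failures pooled) returns
  p = 1.
* All randomized operations take explicit integer seeds; multi-stream
  pipelines derive child seeds with a fixed 32-bit LCG step
  (`deriveSeed()`), keeping every seed a valid R integer.
* Reports serialize NaN as JSON null with a warning.

## Limitations

The binomial proportion test is asymptotic; with very rare outcomes use the
exact flag. The MMD permutation test inherits the median-heuristic
bandwidth's insensitivity to some alternatives. The bootstrap CIs are
percentile (the study design names only "non-parametric bootstrap");
coverage is verified empirically at the package's study sizes, and
percentile intervals are known to undercover slightly at small $n$. The
selection harness's bootstrap resamples settings, which treats settings as
exchangeable; settings sharing a target environment are in fact
correlated.
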