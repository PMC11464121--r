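---
title: "Retroelement epigenetic clocks: models, design choices and limits"
author: "retroclock maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retroelement epigenetic clocks: models, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retroclock)
```

## The problem

Most of the human genome is repetitive, and a substantial fraction of it
consists of retroelements — human endogenous retroviruses (HERVs), LINE-1
elements, LTR remnants and SINEs — that are normally silenced by DNA
methylation. Standard epigenetic clocks predict chronological age from CpG
methylation but are built on array annotations that do not say whether a
CpG sits inside a locus-specific retroelement, so the aging signal carried
by retroelement methylation has gone largely unused. `retroclock`
implements the full pipeline for building and using clocks restricted to
retroelement CpGs:

1. annotate methylation-array probes to locus-level retroelement intervals
   by coordinate intersection,
2. train a penalized linear age predictor (cross-validated elastic net) on
   the retroelement CpG beta values, or on locus-level retroelement
   expression,
3. apply and evaluate clocks (Pearson *r*, median absolute error), compute
   epigenetic age acceleration and group or paired contrasts, intersect
   clock CpG sets, test feature-set enrichment, and quantify test–retest
   reliability via a mixed-model intraclass correlation.

A synthetic-data module generates every input with known ground truth, so
all of the above is testable without any external download.

## The model

The clock is a sparse linear predictor of (possibly transformed) age from
beta values $x_{ij} \in [0,1]$:

$$\hat t_i = \beta_0 + \sum_j \beta_j x_{ij}, \qquad
\hat{\mathrm{age}}_i = g^{-1}(\hat t_i),$$

where $g$ is the identity for human clocks and the relative-age map
$g(a) = \log(a + 2)$ (natural log, offset in years) for the cross-species
clock; the offset keeps age 0 finite and the inverse is
$g^{-1}(t) = e^t - 2$. Coefficients are fit by the elastic net:

$$\min_{\beta_0,\beta}\; \frac{1}{2n}\sum_i\big(t_i - \beta_0 -
x_i^\top\beta\big)^2 + \lambda\Big(\alpha\lVert\tilde\beta\rVert_1 +
\tfrac{1-\alpha}{2}\lVert\tilde\beta\rVert_2^2\Big),$$

with features standardized internally (the penalty applies to the
standardized coefficients $\tilde\beta$; returned coefficients are on the
beta scale). The penalty path starts at
$\lambda_{\max} = \max_j |\tilde x_j^\top (t - \bar t)|/(n\alpha)$ — the
smallest penalty whose solution is exactly null — and descends
log-spaced over `n_lambda` values to
`lambda_max * lambda_min_ratio`. The CpGs with nonzero coefficients *are*
the clock; their training-set mean betas are stored in the model so that
missing probes can be mean-imputed at prediction time, which leaves the
linear predictor unbiased at the training centroid.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.5 | elastic-net mixing; 1 = lasso, 0 = ridge. The mixing value must be chosen explicitly; 0.5 is the common choice in the clock literature and keeps correlated CpGs grouped. |
| `n_folds` | 10 | cross-validation folds, stratified on response quintiles. |
| `n_lambda`, `lambda_min_ratio` | 100, 1e-3 | penalty path length and depth. |
| `selection_rule` | `lambda_min` | CV-error minimizer; `lambda_1se` gives the sparsest model within one SE. |
| `split_fraction` | 0.8 | training share of the sample split. |
| `group_by` | off | donor-grouped splitting: whole donors go to one side, which is the only way to avoid leakage when one donor contributes several tissues or timepoints. |
| transform offset | 2 years | relative-age offset for cross-species training. |
| `max_missing` | 0.2 | per-sample missing-probe fraction above which a sample is excluded from training (and flagged at prediction). |

CV error is mean squared error on the response scale. Age acceleration
defaults to the `difference` method (predicted − chronological, in years)
because that is the quantity reported for cohort contrasts; the
`residual` method (residuals of predicted on chronological within the
cohort) is provided for cross-cohort work where a systematic clock offset
should be removed. Group contrasts default to Student's pooled-variance
*t* (Welch by flag), two-sided p-values throughout. Evaluation reports the
**median** absolute error: "MAE" in the epigenetic-clock literature is the
median, not the mean, and the package follows that convention exactly.

## Annotation rules

A probe interrogates a single cytosine, so annotation treats it as a
1-based point and assigns it to a retroelement locus iff
`start <= pos <= end` on the same chromosome. Strand is ignored:
methylation at a CpG is measured on both strands and the intervals are
orders of magnitude wider than the probe. Probes overlapping several loci
keep all hits (deduplicated by locus id) but enter the clock design matrix
exactly once. Chromosome-naming mismatches (`chr1` vs `1`) are a hard
error unless `chr_alias = TRUE` is passed — silent normalization hides
real annotation/manifest version conflicts. Repeat classes live in the
closed vocabulary `HERV, LINE, LTR, SINE, DNA, Unknown`; labels outside it
are coerced to `Unknown` rather than invented.

## Numerical choices

* **Solver.** Cyclic coordinate descent (compiled) with warm starts along
  the path, sequential strong-rule screening, and active-set iteration.
  Convergence per penalty is declared only when the KKT subgradient
  violation over *all* features is below `kkt_tol` (default 1e-7), checked
  against an independent pure-R implementation in the tests. Coefficients
  smaller than 1e-12 on the standardized scale are snapped to exact zero,
  so the solution at `lambda >= lambda_max` is exactly null rather than
  null up to a rounding ulp.
* **Path early stop.** Fitting is cut short once in-sample $R^2$ exceeds
  0.999 or improves by less than `1e-5 * R^2` between consecutive
  penalties; the saturated tail of the path carries no information for
  selection and dominates compute. Cross-validation fold fits reuse the
  master path and a looser solver tolerance (1e-5), which moves the CV
  curve by far less than its own standard error.
* **alpha = 0.** The $\lambda_{\max}$ formula divides by `alpha`; it is
  clamped at 1e-3 for path construction so ridge-leaning fits still get a
  finite path.
* **Constant response.** Returns an intercept-only model with a warning
  instead of an undefined standardization.
* **Degenerate tests.** A paired contrast with zero within-pair variance
  returns `t = 0, p = 1` (null) or `|t| = Inf, p = 0` (constant shift)
  rather than erroring; the ICC of replicates identical within every
  subject is exactly 1; negative variance components are truncated at 0
  and flagged.
* **Enrichment.** One-sided hypergeometric tail by default (enrichment is
  the hypothesis of interest); fold enrichment
  `(a/|query|)/(|feature|/|universe|)`; odds ratio is the unconditional
  `ad/bc`, infinite when `bc = 0`. BH-FDR is applied *within* each feature
  database — TFBS, chromatin-state and histone-mark panels are separate
  families of hypotheses. Both a whole-platform universe and the
  retroelement-CpG universe are exposed, because enrichment against the
  platform answers "where do these CpGs sit in the epigenome" while the
  retroelement universe answers "which retroelement CpGs made it into the
  clock"; the choice materially changes the null and must be the user's.
* **Reliability.** One-way random-effects ICC,
  $\sigma^2_b/(\sigma^2_b + \sigma^2_w)$, fit by REML (`lme4`); technical
  replicates have no rater factor, so two-way forms do not apply. The
  one-way ANOVA moment estimator with the mean-$k_0$ correction for
  unbalanced designs is the cross-check and fallback.

## What the synthetic data emulates — and what it does not

`simulateMethylationCohort` plants a linear age effect on the logit scale
in a random causal subset of probes
($\mathrm{logit}(\beta) = a_j \pm s\,(t - \bar t) + \varepsilon$), which
respects the (0,1) beta bounds by construction; optional donor, tissue and
species blocks add shared ages, logit shifts, and lifespan-scaled age
ranges (causal effects linear in $\log(\mathrm{age}+2)$ so the
relative-age transform is genuinely exercised).
`simulateExpressionCohort` draws negative-binomial counts with log-normal
library sizes and causal log-mean slopes; `simulateReplicates` draws the
classic two-level variance-components design;
`simulateManifestAnnotation` places loci and probes with a known
containment truth table. Defaults mirror the scale of a blood methylation
cohort study: ages uniform on 12–100 years, 600 samples by 3000 probes
with 150 causal CpGs at 0.02 logit units/year against 0.5 logit noise;
the expression cohort uses 160 donors aged 20–74 with 40 causal loci, and
the replicate design 30 subjects × 2 with variances 9 and 1 (true ICC
0.9). These sizes keep every check runnable on a laptop in minutes while
leaving the recovery thresholds non-trivial.

What passing tests on these data do **not** show: the generator has no
probe-chemistry artifacts (type I/II bias), no batch or plate effects
beyond block shifts, no cell-composition confounding, no correlated CpG
blocks, and its age effects are exactly log-linear. Recovery on synthetic
cohorts demonstrates that the machinery is correct, not that a clock
trained on any particular real cohort will reach a given accuracy.

## Known limitations

* IDAT preprocessing, normalization and probe QC are out of scope; the
  pipeline starts from a validated beta matrix.
* RNA-seq quantification of retroelement expression is consumed as a
  count matrix, not produced.
* Published clock coefficients (Horvath, Hannum, PhenoAge, GrimAge, PC
  clocks, DunedinPACE) are not bundled; `compareClockCpGSets` accepts any
  CpG sets the user supplies.
* The grouped splitter packs whole donors greedily; the achieved training
  fraction can deviate from the target by up to the largest donor.
* ICC confidence intervals are not provided (point estimates only).
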