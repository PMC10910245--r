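---
title: "Stable SNP selection: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stable SNP selection: model, algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette describes the statistical machinery implemented in
`stableselect`, the choices made where the design was genuinely open, and
what the synthetic-cohort tests do and do not demonstrate about real data.

## The problem

Case/control genome-wide association studies of diseases like late-onset
Alzheimer's face a characteristic signal profile: a handful of strongly
associated common variants (in AD, the APOE-linked block on chromosome 19)
sitting on top of a large population of weak effects that are statistically
indistinguishable from false positives at any single analysis. Single-pass
feature selection in this regime is unstable — rerunning the same procedure
on a slightly perturbed sample returns a substantially different SNP list.
`stableselect` addresses this by replicating an entire rank-and-select
procedure across many random splits of the data and keeping only SNPs that
survive selection in a large fraction of replications.

## Ridge regression with error propagation

Phenotypes $y \in \{0,1\}^n$ (1 = case) are modelled linearly in a design
$X$ whose columns are an intercept $X_0 = 1$ and standardized additive
genotype dosages, with independent errors of per-sample scale $\Delta_y$
(diagonal). The penalized goodness of fit is

$$E^2(m) = (y - Xm)^T \Delta_y^{-2} (y - Xm) + C\, m^T m ,$$

minimized in closed form by

$$\bar m = (X^T \Delta_y^{-2} X + C I)^{-1} X^T \Delta_y^{-2} y ,$$

with coefficient covariance
$\mathrm{cov}(\bar m) = A^{-1} X^T \Delta_y^{-2} X A^{-1}$ for
$A = X^T \Delta_y^{-2} X + CI$, and residual

$$E^2_{res} = y^T \Delta_y^{-2} y - (X\bar m)^T \Delta_y^{-2} (X \bar m)
  - C\, \bar m^T \bar m .$$

Two exact identities follow and are enforced by the test suite at numerical
precision: the weighted total sum of squares decomposes into residual,
explained and penalty parts, and for any coefficient vector $m$

$$E^2(m) = E^2_{res} + (m - \bar m)^T (X^T \Delta_y^{-2} X + CI)(m - \bar m).$$

The L2 penalty matters because the genotype designs of interest are
underdetermined ($p \ge n$): without it the model interpolates ("splines")
any phenotype vector and the coefficient covariance diverges along null
directions.

**Per-feature heritability.** The explained term expands as
$\bar m^T (X^T \Delta_y^{-2} X) \bar m$. Its diagonal contributions

$$h_j = \bar m_j^2 \; x_j^T \Delta_y^{-2} x_j$$

are each feature's individual share of the explained phenotypic variation,
and are the ranking score. The off-diagonal cross terms couple correlated
features, which is exactly why LD pruning precedes ranking; an optional
`cross_terms = TRUE` mode includes them
($h_j = \bar m_j\, x_j^T \Delta_y^{-2} X \bar m$) for users who want the
full decomposition. The intercept and covariate columns never receive a
score.

Numerical notes:

* When $p \le n$ the $p \times p$ regularized normal equations are solved
  directly; otherwise the algebraically identical $n \times n$ dual system
  is used. Both paths are asserted equal on small instances.
* $\Delta_y$ defaults to the identity (homoscedastic errors); per-sample
  scales are accepted but the binary-phenotype workflow never sets them.
* Genotype columns are mean-imputed (missingness having already been
  filtered) and standardized to zero mean and unit variance before the
  fit; zero-variance columns become all-zero rather than dividing by zero.
* The penalty defaults to $C = 1$ on the standardized design and is never
  tuned internally. One caveat discovered during development and worth
  stating: when the training sample size is close to $p$, small $C$ sits
  at the interpolation threshold where coefficient variance peaks and the
  ranking degrades. The replication design below avoids the regime by
  training each ranking fold on half the working sample (so
  $n_{train} \approx p/2$ or less relative to typical panels); users
  fitting near-square designs directly should raise $C$.

## Ranking under folds, nested subsets, Youden cutoff

One replication of the selection procedure runs:

1. **Fold-averaged ranking.** `n_folds` class-balanced splits of the
   working samples are drawn; the ridge model is fitted on each training
   part and per-fold scores $c_{i,j}$ (the $h_j$ above) are averaged into
   $c_j$, then ranked decreasingly by a stable sort (ties keep column
   order). Averaging across half-sample folds stabilizes the top of the
   ranking cheaply, since each ridge fit is a single linear solve.
2. **Nested subsets.** With increment
   $\lfloor p / n_{steps} \rfloor$, subset $i$ holds the top
   $i \cdot \lfloor p/n_{steps}\rfloor$ ranked features; the last subset
   is completed to all $p$ features.
3. **Youden curve.** For each of `m_folds` balanced scoring splits (drawn
   independently of the ranking splits, from a separately derived seed)
   and each subset, a linear-kernel SVM is trained on the training part
   restricted to the subset and evaluated on the test part at its native
   decision threshold, recording $J = \text{sensitivity} +
   \text{specificity} - 1$. The curve is the fold-average per step.
4. **Cutoff.** The curve is cut at its first (left-to-right) interior
   local maximum, i.e. the smallest $j$ with
   $K[j-1] \le K[j] \ge K[j+1]$, the first index of a plateau winning;
   when no interior local maximum exists (a monotone curve) the first
   global argmax is used. The selected set of the replication is the
   nested subset at the cutoff.

The single-operating-point $J$ (no threshold sweep) is deliberate: the
quantity scored is the classifier actually fitted on the candidate subset,
not the best achievable ROC point.

## Support counting and the replication-power model

`run_stability()` repeats the whole procedure $N$ times (default 50) with
per-replication seeds derived from a master seed by a fixed counter scheme,
and counts for every SNP the number of replications whose cutoff set
contained it ("support"). A stable set keeps SNPs with support at or above
a threshold; $0.8N$ (40 of 50) is the conventional cut.

Why replication works is captured by a two-type error model: if a fraction
$f$ of SNPs is truly active, and one replication falsely selects an
inactive SNP with probability $\alpha$ while rejecting an active one with
probability $\beta$, the fraction of all-$N$-supported SNPs that are truly
active is

$$\frac{f (1-\beta)^N}{f (1-\beta)^N + (1-f)\alpha^N} \to 1
  \quad (N \to \infty) \text{ whenever } 1-\beta > \alpha .$$

`expected_true_positive_fraction()` evaluates this closed form; the test
suite checks it against a Monte-Carlo simulation of the two-type Bernoulli
process.

The outer loop keeps one fixed working/validation split and re-draws only
the inner splits; the validation samples are scored exactly once, at the
end. Because the working data are fixed across replications, a null SNP
that is by chance associated in this particular sample remains mildly
favoured in every replication — support thresholds below $N$ exist
precisely because such SNPs accumulate moderate support. The
phenotype-shuffling control makes this visible: shuffled cohorts show a
broad mid-range support distribution but rarely sustain full support.

## Variant QC

The pre-analysis stack runs, in fixed order: missingness filter (per-SNP
missing fraction), MAF floor, Hardy-Weinberg goodness of fit, and greedy
windowed LD pruning. Defaults: missingness 0.05, MAF 0.05, HWE p-floor
$10^{-12}$, LD window 50 kb sliding by 5 SNPs at $r^2 \le 0.5$.

Open choices resolved here:

* **HWE test.** A one-degree-of-freedom chi-square goodness of fit on
  genotype counts over all samples (cases included). PLINK's exact test
  would differ in the far tails; the chi-square is transparent, and at a
  $10^{-12}$ floor the difference touches only grossly violating SNPs.
* **LD window.** The window is measured in kilobases (not SNP count) and
  slides by a SNP-count step; within a window the later-positioned SNP of
  any pair exceeding the $r^2$ ceiling is removed. $r^2$ is the squared
  Pearson correlation of mean-imputed dosages; zero-variance columns are
  treated as uncorrelated.
* Missing genotypes are mean-imputed per SNP at analysis time, after the
  missingness filter; genotype imputation proper is out of scope.

## Synthetic cohorts

`simulate_genotypes()` draws per-SNP allele frequencies uniformly from a
configurable interval (default 0.05–0.5, matching the post-QC spectrum),
builds genotypes as sums of two allele draws (hence Hardy-Weinberg
proportions when LD is off), and induces optional block LD through a shared
latent Gaussian (copula thresholding) with within-block correlation
`ld_rho`. Phenotypes are Bernoulli with
$\mathrm{logit}\, P(\text{case}) = \mu + \sum_c \beta_c (g_c - 2q_c)$;
centring the causal dosages makes the intercept set the expected prevalence
directly. A liability-threshold variant is available behind `model =
"liability"`.

The `"ad-like"` preset encodes the few-strong/many-weak architecture: 3
causals at OR 2.5 per allele plus 12 at OR 1.15 among 500 SNPs, cohort
size 600, prevalence 0.5. Causal SNPs are pinned at MAF 0.3 — the strong,
reproducible GWAS hits this design emulates are common variants, and a
causal drawn near the rare end of the spectrum would carry almost no
marginal information at these sample sizes, changing the scenario rather
than the method. `"strong"` and `"weak"` keep only the respective halves
of the architecture.

What the simulator does *not* emulate: realistic human LD maps, population
structure and relatedness, rare-variant spectra, genotyping batch effects,
covariate confounding. Passing recovery tests on these cohorts shows the
machinery is correct and the replication logic behaves as designed, not
that the pipeline overcomes those real-data complications.

## Synthetic study sizes used by the tests

The packaged tests and the acceptance script run the full pipeline on the
preset cohorts (600 samples, 500 SNPs) with ranking over `n_folds = 5`
half-sample splits (`s_test = 0.5`), scoring over `m_folds = 2` splits
with `t_test = 0.65`, `n_steps = 20` curve steps, and `N = 20`
replications (10 for the weak-signal contrast). These sizes are the
package's own choice of synthetic study scale: half-sample ranking folds
are the stability-selection convention and keep each ridge fit well inside
the underdetermined regime; two scoring folds with large test parts give
$J$ estimates whose noise is small against the curve structure; 20-step
curves resolve selected sets down to 5% of the panel. Production runs on
real cohorts would typically raise `m_folds`, `n_steps` and `N` (the
defaults are 5, 100 and 50).

## Downstream evaluation

* **Per-SNP association**: maximum-likelihood logistic regression (IRLS
  via `glm`) with a Wald p-value on the dosage coefficient. Complete or
  quasi-complete separation is flagged (`converged = FALSE`, p reported
  as missing) rather than returned as a spuriously extreme p-value.
* **Contingency OR**: the log odds ratio of a 2×2 disease-by-exposure
  table is treated as normal with variance
  $\sum \text{(reciprocal cell counts)}$; any zero cell triggers the
  flagged Haldane–Anscombe +0.5 correction on all four cells.
* **Predictivity**: linear-kernel SVM F1 (harmonic mean of precision and
  recall) and rank-based AUC, either fold-averaged inside the working set
  (`evaluate_predictivity()`) or once against the held-out validation
  samples (`evaluate_holdout()`).
* **Significance subsets** use $-\log_{10} p$ cuts (base 10 is the GWAS
  convention); p-values are reported raw, since the thresholds quoted for
  such cuts are themselves on raw p-values — no FDR layer is stacked on
  top.
* **PRS weight selection**: external polygenic-score weight vectors
  concentrate in a near-neutral spike around $\beta = 0$; binning the
  weights into 50 equal-width bins over their range and keeping SNPs from
  bins occupied by fewer than $2 \times 10^{-4}$ of the SNPs isolates the
  non-neutral tails. An alternative plain magnitude cut
  (`select_by_beta_magnitude()`) is provided; the histogram rule is the
  primary interface since it adapts to the scale of the weight
  distribution. With all weights equal the range is zero-width and the
  selection is defined to be empty.

## Numerical and tie-break decisions, in one place

* Local-maximum rule: the inequality is $K[j-1] \le K[j] \ge K[j+1]$;
  "first index of a plateau wins"; monotone curves fall back to the first
  global argmax. A literal non-decreasing-triple reading
  ($K[j-1] \le x \le K[j+1]$) would name saddle points, not maxima, and is
  not used.
* Ranking ties keep original column order (stable sort), making results
  invariant to relabeling of equal-score SNPs.
* LD pruning removes the *later-positioned* SNP of an offending pair —
  deterministic and the common greedy practice.
* The SVM regularization cost is the library default (1) and is recorded
  in the run manifest; its KKT stopping tolerance is loosened to 0.01
  (confusion counts do not change at that scale, the solver converges
  markedly faster).
* Seeds: every user-facing entry point takes one seed; internal stages
  derive independent streams via a fixed integer counter scheme, so runs
  are bit-reproducible end to end (`manifest.yaml` records everything
  needed to replay a run).
* Sample alignment orders the genotype/phenotype ID intersection
  lexicographically — any fixed ordering works; this one is
  platform-independent.
* Covariates (age, sex) can be carried in the ridge design via the
  `covariates` argument but are excluded from ranking; the default leaves
  them out entirely, since whether they should compete with SNPs as
  ranked features is a modelling question the package does not decide for
  the user.

## Known limitations

* The heritability score ignores LD cross terms by design; on un-pruned
  panels, correlated clusters share credit unpredictably. Prune first.
* Ridge with fixed $C$ is not a calibrated variance-component estimate;
  scores order features but their absolute scale has no population
  interpretation.
* The Youden cutoff reacts to curve noise; with few scoring folds the
  selected set size varies across replications. That variability is the
  point of support counting, but single-replication output should not be
  interpreted on its own.
* Logistic association is unadjusted for population structure; on real
  cohorts add principal components as covariates upstream, or use a
  mixed-model tool for association and keep this package for selection.
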