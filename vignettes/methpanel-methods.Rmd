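---
title: "Selecting minimal methylation biomarker panels with methpanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting minimal methylation biomarker panels with methpanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methpanel)
```

## The problem

Genome-wide methylation assays (e.g. Illumina HM450 arrays) report a beta
value $\beta = M/(M+U+100) \in [0,1)$ per CpG site — the methylated
fraction of the probe signal. Clinical assays, in contrast, measure a
handful of sites by PCR. Translating an array study into a diagnostic
therefore requires a *small* panel of CpG sites that still classifies
accurately. Two things make naive "top-N most differential sites"
selection fail:

* **redundancy** — the top of a differential ranking is full of
  co-methylated, mutually correlated sites carrying one signal; and
* **tumor heterogeneity** — a marker private to a molecular subtype has
  its between-class mean difference diluted by the subtype fraction, so
  it never reaches the top of a global ranking even though it is the only
  way to recognise that subtype.

`methpanel` addresses both with a staged pipeline and quantifies the
reliability of the result with dedicated diagnostics.

## The pipeline

Given a sites × samples beta matrix with a class label per sample
(`beta_matrix()`), `run_select()` executes:

1. **Differential-mean prefilter** (`delta_beta_filter()`). A site
   survives iff some pair of classes $i, j$ satisfies
   $|\mathrm{mean}(\beta_i) - \mathrm{mean}(\beta_j)| > \Delta\beta$
   (strict; default $\Delta\beta = 0.2$). All $C(C-1)/2$ pairs are
   scanned, so a site only has to discriminate one pair of classes.

2. **Stability selection** (`stability_select()`). Many rounds (default
   1500) of L1-penalised logistic regression, each on a stratified random
   half of the samples; a site's score is the frequency with which its
   coefficient is non-zero. The penalty in each round is a fraction
   (default 0.1) of that round's $\lambda_{\max}$ — the smallest penalty
   that zeroes every coefficient — so the effective strength adapts to the
   subsample. The deliberately weak default admits whole correlated
   blocks: random subsampling lets block members take turns carrying the
   signal, which is exactly why a randomised stage is used instead of a
   single lasso fit. Sites with frequency $\ge$ 0.25 become candidates.

3. **Forest importances** (`rf_importances()`). One random forest
   (default 500 trees) on the candidates, sample weights inversely
   proportional to class frequency to honour unbalanced cohorts; Gini
   impurity importances, normalised to sum to one.

4. **Importance-threshold sweep** (`threshold_sweep()`). Every distinct
   importance value is a threshold; the sites at or above it form a
   subset scored by stratified 10-fold cross-validation with a 1000-tree
   forest. The loss is the multiclass cross-entropy
   $$\mathrm{LogLoss} = -\frac{1}{N} \sum_{i=1}^{N} \sum_{j=1}^{C}
   y_{ij}\, \log p_{ij},$$
   which penalises confident errors *and* under-confident correct calls,
   preferring low-noise sites. Each curve point records the per-fold mean
   and standard error ($\mathrm{SD}/\sqrt{k}$), plus pooled out-of-fold
   precision and recall.

5. **One-standard-error rule** (`one_se_select()`). Among points with at
   most $P$ sites (default 15), find the LogLoss minimum $m$, then return
   the *smallest* subset whose loss is strictly below
   $\mathrm{LogLoss}(m) + \mathrm{SE}(m)$ — the smallest panel
   statistically indistinguishable from the best one.

6. **Final fit and correlation analysis** (`fit_panel()`,
   `find_correlated_sites()`). The panel forest is refit on all training
   samples; every non-panel site with Pearson $r > 0.85$ (signed, strict)
   to a panel site is recorded as an interchange partner.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `delta_beta` | 0.2 | minimum between-class mean beta difference (beta-value units) |
| `P` | 15 | hard upper limit on panel size |
| `rlr_iterations` | 1500 | randomised-regression rounds |
| `rlr_subsample_fraction` | 0.5 | stratified sample fraction per round |
| `rlr_regularization` | 0.1 | L1 penalty as a fraction of per-round $\lambda_{\max}$ |
| `rlr_frequency_threshold` | 0.25 | candidate cut-off on selection frequency |
| `importance_trees` / `sweep_trees` | 500 / 1000 | forest sizes for importance estimation and CV/final fits |
| `cv_folds` | 10 | stratified folds; must not exceed the smallest class |
| `r_threshold` | 0.85 | Pearson cut-off for interchangeable sites |

All randomness flows from one master seed through fixed-position derived
seeds, so a run is a pure function of (data, configuration, seed), and a
saved model (`save_panel_model()`) stores the seed and panel training
data needed to refit the forest bit-identically.

## Diagnostics

* **Interchangeability** (`interchange_test()`). Each permutation swaps
  every panel site for a uniformly drawn member of itself plus its
  correlated cluster, *refits* the forest on the training cohort (tree
  splits are not transferable between columns, so substitution without a
  refit would be ill-defined) and scores test AUC. A narrow AUC interval
  around the baseline means the panel's sites can be traded for partners
  that are easier to assay.
* **Selection stability** (`stability_experiment()`). The whole pipeline
  is rerun on stratified 90% subsamples (without replacement, so classes
  stay populated); agreement between the selected panels — each augmented
  with its correlated sites, since block members are interchangeable — is
  summarised by the Kuncheva index
  $$S = \frac{2}{k(k-1)} \sum_{i<j}
  \frac{r_{ij} N - s^2}{s\,(N - s)},$$
  with $N$ the prefilter-survivor count, $s$ the subset size and
  $r_{ij}$ the pairwise overlap. Real runs produce unequal panel sizes;
  the package then scores each pair as
  $(rN - s_i s_j)/\sqrt{s_i(N-s_i)\,s_j(N-s_j)}$, which reduces exactly
  to the equal-size formula when $s_i = s_j$. A strict mode enforcing
  equal sizes is kept for verification.
* **Noise robustness** (`noise_robustness()`). Independent uniform noise
  in $(-\Delta\mu, +\Delta\mu)$ is added to the panel sites of the test
  matrix (the model stays fixed — only panel sites can affect it), values
  are clipped back to $[0,1]$ to preserve beta semantics, and AUC is
  averaged over Monte-Carlo iterations per level. At $\Delta\mu = 0$ the
  computation reproduces the plain evaluation bit-exactly.
* **Outlier flagging** (`detect_outliers()`). Samples whose predicted
  probability of a class other than their recorded label exceeds a
  threshold (default 0.5) are flagged. In-bag forest predictions on the
  training cohort would simply memorise the labels, so the probabilities
  come from the out-of-bag votes of a forest refit on the scored matrix
  under the model's configuration and seed.
* **Heterogeneity clustering** (`cluster_samples()`). K-means (10
  restarts, fixed seed) on the panel-site profiles of one class exposes
  methylation subtypes; `k` is the caller's choice.

## The synthetic cohort generator

`generate_cohort()` draws each site from a Beta distribution
moment-matched to a requested mean and standard deviation — beta values
are bounded and skewed near the extremes, which a truncated Gaussian
would misrepresent. Informative sites shift the mean of a designated
class, or of designated subtypes within it; correlated blocks add
jittered copies of an informative site (clipped to $[0,1]$); label flips
are applied *after* generation, so a flipped sample keeps the beta
profile of its true class — the premise of the outlier-detection test.

`heterogeneous_cohort_spec()` is the reference design used across the
test suite and the acceptance script: 150 samples (75 tumor in three
equal subtypes, 75 normal) and 2000 sites, of which ten "main" markers
shift tumor subtypes 2–3 (global class differences 0.25–0.4), two
"private" markers shift only subtype 1 (0.8 within the subtype, ≈ 0.27
globally), four markers carry 3-copy correlated blocks (r ≫ 0.85), and
1976 sites are noise. The design makes one third of the tumors
recognisable *only* through their private markers: a selection method
blind to heterogeneity cannot reach high held-out AUC on this cohort,
while the pipeline is expected to return a panel drawn from the planted
markers and their blocks that covers the private family. Shift sizes are
stated as within-target-group shifts; because a subtype covers a fraction
of its class, the global class difference is the shift scaled by that
fraction (`subtype_marker_check()` verifies this dilution), and
within-subtype shifts were sized so the realized global differences land
in the 0.25–0.4 band while still clearing the 0.2 prefilter.

What the generator does **not** emulate: batch effects, probe
cross-reactivity, missing values, type I/II probe chemistry differences,
and realistic genome-wide correlation structure beyond the planted
blocks. Passing tests on these cohorts demonstrate that the machinery is
correct and stable under the stated model, not that any particular
clinical accuracy will be reached on real arrays.

## Numerical choices and edge cases

* Probabilities are clipped to $[\varepsilon, 1-\varepsilon]$ with
  $\varepsilon = 10^{-15}$ (configurable) before the logarithm, keeping
  LogLoss finite.
* The prefilter and the correlation threshold use strict inequalities;
  boundary equality fails.
* Sites with tied importances cannot be separated by a threshold and
  move as a group through the sweep; the same stratified folds are reused
  across all sweep points so subsets are compared on identical splits.
* In the one-SE rule, when the loss minimum has a standard error of
  exactly zero no point satisfies the strict inequality and the minimum
  itself is returned; ties on panel size break toward lower loss.
* The stability bootstrap draws 90% *without* replacement, stratified by
  class; a pipeline failure on a subsample is excluded and counted,
  never silently dropped.
* Missing beta values are rejected at the boundary rather than imputed:
  imputation would silently change which sites are selected.
* Zero-variance sites have undefined Pearson correlation and are
  excluded from correlation analysis with a message.

## Known limitations

* The randomised-regression stage, like any stability selection on a
  fixed finite cohort, will consistently score a site whose *spurious*
  class difference happens to be the largest in the matrix; the
  frequency threshold controls redundancy, not the false discovery rate.
  The prefilter ahead of it is what keeps pure-noise sites out in
  practice.
* Outlier flagging relies on each mislabeled sample being isolated in
  panel space; several same-direction flips can mutually support each
  other in out-of-bag votes and partially evade a high threshold.
* AUC-based diagnostics (interchange, noise) are binary-task only;
  the pipeline itself supports any number of classes.

## Problem sizes used by the shipped tests and script

The test suite and `scripts/acceptance.R` run the reference cohort with
300 randomised-regression rounds, interchange with 500 permutations,
noise curves at 200 iterations per level, and the stability experiment
with 25 bootstrap runs on a compact dominant-family cohort — sizes chosen
so the full validation completes comfortably on a laptop while leaving
the statistical conclusions unchanged; the defaults encode the full
published protocol (1500 rounds, 10\,000 permutations, 1000 iterations,
100 bootstraps).
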