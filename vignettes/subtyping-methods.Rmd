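---
title: "Methods: molecular subtyping of NSCLC from targeted panel expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: molecular subtyping of NSCLC from targeted panel expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Advanced non-small cell lung cancer (NSCLC) is routinely diagnosed from
small-volume specimens such as fine-needle aspirates (FNA). Treatment depends
on separating the two major histologic subtypes, adenocarcinoma (LUAD) and
squamous cell carcinoma (LUSC), but morphology and immunohistochemistry
consume scarce tissue, and ambiguous cases end up labelled "not otherwise
specified" (NOS). A targeted expression panel measured on a digital counting
platform (NanoString nCounter) or extracted from RNA-Seq offers a
tissue-sparing alternative: measure a few dozen subtype-associated genes plus
a handful of housekeeping genes, and call the subtype from a fixed,
transparent statistical model.

`panelsubtype` implements that workflow end to end: per-sample normalization,
a packaged published 15-signature-gene logistic classifier, the elastic-net
model-development engine that produces such classifiers, threshold
calibration for confident clinical calling, NOS-case distribution profiling,
and a seeded synthetic-cohort generator for validating the machinery.

## Individual normalization

Clinical deployment is simplest when one specimen can be processed alone, so
the normalization uses no cross-sample statistic. Per sample:

1. $v_g = \log_2(x_g + c)$ for every panel gene, with pseudocount $c = 1$ by
   default;
2. $c_g = v_g - \bar v_{HK}$ for the diagnostic genes, where $\bar v_{HK}$ is
   the mean of $v$ over the housekeeping genes;
3. $z_g = (c_g - \bar c)\,/\,\mathrm{sd}(c)$ across the diagnostic genes,
   with the $n-1$ sample standard deviation.

Numerical choices worth stating:

* **Pseudocount.** Zero counts are legitimate panel observations;
  $\log_2(x+1)$ keeps them finite. The pure transform (pseudocount 0) is
  exactly invariant to rescaling a sample by any positive factor — library
  size cancels in the centering — and the tests verify that identity to
  1e-9. With the pseudocount the invariance is approximate, perturbed by
  $O(1/x)$ per gene, negligible at typical panel counts (hundreds).
* **Scope of the z-transform.** The z statistics are computed over the
  diagnostic genes only, after the housekeeping centering. Including the
  housekeeping genes in the z-step would let them influence the profile
  twice. A consequence of this convention is that the housekeeping centering
  is mathematically absorbed by the subsequent re-centering; the step is
  retained because it is part of the stated clinical procedure and keeps
  intermediate quantities interpretable. Whether the original device
  z-transformed over all panel genes or the diagnostic subset is not
  determinable from public sources; this package's convention is documented
  here as its own choice.
* **Degenerate profiles.** A sample whose diagnostic genes are identical
  after centering has $\mathrm{sd}(c)=0$; it is returned as an all-zero
  profile with a `degenerate` flag rather than NaN, and downstream
  prediction then reports the intercept-only probability.

## The classifier

Subtype is modelled by logistic regression on the normalized profile:

$$\log \frac{p_i}{1-p_i} = \beta_0 + g_i \beta^T,$$

where $p_i$ is the probability that sample $i$ is LUAD. The packaged
`published_model()` carries the 15 signature-gene coefficients of the
published FNA-developed classifier verbatim (8 negative, LUSC-favouring; 7
positive, LUAD-favouring; gene symbols stored exactly as published, with no
alias remapping). Housekeeping identities are deliberately not part of the
model object: they belong to the user's panel definition, so the published
coefficients can be applied with any panel that names its housekeeping
genes.

Calls use the closed rule LUAD iff $p \ge 0.5$ (the tie is a LUAD call). In
dual-threshold mode, LUAD iff $p \ge \theta_{LUAD}$, LUSC iff
$p \le \theta_{LUSC}$, and the open interval between them is an
indeterminate zone referred to pathologist review; a probability exactly at
a threshold yields the confident call, mirroring the closed default rule.
The sigmoid is evaluated in a form that cannot overflow at any finite
logit, and small tail probabilities are never clipped to 0.

## The model-development engine

Training minimizes the elastic-net penalized negative Bernoulli
log-likelihood

$$\frac{1}{n}\sum_{i=1}^n\left[-y_i\eta_i + \log(1+e^{\eta_i})\right]
  + \lambda\left[(1-\alpha)\tfrac12\lVert\beta\rVert_2^2
  + \alpha\lVert\beta\rVert_1\right],
  \qquad \eta_i = \beta_0 + g_i\beta^T,$$

with $y_i = 1$ for LUAD, $0$ for LUSC, the intercept unpenalized. The fit is
by coordinate descent (glmnet, unstandardized inputs, convergence threshold
1e-12), and the test suite holds it to within 1e-6 of an independent
brute-force minimizer (box-constrained quasi-Newton on the split
$\beta = \beta^+ - \beta^-$ formulation) across a $(\lambda, \alpha)$ grid.

Model selection follows an intensive-resampling design:

* $\alpha$ grid 0 to 1 in steps of 0.1; 3-fold stratified cross-validation;
  1000 resampling iterations by default. Each iteration draws a **fresh
  stratified fold partition** — "resampling" is read as repeated
  cross-validation, not bootstrap, which matches a repeated k-fold design;
  every fold is guaranteed members of both classes.
* The $\lambda$ path has 100 log-spaced values from the data-derived
  $\lambda_{max}$ down to $\lambda_{max}/100$, computed once per $\alpha$
  from the full training data and shared across the folds of an iteration
  (the same convention as `cv.glmnet`); for $\alpha = 0$ the customary
  surrogate mixing value 0.001 defines $\lambda_{max}$, since ridge never
  fully shrinks.
* Within an iteration, the selected $\lambda$ maximizes the mean held-out
  accuracy (calls at $p \ge 0.5$); ties break to the **largest** penalty,
  the most parsimonious model. Recorded complexity is the
  nonzero-coefficient count of the full-data refit at that penalty.
* Across iterations, the chosen $\alpha$ maximizes mean accuracy (ties to
  the smaller $\alpha$), and the final model is refit on all samples at the
  **median** of that $\alpha$'s per-iteration selected penalties — a robust
  summary for a quantity the development design does not otherwise pin
  down.
* Every random draw derives from the `elastic_net_spec()` seed plus the
  iteration number
  (a fixed linear-congruential combination kept below $2^{31}$), so the
  whole workflow is bit-reproducible at reporting precision.

`convergence_summary()` reduces the records to one winner per iteration
(the $\alpha$ with the best accuracy in that iteration, ties to the
smaller) and reports running means with $\pm 1.96\,\mathrm{sd}/\sqrt{k}$
confidence intervals for complexity, accuracy and $\alpha$; at $k = 1$ the
sd is undefined and the bounds are `NA`.

## Evaluation and threshold calibration

* The c-statistic is the tie-corrected pairwise concordance probability,
  computed via midranks ($O(n\log n)$) and held equal to explicit all-pairs
  enumeration in the tests.
* `calibrate_thresholds()` defines the specificity of the confident-LUAD
  call against the true-LUSC samples (the fraction *not* mis-called LUAD),
  and symmetrically for LUSC — the per-call denominators are a documented
  choice. Candidate thresholds are the observed probabilities, their
  midpoints, and 0/1: every achievable operating point occurs at one of
  these, so the grid search is exact. $\theta_{LUAD}$ is the smallest
  feasible candidate and $\theta_{LUSC}$ the largest, maximizing coverage
  (the fraction confidently called) at the required specificity; when no
  candidate is feasible the extreme threshold is returned with a
  feasibility flag, and if the two confident zones would overlap,
  $\theta_{LUSC}$ is pulled back to $\theta_{LUAD}$ to keep the pair
  ordered. Coverage is non-increasing in the specificity target, a property
  the tests check over random instances.
* The events-per-variable ratio `events_per_variable()` is the usual
  overfitting guardrail (samples per predictor; values around 5 are
  commonly cited as the minimum acceptable).
* The two-sample Kolmogorov–Smirnov D is the supremum of the ECDF
  difference over pooled points; the p-value uses the asymptotic Kolmogorov
  series at effective size $n_1 n_2/(n_1+n_2)$. With NOS groups of around a
  dozen cases the asymptotic p is an approximation and is reported as such;
  an exact small-sample test is deliberately not re-implemented.
* `nos_profile()` compares the predicted-probability distributions of NOS
  cases with the typical subtypes via ECDFs, Gaussian kernel densities
  (Silverman's bandwidth), and the two KS tests. Enrichment-style scoring
  of NOS cases is out of scope: no public definition of that analysis
  exists for this workflow, and guessing one would not be testable.

## The synthetic-cohort generator

No clinical FNA data are deposited with the published classifier, so the
package ships a generative stand-in that emulates the *statistical
structure* of such a study, with full ground truth. Defaults are the
development-cohort conditions: 47 LUAD, 25 LUSC and 11 NOS samples on a
67-gene panel (23 LUAD-associated, 40 LUSC-associated, 4 housekeeping).

Per gene $g$ and sample $i$ the latent log2 mean is
$b_g + s_i + e_{g,i}$: a per-gene baseline $b_g \sim N(7, 1.5^2)$ (log2
units, i.e. typical panel counts of roughly 30–500), a per-sample library
factor $s_i \sim N(0, \sigma_{lib}^2)$ with $\sigma_{lib} = 0.3$, and a
subtype effect $e$ of $\pm$ the gene's effect size for concordant/
discordant role–label pairs (0 for housekeeping). Effects are drawn once
per gene from $N(2, 0.5^2)$ log2 units truncated at zero — a strong
differential-expression regime appropriate for a curated diagnostic panel —
and the COUNTS platform then draws negative-binomial counts around
$2^{latent}$ with dispersion 0.1 (variance $\mu + 0.1\mu^2$), emulating
overdispersed digital counting; FPKM_UQ adds mild log-normal noise (0.25
log2 units) instead of modelling transcript lengths. An optional
`n_signal_*` restriction lets only a subset of each role carry real effect,
turning the remaining diagnostic genes into decoys for feature-selection
recovery studies.

NOS cases have no public generative description beyond being molecularly
atypical, so two modes are offered: `MIXTURE` draws each NOS sample from
one of the class distributions at full strength (label hidden), and
`INTERMEDIATE` — the default — at half strength, which concentrates their
predicted probabilities between the class modes.

What the generator does **not** emulate: tumour purity and stromal
admixture, biological heterogeneity within a subtype, probe chemistry and
background counts, batch structure. Its samples are therefore *cleaner*
than clinical FNA data: at the default all-genes-informative settings the
two classes are essentially separable, and the trained models reach
ceiling cross-validated accuracy — unlike the ~0.9 regime reported for
real cohorts. Passing tests on this generator demonstrate that the
machinery is correct and well calibrated (the label-permuted null stays at
prevalence; planted signal genes are recovered with correct signs), not
that any particular clinical performance level would be attained.

## Problem sizes used by the shipped studies

The test suite and the acceptance script scale the resampling studies to
what a careful reviewer can re-run quickly while keeping every structural
feature of the full design: the recovery and null studies use 100
resampling iterations (× 3 folds × the 11-value $\alpha$ grid) on cohorts
of 100 samples, and the end-to-end demonstration uses 50 iterations on the
default 83-sample cohort; the engine's default remains 1000 iterations.
The convergence machinery makes the cost of that choice visible: the
confidence interval half-width shrinks as $1/\sqrt{k}$, so estimates from
100 iterations are about three times wider than at 1000.

## Known limitations

* The packaged published model requires its 15 gene symbols verbatim;
  alias resolution is intentionally out of scope.
* The KS p-values are asymptotic; with very small groups they are
  indicative rather than exact.
* The generator's NOS modes are constructions, not fitted models of real
  NOS biology.
* Probe-level QC (positive-control linearity, binding density, background
  subtraction) is upstream of this package and not performed.
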