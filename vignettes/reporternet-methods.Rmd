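---
title: "Methods: network-integrated biomarker discovery with reporternet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-integrated biomarker discovery with reporternet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reporternet)
```

## Overview

reporternet implements an integrative biomarker-discovery pipeline for
case/control transcriptome studies, of the kind used to propose diagnostic
and prognostic gene candidates in cancer cohorts. The flow is:

1. per-dataset differential expression (moderated t, BH FDR, fold-change
   filter) and intersection of the DEG calls across independent datasets;
2. over-representation analysis of the common DEGs against user-supplied
   gene sets;
3. reconstruction of the DEG-centred protein-protein interaction (PPI)
   subnetwork and hub selection by degree and betweenness centrality;
4. reporter-feature scoring of transcription factors and receptors over
   bipartite regulator-target networks;
5. pre-clinical validation of the pooled candidates on an independent
   cohort: diagnostic (ROC/AUC) and prognostic (Cox prognostic index,
   Kaplan-Meier, log-rank, hazard ratio) screens, with candidate calling by
   the union rule (diagnostic OR prognostic);
6. cross-validated classification of the final panel.

A synthetic-data generator with planted ground truth makes every stage
testable without any external download; it is first-class, tested code,
not a fixture.

## Differential expression

Each dataset is a normalized genes-by-samples matrix on the log2 scale with
binary case/control labels and at least three samples per phenotype. Per
gene we fit the equal-variance two-group model and shrink the residual
variance $s_g^2$ (on $d_g$ degrees of freedom) toward a prior $s_0^2$
estimated from all genes:

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},
\qquad \tilde t_g = \frac{\bar x_{g,\mathrm{case}} - \bar x_{g,\mathrm{ctrl}}}
{\tilde s_g \sqrt{1/n_1 + 1/n_2}} \sim t_{d_g + d_0}.$$

The hyperparameters $(d_0, s_0^2)$ come from a method-of-moments fit of a
scaled inverse-chi-square distribution to the observed variances, worked on
$\log s_g^2$ using digamma/trigamma moments; when the spread of
log-variances does not exceed chi-square sampling noise we set $d_0 =
\infty$ (complete pooling). The statistic is re-implemented here rather
than delegated, with the limma package serving as an independent
cross-check in the test suite (agreement within 10% relative on shared
input is asserted as a property).

A gene is a DEG iff its BH-adjusted p-value is below `alpha` (default
0.05) **and** its absolute fold change reaches `fc_threshold` (default 2,
i.e. $|\log_2 \mathrm{FC}| \ge 1$). The cross-dataset intersection is by
gene identifier only; genes with conflicting directions across datasets
stay in the common set but are flagged, since membership in the common
signature deliberately ignores the regulation pattern.

Multiple probes per gene are assumed collapsed upstream; the loaders treat
row identifiers as already unique per gene.

## Over-representation

Enrichment of the common DEGs in a user-supplied gene-set collection (GMT)
is the one-sided hypergeometric tail $P(X \ge \text{overlap})$ computed
against the intersection of each set with the measured universe, BH-adjusted
across sets, significant at adjusted $p < 0.01$ by default. No pathway
database is queried; the collection is a plain input file.

## Hub proteins

The PPI subnetwork is the induced subgraph on the common DEGs present in
the interactome plus their first neighbors. *Induced* means
neighbor-neighbor edges are retained; published node/edge counts of this
construction cannot distinguish induced from star expansion, and induced is
the standard behavior of interactive network tools, so it is the documented
choice here. Hubs are the union of the top-`k` nodes by degree and the
top-`k` by betweenness (default `k = 10`), so between `k` and `2k` hubs
emerge. Betweenness is exact and unnormalized (normalization would not
change the ranking but would change reported values). Ties at the k-th
rank are broken by the other metric, then lexicographically — a
deterministic rule chosen here, not a fact inherited from any upstream
tool. Graph handling is delegated to igraph; the test suite checks the
betweenness values against an exhaustive shortest-path enumeration oracle
on all seeded small graphs.

## Reporter features

The reporter-features construction scores a regulator (TF or receptor) by
the collective significance of its measured target genes:

1. gene p-values are converted to $Z_g = \Phi^{-1}(1 - p_g)$, clamped to
   $[10^{-15}, 1 - 10^{-15}]$ before inversion;
2. a feature with $k$ measured neighbors gets
   $Z_{\mathrm{agg}} = \sum_i Z_i / \sqrt{k}$;
3. the aggregate is corrected against the background of random same-size
   gene sets: $Z_{\mathrm{corr}} = (Z_{\mathrm{agg}} - \mu_k)/\sigma_k$,
   with $\mu_k, \sigma_k$ Monte-Carlo moments of the aggregate over
   `n_samples` draws without replacement from the full measured-gene Z
   pool (default $10^5$ draws, cached per distinct $k$, one seeded stream);
4. $p = 1 - \Phi(Z_{\mathrm{corr}})$, BH-adjusted across features,
   significant at adjusted $p < 0.001$.

Design choices made where the construction was genuinely open:

* **Gene-level input.** The per-dataset unadjusted p-values are combined
  across datasets by Fisher's method before Z-conversion. Stouffer
  combination and single-dataset scoring are available alternatives
  (`combine_pvalues()`), but Fisher is the default because it is the most
  common meta-analytic combination when only p-values are shared across
  heterogeneous platforms.
* **Background pool.** Features are scored against all measured genes' Z
  values, not only the common DEGs: the null asks "is this neighborhood
  more significant than a random same-size draw from the transcriptome",
  which requires the transcriptome-wide pool.
* **One-tailed scoring.** The score captures collective significance, not
  direction; regulation directions are reported separately by the DEG
  stage.
* **Threshold.** The default significance rule uses the BH-adjusted
  p-value at 0.001; a `raw_threshold` switch applies the cutoff to the raw
  p-value instead, since both conventions circulate for this statistic.
* Receptor scoring is computationally identical to TF scoring; the
  receptor-protein network is simply a second bipartite input file.

## Validation on an independent cohort

**Diagnostic.** Per candidate, AUC is the Mann-Whitney probability
$(\#\text{concordant} + \tfrac12\#\text{ties})/(n_1 n_0)$, computed from
midranks. Because a marker can separate classes in either direction, the
reported AUC is orientation-maximized, $\max(\mathrm{AUC}, 1 -
\mathrm{AUC})$, with the orientation recorded; the flag threshold is
AUC $\ge$ 0.70.

**Prognostic.** Per candidate: a univariate Cox proportional-hazards
coefficient $\beta$ (Breslow ties, via the survival package, with a dense
grid-search likelihood oracle in the tests) on per-gene standardized
expression, so $\beta$ is per standard deviation; the prognostic index
$PI = \beta x$; a median split of PI into high/low risk (ties at the
median go low); the two-group log-rank test; and the hazard ratio from
observed/expected deaths,

$$HR = \frac{O_1 / E_1}{O_2 / E_2},$$

accumulated over event times. The HR is reported from this O/E formula —
not as $e^\beta$ of a two-group Cox fit — because that is the estimator
the screen is defined with; the two agree within ~15% under proportional
hazards with adequate events, and the test suite asserts that consistency.
The median cut point and the standardization are configurable decisions:
the screen's definition does not fix them, so the defaults (median,
standardized) follow the most common survival-portal conventions.
A candidate is prognostic iff log-rank $p < 0.05$. Genes whose Cox fit
fails (constant expression, no events, monotone likelihood) are returned
as NA rows rather than aborting the panel.

**Candidate rule.** The biomarker candidate set is the union — any pooled
hub/reporter flagged diagnostic OR prognostic — and is therefore monotone
in both validation thresholds.

## Classification

The final panel is evaluated by seeded, stratified k-fold cross-validation
(default 5 folds; folds are a pure function of labels, fold count and
seed). Accuracy, recall and F1 (positive class = case, or dead for the
survival task) are computed natively from the confusion table; the
learners are pluggable backends behind a fit/predict contract, with
k-nearest-neighbour and a decision tree shipped (and random forest when
available) — the point of the stage is the evaluation harness, not any
particular learner. The fold protocol is a documented default: the
evaluation design is not fixed by the screen's definition.

## The synthetic-data generator

The generator emulates the study design end-to-end with planted truth:

* **Discovery datasets** (default 3, 10 case + 10 control each, 600
  genes): per-gene baselines uniform on log2 [4, 10], Gaussian noise
  (sd 0.5), a planted DEG fraction (default 10%) shifted by
  `effect_log2fc` (default 2) in cases with Bernoulli(0.5) sign per gene,
  the same planted set in every dataset. The defaults are chosen so that
  a correctly implemented moderated t at the dual cutoff recovers the
  planted set with high sensitivity at these sample sizes.
* **PPI**: preferential attachment (`attach_m = 2`) over the gene
  universe, giving the scale-free topology and hub structure of curated
  interactomes; identifiers are shuffled onto topological positions so
  planted DEGs are not biased toward high-degree nodes.
* **Bipartite networks**: 50 TFs and 50 receptors with 5-20 targets each;
  5 planted active features per network draw 90% of their targets from
  the planted DEG set, the remainder uniformly from the rest of the
  universe (so zero enrichment is exactly the null).
* **Validation cohort** (100 case + 30 control): measures genes *and*
  regulator identifiers as rows, with a 2-sd case/control shift planted
  on the discovery DEGs and all active features, so candidate regulators
  can themselves be screened — emulating a transcriptome-wide validation
  cohort in which regulators are genes like any other.
* **Survival**: exponential event times with rate
  $h_0 \exp(\sum_g \beta_g x_g)$ on standardized expression
  ($h_0 = 10^{-3}$/day), independent uniform censoring on [0, 3000] days;
  5 planted prognostic rows with $\beta = 1$ per sd.

What the generator does **not** emulate: probe-level microarray effects,
batch effects between datasets, platform mapping, correlated
gene-gene expression structure, non-proportional hazards, and informative
censoring. Passing recovery tests on these bundles therefore demonstrates
correctness of the statistical machinery under its own assumptions, not
performance on real cohorts.

Every generator is a pure function of its arguments including the seed;
the bundle writer produces a plain-text directory dialect that the
pipeline reads back, and a full `run_pipeline()` on the same configuration
is byte-reproducible.

## Numerical choices and degenerate inputs

* P-value clamping at $10^{-15}$ bounds the Z-conversion; Fisher
  combination clamps at $10^{-300}$ before logs.
* The trigamma inverse in the variance-prior fit is solved by Newton
  iteration to $10^{-8}$ relative tolerance.
* The Monte-Carlo background uses draws without replacement and errors on
  a degenerate (zero-variance) pool; at least 1000 draws are required.
* Cox fits iterate to $10^{-9}$ with at most 100 Newton steps; monotone
  likelihoods are raised as errors, and screens convert them to NA rows.
* An all-constant expression matrix, an empty edge list, an empty
  survival table, a single-class label vector and a k-th-rank tie are all
  handled explicitly (error or documented deterministic rule, never
  silence).
* Problem sizes in the test suite and acceptance script (600-2000 genes,
  tens of samples, $5\times10^3$-$10^5$ background draws, 50 survival
  replicates) are chosen as the smallest sizes at which the calibration
  and recovery properties are statistically stable.

## Known limitations

* Identifier matching across matrices and networks is exact string match
  after whitespace trimming; symbol aliasing and probe collapsing belong
  to upstream curation.
* The reporter background treats gene Z-scores as exchangeable; correlated
  co-expression within a neighborhood inflates significance on real data,
  a standard caveat of this statistic.
* The O/E hazard ratio is a crude estimator relative to the Cox partial
  likelihood; it is reported because the screen defines it, with the Cox
  coefficient alongside.
* The pipeline consumes normalized matrices; no normalization is
  performed.
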