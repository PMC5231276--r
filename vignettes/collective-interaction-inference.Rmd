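---
title: "Collective SNP-SNP interaction inference and cell-type enrichment"
author: "epistcell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collective SNP-SNP interaction inference and cell-type enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epistcell)
```

## The model

`epistcell` treats case/control association as a property of the *genotype
distribution* of each phenotype group rather than of a regression of
phenotype on genotype.  For a panel of $m$ SNPs with genotype counts
$g_i \in \{0, 1, 2\}$, each group $y \in \{\text{case}, \text{control}\}$
carries a pairwise exponential-family distribution

$$P_y(\mathbf{g}) \propto \exp\Big(\sum_i h_i^y(g_i) +
  \sum_{i<j} J_{ij}^y(g_i, g_j)\Big),$$

with the baseline level 0 carrying no parameters: $h_i^y(0) = 0$ and
$J_{ij}^y(a, b) = 0$ whenever $a = 0$ or $b = 0$.  Each SNP therefore has 2
free additive parameters and each pair 4 free interaction parameters — the
genotypic model with 2 and 4 degrees of freedom for the additive and
interaction parts.  Disease-associated epistasis appears as *differences*
between $J^{\text{case}}$ and $J^{\text{control}}$: if the two groups'
LD (allele-frequency correlation) patterns coincide, coupling differences
vanish even where LD itself is strong, so the interaction parameters isolate
differential LD rather than LD per se.

Individuals are scored by Bayes' theorem,
$P(\text{case} \mid \mathbf{g}) = \pi q_{\text{case}}(\mathbf{g}) /
[\pi q_{\text{case}}(\mathbf{g}) + (1-\pi) q_{\text{control}}(\mathbf{g})]$,
where $q_y$ is the unnormalized density under group $y$'s fitted parameters
and $\pi$ the prior case probability.

## Fitting

**Penalized pseudo-likelihood** (`fit_group_pseudolikelihood`).  The
normalizing constant of $P_y$ is intractable beyond a few SNPs, so each
group's parameters maximize the sum of conditional log-likelihoods
$\sum_n \sum_i \log P(g_i \mid g_{-i})$ minus an $\ell_2$ penalty
$\lambda \sum_{i<j} \lVert J_{ij} \rVert_F^2$.  Key choices:

* The penalty acts on couplings only.  $\lambda = 0$ and
  $\lambda = \infty$ are then the strongest-interaction and no-interaction
  limits, with fields surviving the infinite-$\lambda$ limit.
* The objective is concave with a unique optimum, optimized by L-BFGS.
  Initialization is deterministic — fields start at their closed-form
  marginal logits, couplings at zero — which shortens the optimization path
  without changing the answer (random restarts agree to $10^{-6}$ in the
  objective).  The convergence tolerance is a relative objective change,
  default $10^{-6}$; difference-of-optima statistics (below) use $10^{-9}$
  because they subtract two large objective values.
* Penalizer values at or above `LAMBDA_NONINTERACTING` ($10^6$) are treated
  as the exact non-interacting limit: couplings identically zero and fields
  equal to the closed-form marginal multinomial logits.  This makes the
  reduction of collective single-SNP p-values to the independent-SNP test an
  identity rather than an approximation, and makes the non-interacting
  reference arm of cross-validation cheap and exact.
* Missing genotypes: a missing $g_j$ drops the $(i,j)$ term from SNP $i$'s
  conditional; a missing $g_i$ drops that individual's $i$-th conditional
  (a pairwise-complete policy, unbiased under missingness completely at
  random).  Missing entries contribute 0 to the Bayes-risk exponent.

**Mean-field option** (`fit_group_meanfield`).  For pathway-scale panels
(thousands of SNPs) iterative optimization over all pairs is impractical;
couplings are instead the negative off-diagonal blocks of the inverse
(ridge-regularized) covariance of the $2m$ dummy indicators
$1[g_i = 1], 1[g_i = 2]$, and fields are marginal logits minus the
mean-field correction.  This is the standard naive inverse-covariance
construction; it is an approximation and is used where speed, not per-pair
testing, is the goal.  The ridge default (0.1) keeps the covariance
invertible for panels wider than the sample size; results are insensitive
to it in the well-conditioned regime.

**Calibration of the Bayes risk.**  The two groups' normalizing constants
are absorbed into a single intercept, fitted by intercept-only logistic
recalibration of the unnormalized log-ratio on the training data.  A
monotone transform of the score, it preserves rankings (hence AUC) exactly
while giving usable probabilities.

## Statistics

**Independent-SNP test** (`genotypic_test`): the 2-df multinomial
likelihood-ratio (G-test) comparing separate versus pooled 3-category
genotype distributions — the non-interacting special case of the collective
model.  Zero cells contribute 0 to the sum; degrees of freedom are the
observed pooled levels minus one, capped at 2.  On large tables it agrees
with the Pearson chi-square to $O(1/n)$, which ties it to conventional
genotypic association scans.

**Collective single-SNP p-values** (`collective_single_snp_pvalue`):
a likelihood-ratio statistic comparing the fitted model against a refit with
one SNP's case and control field vectors tied (couplings held fixed),
referred to $\chi^2(2)$.  With one SNP, or at the non-interacting limit, it
reduces exactly to the independent-SNP test.

**Interaction statistics** (`pair_lr_statistic`): the alternative is the
standard per-group fit; the null re-optimizes *all* parameters of both
groups under the single constraint
$J_{ij}^{\text{case}} = J_{ij}^{\text{control}}$ for the tested pair.
Because every pair factor appears in two conditionals of the
pseudo-likelihood, the raw objective difference counts the tested pair's
information twice; the statistic is therefore the duplication-corrected
difference $\mathrm{PL}(\hat\theta_{\text{alt}}) -
\mathrm{PL}(\hat\theta_{\text{null}})$, which coincides with the
exact-likelihood ratio statistic on enumerable models and has null mean
near its 4 degrees of freedom.  P-values come from phenotype-label
permutation (`permutation_pvalues`): one shared set of permutation
replicates serves all pairs (each replicate is one collective inference,
which is what makes the computation feasible), and the add-one estimator
$(1 + \#\{S_\pi \ge S\})/(1 + B)$ never returns zero.

**Cross-validation** (`run_cv`): stratified five-fold assignment by seeded
shuffle; SNP selection (p-value cutoff or top-$m$) is recomputed inside
each training fold; held-out predictions from all folds are pooled into one
AUC per $\lambda$ (Mann-Whitney form, ties one half; Hanley-McNeil 95% CI —
the CI construction is a package choice).  $\Delta$AUC is the maximum AUC
minus the AUC at the largest grid $\lambda$ (the non-interacting proxy,
cross-checked against a couplings-off fit), and its significance is
estimated by permuting phenotype labels over all individuals before fold
assignment and rerunning the *full* cross-validation, selection included.

## Epigenomic enrichment

Chromatin states from 15-state segmentations are reduced to *active*
(TssA, TssAFlnk, TxFlnk, Tx, TxWk, Enh, EnhG, ZNF/Rpts) versus *inactive*
(Het, TssBiv, BivFlnk, EnhBiv, ReprPC, ReprPCWk, Quies).  "ZNF/Rpts" is a
single segmentation state; both of its name parts are accepted as synonyms,
and any other label is an error.  Because genotyped proxies stand in for
unobserved causal SNPs, activity is averaged over each proxy's LD group
(all known SNPs with $r^2 > 0.5$): $f(\text{proxy}, E)$ is the fraction of
LD members inside active intervals of epigenome $E$, and $b(E)$ is the
active fraction of the segmentation by length.  SNP positions are 1-based;
BED intervals are 0-based half-open; a position equal to an interval's BED
end belongs to the next interval.  Uncovered positions count inactive with
a warning (strict mode errors), since real segmentations tile the genome
but synthetic ones need not.

Enrichment uses upper-tail binomial tests with fractional effective counts
rounded *up* to integers (the ceiling is applied exactly as specified even
though it is anti-conservative for small counts).  For interacting pairs,
the effective count of an ordered epigenome combination $(E_a, E_b)$ sums,
over significant proxy pairs $(P, Q)$, the fraction of LD member pairs with
$u \in LD(P)$ active in $E_a$ and $v \in LD(Q)$ active in $E_b$, normalized
by $|LD(P)|\,|LD(Q)|$; the background is $b(E_a) b(E_b)$ times the number
of significant pairs.  Combinations are *ordered* because biology
distinguishes which locus acts in which cell type; symmetric summaries can
be formed by averaging mirror combinations.  Spatial maps accumulate the
same normalized contributions onto bin pairs of a genomic grid (20-kb bins
for counts; 100-kb for enrichment so that expected counts exceed 1, below
which bins are reported untested).  Mirror cells each receive half a
contribution, so maps are symmetric while their total still equals the
effective count exactly — a conservation law the tests assert.

## SNP panels and pathways

Proxy panels are built either by region-stratified quotas on independent-SNP
p-values (ties broken by position then id) or by reducing a larger
candidate set with k-medoids (PAM) on the LD distance $d = -\log r^2$
($r^2 = 0$ capped at $d = 30$), keeping each cluster's smallest-p member.
PAM is used because k-means is ill-posed on a non-Euclidean distance; it is
the reproducible interpretation of clustering on an LD distance.  Pathway
SNP sets are non-redundant unions of SNPs within 50 kb (inclusive at both
boundaries) of constituent genes' coding regions; pathways wider than
2,000 SNPs are reduced by in-fold p-value filtering, preserving
cross-validation hygiene.  Pathway scores are cross-validated AUCs of the
mean-field collective model next to a couplings-off reference.

## The synthetic-data generator

Real genotype resources for this analysis are access-restricted, so the
package generates data with the statistical structure the method assumes,
with known ground truth:

* **Genotypes** are sampled from the pairwise model itself: one independent
  Gibbs chain per individual (systematic scan, burn-in of at least 50
  sweeps when couplings are present, one retained state), guaranteeing
  inter-individual independence.  Coupling-free specs are sampled exactly
  from the closed-form marginals.  The planted signal is a coupling that
  *differs* between groups; the test fixtures couple levels (1,1)/(2,2) in
  cases and (1,2)/(2,1) in controls, which by level-swap symmetry leaves
  every single-SNP marginal identical across groups — association then
  lives purely in interactions.  Positions sit on one synthetic chromosome
  at 5-kb spacing from 31 Mb so that the 31-33 Mb spatial-grid paths run
  on synthetic coordinates.
* **Segmentations** tile each SNP's neighborhood with a core segment
  (containing the SNP, active with a controllable probability, boosted for
  planted pairs in a designated epigenome combination) and an adjacent
  shadow segment of opposite activity.  States are drawn from the 15-label
  vocabulary so the reduction step is always exercised.
* **LD groups** place concordant members (probability =
  `activity_concordance`) in the proxy's core and discordant members in the
  shadow, so group activity concordance is exact by construction in every
  epigenome, and member $r^2$ values lie in $(0.5, 1]$.

What the generator does *not* emulate: realistic human LD block structure,
allele-frequency spectra, Hardy-Weinberg structure, genotyping error, or
population stratification.  Passing recovery tests therefore demonstrates
that the inference machinery is correct and calibrated for data drawn from
its own model class — not that the biological conclusions of any particular
study would replicate.

## Problem sizes and numerical choices

The shipped tests run the full machinery at deliberately small scale,
chosen as the smallest sizes at which each property is sharply testable:
oracle comparisons enumerate $3^m$ states for $m \le 3$ at $n = 5000$;
permutation calibration uses hundreds of replicates of two- and three-SNP
panels with 99 permutations each; signal-recovery fixtures use a few
hundred individuals with planted couplings of magnitude around 1.2, where
the Bayes-optimal AUC (computable by enumeration) is near 0.8.  Tie-breaks
are deterministic everywhere (position, then id); all stochastic steps are
driven by explicit integer seeds, and regenerating any fixture with the
same seed is bit-identical.

## Known limitations

* The pseudo-likelihood composite information identity does not hold
  exactly at finite $n$, so asymptotic $\chi^2$ p-values for interactions
  are approximations; permutation p-values are the primary inference and
  the asymptotic form is used only where stated.
* The mean-field fit is a linear-response approximation, accurate for weak
  couplings; per-pair testing always uses the pseudo-likelihood path.
* Bayes-risk probabilities are calibrated only up to the intercept-only
  recalibration; covariate adjustment and population-structure correction
  are out of scope.
* With fewer than ~20 permutation replicates, add-one p-values are too
  coarse to threshold at conventional levels; the functions refuse
  `n_perm < 19`.
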