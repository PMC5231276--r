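# epistcell

Collective (epistatic) SNP–SNP interaction inference for case/control
genotype data, with cell-type-specific epigenomic enrichment and spatial
mapping of the interacting pairs.

## Who this is for

Statistical geneticists who suspect that part of a disease's heritability
hides in *interactions* between variants — differences in allele-frequency
correlation (differential LD) between cases and controls that no
single-SNP scan can see — and who want to (a) quantify the predictive gain
from modeling those interactions, (b) test individual SNP pairs by
permutation, and (c) ask *in which cell types* the interacting loci are
epigenetically active.

## The model

Each phenotype group `y` gets its own pairwise exponential-family
distribution over genotype counts `g ∈ {0,1,2}^m`:

    P_y(g) ∝ exp( Σ_i h_i^y(g_i) + Σ_{i<j} J_ij^y(g_i, g_j) )

with level 0 as baseline (2 free additive parameters per SNP, 4 free
interaction parameters per pair — the genotypic model).  Groups are fitted
separately by an l2-penalized pseudo-likelihood (penalizer λ on couplings
only, so λ = ∞ is the no-interaction limit) or a fast mean-field
(inverse-covariance) approximation for pathway-scale panels.  Individuals
are scored by Bayes' theorem; model quality is the cross-validated AUC, and
ΔAUC — maximum AUC minus the non-interacting limit — measures the gain from
interactions, with significance from phenotype-label permutation.  Per-pair
interaction statistics compare the per-group fits against a joint refit with
that pair's couplings constrained equal across groups; their null
distributions are again sampled by permutation.  Significant pairs are then
mapped onto chromatin-state segmentations of reference epigenomes:
active-state frequencies are averaged over each proxy SNP's LD group,
enrichment of active pairs in each (ordered) epigenome combination is tested
binomially, and contributions are resolved spatially on 20-kb/100-kb grids.

A full synthetic-data generator (Gibbs sampling from the model, chromatin
segmentations with planted co-activity, LD-proxy groups with controlled
concordance) provides fixtures with known ground truth; all study inputs can
also be read from PLINK text/binary layouts, BED4 segmentations, LD TSVs,
GMT pathway files and gene tables.

## Worked example

```r
library(epistcell)

# plant a coupling that differs between groups but leaves marginals equal:
# cases couple levels (1,1)/(2,2), controls (1,2)/(2,1)
Jc <- matrix(c(1.2, 0, 0, 1.2), 2); Jk <- matrix(c(0, 1.2, 1.2, 0), 2)
spec <- sim_spec(300, 300, 4,
                 couplings_case    = list(coupling(1, 2, Jc), coupling(3, 4, Jc)),
                 couplings_control = list(coupling(1, 2, Jk), coupling(3, 4, Jk)),
                 seed = 11)
gm <- simulate_genotypes(spec)$gm

# single-SNP scan: no marginal signal (all p > 0.5 here)
round(genomewide_scan(gm)$p_value, 2)
#> [1] 0.84 0.80 0.51 0.86

# cross-validated AUC across the penalizer grid
cfg <- cv_config(k_folds = 5, lambda_grid = c(0.02, 0.1, 1e6), top_m = 4, seed = 9)
run_cv(gm, cfg)
#>  lambda       auc         se     ci_lo     ci_hi
#>   2e-02 0.8155167 0.01743667 0.7813414 0.8496919
#>   1e-01 0.8156833 0.01742960 0.7815219 0.8498447
#>   1e+06 0.4155833 0.02317760 0.3701561 0.4610106
#> mean selected m = 4.0; delta AUC = 0.4001
```

The non-interacting limit (λ = 1e6) sits at chance — the marginals carry no
signal — while the interacting model reaches AUC ≈ 0.82, close to the
Bayes-optimal value computable by enumeration for this spec.  ΔAUC ≈ 0.40 is
the interaction gain.  Per-pair permutation tests then localize the signal
(`permutation_pvalues`, `significant_pairs`), and the enrichment stage
(`activity_profile`, `enrichment_landscape`, `spatial_map`) recovers which
epigenome combination the planted pairs are active in.

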