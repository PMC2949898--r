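# biorder

Bi-ordering analysis of gene × sample expression matrices: a fixed-point
biclustering algorithm that ranks *every* gene and *every* sample, a
multi-start consensus layer that condenses its local optima into stable
**super-biclusters**, and statistics that connect the results to sample
phenotypes — hypergeometric class-saturation p-values and the Jonckheere
trend test.

## Who this is for

Analysts of expression cohorts (bulk microarray or RNA-seq–derived
matrices, or single-cell pseudobulk) who need modules of genes that are
coherently over- or under-expressed across a *subset* of samples, with a
measure of how stable each module is and how strongly it aligns with
categorical phenotypes (e.g. histological subtypes) or an ordinal gradient
(e.g. disease progression grade).

## The method in brief

Given a normalized matrix $x_{gs}$, thresholds $\theta_G, \theta_S$ and an
initial sample subset $S$, iterate until both member sets stabilize:

$$f(g) = \langle x_{gs}\rangle_{s\in S},\qquad
  G = \{g:\ f(g)-\overline f > \theta_G/\sqrt{|S|}\}$$
$$h(s) = \langle x_{gs}\rangle_{g\in G},\qquad
  S = \{s:\ h(s)-\overline h > \theta_S/\sqrt{|G|}\}$$

(The denominator is configurable: `sqrt` or `linear`. An under-expression
mode mirrors both inequalities, and a fixed-size variant with guaranteed
termination replaces the thresholds by top-$k$ rank selection.)

The scores $f$ and $h$ order all genes and samples — the *bi-ordering* —
so a fitted bicluster also ranks non-members, which is what makes trend
tests against ordinal annotations possible. `bea()` repeats the iteration
from many Bernoulli(0.2) random sample subsets, deduplicates the converged
results, groups them by gene-set Jaccard similarity (average-linkage, cut
at 0.5) into super-biclusters, and evaluates each group's prototype:

- **SCS / MCS**: hypergeometric upper-tail p-value of the best single
  class / best class subset inside the bicluster (log-space exact tail);
- **Jonckheere trend**: signed one-sided p-value for monotone agreement
  between the sample ordering $h$ and an ordinal score.

## Worked example

A 300 × 60 matrix with one 30-gene × 15-sample block (shift 3, planted in
class A of three classes) and 50 random initializations:

```r
library(biorder)
des <- planted_design(
  n_genes = 300, n_samples = 60,
  class_sizes = c(A = 20, B = 20, C = 20),
  blocks = list(list(genes = 1:30, n_samples = 15, classes = "A",
                     shift = 3, sign = 1))
)
sim <- generate_matrix(des, seed = 7)
fit <- bea(sim$x, sim$annotation, theta_g = 2.8, theta_s = 2,
           n_init = 50, seed = 7, normalize = FALSE)
fit
#> Bi-ordering exploratory analysis
#>   matrix: 300 genes x 60 samples (normalized: FALSE, center = median)
#>   BOA: theta_g = 2.8, theta_s = 2, mode = over, denominator = sqrt
#>   50 initializations (p = 0.2, seed = 7): 48 converged, 2 empty/non-converged
#>   2 unique bicluster(s) -> 2 super-bicluster(s) at Jaccard >= 0.5 (average linkage)
summary(fit)
#> Super-bicluster report (ordered by convergence count)
#>   sbc n_members convergence_count prototype_count n_genes n_samples scs_class
#>  SBC1         1                47              47      30        15         A
#>  SBC2         1                 1               1       1         3         B
#>     scs_p mcs_classes    mcs_p trend_signed_p trend_z
#>  2.91e-10           A 2.91e-10      -8.11e-05  -3.770
#>  2.55e-01           B 2.55e-01       1.64e-01   0.977
recovery_score(fit$superbiclusters[[1]]$prototype, sim$truth[[1]])
#>   gene_jaccard sample_jaccard
#>              1              1
```

Reading the output: 47 of 50 random starts converged to the planted block
exactly (its "basin of attraction"), giving one dominant super-bicluster.
Its prototype is saturated with class A (hypergeometric tail
p ≈ 2.9 × 10⁻¹⁰ — all 15 bicluster samples come from the 20 class-A
samples among 60), and its sample ordering *decreases* along the class
gradient A → C (signed trend p ≈ −8 × 10⁻⁵), as expected for a block
over-expressed in the first class. The singleton SBC2 is a noise
bicluster: 1 gene, no significant saturation — stability (convergence
count) is exactly the feature that separates it from the real module.

`plot(fit)` draws the prototype heat map: member genes ordered by $f$,
all samples ordered by $h$, with the bicluster boundary marked on the
sample axis.

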