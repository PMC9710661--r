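# markerdens

Threshold-free stratification of multiplex tissue-imaging cohorts by the
probability density of a functional marker.

## What problem this solves

Multiplex imaging platforms (mIHC, MIBI, CODEX, ...) measure continuous
per-cell intensities of functional markers such as HLA-DR, PD1, PD-L1 or
Lag3 across the tumor microenvironment of each subject. The conventional
subject-level analysis double-thresholds this signal: a cell is *positive*
if its intensity exceeds `t1`, a subject is *high* if its positive-cell
fraction exceeds `t2` — and both cutoffs are subjective choices that
binarize away most of the information.

`markerdens` compares subjects by their whole intensity *density* instead.
For each subject `j` with scaled intensities `X_ij ∈ [0,1]`, it estimates
the Gaussian-kernel density

    f̂_j(x) = n_j⁻¹ Σ_i w_h(x − X_ij),   h by Silverman's rule of thumb,

on a shared 1024-point grid, and quantifies between-subject differences by
the discrete Jensen–Shannon divergence of the normalized grid masses,

    JSD_jj' = Σ_r [ p_r ln(2p_r/(p_r+q_r)) + q_r ln(2q_r/(p_r+q_r)) ] ∈ [0, 2 ln 2].

The resulting distance matrix `D` feeds two analysis routes:

* **hierarchical stratification** (Ward linkage by default, cut at K
  groups), with the group labels tested against outcomes — a Wald test in
  a linear model for continuous outcomes, a Cox proportional-hazards LRT
  (with Kaplan–Meier summaries) for survival;
* **kernel association tests** using the similarity matrix `G = exp(−D)`
  as the covariance of a subject-level random effect: a variance-component
  LRT in a linear mixed model, and a Laplace-approximated Cox frailty LRT,
  both against the boundary-corrected 50:50 mixture null.

The package also ships the two classical comparators (two-threshold
positivity clustering; K-means on extreme-quantile vectors), a Monte-Carlo
benchmark harness (`run_study()`) reproducing the accuracy tables of the
method's validation study, and a small CLI.

## Worked example

```r
library(markerdens)

dir <- tempfile(); files <- make_fixtures(dir)   # 12-subject toy cohort

D <- cmd_distance(files["cells"], marker = "HLA_DR", cell_type = "CK+")
#> distance matrix: 12 subjects, median cells/subject 55, bandwidths [0.03129, 0.06594]

round(D[1:4, 1:4], 3)
#>       P01   P02   P03   P04
#> P01 0.000 0.022 0.049 0.019
#> P02 0.022 0.000 0.047 0.036
#> P03 0.049 0.047 0.000 0.031
#> P04 0.019 0.036 0.031 0.000

res <- cmd_cluster_test(D, files["outcomes"], model = "coxph")
res$labels
#> <subject_clusters> method=hierarchical, sizes: 6/6
#> P01 P02 P03 P04 P05 P06 P07 P08 P09 P10 P11 P12
#>   1   1   1   1   1   1   2   2   2   2   2   2
res$test
#> <assoc_test> Cox PH likelihood-ratio test (cluster label)
#>   statistic = 0.372  (chi-square(1))
#>   p-value   = 0.5419
#>   effect    = HR=2.579
```

The density clustering recovers the two generating groups of the toy
cohort exactly (subjects P01–P06 vs P07–P12). The hazard ratio between the
strata is 2.6, but with only 12 subjects the LRT is, as it should be, far
from significant. `plot(res$km)` draws the annotated Kaplan–Meier curves.

One cell of the simulation benchmark (sharp-peak design, mode shift 100%,
200 cells/subject, 10 replications):

```r
run_study("beta-shift-A", n_cells = 200, l = 100, reps = 10, seed = 1)
#> <replication_study> beta-shift-A, n=200, l=100, reps=10, seed=1
#>            method mean_ari   mc_se reps
#> 1             jsd   1.0000 0.00000   10
#> 2 quantile_kmeans   0.6304 0.03282   10
#> 3     threshold95   0.1817 0.02245   10
#> 4   threshold97.5   0.6389 0.01427   10
```

The density route separates the groups perfectly while both thresholding
comparators and the quantile heuristic fall well short — the qualitative
ordering the method was designed to demonstrate.

## Command line

```sh
Rscript inst/cli/markerdens.R distance --cells cells.csv --marker HLA_DR \
    --cell-type "CK+" --out D.csv
Rscript inst/cli/markerdens.R cluster-test --distance D.csv \
    --outcome outcomes.csv --model coxph --km-plot km.png
Rscript inst/cli/markerdens.R simulate --config sim.json --out-dir results/
```

Exit codes: 0 success, 2 usage/config error, 3 data error, 4 numerical
failure.

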