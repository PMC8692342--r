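# spectralimpute

Missing-value imputation for gene-expression matrices (genes × samples),
built on local similarity structure. Expression data routinely arrive
with missing cells — weak spots, hybridization faults, slide artifacts —
while most downstream analyses (clustering, classification, differential
expression) require a complete matrix. This package estimates each
missing entry from genes with similar profiles, with the donor pool
restricted by clustering so that unrelated expression programs cannot
contaminate an estimate.

## Method

For a matrix *G* (*N* genes × *M* samples) with availability indicator
*H* (*h<sub>ij</sub>* = 1 iff *G<sub>ij</sub>* observed):

1. **Similarity graph** — pairwise-complete Euclidean distances
   (rescaled by √(*M*/*m<sub>obs</sub>*) for overlap size) are mapped to
   edge weights *S<sub>ij</sub>* = exp(−*d*²/2σ²); full, kNN
   (normal/mutual) and ε-neighbourhood constructions, stored sparsely.
2. **Spectral clustering** — from the random-walk Laplacian
   *L<sub>rw</sub>* = *D*⁻¹(*D* − *W*), genes are embedded by the bottom
   *K* eigenvectors and clustered with K-means (eigengap heuristic for
   *K* = "auto").
3. **Weighted top-K′ imputation** — each missing cell takes the
   inverse-distance weighted mean of its *k′* nearest same-cluster genes
   that observe the sample: *P<sub>i</sub>* = (1/*d<sub>i</sub>*) / Σ
   (1/*d<sub>l</sub>*), *I* = Σ *P<sub>i</sub> g<sub>iu</sub>*;
   categorical attributes take the level with the largest accumulated
   weight.

Five classical local baselines ship behind the same interface:
`knn_impute`, `sknn_impute`, `iknn_impute`, `lls_impute`, `slls_impute`.
A benchmarking module injects exact-count MCAR/MAR missingness, runs 30
replicate masks in a paired design, scores masked-cell RMSE, and sweeps
the neighbour count. A synthetic generator produces complete matrices
with planted block structure so every stage is testable offline. See the
methods vignette (`vignettes/cluster-guided-imputation.Rmd`) for the
model, parameter meanings, and design decisions.

## Worked example

```r
library(spectralimpute)

gen <- generate_clustered_expression(
  synthetic_spec(n_genes = 120, n_samples = 15, n_blocks = 3,
                 separation = 5, noise_sd = 1, seed = 7))
inj <- inject_missing(gen$matrix, masking_spec(rate = 0.10, seed = 7), 1)
res <- impute_dataset(inj$masked, imputer_config(k_prime = 15, n_clusters = "auto"))

res$model
#> ClusterModel: K=3 clusters over 120 genes (sizes: 40, 40, 40)
res
#> ImputationResult: 180 cell(s) imputed, 0 via fallback
rmse(inj$truth, res$completed)
#> [1] 0.9959066
rmse(inj$truth, lls_impute(inj$masked, k = 10)$completed)
#> [1] 4.235148
```

The eigengap heuristic recovers the three planted blocks exactly
(40/40/40), all 180 masked cells are imputed from in-cluster donors (no
fallbacks), and the masked-cell RMSE is close to the per-cell noise sd
of 1 — the best achievable here, since donors carry independent unit
noise. On this cleanly separated toy, plain KNN picks the same donors
and ties the proposed method; the cluster restriction pays off when
missingness or weak separation lets out-of-cluster genes into a global
neighbour list (see the 25% benchmark in
`tests/testthat/test-acceptance.R`). LLS with k = 10 regressors on 13
observed samples extrapolates and does far worse (RMSE 4.24).

## Command line

```sh
Rscript inst/cli/impute.R simulate  --genes 300 --samples 20 --blocks 3 --seed 7 --out synth.tsv
Rscript inst/cli/impute.R impute    --input matrix.tsv --missing-marker "?" \
                                    --method proposed --k-prime 15 --clusters auto \
                                    --output imputed.tsv --provenance prov.tsv
Rscript inst/cli/impute.R benchmark --input synth.tsv --methods proposed,knn,slls \
                                    --rates 0.05,0.25 --replicates 30 --out report.tsv
Rscript inst/cli/impute.R sweep     --input synth.tsv --method knn --k 1,5,15,50,300 \
                                    --rate 0.05 --out sweep.tsv
```

Input tables are TSV with a gene-id first column and a sample-id header;
the missing marker is configurable (`?`, `NA`, `null`, empty by
default). GEO GDS SOFT files are read with `read_gds_soft()`.

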