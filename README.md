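# epitensor

Tensor completion for imputing missing epigenomic signal experiments.

Consortium-scale epigenome mapping (histone ChIP-seq, DNase-seq, ...)
covers only a fraction of the cell type x assay grid. epitensor arranges
the available genome-wide signal tracks as a third-order tensor
`D` (cell types x assays x genomic bins), in which a missing experiment
is a whole fiber along the genome axis, and imputes those fibers with a
PARAFAC/CANDECOMP factorization augmented with per-dimension biases:

```
D[j,k,i]  ~  sum_l C[j,l] * A[k,l] * G[i,l]  +  c[j] + a[k] + g[i]
```

fit by minimizing squared error over observed entries plus L2 penalties
on the factor matrices. Signal is 25 bp-binned bedGraph coverage on the
`-log10 p` scale, variance-stabilized with `asinh`; fitting and all
quality measures stay on the transformed scale.

The package provides the full training procedure (seeded
initialization, burn-in, partition-parallel SGD with element-wise
parameter averaging, Adam with Nesterov momentum and decay schedules,
rank-sum convergence detection, restart line search, and a closed-form
ridge solve of the genome parameters), an additive main-effects
baseline, ten imputation quality measures with cross-method comparison
statistics, stratified test/validation splitting, and a seeded
synthetic low-rank generator so everything is testable without
downloads. The inner SGD loop is compiled (Rcpp); training is
bit-reproducible from a single integer seed.

Intended users: computational biologists imputing signal for
under-assayed cell types, and methods developers who need a transparent
reference implementation of bias-augmented tensor completion.

## Worked example

Simulate a tensor with the structure the model assumes (low-rank truth,
per-dimension biases, Gaussian noise, fiber-wise missingness), train two
validation-fold models, and evaluate the consensus on held-out fibers:

```r
library(epitensor)

syn <- generate_tensor(J = 30, K = 12, I = 2000, L_true = 4, sigma = 0.1,
                       observed_fraction = 0.4, min_support = 3, seed = 1)
D <- syn$tensor
D
#> obs_tensor: 30 cell types x 12 assays x 2000 bins (asinh scale)
#>   144 / 360 experiments observed (60.0% missing)

keys   <- observed_keys(D)
splits <- make_splits(keys, n_test = 5, n_folds = 8, seed = 1)
cfg  <- training_config(L = 8, partition_size = 250, local_iters = 1000,
                        training_locus_fraction = 0.25, seed = 101)
fit  <- train_parafac(D, splits, test_set = 1, fold = 1, config = cfg)
tail(fit$log, 3)
#>     round train_mse valid_mse test_mse      eta       event
#> 253   747   0.00928    0.0234   0.0360 0.000562       round
#> 254   750   0.00928    0.0235   0.0360 0.000562       round
#> 255   751   0.00963    0.0231   0.0353 0.000562 final-solve

cfg2 <- cfg; cfg2$seed <- 102L
fit2 <- train_parafac(D, splits, test_set = 1, fold = 2, config = cfg2)

test_keys <- keys[splits$test_set == 1, ]
imp <- (predict_fibers(fit$model,  test_keys) +
        predict_fibers(fit2$model, test_keys)) / 2
obs <- t(apply(test_keys, 1, function(r) D$values[r[1], r[2], ]))
mean((imp - obs)^2)
#> held-out fibers: 29   consensus MSE: 0.0218 (noise floor 0.01)

round(evaluate_experiment(imp[1, ], obs[1, ]), 4)
#>    MSEglobal      MSE1obs      MSE1imp       GWcorr       Match1    Catch1obs
#>       0.0196       0.0344       0.0264       0.9657       0.8000       1.0000
#>    Catch1imp      AucObs1      AucImp1 CatchPeakObs
#>       1.0000       0.9985       0.9972           NA
```

Reading the numbers: each fold's model converges after a few hundred
parallel rounds (`valid_mse` is monitored every three rounds and the
best checkpoint kept; the `final-solve` row is the closed-form genome
update). The two-fold consensus reaches a held-out-fiber MSE of 0.022
against an irreducible noise floor of sigma^2 = 0.01, genome-wide
correlation 0.97 on the first test fiber, and recovers the top-1%
signal windows essentially perfectly (Catch/AUC measures near 1).
`CatchPeakObs` is `NA` because no peak calls were supplied; pass
per-bin labels (see `peaks_to_labels()`) to compute it. The example
averages raw fiber predictions because the synthetic truth is signed;
for real `-log10 p` tracks use `impute_consensus()`, which additionally
clamps negative imputed values to zero.

For production-style I/O there is a thin command-line front end in
`inst/cli/epitensor.R` with subcommands `simulate`, `prepare` (bin +
transform bedGraph tracks into a tensor container), `split`, `train`,
`impute`, `evaluate`, and `compare`.

## Layout

- `R/` — data model and transforms, baseline, factorization core,
  trainer, metrics, synthetic generator
- `src/` — compiled local-SGD inner loop
- `tests/testthat/` — unit, property and end-to-end suites with
  independent oracles
- `vignettes/tensor-imputation-methods.Rmd` — model, procedure,
  parameter table, design decisions, limitations
- `inst/cli/epitensor.R` — command-line front end
- `scripts/acceptance.R` — see above
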