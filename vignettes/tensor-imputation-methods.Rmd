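---
title: "Imputing epigenomic signal by tensor completion: model and methods"
author: "epitensor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imputing epigenomic signal by tensor completion: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epitensor)
```

## The problem and the model

Consortium-scale epigenome mapping measures many assays (histone
ChIP-seq, DNase-seq) across many cell types, but only a fraction of the
cell type x assay grid is ever assayed. Arranging the available
genome-wide signal tracks as a third-order tensor $D$ of dimension
$J \times K \times I$ (cell types x assays x genomic bins), a missing
experiment is a whole *fiber* along the genome axis. epitensor imputes
those fibers by fitting a PARAFAC/CANDECOMP factorization with additive
per-dimension biases:

$$
\hat D_{jki} \;=\; \sum_{l=1}^{L} C_{jl}\,A_{kl}\,G_{il}
\;+\; c_j + a_k + g_i ,
$$

minimizing the squared error over the observed training entries plus L2
penalties $\lambda_C\|C\|_F^2 + \lambda_A\|A\|_F^2 + \lambda_G\|G\|_F^2$
(the bias vectors are not penalized). The biases absorb per-cell-type,
per-assay and per-position scale so the low-rank term only has to
explain residual structure; beyond the L2 terms there are no
constraints on the factors (no non-negativity, no orthogonality).

Signal enters the tensor as bedGraph $-\log_{10} p$ coverage, averaged
into 25 bp bins and passed through the inverse hyperbolic sine
$\operatorname{asinh}(x) = \ln(x + \sqrt{x^2+1})$, a log-like
variance-stabilizing transform that is defined at zero. Every fit and
every quality measure operates on this transformed scale; the transform
is never reversed for evaluation, which keeps the Gaussian error model
consistent with the squared-error objective.

## Data preparation choices

* **Coordinates** are 0-based half-open on disk (bedGraph convention)
  and 1-based inside R.
* **Binning** (`bin_track()`) uses base-pair-weighted means, with bases
  covered by no interval contributing zero. Generic mapping tools often
  average overlapping interval values unweighted; the weighted mean is
  the better-defined contract (it conserves signal mass when bins tile
  the covered region) and is what this package fixes.
* **Support filter** (`filter_min_support()`): cell types or assays
  with fewer than five completed experiments are removed, iterating to
  a fixed point so every retained label keeps at least five experiments
  among retained labels. On the Roadmap Consolidated availability grid
  this leaves 127 cell types, 24 assays and 1014 experiments; that
  external grid is not shipped here, so the property is documented
  rather than tested.
* **Splits** (`make_splits()`): observed experiments are divided into
  five disjoint test sets, stratified so per-cell-type (and, where
  counts allow, per-assay) test-set sizes differ by at most one; each
  test set's training keys are further partitioned into eight
  validation folds of near-equal size. The stratification algorithm —
  seeded shuffle, then greedy round-robin per cell type with assay
  rebalancing — is this package's concrete choice; only "stratified"
  is inherited. The exact 203/100/711 experiment counts of the original
  1014-experiment split depend on unstated rounding and are not a
  contract.

## Training procedure

`train_parafac()` orchestrates, for one (test set, validation fold)
pair:

1. **Locus subsample.** A seeded random fraction of loci (default 1%)
   is used for the main phase; the genome parameters for all other loci
   are produced later by the closed-form solve.
2. **Initialization** (`init_model()`): factors i.i.d. uniform on
   $(-0.33, 0.33)$; biases from plane means. Taking all three bias
   vectors verbatim as plane means would count the global mean three
   times, so the package centers them: $c_j = \mu_j - \mu$,
   $a_k = \mu_k - \mu$, $g_i = \mu_i$, making the bias-only prediction
   a main-effects-style estimate.
3. **Burn-in** (`burn_in()`): one sequential pass over a seeded half of
   the training entries restricted to at most 8000 loci in a single
   partition, then a catch-up pass over all training entries that
   updates only $G$ and $g$. Without this, the first round of
   parameter averaging blends latent factors that have not yet agreed
   on an identity across partitions.
4. **Partition-parallel SGD** (`parallel_round()`): training loci are
   partitioned into blocks of 1000; each round, every partition gets a
   copy of $C, c, A, a$ (and their optimizer moments), performs 5000
   single-entry SGD updates sampled from its own loci, and the shared
   blocks are averaged element-wise (unweighted) over partitions.
   Partitions draw from independent seed-derived RNG streams, so the
   result is independent of processing order and bit-reproducible;
   execution here is sequential, and the "parallel" contract is purely
   the average-of-independent-local-updates semantics.
5. **Optimizer.** Adam with Nesterov momentum, in the standard
   formulation: $m \leftarrow \beta_{1,t} m + (1-\beta_{1,t})\,
   \nabla$, $v \leftarrow \beta_2 v + (1-\beta_2)\, \nabla^2$, bias
   corrections from the running product of the $\beta_1$ schedule, and
   update direction $(\beta_{1,t+1}\hat m + (1-\beta_{1,t})\hat\nabla)
   / (\sqrt{\hat v} + \epsilon)$. Schedules
   $\eta_t = \eta\,\varphi_\eta^{t-1}$ and
   $\beta_{1,t} = \beta_1\,\varphi_{\beta 1}^{t-1}$ use the per-block
   cumulative update count as $t$. The per-entry regularization
   gradient is apportioned by participation count
   ($2\lambda_C C_{jl} / n_{C_j}$), so stochastic gradients sum exactly
   to the batch gradient — a property the tests verify against central
   finite differences.
6. **Monitoring and convergence.** Training, validation and test MSE
   are recorded every 3 rounds (validation restricted to the training
   loci during the main phase); the best-validation parameters are
   checkpointed. After a minimum of 50 rounds, convergence is declared
   when a one-sided Mann–Whitney rank-sum test (normal approximation,
   tie-corrected) finds the last 6 records, shifted up by $10^{-5}$,
   stochastically greater than the preceding 6 — i.e. validation error
   has stopped decreasing.
7. **Line search.** On convergence the model restarts from the best
   checkpoint with $\eta/2$ and
   $\beta_1 \leftarrow \beta_1 - (1-\beta_1)$, up to three times. Adam
   moments are reset to zero at each restart, the schedule counters
   continue cumulatively, and the convergence window restarts on
   post-restart records (these three details are this package's
   choices; the procedure's description leaves them open).
8. **Second-order genome solve.** Finally $C, c, A, a$ are frozen at
   the best checkpoint and, per locus, $(G_i, g_i)$ are obtained in
   closed form: the sub-problem is convex, solved by ridge normal
   equations with penalty $\lambda_{G2}$ on $G_i$ only ($g_i$ is an
   unpenalized intercept, re-fit jointly); rank-deficient unpenalized
   systems fall back to the minimum-norm SVD solution.

Imputation for a held-out experiment is the element-wise mean of the
per-fold models (`impute_consensus()`), with negative values clamped to
zero — negative signal is invalid for $-\log_{10} p$ tracks.

### Hyperparameters

| parameter | default | meaning |
|---|---|---|
| `eta` | 0.0045 | base learning rate |
| `phi_eta` | $1-10^{-6}$ | per-update learning-rate decay |
| `beta1`, `phi_beta1` | 0.9, $1-10^{-6}$ | Adam first-moment weight and decay |
| `beta2`, `adam_eps` | 0.999, $10^{-8}$ | Adam second moment, stability term |
| `L` | 100 | latent factors |
| `lambda_C` | 4.792 | cell-type factor penalty |
| `lambda_A`, `lambda_G` | $8.757\times 10^{-27}$ | assay / genome factor penalties (effectively none) |
| `lambda_G2` | 0.4122 | ridge weight of the final genome solve |
| `init_range` | 0.33 | half-width of the uniform factor init |
| `partition_size`, `local_iters` | 1000, 5000 | loci per partition, SGD updates per partition per round |
| `burnin_loci` | 8000 | loci used in the burn-in pass |
| `training_locus_fraction` | 0.01 | loci fraction for the main phase |
| `mse_record_every`, `min_rounds` | 3, 50 | recording cadence, convergence warm-up |
| `window_records`, `convergence_shift`, `convergence_alpha` | 6, $10^{-5}$, 0.05 | rank-sum windows and level |
| `line_search_len` | 3 | restarts after first convergence |
| `n_folds` | 8 | validation folds per test set |
| `max_rounds` | 5000 | safety cap on parallel rounds |

`adam_eps`, `min_rounds` and `max_rounds` are this package's settings
for quantities the published table omits. The defaults were selected
for a Roadmap-scale tensor ($J=127$, $K=24$, $I\approx1.3\times10^6$);
on small tensors `training_locus_fraction` should be raised so that the
main phase sees enough loci to identify the cell-type and assay factors
(the package's own recovery experiments use 0.25 at $I = 2000$).

## Quality measures

`evaluate_experiment()` computes, on the transformed scale: MSEglobal,
MSE1obs/MSE1imp (MSE over the top 1% of positions ranked by
observed/imputed signal; other rankings give the cross-method
variants), GWcorr (Pearson), Match1/Catch1obs/Catch1imp (overlap of
top-1% and top-5% position sets), and AucObs1/AucImp1/CatchPeakObs
(rank-based ROC areas with midrank tie handling, the last against
called-peak labels). "Top 1%" is fixed as the
$\max(1, \operatorname{round}(0.01\,N))$ largest values, round-half-up,
ties broken by ascending index — ranking ties and rounding are
otherwise undefined, and this deterministic choice is pinned by tests.
`compare_methods()` reports, per measure, the across-experiment Pearson
correlation between two methods and the mean/SD of natural-log ratios
over experiment pairs where both values are strictly positive.
`ternary_project()` maps a three-method comparison onto the simplex
($x' = x/(x+y+z)$), so equal performance lands at $(1/3, 1/3, 1/3)$.

## The synthetic generator, and what passing tests mean

`generate_tensor()` draws ground-truth factors i.i.d. uniform
$(-1, 1)$, biases uniform $(-0.5, 0.5)$, samples a fiber mask with a
minimum-support guarantee, and adds i.i.d. Gaussian noise
($\sigma = 0.1$ by default) to observed fibers. These defaults put the
low-rank signal variance well above the noise floor, which is what
makes recovery measurable. This is exactly the generative structure the
model assumes, so recovery experiments probe the *training machinery*
— optimizer, averaging, convergence detection, final solve — under
ideal model match. Real signal tracks are non-negative, heavy-tailed,
spatially autocorrelated and not exactly low-rank; passing recovery
tests therefore says the procedure optimizes its objective correctly,
not that real-data accuracy will match.

One consequence of the symmetric generator: the production imputation
path clamps negatives to zero (correct for $-\log_{10} p$ tracks), but
synthetic tensors carry legitimate negative values, so the package's
recovery experiments evaluate the unclamped consensus mean.

The package's recovery benchmark uses $J=30$, $K=12$, $I=2000$,
$L_{\text{true}}=4$, 40% of fibers observed (minimum support 3),
model rank $L=8$, partitions of 250 loci, 1000 local updates per round
and a consensus of two validation-fold models — sizes chosen so the
full procedure (burn-in through final solve) runs end-to-end in
seconds while leaving the completion problem genuinely underdetermined
for an unregularized exact fit, so that the procedure's implicit
regularization (checkpointing on validation error, parameter
averaging, fold consensus, the ridge genome solve) is actually
exercised. The acceptance script reports the resulting held-out-fiber
MSE against the irreducible noise floor of $\sigma^2 = 0.01$.

## Numerical notes and limitations

* Determinism: every stochastic step (mask sampling, splits,
  initialization, entry sampling per partition per round) draws from a
  stream derived from a single integer seed; a full `train_parafac()`
  run is bit-reproducible on one machine.
* The inner SGD loop is compiled (Rcpp) for throughput; a one-step
  equivalence test pins it to the R-level `adam_nag_step()`.
* Degenerate inputs: empty partitions are skipped with a warning; a
  locus with no observations gets $G_i = 0, g_i = 0$ with a warning;
  constant vectors make correlation-based measures an explicit error
  rather than `NA`.
* The objective is non-convex; different seeds reach different local
  optima, which is why consensus averaging over folds is part of the
  method and why single-fold results vary more than the consensus.
* Scale-out infrastructure (cluster execution, whole-genome bigWig
  output) and automated hyperparameter search are out of scope; the
  sequential implementation reproduces the parameter-averaging
  semantics exactly.
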