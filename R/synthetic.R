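#' Generate a synthetic low-rank signal tensor
#'
#' Draws ground-truth factor matrices and bias vectors, samples a
#' fiber-wise observation mask, and emits observed fibers as the model
#' prediction plus i.i.d. Gaussian noise. This is exactly the
#' generative structure the factorization model assumes (low-rank
#' triple product + per-dimension biases + Gaussian error), so
#' parameter-recovery experiments on these tensors probe the trainer
#' under its own model assumptions.
#'
#' True factors are i.i.d. uniform on `(-factor_scale, factor_scale)`
#' and biases uniform on `(-bias_scale, bias_scale)`; the defaults put
#' the low-rank signal variance well above the default noise level so
#' recovery is testable. The mask is sampled to leave every cell type
#' and assay with at least `min_support` observed fibers, and contains
#' exactly `round(observed_fraction * J * K)` fibers.
#'
#' @param J,K,I tensor dimensions.
#' @param L_true true latent rank.
#' @param factor_scale half-width of the factor distribution (default 1).
#' @param bias_scale half-width of the bias distribution (default 0.5).
#' @param sigma noise standard deviation (default 0.1).
#' @param observed_fraction fraction of the J x K fibers observed.
#' @param min_support minimum observed fibers per cell type and assay.
#' @param seed integer seed; the whole draw is deterministic in it.
#' @return list with `tensor` (an [observed_tensor()], transform tag
#'   `"asinh"`) and `truth` (list: `model` a [factor_model()], `sigma`,
#'   `mask`, `seed`).
#' @export
generate_tensor <- function(J, K, I, L_true = 4L, factor_scale = 1,
                            bias_scale = 0.5, sigma = 0.1,
                            observed_fraction = 0.4, min_support = 3L,
                            seed = 1L) {
  if (observed_fraction <= 0 || observed_fraction > 1)
    stop("observed_fraction must be in (0, 1]")
  if (sigma < 0) stop("sigma must be >= 0")
  n_obs <- round(observed_fraction * J * K)
  if (n_obs < max(J, K) * min_support)
    stop("observed_fraction too small to give every cell type and assay ",
         min_support, " experiments")
  truth_model <- with_seed(derive_seed(seed, 100L), {
    factor_model(matrix(runif(J * L_true, -factor_scale, factor_scale), J, L_true),
                 matrix(runif(K * L_true, -factor_scale, factor_scale), K, L_true),
                 matrix(runif(I * L_true, -factor_scale, factor_scale), I, L_true),
                 runif(J, -bias_scale, bias_scale),
                 runif(K, -bias_scale, bias_scale),
                 runif(I, -bias_scale, bias_scale))
  })
  mask <- with_seed(derive_seed(seed, 101L),
                    sample_fiber_mask(J, K, n_obs, min_support))
  arr <- array(NA_real_, dim = c(J, K, I))
  with_seed(derive_seed(seed, 102L), {
    idx <- which(mask, arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    for (m in seq_len(nrow(idx))) {
      j <- idx[m, 1]; k <- idx[m, 2]
      arr[j, k, ] <- predict_entry(truth_model, j, k, seq_len(I)) + rnorm(I, 0, sigma)
    }
  })
  D <- observed_tensor(arr, sprintf("cell%02d", seq_len(J)),
                       sprintf("assay%02d", seq_len(K)), I, transform = "asinh")
  list(tensor = D,
       truth = list(model = truth_model, sigma = sigma, mask = mask,
                    seed = as.integer(seed)))
}

# Sample exactly n_obs fibers such that every row and column of the J x K
# grid keeps at least min_support observed fibers. Constructive: satisfy
# row then column quotas, top up randomly, then trim removable surplus.
sample_fiber_mask <- function(J, K, n_obs, min_support) {
  mask <- matrix(FALSE, J, K)
  for (j in seq_len(J))
    mask[j, sample.int(K, min(min_support, K))] <- TRUE
  for (k in seq_len(K)) {
    deficit <- min_support - sum(mask[, k])
    if (deficit > 0) {
      cand <- which(!mask[, k])
      mask[sample(cand, min(deficit, length(cand))), k] <- TRUE
    }
  }
  while (sum(mask) < n_obs) {
    cand <- which(!mask)
    mask[sample(cand, 1L)] <- TRUE
  }
  while (sum(mask) > n_obs) {
    rs <- rowSums(mask); cs <- colSums(mask)
    obs <- which(mask, arr.ind = TRUE)
    removable <- obs[rs[obs[, 1]] > min_support & cs[obs[, 2]] > min_support, , drop = FALSE]
    if (nrow(removable) == 0L)
      stop("cannot reach requested observed fraction under the support constraint")
    pick <- removable[sample.int(nrow(removable), 1L), ]
    mask[pick[1], pick[2]] <- FALSE
  }
  mask
}

#' Synthetic peak calls from the noiseless truth
#'
#' For each observed experiment, bins whose noiseless value lies in the
#' top `top_frac` are labeled as peaks. A fixture for the CatchPeakObs
#' measure: with `sigma = 0` recovering these labels from the observed
#' signal gives AUC 1.
#'
#' @param truth the `truth` element returned by [generate_tensor()].
#' @param top_frac fraction of bins labeled per experiment (default 0.05).
#' @return named list mapping `"<j>|<k>"` (1-based indices) to 0/1
#'   label vectors of length I.
#' @export
generate_peaks <- function(truth, top_frac = 0.05) {
  if (top_frac <= 0 || top_frac >= 1) stop("top_frac must be in (0, 1)")
  I <- nrow(truth$model$G)
  idx <- which(truth$mask, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  out <- list()
  for (m in seq_len(nrow(idx))) {
    j <- idx[m, 1]; k <- idx[m, 2]
    lab <- integer(I)
    lab[top_fraction_set(predict_entry(truth$model, j, k, seq_len(I)), top_frac)] <- 1L
    out[[paste(j, k, sep = "|")]] <- lab
  }
  out
}

#' Emit a tensor as per-experiment bedGraph tracks
#'
#' Writes one bedGraph file per observed experiment on a synthetic
#' single-chromosome ("chrS") 25 bp coordinate system. Values are
#' written on the raw scale (the inverse `sinh` is applied when the
#' tensor carries the asinh tag), so binning the files and re-applying
#' the transform reproduces the stored tensor.
#'
#' @param D an [observed_tensor()].
#' @param dir output directory.
#' @param bin_width bp per bin (default 25).
#' @return invisibly, the vector of written file paths.
#' @export
emit_tracks <- function(D, dir, bin_width = 25L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  I <- tensor_I(D)
  gr0 <- GenomicRanges::GRanges("chrS", IRanges::IRanges(
    start = (seq_len(I) - 1L) * bin_width + 1L, width = bin_width))
  keys <- observed_keys(D)
  paths <- character(nrow(keys))
  for (m in seq_len(nrow(keys))) {
    v <- D$values[keys$cell_type[m], keys$assay[m], ]
    if (D$transform == "asinh") v <- sinh(v)
    gr <- gr0; gr$score <- v
    paths[m] <- file.path(dir, sprintf("%s__%s.bedGraph",
                                       D$cell_types[keys$cell_type[m]],
                                       D$assays[keys$assay[m]]))
    write_bedgraph(gr, paths[m])
  }
  invisible(paths)
}
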