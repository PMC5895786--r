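#' Fit the additive main-effects baseline
#'
#' The comparison floor for the factorization model. It computes the
#' global mean `mu` of all observed entries, then for every genome
#' slice `i` the row (cell type) residual means against `mu` and the
#' column (assay) residual means against `mu` plus the row residual.
#' Imputation is `mu + r[j, i] + q[k, i]`. On fully observed additive
#' data `u_j + v_k + w_i` the baseline is exact.
#'
#' @param D an [observed_tensor()].
#' @return object of class `main_effects`: list with scalar `mu`,
#'   J x I matrix `r`, K x I matrix `q`.
#' @export
fit_main_effects <- function(D) {
  if (!inherits(D, "obs_tensor")) stop("D must be an obs_tensor")
  if (!any(D$mask)) stop("tensor has no observed entries")
  J <- dim(D$values)[1]; K <- dim(D$values)[2]; I <- dim(D$values)[3]
  mu <- mean(D$values[!is.na(D$values)])
  r <- matrix(0, J, I)
  q <- matrix(0, K, I)
  n_row <- rowSums(D$mask)           # observed assays per cell type
  n_col <- colSums(D$mask)           # observed cell types per assay
  for (i in seq_len(I)) {
    sl <- D$values[, , i]            # J x K slice, NA where missing
    cent <- sl - mu
    rs <- rowSums(cent, na.rm = TRUE)
    r[, i] <- ifelse(n_row > 0, rs / pmax(n_row, 1), 0)
    cent2 <- cent - r[, i]           # subtract row residual, recycled by row
    cs <- colSums(cent2, na.rm = TRUE)
    q[, i] <- ifelse(n_col > 0, cs / pmax(n_col, 1), 0)
  }
  structure(list(mu = mu, r = r, q = q), class = "main_effects")
}

#' Impute from a main-effects model
#'
#' @param m a `main_effects` model from [fit_main_effects()].
#' @param j,k cell type and assay indices (scalars, 1-based).
#' @param i genomic bin indices (vector allowed; default all bins).
#' @return numeric vector `mu + r[j, i] + q[k, i]`.
#' @export
impute_main_effects <- function(m, j, k, i = seq_len(ncol(m$r))) {
  if (j < 1 || j > nrow(m$r) || k < 1 || k > nrow(m$q))
    stop("cell type or assay index out of range")
  if (any(i < 1) || any(i > ncol(m$r))) stop("bin index out of range")
  m$mu + m$r[j, i] + m$q[k, i]
}

#' @export
print.main_effects <- function(x, ...) {
  cat(sprintf("main_effects model: mu = %.4f, %d cell types x %d assays x %d bins\n",
              x$mu, nrow(x$r), nrow(x$q), ncol(x$r)))
  invisible(x)
}
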