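#' Factorization model with per-dimension biases
#'
#' The model reconstructs tensor entry (j, k, i) as
#' \deqn{\hat D_{jki} = \sum_{l=1}^L C_{jl} A_{kl} G_{il} + c_j + a_k + g_i}
#' where C (J x L), A (K x L), G (I x L) are the cell type, assay and
#' genome factor matrices and c, a, g the matching bias vectors.
#'
#' @param C,A,G factor matrices with a common number of columns L.
#' @param c_bias,a_bias,g_bias bias vectors of lengths J, K, I.
#' @return an object of class `factor_model`.
#' @export
factor_model <- function(C, A, G, c_bias, a_bias, g_bias) {
  L <- ncol(C)
  if (ncol(A) != L || ncol(G) != L) stop("C, A, G must share the same column count L")
  if (length(c_bias) != nrow(C) || length(a_bias) != nrow(A) || length(g_bias) != nrow(G))
    stop("bias vector lengths must match factor matrix rows")
  for (x in list(C, A, G, c_bias, a_bias, g_bias)) stopifnot_finite(x, "model parameters")
  structure(list(C = C, A = A, G = G, c = c_bias, a = a_bias, g = g_bias, L = L),
            class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("factor_model: J=%d cell types, K=%d assays, I=%d bins, L=%d latent factors\n",
              nrow(x$C), nrow(x$A), nrow(x$G), x$L))
  invisible(x)
}

#' Regularization weights
#'
#' L2 penalties on the three factor matrices (`lambda_C`, `lambda_A`,
#' `lambda_G`; bias vectors are never penalized) and the ridge weight
#' `lambda_G2` of the closed-form genome solve.
#'
#' @param lambda_C,lambda_A,lambda_G,lambda_G2 non-negative reals.
#' @return a named list of class `reg_weights`.
#' @export
reg_weights <- function(lambda_C = 0, lambda_A = 0, lambda_G = 0, lambda_G2 = 0) {
  w <- list(lambda_C = lambda_C, lambda_A = lambda_A,
            lambda_G = lambda_G, lambda_G2 = lambda_G2)
  if (any(unlist(w) < 0)) stop("regularization weights must be >= 0")
  structure(w, class = "reg_weights")
}

#' Predict a tensor entry
#'
#' @param m a [factor_model()].
#' @param j,k scalar cell type / assay indices (1-based).
#' @param i genomic bin index or vector of indices.
#' @return predicted value(s).
#' @export
predict_entry <- function(m, j, k, i) {
  if (j < 1 || j > nrow(m$C) || k < 1 || k > nrow(m$A) || any(i < 1) || any(i > nrow(m$G)))
    stop("index out of range")
  x <- m$C[j, ] * m$A[k, ]
  drop(m$G[i, , drop = FALSE] %*% x) + m$c[j] + m$a[k] + m$g[i]
}

#' Predict many fibers at once
#'
#' @param m a [factor_model()].
#' @param keys data.frame with `cell_type`, `assay` columns.
#' @param i bin indices (default all).
#' @return matrix `nrow(keys)` x `length(i)` of predictions.
#' @export
predict_fibers <- function(m, keys, i = seq_len(nrow(m$G))) {
  X <- m$C[keys$cell_type, , drop = FALSE] * m$A[keys$assay, , drop = FALSE]
  P <- X %*% t(m$G[i, , drop = FALSE])
  P + m$c[keys$cell_type] + m$a[keys$assay] + rep(m$g[i], each = nrow(P))
}

#' Training objective
#'
#' Sum of squared residuals over the training entries plus L2 penalties
#' on the factor matrices (`lambda_C ||C||_F^2 + lambda_A ||A||_F^2 +
#' lambda_G ||G||_F^2`); biases are unpenalized.
#'
#' @param m a [factor_model()].
#' @param D an [observed_tensor()].
#' @param entries data.frame with columns `cell_type`, `assay`, `bin`
#'   identifying the training entries (all must be observed in `D`).
#' @param lambda a [reg_weights()].
#' @return scalar objective value (non-negative).
#' @export
parafac_objective <- function(m, D, entries, lambda = reg_weights()) {
  d <- D$values[cbind(entries$cell_type, entries$assay, entries$bin)]
  if (anyNA(d)) stop("training entries must be observed in D")
  X <- m$C[entries$cell_type, , drop = FALSE] * m$A[entries$assay, , drop = FALSE]
  pred <- rowSums(X * m$G[entries$bin, , drop = FALSE]) +
    m$c[entries$cell_type] + m$a[entries$assay] + m$g[entries$bin]
  sum((d - pred)^2) +
    lambda$lambda_C * sum(m$C^2) + lambda$lambda_A * sum(m$A^2) +
    lambda$lambda_G * sum(m$G^2)
}

#' Exact per-entry gradients of the objective
#'
#' For one training entry with residual `e = prediction - D[j,k,i]`:
#' the gradient w.r.t. row `C[j, ]` is `2 e * A[k, ] * G[i, ] +
#' (2 lambda_C / n_Cj) * C[j, ]`, where `n_Cj` is the number of
#' training entries that involve row j (and analogously for A and G);
#' bias gradients are `2 e`. Apportioning the L2 term by participation
#' count makes the per-entry gradients sum exactly to the gradient of
#' [parafac_objective()] over the full training set.
#'
#' @param m a [factor_model()].
#' @param d_jki observed value at the entry.
#' @param j,k,i entry indices.
#' @param lambda a [reg_weights()].
#' @param counts list with vectors `cell_type` (length J), `assay`
#'   (length K), `bin` (length I) of per-row training-entry counts.
#' @return list of gradients `C_j`, `A_k`, `G_i`, `c_j`, `a_k`, `g_i`.
#' @export
entry_gradients <- function(m, d_jki, j, k, i, lambda, counts) {
  if (counts$cell_type[j] <= 0 || counts$assay[k] <= 0 || counts$bin[i] <= 0)
    stop("zero participation count for a touched parameter row")
  e <- predict_entry(m, j, k, i) - d_jki
  list(C_j = 2 * e * m$A[k, ] * m$G[i, ] + (2 * lambda$lambda_C / counts$cell_type[j]) * m$C[j, ],
       A_k = 2 * e * m$C[j, ] * m$G[i, ] + (2 * lambda$lambda_A / counts$assay[k]) * m$A[k, ],
       G_i = 2 * e * m$C[j, ] * m$A[k, ] + (2 * lambda$lambda_G / counts$bin[i]) * m$G[i, ],
       c_j = 2 * e, a_k = 2 * e, g_i = 2 * e)
}

# Participation counts of each parameter row in a set of training entries.
entry_counts <- function(entries, J, K, I) {
  list(cell_type = tabulate(entries$cell_type, J),
       assay = tabulate(entries$assay, K),
       bin = tabulate(entries$bin, I))
}

#' Serialize / load a factor model
#'
#' Plain-text container: one file per parameter block plus a metadata
#' record (L, labels, transform tag).
#'
#' @param m a [factor_model()].
#' @param dir directory path.
#' @param meta optional named character vector merged into `meta.tsv`.
#' @export
write_factor_model <- function(m, dir, meta = character()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wm <- function(x, f) write.table(x, file.path(dir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE, col.names = FALSE)
  wm(m$C, "C.tsv"); wm(m$A, "A.tsv"); wm(m$G, "G.tsv")
  wm(m$c, "c.tsv"); wm(m$a, "a.tsv"); wm(m$g, "g.tsv")
  meta <- c(L = as.character(m$L), meta)
  writeLines(paste(names(meta), meta, sep = "\t"), file.path(dir, "meta.tsv"))
  invisible(dir)
}

#' @rdname write_factor_model
#' @export
read_factor_model <- function(dir) {
  rm_ <- function(f) as.matrix(read.table(file.path(dir, f), sep = "\t"))
  rv_ <- function(f) as.numeric(readLines(file.path(dir, f)))
  factor_model(rm_("C.tsv"), rm_("A.tsv"), rm_("G.tsv"),
               rv_("c.tsv"), rv_("a.tsv"), rv_("g.tsv"))
}
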