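# Independent oracles used across tests.

# Central finite differences of the full objective w.r.t. every
# parameter block, as flat named list of arrays.
numeric_gradients <- function(m, D, entries, lambda, h = 1e-6) {
  blocks <- c("C", "A", "G", "c", "a", "g")
  out <- list()
  for (b in blocks) {
    g <- m[[b]] * 0
    for (ii in seq_along(m[[b]])) {
      m1 <- m; m1[[b]][ii] <- m1[[b]][ii] - h
      m2 <- m; m2[[b]][ii] <- m2[[b]][ii] + h
      g[ii] <- (parafac_objective(m2, D, entries, lambda) -
                  parafac_objective(m1, D, entries, lambda)) / (2 * h)
    }
    out[[b]] <- g
  }
  out
}

# Sum entry_gradients over a set of entries into full-block gradients.
summed_entry_gradients <- function(m, D, entries, lambda) {
  J <- nrow(m$C); K <- nrow(m$A); I <- nrow(m$G)
  counts <- list(cell_type = tabulate(entries$cell_type, J),
                 assay = tabulate(entries$assay, K),
                 bin = tabulate(entries$bin, I))
  out <- list(C = m$C * 0, A = m$A * 0, G = m$G * 0,
              c = m$c * 0, a = m$a * 0, g = m$g * 0)
  for (r in seq_len(nrow(entries))) {
    j <- entries$cell_type[r]; k <- entries$assay[r]; i <- entries$bin[r]
    gr <- entry_gradients(m, D$values[j, k, i], j, k, i, lambda, counts)
    out$C[j, ] <- out$C[j, ] + gr$C_j
    out$A[k, ] <- out$A[k, ] + gr$A_k
    out$G[i, ] <- out$G[i, ] + gr$G_i
    out$c[j] <- out$c[j] + gr$c_j
    out$a[k] <- out$a[k] + gr$a_k
    out$g[i] <- out$g[i] + gr$g_i
  }
  out
}

# All (observed fiber x bin) entries of a tensor for a set of keys.
all_entries <- function(keys, I) {
  data.frame(cell_type = rep(keys$cell_type, I),
             assay = rep(keys$assay, I),
             bin = rep(seq_len(I), each = nrow(keys)))
}

# Brute-force Mann-Whitney AUC: count concordant pairs, half credit for ties.
auc_bruteforce <- function(labels, scores) {
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Small random model for gradient tests.
random_model <- function(J, K, I, L, seed) {
  with_seed <- get("with_seed", asNamespace("epitensor"))
  with_seed(seed, factor_model(
    matrix(runif(J * L, -1, 1), J, L),
    matrix(runif(K * L, -1, 1), K, L),
    matrix(runif(I * L, -1, 1), I, L),
    runif(J, -1, 1), runif(K, -1, 1), runif(I, -1, 1)))
}

observed_matrix <- function(D, keys, bins = seq_len(dim(D$values)[3])) {
  out <- t(apply(keys, 1, function(r) D$values[r[1], r[2], bins]))
  if (length(bins) == 1L) out <- matrix(out, nrow = nrow(keys))
  out
}
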