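#' Training configuration
#'
#' All hyperparameters of the objective and the optimizer, with the
#' defaults used for the Roadmap-scale fits: base learning rate
#' `eta = 0.0045` decayed by `phi_eta = 1 - 1e-6` per update, Adam
#' first-moment weight `beta1 = 0.9` decayed by `phi_beta1 = 1 - 1e-6`,
#' `beta2 = 0.999`, `L = 100` latent factors, L2 penalties
#' `lambda_C = 4.792`, `lambda_A = lambda_G = 8.757e-27`, and ridge
#' weight `lambda_G2 = 0.4122` for the closed-form genome solve.
#' Factor matrices are initialized uniformly on
#' `(-init_range, init_range)` with `init_range = 0.33`.
#'
#' The trainer partitions the training loci into blocks of
#' `partition_size` (default 1000) loci, runs `local_iters` (default
#' 5000) single-entry SGD updates per partition per round, burn-in on
#' `burnin_loci` (default 8000) loci, and uses a random
#' `training_locus_fraction` (default 1%) of available loci for the
#' main phase. MSE on the training/validation/test entries is recorded
#' every `mse_record_every` (default 3) rounds; once `min_rounds`
#' rounds have elapsed, convergence is declared when a one-sided
#' rank-sum test finds the most recent `window_records` MSE records
#' (shifted up by `convergence_shift`) stochastically greater than the
#' preceding window at level `convergence_alpha`. After convergence the
#' trainer restarts from the best checkpoint up to `line_search_len`
#' times, halving `eta` and reducing `beta1` each time.
#'
#' @param ... named overrides of any default field.
#' @return a list of class `training_config`.
#' @export
training_config <- function(...) {
  cfg <- list(
    eta = 0.0045, phi_eta = 1 - 1e-6,
    beta1 = 0.9, phi_beta1 = 1 - 1e-6,
    beta2 = 0.999, adam_eps = 1e-8,
    L = 100L,
    lambda_C = 4.792, lambda_A = 8.757e-27, lambda_G = 8.757e-27,
    lambda_G2 = 0.4122,
    init_range = 0.33,
    partition_size = 1000L, local_iters = 5000L,
    burnin_loci = 8000L, training_locus_fraction = 0.01,
    mse_record_every = 3L, min_rounds = 50L,
    window_records = 6L, convergence_shift = 1e-5, convergence_alpha = 0.05,
    line_search_len = 3L, n_folds = 8L, max_rounds = 5000L,
    seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  rates <- c(cfg$eta, cfg$phi_eta, cfg$beta1, cfg$phi_beta1, cfg$beta2,
             cfg$training_locus_fraction)
  if (any(rates <= 0) || any(rates > 1)) stop("rates must lie in (0, 1]")
  if (any(c(cfg$lambda_C, cfg$lambda_A, cfg$lambda_G, cfg$lambda_G2) < 0))
    stop("regularization weights must be >= 0")
  if (any(c(cfg$L, cfg$partition_size, cfg$burnin_loci, cfg$mse_record_every,
            cfg$window_records, cfg$max_rounds) < 1))
    stop("counts must be positive")
  structure(cfg, class = "training_config")
}

#' Learning rate and first-moment decay schedule
#'
#' `eta_t = eta * phi_eta^(t-1)` and `beta1_t = beta1 * phi_beta1^(t-1)`,
#' where t is the per-block cumulative update count.
#'
#' @param t update counter (>= 1).
#' @param eta,phi_eta,beta1,phi_beta1 base values and decay factors.
#' @return list with `eta_t` and `beta1_t`.
#' @export
decay_schedule <- function(t, eta, phi_eta, beta1, phi_beta1) {
  if (any(t < 1)) stop("t must be >= 1")
  list(eta_t = eta * phi_eta^(t - 1), beta1_t = beta1 * phi_beta1^(t - 1))
}

#' One Nesterov-accelerated Adam step on a parameter block
#'
#' Moment recursions `m <- beta1_t m + (1 - beta1_t) grad`,
#' `v <- beta2 v + (1 - beta2) grad^2`; bias corrections use the
#' running product of the beta1 schedule; the update direction is
#' `(beta1_next * mhat + (1 - beta1_t) * ghat) / (sqrt(vhat) + eps)`
#' and the parameter is decremented by `eta_t` times it.
#'
#' @param param parameter block (vector or matrix).
#' @param grad gradient, same shape.
#' @param state list with `m`, `v` (same shape as `param`), counter `t`
#'   and `prod_beta1` (running product of past schedule values); use
#'   [adam_state()] to create a fresh one.
#' @param eta_t,beta1_t current schedule values.
#' @param beta1_next schedule value at step t + 1.
#' @param beta2,adam_eps Adam second-moment weight and stability term.
#' @return list with updated `param` and `state`.
#' @export
adam_nag_step <- function(param, grad, state, eta_t, beta1_t,
                          beta1_next = beta1_t, beta2 = 0.999, adam_eps = 1e-8) {
  if (!all(is.finite(grad))) stop("non-finite gradient")
  state$t <- state$t + 1
  state$m <- beta1_t * state$m + (1 - beta1_t) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  state$prod_beta1 <- state$prod_beta1 * beta1_t
  d1 <- max(1 - state$prod_beta1, 1e-300)
  d1n <- max(1 - state$prod_beta1 * beta1_next, 1e-300)
  ghat <- grad / d1
  mhat <- state$m / d1n
  vhat <- state$v / (1 - beta2^state$t)
  dir <- (beta1_next * mhat + (1 - beta1_t) * ghat) / (sqrt(vhat) + adam_eps)
  list(param = param - eta_t * dir, state = state)
}

#' @rdname adam_nag_step
#' @export
adam_state <- function(param) {
  list(m = param * 0, v = param * 0, t = 0, prod_beta1 = 1)
}

#' Seeded model initialization
#'
#' Factor matrices are i.i.d. uniform on `(-init_range, init_range)`.
#' Bias vectors come from the plane means of the observed data: with
#' global mean `mu`, `c_j = mu_j - mu`, `a_k = mu_k - mu`, `g_i = mu_i`
#' (plane means over observed entries), so the bias-only prediction
#' `c_j + a_k + g_i` is an additive main-effects-style estimate rather
#' than triple-counting the global mean.
#'
#' @param D an [observed_tensor()].
#' @param L latent factor count.
#' @param init_range half-width of the uniform initialization.
#' @param seed integer seed.
#' @return a [factor_model()].
#' @export
init_model <- function(D, L, init_range = 0.33, seed = 1L) {
  if (L < 1) stop("L must be >= 1")
  if (!any(D$mask)) stop("tensor has no observed entries")
  J <- dim(D$values)[1]; K <- dim(D$values)[2]; I <- dim(D$values)[3]
  mu <- mean(D$values, na.rm = TRUE)
  mu_j <- apply(D$values, 1, mean, na.rm = TRUE)
  mu_k <- apply(D$values, 2, mean, na.rm = TRUE)
  mu_i <- apply(D$values, 3, mean, na.rm = TRUE)
  with_seed(derive_seed(seed, 10L), {
    C <- matrix(runif(J * L, -init_range, init_range), J, L)
    A <- matrix(runif(K * L, -init_range, init_range), K, L)
    G <- matrix(runif(I * L, -init_range, init_range), I, L)
  })
  factor_model(C, A, G,
               ifelse(is.finite(mu_j), mu_j - mu, 0),
               ifelse(is.finite(mu_k), mu_k - mu, 0),
               mu_i)
}

#' Mean squared error over a set of fibers
#'
#' @param m a [factor_model()].
#' @param D an [observed_tensor()].
#' @param keys data.frame of fibers (`cell_type`, `assay`), all observed.
#' @param bins bin indices to evaluate over (default all).
#' @return scalar mean squared residual.
#' @export
split_mse <- function(m, D, keys, bins = seq_len(tensor_I(D))) {
  if (nrow(keys) == 0L || length(bins) == 0L) stop("empty evaluation subset")
  obs <- t(apply(keys, 1, function(r) D$values[r[1], r[2], bins]))
  if (length(bins) == 1L) obs <- matrix(obs, nrow = nrow(keys))
  if (anyNA(obs)) stop("evaluation fibers must be observed")
  mean((predict_fibers(m, keys, bins) - obs)^2)
}

#' Convergence detector for the recorded validation MSE series
#'
#' Compares the most recent `window_records` MSE records (window 2)
#' with the immediately preceding `window_records` records (window 1)
#' using a one-sided Mann-Whitney rank-sum test (normal approximation,
#' tie-corrected): converged when `window2 + shift` is found
#' stochastically greater than `window1` at level `alpha`, i.e. the
#' validation error has stopped decreasing.
#'
#' @param valid_mse numeric vector of recorded validation MSE values.
#' @param window_records records per window (default 6).
#' @param shift additive shift applied to window 2 (default 1e-5).
#' @param alpha significance level (default 0.05).
#' @return logical; always `FALSE` with fewer than `2 * window_records`
#'   records.
#' @export
check_convergence <- function(valid_mse, window_records = 6L, shift = 1e-5,
                              alpha = 0.05) {
  n <- length(valid_mse)
  w <- window_records
  if (n < 2L * w) return(FALSE)
  w1 <- valid_mse[(n - 2L * w + 1L):(n - w)]
  w2 <- valid_mse[(n - w + 1L):n]
  p <- suppressWarnings(
    wilcox.test(w2 + shift, w1, alternative = "greater",
                exact = FALSE, correct = FALSE)$p.value)
  is.finite(p) && p < alpha
}

#' Line-search restart transform
#'
#' Returns the best-checkpoint parameters with the learning rate halved
#' and the Adam first-moment weight reduced as
#' `beta1_new = beta1_old - (1 - beta1_old)`. The trainer additionally
#' resets the Adam moments to zero at each restart.
#'
#' @param checkpoint the best [factor_model()] so far (must exist).
#' @param eta,beta1 current base learning rate and first-moment weight.
#' @return list with `model`, `eta`, `beta1`.
#' @export
line_search_restart <- function(checkpoint, eta, beta1) {
  if (is.null(checkpoint)) stop("no checkpoint available for line search")
  list(model = checkpoint, eta = eta / 2, beta1 = beta1 - (1 - beta1))
}

#' Closed-form ridge solve of the genome parameters at one locus
#'
#' With cell type and assay parameters frozen, the objective restricted
#' to locus i is convex: minimize over `(G_i, g_i)` the sum over
#' observed pairs of `(d_jk - x_jk . G_i - c_j - a_k - g_i)^2 +
#' lambda_G2 ||G_i||^2`, where `x_jk = C_j * A_k` elementwise. Solved
#' by ridge normal equations with the penalty on `G_i` only (the
#' intercept `g_i` is unpenalized); rank-deficient systems with
#' `lambda_G2 = 0` fall back to the minimum-norm least-squares
#' solution.
#'
#' @param C,A factor matrices; `c_bias`, `a_bias` bias vectors.
#' @param keys data.frame of observed pairs at the locus.
#' @param d observed values at the locus for those pairs.
#' @param lambda_G2 ridge weight (>= 0).
#' @return list with `G_i` (length L) and scalar `g_i`.
#' @export
second_order_genome_solve <- function(C, A, c_bias, a_bias, keys, d, lambda_G2 = 0) {
  L <- ncol(C)
  if (nrow(keys) == 0L) {
    warning("no observations at locus; returning zeros")
    return(list(G_i = numeric(L), g_i = 0))
  }
  X <- cbind(C[keys$cell_type, , drop = FALSE] * A[keys$assay, , drop = FALSE], 1)
  y <- d - c_bias[keys$cell_type] - a_bias[keys$assay]
  beta <- genome_ridge_solve(X, matrix(y, ncol = 1), lambda_G2)[, 1]
  list(G_i = beta[seq_len(L)], g_i = beta[L + 1L])
}

# Solve (X'X + diag(lambda,...,lambda,0)) B = X'Y for many loci at once
# (Y has one column per locus). Falls back to a minimum-norm SVD solve
# when the penalized normal equations are singular.
genome_ridge_solve <- function(X, Y, lambda_G2) {
  p <- ncol(X)
  pen <- diag(c(rep(lambda_G2, p - 1L), 0), p)
  M <- crossprod(X) + pen
  ok <- TRUE
  B <- tryCatch(solve(M, crossprod(X, Y)), error = function(e) { ok <<- FALSE; NULL })
  if (ok && all(is.finite(B))) return(B)
  # minimum-norm least squares via SVD pseudoinverse (lambda_G2 = 0 path)
  sv <- svd(X)
  tol <- max(dim(X)) * .Machine$double.eps * max(sv$d)
  dinv <- ifelse(sv$d > tol, 1 / sv$d, 0)
  sv$v %*% (dinv * crossprod(sv$u, Y))
}

# ---- internal trainer machinery -------------------------------------------

new_adam <- function(J, K, I, L) {
  list(mC = matrix(0, J, L), vC = matrix(0, J, L), mc = numeric(J), vc = numeric(J),
       mA = matrix(0, K, L), vA = matrix(0, K, L), ma = numeric(K), va = numeric(K),
       mG = matrix(0, I, L), vG = matrix(0, I, L), mg = numeric(I), vg = numeric(I),
       tCA = 0, prodCA = 1, tG = 0, prodG = 1)
}

reset_moments <- function(adam) {
  for (nm in c("mC", "vC", "mc", "vc", "mA", "vA", "ma", "va", "mG", "vG", "mg", "vg"))
    adam[[nm]] <- adam[[nm]] * 0
  adam
}

deep_copy <- function(x) x * 1

# Expand (fibers x loci) into flat 0-based entry arrays for the C++ loop.
partition_entries <- function(D, keys, loci) {
  nf <- nrow(keys)
  list(ej = rep.int(keys$cell_type, length(loci)) - 1L,
       ek = rep.int(keys$assay, length(loci)) - 1L,
       ei = rep(seq_along(loci), each = nf) - 1L,
       d = as.numeric(D$values[cbind(rep.int(keys$cell_type, length(loci)),
                                     rep.int(keys$assay, length(loci)),
                                     rep(loci, each = nf))]))
}

run_local_sgd <- function(model, adam, entries, loci, n_iters, sequential,
                          update_shared, update_genome, eta, beta1, cfg, counts) {
  # the C++ loop updates every array in place: hand it copies so that
  # callers' models and optimizer states are never mutated
  model$C <- deep_copy(model$C); model$c <- deep_copy(model$c)
  model$A <- deep_copy(model$A); model$a <- deep_copy(model$a)
  adam$mC <- deep_copy(adam$mC); adam$vC <- deep_copy(adam$vC)
  adam$mc <- deep_copy(adam$mc); adam$vc <- deep_copy(adam$vc)
  adam$mA <- deep_copy(adam$mA); adam$vA <- deep_copy(adam$vA)
  adam$ma <- deep_copy(adam$ma); adam$va <- deep_copy(adam$va)
  Gp <- deep_copy(model$G[loci, , drop = FALSE])
  gp <- deep_copy(model$g[loci])
  mGp <- deep_copy(adam$mG[loci, , drop = FALSE]); vGp <- deep_copy(adam$vG[loci, , drop = FALSE])
  mgp <- deep_copy(adam$mg[loci]); vgp <- deep_copy(adam$vg[loci])
  res <- local_sgd_cpp(model$C, model$c, model$A, model$a, Gp, gp,
                       entries$ej, entries$ek, entries$ei, entries$d,
                       as.integer(n_iters), sequential, update_shared, update_genome,
                       adam$mC, adam$vC, adam$mc, adam$vc,
                       adam$mA, adam$vA, adam$ma, adam$va,
                       mGp, vGp, mgp, vgp,
                       adam$tCA, adam$tG, adam$prodCA, adam$prodG,
                       eta, cfg$phi_eta, beta1, cfg$phi_beta1,
                       cfg$beta2, cfg$adam_eps,
                       cfg$lambda_C, cfg$lambda_A, cfg$lambda_G,
                       counts$cell_type, counts$assay, counts$bin[loci])
  model$G[loci, ] <- Gp; model$g[loci] <- gp
  adam$mG[loci, ] <- mGp; adam$vG[loci, ] <- vGp
  adam$mg[loci] <- mgp; adam$vg[loci] <- vgp
  list(model = model, adam = adam,
       tCA = res$tCA, tG = res$tG, prodCA = res$prodCA, prodG = res$prodG)
}

#' Burn-in pass
#'
#' Before parameter averaging starts, latent factors need a consistent
#' identity across partitions. Burn-in runs one sequential pass over a
#' seed-chosen half of the training entries restricted to at most
#' `burnin_loci` training loci, updating every parameter block in a
#' single partition; then a catch-up pass over all training entries
#' updates only the genome parameters G and g so the genome dimension
#' receives a comparable number of updates.
#'
#' @param D an [observed_tensor()].
#' @param train_keys data.frame of training fibers.
#' @param train_loci integer vector of training locus indices.
#' @param model a [factor_model()].
#' @param adam optimizer state (internal; created if `NULL`).
#' @param config a [training_config()].
#' @return list with updated `model` and `adam`.
#' @export
burn_in <- function(D, train_keys, train_loci, model, config, adam = NULL) {
  if (nrow(train_keys) == 0L || length(train_loci) == 0L) stop("empty training subset")
  if (is.null(adam)) adam <- new_adam(nrow(model$C), nrow(model$A), nrow(model$G), model$L)
  if (config$local_iters == 0L) return(list(model = model, adam = adam))
  counts <- training_counts(train_keys, train_loci,
                            nrow(model$C), nrow(model$A), nrow(model$G))
  bloci <- train_loci[seq_len(min(config$burnin_loci, length(train_loci)))]
  ent <- partition_entries(D, train_keys, bloci)
  n_ent <- length(ent$d)
  with_seed(derive_seed(config$seed, 20L), {
    half <- sample.int(n_ent, max(1L, n_ent %/% 2L))
  })
  ent_half <- list(ej = ent$ej[half], ek = ent$ek[half], ei = ent$ei[half], d = ent$d[half])
  st <- run_local_sgd(model, adam, ent_half, bloci, length(half), sequential = TRUE,
                      update_shared = TRUE, update_genome = TRUE,
                      eta = config$eta, beta1 = config$beta1, cfg = config, counts = counts)
  model <- st$model; adam <- st$adam
  adam$tCA <- st$tCA; adam$tG <- st$tG; adam$prodCA <- st$prodCA; adam$prodG <- st$prodG
  # catch-up: genome parameters only, one shuffled pass over all training entries
  ent_all <- partition_entries(D, train_keys, train_loci)
  with_seed(derive_seed(config$seed, 21L), {
    ord <- sample.int(length(ent_all$d))
  })
  ent_all <- list(ej = ent_all$ej[ord], ek = ent_all$ek[ord],
                  ei = ent_all$ei[ord], d = ent_all$d[ord])
  st <- run_local_sgd(model, adam, ent_all, train_loci, length(ord), sequential = TRUE,
                      update_shared = FALSE, update_genome = TRUE,
                      eta = config$eta, beta1 = config$beta1, cfg = config, counts = counts)
  model <- st$model; adam <- st$adam
  adam$tG <- st$tG; adam$prodG <- st$prodG
  list(model = model, adam = adam)
}

training_counts <- function(train_keys, train_loci, J, K, I) {
  nl <- length(train_loci)
  cnt <- list(cell_type = tabulate(train_keys$cell_type, J) * nl,
              assay = tabulate(train_keys$assay, K) * nl,
              bin = numeric(I))
  cnt$bin[train_loci] <- nrow(train_keys)
  # guard against division by zero for untouched rows inside the C++ loop
  cnt$cell_type[cnt$cell_type == 0] <- 1
  cnt$assay[cnt$assay == 0] <- 1
  cnt$bin[cnt$bin == 0] <- 1
  cnt
}

#' One round of partition-parallel SGD with parameter averaging
#'
#' Each partition receives copies of the shared cell type and assay
#' parameters (C, c, A, a, with their optimizer moments), runs
#' `local_iters` single-entry SGD updates on entries sampled from its
#' own loci (updating its local copies and its own rows of G, g), and
#' the returned shared parameters are the unweighted element-wise means
#' over partitions. Each partition draws from an independent
#' seed-derived RNG stream, so the result does not depend on the order
#' in which partitions are processed.
#'
#' @param D an [observed_tensor()].
#' @param train_keys data.frame of training fibers.
#' @param partitions list of integer vectors of locus indices.
#' @param model a [factor_model()].
#' @param adam optimizer state.
#' @param config a [training_config()].
#' @param round round number (used to derive partition RNG streams).
#' @param eta,beta1 current base learning rate and first-moment weight
#'   (defaults from `config`; the line search lowers them).
#' @param counts participation counts (computed if `NULL`).
#' @param part_seeds optional explicit per-partition RNG seeds.
#' @return list with averaged `model` and `adam`.
#' @export
parallel_round <- function(D, train_keys, partitions, model, adam, config, round = 1L,
                           eta = config$eta, beta1 = config$beta1,
                           counts = NULL, part_seeds = NULL) {
  if (is.null(counts))
    counts <- training_counts(train_keys, unlist(partitions),
                              nrow(model$C), nrow(model$A), nrow(model$G))
  keep <- vapply(partitions, length, integer(1)) > 0L
  if (!all(keep)) {
    warning("skipping empty partition(s)")
    partitions <- partitions[keep]
  }
  if (length(partitions) == 0L) stop("no non-empty partitions")
  if (is.null(part_seeds))
    part_seeds <- vapply(seq_along(partitions), function(p)
      derive_seed(config$seed, 30L, round, p), integer(1))
  shared <- vector("list", length(partitions))
  res <- NULL
  for (p in seq_along(partitions)) {
    loci <- partitions[[p]]
    ent <- partition_entries(D, train_keys, loci)
    st <- with_seed(part_seeds[p],
      run_local_sgd(model, adam, ent, loci, config$local_iters, sequential = FALSE,
                    update_shared = TRUE, update_genome = TRUE,
                    eta = eta, beta1 = beta1, cfg = config, counts = counts))
    # genome rows are disjoint across partitions: write through to the
    # master model/adam; shared blocks are averaged afterwards
    model$G[loci, ] <- st$model$G[loci, , drop = FALSE]
    model$g[loci] <- st$model$g[loci]
    adam$mG[loci, ] <- st$adam$mG[loci, , drop = FALSE]
    adam$vG[loci, ] <- st$adam$vG[loci, , drop = FALSE]
    adam$mg[loci] <- st$adam$mg[loci]; adam$vg[loci] <- st$adam$vg[loci]
    shared[[p]] <- list(C = st$model$C, c = st$model$c, A = st$model$A, a = st$model$a,
                        mC = st$adam$mC, vC = st$adam$vC, mc = st$adam$mc, vc = st$adam$vc,
                        mA = st$adam$mA, vA = st$adam$vA, ma = st$adam$ma, va = st$adam$va)
    res <- st
  }
  avg <- function(nm) Reduce(`+`, lapply(shared, `[[`, nm)) / length(shared)
  model$C <- avg("C"); model$c <- avg("c"); model$A <- avg("A"); model$a <- avg("a")
  adam$mC <- avg("mC"); adam$vC <- avg("vC"); adam$mc <- avg("mc"); adam$vc <- avg("vc")
  adam$mA <- avg("mA"); adam$vA <- avg("vA"); adam$ma <- avg("ma"); adam$va <- avg("va")
  adam$tCA <- res$tCA; adam$tG <- res$tG
  adam$prodCA <- res$prodCA; adam$prodG <- res$prodG
  list(model = model, adam = adam)
}

#' Train the factorization model
#'
#' Full training procedure for one (test set, validation fold) pair:
#' select a seeded random fraction of loci, initialize, burn in, then
#' iterate partition-parallel SGD rounds with MSE recording and
#' best-validation checkpointing; on convergence restart from the best
#' checkpoint up to `line_search_len` times with halved learning rate
#' and reduced first-moment weight; finally restore the best
#' checkpoint, freeze C, c, A, a, and compute the closed-form ridge
#' solution of the genome parameters at every locus.
#'
#' @param D an [observed_tensor()].
#' @param split a [make_splits()] assignment for the observed keys of `D`.
#' @param test_set which test set to hold out (1-based).
#' @param fold which validation fold to hold out (1-based).
#' @param config a [training_config()].
#' @return list with `model` (a [factor_model()]) and `log` (data.frame
#'   with columns round, train_mse, valid_mse, test_mse, eta, event, and
#'   attribute `best_round`).
#' @export
train_parafac <- function(D, split, test_set, fold, config = training_config()) {
  keys <- split$keys
  if (test_set < 1L || test_set > split$n_test) stop("test_set out of range")
  if (fold < 1L || fold > split$n_folds) stop("fold out of range")
  s_test <- keys[split$test_set == test_set, , drop = FALSE]
  in_train_split <- split$test_set != test_set
  s_valid <- keys[in_train_split & split$folds[, test_set] == fold, , drop = FALSE]
  s_train <- keys[in_train_split & split$folds[, test_set] != fold, , drop = FALSE]
  if (nrow(s_train) == 0L || nrow(s_valid) == 0L) stop("empty training or validation set")
  I <- tensor_I(D)
  with_seed(derive_seed(config$seed, 40L), {
    train_loci <- sort(sample.int(I, max(1L, round(config$training_locus_fraction * I))))
  })
  model <- init_model(D, config$L, config$init_range, config$seed)
  adam <- new_adam(nrow(model$C), nrow(model$A), I, config$L)
  st <- burn_in(D, s_train, train_loci, model, config, adam)
  model <- st$model; adam <- st$adam
  parts <- split(train_loci, ceiling(seq_along(train_loci) / config$partition_size))
  counts <- training_counts(s_train, train_loci, nrow(model$C), nrow(model$A), I)

  eta <- config$eta; beta1 <- config$beta1
  log <- data.frame(round = integer(), train_mse = double(), valid_mse = double(),
                    test_mse = double(), eta = double(), event = character())
  best <- NULL; best_mse <- Inf; best_round <- NA_integer_
  valid_series <- numeric()      # records since the last restart
  rounds_in_phase <- 0L
  ls_done <- 0L
  log[nrow(log) + 1L, ] <- list(0L, split_mse(model, D, s_train, train_loci),
                                split_mse(model, D, s_valid, train_loci),
                                split_mse(model, D, s_test, train_loci),
                                eta, "burnin")
  for (r in seq_len(config$max_rounds)) {
    st <- parallel_round(D, s_train, parts, model, adam, config, round = r,
                         eta = eta, beta1 = beta1, counts = counts)
    model <- st$model; adam <- st$adam
    rounds_in_phase <- rounds_in_phase + 1L
    if (r %% config$mse_record_every == 0L) {
      vm <- split_mse(model, D, s_valid, train_loci)
      ev <- "round"
      if (vm < best_mse) {
        best_mse <- vm; best <- model; best_round <- r; ev <- "checkpoint"
      }
      log[nrow(log) + 1L, ] <- list(r, split_mse(model, D, s_train, train_loci), vm,
                                    split_mse(model, D, s_test, train_loci), eta, ev)
      valid_series <- c(valid_series, vm)
      if (rounds_in_phase >= config$min_rounds &&
          check_convergence(valid_series, config$window_records,
                            config$convergence_shift, config$convergence_alpha)) {
        if (ls_done < config$line_search_len) {
          ls <- line_search_restart(best, eta, beta1)
          model <- ls$model; eta <- ls$eta; beta1 <- ls$beta1
          adam <- reset_moments(adam)
          valid_series <- numeric(); rounds_in_phase <- 0L
          ls_done <- ls_done + 1L
          log[nrow(log) + 1L, ] <- list(r, NA_real_, best_mse, NA_real_, eta, "linesearch")
        } else break
      }
    }
  }
  if (!is.null(best)) model <- best
  # freeze C, c, A, a; closed-form genome solve at every locus
  X <- cbind(model$C[s_train$cell_type, , drop = FALSE] *
               model$A[s_train$assay, , drop = FALSE], 1)
  Y <- apply(s_train, 1, function(rw) D$values[rw[1], rw[2], ])  # I x nf
  B <- genome_ridge_solve(X, t(Y) - model$c[s_train$cell_type] - model$a[s_train$assay],
                          config$lambda_G2)
  model$G <- t(B[seq_len(config$L), , drop = FALSE])
  model$g <- B[config$L + 1L, ]
  log[nrow(log) + 1L, ] <- list(max(log$round) + 1L, split_mse(model, D, s_train, train_loci),
                                split_mse(model, D, s_valid, train_loci),
                                split_mse(model, D, s_test, train_loci), eta, "final-solve")
  attr(log, "best_round") <- best_round
  attr(log, "train_loci") <- train_loci
  list(model = model, log = log)
}

#' Consensus imputation over validation-fold models
#'
#' Element-wise mean of the predictions of several trained models, with
#' negative values clamped to zero (negative signal is invalid for
#' -log10 p tracks).
#'
#' @param models list of [factor_model()]s with consistent dimensions.
#' @param keys data.frame of fibers to impute (`cell_type`, `assay`).
#' @param bins bin indices (default all).
#' @return matrix `nrow(keys)` x `length(bins)` of imputed values.
#' @export
impute_consensus <- function(models, keys, bins = NULL) {
  if (length(models) < 1L) stop("need at least one model")
  dims <- vapply(models, function(m) c(nrow(m$C), nrow(m$A), nrow(m$G), m$L), numeric(4))
  if (any(dims != dims[, 1])) stop("model dimensions do not match")
  if (is.null(bins)) bins <- seq_len(nrow(models[[1]]$G))
  P <- Reduce(`+`, lapply(models, predict_fibers, keys = keys, i = bins)) / length(models)
  pmax(P, 0)
}
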