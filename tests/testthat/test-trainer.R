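test_that("decay schedule reproduces the printed form", {
  s <- decay_schedule(1, 0.0045, 1 - 1e-6, 0.9, 1 - 1e-6)
  expect_equal(s$eta_t, 0.0045)
  expect_equal(s$beta1_t, 0.9)
  s2 <- decay_schedule(100, 0.0045, 1, 0.9, 1)
  expect_equal(s2$eta_t, 0.0045)
  s3 <- decay_schedule(1e6 + 1, 0.0045, 1 - 1e-6, 0.9, 1 - 1e-6)
  expect_equal(s3$eta_t / 0.0045, (1 - 1e-6)^1e6, tolerance = 1e-12)
  expect_equal(s3$eta_t / 0.0045, 0.367879, tolerance = 1e-5)
  expect_error(decay_schedule(0, 0.0045, 1, 0.9, 1), ">= 1")
})

test_that("adam step is a no-op at zero gradient and sign-normalized in the memoryless limit", {
  p <- c(1, -2, 3)
  st <- adam_state(p)
  res <- adam_nag_step(p, c(0, 0, 0), st, eta_t = 0.01, beta1_t = 0.9)
  expect_equal(res$param, p)

  # beta1_t = 0, beta2 = 0, eps -> 0: displacement is eta_t * sign(grad)
  g <- c(0.3, -5, 0.001)
  res2 <- adam_nag_step(p, g, adam_state(p), eta_t = 0.01, beta1_t = 0,
                        beta1_next = 0, beta2 = 0, adam_eps = 1e-300)
  expect_equal(res2$param, p - 0.01 * sign(g), tolerance = 1e-9)
  expect_error(adam_nag_step(p, c(1, NA, 0), adam_state(p), 0.01, 0.9),
               "finite")
})

test_that("adam per-step displacement approaches eta_t under a constant gradient", {
  p <- 0
  st <- adam_state(p)
  prev <- p
  disp <- NA_real_
  for (t in 1:400) {
    res <- adam_nag_step(p, 7.3, st, eta_t = 0.01, beta1_t = 0.9,
                         beta1_next = 0.9, beta2 = 0.999)
    disp <- abs(res$param - p)
    p <- res$param; st <- res$state
  }
  expect_equal(disp, 0.01, tolerance = 0.02)
})

test_that("the compiled local SGD update matches the R adam step", {
  # one sequential iteration on a single entry must reproduce the
  # block-level R update exactly
  syn <- generate_tensor(2, 2, 3, L_true = 2, sigma = 0.1,
                         observed_fraction = 1, min_support = 1, seed = 3)
  D <- syn$tensor
  cfg <- training_config(L = 2, local_iters = 1L, partition_size = 3L,
                         burnin_loci = 3L, training_locus_fraction = 1,
                         lambda_C = 0.5, seed = 8)
  m <- init_model(D, 2, seed = 8)
  keys <- observed_keys(D)
  res <- parallel_round(D, keys, list(1:3), m, epitensor:::new_adam(2, 2, 3, 2),
                        cfg, round = 1, part_seeds = 123L)
  # replicate by hand: find which entry the partition RNG sampled
  ent <- epitensor:::partition_entries(D, keys, 1:3)
  idx <- epitensor:::with_seed(123L, floor(runif(1) * length(ent$d))) + 1
  j <- ent$ej[idx] + 1; k <- ent$ek[idx] + 1; i <- ent$ei[idx] + 1
  counts <- epitensor:::training_counts(keys, 1:3, 2, 2, 3)
  gr <- entry_gradients(m, ent$d[idx], j, k, i,
                        reg_weights(cfg$lambda_C, cfg$lambda_A, cfg$lambda_G),
                        list(cell_type = counts$cell_type, assay = counts$assay,
                             bin = counts$bin))
  stC <- adam_state(m$C[j, ])
  upd <- adam_nag_step(m$C[j, ], gr$C_j, stC, eta_t = cfg$eta,
                       beta1_t = cfg$beta1,
                       beta1_next = cfg$beta1 * cfg$phi_beta1,
                       beta2 = cfg$beta2, adam_eps = cfg$adam_eps)
  expect_equal(res$model$C[j, ], upd$param, tolerance = 1e-12)
  stc <- adam_state(m$c[j])
  updc <- adam_nag_step(m$c[j], gr$c_j, stc, eta_t = cfg$eta,
                        beta1_t = cfg$beta1,
                        beta1_next = cfg$beta1 * cfg$phi_beta1,
                        beta2 = cfg$beta2, adam_eps = cfg$adam_eps)
  expect_equal(res$model$c[j], updc$param, tolerance = 1e-12)
})

test_that("init_model is seeded, in-range, and bias-only predicts plane means", {
  syn <- generate_tensor(4, 3, 6, L_true = 2, sigma = 0.2,
                         observed_fraction = 0.8, min_support = 1, seed = 5)
  D <- syn$tensor
  m1 <- init_model(D, 5, seed = 42)
  m2 <- init_model(D, 5, seed = 42)
  expect_identical(m1, m2)
  expect_true(all(abs(m1$C) < 0.33) && all(abs(m1$G) < 0.33))

  arr <- array(7, c(2, 2, 3))
  Dc <- observed_tensor(arr, c("x", "y"), c("u", "v"), 3)
  mc <- init_model(Dc, 2, seed = 1)
  expect_equal(mc$c, c(0, 0))
  expect_equal(mc$a, c(0, 0))
  expect_equal(mc$g, c(7, 7, 7))
  bias_only <- mc; bias_only$C[] <- 0; bias_only$A[] <- 0; bias_only$G[] <- 0
  expect_equal(predict_entry(bias_only, 1, 2, 2), 7)
})

test_that("burn_in is deterministic, descends on average, and is a no-op at zero iterations", {
  improved <- 0
  for (seed in 1:10) {
    syn <- generate_tensor(6, 4, 40, L_true = 2, sigma = 0.1,
                           observed_fraction = 0.8, min_support = 2, seed = seed)
    D <- syn$tensor
    keys <- observed_keys(D)
    cfg <- training_config(L = 3, burnin_loci = 40L, seed = seed)
    m0 <- init_model(D, 3, seed = seed)
    st <- burn_in(D, keys, 1:40, m0, cfg)
    mse0 <- split_mse(m0, D, keys)
    mse1 <- split_mse(st$model, D, keys)
    if (mse1 <= mse0) improved <- improved + 1
    if (seed == 1) {
      st2 <- burn_in(D, keys, 1:40, m0, cfg)
      expect_identical(st$model, st2$model)
      cfg0 <- cfg; cfg0$local_iters <- 0L
      stn <- burn_in(D, keys, 1:40, m0, cfg0)
      expect_identical(stn$model, m0)
    }
  }
  expect_gte(improved, 9)
})

test_that("parameter averaging over partitions is the unweighted element-wise mean", {
  syn <- generate_tensor(5, 4, 20, L_true = 2, sigma = 0.1,
                         observed_fraction = 0.9, min_support = 2, seed = 6)
  D <- syn$tensor
  keys <- observed_keys(D)
  cfg <- training_config(L = 3, local_iters = 50L, partition_size = 10L,
                         training_locus_fraction = 1, seed = 2)
  m <- init_model(D, 3, seed = 2)
  adam <- epitensor:::new_adam(5, 4, 20, 3)
  counts <- epitensor:::training_counts(keys, 1:20, 5, 4, 20)
  parts <- list(1:10, 11:20)
  both <- parallel_round(D, keys, parts, m, adam, cfg, round = 1,
                         counts = counts, part_seeds = c(11L, 22L))
  # single-partition runs give each local result; with one partition the
  # average is the identity over that partition's result
  r1 <- parallel_round(D, keys, parts[1], m, adam, cfg, round = 1,
                       counts = counts, part_seeds = 11L)
  r2 <- parallel_round(D, keys, parts[2], m, adam, cfg, round = 1,
                       counts = counts, part_seeds = 22L)
  expect_equal(both$model$C, (r1$model$C + r2$model$C) / 2, tolerance = 1e-12)
  expect_equal(both$model$a, (r1$model$a + r2$model$a) / 2, tolerance = 1e-12)
  # genome rows are partition-local, untouched by averaging
  expect_equal(both$model$G[1:10, ], r1$model$G[1:10, ], tolerance = 1e-15)
  expect_equal(both$model$G[11:20, ], r2$model$G[11:20, ], tolerance = 1e-15)

  # identical data and identical RNG streams in both partitions:
  # the average equals either local result
  arrdup <- D$values
  arrdup[, , 11:20] <- D$values[, , 1:10]
  Ddup <- observed_tensor(arrdup, D$cell_types, D$assays, 20)
  mdup <- m; mdup$G[11:20, ] <- m$G[1:10, ]; mdup$g[11:20] <- m$g[1:10]
  bdup <- parallel_round(Ddup, keys, parts, mdup, adam, cfg, round = 1,
                         counts = counts, part_seeds = c(77L, 77L))
  sdup <- parallel_round(Ddup, keys, parts[1], mdup, adam, cfg, round = 1,
                         counts = counts, part_seeds = 77L)
  expect_equal(bdup$model$C, sdup$model$C, tolerance = 1e-12)
  expect_equal(bdup$model$c, sdup$model$c, tolerance = 1e-12)
})

test_that("split_mse averages squared residuals and agrees with mse_global", {
  syn <- generate_tensor(3, 3, 8, L_true = 2, sigma = 0.5,
                         observed_fraction = 1, min_support = 1, seed = 4)
  D <- syn$tensor
  keys <- observed_keys(D)
  expect_equal(split_mse(syn$truth$model, D, keys), {
    imp <- predict_fibers(syn$truth$model, keys)
    obs <- observed_matrix(D, keys)
    mse_global(as.vector(imp), as.vector(obs))
  })
  expect_equal(split_mse(syn$truth$model, syn$tensor, keys, bins = 3),
               mse_global(predict_fibers(syn$truth$model, keys, 3)[, 1],
                          observed_matrix(D, keys, 3)[, 1]))
  expect_error(split_mse(syn$truth$model, D, keys[0, ]), "empty")
})

test_that("convergence triggers on flat or rising validation error only", {
  decreasing <- seq(1.00, by = -0.02, length.out = 12)
  expect_false(check_convergence(decreasing))
  increasing <- rev(decreasing)
  expect_true(check_convergence(increasing))
  expect_false(check_convergence(decreasing[1:11]))
  expect_false(check_convergence(numeric(0)))
  # a plateau triggers via the shift term
  expect_true(check_convergence(rep(0.5, 12)))
})

test_that("line search halves the rate and walks beta1 down its fixed-point map", {
  m <- random_model(2, 2, 2, 1, seed = 1)
  ls <- line_search_restart(m, 0.0045, 0.9)
  expect_equal(ls$eta, 0.00225)
  expect_equal(ls$beta1, 0.8)
  expect_identical(ls$model, m)
  b <- 0.9
  for (want in c(0.8, 0.6, 0.2)) {
    b <- line_search_restart(m, 1, b)$beta1
    expect_equal(b, want)
  }
  expect_equal(line_search_restart(m, 1, 1)$beta1, 1)
  expect_error(line_search_restart(NULL, 1, 0.9), "checkpoint")
})

test_that("the genome solve matches a dense oracle and its limits", {
  set.seed(10)
  for (rep in 1:10) {
    L <- 3; nf <- 12
    C <- matrix(rnorm(6 * L), 6, L); A <- matrix(rnorm(4 * L), 4, L)
    cb <- rnorm(6); ab <- rnorm(4)
    keys <- data.frame(cell_type = sample(1:6, nf, TRUE),
                       assay = sample(1:4, nf, TRUE))
    d <- rnorm(nf)
    lam2 <- runif(1, 0, 2)
    sol <- second_order_genome_solve(C, A, cb, ab, keys, d, lam2)
    X <- cbind(C[keys$cell_type, ] * A[keys$assay, ], 1)
    y <- d - cb[keys$cell_type] - ab[keys$assay]
    beta <- solve(crossprod(X) + diag(c(rep(lam2, L), 0)), crossprod(X, y))
    expect_lt(max(abs(c(sol$G_i, sol$g_i) - beta)), 1e-8)
  }
  # noiseless exact recovery at lambda = 0
  syn <- generate_tensor(6, 5, 4, L_true = 3, sigma = 0,
                         observed_fraction = 1, min_support = 1, seed = 2)
  D <- syn$tensor; keys <- observed_keys(D); tm <- syn$truth$model
  for (i in 1:4) {
    d <- D$values[cbind(keys$cell_type, keys$assay, i)]
    sol <- second_order_genome_solve(tm$C, tm$A, tm$c, tm$a, keys, d, 0)
    fitted <- (tm$C[keys$cell_type, ] * tm$A[keys$assay, ]) %*% sol$G_i +
      tm$c[keys$cell_type] + tm$a[keys$assay] + sol$g_i
    expect_lt(max(abs(fitted - d)), 1e-8)
  }
  # huge ridge: G -> 0 and g -> mean of (d - c_j - a_k)
  d <- D$values[cbind(keys$cell_type, keys$assay, 1)]
  sol_inf <- second_order_genome_solve(tm$C, tm$A, tm$c, tm$a, keys, d, 1e12)
  expect_lt(max(abs(sol_inf$G_i)), 1e-6)
  expect_equal(sol_inf$g_i, mean(d - tm$c[keys$cell_type] - tm$a[keys$assay]),
               tolerance = 1e-6)
  expect_warning(second_order_genome_solve(tm$C, tm$A, tm$c, tm$a,
                                           keys[0, ], numeric(0), 0),
                 "no observations")
})

test_that("training is deterministic and checkpoints track the best validation error", {
  syn <- generate_tensor(8, 5, 60, L_true = 2, sigma = 0.1,
                         observed_fraction = 0.7, min_support = 2, seed = 9)
  D <- syn$tensor
  sp <- make_splits(observed_keys(D), n_test = 3, n_folds = 2, seed = 9)
  cfg <- training_config(L = 3, partition_size = 15L, local_iters = 200L,
                         training_locus_fraction = 0.5, burnin_loci = 30L,
                         min_rounds = 6L, window_records = 2L, max_rounds = 30L,
                         line_search_len = 1L, seed = 13)
  f1 <- train_parafac(D, sp, 1, 1, cfg)
  f2 <- train_parafac(D, sp, 1, 1, cfg)
  expect_identical(f1$model, f2$model)
  expect_identical(f1$log, f2$log)
  best_series <- cummin(f1$log$valid_mse[f1$log$event %in% c("round", "checkpoint")])
  expect_true(all(diff(best_series) <= 0))
  # the stationarity of the final convex sub-problem: genome-only gradient
  # vanishes at every locus after the closed-form solve
  keys <- sp$keys
  tr <- keys[sp$test_set != 1 & sp$folds[, 1] != 1, ]
  m <- f1$model
  X <- cbind(m$C[tr$cell_type, ] * m$A[tr$assay, ], 1)
  for (i in c(1, 30, 60)) {
    d <- D$values[cbind(tr$cell_type, tr$assay, i)]
    resid <- X %*% c(m$G[i, ], m$g[i]) + m$c[tr$cell_type] + m$a[tr$assay] - d
    grad <- 2 * crossprod(X, resid) + 2 * cfg$lambda_G2 * c(m$G[i, ], 0)
    expect_lt(max(abs(grad)), 1e-6)
  }
})

test_that("consensus imputation averages models and clamps negatives", {
  m <- random_model(2, 2, 3, 2, seed = 3)
  mneg <- m; mneg$C[] <- 0; mneg$A[] <- 0; mneg$G[] <- 0
  mneg$c[] <- -0.5; mneg$a[] <- 0; mneg$g[] <- 0
  keys <- data.frame(cell_type = 1L, assay = 1L)
  expect_equal(as.vector(impute_consensus(list(mneg), keys)), c(0, 0, 0))

  mpos <- mneg; mpos$c[] <- 0.4; mneg$c[] <- -0.2
  expect_equal(as.vector(impute_consensus(list(mneg, mpos), keys)),
               rep(0.1, 3), tolerance = 1e-12)
  one <- impute_consensus(list(m), keys)
  many <- impute_consensus(rep(list(m), 4), keys)
  expect_equal(one, many, tolerance = 1e-12)
  bad <- random_model(3, 2, 3, 2, seed = 4)
  expect_error(impute_consensus(list(m, bad), keys), "dimensions")
})
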