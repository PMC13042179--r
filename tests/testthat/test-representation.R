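# Representation learning: FT-Transformer, DVAE, PCA, comparison harness.

small_cfg <- function(seed = 3L, ...) {
  encoder_config(d_token = 16L, n_heads = 2L, d_head = 8L, ffn_hidden = 24L,
                 dropout = 0, d_latent = 4L, batch_size = 8L, max_epochs = 5L,
                 seed = seed, ...)
}

test_that("transformer gradients match finite differences on a tiny model", {
  cfg <- encoder_config(d_token = 8L, n_blocks = 2L, n_heads = 2L, d_head = 4L,
                        ffn_hidden = 6L, dropout = 0, d_latent = 3L,
                        batch_size = 4L, seed = 3L)
  withr::with_seed(1, X <- matrix(rnorm(4 * 5), 4, 5))
  p <- physiophen:::ft_init_params(5L, cfg)
  fw <- physiophen:::ft_forward(p, X, cfg, keep_cache = TRUE)
  gr <- physiophen:::ft_backward(p, fw, cfg)
  eps <- 1e-5
  withr::with_seed(2, {
    for (nm in names(gr)) {
      i <- sample(length(p[[nm]]), 1)
      p2 <- p
      p2[[nm]][i] <- p2[[nm]][i] + eps
      l1 <- physiophen:::ft_forward(p2, X, cfg)$loss
      p2[[nm]][i] <- p2[[nm]][i] - 2 * eps
      l0 <- physiophen:::ft_forward(p2, X, cfg)$loss
      num <- (l1 - l0) / (2 * eps)
      expect_lt(abs(num - gr[[nm]][i]) / max(1e-4, abs(num) + abs(gr[[nm]][i])),
                1e-4)
    }
  })
})

test_that("the compiled training step matches the reference R implementation", {
  cfg <- encoder_config(d_token = 8L, n_blocks = 2L, n_heads = 2L, d_head = 4L,
                        ffn_hidden = 6L, dropout = 0, d_latent = 3L,
                        batch_size = 4L, seed = 3L)
  withr::with_seed(19, X <- matrix(rnorm(6 * 5), 6, 5))
  p <- physiophen:::ft_init_params(5L, cfg)
  fwR <- physiophen:::ft_forward(p, X, cfg, keep_cache = TRUE)
  grR <- physiophen:::ft_backward(p, fwR, cfg)
  st <- physiophen:::cpp_ft_step(p, X, cfg$n_blocks, cfg$n_heads, cfg$d_head,
                                 list(), list(), TRUE)
  expect_equal(st$loss, fwR$loss, tolerance = 1e-12)
  expect_equal(unclass(st$Z), unclass(fwR$Z), tolerance = 1e-12,
               ignore_attr = TRUE)
  for (nm in names(grR)) {
    expect_equal(as.numeric(st$grads[[nm]]), as.numeric(grR[[nm]]),
                 tolerance = 1e-10)
  }
})

test_that("token sequence length is n_features + 1 and the latent width holds", {
  cfg <- small_cfg()
  withr::with_seed(4, X <- matrix(rnorm(40 * 6), 40, 6))
  p <- physiophen:::ft_init_params(6L, cfg)
  fw <- physiophen:::ft_forward(p, X[1:3, ], cfg, keep_cache = TRUE)
  expect_equal(fw$cache$T, 7L)                 # CLS + one token per feature
  expect_equal(nrow(p$pos), 7L)
  expect_equal(dim(fw$Z), c(3L, 4L))
  expect_equal(encoder_config()$d_latent, 32L)
  expect_error(encoder_config(d_token = 100L), "n_heads")
})

test_that("training on rank-2 data drives validation loss below 25% of start", {
  ok <- 0
  for (s in 1:3) {
    withr::with_seed(s, {
      n <- 200
      U <- matrix(rnorm(n * 2), n, 2)
      V <- matrix(rnorm(2 * 30), 2, 30)
      X <- scale(U %*% V + matrix(rnorm(n * 30, 0, 0.05), n, 30))
    })
    cfg <- encoder_config(d_token = 32L, n_heads = 4L, d_head = 8L,
                          ffn_hidden = 64L, dropout = 0, d_latent = 8L,
                          batch_size = 32L, max_epochs = 30L,
                          early_stop_patience = 10L, seed = s)
    enc <- fit_ft_transformer(X, cfg)
    ok <- ok + (enc$best_val < 0.25 * enc$epoch0_val)
  }
  expect_gte(ok, 2)
})

test_that("encoding is deterministic, permutation-equivariant, duplicate-consistent", {
  cfg <- small_cfg()
  withr::with_seed(5, X <- matrix(rnorm(64 * 6), 64, 6))
  enc <- fit_ft_transformer(X, cfg)
  Z1 <- encode(enc, X)
  Z2 <- encode(enc, X)
  expect_equal(unclass(Z1), unclass(Z2), tolerance = 1e-12, ignore_attr = TRUE)
  perm <- sample(nrow(X))
  Zp <- encode(enc, X[perm, ])
  expect_equal(unclass(Zp), unclass(Z1)[perm, ], tolerance = 1e-12,
               ignore_attr = TRUE)
  Xd <- rbind(X[1, ], X[1, ])
  Zd <- encode(enc, Xd)
  expect_equal(Zd[1, ], Zd[2, ], tolerance = 1e-12)
  expect_error(fit_ft_transformer(cbind(X, NA), cfg), "missing")
  expect_error(fit_ft_transformer(X[1:10, ], cfg), "batch_size")
})

test_that("seed determinism: identical config and seed give identical losses", {
  cfg <- small_cfg(seed = 11L)
  withr::with_seed(6, X <- matrix(rnorm(64 * 5), 64, 5))
  e1 <- fit_ft_transformer(X, cfg)
  e2 <- fit_ft_transformer(X, cfg)
  expect_equal(e1$history$val, e2$history$val, tolerance = 1e-6)
})

test_that("learning-rate schedule is non-increasing and halves on plateaus", {
  cfg <- small_cfg(seed = 7L)
  cfg$max_epochs <- 25L
  cfg$plateau_patience <- 2L
  withr::with_seed(7, X <- matrix(rnorm(64 * 5), 64, 5))
  enc <- fit_ft_transformer(X, cfg)
  lrs <- enc$history$lr
  expect_true(all(diff(lrs) <= 1e-12))
  changed <- unique(lrs)
  expect_true(all(abs(diff(log2(changed)) + 1) < 1e-9))  # exact halvings
})

test_that("early stopping halts within patience of the best epoch", {
  cfg <- small_cfg(seed = 8L)
  cfg$max_epochs <- 60L
  cfg$early_stop_patience <- 5L
  withr::with_seed(8, X <- matrix(rnorm(64 * 5), 64, 5))
  enc <- fit_ft_transformer(X, cfg)
  n_ep <- nrow(enc$history)
  expect_lte(n_ep, enc$best_epoch + cfg$early_stop_patience)
  expect_equal(enc$best_val, min(enc$history$val), tolerance = 1e-12)
})

test_that("PCA embedding satisfies its algebraic contracts", {
  withr::with_seed(9, {
    U <- matrix(rnorm(100 * 2), 100, 2)
    V <- matrix(rnorm(2 * 10), 2, 10)
    X <- U %*% V
    X <- sweep(X, 2, rnorm(10), "+")       # affine 2-d subspace
  })
  emb <- fit_pca(X, 2L)
  expect_lt(attr(emb, "reconstruction_mse"), 1e-18)
  withr::with_seed(10, Xr <- matrix(rnorm(200 * 6), 200, 6))
  emb2 <- fit_pca(Xr, 4L)
  cc <- stats::cor(unclass(emb2))
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-6)
  expect_true(all(diff(attr(emb2, "explained_variance")) <= 1e-12))
})

test_that("DVAE: KL non-negative, shape correct, zero KL weight matches an AE", {
  withr::with_seed(11, {
    U <- matrix(rnorm(150 * 3), 150, 3)
    X <- scale(U %*% matrix(rnorm(3 * 12), 3, 12) + matrix(rnorm(150 * 12, 0, .1), 150, 12))
  })
  cfg <- dvae_config(hidden = c(32L, 16L), d_latent = 4L, max_epochs = 30L, seed = 2L)
  emb <- fit_dvae(X, cfg)
  expect_equal(dim(unclass(emb)), c(150L, 4L))
  expect_true(all(attr(emb, "kl_history") >= 0))
  cfg0 <- cfg
  cfg0$kl_weight <- 0
  emb0 <- fit_dvae(X, cfg0)
  # KL-free DVAE reconstructs at least as well as the regularized one
  expect_lte(attr(emb0, "val_mse"), attr(emb, "val_mse") * 1.1)
})

test_that("representation comparison recovers separable structure for all methods", {
  withr::with_seed(12, {
    n <- 180
    g <- sample(1:4, n, TRUE)
    ctr <- matrix(rnorm(4 * 20, 0, 4), 4, 20)
    X <- scale(ctr[g, ] + matrix(rnorm(n * 20, 0, 0.4), n, 20))
  })
  rep_tab <- compare_representations(
    X, methods = c("pca", "none"), labels_true = g, seed = 2,
    projection_cfg = projection_config(n_neighbors = 15, seed = 2,
                                       method = "spectral"),
    consensus_cfg = consensus_config(n_iterations = 40, seed = 2))
  expect_equal(nrow(rep_tab), 2L)
  expect_true(all(rep_tab$ari > 0.9))
  expect_true("none" %in% rep_tab$method)
})
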