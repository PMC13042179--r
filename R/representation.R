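# Baseline representations: PCA, deep variational autoencoder, identity,
# and the cross-method comparison harness.

#' PCA embedding
#'
#' @param x numeric matrix / data frame (rows = samples).
#' @param d_latent number of components.
#' @return `embedding_matrix` (n x d_latent) with attributes `method = "pca"`,
#'   `explained_variance`, `reconstruction_mse`, and the rotation.
#' @export
fit_pca <- function(x, d_latent = 32L) {
  X <- as.matrix(x)
  d_latent <- min(d_latent, ncol(X), nrow(X) - 1L)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  Z <- pc$x[, seq_len(d_latent), drop = FALSE]
  Xhat <- Z %*% t(pc$rotation[, seq_len(d_latent), drop = FALSE])
  Xhat <- sweep(Xhat, 2, pc$center, "+")
  structure(Z, method = "pca",
            explained_variance = pc$sdev^2,
            reconstruction_mse = mean((Xhat - X)^2),
            rotation = pc$rotation[, seq_len(d_latent), drop = FALSE],
            center = pc$center)
}

# ---- deep variational autoencoder ---------------------------------------

#' DVAE configuration
#'
#' @param hidden encoder hidden widths (mirrored in the decoder).
#' @param d_latent latent width.
#' @param kl_weight weight of the KL term in the ELBO.
#' @param lr,batch_size,max_epochs,val_fraction,early_stop_patience,seed
#'   training controls.
#' @return configuration list.
#' @export
dvae_config <- function(hidden = c(128L, 64L), d_latent = 32L, kl_weight = 1,
                        lr = 1e-3, batch_size = 32L, max_epochs = 100L,
                        val_fraction = 0.2, early_stop_patience = 20L,
                        seed = 1L) {
  list(hidden = hidden, d_latent = d_latent, kl_weight = kl_weight, lr = lr,
       batch_size = batch_size, max_epochs = max_epochs,
       val_fraction = val_fraction, early_stop_patience = early_stop_patience,
       seed = seed)
}

dvae_init <- function(Fn, cfg) {
  h1 <- cfg$hidden[1]; h2 <- cfg$hidden[2]; dz <- cfg$d_latent
  list(W1 = rmat(Fn, h1, sqrt(2 / Fn)), b1 = numeric(h1),
       W2 = rmat(h1, h2, sqrt(2 / h1)), b2 = numeric(h2),
       Wm = rmat(h2, dz, 1 / sqrt(h2)), bm = numeric(dz),
       Wv = rmat(h2, dz, 1 / sqrt(h2)), bv = numeric(dz),
       U1 = rmat(dz, h2, sqrt(2 / dz)), c1 = numeric(h2),
       U2 = rmat(h2, h1, sqrt(2 / h2)), c2 = numeric(h1),
       U3 = rmat(h1, Fn, 1 / sqrt(h1)), c3 = numeric(Fn))
}

dvae_forward <- function(p, X, cfg, eps_z = NULL) {
  lin <- function(A, W, b) add_cols(A %*% W, b)
  h1 <- pmax(lin(X, p$W1, p$b1), 0)
  h2 <- pmax(lin(h1, p$W2, p$b2), 0)
  mu <- lin(h2, p$Wm, p$bm)
  lv <- pmin(lin(h2, p$Wv, p$bv), 10)
  if (is.null(eps_z)) {
    z <- mu                                   # evaluation: mean vector
  } else {
    z <- mu + exp(lv / 2) * eps_z
  }
  d1 <- pmax(lin(z, p$U1, p$c1), 0)
  d2 <- pmax(lin(d1, p$U2, p$c2), 0)
  xhat <- lin(d2, p$U3, p$c3)
  kl_el <- 0.5 * (exp(lv) + mu^2 - 1 - lv)    # elementwise KL >= 0
  recon <- mean((xhat - X)^2)
  list(h1 = h1, h2 = h2, mu = mu, lv = lv, z = z, d1 = d1, d2 = d2,
       xhat = xhat, recon = recon, kl = sum(kl_el) / length(X),
       loss = recon + cfg$kl_weight * sum(kl_el) / length(X))
}

dvae_backward <- function(p, fw, X, cfg, eps_z) {
  nF <- length(X)
  g <- list()
  dxhat <- 2 * (fw$xhat - X) / nF
  g$U3 <- crossprod(fw$d2, dxhat); g$c3 <- colSums(dxhat)
  dd2 <- (dxhat %*% t(p$U3)) * (fw$d2 > 0)
  g$U2 <- crossprod(fw$d1, dd2); g$c2 <- colSums(dd2)
  dd1 <- (dd2 %*% t(p$U2)) * (fw$d1 > 0)
  g$U1 <- crossprod(fw$z, dd1); g$c1 <- colSums(dd1)
  dz <- dd1 %*% t(p$U1)
  w <- cfg$kl_weight / nF
  dmu <- dz + w * fw$mu
  dlv <- dz * eps_z * exp(fw$lv / 2) / 2 + w * 0.5 * (exp(fw$lv) - 1)
  dlv[fw$lv >= 10] <- 0
  g$Wm <- crossprod(fw$h2, dmu); g$bm <- colSums(dmu)
  g$Wv <- crossprod(fw$h2, dlv); g$bv <- colSums(dlv)
  dh2 <- (dmu %*% t(p$Wm) + dlv %*% t(p$Wv)) * (fw$h2 > 0)
  g$W2 <- crossprod(fw$h1, dh2); g$b2 <- colSums(dh2)
  dh1 <- (dh2 %*% t(p$W2)) * (fw$h1 > 0)
  g$W1 <- crossprod(X, dh1); g$b1 <- colSums(dh1)
  g
}

#' Fit a deep variational autoencoder
#'
#' Gaussian-latent VAE (encoder F -> 128 -> 64 -> latent mean/log-variance,
#' mirrored decoder) trained on the ELBO written as reconstruction MSE plus
#' `kl_weight` times the (per-value) KL divergence to the standard normal.
#' The latent mean vector is used as the embedding.
#'
#' @param x numeric matrix, no missing values.
#' @param config from [dvae_config()].
#' @return `embedding_matrix` (n x d_latent), attributes `method = "dvae"`,
#'   `history`, `kl_history`, and `val_mse`.
#' @export
fit_dvae <- function(x, config = dvae_config()) {
  X <- as.matrix(x)
  if (anyNA(X)) stop("input matrix must have no missing values")
  n <- nrow(X)
  with_seed(config$seed, {
    idx <- sample.int(n)
    n_val <- max(1L, round(config$val_fraction * n))
    val_idx <- idx[seq_len(n_val)]
    tr_idx <- idx[-seq_len(n_val)]
    p <- dvae_init(ncol(X), config)
    st <- adam_init(p)
    best <- list(loss = Inf, p = p)
    since <- 0L
    hist <- numeric(0); klh <- numeric(0)
    for (ep in seq_len(config$max_epochs)) {
      ord <- sample(tr_idx)
      kl_ep <- 0; nb <- 0L
      for (s in seq(1L, length(ord), by = config$batch_size)) {
        rows <- ord[s:min(s + config$batch_size - 1L, length(ord))]
        if (length(rows) < 2L) next
        Xb <- X[rows, , drop = FALSE]
        eps_z <- matrix(stats::rnorm(length(rows) * config$d_latent),
                        length(rows), config$d_latent)
        fw <- dvae_forward(p, Xb, config, eps_z)
        gr <- dvae_backward(p, fw, Xb, config, eps_z)
        upd <- adam_step(p, gr, st, config$lr)
        p <- upd$p; st <- upd$st
        kl_ep <- kl_ep + fw$kl; nb <- nb + 1L
      }
      vfw <- dvae_forward(p, X[val_idx, , drop = FALSE], config, eps_z = NULL)
      hist <- c(hist, vfw$loss)
      klh <- c(klh, kl_ep / max(nb, 1))
      if (vfw$loss < best$loss - 1e-9) {
        best <- list(loss = vfw$loss, p = p); since <- 0L
      } else {
        since <- since + 1L
        if (since >= config$early_stop_patience) break
      }
    }
    p <- best$p
    Z <- dvae_forward(p, X, config, eps_z = NULL)$mu
    val_mse <- dvae_forward(p, X[val_idx, , drop = FALSE], config, NULL)$recon
    structure(Z, method = "dvae", history = hist, kl_history = klh,
              val_mse = val_mse)
  })
}

#' Adjusted Rand index between two partitions
#'
#' @param a,b integer/factor label vectors of equal length.
#' @return scalar in \[-1, 1\]; 1 for identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  exp_idx <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == exp_idx) return(0)
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

#' Compare representation methods on a feature matrix
#'
#' Embeds the matrix with each requested method, projects to 2-D, runs
#' consensus clustering, and reports the selected K, consensus-CDF sharpness
#' (AUC at the selected K), silhouette / Calinski-Harabasz / Davies-Bouldin
#' scores, and -- when ground-truth labels are supplied -- the adjusted Rand
#' index of the recovered partition.
#'
#' @param x standardized feature matrix.
#' @param methods subset of `c("ft_t", "pca", "dvae", "none")`.
#' @param labels_true optional ground-truth labels.
#' @param seed seed for every stochastic stage.
#' @param encoder_cfg,projection_cfg,consensus_cfg stage configurations.
#' @return data frame, one row per method.
#' @export
compare_representations <- function(x, methods = c("ft_t", "pca", "dvae", "none"),
                                    labels_true = NULL, seed = 1L,
                                    encoder_cfg = NULL, projection_cfg = NULL,
                                    consensus_cfg = NULL) {
  X <- as.matrix(x)
  rows <- lapply(methods, function(m) {
    Z <- switch(m,
      ft_t = {
        cfg <- encoder_cfg %||% encoder_config(seed = seed, max_epochs = 30L)
        cfg$seed <- seed
        encode(fit_ft_transformer(X, cfg), X)
      },
      pca = fit_pca(X, 32L),
      dvae = fit_dvae(X, dvae_config(seed = seed, max_epochs = 40L)),
      none = structure(X, method = "none"),
      stop("unknown method: ", m))
    pc <- projection_cfg %||% projection_config(seed = seed)
    pc$seed <- seed
    pts <- project(Z, pc)
    cc <- consensus_cfg %||% consensus_config(seed = seed)
    cc$seed <- seed
    cons <- consensus_cluster(pts, cc)
    ks <- select_k(cons)
    lab <- assign_labels(cons$consensus[[as.character(ks)]], ks)
    met <- cluster_metrics(pts, lab$labels)
    data.frame(method = m, k_selected = ks,
               cdf_auc = cons$auc[as.character(ks)],
               silhouette = met["silhouette"],
               calinski_harabasz = met["calinski_harabasz"],
               davies_bouldin = met["davies_bouldin"],
               ari = if (!is.null(labels_true))
                 adjusted_rand_index(labels_true, lab$labels) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
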