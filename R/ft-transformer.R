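# Feature-tokenizer transformer autoencoder for tabular data.
#
# Each scalar feature is mapped by a learnable affine to a d_token vector; a
# learnable CLS token is prepended and learnable feature-identity embeddings
# added. The token sequence passes through post-norm transformer encoder
# blocks (multi-head self-attention -> residual + layer norm -> feed-forward
# -> residual + layer norm, with dropout), the CLS output is projected to the
# latent width, and a small feed-forward decoder reconstructs the features.
# Trained with mean-squared reconstruction error and Adam, learning rate
# halved on validation plateau, early stopping with best-weight restore.
# Forward and backward passes are written out explicitly (no autodiff); they
# are verified against finite differences in the test suite.

#' Encoder configuration
#'
#' @param d_token token embedding width (must equal `n_heads * d_head`).
#' @param n_blocks transformer encoder blocks.
#' @param n_heads,d_head attention heads and per-head width.
#' @param ffn_hidden feed-forward hidden units (ReLU).
#' @param dropout dropout rate (attention output and FFN output).
#' @param d_latent latent embedding width.
#' @param lr initial Adam learning rate.
#' @param plateau_factor,plateau_patience halve the learning rate when the
#'   validation loss has not improved for this many epochs.
#' @param early_stop_patience stop after this many epochs without validation
#'   improvement; best weights are restored.
#' @param batch_size minibatch size.
#' @param val_fraction validation split fraction (rows, fixed by seed).
#' @param max_epochs training-epoch cap.
#' @param seed seed for split, initialization, shuffling, dropout.
#' @return list of class `encoder_config`.
#' @export
encoder_config <- function(d_token = 128L, n_blocks = 3L, n_heads = 4L,
                           d_head = 32L, ffn_hidden = 256L, dropout = 0.1,
                           d_latent = 32L, lr = 0.002, plateau_factor = 0.5,
                           plateau_patience = 6L, early_stop_patience = 20L,
                           batch_size = 32L, val_fraction = 0.2,
                           max_epochs = 200L, seed = 1L) {
  if (d_token != n_heads * d_head) stop("d_token must equal n_heads * d_head")
  structure(list(d_token = d_token, n_blocks = n_blocks, n_heads = n_heads,
                 d_head = d_head, ffn_hidden = ffn_hidden, dropout = dropout,
                 d_latent = d_latent, lr = lr, plateau_factor = plateau_factor,
                 plateau_patience = plateau_patience,
                 early_stop_patience = early_stop_patience,
                 batch_size = batch_size, val_fraction = val_fraction,
                 max_epochs = max_epochs, seed = seed),
            class = "encoder_config")
}

rmat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)

ft_init_params <- function(n_feat, cfg) {
  d <- cfg$d_token
  h <- cfg$ffn_hidden
  p <- list(
    W_tok = rmat(n_feat, d, 1 / sqrt(d)),
    B_tok = rmat(n_feat, d, 1 / sqrt(d)),
    cls = stats::rnorm(d, 0, 1 / sqrt(d)),
    pos = rmat(n_feat + 1L, d, 1 / sqrt(d)),
    Wl = rmat(d, cfg$d_latent, 1 / sqrt(d)),
    bl = numeric(cfg$d_latent),
    Wd1 = rmat(cfg$d_latent, 128L, 1 / sqrt(cfg$d_latent)),
    bd1 = numeric(128L),
    Wd2 = rmat(128L, n_feat, 1 / sqrt(128)),
    bd2 = numeric(n_feat)
  )
  for (l in seq_len(cfg$n_blocks)) {
    s <- 1 / sqrt(d)
    p[[paste0("Wq", l)]] <- rmat(d, d, s)
    p[[paste0("Wk", l)]] <- rmat(d, d, s)
    p[[paste0("Wv", l)]] <- rmat(d, d, s)
    p[[paste0("Wo", l)]] <- rmat(d, d, s)
    p[[paste0("bq", l)]] <- numeric(d)
    p[[paste0("bk", l)]] <- numeric(d)
    p[[paste0("bv", l)]] <- numeric(d)
    p[[paste0("bo", l)]] <- numeric(d)
    p[[paste0("g1_", l)]] <- rep(1, d)
    p[[paste0("b1_", l)]] <- numeric(d)
    p[[paste0("W1_", l)]] <- rmat(d, h, sqrt(2 / d))
    p[[paste0("bf1_", l)]] <- numeric(h)
    p[[paste0("W2_", l)]] <- rmat(h, d, 1 / sqrt(h))
    p[[paste0("bf2_", l)]] <- numeric(d)
    p[[paste0("g2_", l)]] <- rep(1, d)
    p[[paste0("b2_", l)]] <- numeric(d)
  }
  p
}

ln_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  out <- add_cols(mul_cols(xhat, g), b)
  list(out = out, xhat = xhat, inv = inv)
}

ln_bwd <- function(dout, xhat, inv, g) {
  dg <- colSums(dout * xhat)
  db <- colSums(dout)
  dxhat <- mul_cols(dout, g)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - m1 - xhat * m2) * inv
  list(dx = dx, dg = dg, db = db)
}

# column-wise add/scale without sweep()'s aperm of a full-size stats array
add_cols <- function(M, v) M + rep(v, each = nrow(M))
mul_cols <- function(M, v) M * rep(v, each = nrow(M))

softmax_rows <- function(S) {
  m <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - m)
  E / rowSums(E)
}

# Forward pass over a batch. X: B x F. Returns latent Z, reconstruction, and
# (optionally) every intermediate needed by the backward pass.
ft_forward <- function(p, X, cfg, train = FALSE, keep_cache = FALSE) {
  B <- nrow(X)
  Fn <- ncol(X)
  d <- cfg$d_token
  T <- Fn + 1L
  nh <- cfg$n_heads
  dh <- cfg$d_head
  idx_h <- lapply(seq_len(nh), function(h) ((h - 1L) * dh + 1L):(h * dh))
  drop_p <- if (train) cfg$dropout else 0

  # tokens, stacked sample-major: rows (b-1)*T + (1..T)
  H <- matrix(0, B * T, d)
  for (b in seq_len(B)) {
    Hb <- p$W_tok * X[b, ] + p$B_tok        # F x d (column-major recycling)
    H[(b - 1L) * T + 1L, ] <- p$cls
    H[(b - 1L) * T + 1L + seq_len(Fn), ] <- Hb
  }
  H <- H + p$pos[rep(seq_len(T), B), ]
  cache <- list(X = X, B = B, T = T, H0 = if (keep_cache) H else NULL,
                blocks = vector("list", cfg$n_blocks))

  for (l in seq_len(cfg$n_blocks)) {
    Q <- add_cols(H %*% p[[paste0("Wq", l)]], p[[paste0("bq", l)]])
    K <- add_cols(H %*% p[[paste0("Wk", l)]], p[[paste0("bk", l)]])
    V <- add_cols(H %*% p[[paste0("Wv", l)]], p[[paste0("bv", l)]])
    O <- matrix(0, B * T, d)
    A_list <- if (keep_cache) vector("list", B) else NULL
    for (b in seq_len(B)) {
      rows <- (b - 1L) * T + seq_len(T)
      Ab <- if (keep_cache) vector("list", nh) else NULL
      for (h in seq_len(nh)) {
        cs <- idx_h[[h]]
        S <- tcrossprod(Q[rows, cs], K[rows, cs]) / sqrt(dh)
        A <- softmax_rows(S)
        O[rows, cs] <- A %*% V[rows, cs]
        if (keep_cache) Ab[[h]] <- A
      }
      if (keep_cache) A_list[[b]] <- Ab
    }
    AO <- add_cols(O %*% p[[paste0("Wo", l)]], p[[paste0("bo", l)]])
    m_attn <- NULL
    if (drop_p > 0) {
      m_attn <- matrix((stats::runif(length(AO)) >= drop_p) / (1 - drop_p),
                       nrow(AO), ncol(AO))
      AO <- AO * m_attn
    }
    R1 <- H + AO
    ln1 <- ln_fwd(R1, p[[paste0("g1_", l)]], p[[paste0("b1_", l)]])
    H1 <- ln1$out
    Z1 <- add_cols(H1 %*% p[[paste0("W1_", l)]], p[[paste0("bf1_", l)]])
    Arelu <- pmax(Z1, 0)
    FF <- add_cols(Arelu %*% p[[paste0("W2_", l)]], p[[paste0("bf2_", l)]])
    m_ffn <- NULL
    if (drop_p > 0) {
      m_ffn <- matrix((stats::runif(length(FF)) >= drop_p) / (1 - drop_p),
                      nrow(FF), ncol(FF))
      FF <- FF * m_ffn
    }
    R2 <- H1 + FF
    ln2 <- ln_fwd(R2, p[[paste0("g2_", l)]], p[[paste0("b2_", l)]])
    if (keep_cache) {
      cache$blocks[[l]] <- list(H_in = H, Q = Q, K = K, V = V, O = O,
                                A = A_list, m_attn = m_attn, ln1 = ln1,
                                H1 = H1, Z1 = Z1, Arelu = Arelu,
                                m_ffn = m_ffn, ln2 = ln2)
    }
    H <- ln2$out
  }

  cls_rows <- (seq_len(B) - 1L) * T + 1L
  Hc <- H[cls_rows, , drop = FALSE]
  Z <- add_cols(Hc %*% p$Wl, p$bl)
  D1 <- add_cols(Z %*% p$Wd1, p$bd1)
  D1r <- pmax(D1, 0)
  Xhat <- add_cols(D1r %*% p$Wd2, p$bd2)
  if (keep_cache) {
    cache$H_final <- H
    cache$Hc <- Hc
    cache$Z <- Z
    cache$D1r <- D1r
  }
  list(Z = Z, Xhat = Xhat, cache = cache,
       loss = mean((Xhat - X)^2))
}

# Backward pass of the mean-squared reconstruction loss; returns gradients
# for every parameter.
ft_backward <- function(p, fw, cfg) {
  cache <- fw$cache
  X <- cache$X
  B <- cache$B
  T <- cache$T
  d <- cfg$d_token
  nh <- cfg$n_heads
  dh <- cfg$d_head
  idx_h <- lapply(seq_len(nh), function(h) ((h - 1L) * dh + 1L):(h * dh))
  g <- list()

  dXhat <- 2 * (fw$Xhat - X) / length(X)
  g$Wd2 <- crossprod(cache$D1r, dXhat)
  g$bd2 <- colSums(dXhat)
  dD1r <- tcrossprod(dXhat, p$Wd2)
  dD1 <- dD1r * (cache$D1r > 0)
  g$Wd1 <- crossprod(cache$Z, dD1)
  g$bd1 <- colSums(dD1)
  dZ <- tcrossprod(dD1, p$Wd1)
  g$Wl <- crossprod(cache$Hc, dZ)
  g$bl <- colSums(dZ)
  dHc <- tcrossprod(dZ, p$Wl)

  dH <- matrix(0, B * T, d)
  cls_rows <- (seq_len(B) - 1L) * T + 1L
  dH[cls_rows, ] <- dHc

  for (l in rev(seq_len(cfg$n_blocks))) {
    blk <- cache$blocks[[l]]
    lb2 <- ln_bwd(dH, blk$ln2$xhat, blk$ln2$inv, p[[paste0("g2_", l)]])
    g[[paste0("g2_", l)]] <- lb2$dg
    g[[paste0("b2_", l)]] <- lb2$db
    dR2 <- lb2$dx
    dFF <- dR2
    if (!is.null(blk$m_ffn)) dFF <- dFF * blk$m_ffn
    g[[paste0("W2_", l)]] <- crossprod(blk$Arelu, dFF)
    g[[paste0("bf2_", l)]] <- colSums(dFF)
    dArelu <- tcrossprod(dFF, p[[paste0("W2_", l)]])
    dZ1 <- dArelu * (blk$Z1 > 0)
    g[[paste0("W1_", l)]] <- crossprod(blk$H1, dZ1)
    g[[paste0("bf1_", l)]] <- colSums(dZ1)
    dH1 <- dR2 + tcrossprod(dZ1, p[[paste0("W1_", l)]])
    lb1 <- ln_bwd(dH1, blk$ln1$xhat, blk$ln1$inv, p[[paste0("g1_", l)]])
    g[[paste0("g1_", l)]] <- lb1$dg
    g[[paste0("b1_", l)]] <- lb1$db
    dR1 <- lb1$dx
    dAO <- dR1
    if (!is.null(blk$m_attn)) dAO <- dAO * blk$m_attn
    g[[paste0("Wo", l)]] <- crossprod(blk$O, dAO)
    g[[paste0("bo", l)]] <- colSums(dAO)
    dO <- tcrossprod(dAO, p[[paste0("Wo", l)]])
    dQ <- matrix(0, B * T, d)
    dK <- matrix(0, B * T, d)
    dV <- matrix(0, B * T, d)
    for (b in seq_len(B)) {
      rows <- (b - 1L) * T + seq_len(T)
      for (h in seq_len(nh)) {
        cs <- idx_h[[h]]
        A <- blk$A[[b]][[h]]
        dOb <- dO[rows, cs, drop = FALSE]
        dA <- tcrossprod(dOb, blk$V[rows, cs, drop = FALSE])
        dV[rows, cs] <- crossprod(A, dOb)
        dS <- A * (dA - rowSums(dA * A))
        dS <- dS / sqrt(dh)
        dQ[rows, cs] <- dS %*% blk$K[rows, cs, drop = FALSE]
        dK[rows, cs] <- crossprod(dS, blk$Q[rows, cs, drop = FALSE])
      }
    }
    g[[paste0("Wq", l)]] <- crossprod(blk$H_in, dQ)
    g[[paste0("bq", l)]] <- colSums(dQ)
    g[[paste0("Wk", l)]] <- crossprod(blk$H_in, dK)
    g[[paste0("bk", l)]] <- colSums(dK)
    g[[paste0("Wv", l)]] <- crossprod(blk$H_in, dV)
    g[[paste0("bv", l)]] <- colSums(dV)
    dH <- dR1 + tcrossprod(dQ, p[[paste0("Wq", l)]]) +
      tcrossprod(dK, p[[paste0("Wk", l)]]) + tcrossprod(dV, p[[paste0("Wv", l)]])
  }

  # token embedding gradients
  g$pos <- rowsum(dH, rep(seq_len(T), B))
  dimnames(g$pos) <- NULL
  g$cls <- colSums(dH[cls_rows, , drop = FALSE])
  g$W_tok <- matrix(0, ncol(X), d)
  g$B_tok <- matrix(0, ncol(X), d)
  for (b in seq_len(B)) {
    rows <- (b - 1L) * T + 1L + seq_len(ncol(X))
    g$W_tok <- g$W_tok + dH[rows, , drop = FALSE] * X[b, ]
    g$B_tok <- g$B_tok + dH[rows, , drop = FALSE]
  }
  g
}

adam_init <- function(p) {
  list(m = lapply(p, function(x) x * 0), v = lapply(p, function(x) x * 0), t = 0)
}

adam_step <- function(p, g, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1
  c1 <- 1 - beta1^st$t
  c2 <- 1 - beta2^st$t
  for (nm in names(g)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g[[nm]]^2
    p[[nm]] <- p[[nm]] - lr * (st$m[[nm]] / c1) / (sqrt(st$v[[nm]] / c2) + eps)
  }
  list(p = p, st = st)
}

#' Fit the feature-tokenizer transformer autoencoder
#'
#' @param x standardized numeric matrix / data frame (rows = samples), no
#'   missing values, at least `2 * batch_size` rows.
#' @param config an [encoder_config()].
#' @param verbose print per-epoch losses.
#' @return object of class `ft_encoder`: trained parameters, config, feature
#'   names, and `history` (per-epoch train/val loss and learning rate).
#' @export
fit_ft_transformer <- function(x, config = encoder_config(), verbose = FALSE) {
  X <- as.matrix(x)
  if (anyNA(X)) stop("input matrix must have no missing values")
  n <- nrow(X)
  if (n < 2L * config$batch_size) stop("need at least 2 * batch_size rows")
  if (config$d_latent >= ncol(X)) stop("d_latent must be below the input dimension")

  with_seed(config$seed, {
    idx <- sample.int(n)
    n_val <- max(1L, round(config$val_fraction * n))
    val_idx <- idx[seq_len(n_val)]
    tr_idx <- idx[-seq_len(n_val)]
    Xtr <- X[tr_idx, , drop = FALSE]
    Xval <- X[val_idx, , drop = FALSE]

    p <- ft_init_params(ncol(X), config)
    st <- adam_init(p)
    lr <- config$lr
    best <- list(loss = Inf, p = p, epoch = 0L)
    since_best <- 0L
    since_plateau <- 0L
    hist <- data.frame(epoch = integer(0), train = numeric(0),
                       val = numeric(0), lr = numeric(0))

    T_len <- ncol(X) + 1L
    d <- config$d_token
    drop_masks <- function(n_rows) {
      if (config$dropout <= 0) return(list(attn = list(), ffn = list()))
      mk <- function() matrix((stats::runif(n_rows * T_len * d) >= config$dropout) /
                                (1 - config$dropout), n_rows * T_len, d)
      list(attn = lapply(seq_len(config$n_blocks), function(l) mk()),
           ffn = lapply(seq_len(config$n_blocks), function(l) mk()))
    }
    eval_loss <- function(Xe) {
      cpp_ft_step(p, Xe, config$n_blocks, config$n_heads, config$d_head,
                  list(), list(), FALSE)$loss
    }
    epoch0_val <- eval_loss(Xval)
    for (ep in seq_len(config$max_epochs)) {
      ord <- sample.int(nrow(Xtr))
      tr_loss <- 0
      nb <- 0L
      for (s in seq(1L, nrow(Xtr), by = config$batch_size)) {
        rows <- ord[s:min(s + config$batch_size - 1L, nrow(Xtr))]
        if (length(rows) < 2L) next
        mk <- drop_masks(length(rows))
        step <- cpp_ft_step(p, Xtr[rows, , drop = FALSE], config$n_blocks,
                            config$n_heads, config$d_head, mk$attn, mk$ffn,
                            TRUE)
        gr <- step$grads
        for (nm in names(gr)) if (!is.matrix(p[[nm]])) gr[[nm]] <- as.numeric(gr[[nm]])
        upd <- adam_step(p, gr, st, lr)
        p <- upd$p
        st <- upd$st
        tr_loss <- tr_loss + step$loss
        nb <- nb + 1L
      }
      val_loss <- eval_loss(Xval)
      hist <- rbind(hist, data.frame(epoch = ep, train = tr_loss / max(nb, 1),
                                     val = val_loss, lr = lr))
      if (verbose) message(sprintf("epoch %d train %.5f val %.5f lr %.4g",
                                   ep, tr_loss / max(nb, 1), val_loss, lr))
      if (val_loss < best$loss - 1e-9) {
        best <- list(loss = val_loss, p = p, epoch = ep)
        since_best <- 0L
        since_plateau <- 0L
      } else {
        since_best <- since_best + 1L
        since_plateau <- since_plateau + 1L
        if (since_plateau >= config$plateau_patience) {
          lr <- lr * config$plateau_factor
          since_plateau <- 0L
        }
        if (since_best >= config$early_stop_patience) break
      }
    }
    structure(list(params = best$p, config = config,
                   feature_names = colnames(X),
                   history = hist, best_epoch = best$epoch,
                   epoch0_val = epoch0_val, best_val = best$loss),
              class = "ft_encoder")
  })
}

#' Encode rows into the latent space
#'
#' Dropout is disabled; duplicate rows map to identical embeddings and row
#' permutations permute embeddings identically.
#'
#' @param encoder a fitted `ft_encoder`.
#' @param x matrix with the same columns the encoder was fitted on.
#' @param batch_size forward batch size.
#' @return `embedding_matrix`: numeric matrix (n x d_latent) with
#'   attributes `method = "ft_t"` and the training history.
#' @export
encode <- function(encoder, x, batch_size = 64L) {
  stopifnot(inherits(encoder, "ft_encoder"))
  X <- as.matrix(x)
  if (anyNA(X)) stop("input matrix must have no missing values")
  Z <- matrix(0, nrow(X), encoder$config$d_latent)
  cfg <- encoder$config
  for (s in seq(1L, nrow(X), by = batch_size)) {
    rows <- s:min(s + batch_size - 1L, nrow(X))
    Z[rows, ] <- cpp_ft_step(encoder$params, X[rows, , drop = FALSE],
                             cfg$n_blocks, cfg$n_heads, cfg$d_head,
                             list(), list(), FALSE)$Z
  }
  structure(Z, method = "ft_t", history = encoder$history)
}
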