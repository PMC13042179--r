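# Resampled agglomerative consensus clustering with CDF-based selection of
# the number of clusters.

#' Consensus clustering configuration
#'
#' @param n_iterations resampling iterations (100).
#' @param sample_fraction fraction of observations per iteration, sampled
#'   without replacement (0.8).
#' @param k_range candidate cluster numbers (2:8).
#' @param linkage hclust linkage for the base clusterer (Ward).
#' @param delta_auc_threshold relative CDF-area gain below which adding
#'   clusters is considered to have plateaued.
#' @param seed seed for the resampling stream.
#' @return list of class `consensus_config`.
#' @export
consensus_config <- function(n_iterations = 100L, sample_fraction = 0.8,
                             k_range = 2:8, linkage = "ward.D2",
                             delta_auc_threshold = 0.025, seed = 1L) {
  if (sample_fraction <= 0 || sample_fraction > 1) {
    stop("sample_fraction must lie in (0, 1]")
  }
  structure(list(n_iterations = n_iterations,
                 sample_fraction = sample_fraction,
                 k_range = sort(unique(as.integer(k_range))),
                 linkage = linkage,
                 delta_auc_threshold = delta_auc_threshold,
                 seed = seed),
            class = "consensus_config")
}

# Empirical CDF of the defined off-diagonal upper-triangle consensus values,
# and its area under the curve over [0, 1] (Monti-style).
consensus_cdf_auc <- function(M) {
  v <- M[upper.tri(M)]
  v <- v[!is.na(v)]
  v <- sort(v)
  xs <- unique(c(0, v, 1))
  cdf <- vapply(xs, function(x) mean(v <= x), 0)
  # lower Riemann sum: an ideal two-point {0, 1} consensus yields the
  # between-pair mass, which grows smoothly in K, rather than a degenerate 1
  auc <- sum(diff(xs) * cdf[-length(cdf)])
  # proportion of ambiguous clustering: CDF mass strictly inside (0.1, 0.9)
  pac <- mean(v > 0.1 & v < 0.9)
  list(x = xs, cdf = cdf, auc = auc, pac = pac)
}

#' Resampled consensus clustering
#'
#' For every iteration a fraction of the observations is subsampled without
#' replacement and partitioned at each candidate K by Ward agglomerative
#' clustering; the consensus value of a pair is the fraction of iterations
#' co-sampling the pair in which it was co-clustered (pairs never co-sampled
#' stay undefined). Per K, the empirical CDF of the off-diagonal consensus
#' values and its area under the curve are recorded.
#'
#' @param points numeric matrix (n >= 20 rows).
#' @param config a [consensus_config()].
#' @return object of class `consensus_result`: `consensus` (list of n x n
#'   matrices by K), `cdf`, `auc`, `delta_auc`, `k_range`, `config`.
#' @export
consensus_cluster <- function(points, config = consensus_config()) {
  X <- as.matrix(points)
  n <- nrow(X)
  if (n < 20L) stop("need at least 20 observations")
  ks <- config$k_range[config$k_range <= floor(config$sample_fraction * n) - 1L]
  if (length(ks) < length(config$k_range)) {
    warning("dropping K values not smaller than the subsample size")
  }
  m <- floor(config$sample_fraction * n)
  co_sampled <- matrix(0L, n, n)
  co_clustered <- stats::setNames(
    lapply(ks, function(k) matrix(0L, n, n)), as.character(ks))

  with_seed(config$seed, {
    for (it in seq_len(config$n_iterations)) {
      idx <- sort(sample.int(n, m))
      hc <- stats::hclust(stats::dist(X[idx, , drop = FALSE]),
                          method = config$linkage)
      co_sampled[idx, idx] <- co_sampled[idx, idx] + 1L
      for (k in ks) {
        lab <- stats::cutree(hc, k)
        same <- outer(lab, lab, "==")
        key <- as.character(k)
        co_clustered[[key]][idx, idx] <- co_clustered[[key]][idx, idx] + same
      }
    }
  })

  consensus <- lapply(co_clustered, function(M) {
    C <- M / co_sampled
    C[co_sampled == 0L] <- NA_real_
    diag(C) <- 1
    C
  })
  cdfs <- lapply(consensus, consensus_cdf_auc)
  auc <- vapply(cdfs, `[[`, 0, "auc")
  pac <- vapply(cdfs, `[[`, 0, "pac")
  delta <- c(NA_real_, diff(auc) / auc[-length(auc)])
  names(delta) <- names(auc)
  structure(list(consensus = consensus, cdf = cdfs, auc = auc, pac = pac,
                 delta_auc = delta, k_range = ks, config = config),
            class = "consensus_result")
}

#' Select the number of clusters from consensus CDFs
#'
#' Default rule (`"pac"`): the point where the CDF stops changing between
#' its tails is found via the proportion of ambiguous clustering,
#' `PAC(K) = CDF(0.9) - CDF(0.1)`; K* is the largest K whose PAC lies within
#' `pac_tol` of the minimal PAC (the canonical minimize-PAC rule, with a
#' narrow tie band so that exactly-stable plateaus resolve to the largest
#' stable K while near-stable over-partitions, which leave a small residue
#' of ambiguous pairs, do not).
#' When even the minimal PAC exceeds `pac_threshold`, no partition is
#' unambiguous and the smallest candidate is returned flagged unstable.
#' The relative CDF-area-gain rule (`"delta_auc"`: largest K with
#' `(AUC_K - AUC_{K-1}) / AUC_{K-1}` above the plateau threshold) is kept as
#' an alternative; on resampled Ward partitions of compact 2-D projections
#' the area gain from splitting a genuine cluster stays a few percent at
#' every K, so the PAC form of the plateau criterion discriminates far more
#' sharply (see the methods vignette).
#'
#' @param result a `consensus_result`.
#' @param rule `"pac"` or `"delta_auc"`.
#' @param pac_threshold ambiguity level above which no K counts as stable.
#' @param pac_tol tie band around the minimal PAC.
#' @param threshold plateau threshold for the delta-AUC rule (defaults to
#'   the config value).
#' @return integer K*, with attribute `stable`.
#' @export
select_k <- function(result, rule = c("pac", "delta_auc"),
                     pac_threshold = 0.1, pac_tol = 0.001,
                     threshold = result$config$delta_auc_threshold) {
  rule <- match.arg(rule)
  if (length(result$k_range) < 2L) stop("k_range must contain at least 2 values")
  if (rule == "pac") {
    if (min(result$pac) > pac_threshold) {
      return(structure(result$k_range[1], stable = FALSE))
    }
    ok <- which(result$pac <= min(result$pac) + pac_tol)
    return(structure(result$k_range[max(ok)], stable = TRUE))
  }
  delta <- result$delta_auc[-1]
  above <- which(delta > threshold)
  if (!length(above)) {
    return(structure(result$k_range[1], stable = FALSE))
  }
  structure(result$k_range[max(above) + 1L], stable = TRUE)
}

#' Final label assignment from a consensus matrix
#'
#' Average-linkage agglomerative clustering of the consensus dissimilarity
#' (1 - consensus, undefined entries imputed by column means) cut at K;
#' per-sample confidence is the mean consensus with the other members of the
#' assigned cluster.
#'
#' @param consensus_matrix n x n consensus matrix at the selected K.
#' @param k number of clusters.
#' @return list with `labels` (1..k) and `confidence` (in \[0, 1\]).
#' @export
assign_labels <- function(consensus_matrix, k) {
  C <- as.matrix(consensus_matrix)
  n <- nrow(C)
  if (anyNA(C)) {
    cm <- colMeans(C, na.rm = TRUE)
    for (j in seq_len(n)) C[is.na(C[, j]), j] <- cm[j]
    C <- (C + t(C)) / 2
  }
  hc <- stats::hclust(stats::as.dist(1 - C), method = "average")
  labels <- stats::cutree(hc, k)
  conf <- vapply(seq_len(n), function(i) {
    mem <- which(labels == labels[i])
    mem <- setdiff(mem, i)
    if (!length(mem)) return(1)
    mean(C[i, mem])
  }, 0)
  list(labels = labels, confidence = pmin(pmax(conf, 0), 1))
}

#' Internal cluster-quality metrics
#'
#' Mean silhouette width, Calinski-Harabasz index (between/within variance
#' ratio) and Davies-Bouldin index (mean worst-case cluster similarity).
#'
#' @param points numeric matrix.
#' @param labels cluster labels (>= 2 clusters, each with >= 2 members).
#' @return named numeric vector.
#' @export
cluster_metrics <- function(points, labels) {
  X <- as.matrix(points)
  labels <- as.integer(factor(labels))
  k <- length(unique(labels))
  if (k < 2L) stop("need at least 2 clusters")
  sil <- mean(cluster::silhouette(labels, stats::dist(X))[, "sil_width"])
  n <- nrow(X)
  mu <- colMeans(X)
  cents <- t(vapply(seq_len(k), function(c) colMeans(X[labels == c, , drop = FALSE]),
                    numeric(ncol(X))))
  sizes <- tabulate(labels, k)
  B <- sum(sizes * rowSums(sweep(cents, 2, mu)^2))
  W <- sum(vapply(seq_len(k), function(c) {
    sum(sweep(X[labels == c, , drop = FALSE], 2, cents[c, ])^2)
  }, 0))
  ch <- (B / (k - 1)) / (W / (n - k))
  S <- vapply(seq_len(k), function(c) {
    mean(sqrt(rowSums(sweep(X[labels == c, , drop = FALSE], 2, cents[c, ])^2)))
  }, 0)
  Dc <- as.matrix(stats::dist(cents))
  db <- mean(vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i), function(j) (S[i] + S[j]) / Dc[i, j], 0))
  }, 0))
  c(silhouette = sil, calinski_harabasz = ch, davies_bouldin = db)
}
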