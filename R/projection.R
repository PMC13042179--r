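# 2-D projection of embeddings prior to consensus clustering.

#' Projection configuration
#'
#' @param n_neighbors neighborhood size.
#' @param min_dist UMAP minimum distance.
#' @param metric distance metric.
#' @param n_components output dimensionality (2).
#' @param seed random state.
#' @param method `"umap"` (via the python umap-learn backend) or
#'   `"spectral"` (pure-R Laplacian eigenmaps on the kNN graph; deterministic
#'   and dependency-free).
#' @return list of class `projection_config`.
#' @export
projection_config <- function(n_neighbors = 30L, min_dist = 0.1,
                              metric = "euclidean", n_components = 2L,
                              seed = 1L, method = c("umap", "spectral")) {
  method <- match.arg(method)
  if (n_neighbors < 2L) stop("n_neighbors must be >= 2")
  structure(list(n_neighbors = n_neighbors, min_dist = min_dist,
                 metric = metric, n_components = n_components,
                 seed = seed, method = method),
            class = "projection_config")
}

python_binary <- function() {
  bin <- Sys.getenv("PHYSIOPHEN_PYTHON", "python")
  if (Sys.which(bin) == "") stop("python interpreter not found for the UMAP backend")
  bin
}

umap_python_script <- function() {
  'import sys, numpy as np\n
import umap\n
args = sys.argv[1:]\n
n_neighbors, min_dist, n_comp, metric = int(args[0]), float(args[1]), int(args[2]), args[3]\n
pairs = args[4:]\n
for k in range(0, len(pairs), 3):\n
    fin, fout, seed = pairs[k], pairs[k + 1], int(pairs[k + 2])\n
    X = np.loadtxt(fin, delimiter=",")\n
    emb = umap.UMAP(n_neighbors=n_neighbors, min_dist=min_dist,\n
                    n_components=n_comp, metric=metric,\n
                    random_state=seed, n_jobs=1).fit_transform(X)\n
    np.savetxt(fout, emb, delimiter=",")\n'
}

# One python call projecting several matrices (amortizes the interpreter /
# JIT start-up cost across runs).
umap_project_batch <- function(mats, config, seeds) {
  stopifnot(length(mats) == length(seeds))
  td <- tempfile("umapjob")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  fins <- character(length(mats))
  fouts <- character(length(mats))
  for (i in seq_along(mats)) {
    fins[i] <- file.path(td, sprintf("in%02d.csv", i))
    fouts[i] <- file.path(td, sprintf("out%02d.csv", i))
    utils::write.table(as.matrix(mats[[i]]), fins[i], sep = ",",
                       row.names = FALSE, col.names = FALSE)
  }
  script <- file.path(td, "run_umap.py")
  writeLines(gsub("\n\n", "\n", umap_python_script()), script)
  args <- c(script, config$n_neighbors, config$min_dist, config$n_components,
            config$metric, as.vector(rbind(fins, fouts, as.character(seeds))))
  res <- suppressWarnings(system2(python_binary(), args, stdout = TRUE, stderr = TRUE))
  if (!all(file.exists(fouts))) {
    stop("UMAP backend failed: ", paste(utils::tail(res, 3), collapse = " | "))
  }
  lapply(fouts, function(f) as.matrix(utils::read.csv(f, header = FALSE)))
}

# Laplacian-eigenmap projection: symmetric kNN graph, normalized Laplacian,
# trailing non-trivial eigenvectors. Deterministic (eigen sign fixed).
spectral_project <- function(X, config) {
  n <- nrow(X)
  k <- min(config$n_neighbors, n - 1L)
  D <- as.matrix(stats::dist(X))
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[2:(k + 1L)]
    sigma <- max(D[i, nb[k]], .Machine$double.eps)
    W[i, nb] <- exp(-(D[i, nb] / sigma)^2)
  }
  W <- pmax(W, t(W))
  # weak global coupling keeps the graph connected (disconnected components
  # would collapse to indistinguishable points in the null space)
  W <- W + 1e-4
  diag(W) <- 0
  dg <- pmax(rowSums(W), .Machine$double.eps)
  L <- diag(n) - diag(1 / sqrt(dg)) %*% W %*% diag(1 / sqrt(dg))
  ei <- eigen((L + t(L)) / 2, symmetric = TRUE)
  take <- (n - 1L):(n - config$n_components)
  V <- ei$vectors[, take, drop = FALSE]
  for (j in seq_len(ncol(V))) {
    i_max <- which.max(abs(V[, j]))
    if (V[i_max, j] < 0) V[, j] <- -V[, j]
  }
  V * sqrt(n)
}

#' Project an embedding to 2-D
#'
#' UMAP backend (python umap-learn, deterministic under `seed` with a single
#' worker) or a pure-R spectral (Laplacian eigenmap) projection.
#'
#' @param embedding numeric matrix (n x d).
#' @param config a [projection_config()].
#' @return numeric matrix (n x n_components).
#' @export
project <- function(embedding, config = projection_config()) {
  X <- as.matrix(embedding)
  if (nrow(X) < config$n_neighbors + 1L) {
    stop("need at least n_neighbors + 1 rows")
  }
  if (config$method == "umap") {
    umap_project_batch(list(X), config, config$seed)[[1]]
  } else {
    spectral_project(X, config)
  }
}

#' Project several embeddings in one backend invocation
#'
#' For the UMAP backend this amortizes the interpreter start-up cost across
#' runs (each matrix keeps its own seed).
#'
#' @param embeddings list of matrices.
#' @param config a [projection_config()].
#' @param seeds integer vector, one per matrix.
#' @return list of projected matrices.
#' @export
project_batch <- function(embeddings, config = projection_config(),
                          seeds = rep(config$seed, length(embeddings))) {
  if (config$method == "umap") {
    umap_project_batch(embeddings, config, seeds)
  } else {
    lapply(seq_along(embeddings), function(i) {
      cfg <- config
      cfg$seed <- seeds[i]
      spectral_project(as.matrix(embeddings[[i]]), cfg)
    })
  }
}
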