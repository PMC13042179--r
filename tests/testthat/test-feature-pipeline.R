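# Feature-cleaning pipeline.

test_that("covariate encoding follows the clinical thresholds exactly", {
  expect_equal(unlist(encode_covariates(95, 24, 14)), c(sbp_low = 1, rr_high = 1,
                                                        gcs_low = 1, composite = 3))
  expect_equal(unlist(encode_covariates(100, 22, 15)), c(sbp_low = 1, rr_high = 1,
                                                         gcs_low = 0, composite = 2))
  expect_equal(unlist(encode_covariates(120, 16, 15)), c(sbp_low = 0, rr_high = 0,
                                                         gcs_low = 0, composite = 0))
  expect_error(encode_covariates(120, 16, 17), "GCS")
  na_row <- encode_covariates(NA, 20, 15)
  expect_true(is.na(na_row$sbp_low) && is.na(na_row$composite))
})

test_that("outlier rejection masks exactly the planted cell, strict at |z| = 6", {
  withr::with_seed(1, v <- rnorm(1000))
  v[17] <- 10
  out <- reject_outliers(data.frame(a = v))
  expect_true(is.na(out$data$a[17]))
  expect_equal(sum(is.na(out$data$a)), 1L)
  # |z| exactly 6 is retained (strict inequality)
  u <- c(rep(c(-1, 1), 50))
  u <- c(u, 6 * stats::sd(c(u, 6)))  # construct approximately, then verify
  z <- (u - mean(u)) / stats::sd(u)
  keep_expected <- sum(abs(z) > 6)
  out2 <- reject_outliers(data.frame(a = u))
  expect_equal(sum(is.na(out2$data$a)), keep_expected)
  # constant column untouched
  out3 <- reject_outliers(data.frame(a = rep(3, 10)))
  expect_equal(sum(is.na(out3$data$a)), 0L)
})

test_that("missingness filter drops > 15% and keeps exactly 15%", {
  x <- data.frame(a = c(rep(NA, 16), rnorm(84)),
                  b = c(rep(NA, 15), rnorm(85)),
                  c = rnorm(100))
  out <- filter_missingness(x)
  expect_setequal(names(out$data), c("b", "c"))
  expect_equal(unname(out$report$missing_fraction["a"]), 0.16)
  full <- filter_missingness(data.frame(a = rnorm(10)))
  expect_equal(names(full$data), "a")
})

test_that("imputation is identity on complete data and respects PMM support", {
  x <- data.frame(a = rnorm(50), b = rnorm(50))
  expect_equal(impute_mice(x, seed = 1), x, ignore_attr = TRUE)
  withr::with_seed(2, {
    y <- as.data.frame(matrix(rnorm(300), ncol = 3))
    y$V2[sample(100, 20)] <- NA
  })
  done <- impute_mice(y, seed = 3)
  expect_false(anyNA(done))
  expect_true(all(done$V2[is.na(y$V2)] %in% y$V2[!is.na(y$V2)]))
  expect_identical(impute_mice(y, seed = 3)$V2, done$V2)  # deterministic
  bad <- data.frame(a = rnorm(10), b = rep(NA_real_, 10))
  expect_error(impute_mice(bad), "100% missing.*b")
})

test_that("chained PMM beats column-mean imputation on correlated MCAR data", {
  rho <- 0.8
  wins <- 0
  for (s in 1:5) {
    withr::with_seed(s, {
      n <- 500
      z <- rnorm(n)
      X <- data.frame(a = z + rnorm(n, 0, sqrt(1 - rho^2)),
                      b = z + rnorm(n, 0, sqrt(1 - rho^2)),
                      c = z + rnorm(n, 0, sqrt(1 - rho^2)))
      truth <- X
      holes <- matrix(runif(n * 3) < 0.1, n, 3)
      X[holes] <- NA
    })
    imp <- impute_mice(X, seed = s)
    rmse_mice <- sqrt(mean((as.matrix(imp)[holes] - as.matrix(truth)[holes])^2))
    means <- colMeans(X, na.rm = TRUE)
    Xm <- X
    for (j in 1:3) Xm[[j]][is.na(X[[j]])] <- means[j]
    rmse_mean <- sqrt(mean((as.matrix(Xm)[holes] - as.matrix(truth)[holes])^2))
    wins <- wins + (rmse_mice < rmse_mean)
  }
  expect_gte(wins, 4)
})

test_that("low-variance filter drops near-constant and constant columns", {
  withr::with_seed(4, {
    x <- data.frame(rare = c(rep(0, 995), rep(1, 5)),
                    normal = rnorm(1000),
                    const = rep(2.5, 1000))
  })
  out <- filter_low_variance(x)
  expect_setequal(out$report$dropped, c("rare", "const"))
  expect_equal(names(out$data), "normal")
})

test_that("correlation reduction removes duplicates and resolves correlated triples", {
  withr::with_seed(5, {
    a <- rnorm(300)
    x <- data.frame(a = a, a_copy = a, z = rnorm(300))
  })
  out <- reduce_correlation(x)
  expect_equal(length(out$report$dropped), 1L)
  expect_true("z" %in% names(out$data))

  withr::with_seed(6, {
    base <- rnorm(400)
    y <- data.frame(p = base + rnorm(400, 0, 0.2),
                    q = base + rnorm(400, 0, 0.2),
                    r = base + rnorm(400, 0, 0.2),
                    ind = rnorm(400))
  })
  out2 <- reduce_correlation(y, threshold = 0.85)
  cm <- abs(stats::cor(out2$data))
  diag(cm) <- 0
  expect_lt(max(cm), 0.85)
  expect_gte(length(out2$report$dropped), 2L)
  expect_true("ind" %in% names(out2$data))

  # independent columns: identity
  withr::with_seed(7, ind <- as.data.frame(matrix(rnorm(200 * 4), ncol = 4)))
  expect_equal(names(reduce_correlation(ind)$data), names(ind))
})

test_that("standardization round-trips and reuses stored moments", {
  withr::with_seed(8, x <- as.data.frame(matrix(rnorm(200 * 3, 5, 2), ncol = 3)))
  st <- standardize(x)
  expect_true(all(abs(colMeans(st$data)) < 1e-9))
  expect_true(all(abs(vapply(st$data, sd, 0) - 1) < 1e-9))
  back <- unstandardize(st$data, st$scaler)
  expect_equal(as.matrix(back), as.matrix(x), tolerance = 1e-9)
  new_rows <- x[1:5, ] + 100
  st2 <- standardize(new_rows, scaler = st$scaler)
  expect_equal(as.matrix(st2$data), as.matrix((new_rows - rep(st$scaler$center, each = 5)) /
                                                rep(st$scaler$scale, each = 5)),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("full pipeline is idempotent, accounts columns exactly, leaves no NA", {
  withr::with_seed(9, {
    n <- 120
    base <- rnorm(n)
    x <- data.frame(f1 = base + rnorm(n, 0, .1), f2 = base + rnorm(n, 0, .1),
                    f3 = rnorm(n), f4 = rnorm(n), f5 = rep(1, n),
                    f6 = rnorm(n))
    x$f3[sample(n, 10)] <- NA
    x$f4[sample(n, 30)] <- NA      # 25% missing -> dropped
    cov <- encode_covariates(runif(n, 80, 140), runif(n, 12, 30),
                             sample(c(3:15), n, TRUE))
  })
  res <- run_feature_pipeline(x, covariates = cov, seed = 2)
  expect_false(anyNA(res$data))
  rep <- res$report
  dropped_n <- length(rep$missingness$dropped) + length(rep$all_missing$dropped) +
    length(rep$low_variance$dropped) + length(rep$correlation$dropped)
  expect_equal(rep$n_final, rep$n_initial + ncol(cov) - dropped_n)
  # disjoint drop sets
  all_drops <- c(rep$missingness$dropped, rep$all_missing$dropped,
                 rep$low_variance$dropped, rep$correlation$dropped)
  expect_false(anyDuplicated(all_drops) > 0)
  # idempotence: re-running on the cleaned unscaled output drops nothing
  res2 <- run_feature_pipeline(res$data_unscaled, seed = 2)
  expect_equal(ncol(res2$data), ncol(res$data))
  expect_equal(res2$report$n_final, res$report$n_final)
})
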