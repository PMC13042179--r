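# Outcome stratification: group tests, summary ANOVA, survival analysis.

test_that("chi-squared on published-style mortality counts is highly significant", {
  deaths <- c(137, 132, 168, 70)
  sizes <- c(580, 721, 601, 272)
  status <- rep(rep(c("died", "survived"), 4),
                times = as.vector(rbind(deaths, sizes - deaths)))
  group <- rep(paste0("SP", 1:4), times = sizes)
  res <- compare_groups(status, group, type = "categorical")
  expect_lt(res$p_value, 0.001)
  expect_true(res$significant)
})

test_that("identical groups give a zero statistic and p = 1", {
  vals <- rep(c("a", "b"), each = 20)
  grp <- rep(c("g1", "g2"), 20)
  res <- compare_groups(vals, grp, type = "categorical")
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1, tolerance = 1e-12)
})

test_that("summary-statistic ANOVA agrees with raw-data ANOVA to 1e-10", {
  withr::with_seed(31, {
    for (rep in 1:4) {
      ns <- sample(10:40, 3)
      groups <- lapply(seq_along(ns), function(i) rnorm(ns[i], mean = i * 0.3))
      res <- anova_from_summary(ns, vapply(groups, mean, 0), vapply(groups, sd, 0))
      df <- data.frame(y = unlist(groups),
                       g = factor(rep(seq_along(ns), ns)))
      ref <- summary(stats::aov(y ~ g, df))[[1]]
      expect_equal(res$F, ref$`F value`[1], tolerance = 1e-10)
      expect_equal(res$p_value, ref$`Pr(>F)`[1], tolerance = 1e-10)
    }
  })
  expect_equal(anova_from_summary(c(10, 10), c(5, 5), c(1, 1))$F, 0)
  expect_equal(anova_from_summary(c(10, 10), c(5, 5), c(1, 1))$p_value, 1)
  expect_error(anova_from_summary(c(10, 10), c(1, 2), c(1, -1)), "negative")
})

test_that("published-style lab summaries reproduce the printed significance", {
  ns <- c(580, 721, 601, 272)
  bun <- anova_from_summary(ns, c(32.073, 30.316, 32.099, 37.125),
                            c(24.766, 22.137, 28.133, 24.756))
  expect_equal(round(bun$p_value, 3), 0.002)
  age <- anova_from_summary(ns, c(55.84, 59.55, 60.12, 71.58),
                            c(16.03, 16.02, 15.95, 12.22))
  expect_lt(age$p_value, 0.001)
  plate <- anova_from_summary(ns, c(231.816, 211.251, 230.699, 209.183),
                              c(126.889, 104.473, 125.225, 109.443))
  expect_lt(plate$p_value, 0.001)
})

test_that("Kaplan-Meier matches the hand product-limit computation", {
  # 6 subjects: times 1, 2+, 3, 4+, 5, 6 -> S(3) = (1 - 1/6)(1 - 1/4) = 0.625
  times <- c(1, 2, 3, 4, 5, 6)
  events <- c(1, 0, 1, 0, 1, 1)
  km <- km_estimate(times, events)
  cv <- km$curves[[1]]
  expect_equal(cv$surv[cv$time == 3], 0.625, tolerance = 1e-9)
  expect_equal(cv$surv[cv$time == 1], 5 / 6, tolerance = 1e-9)
  # no censoring -> empirical survival function
  t2 <- c(1, 2, 3, 4)
  km2 <- km_estimate(t2, rep(1, 4))
  cv2 <- km2$curves[[1]]
  expect_equal(cv2$surv, c(0.75, 0.5, 0.25, 0), tolerance = 1e-12)
  # all censored -> flat at 1
  expect_warning(km3 <- km_estimate(t2, rep(0, 4)), "no events")
  expect_true(all(km3$curves[[1]]$surv == 1))
  expect_true(all(km3$curves[[1]]$upper <= 1 & km3$curves[[1]]$lower >= 0))
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "negative")
})

test_that("log-rank equals a hand-computed two-group oracle to 1e-9", {
  # textbook observed-vs-expected computation on a 10-subject fixture
  logrank_oracle <- function(times, events, groups) {
    ev_times <- sort(unique(times[events == 1]))
    O1 <- 0; E1 <- 0; V <- 0
    for (t in ev_times) {
      at_risk <- times >= t
      n <- sum(at_risk)
      n1 <- sum(at_risk & groups == 1)
      d <- sum(times == t & events == 1)
      d1 <- sum(times == t & events == 1 & groups == 1)
      O1 <- O1 + d1
      E1 <- E1 + d * n1 / n
      if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    (O1 - E1)^2 / V
  }
  times <- c(3, 5, 7, 2, 8, 1, 4, 6, 9, 10)
  events <- c(1, 1, 0, 1, 1, 1, 0, 1, 1, 0)
  groups <- rep(1:2, each = 5)
  res <- logrank_test(times, events, groups)
  expect_equal(res$statistic, logrank_oracle(times, events, groups),
               tolerance = 1e-9)
  expect_equal(res$df, 1L)
  # identical groups -> statistic 0
  same <- logrank_test(rep(times[1:5], 2), rep(events[1:5], 2), rep(1:2, each = 5))
  expect_equal(same$statistic, 0, tolerance = 1e-9)
})

test_that("a strong hazard ratio is detected by the log-rank test", {
  hits <- 0
  for (s in 1:5) {
    withr::with_seed(s + 40, {
      t1 <- rexp(100, rate = 0.1)
      t2 <- rexp(100, rate = 0.3)
      times <- pmin(c(t1, t2), 28)
      events <- as.integer(c(t1, t2) <= 28)
    })
    p <- logrank_test(times, events, rep(1:2, each = 100))$p_value
    hits <- hits + (p < 0.01)
  }
  expect_gte(hits, 4)
})

test_that("type-I error of all tests stays near nominal 5%", {
  n_rep <- 2000
  alpha <- 0.05
  withr::with_seed(77, {
    kw <- logical(n_rep); cs <- logical(n_rep); av <- logical(n_rep)
    lr <- logical(n_rep)
    for (i in seq_len(n_rep)) {
      g <- factor(rep(1:4, each = 50))
      y <- rnorm(200)
      kw[i] <- stats::kruskal.test(y, g)$p.value < alpha
      tabv <- sample(c("yes", "no"), 200, TRUE)
      cs[i] <- compare_groups(tabv, g, type = "categorical")$p_value < alpha
      ns <- rep(50, 4)
      ms <- tapply(y, g, mean); sds <- tapply(y, g, sd)
      av[i] <- anova_from_summary(ns, ms, sds)$p_value < alpha
      tt <- rexp(80, 0.1); ev <- as.integer(tt <= 20); tt <- pmin(tt, 20)
      lr[i] <- logrank_test(tt, ev, rep(1:2, each = 40))$p_value < alpha
    }
  })
  for (rate in c(mean(kw), mean(cs), mean(av), mean(lr))) {
    expect_gte(rate, 0.03)
    expect_lte(rate, 0.07)
  }
})

test_that("prevalence tables are monotone over horizons and track planted risk", {
  withr::with_seed(50, {
    n <- 300
    ph <- sample(paste0("SP", 1:3), n, TRUE)
    d2 <- runif(n) < ifelse(ph == "SP3", 0.4, 0.15)
    d7 <- d2 | (runif(n) < 0.05)
    d28 <- d7 | (runif(n) < 0.05)
    tab <- data.frame(phenotype = ph, ss2 = d2, ss7 = d7, ss28 = d28)
  })
  prev <- prevalence_at(tab, prefixes = "ss")
  for (p in unique(prev$phenotype)) {
    r <- prev$rate[prev$phenotype == p][order(prev$day[prev$phenotype == p])]
    expect_true(all(diff(r) >= 0))
  }
  r28 <- prev[prev$day == 28, ]
  expect_equal(r28$phenotype[which.max(r28$rate)], "SP3")
  zero <- prevalence_at(data.frame(phenotype = "A", ss2 = FALSE, ss7 = FALSE,
                                   ss28 = FALSE), prefixes = "ss")
  expect_true(all(zero$rate == 0))
})

test_that("highest planted shock archetype shows the highest SS28 rate", {
  hits <- 0
  for (s in 1:5) {
    cc <- cohort_config(1000, seed = s + 60)
    co <- generate_cohort(cc, keep_waveforms = FALSE)
    tab <- co$metadata
    tab$phenotype <- tab$archetype
    prev <- prevalence_at(tab, prefixes = "ss")
    r28 <- prev[prev$day == 28, ]
    hits <- hits + (r28$phenotype[which.max(r28$rate)] == "SP3")
  }
  expect_gte(hits, 4)
})
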