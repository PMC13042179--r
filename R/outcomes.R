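# Outcome stratification: group-difference tests, summary-statistic ANOVA,
# Kaplan-Meier survival with log-rank tests, and day-2/7/28 prevalence
# tables.

#' Compare a variable across phenotype groups
#'
#' Continuous variables use the (tie-corrected) Kruskal-Wallis test;
#' categorical variables a chi-squared test on the contingency table
#' (without continuity correction by default, the standard choice for k x m
#' tables).
#'
#' @param values numeric vector, or factor/character for categorical data.
#' @param groups group labels.
#' @param type `"auto"`, `"continuous"` or `"categorical"`.
#' @param correct continuity correction for 2 x 2 chi-squared tables.
#' @return list with `test`, `statistic`, `df`, `p_value`, `significant`
#'   (two-tailed 0.05) and per-group summaries.
#' @export
compare_groups <- function(values, groups, type = c("auto", "continuous", "categorical"),
                           correct = FALSE) {
  type <- match.arg(type)
  groups <- factor(groups)
  if (nlevels(droplevels(groups)) < 2L) stop("need at least 2 groups with data")
  if (type == "auto") {
    type <- if (is.numeric(values) && length(unique(values)) > 5L)
      "continuous" else "categorical"
  }
  if (type == "continuous") {
    ht <- stats::kruskal.test(values, groups)
    summaries <- tapply(values, groups, function(v) {
      c(median = stats::median(v, na.rm = TRUE),
        q1 = stats::quantile(v, 0.25, na.rm = TRUE, names = FALSE),
        q3 = stats::quantile(v, 0.75, na.rm = TRUE, names = FALSE))
    })
  } else {
    tab <- table(groups, values)
    if (any(tab == 0) && any(stats::chisq.test(tab, correct = correct)$expected == 0)) {
      stop("contingency table has an expected cell count of zero")
    }
    ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    summaries <- tab
  }
  list(test = ht$method, statistic = unname(ht$statistic),
       df = unname(ht$parameter), p_value = ht$p.value,
       significant = ht$p.value < 0.05, summaries = summaries)
}

#' One-way ANOVA from printed group summaries
#'
#' Reconstructs the classic F test from per-group sizes, means and SDs:
#' between-group sum of squares from the group means about the grand mean,
#' within-group sum of squares from `(n_i - 1) sd_i^2`, F on
#' `(k - 1, N - k)` degrees of freedom. Lets published summary tables be
#' checked without raw data.
#'
#' @param ns,means,sds equal-length vectors of group sizes, means, SDs.
#' @return list with `F`, `df` (length 2), `p_value`.
#' @export
anova_from_summary <- function(ns, means, sds) {
  stopifnot(length(ns) == length(means), length(means) == length(sds))
  if (length(ns) < 2L) stop("need at least 2 groups")
  if (any(ns < 2)) stop("every group needs n >= 2")
  if (any(sds < 0)) stop("negative SD")
  N <- sum(ns)
  k <- length(ns)
  grand <- sum(ns * means) / N
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum((ns - 1) * sds^2)
  Fstat <- (ss_between / (k - 1)) / (ss_within / (N - k))
  p <- stats::pf(Fstat, k - 1, N - k, lower.tail = FALSE)
  list(F = Fstat, df = c(k - 1, N - k), p_value = p)
}

#' Kaplan-Meier survival estimates per phenotype
#'
#' Product-limit estimator per group with Greenwood-variance 95% confidence
#' intervals (plain transform, clipped to \[0, 1\]).
#'
#' @param times follow-up times (days, censored at the horizon).
#' @param events event indicators (1 = death).
#' @param groups phenotype labels.
#' @return object of class `survival_curves`: per group a data frame
#'   (`time`, `n_risk`, `n_event`, `surv`, `lower`, `upper`), plus the
#'   underlying `survfit` object.
#' @export
km_estimate <- function(times, events, groups = rep(1, length(times))) {
  if (any(times < 0)) stop("negative times")
  if (sum(events) < 1) warning("no events observed")
  groups <- factor(groups)
  fit <- survival::survfit(survival::Surv(times, events) ~ groups,
                           conf.type = "plain", conf.int = 0.95)
  sm <- summary(fit, censored = TRUE)
  strata <- if (is.null(sm$strata)) rep(levels(groups)[1], length(sm$time)) else
    sub("^groups=", "", as.character(sm$strata))
  curves <- split(data.frame(time = sm$time, n_risk = sm$n.risk,
                             n_event = sm$n.event, surv = sm$surv,
                             lower = pmax(0, ifelse(is.na(sm$lower), 0, sm$lower)),
                             upper = pmin(1, ifelse(is.na(sm$upper), 1, sm$upper))),
                  strata)
  structure(list(curves = curves, fit = fit), class = "survival_curves")
}

#' Log-rank test across phenotype groups
#'
#' Standard observed-vs-expected chi-squared statistic across event times
#' with `groups - 1` degrees of freedom.
#'
#' @inheritParams km_estimate
#' @return list with `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(times, events, groups) {
  if (any(times < 0)) stop("negative times")
  groups <- factor(groups)
  sd0 <- survival::survdiff(survival::Surv(times, events) ~ groups, rho = 0)
  df <- length(sd0$n) - 1L
  list(statistic = unname(sd0$chisq), df = df,
       p_value = stats::pchisq(sd0$chisq, df, lower.tail = FALSE))
}

#' Outcome prevalence by phenotype and horizon
#'
#' Mean flag rates per phenotype at the requested horizons, for monotone
#' day-2/7/28 exposure flags (rates are then non-decreasing in horizon).
#'
#' @param outcome_table data frame with a `phenotype` column and flag
#'   columns named `<prefix><day>` (e.g. `ss2`, `ss7`, `ss28`).
#' @param prefixes flag families to tabulate.
#' @param days horizons.
#' @return long data frame: `phenotype`, `outcome`, `day`, `rate`, `n`.
#' @export
prevalence_at <- function(outcome_table, prefixes = c("death", "ss", "vp", "mv"),
                          days = c(2, 7, 28)) {
  stopifnot("phenotype" %in% names(outcome_table))
  rows <- list()
  for (pf in prefixes) {
    for (d in days) {
      col <- paste0(pf, d)
      if (!col %in% names(outcome_table)) next
      agg <- tapply(as.numeric(outcome_table[[col]]), outcome_table$phenotype, mean)
      ns <- tapply(outcome_table[[col]], outcome_table$phenotype, length)
      rows[[length(rows) + 1L]] <- data.frame(
        phenotype = names(agg), outcome = pf, day = d,
        rate = as.numeric(agg), n = as.integer(ns))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
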