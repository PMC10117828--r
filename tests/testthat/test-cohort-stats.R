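# Group comparisons, ROC cutoffs, survival estimators.

test_that("group t-tests match the closed-form pooled-variance statistic", {
  # identical group distributions: t = 0, p = 1
  params <- tibble::tibble(a = c(1, 2, 3, 1, 2, 3))
  grp <- c(0, 0, 0, 1, 1, 1)
  res <- compare_groups(params, grp)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  # hand-computed t on a 3+3 fixture
  x <- c(4.1, 5.0, 6.2); y <- c(7.3, 8.1, 9.4)
  res2 <- compare_groups(tibble::tibble(v = c(x, y)), c(0, 0, 0, 1, 1, 1))
  expect_equal(abs(res2$t), abs(t_oracle(x, y)), tolerance = 1e-12)
  expect_equal(res2$p, 2 * pt(-abs(t_oracle(x, y)), df = 4), tolerance = 1e-12)
  # a 10-SD separation is overwhelmingly significant
  set.seed(71)
  big <- tibble::tibble(v = c(rnorm(20), rnorm(20, 10)))
  res3 <- compare_groups(big, rep(0:1, each = 20))
  expect_lt(res3$p, 1e-10)
  expect_true(res3$significant)
  # degenerate group sizes give NA, flagged not dropped
  res4 <- compare_groups(params, c(0, 1, 1, 1, 1, 1))
  expect_true(is.na(res4$p))
  # FDR option adjusts across parameters
  many <- tibble::as_tibble(setNames(as.data.frame(matrix(rnorm(40 * 6), 40)), paste0("p", 1:6)))
  res5 <- compare_groups(many, rep(0:1, 20), fdr = TRUE)
  expect_equal(res5$p_adj, p.adjust(res5$p, "BH"))
})

test_that("the Youden cutoff equals an exhaustive enumeration oracle", {
  # perfect separation at 5 vs 10 -> midpoint 7.5, J = 1
  res <- roc_cutoff(c(5, 5, 5, 10, 10, 10), c(0, 0, 0, 1, 1, 1))
  expect_equal(res$threshold, 7.5)
  expect_equal(res$criterion, 1)
  expect_identical(res$direction, ">")
  # outcome independent of values: J near 0
  set.seed(72)
  resn <- roc_cutoff(rnorm(400), rbinom(400, 1, 0.5))
  expect_lt(resn$criterion, 0.25)
  expect_error(roc_cutoff(rnorm(10), rep(1, 10)), "classes")
  # enumeration oracle on 500 random instances
  for (i in 1:500) {
    n <- sample(6:25, 1)
    v <- round(runif(n, 0, 10), 1)
    o <- rbinom(n, 1, 0.5)
    if (length(unique(o)) < 2) next
    got <- roc_cutoff(v, o)
    u <- sort(unique(v))
    thr <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else u
    best_j <- -Inf
    for (t in thr) for (dir in c(">", "<")) {
      pos <- if (dir == ">") v > t else v < t
      j <- sum(pos & o == 1) / sum(o == 1) + sum(!pos & o == 0) / sum(o == 0) - 1
      if (j > best_j + 1e-12) best_j <- j
    }
    expect_equal(got$criterion, best_j, tolerance = 1e-9)
  }
})

test_that("the Youden cutoff agrees with pROC on a fixture", {
  skip_if_not_installed("pROC")
  set.seed(73)
  v <- c(rnorm(40, 5), rnorm(40, 7))
  o <- rep(0:1, each = 40)
  got <- roc_cutoff(v, o)
  r <- pROC::roc(o, v, direction = "<", quiet = TRUE)
  ref <- pROC::coords(r, "best", best.method = "youden",
                      ret = c("threshold", "sensitivity", "specificity"))
  # pROC may report several tied optima; ours must be among them
  expect_true(any(abs(got$threshold - ref$threshold) < 1e-9))
  expect_equal(got$sensitivity + got$specificity,
               max(ref$sensitivity + ref$specificity), tolerance = 1e-9)
  expect_equal(got$auc, as.numeric(pROC::auc(r)), tolerance = 1e-9)
})

test_that("log-rank matches the hand oracle and KM reduces to the empirical survival", {
  # 4-patient fixture, no censoring: A events at 1, 2; B at 3, 4
  time <- c(1, 2, 3, 4); event <- c(1, 1, 1, 1); grp <- c("A", "A", "B", "B")
  km <- km_logrank(time, event, grp)
  expect_equal(km$chisq, logrank_oracle(time, event, grp), tolerance = 1e-9)
  expect_equal(km$p, pchisq(km$chisq, 1, lower.tail = FALSE))
  # identical strata: statistic 0
  km0 <- km_logrank(c(1, 2, 3, 1, 2, 3), rep(1, 6), rep(c("A", "B"), each = 3))
  expect_lt(km0$chisq, 1e-10)
  # KM curve without censoring is the empirical survival function
  set.seed(74)
  t1 <- sample(1:50, 20, replace = TRUE)
  km1 <- km_logrank(c(t1, 100), rep(1, 21), c(rep("A", 20), "B"))
  a <- km1$curves[km1$curves$stratum == "A", ]
  expect_equal(a$surv, vapply(a$time, function(s) mean(t1 > s), numeric(1)))
  # larger randomized fixtures against the oracle
  for (i in 1:25) {
    n <- sample(10:40, 1)
    tt <- sample(1:30, n, replace = TRUE)
    ev <- rbinom(n, 1, 0.7)
    g <- sample(c("A", "B"), n, replace = TRUE)
    if (length(unique(g)) < 2 || sum(ev) == 0) next
    expect_equal(km_logrank(tt, ev, g)$chisq, logrank_oracle(tt, ev, g),
                 tolerance = 1e-8)
  }
  expect_error(km_logrank(1:3, c(1, 1, 1), c("A", "A", "A")), "strata")
})

test_that("Cox fits recover null effects and refuse degenerate designs", {
  set.seed(75)
  n <- 500
  d <- tibble::tibble(
    x = rbinom(n, 1, 0.5),
    dfs_months = rexp(n, 0.05),
    dfs_event = TRUE)
  fit <- cox_multivariate(d, covariates = "x")
  expect_lt(abs(fit$coefficients$estimate), 0.2)
  expect_true(fit$converged)
  # collinear covariates are refused
  d$y <- d$x
  expect_error(cox_multivariate(d, covariates = c("x", "y")), "collinear")
  # too few events for the covariate count
  d2 <- dplyr::mutate(d[1:10, ], dfs_event = c(TRUE, rep(FALSE, 9)))
  expect_error(cox_multivariate(d2, covariates = "x"), "too few events")
  # tidy/glance methods expose the fit
  td <- tidy(fit)
  expect_identical(td$term, "x")
  expect_true(all(c("hr", "p_value") %in% names(td)))
  expect_identical(names(glance(fit)),
                   c("n", "n_events", "converged", "logLik", "concordance"))
})

test_that("stage subsetting keeps IIB/III and partitions the cohort", {
  clin <- tibble::tibble(patient = 1:6,
                         stage = c("I", "IIA", "IIB", "IIIA", NA, "IIIC"))
  expect_warning(sub <- stage_subset(clin), "missing stage")
  expect_identical(sub$stage, c("IIB", "IIIA", "IIIC"))
  comp <- clin[!clin$patient %in% sub$patient & !is.na(clin$stage), ]
  expect_identical(sort(c(sub$patient, comp$patient)), (1:6)[-5])
  expect_error(stage_subset(tibble::tibble(stage = c("I", "IIA"))), "empty")
})

test_that("dichotomization honours threshold direction", {
  v <- c(1, 2, 3, 4)
  expect_identical(as.character(dichotomize(v, 2.5)), c("low", "low", "high", "high"))
  cut <- tibble::tibble(threshold = 2.5, direction = "<")
  expect_identical(as.character(dichotomize(v, cut)), c("high", "high", "low", "low"))
})
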