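# Cohort-level prognostic statistics: group t-tests over the spatial
# parameters, ROC-derived cutoffs, Kaplan-Meier / log-rank survival by
# dichotomized parameters, multivariate Cox models and stage subsetting.

#' Group comparison of spatial parameters
#'
#' Two-sample t-test per parameter column between the two groups (pooled
#' variance by default, Welch by option). With `fdr = TRUE` the p-values are
#' Benjamini-Hochberg adjusted across parameters.
#'
#' @param params data frame of parameter columns (one row per patient).
#' @param group logical or two-level vector (e.g. recurrence yes/no).
#' @param welch use Welch's unequal-variance t-test.
#' @param fdr add BH-adjusted p-values.
#' @param alpha significance level for the flag (default 0.05).
#' @return Tibble: `parameter`, `mean_1`, `mean_0`, `t`, `p`, (`p_adj`),
#'   `significant`.
#' @export
compare_groups <- function(params, group, welch = FALSE, fdr = FALSE,
                           alpha = 0.05) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) > 2) stop("`group` must have exactly two levels")
  if (nlevels(group) < 2) {
    warning("only one group level present: all comparisons are NA")
    return(tibble::tibble(parameter = names(params), mean_1 = NA_real_,
                          mean_0 = NA_real_, t = NA_real_, p = NA_real_,
                          significant = NA))
  }
  res <- purrr::map_dfr(names(params), function(nm) {
    v <- params[[nm]]
    ok <- !is.na(v) & !is.na(group)
    g <- group[ok]; v <- v[ok]
    if (min(table(g)) < 2) {
      return(tibble::tibble(parameter = nm, mean_1 = NA_real_, mean_0 = NA_real_,
                            t = NA_real_, p = NA_real_))
    }
    tt <- tryCatch(stats::t.test(v ~ g, var.equal = !welch),
                   error = function(e) NULL)  # e.g. constant data
    tibble::tibble(parameter = nm,
                   mean_1 = mean(v[g == levels(g)[2]]),
                   mean_0 = mean(v[g == levels(g)[1]]),
                   t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
                   p = if (is.null(tt)) NA_real_ else tt$p.value)
  })
  if (fdr) res$p_adj <- stats::p.adjust(res$p, "BH")
  res$significant <- (if (fdr) res$p_adj else res$p) < alpha
  res
}

#' ROC-derived optimal cutoff (Youden's J)
#'
#' Evaluates every midpoint between sorted unique values as a threshold and
#' returns the one maximizing Youden's J = sensitivity + specificity - 1,
#' trying both directions (outcome-positive above or below the threshold).
#' Ties are broken toward the lower threshold. The alternative
#' closest-to-corner criterion minimizes the distance to (0, 1) in ROC
#' space.
#'
#' @param values numeric marker values.
#' @param outcome logical (or 0/1) outcome, both classes present.
#' @param criterion `"youden"` (default) or `"closest"`.
#' @return Tibble: `threshold`, `direction` (`">"` means positive class
#'   above), `criterion`, `sensitivity`, `specificity`, `auc`.
#' @export
roc_cutoff <- function(values, outcome, criterion = c("youden", "closest")) {
  criterion <- match.arg(criterion)
  outcome <- as.logical(outcome)
  ok <- !is.na(values) & !is.na(outcome)
  values <- values[ok]; outcome <- outcome[ok]
  if (length(unique(outcome)) < 2) stop("both outcome classes must be present")
  u <- sort(unique(values))
  thr <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else u
  n1 <- sum(outcome); n0 <- sum(!outcome)
  eval_dir <- function(t, dir) {
    pos <- if (dir == ">") values > t else values < t
    sens <- sum(pos & outcome) / n1
    spec <- sum(!pos & !outcome) / n0
    j <- switch(criterion, youden = sens + spec - 1,
                closest = -sqrt((1 - sens)^2 + (1 - spec)^2))
    c(j = j, sens = sens, spec = spec)
  }
  grid <- expand.grid(t = thr, dir = c(">", "<"), stringsAsFactors = FALSE)
  m <- t(mapply(eval_dir, grid$t, grid$dir))
  # best J; ties -> lower threshold, ">" direction first
  ord <- order(-m[, "j"], grid$t, grid$dir)
  best <- ord[1]
  auc <- {
    r <- rank(values)
    (sum(r[outcome]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  tibble::tibble(threshold = grid$t[best], direction = grid$dir[best],
                 criterion = unname(m[best, "j"]),
                 sensitivity = unname(m[best, "sens"]),
                 specificity = unname(m[best, "spec"]),
                 auc = auc)
}

#' Kaplan-Meier curves and log-rank test by stratum
#'
#' Product-limit estimate per stratum ([survival::survfit()]) and the
#' log-rank test ([survival::survdiff()]). Optionally a permutation p-value
#' (stratum labels permuted) to correct for optimized-cutpoint selection
#' when the labels come from [roc_cutoff()]-style dichotomization.
#'
#' @param time,event survival times (months) and event indicators.
#' @param stratum group labels (>= 1 subject per stratum, >= 2 strata).
#' @param permutation_p number of permutations (0 = none).
#' @return Object of class `km_result`: `fit`, `curves` tibble, `chisq`,
#'   `df`, `p`, optional `p_perm`.
#' @export
km_logrank <- function(time, event, stratum, permutation_p = 0) {
  stratum <- as.factor(droplevels(as.factor(stratum)))
  if (nlevels(stratum) < 2) stop("need at least two non-empty strata")
  if (sum(event) < 1) stop("need at least one event")
  df <- data.frame(time = time, event = as.integer(event), stratum = stratum)
  fit <- survival::survfit(survival::Surv(time, event) ~ stratum, data = df)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ stratum, data = df)
  p <- stats::pchisq(sd_$chisq, length(sd_$n) - 1, lower.tail = FALSE)
  curves <- tibble::tibble(
    stratum = rep(sub("^stratum=", "", names(fit$strata)), fit$strata),
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    surv = fit$surv, lower = fit$lower, upper = fit$upper)
  p_perm <- NA_real_
  if (permutation_p > 0) {
    obs <- sd_$chisq
    stat <- replicate(permutation_p, {
      df$stratum <- sample(df$stratum)
      survival::survdiff(survival::Surv(time, event) ~ stratum, data = df)$chisq
    })
    p_perm <- (1 + sum(stat >= obs)) / (1 + permutation_p)
  }
  structure(list(fit = fit, curves = curves, chisq = unname(sd_$chisq),
                 df = length(sd_$n) - 1, p = p, p_perm = p_perm),
            class = "km_result")
}

#' @export
print.km_result <- function(x, ...) {
  cat(sprintf("<km_result> log-rank chisq = %.3f (df %d), p = %.4g%s\n",
              x$chisq, x$df, x$p,
              if (!is.na(x$p_perm)) sprintf(", permutation p = %.4g", x$p_perm) else ""))
  invisible(x)
}

#' Multivariate Cox proportional-hazards model
#'
#' Partial-likelihood fit with Efron tie handling via
#' [survival::coxph()]. Refuses under-determined designs (events must
#' exceed the number of covariates) and rank-deficient (collinear)
#' covariate matrices; convergence diagnostics are recorded rather than
#' silently dropped.
#'
#' @param data data frame holding time, event and covariates.
#' @param time,event column names.
#' @param covariates character vector of covariate column names.
#' @return Object of class `cox_result`: `fit`, `coefficients` tibble
#'   (coef, HR, se, z, p, confidence bounds), `converged`, `n`, `n_events`.
#' @export
cox_multivariate <- function(data, time = "dfs_months", event = "dfs_event",
                             covariates) {
  stopifnot(length(covariates) >= 1)
  d <- data[stats::complete.cases(data[c(time, event, covariates)]), , drop = FALSE]
  n_events <- sum(as.integer(d[[event]]))
  if (n_events < length(covariates) + 1)
    stop("too few events (", n_events, ") for ", length(covariates), " covariates")
  X <- stats::model.matrix(
    stats::reformulate(covariates), data = d)[, -1, drop = FALSE]
  if (qr(X)$rank < ncol(X))
    stop("collinear covariates: design matrix is rank-deficient")
  fml <- stats::reformulate(covariates,
    response = sprintf("survival::Surv(%s, %s)", time, event))
  fit <- survival::coxph(fml, data = d, ties = "efron")
  s <- summary(fit)
  coefs <- tibble::tibble(
    term = rownames(s$coefficients),
    estimate = s$coefficients[, "coef"],
    hr = s$coefficients[, "exp(coef)"],
    std_error = s$coefficients[, "se(coef)"],
    statistic = s$coefficients[, "z"],
    p_value = s$coefficients[, "Pr(>|z|)"],
    hr_low = s$conf.int[, "lower .95"],
    hr_high = s$conf.int[, "upper .95"])
  structure(list(fit = fit, coefficients = coefs,
                 converged = fit$iter < survival::coxph.control()$iter.max,
                 n = s$n, n_events = n_events),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("<cox_result> n = %d, events = %d, converged: %s\n",
              x$n, x$n_events, x$converged))
  print(as.data.frame(x$coefficients), digits = 3)
  invisible(x)
}

#' Subset a cohort to advanced stages (IIB and III)
#'
#' @param clinical data frame with a `stage` column (substage strings such
#'   as `"IIB"`, `"IIIA"`).
#' @param stages stages retained (default IIB and all III substages).
#' @return The retained rows; rows with missing stage are dropped with a
#'   warning.
#' @export
stage_subset <- function(clinical, stages = c("IIB", "IIIA", "IIIB", "IIIC")) {
  miss <- is.na(clinical$stage)
  if (any(miss)) warning(sum(miss), " patients with missing stage excluded")
  out <- clinical[!miss & clinical$stage %in% stages, , drop = FALSE]
  if (nrow(out) == 0) stop("stage subset is empty")
  tibble::as_tibble(out)
}

#' Dichotomize a parameter at its ROC cutoff (or a fixed cutoff)
#'
#' @param values numeric vector.
#' @param cutoff a [roc_cutoff()] row or a single number (high = above).
#' @return Factor with levels `low`, `high`.
#' @export
dichotomize <- function(values, cutoff) {
  if (is.data.frame(cutoff)) {
    thr <- cutoff$threshold
    high_above <- cutoff$direction == ">"
  } else {
    thr <- cutoff; high_above <- TRUE
  }
  lab <- if (high_above) values > thr else values < thr
  factor(ifelse(lab, "high", "low"), levels = c("low", "high"))
}

# --- broom-style methods ---------------------------------------------------

#' Tidy a Cox result
#' @param x a `cox_result`.
#' @param ... unused.
#' @return Per-covariate tibble of estimates.
#' @export
tidy.cox_result <- function(x, ...) x$coefficients

#' One-row summary of a Cox result
#' @param x a `cox_result`.
#' @param ... unused.
#' @export
glance.cox_result <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events, converged = x$converged,
                 logLik = as.numeric(stats::logLik(x$fit)),
                 concordance = unname(summary(x$fit)$concordance[1]))
}

#' Tidy a Kaplan-Meier result (the per-stratum curves)
#' @param x a `km_result`.
#' @param ... unused.
#' @export
tidy.km_result <- function(x, ...) x$curves

#' One-row summary of a Kaplan-Meier / log-rank result
#' @param x a `km_result`.
#' @param ... unused.
#' @export
glance.km_result <- function(x, ...) {
  tibble::tibble(chisq = x$chisq, df = x$df, p = x$p, p_perm = x$p_perm)
}
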