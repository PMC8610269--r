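# Comparison and survival statistics. All tests are two-sided; missing
# values are removed per analysis and the post-removal group sizes are
# reported. Thin, uniform wrappers over stats:: and survival:: so every
# result carries the same fields (statistic, p_value, n_per_group, method,
# group summaries).

new_test_result <- function(statistic, p_value, n_per_group, method,
                            group_summaries = NULL, note = NULL) {
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 n_per_group = n_per_group, method = method,
                 group_summaries = group_summaries, note = note),
            class = "cav_test_result")
}

#' @export
print.cav_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %s, p = %s (n = %s)\n", x$method,
              format(x$statistic), format.pval(x$p_value),
              paste(x$n_per_group, collapse = "/")))
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

group_summary <- function(values, group) {
  do.call(rbind, lapply(split(values, group), function(v) {
    data.frame(n = length(v), mean = mean(v), median = stats::median(v),
               sd = stats::sd(v))
  }))
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided comparison of two groups; exact null distribution for small,
#' tie-free samples, normal approximation with tie correction otherwise
#' (the `stats::wilcox.test` convention).
#'
#' @param x,y Numeric values for the two groups (missing values dropped).
#' @return A `cav_test_result`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 1 || length(y) < 1)
    stop("each group needs at least one non-missing value", call. = FALSE)
  wt <- suppressWarnings(stats::wilcox.test(x, y))
  new_test_result(wt$statistic, wt$p.value, c(length(x), length(y)),
                  "Wilcoxon rank-sum",
                  group_summary(c(x, y), rep(c("x", "y"),
                                             c(length(x), length(y)))))
}

#' Kruskal-Wallis rank test for three or more groups
#'
#' Chi-square approximation with tie correction. With fewer than three
#' groups the caller is directed to the rank-sum test.
#'
#' @param groups List of numeric vectors (>= 3 groups, each with >= 1
#'   non-missing value).
#' @return A `cav_test_result`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 3)
    stop("fewer than 3 groups: use wilcoxon_rank_sum()", call. = FALSE)
  if (any(lengths(groups) < 1))
    stop("every group needs at least one non-missing value", call. = FALSE)
  kt <- stats::kruskal.test(groups)
  values <- unlist(groups)
  labels <- rep(seq_along(groups), lengths(groups))
  new_test_result(kt$statistic, kt$p.value, lengths(groups),
                  "Kruskal-Wallis", group_summary(values, labels))
}

#' Mean-difference tests: one-sample t, two-sample t, or one-way ANOVA
#'
#' With `deltas` supplied, a one-sample t-test of mean zero on paired
#' differences (e.g. stroma minus epithelium per subject). With `groups`, a
#' two-sample Student t-test for 2 groups or one-way ANOVA for more. Zero
#' variance with n > 1 yields `p = NA` with a warning rather than an error.
#'
#' @param deltas Paired differences (one-sample mode).
#' @param groups List of numeric vectors (two-sample / ANOVA mode).
#' @param var_equal Two-sample mode: assume equal variances (classical
#'   Student test, the default).
#' @return A `cav_test_result`.
#' @export
mean_difference_test <- function(deltas = NULL, groups = NULL,
                                 var_equal = TRUE) {
  if (!is.null(deltas)) {
    deltas <- deltas[!is.na(deltas)]
    if (length(deltas) < 2)
      stop("need at least 2 non-missing paired differences", call. = FALSE)
    if (stats::sd(deltas) == 0) {
      if (all(deltas == 0)) {
        # all differences identically zero: t = 0 by convention, p = 1
        return(new_test_result(0, 1, length(deltas), "one-sample t",
                               note = "all differences zero"))
      }
      warning("zero variance in differences; p undefined", call. = FALSE)
      return(new_test_result(NA_real_, NA_real_, length(deltas),
                             "one-sample t", note = "zero variance"))
    }
    tt <- stats::t.test(deltas)
    return(new_test_result(tt$statistic, tt$p.value, length(deltas),
                           "one-sample t",
                           group_summary(deltas, rep("delta",
                                                     length(deltas)))))
  }
  if (is.null(groups)) stop("supply deltas or groups", call. = FALSE)
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (any(lengths(groups) < 2))
    stop("each group needs n >= 2", call. = FALSE)
  values <- unlist(groups)
  labels <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(groups) == 2) {
    if (stats::sd(groups[[1]]) == 0 && stats::sd(groups[[2]]) == 0) {
      warning("zero variance in both groups; p undefined", call. = FALSE)
      return(new_test_result(NA_real_, NA_real_, lengths(groups),
                             "two-sample t", note = "zero variance"))
    }
    tt <- stats::t.test(groups[[1]], groups[[2]], var.equal = var_equal)
    return(new_test_result(tt$statistic, tt$p.value, lengths(groups),
                           "two-sample t", group_summary(values, labels)))
  }
  fit <- stats::aov(values ~ labels)
  s <- summary(fit)[[1]]
  new_test_result(s[["F value"]][1], s[["Pr(>F)"]][1], lengths(groups),
                  "one-way ANOVA", group_summary(values, labels))
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y Paired numeric vectors; pairs with a missing member are
#'   dropped. Needs >= 3 complete pairs.
#' @return List with `r`, `r2`, `p_value`, `n`; `r` is `NA` (flagged via
#'   `note`) when either variable has zero variance.
#' @export
pearson_correlation <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3)
    stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, r2 = NA_real_, p_value = NA_real_,
                n = length(x), note = "zero variance"))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), r2 = unname(ct$estimate)^2,
       p_value = ct$p.value, n = length(x), note = NULL)
}

#' Kaplan-Meier fit with optional log-rank group comparison
#'
#' Product-limit survival estimate; the reported median survival is the
#' smallest time at which the estimated survival drops to 0.5 or below
#' (`NA`, "not reached", if it never does). With a grouping factor of >= 2
#' levels, a log-rank test across groups is included.
#'
#' @param times Follow-up times (months), >= 0.
#' @param events 1 = event (death), 0 = censored.
#' @param groups Optional grouping vector.
#' @return Object of class `survival_fit`: the `survfit` object, per-group
#'   `medians`, `logrank_chi2`, `logrank_p`, `n_per_group`.
#' @export
km_fit <- function(times, events, groups = NULL) {
  ok <- !is.na(times) & !is.na(events)
  if (!is.null(groups)) ok <- ok & !is.na(groups)
  times <- times[ok]; events <- events[ok]
  if (any(times < 0)) stop("times must be >= 0", call. = FALSE)
  # median = smallest t with S(t) <= 0.5 (NA if the curve never reaches it)
  median_from_curve <- function(time, surv) {
    idx <- which(surv <= 0.5 + 1e-12)
    if (!length(idx)) NA_real_ else time[min(idx)]
  }
  if (is.null(groups)) {
    fit <- survival::survfit(survival::Surv(times, events) ~ 1)
    medians <- c(overall = median_from_curve(fit$time, fit$surv))
    lr_chi2 <- lr_p <- NA_real_
    n <- length(times)
  } else {
    groups <- factor(groups[ok])
    fit <- survival::survfit(survival::Surv(times, events) ~ groups)
    if (is.null(fit$strata)) {
      medians <- stats::setNames(median_from_curve(fit$time, fit$surv),
                                 levels(groups)[1])
    } else {
      idx <- rep(seq_along(fit$strata), fit$strata)
      medians <- vapply(seq_along(fit$strata), function(i)
        median_from_curve(fit$time[idx == i], fit$surv[idx == i]),
        numeric(1))
      names(medians) <- sub("^groups=", "", names(fit$strata))
    }
    if (nlevels(groups) >= 2 && sum(events) > 0) {
      sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
      lr_chi2 <- sd$chisq
      lr_p <- stats::pchisq(sd$chisq, df = nlevels(groups) - 1,
                            lower.tail = FALSE)
    } else {
      lr_chi2 <- lr_p <- NA_real_
    }
    n <- table(groups)
  }
  structure(list(survfit = fit, medians = medians, logrank_chi2 = lr_chi2,
                 logrank_p = lr_p, n_per_group = n),
            class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  med <- paste(sprintf("%s: %s", names(x$medians),
                       ifelse(is.na(x$medians), "not reached",
                              format(round(x$medians, 1)))),
               collapse = ", ")
  cat("Kaplan-Meier median survival (months):", med, "\n")
  if (!is.na(x$logrank_p))
    cat(sprintf("log-rank chi2 = %.3f, p = %s\n", x$logrank_chi2,
                format.pval(x$logrank_p)))
  invisible(x)
}

#' Cox proportional-hazards regression
#'
#' Partial-likelihood fit with Efron tie handling; hazard ratios with Wald
#' 95% confidence intervals and p-values per covariate. Monotone likelihood
#' (perfect separation by a covariate) is flagged as non-convergence rather
#' than silently returned.
#'
#' @param times,events Survival outcome as in [km_fit()].
#' @param covariates Data frame of covariates (rows with missing values are
#'   removed listwise).
#' @param ties Tie-handling method, `"efron"` (default) or `"breslow"`.
#' @return Object of class `cox_fit`: `coef` table (`coef`, `hr`, `ci_low`,
#'   `ci_high`, `p_value`), `n`, `n_events`, `converged`, and the `coxph`
#'   fit.
#' @export
cox_fit <- function(times, events, covariates,
                    ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  covariates <- as.data.frame(covariates)
  dat <- cbind(data.frame(.time = times, .event = events), covariates)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (sum(dat$.event) < 1) stop("no events after missing-data removal",
                                call. = FALSE)
  fit <- tryCatch(
    survival::coxph(survival::Surv(.time, .event) ~ ., data = dat,
                    ties = ties),
    warning = function(w) {
      f <- suppressWarnings(
        survival::coxph(survival::Surv(.time, .event) ~ ., data = dat,
                        ties = ties))
      attr(f, "cav_warning") <- conditionMessage(w)
      f
    })
  sm <- summary(fit)
  warn <- attr(fit, "cav_warning")
  separated <- !is.null(warn) &&
    grepl("infinite|converge|beta may be infinite", warn, ignore.case = TRUE)
  coefs <- data.frame(term = rownames(sm$coefficients),
                      coef = sm$coefficients[, "coef"],
                      hr = sm$conf.int[, "exp(coef)"],
                      ci_low = sm$conf.int[, "lower .95"],
                      ci_high = sm$conf.int[, "upper .95"],
                      p_value = sm$coefficients[, "Pr(>|z|)"],
                      row.names = NULL)
  structure(list(coef = coefs, n = sm$n, n_events = sm$nevent,
                 converged = !separated, note = warn, coxph = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox PH (Efron ties), n = %d, events = %d%s\n", x$n,
              x$n_events, if (x$converged) "" else " [NOT CONVERGED]"))
  print(within(x$coef, {
    hr <- round(hr, 3); ci_low <- round(ci_low, 3)
    ci_high <- round(ci_high, 3); coef <- round(coef, 3)
  }))
  invisible(x)
}

#' Logistic regression of response class on covariates
#'
#' Maximum-likelihood fit; odds ratios with Wald 95% confidence intervals.
#' Complete or quasi-complete separation is flagged (`converged = FALSE`).
#'
#' @param response Binary outcome: logical, 0/1, or a two-level factor /
#'   character (e.g. `"CR"`/`"IR"`; the *second* sorted level is the
#'   modelled event).
#' @param covariates Data frame of covariates (listwise deletion).
#' @return Object of class `logistic_fit`: `coef` table (`coef`, `or`,
#'   `ci_low`, `ci_high`, `p_value`), `n`, `converged`, and the `glm` fit.
#' @export
logistic_fit <- function(response, covariates) {
  covariates <- as.data.frame(covariates)
  if (is.character(response) || is.factor(response)) {
    response <- factor(response)
    if (nlevels(response) != 2)
      stop("response must have exactly two classes", call. = FALSE)
    response <- as.integer(response) - 1L
  }
  dat <- cbind(data.frame(.y = as.numeric(response)), covariates)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (length(unique(dat$.y)) < 2)
    stop("both outcome classes must be present", call. = FALSE)
  warned <- NULL
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = dat, family = stats::binomial()),
    warning = function(w) {
      warned <<- conditionMessage(w)
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)
  est <- sm$coefficients
  # separation shows up as a glm warning, non-convergence, or coefficients
  # drifting to +-infinity with exploding Wald standard errors
  separated <- (!is.null(warned) &&
                  grepl("fitted probabilities numerically 0 or 1", warned)) ||
    !fit$converged || any(abs(est[, "Estimate"]) > 15) ||
    any(est[, "Std. Error"] > 50)
  coefs <- data.frame(term = rownames(est), coef = est[, "Estimate"],
                      or = exp(est[, "Estimate"]),
                      ci_low = exp(est[, "Estimate"] -
                                     1.959964 * est[, "Std. Error"]),
                      ci_high = exp(est[, "Estimate"] +
                                      1.959964 * est[, "Std. Error"]),
                      p_value = est[, "Pr(>|z|)"], row.names = NULL)
  structure(list(coef = coefs, n = nrow(dat), converged = !separated,
                 note = warned, glm = fit),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("logistic regression, n = %d%s\n", x$n,
              if (x$converged) "" else " [SEPARATION FLAGGED]"))
  print(within(x$coef, {
    or <- round(or, 3); ci_low <- round(ci_low, 3)
    ci_high <- round(ci_high, 3); coef <- round(coef, 3)
  }))
  invisible(x)
}
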