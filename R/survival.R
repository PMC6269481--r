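#' Kaplan-Meier product-limit estimate
#'
#' Estimates the survival function from right-censored follow-up via the
#' product-limit estimator \eqn{\hat S(t) = \prod_{t_i \le t} (1 - d_i/n_i)}
#' over the distinct event times, with Greenwood's variance.  Subjects
#' censored exactly at an event time remain in the risk set at that time
#' (the standard convention).  Fitting is delegated to
#' [survival::survfit()]; this container keeps only the event times plus
#' the quantities the downstream readouts need.
#'
#' @param times Nonnegative follow-up times (years).
#' @param events Event indicator per subject (1 = event, 0 = censored).
#' @return An object of class `km_curve`: list with `event_times`,
#'   `at_risk`, `events`, `survival`, `greenwood_var` (variance of
#'   \eqn{\hat S}), `var_log_surv` (cumulative \eqn{\sum d/(n(n-d))}, used
#'   for log-log intervals), `n`, and `max_followup`.
#' @examples
#' km <- km_estimate(c(1, 2, 3), c(1, 0, 1))
#' km$survival  # 2/3 at t=1, 0 at t=3
#' @export
km_estimate <- function(times, events) {
  times <- as.numeric(times)
  events <- as.integer(events)
  if (length(times) != length(events) || !length(times))
    stop("times and events must be equal-length, nonempty vectors")
  if (any(!is.finite(times)) || any(times < 0))
    stop("negative or non-finite survival time")
  if (!all(events %in% c(0L, 1L))) stop("events must be 0 or 1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  keep <- fit$n.event > 0
  surv <- fit$surv[keep]
  # survfit std.err is the SE of log S(t) (Greenwood accumulated on the
  # log scale); S^2 * se^2 recovers Greenwood's variance of S itself
  var_log <- fit$std.err[keep]^2
  structure(list(event_times = fit$time[keep],
                 at_risk = fit$n.risk[keep],
                 events = fit$n.event[keep],
                 survival = surv,
                 greenwood_var = surv^2 * var_log,
                 var_log_surv = var_log,
                 n = length(times),
                 max_followup = max(times)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, %d event times, S(last event) = %.3f\n",
              x$n, length(x$event_times),
              if (length(x$survival)) x$survival[length(x$survival)] else 1))
  invisible(x)
}

#' Read the survival probability off a KM curve
#'
#' Step-function evaluation of \eqn{\hat S(t)} with a log-log (complementary
#' log-log) Greenwood confidence interval, which respects the \[0, 1\]
#' range and gives the asymmetric intervals usual for survival fractions.
#' At times where the estimate is exactly 1 or 0 the transform is
#' undefined and the interval degenerates to the point estimate.
#'
#' @param curve A `km_curve`.
#' @param t Time at which to evaluate (same units as the fit).
#' @param conf Confidence level (default 0.95).
#' @return List with `estimate`, `lower`, `upper`, and `extrapolated`
#'   (`TRUE` when `t` exceeds the last observed follow-up, with a warning).
#' @export
survival_at <- function(curve, t, conf = 0.95) {
  stopifnot(inherits(curve, "km_curve"), is.numeric(t), length(t) == 1L)
  if (!is.finite(t) || t < 0) stop("evaluation time must be a nonnegative number")
  stopifnot(conf > 0, conf < 1)
  extrapolated <- t > curve$max_followup
  if (extrapolated)
    warning("evaluation time ", t, " exceeds the last follow-up (",
            curve$max_followup, "); estimate carried forward")
  idx <- which(curve$event_times <= t)
  if (!length(idx))
    return(list(estimate = 1, lower = 1, upper = 1, extrapolated = extrapolated))
  i <- max(idx)
  s <- curve$survival[i]
  if (s <= 0 || s >= 1)
    return(list(estimate = s, lower = s, upper = s, extrapolated = extrapolated))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  se_loglog <- sqrt(curve$var_log_surv[i]) / abs(log(s))
  lower <- s^exp(z * se_loglog)
  upper <- s^exp(-z * se_loglog)
  list(estimate = s,
       lower = max(0, min(1, lower)),
       upper = max(0, min(1, upper)),
       extrapolated = extrapolated)
}

#' Two-group log-rank test
#'
#' Compares event patterns between two groups by summing observed minus
#' hypergeometric-expected events over the distinct event times, with the
#' standard variance (tie-corrected); the statistic is chi-square with 1
#' degree of freedom.  Computation is delegated to
#' [survival::survdiff()].
#'
#' @param times Nonnegative follow-up times.
#' @param events Event indicator (0/1).
#' @param groups Two-level grouping (factor, character or binary), both
#'   levels nonempty.
#' @return An object of class `logrank_result`: list with `chi2`, `df`,
#'   `p`, `observed` and `expected` (named per group).
#' @export
logrank_test <- function(times, events, groups) {
  times <- as.numeric(times)
  events <- as.integer(events)
  g <- factor(groups)
  if (length(unique(stats::na.omit(g))) != 2L)
    stop("log-rank comparison requires exactly 2 nonempty groups")
  if (length(times) != length(events) || length(times) != length(g))
    stop("times, events and groups must have equal length")
  if (any(!is.finite(times)) || any(times < 0)) stop("negative survival time")
  if (!all(events %in% c(0L, 1L))) stop("events must be 0 or 1")
  if (sum(events) == 0L) stop("no events observed; log-rank test undefined")
  fit <- survival::survdiff(survival::Surv(times, events) ~ g)
  chi2 <- unname(fit$chisq)
  obs <- fit$obs
  expd <- fit$exp
  names(obs) <- names(expd) <- levels(g)
  structure(list(chi2 = chi2, df = 1L,
                 p = stats::pchisq(chi2, df = 1L, lower.tail = FALSE),
                 observed = obs, expected = expd),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank test: chi2 = %.4g on %d df, p = %.4g\n",
              x$chi2, x$df, x$p))
  invisible(x)
}

#' Restrict a cohort to subjects with resolved outcome
#'
#' Logistic modelling of death-of-disease needs a binary outcome, which
#' censored short-followup subjects do not provide.  This keeps subjects
#' who died (outcome 1) or survived event-free for at least `min_followup`
#' years (outcome 0) and drops censored subjects with shorter follow-up.
#'
#' @param clinical Validated clinical `data.frame`.
#' @param min_followup Minimum event-free follow-up (years) for survivors
#'   (default 3).
#' @return List with `outcome` (named 0/1 integer vector) and `sample_ids`
#'   (the kept samples).
#' @export
restrict_outcome_subset <- function(clinical, min_followup = 3) {
  validate_clinical_table(clinical)
  keep <- clinical$os_event == 1L |
    (clinical$os_event == 0L & clinical$os_time >= min_followup)
  if (!any(keep))
    stop("no subject died or reached ", min_followup, " years of follow-up")
  outcome <- clinical$os_event[keep]
  names(outcome) <- clinical$sample_id[keep]
  list(outcome = outcome, sample_ids = clinical$sample_id[keep])
}

#' Multivariate logistic regression with Wald inference
#'
#' Maximum-likelihood logistic fit of a binary outcome on one or more
#' covariates (IRLS, convergence tolerance 1e-8, at most 100 iterations),
#' reporting per-covariate odds ratios and Wald p-values.  Rows with
#' missing covariates are excluded and counted.  Quasi-complete separation
#' is flagged rather than silently reported: a fit where any standardized
#' coefficient exceeds 15 in absolute value (or where the IRLS did not
#' converge) is returned with `converged = FALSE` and a warning.
#'
#' @param outcome Binary (0/1) outcome vector.
#' @param covariates `data.frame` (or named list) of numeric/binary
#'   covariate columns, same length as `outcome`.
#' @return An object of class `logistic_fit`: list with `coefficients`,
#'   `odds_ratio`, `p` (Wald), `se`, `n_used`, `n_excluded`, `converged`,
#'   `separation`.
#' @export
multivariate_logistic <- function(outcome, covariates) {
  outcome <- as.integer(outcome)
  if (!all(stats::na.omit(outcome) %in% c(0L, 1L)))
    stop("outcome must be binary 0/1")
  covariates <- as.data.frame(covariates)
  if (!ncol(covariates)) stop("at least one covariate is required")
  if (nrow(covariates) != length(outcome))
    stop("outcome and covariates have different lengths")
  dat <- cbind(data.frame(.y = outcome), covariates)
  cc <- stats::complete.cases(dat)
  n_excluded <- sum(!cc)
  dat <- dat[cc, , drop = FALSE]
  if (length(unique(dat$.y)) < 2L)
    stop("outcome has a single class after exclusions; logistic fit undefined")
  const <- names(covariates)[vapply(dat[-1L], function(v) length(unique(v)) < 2L, TRUE)]
  if (length(const))
    stop("constant covariate(s): ", paste(const, collapse = ", "))
  fit <- suppressWarnings(stats::glm(
    .y ~ ., family = stats::binomial(), data = dat,
    control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  sm <- summary(fit)$coefficients
  coefs <- sm[, "Estimate"]
  covariate_sd <- vapply(dat[-1L], stats::sd, 0)
  std_coef <- coefs[-1L] * covariate_sd[names(coefs)[-1L]]
  separation <- any(abs(std_coef) > 15) || !fit$converged
  if (separation)
    warning("possible complete separation: standardized coefficient beyond 15; ",
            "estimates unreliable")
  structure(list(coefficients = coefs,
                 odds_ratio = exp(coefs),
                 se = sm[, "Std. Error"],
                 p = sm[, "Pr(>|z|)"],
                 n_used = nrow(dat),
                 n_excluded = n_excluded,
                 converged = fit$converged && !separation,
                 separation = separation),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic fit on %d subjects (%d excluded)%s\n", x$n_used,
              x$n_excluded,
              if (!x$converged) " [NOT CONVERGED / SEPARATION]" else ""))
  tab <- data.frame(coef = x$coefficients, OR = x$odds_ratio, p = x$p)
  print(round(tab, 4))
  invisible(x)
}

#' Score-group survival report
#'
#' Convenience wrapper reproducing the standard survival readout for a
#' median-dichotomized cohort: per-group KM curves, the log-rank
#' comparison, survival at a landmark time with confidence interval, and
#' (when covariates are supplied) the outcome-restricted multivariate
#' logistic fit with the score entered either dichotomized (high vs low)
#' or continuous.
#'
#' @param scores `score_vector` or named numeric scores.
#' @param clinical Validated clinical table covering the scored samples.
#' @param landmark_time Landmark for the survival readout (default 5 years).
#' @param covariates Character vector of clinical covariate columns to
#'   adjust for (subset of `mycn_amplified`, `stage4`, `age_ge_1y`), or
#'   `NULL` to skip the logistic stage.
#' @param score_form `"dichotomized"` (default) enters the score as the
#'   high-group indicator; `"continuous"` enters the raw score.
#' @param min_followup Survivor follow-up floor for the outcome-restricted
#'   subset (years).
#' @return List with `groups`, `km` (per-group `km_curve`), `logrank`,
#'   `landmark` (per-group survival at the landmark), and `logistic`
#'   (or `NULL`).
#' @export
survival_report <- function(scores, clinical, landmark_time = 5,
                            covariates = NULL,
                            score_form = c("dichotomized", "continuous"),
                            min_followup = 3) {
  score_form <- match.arg(score_form)
  validate_clinical_table(clinical)
  s <- if (inherits(scores, "score_vector")) scores$score else scores
  common <- intersect(names(s), clinical$sample_id)
  if (length(common) < 4L)
    stop("need at least 4 samples common to scores and clinical table")
  s <- s[common]
  clin <- clinical[match(common, clinical$sample_id), ]
  groups <- dichotomize_by_median(s)
  km <- lapply(stats::setNames(levels(groups$label), levels(groups$label)),
               function(lv) {
    sel <- groups$label == lv
    km_estimate(clin$os_time[sel], clin$os_event[sel])
  })
  lr <- logrank_test(clin$os_time, clin$os_event, groups$label)
  landmark <- lapply(km, survival_at, t = landmark_time)
  logistic <- NULL
  if (!is.null(covariates)) {
    covariates <- match.arg(covariates,
                            c("mycn_amplified", "stage4", "age_ge_1y"),
                            several.ok = TRUE)
    sub <- restrict_outcome_subset(clin, min_followup = min_followup)
    idx <- match(sub$sample_ids, clin$sample_id)
    score_col <- if (score_form == "dichotomized")
      as.integer(groups$label[idx] == "high") else unname(s[idx])
    covs <- cbind(data.frame(score = score_col),
                  clin[idx, covariates, drop = FALSE])
    logistic <- multivariate_logistic(sub$outcome, covs)
  }
  list(groups = groups, km = km, logrank = lr, landmark = landmark,
       logistic = logistic)
}
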