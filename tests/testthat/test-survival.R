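test_that("product-limit estimate matches hand-computed toys", {
  one <- km_estimate(5, 1)
  expect_equal(one$event_times, 5)
  expect_equal(one$survival, 0)

  cens <- km_estimate(c(2, 4, 6), c(0, 0, 0))
  expect_length(cens$event_times, 0)
  expect_equal(survival_at(cens, 5)$estimate, 1)

  # (1 event, 2 censored, 3 event): S(1) = 2/3, S(3) = (2/3) * (1 - 1/1) = 0
  toy <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(toy$event_times, c(1, 3))
  expect_equal(toy$survival, c(2 / 3, 0))
  expect_equal(toy$at_risk, c(3, 1))
})

test_that("without censoring the KM estimate equals the empirical survivor function", {
  set.seed(19)
  times <- rexp(40, 0.3)
  km <- km_estimate(times, rep(1, 40))
  for (t in c(0.5, 1, 2, 5)) {
    expect_equal(survival_at(km, t)$estimate, mean(times > t))
  }
})

test_that("landmark survival uses log-log Greenwood intervals and flags extrapolation", {
  toy <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  at0 <- survival_at(toy, 0)
  expect_equal(unlist(at0[c("estimate", "lower", "upper")]),
               c(estimate = 1, lower = 1, upper = 1))
  expect_equal(survival_at(toy, 0.5)$estimate, 1)

  at2 <- survival_at(toy, 2)
  expect_equal(at2$estimate, 2 / 3)
  # closed-form Greenwood at t in [1, 3): var(log S) = 1/(3*2)
  s <- 2 / 3
  se_ll <- sqrt(1 / 6) / abs(log(s))
  z <- qnorm(0.975)
  expect_equal(at2$lower, s^exp(z * se_ll))
  expect_equal(at2$upper, s^exp(-z * se_ll))
  expect_true(at2$lower < s && s < at2$upper)

  expect_warning(far <- survival_at(toy, 99), "exceeds the last follow-up")
  expect_true(far$extrapolated)
})

test_that("log-rank test matches the brute-force hypergeometric tables", {
  # identical groups: no evidence at all
  times <- c(1, 2, 3, 4, 5)
  events <- c(1, 0, 1, 1, 0)
  same <- logrank_test(c(times, times), c(events, events),
                       rep(c("a", "b"), each = 5))
  expect_equal(same$chi2, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)

  # complete separation in time between the groups
  t2 <- c(rep(1, 5), rep(10, 5))
  e2 <- rep(1, 10)
  g2 <- rep(c("A", "B"), each = 5)
  lr <- logrank_test(t2, e2, g2)
  expect_equal(lr$chi2, oracle_logrank_chi2(t2, e2, g2), tolerance = 1e-8)
  expect_equal(sum(lr$observed), sum(e2))

  set.seed(27)
  for (i in 1:15) {
    n <- sample(10:40, 1)
    tt <- sample(1:8, n, replace = TRUE)  # heavy ties on purpose
    ee <- rbinom(n, 1, 0.7)
    gg <- rep(c("x", "y"), length.out = n)
    if (sum(ee) == 0) next
    expect_equal(logrank_test(tt, ee, gg)$chi2,
                 oracle_logrank_chi2(tt, ee, gg), tolerance = 1e-8)
  }
})

test_that("log-rank statistic is invariant to label swaps and monotone time transforms", {
  set.seed(31)
  tt <- rexp(30, 0.2)
  ee <- rbinom(30, 1, 0.6)
  gg <- rep(c("a", "b"), 15)
  base <- logrank_test(tt, ee, gg)
  swapped <- logrank_test(tt, ee, ifelse(gg == "a", "b", "a"))
  expect_equal(swapped$chi2, base$chi2)
  warped <- logrank_test(log1p(tt) * 7, ee, gg)
  expect_equal(warped$chi2, base$chi2)
})

test_that("log-rank p-values are uniform under random relabeling of a null cohort", {
  set.seed(77)
  tt <- rexp(40, 0.2)
  ee <- rbinom(40, 1, 0.7)
  ps <- replicate(1000, {
    logrank_test(tt, ee, sample(rep(c("a", "b"), 20)))$p
  })
  expect_lt(suppressWarnings(ks.test(ps, "punif"))$statistic, 0.05)
})

test_that("outcome restriction keeps deaths and long-term survivors only", {
  clin <- data.frame(
    sample_id = c("early_cens", "dead_1y", "alive_5y"),
    os_time = c(2, 1, 5), os_event = c(0L, 1L, 0L),
    mycn_amplified = NA_integer_, stage4 = NA_integer_,
    age_ge_1y = NA_integer_)
  sub <- restrict_outcome_subset(clin, min_followup = 3)
  expect_setequal(sub$sample_ids, c("dead_1y", "alive_5y"))
  expect_equal(sub$outcome[["dead_1y"]], 1L)
  expect_equal(sub$outcome[["alive_5y"]], 0L)

  none <- clin[1, ]
  expect_error(restrict_outcome_subset(none), "no subject")
})

test_that("logistic fit reproduces the closed-form 2x2 odds ratio", {
  set.seed(41)
  x <- rbinom(300, 1, 0.5)
  y <- rbinom(300, 1, plogis(-0.5 + 1.2 * x))
  fit <- multivariate_logistic(y, data.frame(x = x))
  tab <- table(x, y)
  or_2x2 <- (tab["0", "0"] * tab["1", "1"]) / (tab["0", "1"] * tab["1", "0"])
  expect_equal(unname(fit$odds_ratio["x"]), or_2x2, tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("logistic fit covers the null and flags separation", {
  set.seed(57)
  x <- rnorm(500)
  y <- rbinom(500, 1, 0.4)  # outcome independent of x
  fit <- multivariate_logistic(y, data.frame(x = x))
  expect_gt(unname(fit$odds_ratio["x"]), 0.8)
  expect_lt(unname(fit$odds_ratio["x"]), 1.25)
  expect_gt(unname(fit$p["x"]), 0.05)

  sep_x <- c(rep(0, 10), rep(1, 10))
  sep_y <- c(rep(0, 10), rep(1, 10))
  expect_warning(sep_fit <- multivariate_logistic(sep_y, data.frame(x = sep_x)),
                 "separation")
  expect_false(sep_fit$converged)
  expect_true(sep_fit$separation)

  expect_error(multivariate_logistic(rep(1, 10), data.frame(x = rnorm(10))),
               "single class")
  expect_error(multivariate_logistic(rbinom(10, 1, 0.5),
                                     data.frame(x = rep(2, 10))),
               "constant covariate")
})

test_that("survival report assembles groups, curves, log-rank and logistic stages", {
  cohort <- small_cohort(seed = 5, n_samples = 120)
  scores <- signature_score(cohort$mirna, esc_mirna_signature())
  rep <- survival_report(scores, cohort$clinical,
                         covariates = c("mycn_amplified", "stage4"))
  expect_named(rep$km, c("low", "high"))
  expect_equal(sum(rep$logrank$observed), sum(cohort$clinical$os_event))
  expect_true(all(vapply(rep$landmark, function(l) l$estimate, 0) >= 0))
  expect_s3_class(rep$logistic, "logistic_fit")
  expect_true(all(c("score", "mycn_amplified", "stage4") %in%
                  names(rep$logistic$odds_ratio)))
})
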