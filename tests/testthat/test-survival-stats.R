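test_that("endpoint construction applies the censoring rules", {
  rec <- data.frame(sample_id = c("a", "b", "c"),
                    recurrence_months = c(NA, NA, 5),
                    death_months = c(NA, 10, 9),
                    death_cause = c(NA, "non_tumour", "tumour"),
                    stringsAsFactors = FALSE)
  dfs <- build_endpoint(rec, "DFS")
  expect_equal(dfs$time, c(24, 10, 5))
  expect_equal(dfs$event, c(0L, 0L, 1L))
  os <- build_endpoint(rec, "OS")
  expect_equal(os$time, c(24, 10, 9))
  expect_equal(os$event, c(0L, 0L, 1L))
  bad <- data.frame(sample_id = "x", recurrence_months = 8, death_months = 4,
                    death_cause = "tumour")
  expect_error(build_endpoint(bad, "DFS"), "death before recurrence")
})

test_that("KM equals the empirical survival function without censoring", {
  set.seed(61)
  for (i in 1:20) {
    t <- sample(1:15, sample(3:8, 1), replace = TRUE)
    ds <- data.frame(sample_id = seq_along(t), time = t, event = 1L)
    km <- kaplan_meier(ds)
    sf <- summary(km$fit, times = sort(unique(t)))
    expect_equal(sf$surv,
                 vapply(sort(unique(t)), function(x) empirical_survival(t, x),
                        numeric(1)))
  }
  # events at 1, 2 in n = 2: S = 0.5 on [1,2), 0 after
  ds <- data.frame(sample_id = 1:2, time = c(1, 2), event = 1L)
  km <- kaplan_meier(ds)
  s <- summary(km$fit, times = c(1, 2))
  expect_equal(s$surv, c(0.5, 0))
  # censoring-only data never drop the curve
  ds2 <- data.frame(sample_id = 1:3, time = c(2, 4, 6), event = 0L)
  km2 <- kaplan_meier(ds2)
  expect_true(all(summary(km2$fit)$surv == 1 | length(summary(km2$fit)$surv) == 0))
})

test_that("restricted mean survival equals the area under the KM curve", {
  ds <- data.frame(sample_id = 1:4, time = c(2, 4, 6, 8),
                   event = c(1L, 1L, 1L, 1L))
  km <- kaplan_meier(ds)
  # hand integral: 1*2 + .75*2 + .5*2 + .25*2
  expect_equal(unname(km$means$rmean), 2 + 1.5 + 1 + 0.5)
})

test_that("log-rank matches the hand-enumerated O-E oracle", {
  ds <- data.frame(sample_id = 1:4, time = c(1, 2, 3, 4), event = 1L,
                   grp = c("g1", "g1", "g2", "g2"))
  lr <- logrank_test(ds, "grp")
  expect_equal(lr$chisq,
               logrank_oracle_2group(ds$time, ds$event, ds$grp),
               tolerance = 1e-10)
  expect_equal(lr$df, 1)
  # identical groups give statistic 0 / p 1
  ds2 <- data.frame(sample_id = 1:6, time = rep(c(2, 5, 9), 2),
                    event = rep(c(1L, 0L, 1L), 2),
                    grp = rep(c("x", "y"), each = 3))
  lr2 <- logrank_test(ds2, "grp")
  expect_equal(lr2$chisq, 0, tolerance = 1e-12)
  expect_equal(lr2$p, 1)
  # randomized datasets still match the oracle
  set.seed(62)
  for (i in 1:25) {
    n <- sample(6:14, 1)
    ds3 <- data.frame(sample_id = 1:n,
                      time = sample(1:20, n, replace = TRUE),
                      event = rbinom(n, 1, 0.8),
                      grp = sample(c("a", "b"), n, replace = TRUE))
    if (length(unique(ds3$grp)) < 2 || sum(ds3$event) == 0) next
    lr3 <- logrank_test(ds3, "grp")
    expect_equal(lr3$chisq,
                 logrank_oracle_2group(ds3$time, ds3$event, ds3$grp),
                 tolerance = 1e-10)
  }
  expect_error(logrank_test(ds2[ds2$grp == "x", ], "grp"), "2 non-empty")
})

test_that("Cox score test at beta = 0 equals the log-rank statistic", {
  set.seed(63)
  for (i in 1:10) {
    n <- 12
    ds <- data.frame(sample_id = 1:n,
                     time = sample(seq(0.5, 40, by = 0.5), n),  # no ties
                     event = rbinom(n, 1, 0.85),
                     x = rbinom(n, 1, 0.5))
    if (sum(ds$event) == 0 || length(unique(ds$x)) < 2) next
    # random draws can separate; the score test at beta = 0 is still defined
    fit <- suppressWarnings(
      survival::coxph(survival::Surv(time, event) ~ x, data = ds))
    lr <- logrank_test(ds, "x")
    expect_equal(unname(fit$score), lr$chisq, tolerance = 1e-6)
  }
})

test_that("forward-stepwise Cox recovers a strong binary covariate", {
  cfg <- sim_config(n_samples = 400,
                    planted_cnvs = data.frame(name = "hr4", chrom = "B4",
                                              start = 0, stop = 28e6,
                                              amplitude = 0.7,
                                              carrier_prob = 0.4,
                                              stringsAsFactors = FALSE),
                    cnv_log_hazard_ratios = c(hr4 = log(4)), seed = 71)
  truth <- simulate_truth(cfg)
  out <- simulate_outcomes(cfg, truth)
  out$hr4 <- as.integer(truth$carriers[, "hr4"])
  withr::with_seed(72, {
    out$noise1 <- rbinom(400, 1, 0.5)
    out$noise2 <- rnorm(400)
  })
  ds <- build_endpoint(out, "DFS")
  fit <- cox_forward_stepwise(ds, c("hr4", "noise1", "noise2"))
  expect_true("hr4" %in% fit$selected)
  hr <- fit$table$hr[fit$table$term == "hr4"]
  expect_gt(hr, 3.0)
  expect_lt(hr, 5.3)
  expect_true(all(fit$table$hr_low < fit$table$hr &
                    fit$table$hr < fit$table$hr_high))
})

test_that("stepwise with pure-noise candidates usually selects nothing", {
  set.seed(73)
  empty <- 0; reps <- 60
  for (r in 1:reps) {
    n <- 120
    ds <- data.frame(sample_id = 1:n,
                     time = rexp(n, 0.08), event = rbinom(n, 1, 0.7))
    ds$time <- pmin(ds$time, 24)
    for (j in 1:6) ds[[paste0("z", j)]] <- rnorm(n)
    fit <- cox_forward_stepwise(ds, paste0("z", 1:6))
    if (length(fit$selected) == 0) empty <- empty + 1
  }
  expect_gte(empty / reps, 0.6)
})

test_that("stepwise handles trivial and degenerate inputs", {
  ds <- data.frame(sample_id = 1:10, time = 1:10,
                   event = rep(c(1L, 0L), 5))
  fit <- cox_forward_stepwise(ds, character(0))
  expect_length(fit$selected, 0)
  expect_null(fit$fit)
  # complete separation: covariate flagged, run continues
  ds$sep <- as.integer(ds$event == 1)
  ds$ok <- rep(c(0, 1), 5)
  fit2 <- cox_forward_stepwise(ds, c("sep", "ok"))
  expect_true(!"sep" %in% fit2$selected || all(is.finite(coef(fit2$fit))))
})

test_that("Cohen's kappa matches arithmetic and e1071 cross-check", {
  expect_equal(cohens_kappa(c("a", "b", "a"), c("a", "b", "a")), 1)
  # 2x2 table a=4, b=1, c=1, d=4
  l1 <- rep(c("p", "p", "n", "n"), c(4, 1, 1, 4))
  l2 <- rep(c("p", "n", "p", "n"), c(4, 1, 1, 4))
  expect_equal(cohens_kappa(l1, l2), 0.6)
  if (requireNamespace("e1071", quietly = TRUE)) {
    tab <- table(l1, l2)
    expect_equal(cohens_kappa(l1, l2),
                 e1071::classAgreement(tab)$kappa, tolerance = 1e-12)
  }
  # independent labels stay near zero
  set.seed(64)
  a <- sample(c("x", "y"), 200, replace = TRUE)
  b <- sample(c("x", "y"), 200, replace = TRUE)
  expect_lt(abs(cohens_kappa(a, b)), 0.15)
  # both raters constant and identical: undefined
  k <- cohens_kappa(rep("q", 5), rep("q", 5))
  expect_true(is.na(k))
  expect_true(attr(k, "undefined"))
})

test_that("percent agreement counts stratum matches", {
  expect_equal(percent_agreement(1:5, 1:5), 1)
  expect_equal(percent_agreement(1:4, 5:8), 0)
  l1 <- c(rep("I", 7), rep("II", 5))
  l2 <- c(rep("I", 7), rep("III", 5))
  expect_equal(percent_agreement(l1, l2), 7 / 12, tolerance = 1e-12)
  expect_equal(percent_agreement(l1, l2, stratum = 1:7), 1)
  expect_error(percent_agreement(l1, l2, stratum = integer(0)), "empty")
})

test_that("ROC cutoff maximizes Youden's J with the stated tie rules", {
  r <- roc_cutoff(c(10, 20, 30, 40), c(0, 0, 1, 1))
  expect_equal(r$cutoff, 30)
  expect_equal(r$direction, ">=")
  expect_equal(r$youden_j, 1)
  # inverse association is reported with the complementary direction
  r2 <- roc_cutoff(c(10, 20, 30, 40), c(1, 1, 0, 0))
  expect_equal(r2$direction, "<=")
  expect_equal(r2$youden_j, 1)
  expect_error(roc_cutoff(1:4, c(1, 1, 1, 1)), "both")
})
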