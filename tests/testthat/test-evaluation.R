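test_that("AUC matches exhaustive pair counting, with DeLong CI", {
  expect_equal(unname(auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))["auc"]), 1)
  expect_equal(unname(auc(rep(0.3, 10), rep(c(0, 1), 5))["auc"]), 0.5)
  expect_equal(unname(auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))["auc"]),
               0.75)
  expect_error(auc(1:4, c(1, 1, 1, 1)), "both")
  set.seed(71)
  for (r in 1:25) {
    n <- sample(10:200, 1)
    s <- sample(seq(0, 1, 0.05), n, replace = TRUE)   # force ties
    y <- rbinom(n, 1, 0.3)
    if (length(unique(y)) < 2) next
    a <- auc(s, y)
    expect_equal(unname(a["auc"]), auc_pairs(s, y), tolerance = 1e-12)
    expect_true(a["ci_low"] <= a["auc"] && a["auc"] <= a["ci_high"])
  }
  # CI behaves: covers a known AUC most of the time at moderate n
  set.seed(73)
  cover <- replicate(100, {
    s0 <- rnorm(150); s1 <- rnorm(50, 1)
    truth <- pnorm(1 / sqrt(2))
    a <- auc(c(s0, s1), rep(c(0, 1), c(150, 50)))
    a["ci_low"] <= truth && truth <= a["ci_high"]
  })
  expect_gte(mean(cover), 0.85)
})

test_that("Brier score is the mean squared deviation", {
  y <- rbinom(50, 1, 0.5)
  expect_equal(brier(rep(0.5, 50), y), 0.25)
  expect_equal(brier(y, y), 0)
  expect_equal(brier(c(0.2, 0.8), c(0, 1)), 0.04)
  expect_error(brier(c(0.2, 0.8), c(0, 1, 1)), "mismatch")
  expect_error(brier(c(-0.1, 0.5), c(0, 1)), "\\[0, 1\\]")
  # minimized by the true generating probabilities
  co <- simulate_cohort(cohort_config(n = 50000, seed = 19))
  y <- as.integer(co$outcome == "died")
  b_true <- brier(co$p_true, y)
  expect_lt(b_true, brier(pmin(1, co$p_true * 1.5), y))
  expect_lt(b_true, brier(co$p_true^2, y))
  expect_lt(b_true, brier(rep(mean(co$p_true), nrow(co)), y))
})

test_that("Cohen kappa and its strength labels follow the stated bands", {
  y <- rbinom(200, 1, 0.4)
  k <- cohen_kappa(y, y)
  expect_equal(k$kappa, 1)
  expect_equal(k$label, "very good")
  set.seed(79)
  k0 <- cohen_kappa(rbinom(20000, 1, 0.3), rbinom(20000, 1, 0.3))
  expect_lt(abs(k0$kappa), 0.05)
  expect_equal(k0$label, "poor")
  expect_equal(kappa_strength(0.718), "good")
  expect_equal(kappa_strength(c(0.20, 0.21, 0.40, 0.41, 0.60, 0.61, 0.80,
                                0.81)),
               c("poor", "weak", "weak", "moderate", "moderate", "good",
                 "good", "very good"))
  # jointly swapping positive/negative labels leaves kappa unchanged
  p <- rbinom(500, 1, 0.4); o <- rbinom(500, 1, plogis(p - 0.5))
  expect_equal(cohen_kappa(p, o)$kappa, cohen_kappa(1 - p, 1 - o)$kappa)
  expect_warning(k1 <- cohen_kappa(rep(1, 5), rep(1, 5)), "constant")
  expect_equal(k1$kappa, 1)
})

test_that("accuracy at a cutoff matches hand counting", {
  s <- c(0.9, 0.8, 0.7, 0.6, 0.55, 0.4, 0.3, 0.2, 0.45, 0.1)
  y <- c(1, 1, 1, 0, 1, 0, 0, 0, 1, 0)
  # at 0.5: predicted dead = first five -> TP 4, FP 1, TN 4, FN 1
  expect_equal(accuracy_at_cutoff(s, y, 0.5), 80)
  expect_equal(accuracy_at_cutoff(s, y, 0), 100 * mean(y))
  expect_equal(accuracy_at_cutoff(c(0.1, 0.9), c(0, 1), 0.5), 100)
  # accuracy at the kappa-optimal cutoff beats its adjacent candidates
  set.seed(83)
  for (r in 1:20) {
    n <- 150
    s <- round(runif(n), 2); y <- rbinom(n, 1, plogis(5 * s - 2.5))
    if (length(unique(y)) < 2) next
    prof <- select_cutoff_max_kappa(s, y)$profile
    accs <- 100 * (prof$tp + prof$tn) / n
    k <- which.max(prof$kappa)
    if (k > 1) expect_gte(accs[k], accs[k - 1])
    if (k < nrow(prof)) expect_gte(accs[k], accs[k + 1])
  }
})

test_that("Hosmer-Lemeshow flags miscalibration and tolerates small data", {
  # miscalibrated probabilities are rejected essentially always at n=5000
  set.seed(89)
  rej <- replicate(20, {
    p <- runif(5000, 0.05, 0.6)
    y <- rbinom(5000, 1, p)
    hosmer_lemeshow(p / 2, y)$p_value < 0.05
  })
  expect_gte(mean(rej), 0.95)
  # minimal grouping runs on a 10-row fixture
  hl <- hosmer_lemeshow(seq(0.05, 0.95, length.out = 10),
                        c(0, 0, 0, 0, 1, 0, 1, 1, 1, 1), g = 2)
  expect_true(is.finite(hl$statistic) && hl$g == 2)
  # tied quantiles collapse groups with a log message
  expect_message(hosmer_lemeshow(rep(c(0.1, 0.9), each = 50),
                                 rbinom(100, 1, 0.5), g = 10), "collapsed")
})

test_that("Nagelkerke R2 evaluates its closed form", {
  expect_equal(nagelkerke_r2(-40, -40, 100), 0)
  expect_equal(nagelkerke_r2(0, -13.86294, 20), 1, tolerance = 1e-5)
  # n=20 fixture against direct formula evaluation
  set.seed(91)
  x <- rnorm(20); y <- rbinom(20, 1, plogis(x))
  f <- glm(y ~ x, family = binomial())
  l1 <- as.numeric(logLik(f))
  l0 <- as.numeric(logLik(glm(y ~ 1, family = binomial())))
  direct <- (1 - exp(2 * (l0 - l1) / 20)) / (1 - exp(2 * l0 / 20))
  expect_equal(nagelkerke_r2(l1, l0, 20), direct, tolerance = 1e-10)
  expect_error(nagelkerke_r2(-50, -40, 100), "below")
})

test_that("the full evaluation report is internally consistent", {
  co <- encode_design(simulate_cohort(cohort_config(n = 4000, seed = 101)))
  probs <- death_probability(linear_predictor(published_model("M1"), co))
  rep <- evaluate_model(probs, co$outcome, cutoff = published_cutoff("M1"),
                        bands = published_bands("M1"))
  expect_true(rep$auc["auc"] >= 0 && rep$auc["auc"] <= 1)
  expect_true(rep$brier >= 0 && rep$brier <= 1)
  expect_true(rep$accuracy >= 0 && rep$accuracy <= 100)
  expect_true(rep$kappa >= -1 && rep$kappa <= 1)
  expect_equal(unname(sum(rep$confusion)), rep$n)
  expect_equal(rep$kappa_label, kappa_strength(rep$kappa))
  expect_equal(rep$deaths, sum(co$outcome == "died"))
  expect_true(all(diff(rep$fnr_at_bands) >= 0))
})

test_that("the real-time scenario subsets, gates and routes by day", {
  # generate outcomes from the day-1-gated early dynamic model: scoring at
  # day 1 must reproduce the generating probabilities exactly
  cfg <- cohort_config(n = 6000, seed = 103)
  co <- assign_diagnoses(generate_covariates(cfg), cfg)
  co_gated <- apply_time_windows(co, 1)
  co <- simulate_outcome(co_gated, published_model("M3_early"), cfg,
                         day_of_life = 1)
  res <- real_time_scenario(co)
  pd <- res$per_day
  expect_equal(pd$n[pd$day == 1], nrow(co))          # universal subset
  expect_equal(pd$model_id, c("M3_early", "M3_early", "M3_early",
                              "M3_late", "M3_late"))
  oracle <- auc(co$p_true, co$outcome)
  # p_true is rounded to 12 decimals in the cohort, which can flip a
  # handful of near-ties; agreement is to ~1e-6 in AUC
  expect_equal(pd$auc[pd$day == 1], unname(oracle["auc"]), tolerance = 1e-5)
  expect_equal(res$mean_auc, mean(pd$auc, na.rm = TRUE))
  # a day with a single outcome class is excluded from the mean, logged
  surv <- co[co$outcome == "survived", ]
  expect_message(res2 <- real_time_scenario(surv, days = c(1, 8)),
                 "single outcome class")
  expect_true(all(is.na(res2$per_day$auc)))
})

test_that("death-timing formatter reproduces printed percentages", {
  tab <- death_timing_summary(c(373, 1315, 327))
  expect_equal(tab$percent, c(18.5, 65.3, 16.2))
  expect_equal(sum(tab$deaths), 2015)
})
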