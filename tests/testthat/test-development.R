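test_that("univariable preselection applies the right test and threshold", {
  cfg <- cohort_config(n = 4000, seed = 5)
  co <- simulate_cohort(cfg)
  co$mirror <- as.integer(co$outcome == "died")   # perfect association
  co$constant <- 1L
  res <- preselect_variables(co, c("mirror", "gestational_age", "rds",
                                   "constant"))
  expect_equal(res$test[res$variable == "mirror"], "chi_square")
  expect_lt(res$p_value[res$variable == "mirror"], 1e-10)
  expect_true(res$selected[res$variable == "mirror"])
  # continuous GA has a true effect under the generating model -> selected
  expect_equal(res$test[res$variable == "gestational_age"], "mann_whitney")
  expect_true(res$selected[res$variable == "gestational_age"])
  expect_equal(res$note[res$variable == "constant"], "degenerate")
  expect_false(res$selected[res$variable == "constant"])
})

test_that("preselection keeps a null variable at about the alpha rate", {
  set.seed(61)
  n <- 10000
  y <- rep(c("died", "survived"), c(1500, n - 1500))
  hits <- 0
  reps <- 200
  for (r in seq_len(reps)) {
    co <- data.frame(outcome = y, noise = rbinom(n, 1, 0.3))
    hits <- hits + preselect_variables(co, "noise")$selected
  }
  rate <- hits / reps
  expect_lt(abs(rate - 0.15), 3 * sqrt(0.15 * 0.85 / reps))
})

test_that("pseudo-day expansion matches the standardized-day arithmetic", {
  days <- c(1, 3, 8, 15, 22, 31, 46, 61)
  co <- patient_cohort(3, length_of_stay = c(1L, 20L, 70L))
  ex <- expand_pseudo_days(co)
  expect_equal(ex$days_of_life[ex$id == "P000001"], 1)
  expect_equal(ex$days_of_life[ex$id == "P000002"], c(1, 3, 8, 15))
  expect_equal(ex$days_of_life[ex$id == "P000003"], days)
  # deaths are truncated at the day of death
  dead <- patient_cohort(1, outcome = "died", day_of_death = 10L,
                         length_of_stay = 10L)
  expect_equal(expand_pseudo_days(dead)$days_of_life, c(1, 3, 8))
  # closed-form row count on a random cohort
  co <- simulate_cohort(cohort_config(n = 800, seed = 23))
  last <- pmin(co$length_of_stay,
               ifelse(co$outcome == "died", co$day_of_death, Inf))
  expect_equal(nrow(expand_pseudo_days(co)),
               sum(vapply(last, function(L) sum(days <= L), numeric(1))))
  # outcome label is the final hospital outcome on every row
  ex <- expand_pseudo_days(co)
  expect_identical(ex$outcome, co$outcome[match(ex$id, co$id)])
})

test_that("time-window gating matches the printed intervals", {
  p <- base_patient(rds = 1L, severe_rds = 1L, nec = 1L, ivh = 1L, pvl = 1L,
                    bpd = 1L, severe_bpd = 1L, pda = 1L)
  g <- function(day) apply_time_windows(p, day)
  expect_equal(g(1)$rds, 1L);  expect_equal(g(7)$rds, 1L)
  expect_equal(g(8)$rds, 0L);  expect_equal(g(8)$severe_rds, 0L)
  expect_equal(g(13)$nec, 0L); expect_equal(g(14)$nec, 1L)
  expect_equal(g(45)$nec, 1L); expect_equal(g(46)$nec, 0L)
  expect_equal(g(10)$ivh, 1L); expect_equal(g(11)$ivh, 0L)
  expect_equal(g(21)$pvl, 0L); expect_equal(g(22)$pvl, 1L)
  expect_equal(g(22)$bpd, 0L); expect_equal(g(28)$bpd, 0L)
  expect_equal(g(31)$bpd, 1L); expect_equal(g(31)$severe_bpd, 1L)
  # non-windowed variables pass through
  expect_equal(g(60)$pda, 1L)
  # gated flag never exceeds the original flag (property over random cohorts)
  co <- simulate_cohort(cohort_config(n = 300, seed = 31))
  for (day in c(2, 12, 25, 50)) {
    gated <- apply_time_windows(co, day)
    for (col in c("rds", "nec", "ivh", "pvl", "bpd", "severe_ivh"))
      expect_true(all(gated[[col]] <= co[[col]]))
  }
})

test_that("logistic fitting is a faithful ML fit with honest diagnostics", {
  # intercept-only on balanced outcomes
  tab <- data.frame(outcome = rep(c("died", "survived"), 50), x = 0)
  tab$x <- rnorm(100)
  f <- fit_logistic(tab, "outcome", "x")
  expect_lt(abs(f$coefficients$beta[1]), 0.5)
  expect_true(f$converged)
  expect_gte(f$loglik, f$loglik_null)
  # duplicated predictor flagged and dropped
  tab$x2 <- tab$x
  expect_message(f2 <- fit_logistic(tab, "outcome", c("x", "x2")),
                 "collinear")
  expect_equal(f2$dropped, "x2")
  # constant predictor dropped as degenerate
  tab$k <- 1
  expect_message(f3 <- fit_logistic(tab, "outcome", c("x", "k")),
                 "degenerate")
  # separation flagged, not silent
  sep <- data.frame(outcome = rep(c("died", "survived"), each = 30),
                    x = c(rnorm(30, 5), rnorm(30, -5)))
  fs <- fit_logistic(sep, "outcome", "x")
  expect_false(fs$converged)
  expect_true(fs$separation)
  expect_error(fit_logistic(tab[tab$outcome == "died", ], "outcome", "x"),
               "single class")
})

test_that("refitting recovers the generating coefficients", {
  m1 <- published_model("M1")
  truth <- c(m1$intercept, m1$terms$beta)
  vars <- c("level2", "gestational_age", "low_weight_p10", "male",
            "steroids_partial", "steroids_full", "multiple_pregnancy")
  err <- sapply(c(2000, 20000), function(n) {
    co <- encode_design(simulate_cohort(cohort_config(n = n, seed = 97)))
    f <- fit_logistic(co, "outcome", vars)
    expect_true(f$converged)
    # every estimate within 4 SEs of its generating value
    expect_true(all(abs(f$coefficients$beta - truth) <=
                      4 * f$coefficients$se))
    sqrt(mean((f$coefficients$beta - truth)^2))
  })
  expect_lt(err[2], err[1])  # bias/variance shrinks with n
})

test_that("the dynamic model is fit on day-stratified expanded rows", {
  co <- simulate_cohort(cohort_config(n = 3000, seed = 77),
                        true_model = published_model("M3_early"))
  suppressMessages(dyn <- fit_dynamic_model3(co))
  expect_true(dyn$early$n > dyn$late$n)
  expect_equal(dyn$early$n + dyn$late$n, dyn$expanded_rows)
  # days-of-life persists as a covariate with a negative fitted sign
  b_days <- dyn$early$spec$terms$beta[
    dyn$early$spec$terms$variable == "days_of_life"]
  expect_lt(b_days, 0)
  # severe IVH is structurally absent after day 30 (window 0-10): logged drop
  expect_true("severe_ivh" %in% dyn$late$dropped)
  # standardized late days route only 31/46/61 rows to the late model
  ex <- expand_pseudo_days(co)
  expect_setequal(unique(ex$days_of_life[ex$days_of_life > 30]),
                  c(31, 46, 61))
  # degenerate stratum errors by name
  short <- co[co$length_of_stay <= 30, ]
  expect_error(suppressMessages(fit_dynamic_model3(short)), "late stratum")
})

test_that("kappa-optimal cutoff equals exhaustive search", {
  # perfect separation: kappa 1
  s <- c(0.1, 0.2, 0.8, 0.9); y <- c(0, 0, 1, 1)
  res <- select_cutoff_max_kappa(s, y)
  expect_equal(res$kappa, 1)
  expect_true(res$cutoff > 0.2 && res$cutoff <= 0.8)
  expect_error(select_cutoff_max_kappa(s, c(1, 1, 1, 1)), "both")
  # brute-force oracle equivalence on random instances
  set.seed(41)
  for (r in 1:30) {
    n <- sample(20:300, 1)
    s <- round(runif(n), 2)
    y <- rbinom(n, 1, plogis(4 * s - 2))
    if (length(unique(y)) < 2) next
    res <- select_cutoff_max_kappa(s, y)
    oracle <- brute_cutoff(s, y)
    expect_equal(res$kappa, oracle$kappa, tolerance = 1e-12)
    expect_equal(res$cutoff, oracle$cutoff)
  }
  # independent scores: near-zero optimum kappa in most replicates
  set.seed(43)
  small <- replicate(20, {
    s <- runif(1000); y <- rbinom(1000, 1, 0.15)
    select_cutoff_max_kappa(s, y)$kappa
  })
  expect_gte(mean(small < 0.1), 0.95)
})

test_that("FNR thresholds implement the printed definition", {
  scores <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.05, 0.15, 0.6)
  y <- c(1, 1, 1, 1, 1, 0, 0, 0)
  expect_equal(fnr_at(0.2, scores, y), 0.2)   # one of five deaths below
  b <- derive_fnr_thresholds(scores, y)
  # FNR(0.2)=1/5, FNR(0.4)=3/5, FNR(0.5)=4/5: smallest death scores
  # reaching the 0.20/0.50/0.80 levels
  expect_equal(b$thresholds, c(0.2, 0.4, 0.5))
  expect_equal(b$provenance, "derived_from_data")
  # q = 0: threshold at or below the minimum dead score, FNR exactly 0
  b0 <- derive_fnr_thresholds(scores, y, fnr_levels = c(0, 0.5, 0.8))
  expect_lte(b0$thresholds[1], 0.1)
  expect_equal(fnr_at(b0$thresholds[1], scores, y), 0)
  # FNR non-decreasing in t on random inputs
  set.seed(53)
  s <- runif(200); yy <- rbinom(200, 1, 0.2)
  grid <- sort(unique(s))
  expect_true(all(diff(fnr_at(grid, s, yy)) >= 0))
  expect_error(derive_fnr_thresholds(s, rep(0, 200)), "death")
})
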