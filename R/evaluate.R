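# Validation-stage statistics: discrimination, calibration, accuracy,
# concordance, and the real-time per-day scenario.

outcome01 <- function(outcomes) {
  if (is.numeric(outcomes)) as.integer(outcomes)
  else as.integer(outcomes == "died")
}

#' AUC with DeLong 95% confidence interval
#'
#' The area under the ROC curve in its Mann-Whitney form,
#' P(score_death > score_survivor) + P(tie)/2, with the confidence
#' interval from the DeLong placement-value variance (computed via
#' midranks, so it scales to large cohorts).
#'
#' @param scores Numeric scores (higher = more likely to die).
#' @param outcomes Binary outcomes (0/1 or `"survived"`/`"died"`).
#' @return Named vector `c(auc, ci_low, ci_high)` (CI clipped to `[0, 1]`).
#' @export
auc <- function(scores, outcomes) {
  y <- outcome01(outcomes)
  m <- sum(y == 1); n <- sum(y == 0)
  if (m == 0 || n == 0) stop("both outcome classes must be present")
  r_all <- rank(scores, ties.method = "average")
  r_pos <- rank(scores[y == 1], ties.method = "average")
  r_neg <- rank(scores[y == 0], ties.method = "average")
  v10 <- (r_all[y == 1] - r_pos) / n        # placements of deaths
  v01 <- 1 - (r_all[y == 0] - r_neg) / m    # placements of survivors
  a <- mean(v10)
  s10 <- if (m > 1) stats::var(v10) else 0
  s01 <- if (n > 1) stats::var(v01) else 0
  se <- sqrt(s10 / m + s01 / n)
  c(auc = a, ci_low = max(0, a - 1.96 * se), ci_high = min(1, a + 1.96 * se))
}

#' Brier score
#'
#' Mean squared deviation between predicted probability and outcome: 0 for
#' a perfect model, 0.25 for a non-informative (constant 0.5) model.
#'
#' @param probs Predicted probabilities in `[0, 1]`.
#' @param outcomes Binary outcomes.
#' @return A single number in `[0, 1]`.
#' @export
brier <- function(probs, outcomes) {
  y <- outcome01(outcomes)
  if (length(probs) != length(y)) stop("length mismatch")
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  mean((probs - y)^2)
}

#' Cohen kappa with its concordance-strength label
#'
#' kappa = (p_o - p_e) / (1 - p_e) with expected agreement from the
#' marginal products. Strength labels: poor (0-0.20), weak (0.21-0.40),
#' moderate (0.41-0.60), good (0.61-0.80), very good (0.81-1.00); negative
#' kappa is labelled poor.
#'
#' @param predicted,observed Binary vectors of equal length.
#' @return `list(kappa, label)`.
#' @export
cohen_kappa <- function(predicted, observed) {
  p <- outcome01(predicted); o <- outcome01(observed)
  if (length(p) != length(o)) stop("length mismatch")
  n <- length(p)
  po <- mean(p == o)
  pe <- mean(p) * mean(o) + (1 - mean(p)) * (1 - mean(o))
  k <- if (pe == 1) {
    warning("both classifications are constant and equal; kappa defined as 1")
    1
  } else (po - pe) / (1 - pe)
  list(kappa = k, label = kappa_strength(k))
}

#' @rdname cohen_kappa
#' @param kappa A kappa value in `[-1, 1]`.
#' @export
kappa_strength <- function(kappa) {
  labels <- c("poor", "weak", "moderate", "good", "very good")
  labels[1L + (kappa > 0.20) + (kappa > 0.40) + (kappa > 0.60) +
           (kappa > 0.80)]
}

#' Classification accuracy at a cutoff
#'
#' Predicted death iff score >= cutoff; accuracy = 100 (TP + TN) / n.
#'
#' @param scores,outcomes Scores and binary outcomes.
#' @param cutoff Classification cutoff in `[0, 1]` for probability scores.
#' @return Accuracy in percent.
#' @export
accuracy_at_cutoff <- function(scores, outcomes, cutoff) {
  y <- outcome01(outcomes)
  100 * mean((scores >= cutoff) == (y == 1))
}

#' Hosmer-Lemeshow calibration test
#'
#' Groups by equal-frequency quantiles of predicted risk (deciles by
#' default; tied quantiles collapse groups, which is logged), computes the
#' Pearson statistic over observed vs expected deaths and survivals, and
#' refers it to chi-square with g - 2 degrees of freedom. p > 0.05 is read
#' as adequate calibration.
#'
#' @param probs Predicted probabilities.
#' @param outcomes Binary outcomes.
#' @param g Number of groups (default 10).
#' @return `list(statistic, p_value, g, table)`.
#' @export
hosmer_lemeshow <- function(probs, outcomes, g = 10) {
  y <- outcome01(outcomes)
  if (length(y) < 2 * g) stop("need at least 2 observations per group")
  breaks <- unique(quantile(probs, seq(0, 1, length.out = g + 1)))
  if (length(breaks) < g + 1)
    message("tied risk quantiles: groups collapsed from ", g, " to ",
            length(breaks) - 1)
  if (length(breaks) < 3) stop("fewer than 2 distinct risk groups")
  grp <- cut(probs, breaks, include.lowest = TRUE)
  o1 <- tapply(y, grp, sum)
  e1 <- tapply(probs, grp, sum)
  nk <- tapply(y, grp, length)
  keep <- !is.na(nk) & nk > 0
  o1 <- o1[keep]; e1 <- e1[keep]; nk <- nk[keep]
  pk <- e1 / nk
  stat <- sum((o1 - e1)^2 / pmax(nk * pk * (1 - pk), .Machine$double.eps))
  g_eff <- length(nk)
  list(statistic = unname(stat),
       p_value = unname(pchisq(stat, df = g_eff - 2, lower.tail = FALSE)),
       g = g_eff,
       table = data.frame(n = as.vector(nk), observed = as.vector(o1),
                          expected = as.vector(e1)))
}

#' Nagelkerke pseudo R-squared
#'
#' R2 = (1 - exp(2 (L0 - L1) / n)) / (1 - exp(2 L0 / n)) from the model and
#' null log-likelihoods.
#'
#' @param loglik_model,loglik_null Maximized and null log-likelihoods
#'   (`loglik_model >= loglik_null`).
#' @param n Number of observations.
#' @return A value in `[0, 1]`.
#' @export
nagelkerke_r2 <- function(loglik_model, loglik_null, n) {
  if (loglik_model < loglik_null - 1e-8)
    stop("model log-likelihood below null log-likelihood")
  cox_snell <- 1 - exp(2 * (loglik_null - loglik_model) / n)
  max_r2 <- 1 - exp(2 * loglik_null / n)
  cox_snell / max_r2
}

#' Full validation report for one model on one cohort
#'
#' Computes the validation-stage statistics at once: AUC with DeLong CI,
#' Brier score, Cohen kappa (with strength label) and accuracy at the
#' supplied cutoff, the confusion counts, Hosmer-Lemeshow calibration,
#' optionally Nagelkerke R2 (if log-likelihoods are given), and the
#' empirical FNR at each band threshold.
#'
#' @param probs Predicted death probabilities.
#' @param outcomes Binary outcomes.
#' @param cutoff Classification cutoff (development-set value).
#' @param bands A `vlbw_bands` for the FNR column (optional).
#' @param loglik,loglik_null Optional log-likelihoods for Nagelkerke R2.
#' @param hl_groups Hosmer-Lemeshow group count.
#' @return A list of class `vlbw_report`.
#' @export
evaluate_model <- function(probs, outcomes, cutoff, bands = NULL,
                           loglik = NULL, loglik_null = NULL,
                           hl_groups = 10) {
  y <- outcome01(outcomes)
  pred <- as.integer(probs >= cutoff)
  kap <- cohen_kappa(pred, y)
  hl <- tryCatch(hosmer_lemeshow(probs, y, g = hl_groups),
                 error = function(e) NULL)
  rep <- list(
    n = length(y), deaths = sum(y),
    auc = auc(probs, y),
    brier = brier(probs, y),
    cutoff = cutoff,
    accuracy = accuracy_at_cutoff(probs, y, cutoff),
    kappa = kap$kappa, kappa_label = kap$label,
    confusion = c(tp = sum(pred == 1 & y == 1), fp = sum(pred == 1 & y == 0),
                  tn = sum(pred == 0 & y == 0), fn = sum(pred == 0 & y == 1)),
    hosmer_lemeshow = hl,
    nagelkerke = if (!is.null(loglik) && !is.null(loglik_null))
      nagelkerke_r2(loglik, loglik_null, length(y)) else NULL,
    bands = if (!is.null(bands)) bands$thresholds else NULL,
    fnr_at_bands = if (!is.null(bands) && any(y == 1))
      fnr_at(bands$thresholds, probs, y) else NULL
  )
  class(rep) <- "vlbw_report"
  rep
}

#' @export
print.vlbw_report <- function(x, ...) {
  cat(sprintf("<vlbw_report: n=%d, deaths=%d>\n", x$n, x$deaths))
  cat(sprintf("  AUC %.3f (95%% CI %.3f-%.3f)   Brier %.3f\n",
              x$auc["auc"], x$auc["ci_low"], x$auc["ci_high"], x$brier))
  cat(sprintf("  cutoff %.4g: accuracy %.2f%%, kappa %.3f (%s)\n",
              x$cutoff, x$accuracy, x$kappa, x$kappa_label))
  if (!is.null(x$hosmer_lemeshow))
    cat(sprintf("  Hosmer-Lemeshow chi2=%.2f (g=%d), p=%.3g\n",
                x$hosmer_lemeshow$statistic, x$hosmer_lemeshow$g,
                x$hosmer_lemeshow$p_value))
  if (!is.null(x$nagelkerke))
    cat(sprintf("  Nagelkerke R2 %.3f\n", x$nagelkerke))
  if (!is.null(x$fnr_at_bands))
    cat("  FNR at band thresholds:",
        paste(sprintf("%.3f", x$fnr_at_bands), collapse = ", "), "\n")
  invisible(x)
}

#' Real-time per-day validation scenario
#'
#' For each requested day d: keep patients with length of stay >= d, gate
#' their diagnoses by the time-windows at day d, score them with the
#' dynamic sub-model selected by day (early for d <= 30, late after), and
#' compute the AUC. Days whose subset contains a single outcome class are
#' reported as undefined and excluded from the unweighted mean.
#'
#' @param cohort Patient-level data frame with `length_of_stay`, `outcome`
#'   and the model predictors.
#' @param models Named list with elements `M3_early` and `M3_late`
#'   (`vlbw_model`s); default the published specs.
#' @param rule An [expansion_rule()] supplying the windows.
#' @param days Evaluation days.
#' @return `list(per_day = data.frame(day, n, deaths, model_id, auc,
#'   ci_low, ci_high), mean_auc)`.
#' @export
real_time_scenario <- function(cohort,
                               models = list(M3_early = published_model("M3_early"),
                                             M3_late = published_model("M3_late")),
                               rule = expansion_rule(),
                               days = c(1, 8, 15, 31, 61)) {
  rows <- lapply(days, function(d) {
    sub <- cohort[cohort$length_of_stay >= d, , drop = FALSE]
    y <- outcome01(sub$outcome)
    id <- select_submodel(d)
    if (nrow(sub) == 0L || length(unique(y)) < 2) {
      message("day ", d, ": single outcome class; AUC undefined")
      return(data.frame(day = d, n = nrow(sub), deaths = sum(y),
                        model_id = id, auc = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_))
    }
    sub <- apply_time_windows(sub, d, rule)
    z <- linear_predictor(models[[id]], sub, day_of_life = d)
    a <- auc(death_probability(z), y)
    data.frame(day = d, n = nrow(sub), deaths = sum(y), model_id = id,
               auc = a["auc"], ci_low = a["ci_low"], ci_high = a["ci_high"])
  })
  per_day <- do.call(rbind, rows)
  rownames(per_day) <- NULL
  list(per_day = per_day, mean_auc = mean(per_day$auc, na.rm = TRUE))
}

#' Death-timing summary
#'
#' Tabulates deaths by timing window (<24 h, 24 h-30 d, >30 d before
#' discharge) with percentages of all deaths printed to one decimal.
#'
#' @param counts Integer vector of deaths per window, or a cohort data
#'   frame with `outcome` and `day_of_death` from which the counts are
#'   tabulated (day 1 / days 2-30 / day >30).
#' @return Data frame `window`, `deaths`, `percent`.
#' @export
death_timing_summary <- function(counts) {
  if (is.data.frame(counts)) {
    dod <- counts$day_of_death[counts$outcome == "died"]
    counts <- c(sum(dod <= 1), sum(dod > 1 & dod <= 30), sum(dod > 30))
  }
  stopifnot(length(counts) == 3L)
  data.frame(window = c("<24 h", "24 h-30 d", ">30 d"),
             deaths = as.integer(counts),
             percent = as_percent(counts / sum(counts)))
}
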