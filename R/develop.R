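# Development stage: univariable preselection, logistic fitting, the
# day-30-stratified dynamic model, Kappa-optimal cutoff and FNR band
# derivation.

#' Univariable preselection of candidate predictors
#'
#' Categorical candidates are tested against the outcome by the chi-square
#' test (no continuity correction; logged for 2x2 tables), continuous
#' candidates by the Mann-Whitney U test (normal approximation with tie
#' correction). A candidate is kept iff p < alpha. Variables constant in
#' the data are excluded with reason "degenerate".
#'
#' @param cohort Data frame containing `outcome` and the candidates.
#' @param candidate_vars Character vector of column names.
#' @param alpha Preselection significance level (default 0.15).
#' @param types Optional named character vector (`"categorical"` /
#'   `"continuous"`); by default numeric columns with more than 10 distinct
#'   values are treated as continuous.
#' @return Data frame with one row per candidate: `variable`, `type`,
#'   `test`, `p_value`, `selected`, `note`.
#' @export
preselect_variables <- function(cohort, candidate_vars, alpha = 0.15,
                                types = NULL) {
  if (!"outcome" %in% names(cohort)) stop("cohort lacks 'outcome'")
  y <- factor(cohort$outcome)
  rows <- lapply(candidate_vars, function(v) {
    if (!v %in% names(cohort)) stop("candidate '", v, "' not in cohort")
    x <- cohort[[v]]
    type <- if (!is.null(types) && v %in% names(types)) types[[v]]
    else if (is.numeric(x) && length(unique(x[!is.na(x)])) > 10)
      "continuous" else "categorical"
    ok <- !is.na(x) & !is.na(y)
    if (length(unique(x[ok])) < 2)
      return(data.frame(variable = v, type = type, test = NA_character_,
                        p_value = NA_real_, selected = FALSE,
                        note = "degenerate"))
    if (type == "continuous") {
      p <- suppressWarnings(
        wilcox.test(as.numeric(x)[ok] ~ y[ok], exact = FALSE,
                    correct = TRUE)$p.value)
      test <- "mann_whitney"
      note <- ""
    } else {
      tab <- table(x[ok], y[ok])
      res <- suppressWarnings(chisq.test(tab, correct = FALSE))
      p <- res$p.value
      test <- "chi_square"
      note <- if (any(res$expected < 5)) "small expected cell" else ""
    }
    data.frame(variable = v, type = type, test = test, p_value = p,
               selected = is.finite(p) && p < alpha, note = note)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Maximum-likelihood logistic fit
#'
#' Fits `outcome ~ variables` by [stats::glm()] with a binomial family on
#' complete cases. Rank-deficient (aliased) columns are dropped and logged;
#' suspected separation (an absolute coefficient above 15 or fitted
#' probabilities collapsing to 0/1) flags the result rather than failing
#' silently.
#'
#' @param table Data frame of rows to fit (patient-level or expanded).
#' @param outcome Name of the binary outcome column (`"died"`/`"survived"`
#'   character, factor, or 0/1; death is the positive class).
#' @param variables Character vector of numeric/0-1 predictor columns.
#' @param model_id Identifier stored on the resulting spec.
#' @return A list of class `vlbw_fit`: `spec` (a `vlbw_model` built from
#'   the estimates), `coefficients` (term/beta/se table including the
#'   intercept), `loglik`, `loglik_null`, `n`, `converged`, `separation`,
#'   `dropped`, and the underlying `glm` object.
#' @export
fit_logistic <- function(table, outcome = "outcome", variables,
                         model_id = "fit") {
  if (!outcome %in% names(table)) stop("outcome column '", outcome, "' missing")
  miss <- setdiff(variables, names(table))
  if (length(miss))
    stop("predictors missing from the table: ", paste(miss, collapse = ", "))
  y <- table[[outcome]]
  y <- if (is.numeric(y)) as.integer(y) else as.integer(y == "died")
  dat <- table[, variables, drop = FALSE]
  dat <- data.frame(lapply(dat, function(col) as.numeric(col)))
  names(dat) <- variables
  cc <- complete.cases(dat) & !is.na(y)
  n_dropped_rows <- sum(!cc)
  dat <- dat[cc, , drop = FALSE]
  y <- y[cc]
  if (length(unique(y)) < 2)
    stop("outcome has a single class; cannot fit")
  degenerate <- variables[vapply(dat, function(col)
    length(unique(col)) < 2, logical(1))]
  if (length(degenerate)) {
    message("dropped degenerate (constant) predictor(s): ",
            paste(degenerate, collapse = ", "))
    variables <- setdiff(variables, degenerate)
    dat <- dat[, variables, drop = FALSE]
  }
  if (length(y) <= length(variables) + 1)
    stop("fewer rows than parameters")
  dat$.y <- y
  fit <- suppressWarnings(glm(.y ~ ., data = dat, family = binomial()))
  cf <- coef(fit)
  aliased <- names(cf)[is.na(cf)]
  if (length(aliased)) {
    message("dropped collinear predictor(s): ", paste(aliased, collapse = ", "))
    keep <- setdiff(variables, aliased)
    dat2 <- dat[, c(keep, ".y"), drop = FALSE]
    fit <- suppressWarnings(glm(.y ~ ., data = dat2, family = binomial()))
    cf <- coef(fit)
    variables <- keep
  }
  sm <- summary(fit)$coefficients
  mu <- fitted(fit)
  # intercepts can legitimately be large (GA in weeks); judge separation on
  # slope magnitudes and collapsed fitted probabilities only
  separation <- any(abs(cf[-1]) > 15) ||
    (any(mu > 1 - 1e-8 & y == 1) && any(mu < 1e-8 & y == 0))
  ll <- as.numeric(logLik(fit))
  ll0 <- as.numeric(logLik(suppressWarnings(
    glm(.y ~ 1, data = dat, family = binomial()))))
  terms <- data.frame(term = variables, type = "numeric",
                      variable = variables, level = NA_character_,
                      levels = "", scale = 1,
                      beta = unname(cf[variables]),
                      se = unname(sm[variables, "Std. Error"]),
                      stringsAsFactors = FALSE)
  spec <- model_spec(model_id, intercept = unname(cf["(Intercept)"]),
                     intercept_se = unname(sm["(Intercept)", "Std. Error"]),
                     terms = terms)
  structure(list(spec = spec,
                 coefficients = rbind(
                   data.frame(term = "(Intercept)", beta = unname(cf[1]),
                              se = unname(sm[1, "Std. Error"])),
                   terms[, c("term", "beta", "se")]),
                 loglik = ll, loglik_null = ll0, n = length(y),
                 converged = fit$converged && !separation,
                 separation = separation,
                 dropped = c(degenerate, aliased),
                 rows_dropped_na = n_dropped_rows, glm = fit),
            class = "vlbw_fit")
}

#' @export
print.vlbw_fit <- function(x, ...) {
  cat(sprintf("<vlbw_fit %s: n=%d, logLik=%.2f (null %.2f), converged=%s>\n",
              x$spec$model_id, x$n, x$loglik, x$loglik_null, x$converged))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Fit the day-30-stratified dynamic model
#'
#' Expands the cohort over the standardized pseudo-days, routes rows with
#' `days_of_life <= 30` to the early stratum and the rest to the late
#' stratum, and fits a logistic model in each with days of life as a
#' numeric covariate.
#'
#' @param cohort Patient-level data frame.
#' @param rule An [expansion_rule()].
#' @param variables_early,variables_late Predictor columns for each
#'   stratum; defaults are the encoded published variable lists (see
#'   [encode_design()]), plus `days_of_life`.
#' @return `list(early =, late =, expanded_rows =)` of `vlbw_fit`s.
#' @export
fit_dynamic_model3 <- function(cohort, rule = expansion_rule(),
                               variables_early = NULL,
                               variables_late = NULL) {
  expanded <- expand_pseudo_days(cohort, rule)
  expanded <- encode_design(expanded)
  variables_early <- variables_early %||%
    c("multiple_pregnancy", "gestational_age", "steroids_any",
      "maternal_hypertension", "apgar5", "bw100", "severe_rds",
      "severe_pneumothorax", "nec", "severe_infection", "ivh", "severe_ivh",
      "days_of_life")
  variables_late <- variables_late %||%
    c("multiple_pregnancy", "gestational_age", "steroids_any", "apgar5",
      "bw100", "severe_pneumothorax", "nec", "severe_nec",
      "severe_infection", "severe_ivh", "severe_pvl", "severe_anemia",
      "bpd", "days_of_life")
  early <- expanded[expanded$days_of_life <= 30, , drop = FALSE]
  late <- expanded[expanded$days_of_life > 30, , drop = FALSE]
  if (nrow(early) == 0L) stop("early stratum (days 1-30) is empty")
  if (nrow(late) == 0L) stop("late stratum (days >30) is empty")
  list(early = fit_logistic(early, "outcome", variables_early,
                            model_id = "M3_early_fit"),
       late = fit_logistic(late, "outcome", variables_late,
                           model_id = "M3_late_fit"),
       expanded_rows = nrow(expanded))
}

#' Encode model design columns
#'
#' Adds the numeric encodings used by the published equations to a cohort:
#' `male`, `level2`, `steroids_partial`, `steroids_full`, `steroids_any`
#' (partial or full) and `bw100` (birth weight / 100).
#'
#' @param cohort Patient-level (or expanded) data frame.
#' @return The data frame with encoded columns appended.
#' @export
encode_design <- function(cohort) {
  if ("sex" %in% names(cohort))
    cohort$male <- as.integer(cohort$sex == "male")
  if ("level_of_care" %in% names(cohort))
    cohort$level2 <- as.integer(cohort$level_of_care == 2)
  if ("maternal_steroids" %in% names(cohort)) {
    cohort$steroids_partial <- as.integer(cohort$maternal_steroids == "partial")
    cohort$steroids_full <- as.integer(cohort$maternal_steroids == "full")
    cohort$steroids_any <- as.integer(cohort$maternal_steroids %in%
                                        c("partial", "full"))
  }
  if ("birth_weight" %in% names(cohort))
    cohort$bw100 <- cohort$birth_weight / 100
  cohort
}

# Cohen kappa for every candidate cutoff (predicted positive iff
# score >= cutoff), computed in O(n log n) via cumulative counts.
kappa_profile <- function(scores, outcomes) {
  y <- if (is.numeric(outcomes)) as.integer(outcomes)
  else as.integer(outcomes == "died")
  o <- order(scores)
  s <- scores[o]
  ys <- y[o]
  n <- length(y)
  npos <- sum(ys)
  first <- !duplicated(s)
  cutoffs <- s[first]
  idx <- which(first)          # rows with score >= cutoff k: idx[k] .. n
  below_pos <- c(0, cumsum(ys))[idx]   # deaths strictly below cutoff
  tp <- npos - below_pos
  pred_pos <- n - idx + 1
  fp <- pred_pos - tp
  tn <- (n - npos) - fp
  po <- (tp + tn) / n
  pe <- (pred_pos / n) * (npos / n) +
    ((n - pred_pos) / n) * ((n - npos) / n)
  kappa <- ifelse(pe == 1, 1, (po - pe) / (1 - pe))
  data.frame(cutoff = cutoffs, kappa = kappa, tp = tp, fp = fp, tn = tn,
             fn = npos - tp)
}

#' Kappa-optimal classification cutoff
#'
#' Scans every unique score as a candidate cutoff (predicted death iff
#' score >= cutoff) and returns the one maximizing the Cohen Kappa of
#' prediction vs outcome; ties are broken toward the smallest cutoff.
#'
#' @param scores Numeric scores or probabilities.
#' @param outcomes Binary outcomes (0/1 or `"survived"`/`"died"`).
#' @return `list(cutoff, kappa, profile)` where `profile` is the full
#'   cutoff/kappa table.
#' @export
select_cutoff_max_kappa <- function(scores, outcomes) {
  y <- if (is.numeric(outcomes)) as.integer(outcomes)
  else as.integer(outcomes == "died")
  if (length(unique(y)) < 2) stop("both outcome classes must be present")
  prof <- kappa_profile(scores, outcomes)
  best <- which.max(prof$kappa)   # which.max takes the first (smallest cutoff)
  list(cutoff = prof$cutoff[best], kappa = prof$kappa[best], profile = prof)
}

#' Empirical false negative rate at a threshold
#'
#' FNR(t) = number of deaths with score strictly below t, divided by the
#' total number of deaths.
#'
#' @param t Threshold(s).
#' @param scores,outcomes Scores and binary outcomes.
#' @return FNR value(s) in `[0, 1]`.
#' @export
fnr_at <- function(t, scores, outcomes) {
  y <- if (is.numeric(outcomes)) as.integer(outcomes)
  else as.integer(outcomes == "died")
  dead <- scores[y == 1]
  if (length(dead) == 0) stop("no deaths in the data")
  vapply(t, function(ti) mean(dead < ti), numeric(1))
}

#' Derive FNR-based category bands
#'
#' For each target level q, the threshold is the smallest observed death
#' score t with FNR(t) >= q (death scores are the candidate grid, so a
#' threshold is always an attained score of a fatal case). The default
#' levels (0.20, 0.50, 0.80) mirror the four mortality bands 0-20% /
#' 21-50% / 51-80% / 81-100%. Duplicate thresholds are perturbed to the
#' next distinct candidate score (logged).
#'
#' @param scores,outcomes Scores and binary outcomes (at least one death).
#' @param fnr_levels Three increasing FNR target levels.
#' @return A `vlbw_bands` with provenance `"derived_from_data"`.
#' @export
derive_fnr_thresholds <- function(scores, outcomes,
                                  fnr_levels = c(0.20, 0.50, 0.80)) {
  y <- if (is.numeric(outcomes)) as.integer(outcomes)
  else as.integer(outcomes == "died")
  if (!any(y == 1)) stop("no deaths in the data")
  grid <- sort(unique(scores[y == 1]))
  fnr <- fnr_at(grid, scores, outcomes)
  th <- vapply(fnr_levels, function(q) {
    ok <- which(fnr >= q)
    if (!length(ok)) grid[length(grid)] else grid[ok[1]]
  }, numeric(1))
  for (i in 2:length(th)) {
    if (th[i] <= th[i - 1]) {
      nxt <- grid[grid > th[i - 1]]
      if (!length(nxt))
        stop("cannot derive strictly increasing FNR thresholds")
      message("FNR threshold for level ", fnr_levels[i],
              " perturbed to the next distinct score")
      th[i] <- nxt[1]
    }
  }
  category_bands(th, provenance = "derived_from_data")
}
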