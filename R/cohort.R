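# Synthetic SEN1500-like cohort generator.
#
# The generator's defaults are the development-period marginals of the
# registry description (prevalences, GA median/IQR, mortality and
# death-timing fractions). Outcomes are produced by a known logistic
# mechanism (a model spec applied generatively), so development and
# validation stages have ground truth. Correlation structure beyond
# GA -> birth weight, GA -> (RDS, IVH, NEC) and resuscitation -> Apgar is
# independence, since only marginals are described.

PLAIN_DIAGNOSES <- c("rds", "pneumothorax", "pda", "nec", "gi_perforation",
                     "early_sepsis", "late_sepsis", "ivh", "pvl", "rop", "bpd")
SEVERE_DIAGNOSES <- c("advanced_resuscitation", "severe_rds", "severe_pda",
                      "severe_nec", "severe_infection", "severe_rop",
                      "severe_ivh", "severe_pvl", "severe_bpd",
                      "severe_pneumothorax", "severe_anemia")
# severe flag -> plain flag it implies
SEVERE_PAIRS <- c(severe_rds = "rds", severe_pda = "pda", severe_nec = "nec",
                  severe_rop = "rop", severe_ivh = "ivh", severe_pvl = "pvl",
                  severe_bpd = "bpd", severe_pneumothorax = "pneumothorax")
STEROID_LEVELS <- c("none", "partial", "full")
RESUS_LEVELS <- c("nil", "positive_pressure", "intubation", "compressions",
                  "adrenaline")
# per-logit-week decrease of diagnosis risk with gestational age
GA_DIAG_SLOPES <- c(rds = 0.35, ivh = 0.30, nec = 0.25)

COHORT_COLUMNS <- c("id", "maternal_steroids", "chorioamnionitis",
                    "maternal_hypertension", "multiple_pregnancy", "sex",
                    "gestational_age", "birth_weight", "low_weight_p10",
                    "inborn", "level_of_care", "cesarean", "resuscitation",
                    "apgar1", "apgar5", "admission_temp", "crib1",
                    "postnatal_steroids", PLAIN_DIAGNOSES, SEVERE_DIAGNOSES,
                    "length_of_stay", "outcome", "day_of_death")

default_prevalences <- function() {
  list(
    maternal_steroids = c(none = 0.117, partial = 0.189, full = 0.694),
    chorioamnionitis = 0.185, maternal_hypertension = 0.201,
    multiple_pregnancy = 0.357, male = 0.511, low_weight_p10 = 0.344,
    inborn = 0.945, level3 = 0.991, cesarean = 0.711,
    resuscitation = c(nil = 0.351, positive_pressure = 0.290,
                      intubation = 0.295, compressions = 0.026,
                      adrenaline = 0.038),
    postnatal_steroids = 0.063,
    rds = 0.640, pneumothorax = 0.049, pda = 0.359, nec = 0.077,
    gi_perforation = 0.027, early_sepsis = 0.047, late_sepsis = 0.336,
    ivh = 0.267, pvl = 0.063, rop = 0.216, bpd = 0.277,
    severe_rds = 0.348, severe_pda = 0.056, severe_nec = 0.049,
    severe_infection = 0.160, severe_rop = 0.042, severe_ivh = 0.094,
    severe_pvl = 0.026, severe_bpd = 0.145, severe_pneumothorax = 0.049,
    severe_anemia = 0.488
  )
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults reproduce the development-period marginals: binary/categorical
#' prevalences, gestational age median 29.1 with IQR 27.2-30.8 weeks
#' (truncated normal on 22-34 weeks), birth weight linear in GA (median
#' 1117 g at the GA median), overall mortality 14.8% and death timing split
#' (18.5%, 65.3%, 16.2%) across (<24 h, 24 h-30 d, >30 d).
#'
#' @param n Number of patients.
#' @param seed Integer root seed; all stage sub-seeds are derived from it.
#' @param prevalences Named list overriding entries of the default
#'   prevalence map (see `vlbwmort:::default_prevalences()`).
#' @param ga List `median`, `iqr` (length 2), `min`, `max` for the
#'   truncated-normal gestational age in decimal weeks.
#' @param bw_given_ga List `intercept`, `slope`, `sd` (grams) of the linear
#'   birth-weight-given-GA model, truncated to (300, 2000).
#' @param true_model `vlbw_model` used to generate outcomes (default:
#'   published prenatal model M1).
#' @param target_mortality Overall death probability the mechanism is
#'   calibrated to when `calibrate = TRUE` in [simulate_outcome()].
#' @param death_timing Probabilities of death in (<24 h, 24 h-30 d, >30 d);
#'   must sum to 1.
#' @param los List `size`, `pma_weeks`, `min_mu`: survivor length of stay is
#'   1 + negative binomial with mean `max(7 (pma_weeks - GA), min_mu)`.
#' @return A list of class `vlbw_cohort_config`.
#' @export
cohort_config <- function(n = 1000L, seed = 1L, prevalences = list(),
                          ga = list(median = 29.1, iqr = c(27.2, 30.8),
                                    min = 22, max = 34),
                          bw_given_ga = list(intercept = -1793, slope = 100,
                                             sd = 180),
                          true_model = NULL,
                          target_mortality = 0.148,
                          death_timing = c(0.185, 0.653, 0.162),
                          los = list(size = 8, pma_weeks = 36.5, min_mu = 2)) {
  prev <- modifyList(default_prevalences(), prevalences)
  for (nm in names(prev)) {
    p <- prev[[nm]]
    if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
      stop("configuration error: prevalence '", nm, "' outside [0, 1]")
    if (length(p) > 1 && abs(sum(p) - 1) > 1e-9)
      stop("configuration error: probabilities of '", nm, "' must sum to 1")
  }
  if (!is.finite(target_mortality) || target_mortality < 0 ||
      target_mortality > 1)
    stop("configuration error: 'target_mortality' outside [0, 1]")
  if (length(death_timing) != 3L || any(death_timing < 0) ||
      any(death_timing > 1) || abs(sum(death_timing) - 1) > 1e-9)
    stop("configuration error: 'death_timing' must be 3 probabilities summing to 1")
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 prevalences = prev, ga = ga, bw_given_ga = bw_given_ga,
                 true_model = true_model, target_mortality = target_mortality,
                 death_timing = death_timing, los = los),
            class = "vlbw_cohort_config")
}

# deterministic per-stage sub-seed derived from the root seed
stage_seed <- function(seed, stage) (abs(seed) + 104729L * stage) %% 2147483647L

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

rcat <- function(n, probs) {
  if (n == 0L) return(character(0))
  names(probs)[1L + findInterval(runif(n), cumsum(probs), left.open = TRUE)]
}

#' Generate perinatal covariates for a synthetic cohort
#'
#' Draws the perinatal/neonatal variables (outcome and diagnoses unset):
#' GA from a truncated normal matched to the configured median/IQR, birth
#' weight increasing in GA, Apgar scores decreasing with resuscitation
#' severity, plus all marginal binary/categorical fields. Deterministic
#' given `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return A data frame with one row per patient.
#' @export
generate_covariates <- function(config = cohort_config()) {
  stopifnot(inherits(config, "vlbw_cohort_config"))
  set.seed(stage_seed(config$seed, 1L))
  n <- config$n
  pv <- config$prevalences
  ga_cfg <- config$ga
  mu <- ga_cfg$median
  sd <- diff(ga_cfg$iqr) / (2 * qnorm(0.75))
  u <- runif(n, pnorm(ga_cfg$min, mu, sd), pnorm(ga_cfg$max, mu, sd))
  ga <- round(qnorm(u, mu, sd), 2)
  bw_cfg <- config$bw_given_ga
  bw <- as.integer(round(clamp(bw_cfg$intercept + bw_cfg$slope * ga +
                                 rnorm(n, 0, bw_cfg$sd), 301, 1999)))
  resus <- rcat(n, pv$resuscitation)
  resus_level <- match(resus, RESUS_LEVELS) - 1L
  apgar5 <- as.integer(clamp(round(9.5 - 0.8 * resus_level +
                                     rnorm(n, 0, 1.1)), 0, 10))
  apgar1 <- as.integer(clamp(round(apgar5 - 1.6 + rnorm(n, 0, 1.2)), 0, 10))
  data.frame(
    id = sprintf("P%06d", seq_len(n)),
    maternal_steroids = rcat(n, pv$maternal_steroids),
    chorioamnionitis = rbinom(n, 1, pv$chorioamnionitis),
    maternal_hypertension = rbinom(n, 1, pv$maternal_hypertension),
    multiple_pregnancy = rbinom(n, 1, pv$multiple_pregnancy),
    sex = ifelse(rbinom(n, 1, pv$male) == 1, "male", "female"),
    gestational_age = ga,
    birth_weight = bw,
    low_weight_p10 = rbinom(n, 1, pv$low_weight_p10),
    inborn = rbinom(n, 1, pv$inborn),
    level_of_care = ifelse(rbinom(n, 1, pv$level3) == 1, 3L, 2L),
    cesarean = rbinom(n, 1, pv$cesarean),
    resuscitation = resus,
    apgar1 = apgar1,
    apgar5 = apgar5,
    admission_temp = round(rnorm(n, 36.0, 0.74), 1),
    crib1 = as.integer(rnbinom(n, size = 1.5, mu = exp(7.0 - 0.23 * ga))),
    postnatal_steroids = rbinom(n, 1, pv$postnatal_steroids),
    stringsAsFactors = FALSE
  )
}

# Per-patient diagnosis probability with logit-linear GA dependence,
# calibrated (deterministically, by root finding on the realised GA vector)
# so the cohort mean equals the configured marginal prevalence.
ga_linked_prob <- function(prev, slope, ga, ga_median) {
  if (length(ga) == 0L) return(numeric(0))
  if (prev <= 0 || prev >= 1 || slope == 0) return(rep(prev, length(ga)))
  eta <- qlogis(prev) + slope * (ga_median - ga)
  delta <- uniroot(function(d) mean(plogis(eta + d)) - prev,
                   c(-15, 15), tol = 1e-10)$root
  plogis(eta + delta)
}

#' Assign diagnosis and severity flags
#'
#' Plain diagnosis flags are drawn at the configured marginal prevalences;
#' RDS, IVH and NEC risk decreases with gestational age (logit-linear,
#' mean-calibrated to the marginal). Each severe flag is drawn conditional
#' on its plain counterpart so severe implies plain; advanced resuscitation
#' is derived from the resuscitation field (intubation, chest compressions
#' or adrenaline); severe invasive infection is conditional on any sepsis;
#' severe anemia is independent.
#'
#' @param patients Output of [generate_covariates()].
#' @param config The same [cohort_config()].
#' @return `patients` with the 22 diagnosis columns appended.
#' @export
assign_diagnoses <- function(patients, config = cohort_config()) {
  stopifnot(inherits(config, "vlbw_cohort_config"))
  set.seed(stage_seed(config$seed, 2L))
  n <- nrow(patients)
  pv <- config$prevalences
  ga <- patients$gestational_age
  for (d in PLAIN_DIAGNOSES) {
    slope <- if (d %in% names(GA_DIAG_SLOPES)) GA_DIAG_SLOPES[[d]] else 0
    p <- ga_linked_prob(pv[[d]], slope, ga, config$ga$median)
    patients[[d]] <- rbinom(n, 1, p)
  }
  patients$advanced_resuscitation <-
    as.integer(patients$resuscitation %in%
                 c("intubation", "compressions", "adrenaline"))
  for (sv in names(SEVERE_PAIRS)) {
    plain <- SEVERE_PAIRS[[sv]]
    cond <- if (pv[[plain]] > 0) min(1, pv[[sv]] / pv[[plain]]) else 0
    patients[[sv]] <- patients[[plain]] * rbinom(n, 1, cond)
  }
  p_any_sepsis <- 1 - (1 - pv$early_sepsis) * (1 - pv$late_sepsis)
  cond_inf <- if (p_any_sepsis > 0)
    min(1, pv$severe_infection / p_any_sepsis) else 0
  any_sepsis <- as.integer(patients$early_sepsis | patients$late_sepsis)
  patients$severe_infection <- any_sepsis * rbinom(n, 1, cond_inf)
  patients$severe_anemia <- rbinom(n, 1, pv$severe_anemia)
  patients[, union(names(patients), c(PLAIN_DIAGNOSES, SEVERE_DIAGNOSES)),
           drop = FALSE]
}

#' Simulate hospital outcome, day of death and length of stay
#'
#' Applies the generating model to every patient, draws the outcome as
#' Bernoulli(p_i) with p_i = 1/(1+exp(-z_i)), assigns the day of death by a
#' multinomial over the three timing windows (<24 h -> day 1; 24 h-30 d ->
#' uniform on days 2-30; >30 d -> uniform on days 31-90), and draws
#' survivor length of stay as a shifted negative binomial with mean
#' decreasing in GA. For deaths, length of stay equals the day of death.
#'
#' @param patients Cohort with all predictors required by `true_model`.
#' @param true_model Generating `vlbw_model` (default published M1).
#' @param config The [cohort_config()] (timing, length-of-stay and seed).
#' @param day_of_life Day of life at which a dynamic generating model is
#'   evaluated (default 1; ignored by static models).
#' @param calibrate If `TRUE`, the intercept is shifted so the mean
#'   generated probability equals `config$target_mortality`.
#' @return `patients` with columns `p_true`, `outcome`, `day_of_death`,
#'   `length_of_stay` appended.
#' @export
simulate_outcome <- function(patients, true_model = NULL,
                             config = cohort_config(), day_of_life = 1L,
                             calibrate = FALSE) {
  stopifnot(inherits(config, "vlbw_cohort_config"))
  true_model <- true_model %||% config$true_model %||% published_model("M1")
  need <- setdiff(true_model$terms$variable[true_model$terms$type != "days"],
                  names(patients))
  if (length(need))
    stop("predictors missing from the table: ", paste(need, collapse = ", "))
  set.seed(stage_seed(config$seed, 3L))
  n <- nrow(patients)
  z <- linear_predictor(true_model, patients,
                        day_of_life = if (any(true_model$terms$type == "days") ||
                                          !is.null(true_model$stratum))
                          rep_len(day_of_life, n) else NULL)
  if (calibrate && n > 0) {
    off <- uniroot(function(d) mean(plogis(z + d)) - config$target_mortality,
                   c(-30, 30), tol = 1e-10)$root
    z <- z + off
  }
  p <- plogis(z)
  died <- rbinom(n, 1, p) == 1
  window <- rep(NA_integer_, n)
  window[died] <- 1L + findInterval(runif(sum(died)),
                                    cumsum(config$death_timing),
                                    left.open = TRUE)
  dod <- rep(NA_integer_, n)
  dod[which(window == 1L)] <- 1L
  n2 <- sum(window == 2L, na.rm = TRUE)
  dod[which(window == 2L)] <- as.integer(sample(2:30, n2, replace = TRUE))
  n3 <- sum(window == 3L, na.rm = TRUE)
  dod[which(window == 3L)] <- as.integer(sample(31:90, n3, replace = TRUE))
  los_cfg <- config$los
  los <- 1L + rnbinom(n, size = los_cfg$size,
                      mu = pmax(7 * (los_cfg$pma_weeks -
                                       patients$gestational_age),
                                los_cfg$min_mu))
  los[died] <- dod[died]
  # 12 decimals so cohort CSVs round-trip bitwise through read.csv
  patients$p_true <- round(p, 12)
  patients$outcome <- ifelse(died, "died", "survived")
  patients$day_of_death <- dod
  patients$length_of_stay <- as.integer(los)
  patients
}

#' Generate a complete synthetic cohort
#'
#' Runs [generate_covariates()], [assign_diagnoses()] and
#' [simulate_outcome()] with sub-seeds derived from `config$seed`.
#'
#' @inheritParams simulate_outcome
#' @param config A [cohort_config()].
#' @return A complete patient-level data frame.
#' @export
simulate_cohort <- function(config = cohort_config(), true_model = NULL,
                            day_of_life = 1L, calibrate = FALSE) {
  x <- generate_covariates(config)
  x <- assign_diagnoses(x, config)
  simulate_outcome(x, true_model = true_model, config = config,
                   day_of_life = day_of_life, calibrate = calibrate)
}

#' Validate patient-record invariants
#'
#' Checks the record-level invariants (Apgar ranges, GA in 22-34 weeks,
#' birth weight in (300, 2000) g, length of stay >= 1, day of death present
#' iff died and not after discharge, severe flag implies plain flag, enum
#' tokens valid). Used by [read_cohort()] and available directly.
#'
#' @param cohort A patient-level data frame.
#' @return Invisibly `TRUE`; otherwise an error listing violations with row
#'   numbers.
#' @export
validate_cohort <- function(cohort) {
  problems <- character(0)
  note <- function(rows, msg) {
    if (length(rows))
      problems <<- c(problems, paste0(msg, " (rows ",
                                      paste(utils::head(rows, 5),
                                            collapse = ", "),
                                      if (length(rows) > 5) ", ..." else "",
                                      ")"))
  }
  chk_range <- function(col, lo, hi, open = FALSE) {
    if (!col %in% names(cohort)) return()
    x <- cohort[[col]]
    bad <- if (open) which(x <= lo | x >= hi) else which(x < lo | x > hi)
    note(bad, paste0("'", col, "' outside ", if (open) "(" else "[", lo, ", ",
                     hi, if (open) ")" else "]"))
  }
  chk_range("apgar1", 0, 10); chk_range("apgar5", 0, 10)
  chk_range("gestational_age", 22, 34)
  chk_range("birth_weight", 300, 2000, open = TRUE)
  if ("length_of_stay" %in% names(cohort))
    note(which(cohort$length_of_stay < 1), "'length_of_stay' < 1")
  if (all(c("outcome", "day_of_death") %in% names(cohort))) {
    died <- cohort$outcome == "died"
    note(which(died & is.na(cohort$day_of_death)),
         "'day_of_death' absent for a death")
    note(which(!died & !is.na(cohort$day_of_death)),
         "'day_of_death' present for a survivor")
    if ("length_of_stay" %in% names(cohort))
      note(which(died & cohort$day_of_death > cohort$length_of_stay),
           "'day_of_death' after discharge")
  }
  for (sv in names(SEVERE_PAIRS)) {
    plain <- SEVERE_PAIRS[[sv]]
    if (all(c(sv, plain) %in% names(cohort)))
      note(which(cohort[[sv]] == 1 & cohort[[plain]] == 0),
           paste0("'", sv, "' set without '", plain, "'"))
  }
  enums <- list(maternal_steroids = STEROID_LEVELS,
                sex = c("female", "male"), resuscitation = RESUS_LEVELS,
                outcome = c("survived", "died"))
  for (col in names(enums)) {
    if (!col %in% names(cohort)) next
    note(which(!cohort[[col]] %in% enums[[col]]),
         paste0("invalid token in '", col, "'"))
  }
  if (length(problems))
    stop("cohort validation failed:\n  ", paste(problems, collapse = "\n  "))
  invisible(TRUE)
}
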