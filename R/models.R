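# Scoring engine for the staged mortality equations.
#
# A model spec is a list with class "vlbw_model": intercept (+ SE), an
# ordered term table, and for the dynamic sub-models an applicability
# stratum in days of life. Published specs are read from a versioned data
# file so that published and re-derived models share one code path.

MODEL_IDS <- c("M1", "M2", "M3_early", "M3_late")
RISK_CATEGORIES <- c("mild", "moderate", "severe", "very_severe")

#' Construct a model specification
#'
#' @param model_id One of `"M1"`, `"M2"`, `"M3_early"`, `"M3_late"`, or a
#'   free-form identifier for re-derived models.
#' @param intercept,intercept_se Intercept estimate and its standard error.
#' @param terms A data frame with columns `term` (label), `type` (one of
#'   `"numeric"`, `"flag"`, `"indicator"`, `"indicator_any"`, `"days"`),
#'   `variable` (source column; ignored for `"days"`), `level` /`levels`
#'   (for indicators), `scale` (divisor for numeric terms, e.g. 100 for
#'   birth weight in g/100), `beta` and `se`.
#' @param stratum `NULL`, or `list(min_day=, max_day=)` giving the
#'   days-of-life window in which the model applies (`max_day = Inf` for an
#'   open window).
#' @param label Human-readable label.
#' @return An object of class `vlbw_model`.
#' @export
model_spec <- function(model_id, intercept, intercept_se = NA_real_, terms,
                       stratum = NULL, label = model_id) {
  stopifnot(is.character(model_id), length(model_id) == 1L,
            is.numeric(intercept), is.data.frame(terms))
  needed <- c("term", "type", "variable", "beta", "se")
  miss <- setdiff(needed, names(terms))
  if (length(miss))
    stop("model terms table lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(terms$term))
    stop("duplicate term labels in model '", model_id, "'")
  if (any(!is.na(terms$se) & terms$se <= 0))
    stop("all standard errors must be positive")
  if (!"scale" %in% names(terms)) terms$scale <- rep(1, nrow(terms))
  terms$scale[is.na(terms$scale)] <- 1
  structure(list(model_id = model_id, label = label,
                 intercept = intercept, intercept_se = intercept_se,
                 terms = terms, stratum = stratum),
            class = "vlbw_model")
}

#' @export
print.vlbw_model <- function(x, ...) {
  cat(sprintf("<vlbw_model %s: %s>\n", x$model_id, x$label))
  cat(sprintf("  intercept %.4g (SE %.4g), %d terms", x$intercept,
              x$intercept_se, nrow(x$terms)))
  if (!is.null(x$stratum))
    cat(sprintf(", days %s-%s", x$stratum$min_day,
                ifelse(is.finite(x$stratum$max_day), x$stratum$max_day, "Inf")))
  cat("\n")
  invisible(x)
}

published_constants <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "published_models.json",
                          package = "vlbwmort", mustWork = TRUE)
      cache <<- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    }
    cache
  }
})

#' Published model specifications
#'
#' Returns the published logistic equation for one of the four models:
#' prenatal (`M1`), 24 hours of life (`M2`), and the two strata of the
#' dynamic during-admission model (`M3_early`, days 1-30; `M3_late`,
#' day 31 onwards). Coefficients, standard errors and the printed odds
#' ratios / 95% CIs are shipped verbatim in a versioned data file.
#'
#' @param model_id One of `"M1"`, `"M2"`, `"M3_early"`, `"M3_late"`.
#' @return A `vlbw_model`. The term table additionally carries the printed
#'   `or`, `ci_low`, `ci_high` columns for reference.
#' @export
published_model <- function(model_id = MODEL_IDS) {
  model_id <- match.arg(model_id)
  m <- published_constants()$models[[model_id]]
  terms <- do.call(rbind, lapply(m$terms, function(t) {
    data.frame(term = t[["term"]], type = t[["type"]],
               variable = t[["variable"]] %||% NA_character_,
               level = t[["level"]] %||% NA_character_,
               levels = paste(unlist(t[["levels"]] %||% character()),
                              collapse = "|"),
               scale = t[["scale"]] %||% 1,
               beta = t[["beta"]], se = t[["se"]],
               or = t[["or"]] %||% NA_real_,
               ci_low = t[["ci_low"]] %||% NA_real_,
               ci_high = t[["ci_high"]] %||% NA_real_,
               stringsAsFactors = FALSE)
  }))
  stratum <- m$stratum
  if (!is.null(stratum))
    stratum$max_day <- stratum$max_day %||% Inf
  model_spec(model_id, m$intercept, m$intercept_se, terms,
             stratum = stratum, label = m$label)
}

#' Published category bands and Kappa-optimal cut points
#'
#' The three ascending probability thresholds that split predicted death
#' probability into the four prognosis categories (mild / moderate / severe
#' / very severe, i.e. mortality 0-20% / 21-50% / 51-80% / 81-100% bands
#' derived via the false negative rate), and the published Kappa-optimal
#' classification cut point for each model.
#'
#' @param model_id One of `"M1"`, `"M2"`, `"M3_early"`, `"M3_late"`.
#' @return `published_bands()`: an object of class `vlbw_bands` —
#'   `list(thresholds, provenance)`. `published_cutoff()`: a single number.
#' @export
published_bands <- function(model_id = MODEL_IDS) {
  model_id <- match.arg(model_id)
  category_bands(unlist(published_constants()$bands[[model_id]]),
                 provenance = "published_table4")
}

#' @rdname published_bands
#' @export
published_cutoff <- function(model_id = MODEL_IDS) {
  model_id <- match.arg(model_id)
  published_constants()$cutoffs[[model_id]]
}

#' Construct category bands
#'
#' @param thresholds Three strictly increasing probabilities in (0,1).
#' @param provenance `"published_table4"` or `"derived_from_data"`.
#' @return An object of class `vlbw_bands`.
#' @export
category_bands <- function(thresholds, provenance = "derived_from_data") {
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) != 3L || any(!is.finite(thresholds)))
    stop("bands need exactly three finite thresholds")
  if (any(diff(thresholds) <= 0))
    stop("band thresholds must be strictly increasing")
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("band thresholds must lie in (0, 1)")
  structure(list(thresholds = thresholds, provenance = provenance),
            class = "vlbw_bands")
}

# Resolve one term of a model spec to its numeric design value(s).
term_value <- function(t, data, day_of_life) {
  if (t$type == "days") {
    if (is.null(day_of_life))
      stop("model requires 'day_of_life' (days of life) but none was given")
    return(as.numeric(day_of_life))
  }
  v <- t$variable
  if (!v %in% names(data))
    stop("predictor '", v, "' required by term '", t$term,
         "' is missing from the data")
  x <- data[[v]]
  switch(t$type,
    numeric = as.numeric(x) / t$scale,
    flag = {
      x <- as.numeric(x)
      if (any(!x %in% c(0, 1) & !is.na(x)))
        stop("flag predictor '", v, "' must be 0/1")
      x
    },
    indicator = as.numeric(as.character(x) == t$level),
    indicator_any = as.numeric(as.character(x) %in%
                                 strsplit(t$levels, "|", fixed = TRUE)[[1]]),
    stop("unknown term type '", t$type, "'")
  )
}

#' Linear predictor of a mortality model
#'
#' Computes z = intercept + sum of beta_j x_j with the model's exact
#' encodings (steroids reference level "none"; level-of-care indicator is 1
#' for level 2; birth weight in g/100; gestational age in decimal weeks).
#' Vectorised over the rows of `data`.
#'
#' @param model A `vlbw_model`.
#' @param data A data frame of patient records (one or more rows).
#' @param day_of_life Integer day(s) of life, required by the dynamic
#'   sub-models; recycled against rows of `data`.
#' @return Numeric vector of log-odds of death, one per row.
#' @export
linear_predictor <- function(model, data, day_of_life = NULL) {
  stopifnot(inherits(model, "vlbw_model"))
  if (is.data.frame(data) == FALSE) data <- as.data.frame(data)
  if (!is.null(model$stratum) && !is.null(day_of_life)) {
    bad <- day_of_life < model$stratum$min_day |
      day_of_life > (model$stratum$max_day %||% Inf)
    if (any(bad))
      stop("model '", model$model_id, "' applied outside its stratum (days ",
           model$stratum$min_day, "-", model$stratum$max_day, "): day(s) ",
           paste(unique(day_of_life[bad]), collapse = ", "))
  }
  z <- rep_len(model$intercept, nrow(data))
  tt <- model$terms
  for (i in seq_len(nrow(tt))) {
    t <- as.list(tt[i, ])
    z <- z + t$beta * term_value(t, data, day_of_life)
  }
  z
}

#' Death probability from the linear predictor
#'
#' Probability of death = 1 / (1 + exp(-z)); survival probability is its
#' complement (reported in percent as 100 - mortality by the formatter).
#'
#' @param z Finite numeric log-odds.
#' @return Probabilities in (0, 1).
#' @export
death_probability <- function(z) {
  if (any(!is.finite(z)))
    stop("non-finite linear predictor")
  stats::plogis(z)
}

#' Odds ratio and Wald 95% confidence interval for a coefficient
#'
#' @param beta Coefficient estimate.
#' @param se Standard error, must be positive.
#' @return Named numeric vector `c(or, ci_low, ci_high)` with
#'   OR = exp(beta) and CI = exp(beta +/- 1.96 se).
#' @export
odds_ratio <- function(beta, se) {
  if (any(se <= 0)) stop("standard error must be positive")
  cbind(or = exp(beta), ci_low = exp(beta - 1.96 * se),
        ci_high = exp(beta + 1.96 * se))[ , , drop = TRUE]
}

#' Map a death probability to its prognosis category
#'
#' Intervals are `[0, t1]` -> mild, `(t1, t2]` -> moderate, `(t2, t3]` ->
#' severe, `(t3, 1]` -> very severe: a boundary value belongs to the lower
#' interval.
#'
#' @param p_death Probabilities in `[0, 1]`.
#' @param bands A `vlbw_bands` object.
#' @return Factor with levels mild < moderate < severe < very_severe.
#' @export
categorize_risk <- function(p_death, bands) {
  stopifnot(inherits(bands, "vlbw_bands"))
  if (any(p_death < 0 | p_death > 1, na.rm = TRUE))
    stop("probabilities must lie in [0, 1]")
  idx <- 1L + (p_death > bands$thresholds[1]) + (p_death > bands$thresholds[2]) +
    (p_death > bands$thresholds[3])
  factor(RISK_CATEGORIES[idx], levels = RISK_CATEGORIES, ordered = TRUE)
}

#' Select the dynamic sub-model for a day of life
#'
#' @param day_of_life Integer day(s) of life, >= 1.
#' @return `"M3_early"` for days 1-30, `"M3_late"` from day 31 on.
#' @export
select_submodel <- function(day_of_life) {
  if (any(day_of_life < 1)) stop("day of life must be >= 1")
  ifelse(day_of_life <= 30, "M3_early", "M3_late")
}

#' Score a cohort with a mortality model
#'
#' Convenience wrapper producing the calculator's outputs for every row:
#' linear predictor, death/survival probability and prognosis category.
#' With `model = "M3"` the sub-model is chosen per row from `day_of_life`.
#'
#' @param data Patient records.
#' @param model A `vlbw_model`, or `"M3"` for day-routed dynamic scoring.
#' @param day_of_life Day(s) of life (required for dynamic models).
#' @param bands A `vlbw_bands`, or `NULL` to use the published bands of the
#'   scoring model.
#' @return `data` with columns `model_id`, `z`, `p_death`, `p_survival`,
#'   `category` appended.
#' @export
score_cohort <- function(data, model, day_of_life = NULL, bands = NULL) {
  if (identical(model, "M3")) {
    if (is.null(day_of_life)) stop("dynamic scoring requires 'day_of_life'")
    day_of_life <- rep_len(day_of_life, nrow(data))
    ids <- select_submodel(day_of_life)
    out <- data
    out$model_id <- ids
    out$z <- NA_real_
    for (id in unique(ids)) {
      sel <- ids == id
      out$z[sel] <- linear_predictor(published_model(id), data[sel, , drop = FALSE],
                                     day_of_life[sel])
    }
    bands_by <- lapply(setNames(unique(ids), unique(ids)), function(id)
      bands %||% published_bands(id))
    out$p_death <- death_probability(out$z)
    out$p_survival <- 1 - out$p_death
    out$category <- NA_character_
    for (id in unique(ids)) {
      sel <- ids == id
      out$category[sel] <-
        as.character(categorize_risk(out$p_death[sel], bands_by[[id]]))
    }
    return(out)
  }
  stopifnot(inherits(model, "vlbw_model"))
  if (is.null(bands) && model$model_id %in% MODEL_IDS)
    bands <- published_bands(model$model_id)
  out <- data
  out$model_id <- model$model_id
  out$z <- linear_predictor(model, data, day_of_life)
  out$p_death <- death_probability(out$z)
  out$p_survival <- 1 - out$p_death
  out$category <- if (!is.null(bands))
    as.character(categorize_risk(out$p_death, bands)) else NA_character_
  out
}

#' Format a probability as the calculator prints it
#'
#' @param p Probability in `[0, 1]`.
#' @return Percentage rounded to one decimal (e.g. 18.5 for 0.18511).
#' @export
as_percent <- function(p) round(100 * p, 1)
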