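# End-to-end orchestration: simulate -> develop -> validate -> predict.
# Every machine-readable artifact is stamped with the seed and a hash of
# the configuration, so any number is regenerable from config + seed alone.

# Stable polynomial fingerprint of a string (config stamping only, not
# cryptographic); avoids adding a digest dependency.
config_fingerprint <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Default pipeline configuration
#'
#' @param seed Root integer seed.
#' @param n_dev,n_val Development / validation cohort sizes.
#' @param model Model to validate: `"M1"`, `"M2"` or `"M3"` (dynamic).
#' @param bands `"published"` or `"derived"` band provenance.
#' @param calibrate Calibrate generator mortality to the configured target.
#' @return A named list understood by [run_pipeline()].
#' @export
pipeline_config <- function(seed = 1L, n_dev = 8734L, n_val = 6219L,
                            model = "M1", bands = "published",
                            calibrate = FALSE) {
  list(seed = as.integer(seed), n_dev = as.integer(n_dev),
       n_val = as.integer(n_val), model = model, bands = bands,
       calibrate = calibrate)
}

stamp <- function(config) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  list(seed = config$seed,
       config_hash = config_fingerprint(as.character(cfg_json)))
}

write_report <- function(obj, path) {
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, na = "null", force = TRUE)
  invisible(path)
}

#' Run the full pipeline
#'
#' Stages (all by default): `simulate` writes development and validation
#' cohort CSVs generated from the published prenatal mechanism; `develop`
#' refits the three models on the development cohort (including the
#' pseudo-day expansion for the dynamic model), selects Kappa-optimal
#' cutoffs and derives FNR bands, writing model-spec files and a
#' development report; `validate` scores the validation cohort with the
#' chosen model and bands and writes an evaluation report (including the
#' real-time per-day scenario for the dynamic model); `predict` scores an
#' arbitrary cohort CSV. Identical seeds yield byte-identical
#' machine-readable artifacts.
#'
#' @param config A [pipeline_config()] list or path to a JSON file of the
#'   same shape.
#' @param out_dir Output directory (created if needed).
#' @param stages Subset of `c("simulate", "develop", "validate")` to run.
#' @return Named list of artifact paths, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = ".",
                         stages = c("simulate", "develop", "validate")) {
  if (is.character(config)) config <- jsonlite::fromJSON(config)
  config <- modifyList(pipeline_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- stamp(config)
  paths <- list()
  p <- function(f) file.path(out_dir, f)

  if ("simulate" %in% stages) {
    dev <- simulate_cohort(cohort_config(n = config$n_dev, seed = config$seed),
                           calibrate = config$calibrate)
    val <- simulate_cohort(cohort_config(n = config$n_val,
                                         seed = config$seed + 1L),
                           calibrate = config$calibrate)
    paths$cohort_dev <- write_cohort(dev, p("cohort_dev.csv"))
    paths$cohort_val <- write_cohort(val, p("cohort_val.csv"))
  }

  if ("develop" %in% stages) {
    dev <- encode_design(read_cohort(p("cohort_dev.csv")))
    m1_vars <- c("level2", "gestational_age", "low_weight_p10", "male",
                 "steroids_partial", "steroids_full", "multiple_pregnancy")
    m2_vars <- c(m1_vars, "bw100", "apgar5", "maternal_hypertension",
                 "advanced_resuscitation", "admission_temp", "severe_rds")
    presel <- preselect_variables(dev, unique(c(m2_vars, PLAIN_DIAGNOSES)))
    kept <- m1_vars[m1_vars %in% presel$variable[presel$selected]]
    if (length(kept) < length(m1_vars))
      message("preselection dropped from M1: ",
              paste(setdiff(m1_vars, kept), collapse = ", "))
    fits <- list(M1 = fit_logistic(dev, "outcome", kept, model_id = "M1_fit"),
                 M2 = fit_logistic(dev, "outcome", m2_vars, model_id = "M2_fit"))
    dyn <- fit_dynamic_model3(dev)
    fits$M3_early <- dyn$early
    fits$M3_late <- dyn$late
    expanded <- encode_design(expand_pseudo_days(dev))
    eval_rows <- list(M1 = dev, M2 = dev,
                      M3_early = expanded[expanded$days_of_life <= 30, ],
                      M3_late = expanded[expanded$days_of_life > 30, ])
    dev_report <- list(meta = meta, preselection = presel, models = list())
    for (id in names(fits)) {
      f <- fits[[id]]
      paths[[paste0("model_", id)]] <-
        write_model_spec(f$spec, p(paste0("model_", id, ".json")))
      probs <- death_probability(linear_predictor(f$spec, eval_rows[[id]]))
      yy <- eval_rows[[id]]$outcome
      cut <- select_cutoff_max_kappa(probs, yy)
      bands <- derive_fnr_thresholds(probs, yy)
      dev_report$models[[id]] <- list(
        coefficients = f$coefficients, n = f$n, converged = f$converged,
        dropped = f$dropped, loglik = f$loglik, loglik_null = f$loglik_null,
        nagelkerke_r2 = nagelkerke_r2(f$loglik, f$loglik_null, f$n),
        cutoff = cut$cutoff, train_kappa = cut$kappa,
        fnr_bands = bands$thresholds)
    }
    paths$development_report <- write_report(dev_report,
                                             p("development_report.json"))
  }

  if ("validate" %in% stages) {
    val <- encode_design(read_cohort(p("cohort_val.csv")))
    use_published <- identical(config$bands, "published")
    dev_report <- if (file.exists(p("development_report.json")))
      jsonlite::fromJSON(p("development_report.json")) else NULL
    model_arg <- config$model
    if (identical(model_arg, "M3")) {
      day1 <- apply_time_windows(val, 1)
      probs <- death_probability(
        linear_predictor(published_model("M3_early"), day1, day_of_life = 1))
      cutoff <- published_cutoff("M3_early")
      bands <- published_bands("M3_early")
      rts <- real_time_scenario(val)
    } else {
      spec <- if (use_published || is.null(dev_report))
        published_model(model_arg)
      else read_model_spec(p(paste0("model_", model_arg, ".json")))
      probs <- death_probability(linear_predictor(spec, val))
      cutoff <- if (use_published || is.null(dev_report))
        published_cutoff(model_arg)
      else dev_report$models[[model_arg]]$cutoff
      bands <- if (use_published || is.null(dev_report))
        published_bands(model_arg)
      else category_bands(dev_report$models[[model_arg]]$fnr_bands)
      rts <- NULL
    }
    rep <- evaluate_model(probs, val$outcome, cutoff, bands = bands)
    out <- list(meta = meta, model = model_arg,
                bands_provenance = config$bands,
                report = unclass(rep),
                death_timing = death_timing_summary(val),
                real_time = if (!is.null(rts)) rts else NULL)
    paths$validation_report <- write_report(out, p("validation_report.json"))
  }

  invisible(paths)
}

#' Score a cohort CSV with a mortality model (predict stage)
#'
#' @param input Path to a cohort CSV.
#' @param output Path for the scored CSV.
#' @param model `"M1"`, `"M2"`, `"M3"` (day-routed) or a path to a
#'   model-spec JSON.
#' @param day_of_life Day of life (required for `"M3"`); a scalar or the
#'   name of a column of the input.
#' @return The scored data frame, invisibly; writes `output`.
#' @export
predict_csv <- function(input, output, model = "M1", day_of_life = NULL) {
  x <- encode_design(read_cohort(input, validate = FALSE))
  if (is.character(day_of_life) && day_of_life %in% names(x))
    day_of_life <- x[[day_of_life]]
  m <- if (identical(model, "M3")) "M3"
  else if (model %in% MODEL_IDS) published_model(model)
  else read_model_spec(model)
  scored <- score_cohort(x, m, day_of_life = day_of_life)
  write_cohort(scored, output)
  invisible(scored)
}
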