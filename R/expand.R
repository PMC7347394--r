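# Pseudo-evolution day expansion.
#
# Each patient record is replicated over a fixed set of standardized
# in-stay days (capped at the actual stay, and at the day of death for
# deaths), and diagnoses that only apply in predetermined time intervals
# are gated off outside their window. Gating applies to the plain flag and
# its severe counterpart alike. The outcome label on every expanded row is
# the patient's final hospital outcome.

#' Expansion rule: standardized days and diagnosis time-windows
#'
#' Defaults are the standardized day set {1, 3, 8, 15, 22, 31, 46, 61} and
#' the diagnosis windows: RDS days 0-7, NEC days 14-45, IVH days 0-10, PVL
#' after day 21, BPD after day 28 (open windows are encoded as min_day =
#' start+1, max_day = Inf).
#'
#' @param standardized_days Strictly increasing integer days.
#' @param windows Named list `diagnosis = c(min_day, max_day)` (inclusive).
#' @return A list of class `vlbw_expansion_rule`.
#' @export
expansion_rule <- function(standardized_days = c(1L, 3L, 8L, 15L, 22L, 31L,
                                                 46L, 61L),
                           windows = list(rds = c(0, 7), nec = c(14, 45),
                                          ivh = c(0, 10), pvl = c(22, Inf),
                                          bpd = c(29, Inf))) {
  if (any(diff(standardized_days) <= 0))
    stop("standardized days must be strictly increasing")
  for (w in names(windows))
    if (windows[[w]][1] > windows[[w]][2])
      stop("window start after end for '", w, "'")
  structure(list(standardized_days = as.integer(standardized_days),
                 windows = windows),
            class = "vlbw_expansion_rule")
}

#' Gate diagnosis flags by their time-windows
#'
#' A windowed diagnosis flag is retained iff `min_day <= pseudo_day <=
#' max_day`; the severe counterpart of a windowed diagnosis obeys the same
#' window. Non-windowed variables pass through unchanged.
#'
#' @param records One or more patient records (data frame).
#' @param pseudo_day Day of stay, >= 1 (scalar).
#' @param rule An [expansion_rule()].
#' @return `records` with out-of-window flags set to 0.
#' @export
apply_time_windows <- function(records, pseudo_day, rule = expansion_rule()) {
  stopifnot(inherits(rule, "vlbw_expansion_rule"), pseudo_day >= 1)
  for (d in names(rule$windows)) {
    w <- rule$windows[[d]]
    if (pseudo_day >= w[1] && pseudo_day <= w[2]) next
    for (col in intersect(c(d, paste0("severe_", d)), names(records)))
      records[[col]] <- 0L * records[[col]]
  }
  records
}

#' Expand a cohort over standardized pseudo-days
#'
#' Produces one row per (patient, day) for every standardized day not
#' exceeding the patient's effective last day (length of stay; for deaths,
#' the day of death if earlier, so the already-dead are never scored).
#' Diagnosis time-windows are applied per day, a `days_of_life` column
#' carries the pseudo-day, and the outcome label is the final hospital
#' outcome on every row.
#'
#' @param cohort Patient-level data frame with `length_of_stay` (and
#'   `outcome`/`day_of_death` if present).
#' @param rule An [expansion_rule()].
#' @return Expanded data frame with `days_of_life` after `id`.
#' @export
expand_pseudo_days <- function(cohort, rule = expansion_rule()) {
  stopifnot(inherits(rule, "vlbw_expansion_rule"))
  if (!"length_of_stay" %in% names(cohort))
    stop("cohort lacks 'length_of_stay'")
  if (any(cohort$length_of_stay < 1))
    stop("length of stay must be >= 1 for every patient")
  last_day <- cohort$length_of_stay
  if (all(c("outcome", "day_of_death") %in% names(cohort))) {
    died <- cohort$outcome == "died" & !is.na(cohort$day_of_death)
    last_day[died] <- pmin(last_day[died], cohort$day_of_death[died])
  }
  pieces <- lapply(rule$standardized_days, function(d) {
    sub <- cohort[last_day >= d, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    sub <- apply_time_windows(sub, d, rule)
    sub$days_of_life <- d
    sub
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) {
    out <- cohort[0, , drop = FALSE]
    out$days_of_life <- integer(0)
  }
  rownames(out) <- NULL
  out[order(match(out$id, cohort$id), out$days_of_life), , drop = FALSE]
}
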