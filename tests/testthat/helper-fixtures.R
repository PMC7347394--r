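# Fixtures are built in code; nothing is read from disk.

# A single fully-specified patient record (survivor, benign profile).
base_patient <- function(...) {
  p <- data.frame(
    id = "P000001", maternal_steroids = "full", chorioamnionitis = 0L,
    maternal_hypertension = 0L, multiple_pregnancy = 0L, sex = "female",
    gestational_age = 29.0, birth_weight = 1200L, low_weight_p10 = 0L,
    inborn = 1L, level_of_care = 3L, cesarean = 1L, resuscitation = "nil",
    apgar1 = 7L, apgar5 = 9L, admission_temp = 36.0, crib1 = 1L,
    postnatal_steroids = 0L,
    rds = 0L, pneumothorax = 0L, pda = 0L, nec = 0L, gi_perforation = 0L,
    early_sepsis = 0L, late_sepsis = 0L, ivh = 0L, pvl = 0L, rop = 0L,
    bpd = 0L,
    advanced_resuscitation = 0L, severe_rds = 0L, severe_pda = 0L,
    severe_nec = 0L, severe_infection = 0L, severe_rop = 0L, severe_ivh = 0L,
    severe_pvl = 0L, severe_bpd = 0L, severe_pneumothorax = 0L,
    severe_anemia = 0L,
    length_of_stay = 40L, outcome = "survived", day_of_death = NA_integer_,
    stringsAsFactors = FALSE)
  mods <- list(...)
  for (nm in names(mods)) p[[nm]] <- mods[[nm]]
  p
}

# n copies of the base patient with ids and selected column overrides
# (each override vector is recycled to n rows).
patient_cohort <- function(n, ...) {
  co <- base_patient()[rep(1L, n), , drop = FALSE]
  co$id <- sprintf("P%06d", seq_len(n))
  mods <- list(...)
  for (nm in names(mods)) co[[nm]] <- rep_len(mods[[nm]], n)
  rownames(co) <- NULL
  co
}

file_bytes <- function(path) readBin(path, "raw", n = file.size(path))

# independent O(n^2) AUC oracle: exhaustive concordant-pair counting
auc_pairs <- function(scores, outcomes) {
  y <- if (is.numeric(outcomes)) outcomes else as.integer(outcomes == "died")
  pos <- scores[y == 1]; neg <- scores[y == 0]
  tot <- 0
  for (a in pos) tot <- tot + sum(a > neg) + 0.5 * sum(a == neg)
  tot / (length(pos) * length(neg))
}

# independent brute-force kappa-optimal cutoff oracle
kappa_of <- function(pred, y) {
  po <- mean(pred == y)
  pe <- mean(pred) * mean(y) + (1 - mean(pred)) * (1 - mean(y))
  if (pe == 1) 1 else (po - pe) / (1 - pe)
}
brute_cutoff <- function(scores, y) {
  cand <- sort(unique(scores))
  ks <- vapply(cand, function(c) kappa_of(as.integer(scores >= c), y),
               numeric(1))
  list(cutoff = cand[which.max(ks)], kappa = max(ks))
}
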