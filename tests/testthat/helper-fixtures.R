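# Shared fixtures: everything is built in code at test time.

test_clock <- as.POSIXct("2014-10-29 12:00:00", tz = "UTC")

make_test_submission <- function(id = "P001", gender = "male", age = 50L,
                                 diabetes = "no", code = "A",
                                 submitter = "researcher@example.org",
                                 config = engine_config(),
                                 clock = test_clock) {
  confirm_submission(stamp_submission(
    list(participant_id = id, submitter = submitter, gender = gender,
         age_years = age, diabetes = diabetes, ethnicity_code = code),
    config, clock))
}

# Aggregates reproducing the worked minimization instance: a male, young,
# non-diabetic, white participant whose matched marginal totals are
# (25, 26, 14, 30) in the control arm and (23, 22, 18, 35) in the
# experimental arm. Unmatched positions hold the complementary level
# counts so each factor's totals sum to the arm count.
worked_example <- function(scheme = default_scheme()) {
  control <- arm_aggregate(scheme)
  experimental <- arm_aggregate(scheme)
  # order: male, female, young, old, no, yes, white, black, asian, chinese
  control$totals[] <- c(25, 27, 26, 26, 14, 38, 30, 9, 8, 5)
  control$count <- 52L
  experimental$totals[] <- c(23, 28, 22, 29, 18, 33, 35, 7, 6, 3)
  experimental$count <- 51L
  participant <- make_test_submission(id = "NEW", gender = "male", age = 40L,
                                      diabetes = "no", code = "A")
  list(control = control, experimental = experimental,
       vector = make_class_vector(participant, scheme),
       submission = participant)
}

# A finalized record with random levels and a random arm, for round-trip
# and aggregation property tests. Uses the current RNG state.
random_record <- function(config = engine_config(), id = NULL) {
  scheme <- config$scheme
  lv <- lapply(scheme$factors, function(w) sample(names(w), 1L))
  sub <- make_test_submission(
    id = id %||% sprintf("R%05d", sample.int(89999L, 1L) + 10000L),
    gender = lv$gender,
    age = if (lv$age == "old") 70L else 40L,
    diabetes = lv$diabetes,
    code = sample(names(config$ethnicity_vocabulary)[
      config$ethnicity_vocabulary == lv$ethnicity], 1L),
    config = config)
  vec <- make_class_vector(sub, scheme)
  decision <- decide_allocation(vec, arm_aggregate(scheme),
                                arm_aggregate(scheme), r = 0.5)
  finalize_record(sub, vec, decision, scheme)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent oracle: per-element double-loop aggregation, written before
# and kept apart from aggregate_history().
oracle_aggregate <- function(records, scheme) {
  nc <- n_classes(scheme)
  ctl <- numeric(nc); exp <- numeric(nc)
  n_ctl <- 0L; n_exp <- 0L
  for (r in records) {
    v <- unname(unclass(r$values))
    if (v[nc + 1L] != 0) {
      for (j in seq_len(nc)) ctl[j] <- ctl[j] + v[j]
      n_ctl <- n_ctl + 1L
    } else {
      for (j in seq_len(nc)) exp[j] <- exp[j] + v[j]
      n_exp <- n_exp + 1L
    }
  }
  list(control = ctl, experimental = exp, counts = c(n_ctl, n_exp))
}

# Independent oracle: naive loop over classes for the minimization score.
oracle_scores <- function(vec, control, experimental) {
  v <- unname(unclass(vec))
  nc <- length(control$totals)
  sc <- 0; se <- 0
  for (j in seq_len(nc)) {
    if (v[j] != 0) {
      sc <- sc + control$totals[[j]]
      se <- se + experimental$totals[[j]]
    }
  }
  c(control = sc, experimental = se)
}
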