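#' Default detailed-ethnicity vocabulary
#'
#' Intake records a detailed ethnicity code from a 17-option vocabulary;
#' the allocation scheme only uses the four aggregated categories
#' `white`, `black`, `asian` and `chinese`. The shipped mapping uses
#' NHS-style code letters and is a synthetic stand-in: only the
#' assignments of codes A, B and C (all `white`) are normative, the rest
#' of the mapping is trial configuration and can be overridden wholesale.
#'
#' @return Named character vector: 17 detailed codes -> 4 aggregated
#'   categories.
#' @export
default_ethnicity_vocabulary <- function() {
  c(
    A = "white",   # White: British
    B = "white",   # White: Irish
    C = "white",   # White: any other White background
    D = "black",   # Mixed: White and Black Caribbean
    E = "black",   # Mixed: White and Black African
    F = "asian",   # Mixed: White and Asian
    G = "white",   # Mixed: any other Mixed background
    H = "asian",   # Asian: Indian
    J = "asian",   # Asian: Pakistani
    K = "asian",   # Asian: Bangladeshi
    L = "asian",   # Asian: any other Asian background
    M = "black",   # Black: Caribbean
    N = "black",   # Black: African
    P = "black",   # Black: any other Black background
    R = "chinese", # Chinese
    S = "white",   # Any other ethnic group
    Z = "white"    # Not stated
  )
}

#' Validate an ethnicity vocabulary
#'
#' Checks the structural contract at configuration load: exactly 17
#' detailed codes, image of exactly 4 aggregated categories, and codes
#' A, B and C all mapping to `white`.
#'
#' @param vocab Named character vector (code -> aggregated category).
#' @return The vocabulary, invisibly, if valid.
#' @export
validate_ethnicity_vocabulary <- function(vocab) {
  if (!is.character(vocab) || is.null(names(vocab)) ||
      anyDuplicated(names(vocab))) {
    stop_config("ethnicity vocabulary must be a named character vector with unique codes")
  }
  if (length(vocab) != 17L) {
    stop_config("ethnicity vocabulary must have exactly 17 detailed codes, got %d",
                length(vocab))
  }
  if (length(unique(unname(vocab))) != 4L) {
    stop_config("ethnicity vocabulary must aggregate onto exactly 4 categories, got %d",
                length(unique(unname(vocab))))
  }
  if (!all(c("A", "B", "C") %in% names(vocab)) ||
      !all(vocab[c("A", "B", "C")] == "white")) {
    stop_config("ethnicity codes A, B and C must all aggregate to 'white'")
  }
  invisible(vocab)
}

#' Aggregate a detailed ethnicity code
#'
#' @param code Single detailed code (e.g. `"A"`).
#' @param vocab Vocabulary as returned by [default_ethnicity_vocabulary()].
#' @return The aggregated category, one of the vocabulary's 4 values.
#' @export
aggregate_ethnicity <- function(code, vocab = default_ethnicity_vocabulary()) {
  if (!is.character(code) || length(code) != 1L || !code %in% names(vocab)) {
    stop_validation(
      "unknown ethnicity code %s; legal codes: %s",
      deparse(as.character(code)[1]), paste(names(vocab), collapse = ", "))
  }
  unname(vocab[[code]])
}

#' Derive the age class from age in years
#'
#' Ages at or above the threshold fall in the `old` class; the default
#' threshold is 65, so the classes correspond to the bands `<65 years`
#' and `>=65 years`.
#'
#' @param age_years Non-negative integer age, at most 150.
#' @param threshold Dividing age in years (default 65).
#' @return `"young"` or `"old"`.
#' @export
derive_age_class <- function(age_years, threshold = 65L) {
  if (!is.numeric(age_years) || length(age_years) != 1L || is.na(age_years) ||
      age_years < 0 || age_years > 150 || age_years != trunc(age_years)) {
    stop_validation("age_years must be a whole number in [0, 150], got %s",
                    deparse(age_years))
  }
  if (age_years >= threshold) "old" else "young"
}

weekday_name <- function(date) {
  # locale-independent English weekday
  c("Sunday", "Monday", "Tuesday", "Wednesday",
    "Thursday", "Friday", "Saturday")[as.POSIXlt(date)$wday + 1L]
}

#' Validate and stamp a participant submission
#'
#' Transforms raw intake fields into a `participant_submission`: validates
#' every categorical field against the configured vocabularies (reporting
#' all problems at once), aggregates the detailed ethnicity code, derives
#' the age class, and stamps the submission with ISO date, weekday and
#' time taken from `clock`. The returned submission is unconfirmed;
#' allocation expects [confirm_submission()] first (the two-step
#' check-your-input flow), unless the caller opts out.
#'
#' @param fields Named list with `participant_id`, `submitter`, `gender`,
#'   `age_years`, `diabetes`, `ethnicity_code`.
#' @param config An [engine_config()].
#' @param clock POSIXct time of submission (defaults to now).
#' @return A `participant_submission`.
#' @export
stamp_submission <- function(fields, config = engine_config(),
                             clock = Sys.time()) {
  scheme <- config$scheme
  problems <- character(0)
  need <- c("participant_id", "submitter", "gender", "age_years",
            "diabetes", "ethnicity_code")
  missing <- setdiff(need, names(fields)[!vapply(fields, is.null, logical(1))])
  problems <- c(problems, sprintf("missing field: %s", missing))

  chk_level <- function(fac, value) {
    levels <- names(scheme$factors[[fac]])
    if (!is.character(value) || length(value) != 1L || !value %in% levels) {
      sprintf("%s: %s is not one of {%s}", fac,
              deparse(as.character(value)[1]), paste(levels, collapse = ", "))
    } else character(0)
  }
  lv <- list()
  if ("gender" %in% names(fields) && !is.null(fields$gender)) {
    problems <- c(problems, chk_level("gender", fields$gender))
    lv$gender <- fields$gender
  }
  if ("diabetes" %in% names(fields) && !is.null(fields$diabetes)) {
    problems <- c(problems, chk_level("diabetes", fields$diabetes))
    lv$diabetes <- fields$diabetes
  }
  if ("age_years" %in% names(fields) && !is.null(fields$age_years)) {
    lv$age <- tryCatch(
      derive_age_class(fields$age_years, config$age_threshold),
      minimizr_validation_error = function(e) {
        problems <<- c(problems, conditionMessage(e)); NA_character_
      })
  }
  if ("ethnicity_code" %in% names(fields) && !is.null(fields$ethnicity_code)) {
    lv$ethnicity <- tryCatch(
      aggregate_ethnicity(fields$ethnicity_code, config$ethnicity_vocabulary),
      minimizr_validation_error = function(e) {
        problems <<- c(problems, conditionMessage(e)); NA_character_
      })
  }
  for (f in c("participant_id", "submitter")) {
    v <- fields[[f]]
    if (!is.null(v) && (!is.character(v) || length(v) != 1L || !nzchar(v))) {
      problems <- c(problems, sprintf("%s must be a non-empty string", f))
    }
  }
  if (length(problems)) {
    stop_validation("invalid submission:\n%s",
                    paste("  -", problems, collapse = "\n"))
  }

  structure(list(
    participant_id = fields$participant_id,
    submitter      = fields$submitter,
    gender         = fields$gender,
    age_years      = as.integer(fields$age_years),
    diabetes       = fields$diabetes,
    ethnicity_code = fields$ethnicity_code,
    levels         = lv,
    date           = format(as.Date(clock), "%Y-%m-%d"),
    weekday        = weekday_name(clock),
    time           = format(clock, "%H:%M:%S"),
    confirmed      = FALSE
  ), class = "participant_submission")
}

#' Confirm a stamped submission
#'
#' Marks the submission as checked by the submitter, mirroring the
#' confirmation page of an interactive intake flow. Both the CLI and any
#' other front end share this token.
#'
#' @param submission A `participant_submission`.
#' @return The submission with `confirmed = TRUE`.
#' @export
confirm_submission <- function(submission) {
  stopifnot(inherits(submission, "participant_submission"))
  submission$confirmed <- TRUE
  submission
}

#' One-paragraph confirmation summary of a submission
#'
#' @param submission A `participant_submission`.
#' @return Character vector of display lines.
#' @export
submission_summary <- function(submission) {
  stopifnot(inherits(submission, "participant_submission"))
  c(sprintf("Participant ID: %s", submission$participant_id),
    sprintf("Date: %s (%s)", submission$date, submission$weekday),
    sprintf("Submitted by: %s", submission$submitter),
    sprintf("Gender: %s", submission$gender),
    sprintf("Age: %d (%s)", submission$age_years, submission$levels$age),
    sprintf("Diabetes: %s", submission$diabetes),
    sprintf("Ethnicity: code %s (%s)", submission$ethnicity_code,
            submission$levels$ethnicity))
}

#' @export
print.participant_submission <- function(x, ...) {
  cat(submission_summary(x), sep = "\n")
  cat(if (x$confirmed) "confirmed\n" else "awaiting confirmation\n")
  invisible(x)
}
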