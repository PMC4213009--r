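#' Run one complete allocation transaction
#'
#' The workhorse operation tying the modules together: under an
#' exclusive lock on the state file it loads the allocation history,
#' builds the new participant's class vector, aggregates the history
#' into per-arm marginal totals, decides the arm with the configured
#' randomization element, finalizes and appends the record to the state
#' and archive files, and composes the notification messages.
#'
#' Duplicate participant IDs are refused by default to prevent
#' accidental double enrolment; set `allow_duplicate = TRUE` to
#' override. The submission must have been confirmed (see
#' [confirm_submission()]) unless `require_confirmation = FALSE`.
#'
#' @param submission A `participant_submission`.
#' @param config The trial's [engine_config()].
#' @param state_path,archive_path The trial's two files.
#' @param transport Message transport (see [dispatch_notifications()]);
#'   `NULL` skips notification entirely.
#' @param allow_duplicate Permit a participant ID already in the history?
#' @param require_confirmation Insist on a confirmed submission?
#' @return List with `record`, `decision`, `counts` (total, control,
#'   experimental after this allocation), and `deliveries` (or `NULL`).
#' @export
allocate_participant <- function(submission, config, state_path, archive_path,
                                 transport = transport_null(),
                                 allow_duplicate = FALSE,
                                 require_confirmation = TRUE) {
  stopifnot(inherits(submission, "participant_submission"),
            inherits(config, "engine_config"))
  if (require_confirmation && !isTRUE(submission$confirmed)) {
    stop_validation("submission has not been confirmed; call confirm_submission() first")
  }
  scheme <- config$scheme
  with_state_lock(state_path, {
    history <- read_state(state_path, scheme, config$delimiter)
    if (!allow_duplicate) {
      ids <- vapply(history, `[[`, character(1), "participant_id")
      if (submission$participant_id %in% ids) {
        stop_validation("participant ID %s is already in the allocation history; use allow_duplicate to override",
                        submission$participant_id)
      }
    }
    vec <- make_class_vector(submission, scheme)
    arms <- aggregate_history(history, scheme)
    decision <- decide_allocation(vec, arms$control, arms$experimental,
                                  config$randomisation_element)
    record <- finalize_record(submission, vec, decision, scheme)
    append_record(record, state_path, archive_path, config$delimiter)
    counts <- list(
      total = length(history) + 1L,
      control = arms$control$count + (decision$arm == "option1"),
      experimental = arms$experimental$count + (decision$arm == "option2")
    )
    deliveries <- NULL
    if (!is.null(transport)) {
      history_lines <- readLines(state_path, warn = FALSE)
      deliveries <- dispatch_notifications(record, counts, history_lines,
                                           config, transport)
    }
    list(record = record, decision = decision, counts = counts,
         deliveries = deliveries)
  })
}
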