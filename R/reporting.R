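new_message <- function(to, subject, body) {
  structure(list(to = to, subject = subject, body = body),
            class = "trial_message")
}

#' @export
print.trial_message <- function(x, ...) {
  cat("To:", x$to, "\nSubject:", x$subject, "\n\n", x$body, sep = "")
  invisible(x)
}

#' Render the researcher notification message
#'
#' The per-allocation notification is deliberately tiny: a fixed
#' 18-line plain-text template stating the submitted variables, the
#' allocation outcome (as the arm display string, never the internal
#' option number) and the running arm counts, so it stays cheap to
#' transmit and read on any device. The subject line carries the ISO
#' date of the allocation.
#'
#' @param record A finalized `allocation_record` that still carries its
#'   submission (i.e. produced by [finalize_record()], not parsed back
#'   from the state file).
#' @param counts Named list or vector with `total`, `control`,
#'   `experimental` running counts *including* this allocation.
#' @param config The trial's [engine_config()].
#' @return A `trial_message` addressed to the submitter; its `body` has
#'   exactly 18 lines.
#' @export
render_researcher_email <- function(record, counts, config = engine_config()) {
  stopifnot(inherits(record, "allocation_record"))
  sub <- record$submission
  if (is.null(sub) || !any(outcome_part(unclass(record$values)) != 0)) {
    stop_validation("record must be finalized and carry its submission to be rendered")
  }
  lines <- c(
    "Participant allocation notification",
    sprintf("Date: %s", record$date),
    sprintf("Weekday: %s", record$weekday),
    sprintf("Time: %s", sub$time),
    sprintf("Participant ID: %s", record$participant_id),
    sprintf("Submitted by: %s", record$submitter),
    sprintf("Gender: %s", sub$gender),
    sprintf("Age: %d", sub$age_years),
    sprintf("Age class: %s", sub$levels$age),
    sprintf("Diabetes: %s", sub$diabetes),
    sprintf("Ethnicity (detailed code): %s", sub$ethnicity_code),
    sprintf("Ethnicity (aggregated): %s", sub$levels$ethnicity),
    sprintf("Allocated to: %s", record$arm_label),
    sprintf("Total participants allocated: %d", counts[["total"]]),
    sprintf("Control arm count: %d", counts[["control"]]),
    sprintf("Experimental arm count: %d", counts[["experimental"]]),
    sprintf("Randomisation element: %g", config$randomisation_element),
    "End of notification"
  )
  new_message(to = record$submitter,
              subject = sprintf("Allocation result %s - %s",
                                record$date, record$participant_id),
              body = paste0(paste(lines, collapse = "\n"), "\n"))
}

#' Render the administrator notification message
#'
#' Contains everything the researcher message contains, followed by the
#' full state file (including the line just appended) between fixed
#' marker lines. Because every such message embeds the complete
#' allocation history, the administrator's mailbox is a distributed
#' real-time backup: [rebuild_from_backup()] applied to any of these
#' messages reproduces the state file as of that allocation.
#'
#' @inheritParams render_researcher_email
#' @param history_lines Character vector of every state-file line,
#'   including the new record's line.
#' @return A `trial_message` addressed to the administrator.
#' @export
render_admin_email <- function(record, counts, history_lines,
                               config = engine_config()) {
  base <- render_researcher_email(record, counts, config)
  block <- c(history_begin_marker, history_lines, history_end_marker)
  new_message(
    to = config$recipients$admin,
    subject = paste0(base$subject, " (full history)"),
    body = paste0(base$body, paste(block, collapse = "\n"), "\n")
  )
}

#' Compose and dispatch the allocation notifications
#'
#' By default three messages are composed per allocation: one to the
#' submitter, one to the study nurse (a copy of the first, differing
#' only in recipient), and one to the administrator carrying the full
#' history block. Extra configured recipients receive further copies of
#' the researcher message. Delivery goes through a pluggable transport;
#' a transport failure is recorded in the report but never rolls back
#' the allocation, whose truth lives in the state file.
#'
#' @inheritParams render_admin_email
#' @param transport A transport function, e.g. [transport_null()] or
#'   [transport_file()]: called once per message, returning `TRUE` on
#'   successful hand-off.
#' @return A data frame (one row per message) with columns `to`, `role`,
#'   `subject`, `delivered`.
#' @export
dispatch_notifications <- function(record, counts, history_lines,
                                   config = engine_config(),
                                   transport = transport_null()) {
  researcher <- render_researcher_email(record, counts, config)
  nurse <- researcher
  nurse$to <- config$recipients$nurse
  admin <- render_admin_email(record, counts, history_lines, config)
  messages <- list(researcher, nurse, admin)
  roles <- c("submitter", "nurse", "admin")
  for (extra in config$recipients$extra %||% character(0)) {
    copy <- researcher
    copy$to <- extra
    messages <- c(messages, list(copy))
    roles <- c(roles, "extra")
  }
  delivered <- vapply(messages, function(m) {
    isTRUE(tryCatch(transport(m), error = function(e) {
      warning(sprintf("transport failed for %s: %s", m$to, conditionMessage(e)))
      FALSE
    }))
  }, logical(1))
  data.frame(
    to = vapply(messages, `[[`, character(1), "to"),
    role = roles,
    subject = vapply(messages, `[[`, character(1), "subject"),
    delivered = delivered,
    stringsAsFactors = FALSE
  )
}

#' In-memory transport
#'
#' Collects every message it is handed in an environment, for tests and
#' offline use.
#'
#' @return A transport function with a `messages()` accessor attached as
#'   an attribute.
#' @export
transport_null <- function() {
  store <- new.env(parent = emptyenv())
  store$messages <- list()
  f <- function(message) {
    store$messages[[length(store$messages) + 1L]] <- message
    TRUE
  }
  attr(f, "messages") <- function() store$messages
  f
}

#' File transport
#'
#' Writes each message to `outbox_dir/<seq>_<recipient>.txt` with the
#' recipient and subject as header lines, the default offline-friendly
#' delivery mechanism. An SMTP transport can be plugged in with the same
#' one-argument contract.
#'
#' @param outbox_dir Directory for outgoing messages (created if absent).
#' @return A transport function.
#' @export
transport_file <- function(outbox_dir) {
  dir.create(outbox_dir, showWarnings = FALSE, recursive = TRUE)
  counter <- new.env(parent = emptyenv())
  counter$n <- length(list.files(outbox_dir))  # keep names unique across sessions
  function(message) {
    counter$n <- counter$n + 1L
    safe_to <- gsub("[^A-Za-z0-9@._-]", "_", message$to)
    path <- file.path(outbox_dir,
                      sprintf("%s_%03d_%s.txt",
                              format(Sys.time(), "%Y%m%d%H%M%S"),
                              counter$n, safe_to))
    writeLines(c(paste("To:", message$to),
                 paste("Subject:", message$subject),
                 "",
                 sub("\n$", "", message$body)), path)
    TRUE
  }
}

#' Count the lines of a message body
#'
#' @param message A `trial_message`.
#' @return Integer number of text lines.
#' @export
message_line_count <- function(message) {
  length(strsplit(message$body, "\n", fixed = TRUE)[[1]])
}
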