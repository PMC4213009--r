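#' Serialize an allocation record to one state-file line
#'
#' The canonical line dialect is: participant ID, ISO date, weekday,
#' submitter, then every class value including the two outcome classes,
#' joined by the delimiter (default `"zz"`). One line corresponds to one
#' allocated participant; the line carries no terminal delimiter and no
#' newline. Any field whose textual form contains the delimiter or a
#' newline is rejected, naming the field, so that [parse_line()] is an
#' exact inverse; pick a different delimiter in the trial configuration
#' if the trial's identifiers collide with the default.
#'
#' @param record An `allocation_record`.
#' @param delimiter Field delimiter, default `"zz"`.
#' @return A single line of text.
#' @export
format_line <- function(record, delimiter = "zz") {
  stopifnot(inherits(record, "allocation_record"))
  doc <- c(participant_id = record$participant_id, date = record$date,
           weekday = record$weekday, submitter = record$submitter)
  fields <- c(doc, vapply(unclass(record$values), format_value, character(1)))
  bad <- grepl(delimiter, fields, fixed = TRUE) | grepl("[\r\n]", fields)
  if (any(bad)) {
    stop_validation("field %s (%s) contains the delimiter %s or a newline and cannot be serialized",
                    names(fields)[bad][1], deparse(unname(fields[bad][1])),
                    deparse(delimiter))
  }
  paste(fields, collapse = delimiter)
}

# round-trip-safe textual form of a class value
format_value <- function(x) {
  if (x == trunc(x) && abs(x) < 1e15) sprintf("%d", as.integer(x))
  else sprintf("%.17g", x)
}

#' Parse one state-file line into an allocation record
#'
#' Inverse of [format_line()]. The field count is fixed by the scheme
#' (four documentary fields plus `n_classes + 2` values); lines with any
#' other field count, non-numeric class values, a per-factor indicator
#' violation, or zero or two outcome flags raise a corrupt-line error
#' citing `line_no`.
#'
#' @param line One non-empty line of text.
#' @param scheme The trial's [factor_scheme()].
#' @param delimiter Field delimiter used when the line was written.
#' @param line_no Line number used in error messages.
#' @return An `allocation_record` (documentary fields + class vector; the
#'   original submission details beyond those fields are not stored in
#'   the state file).
#' @export
parse_line <- function(line, scheme, delimiter = "zz", line_no = NA_integer_) {
  stopifnot(inherits(scheme, "factor_scheme"))
  if (!is.character(line) || length(line) != 1L || !nzchar(line)) {
    stop_corrupt("line %s: empty or not a single string", format(line_no))
  }
  fields <- strsplit(line, delimiter, fixed = TRUE)[[1]]
  expected <- 4L + n_classes(scheme) + n_outcome
  if (length(fields) != expected) {
    stop_corrupt("line %s: expected %d fields split on %s, found %d",
                 format(line_no), expected, deparse(delimiter), length(fields))
  }
  values <- suppressWarnings(as.numeric(fields[-(1:4)]))
  if (anyNA(values)) {
    stop_corrupt("line %s: non-numeric class value %s", format(line_no),
                 deparse(fields[-(1:4)][which(is.na(values))[1]]))
  }
  names(values) <- class_labels(scheme)
  oc <- outcome_part(values)
  if (sum(oc != 0) != 1L) {
    stop_corrupt("line %s: expected exactly one outcome flag, found %d",
                 format(line_no), sum(oc != 0))
  }
  for (f in names(scheme$factors)) {
    pos <- factor_positions(scheme, f)
    if (sum(values[pos] != 0) != 1L) {
      stop_corrupt("line %s: factor %s has %d nonzero levels, expected exactly 1",
                   format(line_no), f, sum(values[pos] != 0))
    }
  }
  arm <- if (oc[[1]] != 0) "option1" else "option2"
  structure(list(
    participant_id = fields[1], date = fields[2], weekday = fields[3],
    submitter = fields[4],
    values = structure(values, class = "class_vector"),
    arm = arm,
    arm_label = scheme$arm_labels[[if (arm == "option1") 1L else 2L]],
    submission = NULL, decision = NULL
  ), class = "allocation_record")
}

#' Load an allocation history from a state file
#'
#' Reads the append-only state file, skipping (with a warning) any empty
#' lines, and parses every remaining line. A missing file is an empty
#' history, so a fresh trial needs no setup beyond an empty file.
#'
#' @param path Path to the state file.
#' @param scheme The trial's [factor_scheme()].
#' @param delimiter Field delimiter.
#' @return List of `allocation_record`s.
#' @export
read_state <- function(path, scheme, delimiter = "zz") {
  if (!file.exists(path)) return(list())
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(lines)
  if (any(!keep)) {
    warning(sprintf("state file %s: skipped %d empty line(s)", path, sum(!keep)))
  }
  idx <- which(keep)
  lapply(seq_along(idx), function(i) {
    parse_line(lines[idx[i]], scheme, delimiter, line_no = idx[i])
  })
}

#' Append one allocation record to the state and archive files
#'
#' Appends the identical serialized line to both the working state file
#' and the mirror archive file, in that order. The archive is write-only
#' during operation; if it has gone missing mid-trial it is recreated
#' with a warning (subsequent reconciliation is a maintenance task, not
#' automatic). Writability is checked before anything is appended so an
#' unwritable path never leaves a partial line in the state file.
#'
#' @param record An `allocation_record`.
#' @param state_path,archive_path Paths of the two files.
#' @param delimiter Field delimiter.
#' @return The serialized line, invisibly.
#' @export
append_record <- function(record, state_path, archive_path, delimiter = "zz") {
  line <- format_line(record, delimiter)
  for (p in c(state_path, archive_path)) {
    ok <- if (file.exists(p)) file.access(p, 2) == 0L
          else file.access(dirname(p), 2) == 0L
    if (!ok) {
      stop(errorCondition(sprintf("cannot write to %s; nothing appended", p),
                          class = c("minimizr_io_error", "minimizr_error")))
    }
  }
  if (file.exists(state_path) && file.size(state_path) > 0 &&
      !file.exists(archive_path)) {
    warning(sprintf("archive file %s was missing and has been recreated; reconcile it with the state file",
                    archive_path))
  }
  cat(line, "\n", sep = "", file = state_path, append = TRUE)
  cat(line, "\n", sep = "", file = archive_path, append = TRUE)
  invisible(line)
}

history_begin_marker <- "----- BEGIN ALLOCATION HISTORY -----"
history_end_marker   <- "----- END ALLOCATION HISTORY -----"

#' Rebuild a state file from an administrator backup message
#'
#' Every administrator notification embeds the full state file between
#' fixed marker lines, making each message an independent off-site backup
#' of the whole allocation history. This extracts that block and (when
#' `path` is given) writes it back out, reproducing the state file
#' byte-identically as it stood when the message was composed.
#'
#' @param backup_text Full body of an administrator message, as a single
#'   string or a vector of lines.
#' @param path Optional output path for the reconstructed state file.
#' @return The state-file content as a single string (possibly empty),
#'   invisibly when `path` is given.
#' @export
rebuild_from_backup <- function(backup_text, path = NULL) {
  lines <- unlist(strsplit(backup_text, "\n", fixed = TRUE), use.names = FALSE)
  begin <- which(lines == history_begin_marker)
  end <- which(lines == history_end_marker)
  if (length(begin) != 1L || length(end) != 1L || end < begin) {
    stop_corrupt("no allocation-history block found in backup text")
  }
  block <- lines[seq_len(end - begin - 1L) + begin]
  content <- if (length(block)) paste0(paste(block, collapse = "\n"), "\n") else ""
  if (!is.null(path)) {
    writeChar(content, path, eos = NULL)
    return(invisible(content))
  }
  content
}

#' Run an expression under the trial's exclusive advisory lock
#'
#' Serializes concurrent allocation transactions on one state file. The
#' lock is an advisory directory next to the state file, taken with an
#' atomic `dir.create()` and retried until `timeout` seconds have
#' elapsed. Stale locks must be removed by hand (the holder's path is
#' the lock name).
#'
#' @param state_path Path of the state file being protected.
#' @param expr Expression evaluated while the lock is held.
#' @param timeout Seconds to keep retrying before giving up.
#' @return The value of `expr`.
#' @export
with_state_lock <- function(state_path, expr, timeout = 10) {
  lock <- paste0(state_path, ".lock")
  deadline <- Sys.time() + timeout
  repeat {
    if (dir.create(lock, showWarnings = FALSE)) break
    if (Sys.time() > deadline) {
      stop(errorCondition(
        sprintf("timed out after %gs waiting for lock %s", timeout, lock),
        class = c("minimizr_lock_error", "minimizr_error")))
    }
    Sys.sleep(0.05)
  }
  on.exit(unlink(lock, recursive = TRUE), add = TRUE)
  force(expr)
}
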