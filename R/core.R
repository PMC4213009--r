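#' Build a participant's class vector
#'
#' Converts a stamped submission into a numeric vector with one position
#' per allocation class plus the two outcome classes. For each factor
#' exactly one position is nonzero and carries that level's configured
#' weight (with all default weights 1 the vector is 0/1); both outcome
#' positions are 0 until the record is finalized.
#'
#' @param submission A `participant_submission` from [stamp_submission()],
#'   or any list carrying a `levels` element naming one level per factor.
#' @param scheme A [factor_scheme()].
#' @return A `class_vector`: numeric of length `n_classes(scheme) + 2`,
#'   named by [class_labels()].
#' @export
make_class_vector <- function(submission, scheme) {
  stopifnot(inherits(scheme, "factor_scheme"))
  lv <- submission$levels
  nc <- n_classes(scheme)
  values <- numeric(nc + 2L)
  names(values) <- class_labels(scheme)
  for (f in names(scheme$factors)) {
    level <- lv[[f]]
    weights <- scheme$factors[[f]]
    if (is.null(level) || length(level) != 1L || is.na(level) ||
        !level %in% names(weights)) {
      stop_validation("factor %s: level %s is not one of {%s}", f,
                      deparse(as.character(level)[1]),
                      paste(names(weights), collapse = ", "))
    }
    pos <- factor_positions(scheme, f)
    values[pos[match(level, names(weights))]] <- weights[[level]]
  }
  structure(values, class = "class_vector")
}

n_outcome <- 2L

# split a class vector into allocation part and outcome part
allocation_part <- function(values) values[seq_len(length(values) - n_outcome)]
outcome_part    <- function(values) values[length(values) - 1:0]

#' Create an empty per-arm aggregate
#'
#' @param scheme A [factor_scheme()].
#' @return An `arm_aggregate` with all-zero totals and count 0.
#' @export
arm_aggregate <- function(scheme) {
  totals <- numeric(n_classes(scheme))
  names(totals) <- class_labels(scheme, outcomes = FALSE)
  structure(list(totals = totals, count = 0L), class = "arm_aggregate")
}

# add one finalized record's allocation-class values to an aggregate
aggregate_add <- function(aggregate, values) {
  aggregate$totals <- aggregate$totals + allocation_part(unclass(values))
  aggregate$count <- aggregate$count + 1L
  aggregate
}

#' Aggregate an allocation history into per-arm marginal totals
#'
#' Replays a sequence of finalized allocation records into two running
#' aggregates, one per arm: each aggregate's totals are the elementwise
#' sum of the allocation-class values of the records assigned to that
#' arm, and its count is the number of such records.
#'
#' @param records List of `allocation_record`s (each with exactly one
#'   outcome position set).
#' @param scheme A [factor_scheme()].
#' @return List with elements `control` and `experimental`, both
#'   `arm_aggregate`s.
#' @export
aggregate_history <- function(records, scheme) {
  control <- arm_aggregate(scheme)
  experimental <- arm_aggregate(scheme)
  for (i in seq_along(records)) {
    values <- unclass(records[[i]]$values)
    if (length(values) != n_classes(scheme) + n_outcome) {
      stop_corrupt("record %d: class vector length %d does not match scheme (%d)",
                   i, length(values), n_classes(scheme) + n_outcome)
    }
    oc <- outcome_part(values)
    if (sum(oc != 0) != 1L) {
      stop_corrupt("record %d: expected exactly one outcome flag, found %d",
                   i, sum(oc != 0))
    }
    if (oc[[1]] != 0) {
      control <- aggregate_add(control, values)
    } else {
      experimental <- aggregate_add(experimental, values)
    }
  }
  list(control = control, experimental = experimental)
}

#' Minimization scores for a new participant
#'
#' For every allocation class at which the new participant's class vector
#' is nonzero (their true levels), the corresponding marginal totals in
#' the control and experimental aggregates are summed separately. Each
#' score measures how frequent the new participant's characteristics
#' already are in that arm; the arm with the *smaller* score is the
#' minimization-preferred arm.
#'
#' @param vector A `class_vector` for the new participant.
#' @param control,experimental `arm_aggregate`s for the two arms.
#' @return Named numeric: `control` and `experimental` scores.
#' @export
arm_scores <- function(vector, control, experimental) {
  values <- allocation_part(unclass(vector))
  if (length(values) != length(control$totals) ||
      length(values) != length(experimental$totals)) {
    stop_config("class vector and aggregates come from different schemes (lengths %d, %d, %d)",
                length(values), length(control$totals), length(experimental$totals))
  }
  matched <- values != 0
  c(control = sum(control$totals[matched]),
    experimental = sum(experimental$totals[matched]))
}

#' Biased-coin arm draw
#'
#' Draws a uniform number and returns option 1 (control) when the draw
#' falls below `p_option1`, option 2 (experimental) otherwise, so option 1
#' is selected with probability exactly `p_option1`. The drawn value is
#' returned for the audit trail. Uses R's global RNG; seed via
#' [set.seed()] or the engine configuration.
#'
#' @param p_option1 Probability of option 1, in `[0, 1]`.
#' @return List with `arm` (`"option1"` or `"option2"`) and `draw`.
#' @export
randomise_arm <- function(p_option1) {
  if (!is.numeric(p_option1) || length(p_option1) != 1L || is.na(p_option1) ||
      p_option1 < 0 || p_option1 > 1) {
    stop_config("p_option1 must be a probability in [0, 1]")
  }
  draw <- stats::runif(1)
  list(arm = if (draw < p_option1) "option1" else "option2", draw = draw)
}

#' Decide the allocation of a new participant
#'
#' Compares the two minimization scores and applies the randomization
#' element `r`:
#' * equal scores: a fair coin decides (so the first participant of any
#'   trial is always randomized), whatever `r` is;
#' * experimental score greater: control is preferred and selected with
#'   probability `r`;
#' * control score greater: experimental is preferred and selected with
#'   probability `r` (i.e. option 1 with probability `1 - r`).
#'
#' With `r = 1` and unequal scores the decision is deterministic and no
#' random draw is consumed, so the RNG stream is untouched on that branch.
#'
#' @param vector The new participant's `class_vector` (outcomes unset).
#' @param control,experimental `arm_aggregate`s of the history.
#' @param r Randomization element in `[0.5, 1]`.
#' @return An `allocation_decision`: list with `arm`, `control_score`,
#'   `experimental_score`, `mode` (`"tie_random"`, `"deterministic"` or
#'   `"biased_coin"`), and `coin_draw` (`NA` when no draw occurred).
#' @export
decide_allocation <- function(vector, control, experimental, r = 1) {
  check_randomisation_element(r)
  scores <- arm_scores(vector, control, experimental)
  if (scores[["control"]] == scores[["experimental"]]) {
    res <- randomise_arm(0.5)
    mode <- "tie_random"
    draw <- res$draw
    arm <- res$arm
  } else {
    p <- if (scores[["experimental"]] > scores[["control"]]) r else 1 - r
    if (p == 1 || p == 0) {
      arm <- if (p == 1) "option1" else "option2"
      mode <- "deterministic"
      draw <- NA_real_
    } else {
      res <- randomise_arm(p)
      arm <- res$arm
      mode <- "biased_coin"
      draw <- res$draw
    }
  }
  structure(list(
    arm = arm,
    control_score = unname(scores[["control"]]),
    experimental_score = unname(scores[["experimental"]]),
    mode = mode,
    coin_draw = draw
  ), class = "allocation_decision")
}

#' Finalize an allocation record
#'
#' Writes the decided arm into the participant's class vector (outcome
#' position for the chosen arm becomes 1, the other stays 0) and carries
#' the documentary fields through unchanged.
#'
#' @param submission The stamped `participant_submission`.
#' @param vector The participant's `class_vector` with both outcomes 0.
#' @param decision An `allocation_decision`.
#' @param scheme The [factor_scheme()] (resolves the arm display string).
#' @return An `allocation_record`.
#' @export
finalize_record <- function(submission, vector, decision, scheme) {
  stopifnot(inherits(decision, "allocation_decision"),
            inherits(scheme, "factor_scheme"))
  values <- unclass(vector)
  if (any(outcome_part(values) != 0)) {
    stop_validation("class vector already carries an allocation outcome; refusing to allocate twice")
  }
  idx <- length(values) - (if (decision$arm == "option1") 1L else 0L)
  values[idx] <- 1
  structure(list(
    participant_id = submission$participant_id,
    date = submission$date,
    weekday = submission$weekday,
    submitter = submission$submitter,
    values = structure(values, class = "class_vector"),
    arm = decision$arm,
    arm_label = scheme$arm_labels[[if (decision$arm == "option1") 1L else 2L]],
    submission = submission,
    decision = decision
  ), class = "allocation_record")
}

#' @export
print.allocation_decision <- function(x, ...) {
  cat(sprintf("allocation: %s (scores control=%g experimental=%g, mode=%s%s)\n",
              x$arm, x$control_score, x$experimental_score, x$mode,
              if (is.na(x$coin_draw)) "" else sprintf(", draw=%.4f", x$coin_draw)))
  invisible(x)
}

#' @export
print.allocation_record <- function(x, ...) {
  cat(sprintf("%s  %s (%s)  %s -> %s\n", x$participant_id, x$date, x$weekday,
              x$submitter, x$arm_label))
  invisible(x)
}
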