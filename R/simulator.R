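#' Synthetic population model
#'
#' Describes the participant stream of a simulated trial as independent
#' per-factor level prevalences. The default marginals emulate a small
#' renal-medicine trial population: an even gender split, slightly more
#' participants at or over 65 than under, roughly a quarter diabetic,
#' and a predominantly white population with small black, asian and
#' chinese minorities. Factors are drawn independently; real arrival
#' streams have correlated covariates and temporal drift, which this
#' model deliberately omits.
#'
#' @param prevalences Named list, one numeric probability vector per
#'   factor, each named by level and summing to 1.
#' @param n Number of participants (>= 1).
#' @param scheme The [factor_scheme()] the levels must match.
#' @return A `population_model`.
#' @export
population_model <- function(prevalences = default_prevalences(),
                             n = 152L,
                             scheme = default_scheme()) {
  stopifnot(inherits(scheme, "factor_scheme"))
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != trunc(n)) {
    stop_validation("n must be a whole number >= 1, got %s", deparse(n))
  }
  if (!setequal(names(prevalences), names(scheme$factors))) {
    stop_validation("prevalences must cover exactly the scheme's factors: %s",
                    paste(names(scheme$factors), collapse = ", "))
  }
  for (f in names(prevalences)) {
    p <- prevalences[[f]]
    levels <- names(scheme$factors[[f]])
    if (!is.numeric(p) || !setequal(names(p), levels)) {
      stop_validation("factor %s: prevalence vector must name levels {%s}",
                      f, paste(levels, collapse = ", "))
    }
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop_validation("factor %s: prevalences must be non-negative and sum to 1 (got %.12f)",
                      f, sum(p))
    }
    prevalences[[f]] <- p[levels]
  }
  structure(list(prevalences = prevalences, n = as.integer(n),
                 scheme = scheme),
            class = "population_model")
}

#' Default per-factor prevalences of the simulated population
#'
#' Marginals of 152 participants: 76 male, 71 under 65, 39 diabetic, and
#' an ethnicity split of 142 white, 5 black, 4 asian, 1 chinese.
#'
#' @return Named list of named probability vectors.
#' @export
default_prevalences <- function() {
  list(
    gender    = c(male = 76, female = 76) / 152,
    age       = c(young = 71, old = 81) / 152,
    diabetes  = c(no = 113, yes = 39) / 152,
    ethnicity = c(white = 142, black = 5, asian = 4, chinese = 1) / 152
  )
}

#' Generate a synthetic participant stream
#'
#' Draws `model$n` submissions, each factor level independently from its
#' prevalence vector. Ages are drawn uniformly within the band implied
#' by the drawn age class (18-64 or 65-90 at the default threshold), and
#' a detailed ethnicity code is drawn uniformly among the codes mapping
#' to the drawn aggregated category. Reproducible under [set.seed()].
#'
#' @param model A [population_model()].
#' @param config An [engine_config()] supplying the age threshold and
#'   ethnicity vocabulary.
#' @return List of confirmed `participant_submission`s.
#' @export
generate_stream <- function(model, config = engine_config()) {
  stopifnot(inherits(model, "population_model"))
  prev <- model$prevalences
  draw <- function(p) sample(names(p), 1L, prob = p)
  codes_by_cat <- split(names(config$ethnicity_vocabulary),
                        unname(config$ethnicity_vocabulary))
  thr <- config$age_threshold
  lapply(seq_len(model$n), function(i) {
    age_class <- draw(prev$age)
    age <- if (age_class == "old") sample(seq(thr, 90L), 1L)
           else sample(seq(18L, thr - 1L), 1L)
    cat4 <- draw(prev$ethnicity)
    code <- sample(codes_by_cat[[cat4]], 1L)
    sub <- structure(list(
      participant_id = sprintf("S%04d", i),
      submitter = "researcher@example.org",
      gender = draw(prev$gender),
      age_years = as.integer(age),
      diabetes = draw(prev$diabetes),
      ethnicity_code = code,
      levels = list(gender = NA, age = age_class, diabetes = NA,
                    ethnicity = cat4),
      date = "2014-10-29", weekday = "Wednesday", time = "12:00:00",
      confirmed = TRUE
    ), class = "participant_submission")
    sub$levels$gender <- sub$gender
    sub$levels$diabetes <- sub$diabetes
    sub
  })
}

#' Replay a participant stream through the allocation engine
#'
#' Allocates every submission in order against a running history,
#' exactly as sequential calls to the full transaction on a fresh state
#' file would (an in-memory running aggregate replaces re-reading the
#' file each step; the two are equivalent and tested as such). When
#' `state_path` is given the produced state file is written and is
#' loadable by [read_state()].
#'
#' @param stream List of submissions from [generate_stream()].
#' @param config An [engine_config()]; its `randomisation_element`
#'   governs every decision.
#' @param state_path Optional path to also write the state file to.
#' @return A `trial_result`: list with `records`, `decisions`, `control`
#'   and `experimental` aggregates, and the `config`.
#' @export
run_trial <- function(stream, config = engine_config(), state_path = NULL) {
  scheme <- config$scheme
  control <- arm_aggregate(scheme)
  experimental <- arm_aggregate(scheme)
  n <- length(stream)
  records <- vector("list", n)
  decisions <- vector("list", n)
  r <- config$randomisation_element
  for (i in seq_len(n)) {
    vec <- make_class_vector(stream[[i]], scheme)
    decision <- decide_allocation(vec, control, experimental, r)
    record <- finalize_record(stream[[i]], vec, decision, scheme)
    if (decision$arm == "option1") {
      control <- aggregate_add(control, unclass(record$values))
    } else {
      experimental <- aggregate_add(experimental, unclass(record$values))
    }
    records[[i]] <- record
    decisions[[i]] <- decision
  }
  if (!is.null(state_path)) {
    lines <- vapply(records, format_line, character(1),
                    delimiter = config$delimiter)
    writeLines(lines, state_path)
  }
  structure(list(records = records, decisions = decisions,
                 control = control, experimental = experimental,
                 config = config),
            class = "trial_result")
}

#' Per-class balance report of a trial
#'
#' Lays the two arms' marginal totals side by side, one row per
#' factor level, with the absolute between-arm imbalance per class. The
#' summary attribute carries the maximum per-class imbalance and the arm
#' sizes — the statistics the strategy comparison is built on.
#'
#' @param result A `trial_result` from [run_trial()].
#' @return A data frame with columns `factor`, `level`, `control`,
#'   `experimental`, `imbalance`, and attributes `max_imbalance`,
#'   `n_control`, `n_experimental`.
#' @export
balance_report <- function(result) {
  stopifnot(inherits(result, "trial_result"))
  scheme <- result$config$scheme
  labels <- class_labels(scheme, outcomes = FALSE)
  parts <- strsplit(labels, ".", fixed = TRUE)
  ctl <- unname(result$control$totals)
  exp <- unname(result$experimental$totals)
  report <- data.frame(
    factor = vapply(parts, `[[`, character(1), 1L),
    level = vapply(parts, function(p) paste(p[-1], collapse = "."), character(1)),
    control = ctl,
    experimental = exp,
    imbalance = abs(ctl - exp),
    stringsAsFactors = FALSE
  )
  attr(report, "max_imbalance") <- if (nrow(report)) max(report$imbalance) else 0
  attr(report, "n_control") <- result$control$count
  attr(report, "n_experimental") <- result$experimental$count
  report
}

#' Compare allocation strategies by simulation
#'
#' Replays `replicates` independently generated streams under each
#' randomization element in `r_values` (the same streams across
#' elements, for a paired comparison) and summarizes the maximum
#' per-class imbalance and the arm-size difference of each strategy.
#'
#' @param model A [population_model()].
#' @param r_values Randomization elements to compare; 0.5 is pure
#'   randomization, 1 deterministic minimization.
#' @param replicates Number of simulated trials per element (>= 2).
#' @param config Base [engine_config()]; its element is overridden per
#'   row.
#' @return Data frame, one row per element, with the mean and 2.5/97.5
#'   percentiles of max imbalance and of |control - experimental| size.
#' @export
compare_strategies <- function(model, r_values = c(0.5, 1), replicates = 200L,
                               config = engine_config()) {
  if (!is.numeric(replicates) || replicates < 2) {
    stop_validation("replicates must be >= 2")
  }
  streams <- lapply(seq_len(replicates), function(i) generate_stream(model, config))
  rows <- lapply(r_values, function(r) {
    cfg <- config
    cfg$randomisation_element <- r
    check_randomisation_element(r)
    metrics <- vapply(streams, function(s) {
      rep <- balance_report(run_trial(s, cfg))
      c(attr(rep, "max_imbalance"),
        abs(attr(rep, "n_control") - attr(rep, "n_experimental")))
    }, numeric(2))
    data.frame(
      r = r,
      mean_max_imbalance = mean(metrics[1, ]),
      q025_max_imbalance = unname(stats::quantile(metrics[1, ], 0.025)),
      q975_max_imbalance = unname(stats::quantile(metrics[1, ], 0.975)),
      mean_arm_diff = mean(metrics[2, ]),
      q025_arm_diff = unname(stats::quantile(metrics[2, ], 0.025)),
      q975_arm_diff = unname(stats::quantile(metrics[2, ], 0.975))
    )
  })
  do.call(rbind, rows)
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf("trial of %d participants: %d control, %d experimental (r = %g)\n",
              length(x$records), x$control$count, x$experimental$count,
              x$config$randomisation_element))
  invisible(x)
}
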