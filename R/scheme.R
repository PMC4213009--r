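#' Define the allocation factor scheme
#'
#' A factor scheme fixes the layout of every class vector used by the
#' minimization engine: the allocation factors, the ordered levels within
#' each factor, and the per-level weight contributed by a true level.
#' Classes are ordered by concatenating the factors in declared order and
#' the levels in declared order; the two outcome classes (option 1 =
#' control arm, option 2 = experimental arm) always occupy the final two
#' positions of a class vector.
#'
#' @param factors Named list. Each element describes one factor and is
#'   either a character vector of level names (all weights default to 1)
#'   or a named numeric vector mapping level names to non-negative
#'   weights.
#' @param arm_labels Character vector of length 2: display strings for
#'   option 1 (control) and option 2 (experimental).
#' @return An object of class `factor_scheme`.
#' @examples
#' sch <- factor_scheme(list(gender = c("male", "female"),
#'                           age = c("young", "old")))
#' n_classes(sch)
#' @seealso [default_scheme()] for the shipped 10-class scheme.
#' @export
factor_scheme <- function(factors,
                          arm_labels = c("Control Arm", "Experimental Arm")) {
  if (!is.list(factors) || length(factors) == 0L ||
      is.null(names(factors)) || anyDuplicated(names(factors)) ||
      any(!nzchar(names(factors)))) {
    stop_config("`factors` must be a non-empty list with unique, non-empty names")
  }
  if (!is.character(arm_labels) || length(arm_labels) != 2L) {
    stop_config("`arm_labels` must be two display strings (control, experimental)")
  }
  factors <- lapply(factors, function(f) {
    if (is.character(f)) {
      w <- rep(1, length(f))
      names(w) <- f
      f <- w
    }
    if (!is.numeric(f) || length(f) < 2L || is.null(names(f)) ||
        anyDuplicated(names(f)) || any(!nzchar(names(f)))) {
      stop_config("each factor needs >= 2 uniquely named levels")
    }
    if (any(f < 0) || any(!is.finite(f))) {
      stop_config("level weights must be finite and non-negative")
    }
    f
  })
  scheme <- structure(
    list(factors = factors, arm_labels = arm_labels),
    class = "factor_scheme"
  )
  scheme
}

#' The shipped default factor scheme
#'
#' Four factors totalling 10 allocation classes: gender (male/female), age
#' class (young/old around the configured age threshold), diabetes
#' (no/yes), and aggregated ethnicity (white/black/asian/chinese). All
#' weights are 1 unless overridden in a trial configuration.
#'
#' @inheritParams factor_scheme
#' @return A `factor_scheme` with 10 allocation classes.
#' @export
default_scheme <- function(arm_labels = c("Control Arm", "Experimental Arm")) {
  factor_scheme(
    list(
      gender    = c("male", "female"),
      age       = c("young", "old"),
      diabetes  = c("no", "yes"),
      ethnicity = c("white", "black", "asian", "chinese")
    ),
    arm_labels = arm_labels
  )
}

#' Number of allocation classes in a scheme
#'
#' The two outcome classes are not counted.
#' @param scheme A `factor_scheme`.
#' @return Integer.
#' @export
n_classes <- function(scheme) {
  stopifnot(inherits(scheme, "factor_scheme"))
  sum(vapply(scheme$factors, length, integer(1)))
}

#' Class labels of a scheme
#'
#' @param scheme A `factor_scheme`.
#' @param outcomes Include the two outcome positions (`option1`, `option2`)?
#' @return Character vector of `factor.level` labels in class-vector order.
#' @export
class_labels <- function(scheme, outcomes = TRUE) {
  stopifnot(inherits(scheme, "factor_scheme"))
  lab <- unlist(lapply(names(scheme$factors), function(f) {
    paste(f, names(scheme$factors[[f]]), sep = ".")
  }), use.names = FALSE)
  if (outcomes) lab <- c(lab, "option1", "option2")
  lab
}

# index positions (within the allocation classes) of one factor's levels
factor_positions <- function(scheme, factor_name) {
  sizes <- vapply(scheme$factors, length, integer(1))
  i <- match(factor_name, names(scheme$factors))
  offset <- if (i == 1L) 0L else sum(sizes[seq_len(i - 1L)])
  offset + seq_len(sizes[i])
}

#' @export
print.factor_scheme <- function(x, ...) {
  cat("Allocation factor scheme:", n_classes(x), "allocation classes + 2 outcome classes\n")
  for (f in names(x$factors)) {
    w <- x$factors[[f]]
    cat(sprintf("  %-10s %s\n", f,
                paste(sprintf("%s (w=%g)", names(w), w), collapse = ", ")))
  }
  cat("  arms:      ", paste(x$arm_labels, collapse = " / "), "\n")
  invisible(x)
}

# classed condition helpers shared across the package ------------------------

stop_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("minimizr_config_error", "minimizr_error")))
}

stop_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("minimizr_validation_error", "minimizr_error")))
}

stop_corrupt <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("minimizr_corrupt_history_error", "minimizr_error")))
}
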