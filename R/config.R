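#' Engine configuration for a trial
#'
#' Bundles everything the allocation engine needs to run one trial: the
#' factor scheme, the randomization element, the age threshold, the
#' detailed-ethnicity vocabulary, the state-file delimiter, notification
#' recipients, and an optional RNG seed.
#'
#' The randomization element `r` is the probability of following the
#' minimization-preferred arm. `r = 1` (the default) is deterministic
#' minimization; `r = 0.5` is pure randomization; values in between give a
#' biased coin. Values below 0.5 are rejected: they would preferentially
#' allocate *against* the arm that minimizes imbalance, which is never
#' what a trial wants.
#'
#' @param scheme A [factor_scheme()].
#' @param randomisation_element Probability in `[0.5, 1]` of following the
#'   preferred arm.
#' @param age_threshold Age in years dividing the young/old classes.
#' @param ethnicity_vocabulary 17-code mapping, see
#'   [default_ethnicity_vocabulary()].
#' @param delimiter Field delimiter for state-file lines.
#' @param recipients Named list with `nurse`, `admin`, and optionally
#'   `extra` (character vector) e-mail style addresses.
#' @param seed Optional integer seed applied by entry points before any
#'   random draw.
#' @return An object of class `engine_config`.
#' @export
engine_config <- function(scheme = default_scheme(),
                          randomisation_element = 1,
                          age_threshold = 65L,
                          ethnicity_vocabulary = default_ethnicity_vocabulary(),
                          delimiter = "zz",
                          recipients = list(nurse = "nurse@example.org",
                                            admin = "admin@example.org"),
                          seed = NULL) {
  stopifnot(inherits(scheme, "factor_scheme"))
  check_randomisation_element(randomisation_element)
  if (!is.numeric(age_threshold) || length(age_threshold) != 1L ||
      age_threshold <= 0 || age_threshold > 150) {
    stop_config("age_threshold must be a single age in (0, 150]")
  }
  validate_ethnicity_vocabulary(ethnicity_vocabulary)
  if (!is.character(delimiter) || length(delimiter) != 1L || !nzchar(delimiter)) {
    stop_config("delimiter must be a non-empty string")
  }
  if (!all(c("nurse", "admin") %in% names(recipients))) {
    stop_config("recipients must name at least `nurse` and `admin`")
  }
  structure(list(
    scheme = scheme,
    randomisation_element = randomisation_element,
    age_threshold = as.integer(age_threshold),
    ethnicity_vocabulary = ethnicity_vocabulary,
    delimiter = delimiter,
    recipients = recipients,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "engine_config")
}

check_randomisation_element <- function(r) {
  if (!is.numeric(r) || length(r) != 1L || is.na(r)) {
    stop_config("randomisation element must be a single number")
  }
  if (r < 0.5 || r > 1) {
    stop_config(paste(
      "randomisation element %g is outside [0.5, 1]:",
      "it is the probability of following the minimization-preferred arm,",
      "so 1 is deterministic minimization, 0.5 is pure randomization, and",
      "values below 0.5 would systematically allocate against the preferred arm"),
      r)
  }
  invisible(r)
}

#' Read a trial configuration from YAML
#'
#' The file maps factor names to levels (a list of level names, or a
#' mapping of level name to weight), plus `randomisation_element`,
#' `age_threshold`, `arm_labels`, `delimiter`, `recipients`,
#' `ethnicity_vocabulary` and `seed`. Any omitted entry falls back to the
#' shipped default.
#'
#' @param path Path to a YAML file.
#' @return An [engine_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  dflt <- engine_config()
  scheme <- if (is.null(raw$factors)) dflt$scheme else {
    factors <- lapply(raw$factors, function(f) {
      if (is.list(f)) unlist(f) else as.character(unlist(f))
    })
    factor_scheme(factors,
                  arm_labels = if (is.null(raw$arm_labels)) dflt$scheme$arm_labels
                               else as.character(unlist(raw$arm_labels)))
  }
  vocab <- if (is.null(raw$ethnicity_vocabulary)) dflt$ethnicity_vocabulary
           else unlist(raw$ethnicity_vocabulary)
  engine_config(
    scheme = scheme,
    randomisation_element = raw$randomisation_element %||% dflt$randomisation_element,
    age_threshold = raw$age_threshold %||% dflt$age_threshold,
    ethnicity_vocabulary = vocab,
    delimiter = raw$delimiter %||% dflt$delimiter,
    recipients = raw$recipients %||% dflt$recipients,
    seed = raw$seed
  )
}

#' Write a trial configuration to YAML
#'
#' @param config An [engine_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "engine_config"))
  out <- list(
    factors = lapply(config$scheme$factors, as.list),
    arm_labels = config$scheme$arm_labels,
    randomisation_element = config$randomisation_element,
    age_threshold = config$age_threshold,
    ethnicity_vocabulary = as.list(config$ethnicity_vocabulary),
    delimiter = config$delimiter,
    recipients = config$recipients
  )
  if (!is.null(config$seed)) out$seed <- config$seed
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.engine_config <- function(x, ...) {
  print(x$scheme)
  cat(sprintf("randomisation element: %g | age threshold: %d | delimiter: %s\n",
              x$randomisation_element, x$age_threshold, x$delimiter))
  invisible(x)
}
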