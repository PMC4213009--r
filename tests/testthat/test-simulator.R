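test_that("population models are validated", {
  expect_error(population_model(n = 0), class = "minimizr_validation_error")
  bad <- default_prevalences()
  bad$gender <- c(male = 0.7, female = 0.4)
  expect_error(population_model(bad), class = "minimizr_validation_error")
  bad$gender <- c(male = 0.5, other = 0.5)
  expect_error(population_model(bad), class = "minimizr_validation_error")
  expect_s3_class(population_model(n = 10), "population_model")
})

test_that("streams follow the prevalences and are reproducible under seed", {
  prev <- default_prevalences()
  prev$gender <- c(male = 1, female = 0)
  set.seed(41)
  stream <- generate_stream(population_model(prev, n = 30))
  expect_length(stream, 30L)
  expect_true(all(vapply(stream, `[[`, character(1), "gender") == "male"))

  set.seed(42)
  big <- generate_stream(population_model(n = 10000))
  p <- default_prevalences()
  frac <- function(field, level) {
    mean(vapply(big, function(s) s$levels[[field]], character(1)) == level)
  }
  for (f in names(p)) {
    for (lev in names(p[[f]])) {
      bound <- 3 * sqrt(p[[f]][[lev]] * (1 - p[[f]][[lev]]) / 10000)
      expect_lt(abs(frac(f, lev) - p[[f]][[lev]]), bound + 1e-9)
    }
  }
  # age values and ethnicity codes are consistent with the drawn classes
  cfg <- engine_config()
  for (s in big[1:200]) {
    expect_equal(derive_age_class(s$age_years, cfg$age_threshold), s$levels$age)
    expect_equal(aggregate_ethnicity(s$ethnicity_code,
                                     cfg$ethnicity_vocabulary),
                 s$levels$ethnicity)
  }

  set.seed(7); s1 <- generate_stream(population_model(n = 20))
  set.seed(7); s2 <- generate_stream(population_model(n = 20))
  expect_identical(s1, s2)
})

test_that("trial replay matches the history aggregator and the state store", {
  cfg <- engine_config()
  set.seed(43)
  stream <- generate_stream(population_model(n = 40))
  state <- withr::local_tempfile()
  result <- run_trial(stream, cfg, state_path = state)

  expect_equal(result$decisions[[1]]$mode, "tie_random")
  rebuilt <- aggregate_history(result$records, cfg$scheme)
  expect_equal(rebuilt$control, result$control)
  expect_equal(rebuilt$experimental, result$experimental)

  loaded <- read_state(state, cfg$scheme, cfg$delimiter)
  expect_length(loaded, 40L)
  reloaded <- aggregate_history(loaded, cfg$scheme)
  expect_equal(reloaded$control$totals, result$control$totals)
  expect_equal(reloaded$experimental$count, result$experimental$count)

  # incremental replay step-by-step equals aggregate_history at every step
  control <- arm_aggregate(cfg$scheme)
  experimental <- arm_aggregate(cfg$scheme)
  for (i in seq_along(result$records)) {
    full <- aggregate_history(result$records[seq_len(i)], cfg$scheme)
    rec <- result$records[[i]]
    if (rec$arm == "option1") {
      control <- minimizr:::aggregate_add(control, unclass(rec$values))
    } else {
      experimental <- minimizr:::aggregate_add(experimental, unclass(rec$values))
    }
    expect_equal(full$control, control)
    expect_equal(full$experimental, experimental)
  }
})

test_that("identical config, seed and stream give a byte-identical state file", {
  cfg <- engine_config(randomisation_element = 0.8)
  set.seed(44)
  stream <- generate_stream(population_model(n = 25))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  set.seed(123); run_trial(stream, cfg, state_path = f1)
  set.seed(123); run_trial(stream, cfg, state_path = f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("identical participants alternate under deterministic minimization", {
  cfg <- engine_config(randomisation_element = 1)
  sub <- make_test_submission()
  stream <- rep(list(sub), 30L)
  set.seed(45)
  result <- run_trial(stream, cfg)
  expect_lte(abs(result$control$count - result$experimental$count), 1L)
  report <- balance_report(result)
  expect_lte(attr(report, "max_imbalance"), 1)
  # after the first coin flip every decision is deterministic
  modes <- vapply(result$decisions, `[[`, character(1), "mode")
  expect_equal(modes[1], "tie_random")
  expect_true(all(modes[-1] %in% c("deterministic", "tie_random")))
})

test_that("the balance report lays out per-class totals like a two-arm table", {
  cfg <- engine_config()
  set.seed(46)
  result <- run_trial(generate_stream(population_model(n = 60)), cfg)
  report <- balance_report(result)
  expect_equal(nrow(report), 10L)
  expect_named(report, c("factor", "level", "control", "experimental",
                         "imbalance"))
  # per-factor column sums equal the arm sizes
  for (f in unique(report$factor)) {
    rows <- report[report$factor == f, ]
    expect_equal(sum(rows$control), attr(report, "n_control"))
    expect_equal(sum(rows$experimental), attr(report, "n_experimental"))
  }
  expect_equal(attr(report, "max_imbalance"), max(report$imbalance))

  empty <- run_trial(list(), cfg)
  empty_report <- balance_report(empty)
  expect_equal(attr(empty_report, "n_control"), 0L)
  expect_true(all(empty_report$imbalance == 0))
})

test_that("strategy comparison is reproducible and ranks minimization best", {
  model <- population_model(n = 40)
  set.seed(47)
  tab1 <- compare_strategies(model, r_values = c(0.5, 1), replicates = 30)
  set.seed(47)
  tab2 <- compare_strategies(model, r_values = c(0.5, 1), replicates = 30)
  expect_identical(tab1, tab2)
  expect_equal(nrow(tab1), 2L)
  expect_lt(tab1$mean_max_imbalance[tab1$r == 1],
            tab1$mean_max_imbalance[tab1$r == 0.5])
  expect_error(compare_strategies(model, replicates = 1),
               class = "minimizr_validation_error")
})
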