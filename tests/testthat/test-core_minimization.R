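test_that("class vector sets exactly one weighted position per factor", {
  scheme <- default_scheme()
  sub <- make_test_submission(gender = "female", age = 70L, diabetes = "yes",
                              code = "R")
  v <- unclass(make_class_vector(sub, scheme))
  expect_length(v, 12L)
  expect_equal(unname(v[c("gender.male", "gender.female")]), c(0, 1))
  expect_equal(unname(v[c("age.young", "age.old")]), c(0, 1))
  expect_equal(unname(v[c("diabetes.no", "diabetes.yes")]), c(0, 1))
  expect_equal(unname(v["ethnicity.chinese"]), 1)
  expect_equal(unname(v[c("option1", "option2")]), c(0, 0))
  for (f in names(scheme$factors)) {
    pos <- minimizr:::factor_positions(scheme, f)
    expect_equal(sum(v[pos] != 0), 1L)
  }
})

test_that("level weights flow into the class vector", {
  scheme <- factor_scheme(list(
    gender = c(male = 1, female = 1),
    ethnicity = c(white = 0.5, black = 0.5, asian = 0.5, chinese = 0.5)
  ))
  sub <- list(levels = list(gender = "male", ethnicity = "white"))
  v <- unclass(make_class_vector(sub, scheme))
  expect_equal(unname(v["ethnicity.white"]), 0.5)
  expect_equal(unname(v["gender.male"]), 1)
})

test_that("unknown levels are rejected with the offending value named", {
  scheme <- default_scheme()
  sub <- list(levels = list(gender = "other", age = "young", diabetes = "no",
                            ethnicity = "white"))
  err <- expect_error(make_class_vector(sub, scheme),
                      class = "minimizr_validation_error")
  expect_match(conditionMessage(err), "gender")
  expect_match(conditionMessage(err), "other")
})

test_that("history aggregation matches the per-element summation oracle", {
  scheme <- default_scheme()
  # three hand-built records: 2 control, 1 experimental
  make_rec <- function(gender, age, diabetes, code, arm) {
    sub <- make_test_submission(id = paste0("H", gender, code), gender = gender,
                                age = age, diabetes = diabetes, code = code)
    vec <- make_class_vector(sub, scheme)
    dec <- structure(list(arm = arm, control_score = 0, experimental_score = 0,
                          mode = "tie_random", coin_draw = 0.1),
                     class = "allocation_decision")
    finalize_record(sub, vec, dec, scheme)
  }
  recs <- list(
    make_rec("male", 40L, "no", "A", "option1"),
    make_rec("female", 70L, "yes", "B", "option1"),
    make_rec("male", 40L, "no", "M", "option2")
  )
  arms <- aggregate_history(recs, scheme)
  # hand-computed elementwise sums, frozen
  expect_equal(unname(arms$control$totals),
               c(1, 1, 1, 1, 1, 1, 2, 0, 0, 0))
  expect_equal(unname(arms$experimental$totals),
               c(1, 0, 1, 0, 1, 0, 0, 1, 0, 0))
  expect_equal(c(arms$control$count, arms$experimental$count), c(2L, 1L))

  orc <- oracle_aggregate(recs, scheme)
  expect_equal(unname(arms$control$totals), orc$control)
  expect_equal(unname(arms$experimental$totals), orc$experimental)
})

test_that("aggregation conserves counts per factor and rejects corrupt records", {
  scheme <- default_scheme()
  set.seed(42)
  recs <- replicate(25, random_record(), simplify = FALSE)
  arms <- aggregate_history(recs, scheme)
  for (arm in list(arms$control, arms$experimental)) {
    for (f in names(scheme$factors)) {
      pos <- minimizr:::factor_positions(scheme, f)
      expect_equal(sum(arm$totals[pos]), arm$count)
    }
  }
  expect_equal(arms$control$count + arms$experimental$count, 25L)

  empty <- aggregate_history(list(), scheme)
  expect_true(all(empty$control$totals == 0) && empty$control$count == 0L)

  bad <- recs[[1]]
  bad$values[c("option1", "option2")] <- c(1, 1)
  err <- expect_error(aggregate_history(c(recs[1], list(bad)), scheme),
                      class = "minimizr_corrupt_history_error")
  expect_match(conditionMessage(err), "record 2")
})

test_that("minimization scores reproduce the worked example and a brute-force oracle", {
  wx <- worked_example()
  sc <- arm_scores(wx$vector, wx$control, wx$experimental)
  expect_equal(unname(sc), c(95, 98))

  set.seed(7)
  scheme <- default_scheme()
  for (i in 1:50) {
    control <- arm_aggregate(scheme)
    experimental <- arm_aggregate(scheme)
    control$totals[] <- sample(0:40, 10, replace = TRUE)
    experimental$totals[] <- sample(0:40, 10, replace = TRUE)
    vec <- make_class_vector(random_record()$submission, scheme)
    expect_equal(arm_scores(vec, control, experimental),
                 oracle_scores(vec, control, experimental))
  }

  empty <- aggregate_history(list(), scheme)
  expect_equal(unname(arm_scores(wx$vector, empty$control, empty$experimental)),
               c(0, 0))
  short <- arm_aggregate(factor_scheme(list(g = c("a", "b"))))
  expect_error(arm_scores(wx$vector, short, wx$experimental),
               class = "minimizr_config_error")
})

test_that("biased-coin draw honors its probability exactly at the extremes", {
  set.seed(11)
  expect_true(all(replicate(50, randomise_arm(1)$arm) == "option1"))
  expect_true(all(replicate(50, randomise_arm(0)$arm) == "option2"))
  expect_error(randomise_arm(1.2), class = "minimizr_config_error")
  expect_error(randomise_arm(-0.1), class = "minimizr_config_error")

  set.seed(12)
  draws <- replicate(100000, randomise_arm(0.5)$arm)
  expect_lt(abs(mean(draws == "option1") - 0.5), 0.005)
})

test_that("allocation decision follows scores and the randomization element", {
  wx <- worked_example()
  d <- decide_allocation(wx$vector, wx$control, wx$experimental, r = 1)
  expect_equal(d$arm, "option1")
  expect_equal(d$mode, "deterministic")
  expect_true(is.na(d$coin_draw))
  expect_equal(c(d$control_score, d$experimental_score), c(95, 98))

  # mirrored scores prefer the experimental arm deterministically at r = 1
  d2 <- decide_allocation(wx$vector, wx$experimental, wx$control, r = 1)
  expect_equal(d2$arm, "option2")

  empty <- aggregate_history(list(), default_scheme())
  set.seed(3)
  d3 <- decide_allocation(wx$vector, empty$control, empty$experimental, r = 1)
  expect_equal(d3$mode, "tie_random")
  expect_false(is.na(d3$coin_draw))

  expect_error(decide_allocation(wx$vector, wx$control, wx$experimental, r = 0.3),
               class = "minimizr_config_error")
  expect_error(decide_allocation(wx$vector, wx$control, wx$experimental, r = 1.1),
               class = "minimizr_config_error")
})

test_that("deterministic branch consumes no RNG draw", {
  wx <- worked_example()
  set.seed(99)
  before <- .Random.seed
  decide_allocation(wx$vector, wx$control, wx$experimental, r = 1)
  expect_identical(.Random.seed, before)
})

test_that("fraction allocated against the preferred arm converges to 1 - r", {
  wx <- worked_example()  # control preferred (95 < 98)
  for (r in c(0.8, 0.9)) {
    set.seed(1000 + round(100 * r))
    n <- 20000
    arms <- character(n)
    for (i in seq_len(n)) {
      arms[i] <- decide_allocation(wx$vector, wx$control, wx$experimental, r)$arm
    }
    frac_against <- mean(arms == "option2")
    expect_lt(abs(frac_against - (1 - r)), 3 * sqrt(r * (1 - r) / n))
  }
  set.seed(1100)
  expect_true(all(replicate(200,
    decide_allocation(wx$vector, wx$control, wx$experimental, 1)$arm) == "option1"))
})

test_that("finalizing flips exactly one outcome and refuses double allocation", {
  scheme <- default_scheme()
  wx <- worked_example()
  dec_c <- decide_allocation(wx$vector, wx$control, wx$experimental, r = 1)
  rec <- finalize_record(wx$submission, wx$vector, dec_c, scheme)
  expect_equal(unname(unclass(rec$values)[c("option1", "option2")]), c(1, 0))
  expect_equal(rec$arm_label, "Control Arm")
  expect_equal(rec$participant_id, wx$submission$participant_id)

  dec_e <- decide_allocation(wx$vector, wx$experimental, wx$control, r = 1)
  rec_e <- finalize_record(wx$submission, wx$vector, dec_e, scheme)
  expect_equal(unname(unclass(rec_e$values)[c("option1", "option2")]), c(0, 1))
  expect_equal(rec_e$arm_label, "Experimental Arm")

  expect_error(finalize_record(wx$submission, rec$values, dec_c, scheme),
               class = "minimizr_validation_error")

  # aggregating the single finalized record recovers its own class values
  arms <- aggregate_history(list(rec), scheme)
  expect_equal(arms$control$totals,
               minimizr:::allocation_part(unclass(rec$values)))
  expect_equal(arms$experimental$count, 0L)
})

test_that("default scheme structure is fixed", {
  scheme <- default_scheme()
  expect_equal(n_classes(scheme), 10L)
  expect_equal(length(class_labels(scheme)), 12L)
  expect_equal(tail(class_labels(scheme), 2), c("option1", "option2"))
  expect_error(factor_scheme(list(g = "only_one_level")),
               class = "minimizr_config_error")
  expect_error(factor_scheme(list(g = c(a = -1, b = 1))),
               class = "minimizr_config_error")
})
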