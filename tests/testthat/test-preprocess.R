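make_rt_trials <- function(n, condition = "arabic", participant = 1,
                           rt = seq_len(n) + 300, correct = TRUE,
                           timeout = FALSE) {
  tibble::tibble(
    participant_id = participant, condition = condition,
    block = 1L, trial_index = seq_len(n), digit = rep_len(c(1:4, 6:9), n),
    required_response = "less", given_response = ifelse(correct, "less", "greater"),
    correct = correct,
    rt_ms = ifelse(rep_len(timeout, n), NA_real_, rt),
    timeout = timeout
  )
}

test_that("trimming removes exactly the fastest and slowest half percent", {
  trials <- make_rt_trials(1000)
  clean <- preprocess(trials)
  expect_identical(nrow(clean), 990L) # 5 from each tail
  expect_identical(range(clean$rt_ms), c(306, 1295))
  expect_true(all(c("log_rt") %in% names(clean)))
  expect_equal(clean$log_rt, log(clean$rt_ms))
})

test_that("zero trim keeps every correct responded trial", {
  trials <- make_rt_trials(100)
  clean <- preprocess(trials, clean_config(trim_fraction = 0))
  expect_identical(nrow(clean), 100L)
})

test_that("incorrect and timeout trials never reach the RT set", {
  trials <- dplyr::bind_rows(
    make_rt_trials(200),
    make_rt_trials(20, correct = FALSE),
    make_rt_trials(10, timeout = TRUE)
  )
  clean <- preprocess(trials, clean_config(trim_fraction = 0))
  expect_identical(nrow(clean), 200L)
  expect_true(all(clean$correct))
  counts <- attr(clean, "counts")
  expect_identical(counts$n[counts$step == "input"], 230L)
  expect_identical(counts$n[counts$step == "after_timeout_drop"], 220L)
  expect_identical(counts$n[counts$step == "correct_only"], 200L)
  # error rates are computed on responded trials only
  er <- attr(clean, "error_rates")
  expect_equal(er$error_rate, 20 / 220)
})

test_that("preprocessing is idempotent", {
  ex <- small_experiment(n = 4)
  once <- preprocess(ex$trials)
  twice <- preprocess(once)
  expect_identical(once, twice)
})

test_that("high-error participant-condition cells are excluded and reported", {
  ex <- small_experiment(n = 5, seed = 31)
  prof <- inject_reversal(ex$profiles, which = 2, condition = "mandarin")
  tr <- generate_trials(prof, design_spec(), default_table, ex$params, seed = 6)
  clean <- preprocess(tr)
  excl <- attr(clean, "exclusions")
  expect_identical(excl$participant_id, 2L)
  expect_identical(excl$condition, "mandarin")
  expect_gt(excl$error_rate, 0.9)
  expect_match(excl$reason, "reversal")
  kept <- dplyr::filter(clean, participant_id == 2, condition == "mandarin")
  expect_identical(nrow(kept), 0L)
  # the same participant's other condition survives
  expect_gt(nrow(dplyr::filter(clean, participant_id == 2, condition == "arabic")), 0)
})

test_that("fully degenerate input fails with diagnostic counts", {
  trials <- make_rt_trials(50, correct = FALSE)
  expect_error(preprocess(trials), "input 50")
  expect_error(preprocess(make_rt_trials(0)), "empty")
})

test_that("clean_config validates its ranges", {
  expect_error(clean_config(trim_fraction = 0.5))
  expect_error(clean_config(exclusion_error_rate = 0))
})
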