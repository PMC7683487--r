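test_that("identical conditions give zero t and zero d", {
  base <- small_experiment(n = 4, seed = 71)$trials |>
    dplyr::filter(condition == "arabic")
  mirrored <- dplyr::bind_rows(
    base,
    dplyr::mutate(base, condition = "mandarin")
  )
  cmp <- compare_conditions(preprocess(mirrored))
  rt_row <- dplyr::filter(cmp$tests, measure == "log_rt")
  expect_equal(rt_row$t, 0)
  expect_equal(rt_row$d, 0)
})

test_that("paired comparison matches stats::t.test and the d identities", {
  ex <- small_experiment(n = 10, seed = 81)
  clean <- preprocess(ex$trials)
  cmp <- compare_conditions(clean)
  means <- tibble::as_tibble(clean) |>
    dplyr::group_by(participant_id, condition) |>
    dplyr::summarise(m = mean(log_rt), .groups = "drop") |>
    tidyr::pivot_wider(names_from = condition, values_from = m)
  tt <- t.test(means$arabic, means$mandarin, paired = TRUE)
  rt_row <- dplyr::filter(cmp$tests, measure == "log_rt")
  expect_equal(rt_row$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(rt_row$df, unname(tt$parameter), tolerance = 1e-12)
  expect_equal(rt_row$p, tt$p.value, tolerance = 1e-10)
  # d = t / sqrt(n) equals mean(diff) / sd(diff)
  diffs <- means$arabic - means$mandarin
  expect_equal(rt_row$d, mean(diffs) / sd(diffs), tolerance = 1e-10)
  # back-transform consistency
  expect_equal(
    cmp$by_condition$mean_rt_ms,
    exp(cmp$by_condition$mean_log_rt),
    tolerance = 1e-12
  )
})

test_that("error rates enter the comparison from the preprocessing attribute", {
  ex <- small_experiment(n = 8, seed = 91)
  cmp <- compare_conditions(preprocess(ex$trials))
  expect_setequal(cmp$tests$measure, c("log_rt", "error_rate"))
  expect_true(all(c("mean_error_rate", "sd_error_rate") %in% names(cmp$by_condition)))
  expect_true(all(cmp$by_condition$mean_error_rate >= 0))
})

test_that("d and r conversions match their closed forms on random inputs", {
  set.seed(5)
  for (i in 1:50) {
    n <- sample(5:500, 1)
    # r_to_t against the cor.test oracle on actual data
    x <- rnorm(n)
    y <- 0.5 * x + rnorm(n)
    ct <- cor.test(x, y)
    expect_equal(
      r_to_t(unname(ct$estimate), n - 2),
      unname(ct$statistic),
      tolerance = 1e-8
    )
    # d = t/sqrt(n) identity on paired data
    a <- rnorm(20)
    b <- rnorm(20)
    t <- unname(t.test(a, b, paired = TRUE)$statistic)
    expect_equal(cohens_d_from_t(t, 20), mean(a - b) / sd(a - b), tolerance = 1e-10)
  }
  expect_equal(r_to_t(0, 50), 0)
})

test_that("slope correlations carry their tests and flags", {
  ex <- small_experiment(n = 8, seed = 111)
  clean <- preprocess(ex$trials)
  f1 <- suppressWarnings(fit_condition(clean, default_table, "arabic"))
  f2 <- suppressWarnings(fit_condition(clean, default_table, "mandarin"))
  sc <- correlate_slopes(f1, f2)
  expect_identical(nrow(sc), 4L)
  expect_setequal(
    sc$correlation,
    c(
      "psm_across", "psa_across",
      "psm_psa_within_arabic", "psm_psa_within_mandarin"
    )
  )
  expect_true(all(abs(sc$r) <= 1))
  expect_identical(unique(sc$df), unique(sc$n) - 2L)
  expect_equal(sc$t, r_to_t(sc$r, sc$df), tolerance = 1e-12)
  expect_identical(sc$significant, sc$p < 0.0125)
  expect_identical(sort(tidy(sc)$correlation), sort(sc$correlation))
})

test_that("mismatched participant sets are rejected with ids", {
  ex <- small_experiment(n = 6, seed = 121)
  clean <- preprocess(ex$trials)
  f1 <- suppressWarnings(fit_condition(clean, default_table, "arabic"))
  f2 <- suppressWarnings(fit_condition(clean, default_table, "mandarin"))
  f2$participant_slopes <- dplyr::filter(f2$participant_slopes, participant_id != 3)
  expect_error(correlate_slopes(f1, f2), "3")
  expect_error(correlate_slopes(f1, f1), "different conditions")
})
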