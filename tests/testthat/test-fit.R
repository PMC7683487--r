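test_that("null data recover zero slopes as non-significant", {
  pop <- degenerate_params(sd_resid = 0.15, slopes_zero = TRUE)
  prof <- sample_participants(8, pop, seed = 12)
  tr <- generate_trials(prof, design_spec(), default_table, pop, seed = 13)
  fit <- suppressWarnings(
    fit_condition(preprocess(tr), default_table, "arabic")
  )
  sl <- dplyr::filter(fit$fixed, term != "(Intercept)")
  expect_true(all(abs(sl$estimate) < 3 * sl$se))
  expect_false(any(sl$significant))
})

test_that("OLS slope mode matches a per-participant least-squares oracle", {
  ex <- small_experiment(n = 4, seed = 21)
  clean <- preprocess(ex$trials)
  fit <- suppressWarnings(fit_condition(clean, default_table, "mandarin",
    slopes = "ols"
  ))
  dat <- dplyr::filter(tibble::as_tibble(clean), condition == "mandarin") |>
    dplyr::left_join(
      dplyr::select(default_table, digit, w_z, psm_z, psa_z),
      by = "digit"
    )
  for (pid in unique(dat$participant_id)) {
    d <- dplyr::filter(dat, participant_id == pid)
    co <- coef(lm(log_rt ~ w_z + psm_z + psa_z, data = d))
    row <- dplyr::filter(fit$participant_slopes, participant_id == pid)
    expect_equal(row$b_w, unname(co["w_z"]), tolerance = 1e-10)
    expect_equal(row$b_psm, unname(co["psm_z"]), tolerance = 1e-10)
    expect_equal(row$b_psa, unname(co["psa_z"]), tolerance = 1e-10)
    expect_equal(row$intercept, unname(co["(Intercept)"]), tolerance = 1e-10)
  }
})

test_that("degenerate random effects trigger the flagged fallback ladder", {
  pop <- degenerate_params(sd_resid = 0.1)
  prof <- sample_participants(4, pop, seed = 1)
  tr <- generate_trials(prof, design_spec(), default_table, pop, seed = 2)
  expect_warning(
    fit <- fit_condition(preprocess(tr), default_table, "arabic"),
    "fell back"
  )
  expect_true(fit$fallback)
  expect_true(fit$re_structure %in% c("diagonal", "intercept"))
  # per-participant slopes still produced for every participant
  expect_identical(nrow(fit$participant_slopes), 4L)
})

test_that("slope F tests follow the squared-t convention with design dfs", {
  ex <- small_experiment(n = 6, seed = 41)
  clean <- preprocess(ex$trials)
  fit <- suppressWarnings(fit_condition(clean, default_table, "arabic"))
  expect_equal(fit$fixed$F, fit$fixed$statistic^2, tolerance = 1e-12)
  expect_identical(unique(fit$fixed$df1), 1L)
  expect_identical(unique(fit$fixed$df2), fit$n_obs - fit$n_participants - 3L)
  expect_true(all(fit$fixed$p_f >= 0 & fit$fixed$p_f <= 1))
  # cell-means mode: participants x 8 digit cells
  cfit <- suppressWarnings(
    fit_condition(clean, default_table, "arabic", mode = "cells")
  )
  expect_identical(cfit$n_obs, 6L * 8L)
  expect_identical(unique(cfit$fixed$df2), 6L * 8L - 6L - 3L)
  expect_true(cfit$r2 >= 0 && cfit$r2 <= 1)
})

test_that("r2 is the squared fit-observation correlation", {
  ex <- small_experiment(n = 4, seed = 51)
  clean <- preprocess(ex$trials)
  fit <- suppressWarnings(fit_condition(clean, default_table, "arabic"))
  dat <- dplyr::filter(tibble::as_tibble(clean), condition == "arabic")
  expect_equal(fit$r2, cor(fitted(fit$model), dat$log_rt)^2, tolerance = 1e-10)
  expect_true(fit$r2 >= 0 && fit$r2 <= 1)
})

test_that("fit_condition validates its inputs", {
  ex <- small_experiment(n = 4)
  clean <- preprocess(ex$trials)
  expect_error(fit_condition(clean, default_table), "pass `condition`")
  expect_error(fit_condition(clean, default_table, "cantonese"), "cantonese")
  solo <- dplyr::filter(tibble::as_tibble(clean), participant_id == 1)
  expect_error(fit_condition(solo, default_table, "arabic"), "2 participants")
  bad <- dplyr::mutate(tibble::as_tibble(clean), digit = 5L)
  expect_error(fit_condition(bad, default_table, "arabic"), "standard")
})

test_that("tidy and glance expose the fit in broom style", {
  ex <- small_experiment(n = 4, seed = 61)
  fit <- suppressWarnings(
    fit_condition(preprocess(ex$trials), default_table, "mandarin")
  )
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 4L)
  expect_true(all(c("condition", "term", "estimate", "se", "F", "p_f") %in% names(td)))
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$n_participants, 4L)
})
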