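test_that("zero-variance populations reproduce the means exactly", {
  pop <- degenerate_params()
  prof <- sample_participants(5, pop, seed = 1)
  for (cond in c("arabic", "mandarin")) {
    p <- dplyr::filter(prof, condition == cond)
    expect_equal(p$intercept, rep(pop$intercept[[cond]], 5))
    expect_equal(p$b_w, rep(pop$slopes[[cond]][["w"]], 5))
    expect_equal(p$b_psm, rep(pop$slopes[[cond]][["psm"]], 5))
    expect_equal(p$b_psa, rep(pop$slopes[[cond]][["psa"]], 5))
    expect_equal(p$error_rate, rep(pop$error_rate_mean[[cond]], 5))
  }
})

test_that("profile sampling is reproducible under a fixed seed", {
  a <- sample_participants(6, population_params(), seed = 42)
  b <- sample_participants(6, population_params(), seed = 42)
  expect_identical(a, b)
  c <- sample_participants(6, population_params(), seed = 43)
  expect_false(isTRUE(all.equal(a$b_w, c$b_w)))
})

test_that("sampled slope correlations converge to the population inputs", {
  prof <- sample_participants(10000, population_params(), seed = 9)
  man <- dplyr::filter(prof, condition == "mandarin")
  ara <- dplyr::filter(prof, condition == "arabic")
  expect_lt(abs(cor(man$b_psm, man$b_psa) - -0.58), 0.03)
  expect_lt(abs(cor(ara$b_psm, ara$b_psa) - -0.43), 0.03)
  expect_lt(abs(cor(man$b_psm, ara$b_psm) - 0.42), 0.03)
  expect_lt(abs(cor(man$b_psa, ara$b_psa) - 0.26), 0.03)
  expect_lt(abs(sd(man$b_w) - 0.02), 0.001)
  expect_lt(abs(mean(man$intercept) - 6.19), 0.005)
})

test_that("an unattainable correlation structure is rejected before drawing", {
  expect_error(
    population_params(
      cor_within = c(arabic = -0.95, mandarin = -0.95),
      cor_cross_psm = 0.95, cor_cross_psa = -0.95
    ),
    "positive semidefinite"
  )
})

test_that("counterbalancing groups split participants equally", {
  prof <- sample_participants(64, population_params(), seed = 3)
  one_per <- dplyr::distinct(prof, participant_id, group)
  expect_identical(as.integer(table(one_per$group)), rep(16L, 4))
})

test_that("trial generation balances digits exactly within every block", {
  ex <- small_experiment(n = 4)
  counts <- ex$trials |>
    dplyr::count(participant_id, condition, block, digit)
  expect_true(all(counts$n == 15)) # 120 trials / 8 digits
  per_cell <- ex$trials |> dplyr::count(participant_id, condition)
  expect_true(all(per_cell$n == 480)) # 4 blocks x 120
})

test_that("trial records are internally consistent", {
  ex <- small_experiment(n = 4)
  tr <- ex$trials
  expect_true(all(is.na(tr$rt_ms) | tr$rt_ms <= ex$design$deadline_ms))
  expect_true(all(tr$timeout == is.na(tr$rt_ms)))
  expect_true(all(is.na(tr$given_response[tr$timeout])))
  responded <- dplyr::filter(tr, !timeout)
  expect_identical(
    responded$correct,
    responded$given_response == responded$required_response
  )
  expect_identical(
    responded$required_response,
    ifelse(responded$digit > 5, "greater", "less")
  )
})

test_that("a degenerate population yields deterministic perfect trials", {
  pop <- degenerate_params(sd_resid = 0)
  prof <- sample_participants(3, pop, seed = 1)
  tr <- generate_trials(prof, design_spec(), default_table, pop, seed = 2)
  expect_true(all(tr$correct))
  for (cond in c("arabic", "mandarin")) {
    rts <- tr$rt_ms[tr$condition == cond]
    i <- match(tr$digit[tr$condition == cond], default_table$digit)
    mu <- pop$intercept[[cond]] +
      pop$slopes[[cond]][["w"]] * default_table$w_z[i] +
      pop$slopes[[cond]][["psm"]] * default_table$psm_z[i] +
      pop$slopes[[cond]][["psa"]] * default_table$psa_z[i]
    expect_equal(rts, exp(mu), tolerance = 1e-12)
  }
})

test_that("zero slopes collapse RTs onto the intercept", {
  pop <- degenerate_params(sd_resid = 0, slopes_zero = TRUE)
  prof <- sample_participants(2, pop, seed = 1)
  tr <- generate_trials(prof, design_spec(), default_table, pop, seed = 2)
  expect_equal(
    unique(round(tr$rt_ms[tr$condition == "arabic"], 9)),
    round(exp(6.16), 9)
  )
})

test_that("per-condition grand mean log RT tracks the generating intercepts", {
  ex <- small_experiment(n = 63, seed = 202)
  means <- ex$trials |>
    dplyr::filter(!timeout) |>
    dplyr::group_by(condition) |>
    dplyr::summarise(m = mean(log(rt_ms)))
  expect_equal(means$m[means$condition == "arabic"], 6.16, tolerance = 0.02)
  expect_equal(means$m[means$condition == "mandarin"], 6.19, tolerance = 0.02)
})

test_that("key reversal produces near-total error and nothing else does", {
  ex <- small_experiment(n = 6, seed = 77)
  prof <- inject_reversal(ex$profiles, which = 3, condition = "arabic")
  tr <- generate_trials(prof, design_spec(), default_table, ex$params, seed = 5)
  er <- tr |>
    dplyr::filter(!timeout) |>
    dplyr::group_by(participant_id, condition) |>
    dplyr::summarise(er = mean(!correct), .groups = "drop")
  reversed <- dplyr::filter(er, participant_id == 3, condition == "arabic")
  expect_gt(reversed$er, 0.9)
  others <- dplyr::filter(er, !(participant_id == 3 & condition == "arabic"))
  expect_true(all(others$er < 0.5))
  expect_error(inject_reversal(ex$profiles, which = 99), "99")
})

test_that("trial generation is seed-reproducible", {
  ex <- small_experiment(n = 3, seed = 55)
  t1 <- generate_trials(ex$profiles, design_spec(), default_table, ex$params, seed = 8)
  t2 <- generate_trials(ex$profiles, design_spec(), default_table, ex$params, seed = 8)
  expect_identical(t1, t2)
})

test_that("trial generation validates its inputs", {
  ex <- small_experiment(n = 3)
  expect_error(
    generate_trials(ex$profiles[0, ], design_spec(), default_table, ex$params),
    "empty"
  )
  expect_error(
    generate_trials(
      ex$profiles, design_spec(), default_table[default_table$digit != 7, ],
      ex$params
    ),
    "7"
  )
})
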