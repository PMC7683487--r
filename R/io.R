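#' Reproducible run configuration
#'
#' Bundles everything a run depends on -- design, population parameters,
#' cleaning rules, encoding variant, Welford log base and seed -- into one
#' object that serializes losslessly to YAML, so any artifact on disk can be
#' regenerated from the config echoed in its metadata. A commented template
#' ships at `system.file("extdata", "config-template.yml", package =
#' "digitsim")`.
#'
#' @param design A [design_spec()].
#' @param params A [population_params()].
#' @param clean A [clean_config()].
#' @param arabic_variant See [arabic_variants()].
#' @param log_base Welford log base, `"natural"` or `"base10"`.
#' @param seed Integer seed.
#' @param n_participants Participants to simulate.
#' @param n_reps Replicates for [run_recover()].
#' @param file Path to a YAML file.
#' @param config A `run_config` object.
#'
#' @return `run_config()` and `read_config()`: a `run_config` object;
#'   `write_config()`: the path, invisibly.
#' @export
run_config <- function(design = design_spec(), params = population_params(),
                       clean = clean_config(),
                       arabic_variant = default_arabic_variant(),
                       log_base = "natural", seed = 1L,
                       n_participants = 63L, n_reps = 20L) {
  structure(
    list(
      design = design, params = params, clean = clean,
      arabic_variant = arabic_variant, log_base = log_base,
      seed = as.integer(seed), n_participants = as.integer(n_participants),
      n_reps = as.integer(n_reps)
    ),
    class = "run_config"
  )
}

#' @rdname run_config
#' @export
write_config <- function(config, file) {
  stopifnot(inherits(config, "run_config"))
  raw <- list(
    design = unclass(config$design),
    params = lapply(unclass(config$params), function(x) {
      if (is.list(x)) lapply(x, as.list) else as.list(x)
    }),
    clean = unclass(config$clean),
    arabic_variant = as.list(config$arabic_variant),
    log_base = config$log_base,
    seed = config$seed,
    n_participants = config$n_participants,
    n_reps = config$n_reps
  )
  yaml::write_yaml(raw, file)
  invisible(file)
}

#' @rdname run_config
#' @export
read_config <- function(file) {
  raw <- yaml::read_yaml(file)
  num <- function(x) {
    if (is.null(names(x))) unlist(x) else unlist(x)[names(unlist(x))]
  }
  params <- raw$params
  run_config(
    design = do.call(design_spec, lapply(raw$design, unlist)),
    params = population_params(
      intercept = num(params$intercept),
      slopes = lapply(params$slopes, num),
      sd_intercept = params$sd_intercept[[1]],
      sd_slope = params$sd_slope[[1]],
      sd_resid = params$sd_resid[[1]],
      error_rate_mean = num(params$error_rate_mean),
      error_rate_sd = num(params$error_rate_sd),
      cor_within = num(params$cor_within),
      cor_cross_psm = params$cor_cross_psm[[1]],
      cor_cross_psa = params$cor_cross_psa[[1]]
    ),
    clean = do.call(clean_config, raw$clean),
    arabic_variant = num(raw$arabic_variant),
    log_base = raw$log_base,
    seed = raw$seed,
    n_participants = raw$n_participants,
    n_reps = raw$n_reps
  )
}

config_metadata <- function(config) {
  c(
    sprintf("# digitsim %s", as.character(utils::packageVersion("digitsim"))),
    sprintf("# seed: %d", config$seed),
    sprintf(
      "# arabic_variant: %s",
      paste(names(config$arabic_variant), config$arabic_variant,
        sep = "=", collapse = ","
      )
    ),
    sprintf("# log_base: %s", config$log_base)
  )
}

write_csv_with_meta <- function(x, path, config) {
  readr::write_lines(config_metadata(config), path)
  readr::write_csv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a trial-level CSV
#'
#' Reads the delimited trial format written by [run_simulate()] (leading `#`
#' metadata lines are skipped). Columns may appear in any order; a column
#' `mapping` (named character vector, `c(ours = theirs)`) adapts externally
#' deposited data whose column names differ. The digit column must not
#' contain the standard, which is never a probe.
#'
#' @param path CSV path.
#' @param mapping Optional named character vector mapping this package's
#'   column names to the file's.
#' @param standard The standard digit (rejected if found among probes).
#' @return A trial tibble in canonical column order.
#' @export
read_trials <- function(path, mapping = NULL, standard = 5L) {
  dat <- readr::read_csv(path,
    comment = "#", show_col_types = FALSE,
    progress = FALSE
  )
  if (!is.null(mapping)) {
    missing_src <- setdiff(unname(mapping), names(dat))
    if (length(missing_src)) {
      stop(
        "mapping refers to absent column(s): ",
        paste(missing_src, collapse = ", "),
        call. = FALSE
      )
    }
    dat <- dplyr::rename(dat, !!!rlang::set_names(unname(mapping), names(mapping)))
  }
  required <- c(
    "participant_id", "condition", "block", "trial_index", "digit",
    "required_response", "given_response", "correct", "rt_ms", "timeout"
  )
  missing_cols <- setdiff(required, names(dat))
  if (length(missing_cols)) {
    stop(
      "trial file lacks column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  bad <- which(dat$digit == standard)
  if (length(bad)) {
    stop(sprintf(
      "column `digit` contains the standard %d (first at row %d); the standard is never a probe",
      standard, bad[1]
    ), call. = FALSE)
  }
  dplyr::select(dat, dplyr::all_of(required), dplyr::everything())
}

#' Simulate an experiment and write it to disk
#'
#' Draws participant profiles and trial data under `config` and writes
#' `trials.csv` and `profiles.csv` (plus `config.yml`) into `out_dir`. Reruns
#' with the same config and seed reproduce the trial table byte for byte.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the written paths and the simulated tables.
#' @export
run_simulate <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  table <- predictor_table_for(config)
  profiles <- sample_participants(
    config$n_participants, config$params,
    seed = config$seed, design = config$design
  )
  trials <- generate_trials(
    profiles, config$design, table, config$params,
    seed = config$seed + 100000L
  )
  paths <- list(
    trials = file.path(out_dir, "trials.csv"),
    profiles = file.path(out_dir, "profiles.csv"),
    config = file.path(out_dir, "config.yml")
  )
  write_csv_with_meta(trials, paths$trials, config)
  write_csv_with_meta(profiles, paths$profiles, config)
  write_config(config, paths$config)
  invisible(list(paths = paths, trials = trials, profiles = profiles))
}

#' Run the full analysis pipeline on a trial file or table
#'
#' Executes preprocess, per-condition mixed fits, the condition comparison
#' and the slope-correlation analysis, writing CSV tables, a JSON summary and
#' a plain-text report (all stamped with seed, config and encoding-variant
#' metadata) plus a run log of exclusions, trim counts and any fit fallbacks.
#'
#' @param trials A trial tibble or a path readable by [read_trials()].
#' @param config A [run_config()].
#' @param out_dir Optional output directory; when omitted nothing is written.
#' @param ... Passed to [fit_condition()].
#' @return A list with `clean`, `fits`, `comparison`, `slope_cors`,
#'   `predictor_table` (invisibly when writing).
#' @export
run_analyze <- function(trials, config = run_config(), out_dir = NULL, ...) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(trials)) {
    trials <- read_trials(trials, standard = config$design$standard)
  }
  table <- predictor_table_for(config)
  clean <- preprocess(trials, config$clean)
  conds <- intersect(config$params$conditions, unique(clean$condition))
  if (length(conds) < 2L) {
    stop(
      "expected both conditions in the data, found: ",
      paste(conds, collapse = ", "),
      call. = FALSE
    )
  }
  log_lines <- character()
  fits <- lapply(conds, function(cond) {
    withCallingHandlers(
      fit_condition(clean, table, condition = cond, ...),
      warning = function(w) {
        log_lines <<- c(log_lines, sprintf("[%s] %s", cond, conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    )
  })
  names(fits) <- conds
  comparison <- compare_conditions(clean)
  slope_cors <- correlate_slopes(fits[[1]], fits[[2]])
  result <- list(
    clean = clean, fits = fits, comparison = comparison,
    slope_cors = slope_cors, predictor_table = table
  )
  if (is.null(out_dir)) {
    return(result)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- attr(clean, "counts")
  exclusions <- attr(clean, "exclusions")
  fixed <- purrr::imap_dfr(fits, ~ dplyr::mutate(.x$fixed, condition = .y, .before = 1))
  slopes <- purrr::imap_dfr(
    fits,
    ~ dplyr::mutate(.x$participant_slopes, condition = .y, .before = 1)
  )
  write_csv_with_meta(fixed, file.path(out_dir, "fixed_effects.csv"), config)
  write_csv_with_meta(slopes, file.path(out_dir, "participant_slopes.csv"), config)
  write_csv_with_meta(
    tibble::as_tibble(slope_cors),
    file.path(out_dir, "slope_correlations.csv"), config
  )
  write_csv_with_meta(
    comparison$by_condition,
    file.path(out_dir, "condition_summary.csv"), config
  )
  summary <- list(
    package_version = as.character(utils::packageVersion("digitsim")),
    seed = config$seed,
    arabic_variant = as.list(config$arabic_variant),
    log_base = config$log_base,
    n_participants = fits[[1]]$n_participants,
    counts = counts,
    exclusions = exclusions,
    fixed_effects = fixed,
    comparison = comparison$tests,
    slope_correlations = tibble::as_tibble(slope_cors),
    r2 = purrr::map_dbl(fits, "r2"),
    fallback = purrr::map_lgl(fits, "fallback")
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  log_lines <- c(
    config_metadata(config),
    sprintf(
      "trials: %s",
      paste(sprintf("%s=%d", counts$step, counts$n), collapse = ", ")
    ),
    if (nrow(exclusions)) {
      sprintf(
        "excluded: participant %s [%s] (%s)",
        exclusions$participant_id, exclusions$condition, exclusions$reason
      )
    } else {
      "excluded: none"
    },
    log_lines
  )
  readr::write_lines(log_lines, file.path(out_dir, "run.log"))
  report <- c(
    config_metadata(config),
    "",
    utils::capture.output({
      print(fits[[1]])
      print(fits[[2]])
      print(comparison)
      print(as.data.frame(slope_cors), digits = 3, row.names = FALSE)
    })
  )
  readr::write_lines(report, file.path(out_dir, "report.txt"))
  invisible(result)
}

#' Run a parameter-recovery experiment and write its report
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory.
#' @param ... Passed to [fit_condition()] via [recovery_experiment()].
#' @return The [recovery_experiment()] result (invisibly when writing).
#' @export
run_recover <- function(config = run_config(), out_dir = NULL, ...) {
  stopifnot(inherits(config, "run_config"))
  rec <- recovery_experiment(
    params = config$params, design = config$design,
    n_participants = config$n_participants, n_reps = config$n_reps,
    seed = config$seed, table = predictor_table_for(config),
    config = config$clean, ...
  )
  if (is.null(out_dir)) {
    return(rec)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_csv_with_meta(rec$summary, file.path(out_dir, "recovery_summary.csv"), config)
  write_csv_with_meta(rec$estimates, file.path(out_dir, "recovery_estimates.csv"), config)
  write_csv_with_meta(rec$sign_rates, file.path(out_dir, "recovery_sign_rates.csv"), config)
  jsonlite::write_json(
    list(
      package_version = as.character(utils::packageVersion("digitsim")),
      seed = config$seed, n_reps = rec$n_reps,
      n_participants = rec$n_participants,
      summary = rec$summary, sign_rates = rec$sign_rates
    ),
    file.path(out_dir, "recovery.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(rec)
}

predictor_table_for <- function(config) {
  build_predictor_table(
    standard = config$design$standard,
    spec = welford_spec(log_base = config$log_base),
    arabic_variant = config$arabic_variant
  )
}
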