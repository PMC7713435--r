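#' @title Delimited-text schemas
#' @name file_schemas
#' @description
#' All inputs and exports are headered CSV (UTF-8, `.` decimal):
#' * surveys: `year, outcome, sex, age_lo, age_hi, prevalence, n,
#'   response_rate`
#' * demography: `year, sex, age_lo, age_hi, count` (`sex = "all"` rows with
#'   ages 0-100 are totals)
#' * expenditure: `year, per_capita_usd`
#' * trajectory: one row per year x sex x band x profile x status plus a
#'   yearly flows table.
#' Readers validate ranges and name the offending row and column.
NULL

.check_cols <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
}

.check_range <- function(df, col, lo, hi, path) {
  bad <- which(!is.finite(df[[col]]) | df[[col]] < lo | df[[col]] > hi)
  if (length(bad)) {
    stop(sprintf("%s: column '%s' out of range [%g, %g] at row %d (value %s)",
                 path, col, lo, hi, bad[1], format(df[[col]][bad[1]])),
         call. = FALSE)
  }
}

#' Read / write survey prevalence data
#'
#' @param path File path.
#' @return `read_survey_data()`: a validated data frame.
#' @export
read_survey_data <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  .check_cols(df, c("year", "outcome", "sex", "age_lo", "age_hi",
                    "prevalence", "n", "response_rate"), path)
  .check_range(df, "prevalence", 0, 1, path)
  .check_range(df, "response_rate", 1e-9, 1, path)
  .check_range(df, "n", 1, Inf, path)
  bad <- which(df$age_lo >= df$age_hi)
  if (length(bad)) {
    stop(sprintf("%s: age_lo >= age_hi at row %d", path, bad[1]),
         call. = FALSE)
  }
  bad <- which(!df$outcome %in% c("t2dm", .factors))
  if (length(bad)) {
    stop(sprintf("%s: unknown outcome '%s' at row %d", path,
                 df$outcome[bad[1]], bad[1]), call. = FALSE)
  }
  df
}

#' @rdname read_survey_data
#' @param df Data frame to write.
#' @export
write_survey_data <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write demographic target data
#'
#' @param path File path.
#' @export
read_demography_data <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  .check_cols(df, c("year", "sex", "age_lo", "age_hi", "count"), path)
  .check_range(df, "count", 0, Inf, path)
  .check_range(df, "year", 1950, 2050, path)
  df
}

#' @rdname read_demography_data
#' @param df Data frame to write.
#' @export
write_demography_data <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write per-capita expenditure data
#'
#' @param path File path.
#' @export
read_expenditure_data <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  .check_cols(df, c("year", "per_capita_usd"), path)
  .check_range(df, "per_capita_usd", 0, Inf, path)
  df
}

#' @rdname read_expenditure_data
#' @param df Data frame to write.
#' @export
write_expenditure_data <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export / import a trajectory
#'
#' The compartment table has one row per year x sex x band x profile x
#' status; the flows table carries the cumulative birth/death/new-case
#' counters. Values round-trip at full double precision.
#'
#' @param traj A `t2dm_trajectory`.
#' @param path Base path; writes `<path>_compartments.csv` and
#'   `<path>_flows.csv`.
#' @return `write_trajectory()`: the two paths, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  space <- traj$space
  B <- space$n_age_bands
  im <- space$index_map
  comp <- do.call(rbind, lapply(seq_along(traj$years), function(i) {
    data.frame(year = traj$years[i], im[, c("sex", "band", "profile",
                                            "status")],
               persons = traj$state[i, im$index])
  }))
  flows <- do.call(rbind, lapply(seq_along(traj$years), function(i) {
    fl <- cumulative_flows(traj, traj$years[i])
    data.frame(
      year = traj$years[i],
      sex = rep(.sexes, each = B + 2),
      quantity = rep(c("cum_births", "cum_deaths",
                       paste0("cum_new_cases_band", seq_len(B))), 2),
      value = c(fl$births["male"], fl$deaths["male"], fl$new_cases["male", ],
                fl$births["female"], fl$deaths["female"],
                fl$new_cases["female", ])
    )
  }))
  p1 <- paste0(path, "_compartments.csv")
  p2 <- paste0(path, "_flows.csv")
  df1 <- comp
  df1$persons <- format(df1$persons, digits = 17, scientific = TRUE,
                        trim = TRUE)
  write.csv(df1, p1, row.names = FALSE, quote = FALSE)
  df2 <- flows
  df2$value <- format(df2$value, digits = 17, scientific = TRUE, trim = TRUE)
  write.csv(df2, p2, row.names = FALSE, quote = FALSE)
  invisible(c(p1, p2))
}

#' @rdname write_trajectory
#' @param params The `t2dm_params` that produced the export (the trajectory
#'   container carries its parameters; file exports do not).
#' @export
read_trajectory <- function(path, params) {
  comp <- read.csv(paste0(path, "_compartments.csv"),
                   stringsAsFactors = FALSE)
  flows <- read.csv(paste0(path, "_flows.csv"), stringsAsFactors = FALSE)
  space <- build_state_space(params$n_age_bands)
  B <- space$n_age_bands
  years <- sort(unique(comp$year))
  n <- 32L * B + 4L + 2L * B
  st <- matrix(0, nrow = length(years), ncol = n)
  for (i in seq_along(years)) {
    sub <- comp[comp$year == years[i], ]
    idx <- state_index(space, sub$sex, sub$band, sub$profile, sub$status)
    st[i, idx] <- sub$persons
    fl <- flows[flows$year == years[i], ]
    for (sx in 1:2) {
      fsub <- fl[fl$sex == .sexes[sx], ]
      st[i, 32L * B + sx] <- fsub$value[fsub$quantity == "cum_births"]
      st[i, 32L * B + 2L + sx] <- fsub$value[fsub$quantity == "cum_deaths"]
      bands <- as.integer(sub("cum_new_cases_band", "",
                              grep("band", fsub$quantity, value = TRUE)))
      st[i, 32L * B + 4L + (sx - 1L) * B + bands] <-
        fsub$value[grep("band", fsub$quantity)]
    }
  }
  structure(list(years = years, state = st, space = space, params = params),
            class = "t2dm_trajectory")
}

#' Write a fit report
#'
#' Dumps a `t2dm_fit` as structured key-value JSON: best-fit parameters,
#' stage costs, convergence diagnostics and the recorded start points.
#'
#' @param fit A `t2dm_fit`.
#' @param path Output path.
#' @export
write_fit_report <- function(fit, path) {
  jsonlite::write_json(list(
    cost = fit$cost,
    stage_costs = fit$stage_costs,
    evaluations = fit$evaluations,
    iterations = fit$iterations,
    converged = fit$converged,
    x0 = fit$x0,
    parameters = as.list(fit$par)
  ), path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Export an uncertainty analysis
#'
#' Writes the year/point/lo/hi summary and the per-run log (run id, seed,
#' sampled inputs, refit cost, convergence) as two CSV files.
#'
#' @param res A `t2dm_uncertainty`.
#' @param path Base path; writes `<path>_summary.csv` and `<path>_runs.csv`.
#' @export
write_uncertainty <- function(res, path) {
  p1 <- paste0(path, "_summary.csv")
  p2 <- paste0(path, "_runs.csv")
  write.csv(res$summary, p1, row.names = FALSE)
  write.csv(res$runs, p2, row.names = FALSE)
  invisible(c(p1, p2))
}

#' Write / read a model parameter configuration
#'
#' Serializes a `t2dm_params` object to a nested key-value (YAML) text file
#' and back, exactly.
#'
#' @param params A `t2dm_params`.
#' @param path File path.
#' @export
write_model_config <- function(params, path) {
  plain <- unclass(params)
  # yaml drops names of atomic vectors; store named vectors as maps
  plain$mort$logscale <- as.list(params$mort$logscale)
  plain$rr$t2dm <- as.list(params$rr$t2dm)
  plain$rr$mortality_ci <- as.list(params$rr$mortality_ci)
  plain$obesity_mult_2050 <- as.list(params$obesity_mult_2050)
  plain$inc$log_rate <- .mat_to_list(params$inc$log_rate)
  plain$init$logit_prev <- .mat_to_list(params$init$logit_prev)
  plain$rr$t2dm_ci <- .mat_to_list(params$rr$t2dm_ci)
  for (f in .factors) {
    plain$trans$on[[f]] <- .mat_to_list(params$trans$on[[f]])
    plain$trans$off[[f]] <- .mat_to_list(params$trans$off[[f]])
  }
  writeLines(yaml::as.yaml(plain, precision = 15), path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  plain <- yaml::yaml.load_file(path)
  plain$inc$log_rate <- .list_to_mat(plain$inc$log_rate)
  plain$init$logit_prev <- .list_to_mat(plain$init$logit_prev)
  plain$rr$t2dm_ci <- .list_to_mat(plain$rr$t2dm_ci, rows = c("lo", "hi"))
  for (f in .factors) {
    plain$trans$on[[f]] <- .list_to_mat(plain$trans$on[[f]])
    plain$trans$off[[f]] <- .list_to_mat(plain$trans$off[[f]])
  }
  for (nm in c("logscale")) {
    plain$mort[[nm]] <- unlist(plain$mort[[nm]])
  }
  plain$rr$t2dm <- unlist(plain$rr$t2dm)
  plain$rr$mortality_ci <- unlist(plain$rr$mortality_ci)
  plain$obesity_mult_2050 <- unlist(plain$obesity_mult_2050)
  plain$cbr$years <- as.numeric(unlist(plain$cbr$years))
  plain$cbr$values <- as.numeric(unlist(plain$cbr$values))
  plain$n_age_bands <- as.integer(plain$n_age_bands)
  class(plain) <- "t2dm_params"
  validate_params(plain)
  plain
}

.mat_to_list <- function(m) {
  out <- lapply(seq_len(nrow(m)), function(i) as.list(setNames(m[i, ],
                                                               colnames(m))))
  names(out) <- rownames(m)
  out
}

.list_to_mat <- function(l, rows = NULL) {
  m <- do.call(rbind, lapply(l, function(r) unlist(r)))
  rownames(m) <- if (is.null(rows)) names(l) else rows
  m
}

#' Run the full analysis pipeline
#'
#' Generates (or reads) the inputs, fits the model in two stages, projects
#' the epidemic, decomposes attributable fractions, attributes expenditure,
#' optionally runs the Monte Carlo uncertainty analyses, and writes every
#' module's export files plus a JSON run manifest to `out_dir`.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed for all generated randomness.
#' @param surveys,targets,expenditure Optional pre-loaded inputs; when
#'   `NULL`, a seeded synthetic fixture is generated.
#' @param config A [fit_config()].
#' @param report_years Years for the epidemiological and cost reports.
#' @param r_as Expenditure ratios (default `c(2, 3)`).
#' @param n_uncertainty Monte Carlo runs per analysis (0 disables; keep
#'   small for desk-scale runs).
#' @param params Starting parameter scaffold.
#' @return A list with the fitted object, reports, and written paths.
#' @export
run_pipeline <- function(out_dir, seed = 1, surveys = NULL, targets = NULL,
                         expenditure = NULL, config = fit_config(),
                         report_years = seq(1990, 2050, 10),
                         r_as = c(2, 3), n_uncertainty = 0,
                         params = default_model_params()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  synthetic <- is.null(surveys)
  truth <- NULL
  if (synthetic) {
    truth <- make_ground_truth(seed)
    surveys <- generate_surveys(truth, seed = seed)
    targets <- generate_demography_targets(truth)
  }
  if (is.null(expenditure)) expenditure <- generate_expenditure_series(seed)

  fit <- fit_model(surveys, targets, config, params = params)
  traj <- simulate_model(fit$params, t0 = 1950, t1 = max(report_years) + 1)
  epi <- epi_report(traj, report_years)
  paf <- do.call(rbind, lapply(report_years, function(y) {
    cbind(year = y, paf_decomposition(traj, y))
  }))
  scenarios <- unlist(lapply(r_as, function(r) {
    lapply(c("fixed_post_2015", "extrapolated_trend"), function(m) {
      list(r_as = r, mode = m)
    })
  }), recursive = FALSE)
  costs <- cost_report(traj, scenarios, expenditure, years = report_years)

  unc <- NULL
  if (n_uncertainty > 0) {
    spec <- uncertainty_spec(n_runs = n_uncertainty, seed = seed,
                             output_years = report_years)
    unc <- mc_parameter_uncertainty(spec, surveys, targets, config, fit)
  }

  paths <- list(
    surveys = file.path(out_dir, "surveys.csv"),
    demography = file.path(out_dir, "demography.csv"),
    expenditure = file.path(out_dir, "expenditure.csv"),
    epi = file.path(out_dir, "epi_report.csv"),
    paf = file.path(out_dir, "paf.csv"),
    costs = file.path(out_dir, "costs.csv"),
    fit = file.path(out_dir, "fit_params.yaml"),
    fit_report = file.path(out_dir, "fit_report.json"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_survey_data(do.call(rbind, surveys), paths$surveys)
  write_demography_data(targets, paths$demography)
  write_expenditure_data(expenditure, paths$expenditure)
  write.csv(epi, paths$epi, row.names = FALSE)
  write.csv(paf, paths$paf, row.names = FALSE)
  write.csv(costs, paths$costs, row.names = FALSE)
  write_model_config(fit$params, paths$fit)
  write_fit_report(fit, paths$fit_report)
  if (!is.null(unc)) {
    paths$uncertainty <- file.path(out_dir, "uncertainty")
    write_uncertainty(unc, paths$uncertainty)
  }

  recovery <- NULL
  if (synthetic) {
    tr_cells <- truth$cells
    err <- vapply(seq_len(nrow(tr_cells)), function(i) {
      abs(model_prevalence(traj, tr_cells$outcome[i], tr_cells$sex[i],
                           tr_cells$age_lo[i], tr_cells$age_hi[i],
                           tr_cells$year[i]) - tr_cells$prevalence[i])
    }, numeric(1))
    recovery <- list(max_abs_error = max(err), mean_abs_error = mean(err))
  }

  manifest <- list(
    package = "t2dmdyn",
    version = as.character(utils::packageVersion("t2dmdyn")),
    seed = seed,
    synthetic_inputs = synthetic,
    n_equations = 32L * params$n_age_bands,
    fit_cost = fit$cost,
    fit_converged = fit$converged,
    recovery = recovery,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  list(fit = fit, trajectory = traj, epi = epi, paf = paf, costs = costs,
       uncertainty = unc, recovery = recovery, truth = truth, paths = paths)
}
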