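#' Lognormal distribution matching a point estimate and 95% CI
#'
#' Anchors the median at the point estimate and sets the log-scale spread
#' from the CI: `meanlog = log(point)`,
#' `sdlog = (log(hi) - log(lo)) / (2 * 1.959964)`.
#'
#' @param point Point estimate (> 0).
#' @param lo,hi 95% CI bounds, `0 < lo <= point <= hi`.
#' @return List `meanlog`, `sdlog`.
#' @export
lognormal_from_ci <- function(point, lo, hi) {
  if (!(lo > 0 && lo <= point && point <= hi)) {
    stop("require 0 < lo <= point <= hi", call. = FALSE)
  }
  z975 <- qnorm(0.975)
  list(meanlog = log(point), sdlog = (log(hi) - log(lo)) / (2 * z975))
}

#' Uncertainty analysis specification
#'
#' @param n_runs Number of Monte Carlo runs (default 1000; reduced in tests).
#' @param seed Integer seed; run `i` uses `seed + i`.
#' @param rr_ci Named list of `c(point, lo, hi)` for the sampled parameters
#'   (defaults taken from the parameter object's stored CIs:
#'   `rr_obesity`, `rr_smoking`, `rr_inactivity`, `rr_mortality`).
#' @param data_pm Half-width of the uniform multiplicative data perturbation
#'   (default 0.4, i.e. U(0.6, 1.4)).
#' @param quantiles UI quantiles (default 2.5% / 97.5%).
#' @param output_years Years at which prevalence is recorded (default
#'   `seq(1990, 2050, 10)`).
#' @param age_range Prevalence age range (default 20-79).
#' @return A `t2dm_uncertainty_spec` list.
#' @export
uncertainty_spec <- function(n_runs = 1000, seed = 1, rr_ci = NULL,
                             data_pm = 0.4, quantiles = c(0.025, 0.975),
                             output_years = seq(1990, 2050, 10),
                             age_range = c(20, 80)) {
  stopifnot(n_runs >= 1, data_pm >= 0, length(quantiles) == 2)
  structure(list(n_runs = as.integer(n_runs), seed = as.integer(seed),
                 rr_ci = rr_ci, data_pm = data_pm, quantiles = quantiles,
                 output_years = output_years, age_range = age_range),
            class = "t2dm_uncertainty_spec")
}

.default_rr_ci <- function(params) {
  ci <- params$rr$t2dm_ci
  list(
    rr_obesity = c(params$rr$t2dm[["obesity"]], ci["lo", "obesity"],
                   ci["hi", "obesity"]),
    rr_smoking = c(params$rr$t2dm[["smoking"]], ci["lo", "smoking"],
                   ci["hi", "smoking"]),
    rr_inactivity = c(params$rr$t2dm[["inactivity"]], ci["lo", "inactivity"],
                      ci["hi", "inactivity"]),
    rr_mortality = c(params$rr$mortality, params$rr$mortality_ci[["lo"]],
                     params$rr$mortality_ci[["hi"]])
  )
}

.set_rr <- function(params, rr) {
  for (nm in names(rr)) {
    v <- rr[[nm]]
    if (nm == "rr_mortality") params$rr$mortality <- v
    else params$rr$t2dm[[sub("^rr_", "", nm)]] <- v
  }
  # keep CIs bracketing the sampled point so validation passes
  if (!is.null(params$rr$t2dm_ci)) {
    params$rr$t2dm_ci["lo", ] <- pmin(params$rr$t2dm_ci["lo", ],
                                      params$rr$t2dm)
    params$rr$t2dm_ci["hi", ] <- pmax(params$rr$t2dm_ci["hi", ],
                                      params$rr$t2dm)
  }
  params
}

#' Univariate sensitivity sweep of a relative risk
#'
#' Re-runs (optionally refits) the model across a grid of values for one
#' relative risk and reports projected T2DM prevalence at `year`.
#'
#' @param param_name One of `"rr_obesity"`, `"rr_smoking"`,
#'   `"rr_inactivity"`, `"rr_mortality"`.
#' @param values Numeric grid of RR values.
#' @param fit A `t2dm_fit` (the base calibration).
#' @param surveys,targets Data used when `refit = TRUE`.
#' @param config Fit configuration for refits (default: the fit's own,
#'   warm-started).
#' @param refit Refit the epidemiological stage at each value (default
#'   `FALSE`: projection only).
#' @param year Report year (default 2050).
#' @param age_range Default ages 20-79.
#' @return Data frame `value`, `prevalence_pct`.
#' @export
univariate_sweep <- function(param_name, values, fit, surveys = NULL,
                             targets = NULL, config = NULL, refit = FALSE,
                             year = 2050, age_range = c(20, 80)) {
  known <- c("rr_obesity", "rr_smoking", "rr_inactivity", "rr_mortality")
  if (!param_name %in% known) {
    stop("unknown parameter name '", param_name, "'", call. = FALSE)
  }
  out <- data.frame(value = values, prevalence_pct = NA_real_)
  for (i in seq_along(values)) {
    p <- .set_rr(fit$params, setNames(list(values[i]), param_name))
    if (refit) {
      cfg <- if (is.null(config)) fit$config else config
      cfg$x0 <- "params"
      rf <- fit_model(surveys, targets, cfg, params = p)
      p <- rf$params
    }
    traj <- simulate_model(p, t1 = year)
    out$prevalence_pct[i] <- 100 * model_prevalence(
      traj, "t2dm", "both", age_range[1], age_range[2], year)
  }
  out
}

# shared machinery for the two Monte Carlo refit analyses
.mc_runs <- function(spec, surveys, targets, config, base_fit, draw_fun) {
  config$x0 <- "params"  # warm start each refit at the base calibration
  yrs <- spec$output_years
  prev <- matrix(NA_real_, nrow = spec$n_runs, ncol = length(yrs))
  runs <- list()
  failed <- 0L
  for (i in seq_len(spec$n_runs)) {
    run_seed <- spec$seed + i
    drawn <- .with_seed(run_seed, draw_fun)
    res <- tryCatch({
      ft <- fit_model(drawn$surveys, targets, config, params = drawn$params)
      traj <- simulate_model(ft$params, t1 = max(yrs))
      pv <- vapply(yrs, function(y) {
        100 * model_prevalence(traj, "t2dm", "both", spec$age_range[1],
                               spec$age_range[2], y)
      }, numeric(1))
      list(prev = pv, cost = ft$cost, converged = ft$converged)
    }, error = function(e) NULL)
    log_cols <- if (is.null(drawn$log)) NULL else as.data.frame(drawn$log)
    if (is.null(res)) {
      failed <- failed + 1L
      row <- data.frame(run = i, seed = run_seed, cost = NA_real_,
                        converged = FALSE, ok = FALSE)
    } else {
      prev[i, ] <- res$prev
      row <- data.frame(run = i, seed = run_seed, cost = res$cost,
                        converged = res$converged, ok = TRUE)
    }
    runs[[i]] <- if (is.null(log_cols)) row else cbind(row, log_cols)
  }
  ok <- !is.na(prev[, 1])
  if (!any(ok)) stop("all uncertainty runs failed", call. = FALSE)
  qs <- apply(prev[ok, , drop = FALSE], 2, quantile, probs = spec$quantiles)
  base_traj <- simulate_model(base_fit$params, t1 = max(yrs))
  point <- vapply(yrs, function(y) {
    100 * model_prevalence(base_traj, "t2dm", "both", spec$age_range[1],
                           spec$age_range[2], y)
  }, numeric(1))
  structure(list(
    summary = data.frame(year = yrs, point = point, lo = qs[1, ],
                         hi = qs[2, ]),
    prevalence = prev,
    runs = do.call(rbind, runs),
    n_failed = failed,
    high_failure = failed > 0.1 * spec$n_runs,
    spec = spec
  ), class = "t2dm_uncertainty")
}

# evaluate fun() under a temporary RNG state
.with_seed <- function(seed, fun) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  fun()
}

#' Monte Carlo parameter uncertainty (lognormal RR sampling + refit)
#'
#' Each run samples the relative risks from lognormal distributions matched
#' to their 95% CIs ([lognormal_from_ci()]), refits the epidemiological
#' stage (demography fixed, warm-started at the base calibration), and
#' records the projected T2DM prevalence; the 95% UI is the empirical
#' quantile envelope across completed runs.
#'
#' @param spec An [uncertainty_spec()].
#' @param surveys,targets Calibration data.
#' @param config Fit configuration for the refits.
#' @param base_fit The base `t2dm_fit`.
#' @return A `t2dm_uncertainty` object: `summary` (year, point, lo, hi),
#'   per-run log `runs`, the run-by-year prevalence matrix, `n_failed`, and
#'   a `high_failure` flag (> 10% failed runs).
#' @export
mc_parameter_uncertainty <- function(spec, surveys, targets, config,
                                     base_fit) {
  rr_ci <- if (is.null(spec$rr_ci)) .default_rr_ci(base_fit$params) else
    spec$rr_ci
  dists <- lapply(rr_ci, function(v) lognormal_from_ci(v[1], v[2], v[3]))
  .mc_runs(spec, surveys, targets, config, base_fit, function() {
    rr <- lapply(dists, function(d) rlnorm(1, d$meanlog, d$sdlog))
    list(params = .set_rr(base_fit$params, rr), surveys = surveys,
         log = rr)
  })
}

#' Monte Carlo data uncertainty (uniform survey perturbation + refit)
#'
#' Each run multiplies every survey prevalence measure independently by
#' `U(1 - data_pm, 1 + data_pm)` (default +/-40%), clips to `[0, 1]`,
#' refits the epidemiological stage, and records projected prevalence; the
#' 95% UI is the empirical quantile envelope.
#'
#' @inheritParams mc_parameter_uncertainty
#' @return A `t2dm_uncertainty` object.
#' @export
mc_data_uncertainty <- function(spec, surveys, targets, config, base_fit) {
  recs <- .survey_records(surveys)
  .mc_runs(spec, surveys, targets, config, base_fit, function() {
    pert <- recs
    u <- runif(nrow(pert), 1 - spec$data_pm, 1 + spec$data_pm)
    pert$prevalence <- pmin(1, pmax(0, pert$prevalence * u))
    list(params = base_fit$params, surveys = pert,
         log = list(min_prevalence = min(pert$prevalence),
                    max_prevalence = max(pert$prevalence)))
  })
}

#' @export
print.t2dm_uncertainty <- function(x, ...) {
  cat(sprintf("<t2dm_uncertainty> %d runs (%d failed)\n",
              x$spec$n_runs, x$n_failed))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
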