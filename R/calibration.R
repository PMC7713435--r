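#' Fitting configuration
#'
#' @param stage `"two_stage"` (demography first, then epidemiology with
#'   demography fixed; the default), or a single stage `"demography"`,
#'   `"epidemiology"`, or `"joint"` (epidemiological + `demo_weight` x
#'   demographic cost).
#' @param tol Termination tolerance on the simplex spread of cost values
#'   (default `1e-4`).
#' @param max_iter Iteration cap per simplex run (default
#'   `200 * n_parameters`).
#' @param blocks Epidemiological parameter blocks to free (default all:
#'   `"obesity"`, `"smoking"`, `"inactivity"`, `"dm"`). An empty character
#'   vector freezes the epidemiological stage.
#' @param cycles Number of block-cyclic sweeps over the epidemiological
#'   blocks (default 2).
#' @param x0 Start point: `"mid_bounds"` (default) or `"params"` (warm start
#'   at the values in the supplied parameter object).
#' @param lambda Ridge regularization strength (>= 0, default 0): adds
#'   `lambda * sum(((theta - theta_ref) / (upper - lower))^2)` over the free
#'   parameters.
#' @param theta_ref Ridge reference: `"mid_bounds"` (default) or `"initial"`
#'   (the start values), or a named numeric vector.
#' @param demo_weight Scale applied to the demographic cost in `"joint"`
#'   fits (default 1).
#' @param rtol,atol Integration tolerances used inside the cost function
#'   (defaults `1e-6` / `1e-3`; looser than projection runs because the cost
#'   surface needs far less resolution than the reported outputs).
#' @param penalty Finite cost assigned when a simulation fails (default
#'   `1e12`), so the simplex can retreat.
#' @return A `t2dm_fit_config` list.
#' @export
fit_config <- function(stage = c("two_stage", "demography", "epidemiology",
                                 "joint"),
                       tol = 1e-4, max_iter = NULL,
                       blocks = c("obesity", "smoking", "inactivity", "dm"),
                       cycles = 2, x0 = c("mid_bounds", "params"),
                       lambda = 0, theta_ref = "mid_bounds",
                       demo_weight = 1, rtol = 1e-6, atol = 1e-3,
                       penalty = 1e12) {
  stopifnot(tol > 0, lambda >= 0, cycles >= 1)
  structure(list(
    stage = match.arg(stage), tol = tol, max_iter = max_iter,
    blocks = blocks, cycles = cycles, x0 = match.arg(x0),
    lambda = lambda, theta_ref = theta_ref, demo_weight = demo_weight,
    rtol = rtol, atol = atol, penalty = penalty
  ), class = "t2dm_fit_config")
}

#' Free-parameter table
#'
#' Enumerates the fittable parameters of a `t2dm_params` object with their
#' current values, box bounds and block membership. Rates are fitted on the
#' log scale and initial prevalences on the logit scale.
#'
#' @param params A `t2dm_params` object.
#' @return Data frame `name`, `value`, `lower`, `upper`, `block`.
#' @export
param_table <- function(params) {
  rows <- list()
  add <- function(name, value, lower, upper, block) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, value = value, lower = lower, upper = upper, block = block)
  }
  for (i in seq_along(params$cbr$years)) {
    add(paste0("cbr_", params$cbr$years[i]), params$cbr$values[i],
        0.008, 0.065, "demography")
  }
  for (s in .sexes) {
    add(paste0("mort_logscale_", s), params$mort$logscale[[s]],
        -0.9, 0.9, "demography")
  }
  for (f in .factors) {
    blk <- f
    for (s in .sexes) {
      for (k in seq_along(params$trans$knot_ages)) {
        a <- params$trans$knot_ages[k]
        add(paste0("on_", f, "_", s, "_", a), params$trans$on[[f]][s, k],
            log(5e-4), log(0.6), blk)
        add(paste0("off_", f, "_", s, "_", a), params$trans$off[[f]][s, k],
            log(5e-4), log(0.6), blk)
      }
      add(paste0("init_", f, "_", s), params$init$logit_prev[s, f],
          qlogis(0.005), qlogis(0.8), blk)
    }
  }
  for (s in .sexes) {
    add(paste0("obtrend_", s), params$obesity_mult_2050[[s]],
        0.5, 6, "obesity")
  }
  for (s in .sexes) {
    for (k in seq_along(params$inc$knot_ages)) {
      a <- params$inc$knot_ages[k]
      add(paste0("inc_", s, "_", a), params$inc$log_rate[s, k],
          log(1e-5), log(0.12), "dm")
    }
    add(paste0("init_t2dm_", s), params$init$logit_prev[s, "t2dm"],
        qlogis(0.001), qlogis(0.5), "dm")
  }
  do.call(rbind, rows)
}

#' Apply a named parameter vector
#'
#' Writes values named as in [param_table()] back into a `t2dm_params`
#' object (inverse of reading the table's `value` column).
#'
#' @param params A `t2dm_params` object.
#' @param x Named numeric vector (any subset of [param_table()] names).
#' @return The updated `t2dm_params`.
#' @export
set_params <- function(params, x) {
  stopifnot(!is.null(names(x)), !anyNA(names(x)))
  for (nm in names(x)) {
    v <- as.numeric(x[[nm]])
    parts <- strsplit(nm, "_", fixed = TRUE)[[1]]
    head1 <- parts[1]
    if (head1 == "cbr") {
      i <- match(as.numeric(parts[2]), params$cbr$years)
      params$cbr$values[i] <- v
    } else if (head1 == "mort") {
      params$mort$logscale[[parts[3]]] <- v
    } else if (head1 %in% c("on", "off")) {
      f <- parts[2]; s <- parts[3]
      k <- match(as.numeric(parts[4]), params$trans$knot_ages)
      params$trans[[head1]][[f]][s, k] <- v
    } else if (head1 == "init") {
      params$init$logit_prev[parts[3], parts[2]] <- v
    } else if (head1 == "obtrend") {
      params$obesity_mult_2050[[parts[2]]] <- v
    } else if (head1 == "inc") {
      s <- parts[2]
      k <- match(as.numeric(parts[3]), params$inc$knot_ages)
      params$inc$log_rate[s, k] <- v
    } else {
      stop(sprintf("unknown parameter name '%s'", nm), call. = FALSE)
    }
    if (anyNA(v)) stop(sprintf("invalid value for '%s'", nm), call. = FALSE)
  }
  params
}

# combine a list of survey data frames into one record table
.survey_records <- function(surveys) {
  if (is.data.frame(surveys)) surveys <- list(surveys)
  recs <- do.call(rbind, surveys)
  req <- c("year", "outcome", "sex", "age_lo", "age_hi", "prevalence",
           "response_rate")
  missing <- setdiff(req, names(recs))
  if (length(missing)) {
    stop("survey data lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  recs
}

# model population count over a sex / age range at a year
.model_count <- function(traj, year, sex, age_lo, age_hi) {
  occ <- occupancy(traj, year)
  w <- .band_weights(traj$space, age_lo, age_hi)
  s <- if (sex == "all") .sexes else sex
  sum(apply(occ[, , , s, drop = FALSE], 3, sum) * w)
}

# simulate at exactly the years the cost terms need
.cost_trajectory <- function(params, years, config) {
  t1 <- max(years)
  simulate_model(params, t0 = 1950, t1 = t1,
                 output_years = sort(unique(years)),
                 rtol = config$rtol, atol = config$atol)
}

#' Weighted least-squares calibration cost
#'
#' Simulates the model and returns the weighted sum of squared residuals.
#' Survey residuals are differences between modelled and observed prevalence,
#' weighted by the record's (sex-specific) survey response rate, normalized
#' to mean 1; demographic residuals are relative errors of population counts
#' (unit weights). The `"joint"` part adds `demo_weight` times the
#' demographic cost to the survey cost. With `lambda > 0`, a ridge penalty
#' on bound-normalized free parameters is added.
#'
#' @param params A `t2dm_params` object (the point at which to evaluate).
#' @param surveys A survey data frame or list of them (columns `year`,
#'   `outcome`, `sex`, `age_lo`, `age_hi`, `prevalence`, `n`,
#'   `response_rate`).
#' @param targets Demographic targets data frame (`year`, `sex`, `age_lo`,
#'   `age_hi`, `count`; `sex = "all"` rows are totals).
#' @param config A [fit_config()].
#' @param part Which cost to compute: `"epidemiology"`, `"demography"`, or
#'   `"joint"`. Defaults to the config's stage (`"two_stage"` maps to
#'   `"joint"` for reporting).
#' @param free Optional character vector of free-parameter names for the
#'   ridge penalty (default: all parameters of the relevant stage).
#' @return Non-negative scalar; `config$penalty` if the simulation fails.
#' @export
cost_function <- function(params, surveys = NULL, targets = NULL,
                          config = fit_config(), part = NULL, free = NULL) {
  if (is.null(part)) {
    part <- switch(config$stage, two_stage = "joint", config$stage)
  }
  part <- match.arg(part, c("epidemiology", "demography", "joint"))
  recs <- if (part != "demography") .survey_records(surveys) else NULL
  years <- c(if (!is.null(recs)) recs$year,
             if (part != "epidemiology" && !is.null(targets)) targets$year)
  if (!length(years)) stop("no data to fit", call. = FALSE)
  traj <- tryCatch(
    .cost_trajectory(params, years, config),
    error = function(e) NULL
  )
  if (is.null(traj)) return(config$penalty)

  cost <- 0
  if (part != "demography") {
    w <- recs$response_rate
    w <- w / mean(w)
    m <- vapply(seq_len(nrow(recs)), function(i) {
      model_prevalence(traj, recs$outcome[i], recs$sex[i], recs$age_lo[i],
                       recs$age_hi[i], recs$year[i])
    }, numeric(1))
    cost <- cost + sum(w * (m - recs$prevalence)^2)
  }
  if (part != "epidemiology") {
    stopifnot(!is.null(targets))
    md <- vapply(seq_len(nrow(targets)), function(i) {
      .model_count(traj, targets$year[i], targets$sex[i], targets$age_lo[i],
                   targets$age_hi[i])
    }, numeric(1))
    demo_cost <- sum(((md - targets$count) / targets$count)^2)
    cost <- cost + (if (part == "joint") config$demo_weight else 1) * demo_cost
  }
  if (config$lambda > 0) {
    pt <- param_table(params)
    stage_blocks <- if (part == "demography") "demography" else
      if (part == "epidemiology") setdiff(unique(pt$block), "demography") else
        unique(pt$block)
    if (is.null(free)) free <- pt$name[pt$block %in% stage_blocks]
    pt <- pt[pt$name %in% free, , drop = FALSE]
    ref <- if (is.numeric(config$theta_ref)) {
      config$theta_ref[pt$name]
    } else {
      (pt$lower + pt$upper) / 2
    }
    cost <- cost + config$lambda * sum(((pt$value - ref) /
                                          (pt$upper - pt$lower))^2)
  }
  cost
}

# Precompute, for each survey record, the state-vector indices and band
# weights so prevalence reduces to two indexed dot products per record.
.survey_plan <- function(space, recs, out_years) {
  lapply(seq_len(nrow(recs)), function(i) {
    w <- .band_weights(space, recs$age_lo[i], recs$age_hi[i])
    bands <- which(w > 0)
    sxs <- if (recs$sex[i] == "both") .sexes else recs$sex[i]
    grid_all <- expand.grid(status = c("nonDM", "DM"), profile = 1:8,
                            band = bands, sex = sxs,
                            KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    didx <- state_index(space, grid_all$sex, grid_all$band, grid_all$profile,
                        grid_all$status)
    dw <- w[grid_all$band]
    if (recs$outcome[i] == "t2dm") {
      keep <- grid_all$status == "DM"
    } else {
      keep <- grid_all$profile %in% .profiles_with(recs$outcome[i])
    }
    list(row = match(recs$year[i], out_years),
         nidx = didx[keep], nw = dw[keep], didx = didx, dw = dw,
         obs = recs$prevalence[i])
  })
}

.demo_plan <- function(space, targets, out_years) {
  lapply(seq_len(nrow(targets)), function(i) {
    w <- .band_weights(space, targets$age_lo[i], targets$age_hi[i])
    bands <- which(w > 0)
    sxs <- if (targets$sex[i] == "all") .sexes else targets$sex[i]
    grid_all <- expand.grid(status = c("nonDM", "DM"), profile = 1:8,
                            band = bands, sex = sxs,
                            KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    list(row = match(targets$year[i], out_years),
         idx = state_index(space, grid_all$sex, grid_all$band,
                           grid_all$profile, grid_all$status),
         w = w[grid_all$band], obs = targets$count[i])
  })
}

# fast weighted-least-squares evaluator sharing cost_function's definition
.make_cost_evaluator <- function(params, surveys, targets, config, part) {
  space <- build_state_space(params$n_age_bands)
  recs <- if (part != "demography") .survey_records(surveys) else NULL
  years <- c(if (!is.null(recs)) recs$year,
             if (part != "epidemiology" && !is.null(targets)) targets$year)
  out_years <- sort(unique(c(1950, years)))
  splan <- if (!is.null(recs)) .survey_plan(space, recs, out_years)
  sw <- if (!is.null(recs)) recs$response_rate / mean(recs$response_rate)
  dplan <- if (part != "epidemiology" && !is.null(targets)) {
    .demo_plan(space, targets, out_years)
  }
  function(p) {
    traj <- tryCatch(
      simulate_model(p, t0 = 1950, t1 = max(out_years),
                     output_years = out_years, rtol = config$rtol,
                     atol = config$atol),
      error = function(e) NULL
    )
    if (is.null(traj)) return(config$penalty)
    st <- traj$state
    cost <- 0
    if (!is.null(splan)) {
      m <- vapply(splan, function(pl) {
        sum(st[pl$row, pl$nidx] * pl$nw) / sum(st[pl$row, pl$didx] * pl$dw)
      }, numeric(1))
      cost <- cost + sum(sw * (m - vapply(splan, `[[`, numeric(1),
                                          "obs"))^2)
    }
    if (!is.null(dplan)) {
      dres <- vapply(dplan, function(pl) {
        (sum(st[pl$row, pl$idx] * pl$w) - pl$obs) / pl$obs
      }, numeric(1))
      cost <- cost +
        (if (part == "joint") config$demo_weight else 1) * sum(dres^2)
    }
    cost
  }
}

# run one bounded simplex over the named parameter subset
.fit_block <- function(params, names_free, surveys, targets, config, part,
                       start) {
  pt <- param_table(params)
  pt <- pt[match(names_free, pt$name), , drop = FALSE]
  x0 <- switch(start,
               mid_bounds = (pt$lower + pt$upper) / 2,
               params = pmin(pt$upper, pmax(pt$lower, pt$value)))
  evaluator <- .make_cost_evaluator(params, surveys, targets, config, part)
  ridge_ref <- if (is.numeric(config$theta_ref)) {
    as.numeric(config$theta_ref[pt$name])
  } else if (identical(config$theta_ref, "initial")) {
    x0
  } else {
    (pt$lower + pt$upper) / 2
  }
  scale <- pt$upper - pt$lower
  obj <- function(x) {
    p2 <- set_params(params, setNames(x, names_free))
    val <- evaluator(p2)
    if (config$lambda > 0) {
      val <- val + config$lambda * sum(((x - ridge_ref) / scale)^2)
    }
    val
  }
  res <- nelder_mead_bounded(obj, x0, pt$lower, pt$upper, tol = config$tol,
                             max_iter = config$max_iter)
  res$params <- set_params(params, setNames(res$par, names_free))
  res
}

#' Fit the model to survey and demographic data
#'
#' Default two-stage fit: stage 1 frees the demographic parameters (birth
#' rate knots, mortality scales) against the demographic targets; stage 2
#' frees the epidemiological parameters (risk-factor onset/reversal knots,
#' baseline incidence knots, initial prevalences, obesity trend) against the
#' survey prevalence measures with demography fixed. Stage 2 sweeps the
#' nearly-separable parameter blocks (obesity, smoking, inactivity, T2DM)
#' cyclically, each with its own bounded simplex, for `config$cycles`
#' cycles.
#'
#' @param surveys Survey data frame or list of survey data frames.
#' @param targets Demographic targets data frame.
#' @param config A [fit_config()].
#' @param params Starting parameter scaffold (defines band count, knots and
#'   non-fitted constants); default [default_model_params()].
#' @return A `t2dm_fit` object: `params` (best fit), `par` (named vector),
#'   `cost` (final stage cost), `stage_costs`, `residuals` (per survey
#'   record), `evaluations`, `iterations`, `converged`, `x0`, `config`.
#' @export
fit_model <- function(surveys, targets, config = fit_config(),
                      params = default_model_params()) {
  pt_all <- param_table(params)
  stage_costs <- list()
  evals <- 0L
  iters <- 0L
  converged <- TRUE
  x0_record <- list()

  do_demo <- config$stage %in% c("two_stage", "demography", "joint")
  do_epi <- config$stage %in% c("two_stage", "epidemiology", "joint")
  part_epi <- if (config$stage == "joint") "joint" else "epidemiology"

  if (do_demo && config$stage != "joint") {
    if (is.null(targets) || !nrow(targets)) {
      stop("demographic stage requested but no targets supplied",
           call. = FALSE)
    }
    nm <- pt_all$name[pt_all$block == "demography"]
    res <- .fit_block(params, nm, surveys, targets, config, "demography",
                      config$x0)
    params <- res$params
    stage_costs$demography <- res$value
    evals <- evals + res$evaluations
    iters <- iters + res$iterations
    converged <- converged && res$converged
    x0_record$demography <- config$x0
  }

  last_cost <- NA_real_
  if (do_epi || config$stage == "joint") {
    recs <- .survey_records(surveys)
    blocks <- config$blocks
    for (blk in blocks) {
      out_needed <- switch(blk, dm = "t2dm", blk)
      if (!out_needed %in% recs$outcome) {
        stop(sprintf(
          "block '%s' is free but the surveys contain no '%s' measures",
          blk, out_needed), call. = FALSE)
      }
    }
    joint_nm <- if (config$stage == "joint") {
      pt_all$name[pt_all$block == "demography"]
    } else {
      character(0)
    }
    if (!length(blocks)) {
      last_cost <- cost_function(params, surveys, targets, config,
                                 part = part_epi)
    }
    for (cy in seq_len(config$cycles)) {
      for (blk in blocks) {
        # the two sexes are decoupled given demography, so each block is
        # swept one sex at a time (low-dimensional simplexes converge best)
        for (sx in .sexes) {
          in_block <- pt_all$block == blk &
            grepl(paste0("_", sx, "(_|$)"), pt_all$name)
          nm <- c(pt_all$name[in_block],
                  if (cy == 1 && blk == blocks[1] && sx == .sexes[1])
                    joint_nm)
          start <- if (cy == 1) config$x0 else "params"
          res <- .fit_block(params, nm, surveys, targets, config, part_epi,
                            start)
          params <- res$params
          last_cost <- res$value
          evals <- evals + res$evaluations
          iters <- iters + res$iterations
          if (cy == config$cycles) converged <- converged && res$converged
          x0_record[[paste0(blk, "_", sx, "_cycle", cy)]] <- start
        }
      }
    }
    stage_costs[[part_epi]] <- last_cost
  }

  final_part <- if (do_epi || config$stage == "joint") part_epi else "demography"
  residuals <- NULL
  if (!is.null(surveys) && final_part != "demography") {
    recs <- .survey_records(surveys)
    traj <- .cost_trajectory(params, recs$year, config)
    recs$model <- vapply(seq_len(nrow(recs)), function(i) {
      model_prevalence(traj, recs$outcome[i], recs$sex[i], recs$age_lo[i],
                       recs$age_hi[i], recs$year[i])
    }, numeric(1))
    recs$residual <- recs$model - recs$prevalence
    recs$weight <- recs$response_rate / mean(recs$response_rate)
    residuals <- recs
  }

  structure(list(
    params = params,
    par = setNames(param_table(params)$value, param_table(params)$name),
    cost = if (!is.na(last_cost)) last_cost else stage_costs$demography,
    stage_costs = stage_costs,
    residuals = residuals,
    evaluations = evals,
    iterations = iters,
    converged = converged,
    x0 = x0_record,
    config = config
  ), class = "t2dm_fit")
}

#' @export
print.t2dm_fit <- function(x, ...) {
  cat(sprintf("<t2dm_fit> cost %.6g after %d evaluations (%s)\n",
              x$cost, x$evaluations,
              if (x$converged) "converged" else "iteration cap reached"))
  invisible(x)
}
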