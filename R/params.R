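#' @title Model parameters
#' @name model_params
#' @description
#' A `t2dm_params` object holds everything that drives the compartmental
#' system: demography (crude birth rate knots, background mortality scale,
#' sex ratio at birth, 1950 initial population), the seven fitted rate
#' families (baseline T2DM incidence and onset/reversal of each risk factor,
#' as log-rates on age knots interpolated log-linearly onto band midpoints),
#' relative risks, the obesity-onset time trend, and 1950 initial prevalences
#' on the logit scale.
NULL

# Baseline all-cause mortality hazard by age (per person-year): a declining
# early-childhood component plus a Gompertz adult component. A fitted per-sex
# log-scale multiplies this schedule.
.base_mortality <- function(age) {
  0.012 * exp(-age / 10) + 3.2e-05 * exp(0.087 * age)
}

#' Construct model parameters
#'
#' Returns a complete, valid parameter set. The defaults are the synthetic
#' ground-truth values used by [make_ground_truth()] (scenario `"default"`);
#' every component can be overridden via `...` (top-level fields only).
#'
#' @param n_age_bands Number of age bands (default 20, i.e. 5-year bands).
#' @param ... Named top-level fields replacing the defaults (e.g. `rr`,
#'   `cbr`, `init`).
#' @return A `t2dm_params` object.
#' @export
default_model_params <- function(n_age_bands = 20, ...) {
  p <- list(
    n_age_bands = as.integer(n_age_bands),
    band_width = 100 / n_age_bands,
    min_active_age = 20,
    sex_ratio_birth = 1.05,
    cbr = list(
      years = seq(1950, 2050, by = 10),
      values = c(0.047, 0.048, 0.048, 0.046, 0.040, 0.034,
                 0.029, 0.026, 0.023, 0.021, 0.019)
    ),
    mort = list(logscale = c(male = 0.05, female = -0.12)),
    # Relative risks: placeholder point estimates and 95% CIs in the range of
    # published meta-analyses; configurable, sampled by the uncertainty module.
    rr = list(
      t2dm = c(obesity = 3.5, smoking = 1.4, inactivity = 1.3),
      t2dm_ci = matrix(c(2.5, 5.0, 1.2, 1.65, 1.1, 1.55), nrow = 2,
                       dimnames = list(c("lo", "hi"),
                                       c("obesity", "smoking", "inactivity"))),
      mortality = 1.8,
      mortality_ci = c(lo = 1.5, hi = 2.3)
    ),
    rr_combine = "multiplicative",
    inc = list(
      knot_ages = c(20, 35, 50, 65, 80),
      log_rate = rbind(
        male = log(c(0.0018, 0.0060, 0.0125, 0.0170, 0.0170)),
        female = log(c(0.0009, 0.0032, 0.0085, 0.0130, 0.0130))
      )
    ),
    trans = list(
      knot_ages = c(20, 40, 60),
      on = list(
        obesity = rbind(male = log(c(0.030, 0.034, 0.025)),
                        female = log(c(0.052, 0.060, 0.044))),
        smoking = rbind(male = log(c(0.110, 0.022, 0.006)),
                        female = log(c(0.017, 0.006, 0.003))),
        inactivity = rbind(male = log(c(0.032, 0.030, 0.034)),
                           female = log(c(0.017, 0.016, 0.022)))
      ),
      off = list(
        obesity = rbind(male = log(c(0.045, 0.035, 0.035)),
                        female = log(c(0.030, 0.022, 0.022))),
        smoking = rbind(male = log(c(0.018, 0.020, 0.035)),
                        female = log(c(0.025, 0.025, 0.040))),
        inactivity = rbind(male = log(c(0.085, 0.080, 0.070)),
                           female = log(c(0.085, 0.080, 0.070)))
      )
    ),
    obesity_mult_2050 = c(male = 1.45, female = 1.55),
    init = list(
      total_pop = 450000,
      age_decay = 0.038,
      sex_frac_male = 0.515,
      logit_prev = rbind(
        male = qlogis(c(t2dm = 0.055, obesity = 0.14,
                        smoking = 0.40, inactivity = 0.18)),
        female = qlogis(c(t2dm = 0.045, obesity = 0.28,
                          smoking = 0.08, inactivity = 0.12))
      )
    )
  )
  dots <- list(...)
  if (length(dots)) {
    stopifnot(!is.null(names(dots)), all(names(dots) %in% names(p)))
    p <- modifyList(p, dots)
  }
  class(p) <- "t2dm_params"
  validate_params(p)
  p
}

#' Validate a parameter object
#'
#' @param params A `t2dm_params` object.
#' @return `params`, invisibly; signals an error describing the first
#'   violated invariant otherwise.
#' @export
validate_params <- function(params) {
  stopifnot(inherits(params, "t2dm_params"))
  with(params, {
    if (n_age_bands < 1) stop("n_age_bands must be >= 1", call. = FALSE)
    if (any(cbr$values < 0)) stop("birth rates must be >= 0", call. = FALSE)
    if (length(cbr$years) != length(cbr$values))
      stop("birth-rate knot years and values differ in length", call. = FALSE)
    if (sex_ratio_birth <= 0) stop("sex ratio at birth must be > 0", call. = FALSE)
    if (any(rr$t2dm <= 0) || rr$mortality <= 0)
      stop("relative risks must be > 0", call. = FALSE)
    if (!is.null(rr$t2dm_ci) &&
        any(rr$t2dm_ci["lo", ] > rr$t2dm | rr$t2dm_ci["hi", ] < rr$t2dm))
      stop("RR confidence bounds must bracket the point values", call. = FALSE)
    if (any(obesity_mult_2050 < 0))
      stop("obesity trend multipliers must be >= 0", call. = FALSE)
    if (init$total_pop < 0) stop("initial population must be >= 0", call. = FALSE)
  })
  invisible(params)
}

# log-linear interpolation of knot log-rates onto band midpoints;
# rates are zero below the minimum active age
.rates_on_bands <- function(knot_ages, log_rate_sex, mids, min_active_age) {
  v <- exp(approx(knot_ages, log_rate_sex, xout = mids, rule = 2)$y)
  v[mids < min_active_age] <- 0
  v
}

#' Per-band rate table (the seven fitted rate families)
#'
#' Evaluates the age-knot parameterization on the band grid.
#'
#' @param params A `t2dm_params` object.
#' @return A data frame with one row per sex x age band: band bounds,
#'   `baseline_t2dm_incidence`, and onset/reversal hazards
#'   `on_*` / `off_*` for obesity, smoking and inactivity (per person-year).
#' @export
rate_table <- function(params) {
  space <- build_state_space(params$n_age_bands)
  mids <- space$band_mid
  out <- expand.grid(band = seq_len(space$n_age_bands), sex = .sexes,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[, c("sex", "band")]
  out$age_lo <- space$band_lower[out$band]
  out$age_hi <- space$band_upper[out$band]
  for (col in c("baseline_t2dm_incidence", paste0("on_", .factors),
                paste0("off_", .factors))) {
    out[[col]] <- NA_real_
  }
  for (s in .sexes) {
    rows <- out$sex == s
    out$baseline_t2dm_incidence[rows] <- .rates_on_bands(
      params$inc$knot_ages, params$inc$log_rate[s, ], mids,
      params$min_active_age)
    for (f in .factors) {
      out[[paste0("on_", f)]][rows] <- .rates_on_bands(
        params$trans$knot_ages, params$trans$on[[f]][s, ], mids,
        params$min_active_age)
      out[[paste0("off_", f)]][rows] <- .rates_on_bands(
        params$trans$knot_ages, params$trans$off[[f]][s, ], mids,
        params$min_active_age)
    }
  }
  out
}

# flatten params into the list consumed by the C++ core;
# per-band vectors are sex-major (male bands 1..B, then female)
.c_parms <- function(params) {
  space <- build_state_space(params$n_age_bands)
  mids <- space$band_mid
  band_vec <- function(fun) c(fun("male"), fun("female"))
  parms <- list(
    B = space$n_age_bands,
    band_width = space$band_width,
    # aging between bands; `no_aging` is a cohort-diagnostic switch
    aging_rate = if (isTRUE(params$no_aging)) 0 else 1 / space$band_width,
    sex_ratio_birth = params$sex_ratio_birth,
    rr_mortality = params$rr$mortality,
    rr_t2dm = unname(params$rr$t2dm[.factors]),
    trend_m2050 = unname(params$obesity_mult_2050[.sexes]),
    cbr_years = as.numeric(params$cbr$years),
    cbr_values = as.numeric(params$cbr$values),
    mort = band_vec(function(s) {
      .base_mortality(mids) * exp(params$mort$logscale[[s]])
    }),
    inc = band_vec(function(s) {
      .rates_on_bands(params$inc$knot_ages, params$inc$log_rate[s, ], mids,
                      params$min_active_age)
    })
  )
  for (f in .factors) {
    parms[[paste0("on_", f)]] <- band_vec(function(s) {
      .rates_on_bands(params$trans$knot_ages, params$trans$on[[f]][s, ], mids,
                      params$min_active_age)
    })
    parms[[paste0("off_", f)]] <- band_vec(function(s) {
      .rates_on_bands(params$trans$knot_ages, params$trans$off[[f]][s, ], mids,
                      params$min_active_age)
    })
  }
  parms
}

#' T2DM incidence hazard for a compartment
#'
#' Baseline (healthy-profile) incidence for the sex/age band multiplied by
#' the relative risk of every factor present in the profile (multiplicative
#' combination).
#'
#' @param profile Risk profile code 1-8 (see [risk_profiles()]).
#' @param sex `"male"` or `"female"`.
#' @param age_band Age band index (1-based).
#' @param params A `t2dm_params` object.
#' @param t Calendar year (unused: incidence rates are time-constant; kept
#'   for interface symmetry with the time-varying hazards).
#' @return Hazard per person-year.
#' @export
t2dm_hazard <- function(profile, sex, age_band, params, t = NULL) {
  validate_params(params)
  space <- build_state_space(params$n_age_bands)
  stopifnot(profile %in% 1:8, sex %in% .sexes,
            age_band >= 1, age_band <= space$n_age_bands)
  base <- .rates_on_bands(params$inc$knot_ages, params$inc$log_rate[sex, ],
                          space$band_mid, params$min_active_age)[age_band]
  bits <- bitwAnd(profile - 1L, .factor_bit) > 0L
  base * prod(params$rr$t2dm[.factors][bits])
}

#' Initial state vector (1950)
#'
#' Builds the model state at initialization: the 1950 population by sex and
#' band (exponentially decaying age pyramid), with risk factors distributed
#' independently at the per-sex initial prevalences within bands at or above
#' the minimum active age, and T2DM at its initial prevalence within every
#' profile. Cumulative-flow counters start at zero.
#'
#' @param params A `t2dm_params` object.
#' @param space Optional pre-built state space.
#' @return Numeric state vector of length `32 B + 4 + 2 B`.
#' @export
initial_state <- function(params, space = build_state_space(params$n_age_bands)) {
  B <- space$n_age_bands
  y <- numeric(32L * B + 4L + 2L * B)
  wts <- exp(-params$init$age_decay * space$band_mid)
  wts <- wts / sum(wts)
  for (s in .sexes) {
    frac <- if (s == "male") params$init$sex_frac_male else 1 - params$init$sex_frac_male
    pops <- params$init$total_pop * frac * wts
    pv <- plogis(params$init$logit_prev[s, ])
    for (b in seq_len(B)) {
      active <- space$band_mid[b] >= params$min_active_age
      for (p in 1:8) {
        bits <- bitwAnd(p - 1L, .factor_bit) > 0L
        share <- if (active) {
          prod(ifelse(bits, pv[.factors], 1 - pv[.factors]))
        } else {
          if (p == 1L) 1 else 0
        }
        pdm <- if (active) pv[["t2dm"]] else 0
        y[state_index(space, s, b, p, "nonDM")] <- pops[b] * share * (1 - pdm)
        y[state_index(space, s, b, p, "DM")] <- pops[b] * share * pdm
      }
    }
  }
  y
}
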