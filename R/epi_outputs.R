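#' Model prevalence over an age range
#'
#' Aggregates compartment occupancies over the requested sex and age range
#' and returns the fraction carrying the outcome attribute. Whole bands are
#' aggregated; edge bands only partially covered by `[age_lo, age_hi)` enter
#' pro rata by overlap width.
#'
#' @param traj A `t2dm_trajectory`.
#' @param outcome One of `"t2dm"`, `"obesity"`, `"smoking"`, `"inactivity"`.
#' @param sex `"male"`, `"female"` or `"both"`.
#' @param age_lo,age_hi Age range `[age_lo, age_hi)` in years.
#' @param year An output year of the trajectory.
#' @return Prevalence in `[0, 1]`.
#' @export
model_prevalence <- function(traj, outcome, sex, age_lo, age_hi, year) {
  outcome <- match.arg(outcome, c("t2dm", .factors))
  stopifnot(age_lo < age_hi)
  occ <- occupancy(traj, year)
  w <- .band_weights(traj$space, age_lo, age_hi)
  if (all(w == 0)) stop("age range does not overlap the band grid", call. = FALSE)
  s <- if (sex == "both") .sexes else match.arg(sex, .sexes)
  sub <- occ[, , , s, drop = FALSE]
  den <- sum(apply(sub, 3, sum) * w)
  if (den <= 0) stop("undefined prevalence: empty denominator", call. = FALSE)
  if (outcome == "t2dm") {
    hit <- sub["DM", , , , drop = FALSE]
    num <- sum(apply(hit, 3, sum) * w)
  } else {
    prof <- .profiles_with(outcome)
    hit <- sub[, prof, , , drop = FALSE]
    num <- sum(apply(hit, 3, sum) * w)
  }
  num / den
}

# fraction of each band covered by [age_lo, age_hi)
.band_weights <- function(space, age_lo, age_hi) {
  overlap <- pmin(space$band_upper, age_hi) - pmax(space$band_lower, age_lo)
  pmax(overlap, 0) / space$band_width
}

#' Headline epidemiological report
#'
#' For each requested year and sex (and both sexes combined) reports, over
#' the age range (default ages 20-79): T2DM prevalence, persons living with
#' T2DM, annual new T2DM cases (the incidence flow integrated over
#' `[Y, Y+1)`), the incidence rate per 1,000 person-years at risk
#' (person-years of the non-DM population, trapezoidal between the year
#' bounds), and the prevalence of each risk factor.
#'
#' New cases and the incidence rate require the snapshot at `Y + 1`; for
#' years where it is not in the trajectory they are `NA`.
#'
#' @param traj A `t2dm_trajectory`.
#' @param years Years to report (must be output years of `traj`).
#' @param age_range Two-element numeric, default `c(20, 80)` (i.e. 20-79).
#' @return A data frame, one row per year x sex, with percentages on the
#'   0-100 scale.
#' @export
epi_report <- function(traj, years, age_range = c(20, 80)) {
  w <- .band_weights(traj$space, age_range[1], age_range[2])
  rows <- list()
  for (yr in years) {
    occ <- occupancy(traj, yr)
    has_next <- (yr + 1) %in% traj$years
    for (sx in c(.sexes, "both")) {
      s <- if (sx == "both") .sexes else sx
      sub <- occ[, , , s, drop = FALSE]
      tot <- sum(apply(sub, 3, sum) * w)
      if (tot <= 0) stop("undefined report: empty population in age range",
                         call. = FALSE)
      dm <- sum(apply(sub["DM", , , , drop = FALSE], 3, sum) * w)
      atrisk <- tot - dm
      newc <- rate <- NA_real_
      if (has_next) {
        f0 <- cumulative_flows(traj, yr)$new_cases
        f1 <- cumulative_flows(traj, yr + 1)$new_cases
        newc <- sum((colSums(f1[s, , drop = FALSE]) -
                       colSums(f0[s, , drop = FALSE])) * w)
        occ1 <- occupancy(traj, yr + 1)
        sub1 <- occ1[, , , s, drop = FALSE]
        atrisk1 <- sum(apply(sub1, 3, sum) * w) -
          sum(apply(sub1["DM", , , , drop = FALSE], 3, sum) * w)
        py <- (atrisk + atrisk1) / 2
        if (py <= 0) {
          warning("no at-risk person-years: incidence rate undefined",
                  call. = FALSE)
        } else {
          rate <- newc / py * 1000
        }
      }
      rf <- vapply(.factors, function(f) {
        prof <- .profiles_with(f)
        100 * sum(apply(sub[, prof, , , drop = FALSE], 3, sum) * w) / tot
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        year = yr, sex = sx,
        prevalence_pct = 100 * dm / tot,
        n_t2dm = dm,
        new_cases = newc,
        incidence_rate_per_1000 = rate,
        obesity_pct = rf[["obesity"]],
        smoking_pct = rf[["smoking"]],
        inactivity_pct = rf[["inactivity"]]
      )
    }
  }
  do.call(rbind, rows)
}

# instantaneous T2DM incidence flows per stratum at a year, with optional
# relative-risk overrides; returns data.frame(sex, band, profile, weight,
# at_risk, hazard, cases)
.incidence_strata <- function(traj, year, sex, age_range, rr = NULL) {
  params <- traj$params
  if (is.null(rr)) rr <- params$rr$t2dm[.factors]
  space <- traj$space
  occ <- occupancy(traj, year)
  w <- .band_weights(space, age_range[1], age_range[2])
  sxs <- if (identical(sex, "both")) .sexes else sex
  mids <- space$band_mid
  out <- list()
  for (sx in sxs) {
    inc <- .rates_on_bands(params$inc$knot_ages, params$inc$log_rate[sx, ],
                           mids, params$min_active_age)
    for (b in which(w > 0)) {
      for (p in 1:8) {
        bits <- bitwAnd(p - 1L, .factor_bit) > 0L
        lam <- inc[b] * prod(rr[bits])
        n <- occ["nonDM", p, b, sx]
        out[[length(out) + 1L]] <- data.frame(
          sex = sx, band = b, profile = p, weight = w[b],
          at_risk = n, hazard = lam, cases = w[b] * n * lam
        )
      }
    }
  }
  do.call(rbind, out)
}

#' Population attributable fractions with overlap apportionment
#'
#' Decomposes the year's instantaneous T2DM incidence flow into fractions
#' attributable to each risk factor, conserving the excess within every
#' overlap stratum. For a stratum with factor set F, excess cases are
#' `N * lambda0 * (RR_F - 1)`; the excess is apportioned to each factor
#' `X` in F with weight `(rr_X - 1) / sum_{Y in F} (rr_Y - 1)`
#' (`method = "proportional"`, the default) or by averaging sequential
#' removal over all orderings of F (`method = "sequential"`). Both schemes
#' conserve stratum excess exactly and reduce to Levin's formula when a
#' single factor is present.
#'
#' @param traj A `t2dm_trajectory`.
#' @param year An output year.
#' @param factors Factors to report (default all three).
#' @param sex `"male"`, `"female"` or `"both"`.
#' @param age_range Default ages 20-79.
#' @param method Overlap apportionment scheme.
#' @return Data frame `factor`, `paf` (fraction of the year's new cases).
#' @export
paf_decomposition <- function(traj, year, factors = .factors, sex = "both",
                              age_range = c(20, 80),
                              method = c("proportional", "sequential")) {
  method <- match.arg(method)
  stopifnot(all(factors %in% .factors))
  rr <- traj$params$rr$t2dm[.factors]
  st <- .incidence_strata(traj, year, sex, age_range)
  total <- sum(st$cases)
  if (total <= 0) stop("no incident cases: PAF undefined", call. = FALSE)
  attributed <- setNames(numeric(3), .factors)
  for (i in seq_len(nrow(st))) {
    p <- st$profile[i]
    bits <- .factors[bitwAnd(p - 1L, .factor_bit) > 0L]
    if (!length(bits)) next
    base <- st$weight[i] * st$at_risk[i] *
      st$hazard[i] / prod(rr[bits])  # N * lambda0 * w
    if (base <= 0) next
    rrF <- prod(rr[bits])
    excess <- base * (rrF - 1)
    if (method == "proportional") {
      wts <- rr[bits] - 1
      if (sum(wts) == 0) next
      attributed[bits] <- attributed[bits] + excess * wts / sum(wts)
    } else {
      perms <- .permutations(bits)
      contrib <- setNames(numeric(length(bits)), bits)
      for (ord in perms) {
        active <- bits
        for (x in ord) {
          before <- base * prod(rr[active])
          active <- setdiff(active, x)
          after <- base * prod(rr[active])
          contrib[x] <- contrib[x] + (before - after) / length(perms)
        }
      }
      attributed[bits] <- attributed[bits] + contrib[bits]
    }
  }
  data.frame(factor = factors, paf = unname(attributed[factors] / total),
             row.names = NULL)
}

.permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in .permutations(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

#' Counterfactual PAF oracle
#'
#' Recomputes the year's instantaneous incidence flow with the relative
#' risk(s) of `factor` set to 1 while holding compartment occupancies fixed,
#' and returns the fraction of observed new cases removed:
#' `(observed - counterfactual) / observed`. With `factor = "all"` every
#' factor's RR is set to 1 at once, which by construction equals the sum of
#' the apportioned fractions of [paf_decomposition()].
#'
#' @inheritParams paf_decomposition
#' @param factor A single factor name, or `"all"`.
#' @return A fraction.
#' @export
paf_counterfactual_oracle <- function(traj, year, factor, sex = "both",
                                      age_range = c(20, 80)) {
  rr <- traj$params$rr$t2dm[.factors]
  rr_cf <- rr
  if (identical(factor, "all")) rr_cf[] <- 1
  else rr_cf[match.arg(factor, .factors)] <- 1
  obs <- sum(.incidence_strata(traj, year, sex, age_range)$cases)
  if (obs <= 0) stop("no observed cases: PAF undefined", call. = FALSE)
  cf <- sum(.incidence_strata(traj, year, sex, age_range, rr = rr_cf)$cases)
  (obs - cf) / obs
}
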