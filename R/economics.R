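#' Share of health expenditure attributable to T2DM
#'
#' Cost-ratio attribution: if people with T2DM spend `r` times as much on
#' health care per capita as people without, and a fraction `f` of the
#' population has T2DM, the T2DM-attributable share of national health
#' expenditure is `(r - 1) f / (1 + (r - 1) f)`.
#'
#' @param f All-age T2DM fraction of the population, in `[0, 1)`.
#' @param r Expenditure ratio (>= 1), conventionally 2-3.
#' @return Fraction in `[0, 1)`. Vectorised.
#' @export
#' @examples
#' attributable_share(0.5, 2) # 1/3
attributable_share <- function(f, r) {
  stopifnot(all(f >= 0), all(f < 1), all(r >= 1))
  (r - 1) * f / (1 + (r - 1) * f)
}

#' Attributable spending per T2DM case
#'
#' Solves per-capita expenditure `pc * N = e * (N_nonDM + r * N_DM)` for the
#' non-DM per-person spend `e`; the attributable spend per case is
#' `(r - 1) e = (r - 1) pc / (1 + (r - 1) f)`.
#'
#' @param pc Per-capita annual health expenditure (USD/person/year).
#' @param f All-age T2DM fraction.
#' @param r Expenditure ratio.
#' @return USD per case per year. Vectorised.
#' @export
per_case_spend <- function(pc, f, r) {
  stopifnot(all(pc >= 0), all(f >= 0), all(f < 1), all(r >= 1))
  (r - 1) * pc / (1 + (r - 1) * f)
}

#' Extend a per-capita expenditure series to a projection horizon
#'
#' `mode = "fixed_post_2015"` holds every year after the last historical
#' year at the last historical value; `mode = "extrapolated_trend"` extends
#' an ordinary least-squares linear trend fitted to the historical years,
#' floored at zero. Historical years pass through unchanged; gaps within the
#' historical span are linearly interpolated. Report years before the first
#' historical year (the source series starts in 1995 but reports run from
#' 1990) are back-filled on the same OLS trend in both modes.
#'
#' @param series Data frame with columns `year` and `per_capita_usd`.
#' @param mode `"fixed_post_2015"` or `"extrapolated_trend"`.
#' @param horizon Last projection year (default 2050).
#' @param start First report year (default 1990).
#' @return Data frame `year`, `per_capita_usd` covering `start` through
#'   `horizon`, contiguous years.
#' @export
expenditure_scenario <- function(series,
                                 mode = c("fixed_post_2015",
                                          "extrapolated_trend"),
                                 horizon = 2050, start = 1990) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(series),
            all(c("year", "per_capita_usd") %in% names(series)))
  series <- series[order(series$year), ]
  if (nrow(series) < 2) {
    stop("the scenario needs at least two historical years", call. = FALSE)
  }
  trend <- lm(per_capita_usd ~ year, data = series)
  first_year <- min(series$year)
  last_year <- max(series$year)
  years <- seq(min(start, first_year), horizon)
  vals <- numeric(length(years))
  early <- years < first_year
  vals[early] <- pmax(0, predict(trend,
                                 newdata = data.frame(year = years[early])))
  hist <- years >= first_year & years <= last_year
  vals[hist] <- approx(series$year, series$per_capita_usd,
                       xout = years[hist])$y
  future <- years > last_year
  if (any(future)) {
    vals[future] <- if (mode == "fixed_post_2015") {
      series$per_capita_usd[nrow(series)]
    } else {
      pmax(0, predict(trend, newdata = data.frame(year = years[future])))
    }
  }
  data.frame(year = years, per_capita_usd = vals)
}

#' T2DM-attributable health expenditure report
#'
#' For every requested year and scenario, computes the all-age T2DM fraction
#' `f` from the trajectory (DM cases / total population), the per-case
#' attributable spend, the total attributable spend (per-case x case count,
#' exact), and the attributable share of national health expenditure. No
#' discounting is applied.
#'
#' @param traj A `t2dm_trajectory`.
#' @param scenarios A list of scenarios, each a list with `r_as` (2 or 3)
#'   and `mode` (see [expenditure_scenario()]).
#' @param series Historical per-capita expenditure data frame
#'   (`year`, `per_capita_usd`).
#' @param years Years to report (default all trajectory years covered by the
#'   extended series).
#' @return Data frame `year`, `r_as`, `mode`, `per_capita_usd`,
#'   `per_case_usd`, `total_usd`, `share_pct`.
#' @export
cost_report <- function(traj, scenarios, series, years = NULL) {
  stopifnot(length(scenarios) >= 1)
  rows <- list()
  for (sc in scenarios) {
    stopifnot(is.numeric(sc$r_as), sc$r_as >= 1)  # r = 1 as a diagnostic
    ext <- expenditure_scenario(series, sc$mode)
    yrs <- if (is.null(years)) intersect(traj$years, ext$year) else years
    for (yr in yrs) {
      pop <- total_population(traj, yr)
      if (pop <= 0) stop("zero population: cost report undefined", call. = FALSE)
      occ <- occupancy(traj, yr)
      cases <- sum(occ["DM", , , ])
      f <- cases / pop
      pc <- ext$per_capita_usd[match(yr, ext$year)]
      pcs <- per_case_spend(pc, f, sc$r_as)
      rows[[length(rows) + 1L]] <- data.frame(
        year = yr, r_as = sc$r_as, mode = sc$mode,
        per_capita_usd = pc,
        per_case_usd = pcs,
        total_usd = pcs * cases,
        share_pct = 100 * attributable_share(f, sc$r_as)
      )
    }
  }
  do.call(rbind, rows)
}
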