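#' Emulated survey designs
#'
#' Six cross-sectional survey designs emulating the national and community
#' surveys the model is meant to be calibrated to (years 1994-2017, with
#' sex-specific sample sizes and response rates; physical inactivity is only
#' measured by the 2017 survey). Outcomes are reported in 10-year age groups
#' from the design's adult lower age up to 80, plus one whole-range summary
#' row per outcome and sex.
#'
#' @return Data frame, one row per design: `year`, `label`, `age_min`,
#'   `n_male`, `n_female`, `response_male`, `response_female`,
#'   `has_inactivity`.
#' @export
survey_designs <- function() {
  data.frame(
    year = c(1994, 2004, 2004, 2007, 2009, 2017),
    label = c("national_1994", "community_2004", "steps_2004", "steps_2007",
              "national_2009", "national_2017"),
    age_min = c(25, 25, 20, 20, 20, 20),
    n_male = c(1046, 394, 1342, 1939, 776, 1099),
    n_female = c(1790, 727, 1992, 1715, 2458, 2495),
    response_male = c(0.54, 0.94, 0.85, 0.86, 0.36, 0.40),
    response_female = c(0.86, 0.94, 0.85, 0.86, 0.90, 0.94),
    has_inactivity = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)
  )
}

# 10-year reporting groups from `lo` to 80, each row c(age_lo, age_hi)
.age_groups <- function(lo) {
  breaks <- unique(c(seq(lo, 80, by = 10), 80))
  cbind(age_lo = breaks[-length(breaks)], age_hi = breaks[-1])
}

# design cells (one per outcome x sex x age group, plus summary rows)
.design_cells <- function(design) {
  outcomes <- c("t2dm", "obesity", "smoking",
                if (design$has_inactivity) "inactivity")
  groups <- rbind(.age_groups(design$age_min),
                  c(design$age_min, 80))  # whole-range summary row
  cells <- expand.grid(outcome = outcomes, sex = .sexes,
                       g = seq_len(nrow(groups)),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(
    year = design$year,
    outcome = cells$outcome,
    sex = cells$sex,
    age_lo = groups[cells$g, "age_lo"],
    age_hi = groups[cells$g, "age_hi"],
    response_rate = ifelse(cells$sex == "male", design$response_male,
                           design$response_female)
  )
}

#' Synthetic ground truth
#'
#' Builds a complete parameter set, simulates its trajectory over 1950-2051,
#' and tabulates the exact model prevalences at every survey design cell.
#' Scenario `"default"` uses [default_model_params()] (adult T2DM prevalence
#' in the 10-25% range by the 2010s, obesity 25-50% and sex-differentiated,
#' smoking strongly sex-differentiated, inactivity 10-25%);
#' `"flat"` switches the obesity-onset trend off (multiplier 1);
#' `"high_obesity"` steepens it.
#'
#' @param seed Integer seed (retained for reproducibility bookkeeping; the
#'   ground-truth parameters themselves are deterministic per scenario).
#' @param scenario `"default"`, `"flat"` or `"high_obesity"`.
#' @param n_age_bands Age bands (default 20).
#' @return A `t2dm_truth` object: `params`, `trajectory` (1950-2051),
#'   `designs`, `cells` (design cells with exact `prevalence`), `seed`,
#'   `scenario`.
#' @export
make_ground_truth <- function(seed = 1, scenario = c("default", "flat",
                                                     "high_obesity"),
                              n_age_bands = 20) {
  scenario <- match.arg(scenario)
  params <- default_model_params(n_age_bands = n_age_bands)
  if (scenario == "flat") {
    params$obesity_mult_2050 <- c(male = 1, female = 1)
  } else if (scenario == "high_obesity") {
    params$obesity_mult_2050 <- c(male = 2.6, female = 3.0)
  }
  traj <- simulate_model(params, t0 = 1950, t1 = 2051)
  designs <- survey_designs()
  cells <- do.call(rbind, lapply(seq_len(nrow(designs)), function(i) {
    .design_cells(designs[i, ])
  }))
  cells$prevalence <- vapply(seq_len(nrow(cells)), function(i) {
    model_prevalence(traj, cells$outcome[i], cells$sex[i], cells$age_lo[i],
                     cells$age_hi[i], cells$year[i])
  }, numeric(1))
  structure(list(params = params, trajectory = traj, designs = designs,
                 cells = cells, seed = seed, scenario = scenario),
            class = "t2dm_truth")
}

#' Generate noisy survey datasets from a ground truth
#'
#' For each design cell, the sex's sample is allocated over age groups in
#' proportion to the model population, an observed count is drawn as
#' Binomial(n_cell, true prevalence), and the observed prevalence is
#' reported with the design's response rate attached as the fitting weight.
#' Optional response bias multiplies the true prevalence before sampling
#' (e.g. `bias = c(male = 1.15, female = 1)` to distort the poorly
#' responding sex).
#'
#' @param truth A `t2dm_truth`.
#' @param designs Survey designs (default: the truth's).
#' @param seed Integer seed; the draw is deterministic given it.
#' @param bias Optional named per-sex multiplier on true prevalence, or
#'   `NULL` for unbiased sampling.
#' @param noise If `FALSE`, report the exact model prevalences (noise-free
#'   fixture).
#' @return A list of survey data frames (one per design) with columns
#'   `year`, `outcome`, `sex`, `age_lo`, `age_hi`, `prevalence`, `n`,
#'   `response_rate`.
#' @export
generate_surveys <- function(truth, designs = truth$designs, seed = 1,
                             bias = NULL, noise = TRUE) {
  traj <- truth$trajectory
  if (any(!designs$year %in% traj$years)) {
    stop("survey design year outside the trajectory", call. = FALSE)
  }
  .with_seed(seed, function() {
    lapply(seq_len(nrow(designs)), function(i) {
      d <- designs[i, ]
      cells <- .design_cells(d)
      cells$prevalence <- vapply(seq_len(nrow(cells)), function(j) {
        model_prevalence(traj, cells$outcome[j], cells$sex[j],
                         cells$age_lo[j], cells$age_hi[j], cells$year[j])
      }, numeric(1))
      # allocate the sex sample over the 10-year groups by population share
      groups <- .age_groups(d$age_min)
      cells$n <- NA_real_
      for (sx in .sexes) {
        pop <- vapply(seq_len(nrow(groups)), function(g) {
          .model_count(traj, d$year, sx, groups[g, 1], groups[g, 2])
        }, numeric(1))
        share <- pop / sum(pop)
        n_sex <- if (sx == "male") d$n_male else d$n_female
        ng <- pmax(1, round(n_sex * share))
        for (g in seq_len(nrow(groups))) {
          sel <- cells$sex == sx & cells$age_lo == groups[g, 1] &
            cells$age_hi == groups[g, 2]
          cells$n[sel] <- ng[g]
        }
        cells$n[cells$sex == sx & cells$age_lo == d$age_min &
                  cells$age_hi == 80] <- n_sex
      }
      if (noise) {
        p_draw <- cells$prevalence
        if (!is.null(bias)) p_draw <- pmin(1, p_draw * bias[cells$sex])
        k <- rbinom(nrow(cells), size = cells$n, prob = p_draw)
        cells$prevalence <- k / cells$n
      }
      cells[, c("year", "outcome", "sex", "age_lo", "age_hi", "prevalence",
                "n", "response_rate")]
    })
  })
}

#' Generate demographic target series from a ground truth
#'
#' Reads yearly total population (and periodic age/sex-specific counts) off
#' the truth trajectory, optionally with multiplicative lognormal noise.
#'
#' @param truth A `t2dm_truth`.
#' @param years Years of total-population targets (default 1950-2020).
#' @param agespec_every Interval of age/sex-specific target snapshots in
#'   years (default 10; `NA` for totals only).
#' @param noise_sd Log-scale noise standard deviation (default 0 =
#'   noise-free).
#' @param seed Seed for the noise draw.
#' @return Data frame `year`, `sex`, `age_lo`, `age_hi`, `count`
#'   (`sex = "all"`, ages 0-100 rows are totals).
#' @export
generate_demography_targets <- function(truth, years = 1950:2020,
                                        agespec_every = 10, noise_sd = 0,
                                        seed = 1) {
  traj <- truth$trajectory
  space <- traj$space
  rows <- lapply(years, function(y) {
    data.frame(year = y, sex = "all", age_lo = 0, age_hi = 100,
               count = total_population(traj, y))
  })
  if (!is.na(agespec_every)) {
    snap_years <- years[(years - years[1]) %% agespec_every == 0]
    for (y in snap_years) {
      occ <- occupancy(traj, y)
      for (sx in .sexes) {
        cnt <- apply(occ[, , , sx, drop = FALSE], 3, sum)
        rows[[length(rows) + 1L]] <- data.frame(
          year = y, sex = sx, age_lo = space$band_lower,
          age_hi = space$band_upper, count = cnt)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (noise_sd > 0) {
    out$count <- .with_seed(seed, function() {
      out$count * rlnorm(nrow(out), 0, noise_sd)
    })
  }
  out
}

#' Generate a per-capita health expenditure series
#'
#' An increasing historical series (default 1995-2015) with mild
#' year-to-year irregularity, ending at exactly 257 USD in the final year.
#'
#' @param seed Integer seed.
#' @param years Historical years (default 1995:2015).
#' @param start_value,end_value Series endpoints (defaults 120 and 257 USD).
#' @return Data frame `year`, `per_capita_usd`.
#' @export
generate_expenditure_series <- function(seed = 1, years = 1995:2015,
                                        start_value = 120, end_value = 257) {
  n <- length(years)
  base <- seq(start_value, end_value, length.out = n)
  vals <- .with_seed(seed, function() {
    v <- base + c(0, rnorm(n - 2, 0, 3), 0)
    v <- cummax(v)  # keep the series increasing
    v[n] <- end_value
    v
  })
  data.frame(year = years, per_capita_usd = vals)
}

#' Materialize a desk-scale fixture dataset
#'
#' Writes the survey, demography and expenditure files a full pipeline run
#' reads, generated from a seeded ground truth.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param scenario Ground-truth scenario.
#' @param noise Draw binomial survey noise? (default `TRUE`).
#' @return Invisibly, a list of the written paths.
#' @export
write_fixtures <- function(dir, seed = 1, scenario = "default",
                           noise = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- make_ground_truth(seed, scenario)
  surveys <- generate_surveys(truth, seed = seed, noise = noise)
  targets <- generate_demography_targets(truth)
  spend <- generate_expenditure_series(seed)
  paths <- list(
    surveys = file.path(dir, "surveys.csv"),
    demography = file.path(dir, "demography.csv"),
    expenditure = file.path(dir, "expenditure.csv")
  )
  write_survey_data(do.call(rbind, surveys), paths$surveys)
  write_demography_data(targets, paths$demography)
  write_expenditure_data(spend, paths$expenditure)
  invisible(paths)
}
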