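# hand-built trajectory: occupancies placed explicitly, flows zero
manual_trajectory <- function(n_age_bands, fill, years = 2000,
                              params = NULL) {
  sp <- build_state_space(n_age_bands)
  n <- 32 * n_age_bands + 4 + 2 * n_age_bands
  st <- matrix(0, nrow = length(years), ncol = n)
  for (row in fill) {
    idx <- state_index(sp, row$sex, row$band, row$profile, row$status)
    st[, idx] <- row$persons
  }
  structure(list(years = years, state = st, space = sp, params = params),
            class = "t2dm_trajectory")
}

test_that("prevalence aggregates hand-computed band totals", {
  # single band: 30 DM of 200 persons
  tr <- manual_trajectory(2, list(
    list(sex = "male", band = 1, profile = 1, status = "nonDM",
         persons = 170),
    list(sex = "male", band = 1, profile = 1, status = "DM", persons = 30)
  ))
  expect_equal(model_prevalence(tr, "t2dm", "male", 0, 50, 2000), 0.15)

  # two bands (100 and 300 persons, 10 and 60 DM): 70/400
  tr2 <- manual_trajectory(2, list(
    list(sex = "female", band = 1, profile = 1, status = "nonDM",
         persons = 90),
    list(sex = "female", band = 1, profile = 1, status = "DM", persons = 10),
    list(sex = "female", band = 2, profile = 1, status = "nonDM",
         persons = 240),
    list(sex = "female", band = 2, profile = 1, status = "DM", persons = 60)
  ))
  expect_equal(model_prevalence(tr2, "t2dm", "female", 0, 100, 2000),
               70 / 400)
  # pro-rata edge band: [0, 75) takes band 2 at half weight
  expect_equal(model_prevalence(tr2, "t2dm", "female", 0, 75, 2000),
               (10 + 0.5 * 60) / (100 + 0.5 * 300))
  # an entirely DM population has prevalence one
  tr3 <- manual_trajectory(2, list(
    list(sex = "male", band = 1, profile = 1, status = "DM", persons = 50)
  ))
  expect_equal(model_prevalence(tr3, "t2dm", "male", 0, 50, 2000), 1)
  # empty denominator signals
  expect_error(model_prevalence(tr3, "t2dm", "female", 0, 50, 2000),
               "empty denominator")
})

test_that("risk-factor prevalence counts profiles carrying the factor", {
  # profile 2 = obese only; profile 6 (1+4+1) = obese + inactive
  tr <- manual_trajectory(2, list(
    list(sex = "male", band = 1, profile = 1, status = "nonDM",
         persons = 50),
    list(sex = "male", band = 1, profile = 2, status = "nonDM",
         persons = 30),
    list(sex = "male", band = 1, profile = 6, status = "DM", persons = 20)
  ))
  expect_equal(model_prevalence(tr, "obesity", "male", 0, 50, 2000), 0.5)
  expect_equal(model_prevalence(tr, "inactivity", "male", 0, 50, 2000), 0.2)
  expect_equal(model_prevalence(tr, "smoking", "male", 0, 50, 2000), 0)
})

test_that("stationary at-risk pool yields the defining incidence rate", {
  lam <- 0.005
  p <- closed_cohort_params(lam)
  tr <- simulate_model(p, t0 = 1950, t1 = 1960)
  rep1 <- epi_report(tr, 1950, age_range = c(0, 100))
  both <- rep1[rep1$sex == "both", ]
  expect_equal(both$incidence_rate_per_1000, 5.0, tolerance = 1e-4)
  # new-case tally equals the cumulative-counter difference
  f0 <- sum(cumulative_flows(tr, 1950)$new_cases)
  f1 <- sum(cumulative_flows(tr, 1951)$new_cases)
  expect_equal(both$new_cases, f1 - f0, tolerance = 1e-12)
  # and matches the closed-form expectation
  N <- total_population(tr, 1950)
  expect_equal(both$new_cases, N * (1 - exp(-lam)), tolerance = 1e-6)
})

test_that("an all-DM population reports 100% prevalence and no rate", {
  fill <- list(
    list(sex = "male", band = 5, profile = 1, status = "DM", persons = 100),
    list(sex = "female", band = 5, profile = 1, status = "DM", persons = 100)
  )
  tr <- manual_trajectory(20, fill, years = c(2000, 2001))
  warns <- capture_warnings(rep1 <- epi_report(tr, 2000))
  expect_match(warns, "at-risk", all = TRUE)
  expect_equal(rep1$prevalence_pct[rep1$sex == "both"], 100)
  expect_true(is.na(rep1$incidence_rate_per_1000[rep1$sex == "both"]))
})

test_that("single-factor world reduces to Levin's formula", {
  p <- small_params()
  p$inc$log_rate[] <- log(0.01)          # uniform baseline hazard
  p$rr$t2dm <- c(obesity = 3, smoking = 1, inactivity = 1)
  p$rr$t2dm_ci <- NULL
  for (f in c("smoking", "inactivity")) {
    p$trans$on[[f]][] <- -690
    p$init$logit_prev[, f] <- -690
  }
  tr <- simulate_model(p, t1 = 2000)
  # exposure prevalence among the at-risk (non-DM) 20-79 population
  occ <- occupancy(tr, 2000)
  w <- t2dmdyn:::.band_weights(tr$space, 20, 80)
  nonDM <- occ["nonDM", , , ]
  atrisk <- sum(apply(nonDM, 2, sum) * w)
  exposed <- sum(apply(nonDM[t2dmdyn:::.profiles_with("obesity"), , ,
                             drop = FALSE], 2, sum) * w)
  pe <- exposed / atrisk
  levin <- pe * 2 / (1 + pe * 2)
  paf <- paf_decomposition(tr, 2000)
  expect_equal(paf$paf[paf$factor == "obesity"], levin, tolerance = 1e-10)
  expect_equal(paf$paf[paf$factor == "smoking"], 0)
  # the counterfactual oracle agrees exactly in the one-factor world
  expect_equal(paf_counterfactual_oracle(tr, 2000, "obesity"),
               paf$paf[paf$factor == "obesity"], tolerance = 1e-12)
})

test_that("a factor with RR 1 gets zero PAF regardless of prevalence", {
  truth <- get_truth()
  tr <- truth$trajectory
  tr$params$rr$t2dm[["smoking"]] <- 1
  paf <- paf_decomposition(tr, 2020)
  expect_equal(paf$paf[paf$factor == "smoking"], 0)
  expect_gt(model_prevalence(tr, "smoking", "both", 20, 80, 2020), 0.1)
})

test_that("non-overlapping exposed groups give stratum-arithmetic PAFs", {
  p <- default_model_params()
  p$inc$log_rate[] <- log(0.01)
  p$rr$t2dm <- c(obesity = 3, smoking = 2, inactivity = 1.5)
  p$rr$t2dm_ci <- NULL
  # occupancy only in healthy (1), obese-only (2), smoker-only (3) profiles
  tr <- manual_trajectory(20, list(
    list(sex = "male", band = 9, profile = 1, status = "nonDM",
         persons = 600),
    list(sex = "male", band = 9, profile = 2, status = "nonDM",
         persons = 300),
    list(sex = "male", band = 9, profile = 3, status = "nonDM",
         persons = 100)
  ), params = p)
  # hand arithmetic: flows 600*l, 300*3l, 100*2l; excesses 600l and 100l
  total <- 600 + 300 * 3 + 100 * 2
  paf <- paf_decomposition(tr, 2000)
  expect_equal(paf$paf[paf$factor == "obesity"], 300 * 2 / total,
               tolerance = 1e-12)
  expect_equal(paf$paf[paf$factor == "smoking"], 100 * 1 / total,
               tolerance = 1e-12)
  expect_equal(paf$paf[paf$factor == "inactivity"], 0)
})

test_that("apportionment conserves the all-factor counterfactual excess", {
  tr <- get_truth()$trajectory
  for (method in c("proportional", "sequential")) {
    paf <- paf_decomposition(tr, 2020, method = method)
    expect_equal(sum(paf$paf), paf_counterfactual_oracle(tr, 2020, "all"),
                 tolerance = 1e-10)
  }
  # per-sex decomposition also conserves
  paf_m <- paf_decomposition(tr, 2020, sex = "male")
  expect_equal(sum(paf_m$paf),
               paf_counterfactual_oracle(tr, 2020, "all", sex = "male"),
               tolerance = 1e-10)
})

test_that("decomposition equals the oracle in one-factor-at-a-time configs", {
  tr <- get_truth()$trajectory
  for (f in c("obesity", "smoking", "inactivity")) {
    t1 <- tr
    t1$params$rr$t2dm[] <- 1
    t1$params$rr$t2dm[[f]] <- tr$params$rr$t2dm[[f]]
    paf <- paf_decomposition(t1, 2020)
    expect_equal(paf$paf[paf$factor == f],
                 paf_counterfactual_oracle(t1, 2020, f), tolerance = 1e-12)
  }
})

test_that("PAF is monotone in the factor's relative risk", {
  tr <- get_truth()$trajectory
  vals <- vapply(c(1.5, 2.5, 3.5, 4.5), function(r) {
    t1 <- tr
    t1$params$rr$t2dm[["obesity"]] <- r
    paf <- paf_decomposition(t1, 2020)
    paf$paf[paf$factor == "obesity"]
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("constant rates + stationary demography freeze factor prevalence", {
  # flat obesity trend AND a constant birth rate: once the initial
  # condition and the demographic transient wash out, age-group prevalence
  # of every factor is constant in calendar time
  p <- default_model_params()
  p$obesity_mult_2050[] <- 1
  p$cbr$values[] <- 0.04
  tr <- simulate_model(p, t1 = 2050)
  for (f in c("obesity", "smoking", "inactivity")) {
    v1 <- model_prevalence(tr, f, "both", 40, 50, 2020)
    v2 <- model_prevalence(tr, f, "both", 40, 50, 2045)
    expect_lt(abs(v2 - v1), 0.002)
  }
  # the default scenario's rising obesity-onset trend moves the same group
  tr_d <- get_truth()$trajectory
  d1 <- model_prevalence(tr_d, "obesity", "both", 40, 50, 2020)
  d2 <- model_prevalence(tr_d, "obesity", "both", 40, 50, 2045)
  expect_gt(d2 - d1, 0.01)
})
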