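make_records <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, as.data.frame))
}

test_that("cost is zero when the model reproduces every datum", {
  truth <- get_truth()
  cost <- cost_function(truth$params, get_noise_free_surveys(),
                        get_targets(), fit_config(), part = "epidemiology")
  expect_lt(cost, 1e-6)
  cost_d <- cost_function(truth$params, NULL, get_targets(), fit_config(),
                          part = "demography")
  expect_lt(cost_d, 1e-10)
})

test_that("weighted squared error follows the definition", {
  truth <- get_truth()
  # two records engineered so the weights stay unnormalized (mean 1):
  # one with residual 0.1 and weight 0.5, one exact with weight 1.5
  tr <- truth$trajectory
  p_true <- model_prevalence(tr, "t2dm", "male", 40, 50, 2004)
  recs <- make_records(
    list(year = 2004, outcome = "t2dm", sex = "male", age_lo = 40,
         age_hi = 50, prevalence = p_true - 0.1, n = 100,
         response_rate = 0.5),
    list(year = 2004, outcome = "t2dm", sex = "male", age_lo = 50,
         age_hi = 60, prevalence = model_prevalence(tr, "t2dm", "male",
                                                    50, 60, 2004),
         n = 100, response_rate = 1.5)
  )
  cost <- cost_function(truth$params, recs, NULL, fit_config(),
                        part = "epidemiology")
  expect_equal(cost, 0.5 * 0.1^2, tolerance = 1e-4)
})

test_that("cost is invariant under record reordering", {
  truth <- get_truth()
  recs <- do.call(rbind, get_noise_free_surveys())
  recs$prevalence <- pmin(1, recs$prevalence + 0.01)
  c1 <- cost_function(truth$params, recs, NULL, fit_config(),
                      part = "epidemiology")
  set.seed(42)
  c2 <- cost_function(truth$params, recs[sample(nrow(recs)), ], NULL,
                      fit_config(), part = "epidemiology")
  expect_equal(c1, c2, tolerance = 1e-12)
})

test_that("raising the weight of the only misfit record raises the cost", {
  truth <- get_truth()
  tr <- truth$trajectory
  base <- make_records(
    list(year = 2009, outcome = "obesity", sex = "female", age_lo = 30,
         age_hi = 40,
         prevalence = model_prevalence(tr, "obesity", "female", 30, 40,
                                       2009) + 0.05,
         n = 200, response_rate = 0.5),
    list(year = 2009, outcome = "obesity", sex = "female", age_lo = 40,
         age_hi = 50,
         prevalence = model_prevalence(tr, "obesity", "female", 40, 50,
                                       2009),
         n = 200, response_rate = 0.9)
  )
  costs <- vapply(c(0.3, 0.6, 0.9), function(w) {
    recs <- base
    recs$response_rate[1] <- w
    cost_function(truth$params, recs, NULL, fit_config(),
                  part = "epidemiology")
  }, numeric(1))
  expect_true(all(diff(costs) > 0))
})

test_that("ridge regularization adds a strictly positive penalty off-reference", {
  truth <- get_truth()
  sv <- get_noise_free_surveys()
  c0 <- cost_function(truth$params, sv, NULL,
                      fit_config(lambda = 0), part = "epidemiology")
  c1 <- cost_function(truth$params, sv, NULL,
                      fit_config(lambda = 0.1), part = "epidemiology")
  expect_gt(c1, c0)  # truth is off mid-bounds, so the penalty is positive
})

test_that("parameter table and set_params round-trip", {
  p <- default_model_params()
  pt <- param_table(p)
  expect_true(all(pt$lower < pt$upper))
  expect_true(all(pt$value >= pt$lower & pt$value <= pt$upper))
  # perturb every value, write back, read again
  x <- setNames(pt$value + 0.01, pt$name)
  p2 <- set_params(p, x)
  pt2 <- param_table(p2)
  expect_equal(setNames(pt2$value, pt2$name), x)
  expect_error(set_params(p, c(bogus_name = 1)), "unknown parameter")
})

test_that("a fully frozen fit returns the initial cost unchanged", {
  truth <- get_truth()
  sv <- get_noise_free_surveys()
  cfg <- fit_config(stage = "epidemiology", blocks = character(0))
  fit <- fit_model(sv, get_targets(), cfg, params = truth$params)
  ref <- cost_function(truth$params, sv, NULL, cfg, part = "epidemiology")
  expect_equal(fit$cost, ref, tolerance = 1e-12)
  expect_equal(fit$params$inc$log_rate, truth$params$inc$log_rate)
})

test_that("a freed block without matching survey outcomes is refused", {
  truth <- get_truth()
  sv <- do.call(rbind, get_noise_free_surveys())
  sv <- sv[sv$outcome != "inactivity", ]
  cfg <- fit_config(stage = "epidemiology")
  expect_error(fit_model(sv, NULL, cfg, params = truth$params),
               "no 'inactivity' measures")
})

test_that("demography stage without targets is refused", {
  expect_error(fit_model(get_noise_free_surveys(), NULL,
                         fit_config(stage = "demography")),
               "no targets")
})

test_that("demography stage recovers population series from noisy targets", {
  truth <- get_truth()
  noisy <- generate_demography_targets(truth, noise_sd = 0.01, seed = 3)
  cfg <- fit_config(stage = "demography", tol = 1e-6, max_iter = 800)
  fit <- fit_model(NULL, noisy, cfg, params = default_model_params())
  tr <- simulate_model(fit$params, t1 = 2020)
  for (y in seq(1950, 2020, 10)) {
    expect_lt(abs(total_population(tr, y) /
                    total_population(truth$trajectory, y) - 1), 0.03)
  }
  # refitting from the returned optimum does not increase the cost
  cfg2 <- cfg
  cfg2$x0 <- "params"
  fit2 <- fit_model(NULL, noisy, cfg2, params = fit$params)
  expect_lte(fit2$cost, fit$cost + cfg$tol)
})

test_that("joint cost is the weighted sum of its two stage costs", {
  truth <- get_truth()
  sv <- do.call(rbind, get_noisy_surveys())
  tg <- get_targets()
  cfg <- fit_config(stage = "joint", demo_weight = 0.25)
  c_epi <- cost_function(truth$params, sv, tg, cfg, part = "epidemiology")
  c_dem <- cost_function(truth$params, sv, tg, cfg, part = "demography")
  c_joint <- cost_function(truth$params, sv, tg, cfg, part = "joint")
  # the joint path integrates on the union output grid, so agreement is
  # limited by the cost-level integration tolerance, not exact
  expect_equal(c_joint, c_epi + 0.25 * c_dem, tolerance = 1e-4)
})

test_that("simulation failure maps to the finite penalty cost", {
  truth <- get_truth()
  bad <- truth$params
  bad$cbr$values[] <- 1e200   # blows up the integration
  sv <- get_noise_free_surveys()
  cost <- cost_function(bad, sv, NULL, fit_config(), part = "epidemiology")
  expect_identical(cost, 1e12)
})
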