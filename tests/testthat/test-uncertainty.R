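# cheap refit configuration for Monte Carlo machinery tests: the T2DM
# block only, one cycle, capped iterations (warm starts keep this honest)
mc_test_config <- function() {
  fit_config(stage = "epidemiology", blocks = "dm", cycles = 1,
             tol = 1e-5, max_iter = 60)
}

get_mc_base_fit <- function() {
  cached("mc_base_fit", function() {
    cfg <- mc_test_config()
    cfg$x0 <- "params"   # base fit: polish the truth parameters
    fit_model(get_noise_free_surveys(), get_targets(), cfg,
              params = get_truth()$params)
  })
}

test_that("lognormal CI matching follows the quantile formula", {
  d <- lognormal_from_ci(2, 1, 4)
  expect_equal(d$meanlog, log(2))
  expect_equal(d$sdlog, log(4) / (2 * qnorm(0.975)), tolerance = 1e-12)
  expect_equal(d$sdlog, 0.3537, tolerance = 1e-3)
  # degenerate interval
  d0 <- lognormal_from_ci(2, 2, 2)
  expect_identical(d0$sdlog, 0)
  expect_error(lognormal_from_ci(2, 3, 1), "lo <= point <= hi")
  # sampled quantiles reproduce the interval
  set.seed(1)
  x <- rlnorm(1e5, d$meanlog, d$sdlog)
  q <- quantile(x, c(0.025, 0.975))
  expect_equal(unname(q[1]), 1, tolerance = 0.02)
  expect_equal(unname(q[2]), 4, tolerance = 0.02)
})

test_that("a degenerate single-run analysis collapses onto the base fit", {
  base <- get_mc_base_fit()
  point <- c(2, 2, 2)
  spec <- uncertainty_spec(
    n_runs = 1, seed = 7,
    rr_ci = list(rr_obesity = rep(base$params$rr$t2dm[["obesity"]], 3),
                 rr_smoking = rep(base$params$rr$t2dm[["smoking"]], 3),
                 rr_inactivity = rep(base$params$rr$t2dm[["inactivity"]], 3),
                 rr_mortality = rep(base$params$rr$mortality, 3)),
    output_years = c(2020, 2050))
  res <- mc_parameter_uncertainty(spec, get_noise_free_surveys(),
                                  get_targets(), mc_test_config(), base)
  expect_identical(res$summary$lo, res$summary$hi)
  expect_equal(res$summary$lo, res$summary$point, tolerance = 3e-3)
  expect_identical(res$n_failed, 0L)
})

test_that("identical seeds reproduce the whole analysis", {
  base <- get_mc_base_fit()
  spec <- uncertainty_spec(n_runs = 3, seed = 11,
                           output_years = c(2030, 2050))
  r1 <- mc_parameter_uncertainty(spec, get_noise_free_surveys(),
                                 get_targets(), mc_test_config(), base)
  r2 <- mc_parameter_uncertainty(spec, get_noise_free_surveys(),
                                 get_targets(), mc_test_config(), base)
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$runs, r2$runs)
  # sampled inputs are bitwise identical
  expect_identical(r1$runs$rr_obesity, r2$runs$rr_obesity)
})

test_that("wider input CIs widen the uncertainty envelope (paired seeds)", {
  base <- get_mc_base_fit()
  rr <- base$params$rr$t2dm
  narrow <- list(rr_obesity = c(rr[["obesity"]], rr[["obesity"]] / 1.05,
                                rr[["obesity"]] * 1.05),
                 rr_smoking = rep(rr[["smoking"]], 3),
                 rr_inactivity = rep(rr[["inactivity"]], 3),
                 rr_mortality = rep(base$params$rr$mortality, 3))
  wide <- narrow
  wide$rr_obesity <- c(rr[["obesity"]], rr[["obesity"]] / 1.6,
                       rr[["obesity"]] * 1.6)
  run <- function(ci) {
    spec <- uncertainty_spec(n_runs = 8, seed = 21, rr_ci = ci,
                             output_years = c(2030, 2050))
    mc_parameter_uncertainty(spec, get_noise_free_surveys(), get_targets(),
                             mc_test_config(), base)
  }
  rn <- run(narrow)
  rw <- run(wide)
  expect_true(all(rn$summary$lo <= rn$summary$hi))
  expect_gt(mean(rw$summary$hi - rw$summary$lo),
            mean(rn$summary$hi - rn$summary$lo))
})

test_that("zero data perturbation reproduces the base cost in every run", {
  base <- get_mc_base_fit()
  spec <- uncertainty_spec(n_runs = 2, seed = 31, data_pm = 0,
                           output_years = 2050)
  res <- mc_data_uncertainty(spec, get_noise_free_surveys(), get_targets(),
                             mc_test_config(), base)
  expect_true(all(abs(res$runs$cost - base$cost) < 1e-4))
})

test_that("perturbed survey prevalences are clipped into [0, 1]", {
  base <- get_mc_base_fit()
  # surveys with prevalences near 1 would overflow without clipping
  sv <- do.call(rbind, get_noise_free_surveys())
  sv$prevalence <- pmin(1, sv$prevalence + 0.85)
  cfg <- fit_config(stage = "epidemiology", blocks = character(0))
  spec <- uncertainty_spec(n_runs = 3, seed = 41, data_pm = 0.4,
                           output_years = 2050)
  res <- mc_data_uncertainty(spec, sv, get_targets(), cfg, base)
  expect_true(all(res$runs$max_prevalence <= 1))
  expect_true(all(res$runs$min_prevalence >= 0))
  expect_gt(max(res$runs$max_prevalence), 0.999)  # clipping really engaged
})

test_that("run bookkeeping: completed plus failed equals n_runs", {
  base <- get_mc_base_fit()
  spec <- uncertainty_spec(n_runs = 3, seed = 51, output_years = 2050)
  res <- mc_parameter_uncertainty(spec, get_noise_free_surveys(),
                                  get_targets(), mc_test_config(), base)
  expect_identical(nrow(res$runs), 3L)
  expect_identical(sum(res$runs$ok) + res$n_failed, 3L)
  expect_false(res$high_failure)
})

test_that("degenerate sweeps return the base projection", {
  base <- get_mc_base_fit()
  tr <- simulate_model(base$params, t1 = 2050)
  expected <- 100 * model_prevalence(tr, "t2dm", "both", 20, 80, 2050)
  sw <- univariate_sweep("rr_obesity",
                         base$params$rr$t2dm[["obesity"]], base)
  expect_equal(sw$prevalence_pct, expected, tolerance = 1e-10)
  expect_error(univariate_sweep("rr_bmi", 2, base), "unknown parameter")
})

test_that("2050 prevalence rises monotonically with the obesity RR", {
  base <- get_mc_base_fit()
  sw <- univariate_sweep("rr_obesity", c(1.5, 2.5, 3.5, 4.5), base)
  expect_true(all(diff(sw$prevalence_pct) > 0))
})
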