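# Shared fixtures, built once per test run and cached in this environment.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# full-resolution ground truth (20 bands, 640 compartments)
get_truth <- function() cached("truth", function() make_ground_truth(1))

get_noise_free_surveys <- function() {
  cached("sv0", function() generate_surveys(get_truth(), seed = 1,
                                            noise = FALSE))
}

get_noisy_surveys <- function() {
  cached("sv1", function() generate_surveys(get_truth(), seed = 1))
}

get_targets <- function() {
  cached("targets", function() generate_demography_targets(get_truth()))
}

# a small, fast parameter set for dynamics-level tests (10 bands)
small_params <- function(...) default_model_params(n_age_bands = 10, ...)

# closed single-cohort setup: one wide band, no births, no deaths, no
# aging, no risk-factor transitions; only the T2DM incidence hazard acts
closed_cohort_params <- function(hazard = 0.01) {
  p <- default_model_params(n_age_bands = 1)
  p$min_active_age <- 0
  p$no_aging <- TRUE
  p$cbr$values[] <- 0
  p$mort$logscale[] <- -690   # exp(-690) underflows to zero mortality
  p$rr$mortality <- 1
  p$rr$mortality_ci <- c(lo = 1, hi = 1)
  p$inc$log_rate[] <- log(hazard)
  for (f in c("obesity", "smoking", "inactivity")) {
    p$trans$on[[f]][] <- -690
    p$trans$off[[f]][] <- -690
  }
  p$obesity_mult_2050[] <- 1
  p$init$logit_prev[] <- -690  # everyone healthy, non-diabetic at start
  p
}

# the two-stage fit of the noise-free fixture is reused by several tests
get_recovery_fit <- function() {
  cached("recovery_fit", function() {
    cfg <- fit_config(tol = 1e-7, cycles = 3)
    fit_model(get_noise_free_surveys(), get_targets(), cfg,
              params = default_model_params())
  })
}
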