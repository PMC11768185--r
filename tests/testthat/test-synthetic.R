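# The synthetic observation generator: determinism, residual-noise
# calibration, multi-study structure and parameter recovery.

test_that("zero residual noise reproduces the model predictions exactly", {
  spec <- study_spec("oxaliplatin", n_profiles = 2, residual_sd_log = 0,
                     infusion_fraction = 0, seed = 4)
  obs <- generate_observations(spec, registry = REG)
  expect_equal(obs$conc, obs$pred)
  expect_true(all(obs$conc > 0))
})

test_that("generation is reproducible by seed and rejects unknown compounds", {
  spec <- study_spec("oxaliplatin", n_profiles = 2, seed = 9)
  o1 <- generate_observations(spec, registry = REG)
  o2 <- generate_observations(spec, registry = REG)
  expect_identical(o1, o2)
  expect_error(generate_observations(study_spec("nodrug"), registry = REG),
               "unknown compound")
})

test_that("the residual sampler has the requested log-sd", {
  # ~1e4 observations: 20 profiles on a dense sampling grid
  spec <- study_spec("oxaliplatin", n_profiles = 20,
                     dose_range = c(50, 200), infusion_fraction = 0,
                     sampling_times = seq(5, 1000, length.out = 500),
                     residual_sd_log = 0.2, seed = 2)
  obs <- generate_observations(spec, registry = REG)
  expect_gte(nrow(obs), 1e4)
  r <- log10(obs$conc / obs$pred)
  expect_true(sd(r) > 0.19 && sd(r) < 0.21)
  # lognormal residuals: AFE ~ 1 and AAFE ~ 10^(0.7979 * sd) (half-normal
  # mean identity)
  expect_equal(afe(obs$pred, obs$conc), 1, tolerance = 0.02)
  expect_equal(log10(aafe(obs$pred, obs$conc)),
               sqrt(2 / pi) * 0.2, tolerance = 0.02)
})

test_that("a study collection is heterogeneous with a truthful manifest", {
  col <- generate_study_collection("oxaliplatin", n_studies = 16, seed = 3,
                                   registry = REG)
  obs <- col$observations
  expect_length(unique(obs$study), 16)
  expect_true(any(obs$duration_min == 0) && any(obs$duration_min > 0))
  expect_length(unique(obs$dose_mg), length(unique(paste(obs$study,
                                                         obs$profile))))
  expect_equal(col$manifest$n_studies, 16)
  expect_equal(col$manifest$true_clearances_L_min$total, 2.5 / 60)
  # sampling schedules are jittered between studies
  t_by_study <- unique(lapply(split(obs$time_min, obs$study), unique))
  expect_gt(length(t_by_study), 1)
})

test_that("dose-normalised profiles of a linear compound collapse", {
  spec <- study_spec("oxaliplatin", n_profiles = 3,
                     dose_range = c(10, 400), infusion_fraction = 0,
                     residual_sd_log = 0, seed = 6)
  obs <- generate_observations(spec, registry = REG)
  norm <- obs$conc / obs$dose_mg
  by_time <- split(norm, obs$time_min)
  for (v in by_time) {
    expect_lt(diff(range(v)) / mean(v), 1e-6)
  }
})

test_that("noise-free evaluation is self-consistent (AFE 1, full coverage)", {
  spec <- study_spec("oxaliplatin", n_profiles = 2, residual_sd_log = 0,
                     infusion_fraction = 0, seed = 12)
  obs <- generate_observations(spec, registry = REG)
  rep <- evaluation_report(obs$pred, obs$conc)
  expect_equal(rep$afe, 1)
  expect_equal(rep$aafe, 1)
  expect_equal(rep$pct_within_2fold, 100)
})

test_that("least squares on log concentrations recovers the clearance", {
  # sampling must reach the elimination phase for the clearance to be
  # identifiable; oxaliplatin's terminal half-life is in the range of days
  spec <- study_spec("oxaliplatin", n_profiles = 17,
                     dose_range = c(50, 300), infusion_fraction = 0,
                     sampling_times = c(30, 60, 120, 240, 480, 960, 1440,
                                        2160, 2880, 3600, 4320, 5040),
                     residual_sd_log = 0.1, seed = 21)
  obs <- generate_observations(spec, registry = REG)
  expect_gte(nrow(obs), 200)
  fit <- fit_clearance_multiplier(obs, "oxaliplatin", registry = REG)
  expect_lt(abs(fit$multiplier - 1), 0.05)
})
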