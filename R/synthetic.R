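# Synthetic "literature-style" observed datasets: multi-study collections
# of venous-plasma concentration-time observations with heterogeneous IV
# regimens and multiplicative lognormal residual noise, emulating the
# statistical structure of digitised clinical PK data.

#' Study specification for synthetic observations
#'
#' @param compound compound id (must exist in the registry in use).
#' @param n_profiles number of concentration-time profiles.
#' @param dose_range mg; each profile draws its dose uniformly from this
#'   range.
#' @param infusion_fraction probability that a profile uses an infusion
#'   (otherwise bolus).
#' @param infusion_durations candidate infusion durations, min.
#' @param sampling_times increasing sampling grid, min.
#' @param residual_sd_log sd of the log10 residuals (>= 0).
#' @param kinds profile-kind labels sampled per profile.
#' @param seed integer seed.
#' @return A `study_spec` list.
#' @export
study_spec <- function(compound, n_profiles = 5,
                       dose_range = c(50, 300),
                       infusion_fraction = 0.5,
                       infusion_durations = c(30, 60, 120),
                       sampling_times = c(5, 10, 20, 30, 60, 90, 120,
                                          180, 240, 360, 480, 720),
                       residual_sd_log = 0.2,
                       kinds = c("individual", "mean", "pooled"),
                       seed = 1L) {
  if (residual_sd_log < 0) abort_field("residual_sd_log", "must be >= 0")
  if (any(diff(sampling_times) <= 0)) {
    abort_field("sampling_times", "must be increasing")
  }
  structure(list(compound = compound, n_profiles = n_profiles,
                 dose_range = dose_range,
                 infusion_fraction = infusion_fraction,
                 infusion_durations = infusion_durations,
                 sampling_times = sampling_times,
                 residual_sd_log = residual_sd_log,
                 kinds = kinds, seed = as.integer(seed)),
            class = "study_spec")
}

#' Generate synthetic observations for one study
#'
#' Simulates the whole-body model for each profile's regimen and corrupts
#' the venous-plasma predictions with multiplicative lognormal noise
#' (`obs = pred * 10^(rnorm(0, residual_sd_log))`). Reproducible by seed.
#'
#' @param spec a [study_spec()].
#' @param individual an `individual_physiology` (default reference male) or
#'   a population data.frame from [generate_population()], in which case
#'   each profile uses one sampled individual (with its elimination
#'   multipliers).
#' @param registry compound registry (default built-in).
#' @param study_id study label.
#' @param config a [pbpk_config()].
#' @return data.frame of observation records: `study`, `profile`, `kind`,
#'   `time_min`, `conc` (umol/L), `unit`, `dose_mg`, `duration_min`, and
#'   `pred` (the noise-free model value, kept for recovery tests).
#' @export
generate_observations <- function(spec, individual = NULL, registry = NULL,
                                  study_id = "study_1",
                                  config = pbpk_config()) {
  if (is.null(registry)) registry <- suppressWarnings(load_compound_registry())
  if (is.null(registry[[spec$compound]])) {
    stop(sprintf("unknown compound '%s'", spec$compound))
  }
  set.seed(spec$seed)
  pop <- if (is.data.frame(individual)) individual else NULL
  if (is.null(individual)) individual <- reference_individual("male")
  cmps <- model_compound_set(registry, spec$compound)
  tmax <- max(spec$sampling_times)
  grid <- sort(unique(c(seq(0, tmax, length.out = 121), spec$sampling_times)))
  out <- list()
  for (i in seq_len(spec$n_profiles)) {
    dose <- runif(1, spec$dose_range[1], spec$dose_range[2])
    dur <- if (runif(1) < spec$infusion_fraction) {
      sample(spec$infusion_durations, 1)
    } else 0
    kind <- sample(spec$kinds, 1)
    if (!is.null(pop)) {
      row <- pop[sample(nrow(pop), 1), ]
      ind_i <- reference_individual(row$sex, row$age, row$weight)
      mult <- c(renal = row$mult_renal, biliary = row$mult_biliary,
                enzymatic = row$mult_enzymatic, total = row$mult_total)
    } else {
      ind_i <- individual
      mult <- NULL
    }
    model <- assemble_model(ind_i, cmps,
                            list(dose_event(spec$compound, dose, 0, dur)),
                            multipliers = mult, config = config)
    sim <- simulate_pbpk(model, grid)
    pr <- get_profile(sim, spec$compound, "venous_blood", "plasma")
    pred <- approx(pr$time, pr$conc, xout = spec$sampling_times)$y
    noise <- if (spec$residual_sd_log > 0) {
      10^rnorm(length(pred), 0, spec$residual_sd_log)
    } else 1
    out[[i]] <- data.frame(study = study_id, profile = i, kind = kind,
                           time_min = spec$sampling_times,
                           conc = pred * noise, unit = "umol/L",
                           dose_mg = dose, duration_min = dur, pred = pred,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Compound set for one parent drug
#'
#' The named compound plus any metabolites its metabolic links reference,
#' in the shape [assemble_model()] expects.
#'
#' @param registry compound registry list.
#' @param compound_id parent compound id.
#' @return Named list of `compound_model`s.
#' @export
model_compound_set <- function(registry, compound_id) {
  cmp <- registry[[compound_id]]
  ids <- c(compound_id, vapply(cmp$links, function(l) l$metabolite,
                               character(1)))
  registry[ids]
}

#' Generate a heterogeneous multi-study collection
#'
#' Emulates a literature compilation: each study has its own dose level,
#' regimen (bolus or infusion), jittered sampling schedule and profile
#' count. A manifest records the generating seed and the ground-truth
#' elimination parameters for recovery tests.
#'
#' @param compound compound id.
#' @param n_studies number of studies (>= 1).
#' @param seed integer seed.
#' @param registry compound registry (default built-in).
#' @param individual an `individual_physiology` (default reference male).
#' @param dose_range,residual_sd_log shared generation settings.
#' @param config a [pbpk_config()].
#' @return List with `observations` (row-bound records of all studies) and
#'   `manifest` (seed, compound, per-study regimen, true clearances).
#' @export
generate_study_collection <- function(compound, n_studies = 8, seed = 1L,
                                      registry = NULL, individual = NULL,
                                      dose_range = c(25, 500),
                                      residual_sd_log = 0.2,
                                      config = pbpk_config()) {
  if (n_studies < 1) abort_field("n_studies", "must be >= 1")
  if (is.null(registry)) registry <- suppressWarnings(load_compound_registry())
  if (is.null(individual)) individual <- reference_individual("male")
  set.seed(as.integer(seed))
  study_seeds <- sample.int(1e6, n_studies)
  base_times <- c(5, 10, 20, 30, 60, 90, 120, 180, 240, 360, 480, 720)
  obs <- list(); studies <- list()
  for (s in seq_len(n_studies)) {
    set.seed(study_seeds[s])
    jitter <- exp(rnorm(1, 0, 0.15))
    times <- round(sort(unique(pmax(base_times * jitter, 2))), 1)
    dose_lo <- runif(1, dose_range[1], mean(dose_range))
    spec <- study_spec(compound,
                       n_profiles = sample(1:3, 1),
                       dose_range = c(dose_lo, dose_lo * runif(1, 1, 2)),
                       infusion_fraction = 0.5,
                       sampling_times = times,
                       residual_sd_log = residual_sd_log,
                       seed = study_seeds[s])
    o <- generate_observations(spec, individual = individual,
                               registry = registry,
                               study_id = sprintf("study_%02d", s),
                               config = config)
    obs[[s]] <- o
    studies[[s]] <- list(study = sprintf("study_%02d", s),
                         seed = study_seeds[s], sampling_times = times,
                         dose_range = spec$dose_range)
  }
  cl_true <- compound_clearances(registry[[compound]], individual$weight)
  list(observations = do.call(rbind, obs),
       manifest = list(compound = compound, seed = as.integer(seed),
                       n_studies = n_studies,
                       residual_sd_log = residual_sd_log,
                       true_clearances_L_min = cl_true[c("renal", "biliary",
                                                         "enzymatic",
                                                         "total")],
                       studies = studies))
}

#' Simulate a venous-plasma ensemble across a virtual population
#'
#' One whole-body simulation per population row (covariate-scaled
#' physiology plus that row's elimination multipliers), collecting the
#' venous plasma profile of `compound` on a common grid. This is the input
#' to [vpc_percentiles()].
#'
#' @param compound compound id.
#' @param population data.frame from [generate_population()].
#' @param dose a [dose_event()] (default 1 mg bolus of `compound`).
#' @param times common output grid, min.
#' @param registry compound registry (default built-in).
#' @param config a [pbpk_config()].
#' @return Matrix (individuals x time points) of venous plasma
#'   concentrations, umol/L.
#' @export
population_ensemble <- function(compound, population, dose = NULL,
                                times = sim_time_grid(1500, 150),
                                registry = NULL, config = pbpk_config()) {
  if (is.null(registry)) registry <- suppressWarnings(load_compound_registry())
  if (is.null(dose)) dose <- dose_event(compound, 1)
  cmps <- model_compound_set(registry, compound)
  out <- matrix(NA_real_, nrow = nrow(population), ncol = length(times))
  for (i in seq_len(nrow(population))) {
    row <- population[i, ]
    ind <- reference_individual(row$sex, row$age, row$weight)
    mult <- c(renal = row$mult_renal, biliary = row$mult_biliary,
              enzymatic = row$mult_enzymatic, total = row$mult_total)
    model <- assemble_model(ind, cmps, list(dose), multipliers = mult,
                            config = config)
    sim <- simulate_pbpk(model, times)
    out[i, ] <- get_profile(sim, compound, "venous_blood", "plasma")$conc
  }
  out
}

#' Recover the elimination clearance from synthetic observations
#'
#' Least-squares fit, on log concentrations, of a single multiplier applied
#' to every elimination parameter of a (linear) compound. Observations must
#' be single-dose profiles (bolus or infusion, recorded in the record
#' columns); within a linear model, predictions for each profile are the
#' 1 mg simulation scaled by dose.
#'
#' @param observations record data.frame from [generate_observations()].
#' @param compound compound id.
#' @param individual the `individual_physiology` that generated the data.
#' @param registry compound registry (default built-in).
#' @param interval search interval for the multiplier.
#' @param config a [pbpk_config()].
#' @return List with `multiplier` (1 = generating value recovered) and
#'   `objective` (residual sum of squares of log10 concentrations).
#' @export
fit_clearance_multiplier <- function(observations, compound,
                                     individual = NULL, registry = NULL,
                                     interval = c(0.25, 4),
                                     config = pbpk_config()) {
  if (is.null(registry)) registry <- suppressWarnings(load_compound_registry())
  if (is.null(individual)) individual <- reference_individual("male")
  cmps <- model_compound_set(registry, compound)
  durations <- unique(observations$duration_min)
  tmax <- max(observations$time_min)
  grid <- sort(unique(c(seq(0, tmax, length.out = 121),
                        observations$time_min)))
  obj <- function(m) {
    mult <- c(renal = m, biliary = m, enzymatic = m, total = m)
    ss <- 0
    for (dur in durations) {
      model <- assemble_model(individual, cmps,
                              list(dose_event(compound, 1, 0, dur)),
                              multipliers = mult, config = config)
      sim <- simulate_pbpk(model, grid)
      pr <- get_profile(sim, compound, "venous_blood", "plasma")
      sel <- observations$duration_min == dur
      pred <- approx(pr$time, pr$conc,
                     xout = observations$time_min[sel])$y *
        observations$dose_mg[sel]
      keep <- pred > 0 & observations$conc[sel] > 0
      ss <- ss + sum((log10(pred[keep]) -
                        log10(observations$conc[sel][keep]))^2)
    }
    ss
  }
  fit <- optimize(obj, interval = interval, tol = 1e-3)
  list(multiplier = fit$minimum, objective = fit$objective)
}
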