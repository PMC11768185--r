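#' Load the reference physiology table
#'
#' Reads the organ table (volumes, blood flows, sub-compartment volume
#' fractions, PS base values) joined with the tissue-composition table
#' shipped with the package, or from user files with the same columns.
#'
#' @param physiology_file,composition_file optional CSV paths; defaults to
#'   the built-in reference tables.
#' @return A data.frame with one row per (sex, organ).
#' @export
load_reference_physiology <- function(physiology_file = NULL,
                                      composition_file = NULL) {
  if (is.null(physiology_file)) {
    physiology_file <- system.file("extdata", "physiology_reference.csv",
                                   package = "colonpbpk", mustWork = TRUE)
  }
  if (is.null(composition_file)) {
    composition_file <- system.file("extdata", "tissue_composition.csv",
                                    package = "colonpbpk", mustWork = TRUE)
  }
  phys <- read.csv(physiology_file, stringsAsFactors = FALSE)
  comp <- read.csv(composition_file, stringsAsFactors = FALSE)
  out <- merge(phys, comp, by.x = "organ", by.y = "tissue",
               all.x = TRUE, sort = FALSE)
  # blood pools have no tissue composition row; carry plasma/red-cell rows
  out
}

# reference body weights (kg) underlying the shipped tables
.W_REF <- c(male = 73, female = 60)

#' Plasma and red-cell compositions
#'
#' Convenience accessors for the two blood composition rows of the shipped
#' composition table.
#' @param composition_file optional CSV path.
#' @return One-row data.frame with the composition fields.
#' @export
plasma_composition <- function(composition_file = NULL) {
  .blood_composition("plasma", composition_file)
}

#' @rdname plasma_composition
#' @export
red_cell_composition <- function(composition_file = NULL) {
  .blood_composition("red_cells", composition_file)
}

.blood_composition <- function(which, composition_file = NULL) {
  if (is.null(composition_file)) {
    composition_file <- system.file("extdata", "tissue_composition.csv",
                                    package = "colonpbpk", mustWork = TRUE)
  }
  comp <- read.csv(composition_file, stringsAsFactors = FALSE)
  comp[comp$tissue == which, , drop = FALSE]
}

#' Build one virtual individual
#'
#' Scales the sex-specific reference organ table to the requested body
#' weight: organ volumes scale linearly with weight relative to the
#' reference weight (73 kg male, 60 kg female); blood flows and cardiac
#' output scale allometrically with weight^0.75. Age is carried as a
#' covariate only.
#'
#' @param sex `"male"` or `"female"`.
#' @param age years, in `[0, 120]`.
#' @param weight kg, positive.
#' @param hematocrit volume fraction of blood occupied by red cells,
#'   in (0, 1); default 0.47.
#' @param reference optional physiology table from
#'   [load_reference_physiology()].
#' @return An object of class `individual_physiology`: a list with fields
#'   `sex`, `age`, `weight`, `hematocrit`, `cardiac_output` (L/min) and
#'   `organs` (data.frame incl. the venous/arterial blood pools).
#' @export
reference_individual <- function(sex = c("male", "female"), age = 30,
                                 weight = NULL, hematocrit = 0.47,
                                 reference = NULL) {
  sex <- match.arg(sex)
  if (is.null(weight)) weight <- unname(.W_REF[sex])
  if (!is.numeric(age) || age < 0 || age > 120) {
    abort_field("age", "must be in [0, 120] years")
  }
  if (!is.numeric(weight) || weight <= 0) {
    abort_field("weight", "must be > 0 kg")
  }
  if (!is.numeric(hematocrit) || hematocrit <= 0 || hematocrit >= 1) {
    abort_field("hematocrit", "must be in (0, 1)")
  }
  if (is.null(reference)) reference <- load_reference_physiology()
  org <- reference[reference$sex == sex, , drop = FALSE]
  if (nrow(org) == 0L) abort_field("sex", "no reference rows for this sex")
  wref <- unname(.W_REF[sex])
  sv <- weight / wref
  sq <- (weight / wref)^0.75
  org$volume_L <- org$volume_L * sv
  org$flow_L_per_min <- org$flow_L_per_min * sq
  # PS base values are per litre of tissue; absolute PS scales with volume
  org$endothelial_ps <- org$endothelial_ps_per_L * org$volume_L
  org$cellular_ps <- org$cellular_ps_per_L * org$volume_L
  co_ref <- c(male = 5.6, female = 5.6 * (60 / 73)^0.75)
  ind <- structure(list(
    sex = sex, age = age, weight = weight, hematocrit = hematocrit,
    cardiac_output = unname(co_ref[sex]) * sq,
    organs = org
  ), class = "individual_physiology")
  validate_individual(ind)
  ind
}

#' Build an individual from an explicit organ table
#'
#' Low-level constructor for non-standard bodies (reduced test systems,
#' sensitivity analyses). The organ data.frame must carry the same columns
#' as the reference table (volumes, flows, fractions, composition, PS).
#'
#' @param organs data.frame of organ rows including `venous_blood` and
#'   `arterial_blood` pools.
#' @param sex,age,weight,hematocrit,cardiac_output covariates; defaults are
#'   permissive.
#' @param validate run [validate_individual()] (default TRUE).
#' @return An `individual_physiology` object.
#' @export
individual_physiology <- function(organs, sex = "male", age = 30,
                                  weight = 73, hematocrit = 0.47,
                                  cardiac_output = 1e6, validate = TRUE) {
  if (!all(c("endothelial_ps", "cellular_ps") %in% names(organs))) {
    organs$endothelial_ps <- organs$endothelial_ps_per_L * organs$volume_L
    organs$cellular_ps <- organs$cellular_ps_per_L * organs$volume_L
  }
  ind <- structure(list(sex = sex, age = age, weight = weight,
                        hematocrit = hematocrit,
                        cardiac_output = cardiac_output, organs = organs),
                   class = "individual_physiology")
  if (validate) validate_individual(ind)
  ind
}

#' Validate an individual physiology
#'
#' Checks the organ-level invariants (positive volumes, non-negative flows,
#' sub-compartment fractions in (0,1) summing to 1, non-negative PS values)
#' and the body-level invariants (hematocrit in (0,1), systemic organ flows
#' not exceeding cardiac output, presence of the blood pools).
#'
#' @param ind an `individual_physiology`.
#' @return Invisibly TRUE; errors name the offending field.
#' @export
validate_individual <- function(ind) {
  org <- ind$organs
  if (any(org$volume_L <= 0)) abort_field("volume", "organ volumes must be > 0")
  if (any(org$flow_L_per_min < 0, na.rm = TRUE)) {
    abort_field("blood_flow", "organ flows must be >= 0")
  }
  fr <- org$frac_vascular + org$frac_interstitial + org$frac_intracellular
  if (any(abs(fr - 1) > 1e-9)) {
    abort_field("fractions", "sub-compartment fractions must sum to 1")
  }
  bad <- org$frac_vascular <= 0 | org$frac_vascular >= 1 |
    org$frac_interstitial <= 0 | org$frac_interstitial >= 1 |
    org$frac_intracellular <= 0 | org$frac_intracellular >= 1
  if (any(bad)) abort_field("fractions", "each fraction must lie in (0, 1)")
  if (any(org$endothelial_ps < 0) || any(org$cellular_ps < 0)) {
    abort_field("PS", "permeability-surface products must be >= 0")
  }
  if (ind$hematocrit <= 0 || ind$hematocrit >= 1) {
    abort_field("hematocrit", "must be in (0, 1)")
  }
  pools <- c("venous_blood", "arterial_blood")
  if (!all(pools %in% org$organ)) {
    abort_field("organs", "venous_blood and arterial_blood pools are required")
  }
  systemic <- !(org$organ %in% c(pools, "lung"))
  qsum <- sum(org$flow_L_per_min[systemic], na.rm = TRUE)
  if (qsum > ind$cardiac_output + 1e-9) {
    abort_field("cardiac_output", "sum of organ blood flows exceeds cardiac output")
  }
  invisible(TRUE)
}

#' Population specification
#'
#' @param n number of individuals (>= 1).
#' @param female_fraction fraction of females in `[0, 1]`.
#' @param age_range,weight_range ordered two-element ranges (years; kg).
#' @param elimination_cv coefficient of variation (>= 0) applied as lognormal
#'   multipliers to the elimination parameters.
#' @return A `population_spec` list.
#' @export
population_spec <- function(n = 1000, female_fraction = 0.5,
                            age_range = c(25, 80),
                            weight_range = c(37.5, 130),
                            elimination_cv = 0.5) {
  if (!is.numeric(n) || n < 1) abort_field("n", "must be >= 1")
  if (female_fraction < 0 || female_fraction > 1) {
    abort_field("female_fraction", "must be in [0, 1]")
  }
  if (diff(age_range) < 0) abort_field("age_range", "must be ordered")
  if (diff(weight_range) < 0) abort_field("weight_range", "must be ordered")
  if (elimination_cv < 0) abort_field("elimination_cv", "must be >= 0")
  structure(list(n = as.integer(n), female_fraction = female_fraction,
                 age_range = age_range, weight_range = weight_range,
                 elimination_cv = elimination_cv),
            class = "population_spec")
}

#' Generate a virtual population
#'
#' Sex is assigned by deterministic quota (`round(n * female_fraction)`
#' females first, then males); ages and weights are drawn uniformly over the
#' specified ranges. Elimination-parameter multipliers are drawn lognormally
#' with mean 1 and coefficient of variation `spec$elimination_cv`, one
#' multiplier per individual for each of the four elimination routes.
#'
#' @param spec a [population_spec()].
#' @param seed integer seed; the call is bit-reproducible given the seed.
#' @return A data.frame with one row per individual: `id`, `sex`, `age`,
#'   `weight`, and multiplier columns `mult_renal`, `mult_biliary`,
#'   `mult_enzymatic`, `mult_total`.
#' @export
generate_population <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(as.integer(seed))
  n <- spec$n
  n_female <- round(n * spec$female_fraction)
  sex <- c(rep("female", n_female), rep("male", n - n_female))
  age <- runif(n, spec$age_range[1], spec$age_range[2])
  weight <- runif(n, spec$weight_range[1], spec$weight_range[2])
  mult <- sample_elimination_multipliers(n, spec$elimination_cv,
                                         seed = NULL)
  data.frame(id = seq_len(n), sex = sex, age = age, weight = weight,
             mult, stringsAsFactors = FALSE)
}

#' Sample elimination-parameter multipliers
#'
#' Lognormal multipliers with mean 1 and coefficient of variation `cv`
#' (so `sdlog = sqrt(log(1 + cv^2))`, `meanlog = -sdlog^2/2`), drawn
#' independently for each of the four elimination routes.
#'
#' @param n number of individuals.
#' @param cv coefficient of variation (>= 0); `cv = 0` returns all ones.
#' @param seed optional integer seed; `NULL` continues the current RNG
#'   stream (used internally by [generate_population()]).
#' @return data.frame with columns `mult_renal`, `mult_biliary`,
#'   `mult_enzymatic`, `mult_total`; all entries strictly positive.
#' @export
sample_elimination_multipliers <- function(n, cv, seed = 1L) {
  if (cv < 0) abort_field("cv", "must be >= 0")
  if (!is.null(seed)) set.seed(as.integer(seed))
  routes <- c("mult_renal", "mult_biliary", "mult_enzymatic", "mult_total")
  if (cv == 0) {
    out <- as.data.frame(matrix(1, nrow = n, ncol = length(routes)))
  } else {
    sdlog <- sqrt(log(1 + cv^2))
    out <- as.data.frame(matrix(exp(rnorm(n * length(routes),
                                          -sdlog^2 / 2, sdlog)),
                                nrow = n))
  }
  names(out) <- routes
  out
}

#' Extract the elimination multipliers of one population row
#' @param population data.frame from [generate_population()].
#' @param id individual id.
#' @return Named numeric vector `c(renal=, biliary=, enzymatic=, total=)`.
#' @export
elimination_multipliers <- function(population, id) {
  row <- population[population$id == id, , drop = FALSE]
  if (nrow(row) != 1L) abort_field("id", "unknown individual id")
  c(renal = row$mult_renal, biliary = row$mult_biliary,
    enzymatic = row$mult_enzymatic, total = row$mult_total)
}
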