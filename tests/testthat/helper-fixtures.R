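# Shared fixtures: cached registry, reference individual, degenerate test
# bodies and whole-body simulations reused across test files.

REG <- suppressWarnings(load_compound_registry())
IND_M <- reference_individual("male")
PARENTS <- c("irinotecan", "fluorouracil", "oxaliplatin", "leucovorin")

.sim_cache <- new.env(parent = emptyenv())

# 1 mg bolus whole-body simulation of a parent (+ its metabolites), cached
parent_sim <- function(id, t_end = 3000, n = 400) {
  key <- sprintf("%s_%g_%d", id, t_end, n)
  if (is.null(.sim_cache[[key]])) {
    model <- assemble_model(IND_M, model_compound_set(REG, id),
                            list(dose_event(id, 1)))
    .sim_cache[[key]] <- simulate_pbpk(model, sim_time_grid(t_end, n))
  }
  .sim_cache[[key]]
}

# plasma-like composition columns (tissue identical to plasma => Kp = 1
# for neutral unbound compounds)
plasma_like_comp <- function() {
  pl <- plasma_composition()
  data.frame(f_water = pl$f_water, f_neutral_lipid = pl$f_neutral_lipid,
             f_phospholipid = pl$f_phospholipid, f_protein = pl$f_protein,
             interstitial_protein_ratio = 1)
}

# a neutral, fully unbound probe compound with a renal clearance (L/min)
probe_compound <- function(cl_renal_L_min = 0.2, logP = 0, mw = 400,
                           fu = 1) {
  compound_model("probe", molecular_weight = mw, logP = logP,
                 fraction_unbound = fu,
                 renal_clearance = list(value = cl_renal_L_min * 1000,
                                        unit = "mL/min"))
}

# degenerate body: venous/arterial pools plus the named organs, each built
# from a plasma-like composition so partitioning is trivial
make_test_body <- function(organs = "kidney",
                           organ_volumes = 10,
                           organ_flows = 0.5,
                           v_ven = 2, v_art = 1e-5,
                           ps_per_L = 1e5,
                           frac_vascular = 1e-4,
                           frac_interstitial = 1e-4,
                           hematocrit = 0.47) {
  comp <- plasma_like_comp()
  n <- length(organs)
  org <- data.frame(
    organ = c(organs, "venous_blood", "arterial_blood"),
    volume_L = c(organ_volumes, v_ven, v_art),
    flow_L_per_min = c(organ_flows, NA, NA),
    frac_vascular = c(rep(frac_vascular, n), 1 - 2e-7, 1 - 2e-7),
    frac_interstitial = c(rep(frac_interstitial, n), 1e-7, 1e-7),
    stringsAsFactors = FALSE)
  org$frac_intracellular <- 1 - org$frac_vascular - org$frac_interstitial
  org$endothelial_ps_per_L <- ps_per_L
  org$cellular_ps_per_L <- ps_per_L
  org <- cbind(org, comp[rep(1, nrow(org)), ], row.names = NULL)
  individual_physiology(org, hematocrit = hematocrit)
}

# fast-exchange config for analytic-oracle comparisons
oracle_config <- function(...) {
  pbpk_config(rbc_exchange_rate = 1e4, rtol = 1e-10, atol = 1e-12, ...)
}

# analytic two-compartment bolus solution (central concentration)
biexponential <- function(t, dose, V1, V2, Q, CL) {
  k10 <- CL / V1; k12 <- Q / V1; k21 <- Q / V2
  s <- k10 + k12 + k21
  disc <- sqrt(s^2 - 4 * k10 * k21)
  alpha <- (s + disc) / 2
  beta <- (s - disc) / 2
  (dose / V1) * ((alpha - k21) * exp(-alpha * t) -
                   (beta - k21) * exp(-beta * t)) / (alpha - beta)
}
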