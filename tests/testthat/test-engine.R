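# Oracles for the ODE engine: closed-form reductions, conservation and
# stoichiometry.

test_that("a degenerate one-organ body reduces to the 1-compartment equation", {
  body <- make_test_body("kidney", organ_volumes = 10, organ_flows = 50,
                         ps_per_L = 100)
  cmp <- probe_compound(cl_renal_L_min = 0.2)
  model <- assemble_model(body, cmp, config = oracle_config())
  p <- model$params$probe
  g <- model$geometry
  # pre-equilibrated state at plasma concentration C everywhere
  C <- 2
  y <- numeric(model$n_state)
  y[p$i_bc] <- p$krbc * C * g$V_bc
  y[p$i_pl] <- C * g$V_pl
  y[p$i_is] <- (p$fu / p$fui) * C * g$V_is
  y[p$i_cl] <- p$kp * C * g$V_cl
  y[p$i_ven_bc] <- p$krbc * C * g$V_ven_bc
  y[p$i_ven_pl] <- C * g$V_ven_pl
  y[p$i_art_bc] <- p$krbc * C * g$V_art_bc
  y[p$i_art_pl] <- C * g$V_art_pl
  dy <- model$rate(0, y, list())
  cl_eff <- 0.2 * p$fu            # renal clearance on unbound plasma
  body_idx <- c(p$i_bc, p$i_pl, p$i_is, p$i_cl, p$i_ven_bc, p$i_ven_pl,
                p$i_art_bc, p$i_art_pl)
  v_eff <- sum(g$V_pl, g$V_ven_pl, g$V_art_pl,
               p$krbc * c(g$V_bc, g$V_ven_bc, g$V_art_bc),
               (p$fu / p$fui) * g$V_is, p$kp * g$V_cl)
  a_tot <- sum(y[body_idx])
  expect_equal(sum(dy[body_idx]), -(cl_eff / v_eff) * a_tot,
               tolerance = 1e-12)
  expect_equal(dy[p$i_cum_renal], cl_eff * C, tolerance = 1e-12)
})

test_that("the collapsed body recovers AUC = Dose/CL and slope CL/V", {
  body <- make_test_body("kidney", organ_volumes = 10, organ_flows = 2000,
                         v_ven = 2, v_art = 1, ps_per_L = 1e3)
  cl <- 0.02
  cmp <- probe_compound(cl_renal_L_min = cl)
  model <- assemble_model(body, cmp, list(dose_event("probe", 1)),
                          config = oracle_config())
  p <- model$params$probe
  g <- model$geometry
  dose <- 1 / 400 * 1000   # umol
  sim <- simulate_pbpk(model, sim_time_grid(9000, 500))
  kid <- get_profile(sim, "probe", "kidney", "plasma")
  expect_equal(auc_inf(kid$time, kid$conc)$auc_inf, dose / cl,
               tolerance = 1e-4)
  ven <- get_profile(sim, "probe", "venous_blood", "plasma")
  expect_equal(auc_inf(ven$time, ven$conc)$auc_inf, dose / cl,
               tolerance = 1e-3)
  v_eff <- sum(g$V_pl, g$V_ven_pl, g$V_art_pl,
               p$krbc * c(g$V_bc, g$V_ven_bc, g$V_art_bc),
               (p$fu / p$fui) * g$V_is, p$kp * g$V_cl)
  lz <- terminal_slope(ven$time, ven$conc)$lambda_z
  expect_equal(lz, cl / v_eff, tolerance = 1e-4)
})

test_that("a two-organ flow-limited body matches the analytic biexponential", {
  # hematocrit ~0: the blood-cell phase is negligible and the body is an
  # exact two-compartment system (central blood pool + flow-limited organ)
  body <- make_test_body("muscle", organ_volumes = 10, organ_flows = 0.5,
                         v_ven = 2, v_art = 1e-5, ps_per_L = 1e4,
                         hematocrit = 0.001)
  cmp <- probe_compound(cl_renal_L_min = 0.2)
  model <- assemble_model(body, cmp, list(dose_event("probe", 1)),
                          config = oracle_config())
  p <- model$params$probe
  h <- body$hematocrit
  phi <- (1 - h) + h * p$krbc
  V1 <- (2 + 1e-5) * phi
  V2 <- 10 * (1e-4 * phi + 1e-4 * (p$fu / p$fui[1]) + 0.9998 * p$kp[1])
  Qeff <- 0.5 * phi
  dose <- 1 / 400 * 1000
  times <- sim_time_grid(2000, 400)
  sim <- simulate_pbpk(model, times)
  ven <- get_profile(sim, "probe", "venous_blood", "plasma")
  sel <- ven$time >= 1
  ana <- biexponential(ven$time[sel], dose, V1, V2, Qeff, 0.2 * p$fu)
  expect_lt(max(abs(ven$conc[sel] - ana)) / max(ana), 1e-4)
})

test_that("Michaelis-Menten saturable catabolism honours its limits", {
  model <- assemble_model(IND_M, REG[c("fluorouracil", "fuh2")])
  p <- model$params$fluorouracil
  g <- model$geometry
  i_liv <- match("liver", g$onames)
  km <- p$cl$km_umol_L
  vmax <- p$vmax_umol_min
  rate_at <- function(cu) {
    y <- numeric(model$n_state)
    # liver intracellular amount giving unbound-equivalent concentration cu
    y[p$i_cl[i_liv]] <- cu * p$kp[i_liv] / p$fu * g$V_cl[i_liv]
    dy <- model$rate(0, y, list())
    dy[p$i_cum_conv] + dy[p$i_cum_hepatic]   # total DPD flux
  }
  # midpoint: rate exactly Vmax/2 at Cu = Km
  expect_equal(rate_at(km), vmax / 2, tolerance = 1e-12)
  # linear limit: rate ~ (Vmax/Km) * Cu for Cu << Km
  cu <- km * 1e-4
  expect_equal(rate_at(cu), vmax / km * cu, tolerance = 2e-4)
  # conversion split: 90% of the flux appears as FUH2
  y <- numeric(model$n_state)
  y[p$i_cl[i_liv]] <- km * p$kp[i_liv] / p$fu * g$V_cl[i_liv]
  dy <- model$rate(0, y, list())
  expect_equal(dy[p$i_cum_conv], 0.9 * vmax / 2, tolerance = 1e-12)
  m <- model$params$fuh2
  expect_equal(dy[m$i_cl[i_liv]], 0.9 * vmax / 2, tolerance = 1e-12)
})

test_that("zero dose stays identically zero and doubling a dose doubles a linear model", {
  model0 <- assemble_model(IND_M, model_compound_set(REG, "oxaliplatin"))
  sim0 <- simulate_pbpk(model0, sim_time_grid(500, 60))
  expect_true(all(sim0$states == 0))

  grid <- sim_time_grid(1500, 150)
  sims <- lapply(c(1, 2), function(d) {
    m <- assemble_model(IND_M, model_compound_set(REG, "oxaliplatin"),
                        list(dose_event("oxaliplatin", d)))
    simulate_pbpk(m, grid, rtol = 1e-10, atol = 1e-13)
  })
  c1 <- get_profile(sims[[1]], "oxaliplatin", "venous_blood", "plasma")$conc
  c2 <- get_profile(sims[[2]], "oxaliplatin", "venous_blood", "plasma")$conc
  expect_lt(max(abs(c2 / 2 - c1)) / max(c1), 1e-6)
})

test_that("mass balance closes to 1e-6 across compounds and regimens", {
  cases <- list(
    list(id = "irinotecan", dose = 1, dur = 0),
    list(id = "fluorouracil", dose = 500, dur = 30),
    list(id = "oxaliplatin", dose = 130, dur = 120),
    list(id = "leucovorin", dose = 50, dur = 0)
  )
  for (cs in cases) {
    m <- assemble_model(IND_M, model_compound_set(REG, cs$id),
                        list(dose_event(cs$id, cs$dose, 0, cs$dur)))
    sim <- simulate_pbpk(m, sim_time_grid(2000, 150))
    expect_lt(mass_balance(sim), 1e-6)
  }
})

test_that("infusions administer rate * elapsed time and convert moles one-to-one", {
  m <- assemble_model(IND_M, model_compound_set(REG, "fluorouracil"),
                      list(dose_event("fluorouracil", 600, 10, 120)))
  total_umol <- 600 / REG$fluorouracil$physchem$molecular_weight * 1000
  expect_equal(unname(administered_amount(m, 70)["fluorouracil"]),
               total_umol * 60 / 120)
  expect_equal(unname(administered_amount(m, 5)["fluorouracil"]), 0)
  expect_equal(unname(administered_amount(m, 1e4)["fluorouracil"]),
               total_umol)

  sim <- simulate_pbpk(m, sim_time_grid(2500, 200))
  expect_lt(mass_balance(sim), 1e-6)
  # stoichiometry: metabolite formed = parent converted
  p <- m$params$fluorouracil; mb <- m$params$fuh2
  fin <- sim$states[nrow(sim$states), ]
  met_total <- sum(fin[c(mb$i_bc, mb$i_pl, mb$i_is, mb$i_cl,
                         mb$i_ven_bc, mb$i_ven_pl, mb$i_art_bc,
                         mb$i_art_pl)]) +
    fin[mb$i_cum_renal] + fin[mb$i_cum_hepatic]
  expect_equal(met_total, unname(fin[p$i_cum_conv]), tolerance = 1e-8)
})

test_that("assembly rejects dangling links and unknown dose targets", {
  expect_error(assemble_model(IND_M, REG["fluorouracil"]),
               "dangling metabolite link")
  expect_error(assemble_model(IND_M, REG[c("fluorouracil", "fuh2")],
                              list(dose_event("nope", 1))),
               "unknown compound")
  m <- assemble_model(IND_M, REG[c("fluorouracil", "fuh2")])
  expect_error(simulate_pbpk(m, c(0, 0, 1)), "strictly increasing")
})
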