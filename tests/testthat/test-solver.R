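test_that("layer stack geometry and CFL step behave as expected", {
  st <- layer_stack(20e-4, 30e-4, 0.5, 10)
  expect_equal(st$n_nodes, 28)
  expect_equal(max(st$x), 30e-4 + 2 * 20e-4)
  # shared interface nodes sit exactly at delta and delta + d
  expect_equal(st$x[st$interface_nodes], c(20e-4, 50e-4))
  expect_equal(sum(st$cv), max(st$x))
  # beta = 1 in the films, xi in the membrane
  expect_equal(unique(st$beta_face[1:9]), 1)
  expect_equal(unique(st$beta_face[10:18]), 0.5)

  D <- c(1e-5, 2e-5)
  dt <- cfl_timestep(st, D, safety = 1)
  expect_equal(dt, min(st$h_face^2 / (2 * st$beta_face)) / max(D))
  # halving the spacing quarters the step
  st2 <- layer_stack(20e-4, 30e-4, 0.5, 19)
  expect_equal(cfl_timestep(st2, D, 1) / dt, 0.25, tolerance = 0.01)
  # reduced membrane mobility relaxes the membrane-layer bound by 1/xi:
  # with the membrane limiting, a smaller xi allows a larger step
  st_thinmem <- function(xi) layer_stack(20e-4, 5e-4, xi, 10)
  expect_equal(cfl_timestep(st_thinmem(0.25), D, 1) /
                 cfl_timestep(st_thinmem(0.5), D, 1), 2)
})

test_that("zero-current potential gradient matches electrolyte theory", {
  sp <- species_table(25)
  spi <- sp[sp$species %in% c("Na", "Cl"), ]

  # uniform composition: no gradient, no field
  conc <- setNames(c(0.1, 0.1), spi$species)
  g0 <- setNames(c(0, 0), spi$species)
  expect_equal(potential_gradient(conc, g0, spi, 298.15), 0)

  # binary electrolyte: closed-form diffusion potential
  # dphi/dx = -(RT/F) (D+ - D-)/(D+ + D-) * (1/C) dC/dx
  g <- setNames(c(-3, -3), spi$species)
  DNa <- spi$D_cm2_s[spi$species == "Na"]
  DCl <- spi$D_cm2_s[spi$species == "Cl"]
  expected <- -(8.314 * 298.15 / 96485) * (DNa - DCl) / (DNa + DCl) *
    (-3 / 0.1)
  expect_equal(potential_gradient(conc, g, spi, 298.15), expected)

  # equal cation/anion mobilities: field vanishes for any common gradient
  sp_sym <- spi
  sp_sym$D_cm2_s <- c(1.5e-5, 1.5e-5)
  expect_equal(potential_gradient(conc, g, sp_sym, 298.15), 0)

  # all-neutral composition: warning and zero
  spu <- sp[sp$species == "Ur", ]
  expect_warning(
    out <- potential_gradient(c(Ur = 0.1), c(Ur = -1), spu, 298.15),
    "neutral")
  expect_equal(out, 0)
})

test_that("face fluxes reduce to Fick's law and satisfy zero current", {
  sp <- species_table(37)
  st <- layer_stack(20e-4, 30e-4, 0.4, 10)

  # single neutral solute with a globally linear profile: films carry
  # -D dC/dx, the membrane the xi-scaled value
  spu <- sp[sp$species == "Ur", ]
  state <- matrix(1e-2 * (1 - st$x / max(st$x)), ncol = 1,
                  dimnames = list(NULL, "Ur"))
  J <- flux_field(state, st, spu)
  slope <- (0 - 1e-2) / max(st$x)
  D <- spu$D_cm2_s
  expect_equal(unname(J[1:9, 1]), rep(-D * slope * 1e-3, 9))
  expect_equal(unname(J[10:18, 1]), rep(-0.4 * D * slope * 1e-3, 9))

  # zero-current identity on random ionic states
  spi <- sp[sp$species %in% c("P1", "P2", "Na", "Cl", "H", "OH"), ]
  set.seed(7)
  for (rep in 1:10) {
    state <- matrix(10^runif(st$n_nodes * nrow(spi), -8, -1),
                    st$n_nodes, nrow(spi),
                    dimnames = list(NULL, spi$species))
    J <- flux_field(state, st, spi)
    zJ <- J %*% spi$z
    azJ <- abs(J) %*% abs(spi$z)
    expect_lt(max(abs(zJ) / azJ), 1e-10)
  }
})

test_that("a uniform equilibrium state is a fixed point of the stepper", {
  sp <- species_table(37)
  spi <- sp[sp$species %in% c("P1", "P2", "Na", "H", "OH"), ]
  st <- layer_stack(15e-4, 20e-4, 0.5, 8)
  comp <- electroneutral_composition(Ptot = 2.9e-3, pH = 7.4)[spi$species]
  state <- initial_state(st, comp, comp)
  dt <- cfl_timestep(st, spi$D_cm2_s)
  out <- transport_step(state, st, spi, dt = dt, n_steps = 100)
  expect_equal(out$state, state, tolerance = 1e-12)
  expect_equal(max(abs(out$J_faces)), 0, tolerance = 1e-18)
})

test_that("quasi-steady neutral-solute transport matches series resistance", {
  sp <- species_table(37)
  spu <- sp[sp$species == "Ur", ]
  delta <- 20e-4; d <- 30e-4; xi <- 0.5
  CA <- 1.67e-2

  run_L <- function(nodes) {
    st <- layer_stack(delta, d, xi, nodes)
    r <- run_to_quasi_steady(st, spu, c(Ur = CA), c(Ur = 0),
                             config = solver_config(
                               nodes_per_layer = nodes, horizon_s = 60,
                               reaction_mode = "off"))
    expect_true(r$converged)
    mass_transfer_coefficient(r$J_mid[["Ur"]], CA, 0)
  }
  L30 <- run_L(30)
  L_oracle <- oracle_series_L(spu$D_cm2_s, delta, d, xi)
  expect_equal(L30 / L_oracle, 1, tolerance = 0.005)

  # spatial convergence: 60 vs 30 nodes per layer below 0.2%
  L60 <- run_L(60)
  expect_equal(L60 / L30, 1, tolerance = 0.002)

  # linearity: doubling both boundary values leaves L unchanged
  st <- layer_stack(delta, d, xi, 30)
  r2 <- run_to_quasi_steady(st, spu, c(Ur = 2 * CA), c(Ur = 0),
                            config = solver_config(horizon_s = 60,
                                                   reaction_mode = "off"))
  L2 <- mass_transfer_coefficient(r2$J_mid[["Ur"]], 2 * CA, 0)
  expect_equal(L2 / L30, 1, tolerance = 1e-6)

  # flux scaled by xi inside the membrane at quasi-steady state is already
  # captured by the series formula; a zero concentration difference gives
  # zero flux
  r0 <- run_to_quasi_steady(st, spu, c(Ur = CA), c(Ur = CA),
                            config = solver_config(horizon_s = 5,
                                                   reaction_mode = "off"))
  expect_equal(r0$J_mid[["Ur"]], 0, tolerance = 1e-20)
  expect_error(mass_transfer_coefficient(r0$J_mid[["Ur"]], CA, CA),
               "undefined")
})

test_that("binary NaCl transport diffuses with the harmonic-mean coefficient", {
  sp <- species_table(25)
  spi <- sp[sp$species %in% c("Na", "Cl"), ]
  delta <- 20e-4; d <- 30e-4; xi <- 0.5
  st <- layer_stack(delta, d, xi, 30)
  r <- run_to_quasi_steady(st, spi, c(Na = 0.1, Cl = 0.1),
                           c(Na = 0, Cl = 0),
                           config = solver_config(horizon_s = 60,
                                                  reaction_mode = "off"))
  expect_true(r$converged)
  # electroneutral salt flux: both ions move together
  expect_equal(r$J_mid[["Na"]] / r$J_mid[["Cl"]], 1, tolerance = 1e-9)
  Ds <- oracle_binary_Ds(spi$D_cm2_s[spi$species == "Na"],
                         spi$D_cm2_s[spi$species == "Cl"])
  J_oracle <- Ds * 0.1e-3 / (2 * delta + d / xi)
  expect_equal(r$J_mid[["Na"]] / J_oracle, 1, tolerance = 0.01)
  expect_lt(r$max_charge_imbalance, 1e-9)
})

test_that("reactive phosphate runs conserve charge and total phosphate", {
  setup <- small_ionic_setup()
  cfg <- solver_config(nodes_per_layer = 12, horizon_s = 30)
  r <- run_to_quasi_steady(setup$stack, setup$sp, setup$bA, setup$bB,
                           config = cfg)
  expect_true(r$converged)
  expect_lt(r$max_charge_imbalance, 1e-9)

  # discrete conservation audit: the change of the interior inventory of
  # reaction-conserved quantities equals the net time-integrated boundary
  # influx (reactions only interconvert P1 and P2)
  st0 <- initial_state(setup$stack, setup$bA, setup$bB)
  interior <- 2:(setup$stack$n_nodes - 1)
  audit <- function(w) {
    dC <- (r$state[interior, , drop = FALSE] -
             st0[interior, , drop = FALSE]) %*% w
    lhs <- sum(setup$stack$cv[interior] * dC) * 1e-3
    rhs <- sum((r$boundary_influx - r$boundary_outflux) * w)
    c(lhs = lhs, rhs = rhs)
  }
  wP <- as.numeric(setup$sp$species %in% c("P1", "P2"))
  aP <- audit(wP)
  expect_equal(aP[["lhs"]], aP[["rhs"]], tolerance = 1e-6)
  wNa <- as.numeric(setup$sp$species == "Na")
  aNa <- audit(wNa)
  expect_equal(aNa[["lhs"]], aNa[["rhs"]], tolerance = 1e-6)

  # total phosphate is transported but not created: the quasi-steady total
  # phosphate flux is uniform across the membrane
  JP <- r$J_faces[, "P1"] + r$J_faces[, "P2"]
  mem_faces <- setup$stack$monitor_faces + 1
  expect_equal(max(JP[mem_faces]) / min(JP[mem_faces]), 1,
               tolerance = 1e-4)
})

test_that("quasi-steady fluxes are governed by equilibria, not rate constants", {
  setup <- small_ionic_setup(nodes = 10)
  cfg <- function(mode) solver_config(nodes_per_layer = 10, horizon_s = 20,
                                      reaction_mode = mode)
  ptot_flux <- function(r) r$J_mid[["P1"]] + r$J_mid[["P2"]]

  # explicit kinetics at moderate rates vs the same rates scaled x10
  eq1 <- equilibrium_set(k_rec_water = 1.4e8, k_rec_phosphate = 1e7)
  eq10 <- equilibrium_set(k_rec_water = 1.4e9, k_rec_phosphate = 1e8)
  r1 <- run_to_quasi_steady(setup$stack, setup$sp, setup$bA, setup$bB,
                            eq = eq1, config = cfg("explicit"))
  r10 <- run_to_quasi_steady(setup$stack, setup$sp, setup$bA, setup$bB,
                             eq = eq10, config = cfg("explicit"))
  expect_equal(ptot_flux(r10) / ptot_flux(r1), 1, tolerance = 0.005)

  # the equilibrium-splitting mode agrees with the literal kinetics
  re <- run_to_quasi_steady(setup$stack, setup$sp, setup$bA, setup$bB,
                            config = cfg("equilibrium"))
  expect_equal(ptot_flux(re) / ptot_flux(r10), 1, tolerance = 0.005)
})
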