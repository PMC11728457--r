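test_that("phosphate speciation matches the closed form and conserves total", {
  # symmetric split at pH = pK
  s <- speciate_phosphate(1e-3, CH = 6.55e-8, K = 6.55e-8)
  expect_equal(s$P1, 5e-4)
  expect_equal(s$P2, 5e-4)

  # zero total
  s0 <- speciate_phosphate(0, 1e-7)
  expect_identical(c(s0$P1, s0$P2), c(0, 0))

  # physiological feed at pH 7.4 (frozen from direct evaluation)
  s <- speciate_phosphate(2.9e-3, CH = 10^-7.4, K = 6.55e-8)
  expect_equal(s$P1, 1.096289e-3, tolerance = 1e-6)
  expect_equal(s$P2, 1.803711e-3, tolerance = 1e-6)

  # conservation over many random inputs
  set.seed(11)
  n <- 1e5
  Ptot <- runif(n, 0, 0.1)
  CH <- 10^runif(n, -12, -2)
  s <- speciate_phosphate(Ptot, CH)
  expect_equal(s$P1 + s$P2, Ptot, tolerance = 1e-14)

  expect_error(speciate_phosphate(1e-3, CH = 0), "positive")
  expect_error(speciate_phosphate(1e-3, CH = 1e-7, K = -1), "positive")
  expect_error(speciate_phosphate(-1e-3, CH = 1e-7), "non-negative")
})

test_that("reaction source terms vanish at equilibrium and conserve charge", {
  eq <- equilibrium_set()
  # detailed balance built into the constructor
  expect_equal(eq$k1 / eq$km1, eq$K)
  expect_equal(eq$kd * eq$C_H2O / eq$kr, eq$Kw)

  # equilibrium state -> all rates zero
  comp <- electroneutral_composition(Ptot = 2.9e-3, pH = 7.4, eq = eq)
  r <- reaction_rates(comp, eq)
  expect_equal(max(abs(r)) / (eq$kd * eq$C_H2O), 0, tolerance = 1e-10)

  # one-sided reaction: no P2 present, water balanced
  CH <- 1e-7
  comp1 <- c(P1 = 1e-3, P2 = 0, H = CH, OH = eq$Kw / CH)
  r1 <- reaction_rates(comp1, eq)
  expect_equal(r1[["P2"]], eq$k1 * 1e-3)
  expect_equal(r1[["P1"]], -r1[["P2"]])
  expect_equal(r1[["H"]], eq$k1 * 1e-3)

  # charge-weighted sum is identically zero for random states
  set.seed(21)
  for (i in 1:50) {
    st <- c(P1 = runif(1, 0, 1e-2), P2 = runif(1, 0, 1e-2),
            H = 10^runif(1, -10, -3), OH = 10^runif(1, -10, -3),
            Na = runif(1), Cl = runif(1), Ur = runif(1), Crn = runif(1))
    r <- reaction_rates(st, eq)
    z <- c(Ur = 0, Crn = 0, P1 = -1, P2 = -2, Na = 1, Cl = -1,
           H = 1, OH = -1)
    expect_equal(sum(z[names(r)] * r), 0,
                 tolerance = 1e-12 * sum(abs(r)))
  }

  expect_error(reaction_rates(c(H = -1e-7, OH = 1e-7)), "non-negative")
})

test_that("electroneutral compositions close the charge balance", {
  eq <- equilibrium_set()
  # pure saline at neutral pH: Na tracks Cl
  c1 <- electroneutral_composition(Ptot = 0, C_NaCl = 0.1, pH = 7.0)
  expect_equal(c1[["Na"]], c1[["Cl"]], tolerance = 1e-5)
  expect_equal(c1[["Cl"]], 0.1)

  # phosphate feed: frozen from speciation + charge balance
  c2 <- electroneutral_composition(Ptot = 2.9e-3, C_NaCl = 0, pH = 7.4)
  expect_equal(c2[["Na"]], 4.703917e-3, tolerance = 1e-6)

  # construction invariant over random feeds
  set.seed(31)
  for (i in 1:50) {
    cc <- electroneutral_composition(Ptot = runif(1, 0, 1e-2),
                                     C_NaCl = runif(1, 0, 0.2),
                                     pH = runif(1, 6, 8))
    z <- c(Ur = 0, Crn = 0, P1 = -1, P2 = -2, Na = 1, Cl = -1,
           H = 1, OH = -1)
    expect_lt(abs(sum(z * cc)), 1e-12 * sum(abs(z) * cc))
  }

  # strongly acidic feed without a salt background cannot be balanced by Na+
  expect_error(electroneutral_composition(Ptot = 0, C_NaCl = 0, pH = 3),
               "infeasible")
})

test_that("pure reaction relaxation reaches both equilibria from any state", {
  eq <- equilibrium_set()
  set.seed(41)
  for (i in 1:20) {
    st <- c(P1 = runif(1, 0, 5e-3), P2 = runif(1, 0, 5e-3),
            H = 10^runif(1, -9, -5), OH = 10^runif(1, -9, -5))
    relaxed <- equilibrate_composition(st, eq)
    expect_equal(relaxed[["H"]] * relaxed[["OH"]] / eq$Kw, 1,
                 tolerance = 1e-6)
    expect_equal(relaxed[["P2"]] * relaxed[["H"]] /
                   (eq$K * relaxed[["P1"]]), 1, tolerance = 1e-6)
    # conserved quantities of the reaction network
    expect_equal(relaxed[["P1"]] + relaxed[["P2"]],
                 st[["P1"]] + st[["P2"]], tolerance = 1e-12)
    expect_equal(relaxed[["H"]] - relaxed[["OH"]] - relaxed[["P2"]],
                 st[["H"]] - st[["OH"]] - st[["P2"]], tolerance = 1e-9)
  }

  # independent kinetic oracle: explicit integration of the rate equations
  # (slowed rates keep the ODE non-stiff) lands on the same fixed point
  eq_slow <- equilibrium_set(k_rec_water = 1.4e5, k_rec_phosphate = 1e5)
  st <- c(P1 = 2e-3, P2 = 1e-3, H = 1e-6, OH = 1e-8)
  y <- st
  dt <- 1e-4
  for (k in 1:200000) {
    r <- reaction_rates(y, eq_slow)
    y <- pmax(y + dt * r[names(y)], 0)
  }
  relaxed <- equilibrate_composition(st, eq_slow)
  expect_equal(unname(y["H"]), relaxed[["H"]], tolerance = 1e-4)
  expect_equal(unname(y["P1"]), relaxed[["P1"]], tolerance = 1e-4)
})

test_that("species table carries the fixed charges and scaled diffusivities", {
  tab <- species_table(37)
  expect_identical(setNames(tab$z, tab$species),
                   c(Ur = 0L, Crn = 0L, P1 = -1L, P2 = -2L, Na = 1L,
                     Cl = -1L, H = 1L, OH = -1L))
  expect_true(all(tab$D_cm2_s > 0))
  expect_equal(tab$D_cm2_s[tab$species == "Ur"], 1.9e-5)
  # Stokes-Einstein scaling: about +34% from 25 to 37 C
  t25 <- species_table(25)
  ratio <- tab$D_cm2_s[tab$species == "Cl"] /
    t25$D_cm2_s[t25$species == "Cl"]
  expect_equal(ratio, 1.34, tolerance = 0.01)
  # overrides are honored and validated
  t2 <- species_table(37, D_override = c(Ur = 2e-5))
  expect_equal(t2$D_cm2_s[t2$species == "Ur"], 2e-5)
  expect_error(species_table(37, D_override = c(Xx = 1e-5)), "unknown")
})
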