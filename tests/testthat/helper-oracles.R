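# Independent closed-form references used across tests. These are written
# from first principles here, separately from the package implementation,
# so that solver results are checked against an external formula.

# quasi-steady mass-transfer coefficient of a neutral solute across
# solution film | membrane | solution film treated as resistances in series
oracle_series_L <- function(D, delta_cm, d_cm, xi) {
  1 / (2 * delta_cm / D + d_cm / (xi * D))
}

# diffusion potential coefficient of a binary 1:1 electrolyte: the salt
# diffuses with the harmonic-mean coefficient 2 D+ D- / (D+ + D-)
oracle_binary_Ds <- function(D_plus, D_minus) {
  2 * D_plus * D_minus / (D_plus + D_minus)
}

# counter-current clearance, written out independently from Eq-style inputs
oracle_clearance <- function(L, Smb_cm2, QA_ml_min, QB_ml_min) {
  QA <- QA_ml_min / 60
  QB <- QB_ml_min / 60
  theta <- -Smb_cm2 * (1 - QA / QB) / QA
  60 * QA * (1 - exp(theta * L)) / (1 - (QA / QB) * exp(theta * L))
}

# small ionic test stack shared by several solver tests: thin layers keep
# the CFL-limited runs fast while preserving all couplings
small_ionic_setup <- function(xi = 0.5, nodes = 12) {
  sp <- species_table(37)
  spi <- sp[sp$species %in% c("P1", "P2", "Na", "H", "OH"), ]
  list(stack = layer_stack(15e-4, 20e-4, xi, nodes),
       sp = spi,
       bA = electroneutral_composition(Ptot = 2.9e-3, pH = 7.4)[spi$species],
       bB = electroneutral_composition(Ptot = 0, pH = 7.0)[spi$species])
}

lab_reference <- function() {
  list(spec = dialyzer_spec(dhf_um = 190, lhf_cm = 15, d_um = 140,
                            Nhf = 90, delta_um = 63),
       ops = operating_conditions(300, 500))
}
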