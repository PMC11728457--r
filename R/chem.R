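#' Acid-base equilibria and rate constants
#'
#' Bundles the two equilibria of the model -- water autoprotolysis
#' (`Kw = [H+][OH-]`) and the second dissociation of phosphoric acid
#' (`K = [HPO4^2-][H+]/[H2PO4-]`, pK 7.184 at 37 C) -- together with forward
#' and backward rate constants satisfying detailed balance. The source only
#' fixes the equilibrium constants; the defaults for the recombination rates
#' are diffusion-limited literature values, and quasi-steady transport
#' results are insensitive to them (only the equilibria matter).
#'
#' @param Kw water ion product, mol^2 L^-2.
#' @param K phosphate dissociation constant, mol L^-1.
#' @param k_rec_water water recombination rate constant `kr`, L mol^-1 s^-1.
#' @param k_rec_phosphate phosphate recombination rate constant `k-1`,
#'   L mol^-1 s^-1.
#' @param C_H2O molar concentration of water, mol L^-1.
#' @return object of class `equilibrium_set`: list with `Kw`, `K`, `k1`
#'   (s^-1), `km1`, `kd` (s^-1), `kr`, `C_H2O`. Detailed balance
#'   (`k1/km1 == K`, `kd*C_H2O/kr == Kw`) holds by construction.
#' @export
equilibrium_set <- function(Kw = 1e-14, K = 6.55e-8,
                            k_rec_water = 1.4e11,
                            k_rec_phosphate = 1e10,
                            C_H2O = 55.3) {
  stopifnot(Kw > 0, K > 0, k_rec_water > 0, k_rec_phosphate > 0, C_H2O > 0)
  structure(list(Kw = Kw, K = K,
                 k1 = K * k_rec_phosphate, km1 = k_rec_phosphate,
                 kd = k_rec_water * Kw / C_H2O, kr = k_rec_water,
                 C_H2O = C_H2O),
            class = "equilibrium_set")
}

#' Phosphate speciation at a given proton concentration
#'
#' Splits total phosphate into the singly (H2PO4-, `P1`) and doubly
#' (HPO4^2-, `P2`) charged anions:
#' `P1 = Ptot / (1 + K/CH)`, `P2 = Ptot / (1 + CH/K)`.
#' The two fractions sum to `Ptot` exactly.
#'
#' @param Ptot total phosphate concentration, mol L^-1 (vectorized).
#' @param CH proton concentration, mol L^-1.
#' @param K phosphate dissociation constant, mol L^-1.
#' @return list with numeric components `P1` and `P2`.
#' @examples
#' speciate_phosphate(2.9e-3, 10^-7.4)
#' @export
speciate_phosphate <- function(Ptot, CH, K = 6.55e-8) {
  if (any(CH <= 0)) stop("CH must be positive")
  if (any(K <= 0)) stop("K must be positive")
  if (any(Ptot < 0)) stop("Ptot must be non-negative")
  list(P1 = Ptot / (1 + K / CH),
       P2 = Ptot / (1 + CH / K))
}

#' Reaction source terms for the phosphate and water equilibria
#'
#' Rates of change (mol L^-1 s^-1) from the two homogeneous reactions:
#' phosphate dissociation `P1 <-> P2 + H` and water `H2O <-> H + OH`.
#' All other species have zero source. The charge-weighted sum of the rates
#' vanishes identically (the reactions are charge neutral).
#'
#' @param conc named numeric vector of concentrations (mol L^-1); must
#'   contain `H` and `OH`, and `P1`/`P2` if phosphate is present.
#' @param eq an [equilibrium_set()].
#' @return named numeric vector of source terms, one per canonical species.
#' @export
reaction_rates <- function(conc, eq = equilibrium_set()) {
  if (any(conc < 0)) stop("concentrations must be non-negative")
  get0 <- function(nm) if (nm %in% names(conc)) unname(conc[[nm]]) else 0
  CH <- get0("H"); COH <- get0("OH")
  CP1 <- get0("P1"); CP2 <- get0("P2")
  r_phos <- eq$k1 * CP1 - eq$km1 * CP2 * CH   # net P1 -> P2 + H
  r_water <- eq$kd * eq$C_H2O - eq$kr * CH * COH
  r <- setNames(numeric(length(SPECIES)), SPECIES)
  r[["H"]] <- r_phos + r_water
  r[["OH"]] <- r_water
  r[["P1"]] <- -r_phos
  r[["P2"]] <- r_phos
  r
}

#' Electroneutral bulk composition from totals and pH
#'
#' Builds a full species vector for a compartment: `CH = 10^-pH`,
#' `COH = Kw/CH`, phosphate split by [speciate_phosphate()], `Cl- = C_NaCl`,
#' and Na+ chosen so that the charge balance `sum(z_i C_i) = 0` closes.
#'
#' @param Ptot total phosphate, mol L^-1.
#' @param C_NaCl sodium chloride background, mol L^-1 (sets Cl-).
#' @param pH compartment pH (concentration scale).
#' @param C_Ur,C_Crn urea and creatinine concentrations, mol L^-1.
#' @param eq an [equilibrium_set()].
#' @return named numeric vector over the canonical species order.
#' @examples
#' electroneutral_composition(Ptot = 2.9e-3, pH = 7.4)
#' @export
electroneutral_composition <- function(Ptot = 0, C_NaCl = 0, pH = 7.4,
                                       C_Ur = 0, C_Crn = 0,
                                       eq = equilibrium_set()) {
  stopifnot(pH > 0, pH < 14, Ptot >= 0, C_NaCl >= 0, C_Ur >= 0, C_Crn >= 0)
  CH <- 10^(-pH)
  COH <- eq$Kw / CH
  ph <- speciate_phosphate(Ptot, CH, eq$K)
  # sum(z C) = Na - Cl + H - OH - P1 - 2 P2 = 0
  CNa <- C_NaCl + COH + ph$P1 + 2 * ph$P2 - CH
  if (CNa < 0)
    stop("infeasible charge balance: required Na+ would be negative ",
         "(excess protons cannot be balanced without another cation)")
  c(Ur = C_Ur, Crn = C_Crn, P1 = ph$P1, P2 = ph$P2,
    Na = CNa, Cl = C_NaCl, H = CH, OH = COH)
}

#' Relax a composition to reaction equilibrium
#'
#' Finds the state reached by letting the phosphate and water reactions run
#' to completion with transport frozen. Conserves total phosphate, the
#' reaction invariant `CH - COH - CP2`, and (hence) charge; the result
#' satisfies `CH*COH = Kw` and `CP2*CH = K*CP1`.
#'
#' @param conc named species vector (mol L^-1) containing at least `H`, `OH`
#'   (and `P1`, `P2` when phosphate is present).
#' @param eq an [equilibrium_set()].
#' @return the input vector with `H`, `OH`, `P1`, `P2` replaced by their
#'   equilibrium values.
#' @export
equilibrate_composition <- function(conc, eq = equilibrium_set()) {
  stopifnot(all(c("H", "OH") %in% names(conc)))
  get0 <- function(nm) if (nm %in% names(conc)) unname(conc[[nm]]) else 0
  Ptot <- get0("P1") + get0("P2")
  Q <- conc[["H"]] - conc[["OH"]] - get0("P2")
  CH <- cpp_equilibrium_CH(Ptot, Q, eq$Kw, eq$K, conc[["H"]])
  out <- conc
  out[["H"]] <- CH
  out[["OH"]] <- eq$Kw / CH
  if ("P1" %in% names(conc)) {
    ph <- speciate_phosphate(Ptot, CH, eq$K)
    out[["P1"]] <- ph$P1
    out[["P2"]] <- ph$P2
  }
  out
}

# charge imbalance |sum z C| relative to sum |z| C, for diagnostics
charge_imbalance <- function(conc) {
  z <- SPECIES_Z[names(conc)]
  tot <- sum(abs(z) * conc)
  if (tot == 0) return(0)
  abs(sum(z * conc)) / tot
}
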