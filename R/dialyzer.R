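#' Diffusion boundary layer thickness for a hollow fiber
#'
#' Convective-diffusion estimate for a long narrow channel: the average DBL
#' thickness equals one third of the channel width, i.e. of the fiber inner
#' diameter. The same value is used on both sides of the membrane.
#'
#' @param dhf_um fiber inner diameter, micrometers.
#' @return DBL thickness, micrometers.
#' @export
dbl_thickness <- function(dhf_um) {
  if (any(dhf_um <= 0)) stop("dhf must be positive")
  dhf_um / 3
}

#' Effective membrane area of a fiber bundle
#'
#' `Smb = pi * dhf * Nhf * lhf` (inner lateral surface).
#'
#' @param dhf_um fiber inner diameter, micrometers.
#' @param Nhf number of fibers.
#' @param lhf_cm effective fiber length, cm.
#' @return membrane area, cm2.
#' @export
membrane_area <- function(dhf_um, Nhf, lhf_cm) {
  if (any(dhf_um <= 0) || any(lhf_cm <= 0) || any(Nhf < 0))
    stop("geometry values must be positive (Nhf >= 0)")
  pi * (dhf_um * 1e-4) * Nhf * lhf_cm
}

#' Fiber count from datasheet membrane area
#'
#' `Nhf = Smb / (pi dhf lhf)`, rounded to the nearest `round_to` fibers
#' (datasheet convention: nearest hundred).
#'
#' @param Smb_cm2 effective membrane area, cm2.
#' @param dhf_um fiber inner diameter, micrometers.
#' @param lhf_cm effective fiber length, cm.
#' @param round_to rounding granularity (default 100; use 1 for exact).
#' @return fiber count.
#' @export
fibers_from_area <- function(Smb_cm2, dhf_um, lhf_cm, round_to = 100) {
  if (any(Smb_cm2 <= 0)) stop("Smb must be positive")
  n <- Smb_cm2 / (pi * dhf_um * 1e-4 * lhf_cm)
  round(n / round_to) * round_to
}

#' Hollow-fiber dialyzer geometry
#'
#' Either the fiber count `Nhf` or the effective membrane area `Smb_cm2`
#' must be given; the other is completed from
#' `Smb = pi dhf Nhf lhf`. The DBL thickness defaults to the `dhf/3` rule
#' ([dbl_thickness()]); an explicit `delta_um` overrides it.
#'
#' @param dhf_um fiber inner diameter, micrometers.
#' @param lhf_cm effective fiber length, cm.
#' @param d_um membrane (fiber wall) thickness, micrometers.
#' @param Nhf fiber count (optional if `Smb_cm2` given).
#' @param Smb_cm2 effective membrane area, cm2 (optional if `Nhf` given).
#' @param delta_um DBL thickness, micrometers (optional; `dhf/3` rule when
#'   unset).
#' @return object of class `dialyzer_spec`.
#' @examples
#' dialyzer_spec(dhf_um = 190, lhf_cm = 15, d_um = 140, Nhf = 90)  # lab unit
#' @export
dialyzer_spec <- function(dhf_um, lhf_cm, d_um, Nhf = NULL, Smb_cm2 = NULL,
                          delta_um = NULL) {
  stopifnot(dhf_um > 0, lhf_cm > 0, d_um > 0)
  if (is.null(Nhf) && is.null(Smb_cm2))
    stop("give Nhf or Smb_cm2")
  if (is.null(Nhf))
    Nhf <- fibers_from_area(Smb_cm2, dhf_um, lhf_cm, round_to = 100)
  if (Nhf < 1) stop("Nhf must be >= 1")
  S_geom <- membrane_area(dhf_um, Nhf, lhf_cm)
  if (!is.null(Smb_cm2) && abs(S_geom / Smb_cm2 - 1) > 0.02)
    warning(sprintf("Smb from geometry (%.1f cm2) differs from supplied %.1f cm2",
                    S_geom, Smb_cm2))
  if (is.null(delta_um)) delta_um <- dbl_thickness(dhf_um)
  stopifnot(delta_um > 0)
  structure(list(dhf_um = dhf_um, lhf_cm = lhf_cm, d_um = d_um,
                 Nhf = Nhf, Smb_cm2 = S_geom, delta_um = delta_um),
            class = "dialyzer_spec")
}

#' @export
print.dialyzer_spec <- function(x, ...) {
  cat(sprintf(paste0("Dialyzer: %d fibers, dhf %.0f um, wall %.1f um, ",
                     "length %.1f cm\n  Smb %.1f cm2, DBL %.1f um\n"),
              x$Nhf, x$dhf_um, x$d_um, x$lhf_cm, x$Smb_cm2, x$delta_um))
  invisible(x)
}

#' Operating conditions of a dialysis run
#'
#' Counter-current operation requires `0 <= QA < QB`.
#'
#' @param QA_ml_min blood-side (diluate) flow rate, mL min^-1.
#' @param QB_ml_min dialysate flow rate, mL min^-1.
#' @param temperature_C working temperature, degrees Celsius.
#' @return object of class `operating_conditions`.
#' @export
operating_conditions <- function(QA_ml_min, QB_ml_min, temperature_C = 37) {
  if (!(QA_ml_min >= 0 && QA_ml_min < QB_ml_min))
    stop("counter-current clearance requires 0 <= QA < QB")
  structure(list(QA_ml_min = QA_ml_min, QB_ml_min = QB_ml_min,
                 temperature_C = temperature_C),
            class = "operating_conditions")
}

#' Counter-current clearance from the mass-transfer coefficient
#'
#' `CL = QA (1 - e^{theta L}) / (1 - (QA/QB) e^{theta L})` with
#' `theta = -pi dhf Nhf lhf (1 - QA/QB) / QA = -Smb (1 - QA/QB) / QA`.
#' Flows are converted to cm3 s^-1 internally; the result is in mL min^-1
#' and always lies in `[0, QA]`, increasing in `L`.
#'
#' @param L mass-transfer coefficient, cm s^-1 (vectorized).
#' @param spec a [dialyzer_spec()].
#' @param ops an [operating_conditions()] (`QA > 0`, `QA < QB`).
#' @return clearance, mL min^-1.
#' @export
clearance_from_L <- function(L, spec, ops) {
  if (any(L < 0)) stop("L must be non-negative")
  QA <- ops$QA_ml_min / 60   # cm3 s^-1
  QB <- ops$QB_ml_min / 60
  if (QA == 0) return(rep(0, length(L)))
  theta <- -spec$Smb_cm2 * (1 - QA / QB) / QA   # s cm^-1
  e <- exp(theta * L)
  cl <- QA * (1 - e) / (1 - (QA / QB) * e)
  cl * 60
}

#' Experimental clearance from outlet concentration
#'
#' `CL = QA (1 - C_out/C_in)`.
#'
#' @param QA_ml_min diluate flow rate, mL min^-1.
#' @param C_out,C_in outlet and inlet solute concentrations (same units,
#'   `0 <= C_out <= C_in`, `C_in > 0`).
#' @return clearance, mL min^-1.
#' @export
clearance_from_outlet <- function(QA_ml_min, C_out, C_in) {
  if (any(C_in <= 0)) stop("C_in must be positive")
  if (any(C_out < 0) || any(C_out > C_in))
    stop("data error: C_out must lie in [0, C_in]")
  QA_ml_min * (1 - C_out / C_in)
}

# default feed totals (mol/L): typical uremic plasma levels used throughout
feed_defaults <- function() {
  c(Ur = 1.67e-2, Crn = 8.85e-4, Ptot = 2.9e-3)
}

# speciation-weighted aqueous diffusivity of a solute; for total phosphate
# the two anion diffusivities are weighted by their equilibrium fractions
# at the given pH
effective_solute_D <- function(solute, sp, pH = 7.4,
                               eq = equilibrium_set()) {
  Dv <- setNames(sp$D_cm2_s, sp$species)
  if (solute %in% c("Ur", "Crn")) return(Dv[[solute]])
  if (solute == "Ptot") {
    frac <- speciate_phosphate(1, 10^(-pH), eq$K)
    return(frac$P1 * Dv[["P1"]] + frac$P2 * Dv[["P2"]])
  }
  if (solute %in% names(Dv)) return(Dv[[solute]])
  stop("unknown solute: ", solute)
}

#' Simulate dialyzer clearance from the membrane structure
#'
#' End-to-end pipeline: builds the DBL | membrane | DBL stack (tortuosity
#' from the membrane structure, DBL from the spec), runs the transient
#' transport solver to a quasi-steady state for each requested solute,
#' converts the mid-membrane flux to a mass-transfer coefficient and then to
#' the counter-current clearance.
#'
#' Solutes are dialyzed as individual solutions, as in a lab
#' characterization: neutral solutes (`Ur`, `Crn`) with no salt background
#' are transport-decoupled from the ionic subsystem and run with a
#' single-species state; total phosphate (`Ptot`) runs the coupled
#' electro-diffusion-reaction system (both anions, Na+, H+, OH-, and Cl-
#' when a NaCl background is present).
#'
#' @param membrane a [membrane_structure()] (or list with `xi`).
#' @param spec a [dialyzer_spec()].
#' @param ops an [operating_conditions()].
#' @param solutes character subset of `c("Ur", "Crn", "Ptot")`.
#' @param feed named feed totals, mol L^-1 (defaults: urea 1.67e-2,
#'   creatinine 8.85e-4, total phosphate 2.9e-3).
#' @param config a [solver_config()].
#' @param eq an [equilibrium_set()].
#' @param pH_A feed pH (default 7.4, physiological).
#' @param pH_B dialysate pH (default 7.0, deionized water).
#' @param C_NaCl_A,C_NaCl_B NaCl background in each compartment, mol L^-1.
#' @param dialyzer_id label copied into the output records.
#' @return data.frame of clearance records: one row per solute with the
#'   mass-transfer coefficient `L_cm_s`, clearance `CL_ml_min`, geometry and
#'   flow columns, convergence diagnostics, and `source = "simulated"`.
#' @export
simulate_clearance <- function(membrane, spec, ops,
                               solutes = c("Ur", "Crn", "Ptot"),
                               feed = feed_defaults(),
                               config = solver_config(),
                               eq = equilibrium_set(),
                               pH_A = 7.4, pH_B = 7.0,
                               C_NaCl_A = 0, C_NaCl_B = 0,
                               dialyzer_id = "dialyzer") {
  solutes <- match.arg(solutes, c("Ur", "Crn", "Ptot"),
                       several.ok = TRUE)
  stopifnot(all(solutes %in% names(feed)))
  sp_full <- species_table(ops$temperature_C)
  stack <- layer_stack(spec$delta_um * 1e-4, spec$d_um * 1e-4,
                       membrane$xi, config$nodes_per_layer)
  rows <- lapply(solutes, function(sol) {
    neutral <- sol %in% c("Ur", "Crn")
    if (neutral && C_NaCl_A == 0 && C_NaCl_B == 0) {
      keep <- sol
      bA <- setNames(feed[[sol]], sol)
      bB <- setNames(0, sol)
    } else {
      keep <- c(if (neutral) sol, "P1", "P2", "Na", "H", "OH",
                if (C_NaCl_A > 0 || C_NaCl_B > 0) "Cl")
      compA <- electroneutral_composition(
        Ptot = if (sol == "Ptot") feed[["Ptot"]] else 0,
        C_NaCl = C_NaCl_A, pH = pH_A,
        C_Ur = if (sol == "Ur") feed[["Ur"]] else 0,
        C_Crn = if (sol == "Crn") feed[["Crn"]] else 0, eq = eq)
      compB <- electroneutral_composition(Ptot = 0, C_NaCl = C_NaCl_B,
                                          pH = pH_B, eq = eq)
      bA <- compA[keep]
      bB <- compB[keep]
    }
    spi <- sp_full[match(keep, sp_full$species), , drop = FALSE]
    res <- run_to_quasi_steady(stack, spi, bA, bB, eq = eq,
                               config = config)
    if (sol == "Ptot") {
      J <- res$J_mid[["P1"]] + res$J_mid[["P2"]]
      dC <- feed[["Ptot"]] - 0
    } else {
      J <- res$J_mid[[sol]]
      dC <- feed[[sol]] - 0
    }
    L <- mass_transfer_coefficient(J, dC, 0)
    CL <- clearance_from_L(max(L, 0), spec, ops)
    data.frame(dialyzer_id = dialyzer_id, solute = sol,
               QA_ml_min = ops$QA_ml_min, QB_ml_min = ops$QB_ml_min,
               Smb_cm2 = spec$Smb_cm2, L_cm_s = L, CL_ml_min = CL,
               converged = res$converged, t_elapsed_s = res$t,
               max_charge_imbalance = res$max_charge_imbalance,
               source = "simulated", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# fast forward clearance: series-resistance L + counter-current formula.
# Legitimate for neutral solutes; for total phosphate it uses the
# speciation-weighted diffusivity (documented approximation).
fast_clearance <- function(xi, spec, ops, solute,
                           sp = species_table(ops$temperature_C),
                           pH = 7.4, eq = equilibrium_set()) {
  D <- effective_solute_D(solute, sp, pH = pH, eq = eq)
  L <- series_resistance_L(D, spec$delta_um * 1e-4, spec$d_um * 1e-4, xi)
  clearance_from_L(L, spec, ops)
}

#' Read / write clearance record tables
#'
#' CSV columns: `dialyzer_id, solute, QA_ml_min, QB_ml_min, Smb_cm2,
#' CL_ml_min, source`.
#'
#' @param path file path.
#' @return data.frame of records.
#' @export
read_clearance_records <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("dialyzer_id", "solute", "QA_ml_min", "QB_ml_min", "Smb_cm2",
            "CL_ml_min")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("clearance record file lacks columns: ",
         paste(miss, collapse = ", "))
  bad <- df$CL_ml_min < 0 | df$CL_ml_min > df$QA_ml_min
  if (any(bad))
    stop("invalid records: clearance outside [0, QA] in rows ",
         paste(which(bad), collapse = ", "))
  df
}

#' @rdname read_clearance_records
#' @param df data.frame of records to write.
#' @export
write_clearance_records <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
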