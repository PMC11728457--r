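#' Synthetic permeability-versus-concentration dataset
#'
#' Emulates a diffusion-permeability characterization of one membrane:
#' `P(C) = fp^(1/alpha) * Ds(C) * exp(eps)` with
#' `eps ~ Normal(0, noise_cv)` i.i.d. (multiplicative lognormal error --
#' relative measurement noise, strictly positive values). Pure function of
#' its arguments and the seed.
#'
#' @param fp,alpha generating structural parameters.
#' @param C_grid NaCl concentrations, mol L^-1 (default: the standard
#'   four-point characterization grid 0.10, 0.25, 0.50, 0.75).
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   (0 = exact model values).
#' @param seed mandatory integer seed.
#' @param Ds_of_C see [fit_alpha()].
#' @return data.frame with columns `C_NaCl_mol_L`, `P_cm2_s` and attribute
#'   `truth` (list of generating parameters).
#' @export
synth_permeability <- function(fp, alpha, C_grid = c(0.10, 0.25, 0.50, 0.75),
                               noise_cv = 0, seed, Ds_of_C = NULL) {
  if (missing(seed)) stop("seed is required")
  stopifnot(noise_cv >= 0, length(C_grid) >= 1)
  Dsf <- as_Ds_of_C(Ds_of_C)
  P0 <- diffusion_permeability(fp, alpha, Dsf(C_grid))
  eps <- if (noise_cv > 0)
    with_seed(seed, stats::rnorm(length(C_grid), 0, noise_cv))
  else rep(0, length(C_grid))
  out <- data.frame(C_NaCl_mol_L = C_grid, P_cm2_s = P0 * exp(eps))
  attr(out, "truth") <- list(fp = fp, alpha = alpha, noise_cv = noise_cv,
                             seed = seed)
  out
}

#' Synthetic datasheet-style clearance records
#'
#' Emulates a manufacturer's clearance table for one membrane family:
#' clearance from the series-resistance forward model at tortuosity `xi`
#' over a grid of membrane areas, blood-side flow rates and solutes, with
#' multiplicative lognormal noise. Records are clipped to the physical
#' range `[0, QA]`; clipped rows are flagged in the `clipped` column.
#'
#' @param xi generating tortuosity coefficient.
#' @param geometry list/row with `delta_um`, `dhf_um`, `lhf_cm`, `d_um`.
#' @param Smb_m2 membrane areas, m2.
#' @param QA_ml_min blood-side flow rates, mL min^-1.
#' @param QB_ml_min dialysate flow rate, mL min^-1 (scalar).
#' @param solutes subset of `c("Ur", "Crn", "Ptot")`.
#' @param noise_cv relative measurement error (datasheet convention ~0.1).
#' @param seed mandatory integer seed.
#' @param sp species table at the working temperature.
#' @return data.frame of clearance records (`source = "synthetic"`).
#' @export
synth_clearance <- function(xi, geometry, Smb_m2 = c(1.0, 1.4, 1.8),
                            QA_ml_min = c(200, 300, 400), QB_ml_min = 500,
                            solutes = c("Ur", "Crn", "Ptot"),
                            noise_cv = 0, seed, sp = species_table(37)) {
  if (missing(seed)) stop("seed is required")
  stopifnot(noise_cv >= 0, xi > 0, xi <= 1)
  geometry <- as.list(geometry)
  grid <- expand.grid(Smb_m2 = Smb_m2, QA_ml_min = QA_ml_min,
                      solute = solutes, stringsAsFactors = FALSE)
  cl0 <- vapply(seq_len(nrow(grid)), function(i) {
    spec <- dialyzer_spec(dhf_um = geometry$dhf_um,
                          lhf_cm = geometry$lhf_cm, d_um = geometry$d_um,
                          Smb_cm2 = grid$Smb_m2[i] * 1e4,
                          delta_um = geometry$delta_um)
    ops <- operating_conditions(grid$QA_ml_min[i], QB_ml_min)
    fast_clearance(xi, spec, ops, grid$solute[i], sp = sp)
  }, numeric(1))
  eps <- if (noise_cv > 0)
    with_seed(seed, stats::rnorm(nrow(grid), 0, noise_cv))
  else rep(0, nrow(grid))
  cl <- cl0 * exp(eps)
  clipped <- cl > grid$QA_ml_min | cl < 0
  cl <- pmin(pmax(cl, 0), grid$QA_ml_min)
  out <- data.frame(dialyzer_id = sprintf("synthetic_%.1fm2", grid$Smb_m2),
                    solute = grid$solute,
                    QA_ml_min = grid$QA_ml_min, QB_ml_min = QB_ml_min,
                    Smb_cm2 = grid$Smb_m2 * 1e4,
                    CL_ml_min = cl, clipped = clipped,
                    source = "synthetic", stringsAsFactors = FALSE)
  attr(out, "truth") <- list(xi = xi, noise_cv = noise_cv, seed = seed)
  out
}
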