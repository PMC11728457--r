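#' Water mass fraction of a swollen membrane
#'
#' `W = (m_swollen - m_dry) / m_swollen`.
#'
#' @param m_swollen,m_dry sample masses in the swollen and dry state, g.
#' @return water mass fraction in `[0, 1)`.
#' @export
water_content <- function(m_swollen, m_dry) {
  if (any(m_dry <= 0)) stop("m_dry must be positive")
  if (any(m_dry > m_swollen))
    stop("measurement error: dry mass exceeds swollen mass")
  (m_swollen - m_dry) / m_swollen
}

#' Volume fraction of pores from water content
#'
#' `fp = rho * W / (1 + (rho - 1) * W)` where `rho` is the density of the
#' polymer (g cm^-3). The default 1.24 g cm^-3 is the standard polysulfone
#' density.
#'
#' @param W water mass fraction, in `[0, 1)`.
#' @param rho polymer density, g cm^-3.
#' @return porosity in `[0, 1]`.
#' @export
porosity_from_water_content <- function(W, rho = 1.24) {
  if (any(W < 0 | W >= 1)) stop("W must be in [0, 1)")
  if (any(rho <= 0)) stop("rho must be positive")
  rho * W / (1 + (rho - 1) * W)
}

#' Tortuosity coefficient from porosity and pore arrangement
#'
#' `xi = fp^(1/alpha)`. `alpha = 1` corresponds to pores parallel to the
#' transport axis (`xi = fp`); `alpha -> 0` to a random arrangement
#' (`xi -> 0` for `fp < 1`).
#'
#' @param fp porosity, in `(0, 1]`.
#' @param alpha pore-arrangement parameter, in `(0, 1]`.
#' @return tortuosity coefficient `xi <= fp`.
#' @export
tortuosity_coefficient <- function(fp, alpha) {
  if (any(fp <= 0 | fp > 1)) stop("fp must be in (0, 1]")
  if (any(alpha <= 0 | alpha > 1)) stop("alpha must be in (0, 1]")
  fp^(1 / alpha)
}

#' Pore-arrangement parameter from porosity and tortuosity coefficient
#'
#' `alpha = log(fp) / log(xi)` (any logarithm base; the ratio is base-free).
#'
#' @param fp porosity, strictly inside `(0, 1)`.
#' @param xi tortuosity coefficient, strictly inside `(0, 1)`, `xi <= fp`.
#' @return pore-arrangement parameter in `(0, 1]`.
#' @export
alpha_from_porosity_and_xi <- function(fp, xi) {
  if (any(fp <= 0 | fp >= 1))
    stop("alpha is undefined unless 0 < fp < 1")
  if (any(xi <= 0 | xi >= 1))
    stop("alpha is undefined unless 0 < xi < 1")
  if (any(xi > fp)) stop("xi must not exceed fp")
  log(fp) / log(xi)
}

#' Membrane diffusion permeability from structure
#'
#' `P = fp^(1/alpha) * Ds = xi * Ds`, the microheterogeneous
#' structure-property relation for a single-conducting-phase, non-charged
#' membrane. `P <= fp * Ds <= Ds` always.
#'
#' @inheritParams tortuosity_coefficient
#' @param Ds solution diffusion coefficient, cm2 s^-1.
#' @return diffusion permeability coefficient, cm2 s^-1.
#' @export
diffusion_permeability <- function(fp, alpha, Ds) {
  if (any(Ds <= 0)) stop("Ds must be positive")
  tortuosity_coefficient(fp, alpha) * Ds
}

#' Mutual diffusion coefficient of an NaCl solution at infinite dilution
#'
#' Harmonic mean of the two ionic limiting diffusivities,
#' `Ds = 2 D_Na D_Cl / (D_Na + D_Cl)`; 1.61e-5 cm2 s^-1 at 25 C with the
#' standard limiting values.
#'
#' @param D_Na,D_Cl ionic diffusion coefficients, cm2 s^-1.
#' @return solution diffusion coefficient, cm2 s^-1.
#' @export
nacl_solution_diffusivity <- function(D_Na = SPECIES_D25[["Na"]],
                                      D_Cl = SPECIES_D25[["Cl"]]) {
  stopifnot(D_Na > 0, D_Cl > 0)
  2 * D_Na * D_Cl / (D_Na + D_Cl)
}

#' NaCl mutual diffusion coefficient as a function of concentration
#'
#' Linear interpolation of tabulated literature values at 25 C. Used as the
#' default concentration mapping when fitting the pore-arrangement parameter
#' to permeability-versus-concentration data; the shallow minimum near
#' 0.3-0.5 mol/L is the classical behavior of aqueous NaCl.
#'
#' @param C NaCl concentration, mol L^-1 (vectorized). Values outside the
#'   table range take the nearest tabulated value.
#' @return diffusion coefficient, cm2 s^-1.
#' @export
nacl_mutual_diffusivity <- function(C) {
  tab_C <- c(0, 0.05, 0.1, 0.25, 0.5, 0.75, 1.0, 1.5, 2.0)
  tab_D <- c(1.610, 1.507, 1.483, 1.475, 1.474, 1.478, 1.484, 1.495,
             1.516) * 1e-5
  approx(tab_C, tab_D, xout = C, rule = 2)$y
}

#' Membrane structure descriptor
#'
#' Completes a consistent set of structural parameters from any sufficient
#' subset: water content `W` (with polymer density `rho`) determines the
#' porosity `fp`; any two of (`fp`, `alpha`, `xi`) determine the third
#' through `xi = fp^(1/alpha)`.
#'
#' @param W water mass fraction (optional).
#' @param rho polymer density, g cm^-3 (default polysulfone).
#' @param fp porosity (optional if `W` given).
#' @param alpha pore-arrangement parameter (optional if `xi` given).
#' @param xi tortuosity coefficient (optional if `alpha` given).
#' @return object of class `membrane_structure`: list with fields `W`,
#'   `rho`, `fp`, `alpha`, `xi` (W may be `NA` when not supplied).
#' @examples
#' membrane_structure(W = 0.74)               # fp from water content
#' membrane_structure(fp = 0.8, alpha = 0.05) # lab reference membrane
#' @export
membrane_structure <- function(W = NULL, rho = 1.24, fp = NULL,
                               alpha = NULL, xi = NULL) {
  if (is.null(fp)) {
    if (!is.null(W)) fp <- porosity_from_water_content(W, rho)
    else if (!is.null(alpha) && !is.null(xi)) fp <- xi^alpha
  }
  if (is.null(fp))
    stop("insufficient inputs: need W (+rho), fp, or alpha + xi")
  if (is.null(xi) && !is.null(alpha))
    xi <- tortuosity_coefficient(fp, alpha)
  if (is.null(alpha) && !is.null(xi))
    alpha <- alpha_from_porosity_and_xi(fp, xi)
  if (is.null(alpha)) {
    # porosity-only descriptor: transport-related fields stay unset
    alpha <- NA_real_
    xi <- NA_real_
  } else {
    xi_chk <- tortuosity_coefficient(fp, alpha)
    if (abs(xi - xi_chk) > 0.02 * xi_chk)
      warning(sprintf(paste0("supplied (fp, alpha, xi) disagree by %.1f%%; ",
                             "keeping xi = %.4g"),
                      100 * abs(xi / xi_chk - 1), xi))
  }
  structure(list(W = if (is.null(W)) NA_real_ else W, rho = rho,
                 fp = fp, alpha = alpha, xi = xi),
            class = "membrane_structure")
}

#' @export
print.membrane_structure <- function(x, ...) {
  cat("Membrane structure\n")
  if (!is.na(x$W))
    cat(sprintf("  water content W: %.3f (rho = %.3g g/cm3)\n", x$W, x$rho))
  cat(sprintf("  porosity fp:        %.3f\n", x$fp))
  cat(sprintf("  pore arrangement a: %.4f\n", x$alpha))
  cat(sprintf("  tortuosity coef xi: %.4g\n", x$xi))
  invisible(x)
}

#' Read / write a membrane characterization table
#'
#' CSV with columns `membrane_id, W, rho, fp, alpha, xi` and optionally
#' `P_cm2_s, C_NaCl_mol_L`. Missing structural columns are completed row by
#' row through [membrane_structure()] when possible.
#'
#' @param path file path.
#' @param complete complete missing fp/alpha/xi columns where derivable.
#' @return data.frame.
#' @export
read_membrane_table <- function(path, complete = TRUE) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"membrane_id" %in% names(df))
    stop("membrane table needs a membrane_id column")
  if (complete) {
    for (col in c("W", "rho", "fp", "alpha", "xi"))
      if (!col %in% names(df)) df[[col]] <- NA_real_
    for (i in seq_len(nrow(df))) {
      ms <- tryCatch(
        membrane_structure(
          W = if (is.na(df$W[i])) NULL else df$W[i],
          rho = if (is.na(df$rho[i])) 1.24 else df$rho[i],
          fp = if (is.na(df$fp[i])) NULL else df$fp[i],
          alpha = if (is.na(df$alpha[i])) NULL else df$alpha[i],
          xi = if (is.na(df$xi[i])) NULL else df$xi[i]),
        error = function(e) NULL)
      if (!is.null(ms)) {
        df$fp[i] <- ms$fp; df$alpha[i] <- ms$alpha; df$xi[i] <- ms$xi
        if (is.na(df$rho[i])) df$rho[i] <- ms$rho
      }
    }
  }
  df
}

#' @rdname read_membrane_table
#' @param df data.frame to write.
#' @export
write_membrane_table <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
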