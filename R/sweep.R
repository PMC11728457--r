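#' One-parameter clearance sweep
#'
#' Varies a single geometric or structural parameter over a grid, holding
#' everything else at the base configuration, and records the simulated
#' clearance at each grid point. The membrane area is deliberately not held
#' constant: each parameter's effect is taken independently.
#'
#' For `Nhf` and `lhf_cm` the 1-D transport problem is unchanged, so the
#' quasi-steady mass-transfer coefficient is computed once and only the
#' counter-current formula is re-evaluated per grid point; all other
#' parameters trigger a full solver run per point.
#'
#' @param param one of `"lhf_cm"`, `"dhf_um"`, `"d_um"`, `"Nhf"`,
#'   `"delta_um"`, `"fp"`, `"alpha"`.
#' @param values numeric grid for the parameter.
#' @param membrane base [membrane_structure()].
#' @param spec base [dialyzer_spec()].
#' @param ops an [operating_conditions()].
#' @param solute single solute (default `"Ur"`).
#' @param config a [solver_config()].
#' @param delta_rule when sweeping `dhf_um`, recompute the DBL thickness by
#'   the `dhf/3` rule (default TRUE) instead of keeping the base value.
#' @param ... further arguments passed to [simulate_clearance()].
#' @return tidy data.frame: one row per grid point with `param`, `value`,
#'   `L_cm_s`, `CL_ml_min`.
#' @export
sweep_clearance <- function(param = c("lhf_cm", "dhf_um", "d_um", "Nhf",
                                      "delta_um", "fp", "alpha"),
                            values, membrane, spec, ops, solute = "Ur",
                            config = solver_config(), delta_rule = TRUE,
                            ...) {
  param <- match.arg(param)
  stopifnot(length(values) >= 1)

  build <- function(v) {
    m <- membrane
    delta <- spec$delta_um
    dhf <- spec$dhf_um; lhf <- spec$lhf_cm; d <- spec$d_um
    Nhf <- spec$Nhf
    switch(param,
           lhf_cm = { lhf <- v },
           dhf_um = { dhf <- v
                      if (delta_rule) delta <- dbl_thickness(v) },
           d_um = { d <- v },
           Nhf = { Nhf <- v },
           delta_um = { delta <- v },
           fp = { m <- membrane_structure(fp = v, alpha = membrane$alpha) },
           alpha = { m <- membrane_structure(fp = membrane$fp, alpha = v) })
    list(membrane = m,
         spec = dialyzer_spec(dhf_um = dhf, lhf_cm = lhf, d_um = d,
                              Nhf = Nhf, delta_um = delta))
  }

  reuse_L <- param %in% c("Nhf", "lhf_cm")
  L_base <- NULL
  if (reuse_L) {
    base <- simulate_clearance(membrane, spec, ops, solutes = solute,
                               config = config, ...)
    L_base <- base$L_cm_s
  }
  rows <- lapply(values, function(v) {
    cfg <- build(v)
    if (reuse_L) {
      CL <- clearance_from_L(L_base, cfg$spec, ops)
      data.frame(param = param, value = v, L_cm_s = L_base,
                 CL_ml_min = CL, stringsAsFactors = FALSE)
    } else {
      rec <- simulate_clearance(cfg$membrane, cfg$spec, ops,
                                solutes = solute, config = config, ...)
      data.frame(param = param, value = v, L_cm_s = rec$L_cm_s,
                 CL_ml_min = rec$CL_ml_min, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
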