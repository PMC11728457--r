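#' Fit result container
#'
#' @param parameter name of the fitted parameter ("alpha" or "xi").
#' @param estimate fitted value.
#' @param rss residual sum of squares at the optimum.
#' @param residuals data.frame of per-point residuals.
#' @param trace data.frame of objective evaluations (par, rss).
#' @return object of class `fit_result`.
#' @keywords internal
fit_result <- function(parameter, estimate, rss, residuals, trace) {
  structure(list(parameter = parameter, estimate = estimate, rss = rss,
                 residuals = residuals, n_obs = nrow(residuals),
                 trace = trace),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Fit of %s: estimate = %.6g (RSS = %.4g over %d points, %d objective evaluations)\n",
              x$parameter, x$estimate, x$rss, x$n_obs, nrow(x$trace)))
  invisible(x)
}

# normalize the Ds(C) argument: NULL -> literature NaCl table, scalar ->
# constant, function -> as-is
as_Ds_of_C <- function(Ds_of_C) {
  if (is.null(Ds_of_C)) return(nacl_mutual_diffusivity)
  if (is.function(Ds_of_C)) return(Ds_of_C)
  if (is.numeric(Ds_of_C) && length(Ds_of_C) == 1) {
    force(Ds_of_C)
    return(function(C) rep(Ds_of_C, length(C)))
  }
  stop("Ds_of_C must be NULL, a scalar, or a function of concentration")
}

#' Fit the pore-arrangement parameter to permeability data
#'
#' Least squares in log space (permeability spans orders of magnitude) for
#' the structure-property relation `P(C) = fp^(1/alpha) * Ds(C)`:
#' `alpha = argmin sum (log P_model - log P_obs)^2` over `(0, 1]` by
#' bounded derivative-free scalar minimization.
#'
#' @param data data.frame with columns `C_NaCl_mol_L` and `P_cm2_s`
#'   (positive, at least one row).
#' @param fp known membrane porosity, in `(0, 1)`.
#' @param Ds_of_C solution diffusivity versus concentration: `NULL`
#'   (default, interpolated literature NaCl values at 25 C), a scalar, or a
#'   function of concentration.
#' @param tol parameter tolerance of the optimizer.
#' @return a `fit_result` with the estimated `alpha`, RSS, per-point
#'   residuals, and the optimizer's evaluation trace.
#' @export
fit_alpha <- function(data, fp, Ds_of_C = NULL, tol = 1e-6) {
  stopifnot(is.data.frame(data), nrow(data) >= 1,
            all(c("C_NaCl_mol_L", "P_cm2_s") %in% names(data)))
  if (any(data$P_cm2_s <= 0) || any(data$C_NaCl_mol_L < 0))
    stop("permeability data must be positive")
  if (fp <= 0 || fp >= 1) stop("fp must be in (0, 1)")
  Dsf <- as_Ds_of_C(Ds_of_C)
  Ds <- Dsf(data$C_NaCl_mol_L)
  if (all(data$P_cm2_s >= Ds))
    stop("no admissible alpha: observed permeability exceeds the solution ",
         "diffusivity at every concentration")
  logratio <- log(data$P_cm2_s / Ds)
  trace_env <- new.env()
  trace_env$par <- numeric(0)
  trace_env$rss <- numeric(0)
  obj <- function(a) {
    r <- sum(((1 / a) * log(fp) - logratio)^2)
    trace_env$par <- c(trace_env$par, a)
    trace_env$rss <- c(trace_env$rss, r)
    r
  }
  opt <- optimize(obj, interval = c(1e-6, 1), tol = tol)
  a_hat <- opt$minimum
  # interior refinement: the log-residual is linear in 1/alpha, so the
  # exact stationary point is available in closed form; keep it when it
  # lies inside the admissible interval and improves the objective
  u_star <- mean(logratio) / log(fp)
  if (u_star >= 1) {
    a_cf <- 1 / u_star
    if (obj(a_cf) <= opt$objective) a_hat <- a_cf
  }
  res <- data.frame(C_NaCl_mol_L = data$C_NaCl_mol_L,
                    P_obs = data$P_cm2_s,
                    P_fit = tortuosity_coefficient(fp, a_hat) * Ds)
  res$log_residual <- log(res$P_obs) - log(res$P_fit)
  fit_result("alpha", a_hat, sum(res$log_residual^2), res,
             data.frame(par = trace_env$par, rss = trace_env$rss))
}

#' Fit the tortuosity coefficient to clearance records
#'
#' One `xi` is fitted jointly across all records (solutes, membrane areas
#' and flow rates) of a dialyzer family by minimizing
#' `sum (CL_sim(xi) - CL_obs)^2` over `(0, 1)` with bounded scalar
#' minimization (linear loss: clearance spans at most a decade).
#'
#' @param records data.frame of clearance records (`dialyzer_id, solute,
#'   QA_ml_min, QB_ml_min, Smb_cm2, CL_ml_min`).
#' @param geometry single-row data.frame or list with the shared fiber
#'   geometry: `delta_um`, `dhf_um`, `lhf_cm`, `d_um` (the fiber count per
#'   record is resolved from each record's `Smb_cm2`).
#' @param method `"fast"` (default): series-resistance forward model --
#'   exact for neutral solutes, speciation-weighted diffusivity for total
#'   phosphate; `"simulate"`: full transport solver per record per trial
#'   `xi` (slow, for final verification).
#' @param sp species table at the working temperature.
#' @param config solver configuration for `method = "simulate"`.
#' @param tol parameter tolerance of the optimizer.
#' @return a `fit_result` with the estimated `xi`.
#' @export
fit_xi <- function(records, geometry, method = c("fast", "simulate"),
                   sp = species_table(37), config = solver_config(),
                   tol = 1e-6) {
  method <- match.arg(method)
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  # records at the physical extraction bound CL = QA are censored (the
  # counter-current model only reaches QA in the infinite-L limit); keeping
  # them would bias the fit upward, so they are dropped with a message
  at_bound <- records$CL_ml_min >= records$QA_ml_min * (1 - 1e-9)
  if (any(at_bound)) {
    message(sum(at_bound), " record(s) at the CL = QA bound excluded ",
            "from the fit (censored)")
    records <- records[!at_bound, , drop = FALSE]
    if (nrow(records) == 0)
      stop("no informative records left: all clearances sit at the ",
           "extraction bound")
  }
  geometry <- as.list(geometry)
  need <- c("delta_um", "dhf_um", "lhf_cm", "d_um")
  if (!all(need %in% names(geometry)))
    stop("geometry needs fields: ", paste(need, collapse = ", "))

  specs <- lapply(seq_len(nrow(records)), function(i)
    dialyzer_spec(dhf_um = geometry$dhf_um, lhf_cm = geometry$lhf_cm,
                  d_um = geometry$d_um, Smb_cm2 = records$Smb_cm2[i],
                  delta_um = geometry$delta_um))
  opsl <- lapply(seq_len(nrow(records)), function(i)
    operating_conditions(records$QA_ml_min[i], records$QB_ml_min[i]))

  predict_cl <- function(xi) {
    vapply(seq_len(nrow(records)), function(i) {
      if (method == "fast")
        fast_clearance(xi, specs[[i]], opsl[[i]], records$solute[i],
                       sp = sp)
      else
        simulate_clearance(list(xi = xi), specs[[i]], opsl[[i]],
                           solutes = records$solute[i],
                           config = config)$CL_ml_min
    }, numeric(1))
  }

  trace_env <- new.env()
  trace_env$par <- numeric(0)
  trace_env$rss <- numeric(0)
  obj <- function(xi) {
    r <- tryCatch(sum((predict_cl(xi) - records$CL_ml_min)^2),
                  error = function(e) 1e12)   # reject failed trials
    trace_env$par <- c(trace_env$par, xi)
    trace_env$rss <- c(trace_env$rss, r)
    r
  }
  opt <- optimize(obj, interval = c(1e-4, 1 - 1e-9), tol = tol)
  cl_fit <- predict_cl(opt$minimum)
  res <- data.frame(records[c("dialyzer_id", "solute", "QA_ml_min",
                              "Smb_cm2")],
                    CL_obs = records$CL_ml_min, CL_fit = cl_fit,
                    residual = records$CL_ml_min - cl_fit)
  fit_result("xi", opt$minimum, sum(res$residual^2), res,
             data.frame(par = trace_env$par, rss = trace_env$rss))
}

#' Porosity / pore-arrangement trade-off at fixed tortuosity
#'
#' A given tortuosity coefficient can be realized by many `(fp, alpha)`
#' pairs: `alpha(fp) = log(fp) / log(xi)`. The curve falls from `alpha = 1`
#' at `fp = xi` toward 0 as `fp` approaches 1: at fixed tortuosity, a more
#' porous membrane must have a less ordered pore arrangement. Grid points
#' with `fp <= xi` are excluded (they would need `alpha > 1`).
#'
#' @param xi tortuosity coefficient, in `(0, 1)`.
#' @param fp_grid porosity grid, inside `(xi, 1)`.
#' @return data.frame with columns `fp`, `alpha`.
#' @export
alpha_fp_tradeoff <- function(xi, fp_grid) {
  if (xi <= 0 || xi >= 1) stop("xi must be in (0, 1)")
  keep <- fp_grid > xi & fp_grid < 1
  if (!any(keep))
    stop("no admissible grid points: need xi < fp < 1")
  fp <- fp_grid[keep]
  data.frame(fp = fp, alpha = alpha_from_porosity_and_xi(fp, rep(xi, length(fp))))
}

#' Read a permeability dataset
#'
#' CSV with columns `C_NaCl_mol_L`, `P_cm2_s` (and optionally
#' `membrane_id`).
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_permeability_data <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("C_NaCl_mol_L", "P_cm2_s") %in% names(df)))
    stop("permeability file needs columns C_NaCl_mol_L, P_cm2_s")
  df
}
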