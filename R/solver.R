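#' Spatial discretization of the DBL | membrane | DBL stack
#'
#' Uniform grid within each layer; the two interface nodes are shared
#' between neighboring layers. The mobility factor is 1 in the two diffusion
#' boundary layers and equal to the tortuosity coefficient `xi` inside the
#' membrane.
#'
#' @param delta_cm diffusion boundary layer thickness, cm (same on both
#'   sides).
#' @param d_cm membrane thickness, cm.
#' @param xi membrane tortuosity coefficient, in `(0, 1]`.
#' @param nodes_per_layer nodes per layer (>= 3; default 30).
#' @return object of class `layer_stack`: list with node coordinates `x`
#'   (cm), per-face spacing `h_face`, per-face mobility `beta_face`,
#'   per-node control volumes `cv`, node count `n_nodes`, the index of the
#'   mid-membrane face `mid_face`, and the two interface node indices.
#' @export
layer_stack <- function(delta_cm, d_cm, xi, nodes_per_layer = 30) {
  stopifnot(delta_cm > 0, d_cm > 0, xi > 0, xi <= 1, nodes_per_layer >= 3)
  n <- as.integer(nodes_per_layer)
  x1 <- seq(0, delta_cm, length.out = n)
  x2 <- seq(delta_cm, delta_cm + d_cm, length.out = n)
  x3 <- seq(delta_cm + d_cm, d_cm + 2 * delta_cm, length.out = n)
  x <- c(x1, x2[-1], x3[-1])
  N <- length(x)
  h <- diff(x)
  beta <- c(rep(1, n - 1), rep(xi, n - 1), rep(1, n - 1))
  cv <- c(h[1] / 2, (h[-length(h)] + h[-1]) / 2, h[length(h)] / 2)
  # membrane faces are (n-1)..(2n-3) in 0-based face indexing
  mid_face <- (n - 1L) + (n - 1L) %/% 2L
  monitor_faces <- c(n - 1L, mid_face, 2L * n - 3L)
  structure(list(x = x, h_face = h, beta_face = beta, cv = cv,
                 n_nodes = N, nodes_per_layer = n,
                 interface_nodes = c(n, 2L * n - 1L),
                 mid_face = mid_face, monitor_faces = monitor_faces,
                 delta_cm = delta_cm, d_cm = d_cm, xi = xi),
            class = "layer_stack")
}

#' Solver configuration
#'
#' @param nodes_per_layer grid nodes per layer (default 30; second-order
#'   central differences make 30/layer sufficient for sub-0.2% flux
#'   accuracy).
#' @param cfl_safety safety factor in `(0, 1]` applied to the
#'   Courant-Friedrichs-Lewy diffusion limit (default 0.5).
#' @param horizon_s simulated-time horizon, s (default 60). Membranes with a
#'   very small tortuosity coefficient relax slowly (time scale
#'   `d^2/(pi^2 xi D)`) and may need a longer horizon to meet `flux_tol`.
#' @param flux_tol relative flux change per check window below which the
#'   run is declared quasi-steady (default 1e-6).
#' @param check_dt convergence check window, simulated seconds (default 1).
#' @param reaction_mode `"equilibrium"` (operator splitting with exact
#'   per-node relaxation of the acid-base reactions; default), `"explicit"`
#'   (literal sub-stepped kinetics, for validation), or `"off"`.
#' @return list of class `solver_config`.
#' @export
solver_config <- function(nodes_per_layer = 30, cfl_safety = 0.5,
                          horizon_s = 60, flux_tol = 1e-6, check_dt = 1,
                          reaction_mode = c("equilibrium", "explicit",
                                            "off")) {
  reaction_mode <- match.arg(reaction_mode)
  stopifnot(cfl_safety > 0, cfl_safety <= 1, nodes_per_layer >= 3,
            horizon_s > 0, flux_tol > 0, check_dt > 0)
  structure(list(nodes_per_layer = as.integer(nodes_per_layer),
                 cfl_safety = cfl_safety, horizon_s = horizon_s,
                 flux_tol = flux_tol, check_dt = check_dt,
                 reaction_mode = reaction_mode),
            class = "solver_config")
}

#' Electric potential gradient from the zero-current condition
#'
#' Eliminates the potential from the Nernst-Planck fluxes: with no net
#' current, `dphi/dx = -(RT/F) * sum(z D dC/dx) / sum(z^2 D C)`. The layer
#' mobility factor multiplies every species identically and cancels.
#'
#' @param conc named species concentrations at the point, mol L^-1.
#' @param grad_conc concentration gradients, (mol L^-1) cm^-1, same names.
#' @param sp species table ([species_table()]) restricted to the species in
#'   `conc`.
#' @param temperature_K absolute temperature (default 310.15).
#' @return potential gradient in V cm^-1 (0, with a warning, when no ions
#'   are present).
#' @export
potential_gradient <- function(conc, grad_conc, sp,
                               temperature_K = 310.15) {
  stopifnot(identical(names(conc), sp$species),
            identical(names(grad_conc), sp$species))
  den <- sum(sp$z^2 * sp$D_cm2_s * conc)
  if (den <= 0) {
    warning("all-neutral composition: no migration possible, dphi/dx = 0")
    return(0)
  }
  num <- sum(sp$z * sp$D_cm2_s * grad_conc)
  -(GAS_CONSTANT * temperature_K / FARADAY) * num / den
}

#' Nernst-Planck face fluxes for a state
#'
#' Central-difference fluxes on every cell face,
#' `J_i = -beta D_i (dC_i/dx + z_i C_i (F/RT) dphi/dx)`, with the potential
#' gradient fixed per face by the zero-current condition, so that
#' `sum(z_i J_i) = 0` on every face to round-off.
#'
#' @param state nodes x species concentration matrix (mol L^-1), columns
#'   named by species.
#' @param stack a [layer_stack()].
#' @param sp species table rows matching the state columns.
#' @return matrix of face fluxes in mol cm^-2 s^-1 (rows = faces).
#' @export
flux_field <- function(state, stack, sp) {
  stopifnot(nrow(state) == stack$n_nodes,
            identical(colnames(state), sp$species))
  NF <- stack$n_nodes - 1L
  grads <- (state[-1, , drop = FALSE] - state[-nrow(state), , drop = FALSE]) /
    stack$h_face
  cfs <- (state[-1, , drop = FALSE] + state[-nrow(state), , drop = FALSE]) / 2
  num <- grads %*% (sp$z * sp$D_cm2_s)
  den <- cfs %*% (sp$z^2 * sp$D_cm2_s)
  psi <- ifelse(den > 0, -num / den, 0)          # (F/RT) dphi/dx, cm^-1
  J <- -(stack$beta_face *
           (sweep(grads, 2, sp$D_cm2_s, `*`) +
              sweep(cfs * matrix(psi, NF, ncol(state)), 2,
                    sp$z * sp$D_cm2_s, `*`)))
  colnames(J) <- sp$species
  J * 1e-3   # (mol/L) cm/s -> mol cm^-2 s^-1
}

#' Stable explicit time step from the CFL diffusion limit
#'
#' `dt = safety * min over faces and species of h^2 / (2 beta D)`. The
#' reduced mobility inside the membrane (`beta = xi < 1`) relaxes the
#' membrane-layer bound by `1/xi`.
#'
#' @param stack a [layer_stack()].
#' @param D vector of diffusion coefficients, cm2 s^-1.
#' @param safety multiplicative safety factor in `(0, 1]`.
#' @return time step in seconds.
#' @export
cfl_timestep <- function(stack, D, safety = 0.5) {
  stopifnot(safety > 0, safety <= 1, all(D > 0))
  safety * min(stack$h_face^2 / (2 * stack$beta_face)) / max(D)
}

# map a config + species set to the C++ call arguments
chem_indices <- function(species) {
  idx <- match(c("H", "OH", "P1", "P2"), species) - 1L
  idx[is.na(idx)] <- -1L
  idx
}

# flux-watch groups for convergence: each transported solute its own group,
# the two phosphate anions share one (the solute is total phosphate); H/OH
# are slaved to the equilibria and not watched.
watch_groups <- function(species) {
  g <- integer(length(species))
  nxt <- 1L
  for (i in seq_along(species)) {
    s <- species[i]
    if (s %in% c("H", "OH")) next
    if (s == "P2" && "P1" %in% species) {
      g[i] <- g[match("P1", species)]
    } else {
      g[i] <- nxt
      nxt <- nxt + 1L
    }
  }
  if (all(g == 0L) && length(species) > 0) g[] <- seq_along(species)
  g
}

#' Advance the transport state by explicit Euler steps
#'
#' Low-level single/multi-step driver used by [run_to_quasi_steady()];
#' exposed for inspection and testing. Boundary nodes are Dirichlet
#' (clamped at the supplied state's first and last rows).
#'
#' @inheritParams flux_field
#' @param eq an [equilibrium_set()].
#' @param dt time step, s (must satisfy the CFL bound).
#' @param n_steps number of steps to take.
#' @param reaction_mode see [solver_config()].
#' @return list with the updated `state`, face fluxes `J_faces`
#'   (mol cm^-2 s^-1) from the last step, and elapsed time `t`.
#' @export
transport_step <- function(state, stack, sp, eq = equilibrium_set(),
                           dt, n_steps = 1,
                           reaction_mode = "equilibrium") {
  mode <- match(match.arg(reaction_mode,
                          c("equilibrium", "explicit", "off")),
                c("off", "equilibrium", "explicit")) - 1L
  res <- cpp_run_transport(state, sp$z, sp$D_cm2_s, stack$beta_face,
                           stack$h_face, stack$cv,
                           dt, Inf, Inf, 0, stack$mid_face,
                           stack$monitor_faces,
                           watch_groups(sp$species),
                           mode, chem_indices(sp$species),
                           eq$Kw, eq$K, eq$k1, eq$km1, eq$kd, eq$kr,
                           eq$C_H2O, as.double(n_steps))
  if (res$failed) stop("transport step failed: persistent negative ",
                       "concentrations (stiffness misconfiguration?)")
  st <- res$C
  dimnames(st) <- dimnames(state)
  Jf <- res$J_faces * 1e-3
  colnames(Jf) <- sp$species
  list(state = st, J_faces = Jf, t = res$t)
}

#' Initial condition of a dialysis transient
#'
#' Uniform compartment concentrations throughout each diffusion boundary
#' layer; concentrations inside the membrane linearly distributed between
#' its two interfaces.
#'
#' @param stack a [layer_stack()].
#' @param boundary_A,boundary_B named compartment concentration vectors
#'   (mol L^-1).
#' @return nodes x species concentration matrix.
#' @export
initial_state <- function(stack, boundary_A, boundary_B) {
  species <- names(boundary_A)
  stopifnot(setequal(species, names(boundary_B)))
  boundary_B <- boundary_B[species]
  N <- stack$n_nodes
  state <- matrix(0, N, length(species), dimnames = list(NULL, species))
  i1 <- stack$interface_nodes[1]
  i2 <- stack$interface_nodes[2]
  for (s in seq_along(species)) {
    prof <- numeric(N)
    prof[1:i1] <- boundary_A[[s]]
    prof[i2:N] <- boundary_B[[s]]
    prof[i1:i2] <- seq(boundary_A[[s]], boundary_B[[s]],
                       length.out = i2 - i1 + 1)
    state[, s] <- prof
  }
  state
}

#' Integrate the stack to a quasi-steady state
#'
#' Builds the initial condition (uniform compartment concentrations in the
#' two boundary layers, linear profiles across the membrane), then advances
#' the explicit Euler scheme at the CFL-limited step until the membrane
#' mid-face flux of every transported solute changes by less than
#' `flux_tol` (relative) per check window, or the time horizon is reached.
#'
#' @param stack a [layer_stack()].
#' @param sp species table rows for the transported species.
#' @param boundary_A,boundary_B named concentration vectors (mol L^-1) for
#'   the feed (A) and dialysate (B) compartments; names must match
#'   `sp$species`.
#' @param eq an [equilibrium_set()].
#' @param config a [solver_config()].
#' @return object of class `qss_result`: list with the final concentration
#'   matrix `state` (nodes x species), node coordinates `x`, face fluxes
#'   `J_faces` and mid-membrane fluxes `J_mid` (mol cm^-2 s^-1), elapsed
#'   simulated time `t`, `converged` flag, step count, time step, the
#'   time-integrated boundary fluxes, and the maximum nodal charge
#'   imbalance.
#' @export
run_to_quasi_steady <- function(stack, sp, boundary_A, boundary_B,
                                eq = equilibrium_set(),
                                config = solver_config()) {
  species <- sp$species
  state <- initial_state(stack, boundary_A[species], boundary_B[species])
  dt <- cfl_timestep(stack, sp$D_cm2_s, config$cfl_safety)
  mode <- match(config$reaction_mode, c("off", "equilibrium", "explicit")) - 1L
  res <- cpp_run_transport(state, sp$z, sp$D_cm2_s, stack$beta_face,
                           stack$h_face, stack$cv,
                           dt, config$horizon_s, config$check_dt,
                           config$flux_tol, stack$mid_face,
                           stack$monitor_faces,
                           watch_groups(species),
                           mode, chem_indices(species),
                           eq$Kw, eq$K, eq$k1, eq$km1, eq$kd, eq$kr,
                           eq$C_H2O, Inf)
  if (res$failed)
    stop("solver failed: persistent negative concentrations after ",
         res$rejects, " step rejections")
  st <- res$C
  dimnames(st) <- dimnames(state)
  Jf <- res$J_faces * 1e-3
  colnames(Jf) <- species
  out <- list(state = st, x = stack$x, J_faces = Jf,
              J_mid = setNames(res$J_mid * 1e-3, species),
              t = res$t, converged = res$converged,
              steps = res$steps, dt = res$dt, rejects = res$rejects,
              boundary_influx = setNames(res$boundary_influx * 1e-3,
                                         species),
              boundary_outflux = setNames(res$boundary_outflux * 1e-3,
                                          species),
              max_charge_imbalance = res$max_charge_imbalance,
              stack = stack)
  class(out) <- "qss_result"
  if (!res$converged)
    warning(sprintf(paste0("quasi-steady tolerance %.1e not met within ",
                           "horizon %.3g s (flux still relaxing); consider ",
                           "a longer horizon_s"),
                    config$flux_tol, config$horizon_s))
  out
}

#' @export
print.qss_result <- function(x, ...) {
  cat(sprintf("Quasi-steady transport run: %s after %.3g s (%g steps, dt = %.3g s)\n",
              if (x$converged) "converged" else "NOT converged",
              x$t, x$steps, x$dt))
  cat("mid-membrane fluxes (mol cm-2 s-1):\n")
  print(signif(x$J_mid, 4))
  cat(sprintf("max nodal charge imbalance: %.2e\n",
              x$max_charge_imbalance))
  invisible(x)
}

#' Mass-transfer coefficient from flux and compartment concentrations
#'
#' `L = J / (C_A - C_B)` with the concentration difference converted from
#' mol L^-1 to mol cm^-3; units cm s^-1. For total phosphate, pass the
#' summed flux of the two anions against the difference in total phosphate.
#'
#' @param J quasi-steady solute flux, mol cm^-2 s^-1.
#' @param C_A,C_B compartment concentrations, mol L^-1 (`C_A != C_B`).
#' @return mass-transfer coefficient, cm s^-1.
#' @export
mass_transfer_coefficient <- function(J, C_A, C_B) {
  if (any(C_A == C_B))
    stop("mass-transfer coefficient undefined at zero concentration ",
         "difference")
  J / ((C_A - C_B) * 1e-3)
}

#' Closed-form series-resistance mass-transfer coefficient
#'
#' For a neutral solute the quasi-steady stack behaves as three diffusive
#' resistances in series: `L = 1 / (2 delta / D + d / (xi D))`. Used as the
#' analytic reference for the transport solver and as the fast forward
#' model when fitting the tortuosity coefficient.
#'
#' @param D solute diffusion coefficient, cm2 s^-1.
#' @param delta_cm boundary layer thickness, cm.
#' @param d_cm membrane thickness, cm.
#' @param xi tortuosity coefficient.
#' @return mass-transfer coefficient, cm s^-1.
#' @export
series_resistance_L <- function(D, delta_cm, d_cm, xi) {
  stopifnot(all(D > 0), all(delta_cm > 0), all(d_cm > 0), all(xi > 0))
  1 / (2 * delta_cm / D + d_cm / (xi * D))
}

#' Write a concentration/flux profile to CSV
#'
#' One row per node: coordinate, concentrations, and (interpolated to
#' nodes) species fluxes.
#'
#' @param result a `qss_result` from [run_to_quasi_steady()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_profile <- function(result, path) {
  J <- result$J_faces
  Jn <- rbind(J[1, , drop = FALSE],
              (J[-1, , drop = FALSE] + J[-nrow(J), , drop = FALSE]) / 2,
              J[nrow(J), , drop = FALSE])
  df <- data.frame(x_cm = result$x, result$state,
                   setNames(as.data.frame(Jn),
                            paste0("J_", colnames(J))),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
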