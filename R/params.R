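#' Model parameters for the tumour--virus system
#'
#' Builds the parameter set shared by every model in the hierarchy: the
#' stochastic lattice simulator ([abm_simulate()]), the continuum solvers
#' ([pde_solve()]), the non-spatial models ([ode_equilibria()],
#' [hopf_scan()]) and the wave-speed theory ([wave_speed_three_species()]).
#' Defaults are the reference values of the underlying study (the lower
#' burst-size / clearance pair); `K` and `V_0` default per spatial dimension.
#'
#' @param p Maximal duplication rate of uninfected cells (1/h).
#' @param q Death (lysis) rate of infected cells (1/h).
#' @param q_v Viral clearance rate (1/h). Reference values: 1.67e-1 or 1.00.
#' @param alpha Viral burst size (virions released per lysed cell).
#'   Reference values: 580 or 3500.
#' @param beta Infection rate (virions/(cells h), scaled by `K` in the
#'   infection probability).
#' @param D_U Diffusion coefficient for undirected cell movement (mm^2/h).
#' @param D_P Diffusion coefficient for pressure-driven movement (mm^2/h).
#'   Defaults to [matched_pressure_diffusion()] of `D_U` so that the untreated
#'   front speeds of the two movement rules coincide.
#' @param D_v Viral diffusion coefficient (mm^2/h).
#' @param K Carrying capacity (cells/mm in 1D, cells/mm^2 in 2D). If `NULL`,
#'   the dimension-appropriate reference value (1e3 or 1e4) is used.
#' @param R_u,R_v,R_i Initial radii (mm) of the uninfected-cell, viral and
#'   infected-cell plateaux.
#' @param V_0 Initial viral plateau height. If `NULL`, 2.67e4 in 1D and
#'   (2.67e3)^2 in 2D.
#' @param tau Agent-based time step (h).
#' @param delta Agent-based lattice spacing (mm).
#' @param movement Cell movement rule, `"undirected"` or `"pressure"`.
#' @param dimension Spatial dimension, 1 or 2.
#'
#' @return An object of class `ov_params` (a named list).
#' @seealso [validate_params()], [beta_tilde()], [theta_from_diffusion()]
#' @examples
#' pars <- model_params()
#' beta_tilde(pars)
#' @export
model_params <- function(p = 1.87e-2, q = 4.17e-2, q_v = 1.67e-1,
                         alpha = 580, beta = 7e-4,
                         D_U = 1.88e-4, D_P = matched_pressure_diffusion(D_U),
                         D_v = 1e-2, K = NULL,
                         R_u = 2.6, R_v = 0.5, R_i = 0, V_0 = NULL,
                         tau = 0.02, delta = 0.1,
                         movement = c("undirected", "pressure"),
                         dimension = 1) {
  movement <- match.arg(movement)
  dimension <- as.integer(dimension)
  if (!dimension %in% c(1L, 2L)) {
    stop("`dimension` must be 1 or 2", call. = FALSE)
  }
  if (is.null(K)) K <- if (dimension == 1L) 1e3 else 1e4
  if (is.null(V_0)) V_0 <- if (dimension == 1L) 2.67e4 else (2.67e3)^2
  pars <- list(
    p = p, q = q, q_v = q_v, alpha = alpha, beta = beta,
    D_U = D_U, D_P = D_P, D_v = D_v, K = K,
    R_u = R_u, R_v = R_v, R_i = R_i, V_0 = V_0,
    tau = tau, delta = delta, movement = movement, dimension = dimension
  )
  rates <- c("p", "q", "q_v", "beta", "K", "tau", "delta")
  for (nm in rates) {
    if (!is.numeric(pars[[nm]]) || length(pars[[nm]]) != 1L || pars[[nm]] <= 0) {
      stop("`", nm, "` must be a single strictly positive number", call. = FALSE)
    }
  }
  for (nm in c("alpha", "D_U", "D_P", "D_v", "R_u", "R_v", "R_i", "V_0")) {
    if (!is.numeric(pars[[nm]]) || length(pars[[nm]]) != 1L || pars[[nm]] < 0) {
      stop("`", nm, "` must be a single non-negative number", call. = FALSE)
    }
  }
  structure(pars, class = "ov_params")
}

#' @export
print.ov_params <- function(x, ...) {
  cat("<ov_params> ", x$dimension, "D, ", x$movement, " movement\n", sep = "")
  cat(sprintf("  p = %.3g  q = %.3g  q_v = %.3g  alpha = %g  beta = %.3g\n",
              x$p, x$q, x$q_v, x$alpha, x$beta))
  cat(sprintf("  D_U = %.3g  D_P = %.3g  D_v = %.3g  K = %g\n",
              x$D_U, x$D_P, x$D_v, x$K))
  cat(sprintf("  R_u = %g  R_v = %g  R_i = %g  V_0 = %.4g\n",
              x$R_u, x$R_v, x$R_i, x$V_0))
  cat(sprintf("  tau = %g h  delta = %g mm   beta_tilde = %.4g /h\n",
              x$tau, x$delta, beta_tilde(x)))
  invisible(x)
}

#' Effective cell-to-cell infection rate
#'
#' Under the quasi-steady viral assumption (clearance much faster than cell
#' turnover) the virus tracks the infected cells, `v ~ (alpha q / q_v) i`, and
#' virus-mediated infection collapses to a cell-to-cell rate
#' `beta_tilde = beta * alpha * q / q_v`. The result is invariant under
#' rescaling `(alpha, q_v) -> (c alpha, c q_v)`.
#'
#' @param params An [model_params()] object.
#' @return The rate `beta_tilde` (1/h).
#' @examples
#' beta_tilde(model_params(alpha = 3500, q_v = 1)) # 0.102
#' @export
beta_tilde <- function(params) {
  if (params$q_v == 0) stop("q_v = 0: beta_tilde is undefined", call. = FALSE)
  params$beta * params$alpha * params$q / params$q_v
}

#' Lattice movement probability from a diffusion coefficient
#'
#' The continuum limit of the lattice walk requires
#' `theta * delta^2 / (2 tau) -> D` in 1D and `theta * delta^2 / (4 tau) -> D`
#' in 2D, so the per-step movement probability is `theta = 2 tau D / delta^2`
#' (1D) or `4 tau D / delta^2` (2D), with `D = D_U` or `D_P` depending on the
#' movement rule.
#'
#' @inheritParams beta_tilde
#' @return The probability `theta` in `[0, 1]`.
#' @export
theta_from_diffusion <- function(params) {
  D <- if (params$movement == "undirected") params$D_U else params$D_P
  fac <- if (params$dimension == 1L) 2 else 4
  theta <- fac * params$tau * D / params$delta^2
  if (theta > 1) {
    stop(sprintf(
      "theta = %.3g > 1: discretisation too coarse for D = %.3g (reduce tau or increase delta)",
      theta, D), call. = FALSE)
  }
  theta
}

#' Pressure-driven diffusivity matching the undirected front speed
#'
#' An untreated tumour front travels at `2 sqrt(D_U p)` under undirected
#' movement and at `sqrt(D_P p / 2)` under pressure-driven movement. Equating
#' the two gives `D_P = 8 D_U`, the value used to compare the movement rules
#' at identical propagation speed.
#'
#' @param D_U Undirected diffusion coefficient (mm^2/h).
#' @param p Duplication rate (1/h); only its positivity matters, the matching
#'   is independent of `p`.
#' @return The matched `D_P` (mm^2/h).
#' @examples
#' matched_pressure_diffusion(1.88e-4) # 1.50e-3
#' @export
matched_pressure_diffusion <- function(D_U, p = NULL) {
  if (D_U < 0) stop("D_U must be non-negative", call. = FALSE)
  if (!is.null(p) && p < 0) stop("p must be non-negative", call. = FALSE)
  8 * D_U
}

#' Piecewise-constant radial initial condition
#'
#' The standard initial state: uninfected cells at 90% of carrying capacity on
#' a plateau of radius `R_u`, no infected cells, and a viral plateau of height
#' `V_0` and radius `R_v`.
#'
#' @inheritParams beta_tilde
#' @param u_height,i_height,v_height Plateau heights (densities).
#' @param R_u,R_i,R_v Plateau radii (mm); default from `params`.
#' @return An object of class `ov_initial` with fields `u0`, `i0`, `v0`, each
#'   a list `(height, radius)`.
#' @export
initial_condition <- function(params,
                              u_height = 0.9 * params$K, R_u = params$R_u,
                              i_height = 0, R_i = params$R_i,
                              v_height = params$V_0, R_v = params$R_v) {
  if (u_height < 0 || i_height < 0 || v_height < 0) {
    stop("plateau heights must be non-negative", call. = FALSE)
  }
  structure(list(u0 = list(height = u_height, radius = R_u),
                 i0 = list(height = i_height, radius = R_i),
                 v0 = list(height = v_height, radius = R_v)),
            class = "ov_initial")
}

plateau_profile <- function(x, height, radius) {
  if (height == 0 || radius <= 0) return(numeric(length(x)))
  ifelse(abs(x) <= radius + 1e-12, height, 0)
}

#' Realise an initial condition on a grid
#'
#' For the agent-based target, cell plateaux become integer counts per lattice
#' site, `round(height * delta)` in 1D and `round(height * delta^2)` in 2D
#' (nearest-integer rounding: unbiased in the plateau interior, error confined
#' to plateau edges). For the PDE target, densities are sampled at the nodes.
#'
#' @inheritParams beta_tilde
#' @param ic An [initial_condition()] object.
#' @param x Grid coordinates: site centres (1D, may be signed; radial grids
#'   start at 0). For 2D agent-based lattices pass the 1D axis; the square
#'   lattice is built internally by [abm_simulate()].
#' @param target `"abm"` for integer counts, `"pde"` for densities.
#' @return A list with entries `U`, `I` (integer counts) and `v` for
#'   `target = "abm"`; `u`, `i`, `v` (densities) for `target = "pde"`.
#' @export
make_initial_state <- function(ic, x, target = c("abm", "pde"), params) {
  target <- match.arg(target)
  for (f in c("u0", "i0", "v0")) {
    if (f != "v0" && ic[[f]]$height > params$K) {
      stop("initial cell plateau exceeds the carrying capacity K", call. = FALSE)
    }
  }
  radii <- c(ic$u0$radius, ic$v0$radius)
  if (any(is.finite(radii) & radii > max(abs(x)) + 1e-12)) {
    stop("grid does not span the initial plateaux", call. = FALSE)
  }
  u <- plateau_profile(x, ic$u0$height, ic$u0$radius)
  i <- plateau_profile(x, ic$i0$height, ic$i0$radius)
  v <- plateau_profile(x, ic$v0$height, ic$v0$radius)
  if (target == "pde") {
    return(list(u = u, i = i, v = v))
  }
  meas <- params$delta^params$dimension
  list(U = as.integer(round(u * meas)), I = as.integer(round(i * meas)), v = v)
}

#' Validate probability and stability constraints
#'
#' Checks the constraints under which every per-step event probability of the
#' lattice model stays in `[0, 1]` and the explicit viral scheme is stable:
#' `tau * p <= 1` (demography, worst case at zero density), `tau * q <= 1`
#' (lysis), `tau * beta * v / K <= 1` for the largest anticipated viral
#' concentration, `theta <= 1`, and the viral CFL condition
#' `tau * D_v / delta^2 <= 1/2`. Also warns when `K` differs from the
#' dimension-appropriate reference value.
#'
#' @inheritParams beta_tilde
#' @param v_max Largest anticipated viral concentration; defaults to `V_0`.
#'   (The simulator re-checks the realised probabilities at every step.)
#' @return A character vector of violated constraints; empty when all pass.
#' @export
validate_params <- function(params, v_max = params$V_0) {
  bad <- character(0)
  if (params$tau * params$p > 1) {
    bad <- c(bad, sprintf("tau*|G| = %.3g > 1 (demography probability)",
                          params$tau * params$p))
  }
  if (params$tau * params$q > 1) {
    bad <- c(bad, sprintf("tau*q = %.3g > 1 (lysis probability)",
                          params$tau * params$q))
  }
  if (params$tau * params$beta * v_max / params$K > 1) {
    bad <- c(bad, sprintf("tau*beta*v/K = %.3g > 1 at v = %.3g (infection probability)",
                          params$tau * params$beta * v_max / params$K, v_max))
  }
  if (params$tau * params$q_v > 1) {
    bad <- c(bad, sprintf("tau*q_v = %.3g > 1 (viral decay)", params$tau * params$q_v))
  }
  if (params$tau * params$D_v / params$delta^2 > 0.5) {
    bad <- c(bad, sprintf("tau*D_v/delta^2 = %.3g > 1/2 (viral scheme CFL)",
                          params$tau * params$D_v / params$delta^2))
  }
  theta <- tryCatch(theta_from_diffusion(params), error = function(e) NA_real_)
  if (is.na(theta)) {
    bad <- c(bad, "theta > 1 (movement probability)")
  }
  K_ref <- if (params$dimension == 1L) 1e3 else 1e4
  if (params$K != K_ref) {
    warning(sprintf("K = %g differs from the reference value %g for %dD",
                    params$K, K_ref, params$dimension), call. = FALSE)
  }
  bad
}
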