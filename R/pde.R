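#' Solve a continuum model of the hierarchy
#'
#' Explicit-in-time finite differences for the four deterministic systems:
#'
#' * `"U3"` — linear (undirected) cell diffusion with an explicit virus
#'   equation;
#' * `"P3"` — pressure-driven cross-diffusion (both species advected down the
#'   gradient of total density `rho = u + i`) with an explicit virus;
#' * `"U2"` — linear diffusion with the quasi-steady virus collapsed into the
#'   cell-to-cell rate [beta_tilde()];
#' * `"P2"` — cross-diffusion with the quasi-steady virus.
#'
#' Linear diffusion uses the centred 3-point stencil; the cross-diffusion flux
#' `(D_P/K) u d(u+i)/dx` uses first-order donor-cell upwinding on shared face
#' velocities. On a radially symmetric 2D grid the r = 0 singularity is closed
#' by symmetry. Boundaries are no-flux. Negative undershoots are clipped to
#' zero and counted; a warning is raised if they exceed `1e-12` in magnitude.
#'
#' @inheritParams abm_simulate
#' @param ic An [initial_condition()] object (default: the standard
#'   plateaux), or a list of node-level numeric fields `u`, `i` (and `v`)
#'   matching the grid.
#' @param model One of `"U3"`, `"P3"`, `"U2"`, `"P2"`.
#' @param L Domain half-length in 1D, outer radius in radial mode (mm).
#'   Defaults to 20 (1D) or 15 (radial).
#' @param dx,dt Grid spacing (mm) and time step (h).
#' @param radial If `TRUE`, solve on `r in [0, L]` with the radially symmetric
#'   2D operators. Defaults to `params$dimension == 2`.
#' @param record_every Record full profiles every this many steps (default:
#'   about 200 frames). Spatial integrals of `u` and `i` are tracked every
#'   step.
#' @return An `ov_trajectory`; `totals` holds the spatial integrals (expected
#'   cell numbers) at every step.
#' @export
pde_solve <- function(model = c("U3", "P3", "U2", "P2"), params,
                      ic = initial_condition(params), L = NULL,
                      dx = 0.1, dt = 1e-3, horizon,
                      radial = params$dimension == 2L, record_every = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(params, "ov_params"))
  pressure <- model %in% c("P3", "P2")
  explicit_virus <- model %in% c("U3", "P3")
  D_cell <- if (pressure) params$D_P else params$D_U
  if (is.null(L)) L <- if (radial) 15 else 20
  nsteps <- round(horizon / dt)
  if (abs(nsteps * dt - horizon) > 1e-9 * max(1, horizon)) {
    stop("`horizon` must be an integer multiple of dt", call. = FALSE)
  }
  if (is.null(record_every)) record_every <- max(1L, floor(nsteps / 200))
  # CFL for the linear operators; the upwind advection runs far below its
  # own limit at reference parameters (face velocities ~ 1e-2 mm/h)
  D_lin <- max(if (pressure) 0 else D_cell, if (explicit_virus) params$D_v else 0)
  if (dt * D_lin / dx^2 > 0.5) {
    stop(sprintf("CFL violated: dt*D/dx^2 = %.3g > 1/2", dt * D_lin / dx^2),
         call. = FALSE)
  }
  if (pressure && dt * 2 * D_cell / dx^2 > 0.5) {
    # effective diffusivity of the cross term is D_P * rho/K <~ 2 D_P
    stop("CFL violated for the cross-diffusion term", call. = FALSE)
  }
  x <- if (radial) seq(0, L, by = dx) else seq(-L, L, by = dx)
  st <- if (inherits(ic, "ov_initial")) {
    make_initial_state(ic, x, target = "pde", params = params)
  } else {
    # node-level initial fields (u, i, v) supplied directly
    stopifnot(is.list(ic), length(ic$u) == length(x),
              length(ic$i) == length(x))
    ic
  }
  beta_eff <- if (explicit_virus) params$beta else beta_tilde(params)
  res <- pde_run_cpp(st$u, st$i, if (explicit_virus) st$v else numeric(0),
                     dx, dt, as.integer(nsteps), as.integer(record_every),
                     radial, pressure, explicit_virus,
                     params$p, params$q, params$q_v, params$alpha, beta_eff,
                     params$K, D_cell, params$D_v)
  if (res$worst_undershoot < -1e-12) {
    warning(sprintf("negative densities clipped (%d times, worst %.3g)",
                    as.integer(res$clip_count), res$worst_undershoot),
            call. = FALSE)
  }
  totals <- data.frame(t = res$int_t, U = res$int_U, I = res$int_I)
  new_trajectory(
    kind = "pde", model = model, params = params, x = x,
    times = res$times, u = res$U, i = res$I,
    v = if (explicit_virus) res$v else NULL,
    totals = totals, radial = radial, nx = length(x), ny = 1L,
    extra = list(dx = dx, dt = dt, clip_count = res$clip_count))
}

#' Discrepancy between explicit-virus and quasi-steady models
#'
#' Solves the explicit-virus system (U3 or P3, by the movement rule in
#' `params`) and its quasi-steady reduction (U2 or P2, with the effective rate
#' [beta_tilde()]) on the same grid and reports the sup-norm discrepancy of
#' the uninfected density over the recorded times. The reduced model carries
#' no virus, so the viral initial condition is translated into its
#' quasi-steady infected-cell equivalent, `i0 + (q_v/(alpha q)) v0` — without
#' this the reduced system could never start an infection from `i0 = 0`. In
#' the limit of fast viral turnover and slow viral diffusion the discrepancy
#' vanishes.
#'
#' @inheritParams pde_solve
#' @return A list with `times`, `sup_u` (per-time sup-norm discrepancy),
#'   `max_sup`, and the two trajectories.
#' @export
quasi_steady_check <- function(params, ic = initial_condition(params),
                               L = NULL, dx = 0.1, dt = 1e-3, horizon,
                               radial = params$dimension == 2L) {
  full <- if (params$movement == "undirected") "U3" else "P3"
  red <- if (params$movement == "undirected") "U2" else "P2"
  if (is.null(L)) L <- if (radial) 15 else 20
  x <- if (radial) seq(0, L, by = dx) else seq(-L, L, by = dx)
  st <- make_initial_state(ic, x, target = "pde", params = params)
  st_red <- list(u = st$u,
                 i = st$i + params$q_v / (params$alpha * params$q) * st$v,
                 v = st$v * 0)
  tr3 <- pde_solve(full, params, st, L = L, dx = dx, dt = dt,
                   horizon = horizon, radial = radial)
  tr2 <- pde_solve(red, params, st_red, L = L, dx = dx, dt = dt,
                   horizon = horizon, radial = radial)
  sup_u <- vapply(seq_along(tr3$times), function(k) {
    max(abs(tr3$u[k, ] - tr2$u[k, ]))
  }, numeric(1))
  list(times = tr3$times, sup_u = sup_u, max_sup = max(sup_u),
       full = tr3, reduced = tr2)
}
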