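#' Discrete tumour control probability
#'
#' Fraction of ensemble replicates whose uninfected population went extinct by
#' time `t`. Uninfected extinction is absorbing (no new cancer cells can arise
#' after it), so the curve is a non-decreasing step function with values in
#' `{0, 1/M, ..., 1}`.
#'
#' @param ens An `ov_ensemble` from [abm_ensemble()].
#' @param t Time or vector of times (h) within the ensemble horizon.
#' @return Probability value(s) in `[0, 1]`.
#' @export
tcp_discrete <- function(ens, t) {
  stopifnot(inherits(ens, "ov_ensemble"))
  vapply(t, function(tt) mean(ens$replicates$t_ext_U <= tt), numeric(1))
}

#' Discrete infection control probability
#'
#' Fraction of replicates with zero infected cells at time `t`, evaluated
#' pointwise on the stored totals grid (nearest recorded time at or before
#' `t`). Pointwise — not absorbing — because infected cells can re-emerge
#' through new infection events while virus persists; set
#' `absorbing = TRUE` for the variant that latches once the infection has
#' been cleared after onset.
#'
#' @inheritParams tcp_discrete
#' @param absorbing If `TRUE`, count a replicate as controlled from the first
#'   time its infected population hits zero after infection onset.
#' @return Probability value(s) in `[0, 1]`.
#' @export
icp_discrete <- function(ens, t, absorbing = FALSE) {
  stopifnot(inherits(ens, "ov_ensemble"))
  if (absorbing) {
    return(vapply(t, function(tt) mean(ens$replicates$first_I0 <= tt),
                  numeric(1)))
  }
  vapply(t, function(tt) {
    k <- findInterval(tt + 1e-9, ens$totals_t)
    if (k < 1) k <- 1
    mean(ens$tot_I[k, ] == 0)
  }, numeric(1))
}

poisson_cp <- function(traj, t, which = c("U", "I")) {
  which <- match.arg(which)
  stopifnot(inherits(traj, "ov_trajectory"))
  if (!isTRUE(traj$radial)) {
    stop("Poissonian control probabilities are defined for radial 2D solutions",
         call. = FALSE)
  }
  ints <- traj$totals[[which]]
  tg <- traj$totals$t
  # nearest recorded time, vectorised (tg is sorted and uniform)
  k <- findInterval(t, tg, all.inside = TRUE)
  k <- k + (abs(tg[pmin(k + 1L, length(tg))] - t) < abs(tg[k] - t))
  exp(-ints[k])
}

#' Poissonian tumour control probability
#'
#' Treats the surviving uninfected cell number implied by a radial continuum
#' solution as Poisson-distributed: `TCP(t) = exp(-2 pi integral_0^R u(t,r) r
#' dr)`. The integral is the trapezoid quadrature on the solver grid (tracked
#' at every step), with `R` the computational radius — densities vanish beyond
#' the front.
#'
#' @param traj A radial `ov_trajectory` from [pde_solve()].
#' @param t Time or vector of times (h).
#' @return Probability value(s) in `(0, 1]`.
#' @export
tcp_poisson <- function(traj, t) poisson_cp(traj, t, "U")

#' Poissonian infection control probability
#'
#' As [tcp_poisson()] with the infected density:
#' `ICP(t) = exp(-2 pi integral_0^R i(t,r) r dr)`.
#'
#' @inheritParams tcp_poisson
#' @return Probability value(s) in `(0, 1]`.
#' @export
icp_poisson <- function(traj, t) poisson_cp(traj, t, "I")

#' Maximal control probabilities across burst sizes
#'
#' For each burst size `alpha`, solves the radial explicit-virus systems (both
#' movement rules: linear diffusion and cross-diffusion) and records the
#' maximum over strictly positive times of the Poissonian TCP and ICP.
#' Restricting to `t > 0` matters for the ICP: the standard initial condition
#' has no infected cells, so `ICP(0) = 1` regardless of the inevitable
#' subsequent infection.
#'
#' @inheritParams beta_tilde
#' @param alpha_values Burst sizes to scan.
#' @param L,dx,dt Radial grid settings (see [pde_solve()]).
#' @param horizon Final time (h).
#' @param models Which systems to run (default both `"U3"` and `"P3"`).
#' @return A data frame with columns `alpha`, `model`, `max_tcp`, `max_icp`.
#' @export
extinction_scan <- function(params, alpha_values, L = 15, dx = 0.1, dt = 1e-3,
                            horizon = 1500, models = c("U3", "P3")) {
  stopifnot(params$dimension == 2L)
  grid <- expand.grid(alpha = alpha_values, model = models,
                      stringsAsFactors = FALSE)
  grid$max_tcp <- NA_real_
  grid$max_icp <- NA_real_
  for (k in seq_len(nrow(grid))) {
    pr <- params
    pr$alpha <- grid$alpha[k]
    tr <- pde_solve(grid$model[k], pr, L = L, dx = dx, dt = dt,
                    horizon = horizon, radial = TRUE)
    pos <- traj_positive_times(tr)
    grid$max_tcp[k] <- max(exp(-tr$totals$U[pos]))
    grid$max_icp[k] <- max(exp(-tr$totals$I[pos]))
  }
  grid
}

traj_positive_times <- function(traj) which(traj$totals$t > 0)
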