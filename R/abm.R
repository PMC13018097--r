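#' Simulate the hybrid stochastic lattice model
#'
#' Runs the agent-based model: integer uninfected/infected cell counts on a
#' lattice (1D chain or 2D square grid) with probabilistic division, death,
#' movement, infection and lysis, coupled to a continuous viral concentration
#' updated by an explicit balance equation forced by the stochastic lysis
#' events. One synchronous update per step, all event probabilities evaluated
#' on the time-n state, in the order lysis, infection, demography, movement,
#' virus. Boundaries are reflecting for both cells and virus.
#'
#' @inheritParams beta_tilde
#' @param ic An [initial_condition()] object; defaults to the standard
#'   plateaux.
#' @param L Domain half-length (mm); the lattice spans `[-L, L]` (per axis in
#'   2D). Defaults to `R_u + 5` (1D) or `R_u + 2.5` (2D) — a buffer generous
#'   enough for the reference front speeds over several hundred hours.
#' @param horizon Final time (h); must be an integer multiple of `tau`.
#' @param seed Integer RNG seed; the run is reproducible given
#'   `(params, ic, seed)`.
#' @param record_every Record full lattice snapshots every this many steps;
#'   defaults to roughly 100 frames. Scalar totals are tracked at every step.
#' @return An `ov_trajectory` with per-site densities `u`, `i` (counts divided
#'   by `delta^dimension`), viral concentration `v`, and a `totals` data frame
#'   `(t, U, I, v)` tracked at every step.
#' @seealso [abm_ensemble()], [pde_solve()]
#' @export
abm_simulate <- function(params, ic = initial_condition(params),
                         L = NULL, horizon, seed = 1L,
                         record_every = NULL) {
  stopifnot(inherits(params, "ov_params"))
  bad <- validate_params(params)
  if (length(bad)) {
    stop("invalid parameters: ", paste(bad, collapse = "; "), call. = FALSE)
  }
  if (is.null(L)) {
    L <- params$R_u + if (params$dimension == 1L) 5 else 2.5
  }
  nsteps <- round(horizon / params$tau)
  if (abs(nsteps * params$tau - horizon) > 1e-9 * max(1, horizon)) {
    stop("`horizon` must be an integer multiple of tau", call. = FALSE)
  }
  if (is.null(record_every)) {
    record_every <- max(1L, floor(nsteps / 100))
  }
  x <- seq(-L, L, by = params$delta)
  nx <- length(x)
  if (params$dimension == 1L) {
    r <- abs(x)
    ny <- 1L
  } else {
    r <- sqrt(outer(x^2, x^2, `+`)) # lattice radii, column-major nx x nx
    ny <- nx
  }
  st <- make_initial_state(ic, as.vector(r), target = "abm", params = params)
  set.seed(seed)
  res <- abm_run_cpp(st$U, st$I, st$v,
                     nx, ny, params$tau, params$delta, params$dimension,
                     params$p, params$q, params$q_v, params$alpha, params$beta,
                     params$K, params$D_v, theta_from_diffusion(params),
                     params$movement == "pressure",
                     as.integer(nsteps), as.integer(record_every))
  meas <- params$delta^params$dimension
  # domain-overflow check: cells on the outermost ring at any recorded frame
  edge <- if (params$dimension == 1L) c(1L, nx) else {
    which(as.vector(r) >= L - params$delta / 2)
  }
  if (any(res$U[, edge, drop = FALSE] > 0L) ||
      any(res$I[, edge, drop = FALSE] > 0L)) {
    warning("cells reached the domain boundary; increase L", call. = FALSE)
  }
  totals <- data.frame(t = res$tot_t, U = res$tot_U, I = res$tot_I,
                       v = res$tot_v)
  new_trajectory(
    kind = "abm", model = paste0("abm_", params$movement), params = params,
    x = if (params$dimension == 1L) x else x, times = res$times,
    u = res$U / meas, i = res$I / meas, v = res$v, totals = totals,
    radial = FALSE, nx = nx, ny = ny,
    extra = list(seed = seed, r = as.vector(r), counts_U = res$U,
                 counts_I = res$I))
}

#' Run a seeded ensemble of agent-based replicates
#'
#' Repeats [abm_simulate()] for seeds `base_seed, base_seed + 1, ...` and
#' collects, per replicate, the first time the total uninfected count hits
#' zero (`Inf` if never — uninfected extinction is absorbing since no new
#' cancer cells can arise afterwards), the first and last times the infected
#' count is zero after the infection has started, and the final totals.
#' Sub-sampled total-count time series are kept for the control-probability
#' estimators.
#'
#' @inheritParams abm_simulate
#' @param M Number of replicates (>= 1).
#' @param base_seed Seed of the first replicate.
#' @param totals_every Keep the totals series every this many steps.
#' @return An `ov_ensemble`: list with `replicates` (data frame
#'   `seed, t_ext_U, first_I0, last_I0, final_U, final_I`), matrices
#'   `tot_U`, `tot_I` (times by replicates) on the sub-sampled time grid
#'   `totals_t`, plus `horizon` and `params`.
#' @export
abm_ensemble <- function(params, ic = initial_condition(params),
                         L = NULL, horizon, M, base_seed = 1L,
                         record_every = NULL, totals_every = NULL) {
  stopifnot(M >= 1)
  nsteps <- round(horizon / params$tau)
  if (is.null(totals_every)) totals_every <- max(1L, floor(nsteps / 400))
  keep <- seq(1L, nsteps + 1L, by = totals_every)
  tot_U <- tot_I <- matrix(NA_real_, length(keep), M)
  reps <- data.frame(seed = integer(M), t_ext_U = numeric(M),
                     first_I0 = numeric(M), last_I0 = numeric(M),
                     final_U = numeric(M), final_I = numeric(M))
  totals_t <- NULL
  for (m in seq_len(M)) {
    seed <- base_seed + m - 1L
    tr <- abm_simulate(params, ic = ic, L = L, horizon = horizon, seed = seed,
                       record_every = record_every %||% nsteps)
    tt <- tr$totals
    if (is.null(totals_t)) totals_t <- tt$t[keep]
    tot_U[, m] <- tt$U[keep]
    tot_I[, m] <- tt$I[keep]
    ext <- which(tt$U == 0)
    started <- which(tt$I > 0)
    after <- if (length(started)) which(tt$I == 0 & seq_along(tt$I) > started[1]) else integer(0)
    reps$seed[m] <- seed
    reps$t_ext_U[m] <- if (length(ext)) tt$t[ext[1]] else Inf
    reps$first_I0[m] <- if (length(after)) tt$t[after[1]] else Inf
    reps$last_I0[m] <- if (length(after)) tt$t[after[length(after)]] else Inf
    reps$final_U[m] <- tt$U[nrow(tt)]
    reps$final_I[m] <- tt$I[nrow(tt)]
  }
  structure(list(replicates = reps, totals_t = totals_t,
                 tot_U = tot_U, tot_I = tot_I,
                 horizon = horizon, params = params, M = M),
            class = "ov_ensemble")
}

#' @export
print.ov_ensemble <- function(x, ...) {
  surv <- sum(!is.finite(x$replicates$t_ext_U))
  cat("<ov_ensemble> M = ", x$M, ", horizon = ", x$horizon, " h; ",
      surv, " replicate(s) with surviving tumour\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
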