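#' Infection invasion speed for the quasi-steady (two-species) model
#'
#' Linearising the quasi-steady system about a uniform uninfected background
#' `u0` gives the pulled-front speed `c = 2 sqrt(D_U (beta_tilde u0/K - q))`;
#' invasion requires `beta_tilde u0/K > q`.
#'
#' @inheritParams beta_tilde
#' @param background_u Uninfected density ahead of the front (default `K`).
#' @return An `ov_wave` list with `speed` (mm/h; `NA` with
#'   `invasion = FALSE` when the invasion condition fails) and a `method` tag.
#' @export
wave_speed_two_species <- function(params, background_u = params$K) {
  r <- beta_tilde(params) * background_u / params$K - params$q
  if (r <= 0) {
    return(structure(list(speed = NA_real_, invasion = FALSE,
                          method = "two_species_closed_form"),
                     class = "ov_wave"))
  }
  structure(list(speed = 2 * sqrt(params$D_U * r), invasion = TRUE,
                 method = "two_species_closed_form"), class = "ov_wave")
}

# growth rate of the (i, v) linearisation at spatial decay rate lambda:
# largest eigenvalue of [[D_U l^2 - q, beta u0/K], [alpha q, D_v l^2 - q_v]]
linear_growth_rate <- function(lambda, params, background_u) {
  a11 <- params$D_U * lambda^2 - params$q
  a12 <- params$beta * background_u / params$K
  a21 <- params$alpha * params$q
  a22 <- params$D_v * lambda^2 - params$q_v
  tr <- a11 + a22
  disc <- (a11 - a22)^2 + 4 * a12 * a21
  (tr + sqrt(disc)) / 2
}

#' Infection invasion speed for the explicit-virus (three-species) model
#'
#' Linear-determinacy (pulled front) computation: linearise the explicit-virus
#' system about `(u0, 0, 0)`; for an exponential profile with decay rate
#' `lambda`, the infected/virus subsystem grows at the largest eigenvalue
#' `mu(lambda)` of `[[D_U lambda^2 - q, beta u0/K], [alpha q,
#' D_v lambda^2 - q_v]]`, so the envelope speed is `c(lambda) =
#' mu(lambda)/lambda` and the selected minimal speed is the bracketed minimum
#' over `lambda > 0` (searched on `log lambda` in `[1e-2, 1e3]` 1/mm). As the
#' clearance rate grows at fixed `alpha/q_v`, the speed converges to
#' [wave_speed_two_species()].
#'
#' @inheritParams wave_speed_two_species
#' @return An `ov_wave` with `speed`, the minimising decay rate
#'   `lambda_star` (1/mm) and `method`; `invasion = FALSE` when no positive
#'   growth exists.
#' @export
wave_speed_three_species <- function(params, background_u = params$K) {
  mu0 <- linear_growth_rate(1e-8, params, background_u)
  if (mu0 <= 0) {
    return(structure(list(speed = NA_real_, lambda_star = NA_real_,
                          invasion = FALSE, method = "linear_determinacy"),
                     class = "ov_wave"))
  }
  obj <- function(loglam) {
    lam <- exp(loglam)
    mu <- linear_growth_rate(lam, params, background_u)
    if (mu <= 0) return(Inf)
    mu / lam
  }
  opt <- stats::optimize(obj, c(log(1e-2), log(1e3)), tol = 1e-10)
  structure(list(speed = opt$objective, lambda_star = exp(opt$minimum),
                 invasion = TRUE, method = "linear_determinacy"),
            class = "ov_wave")
}

#' @export
print.ov_wave <- function(x, ...) {
  if (isFALSE(x$invasion)) {
    cat("<ov_wave> no invasion (", x$method, ")\n", sep = "")
  } else {
    cat("<ov_wave> c = ", format(x$speed, digits = 4), " mm/h (", x$method,
        ")\n", sep = "")
  }
  invisible(x)
}

#' Uninfected density at the back of the invasion front
#'
#' The uninfected peak left behind the infection wave settles at the density
#' `u_bar` at which the infection travels exactly at the untreated tumour
#' speed `2 sqrt(D_U p)`. For the quasi-steady model this is the closed form
#' `u_bar = (q + p) K / beta_tilde = u* + p K / beta_tilde`; for the
#' explicit-virus model it is the root of
#' `wave_speed_three_species(u_bar) = 2 sqrt(D_U p)` bracketed in
#' `(q K / beta_tilde, K)`, and is at most the two-species value.
#'
#' @inheritParams beta_tilde
#' @param model `"U2"` (closed form) or `"U3"` (root-finding).
#' @return The density `u_bar` (same units as `K`).
#' @export
front_density <- function(params, model = c("U2", "U3")) {
  model <- match.arg(model)
  bt <- beta_tilde(params)
  if (bt <= params$q) {
    stop("no invasion: beta_tilde <= q", call. = FALSE)
  }
  if (model == "U2") {
    return((params$q + params$p) * params$K / bt)
  }
  target <- 2 * sqrt(params$D_U * params$p)
  g <- function(u) wave_speed_three_species(params, background_u = u)$speed - target
  lo <- params$q * params$K / bt
  hi <- params$K
  g_lo <- tryCatch(g(lo * (1 + 1e-10)), error = function(e) NA_real_)
  g_hi <- g(hi)
  if (!is.finite(g_lo)) g_lo <- -target
  if (is.na(g_lo) || is.na(g_hi) || g_lo * g_hi > 0) {
    stop("front density root not bracketed in (qK/beta_tilde, K)",
         call. = FALSE)
  }
  stats::uniroot(g, c(lo * (1 + 1e-10), hi), tol = 1e-10)$root
}

#' Untreated tumour front speed
#'
#' The invasion speed of an uninfected tumour into empty tissue:
#' `2 sqrt(D_U p)` for undirected movement (classical pulled front) and
#' `sqrt(D_P p / 2)` for pressure-driven movement (sharp-interface nonlinear
#' diffusion front). For the pressure rule under active treatment the front
#' density differs from `K` and the speed scales with it; pass
#' `effective_density` to evaluate that experimental variant (no closed-form
#' reference exists for it here).
#'
#' @inheritParams beta_tilde
#' @param effective_density Optional front density replacing `K` in the
#'   pressure-driven formula (experimental; only meaningful for
#'   `movement = "pressure"`).
#' @return Speed (mm/h).
#' @export
untreated_front_speed <- function(params, effective_density = NULL) {
  if (params$movement == "undirected") {
    2 * sqrt(params$D_U * params$p)
  } else {
    scale <- if (is.null(effective_density)) 1 else effective_density / params$K
    sqrt(params$D_P * params$p * scale / 2)
  }
}

#' Track an invasion front on a trajectory
#'
#' Locates, at each recorded time, the outermost grid position at which the
#' chosen species density is at least `level`, and fits the front speed by
#' least squares over a time window.
#'
#' @param traj An `ov_trajectory` (1D or radial; 2D lattices are reduced to
#'   radial profiles via the site radii).
#' @param species `"u"`, `"i"` or `"total"`.
#' @param level Detection threshold (density); default `0.05 * K`.
#' @param window Time window `c(from, to)` for the speed fit; default the
#'   last half of the trajectory.
#' @return A list with `times`, `position` (front position per recorded time,
#'   `NA` where undetected) and `speed` (fitted slope; `NA` when fewer than 3
#'   detections fall in the window).
#' @export
track_front <- function(traj, species = c("u", "i", "total"),
                        level = 0.05 * traj$params$K, window = NULL) {
  species <- match.arg(species)
  stopifnot(inherits(traj, "ov_trajectory"))
  if (length(traj$times) < 3) {
    stop("trajectory must have at least 3 recorded times", call. = FALSE)
  }
  dens <- switch(species, u = traj$u, i = traj$i, total = traj$u + traj$i)
  pos2d <- !is.null(traj$ny) && traj$ny > 1L
  coord <- if (pos2d) traj$r else abs(traj$x)
  position <- vapply(seq_along(traj$times), function(k) {
    hit <- which(dens[k, ] >= level)
    if (length(hit) == 0) NA_real_ else max(coord[hit])
  }, numeric(1))
  if (is.null(window)) {
    window <- c(max(traj$times) / 2, max(traj$times))
  }
  sel <- which(traj$times >= window[1] & traj$times <= window[2] &
                 !is.na(position))
  speed <- if (length(sel) >= 3) {
    unname(stats::coef(stats::lm(position[sel] ~ traj$times[sel]))[2])
  } else {
    NA_real_
  }
  list(times = traj$times, position = position, speed = speed, level = level)
}
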