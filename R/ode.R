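#' Right-hand sides of the non-spatial models
#'
#' Full model (`u`, `i`, `v`): logistic growth of uninfected cells with
#' infection `beta*u*v/K`, lysis of infected cells at rate `q`, viral
#' production `alpha*q*i` and clearance `q_v*v`. Reduced model (`u`, `i`):
#' the quasi-steady virus collapsed into the cell-to-cell rate [beta_tilde()].
#'
#' @inheritParams beta_tilde
#' @param y State vector: `c(u, i, v)` (full) or `c(u, i)` (reduced).
#' @param model `"full"` or `"reduced"`.
#' @return Time derivative of `y`.
#' @export
ode_rhs <- function(y, params, model = c("full", "reduced")) {
  model <- match.arg(model)
  K <- params$K
  u <- y[1]
  i <- y[2]
  growth <- params$p * u * (1 - (u + i) / K)
  if (model == "full") {
    v <- y[3]
    inf <- params$beta / K * u * v
    c(growth - inf, inf - params$q * i,
      params$alpha * params$q * i - params$q_v * v)
  } else {
    inf <- beta_tilde(params) / K * u * i
    c(growth - inf, inf - params$q * i)
  }
}

ode_jacobian <- function(y, params, model = c("full", "reduced")) {
  model <- match.arg(model)
  K <- params$K
  p <- params$p
  u <- y[1]
  i <- y[2]
  if (model == "full") {
    v <- y[3]
    b <- params$beta
    matrix(c(
      p * (1 - (2 * u + i) / K) - b * v / K, -p * u / K, -b * u / K,
      b * v / K, -params$q, b * u / K,
      0, params$alpha * params$q, -params$q_v),
      nrow = 3, byrow = TRUE)
  } else {
    bt <- beta_tilde(params)
    matrix(c(
      p * (1 - (2 * u + i) / K) - bt * i / K, -p * u / K - bt * u / K,
      bt * i / K, bt * u / K - params$q),
      nrow = 2, byrow = TRUE)
  }
}

#' Equilibria of the non-spatial models
#'
#' Both models share three equilibria: extinction `(0, 0)`, the infection-free
#' state `(K, 0)`, and the coexistence point
#' `u* = q K / beta_tilde`, `i* = p K (beta_tilde - q) /
#' (beta_tilde (beta_tilde + p))`; the full model adds the quasi-steady viral
#' component `v* = (alpha q / q_v) i*`. The coexistence point is flagged
#' non-physical when `beta_tilde < q` (negative `i*`).
#'
#' @inheritParams ode_rhs
#' @return A list of `ov_equilibrium` objects (fields `y`, `physical`,
#'   `classification`, `eigenvalues`), classified by [ode_stability()].
#' @export
ode_equilibria <- function(params, model = c("full", "reduced")) {
  model <- match.arg(model)
  K <- params$K
  bt <- beta_tilde(params)
  if (bt == 0) stop("beta_tilde = 0: no interior equilibrium", call. = FALSE)
  u_star <- params$q * K / bt
  i_star <- params$p * K * (bt - params$q) / (bt * (bt + params$p))
  pts <- if (model == "full") {
    v_of <- function(i) params$alpha * params$q / params$q_v * i
    list(c(u = 0, i = 0, v = 0), c(u = K, i = 0, v = 0),
         c(u = u_star, i = i_star, v = v_of(i_star)))
  } else {
    list(c(u = 0, i = 0), c(u = K, i = 0), c(u = u_star, i = i_star))
  }
  lapply(pts, function(y) {
    eq <- structure(list(y = y, physical = all(y >= 0), model = model),
                    class = "ov_equilibrium")
    cl <- ode_stability(eq, params, model)
    eq$classification <- cl$classification
    eq$eigenvalues <- cl$eigenvalues
    eq
  })
}

#' @export
print.ov_equilibrium <- function(x, ...) {
  cat("<ov_equilibrium> (", paste(signif(x$y, 4), collapse = ", "), ") ",
      x$classification, if (!x$physical) " [non-physical]", "\n", sep = "")
  invisible(x)
}

#' Linear stability of an equilibrium
#'
#' Classifies by the sign of the largest real part of the Jacobian
#' eigenvalues; a largest real part within `1e-10` of zero is reported as
#' `"marginal"`.
#'
#' @param eq An `ov_equilibrium` (or a bare state vector).
#' @inheritParams ode_rhs
#' @return A list with `classification` (`"stable"`, `"unstable"` or
#'   `"marginal"`) and the `eigenvalues`.
#' @export
ode_stability <- function(eq, params, model = c("full", "reduced")) {
  model <- match.arg(model)
  y <- if (inherits(eq, "ov_equilibrium")) eq$y else eq
  J <- ode_jacobian(y, params, model)
  ev <- eigen(J, only.values = TRUE)$values
  mx <- max(Re(ev))
  cl <- if (abs(mx) < 1e-10) "marginal" else if (mx < 0) "stable" else "unstable"
  list(classification = cl, eigenvalues = ev)
}

interior_equilibrium <- function(params, model = "full") {
  eqs <- ode_equilibria(params, model)
  eqs[[3]]
}

# Real part of the critical (complex) eigenvalue pair at the coexistence
# equilibrium of the full model, as a function of alpha.
hopf_re <- function(alpha, params) {
  pr <- params
  pr$alpha <- alpha
  eq <- interior_equilibrium(pr, "full")
  ev <- eq$eigenvalues
  cplx <- ev[abs(Im(ev)) > 1e-12]
  if (length(cplx) == 0) return(max(Re(ev)))
  max(Re(cplx))
}

#' Bifurcation scan of the full model in the burst size
#'
#' For each burst size `alpha`: locate the coexistence equilibrium, classify
#' its stability, and — where it is unstable — integrate the full non-spatial
#' model past a transient and record the minimum and maximum of the uninfected
#' density over the residual window (the limit-cycle envelope). The Hopf point
#' is bracketed by the sign change of the real part of the critical eigenvalue
#' pair and refined by bisection to `|Re| < 1e-8`.
#'
#' @inheritParams ode_rhs
#' @param alpha_values Sorted vector of burst sizes to scan.
#' @param horizon Total integration time (h) for the cycle envelope.
#' @param transient Initial time span (h) discarded before measuring.
#' @param rtol Integrator relative tolerance.
#' @return An `ov_bifurcation`: data frame `diagram` with columns `alpha`,
#'   `u_eq`, `stable`, `u_min_cycle`, `u_max_cycle`, plus `alpha_hopf` (`NA`
#'   when no sign change is bracketed by the scanned range).
#' @export
hopf_scan <- function(params, alpha_values, horizon = 1.5e4,
                      transient = 1e4, rtol = 1e-9) {
  stopifnot(!is.unsorted(alpha_values))
  res <- data.frame(alpha = alpha_values, u_eq = NA_real_, stable = NA,
                    u_min_cycle = NA_real_, u_max_cycle = NA_real_)
  re_vals <- numeric(length(alpha_values))
  for (k in seq_along(alpha_values)) {
    pr <- params
    pr$alpha <- alpha_values[k]
    eq <- interior_equilibrium(pr, "full")
    res$u_eq[k] <- eq$y[["u"]]
    res$stable[k] <- eq$classification == "stable"
    re_vals[k] <- hopf_re(alpha_values[k], params)
    if (eq$classification == "unstable" && eq$physical) {
      y0 <- c(0.9 * pr$K, 1, pr$alpha * pr$q / pr$q_v)
      sol <- rk45_integrate(function(t, y) ode_rhs(y, pr, "full"),
                            y0, 0, horizon, rtol = rtol, atol = 1e-10,
                            hmax = 5, record_from = transient)
      if (length(sol$t) > 10) {
        res$u_min_cycle[k] <- min(sol$y[, 1])
        res$u_max_cycle[k] <- max(sol$y[, 1])
      } else {
        warning("cycle amplitude not resolved at alpha = ", pr$alpha,
                call. = FALSE)
      }
    }
  }
  alpha_hopf <- NA_real_
  sgn <- sign(re_vals)
  flip <- which(diff(sgn) != 0 & sgn[-length(sgn)] != 0)
  if (length(flip)) {
    k <- flip[1]
    lo <- alpha_values[k]
    hi <- alpha_values[k + 1]
    f_lo <- re_vals[k]
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      f_mid <- hopf_re(mid, params)
      if (abs(f_mid) < 1e-8) break
      if (sign(f_mid) == sign(f_lo)) {
        lo <- mid
        f_lo <- f_mid
      } else hi <- mid
    }
    alpha_hopf <- (lo + hi) / 2
  }
  structure(list(diagram = res, alpha_hopf = alpha_hopf, params = params),
            class = "ov_bifurcation")
}

#' @export
print.ov_bifurcation <- function(x, ...) {
  cat("<ov_bifurcation> ", nrow(x$diagram), " alpha values; Hopf at alpha ~ ",
      format(x$alpha_hopf), "\n", sep = "")
  print(utils::head(x$diagram, 10))
  invisible(x)
}
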