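new_trajectory <- function(kind, model, params, x, times, u, i, v = NULL,
                           totals, radial = FALSE, nx = NULL, ny = NULL,
                           extra = list()) {
  structure(c(list(kind = kind, model = model, params = params, x = x,
                   times = times, u = u, i = i, v = v, totals = totals,
                   radial = radial, nx = nx, ny = ny), extra),
            class = "ov_trajectory")
}

#' @export
print.ov_trajectory <- function(x, ...) {
  cat("<ov_trajectory> ", x$model, " (", x$kind, "), ",
      length(x$times), " recorded times, t in [0, ",
      format(max(x$times)), "] h\n", sep = "")
  n <- nrow(x$totals)
  cat(sprintf("  final totals: U = %.4g, I = %.4g\n",
              x$totals$U[n], x$totals$I[n]))
  invisible(x)
}

#' Total tumour burden over time
#'
#' Sum of uninfected and infected cells at each time the simulator tracked:
#' integer totals for the agent-based model, `integral of (u + i)` with the
#' appropriate spatial measure (dx in 1D, 2*pi*r*dr radial) for the PDE
#' solutions.
#'
#' @param traj An `ov_trajectory` from [abm_simulate()] or [pde_solve()].
#' @return A data frame with columns `t` and `total`.
#' @export
total_cells <- function(traj) {
  stopifnot(inherits(traj, "ov_trajectory"))
  data.frame(t = traj$totals$t, total = traj$totals$U + traj$totals$I)
}

#' Extract a density profile at a recorded time
#'
#' @param traj An `ov_trajectory`.
#' @param species `"u"`, `"i"` or `"v"`.
#' @param t Requested time (h); the nearest recorded frame is used.
#' @return For 1D/radial trajectories, a numeric vector over `traj$x`; for 2D
#'   lattices, an `nx` by `ny` matrix.
#' @export
profile_at <- function(traj, species = c("u", "i", "v"), t) {
  species <- match.arg(species)
  k <- which.min(abs(traj$times - t))
  f <- traj[[species]]
  if (is.null(f)) stop("trajectory has no `", species, "` field", call. = FALSE)
  row <- f[k, ]
  if (!is.null(traj$nx) && traj$nx * traj$ny == length(row) && traj$ny > 1) {
    return(matrix(row, traj$nx, traj$ny))
  }
  row
}
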