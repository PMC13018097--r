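# Adaptive Dormand-Prince RK5(4) integrator. Small and self-contained: the
# non-spatial systems here are 2-3 smooth equations, far from needing an
# external solver, and amplitude extraction near the Hopf point wants a tight,
# controllable tolerance.

rk45_integrate <- function(f, y0, t0, t1, rtol = 1e-9, atol = 1e-12,
                           hmax = (t1 - t0) / 10, hini = NULL,
                           record_from = t0) {
  # Dormand-Prince coefficients
  a <- list(
    c(1 / 5),
    c(3 / 40, 9 / 40),
    c(44 / 45, -56 / 15, 32 / 9),
    c(19372 / 6561, -25360 / 2187, 64448 / 6561, -212 / 729),
    c(9017 / 3168, -355 / 33, 46732 / 5247, 49 / 176, -5103 / 18656),
    c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84))
  b5 <- c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84, 0)
  b4 <- c(5179 / 57600, 0, 7571 / 16695, 393 / 640, -92097 / 339200,
          187 / 2100, 1 / 40)
  cc <- c(0, 1 / 5, 3 / 10, 4 / 5, 8 / 9, 1, 1)

  t <- t0
  y <- y0
  h <- hini %||% min(hmax, (t1 - t0) / 100)
  ts <- numeric(0)
  ys <- NULL
  k1 <- f(t, y)
  nmax <- 5e6
  it <- 0L
  while (t < t1) {
    it <- it + 1L
    if (it > nmax) stop("rk45: step limit exceeded", call. = FALSE)
    if (t + h > t1) h <- t1 - t
    ks <- matrix(0, length(y), 7)
    ks[, 1] <- k1
    for (s in 2:7) {
      yy <- y + h * as.vector(ks[, 1:(s - 1), drop = FALSE] %*%
                                if (s <= 6) a[[s - 1]] else b5[1:6])
      ks[, s] <- f(t + cc[s] * h, yy)
    }
    y5 <- y + h * as.vector(ks %*% b5)
    y4 <- y + h * as.vector(ks %*% b4)
    sc <- atol + rtol * pmax(abs(y), abs(y5))
    err <- sqrt(mean(((y5 - y4) / sc)^2))
    if (err <= 1 || h <= 1e-12 * max(1, abs(t))) {
      t <- t + h
      y <- y5
      k1 <- ks[, 7] # FSAL
      if (t >= record_from) {
        ts <- c(ts, t)
        ys <- rbind(ys, y)
      }
    }
    fac <- if (err == 0) 5 else 0.9 * err^(-0.2)
    h <- min(hmax, h * min(5, max(0.2, fac)))
  }
  list(t = ts, y = ys)
}
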