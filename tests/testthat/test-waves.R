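test_that("closed-form speeds: two-species, untreated fronts, thresholds", {
  p <- pair_high()
  bt <- beta_tilde(p)
  # arithmetic oracle 2*sqrt(D_U*(bt - q))
  expect_equal(wave_speed_two_species(p)$speed,
               2 * sqrt(1.88e-4 * (bt - 4.17e-2)), tolerance = 1e-12)
  # at the invasion threshold the speed vanishes / invasion flag drops
  w0 <- wave_speed_two_species(p, background_u = p$q * p$K / bt)
  expect_false(w0$invasion)
  # untreated speeds: 2*sqrt(D_U*p) and sqrt(D_P*p/2)
  expect_equal(untreated_front_speed(model_params()),
               2 * sqrt(1.88e-4 * 1.87e-2), tolerance = 1e-12)
  expect_equal(untreated_front_speed(model_params(movement = "pressure")),
               sqrt(1.504e-3 * 1.87e-2 / 2), tolerance = 1e-12)
  p0 <- model_params()
  p0$p <- 0
  expect_identical(untreated_front_speed(p0), 0)
})

test_that("three-species dispersion: closed-form identity at D_v = D_U", {
  # with equal diffusivities mu(lambda) = D_U*lambda^2 + nu with nu the
  # largest eigenvalue of the reaction matrix, so c* = 2*sqrt(D_U*nu);
  # independent oracle: the minimisation never uses this reduction
  for (pars in list(pair_high(), pair_low(),
                    model_params(alpha = 1000, q_v = 0.3))) {
    pars$D_v <- pars$D_U
    q <- pars$q; qv <- pars$q_v; bt <- beta_tilde(pars)
    nu <- (-(q + qv) + sqrt((qv - q)^2 + 4 * bt * qv)) / 2
    expect_equal(wave_speed_three_species(pars)$speed, 2 * sqrt(pars$D_U * nu),
                 tolerance = 1e-6)
  }
})

test_that("three-species speed converges to the two-species limit in q_v", {
  # fixed alpha/q_v = 3500; D_v = 1e-2 >> D_U: approach from above
  c2 <- wave_speed_two_species(pair_high())$speed
  cs <- vapply(c(1, 10, 100, 1000), function(qv) {
    wave_speed_three_species(model_params(alpha = 3500 * qv, q_v = qv))$speed
  }, numeric(1))
  expect_true(all(cs > c2))
  expect_true(all(diff(cs) < 0)) # monotone convergence along the tail
  expect_equal(cs[4], c2, tolerance = 3e-3)
  # ordering by viral diffusivity at moderate q_v
  expect_gt(wave_speed_three_species(pair_high())$speed, c2)       # D_v > D_U
  p_slow <- model_params(alpha = 3500, q_v = 1, D_v = 1e-5)
  expect_lt(wave_speed_three_species(p_slow)$speed, c2)            # D_v < D_U
  # q_v -> 0 at fixed ratio: speed collapses
  tiny <- wave_speed_three_species(model_params(alpha = 3500 * 1e-6,
                                                q_v = 1e-6))$speed
  expect_lt(tiny, 0.2 * c2)
})

test_that("c*(q_v) has an interior maximum in the reference sweep", {
  qvs <- c(1e-3, 1e-2, 0.1, 1, 10, 100)
  cs <- vapply(qvs, function(qv) {
    wave_speed_three_species(model_params(alpha = 3500 * qv, q_v = qv))$speed
  }, numeric(1))
  k <- which.max(cs)
  expect_gt(k, 1)
  expect_lt(k, length(qvs))
  # minimiser reproducible under bracket perturbation (smooth unimodal c(lambda))
  p <- pair_high()
  w <- wave_speed_three_species(p)
  obj <- function(lam) oncowave:::linear_growth_rate(lam, p, p$K) / lam
  for (eps in c(0.9, 1.1)) {
    expect_gt(obj(w$lambda_star * eps), w$speed - 1e-12)
  }
})

test_that("no-invasion marker when the background cannot be invaded", {
  p_lo <- model_params(alpha = 100) # beta_tilde < q
  expect_false(wave_speed_two_species(p_lo)$invasion)
  expect_false(wave_speed_three_species(p_lo)$invasion)
})

test_that("front densities: closed form, trivial limits, model ordering", {
  p <- pair_high()
  bt <- beta_tilde(p)
  expect_equal(front_density(p, "U2"), (p$q + p$p) * p$K / bt,
               tolerance = 1e-12)
  # p -> 0 collapses to u* = qK/beta_tilde
  p0 <- pair_high()
  p0$p <- 1e-14
  expect_equal(front_density(p0, "U2"), p0$q * p0$K / bt, tolerance = 1e-6)
  # by construction, the two-species background density makes the infection
  # travel exactly at the untreated speed
  ubar <- front_density(p, "U2")
  expect_equal(wave_speed_two_species(p, background_u = ubar)$speed,
               2 * sqrt(p$D_U * p$p), tolerance = 1e-12)
  # explicit-virus front density solves the dispersion relation and sits
  # below the two-species value at high viral diffusivity
  ubar3 <- front_density(p, "U3")
  expect_equal(wave_speed_three_species(p, background_u = ubar3)$speed,
               2 * sqrt(p$D_U * p$p), tolerance = 1e-6)
  expect_lt(ubar3, ubar)
})

test_that("track_front measures positions and speeds on synthetic data", {
  p <- model_params()
  # a front moving at exactly 0.01 mm/h on a fabricated trajectory
  x <- seq(-10, 10, 0.1)
  times <- seq(0, 400, 50)
  u <- t(vapply(times, function(t) ifelse(abs(x) <= 2 + 0.01 * t, 600, 0),
                numeric(length(x))))
  traj <- structure(list(kind = "pde", model = "U2", params = p, x = x,
                         times = times, u = u, i = u * 0, v = NULL,
                         totals = data.frame(t = times,
                                             U = rowSums(u) * 0.1,
                                             I = 0),
                         radial = FALSE, nx = length(x), ny = 1L),
                    class = "ov_trajectory")
  ft <- track_front(traj, "u", level = 300)
  expect_equal(ft$speed, 0.01, tolerance = 0.05)
  # stationary profile: slope 0
  u2 <- u
  u2[] <- rep(u[1, ], each = length(times))
  traj$u <- u2
  expect_equal(track_front(traj, "u", level = 300)$speed, 0, tolerance = 1e-10)
  # undetected front: empty result
  expect_true(is.na(track_front(traj, "i", level = 300)$speed))
})
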