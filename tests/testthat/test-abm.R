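test_that("same seed reproduces a run bitwise; horizon 0 returns initial state", {
  p <- reference_params()
  a <- abm_simulate(p, L = 4, horizon = 20, seed = 7)
  b <- abm_simulate(p, L = 4, horizon = 20, seed = 7)
  expect_identical(a$totals, b$totals)
  expect_identical(a$u, b$u)
  z <- abm_simulate(p, L = 4, horizon = 0, seed = 1)
  expect_length(z$times, 1)
  expect_equal(z$totals$U, sum(z$counts_U[1, ]))
})

test_that("conservation with all processes off; movement-only preserves totals", {
  p <- model_params(p = 1e-12, q = 1e-12, beta = 1e-12, alpha = 0,
                    D_U = 0, R_v = 0)
  # theta = 0, demography/lysis/infection effectively off
  tr <- abm_simulate(p, L = 4, horizon = 10, seed = 3)
  expect_true(all(tr$totals$U == tr$totals$U[1]))
  expect_true(all(tr$totals$I == 0))
  # movement on, demography off: totals still conserved exactly
  p2 <- model_params(p = 1e-12, q = 1e-12, beta = 1e-12, alpha = 0, R_v = 0)
  tr2 <- abm_simulate(p2, L = 6, horizon = 50, seed = 3)
  expect_true(all(tr2$totals$U == tr2$totals$U[1]))
})

test_that("no infection without virus contact; beta = 0 keeps I at zero", {
  p <- model_params(beta = 1e-300) # effectively zero, keeps validation happy
  p$beta <- 0
  tr <- abm_simulate(p, L = 4, horizon = 40, seed = 2)
  expect_true(all(tr$totals$I == 0))
})

test_that("viral decay is exact geometric when alpha = 0 and v is uniform", {
  # closed-form oracle: uniform v has zero Laplacian, no release, so
  # v_n = V_0 (1 - tau q_v)^n deterministically
  p <- model_params(alpha = 0, R_v = Inf, R_u = 1, V_0 = 50)
  tr <- abm_simulate(p, L = 3, horizon = 2, seed = 1, record_every = 25)
  n_per_frame <- 25
  expected <- 50 * (1 - p$tau * p$q_v)^(n_per_frame * (seq_along(tr$times) - 1))
  mid <- which.min(abs(tr$x)) # any interior site; field stays uniform
  expect_equal(tr$v[, mid], expected, tolerance = 1e-12)
})

test_that("one-site mean-field increments match the ODE right-hand side", {
  # single site with large counts, movement off: the expected one-step
  # increments must equal tau * RHS of the non-spatial model to O(tau^2).
  # delta = 1 so counts equal densities; 50 replicates shrink the Monte Carlo
  # noise well below the asserted 2% band while the O(tau^2) cross terms sit
  # near 0.7%.
  tau <- 0.02; K <- 1e6
  u0 <- 4e5; i0 <- 2e5; v0 <- 5e5
  p <- 0.5; q <- 0.3; q_v <- 0.4; alpha <- 10; beta <- 1
  reps <- 50
  set.seed(42)
  dU <- dI <- dV <- numeric(reps)
  for (r in seq_len(reps)) {
    st <- oncowave:::abm_run_cpp(as.integer(u0), as.integer(i0), v0,
                                 1L, 1L, tau, 1, 1L,
                                 p, q, q_v, alpha, beta, K, 0, 0, FALSE,
                                 1L, 1L)
    dU[r] <- st$tot_U[2] - st$tot_U[1]
    dI[r] <- st$tot_I[2] - st$tot_I[1]
    dV[r] <- st$tot_v[2] - st$tot_v[1]
  }
  rhs_u <- p * u0 * (1 - (u0 + i0) / K) - beta / K * u0 * v0
  rhs_i <- beta / K * u0 * v0 - q * i0
  rhs_v <- alpha * q * i0 - q_v * v0
  expect_equal(mean(dU), tau * rhs_u, tolerance = 0.02)
  expect_equal(mean(dI), tau * rhs_i, tolerance = 0.02)
  expect_equal(mean(dV), tau * rhs_v, tolerance = 0.02)
})

test_that("pressure rule never moves cells up a density gradient", {
  # two-site chain, no demography: the low-density site can never lose cells
  # to the high-density one, so the high count is non-increasing
  p <- model_params(p = 1e-12, q = 1e-12, beta = 1e-12, alpha = 0, R_v = 0,
                    movement = "pressure", tau = 0.1, delta = 0.1, D_P = 5e-3)
  U0 <- as.integer(c(0, 0, 10, 80, 0, 0, 0))
  set.seed(11)
  # while the peak clearly dominates, it can only lose cells: F into a site
  # of higher density is zero by construction
  U <- U0
  for (k in 1:10) {
    res <- oncowave:::abm_run_cpp(U, integer(7), numeric(7), 7L, 1L,
                                  p$tau, p$delta, 1L,
                                  p$p, p$q, p$q_v, 0, p$beta, p$K, 0,
                                  theta_from_diffusion(p), TRUE, 1L, 1L)
    Unew <- res$U[2, ]
    expect_lte(Unew[4], U[4])
    U <- as.integer(Unew)
  }
})

test_that("non-negativity holds along a reference run", {
  p <- pair_low()
  tr <- abm_simulate(p, L = 5, horizon = 60, seed = 5)
  expect_true(all(tr$u >= 0))
  expect_true(all(tr$i >= 0))
  expect_true(all(tr$v >= 0))
})

test_that("quasi-steady ratio tracks infected density in the reference regime", {
  p <- pair_low()
  tr <- abm_simulate(p, L = 8, horizon = 300, seed = 1, record_every = 5000)
  k <- length(tr$times)
  sm <- function(z) as.numeric(stats::filter(z, rep(1 / 9, 9), sides = 2))
  ratio <- sm(tr$v[k, ] * p$q_v / (p$alpha * p$q))
  inf <- sm(tr$i[k, ])
  keep <- !is.na(ratio) & !is.na(inf)
  expect_lt(max(abs(ratio[keep] - inf[keep])), 0.15 * p$K)
})

test_that("ensemble bookkeeping: extinction times, M = 1 reduces to simulate", {
  p <- model_params(tau = 0.1) # cheap
  ens <- abm_ensemble(p, L = 4, horizon = 10, M = 1, base_seed = 9)
  tr <- abm_simulate(p, L = 4, horizon = 10, seed = 9,
                     record_every = round(10 / p$tau))
  expect_equal(ens$replicates$final_U, tail(tr$totals$U, 1))
  expect_equal(ens$replicates$final_I, tail(tr$totals$I, 1))
  # beta_tilde < q regime: infection cannot invade, tumour survives everywhere
  p2 <- model_params(alpha = 100, tau = 0.1)
  expect_lt(beta_tilde(p2), p2$q)
  ens2 <- abm_ensemble(p2, L = 4, horizon = 40, M = 3, base_seed = 1)
  expect_true(all(!is.finite(ens2$replicates$t_ext_U)))
  expect_true(all(ens2$replicates$final_U > 0))
})
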