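# Spring-tethered boundary dynamics and first-passage border stiffening.

test_that("zero boundary diffusivity leaves the edges immobile", {
  b <- simulate_boundaries(K = 0, gamma = 1, Lbar = 10, duration = 10,
                           dt = 0.01, seed = 1)
  expect_true(all(b$L1[, 1] == b$L1[1, 1]))
  expect_true(all(b$L2[, 1] == b$L2[1, 1]))
})

test_that("separation relaxes to the equilibrium width with the
           Ornstein-Uhlenbeck stationary variance", {
  K <- 1; gam <- 0.5; Lbar <- 10
  b <- simulate_boundaries(K, gam, Lbar, duration = 5000, dt = 0.05,
                           seed = 4)
  sep <- b$L2[, 1] - b$L1[, 1]
  keep <- seq(floor(length(sep) * 0.1), length(sep))
  expect_equal(mean(sep[keep]), Lbar, tolerance = 0.05)
  expect_equal(var(sep[keep]), 2 / gam, tolerance = 0.05 * 2 / gam + 0.3)
})

test_that("edge ordering is never violated", {
  b <- simulate_boundaries(K = 2, gamma = 1, Lbar = 3, duration = 500,
                           dt = 0.01, seed = 11)
  expect_true(all(b$L2 > b$L1))
})

test_that("centroid MSD grows as the integral of the modulated
           diffusivity", {
  K <- 1
  # constant phi: MSD(lag) = K * lag (time-averaged over the path)
  b <- simulate_boundaries(K, gamma = 0.5, Lbar = 10, duration = 4000,
                           dt = 0.05, seed = 2)
  cen <- (b$L1[, 1] + b$L2[, 1]) / 2
  lags <- c(200, 1000, 4000)      # in steps of dt
  msd <- vapply(lags, function(l)
    mean((cen[-seq_len(l)] - cen[seq_len(length(cen) - l)])^2),
    numeric(1))
  expect_equal(msd / (K * lags * 0.05), rep(1, 3), tolerance = 0.15)
  # sub-linear modulation: ensemble variance tracks int K phi ds
  reps <- 30
  v_end <- vapply(seq_len(reps), function(r) {
    bs <- simulate_boundaries(K, gamma = 0.5, Lbar = 10, phi = "sqrt_t",
                              duration = 200, dt = 0.05,
                              dimension = 2, seed = 100 + r)
    cen2 <- (bs$L1 + bs$L2) / 2
    mean((cen2[nrow(cen2), ] - cen2[1, ])^2)
  }, numeric(1))
  expected <- K * integrate(function(t) 1 / sqrt(t + 1), 0, 200)$value
  expect_equal(mean(v_end), expected, tolerance = 0.25 * expected)
})

test_that("frozen boundaries reduce the composed occupation to the
           fixed-territory law", {
  b <- simulate_boundaries(K = 0, gamma = 1, Lbar = 8, duration = 5,
                           dt = 0.01, seed = 1)
  xg <- seq(-6, 6, length.out = 241)
  occ <- compose_occupation(b, xg)
  inside <- abs(xg) < 4
  expect_equal(occ$density[inside], rep(1 / 8, sum(inside)),
               tolerance = 0.01)
  expect_equal(sum(diff(xg) * (head(occ$density, -1) +
                                 tail(occ$density, -1)) / 2), 1,
               tolerance = 1e-9)
})

test_that("softer springs put more occupation mass beyond the mean
           edges", {
  xg <- seq(-40, 40, length.out = 801)
  tail_mass <- vapply(c(0.5, 0.1, 0.02), function(gam) {
    b <- simulate_boundaries(K = 1, gamma = gam, Lbar = 20,
                             duration = 3000, dt = 0.05, seed = 6)
    occ <- compose_occupation(b, xg)
    sum(occ$density[abs(occ$x) > 10]) * diff(xg)[1]
  }, numeric(1))
  expect_true(all(diff(tail_mass) > 0))
})

test_that("empty boundary samples are rejected", {
  b <- simulate_boundaries(K = 0, gamma = 1, Lbar = 8, duration = 5,
                           dt = 0.01, seed = 1)
  expect_error(compose_occupation(b, seq(100, 110, length.out = 5)),
               "mass is zero")
})

test_that("border diffusivity factor decays exponentially in the active
           scent time", {
  D <- 1; L <- 2
  expect_equal(k_from_ta(D, L, 0), 1)
  ta <- c(1, 2, 4, 8)
  lk <- log(k_from_ta(D, L, ta))
  fit <- lm(lk ~ ta)
  expect_equal(unname(coef(fit)[2]), -pi^2 * D / (4 * L^2),
               tolerance = 1e-10)
  # dimensional collapse: doubling L at fixed D * T_A / L^2
  expect_equal(k_from_ta(D, 2 * L, 4 * 3), k_from_ta(D, L, 3),
               tolerance = 1e-12)
})

test_that("the leading-mode approximation matches the eigenmode survival
           at long times", {
  D <- 1; L <- 2
  ta <- seq(6, 12, by = 2)        # several multiples of the mode-1 time
  full <- k_from_ta(D, L, ta, n_modes = 60)
  lead <- k_from_ta(D, L, ta)
  slope_full <- coef(lm(log(full) ~ ta))[2]
  expect_equal(unname(slope_full), -pi^2 * D / (4 * L^2), tolerance = 0.01)
  expect_equal(full / lead, rep(4 / pi, 4), tolerance = 1e-3)
})

test_that("first-passage survival is a proper decreasing probability", {
  s <- fp_survival(1, 1, c(0, 0.1, 0.5, 1, 5))
  # the alternating series converges slowly right at t = 0
  expect_equal(s[1], 1, tolerance = 5e-3)
  expect_true(all(diff(s) < 0))
  expect_true(all(s >= 0 & s <= 1))
})

test_that("simulated TRW border diffusivity is log-linear in the active
           scent time", {
  TAs <- c(50, 100, 200, 400)
  Ks <- vapply(TAs, function(TA) {
    be <- boundary_msd_1d(400, 20, t_active = TA, steps = 8e5,
                          record_every = 20, seed = 5)
    approx(be$lag, be$msd, xout = 2000)$y / (2 * 2000)
  }, numeric(1))
  expect_lt(cor(log(Ks), TAs), -0.95)
})
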