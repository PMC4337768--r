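# Trajectory estimators: moments, Hurst exponents, steady-state and
# likelihood fits.

test_that("trajectory sets validate, sort and reject duplicates", {
  df <- data.frame(id = c(2, 1, 1), t = c(0, 5, 1), x = 1:3, y = 0)
  ts <- trajectory_set(df)
  expect_equal(ts$id, c(1, 1, 2))
  expect_equal(ts$t, c(1, 5, 0))
  expect_identical(attr(ts, "dimension"), 2L)
  expect_error(trajectory_set(data.frame(id = 1, t = c(1, 1), x = 1:2)),
               "duplicate")
  expect_error(trajectory_set(data.frame(a = 1)), "columns id, t, x")
  ts1 <- trajectory_set(data.frame(id = 1, t = 0:3, x = rnorm(4)))
  expect_identical(attr(ts1, "dimension"), 1L)
})

test_that("second moment of free diffusion follows the Einstein law", {
  D <- 0.7
  traj <- generate_anomalous(400, D_of_t = D, fix_interval = 1,
                             duration = 16, seed = 3)
  mc <- empirical_moment(traj, q = 2, lags = c(0, 2, 4, 8, 16))
  expect_equal(mc$value[1], 0)
  expect_equal(mc$value[-1] / (4 * D * mc$lag[-1]), rep(1, 4),
               tolerance = 0.1)
})

test_that("moments saturate at the intrinsic home-range plateau for
           tethered walkers", {
  L <- 1
  traj <- generate_tethered(300, potential("harmonic", L = L), D = 0.5,
                            extent = 0, fix_interval = 4, duration = 40,
                            seed = 5)
  mc <- empirical_moment(traj, q = 2, lags = c(20, 40), B = 100)
  # displacement between two independent steady-state fixes: 2 * 2 * L^2/2
  expect_equal(mc$value, rep(2 * L^2, 2), tolerance = 0.1)
})

test_that("moment estimates are invariant under row permutations", {
  traj <- generate_anomalous(20, D_of_t = 1, fix_interval = 1,
                             duration = 8, seed = 9)
  perm <- trajectory_set(as.data.frame(traj)[sample(nrow(traj)), ])
  m1 <- empirical_moment(traj, 2, c(2, 5))
  m2 <- empirical_moment(perm, 2, c(2, 5))
  expect_equal(m1$value, m2$value)
})

test_that("empty lag bins are reported, not dropped", {
  traj <- generate_anomalous(5, D_of_t = 1, fix_interval = 1,
                             duration = 5, seed = 1)
  expect_warning(mc <- empirical_moment(traj, 2, c(2, 50)), "no displacement")
  expect_equal(nrow(mc), 2L)
  expect_true(is.na(mc$value[2]))
})

test_that("the two-time Hurst relation is exact on closed-form moments", {
  # Gaussian diffusion: <|dx|^q>(t) = c_q t^{q/2}, any q
  for (q in c(0.5, 1, 2, 3.7)) {
    m1 <- 2^(q / 2); m2 <- 8^(q / 2)
    expect_equal(hurst_from_moments(m1, m2, 2, 8, q), 0.5,
                 tolerance = 1e-12)
  }
  # moment rescaling leaves H unchanged
  expect_equal(hurst_from_moments(3 * 2, 3 * 4, 1, 2, 2),
               hurst_from_moments(2, 4, 1, 2, 2))
  expect_error(hurst_from_moments(0, 1, 1, 2, 2), "positive")
})

test_that("ballistic trajectories give H = 1 exactly for every q", {
  traj <- ballistic_trajectories(8, v = 2, times = 0:16)
  h <- hurst_exponent(traj, q = c(0.5, 1, 2, 3), t1 = 2, t2 = 8, B = 0)
  expect_equal(h$H, rep(1, 4), tolerance = 1e-12)
  expect_equal(h$delta, rep(1, 4), tolerance = 1e-12)
})

test_that("Brownian walks are monofractal with H = 1/2 inside the
           bootstrap bands", {
  traj <- generate_anomalous(250, D_of_t = 1, fix_interval = 1,
                             duration = 64, seed = 13)
  h <- hurst_exponent(traj, q = c(0.5, 1, 2, 3), B = 150, seed = 2)
  expect_true(all(h$lo <= 0.5 & 0.5 <= h$hi))
  expect_true(all(abs(h$H - 0.5) < 0.05))
  expect_true(attr(h, "monofractal"))
  expect_false(any(h$implausible))
})

test_that("steady-state potential fit recovers the harmonic length and
           centre equivariantly", {
  traj <- generate_tethered(10, potential("harmonic", L = 1), D = 0.5,
                            extent = 0, fix_interval = 2, duration = 40,
                            seed = 21)
  f <- fit_steady_state(traj, "harmonic")
  expect_equal(f$L, 1, tolerance = 0.1)
  expect_equal(unname(f$centre["x"]), 0, tolerance = 0.1)
  shifted <- as.data.frame(traj)
  shifted$x <- shifted$x + 5
  f2 <- fit_steady_state(trajectory_set(shifted), "harmonic")
  # equivariance holds up to the simplex termination precision
  expect_equal(unname(f2$centre["x"] - f$centre["x"]), 5, tolerance = 1e-4)
  expect_equal(f2$L, f$L, tolerance = 1e-4)
})

test_that("steady-state fit error shrinks with sample size", {
  err_at <- function(n, reps = 6) {
    vapply(seq_len(reps), function(r) {
      traj <- generate_tethered(1, potential("harmonic", L = 1), D = 0.5,
                                extent = 0, fix_interval = 1,
                                duration = n, seed = 1000 * n + r)
      abs(fit_steady_state(traj, "harmonic")$L - 1)
    }, numeric(1))
  }
  med <- vapply(c(500, 2000, 8000), function(n) median(err_at(n)),
                numeric(1))
  expect_true(all(diff(med) < 0))
})

test_that("likelihood fit recovers tethered-diffusion parameters and
           keeps its optimizer contracts", {
  traj <- generate_tethered(6, potential("harmonic", L = 2), D = 1,
                            extent = 0, fix_interval = 2, duration = 80,
                            seed = 31)
  f <- fit_likelihood(traj, B = 60, restarts = 6, seed = 7)
  expect_equal(unname(f$par["D"]), 1, tolerance = 0.35)
  expect_equal(unname(f$par["L"]), 2, tolerance = 0.15)
  # best log-likelihood is non-decreasing across accepted restarts
  expect_true(all(diff(f$trace) >= 0))
  # percentile intervals contain the point estimates
  expect_true(f$ci["D", 1] <= f$par["D"] && f$par["D"] <= f$ci["D", 2])
  expect_true(f$ci["L", 1] <= f$par["L"] && f$par["L"] <= f$ci["L", 2])
  expect_error(
    fit_likelihood(trajectory_set(data.frame(id = 1, t = 0, x = 0, y = 0))),
    "degenerate")
})

test_that("adiabatic territorial likelihood recovers the equilibrium
           width", {
  set.seed(5)
  n <- 1500; Lbar <- 10; gam <- 2
  s <- abs(rnorm(n, Lbar, sqrt(2 / gam)))
  x <- runif(n, -s / 2, s / 2)
  y <- runif(n, -s / 2, s / 2)
  traj <- trajectory_set(data.frame(id = 1, t = seq_len(n), x = x, y = y))
  f <- fit_likelihood(traj, model = "trw_adiabatic", B = 0, restarts = 6,
                      seed = 3)
  expect_equal(unname(f$par["Lbar"]), Lbar, tolerance = 0.1)
  expect_equal(unname(f$par["xc"]), 0, tolerance = 0.5)
})

test_that("high-order moments warn when the window cannot hold the
           home-range tails", {
  traj <- generate_tethered(20, potential("harmonic", L = 1), D = 0.5,
                            extent = 0, fix_interval = 2, duration = 30,
                            seed = 2)
  expect_warning(empirical_moment(traj, q = 4, lags = c(10), window = 1),
                 "biased low")
})
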