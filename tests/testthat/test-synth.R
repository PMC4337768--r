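# Synthetic-data generators and the generator-estimator consistency loop.

test_that("generators are deterministic under a fixed seed", {
  a <- generate_tethered(3, potential("harmonic", L = 1), D = 0.5,
                         extent = 4, fix_interval = 1, duration = 10,
                         seed = 7)
  b <- generate_tethered(3, potential("harmonic", L = 1), D = 0.5,
                         extent = 4, fix_interval = 1, duration = 10,
                         seed = 7)
  expect_identical(as.data.frame(a), as.data.frame(b))
  p1 <- generate_persistent(2, v = 1, T = 1, domain = list(type = "box",
                                                           lx = 3),
                            fix_interval = 0.5, duration = 5, seed = 3)
  p2 <- generate_persistent(2, v = 1, T = 1, domain = list(type = "box",
                                                           lx = 3),
                            fix_interval = 0.5, duration = 5, seed = 3)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
})

test_that("vanishing diffusivity pins walkers at their burrows", {
  traj <- generate_tethered(4, potential("harmonic", L = 1), D = 0,
                            extent = 10, fix_interval = 1, duration = 5,
                            seed = 2)
  centres <- attr(traj, "centres")
  for (i in 1:4) {
    s <- traj[traj$id == i, ]
    expect_true(all(s$x == centres$xc[i]))
    expect_true(all(s$y == centres$yc[i]))
  }
})

test_that("tethered fixes sample the Boltzmann steady state", {
  L <- 1
  traj <- generate_tethered(40, potential("harmonic", L = L), D = 0.5,
                            extent = 0, fix_interval = 5, duration = 100,
                            seed = 11)
  # thinned fixes are nearly independent draws from N(0, L^2/2)
  z <- c(traj$x, traj$y) / (L / sqrt(2))
  ks <- suppressWarnings(stats::ks.test(z, "pnorm"))
  expect_gt(ks$p.value, 0.01)
})

test_that("mark-recapture sampling windows the fixes and reports empty
           samples", {
  df <- data.frame(id = rep(1, 4), t = 1:4,
                   x = c(0.1, 5, -0.2, 0.3), y = c(0, 0, 0.1, -0.1))
  traj <- trajectory_set(df)
  p <- mark_recapture_sample(traj, G = 1)
  expect_true(all(abs(c(p$x0, p$x1)) <= 0.5))
  expect_true(all(p$lag > 0))
  expect_equal(nrow(p), 3L)     # pairs among fixes 1, 3, 4
  expect_error(mark_recapture_sample(traj, G = 0.01), "empty sample")
  expect_error(mark_recapture_sample(traj, G = 1, lag_min = 10),
               "empty sample")
})

test_that("unwindowed pair MSD of tethered walkers reaches the intrinsic
           saturation", {
  L <- 1
  traj <- generate_tethered(150, potential("harmonic", L = L), D = 0.5,
                            extent = 0, fix_interval = 4, duration = 40,
                            seed = 13)
  p <- mark_recapture_sample(traj, G = 1e6, lag_min = 6)
  sm <- saturation_msd(p)
  # two independent steady-state fixes per axis: 2 * L^2/2, twice for 2d
  expect_equal(sm$msd, 2 * L^2, tolerance = 0.08)
})

test_that("persistent walks in a box reproduce the confined eigenmode
           MSD", {
  v <- 1; T <- 1; lam <- 2
  traj <- generate_persistent(1500, v = v, T = T,
                              domain = list(type = "box", lx = lam),
                              fix_interval = 0.25, duration = 10,
                              seed = 9, turning = "axis_telegrapher")
  ts <- sort(unique(traj$t))
  X <- matrix(traj$x, nrow = length(ts))
  Y <- matrix(traj$y, nrow = length(ts))
  msd <- rowMeans((X - rep(X[1, ], each = length(ts)))^2 +
                    (Y - rep(Y[1, ], each = length(ts)))^2)
  p <- confined_walker_params(v = v / sqrt(2), T = T, lambda_x = lam)
  th <- confined_msd(p, ts)
  sel <- ts >= 0.5 & ts <= 10
  expect_lt(max(abs(msd[sel] - th[sel]) / th[sel]), 0.08)
})

test_that("uniform turning in an arena gives zero effective persistence", {
  traj <- generate_persistent(30, v = 1, T = 0.5,
                              domain = list(type = "arena", R = 3),
                              mean_cos = 0, fix_interval = 2.5,
                              duration = 100, seed = 15)
  # headings sampled every 5 persistence times are decorrelated
  cosang <- unlist(lapply(split(as.data.frame(traj), traj$id), function(s) {
    dx <- diff(s$x); dy <- diff(s$y)
    a <- atan2(dy, dx)
    cos(diff(a))
  }))
  mc <- max(mean(cosang), 0)
  expect_lt(mc, 0.1)
  steps <- unlist(lapply(split(as.data.frame(traj), traj$id), function(s)
    sqrt(diff(s$x)^2 + diff(s$y)^2)))
  expect_lt(effective_persistence(mean(steps), 3, mc), 0.2)
})

test_that("without turning the walk is ballistic between reflections", {
  traj <- generate_persistent(5, v = 2, T = 1e12,
                              domain = list(type = "box", lx = 1e6),
                              fix_interval = 1, duration = 10, seed = 4,
                              start = "centre")
  for (i in 1:5) {
    s <- traj[traj$id == i, ]
    d <- sqrt((s$x - s$x[1])^2 + (s$y - s$y[1])^2)
    expect_equal(d, 2 * s$t, tolerance = 1e-9)
  }
})

test_that("anomalous generator scales as prescribed and degenerates
           correctly", {
  # D(t) = 0: frozen walkers
  z <- generate_anomalous(3, D_of_t = function(t) 0 * t, fix_interval = 1,
                          duration = 5, seed = 1)
  expect_true(all(z$x == 0) && all(z$y == 0))
  expect_error(generate_anomalous(2, D_of_t = function(t) -1 + 0 * t,
                                  fix_interval = 1, duration = 4,
                                  seed = 1), "non-negative")
  # power-law D(t): Hurst exponent recovered across q
  traj <- generate_anomalous(250, hurst = 0.75, fix_interval = 1,
                             duration = 64, seed = 14)
  h <- hurst_exponent(traj, q = c(1, 2, 3), B = 0, t1 = 2, t2 = 32)
  expect_true(all(abs(h$H - 0.75) < 0.05))
})
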