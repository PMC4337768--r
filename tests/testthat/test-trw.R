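# Territorial random walk: avoidance rules, lattice simulation and
# territory bookkeeping.

test_that("retreat bias hits its endpoints for the whole alpha family", {
  for (a in c(1, 2, 10, Inf)) {
    expect_equal(retreat_bias(0, 1250, a), 1, info = paste("alpha", a))
    expect_equal(retreat_bias(1250, 1250, a), 0.5,
                 info = paste("alpha", a))
    expect_equal(retreat_bias(2000, 1250, a), 0.5)
  }
  # step response of the original model
  expect_equal(retreat_bias(0.99 * 1250, 1250, Inf), 1)
  # graded response decays monotonically in the mark age
  taus <- seq(0, 1250, length.out = 30)
  expect_true(all(diff(retreat_bias(taus, 1250, 2)) <= 0))
  expect_error(retreat_bias(1, 1250, 0), "positive")
})

test_that("biased-step probabilities follow the centroid geometry", {
  expect_equal(step_probabilities(c(0, 0), c(0, 0), 0.5),
               c(left = .25, right = .25, up = .25, down = .25))
  # walker due east of the centroid with certain retreat
  expect_equal(step_probabilities(c(5, 0), c(0, 0), 1),
               c(left = .5, right = 0, up = .25, down = .25))
  # sum to one for arbitrary geometry and bias
  set.seed(1)
  for (k in 1:20) {
    pr <- step_probabilities(runif(2, -10, 10), runif(2, -10, 10),
                             runif(1, 0.5, 1))
    expect_equal(sum(pr), 1, tolerance = 1e-12)
    expect_true(all(pr >= 0))
  }
  expect_error(step_probabilities(c(1, 0), c(0, 0), 0.3), "1/2")
})

test_that("spatial competition parameter is the classic ratio", {
  # 16 walkers on 25x25 at T_A = 1250 lattice steps: Z = 32, i.e.
  # 4 D T_A = 1250 site units at the lattice diffusivity D = 1/4
  expect_equal(spatial_competition(0.25, 16 / 625, 1250), 32)
  expect_equal(spatial_competition(0.25, 2 * 16 / 625, 1250), 64)
  expect_equal(spatial_competition(0, 16 / 625, 1250), 0)
})

test_that("simulation is bit-reproducible under a fixed seed", {
  cfg <- trw_config(15, 15, 4, t_active = 150, steps = 2000, seed = 42,
                    record_every = 20)
  s1 <- trw_simulate(cfg)
  s2 <- trw_simulate(cfg)
  expect_identical(s1$trajectories, s2$trajectories)
  expect_identical(s1$utilization, s2$utilization)
})

test_that("a single walker is an unbiased lattice walk with Einstein MSD", {
  cfg <- trw_config(51, 51, 1, t_active = 100, steps = 40000, seed = 3,
                    record_every = 5)
  m <- trw_msd(trw_simulate(cfg), method = "window",
               lags = c(10, 50, 100, 500))
  # 2d nearest-neighbour walk, one hop per step: MSD = t (4D with D = 1/4)
  expect_equal(m$msd / m$t, rep(1, 4), tolerance = 0.05)
})

test_that("full exclusion keeps actively marked areas pairwise disjoint", {
  cfg <- trw_config(25, 25, 16, t_active = 400, steps = 10000, seed = 5,
                    record_every = 50)
  sim <- trw_simulate(cfg)
  expect_gt(sim$overlap_checks, 100)
  expect_identical(sim$overlap_violations, 0L)
  # final-state audit from the returned mark field
  active_owners <- colSums(sim$mark_age >= 0)
  expect_true(all(active_owners <= 1))
  # no active mark is older than the active scent time
  expect_true(all(sim$mark_age <= cfg$t_active))
})

test_that("utilization distributions are normalized and territories
           stay inside the lattice", {
  cfg <- trw_config(20, 20, 6, t_active = 300, alpha = 10,
                    mode = "alpha_family", steps = 6000, seed = 8,
                    record_every = 100)
  sim <- trw_simulate(cfg)
  expect_equal(unname(rowSums(sim$utilization)), rep(1, 6),
               tolerance = 1e-12)
  terr <- sim$territory
  expect_true(all(terr$area <= 400))
  expect_true(all(terr$m_c >= 0 & terr$m_c < 20))
  expect_true(all(terr$n_c >= 0 & terr$n_c < 20))
})

test_that("graded avoidance permits overlapping marked areas", {
  cfg <- trw_config(15, 15, 6, t_active = 500, alpha = 2,
                    mode = "alpha_family", steps = 4000, seed = 2,
                    record_every = 100)
  sim <- trw_simulate(cfg)
  owners_per_site <- colSums(sim$mark_age >= 0)
  expect_gt(max(owners_per_site), 1)
})

test_that("with the avoidance response switched off walkers are free", {
  cfg <- trw_config(41, 41, 12, t_active = 200, mode = "alpha_family",
                    steps = 20000, seed = 4, record_every = 5,
                    ignore_scent = TRUE)
  m <- trw_msd(trw_simulate(cfg), method = "window",
               lags = c(50, 200, 1000))
  expect_equal(m$msd / m$t, rep(1, 3), tolerance = 0.05)
})

test_that("exclusion confines walkers relative to free motion", {
  base <- trw_config(25, 25, 16, t_active = 1250, steps = 20000, seed = 9,
                     record_every = 10)
  sim <- trw_simulate(base)
  m <- trw_msd(sim, method = "window", lags = c(5000, 10000))
  # free walkers would reach MSD ~ lag; territorial walkers stay near
  # their per-capita share of the lattice
  expect_lt(max(m$msd), 625 / 16 * 4)
})

test_that("frozen marks freeze the 1d territory edges", {
  be <- boundary_msd_1d(100, 5, t_active = 1e9, steps = 30000,
                        record_every = 10, seed = 1)
  expect_lt(max(be$msd), 1)
})

test_that("1d edge tracking returns finite edges and logs collapses", {
  be <- boundary_msd_1d(120, 4, t_active = 150, steps = 50000,
                        record_every = 10, seed = 7)
  expect_true(all(is.finite(be$msd)))
  expect_true(all(diff(be$lag) > 0))
  expect_gte(be$n_collapsed, 0)
  # edges move faster when marks decay faster (fast boundary regime)
  be_slow <- boundary_msd_1d(120, 4, t_active = 3000, steps = 50000,
                             record_every = 10, seed = 7)
  lag_probe <- 500
  v_fast <- approx(be$lag, be$msd, lag_probe)$y
  v_slow <- approx(be_slow$lag, be_slow$msd, lag_probe)$y
  expect_gt(v_fast, v_slow)
})
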