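# Confining potentials, Boltzmann steady states and the home-range
# length functional.

families_finite_moment <- c("harmonic", "log_cubed", "box_erf",
                            "hard_box", "multi_harmonic")

test_that("built-in potentials are even with their minimum at the centre", {
  for (fam in c(families_finite_moment, "logarithmic")) {
    pot <- potential(fam, L = 1.7)
    xs <- seq(0.05, 3, length.out = 40) * pot$L
    xs <- xs[xs < diff(pot$support) / 2 | !is.finite(pot$support[2])]
    expect_equal(pot$u(xs), pot$u(-xs), tolerance = 1e-12,
                 info = fam)
    expect_true(all(pot$u(xs) >= pot$u(0)), info = fam)
  }
})

test_that("harmonic Boltzmann density is a Gaussian with variance L^2/2", {
  L <- 2
  d <- boltzmann_density(potential("harmonic", L = L))
  trap <- function(y) sum(diff(d$abscissae) * (y[-1] + y[-length(y)]) / 2)
  expect_equal(trap(d$values), 1, tolerance = 1e-8)
  expect_equal(trap(d$abscissae^2 * d$values), L^2 / 2, tolerance = 1e-6)
  # pointwise against the closed-form Gaussian
  g <- stats::dnorm(d$abscissae, 0, L / sqrt(2))
  expect_equal(d$values, g, tolerance = 1e-10)
})

test_that("boltzmann_density is translation covariant", {
  for (fam in c("harmonic", "logarithmic", "box_erf")) {
    pot <- potential(fam, L = 1.3)
    x <- seq(-3, 3, length.out = 101)
    d0 <- boltzmann_density(pot, centre = 0, x = x)
    dc <- boltzmann_density(pot, centre = 0.7, x = x + 0.7)
    expect_equal(dc$values, d0$values, tolerance = 1e-12, info = fam)
  }
})

test_that("flat potentials are rejected as non-normalizable", {
  flat <- potential("custom", fun = function(x) 0 * x)
  expect_error(boltzmann_density(flat), "does not converge")
  expect_error(home_range_length(flat), "does not converge")
})

test_that("self-convolution matches closed forms for the harmonic family", {
  L <- 1.5
  f <- self_convolution(potential("harmonic", L = L))
  # zero offset: integral of exp(-2 x^2/L^2) = L sqrt(pi/2)
  expect_equal(f(0), L * sqrt(pi / 2), tolerance = 1e-9)
  # Gaussian self-convolution: f(y)/f(0) = exp(-y^2 / (2 L^2))
  ys <- c(0.3, 1, 2.5)
  expect_equal(f(ys) / f(0), exp(-ys^2 / (2 * L^2)), tolerance = 1e-8)
  # evenness for an asymmetric-looking sample of offsets
  expect_equal(f(ys), f(-ys), tolerance = 1e-10)
})

test_that("self-convolution is even for non-Gaussian families", {
  for (fam in c("logarithmic", "box_erf", "multi_harmonic")) {
    f <- self_convolution(potential(fam, L = 1))
    ys <- c(0.2, 0.9, 1.7)
    expect_equal(f(ys), f(-ys), tolerance = 1e-8, info = fam)
  }
})

test_that("home-range length functional has its symbolic values", {
  expect_equal(home_range_length(potential("harmonic", L = 2)), 2,
               tolerance = 1e-9)
  expect_equal(home_range_length(potential("hard_box", L = 1)),
               1 / sqrt(6), tolerance = 1e-9)
  expect_equal(home_range_length(potential("hard_box", L = 3.2)),
               3.2 / sqrt(6), tolerance = 1e-9)
})

test_that("real-space and reciprocal-space routes agree for every family
           with a finite second moment", {
  for (fam in families_finite_moment) {
    pot <- potential(fam, L = 1.4)
    expect_equal(home_range_length_kspace(pot), home_range_length(pot),
                 tolerance = 1e-6, info = fam)
  }
})

test_that("the Lorentzian (logarithmic) family reports its divergent
           second moment", {
  expect_error(home_range_length(potential("logarithmic", L = 1)),
               "second moment .* diverges")
})

test_that("tabulated custom potentials interpolate and extrapolate", {
  xs <- seq(-4, 4, by = 0.05)
  tab <- cbind(xs, xs^2)          # harmonic with L = 1, tabulated
  pot <- potential("custom", table = tab)
  expect_lt(abs(pot$u(0.52) - 0.52^2), 1e-3)
  # quadratic extrapolation beyond the last point recovers x^2
  expect_equal(pot$u(6), 36, tolerance = 1e-6)
  expect_equal(home_range_length(pot), 1, tolerance = 2e-3)
  # file-based round trip
  tf <- tempfile(fileext = ".txt")
  write.table(tab, tf, row.names = FALSE, col.names = FALSE)
  pot2 <- potential("custom", table = tf)
  expect_equal(pot2$u(1.3), pot$u(1.3))
})

test_that("2d separable steady state is the product of 1d densities", {
  pot <- potential("harmonic", L = 1)
  x <- seq(-2, 2, length.out = 21)
  d1 <- boltzmann_density(pot, x = x)$values
  # direct 2d normalization over the separable potential
  Z2 <- territoria:::.pot_integrate(function(z) exp(-pot$u(z)),
                                    pot$support)^2
  joint <- outer(exp(-pot$u(x)), exp(-pot$u(x))) / Z2
  expect_equal(joint, outer(d1, d1), tolerance = 1e-10)
})
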