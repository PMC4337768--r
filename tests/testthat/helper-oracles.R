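# Shared oracles, independent of the implementation paths they check.

# MSD of pure diffusion in a reflecting box of width lam, uniform start:
# eigenfunction series over odd modes
diffusion_box_msd <- function(lam, D, t, n_modes = 200) {
  out <- rep(lam^2 / 6, length(t))
  for (n in seq_len(n_modes)) {
    m <- 2 * n - 1
    out <- out - (16 * lam^2 / pi^4) / m^4 *
      exp(-m^2 * pi^2 * D * t / lam^2)
  }
  out
}

# numerical Fourier transform of the Boltzmann weight and its derivatives
# (reciprocal-space route used by the probe/motion factorization)
phat_moments <- function(pot, k) {
  s <- pot$support
  p0 <- vapply(k, function(kk) territoria:::.pot_integrate(
    function(x) exp(-pot$u(x)) * cos(kk * x), s), numeric(1))
  p1 <- vapply(k, function(kk) territoria:::.pot_integrate(
    function(x) -x * exp(-pot$u(x)) * sin(kk * x), s), numeric(1))
  p2 <- vapply(k, function(kk) territoria:::.pot_integrate(
    function(x) -x^2 * exp(-pot$u(x)) * cos(kk * x), s), numeric(1))
  list(p = p0, dp = p1, d2p = p2)
}

# straight-line (ballistic) trajectory set: |displacement| = v * t exactly
ballistic_trajectories <- function(n_animals, v, times) {
  ang <- seq(0, 2 * pi, length.out = n_animals + 1)[-1]
  trajectory_set(data.frame(
    id = rep(seq_len(n_animals), each = length(times)),
    t = rep(times, n_animals),
    x = as.vector(outer(times, v * cos(ang))),
    y = as.vector(outer(times, v * sin(ang)))))
}
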