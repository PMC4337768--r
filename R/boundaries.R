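# Adiabatic mean-field dynamics of territory edges: each axis carries a
# pair of boundaries (L1, L2) that diffuse with (possibly time-modulated)
# diffusivity K*phi(t) and are pulled by a spring toward the equilibrium
# separation Lbar. Separation and centroid decouple: the separation is an
# Ornstein-Uhlenbeck-like process reflected at zero, the centroid a free
# diffusion with variance growing as the integral of K*phi.

#' Simulate spring-tethered territory boundaries
#'
#' Euler-Maruyama integration of the stochastic system equivalent to the
#' boundary Fokker-Planck dynamics: per axis,
#' \deqn{dL_{1} = +\tfrac{\gamma}{2} K\varphi(t) (L_2 - L_1 - \bar L)\,dt
#'   + \sqrt{2K\varphi(t)}\,dW_1,}
#' \deqn{dL_{2} = -\tfrac{\gamma}{2} K\varphi(t) (L_2 - L_1 - \bar L)\,dt
#'   + \sqrt{2K\varphi(t)}\,dW_2,}
#' with reflection preventing the edges from exchanging order. With
#' constant \eqn{\varphi}, the separation relaxes to mean \eqn{\bar L}
#' (stationary variance \eqn{2/\gamma}) and the centroid MSD grows linearly
#' as \eqn{\int_0^t K\varphi(s)\,ds}; sub-linear modulations reproduce the
#' sub-diffusive boundary motion of the full lattice model
#' (\eqn{\varphi \propto t^{-1/2}} for the 1d single-file \eqn{\sqrt t}
#' scaling, \eqn{\varphi \propto 1/\ln t} for the 2d \eqn{t/\ln t} law).
#'
#' @param K boundary diffusivity (length^2/time).
#' @param gamma spring constant (1/length).
#' @param Lbar equilibrium territory width (length); one value per axis or
#'   a single value recycled.
#' @param phi diffusivity modulation: `"constant"`, `"sqrt_t"`
#'   (\eqn{\varphi(t) = c/\sqrt{t + 1}}, so \eqn{\int\varphi \sim
#'   2c\sqrt t}), or `"t_over_log_t"` (\eqn{\varphi(t) = c/\ln(e + t)},
#'   so \eqn{\int\varphi \sim c\,t/\ln t}).
#' @param phi_scale the scale constant `c` of the modulation.
#' @param duration total simulated time.
#' @param dt time step; must resolve the relaxation rate
#'   (`dt <= 0.1 / (K * gamma)`).
#' @param dimension number of axes (1 or 2).
#' @param L0 optional list of initial `(L1, L2)` per axis; default edges at
#'   `+-Lbar/2`.
#' @param seed RNG seed.
#' @return Object of class `"boundary_sim"`: list with `t` (times) and per
#'   axis matrices `L1`, `L2` (columns = axes), plus the parameters.
#' @examples
#' b <- simulate_boundaries(K = 1, gamma = 2, Lbar = 10, duration = 50,
#'                          dt = 0.01, seed = 1)
#' @export
simulate_boundaries <- function(K, gamma, Lbar, phi = c("constant", "sqrt_t",
                                                        "t_over_log_t"),
                                phi_scale = 1, duration, dt,
                                dimension = 1, L0 = NULL, seed = 1L) {
  phi <- match.arg(phi)
  stopifnot(K >= 0, gamma > 0, all(Lbar > 0), duration > 0, dt > 0,
            dimension %in% c(1, 2))
  if (K > 0 && dt > 0.1 / (K * gamma))
    stop("dt too coarse: need dt <= 0.1/(K*gamma) = ",
         format(0.1 / (K * gamma)))
  Lbar <- rep_len(Lbar, dimension)
  phifun <- switch(phi,
                   constant = function(t) rep_len(phi_scale, length(t)),
                   sqrt_t = function(t) phi_scale / sqrt(t + 1),
                   t_over_log_t = function(t) phi_scale / log(exp(1) + t))
  set.seed(seed)
  nstep <- ceiling(duration / dt)
  tgrid <- seq(0, by = dt, length.out = nstep + 1)
  L1 <- matrix(NA_real_, nstep + 1, dimension)
  L2 <- matrix(NA_real_, nstep + 1, dimension)
  for (ax in seq_len(dimension)) {
    init <- if (is.null(L0)) c(-Lbar[ax] / 2, Lbar[ax] / 2) else L0[[ax]]
    stopifnot(init[2] > init[1])
    # separation s (reflected at 0) and centroid c evolve independently
    s <- init[2] - init[1]
    cen <- (init[1] + init[2]) / 2
    L1[1, ax] <- init[1]; L2[1, ax] <- init[2]
    ph <- phifun(tgrid[-(nstep + 1)])
    dWs <- stats::rnorm(nstep); dWc <- stats::rnorm(nstep)
    for (k in seq_len(nstep)) {
      Kp <- K * ph[k]
      s <- s - Kp * gamma * (s - Lbar[ax]) * dt +
        sqrt(4 * Kp * dt) * dWs[k]
      s <- abs(s)                       # reflection: edges keep their order
      cen <- cen + sqrt(Kp * dt) * dWc[k]
      L1[k + 1, ax] <- cen - s / 2
      L2[k + 1, ax] <- cen + s / 2
    }
  }
  structure(list(t = tgrid, L1 = L1, L2 = L2, K = K, gamma = gamma,
                 Lbar = Lbar, phi = phi, phi_scale = phi_scale,
                 dt = dt, dimension = dimension),
            class = "boundary_sim")
}

#' @export
print.boundary_sim <- function(x, ...) {
  sep <- x$L2 - x$L1
  cat("Boundary simulation: K =", format(x$K), " gamma =", format(x$gamma),
      " Lbar =", paste(format(x$Lbar), collapse = ", "),
      " phi =", x$phi, "\n")
  cat("  duration", format(max(x$t)), " mean separation",
      paste(format(signif(colMeans(sep), 4)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.boundary_sim <- function(x, axis = 1, ...) {
  graphics::matplot(x$t, cbind(x$L1[, axis], x$L2[, axis]), type = "l",
                    lty = 1, col = c(2, 4), xlab = "t",
                    ylab = "edge position", ...)
  invisible(x)
}

#' Boundary-averaged occupation probability
#'
#' Composes the occupation probability of an animal inside fluctuating
#' boundaries as the adiabatic product \eqn{P(x, L) \approx W(x|L) B(L)}:
#' the long-time fixed-territory occupation `W` (uniform between the edges,
#' the stationary limit of the no-flux confined propagator) is averaged
#' over boundary configurations sampled from a [simulate_boundaries()] run.
#' With frozen boundaries (`K = 0`) this reduces exactly to the
#' fixed-territory occupation; mobile boundaries spread occupation mass
#' beyond the mean edges.
#'
#' @param boundaries a `boundary_sim` object.
#' @param x_grid abscissae at which to evaluate the occupation density.
#' @param axis which axis of the boundary simulation to use.
#' @param burn_in fraction of initial samples discarded before averaging.
#' @param centre if `TRUE` (default) each boundary configuration is taken
#'   relative to its instantaneous centroid, so the map is the occupation
#'   relative to the territory centre (the centroid itself performs free
#'   diffusion and has no stationary law); `FALSE` uses absolute edges.
#' @return Data frame with columns `x` and `density`; the trapezoid
#'   integral over `x_grid` is 1.
#' @examples
#' b <- simulate_boundaries(K = 1, gamma = 2, Lbar = 10, duration = 200,
#'                          dt = 0.01, seed = 1)
#' occ <- compose_occupation(b, seq(-15, 15, length.out = 201))
#' @export
compose_occupation <- function(boundaries, x_grid, axis = 1,
                               burn_in = 0.2, centre = TRUE) {
  stopifnot(inherits(boundaries, "boundary_sim"),
            is.numeric(x_grid), length(x_grid) >= 3,
            !is.unsorted(x_grid))
  n <- length(boundaries$t)
  keep <- seq.int(max(1L, floor(burn_in * n)), n)
  L1 <- boundaries$L1[keep, axis]; L2 <- boundaries$L2[keep, axis]
  if (centre) {
    cen <- (L1 + L2) / 2
    L1 <- L1 - cen; L2 <- L2 - cen
  }
  if (!length(L1)) stop("empty boundary sample")
  dens <- numeric(length(x_grid))
  for (k in seq_along(L1)) {
    w <- L2[k] - L1[k]
    if (w <= 0) next
    inside <- x_grid >= L1[k] & x_grid <= L2[k]
    dens[inside] <- dens[inside] + 1 / w
  }
  dens <- dens / length(L1)
  tot <- sum(diff(x_grid) * (utils::head(dens, -1) + utils::tail(dens, -1)) / 2)
  if (tot <= 0) stop("occupation mass is zero on the supplied grid; widen it")
  data.frame(x = x_grid, density = dens / tot)
}

#' Relative boundary diffusivity from the active scent time
#'
#' The territory border is immobile while the resident revisits it before
#' its marks expire; the border diffusivity is therefore proportional to
#' the probability that the resident has NOT completed a round trip across
#' its territory (width `L`, walker diffusivity `D`) within the active
#' scent time. In the leading first-passage mode this survival decays as
#' \eqn{e^{-\pi^2 D \mathcal{T}_A / (4 L^2)}}, giving an exponential
#' dependence of the border diffusivity on the active scent time. The full
#' eigenmode survival sum is available via `n_modes > 1` and serves as the
#' brute-force reference for the leading-mode approximation.
#'
#' @param D walker diffusivity (length^2/time).
#' @param L territory width (length).
#' @param t_active active scent time (time), possibly a vector.
#' @param n_modes 1 (default) for the leading-mode exponential; larger
#'   values evaluate the eigenmode survival series of the first-passage
#'   problem (absorbing target edge, reflecting rear edge).
#' @return The unnormalized proportionality factor (1 at `t_active = 0`).
#' @examples
#' k_from_ta(D = 1, L = 2, t_active = c(0, 1, 2, 4))
#' @export
k_from_ta <- function(D, L, t_active, n_modes = 1L) {
  stopifnot(D > 0, L > 0, all(t_active >= 0), n_modes >= 1)
  if (n_modes == 1L) return(exp(-pi^2 * D * t_active / (4 * L^2)))
  fp_survival(D, L, t_active, n_modes = n_modes)
}

#' First-passage survival across an interval
#'
#' Probability that a diffusing particle started at one end of an interval
#' of length `L` (reflecting wall behind it) has not yet reached the
#' absorbing opposite end by time `t`:
#' \deqn{S(t) = \frac{4}{\pi}\sum_{n\ge1}\frac{(-1)^{n+1}}{2n-1}
#'   e^{-(2n-1)^2\pi^2 D t/(4L^2)}.}
#'
#' @param D diffusivity.
#' @param L interval length.
#' @param t time (vectorised).
#' @param n_modes number of eigenmodes summed.
#' @return Survival probabilities in \eqn{[0, 1]}.
#' @export
fp_survival <- function(D, L, t, n_modes = 100L) {
  stopifnot(D > 0, L > 0, all(t >= 0))
  out <- numeric(length(t))
  for (n in seq_len(n_modes)) {
    m <- 2 * n - 1
    out <- out + (4 / pi) * (-1)^(n + 1) / m *
      exp(-m^2 * pi^2 * D * t / (4 * L^2))
  }
  pmin(pmax(out, 0), 1)
}
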