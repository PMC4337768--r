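# Seeded synthetic-data generators: tethered Smoluchowski walkers with
# scattered burrows, mark-recapture windowing, persistent walks in boxes
# and circular arenas, and (possibly anomalous) free diffusion.

#' Generate burrow-tethered diffusing walkers
#'
#' Euler-Maruyama integration of overdamped tethered diffusion: each animal
#' diffuses with constant `D` while drifting down its own confining
#' potential centred on a burrow, \eqn{dx = -D\, u'(x - x_c)\,dt +
#' \sqrt{2D}\,dW} with \eqn{u = U/D} the dimensionless potential. Burrow
#' centres are drawn uniformly over a square of side `extent` (set
#' `extent = 0` to place all burrows at the origin). The integration step
#' is `min(L^2/D)/100` and each animal is equilibrated for 20 relaxation
#' times (\eqn{\tau = L^2/2D}) before the first fix, so recorded fixes
#' sample the Boltzmann steady state.
#'
#' @param n_animals number of animals.
#' @param potential a [potential()] object (same shape for both axes). The
#'   `hard_box` family is integrated as free diffusion with reflecting
#'   walls.
#' @param D diffusivity (length^2/time).
#' @param extent side of the square over which burrow centres are
#'   scattered.
#' @param fix_interval time between recorded fixes.
#' @param duration recorded time span per animal (after warm-up).
#' @param seed RNG seed.
#' @param dimension 1 or 2.
#' @return A [trajectory_set()]; burrow centres in attribute `"centres"`.
#' @examples
#' traj <- generate_tethered(3, potential("harmonic", L = 1), D = 0.5,
#'                           extent = 10, fix_interval = 1, duration = 20,
#'                           seed = 1)
#' @export
generate_tethered <- function(n_animals, potential, D, extent,
                              fix_interval, duration, seed = 1L,
                              dimension = 2L) {
  stopifnot(inherits(potential, "potential"), n_animals >= 1, D >= 0,
            extent >= 0, fix_interval > 0, duration >= fix_interval,
            dimension %in% c(1, 2))
  set.seed(seed)
  L <- potential$L
  centres_x <- stats::runif(n_animals, -extent / 2, extent / 2)
  centres_y <- if (dimension == 2L)
    stats::runif(n_animals, -extent / 2, extent / 2) else rep(0, n_animals)

  if (D == 0) {
    times <- seq(0, duration, by = fix_interval)
    out <- data.frame(
      id = rep(seq_len(n_animals), each = length(times)),
      t = rep(times, n_animals),
      x = rep(centres_x, each = length(times)))
    if (dimension == 2L) out$y <- rep(centres_y, each = length(times))
    ts <- trajectory_set(out)
    attr(ts, "centres") <- data.frame(id = seq_len(n_animals),
                                      xc = centres_x, yc = centres_y)
    return(ts)
  }

  dt <- (L^2 / D) / 100
  hard <- potential$family == "hard_box"
  h <- 1e-5 * L
  uprime <- function(z) (potential$u(z + h) - potential$u(z - h)) / (2 * h)
  tau <- L^2 / (2 * D)
  warm_steps <- ceiling(20 * tau / dt)
  times <- seq(0, duration, by = fix_interval)
  sub <- max(1L, round(fix_interval / dt))
  dt <- fix_interval / sub   # land exactly on fix times

  step_axis <- function(pos, centre) {
    # one Euler-Maruyama step for all animals along one axis
    noise <- stats::rnorm(n_animals, 0, sqrt(2 * D * dt))
    if (hard) {
      pos <- pos + noise
      # reflect at centre +- L/2
      rel <- pos - centre
      rel <- ifelse(rel > L / 2, L - rel,
                    ifelse(rel < -L / 2, -L - rel, rel))
      centre + rel
    } else {
      pos - D * uprime(pos - centre) * dt + noise
    }
  }

  x <- centres_x; y <- centres_y
  for (k in seq_len(warm_steps)) {
    x <- step_axis(x, centres_x)
    if (dimension == 2L) y <- step_axis(y, centres_y)
  }
  nfix <- length(times)
  X <- matrix(NA_real_, nfix, n_animals)
  Y <- if (dimension == 2L) matrix(NA_real_, nfix, n_animals)
  X[1, ] <- x; if (dimension == 2L) Y[1, ] <- y
  for (k in 2:nfix) {
    for (s in seq_len(sub)) {
      x <- step_axis(x, centres_x)
      if (dimension == 2L) y <- step_axis(y, centres_y)
    }
    X[k, ] <- x
    if (dimension == 2L) Y[k, ] <- y
  }
  out <- data.frame(id = rep(seq_len(n_animals), each = nfix),
                    t = rep(times, n_animals),
                    x = as.vector(X))
  if (dimension == 2L) out$y <- as.vector(Y)
  ts <- trajectory_set(out)
  attr(ts, "centres") <- data.frame(id = seq_len(n_animals),
                                    xc = centres_x, yc = centres_y)
  ts
}

#' Mark-recapture sampling through a finite window
#'
#' Emulates trapping on a finite grid: retains only fixes inside the
#' square window of side `G` centred at the origin and emits all
#' capture-recapture pairs per animal whose lag exceeds the stationarity
#' lag.
#'
#' @param traj a [trajectory_set()].
#' @param G window side length.
#' @param lag_min stationarity lag: pairs separated by less time are
#'   dropped (0 keeps all ordered pairs).
#' @return Data frame of capture pairs with columns `id`, `t0`, `t1`,
#'   `lag`, `x0`, `x1`, `dx` (and `y0`, `y1`, `dy` in 2d).
#' @export
mark_recapture_sample <- function(traj, G, lag_min = 0) {
  stopifnot(inherits(traj, "trajectory_set"), G > 0, lag_min >= 0)
  dimension <- attr(traj, "dimension")
  df <- as.data.frame(traj)
  inside <- abs(df$x) <= G / 2
  if (dimension == 2L) inside <- inside & abs(df$y) <= G / 2
  df <- df[inside, , drop = FALSE]
  if (!nrow(df)) stop("empty sample: no fixes inside the window")
  pairs <- do.call(rbind, lapply(split(df, df$id), function(s) {
    n <- nrow(s)
    if (n < 2) return(NULL)
    idx <- which(outer(s$t, s$t, "-") > lag_min, arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    p <- data.frame(id = s$id[1],
                    t0 = s$t[idx[, 2]], t1 = s$t[idx[, 1]],
                    x0 = s$x[idx[, 2]], x1 = s$x[idx[, 1]])
    p$lag <- p$t1 - p$t0
    p$dx <- p$x1 - p$x0
    if (dimension == 2L) {
      p$y0 <- s$y[idx[, 2]]; p$y1 <- s$y[idx[, 1]]
      p$dy <- p$y1 - p$y0
    }
    p
  }))
  if (is.null(pairs) || !nrow(pairs))
    stop("empty sample: no capture pairs beyond the stationarity lag")
  rownames(pairs) <- NULL
  pairs
}

#' Generate persistent (run-and-turn) walkers in a bounded domain
#'
#' Simulates correlated random walks: each walker moves at constant speed
#' `v` and redraws its heading at Poisson rate `1/T` (exponential run
#' durations of mean `T`). In a rectangular box the heading is either
#' isotropic (`turning = "uniform"`) or diagonal with independent
#' dichotomous velocity components of magnitude \eqn{v/\sqrt 2} per axis,
#' each redrawn at rate `1/T` (`turning = "axis_telegrapher"`): the latter
#' realises exactly the separable exponential-memory walk whose confined
#' MSD is [confined_msd()] with per-axis speed \eqn{v/\sqrt 2}. In a
#' circular arena the turning angle relative to the current heading is
#' drawn from a wrapped-Cauchy kernel with mean cosine `mean_cos`
#' (`mean_cos = 0` is uniform turning). Walls reflect specularly.
#'
#' @param n_animals number of walkers.
#' @param v speed.
#' @param T mean persistence (run) time.
#' @param domain `list(type = "box", lx =, ly =)` or
#'   `list(type = "arena", R =)`.
#' @param mean_cos mean cosine of the turning-angle kernel (arena only).
#' @param turning heading model in the box: `"uniform"` or
#'   `"axis_telegrapher"` (ignored in the arena).
#' @param fix_interval time between recorded fixes.
#' @param duration recorded time span.
#' @param dt integration substep (default `min(T, crossing time)/50`).
#' @param seed RNG seed.
#' @param start `"uniform"` (default) or `"centre"`.
#' @return A [trajectory_set()].
#' @export
generate_persistent <- function(n_animals, v, T, domain,
                                mean_cos = 0, fix_interval, duration,
                                dt = NULL, seed = 1L,
                                start = c("uniform", "centre"),
                                turning = c("uniform", "axis_telegrapher")) {
  stopifnot(n_animals >= 1, v > 0, T > 0, is.list(domain),
            fix_interval > 0, duration >= fix_interval,
            mean_cos >= 0, mean_cos < 1)
  start <- match.arg(start)
  turning <- match.arg(turning)
  set.seed(seed)
  type <- match.arg(domain$type, c("box", "arena"))
  if (type == "box") {
    lx <- domain$lx; ly <- if (is.null(domain$ly)) lx else domain$ly
    stopifnot(lx > 0, ly > 0)
    cross <- min(lx, ly) / v
  } else {
    R <- domain$R
    stopifnot(R > 0)
    cross <- 2 * R / v
  }
  if (is.null(dt)) dt <- min(T, cross) / 50
  sub <- max(1L, round(fix_interval / dt))
  dt <- fix_interval / sub
  pturn <- -expm1(-dt / T)

  if (type == "box") {
    x <- if (start == "uniform") stats::runif(n_animals, 0, lx) else rep(lx / 2, n_animals)
    y <- if (start == "uniform") stats::runif(n_animals, 0, ly) else rep(ly / 2, n_animals)
  } else {
    if (start == "uniform") {
      rr <- R * sqrt(stats::runif(n_animals))
      aa <- stats::runif(n_animals, 0, 2 * pi)
      x <- rr * cos(aa); y <- rr * sin(aa)
    } else x <- y <- rep(0, n_animals)
  }
  th <- stats::runif(n_animals, 0, 2 * pi)
  axis_tg <- type == "box" && turning == "axis_telegrapher"
  if (axis_tg) {
    sx <- sample(c(-1, 1), n_animals, replace = TRUE)
    sy <- sample(c(-1, 1), n_animals, replace = TRUE)
    va <- v / sqrt(2)
  }

  turn <- function(th, k) {
    if (type == "box" || mean_cos == 0) {
      stats::runif(k, 0, 2 * pi)
    } else {
      # wrapped-Cauchy turning kernel: mean resultant = mean_cos
      u <- stats::runif(k)
      dth <- 2 * atan(((1 - mean_cos) / (1 + mean_cos)) *
                        tan(pi * (u - 0.5)))
      th + dth
    }
  }

  times <- seq(0, duration, by = fix_interval)
  nfix <- length(times)
  X <- matrix(NA_real_, nfix, n_animals)
  Y <- matrix(NA_real_, nfix, n_animals)
  X[1, ] <- x; Y[1, ] <- y
  for (k in 2:nfix) {
    for (s in seq_len(sub)) {
      if (axis_tg) {
        x2 <- x + va * dt * sx
        y2 <- y + va * dt * sy
        hit <- x2 < 0 | x2 > lx
        x2 <- ifelse(x2 < 0, -x2, ifelse(x2 > lx, 2 * lx - x2, x2))
        sx <- ifelse(hit, -sx, sx)
        hit <- y2 < 0 | y2 > ly
        y2 <- ifelse(y2 < 0, -y2, ifelse(y2 > ly, 2 * ly - y2, y2))
        sy <- ifelse(hit, -sy, sy)
        x <- x2; y <- y2
        tn <- stats::runif(n_animals) < pturn
        if (any(tn)) sx[tn] <- sample(c(-1, 1), sum(tn), replace = TRUE)
        tn <- stats::runif(n_animals) < pturn
        if (any(tn)) sy[tn] <- sample(c(-1, 1), sum(tn), replace = TRUE)
        next
      }
      x2 <- x + v * dt * cos(th)
      y2 <- y + v * dt * sin(th)
      if (type == "box") {
        # specular reflections
        hit <- x2 < 0 | x2 > lx
        x2 <- ifelse(x2 < 0, -x2, ifelse(x2 > lx, 2 * lx - x2, x2))
        th <- ifelse(hit, pi - th, th)
        hit <- y2 < 0 | y2 > ly
        y2 <- ifelse(y2 < 0, -y2, ifelse(y2 > ly, 2 * ly - y2, y2))
        th <- ifelse(hit, -th, th)
      } else {
        r2 <- sqrt(x2^2 + y2^2)
        out <- r2 > R
        if (any(out)) {
          # reflect velocity about the boundary normal, pull point inside
          nx <- x2[out] / r2[out]; ny <- y2[out] / r2[out]
          vx <- cos(th[out]); vy <- sin(th[out])
          dot <- vx * nx + vy * ny
          vx <- vx - 2 * dot * nx
          vy <- vy - 2 * dot * ny
          th[out] <- atan2(vy, vx)
          scale <- (2 * R - r2[out]) / r2[out]
          x2[out] <- x2[out] * scale
          y2[out] <- y2[out] * scale
        }
      }
      x <- x2; y <- y2
      tn <- stats::runif(n_animals) < pturn
      if (any(tn)) th[tn] <- turn(th[tn], sum(tn))
    }
    X[k, ] <- x; Y[k, ] <- y
  }
  trajectory_set(data.frame(
    id = rep(seq_len(n_animals), each = nfix),
    t = rep(times, n_animals),
    x = as.vector(X), y = as.vector(Y)))
}

#' Generate (possibly anomalous) free diffusion
#'
#' Gaussian walks with time-dependent diffusivity `D(t)`: per axis the
#' increment over `[t, t+dt]` is normal with variance
#' \eqn{2\int_t^{t+dt} D(s)\,ds} (evaluated exactly on the fix grid, since
#' the process is Gaussian). A power-law modulation
#' \eqn{D(t) \propto t^{2H-1}} produces monofractal scaling with Hurst
#' exponent `H`; constant `D` recovers ordinary Brownian motion with the
#' Einstein MSD \eqn{2 n D t}.
#'
#' @param n_animals number of walkers.
#' @param D_of_t diffusivity: a single non-negative number (constant), or
#'   a vectorised non-negative function of time.
#' @param hurst alternative to `D_of_t`: target Hurst exponent in (0, 1];
#'   uses \eqn{D(t) = D0\, H\, (t/t_ref)^{2H-1}}.
#' @param D0 diffusivity scale used with `hurst`.
#' @param t_ref reference time for the power-law modulation.
#' @param fix_interval time between fixes.
#' @param duration recorded time span.
#' @param seed RNG seed.
#' @param dimension 1 or 2.
#' @return A [trajectory_set()] started at the origin.
#' @examples
#' generate_anomalous(2, D_of_t = 1, fix_interval = 1, duration = 5, seed = 1)
#' @export
generate_anomalous <- function(n_animals, D_of_t = NULL, hurst = NULL,
                               D0 = 1, t_ref = 1, fix_interval, duration,
                               seed = 1L, dimension = 2L) {
  stopifnot(n_animals >= 1, fix_interval > 0, duration >= fix_interval,
            dimension %in% c(1, 2))
  if (is.null(D_of_t) == is.null(hurst))
    stop("supply exactly one of D_of_t or hurst")
  set.seed(seed)
  times <- seq(0, duration, by = fix_interval)
  if (!is.null(hurst)) {
    stopifnot(hurst > 0, hurst <= 1.25)
    # int_0^t D(s) ds = (D0/2) t_ref (t/t_ref)^{2H}
    Dint <- (D0 / 2) * t_ref * (times / t_ref)^(2 * hurst)
  } else if (is.function(D_of_t)) {
    fine <- seq(0, max(times), length.out = 4096)
    dv <- D_of_t(fine)
    if (any(dv < 0)) stop("D(t) must be non-negative")
    cums <- c(0, cumsum((dv[-1] + dv[-length(dv)]) / 2 * diff(fine)))
    Dint <- stats::approx(fine, cums, xout = times)$y
  } else {
    stopifnot(is.numeric(D_of_t), length(D_of_t) == 1L, D_of_t >= 0)
    Dint <- D_of_t * times
  }
  varinc <- 2 * diff(Dint)
  if (any(varinc < -1e-12)) stop("D(t) must be non-negative")
  varinc <- pmax(varinc, 0)
  nfix <- length(times)
  mk_axis <- function() {
    inc <- matrix(stats::rnorm((nfix - 1) * n_animals,
                               sd = rep(sqrt(varinc), n_animals)),
                  nfix - 1, n_animals)
    rbind(0, apply(inc, 2, cumsum))
  }
  X <- mk_axis()
  out <- data.frame(id = rep(seq_len(n_animals), each = nfix),
                    t = rep(times, n_animals), x = as.vector(X))
  if (dimension == 2L) out$y <- as.vector(mk_axis())
  trajectory_set(out)
}
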