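# Territorial random walk (TRW): scent-marking lattice walkers with finite
# active scent time, full-retreat exclusion or graded (alpha-family)
# avoidance, and territory/utilization outputs.

#' Configuration of a territorial random walk simulation
#'
#' @param nx,ny lattice sites per axis (periodic boundaries).
#' @param n_walkers number of walkers N (at most `nx * ny`).
#' @param t_active active scent time \eqn{\mathcal{T}_A} in steps: a mark
#'   deposited at time `s` elicits avoidance until `s + t_active`.
#' @param alpha retreat-response exponent of the graded avoidance family
#'   (`Inf` reproduces the original full-retreat step response).
#' @param steps number of simulation steps (one hop attempt per walker per
#'   step, shuffled sweep order; the hop time is the time unit).
#' @param seed RNG seed.
#' @param mode `"full_exclusion"` (retreat into own territory upon any
#'   active foreign mark; deposited marks erase other owners' marks at that
#'   site, so actively marked areas are disjoint at all times) or
#'   `"alpha_family"` (graded centroid-directed bias, overlapping marked
#'   areas allowed).
#' @param check `"before_hop"` (the target site is inspected before hopping
#'   and the walker responds without entering) or `"after_landing"` (a
#'   walker notices a foreign mark on the site it lands on and responds
#'   from the next hop). Defaults by mode: full exclusion inspects before
#'   hopping (marked areas stay disjoint and freeze as
#'   \eqn{\mathcal{T}_A \to \infty}), the graded alpha family responds
#'   after landing (walkers may enter foreign terrain, producing the
#'   overlapping marked areas the graded response is for).
#' @param record_every interval (steps) between recorded lattice snapshots
#'   and trajectory fixes.
#' @param util_window number of final steps over which the utilization
#'   distribution is accumulated; defaults to `2.5 * t_active`.
#' @param init optional integer matrix `n_walkers x 2` of 0-based initial
#'   sites; default places walkers on an evenly spaced grid.
#' @param ignore_scent if `TRUE`, the avoidance response is switched off
#'   (`p = 1/2` for every mark age): walkers deposit marks but move as free
#'   random walkers. Useful as a null model.
#' @return Object of class `"trw_config"`.
#' @examples
#' cfg <- trw_config(25, 25, n_walkers = 16, t_active = 1250, steps = 5000)
#' @export
trw_config <- function(nx, ny, n_walkers, t_active, alpha = Inf,
                       steps = 10000L, seed = 1L,
                       mode = c("full_exclusion", "alpha_family"),
                       check = NULL,
                       record_every = 100L, util_window = NULL,
                       init = NULL, ignore_scent = FALSE) {
  mode <- match.arg(mode)
  if (is.null(check))
    check <- if (mode == "full_exclusion") "before_hop" else "after_landing"
  check <- match.arg(check, c("before_hop", "after_landing"))
  stopifnot(nx >= 2, ny >= 1, n_walkers >= 1, n_walkers <= nx * ny,
            t_active > 0, steps >= 1, record_every >= 1,
            alpha > 0)
  if (is.null(util_window)) util_window <- ceiling(2.5 * t_active)
  if (is.null(init)) init <- .default_init(nx, ny, n_walkers)
  init <- as.matrix(init)
  stopifnot(nrow(init) == n_walkers, ncol(init) == 2,
            all(init[, 1] >= 0 & init[, 1] < nx),
            all(init[, 2] >= 0 & init[, 2] < ny))
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 n_walkers = as.integer(n_walkers),
                 t_active = as.integer(t_active), alpha = alpha,
                 steps = as.integer(steps), seed = as.integer(seed),
                 mode = mode, check = check,
                 record_every = as.integer(record_every),
                 util_window = as.integer(util_window),
                 init = matrix(as.integer(init), ncol = 2),
                 ignore_scent = isTRUE(ignore_scent)),
            class = "trw_config")
}

# evenly spread starting sites
.default_init <- function(nx, ny, N) {
  k <- ceiling(sqrt(N))
  gx <- floor((seq_len(k) - 0.5) / k * nx)
  gy <- floor((seq_len(k) - 0.5) / k * ny)
  g <- expand.grid(x = gx, y = gy)[seq_len(N), ]
  as.matrix(g)
}

#' @export
print.trw_config <- function(x, ...) {
  cat("TRW configuration: ", x$nx, "x", x$ny, " periodic lattice, N = ",
      x$n_walkers, "\n  T_A = ", x$t_active, " steps, alpha = ",
      format(x$alpha), ", mode = ", x$mode, ", steps = ", x$steps,
      "\n  density rho = ", format(signif(x$n_walkers / (x$nx * x$ny), 4)),
      ", Z = ", format(signif(spatial_competition(
        0.25, x$n_walkers / (x$nx * x$ny), x$t_active), 4)), "\n", sep = "")
  invisible(x)
}

#' Retreat bias as a function of mark age
#'
#' The probability `p` of stepping away from a foreign mark of age `tau`,
#' in the one-parameter family
#' \deqn{p(\tau) = \frac{1}{2}\left[1 + \sqrt{1 - (\tau/\mathcal{T}_A)^\alpha}
#'  \right], \quad \tau \le \mathcal{T}_A,}
#' and \eqn{p = 1/2} for older marks. The family satisfies \eqn{p(0) = 1}
#' (fresh mark: certain retreat) and \eqn{p(\mathcal{T}_A) = 1/2} (expired
#' mark: ignored) for every \eqn{\alpha}; \eqn{\alpha \to \infty} gives the
#' step response of the original full-retreat model.
#'
#' @param tau mark age (steps), non-negative (vectorised).
#' @param t_active active scent time \eqn{\mathcal{T}_A}.
#' @param alpha positive exponent, possibly `Inf`.
#' @return Bias probabilities in \eqn{[1/2, 1]}.
#' @examples
#' retreat_bias(c(0, 625, 1250, 2000), t_active = 1250, alpha = 2)
#' @export
retreat_bias <- function(tau, t_active, alpha) {
  stopifnot(all(tau >= 0), t_active > 0, length(alpha) == 1L)
  if (alpha <= 0) stop("alpha must be positive")
  r <- tau / t_active
  inner <- if (is.finite(alpha)) r^alpha else as.numeric(r >= 1)
  p <- 0.5 * (1 + sqrt(pmax(1 - inner, 0)))
  p[tau > t_active] <- 0.5
  p
}

#' Directional probabilities of the biased avoidance step
#'
#' After encountering a foreign mark, a walker at lattice site `position`
#' steps with probabilities biased toward the centroid of its own marked
#' area:
#' \deqn{l_\pm = \tfrac14\{1 \pm (2p-1)\kappa_l\},\quad
#'       u_\pm = \tfrac14\{1 \mp (2p-1)\kappa_u\},}
#' where \eqn{\kappa_l, \kappa_u} are the direction cosines of the offset
#' from the centroid to the walker. The four probabilities sum to one for
#' any input; `p = 1/2` gives the unbiased step. A walker sitting exactly on
#' its centroid steps without bias (both \eqn{\kappa} set to 0).
#'
#' @param position numeric length-2, walker site `(m, n)`.
#' @param centroid numeric length-2, centroid `(m_c, n_c)` of the walker's
#'   active marked area.
#' @param p retreat bias in \eqn{[1/2, 1]} (see [retreat_bias()]).
#' @return Named numeric vector `(left, right, up, down)`.
#' @examples
#' step_probabilities(c(5, 0), c(0, 0), p = 1)   # due east: (1/2,0,1/4,1/4)
#' @export
step_probabilities <- function(position, centroid, p) {
  stopifnot(length(position) == 2L, length(centroid) == 2L,
            length(p) == 1L)
  if (p < 0.5 || p > 1) stop("p must lie in [1/2, 1]")
  d <- position - centroid
  dist <- sqrt(sum(d^2))
  k <- if (dist > 0) d / dist else c(0, 0)
  b <- 2 * p - 1
  c(left  = 0.25 * (1 + b * k[1]),
    right = 0.25 * (1 - b * k[1]),
    up    = 0.25 * (1 - b * k[2]),
    down  = 0.25 * (1 + b * k[2]))
}

#' Spatial competition parameter
#'
#' \eqn{Z = 4 D \rho \mathcal{T}_A}: the ratio of the area a diffusing
#' walker covers during the active scent time to the per-capita share of
#' the terrain. Small and large `Z` correspond to fast and slow territory
#' boundary dynamics. For the nearest-neighbour lattice walk with unit
#' spacing and one hop per step, \eqn{D = 1/4} (site\eqn{^2}/step), so
#' `Z = rho * t_active` in lattice units.
#'
#' @param D diffusivity (site^2/step for the lattice walk).
#' @param rho walker density (walkers per site).
#' @param t_active active scent time (steps).
#' @return The dimensionless competition parameter Z.
#' @examples
#' spatial_competition(0.25, 16 / 625, 1250)   # the classic Z = 32 setting
#' @export
spatial_competition <- function(D, rho, t_active) {
  stopifnot(D >= 0, rho > 0, t_active > 0)
  4 * D * rho * t_active
}

#' Simulate territorial random walkers
#'
#' Runs the scent-mediated lattice model: walkers deposit (and refresh) a
#' mark at every visited site; marks stay active for `t_active` steps; upon
#' encountering an active foreign mark a walker either fully retreats to a
#' neighbouring site free of foreign marks (`full_exclusion`) or takes a
#' centroid-directed biased step whose strength decays with the age of the
#' encountered mark (`alpha_family`, see [retreat_bias()]). In full
#' exclusion a deposited mark erases other owners' marks on that site, so
#' the actively marked areas are pairwise disjoint at every instant.
#'
#' @param config a [trw_config()] object.
#' @return Object of class `"trw_sim"` with elements:
#'   \item{trajectories}{data frame `id, t, m, n` of unwrapped walker
#'     positions at recorded steps (lattice units; wrap with `%% nx` for
#'     sites).}
#'   \item{utilization}{matrix `n_walkers x (nx*ny)` of per-owner site
#'     occupancy frequencies accumulated over the final `util_window`
#'     steps; rows sum to 1.}
#'   \item{territory}{data frame per owner at the final step: active-mark
#'     `area` (sites) and centroid `(m_c, n_c)`.}
#'   \item{mark_age}{matrix `n_walkers x (nx*ny)`; age of each owner's
#'     active mark at the final step, `-1` where inactive.}
#'   \item{overlap_checks, overlap_violations}{number of recorded-step
#'     disjointness audits and of owner-pair overlaps found (full exclusion
#'     only; should be 0).}
#' @examples
#' sim <- trw_simulate(trw_config(15, 15, 4, t_active = 200, steps = 2000,
#'                                seed = 7))
#' sim$overlap_violations
#' @export
trw_simulate <- function(config) {
  stopifnot(inherits(config, "trw_config"))
  set.seed(config$seed)
  alpha_eff <- if (config$ignore_scent) -1 else config$alpha
  res <- .trw_simulate_cpp(config$nx, config$ny, config$n_walkers,
                           config$t_active, alpha_eff, config$steps,
                           config$mode == "full_exclusion" &&
                             !config$ignore_scent,
                           config$check == "before_hop" &&
                             !config$ignore_scent,
                           config$record_every, config$util_window,
                           config$init)
  N <- config$n_walkers
  nrec <- length(res$t)
  traj <- data.frame(
    id = rep(seq_len(N), each = nrec),
    t = rep(res$t, N),
    m = as.vector(res$x),
    n = as.vector(res$y))
  terr <- .territory_snapshot(res$mark_age, config)
  structure(list(trajectories = traj,
                 utilization = res$utilization,
                 territory = terr,
                 mark_age = res$mark_age,
                 overlap_checks = res$overlap_checks,
                 overlap_violations = res$overlap_violations,
                 config = config),
            class = "trw_sim")
}

# area and minimal-image centroid of each owner's active marks
.territory_snapshot <- function(mark_age, config) {
  nx <- config$nx; ny <- config$ny
  N <- nrow(mark_age)
  out <- data.frame(id = seq_len(N), area = 0L,
                    m_c = NA_real_, n_c = NA_real_)
  for (i in seq_len(N)) {
    act <- which(mark_age[i, ] >= 0) - 1L
    out$area[i] <- length(act)
    if (!length(act)) next
    mx <- act %% nx
    my <- act %/% nx
    # minimal image relative to the first active site
    offx <- ((mx - mx[1] + nx %/% 2) %% nx) - nx %/% 2
    offy <- ((my - my[1] + ny %/% 2) %% ny) - ny %/% 2
    out$m_c[i] <- (mx[1] + mean(offx)) %% nx
    out$n_c[i] <- (my[1] + mean(offy)) %% ny
  }
  out
}

#' @export
print.trw_sim <- function(x, ...) {
  cfg <- x$config
  cat("TRW simulation: ", cfg$nx, "x", cfg$ny, " lattice, N = ",
      cfg$n_walkers, ", ", cfg$steps, " steps (", cfg$mode, ")\n", sep = "")
  cat("  mean territory area:", format(signif(mean(x$territory$area), 4)),
      "sites; disjointness audits:", x$overlap_checks,
      "violations:", x$overlap_violations, "\n")
  invisible(x)
}

#' Contour map of TRW utilization distributions
#'
#' Draws per-owner contour maps of the utilization distribution in the
#' style of the classic territorial-pattern figures; default contour levels
#' are multiples of \eqn{10^{-4}}.
#'
#' @param x a `trw_sim` object.
#' @param owners which walkers to draw (default all).
#' @param levels contour levels.
#' @param ... passed to [graphics::contour()].
#' @export
plot.trw_sim <- function(x, owners = seq_len(nrow(x$utilization)),
                         levels = 1e-4 * c(1, 2, 4, 6, 8, 10, 12, 14,
                                           20, 40, 80), ...) {
  cfg <- x$config
  first <- TRUE
  cols <- grDevices::hcl.colors(length(owners), "Dark 3")
  for (k in seq_along(owners)) {
    u <- matrix(x$utilization[owners[k], ], nrow = cfg$nx)
    graphics::contour(x = seq_len(cfg$nx) - 1, y = seq_len(cfg$ny) - 1,
                      z = u, levels = levels, add = !first,
                      col = cols[k], drawlabels = FALSE,
                      xlab = "m", ylab = "n", ...)
    first <- FALSE
  }
  invisible(x)
}

#' Mean-square displacement of recorded TRW walkers
#'
#' Either the ensemble MSD over walkers (displacement from each walker's
#' first recorded fix; `method = "origin"`) or the time-averaged MSD at a
#' set of lags, pooled over walkers and start times (`method = "window"`;
#' self-averaging even for a single walker).
#'
#' @param sim a `trw_sim` object.
#' @param method `"origin"` or `"window"`.
#' @param lags lags in steps (`"window"` only); must be multiples of the
#'   recording interval. Default: a geometric grid.
#' @return Data frame with columns `t` (lag) and `msd` (site^2).
#' @export
trw_msd <- function(sim, method = c("origin", "window"), lags = NULL) {
  stopifnot(inherits(sim, "trw_sim"))
  method <- match.arg(method)
  tr <- sim$trajectories
  ids <- unique(tr$id)
  ts <- sort(unique(tr$t))
  pos <- lapply(ids, function(i) {
    s <- tr[tr$id == i, ]
    s[order(s$t), c("m", "n")]
  })
  if (method == "origin") {
    disp <- sapply(pos, function(s)
      (s$m - s$m[1])^2 + (s$n - s$n[1])^2)
    return(data.frame(t = ts, msd = rowMeans(as.matrix(disp))))
  }
  rec <- sim$config$record_every
  nrec <- length(ts)
  if (is.null(lags)) {
    lags <- unique(round(10^seq(0, log10(nrec / 4), length.out = 16)))
  } else {
    if (any(lags %% rec != 0))
      stop("lags must be multiples of the recording interval (", rec, ")")
    lags <- lags / rec
  }
  lags <- lags[lags >= 1 & lags < nrec]
  msd <- vapply(lags, function(l) {
    mean(vapply(pos, function(s) {
      dm <- s$m[-seq_len(l)] - s$m[seq_len(nrec - l)]
      dn <- s$n[-seq_len(l)] - s$n[seq_len(nrec - l)]
      mean(dm^2 + dn^2)
    }, numeric(1)))
  }, numeric(1))
  data.frame(t = lags * rec, msd = msd)
}

#' Territory-edge dynamics of the 1d territorial walk
#'
#' Runs the 1d full-exclusion TRW on a ring and tracks the territory
#' edges: edge `k` is the midpoint between the rightmost active mark of
#' owner `k` and the leftmost active mark of the next owner along the ring
#' (walkers cannot cross in single file, so the cyclic owner order is
#' conserved). Returns the time-averaged MSD of the edges as a function of
#' lag; in the strongly competing (large-Z) regime the edge MSD grows as
#' \eqn{\sqrt{t}}, the tagged-particle signature of single-file exclusion.
#' Windows in which an owner has lost all active marks (territory collapse)
#' are excluded from the averages and counted.
#'
#' @param nx ring length (sites).
#' @param n_walkers number of walkers (>= 3).
#' @param t_active active scent time (steps).
#' @param steps simulation length.
#' @param record_every sampling interval for edge positions.
#' @param lags integer lags (in recorded samples) at which to evaluate the
#'   edge MSD; default a geometric grid.
#' @param seed RNG seed.
#' @return Object of class `"trw_edges"`: list with `lag` (steps), `msd`
#'   (site^2), `edges` (matrix of recorded edge positions), `n_collapsed`
#'   (excluded samples) and the call parameters.
#' @examples
#' be <- boundary_msd_1d(60, 3, t_active = 3000, steps = 20000, seed = 2)
#' @export
boundary_msd_1d <- function(nx, n_walkers, t_active, steps,
                            record_every = 5L, lags = NULL, seed = 1L) {
  stopifnot(nx >= 6, n_walkers >= 3, n_walkers < nx / 2, t_active > 0)
  set.seed(seed)
  init <- as.integer(floor((seq_len(n_walkers) - 0.5) / n_walkers * nx))
  res <- .trw1d_simulate_cpp(as.integer(nx), as.integer(n_walkers),
                             as.integer(t_active), as.integer(steps),
                             as.integer(record_every), init)
  E <- res$edges
  bad <- res$collapsed > 0
  E[bad] <- NA
  nrec <- nrow(E)
  if (is.null(lags)) {
    lags <- unique(round(10^seq(0, log10(nrec / 4), length.out = 24)))
  }
  lags <- lags[lags >= 1 & lags < nrec]
  msd <- vapply(lags, function(l) {
    d <- E[-seq_len(l), , drop = FALSE] - E[seq_len(nrec - l), , drop = FALSE]
    mean(d^2, na.rm = TRUE)
  }, numeric(1))
  structure(list(lag = lags * record_every, msd = msd, edges = E,
                 n_collapsed = sum(bad), nx = nx, n_walkers = n_walkers,
                 t_active = t_active, steps = steps,
                 record_every = record_every),
            class = "trw_edges")
}

#' @export
print.trw_edges <- function(x, ...) {
  cat("1d TRW edge dynamics: ring of", x$nx, "sites,", x$n_walkers,
      "walkers, T_A =", x$t_active, "\n")
  fit <- stats::lm(log(msd) ~ log(lag), data.frame(lag = x$lag, msd = x$msd))
  cat("  overall log-log slope:", format(signif(coef(fit)[2], 3)),
      " collapsed samples:", x$n_collapsed, "\n")
  invisible(x)
}

#' @export
plot.trw_edges <- function(x, ...) {
  plot(x$lag, x$msd, log = "xy", xlab = "lag (steps)",
       ylab = expression("edge MSD (site"^2 * ")"), ...)
  invisible(x)
}

#' Mean return time of a lattice walker to its starting site
#'
#' Monte Carlo check of the Kac recurrence lemma: for an unbiased
#' nearest-neighbour walker on a periodic `nx x ny` lattice the mean
#' recurrence time to any given site equals the number of sites.
#'
#' @param nx,ny lattice dimensions.
#' @param steps number of hops to simulate.
#' @param seed RNG seed.
#' @return List with `mean_return` (steps) and `n_returns`.
#' @examples
#' kac_return_time(5, 5, steps = 1e5, seed = 1)$mean_return  # ~ 25
#' @export
kac_return_time <- function(nx, ny, steps, seed = 1L) {
  stopifnot(nx >= 2, ny >= 1, steps >= 1)
  set.seed(seed)
  .lattice_return_times_cpp(as.integer(nx), as.integer(ny),
                            as.integer(steps))
}
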