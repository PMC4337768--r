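# Estimators operating on relocation data: displacement moments and
# multifractal Hurst exponents, steady-state potential fitting, and
# maximum-likelihood movement-parameter estimation with bootstrap.

#' Validated set of relocation trajectories
#'
#' The common currency of the estimators: one row per fix with columns
#' `id` (animal), `t` (time), `x` and optionally `y` (positions in
#' consistent units). Times must be strictly increasing within each animal
#' and `(id, t)` pairs unique.
#'
#' @param data data frame with columns `id`, `t`, `x` and optionally `y`.
#' @return Object of class `"trajectory_set"` (a data frame), sorted by
#'   animal and time, with attribute `"dimension"` (1 or 2).
#' @examples
#' trajectory_set(data.frame(id = 1, t = 0:2, x = c(0, 1, 0), y = 0))
#' @export
trajectory_set <- function(data) {
  stopifnot(is.data.frame(data))
  need <- c("id", "t", "x")
  if (!all(need %in% names(data)))
    stop("trajectory data must have columns id, t, x (and optionally y)")
  dimension <- if ("y" %in% names(data)) 2L else 1L
  cols <- c("id", "t", "x", if (dimension == 2L) "y")
  data <- data[cols]
  if (!is.numeric(data$t) || !is.numeric(data$x) ||
      (dimension == 2L && !is.numeric(data$y)))
    stop("t, x, y must be numeric")
  if (anyNA(data)) stop("missing values in trajectory data")
  data <- data[order(data$id, data$t), , drop = FALSE]
  dup <- duplicated(data[c("id", "t")])
  if (any(dup))
    stop("duplicate (id, t) records: ",
         paste(utils::head(paste0("(", data$id[dup], ", ", data$t[dup], ")"),
                           5), collapse = " "))
  rownames(data) <- NULL
  structure(data, dimension = dimension,
            class = c("trajectory_set", "data.frame"))
}

#' @export
print.trajectory_set <- function(x, ...) {
  ids <- unique(x$id)
  cat("Trajectory set: ", length(ids), " animal(s), ", nrow(x),
      " fixes, ", attr(x, "dimension"), "d, time span [",
      format(min(x$t)), ", ", format(max(x$t)), "]\n", sep = "")
  invisible(x)
}

#' @export
plot.trajectory_set <- function(x, ...) {
  if (attr(x, "dimension") == 2L) {
    plot(x$x, x$y, type = "n", xlab = "x", ylab = "y", asp = 1, ...)
    for (i in unique(x$id)) {
      s <- x[x$id == i, ]
      graphics::lines(s$x, s$y, col = grDevices::adjustcolor(which(unique(x$id) == i), 0.6))
    }
  } else {
    plot(x$t, x$x, type = "n", xlab = "t", ylab = "x", ...)
    for (i in unique(x$id)) {
      s <- x[x$id == i, ]
      graphics::lines(s$t, s$x, col = which(unique(x$id) == i))
    }
  }
  invisible(x)
}

# displacement table at a given lag: all fix pairs (per animal) whose time
# difference matches `lag` within tol
.lag_displacements <- function(traj, lag, tol) {
  out_d <- numeric(0)
  for (i in unique(traj$id)) {
    s <- traj[traj$id == i, ]
    n <- nrow(s)
    if (n < 2) next
    dtmat <- outer(s$t, s$t, "-")
    idx <- which(abs(dtmat - lag) <= tol & dtmat > 0, arr.ind = TRUE)
    if (!nrow(idx)) next
    dx <- s$x[idx[, 1]] - s$x[idx[, 2]]
    d2 <- dx^2
    if (attr(traj, "dimension") == 2L) {
      dy <- s$y[idx[, 1]] - s$y[idx[, 2]]
      d2 <- d2 + dy^2
    }
    out_d <- c(out_d, sqrt(d2))
  }
  out_d
}

#' Empirical displacement moments
#'
#' Estimates the aggregate q-th displacement moment
#' \eqn{\langle|\Delta x|^q\rangle(t)} at a set of lags by pooling, with
#' equal weight, all displacement pairs of all animals whose time
#' separation matches the lag (`method = "pairs"`, the time-window
#' average), or only displacements from each animal's first fix
#' (`method = "origin"`, the ensemble estimate). Lags with no matching
#' pairs are reported with `NA` and a warning rather than dropped.
#'
#' High-order moments (`q > 2`) probe the tails of the occupation and are
#' biased low when the observation window is not much larger than the home
#' range; a warning is issued when `window` is supplied and is less than 4
#' estimated home-range lengths.
#'
#' @param traj a [trajectory_set()].
#' @param q moment order (single positive number).
#' @param lags vector of positive lags (time units of `t`).
#' @param method `"origin"` (default) or `"pairs"`; the time-window
#'   `"pairs"` average assumes stationary increments.
#' @param lag_tol matching tolerance; default half the median sampling
#'   interval.
#' @param B bootstrap resamples for confidence bands (0 = none).
#' @param probs bootstrap band quantiles.
#' @param window optional observation-window side, used only for the
#'   finite-window bias warning.
#' @return Object of class `"moment_curve"`: data frame with columns
#'   `lag`, `value`, `n_pairs` and (if `B > 0`) `lo`, `hi`.
#' @export
empirical_moment <- function(traj, q, lags, method = c("origin", "pairs"),
                             lag_tol = NULL, B = 0L,
                             probs = c(0.025, 0.975), window = NULL) {
  stopifnot(inherits(traj, "trajectory_set"), q > 0, all(lags >= 0))
  method <- match.arg(method)
  if (is.null(lag_tol)) {
    dts <- unlist(tapply(traj$t, traj$id, function(tt) diff(tt)))
    lag_tol <- stats::median(dts) / 2
  }
  vals <- los <- his <- rep(NA_real_, length(lags))
  ns <- integer(length(lags))
  for (k in seq_along(lags)) {
    if (lags[k] == 0) {             # zero lag: displacement identically 0
      vals[k] <- 0; ns[k] <- nrow(traj)
      if (B > 0) { los[k] <- 0; his[k] <- 0 }
      next
    }
    d <- if (method == "pairs") .lag_displacements(traj, lags[k], lag_tol)
         else .origin_displacements(traj, lags[k], lag_tol)
    ns[k] <- length(d)
    if (!length(d)) next
    vals[k] <- mean(d^q)
    if (B > 0) {
      bs <- vapply(seq_len(B), function(b)
        mean(sample(d, replace = TRUE)^q), numeric(1))
      qs <- stats::quantile(bs, probs, names = FALSE)
      los[k] <- qs[1]; his[k] <- qs[2]
    }
  }
  if (any(ns == 0))
    warning("no displacement pairs at lag(s) ",
            paste(format(lags[ns == 0]), collapse = ", "))
  if (!is.null(window) && q > 2) {
    Lrough <- sqrt(2 * stats::var(traj$x))
    if (window < 4 * Lrough)
      warning("observation window is < 4 estimated home-range lengths: ",
              "moments with q > 2 are biased low by the finite window")
  }
  out <- data.frame(lag = lags, value = vals, n_pairs = ns)
  if (B > 0) { out$lo <- los; out$hi <- his }
  structure(out, q = q, method = method,
            class = c("moment_curve", "data.frame"))
}

.origin_displacements <- function(traj, lag, tol) {
  out <- numeric(0)
  for (i in unique(traj$id)) {
    s <- traj[traj$id == i, ]
    if (nrow(s) < 2) next
    dt <- s$t - s$t[1]
    sel <- which(abs(dt - lag) <= tol & dt > 0)
    if (!length(sel)) next
    d2 <- (s$x[sel] - s$x[1])^2
    if (attr(traj, "dimension") == 2L) d2 <- d2 + (s$y[sel] - s$y[1])^2
    out <- c(out, sqrt(d2))
  }
  out
}

#' @export
print.moment_curve <- function(x, ...) {
  cat("Displacement moment curve: q =", attr(x, "q"),
      " (", attr(x, "method"), " estimate), ", nrow(x), " lags\n")
  print.data.frame(utils::head(as.data.frame(x), 8))
  if (nrow(x) > 8) cat("  ...\n")
  invisible(x)
}

#' @export
plot.moment_curve <- function(x, ...) {
  plot(x$lag, x$value, log = "xy", xlab = "lag",
       ylab = bquote("<|" * Delta * "x|"^.(attr(x, "q")) * ">"), ...)
  if (!is.null(x$lo)) {
    graphics::arrows(x$lag, x$lo, x$lag, x$hi, angle = 90, code = 3,
                     length = 0.02, col = "grey50")
  }
  invisible(x)
}

#' Hurst exponent from two moment values
#'
#' The exact two-time relation
#' \deqn{H(q) = \ln\!\left[\frac{\langle|\Delta x|^q\rangle(t_1)}
#'  {\langle|\Delta x|^q\rangle(t_2)}\right]\frac{1}{q\ln(t_1/t_2)}}
#' (exact under pure power-law scaling of the moments).
#'
#' @param m1,m2 q-th moment values at times `t1`, `t2` (both positive).
#' @param t1,t2 the two times (distinct, positive).
#' @param q moment order(s).
#' @return H(q), same length as `q`.
#' @examples
#' hurst_from_moments(2, 4, 1, 2, q = 2)   # 0.5: diffusive doubling
#' @export
hurst_from_moments <- function(m1, m2, t1, t2, q) {
  stopifnot(t1 > 0, t2 > 0, t1 != t2, all(q > 0))
  if (any(c(m1, m2) <= 0) || anyNA(c(m1, m2)))
    stop("moments must be positive for the Hurst log-ratio to be defined")
  log(m1 / m2) / (q * log(t1 / t2))
}

#' Multifractal Hurst-exponent estimate from trajectories
#'
#' Estimates H(q) over a grid of moment orders by applying
#' [hurst_from_moments()] to empirical moments at two lags, with
#' percentile bootstrap intervals obtained by resampling displacement
#' pairs. A trajectory set is flagged monofractal when every H(q) interval
#' overlaps every other (no detectable q-dependence); the fractal dimension
#' \eqn{\delta = 2 - H} is reported alongside. Estimates outside the
#' plausibility band \eqn{[0, 1.25]} are flagged.
#'
#' @param traj a [trajectory_set()].
#' @param q vector of moment orders.
#' @param t1,t2 the two lags (default: the widest well-populated decade,
#'   i.e. the smallest lag with at least `min_pairs` displacement pairs and
#'   the largest lag below the median time span with as many).
#' @param B bootstrap resamples.
#' @param min_pairs minimum displacement pairs per lag for the automatic
#'   lag choice.
#' @param lag_tol lag matching tolerance (see [empirical_moment()]).
#' @param seed RNG seed for the bootstrap.
#' @param method displacement pooling, as in [empirical_moment()];
#'   `"origin"` (default) is required for aging (anomalous) walks.
#' @return Object of class `"hurst_estimate"`: data frame with columns
#'   `q`, `H`, `lo`, `hi`, `delta`, `implausible`, plus attributes `t1`,
#'   `t2`, `monofractal`.
#' @export
hurst_exponent <- function(traj, q = c(0.5, 1, 2, 3), t1 = NULL, t2 = NULL,
                           B = 200L, min_pairs = 30L, lag_tol = NULL,
                           seed = NULL, method = c("origin", "pairs")) {
  stopifnot(inherits(traj, "trajectory_set"), all(q > 0))
  method <- match.arg(method)
  displ <- if (method == "origin") .origin_displacements
           else .lag_displacements
  if (!is.null(seed)) set.seed(seed)
  if (is.null(lag_tol)) {
    dts <- unlist(tapply(traj$t, traj$id, function(tt) diff(tt)))
    lag_tol <- stats::median(dts) / 2
  }
  if (is.null(t1) || is.null(t2)) {
    auto <- .choose_hurst_lags(traj, lag_tol, min_pairs, displ)
    if (is.null(t1)) t1 <- auto[1]
    if (is.null(t2)) t2 <- auto[2]
  }
  stopifnot(t1 != t2)
  d1 <- displ(traj, t1, lag_tol)
  d2 <- displ(traj, t2, lag_tol)
  if (!length(d1) || !length(d2))
    stop("no displacement pairs at the chosen lags (t1 = ", format(t1),
         ", t2 = ", format(t2), ")")
  Hhat <- vapply(q, function(qq)
    hurst_from_moments(mean(d1^qq), mean(d2^qq), t1, t2, qq), numeric(1))
  lo <- hi <- rep(NA_real_, length(q))
  if (B > 0) {
    bmat <- matrix(NA_real_, B, length(q))
    for (b in seq_len(B)) {
      r1 <- sample(d1, replace = TRUE)
      r2 <- sample(d2, replace = TRUE)
      bmat[b, ] <- vapply(q, function(qq) {
        m1 <- mean(r1^qq); m2 <- mean(r2^qq)
        if (m1 <= 0 || m2 <= 0) return(NA_real_)
        hurst_from_moments(m1, m2, t1, t2, qq)
      }, numeric(1))
    }
    lo <- apply(bmat, 2, stats::quantile, 0.025, na.rm = TRUE)
    hi <- apply(bmat, 2, stats::quantile, 0.975, na.rm = TRUE)
  }
  mono <- if (B > 0) max(lo, na.rm = TRUE) <= min(hi, na.rm = TRUE) else NA
  out <- data.frame(q = q, H = Hhat, lo = lo, hi = hi,
                    delta = 2 - Hhat,
                    implausible = Hhat < 0 | Hhat > 1.25)
  structure(out, t1 = t1, t2 = t2, monofractal = mono,
            class = c("hurst_estimate", "data.frame"))
}

# widest well-populated pair of lags roughly a decade apart
.choose_hurst_lags <- function(traj, tol, min_pairs,
                               displ = .origin_displacements) {
  dts <- unlist(tapply(traj$t, traj$id, function(tt) diff(tt)))
  base <- stats::median(dts)
  span <- stats::median(tapply(traj$t, traj$id,
                               function(tt) max(tt) - min(tt)))
  cand <- base * 2^(0:20)
  cand <- cand[cand <= span / 2]
  ok <- vapply(cand, function(l)
    length(displ(traj, l, tol)) >= min_pairs, logical(1))
  cand <- cand[ok]
  if (length(cand) < 2)
    stop("not enough well-populated lags to choose (t1, t2) automatically")
  c(cand[1], cand[length(cand)])
}

#' @export
print.hurst_estimate <- function(x, ...) {
  cat("Hurst exponent estimate (t1 =", format(attr(x, "t1")),
      ", t2 =", format(attr(x, "t2")), ")\n")
  print.data.frame(cbind(as.data.frame(x)[c("q", "H", "lo", "hi", "delta")]),
                   digits = 4, row.names = FALSE)
  if (isTRUE(attr(x, "monofractal")))
    cat("  H(q) is q-independent within bootstrap bands: monofractal\n")
  else if (isFALSE(attr(x, "monofractal")))
    cat("  H(q) varies with q beyond bootstrap bands: multifractal\n")
  if (any(x$implausible))
    cat("  warning: H outside the plausibility band [0, 1.25]\n")
  invisible(x)
}

#' @export
coef.hurst_estimate <- function(object, ...) {
  stats::setNames(object$H, paste0("H(q=", object$q, ")"))
}

#' @export
summary.hurst_estimate <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
plot.hurst_estimate <- function(x, ...) {
  plot(x$q, x$H, ylim = range(c(x$lo, x$hi, x$H), na.rm = TRUE),
       xlab = "q", ylab = "H(q)", pch = 19, ...)
  if (!all(is.na(x$lo)))
    graphics::arrows(x$q, x$lo, x$q, x$hi, angle = 90, code = 3,
                     length = 0.03)
  invisible(x)
}

# ---- steady-state potential fitting -----------------------------------

#' Fit a confining-potential shape to the long-time occupation
#'
#' Maximum-likelihood fit of the separable Boltzmann steady state
#' \eqn{P(x,y) \propto e^{-[U(x-x_c)+V(y-y_c)]/D}} to relocation fixes,
#' over a chosen potential family: estimates the length scale `L` (shared
#' by both axes) and the centre \eqn{(x_c, y_c)}. Only the ratio
#' \eqn{U/D} is identifiable from the occupation histogram; measuring `D`
#' itself requires the time structure (see
#' [fit_likelihood()]). Fixes should be approximately independent: supply
#' `thin` to subsample each animal at that time interval.
#'
#' @param traj a [trajectory_set()] (fixes of one animal or of several
#'   animals sharing a home-range shape and centre).
#' @param family potential family name (see [potential()]); families whose
#'   Boltzmann weight is integrable.
#' @param thin optional thinning interval (time units).
#' @return Object of class `"ss_fit"`: list with `L`, `centre`, `family`,
#'   `logLik`, `n`.
#' @export
fit_steady_state <- function(traj, family = "harmonic", thin = NULL) {
  stopifnot(inherits(traj, "trajectory_set"))
  dimension <- attr(traj, "dimension")
  df <- as.data.frame(traj)
  if (!is.null(thin)) df <- .thin_fixes(df, thin)
  n <- nrow(df)
  if (n < 20) stop("too few fixes (", n, ") to fit a steady state")
  xc0 <- mean(df$x); yc0 <- if (dimension == 2L) mean(df$y) else 0
  L0 <- sqrt(2 * stats::var(df$x))
  if (!is.finite(L0) || L0 <= 0) stop("non-identifiable centre/scale: ",
                                      "fixes are degenerate")
  logZ <- function(L) {
    pot <- potential(family, L = L)
    log(.pot_integrate(function(z) exp(-pot$u(z)), pot$support))
  }
  nll <- function(par) {
    L <- exp(par[1]); xc <- par[2]
    pot <- potential(family, L = L)
    v <- sum(pot$u(df$x - xc))
    if (dimension == 2L) v <- v + sum(pot$u(df$y - par[3]))
    v + dimension * n * logZ(L)
  }
  par0 <- c(log(L0), xc0, if (dimension == 2L) yc0)
  opt <- stats::optim(par0, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  structure(list(L = exp(opt$par[1]),
                 centre = c(x = opt$par[2],
                            y = if (dimension == 2L) opt$par[3] else NA),
                 family = family, logLik = -opt$value, n = n,
                 convergence = opt$convergence),
            class = "ss_fit")
}

.thin_fixes <- function(df, thin) {
  do.call(rbind, lapply(split(df, df$id), function(s) {
    sel <- integer(0)
    last <- -Inf
    for (k in seq_len(nrow(s))) {
      if (s$t[k] - last >= thin) { sel <- c(sel, k); last <- s$t[k] }
    }
    s[sel, , drop = FALSE]
  }))
}

#' @export
print.ss_fit <- function(x, ...) {
  cat("Steady-state potential fit (", x$family, " family, n = ", x$n,
      " fixes)\n", sep = "")
  cat(sprintf("  L = %.6g   centre = (%.6g, %.6g)   logLik = %.4f\n",
              x$L, x$centre[1], x$centre[2], x$logLik))
  invisible(x)
}

#' @export
coef.ss_fit <- function(object, ...) {
  c(L = object$L, xc = unname(object$centre[1]),
    yc = unname(object$centre[2]))
}

#' @export
logLik.ss_fit <- function(object, ...) {
  structure(object$logLik, df = 3, class = "logLik")
}

# ---- maximum-likelihood movement fits ---------------------------------

# hand-rolled Latin hypercube over [0,1]^d
.lhs_points <- function(n, d) {
  sapply(seq_len(d), function(j)
    (sample(n) - stats::runif(n)) / n)
}

# per-pair OU transition log-density (harmonic tethering): both axes
.ou_nll <- function(par, pairs, dimension) {
  D <- exp(par[1]); L <- exp(par[2])
  xc <- par[3]; yc <- if (dimension == 2L) par[4] else 0
  th <- 2 * D / L^2                         # relaxation rate
  rho <- exp(-th * pairs$dt)
  s2 <- (L^2 / 2) * (1 - rho^2)
  if (any(s2 <= 0)) return(1e10)
  ll <- stats::dnorm(pairs$x1, xc + (pairs$x0 - xc) * rho, sqrt(s2),
                     log = TRUE)
  if (dimension == 2L)
    ll <- ll + stats::dnorm(pairs$y1, yc + (pairs$y0 - yc) * rho, sqrt(s2),
                            log = TRUE)
  v <- -sum(ll)
  if (!is.finite(v)) 1e10 else v
}

# adiabatic long-time territorial density: per-axis mixture of uniforms
# over the stationary boundary separation (normal around Lbar, sd
# sqrt(2/gamma), reflected at 0): p(x) = int_{2|x|}^inf q(s)/s ds
.adiabatic_logdens <- function(x, Lbar, gamma) {
  sd <- sqrt(2 / gamma)
  hi <- Lbar + 10 * sd
  nodes <- 96
  vapply(x, function(xx) {
    lo <- 2 * abs(xx)
    if (lo >= hi) return(-Inf)
    gl <- seq(lo, hi, length.out = nodes)
    q <- stats::dnorm(gl, Lbar, sd) + stats::dnorm(-gl, Lbar, sd)
    v <- sum(diff(gl) * (utils::head(q / gl, -1) + utils::tail(q / gl, -1)) / 2)
    if (v <= 0) -Inf else log(v)
  }, numeric(1))
}

.adiabatic_nll <- function(par, df, dimension) {
  Lbar <- exp(par[1]); gamma <- exp(par[2])
  xc <- par[3]; yc <- if (dimension == 2L) par[4] else 0
  v <- -sum(.adiabatic_logdens(df$x - xc, Lbar, gamma))
  if (dimension == 2L)
    v <- v - sum(.adiabatic_logdens(df$y - yc, Lbar, gamma))
  if (!is.finite(v)) 1e10 else v
}

#' Maximum-likelihood movement-parameter estimation with bootstrap
#'
#' Fits movement parameters to (approximately independent) relocation
#' fixes by direct-search simplex maximization of the log-likelihood
#' \eqn{\Xi = \sum_n \ln p(x_n, y_n, t_n | \theta)}, with multi-start from
#' Latin-hypercube initial points and percentile bootstrap intervals from
#' resampled fixes.
#'
#' Models:
#' \describe{
#'   \item{`homerange_smoluchowski`}{harmonically tethered diffusion
#'     (Ornstein-Uhlenbeck): parameters `D` (diffusivity), `L` (home-range
#'     length; stationary variance \eqn{L^2/2} per axis) and the centre.
#'     The likelihood uses the exact transition density between
#'     consecutive fixes, so `D` and `L` are jointly identifiable.}
#'   \item{`trw_adiabatic`}{long-time adiabatic territorial occupation:
#'     positions relative to the home-range centre are distributed as the
#'     boundary-averaged uniform occupation, a mixture over the stationary
#'     edge separation (mean `Lbar`, variance `2/gamma`). Parameters
#'     `Lbar`, `gamma` and the centre; the fast movement parameters (v, T)
#'     and the boundary diffusivity K drop out of this stationary limit.}
#' }
#'
#' @param traj a [trajectory_set()].
#' @param model `"homerange_smoluchowski"` or `"trw_adiabatic"`.
#' @param thin optional thinning interval applied before fitting.
#' @param B number of bootstrap resamples (0 = none).
#' @param restarts number of Latin-hypercube starts.
#' @param seed RNG seed.
#' @return Object of class `"likelihood_fit"`: list with `par` (named
#'   estimates), `logLik`, `trace` (best log-likelihood after each
#'   accepted restart, non-decreasing), `boot` (matrix of bootstrap
#'   estimates) and `ci` (percentile 95% intervals).
#' @examples
#' \donttest{
#' traj <- generate_tethered(n_animals = 5, potential = potential("harmonic", L = 2),
#'                           D = 1, extent = 0, fix_interval = 2,
#'                           duration = 60, seed = 1)
#' fit_likelihood(traj, B = 50, seed = 1)
#' }
#' @export
fit_likelihood <- function(traj,
                           model = c("homerange_smoluchowski",
                                     "trw_adiabatic"),
                           thin = NULL, B = 200L, restarts = 8L,
                           seed = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(traj, "trajectory_set"))
  if (!is.null(seed)) set.seed(seed)
  dimension <- attr(traj, "dimension")
  df <- as.data.frame(traj)
  if (!is.null(thin)) df <- .thin_fixes(df, thin)
  if (nrow(df) < 2) stop("degenerate input: at least two fixes are needed")

  if (model == "homerange_smoluchowski") {
    pairs <- .transition_pairs(df, dimension)
    if (nrow(pairs) < 2) stop("degenerate input: need >= 2 transition pairs")
    nll <- function(par) .ou_nll(par, pairs, dimension)
    # data-driven start ranges
    L0 <- sqrt(2 * stats::var(df$x))
    D0 <- mean((pairs$x1 - pairs$x0)^2 / (2 * pairs$dt))
    centre0 <- c(mean(df$x), if (dimension == 2L) mean(df$y))
    lo <- c(log(D0 / 30), log(L0 / 8), centre0 - L0)
    hi <- c(log(D0 * 30), log(L0 * 8), centre0 + L0)
    par_names <- c("D", "L", "xc", if (dimension == 2L) "yc")
    resample <- function() {
      idx <- sample(nrow(pairs), replace = TRUE)
      p2 <- pairs[idx, , drop = FALSE]
      function(par) .ou_nll(par, p2, dimension)
    }
  } else {
    nll <- function(par) .adiabatic_nll(par, df, dimension)
    L0 <- sqrt(12 * stats::var(df$x))  # width of a uniform with that var
    centre0 <- c(mean(df$x), if (dimension == 2L) mean(df$y))
    lo <- c(log(L0 / 8), log(1e-2 / L0^2 * 2), centre0 - L0)
    hi <- c(log(L0 * 8), log(1e2 / L0^2 * 2), centre0 + L0)
    par_names <- c("Lbar", "gamma", "xc", if (dimension == 2L) "yc")
    resample <- function() {
      idx <- sample(nrow(df), replace = TRUE)
      d2 <- df[idx, , drop = FALSE]
      function(par) .adiabatic_nll(par, d2, dimension)
    }
  }

  d <- length(lo)
  starts <- .lhs_points(restarts, d)
  starts <- t(t(starts) * (hi - lo) + lo)
  best <- NULL
  trace <- numeric(0)
  for (r in seq_len(restarts)) {
    opt <- tryCatch(
      stats::optim(starts[r, ], nll, method = "Nelder-Mead",
                   control = list(maxit = 3000, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
    trace <- c(trace, -best$value)
  }
  if (is.null(best))
    stop("optimizer failed to converge from all ", restarts, " restarts")

  est <- best$par
  est[1:2] <- exp(est[1:2])
  names(est) <- par_names

  boot <- NULL; ci <- NULL
  if (B > 0) {
    boot <- matrix(NA_real_, B, d, dimnames = list(NULL, par_names))
    for (b in seq_len(B)) {
      nb <- resample()
      ob <- tryCatch(
        stats::optim(best$par, nb, method = "Nelder-Mead",
                     control = list(maxit = 1500, reltol = 1e-8)),
        error = function(e) NULL)
      if (is.null(ob)) next
      pb <- ob$par
      pb[1:2] <- exp(pb[1:2])
      boot[b, ] <- pb
    }
    ci <- t(apply(boot, 2, stats::quantile, c(0.025, 0.975), na.rm = TRUE))
  }

  structure(list(par = est, logLik = -best$value, trace = trace,
                 model = model, dimension = dimension,
                 n = nrow(df), boot = boot, ci = ci),
            class = "likelihood_fit")
}

.transition_pairs <- function(df, dimension) {
  do.call(rbind, lapply(split(df, df$id), function(s) {
    n <- nrow(s)
    if (n < 2) return(NULL)
    data.frame(x0 = s$x[-n], x1 = s$x[-1],
               y0 = if (dimension == 2L) s$y[-n] else 0,
               y1 = if (dimension == 2L) s$y[-1] else 0,
               dt = diff(s$t))
  }))
}

#' @export
print.likelihood_fit <- function(x, ...) {
  cat("Maximum-likelihood movement fit (", x$model, ", n = ", x$n,
      " fixes)\n", sep = "")
  est <- format(signif(x$par, 5))
  cat("  estimates:", paste(names(x$par), est, sep = " = ",
                            collapse = ", "), "\n")
  cat(sprintf("  logLik = %.4f\n", x$logLik))
  if (!is.null(x$ci)) {
    cat("  95% bootstrap intervals:\n")
    print(signif(x$ci, 5))
  }
  invisible(x)
}

#' @export
coef.likelihood_fit <- function(object, ...) object$par

#' @export
logLik.likelihood_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$par), class = "logLik")
}

#' @export
confint.likelihood_fit <- function(object, parm, level = 0.95, ...) {
  if (is.null(object$boot)) stop("fit has no bootstrap sample")
  a <- (1 - level) / 2
  ci <- t(apply(object$boot, 2, stats::quantile, c(a, 1 - a),
                na.rm = TRUE))
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
summary.likelihood_fit <- function(object, ...) {
  print(object)
  cat("  optimizer trace (best logLik per accepted restart):\n   ",
      paste(format(signif(object$trace, 6)), collapse = " "), "\n")
  invisible(object)
}
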