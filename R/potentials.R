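#' Confining potentials for home-range models
#'
#' Constructs a dimensionless confining potential \eqn{U(x)/D} with intrinsic
#' length scale `L`. The potential is the generator of a home range: an animal
#' tethered to a centre (burrow, den) by the drift \eqn{-U'(x)} and diffusing
#' with constant \eqn{D} reaches the Boltzmann steady state
#' \eqn{p(x) \propto e^{-U(x)/D}}. Only the ratio \eqn{U/D} ever enters the
#' steady-state theory, so potentials are stored dimensionless; \eqn{D}
#' appears separately in the dynamical generators.
#'
#' Built-in families (offset \eqn{x} measured from the centre):
#' \describe{
#'   \item{`harmonic`}{\eqn{U/D = x^2/L^2}; Gaussian steady state with
#'     variance \eqn{L^2/2}.}
#'   \item{`logarithmic`}{\eqn{U/D = \ln(1 + x^2/L^2)}; Lorentzian (Cauchy)
#'     steady state with scale \eqn{L}. Heavy-tailed: the second moment
#'     diverges, so [home_range_length()] is undefined for this family, but
#'     the windowed saturation MSD is finite and has the closed form
#'     [msd_ss_logarithmic()].}
#'   \item{`log_cubed`}{\eqn{U/D = \ln(1 + 2x^2/L^2)^3}; power-law steady
#'     state \eqn{(1+2x^2/L^2)^{-3}} with finite moments.}
#'   \item{`box_erf`}{smoothed box: steady state proportional to
#'     \eqn{\mathrm{erf}[a(x/L+1/2)] - \mathrm{erf}[a(x/L-1/2)]} with
#'     \eqn{a = \sqrt{6\pi/11}}, i.e. a width-`L` box convolved with a
#'     Gaussian.}
#'   \item{`hard_box`}{\eqn{U = 0} on \eqn{(-L/2, L/2)}, infinite outside;
#'     `L` is the box width. Integrals are truncated to the support.}
#'   \item{`multi_harmonic`}{piecewise quadratic with two harmonic regimes of
#'     different curvature, C1-matched at a crossover radius: inner
#'     \eqn{s_{in} x^2/L^2} for \eqn{|x| \le r_0}, continuing with curvature
#'     \eqn{s_{out}/L^2} outside. A reconstruction of a two-regime
#'     den-attraction potential; parameters `s_in`, `s_out`, `r0`
#'     (defaults 1, 5, `L`).}
#'   \item{`custom`}{tabulated `(offset, U/D)` pairs (two-column matrix,
#'     data frame, or path to a two-column text file), linearly interpolated
#'     and extrapolated quadratically beyond the last tabulated point, or a
#'     function of the offset.}
#' }
#'
#' @param family character; one of `"harmonic"`, `"logarithmic"`,
#'   `"log_cubed"`, `"box_erf"`, `"hard_box"`, `"multi_harmonic"`, `"custom"`.
#' @param L length scale (same units as positions, e.g. metres). For
#'   `hard_box` this is the box width.
#' @param table for `family = "custom"`: two-column matrix/data frame of
#'   `(offset, U/D)` values, or the path of a two-column whitespace- or
#'   comma-separated text file.
#' @param fun for `family = "custom"`: a vectorised function of the offset
#'   returning \eqn{U/D}. Exactly one of `table`/`fun` must be given.
#' @param s_in,s_out,r0 shape parameters of the `multi_harmonic` family.
#' @return An object of class `"potential"`: a list with elements `family`,
#'   `L`, `params`, `u` (the \eqn{U(x)/D} function of the offset) and
#'   `support` (finite only for `hard_box`).
#' @examples
#' pot <- potential("harmonic", L = 50)
#' pot$u(25)            # U(25 m)/D = 0.25
#' home_range_length(pot)
#' @seealso [boltzmann_density()], [home_range_length()], [self_convolution()]
#' @export
potential <- function(family = c("harmonic", "logarithmic", "log_cubed",
                                 "box_erf", "hard_box", "multi_harmonic",
                                 "custom"),
                      L = 1, table = NULL, fun = NULL,
                      s_in = 1, s_out = 5, r0 = L) {
  family <- match.arg(family)
  stopifnot(is.numeric(L), length(L) == 1L, is.finite(L), L > 0)
  support <- c(-Inf, Inf)
  params <- list()
  u <- switch(family,
    harmonic = function(x) (x / L)^2,
    logarithmic = function(x) log1p((x / L)^2),
    log_cubed = function(x) 3 * log1p(2 * (x / L)^2),
    box_erf = {
      a <- sqrt(6 * pi / 11)
      function(x) {
        g <- .erf(a * (x / L + 0.5)) - .erf(a * (x / L - 0.5))
        # erf difference underflows to 0 far out; continue with the
        # quadratic tail of -log of the Gaussian-convolved box
        out <- ifelse(g > 0, -log(pmax(g, .Machine$double.xmin)),
                      a^2 * (abs(x) / L - 0.5)^2)
        far <- g <= .Machine$double.xmin * 8
        if (any(far)) out[far] <- a^2 * (abs(x[far]) / L - 0.5)^2
        out
      }
    },
    hard_box = {
      support <- c(-L / 2, L / 2)
      function(x) ifelse(abs(x) < L / 2, 0, Inf)
    },
    multi_harmonic = {
      stopifnot(s_in > 0, s_out > 0, r0 > 0)
      params <- list(s_in = s_in, s_out = s_out, r0 = r0)
      function(x) {
        ax <- abs(x)
        ifelse(ax <= r0,
               s_in * (ax / L)^2,
               (s_in * r0^2 + 2 * s_in * r0 * (ax - r0) +
                  s_out * (ax - r0)^2) / L^2)
      }
    },
    custom = .custom_potential(table, fun)
  )
  structure(list(family = family, L = L, params = params,
                 u = u, support = support),
            class = "potential")
}

# error function via the normal CDF
.erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

.custom_potential <- function(table, fun) {
  if (is.null(table) == is.null(fun))
    stop("custom potential needs exactly one of `table` or `fun`")
  if (!is.null(fun)) {
    stopifnot(is.function(fun))
    return(fun)
  }
  if (is.character(table)) {
    table <- utils::read.table(table, header = FALSE,
                               sep = "", comment.char = "#",
                               col.names = c("offset", "u"))
  }
  table <- as.matrix(table)
  if (ncol(table) != 2L || nrow(table) < 3L || anyNA(table))
    stop("custom potential table must be numeric with columns (offset, U/D) and >= 3 rows")
  ord <- order(table[, 1L])
  xs <- table[ord, 1L]; us <- table[ord, 2L]
  if (anyDuplicated(xs)) stop("duplicate offsets in custom potential table")
  n <- length(xs)
  # quadratic through the last three points on each side, for extrapolation
  qfit <- function(idx) {
    cf <- stats::lm.fit(cbind(1, xs[idx], xs[idx]^2), us[idx])$coefficients
    cf[is.na(cf)] <- 0
    cf
  }
  lo_cf <- qfit(1:3); hi_cf <- qfit((n - 2):n)
  function(x) {
    out <- stats::approx(xs, us, xout = x, rule = 2)$y
    below <- x < xs[1L]; above <- x > xs[n]
    if (any(below))
      out[below] <- lo_cf[1] + lo_cf[2] * x[below] + lo_cf[3] * x[below]^2
    if (any(above))
      out[above] <- hi_cf[1] + hi_cf[2] * x[above] + hi_cf[3] * x[above]^2
    out
  }
}

#' @export
print.potential <- function(x, ...) {
  cat("Confining potential U(x)/D\n")
  cat("  family:", x$family, "  length scale L:", format(x$L), "\n")
  if (length(x$params))
    cat("  shape parameters:",
        paste(names(x$params), unlist(x$params), sep = " = ",
              collapse = ", "), "\n")
  if (is.finite(x$support[1]))
    cat("  support: (", x$support[1], ",", x$support[2], ")\n")
  invisible(x)
}

#' @export
plot.potential <- function(x, xlim = c(-3, 3) * x$L, n = 401, ...) {
  xs <- seq(xlim[1], xlim[2], length.out = n)
  us <- x$u(xs)
  us[!is.finite(us)] <- NA
  plot(xs, us, type = "l", xlab = "offset from centre",
       ylab = "U(x)/D", main = paste0("potential (", x$family, ")"), ...)
  invisible(x)
}

# ---- quadrature helpers ------------------------------------------------

# integrate g over the potential's support; infinite ranges go through
# stats::integrate's transformation. rel.tol kept tight: steady-state
# integrands are smooth.
.pot_integrate <- function(g, support, rel.tol = 1e-10, ...) {
  # adaptive quadrature first, with graded tolerances; non-smooth
  # integrands (tabulated potentials have kinks at every node) fall back
  # to a dense trapezoid on a compactified variable
  for (tol in unique(c(rel.tol, 1e-8))) {
    res <- tryCatch(
      stats::integrate(g, support[1], support[2], rel.tol = tol,
                       subdivisions = 800L, ...),
      error = function(e) e)
    if (!inherits(res, "error")) return(res$value)
  }
  .trapz_compactified(g, support)
}

# trapezoid rule after mapping (possibly infinite) limits onto (0, 1)
.trapz_compactified <- function(g, support, n = 80001L) {
  a <- support[1]; b <- support[2]
  s <- seq(1e-9, 1 - 1e-9, length.out = n)
  if (is.finite(a) && is.finite(b)) {
    x <- a + (b - a) * s
    w <- rep(b - a, n)
  } else if (is.finite(a)) {          # (a, Inf)
    x <- a + s / (1 - s)
    w <- 1 / (1 - s)^2
  } else if (is.finite(b)) {          # (-Inf, b)
    x <- b - (1 - s) / s
    w <- 1 / s^2
  } else {                            # whole line: x = t/(1-t^2)
    t <- 2 * s - 1
    x <- t / (1 - t^2)
    w <- 2 * (1 + t^2) / (1 - t^2)^2
  }
  y <- g(x) * w
  y[!is.finite(y)] <- 0
  sum((y[-1] + y[-n]) / 2 * diff(s))
}

# Convergence check for int exp(-u) x^pow dx on (0, Inf): the integral on
# successive annuli [R, 2R] must decay geometrically. Returns TRUE/FALSE.
.tail_converges <- function(u, L, pow = 0) {
  g <- function(x) exp(-u(x)) * x^pow
  radii <- L * 2^(3:9)
  inc <- vapply(seq_along(radii)[-1], function(i) {
    tryCatch(stats::integrate(g, radii[i - 1], radii[i],
                              rel.tol = 1e-8)$value,
             error = function(e) NA_real_)
  }, numeric(1))
  if (anyNA(inc)) return(FALSE)
  # geometric decay of annulus contributions
  all(inc[-1] <= 0.75 * pmax(inc[-length(inc)], .Machine$double.xmin)) ||
    all(inc < 1e-14 * max(inc[1], .Machine$double.xmin))
}

.check_integrable <- function(pot) {
  if (is.finite(pot$support[2])) return(invisible(TRUE))
  if (!.tail_converges(pot$u, pot$L, pow = 0))
    stop("normalization integral of exp(-U/D) does not converge: ",
         "potential does not grow fast enough at large |x|", call. = FALSE)
  invisible(TRUE)
}

# ---- Boltzmann steady state -------------------------------------------

#' Boltzmann steady-state density of a confining potential
#'
#' The stationary distribution of an overdamped walker tethered by the
#' potential is \eqn{p(x) = e^{-U(x-c)/D} / \int e^{-U(x'-c)/D} dx'},
#' independent of the initial condition.
#'
#' @param potential a [potential()] object.
#' @param centre location of the potential minimum (the burrow/den site).
#' @param x optional abscissae at which to tabulate the density; by default
#'   an automatically chosen grid covering the support of the density.
#' @param n number of grid points when `x` is not supplied.
#' @return An object of class `"density_1d"`: a data frame with columns
#'   `abscissae` and `values` (probability density, 1/length); the
#'   normalization constant is kept in attribute `"norm"`.
#' @examples
#' d <- boltzmann_density(potential("harmonic", L = 1))
#' sum(diff(d$abscissae) * (head(d$values, -1) + tail(d$values, -1)) / 2)
#' @export
boltzmann_density <- function(potential, centre = 0, x = NULL, n = 2048L) {
  stopifnot(inherits(potential, "potential"))
  .check_integrable(potential)
  u <- potential$u
  Z <- .pot_integrate(function(z) exp(-u(z)), potential$support)
  if (!is.finite(Z) || Z <= 0)
    stop("normalization integral of exp(-U/D) does not converge")
  if (is.null(x)) {
    half <- .density_halfwidth(potential)
    x <- centre + seq(-half, half, length.out = n)
  }
  vals <- exp(-u(x - centre)) / Z
  vals[!is.finite(vals)] <- 0
  structure(data.frame(abscissae = x, values = vals),
            norm = Z, centre = centre, family = potential$family,
            class = c("density_1d", "data.frame"))
}

# half-width where the density has decayed to ~1e-16 of its peak
.density_halfwidth <- function(pot) {
  if (is.finite(pot$support[2])) return(pot$support[2])
  target <- pot$u(0) + 40
  f <- function(x) pot$u(x) - target
  hi <- pot$L
  while (f(hi) < 0 && hi < pot$L * 1e8) hi <- hi * 2
  stats::uniroot(f, c(pot$L * 1e-6, hi), tol = 1e-6 * pot$L)$root
}

#' @export
print.density_1d <- function(x, ...) {
  cat("Boltzmann steady-state density (", attr(x, "family"),
      " potential), centre ", format(attr(x, "centre")),
      ", ", nrow(x), " grid points\n", sep = "")
  invisible(x)
}

#' @export
plot.density_1d <- function(x, ...) {
  plot(x$abscissae, x$values, type = "l", xlab = "position",
       ylab = "density", ...)
  invisible(x)
}

# ---- self-convolution --------------------------------------------------

#' Self-convolution of the Boltzmann weight
#'
#' Returns the function
#' \eqn{f(y) = \int dz\, \exp\{-[U(z) + U(z-y)]/D\}}, the convolution of
#' \eqn{e^{-U/D}} with itself. `f` is the motion factor of the windowed
#' steady-state MSD (see [msd_ss_numeric()]); it is even in `y`.
#'
#' @param potential a [potential()] object.
#' @param rel.tol relative quadrature tolerance per offset.
#' @return A vectorised function of the offset `y`.
#' @examples
#' f <- self_convolution(potential("harmonic", L = 1))
#' f(0)  # = integral of exp(-2 U/D) = sqrt(pi/2)
#' @export
self_convolution <- function(potential, rel.tol = 1e-10) {
  stopifnot(inherits(potential, "potential"))
  .check_integrable(potential)
  u <- potential$u
  s <- potential$support
  function(y) {
    vapply(y, function(yy) {
      lo <- max(s[1], s[1] + yy); hi <- min(s[2], s[2] + yy)
      if (lo >= hi) return(0)
      res <- tryCatch(
        stats::integrate(function(z) exp(-(u(z) + u(z - yy))), lo, hi,
                         rel.tol = rel.tol, subdivisions = 400L),
        error = function(e)
          stop("self-convolution quadrature failed at offset ",
               format(yy), ": ", conditionMessage(e), call. = FALSE))
      res$value
    }, numeric(1))
  }
}

# ---- intrinsic home-range length --------------------------------------

#' Intrinsic home-range length of a potential
#'
#' The home-range length is defined from the second moment of the Boltzmann
#' weight,
#' \deqn{L = \sqrt{\frac{2\int_0^\infty x^2 e^{-U(x)/D} dx}
#'                     {\int_0^\infty e^{-U(x)/D} dx}},}
#' i.e. \eqn{L^2} is twice the steady-state positional variance. For the
#' harmonic family this returns the stored length scale exactly; a hard box
#' of width \eqn{a} gives \eqn{a/\sqrt{6}}.
#'
#' @param potential a [potential()] object.
#' @return The home-range length (same units as `L`).
#' @examples
#' home_range_length(potential("harmonic", L = 2))   # 2
#' home_range_length(potential("hard_box", L = 1))   # 1/sqrt(6)
#' @export
home_range_length <- function(potential) {
  stopifnot(inherits(potential, "potential"))
  .check_integrable(potential)
  u <- potential$u
  hi <- if (is.finite(potential$support[2])) potential$support[2] else Inf
  if (!is.finite(hi)) {
    if (!.tail_converges(u, potential$L, pow = 2)) {
      # name the tail: slope of U/D against log x
      xs <- potential$L * c(1e3, 1e4)
      slope <- (u(xs[2]) - u(xs[1])) / log(xs[2] / xs[1])
      stop("second moment of exp(-U/D) diverges: potential grows only like ",
           format(round(slope, 2)), " * log(x) at large x (needs tail ",
           "decay faster than x^-3)", call. = FALSE)
    }
  }
  num <- .pot_integrate(function(x) x^2 * exp(-u(x)), c(0, hi))
  den <- .pot_integrate(function(x) exp(-u(x)), c(0, hi))
  sqrt(2 * num / den)
}

#' Home-range length via the reciprocal-space route
#'
#' Evaluates the same length as [home_range_length()] from the Fourier
#' transform \eqn{\hat P(k)} of the Boltzmann weight,
#' \eqn{L = \sqrt{-2 [\hat P''(k)/\hat P(k)]_{k=0}}}, using a numerical
#' transform and Richardson-extrapolated central differences. Provided as an
#' independent route for cross-checking; the two agree to high accuracy for
#' all families with finite second moment.
#'
#' @param potential a [potential()] object.
#' @return The home-range length.
#' @export
home_range_length_kspace <- function(potential) {
  stopifnot(inherits(potential, "potential"))
  .check_integrable(potential)
  u <- potential$u
  s <- potential$support
  Phat <- function(k) .pot_integrate(function(x) exp(-u(x)) * cos(k * x), s)
  p0 <- Phat(0)
  d2 <- function(h) 2 * (Phat(h) - p0) / h^2   # even function: P(h)=P(-h)
  h <- 0.02 / potential$L
  a <- d2(h); b <- d2(h / 2)
  d2_0 <- (4 * b - a) / 3                      # Richardson, O(h^4)
  val <- -2 * d2_0 / p0
  if (!is.finite(val) || val <= 0)
    stop("reciprocal-space curvature is not positive; second moment ",
         "may diverge")
  sqrt(val)
}
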