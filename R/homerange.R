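# Home-range estimation from the saturation of mark-recapture MSD observed
# through a finite trapping window of side G. The steady-state MSD of
# burrow-tethered walkers, pooled over uniformly distributed burrow centres
# and restricted to the window, saturates at a value set jointly by the
# intrinsic home-range length L and by G; the normalized saturation value is
# a monotone sigmoid in zeta = L/G which can be inverted to recover L.

#' Steady-state windowed MSD by quadrature
#'
#' Computes the steady-state mean-square displacement of capture-recapture
#' pairs observed inside a window of side `G`, for walkers tethered to
#' burrows whose locations are uniformly distributed over the terrain:
#' \deqn{\langle\Delta x^2\rangle_{ss} =
#'   \frac{\int_0^G y^2 (G-y) f(y) dy}{\int_0^G (G-y) f(y) dy},}
#' where \eqn{f} is the self-convolution of the Boltzmann weight
#' ([self_convolution()]). In 2d the window is square (or rectangular via
#' `Gy`) and the per-axis values are summed; the potential along the
#' orthogonal axis may differ.
#'
#' A non-uniform burrow-centre density `rho` is accepted and handled by
#' direct triple quadrature of the defining ratio (experimental; a warning
#' is issued).
#'
#' @param potential a [potential()] object (x axis).
#' @param G window side length (same units as the potential's `L`).
#' @param dimension 1 or 2.
#' @param potential_y potential along the y axis (2d only); defaults to
#'   `potential`.
#' @param Gy window side along y (2d only); defaults to `G`.
#' @param rho optional burrow-centre density function (1d only),
#'   experimental.
#' @return Saturation MSD in squared length units.
#' @examples
#' pot <- potential("harmonic", L = 1)
#' msd_ss_numeric(pot, G = 1) / (1 / 6)   # equals msd_ss_harmonic(1)
#' @export
msd_ss_numeric <- function(potential, G, dimension = 1,
                           potential_y = potential, Gy = G, rho = NULL) {
  stopifnot(inherits(potential, "potential"), G > 0,
            dimension %in% c(1, 2))
  if (!is.null(rho)) {
    if (dimension != 1)
      stop("non-uniform burrow density is supported in 1d only")
    warning("non-uniform burrow-centre density: experimental direct ",
            "quadrature of the defining triple integral")
    return(.msd_ss_rho(potential, G, rho))
  }
  val <- .msd_ss_axis(potential, G)
  if (dimension == 2) val <- val + .msd_ss_axis(potential_y, Gy)
  val
}

.msd_ss_axis <- function(pot, G) {
  f <- self_convolution(pot)
  num <- .pot_integrate(function(y) y^2 * (G - y) * f(y), c(0, G),
                        rel.tol = 1e-9)
  den <- .pot_integrate(function(y) (G - y) * f(y), c(0, G),
                        rel.tol = 1e-9)
  if (den <= 0) stop("windowed normalization vanished; check the potential")
  num / den
}

# direct triple quadrature of the defining MSD ratio with burrow density rho
.msd_ss_rho <- function(pot, G, rho) {
  u <- pot$u
  pair_int <- function(xc) {
    # inner double integral over (x0, x) in the window, for fixed centre
    w <- function(x) exp(-u(x - xc))
    m0 <- .pot_integrate(w, c(-G / 2, G / 2), rel.tol = 1e-8)
    m1 <- .pot_integrate(function(x) x * w(x), c(-G / 2, G / 2),
                         rel.tol = 1e-8)
    m2 <- .pot_integrate(function(x) x^2 * w(x), c(-G / 2, G / 2),
                         rel.tol = 1e-8)
    # int int (x-x0)^2 w(x0) w(x) = 2 m2 m0 - 2 m1^2
    c(num = 2 * (m2 * m0 - m1^2), den = m0^2)
  }
  span <- 20 * pot$L + G
  gn <- function(xc) vapply(xc, function(c0) rho(c0) * pair_int(c0)["num"],
                            numeric(1))
  gd <- function(xc) vapply(xc, function(c0) rho(c0) * pair_int(c0)["den"],
                            numeric(1))
  num <- stats::integrate(gn, -span, span, rel.tol = 1e-6,
                          subdivisions = 200L)$value
  den <- stats::integrate(gd, -span, span, rel.tol = 1e-6,
                          subdivisions = 200L)$value
  num / den
}

#' Closed-form normalized saturation MSD, harmonic potential
#'
#' For the harmonic potential \eqn{U/D = x^2/L^2} the normalized
#' steady-state windowed MSD has the closed form
#' \deqn{\frac{\langle\Delta x^2\rangle_{ss}}{G^2/6} = 6\zeta^2\left\{1 +
#'  \frac{\sinh[(1/2\zeta)^2]}{\sinh[(1/2\zeta)^2] - \frac{1}{2\zeta}
#'  \sqrt{\pi/2}\, e^{(1/2\zeta)^2}\,\mathrm{erf}(1/\sqrt{2}\zeta)}\right\}}
#' with \eqn{\zeta = L/G}. Evaluation is numerically stabilised: the ratio is
#' computed with the common factor \eqn{e^{(1/2\zeta)^2}} removed (avoiding
#' overflow at small \eqn{\zeta}) and switches to the asymptotic series
#' \eqn{1 - 7/(60\zeta^2)} for \eqn{\zeta > 20} (where direct evaluation
#' loses precision to cancellation). The curve rises from 0 at
#' \eqn{\zeta \to 0} to 1 as \eqn{\zeta \to \infty}.
#'
#' @param zeta positive ratio L/G (vectorised).
#' @return Normalized saturation MSD in (0, 1).
#' @examples
#' msd_ss_harmonic(c(0.1, 1, 1000))
#' @export
msd_ss_harmonic <- function(zeta) {
  stopifnot(is.numeric(zeta), all(is.finite(zeta)))
  if (any(zeta <= 0)) stop("zeta must be positive")
  out <- numeric(length(zeta))
  big <- zeta > 20
  out[big] <- 1 - 7 / (60 * zeta[big]^2)
  z <- zeta[!big]
  if (length(z)) {
    u <- 1 / (2 * z)
    a <- -expm1(-2 * u^2)                    # 2 e^{-u^2} sinh(u^2), exact
    s <- u * sqrt(2 * pi) * .erf(sqrt(2) * u)
    out[!big] <- 6 * z^2 * (1 + a / (a - s))
  }
  out
}

#' Closed-form normalized saturation MSD, logarithmic potential
#'
#' For the logarithmic potential \eqn{U/D = \ln(1 + x^2/L^2)} (Lorentzian
#' steady state) the normalized steady-state windowed MSD is
#' \deqn{\frac{\langle\Delta x^2\rangle_{ss}}{G^2/6} = 6\left\{
#'   \frac{\zeta}{\arctan(1/2\zeta) - \zeta\ln[1 + 1/(2\zeta)^2]}
#'   - 4\zeta^2\right\}.}
#' Switches to the asymptotic series \eqn{1 - 7/(120\zeta^2)} for
#' \eqn{\zeta > 20}.
#'
#' @inheritParams msd_ss_harmonic
#' @return Normalized saturation MSD in (0, 1).
#' @examples
#' msd_ss_logarithmic(c(0.1, 1, 1000))
#' @export
msd_ss_logarithmic <- function(zeta) {
  stopifnot(is.numeric(zeta), all(is.finite(zeta)))
  if (any(zeta <= 0)) stop("zeta must be positive")
  out <- numeric(length(zeta))
  big <- zeta > 20
  out[big] <- 1 - 7 / (120 * zeta[big]^2)
  z <- zeta[!big]
  if (length(z)) {
    w <- 1 / (2 * z)
    out[!big] <- 6 * (z / (atan(w) - z * log1p(w^2)) - 4 * z^2)
  }
  out
}

#' Saturation curve of normalized MSD against zeta = L/G
#'
#' Tabulates the monotone sigmoid relating the normalized steady-state
#' windowed MSD to \eqn{\zeta = L/G} for a potential family. Closed forms
#' are used for the `harmonic` and `logarithmic` families; all other
#' families go through the quadrature pipeline of [msd_ss_numeric()] with
#' `G = 1`, `L = zeta`.
#'
#' @param family a family name accepted by [potential()], or a `potential`
#'   object used as a shape template (its `L` is overridden along the grid).
#' @param zeta_grid positive, sorted vector of L/G values.
#' @param ... extra arguments passed to [potential()] for numeric families.
#' @return Object of class `"saturation_curve"`: data frame with columns
#'   `zeta` and `msd_norm`, family kept as an attribute.
#' @examples
#' sc <- build_saturation_curve("harmonic", 10^seq(-2, 2, length.out = 41))
#' @export
build_saturation_curve <- function(family, zeta_grid, ...) {
  stopifnot(is.numeric(zeta_grid), length(zeta_grid) >= 1,
            all(is.finite(zeta_grid)), all(zeta_grid > 0),
            !is.unsorted(zeta_grid, strictly = TRUE))
  if (inherits(family, "potential")) {
    fam <- family$family
    make <- function(L) { p <- family; p$L <- L; p }  # not used for closed forms
  } else {
    fam <- match.arg(family, c("harmonic", "logarithmic", "log_cubed",
                               "box_erf", "hard_box", "multi_harmonic"))
    make <- function(L) potential(fam, L = L, ...)
  }
  vals <- switch(fam,
    harmonic = msd_ss_harmonic(zeta_grid),
    logarithmic = msd_ss_logarithmic(zeta_grid),
    vapply(zeta_grid, function(z)
      .msd_ss_axis(.rescale_potential(make, z), 1) / (1 / 6), numeric(1))
  )
  if (length(vals) > 1 && any(diff(vals) <= 0))
    stop("computed saturation curve is not strictly increasing: ",
         "internal-consistency failure (quadrature breakdown)")
  structure(data.frame(zeta = zeta_grid, msd_norm = vals),
            family = fam,
            class = c("saturation_curve", "data.frame"))
}

.rescale_potential <- function(make, L) {
  p <- make(L)
  if (!inherits(p, "potential")) stop("invalid potential template")
  p
}

#' @export
print.saturation_curve <- function(x, ...) {
  cat("Saturation curve (", attr(x, "family"), " potential): ",
      nrow(x), " zeta points in [", format(min(x$zeta)), ", ",
      format(max(x$zeta)), "], normalized MSD in [",
      format(signif(min(x$msd_norm), 4)), ", ",
      format(signif(max(x$msd_norm), 4)), "]\n", sep = "")
  invisible(x)
}

#' @export
plot.saturation_curve <- function(x, ...) {
  plot(x$zeta, x$msd_norm, type = "l", log = "x",
       xlab = expression(zeta == L / G),
       ylab = expression("normalized " * MSD[ss]),
       main = paste0("saturation curve (", attr(x, "family"), ")"), ...)
  invisible(x)
}

#' Invert the saturation curve: home-range length from an observed MSD
#'
#' Given the saturated MSD measured from capture-recapture pairs inside a
#' window of side `G`, solves the monotone saturation curve for
#' \eqn{\zeta = L/G} and returns \eqn{L = \zeta G}. The error interval is
#' propagated by inverting the curve at `msd` \eqn{\pm} `err` (asymmetric in
#' general). The observed value normalized by \eqn{G^2/6} (1d) or
#' \eqn{G^2/3} (2d square window, identical orthogonal potentials) must lie
#' strictly inside (0, 1): 1 is the flat-potential (infinite home range)
#' bound for the windowed MSD.
#'
#' @param msd observed saturation MSD (squared length units).
#' @param err symmetric measurement error on `msd` (same units); 0 for none.
#' @param G window side length.
#' @param curve a [build_saturation_curve()] object, or a family name
#'   (`"harmonic"`/`"logarithmic"`) for closed-form root finding.
#' @param dimension 1 or 2.
#' @return Object of class `"homerange_estimate"` with elements `L`, `L_lo`,
#'   `L_hi`, `zeta`, `zeta_lo`, `zeta_hi`, `family`, `G`, `dimension`,
#'   `msd_norm`.
#' @examples
#' target <- msd_ss_harmonic(0.8) * 100^2 / 6
#' invert_msd(target, err = 0, G = 100, curve = "harmonic")
#' @export
invert_msd <- function(msd, err = 0, G, curve = "harmonic", dimension = 1) {
  stopifnot(is.numeric(msd), length(msd) == 1L, is.numeric(err), err >= 0,
            G > 0, dimension %in% c(1, 2))
  norm_const <- G^2 / 6 * dimension
  inv1 <- function(m) .invert_norm(m / norm_const, curve)
  # interval endpoints may fall outside the invertible band; clamp them to
  # the degenerate limits (pinned walkers / flat potential) instead of
  # failing like the point estimate does
  inv_clamped <- function(m) {
    mn <- m / norm_const
    if (!is.finite(mn) || mn <= 0) return(0)
    if (mn >= 1) return(Inf)
    tryCatch(.invert_norm(mn, curve), error = function(e) {
      if (mn > 0.5) Inf else 0
    })
  }
  zeta <- inv1(msd)
  zlo <- if (err > 0) inv_clamped(msd - err) else zeta
  zhi <- if (err > 0) inv_clamped(msd + err) else zeta
  fam <- if (inherits(curve, "saturation_curve")) attr(curve, "family")
         else curve
  structure(list(L = zeta * G, L_lo = zlo * G, L_hi = zhi * G,
                 zeta = zeta, zeta_lo = zlo, zeta_hi = zhi,
                 family = fam, G = G, dimension = dimension,
                 msd = msd, err = err, msd_norm = msd / norm_const),
            class = "homerange_estimate")
}

# invert a single normalized value in (0,1)
.invert_norm <- function(mnorm, curve) {
  if (!is.finite(mnorm) || mnorm >= 1 || mnorm <= 0)
    stop("normalized MSD ", format(signif(mnorm, 4)),
         " is out of range (0, 1): saturation exceeds flat-potential bound ",
         "or is non-positive")
  if (inherits(curve, "saturation_curve")) {
    y <- curve$msd_norm; z <- curve$zeta
    if (mnorm == y[1]) return(z[1])
    if (mnorm == y[length(y)]) return(z[length(z)])
    if (mnorm < min(y) || mnorm > max(y))
      stop("observed normalized MSD ", format(signif(mnorm, 4)),
           " lies outside the tabulated curve range [",
           format(signif(min(y), 4)), ", ", format(signif(max(y), 4)), "]")
    # monotone interpolation of log(zeta) against the curve ordinate
    sf <- stats::splinefun(y, log(z), method = "hyman")
    return(exp(sf(mnorm)))
  }
  fun <- switch(match.arg(curve, c("harmonic", "logarithmic")),
                harmonic = msd_ss_harmonic,
                logarithmic = msd_ss_logarithmic)
  # bisection in log zeta on [1e-3, 1e3]; curve is monotone so the root
  # is unique
  g <- function(lz) fun(exp(lz)) - mnorm
  lo <- log(1e-3); hi <- log(1e3)
  if (g(lo) > 0 || g(hi) < 0)
    stop("normalized MSD outside the invertible range for this family")
  exp(stats::uniroot(g, c(lo, hi), tol = 1e-10)$root)
}

#' @export
print.homerange_estimate <- function(x, ...) {
  cat("Home-range estimate (", x$family, " potential, ", x$dimension,
      "d window G = ", format(x$G), ")\n", sep = "")
  cat(sprintf("  L    = %.6g  [%.6g, %.6g]\n", x$L,
              min(x$L_lo, x$L_hi), max(x$L_lo, x$L_hi)))
  cat(sprintf("  zeta = %.6g  [%.6g, %.6g]\n", x$zeta,
              min(x$zeta_lo, x$zeta_hi), max(x$zeta_lo, x$zeta_hi)))
  cat(sprintf("  observed MSD = %.6g (normalized %.4f)\n",
              x$msd, x$msd_norm))
  invisible(x)
}

#' @export
coef.homerange_estimate <- function(object, ...) {
  c(L = object$L, zeta = object$zeta)
}

#' @export
summary.homerange_estimate <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Saturated MSD from capture-recapture pairs
#'
#' Computes the steady-state MSD estimate from a capture-pair table (see
#' [mark_recapture_sample()]): the mean of the squared displacement over all
#' pairs whose lag exceeds `lag_min` (the stationarity lag beyond which the
#' tethered walker has relaxed to its steady state), pooling all pairs with
#' equal weight. In 2d the squared displacement is the sum over both axes.
#'
#' @param pairs data frame with columns `dx` (and optionally `dy`), `lag`
#'   and `id`, as produced by [mark_recapture_sample()].
#' @param lag_min stationarity lag; pairs with `lag <= lag_min` are dropped.
#' @return A list with `msd`, its standard error `se` (clustered by animal:
#'   pairs within an animal are strongly correlated, so the error is taken
#'   across animal-level means), `n_pairs` and `n_animals`.
#' @export
saturation_msd <- function(pairs, lag_min = 0) {
  stopifnot(is.data.frame(pairs), "dx" %in% names(pairs),
            "lag" %in% names(pairs))
  keep <- pairs$lag > lag_min
  if (!any(keep)) stop("no capture pairs beyond the stationarity lag")
  pairs <- pairs[keep, , drop = FALSE]
  d2 <- pairs$dx^2
  if ("dy" %in% names(pairs)) d2 <- d2 + pairs$dy^2
  msd <- mean(d2)
  if ("id" %in% names(pairs) && length(unique(pairs$id)) > 1L) {
    cl <- tapply(d2, pairs$id, mean)
    se <- stats::sd(cl) / sqrt(length(cl))
    n_animals <- length(cl)
  } else {
    se <- stats::sd(d2) / sqrt(length(d2))
    n_animals <- 1L
  }
  list(msd = msd, se = se, n_pairs = length(d2), n_animals = n_animals)
}
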