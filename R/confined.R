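# Analytic MSD of a persistent (telegrapher-memory) walker inside a fixed
# rectangular territory, with no-flux walls and uniform initial condition.

#' Parameters of a persistent walker in a fixed rectangular territory
#'
#' Bundles the movement and territory parameters: speed `v`, mean
#' persistence time `T` (the walker keeps its heading for an exponentially
#' distributed time of mean `T`), and territory widths `lambda_x`,
#' `lambda_y`. Derived quantities: per-axis relative correlation
#' \eqn{\zeta_z = vT/\lambda_z} and diffusivity \eqn{D = v^2 T} (consistent
#' with the exponential step memory \eqn{\phi(t) = (v^2/D) e^{-t/T}}).
#'
#' @param v speed (length/time).
#' @param T mean persistence time (time).
#' @param lambda_x,lambda_y territory widths (length).
#' @return Object of class `"confined_walker_params"`.
#' @examples
#' confined_walker_params(v = 1, T = 0.5, lambda_x = 10, lambda_y = 10)
#' @export
confined_walker_params <- function(v, T, lambda_x, lambda_y = lambda_x) {
  stopifnot(v > 0, T > 0, lambda_x > 0, lambda_y > 0)
  structure(list(v = v, T = T, lambda_x = lambda_x, lambda_y = lambda_y,
                 zeta_x = v * T / lambda_x, zeta_y = v * T / lambda_y,
                 D = v^2 * T),
            class = "confined_walker_params")
}

#' @export
print.confined_walker_params <- function(x, ...) {
  cat("Confined persistent walker: v =", format(x$v), " T =", format(x$T),
      "\n  territory", format(x$lambda_x), "x", format(x$lambda_y),
      "  zeta = (", format(signif(x$zeta_x, 4)), ",",
      format(signif(x$zeta_y, 4)), ")  D = v^2 T =", format(x$D), "\n")
  invisible(x)
}

# Per-axis eigenmode sum. Mode m = 2n-1 contributes weight m^-4 and
# frequency Theta_m = sqrt(4 m^2 pi^2 zeta^2 - 1)/(2T); below the
# oscillation threshold the radicand is negative and cos/sin continue
# analytically to cosh/sinh (evaluated in exponential form to avoid
# overflow). `verbatim_n = TRUE` uses the sum index n instead of the mode
# number 2n-1 inside the radicand (the two agree on the n = 1 mode).
.confined_msd_axis <- function(lambda, v, T, t, tol = 1e-12,
                               n_max = 1e5L, verbatim_n = FALSE) {
  zeta <- v * T / lambda
  total <- numeric(length(t))
  partial <- 0
  for (n in seq_len(n_max)) {
    m <- 2L * n - 1L
    w <- 1 / m^4
    freq_idx <- if (verbatim_n) n else m
    rad <- 4 * freq_idx^2 * pi^2 * zeta^2 - 1
    if (abs(rad) < 1e-12) {
      # degenerate mode: Theta -> 0, sin(Theta t)/(2 T Theta) -> t/(2T)
      term <- (1 + t / (2 * T)) * exp(-t / (2 * T))
    } else if (rad > 0) {
      Theta <- sqrt(rad) / (2 * T)
      term <- (cos(Theta * t) + sin(Theta * t) / (2 * T * Theta)) *
        exp(-t / (2 * T))
    } else {
      th <- sqrt(-rad) / (2 * T)        # th < 1/(2T): exponents <= 0
      ep <- exp((th - 1 / (2 * T)) * t)
      em <- exp((-th - 1 / (2 * T)) * t)
      term <- (ep + em) / 2 + (ep - em) / (4 * T * th)
    }
    total <- total + w * term
    partial <- partial + w
    if (w < tol * partial && n > 2L) break
  }
  lambda^2 * (1 / 6 - (16 / pi^4) * total)
}

#' MSD of a persistent walker in a fixed rectangular territory
#'
#' Evaluates the eigenmode series for the mean-square displacement of a
#' persistent walker (speed `v`, mean persistence time `T`, exponential step
#' memory) confined by no-flux walls to a rectangle of sides `lambda_x`,
#' `lambda_y`, starting from a uniform distribution over the territory. Per
#' axis,
#' \deqn{\langle\Delta z^2\rangle(t) = \lambda_z^2\left\{\frac{1}{6}
#'  - \frac{16}{\pi^4}\sum_{n\ge1}\frac{e^{-t/2T}}{(2n-1)^4}
#'  \left[\cos(\Theta_n t) + \frac{\sin(\Theta_n t)}{2T\Theta_n}\right]
#'  \right\}}
#' with \eqn{\Theta_n = \sqrt{4(2n-1)^2\pi^2\zeta_z^2 - 1}/(2T)} and
#' \eqn{\zeta_z = vT/\lambda_z}. When the radicand is negative the
#' trigonometric terms continue analytically to hyperbolic ones; the series
#' is summed adaptively (terms decay as \eqn{(2n-1)^{-4}}).
#'
#' The MSD vanishes at \eqn{t = 0}, is ballistic
#' (\eqn{\approx v^2 t^2}) at short times, and saturates at the plateau
#' \eqn{(\lambda_x^2 + \lambda_y^2)/6}. Damped oscillations around the
#' plateau appear if and only if \eqn{\zeta_z > (2\pi)^{-1}} (the first mode
#' frequency becomes real; see [oscillation_threshold()]).
#'
#' @param params a [confined_walker_params()] object.
#' @param t time or vector of times (\eqn{\ge 0}).
#' @param tol relative series tolerance (term-weight cutoff).
#' @return MSD values (squared length), one per element of `t`.
#' @examples
#' p <- confined_walker_params(v = 1, T = 1, lambda_x = 2)
#' confined_msd(p, c(0, 1, 100))
#' @export
confined_msd <- function(params, t, tol = 1e-12) {
  stopifnot(inherits(params, "confined_walker_params"),
            is.numeric(t), all(is.finite(t)), all(t >= 0))
  .confined_msd_axis(params$lambda_x, params$v, params$T, t, tol) +
    .confined_msd_axis(params$lambda_y, params$v, params$T, t, tol)
}

#' Oscillation threshold of the confined MSD
#'
#' The critical relative correlation \eqn{\zeta_z = vT/\lambda_z} above
#' which the confined-walker MSD develops damped oscillations around its
#' plateau: the first eigenmode frequency
#' \eqn{\Theta_1 = \sqrt{4\pi^2\zeta^2 - 1}/(2T)} turns from imaginary to
#' real at \eqn{\zeta = (2\pi)^{-1}}.
#'
#' @return The threshold value \eqn{1/(2\pi) \approx 0.1592}.
#' @export
oscillation_threshold <- function() 1 / (2 * pi)

#' Effective persistence in a circular arena
#'
#' Dimensionless effective persistence of a correlated random walk observed
#' in a circular arena of radius `R`:
#' \deqn{\xi = -\mathcal{L} / [R \ln\langle\cos\theta\rangle],}
#' where \eqn{\mathcal{L}} is the mean step length and
#' \eqn{\langle\cos\theta\rangle} the mean cosine of the turning angles
#' measured away from the reflecting wall. A uniform turning-angle
#' distribution (\eqn{\langle\cos\theta\rangle = 0}) gives \eqn{\xi = 0}
#' (Brownian limit); \eqn{\langle\cos\theta\rangle \to 1} gives
#' \eqn{\xi \to +\infty} (ballistic limit, returned as `Inf`).
#'
#' @param mean_step mean step length \eqn{\mathcal{L}} (length).
#' @param radius arena radius `R` (length).
#' @param mean_cos mean cosine of turning angles, in \eqn{[0, 1]}.
#' @return The effective persistence \eqn{\xi \ge 0} (possibly `Inf`).
#' @examples
#' effective_persistence(0.1, 1, exp(-1))   # 0.1
#' effective_persistence(0.1, 1, 0)         # 0: uniform turning
#' @export
effective_persistence <- function(mean_step, radius, mean_cos) {
  stopifnot(mean_step >= 0, radius > 0, is.numeric(mean_cos),
            length(mean_cos) == 1L)
  if (mean_cos < 0)
    stop("mean_cos must be non-negative (anti-persistent walks are outside ",
         "the effective-persistence formula's domain)")
  if (mean_cos >= 1) return(Inf)   # ballistic limit, distinguished value
  if (mean_cos == 0) return(0)     # ln -> -Inf, xi -> 0
  -mean_step / (radius * log(mean_cos))
}
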