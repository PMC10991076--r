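#' Fiber orientation distribution (1D)
#'
#' In one dimension the orientational distribution of tissue fibers
#' reduces to the pair \eqn{(q_+(x), q_-(x))} of probabilities of the two
#' directions, with \eqn{q_+ + q_- = 1} at every position (this is the
#' normalisation \eqn{\bar q = 1/d} of the turning kernel).
#'
#' @param qplus,qminus probabilities of the `+`/`-` direction: scalars or
#'   vectorised functions of position.
#' @param tol tolerance for the normalisation check.
#' @return An object of class `fiber_dist_1d` with function fields
#'   `qplus(x)`, `qminus(x)`.
#' @export
fiber_distribution_1d <- function(qplus, qminus, tol = 1e-8) {
  fp <- if (is.function(qplus)) qplus else function(x) rep(qplus, length(x))
  fm <- if (is.function(qminus)) qminus else function(x) rep(qminus, length(x))
  xs <- seq(-10, 10, length.out = 201L)
  qp <- fp(xs); qm <- fm(xs)
  if (any(qp < -tol) || any(qm < -tol))
    stop("fiber distribution must be non-negative")
  if (max(abs(qp + qm - 1)) > tol)
    stop("fiber distribution not normalised: q+ + q- must equal 1")
  structure(list(qplus = fp, qminus = fm), class = "fiber_dist_1d")
}

#' Fiber orientation distribution on the circle (d = 2)
#'
#' @param q non-negative function of the angle `theta` in `[0, 2*pi)`,
#'   normalised so that its integral over the circle is 1 (equivalently
#'   \eqn{\bar q = 1/2} over the unit velocity disc).
#' @param tol tolerance for the normalisation check.
#' @return An object of class `fiber_dist_circle`.
#' @export
fiber_distribution_circle <- function(q, tol = 1e-8) {
  stopifnot(is.function(q))
  total <- stats::integrate(q, 0, 2 * pi, abs.tol = tol / 10)$value
  if (abs(total - 1) > tol)
    stop("fiber distribution not normalised: integral of q over the circle must be 1")
  structure(list(q = q), class = "fiber_dist_circle")
}

#' Directional moments of a fiber distribution
#'
#' Computes the mean fiber direction \eqn{E[q] = \int \theta q(\theta)}
#' and second moment \eqn{D[q] = \int \theta \theta^T q(\theta)} over the
#' unit directions. For `d = 1` these reduce to \eqn{E = q_+ - q_-} and
#' \eqn{D = q_+ + q_- = 1}.
#'
#' @param q a [fiber_distribution_1d()] or [fiber_distribution_circle()].
#' @param x positions at which to evaluate (1D case only).
#' @return For 1D input, a list with numeric vectors `E` and `D`; for the
#'   circle, a list with a length-2 vector `E` and a 2x2 matrix `D`.
#' @export
fiber_moments <- function(q, x = 0) {
  if (inherits(q, "fiber_dist_1d")) {
    qp <- q$qplus(x); qm <- q$qminus(x)
    return(list(E = qp - qm, D = qp + qm))
  }
  if (inherits(q, "fiber_dist_circle")) {
    E <- c(stats::integrate(function(t) cos(t) * q$q(t), 0, 2 * pi)$value,
           stats::integrate(function(t) sin(t) * q$q(t), 0, 2 * pi)$value)
    D <- matrix(c(
      stats::integrate(function(t) cos(t)^2 * q$q(t), 0, 2 * pi)$value,
      stats::integrate(function(t) cos(t) * sin(t) * q$q(t), 0, 2 * pi)$value,
      stats::integrate(function(t) cos(t) * sin(t) * q$q(t), 0, 2 * pi)$value,
      stats::integrate(function(t) sin(t)^2 * q$q(t), 0, 2 * pi)$value), 2, 2)
    if (min(eigen(D, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
      stop("second fiber moment must be positive semidefinite")
    return(list(E = E, D = D))
  }
  stop("unknown fiber distribution class")
}

#' Coefficient fields for the macroscopic solver
#'
#' Builds the affine diffusion-moment field \eqn{D(x) = D_0 + \delta x}
#' and mean-direction field \eqn{E(x)} used by the 1D macroscopic
#' equation. These are treated as free coefficient fields.
#'
#' @param D0 minimum diffusion-moment value, non-negative.
#' @param delta slope of the affine perturbation.
#' @param L domain length (for the non-negativity check).
#' @param E mean-direction field: scalar or function of `x`; default 0.
#' @return An object of class `fiber_field` with vectorised function
#'   fields `D(x)`, `dD(x)` (exact derivative) and `E(x)`.
#' @export
make_fiber_field <- function(D0, delta = 0, L = 6, E = 0) {
  stopifnot(D0 >= 0)
  if (min(D0, D0 + delta * L) < 0)
    stop("diffusion field D0 + delta * x is negative on [0, L]")
  Ef <- if (is.function(E)) E else function(x) rep(E, length(x))
  structure(
    list(D = function(x) D0 + delta * x,
         dD = function(x) rep(delta, length(x)),
         E = Ef, D0 = D0, delta = delta),
    class = "fiber_field")
}
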