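#' Adhesion force law
#'
#' Bundles the dimensionless force profile \eqn{F} on \eqn{[0, r]}, the
#' sensing radius \eqn{r} and the spatial dimension \eqn{d}. The induced
#' adhesion potential is
#' \deqn{H_r(x) = \frac{1}{r|B_r|} \int_{\min(|x|, r)}^{r} F(s)\, ds,}
#' where \eqn{|B_r|} is the volume of the sensing ball (\eqn{2r} in one
#' dimension). Cells interact only within distance \eqn{r}.
#'
#' @param F force profile, a vectorised non-negative function on `[0, r]`.
#'   The default is the distance-independent profile `F == 1`.
#' @param r sensing radius, a positive scalar (space units).
#' @param d spatial dimension, a positive integer.
#' @return An object of class `force_law` with fields `F`, `r`, `d` and
#'   the derived `ball_volume`.
#' @examples
#' law <- force_law()            # F == 1, r = 1, d = 1
#' potential_value(0, law)       # 0.5
#' potential_gradient(0.3, law)  # -0.5
#' @export
force_law <- function(F = function(s) rep(1, length(s)), r = 1, d = 1L) {
  stopifnot(is.function(F), is.numeric(r), length(r) == 1L, r > 0,
            d >= 1, d == as.integer(d))
  d <- as.integer(d)
  sgrid <- seq(0, r, length.out = 101L)
  fs <- F(sgrid)
  if (length(fs) != length(sgrid) || any(!is.finite(fs)) || any(fs < 0))
    stop("force profile F must be vectorised, finite and non-negative on [0, r]")
  structure(
    list(F = F, r = r, d = d, ball_volume = ball_volume(r, d)),
    class = "force_law")
}

#' Volume of the d-dimensional ball of radius r
#'
#' @param r radius.
#' @param d dimension.
#' @return \eqn{\pi^{d/2} r^d / \Gamma(d/2+1)}; equals `2 * r` for `d = 1`.
#' @export
ball_volume <- function(r, d) {
  pi^(d / 2) * r^d / gamma(d / 2 + 1)
}

#' @export
print.force_law <- function(x, ...) {
  cat(sprintf("<force_law> d = %d, r = %g, |B_r| = %g, F(0) = %g\n",
              x$d, x$r, x$ball_volume, x$F(0)))
  invisible(x)
}

#' Adhesion potential
#'
#' Evaluates \eqn{H_r(x)}; vanishes for \eqn{|x| \ge r}.
#'
#' @param x offset: a numeric vector of length `d`, or, for `d = 1`, a
#'   numeric vector of offsets (vectorised evaluation).
#' @param law a [force_law()].
#' @return potential value(s), non-negative.
#' @export
potential_value <- function(x, law) {
  stopifnot(inherits(law, "force_law"))
  if (law$d == 1L) {
    vapply(abs(x), function(s) .hr_scalar(s, law), numeric(1))
  } else {
    stopifnot(length(x) == law$d)
    .hr_scalar(sqrt(sum(x^2)), law)
  }
}

.hr_scalar <- function(s, law) {
  if (s >= law$r) return(0)
  val <- stats::integrate(law$F, lower = s, upper = law$r,
                          rel.tol = 1e-10, abs.tol = 1e-12)$value
  val / (law$r * law$ball_volume)
}

#' Gradient of the adhesion potential
#'
#' \deqn{\nabla H_r(x) = -\frac{1}{r|B_r|} \frac{x}{|x|} F(|x|)}
#' for \eqn{0 < |x| < r} and zero outside the closed sensing ball. On the
#' measure-zero sets where the gradient is classically undefined the
#' convention is: zero at \eqn{x = 0}, and the one-sided value based on
#' \eqn{F(r)} at \eqn{|x| = r}.
#'
#' @inheritParams potential_value
#' @return gradient value(s); odd in `x`.
#' @export
potential_gradient <- function(x, law) {
  stopifnot(inherits(law, "force_law"))
  pref <- 1 / (law$r * law$ball_volume)
  if (law$d == 1L) {
    s <- abs(x)
    out <- numeric(length(x))
    in_ball <- s > 0 & s <= law$r
    out[in_ball] <- -pref * sign(x[in_ball]) * law$F(s[in_ball])
    return(out)
  }
  stopifnot(length(x) == law$d)
  s <- sqrt(sum(x^2))
  if (s == 0 || s > law$r) return(numeric(law$d))
  -pref * (x / s) * law$F(s)
}

#' Check the speed-cap condition
#'
#' Cell speeds stay inside the unit velocity ball provided
#' \deqn{\frac{1}{r|B_r|} \sup \chi \ \sup F \le a,}
#' i.e. the maximal adhesion acceleration never exceeds the viscous
#' deceleration at unit speed.
#'
#' @param law a [force_law()].
#' @param chi_sup supremum of the adhesion sensitivity \eqn{\chi \ge 0}.
#' @param a deceleration rate, non-negative.
#' @return `TRUE` if the bound holds.
#' @export
velocity_bound_ok <- function(law, chi_sup, a) {
  stopifnot(inherits(law, "force_law"), chi_sup >= 0, a >= 0)
  sup_F <- max(law$F(seq(0, law$r, length.out = 1001L)))
  chi_sup * sup_F / (law$r * law$ball_volume) <= a
}
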