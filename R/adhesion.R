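#' Non-local adhesion operator at a point (quadrature)
#'
#' Evaluates
#' \deqn{\mathcal{A}_r u(x) = \frac{1}{r|B_r|} \int_{B_r} u(x+\xi)
#'   \frac{\xi}{|\xi|} F(|\xi|)\, d\xi,}
#' the average over the sensing ball of the density weighted by the
#' directional kernel. It coincides with the convolution
#' \eqn{\nabla H_r \star u}. This is the slow adaptive-quadrature path,
#' intended as an oracle for the grid discretisation
#' [adhesion_grid_1d()].
#'
#' @param u density: a function of position, evaluable on the ball of
#'   radius `r` around `x` (zero-extend it yourself if the support is
#'   bounded). For `d = 1` a function of a scalar; for `d = 2` a function
#'   of a length-2 vector.
#' @param x evaluation position (numeric, length `d`).
#' @param law a [force_law()] with `d` in `{1, 2}`.
#' @param abs_tol absolute quadrature tolerance.
#' @return the adhesion velocity vector (scalar for `d = 1`).
#' @export
adhesion_point <- function(u, x, law, abs_tol = 1e-10) {
  stopifnot(inherits(law, "force_law"))
  r <- law$r
  pref <- 1 / (r * law$ball_volume)
  if (law$d == 1L) {
    f_right <- function(xi) vapply(xi, function(s) u(x + s), numeric(1)) * law$F(xi)
    f_left <- function(xi) vapply(xi, function(s) u(x - s), numeric(1)) * law$F(xi)
    right <- stats::integrate(f_right, 0, r, abs.tol = abs_tol,
                              rel.tol = .Machine$double.eps^0.5)
    left <- stats::integrate(f_left, 0, r, abs.tol = abs_tol,
                             rel.tol = .Machine$double.eps^0.5)
    return(pref * (right$value - left$value))
  }
  if (law$d == 2L) {
    comp <- function(k) {
      outer_f <- function(svec) {
        vapply(svec, function(s) {
          inner <- function(th) {
            e <- rbind(cos(th), sin(th))
            vals <- vapply(seq_along(th), function(j)
              u(x + s * e[, j]) * e[k, j], numeric(1))
            vals
          }
          s * law$F(s) *
            stats::integrate(inner, 0, 2 * pi, abs.tol = abs_tol)$value
        }, numeric(1))
      }
      stats::integrate(outer_f, 0, r, abs.tol = abs_tol)$value
    }
    return(pref * c(comp(1), comp(2)))
  }
  stop("adhesion_point supports d = 1 or d = 2")
}

#' Grid discretisation of the adhesion operator (1D)
#'
#' Production path for the non-local adhesion term on a uniform grid over
#' `[0, L]`: a right Riemann sum over the stencil
#' \eqn{l \in \{a(m), \dots, b(m)\}} with
#' \eqn{a(m) = \max(-(\ell_r - 1), -m)}, \eqn{b(m) = \min(\ell_r, M - m)}
#' and \eqn{\ell_r = \mathrm{round}(r/h)}; density values outside the
#' domain contribute zero. With `scale = "operator"` (default) the sum is
#' multiplied by \eqn{1/(r|B_r|)} so the result approximates
#' \eqn{\mathcal{A}_r u}; with `scale = "riemann"` the bare sum
#' \eqn{s_m = h \sum_l u(x_{m+l}) \mathrm{sign}(l h) F(|l h|)} is
#' returned.
#'
#' @param u a [density_field()].
#' @param law a [force_law()] with `d = 1` and `r > h`.
#' @param scale `"operator"` or `"riemann"` (see above).
#' @return numeric vector of signed values, one per node.
#' @export
adhesion_grid_1d <- function(u, law, scale = c("operator", "riemann")) {
  stopifnot(inherits(u, "density_field"), inherits(law, "force_law"),
            law$d == 1L)
  scale <- match.arg(scale)
  h <- u$h
  if (law$r <= h) stop("sensing radius unresolved: r must exceed the grid spacing h")
  lr <- as.integer(round(law$r / h))
  M1 <- n_nodes(u)
  offsets <- seq.int(-(lr - 1L), lr)
  wts <- sign(offsets) * law$F(abs(offsets) * h)
  upad <- c(numeric(lr), u$values, numeric(lr))
  s <- numeric(M1)
  base <- lr + 1L   # index of node m = 0 in upad is base + 0
  for (k in seq_along(offsets)) {
    w <- wts[k]
    if (w == 0) next
    l <- offsets[k]
    s <- s + w * upad[(base + l):(base + l + M1 - 1L)]
  }
  s <- h * s
  if (scale == "operator") s <- s / (law$r * law$ball_volume)
  s
}

#' Ring (sphere) non-local operator
#'
#' Evaluates \eqn{\int_{S_\rho} u(x+\xi)\, \xi \, dS(\xi)}, the surface
#' integral over the sphere of radius `rho` centred at `x`. This operator
#' arises from the discontinuous indicator potential and also appears in
#' non-local chemotaxis models. Only `d >= 2` is meaningful; `d = 2` is
#' implemented with the trapezoidal rule on the circle (spectrally
#' accurate for smooth periodic integrands).
#'
#' @param u density function of a length-`d` position vector.
#' @param x centre (numeric, length `d`).
#' @param rho sphere radius, positive.
#' @param d spatial dimension, must be 2.
#' @param n_theta number of quadrature angles.
#' @return a length-`d` vector.
#' @export
ring_operator <- function(u, x, rho, d = 2L, n_theta = 512L) {
  if (d < 2) stop("ring_operator is undefined for d = 1; use adhesion_point")
  if (d != 2L) stop("only d = 2 sphere quadrature is implemented")
  stopifnot(rho > 0, length(x) == 2L)
  th <- 2 * pi * (seq_len(n_theta) - 1L) / n_theta
  e <- rbind(cos(th), sin(th))
  vals <- vapply(seq_len(n_theta), function(j) u(x + rho * e[, j]), numeric(1))
  dS <- rho * 2 * pi / n_theta          # arc-length element
  c(sum(vals * e[1, ]), sum(vals * e[2, ])) * rho * dS   # xi = rho * e
}
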