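#' CAM binding/unbinding kinetics
#'
#' Wraps the rate constants \eqn{k^\pm(S, \rho)} of the reversible CAM
#' binding reaction between two cells at distance \eqn{\rho} under
#' chemical concentration \eqn{S}. Both rates are forced to zero for
#' \eqn{\rho \ge r} (cells out of reach cannot bind, and bonds break as
#' the separation approaches the sensing radius), and the unbinding rate
#' is capped at `cap` since some rate families blow up as
#' \eqn{\rho \to r}.
#'
#' @param kplus,kminus rate functions `(S, rho)`, vectorised in both
#'   arguments, non-negative.
#' @param r sensing radius.
#' @param d spatial dimension (sets `|B_r|` for the pair kernels).
#' @param cap ceiling applied to `kminus` (default `1e6`).
#' @return An object of class `binding_kinetics` with the wrapped (cutoff
#'   and capped) `kplus`, `kminus`.
#' @export
binding_kinetics <- function(kplus, kminus, r, d = 1L, cap = 1e6) {
  stopifnot(is.function(kplus), is.function(kminus), r > 0, cap > 0)
  wrap <- function(k, ceiling_at) {
    force(k); force(ceiling_at)
    function(S, rho) {
      out <- ifelse(rho < r, k(S, rho), 0)
      out <- pmax(out, 0)
      pmin(out, ceiling_at)
    }
  }
  structure(
    list(kplus = wrap(kplus, Inf), kminus = wrap(kminus, cap),
         r = r, d = as.integer(d), cap = cap),
    class = "binding_kinetics")
}

#' Separable example family of binding rates
#'
#' The separable family \eqn{k^\pm(S, \rho) = K^\pm(S)\,\varphi^\pm(\rho)}
#' with
#' \deqn{\varphi^+(\rho) = (r^{b^+} - \rho^{b^+})^{a^+}, \qquad
#'       \varphi^-(\rho) = (r^{b^-} - \rho^{b^-})^{-a^-}}
#' for \eqn{\rho < r} and zero beyond. Binding weakens and detachment
#' speeds up as the separation approaches the sensing radius; the
#' unbinding blow-up at \eqn{\rho \to r} is capped.
#'
#' @param Kplus,Kminus chemical modulation: non-negative scalars or
#'   vectorised functions of `S` (`Kplus` non-decreasing, `Kminus`
#'   non-increasing in typical use).
#' @param aplus,bplus,aminus,bminus positive exponents.
#' @param r sensing radius.
#' @param d spatial dimension.
#' @param cap ceiling for the unbinding rate.
#' @return a [binding_kinetics()].
#' @export
kinetics_example <- function(Kplus = 1, Kminus = 1, aplus = 1, bplus = 1,
                             aminus = 1, bminus = 1, r = 1, d = 1L,
                             cap = 1e6) {
  stopifnot(aplus > 0, bplus > 0, aminus > 0, bminus > 0)
  Kp <- if (is.function(Kplus)) Kplus else function(S) rep(Kplus, length(S))
  Km <- if (is.function(Kminus)) Kminus else function(S) rep(Kminus, length(S))
  kp <- function(S, rho) Kp(S) * (pmax(r^bplus - rho^bplus, 0))^aplus
  km <- function(S, rho) Km(S) * (pmax(r^bminus - rho^bminus, 0))^(-aminus)
  binding_kinetics(kp, km, r = r, d = d, cap = cap)
}

#' Pair binding kernels
#'
#' \eqn{G^\pm_r = k^\pm(S_{mid}, \rho)/|B_r|} for a cell pair at distance
#' `dist` with chemical concentration `S_mid` at the midpoint.
#'
#' @param S_mid chemical value(s) at the pair midpoint.
#' @param dist pair distance(s), non-negative.
#' @param kin a [binding_kinetics()].
#' @return a list with components `Gplus` and `Gminus`.
#' @export
g_pair <- function(S_mid, dist, kin) {
  stopifnot(inherits(kin, "binding_kinetics"), all(dist >= 0))
  Bvol <- ball_volume(kin$r, kin$d)
  list(Gplus = kin$kplus(S_mid, dist) / Bvol,
       Gminus = kin$kminus(S_mid, dist) / Bvol)
}

# Shared stencil for nodewise non-local integrals over |x - x'| < r:
# offsets l in {-(lr-1), ..., lr}, zero-extension outside [0, L].
nonlocal_offsets <- function(h, r) {
  lr <- as.integer(round(r / h))
  if (lr < 1L) stop("sensing radius unresolved: r must exceed h")
  seq.int(-(lr - 1L), lr)
}

#' Non-local binding operator on a grid
#'
#' Riemann-sum evaluation of
#' \eqn{\mathcal{G}^\pm_r[S]\mu(x) = \int G^\pm_r(S(\tfrac{x+x'}{2}),
#' |x-x'|)\, \mu(x')\, dx'} on the nodes of a 1D grid, zero-extending
#' `mu` outside `[0, L]`. The chemical field is evaluated at the exact
#' pair midpoints (off-grid in general).
#'
#' @param mu a [density_field()], non-negative.
#' @param S chemical field: a vectorised function of position, or a
#'   single scalar.
#' @param kin a [binding_kinetics()].
#' @param sign `"+"` (binding) or `"-"` (unbinding).
#' @return numeric vector of nodal values.
#' @export
apply_g <- function(mu, S, kin, sign = c("+", "-")) {
  stopifnot(inherits(mu, "density_field"), inherits(kin, "binding_kinetics"))
  sign <- match.arg(sign)
  Sf <- if (is.function(S)) S else function(x) rep(S, length(x))
  kfun <- if (sign == "+") kin$kplus else kin$kminus
  Bvol <- ball_volume(kin$r, kin$d)
  h <- mu$h
  M1 <- n_nodes(mu)
  offsets <- nonlocal_offsets(h, kin$r)
  lr <- max(offsets)
  upad <- c(numeric(lr), mu$values, numeric(lr))
  base <- lr + 1L
  out <- numeric(M1)
  for (l in offsets) {
    uv <- upad[(base + l):(base + l + M1 - 1L)]
    if (all(uv == 0)) next
    Smid <- Sf(mu$x + l * h / 2)
    out <- out + kfun(Smid, abs(l) * h) * uv
  }
  h * out / Bvol
}

#' Equilibrium bound fraction field
#'
#' The bound-fraction equilibrium map
#' \deqn{\mathcal{Y}_r[S](\mu_0, \mu_1) =
#'   \frac{\mathcal{G}^+_r(\mu_0-\mu_1)}
#'        {\mathcal{G}^+_r(\mu_0-\mu_1) + \mathcal{G}^-_r\mu_1},}
#' evaluated nodewise; values lie in `[0, 1]`. Nodes where the
#' denominator vanishes are an error unless the local density itself is
#' zero there (then the bound fraction is irrelevant and reported as 0).
#'
#' @param mu0 zeroth moment (total density), a [density_field()].
#' @param mu1 first bound-CAM moment, a [density_field()] with
#'   `0 <= mu1 <= mu0` nodewise.
#' @param S chemical field (function of position or scalar).
#' @param kin a [binding_kinetics()].
#' @return numeric vector of bound fractions per node.
#' @export
y_star <- function(mu0, mu1, S, kin) {
  stopifnot(same_grid(mu0, mu1))
  if (any(mu1$values < -1e-12) || any(mu1$values > mu0$values + 1e-9))
    stop("moment ordering violated: need 0 <= mu1 <= mu0 nodewise")
  free <- density_field(pmax(mu0$values - mu1$values, 0), mu0$h, mu0$L)
  Gp <- apply_g(free, S, kin, "+")
  Gm <- apply_g(mu1, S, kin, "-")
  denom <- Gp + Gm
  out <- numeric(length(denom))
  ok <- denom > 0
  out[ok] <- Gp[ok] / denom[ok]
  bad <- !ok & mu0$values > 0
  if (any(bad))
    stop(sprintf("degenerate binding state: zero denominator at node %d (x = %g)",
                 which(bad)[1] - 1L, mu0$x[which(bad)[1]]))
  pmin(pmax(out, 0), 1)
}

#' Solve the non-linear integral equation for the bound-CAM moment
#'
#' Finds \eqn{\mu_1} satisfying the fixed-point equation
#' \eqn{\mu_1 = \mu_0\, \mathcal{Y}_r[S](\mu_0, \mu_1)} by damped Picard
#' iteration started at \eqn{\mu_1 = \mu_0/2}.
#'
#' @param mu0 total density, a non-negative [density_field()].
#' @param S chemical field (function of position or scalar).
#' @param kin a [binding_kinetics()].
#' @param tol residual sup-norm tolerance.
#' @param max_iter maximum Picard iterations.
#' @param omega damping weight in `(0, 1]`.
#' @return a [density_field()] `mu1` with `0 <= mu1 <= mu0`; attributes
#'   `iterations` and `residual` record the convergence history endpoint.
#' @export
solve_bound_fraction <- function(mu0, S, kin, tol = 1e-10, max_iter = 1e4,
                                 omega = 0.5) {
  stopifnot(inherits(mu0, "density_field"), all(mu0$values >= 0))
  mu1 <- mu0$values / 2
  resid <- Inf
  for (it in seq_len(max_iter)) {
    ys <- y_star(mu0, density_field(mu1, mu0$h, mu0$L), S, kin)
    target <- mu0$values * ys
    resid <- max(abs(mu1 - target))
    mu1 <- (1 - omega) * mu1 + omega * target
    mu1 <- pmin(pmax(mu1, 0), mu0$values)
    if (resid <= tol) break
  }
  if (resid > tol)
    stop(sprintf("bound-CAM fixed point did not converge: residual %.3e after %d iterations",
                 resid, max_iter))
  out <- density_field(mu1, mu0$h, mu0$L)
  attr(out, "iterations") <- it
  attr(out, "residual") <- resid
  out
}

#' Closed-form bound moment for local kinetics
#'
#' When binding and unbinding act only at zero separation the integral
#' operators collapse to multiplications and the bound moment is
#' \deqn{\mu_1 = \frac{\sqrt{K^+}}{\sqrt{K^-} + \sqrt{K^+}}\, \mu_0.}
#'
#' @param Kplus,Kminus non-negative rate fields (numeric vectors), not
#'   both zero at any node.
#' @param mu0 total density: numeric vector or [density_field()].
#' @return object of the same shape as `mu0`.
#' @export
bound_fraction_local <- function(Kplus, Kminus, mu0) {
  vals <- if (inherits(mu0, "density_field")) mu0$values else mu0
  n <- length(vals)
  Kp <- rep_len(Kplus, n); Km <- rep_len(Kminus, n)
  if (any(Kp < 0) || any(Km < 0)) stop("rates must be non-negative")
  if (any(Kp + Km == 0))
    stop("both rates vanish at a node; bound fraction undefined")
  out <- sqrt(Kp) / (sqrt(Km) + sqrt(Kp)) * vals
  if (inherits(mu0, "density_field")) density_field(out, mu0$h, mu0$L) else out
}

#' Speed-profile factor of the mesoscopic reconstruction
#'
#' The factor \eqn{\xi_1(v)} in the equilibrium mesoscopic density
#' \eqn{c^0 = \bar c^0\, q\, \xi_1}:
#' \deqn{\xi_1(v) = \frac{d}{da-1}\big(|v|^{-d+1/a} - 1\big)
#'   \quad (a \ne 1/d), \qquad
#'   \xi_1(v) = -\frac{d}{a} \ln |v| \quad (a = 1/d).}
#' Its `q`-weighted integral over the unit velocity ball is 1.
#'
#' @param v velocity (vectorised); `0 < |v| <= 1`.
#' @param a deceleration rate, positive.
#' @param d spatial dimension.
#' @return numeric vector of the same length as `v`.
#' @export
xi1 <- function(v, a, d = 1L) {
  s <- abs(v)
  if (any(s == 0)) stop("xi1 is singular at v = 0")
  if (any(s > 1 + 1e-12)) stop("speeds must lie in (0, 1]")
  if (abs(a - 1 / d) < 1e-14) {
    -(d / a) * log(s)
  } else {
    d / (d * a - 1) * (s^(-d + 1 / a) - 1)
  }
}

#' Mesoscopic velocity-profile reconstruction
#'
#' Factorised equilibrium profile \eqn{v \mapsto \mu_0\, q(v)\, \xi_1(v)}
#' at a fixed position; its integral over the velocity ball equals
#' \eqn{\mu_0}.
#'
#' @param mu0_point macroscopic density at the position (scalar).
#' @param q_point fiber distribution at the position: for `d = 1` a list
#'   or vector with `qplus`, `qminus`.
#' @param a deceleration rate.
#' @param d spatial dimension (1 implemented).
#' @return a vectorised function of the signed velocity on `(-1, 1)`.
#' @export
reconstruct_meso <- function(mu0_point, q_point, a, d = 1L) {
  if (d != 1L) stop("reconstruction implemented for d = 1")
  qp <- q_point[["qplus"]]; qm <- q_point[["qminus"]]
  stopifnot(abs(qp + qm - 1) < 1e-8)
  function(v) {
    qv <- ifelse(v > 0, qp, qm)
    ifelse(v == 0, NA_real_, mu0_point * qv * xi1(v, a, d))
  }
}
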