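#' Configuration of the macroscopic 1D solver
#'
#' Collects the parameters of the macroscopic myopic-diffusion /
#' non-local-adhesion equation
#' \deqn{(a+1)\,\partial_t u = c_1 \partial_x\!\big(D(x)\,\partial_x u\big)
#'  + \partial_x\!\Big(u\big(\theta c_1 \partial_x D - \chi_0
#'    \mathcal{A}_r u\big)\Big), \qquad
#'    c_1 = \frac{1}{2a+1}\frac{d}{d+2},}
#' on `[0, L]` with no-flux boundary conditions; the density is extended
#' by zero inside the non-local integral. Defaults reproduce the
#' reference simulation study: `L = 6`, `T = 25`, `h = dt_outer = 0.01`,
#' `a = 1`, `F == 1`, `r = 1`, `u0 == 5` (for `a = d = 1` the diffusion
#' prefactor is `1/9` and the equation carries the overall factor
#' `a + 1 = 2`).
#'
#' @param D0 minimum diffusion-moment value.
#' @param delta slope of the affine diffusion perturbation
#'   `D(x) = D0 + delta * x`.
#' @param chi0 adhesion sensitivity scale, non-negative.
#' @param theta myopic-drift switch, 0 or 1 (0 removes the drift
#'   `theta * c1 * dD/dx`, rendering the diffusion non-myopic).
#' @param L,T domain length and final time.
#' @param h spatial step; `dt_outer` splitting window; `T` must be a
#'   multiple of `dt_outer`.
#' @param inner_substeps inner time mesh refinement of the stiff
#'   method-of-lines integrator within each splitting window.
#' @param a deceleration rate.
#' @param law a [force_law()] with `d = 1`.
#' @param E_field mean fiber direction field (hyperbolic modes): scalar
#'   or function of `x`.
#' @param mode one of `"parabolic"`, `"parabolic_cam"`, `"hyperbolic"`,
#'   `"cte"`.
#' @param epsilon scale parameter multiplying the diffusive/adhesive
#'   corrections in `"hyperbolic"` mode.
#' @param kinetics,S binding kinetics and chemical field `(t, x)` for
#'   `"parabolic_cam"` mode.
#' @param u0 initial density: a [density_field()] or `NULL` for the
#'   uniform level 5.
#' @param advection face-value rule for the advective flux: `"centered"`
#'   (default) or `"upwind"`.
#' @param snapshot_stride record every so many outer steps.
#' @param rtol,atol tolerances of the inner integrator.
#' @return An object of class `macro_config`.
#' @export
macro_config <- function(D0 = 0.15, delta = 0, chi0 = 0.5, theta = 1,
                         L = 6, T = 25, h = 0.01, dt_outer = 0.01,
                         inner_substeps = 41L, a = 1,
                         law = force_law(r = 1, d = 1L),
                         E_field = 0, mode = c("parabolic", "parabolic_cam",
                                               "hyperbolic", "cte"),
                         epsilon = 1, kinetics = NULL, S = NULL, u0 = NULL,
                         advection = c("centered", "upwind"),
                         snapshot_stride = 1L, rtol = 1e-7, atol = 1e-9) {
  mode <- match.arg(mode)
  advection <- match.arg(advection)
  stopifnot(h > 0, dt_outer > 0, L > 0, T > 0, chi0 >= 0, a > 0,
            theta %in% c(0, 1), inner_substeps >= 1L,
            inherits(law, "force_law"), law$d == 1L)
  if (abs(T / dt_outer - round(T / dt_outer)) > 1e-9)
    stop("T must be a multiple of dt_outer")
  field <- make_fiber_field(D0, delta, L = L, E = E_field)
  if (is.null(u0)) {
    M1 <- as.integer(round(L / h)) + 1L
    u0 <- density_field(rep(5, M1), h = h, L = L)
  }
  stopifnot(inherits(u0, "density_field"),
            abs(u0$L - L) < 1e-9, abs(u0$h - h) < 1e-12)
  if (mode == "parabolic_cam" && (is.null(kinetics) || is.null(S)))
    stop("parabolic_cam mode requires `kinetics` and `S`")
  structure(
    list(D0 = D0, delta = delta, chi0 = chi0, theta = theta, L = L, T = T,
         h = h, dt_outer = dt_outer, inner_substeps = as.integer(inner_substeps),
         a = a, d = 1L, law = law, field = field, mode = mode,
         epsilon = epsilon, kinetics = kinetics, S = S, u0 = u0,
         advection = advection, snapshot_stride = as.integer(snapshot_stride),
         rtol = rtol, atol = atol,
         c1 = (1 / (2 * a + 1)) * (1 / 3)),   # d = 1: d/(d+2) = 1/3
    class = "macro_config")
}

#' @export
print.macro_config <- function(x, ...) {
  cat(sprintf(
    "<macro_config> mode = %s, D0 = %g, delta = %g, chi0 = %g, theta = %g\n",
    x$mode, x$D0, x$delta, x$chi0, x$theta))
  cat(sprintf("  grid: h = %g on [0, %g]; outer dt = %g to T = %g\n",
              x$h, x$L, x$dt_outer, x$T))
  invisible(x)
}

# Conservative finite-volume right-hand side with a frozen nodal
# adhesion-advection velocity. Boundary cells have width h/2; the flux
# through the domain boundary is zero, so the trapezoid-weighted mass
# derivative vanishes identically.
#' Finite-volume right-hand side of the parabolic equation
#'
#' Spatial discretisation of the divergence-form equation with the
#' non-local adhesion velocity frozen at the given nodal values (the
#' outer-splitting linearisation). Exposed mainly for testing against
#' manufactured solutions.
#'
#' @param u nodal density values (numeric vector).
#' @param frozen_adh nodal values of the full adhesion advection
#'   velocity \eqn{\chi_0 \mathcal{A}_r u} (or its bound-CAM weighted
#'   version), interpolated linearly to cell faces.
#' @param cfg a [macro_config()].
#' @return nodal values of \eqn{\partial_t u}.
#' @export
rhs_parabolic <- function(u, frozen_adh, cfg) {
  h <- cfg$h
  M1 <- length(u)
  x_face <- (seq_len(M1 - 1L) - 0.5) * h
  D_face <- cfg$field$D(x_face)
  if (any(D_face < 0)) stop("diffusion field must be non-negative")
  dD_face <- cfg$field$dD(x_face)
  adh_face <- (frozen_adh[-M1] + frozen_adh[-1L]) / 2
  w_face <- cfg$theta * cfg$c1 * dD_face - adh_face
  u_face <- if (cfg$advection == "centered") {
    (u[-M1] + u[-1L]) / 2
  } else {
    ifelse(w_face < 0, u[-M1], u[-1L])
  }
  flux <- cfg$c1 * D_face * (u[-1L] - u[-M1]) / h + u_face * w_face
  du <- numeric(M1)
  du[1L] <- flux[1L] / (h / 2)
  du[M1] <- -flux[M1 - 1L] / (h / 2)
  du[2:(M1 - 1L)] <- (flux[-1L] - flux[-(M1 - 1L)]) / h
  du / (cfg$a + 1)
}

#' One outer splitting step
#'
#' Freezes the non-local adhesion velocity at the current density (grid
#' cross-correlation stencil, linearly interpolated to faces) and
#' advances the resulting local advection-diffusion problem over one
#' splitting window with a stiff method-of-lines integrator on the inner
#' time mesh.
#'
#' @param u a [density_field()].
#' @param cfg a [macro_config()].
#' @param frozen_adh optional pre-scaled nodal adhesion velocity; by
#'   default `chi0 * adhesion_grid_1d(u, law)`.
#' @return the advanced [density_field()].
#' @export
step_outer <- function(u, cfg, frozen_adh = NULL) {
  if (is.null(frozen_adh))
    frozen_adh <- cfg$chi0 * adhesion_grid_1d(u, cfg$law)
  times <- seq(0, cfg$dt_outer, length.out = cfg$inner_substeps + 1L)
  sol <- deSolve::ode(
    y = u$values, times = times,
    func = function(t, y, p) list(rhs_parabolic(y, frozen_adh, cfg)),
    method = "lsoda", jactype = "bandint", bandup = 1L, banddown = 1L,
    rtol = cfg$rtol, atol = cfg$atol)
  if (attr(sol, "istate")[1L] < 0)
    stop("inner method-of-lines integrator failed within the splitting window")
  density_field(as.numeric(sol[nrow(sol), -1L]), h = u$h, L = u$L)
}

new_kymograph <- function(times, x, rows, cfg) {
  density <- do.call(rbind, rows)
  dimnames(density) <- NULL
  mass <- apply(density, 1L, function(v)
    total_mass(density_field(v, h = x[2] - x[1], L = x[length(x)])))
  structure(list(times = times, x = x, density = density, mass = mass,
                 config = cfg),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %d snapshots x %d nodes, t in [%g, %g], mass drift %.3g%%\n",
              nrow(x$density), ncol(x$density), x$times[1],
              x$times[length(x$times)],
              100 * abs(x$mass[length(x$mass)] - x$mass[1]) / x$mass[1]))
  invisible(x)
}

#' Solve the parabolic initial-boundary value problem
#'
#' Iterates [step_outer()] from the initial density to the final time,
#' recording density snapshots.
#'
#' @param cfg a [macro_config()] with `mode = "parabolic"`.
#' @return a `kymograph`: snapshot `times`, node coordinates `x`, the
#'   time-by-space `density` matrix, per-snapshot `mass` and the config.
#' @export
solve_ibvp <- function(cfg) {
  stopifnot(inherits(cfg, "macro_config"), cfg$mode == "parabolic")
  n_outer <- as.integer(round(cfg$T / cfg$dt_outer))
  u <- cfg$u0
  times <- 0
  rows <- list(u$values)
  for (k in seq_len(n_outer)) {
    u <- step_outer(u, cfg)
    if (k %% cfg$snapshot_stride == 0L || k == n_outer) {
      times <- c(times, k * cfg$dt_outer)
      rows <- c(rows, list(u$values))
    }
  }
  new_kymograph(times, u$x, rows, cfg)
}

#' Solve the CAM-coupled parabolic system
#'
#' Per outer step the non-linear integral equation for the bound-CAM
#' moment is solved at the current density (fast binding kinetics make
#' the equilibrium instantaneous on the macroscopic clock); the adhesion
#' advection velocity is then weighted by the resulting bound fraction
#' before the splitting step.
#'
#' @param cfg a [macro_config()] with `mode = "parabolic_cam"`, with
#'   `kinetics` a [binding_kinetics()] and `S` a function `(t, x)`.
#' @param fp_tol,fp_max_iter tolerances of the fixed-point solver.
#' @return a list with kymographs `u` (density) and `mu1` (bound-CAM
#'   moment).
#' @export
solve_ibvp_cam <- function(cfg, fp_tol = 1e-10, fp_max_iter = 1e4) {
  stopifnot(inherits(cfg, "macro_config"), cfg$mode == "parabolic_cam")
  n_outer <- as.integer(round(cfg$T / cfg$dt_outer))
  u <- cfg$u0
  times <- 0
  S_at <- function(t) { force(t); function(x) cfg$S(t, x) }
  mu1 <- solve_bound_fraction(u, S_at(0), cfg$kinetics,
                              tol = fp_tol, max_iter = fp_max_iter)
  rows <- list(u$values)
  rows_mu1 <- list(mu1$values)
  for (k in seq_len(n_outer)) {
    t_k <- (k - 1L) * cfg$dt_outer
    mu1 <- solve_bound_fraction(u, S_at(t_k), cfg$kinetics,
                                tol = fp_tol, max_iter = fp_max_iter)
    ystar <- ifelse(u$values > 0, mu1$values / pmax(u$values, 1e-300), 0)
    frozen <- cfg$chi0 * ystar * adhesion_grid_1d(u, cfg$law)
    u <- step_outer(u, cfg, frozen_adh = frozen)
    if (k %% cfg$snapshot_stride == 0L || k == n_outer) {
      times <- c(times, k * cfg$dt_outer)
      rows <- c(rows, list(u$values))
      rows_mu1 <- c(rows_mu1, list(mu1$values))
    }
  }
  list(u = new_kymograph(times, u$x, rows, cfg),
       mu1 = new_kymograph(times, u$x, rows_mu1, cfg))
}

#' Solve the hyperbolic-scaling transport modes
#'
#' `mode = "cte"` solves the conservative transport equation
#' \eqn{(a+1)\partial_t u + \tfrac{d}{d+1}\partial_x(E u) = 0} with
#' first-order upwinding and explicit time stepping. `mode =
#' "hyperbolic"` adds the order-`epsilon` corrections: the myopic
#' diffusion and non-local adhesion right-hand side plus the
#' mean-direction cross term
#' \eqn{-\tfrac{1}{(a+1)^2}\tfrac{d^2}{(d+1)^2}
#'   \partial_x(E\,\partial_x(uE))}.
#' The explicit step uses `dt_outer` as time step and enforces the
#' advective CFL condition.
#'
#' @param cfg a [macro_config()] with `mode` `"cte"` or `"hyperbolic"`
#'   and `E_field` set.
#' @return a `kymograph`.
#' @export
solve_hyperbolic <- function(cfg) {
  stopifnot(inherits(cfg, "macro_config"), cfg$mode %in% c("cte", "hyperbolic"))
  h <- cfg$h; dt <- cfg$dt_outer; a <- cfg$a
  u <- cfg$u0
  M1 <- n_nodes(u)
  x_face <- (seq_len(M1 - 1L) - 0.5) * h
  E_face <- cfg$field$E(x_face)
  E_node <- cfg$field$E(u$x)
  cfl <- max(abs(E_face)) * dt * (1 / 2) / ((a + 1) * h)   # d/(d+1) = 1/2
  if (cfl > 1)
    stop(sprintf("CFL violation in hyperbolic step: %.3f > 1", cfl))
  n_steps <- as.integer(round(cfg$T / dt))
  times <- 0
  rows <- list(u$values)
  for (k in seq_len(n_steps)) {
    u <- density_field(u$values + dt * hyperbolic_rhs(u$values, E_face,
                                                      E_node, cfg),
                       h = h, L = cfg$L)
    if (k %% cfg$snapshot_stride == 0L || k == n_steps) {
      times <- c(times, k * dt)
      rows <- c(rows, list(u$values))
    }
  }
  new_kymograph(times, u$x, rows, cfg)
}

hyperbolic_rhs <- function(u, E_face, E_node, cfg) {
  h <- cfg$h; a <- cfg$a
  M1 <- length(u)
  # upwind conservative transport flux (d = 1: d/(d+1) = 1/2)
  u_up <- ifelse(E_face > 0, u[-M1], u[-1L])
  f <- (1 / 2) * E_face * u_up / (a + 1)
  div <- numeric(M1)
  div[1L] <- f[1L] / (h / 2)
  div[M1] <- -f[M1 - 1L] / (h / 2)
  div[2:(M1 - 1L)] <- (f[-1L] - f[-(M1 - 1L)]) / h
  du <- -div
  if (cfg$mode == "hyperbolic") {
    cfg_my <- cfg
    cfg_my$theta <- 1    # the correction carries the full myopic form
    frozen <- cfg$chi0 * adhesion_grid_1d(density_field(u, h, cfg$L), cfg$law)
    du <- du + cfg$epsilon * rhs_parabolic(u, frozen, cfg_my)
    # mean-direction cross term -(1/(a+1)^2) (d/(d+1))^2 dx(E dx(uE)),
    # divided by the overall (a+1)
    g <- u * E_node
    inner <- E_face * (g[-1L] - g[-M1]) / h
    cross <- numeric(M1)
    cross[1L] <- inner[1L] / (h / 2)
    cross[M1] <- -inner[M1 - 1L] / (h / 2)
    cross[2:(M1 - 1L)] <- (inner[-1L] - inner[-(M1 - 1L)]) / h
    du <- du - cfg$epsilon * (1 / (a + 1)^3) * (1 / 4) * cross
  }
  du
}
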