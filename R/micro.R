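#' Microscopic population state
#'
#' State of `N` point cells with positions, velocities in the open unit
#' ball (speeds are rescaled so 1 is an unattainable cap), and optionally
#' the fraction `y` of bound cell adhesion molecules (CAMs) per cell.
#'
#' @param x positions: numeric vector (`d = 1`) or `N x d` matrix.
#' @param v velocities, same shape as `x`; speeds must be below 1.
#' @param y optional bound-CAM fractions in `[0, 1]` (enables CAM mode:
#'   the adhesion force on cell `i` is weighted by `y_i`).
#' @param t current time.
#' @param a deceleration rate (viscous friction), positive.
#' @param chi adhesion sensitivity: non-negative scalar or function
#'   `(t, x)` (with `x` an `N x d` matrix) returning one value per cell.
#' @param law a [force_law()].
#' @param kinetics optional [binding_kinetics()] (required in CAM mode).
#' @param S optional chemical field, function `(t, x)` vectorised over the
#'   rows of `x` (required in CAM mode).
#' @param chi_sup supremum of `chi`, used by the speed-cap check; defaults
#'   to `chi` itself when `chi` is a scalar.
#' @return An object of class `micro_state`.
#' @export
micro_state <- function(x, v, y = NULL, t = 0, a = 1, chi = 1,
                        law = force_law(), kinetics = NULL, S = NULL,
                        chi_sup = NULL) {
  x <- as_pos_matrix(x, law$d)
  v <- as_pos_matrix(v, law$d)
  stopifnot(nrow(x) == nrow(v), a > 0)
  if (any(sqrt(rowSums(v^2)) > 1 + 1e-12))
    stop("initial speeds must not exceed the unit cap")
  if (!is.null(y)) {
    stopifnot(length(y) == nrow(x), all(y >= -1e-12), all(y <= 1 + 1e-12))
    y <- pmin(pmax(y, 0), 1)
    if (is.null(kinetics) || is.null(S))
      stop("CAM mode requires both `kinetics` and `S`")
  }
  chi_fun <- if (is.function(chi)) chi else {
    chi0 <- chi
    function(t, x) rep(chi0, nrow(x))
  }
  if (is.null(chi_sup)) {
    if (!is.function(chi)) chi_sup <- chi
    else stop("supply `chi_sup` when `chi` is a function")
  }
  structure(
    list(x = x, v = v, y = y, t = t, N = nrow(x), a = a,
         chi = chi_fun, chi_sup = chi_sup, law = law,
         kinetics = kinetics, S = S),
    class = "micro_state")
}

as_pos_matrix <- function(x, d) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == d)
    return(x)
  }
  stopifnot(d == 1L)
  matrix(as.numeric(x), ncol = 1L)
}

#' @export
print.micro_state <- function(x, ...) {
  cat(sprintf("<micro_state> N = %d, d = %d, t = %g%s\n", x$N,
              ncol(x$x), x$t, if (is.null(x$y)) "" else ", CAM mode"))
  invisible(x)
}

# Tabulate the force profile for the compiled pairwise kernel.
force_table <- function(law, nf = 4097L) law$F(seq(0, law$r, length.out = nf))

#' Mean-field adhesion acceleration
#'
#' Acceleration of each cell due to pairwise adhesion:
#' \deqn{\chi(t, x_i)\, [y_i]\, \frac{1}{N} \sum_{j \ne i}
#'   \nabla H_r(x_i - x_j),}
#' where the bound-CAM weight \eqn{y_i} enters only in CAM mode. Pairs at
#' distance 0 or beyond the sensing radius contribute zero.
#'
#' @param state a [micro_state()].
#' @param i optional cell index; if `NULL` the full `N x d` matrix is
#'   returned.
#' @param use_cpp use the compiled pairwise kernel (default). The pure-R
#'   direct sum is retained as a reference path.
#' @return acceleration vector for cell `i`, or an `N x d` matrix.
#' @export
adhesion_acceleration <- function(state, i = NULL, use_cpp = TRUE) {
  acc <- accel_matrix(state$x, state$y, state$t, state, use_cpp)
  if (is.null(i)) acc else acc[i, ]
}

accel_matrix <- function(x, y, t, state, use_cpp = TRUE) {
  law <- state$law
  chi_vals <- state$chi(t, x)
  if (use_cpp) {
    return(pairwise_accel_cpp(x, y, chi_vals, force_table(law),
                              law$r, 1 / (law$r * law$ball_volume)))
  }
  N <- nrow(x)
  d <- ncol(x)
  pref <- 1 / (law$r * law$ball_volume)
  acc <- matrix(0, N, d)
  for (ii in seq_len(N)) {
    z <- sweep(x, 2L, x[ii, ], FUN = "-") * -1  # x_i - x_j per row j
    dist <- sqrt(rowSums(z^2))
    sel <- dist > 0 & dist <= law$r
    if (!any(sel)) next
    g <- -pref * z[sel, , drop = FALSE] / dist[sel] * law$F(dist[sel])
    acc[ii, ] <- colSums(g) / N
  }
  w <- chi_vals * (if (is.null(y)) 1 else y)
  acc * w
}

#' Bound-CAM binding rate of each cell
#'
#' Mass-action net binding rate
#' \deqn{\frac{dy_i}{dt} = \frac{1}{N}\sum_{j \ne i}
#'   G^+_r (1-y_i)(1-y_j) - G^-_r y_i y_j,}
#' with kernels \eqn{G^\pm_r = k^\pm(S_{mid}, |x_i - x_j|)/|B_r|}
#' evaluated at the chemical concentration midway between the two cells.
#'
#' @inheritParams adhesion_acceleration
#' @return rate for cell `i`, or the length-`N` vector of rates.
#' @export
cam_rate <- function(state, i = NULL) {
  rates <- cam_rate_vec(state$x, state$y, state$t, state)
  if (is.null(i)) rates else rates[i]
}

cam_rate_vec <- function(x, y, t, state) {
  kin <- state$kinetics
  if (is.null(kin) || is.null(y) || is.null(state$S))
    stop("cam_rate requires CAM mode (y, kinetics and S set)")
  N <- nrow(x)
  d <- ncol(x)
  Bvol <- ball_volume(kin$r, d)
  dist <- as.matrix(stats::dist(x))
  # S at all pair midpoints (x_i + x_j)/2, evaluated in one call
  mids <- matrix(0, N * N, d)
  for (k in seq_len(d))
    mids[, k] <- (rep(x[, k], times = N) + rep(x[, k], each = N)) / 2
  Smid <- matrix(state$S(t, mids), N, N)
  Gp <- kin$kplus(Smid, dist) / Bvol
  Gm <- kin$kminus(Smid, dist) / Bvol
  diag(Gp) <- 0; diag(Gm) <- 0
  free <- 1 - y
  gains <- free * as.numeric(Gp %*% free)
  losses <- y * as.numeric(Gm %*% y)
  (gains - losses) / N
}

#' One deterministic step (RK4)
#'
#' Advances positions, velocities and (in CAM mode) bound fractions by one
#' explicit fourth-order Runge-Kutta step of the coupled system
#' `dx/dt = v`, `dv/dt = -a v + adhesion acceleration`,
#' `dy/dt = binding rate`. Afterwards `y` is clipped to `[0, 1]` (the
#' continuous dynamics cannot leave the interval; clipping removes
#' integrator round-off only).
#'
#' @param state a [micro_state()].
#' @param dt step size, positive. A non-stiff choice satisfies
#'   `a * dt <= 0.1`.
#' @return the advanced `micro_state`.
#' @export
step_deterministic <- function(state, dt) {
  stopifnot(dt > 0)
  cam <- !is.null(state$y)
  deriv <- function(t, x, v, y) {
    list(dx = v,
         dv = -state$a * v + accel_matrix(x, y, t, state),
         dy = if (cam) cam_rate_vec(x, y, t, state) else NULL)
  }
  t0 <- state$t
  k1 <- deriv(t0, state$x, state$v, state$y)
  k2 <- deriv(t0 + dt / 2, state$x + dt / 2 * k1$dx,
              state$v + dt / 2 * k1$dv,
              if (cam) state$y + dt / 2 * k1$dy)
  k3 <- deriv(t0 + dt / 2, state$x + dt / 2 * k2$dx,
              state$v + dt / 2 * k2$dv,
              if (cam) state$y + dt / 2 * k2$dy)
  k4 <- deriv(t0 + dt, state$x + dt * k3$dx, state$v + dt * k3$dv,
              if (cam) state$y + dt * k3$dy)
  state$x <- state$x + dt / 6 * (k1$dx + 2 * k2$dx + 2 * k3$dx + k4$dx)
  state$v <- state$v + dt / 6 * (k1$dv + 2 * k2$dv + 2 * k3$dv + k4$dv)
  if (cam) {
    ynew <- state$y + dt / 6 * (k1$dy + 2 * k2$dy + 2 * k3$dy + k4$dy)
    state$y <- pmin(pmax(ynew, 0), 1)
  }
  state$t <- t0 + dt
  state
}

#' One stochastic reorientation step (velocity jump)
#'
#' Realises the turning operator \eqn{d q \bar c - c} as a jump process:
#' each cell independently reorients during `dt` with probability
#' `1 - exp(-dt)` (unit turning rate). A reorienting cell draws its new
#' velocity from the density `d * q` on the unit velocity ball; in 1D the
#' direction is `+1` with probability `q_+(x)` and the speed is uniform on
#' `(0, 1)`. Uses the current R random number generator stream.
#'
#' @param state a [micro_state()] in one dimension.
#' @param dt step size, positive.
#' @param q a [fiber_distribution_1d()].
#' @return the state with reoriented velocities (time unchanged; pair with
#'   [step_deterministic()] inside [simulate_micro()]).
#' @export
step_turning <- function(state, dt, q) {
  if (ncol(state$x) != 1L)
    stop("velocity-jump simulation is implemented for d = 1 only")
  stopifnot(inherits(q, "fiber_dist_1d"), dt > 0)
  N <- state$N
  turns <- stats::runif(N) < 1 - exp(-dt)
  if (any(turns)) {
    xs <- state$x[turns, 1L]
    dir <- ifelse(stats::runif(sum(turns)) < q$qplus(xs), 1, -1)
    speed <- stats::runif(sum(turns))
    state$v[turns, 1L] <- dir * speed
  }
  state
}

#' Empirical density of a particle state
#'
#' Bins particle positions onto the nodes of a uniform grid (node `m`
#' collects positions within `h/2` of `x_m`) and rescales so the field
#' integrates to `total_mass`.
#'
#' @param state a 1D [micro_state()].
#' @param grid a [density_field()] template or a list with `h` and `L`.
#' @param total_mass mass the binned field should integrate to (the
#'   mean-field normalisation is 1).
#' @return a [density_field()].
#' @export
empirical_density <- function(state, grid, total_mass = 1) {
  if (ncol(state$x) != 1L) stop("empirical_density expects a 1D state")
  h <- grid$h; L <- grid$L
  M1 <- as.integer(round(L / h)) + 1L
  pos <- state$x[, 1L]
  edges <- seq(-h / 2, by = h, length.out = M1 + 1L)
  keep <- pos >= edges[1] & pos < edges[M1 + 1L]
  if (!all(keep))
    warning(sprintf("%d particle(s) outside [0, L] dropped from the histogram",
                    sum(!keep)))
  counts <- tabulate(findInterval(pos[keep], edges), nbins = M1)
  vals <- counts / (sum(counts) * h) * total_mass
  if (sum(counts) == 0) vals <- numeric(M1)
  density_field(vals, h = h, L = L)
}

#' Simulate the microscopic model
#'
#' Interleaves deterministic RK4 steps with (optionally) stochastic
#' velocity jumps, recording snapshots of the full state.
#'
#' @param initial a [micro_state()].
#' @param T final time.
#' @param dt step size.
#' @param q optional [fiber_distribution_1d()]; if supplied, a turning
#'   step follows every deterministic step.
#' @param snapshot_every record every so many steps (the initial and final
#'   states are always recorded).
#' @param seed optional integer seed for the jump process, recorded in the
#'   trajectory metadata.
#' @param check_bound verify the speed-cap condition before simulating.
#' @return An object of class `trajectory`: snapshot `times`, list of
#'   `states`, the `seed` and generator identifier.
#' @export
simulate_micro <- function(initial, T, dt, q = NULL, snapshot_every = 1L,
                           seed = NULL, check_bound = TRUE) {
  stopifnot(inherits(initial, "micro_state"), T > 0, dt > 0)
  if (check_bound && !velocity_bound_ok(initial$law, initial$chi_sup, initial$a))
    stop("speed-cap condition violated: chi_sup * sup F / (r |B_r|) > a; ",
         "refusing to simulate")
  if (!is.null(seed)) set.seed(seed)
  n_steps <- as.integer(round(T / dt))
  state <- initial
  times <- state$t
  states <- list(state)
  for (k in seq_len(n_steps)) {
    state <- step_deterministic(state, dt)
    if (!is.null(q)) state <- step_turning(state, dt, q)
    if (k %% snapshot_every == 0L || k == n_steps) {
      times <- c(times, state$t)
      states <- c(states, list(state))
    }
  }
  structure(
    list(times = times, states = states, N = initial$N, seed = seed,
         generator = RNGkind()[1]),
    class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> N = %d, %d snapshots, t in [%g, %g]\n",
              x$N, length(x$times), x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' Export a trajectory as a delimited-text table
#'
#' One row per particle per snapshot with columns `t`, `id`, the position
#' components, the velocity components and (CAM mode) `y`.
#'
#' @param traj a `trajectory` from [simulate_micro()].
#' @param path output file path (tab-separated).
#' @return the path, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  rows <- lapply(seq_along(traj$times), function(k) {
    st <- traj$states[[k]]
    d <- ncol(st$x)
    df <- data.frame(t = st$t, id = seq_len(st$N))
    for (j in seq_len(d)) df[[paste0("x", j)]] <- st$x[, j]
    for (j in seq_len(d)) df[[paste0("v", j)]] <- st$v[, j]
    if (!is.null(st$y)) df$y <- st$y
    df
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
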