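#' Initial-condition generators
#'
#' Deterministic generators for the initial densities used throughout:
#' the uniform level (the reference study starts from `u0 == 5` on
#' `[0, 6]`) and sums of Gaussian bumps.
#'
#' @param kind `"uniform"` or `"gaussian_bumps"`.
#' @param level uniform level (uniform case).
#' @param centers,widths,masses bump parameters (recycled to a common
#'   length; Gaussian case).
#' @param L,h grid extent and spacing.
#' @return a [density_field()].
#' @export
make_ic <- function(kind = c("uniform", "gaussian_bumps"), level = 5,
                    centers = 3, widths = 0.2, masses = 30, L = 6, h = 0.01) {
  kind <- match.arg(kind)
  M1 <- as.integer(round(L / h)) + 1L
  x <- seq(0, by = h, length.out = M1)
  if (kind == "uniform") {
    if (level < 0) stop("density level must be non-negative")
    return(density_field(rep(level, M1), h = h, L = L))
  }
  n <- max(length(centers), length(widths), length(masses))
  centers <- rep_len(centers, n)
  widths <- rep_len(widths, n)
  masses <- rep_len(masses, n)
  if (any(widths <= 0) || any(masses < 0))
    stop("bump widths must be positive and masses non-negative")
  vals <- numeric(M1)
  for (k in seq_len(n))
    vals <- vals + masses[k] * stats::dnorm(x, centers[k], widths[k])
  density_field(vals, h = h, L = L)
}

#' Seeded particle cloud generator
#'
#' Uniform positions in a box, velocities uniform in the speed-capped
#' ball, and (CAM mode) bound fractions uniform in `(0, 1)`. The preset
#' `"two-cell"` returns the mirror-symmetric attracting pair at distance
#' 0.5 with zero velocities.
#'
#' @param n number of particles.
#' @param region position range: length-2 vector (1D) or a `2 x d`
#'   matrix of (lower, upper) rows.
#' @param speed_cap maximal initial speed, in `[0, 1)`.
#' @param seed integer seed.
#' @param cam draw initial bound fractions.
#' @param preset optional named preset (`"two-cell"`).
#' @param ... further arguments passed to [micro_state()] (e.g. `a`,
#'   `chi`, `law`, `kinetics`, `S`).
#' @return a [micro_state()].
#' @export
make_particle_cloud <- function(n = 100L, region = c(0, 6), speed_cap = 0.5,
                                seed = 1L, cam = FALSE, preset = NULL, ...) {
  if (!is.null(preset)) {
    if (preset != "two-cell") stop(sprintf("unknown preset '%s'", preset))
    return(micro_state(x = c(0, 0.5), v = c(0, 0), ...))
  }
  stopifnot(n >= 1L, speed_cap >= 0, speed_cap < 1)
  set.seed(seed)
  if (!is.matrix(region)) region <- matrix(region, nrow = 2L)
  d <- ncol(region)
  x <- vapply(seq_len(d), function(k)
    stats::runif(n, region[1L, k], region[2L, k]), numeric(n))
  x <- matrix(x, ncol = d)
  # uniform in the speed-capped ball: direction uniform, radius ~ s^(1/d)
  dir <- matrix(stats::rnorm(n * d), ncol = d)
  dir <- dir / pmax(sqrt(rowSums(dir^2)), 1e-300)
  rad <- speed_cap * stats::runif(n)^(1 / d)
  v <- dir * rad
  y <- if (cam) stats::runif(n) else NULL
  micro_state(x = x, v = v, y = y, ...)
}
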