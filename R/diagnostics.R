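#' Total mass of a density field
#'
#' Left-endpoint rule `h * sum(values[-last])`, consistent with the
#' finite-volume cells of the solver grid (for a uniform level `u == 5`
#' on `[0, 6]` this gives exactly 30).
#'
#' @param u a [density_field()].
#' @return scalar mass.
#' @export
total_mass <- function(u) {
  stopifnot(inherits(u, "density_field"))
  u$h * sum(u$values[-n_nodes(u)])
}

#' Detect aggregates in a density profile
#'
#' Aggregates are maximal contiguous runs of nodes with density strictly
#' above `threshold`; each run contributes one peak at its maximum node
#' (leftmost on ties). The natural threshold for a run started from a
#' uniform level is that level itself: aggregates are tight against a
#' depleted background, so any threshold between background and peak
#' yields the same count.
#'
#' @param u a [density_field()].
#' @param threshold positive density level.
#' @return An object of class `aggregate_summary`: `count`,
#'   `peak_positions`, `peak_heights`, `min_spacing` (`NA` when fewer
#'   than two peaks) and the `threshold` used.
#' @export
detect_aggregates <- function(u, threshold = 5) {
  stopifnot(inherits(u, "density_field"), threshold > 0)
  above <- u$values > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  pos <- numeric(0); height <- numeric(0)
  for (k in runs) {
    idx <- starts[k]:ends[k]
    j <- idx[which.max(u$values[idx])]   # which.max: leftmost tie-break
    pos <- c(pos, u$x[j])
    height <- c(height, u$values[j])
  }
  structure(
    list(count = length(pos), peak_positions = pos, peak_heights = height,
         min_spacing = if (length(pos) >= 2L) min(diff(pos)) else NA_real_,
         threshold = threshold),
    class = "aggregate_summary")
}

#' @export
print.aggregate_summary <- function(x, ...) {
  cat(sprintf("<aggregate_summary> %d aggregate(s) above %g", x$count,
              x$threshold))
  if (x$count > 0)
    cat(sprintf("; peaks at %s (heights %s)",
                paste(signif(x$peak_positions, 4), collapse = ", "),
                paste(signif(x$peak_heights, 4), collapse = ", ")))
  if (!is.na(x$min_spacing))
    cat(sprintf("; min spacing %.3g", x$min_spacing))
  cat("\n")
  invisible(x)
}

#' Ratio of maximal final densities of two runs
#'
#' Max over space of the final snapshot of `kA` divided by the same for
#' `kB`; quantifies how much denser the aggregates of one run are.
#'
#' @param kA,kB kymographs on the same grid.
#' @return scalar ratio.
#' @export
peak_density_ratio <- function(kA, kB) {
  if (length(kA$x) != length(kB$x) || max(abs(kA$x - kB$x)) > 1e-9)
    stop("kymographs are on different grids")
  max(kA$density[nrow(kA$density), ]) / max(kB$density[nrow(kB$density), ])
}

#' Micro-macro comparison at shared snapshot times
#'
#' Relative L1 distance between the empirical densities of a particle
#' trajectory and the rows of a kymograph, at every time present in
#' both.
#'
#' @param traj a `trajectory` from [simulate_micro()].
#' @param kymo a `kymograph`.
#' @param total_mass mass to which the empirical histograms are scaled.
#' @param tol time-matching tolerance.
#' @return data frame with columns `t` and `l1_error`.
#' @export
compare_micro_macro <- function(traj, kymo, total_mass = 1, tol = 1e-9) {
  grid <- list(h = kymo$x[2] - kymo$x[1], L = kymo$x[length(kymo$x)])
  shared <- which(vapply(traj$times, function(t)
    any(abs(kymo$times - t) < tol), logical(1)))
  if (length(shared) == 0L) stop("no shared snapshot times")
  err <- vapply(shared, function(k) {
    i <- which.min(abs(kymo$times - traj$times[k]))
    emp <- empirical_density(traj$states[[k]], grid, total_mass = total_mass)
    ref <- kymo$density[i, ]
    sum(abs(emp$values - ref)) * grid$h / (sum(abs(ref)) * grid$h)
  }, numeric(1))
  data.frame(t = traj$times[shared], l1_error = err)
}

#' One-line run summary for sweep tables
#'
#' @param kymo a `kymograph`.
#' @param threshold aggregate-detection threshold.
#' @return a one-row data frame echoing the configuration and reporting
#'   final-time aggregate statistics and relative mass drift.
#' @export
summarise_run <- function(kymo, threshold = 5) {
  cfg <- kymo$config
  u_final <- density_field(kymo$density[nrow(kymo$density), ],
                           h = kymo$x[2] - kymo$x[1],
                           L = kymo$x[length(kymo$x)])
  agg <- detect_aggregates(u_final, threshold)
  data.frame(
    D0 = cfg$D0, delta = cfg$delta, chi0 = cfg$chi0, theta = cfg$theta,
    T = cfg$T, h = cfg$h,
    n_aggregates = agg$count,
    min_spacing = agg$min_spacing,
    peak_max = if (agg$count > 0) max(agg$peak_heights) else max(u_final$values),
    mass_drift_rel = abs(kymo$mass[length(kymo$mass)] - kymo$mass[1]) /
      kymo$mass[1])
}
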