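#' Density field on a uniform 1D grid
#'
#' Carrier for the macroscopic cell density on the interval `[0, L]` with
#' nodes \eqn{x_m = m h}, both endpoints included (so `L/h + 1` nodes).
#'
#' @param values numeric vector of nodal densities (cells per unit length).
#' @param h grid spacing, positive.
#' @param L domain length; defaults to `h * (length(values) - 1)`.
#' @return An object of class `density_field` with fields `values`, `h`,
#'   `L` and the node coordinates `x`.
#' @export
density_field <- function(values, h, L = h * (length(values) - 1L)) {
  stopifnot(is.numeric(values), length(values) >= 2L, h > 0)
  if (abs(L - h * (length(values) - 1L)) > 1e-9 * max(L, 1))
    stop("grid mismatch: L must equal h * (number of nodes - 1)")
  structure(
    list(values = as.numeric(values), h = h, L = L,
         x = seq(0, by = h, length.out = length(values))),
    class = "density_field")
}

#' @export
print.density_field <- function(x, ...) {
  cat(sprintf("<density_field> %d nodes on [0, %g], h = %g, mass = %.6g\n",
              length(x$values), x$L, x$h, total_mass(x)))
  invisible(x)
}

n_nodes <- function(u) length(u$values)

same_grid <- function(a, b) {
  length(a$values) == length(b$values) &&
    abs(a$h - b$h) < 1e-12 && abs(a$L - b$L) < 1e-9
}
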