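#' Periodic two-dimensional domain
#'
#' All positions live on a square torus with the given edge length (in units
#' of the social repulsion length scale `lr`). Distances and displacements use
#' the minimum-image convention: each displacement component is reduced to
#' `[-edge_length/2, edge_length/2]`.
#'
#' @param edge_length positive edge length of the square domain (default 346,
#'   the reference simulation domain in units of `lr`).
#' @return an object of class `torus_geometry`.
#' @export
#' @examples
#' geo <- torus_geometry(100)
#' torus_distance(c(1, 1), c(99, 99), geo)  # wraps: sqrt(8), not sqrt(2*98^2)
torus_geometry <- function(edge_length = 346) {
  stopifnot(is.numeric(edge_length), length(edge_length) == 1,
            is.finite(edge_length), edge_length > 0)
  structure(list(edge_length = as.numeric(edge_length)), class = "torus_geometry")
}

#' @export
print.torus_geometry <- function(x, ...) {
  cat("<torus_geometry> edge length", x$edge_length, "lr\n")
  invisible(x)
}

#' Wrap coordinates onto the torus
#'
#' @param x numeric vector or matrix of coordinates.
#' @param geometry a [torus_geometry()].
#' @return coordinates wrapped into `[0, edge_length)`.
#' @export
torus_wrap <- function(x, geometry) {
  L <- geometry$edge_length
  out <- x %% L
  out[out >= L] <- 0
  out
}

#' Minimum-image displacement between points
#'
#' Componentwise displacement `a - b` reduced to the nearest periodic image.
#'
#' @param a,b numeric 2-vectors or n x 2 matrices of positions.
#' @inheritParams torus_wrap
#' @return displacement(s) with each component in `[-L/2, L/2]`.
#' @export
torus_displacement <- function(a, b, geometry) {
  L <- geometry$edge_length
  d <- a - b
  d - L * round(d / L)
}

#' Minimum-image distance between points
#'
#' @inheritParams torus_displacement
#' @return Euclidean distance(s) to the nearest periodic image.
#' @export
torus_distance <- function(a, b, geometry) {
  d <- torus_displacement(a, b, geometry)
  if (is.matrix(d)) sqrt(rowSums(d^2)) else sqrt(sum(d^2))
}
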