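#' A single Gaussian resource peak
#'
#' A peak contributes `amplitude * exp(-d^2 / decay_length^2)` to the resource
#' value at a point at minimum-image distance `d` from its centroid.
#'
#' @param centroid numeric 2-vector, peak centre on the torus.
#' @param amplitude resource value at the centre (`lambda0`, default 10).
#' @param decay_length Gaussian decay length (`lambda1`, default 20).
#' @return an object of class `resource_peak`.
#' @export
resource_peak <- function(centroid, amplitude = 10, decay_length = 20) {
  stopifnot(length(centroid) == 2, all(is.finite(centroid)),
            is.finite(amplitude), amplitude >= 0,
            is.finite(decay_length), decay_length > 0)
  structure(list(centroid = as.numeric(centroid),
                 amplitude = as.numeric(amplitude),
                 amplitude_init = as.numeric(amplitude),
                 decay_length = as.numeric(decay_length)),
            class = "resource_peak")
}

#' Dynamic multi-peak resource landscape
#'
#' A set of Gaussian peaks on a torus. Each peak performs Brownian motion with
#' drift `drift` and per-component standard deviation `diffusion_sd` per time
#' step, and with probability `1/relocation_timescale` per step it disappears
#' and reappears uniformly at random on the domain (its amplitude resetting to
#' the configured initial value). With `depletion_rate > 0` agents consume
#' resource at rate `u * S(x_i)` per step (see [deplete()]).
#'
#' @param peaks list of [resource_peak()] objects (may be empty for a uniform,
#'   resource-free environment).
#' @param drift numeric 2-vector, peak drift per unit time (`alpha`,
#'   default `c(1, 0)`).
#' @param diffusion_sd per-component standard deviation of the Brownian
#'   increment per step (`beta`, default 0.1).
#' @param relocation_timescale expected steps between relocations (`tau_p`,
#'   default 1500; `Inf` disables relocation).
#' @param depletion_rate consumption rate `u >= 0`; 0 disables depletion.
#' @param geometry a [torus_geometry()].
#' @return an object of class `resource_field`.
#' @export
#' @examples
#' geo <- torus_geometry(346)
#' fld <- resource_field(list(resource_peak(c(100, 100))), geometry = geo)
#' field_value(fld, c(100, 100))  # 10 at the peak centre
resource_field <- function(peaks = list(), drift = c(1, 0), diffusion_sd = 0.1,
                           relocation_timescale = 1500, depletion_rate = 0,
                           geometry = torus_geometry()) {
  stopifnot(is.list(peaks), all(vapply(peaks, inherits, TRUE, "resource_peak")),
            length(drift) == 2, all(is.finite(drift)),
            is.finite(diffusion_sd), diffusion_sd >= 0,
            relocation_timescale > 0,
            is.finite(depletion_rate), depletion_rate >= 0,
            inherits(geometry, "torus_geometry"))
  peaks <- lapply(peaks, function(p) {
    p$centroid <- torus_wrap(p$centroid, geometry)
    p
  })
  structure(list(peaks = peaks, drift = as.numeric(drift),
                 diffusion_sd = as.numeric(diffusion_sd),
                 relocation_timescale = as.numeric(relocation_timescale),
                 depletion_rate = as.numeric(depletion_rate),
                 geometry = geometry),
            class = "resource_field")
}

#' Build a resource field from scalar parameters
#'
#' Convenience constructor mirroring the run-configuration environment block:
#' `n_peaks` identical peaks with the given amplitude and decay length,
#' centred either uniformly at random (using the current RNG state) or at the
#' supplied coordinates.
#'
#' @param n_peaks number of peaks `M` (default 2).
#' @param amplitude,decay_length peak parameters `lambda0`, `lambda1`.
#' @param centroids `"uniform"` or an `n_peaks` x 2 matrix of centres.
#' @inheritParams resource_field
#' @return a [resource_field()].
#' @export
make_resource_field <- function(n_peaks = 2, amplitude = 10, decay_length = 20,
                                centroids = "uniform", drift = c(1, 0),
                                diffusion_sd = 0.1, relocation_timescale = 1500,
                                depletion_rate = 0, geometry = torus_geometry()) {
  stopifnot(n_peaks >= 0)
  L <- geometry$edge_length
  if (identical(centroids, "uniform")) {
    centroids <- matrix(runif(2 * n_peaks, 0, L), ncol = 2)
  } else {
    centroids <- as.matrix(centroids)
    stopifnot(nrow(centroids) == n_peaks, ncol(centroids) == 2)
  }
  peaks <- lapply(seq_len(n_peaks), function(p)
    resource_peak(centroids[p, ], amplitude, decay_length))
  resource_field(peaks, drift, diffusion_sd, relocation_timescale,
                 depletion_rate, geometry)
}

#' @export
print.resource_field <- function(x, ...) {
  cat("<resource_field>", length(x$peaks), "peak(s) on a torus of edge",
      x$geometry$edge_length, "\n")
  if (length(x$peaks)) {
    m <- peaks_matrix(x)
    colnames(m) <- c("x", "y", "amplitude", "decay_length")
    print(round(m, 3))
  }
  invisible(x)
}

# peaks as the x / y / amplitude / decay_length matrix used by the C++ kernels
peaks_matrix <- function(field) {
  if (!length(field$peaks)) return(matrix(numeric(0), ncol = 4))
  t(vapply(field$peaks, function(p)
    c(p$centroid, p$amplitude, p$decay_length), numeric(4)))
}

peaks_amp_init <- function(field) {
  vapply(field$peaks, function(p) p$amplitude_init, numeric(1))
}

# rebuild the peak list from a kernel matrix, preserving initial amplitudes
set_peaks_matrix <- function(field, m) {
  field$peaks <- lapply(seq_len(nrow(m)), function(p) {
    pk <- field$peaks[[p]]
    pk$centroid <- c(m[p, 1], m[p, 2])
    pk$amplitude <- m[p, 3]
    pk
  })
  field
}

#' Resource value at one or more points
#'
#' Sums the Gaussian contribution of every peak, with minimum-image distances:
#' `S(x) = sum_p amplitude_p * exp(-d_p^2 / decay_length_p^2)`.
#'
#' @param field a [resource_field()].
#' @param x numeric 2-vector or n x 2 matrix of query points.
#' @return resource value(s), non-negative.
#' @export
field_value <- function(field, x) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 2)
  if (!all(is.finite(x))) stop("non-finite coordinates")
  out <- cpp_field_values(peaks_matrix(field), x, field$geometry$edge_length)
  if (length(out) == 1) out[[1]] else out
}

#' Advance the resource peaks by one time step
#'
#' Each centroid moves by `drift` plus an isotropic Gaussian increment with
#' per-component standard deviation `diffusion_sd`, wrapped onto the torus;
#' independently, with probability `1/relocation_timescale`, a peak relocates
#' to a uniform random position and its amplitude resets to the configured
#' initial value. Uses the current R RNG state; draws are ordered by peak
#' (x-increment, y-increment, relocation test, then relocation coordinates).
#'
#' @param field a [resource_field()].
#' @return the updated field.
#' @export
step_peaks <- function(field) {
  L <- field$geometry$edge_length
  p_rel <- if (is.finite(field$relocation_timescale))
    1 / field$relocation_timescale else 0
  field$peaks <- lapply(field$peaks, function(p) {
    p$centroid <- torus_wrap(
      p$centroid + field$drift + rnorm(2, 0, field$diffusion_sd),
      field$geometry)
    if (p_rel > 0 && runif(1) < p_rel) {
      p$centroid <- runif(2, 0, L)
      p$amplitude <- p$amplitude_init
    }
    p
  })
  field
}

#' Consume resource at agent positions (depletion variant)
#'
#' Each agent consumes `u * S(x_i)` in one step. The consumption is attributed
#' to peaks in proportion to their contribution to `S(x_i)`; each peak's
#' amplitude is reduced by its attributed total, floored at zero.
#'
#' @param field a [resource_field()].
#' @param positions n x 2 matrix of agent positions.
#' @param consumption_rate rate `u >= 0` (defaults to the field's
#'   `depletion_rate`).
#' @return list with elements `field` (updated) and `consumed` (per-agent
#'   amounts).
#' @export
deplete <- function(field, positions, consumption_rate = field$depletion_rate) {
  if (consumption_rate < 0) stop("consumption_rate must be >= 0")
  if (!is.matrix(positions)) positions <- matrix(positions, ncol = 2)
  n <- nrow(positions)
  m <- peaks_matrix(field)
  npk <- nrow(m)
  if (consumption_rate == 0 || npk == 0)
    return(list(field = field, consumed = numeric(n)))
  L <- field$geometry$edge_length
  # per-agent, per-peak contributions
  contrib <- vapply(seq_len(npk), function(p) {
    d <- torus_distance(positions,
                        matrix(m[p, 1:2], n, 2, byrow = TRUE), field$geometry)
    m[p, 3] * exp(-d^2 / m[p, 4]^2)
  }, numeric(n))
  contrib <- matrix(contrib, nrow = n)
  stot <- rowSums(contrib)
  consumed <- consumption_rate * stot
  share <- contrib / ifelse(stot > 0, stot, 1)
  drain <- colSums(share * consumed)
  m[, 3] <- pmax(0, m[, 3] - drain)
  list(field = set_peaks_matrix(field, m), consumed = consumed)
}

#' Integrated mass of a resource peak
#'
#' The integral of the peak's value over the plane. For `method = "analytic"`
#' this is the closed form `amplitude * pi * decay_length^2`; `"quadrature"`
#' integrates the radial profile numerically (useful as a cross-check).
#'
#' @param peak a [resource_peak()].
#' @param method `"analytic"` (default) or `"quadrature"`.
#' @return scalar mass.
#' @export
peak_mass <- function(peak, method = c("analytic", "quadrature")) {
  method <- match.arg(method)
  if (method == "analytic")
    return(peak$amplitude * pi * peak$decay_length^2)
  f <- function(r) 2 * pi * r * peak$amplitude * exp(-r^2 / peak$decay_length^2)
  integrate(f, 0, Inf, rel.tol = 1e-10)$value
}

#' Export a field snapshot on a regular grid
#'
#' Evaluates the resource value on an `n_grid` x `n_grid` grid, row-major with
#' x varying fastest. Coordinates are in units of `lr`.
#'
#' @param field a [resource_field()].
#' @param n_grid grid resolution per axis.
#' @return data frame with columns `x`, `y`, `value`.
#' @export
field_grid <- function(field, n_grid = 64) {
  L <- field$geometry$edge_length
  g <- seq(0, L, length.out = n_grid + 1)[seq_len(n_grid)]
  pts <- expand.grid(x = g, y = g)  # x fastest
  pts$value <- field_value(field, as.matrix(pts))
  pts
}
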