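#' Random collision-free placement of spheres in a box
#'
#' Uniform random positions, largest sphere first, with a bounded number of
#' rejection-sampling retries per sphere; errors (reporting the packing
#' fraction) when placement fails.  With reflecting walls spheres are placed
#' fully inside the box; with periodic boundaries only the centre is
#' constrained.
#'
#' @param radii numeric vector of sphere radii (Angstrom).
#' @param side box side (Angstrom).
#' @param boundary `"reflect"` or `"periodic"`.
#' @param max_tries rejection-sampling attempts per sphere.
#' @param packing_limit refuse outright above this total volume fraction.
#' @return an n x 3 matrix of positions.
#' @export
place_initial <- function(radii, side, boundary = c("reflect", "periodic"),
                          max_tries = 2000, packing_limit = 0.45) {
  boundary <- match.arg(boundary)
  if (length(radii) == 0) return(matrix(numeric(0), 0, 3))
  stopifnot(all(radii > 0), side > 0)
  packing <- sum(4 / 3 * pi * radii^3) / side^3
  if (packing > packing_limit)
    stop(sprintf("packing fraction %.3f exceeds limit %.2f", packing,
                 packing_limit))
  .place_spheres_cpp(as.numeric(radii), side, as.integer(max_tries),
                     if (boundary == "periodic") 1L else 0L)
}

#' Displace a position and fold it back into the box
#'
#' Moves `pos` by `L * dir` and folds the result into `[0, side)` by
#' specular reflection at each wall (repeated folding handles steps longer
#' than the box) or by wrap-around for periodic boundaries.
#'
#' @param pos length-3 position (Angstrom).
#' @param dir length-3 unit direction.
#' @param L step modulus (Angstrom).
#' @param side box side (Angstrom).
#' @param boundary `"reflect"` or `"periodic"`.
#' @return the folded new position.
#' @export
propose_move <- function(pos, dir, L, side,
                         boundary = c("reflect", "periodic")) {
  boundary <- match.arg(boundary)
  x <- pos + L * dir
  if (boundary == "periodic") return(x %% side)
  p <- x %% (2 * side)
  out <- ifelse(p < side, p, 2 * side - p)
  pmin(out, side * (1 - 1e-15))
}

#' Fixed-radius neighbour query
#'
#' Ids (row indices) of all points whose centre-to-centre distance from
#' `pos` is at most `radius`; a closed ball, so points exactly on the
#' boundary are included.  Uses a uniform-grid index for small radii and a
#' direct scan otherwise; under periodic boundaries the minimum-image metric
#' is used.
#'
#' @param positions n x 3 matrix of points.
#' @param pos length-3 query position.
#' @param radius query radius (Angstrom), >= 0.
#' @param side box side (needed for the grid and the periodic metric).
#' @param boundary `"reflect"` or `"periodic"`.
#' @return integer vector of row indices (sorted).
#' @export
neighbors_within <- function(positions, pos, radius, side,
                             boundary = c("reflect", "periodic")) {
  boundary <- match.arg(boundary)
  stopifnot(radius >= 0, side > 0)
  if (NROW(positions) == 0) return(integer(0))
  positions <- matrix(as.numeric(positions), ncol = 3)
  .neighbors_within_cpp(positions, as.numeric(pos), radius, side,
                        if (boundary == "periodic") 1L else 0L)
}
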