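#' Measure the three-point articulation angle
#'
#' The signed angle (radians, counter-clockwise) at `vertex` from the ray
#' towards `ray_a` to the ray towards `ray_b`, for the derotation triple of
#' a scheme — e.g. the croup-to-neck angle drawn by outline points 1, 15
#' and 30.
#'
#' @param x a `k x 2` matrix, `k x 2 x n` array or [landmark_set()].
#' @param triple integer triple `(ray_a, vertex, ray_b)` or a
#'   [point_scheme()] (its `derotation_triple` is used).
#' @return signed angle(s) in `(-pi, pi]`, one per configuration.
#' @export
measure_angle <- function(x, triple) {
  if (inherits(triple, "point_scheme")) triple <- triple$derotation_triple
  coords <- as_coords_array(x)
  ax <- coords[triple[1L], 1L, ] - coords[triple[2L], 1L, ]
  ay <- coords[triple[1L], 2L, ] - coords[triple[2L], 2L, ]
  bx <- coords[triple[3L], 1L, ] - coords[triple[2L], 1L, ]
  by <- coords[triple[3L], 2L, ] - coords[triple[2L], 2L, ]
  if (any(ax^2 + ay^2 == 0) || any(bx^2 + by^2 == 0))
    stop("degenerate angle: a ray point coincides with the vertex")
  atan2(ax * by - ay * bx, ax * bx + ay * by)
}

#' Circular mean and dispersion of angles
#'
#' Utilities for summarizing measured articulation angles, which live on
#' the circle: `circular_mean` is the direction of the mean resultant
#' vector, and `circular_sd` is the root-mean-square angular deviation
#' from it (deviations wrapped to `(-pi, pi]`), which matches the ordinary
#' standard deviation when the dispersion is small but is immune to
#' wrap-around at +/-pi.
#'
#' @param theta angles in radians.
#' @return a scalar, in radians.
#' @export
circular_mean <- function(theta) atan2(mean(sin(theta)), mean(cos(theta)))

#' @rdname circular_mean
#' @export
circular_sd <- function(theta) {
  dev <- (theta - circular_mean(theta) + pi) %% (2 * pi) - pi
  sqrt(mean(dev^2))
}

#' Remove articulation by fixing a three-point angle
#'
#' Rigidly rotates the landmark subset distal to the articulation vertex
#' (all points with index strictly greater than the vertex index) about the
#' vertex so that the signed angle `ray_a - vertex - ray_b` equals
#' `reference_angle`. Points up to and including the vertex are unchanged,
#' and all pairwise distances within the rotated subset are preserved, so
#' the operation removes only the articulation (e.g. the balance movement
#' of the neck) that otherwise smears variance over stable landmarks during
#' least-squares superimposition (the Pinocchio effect).
#'
#' @param x a `k x 2` configuration matrix.
#' @param triple `(ray_a, vertex, ray_b)` indices with
#'   `ray_a <= vertex < ray_b`, or a [point_scheme()].
#' @param reference_angle target signed angle in radians.
#' @return the derotated `k x 2` matrix.
#' @export
derotate <- function(x, triple, reference_angle) {
  if (inherits(triple, "point_scheme")) triple <- triple$derotation_triple
  x <- as_config_matrix(x)
  if (!(triple[1L] <= triple[2L] && triple[2L] < triple[3L]))
    stop("derotation triple must satisfy ray_a <= vertex < ray_b ",
         "(the rotated subset is vertex+1 .. k)")
  cur <- measure_angle(x, triple)
  delta <- (reference_angle - cur + pi) %% (2 * pi) - pi
  rotate_about(x, triple[2L], (triple[2L] + 1L):nrow(x), delta)
}

## internal: rotate the given point indices about the vertex point by delta
rotate_about <- function(x, vertex, indices, delta) {
  v <- x[vertex, ]
  R <- matrix(c(cos(delta), sin(delta), -sin(delta), cos(delta)), 2L)
  x[indices, ] <- sweep(sweep(x[indices, , drop = FALSE], 2L, v) %*% t(R),
                        2L, v, `+`)
  x
}

#' Derotate a whole sample to a common reference angle
#'
#' Measures the articulation angle of every configuration and rotates each
#' distal subset so all specimens share one reference angle. By default the
#' reference is the circular mean of the measured angles over the whole
#' sample (contexts pooled); pass a value to fix it explicitly or derotate
#' per group.
#'
#' @param x a [landmark_set()] or `k x 2 x n` array.
#' @param triple derotation triple or [point_scheme()].
#' @param reference_angle optional fixed reference (radians); default the
#'   sample circular mean.
#' @return a list with `coords` (derotated `k x 2 x n` array),
#'   `reference_angle` and `angles` (the measured input angles).
#' @export
derotate_set <- function(x, triple, reference_angle = NULL) {
  if (inherits(triple, "point_scheme")) triple <- triple$derotation_triple
  coords <- as_coords_array(x)
  angles <- measure_angle(coords, triple)
  if (is.null(reference_angle)) reference_angle <- circular_mean(angles)
  for (s in seq_len(dim(coords)[3L]))
    coords[, , s] <- derotate(coords[, , s], triple, reference_angle)
  list(coords = coords, reference_angle = reference_angle, angles = angles)
}
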