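#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of the points from their
#' centroid — the size measure removed by Procrustes scaling.
#'
#' @param x a `k x 2` coordinate matrix (or a `landmark_set` with one
#'   configuration).
#' @return a positive scalar.
#' @export
centroid_size <- function(x) {
  x <- as_config_matrix(x)
  if (nrow(x) < 2L) stop("centroid size needs at least 2 points")
  cs <- sqrt(sum(sweep(x, 2L, colMeans(x))^2))
  if (cs == 0) stop("degenerate configuration: all points coincident")
  cs
}

## internal: accept k x 2 matrix or single-config landmark_set
as_config_matrix <- function(x) {
  if (inherits(x, "landmark_set")) {
    if (n_specimens(x) != 1L) stop("expected a single configuration")
    return(x$coords[, , 1L])
  }
  stopifnot(is.matrix(x), ncol(x) == 2L)
  x
}

## internal: complex representation of a k x 2 matrix / k x 2 x n array
as_complex <- function(x) {
  if (length(dim(x)) == 3L)
    matrix(complex(real = x[, 1L, ], imaginary = x[, 2L, ]), dim(x)[1L])
  else complex(real = x[, 1L], imaginary = x[, 2L])
}
from_complex <- function(z) {
  if (is.matrix(z)) {
    a <- array(NA_real_, c(nrow(z), 2L, ncol(z)))
    a[, 1L, ] <- Re(z); a[, 2L, ] <- Im(z)
    a
  } else cbind(x = Re(z), y = Im(z))
}

#' Ordinary Procrustes alignment of one configuration onto another
#'
#' Finds the similarity transform (rotation, positive scale, translation —
#' never a reflection) minimizing the sum of squared distances between the
#' transformed source points and the target points.
#'
#' @param source,target `k x 2` coordinate matrices with equal `k`.
#' @return a list with `angle` (radians, counter-clockwise), `scale`,
#'   `translation` (length-2), `aligned` (transformed source) and `rss`
#'   (residual sum of squares at the optimum).
#' @export
align_pair <- function(source, target) {
  X <- as_config_matrix(source); Y <- as_config_matrix(target)
  if (nrow(X) != nrow(Y))
    stop("configurations differ in point count: ", nrow(X), " vs ", nrow(Y))
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2L, cx); Yc <- sweep(Y, 2L, cy)
  ssx <- sum(Xc^2); ssy <- sum(Yc^2)
  if (ssx == 0 || ssy == 0) stop("degenerate configuration in align_pair")
  ## optimal rotation/scale in complex form: Y ~ beta * e^{i theta} X
  num <- sum(Xc[, 1L] * Yc[, 2L] - Xc[, 2L] * Yc[, 1L])
  den <- sum(Xc[, 1L] * Yc[, 1L] + Xc[, 2L] * Yc[, 2L])
  theta <- atan2(num, den)
  beta <- sqrt(num^2 + den^2) / ssx
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L)
  aligned <- beta * Xc %*% t(R)
  aligned <- sweep(aligned, 2L, cy, `+`)
  rss <- max(0, ssy - (num^2 + den^2) / ssx)
  list(angle = theta, scale = beta,
       translation = cy - as.numeric(beta * (R %*% cx)),
       aligned = aligned, rss = rss)
}

#' Generalized Procrustes analysis
#'
#' Iteratively superimposes a sample of configurations: each is centered and
#' scaled to unit centroid size (partial-Procrustes convention), rotated to
#' the current consensus, and the consensus (coordinate-wise mean,
#' renormalized to unit size) is recomputed until its root-mean-square
#' change falls below `tol`.
#'
#' @param x a [landmark_set()], `k x 2 x n` array or list of matrices.
#' @param tol convergence tolerance on RMS consensus change (default 1e-8).
#' @param max_iter maximum iterations (default 100); non-convergence gives a
#'   warning and a result flagged `converged = FALSE`.
#' @param scale_to_unit if `FALSE`, perform full-Procrustes scaling of each
#'   configuration to the consensus instead of fixing unit centroid size.
#' @return an object of class `gpa_fit`: `aligned` (`k x 2 x n`),
#'   `consensus` (`k x 2`, unit centroid size), `centroid_sizes`,
#'   `iterations`, `final_change`, `converged`, plus `derotated` /
#'   `reference_angle` bookkeeping fields.
#' @export
gpa <- function(x, tol = 1e-8, max_iter = 100L, scale_to_unit = TRUE) {
  coords <- as_coords_array(x)
  k <- dim(coords)[1L]; n <- dim(coords)[3L]
  if (n < 2L) stop("GPA needs at least 2 configurations")
  Z <- as_complex(coords)                       # k x n
  Z <- sweep(Z, 2L, colMeans(Z))                # center
  sizes <- sqrt(colSums(Mod(Z)^2))
  if (any(sizes == 0)) stop("degenerate (coincident-point) configuration")
  Z <- sweep(Z, 2L, sizes, `/`)                 # unit centroid size
  consensus <- Z[, 1L]
  iter <- 0L; change <- Inf
  while (iter < max_iter && change >= tol) {
    iter <- iter + 1L
    ## rotate (and optionally rescale) each configuration onto the consensus
    u <- colSums(Conj(Z) * consensus)           # per-specimen cross terms
    rot <- u / Mod(u)
    if (scale_to_unit) Z <- sweep(Z, 2L, rot, `*`)
    else {
      beta <- Mod(u) / colSums(Mod(Z)^2)
      Z <- sweep(Z, 2L, beta * rot, `*`)
    }
    new_consensus <- rowMeans(Z)
    new_consensus <- new_consensus - mean(new_consensus)
    new_consensus <- new_consensus / sqrt(sum(Mod(new_consensus)^2))
    change <- sqrt(mean(Mod(new_consensus - consensus)^2))
    consensus <- new_consensus
  }
  converged <- change < tol
  if (!converged)
    warning("GPA did not converge in ", max_iter,
            " iterations (last RMS change ", signif(change, 3), ")")
  ## final rotation pass so every shape is optimally aligned to the
  ## converged consensus
  u <- colSums(Conj(Z) * consensus)
  Z <- sweep(Z, 2L, u / Mod(u), `*`)
  cz <- rowMeans(Z); cz <- cz - mean(cz)
  cz <- cz / sqrt(sum(Mod(cz)^2))   # consensus kept at unit centroid size
  structure(list(
    aligned = from_complex(Z),
    consensus = from_complex(cz),
    centroid_sizes = sizes,
    iterations = iter, final_change = change, converged = converged,
    specimen_id = if (inherits(x, "landmark_set")) x$info$specimen_id
                  else dimnames(coords)[[3L]],
    derotated = FALSE, reference_angle = NULL),
    class = "gpa_fit")
}

#' @export
print.gpa_fit <- function(x, ...) {
  d <- dim(x$aligned)
  cat("gpa_fit:", d[3L], "aligned configurations of", d[1L], "points;",
      x$iterations, "iterations,",
      if (x$converged) "converged" else "NOT converged",
      sprintf("(final change %.2e)\n", x$final_change))
  if (x$derotated)
    cat(sprintf("  derotated to reference angle %.2f deg\n",
                x$reference_angle * 180 / pi))
  invisible(x)
}

#' Partial Procrustes distance between two normalized shapes
#'
#' The square root of the minimal residual sum of squares over rotations,
#' for two configurations already centered and scaled to unit centroid
#' size.
#'
#' @param a,b `k x 2` matrices, centered with unit centroid size.
#' @param tol normalization check tolerance.
#' @return a non-negative scalar.
#' @export
procrustes_distance <- function(a, b, tol = 1e-6) {
  a <- as_config_matrix(a); b <- as_config_matrix(b)
  if (nrow(a) != nrow(b)) stop("shapes differ in point count")
  for (m in list(a, b)) {
    if (max(abs(colMeans(m))) > tol || abs(sqrt(sum(m^2)) - 1) > tol)
      stop("procrustes_distance expects centered, unit-size shapes; ",
           "align/normalize first (e.g. via gpa())")
  }
  za <- as_complex(a); zb <- as_complex(b)
  u <- sum(Conj(zb) * za)
  phase <- if (Mod(u) > 0) u / Mod(u) else 1 + 0i
  ## residual computed directly for full precision near zero distance
  sqrt(sum(Mod(za - zb * phase)^2))
}
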