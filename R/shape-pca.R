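#' Principal component analysis of Procrustes coordinates
#'
#' Singular-value decomposition of the flattened aligned coordinates
#' centered at their mean (the consensus), i.e. PCA on the covariance of
#' the Procrustes coordinates — coordinates share units so no correlation
#' scaling is applied. A deterministic sign convention makes each loading's
#' largest-magnitude entry positive so PC orientation is reproducible
#' across runs and platforms.
#'
#' @param ensemble a `gpa_fit` (or `slide_fit`, whose final ensemble is
#'   used).
#' @return an object of class `shape_pca`: `loadings` (`2k x c` orthonormal
#'   columns, x-block then y-block), `scores` (`n x c`, zero column means),
#'   `percent_variance` (length `c`, summing to ~100), `consensus`
#'   (`k x 2` mean shape used as center), `k`, `n`.
#' @export
shape_pca <- function(ensemble) {
  if (inherits(ensemble, "slide_fit")) ensemble <- ensemble$ensemble
  stopifnot(inherits(ensemble, "gpa_fit"))
  coords <- ensemble$aligned
  k <- dim(coords)[1L]; n <- dim(coords)[3L]
  if (n < 2L) stop("shape PCA needs at least 2 specimens")
  X <- t(apply(coords, 3L, as.numeric))        # n x 2k, columns x1..xk,y1..yk
  center <- colMeans(X)
  X0 <- sweep(X, 2L, center)
  sv <- svd(X0)
  total <- sum(sv$d^2)
  ## superimposition suppresses 4 similarity dimensions, but only to second
  ## order, so the full basis is kept: the trailing ~4 components carry
  ## numerically negligible variance and the decomposition stays exact
  ncomp <- max(1L, min(n - 1L, 2L * k))
  loadings <- sv$v[, seq_len(ncomp), drop = FALSE]
  scores <- (sv$u %*% diag(sv$d, length(sv$d)))[, seq_len(ncomp), drop = FALSE]
  ## sign convention: largest-|.| loading entry positive
  for (j in seq_len(ncomp)) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  pct <- 100 * sv$d[seq_len(ncomp)]^2 / total
  structure(list(loadings = loadings, scores = scores,
                 percent_variance = pct,
                 consensus = matrix(center, k, 2L,
                                    dimnames = list(NULL, c("x", "y"))),
                 k = k, n = n,
                 specimen_id = ensemble$specimen_id),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  cat("shape_pca:", x$n, "specimens,", x$k, "points,",
      length(x$percent_variance), "components\n")
  show <- utils::head(x$percent_variance, 5L)
  cat("  % variance:", paste(sprintf("%.1f", show), collapse = ", "),
      if (length(x$percent_variance) > 5L) "...", "\n")
  invisible(x)
}

#' Leading principal components above a variance threshold
#'
#' Returns the indices of the leading components whose percent variance is
#' at least `threshold_percent`, stopping at the first component below the
#' threshold (components after a sub-threshold one are discarded, following
#' the rule that PCs explaining under 10% of variance are dropped). Always
#' retains at least the first component.
#'
#' @param pca a [shape_pca()] (or a numeric vector of percent variances).
#' @param threshold_percent retention threshold in percent, in (0, 100).
#' @return integer vector of retained component indices.
#' @export
retained_components <- function(pca, threshold_percent = 10) {
  stopifnot(threshold_percent > 0, threshold_percent < 100)
  pct <- if (inherits(pca, "shape_pca")) pca$percent_variance else as.numeric(pca)
  above <- pct >= threshold_percent
  n_keep <- if (!above[1L]) 1L
            else if (all(above)) length(pct)
            else which(!above)[1L] - 1L
  seq_len(n_keep)
}

#' Shape at a given score along a principal component
#'
#' Reconstructs `consensus + score * loading` as a `k x 2` configuration;
#' with the observed minimum / maximum score of a component this gives the
#' extreme shapes visualized by deformation grids.
#'
#' @param pca a [shape_pca()].
#' @param component component index.
#' @param score position along the component, in score units.
#' @return a `k x 2` shape matrix.
#' @export
pc_extreme_shape <- function(pca, component, score) {
  stopifnot(inherits(pca, "shape_pca"))
  if (component < 1L || component > ncol(pca$loadings))
    stop("component ", component, " out of range 1..", ncol(pca$loadings))
  pca$consensus + score * matrix(pca$loadings[, component], pca$k, 2L)
}

#' Thin-plate-spline deformation grid
#'
#' Maps a regular square lattice covering the reference shape's bounding
#' box (expanded by a relative margin) through the TPS warp from the
#' reference to `reference + magnitude * (target - reference)` — the grids
#' used to visualize the deformation along a principal component.
#'
#' @param reference,target `k x 2` shapes.
#' @param grid_density nodes per side (default 24).
#' @param magnitude scalar multiplier of the deformation (0 gives the
#'   undeformed lattice exactly).
#' @param margin relative bounding-box expansion (default 0.15).
#' @return an object of class `deformation_grid`: `source_grid` and
#'   `warped_grid` (`m^2 x 2` node coordinates, row-major by grid row),
#'   `n_side`, `magnitude`, plus the warped `landmarks`.
#' @export
deformation_grid <- function(reference, target, grid_density = 24L,
                             magnitude = 1, margin = 0.15) {
  reference <- as_config_matrix(reference); target <- as_config_matrix(target)
  if (!all(dim(reference) == dim(target))) stop("shapes are not conformable")
  if (grid_density < 2L) stop("grid_density must be at least 2")
  rng_x <- range(reference[, 1L]); rng_y <- range(reference[, 2L])
  pad_x <- margin * diff(rng_x); pad_y <- margin * diff(rng_y)
  side <- max(diff(rng_x) + 2 * pad_x, diff(rng_y) + 2 * pad_y)
  cx <- mean(rng_x); cy <- mean(rng_y)
  xs <- seq(cx - side / 2, cx + side / 2, length.out = grid_density)
  ys <- seq(cy - side / 2, cy + side / 2, length.out = grid_density)
  src <- as.matrix(expand.grid(x = xs, y = ys))
  tgt <- reference + magnitude * (target - reference)
  if (magnitude == 0) {
    warped <- src
    lm_warped <- reference
  } else {
    w <- tps_warp(reference, tgt)
    warped <- predict(w, src)
    lm_warped <- predict(w, reference)
  }
  structure(list(source_grid = src, warped_grid = warped,
                 n_side = as.integer(grid_density), magnitude = magnitude,
                 landmarks = lm_warped),
            class = "deformation_grid")
}

#' Write a deformation grid as node-coordinate CSV
#'
#' Emits rows `(grid_id, node_row, node_col, x, y)` for both the source and
#' warped lattices, suitable for downstream plotting.
#'
#' @param grid a [deformation_grid()].
#' @param path output CSV path.
#' @param id label prefix for the `grid_id` column.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(grid, path, id = "grid") {
  stopifnot(inherits(grid, "deformation_grid"))
  m <- grid$n_side
  idx <- expand.grid(node_col = seq_len(m), node_row = seq_len(m))
  df <- rbind(
    data.frame(grid_id = paste0(id, "_source"), node_row = idx$node_row,
               node_col = idx$node_col, x = grid$source_grid[, 1L],
               y = grid$source_grid[, 2L]),
    data.frame(grid_id = paste0(id, "_warped"), node_row = idx$node_row,
               node_col = idx$node_col, x = grid$warped_grid[, 1L],
               y = grid$warped_grid[, 2L]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
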