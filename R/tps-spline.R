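## Thin-plate-spline machinery: radial kernel U(r) = r^2 log r^2 (with
## U(0) = 0), the bending-energy matrix, and interpolating warps used both
## for semilandmark sliding and for deformation grids.

## kernel evaluated on squared distances
tps_U <- function(r2) ifelse(r2 > 0, r2 * log(r2), 0)

## kernel matrix between two point sets (rows of a, rows of b)
tps_kernel <- function(a, b) {
  r2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  tps_U(pmax(r2, 0))
}

## internal: build and invert the bordered TPS system for a reference
tps_system <- function(reference, regularize = TRUE, ridge = 1e-8) {
  k <- nrow(reference)
  d2 <- as.matrix(stats::dist(reference))^2
  dup <- which(d2 == 0 & upper.tri(d2), arr.ind = TRUE)
  if (nrow(dup))
    stop("singular TPS kernel: coincident reference points ",
         paste(apply(dup, 1L, function(r) paste(r[2L], r[1L], sep = "/")),
               collapse = ", "))
  K <- tps_U(d2)
  Q <- cbind(1, reference)
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 3L, 3L)))
  Linv <- tryCatch(solve(L), error = function(e) NULL)
  if (is.null(Linv)) {
    if (!regularize)
      stop("singular TPS system (collinear reference points?); ",
           "retry with regularize = TRUE")
    ## exactly collinear references make the affine block rank-deficient, so
    ## no kernel ridge can help; take the Moore-Penrose pseudo-inverse
    message("TPS system singular (collinear reference?); ",
            "using the Moore-Penrose pseudo-inverse as regularized solution")
    sv <- svd(L)
    keep <- sv$d > ridge * max(sv$d)
    Linv <- sv$v[, keep, drop = FALSE] %*%
      (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
  }
  list(L = L, Linv = Linv, k = k)
}

#' Bending-energy matrix of a thin-plate spline reference
#'
#' The `k x k` matrix `B` such that for a displacement field `d` of the
#' reference points (per coordinate axis), `t(d) %*% B %*% d` is the TPS
#' bending energy of the interpolating warp. `B` is symmetric positive
#' semidefinite and annihilates affine displacement fields (constant,
#' `x` and `y`), so a 3-point reference gives the zero matrix exactly.
#'
#' @param reference `k x 2` reference configuration (typically the GPA
#'   consensus).
#' @param regularize handle a singular system (exactly collinear
#'   references, whose affine block is rank-deficient) by taking the
#'   Moore-Penrose pseudo-inverse, with a logged message; if `FALSE`,
#'   degenerate references are an error.
#' @param ridge relative singular-value cutoff used when regularizing.
#' @return a `k x k` symmetric matrix.
#' @export
bending_energy_matrix <- function(reference, regularize = TRUE, ridge = 1e-8) {
  reference <- as_config_matrix(reference)
  k <- nrow(reference)
  if (k < 3L) stop("bending energy needs at least 3 reference points")
  if (k == 3L) return(matrix(0, 3L, 3L))  # three points admit only affine warps
  sys <- tps_system(reference, regularize, ridge)
  B <- sys$Linv[seq_len(k), seq_len(k)]
  (B + t(B)) / 2
}

#' Total bending energy of a deformation
#'
#' Sum over both coordinate axes of the quadratic form `t(d) B d`, where
#' `d` is the displacement from the reference to the target.
#'
#' @param B bending-energy matrix of the reference.
#' @param reference,target `k x 2` matrices.
#' @return a non-negative scalar.
#' @export
bending_energy <- function(B, reference, target) {
  d <- target - reference
  as.numeric(crossprod(d[, 1L], B %*% d[, 1L]) +
             crossprod(d[, 2L], B %*% d[, 2L]))
}

#' Thin-plate-spline interpolating warp
#'
#' Computes the TPS warp taking every reference point exactly onto its
#' target point, decomposed into an affine part and non-affine kernel
#' weights satisfying the usual side conditions (weights orthogonal to 1,
#' x, y).
#'
#' @param reference,target `k x 2` matrices with equal `k`.
#' @param regularize,ridge see [bending_energy_matrix()].
#' @return an object of class `tps_warp` with fields `reference`,
#'   `affine_part` (3 x 2: rows 1, x, y), `nonaffine_weights` (k x 2).
#'   Apply it to new points with [predict.tps_warp()].
#' @export
tps_warp <- function(reference, target, regularize = TRUE, ridge = 1e-8) {
  reference <- as_config_matrix(reference); target <- as_config_matrix(target)
  if (nrow(reference) != nrow(target)) stop("point counts differ")
  k <- nrow(reference)
  sys <- tps_system(reference, regularize, ridge)
  rhs <- rbind(target, matrix(0, 3L, 2L))
  coefs <- sys$Linv %*% rhs
  structure(list(reference = reference,
                 nonaffine_weights = coefs[seq_len(k), , drop = FALSE],
                 affine_part = coefs[k + (1:3), , drop = FALSE]),
            class = "tps_warp")
}

#' Evaluate a thin-plate-spline warp at new points
#'
#' @param object a [tps_warp()].
#' @param newdata `m x 2` matrix of points to map (default: the reference
#'   points, which reproduce the target).
#' @param ... unused.
#' @return an `m x 2` matrix of warped coordinates.
#' @export
predict.tps_warp <- function(object, newdata = object$reference, ...) {
  newdata <- as_config_matrix(newdata)
  cbind(1, newdata) %*% object$affine_part +
    tps_kernel(newdata, object$reference) %*% object$nonaffine_weights
}
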