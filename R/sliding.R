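## minimum-norm solution of the symmetric PSD system A t = rhs, dropping
## eigendirections below rtol * max eigenvalue
pinv_solve <- function(A, rhs, rtol = 1e-7) {
  e <- eigen(A, symmetric = TRUE)
  keep <- e$values > rtol * max(e$values, 0)
  if (!any(keep)) return(rep(0, length(rhs)))
  V <- e$vectors[, keep, drop = FALSE]
  as.numeric(V %*% ((crossprod(V, rhs)) / e$values[keep]))
}

#' One bending-energy sliding pass over an aligned ensemble
#'
#' For every specimen, displaces each sliding semilandmark `i` by `t_i u_i`
#' along the unit chord `u_i` between its `before`/`after` neighbors (a
#' one-sided chord at curve ends), choosing the displacement vector `t`
#' that minimizes the TPS bending energy of the deformation from the
#' consensus to the displaced specimen — a single closed-form linear solve
#' per specimen. Non-slider points are untouched, and the displaced
#' configurations are returned without re-superimposition.
#'
#' @param ensemble a `gpa_fit` from [gpa()].
#' @param scheme a [point_scheme()] whose indices refer to the ensemble's
#'   points; must contain at least one slider.
#' @param B optional precomputed bending-energy matrix of the consensus.
#' @return a list with `coords` (displaced `k x 2 x n` array),
#'   `displacements` (`n x m` signed sliding amounts), `energy_before`,
#'   `energy_after` (per-specimen bending energies against the consensus).
#' @export
slide_once <- function(ensemble, scheme, B = NULL) {
  stopifnot(inherits(ensemble, "gpa_fit"), inherits(scheme, "point_scheme"))
  triples <- scheme$slider_triples
  m <- nrow(triples)
  if (m == 0L) stop("scheme has no sliders")
  coords <- ensemble$aligned
  C <- ensemble$consensus
  k <- dim(coords)[1L]; n <- dim(coords)[3L]
  if (k != scheme$n_points)
    stop("scheme is for ", scheme$n_points, " points but ensemble has ", k)
  if (is.null(B)) B <- bending_energy_matrix(C)
  sl <- triples[, "slider"]
  disp <- matrix(0, n, m)
  e_before <- e_after <- numeric(n)
  for (s in seq_len(n)) {
    X <- coords[, , s]
    ## tangents: chord between neighbors on the specimen's own outline;
    ## before == after encodes a one-sided chord to the single neighbor
    one_sided <- triples[, "before"] == triples[, "after"]
    chord <- X[triples[, "after"], , drop = FALSE] -
             X[triples[, "before"], , drop = FALSE]
    if (any(one_sided))
      chord[one_sided, ] <- X[triples[one_sided, "after"], , drop = FALSE] -
                            X[sl[one_sided], , drop = FALSE]
    len <- sqrt(rowSums(chord^2))
    if (any(len == 0))
      stop("zero-length tangent chord for slider ",
           paste(sl[len == 0], collapse = ", "), " in specimen ",
           if (!is.null(ensemble$specimen_id)) ensemble$specimen_id[s] else s)
    u <- chord / len
    dx <- X[, 1L] - C[, 1L]; dy <- X[, 2L] - C[, 2L]
    e_before[s] <- as.numeric(crossprod(dx, B %*% dx) + crossprod(dy, B %*% dy))
    Bss <- B[sl, sl, drop = FALSE]
    A <- Bss * tcrossprod(u[, 1L]) + Bss * tcrossprod(u[, 2L])
    rhs <- -(u[, 1L] * (B %*% dx)[sl] + u[, 2L] * (B %*% dy)[sl])
    ## Combinations of tangent moves that approximate affine displacement
    ## fields lie in the near-null space of A (affine fields carry no
    ## bending energy), so a plain solve amplifies noise along them; the
    ## truncated pseudo-inverse takes the minimum-norm minimizer instead.
    t_amt <- pinv_solve(A, rhs, rtol = 1e-7)
    disp[s, ] <- t_amt
    X[sl, ] <- X[sl, ] + t_amt * u
    coords[, , s] <- X
    dx <- X[, 1L] - C[, 1L]; dy <- X[, 2L] - C[, 2L]
    e_after[s] <- as.numeric(crossprod(dx, B %*% dx) + crossprod(dy, B %*% dy))
  }
  list(coords = coords, displacements = disp,
       energy_before = e_before, energy_after = e_after)
}

#' Slide semilandmarks to convergence
#'
#' Alternates a bending-energy sliding pass with generalized Procrustes
#' re-superimposition (recomputing the consensus), which removes the
#' arbitrary initial spacing of points along the outline curve. The outer
#' loop is a monotone descent on the ensemble's total bending energy: an
#' iteration is accepted only if the energy (summed over specimens against
#' the updated consensus) decreases, so the energy trace is non-increasing
#' by construction; the loop stops when the RMS slider movement drops below
#' `tol`, when no energy-decreasing pass exists, or at `max_iter`. With no
#' sliders in the scheme the result is exactly the plain GPA fit.
#'
#' @param x a [landmark_set()], coordinate array, or an existing `gpa_fit`.
#' @param scheme a [point_scheme()].
#' @param tol RMS slider movement tolerance in shape units (default 1e-6).
#' @param max_iter maximum sliding iterations (default 10); non-convergence
#'   gives a flagged result (`converged = FALSE`) with the movement trace.
#' @param gpa_tol,gpa_max_iter tolerances of the inner GPA.
#' @return an object of class `slide_fit`: `ensemble` (final `gpa_fit` of
#'   the slid coordinates), `displacements` (last accepted pass),
#'   `movement_trace`, `bending_energy_trace` (total bending energy against
#'   the consensus after each accepted pass; non-increasing), `iterations`
#'   (accepted passes), `converged`, `stop_reason` (`"movement"`,
#'   `"energy"` or `"max_iter"`).
#' @export
slide_until_converged <- function(x, scheme, tol = 1e-6, max_iter = 10L,
                                  gpa_tol = 1e-8, gpa_max_iter = 100L) {
  stopifnot(inherits(scheme, "point_scheme"))
  fit <- if (inherits(x, "gpa_fit")) x
         else gpa(x, tol = gpa_tol, max_iter = gpa_max_iter)
  if (nrow(scheme$slider_triples) == 0L) {
    return(structure(list(ensemble = fit,
                          displacements = matrix(0, dim(fit$aligned)[3L], 0L),
                          movement_trace = numeric(0),
                          bending_energy_trace = numeric(0),
                          iterations = 0L, converged = TRUE),
                     class = "slide_fit"))
  }
  total_energy <- function(f) {
    B <- bending_energy_matrix(f$consensus)
    s <- 0
    for (i in seq_len(dim(f$aligned)[3L]))
      s <- s + bending_energy(B, f$consensus, f$aligned[, , i])
    s
  }
  movement <- energy <- numeric(0)
  e_prev <- total_energy(fit)
  iter <- 0L; stop_reason <- "max_iter"; disp <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- slide_once(fit, scheme)
    rms <- sqrt(mean(step$displacements^2))
    candidate <- gpa(step$coords, tol = gpa_tol, max_iter = gpa_max_iter)
    e_new <- total_energy(candidate)
    ## monotone acceptance: a pass must lower the ensemble bending energy
    ## (measured against the re-superimposed consensus); otherwise the
    ## previous state is already the loop's minimizer and iteration stops
    if (e_new >= e_prev) { iter <- iter - 1L; stop_reason <- "energy"; break }
    fit <- candidate
    disp <- step$displacements
    movement <- c(movement, rms)
    energy <- c(energy, e_new)
    e_prev <- e_new
    if (rms < tol) { stop_reason <- "movement"; break }
  }
  converged <- stop_reason != "max_iter"
  if (!converged)
    warning("semilandmark sliding reached max_iter = ", max_iter,
            " while still improving (last RMS movement ",
            signif(movement[length(movement)], 3), ")")
  if (is.null(disp))
    disp <- matrix(0, dim(fit$aligned)[3L], nrow(scheme$slider_triples))
  structure(list(ensemble = fit, displacements = disp,
                 movement_trace = movement, bending_energy_trace = energy,
                 iterations = iter, converged = converged,
                 stop_reason = stop_reason),
            class = "slide_fit")
}

#' @export
print.slide_fit <- function(x, ...) {
  cat("slide_fit:", x$iterations, "sliding iterations,",
      if (x$converged) "converged" else "NOT converged", "\n")
  if (length(x$bending_energy_trace))
    cat("  bending energy trace:",
        paste(signif(x$bending_energy_trace, 4), collapse = " -> "), "\n")
  print(x$ensemble)
  invisible(x)
}
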