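#' Landmark configuration set
#'
#' A `landmark_set` holds digitized point configurations for a sample of
#' photographs: a `k x 2 x n` coordinate array (points in anatomical order,
#' caudal to rostral along the dorsum) together with per-photograph
#' identifiers and optional scale factors (units per pixel).
#'
#' Coordinates are stored y-up: larger y means dorsally higher. Image files
#' digitized with a y-down pixel convention should be read with
#' `flip_y = TRUE` in [read_tps()].
#'
#' @param coords a `k x 2 x n` numeric array, a single `k x 2` matrix, or a
#'   list of `k x 2` matrices sharing `k`.
#' @param specimen_id character vector of length `n`; defaults to
#'   `spec_1 ... spec_n`.
#' @param image_name optional character vector of source image names.
#' @param scale optional numeric vector of positive scale factors.
#' @param mirrored logical vector flagging configurations that have been
#'   mirrored about their centroid to normalize facing direction.
#' @return an object of class `landmark_set` with elements `coords`
#'   (`k x 2 x n`), `info` (data frame of per-specimen identifiers).
#' @export
landmark_set <- function(coords, specimen_id = NULL, image_name = NULL,
                         scale = NULL, mirrored = NULL) {
  if (is.list(coords) && !is.array(coords)) {
    ks <- vapply(coords, nrow, integer(1))
    if (length(unique(ks)) > 1L)
      stop("all configurations must share the same number of points; found k = ",
           paste(unique(ks), collapse = ", "))
    coords <- array(unlist(coords), dim = c(ks[1L], 2L, length(ks)))
  }
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[2L] == 2L)
  k <- dim(coords)[1L]; n <- dim(coords)[3L]
  if (k < 3L) stop("a landmark configuration needs at least 3 points, got ", k)
  if (!all(is.finite(coords))) stop("non-finite coordinates in landmark set")
  if (is.null(specimen_id)) specimen_id <- paste0("spec_", seq_len(n))
  if (anyDuplicated(specimen_id)) stop("duplicated specimen_id values")
  if (!is.null(scale) && any(!is.na(scale) & scale <= 0))
    stop("scale factors must be positive")
  info <- data.frame(
    specimen_id = as.character(specimen_id),
    image_name  = if (is.null(image_name)) NA_character_ else as.character(image_name),
    scale       = if (is.null(scale)) NA_real_ else as.numeric(scale),
    mirrored    = if (is.null(mirrored)) FALSE else as.logical(mirrored),
    stringsAsFactors = FALSE
  )
  dimnames(coords) <- list(NULL, c("x", "y"), info$specimen_id)
  structure(list(coords = coords, info = info), class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  d <- dim(x$coords)
  cat("landmark_set:", d[3L], "configurations of", d[1L], "points (2D)\n")
  if (any(x$info$mirrored)) cat("  mirrored:", sum(x$info$mirrored), "\n")
  invisible(x)
}

#' Number of landmarks / specimens in a landmark set
#' @param x a `landmark_set`.
#' @return integer count.
#' @export
n_landmarks <- function(x) dim(x$coords)[1L]

#' @rdname n_landmarks
#' @export
n_specimens <- function(x) dim(x$coords)[3L]

#' Mirror configurations about their centroid
#'
#' Reflects the x coordinate of selected configurations about the
#' configuration centroid so that all specimens face the same direction
#' (photographs taken from the "wrong" side are horizontally turned).
#' Mirroring twice restores the original coordinates exactly.
#'
#' @param x a `landmark_set`.
#' @param which specimen indices or `specimen_id` values to mirror; default
#'   all.
#' @return the modified `landmark_set`, with the `mirrored` flag toggled.
#' @export
mirror_configs <- function(x, which = seq_len(n_specimens(x))) {
  stopifnot(inherits(x, "landmark_set"))
  if (is.character(which)) which <- match(which, x$info$specimen_id)
  if (anyNA(which)) stop("unknown specimen_id in 'which'")
  for (i in which) {
    cx <- mean(x$coords[, 1L, i])
    x$coords[, 1L, i] <- 2 * cx - x$coords[, 1L, i]
  }
  x$info$mirrored[which] <- !x$info$mirrored[which]
  x
}

## internal: coerce a landmark_set / array / list to a k x 2 x n array
as_coords_array <- function(x) {
  if (inherits(x, "landmark_set")) return(x$coords)
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  if (is.matrix(x)) return(array(x, dim = c(dim(x), 1L)))
  if (is.list(x)) return(landmark_set(x)$coords)
  stop("cannot interpret input as landmark coordinates")
}
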