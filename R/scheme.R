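#' Point schemes: landmark / semilandmark roles along the dorsal outline
#'
#' A `point_scheme` describes how the digitized points of a configuration are
#' treated by a shape-analysis method: which points are fixed anatomical
#' landmarks, which are sliding semilandmarks (and between which neighbors
#' each slides), which points are excluded from the analysis, the named
#' subsets of the outline (full dorsum, croup+back, neck+head), and the
#' three-point angle used to remove the neck articulation.
#'
#' Slider triples are `(before, slider, after)` index triples: the slider's
#' tangent is the chord between its `before` and `after` neighbors. An
#' endpoint slider uses a one-sided chord, encoded by `before == after` (the
#' single neighbor).
#'
#' @param n_points number of digitized points per configuration.
#' @param roles character vector of length `n_points` with entries
#'   `"landmark"`, `"slider"` or `"excluded"` (excluded points are digitized
#'   but dropped by the method, as in the 9-landmark scheme).
#' @param slider_triples integer matrix with columns `before`, `slider`,
#'   `after`; one row per slider. Defaults to chords between immediate
#'   neighbors along the outline for every slider role.
#' @param subsets named list of index vectors. Defaults to
#'   `dorsum = 1:n`, `croup_back = 1:ceiling(n/2)`,
#'   `neck_head = ceiling(n/2):n`.
#' @param derotation_triple integer triple `(ray_a, vertex, ray_b)` defining
#'   the croup/back-to-neck angle that derotation fixes; default
#'   `(1, ceiling(n/2), n)`.
#' @param method_name short name of the method variant.
#' @return a validated object of class `point_scheme`.
#' @seealso [builtin_scheme()], [load_scheme()]
#' @export
point_scheme <- function(n_points, roles, slider_triples = NULL,
                         subsets = NULL, derotation_triple = NULL,
                         method_name = "custom") {
  n_points <- as.integer(n_points)
  stopifnot(n_points >= 3L, length(roles) == n_points)
  roles <- as.character(roles)
  bad_role <- setdiff(unique(roles), c("landmark", "slider", "excluded"))
  if (length(bad_role))
    stop("unknown point role(s): ", paste(bad_role, collapse = ", "),
         " (allowed: landmark, slider, excluded)")
  sliders <- which(roles == "slider")
  if (is.null(slider_triples)) slider_triples <- default_triples(roles)
  if (length(sliders) == 0L) {
    slider_triples <- matrix(integer(0), 0L, 3L)
  } else {
    slider_triples <- matrix(as.integer(slider_triples), ncol = 3L)
  }
  colnames(slider_triples) <- c("before", "slider", "after")
  mid <- ceiling(n_points / 2)
  if (is.null(subsets))
    subsets <- list(dorsum = seq_len(n_points),
                    croup_back = seq_len(mid),
                    neck_head = mid:n_points)
  if (is.null(derotation_triple)) derotation_triple <- c(1L, mid, n_points)
  derotation_triple <- as.integer(derotation_triple)

  ## validation
  tri_mid <- slider_triples[, "slider"]
  if (anyDuplicated(tri_mid))
    stop("scheme validation: duplicate slider index in triples: ",
         paste(tri_mid[duplicated(tri_mid)], collapse = ", "))
  if (!setequal(tri_mid, sliders))
    stop("scheme validation: every slider role must appear in exactly one ",
         "triple as the middle element (sliders ",
         paste(setdiff(sliders, tri_mid), collapse = ", "), " missing)")
  if (any(slider_triples < 1L | slider_triples > n_points))
    stop("scheme validation: slider triple index out of range 1..", n_points)
  bad <- slider_triples[, "before"] == tri_mid | slider_triples[, "after"] == tri_mid
  if (any(bad))
    stop("scheme validation: triple neighbors must differ from the slider ",
         "index (offending sliders: ", paste(tri_mid[bad], collapse = ", "), ")")
  for (nm in names(subsets)) {
    idx <- subsets[[nm]]
    if (any(idx < 1L | idx > n_points))
      stop("scheme validation: subset '", nm, "' outside 1..", n_points)
  }
  if (length(derotation_triple) != 3L || anyDuplicated(derotation_triple) ||
      any(derotation_triple < 1L | derotation_triple > n_points))
    stop("scheme validation: derotation triple must be 3 distinct indices in 1..",
         n_points)
  structure(list(n_points = n_points, roles = roles,
                 slider_triples = slider_triples, subsets = subsets,
                 derotation_triple = derotation_triple,
                 method_name = method_name),
            class = "point_scheme")
}

#' @export
print.point_scheme <- function(x, ...) {
  cat("point_scheme '", x$method_name, "': ", x$n_points, " points (",
      sum(x$roles == "landmark"), " landmarks, ",
      sum(x$roles == "slider"), " sliders",
      if (any(x$roles == "excluded"))
        paste0(", ", sum(x$roles == "excluded"), " excluded") else "",
      ")\n", sep = "")
  cat("  derotation triple:", paste(x$derotation_triple, collapse = "-"),
      "| subsets:", paste(names(x$subsets), collapse = ", "), "\n")
  invisible(x)
}

## default triples: each slider slides on the chord between its outline
## neighbors; endpoint sliders get a one-sided chord (before == after).
default_triples <- function(roles) {
  n <- length(roles)
  sliders <- which(roles == "slider")
  if (length(sliders) == 0L) return(matrix(integer(0), 0L, 3L))
  active <- which(roles != "excluded")
  t(vapply(sliders, function(s) {
    pos <- match(s, active)
    before <- if (pos > 1L) active[pos - 1L] else active[pos + 1L]
    after  <- if (pos < length(active)) active[pos + 1L] else active[pos - 1L]
    c(before, s, after)
  }, integer(3)))
}

#' Built-in analysis schemes for the 30-point dorsal outline
#'
#' Three method variants over the standard 30-point caudal-to-rostral
#' digitization of the upper body outline:
#' \describe{
#'   \item{`landmarks`}{9 anatomical landmarks only (the 7 body marks, the
#'     medial eye canthus and the middle of the neck upline); the remaining
#'     21 outline points are excluded.}
#'   \item{`mixed`}{8 landmarks (7 marks + eye canthus) and the 22 other
#'     outline points as sliding semilandmarks.}
#'   \item{`ssl`}{only the eye canthus fixed; the 29 other points slide.}
#' }
#' The default anatomical template places the marks at indices 1 (first
#' coccygeal vertebra), 5 (lumbo-sacral junction), 9 (thoraco-lumbar
#' junction), 15 (tenth thoracic vertebra, the low point of the withers and
#' the articulation vertex), 22 (atlas), 27 (temporo-mandibular joint) and
#' 30 (rostral facial crest), with the eye canthus at 28 and the mid-neck
#' point at 18. Index assignments are conventions of this template and are
#' fully configurable through scheme files.
#'
#' @param name one of `"landmarks"`, `"mixed"`, `"ssl"`.
#' @param n_points digitization size (default 30).
#' @return a [point_scheme()].
#' @export
builtin_scheme <- function(name = c("landmarks", "mixed", "ssl"),
                           n_points = 30L) {
  name <- match.arg(name)
  if (n_points != 30L)
    stop("built-in schemes are defined for the 30-point digitization")
  marks <- c(1L, 5L, 9L, 15L, 22L, 27L, 30L)  # the 7 clay marks
  eye <- 28L; mid_neck <- 18L
  roles <- rep("slider", 30L)
  roles[switch(name,
               landmarks = c(marks, eye, mid_neck),
               mixed = c(marks, eye),
               ssl = eye)] <- "landmark"
  if (name == "landmarks") roles[roles == "slider"] <- "excluded"
  point_scheme(30L, roles, method_name = name)
}

#' Load a point scheme from a YAML file
#'
#' The scheme file lists either a full per-point `roles` vector or a
#' `landmarks` index list (remaining points become sliders), plus optional
#' `slider_triples`, `subsets` (index ranges as `[from, to]` pairs or index
#' vectors), `derotation_triple` and `method_name`. Built-in scheme names are
#' also accepted in place of a path.
#'
#' @param path path to a YAML scheme file, or a built-in scheme name.
#' @return a validated [point_scheme()].
#' @export
load_scheme <- function(path) {
  if (path %in% c("landmarks", "mixed", "ssl")) return(builtin_scheme(path))
  if (!file.exists(path)) stop("scheme file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$n_points)) stop("scheme file must declare n_points")
  n <- as.integer(y$n_points)
  if (!is.null(y$roles)) {
    roles <- as.character(y$roles)
  } else if (!is.null(y$landmarks)) {
    roles <- rep("slider", n)
    roles[as.integer(y$landmarks)] <- "landmark"
    if (!is.null(y$excluded)) roles[as.integer(y$excluded)] <- "excluded"
  } else stop("scheme file must provide 'roles' or 'landmarks'")
  triples <- if (!is.null(y$slider_triples))
    do.call(rbind, lapply(y$slider_triples, as.integer))
  subsets <- if (!is.null(y$subsets)) {
    lapply(y$subsets, function(s) {
      s <- as.integer(unlist(s))
      if (length(s) == 2L && s[2L] > s[1L] + 1L) seq(s[1L], s[2L]) else s
    })
  }
  point_scheme(n, roles, slider_triples = triples, subsets = subsets,
               derotation_triple = if (!is.null(y$derotation_triple))
                 as.integer(y$derotation_triple),
               method_name = if (!is.null(y$method_name)) y$method_name
                             else sub("\\.[^.]*$", "", basename(path)))
}

#' Restrict a scheme (and optionally coordinates) to a named subset
#'
#' Selects the scheme's active points (non-excluded roles) within a named
#' subset and re-indexes roles, slider triples and the derotation triple to
#' the restricted configuration. Sliders whose `before`/`after` neighbor
#' falls outside the subset get a one-sided chord to the surviving neighbor;
#' a slider with no surviving neighbor becomes a landmark.
#'
#' @param scheme a [point_scheme()].
#' @param subset a subset name in `scheme$subsets` or an index vector.
#' @return a list with `scheme` (restricted [point_scheme()]) and `indices`
#'   (the source indices retained, in order).
#' @export
restrict_scheme <- function(scheme, subset = "dorsum") {
  stopifnot(inherits(scheme, "point_scheme"))
  idx <- if (is.character(subset)) {
    if (!subset %in% names(scheme$subsets))
      stop("unknown subset '", subset, "'; available: ",
           paste(names(scheme$subsets), collapse = ", "))
    scheme$subsets[[subset]]
  } else as.integer(subset)
  keep <- idx[scheme$roles[idx] != "excluded"]
  if (length(keep) < 3L) stop("subset retains fewer than 3 active points")
  new_index <- match(seq_len(scheme$n_points), keep)  # source -> local
  roles <- scheme$roles[keep]
  triples <- scheme$slider_triples
  new_triples <- NULL
  for (r in seq_len(nrow(triples))) {
    s <- new_index[triples[r, "slider"]]
    if (is.na(s)) next
    b <- new_index[triples[r, "before"]]
    a <- new_index[triples[r, "after"]]
    if (is.na(b) && is.na(a)) { roles[s] <- "landmark"; next }
    if (is.na(b)) b <- a
    if (is.na(a)) a <- b
    new_triples <- rbind(new_triples, c(b, s, a))
  }
  dt <- new_index[scheme$derotation_triple]
  sub_scheme <- point_scheme(
    length(keep), roles, slider_triples = new_triples,
    subsets = list(all = seq_along(keep)),
    derotation_triple = if (!anyNA(dt)) dt else c(1L, 2L, 3L),
    method_name = scheme$method_name)
  sub_scheme$derotation_valid <- !anyNA(dt)
  list(scheme = sub_scheme, indices = keep)
}

#' Export slider triples as a tpsUtil-style sliders file
#'
#' Writes three integer columns (`before`, `slide`, `after`), one row per
#' slider, as used by tps-family sliding tools.
#'
#' @param scheme a [point_scheme()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sliders_file <- function(scheme, path) {
  stopifnot(inherits(scheme, "point_scheme"))
  utils::write.table(scheme$slider_triples, path, row.names = FALSE,
                     col.names = c("before", "slide", "after"), quote = FALSE)
  invisible(path)
}
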