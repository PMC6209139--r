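#' Read a TPS landmark file
#'
#' Parses the plain-text landmark format produced by the tpsDig family of
#' digitizing tools: each record starts with an `LM=<k>` line, followed by
#' `k` whitespace-separated `x y` coordinate lines, optionally followed by
#' `IMAGE=`, `ID=` and `SCALE=` lines. Keys are matched case-insensitively;
#' unknown keys are skipped with a warning (tps-family files vary).
#'
#' Coordinates are interpreted y-up. Files digitized in an image (y-down)
#' convention can be converted on read with `flip_y = TRUE`, which negates y
#' about each configuration's centroid.
#'
#' @param path path to a TPS file.
#' @param flip_y logical; flip the y axis of every configuration on read.
#' @param mirror specimen ids or indices to mirror about their centroid (see
#'   [mirror_configs()]), for photographs facing the wrong way.
#' @return a [landmark_set()].
#' @export
read_tps <- function(path, flip_y = FALSE, mirror = NULL) {
  if (!file.exists(path)) stop("TPS file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  recs <- list(); rec_no <- 0L
  i <- 1L; n_lines <- length(lines)
  unknown <- character(0)
  while (i <= n_lines) {
    if (!nzchar(lines[i])) { i <- i + 1L; next }
    m <- regmatches(lines[i], regexec("^[Ll][Mm]=\\s*([0-9]+)\\s*$", lines[i]))[[1L]]
    if (length(m) == 0L)
      stop("TPS parse error at line ", i, ": expected an LM= record header, got '",
           lines[i], "'")
    k <- as.integer(m[2L]); rec_no <- rec_no + 1L
    i <- i + 1L
    pts <- matrix(NA_real_, k, 2L)
    for (j in seq_len(k)) {
      if (i > n_lines || grepl("=", lines[i], fixed = TRUE))
        stop("TPS parse error: record ", rec_no, " declares LM=", k,
             " but has only ", j - 1L, " coordinate lines")
      xy <- suppressWarnings(as.numeric(strsplit(lines[i], "[ \t,]+")[[1L]]))
      if (length(xy) != 2L || anyNA(xy))
        stop("TPS parse error at line ", i, ": non-numeric coordinate '",
             lines[i], "' in record ", rec_no)
      pts[j, ] <- xy
      i <- i + 1L
    }
    meta <- list(image = NA_character_, id = NA_character_, scale = NA_real_)
    while (i <= n_lines && nzchar(lines[i]) &&
           grepl("=", lines[i], fixed = TRUE) &&
           !grepl("^[Ll][Mm]=", lines[i])) {
      kv <- regmatches(lines[i], regexec("^([A-Za-z_]+)=(.*)$", lines[i]))[[1L]]
      key <- toupper(kv[2L]); val <- trimws(kv[3L])
      if (key == "IMAGE") meta$image <- val
      else if (key == "ID") meta$id <- val
      else if (key == "SCALE") {
        sc <- suppressWarnings(as.numeric(val))
        if (is.na(sc) || sc <= 0)
          stop("TPS parse error at line ", i, ": invalid SCALE '", val, "'")
        meta$scale <- sc
      } else unknown <- c(unknown, key)
      i <- i + 1L
    }
    recs[[rec_no]] <- list(points = pts, meta = meta)
  }
  if (length(unknown))
    warning("ignored unknown TPS keys: ", paste(unique(unknown), collapse = ", "))
  if (length(recs) == 0L) stop("TPS file contains no records: ", path)
  ks <- vapply(recs, function(r) nrow(r$points), integer(1))
  if (length(unique(ks)) > 1L)
    stop("TPS records have differing point counts: ", paste(unique(ks), collapse = ", "))
  ids <- vapply(recs, function(r) r$meta$id, character(1))
  if (all(is.na(ids))) ids <- paste0("spec_", seq_along(recs))
  else ids[is.na(ids)] <- paste0("spec_", which(is.na(ids)))
  ls <- landmark_set(
    coords = lapply(recs, `[[`, "points"),
    specimen_id = ids,
    image_name = vapply(recs, function(r) r$meta$image, character(1)),
    scale = vapply(recs, function(r) r$meta$scale, numeric(1))
  )
  if (flip_y) {
    for (s in seq_len(n_specimens(ls))) {
      cy <- mean(ls$coords[, 2L, s])
      ls$coords[, 2L, s] <- 2 * cy - ls$coords[, 2L, s]
    }
  }
  if (!is.null(mirror)) ls <- mirror_configs(ls, mirror)
  ls
}

#' Write a TPS landmark file
#'
#' Emits one `LM=` record per configuration with coordinates at fixed
#' 6-decimal precision, followed by `IMAGE=`, `ID=` and `SCALE=` lines when
#' present, so that `read_tps(write_tps(x))` returns the input coordinates
#' within 1e-6 and the byte layout is stable across runs.
#'
#' @param x a [landmark_set()] (or coercible coordinates).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(x, path) {
  if (is.list(x) && !inherits(x, "landmark_set") && length(x) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  if (!inherits(x, "landmark_set")) x <- landmark_set(x)
  con <- file(path, open = "wt")
  on.exit(close(con))
  k <- n_landmarks(x)
  for (s in seq_len(n_specimens(x))) {
    writeLines(paste0("LM=", k), con)
    writeLines(sprintf("%.6f %.6f", x$coords[, 1L, s], x$coords[, 2L, s]), con)
    if (!is.na(x$info$image_name[s]))
      writeLines(paste0("IMAGE=", x$info$image_name[s]), con)
    writeLines(paste0("ID=", x$info$specimen_id[s]), con)
    if (!is.na(x$info$scale[s]))
      writeLines(sprintf("SCALE=%.6f", x$info$scale[s]), con)
  }
  invisible(path)
}
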