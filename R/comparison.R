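## Internal: run one GM pipeline variant on one context's photographs.
## Steps: (optional derotation of the raw 30-point configurations to a
## common reference angle) -> restriction to the scheme's active points
## within the requested subset -> GPA -> semilandmark sliding if the
## restricted scheme has sliders -> shape PCA.
run_variant <- function(coords, scheme, subset = "dorsum",
                        derotate = FALSE, reference_angle = NULL,
                        gpa_tol = 1e-8, slide_tol = 1e-6,
                        slide_max_iter = 10L) {
  coords <- as_coords_array(coords)
  ref_angle <- NULL
  if (derotate) {
    dr <- derotate_set(coords, scheme$derotation_triple, reference_angle)
    coords <- dr$coords
    ref_angle <- dr$reference_angle
  }
  rs <- restrict_scheme(scheme, subset)
  sub_coords <- coords[rs$indices, , , drop = FALSE]
  slid <- slide_until_converged(sub_coords, rs$scheme, tol = slide_tol,
                                max_iter = slide_max_iter, gpa_tol = gpa_tol)
  ensemble <- slid$ensemble
  ensemble$derotated <- derotate
  ensemble$reference_angle <- ref_angle
  pca <- shape_pca(ensemble)
  list(ensemble = ensemble, sliding = slid, pca = pca,
       indices = rs$indices, reference_angle = ref_angle)
}

## Internal: expand requested variants into a definition table
variant_grid <- function(schemes, subsets, derotate) {
  der_opts <- switch(as.character(derotate)[1L],
                     "both" = c(FALSE, TRUE),
                     "TRUE" = TRUE, "on" = TRUE,
                     "FALSE" = FALSE, "off" = FALSE,
                     stop("derotate must be TRUE, FALSE, 'on', 'off' or 'both'"))
  expand.grid(scheme = schemes, subset = subsets, derotate = der_opts,
              stringsAsFactors = FALSE)
}

#' Compare GM method variants by mixed-ANOVA discrimination
#'
#' Runs every requested method variant (scheme x outline subset x
#' derotation choice) on the same photographs, separately per context, and
#' extracts the mixed-ANOVA F statistic and p-value of the fixed factor for
#' each retained principal component (components explaining at least
#' `threshold` percent of variance, capped at `max_pcs`). The F values rank
#' the variants by how sharply they discriminate the populations.
#'
#' A failed variant (e.g. a degenerate subset) contributes flagged rows
#' with `NA` statistics and a diagnostic message instead of aborting the
#' table.
#'
#' @param x a [landmark_set()], coordinate array, or `posture_sim`.
#' @param metadata photograph-level data frame (ignored when `x` is a
#'   `posture_sim`); must contain `horse_id`, `context` and the fixed
#'   factor.
#' @param schemes character vector of scheme names (built-in or paths) or a
#'   list of [point_scheme()] objects.
#' @param subsets outline subset names (default `"dorsum"`).
#' @param derotate `FALSE`, `TRUE` or `"both"`.
#' @param contexts contexts to analyze separately.
#' @param factor fixed factor column name (default `"school"`).
#' @param threshold PC retention threshold in percent.
#' @param max_pcs maximum number of PCs analyzed per variant (default 3).
#' @param anova_method passed to [fit_mixed_anova()].
#' @param ... tolerances passed to the pipeline (`gpa_tol`, `slide_tol`,
#'   `slide_max_iter`).
#' @return a `method_comparison` data frame with one row per
#'   method x subset x derotation x context x PC: columns `method`,
#'   `subset`, `derotated`, `context`, `pc`, `percent_variance`, `factor`,
#'   `F`, `p`, `df_num`, `df_den`, `n_obs`, `n_individuals`, `note`.
#' @export
method_comparison_table <- function(x, metadata = NULL,
                                    schemes = c("landmarks", "mixed", "ssl"),
                                    subsets = "dorsum", derotate = FALSE,
                                    contexts = c("standing", "walking"),
                                    factor = "school", threshold = 10,
                                    max_pcs = 3L,
                                    anova_method = "lmm", ...) {
  if (inherits(x, "posture_sim")) {
    metadata <- x$metadata
    x <- x$landmarks
  }
  coords <- as_coords_array(x)
  if (is.null(metadata)) stop("metadata required")
  if (dim(coords)[3L] != nrow(metadata))
    stop("metadata rows (", nrow(metadata), ") do not match configurations (",
         dim(coords)[3L], ")")
  scheme_objs <- resolve_schemes(schemes)
  grid <- variant_grid(names(scheme_objs), subsets, derotate)
  contexts <- intersect(contexts, unique(metadata$context))
  if (length(contexts) == 0L) stop("no requested context present in metadata")
  rows <- list()
  for (v in seq_len(nrow(grid))) {
    sch <- scheme_objs[[grid$scheme[v]]]
    for (ctx in contexts) {
      in_ctx <- metadata$context == ctx
      md <- metadata[in_ctx, , drop = FALSE]
      res <- tryCatch(
        run_variant(coords[, , in_ctx, drop = FALSE], sch,
                    subset = grid$subset[v], derotate = grid$derotate[v], ...),
        error = function(e) e)
      base <- data.frame(method = grid$scheme[v], subset = grid$subset[v],
                         derotated = grid$derotate[v], context = ctx,
                         stringsAsFactors = FALSE)
      if (inherits(res, "error")) {
        rows[[length(rows) + 1L]] <- cbind(
          base, pc = NA_integer_, percent_variance = NA_real_,
          factor = factor, F = NA_real_, p = NA_real_, df_num = NA_real_,
          df_den = NA_real_, n_obs = sum(in_ctx), n_individuals = NA_integer_,
          note = paste("failed:", conditionMessage(res)))
        next
      }
      pcs <- utils::head(retained_components(res$pca, threshold), max_pcs)
      for (pc in pcs) {
        an <- tryCatch(
          fit_mixed_anova(res$pca$scores[, pc], md, factor,
                          method = anova_method),
          error = function(e) e)
        rows[[length(rows) + 1L]] <- if (inherits(an, "error")) cbind(
          base, pc = pc, percent_variance = res$pca$percent_variance[pc],
          factor = factor, F = NA_real_, p = NA_real_, df_num = NA_real_,
          df_den = NA_real_, n_obs = nrow(md), n_individuals = NA_integer_,
          note = paste("failed:", conditionMessage(an)))
        else cbind(
          base, pc = pc, percent_variance = res$pca$percent_variance[pc],
          an, note = "")
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("method_comparison", "data.frame")
  out
}

## Internal: accept scheme names, paths or point_scheme objects
resolve_schemes <- function(schemes) {
  if (inherits(schemes, "point_scheme")) schemes <- list(schemes)
  if (is.character(schemes)) {
    objs <- lapply(schemes, load_scheme)
    names(objs) <- schemes
  } else {
    objs <- schemes
    if (is.null(names(objs)))
      names(objs) <- vapply(objs, `[[`, "", "method_name")
  }
  if (anyDuplicated(names(objs)))
    names(objs) <- make.unique(names(objs))
  objs
}

#' Identity-parameter ANOVA table
#'
#' For one method variant, tests each identity covariate (equid type,
#' proportion class, sex as categorical factors; age as a single-df
#' continuous covariate) on each retained PC, per context — the analogue of
#' the study's identity-parameter tables. Constant factors are skipped with
#' a warning.
#'
#' @param x,metadata as in [method_comparison_table()].
#' @param scheme one scheme name or [point_scheme()].
#' @param factors identity covariate columns to test.
#' @param subset,derotate,contexts,threshold,max_pcs,anova_method,... as in
#'   [method_comparison_table()].
#' @return a `method_comparison` data frame (one row per
#'   factor x PC x context).
#' @export
identity_parameter_table <- function(x, metadata = NULL, scheme = "ssl",
                                     factors = c("equid_type", "proportion",
                                                 "age", "sex"),
                                     subset = "dorsum", derotate = FALSE,
                                     contexts = c("standing", "walking"),
                                     threshold = 10, max_pcs = 3L,
                                     anova_method = "lmm", ...) {
  if (inherits(x, "posture_sim")) {
    metadata <- x$metadata
    x <- x$landmarks
  }
  coords <- as_coords_array(x)
  sch <- resolve_schemes(scheme)[[1L]]
  contexts <- intersect(contexts, unique(metadata$context))
  rows <- list()
  for (ctx in contexts) {
    in_ctx <- metadata$context == ctx
    md <- metadata[in_ctx, , drop = FALSE]
    res <- run_variant(coords[, , in_ctx, drop = FALSE], sch,
                       subset = subset, derotate = derotate, ...)
    pcs <- utils::head(retained_components(res$pca, threshold), max_pcs)
    for (fac in factors) {
      vals <- md[[fac]]
      if (length(unique(vals)) < 2L) {
        warning("identity factor '", fac, "' is constant in context ", ctx,
                "; skipped")
        next
      }
      for (pc in pcs) {
        an <- fit_mixed_anova(res$pca$scores[, pc], md, fac,
                              method = anova_method)
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(method = sch$method_name, subset = subset,
                     derotated = derotate, context = ctx,
                     stringsAsFactors = FALSE),
          pc = pc, percent_variance = res$pca$percent_variance[pc],
          an, note = "")
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("method_comparison", "data.frame")
  out
}
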