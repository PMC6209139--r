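#' Run the full method-comparison experiment
#'
#' One-command orchestration: loads (or simulates) the photographs and
#' covariates, runs every requested method variant per context
#' (derotation, GPA, semilandmark sliding, shape PCA), fits the
#' mixed-model ANOVAs, and writes a report bundle to `out_dir`:
#' \itemize{
#'   \item `variance_table.csv` — percent variance of the first PCs per
#'     variant and context;
#'   \item `anova_table.csv` — F / p per variant, context, PC for the
#'     population factor;
#'   \item `identity_table.csv` — identity-parameter ANOVAs (when
#'     requested);
#'   \item `grids/` — deformation-grid node coordinates for the retained-PC
#'     extremes of each variant;
#'   \item `manifest.json` — seed, tolerances, convergence flags and every
#'     file written;
#'   \item `run.log` — plain-text log of parameters and convergence.
#' }
#' Outputs are deterministic: rerunning with the same configuration and
#' seed reproduces the CSVs byte for byte.
#'
#' @param config a named list (or path to a YAML file) with entries:
#'   `tps` and `metadata` input paths (omit both to simulate), `simulate`
#'   (list of [simulation_params()] arguments), `schemes`, `subsets`,
#'   `derotate` (`"on"`, `"off"` or `"both"`), `contexts`, `factor`,
#'   `threshold`, `max_pcs`, `identity_factors`, `grid_density`, `seed`,
#'   `out_dir`.
#' @return invisibly, a list with the tables and the manifest.
#' @export
run_method_comparison <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(list(
    tps = NULL, metadata = NULL, simulate = list(),
    schemes = c("landmarks", "mixed", "ssl"), subsets = "dorsum",
    derotate = "off", contexts = c("standing", "walking"),
    factor = "school", threshold = 10, max_pcs = 3L,
    identity_factors = NULL, grid_density = 24L,
    seed = 1L, out_dir = "posturegm_report"), config)

  problems <- character(0)
  if (!is.null(cfg$tps) && !file.exists(cfg$tps))
    problems <- c(problems, paste("TPS file not found:", cfg$tps))
  if (!is.null(cfg$metadata) && !file.exists(cfg$metadata))
    problems <- c(problems, paste("covariate table not found:", cfg$metadata))
  if (xor(is.null(cfg$tps), is.null(cfg$metadata)))
    problems <- c(problems, "provide both 'tps' and 'metadata', or neither")
  scheme_objs <- tryCatch(resolve_schemes(cfg$schemes), error = function(e) {
    problems <<- c(problems, conditionMessage(e)); NULL
  })
  if (length(problems))
    stop("configuration invalid:\n  - ", paste(problems, collapse = "\n  - "))

  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  grids_dir <- file.path(cfg$out_dir, "grids")
  dir.create(grids_dir, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "run.log")
  log_lines <- c(sprintf("posturegm %s method comparison",
                         as.character(utils::packageVersion("posturegm"))),
                 sprintf("seed: %d", cfg$seed),
                 sprintf("threshold: %s%%  max_pcs: %d",
                         format(cfg$threshold), cfg$max_pcs))

  if (is.null(cfg$tps)) {
    sim_args <- cfg$simulate
    sim_args$seed <- cfg$seed
    params <- do.call(simulation_params, sim_args)
    dataset <- sample_dataset(params)
    lm_set <- dataset$landmarks
    metadata <- dataset$metadata
    log_lines <- c(log_lines, sprintf(
      "simulated dataset: %d schools x %d horses x (%d standing + %d walking)",
      params$n_schools, params$horses_per_school, params$photos_standing,
      params$photos_walking))
  } else {
    lm_set <- read_tps(cfg$tps)
    covars <- read_metadata_table(cfg$metadata)
    info <- specimen_keys(lm_set$info$specimen_id)
    metadata <- join_metadata(cbind(lm_set$info["specimen_id"], info), covars)
    log_lines <- c(log_lines, sprintf("loaded %d configurations from %s",
                                      n_specimens(lm_set), cfg$tps))
  }

  anova_tab <- method_comparison_table(
    lm_set, metadata, schemes = scheme_objs, subsets = cfg$subsets,
    derotate = cfg$derotate, contexts = cfg$contexts, factor = cfg$factor,
    threshold = cfg$threshold, max_pcs = cfg$max_pcs)

  var_tab <- unique(anova_tab[!is.na(anova_tab$pc),
                              c("method", "subset", "derotated", "context",
                                "pc", "percent_variance")])
  files <- character(0)
  write_det_csv <- function(df, name) {
    p <- file.path(cfg$out_dir, name)
    df <- as.data.frame(lapply(df, function(col)
      if (is.numeric(col)) signif(col, 12) else col))
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    files <<- c(files, name)
    p
  }
  write_det_csv(var_tab, "variance_table.csv")
  write_det_csv(as.data.frame(anova_tab), "anova_table.csv")

  if (!is.null(cfg$identity_factors)) {
    id_tab <- identity_parameter_table(
      lm_set, metadata, scheme = scheme_objs[[1L]],
      factors = cfg$identity_factors, subset = cfg$subsets[[1L]],
      derotate = identical(cfg$derotate, "on"), contexts = cfg$contexts,
      threshold = cfg$threshold, max_pcs = cfg$max_pcs)
    write_det_csv(as.data.frame(id_tab), "identity_table.csv")
  }

  ## deformation grids at the observed score extremes of each retained PC,
  ## per variant and context
  grid <- variant_grid(names(scheme_objs), cfg$subsets, cfg$derotate)
  convergence <- list()
  for (v in seq_len(nrow(grid))) {
    for (ctx in intersect(cfg$contexts, unique(metadata$context))) {
      in_ctx <- metadata$context == ctx
      tag <- sprintf("%s_%s_%s_%s", grid$scheme[v], grid$subset[v],
                     if (grid$derotate[v]) "derot" else "raw", ctx)
      res <- tryCatch(
        run_variant(as_coords_array(lm_set)[, , in_ctx, drop = FALSE],
                    scheme_objs[[grid$scheme[v]]], subset = grid$subset[v],
                    derotate = grid$derotate[v]),
        error = function(e) e)
      if (inherits(res, "error")) {
        log_lines <- c(log_lines, sprintf("variant %s FAILED: %s", tag,
                                          conditionMessage(res)))
        next
      }
      convergence[[tag]] <- list(
        gpa_iterations = res$ensemble$iterations,
        gpa_converged = res$ensemble$converged,
        sliding_iterations = res$sliding$iterations,
        sliding_converged = res$sliding$converged,
        reference_angle = res$reference_angle)
      log_lines <- c(log_lines, sprintf(
        "variant %s: GPA %d it (%s), sliding %d it (%s)", tag,
        res$ensemble$iterations,
        if (res$ensemble$converged) "converged" else "NOT converged",
        res$sliding$iterations,
        if (res$sliding$converged) "converged" else "NOT converged"))
      pcs <- utils::head(retained_components(res$pca, cfg$threshold),
                         cfg$max_pcs)
      for (pc in pcs) {
        for (side in c("min", "max")) {
          sc <- if (side == "min") min(res$pca$scores[, pc])
                else max(res$pca$scores[, pc])
          shp <- pc_extreme_shape(res$pca, pc, sc)
          g <- deformation_grid(res$pca$consensus, shp,
                                grid_density = cfg$grid_density)
          name <- file.path("grids", sprintf("%s_pc%d_%s.csv", tag, pc, side))
          write_grid_csv(g, file.path(cfg$out_dir, name),
                         id = sprintf("pc%d_%s", pc, side))
          files <- c(files, name)
        }
      }
    }
  }

  manifest <- list(
    package = "posturegm",
    version = as.character(utils::packageVersion("posturegm")),
    seed = cfg$seed,
    factor = cfg$factor, threshold = cfg$threshold, max_pcs = cfg$max_pcs,
    schemes = names(scheme_objs), subsets = cfg$subsets,
    derotate = cfg$derotate, contexts = cfg$contexts,
    tolerances = list(gpa_tol = 1e-8, slide_tol = 1e-6, slide_max_iter = 10),
    convergence = convergence,
    files = c(files, "manifest.json", "run.log"))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, log_path)
  invisible(list(anova_table = anova_tab, variance_table = var_tab,
                 manifest = manifest, out_dir = cfg$out_dir))
}

## Internal: recover horse_id / context from simulated specimen ids of the
## form <horse>_<context>_<photo>
specimen_keys <- function(specimen_id) {
  m <- regmatches(specimen_id,
                  regexec("^(.*)_(standing|walking)_([0-9]+)$", specimen_id))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad))
    stop("cannot parse horse/context from specimen id(s): ",
         paste(utils::head(specimen_id[bad], 3L), collapse = ", "),
         " (expected <horse>_<standing|walking>_<photo>)")
  data.frame(horse_id = vapply(m, `[`, "", 2L),
             context = vapply(m, `[`, "", 3L),
             stringsAsFactors = FALSE)
}
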