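## Controlled vocabularies for the covariate table.
.meta_levels <- list(
  context = c("standing", "walking"),
  equid_type = c("pony", "horse"),
  proportion = c("dolichomorphic", "mesomorphic", "brachymorphic")
)

#' Read the specimen covariate table
#'
#' Reads a delimited table (CSV by default) with one row per horse and
#' context, columns `horse_id`, `school`, `context`, `sex`, `age`,
#' `equid_type`, `proportion`. Categorical columns are validated against
#' controlled vocabularies: `context` in standing/walking, `equid_type` in
#' pony/horse, `proportion` in dolichomorphic/mesomorphic/brachymorphic.
#' `age` must be numeric (years) and non-negative. Numbers use a decimal
#' point. Landmark configurations join to this table by `horse_id` +
#' `context`.
#'
#' @param path path to the covariate file.
#' @param sep field separator (default `","`).
#' @return a data frame of validated covariates.
#' @export
read_metadata_table <- function(path, sep = ",") {
  if (!file.exists(path)) stop("covariate table not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  required <- c("horse_id", "school", "context", "sex", "age",
                "equid_type", "proportion")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("covariate table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) {
    warning("covariate table is empty: ", path)
    return(df)
  }
  for (col in names(.meta_levels)) {
    bad <- !df[[col]] %in% .meta_levels[[col]]
    if (any(bad))
      stop("invalid ", col, " value(s) '",
           paste(unique(df[[col]][bad]), collapse = "', '"),
           "' (allowed: ", paste(.meta_levels[[col]], collapse = ", "), ")")
  }
  age_num <- suppressWarnings(as.numeric(df$age))
  if (anyNA(age_num))
    stop("non-numeric age value at row(s) ",
         paste(which(is.na(age_num)), collapse = ", "))
  if (any(age_num < 0)) stop("negative age values are not allowed")
  df$age <- age_num
  key <- paste(df$horse_id, df$context, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate horse_id + context rows: ",
         paste(unique(df$horse_id[duplicated(key)]), collapse = ", "))
  df
}

#' Join photograph-level specimens to the covariate table
#'
#' @param info data frame with at least `horse_id` and `context` columns
#'   (one row per photograph).
#' @param metadata covariate table from [read_metadata_table()].
#' @return `info` with the covariate columns appended.
#' @export
join_metadata <- function(info, metadata) {
  key_i <- paste(info$horse_id, info$context, sep = "\r")
  key_m <- paste(metadata$horse_id, metadata$context, sep = "\r")
  idx <- match(key_i, key_m)
  if (anyNA(idx))
    stop("photograph(s) with no covariate row: ",
         paste(unique(info$horse_id[is.na(idx)]), collapse = ", "))
  cols <- setdiff(names(metadata), c("horse_id", "context"))
  cbind(info, metadata[idx, cols, drop = FALSE], row.names = NULL)
}
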