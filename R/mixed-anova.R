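#' Mixed-model ANOVA of PC scores with individual as a random factor
#'
#' Fits a random-intercept model `score ~ fixed_factor + (1 | individual)`
#' by restricted maximum likelihood (via \pkg{lme4}) and reports the Wald F
#' statistic for the fixed factor with a containment-style denominator
#' degrees of freedom `n_individuals - (df_num + 1)` — for a between-animal
#' factor with repeated photographs per animal this matches the classical
#' F test on per-animal means in balanced designs (available directly as
#' `method = "horse_means"`, a cross-check mode). Numeric covariates (e.g.
#' age in years) are treated as single-df continuous terms.
#'
#' @param scores numeric vector, one value (e.g. a PC score) per
#'   photograph.
#' @param metadata data frame aligned with `scores`, containing the fixed
#'   factor column and the random-factor column.
#' @param fixed_factor name of the fixed-effect column.
#' @param random_factor name of the individual (grouping) column, default
#'   `"horse_id"`.
#' @param method `"lmm"` (REML random-intercept fit) or `"horse_means"`
#'   (one-way ANOVA on per-individual mean scores; requires the fixed
#'   factor to be constant within individuals).
#' @return a one-row data frame: `factor`, `F`, `p`, `df_num`, `df_den`,
#'   `n_obs`, `n_individuals`.
#' @export
fit_mixed_anova <- function(scores, metadata, fixed_factor,
                            random_factor = "horse_id",
                            method = c("lmm", "horse_means")) {
  method <- match.arg(method)
  if (!fixed_factor %in% names(metadata))
    stop("fixed factor '", fixed_factor, "' not in metadata")
  if (!random_factor %in% names(metadata))
    stop("random factor '", random_factor, "' not in metadata")
  if (length(scores) != nrow(metadata))
    stop("scores and metadata lengths differ")
  fx <- metadata[[fixed_factor]]
  horse <- as.factor(metadata[[random_factor]])
  if (anyNA(fx) || anyNA(horse) || anyNA(scores))
    stop("missing values in scores or factors")
  continuous <- is.numeric(fx)
  if (!continuous) {
    fx <- droplevels(as.factor(fx))
    if (nlevels(fx) < 2L)
      stop("fixed factor '", fixed_factor, "' has a single level")
    per_level <- tapply(horse, fx, function(h) length(unique(h)))
    if (any(per_level < 2L))
      warning("factor level(s) with fewer than 2 individuals: ",
              paste(names(per_level)[per_level < 2L], collapse = ", "))
  } else if (stats::var(fx) == 0)
    stop("continuous covariate '", fixed_factor, "' is constant")
  q <- if (continuous) 1L else nlevels(fx) - 1L
  n_ind <- nlevels(droplevels(horse))
  df_den <- n_ind - (q + 1L)
  if (df_den < 1L)
    stop("singular fit: fewer individuals (", n_ind,
         ") than fixed-effect levels")
  dat <- data.frame(.score = scores, .fx = fx, .horse = horse)
  if (method == "horse_means" ||
      all(tapply(scores, horse, length) == 1L)) {
    varies <- any(tapply(as.character(dat$.fx), dat$.horse,
                         function(v) length(unique(v))) > 1L)
    if (varies)
      stop("fixed factor varies within individuals; use method = 'lmm'")
    agg <- stats::aggregate(.score ~ .horse + .fx, dat, mean)
    fit <- stats::lm(.score ~ .fx, agg)
    an <- stats::anova(fit)
    Fv <- an$`F value`[1L]
    pv <- stats::pf(Fv, q, df_den, lower.tail = FALSE)
  } else {
    fit <- suppressMessages(
      lme4::lmer(.score ~ .fx + (1 | .horse), data = dat, REML = TRUE,
                 control = lme4::lmerControl(calc.derivs = FALSE)))
    b <- lme4::fixef(fit)
    V <- as.matrix(stats::vcov(fit))
    idx <- which(names(b) != "(Intercept)")
    bq <- b[idx]
    Fv <- as.numeric(crossprod(bq, solve(V[idx, idx, drop = FALSE], bq))) / q
    pv <- stats::pf(Fv, q, df_den, lower.tail = FALSE)
  }
  data.frame(factor = fixed_factor, F = Fv, p = pv,
             df_num = q, df_den = df_den,
             n_obs = length(scores), n_individuals = n_ind,
             stringsAsFactors = FALSE)
}

#' Pearson correlation coefficient
#'
#' Sample Pearson correlation between two numeric vectors, with input
#' validation (at least three pairs, neither vector constant).
#'
#' @param x,y numeric vectors of equal length.
#' @return a scalar in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("constant input: correlation undefined")
  stats::cor(x, y, method = "pearson")
}
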