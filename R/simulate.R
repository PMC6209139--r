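#' Simulation parameters for synthetic dorsal-outline datasets
#'
#' Defaults mirror the sampling design of the riding-school study: 11
#' schools, 8 horses per school (the study's median), 10 photographs per
#' horse standing motionless and 20 hand walking. Shape scales are in body
#' lengths (the template body axis has length 1): the group effect is a
#' localized smooth bump whose per-school amplitude spans
#' `+/- amplitude`; the horse random effect perturbs the croup, back and
#' neck regions; the neck-rotation nuisance rotates all points distal to
#' the withers vertex by a Normal(0, `neck_rotation_sd` degrees) angle per
#' photograph; digitization noise is i.i.d. Gaussian per coordinate.
#'
#' @param n_schools number of schools (populations).
#' @param horses_per_school horses per school.
#' @param photos_standing,photos_walking photographs per horse per context.
#' @param group_effect list with `region` (one of croup/back/withers/neck)
#'   and `amplitude` (body lengths); amplitude 0 disables group structure.
#' @param horse_sd per-horse random shape effect scale (body lengths).
#' @param neck_rotation_sd per-photograph neck rotation SD in degrees.
#' @param digitization_sd coordinate noise SD (body lengths).
#' @param walking_neck_drop deterministic neck-lowering rotation (degrees)
#'   applied in the walking context.
#' @param n_points outline points per configuration.
#' @param seed integer seed; the dataset is fully reproducible from it.
#' @return a validated list of class `simulation_params`.
#' @export
simulation_params <- function(n_schools = 11L, horses_per_school = 8L,
                              photos_standing = 10L, photos_walking = 20L,
                              group_effect = list(region = "back",
                                                  amplitude = 0.03),
                              horse_sd = 0.015, neck_rotation_sd = 15,
                              digitization_sd = 0.005,
                              walking_neck_drop = 10,
                              n_points = 30L, seed = 1L) {
  p <- list(n_schools = as.integer(n_schools),
            horses_per_school = as.integer(horses_per_school),
            photos_standing = as.integer(photos_standing),
            photos_walking = as.integer(photos_walking),
            group_effect = group_effect, horse_sd = horse_sd,
            neck_rotation_sd = neck_rotation_sd,
            digitization_sd = digitization_sd,
            walking_neck_drop = walking_neck_drop,
            n_points = as.integer(n_points), seed = as.integer(seed))
  if (p$n_schools < 1L || p$horses_per_school < 1L)
    stop("need at least one school and one horse")
  if (p$photos_standing + p$photos_walking < 1L)
    stop("need at least one photograph per horse")
  scales <- c(p$horse_sd, p$neck_rotation_sd, p$digitization_sd,
              group_effect$amplitude)
  if (any(scales < 0)) stop("all scale parameters must be >= 0")
  if (!group_effect$region %in% names(.outline_regions))
    stop("unknown effect region '", group_effect$region, "'; regions: ",
         paste(names(.outline_regions), collapse = ", "))
  structure(p, class = "simulation_params")
}

## named index regions of the 30-point outline (scaled for other n)
.outline_regions <- list(croup = c(1, 7), back = c(6, 14),
                         withers = c(13, 17), neck = c(17, 27))

#' Outline indices of a named anatomical region
#'
#' @param region one of `"croup"`, `"back"`, `"withers"`, `"neck"`.
#' @param n_points outline size (regions scale proportionally from the
#'   30-point template).
#' @return an integer index vector.
#' @export
region_indices <- function(region, n_points = 30L) {
  if (!region %in% names(.outline_regions))
    stop("unknown region '", region, "'; regions: ",
         paste(names(.outline_regions), collapse = ", "))
  rng <- round(.outline_regions[[region]] * n_points / 30)
  seq(max(1L, rng[1L]), min(n_points, rng[2L]))
}

## smooth raised-cosine bump over an index range, peak 1 at the center
region_bump <- function(region, n_points = 30L) {
  idx <- region_indices(region, n_points)
  w <- numeric(n_points)
  t <- seq_along(idx) / (length(idx) + 1)
  w[idx] <- (1 - cos(2 * pi * t)) / 2
  w
}

## closed-form dorsal height profile of the body section, s in [0, 1]
## (tail to withers): croup rise, back hollow, withers peak as Gaussian
## bumps on a flat baseline.
dorsal_profile <- function(s, croup_height = 0.10, back_depth = 0.05,
                           withers_height = 0.08) {
  croup_height * exp(-((s - 1 / 7) / 0.10)^2) -
    back_depth * exp(-((s - 4 / 7) / 0.18)^2) +
    withers_height * exp(-((s - 1) / 0.12)^2)
}

#' Template dorsal outline
#'
#' A smooth parametric profile of the upper body outline in anatomical
#' order (caudal to rostral): the body section (tail to withers — croup
#' rise, back hollow, withers peak) runs along the x axis with unit length,
#' and the neck/head section articulates at the withers vertex
#' (`ceiling(n/2)`), rising at `neck_angle` and easing into a flatter head
#' segment. The derotation triple `(1, vertex, n)` is geometrically
#' meaningful on this template.
#'
#' @param n_points outline points (at least 9, default 30).
#' @param croup_height,back_depth,withers_height body profile amplitudes
#'   (body lengths).
#' @param neck_angle,head_angle section headings in degrees.
#' @param neck_length,head_length section lengths (body lengths).
#' @return a `k x 2` coordinate matrix with attribute `"vertex"` (the
#'   articulation index).
#' @export
make_template_outline <- function(n_points = 30L, croup_height = 0.10,
                                  back_depth = 0.05, withers_height = 0.08,
                                  neck_angle = 50, head_angle = -10,
                                  neck_length = 0.55, head_length = 0.18) {
  n_points <- as.integer(n_points)
  if (n_points < 9L)
    stop("need at least 9 points to place croup, back, withers, neck and head")
  n_body <- ceiling(n_points / 2)
  n_neck <- n_points - n_body
  s <- seq(0, 1, length.out = n_body)
  body <- cbind(x = s, y = dorsal_profile(s, croup_height, back_depth,
                                          withers_height))
  ## neck/head: equal steps along a heading that eases from neck_angle to
  ## head_angle over the last (head) quarter of the section
  total <- neck_length + head_length
  hf <- head_length / total
  t <- seq_len(n_neck) / n_neck
  blend <- pmin(1, pmax(0, (t - (1 - hf - 0.1)) / 0.2))
  blend <- blend^2 * (3 - 2 * blend)          # smoothstep
  psi <- (1 - blend) * neck_angle + blend * head_angle
  psi <- psi * pi / 180
  step <- total / n_neck
  neck <- cbind(x = body[n_body, 1L] + cumsum(step * cos(psi)),
                y = body[n_body, 2L] + cumsum(step * sin(psi)))
  out <- rbind(body, neck)
  dimnames(out) <- list(NULL, c("x", "y"))
  attr(out, "vertex") <- n_body
  out
}

#' Sample a synthetic photograph dataset
#'
#' Generates one configuration per photograph:
#' template + school shape offset + per-horse random shape effect +
#' context effect (walking lowers the neck by a fixed rotation) +
#' per-photograph neck rotation nuisance (rigid rotation of all points
#' distal to the withers vertex) + i.i.d. digitization noise. Covariates
#' (sex, age, equid type, proportion class) are sampled per horse with
#' probabilities echoing the study population (50:35 geldings:mares, ages
#' 7-20 with mean 13) and carry no shape effect unless injected. Fully
#' reproducible from `params$seed`.
#'
#' @param params a [simulation_params()].
#' @return a list of class `posture_sim`: `landmarks` (a [landmark_set()]),
#'   `metadata` (photograph-level data frame: `specimen_id`, `horse_id`,
#'   `school`, `context`, `photo`, `sex`, `age`, `equid_type`,
#'   `proportion`), `template`, `params`.
#' @export
sample_dataset <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(params$seed)
  k <- params$n_points
  template <- make_template_outline(k)
  vertex <- attr(template, "vertex")
  ns <- params$n_schools; nh <- params$horses_per_school
  n_photos_per_horse <- params$photos_standing + params$photos_walking
  n <- ns * nh * n_photos_per_horse

  ## deterministic per-school effect coefficients spanning [-1, 1]
  school_coef <- if (ns > 1L) seq(-1, 1, length.out = ns) else 0
  ge <- params$group_effect
  group_bump <- region_bump(ge$region, k)

  horse_bumps <- cbind(region_bump("croup", k), region_bump("back", k),
                       region_bump("neck", k))
  contexts <- rep(c("standing", "walking"),
                  c(params$photos_standing, params$photos_walking))

  coords <- array(NA_real_, c(k, 2L, n))
  meta <- vector("list", n)
  idx <- 0L; horse_no <- 0L
  for (s in seq_len(ns)) {
    school_template <- template
    school_template[, 2L] <- school_template[, 2L] +
      ge$amplitude * school_coef[s] * group_bump
    for (h in seq_len(nh)) {
      horse_no <- horse_no + 1L
      horse_id <- sprintf("s%02d_h%02d", s, h)
      z <- stats::rnorm(3L)
      horse_template <- school_template
      horse_template[, 2L] <- horse_template[, 2L] +
        params$horse_sd * as.numeric(horse_bumps %*% z)
      sex <- sample(c("gelding", "mare"), 1L, prob = c(50, 35))
      age <- min(20L, max(7L, as.integer(round(stats::rnorm(1L, 13, 3.5)))))
      equid_type <- sample(c("pony", "horse"), 1L, prob = c(0.4, 0.6))
      proportion <- sample(c("dolichomorphic", "mesomorphic", "brachymorphic"),
                           1L, prob = c(0.15, 0.65, 0.20))
      counter <- c(standing = 0L, walking = 0L)
      for (ph in seq_along(contexts)) {
        ctx <- contexts[ph]
        counter[ctx] <- counter[ctx] + 1L
        cfg <- horse_template
        rot <- stats::rnorm(1L, 0, params$neck_rotation_sd) * pi / 180
        if (ctx == "walking") rot <- rot - params$walking_neck_drop * pi / 180
        if (rot != 0)
          cfg <- rotate_about(cfg, vertex, (vertex + 1L):k, rot)
        cfg <- cfg + matrix(stats::rnorm(2L * k, 0, params$digitization_sd),
                            k, 2L)
        idx <- idx + 1L
        coords[, , idx] <- cfg
        meta[[idx]] <- data.frame(
          specimen_id = sprintf("%s_%s_%02d", horse_id, ctx, counter[ctx]),
          horse_id = horse_id, school = sprintf("school%02d", s),
          context = ctx, photo = counter[ctx],
          sex = sex, age = age, equid_type = equid_type,
          proportion = proportion, stringsAsFactors = FALSE)
      }
    }
  }
  metadata <- do.call(rbind, meta)
  lm <- landmark_set(coords, specimen_id = metadata$specimen_id)
  structure(list(landmarks = lm, metadata = metadata, template = template,
                 params = params),
            class = "posture_sim")
}

#' @export
print.posture_sim <- function(x, ...) {
  cat("posture_sim:", nrow(x$metadata), "photographs,",
      length(unique(x$metadata$horse_id)), "horses,",
      length(unique(x$metadata$school)), "schools\n")
  invisible(x)
}

#' Inject a known group effect into a dataset
#'
#' Adds a localized smooth dorsal bump of the given amplitude to every
#' photograph of the designated schools, confined exactly to the region's
#' outline indices — a recoverable population signal for validating
#' discrimination.
#'
#' @param dataset a `posture_sim` from [sample_dataset()].
#' @param effect_region one of `"croup"`, `"back"`, `"withers"`, `"neck"`.
#' @param amplitude bump height (body lengths); 0 leaves the dataset
#'   unchanged.
#' @param schools school labels to modify; default the upper half.
#' @return the modified dataset.
#' @export
inject_known_groups <- function(dataset, effect_region, amplitude,
                                schools = NULL) {
  stopifnot(inherits(dataset, "posture_sim"))
  k <- n_landmarks(dataset$landmarks)
  bump <- amplitude * region_bump(effect_region, k)
  if (is.null(schools)) {
    all_schools <- sort(unique(dataset$metadata$school))
    from <- min(length(all_schools), ceiling(length(all_schools) / 2) + 1L)
    schools <- all_schools[from:length(all_schools)]
  }
  hit <- which(dataset$metadata$school %in% schools)
  for (i in hit)
    dataset$landmarks$coords[, 2L, i] <- dataset$landmarks$coords[, 2L, i] + bump
  dataset
}

#' Meta-only convenience: horse-by-context covariate table of a simulation
#'
#' Collapses the photograph-level metadata of a [sample_dataset()] result
#' to one row per horse and context, the layout read back by
#' [read_metadata_table()].
#'
#' @param dataset a `posture_sim`.
#' @return a data frame with columns `horse_id`, `school`, `context`,
#'   `sex`, `age`, `equid_type`, `proportion`.
#' @export
covariate_table <- function(dataset) {
  stopifnot(inherits(dataset, "posture_sim"))
  md <- dataset$metadata
  unique(md[, c("horse_id", "school", "context", "sex", "age",
                "equid_type", "proportion")])
}
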