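test_that("the template outline is anatomically ordered and well formed", {
  tpl <- make_template_outline()
  expect_equal(dim(tpl), c(30L, 2L))
  vertex <- attr(tpl, "vertex")
  expect_equal(vertex, 15L)
  # strictly increasing x from tail to withers
  expect_true(all(diff(tpl[1:vertex, 1]) > 0))
  expect_true(is.finite(centroid_size(tpl)) && centroid_size(tpl) > 0)
  # body heights follow the generator's closed-form profile
  s <- seq(0, 1, length.out = vertex)
  expect_equal(tpl[1:vertex, 2], posturegm:::dorsal_profile(s),
               tolerance = 1e-9)
  # neck rises from the withers vertex
  expect_gt(tpl[30, 2], tpl[vertex, 2])
  expect_error(make_template_outline(8), "at least 9")
})

test_that("datasets are reproducible from the seed", {
  p <- simulation_params(n_schools = 3, horses_per_school = 2,
                         photos_standing = 2, photos_walking = 2, seed = 99)
  a <- sample_dataset(p)
  b <- sample_dataset(p)
  expect_identical(a$landmarks$coords, b$landmarks$coords)
  expect_identical(a$metadata, b$metadata)
  c <- sample_dataset(simulation_params(n_schools = 3, horses_per_school = 2,
                                        photos_standing = 2,
                                        photos_walking = 2, seed = 100))
  expect_false(identical(a$landmarks$coords, c$landmarks$coords))
})

test_that("with all noise off, standing photos equal the template", {
  p <- simulation_params(n_schools = 2, horses_per_school = 2,
                         photos_standing = 2, photos_walking = 2,
                         group_effect = list(region = "back", amplitude = 0),
                         horse_sd = 0, neck_rotation_sd = 0,
                         digitization_sd = 0, seed = 5)
  d <- sample_dataset(p)
  standing <- which(d$metadata$context == "standing")
  for (i in standing)
    expect_equal(d$landmarks$coords[, , i], unclass(d$template)[, ],
                 tolerance = 1e-12, ignore_attr = TRUE)
  # walking photos differ only distal to the articulation vertex
  walking <- which(d$metadata$context == "walking")[1]
  expect_equal(d$landmarks$coords[1:15, , walking], d$template[1:15, ],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_gt(max(abs(d$landmarks$coords[16:30, , walking] -
                    d$template[16:30, ])), 1e-3)
})

test_that("the neck-rotation nuisance has the requested angular spread", {
  p <- simulation_params(n_schools = 2, horses_per_school = 5,
                         photos_standing = 100, photos_walking = 0,
                         neck_rotation_sd = 15, seed = 42)
  d <- sample_dataset(p)
  ang <- measure_angle(d$landmarks, c(1, 15, 30))
  expect_lt(abs(circular_sd(ang) * 180 / pi - 15), 1)
})

test_that("the sampling design and covariates mirror the study layout", {
  d <- sample_dataset(simulation_params(seed = 3))
  md <- d$metadata
  expect_equal(nrow(md), 11 * 8 * 30)
  expect_equal(length(unique(md$school)), 11L)
  expect_equal(length(unique(md$horse_id)), 88L)
  counts <- table(md$context) / 88
  expect_equal(as.numeric(counts[c("standing", "walking")]), c(10, 20))
  expect_true(all(md$age >= 7 & md$age <= 20))
  expect_true(all(md$proportion %in% c("dolichomorphic", "mesomorphic",
                                       "brachymorphic")))
  # covariate table collapses to one row per horse x context and joins back
  cov <- covariate_table(d)
  expect_equal(nrow(cov), 88 * 2)
  joined <- join_metadata(md[, c("specimen_id", "horse_id", "context")], cov)
  expect_equal(nrow(joined), nrow(md))
})

test_that("group injection is confined to the region and scales distances", {
  p <- simulation_params(n_schools = 4, horses_per_school = 2,
                         photos_standing = 3, photos_walking = 0, seed = 8,
                         group_effect = list(region = "back", amplitude = 0))
  d0 <- sample_dataset(p)
  expect_identical(inject_known_groups(d0, "croup", 0)$landmarks$coords,
                   d0$landmarks$coords)
  d1 <- inject_known_groups(d0, "croup", 0.05)
  changed <- which(apply(d1$landmarks$coords != d0$landmarks$coords, 1, any))
  expect_true(all(changed <= 15))
  # doubling the amplitude increases mean between-group shape distance
  gdist <- function(d) {
    fit <- gpa(d$landmarks$coords)
    grp <- d$metadata$school %in% unique(d$metadata$school)[3:4]
    m1 <- apply(fit$aligned[, , grp], c(1, 2), mean)
    m2 <- apply(fit$aligned[, , !grp], c(1, 2), mean)
    sqrt(sum((m1 - m2)^2))
  }
  d2 <- inject_known_groups(d0, "croup", 0.10)
  expect_gt(gdist(d2), gdist(d1))
  expect_error(inject_known_groups(d0, "flank", 0.1), "croup")
})
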