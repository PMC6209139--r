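test_that("built-in schemes match the published method point counts", {
  ssl <- builtin_scheme("ssl")
  expect_equal(sum(ssl$roles == "landmark"), 1L)
  expect_equal(sum(ssl$roles == "slider"), 29L)
  mixed <- builtin_scheme("mixed")
  expect_equal(sum(mixed$roles == "landmark"), 8L)
  expect_equal(sum(mixed$roles == "slider"), 22L)
  lms <- builtin_scheme("landmarks")
  expect_equal(sum(lms$roles == "landmark"), 9L)
  expect_equal(sum(lms$roles == "excluded"), 21L)
  expect_equal(nrow(lms$slider_triples), 0L)
  # landmark + slider roles cover the full 30-point digitization for the
  # semilandmark methods
  for (s in list(ssl, mixed))
    expect_equal(sum(s$roles %in% c("landmark", "slider")), 30L)
  # every slider appears exactly once as a triple middle element
  for (s in list(ssl, mixed))
    expect_setequal(s$slider_triples[, "slider"], which(s$roles == "slider"))
  # shared anatomy: subsets and the 1-15-30 derotation triple
  expect_equal(ssl$derotation_triple, c(1L, 15L, 30L))
  expect_equal(ssl$subsets$croup_back, 1:15)
  expect_equal(ssl$subsets$neck_head, 15:30)
})

test_that("scheme validation rejects malformed slider triples", {
  roles <- c("landmark", rep("slider", 4), "landmark")
  expect_error(point_scheme(6, roles,
                            slider_triples = rbind(c(5, 5, 6), c(2, 3, 4),
                                                   c(3, 4, 5), c(1, 2, 3))),
               "differ from the slider")
  expect_error(point_scheme(6, roles,
                            slider_triples = rbind(c(1, 2, 3), c(2, 3, 4),
                                                   c(3, 4, 7), c(4, 5, 6))),
               "out of range")
  expect_error(point_scheme(6, roles,
                            slider_triples = rbind(c(1, 2, 3), c(1, 2, 4),
                                                   c(3, 4, 5), c(4, 5, 6))),
               "duplicate slider")
  expect_error(point_scheme(6, roles,
                            slider_triples = rbind(c(1, 2, 3), c(2, 3, 4))),
               "exactly one")
})

test_that("schemes load from YAML files", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "method_name: custom_neck",
    "n_points: 10",
    "landmarks: [1, 10]",
    "subsets:",
    "  dorsum: [1, 10]",
    "  front: [5, 10]",
    "derotation_triple: [1, 5, 10]"), path)
  sch <- load_scheme(path)
  expect_s3_class(sch, "point_scheme")
  expect_equal(sch$method_name, "custom_neck")
  expect_equal(sum(sch$roles == "slider"), 8L)
  expect_equal(sch$subsets$front, 5:10)
  expect_equal(sch$derotation_triple, c(1L, 5L, 10L))
  # built-in names pass through
  expect_equal(load_scheme("mixed")$method_name, "mixed")
  # invalid file errors
  writeLines(c("n_points: 5"), path)
  expect_error(load_scheme(path), "roles")
})

test_that("restricting a scheme to a subset re-indexes roles and triples", {
  ssl <- builtin_scheme("ssl")
  rs <- restrict_scheme(ssl, "croup_back")
  expect_equal(rs$indices, 1:15)
  expect_equal(rs$scheme$n_points, 15L)
  # slider 15 loses its rostral neighbor: one-sided chord (before == after)
  tr <- rs$scheme$slider_triples
  row15 <- tr[tr[, "slider"] == 15L, ]
  expect_equal(row15[["before"]], row15[["after"]])
  # landmarks scheme restricted to croup_back keeps the 4 caudal landmarks
  lrs <- restrict_scheme(builtin_scheme("landmarks"), "croup_back")
  expect_equal(lrs$indices, c(1L, 5L, 9L, 15L))
  expect_true(all(lrs$scheme$roles == "landmark"))
})

test_that("slider triples export as a three-column sliders file", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_sliders_file(builtin_scheme("mixed"), path)
  tab <- read.table(path, header = TRUE)
  expect_identical(names(tab), c("before", "slide", "after"))
  expect_equal(nrow(tab), 22L)
})

test_that("the shipped example scheme file loads and matches mixed counts", {
  path <- system.file("extdata", "scheme_example.yaml", package = "posturegm")
  sch <- load_scheme(path)
  expect_equal(sum(sch$roles == "landmark"), 8L)
  expect_equal(sum(sch$roles == "slider"), 22L)
  expect_equal(sch$derotation_triple, c(1L, 15L, 30L))
})
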