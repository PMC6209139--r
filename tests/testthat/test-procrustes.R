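test_that("centroid size matches its defining sum and is homogeneous", {
  sq <- matrix(c(0, 2, 2, 0, 0, 0, 2, 2), 4, 2)
  expect_equal(centroid_size(sq), 2 * sqrt(2))
  set.seed(5)
  x <- rand_config(30)
  # independent direct summation
  ctr <- c(mean(x[, 1]), mean(x[, 2]))
  direct <- sqrt(sum((x[, 1] - ctr[1])^2 + (x[, 2] - ctr[2])^2))
  expect_equal(centroid_size(x), direct, tolerance = 1e-12)
  expect_equal(centroid_size(3.7 * x), 3.7 * centroid_size(x))
  expect_error(centroid_size(matrix(1, 5, 2)), "coincident")
})

test_that("align_pair recovers exact similarity transforms", {
  set.seed(6)
  x <- rand_config(8)
  R90 <- matrix(c(0, 1, -1, 0), 2)
  y <- sweep(2 * x %*% t(R90), 2, c(3, -1), `+`)
  fit <- align_pair(x, y)
  expect_equal(fit$angle, pi / 2, tolerance = 1e-12)
  expect_equal(fit$scale, 2, tolerance = 1e-12)
  expect_equal(fit$rss, 0, tolerance = 1e-10)
  expect_equal(fit$aligned, y, tolerance = 1e-10, ignore_attr = TRUE)
  self <- align_pair(x, x)
  expect_equal(self$angle, 0)
  expect_equal(self$scale, 1)
  expect_equal(self$rss, 0, tolerance = 1e-12)
})

test_that("align_pair residual matches a rotation-grid search oracle", {
  set.seed(7)
  for (i in 1:5) {
    X <- rand_config(8); Y <- rand_config(8)
    expect_equal(align_pair(X, Y)$rss, brute_force_rss(X, Y),
                 tolerance = 1e-4)
  }
})

test_that("align_pair never reflects", {
  set.seed(8)
  x <- rand_config(10)
  y <- x; y[, 1] <- -y[, 1]           # mirrored target
  fit <- align_pair(x, y)
  # the recovered transform is a proper rotation, so a mirrored target
  # cannot be matched exactly
  expect_gt(fit$rss, 0.1)
  R <- matrix(c(cos(fit$angle), sin(fit$angle),
                -sin(fit$angle), cos(fit$angle)), 2)
  expect_equal(det(R), 1, tolerance = 1e-12)
})

test_that("GPA normalizes, averages and converges", {
  set.seed(9)
  base <- make_template_outline()
  coords <- noisy_ensemble(base, 12, sd = 0.01)
  fit <- gpa(coords)
  expect_true(fit$converged)
  k <- dim(fit$aligned)[1]
  for (s in seq_len(12)) {
    expect_lt(max(abs(colMeans(fit$aligned[, , s]))), 1e-9)
    expect_equal(sum(fit$aligned[, , s]^2), 1, tolerance = 1e-9)
  }
  # consensus is the renormalized coordinate-wise mean of the aligned shapes
  m <- apply(fit$aligned, c(1, 2), mean)
  expect_equal(fit$consensus, m / sqrt(sum(m^2)), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(sqrt(sum(fit$consensus^2)), 1, tolerance = 1e-6)
})

test_that("identical or similarity-equivalent configurations collapse", {
  set.seed(10)
  x <- rand_config(10)
  same <- gpa(array(rep(x, 4), dim = c(10, 2, 4)))
  for (s in 2:4)
    expect_equal(same$aligned[, , s], same$aligned[, , 1], tolerance = 1e-9)
  pair <- gpa(array(c(x, rand_similarity(x)), dim = c(10, 2, 2)))
  expect_equal(procrustes_distance(pair$aligned[, , 1], pair$aligned[, , 2]),
               0, tolerance = 1e-9)
})

test_that("GPA is invariant to similarity pre-transforms and input order", {
  set.seed(12)
  base <- make_template_outline()
  coords <- noisy_ensemble(base, 10, sd = 0.02)
  fit0 <- gpa(coords)
  moved <- coords
  for (s in 1:10) moved[, , s] <- rand_similarity(coords[, , s])
  fit1 <- gpa(moved)
  # aligned shapes agree up to one global rotation of the ensemble
  a <- align_pair(fit1$consensus, fit0$consensus)
  R <- matrix(c(cos(a$angle), sin(a$angle), -sin(a$angle), cos(a$angle)), 2)
  rms <- sqrt(mean((array(apply(fit1$aligned, 3, function(m) m %*% t(R)),
                          dim(fit1$aligned)) - fit0$aligned)^2))
  expect_lt(rms, 1e-8)
  shuf <- gpa(coords[, , sample(10)])
  expect_lt(procrustes_distance(shuf$consensus, fit0$consensus), 1e-8)
})

test_that("procrustes_distance is a metric on normalized shapes", {
  set.seed(13)
  a <- normalize_shape(rand_config(9))
  b <- normalize_shape(rand_config(9))
  expect_equal(procrustes_distance(a, a), 0)
  expect_equal(procrustes_distance(a, b), procrustes_distance(b, a),
               tolerance = 1e-12)
  for (i in 1:100) {
    x <- normalize_shape(rand_config(7))
    y <- normalize_shape(rand_config(7))
    z <- normalize_shape(rand_config(7))
    expect_lte(procrustes_distance(x, z),
               procrustes_distance(x, y) + procrustes_distance(y, z) + 1e-12)
  }
  expect_error(procrustes_distance(rand_config(9) + 5, b), "unit-size")
})
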