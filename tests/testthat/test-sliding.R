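# five-point open curve with a single slider at index 3
toy_scheme <- function() {
  point_scheme(5, c("landmark", "landmark", "slider", "landmark", "landmark"),
               slider_triples = rbind(c(2L, 3L, 4L)))
}

toy_fit <- function(consensus, specimens) {
  structure(list(aligned = specimens, consensus = consensus,
                 centroid_sizes = rep(1, dim(specimens)[3]),
                 iterations = 0L, final_change = 0, converged = TRUE,
                 specimen_id = NULL, derotated = FALSE,
                 reference_angle = NULL),
            class = "gpa_fit")
}

test_that("a specimen equal to the consensus does not slide", {
  set.seed(51)
  C <- rand_config(5)
  fit <- toy_fit(C, array(C, c(5, 2, 1)))
  step <- slide_once(fit, toy_scheme())
  expect_lt(max(abs(step$displacements)), 1e-10)
  expect_equal(step$coords[, , 1], C, ignore_attr = TRUE)
})

test_that("single-slider displacement matches a 1-D bending-energy minimizer", {
  set.seed(52)
  for (rep in 1:5) {
    C <- cbind(seq(0, 1, length.out = 5), c(0, 0.2, 0.1, 0.25, 0.05)) +
      rnorm(10, sd = 0.02)
    X <- C + rnorm(10, sd = 0.05)
    fit <- toy_fit(C, array(X, c(5, 2, 1)))
    step <- slide_once(fit, toy_scheme())
    B <- bending_energy_matrix(C)
    u <- (X[4, ] - X[2, ]) / sqrt(sum((X[4, ] - X[2, ])^2))
    energy_at <- function(t) {
      Xt <- X; Xt[3, ] <- Xt[3, ] + t * u
      bending_energy(B, C, Xt)
    }
    t_star <- optimize(energy_at, c(-2, 2), tol = 1e-10)$minimum
    expect_equal(step$displacements[1, 1], t_star, tolerance = 1e-6)
    expect_lte(step$energy_after[1], step$energy_before[1])
  }
})

test_that("sliding never moves non-slider points before re-superimposition", {
  set.seed(53)
  coords <- noisy_ensemble(make_template_outline(), 6, sd = 0.01)
  scheme <- restrict_scheme(builtin_scheme("mixed"), "dorsum")$scheme
  fit <- gpa(coords)
  step <- slide_once(fit, scheme)
  fixed <- which(scheme$roles == "landmark")
  expect_identical(step$coords[fixed, , ], fit$aligned[fixed, , ])
})

test_that("every sliding pass lowers each specimen's bending energy", {
  set.seed(54)
  coords <- noisy_ensemble(make_template_outline(), 8, sd = 0.015)
  scheme <- restrict_scheme(builtin_scheme("ssl"), "dorsum")$scheme
  step <- slide_once(gpa(coords), scheme)
  expect_true(all(step$energy_after <= step$energy_before + 1e-12))
})

test_that("the ensemble bending-energy trace is non-increasing", {
  set.seed(55)
  coords <- noisy_ensemble(make_template_outline(), 10, sd = 0.02)
  sf <- slide_until_converged(coords, restrict_scheme(builtin_scheme("ssl"),
                                                      "dorsum")$scheme)
  expect_true(sf$converged)
  expect_true(all(diff(sf$bending_energy_trace) <= 0))
})

test_that("identical configurations converge immediately with zero movement", {
  set.seed(56)
  x <- make_template_outline()
  coords <- array(rep(x, 5), c(30, 2, 5))
  sf <- slide_until_converged(coords, builtin_scheme("ssl"))
  expect_true(sf$converged)
  expect_lte(sf$iterations, 1L)
  expect_lt(max(abs(sf$displacements)), 1e-8)
})

test_that("a sliderless scheme reduces sliding to plain GPA exactly", {
  set.seed(57)
  coords <- noisy_ensemble(make_template_outline(), 6, sd = 0.01)
  rs <- restrict_scheme(builtin_scheme("landmarks"), "dorsum")
  sub <- coords[rs$indices, , ]
  sf <- slide_until_converged(sub, rs$scheme)
  fit <- gpa(sub)
  expect_equal(sf$ensemble$aligned, fit$aligned, tolerance = 1e-12)
  expect_equal(sf$iterations, 0L)
})

test_that("sliding removes arbitrary per-specimen spacing along the curve", {
  set.seed(58)
  scheme <- restrict_scheme(builtin_scheme("mixed"), "croup_back")$scheme
  marks <- which(scheme$roles == "landmark")
  n <- 12
  # each specimen is a smooth perturbation of the body outline, sampled
  # once evenly and once with jittered arc-length spacing of the sliders
  base_curves <- lapply(1:n, function(i) {
    s <- seq(0, 1, length.out = 400)
    amp <- rnorm(3, sd = 0.02)
    cbind(s, posturegm:::dorsal_profile(s) +
            amp[1] * sin(pi * s) + amp[2] * sin(2 * pi * s) +
            amp[3] * sin(3 * pi * s))
  })
  sample_curve <- function(curve, fracs) {
    arc <- c(0, cumsum(sqrt(diff(curve[, 1])^2 + diff(curve[, 2])^2)))
    arc <- arc / max(arc)
    cbind(approx(arc, curve[, 1], xout = fracs)$y,
          approx(arc, curve[, 2], xout = fracs)$y)
  }
  even <- seq(0, 1, length.out = 15)
  jit <- matrix(rnorm(15 * n, sd = 0.012), n, 15)
  jit[, marks] <- 0
  coords_a <- array(vapply(base_curves, sample_curve, matrix(0, 15, 2),
                           fracs = even), c(15, 2, n))
  coords_b <- coords_a
  for (i in seq_len(n))
    coords_b[, , i] <- sample_curve(base_curves[[i]], sort(even + jit[i, ]))
  slid_a <- slide_until_converged(coords_a, scheme)$ensemble
  slid_b <- slide_until_converged(coords_b, scheme)$ensemble
  raw_a <- gpa(coords_a); raw_b <- gpa(coords_b)
  per_spec <- function(fa, fb)
    mean(vapply(seq_len(n), function(i)
      procrustes_distance(fa$aligned[, , i], fb$aligned[, , i]), numeric(1)))
  d_raw <- per_spec(raw_a, raw_b)
  d_slid <- per_spec(slid_a, slid_b)
  # sliding brings each re-spaced specimen back to its evenly spaced twin
  expect_lt(d_slid, d_raw / 3)
})

test_that("one sliding pass recovers a re-spaced copy of the consensus", {
  set.seed(59)
  scheme <- restrict_scheme(builtin_scheme("mixed"), "croup_back")$scheme
  marks <- which(scheme$roles == "landmark")
  s <- seq(0, 1, length.out = 400)
  curve <- cbind(s, posturegm:::dorsal_profile(s))
  arc <- c(0, cumsum(sqrt(diff(curve[, 1])^2 + diff(curve[, 2])^2)))
  arc <- arc / max(arc)
  sample_curve <- function(fracs)
    cbind(approx(arc, curve[, 1], xout = fracs)$y,
          approx(arc, curve[, 2], xout = fracs)$y)
  even <- seq(0, 1, length.out = 15)
  C <- sample_curve(even)
  jv <- rnorm(15, sd = 0.012); jv[marks] <- 0
  X <- sample_curve(sort(even + jv))
  fit <- structure(list(aligned = array(X, c(15, 2, 1)), consensus = C,
                        centroid_sizes = 1, iterations = 0L,
                        final_change = 0, converged = TRUE,
                        specimen_id = NULL, derotated = FALSE,
                        reference_angle = NULL), class = "gpa_fit")
  step <- slide_once(fit, scheme)
  before <- sqrt(mean((X - C)^2))
  after <- sqrt(mean((step$coords[, , 1] - C)^2))
  # one pass removes the tangential (spacing) component; what remains is
  # the normal-direction sampling error of the jittered polyline
  expect_lt(after, before / 3)
})
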