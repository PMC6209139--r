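# shared generators for randomized shape tests (all seeded by the caller)

# random non-degenerate k-point configuration
rand_config <- function(k, spread = 1) {
  matrix(stats::rnorm(2 * k, sd = spread), k, 2,
         dimnames = list(NULL, c("x", "y")))
}

# center and scale a configuration to unit centroid size
normalize_shape <- function(x) {
  x <- sweep(x, 2, colMeans(x))
  x / sqrt(sum(x^2))
}

# random similarity transform of a configuration (no reflection)
rand_similarity <- function(x) {
  th <- stats::runif(1, 0, 2 * pi)
  sc <- stats::runif(1, 0.2, 5)
  tr <- stats::rnorm(2, sd = 10)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  sweep(sc * x %*% t(R), 2, tr, `+`)
}

# small ensemble of noisy copies of a base shape
noisy_ensemble <- function(base, n, sd = 0.02) {
  k <- nrow(base)
  array(apply(matrix(seq_len(n)), 1, function(i) base + rnorm(2 * k, sd = sd)),
        dim = c(k, 2, n))
}

# brute-force ordinary-Procrustes residual: grid over rotation angles with
# per-angle optimal scale and translation (independent of align_pair)
brute_force_rss <- function(X, Y, step = 0.001) {
  Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
  ssx <- sum(Xc^2)
  thetas <- seq(0, 2 * pi, by = step)
  rss <- vapply(thetas, function(th) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    Xr <- Xc %*% t(R)
    beta <- max(0, sum(Xr * Yc) / ssx)
    sum((Yc - beta * Xr)^2)
  }, numeric(1))
  min(rss)
}
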