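# Independent brute-force oracle for the border-corrected K estimator:
# literal double loop over centers and neighbors, no shared code with the
# package implementation.
khat_brute <- function(x, y, side, hs) {
  n <- length(x)
  area <- side^2
  out <- numeric(length(hs))
  for (k in seq_along(hs)) {
    h <- hs[k]
    cnt <- 0L
    ne <- 0L
    for (i in seq_len(n)) {
      bd <- min(x[i], y[i], side - x[i], side - y[i])
      if (bd > h) {
        ne <- ne + 1L
        for (j in seq_len(n)) {
          if (j != i &&
              sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2) <= h) {
            cnt <- cnt + 1L
          }
        }
      }
    }
    out[k] <- if (ne == 0L) NA_real_ else (area / n) * cnt / ne
  }
  out
}

# Uniform points with iid half/half labels: a constant-risk null pattern.
make_null_pattern <- function(n, side = 10) {
  w <- square_window(side)
  labeled_pattern(runif(n, 0, side), runif(n, 0, side),
                  sample(rep(c("case", "control"), length.out = n)), w)
}

# Null pattern confined to the central half of the window: every point is
# farther than side/4 from the boundary, so D is defined at all grid ranges
# under every labeling. Labels stay exchangeable, so test sizes are exact.
make_inner_pattern <- function(n, side = 10) {
  w <- square_window(side)
  labeled_pattern(runif(n, side * 0.27, side * 0.73),
                  runif(n, side * 0.27, side * 0.73),
                  sample(rep(c("case", "control"), length.out = n)), w)
}

# Mix of uniform and clustered unmarked point sets for oracle checks.
make_test_points <- function(n, side = 1, clustered = FALSE) {
  if (clustered) {
    k <- max(1L, n %/% 20L)
    cx <- runif(k, 0, side); cy <- runif(k, 0, side)
    id <- sample.int(k, n, replace = TRUE)
    x <- pmin(pmax(cx[id] + rnorm(n, sd = side / 30), 0), side)
    y <- pmin(pmax(cy[id] + rnorm(n, sd = side / 30), 0), side)
  } else {
    x <- runif(n, 0, side); y <- runif(n, 0, side)
  }
  list(x = x, y = y)
}

# The study geometry scaled down proportionally: same parent intensity,
# window shrunk so the expected sample is ~ n_target, cluster radius shrunk
# by the same linear factor as the window side.
reduced_sim <- function(n_target = 600, lambda = 50) {
  full <- sim_config()
  # area shrink factor giving E[n] = kappa * area * 2 * lambda = n_target
  scale2 <- n_target / (full$kappa * full$window$area * 2 * lambda)
  s <- sqrt(scale2)
  sim_config(side_length = full$window$side_length * s,
             kappa = full$kappa,
             lambda_case = lambda, lambda_control = lambda,
             cluster_radius = full$cluster_radius * s)
}

# Build a permutation-null object directly from a replicate matrix, for
# order-statistic tests with known values.
synthetic_null <- function(observed, replicates, side = 10) {
  r <- length(observed)
  structure(list(observed = observed,
                 replicates = replicates,
                 grid = make_range_grid(side, r),
                 n_perm = nrow(replicates),
                 n_case = 10L, n_control = 10L,
                 seed = NA_integer_),
            class = "kdiff_null")
}
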