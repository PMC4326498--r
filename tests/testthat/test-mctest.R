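test_that("random labeling preserves the mark multiset and is uniform", {
  m <- c("case", "control", "control")
  out <- random_labeling(m, seed = 1)
  expect_identical(sort(out), sort(m))
  expect_error(random_labeling(rep("case", 5)), "both")

  # with 1 case among 3 points, each position is the case 1/3 of the time
  set.seed(2)
  pos <- replicate(30000, which(random_labeling(m) == "case"))
  gof <- chisq.test(tabulate(pos, 3), p = rep(1 / 3, 3))
  expect_gt(gof$p.value, 0.001)
})

test_that("the permutation null has the right shape and is reproducible", {
  set.seed(3)
  p <- make_null_pattern(50, side = 10)
  g <- make_range_grid(10, 4)
  null <- permutation_null(p, g, n_perm = 19, seed = 11)
  expect_identical(dim(null$replicates), c(19L, 4L))
  expect_identical(null, permutation_null(p, g, n_perm = 19, seed = 11))
  # observed column goes through the same arithmetic as dhat()
  expect_identical(null$observed, dhat(p, g)$dhat)
  # replicate rows preserve counts implicitly: each row is a D of the same
  # locations, so swapping all labels of the pattern negates the observed
  expect_error(permutation_null(p, g, n_perm = 0), "n_perm")
})

test_that("blocked pair counting matches the single-block path exactly", {
  # force multiple center blocks and compare against dhat(), whose own
  # block layout differs: integer-exact counts make them bitwise equal
  set.seed(35)
  n <- 3000                                # block size ~ 2666 -> 2 blocks
  w <- square_window(50)
  p <- labeled_pattern(runif(n, 0, 50), runif(n, 0, 50),
                       sample(rep(c("case", "control"), n / 2)), w)
  g <- make_range_grid(50, 3)
  null <- permutation_null(p, g, n_perm = 4, seed = 36)
  expect_identical(null$observed, dhat(p, g)$dhat)
})

test_that("tests are bitwise invariant to the input point order", {
  set.seed(4)
  p <- make_null_pattern(60, side = 10)
  ord <- sample.int(60)
  p2 <- labeled_pattern(p$x[ord], p$y[ord], p$mark[ord], p$window)
  g <- make_range_grid(10, 3)
  n1 <- permutation_null(p, g, n_perm = 29, seed = 5)
  n2 <- permutation_null(p2, g, n_perm = 29, seed = 5)
  expect_identical(n1$observed, n2$observed)
  expect_identical(n1$replicates, n2$replicates)
  for (m in c("pointwise", "simultaneous", "integrated")) {
    t1 <- test_from_null(n1, m)
    t2 <- test_from_null(n2, m)
    expect_identical(t1$reject_any, t2$reject_any)
    expect_identical(t1$p_value, t2$p_value)
  }
})

test_that("pointwise envelopes are the ranked replicate values", {
  reps <- matrix(1:199, 199, 1)
  null <- synthetic_null(observed = 100, replicates = reps)
  env <- pointwise_envelope(null)           # defaults 5 / 195 at n_perm 199
  expect_equal(env$lower, 5)
  expect_equal(env$upper, 195)
  env2 <- pointwise_envelope(null, 1, 199)
  expect_equal(c(env2$lower, env2$upper), c(1, 199))

  const <- synthetic_null(0.5, matrix(7, 99, 1))
  envc <- pointwise_envelope(const, 3, 97)
  expect_equal(envc$lower, envc$upper)
  expect_error(pointwise_envelope(null, 0, 199), "ranks")
  expect_error(pointwise_envelope(null, 5, 200), "ranks")
})

test_that("pointwise rejection is strict and any-range", {
  reps <- matrix(rep(1:199, 3), 199, 3)
  null <- synthetic_null(c(100, 195, 196), reps)
  out <- test_from_null(null, "pointwise")
  # 100 inside; 195 equal to the upper critical value is NOT a rejection;
  # 196 strictly outside rejects, and any single range rejects overall
  expect_identical(out$reject_at_range, c(FALSE, FALSE, TRUE))
  expect_true(out$reject_any)
  inside <- test_from_null(synthetic_null(c(50, 60, 70), reps), "pointwise")
  expect_false(inside$reject_any)
})

test_that("the observed rank among replicates is uniform under the null", {
  set.seed(12)
  n_perm <- 19
  ranks <- replicate(400, {
    p <- make_inner_pattern(40, side = 10)
    null <- permutation_null(p, make_range_grid(10, 1), n_perm = n_perm)
    sum(null$replicates[, 1] < null$observed) + 1
  })
  gof <- chisq.test(tabulate(ranks, n_perm + 1),
                    p = rep(1 / (n_perm + 1), n_perm + 1))
  expect_gt(gof$p.value, 0.001)
})

test_that("single-range pointwise test has nominal size on null data", {
  set.seed(13)
  rej <- replicate(300, {
    p <- make_inner_pattern(40, side = 10)
    test_dataset(p, make_range_grid(10, 1), n_perm = 39,
                 method = "pointwise")$reject_any
  })
  # ranks 1/39 of 39 replicates give an exact size-0.05 two-sided test
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / 300))
})

test_that("the integrated statistic is a standardized sum with MC p-value", {
  set.seed(14)
  reps <- matrix(rnorm(199 * 4), 199, 4)
  null <- synthetic_null(rep(0, 4), reps)
  out <- integrated_statistic(null)
  expect_equal(out$statistic, 0)
  expect_gt(out$p_value, 0.5)               # symmetric replicates
  expect_true(out$p_value <= 1)

  # positive rescaling of all D values leaves the p-value unchanged
  obs <- synthetic_null(c(1, 2, -1, 0.5), reps)
  obs2 <- synthetic_null(c(1, 2, -1, 0.5) * 3.7, reps * 3.7)
  expect_equal(integrated_statistic(obs2)$p_value,
               integrated_statistic(obs)$p_value)

  degen <- synthetic_null(c(0, 0), cbind(rnorm(99), rep(2, 99)))
  expect_error(integrated_statistic(degen), "range 2")
})

test_that("the simultaneous envelope rejects obvious departures and controls size", {
  # all replicates identically zero: any nonzero observed D rejects
  null <- synthetic_null(c(0, 0.1, 0), matrix(0, 199, 3))
  out <- test_from_null(null, "simultaneous")
  expect_true(out$reject_any)
  expect_identical(out$reject_at_range, c(FALSE, TRUE, FALSE))

  # with r = 1 the simultaneous and pointwise rules agree up to the rank
  # convention: disagreement rate over null datasets is at most a few /200
  set.seed(15)
  both <- t(replicate(200, {
    p <- make_inner_pattern(30, side = 10)
    null <- permutation_null(p, make_range_grid(10, 1), n_perm = 199)
    c(pw = test_from_null(null, "pointwise")$reject_any,
      sim = test_from_null(null, "simultaneous")$reject_any)
  }))
  expect_lt(mean(both[, "pw"] != both[, "sim"]), 0.05)
})

test_that("undefined D values make tests fail loudly", {
  # all points hug the boundary so the largest range has no eligible center
  w <- square_window(1)
  x <- c(runif(10, 0, 0.04), runif(10, 0.96, 1))
  y <- runif(20, 0, 1)
  p <- labeled_pattern(x, y, rep(c("case", "control"), 10), w)
  g <- make_range_grid(1, 2)                # h includes 0.25 > max bdist
  expect_warning(null <- permutation_null(p, g, n_perm = 9, seed = 1),
                 "eligible")
  expect_error(test_from_null(null, "pointwise"), "undefined")
  expect_error(test_from_null(null, "integrated"), "undefined")
})

test_that("per-dataset test reports carry the full decision trail", {
  set.seed(16)
  p <- make_inner_pattern(40, side = 10)
  g <- make_range_grid(10, 3)
  out <- test_dataset(p, g, n_perm = 39, method = "pointwise", seed = 2)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_test_report(out, path, dataset_id = 7)
  rep_csv <- read.csv(path)
  expect_identical(nrow(rep_csv), 3L)
  expect_identical(rep_csv$dataset_id, rep(7L, 3))
  expect_equal(rep_csv$d_obs, out$d_obs, tolerance = 1e-12)
  expect_identical(as.logical(rep_csv$reject), out$reject_at_range)

  outi <- test_dataset(p, g, n_perm = 39, method = "integrated", seed = 2)
  write_test_report(outi, path)
  rep2 <- read.csv(path)
  expect_true(all(c("statistic", "p_value") %in% names(rep2)))
  expect_equal(unique(rep2$p_value), outi$p_value)
})
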