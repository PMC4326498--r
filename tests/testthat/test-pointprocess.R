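test_that("parent generation is Poisson with the right mean and respects kappa = 0", {
  w <- square_window(sqrt(3e6))
  expect_identical(nrow(generate_parents(w, 0, seed = 1)), 0L)
  expect_error(generate_parents(w, -1), "kappa")

  set.seed(1)
  counts <- replicate(10000, nrow(generate_parents(w, 1e-4)))
  # Poisson(kappa * area) = Poisson(300); 3 standard errors of the mean
  expect_lt(abs(mean(counts) - 300), 3 * sqrt(300 / 10000))
  expect_true(all(apply(generate_parents(w, 1e-4, seed = 2), 2,
                        function(v) all(v >= 0 & v <= w$side_length))))
})

test_that("children stay within the cluster radius of their parent and in the window", {
  cfg <- sim_config(side_length = 300, kappa = 1e-3,
                    lambda_case = 5, lambda_control = 5, cluster_radius = 4)
  p <- generate_cox_pattern(cfg, seed = 42)
  parents <- attr(p, "parents")
  pid <- attr(p, "parent_id")
  expect_identical(length(pid), n_points(p))
  d_parent <- sqrt((p$x - parents$x[pid])^2 + (p$y - parents$y[pid])^2)
  expect_true(all(d_parent <= cfg$cluster_radius + 1e-12))
  expect_true(all(p$x >= 0 & p$x <= 300 & p$y >= 0 & p$y <= 300))
  expect_true(all(p$mark %in% c("case", "control")))
})

test_that("total sample size matches the compound-Poisson closed form", {
  # E[n] = kappa |A| (lc + lk), Var[n] = kappa |A| ((lc+lk) + (lc+lk)^2),
  # checked before clipping; clipping loss measured and small at this geometry
  cfg <- sim_config(side_length = 500, kappa = 4e-4,
                    lambda_case = 5, lambda_control = 5, cluster_radius = 2)
  mom <- expected_pattern_moments(cfg)
  expect_equal(mom$mean_n, 1000)
  expect_equal(mom$sd_n, sqrt(100 * (10 + 100)))

  set.seed(99)
  nsim <- 1000
  kept <- clipped <- numeric(nsim)
  for (i in seq_len(nsim)) {
    p <- generate_cox_pattern(cfg)
    kept[i] <- n_points(p)
    clipped[i] <- attr(p, "n_clipped")
  }
  unclipped <- kept + clipped
  se_mean <- mom$sd_n / sqrt(nsim)
  expect_lt(abs(mean(unclipped) - mom$mean_n), 4 * se_mean)
  se_sd <- mom$sd_n / sqrt(2 * (nsim - 1))
  expect_lt(abs(sd(unclipped) - mom$sd_n), 4 * se_sd)
  # clipping loss at this geometry is under 1%, measured not assumed
  expect_lt(mean(clipped) / mean(unclipped), 0.01)
})

test_that("case and control counts share parents but are conditionally independent", {
  # across datasets the totals are positively correlated (shared parents)
  cfg <- sim_config(side_length = 500, kappa = 2e-4,
                    lambda_case = 20, lambda_control = 20, cluster_radius = 2)
  set.seed(7)
  tot <- t(replicate(200, {
    p <- generate_cox_pattern(cfg)
    c(n_case(p), n_control(p))
  }))
  expect_gt(cor(tot[, 1], tot[, 2]), 0.5)

  # per parent, case and control child counts are independent Poissons
  cfg2 <- sim_config(side_length = 1000, kappa = 2e-3,
                     lambda_case = 3, lambda_control = 3, cluster_radius = 2)
  p <- generate_cox_pattern(cfg2, seed = 8)
  np <- nrow(attr(p, "parents"))
  pid <- attr(p, "parent_id")
  per_case <- tabulate(pid[p$mark == "case"], nbins = np)
  per_ctrl <- tabulate(pid[p$mark == "control"], nbins = np)
  expect_gt(np, 1500)
  expect_lt(abs(cor(per_case, per_ctrl)), 3 / sqrt(np))
})

test_that("identical seeds reproduce identical patterns bit for bit", {
  cfg <- sim_config(side_length = 300, kappa = 5e-4,
                    lambda_case = 10, lambda_control = 10, cluster_radius = 5)
  p1 <- generate_cox_pattern(cfg, seed = 123)
  p2 <- generate_cox_pattern(cfg, seed = 123)
  expect_identical(p1, p2)
  streams <- rng_streams(123, 2)
  q1 <- generate_cox_pattern(cfg, seed = streams[[1]])
  q2 <- generate_cox_pattern(cfg, seed = streams[[2]])
  expect_identical(q1, generate_cox_pattern(cfg, seed = streams[[1]]))
  expect_false(identical(q1$x, q2$x))
})

test_that("pattern summaries report exact means and flag undefined sds", {
  w <- square_window(10)
  p <- labeled_pattern(runif(20, 0, 10), runif(20, 0, 10),
                       rep(c("case", "control"), each = 10), w)
  s1 <- summarize_patterns(list(p))
  expect_equal(s1$mean_n, 20)
  expect_equal(s1$mean_prop_case, 0.5)
  expect_true(is.na(s1$sd_n))

  counts <- data.frame(n_total = c(10, 20, 30), n_case = c(5, 10, 18))
  s2 <- summarize_patterns(counts)
  expect_equal(s2$mean_n, 20)
  expect_equal(s2$sd_n, sd(c(10, 20, 30)))
  expect_equal(s2$mean_prop_case, mean(c(0.5, 0.5, 0.6)))
  expect_error(summarize_patterns(list()), "non-empty")
})

test_that("smoothed risk is a kernel-weighted case fraction with flagged gaps", {
  w <- square_window(10)
  all_cases <- labeled_pattern(runif(15, 0, 10), runif(15, 0, 10),
                               rep("case", 15), w)
  # validity of the testing precondition does not apply to the smoother
  r1 <- nadaraya_watson_risk(all_cases, bandwidth = 2,
                             grid = data.frame(x = c(2, 5), y = c(2, 5)))
  expect_equal(r1$risk, c(1, 1))

  sym <- labeled_pattern(c(4, 6), c(5, 5), c("case", "control"), w)
  r2 <- nadaraya_watson_risk(sym, bandwidth = 1,
                             grid = data.frame(x = 5, y = 5))
  expect_equal(r2$risk, 0.5)

  # hand-evaluated Gaussian kernel ratio: case at distance 1, control at 2
  two <- labeled_pattern(c(5, 5), c(6, 7), c("case", "control"), w)
  r3 <- nadaraya_watson_risk(two, bandwidth = 1,
                             grid = data.frame(x = 5, y = 5))
  w1 <- exp(-1 / 2); w2 <- exp(-4 / 2)
  expect_equal(r3$risk, w1 / (w1 + w2))

  # zero kernel mass is NA with a warning, never silently 0
  far <- labeled_pattern(c(0.1, 0.2), c(0.1, 0.2), c("case", "control"), w)
  expect_warning(
    r4 <- nadaraya_watson_risk(far, bandwidth = 0.01,
                               grid = data.frame(x = 9.9, y = 9.9)),
    "undefined")
  expect_true(is.na(r4$risk))
  expect_error(nadaraya_watson_risk(sym, bandwidth = 0), "bandwidth")
})
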