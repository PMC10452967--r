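two_runs <- function(n = 400, seeds = c(31, 32), qualities = c(3.1, 3.6)) {
  list(run_experiment(experiment_config(qualities[1], 5, n_ants = n,
                                        seed = seeds[1])),
       run_experiment(experiment_config(qualities[2], 5, n_ants = n,
                                        seed = seeds[2])))
}

test_that("proportion standard error follows the closed form", {
  expect_equal(proportion_se(0.5, 10000), 0.005)
  expect_equal(proportion_se(0, 50), 0)
  expect_equal(proportion_se(0.79, 10000), sqrt(0.79 * 0.21 / 10000))
  expect_error(proportion_se(0.5, 0), "at least 1")
})

test_that("high-threshold count is the minimum of the two rejection counts", {
  rs <- two_runs()
  expect_equal(high_threshold_count(rs[[1]], rs[[2]]),
               min(rs[[1]]$n_reject_poor, rs[[2]]$n_reject_poor))
  expect_equal(high_threshold_count(rs[[1]], rs[[1]]), rs[[1]]$n_reject_poor)
  mismatched <- run_experiment(experiment_config(3.6, 5, n_ants = 100, seed = 1))
  expect_error(high_threshold_count(rs[[1]], mismatched), "colony sizes")
})

test_that("high-threshold decomposition gives h + (p_a - h)(p_b - h), symmetrically", {
  rs <- two_runs()
  est <- joint_accept_good(rs[[1]], rs[[2]])
  h <- min(rs[[1]]$n_reject_poor, rs[[2]]$n_reject_poor) / 400
  p_a <- rs[[1]]$n_commit_good / 400
  p_b <- rs[[2]]$n_commit_good / 400
  expect_equal(est$p_joint, h + (p_a - h) * (p_b - h), tolerance = 1e-12)
  est_rev <- joint_accept_good(rs[[2]], rs[[1]])
  expect_equal(est_rev$p_joint, est$p_joint, tolerance = 1e-12)
  # lower bounds of the construction
  expect_gte(est$p_joint, est$h)
  expect_gte(est$p_joint, (est$p_a - est$h) * (est$p_b - est$h))
  # h = 0 reduces to independence
  expect_equal(0 + (p_a - 0) * (p_b - 0), p_a * p_b)
})

test_that("constructed joints respect Frechet bounds against their marginals", {
  for (s in 1:4) {
    rs <- two_runs(n = 300, seeds = c(s, s + 100))
    est <- suppressWarnings(joint_accept_good(rs[[1]], rs[[2]]))
    expect_gte(est$p_joint, max(0, est$p_a + est$p_b - 1) - 1e-12)
    expect_lte(est$p_joint, min(est$p_a, est$p_b) + 1e-12)
  }
})

test_that("multinomial bootstrap agrees with naive per-ant resampling", {
  rs <- two_runs(n = 150, seeds = c(8, 9))
  se_fast <- as.numeric(bootstrap_joint_se(rs[[1]], rs[[2]], reps = 4000,
                                           seed = 17))
  se_naive <- bootstrap_joint_naive(rs[[1]], rs[[2]], reps = 4000, seed = 18)
  expect_lt(abs(se_fast - se_naive) / se_naive, 0.15)
})

test_that("bootstrap SE is zero for degenerate colonies and scales as 1/sqrt(n)", {
  # all ants end in the same outcome cell: tight thresholds, no assessment
  # noise, and the poor site made undiscoverable
  no_poor <- default_discovery_prob(); no_poor[, 2] <- 0
  degen <- lapply(c(1, 2), function(s)
    run_experiment(experiment_config(3.1, 6.5, n_ants = 100, seed = s,
                                     threshold_mean = 2, threshold_sd = 1e-9,
                                     assessment_error_sd = 0,
                                     discovery_prob = no_poor)))
  expect_equal(as.numeric(bootstrap_joint_se(degen[[1]], degen[[2]],
                                             reps = 200, seed = 1)), 0)
  expect_error(bootstrap_joint_se(degen[[1]], degen[[2]], reps = 0), "at least 1")

  se_n <- sapply(c(200, 800), function(n) {
    rs <- two_runs(n = n, seeds = c(51, 52))
    as.numeric(bootstrap_joint_se(rs[[1]], rs[[2]], reps = 3000, seed = 3))
  })
  ratio <- se_n[1] / se_n[2]
  expect_gt(ratio, 1.4)  # quadrupling n should halve the SE, roughly
  expect_lt(ratio, 2.8)
})
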