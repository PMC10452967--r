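small_cfg <- function(...) {
  experiment_config(quality_poor = 4.6, quality_good = 6.5, n_ants = 200,
                    seed = 5, ...)
}

test_that("threshold sampling follows the colony's normal distribution", {
  set.seed(1)
  th <- sample_thresholds(10000, 5, 1)
  expect_lt(abs(mean(th) - 5), 4 / sqrt(10000))
  expect_lt(abs(mean(th > 6.5) - pnorm(6.5, 5, 1, lower.tail = FALSE)), 0.01)
  expect_equal(sample_thresholds(1, 5, 1e-9), 5, tolerance = 1e-6)
  expect_error(sample_thresholds(0, 5, 1), "positive")
  expect_error(sample_thresholds(10, 5, 0), "positive")
})

test_that("site evaluation is a noisy threshold rule", {
  set.seed(2)
  expect_false(any(evaluate_site(-1000, 5, 1, n = 1000)))  # home uninhabitable
  expect_true(all(evaluate_site(6.5, 5, 0, n = 10)))       # zero noise, above
  expect_false(any(evaluate_site(4.6, 5, 0, n = 10)))      # zero noise, below
  expect_lt(abs(mean(evaluate_site(5, 5, 1, n = 20000)) - 0.5), 0.02)
})

test_that("step_ant honours the five-state transition contract", {
  cfg <- small_cfg()
  ant <- ant_state(threshold = 5)
  expect_equal(ant$phase, "evaluating home site")
  committed <- ant
  committed$phase <- "committed to superior site"
  expect_error(step_ant(committed, cfg), "absorbing")

  # zero noise, threshold below the good quality: discovery of the good site
  # commits immediately and is recorded as the first site found
  cfg0 <- experiment_config(4.6, 6.5, n_ants = 1, seed = 1,
                            assessment_error_sd = 0)
  set.seed(42)
  ant <- ant_state(threshold = 5)
  for (i in 1:500) {
    ant <- step_ant(ant, cfg0)
    if (!is.na(ant$first_site_found)) break
  }
  expect_false(is.na(ant$first_site_found))
  if (ant$first_site_found == "good") {
    expect_equal(ant$phase, "committed to superior site")
  } else {
    expect_equal(ant$first_site_found, "poor")
  }
  expect_gt(ant$clock, 0)
})

test_that("runs are bit-reproducible under a fixed seed", {
  r1 <- run_experiment(small_cfg())
  r2 <- run_experiment(small_cfg())
  expect_identical(r1, r2)
  r3 <- run_experiment(experiment_config(4.6, 6.5, n_ants = 200, seed = 6))
  expect_false(identical(r1$ants$clock, r3$ants$clock))
})

test_that("committed counts partition the colony at termination", {
  for (s in 1:3) {
    r <- run_experiment(experiment_config(3.6, 5.5, n_ants = 300, seed = s))
    expect_equal(r$n_commit_good + r$n_commit_poor + r$n_uncommitted, 300)
    expect_lte(r$n_switch_to_good, r$n_commit_good)
    expect_lte(r$n_switch_to_good, r$n_first_poor)
    expect_equal(r$n_reject_poor,
                 sum(r$ants$evaluated_poor &
                       (is.na(r$ants$final_site) | r$ants$final_site != "poor")))
  }
})

test_that("with no noise and low thresholds the first discovered site wins", {
  cfg <- experiment_config(4.6, 6.5, n_ants = 4000, seed = 9,
                           threshold_mean = 2, threshold_sd = 1e-6,
                           assessment_error_sd = 0)
  r <- run_experiment(cfg)
  expect_equal(r$n_uncommitted, 0)
  expect_true(all(r$ants$first_site == r$ants$final_site))
  p_good_first <- first_good_probability(cfg$discovery_prob)
  p_hat <- r$n_commit_good / cfg$n_ants
  expect_lt(abs(p_hat - p_good_first),
            4 * sqrt(p_good_first * (1 - p_good_first) / cfg$n_ants))
})

test_that("unreachable thresholds terminate with flagged uncommitted ants", {
  cfg <- experiment_config(4.6, 6.5, n_ants = 5, seed = 1,
                           threshold_mean = 50, threshold_sd = 1e-6,
                           assessment_error_sd = 0, max_time = 2000)
  r <- run_experiment(cfg)
  expect_equal(r$n_uncommitted, 5)
  expect_equal(r$n_commit_good + r$n_commit_poor, 0)
})

test_that("degenerate poor = good configuration is symmetric apart from geography", {
  cfg <- experiment_config(5.5, 5.5, n_ants = 2000, seed = 21,
                           travel_time = matrix(1, 3, 3),
                           discovery_prob = matrix(c(0.5, 0.2, 0.2,
                                                     0.2, 0.5, 0.2,
                                                     0.2, 0.2, 0.5),
                                                   3, 3, byrow = TRUE))
  r <- run_experiment(cfg)
  p <- r$n_commit_good / cfg$n_ants
  expect_lt(abs(p - 0.5), 4 * sqrt(0.25 / cfg$n_ants))
})

test_that("summary table mirrors the per-experiment schema", {
  rs <- lapply(c(3.1, 4.6), function(q)
    run_experiment(experiment_config(q, 6.5, n_ants = 200, seed = 3)))
  tab <- summarize_experiments(rs)
  expect_equal(nrow(tab), 2)
  expect_named(tab, c("experiment", "quality_poor", "quality_good", "n_ants",
                      "p_accept_good", "se_p", "switch_rate", "n_reject_poor",
                      "duration_min", "n_uncommitted"))
  expect_equal(tab$p_accept_good, round(tab$p_accept_good, 4))
  expect_error(summarize_experiments(list()), "at least one")
})
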