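test_that("product correlation matches the enumerated 2x2 outcome table", {
  cases <- list(c(0.78, 0.68, 0.51), c(1, 1, 1), c(0.5, 0.5, 0.25),
                c(0.50, 0.79, 0.38), c(0.59, 0.49, 0.31))
  for (cs in cases) {
    expect_equal(correlation_from_joint(cs[1], cs[2], cs[3]),
                 correlation_brute(cs[1], cs[2], cs[3]), tolerance = 1e-12)
  }
  expect_equal(correlation_from_joint(0.78, 0.68, 0.51), 0.12)
  expect_equal(correlation_from_joint(1, 1, 1), 1)
  expect_equal(correlation_from_joint(0.5, 0.5, 0.25), 0)
  set.seed(41)
  for (i in 1:50) {
    p_a <- runif(1); p_b <- runif(1)
    p_j <- runif(1, max(0, p_a + p_b - 1), min(p_a, p_b))
    expect_equal(correlation_from_joint(p_a, p_b, p_j),
                 correlation_brute(p_a, p_b, p_j), tolerance = 1e-12)
  }
})

test_that("out-of-bounds probabilities and Frechet violations are rejected by name", {
  expect_error(correlation_from_joint(1.2, 0.5, 0.4, label = "q9"), "q9")
  expect_error(correlation_from_joint(0.5, 0.5, 0.6, label = "q7"),
               "Frechet.*q7")
  expect_error(correlation_from_joint(0.9, 0.8, 0.5), "Frechet")
  expect_error(linked_pair("q1", c("c1", "c2"), 0.9, 0.8, 0.5), "Frechet")
})

test_that("s_odd closed form equals brute-force enumeration for ranks 3 to 6", {
  expect_equal(s_odd(c(-0.06, 0.12, 0.06, 0.08)), 0.32)
  expect_equal(s_odd(c(1, 1, 1, 1)), 2)
  expect_equal(s_odd(c(1, 1, 1, -1)), 4)
  set.seed(7)
  for (n in 3:6) {
    for (i in 1:100) {
      E <- runif(n, -1, 1)
      expect_equal(s_odd(E), s_odd_brute(E), tolerance = 1e-12)
    }
    E0 <- runif(n, -1, 1); E0[sample(n, 1)] <- 0  # zero entries
    expect_equal(s_odd(E0), s_odd_brute(E0), tolerance = 1e-12)
  }
  expect_error(s_odd(numeric(0)), "empty")
})

test_that("inconsistent connectedness Delta sums absolute marginal differences", {
  m <- list(c(0.00, 0.58), c(0.56, 0.36), c(0.38, 0.16), c(0.18, -0.02))
  expect_equal(delta_icc(m), 1.20)
  expect_equal(delta_icc(list(c(0.3, 0.3), c(-0.7, -0.7), c(0, 0))), 0)
  expect_equal(delta_icc(list(c(1, -1), c(0, 0), c(0, 0), c(0, 0))), 2)
  expect_error(delta_icc(list(c(2, 0), c(0, 0), c(0, 0))), "\\[-1, 1\\]")
})

test_that("sign transitivity requires one shared sign including the closing edge", {
  expect_true(is_sign_transitive(c(1, 1, 1, 1)))
  expect_false(is_sign_transitive(c(1, 1, 1, -1)))
  expect_true(is_sign_transitive(c(-0.5, -0.5, -0.5, -0.5)))
  expect_false(is_sign_transitive(c(0.5, 0, 0.5, 0.5)))  # zero breaks the premise
  expect_false(is_sign_transitive(c(-0.5, 0.5, 0.5, 0.5)))
})

test_that("report identity dC_cbd = dC_chsh - Delta holds on random systems", {
  set.seed(13)
  for (i in 1:200) {
    p_a <- runif(4); p_b <- runif(4)
    p_j <- mapply(function(a, b) runif(1, max(0, a + b - 1), min(a, b)),
                  p_a, p_b)
    pairs <- lapply(1:4, function(k) {
      nxt <- if (k == 4) 1 else k + 1
      linked_pair(paste0("q", k), paste0("c", c(k, nxt)),
                  p_a[k], p_b[k], p_j[k])
    })
    rep <- contextuality_report(cyclic_system(pairs))
    expect_equal(rep$dC_cbd, rep$dC_chsh - rep$delta, tolerance = 1e-12)
    expect_lte(rep$dC_cbd, rep$dC_chsh + 1e-12)
    expect_lte(rep$s_odd, rep$rank)
    expect_true(all(abs(rep$E) <= 1 + 1e-12))
  }
})

test_that("boundary system (all E = 1, consistent marginals) sits exactly at dC = 0", {
  pairs <- lapply(1:4, function(k) {
    nxt <- if (k == 4) 1 else k + 1
    linked_pair(paste0("q", k), paste0("c", c(k, nxt)), 1, 1, 1)
  })
  rep <- contextuality_report(cyclic_system(pairs))
  expect_equal(rep$dC_chsh, 0)
  expect_equal(rep$dC_cbd, 0)
  expect_false(rep$type2)  # boundary counts as non-violation
  expect_true(rep$sign_transitive)
})

test_that("cyclic systems validate chaining and round-trip through JSON", {
  bad <- lapply(1:4, function(k)
    linked_pair(paste0("q", k), c("cX", "cY"), 0.5, 0.5, 0.25))
  expect_error(cyclic_system(bad), "chain")
  sys <- tsirelson_system()
  rt <- system_from_json(system_to_json(sys))
  expect_equal(rt, sys)
  tmp <- tempfile(fileext = ".json")
  system_to_json(ice_cream_system(), tmp)
  expect_equal(system_from_json(tmp), ice_cream_system())
})
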