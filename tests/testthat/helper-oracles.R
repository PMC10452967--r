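# Independent brute-force oracles, kept deliberately naive.

# maximum of the signed sum over all sign patterns with an odd number of
# minus signs, by enumeration of all 2^n patterns
s_odd_brute <- function(E) {
  n <- length(E)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  odd <- rowSums(signs < 0) %% 2 == 1
  max(signs[odd, , drop = FALSE] %*% E)
}

# product expectation by enumerating the 2x2 outcome table implied by
# (p_a, p_b, p_joint) with +1/-1 coding
correlation_brute <- function(p_a, p_b, p_joint) {
  p11 <- p_joint
  p10 <- p_a - p_joint
  p01 <- p_b - p_joint
  p00 <- 1 - p_a - p_b + p_joint
  p11 - p10 - p01 + p00
}

# naive per-ant bootstrap of the high-threshold joint (index resampling)
bootstrap_joint_naive <- function(result_a, result_b, reps, seed) {
  set.seed(seed)
  n <- result_a$config$n_ants
  stat <- function(res, idx) {
    a <- res$ants[idx, ]
    good <- !is.na(a$final_site) & a$final_site == "good"
    rej <- a$evaluated_poor & (is.na(a$final_site) | a$final_site != "poor")
    c(p = mean(good), r = mean(rej))
  }
  pj <- replicate(reps, {
    sa <- stat(result_a, sample.int(n, n, replace = TRUE))
    sb <- stat(result_b, sample.int(n, n, replace = TRUE))
    h <- min(sa["r"], sb["r"])
    h + (sa["p"] - h) * (sb["p"] - h)
  })
  sd(pj)
}

# random rank-4 consistently connected system with zero marginals
random_zero_marginal_system <- function() {
  E <- runif(4, -1, 1)
  pairs <- lapply(1:4, function(k) {
    nxt <- if (k == 4) 1 else k + 1
    linked_pair(paste0("q", k), paste0("c", c(k, nxt)),
                p_a = 0.5, p_b = 0.5, p_joint = (E[k] + 1) / 4)
  })
  list(E = E, system = cyclic_system(pairs))
}

# probability that an ant starting at the home nest discovers the good site
# before the poor site, under the epoch rule (random check order, first
# Bernoulli success), conditioned on eventually finding either
first_good_probability <- function(disc) {
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  p_sel <- numeric(3)
  for (s in 1:3) {
    tot <- 0
    for (r in 1:6) {
      ord <- perms[r, ]
      pos <- which(ord == s)
      fail_before <- prod(1 - disc[1, ord[seq_len(pos - 1)]])
      tot <- tot + fail_before * disc[1, s]
    }
    p_sel[s] <- tot / 6
  }
  p_sel[3] / (p_sel[2] + p_sel[3])
}
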