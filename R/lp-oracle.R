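#' Independent noncontextuality oracle via coupling feasibility
#'
#' Checks Contextuality-by-Default noncontextuality of a cyclic system without
#' using the closed-form `s_odd` criterion. A system is noncontextual iff
#' there exists a single joint distribution (a coupling) over all 2n variables
#' that (i) reproduces every pair's observed marginals and joint, and
#' (ii) simultaneously attains, for every connection (the two variables of
#' consecutive pairs recorded in the same context), the maximal possible
#' agreement probability `1 - |p - p'|` allowed by the two marginals.
#'
#' The search is over the `2^(2n)` deterministic outcome atoms. Existence of a
#' non-negative, normalised weight vector satisfying the linear constraints is
#' decided by non-negative least squares ([pracma::lsqnonneg()]): the system
#' is noncontextual iff the residual is (numerically) zero. The signed margin
#' reported is minus the residual distance, a diagnostic of how far the
#' constraints are from being jointly satisfiable; it is 0 for noncontextual
#' systems.
#'
#' For consistently connected systems with zero marginal expectations the
#' verdict coincides with the criterion `s_odd(E) <= n - 2`, and in general it
#' agrees with the sign of `dC_cbd` of [contextuality_report()] computed with
#' the connection-based inconsistency measure.
#'
#' @param system A [cyclic_system()] of rank at most 6 (the atom count grows
#'   as `4^n`).
#' @param tol Residual tolerance below which the coupling is accepted.
#' @return A list with `noncontextual` (logical), `margin` (<= 0), and
#'   `weights` (the fitted atom weights, for diagnostics).
#' @export
#' @examples
#' noncontextual_lp_oracle(pr_box_system())$noncontextual        # FALSE
#' noncontextual_lp_oracle(classical_mixture_system())$noncontextual # TRUE
noncontextual_lp_oracle <- function(system, tol = 1e-7) {
  stopifnot(inherits(system, "cyclic_system"))
  n <- system$rank
  if (n > 6L) stop("oracle supports rank <= 6 (atom enumeration)")
  pa <- vapply(system$pairs, `[[`, numeric(1), "p_a")
  pb <- vapply(system$pairs, `[[`, numeric(1), "p_b")
  pj <- vapply(system$pairs, `[[`, numeric(1), "p_joint")
  for (k in seq_len(n))
    check_frechet(pa[k], pb[k], pj[k], system$pairs[[k]]$label_content)

  nv <- 2L * n
  atoms <- as.matrix(expand.grid(rep(list(c(0, 1)), nv), KEEP.OUT.ATTRS = FALSE))
  na <- nrow(atoms)
  Lc <- seq(1L, nv, by = 2L)  # first-context variable of pair k
  Rc <- seq(2L, nv, by = 2L)  # second-context variable of pair k
  A <- matrix(0, 4L * n + 1L, na)
  b <- numeric(4L * n + 1L)
  for (k in seq_len(n)) {
    kn <- if (k == n) 1L else k + 1L
    A[3L * k - 2L, ] <- atoms[, Lc[k]];                      b[3L * k - 2L] <- pa[k]
    A[3L * k - 1L, ] <- atoms[, Rc[k]];                      b[3L * k - 1L] <- pb[k]
    A[3L * k, ]      <- atoms[, Lc[k]] * atoms[, Rc[k]];     b[3L * k] <- pj[k]
    A[3L * n + k, ]  <- as.numeric(atoms[, Rc[k]] == atoms[, Lc[kn]])
    b[3L * n + k]    <- 1 - abs(pb[k] - pa[kn])
  }
  A[4L * n + 1L, ] <- 1
  b[4L * n + 1L] <- 1

  fit <- pracma::lsqnonneg(A, b)
  resid <- sqrt(max(fit$resid.norm, 0))
  list(noncontextual = resid < tol,
       margin = -resid,
       weights = fit$x)
}
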