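# Estimators for linked experiment pairs: the standard error of a proportion,
# the high-threshold joint-probability construction, and bootstrap standard
# errors for the constructed joints.

#' Standard error of a proportion
#'
#' @param p Estimated proportion.
#' @param n Sample size (>= 1).
#' @return `sqrt(p (1 - p) / n)`.
#' @export
#' @examples
#' proportion_se(0.5, 10000)  # 0.005
proportion_se <- function(p, n) {
  check_probability(p, "p")
  if (n < 1) stop("'n' must be at least 1")
  sqrt(p * (1 - p) / n)
}

#' High-threshold count of a linked pair
#'
#' Ants whose thresholds are so high that they reject the inferior nest in
#' every context have no alternative to the superior site; their minimum
#' count across the two experiments anchors the joint distribution. The
#' count of such invariant rejectors is estimated as the minimum, over the
#' two experiments, of the number of ants that evaluated the poor site at
#' least once and did not commit to it.
#'
#' @param result_a,result_b Two [run_experiment()] results with the same
#'   colony size.
#' @return Integer count.
#' @export
high_threshold_count <- function(result_a, result_b) {
  stopifnot(inherits(result_a, "emigration_result"),
            inherits(result_b, "emigration_result"))
  if (result_a$config$n_ants != result_b$config$n_ants)
    stop("experiments have different colony sizes: ",
         result_a$config$n_ants, " vs ", result_b$config$n_ants)
  min(result_a$n_reject_poor, result_b$n_reject_poor)
}

#' Constructed joint probability of accepting the good nest in both contexts
#'
#' Decomposes the joint into the invariant high-threshold rejectors (fraction
#' `h`, who choose the good site in both experiments by necessity) plus an
#' independence term for the remaining ants:
#' `p_joint = h + (p_a - h) (p_b - h)`.
#' A raw value outside the Frechet bounds (the construction is heuristic) is
#' clipped into them with a warning, so downstream contextuality computations
#' receive a valid joint.
#'
#' @param result_a,result_b Two [run_experiment()] results of the linked pair.
#' @return An object of class `"joint_estimate"`: `p_joint`, `p_a`, `p_b`,
#'   `h`, `n_high`, `n_ants`, `method`.
#' @export
joint_accept_good <- function(result_a, result_b) {
  n_high <- high_threshold_count(result_a, result_b)
  n <- result_a$config$n_ants
  h <- n_high / n
  p_a <- result_a$n_commit_good / n
  p_b <- result_b$n_commit_good / n
  if (p_a - h < -TOL || p_b - h < -TOL)
    stop(sprintf(
      "negative remainder in high-threshold decomposition (p_a = %.4f, p_b = %.4f, h = %.4f)",
      p_a, p_b, h))
  raw <- h + (p_a - h) * (p_b - h)
  lo <- max(0, p_a + p_b - 1)
  hi <- min(p_a, p_b)
  p_joint <- raw
  if (raw < lo || raw > hi) {
    p_joint <- min(max(raw, lo), hi)
    warning(sprintf(
      "constructed joint %.4f outside Frechet bounds [%.4f, %.4f]; clipped",
      raw, lo, hi))
  }
  structure(
    list(p_joint = p_joint, p_a = p_a, p_b = p_b, h = h,
         n_high = n_high, n_ants = n,
         method = "high-threshold+independent"),
    class = "joint_estimate")
}

#' @export
print.joint_estimate <- function(x, ...) {
  cat(sprintf("Joint estimate (%s): p_joint = %.4f (p_a = %.4f, p_b = %.4f, h = %.4f)\n",
              x$method, x$p_joint, x$p_a, x$p_b, x$h))
  invisible(x)
}

# Collapse a result's per-ant outcomes into the four cells that determine the
# joint construction: (committed to good) x (rejected poor). Resampling n
# ants with replacement is then a single multinomial draw per replicate.
ant_cells <- function(result) {
  good <- !is.na(result$ants$final_site) & result$ants$final_site == "good"
  rej <- result$ants$evaluated_poor &
    (is.na(result$ants$final_site) | result$ants$final_site != "poor")
  c(sum(good & rej), sum(good & !rej), sum(!good & rej), sum(!good & !rej))
}

#' Bootstrap standard error of the constructed joint
#'
#' Resamples each experiment's per-ant outcomes independently (with
#' replacement, at the original colony size) and recomputes the
#' high-threshold joint for each replicate. Because the joint depends on the
#' per-ant data only through the four cells (committed-to-good x
#' rejected-poor), each resample reduces to a multinomial draw, which keeps
#' even 100,000 replicates cheap.
#'
#' @param result_a,result_b Two [run_experiment()] results of the linked pair.
#' @param reps Number of bootstrap resamples (the study uses 100,000).
#' @param seed Integer seed for the resampling stream.
#' @return The bootstrap standard error (a single number), with the vector of
#'   replicate joints in attribute `"replicates"`.
#' @export
bootstrap_joint_se <- function(result_a, result_b, reps = 100000L, seed = 1L) {
  if (reps < 1) stop("'reps' must be at least 1")
  n <- result_a$config$n_ants
  if (n != result_b$config$n_ants) stop("experiments have different colony sizes")
  set.seed(seed)
  ca <- ant_cells(result_a)
  cb <- ant_cells(result_b)
  ra <- stats::rmultinom(reps, n, ca / n)
  rb <- stats::rmultinom(reps, n, cb / n)
  p_a <- (ra[1L, ] + ra[2L, ]) / n
  p_b <- (rb[1L, ] + rb[2L, ]) / n
  h <- pmin(ra[1L, ] + ra[3L, ], rb[1L, ] + rb[3L, ]) / n
  pj <- h + (p_a - h) * (p_b - h)
  se <- stats::sd(pj)
  attr(se, "replicates") <- pj
  se
}
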