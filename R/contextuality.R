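#' Product correlation of two Bernoulli outcomes from marginals and joint
#'
#' With outcomes coded +1 (superior nest accepted) and -1 (not accepted), the
#' expectation of the product of the two coded outcomes is determined by the
#' two marginals and the joint acceptance probability:
#' `E = 1 - 2 p_a - 2 p_b + 4 p_joint`. This is the correlation entering the
#' CHSH-type expression for the cycle.
#'
#' @param p_a,p_b Marginal acceptance probabilities.
#' @param p_joint Probability of acceptance in both experiments; must satisfy
#'   the Frechet bounds versus the marginals.
#' @param label Label used in error messages.
#' @return The product expectation, a number in `[-1, 1]`.
#' @export
#' @examples
#' correlation_from_joint(0.78, 0.68, 0.51)  # 0.12
correlation_from_joint <- function(p_a, p_b, p_joint, label = "pair") {
  check_probability(p_a, paste0("p_a of ", label))
  check_probability(p_b, paste0("p_b of ", label))
  check_probability(p_joint, paste0("p_joint of ", label))
  check_frechet(p_a, p_b, p_joint, label)
  1 - 2 * p_a - 2 * p_b + 4 * p_joint
}

#' Maximal odd-signed sum of cycle correlations
#'
#' `s_odd` is the maximum, over all sign patterns with an odd number of minus
#' signs, of the signed sum of the cycle's n correlations. For rank 4 with
#' correlations `(E1, E2, E3, -E4)` attaining the maximum, this is the CHSH
#' expression `|E1 + E2 + E3 - E4|` maximised over which term is negated.
#'
#' The closed form used here: the sum of `|E_k|` if an odd number of the `E_k`
#' are negative, otherwise that sum minus twice the smallest `|E_k|` (one term
#' must absorb the remaining forced minus sign).
#'
#' @param E Numeric vector of n >= 3 correlations in `[-1, 1]`.
#' @return The maximal odd-signed sum; at most `n`.
#' @export
#' @examples
#' s_odd(c(1, 1, 1, -1))            # 4: maximal, intransitive cycle
#' s_odd(c(1, 1, 1, 1))             # 2: one minus forced onto a +1
#' s_odd(c(-0.06, 0.12, 0.06, 0.08)) # 0.32
s_odd <- function(E) {
  if (length(E) == 0L) stop("'E' must not be empty")
  if (length(E) < 3L) stop("a cyclic system has rank at least 3")
  check_expectation(E, "correlations 'E'")
  s <- sum(abs(E))
  if (sum(E < 0) %% 2L == 1L) s else s - 2 * min(abs(E))
}

#' Inconsistent-connectedness measure of a cyclic system
#'
#' The measure of inconsistent connectedness (Type I contextuality) is the sum
#' over linked pairs of the absolute difference of the content's marginal
#' expectation across its two contexts: `Delta = sum_k |m_A(k) - m_B(k)|`,
#' where `m = 2p - 1` is the expectation of the +1/-1 coded outcome. It is
#' zero exactly when every content has identical marginals in both of its
#' contexts (consistent connectedness).
#'
#' @param m_pairs A list (or n x 2 matrix) of n pairs of marginal expectations
#'   in `[-1, 1]`.
#' @return Non-negative number.
#' @export
#' @examples
#' delta_icc(list(c(0.00, 0.58), c(0.56, 0.36), c(0.38, 0.16), c(0.18, -0.02)))
delta_icc <- function(m_pairs) {
  if (is.matrix(m_pairs)) m_pairs <- asplit(m_pairs, 1L)
  m <- vapply(m_pairs, function(p) {
    stopifnot(length(p) == 2L)
    check_expectation(p, "marginal expectations")
    abs(p[1L] - p[2L])
  }, numeric(1))
  sum(m)
}

#' Sign transitivity of cycle correlations
#'
#' A cyclic system is f-sign transitive when the first n - 1 correlations all
#' share one sign s and the closing correlation has that same sign s. Breach
#' of sign transitivity is necessary (not sufficient) for the maximal
#' violation of the CHSH-type inequality. An exact zero breaks the
#' shared-sign premise and the system is reported as not sign transitive.
#'
#' @param E Numeric vector of n >= 3 correlations.
#' @return `TRUE` or `FALSE`.
#' @export
#' @examples
#' is_sign_transitive(c(1, 1, 1, 1))    # TRUE
#' is_sign_transitive(c(1, 1, 1, -1))   # FALSE: intransitive cycle
is_sign_transitive <- function(E) {
  if (length(E) < 3L) stop("a cyclic system has rank at least 3")
  check_expectation(E, "correlations 'E'")
  if (any(E == 0)) return(FALSE)
  s <- sign(E[1L])
  all(sign(E) == s)
}

#' Contextuality report for a cyclic system
#'
#' Computes, for a cyclic system of rank n with correlations `E` and marginal
#' expectations `m`:
#' \describe{
#'   \item{`dC_chsh`}{`s_odd(E) - (n - 2)`: positive iff the classical
#'     CHSH-type bound for consistently connected systems is violated.}
#'   \item{`dC_cbd`}{`s_odd(E) - (n - 2) - Delta`: the
#'     Contextuality-by-Default criterion corrected for inconsistent
#'     connectedness; positive iff the system is truly (Type II) contextual.}
#' }
#' `Delta` is summed over the n linked same-content pairs, so by construction
#' `dC_cbd = dC_chsh - Delta` and `dC_cbd <= dC_chsh`.
#'
#' Violation flags use strict positivity with a `1e-9` tolerance, so a system
#' exactly on the boundary (`dC = 0`) counts as a non-violation.
#'
#' @param system A [cyclic_system()].
#' @return An object of class `"contextuality_report"`: a list with elements
#'   `rank`, `E`, `m` (2n marginal expectations, pair-ordered), `s_odd`,
#'   `delta`, `dC_chsh`, `dC_cbd`, `sign_transitive`, `type1` (inconsistently
#'   connected), `type2` (truly contextual).
#' @export
#' @examples
#' contextuality_report(pr_box_system())
contextuality_report <- function(system) {
  stopifnot(inherits(system, "cyclic_system"))
  n <- system$rank
  E <- vapply(seq_len(n), function(k) {
    p <- system$pairs[[k]]
    correlation_from_joint(p$p_a, p$p_b, p$p_joint, label = p$label_content)
  }, numeric(1))
  m_pairs <- lapply(system$pairs, function(p) c(2 * p$p_a - 1, 2 * p$p_b - 1))
  so <- s_odd(E)
  delta <- delta_icc(m_pairs)
  dC_chsh <- so - (n - 2)
  dC_cbd <- dC_chsh - delta
  structure(
    list(rank = n,
         E = E,
         m = unlist(m_pairs),
         s_odd = so,
         delta = delta,
         dC_chsh = dC_chsh,
         dC_cbd = dC_cbd,
         sign_transitive = is_sign_transitive(E),
         type1 = delta > TOL,
         type2 = dC_cbd > TOL),
    class = "contextuality_report")
}

#' @export
print.contextuality_report <- function(x, ...) {
  cat(sprintf("Contextuality report (cyclic system, rank %d)\n", x$rank))
  cat("  E:      ", paste(sprintf("% .4f", x$E), collapse = " "), "\n")
  cat(sprintf("  s_odd = %.4f, Delta = %.4f\n", x$s_odd, x$delta))
  cat(sprintf("  dC (CHSH) = %.2f   dC (CbD) = %.2f\n", x$dC_chsh, x$dC_cbd))
  cat(sprintf("  sign transitive: %s\n", x$sign_transitive))
  cat(sprintf("  Type I (inconsistently connected): %s\n", x$type1))
  cat(sprintf("  Type II (truly contextual):        %s\n", x$type2))
  invisible(x)
}

#' Serialize a contextuality report to JSON
#'
#' @param report A [contextuality_report()].
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string, invisibly if written to `path`.
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "contextuality_report"))
  txt <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
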