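# Reference cyclic systems with known contextuality status. These serve as
# oracle surfaces for the contextuality statistics and the coupling
# feasibility oracle: a classical mixture must always come out
# noncontextual, the PR box and the Tsirel'son system contextual, and the
# intransitive ice-cream preference cycle attains the algebraic maximum of
# the CHSH expression.

#' Intransitive ice-cream preference cycle
#'
#' Encodes a deterministic, principled but intransitive set of pairwise
#' preferences over four ice creams - double-fudge chocolate beats double
#' chocolate, which beats chocolate, which beats pistachio, which in turn
#' beats double-fudge chocolate (taste decides small differences in reflux
#' potential; large differences flip the criterion to pain avoidance).
#'
#' Each of the four pairwise comparisons is a linked pair with deterministic
#' +1/-1 variables that agree on the three transitive edges (E = +1) and
#' disagree on the cycle-closing edge (E = -1), the minimal deterministic
#' construction realizing the preference pattern. The CHSH expression
#' attains its algebraic maximum of four, exceeding the Tsirel'son bound
#' `2 * sqrt(2)`, and the system is not sign transitive.
#'
#' @return A rank-4 [cyclic_system()].
#' @export
#' @examples
#' contextuality_report(ice_cream_system())$s_odd  # 4
ice_cream_system <- function() {
  flavours <- c("double-fudge", "double-chocolate", "chocolate", "pistachio")
  p_a <- c(1, 1, 1, 1)
  p_b <- c(1, 1, 1, 0)
  p_j <- c(1, 1, 1, 0)
  pairs <- lapply(seq_len(4L), function(k) {
    nxt <- if (k == 4L) 1L else k + 1L
    linked_pair(paste0(flavours[k], ">", flavours[nxt]),
                c(flavours[k], flavours[nxt]),
                p_a = p_a[k], p_b = p_b[k], p_joint = p_j[k])
  })
  cyclic_system(pairs)
}

#' PR-box reference system
#'
#' The consistently connected rank-4 system with uniform marginals and
#' correlations `(1, 1, 1, -1)`: the maximal algebraic violation of the
#' CHSH-type bound with zero inconsistent connectedness.
#'
#' @return A rank-4 [cyclic_system()].
#' @export
pr_box_system <- function() {
  E <- c(1, 1, 1, -1)
  abstract_system((E + 1) / 4)
}

#' Tsirel'son-bound reference system
#'
#' Zero marginals with correlations `(1, 1, 1, -1) * sqrt(2) / 2`, so the
#' CHSH expression equals the quantum-mechanical maximum `2 * sqrt(2)`.
#'
#' @return A rank-4 [cyclic_system()].
#' @export
tsirelson_system <- function() {
  E <- sqrt(2) / 2 * c(1, 1, 1, -1)
  abstract_system((E + 1) / 4)
}

# rank-4 system with p_a = p_b = 1/2 and given joints, labelled q1..q4/c1..c4
abstract_system <- function(p_joint) {
  n <- length(p_joint)
  pairs <- lapply(seq_len(n), function(k) {
    nxt <- if (k == n) 1L else k + 1L
    linked_pair(paste0("q", k), paste0("c", c(k, nxt)),
                p_a = 0.5, p_b = 0.5, p_joint = p_joint[k])
  })
  cyclic_system(pairs)
}

#' Classical mixture system (negative control)
#'
#' Builds a rank-4 cyclic system as a mixture of the 16 deterministic
#' assignments of +1/-1 values to the four context labels; pair k then
#' observes the values of contexts k and k + 1. Any such mixture admits a
#' joint distribution by construction, so the coupling oracle must report it
#' noncontextual. The uniform mixture gives all-zero correlations and
#' marginals; a point mass gives `|E| = 1` everywhere with `s_odd = 2`.
#'
#' @param weights Probability vector of length 16 over the deterministic
#'   assignments (rows of `expand.grid` over four +1/-1 values); defaults to
#'   the uniform mixture.
#' @return A rank-4 [cyclic_system()].
#' @export
#' @examples
#' noncontextual_lp_oracle(classical_mixture_system())$noncontextual  # TRUE
classical_mixture_system <- function(weights = rep(1 / 16, 16)) {
  if (length(weights) != 16L || any(weights < 0) || any(is.na(weights)))
    stop("'weights' must be 16 non-negative numbers")
  tot <- sum(weights)
  if (tot <= 0) stop("'weights' must have positive sum")
  w <- weights / tot
  assign <- as.matrix(expand.grid(rep(list(c(-1, 1)), 4L),
                                  KEEP.OUT.ATTRS = FALSE))
  pairs <- lapply(seq_len(4L), function(k) {
    nxt <- if (k == 4L) 1L else k + 1L
    va <- assign[, k]; vb <- assign[, nxt]
    linked_pair(paste0("q", k), paste0("c", c(k, nxt)),
                p_a = sum(w[va == 1]),
                p_b = sum(w[vb == 1]),
                p_joint = sum(w[va == 1 & vb == 1]))
  })
  cyclic_system(pairs)
}
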