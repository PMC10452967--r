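# Deterministic infinite-population colony-choice model.
#
# In the infinite-population limit a colony selects a site 100% of the time
# even if only a bare majority of individual ants prefers it, so the model
# produces binary outcomes: the winner is the superior site iff the
# individual acceptance probability H is at least 1/2 (ties resolve to the
# superior site). The continuous dynamic below only shapes the *duration* of
# the decision; the winner is fixed by H alone.
#
# Compartments (fractions of the colony):
#   h  at home (inactive);       u  scouting;
#   cw committed to the winning site;  cl committed to the losing site.
# Flows, with recruitment rate alpha_s and leak rate alpha:
#   h'  = -alpha_s h + alpha u
#   u'  =  alpha_s h - (alpha_s + alpha) u + alpha_s cw cl
#   cw' =  alpha_s Hw u
#   cl' =  alpha_s (1 - Hw) u - alpha_s cw cl
# Scouts are activated at rate alpha_s, give up and return home at the leak
# rate alpha, and commit to the two sites in proportion Hw : (1 - Hw), where
# Hw is the individual preference for the winning site. Ants committed to the
# minority site are poached by recruiters of the majority site (mass-action
# term alpha_s cw cl), so the winner's committed fraction tends to 1.

#' Parameters of the infinite-population colony-choice model
#'
#' @param H Probability that an individual ant accepts the superior site.
#' @param alpha_s Recruitment rate: rate of movement to a nest site per unit
#'   time (> 0).
#' @param alpha Leak rate: rate at which scouting ants return to the home
#'   nest (>= 0). Affects the duration, never the outcome.
#' @param z Initial scout fraction in (0, 1]. Affects the duration, never the
#'   outcome.
#' @return An object of class `"ode_params"`.
#' @export
ode_params <- function(H, alpha_s = 0.46, alpha = 0.1, z = 0.2) {
  check_probability(H, "H")
  stopifnot(alpha_s >= 0, alpha >= 0, z > 0, z <= 1)
  structure(list(H = H, alpha_s = alpha_s, alpha = alpha, z = z),
            class = "ode_params")
}

#' Winner of an infinite-population choice
#'
#' +1 (superior site) iff `H >= 0.5`, else -1 (inferior site). The tie at
#' exactly 0.5 resolves to the superior site.
#'
#' @param H Individual acceptance probability of the superior site.
#' @return +1 or -1.
#' @export
#' @examples
#' outcome_sign(0.49)  # -1: preference reversal
#' outcome_sign(0.50)  # +1
outcome_sign <- function(H) {
  check_probability(H, "H")
  if (H >= 0.5) 1 else -1
}

#' Run the infinite-population colony-choice model
#'
#' Integrates the compartment model described above until 90% of the colony
#' is committed to the winning site.
#'
#' @param params An [ode_params()].
#' @param t_max Upper bound on integration time (model time units).
#' @return An object of class `"ode_outcome"`: `winner` (+1 superior / -1
#'   inferior), `select_prob_superior` (exactly 0 or 1), and `duration`
#'   (time until the winning site's committed fraction reaches 0.9).
#' @export
#' @examples
#' run_colony_ode(ode_params(H = 0.79, alpha_s = 0.46))
run_colony_ode <- function(params, t_max = 1e6) {
  stopifnot(inherits(params, "ode_params"))
  if (params$alpha_s <= 0)
    stop("alpha_s = 0: no recruitment, the colony never commits")
  w <- outcome_sign(params$H)
  Hw <- if (w > 0) params$H else 1 - params$H
  deriv <- function(t, y, p) {
    h <- y[1L]; u <- y[2L]; cw <- y[3L]; cl <- y[4L]
    poach <- p$alpha_s * cw * cl
    list(c(-p$alpha_s * h + p$alpha * u,
           p$alpha_s * h - (p$alpha_s + p$alpha) * u + poach,
           p$alpha_s * Hw * u,
           p$alpha_s * (1 - Hw) * u - poach))
  }
  root <- function(t, y, p) y[3L] - 0.9
  y0 <- c(h = 1 - params$z, u = params$z, cw = 0, cl = 0)
  sol <- deSolve::lsodar(y0, times = c(0, t_max), func = deriv,
                         parms = params, rootfunc = root)
  tr <- attr(sol, "troot")
  if (is.null(tr) || length(tr) == 0L)
    stop("winning-site commitment did not reach 0.9 within t_max")
  structure(
    list(winner = w,
         select_prob_superior = if (w > 0) 1 else 0,
         duration = tr[1L],
         params = params),
    class = "ode_outcome")
}

#' @export
print.ode_outcome <- function(x, ...) {
  cat(sprintf("Colony ODE outcome: winner = %s, duration = %.2f\n",
              if (x$winner > 0) "superior (+1)" else "inferior (-1)",
              x$duration))
  invisible(x)
}

#' Zero-noise cyclic system from eight individual acceptance probabilities
#'
#' Maps the eight experiments' individual acceptance probabilities H to the
#' deterministic colony outcomes of the infinite-population model and builds
#' the rank-4 cyclic system of the study design. Because each outcome is a
#' 0/1 probability, the joint of a linked pair is the product of the two
#' outcomes: the joint of anything with 0 is 0, and the joint of 1 and 1
#' is 1.
#'
#' @param H_list Numeric vector of 8 acceptance probabilities, ordered as the
#'   study's experiments 1 to 8.
#' @return A list with `outcomes` (eight values, +1/-1), `p` (the 0/1
#'   acceptance probabilities), and `system` (a [cyclic_system()] with
#'   deterministic joints).
#' @export
#' @examples
#' zn <- zero_noise_cyclic_outcomes(reference_summary()$p_accept_good)
#' contextuality_report(zn$system)  # dC_chsh = 2, dC_cbd = 0
zero_noise_cyclic_outcomes <- function(H_list) {
  if (length(H_list) != 8L)
    stop("'H_list' must contain exactly 8 acceptance probabilities")
  o <- vapply(H_list, outcome_sign, numeric(1))
  p <- (o + 1) / 2
  design <- build_design()
  pairs <- lapply(seq_len(4L), function(k) {
    a <- design$linkage$exp_a[k]; b <- design$linkage$exp_b[k]
    linked_pair(design$linkage$content[k],
                c(design$experiments$context[a], design$experiments$context[b]),
                p_a = p[a], p_b = p[b], p_joint = p[a] * p[b])
  })
  list(outcomes = o, p = p, system = cyclic_system(pairs))
}
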