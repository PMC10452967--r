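# internal validation helpers

TOL <- 1e-9  # boundary classification tolerance, see methods vignette

check_probability <- function(p, what) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < -TOL || p > 1 + TOL)
    stop(sprintf("%s must be a probability in [0, 1], got %s", what,
                 format(p)), call. = FALSE)
  invisible(TRUE)
}

check_frechet <- function(p_a, p_b, p_joint, label) {
  lo <- max(0, p_a + p_b - 1)
  hi <- min(p_a, p_b)
  if (p_joint < lo - TOL || p_joint > hi + TOL)
    stop(sprintf(
      "Frechet bounds violated for pair '%s': p_joint = %g outside [%g, %g] given p_a = %g, p_b = %g",
      label, p_joint, lo, hi, p_a, p_b), call. = FALSE)
  invisible(TRUE)
}

check_expectation <- function(m, what) {
  if (!is.numeric(m) || anyNA(m) || any(abs(m) > 1 + TOL))
    stop(sprintf("%s must lie in [-1, 1]", what), call. = FALSE)
  invisible(TRUE)
}
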