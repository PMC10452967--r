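# Orchestration of the full study: the 8-experiment design, both models,
# the assembled rank-4 cyclic system and its contextuality reports.

#' The eight-experiment study design
#'
#' Four superior ("object") nest qualities q1-q4 = 5, 5.5, 6, 6.5 and four
#' inferior ("context") nest qualities c1-c4 = 3.1, 3.6, 4.1, 4.6, arranged
#' so that each superior nest is presented in two contexts and consecutive
#' linked pairs share a context, forming a single 4-cycle:
#'
#' | experiment | 1 | 2 | 3 | 4 | 5 | 6 | 7 | 8 |
#' |---|---|---|---|---|---|---|---|---|
#' | poor | 4.6 | 3.1 | 3.1 | 3.6 | 3.6 | 4.1 | 4.1 | 4.6 |
#' | good | 6.5 | 6.5 | 5 | 5 | 5.5 | 5.5 | 6 | 6 |
#'
#' Linked pairs (sharing the good nest): (1,2) = q4, (3,4) = q1, (5,6) = q2,
#' (7,8) = q3.
#'
#' @return An object of class `"design_matrix"`: `objects` and `contexts`
#'   (named quality vectors), `experiments` (a data frame with the poor/good
#'   qualities and their labels), and `linkage` (the four linked pairs with
#'   their shared content and the chained contexts).
#' @export
#' @examples
#' build_design()$experiments
build_design <- function() {
  objects <- c(q1 = 5, q2 = 5.5, q3 = 6, q4 = 6.5)
  contexts <- c(c1 = 3.1, c2 = 3.6, c3 = 4.1, c4 = 4.6)
  experiments <- data.frame(
    experiment = 1:8,
    quality_poor = c(4.6, 3.1, 3.1, 3.6, 3.6, 4.1, 4.1, 4.6),
    quality_good = c(6.5, 6.5, 5, 5, 5.5, 5.5, 6, 6))
  experiments$content <- names(objects)[match(experiments$quality_good, objects)]
  experiments$context <- names(contexts)[match(experiments$quality_poor, contexts)]
  linkage <- data.frame(
    pair = 1:4,
    exp_a = c(1L, 3L, 5L, 7L),
    exp_b = c(2L, 4L, 6L, 8L))
  linkage$content <- experiments$content[linkage$exp_a]
  structure(list(objects = objects, contexts = contexts,
                 experiments = experiments, linkage = linkage),
            class = "design_matrix")
}

#' Reference summary values of the original simulation study
#'
#' The published per-experiment summary of the agent-based emigration runs at
#' n = 10,000 that this package reimplements: acceptance probabilities of the
#' good site (also used as the individual acceptance probabilities H of the
#' infinite-population model), switch rates, durations, and the four
#' constructed joint probabilities of the linked pairs. These numbers are
#' inputs for the worked examples and the desk-scale acceptance checks.
#'
#' @return A list with `p_accept_good` (8), `switch_rate` (8),
#'   `duration_min` (8), `p_joint` (4, ordered as linked pairs (1,2), (3,4),
#'   (5,6), (7,8)), and `n_ants`.
#' @export
#' @examples
#' ref <- reference_summary()
#' report_from_table(ref$p_accept_good, ref$p_joint)
reference_summary <- function() {
  list(
    p_accept_good = c(0.50, 0.79, 0.78, 0.68, 0.69, 0.58, 0.59, 0.49),
    switch_rate = c(0.18, 0.46, 0.50, 0.40, 0.38, 0.28, 0.27, 0.18),
    duration_min = c(131, 206, 497, 526, 247, 231, 168, 163),
    p_joint = c(0.38, 0.51, 0.40, 0.31),
    n_ants = 10000L)
}

#' Contextuality report from a printed summary table
#'
#' Direct worked-example entry point bypassing simulation: builds the study's
#' rank-4 cyclic system from eight acceptance probabilities and the four
#' joints of the linked pairs, then computes the contextuality report.
#'
#' @param p_accept Numeric vector of 8 acceptance probabilities (experiments
#'   1-8).
#' @param p_joint Numeric vector of 4 joint probabilities for linked pairs
#'   (1,2), (3,4), (5,6), (7,8).
#' @param n_ants Colony size recorded on the pairs (for provenance only).
#' @return A [contextuality_report()].
#' @export
#' @examples
#' ref <- reference_summary()
#' rep <- report_from_table(ref$p_accept_good, ref$p_joint)
#' rep$dC_chsh  # -1.68
report_from_table <- function(p_accept, p_joint, n_ants = 10000L) {
  if (length(p_accept) != 8L) stop("'p_accept' must have length 8")
  if (length(p_joint) != 4L) stop("'p_joint' must have length 4")
  design <- build_design()
  pairs <- lapply(seq_len(4L), function(k) {
    a <- design$linkage$exp_a[k]; b <- design$linkage$exp_b[k]
    linked_pair(design$linkage$content[k],
                c(design$experiments$context[a], design$experiments$context[b]),
                p_a = p_accept[a], p_b = p_accept[b], p_joint = p_joint[k],
                n_a = n_ants, n_b = n_ants)
  })
  contextuality_report(cyclic_system(pairs))
}

# bootstrap both dC statistics by resampling all eight experiments' per-ant
# cell counts (multinomial trick, see bootstrap_joint_se)
bootstrap_dc_se <- function(results, design, reps, seed) {
  set.seed(seed)
  n <- results[[1L]]$config$n_ants
  cells <- lapply(results, ant_cells)
  draws <- lapply(cells, function(cc) stats::rmultinom(reps, n, cc / n))
  p <- vapply(draws, function(d) (d[1L, ] + d[2L, ]) / n, numeric(reps))
  rej <- vapply(draws, function(d) (d[1L, ] + d[3L, ]) / n, numeric(reps))
  E <- matrix(0, reps, 4L)
  D <- numeric(reps)
  for (k in seq_len(4L)) {
    a <- design$linkage$exp_a[k]; b <- design$linkage$exp_b[k]
    h <- pmin(rej[, a], rej[, b])
    pj <- h + (p[, a] - h) * (p[, b] - h)
    pj <- pmin(pmax(pj, pmax(0, p[, a] + p[, b] - 1)), pmin(p[, a], p[, b]))
    E[, k] <- 1 - 2 * p[, a] - 2 * p[, b] + 4 * pj
    D <- D + abs(2 * p[, a] - 2 * p[, b])
  }
  absE <- abs(E)
  sodd <- rowSums(absE) -
    2 * ifelse(rowSums(E < 0) %% 2 == 1, 0, apply(absE, 1L, min))
  list(se_dC_chsh = stats::sd(sodd - 2),
       se_dC_cbd = stats::sd(sodd - 2 - D))
}

#' Run the complete study
#'
#' Runs the eight Monte-Carlo emigration experiments of [build_design()],
#' constructs the four linked-pair joints with bootstrap standard errors,
#' assembles the rank-4 cyclic system and its contextuality report, and runs
#' the zero-noise infinite-population model on the simulated acceptance
#' probabilities for comparison. Bootstrap standard errors for both dC
#' statistics are obtained by resampling all eight experiments.
#'
#' @param n_ants Colony size per experiment.
#' @param seed Root seed; per-experiment seeds and the bootstrap stream are
#'   derived from it, so the whole study is reproducible end to end.
#' @param bootstrap_reps Bootstrap resamples per joint (the study design uses
#'   100,000).
#' @param design A [build_design()] object (override for scaled-down runs
#'   only; the qualities are the study's conditions).
#' @param ... Further arguments passed to [experiment_config()] (e.g.
#'   `threshold_mean`, `assessment_error_sd`).
#' @return An object of class `"run_report"`: `summary` (the per-experiment
#'   table), `joints` (four [joint_accept_good()] estimates with bootstrap
#'   SEs), `system`, `report_mc` (Monte-Carlo contextuality report with
#'   bootstrap SEs attached as `se_dC_chsh`, `se_dC_cbd`), `zero_noise`
#'   (the infinite-population outcomes and report), `seeds`, and `results`
#'   (the raw per-experiment results).
#' @export
#' @examples
#' rr <- run_study(n_ants = 200, seed = 42, bootstrap_reps = 500)
#' rr$report_mc$dC_chsh
run_study <- function(n_ants = 10000L, seed = 1L, bootstrap_reps = 100000L,
                      design = build_design(), ...) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 10L)
  exps <- design$experiments
  results <- lapply(seq_len(nrow(exps)), function(i) {
    run_experiment(experiment_config(
      quality_poor = exps$quality_poor[i],
      quality_good = exps$quality_good[i],
      n_ants = n_ants, seed = seeds[i], ...))
  })
  summary <- summarize_experiments(results)
  summary$content <- exps$content
  summary$context <- exps$context

  joints <- lapply(seq_len(4L), function(k) {
    a <- design$linkage$exp_a[k]; b <- design$linkage$exp_b[k]
    est <- joint_accept_good(results[[a]], results[[b]])
    est$se <- as.numeric(bootstrap_joint_se(results[[a]], results[[b]],
                                            reps = bootstrap_reps,
                                            seed = seeds[9L] + k))
    est
  })

  pairs <- lapply(seq_len(4L), function(k) {
    a <- design$linkage$exp_a[k]; b <- design$linkage$exp_b[k]
    linked_pair(design$linkage$content[k],
                c(exps$context[a], exps$context[b]),
                p_a = joints[[k]]$p_a, p_b = joints[[k]]$p_b,
                p_joint = joints[[k]]$p_joint,
                n_a = n_ants, n_b = n_ants)
  })
  system <- cyclic_system(pairs)
  report_mc <- contextuality_report(system)
  dc_se <- bootstrap_dc_se(results, design,
                           reps = min(bootstrap_reps, 20000L),
                           seed = seeds[10L])
  report_mc$se_dC_chsh <- dc_se$se_dC_chsh
  report_mc$se_dC_cbd <- dc_se$se_dC_cbd

  H <- summary$p_accept_good
  zn <- zero_noise_cyclic_outcomes(H)
  zero_noise <- list(outcomes = zn$outcomes,
                     report = contextuality_report(zn$system))

  structure(
    list(summary = summary,
         joints = joints,
         system = system,
         report_mc = report_mc,
         zero_noise = zero_noise,
         seeds = seeds,
         n_ants = n_ants,
         results = results,
         version = as.character(utils::packageVersion("antcontext")),
         timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)),
    class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Nest-choice contextuality study (n = %d per experiment)\n\n",
              x$n_ants))
  print(x$summary[, c("experiment", "quality_poor", "quality_good",
                      "p_accept_good", "switch_rate", "duration_min")],
        row.names = FALSE)
  cat("\nJoint probabilities of accepting the good nest in both contexts:\n")
  for (k in seq_along(x$joints))
    cat(sprintf("  pair %d (%s): %.4f +/- %.5f\n", k,
                x$system$pairs[[k]]$label_content,
                x$joints[[k]]$p_joint, x$joints[[k]]$se))
  cat(sprintf("\nMonte-Carlo:  dC (CHSH) = %.2f +/- %.4f   dC (CbD) = %.2f +/- %.4f\n",
              x$report_mc$dC_chsh, x$report_mc$se_dC_chsh,
              x$report_mc$dC_cbd, x$report_mc$se_dC_cbd))
  cat(sprintf("Zero-noise:   dC (CHSH) = %.2f             dC (CbD) = %.2f\n",
              x$zero_noise$report$dC_chsh, x$zero_noise$report$dC_cbd))
  invisible(x)
}
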