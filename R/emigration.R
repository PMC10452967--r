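# Agent-based Monte-Carlo simulator of forced nest emigration.
#
# A colony of n ants is forced out of an uninhabitable home nest (quality
# -1000) and chooses between a nearby inferior nest ("poor", site A) and a
# distant superior nest ("good", site B). Each ant carries a fixed acceptance
# threshold drawn from a normal distribution; every evaluation of a site is
# perturbed by fresh normal assessment noise; an ant commits - irreversibly -
# to the first site whose perceived quality reaches its threshold.
#
# Time advances in discrete decision epochs. In one epoch an ant at site X
# checks the three candidate sites in random order; each is discovered
# independently with probability discovery_prob[X, Y]; the first discovery
# wins, costs travel_time[X, Y] seconds, and is evaluated. If nothing is
# discovered the ant waits one second and redraws next epoch. Diagonal
# travel-time entries are one-second "stay" epochs (re-assessment of the
# current site).

SITE_LEVELS <- c("old", "poor", "good")

#' Default travel-time matrix (seconds)
#'
#' Mean travel times between the home nest and the two candidate sites,
#' derived from a walking speed of 8.4 mm/s; diagonal entries are one-second
#' stay epochs.
#'
#' @return A 3 x 3 numeric matrix with dimnames `old`, `poor`, `good`.
#' @export
default_travel_time <- function() {
  matrix(c(1, 36, 143,
           36, 1, 116,
           143, 116, 1),
         nrow = 3, byrow = TRUE,
         dimnames = list(SITE_LEVELS, SITE_LEVELS))
}

#' Default site-discovery probability matrix
#'
#' Entry `[X, Y]` is the independent per-epoch probability that an ant
#' currently at site X discovers site Y. Rows intentionally do not sum to 1:
#' in each epoch the candidate sites are checked in random order and the
#' first success is the site discovered; with some probability nothing is
#' discovered and the ant redraws next epoch.
#'
#' The values derive from the published "probabilities of finding nests"
#' table, whose rows list the nest *being found* and whose columns list the
#' searcher's current location; this matrix is stored in `[from, to]`
#' orientation (the transpose). That orientation is the only one consistent
#' with the published switch rates: from the home nest the poor and good
#' sites are found at 0.06 and 0.03 per epoch, so about one third of ants
#' discover the good (far) site first.
#'
#' @return A 3 x 3 numeric matrix with dimnames `old`, `poor`, `good`.
#' @export
default_discovery_prob <- function() {
  found <- matrix(c(0.91, 0.15, 0.03,   # finding old  from old/poor/good
                    0.06, 0.80, 0.06,   # finding poor from old/poor/good
                    0.03, 0.05, 0.91),  # finding good from old/poor/good
                  nrow = 3, byrow = TRUE,
                  dimnames = list(SITE_LEVELS, SITE_LEVELS))
  t(found)
}

#' Configuration of one emigration experiment
#'
#' @param quality_poor,quality_good True qualities of the nearby (inferior)
#'   and distant (superior) candidate nests, on the same scale as the
#'   acceptance thresholds.
#' @param n_ants Colony size.
#' @param quality_old Quality of the destroyed home nest; the default -1000
#'   makes it uninhabitable, so ants never commit to it.
#' @param threshold_mean,threshold_sd Parameters of the normal distribution of
#'   individual acceptance thresholds (fixed per ant for its lifetime).
#' @param assessment_error_sd Standard deviation of the fresh normal noise
#'   added to the true quality at every evaluation event.
#' @param travel_time 3 x 3 matrix of travel times in seconds, rows/columns
#'   ordered old, poor, good.
#' @param discovery_prob 3 x 3 matrix of per-epoch discovery probabilities.
#' @param seed Integer seed making the run reproducible.
#' @param max_time Per-ant time budget in seconds; ants whose clock exceeds it
#'   uncommitted are reported in `n_uncommitted` rather than looping forever.
#'   The default is ten times the longest duration observed across the study
#'   design.
#' @return An object of class `"experiment_config"`.
#' @export
#' @examples
#' cfg <- experiment_config(3.1, 6.5, n_ants = 500, seed = 1)
experiment_config <- function(quality_poor, quality_good,
                              n_ants = 10000L,
                              quality_old = -1000,
                              threshold_mean = 5,
                              threshold_sd = 1,
                              assessment_error_sd = 1,
                              travel_time = default_travel_time(),
                              discovery_prob = default_discovery_prob(),
                              seed = 1L,
                              max_time = 10 * 526 * 60) {
  stopifnot(is.numeric(quality_poor), is.numeric(quality_good),
            n_ants >= 1, threshold_sd > 0, assessment_error_sd >= 0,
            is.matrix(travel_time), all(dim(travel_time) == c(3L, 3L)),
            all(travel_time >= 0),
            is.matrix(discovery_prob), all(dim(discovery_prob) == c(3L, 3L)),
            all(discovery_prob >= 0), all(discovery_prob <= 1),
            max_time > 0)
  structure(
    list(quality_old = quality_old,
         quality_poor = quality_poor,
         quality_good = quality_good,
         n_ants = as.integer(n_ants),
         threshold_mean = threshold_mean,
         threshold_sd = threshold_sd,
         assessment_error_sd = assessment_error_sd,
         travel_time = unname(travel_time),
         discovery_prob = unname(discovery_prob),
         seed = as.integer(seed),
         max_time = max_time),
    class = "experiment_config")
}

#' Draw individual acceptance thresholds
#'
#' Thresholds are normally distributed across the colony and fixed for an
#' ant's lifetime.
#'
#' @param n Number of ants.
#' @param mean,sd Normal distribution parameters (`sd > 0`).
#' @return Numeric vector of length `n`.
#' @export
sample_thresholds <- function(n, mean, sd) {
  if (n <= 0) stop("'n' must be positive")
  if (sd <= 0) stop("'sd' must be positive")
  stats::rnorm(n, mean, sd)
}

#' Evaluate a site against an ant's threshold
#'
#' The ant perceives `true_quality` plus a fresh draw of normal assessment
#' noise and accepts iff the perceived quality reaches its threshold.
#'
#' @param true_quality True quality of the site.
#' @param threshold The ant's fixed acceptance threshold.
#' @param error_sd Assessment noise standard deviation (>= 0).
#' @param n Number of independent evaluation events to draw.
#' @return Logical vector: `TRUE` = accept.
#' @export
#' @examples
#' set.seed(1)
#' mean(evaluate_site(5, 5, 1, n = 1e4))  # ~0.5: symmetric noise at threshold
evaluate_site <- function(true_quality, threshold, error_sd, n = 1L) {
  if (error_sd < 0) stop("'error_sd' must be non-negative")
  true_quality + stats::rnorm(n, 0, error_sd) >= threshold
}

#' Initial state of a single ant
#'
#' @param threshold The ant's acceptance threshold.
#' @return An object of class `"ant_state"`: location (`"old"`, `"poor"`,
#'   `"good"`), one of the five phases (evaluating home/inferior/superior
#'   site, committed to inferior/superior site), the first non-home site
#'   discovered, and the ant's clock in seconds.
#' @export
ant_state <- function(threshold) {
  structure(
    list(threshold = threshold,
         location = "old",
         phase = "evaluating home site",
         first_site_found = NA_character_,
         clock = 0),
    class = "ant_state")
}

ant_committed <- function(ant) startsWith(ant$phase, "committed")

#' Advance one ant by one decision epoch
#'
#' Single-ant reference implementation of the transition rule described above;
#' [run_experiment()] applies the identical rule to all uncommitted ants
#' simultaneously. Committed phases are absorbing, so stepping a committed
#' ant is an error.
#'
#' @param ant An [ant_state()].
#' @param config An [experiment_config()].
#' @return The updated `ant_state`.
#' @export
step_ant <- function(ant, config) {
  stopifnot(inherits(ant, "ant_state"), inherits(config, "experiment_config"))
  if (ant_committed(ant))
    stop("cannot step a committed ant: committed phases are absorbing")
  loc <- match(ant$location, SITE_LEVELS)
  qual <- c(config$quality_old, config$quality_poor, config$quality_good)
  order3 <- sample.int(3L)
  found <- 0L
  for (s in order3) {
    if (stats::runif(1) < config$discovery_prob[loc, s]) { found <- s; break }
  }
  if (found == 0L) {
    ant$clock <- ant$clock + 1
    return(ant)
  }
  ant$clock <- ant$clock + config$travel_time[loc, found]
  if (found > 1L && is.na(ant$first_site_found))
    ant$first_site_found <- SITE_LEVELS[found]
  accept <- found > 1L &&
    evaluate_site(qual[found], ant$threshold, config$assessment_error_sd)
  ant$location <- SITE_LEVELS[found]
  ant$phase <- if (accept) {
    if (found == 2L) "committed to inferior site" else "committed to superior site"
  } else {
    c("evaluating home site", "evaluating inferior site",
      "evaluating superior site")[found]
  }
  ant
}

#' Run one emigration experiment
#'
#' Simulates the whole colony until every ant has committed (or exhausted
#' `max_time`). The random-number stream is seeded from `config$seed`, so
#' identical configurations give bit-identical results.
#'
#' @param config An [experiment_config()].
#' @return An object of class `"emigration_result"`: commitment counts
#'   (`n_commit_good`, `n_commit_poor`, `n_uncommitted`), `n_reject_poor`
#'   (ants that evaluated the poor site at least once and did not commit to
#'   it), `n_switch_to_good` (ants whose first discovered site was the poor
#'   one but that committed to the good one), `n_first_poor`, `duration_min`
#'   (minutes until the last commitment), the per-ant table `ants`
#'   (threshold, first site, final site, poor-site evaluation flag, clock),
#'   the seed and the config.
#' @export
#' @examples
#' res <- run_experiment(experiment_config(3.1, 6.5, n_ants = 300, seed = 7))
#' res$n_commit_good / res$config$n_ants
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  set.seed(config$seed)
  n <- config$n_ants
  qual <- c(config$quality_old, config$quality_poor, config$quality_good)
  disc <- config$discovery_prob
  trav <- config$travel_time
  perms <- rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                 c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))

  threshold <- sample_thresholds(n, config$threshold_mean, config$threshold_sd)
  loc <- rep(1L, n)
  clock <- numeric(n)
  first <- integer(n)        # 0 = none yet, 2 = poor, 3 = good
  eval_poor <- logical(n)
  committed <- integer(n)    # 0 = active, 2 = poor, 3 = good
  active <- seq_len(n)

  while (length(active) > 0L) {
    k <- length(active)
    l <- loc[active]
    # discovery: check the three sites in random order, first success wins
    pid <- sample.int(6L, k, replace = TRUE)
    s1 <- perms[pid, 1L]; s2 <- perms[pid, 2L]; s3 <- perms[pid, 3L]
    u <- matrix(stats::runif(3L * k), k, 3L)
    f1 <- u[, 1L] < disc[cbind(l, s1)]
    f2 <- u[, 2L] < disc[cbind(l, s2)]
    f3 <- u[, 3L] < disc[cbind(l, s3)]
    site <- ifelse(f1, s1, ifelse(f2, s2, ifelse(f3, s3, 0L)))
    dt <- ifelse(site > 0L, trav[cbind(l, pmax(site, 1L))], 1)
    clock[active] <- clock[active] + dt

    idx <- which(site > 0L)
    accept <- logical(k)
    if (length(idx) > 0L) {
      noise <- stats::rnorm(length(idx), 0, config$assessment_error_sd)
      accept[idx] <- qual[site[idx]] + noise >= threshold[active][idx] &
        site[idx] > 1L
    }
    newfirst <- site > 1L & first[active] == 0L
    first[active[newfirst]] <- site[newfirst]
    eval_poor[active[site == 2L]] <- TRUE
    committed[active[accept]] <- site[accept]
    moved <- !accept & site > 0L
    loc[active[moved]] <- site[moved]
    active <- active[!accept]
    if (length(active) > 0L)
      active <- active[clock[active] < config$max_time]
  }

  done <- committed > 0L
  ants <- data.frame(
    ant = seq_len(n),
    threshold = threshold,
    first_site = c(NA, SITE_LEVELS)[first + 1L],
    final_site = c(NA, SITE_LEVELS)[committed + 1L],
    evaluated_poor = eval_poor,
    clock = clock)
  structure(
    list(n_commit_good = sum(committed == 3L),
         n_commit_poor = sum(committed == 2L),
         n_uncommitted = sum(!done),
         n_reject_poor = sum(eval_poor & committed != 2L),
         n_switch_to_good = sum(first == 2L & committed == 3L),
         n_first_poor = sum(first == 2L),
         duration_min = if (any(done)) max(clock[done]) / 60 else 0,
         ants = ants,
         seed = config$seed,
         config = config),
    class = "emigration_result")
}

#' @export
print.emigration_result <- function(x, ...) {
  n <- x$config$n_ants
  cat(sprintf("Emigration run (n = %d, poor = %g, good = %g, seed = %d)\n",
              n, x$config$quality_poor, x$config$quality_good, x$seed))
  cat(sprintf("  P(accept good) = %.4f  P(accept poor) = %.4f\n",
              x$n_commit_good / n, x$n_commit_poor / n))
  cat(sprintf("  rejected poor: %d  switched to good: %d / %d first-poor\n",
              x$n_reject_poor, x$n_switch_to_good, x$n_first_poor))
  cat(sprintf("  duration: %.0f min  uncommitted: %d\n",
              x$duration_min, x$n_uncommitted))
  invisible(x)
}

#' Summarise a list of emigration experiments
#'
#' One row per experiment: acceptance probability of the good site with its
#' proportion standard error, the switch rate (fraction of ants that
#' discovered the poor site first but committed to the good one), the
#' duration, and the poor-site rejection count used by the high-threshold
#' joint construction.
#'
#' @param results A list of [run_experiment()] results.
#' @return A `data.frame`.
#' @export
summarize_experiments <- function(results) {
  if (length(results) == 0L) stop("need at least one result")
  stopifnot(all(vapply(results, inherits, logical(1), "emigration_result")))
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    n <- r$config$n_ants
    p <- r$n_commit_good / n
    data.frame(
      experiment = i,
      quality_poor = r$config$quality_poor,
      quality_good = r$config$quality_good,
      n_ants = n,
      p_accept_good = round(p, 4),
      se_p = proportion_se(p, n),
      switch_rate = if (r$n_first_poor > 0) r$n_switch_to_good / r$n_first_poor else 0,
      n_reject_poor = r$n_reject_poor,
      duration_min = r$duration_min,
      n_uncommitted = r$n_uncommitted)
  })
  do.call(rbind, rows)
}
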