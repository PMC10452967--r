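#' Linked pair of experiments sharing a content
#'
#' A linked pair records one measured content (here: the identity of the
#' superior, far nest) observed in two different contexts (the two inferior,
#' near nests it was paired with), together with the marginal probability of
#' accepting the superior nest in each experiment and a constructed joint
#' probability of accepting it in both.
#'
#' The three probabilities must satisfy the Frechet bounds
#' `max(0, p_a + p_b - 1) <= p_joint <= min(p_a, p_b)`; otherwise no bivariate
#' Bernoulli distribution with these marginals and joint exists.
#'
#' @param label_content Character label of the shared content (e.g. `"q4"`).
#' @param labels_context Character vector of length 2 naming the two contexts
#'   (e.g. `c("c4", "c1")`).
#' @param p_a,p_b Marginal acceptance probabilities in the two experiments.
#' @param p_joint Probability of acceptance in both experiments.
#' @param n_a,n_b Number of simulated ants in each experiment (used for
#'   standard errors; may be `NA` for abstract systems).
#'
#' @return An object of class `"linked_pair"`.
#' @seealso [cyclic_system()], [correlation_from_joint()]
#' @export
#' @examples
#' linked_pair("q1", c("c1", "c2"), p_a = 0.78, p_b = 0.68, p_joint = 0.51)
linked_pair <- function(label_content, labels_context, p_a, p_b, p_joint,
                        n_a = NA_integer_, n_b = NA_integer_) {
  stopifnot(is.character(label_content), length(label_content) == 1L,
            is.character(labels_context), length(labels_context) == 2L)
  check_probability(p_a, paste0("p_a of pair '", label_content, "'"))
  check_probability(p_b, paste0("p_b of pair '", label_content, "'"))
  check_probability(p_joint, paste0("p_joint of pair '", label_content, "'"))
  check_frechet(p_a, p_b, p_joint, label_content)
  structure(
    list(label_content = label_content,
         labels_context = labels_context,
         p_a = p_a, p_b = p_b, p_joint = p_joint,
         n_a = as.integer(n_a), n_b = as.integer(n_b)),
    class = "linked_pair")
}

#' Cyclic system of linked experiment pairs
#'
#' A cyclic system of rank n consists of n linked pairs whose context labels
#' chain cyclically: the second context of pair k is the first context of pair
#' k + 1 (wrapping around). Rank 4 is the CHSH scenario.
#'
#' @param pairs A list of [linked_pair()] objects, in cycle order.
#' @return An object of class `"cyclic_system"` with elements `rank` and
#'   `pairs`.
#' @export
#' @examples
#' pr_box_system()
cyclic_system <- function(pairs) {
  if (!is.list(pairs) || length(pairs) < 3L)
    stop("a cyclic system needs at least 3 linked pairs")
  if (!all(vapply(pairs, inherits, logical(1), "linked_pair")))
    stop("all elements of 'pairs' must be linked_pair objects")
  n <- length(pairs)
  for (k in seq_len(n)) {
    nxt <- if (k == n) 1L else k + 1L
    if (pairs[[k]]$labels_context[2L] != pairs[[nxt]]$labels_context[1L])
      stop(sprintf(
        "context labels do not chain: pair %d ends in '%s' but pair %d starts in '%s'",
        k, pairs[[k]]$labels_context[2L], nxt, pairs[[nxt]]$labels_context[1L]))
  }
  structure(list(rank = n, pairs = pairs), class = "cyclic_system")
}

#' @export
print.cyclic_system <- function(x, ...) {
  cat(sprintf("Cyclic system of rank %d\n", x$rank))
  for (k in seq_len(x$rank)) {
    p <- x$pairs[[k]]
    cat(sprintf("  %s in (%s, %s): p_a = %.4f, p_b = %.4f, p_joint = %.4f\n",
                p$label_content, p$labels_context[1L], p$labels_context[2L],
                p$p_a, p$p_b, p$p_joint))
  }
  invisible(x)
}

#' @export
print.linked_pair <- function(x, ...) {
  cat(sprintf("Linked pair %s in (%s, %s): p_a = %.4f, p_b = %.4f, p_joint = %.4f\n",
              x$label_content, x$labels_context[1L], x$labels_context[2L],
              x$p_a, x$p_b, x$p_joint))
  invisible(x)
}

#' Serialize a cyclic system to JSON
#'
#' @param system A [cyclic_system()].
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly if written to `path`.
#' @export
system_to_json <- function(system, path = NULL) {
  stopifnot(inherits(system, "cyclic_system"))
  doc <- list(
    rank = system$rank,
    pairs = lapply(system$pairs, function(p) {
      list(label_content = p$label_content,
           labels_context = p$labels_context,
           p_a = p$p_a, p_b = p$p_b, p_joint = p$p_joint,
           n_a = p$n_a, n_b = p$n_b)
    }))
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null",
                          na = "null")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Read a cyclic system from JSON
#'
#' @param json A JSON string or path to a JSON file produced by
#'   [system_to_json()].
#' @return A [cyclic_system()].
#' @export
system_from_json <- function(json) {
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  pairs <- lapply(doc$pairs, function(p) {
    linked_pair(p$label_content, unlist(p$labels_context),
                p$p_a, p$p_b, p$p_joint,
                n_a = if (is.null(p$n_a)) NA_integer_ else p$n_a,
                n_b = if (is.null(p$n_b)) NA_integer_ else p$n_b)
  })
  sys <- cyclic_system(pairs)
  if (sys$rank != doc$rank) stop("rank field disagrees with number of pairs")
  sys
}
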