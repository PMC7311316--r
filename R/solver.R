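#' Score one expanded path
#'
#' The primary score of a path is the lowest confidence of any of its
#' steps. Ties between paths are broken by a secondary score that weights
#' low-, medium- and high-confidence steps by -2, -0.1 and +1, then by
#' preferring the longer path. The secondary score is computed in tenths
#' (scaled integers) so 0.1-accumulation cannot produce spurious
#' floating-point ties.
#'
#' @param confidences character vector of step tiers along the path.
#' @return list with \code{primary} (tier name), \code{secondary}
#'   (numeric), \code{secondary10} (exact, in tenths) and \code{length}.
#' @export
score_path <- function(confidences) {
  if (length(confidences) == 0L) stop("empty path")
  r <- conf_rank(confidences)
  if (any(r == 0L)) stop("path contains non-candidate tier 'none'")
  n_high <- sum(r == 3L); n_med <- sum(r == 2L); n_low <- sum(r == 1L)
  secondary10 <- 10L * n_high - 1L * n_med - 20L * n_low
  list(primary = conf_from_rank(min(r)), secondary = secondary10 / 10,
       secondary10 = secondary10, length = length(confidences))
}

#' Select the best path for a pathway
#'
#' Expands the pathway into its concrete alternative routes, scores each
#' against the per-step confidences, and picks the winner: highest
#' primary tier, then highest secondary score, then the longer path, then
#' (residual ties) the first in deterministic expansion order.
#'
#' @param pathway a \code{pathway_definition}.
#' @param step_results named list of \code{step_result}s (or a named
#'   character vector of tiers) covering every step used in any
#'   expansion.
#' @param cap expansion cap (see \code{\link{expand_paths}}).
#' @return a \code{path_result}: list with \code{pathway_id},
#'   \code{step_ids}, \code{confidences}, \code{primary_confidence},
#'   \code{secondary_score}, \code{length}, \code{rules_used} (rule ids
#'   on the chosen expansion) and \code{expansion_index}.
#' @export
best_path <- function(pathway, step_results, cap = 10000L) {
  paths <- expand_paths(pathway, cap = cap)
  tier_of <- function(step_id) {
    sr <- step_results[[step_id]]
    if (is.null(sr)) stop("no step result for step '", step_id, "'")
    if (is.character(sr)) sr else sr$confidence
  }
  best <- NULL
  for (k in seq_along(paths)) {
    steps <- as.character(paths[[k]])
    confs <- vapply(steps, tier_of, "")
    sc <- score_path(confs)
    key <- c(conf_rank(sc$primary), sc$secondary10, sc$length)
    if (is.null(best) || key_greater(key, best$key)) {
      best <- list(key = key, steps = steps, confs = confs, sc = sc, index = k,
                   rules = attr(paths[[k]], "rules"))
    }
  }
  structure(list(pathway_id = pathway$pathway_id, step_ids = best$steps,
                 confidences = unname(best$confs),
                 primary_confidence = best$sc$primary,
                 secondary_score = best$sc$secondary,
                 length = best$sc$length,
                 rules_used = best$rules,
                 expansion_index = best$index),
            class = "path_result")
}

# strict lexicographic greater-than over numeric keys
key_greater <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] > b[i]) return(TRUE)
    if (a[i] < b[i]) return(FALSE)
  }
  FALSE
}

#' @export
print.path_result <- function(x, ...) {
  cat("Best path for pathway '", x$pathway_id, "' (", x$primary_confidence,
      ", secondary ", format(x$secondary_score), "):\n  ",
      paste(paste0(x$step_ids, "[", substr(x$confidences, 1, 1), "]"),
            collapse = " -> "), "\n", sep = "")
  invisible(x)
}

#' Check cross-pathway requirements
#'
#' A requirement links a pathway (scope \code{all}) or one of its
#' subpathway rules to a step of another pathway. When the scoped rule is
#' actually used on its pathway's selected best path, a
#' \code{MUST_BE_PRESENT} requirement is violated if the required step is
#' not found at medium-or-better confidence, and a
#' \code{MUST_NOT_BE_PRESENT} requirement is violated if the required
#' step sits on the other pathway's best path at medium-or-better
#' confidence (mutually exclusive route selections, e.g. running
#' transsulfuration in both directions).
#'
#' @param best_paths named list of \code{path_result}s keyed by pathway
#'   id.
#' @param step_results nested named list: \code{step_results[[pathway_id]][[step_id]]}
#'   is a \code{step_result} or tier name.
#' @param pathways named list of \code{pathway_definition}s.
#' @return character vector of warning messages (empty when all
#'   requirements hold).
#' @export
check_requirements <- function(best_paths, step_results, pathways) {
  warnings <- character()
  tier_of <- function(pid, sid) {
    sr <- step_results[[pid]][[sid]]
    if (is.null(sr)) return("low")
    if (is.character(sr)) sr else sr$confidence
  }
  for (p in pathways) {
    bp <- best_paths[[p$pathway_id]]
    if (is.null(bp)) next
    for (req in p$requirements) {
      if (!req$scope %in% bp$rules_used) next
      if (is.null(pathways[[req$req_pathway]]) || is.null(best_paths[[req$req_pathway]]))
        next
      tier <- tier_of(req$req_pathway, req$req_step)
      if (req$polarity == "MUST_BE_PRESENT") {
        if (conf_rank(tier) < conf_rank("medium"))
          warnings <- c(warnings, paste0(
            "pathway '", p$pathway_id, "' (rule '", req$scope, "') requires step '",
            req$req_step, "' of pathway '", req$req_pathway,
            "', which is only ", tier, " confidence"))
      } else {
        on_best <- req$req_step %in% best_paths[[req$req_pathway]]$step_ids
        if (on_best && conf_rank(tier) >= conf_rank("medium"))
          warnings <- c(warnings, paste0(
            "pathway '", p$pathway_id, "' (rule '", req$scope,
            "') is incompatible with step '", req$req_step, "' of pathway '",
            req$req_pathway, "' being on its best path"))
      }
    }
  }
  warnings
}

#' Gaps on a best path
#'
#' A gap is a step on the selected best path whose confidence is below
#' high.
#'
#' @param path_result a \code{path_result}.
#' @return data.frame \code{step_id}, \code{confidence} of the gap steps.
#' @export
path_gaps <- function(path_result) {
  idx <- conf_rank(path_result$confidences) < conf_rank("high")
  data.frame(step_id = path_result$step_ids[idx],
             confidence = path_result$confidences[idx],
             stringsAsFactors = FALSE)
}
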