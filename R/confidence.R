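#' Confidence tiers
#'
#' Candidates, steps and paths are scored on a three-level ordinal scale:
#' \code{"high"}, \code{"medium"}, \code{"low"}. Internally tiers are
#' compared by rank (high = 3, medium = 2, low = 1); \code{"none"} (rank 0)
#' marks a hit that does not qualify as a candidate at all.
#'
#' @param conf character vector of tier names.
#' @return \code{conf_rank} returns an integer vector of ranks;
#'   \code{conf_max}/\code{conf_min} return a single tier name.
#' @keywords internal
#' @name confidence
NULL

.conf_levels <- c(none = 0L, low = 1L, medium = 2L, high = 3L)

conf_rank <- function(conf) {
  r <- .conf_levels[conf]
  if (anyNA(r)) stop("unknown confidence tier: ", paste(conf[is.na(r)], collapse = ", "))
  unname(r)
}

conf_from_rank <- function(rank) {
  names(.conf_levels)[match(rank, .conf_levels)]
}

conf_max <- function(conf) {
  if (length(conf) == 0L) return("none")
  conf_from_rank(max(conf_rank(conf)))
}

conf_min <- function(conf) {
  if (length(conf) == 0L) return("none")
  conf_from_rank(min(conf_rank(conf)))
}
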