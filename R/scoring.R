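#' Engine configuration
#'
#' All thresholds of the engine with their defaults: search acceptance
#' (30\% identity, E < 0.01), the high-confidence rule (identity > 40\%,
#' subject coverage > 80\%, bit score at least 10 bits above the other
#' hit), the two medium routes (identity > 40\% with coverage > 70\%
#' regardless of the other hit; identity > 30\% with coverage > 80\% and a
#' bit score above the other hit), the low-confidence floor (coverage >=
#' 50\%), split joining (+10 bit margin per part, subject-coordinate
#' overlap at most 20\% of either alignment, combined coverage >= 70\%),
#' the HMM high rule (model coverage >= 80\% and the other hit under 40\%
#' identity or under 75\% coverage), the relevant-region filter (other
#' hits must overlap at least 50\% of the candidate's relevant region),
#' and genome relatedness (marker hits at >= 50\% identity and >= 70\%
#' coverage; related when >= 10 one-to-one hits with median identity >=
#' 75\%). All coverages are measured on the subject/model side.
#'
#' @param ... named overrides of the defaults.
#' @return named list of configuration values.
#' @export
default_config <- function(...) {
  cfg <- list(
    min_identity = 30, max_evalue = 0.01, backend = "builtin",
    high_identity = 40, high_coverage = 0.80, high_margin = 10,
    medium_identity = 40, medium_coverage = 0.70,
    medium2_identity = 30, medium2_coverage = 0.80,
    low_coverage = 0.50,
    split_margin = 10, split_max_overlap = 0.20, split_min_coverage = 0.70,
    hmm_high_coverage = 0.80, hmm_other_identity = 40, hmm_other_coverage = 0.75,
    region_min_overlap = 0.50, region_filter = TRUE,
    related_min_identity = 50, related_min_coverage = 0.70,
    related_min_hits = 10, related_median_identity = 75,
    expansion_cap = 10000L, seed = 1L)
  overrides <- list(...)
  if (length(overrides) > 0L) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad) > 0L) stop("unknown config option(s): ", paste(bad, collapse = ", "))
    cfg[names(overrides)] <- overrides
  }
  cfg
}

subject_coverage <- function(hit) (hit$s_end - hit$s_start + 1) / hit$subject_length

#' Find the "other" hit constraining a candidate
#'
#' The other hit is a candidate protein's best-scoring alignment to a
#' reference protein with a different function: among the candidate's
#' hits against the full characterized database, hits to proteins that
#' match the step or are on its ignore list are disregarded, and hits
#' whose query-side alignment overlaps less than half of the candidate's
#' relevant region are disregarded too (this region restriction is what
#' lets a fusion protein score highly for both of its activities). The
#' survivor with the highest bit score, if any, is returned.
#'
#' @param candidate_protein protein id of the candidate.
#' @param region list/row with \code{start}, \code{end}: the relevant
#'   region on the candidate (the step alignment's query range, or the
#'   HMM hit's query envelope).
#' @param step_queries \code{step_query_set} for the step.
#' @param all_db_hits the candidate genome's alignment hits against the
#'   full characterized database (search thresholds already applied).
#' @param protein_length length of the candidate protein (for bounds
#'   checking of \code{region}).
#' @param config engine configuration (\code{\link{default_config}}).
#' @return one-row data.frame (\code{subject_id}, \code{bit_score},
#'   \code{percent_identity}, \code{subject_coverage}) or \code{NULL}.
#' @export
find_other_hit <- function(candidate_protein, region, step_queries, all_db_hits,
                           protein_length = NULL, config = default_config()) {
  if (!is.null(protein_length) &&
      (region$start < 1L || region$end > protein_length || region$start > region$end))
    stop("relevant region [", region$start, ", ", region$end,
         "] outside protein bounds (length ", protein_length, ")")
  h <- all_db_hits[all_db_hits$query_id == candidate_protein, , drop = FALSE]
  if (nrow(h) == 0L) return(NULL)
  step_ids <- c(step_queries$characterized$protein_id,
                step_queries$curated_only$protein_id, step_queries$ignored)
  h <- h[!(h$subject_id %in% step_ids), , drop = FALSE]
  if (nrow(h) == 0L) return(NULL)
  if (isTRUE(config$region_filter)) {
    rlen <- region$end - region$start + 1
    ov <- pmax(0, pmin(h$q_end, region$end) - pmax(h$q_start, region$start) + 1)
    h <- h[ov >= config$region_min_overlap * rlen, , drop = FALSE]
    if (nrow(h) == 0L) return(NULL)
  }
  best <- h[order(-h$bit_score, h$subject_id), , drop = FALSE][1L, , drop = FALSE]
  data.frame(subject_id = best$subject_id, bit_score = best$bit_score,
             percent_identity = best$percent_identity,
             subject_coverage = subject_coverage(best),
             stringsAsFactors = FALSE)
}

#' Classify an alignment-based candidate into a confidence tier
#'
#' High confidence requires similarity to an experimentally characterized
#' protein: identity over 40\%, alignment covering over 80\% of the
#' subject, and a bit score at least 10 bits above the other hit (absent
#' other hit counts as satisfied). Medium confidence is reached either
#' with identity over 40\% and coverage over 70\% (regardless of the
#' other hit) or with identity over 30\%, coverage over 80\%, and a bit
#' score above the other hit's. Hits covering at least half the subject
#' are low confidence. Curated-only subjects can never justify high
#' confidence. The highest applicable tier is returned, or \code{"none"}
#' when the hit does not qualify as a candidate at all.
#'
#' @param hit one alignment hit (row with \code{percent_identity},
#'   \code{bit_score} and either \code{subject_coverage} or
#'   \code{s_start}/\code{s_end}/\code{subject_length}).
#' @param subject_status \code{"CHARACTERIZED"} or \code{"CURATED_ONLY"}.
#' @param other other hit as returned by \code{\link{find_other_hit}}, or
#'   \code{NULL}.
#' @param config engine configuration.
#' @return \code{"high"}, \code{"medium"}, \code{"low"} or \code{"none"}.
#' @export
classify_blast_candidate <- function(hit, subject_status, other = NULL,
                                     config = default_config()) {
  cov <- if (!is.null(hit$subject_coverage)) hit$subject_coverage else subject_coverage(hit)
  id <- hit$percent_identity
  bits <- hit$bit_score
  other_bits <- if (is.null(other)) -Inf else other$bit_score
  if (subject_status == "CHARACTERIZED" &&
      id > config$high_identity && cov > config$high_coverage &&
      bits >= other_bits + config$high_margin)
    return("high")
  if ((id > config$medium_identity && cov > config$medium_coverage) ||
      (id > config$medium2_identity && cov > config$medium2_coverage &&
       bits > other_bits))
    return("medium")
  if (cov >= config$low_coverage) return("low")
  "none"
}

#' Classify an HMM-based candidate into a confidence tier
#'
#' Any hit above the profile's trusted cutoff is at least medium
#' confidence. It is high confidence when the alignment covers at least
#' 80\% of the model and the other hit (if any) is under 40\% identity or
#' under 75\% coverage.
#'
#' @param hit one HMM hit (row from \code{\link{search_hmms}}).
#' @param other other hit or \code{NULL}.
#' @param config engine configuration.
#' @return \code{"high"} or \code{"medium"}.
#' @export
classify_hmm_candidate <- function(hit, other = NULL, config = default_config()) {
  cov <- (hit$hmm_end - hit$hmm_start + 1) / hit$model_length
  other_ok <- is.null(other) ||
    other$percent_identity < config$hmm_other_identity ||
    other$subject_coverage < config$hmm_other_coverage
  if (cov >= config$hmm_high_coverage && other_ok) "high" else "medium"
}

#' Join two low-coverage hits into a split candidate
#'
#' Two distinct proteins aligned to the same reference protein are joined
#' when each part scores at least 10 bits above its own other hit, the
#' two alignments overlap by at most 20\% of either alignment's subject
#' span, and together they cover at least 70\% of the reference protein.
#' The joined candidate's identity is the alignment-length-weighted mean
#' of the part identities, and it is kept only if its confidence tier
#' exceeds that of both components.
#'
#' @param part_hits two-row data.frame of alignment hits of two different
#'   proteins to the same subject.
#' @param others list of two (other hit or \code{NULL}), one per part.
#' @param subject_status status of the shared subject.
#' @param component_confidences optional character vector of the two
#'   parts' own tiers for this step (\code{"none"} if a part is not a
#'   candidate on its own); when supplied, the join is rejected unless it
#'   outranks both.
#' @param config engine configuration.
#' @return list describing the joined candidate (\code{parts},
#'   \code{subject_id}, \code{percent_identity}, \code{subject_coverage},
#'   \code{bit_score}, \code{confidence}) or \code{NULL} if the parts are
#'   not joined.
#' @export
join_split_candidates <- function(part_hits, others, subject_status = "CHARACTERIZED",
                                  component_confidences = NULL,
                                  config = default_config()) {
  stopifnot(nrow(part_hits) == 2L)
  if (part_hits$query_id[1] == part_hits$query_id[2]) return(NULL)
  if (part_hits$subject_id[1] != part_hits$subject_id[2])
    stop("split parts must align to the same subject")
  for (i in 1:2) {
    other_bits <- if (is.null(others[[i]])) -Inf else others[[i]]$bit_score
    if (part_hits$bit_score[i] < other_bits + config$split_margin) return(NULL)
  }
  span <- part_hits$s_end - part_hits$s_start + 1
  ov <- max(0, min(part_hits$s_end) - max(part_hits$s_start) + 1)
  if (ov > config$split_max_overlap * min(span)) return(NULL)
  slen <- part_hits$subject_length[1]
  combined_cov <- (sum(span) - ov) / slen
  if (combined_cov < config$split_min_coverage) return(NULL)
  # alignment-length-weighted mean identity of the parts
  alen <- part_hits$q_end - part_hits$q_start + 1
  combined_id <- sum(part_hits$percent_identity * alen) / sum(alen)
  conf <- classify_blast_candidate(
    list(percent_identity = combined_id, subject_coverage = combined_cov,
         bit_score = sum(part_hits$bit_score)),
    subject_status, other = NULL, config = config)
  if (conf == "none") return(NULL)
  if (!is.null(component_confidences) &&
      conf_rank(conf) <= max(conf_rank(component_confidences)))
    return(NULL)
  ord <- order(part_hits$s_start)
  list(parts = part_hits$query_id[ord], subject_id = part_hits$subject_id[1],
       percent_identity = combined_id, subject_coverage = combined_cov,
       bit_score = sum(part_hits$bit_score), confidence = conf)
}

#' Score a step from its candidates
#'
#' The confidence of a step is the confidence of its best candidate;
#' steps with no candidates at all are low confidence, which keeps paths
#' with gaps in consideration. Candidates are ordered by tier, then
#' descending bit score, then protein id.
#'
#' @param step a step definition (for the id and description).
#' @param candidates data.frame of candidates for this step (possibly
#'   zero rows) with at least \code{confidence}, \code{bit_score},
#'   \code{parts} columns.
#' @return a \code{step_result}: list with \code{step_id},
#'   \code{confidence}, \code{candidates} (sorted data.frame).
#' @export
score_step <- function(step, candidates) {
  if (is.null(candidates) || nrow(candidates) == 0L) {
    candidates <- empty_candidates()
    conf <- "low"
  } else {
    candidates <- candidates[order(-conf_rank(candidates$confidence),
                                   -candidates$bit_score, candidates$parts), ,
                             drop = FALSE]
    rownames(candidates) <- NULL
    conf <- candidates$confidence[1]
  }
  structure(list(step_id = step$step_id, confidence = conf, candidates = candidates),
            class = "step_result")
}

empty_candidates <- function() {
  data.frame(step_id = character(), parts = character(), origin = character(),
             confidence = character(), percent_identity = numeric(),
             subject_coverage = numeric(), bit_score = numeric(),
             subject_id = character(), other_id = character(),
             other_bit_score = numeric(), other_identity = numeric(),
             other_coverage = numeric(), stringsAsFactors = FALSE)
}

candidate_row <- function(step_id, parts, origin, confidence, identity, coverage,
                          bits, subject_id, other) {
  data.frame(step_id = step_id, parts = paste(parts, collapse = "+"),
             origin = origin, confidence = confidence,
             percent_identity = identity, subject_coverage = coverage,
             bit_score = bits, subject_id = subject_id,
             other_id = if (is.null(other)) NA_character_ else other$subject_id,
             other_bit_score = if (is.null(other)) NA_real_ else other$bit_score,
             other_identity = if (is.null(other)) NA_real_ else other$percent_identity,
             other_coverage = if (is.null(other)) NA_real_ else other$subject_coverage,
             stringsAsFactors = FALSE)
}

#' Find and classify every candidate for one step
#'
#' Combines the alignment route (hits of the genome's proteins to the
#' step's characterized and curated-only proteins), the HMM route (hits
#' above trusted cutoffs to the step's profiles), and split joining, each
#' constrained by the region-restricted other hit. A protein may be a
#' candidate for several steps simultaneously; steps are scored
#' independently of each other.
#'
#' @param step step definition.
#' @param step_queries the step's \code{step_query_set}.
#' @param all_db_hits alignment hits of the genome's proteins against the
#'   full reference protein database.
#' @param hmm_hits HMM hits of the genome's proteins
#'   (\code{\link{search_hmms}}), or \code{NULL}.
#' @param config engine configuration.
#' @return a \code{step_result} (see \code{\link{score_step}}).
#' @export
find_step_candidates <- function(step, step_queries, all_db_hits, hmm_hits = NULL,
                                 config = default_config()) {
  sq <- step_queries
  status_of <- c(stats::setNames(rep("CHARACTERIZED", nrow(sq$characterized)),
                                 sq$characterized$protein_id),
                 stats::setNames(rep("CURATED_ONLY", nrow(sq$curated_only)),
                                 sq$curated_only$protein_id))
  step_subject_ids <- names(status_of)
  shits <- all_db_hits[all_db_hits$subject_id %in% step_subject_ids, , drop = FALSE]

  rows <- list()
  best_by_protein <- list()  # protein -> rank of its best single-protein tier
  note <- function(protein, conf) {
    r <- conf_rank(conf)
    if (is.null(best_by_protein[[protein]]) || best_by_protein[[protein]] < r)
      best_by_protein[[protein]] <<- r
  }

  # alignment route: classify each hit; keep the best (tier, bits) per protein
  if (nrow(shits) > 0L) {
    for (protein in unique(shits$query_id)) {
      ph <- shits[shits$query_id == protein, , drop = FALSE]
      best <- NULL
      for (i in seq_len(nrow(ph))) {
        hit <- ph[i, , drop = FALSE]
        other <- find_other_hit(protein, list(start = hit$q_start, end = hit$q_end),
                                sq, all_db_hits, protein_length = hit$query_length,
                                config = config)
        conf <- classify_blast_candidate(hit, status_of[[hit$subject_id]], other, config)
        if (conf == "none") next
        cand <- candidate_row(sq$step_id, protein, "blast", conf,
                              hit$percent_identity, subject_coverage(hit),
                              hit$bit_score, hit$subject_id, other)
        if (is.null(best) || conf_rank(conf) > conf_rank(best$confidence) ||
            (conf_rank(conf) == conf_rank(best$confidence) &&
             cand$bit_score > best$bit_score))
          best <- cand
      }
      if (!is.null(best)) {
        rows[[length(rows) + 1L]] <- best
        note(protein, best$confidence)
      }
    }
  }

  # HMM route
  if (!is.null(hmm_hits) && nrow(hmm_hits) > 0L && nrow(sq$hmms) > 0L) {
    hh <- hmm_hits[hmm_hits$hmm_id %in% sq$hmms$hmm_id, , drop = FALSE]
    for (i in seq_len(nrow(hh))) {
      hit <- hh[i, , drop = FALSE]
      other <- find_other_hit(hit$query_id, list(start = hit$q_start, end = hit$q_end),
                              sq, all_db_hits, config = config)
      conf <- classify_hmm_candidate(hit, other, config)
      cov <- (hit$hmm_end - hit$hmm_start + 1) / hit$model_length
      rows[[length(rows) + 1L]] <- candidate_row(
        sq$step_id, hit$query_id, "hmm", conf, NA_real_, cov, hit$bit_score,
        hit$hmm_id, other)
      note(hit$query_id, conf)
    }
  }

  # split route: pairs of distinct proteins aligned to the same subject
  if (nrow(shits) > 0L) {
    for (subj in unique(shits$subject_id)) {
      sh <- shits[shits$subject_id == subj, , drop = FALSE]
      if (nrow(sh) < 2L) next
      combos <- utils::combn(seq_len(nrow(sh)), 2L, simplify = FALSE)
      for (pair in combos) {
        ph <- sh[pair, , drop = FALSE]
        if (ph$query_id[1] == ph$query_id[2]) next
        others <- lapply(1:2, function(i) {
          find_other_hit(ph$query_id[i],
                         list(start = ph$q_start[i], end = ph$q_end[i]),
                         sq, all_db_hits, protein_length = ph$query_length[i],
                         config = config)
        })
        comp_conf <- conf_from_rank(vapply(ph$query_id, function(p) {
          if (is.null(best_by_protein[[p]])) 0L else best_by_protein[[p]]
        }, 0L))
        joined <- join_split_candidates(ph, others, status_of[[subj]],
                                        component_confidences = comp_conf,
                                        config = config)
        if (is.null(joined)) next
        rows[[length(rows) + 1L]] <- candidate_row(
          sq$step_id, joined$parts, "split", joined$confidence,
          joined$percent_identity, joined$subject_coverage, joined$bit_score,
          joined$subject_id, NULL)
      }
    }
  }

  cands <- if (length(rows) > 0L) do.call(rbind, rows) else empty_candidates()
  score_step(list(step_id = sq$step_id), cands)
}
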