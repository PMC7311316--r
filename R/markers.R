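#' Extract ribosomal marker proteins from a proteome
#'
#' Searches the proteome against a set of single-copy marker profiles
#' (ribosomal proteins) and keeps, per marker, the single protein hitting
#' it above the trusted cutoff. Markers matched by two or more proteins
#' are dropped entirely — a duplicated marker is not a reliable witness
#' of relatedness.
#'
#' @param proteome named character vector or \code{AAStringSet}.
#' @param marker_hmms marker HMM metadata (\code{\link{read_hmm_meta}}).
#' @param genome_id identifier stored on the profile.
#' @param domain \code{"bacteria"} or \code{"archaea"}; profiles from
#'   different domains never compare as related.
#' @return a \code{marker_profile}: list with \code{genome_id},
#'   \code{domain} and \code{markers}, a named character vector mapping
#'   marker (HMM) id to one protein sequence.
#' @export
extract_markers <- function(proteome, marker_hmms, genome_id = "genome",
                            domain = "bacteria") {
  proteome <- as_aa_set(proteome, "proteome")
  markers <- character()
  if (length(proteome) > 0L && nrow(marker_hmms) > 0L) {
    hits <- search_hmms(proteome, marker_hmms)
    if (nrow(hits) > 0L) {
      seqs <- as.character(proteome)
      for (m in unique(hits$hmm_id)) {
        h <- hits[hits$hmm_id == m, , drop = FALSE]
        if (length(unique(h$query_id)) != 1L) next  # multi-copy marker: drop
        markers[[m]] <- seqs[[h$query_id[1]]]
      }
    }
  }
  if (length(markers) > 0L) markers <- markers[order(names(markers))]
  structure(list(genome_id = genome_id, domain = domain, markers = markers),
            class = "marker_profile")
}

#' Marker-based relatedness between two genomes
#'
#' For every marker present in both profiles, the two marker proteins are
#' globally aligned; hits with at least 50\% identity and at least 70\%
#' coverage are retained. Hits where one protein matches multiple
#' partners (the same sequence serving several markers) are discarded so
#' only one-to-one hits count. The genomes are related when at least 10
#' hits are retained and their median identity is at least 75\% — about
#' the same family in practice.
#'
#' @param query,reference \code{marker_profile}s.
#' @param config engine configuration (\code{related_*} thresholds).
#' @return a \code{relatedness_result}: list with \code{n_retained},
#'   \code{median_identity}, \code{related}, and a \code{hits}
#'   data.frame.
#' @export
relatedness <- function(query, reference, config = default_config()) {
  res <- function(hits) {
    n <- nrow(hits)
    med <- if (n > 0L) stats::median(hits$identity) else NA_real_
    structure(list(n_retained = n, median_identity = med,
                   related = n >= config$related_min_hits &&
                     isTRUE(med >= config$related_median_identity),
                   hits = hits),
              class = "relatedness_result")
  }
  empty <- data.frame(marker = character(), identity = numeric(),
                      coverage = numeric(), stringsAsFactors = FALSE)
  if (!identical(query$domain, reference$domain)) return(res(empty))
  shared <- intersect(names(query$markers), names(reference$markers))
  if (length(shared) == 0L) return(res(empty))
  rows <- lapply(shared, function(m) {
    al <- global_align_identity(query$markers[[m]], reference$markers[[m]])
    data.frame(marker = m, identity = al$identity, coverage = al$coverage,
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, rows)
  hits <- hits[hits$identity >= config$related_min_identity &
               hits$coverage >= config$related_min_coverage, , drop = FALSE]
  # one-to-one filter: a sequence serving several markers on either side
  # invalidates all of its hits
  if (nrow(hits) > 0L) {
    qseq <- unname(query$markers[hits$marker])
    rseq <- unname(reference$markers[hits$marker])
    keep <- !(qseq %in% qseq[duplicated(qseq)]) & !(rseq %in% rseq[duplicated(rseq)])
    hits <- hits[keep, , drop = FALSE]
  }
  rownames(hits) <- NULL
  res(hits)
}

#' @export
print.relatedness_result <- function(x, ...) {
  cat("Relatedness: ", x$n_retained, " retained marker hit(s), median identity ",
      if (is.na(x$median_identity)) "NA" else sprintf("%.1f%%", x$median_identity),
      " -> ", if (x$related) "related" else "not related", "\n", sep = "")
  invisible(x)
}

#' Read a known-gap catalog
#'
#' A catalog directory holds \code{known_gaps.tsv} (columns
#' \code{genome_id}, \code{pathway_id}, \code{step_id}) and a
#' \code{markers/} subdirectory with one protein FASTA per cataloged
#' genome (\code{<genome_id>.faa}, one sequence per marker, named by
#' marker id).
#'
#' @param dir catalog directory.
#' @param domain domain recorded on the cataloged genomes' profiles.
#' @return list with \code{entries} (data.frame) and \code{profiles}
#'   (named list of \code{marker_profile}s).
#' @export
read_known_gap_catalog <- function(dir, domain = "bacteria") {
  tsv <- file.path(dir, "known_gaps.tsv")
  if (!file.exists(tsv)) stop("missing known-gap table: ", tsv)
  entries <- utils::read.delim(tsv, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("genome_id", "pathway_id", "step_id")
  if (!all(need %in% names(entries)))
    stop("known_gaps.tsv must have columns: ", paste(need, collapse = ", "))
  profiles <- list()
  for (g in unique(entries$genome_id)) {
    faa <- file.path(dir, "markers", paste0(g, ".faa"))
    if (!file.exists(faa))
      stop("cataloged genome '", g, "' has no marker FASTA at ", faa)
    seqs <- Biostrings::readAAStringSet(faa)
    markers <- stats::setNames(as.character(seqs), names(seqs))
    profiles[[g]] <- structure(
      list(genome_id = g, domain = domain, markers = markers[order(names(markers))]),
      class = "marker_profile")
  }
  list(entries = entries, profiles = profiles)
}

#' Write a known-gap catalog (used by the fixture generator)
#'
#' @param catalog list as returned by \code{\link{read_known_gap_catalog}}.
#' @param dir destination directory.
#' @export
write_known_gap_catalog <- function(catalog, dir) {
  dir.create(file.path(dir, "markers"), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(catalog$entries, file.path(dir, "known_gaps.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (g in names(catalog$profiles)) {
    p <- catalog$profiles[[g]]
    seqs <- Biostrings::AAStringSet(p$markers)
    Biostrings::writeXStringSet(seqs, file.path(dir, "markers", paste0(g, ".faa")),
                                width = 60L)
  }
  invisible(dir)
}

#' Mark known gaps on a genome result
#'
#' Every non-high step on a selected best path is compared against the
#' catalog: if a related cataloged genome (per \code{\link{relatedness}})
#' lists the same (pathway, step) as a known gap, the step is flagged,
#' carrying the supporting genome id(s). A known gap signals that the
#' missing step likely reflects unknown biology rather than a missing
#' capability, because a relative with the same gap grows in minimal
#' medium.
#'
#' @param result a \code{genome_result} (see \code{\link{analyze_genome}}).
#' @param catalog known-gap catalog (\code{\link{read_known_gap_catalog}}).
#' @param query_profile the analyzed genome's \code{marker_profile}.
#' @param config engine configuration.
#' @return the \code{genome_result} with a \code{known_gap} column filled
#'   in its \code{gaps} table and a \code{related_genomes} element added.
#' @export
mark_known_gaps <- function(result, catalog, query_profile,
                            config = default_config()) {
  related_ids <- character()
  for (g in names(catalog$profiles)) {
    if (relatedness(query_profile, catalog$profiles[[g]], config)$related)
      related_ids <- c(related_ids, g)
  }
  gaps <- result$gaps
  gaps$known_gap <- vapply(seq_len(nrow(gaps)), function(i) {
    support <- catalog$entries$genome_id[
      catalog$entries$pathway_id == gaps$pathway_id[i] &
      catalog$entries$step_id == gaps$step_id[i] &
      catalog$entries$genome_id %in% related_ids]
    paste(sort(unique(support)), collapse = ",")
  }, "")
  result$gaps <- gaps
  result$related_genomes <- sort(related_ids)
  result
}
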