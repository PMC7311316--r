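#' Protein-vs-protein homology search
#'
#' The search contract used throughout the engine: local alignment of
#' every query against every subject, reported as tabular hits with
#' percent identity (identities over aligned columns, gap columns
#' included), bit score, E-value and 1-based alignment coordinates.
#' Only hits passing both thresholds are returned, ordered by
#' \code{query_id}, then descending bit score, then \code{subject_id}.
#'
#' Two interchangeable backends satisfy the contract: the default
#' \code{"builtin"} backend runs Smith--Waterman locally through
#' \pkg{Biostrings} (BLOSUM62, affine gap open 11 / extend 1) with a
#' Karlin--Altschul-style bit score and a size-scaled E-value; the
#' \code{"blast"} backend shells out to NCBI \code{blastp}
#' (\code{makeblastdb} + \code{blastp -outfmt 6}). The builtin backend is
#' fully deterministic and has no external dependency.
#'
#' @param queries named character vector (or \code{AAStringSet}) of query
#'   protein sequences.
#' @param subjects named character vector (or \code{AAStringSet}) of
#'   subject protein sequences.
#' @param min_identity minimum percent identity (default 30).
#' @param max_evalue maximum E-value, exclusive (default 0.01).
#' @param backend \code{"builtin"} or \code{"blast"}.
#' @return data.frame with columns \code{query_id}, \code{subject_id},
#'   \code{percent_identity}, \code{bit_score}, \code{e_value},
#'   \code{q_start}, \code{q_end}, \code{s_start}, \code{s_end},
#'   \code{query_length}, \code{subject_length}.
#' @export
search_proteins <- function(queries, subjects, min_identity = 30,
                            max_evalue = 0.01, backend = "builtin") {
  queries <- as_aa_set(queries, "queries")
  subjects <- as_aa_set(subjects, "subjects")
  if (length(queries) == 0L) stop("empty query set")
  if (length(subjects) == 0L) stop("empty subject set")
  hits <- switch(backend,
    builtin = search_proteins_builtin(queries, subjects),
    blast = search_proteins_blast(queries, subjects),
    stop("unknown search backend '", backend, "'"))
  hits <- hits[hits$percent_identity >= min_identity & hits$e_value < max_evalue, ,
               drop = FALSE]
  hits <- hits[order(hits$query_id, -hits$bit_score, hits$subject_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

as_aa_set <- function(x, what) {
  if (inherits(x, "AAStringSet")) return(x)
  if (is.character(x)) {
    if (is.null(names(x)) && length(x) > 0L)
      stop(what, " must be named (sequence ids)")
    return(Biostrings::AAStringSet(x))
  }
  stop(what, " must be a named character vector or AAStringSet")
}

# Karlin-Altschul parameters for BLOSUM62 with gap open 11 / extend 1
# (standard gapped values); exact calibration is not load-bearing: all
# decisions rest on identity/coverage/bit-margin thresholds, and the
# E-value only has to separate genuine local alignments from noise.
.ka_lambda <- 0.267
.ka_k <- 0.041

raw_to_bits <- function(raw) (.ka_lambda * raw - log(.ka_k)) / log(2)

.pkg_cache <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.pkg_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$blosum62 <- get("BLOSUM62", envir = e)
  }
  .pkg_cache$blosum62
}

search_proteins_builtin <- function(queries, subjects) {
  mat <- blosum62()
  qlen <- Biostrings::width(queries)
  slen <- Biostrings::width(subjects)
  rows <- vector("list", length(subjects))
  for (j in seq_along(subjects)) {
    pa <- Biostrings::pairwiseAlignment(
      pattern = queries, subject = subjects[[j]], type = "local",
      substitutionMatrix = mat, gapOpening = 11, gapExtension = 1)
    bits <- raw_to_bits(Biostrings::score(pa))
    ev <- qlen * slen[j] * 2^(-bits)
    pat <- Biostrings::pattern(pa)
    sub <- Biostrings::subject(pa)
    rows[[j]] <- data.frame(
      query_id = names(queries),
      subject_id = names(subjects)[j],
      percent_identity = Biostrings::pid(pa, type = "PID1"),
      bit_score = bits,
      e_value = ev,
      q_start = Biostrings::start(pat), q_end = Biostrings::end(pat),
      s_start = Biostrings::start(sub), s_end = Biostrings::end(sub),
      query_length = qlen, subject_length = slen[j],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

search_proteins_blast <- function(queries, subjects) {
  if (Sys.which("blastp") == "" || Sys.which("makeblastdb") == "")
    stop("blast backend unavailable: blastp/makeblastdb not on PATH")
  td <- tempfile("blast")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  qf <- file.path(td, "q.faa"); sf <- file.path(td, "s.faa")
  Biostrings::writeXStringSet(queries, qf)
  Biostrings::writeXStringSet(subjects, sf)
  system2("makeblastdb", c("-in", sf, "-dbtype", "prot"), stdout = FALSE, stderr = FALSE)
  out <- file.path(td, "hits.tsv")
  status <- system2("blastp", c("-query", qf, "-db", sf, "-out", out,
                                "-outfmt", shQuote(paste("6 qseqid sseqid pident bitscore",
                                                         "evalue qstart qend sstart send",
                                                         "qlen slen")),
                                "-evalue", "10", "-seg", "no"),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop("blast backend failed (blastp exit status ", status, ")")
  cols <- c("query_id", "subject_id", "percent_identity", "bit_score", "e_value",
            "q_start", "q_end", "s_start", "s_end", "query_length", "subject_length")
  if (file.size(out) == 0L) {
    hits <- as.data.frame(stats::setNames(rep(list(character()), length(cols)), cols))
    return(hits)
  }
  hits <- utils::read.delim(out, header = FALSE, col.names = cols,
                            stringsAsFactors = FALSE)
  # keep the best local alignment per query/subject pair, as the builtin does
  hits <- hits[order(hits$query_id, hits$subject_id, -hits$bit_score), , drop = FALSE]
  hits[!duplicated(hits[, c("query_id", "subject_id")]), , drop = FALSE]
}

#' Profile-HMM search above trusted cutoffs
#'
#' Searches query proteins against HMMER3 profiles via \code{hmmsearch}
#' and keeps, per (query, profile) pair, the best-scoring domain of any
#' sequence whose full-sequence bit score is at or above the profile's
#' trusted cutoff. Model coverage is computed on the profile side
#' (\code{(hmm_end - hmm_start + 1) / model_length}); the query envelope
#' coordinates delimit the relevant region used in later scoring.
#'
#' @param queries named character vector or \code{AAStringSet}.
#' @param hmms HMM metadata data.frame from \code{\link{read_hmm_meta}}
#'   (needs \code{hmm_id}, \code{model_length}, \code{trusted_cutoff},
#'   \code{path}).
#' @return data.frame with columns \code{query_id}, \code{hmm_id},
#'   \code{bit_score}, \code{q_start}, \code{q_end}, \code{hmm_start},
#'   \code{hmm_end}, \code{model_length}, ordered by \code{query_id},
#'   descending bit score, \code{hmm_id}.
#' @export
search_hmms <- function(queries, hmms) {
  queries <- as_aa_set(queries, "queries")
  empty <- data.frame(query_id = character(), hmm_id = character(),
                      bit_score = numeric(), q_start = integer(), q_end = integer(),
                      hmm_start = integer(), hmm_end = integer(),
                      model_length = integer(), stringsAsFactors = FALSE)
  if (length(queries) == 0L || is.null(hmms) || nrow(hmms) == 0L) return(empty)
  if (Sys.which("hmmsearch") == "")
    stop("hmm backend unavailable: hmmsearch not on PATH")
  td <- tempfile("hmm")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  qf <- file.path(td, "q.faa")
  Biostrings::writeXStringSet(queries, qf)
  hf <- file.path(td, "profiles.hmm")
  ok <- file.append(hf, unique(hmms$path))
  if (!all(ok)) stop("could not read profile file(s): ",
                     paste(unique(hmms$path)[!ok], collapse = ", "))
  domtbl <- file.path(td, "hits.domtbl")
  status <- system2("hmmsearch", c("--domtblout", domtbl, "--noali", "-E", "1000",
                                   "--seed", "1", hf, qf),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop("hmmsearch failed (exit status ", status, ")")
  lines <- grep("^#", readLines(domtbl, warn = FALSE), value = TRUE, invert = TRUE)
  if (length(lines) == 0L) return(empty)
  f <- strsplit(trimws(lines), "\\s+")
  hits <- data.frame(
    query_id = vapply(f, `[`, "", 1L),
    hmm_id = vapply(f, `[`, "", 4L),
    full_bits = as.numeric(vapply(f, `[`, "", 8L)),
    dom_bits = as.numeric(vapply(f, `[`, "", 14L)),
    hmm_start = as.integer(vapply(f, `[`, "", 16L)),
    hmm_end = as.integer(vapply(f, `[`, "", 17L)),
    q_start = as.integer(vapply(f, `[`, "", 20L)),  # envelope coordinates
    q_end = as.integer(vapply(f, `[`, "", 21L)),
    stringsAsFactors = FALSE)
  hits <- hits[hits$hmm_id %in% hmms$hmm_id, , drop = FALSE]
  idx <- match(hits$hmm_id, hmms$hmm_id)
  hits$model_length <- hmms$model_length[idx]
  hits <- hits[hits$full_bits >= hmms$trusted_cutoff[idx], , drop = FALSE]
  # best domain per (query, profile)
  hits <- hits[order(hits$query_id, hits$hmm_id, -hits$dom_bits), , drop = FALSE]
  hits <- hits[!duplicated(hits[, c("query_id", "hmm_id")]), , drop = FALSE]
  hits$bit_score <- hits$full_bits
  hits <- hits[order(hits$query_id, -hits$bit_score, hits$hmm_id),
               c("query_id", "hmm_id", "bit_score", "q_start", "q_end",
                 "hmm_start", "hmm_end", "model_length"), drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Global alignment identity and coverage
#'
#' End-to-end (Needleman--Wunsch) alignment of two protein sequences with
#' BLOSUM62 and affine gaps (11/1). Identity is computed over alignment
#' columns after trimming terminal gaps (internal gap columns count as
#' mismatches); coverage is the trimmed alignment span divided by the
#' longer sequence's length. Symmetric in its arguments.
#'
#' @param a,b protein sequences (character scalars).
#' @return list with \code{identity} (percent) and \code{coverage}
#'   (fraction).
#' @export
global_align_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence in global alignment")
  mat <- blosum62()
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(a), subject = Biostrings::AAString(b),
    type = "global", substitutionMatrix = mat, gapOpening = 11, gapExtension = 1)
  pa_chars <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  pb_chars <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  gap <- pa_chars == "-" | pb_chars == "-"
  # trim terminal gap columns
  non_term <- which(pa_chars != "-" & pb_chars != "-")
  if (length(non_term) == 0L) return(list(identity = 0, coverage = 0))
  keep <- seq(min(non_term), max(non_term))
  ident <- 100 * sum(pa_chars[keep] == pb_chars[keep] & !gap[keep]) / length(keep)
  cov <- length(keep) / max(nchar(a), nchar(b))
  list(identity = ident, coverage = cov)
}
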