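#' Reference protein databases
#'
#' The engine searches a genome's proteins against a reference database of
#' (i) characterized proteins — sequences with experimental evidence for
#' their function, the only basis for high-confidence calls — and (ii)
#' curated-only proteins — annotated enzymes without experimental
#' evidence, which support at most medium confidence — plus profile HMMs
#' with curator-set trusted cutoffs.
#'
#' On disk a reference database is a directory with \code{proteins.faa}
#' (protein FASTA), \code{proteins.tsv} (columns \code{protein_id},
#' \code{status}, \code{source_db}, \code{ec_numbers} (';'-separated, may
#' be empty), \code{description}) and an \code{hmms/} subdirectory of
#' HMMER3 text profiles, each carrying a \code{TC} line.
#'
#' @param dir database directory.
#' @return \code{read_reference_db} returns a list with \code{proteins}
#'   (data.frame with the sidecar columns plus \code{sequence}) and
#'   \code{hmms} (data.frame \code{hmm_id}, \code{model_length},
#'   \code{trusted_cutoff}, \code{ec_numbers}, \code{path}).
#' @export
read_reference_db <- function(dir) {
  faa <- file.path(dir, "proteins.faa")
  tsv <- file.path(dir, "proteins.tsv")
  if (!file.exists(faa)) stop("missing protein FASTA: ", faa)
  if (!file.exists(tsv)) stop("missing protein metadata sidecar: ", tsv)
  seqs <- Biostrings::readAAStringSet(faa)
  meta <- utils::read.delim(tsv, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("protein_id", "status", "source_db", "ec_numbers", "description")
  if (!all(need %in% names(meta)))
    stop("proteins.tsv must have columns: ", paste(need, collapse = ", "))
  idx <- match(meta$protein_id, names(seqs))
  if (anyNA(idx))
    stop("proteins.tsv lists ids absent from proteins.faa: ",
         paste(meta$protein_id[is.na(idx)], collapse = ", "))
  meta$sequence <- as.character(seqs)[idx]
  check_protein_records(meta)

  hmm_dir <- file.path(dir, "hmms")
  hmm_files <- if (dir.exists(hmm_dir))
    sort(list.files(hmm_dir, pattern = "\\.hmm$", full.names = TRUE)) else character()
  hmms <- read_hmm_meta(hmm_files)
  list(proteins = meta, hmms = hmms)
}

check_protein_records <- function(records) {
  stopifnot(is.data.frame(records))
  if (any(!nzchar(records$sequence))) stop("empty protein sequence in reference records")
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", records$sequence)
  if (any(bad))
    stop("non-amino-acid characters in sequences of: ",
         paste(records$protein_id[bad], collapse = ", "))
  if (!all(records$status %in% c("CHARACTERIZED", "CURATED_ONLY")))
    stop("status must be CHARACTERIZED or CURATED_ONLY")
  if (anyDuplicated(records$protein_id))
    stop("duplicate protein ids: ",
         paste(unique(records$protein_id[duplicated(records$protein_id)]), collapse = ", "))
  invisible(records)
}

#' @rdname read_reference_db
#' @param db database list as returned by \code{read_reference_db}.
#' @export
write_reference_db <- function(db, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seqs <- Biostrings::AAStringSet(db$proteins$sequence)
  names(seqs) <- db$proteins$protein_id
  Biostrings::writeXStringSet(seqs, file.path(dir, "proteins.faa"), width = 60L)
  meta <- db$proteins[, c("protein_id", "status", "source_db", "ec_numbers", "description")]
  utils::write.table(meta, file.path(dir, "proteins.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(db$hmms) && nrow(db$hmms) > 0L) {
    hmm_dir <- file.path(dir, "hmms")
    dir.create(hmm_dir, showWarnings = FALSE)
    for (i in seq_len(nrow(db$hmms))) {
      dest <- file.path(hmm_dir, paste0(db$hmms$hmm_id[i], ".hmm"))
      if (!identical(normalizePath(db$hmms$path[i], mustWork = FALSE),
                     normalizePath(dest, mustWork = FALSE)))
        file.copy(db$hmms$path[i], dest, overwrite = TRUE)
    }
  }
  invisible(dir)
}

#' Parse HMMER3 profile headers
#'
#' Reads NAME, LENG and TC from HMMER3 text profiles. A profile without a
#' trusted-cutoff (\code{TC}) line is an error: searches accept hits only
#' at or above the curator's trusted cutoff, so a profile without one
#' cannot be used.
#'
#' @param files character vector of \code{.hmm} file paths (each may hold
#'   several concatenated profiles).
#' @param ec_numbers optional named character vector mapping hmm_id to
#'   ';'-separated EC numbers.
#' @return data.frame \code{hmm_id}, \code{model_length},
#'   \code{trusted_cutoff}, \code{ec_numbers}, \code{path}.
#' @export
read_hmm_meta <- function(files, ec_numbers = NULL) {
  rows <- list()
  for (f in files) {
    lines <- readLines(f, warn = FALSE)
    starts <- grep("^HMMER3", lines)
    ends <- grep("^//", lines)
    if (length(starts) == 0L) stop("not a HMMER3 profile: ", f)
    for (k in seq_along(starts)) {
      block <- lines[starts[k]:ends[k]]
      name <- sub("^NAME\\s+", "", grep("^NAME\\s", block, value = TRUE)[1])
      leng <- as.integer(sub("^LENG\\s+", "", grep("^LENG\\s", block, value = TRUE)[1]))
      tc_line <- grep("^TC\\s", block, value = TRUE)
      if (length(tc_line) == 0L)
        stop("profile '", name, "' in ", f, " has no trusted cutoff (TC line)")
      tc <- as.numeric(strsplit(trimws(sub("^TC\\s+", "", tc_line[1])), "\\s+")[[1]][1])
      if (!is.finite(tc)) stop("non-finite trusted cutoff for profile '", name, "' in ", f)
      ec <- if (!is.null(ec_numbers) && name %in% names(ec_numbers)) ec_numbers[[name]] else ""
      rows[[length(rows) + 1L]] <- data.frame(
        hmm_id = name, model_length = leng, trusted_cutoff = tc,
        ec_numbers = ec, path = f, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(hmm_id = character(), model_length = integer(),
                      trusted_cutoff = numeric(), ec_numbers = character(),
                      path = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Drop uncharacterized records from a characterized-protein pool
#'
#' Records are dropped when the description begins with "uncharacterized"
#' or is exactly (case-insensitively) "uncharacterized protein",
#' "DUF<digits> family protein", "PF<digits> family protein" or
#' "UPF<digits> family protein". For records whose \code{source_db} is
#' EcoCyc or CharProtDB, descriptions beginning with "putative" or
#' "protein" are also dropped, and for CharProtDB additionally those
#' beginning with "probably".
#'
#' @param records protein record data.frame (see
#'   \code{\link{read_reference_db}}).
#' @param source_db optional scalar overriding the records' own
#'   \code{source_db} column.
#' @return the filtered data.frame.
#' @export
filter_uncharacterized <- function(records, source_db = NULL) {
  if (nrow(records) == 0L) return(records)
  src <- if (is.null(source_db)) records$source_db else rep(source_db, nrow(records))
  d <- records$description
  drop <- grepl("^uncharacterized", d, ignore.case = TRUE) |
    grepl("^uncharacterized protein$", d, ignore.case = TRUE) |
    grepl("^DUF[0-9]+ family protein$", d, ignore.case = TRUE) |
    grepl("^PF[0-9]+ family protein$", d, ignore.case = TRUE) |
    grepl("^UPF[0-9]+ family protein$", d, ignore.case = TRUE)
  strict <- src %in% c("EcoCyc", "CharProtDB")
  drop <- drop | (strict & (grepl("^putative\\b", d, ignore.case = TRUE) |
                            grepl("^protein\\b", d, ignore.case = TRUE)))
  drop <- drop | (src %in% "CharProtDB" & grepl("^probably\\b", d, ignore.case = TRUE))
  records[!drop, , drop = FALSE]
}

#' Build the curated-only subset by clustering at 60\% identity
#'
#' Enzyme-annotated curated records are greedily clustered at the given
#' global-identity threshold (longest sequence first seeds each cluster);
#' clusters whose members carry different EC sets are split by EC
#' signature; one representative — the lexicographically smallest
#' protein id — is kept per final cluster.
#'
#' @param records protein record data.frame; every record must carry at
#'   least one (possibly incomplete) EC number.
#' @param cluster_identity identity threshold as a fraction (default 0.60).
#' @return data.frame of representatives, one per final cluster.
#' @export
build_curated_subset <- function(records, cluster_identity = 0.60) {
  if (nrow(records) == 0L) return(records)
  if (any(!nzchar(records$ec_numbers)))
    stop("build_curated_subset requires enzyme-annotated records (>=1 EC each)")
  ord <- order(-nchar(records$sequence), records$protein_id)
  recs <- records[ord, , drop = FALSE]
  cluster <- rep(NA_integer_, nrow(recs))
  ncl <- 0L
  for (i in seq_len(nrow(recs))) {
    if (!is.na(cluster[i])) next
    ncl <- ncl + 1L
    cluster[i] <- ncl
    rest <- which(is.na(cluster))
    if (length(rest) == 0L) next
    for (j in rest) {
      idc <- global_align_identity(recs$sequence[i], recs$sequence[j])
      if (idc$identity >= cluster_identity * 100) cluster[j] <- ncl
    }
  }
  # split heterogeneous clusters by EC signature
  sig <- vapply(strsplit(recs$ec_numbers, ";", fixed = TRUE),
                function(e) paste(sort(trimws(e)), collapse = ";"), "")
  key <- paste(cluster, sig, sep = "|")
  reps <- vapply(split(recs$protein_id, key), function(ids) min(ids), "")
  out <- records[match(sort(unname(reps)), records$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# does a (possibly incomplete) EC matcher such as "2.7.1.-" select a
# record EC? Components equal to "-" match any completion.
ec_component_match <- function(matcher_ec, record_ec) {
  a <- strsplit(matcher_ec, ".", fixed = TRUE)[[1]]
  b <- strsplit(record_ec, ".", fixed = TRUE)[[1]]
  if (length(a) != 4L || length(b) != 4L) return(FALSE)
  all(a == "-" | b == "-" | a == b)
}

ec_select <- function(matcher_ec, ec_field) {
  vapply(strsplit(ec_field, ";", fixed = TRUE), function(ecs) {
    ecs <- trimws(ecs)
    any(vapply(ecs[nzchar(ecs)], ec_component_match, TRUE, matcher_ec = matcher_ec))
  }, TRUE)
}

#' Case-insensitive word-boundary term matching
#'
#' A term matches a description when it occurs case-insensitively with
#' both ends at word boundaries, where a word boundary is a transition
#' between an alphanumeric character and a non-alphanumeric character or
#' the string edge. So "hisF" matches "synthase subunit HisF" but not
#' "HisFG fusion".
#'
#' @param term character scalar.
#' @param descriptions character vector.
#' @return logical vector.
#' @export
term_match <- function(term, descriptions) {
  esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", term)
  pattern <- paste0("(?<![A-Za-z0-9])", esc, "(?![A-Za-z0-9])")
  grepl(pattern, descriptions, ignore.case = TRUE, perl = TRUE)
}

#' Resolve a step definition to its concrete query sets
#'
#' Applies the step's matchers to the reference database: EC matchers
#' select protein records (and HMMs) annotated with a matching EC
#' (incomplete EC numbers match any completion), term matchers select
#' records by word-boundary description match, curated/uniprot matchers
#' select records by id, and HMM matchers select profiles by id. Ignore
#' matchers populate the \code{ignored} id set; hits to ignored proteins
#' are disregarded when a candidate is tested for similarity to proteins
#' with other functions.
#'
#' @param step a step definition (element of
#'   \code{pathway_definition$steps}).
#' @param db reference database (\code{\link{read_reference_db}}).
#' @return a \code{step_query_set}: list with \code{step_id},
#'   \code{characterized} and \code{curated_only} (record data.frames with
#'   a \code{matched_by} provenance column), \code{hmms} (HMM metadata
#'   rows), and \code{ignored} (character vector of protein ids). Matchers
#'   that select nothing are reported in attribute \code{"warnings"}.
#' @export
resolve_step_queries <- function(step, db) {
  prot <- db$proteins
  sel_char <- integer(); sel_cur <- integer(); sel_hmm <- integer()
  by_char <- character(); by_cur <- character(); warnings <- character()
  is_char <- prot$status == "CHARACTERIZED"

  take <- function(hit_idx, label) {
    got <- FALSE
    ci <- hit_idx[is_char[hit_idx]]
    ui <- hit_idx[!is_char[hit_idx]]
    if (length(ci) > 0L) {
      new <- setdiff(ci, sel_char)
      sel_char <<- c(sel_char, new)
      by_char <<- c(by_char, rep(label, length(new)))
      got <- TRUE
    }
    if (length(ui) > 0L) {
      new <- setdiff(ui, sel_cur)
      sel_cur <<- c(sel_cur, new)
      by_cur <<- c(by_cur, rep(label, length(new)))
      got <- TRUE
    }
    got
  }

  for (m in step$matchers) {
    label <- paste0(m$kind, ":", m$value)
    got <- switch(m$kind,
      EC = {
        hit <- which(ec_select(m$value, prot$ec_numbers))
        g <- take(hit, label)
        if (nrow(db$hmms) > 0L) {
          h <- which(ec_select(m$value, db$hmms$ec_numbers))
          if (length(h) > 0L) { sel_hmm <- unique(c(sel_hmm, h)); g <- TRUE }
        }
        g
      },
      TERM = take(which(term_match(m$value, prot$description)), label),
      CURATED_ID = ,
      UNIPROT = take(which(prot$protein_id == m$value), label),
      HMM = {
        h <- which(db$hmms$hmm_id == m$value)
        sel_hmm <- unique(c(sel_hmm, h))
        length(h) > 0L
      })
    if (!isTRUE(got))
      warnings <- c(warnings, paste0("matcher ", label, " of step '", step$step_id,
                                     "' selected no database objects"))
  }

  ignored <- character()
  for (m in step$ignore) {
    ids <- switch(m$kind,
      EC = prot$protein_id[ec_select(m$value, prot$ec_numbers)],
      TERM = prot$protein_id[term_match(m$value, prot$description)],
      CURATED_ID = ,
      UNIPROT = m$value,  # id is ignorable whether or not present in the db
      HMM = character())
    ignored <- union(ignored, ids)
  }

  mk <- function(idx, by) {
    out <- prot[idx, , drop = FALSE]
    out$matched_by <- by
    rownames(out) <- NULL
    out
  }
  structure(list(step_id = step$step_id,
                 characterized = mk(sel_char, by_char),
                 curated_only = mk(sel_cur, by_cur),
                 hmms = db$hmms[sort(sel_hmm), , drop = FALSE],
                 ignored = ignored),
            warnings = warnings, class = "step_query_set")
}
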