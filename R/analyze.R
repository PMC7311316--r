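empty_hits <- function() {
  data.frame(query_id = character(), subject_id = character(),
             percent_identity = numeric(), bit_score = numeric(),
             e_value = numeric(), q_start = integer(), q_end = integer(),
             s_start = integer(), s_end = integer(),
             query_length = integer(), subject_length = integer(),
             stringsAsFactors = FALSE)
}

#' Analyze one genome against a pathway set
#'
#' Runs the full reconstruction for one proteome: searches every protein
#' against the reference database (one search, reused both for finding
#' step candidates and as the pool of "other" hits), searches the
#' database's profiles, then for every pathway scores each step's
#' candidates, selects the best path, collects gaps (steps on the best
#' path below high confidence) and checks cross-pathway requirements.
#'
#' @param proteome named character vector or \code{AAStringSet} of the
#'   genome's predicted proteins (may be empty: every step is then low
#'   confidence and every pathway all gaps).
#' @param pathways named list of \code{pathway_definition}s
#'   (\code{\link{read_pathway_set}}).
#' @param db reference database (\code{\link{read_reference_db}}).
#' @param genome_id label for reports.
#' @param config engine configuration (\code{\link{default_config}}).
#' @return a \code{genome_result}: list with \code{genome_id},
#'   \code{best_paths} (named list of \code{path_result}s),
#'   \code{step_results} (nested: pathway id, then step id),
#'   \code{gaps} (data.frame \code{pathway_id}, \code{step_id},
#'   \code{confidence}, \code{known_gap}), \code{warnings}, \code{config}.
#' @export
analyze_genome <- function(proteome, pathways, db, genome_id = "genome",
                           config = default_config()) {
  proteome <- as_aa_set(proteome, "proteome")
  if (inherits(pathways, "pathway_definition")) {
    pathways <- stats::setNames(list(pathways), pathways$pathway_id)
  }
  db_seqs <- stats::setNames(db$proteins$sequence, db$proteins$protein_id)
  all_db_hits <- if (length(proteome) > 0L) {
    search_proteins(proteome, db_seqs, min_identity = config$min_identity,
                    max_evalue = config$max_evalue, backend = config$backend)
  } else empty_hits()
  hmm_hits <- if (length(proteome) > 0L) search_hmms(proteome, db$hmms) else NULL

  warnings <- character()
  step_results <- list()
  best_paths <- list()
  for (pid in names(pathways)) {
    p <- pathways[[pid]]
    sres <- list()
    for (sid in names(p$steps)) {
      sq <- resolve_step_queries(p$steps[[sid]], db)
      warnings <- c(warnings, attr(sq, "warnings"))
      sres[[sid]] <- find_step_candidates(p$steps[[sid]], sq, all_db_hits,
                                          hmm_hits, config)
    }
    step_results[[pid]] <- sres
    best_paths[[pid]] <- best_path(p, sres, cap = config$expansion_cap)
  }
  warnings <- c(warnings, check_requirements(best_paths, step_results, pathways))

  gaps <- do.call(rbind, c(list(data.frame(pathway_id = character(),
                                           step_id = character(),
                                           confidence = character(),
                                           stringsAsFactors = FALSE)),
    lapply(names(best_paths), function(pid) {
      g <- path_gaps(best_paths[[pid]])
      g <- g[!duplicated(g$step_id), , drop = FALSE]
      if (nrow(g) == 0L) return(NULL)
      data.frame(pathway_id = pid, g, stringsAsFactors = FALSE)
    })))
  gaps$known_gap <- rep("", nrow(gaps))
  rownames(gaps) <- NULL

  structure(list(genome_id = genome_id, best_paths = best_paths,
                 step_results = step_results, gaps = gaps,
                 warnings = unique(warnings), config = config),
            class = "genome_result")
}

#' @export
print.genome_result <- function(x, ...) {
  cat("Genome '", x$genome_id, "': ", length(x$best_paths), " pathway(s), ",
      nrow(x$gaps), " gap(s)\n", sep = "")
  for (pid in names(x$best_paths)) {
    bp <- x$best_paths[[pid]]
    cat("  ", pid, " [", bp$primary_confidence, "]: ",
        paste(paste0(bp$step_ids, "(", substr(bp$confidences, 1, 1), ")"),
              collapse = " "), "\n", sep = "")
  }
  if (length(x$warnings) > 0L)
    cat("  warnings: ", length(x$warnings), "\n", sep = "")
  invisible(x)
}

#' @export
summary.genome_result <- function(object, ...) {
  df <- do.call(rbind, lapply(names(object$best_paths), function(pid) {
    bp <- object$best_paths[[pid]]
    data.frame(pathway_id = pid, primary_confidence = bp$primary_confidence,
               secondary_score = bp$secondary_score, n_steps = bp$length,
               n_gaps = sum(conf_rank(bp$confidences) < conf_rank("high")),
               best_path = paste(bp$step_ids, collapse = " "),
               stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  df
}

genome_result_as_list <- function(result) {
  top_candidate <- function(sr) {
    if (nrow(sr$candidates) == 0L) return(NULL)
    as.list(sr$candidates[1L, c("parts", "origin", "confidence",
                                "percent_identity", "subject_coverage",
                                "bit_score", "subject_id")])
  }
  pw <- lapply(names(result$best_paths), function(pid) {
    bp <- result$best_paths[[pid]]
    steps <- lapply(seq_along(bp$step_ids), function(i) {
      sid <- bp$step_ids[i]
      list(id = sid, confidence = bp$confidences[i],
           top_candidate = top_candidate(result$step_results[[pid]][[sid]]))
    })
    g <- result$gaps[result$gaps$pathway_id == pid, , drop = FALSE]
    list(best_path = as.list(bp$step_ids),
         primary_confidence = bp$primary_confidence,
         secondary_score = bp$secondary_score,
         steps = steps,
         gaps = lapply(seq_len(nrow(g)), function(i)
           list(step_id = g$step_id[i], confidence = g$confidence[i],
                known_gap = g$known_gap[i])))
  })
  names(pw) <- names(result$best_paths)
  list(genome_id = result$genome_id, pathways = pw,
       warnings = as.list(result$warnings),
       related_genomes = as.list(result$related_genomes %||% character()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write per-genome reports
#'
#' \code{write_genome_json} writes the machine-readable result
#' (pathways, best paths, per-step confidences and top candidates, gaps
#' with known-gap flags, warnings); \code{write_candidates_tsv} writes
#' every candidate of every step; \code{write_summary_tsv} writes one row
#' per pathway. All outputs are deterministic: two runs on identical
#' inputs and configuration produce byte-identical files.
#'
#' @param result a \code{genome_result}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_genome_json <- function(result, path) {
  jsonlite::write_json(genome_result_as_list(result), path,
                       auto_unbox = TRUE, pretty = TRUE, digits = 6, null = "null")
  invisible(path)
}

#' @rdname write_genome_json
#' @export
write_candidates_tsv <- function(result, path) {
  rows <- list()
  for (pid in names(result$step_results)) {
    for (sid in names(result$step_results[[pid]])) {
      cands <- result$step_results[[pid]][[sid]]$candidates
      if (nrow(cands) == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(pathway_id = pid, cands,
                                              stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(pathway_id = character(), empty_candidates())
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(x) formatC(x, digits = 4, format = "f"))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genome_json
#' @export
write_summary_tsv <- function(result, path) {
  out <- summary(result)
  out$secondary_score <- formatC(out$secondary_score, digits = 1, format = "f")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run a full analysis from files to an output directory
#'
#' The file-level entry point behind the \code{analyze} CLI subcommand:
#' reads a proteome FASTA, a directory of pathway definition files and a
#' reference database directory, validates the definitions, runs
#' \code{\link{analyze_genome}}, and writes \code{result.json},
#' \code{candidates.tsv}, \code{summary.tsv} and \code{run_record.json}
#' into \code{out_dir}.
#'
#' @param proteome_fasta path to the proteome FASTA.
#' @param pathway_dir directory of pathway definition files.
#' @param db_dir reference database directory.
#' @param out_dir output directory (created if needed).
#' @param config engine configuration.
#' @param genome_id label; defaults to the FASTA base name.
#' @return the \code{genome_result}, invisibly.
#' @export
cmd_analyze <- function(proteome_fasta, pathway_dir, db_dir, out_dir,
                        config = default_config(), genome_id = NULL) {
  t0 <- proc.time()[["elapsed"]]
  if (!file.exists(proteome_fasta)) stop("unreadable proteome FASTA: ", proteome_fasta)
  proteome <- Biostrings::readAAStringSet(proteome_fasta)
  pathways <- read_pathway_set(pathway_dir)
  db <- read_reference_db(db_dir)
  report <- validate_definitions(pathways)
  if (is.null(genome_id))
    genome_id <- sub("\\.(faa|fasta|fa)$", "", basename(proteome_fasta))
  result <- analyze_genome(proteome, pathways, db, genome_id = genome_id,
                           config = config)
  if (nrow(report) > 0L)
    result$warnings <- unique(c(result$warnings, paste0(
      "definition finding [", report$kind, "] ", report$pathway_id, ": ",
      report$detail)))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_genome_json(result, file.path(out_dir, "result.json"))
  write_candidates_tsv(result, file.path(out_dir, "candidates.tsv"))
  write_summary_tsv(result, file.path(out_dir, "summary.tsv"))
  write_run_record(file.path(out_dir, "run_record.json"), config,
                   inputs = c(proteome = proteome_fasta),
                   elapsed = proc.time()[["elapsed"]] - t0,
                   warnings = result$warnings)
  invisible(result)
}

write_run_record <- function(path, config, inputs, elapsed, warnings) {
  cfg_file <- tempfile(fileext = ".yaml")
  on.exit(unlink(cfg_file))
  yaml::write_yaml(config, cfg_file)
  rec <- list(
    tool_version = as.character(utils::packageVersion("pathgaps")),
    config_hash = unname(tools::md5sum(cfg_file)),
    input_digests = as.list(tools::md5sum(unname(inputs))),
    elapsed_seconds = round(elapsed, 3),
    warnings = as.list(warnings))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Annotate an analysis with known gaps from a catalog
#'
#' The file-level entry point behind the \code{known-gaps} CLI
#' subcommand: re-runs the gap annotation of an existing analysis
#' (\code{\link{cmd_analyze}} outputs) against a known-gap catalog. The
#' proteome is searched against the catalog's marker profiles, related
#' cataloged genomes are identified, matching gaps are flagged, and the
#' annotated result JSON is written.
#'
#' @param result a \code{genome_result} (or the path of a directory
#'   containing the \code{result.json}-producing analysis re-run is not
#'   supported; pass the object).
#' @param catalog_dir known-gap catalog directory; must contain
#'   \code{known_gaps.tsv}, \code{markers/} and \code{marker_hmms/}
#'   (HMMER3 profiles used to extract the query's markers).
#' @param proteome_fasta the analyzed genome's proteome FASTA.
#' @param out_json path for the annotated result JSON (optional).
#' @param config engine configuration.
#' @param domain marker domain of the query genome.
#' @return the annotated \code{genome_result}, invisibly.
#' @export
cmd_known_gaps <- function(result, catalog_dir, proteome_fasta, out_json = NULL,
                           config = default_config(), domain = "bacteria") {
  catalog <- read_known_gap_catalog(catalog_dir, domain = domain)
  hmm_dir <- file.path(catalog_dir, "marker_hmms")
  if (!dir.exists(hmm_dir))
    stop("catalog has no marker_hmms/ directory: ", catalog_dir)
  marker_hmms <- read_hmm_meta(sort(list.files(hmm_dir, pattern = "\\.hmm$",
                                               full.names = TRUE)))
  proteome <- Biostrings::readAAStringSet(proteome_fasta)
  qp <- extract_markers(proteome, marker_hmms, genome_id = result$genome_id,
                        domain = domain)
  result <- mark_known_gaps(result, catalog, qp, config)
  if (!is.null(out_json)) write_genome_json(result, out_json)
  invisible(result)
}
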