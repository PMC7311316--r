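.aa20 <- c("A","C","D","E","F","G","H","I","K","L",
           "M","N","P","Q","R","S","T","V","W","Y")

random_protein <- function(n) paste(sample(.aa20, n, replace = TRUE), collapse = "")

#' Mutate a protein sequence to a target global identity
#'
#' Applies point substitutions (no indels) at randomly chosen positions
#' until the realized global-alignment identity is within 3 percentage
#' points of the target. Substitution-only mutation keeps coverage at
#' ~100\%, so fixture identity and coverage can be varied independently.
#'
#' @param seq protein sequence (length >= 100).
#' @param target target identity as a fraction in [0.15, 1].
#' @param max_attempts bound on the adjust-and-remeasure loop.
#' @return list with \code{sequence} and \code{identity} (realized, in
#'   percent, measured by \code{\link{global_align_identity}}).
#' @export
mutate_to_identity <- function(seq, target, max_attempts = 25L) {
  n <- nchar(seq)
  if (target < 0.15 || target > 1) stop("identity target must be in [0.15, 1]")
  if (n < 100L) stop("sequence too short to mutate reliably (need >= 100 residues)")
  if (target == 1) return(list(sequence = seq, identity = 100))
  chars <- strsplit(seq, "")[[1]]
  k <- round((1 - target) * n)
  for (attempt in seq_len(max_attempts)) {
    k <- max(0L, min(n, k))
    mut <- chars
    pos <- sample.int(n, k)
    for (p in pos) mut[p] <- sample(setdiff(.aa20, chars[p]), 1L)
    cand <- paste(mut, collapse = "")
    realized <- global_align_identity(seq, cand)$identity
    if (abs(realized - target * 100) <= 3)
      return(list(sequence = cand, identity = realized))
    k <- k + as.integer(round((realized - target * 100) / 100 * n))
    if (k <= 0L || k >= n) k <- round((1 - target) * n)
  }
  stop("could not reach identity target ", target, " within ", max_attempts, " attempts")
}

#' Plant directives for the fixture generator
#'
#' A directive describes what to plant in a genome for one step:
#' \describe{
#'   \item{ortholog}{one full-length protein at the given identity to the
#'     step's reference protein; identity above 40\% yields a
#'     high-confidence candidate, 30--40\% a medium one.}
#'   \item{fusion}{one protein concatenating mutated copies of this
#'     step's and the partner step's reference proteins; expected high
#'     for both steps (the relevant-region rule rescues each half from
#'     the other half's hit).}
#'   \item{split}{the step's reference protein mutated, then bisected at
#'     the breakpoint fraction into two separate proteins; expected to be
#'     joined back to the tier the intact protein would get.}
#'   \item{decoy}{an ortholog at the given identity plus a
#'     characterized reference protein with a different function at
#'     higher identity (\code{decoy_identity}) to the planted protein,
#'     forcing an other-hit demotion to medium.}
#'   \item{absent}{nothing planted; the step is expected low confidence
#'     (a gap).}
#' }
#'
#' @param step step id the directive applies to.
#' @param kind one of \code{"ortholog"}, \code{"fusion"}, \code{"split"},
#'   \code{"decoy"}, \code{"absent"}.
#' @param identity identity target in [0.15, 1]. Targets near the 30\% or
#'   40\% decision boundaries make the expected tier ambiguous; the
#'   shipped defaults stay clear of them.
#' @param partner second step for \code{kind = "fusion"}.
#' @param breakpoint bisection fraction in (0.2, 0.8) for
#'   \code{kind = "split"}.
#' @param decoy_identity identity of the planted decoy reference protein
#'   to the planted ortholog, for \code{kind = "decoy"}.
#' @return directive list, for use in \code{\link{fixture_spec}}.
#' @export
plant <- function(step, kind = c("ortholog", "fusion", "split", "decoy", "absent"),
                  identity = 0.8, partner = NULL, breakpoint = 0.5,
                  decoy_identity = 0.85) {
  kind <- match.arg(kind)
  if (identity < 0.15 || identity > 1) stop("identity target must be in [0.15, 1]")
  if (kind == "fusion" && is.null(partner)) stop("fusion directive needs a partner step")
  if (kind == "split" && (breakpoint <= 0.2 || breakpoint >= 0.8))
    stop("split breakpoint must be in (0.2, 0.8)")
  list(step = step, kind = kind, identity = identity, partner = partner,
       breakpoint = breakpoint, decoy_identity = decoy_identity)
}

#' Specify a synthetic fixture universe
#'
#' A fixture universe is everything the engine consumes, generated at toy
#' scale with a known answer: a reference database (characterized and
#' curated-only records), pathway definition files, per-genome proteomes
#' with planted orthologs / fusions / splits / decoys, marker proteins
#' and profiles, and a known-gap catalog anchored on a reference genome
#' carrying the unmutated marker set.
#'
#' @param seed integer seed; the same seed yields byte-identical fixture
#'   files.
#' @param genomes named list: genome id to list of \code{\link{plant}}
#'   directives. Steps without a directive get nothing planted (expected
#'   low).
#' @param pathway_ids which of the built-in toy pathways to include:
#'   \code{"ser"} (3 linear steps), \code{"met"} (transsulfuration-style
#'   subpathway with 2 alternatives), \code{"arg"} (two route variants
#'   sharing tail steps).
#' @param marker_count number of marker proteins per genome (0 disables
#'   markers and the catalog).
#' @param marker_identity named numeric: per-genome identity target of
#'   its markers to the catalog reference's markers (default 1.0).
#' @param catalog_gaps data.frame (\code{pathway_id}, \code{step_id}) of
#'   gaps attributed to the catalog reference genome.
#' @param n_background random background proteins per proteome.
#' @param protein_length,marker_length sequence lengths used for
#'   reference proteins and markers.
#' @return a \code{fixture_spec} list.
#' @export
fixture_spec <- function(seed, genomes, pathway_ids = c("ser", "met", "arg"),
                         marker_count = 12L, marker_identity = NULL,
                         catalog_gaps = NULL, n_background = 2L,
                         protein_length = 240L, marker_length = 180L) {
  pathway_ids <- match.arg(pathway_ids, several.ok = TRUE)
  mi <- stats::setNames(rep(1.0, length(genomes)), names(genomes))
  if (!is.null(marker_identity)) mi[names(marker_identity)] <- marker_identity
  structure(list(seed = as.integer(seed), genomes = genomes,
                 pathway_ids = pathway_ids, marker_count = as.integer(marker_count),
                 marker_identity = mi, catalog_gaps = catalog_gaps,
                 n_background = as.integer(n_background),
                 protein_length = as.integer(protein_length),
                 marker_length = as.integer(marker_length)),
            class = "fixture_spec")
}

# toy pathway definitions: step ids, DSL text builders. One step per
# pathway is matched by term (not EC) to exercise both matcher kinds.
fixture_pathway_steps <- list(
  ser = c("serA", "serC", "serB"),
  met = c("metA", "metB", "metC", "metZ", "metE"),
  arg = c("argA", "argB", "argA2", "argC"))

fixture_pathway_text <- function(pid, ecs) {
  step_line <- function(s, use_term = FALSE) {
    matcher <- if (use_term) paste0("term:", s) else paste0("EC:", ecs[[s]])
    paste0("step ", s, ": reference enzyme for ", s, " :: ", matcher)
  }
  switch(pid,
    ser = c("pathway ser",
            step_line("serA"), step_line("serC", use_term = TRUE), step_line("serB"),
            "rule all = serA serC serB"),
    met = c("pathway met",
            step_line("metA"), step_line("metB"), step_line("metC", use_term = TRUE),
            step_line("metZ"), step_line("metE"),
            "rule trans = metB metC | metZ",
            "rule all = metA trans metE"),
    arg = c("pathway arg",
            step_line("argA"), step_line("argB"), step_line("argA2", use_term = TRUE),
            step_line("argC"),
            "rule acet = argA argB",
            "rule succ = argA2 argB",
            "rule all = acet argC | succ argC",
            "require succ: ser/serA present"))
}

# expected tier implied by a directive's realized identity, per the
# documented candidate-classification rules (full-length hit, coverage ~1)
tier_for_identity <- function(identity_pct, decoy = FALSE) {
  if (identity_pct > 40) { if (decoy) "medium" else "high" }
  else if (identity_pct > 30) "medium"
  else "low"
}

# independent best-path choice on expected tiers: argmax over the
# expanded routes by (min tier, -2/-0.1/+1 secondary in tenths, length),
# first expansion wins residual ties
key_best_path <- function(pathway, tiers) {
  paths <- expand_paths(pathway)
  best <- NULL
  for (k in seq_along(paths)) {
    steps <- as.character(paths[[k]])
    r <- conf_rank(unname(tiers[steps]))
    key <- c(min(r), 10L * sum(r == 3L) - sum(r == 2L) - 20L * sum(r == 1L),
             length(steps))
    if (is.null(best) || key_greater(key, best$key)) best <- list(key = key, steps = steps)
  }
  best$steps
}

#' Generate a fixture universe with its answer key
#'
#' Deterministically (per seed) builds every on-disk input the engine
#' consumes and the answer key that the documented rules imply for it:
#' expected per-step confidence tiers, expected best path per pathway,
#' expected gaps with known-gap flags, and expected relatedness of each
#' genome to the catalog reference.
#'
#' @param spec a \code{\link{fixture_spec}}.
#' @param dir directory to write the universe into (created).
#' @return list with \code{dir}, \code{db}, \code{pathways},
#'   \code{proteomes} (named list of named character vectors),
#'   \code{catalog_dir} (or \code{NULL}), and \code{answer_key} (list
#'   with \code{steps}, \code{best_paths}, \code{gaps},
#'   \code{relatedness} as documented above).
#' @export
build_universe <- function(spec, dir = tempfile("universe")) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  steps <- unlist(fixture_pathway_steps[spec$pathway_ids], use.names = FALSE)
  for (g in spec$genomes)
    for (d in g) {
      if (!d$step %in% steps) stop("directive references unknown step '", d$step, "'")
      if (d$kind == "fusion" && !d$partner %in% steps)
        stop("fusion partner '", d$partner, "' is not a known step")
    }

  # reference proteins and EC numbers, one per step
  ecs <- stats::setNames(paste0("1.1.1.", seq_along(steps)), steps)
  ref_seq <- stats::setNames(vapply(steps, function(s)
    random_protein(spec$protein_length), ""), steps)
  prot <- data.frame(
    protein_id = paste0("REF_", steps),
    status = "CHARACTERIZED", source_db = "SwissProt",
    ec_numbers = unname(ecs),
    description = paste0(steps, " reference enzyme"),
    sequence = unname(ref_seq), stringsAsFactors = FALSE)
  # a curated-only homolog pool (annotated, no experimental evidence):
  # same EC as the first step of each included pathway, unrelated sequence
  for (pid in spec$pathway_ids) {
    s1 <- fixture_pathway_steps[[pid]][1]
    prot <- rbind(prot, data.frame(
      protein_id = paste0("CUR_", s1), status = "CURATED_ONLY",
      source_db = "SwissProt", ec_numbers = ecs[[s1]],
      description = paste0(s1, " annotated homolog"),
      sequence = random_protein(spec$protein_length), stringsAsFactors = FALSE))
  }

  # pathway definition files
  pw_dir <- file.path(dir, "pathways")
  dir.create(pw_dir, showWarnings = FALSE)
  for (pid in spec$pathway_ids)
    writeLines(fixture_pathway_text(pid, ecs), file.path(pw_dir, paste0(pid, ".pathway")))
  pathways <- read_pathway_set(pw_dir)

  # markers
  marker_ids <- if (spec$marker_count > 0L)
    sprintf("M%02d", seq_len(spec$marker_count)) else character()
  base_markers <- stats::setNames(vapply(marker_ids, function(m)
    random_protein(spec$marker_length), ""), marker_ids)

  # proteomes with planted directives, and the per-genome key rows
  proteomes <- list()
  key_steps <- list()
  decoy_n <- 0L
  for (gid in names(spec$genomes)) {
    seqs <- character()
    expected <- stats::setNames(rep("low", length(steps)), steps)
    for (d in spec$genomes[[gid]]) {
      base <- ref_seq[[d$step]]
      if (d$kind == "ortholog") {
        m <- mutate_to_identity(base, d$identity)
        seqs[[paste0(gid, "_", d$step)]] <- m$sequence
        expected[d$step] <- tier_for_identity(m$identity)
      } else if (d$kind == "fusion") {
        m1 <- mutate_to_identity(base, d$identity)
        m2 <- mutate_to_identity(ref_seq[[d$partner]], d$identity)
        seqs[[paste0(gid, "_", d$step, "_", d$partner, "_fusion")]] <-
          paste0(m1$sequence, m2$sequence)
        expected[d$step] <- tier_for_identity(m1$identity)
        expected[d$partner] <- tier_for_identity(m2$identity)
      } else if (d$kind == "split") {
        m <- mutate_to_identity(base, d$identity)
        cut <- round(d$breakpoint * nchar(m$sequence))
        seqs[[paste0(gid, "_", d$step, "_part1")]] <- substr(m$sequence, 1, cut)
        seqs[[paste0(gid, "_", d$step, "_part2")]] <-
          substr(m$sequence, cut + 1, nchar(m$sequence))
        expected[d$step] <- tier_for_identity(m$identity)
      } else if (d$kind == "decoy") {
        m <- mutate_to_identity(base, d$identity)
        pidd <- paste0(gid, "_", d$step)
        seqs[[pidd]] <- m$sequence
        decoy_n <- decoy_n + 1L
        dm <- mutate_to_identity(m$sequence, d$decoy_identity)
        prot <- rbind(prot, data.frame(
          protein_id = sprintf("DECOY_%02d", decoy_n), status = "CHARACTERIZED",
          source_db = "SwissProt", ec_numbers = paste0("9.9.9.", decoy_n),
          description = sprintf("unrelated oxidoreductase %d", decoy_n),
          sequence = dm$sequence, stringsAsFactors = FALSE))
        expected[d$step] <- tier_for_identity(m$identity, decoy = TRUE)
      }  # absent: nothing planted, expected stays low
    }
    for (b in seq_len(spec$n_background))
      seqs[[paste0(gid, "_bg", b)]] <- random_protein(spec$protein_length)
    if (spec$marker_count > 0L) {
      for (m in marker_ids) {
        mm <- mutate_to_identity(base_markers[[m]], spec$marker_identity[[gid]])
        seqs[[paste0(gid, "_marker_", m)]] <- mm$sequence
      }
    }
    proteomes[[gid]] <- seqs
    key_steps[[gid]] <- expected
  }

  # write reference db and proteomes
  db <- list(proteins = prot, hmms = read_hmm_meta(character()))
  db_dir <- file.path(dir, "db")
  write_reference_db(db, db_dir)
  prot_dir <- file.path(dir, "proteomes")
  dir.create(prot_dir, showWarnings = FALSE)
  for (gid in names(proteomes)) {
    ss <- Biostrings::AAStringSet(proteomes[[gid]])
    Biostrings::writeXStringSet(ss, file.path(prot_dir, paste0(gid, ".faa")), width = 60L)
  }

  # known-gap catalog anchored on a reference genome with the unmutated
  # marker set
  catalog_dir <- NULL
  if (spec$marker_count > 0L) {
    catalog_dir <- file.path(dir, "catalog")
    entries <- if (is.null(spec$catalog_gaps))
      data.frame(genome_id = character(), pathway_id = character(),
                 step_id = character(), stringsAsFactors = FALSE)
    else data.frame(genome_id = "catref", spec$catalog_gaps, stringsAsFactors = FALSE)
    catalog <- list(entries = entries,
                    profiles = list(catref = structure(
                      list(genome_id = "catref", domain = "bacteria",
                           markers = base_markers),
                      class = "marker_profile")))
    write_known_gap_catalog(catalog, catalog_dir)
    build_marker_hmms(base_markers, file.path(catalog_dir, "marker_hmms"),
                      trusted_cutoff = 50)
  }

  # answer key
  key_rows <- list(); key_paths <- list(); key_gaps <- list(); key_rel <- list()
  for (gid in names(spec$genomes)) {
    tiers <- key_steps[[gid]]
    key_rows[[gid]] <- data.frame(genome_id = gid, pathway_id = rep(
      spec$pathway_ids, lengths(fixture_pathway_steps[spec$pathway_ids])),
      step_id = steps, expected_confidence = unname(tiers),
      stringsAsFactors = FALSE)
    related <- spec$marker_count >= 10L &&
      spec$marker_identity[[gid]] * 100 >= 75
    key_rel[[gid]] <- data.frame(genome_id = gid, related = related,
                                 stringsAsFactors = FALSE)
    bp <- list()
    for (pid in spec$pathway_ids) {
      bp[[pid]] <- key_best_path(pathways[[pid]], tiers)
      gap_steps <- unique(bp[[pid]][conf_rank(tiers[bp[[pid]]]) < conf_rank("high")])
      if (length(gap_steps) > 0L) {
        known <- vapply(gap_steps, function(s) {
          spec$marker_count > 0L && related && !is.null(spec$catalog_gaps) &&
            any(spec$catalog_gaps$pathway_id == pid & spec$catalog_gaps$step_id == s)
        }, TRUE)
        key_gaps[[paste(gid, pid)]] <- data.frame(
          genome_id = gid, pathway_id = pid, step_id = gap_steps,
          expected_confidence = unname(tiers[gap_steps]),
          expected_known_gap = known, stringsAsFactors = FALSE)
      }
    }
    key_paths[[gid]] <- bp
  }
  answer_key <- list(
    steps = do.call(rbind, c(key_rows, list(make.row.names = FALSE))),
    best_paths = key_paths,
    gaps = if (length(key_gaps) > 0L)
      do.call(rbind, c(key_gaps, list(make.row.names = FALSE)))
    else data.frame(genome_id = character(), pathway_id = character(),
                    step_id = character(), expected_confidence = character(),
                    expected_known_gap = logical(), stringsAsFactors = FALSE),
    relatedness = do.call(rbind, c(key_rel, list(make.row.names = FALSE))))

  list(dir = dir, db = db, pathways = pathways, proteomes = proteomes,
       catalog_dir = catalog_dir, answer_key = answer_key)
}

#' Default fixture study conditions
#'
#' The standard universe used by the integration checks: the three toy
#' pathways (12 steps), five genomes spanning the behaviours the engine
#' must handle, twelve markers, and a catalog listing one known gap.
#' \describe{
#'   \item{g_complete}{a strong ortholog (80\% identity) for every step;
#'     expected all high, no gaps; markers identical to the catalog
#'     reference.}
#'   \item{g_gapped}{complete except serB absent (its gap is listed in
#'     the catalog, and the genome is related, so the gap is expected to
#'     be flagged known); the two alternative-route pathways carry
#'     orthologs on one route only.}
#'   \item{g_fusion}{serA and serC fused into one protein; expected high
#'     for both steps.}
#'   \item{g_split}{metE bisected into two proteins (expected joined back
#'     to high); argC carries a decoy forcing a medium call.}
#'   \item{g_diverged}{medium-grade orthologs (35\%) for two serine
#'     steps, everything else absent; markers at 60\% identity, so the
#'     genome is unrelated and none of its gaps can be known.}
#' }
#'
#' @param seed integer seed.
#' @return a \code{\link{fixture_spec}}.
#' @export
example_fixture_spec <- function(seed) {
  orth <- function(steps, identity = 0.8)
    lapply(steps, plant, kind = "ortholog", identity = identity)
  fixture_spec(
    seed = seed,
    genomes = list(
      g_complete = orth(unlist(fixture_pathway_steps, use.names = FALSE)),
      g_gapped = c(orth(c("serA", "serC", "metA", "metZ", "metE",
                          "argA2", "argB", "argC"))),
      g_fusion = c(list(plant("serA", "fusion", partner = "serC")),
                   orth(c("serB", "metA", "metB", "metC", "metE",
                          "argA", "argB", "argC"))),
      g_split = c(list(plant("metE", "split", breakpoint = 0.4),
                       plant("argC", "decoy", identity = 0.55)),
                  orth(c("serA", "serC", "serB", "metA", "metZ",
                         "argA", "argB"))),
      g_diverged = orth(c("serA", "serC"), identity = 0.35)),
    marker_identity = c(g_complete = 1.0, g_gapped = 0.9, g_fusion = 0.85,
                        g_split = 0.8, g_diverged = 0.6),
    catalog_gaps = data.frame(pathway_id = "ser", step_id = "serB",
                              stringsAsFactors = FALSE))
}

#' Build toy HMMER3 profiles from seed sequences
#'
#' For each seed sequence, a small family of mutated copies is emitted as
#' an (ungapped) alignment, \code{hmmbuild} turns it into a profile, and
#' a trusted-cutoff (TC) line is injected. Used for the synthetic marker
#' set and for toy step profiles in tests.
#'
#' @param seeds named character vector of seed sequences (names become
#'   profile names).
#' @param dir output directory for \code{<name>.hmm} files.
#' @param trusted_cutoff bit-score cutoff written into each profile.
#' @param n_family mutated copies per alignment.
#' @param family_identity identity of the copies to the seed.
#' @return invisible character vector of profile file paths.
#' @export
build_marker_hmms <- function(seeds, dir, trusted_cutoff = 50, n_family = 5L,
                              family_identity = 0.85) {
  if (Sys.which("hmmbuild") == "") stop("hmmbuild not on PATH")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- character()
  for (nm in names(seeds)) {
    fam <- c(seeds[[nm]], vapply(seq_len(n_family), function(i)
      mutate_to_identity(seeds[[nm]], family_identity)$sequence, ""))
    names(fam) <- c(paste0(nm, "_seed"), paste0(nm, "_v", seq_len(n_family)))
    afa <- tempfile(fileext = ".afa")
    Biostrings::writeXStringSet(Biostrings::AAStringSet(fam), afa, width = 60L)
    hmm <- file.path(dir, paste0(nm, ".hmm"))
    status <- system2("hmmbuild", c("-n", nm, "--amino", hmm, afa),
                      stdout = FALSE, stderr = FALSE)
    unlink(afa)
    if (status != 0L) stop("hmmbuild failed for profile '", nm, "'")
    # pin the build timestamp so identical seeds give byte-identical profiles
    lines <- readLines(hmm, warn = FALSE)
    lines <- sub("^DATE  .*", "DATE  Thu Jan  1 00:00:00 1970", lines)
    writeLines(lines, hmm)
    set_trusted_cutoff(hmm, trusted_cutoff)
    out <- c(out, hmm)
  }
  invisible(out)
}

#' @rdname build_marker_hmms
#' @param hmm_file path to a HMMER3 text profile.
#' @export
set_trusted_cutoff <- function(hmm_file, trusted_cutoff) {
  lines <- readLines(hmm_file, warn = FALSE)
  lines <- lines[!grepl("^TC\\s", lines)]
  anchor <- grep("^CKSUM\\s", lines)
  if (length(anchor) == 0L) anchor <- grep("^LENG\\s", lines)
  tc_line <- sprintf("TC    %.2f %.2f;", trusted_cutoff, trusted_cutoff)
  lines <- append(lines, tc_line, after = anchor[1])
  writeLines(lines, hmm_file)
  invisible(hmm_file)
}
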