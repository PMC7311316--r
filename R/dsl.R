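#' Pathway definition files
#'
#' Pathways are described in a small line-oriented text format, one pathway
#' per file. Blank lines and lines starting with \code{#} are ignored.
#' The directives are:
#'
#' \preformatted{
#' pathway <pathway_id>
#' step <step_id>: <description> :: <matcher>, <matcher>, ...
#' ignore <step_id>: <matcher>, <matcher>, ...
#' rule <rule_id> = <item> <item> ... | <item> ... | ...
#' require <scope>: <pathway_id>/<step_id> present
#' require <scope>: <pathway_id>/<step_id> absent
#' }
#'
#' A matcher is \code{EC:<ec number>} (incomplete EC numbers such as
#' \code{2.5.1.-} are allowed), \code{term:<word or phrase>},
#' \code{curated:<protein id>}, \code{uniprot:<accession>} or
#' \code{hmm:<model id>}. A rule item is a step id or the id of another
#' rule (a subpathway); alternative instantiations are separated by
#' \code{|}. Every pathway must define the rule \code{all}, whose
#' instantiations are the pathway's alternative routes. A \code{require}
#' directive links a pathway (scope \code{all}) or a subpathway rule to a
#' step of another pathway that must (\code{present}) or must not
#' (\code{absent}) be confidently found when the scoped rule is used on
#' the selected best path.
#'
#' @param path path to a definition file.
#' @param text character scalar (or vector of lines) holding the file
#'   contents; used instead of \code{path} by \code{parse_pathway_text}.
#' @param source label used in error messages.
#' @return A \code{pathway_definition}: a list with elements
#'   \code{pathway_id}, \code{steps} (named list of step definitions, each
#'   with \code{step_id}, \code{description}, \code{matchers},
#'   \code{ignore}), \code{rules} (named list, each with \code{rule_id} and
#'   \code{instantiations}, a list of character vectors), and
#'   \code{requirements}.
#' @examples
#' pd <- parse_pathway_text(c(
#'   "pathway ser",
#'   "step serA: phosphoglycerate dehydrogenase :: EC:1.1.1.95",
#'   "step serB: phosphoserine phosphatase :: EC:3.1.3.3",
#'   "step serC: phosphoserine aminotransferase :: EC:2.6.1.52",
#'   "rule all = serA serC serB"))
#' expand_paths(pd)
#' @export
parse_pathway_file <- function(path) {
  parse_pathway_text(readLines(path, warn = FALSE), source = basename(path))
}

.matcher_kinds <- c("EC", "TERM", "CURATED_ID", "HMM", "UNIPROT")
.ec_regex <- "^[0-9]+\\.([0-9]+|-)\\.([0-9]+|-)\\.(n?[0-9]+|-)$"

parse_matcher <- function(txt, where) {
  txt <- trimws(txt)
  m <- regmatches(txt, regexec("^([A-Za-z_]+):(.+)$", txt))[[1]]
  if (length(m) == 0L) stop("malformed matcher '", txt, "' at ", where)
  kind <- switch(tolower(m[2]),
    ec = "EC", term = "TERM", curated = "CURATED_ID",
    hmm = "HMM", uniprot = "UNIPROT",
    stop("unknown matcher kind '", m[2], "' at ", where))
  value <- trimws(m[3])
  if (!nzchar(value)) stop("empty matcher value at ", where)
  if (kind == "EC" && !grepl(.ec_regex, value))
    stop("invalid EC number '", value, "' at ", where)
  list(kind = kind, value = value)
}

#' @rdname parse_pathway_file
#' @export
parse_pathway_text <- function(text, source = "<text>") {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  pathway_id <- NULL
  steps <- list()
  rules <- list()
  requirements <- list()
  loc <- function(i) paste0(source, ":", i)

  for (i in seq_along(lines)) {
    line <- sub("#.*$", "", lines[[i]])
    line <- trimws(line)
    if (!nzchar(line)) next

    if (grepl("^pathway\\s+", line)) {
      pathway_id <- trimws(sub("^pathway\\s+", "", line))
      if (!grepl("^[A-Za-z0-9_.-]+$", pathway_id))
        stop("invalid pathway id '", pathway_id, "' at ", loc(i))
    } else if (grepl("^step\\s+", line)) {
      body <- sub("^step\\s+", "", line)
      m <- regmatches(body, regexec("^([A-Za-z0-9_.-]+)\\s*:\\s*(.*?)\\s*::\\s*(.+)$", body))[[1]]
      if (length(m) == 0L)
        stop("malformed step line at ", loc(i), " (expected 'step id: description :: matchers')")
      step_id <- m[2]
      if (step_id %in% names(steps))
        stop("duplicate step id '", step_id, "' at ", loc(i))
      matchers <- lapply(strsplit(m[4], ",", fixed = TRUE)[[1]], parse_matcher, where = loc(i))
      if (length(matchers) == 0L) stop("step '", step_id, "' has no matchers at ", loc(i))
      steps[[step_id]] <- list(step_id = step_id, description = m[3],
                               matchers = matchers, ignore = list())
    } else if (grepl("^ignore\\s+", line)) {
      body <- sub("^ignore\\s+", "", line)
      m <- regmatches(body, regexec("^([A-Za-z0-9_.-]+)\\s*:\\s*(.+)$", body))[[1]]
      if (length(m) == 0L) stop("malformed ignore line at ", loc(i))
      step_id <- m[2]
      if (!step_id %in% names(steps))
        stop("ignore for undefined step '", step_id, "' at ", loc(i))
      more <- lapply(strsplit(m[3], ",", fixed = TRUE)[[1]], parse_matcher, where = loc(i))
      steps[[step_id]]$ignore <- c(steps[[step_id]]$ignore, more)
    } else if (grepl("^rule\\s+", line)) {
      body <- sub("^rule\\s+", "", line)
      m <- regmatches(body, regexec("^([A-Za-z0-9_.-]+)\\s*=\\s*(.+)$", body))[[1]]
      if (length(m) == 0L) stop("malformed rule line at ", loc(i))
      rule_id <- m[2]
      if (rule_id %in% names(rules)) stop("duplicate rule id '", rule_id, "' at ", loc(i))
      insts <- lapply(strsplit(m[3], "|", fixed = TRUE)[[1]], function(alt) {
        items <- strsplit(trimws(alt), "\\s+")[[1]]
        if (length(items) == 0L || !all(nzchar(items)))
          stop("empty instantiation in rule '", rule_id, "' at ", loc(i))
        items
      })
      rules[[rule_id]] <- list(rule_id = rule_id, instantiations = insts)
    } else if (grepl("^require\\s+", line)) {
      body <- sub("^require\\s+", "", line)
      m <- regmatches(body, regexec(
        "^([A-Za-z0-9_.-]+)\\s*:\\s*([A-Za-z0-9_.-]+)/([A-Za-z0-9_.-]+)\\s+(present|absent)$", body))[[1]]
      if (length(m) == 0L)
        stop("malformed require line at ", loc(i),
             " (expected 'require scope: pathway/step present|absent')")
      requirements[[length(requirements) + 1L]] <- list(
        scope = m[2], req_pathway = m[3], req_step = m[4],
        polarity = if (m[5] == "present") "MUST_BE_PRESENT" else "MUST_NOT_BE_PRESENT")
    } else {
      stop("unrecognized directive at ", loc(i), ": '", line, "'")
    }
  }

  if (is.null(pathway_id)) stop("no 'pathway' directive in ", source)
  if (!"all" %in% names(rules)) stop("pathway '", pathway_id, "' has no 'all' rule (", source, ")")

  # every rule item must resolve to a step or a rule of this pathway
  for (r in rules) {
    for (inst in r$instantiations) {
      bad <- setdiff(inst, c(names(steps), names(rules)))
      if (length(bad) > 0L)
        stop("undefined reference ", paste(bad, collapse = ", "),
             " in rule '", r$rule_id, "' of pathway '", pathway_id, "'")
    }
  }
  # requirement scopes must resolve locally (the required item is checked
  # across the pathway set by validate_definitions)
  for (req in requirements) {
    if (!req$scope %in% names(rules))
      stop("requirement scope '", req$scope, "' is not a rule of pathway '", pathway_id, "'")
  }
  check_rule_acyclic(rules, pathway_id)

  structure(list(pathway_id = pathway_id, steps = steps, rules = rules,
                 requirements = requirements, source = source),
            class = "pathway_definition")
}

# DFS cycle check over rule -> rule references
check_rule_acyclic <- function(rules, pathway_id) {
  state <- new.env(parent = emptyenv())
  visit <- function(id, stack) {
    if (id %in% stack)
      stop("cyclic rule references in pathway '", pathway_id, "': ",
           paste(c(stack[match(id, stack):length(stack)], id), collapse = " -> "))
    if (isTRUE(state[[id]])) return(invisible())
    for (inst in rules[[id]]$instantiations)
      for (item in inst)
        if (item %in% names(rules)) visit(item, c(stack, id))
    state[[id]] <- TRUE
  }
  for (id in names(rules)) visit(id, character())
  invisible()
}

#' @export
print.pathway_definition <- function(x, ...) {
  cat("Pathway definition '", x$pathway_id, "': ", length(x$steps), " steps, ",
      length(x$rules), " rules, ", length(x$requirements), " requirements\n", sep = "")
  npaths <- tryCatch(length(expand_paths(x)), error = function(e) NA_integer_)
  cat("  steps: ", paste(names(x$steps), collapse = " "), "\n", sep = "")
  if (!is.na(npaths)) cat("  alternative paths: ", npaths, "\n", sep = "")
  invisible(x)
}

#' Serialize a pathway definition back to its text format
#'
#' Writing then re-parsing yields an identical definition (round-trip).
#'
#' @param pathway a \code{pathway_definition}.
#' @return character vector of lines.
#' @export
serialize_pathway <- function(pathway) {
  fmt_matcher <- function(m) {
    prefix <- c(EC = "EC", TERM = "term", CURATED_ID = "curated",
                HMM = "hmm", UNIPROT = "uniprot")[[m$kind]]
    paste0(prefix, ":", m$value)
  }
  out <- paste("pathway", pathway$pathway_id)
  for (s in pathway$steps) {
    out <- c(out, paste0("step ", s$step_id, ": ", s$description, " :: ",
                         paste(vapply(s$matchers, fmt_matcher, ""), collapse = ", ")))
    if (length(s$ignore) > 0L)
      out <- c(out, paste0("ignore ", s$step_id, ": ",
                           paste(vapply(s$ignore, fmt_matcher, ""), collapse = ", ")))
  }
  for (r in pathway$rules) {
    out <- c(out, paste0("rule ", r$rule_id, " = ",
                         paste(vapply(r$instantiations, paste, "", collapse = " "),
                               collapse = " | ")))
  }
  for (q in pathway$requirements) {
    out <- c(out, paste0("require ", q$scope, ": ", q$req_pathway, "/", q$req_step, " ",
                         if (q$polarity == "MUST_BE_PRESENT") "present" else "absent"))
  }
  out
}

#' Expand a pathway into its concrete alternative step sequences
#'
#' Alternative instantiations multiply combinatorially (Cartesian product,
#' depth-first, in instantiation order) and subpathway rules are inlined
#' recursively, so the result enumerates every concrete route through the
#' pathway. Expansion order is deterministic and is the tie-break of last
#' resort when paths are ranked.
#'
#' @param pathway a \code{pathway_definition}.
#' @param cap maximum number of expanded paths before an error is raised
#'   (guards against combinatorial blow-up; real definition sets are far
#'   below it).
#' @return list of character vectors of step ids, in expansion order. Each
#'   element carries the rule ids it traversed in attribute \code{"rules"}.
#' @export
expand_paths <- function(pathway, cap = 10000L) {
  expand_rule <- function(rule_id) {
    out <- list()
    for (inst in pathway$rules[[rule_id]]$instantiations) {
      # per-item expansions: a step contributes itself, a rule its paths
      parts <- lapply(inst, function(item) {
        if (item %in% names(pathway$rules)) expand_rule(item)
        else list(structure(item, rules = character()))
      })
      combos <- list(structure(character(), rules = character()))
      for (p in parts) {
        combos <- unlist(lapply(combos, function(acc) {
          lapply(p, function(piece) {
            structure(c(acc, as.character(piece)),
                      rules = union(attr(acc, "rules"), attr(piece, "rules")))
          })
        }), recursive = FALSE)
        if (length(combos) > cap)
          stop("path expansion of pathway '", pathway$pathway_id,
               "' exceeds cap of ", cap, " paths")
      }
      combos <- lapply(combos, function(p) {
        attr(p, "rules") <- union(attr(p, "rules"), rule_id)
        p
      })
      out <- c(out, combos)
      if (length(out) > cap)
        stop("path expansion of pathway '", pathway$pathway_id,
             "' exceeds cap of ", cap, " paths")
    }
    out
  }
  paths <- expand_rule("all")
  stopifnot(length(paths) >= 1L)
  paths
}

#' Validate a set of pathway definitions
#'
#' Report-only checks across a pathway set: steps defined but unreachable
#' from the \code{all} rule, rules never referenced (directly or through
#' other rules) from \code{all}, and requirements pointing at pathways or
#' steps that do not exist in the set.
#'
#' @param pathways list of \code{pathway_definition} objects.
#' @return data.frame with columns \code{pathway_id}, \code{kind}
#'   (\code{"unreachable_step"}, \code{"unused_rule"},
#'   \code{"unresolvable_requirement"}) and \code{detail}; zero rows when
#'   the set is clean.
#' @export
validate_definitions <- function(pathways) {
  if (inherits(pathways, "pathway_definition")) pathways <- list(pathways)
  findings <- list()
  add <- function(pid, kind, detail)
    findings[[length(findings) + 1L]] <<- data.frame(
      pathway_id = pid, kind = kind, detail = detail, stringsAsFactors = FALSE)
  ids <- vapply(pathways, function(p) p$pathway_id, "")

  for (p in pathways) {
    # reachability from "all" over the rule graph
    reached_steps <- character(); reached_rules <- character()
    walk <- function(rule_id) {
      if (rule_id %in% reached_rules) return(invisible())
      reached_rules <<- c(reached_rules, rule_id)
      for (inst in p$rules[[rule_id]]$instantiations)
        for (item in inst) {
          if (item %in% names(p$rules)) walk(item) else reached_steps <<- c(reached_steps, item)
        }
    }
    walk("all")
    for (s in setdiff(names(p$steps), reached_steps))
      add(p$pathway_id, "unreachable_step", s)
    for (r in setdiff(names(p$rules), reached_rules))
      add(p$pathway_id, "unused_rule", r)
    for (q in p$requirements) {
      target <- pathways[which(ids == q$req_pathway)]
      ok <- length(target) == 1L && q$req_step %in% names(target[[1L]]$steps)
      if (!ok)
        add(p$pathway_id, "unresolvable_requirement",
            paste0(q$scope, ": ", q$req_pathway, "/", q$req_step))
    }
  }
  if (length(findings) == 0L)
    return(data.frame(pathway_id = character(), kind = character(),
                      detail = character(), stringsAsFactors = FALSE))
  do.call(rbind, findings)
}

#' Read a directory of pathway definition files
#'
#' @param dir directory containing \code{*.pathway} (or \code{*.txt})
#'   definition files, one pathway per file.
#' @return named list of \code{pathway_definition} objects keyed by
#'   pathway id, in lexicographic file order.
#' @export
read_pathway_set <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.(pathway|txt)$", full.names = TRUE))
  if (length(files) == 0L) stop("no pathway definition files in ", dir)
  defs <- lapply(files, parse_pathway_file)
  ids <- vapply(defs, function(p) p$pathway_id, "")
  if (anyDuplicated(ids)) stop("duplicate pathway ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  names(defs) <- ids
  defs
}
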