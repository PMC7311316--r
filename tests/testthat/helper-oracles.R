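# Independent oracles used across the suite. These are deliberately
# written against the documented rules, separately from the package
# implementation, so the two can disagree.

aa20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

rand_prot <- function(n) paste(sample(aa20, n, replace = TRUE), collapse = "")

# --- classification oracle: a rule table evaluated on grids ---------------
# other_bits = NA means "no other hit". Returns the highest applicable tier.
oracle_blast_tier <- function(identity, coverage, bits, other_bits, status) {
  no_other <- is.na(other_bits)
  high <- status == "CHARACTERIZED" & identity > 40 & coverage > 0.80 &
    (no_other | bits >= other_bits + 10)
  med <- (identity > 40 & coverage > 0.70) |
    (identity > 30 & coverage > 0.80 & (no_other | bits > other_bits))
  low <- coverage >= 0.50
  ifelse(high, "high", ifelse(med, "medium", ifelse(low, "low", "none")))
}

oracle_hmm_tier <- function(coverage, other_identity, other_coverage) {
  no_other <- is.na(other_identity)
  high <- coverage >= 0.80 &
    (no_other | other_identity < 40 | other_coverage < 0.75)
  ifelse(high, "high", "medium")
}

# --- independent path expansion and best-path choice ----------------------
tier_rank <- c(low = 1L, medium = 2L, high = 3L)

# recursive enumeration over a rules list (named list of lists of
# character vectors), independent of expand_paths
brute_expand <- function(rules, id = "all") {
  out <- list()
  for (inst in rules[[id]]) {
    partial <- list(character())
    for (item in inst) {
      pieces <- if (item %in% names(rules)) brute_expand(rules, item) else list(item)
      partial <- unlist(lapply(partial, function(acc)
        lapply(pieces, function(p) c(acc, p))), recursive = FALSE)
    }
    out <- c(out, partial)
  }
  out
}

# argmax by explicit sort over all enumerated paths
brute_best_path <- function(rules, tiers) {
  paths <- brute_expand(rules)
  scores <- t(vapply(paths, function(steps) {
    r <- tier_rank[tiers[steps]]
    c(primary = min(r),
      secondary10 = 10 * sum(r == 3) - sum(r == 2) - 20 * sum(r == 1),
      len = length(steps))
  }, c(primary = 0, secondary10 = 0, len = 0)))
  ord <- order(-scores[, "primary"], -scores[, "secondary10"], -scores[, "len"],
               seq_along(paths))
  paths[[ord[1]]]
}

# random acyclic rule graph: rules may only reference steps and
# earlier-defined rules, so cycles are impossible by construction
random_rule_graph <- function(n_steps = 6, n_rules = 3, max_alts = 3) {
  steps <- paste0("s", seq_len(n_steps))
  rule_ids <- c(paste0("r", seq_len(n_rules - 1)), "all")
  rules <- list()
  for (k in seq_along(rule_ids)) {
    available <- c(steps, rule_ids[seq_len(k - 1)])
    n_alts <- sample.int(max_alts, 1)
    rules[[rule_ids[k]]] <- lapply(seq_len(n_alts), function(i)
      sample(available, sample.int(3, 1), replace = TRUE))
  }
  rules
}

# render a rules graph + steps as DSL text (every step gets a dummy matcher)
rules_to_dsl <- function(rules, pathway_id = "toy") {
  steps <- setdiff(unique(unlist(rules)), names(rules))
  c(paste("pathway", pathway_id),
    vapply(steps, function(s)
      paste0("step ", s, ": step ", s, " :: term:", s), ""),
    vapply(names(rules), function(rid)
      paste0("rule ", rid, " = ",
             paste(vapply(rules[[rid]], paste, "", collapse = " "), collapse = " | ")),
      ""))
}

# --- tiny reference-db / hit-row builders ---------------------------------
make_db <- function(proteins, hmms = NULL) {
  # proteins: data.frame(protein_id, sequence, description, ec_numbers, status)
  defaults <- data.frame(status = "CHARACTERIZED", source_db = "SwissProt",
                         ec_numbers = "", description = "",
                         stringsAsFactors = FALSE)
  for (col in names(defaults))
    if (is.null(proteins[[col]])) proteins[[col]] <- defaults[[col]]
  if (is.null(hmms)) hmms <- read_hmm_meta(character())
  list(proteins = proteins, hmms = hmms)
}

hit_row <- function(query_id, subject_id, identity = 80, bits = 200,
                    q_start = 1, q_end = 100, s_start = 1, s_end = 100,
                    qlen = 100, slen = 100, evalue = 1e-30) {
  data.frame(query_id = query_id, subject_id = subject_id,
             percent_identity = identity, bit_score = bits, e_value = evalue,
             q_start = q_start, q_end = q_end, s_start = s_start, s_end = s_end,
             query_length = qlen, subject_length = slen, stringsAsFactors = FALSE)
}

other_row <- function(subject_id = "other", bits = 100, identity = 50, coverage = 0.9) {
  data.frame(subject_id = subject_id, bit_score = bits, percent_identity = identity,
             subject_coverage = coverage, stringsAsFactors = FALSE)
}

candidate_df <- function(step_id, parts, confidence, bits = 100) {
  data.frame(step_id = step_id, parts = parts, origin = "blast",
             confidence = confidence, percent_identity = 80,
             subject_coverage = 0.9, bit_score = bits, subject_id = "REF",
             other_id = NA_character_, other_bit_score = NA_real_,
             other_identity = NA_real_, other_coverage = NA_real_,
             stringsAsFactors = FALSE)
}

# a minimal step query set
make_sq <- function(step_id = "stp", characterized_ids = character(),
                    curated_ids = character(), ignored = character(), hmms = NULL) {
  mk <- function(ids) data.frame(protein_id = ids, stringsAsFactors = FALSE)
  if (is.null(hmms)) hmms <- read_hmm_meta(character())
  structure(list(step_id = step_id, characterized = mk(characterized_ids),
                 curated_only = mk(curated_ids), hmms = hmms, ignored = ignored),
            class = "step_query_set")
}
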