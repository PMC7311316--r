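test_that("other-hit search honors region overlap, ignore list and max-bits rule", {
  sq <- make_sq("sx", characterized_ids = "REF_X", ignored = "IGN1")
  # fusion-shaped candidate: X half is residues 1..300, Y half 301..600
  db_hits <- rbind(
    hit_row("fus", "REF_X", bits = 200, q_start = 1, q_end = 300,
            s_start = 1, s_end = 300, qlen = 600, slen = 300),
    hit_row("fus", "REF_Y", bits = 500, q_start = 301, q_end = 600,
            s_start = 1, s_end = 300, qlen = 600, slen = 300))
  region_x <- list(start = 1, end = 300)
  # the huge-bit-score Y-half hit overlaps 0% of the X region: discarded
  expect_null(find_other_hit("fus", region_x, sq, db_hits, protein_length = 600))
  # with the region filter disabled it becomes the other hit
  cfg <- default_config(region_filter = FALSE)
  oh <- find_other_hit("fus", region_x, sq, db_hits, protein_length = 600,
                       config = cfg)
  expect_identical(oh$subject_id, "REF_Y")

  # competitor in the ignored set is disregarded
  db_hits2 <- rbind(db_hits[1, ],
                    hit_row("fus", "IGN1", bits = 900, q_start = 1, q_end = 300,
                            qlen = 600))
  expect_null(find_other_hit("fus", region_x, sq, db_hits2, protein_length = 600))

  # two surviving competitors: the higher-bits one wins
  db_hits3 <- rbind(db_hits[1, ],
                    hit_row("fus", "C1", bits = 120, q_start = 1, q_end = 300, qlen = 600),
                    hit_row("fus", "C2", bits = 95, q_start = 1, q_end = 300, qlen = 600))
  expect_identical(find_other_hit("fus", region_x, sq, db_hits3,
                                  protein_length = 600)$subject_id, "C1")

  # a competitor overlapping just under half the region is discarded
  db_hits4 <- rbind(db_hits[1, ],
                    hit_row("fus", "C3", bits = 400, q_start = 1, q_end = 149,
                            qlen = 600))
  expect_null(find_other_hit("fus", region_x, sq, db_hits4, protein_length = 600))

  expect_error(find_other_hit("fus", list(start = 0, end = 300), sq, db_hits,
                              protein_length = 600), "outside protein bounds")
})

test_that("alignment-candidate tiers follow the printed threshold rules", {
  cls <- function(id, cov, bits = 200, status = "CHARACTERIZED", other = NULL)
    classify_blast_candidate(list(percent_identity = id, subject_coverage = cov,
                                  bit_score = bits), status, other)
  expect_identical(cls(85, 0.95), "high")
  # fails the +10 margin, passes the 40/70 regardless-of-other rule
  expect_identical(cls(45, 0.95, bits = 200, other = other_row(bits = 195)), "medium")
  # fails "bit score higher than other", passes 50% coverage
  expect_identical(cls(35, 0.85, bits = 200, other = other_row(bits = 250)), "low")
  # curated-only can never be high
  expect_identical(cls(45, 0.95, status = "CURATED_ONLY"), "medium")
  # boundary pinning: "over 40%" is strict, "at least 50% coverage" is not
  expect_identical(cls(40, 0.95), "medium")     # 40 is not over 40
  expect_identical(cls(41, 0.80), "medium")     # 0.80 is not over 0.80
  expect_identical(cls(30, 0.95), "low")        # 30 is not over 30
  expect_identical(cls(29, 0.50), "low")        # identity below threshold, cov >= 0.5
  expect_identical(cls(29, 0.49), "none")
  # margin boundary: exactly +10 still high
  expect_identical(cls(85, 0.95, bits = 210, other = other_row(bits = 200)), "high")
  expect_identical(cls(85, 0.95, bits = 209, other = other_row(bits = 200)), "medium")
})

test_that("hmm-candidate tiers follow the model-coverage and other-hit rules", {
  hmm_hit <- function(cov) list(hmm_start = 1, hmm_end = round(cov * 100),
                                model_length = 100, bit_score = 80)
  expect_identical(classify_hmm_candidate(hmm_hit(0.95)), "high")
  expect_identical(classify_hmm_candidate(hmm_hit(0.80)), "high")  # at least 80%
  expect_identical(classify_hmm_candidate(
    hmm_hit(0.95), other_row(identity = 55, coverage = 0.90)), "medium")
  expect_identical(classify_hmm_candidate(
    hmm_hit(0.95), other_row(identity = 35, coverage = 0.90)), "high")
  expect_identical(classify_hmm_candidate(
    hmm_hit(0.95), other_row(identity = 55, coverage = 0.70)), "high")
  expect_identical(classify_hmm_candidate(hmm_hit(0.60)), "medium")
})

test_that("tier never drops when identity or coverage increases", {
  others <- list(NULL, other_row(bits = 195), other_row(bits = 260))
  for (status in c("CHARACTERIZED", "CURATED_ONLY")) {
    for (other in others) {
      prev_by_cov <- NULL
      for (id in seq(25, 100, by = 5)) {
        tiers <- vapply(seq(0.4, 1.0, by = 0.1), function(cov)
          classify_blast_candidate(
            list(percent_identity = id, subject_coverage = cov, bit_score = 200),
            status, other), "")
        ranks <- c(none = 0, low = 1, medium = 2, high = 3)[tiers]
        expect_true(all(diff(ranks) >= 0))           # monotone in coverage
        if (!is.null(prev_by_cov)) expect_true(all(ranks >= prev_by_cov))
        prev_by_cov <- ranks                          # monotone in identity
      }
    }
  }
})

test_that("split joining enforces margin, overlap and combined coverage", {
  mk_pair <- function(s1, e1, s2, e2, bits = c(300, 300), slen = 1000) {
    rbind(hit_row("partA", "REF", identity = 90, bits = bits[1],
                  q_start = 1, q_end = e1 - s1 + 1, s_start = s1, s_end = e1,
                  qlen = e1 - s1 + 1, slen = slen),
          hit_row("partB", "REF", identity = 90, bits = bits[2],
                  q_start = 1, q_end = e2 - s2 + 1, s_start = s2, s_end = e2,
                  qlen = e2 - s2 + 1, slen = slen))
  }
  no_others <- list(NULL, NULL)

  # tiling halves with 3% overlap: joined, full coverage, high
  j <- join_split_candidates(mk_pair(1, 520, 505, 1000), no_others)
  expect_identical(j$confidence, "high")
  expect_equal(j$subject_coverage, 1.0)
  expect_identical(j$parts, c("partA", "partB"))

  # overlap 101 of a 321-residue span (> 20% of either): rejected
  expect_null(join_split_candidates(mk_pair(1, 300, 200, 520), no_others))

  # combined coverage 0.36 < 0.70: rejected
  expect_null(join_split_candidates(mk_pair(1, 300, 600, 660), no_others))

  # a part without a 10-bit margin over its own other hit: rejected
  expect_null(join_split_candidates(mk_pair(1, 520, 505, 1000),
                                    list(NULL, other_row(bits = 295))))
  # margin met exactly: joined
  expect_identical(join_split_candidates(mk_pair(1, 520, 505, 1000),
                                         list(NULL, other_row(bits = 290)))$confidence,
                   "high")

  # same protein twice is not a split
  same <- mk_pair(1, 520, 505, 1000)
  same$query_id <- "partA"
  expect_null(join_split_candidates(same, no_others))

  # kept only when it outranks both components
  expect_null(join_split_candidates(mk_pair(1, 520, 505, 1000), no_others,
                                    component_confidences = c("high", "low")))
  expect_identical(join_split_candidates(mk_pair(1, 520, 505, 1000), no_others,
                                         component_confidences = c("low", "low"))$confidence,
                   "high")

  # combined identity is the alignment-length-weighted mean
  pair <- mk_pair(1, 520, 505, 1000)
  pair$percent_identity <- c(100, 50)
  j2 <- join_split_candidates(pair, no_others)
  expect_equal(j2$percent_identity,
               (100 * 520 + 50 * 496) / (520 + 496))
})

test_that("step confidence is the best candidate's tier; no candidates means low", {
  step <- list(step_id = "s")
  cands <- rbind(
    candidate_df("s", "p1", "medium", bits = 150),
    candidate_df("s", "p2", "high", bits = 280),
    candidate_df("s", "p3", "high", bits = 310),
    candidate_df("s", "p4", "low", bits = 400))
  sr <- score_step(step, cands)
  expect_identical(sr$confidence, "high")
  expect_identical(sr$candidates$parts[1:2], c("p3", "p2"))  # tier then bits
  empty <- score_step(step, NULL)
  expect_identical(empty$confidence, "low")
  expect_identical(nrow(empty$candidates), 0L)
})

test_that("a fused protein is credited to both steps; the region rule is what saves it", {
  set.seed(31)
  spec <- fixture_spec(1201, genomes = list(
    g = list(plant("serA", "fusion", partner = "serC"),
             plant("serB", "ortholog"))),
    pathway_ids = "ser", marker_count = 0L)
  u <- build_universe(spec)
  res <- analyze_genome(u$proteomes$g, u$pathways, u$db, "g")
  expect_identical(res$step_results$ser$serA$confidence, "high")
  expect_identical(res$step_results$ser$serC$confidence, "high")
  fused_id <- grep("fusion", names(u$proteomes$g), value = TRUE)
  expect_identical(res$step_results$ser$serA$candidates$parts[1], fused_id)
  expect_identical(res$step_results$ser$serC$candidates$parts[1], fused_id)

  # disabling the relevant-region rule demotes at least one of the pair
  res2 <- analyze_genome(u$proteomes$g, u$pathways, u$db, "g",
                         config = default_config(region_filter = FALSE))
  tiers <- c(res2$step_results$ser$serA$confidence,
             res2$step_results$ser$serC$confidence)
  expect_true(any(tiers != "high"))
})

test_that("exact halves of a planted protein are joined to the intact tier", {
  set.seed(32)
  spec <- fixture_spec(1301, genomes = list(
    g = list(plant("serA", "split", identity = 1.0, breakpoint = 0.5),
             plant("serC", "ortholog"), plant("serB", "ortholog"))),
    pathway_ids = "ser", marker_count = 0L)
  u <- build_universe(spec)
  res <- analyze_genome(u$proteomes$g, u$pathways, u$db, "g")
  sr <- res$step_results$ser$serA
  expect_identical(sr$confidence, "high")
  expect_identical(sr$candidates$origin[1], "split")
  expect_identical(sort(strsplit(sr$candidates$parts[1], "+", fixed = TRUE)[[1]]),
                   c("g_serA_part1", "g_serA_part2"))
  # the intact protein would be high too (100% identity, full coverage)
  intact <- analyze_genome(
    c(whole = u$db$proteins$sequence[u$db$proteins$protein_id == "REF_serA"]),
    u$pathways, u$db, "g2")
  expect_identical(intact$step_results$ser$serA$confidence, "high")
})
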