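test_that("path scores combine the stated weights exactly", {
  expect_equal(score_path(c("high", "high", "high")),
               list(primary = "high", secondary = 3.0, secondary10 = 30L, length = 3L))
  expect_equal(score_path(c("high", "medium", "low")),
               list(primary = "low", secondary = -1.1, secondary10 = -11L, length = 3L))
  expect_equal(score_path(c("medium", "medium")),
               list(primary = "medium", secondary = -0.2, secondary10 = -2L, length = 2L))
  expect_error(score_path(character()), "empty path")
})

test_that("path score is invariant under reordering of the steps", {
  set.seed(41)
  for (i in 1:25) {
    tiers <- sample(c("high", "medium", "low"), sample(2:7, 1), replace = TRUE)
    expect_identical(score_path(tiers)[c("primary", "secondary10")],
                     score_path(sample(tiers))[c("primary", "secondary10")])
  }
})

two_route <- function(alt1, alt2) {
  steps <- unique(c(alt1, alt2))
  parse_pathway_text(c("pathway p",
    vapply(steps, function(s) paste0("step ", s, ": s :: term:", s), ""),
    paste("rule all =", paste(alt1, collapse = " "), "|",
          paste(alt2, collapse = " "))))
}

test_that("best-path selection uses primary tier, secondary score, then length", {
  # primary high beats primary medium
  pd <- two_route(c("a", "b"), c("a", "c", "b"))
  bp <- best_path(pd, c(a = "high", b = "high", c = "medium"))
  expect_identical(bp$step_ids, c("a", "b"))
  expect_identical(bp$primary_confidence, "high")

  # same primary: higher secondary wins ([H,M] 0.9 vs [M,H,H] 1.9)
  pd2 <- two_route(c("a", "b"), c("c", "d", "e"))
  bp2 <- best_path(pd2, c(a = "high", b = "medium", c = "medium",
                          d = "high", e = "high"))
  expect_identical(bp2$step_ids, c("c", "d", "e"))
  expect_equal(bp2$secondary_score, 1.9)

  # full tie on (primary, secondary, length): first expansion wins
  pd3 <- two_route(c("a", "b"), c("c", "d"))
  bp3 <- best_path(pd3, c(a = "medium", b = "high", c = "high", d = "medium"))
  expect_identical(bp3$step_ids, c("a", "b"))
  expect_identical(bp3$expansion_index, 1L)

  # same primary and secondary impossible with different counts; longer
  # path preferred when achievable: [M,M] (-0.2) loses to [M] (-0.1) on
  # secondary, so construct an actual length tie-break: two all-high routes
  pd4 <- two_route(c("a", "b", "c"), c("d", "e", "f"))
  bp4 <- best_path(pd4, c(a = "high", b = "high", c = "high",
                          d = "high", e = "high", f = "high"))
  expect_identical(bp4$expansion_index, 1L)
})

test_that("best path equals brute-force argmax on random graphs", {
  set.seed(43)
  for (i in 1:150) {
    rules <- random_rule_graph(n_steps = sample(3:6, 1), n_rules = sample(2:4, 1))
    pd <- parse_pathway_text(rules_to_dsl(rules))
    steps <- names(pd$steps)
    tiers <- stats::setNames(sample(c("high", "medium", "low"),
                                    length(steps), replace = TRUE), steps)
    got <- best_path(pd, tiers)
    want <- brute_best_path(rules, tiers)
    expect_identical(got$step_ids, want)
  }
})

test_that("gap lists are consistent with best-path confidences", {
  set.seed(44)
  for (i in 1:20) {
    rules <- random_rule_graph()
    pd <- parse_pathway_text(rules_to_dsl(rules))
    tiers <- stats::setNames(sample(c("high", "medium", "low"),
                                    length(pd$steps), replace = TRUE),
                             names(pd$steps))
    bp <- best_path(pd, tiers)
    gaps <- path_gaps(bp)
    expect_identical(nrow(gaps), sum(tiers[bp$step_ids] != "high"))
    expect_true(all(gaps$confidence %in% c("medium", "low")))
  }
})

test_that("requirement warnings fire only when the scoped rule is on the best path", {
  defs <- read_pathway_set(system.file("extdata", "pathways", package = "pathgaps"))
  tiers <- function(...) {
    tl <- list(...)
    lapply(tl, function(x) x)
  }
  mk_results <- function(arg_tiers, ser_tiers, met_tiers) {
    sr <- list(arg = as.list(arg_tiers), ser = as.list(ser_tiers),
               met = as.list(met_tiers))
    bp <- lapply(names(sr), function(pid)
      best_path(defs[[pid]], unlist(sr[[pid]])))
    names(bp) <- names(sr)
    list(bp = bp, sr = sr)
  }
  # succinylated route selected, serA low: warning naming serA
  r <- mk_results(c(argA = "low", argB = "high", argA2 = "high", argC = "high"),
                  c(serA = "low", serC = "high", serB = "high"),
                  c(metA = "high", metB = "high", metC = "high",
                    metZ = "low", metE = "high"))
  w <- check_requirements(r$bp, r$sr, defs)
  expect_length(w, 1)
  expect_match(w, "serA")
  # same route, serA high: no warning
  r2 <- mk_results(c(argA = "low", argB = "high", argA2 = "high", argC = "high"),
                   c(serA = "high", serC = "high", serB = "high"),
                   c(metA = "high", metB = "high", metC = "high",
                     metZ = "low", metE = "high"))
  expect_length(check_requirements(r2$bp, r2$sr, defs), 0)
  # acetylated route selected: requirement out of scope even if serA is low
  r3 <- mk_results(c(argA = "high", argB = "high", argA2 = "low", argC = "high"),
                   c(serA = "low", serC = "high", serB = "high"),
                   c(metA = "high", metB = "high", metC = "high",
                     metZ = "low", metE = "high"))
  expect_length(check_requirements(r3$bp, r3$sr, defs), 0)
})

test_that("mutually exclusive route selections are flagged", {
  # two toy pathways that must not both run their 'via' route
  pa <- parse_pathway_text(c("pathway fwd",
    "step f1: f :: term:f1", "step f2: f :: term:f2",
    "rule via = f1 f2", "rule all = via",
    "require via: rev/r1 absent"))
  pb <- parse_pathway_text(c("pathway rev",
    "step r1: r :: term:r1", "step r2: r :: term:r2",
    "rule all = r1 r2"))
  defs <- list(fwd = pa, rev = pb)
  sr <- list(fwd = list(f1 = "high", f2 = "high"),
             rev = list(r1 = "high", r2 = "high"))
  bp <- list(fwd = best_path(pa, unlist(sr$fwd)),
             rev = best_path(pb, unlist(sr$rev)))
  w <- check_requirements(bp, sr, defs)
  expect_length(w, 1)
  expect_match(w, "incompatible")
  # no warning when the conflicting step is absent (low) on the other side
  sr2 <- sr; sr2$rev$r1 <- "low"
  bp2 <- list(fwd = bp$fwd, rev = best_path(pb, unlist(sr2$rev)))
  expect_length(check_requirements(bp2, sr2, defs), 0)
})
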