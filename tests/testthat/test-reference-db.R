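recs <- function(desc, src = "SwissProt") {
  data.frame(protein_id = paste0("P", seq_along(desc)), status = "CHARACTERIZED",
             source_db = src, ec_numbers = "", description = desc,
             sequence = "ACDEFGHIKL", stringsAsFactors = FALSE)
}

test_that("uncharacterized-record filter applies the stated description rules", {
  kept <- function(desc, src = "SwissProt")
    nrow(filter_uncharacterized(recs(desc, src))) == 1L
  expect_false(kept("Uncharacterized protein YqeK"))
  expect_false(kept("uncharacterized oxidoreductase"))
  expect_false(kept("DUF1234 family protein"))
  expect_false(kept("upf0001 family protein"))
  expect_true(kept("DUF family protein"))          # no digits: not a family tag
  expect_true(kept("PFAM-like family protein"))
  expect_false(kept("putative oxidoreductase", "EcoCyc"))
  expect_true(kept("putative oxidoreductase", "SwissProt"))
  expect_false(kept("protein YdiU", "CharProtDB"))
  expect_true(kept("proteinase K", "EcoCyc"))      # word boundary after 'protein'
  expect_false(kept("probably a kinase", "CharProtDB"))
  expect_true(kept("probably a kinase", "EcoCyc"))
})

test_that("filter agrees with a regex oracle on a generated description corpus", {
  set.seed(11)
  words <- c("uncharacterized", "putative", "protein", "probably", "kinase",
             "DUF1234", "family", "synthase", "subunit", "reductase")
  srcs <- c("SwissProt", "EcoCyc", "CharProtDB", "BRENDA")
  for (i in 1:200) {
    d <- paste(sample(words, sample(1:4, 1), replace = TRUE), collapse = " ")
    s <- sample(srcs, 1)
    oracle_drop <-
      grepl("^uncharacterized", d, ignore.case = TRUE) ||
      grepl("^(DUF|PF|UPF)[0-9]+ family protein$", d, ignore.case = TRUE) ||
      (s %in% c("EcoCyc", "CharProtDB") &&
         grepl("^(putative|protein)\\b", d, ignore.case = TRUE)) ||
      (s == "CharProtDB" && grepl("^probably\\b", d, ignore.case = TRUE))
    expect_identical(nrow(filter_uncharacterized(recs(d, s))) == 0L, oracle_drop,
                     info = paste(s, d))
  }
})

test_that("curated subset clustering splits by EC and is deterministic", {
  set.seed(5)
  s <- rand_prot(150)
  same <- data.frame(protein_id = c("B", "A", "C"), status = "CURATED_ONLY",
                     source_db = "SwissProt", ec_numbers = "2.7.1.39",
                     description = "x", sequence = s, stringsAsFactors = FALSE)
  out <- build_curated_subset(same)
  expect_identical(out$protein_id, "A")   # lexicographically smallest id

  two_ec <- same[1:2, ]
  two_ec$ec_numbers <- c("2.7.1.39", "4.2.3.1")
  expect_identical(sort(build_curated_subset(two_ec)$protein_id), c("A", "B"))

  expect_identical(nrow(build_curated_subset(same[0, ])), 0L)
})

test_that("sequences below the identity threshold do not cluster", {
  set.seed(6)
  base <- rand_prot(160)
  seqs <- vapply(1:10, function(i) mutate_to_identity(base, 0.55)$sequence, "")
  # verify with the aligner that all pairwise identities are below 60%
  for (i in 1:9) for (j in (i + 1):10)
    expect_lt(global_align_identity(seqs[i], seqs[j])$identity, 60)
  df <- data.frame(protein_id = sprintf("Q%02d", 1:10), status = "CURATED_ONLY",
                   source_db = "SwissProt", ec_numbers = "1.1.1.1",
                   description = "x", sequence = seqs, stringsAsFactors = FALSE)
  expect_identical(nrow(build_curated_subset(df)), 10L)
})

test_that("term matching respects word boundaries (vs a regex oracle)", {
  expect_true(term_match("hisF", "Imidazole glycerol phosphate synthase subunit HisF"))
  expect_false(term_match("hisF", "HisFG fusion"))
  expect_true(term_match("hisF", "hisF"))
  expect_true(term_match("hisF", "(HisF)"))
  expect_false(term_match("hisF", "xhisF"))

  set.seed(12)
  tokens <- c("hisF", "hisFG", "serA", "Aser", "kinase2", "2kinase")
  seps <- c(" ", "-", "/", "", "(", ")")
  for (i in 1:200) {
    term <- sample(c("hisF", "serA", "kinase2"), 1)
    desc <- paste0(sample(seps, 1), sample(tokens, 1), sample(seps, 1),
                   sample(tokens, 1), sample(seps, 1))
    oracle <- grepl(paste0("(?<![A-Za-z0-9])", term, "(?![A-Za-z0-9])"),
                    desc, ignore.case = TRUE, perl = TRUE)
    expect_identical(term_match(term, desc), oracle, info = paste(term, desc))
  }
})

test_that("incomplete EC numbers match any completion", {
  db <- make_db(data.frame(
    protein_id = c("X1", "X2", "X3"),
    sequence = "ACDEFGHIKL",
    ec_numbers = c("2.7.1.39", "2.7.2.4", "4.2.3.1"),
    description = c("a", "b", "c"), stringsAsFactors = FALSE))
  step <- list(step_id = "s", matchers = list(list(kind = "EC", value = "2.7.1.-")),
               ignore = list())
  sq <- resolve_step_queries(step, db)
  expect_identical(sq$characterized$protein_id, "X1")
  step$matchers[[1]]$value <- "2.7.-.-"
  expect_setequal(resolve_step_queries(step, db)$characterized$protein_id,
                  c("X1", "X2"))
})

test_that("step query resolution separates pools, records provenance and ignores", {
  db <- make_db(data.frame(
    protein_id = c("CHAR1", "CUR1", "OTHER", "Q0QLE2"),
    sequence = "ACDEFGHIKL",
    status = c("CHARACTERIZED", "CURATED_ONLY", "CHARACTERIZED", "CHARACTERIZED"),
    ec_numbers = c("2.5.1.49", "2.5.1.49", "1.1.1.1", "4.2.1.33"),
    description = c("sulfhydrylase", "annotated sulfhydrylase",
                    "unrelated", "methylmalate dehydratase"),
    stringsAsFactors = FALSE))
  step <- list(step_id = "leuC",
               matchers = list(list(kind = "EC", value = "2.5.1.49")),
               ignore = list(list(kind = "UNIPROT", value = "Q0QLE2"),
                             list(kind = "UNIPROT", value = "Q0QLE1")))
  sq <- resolve_step_queries(step, db)
  expect_identical(sq$characterized$protein_id, "CHAR1")
  expect_identical(sq$curated_only$protein_id, "CUR1")
  expect_identical(sq$characterized$matched_by, "EC:2.5.1.49")
  # ignore ids are recorded even when absent from the database
  expect_setequal(sq$ignored, c("Q0QLE2", "Q0QLE1"))
  # curated-only records never enter the characterized pool
  expect_false(any(sq$characterized$protein_id %in%
                     db$proteins$protein_id[db$proteins$status == "CURATED_ONLY"]))
  # pure function of (step, db)
  expect_identical(resolve_step_queries(step, db), sq)
  # matcher with no members warns in the report, not fatally
  step2 <- list(step_id = "s2", matchers = list(list(kind = "EC", value = "9.9.9.9")),
                ignore = list())
  sq2 <- resolve_step_queries(step2, db)
  expect_match(attr(sq2, "warnings"), "selected no database objects")
})

test_that("reference db round-trips through its on-disk format", {
  set.seed(7)
  db <- make_db(data.frame(
    protein_id = c("A1", "B2"), sequence = c(rand_prot(120), rand_prot(80)),
    ec_numbers = c("1.1.1.1", ""), description = c("alpha", "beta"),
    status = c("CHARACTERIZED", "CURATED_ONLY"), stringsAsFactors = FALSE))
  dir <- tempfile("db")
  write_reference_db(db, dir)
  back <- read_reference_db(dir)
  cols <- c("protein_id", "status", "source_db", "ec_numbers", "description", "sequence")
  expect_identical(back$proteins[cols], db$proteins[cols])
  # sidecar/FASTA mismatch is fatal
  meta <- utils::read.delim(file.path(dir, "proteins.tsv"))
  meta$protein_id[1] <- "MISSING"
  utils::write.table(meta, file.path(dir, "proteins.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_error(read_reference_db(dir), "absent from proteins.faa")
})
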