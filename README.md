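# pathgaps

Homology-based reconstruction of amino acid biosynthesis pathways in
bacterial and archaeal genomes, with explicit confidence tiers and gap
reporting.

Checking whether a microbe can synthesize an amino acid means checking
its genome for *every* step of *every* known route — including variant
pathways, fused genes carrying two activities, and ancestral enzymes
split across two genes. Best-hit annotation pipelines handle none of
these well, and annotation databases are full of unverified labels.
`pathgaps` is for microbiologists and comparative genomicists who want a
conservative, traceable reconstruction: instead of predicting
prototrophy or auxotrophy, it reports the most plausible route for each
pathway and highlights exactly where the evidence is weak.

## The method

A **pathway** is a set of **steps** (one enzymatic reaction, or one
subunit of a heteromeric enzyme) organised by **rules**: each rule lists
alternative ordered sequences of steps and subpathway rules, and the
distinguished rule `all` defines the pathway. Each step is defined by
matchers — EC numbers, description terms, curated identifiers, or
profile-HMM accessions — resolved against a reference database of
**characterized** proteins (experimental evidence; the only basis for
high confidence) and **curated-only** proteins (annotated enzymes
without experimental evidence).

Candidates for a step come from local alignment (hits at ≥ 30 % identity,
E < 0.01) and from profile HMMs (hits at or above the curator's trusted
cutoff). Each candidate is compared against the *full* characterized
database to find its **other hit** — the best-scoring alignment to a
protein with a different function, restricted to alignments that overlap
at least 50 % of the candidate's relevant region (this region restriction
is what lets one fusion protein score highly for two steps). With
identity *I*, subject coverage *C*, bit score *B*, and other-hit bit
score *B′*:

* **high** — characterized subject, *I* > 40 %, *C* > 0.80, and
  *B* ≥ *B′* + 10 (or HMM model coverage ≥ 0.80 with the other hit under
  40 % identity or under 75 % coverage);
* **medium** — *I* > 40 % and *C* > 0.70 (regardless of the other hit),
  or *I* > 30 %, *C* > 0.80 and *B* > *B′*, or any hit above an HMM
  trusted cutoff;
* **low** — *C* ≥ 0.50. A step with no candidates at all is also low,
  so incomplete pathways stay comparable.

Two proteins aligning to non-overlapping regions (≤ 20 % mutual overlap)
of the same reference protein, each ≥ 10 bits above its own other hit
and jointly covering ≥ 70 % of it, are **joined** as a split candidate.
A step's confidence is its best candidate's; a path's primary score is
the *minimum* over its steps; ties break by the secondary score
(−2 per low, −0.1 per medium, +1 per high step), then by the longer
path. Steps on the selected best path below high confidence are
**gaps**. Finally, ribosomal marker proteins decide whether the genome
is related to a cataloged organism (≥ 10 one-to-one marker hits at
≥ 50 % identity / ≥ 70 % coverage with median identity ≥ 75 %); gaps
shared with a related organism that grows in minimal medium are flagged
as **known gaps** — likely unknown biology rather than a missing
capability.

## Worked example

Everything below runs offline: the fixture generator builds a reference
database, pathway definitions, proteomes with planted orthologs /
fusions / splits / decoys, and a known-gap catalog.

```r
library(pathgaps)

u <- build_universe(example_fixture_spec(1))
res <- analyze_genome(u$proteomes$g_split, u$pathways, u$db,
                      genome_id = "g_split")
print(res)
#> Genome 'g_split': 3 pathway(s), 1 gap(s)
#>   arg [medium]: argA(h) argB(h) argC(m)
#>   met [high]: metA(h) metZ(h) metE(h)
#>   ser [high]: serA(h) serC(h) serB(h)
summary(res)
#>   pathway_id primary_confidence secondary_score n_steps n_gaps      best_path
#> 1        arg             medium             1.9       3      1 argA argB argC
#> 2        met               high             3.0       3      0 metA metZ metE
#> 3        ser               high             3.0       3      0 serA serC serB
```

This genome carries a planted decoy for `argC`: its candidate is over
40 % identical with good coverage, but a characterized protein with a
different function scores nearly as well, so the step is demoted to
medium — a gap on the arginine route. `metE` was planted as a split
gene, and the two pieces are joined back into one high-confidence
candidate:

```r
res$step_results$met$metE$candidates[1, c("parts", "origin", "confidence",
                                          "percent_identity", "subject_coverage")]
#>                                   parts origin confidence percent_identity subject_coverage
#> 1 g_split_metE_part1+g_split_metE_part2  split       high         81.35593        0.9833333
```

Marker-based relatedness then decides which gaps are "known" in the
catalog (here `argC` is a genuine gap — it is not cataloged):

```r
catalog <- read_known_gap_catalog(u$catalog_dir)
hmms <- read_hmm_meta(sort(list.files(file.path(u$catalog_dir, "marker_hmms"),
                                      pattern = "\\.hmm$", full.names = TRUE)))
qp <- extract_markers(u$proteomes$g_split, hmms, "g_split")
res <- mark_known_gaps(res, catalog, qp)
res$gaps
#>   pathway_id step_id confidence known_gap
#> 1        arg    argC     medium
```

File-level entry points (`cmd_analyze`, `cmd_known_gaps`) read FASTA /
definition / database directories and write `result.json`,
`candidates.tsv` and `summary.tsv`; `inst/cli/pathgaps` wraps them as
`analyze`, `known-gaps`, `validate-defs` and `make-fixtures`
subcommands.

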