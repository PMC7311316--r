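---
title: "Confidence-tiered pathway reconstruction: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confidence-tiered pathway reconstruction: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathgaps)
```

## The reconstruction model

The engine answers a narrow question well rather than a broad one
badly: *for each pathway, which concrete route through its steps is best
supported by homology, and where exactly is the support weak?* It never
claims an organism can or cannot make a compound — candidate evidence is
graded and the grading is exposed, so a person can decide.

A pathway is a rule tree. Steps are leaves; each rule holds one or more
alternative ordered instantiations whose items are steps or other rules
(subpathways); `all` is the root. `expand_paths()` inlines subpathways
recursively and takes the Cartesian product of alternatives
(depth-first, in written order), so scoring operates on plain step
sequences. The expansion order is part of the contract: it is the final
tie-break, so it is deterministic and tested. A cap (default 10,000
paths) turns combinatorial blow-up into an explicit error — realistic
definition sets are orders of magnitude below it.

Candidate finding is two-channel. The alignment channel searches the
genome's proteins against the step's characterized and curated-only
reference proteins and accepts hits at ≥ 30 % identity with E < 0.01.
The profile channel searches the step's HMMs and accepts hits at or
above each profile's trusted cutoff — the curator's own bit-score
threshold, which is why a profile without one is rejected at load time
rather than searched permissively.

The discriminating device is the *other hit*. Every candidate is also
compared against the full characterized database; hits to proteins that
match the step (or sit on its ignore list) are disregarded, as are hits
overlapping less than half of the candidate's relevant region — the
query range of the step alignment, or the HMM hit's envelope. What
survives with the highest bit score represents "this protein may really
do something else". The region restriction is the fusion rescue: in a
two-domain fusion, each half is judged only against competitors
overlapping *its* region, so the other half's (often stronger) hit
cannot veto it.

Classification applies the printed thresholds exactly as phrased:
"over" is a strict inequality, "at least" is not, and the boundary cases
(identity exactly 40, coverage exactly 0.80, margin exactly +10) are
pinned in tests so the convention cannot drift. Curated-only subjects
cap at medium: without experimental evidence, no annotation is allowed
to produce a high-confidence claim. Low confidence requires only ≥ 50 %
coverage; the printed low rule mentions neither the other hit nor a
margin, so low ignores them — a reading we record rather than guess
around, and the tier grid in the tests fixes it.

Split joining mirrors the biology of a bisected gene: two distinct
proteins tiling the same reference protein (≤ 20 % mutual overlap in
subject coordinates, which is the only coordinate system the two parts
share), each ≥ 10 bits clear of its own other hit, jointly covering
≥ 70 % of the subject. The joined candidate's identity is the
alignment-length-weighted mean of the parts — the reference is silent
here, so this is our documented choice — and the join is kept only when
it outranks both parts alone. Three-way splits are out of scope.

Path scoring is lexicographic: primary = minimum step tier, then the
secondary sum with weights −2 / −0.1 / +1 for low / medium / high, then
path length, then expansion order. The secondary score is computed in
tenths as scaled integers, because accumulating 0.1 in floating point
can turn exact ties into platform-dependent choices. Requirements — "this route
presumes step X of pathway Y", or "these two routes are mutually
exclusive" — fire only when the scoped rule is actually used on the
selected best path; a route that lost the path competition should not
generate warnings.

Relatedness for known-gap transfer uses single-copy ribosomal markers:
one protein per marker (markers hit by two or more proteins are dropped
outright — a duplicated marker is not a reliable witness), global
alignment per shared marker, hits kept at ≥ 50 % identity and ≥ 70 %
coverage, one-to-one only, related when ≥ 10 hits survive with median
identity ≥ 75 %. The query genome is always the side being searched;
because the per-pair identity measure is global and symmetric, the
asymmetry only affects which markers exist, not their identities.

## Tunable parameters

All thresholds live in `default_config()` and are overridable (per call
or via the CLI's YAML config):

| parameter | default | unit / side | role |
|---|---|---|---|
| `min_identity`, `max_evalue` | 30, 0.01 | % over aligned columns; E | search acceptance |
| `high_identity`, `high_coverage`, `high_margin` | 40, 0.80, 10 | %, subject fraction, bits | high tier |
| `medium_identity`, `medium_coverage` | 40, 0.70 | %, subject fraction | medium, other-hit-independent route |
| `medium2_identity`, `medium2_coverage` | 30, 0.80 | %, subject fraction | medium, margin route |
| `low_coverage` | 0.50 | subject fraction | low tier |
| `split_margin`, `split_max_overlap`, `split_min_coverage` | 10, 0.20, 0.70 | bits, fraction of either alignment, subject fraction | split joining |
| `hmm_high_coverage`, `hmm_other_identity`, `hmm_other_coverage` | 0.80, 40, 0.75 | model fraction, %, subject fraction | HMM high tier |
| `region_min_overlap` | 0.50 | fraction of region | other-hit relevance filter |
| `related_min_identity`, `related_min_coverage`, `related_min_hits`, `related_median_identity` | 50, 0.70, 10, 75 | %, fraction, count, % | relatedness |
| `expansion_cap` | 10000 | paths | expansion guard |

Every coverage above is measured on the subject (reference protein) or
model side. The rules are phrased as "the alignment covers … of *that
protein* / *the HMM*", which names the subject side explicitly; the
query side is still stored on every hit because the region filter and
split logic need it. Whether the HMM rule's 75 % other-hit coverage is
subject- or query-side is not stated anywhere we could find; we use
subject-side for consistency with every other coverage in the engine.

`region_filter` exists as a switch so the fusion tests can demonstrate
*why* the region rule matters: with it off, at least one half of every
planted fusion loses its 10-bit margin to the other half's hit.

## Numerical and convention choices

**Percent identity** is identities over aligned columns (gap columns
count against), the common tabular-output convention. For global
comparisons (markers, fixture verification, clustering) identity is
computed after trimming terminal-gap columns and coverage is the trimmed
span over the longer sequence — so a fragment aligned end-to-end inside
a longer protein is penalised in coverage, not identity.

**The built-in aligner** is Smith–Waterman / Needleman–Wunsch through
`Biostrings::pairwiseAlignment` with BLOSUM62 and affine gaps 11/1 — the
de facto standard. Bit scores use a Karlin–Altschul-style conversion
with the standard gapped BLOSUM62 parameters (λ = 0.267, K = 0.041) and
E = m·n·2^−bits per pair. The calibration is deliberately not
load-bearing: every decision in the engine rests on identity, coverage
and bit-score *margins*, and the E-value only needs to separate genuine
local alignments from noise. A BLAST+ adapter satisfies the same
contract and the suite checks both backends agree (hit presence and
identity within 3 points) on a 50-pair panel spanning 15–100 % realized
identity. Profile search is delegated to HMMER; reimplementing its
internals is explicitly out of scope, and trusted-cutoff filtering plus
deterministic ordering are applied on top of its domain table.

**Tie-breaking and determinism.** Hits order by query, descending bits,
subject id; candidates by tier, bits, protein id; cluster
representatives are the lexicographically smallest id (the reference
procedure picks arbitrarily; tests need a fixed choice). Repeated runs
with the same inputs and configuration are byte-identical, which the
suite asserts at file level.

**Degenerate inputs.** An empty proteome is analyzable: every step is
low, every pathway reports all gaps. Empty query sets passed directly to
the search contract are an error, as are regions outside protein bounds,
profiles without trusted cutoffs, and expansion past the cap. Matchers
that select nothing are warnings, not errors — a database may simply
lack members for a step.

**Open readings resolved here.** A step may appear twice in one
expanded path and is scored identically at each occurrence. Term
matchers apply to both the characterized and curated-only pools, with
provenance recorded. For requirement checking, subpathways are inlined;
a "subpathway's tier" never exists as its own object.

## What the synthetic fixtures emulate — and what they do not

`build_universe()` generates the complete input surface: reference
FASTA/TSV, pathway definition files, proteomes, marker FASTAs, marker
HMMs (built with `hmmbuild` from mutated families, timestamps pinned)
and a known-gap catalog — along with the answer key those directives
imply under the documented rules. Orthologs are planted by
substitution-only mutation to a target global identity (realized within
±3 points, verified by the aligner itself); substitution-only keeps
coverage at ~100 % so identity and coverage vary independently.
Background and reference sequences are i.i.d. uniform over the 20 amino
acids.

The defaults are the study conditions: `example_fixture_spec()` builds
three pathways (12 steps, including a 2-alternative subpathway and a
two-variant route), five genomes (complete; gapped with a cataloged
known gap; fused; split plus decoy; diverged and unrelated), twelve
markers of length 180, reference proteins of length 240, ortholog
identities of 0.80 (high), 0.55 (decoy-demoted), 0.35 (medium), and
marker identities 1.0 / 0.9 / 0.85 / 0.8 / 0.6 against the catalog
reference. Identity targets deliberately avoid the 30 % and 40 %
decision boundaries, where the expected tier would be ambiguous within
the mutation tolerance.

What passing these tests shows: the engine implements the documented
rules exactly, end to end, including fusion rescue, split joining,
decoy demotion, route selection and known-gap transfer. What it does
not show: behavior on real proteomes. Real sequences have biased
composition, indels, domain shuffling, paralog families and annotation
noise; the fixtures have none of these (no indels beyond the
fusion/split constructs, no realistic evolution). The thresholds
themselves encode field experience with real data, but their empirical
adequacy is inherited from that experience, not re-demonstrated here.

## Problem sizes used by the checks

The suite runs at toy scale chosen to exercise every code path while
keeping a full run in minutes on one CPU: an exhaustive ~16,000-case
classification grid against a table-driven oracle; 1,000 random rule
graphs against brute-force best-path search; 20 fusion universes (with
the region filter toggled to demonstrate the rescue); split universes
across breakpoints 0.3–0.7 plus adversarial rejections of each join
condition; ten five-genome universes reproduced against their answer
keys including known-gap flags; the six relatedness threshold cases
(markers of length 300 so targets like 74 % and 76 % are realized
exactly); and byte-level determinism of all outputs. The acceptance
script reruns the same machinery at slightly smaller counts and reports
the resulting rates.

## Known limitations

Beyond the fixture realism caveats above: no three-way split detection;
no auxotrophy prediction (by design); the built-in aligner is quadratic
per pair and meant for reference databases of hundreds, not hundreds of
thousands, of sequences — plug in the BLAST backend for larger runs; the
E-value calibration is approximate; and requirement semantics cover
presence/absence of single steps, not arbitrary logical combinations.
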