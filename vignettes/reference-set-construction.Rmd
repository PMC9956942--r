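---
title: "Constructing KO-grouped reference gene sets: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing KO-grouped reference gene sets: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(koextractr)
```

## The procedure

`koextractr` turns per-genome KEGG Orthology annotation output into a
non-redundant, species-tagged reference gene set, in four stages.

**1. Hit selection.** KofamKOALA-style detail output lists, per gene, the
assigned KO, the KO's adaptive score threshold, the bit score, the E-value
and a definition; assignments whose score clears the threshold carry a
leading `*`. Two filters apply, independently togglable and both on by
default: keep only asterisk-marked rows, and keep only rows with E-value
at most 1e-5. The E-value ceiling matters even for marked rows because
adaptive thresholds are not defined for every KO (the detail format prints
`-` there, which this package reads as *absent*, never as zero — a zero
threshold would silently mark everything reliable). Merging across a
result directory is deterministic: files in lexicographic order, rows in
file order, each row tagged with a genome label obtained by stripping one
trailing extension from the file name (never splitting on internal dots,
which would mangle assembly accession versions like `GCF_000011585.1`).

**2. Extraction.** Sequences are located by identifier, scoped to the
genome the hit came from — a gene id is never resolved against another
genome's file, because RefSeq protein accessions can recur across
assemblies of related strains. Protein records are keyed by the first
whitespace token of the header; CDS records (`*_cds_from_genomic.fna`
dialect) are keyed primarily by their `[protein_id=...]` header attribute,
which is the link NCBI maintains between a CDS and its protein product,
with the raw record id as fallback. Every key is also registered with its
trailing `.N` version stripped, so an annotator's `WP_1` still finds the
release's `WP_1.1`; an exact-version key always beats the stripped
fallback, and a stripped key that would be ambiguous within a genome is
disabled rather than guessed. Extracted copies get their header rewritten
to `{gene_id} {original description} [KO:Kxxxxx] [Organism strain]` —
grep-able, FASTA-legal, stable field order — and are grouped by KO, then
genome. Hits that resolve nowhere go to a miss list with a warning;
extraction is resumable, not brittle.

**3. Length filtering and de-redundancy.** Public assemblies contain
partial genes, so the grouped set is filtered against a family reference
length: keep length ≥ `ceil(min_fraction × reference_length)`. The default
`min_fraction = 0.75` is chosen so the canonical case is unambiguous — a
~400 aa fragment of the ~806 aa CODH/ACS subunit alpha falls far below the
605 aa cutoff while moderately trimmed termini survive. The remaining set
is collapsed at 100% identity. "100%" has two defensible readings, and
both are implemented: `exact` (the default) clusters only byte-identical
residue strings, which is the conservative choice when downstream counts
of "non-redundant genes" matter; `containment` emulates the greedy
length-sorted behaviour of classical clustering tools, absorbing a
sequence into the first longer representative that contains it as an
exact substring. Representative choice is deterministic in both modes:
longest sequence, ties broken by lexicographically smallest id. Both modes
are idempotent and are tested against an O(n²) all-pairs oracle.

**4. Assessment.** Two metrics close the loop. *Recall* compares the
extraction manifest with an expected manifest on (genome, KO, gene)
triples; extracted triples not in the expected set are reported separately
and never inflate recall. The *false-negative rate* takes a tabular
best-hit file (query, subject, percent identity, subject gene name): per
query only the maximum-identity hit counts (ties broken by presence of an
informative name, then subject id), and the query is a true positive at
threshold *t* iff that hit exists, has identity ≥ *t*, and its gene name
is informative. "Uninformative" is a configurable case-insensitive lexicon
— empty, `hypothetical protein`, `uncharacterized…`, `unknown…`,
`predicted protein`, `DUF…` — because annotation pipelines express "no
idea" in several dialects; a `require_name` regex switches to the strict
reading in which only the correct gene symbol counts. Rates are reported
as integer percentages rounded half-up, the convention under which 19, 43
and 44 misses out of 54 queries give 35%, 80% and 81%. With best-hit
semantics the rate is non-decreasing in the threshold, and the test suite
asserts this as a property.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `max_evalue` | 1e-5 | — | standard alignment default; guards KOs without adaptive thresholds |
| `significant_only` | `TRUE` | — | asterisk rows are the annotator's own reliable set |
| `min_fraction` | 0.75 | fraction of reference length | separates ~400 aa partials from an ~806 aa reference unambiguously |
| `mode` (dedup) | `"exact"` | — | conservative reading of 100%-identity clustering |
| `denominator` (identity) | `"alignment"` | — | 100% then implies byte-identity |
| `thresholds` (FN table) | 40–100 by 10 | % identity | the conventional benchmark ladder |

`percent_identity()` uses a global alignment with match = 1, mismatch = 0
and linear gap penalty −1 (via `Biostrings::pairwiseAlignment`). This is a
deliberate, documented desk-scale stand-in that makes the assessment stage
self-contained; it is not a reimplementation of a heuristic search engine,
and no claim of speed parity is made.

## The synthetic generator: what it does and does not emulate

`generate()` produces, under one seed, a byte-deterministic batch of
genomes: per genome a protein FASTA and a CDS FASTA whose records are
linked by `[protein_id=...]` tokens, a detail result file with an
asterisk-marked row per generated gene plus one sub-threshold decoy row
(non-asterisk, E-value 1e-3 — removed by either default filter), an
NCBI-style assembly summary with the organism in column 8 and the strain
in column 9, and an expected manifest of every (genome, KO, gene) triple.
Defaults mirror the 20-genome, two-KO (K00192/K00195), one-gene-per-KO
benchmark layout; protein lengths are uniform in 300–850 aa, a band that
brackets realistic CODH/ACS subunit lengths including the 806 aa subunit
alpha. The `dropout` parameter withholds a seeded sample of annotation
rows — the genes stay in the genomes and in the expected manifest — which
is how annotators of different sensitivity are emulated: withholding 0, 3,
1 and 6 of 40 rows yields extracted counts of 40, 37, 39 and 34 and
recalls of 1, 0.925, 0.975 and 0.85.

Back-translation uses one fixed codon per amino acid plus a `TAA` stop
(consistent under the bacterial/archaeal code, table 11); residues are
uniform over the 20-letter alphabet. The generator therefore exercises
identifier plumbing, not biology: no codon bias, no homology between
genomes, no HMM score distributions, no mis-annotation noise. Passing
tests consequently demonstrate that the bookkeeping — selection,
genome-scoped matching, species joining, grouping, counting — is exact;
they do not demonstrate annotator accuracy on real genomes, which depends
on the upstream HMM search this package deliberately consumes rather than
runs.

## Numerical and degenerate-input choices

* FN percentages round half-up (`floor(x + 0.5)`), not banker's rounding.
* Length cutoff uses `ceiling`, so the boundary sequence (exactly at
  `min_fraction × reference`) is kept.
* Empty FASTA sequences and duplicate ids are warnings with all records
  kept; a hit set in which *nothing* resolves is a warning plus an empty
  result, while an empty *input* hit set is an error — the former is a
  plausible data state, the latter a caller bug.
* An ambiguous assembly summary (two rows matching one genome) is an
  error rather than an arbitrary pick.
* Re-running `write_tree()` into a populated directory refuses without
  `force`, so batch jobs cannot silently interleave two runs.
* Test and acceptance problem sizes (≤ 20 genomes, ≤ 3 KOs, ≤ 200
  sequences for the clustering oracle) were chosen as the smallest sizes
  at which every code path and the published benchmark arithmetic are
  exercised.

## Known limitations

Coordinate-based extraction from genomic FASTA, GFF/GenBank input, and
on-the-fly CDS↔protein translation are out of scope: extraction works
from annotation-derived sequence files only. The containment dedup is
O(n²·L) and intended for reference-set scale (thousands of sequences),
not metagenome scale. `percent_identity()` scores with a single fixed
scheme; substitution-matrix scoring is not exposed.
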