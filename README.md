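# koextractr

Build species-annotated ortholog reference gene sets from KEGG Orthology
(KO) annotation output.

HMM-based KO annotators such as KofamScan/KofamKOALA assign K numbers
(`K` + five digits) to the proteins of a genome and mark assignments that
exceed the KO-specific adaptive score threshold with an asterisk `*`.
Building a curated reference database for a pathway — for example the
archaeal Wood–Ljungdahl (reductive acetyl-CoA) pathway, whose CODH/ACS
subunit genes span KOs K00192–K00198, K14138 and K15023 — then requires a
chain of plumbing that is easy to get subtly wrong at scale: select the
asterisk-marked hits below an E-value ceiling across hundreds of result
files, pull the matching protein and CDS sequences out of the per-genome
FASTA files, tag each sequence with the organism and strain from the NCBI
assembly summary, group everything by KO, drop partial sequences, collapse
the set at 100% identity, and finally measure how good the resulting
database is. `koextractr` implements that chain as a tested R library with
a command-line front end, for microbial genomics practitioners who have
annotation output in hand and want a reproducible reference set out.

## What it computes

* **Selection** — a hit is retained when it is asterisk-marked (score ≥
  the KO's adaptive threshold) *and* its E-value ≤ 1e-5; both filters can
  be relaxed independently.
* **Extraction** — genome-scoped identifier matching: protein records by
  the first header token, CDS records by their `[protein_id=...]` header
  attribute, with version-stripped fallback (`WP_1.1` ↔ `WP_1`). Output
  headers gain `[KO:Kxxxxx] [Organism strain]` clauses.
* **Length filter** — keep sequences with length ≥
  `ceil(min_fraction × reference_length)`; e.g. with the ~806 aa CODH/ACS
  subunit alpha (K00192) reference and the default fraction 0.75, a ~400 aa
  partial is dropped (cutoff 605 aa).
* **De-redundancy at 100%** — `exact` mode clusters byte-identical
  sequences; `containment` mode greedily absorbs exact substrings into the
  longest representative (the CD-HIT-like reading of `-c 1`).
* **Assessment** — per query the best hit (max identity) is a true
  positive at threshold *t* iff identity ≥ *t* and the subject gene name is
  informative (not "hypothetical protein" etc.); the false-negative rate is
  `round(100 · FN / n)` per threshold. Recall of an extraction run is the
  fraction of expected (genome, KO, gene) triples recovered.

A seeded generator (`fixture_spec()` / `generate()`) produces coherent
synthetic genome sets — paired `.faa`/`.fna` files linked by protein ids,
annotation result files, assembly summaries, and an expected manifest — so
the entire pipeline runs and is tested without any download.

## Worked example

```r
library(koextractr)

paths <- generate(fixture_spec(n_genomes = 20, kos = c("K00192", "K00195"),
                               dropout = 0, seed = 7), "demo_fixture")
hits  <- merge_result_files(paths$results)       # asterisk + 1e-5 filters
index <- build_index(paths$genomes, "protein")
res   <- extract(hits, index, read_assembly_dir(paths$species))
print(res)
#> <extraction_result> 40 sequence(s) in 2 KO group(s), 0 miss(es)
#>   K00192: 20 sequence(s) across 20 genome(s)
#>   K00195: 20 sequence(s) across 20 genome(s)
recall(paths$expected, res)$recall
#> [1] 1
write_tree(res, "demo_out")                      # demo_out/K00192/<genome>.faa, manifest.tsv
```

40 sequences are recovered — every one of the 20 genomes contributes one
gene per KO — and recall against the generator's expected manifest is 1.
Withholding 3 of the 40 annotation rows (`dropout = 3/40`) drops the count
to 37 and recall to 0.925, mirroring what a less sensitive annotator
produces.

The same steps from a shell:

```sh
inst/exec/koextract simulate --genomes 20 --kos K00192,K00195 --seed 7 --out demo_fixture
inst/exec/koextract extract -i demo_fixture/genomes -f demo_fixture/results \
    -s demo_fixture/species -o demo_out
```

Subcommands: `merge`, `extract`, `stats`, `filter`, `dedup`, `assess`,
`recall`, `simulate` (see `--help`). Exit codes: 0 success, 1 usage error,
2 data error.

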