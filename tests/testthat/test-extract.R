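local_fixture <- function(n_genomes = 5L, kos = c("K00192", "K00195"),
                          dropout = 0, seed = 11L, env = parent.frame()) {
  out <- withr::local_tempdir(.local_envir = env)
  generate(fixture_spec(n_genomes = n_genomes, kos = kos,
                        dropout = dropout, seed = seed), out)
}

test_that("index keys cover exact and version-stripped ids, and CDS protein_id", {
  paths <- local_fixture(n_genomes = 2L)
  idx <- build_index(paths$genomes, "protein")
  g <- names(idx$genomes)[[1]]
  pid <- idx$genomes[[g]]$records$seq_id[[1]]
  expect_match(pid, "^WP_\\d+\\.1$")
  expect_equal(koextractr:::index_lookup(idx, g, pid)$seq_id, pid)
  stripped <- sub("\\.\\d+$", "", pid)
  expect_equal(koextractr:::index_lookup(idx, g, stripped)$seq_id, pid)
  # nucleotide records resolve by their [protein_id=...] token
  nidx <- build_index(paths$genomes, "nucleotide")
  rec <- koextractr:::index_lookup(nidx, g, pid)
  expect_false(is.null(rec))
  expect_match(rec$seq_id, "^lcl\\|")
  expect_equal(rec$attributes[[1]][["protein_id"]], pid)
  # a foreign genome never resolves the same id
  other <- names(idx$genomes)[[2]]
  expect_null(koextractr:::index_lookup(idx, other, pid))
})

test_that("colliding keys within a genome and empty directories are errors", {
  dir <- withr::local_tempdir()
  writeLines(c(">WP_1.1 a", "MK", ">WP_1.1 b", "MV"), file.path(dir, "g.faa"))
  expect_warning(expect_error(build_index(dir, "protein"), "colliding"),
                 "duplicate")
  expect_error(build_index(withr::local_tempdir(), "protein"), "no protein FASTA")
})

test_that("species matching is accession-prefix based with an exact-stem fallback", {
  asm <- tibble::tibble(
    accession = c("GCF_000011585.1", "GCF_000011586.1", "plainstem"),
    organism_name = c("Methanococcus maripaludis", "Archaeoglobus fulgidus", "X y"),
    infraspecific_name = c("strain=S2", "", ""))
  hit <- match_species("GCF_000011585.1_ASM1158v1_protein", asm)
  expect_equal(hit$organism_name, "Methanococcus maripaludis")
  expect_equal(match_species("plainstem", asm)$organism_name, "X y")
  expect_null(match_species("GCF_999999999.9_nothing", asm))
  dup <- dplyr::bind_rows(asm, asm[1, ])
  dup$infraspecific_name[[4]] <- "strain=other"
  expect_error(match_species("GCF_000011585.1_x", dup), "ambiguous")
})

test_that("a full 20-genome two-KO run extracts 40 genes in 2 groups of 20", {
  paths <- local_fixture(n_genomes = 20L, seed = 7L)
  hits <- merge_result_files(paths$results)
  idx <- build_index(paths$genomes, "protein")
  asm <- read_assembly_dir(paths$species)
  res <- extract(hits, idx, asm)
  expect_equal(res$stats$n_extracted, 40L)
  expect_equal(sort(names(res$groups)), c("K00192", "K00195"))
  expect_equal(length(res$groups$K00192), 20L)
  expect_equal(length(res$groups$K00195), 20L)
  expect_equal(nrow(res$misses), 0L)
  # species tag and KO tag land in the rewritten headers
  first <- res$groups$K00192[[1]]
  expect_match(first$description[[1]], "\\[KO:K00192\\]")
  expect_match(first$description[[1]], "\\[Methano|\\[Archaeo")
})

test_that("hits spanning seven KOs produce seven KO groups", {
  kos <- c("K00192", "K00193", "K00194", "K00195", "K00197", "K00198", "K14138")
  paths <- local_fixture(n_genomes = 3L, kos = kos)
  res <- extract(merge_result_files(paths$results),
                 build_index(paths$genomes, "protein"), NULL)
  expect_equal(length(res$groups), 7L)
  expect_setequal(names(res$groups), kos)
})

test_that("unresolvable hits go to the miss list and conservation holds", {
  paths <- local_fixture(n_genomes = 3L)
  hits <- merge_result_files(paths$results)
  ghost <- hits[1, ]
  ghost$gene_id <- "WP_000000000.1"
  hits2 <- dplyr::bind_rows(hits, ghost, hits[2, ])  # one miss + one exact duplicate
  idx <- build_index(paths$genomes, "protein")
  expect_warning(res <- extract(hits2, idx, NULL), "could not be matched")
  dedup_hits <- dplyr::distinct(hits2, genome_id, gene_id, ko_id)
  expect_equal(res$stats$n_extracted + res$stats$n_missed, nrow(dedup_hits))
  expect_equal(res$misses$gene_id, "WP_000000000.1")
  # organism falls back to NA without a summary
  expect_true(all(res$manifest$organism_name == "NA"))
})

test_that("all-missing hits yield empty groups with a warning, zero hits an error", {
  paths <- local_fixture(n_genomes = 2L)
  idx <- build_index(paths$genomes, "protein")
  hits <- merge_result_files(paths$results)
  hits$gene_id <- paste0("nope_", seq_len(nrow(hits)))
  expect_warning(res <- extract(hits, idx, NULL), "could not be matched")
  expect_equal(length(res$groups), 0L)
  expect_equal(res$stats$n_extracted, 0L)
  expect_error(extract(hits[0, ], idx, NULL), "no annotation hits")
})

test_that("extraction equals a naive linear-scan oracle on a multi-genome fixture", {
  for (seed in c(3L, 19L)) {
    paths <- local_fixture(n_genomes = 12L, kos = c("K00192", "K00195", "K00198"),
                           seed = seed)
    hits <- merge_result_files(paths$results)
    res <- extract(hits, build_index(paths$genomes, "protein"), NULL)
    oracle <- naive_scan_oracle(hits, paths$genomes, "protein")
    got <- res$manifest[, c("ko_id", "genome_id", "gene_id")]
    got$residues <- unlist(lapply(seq_len(nrow(got)), function(i) {
      res$groups[[got$ko_id[[i]]]][[got$genome_id[[i]]]] |>
        (\(df) df$residues[df$seq_id == got$gene_id[[i]]])()
    }))
    key <- function(d) paste(d$ko_id, d$genome_id, d$gene_id, d$residues)
    expect_setequal(key(got), key(oracle))
  }
})

test_that("extracted residues are byte-identical to the source FASTA", {
  paths <- local_fixture(n_genomes = 4L)
  res <- extract(merge_result_files(paths$results),
                 build_index(paths$genomes, "protein"), NULL)
  for (ko in names(res$groups)) {
    for (g in names(res$groups[[ko]])) {
      src <- read_fasta(file.path(paths$genomes, paste0(g, ".faa")), "protein")
      for (i in seq_len(nrow(res$groups[[ko]][[g]]))) {
        rec <- res$groups[[ko]][[g]][i, ]
        expect_identical(rec$residues, src$residues[src$seq_id == rec$seq_id])
      }
    }
  }
})

test_that("a decoy record in a different genome never changes the output", {
  paths <- local_fixture(n_genomes = 3L, seed = 23L)
  hits <- merge_result_files(paths$results)
  res1 <- extract(hits, build_index(paths$genomes, "protein"), NULL)
  # plant a decoy with genome 1's first gene id inside a brand-new genome
  target <- hits$gene_id[[1]]
  writeLines(c(sprintf(">%s decoy copy", target), "MKVDECOY"),
             file.path(paths$genomes, "GCF_999999999.1_decoy.faa"))
  res2 <- extract(hits, build_index(paths$genomes, "protein"), NULL)
  expect_equal(res1$manifest, res2$manifest)
  expect_equal(res1$groups, res2$groups)
})

test_that("write_tree lays out per-KO directories and refuses to clobber", {
  paths <- local_fixture(n_genomes = 20L, seed = 7L)
  res <- extract(merge_result_files(paths$results),
                 build_index(paths$genomes, "protein"),
                 read_assembly_dir(paths$species))
  out <- file.path(withr::local_tempdir(), "tree")
  manifest_path <- write_tree(res, out)
  kos <- list.dirs(out, recursive = FALSE)
  expect_setequal(basename(kos), c("K00192", "K00195"))
  expect_equal(length(list.files(kos[[1]], pattern = "\\.faa$")), 20L)
  expect_equal(length(list.files(kos[[2]], pattern = "\\.faa$")), 20L)
  manifest <- utils::read.table(manifest_path, sep = "\t", header = TRUE)
  expect_equal(nrow(manifest), 40L)
  expect_error(write_tree(res, out), "not empty")
  expect_silent(write_tree(res, out, force = TRUE))
})
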