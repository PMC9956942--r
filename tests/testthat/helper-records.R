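# Shared builders for in-code fixtures.

make_records <- function(ids, residues, descriptions = rep("", length(ids)),
                         moltype = "protein") {
  tibble::tibble(
    seq_id = ids,
    description = descriptions,
    residues = residues,
    moltype = moltype,
    attributes = lapply(descriptions, koextractr:::parse_header_attributes),
    source_file = "in-memory"
  )
}

random_records <- function(n, min_len = 5L, max_len = 60L, prefix = "seq") {
  residues <- vapply(seq_len(n), function(i) {
    len <- sample(min_len:max_len, 1L)
    paste(sample(c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                   "R","S","T","V","W","Y"), len, replace = TRUE),
          collapse = "")
  }, character(1))
  descriptions <- ifelse(seq_len(n) %% 2L == 0L,
                         sprintf("synthetic record %d [protein_id=%s_%d.1]", seq_len(n), prefix, seq_len(n)),
                         "")
  make_records(sprintf("%s_%d.1", prefix, seq_len(n)), residues, descriptions)
}

# A tiny three-file result directory: per file, 2 significant + 1
# non-significant row.
write_result_dir <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in 1:3) {
    lines <- c(
      "# gene name\tKO\tthrshld\tscore(full)\tE-value\t\"KO definition\"",
      sprintf("* gene%d_1\tK00192\t650.3\t702.1\t1.2e-210\t\"CODH/ACS subunit alpha\"", g),
      sprintf("* gene%d_2\tK00195\t-\t500.0\t3.1e-150\t\"CODH/ACS subunit beta\"", g),
      sprintf("  gene%d_3\tK03520\t450.0\t30.2\t1.0e-03\t\"CO dehydrogenase large subunit\"", g)
    )
    writeLines(lines, file.path(dir, sprintf("genome%d.out", g)))
  }
  dir
}

# Independent naive extraction oracle: for every hit, linearly scan each
# record of the named genome's FASTA file (no index, no package reader)
# and return (ko, genome, gene, residues) rows.
naive_scan_oracle <- function(hits, genome_dir, moltype = "protein") {
  ext <- if (moltype == "protein") "\\.faa$" else "\\.fna$"
  files <- list.files(genome_dir, pattern = ext, full.names = TRUE)
  stems <- vapply(files, function(f) sub("\\.(faa|fna)$", "", basename(f)), character(1))
  out <- list()
  hits <- unique(hits[, c("genome_id", "gene_id", "ko_id")])
  for (i in seq_len(nrow(hits))) {
    f <- files[stems == hits$genome_id[[i]]]
    if (length(f) != 1L) next
    set <- Biostrings::readBStringSet(f)
    for (j in seq_along(set)) {
      header <- names(set)[[j]]
      first_tok <- sub("\\s.*$", "", header)
      pid <- regmatches(header, regexpr("\\[protein_id=[^]]*\\]", header))
      pid <- if (length(pid)) sub("^\\[protein_id=([^]]*)\\]$", "\\1", pid) else ""
      target <- hits$gene_id[[i]]
      if (first_tok == target || pid == target ||
          sub("\\.\\d+$", "", first_tok) == sub("\\.\\d+$", "", target) ||
          (nzchar(pid) && sub("\\.\\d+$", "", pid) == sub("\\.\\d+$", "", target))) {
        out[[length(out) + 1L]] <- data.frame(
          ko_id = hits$ko_id[[i]], genome_id = hits$genome_id[[i]],
          gene_id = target, residues = toupper(as.character(set[[j]])),
          stringsAsFactors = FALSE)
        break
      }
    }
  }
  do.call(rbind, c(out, list(data.frame(ko_id = character(), genome_id = character(),
                                        gene_id = character(), residues = character(),
                                        stringsAsFactors = FALSE))))
}
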