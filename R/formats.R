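#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr bind_rows arrange group_by summarise ungroup n distinct
#' @importFrom stats median setNames
#' @importFrom utils head tail
NULL

KO_PATTERN <- "^K\\d{5}$"
ACCESSION_PATTERN <- "GC[AF]_\\d+\\.\\d+"

empty_hits <- function() {
  tibble::tibble(
    genome_id = character(), gene_id = character(), ko_id = character(),
    threshold = numeric(), score = numeric(), evalue = numeric(),
    definition = character(), significant = logical()
  )
}

num_or_na <- function(x) {
  ifelse(x == "-" | x == "", NA_real_, suppressWarnings(as.numeric(x)))
}

#' Parse a KofamKOALA-style detail result
#'
#' Reads the per-gene detail output of an HMM-based KO annotator. Each data
#' row carries a leading significance marker (`*` when the bit score exceeds
#' the KO-specific adaptive threshold), the gene identifier, the KO
#' identifier (`K` + five digits), the adaptive threshold, the bit score,
#' the E-value and a free-text KO definition. Lines beginning with `#` are
#' headers and are skipped. Threshold and score values of `-` (emitted for
#' KOs without an adaptive threshold) become `NA`, never zero.
#'
#' @param lines Character vector of raw result lines (or a single file path;
#'   see [merge_result_files()] for directory-level reading).
#' @param genome_id Label of the source genome attached to every hit.
#' @return A tibble with one row per annotation hit and columns
#'   `genome_id`, `gene_id`, `ko_id`, `threshold`, `score`, `evalue`,
#'   `definition`, `significant`. Lines that cannot be parsed are collected
#'   into the `parse_errors` attribute (a character vector) and reported
#'   with a single warning; they are never silently dropped.
#' @export
parse_kofam_detail <- function(lines, genome_id) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L, nzchar(genome_id))
  if (length(lines) == 1L && !grepl("[\t\n]", lines) && file.exists(lines)) {
    lines <- readLines(lines, warn = FALSE)
  }
  lines <- lines[nzchar(trimws(lines))]
  is_header <- grepl("^#", lines)
  data <- lines[!is_header]
  errors <- character()
  rows <- vector("list", length(data))
  for (i in seq_along(data)) {
    ln <- data[[i]]
    significant <- startsWith(ln, "*")
    body <- sub("^[* ]\\s*", "", ln)
    if (grepl("\t", body)) {
      fields <- trimws(strsplit(body, "\t")[[1]])
    } else {
      fields <- strsplit(body, "\\s+")[[1]]
    }
    if (length(fields) < 6L) {
      errors <- c(errors, sprintf("line %d: expected >= 6 fields after marker, got %d: %s",
                                  i, length(fields), ln))
      next
    }
    definition <- paste(fields[6:length(fields)], collapse = " ")
    rows[[i]] <- tibble::tibble(
      genome_id = genome_id,
      gene_id = fields[[1]],
      ko_id = fields[[2]],
      threshold = num_or_na(fields[[3]]),
      score = num_or_na(fields[[4]]),
      evalue = suppressWarnings(as.numeric(fields[[5]])),
      definition = definition,
      significant = significant
    )
  }
  hits <- dplyr::bind_rows(c(list(empty_hits()), rows))
  bad_ko <- !grepl(KO_PATTERN, hits$ko_id)
  if (any(bad_ko)) {
    errors <- c(errors, sprintf("malformed KO identifier '%s' (gene %s)",
                                hits$ko_id[bad_ko], hits$gene_id[bad_ko]))
    hits <- hits[!bad_ko, ]
  }
  if (length(errors) > 0L) {
    warning(sprintf("parse_kofam_detail: %d unparseable line(s) in '%s': %s",
                    length(errors), genome_id,
                    paste(utils::head(errors, 5L), collapse = "; ")),
            call. = FALSE)
  }
  attr(hits, "parse_errors") <- errors
  hits
}

#' Strip a single trailing file extension to obtain a genome label
#'
#' Only one trailing extension from `suffixes` is removed; internal dots
#' (assembly accession versions such as `GCF_000011585.1`) are preserved.
#'
#' @param filename File name (base name is taken).
#' @param suffixes Candidate extensions, tried in order.
#' @return The stripped stem.
#' @export
strip_genome_suffix <- function(filename,
                                suffixes = c(".out", ".faa", ".fna", ".txt", ".tsv", ".fasta")) {
  stem <- basename(filename)
  for (s in suffixes) {
    if (endsWith(stem, s)) {
      return(substr(stem, 1L, nchar(stem) - nchar(s)))
    }
  }
  stem
}

#' Merge per-genome KO annotation result files
#'
#' Reimplements the merge loop over batch annotation results: every result
#' file in `result_dir` is parsed, each hit is tagged with a genome label
#' derived from its file name, and the hits are concatenated in
#' lexicographic file order. Asterisk-marked (significant) selection and the
#' E-value ceiling are independent, composable filters; the defaults keep
#' only significant hits with E-value at most 1e-5.
#'
#' @param result_dir Directory of result files.
#' @param significant_only Keep only asterisk-marked rows (default `TRUE`).
#' @param max_evalue Drop rows with E-value above this ceiling; `NULL`
#'   disables the filter. Default `1e-5`.
#' @param suffixes Extensions stripped from file names to form `genome_id`.
#' @param pattern Regular expression selecting result files (default: all
#'   regular files).
#' @return A tibble of annotation hits (see [parse_kofam_detail()]).
#' @export
merge_result_files <- function(result_dir, significant_only = TRUE,
                               max_evalue = 1e-5,
                               suffixes = c(".out", ".txt", ".tsv"),
                               pattern = NULL) {
  if (!dir.exists(result_dir)) {
    stop(sprintf("result directory does not exist: %s", result_dir), call. = FALSE)
  }
  files <- list.files(result_dir, pattern = pattern, full.names = TRUE)
  files <- files[file.exists(files) & !dir.exists(files)]
  files <- files[order(basename(files), method = "radix")]
  if (length(files) == 0L) {
    stop(sprintf("no result files found in %s", result_dir), call. = FALSE)
  }
  parts <- lapply(files, function(f) {
    lines <- tryCatch(readLines(f, warn = FALSE),
                      error = function(e) stop(sprintf("cannot read result file %s: %s",
                                                       f, conditionMessage(e)), call. = FALSE))
    parse_kofam_detail(lines, genome_id = strip_genome_suffix(f, suffixes))
  })
  hits <- dplyr::bind_rows(c(list(empty_hits()), parts))
  if (isTRUE(significant_only)) hits <- hits[hits$significant, ]
  if (!is.null(max_evalue)) hits <- hits[!is.na(hits$evalue) & hits$evalue <= max_evalue, ]
  hits
}

#' Read a merged annotation table
#'
#' Two dialects are accepted. `canonical` is the eight-column table this
#' package writes (`genome_id`, `gene_id`, `ko_id`, `threshold`, `score`,
#' `evalue`, `definition`, `significant`, with a header line). `raw` is a
#' filename-prefixed concatenation of detail rows in which each line starts
#' with the genome label followed by the original detail row, marker column
#' included — the shape produced by prepending the file name during a shell
#' merge.
#'
#' @param path Path to the merged table.
#' @param dialect `"canonical"` or `"raw"`.
#' @return A tibble of annotation hits.
#' @export
read_merged_annotations <- function(path, dialect = c("canonical", "raw")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  if (dialect == "canonical") {
    df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                            comment.char = "", stringsAsFactors = FALSE)
    need <- c("genome_id", "gene_id", "ko_id", "threshold", "score",
              "evalue", "definition", "significant")
    missing <- setdiff(need, names(df))
    if (length(missing) > 0L) {
      stop(sprintf("merged table %s lacks column(s): %s", path,
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    out <- tibble::as_tibble(df[need])
    out$significant <- as.logical(out$significant)
    return(out)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  rows <- lapply(lines, function(ln) {
    fields <- if (grepl("\t", ln)) trimws(strsplit(ln, "\t")[[1]]) else strsplit(ln, "\\s+")[[1]]
    # genome label, then the original detail row whose first field may be '*'
    genome <- fields[[1]]
    rest <- fields[-1]
    significant <- length(rest) > 0L && rest[[1]] == "*"
    if (significant) rest <- rest[-1]
    if (length(rest) < 6L) {
      stop(sprintf("raw merged line with too few fields: %s", ln), call. = FALSE)
    }
    tibble::tibble(
      genome_id = strip_genome_suffix(genome),
      gene_id = rest[[1]], ko_id = rest[[2]],
      threshold = num_or_na(rest[[3]]), score = num_or_na(rest[[4]]),
      evalue = suppressWarnings(as.numeric(rest[[5]])),
      definition = paste(rest[6:length(rest)], collapse = " "),
      significant = significant
    )
  })
  dplyr::bind_rows(c(list(empty_hits()), rows))
}

#' Write a merged annotation table (canonical eight-column dialect)
#'
#' @param hits Tibble of annotation hits.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_merged_annotations <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# ---- FASTA -----------------------------------------------------------------

parse_header_attributes <- function(description) {
  m <- gregexpr("\\[([^\\]=\\s]+)=([^\\]]*)\\]", description, perl = TRUE)
  toks <- regmatches(description, m)[[1]]
  if (length(toks) == 0L) return(stats::setNames(character(), character()))
  keys <- sub("^\\[([^=]+)=.*$", "\\1", toks)
  vals <- sub("^\\[[^=]+=([^\\]]*)\\]$", "\\1", toks, perl = TRUE)
  stats::setNames(vals, keys)
}

#' Read a FASTA file into a sequence-record tibble
#'
#' Headers are split into `seq_id` (first whitespace-delimited token) and
#' `description` (the remainder); bracketed `[key=value]` tokens in the
#' description — the NCBI `cds_from_genomic` dialect, e.g. `[protein_id=...]`
#' — are parsed into the `attributes` list-column. Residues are normalized
#' to upper case. Empty sequences and duplicated `seq_id`s are warnings,
#' not errors: real RefSeq files contain such oddities and the pipeline
#' must be able to continue past them.
#'
#' @param path FASTA file path.
#' @param moltype `"protein"` or `"nucleotide"`; recorded on every row and
#'   used to validate the residue alphabet.
#' @return A tibble with columns `seq_id`, `description`, `residues`,
#'   `moltype`, `attributes` (named character vectors) and `source_file`.
#' @export
read_fasta <- function(path, moltype = c("protein", "nucleotide")) {
  moltype <- match.arg(moltype)
  if (!file.exists(path)) stop(sprintf("no such FASTA file: %s", path), call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  seq_id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  residues <- toupper(as.character(set))
  if (any(!nzchar(seq_id))) stop(sprintf("FASTA record with empty id in %s", path), call. = FALSE)
  if (anyDuplicated(seq_id)) {
    dups <- unique(seq_id[duplicated(seq_id)])
    warning(sprintf("duplicate seq_id(s) in %s: %s (all records kept)",
                    path, paste(utils::head(dups, 5L), collapse = ", ")), call. = FALSE)
  }
  if (any(!nzchar(residues))) {
    warning(sprintf("%d empty sequence(s) in %s (kept)",
                    sum(!nzchar(residues)), path), call. = FALSE)
  }
  alphabet <- if (moltype == "protein") "^[ACDEFGHIKLMNPQRSTVWYBXZJUO*-]*$" else "^[ACGTUNRYSWKMBDHV-]*$"
  bad <- !grepl(alphabet, residues)
  if (any(bad)) {
    warning(sprintf("%d record(s) in %s contain characters outside the %s alphabet",
                    sum(bad), path, moltype), call. = FALSE)
  }
  tibble::tibble(
    seq_id = unname(seq_id),
    description = unname(description),
    residues = unname(residues),
    moltype = moltype,
    attributes = lapply(description, parse_header_attributes),
    source_file = basename(path)
  )
}

#' Write sequence records to FASTA
#'
#' Round-trip safe with [read_fasta()]: ids, descriptions and residues are
#' reproduced byte-identically (residues are already upper case on read).
#'
#' @param records Sequence-record tibble (needs `seq_id`, `description`,
#'   `residues`).
#' @param path Output path.
#' @param line_width Residues per line (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, line_width = 70L) {
  stopifnot(line_width >= 1L)
  if (nrow(records) == 0L) {
    warning(sprintf("writing empty FASTA file %s", path), call. = FALSE)
    file.create(path)
    return(invisible(path))
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    header <- if (nzchar(records$description[[i]])) {
      paste(records$seq_id[[i]], records$description[[i]])
    } else records$seq_id[[i]]
    writeLines(paste0(">", header), con)
    res <- records$residues[[i]]
    if (nzchar(res)) {
      starts <- seq(1L, nchar(res), by = line_width)
      writeLines(substring(res, starts, pmin(starts + line_width - 1L, nchar(res))), con)
    }
  }
  invisible(path)
}

#' Parse an NCBI assembly-summary file
#'
#' Tab-separated; lines starting with `#` are headers. Only three columns
#' are consumed: the assembly accession (column 1), the organism name
#' (column 8) and the infraspecific/strain name (column 9, may be empty).
#' Data lines with fewer than nine columns are collected as recoverable
#' per-line errors (reported via a warning and the `parse_errors`
#' attribute).
#'
#' @param path Path to an `assembly_summary.txt`-style file.
#' @return A tibble with columns `accession`, `organism_name`,
#'   `infraspecific_name`.
#' @export
parse_assembly_summary <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such assembly summary: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  errors <- character()
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 9L) {
      errors <- c(errors, sprintf("line %d: %d column(s), need >= 9", i, length(fields)))
      next
    }
    rows[[i]] <- tibble::tibble(
      accession = fields[[1]],
      organism_name = fields[[8]],
      infraspecific_name = fields[[9]]
    )
  }
  out <- dplyr::bind_rows(c(
    list(tibble::tibble(accession = character(), organism_name = character(),
                        infraspecific_name = character())),
    rows
  ))
  if (length(errors) > 0L) {
    warning(sprintf("parse_assembly_summary: %d short line(s) in %s: %s",
                    length(errors), path,
                    paste(utils::head(errors, 5L), collapse = "; ")), call. = FALSE)
  }
  attr(out, "parse_errors") <- errors
  out
}

#' Read every assembly summary in a directory
#'
#' @param species_dir Directory holding one or more summary files.
#' @return A combined tibble of assembly rows.
#' @export
read_assembly_dir <- function(species_dir) {
  if (!dir.exists(species_dir)) {
    stop(sprintf("species directory does not exist: %s", species_dir), call. = FALSE)
  }
  files <- list.files(species_dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop(sprintf("no summary files in %s", species_dir), call. = FALSE)
  dplyr::bind_rows(lapply(sort(files), parse_assembly_summary))
}
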