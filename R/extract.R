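#' Build a genome-scoped sequence index
#'
#' Reads every FASTA file of the stated molecule type in `genome_dir` and
#' indexes each record under its lookup keys. For every record the primary
#' key is the first whitespace token of the header; nucleotide (CDS) records
#' are additionally keyed by the `[protein_id=...]` header attribute, which
#' is how CDS sequences are located from protein accession numbers. Every
#' key is also registered in version-stripped form (`WP_1.1` resolves via
#' `WP_1` too), tolerating version drift between annotator output and the
#' sequence release; an exact-version key always wins over the stripped
#' fallback. Lookups are genome-scoped: a gene identifier is never resolved
#' against a different genome's file.
#'
#' @param genome_dir Directory of genome FASTA files (`.faa` for protein,
#'   `.fna`/`.fasta` for nucleotide).
#' @param moltype `"protein"` or `"nucleotide"`.
#' @param suffixes Extensions stripped from file names to form the
#'   genome label.
#' @return An object of class `seq_index`.
#' @export
build_index <- function(genome_dir, moltype = c("protein", "nucleotide"),
                        suffixes = c(".faa", ".fna", ".fasta")) {
  moltype <- match.arg(moltype)
  if (!dir.exists(genome_dir)) {
    stop(sprintf("genome directory does not exist: %s", genome_dir), call. = FALSE)
  }
  ext <- if (moltype == "protein") "\\.(faa|fasta)$" else "\\.(fna|fasta)$"
  files <- sort(list.files(genome_dir, pattern = ext, full.names = TRUE))
  if (length(files) == 0L) {
    stop(sprintf("no %s FASTA files in %s", moltype, genome_dir), call. = FALSE)
  }
  genomes <- list()
  for (f in files) {
    genome_id <- strip_genome_suffix(f, suffixes)
    records <- read_fasta(f, moltype = moltype)
    keys <- as.list(records$seq_id)
    if (moltype == "nucleotide") {
      keys <- Map(function(k, at) {
        pid <- at[["protein_id"]]
        # protein accession is the primary CDS lookup key, bare id the fallback
        if (!is.null(pid) && !is.na(pid) && nzchar(pid)) c(pid, k) else k
      }, keys, records$attributes)
    }
    exact <- integer()
    for (i in seq_along(keys)) {
      for (k in keys[[i]]) {
        if (k %in% names(exact)) {
          stop(sprintf("colliding index key '%s' in genome %s (records %s and %s)",
                       k, genome_id, records$seq_id[[exact[[k]]]], records$seq_id[[i]]),
               call. = FALSE)
        }
        exact[[k]] <- i
      }
    }
    stripped_keys <- sub("\\.\\d+$", "", names(exact))
    stripped <- integer()
    ambiguous <- character()
    for (j in seq_along(stripped_keys)) {
      sk <- stripped_keys[[j]]
      if (sk %in% names(exact)) next  # exact key of that spelling exists; it wins
      if (sk %in% names(stripped)) {
        if (stripped[[sk]] != exact[[j]]) ambiguous <- c(ambiguous, sk)
      } else {
        stripped[[sk]] <- exact[[j]]
      }
    }
    if (length(ambiguous) > 0L) stripped <- stripped[!names(stripped) %in% ambiguous]
    genomes[[genome_id]] <- list(records = records, exact = exact, stripped = stripped)
  }
  structure(list(genomes = genomes, moltype = moltype), class = "seq_index")
}

#' @export
print.seq_index <- function(x, ...) {
  n_rec <- sum(vapply(x$genomes, function(g) nrow(g$records), integer(1)))
  cat(sprintf("<seq_index> %d genome(s), %d %s record(s)\n",
              length(x$genomes), n_rec, x$moltype))
  invisible(x)
}

index_lookup <- function(index, genome_id, gene_id) {
  g <- index$genomes[[genome_id]]
  if (is.null(g)) return(NULL)
  i <- g$exact[gene_id]
  if (is.na(i)) i <- g$exact[sub("\\.\\d+$", "", gene_id)]
  if (is.na(i)) i <- g$stripped[sub("\\.\\d+$", "", gene_id)]
  if (is.na(i)) return(NULL)
  g$records[unname(i), ]
}

#' Match a genome label to its assembly-summary row
#'
#' An assembly accession (`GC[AF]_` + digits + version) embedded in the
#' genome label is extracted and prefix-matched against the summary
#' accessions; failing that, an exact match of the whole label is tried.
#' Species tagging is optional throughout the pipeline, so no match is not
#' an error — `NULL` is returned and the organism field falls back to "NA".
#'
#' @param genome_id Genome label (typically an NCBI assembly file stem).
#' @param assemblies Assembly tibble from [parse_assembly_summary()], or
#'   `NULL`.
#' @return A one-row assembly tibble, or `NULL` when unmatched.
#' @export
match_species <- function(genome_id, assemblies) {
  if (is.null(assemblies) || nrow(assemblies) == 0L) return(NULL)
  m <- regmatches(genome_id, regexpr(ACCESSION_PATTERN, genome_id))
  hit <- if (length(m) == 1L) assemblies[assemblies$accession == m, ] else assemblies[0, ]
  if (nrow(hit) == 0L) hit <- assemblies[assemblies$accession == genome_id, ]
  if (nrow(hit) == 0L) return(NULL)
  if (nrow(unique(hit)) > 1L || nrow(hit) > 1L) {
    stop(sprintf("ambiguous assembly summary: %d rows match genome '%s'",
                 nrow(hit), genome_id), call. = FALSE)
  }
  hit
}

species_clause <- function(info) {
  if (is.null(info)) return(NULL)
  org <- trimws(paste(info$organism_name, info$infraspecific_name))
  sprintf("[%s]", org)
}

#' Extract annotated sequences grouped by KO
#'
#' The keyword-matching core: each annotation hit is resolved genome-scoped
#' against the sequence index, the found record is copied with its header
#' rewritten to carry the KO and species tags, and the copies are grouped
#' by KO then by genome. Exact duplicate hit rows (same genome, gene and
#' KO) are collapsed before extraction; the same gene assigned to two
#' different KOs is extracted into both KO groups. Hits whose gene cannot
#' be located go to the miss list with a warning — extraction never fails
#' because of an absent gene.
#'
#' The rewritten header is
#' `{gene_id} {original description} [KO:{ko_id}] [{organism} {strain}]`,
#' with the species clause omitted when no assembly row matches.
#'
#' @param hits Annotation-hit tibble (see [merge_result_files()]).
#' @param index A `seq_index` from [build_index()].
#' @param assemblies Assembly tibble, or `NULL` to skip species tagging.
#' @return An object of class `extraction_result`: list with `groups`
#'   (nested list `ko_id -> genome_id -> record tibble`), `manifest`
#'   (one row per extracted sequence), `misses` (unresolved hits) and
#'   `stats` (per-KO and per-genome counts).
#' @export
extract <- function(hits, index, assemblies = NULL) {
  stopifnot(inherits(index, "seq_index"))
  if (is.null(hits) || nrow(hits) == 0L) stop("no annotation hits to extract", call. = FALSE)
  n0 <- nrow(hits)
  hits <- dplyr::distinct(hits, genome_id, gene_id, ko_id, .keep_all = TRUE)
  if (nrow(hits) < n0) {
    message(sprintf("collapsed %d duplicate hit row(s)", n0 - nrow(hits)))
  }
  species_cache <- list()
  groups <- list()
  manifest_rows <- vector("list", nrow(hits))
  miss_rows <- vector("list", nrow(hits))
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    rec <- index_lookup(index, h$genome_id, h$gene_id)
    if (is.null(rec)) {
      miss_rows[[i]] <- h
      next
    }
    if (is.null(species_cache[[h$genome_id]])) {
      species_cache[[h$genome_id]] <- list(info = match_species(h$genome_id, assemblies))
    }
    info <- species_cache[[h$genome_id]]$info
    clause <- c(sprintf("[KO:%s]", h$ko_id), species_clause(info))
    desc <- trimws(paste(c(rec$description[[1]], clause), collapse = " "))
    out <- rec
    out$seq_id <- h$gene_id
    out$description <- desc
    groups[[h$ko_id]][[h$genome_id]] <-
      dplyr::bind_rows(groups[[h$ko_id]][[h$genome_id]], out)
    manifest_rows[[i]] <- tibble::tibble(
      ko_id = h$ko_id, genome_id = h$genome_id, gene_id = h$gene_id,
      length = nchar(rec$residues[[1]]),
      organism_name = if (is.null(info)) "NA" else info$organism_name,
      infraspecific_name = if (is.null(info)) "" else info$infraspecific_name,
      source_file = rec$source_file[[1]]
    )
  }
  manifest <- dplyr::bind_rows(manifest_rows)
  misses <- dplyr::bind_rows(c(list(empty_hits()), miss_rows))
  if (nrow(misses) > 0L) {
    warning(sprintf("%d hit(s) could not be matched to a sequence (see misses)",
                    nrow(misses)), call. = FALSE)
  }
  if (nrow(manifest) == 0L) {
    manifest <- tibble::tibble(
      ko_id = character(), genome_id = character(), gene_id = character(),
      length = integer(), organism_name = character(),
      infraspecific_name = character(), source_file = character()
    )
  }
  stats <- list(
    n_extracted = nrow(manifest),
    n_missed = nrow(misses),
    per_ko = if (nrow(manifest)) table(manifest$ko_id) else table(character()),
    per_genome = if (nrow(manifest)) table(manifest$genome_id) else table(character())
  )
  structure(list(groups = groups, manifest = manifest, misses = misses,
                 stats = stats, moltype = index$moltype),
            class = "extraction_result")
}

#' @export
print.extraction_result <- function(x, ...) {
  cat(sprintf("<extraction_result> %d sequence(s) in %d KO group(s), %d miss(es)\n",
              x$stats$n_extracted, length(x$groups), x$stats$n_missed))
  for (ko in names(x$groups)) {
    n <- sum(vapply(x$groups[[ko]], nrow, integer(1)))
    cat(sprintf("  %s: %d sequence(s) across %d genome(s)\n",
                ko, n, length(x$groups[[ko]])))
  }
  invisible(x)
}

sanitize_filename <- function(x) gsub("[^A-Za-z0-9._-]", "_", x)

#' Write an extraction result as a per-KO directory tree
#'
#' Layout: `outdir/{ko_id}/{genome_id}.faa` (or `.fna` for nucleotide
#' extractions), one file per (KO, genome) pair with at least one sequence,
#' plus `manifest.tsv` and `misses.tsv` at the top level. Refuses to write
#' into a non-empty directory unless `force = TRUE`.
#'
#' @param result An `extraction_result`.
#' @param outdir Output directory (created if needed).
#' @param force Overwrite a non-empty `outdir`.
#' @return Path of the written manifest, invisibly.
#' @export
write_tree <- function(result, outdir, force = FALSE) {
  stopifnot(inherits(result, "extraction_result"))
  existing <- if (dir.exists(outdir)) {
    setdiff(list.files(outdir, all.files = TRUE, no.. = TRUE), "run.log")
  } else character()
  if (length(existing) > 0L) {
    if (!isTRUE(force)) {
      stop(sprintf("output directory %s is not empty (use force = TRUE to overwrite)",
                   outdir), call. = FALSE)
    }
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (identical(result$moltype, "nucleotide")) ".fna" else ".faa"
  for (ko in names(result$groups)) {
    ko_dir <- file.path(outdir, sanitize_filename(ko))
    dir.create(ko_dir, showWarnings = FALSE)
    for (genome in names(result$groups[[ko]])) {
      write_fasta(result$groups[[ko]][[genome]],
                  file.path(ko_dir, paste0(sanitize_filename(genome), ext)))
    }
  }
  manifest_path <- file.path(outdir, "manifest.tsv")
  utils::write.table(result$manifest, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  utils::write.table(result$misses, file.path(outdir, "misses.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(manifest_path)
}
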