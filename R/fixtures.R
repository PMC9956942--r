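# Deterministic back-translation: one fixed codon per amino acid (standard
# genetic code / translation table 11 for coding sequences). Biological
# realism is irrelevant here; identifier consistency between the protein
# and CDS files is the contract.
CODON_OF <- c(
  A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
  Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
  L = "CTT", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
  S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT"
)

KO_DEFINITIONS <- c(
  K00192 = "acetyl-CoA decarbonylase/synthase, CODH/ACS complex subunit alpha",
  K00193 = "acetyl-CoA decarbonylase/synthase complex subunit beta",
  K00194 = "acetyl-CoA decarbonylase/synthase complex subunit delta",
  K00195 = "acetyl-CoA decarbonylase/synthase complex subunit gamma",
  K00197 = "acetyl-CoA decarbonylase/synthase complex subunit gamma 2",
  K00198 = "anaerobic carbon-monoxide dehydrogenase catalytic subunit",
  K14138 = "acetyl-CoA synthase",
  K15023 = "acetyl-CoA decarbonylase/synthase complex subunit epsilon"
)

ORGANISM_POOL <- data.frame(
  organism = c("Methanococcus maripaludis", "Methanosarcina acetivorans",
               "Methanocaldococcus jannaschii", "Methanothermobacter thermautotrophicus",
               "Methanobrevibacter smithii", "Archaeoglobus fulgidus",
               "Methanopyrus kandleri", "Methanosphaera stadtmanae",
               "Methanoculleus marisnigri", "Methanospirillum hungatei"),
  strain = c("strain=S2", "strain=C2A", "strain=DSM 2661", "strain=Delta H",
             "strain=ATCC 35061", "strain=DSM 4304", "strain=AV19", "",
             "strain=JR1", "strain=JF-1"),
  stringsAsFactors = FALSE
)

with_fixture_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specify a synthetic fixture
#'
#' Describes a coherent batch of synthetic archaeal-style genomes: paired
#' protein (`.faa`) and CDS (`.fna`) files linked by `[protein_id=...]`
#' tokens, per-genome annotation result files, NCBI-style assembly
#' summaries, and an expected manifest listing every generated
#' (genome, KO, gene) triple. The defaults mirror the 20-genome, two-KO
#' (K00192/K00195) benchmark layout with one gene per KO per genome.
#'
#' @param n_genomes Number of genomes (>= 1).
#' @param kos KO identifiers (`K` + 5 digits), non-empty.
#' @param genes_per_ko_per_genome Genes generated per KO in each genome.
#' @param protein_length_range Inclusive (min, max) protein length in
#'   residues; both at least 10.
#' @param dropout Fraction of annotation rows withheld from the result
#'   files (the genes stay in the genomes and in the expected manifest),
#'   in `[0, 1)`.
#' @param seed Integer seed; generation is byte-deterministic under it.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_genomes = 20L, kos = c("K00192", "K00195"),
                         genes_per_ko_per_genome = 1L,
                         protein_length_range = c(300L, 850L),
                         dropout = 0, seed = 1L) {
  stopifnot(n_genomes >= 1L, length(kos) >= 1L,
            genes_per_ko_per_genome >= 1L)
  if (!all(grepl(KO_PATTERN, kos))) stop("malformed KO identifier in kos", call. = FALSE)
  if (length(protein_length_range) != 2L || any(protein_length_range < 10L) ||
      protein_length_range[1] > protein_length_range[2]) {
    stop("protein_length_range must be (min, max) with min >= 10", call. = FALSE)
  }
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)", call. = FALSE)
  structure(list(n_genomes = as.integer(n_genomes), kos = kos,
                 genes_per_ko_per_genome = as.integer(genes_per_ko_per_genome),
                 protein_length_range = as.integer(protein_length_range),
                 dropout = dropout, seed = as.integer(seed)),
            class = "fixture_spec")
}

random_protein <- function(length) {
  paste0("M", paste(sample(names(CODON_OF), length - 1L, replace = TRUE),
                    collapse = ""))
}

back_translate <- function(protein) {
  paste0(paste(CODON_OF[strsplit(protein, "")[[1]]], collapse = ""), "TAA")
}

#' Generate a synthetic fixture on disk
#'
#' Writes, under `outdir`: `genomes/` (paired `<stem>.faa` / `<stem>.fna`
#' per genome, stems following the NCBI convention
#' `GCF_9xxxxxxxx.1_ASM<i>v1`), `results/` (one `<stem>.out` annotation
#' detail file per genome with asterisk-marked rows for every generated
#' gene not withheld by `dropout`, plus one sub-threshold decoy row),
#' `species/assembly_summary.txt` (tab-separated, accessions in column 1,
#' organism and strain in columns 8 and 9), and `expected_manifest.tsv`
#' listing every generated (genome, KO, gene) triple. Output is
#' byte-deterministic under the spec seed.
#'
#' @param spec A [fixture_spec()].
#' @param outdir Output directory (created; must be empty or absent).
#' @return List of paths: `genomes`, `results`, `species`,
#'   `expected_manifest`, plus the tibble `expected`.
#' @export
generate <- function(spec, outdir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  genomes_dir <- file.path(outdir, "genomes")
  results_dir <- file.path(outdir, "results")
  species_dir <- file.path(outdir, "species")
  for (d in c(genomes_dir, results_dir, species_dir)) {
    dir.create(d, showWarnings = FALSE)
  }
  with_fixture_seed(spec$seed, {
    gene_counter <- 0L
    expected <- list()
    annotation_rows <- list()
    summary_rows <- character(spec$n_genomes)
    for (g in seq_len(spec$n_genomes)) {
      acc <- sprintf("GCF_9%08d.1", g)
      stem <- sprintf("%s_ASM%dv1", acc, g)
      org <- ORGANISM_POOL[((g - 1L) %% nrow(ORGANISM_POOL)) + 1L, ]
      faa <- character()
      fna <- character()
      out_lines <- c("# gene name\tKO\tthrshld\tscore(full)\tE-value\t\"KO definition\"",
                     "#---------\t--\t-------\t-----------\t-------\t---------------")
      cds_i <- 0L
      for (ko in spec$kos) {
        for (k in seq_len(spec$genes_per_ko_per_genome)) {
          gene_counter <- gene_counter + 1L
          pid <- sprintf("WP_9%08d.1", gene_counter)
          len <- spec$protein_length_range[1] +
            sample.int(diff(spec$protein_length_range) + 1L, 1L) - 1L
          prot <- random_protein(len)
          def <- if (ko %in% names(KO_DEFINITIONS)) KO_DEFINITIONS[[ko]] else {
            sprintf("synthetic ortholog family %s", ko)
          }
          faa <- c(faa,
                   sprintf(">%s %s [%s]", pid, def, org$organism),
                   wrap_residues(prot))
          cds_i <- cds_i + 1L
          fna <- c(fna,
                   sprintf(">lcl|%s_cds_%s_%d [locus_tag=SYN_%05d] [protein_id=%s] [location=%d..%d]",
                           acc, pid, cds_i, gene_counter, pid,
                           cds_i * 2000L, cds_i * 2000L + (len + 1L) * 3L - 1L),
                   wrap_residues(back_translate(prot)))
          thr <- round(stats::runif(1, 200, 600), 2)
          score <- round(thr + stats::runif(1, 20, 150), 1)
          evalue <- signif(10^(-stats::runif(1, 50, 250)), 3)
          annotation_rows[[length(annotation_rows) + 1L]] <- list(
            stem = stem,
            line = sprintf("* %s\t%s\t%s\t%s\t%s\t\"%s\"",
                           pid, ko, format(thr, scientific = FALSE),
                           format(score, scientific = FALSE),
                           format(evalue), def)
          )
          expected[[length(expected) + 1L]] <- tibble::tibble(
            genome_id = stem, ko_id = ko, gene_id = pid
          )
        }
      }
      # one sub-threshold decoy per genome: neither asterisk-marked nor
      # below the E-value ceiling, so both default filters remove it
      first_pid <- sprintf("WP_9%08d.1",
                           gene_counter - length(spec$kos) * spec$genes_per_ko_per_genome + 1L)
      decoy <- sprintf("  %s\tK03520\t450.00\t31.2\t1.3e-03\t\"aerobic carbon-monoxide dehydrogenase large subunit\"",
                       first_pid)
      writeLines(faa, file.path(genomes_dir, paste0(stem, ".faa")))
      writeLines(fna, file.path(genomes_dir, paste0(stem, ".fna")))
      summary_rows[[g]] <- paste(c(acc, "PRJNA000000", "SAMN00000000", "",
                                   "representative genome", "000000", "2157",
                                   org$organism, org$strain,
                                   rep("na", 13L)), collapse = "\t")
      attr(out_lines, "stem") <- stem
      out_path <- file.path(results_dir, paste0(stem, ".out"))
      writeLines(out_lines, out_path)
      annotation_rows[[length(annotation_rows) + 1L]] <- list(stem = stem, line = decoy)
    }
    expected <- dplyr::bind_rows(expected)
    # withhold a deterministic sample of significant annotation rows
    sig_idx <- which(vapply(annotation_rows, function(r) startsWith(r$line, "*"), logical(1)))
    n_drop <- round(spec$dropout * length(sig_idx))
    drop_idx <- if (n_drop > 0L) sig_idx[sample.int(length(sig_idx), n_drop)] else integer()
    keep <- setdiff(seq_along(annotation_rows), drop_idx)
    for (r in annotation_rows[keep]) {
      cat(r$line, "\n", sep = "",
          file = file.path(results_dir, paste0(r$stem, ".out")), append = TRUE)
    }
    writeLines(c("#   See assembly summary documentation for column definitions",
                 paste0("# ", paste(c("assembly_accession", "bioproject", "biosample",
                                      "wgs_master", "refseq_category", "taxid",
                                      "species_taxid", "organism_name",
                                      "infraspecific_name",
                                      paste0("col", 10:22)), collapse = "\t")),
                 summary_rows),
               file.path(species_dir, "assembly_summary.txt"))
    manifest_path <- file.path(outdir, "expected_manifest.tsv")
    utils::write.table(expected, manifest_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    list(genomes = genomes_dir, results = results_dir, species = species_dir,
         expected_manifest = manifest_path, expected = expected)
  })
}

wrap_residues <- function(res, width = 70L) {
  starts <- seq(1L, nchar(res), by = width)
  substring(res, starts, pmin(starts + width - 1L, nchar(res)))
}

#' Generate a hit table reproducing requested false-negative counts
#'
#' Constructs a tabular alignment hit file (query, subject, percent
#' identity, subject gene name) whose [fn_table()] output reproduces the
#' requested per-threshold false-negative counts exactly. Queries meant to
#' be false negatives at every threshold are split between no-hit rows and
#' hits whose subject carries an uninformative name; queries that flip
#' from true positive to false negative between two thresholds get an
#' identity between them. Row order is shuffled deterministically under
#' the seed.
#'
#' @param n_queries Number of distinct queries.
#' @param fn_counts Named numeric vector: names are ascending identity
#'   thresholds, values the false-negative counts (non-decreasing, each
#'   at most `n_queries`).
#' @param seed Integer seed.
#' @param path Output TSV path.
#' @return `path`, invisibly; the tibble is attached as attribute `hits`.
#' @export
generate_hit_table <- function(n_queries, fn_counts, seed = 1L, path) {
  thresholds <- as.numeric(names(fn_counts))
  if (anyNA(thresholds) || is.unsorted(thresholds, strictly = TRUE)) {
    stop("fn_counts must be named by strictly ascending thresholds", call. = FALSE)
  }
  counts <- as.integer(fn_counts)
  if (any(counts < 0L) || any(counts > n_queries)) {
    stop("fn counts must lie in [0, n_queries]", call. = FALSE)
  }
  if (is.unsorted(counts)) {
    stop("fn counts must be non-decreasing with threshold", call. = FALSE)
  }
  rows <- list()
  qi <- 0L
  next_query <- function() {
    qi <<- qi + 1L
    sprintf("query_%03d", qi)
  }
  # always-FN block: half no-hit, half uninformative subject names
  n_always <- counts[[1]]
  n_nohit <- ceiling(n_always / 2)
  for (i in seq_len(n_nohit)) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      query_id = next_query(), subject_id = NA_character_,
      identity_pct = NA_real_, subject_gene_name = NA_character_)
  }
  for (i in seq_len(n_always - n_nohit)) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      query_id = next_query(), subject_id = sprintf("sub_anon_%03d", i),
      identity_pct = 100, subject_gene_name = "hypothetical protein")
  }
  # threshold-crossing blocks: identity between consecutive thresholds
  for (j in seq_along(thresholds)[-1]) {
    d <- counts[[j]] - counts[[j - 1L]]
    ident <- (thresholds[[j - 1L]] + thresholds[[j]]) / 2
    for (i in seq_len(d)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        query_id = next_query(), subject_id = sprintf("sub_mid%d_%03d", j, i),
        identity_pct = ident, subject_gene_name = "cdhA")
    }
  }
  # always-TP block
  for (i in seq_len(n_queries - counts[[length(counts)]])) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      query_id = next_query(), subject_id = sprintf("sub_tp_%03d", i),
      identity_pct = 100, subject_gene_name = "cdhA")
  }
  hits <- dplyr::bind_rows(rows)
  hits <- with_fixture_seed(seed, hits[sample(nrow(hits)), ])
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  attr(path, "hits") <- hits
  invisible(path)
}
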