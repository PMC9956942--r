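#' Per-sequence length report
#'
#' The fx2tab-style statistics step: one row per sequence with its exact
#' residue length, plus an n/min/median/max summary. Row order is input
#' order.
#'
#' @param records Sequence-record tibble.
#' @return A list with `rows` (tibble `seq_id`, `length`) and `summary`
#'   (list `n`, `min`, `median`, `max`; the latter three are `NA` for an
#'   empty input).
#' @export
length_report <- function(records) {
  lens <- nchar(records$residues)
  rows <- tibble::tibble(seq_id = records$seq_id, length = lens)
  summary <- if (length(lens) == 0L) {
    list(n = 0L, min = NA_real_, median = NA_real_, max = NA_real_)
  } else {
    list(n = length(lens), min = min(lens), median = stats::median(lens),
         max = max(lens))
  }
  list(rows = rows, summary = summary)
}

#' Filter sequences against a reference length
#'
#' Drops partial sequences: a record is kept when its length is at least
#' `ceiling(min_fraction * reference_length)`. The canonical worked example
#' is the CODH/ACS complex subunit alpha (K00192), whose full-length
#' protein is ~806 aa; truncated ~400 aa entries fall well below the
#' default 75% cutoff and are removed before building the reference set.
#'
#' @param records Sequence-record tibble.
#' @param reference_length Full-length reference, in residues (> 0).
#' @param min_fraction Minimum fraction of the reference length, in (0, 1].
#' @return List with `kept` and `dropped` tibbles; together they partition
#'   the input, orders preserved.
#' @export
filter_by_reference_length <- function(records, reference_length,
                                       min_fraction = 0.75) {
  stopifnot(length(reference_length) == 1L, reference_length > 0)
  if (!is.numeric(min_fraction) || length(min_fraction) != 1L ||
      min_fraction <= 0 || min_fraction > 1) {
    stop("min_fraction must lie in (0, 1]", call. = FALSE)
  }
  cutoff <- ceiling(min_fraction * reference_length)
  keep <- nchar(records$residues) >= cutoff
  list(kept = records[keep, ], dropped = records[!keep, ], cutoff = cutoff)
}

#' Collapse a sequence set at 100% identity
#'
#' The de-redundancy step producing a non-redundant representative set, in
#' two readings of "100% identity". `exact` (the default, conservative
#' reading): sequences with byte-identical residues form one cluster.
#' `containment` (the CD-HIT-like greedy reading): sequences are sorted by
#' length descending, and each sequence joins the first earlier
#' representative that contains it as a contiguous substring, else founds
#' a new cluster — so a full-length sequence absorbs its exact fragments.
#' Representative tie-breaking is deterministic: longest sequence first,
#' then lexicographically smallest `seq_id`. The operation is idempotent.
#'
#' @param records Sequence-record tibble.
#' @param mode `"exact"` or `"containment"`.
#' @return List with `representatives` (record tibble, one per cluster, in
#'   representative order) and `clusters` (tibble `representative`,
#'   `member`, `member_length`) and `mode`.
#' @export
dedup_exact <- function(records, mode = c("exact", "containment")) {
  mode <- match.arg(mode)
  if (nrow(records) == 0L) {
    return(list(representatives = records,
                clusters = tibble::tibble(representative = character(),
                                          member = character(),
                                          member_length = integer()),
                mode = mode))
  }
  lens <- nchar(records$residues)
  # deterministic processing order: length desc, then id asc
  ord <- order(-lens, records$seq_id, method = "radix")
  if (mode == "exact") {
    rep_for <- ord[match(records$residues, records$residues[ord])]
    rep_pos <- unique(rep_for[ord])
    rep_id <- records$seq_id[rep_for]
  } else {
    rep_idx <- integer(0)                  # indices (into records) of representatives
    assigned <- integer(nrow(records))     # representative index per record
    for (i in ord) {
      found <- 0L
      for (r in rep_idx) {
        if (grepl(records$residues[[i]], records$residues[[r]], fixed = TRUE)) {
          found <- r
          break
        }
      }
      if (found == 0L) {
        rep_idx <- c(rep_idx, i)
        found <- i
      }
      assigned[[i]] <- found
    }
    rep_pos <- rep_idx
    rep_id <- records$seq_id[assigned]
  }
  clusters <- tibble::tibble(
    representative = rep_id,
    member = records$seq_id,
    member_length = lens
  )
  list(representatives = records[rep_pos, ], clusters = clusters, mode = mode)
}

#' Global percent identity between two sequences
#'
#' A desk-scale pairwise-identity measure making the assessment stage
#' self-contained: a Needleman–Wunsch global alignment with match = 1,
#' mismatch = 0 and a linear gap penalty of -1, with identity defined as
#' 100 x matches / L, where L is the alignment length
#' (`denominator = "alignment"`) or the shorter sequence length
#' (`denominator = "shorter"`). Symmetric in its arguments. This is a
#' simple exact aligner, not a heuristic search engine.
#'
#' @param a,b Non-empty residue strings.
#' @param denominator `"alignment"` or `"shorter"`.
#' @return Percent identity in `[0, 100]`.
#' @export
percent_identity <- function(a, b, denominator = c("alignment", "shorter")) {
  denominator <- match.arg(denominator)
  stopifnot(is.character(a), is.character(b), length(a) == 1L, length(b) == 1L)
  if (!nzchar(a) || !nzchar(b)) stop("percent_identity: empty sequence", call. = FALSE)
  letters_ab <- unique(strsplit(paste0(a, b), "")[[1]])
  sub_mat <- matrix(0, length(letters_ab), length(letters_ab),
                    dimnames = list(letters_ab, letters_ab))
  diag(sub_mat) <- 1
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = sub_mat,
                                       gapOpening = 0, gapExtension = 1)
  matches <- Biostrings::nmatch(aln)
  L <- switch(denominator,
              alignment = nchar(as.character(Biostrings::alignedPattern(aln))),
              shorter = min(nchar(a), nchar(b)))
  100 * matches / L
}
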