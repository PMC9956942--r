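#' Default lexicon of "unpredicted" gene-name patterns
#'
#' Case-insensitive regular expressions marking a subject gene name as
#' uninformative: a match means the query counts as a false negative even
#' when the alignment itself is good. User-extensible everywhere it is
#' consumed.
#'
#' @return Character vector of regular expressions.
#' @export
unpredicted_name_patterns <- function() {
  c("^hypothetical protein$", "^uncharacteri[sz]ed", "^unknown",
    "^predicted protein$", "^DUF\\d*")
}

name_is_predicted <- function(name, lexicon = unpredicted_name_patterns(),
                              require_name = NULL) {
  if (is.na(name) || !nzchar(trimws(name))) return(FALSE)
  for (p in lexicon) {
    if (grepl(p, trimws(name), ignore.case = TRUE)) return(FALSE)
  }
  if (!is.null(require_name) && !grepl(require_name, name, ignore.case = TRUE)) {
    return(FALSE)
  }
  TRUE
}

normalize_query_hits <- function(hits, lexicon, require_name) {
  need <- c("query_id", "subject_id", "identity_pct", "subject_gene_name")
  missing <- setdiff(need, names(hits))
  if (length(missing) > 0L) {
    stop(sprintf("hit table lacks column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  hits$predicted <- vapply(hits$subject_gene_name, name_is_predicted,
                           logical(1), lexicon = lexicon,
                           require_name = require_name)
  if (anyDuplicated(hits$query_id)) {
    warning("duplicate query_id rows resolved to the best hit per query",
            call. = FALSE)
  }
  # best hit: max identity, ties broken by predicted name, then subject_id
  ord <- order(hits$query_id,
               -replace(hits$identity_pct, is.na(hits$identity_pct), -Inf),
               -hits$predicted, hits$subject_id, method = "radix")
  hits <- hits[ord, ]
  hits[!duplicated(hits$query_id), ]
}

#' Classify query hits as true positive or false negative at a threshold
#'
#' Each query keeps its single best hit (maximum identity; ties broken by
#' presence of a predicted name, then lexicographically by subject id). A
#' query is a true positive when its best hit exists, reaches the identity
#' threshold and carries a predicted (informative) gene name; otherwise it
#' is a false negative. `tp + fn` always equals the number of distinct
#' queries.
#'
#' @param hits Tibble with columns `query_id`, `subject_id`,
#'   `identity_pct`, `subject_gene_name`. A query with no hit is a row with
#'   `NA` subject fields.
#' @param threshold Identity threshold in `[0, 100]`.
#' @param lexicon Patterns marking names as unpredicted
#'   (see [unpredicted_name_patterns()]).
#' @param require_name Optional regular expression the subject gene name
#'   must additionally match (the strict reading in which only the correct
#'   gene symbol counts as annotated).
#' @return List with integer `tp` and `fn`.
#' @export
classify <- function(hits, threshold, lexicon = unpredicted_name_patterns(),
                     require_name = NULL) {
  best <- normalize_query_hits(hits, lexicon, require_name)
  tp <- !is.na(best$identity_pct) & best$identity_pct >= threshold & best$predicted
  list(tp = sum(tp), fn = sum(!tp))
}

round_half_up <- function(x) floor(x + 0.5)

#' False-negative rates across identity thresholds
#'
#' Applies [classify()] at each threshold and reports counts and the
#' false-negative rate as an integer percentage (rounded half-up, the
#' arithmetic that takes 19 of 54 to 35%). With best-hit semantics the
#' rate is non-decreasing in the threshold.
#'
#' @inheritParams classify
#' @param thresholds Ascending identity thresholds
#'   (default `c(40, 50, 60, 70, 80, 90, 100)`).
#' @return A tibble with columns `threshold`, `n_queries`, `tp`, `fn`,
#'   `fn_rate_pct`.
#' @export
fn_table <- function(hits, thresholds = c(40, 50, 60, 70, 80, 90, 100),
                     lexicon = unpredicted_name_patterns(),
                     require_name = NULL) {
  if (is.null(hits) || nrow(hits) == 0L) stop("empty hit table", call. = FALSE)
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly ascending", call. = FALSE)
  }
  rows <- lapply(thresholds, function(t) {
    cl <- suppressWarnings(classify(hits, t, lexicon, require_name))
    tibble::tibble(threshold = t, n_queries = cl$tp + cl$fn,
                   tp = cl$tp, fn = cl$fn,
                   fn_rate_pct = round_half_up(100 * cl$fn / (cl$tp + cl$fn)))
  })
  dplyr::bind_rows(rows)
}

#' Recall of an extraction run against an expected manifest
#'
#' Compares the (genome, KO, gene) triples an extraction produced with the
#' reference triples that should have been recovered. Recall is the
#' fraction of expected triples present in the result. Extracted triples
#' absent from the expected manifest are counted separately as
#' `unexpected` and never inflate recall.
#'
#' @param expected Tibble with columns `genome_id`, `ko_id`, `gene_id`.
#' @param result An `extraction_result` (its manifest is used) or a
#'   manifest tibble with the same three columns.
#' @return List with `expected` (count), `extracted` (count of expected
#'   triples found), `recall` in `[0, 1]`, and `unexpected`.
#' @export
recall <- function(expected, result) {
  if (is.null(expected) || nrow(expected) == 0L) {
    stop("expected manifest is empty", call. = FALSE)
  }
  manifest <- if (inherits(result, "extraction_result")) result$manifest else result
  key <- function(df) paste(df$genome_id, df$ko_id, df$gene_id, sep = "\r")
  expected_keys <- unique(key(expected))
  found_keys <- unique(key(manifest))
  n_found <- sum(expected_keys %in% found_keys)
  list(
    expected = length(expected_keys),
    extracted = n_found,
    recall = n_found / length(expected_keys),
    unexpected = sum(!found_keys %in% expected_keys)
  )
}

#' Read a tabular hit table (outfmt-6-like plus a gene-name column)
#'
#' Tab-separated columns: `query_id`, `subject_id`, `identity_pct`,
#' `subject_gene_name`. A query with no hit may be encoded with empty
#' subject fields.
#'
#' @param path File path.
#' @return Hit tibble suitable for [classify()] / [fn_table()].
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such hit table: %s", path), call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          comment.char = "#", stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  need <- c("query_id", "subject_id", "identity_pct", "subject_gene_name")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("hit table %s lacks column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df$identity_pct <- suppressWarnings(as.numeric(df$identity_pct))
  df$subject_gene_name <- as.character(df$subject_gene_name)
  df$subject_id <- as.character(df$subject_id)
  tibble::as_tibble(df[need])
}
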