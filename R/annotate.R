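# Annotation bookkeeping over externally produced protein/domain hit tables:
# best-hit selection at an e-value cutoff, annotation-rate arithmetic with
# half-up rounding as printed in summary figures, and keyword search over
# best-hit descriptions.

# Round half away from zero at `digits` decimals (printed-table convention;
# base round() is banker's rounding).
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Annotation rate as a printed percentage
#'
#' 100 * n_annotated / n_total, rounded half-up to one decimal — the form in
#' which database-hit rates are reported in assembly summary figures.
#'
#' @param n_annotated Number of annotated contigs.
#' @param n_total Universe size (> 0).
#' @return Percentage with one decimal.
#' @export
annotation_rate <- function(n_annotated, n_total) {
  if (n_total <= 0) stop("annotation_rate: n_total must be positive")
  stopifnot(n_annotated >= 0, n_annotated <= n_total)
  round_half_up(100 * n_annotated / n_total, 1L)
}

#' Integer cross-tabulation percentage
#'
#' 100 * subset_size / set_size rounded half-up to an integer, as used for
#' pie-chart style subset percentages.
#'
#' @param subset_size Size of the subset.
#' @param set_size Size of the set (> 0).
#' @return Integer percentage.
#' @export
set_crosstab_percent <- function(subset_size, set_size) {
  if (set_size <= 0) stop("set_crosstab_percent: set_size must be positive")
  stopifnot(subset_size >= 0, subset_size <= set_size)
  as.integer(round_half_up(100 * subset_size / set_size, 0L))
}

#' Best-hit annotation table
#'
#' Keeps, per query, the hit with the lowest e-value (ties: highest bitscore,
#' then subject id) among hits at or below the cutoff. Input row order is
#' irrelevant.
#'
#' @param hit_table Hit data.frame (as from [parse_hit_table()]), optionally
#'   with a `description` column.
#' @param max_evalue E-value cutoff (default 1e-5, inclusive).
#' @param source Label for the hit source (e.g. "protein_db", "domain_db").
#' @return data.frame with one row per annotated query: `contig_id`,
#'   `best_hit_id`, `best_hit_description`, `evalue`, `bitscore`, `source`.
#' @export
best_hit_annotation <- function(hit_table, max_evalue = 1e-5,
                                source = "protein_db") {
  hits <- hit_table[hit_table$evalue <= max_evalue, , drop = FALSE]
  desc <- if ("description" %in% names(hits)) hits$description
          else rep(NA_character_, nrow(hits))
  if (nrow(hits) == 0L) {
    return(data.frame(contig_id = character(0), best_hit_id = character(0),
                      best_hit_description = character(0), evalue = numeric(0),
                      bitscore = numeric(0), source = character(0),
                      stringsAsFactors = FALSE))
  }
  ord <- order(hits$query_id, hits$evalue, -hits$bitscore, hits$subject_id)
  hits <- hits[ord, , drop = FALSE]
  desc <- desc[ord]
  keep <- !duplicated(hits$query_id)
  data.frame(
    contig_id = hits$query_id[keep],
    best_hit_id = hits$subject_id[keep],
    best_hit_description = desc[keep],
    evalue = hits$evalue[keep],
    bitscore = hits$bitscore[keep],
    source = source,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Keyword search over best-hit descriptions
#'
#' Case-insensitive fixed substring match of each term against the
#' `best_hit_description` column; results are the union over terms, without
#' duplicates, in annotation-table order.
#'
#' @param annotation Annotation table from [best_hit_annotation()].
#' @param terms Nonempty character vector of search terms.
#' @return Character vector of matching contig ids.
#' @export
keyword_search <- function(annotation, terms) {
  stopifnot(length(terms) >= 1L, all(nzchar(terms)))
  desc <- tolower(ifelse(is.na(annotation$best_hit_description), "",
                         annotation$best_hit_description))
  hit <- Reduce(`|`, lapply(tolower(terms), function(tm)
    grepl(tm, desc, fixed = TRUE)))
  unique(annotation$contig_id[hit])
}
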