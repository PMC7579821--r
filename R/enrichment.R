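# Term over-representation: exact upper-tail hypergeometric probability with
# the fold-enrichment (> 4) and raw P (< 0.05) filters. No multiplicity
# correction gates the filter (a BH column is emitted for information only).

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of observing at
#' least `k` annotated genes in a size-`n` draw from a universe of `N` genes
#' of which `K` carry the term.
#'
#' @param k Observed overlap.
#' @param n Foreground (draw) size.
#' @param K Universe genes carrying the term.
#' @param N Universe size.
#' @return Exact tail probability in (0, 1].
#' @export
hypergeom_tail <- function(k, n, K, N) {
  if (any(c(k, n, K, N) < 0) || k > min(n, K) || n > N || K > N) {
    stop(sprintf("inconsistent hypergeometric counts: k=%s n=%s K=%s N=%s",
                 k, n, K, N))
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Term over-representation in a gene set
#'
#' Tests each term with at least one foreground gene against the universe via
#' the upper-tail hypergeometric probability. A term passes when fold
#' enrichment (k/n)/(K/N) strictly exceeds `min_fold` and p < `alpha` — the
#' raw-P, fold-filtered rule used for GO term reporting. Term genes outside
#' the universe are ignored.
#'
#' @param foreground Character vector of genes (must lie in `universe`).
#' @param term_map data.frame with columns `term` and `gene`; optional
#'   columns `name` and `category` are carried through per term.
#' @param universe Character vector: the background gene universe.
#' @param min_fold Fold-enrichment filter (default 4, strict).
#' @param alpha Raw P-value filter (default 0.05, strict).
#' @return data.frame sorted by p then term: `term`, `k`, `n`, `K`, `N`,
#'   `fold`, `p`, `p_adj` (BH, informational), `passes`.
#' @export
enrich <- function(foreground, term_map, universe, min_fold = 4,
                   alpha = 0.05) {
  foreground <- unique(foreground)
  universe <- unique(universe)
  outside <- setdiff(foreground, universe)
  if (length(outside) > 0L) {
    stop("foreground gene(s) not in universe: ",
         paste(head(outside, 5L), collapse = ", "))
  }
  stopifnot(all(c("term", "gene") %in% names(term_map)))
  tm <- term_map[term_map$gene %in% universe, , drop = FALSE]
  genes_by_term <- split(tm$gene, tm$term)
  N <- length(universe)
  n <- length(foreground)
  rows <- lapply(names(genes_by_term), function(term) {
    g <- unique(genes_by_term[[term]])
    K <- length(g)
    k <- sum(g %in% foreground)
    if (k == 0L) return(NULL)
    fold <- (k / n) / (K / N)
    p <- hypergeom_tail(k, n, K, N)
    data.frame(term = term, k = k, n = n, K = K, N = N, fold = fold, p = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(term = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), fold = numeric(0),
                      p = numeric(0), p_adj = numeric(0), passes = logical(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out$passes <- out$fold > min_fold & out$p < alpha
  out <- out[order(out$p, out$term), , drop = FALSE]
  meta_cols <- intersect(c("name", "category"), names(term_map))
  for (mc in meta_cols) {
    lut <- term_map[!duplicated(term_map$term), c("term", mc)]
    out[[mc]] <- lut[[mc]][match(out$term, lut$term)]
  }
  rownames(out) <- NULL
  out
}
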