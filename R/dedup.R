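# Redundancy reduction: greedy incremental identity clustering in the CD-HIT
# family, at 97% nucleotide identity and, after longest-ORF translation, 95%
# amino-acid identity. Identity is matches / length of the shorter sequence
# under the optimal semi-global alignment (shorter aligned globally against
# the best-matching region of the longer), scored match +1, mismatch -1,
# gap -1 per position.

#' Pairwise sequence identity
#'
#' Aligns the shorter sequence globally against the best-matching region of
#' the longer (semi-global alignment) with unit match/mismatch/gap scoring
#' and returns matches / length of the shorter sequence — the identity
#' convention of greedy clustering tools whose denominators are the shorter
#' sequence. Among alignments of optimal score the one with the most matches
#' defines the identity, making the value deterministic.
#'
#' @param a,b Nonempty sequences (nucleotide or amino acid).
#' @return Identity fraction in \[0, 1\].
#' @export
pairwise_identity <- function(a, b) {
  stopifnot(nchar(a) >= 1L, nchar(b) >= 1L)
  if (nchar(a) <= nchar(b)) {
    pattern <- a; subject <- b
  } else {
    pattern <- b; subject <- a
  }
  .semiglobal_matches(pattern, subject)$matches / nchar(pattern)
}

# Positional k-mer containment prescreen bound. If identity(seq, rep) >= t
# then at most d = floor((1 - t) * Ls) positions of the shorter differ, and
# each difference can destroy at most k of its (Ls - k + 1) k-mers; so at
# least (Ls - k + 1) - d * k k-mer positions of the shorter must occur in the
# longer. Observing fewer proves identity < t, so skipping is admissible.
prescreen_pass <- function(seq_kmers_pos, rep_set, Ls, k, threshold) {
  n_pos <- length(seq_kmers_pos)
  if (n_pos == 0L) return(TRUE)           # k > Ls: bound vacuous, must align
  d <- floor((1 - threshold) * Ls + 1e-9)
  bound <- max(0L, n_pos - d * k)
  sum(seq_kmers_pos %in% rep_set) >= bound
}

kmer_positions <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  substring(seq, 1:(L - k + 1L), k:L)
}

#' Greedy incremental identity clustering
#'
#' Sequences are sorted by descending length (ties by id) and scanned once:
#' each sequence joins the first existing cluster whose representative it
#' matches at `threshold` identity or better, otherwise it founds a new
#' cluster. A positional k-mer containment prescreen (k = 8 nt / 3 aa) skips
#' only pairs provably below the threshold, so clustering is identical to
#' running the full alignment for every pair. Representatives are therefore
#' the longest member of each cluster (lexicographic id on ties).
#'
#' @param seqs Named character vector of sequences.
#' @param threshold Identity threshold in (0, 1].
#' @param level `"nucleotide"` or `"protein"` (sets the prescreen k-mer size).
#' @return List of clusters, each `list(representative_id, member_ids, level,
#'   threshold)`, in order of cluster creation.
#' @export
greedy_cluster <- function(seqs, threshold,
                           level = c("nucleotide", "protein")) {
  level <- match.arg(level)
  stopifnot(threshold > 0, threshold <= 1)
  if (length(seqs) == 0L) return(list())
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  k <- if (level == "nucleotide") 8L else 3L
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  reps <- character(0)
  rep_sets <- list()
  members <- list()
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    id <- names(seqs)[[i]]
    pos <- kmer_positions(s, k)
    placed <- FALSE
    for (ci in seq_along(reps)) {
      if (!prescreen_pass(pos, rep_sets[[ci]], nchar(s), k, threshold)) next
      ident <- pairwise_identity(s, seqs[[reps[ci]]])
      if (ident >= threshold - 1e-12) {
        members[[ci]] <- c(members[[ci]], id)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, id)
      rep_sets[[length(reps)]] <- unique(pos)
      members[[length(reps)]] <- id
    }
  }
  lapply(seq_along(reps), function(ci) {
    list(representative_id = reps[[ci]], member_ids = members[[ci]],
         level = level, threshold = threshold)
  })
}

#' Redundancy-reduction cascade
#'
#' Clusters host contigs at `nt_threshold` nucleotide identity, translates
#' the surviving representatives via their longest ORF, clusters the
#' peptides at `aa_threshold` identity, and returns the representatives that
#' survive both levels. Contigs without a qualifying ORF bypass protein
#' clustering and are retained — dropping them would silently shrink the
#' reference set.
#'
#' @param host_contigs Named character vector of host contigs.
#' @param nt_threshold Nucleotide identity threshold (default 0.97).
#' @param aa_threshold Amino-acid identity threshold (default 0.95).
#' @param min_aa Minimum ORF length in residues (default 30).
#' @return List with `reference` (surviving contig set), `map` (data.frame
#'   `contig_id`, `representative_id`, `merge_level` in \{"none",
#'   "nucleotide", "protein"\}), `clusters_nt`, `clusters_aa`, and `peptides`
#'   (named vector for representatives with an ORF).
#' @export
dedup_pipeline <- function(host_contigs, nt_threshold = 0.97,
                           aa_threshold = 0.95, min_aa = 30L) {
  clusters_nt <- greedy_cluster(host_contigs, nt_threshold, "nucleotide")
  nt_rep_of <- unlist(lapply(clusters_nt, function(cl)
    setNames(rep(cl$representative_id, length(cl$member_ids)), cl$member_ids)))
  nt_reps <- vapply(clusters_nt, `[[`, character(1), "representative_id")

  orfs <- lapply(host_contigs[nt_reps], longest_orf, min_aa = min_aa)
  has_orf <- !vapply(orfs, is.null, logical(1))
  peptides <- vapply(orfs[has_orf], `[[`, character(1), "peptide")
  names(peptides) <- nt_reps[has_orf]

  clusters_aa <- greedy_cluster(peptides, aa_threshold, "protein")
  aa_rep_of <- unlist(lapply(clusters_aa, function(cl)
    setNames(rep(cl$representative_id, length(cl$member_ids)), cl$member_ids)))

  final_rep <- function(id) {
    r <- nt_rep_of[[id]]
    if (!is.null(aa_rep_of) && r %in% names(aa_rep_of)) aa_rep_of[[r]] else r
  }
  map <- data.frame(
    contig_id = names(host_contigs),
    representative_id = vapply(names(host_contigs), final_rep, character(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  merged_nt <- names(host_contigs) != nt_rep_of[names(host_contigs)]
  merged_aa <- !merged_nt & names(host_contigs) != map$representative_id
  map$merge_level <- ifelse(merged_nt, "nucleotide",
                            ifelse(merged_aa, "protein", "none"))
  survivors <- unique(map$representative_id)
  list(
    reference = host_contigs[survivors],
    map = map,
    clusters_nt = clusters_nt,
    clusters_aa = clusters_aa,
    peptides = peptides
  )
}
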