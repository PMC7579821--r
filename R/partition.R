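# Taxonomic partitioning of holobiont contigs: classify each contig as host,
# symbiont, or other from alignment evidence, resolve contigs hitting both
# reference databases by the combined-database top hit, keep branch-count
# bookkeeping with conservation identities, and profile per-class GC content.

HIT_COLUMNS <- c("query_id", "subject_id", "percent_identity", "align_len",
                 "mismatches", "gap_opens", "qstart", "qend", "sstart",
                 "send", "evalue", "bitscore")

#' Parse a 12-column tabular alignment hit file
#'
#' Standard BLAST-style outfmt-6 table. Rows with e-value above `max_evalue`
#' are dropped (the boundary value is kept); malformed rows raise an error
#' with their line number. An optional 13th column is read as `description`.
#'
#' @param path Path to the tab-separated hit table.
#' @param db_label Database label attached to every row (e.g. "host").
#' @param max_evalue E-value cutoff (default 1e-3, inclusive).
#' @return data.frame of hits with a `subject_db` column.
#' @export
parse_hit_table <- function(path, db_label, max_evalue = 1e-3) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    hits <- as.data.frame(setNames(rep(list(character(0)), 12L), HIT_COLUMNS))
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    bad <- which(nf != 12L & nf != 13L)
    if (length(bad) > 0L) {
      stop("malformed hit table row at line ", bad[[1L]], " of '", path,
           "': expected 12 (or 13) tab-separated columns, got ", nf[bad[[1L]]])
    }
    has_desc <- any(nf == 13L)
    mat <- t(vapply(fields, function(f) f[1:12], character(12)))
    hits <- data.frame(
      query_id = mat[, 1], subject_id = mat[, 2],
      percent_identity = as.numeric(mat[, 3]),
      align_len = as.integer(mat[, 4]), mismatches = as.integer(mat[, 5]),
      gap_opens = as.integer(mat[, 6]), qstart = as.integer(mat[, 7]),
      qend = as.integer(mat[, 8]), sstart = as.integer(mat[, 9]),
      send = as.integer(mat[, 10]), evalue = as.numeric(mat[, 11]),
      bitscore = as.numeric(mat[, 12]),
      stringsAsFactors = FALSE
    )
    if (has_desc) {
      hits$description <- vapply(fields, function(f)
        if (length(f) >= 13L) f[13L] else NA_character_, character(1))
    }
    if (anyNA(hits$evalue) || anyNA(hits$bitscore)) {
      bad <- which(is.na(hits$evalue) | is.na(hits$bitscore))[1L]
      stop("malformed numeric field at line ", bad, " of '", path, "'")
    }
  }
  hits$subject_db <- rep(db_label, nrow(hits))
  hits[hits$evalue <= max_evalue, , drop = FALSE]
}

# Vectorised reverse complement of equal-width k-mer strings.
revcomp_kmers <- function(km, k) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", km)
  cols <- lapply(k:1, function(i) substring(comp, i, i))
  do.call(paste0, cols)
}

# Distinct k-mers of one sequence; canonical = lexicographic min of the k-mer
# and its reverse complement, so hits are strand-insensitive.
kmer_set <- function(seq, k, canonical = TRUE) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  km <- substring(seq, 1:(L - k + 1L), k:L)
  if (canonical) {
    km <- pmin(km, revcomp_kmers(km, k))
  }
  unique(km)
}

#' k-mer containment screen against reference databases
#'
#' A desk-scale alignment stand-in: for each contig and each database it
#' emits a pseudo-hit whenever the fraction of the contig's distinct
#' canonical k-mers found in the database ("containment") reaches
#' `min_containment`. The pseudo-bitscore is containment x contig length / k,
#' so longer and better-contained contigs score higher; the e-value slot is 0.
#'
#' @param contigs Named character vector of contigs.
#' @param host_refs,symbiont_refs Named character vectors of reference
#'   sequences (nonempty).
#' @param k k-mer size (default 21).
#' @param min_containment Minimum containment to emit a hit (default 0.2).
#' @return List with `host` and `symbiont` hit data.frames in the same shape
#'   as [parse_hit_table()] output.
#' @export
kmer_screen <- function(contigs, host_refs, symbiont_refs, k = 21L,
                        min_containment = 0.2) {
  stopifnot(length(host_refs) > 0L, length(symbiont_refs) > 0L)
  db_sets <- list(
    host = unique(unlist(lapply(host_refs, kmer_set, k = k), use.names = FALSE)),
    symbiont = unique(unlist(lapply(symbiont_refs, kmer_set, k = k),
                             use.names = FALSE))
  )
  contig_kmers <- lapply(contigs, kmer_set, k = k)
  out <- lapply(names(db_sets), function(db) {
    cont <- vapply(contig_kmers, function(km) {
      if (length(km) == 0L) return(0)
      mean(km %in% db_sets[[db]])
    }, numeric(1))
    emit <- which(cont >= min_containment)
    data.frame(
      query_id = names(contigs)[emit],
      subject_id = rep(paste0(db, "_db"), length(emit)),
      percent_identity = 100 * cont[emit],
      align_len = nchar(contigs)[emit],
      mismatches = 0L, gap_opens = 0L, qstart = 1L,
      qend = nchar(contigs)[emit], sstart = 1L, send = nchar(contigs)[emit],
      evalue = 0, bitscore = cont[emit] * nchar(contigs)[emit] / k,
      subject_db = rep(db, length(emit)),
      stringsAsFactors = FALSE, row.names = NULL
    )
  })
  names(out) <- names(db_sets)
  out
}

# Best hit per query within one database: highest bitscore, then lowest
# e-value, then longest alignment, then subject id (determinism).
best_per_query <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  ord <- order(hits$query_id, -hits$bitscore, hits$evalue, -hits$align_len,
               hits$subject_id)
  hits <- hits[ord, , drop = FALSE]
  hits[!duplicated(hits$query_id), , drop = FALSE]
}

#' Assign contigs to host, symbiont, or other
#'
#' Implements the exclusive/ambiguous partition flow: contigs hitting only
#' the host database are exclusive host, only the symbiont database exclusive
#' symbiont, neither are "other", and contigs hitting both are resolved by
#' the single top hit over the combined hit set. The top-hit criterion is
#' bitscore, with ties broken by lower e-value, then longer alignment, then
#' host before symbiont.
#'
#' @param contigs Named character vector of contigs (the full set).
#' @param host_hits,symbiont_hits Hit data.frames (already e-value filtered).
#' @return List with `assignments` (one row per contig: `contig_id`, `call`,
#'   `branch`, `best_host_bitscore`, `best_symbiont_bitscore`) and `ledger`
#'   (see [ledger_totals()]).
#' @export
assign_contigs <- function(contigs, host_hits, symbiont_hits) {
  ids <- names(contigs)
  stray <- setdiff(unique(c(host_hits$query_id, symbiont_hits$query_id)), ids)
  if (length(stray) > 0L) {
    stop("hit table references contig(s) absent from the contig set: ",
         paste(head(stray, 5L), collapse = ", "))
  }
  bh <- best_per_query(host_hits)
  bs <- best_per_query(symbiont_hits)
  hb <- setNames(bh$bitscore, bh$query_id)[ids]
  he <- setNames(bh$evalue, bh$query_id)[ids]
  hl <- setNames(as.numeric(bh$align_len), bh$query_id)[ids]
  sb <- setNames(bs$bitscore, bs$query_id)[ids]
  se <- setNames(bs$evalue, bs$query_id)[ids]
  sl <- setNames(as.numeric(bs$align_len), bs$query_id)[ids]
  has_h <- !is.na(hb)
  has_s <- !is.na(sb)
  call <- branch <- character(length(ids))
  call[!has_h & !has_s] <- "other"
  branch[!has_h & !has_s] <- "no_hit"
  call[has_h & !has_s] <- "host"
  branch[has_h & !has_s] <- "exclusive_host"
  call[!has_h & has_s] <- "symbiont"
  branch[!has_h & has_s] <- "exclusive_symbiont"
  both <- has_h & has_s
  if (any(both)) {
    # top hit over the combined set; host wins full ties (documented)
    host_top <- (hb[both] > sb[both]) |
      (hb[both] == sb[both] & he[both] < se[both]) |
      (hb[both] == sb[both] & he[both] == se[both] & hl[both] >= sl[both])
    call[both] <- ifelse(host_top, "host", "symbiont")
    branch[both] <- ifelse(host_top, "ambiguous_resolved_host",
                           "ambiguous_resolved_symbiont")
  }
  assignments <- data.frame(
    contig_id = ids, call = call, branch = branch,
    best_host_bitscore = unname(hb), best_symbiont_bitscore = unname(sb),
    stringsAsFactors = FALSE, row.names = NULL
  )
  ledger <- ledger_totals(
    n_exclusive_host = sum(branch == "exclusive_host"),
    n_exclusive_symbiont = sum(branch == "exclusive_symbiont"),
    n_ambiguous_to_host = sum(branch == "ambiguous_resolved_host"),
    n_ambiguous_to_symbiont = sum(branch == "ambiguous_resolved_symbiont"),
    n_no_hit = sum(branch == "no_hit")
  )
  list(assignments = assignments, ledger = ledger)
}

#' Partition ledger with conservation identities
#'
#' Builds the branch-count ledger from the per-branch counts and derives the
#' totals. When `n_ambiguous` or `n_total` are supplied they are checked
#' against the derived values; any violated identity is reported.
#'
#' @param n_exclusive_host,n_exclusive_symbiont Counts of contigs hitting one
#'   database only.
#' @param n_ambiguous_to_host,n_ambiguous_to_symbiont Resolved counts for
#'   contigs hitting both databases.
#' @param n_no_hit Contigs hitting neither database.
#' @param n_ambiguous,n_total Optional cross-check totals.
#' @return List with all branch counts plus `n_ambiguous`, `n_total`,
#'   `n_host_final`, `n_symbiont_final`.
#' @export
ledger_totals <- function(n_exclusive_host, n_exclusive_symbiont,
                          n_ambiguous_to_host, n_ambiguous_to_symbiont,
                          n_no_hit = 0L, n_ambiguous = NULL, n_total = NULL) {
  counts <- c(n_exclusive_host, n_exclusive_symbiont, n_ambiguous_to_host,
              n_ambiguous_to_symbiont, n_no_hit)
  if (any(counts < 0)) stop("ledger counts must be nonnegative")
  amb <- n_ambiguous_to_host + n_ambiguous_to_symbiont
  tot <- n_exclusive_host + n_exclusive_symbiont + amb + n_no_hit
  fails <- character(0)
  if (!is.null(n_ambiguous) && n_ambiguous != amb) {
    fails <- c(fails, sprintf(
      "n_ambiguous_to_host + n_ambiguous_to_symbiont = %d != n_ambiguous = %d",
      amb, n_ambiguous))
  }
  if (!is.null(n_total) && n_total != tot) {
    fails <- c(fails, sprintf("sum of branches = %d != n_total = %d", tot, n_total))
  }
  if (length(fails) > 0L) {
    stop("ledger identities violated: ", paste(fails, collapse = "; "))
  }
  list(
    n_total = tot,
    n_exclusive_host = n_exclusive_host,
    n_exclusive_symbiont = n_exclusive_symbiont,
    n_ambiguous = amb,
    n_ambiguous_to_host = n_ambiguous_to_host,
    n_ambiguous_to_symbiont = n_ambiguous_to_symbiont,
    n_no_hit = n_no_hit,
    n_host_final = n_exclusive_host + n_ambiguous_to_host,
    n_symbiont_final = n_exclusive_symbiont + n_ambiguous_to_symbiont
  )
}

#' Per-class GC profiles
#'
#' Histograms GC percentage at 1-point bins for each assignment class plus
#' "all". The mode is the centre of the maximal-count bin (lowest bin wins
#' ties); empty classes get an empty histogram and `NA` mode.
#'
#' @param contigs Named character vector of contigs.
#' @param assignments Assignment data.frame from [assign_contigs()].
#' @return Named list of profiles, each with `class`, `breaks`, `counts`,
#'   `mode_percent`, `n`.
#' @export
gc_profile <- function(contigs, assignments) {
  stopifnot(setequal(names(contigs), assignments$contig_id))
  gc_pct <- 100 * gc_content(contigs)
  cls <- setNames(assignments$call, assignments$contig_id)[names(contigs)]
  breaks <- 0:100
  centers <- breaks[-1] - 0.5
  profile_of <- function(label, values) {
    if (length(values) == 0L) {
      return(list(class = label, breaks = breaks, counts = integer(100),
                  mode_percent = NA_real_, n = 0L))
    }
    counts <- tabulate(pmin(pmax(ceiling(values), 1L), 100L), nbins = 100L)
    list(class = label, breaks = breaks, counts = counts,
         mode_percent = centers[which.max(counts)], n = length(values))
  }
  out <- list(all = profile_of("all", gc_pct))
  for (label in c("host", "symbiont", "other")) {
    out[[label]] <- profile_of(label, gc_pct[cls == label])
  }
  out
}
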