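# Sequence-level substrate: FASTA I/O, GC content, assembly statistics and
# six-frame ORF extraction. Contig sets are named uppercase character vectors;
# Biostrings does the heavy lifting for I/O and letter counting.

IUPAC_NT <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
              "B", "D", "H", "V", "N")

#' Read a FASTA file into a contig set
#'
#' Sequences are normalised to uppercase and returned as a named character
#' vector (the package's contig-set representation). Duplicate ids are
#' rejected, naming the first offender; an empty file yields an empty set
#' with a warning.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(set) == 0L) {
    warning("FASTA file '", path, "' contains no records")
    return(setNames(character(0), character(0)))
  }
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate sequence id in '", path, "': ", dup[[1L]])
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  seqs
}

#' Write a contig set to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width in bases.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(length(seqs) == 0L || !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' GC content of nucleotide sequences
#'
#' Fraction (G + C) / (A + C + G + T). IUPAC ambiguity codes (including N)
#' are excluded from both numerator and denominator, so N-rich contigs do
#' not bias GC histograms. A sequence with no unambiguous base yields `NaN`
#' with a warning.
#'
#' @param seqs Character vector of nucleotide sequences (vectorised).
#' @return Numeric vector of GC fractions in \[0, 1\].
#' @export
gc_content <- function(seqs) {
  stopifnot(length(seqs) >= 1L, all(nchar(seqs) >= 1L))
  set <- Biostrings::BStringSet(toupper(seqs))
  lf <- Biostrings::letterFrequency(set, letters = c("A", "C", "G", "T"))
  denom <- rowSums(lf)
  if (any(denom == 0)) {
    warning("sequence(s) with zero unambiguous bases: GC content undefined (NaN)")
  }
  out <- (lf[, "G"] + lf[, "C"]) / denom
  names(out) <- names(seqs)
  out
}

#' N50 of a set of sequence lengths
#'
#' The length L such that sequences of length >= L cover at least half of the
#' total bases, computed by descending-length accumulation.
#'
#' @param lengths Integer vector of sequence lengths.
#' @return The N50 length (one of the input lengths).
#' @export
n50 <- function(lengths) {
  stopifnot(length(lengths) >= 1L, all(lengths >= 1L))
  len <- sort(as.numeric(lengths), decreasing = TRUE)
  csum <- cumsum(len)
  len[which(csum >= sum(len) / 2)[1L]]
}

#' Assembly summary statistics
#'
#' Computes the familiar assembly table row: number of sequences, total bases,
#' min/mean/max length, N50, and pooled GC percentage over unambiguous bases.
#'
#' @param seqs Named character vector of sequences (nonempty).
#' @return List with elements `n_seqs`, `total_bp`, `min_len`, `mean_len`,
#'   `max_len`, `n50`, `gc_percent`.
#' @export
assembly_stats <- function(seqs) {
  if (length(seqs) == 0L) stop("assembly_stats: empty sequence set")
  len <- nchar(seqs)
  set <- Biostrings::BStringSet(toupper(seqs))
  lf <- colSums(Biostrings::letterFrequency(set, letters = c("A", "C", "G", "T")))
  gc <- 100 * (lf[["G"]] + lf[["C"]]) / sum(lf)
  list(
    n_seqs = length(seqs),
    total_bp = sum(as.numeric(len)),
    min_len = min(len),
    mean_len = mean(len),
    max_len = max(len),
    n50 = n50(len),
    gc_percent = gc
  )
}

#' Reverse complement
#'
#' @param seq Single nucleotide string (IUPAC codes allowed).
#' @return Reverse-complemented string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Translate a vector of codons to amino acids under the standard code.
# Codons containing anything but A/C/G/T become "X".
translate_codons <- function(codons) {
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  aa
}

#' Longest open reading frame over six frames
#'
#' Scans all six reading frames for ATG-to-stop open reading frames under the
#' standard genetic code and returns the longest. The stop codon is required
#' and excluded from the peptide but included in the nucleotide span. Ties on
#' peptide length are broken by frame order +1, +2, +3, -1, -2, -3, then by
#' the leftmost start within the frame's scan orientation. Coordinates are
#' 0-based, half-open, on the forward strand.
#'
#' @param seq Single nucleotide string.
#' @param min_aa Minimum peptide length (default 30 aa).
#' @param require_start If `FALSE`, stop-to-stop fragments (clipped to the
#'   first residue after the previous stop) qualify without an ATG.
#' @return List with `frame`, `nt_start`, `nt_end`, `peptide`, or `NULL` when
#'   no qualifying ORF exists.
#' @export
longest_orf <- function(seq, min_aa = 30L, require_start = TRUE) {
  seq <- toupper(seq)
  L <- nchar(seq)
  strands <- list(fwd = seq, rev = if (L >= 3L) revcomp(seq) else "")
  best <- NULL
  for (si in 1:2) {
    s <- strands[[si]]
    for (off in 0:2) {
      if (nchar(s) - off < 3L) next
      starts <- seq.int(off + 1L, nchar(s) - 2L, by = 3L)
      codons <- substring(s, starts, starts + 2L)
      aa <- translate_codons(codons)
      stops <- which(aa == "*")
      if (length(stops) == 0L) next
      seg_begin <- 1L
      for (st in stops) {
        if (st > seg_begin) {
          idx <- seg_begin:(st - 1L)
          first_m <- if (require_start) idx[aa[idx] == "M"][1L] else idx[1L]
          if (!is.na(first_m)) {
            pep_len <- st - first_m
            if (pep_len >= min_aa) {
              frame <- if (si == 1L) off + 1L else -(off + 1L)
              # codon positions on the scanned strand, stop codon included
              a <- starts[first_m]
              b <- starts[st] + 2L
              if (si == 1L) {
                nt_start <- a - 1L; nt_end <- b
              } else {
                nt_start <- L - b; nt_end <- L - a + 1L
              }
              cand <- list(frame = frame, nt_start = nt_start, nt_end = nt_end,
                           peptide = paste(aa[first_m:(st - 1L)], collapse = ""))
              if (is.null(best) || pep_len > nchar(best$peptide)) best <- cand
            }
          }
        }
        seg_begin <- st + 1L
      }
    }
  }
  best
}
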