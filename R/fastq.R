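# Read cleaning: phred+33 FASTQ in, quality-trimmed and filtered FASTQ out.
# Filters mirror common Illumina pre-processing: 3' quality trimming at Q20,
# removal of reads with > 5% N, and a minimum post-trim length of 25 bp.

#' Read a phred+33 FASTQ file
#'
#' Returns a list with `id`, `seq` and `qual` character vectors. Records whose
#' sequence and quality strings differ in length are rejected with the record
#' id, as are structurally malformed files.
#'
#' @param path Path to an (optionally gzipped) FASTQ file.
#' @return List of parallel character vectors `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ '", path, "': line count not a multiple of 4")
  }
  n <- length(lines) %/% 4L
  if (n == 0L) {
    return(list(id = character(0), seq = character(0), qual = character(0)))
  }
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seq <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  if (!all(startsWith(hdr, "@")) || !all(startsWith(plus, "+"))) {
    bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+"))[1L]
    stop("malformed FASTQ record ", bad, " in '", path, "'")
  }
  id <- sub("\\s.*$", "", substring(hdr, 2L))
  mismatch <- which(nchar(seq) != nchar(qual))
  if (length(mismatch) > 0L) {
    stop("FASTQ record '", id[mismatch[1L]],
         "': sequence and quality lengths differ")
  }
  list(id = id, seq = toupper(seq), qual = qual)
}

#' Write phred+33 FASTQ
#'
#' @param reads List with `id`, `seq`, `qual` (as from [read_fastq()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(length(reads$id) == length(reads$seq),
            length(reads$id) == length(reads$qual))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(reads$id) > 0L) {
    out <- rbind(paste0("@", reads$id), reads$seq, "+", reads$qual)
    writeLines(as.vector(out), con)
  }
  invisible(path)
}

# Decode a phred+33 quality string to integer scores.
phred33 <- function(qual) {
  as.integer(charToRaw(qual)) - 33L
}

# 3' trim: drop trailing bases while the mean quality of the terminal window
# (4 bases, fewer near the start) stays below min_q. Returns the kept length.
trim3_length <- function(q, min_q, window = 4L) {
  len <- length(q)
  while (len > 0L) {
    w <- q[max(1L, len - window + 1L):len]
    if (mean(w) >= min_q) break
    len <- len - 1L
  }
  len
}

#' Clean sequencing reads
#'
#' Quality-based 3' trimming followed by N-content and length filters:
#' trailing bases are trimmed while the mean quality of the terminal 4-base
#' window is below `min_q` (default Q20); reads whose N fraction exceeds
#' `max_n_frac` (strictly greater than 5\% by default) or whose post-trim
#' length falls below `min_len` (25 bp) are removed. With
#' `mode = "mean_read"` the Q20 criterion is instead applied to the whole
#' read's mean quality and no trimming is done.
#'
#' @param reads A FASTQ path or a list as returned by [read_fastq()].
#' @param min_q Minimum phred quality (default 20).
#' @param max_n_frac Maximum tolerated N fraction (default 0.05; reads
#'   strictly above are removed).
#' @param min_len Minimum post-trim read length in bp (default 25).
#' @param mode `"trim"` (default, per-base 3' trimming) or `"mean_read"`.
#' @param out Optional path; when given, surviving reads are written there.
#' @return List with `reads` (the surviving records) and `report` (counts
#'   in/out and per-filter removals plus bases trimmed).
#' @export
clean_reads <- function(reads, min_q = 20L, max_n_frac = 0.05, min_len = 25L,
                        mode = c("trim", "mean_read"), out = NULL) {
  mode <- match.arg(mode)
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  n_in <- length(reads$id)
  quals <- lapply(reads$qual, phred33)
  if (mode == "trim") {
    keep_len <- vapply(quals, trim3_length, integer(1), min_q = min_q)
    trimmed_seq <- substr(reads$seq, 1L, keep_len)
    trimmed_qual <- substr(reads$qual, 1L, keep_len)
    bases_trimmed <- sum(nchar(reads$seq) - keep_len)
    pass_q <- rep(TRUE, n_in)
  } else {
    keep_len <- nchar(reads$seq)
    trimmed_seq <- reads$seq
    trimmed_qual <- reads$qual
    bases_trimmed <- 0L
    pass_q <- vapply(quals, function(q) mean(q) >= min_q, logical(1))
  }
  n_count <- vapply(strsplit(trimmed_seq, ""), function(x) sum(x == "N"),
                    integer(1))
  n_frac <- ifelse(keep_len > 0L, n_count / keep_len, 0)
  pass_n <- n_frac <= max_n_frac
  pass_len <- keep_len >= min_len
  keep <- pass_q & pass_n & pass_len
  surv <- list(id = reads$id[keep], seq = trimmed_seq[keep],
               qual = trimmed_qual[keep])
  report <- list(
    n_in = n_in,
    n_out = sum(keep),
    n_removed_quality = sum(!pass_q),
    n_removed_n = sum(pass_q & !pass_n),
    n_removed_length = sum(pass_q & pass_n & !pass_len),
    bases_trimmed = bases_trimmed
  )
  if (!is.null(out)) write_fastq(surv, out)
  list(reads = surv, report = report)
}
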