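# Independent oracles used across the suite. Each is a deliberately naive
# implementation (enumeration / textbook recursion) kept separate from the
# package's own code paths.

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

random_peptide <- function(n) {
  aas <- setdiff(unique(unname(Biostrings::GENETIC_CODE)), "*")
  paste(sample(aas, n, replace = TRUE), collapse = "")
}

# N50 by enumeration over every candidate threshold.
oracle_n50 <- function(lengths) {
  cands <- sort(unique(lengths), decreasing = TRUE)
  for (L in cands) {
    if (sum(lengths[lengths >= L]) >= sum(lengths) / 2) return(L)
  }
  min(lengths)
}

# Semi-global identity by a plain O(nm) R dynamic programme with the same
# objective as the package (max score, then max matches; match +1, mismatch
# -1, gap -1; subject prefix/suffix free). Matrix-based, loop-heavy on
# purpose; only for tiny sequences.
oracle_identity <- function(a, b) {
  if (nchar(a) <= nchar(b)) { p <- a; s <- b } else { p <- b; s <- a }
  pc <- strsplit(p, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  m <- length(pc); n <- length(sc)
  S <- matrix(0, m + 1, n + 1)
  M <- matrix(0, m + 1, n + 1)
  S[, 1] <- -(0:m)
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      hit <- pc[i - 1] == sc[j - 1]
      cand_s <- c(S[i - 1, j - 1] + ifelse(hit, 1, -1),
                  S[i - 1, j] - 1, S[i, j - 1] - 1)
      cand_m <- c(M[i - 1, j - 1] + as.integer(hit), M[i - 1, j], M[i, j - 1])
      best <- max(cand_s)
      S[i, j] <- best
      M[i, j] <- max(cand_m[cand_s == best])
    }
  }
  best <- max(S[m + 1, ])
  max(M[m + 1, S[m + 1, ] == best]) / m
}

# Exact upper hypergeometric tail by term-wise enumeration with choose().
oracle_hyper_tail <- function(k, n, K, N) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Benjamini-Hochberg step-up by direct definition:
# q_(i) = min_{j >= i} p_(j) * n / j, in the original order.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- pmin(rev(cummin(rev(p[o] * n / seq_len(n)))), 1)
  q <- numeric(n)
  q[o] <- q_sorted
  q
}

# Canonical k-mer set by direct construction (strand-min of each window).
oracle_kmer_set <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  km <- substring(seq, 1:(L - k + 1), k:L)
  rc <- vapply(km, function(x)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x))),
    character(1), USE.NAMES = FALSE)
  unique(pmin(km, rc))
}

# Six-frame longest-ORF scan by brute force over every ATG position: for
# each strand/frame/start, extend codon by codon to the first stop.
oracle_longest_orf <- function(seq, min_aa = 1L) {
  code <- Biostrings::GENETIC_CODE
  L <- nchar(seq)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  best <- NULL
  frames <- list(c(1, 1), c(1, 2), c(1, 3), c(-1, 1), c(-1, 2), c(-1, 3))
  for (fr in frames) {
    s <- if (fr[1] == 1) seq else rc
    for (start in seq(fr[2], L - 2)) {
      if ((start - fr[2]) %% 3 != 0) next
      if (substr(s, start, start + 2) != "ATG") next
      pep <- ""
      pos <- start
      repeat {
        if (pos + 2 > L) { pep <- NULL; break }
        cod <- substr(s, pos, pos + 2)
        aa <- code[cod]
        if (is.na(aa)) aa <- "X"
        if (aa == "*") break
        pep <- paste0(pep, aa)
        pos <- pos + 3
      }
      if (is.null(pep) || nchar(pep) < min_aa) next
      if (is.null(best) || nchar(pep) > nchar(best$peptide)) {
        a <- start; b <- pos + 2
        best <- list(
          frame = fr[1] * fr[2],
          nt_start = if (fr[1] == 1) a - 1 else L - b,
          nt_end = if (fr[1] == 1) b else L - a + 1,
          peptide = pep
        )
      }
    }
  }
  best
}

# Greedy clustering without any prescreen, using the oracle identity; for
# verifying that the package's k-mer prescreen is admissible.
oracle_greedy_cluster <- function(seqs, threshold) {
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  reps <- character(0)
  members <- list()
  for (i in seq_along(seqs)) {
    id <- names(seqs)[[i]]
    placed <- FALSE
    for (ci in seq_along(reps)) {
      if (oracle_identity(seqs[[i]], seqs[[reps[ci]]]) >= threshold - 1e-12) {
        members[[ci]] <- c(members[[ci]], id)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, id)
      members[[length(reps)]] <- id
    }
  }
  lapply(seq_along(reps), function(ci)
    list(representative_id = reps[[ci]], member_ids = members[[ci]]))
}

# Encode a peptide as DNA using a fixed codon per amino acid.
encode_peptide <- function(pep, third_base = "T") {
  code <- Biostrings::GENETIC_CODE
  pick <- function(aa) {
    cands <- names(code)[code == aa]
    pref <- cands[substr(cands, 3, 3) == third_base]
    if (length(pref) > 0) pref[1] else cands[1]
  }
  paste(vapply(strsplit(pep, "")[[1]], pick, character(1)), collapse = "")
}
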