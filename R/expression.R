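# Count-matrix stage: TMM/CPM normalisation, hierarchical-clustering outlier
# detection, per-gene one-way ANOVA across gametogenic phases with
# Benjamini-Hochberg adjustment, phase-specific and fold-change-filtered gene
# sets, and row Z-scores for heatmap export.

PHASE_LEVELS <- c("early", "middle", "late", "mature")

#' Construct an annotated count matrix
#'
#' Bundles a nonnegative integer gene x sample count matrix with per-sample
#' metadata (sex, ordered gametogenic phase, colony). Library sizes are the
#' column sums.
#'
#' @param counts Integer matrix, genes in rows, samples in columns (both
#'   dimnames required).
#' @param meta data.frame with columns `sample`, `sex` ("F"/"M"), `phase`
#'   (one of early/middle/late/mature), `colony`; one row per column of
#'   `counts`.
#' @return Object of class `holo_counts`: list with `counts`, `samples`,
#'   `lib_size`.
#' @export
count_matrix <- function(counts, meta) {
  counts <- as.matrix(counts)
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)))
  if (any(counts < 0)) stop("count matrix contains negative entries")
  stopifnot(all(c("sample", "sex", "phase", "colony") %in% names(meta)))
  missing <- setdiff(colnames(counts), meta$sample)
  if (length(missing) > 0L) {
    stop("metadata missing for sample(s): ", paste(missing, collapse = ", "))
  }
  meta <- meta[match(colnames(counts), meta$sample), , drop = FALSE]
  stopifnot(all(meta$phase %in% PHASE_LEVELS), all(meta$sex %in% c("F", "M")))
  meta$phase <- factor(meta$phase, levels = PHASE_LEVELS)
  structure(list(counts = counts, samples = meta,
                 lib_size = colSums(counts)),
            class = "holo_counts")
}

#' @export
print.holo_counts <- function(x, ...) {
  cat("holo_counts:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  cat("  sexes:", paste(names(table(x$samples$sex)), table(x$samples$sex),
                        collapse = ", "), "\n")
  invisible(x)
}

#' TMM normalisation factors
#'
#' Trimmed mean of M-values: per sample versus a reference column,
#' library-size-adjusted log2 ratios (M) and average log abundances (A) are
#' computed over genes positive in both, doubly trimmed (30\% on M, 5\% on A
#' by default), and combined by precision weighting; the factor is 2 to that
#' mean. Factors are rescaled to geometric mean 1. The reference is the
#' sample whose upper-quartile count fraction is closest to the mean
#' upper-quartile.
#'
#' @param counts Count matrix or `holo_counts` object (>= 2 samples).
#' @param ref_sample Optional reference column name or index.
#' @param m_trim Two-sided trim fraction on M (default 0.30).
#' @param a_trim Two-sided trim fraction on A (default 0.05).
#' @return Named numeric vector of normalisation factors.
#' @export
tmm_factors <- function(counts, ref_sample = NULL, m_trim = 0.30,
                        a_trim = 0.05) {
  if (inherits(counts, "holo_counts")) counts <- counts$counts
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("TMM requires at least 2 samples")
  lib <- colSums(counts)
  zero <- colnames(counts)[lib == 0]
  if (length(zero) > 0L) {
    stop("sample(s) with all-zero counts: ", paste(zero, collapse = ", "))
  }
  if (is.null(ref_sample)) {
    f75 <- apply(counts, 2L, function(x) quantile(x, 0.75)) / lib
    ref <- which.min(abs(f75 - mean(f75)))
  } else {
    ref <- if (is.character(ref_sample)) match(ref_sample, colnames(counts))
           else as.integer(ref_sample)
    if (is.na(ref)) stop("unknown reference sample")
  }
  yr <- counts[, ref]
  Nr <- lib[ref]
  one_factor <- function(y, N) {
    pos <- y > 0 & yr > 0
    if (!any(pos)) return(1)
    M <- log2((y[pos] / N) / (yr[pos] / Nr))
    A <- 0.5 * log2((y[pos] / N) * (yr[pos] / Nr))
    v <- (N - y[pos]) / (N * y[pos]) + (Nr - yr[pos]) / (Nr * yr[pos])
    fin <- is.finite(M) & is.finite(A)
    M <- M[fin]; A <- A[fin]; v <- v[fin]
    ng <- length(M)
    if (ng == 0L) return(1)
    loM <- floor(ng * m_trim) + 1; hiM <- ng + 1 - loM
    loA <- floor(ng * a_trim) + 1; hiA <- ng + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    if (!any(keep)) return(1)
    f <- sum(M[keep] / v[keep]) / sum(1 / v[keep])
    if (!is.finite(f)) f <- 0
    2^f
  }
  f <- vapply(seq_len(ncol(counts)), function(j) one_factor(counts[, j], lib[j]),
              numeric(1))
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(counts))
}

#' Counts per million
#'
#' cpm\[g, s\] = 1e6 * (count + pseudo) / (library size * factor). With unit
#' factors and zero pseudo-count every column sums to one million.
#'
#' @param counts Count matrix or `holo_counts` object.
#' @param factors Positive normalisation factors (default all 1).
#' @param pseudo Pseudo-count added to each entry (default 0).
#' @return Numeric matrix of CPM values.
#' @export
cpm_matrix <- function(counts, factors = NULL, pseudo = 0) {
  if (inherits(counts, "holo_counts")) counts <- counts$counts
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  if (is.null(factors)) factors <- rep(1, ncol(counts))
  stopifnot(all(factors > 0), length(factors) == ncol(counts))
  sweep(counts + pseudo, 2L, lib * factors, "/") * 1e6
}

#' Detect outlier samples by hierarchical clustering
#'
#' Average-linkage clustering on 1 - Pearson correlation of log2(CPM + 1);
#' a sample is flagged when the height at which it first merges into the tree
#' exceeds median + `n_mad` x MAD of all samples' merge heights — a
#' reproducible stand-in for the visual dendrogram call used when removing
#' aberrant gonad libraries.
#'
#' @param cpm CPM matrix (genes x samples, >= 4 samples).
#' @param n_mad Multiplier on the MAD (default 3).
#' @return List with `tree` (hclust), `heights` (per-sample merge height),
#'   `threshold`, `flagged` (character vector of sample ids).
#' @export
detect_outliers <- function(cpm, n_mad = 3) {
  if (ncol(cpm) < 4L) stop("outlier detection requires at least 4 samples")
  lg <- log2(cpm + 1)
  d <- as.dist(1 - cor(lg, method = "pearson"))
  tree <- hclust(d, method = "average")
  n <- ncol(cpm)
  merge_height <- numeric(n)
  for (i in seq_len(nrow(tree$merge))) {
    for (leaf in tree$merge[i, ]) {
      if (leaf < 0) merge_height[-leaf] <- tree$height[i]
    }
  }
  names(merge_height) <- colnames(cpm)
  thr <- median(merge_height) + n_mad * mad(merge_height)
  list(tree = tree, heights = merge_height, threshold = thr,
       flagged = names(merge_height)[merge_height > thr])
}

#' Across-phase differential expression by one-way ANOVA
#'
#' Per gene, a fixed-effects one-way analysis of variance of log2(CPM + 1)
#' across gametogenic phases, with Benjamini-Hochberg adjustment across all
#' tested genes. Genes with zero variance everywhere get p = 1. Per-phase
#' mean CPM (untransformed) is reported for downstream fold-change filters.
#'
#' @param cpm CPM matrix (genes x samples).
#' @param phases Factor or character vector of phase labels per sample; every
#'   represented phase needs >= 2 replicates and >= 2 phases are required.
#' @param alpha FDR threshold for the `is_de` flag (default 0.05).
#' @return data.frame: `gene`, `mean_cpm_<phase>` columns, `statistic`, `p`,
#'   `q`, `is_de`; phase levels kept as attribute `"phases"`.
#' @export
de_test <- function(cpm, phases, alpha = 0.05) {
  if (!is.factor(phases)) {
    lev <- if (all(phases %in% PHASE_LEVELS)) {
      intersect(PHASE_LEVELS, unique(phases))
    } else {
      unique(phases)
    }
    phases <- factor(phases, levels = lev)
  }
  phases <- droplevels(phases)
  stopifnot(length(phases) == ncol(cpm))
  tab <- table(phases)
  if (length(tab) < 2L) stop("differential testing requires >= 2 phases")
  if (any(tab < 2L)) {
    stop("phase(s) with fewer than 2 replicates: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  }
  y <- log2(cpm + 1)
  n <- ncol(y)
  k <- length(levels(phases))
  group <- lapply(levels(phases), function(p) which(phases == p))
  gm <- vapply(group, function(j) rowMeans(y[, j, drop = FALSE]), numeric(nrow(y)))
  sizes <- vapply(group, length, integer(1))
  grand <- rowMeans(y)
  ssb <- as.vector(gm^2 %*% sizes) - n * grand^2
  sst <- rowSums(y^2) - n * grand^2
  ssw <- pmax(sst - ssb, 0)
  ssb <- pmax(ssb, 0)
  fstat <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- pf(fstat, k - 1, n - k, lower.tail = FALSE)
  # degenerate genes: no within- or between-phase variation at all
  flat <- ssw < 1e-12 & ssb < 1e-12
  p[flat] <- 1
  fstat[flat] <- 0
  sep <- ssw < 1e-12 & ssb >= 1e-12   # perfectly separated means
  p[sep] <- 0
  fstat[sep] <- Inf
  q <- p.adjust(p, method = "BH")
  mean_cpm <- vapply(group, function(j) rowMeans(cpm[, j, drop = FALSE]),
                     numeric(nrow(cpm)))
  out <- data.frame(gene = rownames(cpm), stringsAsFactors = FALSE)
  for (i in seq_along(levels(phases))) {
    out[[paste0("mean_cpm_", levels(phases)[i])]] <- mean_cpm[, i]
  }
  out$statistic <- fstat
  out$p <- p
  out$q <- q
  out$is_de <- q < alpha
  attr(out, "phases") <- levels(phases)
  rownames(out) <- NULL
  out
}

#' Pairwise log2 fold change between phase means
#'
#' log2((mean_a + 1) / (mean_b + 1)): a pseudo-CPM of 1 is added to both
#' means so fold changes stay finite on silent phases.
#'
#' @param mean_a,mean_b Mean CPM vectors.
#' @return log2 fold-change vector.
#' @export
lfc_means <- function(mean_a, mean_b) {
  log2((mean_a + 1) / (mean_b + 1))
}

#' Phase-specific upregulated gene sets
#'
#' A gene is specific to phase p when it is differentially expressed and its
#' mean CPM in p strictly exceeds its mean CPM in every other phase (ties
#' disqualify). It additionally passes the high-fold-change filter when the
#' minimum over other phases of log2((mean_p + 1)/(mean_q + 1)) strictly
#' exceeds `high_fc_threshold` (5 for ovaries, 8 for testes in the reference
#' analysis).
#'
#' @param de DE table from [de_test()].
#' @param high_fc_threshold log2 fold-change threshold.
#' @return Named list per phase with `specific` and `high_fc` gene id
#'   vectors; the threshold is attached as attribute.
#' @export
phase_specific_sets <- function(de, high_fc_threshold) {
  phases <- attr(de, "phases")
  means <- as.matrix(de[, paste0("mean_cpm_", phases), drop = FALSE])
  out <- list()
  for (i in seq_along(phases)) {
    others <- means[, -i, drop = FALSE]
    strict_max <- de$is_de & apply(means[, i] > others, 1L, all)
    min_lfc <- apply(lfc_means(means[, i], others), 1L, min)
    out[[phases[i]]] <- list(
      specific = de$gene[strict_max],
      high_fc = de$gene[strict_max & min_lfc > high_fc_threshold]
    )
  }
  attr(out, "high_fc_threshold") <- high_fc_threshold
  out
}

#' Overlap of differentially expressed gene sets between sexes
#'
#' @param de_female,de_male DE tables from [de_test()] over the same gene
#'   universe.
#' @return List with id vectors `female_only`, `male_only`, `shared` and the
#'   corresponding `counts`.
#' @export
overlap_sets <- function(de_female, de_male) {
  if (!setequal(de_female$gene, de_male$gene)) {
    stop("DE tables are not on the same gene universe")
  }
  f <- de_female$gene[de_female$is_de]
  m <- de_male$gene[de_male$is_de]
  shared <- intersect(f, m)
  list(
    female_only = setdiff(f, m), male_only = setdiff(m, f), shared = shared,
    counts = c(female = length(f), male = length(m), shared = length(shared))
  )
}

#' Row Z-scores for heatmap export
#'
#' Per gene: (x - row mean) / row sd with the population (1/n) standard
#' deviation; constant rows become all zeros.
#'
#' @param mat Numeric matrix with >= 2 columns.
#' @return Matrix of the same shape.
#' @export
zscore_rows <- function(mat) {
  stopifnot(ncol(mat) >= 2L)
  m <- rowMeans(mat)
  s <- sqrt(rowMeans((mat - m)^2))
  z <- (mat - m) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  z
}
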