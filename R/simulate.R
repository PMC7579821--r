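# Synthetic holobiont generator. Produces every input the pipeline consumes,
# with ground truth: host/symbiont reference sequences at their class-typical
# GC compositions (41.5% vs 50.6%), contigs as divergent reference
# subsequences plus chimeras, near-duplicate haplotype groups, "other"
# contigs, negative-binomial counts over a 2-sex x 4-phase x 3-colony design
# with planted phase-specific effects and whole-sample outliers, and term
# maps with planted enriched terms.

#' Simulation configuration
#'
#' Defaults encode the study conditions the analysis is designed for: 500
#' contigs over host (GC 41.5\%), symbiont (GC 50.6\%), chimeric and foreign
#' origins with 3\% divergence from their references; near-duplicate groups
#' at ~99\% within-group identity; 2000 genes over a 2-sex x 4-phase x
#' 3-colony design with negative-binomial dispersion 0.1, one permuted-profile
#' outlier sample per sex, planted mature-phase effects of log2 6 (female)
#' and log2 9 (male), moderate effects in the remaining phases, and two
#' planted enriched terms per sex.
#'
#' @param seed Integer seed driving all generation.
#' @param ... Overrides for any default field (unknown fields are rejected).
#' @return Object of class `holo_sim_config`.
#' @export
sim_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    # sequence layer
    n_host_refs = 6L, n_symbiont_refs = 6L, ref_len_range = c(3000L, 6000L),
    gc_host = 0.415, gc_symbiont = 0.506, gc_other = 0.44,
    n_contigs = 500L, contig_len_range = c(300L, 1500L),
    frac_host = 0.55, frac_symbiont = 0.28, frac_other = 0.11,
    divergence = 0.03,
    n_dup_groups = 12L, dup_group_size_range = c(2L, 5L), dup_copy_mut = 0.005,
    # expression layer
    n_genes = 2000L, sexes = c("F", "M"),
    phases = c("early", "middle", "late", "mature"), n_colonies = 3L,
    baseline_meanlog = log(50), baseline_sdlog = 1.5,
    planted_meanlog = log(100), planted_sdlog = 0.5,
    lib_factor_range = c(0.7, 1.3), dispersion = 0.1,
    n_de_mature = c(F = 40L, M = 30L), effect_mature = c(F = 6, M = 9),
    n_de_other_phase = 10L, effect_other_phase = 3,
    n_outliers_per_sex = 1L,
    # term layer
    n_terms = 50L, term_size_range = c(10L, 60L),
    n_planted_terms = 2L, planted_term_frac = 0.6
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown simulation config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  with(cfg, {
    stopifnot(gc_host >= 0, gc_host <= 1, gc_symbiont >= 0, gc_symbiont <= 1,
              divergence >= 0, divergence <= 1,
              frac_host + frac_symbiont + frac_other <= 1,
              n_colonies >= 2L, dispersion >= 0)
  })
  structure(cfg, class = "holo_sim_config")
}

# Independent deterministic seed per generation stage.
stage_seed <- function(cfg, offset) {
  as.integer((as.numeric(cfg$seed) * 7919 + offset) %% .Machine$integer.max)
}

random_seq <- function(len, gc) {
  paste(sample(c("A", "T", "G", "C"), len, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# Point-mutate a sequence: each base substituted with prob `rate` to one of
# the three other bases.
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(chars)) < rate)
  if (length(hit) > 0L) {
    bases <- c("A", "C", "G", "T")
    chars[hit] <- vapply(chars[hit], function(b)
      sample(setdiff(bases, b), 1L), character(1))
  }
  paste(chars, collapse = "")
}

#' Generate host and symbiont reference sequences
#'
#' i.i.d. bases with GC-weighted composition per class, so realised mean GC
#' concentrates near the class target.
#'
#' @param config A [sim_config()].
#' @return List with `host` and `symbiont` named sequence vectors.
#' @export
gen_references <- function(config) {
  set.seed(stage_seed(config, 1L))
  lens_h <- sample(config$ref_len_range[1]:config$ref_len_range[2],
                   config$n_host_refs, replace = TRUE)
  lens_s <- sample(config$ref_len_range[1]:config$ref_len_range[2],
                   config$n_symbiont_refs, replace = TRUE)
  host <- setNames(vapply(lens_h, random_seq, character(1), gc = config$gc_host),
                   sprintf("host_ref_%02d", seq_along(lens_h)))
  symbiont <- setNames(vapply(lens_s, random_seq, character(1),
                              gc = config$gc_symbiont),
                       sprintf("sym_ref_%02d", seq_along(lens_s)))
  list(host = host, symbiont = symbiont)
}

ref_subsequence <- function(refs, len) {
  ref <- refs[[sample(length(refs), 1L)]]
  len <- min(len, nchar(ref))
  start <- sample(nchar(ref) - len + 1L, 1L)
  substr(ref, start, start + len - 1L)
}

#' Generate contigs with ground truth
#'
#' Host and symbiont contigs are subsequences of their references carrying
#' point mutations at the configured divergence; duplicate groups are
#' re-mutated copies of a single draw; chimeras concatenate a host and a
#' symbiont subsequence; "other" contigs are fresh random sequences. The
#' returned truth table records origin, duplicate group, and chimera status
#' for every contig.
#'
#' @param config A [sim_config()].
#' @param refs References from [gen_references()].
#' @return List with `contigs` (named vector, shuffled order) and `truth`
#'   (data.frame `contig_id`, `origin`, `dup_group`, `is_chimera`).
#' @export
gen_contigs <- function(config, refs) {
  set.seed(stage_seed(config, 2L))
  n <- config$n_contigs
  n_host <- round(config$frac_host * n)
  n_sym <- round(config$frac_symbiont * n)
  n_other <- round(config$frac_other * n)
  n_chim <- n - n_host - n_sym - n_other
  rlen <- function() sample(config$contig_len_range[1]:config$contig_len_range[2], 1L)

  seqs <- character(0); origin <- character(0)
  dup_group <- integer(0); is_chim <- logical(0)
  add <- function(s, o, g = NA_integer_, ch = FALSE) {
    seqs <<- c(seqs, s); origin <<- c(origin, o)
    dup_group <<- c(dup_group, g); is_chim <<- c(is_chim, ch)
  }

  # duplicate groups live inside the host class
  sizes <- sample(config$dup_group_size_range[1]:config$dup_group_size_range[2],
                  config$n_dup_groups, replace = TRUE)
  n_dup_members <- sum(sizes)
  if (n_dup_members > n_host) stop("duplicate groups exceed host contig budget")
  for (g in seq_len(config$n_dup_groups)) {
    base <- mutate_seq(ref_subsequence(refs$host, rlen()), config$divergence)
    lens <- sort(sample(seq(0.9, 1, length.out = 50), sizes[g]),
                 decreasing = TRUE)  # trim copies so lengths differ
    for (m in seq_len(sizes[g])) {
      copy <- substr(base, 1L, max(50L, round(lens[m] * nchar(base))))
      add(mutate_seq(copy, config$dup_copy_mut), "host", g = g)
    }
  }
  for (i in seq_len(n_host - n_dup_members)) {
    add(mutate_seq(ref_subsequence(refs$host, rlen()), config$divergence), "host")
  }
  for (i in seq_len(n_sym)) {
    add(mutate_seq(ref_subsequence(refs$symbiont, rlen()), config$divergence),
        "symbiont")
  }
  for (i in seq_len(n_other)) {
    add(random_seq(rlen(), config$gc_other), "other")
  }
  for (i in seq_len(n_chim)) {
    half <- max(150L, rlen() %/% 2L)
    add(paste0(
      mutate_seq(ref_subsequence(refs$host, half), config$divergence),
      mutate_seq(ref_subsequence(refs$symbiont, half), config$divergence)
    ), "ambiguous", ch = TRUE)
  }
  ids <- sprintf("contig%04d", seq_along(seqs))
  names(seqs) <- ids
  truth <- data.frame(contig_id = ids, origin = origin, dup_group = dup_group,
                      is_chimera = is_chim, stringsAsFactors = FALSE)
  shuffle <- sample(length(seqs))
  list(contigs = seqs[shuffle], truth = truth[shuffle, , drop = FALSE])
}

#' Generate a phase-structured count matrix with ground truth
#'
#' Counts are negative binomial with log-normal gene baselines, per-sample
#' library-size factors, and variance mu + phi * mu^2. Planted genes have
#' their mean multiplied by 2^effect in their phase within one sex; planted
#' genes are drawn from a moderately-expressed baseline so fold-change
#' filters act on expressed genes, as they do in real data. Outlier samples
#' are generated from a permuted gene profile, which depth normalisation
#' cannot absorb.
#'
#' @param config A [sim_config()].
#' @return List with `counts` (a [count_matrix()]), `truth` (data.frame
#'   `gene`, `sex`, `phase`, `log2fc` for planted genes) and `outliers`
#'   (sample ids).
#' @export
gen_counts <- function(config) {
  set.seed(stage_seed(config, 3L))
  genes <- sprintf("gene%04d", seq_len(config$n_genes))
  meta <- expand.grid(colony = seq_len(config$n_colonies),
                      phase = config$phases, sex = config$sexes,
                      stringsAsFactors = FALSE)
  meta$sample <- sprintf("%s_%s_c%d", meta$sex, meta$phase, meta$colony)
  meta <- meta[, c("sample", "sex", "phase", "colony")]

  baseline <- exp(rnorm(config$n_genes, config$baseline_meanlog,
                        config$baseline_sdlog))
  names(baseline) <- genes

  # plant effects on disjoint gene sets, per sex
  planted <- data.frame(gene = character(0), sex = character(0),
                        phase = character(0), log2fc = numeric(0),
                        stringsAsFactors = FALSE)
  pool <- genes
  total_planted <- sum(config$n_de_mature) +
    config$n_de_other_phase * length(config$sexes) *
      (length(config$phases) - 1)
  if (total_planted > config$n_genes) {
    stop("planted DE genes (", total_planted, ") exceed n_genes (",
         config$n_genes, ")")
  }
  for (sex in config$sexes) {
    for (phase in config$phases) {
      n_p <- if (phase == "mature") config$n_de_mature[[sex]]
             else config$n_de_other_phase
      if (n_p == 0L) next
      eff <- if (phase == "mature") config$effect_mature[[sex]]
             else config$effect_other_phase
      g <- sample(pool, n_p)
      pool <- setdiff(pool, g)
      planted <- rbind(planted, data.frame(
        gene = g, sex = sex, phase = phase, log2fc = eff,
        stringsAsFactors = FALSE))
    }
  }
  # planted genes get a moderately-expressed baseline
  baseline[unique(planted$gene)] <- exp(rnorm(length(unique(planted$gene)),
                                              config$planted_meanlog,
                                              config$planted_sdlog))

  lib_factor <- runif(nrow(meta), config$lib_factor_range[1],
                      config$lib_factor_range[2])
  outliers <- character(0)
  for (sex in config$sexes) {
    idx <- which(meta$sex == sex)
    outliers <- c(outliers, meta$sample[idx[seq_len(config$n_outliers_per_sex)]])
  }

  size <- if (config$dispersion > 0) 1 / config$dispersion else Inf
  counts <- matrix(0L, nrow = config$n_genes, ncol = nrow(meta),
                   dimnames = list(genes, meta$sample))
  for (j in seq_len(nrow(meta))) {
    mu <- baseline
    if (meta$sample[j] %in% outliers) {
      mu <- setNames(baseline[sample(length(baseline))], genes)
    } else {
      sel <- planted[planted$sex == meta$sex[j] & planted$phase == meta$phase[j], ]
      if (nrow(sel) > 0L) mu[sel$gene] <- mu[sel$gene] * 2^sel$log2fc
    }
    mu <- mu * lib_factor[j]
    counts[, j] <- if (is.finite(size)) rnbinom(config$n_genes, mu = mu, size = size)
                   else rpois(config$n_genes, mu)
  }
  list(counts = count_matrix(counts, meta), truth = planted,
       outliers = outliers)
}

#' Generate a term map with planted enriched terms
#'
#' Random terms of configured sizes over the gene universe, plus
#' `n_planted_terms` per sex drawing `planted_term_frac` of their genes from
#' that sex's planted mature-phase gene set, giving large true fold
#' enrichment by construction.
#'
#' @param config A [sim_config()].
#' @param counts_truth Planted-gene truth from [gen_counts()].
#' @return List with `term_map` (data.frame `term`, `gene`, `category`) and
#'   `planted_terms` (data.frame `term`, `sex`).
#' @export
gen_term_map <- function(config, counts_truth) {
  set.seed(stage_seed(config, 4L))
  genes <- sprintf("gene%04d", seq_len(config$n_genes))
  rows <- list()
  for (t in seq_len(config$n_terms)) {
    sz <- sample(config$term_size_range[1]:config$term_size_range[2], 1L)
    rows[[t]] <- data.frame(term = sprintf("T%03d", t),
                            gene = sample(genes, sz),
                            stringsAsFactors = FALSE)
  }
  planted_terms <- data.frame(term = character(0), sex = character(0),
                              stringsAsFactors = FALSE)
  tid <- config$n_terms
  for (sex in config$sexes) {
    target <- counts_truth$gene[counts_truth$sex == sex &
                                counts_truth$phase == "mature"]
    if (length(target) == 0L) next
    for (p in seq_len(config$n_planted_terms)) {
      tid <- tid + 1L
      sz <- sample(config$term_size_range[1]:config$term_size_range[2], 1L)
      n_from <- min(length(target), max(1L, round(config$planted_term_frac * sz)))
      g <- c(sample(target, n_from),
             sample(setdiff(genes, target), sz - n_from))
      rows[[tid]] <- data.frame(term = sprintf("T%03d", tid), gene = g,
                                stringsAsFactors = FALSE)
      planted_terms <- rbind(planted_terms, data.frame(
        term = sprintf("T%03d", tid), sex = sex, stringsAsFactors = FALSE))
    }
  }
  term_map <- do.call(rbind, rows)
  term_map$category <- "BP"
  list(term_map = term_map, planted_terms = planted_terms)
}

#' Generate a complete synthetic holobiont dataset
#'
#' Runs all generator stages under one configuration and returns every input
#' the pipeline consumes together with the full ground truth.
#'
#' @param config A [sim_config()].
#' @return List: `refs`, `contigs`, `contig_truth`, `counts`, `de_truth`,
#'   `outliers`, `term_map`, `planted_terms`, `config`.
#' @export
simulate_holobiont <- function(config = sim_config()) {
  refs <- gen_references(config)
  ct <- gen_contigs(config, refs)
  cn <- gen_counts(config)
  tm <- gen_term_map(config, cn$truth)
  list(refs = refs, contigs = ct$contigs, contig_truth = ct$truth,
       counts = cn$counts, de_truth = cn$truth, outliers = cn$outliers,
       term_map = tm$term_map, planted_terms = tm$planted_terms,
       config = config)
}
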