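nb_matrix <- function(n_genes, n_samples, seed, mu_sdlog = 1.5, size = 10) {
  set.seed(seed)
  mu <- exp(rnorm(n_genes, log(50), mu_sdlog))
  matrix(rnbinom(n_genes * n_samples, mu = rep(mu, n_samples), size = size),
         nrow = n_genes,
         dimnames = list(sprintf("g%04d", 1:n_genes),
                         sprintf("s%02d", 1:n_samples)))
}

test_that("TMM factors are 1 for pure depth differences", {
  x <- nb_matrix(500, 2, seed = 61)
  x[, 2] <- 2L * x[, 1]                 # pure depth: M == 0 everywhere
  expect_equal(unname(tmm_factors(x)), c(1, 1), tolerance = 1e-12)
  y <- cbind(a = x[, 1], b = x[, 1], c = x[, 1], d = x[, 1])
  expect_equal(unname(tmm_factors(y)), rep(1, 4), tolerance = 1e-12)
})

test_that("TMM corrects asymmetric composition and keeps geomean 1", {
  x <- nb_matrix(2000, 6, seed = 62)
  inflate <- seq_len(100)               # 5% of genes 8-fold up in sample 1
  x[inflate, 1] <- x[inflate, 1] * 8L
  f <- tmm_factors(x)
  # the trimmed mean of M for the inflated sample is negative (its
  # non-inflated genes are diluted by the extra library mass), so its
  # factor drops below 1 while the others stay near 1
  expect_lt(f[[1]], 1)
  expect_true(all(abs(f[-1] - 1) < 0.1))
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
  # M values are depth-invariant; precision weights depend mildly on
  # absolute counts, so rescaling a column moves factors only marginally
  x2 <- x; x2[, 3] <- x2[, 3] * 5L
  expect_equal(tmm_factors(x2), f, tolerance = 0.02)
})

test_that("TMM agrees with the edgeR reference implementation", {
  skip_if_not_installed("edgeR")
  for (s in 63:65) {
    x <- nb_matrix(1500, 6, seed = s)
    expect_equal(unname(tmm_factors(x)),
                 unname(edgeR::calcNormFactors(x, method = "TMM")),
                 tolerance = 1e-10)
  }
})

test_that("TMM rejects all-zero samples", {
  x <- nb_matrix(100, 3, seed = 66)
  x[, 2] <- 0L
  expect_error(tmm_factors(x), "s02")
})

test_that("CPM obeys its normalisation identities", {
  x <- matrix(c(1, 1, 2), ncol = 1, dimnames = list(c("a", "b", "c"), "s1"))
  expect_equal(unname(cpm_matrix(x)[, 1]), c(250000, 250000, 500000))
  y <- nb_matrix(300, 4, seed = 67)
  expect_equal(unname(colSums(cpm_matrix(y))), rep(1e6, 4))
  y2 <- y; y2[, 2] <- y2[, 2] * 3L
  expect_equal(cpm_matrix(y2)[, 2], cpm_matrix(y)[, 2])
})

test_that("outlier detection flags permuted profiles but not duplicates", {
  x <- nb_matrix(1000, 11, seed = 68)
  x <- cbind(x, dup = x[, 1])                      # exact duplicate
  set.seed(68)
  x[, 5] <- x[sample(nrow(x)), 5]                  # permuted profile
  out <- detect_outliers(cpm_matrix(x, tmm_factors(x)))
  expect_identical(out$flagged, "s05")
  expect_false("dup" %in% out$flagged)
  expect_error(detect_outliers(cpm_matrix(x[, 1:3])), "4 samples")
})

test_that("outlier false positives stay rare under the null", {
  n_flagged <- 0L
  for (s in 69:78) {
    x <- nb_matrix(800, 12, seed = s)
    n_flagged <- n_flagged +
      length(detect_outliers(cpm_matrix(x, tmm_factors(x)))$flagged)
  }
  expect_lt(n_flagged / (10 * 12), 0.05)
})

test_that("the across-phase ANOVA handles degenerate and planted genes", {
  phases <- rep(c("early", "middle", "late", "mature"), each = 3)
  x <- nb_matrix(1000, 12, seed = 79)
  planted <- 2:41
  mature <- phases == "mature"
  x[planted, mature] <- x[planted, mature] * 64L   # log2 FC 6
  cpm <- cpm_matrix(x, tmm_factors(x))
  cpm[1, ] <- 100                                  # flat expression profile
  de <- de_test(cpm, phases)
  expect_equal(de$p[1], 1)
  expect_false(de$is_de[1])
  expect_true(all(de$q >= de$p))
  sens <- mean(de$is_de[planted])
  expect_gte(sens, 0.9)
  expect_error(de_test(cpm[, 1:4], c("early", "early", "early", "middle")),
               "2 replicates")
})

test_that("empirical FDR stays near nominal in the planted simulation", {
  phases <- rep(c("early", "middle", "late", "mature"), each = 3)
  fd <- 0L; disc <- 0L
  for (s in 80:83) {
    x <- nb_matrix(1500, 12, seed = s)
    planted <- 1:150
    x[planted, phases == "mature"] <- x[planted, phases == "mature"] * 64L
    de <- de_test(cpm_matrix(x, tmm_factors(x)), phases)
    fd <- fd + sum(de$is_de[-planted])
    disc <- disc + sum(de$is_de)
  }
  expect_lte(fd / max(disc, 1), 1.5 * 0.05)
})

test_that("phase-specific sets apply the strict-max and fold rules", {
  fake_de <- function(means, is_de = TRUE) {
    df <- data.frame(gene = paste0("g", seq_len(nrow(means))),
                     stringsAsFactors = FALSE)
    for (i in 1:4) {
      df[[paste0("mean_cpm_", c("early", "middle", "late", "mature")[i])]] <-
        means[, i]
    }
    df$statistic <- 10; df$p <- 1e-6; df$q <- 1e-5; df$is_de <- is_de
    attr(df, "phases") <- c("early", "middle", "late", "mature")
    df
  }
  # (1,1,1,100): min pairwise log2 FC = log2(101/2) ~ 5.66 > 5
  de <- fake_de(matrix(c(1, 1, 1, 100), nrow = 1))
  sets <- phase_specific_sets(de, 5)
  expect_equal(sets$mature$specific, "g1")
  expect_equal(sets$mature$high_fc, "g1")
  # (1,1,1,200) against threshold 8: log2(201/2) ~ 6.65 < 8 fails
  sets8 <- phase_specific_sets(fake_de(matrix(c(1, 1, 1, 200), nrow = 1)), 8)
  expect_equal(sets8$mature$specific, "g1")
  expect_length(sets8$mature$high_fc, 0)
  # tied maxima disqualify; non-DE genes never enter any set
  tied <- fake_de(matrix(c(1, 1, 100, 100), nrow = 1))
  expect_length(phase_specific_sets(tied, 5)$mature$specific, 0)
  notde <- fake_de(matrix(c(1, 1, 1, 100), nrow = 1), is_de = FALSE)
  expect_length(phase_specific_sets(notde, 5)$mature$specific, 0)
})

test_that("high-FC subsets are nested in DE phase-specific sets", {
  phases <- rep(c("early", "middle", "late", "mature"), each = 3)
  x <- nb_matrix(800, 12, seed = 84)
  x[1:30, phases == "mature"] <- x[1:30, phases == "mature"] * 80L
  de <- de_test(cpm_matrix(x, tmm_factors(x)), phases)
  sets <- phase_specific_sets(de, 5)
  for (ph in names(sets)) {
    expect_true(all(sets[[ph]]$specific %in% de$gene[de$is_de]))
    expect_true(all(sets[[ph]]$high_fc %in% sets[[ph]]$specific))
  }
})

test_that("cross-sex overlap is plain set algebra on DE flags", {
  mk <- function(genes, de_genes) {
    df <- data.frame(gene = genes, statistic = 1, p = 0.5, q = 0.5,
                     is_de = genes %in% de_genes, stringsAsFactors = FALSE)
    attr(df, "phases") <- c("early", "mature")
    df
  }
  g <- paste0("g", 1:10)
  ov <- overlap_sets(mk(g, c("g1", "g2")), mk(g, "g3"))
  expect_equal(unname(ov$counts), c(2, 1, 0))
  same <- overlap_sets(mk(g, c("g1", "g2")), mk(g, c("g1", "g2")))
  expect_equal(unname(same$counts["shared"]), 2)
  expect_error(overlap_sets(mk(g, "g1"), mk(paste0("x", 1:10), "x1")),
               "universe")
})

test_that("row Z-scores normalise rows and zero out constants", {
  z <- zscore_rows(matrix(c(1, 2, 3), nrow = 1))
  expect_equal(as.vector(z), c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  zc <- zscore_rows(matrix(5, nrow = 1, ncol = 4))
  expect_equal(as.vector(zc), rep(0, 4))
  set.seed(85)
  m <- matrix(rnorm(50), nrow = 5)
  zm <- zscore_rows(m)
  expect_equal(unname(rowMeans(zm)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(sqrt(rowMeans(zm^2))), rep(1, 5), tolerance = 1e-12)
})
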