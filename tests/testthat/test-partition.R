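make_hit_row <- function(q, s, evalue, bits, alen = 100) {
  paste(q, s, "95.0", alen, 5, 0, 1, alen, 1, alen,
        format(evalue, scientific = TRUE), bits, sep = "\t")
}

test_that("hit-table parsing enforces the e-value cutoff inclusively", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(make_hit_row("c1", "ref1", 1e-2, 50),
               make_hit_row("c2", "ref1", 1e-3, 60),
               make_hit_row("c3", "ref2", 1e-10, 200)), path)
  hits <- parse_hit_table(path, "host", max_evalue = 1e-3)
  expect_setequal(hits$query_id, c("c2", "c3"))   # 1e-2 excluded, 1e-3 kept
  expect_true(all(hits$subject_db == "host"))
})

test_that("hit-table parsing reports malformed rows with line numbers", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(make_hit_row("c1", "ref1", 1e-5, 50),
               paste(rep("x", 11), collapse = "\t")), path)
  expect_error(parse_hit_table(path, "host"), "line 2")
})

test_that("k-mer screen matches the exact k-mer set oracle", {
  set.seed(48)
  host_refs <- setNames(vapply(rep(2000, 3), random_dna, character(1),
                               gc = 0.41), paste0("h", 1:3))
  sym_refs <- setNames(vapply(rep(2000, 3), random_dna, character(1),
                              gc = 0.51), paste0("s", 1:3))
  verbatim <- substr(host_refs[[1]], 101, 700)
  rand <- random_dna(1000)
  chim <- paste0(substr(host_refs[[2]], 1, 300), substr(sym_refs[[2]], 1, 300))
  contigs <- c(verb = verbatim, rand = rand, chim = chim)
  hits <- kmer_screen(contigs, host_refs, sym_refs, k = 21)
  # verbatim copy: containment 1 vs host
  vh <- hits$host[hits$host$query_id == "verb", ]
  expect_equal(nrow(vh), 1)
  expect_equal(vh$percent_identity, 100)
  expect_equal(vh$bitscore, nchar(verbatim) / 21)
  # random contig: no hits either side
  expect_false("rand" %in% hits$host$query_id)
  expect_false("rand" %in% hits$symbiont$query_id)
  # chimera hits both, with containment equal to the exact set overlap
  expect_true("chim" %in% hits$host$query_id)
  expect_true("chim" %in% hits$symbiont$query_id)
  db <- unique(unlist(lapply(host_refs, oracle_kmer_set, k = 21)))
  ck <- oracle_kmer_set(chim, 21)
  expect_equal(hits$host$percent_identity[hits$host$query_id == "chim"],
               100 * mean(ck %in% db))
})

test_that("contig assignment follows the exclusive/ambiguous/top-hit rules", {
  contigs <- c(a = "ACGT", b = "ACGT", c = "ACGT", d = "ACGT")
  hh <- data.frame(query_id = c("a", "d"), subject_id = "h",
                   percent_identity = 95, align_len = c(100L, 100L),
                   mismatches = 0L, gap_opens = 0L, qstart = 1L, qend = 100L,
                   sstart = 1L, send = 100L, evalue = c(1e-20, 1e-10),
                   bitscore = c(200, 100), stringsAsFactors = FALSE)
  sh <- data.frame(query_id = c("a", "b", "d"), subject_id = "s",
                   percent_identity = 95, align_len = c(100L, 100L, 100L),
                   mismatches = 0L, gap_opens = 0L, qstart = 1L, qend = 100L,
                   sstart = 1L, send = 100L, evalue = c(1e-20, 1e-8, 1e-10),
                   bitscore = c(150, 80, 100), stringsAsFactors = FALSE)
  res <- assign_contigs(contigs, hh, sh)
  asg <- setNames(res$assignments$branch, res$assignments$contig_id)
  expect_equal(asg[["a"]], "ambiguous_resolved_host")   # 200 beats 150
  expect_equal(asg[["b"]], "exclusive_symbiont")
  expect_equal(asg[["c"]], "no_hit")
  expect_equal(asg[["d"]], "ambiguous_resolved_host")   # full tie -> host
  calls <- setNames(res$assignments$call, res$assignments$contig_id)
  expect_equal(unname(calls[c("a", "b", "c", "d")]),
               c("host", "symbiont", "other", "host"))
  expect_equal(res$ledger$n_total, 4)
  expect_equal(res$ledger$n_ambiguous, 2)
})

test_that("assignment is invariant to contig and hit row order", {
  set.seed(49)
  refs_h <- setNames(vapply(rep(1500, 2), random_dna, character(1)),
                     c("h1", "h2"))
  refs_s <- setNames(vapply(rep(1500, 2), random_dna, character(1)),
                     c("s1", "s2"))
  contigs <- setNames(lapply(1:30, function(i) {
    src <- if (i %% 3 == 0) refs_s else refs_h
    substr(src[[1 + i %% 2]], i * 10, i * 10 + 400)
  }), sprintf("c%02d", 1:30))
  contigs <- unlist(contigs)
  hits <- kmer_screen(contigs, refs_h, refs_s)
  res1 <- assign_contigs(contigs, hits$host, hits$symbiont)
  shuf <- sample(length(contigs))
  res2 <- assign_contigs(contigs[shuf],
                         hits$host[sample(nrow(hits$host)), ],
                         hits$symbiont[sample(nrow(hits$symbiont)), ])
  a1 <- res1$assignments[order(res1$assignments$contig_id), ]
  a2 <- res2$assignments[order(res2$assignments$contig_id), ]
  rownames(a1) <- rownames(a2) <- NULL
  expect_equal(a1, a2)
  expect_equal(res1$ledger, res2$ledger)
})

test_that("without symbiont hits the rule degenerates to host/other", {
  contigs <- c(a = "ACGT", b = "ACGT")
  hh <- data.frame(query_id = "a", subject_id = "h", percent_identity = 95,
                   align_len = 100L, mismatches = 0L, gap_opens = 0L,
                   qstart = 1L, qend = 100L, sstart = 1L, send = 100L,
                   evalue = 1e-20, bitscore = 200, stringsAsFactors = FALSE)
  empty <- hh[0, ]
  res <- assign_contigs(contigs, hh, empty)
  expect_equal(sort(unique(res$assignments$call)), c("host", "other"))
  expect_equal(res$ledger$n_ambiguous, 0)
  expect_equal(res$ledger$n_symbiont_final, 0)
})

test_that("assignment rejects hits for unknown contigs", {
  hh <- data.frame(query_id = "ghost", subject_id = "h",
                   percent_identity = 95, align_len = 100L, mismatches = 0L,
                   gap_opens = 0L, qstart = 1L, qend = 100L, sstart = 1L,
                   send = 100L, evalue = 1e-20, bitscore = 200,
                   stringsAsFactors = FALSE)
  expect_error(assign_contigs(c(a = "ACGT"), hh, hh[0, ]), "ghost")
})

test_that("ledger totals derive and validate the conservation identities", {
  l <- ledger_totals(n_exclusive_host = 72238, n_exclusive_symbiont = 31353,
                     n_ambiguous_to_host = 23742,
                     n_ambiguous_to_symbiont = 19590)
  expect_equal(l$n_host_final, 95980)
  expect_equal(l$n_symbiont_final, 50943)
  expect_equal(l$n_ambiguous, 43332)
  z <- ledger_totals(0, 0, 0, 0)
  expect_true(all(unlist(z) == 0))
  expect_error(
    ledger_totals(10, 10, 5, 5, n_ambiguous = 11),
    "n_ambiguous"
  )
})

test_that("per-class GC profiles localise the class modes", {
  set.seed(50)
  host <- setNames(vapply(rep(800, 60), random_dna, character(1), gc = 0.40),
                   sprintf("h%02d", 1:60))
  sym <- setNames(vapply(rep(800, 60), random_dna, character(1), gc = 0.55),
                  sprintf("s%02d", 1:60))
  contigs <- c(host, sym)
  asg <- data.frame(contig_id = names(contigs),
                    call = rep(c("host", "symbiont"), each = 60),
                    branch = rep(c("exclusive_host", "exclusive_symbiont"),
                                 each = 60),
                    stringsAsFactors = FALSE)
  prof <- gc_profile(contigs, asg)
  expect_equal(sum(prof$all$counts), 120)
  expect_equal(sum(prof$host$counts), 60)
  expect_true(abs(prof$host$mode_percent - 40) <= 2)
  expect_true(abs(prof$symbiont$mode_percent - 55) <= 2)
  expect_true(is.na(prof$other$mode_percent))
  # uniform-GC degenerate case: every class mode in the bin containing 50
  flat <- c(x = "ATGC", y = "GCAT")
  asg2 <- data.frame(contig_id = c("x", "y"), call = c("host", "host"),
                     branch = "exclusive_host", stringsAsFactors = FALSE)
  p2 <- gc_profile(flat, asg2)
  expect_true(abs(p2$host$mode_percent - 50) <= 0.5)
})
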