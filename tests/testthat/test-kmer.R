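test_that("k-mer index of a linear graph has n-k+1 single-position entries", {
  p <- prg_from_rows(c(a = "ACGTTGCA"))
  idx <- build_graph_kmer_index(p, k = 4L)
  expect_equal(idx$n_kmers, 5L)
  keys <- ls(idx$env)
  expect_setequal(keys, c("ACGT", "CGTT", "GTTG", "TTGC", "TGCA"))
  for (k in keys) expect_equal(nrow(get(k, envir = idx$env)), 1L)
})

test_that("bubbles and deletions are enumerated exactly (brute-force oracle)", {
  # SNP bubble: every window over the bubble has both variants
  p <- prg_from_rows(c(a = "ACGTACGT", b = "ACGAACGT"))
  idx <- build_graph_kmer_index(p, k = 4L)
  want <- unique(unlist(lapply(enumerate_path_sequences(p), function(s)
    substring(s, 1:(nchar(s) - 3), 4:nchar(s)))))
  expect_setequal(ls(idx$env), want)

  # deletion bubble: k-mers spanning the gap have full length k
  pd <- prg_from_rows(c(a = "ACGTACGT", b = "ACG--CGT"))
  idxd <- build_graph_kmer_index(pd, k = 4L)
  wantd <- unique(unlist(lapply(enumerate_path_sequences(pd), function(s)
    substring(s, 1:(nchar(s) - 3), 4:nchar(s)))))
  expect_setequal(ls(idxd$env), wantd)
  expect_true(all(nchar(ls(idxd$env)) == 4L))
  expect_true("GTCG" %in% ls(idxd$env))   # spans the deletion
})

test_that("index completeness: every allele k-substring is found", {
  db <- generate_allele_db(tiny_cfg(3))
  prg <- build_prg_from_db(db, spacer_length = 50L)
  idx <- build_graph_kmer_index(prg, k = 21L)
  for (id in names(prg$paths)) {
    # per coverage run: exon-only alleles have no cross-exon walks
    for (r in prg$paths[[id]]) {
      s <- paste(r$labels[r$labels != "-"], collapse = "")
      if (nchar(s) < 21L) next
      kms <- substring(s, 1:(nchar(s) - 20L), 21L:nchar(s))
      expect_true(all(vapply(kms, exists, logical(1), envir = idx$env,
                             inherits = FALSE)))
    }
  }
})

test_that("frontier blow-up aborts with a window diagnostic", {
  set.seed(4)
  rows <- setNames(replicate(8, paste(sample(c("A", "C", "G", "T"), 40, TRUE),
                                      collapse = "")), paste0("a", 1:8))
  p <- prg_from_rows(rows)
  expect_error(build_graph_kmer_index(p, k = 31L, max_frontier = 50),
               "level")
})

test_that("background k-mer set is closed under reverse complement", {
  b1 <- build_background_kmer_set("ACGT", k = 4L)
  expect_equal(b1$n_kmers, 1L)   # own reverse complement
  b2 <- build_background_kmer_set("AAAA", k = 4L)
  expect_equal(b2$n_kmers, 2L)
  expect_true(exists("TTTT", envir = b2$env))
  b0 <- build_background_kmer_set(character(0), k = 4L)
  expect_equal(b0$n_kmers, 0L)
  # N-containing k-mers skipped
  bn <- build_background_kmer_set("ACGNACG", k = 4L)
  expect_equal(bn$n_kmers, 0L)
})

test_that("filter applies positive and negative selection with reason codes", {
  set.seed(8)
  gene <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  p <- prg_from_rows(c(a = gene))
  idx <- build_graph_kmer_index(p, k = 31L)
  bg_seq <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  thr <- filter_thresholds()

  # pair sampled verbatim from a PRG allele, empty background: kept
  bg0 <- build_background_kmer_set(character(0), 31L)
  d <- filter_read_pair(substr(gene, 1, 100),
                        prgtyper:::revcomp(substr(gene, 201, 300)),
                        idx, bg0, thr)
  expect_true(d$keep)
  expect_equal(d$positive_fraction, 1)

  # pair from unrelated background: positive selection discards it
  bg <- build_background_kmer_set(bg_seq, 31L)
  d2 <- filter_read_pair(substr(bg_seq, 1, 100), substr(bg_seq, 201, 300),
                         idx, bg, thr)
  expect_false(d2$keep)
  expect_equal(d2$reason, "positive_selection")

  # region shared verbatim between PRG and background: both negative-selection
  # clauses fail
  bg_shared <- build_background_kmer_set(c(bg_seq, gene), 31L)
  d3 <- filter_read_pair(substr(gene, 1, 100), substr(gene, 151, 250),
                         idx, bg_shared, thr)
  expect_false(d3$keep)
  expect_equal(d3$reason, "negative_selection")

  # mate shorter than k
  d4 <- filter_read_pair("ACGT", substr(gene, 1, 100), idx, bg0, thr)
  expect_false(d4$keep)
  expect_equal(d4$reason, "too_short")

  # require_unique = FALSE keeps the shared-homology pair
  d5 <- filter_read_pair(substr(gene, 1, 100), substr(gene, 151, 250),
                         idx, bg_shared, filter_thresholds(require_unique = FALSE))
  expect_true(d5$keep)
})

test_that("filter keeps all error-free pairs and >=95% at 1% error", {
  db <- generate_allele_db(small_cfg(21))
  prg <- build_prg_from_db(db, spacer_length = 100L)
  idx <- build_graph_kmer_index(prg, k = 31L)
  bg <- build_background_kmer_set(db$background, k = 31L)

  db0 <- db; db0$cfg$error_rate <- 0
  clean <- simulate_diploid_reads(db0, seed = 31, coverage = 10)
  dec <- filter_read_pairs(clean, idx, bg)
  expect_equal(mean(dec$keep), 1)

  dbe <- db; dbe$cfg$error_rate <- 0.01
  noisy <- simulate_diploid_reads(dbe, seed = 32, coverage = 100)
  expect_gte(length(noisy$id), 1000L)
  dece <- filter_read_pairs(noisy, idx, bg)
  expect_gte(mean(dece$keep), 0.95)

  # determinism: identical inputs give identical decisions
  dec2 <- filter_read_pairs(clean, idx, bg)
  expect_identical(dec, dec2)
})
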