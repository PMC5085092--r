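test_that("seeds chain k-mer hits into maximal exact matches", {
  set.seed(13)
  gene <- paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")
  p <- prg_from_rows(c(a = gene))
  idx <- build_graph_kmer_index(p, k = 31L)

  # read equal to a unique 50-character graph path: exactly one seed
  read <- substr(gene, 21, 70)
  seeds <- find_seeds(read, idx)
  fwd <- seeds[seeds$strand == "+", ]
  expect_equal(nrow(fwd), 1L)
  expect_equal(fwd$read_start, 1L)
  expect_equal(fwd$read_end, 50L)
  expect_equal(fwd$g_start, 21L)
  expect_equal(fwd$g_end, 70L)

  # one mismatch at position 51 of 100 splits the read into two seeds
  read2 <- substr(gene, 21, 120)
  ch <- strsplit(read2, "")[[1]]
  ch[51] <- setdiff(c("A", "C", "G", "T"), ch[51])[1]
  read2 <- paste(ch, collapse = "")
  seeds2 <- find_seeds(read2, idx)
  fwd2 <- seeds2[seeds2$strand == "+", ]
  expect_equal(nrow(fwd2), 2L)
  expect_setequal(fwd2$read_start, c(1L, 52L))
  expect_setequal(fwd2$read_end, c(50L, 100L))

  # read absent from the graph: no seeds
  expect_equal(nrow(find_seeds(strrep("A", 40), idx)), 0L)
})

test_that("extension reproduces closed-form scores and spans graph gaps", {
  prg <- toy_fixture_prg()
  idx <- build_graph_kmer_index(prg, k = 4L)
  params <- scoring_params(min_seed = 4L)
  s <- allele_path_sequence(prg, "TOY*01")

  # error-free read fully inside one allele path: all-match columns
  read <- substr(s, 3, 22)
  alns <- align_read_to_graph(read, constant_qual(20, 40), prg, idx, params)
  a <- alns[[1]]
  eps <- rep(1e-4, 20)   # Q40 floored at the eps floor
  expect_equal(a$score, sum(log1p(-eps)), tolerance = 1e-12)
  expect_true(all(a$op[!is.na(a$read_pos)] == 1L))

  # read spanning a graph-encoded deletion: '-' edges traversed at no cost
  read2 <- substr(s, 6, 17)
  alns2 <- align_read_to_graph(read2, constant_qual(12, 40), prg, idx, params)
  a2 <- alns2[[1]]
  expect_true(any(a2$op == 4L))
  expect_equal(a2$score, sum(log1p(-rep(1e-4, 12))), tolerance = 1e-12)

  # seed-anchored extension returns the same alignment
  seeds <- find_seeds(read2, idx, min_seed = 4L)
  seed <- seeds[seeds$strand == "+", ][1, ]
  a3 <- extend_seed(seed, read2, constant_qual(12, 40), prg, params)
  expect_equal(a3$score, a2$score)
})

test_that("graph alignment equals the brute-force path oracle", {
  set.seed(17)
  params <- scoring_params(score_drop = Inf, clip = -1e9)
  for (i in 1:25) {
    prg <- random_small_prg()
    read <- read_from_graph(prg, nmut = sample(0:2, 1))
    qual <- constant_qual(nchar(read), 30L)
    eps <- rep(1e-3, nchar(read))
    expect_equal(graph_best_score(prg, read, qual, params),
                 oracle_best_score(prg, read, eps, params),
                 tolerance = 1e-9)
  }
})

test_that("strand symmetry: the reverse complement aligns with the same score", {
  set.seed(19)
  gene <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  p <- prg_from_rows(c(a = gene))
  idx <- build_graph_kmer_index(p, k = 31L)
  read <- substr(gene, 50, 140)
  rc <- prgtyper:::revcomp(read)
  q <- constant_qual(nchar(read), 30L)
  af <- align_read_to_graph(read, q, p, idx)
  ar <- align_read_to_graph(rc, q, p, idx)
  expect_equal(af[[1]]$score, ar[[1]]$score, tolerance = 1e-12)
  expect_equal(af[[1]]$start_level, ar[[1]]$start_level)
  expect_equal(ar[[1]]$strand, "-")
})

test_that("one extra mismatch never increases the best score", {
  set.seed(23)
  gene <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  mut_gene <- strsplit(gene, "")[[1]]
  snps <- c(30L, 90L, 160L)
  for (s in snps) mut_gene[s] <- setdiff(c("A", "C", "G", "T"), mut_gene[s])[1]
  p <- prg_from_rows(c(a = gene, b = paste(mut_gene, collapse = "")))
  idx <- build_graph_kmer_index(p, k = 31L)
  read <- substr(gene, 40, 139)
  q <- constant_qual(100, 30L)
  base <- align_read_to_graph(read, q, p, idx)[[1]]$score
  for (pos in c(5L, 50L, 95L)) {
    ch <- strsplit(read, "")[[1]]
    ch[pos] <- setdiff(c("A", "C", "G", "T"), ch[pos])[1]
    mut <- paste(ch, collapse = "")
    sc <- align_read_to_graph(mut, q, p, idx)[[1]]$score
    expect_lte(sc, base)
  }
})

test_that("paired scoring multiplies candidates and models insert size", {
  set.seed(29)
  gene <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  p <- prg_from_rows(c(a = gene))
  idx <- build_graph_kmer_index(p, k = 31L)
  model <- insert_size_model(300, 30)
  params <- scoring_params()
  q <- constant_qual(100, 30L)

  r1 <- substr(gene, 1, 100)
  r2 <- prgtyper:::revcomp(substr(gene, 201, 300))
  a1 <- align_read_to_graph(r1, q, p, idx, params)
  a2 <- align_read_to_graph(r2, q, p, idx, params)

  # cartesian product: 3 x 2 candidate alignments -> 6 pairs
  pairs6 <- pair_and_score(rep(a1[1], 3), rep(a2[1], 2), model, params)
  expect_length(pairs6, 6L)

  # proper FR pair at the model mean: insert term is the density maximum
  pr <- pair_and_score(a1[1], a2[1], model, params)[[1]]
  expect_true(pr$proper)
  expect_equal(pr$insert, 300)
  expect_equal(pr$loglik - a1[[1]]$score - a2[[1]]$score,
               dnorm(300, 300, 30, log = TRUE), tolerance = 1e-12)

  # same-strand pair: improper-pair penalty instead of the insert term
  a2f <- align_read_to_graph(substr(gene, 201, 300), q, p, idx, params)
  impr <- pair_and_score(a1[1], a2f[1], model, params)[[1]]
  expect_false(impr$proper)
  expect_equal(impr$loglik - a1[[1]]$score - a2f[[1]]$score,
               params$improper_pair)
})

test_that("posterior normalization, ML selection and position qualities", {
  # single candidate: posterior 1, every per-position quality 1
  set.seed(31)
  gene <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  p <- prg_from_rows(c(a = gene))
  idx <- build_graph_kmer_index(p, k = 31L)
  model <- insert_size_model(250, 30)
  q <- constant_qual(80, 30L)
  sel <- align_read_pair(substr(gene, 1, 80), q,
                         prgtyper:::revcomp(substr(gene, 171, 250)), q,
                         p, idx, model)
  expect_equal(sum(sel$posteriors), 1, tolerance = 1e-9)
  expect_equal(sel$mapq, 1, tolerance = 1e-9)
  expect_true(all(sel$pos_quality1$qual == 1))

  # two equal-score placements (exact repeat): posteriors 0.5/0.5 and
  # per-position qualities 0.5 at the ambiguous columns
  unit <- substr(gene, 1, 60)
  dup <- paste0(unit, substr(gene, 61, 160), unit)
  pd <- prg_from_rows(c(a = dup))
  idxd <- build_graph_kmer_index(pd, k = 31L)
  qd <- constant_qual(40, 30L)
  alns <- align_read_to_graph(substr(unit, 10, 49), qd, pd, idxd)
  expect_gte(length(alns), 2L)
  prs <- pair_and_score(alns, list(), insert_size_model(100, 20))
  ps <- posterior_and_select(prs)
  expect_equal(sum(ps$posteriors), 1, tolerance = 1e-9)
  expect_equal(max(ps$posteriors), 0.5, tolerance = 1e-9)
  expect_true(all(abs(ps$pos_quality1$qual - 0.5) < 1e-9))
  # deterministic tie-break: lowest start level wins
  expect_equal(ps$aln1$start_level, 10L)

  expect_error(posterior_and_select(list()), "unmapped")
})
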